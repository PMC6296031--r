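#' Per-gene 2 x 4 factorial linear model with genotype contrasts
#'
#' Fits, gene by gene, the full-interaction cell-means model over the
#' genotype x month design by ordinary least squares, pooling the residual
#' variance across all design cells, and estimates the TG - WT contrast at
#' each month with its t statistic and two-sided p-value.
#'
#' Degenerate genes (zero pooled residual variance) are handled explicitly:
#' a zero contrast gets p = 1; a nonzero contrast with zero residual gets
#' p = 0 and is flagged in `degenerate`.
#'
#' @param signals Gene x sample log2 matrix.
#' @param meta Sample metadata with `sample_id`, `genotype` (WT/TG),
#'   `month`; rows must cover every column of `signals`.
#' @return A `factorial_fit` object with components `coefficients`
#'   (gene x month log2 fold-change matrix, TG - WT), `p_values`, `se`,
#'   `t_stats`, `sigma2`, `df`, `cell_means`, `months`, `degenerate`.
#' @export
fit_factorial <- function(signals, meta) {
  stop_if_not_matrix(signals)
  meta <- meta[match(colnames(signals), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover every sample column", call. = FALSE)
  months <- sort(unique(meta$month))
  cell <- interaction(meta$genotype, meta$month, drop = FALSE, sep = "_")
  tab <- table(meta$genotype, meta$month)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop(sprintf("empty design cell: %s x month %s",
                 rownames(tab)[empty[1, 1]], colnames(tab)[empty[1, 2]]),
         call. = FALSE)
  }
  if (any(tab < 2))
    stop("need >= 2 replicates in every genotype x month cell", call. = FALSE)
  n_cells <- nlevels(cell)
  n <- ncol(signals)
  # cell means by matrix multiplication against the cell indicator
  ind <- stats::model.matrix(~ 0 + cell)
  counts <- colSums(ind)
  cell_means <- signals %*% ind %*% diag(1 / counts, n_cells)
  colnames(cell_means) <- levels(cell)
  fitted <- cell_means[, as.integer(cell), drop = FALSE]
  rss <- rowSums((signals - fitted)^2)
  df <- n - n_cells
  sigma2 <- rss / df
  est <- p <- se <- tt <- matrix(NA_real_, nrow(signals), length(months),
                                 dimnames = list(rownames(signals), months))
  for (j in seq_along(months)) {
    m <- months[j]
    tg <- paste0("TG_", m); wt <- paste0("WT_", m)
    n_tg <- counts[paste0("cell", tg)]; n_wt <- counts[paste0("cell", wt)]
    est[, j] <- cell_means[, tg] - cell_means[, wt]
    se[, j] <- sqrt(sigma2 * (1 / n_tg + 1 / n_wt))
    tt[, j] <- est[, j] / se[, j]
    p[, j] <- 2 * stats::pt(-abs(tt[, j]), df)
  }
  degen <- sigma2 <= 0 | !is.finite(sigma2)
  if (any(degen)) {
    p[degen, ] <- ifelse(est[degen, , drop = FALSE] == 0, 1, 0)
    tt[degen, ] <- ifelse(est[degen, , drop = FALSE] == 0, 0, Inf)
  }
  structure(list(coefficients = est, p_values = p, se = se, t_stats = tt,
                 sigma2 = sigma2, df = df, cell_means = cell_means,
                 months = months, degenerate = names(which(degen))),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("Factorial fit: %d genes, months %s, %d residual df\n",
              nrow(x$coefficients), paste(x$months, collapse = "/"), x$df))
  if (length(x$degenerate))
    cat(sprintf("  %d degenerate (zero-residual) gene(s)\n",
                length(x$degenerate)))
  invisible(x)
}

#' @export
coef.factorial_fit <- function(object, ...) object$coefficients

#' @export
summary.factorial_fit <- function(object, ...) {
  out <- data.frame(
    month = object$months,
    median_log2fc = apply(object$coefficients, 2, stats::median),
    n_p_lt_05 = colSums(object$p_values < 0.05))
  rownames(out) <- NULL
  out
}

#' Call differentially expressed genes per contrast
#'
#' Applies Benjamini-Hochberg FDR control to each month's p-values
#' separately across genes ("FDR per contrast") and flags DEGs by the
#' strict double threshold fdr < alpha and |fold change| > fc_cut, where
#' fold change is the signed anti-logged value sign(lfc) * 2^|lfc|.
#'
#' @param fit A [fit_factorial()] object.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_cut Absolute fold-change threshold (default 1.5).
#' @return A `contrast_table` data frame: `gene`, `month`, `log2fc`,
#'   `fold_change`, `p_value`, `fdr`, `is_deg`.
#' @export
call_degs <- function(fit, alpha = 0.05, fc_cut = 1.5) {
  if (!inherits(fit, "factorial_fit")) stop("need a factorial_fit", call. = FALSE)
  if (!nrow(fit$coefficients)) stop("fit covers no genes", call. = FALSE)
  months <- fit$months
  rows <- lapply(seq_along(months), function(j) {
    lfc <- fit$coefficients[, j]
    p <- fit$p_values[, j]
    fdr <- stats::p.adjust(p, method = "BH")
    fc <- signed_fold_change(lfc)
    data.frame(gene = rownames(fit$coefficients), month = months[j],
               log2fc = lfc, fold_change = fc, p_value = p, fdr = fdr,
               is_deg = fdr < alpha & abs(fc) > fc_cut,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "fc_cut") <- fc_cut
  out
}

#' Summarize DEG calls: per-month counts, Venn partition, persistence
#'
#' Produces the per-month totals split by direction and by |fold change|
#' above/below 2, the union of DEGs across months, the 15-cell Venn
#' partition over month subsets, and the persistence fraction: the share of
#' earliest-month DEGs that remain DEGs at every later month.
#'
#' @param tab A `contrast_table` from [call_degs()].
#' @param fc_split Fold-change magnitude used to split counts (default 2;
#'   the split is |fc| > 2 vs <= 2).
#' @return A `deg_summary` list: `per_month`, `union`, `venn`,
#'   `persistence` (NA when no earliest-month DEGs exist).
#' @export
summarize_degs <- function(tab, fc_split = 2) {
  months <- sort(unique(tab$month))
  per_month <- do.call(rbind, lapply(months, function(m) {
    d <- tab[tab$month == m & tab$is_deg, , drop = FALSE]
    data.frame(month = m, total = nrow(d),
               up = sum(d$fold_change > 0), down = sum(d$fold_change < 0),
               n_abs_fc_gt2 = sum(abs(d$fold_change) > fc_split),
               n_abs_fc_le2 = sum(abs(d$fold_change) <= fc_split))
  }))
  deg_by_month <- lapply(months, function(m)
    tab$gene[tab$month == m & tab$is_deg])
  names(deg_by_month) <- as.character(months)
  union_genes <- sort(unique(unlist(deg_by_month)))
  # Venn cells: one per non-empty subset of months; disjoint by construction
  membership <- vapply(deg_by_month, function(g) union_genes %in% g,
                       logical(length(union_genes)))
  if (length(union_genes) == 1L) membership <- matrix(membership, nrow = 1)
  venn <- list()
  if (length(union_genes)) {
    key <- apply(membership, 1, function(b)
      paste(months[b], collapse = "_"))
    venn <- split(union_genes, key)
  }
  first <- as.character(months[1])
  early <- deg_by_month[[first]]
  persistence <- NA_real_
  if (length(early) && length(months) > 1) {
    later <- Reduce(intersect, deg_by_month[-1])
    persistence <- length(intersect(early, later)) / length(early)
  }
  structure(list(per_month = per_month, union = union_genes, venn = venn,
                 persistence = persistence), class = "deg_summary")
}

#' @export
print.deg_summary <- function(x, ...) {
  cat("DEG summary\n")
  print(x$per_month, row.names = FALSE)
  cat(sprintf("union: %d genes; persistence of earliest-month DEGs: %s\n",
              length(x$union),
              ifelse(is.na(x$persistence), "undefined",
                     sprintf("%.2f%%", 100 * x$persistence))))
  invisible(x)
}

#' Three-way DEG set comparison with direction concordance
#'
#' Intersects three signed DEG sets and reports, per common gene, whether
#' the direction of change agrees in all three.
#'
#' @param set_a,set_b,set_c Named numeric vectors of direction signs
#'   (+1 / -1) indexed by gene id.
#' @return List with `common` (gene ids), `concordant` (named logical),
#'   `n_concordant_up`, `n_concordant_down`.
#' @export
compare_deg_sets <- function(set_a, set_b, set_c) {
  common <- sort(Reduce(intersect, list(names(set_a), names(set_b), names(set_c))))
  conc <- vapply(common, function(g)
    set_a[[g]] == set_b[[g]] && set_b[[g]] == set_c[[g]], logical(1))
  list(common = common,
       concordant = conc,
       n_concordant_up = sum(conc & vapply(common, function(g) set_a[[g]] > 0, logical(1))),
       n_concordant_down = sum(conc & vapply(common, function(g) set_a[[g]] < 0, logical(1))))
}
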