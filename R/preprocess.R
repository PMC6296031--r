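#' Default QC pass ranges
#'
#' Permissive ranges for the five tracked QC metrics; each is a
#' `c(min, max)` pass interval.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_qc_thresholds <- function() {
  list(mapping_rate = c(0.7, 1),
       mapped_reads = c(1e7, Inf),
       three_prime_bias = c(0.5, 2),
       rrna_mito_fraction = c(0, 0.2),
       adapter_content = c(0, 0.1))
}

#' Exclude samples that fail QC
#'
#' A sample is excluded iff any tracked metric falls outside its pass
#' range; the report lists every violated metric per excluded sample.
#'
#' @param qc Data frame with `sample_id` and one column per metric named in
#'   `thresholds`.
#' @param thresholds Named list of `c(min, max)` pass ranges.
#' @return List with `kept` (sample ids) and `excluded` (data frame
#'   `sample_id`, `metric`, `value`).
#' @export
exclude_failed_samples <- function(qc, thresholds = default_qc_thresholds()) {
  missing <- setdiff(names(thresholds), names(qc))
  if (length(missing))
    stop(sprintf("QC table lacks metric(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (anyNA(qc[names(thresholds)]))
    stop("missing metric value(s) in QC table", call. = FALSE)
  viol <- lapply(names(thresholds), function(m) {
    rng <- thresholds[[m]]
    bad <- qc[[m]] < rng[1] | qc[[m]] > rng[2]
    if (!any(bad)) return(NULL)
    data.frame(sample_id = qc$sample_id[bad], metric = m,
               value = qc[[m]][bad], stringsAsFactors = FALSE)
  })
  excluded <- do.call(rbind, viol)
  if (is.null(excluded))
    excluded <- data.frame(sample_id = character(), metric = character(),
                           value = numeric(), stringsAsFactors = FALSE)
  excluded <- excluded[order(match(excluded$sample_id, qc$sample_id)), ,
                       drop = FALSE]
  rownames(excluded) <- NULL
  list(kept = setdiff(qc$sample_id, excluded$sample_id), excluded = excluded)
}

#' Filter low-count exons
#'
#' An exon is retained iff at most 80% of samples have fewer than
#' `min_count` reads (both bounds strict: exactly 80% low is retained, a
#' count of exactly `min_count` is not low). Genes whose exons are all
#' removed are dropped and listed.
#'
#' @param x An `exon_counts` object.
#' @param min_count Low-count threshold (default 10).
#' @param max_low_fraction Maximum tolerated fraction of low samples
#'   (default 0.8).
#' @return An `exon_counts` object with attribute `dropped_genes`.
#' @export
filter_exons <- function(x, min_count = 10, max_low_fraction = 0.8) {
  if (!nrow(x$counts) || !ncol(x$counts))
    stop("empty count matrix", call. = FALSE)
  low_frac <- rowMeans(x$counts < min_count)
  keep <- low_frac <= max_low_fraction
  kept_genes <- unique(x$exon_to_gene$gene_id[
    match(rownames(x$counts)[keep], x$exon_to_gene$exon_id)])
  dropped <- setdiff(unique(x$exon_to_gene$gene_id), kept_genes)
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$exon_to_gene <- x$exon_to_gene[x$exon_to_gene$exon_id %in%
                                       rownames(out$counts), , drop = FALSE]
  attr(out, "dropped_genes") <- dropped
  out
}

#' Robust exon-to-gene summarization for one gene
#'
#' Fits the two-way additive model log2 value = gene-sample effect + exon
#' effect robustly and returns the per-sample effect with exon effects
#' centered at zero mean. The default is median polish (alternating row and
#' column medians); Huber M-estimation is available as an option. A
#' single-exon gene returns its row unchanged.
#'
#' @param exon_log2 Numeric exon x sample matrix of log2 values for one gene.
#' @param method `"medpolish"` (default) or `"huber"`.
#' @return Numeric per-sample gene signal (named by sample).
#' @export
rollup_gene <- function(exon_log2, method = c("medpolish", "huber")) {
  method <- match.arg(method)
  if (is.null(dim(exon_log2))) exon_log2 <- matrix(exon_log2, nrow = 1)
  if (!nrow(exon_log2)) stop("no exon rows", call. = FALSE)
  if (anyNA(exon_log2)) stop("missing values in exon matrix", call. = FALSE)
  if (nrow(exon_log2) == 1L) {
    out <- exon_log2[1, ]
    names(out) <- colnames(exon_log2)
    return(out)
  }
  if (method == "medpolish") {
    # the 20-iteration cap is deliberate; hitting it is not an error
    fit <- withCallingHandlers(
      stats::medpolish(exon_log2, maxiter = 20, eps = 1e-6,
                       trace.iter = FALSE),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    # move the mean exon effect into the overall term so exon effects are
    # centered at zero mean and the sample effect is on the data scale
    out <- fit$overall + mean(fit$row) + fit$col
  } else {
    n_e <- nrow(exon_log2); n_s <- ncol(exon_log2)
    sample_f <- factor(rep(seq_len(n_s), each = n_e))
    exon_f <- factor(rep(seq_len(n_e), times = n_s))
    fit <- MASS::rlm(as.vector(exon_log2) ~ 0 + sample_f + exon_f,
                     contrasts = list(exon_f = "contr.sum"), maxit = 50)
    out <- fit$coefficients[seq_len(n_s)]
    # contr.sum leaves exon effects summing to zero already
  }
  names(out) <- colnames(exon_log2)
  out
}

#' Additive per-sample median normalization
#'
#' Shifts every sample by an additive offset so that all per-sample medians
#' equal the grand median of the per-sample medians; offsets are recorded.
#'
#' @param signals Gene x sample log2 matrix.
#' @return List with normalized `signals` and per-sample `offsets`.
#' @export
median_normalize <- function(signals) {
  stop_if_not_matrix(signals)
  if (ncol(signals) < 2) stop("need >= 2 samples", call. = FALSE)
  med <- apply(signals, 2, stats::median)
  offsets <- stats::median(med) - med
  list(signals = sweep(signals, 2, offsets, "+"), offsets = offsets)
}

#' Full exon-to-gene rollup pipeline
#'
#' Applies exon filtering, per-gene robust summarization of
#' log2(count + pseudocount), and per-sample median normalization.
#'
#' @param x An `exon_counts` object.
#' @param pseudocount Added before log2 (default 1).
#' @param method Robust fit method, see [rollup_gene()].
#' @param normalize Apply [median_normalize()] (default TRUE).
#' @return A `gene_signals` list: `signals` (gene x sample log2 matrix),
#'   `offsets`, and `dropped_genes`.
#' @export
rollup <- function(x, pseudocount = 1, method = "medpolish", normalize = TRUE) {
  filt <- filter_exons(x)
  log2m <- log2(filt$counts + pseudocount)
  genes <- unique(filt$exon_to_gene$gene_id)
  gene_of <- filt$exon_to_gene$gene_id[match(rownames(log2m),
                                             filt$exon_to_gene$exon_id)]
  signals <- matrix(NA_real_, length(genes), ncol(log2m),
                    dimnames = list(genes, colnames(log2m)))
  for (g in genes) {
    signals[g, ] <- rollup_gene(log2m[gene_of == g, , drop = FALSE],
                                method = method)
  }
  offsets <- stats::setNames(numeric(ncol(signals)), colnames(signals))
  if (normalize) {
    nm <- median_normalize(signals)
    signals <- nm$signals
    offsets <- nm$offsets
  }
  structure(list(signals = signals, offsets = offsets,
                 dropped_genes = attr(filt, "dropped_genes")),
            class = "gene_signals")
}
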