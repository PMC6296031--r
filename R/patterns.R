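#' Principal component analysis of samples
#'
#' Computes sample-level principal components over per-gene standardized
#' expression. Component signs are fixed by convention: the loading with the
#' largest magnitude is made positive. Constant (zero-variance) genes are
#' dropped before standardization.
#'
#' @param signals Gene x sample log2 matrix (>= 3 samples).
#' @return List with `scores` (sample x component), `var_fraction`,
#'   `loadings`, `dropped_constant` (gene ids).
#' @export
pca_signals <- function(signals) {
  stop_if_not_matrix(signals)
  if (ncol(signals) < 3) stop("need >= 3 samples", call. = FALSE)
  sds <- apply(signals, 1, stats::sd)
  constant <- rownames(signals)[sds == 0]
  x <- signals[sds > 0, , drop = FALSE]
  if (!nrow(x)) stop("all genes are constant", call. = FALSE)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, var_fraction = var_fraction,
       loadings = loadings, dropped_constant = constant)
}

#' Two-way hierarchical clustering of samples (and optionally genes)
#'
#' Ward linkage on Euclidean distances of per-gene standardized data, the
#' combination used for sample-level heat-map clustering. Tie-breaking is
#' deterministic via input order. Gene-side clustering gives the second
#' ordering of a two-way heat map.
#'
#' @param signals Gene x sample log2 matrix.
#' @param k Optional number of flat sample clusters to cut.
#' @param genes Also cluster genes (default FALSE).
#' @return List with `sample_hclust`, `sample_order`, optional `clusters`,
#'   and (if `genes`) `gene_hclust`, `gene_order`.
#' @export
hier_cluster_samples <- function(signals, k = NULL, genes = FALSE) {
  stop_if_not_matrix(signals)
  if (ncol(signals) < 2) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(signals, 1, stats::sd)
  x <- signals[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  out <- list(sample_hclust = hc, sample_order = colnames(signals)[hc$order])
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  if (genes) {
    ghc <- stats::hclust(stats::dist(z), method = "ward.D2")
    out$gene_hclust <- ghc
    out$gene_order <- rownames(x)[ghc$order]
  }
  out
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc An `hclust` object.
#' @param path Output file path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Temporal expression profiles per gene
#'
#' For each gene, the median expression across replicates in every
#' (genotype, month) cell, as an ordered vector (all WT cells by month,
#' then all TG cells by month), plus the standardized (zero-mean,
#' unit-variance) variant. Constant raw profiles are flagged.
#'
#' @param signals Gene x sample matrix.
#' @param meta Sample metadata (`sample_id`, `genotype`, `month`).
#' @param genes Optional subset of genes (e.g. the DEG union).
#' @return List with `profiles`, `standardized` (gene x cell matrices with
#'   columns like `WT_2`), `constant` (gene ids), `months`.
#' @export
temporal_profiles <- function(signals, meta, genes = NULL) {
  stop_if_not_matrix(signals)
  meta <- meta[match(colnames(signals), meta$sample_id), , drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(signals))
    if (length(missing))
      stop(sprintf("genes not in signals: %s", paste(utils::head(missing), collapse = ", ")),
           call. = FALSE)
    signals <- signals[genes, , drop = FALSE]
  }
  months <- sort(unique(meta$month))
  cells <- c(paste0("WT_", months), paste0("TG_", months))
  prof <- matrix(NA_real_, nrow(signals), length(cells),
                 dimnames = list(rownames(signals), cells))
  for (g in c("WT", "TG")) for (m in months) {
    sel <- meta$genotype == g & meta$month == m
    prof[, paste0(g, "_", m)] <- apply(signals[, sel, drop = FALSE], 1, stats::median)
  }
  sds <- apply(prof, 1, stats::sd)
  constant <- rownames(prof)[sds == 0]
  std <- prof
  ok <- sds > 0
  std[ok, ] <- t(scale(t(prof[ok, , drop = FALSE])))
  std[!ok, ] <- NA_real_
  list(profiles = prof, standardized = std, constant = constant,
       months = months)
}

# canonical standardized profile vectors for renumbering clusters 1..4
canonical_profiles <- function(months) {
  curves <- pattern_curves(n_months = length(months))
  t(vapply(curves, function(p) {
    v <- c(p$WT, p$TG)
    as.numeric(scale(v))
  }, numeric(2 * length(months))))
}

#' Correlation-based temporal clustering of DEG profiles
#'
#' Distance = 1 - Pearson correlation between standardized temporal
#' profiles; average-linkage hierarchical clustering cut into `k` clusters.
#' When `k = 4`, clusters are renumbered to the four canonical longitudinal
#' patterns (1: TG down / WT flat; 2: TG up / WT flat; 3: TG up-peaked /
#' WT down; 4: TG down / WT up) by maximizing the total correlation of
#' cluster median profiles with the canonical curves over all
#' renumberings. Constant-profile genes are excluded and reported.
#'
#' @param profiles Output of [temporal_profiles()].
#' @param k Number of clusters (default 4).
#' @return A `cluster_assignment` list: `assignment` (named integer),
#'   `sizes`, `medians` (cluster x cell median standardized profiles),
#'   `excluded_constant`, `renumbering`.
#' @export
temporal_clusters <- function(profiles, k = 4) {
  std <- profiles$standardized
  std <- std[!(rownames(std) %in% profiles$constant), , drop = FALSE]
  if (k > nrow(std))
    stop("k exceeds the number of clusterable genes", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(std)))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  medians <- t(vapply(seq_len(k), function(cl)
    apply(std[raw == cl, , drop = FALSE], 2, stats::median),
    numeric(ncol(std))))
  renumbering <- seq_len(k)
  if (k == 4) {
    canon <- canonical_profiles(profiles$months)
    sim <- stats::cor(t(medians), t(canon))   # cluster x pattern
    perms <- perm4()
    score <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(4), p)]))
    renumbering <- perms[which.max(score), ]  # raw cluster i -> pattern id
  }
  assignment <- stats::setNames(renumbering[raw], rownames(std))
  ord <- order(renumbering)
  medians <- medians[ord, , drop = FALSE]
  rownames(medians) <- as.character(sort(renumbering))
  structure(list(assignment = assignment,
                 sizes = table(assignment),
                 medians = medians,
                 excluded_constant = profiles$constant,
                 renumbering = renumbering,
                 hclust = hc),
            class = "cluster_assignment")
}

# all 24 permutations of 1:4
perm4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4), ]
  as.matrix(unname(p))
}

#' Gap-statistic helper for choosing the number of temporal clusters
#'
#' Compares the within-cluster dispersion of the observed clustering to
#' that of profiles with independently permuted columns, over a range of k.
#' Provided for exploration; the default analysis fixes k = 4.
#'
#' @param profiles Output of [temporal_profiles()].
#' @param k_range Candidate cluster counts.
#' @param n_ref Number of reference permutations.
#' @param seed Integer seed.
#' @return Data frame with `k`, `log_w`, `log_w_ref`, `gap`.
#' @export
gap_statistic <- function(profiles, k_range = 2:8, n_ref = 20, seed = 1L) {
  std <- profiles$standardized
  std <- std[!(rownames(std) %in% profiles$constant), , drop = FALSE]
  wk <- function(x, k) {
    d <- stats::as.dist(1 - stats::cor(t(x)))
    cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
    dm <- as.matrix(d)
    sum(vapply(unique(cl), function(g) {
      i <- which(cl == g)
      if (length(i) < 2) return(0)
      sum(dm[i, i]) / (2 * length(i))
    }, numeric(1)))
  }
  with_seed(seed, {
    refs <- lapply(seq_len(n_ref), function(i)
      apply(std, 2, sample))
    do.call(rbind, lapply(k_range, function(k) {
      lw <- log(wk(std, k))
      lwr <- mean(vapply(refs, function(r) log(wk(r, k)), numeric(1)))
      data.frame(k = k, log_w = lw, log_w_ref = lwr, gap = lwr - lw)
    }))
  })
}
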