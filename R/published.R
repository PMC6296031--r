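#' Published DEG distribution of the rTg4510 microglia study
#'
#' Per-age DEG counts (total, up, down, and the |fold change| > 2 vs <= 2
#' split) reported for the longitudinal rTg4510 vs WT microglia RNA-seq
#' study deposited as GEO GSE123467 (28 of 32 samples passing QC; DEG
#' criteria FDR < 0.05 and |fold change| > 1.5, FDR per contrast).
#'
#' @return Data frame with columns `month`, `total`, `up`, `down`,
#'   `n_abs_fc_gt2`, `n_abs_fc_le2`.
#' @export
published_deg_summary <- function() {
  data.frame(
    month = c(2, 4, 6, 8),
    total = c(368, 2564, 3689, 2950),
    up = c(293, 1760, 2101, 1952),
    down = c(75, 804, 1588, 998),
    n_abs_fc_gt2 = c(70, 1286, 2036, 1665),
    n_abs_fc_le2 = c(298, 1278, 1653, 1285))
}

#' Published headline counts of the rTg4510 microglia study
#'
#' Key reported quantities from the same study (GEO GSE123467): total
#' mapped genes, the DEG union across ages, the number of 2-month DEGs
#' persisting at every later age, the four temporal cluster sizes, the
#' M1/M2 signature panel sizes and their differentially expressed subsets,
#' and the first principal component's variance share.
#'
#' @return Named list of counts and values.
#' @export
published_headline_counts <- function() {
  list(
    mapped_genes = 18588,
    deg_union = 4672,
    month2_degs = 368,
    month2_degs_persistent = 314,
    cluster_sizes = c(`1` = 640, `2` = 1761, `3` = 831, `4` = 1440),
    m1_panel = 38, m1_affected = 16,
    m2_panel = 40, m2_affected = 20,
    three_study_common_degs = 265,
    pc1_variance_pct = 27.7)
}
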