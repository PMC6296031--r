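#' Map a gene set through an ortholog table
#'
#' In `one_to_one` mode, source genes with zero or multiple target mappings
#' (or targets claimed by several sources) are dropped and reported; in
#' `all` mode, every mapping is kept.
#'
#' @param genes Character vector of source gene ids.
#' @param map Ortholog data frame (`source_gene`, `target_gene`).
#' @param mode `"one_to_one"` (default) or `"all"`.
#' @return List with `mapped` (target ids), `ambiguous` (sources with
#'   multiple targets), `missing` (sources with none).
#' @export
map_orthologs <- function(genes, map, mode = c("one_to_one", "all")) {
  mode <- match.arg(mode)
  if (mode == "one_to_one") {
    multi_src <- unique(map$source_gene[duplicated(map$source_gene)])
    multi_tgt <- unique(map$target_gene[duplicated(map$target_gene)])
    ok <- !(map$source_gene %in% multi_src) & !(map$target_gene %in% multi_tgt)
    usable <- map[ok, , drop = FALSE]
    ambiguous <- intersect(genes, c(multi_src,
                                    map$source_gene[map$target_gene %in% multi_tgt]))
  } else {
    usable <- map
    ambiguous <- character(0)
  }
  hit <- usable[usable$source_gene %in% genes, , drop = FALSE]
  missing <- setdiff(genes, c(usable$source_gene, ambiguous))
  list(mapped = sort(unique(hit$target_gene)),
       ambiguous = sort(ambiguous),
       missing = sort(missing))
}

# sample odds ratio with Haldane-Anscombe 0.5 correction on zero cells
odds_ratio <- function(a, b, c_, d) {
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

#' Overlap enrichment of DEG sets against network modules
#'
#' For every (DEG set, module) pair, builds the 2 x 2 table over the shared
#' universe, computes the cross-product odds ratio (with Haldane-Anscombe
#' 0.5 correction when any cell is zero), Fisher's exact two-sided p-value,
#' and BH q-values across all tested pairs.
#'
#' @param deg_sets Named list of (mapped) gene sets, e.g. one per age.
#' @param modules Named integer module partition over network nodes.
#' @param universe Gene universe for the tables; defaults to the module
#'   node set. Sets and modules are restricted to it.
#' @return An `overlap_result` data frame: `deg_set`, `module`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p_value`, `q_value`.
#' @export
overlap_enrichment <- function(deg_sets, modules, universe = NULL) {
  if (is.null(universe)) universe <- names(modules)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  modules <- modules[names(modules) %in% universe]
  mod_ids <- sort(unique(modules))
  out <- do.call(rbind, lapply(names(deg_sets), function(ds) {
    set <- intersect(deg_sets[[ds]], universe)
    do.call(rbind, lapply(mod_ids, function(m) {
      mem <- names(modules)[modules == m]
      a <- length(intersect(set, mem))
      b <- length(set) - a
      c_ <- length(mem) - a
      d <- length(universe) - a - b - c_
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
      data.frame(deg_set = ds, module = m, a = a, b = b, c = c_, d = d,
                 odds_ratio = odds_ratio(a, b, c_, d), p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("overlap_result", "data.frame")
  out
}

# two-sided rank-sum p: exact when both groups <= 12 and tie-free,
# else tie-corrected normal approximation with continuity correction
wilcoxon_ranksum <- function(x, y) {
  exact <- length(x) <= 12 && length(y) <= 12 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Compare network connectivity of DEG age groups
#'
#' Extracts the network degree of each mapped DEG per age group and
#' compares every pair of groups with a two-sided Wilcoxon rank-sum test
#' (exact when both groups have at most 12 genes and no ties, otherwise a
#' tie-corrected normal approximation).
#'
#' @param net A `gene_network`.
#' @param deg_sets Named list of mapped gene sets per age (>= 2 groups).
#' @return A `connectivity_comparison` list: `degrees` (list of named
#'   degree vectors), `summary` (mean/median degree per group), `tests`
#'   (data frame `group_a`, `group_b`, `p_value`; NA when a group maps to
#'   no network gene).
#' @export
connectivity_compare <- function(net, deg_sets) {
  if (length(deg_sets) < 2) stop("need >= 2 age groups", call. = FALSE)
  degrees <- lapply(deg_sets, function(s) net$degree[intersect(s, net$nodes)])
  summ <- data.frame(
    group = names(deg_sets),
    n = vapply(degrees, length, integer(1)),
    mean_degree = vapply(degrees, function(d)
      if (length(d)) mean(d) else NA_real_, numeric(1)),
    median_degree = vapply(degrees, function(d)
      if (length(d)) stats::median(d) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  combos <- utils::combn(names(deg_sets), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    ga <- combos[1, i]; gb <- combos[2, i]
    p <- if (length(degrees[[ga]]) && length(degrees[[gb]]))
      wilcoxon_ranksum(degrees[[ga]], degrees[[gb]])
    else NA_real_
    data.frame(group_a = ga, group_b = gb, p_value = p,
               stringsAsFactors = FALSE)
  }))
  structure(list(degrees = degrees, summary = summ, tests = tests),
            class = "connectivity_comparison")
}

#' @export
print.connectivity_comparison <- function(x, ...) {
  cat("Connectivity by group\n")
  print(x$summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
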