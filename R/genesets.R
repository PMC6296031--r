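#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query list with the
#' hypergeometric upper tail P(X >= k), followed by Benjamini-Hochberg
#' adjustment across all tested sets. A set is significant when p < p_cut
#' and q < q_cut (defaults 0.05 and 0.1).
#'
#' Query genes outside the universe are dropped with a warning; sets are
#' restricted to the universe and empty sets after restriction are skipped.
#'
#' @param query Character vector of gene ids.
#' @param collection Named list of gene sets.
#' @param universe Character vector, the gene universe (defaults to the
#'   union of the collection).
#' @param p_cut,q_cut Significance cutoffs.
#' @return Data frame: `set`, `k` (overlap), `K` (set size), `n` (query
#'   size), `N` (universe size), `p_value`, `q_value`, `significant`.
#' @export
ora <- function(query, collection, universe = NULL,
                p_cut = 0.05, q_cut = 0.1) {
  if (is.null(universe)) universe <- sort(unique(unlist(collection)))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  if (!length(query))
    stop("empty query after restriction to the universe", call. = FALSE)
  query <- unique(query)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    if (!length(set)) return(NULL)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no non-empty sets after restriction", call. = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_cut & out$q_value < q_cut
  out[order(out$p_value, out$set), ]
}

#' Upstream-regulator activation z-scores and enrichment p-values
#'
#' For each signed regulon, over its targets that are DEGs at the chosen
#' month: z = (sum of sign matches) / sqrt(N), where a match is +1 when the
#' predicted and observed directions agree and -1 otherwise, and N is the
#' number of DEG targets. The enrichment p-value is the direction-blind
#' hypergeometric over-representation of the regulon's targets in the DEG
#' list. Regulators are then gated on p < p_cut and ranked by decreasing
#' |z| (ties broken lexicographically) to produce the top list.
#'
#' @param tab A `contrast_table` from [call_degs()].
#' @param regulons Named list of regulons (named sign vectors over targets).
#' @param month The age at which DEG calls are read.
#' @param p_cut Gate on the enrichment p-value (default 0.05).
#' @param top Size of the reported top list (default 10).
#' @return Data frame: `regulator`, `n_targets`, `n_deg_targets`, `z`,
#'   `p_value`, `selected` (in the gated top list). `z` is NA when a
#'   regulon has no DEG targets.
#' @export
upstream_regulators <- function(tab, regulons, month, p_cut = 0.05, top = 10) {
  sub <- tab[tab$month == month, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("no contrasts at month %s", month), call. = FALSE)
  universe <- sub$gene
  deg <- sub[sub$is_deg, , drop = FALSE]
  obs_sign <- stats::setNames(sign(deg$log2fc), deg$gene)
  N_univ <- length(universe)
  n_deg <- nrow(deg)
  rows <- lapply(names(regulons), function(r) {
    reg <- regulons[[r]]
    reg <- reg[names(reg) %in% universe]
    targets_deg <- intersect(names(reg), names(obs_sign))
    N <- length(targets_deg)
    z <- if (N > 0) {
      sum(ifelse(reg[targets_deg] == obs_sign[targets_deg], 1, -1)) / sqrt(N)
    } else NA_real_
    K <- length(reg)
    p <- if (K > 0)
      stats::phyper(N - 1, K, N_univ - K, n_deg, lower.tail = FALSE)
    else NA_real_
    data.frame(regulator = r, n_targets = K, n_deg_targets = N, z = z,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  gated <- out[!is.na(out$p_value) & out$p_value < p_cut & !is.na(out$z), ,
               drop = FALSE]
  gated <- gated[order(-abs(gated$z), gated$regulator), , drop = FALSE]
  top_ids <- utils::head(gated$regulator, top)
  out$selected <- out$regulator %in% top_ids
  out[order(-abs(out$z), out$regulator, na.last = TRUE), ]
}
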