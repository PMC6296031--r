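#' Pairwise mutual information with equal-frequency binning
#'
#' Discretizes each gene into ceiling(sqrt(n)) equal-frequency bins
#' (rank-based, deterministic under ties) and computes the binned mutual
#' information (nats) for every gene pair, with the Miller-Madow
#' small-sample bias correction. The correction matters: the plug-in
#' estimator's upward bias is roughly constant across pairs and would
#' otherwise flatten the relative differences that DPI pruning relies on.
#'
#' @param data Gene x sample numeric matrix.
#' @param bins Number of bins (default `ceiling(sqrt(n_samples))`).
#' @return Symmetric gene x gene MI matrix with zero diagonal.
#' @export
mutual_information <- function(data, bins = NULL) {
  stop_if_not_matrix(data, "data")
  n <- ncol(data)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  disc <- t(apply(data, 1, function(x) {
    ceiling(rank(x, ties.method = "first") * bins / n)
  }))
  p <- nrow(data)
  mi <- matrix(0, p, p, dimnames = list(rownames(data), rownames(data)))
  logn <- log(n)
  marg <- lapply(seq_len(p), function(i) tabulate(disc[i, ], bins))
  for (i in seq_len(p - 1)) {
    di <- disc[i, ]
    mi_i <- marg[[i]]
    for (j in (i + 1):p) {
      joint <- tabulate(di + bins * (disc[j, ] - 1L), bins * bins)
      nz <- joint > 0
      pj <- joint[nz] / n
      # expected joint under independence for the occupied cells
      cell <- which(nz)
      ri <- ((cell - 1L) %% bins) + 1L
      cj <- ((cell - 1L) %/% bins) + 1L
      ei <- (mi_i[ri] / n) * (marg[[j]][cj] / n)
      v <- sum(pj * log(pj / ei))
      # Miller-Madow: subtract (K_xy - K_x - K_y + 1) / 2n over occupied bins
      kx <- sum(mi_i > 0)
      ky <- sum(marg[[j]] > 0)
      v <- v - (sum(nz) - kx - ky + 1) / (2 * n)
      mi[i, j] <- mi[j, i] <- max(v, 0)
    }
  }
  mi
}

#' Data-processing-inequality pruning of an MI matrix
#'
#' For every triangle, the weakest edge is zeroed when it falls below
#' (1 - eps) of the minimum of the other two edges — the ARACNe indirect-
#' interaction filter.
#'
#' @param mi Symmetric MI matrix.
#' @param eps DPI tolerance (default 0.15).
#' @return Pruned MI matrix.
#' @export
dpi_prune <- function(mi, eps = 0.15) {
  p <- nrow(mi)
  remove <- matrix(FALSE, p, p)
  for (k in seq_len(p)) {
    # min(mi[i,k], mi[j,k]) for all pairs (i, j)
    thr <- (1 - eps) * outer(mi[, k], mi[, k], pmin)
    cand <- mi < thr
    cand[k, ] <- FALSE
    cand[, k] <- FALSE
    remove <- remove | cand
  }
  diag(remove) <- FALSE
  mi[remove] <- 0
  mi
}

# per-node sparse neighborhood regression via glmnet, lambda chosen by BIC
# along the path; returns |coefficient| weights symmetrized by max
neighborhood_weights <- function(data, alpha) {
  p <- nrow(data)
  n <- ncol(data)
  w <- matrix(0, p, p, dimnames = list(rownames(data), rownames(data)))
  x_all <- t(data)
  for (i in seq_len(p)) {
    y <- x_all[, i]
    x <- x_all[, -i, drop = FALSE]
    fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = TRUE,
                          nlambda = 50)
    pred <- stats::predict(fit, newx = x)
    rss <- colSums((pred - y)^2)
    df <- fit$df
    bic <- n * log(pmax(rss, 1e-12) / n) + (df + 1) * log(n)
    beta <- as.numeric(fit$beta[, which.min(bic)])
    w[i, -i] <- abs(beta)
  }
  pmax(w, t(w))
}

# maximum-relevance minimum-redundancy forward selection on an MI matrix
mrmr_weights <- function(mi, max_sel = 10) {
  p <- nrow(mi)
  w <- matrix(0, p, p, dimnames = dimnames(mi))
  for (t in seq_len(p)) {
    rest <- setdiff(seq_len(p), t)
    selected <- integer(0)
    for (step in seq_len(min(max_sel, length(rest)))) {
      cand <- setdiff(rest, selected)
      score <- vapply(cand, function(j) {
        red <- if (length(selected)) mean(mi[j, selected]) else 0
        mi[t, j] - red
      }, numeric(1))
      best <- which.max(score)
      if (score[best] <= 0) break
      j <- cand[best]
      w[t, j] <- max(w[t, j], score[best])
      selected <- c(selected, j)
    }
  }
  pmax(w, t(w))
}

#' Base co-expression network inference methods
#'
#' Computes one symmetric non-negative weight matrix per method:
#' \describe{
#'   \item{corr_adjacency}{soft-threshold correlation adjacency |r|^beta
#'     (WGCNA-style; `beta` default 6).}
#'   \item{mi_aracne}{binned mutual information with DPI pruning
#'     (`eps` default 0.15).}
#'   \item{lasso_neighborhood, ridge_neighborhood}{per-node sparse / ridge
#'     regression on all other genes, per-node penalty chosen by BIC,
#'     weights |coefficient| symmetrized by the larger of the two directed
#'     magnitudes.}
#'   \item{mrnet_like}{max-relevance min-redundancy forward selection on
#'     the MI matrix.}
#'   \item{c3net_like}{each node keeps only its maximum-MI partner.}
#' }
#'
#' @param method One of the method ids above.
#' @param data Gene x sample matrix.
#' @param beta Soft-threshold power for `corr_adjacency`.
#' @param eps DPI tolerance for `mi_aracne`.
#' @return Symmetric non-negative weight matrix with zero diagonal.
#' @export
infer_base <- function(method, data, beta = 6, eps = 0.15) {
  stop_if_not_matrix(data, "data")
  methods <- c("corr_adjacency", "mi_aracne", "lasso_neighborhood",
               "ridge_neighborhood", "mrnet_like", "c3net_like")
  if (!method %in% methods)
    stop(sprintf("unknown method '%s'; use one of: %s", method,
                 paste(methods, collapse = ", ")), call. = FALSE)
  w <- switch(method,
    corr_adjacency = abs(stats::cor(t(data)))^beta,
    mi_aracne = dpi_prune(mutual_information(data), eps = eps),
    lasso_neighborhood = neighborhood_weights(data, alpha = 1),
    ridge_neighborhood = neighborhood_weights(data, alpha = 0),
    mrnet_like = mrmr_weights(mutual_information(data)),
    c3net_like = {
      mi <- mutual_information(data)
      keep <- matrix(FALSE, nrow(mi), ncol(mi))
      for (i in seq_len(nrow(mi))) {
        j <- which.max(mi[i, ])
        if (mi[i, j] > 0) keep[i, j] <- TRUE
      }
      keep <- keep | t(keep)
      mi * keep
    })
  diag(w) <- 0
  w
}

#' Aggregate per-method edge weights into mean ranks
#'
#' Within each method, edges are ranked by descending weight (1 =
#' strongest, ties averaged) over the common pair universe; the aggregate
#' is the arithmetic mean rank across methods. Rows are ordered by
#' (mean_rank, lexicographic pair id), deterministically.
#'
#' @param weights Named list of symmetric weight matrices over identical
#'   gene sets (>= 2 methods).
#' @return An `edge_rank_table` data frame: `gene_a`, `gene_b`, one rank
#'   column per method, `mean_rank`.
#' @export
aggregate_ranks <- function(weights) {
  if (length(weights) < 2) stop("need >= 2 methods", call. = FALSE)
  genes <- rownames(weights[[1]])
  for (w in weights)
    if (!identical(rownames(w), genes) || !identical(colnames(w), genes))
      stop("methods cover different pair universes", call. = FALSE)
  ut <- which(upper.tri(weights[[1]]), arr.ind = TRUE)
  gene_a <- genes[ut[, 1]]
  gene_b <- genes[ut[, 2]]
  ranks <- vapply(weights, function(w)
    rank(-w[upper.tri(w)], ties.method = "average"),
    numeric(nrow(ut)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  colnames(ranks) <- names(weights)
  out <- data.frame(gene_a = pmin(gene_a, gene_b),
                    gene_b = pmax(gene_a, gene_b),
                    ranks, mean_rank = rowMeans(ranks),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$mean_rank, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  class(out) <- c("edge_rank_table", "data.frame")
  out
}

#' BIC-guided neighborhood edge selection
#'
#' For each node, candidate neighbors are considered in aggregate mean-rank
#' order and added greedily to a linear regression of the node on its
#' selected neighbors while the Bayesian Information Criterion strictly
#' decreases (stopping at the first non-improvement or at
#' `max_neighbors`). The final edge set is the union over nodes: an edge
#' exists when selected from either endpoint.
#'
#' @param ranks An [aggregate_ranks()] table covering all candidate pairs.
#' @param data Gene x sample matrix.
#' @param max_neighbors Per-node neighborhood cap (default 10).
#' @return A `gene_network` list: `nodes`, `edges` (data frame `gene_a`,
#'   `gene_b`, `mean_rank`), `degree`, and `neighborhoods` (the per-node
#'   selected neighbor sets before the union).
#' @export
select_edges_bic <- function(ranks, data, max_neighbors = 10) {
  stop_if_not_matrix(data, "data")
  n <- ncol(data)
  if (n <= max_neighbors + 1)
    stop("need n_samples > max_neighbors + 1 for BIC selection", call. = FALSE)
  genes <- rownames(data)
  x_all <- t(data)
  bic_of <- function(y, xmat) {
    fit <- stats::lm.fit(cbind(1, xmat), y)
    rss <- sum(fit$residuals^2)
    n * log(max(rss, 1e-12) / n) + (ncol(xmat) + 1 + 1) * log(n)
  }
  selected <- vector("list", length(genes))
  names(selected) <- genes
  for (g in genes) {
    inc <- ranks[ranks$gene_a == g | ranks$gene_b == g, , drop = FALSE]
    cand <- ifelse(inc$gene_a == g, inc$gene_b, inc$gene_a)
    y <- x_all[, g]
    cur <- character(0)
    cur_bic <- bic_of(y, matrix(numeric(0), n, 0))
    for (cnd in cand) {
      if (length(cur) >= max_neighbors) break
      b <- bic_of(y, x_all[, c(cur, cnd), drop = FALSE])
      if (b < cur_bic) {
        cur <- c(cur, cnd)
        cur_bic <- b
      } else break
    }
    selected[[g]] <- cur
  }
  pairs <- unique(do.call(rbind, lapply(genes, function(g) {
    if (!length(selected[[g]])) return(NULL)
    data.frame(gene_a = pmin(g, selected[[g]]),
               gene_b = pmax(g, selected[[g]]), stringsAsFactors = FALSE)
  })))
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  rkey <- paste(ranks$gene_a, ranks$gene_b, sep = "|")
  pairs$mean_rank <- ranks$mean_rank[match(key, rkey)]
  pairs <- pairs[order(pairs$mean_rank, pairs$gene_a, pairs$gene_b), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  degree <- stats::setNames(integer(length(genes)), genes)
  tab <- table(c(pairs$gene_a, pairs$gene_b))
  degree[names(tab)] <- as.integer(tab)
  structure(list(nodes = genes, edges = pairs, degree = degree,
                 neighborhoods = selected),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d nodes, %d edges, mean degree %.2f\n",
              length(x$nodes), nrow(x$edges), mean(x$degree)))
  if (!is.null(x$modules))
    cat(sprintf("  %d modules\n", length(unique(x$modules))))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = net$nodes)
}

#' Consensus module detection over multiple community algorithms
#'
#' Runs several graph community-detection algorithms, builds the node-pair
#' co-assignment frequency matrix, keeps pairs co-assigned in at least
#' `threshold` of the methods as a consensus graph, and partitions that
#' graph with Louvain under a fixed seed. Modules are numbered by
#' decreasing size.
#'
#' @param net A `gene_network`.
#' @param methods Subset of `c("louvain", "walktrap", "fast_greedy",
#'   "label_propagation")`, at least two.
#' @param threshold Consensus co-assignment frequency (default 0.5).
#' @param seed Seed fixing the stochastic algorithms and the final pass.
#' @return List with `partition` (named integer module ids), `consensus`
#'   (node x node co-assignment frequency matrix), `per_method`
#'   memberships.
#' @export
consensus_modules <- function(net,
                              methods = c("louvain", "walktrap",
                                          "fast_greedy", "label_propagation"),
                              threshold = 0.5, seed = 42L) {
  known <- c("louvain", "walktrap", "fast_greedy", "label_propagation")
  if (!all(methods %in% known) || length(methods) < 2)
    stop("need >= 2 methods from the implemented set", call. = FALSE)
  g <- as_igraph(net)
  nodes <- net$nodes
  run <- function(m) with_seed(seed + match(m, known), {
    comm <- switch(m,
      louvain = igraph::cluster_louvain(g),
      walktrap = igraph::cluster_walktrap(g),
      fast_greedy = igraph::cluster_fast_greedy(g),
      label_propagation = igraph::cluster_label_prop(g))
    igraph::membership(comm)[nodes]
  })
  memberships <- lapply(stats::setNames(methods, methods), run)
  co <- Reduce(`+`, lapply(memberships, function(m)
    outer(m, m, `==`) * 1)) / length(methods)
  dimnames(co) <- list(nodes, nodes)
  diag(co) <- 1
  keep <- which(co >= threshold & upper.tri(co), arr.ind = TRUE)
  cg <- igraph::graph_from_data_frame(
    data.frame(from = nodes[keep[, 1]], to = nodes[keep[, 2]]),
    directed = FALSE, vertices = nodes)
  final <- with_seed(seed, igraph::membership(igraph::cluster_louvain(cg)))
  final <- final[nodes]
  # renumber by decreasing size, ties by smallest member id
  sizes <- table(final)
  first_member <- vapply(names(sizes), function(id)
    min(nodes[final == id]), character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  partition <- stats::setNames(as.integer(relabel[as.character(final)]), nodes)
  list(partition = partition, consensus = co, per_method = memberships)
}

#' Cell-type annotation of network modules by marker enrichment
#'
#' Marker sets are first disjointified (genes appearing in more than one
#' set are dropped). Each module is tested against each marker set with
#' Fisher's exact test over the node universe; the module label is the
#' most-enriched cell type if its BH q-value is below `q_cut`, otherwise
#' "unassigned".
#'
#' @param partition Named integer module assignment over network nodes.
#' @param markers Named list of marker gene sets (cell types).
#' @param q_cut BH q-value threshold (default 0.05).
#' @return Data frame: `module`, `celltype`, `p_value`, `q_value`.
#' @export
annotate_celltypes <- function(partition, markers, q_cut = 0.05) {
  universe <- names(partition)
  counts <- table(unlist(lapply(markers, unique)))
  shared <- names(counts)[counts > 1]
  markers <- lapply(markers, function(s)
    intersect(setdiff(unique(s), shared), universe))
  modules <- sort(unique(partition))
  tests <- do.call(rbind, lapply(modules, function(mod) {
    mem <- universe[partition == mod]
    do.call(rbind, lapply(names(markers), function(ct) {
      mk <- markers[[ct]]
      a <- length(intersect(mem, mk))
      b <- length(setdiff(mem, mk))
      c_ <- length(setdiff(mk, mem))
      d <- length(universe) - a - b - c_
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                              alternative = "greater")$p.value
      data.frame(module = mod, celltype = ct, overlap = a, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests$q_value <- stats::p.adjust(tests$p_value, method = "BH")
  out <- do.call(rbind, lapply(modules, function(mod) {
    sub <- tests[tests$module == mod, , drop = FALSE]
    best <- sub[order(sub$p_value, sub$celltype), ][1, ]
    if (is.na(best$q_value) || best$q_value >= q_cut || best$overlap == 0)
      best$celltype <- "unassigned"
    best[, c("module", "celltype", "p_value", "q_value")]
  }))
  rownames(out) <- NULL
  out
}

#' Write a network edge list with per-method and mean ranks
#' @param ranks An `edge_rank_table`.
#' @param path Output TSV path.
#' @export
write_edge_ranks <- function(ranks, path) {
  utils::write.table(ranks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
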