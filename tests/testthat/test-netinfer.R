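test_that("correlation adjacency hits its exact and null limits", {
  # rank-1 two-gene data: |r| = 1, weight 1 at any power
  x <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  colnames(x) <- paste0("s", 1:5)
  w <- infer_base("corr_adjacency", x, beta = 1)
  expect_equal(w["a", "b"], 1, tolerance = 1e-12)
  expect_equal(diag(w), c(a = 0, b = 0))

  # independent standard normals, n = 500: 95th percentile of weights small
  set.seed(1)
  xn <- matrix(rnorm(40 * 500), 40, 500,
               dimnames = list(sprintf("g%02d", 1:40), sprintf("s%03d", 1:500)))
  wn <- infer_base("corr_adjacency", xn, beta = 1)
  expect_lt(quantile(wn[upper.tri(wn)], 0.95), 0.15)

  expect_error(infer_base("nope", x), "unknown method")
})

test_that("DPI removes the indirect edge of a Markov chain", {
  removed <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 300
    x <- rnorm(n)
    y <- x + rnorm(n, sd = 0.5)
    z <- y + rnorm(n, sd = 0.5)
    d <- rbind(X = x, Y = y, Z = z)
    colnames(d) <- sprintf("s%03d", 1:n)
    w <- infer_base("mi_aracne", d)
    if (w["X", "Z"] == 0 && w["X", "Y"] > 0 && w["Y", "Z"] > 0)
      removed <- removed + 1L
  }
  expect_gt(removed, 10L)   # 20-seed majority
})

test_that("mutual information is symmetric, non-negative, and informative", {
  set.seed(3)
  x <- rbind(a = rnorm(200), b = rnorm(200))
  x <- rbind(x, c = x["a", ] + rnorm(200, sd = 0.2))
  colnames(x) <- sprintf("s%03d", 1:200)
  mi <- mutual_information(x)
  expect_equal(mi, t(mi))
  expect_true(all(mi >= 0))
  expect_gt(mi["a", "c"], mi["a", "b"])   # dependent pair dominates
})

test_that("rank aggregation is order-invariant and matches brute force", {
  set.seed(4)
  genes <- sprintf("g%02d", 1:10)
  mk <- function() {
    w <- matrix(0, 10, 10, dimnames = list(genes, genes))
    w[upper.tri(w)] <- runif(45)
    w + t(w)
  }
  ws <- list(m1 = mk(), m2 = mk(), m3 = mk())
  agg <- aggregate_ranks(ws)
  # brute-force recomputation per pair
  for (row in sample(nrow(agg), 10)) {
    a <- agg$gene_a[row]; b <- agg$gene_b[row]
    manual <- mean(vapply(ws, function(w) {
      vals <- w[upper.tri(w)]
      sum(vals > w[a, b]) + (1 + sum(vals == w[a, b])) / 2
    }, numeric(1)))
    expect_equal(agg$mean_rank[row], manual, tolerance = 1e-12)
  }
  # method order is irrelevant
  agg2 <- aggregate_ranks(ws[c(3, 1, 2)])
  expect_equal(agg2$mean_rank, agg$mean_rank, tolerance = 1e-12)
  expect_identical(agg2$gene_a, agg$gene_a)

  # identical orderings aggregate to that ordering
  same <- list(a = ws$m1, b = ws$m1 * 2 + 1)
  aggs <- aggregate_ranks(same)
  expect_equal(order(aggs$mean_rank),
               order(-apply(aggs, 1, function(r)
                 ws$m1[r[["gene_a"]], r[["gene_b"]]])))

  # exactly reversed orderings: every mean rank = (E + 1) / 2
  rev2 <- list(a = ws$m1, b = max(ws$m1) - ws$m1)
  diag(rev2$b) <- 0
  aggr <- aggregate_ranks(rev2)
  expect_true(all(abs(aggr$mean_rank - (45 + 1) / 2) < 1e-12))

  bad <- ws
  rownames(bad$m2) <- colnames(bad$m2) <- rev(genes)
  expect_error(aggregate_ranks(bad), "different pair universes")
})

test_that("BIC selection stays sparse on noise, finds planted structure", {
  # pure noise under the standard three-method ensemble: mean selected
  # neighborhood size stays at/below 1
  sizes <- numeric(3)
  for (s in 1:3) {
    set.seed(30 + s)
    x <- matrix(rnorm(50 * 200), 50, 200,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%03d", 1:200)))
    agg <- aggregate_ranks(list(corr = infer_base("corr_adjacency", x),
                                mi = infer_base("mi_aracne", x),
                                lasso = infer_base("lasso_neighborhood", x)))
    net <- select_edges_bic(agg, x, max_neighbors = 10)
    sizes[s] <- mean(lengths(net$neighborhoods))
  }
  expect_lte(mean(sizes), 1)

  # a strongly coupled 10-gene module embedded in 30 noise genes: every
  # module node keeps a within-module neighbor and, averaged over seeds,
  # cross-module contamination stays below 5% of selected edges
  cross_frac <- numeric(5)
  for (s in 1:5) {
    truth <- planted_truth(genes = 40, n_modules = 1, module_size = 10,
                           deg_fraction = 0, seed = 70 + s)
    x <- generate_coexpression_samples(200, truth, noise_sd = 0.3,
                                       seed = 70 + s)
    agg <- aggregate_ranks(list(c = infer_base("corr_adjacency", x),
                                m = infer_base("mi_aracne", x),
                                l = infer_base("lasso_neighborhood", x)))
    net <- select_edges_bic(agg, x, max_neighbors = 10)
    mod_genes <- names(truth$module)[!is.na(truth$module)]
    in_mod <- net$edges$gene_a %in% mod_genes & net$edges$gene_b %in% mod_genes
    cross <- xor(net$edges$gene_a %in% mod_genes,
                 net$edges$gene_b %in% mod_genes)
    per_node_in <- vapply(mod_genes, function(g)
      any(net$edges$gene_a == g & in_mod) |
        any(net$edges$gene_b == g & in_mod), logical(1))
    expect_true(all(per_node_in))
    cross_frac[s] <- sum(cross) / max(nrow(net$edges), 1)
  }
  expect_lt(mean(cross_frac), 0.05)

  # degree conservation and determinism (reusing the last seed's run)
  expect_identical(sum(net$degree), 2L * nrow(net$edges))
  expect_identical(select_edges_bic(agg, x, max_neighbors = 10)$edges,
                   net$edges)
  expect_error(select_edges_bic(agg, x[, 1:10], max_neighbors = 10),
               "BIC")
})

test_that("consensus modules recover cliques and planted communities", {
  # two disjoint 15-cliques
  genes <- sprintf("n%02d", 1:30)
  cl <- function(idx) {
    pr <- t(combn(genes[idx], 2))
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2], stringsAsFactors = FALSE)
  }
  net <- make_network(rbind(cl(1:15), cl(16:30)), nodes = genes)
  cm <- consensus_modules(net)
  truthm <- rep(1:2, each = 15)
  expect_equal(ari(cm$partition[genes], truthm), 1)
  expect_equal(cm$consensus, t(cm$consensus))
  expect_true(all(diag(cm$consensus) == 1))

  # planted 4-block graphs: within-p 0.3, between-p 0.02, 40 nodes/module
  aris <- numeric(5)
  for (s in 1:5) {
    set.seed(50 + s)
    n <- 160
    block <- rep(1:4, each = 40)
    ids <- sprintf("v%03d", 1:n)
    pr <- t(combn(n, 2))
    pw <- ifelse(block[pr[, 1]] == block[pr[, 2]], 0.3, 0.02)
    keep <- runif(nrow(pr)) < pw
    edges <- data.frame(gene_a = ids[pr[keep, 1]], gene_b = ids[pr[keep, 2]],
                        stringsAsFactors = FALSE)
    netb <- make_network(edges, nodes = ids)
    cmb <- consensus_modules(netb, seed = 50 + s)
    aris[s] <- ari(cmb$partition[ids], block)
  }
  expect_gte(mean(aris >= 0.8), 0.8)
  expect_error(consensus_modules(net, methods = "louvain"), ">= 2 methods")
})

test_that("cell-type annotation labels pure modules and skips empty ones", {
  markers <- list(microglia = sprintf("m%02d", 1:20),
                  neuron = sprintf("n%02d", 1:20),
                  shared = character(0))
  # module 1 pure microglia, module 2 pure neuron, module 3 unrelated
  partition <- setNames(rep(1:3, each = 20),
                        c(sprintf("m%02d", 1:20), sprintf("n%02d", 1:20),
                          sprintf("x%02d", 1:20)))
  ann <- annotate_celltypes(partition, markers[1:2])
  expect_identical(ann$celltype[ann$module == 1], "microglia")
  expect_identical(ann$celltype[ann$module == 2], "neuron")
  expect_identical(ann$celltype[ann$module == 3], "unassigned")
  expect_lt(ann$q_value[ann$module == 1], 1e-6)

  # genes in more than one marker set are dropped before testing
  markers2 <- list(A = c(sprintf("m%02d", 1:20), "n01"),
                   B = sprintf("n%02d", 1:20))
  ann2 <- annotate_celltypes(partition, markers2)
  expect_identical(ann2$celltype[ann2$module == 1], "A")

  # planted 70%-purity modules are labeled correctly in most seeds
  good <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(60 + s)
    mk <- list(ct1 = sprintf("a%03d", 1:60), ct2 = sprintf("b%03d", 1:60))
    p1 <- c(sample(mk$ct1, 28), sample(mk$ct2, 12))
    p2 <- c(sample(setdiff(mk$ct2, p1), 28), sample(setdiff(mk$ct1, p1), 12))
    part <- setNames(rep(1:2, each = 40), c(p1, p2))
    a <- annotate_celltypes(part, mk)
    good <- good + sum(a$celltype == c("ct1", "ct2"))
    total <- total + 2L
  }
  expect_gte(good / total, 0.9)
})

test_that("the full ensemble pipeline recovers planted modules end-to-end", {
  aris <- numeric(3)
  for (s in 1:3) {
    truth <- planted_truth(genes = 120, n_modules = 4, module_size = 30,
                           deg_fraction = 0, seed = 400 + s)
    x <- generate_coexpression_samples(300, truth, noise_sd = 0.5,
                                       seed = 400 + s)
    w <- list(corr = infer_base("corr_adjacency", x),
              mi = infer_base("mi_aracne", x),
              lasso = infer_base("lasso_neighborhood", x))
    net <- select_edges_bic(aggregate_ranks(w), x, max_neighbors = 10)
    cm <- consensus_modules(net, seed = 400 + s)
    aris[s] <- ari(cm$partition[truth$genes], truth$module[truth$genes])
  }
  expect_true(all(aris >= 0.7))
})
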