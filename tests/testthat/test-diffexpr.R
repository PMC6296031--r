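test_that("contrasts equal cell-mean differences and recover planted shifts", {
  meta <- factorial_meta()
  planted <- list(G0001 = c(0, 0, 0, 0, 1, 1, 1, 1))  # TG +1 at every month
  x <- factorial_signals(30, meta, sigma = 0.1, planted = planted, seed = 1)
  fit <- fit_factorial(x, meta)
  # contrast algebra: estimate = mean(TG at m) - mean(WT at m)
  for (m in c(2, 4, 6, 8)) {
    tg <- meta$sample_id[meta$genotype == "TG" & meta$month == m]
    wt <- meta$sample_id[meta$genotype == "WT" & meta$month == m]
    expect_equal(unname(coef(fit)[, as.character(m)]),
                 unname(rowMeans(x[, tg]) - rowMeans(x[, wt])),
                 tolerance = 1e-10)
  }
  # planted +1 log2 shift recovered within 0.3 at every month (95% of seeds)
  hits <- 0L
  for (s in 1:40) {
    xs <- factorial_signals(5, meta, sigma = 0.1, planted = planted, seed = s)
    fs <- fit_factorial(xs, meta)
    if (all(abs(coef(fs)["G0001", ] - 1) < 0.3)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("degenerate genes follow the explicit p-value conventions", {
  meta <- factorial_meta(n_rep = 2)
  x <- matrix(5, 3, nrow(meta),
              dimnames = list(c("flat", "shifted", "noisy"), meta$sample_id))
  x["shifted", meta$genotype == "TG"] <- 6            # zero residual, nonzero
  set.seed(2); x["noisy", ] <- rnorm(nrow(meta))
  fit <- fit_factorial(x, meta)
  expect_true(all(fit$p_values["flat", ] == 1))
  expect_true(all(coef(fit)["flat", ] == 0))
  expect_true(all(fit$p_values["shifted", ] == 0))
  expect_setequal(fit$degenerate, c("flat", "shifted"))
  expect_true(all(fit$p_values["noisy", ] > 0))
})

test_that("design validation names the problem", {
  meta <- factorial_meta()
  x <- factorial_signals(4, meta, seed = 3)
  broken <- meta[!(meta$genotype == "TG" & meta$month == 4), ]
  expect_error(fit_factorial(x[, broken$sample_id], broken),
               "empty design cell")
  thin <- meta[meta$replicate == 1, ]
  expect_error(fit_factorial(x[, thin$sample_id], thin), ">= 2 replicates")
})

test_that("DEG calling enforces strict cutoffs and per-contrast BH", {
  # a gene sitting exactly at 1.5-fold is never a DEG, whatever its fdr
  months <- c(2, 4, 6, 8)
  cm <- matrix(c(rep(log2(1.5), 4), rep(3, 4)), 2, 4, byrow = TRUE,
               dimnames = list(c("boundary", "strong"), months))
  fake <- structure(list(coefficients = cm,
                         p_values = matrix(1e-12, 2, 4,
                                           dimnames = dimnames(cm)),
                         months = months), class = "factorial_fit")
  tab <- call_degs(fake)
  g1 <- tab[tab$gene == "boundary", ]
  expect_true(all(g1$fold_change == 1.5))
  expect_false(any(g1$is_deg))
  expect_true(all(tab$is_deg[tab$gene == "strong"]))
  meta <- factorial_meta()
  x <- factorial_signals(40, meta, sigma = 0.4, seed = 4)
  tab <- call_degs(fit_factorial(x, meta))
  # fdr is BH within month: matches the brute-force step-up oracle
  for (m in c(2, 8)) {
    sub <- tab[tab$month == m, ]
    expect_equal(sub$fdr, bh_oracle(sub$p_value), tolerance = 1e-12)
  }
})

test_that("BH q-values match the hand-computed toy example", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(bh_oracle(p), c(0.004, 0.02, 0.02 + 2/300, 0.8),
               tolerance = 1e-12)
  expect_equal(p.adjust(p, method = "BH"), bh_oracle(p), tolerance = 1e-12)
  # monotone in p-value rank
  set.seed(5)
  pr <- runif(100)
  q <- bh_oracle(pr)
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
})

test_that("label swap negates log2fc and preserves p-values", {
  meta <- factorial_meta()
  x <- factorial_signals(25, meta, sigma = 0.5,
                         planted = list(G0003 = c(0, 0, 0, 0, 2, 2, 1, 1)),
                         seed = 6)
  fit <- fit_factorial(x, meta)
  swapped <- meta
  swapped$genotype <- ifelse(meta$genotype == "WT", "TG", "WT")
  fit2 <- fit_factorial(x, swapped)
  expect_equal(coef(fit2), -coef(fit), tolerance = 1e-12)
  expect_equal(fit2$p_values, fit$p_values, tolerance = 1e-12)
})

test_that("null p-values are uniform and planted effects give power", {
  meta <- factorial_meta()
  x <- factorial_signals(5000, meta, sigma = 0.3, seed = 7)
  fit <- fit_factorial(x, meta)
  for (j in 1:4) {
    ks <- suppressWarnings(ks.test(fit$p_values[, j], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
  # power: planted log2fc 1.5, sigma 0.3, n = 4/cell -> >= 90% called at
  # month 8 (average over seeds)
  called <- total <- 0L
  for (s in 1:10) {
    planted <- setNames(lapply(1:50, function(i) c(rep(0, 4), rep(1.5, 4))),
                        sprintf("G%04d", 1:50))
    xs <- factorial_signals(500, meta, sigma = 0.3, planted = planted,
                            seed = 100 + s)
    tabs <- call_degs(fit_factorial(xs, meta))
    m8 <- tabs[tabs$month == 8 & tabs$gene %in% names(planted), ]
    called <- called + sum(m8$is_deg)
    total <- total + nrow(m8)
  }
  expect_gte(called / total, 0.9)
})

test_that("DEG summaries match exhaustive membership enumeration", {
  # random DEG flags over 100 genes and 4 months
  set.seed(8)
  genes <- sprintf("G%03d", 1:100)
  tab <- expand.grid(gene = genes, month = c(2, 4, 6, 8),
                     stringsAsFactors = FALSE)
  tab$log2fc <- rnorm(nrow(tab))
  tab$fold_change <- sign(tab$log2fc) * 2^abs(tab$log2fc)
  tab$p_value <- runif(nrow(tab))
  tab$fdr <- tab$p_value
  tab$is_deg <- runif(nrow(tab)) < 0.3
  class(tab) <- c("contrast_table", "data.frame")
  s <- summarize_degs(tab)
  # brute-force per-gene membership enumeration
  for (key in names(s$venn)) {
    months_in <- as.numeric(strsplit(key, "_")[[1]])
    oracle <- Filter(function(g) {
      m_of_g <- sort(tab$month[tab$gene == g & tab$is_deg])
      identical(m_of_g, sort(months_in))
    }, genes)
    expect_setequal(s$venn[[key]], oracle)
  }
  expect_setequal(unlist(s$venn), s$union)
  expect_identical(sum(lengths(s$venn)), length(s$union))   # disjoint cells
  # per-month counts are internally consistent
  expect_equal(s$per_month$up + s$per_month$down, s$per_month$total)
  expect_equal(s$per_month$n_abs_fc_gt2 + s$per_month$n_abs_fc_le2,
               s$per_month$total)
  # persistence: fraction of month-2 DEGs present at 4, 6 and 8
  early <- tab$gene[tab$month == 2 & tab$is_deg]
  later <- Reduce(intersect, lapply(c(4, 6, 8), function(m)
    tab$gene[tab$month == m & tab$is_deg]))
  expect_equal(s$persistence, length(intersect(early, later)) / length(early))
})

test_that("summary handles the no-DEG and all-persistent edge cases", {
  genes <- sprintf("G%03d", 1:10)
  tab <- expand.grid(gene = genes, month = c(2, 4), stringsAsFactors = FALSE)
  tab$log2fc <- 1; tab$fold_change <- 2; tab$p_value <- 1; tab$fdr <- 1
  tab$is_deg <- FALSE
  class(tab) <- c("contrast_table", "data.frame")
  s0 <- summarize_degs(tab)
  expect_true(all(s0$per_month$total == 0))
  expect_true(is.na(s0$persistence))
  tab$is_deg <- TRUE
  s1 <- summarize_degs(tab)
  expect_equal(s1$persistence, 1)
})

test_that("three-way DEG comparison counts concordant overlap", {
  a <- setNames(c(1, 1, 1, 1, 1, -1, -1, 1, -1), sprintf("g%d", 1:9))
  b <- setNames(c(1, 1, 1, 1, 1, -1, -1, -1, 1), sprintf("g%d", c(1:8, 10)))
  c_ <- setNames(c(1, 1, 1, 1, 1, -1, -1, 1), sprintf("g%d", c(1:7, 11)))
  res <- compare_deg_sets(a, b, c_)
  expect_setequal(res$common, sprintf("g%d", 1:7))   # brute-force triple loop
  expect_identical(res$n_concordant_up, 5L)
  expect_identical(res$n_concordant_down, 2L)
  expect_length(compare_deg_sets(a[1:2], b[3:4], c_[5:6])$common, 0)
})
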