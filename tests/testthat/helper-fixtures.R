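# shared fixtures and independent oracles for the suite

# adjusted Rand index between two labelings (igraph's implementation)
ari <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}

# brute-force Benjamini-Hochberg step-up: q_i = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# a small exon_counts object built directly from a count matrix
make_exon_counts <- function(counts, gene_of, meta = NULL) {
  if (is.null(meta))
    meta <- data.frame(sample_id = colnames(counts),
                       genotype = "WT", month = 2,
                       replicate = seq_len(ncol(counts)),
                       stringsAsFactors = FALSE)
  structure(list(
    counts = counts,
    exon_to_gene = data.frame(exon_id = rownames(counts), gene_id = gene_of,
                              stringsAsFactors = FALSE),
    samples = meta), class = "exon_counts")
}

# gene x sample matrix of iid Gaussian noise around per-cell means
# planted: named list gene -> length-8 cell-mean vector (WT months then TG)
factorial_signals <- function(n_genes, meta, sigma = 0.3, planted = list(),
                              seed = 1) {
  set.seed(seed)
  months <- sort(unique(meta$month))
  cell <- paste0(meta$genotype, "_", meta$month)
  cells <- c(paste0("WT_", months), paste0("TG_", months))
  x <- matrix(rnorm(n_genes * nrow(meta), sd = sigma), n_genes, nrow(meta),
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              meta$sample_id))
  for (g in names(planted)) {
    mu <- setNames(planted[[g]], cells)
    x[g, ] <- x[g, ] + mu[cell]
  }
  x
}

# a 2x4 design metadata table
factorial_meta <- function(n_rep = 4, months = c(2, 4, 6, 8)) {
  grid <- expand.grid(replicate = seq_len(n_rep), genotype = c("WT", "TG"),
                      month = months, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%d_r%d", grid$genotype, grid$month,
                                 grid$replicate),
             grid, stringsAsFactors = FALSE)
}

# hand-built gene_network from an explicit degree-realizing edge list
make_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  degree <- setNames(integer(length(nodes)), nodes)
  tab <- table(c(edges$gene_a, edges$gene_b))
  degree[names(tab)] <- as.integer(tab)
  structure(list(nodes = nodes, edges = edges, degree = degree),
            class = "gene_network")
}
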