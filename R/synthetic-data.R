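#' Design specification for a synthetic factorial microglia study
#'
#' Describes a two-genotype (WT vs TG) by multi-age bulk RNA-seq design with
#' exon-level negative-binomial counts: gene baselines, exon structure,
#' library-size variation, and per-gene dispersion. The defaults emulate a
#' 2 x 4 genotype-by-month design with 4 replicates per cell.
#'
#' @param n_genes Number of genes to simulate.
#' @param months Strictly increasing ages (months) sampled.
#' @param n_replicates_per_cell Replicates in each genotype x month cell.
#' @param exons_per_gene Integer range `c(min, max)`; exon counts per gene
#'   are drawn uniformly from this range.
#' @param baseline_log2 Mean and sd of per-gene baseline log2 expected count.
#' @param library_size `c(meanlog, sdlog)` of the log-normal per-sample
#'   library-size factor (factor 1 = nominal depth).
#' @param dispersion `c(meanlog, sdlog)` of the log-normal per-gene NB
#'   dispersion phi, with variance = mu + mu^2 * phi.
#' @param seed Integer seed; fully determines all generated output.
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_genes = 500,
                        months = c(2, 4, 6, 8),
                        n_replicates_per_cell = 4,
                        exons_per_gene = c(1, 10),
                        baseline_log2 = c(mean = 10, sd = 0.5),
                        library_size = c(meanlog = 0, sdlog = 0.05),
                        dispersion = c(meanlog = log(0.02), sdlog = 0.3),
                        seed = 1L) {
  if (n_genes < 1 || n_replicates_per_cell < 1)
    stop("counts in the design must be >= 1", call. = FALSE)
  if (any(diff(months) <= 0))
    stop("`months` must be strictly increasing", call. = FALSE)
  if (exons_per_gene[1] < 1 || exons_per_gene[2] < exons_per_gene[1])
    stop("`exons_per_gene` must be an increasing range with min >= 1", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes),
    genotypes = c("WT", "TG"),
    months = months,
    n_replicates_per_cell = as.integer(n_replicates_per_cell),
    exons_per_gene = as.integer(exons_per_gene),
    baseline_log2 = baseline_log2,
    library_size = library_size,
    dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "design_spec")
}

#' Canonical temporal differential-expression pattern curves
#'
#' Log2 mean shifts (relative to the gene baseline) at each age for the four
#' planted longitudinal patterns, per genotype:
#' pattern 1 — TG down-regulated with age, WT flat;
#' pattern 2 — TG continuously up-regulated, WT flat;
#' pattern 3 — TG up with a mid-course peak, WT declining;
#' pattern 4 — TG down-regulated, WT moderately up.
#'
#' @param magnitude Scales every curve (1 keeps the defaults, whose largest
#'   terminal shifts are about 3 log2 units).
#' @param n_months Number of ages (curves are defined on the month index).
#' @return A list of four pattern elements, each with `WT` and `TG` numeric
#'   vectors of length `n_months`.
#' @export
pattern_curves <- function(magnitude = 1, n_months = 4) {
  stopifnot(n_months >= 2)
  # piecewise-linear in month index; values at 4 canonical ages,
  # interpolated if n_months differs
  base <- list(
    `1` = list(WT = c(0, 0, 0, 0),        TG = c(0, -1, -2, -3)),
    `2` = list(WT = c(0, 0, 0, 0),        TG = c(0, 1, 2, 3)),
    `3` = list(WT = c(0, -0.5, -1, -1.5), TG = c(0, 2, 2, 1)),
    `4` = list(WT = c(0, 0.5, 1, 1.5),    TG = c(0, -1, -2, -2.5))
  )
  lapply(base, function(p) lapply(p, function(v) {
    magnitude * stats::approx(seq_len(4), v, xout = seq(1, 4, length.out = n_months))$y
  }))
}

#' Planted ground truth for the synthetic study
#'
#' Assigns genes to temporal DEG patterns (or none), to co-expression
#' modules (or none), and modules to cell-type labels. The truth object is
#' consumed by the count and co-expression generators and by the tests that
#' score recovery.
#'
#' @param genes Gene ids (character vector) or a single integer count.
#' @param deg_fraction Fraction of genes planted as DEGs.
#' @param pattern_weights Relative frequency of the four patterns among
#'   planted DEGs.
#' @param curves Pattern curves, see [pattern_curves()].
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module.
#' @param celltypes Labels recycled over modules.
#' @param seed Integer seed.
#' @return A `planted_truth` list with fields `genes`, `deg_pattern`
#'   (named integer, 0 = none), `curves`, `module` (named integer, NA =
#'   none), and `celltype_of_module`.
#' @export
planted_truth <- function(genes = 500,
                          deg_fraction = 0.2,
                          pattern_weights = rep(1, 4),
                          curves = pattern_curves(),
                          n_modules = 4,
                          module_size = 30,
                          celltypes = c("microglia", "endothelial", "astrocyte",
                                        "neuron", "oligodendrocyte"),
                          seed = 1L) {
  if (length(genes) == 1L && is.numeric(genes))
    genes <- sprintf("G%05d", seq_len(genes))
  n <- length(genes)
  if (n_modules * module_size > n)
    stop("module assignment requires n_modules * module_size <= n_genes", call. = FALSE)
  with_seed(seed, {
    n_deg <- round(deg_fraction * n)
    deg_pattern <- integer(n)
    names(deg_pattern) <- genes
    if (n_deg > 0) {
      picked <- sample(genes, n_deg)
      pat <- rep(seq_len(4), times = round(n_deg * pattern_weights / sum(pattern_weights)))
      pat <- c(pat, sample(4, max(0, n_deg - length(pat)), replace = TRUE))[seq_len(n_deg)]
      deg_pattern[picked] <- pat
    }
    module <- rep(NA_integer_, n)
    names(module) <- genes
    in_mod <- sample(genes, n_modules * module_size)
    module[in_mod] <- rep(seq_len(n_modules), each = module_size)
    celltype_of_module <- stats::setNames(
      rep_len(celltypes, n_modules), as.character(seq_len(n_modules)))
    structure(list(genes = genes, deg_pattern = deg_pattern, curves = curves,
                   module = module, celltype_of_module = celltype_of_module),
              class = "planted_truth")
  })
}

# expected log2 shift for a gene in a given (genotype, month-index) cell
truth_shift <- function(truth, pattern, genotype, month_idx) {
  if (pattern == 0L) return(0)
  truth$curves[[pattern]][[genotype]][month_idx]
}

#' Sample metadata for a design
#'
#' @param spec A [design_spec()].
#' @return Data frame with `sample_id`, `genotype`, `month`, `replicate`.
#' @export
design_samples <- function(spec) {
  grid <- expand.grid(replicate = seq_len(spec$n_replicates_per_cell),
                      genotype = spec$genotypes, month = spec$months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%dm_r%d", grid$genotype, grid$month, grid$replicate),
    genotype = grid$genotype, month = grid$month, replicate = grid$replicate,
    stringsAsFactors = FALSE)
}

#' Generate exon-level negative-binomial counts under the factorial design
#'
#' Each gene has a baseline log2 expectation; planted DEGs follow their
#' pattern curve as a genotype- and age-dependent log2 shift. A gene's exons
#' share the gene-level expectation times fixed Dirichlet exon proportions
#' (constant across samples, as the rollup model assumes). Counts are NB
#' with variance mu + mu^2 * phi; per-sample log-normal library factors
#' scale all expectations.
#'
#' @param spec A [design_spec()].
#' @param truth A [planted_truth()] over the same gene universe.
#' @return An `exon_counts` list: integer `counts` (exon x sample),
#'   `exon_to_gene` data frame, `samples` metadata, and per-gene `phi`.
#' @export
generate_exon_counts <- function(spec, truth) {
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  if (!identical(genes, truth$genes))
    stop("spec and truth reference different gene universes", call. = FALSE)
  samples <- design_samples(spec)
  n_s <- nrow(samples)
  month_idx <- match(samples$month, spec$months)
  with_seed(spec$seed, {
    base <- stats::rnorm(spec$n_genes, spec$baseline_log2[["mean"]],
                         spec$baseline_log2[["sd"]])
    phi <- stats::rlnorm(spec$n_genes, spec$dispersion[["meanlog"]],
                         spec$dispersion[["sdlog"]])
    libf <- stats::rlnorm(n_s, spec$library_size[["meanlog"]],
                          spec$library_size[["sdlog"]])
    n_exons <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]),
                      spec$n_genes, replace = TRUE)
    # fixed exon proportions per gene (Dirichlet via normalized gammas)
    props <- lapply(n_exons, function(k) {
      g <- stats::rgamma(k, shape = 5)
      g / sum(g)
    })
    # per-gene per-sample log2 shift
    shift <- matrix(0, spec$n_genes, n_s)
    for (p in 1:4) {
      idx <- which(truth$deg_pattern == p)
      if (!length(idx)) next
      sh <- vapply(seq_len(n_s), function(s)
        truth_shift(truth, p, samples$genotype[s], month_idx[s]), numeric(1))
      shift[idx, ] <- matrix(sh, length(idx), n_s, byrow = TRUE)
    }
    mu_gene <- 2^(base + shift) * matrix(libf, spec$n_genes, n_s, byrow = TRUE)
    exon_id <- unlist(lapply(seq_len(spec$n_genes), function(g)
      sprintf("%s_e%02d", genes[g], seq_len(n_exons[g]))))
    exon_gene <- rep(genes, n_exons)
    counts <- matrix(0L, length(exon_id), n_s,
                     dimnames = list(exon_id, samples$sample_id))
    row0 <- 0L
    for (g in seq_len(spec$n_genes)) {
      mu_e <- outer(props[[g]], mu_gene[g, ])     # exon x sample expectations
      counts[row0 + seq_len(n_exons[g]), ] <-
        matrix(as.integer(stats::rnbinom(length(mu_e), mu = mu_e,
                                         size = 1 / phi[g])),
               n_exons[g], n_s)
      row0 <- row0 + n_exons[g]
    }
    structure(list(
      counts = counts,
      exon_to_gene = data.frame(exon_id = exon_id, gene_id = exon_gene,
                                stringsAsFactors = FALSE),
      samples = samples,
      phi = stats::setNames(phi, genes)
    ), class = "exon_counts")
  })
}

#' Generate per-sample QC metrics, optionally corrupting some samples
#'
#' Emits a QC metric table (mapping rate, mapped reads, 3' bias, rRNA +
#' mitochondrial fraction, adapter content) in which a chosen number of
#' samples receive a failing mapping rate, to exercise sample exclusion.
#'
#' @param samples Sample metadata (needs `sample_id`).
#' @param n_fail Number of samples given a corrupted (failing) mapping rate.
#' @param seed Integer seed.
#' @return Data frame, one row per sample.
#' @export
generate_qc_metrics <- function(samples, n_fail = 0, seed = 1L) {
  n <- nrow(samples)
  if (n_fail > n) stop("n_fail exceeds the number of samples", call. = FALSE)
  with_seed(seed, {
    qc <- data.frame(
      sample_id = samples$sample_id,
      mapping_rate = stats::runif(n, 0.85, 0.95),
      mapped_reads = round(stats::runif(n, 4e7, 6e7)),
      three_prime_bias = stats::runif(n, 0.9, 1.1),
      rrna_mito_fraction = stats::runif(n, 0.01, 0.08),
      adapter_content = stats::runif(n, 0, 0.02),
      stringsAsFactors = FALSE)
    if (n_fail > 0) {
      bad <- sample(n, n_fail)
      qc$mapping_rate[bad] <- stats::runif(n_fail, 0.1, 0.4)
    }
    qc
  })
}

#' Generate latent-factor co-expression samples
#'
#' Genes assigned to a planted module load on that module's latent factor;
#' unassigned genes are independent noise. Between-module factors are
#' independent, so the expected within-module pairwise correlation
#' (loading^2 / (loading^2 + noise_sd^2)) strictly exceeds the
#' between-module expectation (zero).
#'
#' @param n_samples Number of samples (>= 10).
#' @param truth A [planted_truth()] carrying the module assignment.
#' @param noise_sd Positive independent noise standard deviation.
#' @param loading Factor loading shared by module genes.
#' @param seed Integer seed.
#' @return Numeric gene x sample matrix.
#' @export
generate_coexpression_samples <- function(n_samples, truth, noise_sd = 0.5,
                                          loading = 1, seed = 1L) {
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (n_samples < 10) stop("`n_samples` must be >= 10", call. = FALSE)
  genes <- truth$genes
  with_seed(seed, {
    mods <- sort(unique(truth$module[!is.na(truth$module)]))
    factors <- matrix(stats::rnorm(length(mods) * n_samples), length(mods),
                      n_samples, dimnames = list(as.character(mods), NULL))
    x <- matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
                length(genes), n_samples,
                dimnames = list(genes, sprintf("S%04d", seq_len(n_samples))))
    for (m in mods) {
      idx <- which(truth$module == m)
      x[idx, ] <- x[idx, ] +
        matrix(factors[as.character(m), ], length(idx), n_samples, byrow = TRUE) * loading
    }
    x
  })
}

#' Generate gene sets, signed regulons, marker sets, and an ortholog map
#'
#' Gene sets are built from the planted temporal patterns (one set per
#' pattern) plus random null sets; regulons include one "active" regulator
#' per pattern whose predicted signs match the pattern's terminal direction,
#' plus null regulators with random targets and signs; marker sets collect
#' the genes of modules sharing a cell-type label; the ortholog map is
#' one-to-one over a configurable fraction of the gene universe.
#'
#' @param truth A [planted_truth()].
#' @param seed Integer seed.
#' @param n_null_sets Number of random gene sets.
#' @param null_set_size Genes per null set.
#' @param n_null_regulons Number of null regulators.
#' @param regulon_size Targets per regulator.
#' @param ortholog_fraction Fraction of genes with a (one-to-one) ortholog.
#' @return List with `gene_sets`, `regulons`, `marker_sets`, `orthologs`.
#' @export
generate_genesets_and_regulons <- function(truth, seed = 1L,
                                           n_null_sets = 10, null_set_size = 30,
                                           n_null_regulons = 50, regulon_size = 20,
                                           ortholog_fraction = 1.0) {
  genes <- truth$genes
  # direction of each pattern at the terminal age (TG - WT)
  terminal_dir <- vapply(truth$curves, function(p) {
    d <- p$TG[length(p$TG)] - p$WT[length(p$WT)]
    sign(d)
  }, numeric(1))
  with_seed(seed, {
    gene_sets <- list()
    for (p in 1:4) {
      members <- names(truth$deg_pattern)[truth$deg_pattern == p]
      if (length(members)) gene_sets[[sprintf("pattern%d_set", p)]] <- members
    }
    for (i in seq_len(n_null_sets))
      gene_sets[[sprintf("null_set_%02d", i)]] <-
        sample(genes, min(null_set_size, length(genes)))

    regulons <- list()
    for (p in 1:4) {
      members <- names(truth$deg_pattern)[truth$deg_pattern == p]
      if (!length(members)) next
      tg <- sample(members, min(regulon_size, length(members)))
      regulons[[sprintf("ACTIVE_P%d", p)]] <-
        stats::setNames(rep(terminal_dir[p], length(tg)), tg)
    }
    for (i in seq_len(n_null_regulons)) {
      sz <- min(regulon_size, length(genes))
      tg <- sample(genes, sz)
      regulons[[sprintf("NULL_R%02d", i)]] <-
        stats::setNames(sample(c(-1, 1), sz, replace = TRUE), tg)
    }

    marker_sets <- list()
    for (ct in unique(truth$celltype_of_module)) {
      mods <- as.integer(names(truth$celltype_of_module)[truth$celltype_of_module == ct])
      members <- names(truth$module)[!is.na(truth$module) & truth$module %in% mods]
      if (length(members)) marker_sets[[ct]] <- members
    }

    src <- sample(genes, round(ortholog_fraction * length(genes)))
    orthologs <- data.frame(source_gene = sort(src),
                            target_gene = paste0("HS_", sort(src)),
                            stringsAsFactors = FALSE)
    list(gene_sets = gene_sets, regulons = regulons,
         marker_sets = marker_sets, orthologs = orthologs)
  })
}
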