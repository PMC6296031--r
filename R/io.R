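#' Write exon counts, sample metadata, and QC metrics as TSV
#'
#' Counts are written with `exon_id` and `gene_id` as the first two columns,
#' one column per sample thereafter.
#'
#' @param x An `exon_counts` object.
#' @param dir Output directory (created if absent).
#' @param qc Optional QC metrics data frame.
#' @return Invisibly, the paths written.
#' @export
write_exon_counts <- function(x, dir, qc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "exon_counts.tsv")
  df <- data.frame(exon_id = rownames(x$counts),
                   gene_id = x$exon_to_gene$gene_id[
                     match(rownames(x$counts), x$exon_to_gene$exon_id)],
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- file.path(dir, "samples.tsv")
  utils::write.table(x$samples, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(counts = cpath, samples = mpath)
  if (!is.null(qc)) {
    qpath <- file.path(dir, "qc_metrics.tsv")
    utils::write.table(qc, qpath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, qc = qpath)
  }
  invisible(paths)
}

#' Read exon counts and sample metadata written by [write_exon_counts()]
#'
#' @param counts_path Path to the exon-count TSV.
#' @param samples_path Path to the sample-metadata TSV.
#' @return An `exon_counts` object.
#' @export
read_exon_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("exon_id", "gene_id") %in% names(df)[1:2]))
    stop("first two columns must be exon_id and gene_id", call. = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$exon_id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!identical(colnames(counts), samples$sample_id))
    stop("count columns do not match metadata sample order", call. = FALSE)
  structure(list(counts = counts,
                 exon_to_gene = df[, 1:2],
                 samples = samples), class = "exon_counts")
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1))
}

#' Write a named list of gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed regulon TSV (regulator, target, sign)
#'
#' @param path Regulon file; `sign` must be +1 or -1.
#' @return Named list of regulons, each a named sign vector over targets.
#' @export
read_regulons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(df)))
    stop("regulon file needs columns regulator, target, sign", call. = FALSE)
  if (!all(df$sign %in% c(-1, 1)))
    stop("regulon signs must be +1 or -1", call. = FALSE)
  dup <- duplicated(df[, c("regulator", "target")])
  if (any(dup))
    stop("duplicated regulator-target rows in regulon file", call. = FALSE)
  split(stats::setNames(df$sign, df$target), df$regulator)
}

#' Write regulons to TSV
#' @param regulons Named list of named sign vectors.
#' @param path Output path.
#' @export
write_regulons <- function(regulons, path) {
  df <- do.call(rbind, lapply(names(regulons), function(r)
    data.frame(regulator = r, target = names(regulons[[r]]),
               sign = as.integer(regulons[[r]]), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ortholog map TSV
#'
#' @param path TSV with columns `source_gene` and `target_gene`.
#' @return Data frame with those two columns.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_gene", "target_gene") %in% names(df)))
    stop("ortholog file needs columns source_gene and target_gene", call. = FALSE)
  bad <- which(!nzchar(df$source_gene) | !nzchar(df$target_gene) |
                 is.na(df$source_gene) | is.na(df$target_gene))
  if (length(bad))
    stop(sprintf("malformed ortholog row(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  df
}

#' Write a gene x sample signal matrix as TSV
#' @param signals Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_signals <- function(signals, path) {
  stop_if_not_matrix(signals)
  df <- data.frame(gene_id = rownames(signals), signals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample signal matrix written by [write_signals()]
#' @param path TSV path.
#' @return Numeric matrix.
#' @export
read_signals <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize planted truth to JSON
#' @param truth A `planted_truth` object.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    genes = truth$genes,
    deg_pattern = as.list(truth$deg_pattern),
    module = as.list(truth$module),
    celltype_of_module = as.list(truth$celltype_of_module)
  ), path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
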