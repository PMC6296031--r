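#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that generator calls are reproducible without disturbing the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# signed fold change on the anti-logged scale: sign(lfc) * 2^|lfc|
signed_fold_change <- function(log2fc) {
  fc <- sign(log2fc) * 2^abs(log2fc)
  fc[log2fc == 0] <- 1
  fc
}

# canonical unordered pair ids, a < b lexicographically
pair_id <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "|")
}

stop_if_not_matrix <- function(x, what = "signals") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("`%s` must have row and column names", what), call. = FALSE)
  invisible(x)
}
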