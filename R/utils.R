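# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score a vector; errors on (near-)constant input with a caller-supplied label
zscore <- function(x, what = "variate") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant ", what, call. = FALSE)
  }
  (x - mean(x)) / s
}

column_labels <- function(x, prefix = "V") {
  colnames(x) %||% paste0(prefix, seq_len(ncol(x)))
}

as_numeric_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("`", arg, "` contains missing or non-finite values", call. = FALSE)
  }
  x
}
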