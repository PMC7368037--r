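# Mode scoring and the multivariate association between neurocognitive mode
# scores and the 13 experience-sampling items: Type III multiple multivariate
# regression tested with Pillai's trace, overall and per stratum (task
# condition or day), plus pattern-similarity comparisons.

#' The 13 experience-sampling item names
#' @return Character vector of item names.
#' @export
mdes_items <- function() {
  c("task", "future", "past", "self", "people", "emotion", "images",
    "words", "vivid", "detailed", "habit", "evolving", "deliberate")
}

#' Neurocognitive mode scores from canonical variates
#'
#' A subject's mode score is the mean of the z-scored connectivity variate
#' and the z-scored task variate of that mode. (Averaging versus summing the
#' two variates changes the score by a factor of 2 only, so every downstream
#' correlation and test statistic is identical.)
#'
#' @param xu Connectivity-side variates: numeric vector, matrix
#'   (subjects x modes), or the list returned by [predict.scca()] (in which
#'   case `yv` is taken from it).
#' @param yv Task-side variates, matching `xu` in shape.
#' @return An object of class `"mode_scores"`: list with `score` (matrix,
#'   subjects x modes), and the z-scored components `variate_fc`,
#'   `variate_task`.
#' @export
mode_score <- function(xu, yv = NULL) {
  if (is.list(xu) && !is.data.frame(xu) && is.null(yv)) {
    yv <- xu$yv
    xu <- xu$xu
  }
  xu <- as.matrix(xu)
  yv <- as.matrix(yv)
  if (!all(dim(xu) == dim(yv))) stop("`xu` and `yv` must have equal dims")
  zx <- apply(xu, 2, zscore, what = "connectivity variate")
  zy <- apply(yv, 2, zscore, what = "task variate")
  zx <- matrix(zx, nrow(xu), ncol(xu), dimnames = dimnames(xu))
  zy <- matrix(zy, nrow(yv), ncol(yv), dimnames = dimnames(xu))
  structure(
    list(score = (zx + zy) / 2, variate_fc = zx, variate_task = zy),
    class = "mode_scores"
  )
}

#' @export
print.mode_scores <- function(x, ...) {
  cat("Neurocognitive mode scores:", nrow(x$score), "subjects,",
      ncol(x$score), "mode(s)\n")
  invisible(x)
}

# Pillai's trace and its F approximation for a single-df hypothesis SSCP H
# against error SSCP E (vh = hypothesis df, ve = error df, q = responses).
pillai_stats <- function(H, E, vh, ve) {
  q <- ncol(E)
  HE <- tryCatch(solve(H + E, H), error = function(e) {
    stop("singular hypothesis-plus-error SSCP matrix", call. = FALSE)
  })
  V <- sum(diag(HE))
  s <- min(vh, q)
  m <- (abs(q - vh) - 1) / 2
  nn <- (ve - q - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f_stat <- if (V >= s) Inf else (df2 / df1) * V / (s - V)
  p <- if (is.infinite(f_stat)) 0 else
    stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  list(pillai = V, f_stat = f_stat, df_num = df1, df_den = df2,
       p_value = p, eta_sq = V / s, s = s)
}

#' Type III multivariate regression with Pillai's trace
#'
#' Regresses a multivariate outcome block (typically the 13 z-scored
#' experience-sampling item means) on a set of predictors (neurocognitive
#' mode scores plus nuisance covariates). For each predictor, the Type III
#' hypothesis sum-of-squares-and-cross-products matrix is obtained by
#' comparing the full model with the model omitting that predictor
#' (equivalent to the classical Type III test for continuous, non-nested
#' predictors); Pillai's trace `V = tr(H (H + E)^-1)`, its standard F
#' approximation, and the multivariate effect size `eta_sq = V / s` are
#' reported, together with the per-item coefficient vector (scaled per
#' standard deviation of the predictor) that constitutes the predictor's
#' associated thought pattern.
#'
#' @param items Numeric matrix of outcomes, subjects x q (z-scored items in
#'   the standard pipeline).
#' @param predictors Data frame or matrix of predictors of interest (e.g.
#'   mode scores), subjects aligned with `items`.
#' @param covariates Optional additional nuisance predictors entering the
#'   model (and reported) the same way.
#' @return An object of class `"mdes_manova"`: list of per-predictor
#'   `"thought_pattern"` records (`predictor`, `coefficients`, `pillai`,
#'   `f_stat`, `df_num`, `df_den`, `p_value`, `eta_sq`, `n`), plus `n`,
#'   `error_df` and the fitted coefficient matrix.
#' @export
manova_pillai <- function(items, predictors, covariates = NULL) {
  items <- as_numeric_matrix(items, "items")
  pred <- as.data.frame(predictors)
  if (!is.null(covariates)) pred <- cbind(pred, as.data.frame(covariates))
  if (nrow(pred) != nrow(items)) {
    stop("`items` and predictors must have the same number of rows")
  }
  q <- ncol(items)
  if (nrow(items) <= ncol(pred) + q) {
    stop("need n > number of predictors + number of items (",
         ncol(pred), " + ", q, ")")
  }
  X <- stats::model.matrix(~., data = pred)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }
  n <- nrow(items)
  ve <- n - ncol(X)
  res_full <- qr.resid(qrX, items)
  E <- crossprod(res_full)
  B <- qr.coef(qrX, items)
  item_names <- column_labels(items, "item")

  terms_idx <- seq(2L, ncol(X)) # every non-intercept column
  patterns <- lapply(terms_idx, function(j) {
    Xr <- X[, -j, drop = FALSE]
    Er <- crossprod(qr.resid(qr(Xr), items))
    st <- pillai_stats(Er - E, E, vh = 1, ve = ve)
    beta <- B[j, ] * stats::sd(X[, j])
    names(beta) <- item_names
    structure(
      c(list(predictor = colnames(X)[j], coefficients = beta, n = n), st),
      class = "thought_pattern"
    )
  })
  names(patterns) <- colnames(X)[terms_idx]
  structure(
    list(patterns = patterns, n = n, error_df = ve, coef = B, E = E),
    class = "mdes_manova"
  )
}

#' @export
print.thought_pattern <- function(x, ...) {
  cat(sprintf(
    "%s: Pillai = %.3f, F(%g, %g) = %.3f, p = %.4g, eta_sq = %.3f\n",
    x$predictor, x$pillai, x$df_num, x$df_den, x$f_stat, x$p_value,
    x$eta_sq))
  ord <- order(-abs(x$coefficients))
  cat("  leading items:",
      paste(sprintf("%s (%+.2f)", names(x$coefficients)[ord][1:5],
                    x$coefficients[ord][1:5]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mdes_manova <- function(x, ...) {
  cat("Multivariate regression on", ncol(x$E), "items,", x$n,
      "subjects (error df", x$error_df, ")\n")
  for (p in x$patterns) {
    cat(sprintf("  %-18s Pillai = %.3f  F(%g, %g) = %6.3f  p = %-9.4g eta_sq = %.3f\n",
                p$predictor, p$pillai, p$df_num, p$df_den, p$f_stat,
                p$p_value, p$eta_sq))
  }
  invisible(x)
}

#' @export
coef.mdes_manova <- function(object, ...) {
  do.call(rbind, lapply(object$patterns, function(p) p$coefficients))
}

#' Stratified thought-pattern analyses
#'
#' Repeats [manova_pillai()] within strata of the experience-sampling data —
#' per task condition or per day — to assess the stability of the
#' mode-to-thought mapping across contexts. Item responses are averaged over
#' the collapsed factor within each stratum, z-scored within stratum, and
#' subjects missing a stratum are dropped from that stratum only.
#'
#' @param mdes Long data frame with columns `subject`, `condition`, `day`
#'   and the 13 item columns ([mdes_items()]).
#' @param predictors Data frame of predictors keyed by row name or aligned
#'   with the full subject roster given in `subjects`.
#' @param subjects Character vector of subject ids aligning `predictors`
#'   rows; defaults to `rownames(predictors)`.
#' @param by Stratifying column, `"condition"` or `"day"`.
#' @param items Item column names (default [mdes_items()]).
#' @return Named list of `"mdes_manova"` objects, one per stratum level.
#' @export
stratified_patterns <- function(mdes, predictors, subjects = NULL,
                                by = c("condition", "day"),
                                items = mdes_items()) {
  by <- match.arg(by)
  if (!all(c("subject", by, items) %in% names(mdes))) {
    stop("`mdes` must contain columns subject, ", by,
         " and the item columns")
  }
  predictors <- as.data.frame(predictors)
  subjects <- subjects %||% rownames(predictors)
  if (is.null(subjects)) stop("supply `subjects` or row-named `predictors`")
  levels_by <- sort(unique(mdes[[by]]))
  out <- lapply(levels_by, function(lv) {
    sub <- mdes[mdes[[by]] == lv, , drop = FALSE]
    agg <- stats::aggregate(sub[items], by = list(subject = sub$subject),
                            FUN = mean)
    keep <- match(agg$subject, subjects)
    if (anyNA(keep)) stop("stratum ", lv, ": unknown subject id(s)")
    y <- as.matrix(agg[items])
    if (nrow(y) <= ncol(predictors) + length(items)) {
      stop("stratum ", by, " = ", lv, " has too few subjects (",
           nrow(y), ") for ", ncol(predictors), " predictors and ",
           length(items), " items")
    }
    y <- standardize_columns(y)
    manova_pillai(y, predictors[keep, , drop = FALSE])
  })
  names(out) <- as.character(levels_by)
  out
}

#' Similarity of two thought patterns
#'
#' Pearson correlation between two coefficient vectors over the
#' experience-sampling items, with the two-sided p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param a,b Coefficient vectors (or `"thought_pattern"` objects) of equal
#'   length >= 3.
#' @return List with `r`, `p` and `n` (vector length).
#' @export
pattern_similarity <- function(a, b) {
  if (inherits(a, "thought_pattern")) a <- a$coefficients
  if (inherits(b, "thought_pattern")) b <- b$coefficients
  if (length(a) != length(b) || length(a) < 3) {
    stop("`a` and `b` must have equal length >= 3")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("cannot correlate a constant coefficient vector")
  }
  n <- length(a)
  am <- a - mean(a)
  bm <- b - mean(b)
  r <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
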