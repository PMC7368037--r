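# Connectome feature engineering: Pearson correlations between ROI time
# series, Fisher r-to-z, upper-triangle vectorization, robust feature
# filtering and confound residualization.

#' ROI pair index for upper-triangle vectorization
#'
#' Enumerates all unordered ROI pairs (i, j) with i < j in row-major order:
#' (1,2), (1,3), ..., (1,R), (2,3), ... This fixed order defines the layout of
#' every connectivity feature vector produced by the package.
#'
#' @param n_rois Number of regions of interest (>= 2).
#' @return A data frame with integer columns `i` and `j`, one row per pair,
#'   `n_rois * (n_rois - 1) / 2` rows in total.
#' @examples
#' roi_pairs(4)
#' @export
roi_pairs <- function(n_rois) {
  n_rois <- as.integer(n_rois)
  if (is.na(n_rois) || n_rois < 2) stop("`n_rois` must be an integer >= 2")
  i <- rep.int(seq_len(n_rois - 1L), times = (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(a) (a + 1L):n_rois))
  data.frame(i = i, j = as.integer(j))
}

#' Fisher-z connectivity vector from ROI time series
#'
#' Computes the Pearson correlation between every pair of ROI time series,
#' applies the Fisher r-to-z transform `atanh(r)`, and returns the upper
#' triangle of the correlation matrix as a vector in the order given by
#' [roi_pairs()]. Correlations are clipped to `+/- (1 - clip)` before the
#' transform so that perfectly correlated series yield finite features.
#'
#' @param ts Numeric matrix of ROI time series, timepoints in rows and ROIs in
#'   columns. At least 3 timepoints and 2 ROIs; no missing values; every ROI
#'   must have nonzero variance.
#' @param clip Small positive tolerance bounding `|r|` away from 1 before
#'   `atanh` (default `1e-7`).
#' @param subject_id Optional subject identifier carried into the result.
#' @return An object of class `"connectivity_vector"`: a list with elements
#'   `subject_id`, `z_values` (named numeric vector of length
#'   `R * (R - 1) / 2`) and `pair_index` (the [roi_pairs()] data frame with ROI
#'   labels attached).
#' @examples
#' ts <- matrix(rnorm(50 * 5), 50, 5)
#' cv <- compute_connectome(ts)
#' length(cv$z_values) # 10
#' @export
compute_connectome <- function(ts, clip = 1e-7, subject_id = NULL) {
  ts <- as_numeric_matrix(ts, "ts")
  if (nrow(ts) < 3) stop("at least 3 timepoints are required")
  if (ncol(ts) < 2) stop("at least 2 ROIs are required")
  if (!is.numeric(clip) || length(clip) != 1 || clip <= 0 || clip >= 1) {
    stop("`clip` must be a single value in (0, 1)")
  }
  labels <- column_labels(ts, "roi")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI time series: ",
         paste(labels[sds == 0], collapse = ", "))
  }
  r <- stats::cor(ts)
  pairs <- roi_pairs(ncol(ts))
  rv <- r[cbind(pairs$i, pairs$j)]
  rv <- pmin(pmax(rv, -(1 - clip)), 1 - clip)
  z <- atanh(rv)
  names(z) <- paste(labels[pairs$i], labels[pairs$j], sep = "--")
  pairs$label_i <- labels[pairs$i]
  pairs$label_j <- labels[pairs$j]
  structure(
    list(subject_id = subject_id, z_values = z, pair_index = pairs),
    class = "connectivity_vector"
  )
}

#' @export
print.connectivity_vector <- function(x, ...) {
  cat("Fisher-z connectivity vector",
      if (!is.null(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  cat("  features:", length(x$z_values),
      " range: [", sprintf("%.3f", min(x$z_values)), ",",
      sprintf("%.3f", max(x$z_values)), "]\n")
  invisible(x)
}

#' Stack per-subject connectivity vectors into a feature matrix
#'
#' @param ts_list Named list of ROI time-series matrices (one per subject).
#' @param clip Passed to [compute_connectome()].
#' @return Numeric matrix, subjects in rows, ROI-pair features in columns.
#' @export
connectome_features <- function(ts_list, clip = 1e-7) {
  if (!is.list(ts_list) || length(ts_list) == 0) {
    stop("`ts_list` must be a non-empty list of time-series matrices")
  }
  ids <- names(ts_list) %||% paste0("sub", seq_along(ts_list))
  rows <- lapply(seq_along(ts_list), function(k) {
    cv <- tryCatch(
      compute_connectome(ts_list[[k]], clip = clip, subject_id = ids[k]),
      error = function(e) {
        stop("subject ", ids[k], ": ", conditionMessage(e), call. = FALSE)
      }
    )
    cv$z_values
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

#' Select the most variable features by median absolute deviation
#'
#' Ranks columns by their raw median absolute deviation
#' `median(|x - median(x)|)` (no consistency constant) and retains the
#' `floor(fraction * p)` largest, breaking ties in favour of lower column
#' indices. Features that do not vary across subjects cannot carry individual
#' differences, so downstream modelling is restricted to the most variable
#' connections.
#'
#' @param x Numeric matrix, subjects in rows, features in columns.
#' @param fraction Fraction of columns to retain, in (0, 1]; default 0.05.
#' @return An object of class `"mad_filter"`: list with `selected` (ordered,
#'   ascending column indices), `mad` (per-column MAD), `fraction` and
#'   `n_selected`.
#' @examples
#' x <- matrix(rnorm(20 * 40), 20, 40)
#' fs <- mad_filter(x, 0.1)
#' fs$n_selected # 4
#' @export
mad_filter <- function(x, fraction = 0.05) {
  x <- as_numeric_matrix(x, "x")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]")
  }
  p <- ncol(x)
  k <- floor(fraction * p)
  if (k < 1) {
    stop("`fraction` = ", fraction, " retains zero of ", p, " features")
  }
  mads <- apply(x, 2, function(col) stats::median(abs(col - stats::median(col))))
  ord <- order(-mads, seq_len(p)) # ties -> lower column index
  selected <- sort(ord[seq_len(k)])
  structure(
    list(selected = selected, mad = mads, fraction = fraction, n_selected = k),
    class = "mad_filter"
  )
}

#' @export
print.mad_filter <- function(x, ...) {
  cat("MAD feature filter: retained", x$n_selected, "of", length(x$mad),
      sprintf("features (fraction %.3g)\n", x$fraction))
  invisible(x)
}

#' Residualize features on nuisance covariates
#'
#' Replaces each column of `x` by its least-squares residual on the covariates
#' (plus an intercept), removing linear effects of, e.g., age, sex and head
#' motion before association analysis. Residual columns are mean zero and
#' orthogonal to every covariate.
#'
#' @param x Numeric matrix, subjects in rows.
#' @param confounds Covariate matrix or data frame, rows aligned with `x`.
#' @return Matrix of residuals with the dimensions and dimnames of `x`.
#' @export
residualize_confounds <- function(x, confounds) {
  x <- as_numeric_matrix(x, "x")
  cdf <- as.data.frame(confounds)
  if (nrow(cdf) != nrow(x)) {
    stop("`x` and `confounds` must have the same number of rows")
  }
  cm <- stats::model.matrix(~., data = cdf)
  qrC <- qr(cm)
  if (qrC$rank < ncol(cm)) {
    bad <- colnames(cm)[qrC$pivot[(qrC$rank + 1):ncol(cm)]]
    stop("confound matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrC, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Standardize matrix columns to mean zero, unit variance
#'
#' Uses the sample standard deviation (n - 1 denominator). Errors if any
#' column is constant, naming it.
#'
#' @param x Numeric matrix.
#' @return Standardized matrix with the dimnames of `x`.
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3)))
#' @export
standardize_columns <- function(x) {
  x <- as_numeric_matrix(x, "x")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    stop("zero-variance column(s): ",
         paste(column_labels(x)[s == 0], collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = s)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- dimnames(x)
  out
}
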