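# Sparse canonical correlation analysis via L1-penalised rank-1 matrix
# decomposition of the cross-product matrix M = X'Y, with deflation for
# successive modes.  The solver alternates soft-thresholded unit-vector
# updates (penalised matrix decomposition under a diagonal-covariance CCA
# surrogate); with the penalties inactive it converges to the leading
# singular-vector pair of M.

#' Soft-thresholding operator
#'
#' Elementwise `sign(a) * max(|a| - delta, 0)`.
#'
#' @param a Numeric vector.
#' @param delta Nonnegative threshold.
#' @return Shrunken vector of the same length.
#' @examples
#' soft_threshold(c(3, -0.5, -3), 1) # 2, 0, -2
#' @export
soft_threshold <- function(a, delta) {
  if (delta < 0) stop("`delta` must be nonnegative")
  sign(a) * pmax(abs(a) - delta, 0)
}

#' L1-constrained unit vector
#'
#' Returns `w = S(a, delta) / ||S(a, delta)||_2` where `S` is
#' [soft_threshold()] and `delta >= 0` is the smallest threshold (found by
#' bisection) such that `||w||_1 <= c`. With `delta = 0` when the plain
#' unit-normalized vector already satisfies the bound. This is the
#' projection-like update at the heart of the penalised matrix decomposition.
#'
#' @param a Nonzero numeric vector.
#' @param c Absolute L1 bound, in `[1, sqrt(length(a))]`.
#' @param tol Bisection tolerance on `delta` (default `1e-8`).
#' @return Unit-L2 vector with `||w||_1 <= c` (up to `tol`).
#' @examples
#' l1_constrained_unit_vector(c(3, 1), 1) # (1, 0)
#' @export
l1_constrained_unit_vector <- function(a, c, tol = 1e-8) {
  if (all(a == 0)) stop("cannot normalize an all-zero vector")
  if (c < 1 - 1e-12) stop("`c` must be at least 1")
  w <- a / sqrt(sum(a^2))
  if (sum(abs(w)) <= c + tol) return(w)
  lo <- 0
  hi <- max(abs(a))
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    s <- soft_threshold(a, mid)
    if (all(s == 0)) {
      hi <- mid
    } else {
      w <- s / sqrt(sum(s^2))
      if (sum(abs(w)) > c) lo <- mid else hi <- mid
    }
    if (hi - lo <= tol * max(1, hi)) break
  }
  s <- soft_threshold(a, hi)
  if (all(s == 0)) {
    # bound c >= 1 is always attainable with a single nonzero coordinate
    s <- numeric(length(a))
    top <- which.max(abs(a))
    s[top] <- a[top]
  }
  s / sqrt(sum(s^2))
}

# one rank-1 penalised decomposition of a cross-product matrix M
# (compiled inner loop; see src/scca_rank1.cpp)
scca_rank1 <- function(M, cx, cy, tol = 1e-6, max_iter = 200L) {
  dimnames(M) <- NULL
  scca_rank1_cpp(M, cx, cy, tol, as.integer(max_iter))
}

penalty_bound <- function(fraction, p) max(1, fraction * sqrt(p))

#' Sparse canonical correlation analysis
#'
#' Fits `K` sparse canonical modes linking two row-aligned data matrices.
#' Each mode is a rank-1 L1-penalised decomposition of the (column-centered)
#' cross-product matrix `M = X'Y`: starting from the leading right singular
#' vector of `M`, the solver alternates
#' `u <- l1_constrained_unit_vector(M v, c_x)` and
#' `v <- l1_constrained_unit_vector(M'u, c_y)` until the largest elementwise
#' change falls below `tol`, then deflates `M <- M - (u'Mv) u v'`. Penalty
#' fractions in (0, 1] are mapped to absolute L1 bounds
#' `max(1, fraction * sqrt(p))` per side; a fraction of 1 disables the
#' penalty, in which case mode 1 equals the leading singular-vector pair of
#' `M`.
#'
#' Canonical correlations are reported as signed sample Pearson correlations
#' of the variates `Xu` and `Yv`; mode orientation is fixed by making the
#' largest-magnitude entry of `v` positive.
#'
#' @param x,y Row-aligned numeric matrices (subjects in rows). Columns are
#'   centered internally; for canonical-correlation analysis they should be
#'   standardized beforehand (see [standardize_columns()]) or via
#'   `scale = TRUE`.
#' @param penalty Length-2 vector of penalty fractions `(c_x, c_y)` in
#'   (0, 1].
#' @param K Number of modes to extract.
#' @param tol Convergence tolerance on the maximum weight change.
#' @param max_iter Maximum alternations per mode.
#' @param center,scale Center / scale columns before fitting.
#' @return An object of class `"scca"`: list with weight matrices `u`
#'   (p x K) and `v` (q x K), canonical correlations `cors`, singular values
#'   `d`, nonzero counts `n_nonzero_u` / `n_nonzero_v`, per-mode `converged`,
#'   `iterations` and `objective` traces, the penalty specification, the
#'   column centers/scales used, and `deflation_residual` (Frobenius norm of
#'   the deflated cross-product after K modes).
#' @seealso [scca_cv()] for penalty selection, [scca_permtest()] for mode
#'   significance, [predict.scca()] for canonical variates.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30 * 5), 30, 5)
#' y <- matrix(rnorm(30 * 4), 30, 4)
#' fit <- scca(x, y, penalty = c(1, 1), K = 2)
#' fit
#' @export
scca <- function(x, y, penalty = c(0.3, 0.7), K = 1L, tol = 1e-6,
                 max_iter = 200L, center = TRUE, scale = FALSE) {
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  if (nrow(x) != nrow(y)) stop("`x` and `y` must have the same number of rows")
  if (length(penalty) != 2 || any(penalty <= 0) || any(penalty > 1)) {
    stop("`penalty` must be two fractions in (0, 1]")
  }
  K <- as.integer(K)
  if (K < 1 || K > min(ncol(x), ncol(y))) {
    stop("`K` must be between 1 and min(ncol(x), ncol(y))")
  }
  x_center <- if (center) colMeans(x) else rep(0, ncol(x))
  y_center <- if (center) colMeans(y) else rep(0, ncol(y))
  x_scale <- rep(1, ncol(x))
  y_scale <- rep(1, ncol(y))
  if (scale) {
    x_scale <- apply(x, 2, stats::sd)
    y_scale <- apply(y, 2, stats::sd)
    if (any(x_scale == 0) || any(y_scale == 0)) {
      stop("cannot scale zero-variance columns; see standardize_columns()")
    }
  }
  xc <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  yc <- sweep(sweep(y, 2, y_center), 2, y_scale, "/")

  p <- ncol(xc)
  q <- ncol(yc)
  cx <- penalty_bound(penalty[1], p)
  cy <- penalty_bound(penalty[2], q)
  M <- crossprod(xc, yc)

  u <- matrix(0, p, K, dimnames = list(column_labels(x), paste0("mode", 1:K)))
  v <- matrix(0, q, K, dimnames = list(column_labels(y), paste0("mode", 1:K)))
  d <- cors <- numeric(K)
  converged <- logical(K)
  iterations <- integer(K)
  objective <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- scca_rank1(M, cx, cy, tol = tol, max_iter = max_iter)
    u[, k] <- fit$u
    v[, k] <- fit$v
    d[k] <- fit$d
    converged[k] <- fit$converged
    iterations[k] <- fit$iterations
    objective[[k]] <- fit$objective
    xu <- drop(xc %*% fit$u)
    yv <- drop(yc %*% fit$v)
    cors[k] <- if (stats::sd(xu) == 0 || stats::sd(yv) == 0) NA_real_ else
      stats::cor(xu, yv)
    M <- M - fit$d * tcrossprod(fit$u, fit$v)
  }
  # canonical modes are reported in order of decreasing canonical
  # correlation (the defining order of CCA); deflation order is internal
  ord <- order(-cors, na.last = TRUE)
  u <- u[, ord, drop = FALSE]
  v <- v[, ord, drop = FALSE]
  d <- d[ord]
  cors <- cors[ord]
  converged <- converged[ord]
  iterations <- iterations[ord]
  objective <- objective[ord]
  colnames(u) <- colnames(v) <- paste0("mode", seq_len(K))
  structure(
    list(
      u = u, v = v, d = d, cors = cors,
      n_nonzero_u = colSums(u != 0), n_nonzero_v = colSums(v != 0),
      converged = converged, iterations = iterations, objective = objective,
      penalty = penalty, penalty_abs = c(cx = cx, cy = cy),
      x_center = x_center, x_scale = x_scale,
      y_center = y_center, y_scale = y_scale,
      deflation_residual = sqrt(sum(M^2)),
      dims = c(n = nrow(x), p = p, q = q), K = K,
      call = match.call()
    ),
    class = "scca"
  )
}

#' @export
print.scca <- function(x, ...) {
  cat("Sparse CCA fit:", x$dims["n"], "subjects,", x$dims["p"], "x",
      x$dims["q"], "features; penalty fractions",
      sprintf("(%.2f, %.2f)\n", x$penalty[1], x$penalty[2]))
  tab <- data.frame(
    mode = seq_len(x$K),
    canonical_r = round(x$cors, 4),
    nnz_u = x$n_nonzero_u,
    nnz_v = x$n_nonzero_v,
    converged = x$converged,
    iterations = x$iterations
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.scca <- function(object, n_top = 5L, ...) {
  loadings <- lapply(seq_len(object$K), function(k) {
    vv <- object$v[, k]
    ord <- order(-abs(vv))
    head(data.frame(variable = rownames(object$v)[ord], weight = vv[ord],
                    row.names = NULL), n_top)
  })
  structure(list(fit = object, top_v = loadings), class = "summary.scca")
}

#' @export
print.summary.scca <- function(x, ...) {
  print(x$fit)
  for (k in seq_along(x$top_v)) {
    cat("\nMode", k, "- leading task-side loadings:\n")
    print(x$top_v[[k]], row.names = FALSE)
  }
  invisible(x)
}

#' Extract canonical weight vectors
#'
#' @param object A fitted [scca()] object.
#' @param side `"x"` (connectivity side), `"y"` (task side) or `"both"`.
#' @param ... Unused.
#' @return A weight matrix, or a list of both.
#' @export
coef.scca <- function(object, side = c("both", "x", "y"), ...) {
  side <- match.arg(side)
  switch(side, x = object$u, y = object$v,
         both = list(u = object$u, v = object$v))
}

#' Canonical variates for new (or training) data
#'
#' Projects data onto the fitted canonical weight vectors, applying the
#' centering/scaling recorded at fit time.
#'
#' @param object A fitted [scca()] object.
#' @param newx,newy Matrices with the same columns as the training `x` / `y`.
#'   Either may be omitted.
#' @param ... Unused.
#' @return List with matrices `xu` and/or `yv` (subjects x modes).
#' @export
predict.scca <- function(object, newx = NULL, newy = NULL, ...) {
  out <- list()
  if (!is.null(newx)) {
    newx <- as_numeric_matrix(newx, "newx")
    if (ncol(newx) != object$dims["p"]) stop("`newx` has wrong column count")
    xc <- sweep(sweep(newx, 2, object$x_center), 2, object$x_scale, "/")
    out$xu <- xc %*% object$u
  }
  if (!is.null(newy)) {
    newy <- as_numeric_matrix(newy, "newy")
    if (ncol(newy) != object$dims["q"]) stop("`newy` has wrong column count")
    yc <- sweep(sweep(newy, 2, object$y_center), 2, object$y_scale, "/")
    out$yv <- yc %*% object$v
  }
  if (length(out) == 0) stop("supply `newx` and/or `newy`")
  out
}

#' Canonical variates of a single mode
#'
#' Convenience wrapper around [predict.scca()] returning the per-subject
#' connectivity and task variates `X u_k`, `Y v_k` of one mode.
#'
#' @param object A fitted [scca()] object.
#' @param x,y Data matrices (typically the training data).
#' @param k Mode index.
#' @return List with numeric vectors `xu`, `yv` and the mode index `k`.
#' @export
canonical_variates <- function(object, x, y, k = 1L) {
  k <- as.integer(k)
  if (k < 1 || k > object$K) stop("`k` must be in 1..K")
  pr <- predict(object, newx = x, newy = y)
  list(xu = drop(pr$xu[, k]), yv = drop(pr$yv[, k]), k = k)
}

#' Plot method for scca fits
#'
#' With `x`/`y` data supplied, scatter-plots the two canonical variates of
#' mode `k`; otherwise draws a barplot of the task-side weights of mode `k`.
#'
#' @param x A fitted [scca()] object.
#' @param xdata,ydata Optional data matrices for the variate scatter plot.
#' @param k Mode to display.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.scca <- function(x, xdata = NULL, ydata = NULL, k = 1L, ...) {
  if (!is.null(xdata) && !is.null(ydata)) {
    cv <- canonical_variates(x, xdata, ydata, k = k)
    graphics::plot(cv$xu, cv$yv,
                   xlab = sprintf("connectivity variate (mode %d)", k),
                   ylab = sprintf("task variate (mode %d)", k),
                   main = sprintf("canonical r = %.3f", x$cors[k]), ...)
    graphics::abline(stats::lm(cv$yv ~ cv$xu), col = "grey40")
  } else {
    graphics::barplot(x$v[, k], las = 2,
                      ylab = sprintf("task weight (mode %d)", k), ...)
  }
  invisible(x)
}
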