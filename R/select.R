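# Model selection: penalty tuning by cross-validated out-of-sample rank-1
# canonical correlation, and mode significance by a permutation test that
# compares every observed mode to the permutation distribution of the FIRST
# canonical correlation (family-wise error control).

#' Default penalty search grid
#'
#' Cartesian product of candidate penalty fractions for the two sides.
#'
#' @param cx,cy Candidate fractions in (0, 1] (defaults 0.1 to 1.0 in steps
#'   of 0.1).
#' @return Data frame with columns `cx`, `cy`.
#' @export
default_penalty_grid <- function(cx = seq(0.1, 1, by = 0.1),
                                 cy = seq(0.1, 1, by = 0.1)) {
  if (any(cx <= 0 | cx > 1) || any(cy <= 0 | cy > 1)) {
    stop("penalty fractions must lie in (0, 1]")
  }
  expand.grid(cx = cx, cy = cy, KEEP.OUT.ATTRS = FALSE)
}

#' Cross-validated penalty search for sparse CCA
#'
#' For every penalty pair on the grid, fits the rank-1 sparse CCA on the
#' training rows of each fold and records the out-of-sample (signed) Pearson
#' correlation of the held-out canonical variates; the CV score of a pair is
#' the mean across folds. The pair maximizing the CV score is selected, with
#' ties broken towards the larger `cx + cy`, then the larger `cx` (i.e. the
#' least sparse of the tied models). Folds in which a held-out variate is
#' constant contribute a correlation of 0 and are counted in `n_degenerate`.
#'
#' @param x,y Row-aligned data matrices (standardized beforehand in the
#'   standard pipeline).
#' @param grid Data frame of candidate fractions, see
#'   [default_penalty_grid()].
#' @param k_folds Number of cross-validation folds (default 5).
#' @param seed Seed for the single subject shuffle defining the folds.
#' @param tol,max_iter Passed to the rank-1 solver.
#' @return An object of class `"scca_cv"`: list with `best_penalty` (named
#'   vector `cx`, `cy`), `table` (grid plus `cv_r`), `fold_r` (grid rows x
#'   folds), `folds` (fold assignment), `k_folds`, `seed`, `n_degenerate`.
#' @export
scca_cv <- function(x, y, grid = default_penalty_grid(), k_folds = 5L,
                    seed = 1L, tol = 1e-6, max_iter = 200L) {
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  n <- nrow(x)
  if (nrow(y) != n) stop("`x` and `y` must have the same number of rows")
  k_folds <- as.integer(k_folds)
  if (k_folds < 2 || k_folds > n) stop("`k_folds` must be in 2..n")
  if (!all(c("cx", "cy") %in% names(grid)) || nrow(grid) < 1) {
    stop("`grid` must be a data frame with columns cx, cy")
  }
  if (any(grid$cx <= 0 | grid$cx > 1 | grid$cy <= 0 | grid$cy > 1)) {
    stop("penalty fractions must lie in (0, 1]")
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  p <- ncol(x)
  q <- ncol(y)
  n_degenerate <- 0L
  fold_r <- matrix(NA_real_, nrow(grid), k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- y[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    yte <- y[!tr, , drop = FALSE]
    xtr <- sweep(xtr, 2, colMeans(xtr))
    ytr <- sweep(ytr, 2, colMeans(ytr))
    M <- crossprod(xtr, ytr)
    for (g in seq_len(nrow(grid))) {
      fit <- scca_rank1(M, penalty_bound(grid$cx[g], p),
                        penalty_bound(grid$cy[g], q),
                        tol = tol, max_iter = max_iter)
      xu <- drop(xte %*% fit$u)
      yv <- drop(yte %*% fit$v)
      if (stats::sd(xu) == 0 || stats::sd(yv) == 0) {
        n_degenerate <- n_degenerate + 1L
        fold_r[g, f] <- 0
      } else {
        fold_r[g, f] <- stats::cor(xu, yv)
      }
    }
  }
  cv_r <- rowMeans(fold_r)
  best <- order(-cv_r, -(grid$cx + grid$cy), -grid$cx)[1]
  if (n_degenerate > 0) {
    warning(n_degenerate,
            " fold fit(s) produced a constant held-out variate; ",
            "their correlation was recorded as 0")
  }
  structure(
    list(
      best_penalty = c(cx = grid$cx[best], cy = grid$cy[best]),
      table = cbind(grid, cv_r = cv_r),
      fold_r = fold_r, folds = folds, k_folds = k_folds, seed = seed,
      n_degenerate = n_degenerate
    ),
    class = "scca_cv"
  )
}

#' @export
print.scca_cv <- function(x, ...) {
  cat("Sparse CCA penalty search:", nrow(x$table), "candidate pairs,",
      x$k_folds, "folds\n")
  cat(sprintf("  selected (cx, cy) = (%.2f, %.2f), CV rank-1 r = %.4f\n",
              x$best_penalty["cx"], x$best_penalty["cy"],
              max(x$table$cv_r)))
  if (x$n_degenerate > 0) {
    cat("  degenerate folds:", x$n_degenerate, "\n")
  }
  invisible(x)
}

#' @export
plot.scca_cv <- function(x, ...) {
  cxs <- sort(unique(x$table$cx))
  cys <- sort(unique(x$table$cy))
  z <- matrix(NA_real_, length(cxs), length(cys))
  z[cbind(match(x$table$cx, cxs), match(x$table$cy, cys))] <- x$table$cv_r
  graphics::image(cxs, cys, z, xlab = "cx (connectivity penalty fraction)",
                  ylab = "cy (task penalty fraction)",
                  main = "CV out-of-sample rank-1 correlation", ...)
  graphics::points(x$best_penalty["cx"], x$best_penalty["cy"], pch = 4,
                   lwd = 2)
  invisible(x)
}

# permutation p-value with the (1 + b) / (1 + B) estimator
perm_pvalue <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Permutation test for canonical-mode significance
#'
#' Fits `K` sparse canonical modes on the intact data, then builds a null
#' distribution by permuting the row order of `y` (breaking the link between
#' individuals in the two domains) and refitting; only the FIRST canonical
#' correlation of each permuted sample enters the null, so every observed
#' mode is compared against the strongest association attainable by chance
#' — a family-wise-error-controlling comparison. Because fitted modes are
#' ordered by decreasing canonical correlation, the permuted first
#' canonical correlation is the maximum over the `K` extracted modes, which
#' makes the family-wise comparison exact under exchangeability.
#' P-values use the
#' `(1 + b) / (1 + B)` estimator, never exactly zero. Modes with
#' `p_fwe < alpha` are accepted.
#'
#' @param x,y Row-aligned data matrices (standardized in the standard
#'   pipeline).
#' @param penalty Penalty fractions `(cx, cy)`, typically from [scca_cv()].
#' @param K Number of modes to test.
#' @param n_perm Number of permutations (default 1000). Values below 100
#'   trigger a warning about coarse p-value resolution.
#' @param alpha Acceptance level (default 0.05).
#' @param seed Seed for the permutation stream.
#' @param tol,max_iter Passed to the solver.
#' @return An object of class `"scca_perm"`: list with the observed `fit`
#'   ([scca()] object), `observed_r`, `null_first_r` (length `n_perm`),
#'   `p_fwe`, `accepted`, `alpha`, `n_perm`, `seed`.
#' @export
scca_permtest <- function(x, y, penalty, K = 1L, n_perm = 1000L,
                          alpha = 0.05, seed = 1L, tol = 1e-6,
                          max_iter = 200L) {
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  n <- nrow(x)
  if (nrow(y) != n) stop("`x` and `y` must have the same number of rows")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) stop("`n_perm` must be a positive integer")
  if (n_perm < 100) {
    warning("n_perm = ", n_perm,
            " gives coarse p-value resolution (minimum attainable p = ",
            signif(1 / (1 + n_perm), 3), ")")
  }
  fit <- scca(x, y, penalty = penalty, K = K, tol = tol,
              max_iter = max_iter)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  cx <- fit$penalty_abs["cx"]
  cy <- fit$penalty_abs["cy"]
  null_first_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      yp <- yc[perm, , drop = FALSE]
      M <- crossprod(xc, yp)
      # first canonical correlation of the permuted sample: modes are
      # ordered by canonical correlation, so this is the largest r over
      # the K extracted modes (the max statistic that makes the
      # family-wise comparison exact)
      best <- -Inf
      for (k in seq_len(K)) {
        r1 <- scca_rank1(M, cx, cy, tol = tol, max_iter = max_iter)
        xu <- drop(xc %*% r1$u)
        yv <- drop(yp %*% r1$v)
        r <- if (stats::sd(xu) == 0 || stats::sd(yv) == 0) 0 else
          stats::cor(xu, yv)
        if (r > best) best <- r
        M <- M - r1$d * tcrossprod(r1$u, r1$v)
      }
      best
    }, numeric(1))
  })
  p_fwe <- vapply(fit$cors, perm_pvalue, numeric(1),
                  null_values = null_first_r)
  structure(
    list(
      fit = fit, observed_r = fit$cors, null_first_r = null_first_r,
      p_fwe = p_fwe, accepted = p_fwe < alpha, alpha = alpha,
      n_perm = n_perm, seed = seed
    ),
    class = "scca_perm"
  )
}

#' @export
print.scca_perm <- function(x, ...) {
  cat("Permutation mode test:", x$n_perm, "permutations of the task rows\n")
  tab <- data.frame(
    mode = seq_along(x$observed_r),
    canonical_r = round(x$observed_r, 4),
    p_fwe = signif(x$p_fwe, 4),
    accepted = x$accepted
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.scca_perm <- function(x, ...) {
  graphics::hist(x$null_first_r, breaks = 30,
                 xlab = "permuted first canonical correlation",
                 main = "Permutation null distribution",
                 xlim = range(c(x$null_first_r, x$observed_r)), ...)
  graphics::abline(v = x$observed_r, col = "red3", lwd = 2)
  invisible(x)
}
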