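# Shared fixtures and independent reference implementations used as oracles.

# small default config for fast cohort construction
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 60, n_rois = 10, n_modes = 1,
                   mode_strengths = 0.6, u_sparsity = 5 / 45,
                   v_sparsity = 4 / 13, seed = 42)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# brute-force pairwise Pearson + Fisher-z oracle (independent of cor())
reference_connectome <- function(ts, clip = 1e-7) {
  R <- ncol(ts)
  out <- numeric(0)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      a <- ts[, i] - mean(ts[, i])
      b <- ts[, j] - mean(ts[, j])
      r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      r <- max(min(r, 1 - clip), -(1 - clip))
      out <- c(out, atanh(r))
    }
  }
  out
}

# explicit normal-equations residual maker (I - C (C'C)^-1 C')
reference_residualize <- function(x, confounds) {
  C <- cbind(1, as.matrix(confounds))
  P <- diag(nrow(C)) - C %*% solve(crossprod(C)) %*% t(C)
  P %*% x
}

# pure-R alternating solver, written independently of the compiled path
reference_scca_rank1 <- function(M, cx, cy, tol = 1e-6, max_iter = 200) {
  l1u <- function(a, bound) {
    w <- a / sqrt(sum(a^2))
    if (sum(abs(w)) <= bound + 1e-8) return(w)
    lo <- 0
    hi <- max(abs(a))
    while (hi - lo > 1e-10 * max(1, hi)) {
      mid <- (lo + hi) / 2
      s <- pmax(abs(a) - mid, 0) * sign(a)
      if (sum(abs(s)) == 0 || sum(abs(s)) <= bound * sqrt(sum(s^2))) {
        hi <- mid
      } else {
        lo <- mid
      }
    }
    s <- pmax(abs(a) - hi, 0) * sign(a)
    s / sqrt(sum(s^2))
  }
  v <- svd(M)$v[, 1]
  u <- rep(0, nrow(M))
  for (it in seq_len(max_iter)) {
    u_new <- l1u(drop(M %*% v), cx)
    v_new <- l1u(drop(crossprod(M, u_new)), cy)
    if (max(abs(u_new - u), abs(v_new - v)) < tol) {
      u <- u_new
      v <- v_new
      break
    }
    u <- u_new
    v <- v_new
  }
  top <- which.max(abs(v))
  if (v[top] < 0) {
    u <- -u
    v <- -v
  }
  list(u = u, v = v)
}

# Pillai / F via the eigenvalue form V = sum(lambda / (1 + lambda)) of E^-1 H
reference_pillai <- function(H, E, vh, ve) {
  q <- ncol(E)
  lambda <- Re(eigen(solve(E) %*% H, only.values = TRUE)$values)
  V <- sum(lambda / (1 + lambda))
  s <- min(vh, q)
  m <- (abs(q - vh) - 1) / 2
  nn <- (ve - q - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  list(pillai = V, f_stat = (df2 / df1) * V / (s - V),
       df1 = df1, df2 = df2)
}

# align the sign of an estimated vector to a reference before comparison
sign_align <- function(est, ref) est * sign(sum(est * ref))

# match fitted modes to planted modes by task-side cosine similarity
match_modes <- function(fit, v_true) {
  vapply(v_true, function(vt) {
    which.max(abs(crossprod(fit$v, vt)))
  }, integer(1))
}
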