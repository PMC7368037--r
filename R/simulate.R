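# Synthetic cohort generator with planted sparse cross-covariance modes.
#
# The generative model: K latent subject scores z_k ~ N(0, 1), mutually
# independent; sparse unit canonical vectors u_k (connectivity space) and v_k
# (task space) with disjoint, equal-magnitude supports; features
#   X = mu + sum_k a_k z_k u_k' + heteroscedastic edge noise
#   Y =      sum_k b_k z_k v_k' + homoscedastic task noise,
# with a_k, b_k calibrated so that the population correlation of
# (X u_k, Y v_k) equals the requested mode strength rho_k.  Experience
# sampling items are linearly coupled to the latent scores; age, sex and
# head motion act additively on the features.  Edge noise scales vary
# (lognormally) across edges and the planted supports are drawn from the
# most variable edges: between-subject signal is itself between-subject
# variance, so a generative model in which association-carrying edges were
# near-constant across subjects would be internally inconsistent (and the
# robust variance filter exists precisely because signal lives in variable
# edges).

default_mdes_loadings <- function() {
  c(task = -0.40, future = 0.35, past = 0.30, self = 0.25, people = 0.10,
    emotion = -0.10, images = 0.20, words = 0.10, vivid = 0.35,
    detailed = 0.40, habit = 0.10, evolving = 0.15, deliberate = -0.25)
}

#' Configuration for a synthetic cohort
#'
#' Collects and validates every generator setting. Defaults emulate the
#' target study design: 178 subjects, a 100-ROI connectome (4,950 Fisher-z
#' edge features), 13 cognitive scores, 13 experience-sampling items, and
#' two planted modes of canonical correlation 0.57 and 0.59 with thought
#' reports coupled to the second (stronger) mode only.
#'
#' @param n_subjects Number of subjects (default 178).
#' @param n_rois Number of ROIs (default 100; features = R(R-1)/2).
#' @param n_timepoints Time-series length for `generation_mode =
#'   "timeseries"` (default 177, i.e. 180 volumes minus 3 dummies).
#' @param n_modes Number of planted modes `K` (0 for a pure-null cohort).
#' @param mode_strengths Canonical correlations `rho_k`, each in (0, 1);
#'   length `n_modes`.
#' @param u_sparsity,v_sparsity Fraction of nonzero entries per planted
#'   canonical vector, in (0, 1].
#' @param mdes_loadings `n_modes` x 13 matrix coupling latent scores to the
#'   experience-sampling items. Default: zero except the last planted mode,
#'   which carries an off-task / mental-time-travel pattern (negative task
#'   focus; positive future, past, self, vivid, detailed).
#' @param noise_sd Median residual standard deviation of the edge features
#'   (default 0.2, a typical between-subject spread of Fisher-z edges); also
#'   the task-score residual standard deviation.
#' @param edge_sd_spread Log-scale spread of the per-edge noise standard
#'   deviations (default 0.3).
#' @param signal_pool Fraction of the most variable edges from which the
#'   planted supports are drawn (default 0.05).
#' @param mdes_noise_sd Residual standard deviation of each per-condition,
#'   per-day experience-sampling cell (default 1; the overall item mean then
#'   carries noise `1/sqrt(6)` of this).
#' @param item_cor Optional 13 x 13 correlation matrix for the item noise
#'   (default: independent).
#' @param confound_sd Relative magnitude of the additive age/sex/motion
#'   effects on the features (0 disables them; default 0.25).
#' @param day_dropout Per-day probability that a subject misses that
#'   session's experience sampling (default `c(0, 0.02, 0.15)`, mirroring
#'   attrition over repeated sessions).
#' @param generation_mode `"direct_features"` (Fisher-z features generated
#'   directly) or `"timeseries"` (per-subject ROI series drawn from a
#'   multivariate normal whose correlation matrix inverts the planted
#'   Fisher-z values; adds realistic estimation noise).
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return An object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_subjects = 178, n_rois = 100,
                          n_timepoints = 177, n_modes = 2,
                          mode_strengths = c(0.57, 0.59),
                          u_sparsity = 0.004, v_sparsity = 0.3,
                          mdes_loadings = NULL, noise_sd = 0.2,
                          edge_sd_spread = 0.3, signal_pool = 0.05,
                          mdes_noise_sd = 1, item_cor = NULL,
                          confound_sd = 0.25,
                          day_dropout = c(0, 0.02, 0.15),
                          generation_mode = c("direct_features",
                                              "timeseries"),
                          seed = 1L) {
  generation_mode <- match.arg(generation_mode)
  n_subjects <- as.integer(n_subjects)
  n_rois <- as.integer(n_rois)
  n_modes <- as.integer(n_modes)
  stopifnot(n_subjects >= 2, n_rois >= 2, n_timepoints >= 3, n_modes >= 0)
  if (length(mode_strengths) != n_modes) {
    stop("`mode_strengths` must have length `n_modes`")
  }
  if (n_modes > 0 && (any(mode_strengths <= 0) || any(mode_strengths >= 1))) {
    stop("all mode strengths must lie in the open interval (0, 1)")
  }
  if (u_sparsity <= 0 || u_sparsity > 1 || v_sparsity <= 0 || v_sparsity > 1) {
    stop("sparsity fractions must lie in (0, 1]")
  }
  if (noise_sd < 0 || mdes_noise_sd < 0 || confound_sd < 0) {
    stop("standard deviations must be nonnegative")
  }
  if (length(day_dropout) != 3 || any(day_dropout < 0 | day_dropout >= 1)) {
    stop("`day_dropout` must be three probabilities in [0, 1)")
  }
  n_mdes <- 13L
  if (is.null(mdes_loadings)) {
    mdes_loadings <- matrix(0, n_modes, n_mdes,
                            dimnames = list(NULL, mdes_items()))
    if (n_modes > 0) mdes_loadings[n_modes, ] <- default_mdes_loadings()
  } else {
    mdes_loadings <- as.matrix(mdes_loadings)
    if (!all(dim(mdes_loadings) == c(n_modes, n_mdes))) {
      stop("`mdes_loadings` must be n_modes x 13")
    }
    colnames(mdes_loadings) <- mdes_items()
  }
  if (!is.null(item_cor)) {
    item_cor <- as.matrix(item_cor)
    if (!all(dim(item_cor) == c(n_mdes, n_mdes)) ||
        any(abs(item_cor - t(item_cor)) > 1e-10) ||
        any(abs(diag(item_cor) - 1) > 1e-10)) {
      stop("`item_cor` must be a symmetric 13 x 13 correlation matrix")
    }
  }
  structure(
    list(n_subjects = n_subjects, n_rois = n_rois,
         n_timepoints = as.integer(n_timepoints), n_modes = n_modes,
         mode_strengths = as.numeric(mode_strengths),
         u_sparsity = u_sparsity, v_sparsity = v_sparsity,
         mdes_loadings = mdes_loadings, noise_sd = noise_sd,
         edge_sd_spread = edge_sd_spread, signal_pool = signal_pool,
         mdes_noise_sd = mdes_noise_sd, item_cor = item_cor,
         confound_sd = confound_sd, day_dropout = day_dropout,
         generation_mode = generation_mode, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:\n")
  cat("  subjects:", x$n_subjects, " ROIs:", x$n_rois,
      sprintf("(%d edge features)", x$n_rois * (x$n_rois - 1) / 2), "\n")
  cat("  planted modes:", x$n_modes,
      if (x$n_modes > 0) paste0("(rho = ",
                                paste(x$mode_strengths, collapse = ", "),
                                ")"), "\n")
  cat("  generation mode:", x$generation_mode, " seed:", x$seed, "\n")
  invisible(x)
}

# sparse vector with equal-magnitude entries +-1/sqrt(nnz) on `support`
sparse_unit <- function(p, support) {
  w <- numeric(p)
  w[support] <- sample(c(-1, 1), length(support), replace = TRUE) /
    sqrt(length(support))
  w
}

# eigenvalue-clipping projection to the nearest positive-definite
# correlation matrix; `floor` is the minimum retained eigenvalue
nearest_pd_correlation <- function(C, floor = 1e-6, hard_limit = -0.5) {
  ee <- eigen(C, symmetric = TRUE)
  if (min(ee$values) < hard_limit) {
    stop("target correlation matrix is too far from positive definite ",
         sprintf("(min eigenvalue %.3f)", min(ee$values)), call. = FALSE)
  }
  if (min(ee$values) >= floor) return(C)
  vals <- pmax(ee$values, floor)
  C2 <- ee$vectors %*% (vals * t(ee$vectors))
  d <- sqrt(diag(C2))
  C2 / tcrossprod(d)
}

# encode the planted task-score matrix S (n x 13, schedule column order) as a
# long raw-measure table that assemble_scores() inverts exactly (every
# derived score is an increasing affine function of its planted column)
encode_raw_task_table <- function(S, subjects) {
  unit <- function(j) {
    s <- stats::sd(S[, j])
    if (s == 0) rep(0, nrow(S)) else S[, j] / s
  }
  rows <- list()
  add <- function(measure, value, condition = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subjects, measure = measure, condition = condition,
      value = value, stringsAsFactors = FALSE)
  }
  add("digit_span_forward", 7 + 0.6 * unit(1))
  add("digit_span_backward", 5 + 0.6 * unit(1))
  add("fluency_category", 21 + 1.5 * unit(2))
  add("fluency_letter", 18 - 1.5 * unit(2))
  add("naming_accuracy", 0.85 + 0.05 * unit(3))
  add("four_mountains_accuracy", 0.70 + 0.05 * unit(4))
  add("rapm_accuracy", 0.60 + 0.05 * unit(5))
  add("switch_cost", 150 - 40 * unit(6))     # ms; flexibility = -switch_cost
  add("inhibition_cost", 100 - 30 * unit(7)) # ms; inhibition = -cost
  eff_cond <- function(condition, eff_target) {
    acc <- stats::runif(nrow(S), 0.75, 0.95)
    add("reaction_time", -eff_target * acc, condition)
    add("accuracy", acc, condition)
  }
  eff_cond("feature_matching", -1.5 + 0.12 * unit(8))
  eff_cond("paired_associate", -1.6 + 0.12 * unit(9))
  eff_cond("strong", -1.4 + 0.06 * unit(10))
  eff_cond("weak", -1.4 - 0.06 * unit(10))
  eff_cond("picture", -1.3 + 0.06 * unit(11))
  eff_cond("word", -1.3 - 0.06 * unit(11))
  eff_cond("specific", -1.5 + 0.06 * unit(12))
  eff_cond("general", -1.5 - 0.06 * unit(12))
  add("unusual_uses", 12 + 2 * unit(13))
  do.call(rbind, rows)
}

# draw an n x q noise matrix, optionally with correlated columns
noise_matrix <- function(n, q, sd, item_cor = NULL) {
  E <- matrix(stats::rnorm(n * q, sd = sd), n, q)
  if (!is.null(item_cor)) E <- E %*% chol(item_cor)
  E
}

.simulate_cohort <- function(config) {
  n <- config$n_subjects
  R <- config$n_rois
  p <- R * (R - 1L) / 2L
  q <- 13L
  K <- config$n_modes
  pairs <- roi_pairs(R)
  pair_labels <- paste0("roi", pairs$i, "--roi", pairs$j)
  subjects <- sprintf("sub-%03d", seq_len(n))

  # per-edge baseline mean and noise scale (lognormal spread across edges)
  mu_edge <- stats::rnorm(p, mean = 0.25, sd = 0.15)
  sigma_edge <- config$noise_sd *
    exp(stats::rnorm(p, sd = config$edge_sd_spread))

  # planted canonical vectors: disjoint supports among the most variable edges
  nnz_u <- max(1L, as.integer(round(config$u_sparsity * p)))
  nnz_v <- max(1L, as.integer(round(config$v_sparsity * q)))
  if (K > 0) {
    pool_size <- max(ceiling(config$signal_pool * p), K * nnz_u)
    if (pool_size > p) stop("not enough edge features for the requested ",
                            "number and sparsity of modes")
    if (K * nnz_v > q) stop("K * nnz_v exceeds the 13 task scores; lower ",
                            "`v_sparsity` or `n_modes`")
    pool <- order(sigma_edge, decreasing = TRUE)[seq_len(pool_size)]
    u_support <- split(sample(pool, K * nnz_u),
                       rep(seq_len(K), each = nnz_u))
    # signal edges of one mode share a common noise scale, so that column
    # standardization rescales the support uniformly and the planted
    # direction is preserved in the standardized cross-covariance
    for (s in u_support) sigma_edge[s] <- mean(sigma_edge[s])
    v_support <- split(sample.int(q, K * nnz_v),
                       rep(seq_len(K), each = nnz_v))
    u_true <- lapply(u_support, function(s) sparse_unit(p, s))
    v_true <- lapply(v_support, function(s) sparse_unit(q, s))
  } else {
    u_support <- v_support <- u_true <- v_true <- list()
  }

  Z <- matrix(stats::rnorm(n * max(K, 1L)), n, max(K, 1L))[, seq_len(K),
                                                           drop = FALSE]

  # signal amplitudes calibrated so corr(X u_k, Y v_k) = rho_k in population
  amp <- function(rho, noise) {
    if (noise == 0) 1 else noise * sqrt(rho / (1 - rho))
  }
  a <- b <- numeric(K)
  X <- sweep(matrix(stats::rnorm(n * p), n, p), 2, sigma_edge, "*")
  X <- sweep(X, 2, mu_edge, "+")
  Y <- matrix(stats::rnorm(n * q, sd = config$noise_sd), n, q)
  for (k in seq_len(K)) {
    rho <- config$mode_strengths[k]
    sig_u <- sqrt(sum((u_true[[k]] * sigma_edge)^2))
    sig_v <- config$noise_sd # equal-magnitude v => projected noise sd
    a[k] <- amp(rho, sig_u)
    b[k] <- amp(rho, sig_v)
    s <- u_support[[k]]
    X[, s] <- X[, s] + a[k] * tcrossprod(Z[, k], u_true[[k]][s])
    Y <- Y + b[k] * tcrossprod(Z[, k], v_true[[k]])
  }

  # covariates and additive confound effects
  age <- stats::runif(n, 18, 31)
  sex <- stats::rbinom(n, 1, 0.64)
  mean_fd <- stats::rlnorm(n, meanlog = log(0.15), sdlog = 0.35)
  covariates <- data.frame(age = age, sex = sex, mean_fd = mean_fd,
                           row.names = subjects)
  Cs <- scale(as.matrix(covariates))
  confound_x <- confound_y <- NULL
  # in a null cohort (K = 0) the covariates act on the connectivity side
  # only, keeping X and Y exactly independent as the null model requires
  if (config$confound_sd > 0) {
    Bx <- matrix(stats::rnorm(3 * p), 3, p) *
      rep(config$confound_sd * sigma_edge / sqrt(3), each = 3)
    By <- matrix(stats::rnorm(3 * q,
                              sd = config$confound_sd * config$noise_sd /
                                sqrt(3)), 3, q)
    if (K == 0) By[] <- 0
    X <- X + Cs %*% Bx
    Y <- Y + Cs %*% By
    sds <- attr(Cs, "scaled:scale")
    confound_x <- Bx / sds  # coefficients on the raw covariate scale
    confound_y <- By / sds
    rownames(confound_x) <- rownames(confound_y) <- colnames(covariates)
  }
  colnames(X) <- pair_labels
  rownames(X) <- subjects
  colnames(Y) <- c("digit_span", "verbal_fluency_contrast", "picture_naming",
                   "four_mountains", "rapm", "flexibility", "inhibition",
                   "feature_matching_eff", "paired_associate_eff",
                   "strength_contrast", "modality_contrast",
                   "specificity_contrast", "unusual_uses")
  rownames(Y) <- subjects

  raw_task <- encode_raw_task_table(Y, subjects)

  # experience sampling: 2 conditions x 3 days of per-cell item means
  P <- if (K > 0) Z %*% config$mdes_loadings else matrix(0, n, q)
  present_day <- vapply(1:3, function(d) {
    stats::runif(n) >= config$day_dropout[d]
  }, logical(n))
  mdes_rows <- list()
  for (cond in c("0back", "1back")) {
    for (d in 1:3) {
      cell <- P + noise_matrix(n, q, config$mdes_noise_sd, config$item_cor)
      colnames(cell) <- mdes_items()
      keep <- present_day[, d]
      mdes_rows[[paste(cond, d)]] <- data.frame(
        subject = subjects[keep], condition = cond, day = d,
        cell[keep, , drop = FALSE], stringsAsFactors = FALSE)
    }
  }
  mdes <- do.call(rbind, mdes_rows)
  rownames(mdes) <- NULL
  overall <- stats::aggregate(mdes[mdes_items()],
                              by = list(subject = mdes$subject), FUN = mean)
  overall <- overall[match(subjects, overall$subject), ]
  rownames(overall) <- NULL

  roi_timeseries <- NULL
  connectivity <- X
  if (config$generation_mode == "timeseries") {
    roi_timeseries <- lapply(seq_len(n), function(i) {
      zmat <- matrix(0, R, R)
      zmat[cbind(pairs$i, pairs$j)] <- X[i, ]
      rmat <- tanh(zmat + t(zmat))
      diag(rmat) <- 1
      Cm <- tryCatch(nearest_pd_correlation(rmat), error = function(e) {
        stop("subject ", subjects[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
      ts <- matrix(stats::rnorm(config$n_timepoints * R),
                   config$n_timepoints, R) %*% chol(Cm)
      colnames(ts) <- paste0("roi", seq_len(R))
      ts
    })
    names(roi_timeseries) <- subjects
    connectivity <- NULL
  }

  ground_truth <- list(
    K_true = K, u_true = u_true, v_true = v_true, z_true = Z,
    mode_strengths = config$mode_strengths, a = a, b = b,
    u_support = u_support, v_support = v_support,
    mdes_loadings = config$mdes_loadings,
    confound_coef_x = confound_x, confound_coef_y = confound_y,
    sigma_edge = sigma_edge, mu_edge = mu_edge
  )
  structure(
    list(subjects = subjects, config = config,
         connectivity = connectivity, roi_timeseries = roi_timeseries,
         pair_index = pairs, raw_task = raw_task, task_scores = Y,
         mdes = mdes, mdes_overall = overall, covariates = covariates,
         ground_truth = ground_truth),
    class = "synthetic_cohort"
  )
}

#' Generate a synthetic cohort with planted modes
#'
#' Draws a full cohort — connectivity features (or ROI time series), a raw
#' cognitive-task table, per-condition/per-day experience-sampling item
#' means, covariates — from the generative model described in
#' [cohort_config()], and returns it together with the realized ground
#' truth.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `"synthetic_cohort"`: list with elements
#'   `subjects`, `connectivity` (subjects x edges Fisher-z matrix; `NULL` in
#'   time-series mode), `roi_timeseries` (list; `NULL` in direct mode),
#'   `pair_index`, `raw_task` (long table), `task_scores` (the planted 13
#'   score columns, pre-standardization), `mdes` (long per-condition/day
#'   table), `mdes_overall`, `covariates` and `ground_truth`.
#' @examples
#' cfg <- cohort_config(n_subjects = 40, n_rois = 10, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$connectivity) # 40 x 45
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created with cohort_config()")
  }
  with_seed(config$seed, .simulate_cohort(config))
}

#' Generate a null cohort (no brain-behaviour association)
#'
#' Identical marginal structure to [simulate_cohort()] but with all planted
#' mode strengths forced to zero: connectivity, task scores and experience
#' sampling are mutually independent. The ground truth records `K_true = 0`
#' and empty canonical-vector lists.
#'
#' @param config A [cohort_config()] object (its `n_modes` /
#'   `mode_strengths` are ignored).
#' @return A `"synthetic_cohort"` object.
#' @export
simulate_null_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created with cohort_config()")
  }
  null_config <- config
  null_config$n_modes <- 0L
  null_config$mode_strengths <- numeric(0)
  null_config$mdes_loadings <- matrix(0, 0, 13,
                                      dimnames = list(NULL, mdes_items()))
  with_seed(config$seed, .simulate_cohort(null_config))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$config$n_rois * (x$config$n_rois - 1) / 2
  cat("Synthetic cohort:", length(x$subjects), "subjects,",
      x$config$n_rois, "ROIs (", p, "edge features ),",
      x$ground_truth$K_true, "planted mode(s)\n")
  cat("  generation mode:", x$config$generation_mode,
      " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' Writes every table of the cohort as tab-separated text plus a JSON
#' ground-truth sidecar and a manifest listing all paths and the seed.
#'
#' @param cohort A `"synthetic_cohort"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must be a synthetic_cohort")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(obj, name, rn = FALSE) {
    path <- file.path(dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
    path
  }
  paths <- list()
  if (!is.null(cohort$connectivity)) {
    paths$connectivity <- tsv(cohort$connectivity, "connectivity.tsv",
                              rn = TRUE)
  }
  if (!is.null(cohort$roi_timeseries)) {
    ts_dir <- file.path(dir, "timeseries")
    dir.create(ts_dir, showWarnings = FALSE)
    paths$timeseries <- vapply(names(cohort$roi_timeseries), function(id) {
      f <- file.path(ts_dir, paste0(id, ".tsv"))
      utils::write.table(cohort$roi_timeseries[[id]], f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f
    }, character(1))
  }
  paths$pair_index <- tsv(cohort$pair_index, "pair_index.tsv")
  paths$raw_task <- tsv(cohort$raw_task, "task_raw.tsv")
  paths$task_scores <- tsv(cohort$task_scores, "task_scores_planted.tsv",
                           rn = TRUE)
  paths$mdes <- tsv(cohort$mdes, "mdes_strata.tsv")
  paths$mdes_overall <- tsv(cohort$mdes_overall, "mdes_overall.tsv")
  paths$covariates <- tsv(cohort$covariates, "covariates.tsv", rn = TRUE)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(cohort$ground_truth, gt_path, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  paths$ground_truth <- gt_path
  manifest <- list(seed = cohort$config$seed,
                   generation_mode = cohort$config$generation_mode,
                   n_subjects = cohort$config$n_subjects,
                   n_rois = cohort$config$n_rois, paths = paths)
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
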