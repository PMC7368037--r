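test_that("mode scores are the mean of the z-scored variates", {
  set.seed(1)
  xu <- rnorm(40, mean = 3, sd = 2)
  yv <- rnorm(40, mean = -1, sd = 0.5)
  ms <- mode_score(xu, yv)
  zx <- (xu - mean(xu)) / sd(xu)
  zy <- (yv - mean(yv)) / sd(yv)
  expect_equal(unname(ms$score[, 1]), (zx + zy) / 2, tolerance = 1e-12)
  # identical variates: the score equals the z-scored variate
  ms2 <- mode_score(xu, xu)
  expect_equal(unname(ms2$score[, 1]), zx, tolerance = 1e-12)
  expect_error(mode_score(rep(1, 10), rnorm(10)), "constant")
})

test_that("mean-of-z and sum-of-z scores are statistically equivalent", {
  set.seed(2)
  xu <- rnorm(60)
  yv <- 0.5 * xu + rnorm(60)
  outcome <- rnorm(60)
  ms <- mode_score(xu, yv)
  sum_score <- ms$variate_fc + ms$variate_task
  expect_equal(unname(sum_score), unname(2 * ms$score), tolerance = 1e-12)
  expect_equal(cor(ms$score[, 1], outcome), cor(sum_score[, 1], outcome),
               tolerance = 1e-12)
})

test_that("a saturated univariate regression yields Pillai 1, exact slope", {
  set.seed(3)
  x <- scale(rnorm(30))[, 1] # unit sd so the reported beta equals the slope
  y <- cbind(item = 2 * x)
  res <- manova_pillai(y, data.frame(x = x))
  p <- res$patterns$x
  expect_equal(p$pillai, 1, tolerance = 1e-10)
  expect_true(is.infinite(p$f_stat))
  expect_equal(p$p_value, 0)
  expect_equal(unname(p$coefficients), 2, tolerance = 1e-8)
})

test_that("Pillai and F match the eigenvalue-form oracle", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 40
    y <- matrix(rnorm(n * 3), n, 3)
    pred <- data.frame(a = rnorm(n), b = rnorm(n))
    res <- manova_pillai(y, pred)
    X <- model.matrix(~., pred)
    E <- crossprod(qr.resid(qr(X), y))
    for (j in 2:3) {
      Er <- crossprod(qr.resid(qr(X[, -j]), y))
      ref <- reference_pillai(Er - E, E, vh = 1, ve = n - 3)
      got <- res$patterns[[colnames(X)[j]]]
      expect_equal(got$pillai, ref$pillai, tolerance = 1e-8)
      expect_equal(got$f_stat, ref$f_stat, tolerance = 1e-8)
      expect_equal(got$df_num, ref$df1)
      expect_equal(got$df_den, ref$df2)
      expect_equal(got$eta_sq, ref$pillai / 1, tolerance = 1e-10)
    }
  }
})

test_that("Type III statistics agree with car::Manova", {
  skip_if_not_installed("car")
  set.seed(5)
  n <- 60
  y <- matrix(rnorm(n * 4), n, 4)
  colnames(y) <- paste0("i", 1:4)
  d <- data.frame(m1 = rnorm(n), m2 = rnorm(n), age = runif(n, 18, 31))
  res <- manova_pillai(y, d)
  fit <- lm(y ~ m1 + m2 + age, data = d)
  cm <- summary(car::Manova(fit, type = "III"))$multivariate.tests
  for (term in c("m1", "m2", "age")) {
    stats <- cm[[term]]
    ev <- Re(eigen(qr.coef(qr(stats$SSPE), stats$SSPH),
                   only.values = TRUE)$values)
    expect_equal(res$patterns[[term]]$pillai, sum(ev / (1 + ev)),
                 tolerance = 1e-8)
  }
})

test_that("Pillai is invariant to joint invertible item transforms", {
  set.seed(6)
  n <- 50
  y <- matrix(rnorm(n * 5), n, 5)
  pred <- data.frame(x = rnorm(n))
  A <- matrix(rnorm(25), 5, 5) + 5 * diag(5)
  res1 <- manova_pillai(y, pred)
  res2 <- manova_pillai(y %*% A, pred)
  expect_equal(res1$patterns$x$pillai, res2$patterns$x$pillai,
               tolerance = 1e-8)
  expect_equal(res1$patterns$x$f_stat, res2$patterns$x$f_stat,
               tolerance = 1e-8)
})

test_that("an orthogonalized pure-noise covariate leaves coefficients alone", {
  set.seed(7)
  n <- 50
  y <- matrix(rnorm(n * 4), n, 4)
  x <- rnorm(n)
  noise <- rnorm(n)
  design <- cbind(1, x)
  noise_orth <- noise - design %*% solve(crossprod(design)) %*%
    crossprod(design, noise)
  r1 <- manova_pillai(y, data.frame(x = x))
  r2 <- manova_pillai(y, data.frame(x = x, z = drop(noise_orth)))
  expect_equal(r1$patterns$x$coefficients, r2$patterns$x$coefficients,
               tolerance = 1e-10)
})

test_that("null mode scores give calibrated MANOVA p-values", {
  set.seed(8)
  n <- 60
  rej <- vapply(1:1000, function(b) {
    y <- matrix(rnorm(n * 13), n, 13)
    res <- manova_pillai(y, data.frame(score = rnorm(n)),
                         data.frame(age = runif(n, 18, 31),
                                    sex = rbinom(n, 1, 0.6),
                                    fd = rlnorm(n, log(0.15), 0.3)))
    res$patterns$score$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("collinear or undersized designs are rejected informatively", {
  set.seed(9)
  y <- matrix(rnorm(40 * 3), 40, 3)
  x <- rnorm(40)
  expect_error(manova_pillai(y, data.frame(a = x, b = 2 * x)), "collinear")
  expect_error(manova_pillai(matrix(rnorm(9 * 8), 9, 8),
                             data.frame(a = rnorm(9))), "n >")
})

test_that("pattern similarity matches cor.test and handles edge cases", {
  set.seed(10)
  a <- rnorm(13)
  b <- 0.5 * a + rnorm(13)
  ps <- pattern_similarity(a, b)
  ct <- cor.test(a, b)
  expect_equal(ps$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ps$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pattern_similarity(a, a)$r, 1)
  expect_equal(pattern_similarity(a, -a)$r, -1)
  expect_error(pattern_similarity(rep(1, 13), a), "constant")
  expect_error(pattern_similarity(a[1:2], b[1:2]), "length")
})

test_that("identical strata produce identical thought patterns", {
  set.seed(11)
  n <- 40
  items <- matrix(rnorm(n * 13), n, 13)
  colnames(items) <- mdes_items()
  subjects <- sprintf("s%02d", 1:n)
  mdes <- rbind(
    data.frame(subject = subjects, condition = "0back", day = 1, items,
               check.names = FALSE),
    data.frame(subject = subjects, condition = "1back", day = 1, items,
               check.names = FALSE)
  )
  pred <- data.frame(score = rnorm(n), row.names = subjects)
  res <- stratified_patterns(mdes, pred, by = "condition")
  expect_equal(res[["0back"]]$patterns$score$coefficients,
               res[["1back"]]$patterns$score$coefficients,
               tolerance = 1e-12)
})

test_that("undersized strata fail with the stratum named", {
  set.seed(12)
  n <- 30
  items <- matrix(rnorm(n * 13), n, 13)
  colnames(items) <- mdes_items()
  subjects <- sprintf("s%02d", 1:n)
  mdes <- rbind(
    data.frame(subject = subjects, condition = "0back", day = 1, items,
               check.names = FALSE),
    data.frame(subject = subjects[1:10], condition = "1back", day = 1,
               items[1:10, ], check.names = FALSE)
  )
  pred <- data.frame(score = rnorm(n), row.names = subjects)
  expect_error(stratified_patterns(mdes, pred, by = "condition"),
               "1back.*too few")
})

test_that("condition-invariant coupling yields stable patterns; permuted strata decorrelate", {
  rs_stable <- numeric(0)
  rs_broken <- numeric(0)
  for (b in 1:8) {
    cfg <- cohort_config(n_subjects = 178, n_rois = 10, n_modes = 1,
                         mode_strengths = 0.59, u_sparsity = 6 / 45,
                         v_sparsity = 4 / 13,
                         mdes_loadings = matrix(neurocca:::default_mdes_loadings(),
                                                1, 13),
                         day_dropout = c(0, 0, 0), seed = 7000 + b)
    co <- simulate_cohort(cfg)
    score <- (scale(co$ground_truth$z_true[, 1]) +
                rnorm(178, sd = 0.3))[, 1] # noisy proxy for the mode score
    pred <- data.frame(score = score, co$covariates)
    res <- stratified_patterns(co$mdes, pred, subjects = co$subjects,
                               by = "condition")
    a <- res[["0back"]]$patterns$score$coefficients
    bb <- res[["1back"]]$patterns$score$coefficients
    rs_stable <- c(rs_stable, pattern_similarity(a, bb)$r)
    # negative control: break one stratum by permuting its item rows
    mdes_broken <- co$mdes
    idx <- which(mdes_broken$condition == "1back")
    set.seed(b)
    mdes_broken[idx, mdes_items()] <-
      mdes_broken[sample(idx), mdes_items()]
    res2 <- stratified_patterns(mdes_broken, pred,
                                subjects = co$subjects, by = "condition")
    rs_broken <- c(rs_broken,
                   pattern_similarity(res2[["0back"]]$patterns$score,
                                      res2[["1back"]]$patterns$score)$r)
  }
  expect_gte(median(rs_stable), 0.9)
  expect_lt(median(abs(rs_broken)), 0.4)
})
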