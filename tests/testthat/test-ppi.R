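test_that("the PPI percentage formula and its sign convention are exact", {
  expect_equal(ppi_percent(2, 1), 50)
  expect_equal(ppi_percent(2, 2), 0)
  expect_equal(ppi_percent(2, 2.5), -25)     # facilitation
  expect_error(ppi_percent(0, 1), "positive")
  expect_error(ppi_percent(-1, 1), "positive")

  # scale invariance, exactly
  set.seed(8)
  p <- stats::runif(50, 0.5, 8); b <- stats::runif(50, 0, 8)
  for (k in c(0.1, 3, 1e4))
    expect_equal(ppi_percent(k * p, k * b), ppi_percent(p, b),
                 tolerance = 1e-12)
})

test_that("ppi_table recovers ground truth on noise-free data", {
  session <- build_session(seed = 5)
  prof <- subject_profile(A0 = 4, beta_true = 0,
                          ppi_true = c(`30` = 0, `60` = 0.5, `120` = 0.1))
  d <- simulate_trial_amplitudes(prof, session, seed = 1, trial_noise_sd = 0)
  d$subject <- "s1"
  pt <- ppi_table(d)
  ov <- pt[pt$run == "overall", ]
  expect_equal(ov$ppi_percent[ov$soa_ms == 60], 50, tolerance = 0.01)
  expect_equal(ov$ppi_percent[ov$soa_ms == 30], 0, tolerance = 0.01)
  expect_equal(ov$ppi_percent[ov$soa_ms == 120], 10, tolerance = 0.01)
  # per-run rows use that run's pulse mean
  expect_equal(pt$pulse_mean[pt$run == "2" & pt$soa_ms == 60],
               mean(d$peak_amp[d$run == 2 & d$trial_type == "pulse"]))

  # all-zero inhibition
  d0 <- simulate_trial_amplitudes(
    subject_profile(A0 = 4, beta_true = 0,
                    ppi_true = c(`30` = 0, `60` = 0, `120` = 0)),
    session, seed = 2, trial_noise_sd = 0)
  d0$subject <- "s1"
  expect_true(all(abs(ppi_table(d0)$ppi_percent) < 1e-9))
})

test_that("a missing run propagates as NA and a warning, overall uses the rest", {
  session <- build_session(seed = 5)
  prof <- subject_profile(A0 = 4, beta_true = 0,
                          ppi_true = c(`30` = 0, `60` = 0.5, `120` = 0.1))
  d <- simulate_trial_amplitudes(prof, session, seed = 1, trial_noise_sd = 0)
  d$subject <- "s1"
  d <- d[d$run != 2, ]
  pt <- suppressWarnings(ppi_table(d))
  expect_true(all(is.na(pt$ppi_percent[pt$run == "2"])))
  expect_equal(pt$ppi_percent[pt$run == "overall" & pt$soa_ms == 60], 50,
               tolerance = 0.01)
  w <- testthat::capture_warnings(ppi_table(d))
  expect_true(any(grepl("runs 1,3", w)))
})

test_that("Greenhouse-Geisser epsilon matches the double-centering oracle and its bounds", {
  expect_equal(gg_epsilon(matrix(stats::rnorm(20), 10, 2)), 1)   # k = 2

  set.seed(21)
  for (i in 1:200) {
    k <- sample(3:5, 1)
    m <- matrix(stats::rnorm(12 * k), 12, k)
    e <- gg_epsilon(m)
    expect_equal(e, gg_oracle(m), tolerance = 1e-10)
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
  }

  # compound symmetry -> sphericity -> epsilon near 1
  set.seed(22)
  Ycs <- matrix(stats::rnorm(500 * 3), 500, 3) + stats::rnorm(500)
  expect_equal(gg_epsilon(Ycs), 1, tolerance = 0.02)

  # a single dominant contrast drives epsilon to the 1/(k-1) floor
  set.seed(23)
  b <- stats::rnorm(500)
  Ymin <- cbind(b, -b, stats::rnorm(500, 0, 1e-5))
  expect_equal(gg_epsilon(Ymin), 0.5, tolerance = 0.01)

  expect_error(gg_epsilon(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "incomplete")
})

test_that("the repeated-measures ANOVA agrees with car::Anova with and without covariates", {
  set.seed(42)
  n <- 42; k <- 3
  subj <- stats::rnorm(n, 0, 2)
  Y <- matrix(stats::rnorm(n * k), n, k) + subj +
    matrix(c(0, 0.5, 1), n, k, byrow = TRUE)
  colnames(Y) <- paste0("soa", c(30, 60, 120))
  cv <- data.frame(age = stats::rnorm(n, 24, 4),
                   sex = factor(sample(c("F", "M"), n, TRUE)),
                   phase = factor(sample(c("foll", "lut", "none"), n, TRUE)),
                   hab = stats::rnorm(n))
  r <- rm_anova_covariates(Y, cv)

  cvc <- transform(cv, age = age - mean(age), hab = hab - mean(hab))
  mlm <- stats::lm(Y ~ age + sex + phase + hab, data = cvc)
  A <- summary(car::Anova(mlm, idata = data.frame(soa = factor(c(30, 60, 120))),
                          idesign = ~soa, type = 3), multivariate = FALSE)
  ut <- A$univariate.tests
  expect_equal(r$within$F,
               unname(ut[c("soa", "age:soa", "sex:soa", "phase:soa", "hab:soa"),
                         "F value"]),
               tolerance = 1e-8)
  expect_equal(r$between$F,
               unname(ut[c("age", "sex", "phase", "hab"), "F value"]),
               tolerance = 1e-8)
  expect_equal(r$epsilon, unname(A$pval.adjustments["soa", "GG eps"]),
               tolerance = 1e-8)
  # every within-subject term shares the epsilon-adjusted error df
  expect_true(all(r$within$df2 == r$within$df2[1]))
  expect_equal(r$within$df1[1], r$epsilon * (k - 1))

  # no-covariate path against car as well
  r0 <- rm_anova_covariates(Y)
  mlm0 <- stats::lm(Y ~ 1)
  A0 <- summary(car::Anova(mlm0, idata = data.frame(soa = factor(c(30, 60, 120))),
                           idesign = ~soa, type = 3), multivariate = FALSE)
  expect_equal(r0$F, unname(A0$univariate.tests["soa", "F value"]),
               tolerance = 1e-8)
  expect_equal(r0$epsilon, unname(A0$pval.adjustments["soa", "GG eps"]),
               tolerance = 1e-8)

  # identical rows across conditions: no condition effect
  Yflat <- matrix(stats::rnorm(n), n, k)
  expect_lt(rm_anova_covariates(Yflat)$F, 1e-20)

  # singular designs are named
  cv_bad <- data.frame(x1 = 1:n, x2 = 2 * (1:n))
  expect_error(rm_anova_covariates(Y, cv_bad), "collinear")
})

test_that("Bonferroni pairwise comparisons match paired t tests", {
  set.seed(9)
  Y <- matrix(stats::rnorm(60), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  r <- rm_anova_covariates(Y)
  tt <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(r$pairwise$t[1], unname(tt$statistic))
  expect_equal(r$pairwise$p_bonferroni[1], min(1, tt$p.value * 3))
  expect_equal(nrow(r$pairwise), 3L)
})

test_that("ICC(3,1) matches the two-way ANOVA oracle and is offset-invariant", {
  m <- matrix(c(9, 2, 5, 6, 1, 3, 8, 4, 6, 7, 1, 2), 4, 3, byrow = TRUE)
  ic <- icc_consistency_single(m)
  expect_equal(ic$icc, icc_oracle(m), tolerance = 1e-12)
  expect_true(ic$ci95[1] <= ic$icc && ic$icc <= ic$ci95[2])

  # perfect consistency under additive column shifts
  x <- stats::rnorm(10)
  expect_equal(icc_consistency_single(cbind(x, x + 1, x + 2))$icc, 1)

  set.seed(14)
  for (i in 1:100) {
    mm <- matrix(stats::rnorm(18), 6, 3)
    expect_equal(icc_consistency_single(mm)$icc, icc_oracle(mm),
                 tolerance = 1e-10)
    # consistency ignores a constant added to any single column
    mm2 <- mm; mm2[, 2] <- mm2[, 2] + 5
    expect_equal(icc_consistency_single(mm2)$icc,
                 icc_consistency_single(mm)$icc, tolerance = 1e-10)
  }

  # independent columns: ICC near zero
  set.seed(15)
  big <- matrix(stats::rnorm(3000), 1000, 3)
  expect_lt(abs(icc_consistency_single(big)$icc), 0.06)

  expect_error(icc_consistency_single(matrix(1:4, 2, 2)), "n >= 3")
})

test_that("per-SOA one-sample tests and the normality gate behave as specified", {
  session <- build_session(seed = 5)
  profs <- sample_profiles(12, seed = 40, beta_range = c(0, 0), ppi_sd = 0)
  sc <- do.call(rbind, lapply(seq_along(profs), function(s) {
    d <- simulate_trial_amplitudes(profs[[s]], session, seed = 400 + s)
    d$subject <- s; d
  }))
  tests <- soa_nonzero_tests(ppi_table(sc))
  expect_equal(tests$soa_ms, c(30, 60, 120))
  expect_equal(tests$n, rep(12L, 3))
  expect_gt(tests$p[tests$soa_ms == 30], 0.05)   # no true inhibition at 30 ms
  expect_lt(tests$p[tests$soa_ms == 60], 0.05)   # strong inhibition at 60 ms

  # all PPI identically zero: zero-variance error path
  d0 <- simulate_trial_amplitudes(
    subject_profile(A0 = 4, beta_true = 0,
                    ppi_true = c(`30` = 0, `60` = 0, `120` = 0)),
    session, seed = 2, trial_noise_sd = 0)
  sc0 <- do.call(rbind, lapply(1:3, function(s) { d <- d0; d$subject <- s; d }))
  expect_error(soa_nonzero_tests(ppi_table(sc0)), "variance")

  set.seed(16)
  expect_false(shapiro_gate(stats::rlnorm(42, 0, 1))$parametric)
  expect_true(shapiro_gate(stats::qnorm(seq(0.01, 0.99, length.out = 42)))$parametric)
  expect_error(shapiro_gate(c(1, 2)), "3 <= n")
  expect_error(shapiro_gate(rep(1, 10)), "constant")
})
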