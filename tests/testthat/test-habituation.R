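test_that("the habituation slope fit is exact on noiseless data", {
  i <- 1:28
  f <- fit_habituation(5 - 2 * log10(i))
  expect_equal(f$a, 5)
  expect_equal(f$b, -2, tolerance = 1e-12)
  expect_equal(f$a_bar, mean((5 - 2 * log10(i))[-1]))
  expect_equal(f$n_trials_used, 28L)

  fc <- fit_habituation(rep(3, 10))
  expect_equal(fc$a, 3)
  expect_equal(fc$b, 0)

  # natural-log option rescales the slope by log(10)
  fe <- fit_habituation(5 - 2 * log10(i), log_base = exp(1))
  expect_equal(fe$b, -2 * log(10, base = exp(1))^-1 * 1, tolerance = 1e-12)
  expect_equal(fe$b * log(10), -2, tolerance = 1e-12)
})

test_that("the 3-trial slope matches the fixed-intercept least-squares oracle", {
  # brute-force oracle: minimise over a slope grid, then refine analytically
  y <- c(4, 3, 2)
  x <- log10(1:3)
  sse <- function(b) sum((y - 4 - b * x)^2)
  grid <- seq(-6, 0, by = 1e-5)
  b_grid <- grid[which.min(vapply(grid, sse, 0))]
  b_formula <- (log10(2) * (3 - 4) + log10(3) * (2 - 4)) /
    (log10(2)^2 + log10(3)^2)
  f <- fit_habituation(y)
  expect_equal(f$b, b_formula, tolerance = 1e-12)
  expect_equal(f$b, b_grid, tolerance = 1e-4)
  # trial 1 has X = 0 and cannot influence the slope
  y2 <- y; y2[1] <- 4 + 1e6
  expect_equal(fit_habituation(c(4, 3, 2), ordinals = c(1, 2, 3))$b,
               fit_habituation(y)$b)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_habituation(c(1, 2)), "at least 3")
  expect_error(fit_habituation(c(1, 2, 3), ordinals = c(2, 3, 4)), "ordinal 1")
  expect_error(fit_habituation(c(1, 2, 3), ordinals = c(1, 1, 1)), "zero")
})

test_that("intercept correction renders b' independent of a under group centering", {
  set.seed(31)
  fits <- lapply(1:40, function(i) {
    a <- stats::runif(1, 2, 8)
    structure(list(subject = i, a = a, b = -0.4 * a + stats::rnorm(1, 0, 0.3),
                   a_bar = a * 0.8), class = "habituation_fit")
  })
  ch <- correct_slopes(fits, mode = "unstandardised", center = "group")
  expect_lt(abs(stats::cov(ch$b_prime, ch$a) / stats::var(ch$a)), 1e-10)

  # c = 0 cohort: correction leaves b untouched
  set.seed(32)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  b <- b - stats::cov(b, a) / stats::var(a) * a        # force cov(b, a) = 0
  fits0 <- lapply(1:20, function(i)
    structure(list(subject = i, a = a[i], b = b[i], a_bar = a[i]),
              class = "habituation_fit"))
  ch0 <- correct_slopes(fits0)
  expect_equal(ch0$b_prime, ch0$b, tolerance = 1e-10)
  expect_equal(attr(ch0, "c"), 0, tolerance = 1e-12)

  # exchangeability: identical subjects get identical b'
  fits3 <- fits[1:3]
  dup <- correct_slopes(c(fits3, fits3[2]))
  expect_equal(dup$b_prime[2], dup$b_prime[4])

  # standardised mode rescales c by sd(a)/sd(b)
  chs <- correct_slopes(fits, mode = "standardised", center = "group")
  a_all <- vapply(fits, `[[`, 0, "a"); b_all <- vapply(fits, `[[`, 0, "b")
  c_std <- stats::cov(b_all, a_all) / stats::var(a_all) *
    stats::sd(a_all) / stats::sd(b_all)
  expect_equal(attr(chs, "c"), c_std, tolerance = 1e-12)

  flat <- lapply(1:5, function(i)
    structure(list(subject = i, a = 2, b = i, a_bar = 2),
              class = "habituation_fit"))
  expect_error(correct_slopes(flat), "variance")
})

test_that("fitted slopes recover the generative slopes across a cohort", {
  profs <- sample_profiles(60, seed = 11)
  session <- build_session(seed = 5)
  res <- t(vapply(seq_along(profs), function(s) {
    d <- simulate_trial_amplitudes(profs[[s]], session, seed = 100 + s)
    p <- d[d$trial_type == "pulse" & d$responded, ]
    f <- fit_habituation(p$peak_amp, ordinals = p$ordinal)
    c(b = f$b, bt = profs[[s]]$beta_true)
  }, numeric(2)))
  expect_lt(abs(mean(res[, "b"] - res[, "bt"])), 0.1)
  expect_gt(stats::cor(res[, "b"], res[, "bt"]), 0.9)
})

test_that("one-sample t statistic, df, p and Cohen's d are correct", {
  t1 <- one_sample_t(c(2, 4))
  expect_equal(t1$t, 3)          # mean 3, sd sqrt(2), sem 1
  expect_equal(t1$df, 1)
  expect_equal(t1$d, 3 / stats::sd(c(2, 4)))

  t2 <- one_sample_t(c(-1, 1))
  expect_equal(t2$t, 0)
  expect_equal(t2$p, 1)

  expect_error(one_sample_t(c(1, 1, 1)), "variance")
  expect_error(one_sample_t(2), "at least 2")

  t3 <- one_sample_t(c(2, 4, 9), mu = 5)
  expect_equal(t3$t, unname(stats::t.test(c(2, 4, 9), mu = 5)$statistic))
  expect_equal(t3$d, abs(mean(c(2, 4, 9)) - 5) / stats::sd(c(2, 4, 9)))
})

test_that("Friedman test matches the rank-formula oracle and base R", {
  expect_equal(friedman_test(matrix(5, 4, 3))$chi2, 0)
  expect_equal(friedman_test(matrix(5, 4, 3))$p, 1)
  expect_equal(friedman_test(rbind(c(1, 2, 3), c(3, 2, 1)))$chi2, 0)

  # identical orderings give the maximal statistic n*(k-1) for k = 3
  m_max <- rbind(c(3, 2, 1), c(30, 20, 10), c(0.3, 0.2, 0.1))
  fr <- friedman_test(m_max)
  expect_equal(fr$chi2, 2 * 3)   # 12n/(k(k+1)) * sum((Rbar-2)^2) = n(k-1)
  expect_equal(fr$df, 2L)

  set.seed(77)
  for (i in 1:200) {
    m <- matrix(stats::rnorm(15), 5, 3)
    expect_equal(friedman_test(m)$chi2, friedman_oracle(m), tolerance = 1e-12)
    expect_equal(friedman_test(m)$chi2,
                 unname(stats::friedman.test(m)$statistic), tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
})

test_that("Spearman rho and its Fisher-z interval behave correctly", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearman_ci(x, x)$rho, 1)
  expect_equal(spearman_ci(x, -x)$rho, -1)
  expect_equal(spearman_ci(x, c(1, 3, 2, 4))$rho, 0.8)
  expect_equal(spearman_ci(x, c(1, 3, 2, 4))$rho,
               spearman_oracle(x, c(1, 3, 2, 4)))
  expect_error(spearman_ci(c(1, 1, 1, 1), x), "constant")
  expect_error(spearman_ci(1:3, 3:1), "at least 4")

  set.seed(12)
  xx <- stats::runif(30); yy <- xx + stats::rnorm(30, 0, 0.3)
  s <- spearman_ci(xx, yy)
  expect_equal(s$rho, spearman_oracle(xx, yy), tolerance = 1e-12)
  expect_true(s$ci95[1] < s$rho && s$rho < s$ci95[2])
  expect_equal(tanh(atanh(s$rho) + stats::qnorm(0.975) / sqrt(30 - 3)),
               s$ci95[2], tolerance = 1e-12)
})

test_that("group pulse-run means and SEM are computed per run", {
  m <- rbind(c(2, 2, 2), c(4, 4, 4))
  pr <- pulse_run_means(m)
  expect_equal(pr$mean, c(3, 3, 3))
  expect_equal(pr$sem, c(1, 1, 1))
  one <- pulse_run_means(matrix(1:3, 1))
  expect_true(all(is.na(one$sem)))
})
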