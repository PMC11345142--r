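#' Fit the per-subject startle habituation slope
#'
#' Fits `Y = b*X + a` to the pulse-trial amplitudes, with the intercept `a`
#' fixed at the trial-1 (first-ordinal) amplitude and `X = log(ordinal)`.
#' Given the fixed intercept, the least-squares slope is
#' `b = sum(X*(Y-a)) / sum(X^2)`; the trial-1 point (X = 0) contributes
#' nothing to it. Ordinals default to the position in the amplitude vector;
#' the pipeline passes session-wide startle-eliciting ordinals so the fitted
#' trend matches the generative habituation process (pulse-rank or absolute
#' trial numbering can be supplied instead).
#'
#' @param pulse_amps pulse-trial amplitudes in presentation order, mV.
#' @param ordinals trial ordinals for X; the first must be 1 (the intercept
#'   trial).
#' @param log_base 10 (default) or exp(1).
#' @param subject subject identifier carried into the result.
#' @return an object of class `habituation_fit`: list with `a` (intercept,
#'   mV), `b` (slope, mV/log(trial)), `a_bar` (mean amplitude excluding trial
#'   1), `n_trials_used`, `log_base`, `subject`. `b_prime` is NA until
#'   [correct_slopes()] is applied across a cohort.
#' @export
fit_habituation <- function(pulse_amps, ordinals = seq_along(pulse_amps),
                            log_base = 10, subject = NA) {
  ok <- is.finite(pulse_amps) & is.finite(ordinals)
  y <- pulse_amps[ok]; o <- ordinals[ok]
  if (length(y) < 3) stop("need at least 3 usable pulse trials")
  if (o[1] != 1) stop("trial-1 (ordinal 1) amplitude required as intercept")
  x <- log(o, base = log_base)
  if (all(x == 0)) stop("all log-trial predictors are zero")
  a <- y[1]
  b <- sum(x * (y - a)) / sum(x^2)
  structure(list(subject = subject, a = a, b = b, b_prime = NA_real_,
                 a_bar = mean(y[-1]), n_trials_used = length(y),
                 log_base = log_base),
            class = "habituation_fit")
}

#' @export
print.habituation_fit <- function(x, ...) {
  cat(sprintf(
    "Habituation fit%s: a = %.4g mV, b = %.4g mV/log%s(trial) (%d trials)%s\n",
    if (is.na(x$subject)) "" else paste0(" [", x$subject, "]"),
    x$a, x$b, if (x$log_base == 10) "10" else "e", x$n_trials_used,
    if (is.na(x$b_prime)) "" else sprintf(", b' = %.4g", x$b_prime)))
  invisible(x)
}

#' @export
coef.habituation_fit <- function(object, ...) {
  c(a = object$a, b = object$b, b_prime = object$b_prime)
}

#' Intercept-correct habituation slopes across a cohort
#'
#' Computes `b'_s = b_s - c * (a_s - abar_s)` for every subject. The
#' correction coefficient `c` is, by default, the unstandardised OLS
#' coefficient of `b` on `a` across subjects (`cov(b,a)/var(a)`), which is the
#' choice that renders `b'` independent of the initial amplitude;
#' `mode = "standardised"` uses the standardised beta of that regression
#' instead. `center = "subject"` (default) takes `abar_s` as each subject's
#' own mean pulse amplitude excluding trial 1; `center = "group"` uses the
#' group mean of `a`, the variant under which the cohort-level regression of
#' `b'` on `a` is exactly zero.
#'
#' @param fits list of [fit_habituation()] objects (needs >= 3 subjects and
#'   non-zero variance in `a`).
#' @param mode "unstandardised" (default) or "standardised".
#' @param center "subject" (default) or "group".
#' @return an object of class `habituation_cohort`: data.frame with columns
#'   subject, a, b, a_bar, b_prime; attributes `c` (coefficient used), `mode`,
#'   `center`.
#' @export
correct_slopes <- function(fits, mode = c("unstandardised", "standardised"),
                           center = c("subject", "group")) {
  mode <- match.arg(mode); center <- match.arg(center)
  stopifnot(length(fits) >= 3)
  a <- vapply(fits, `[[`, 0, "a")
  b <- vapply(fits, `[[`, 0, "b")
  a_bar <- vapply(fits, `[[`, 0, "a_bar")
  if (stats::var(a) == 0)
    stop("no variance in intercepts a across subjects; correction undefined")
  c_unstd <- stats::cov(b, a) / stats::var(a)
  cc <- if (mode == "unstandardised") c_unstd
        else c_unstd * stats::sd(a) / stats::sd(b)
  ctr <- if (center == "subject") a_bar else rep(mean(a), length(a))
  out <- data.frame(subject = vapply(fits, function(f) as.character(f$subject), ""),
                    a = a, b = b, a_bar = a_bar,
                    b_prime = b - cc * (a - ctr))
  structure(out, c = cc, mode = mode, center = center,
            class = c("habituation_cohort", "data.frame"))
}

#' @export
summary.habituation_cohort <- function(object, ...) {
  cat(sprintf("Habituation cohort: n = %d, c = %.4g (%s, %s centering)\n",
              nrow(object), attr(object, "c"), attr(object, "mode"),
              attr(object, "center")))
  cat(sprintf("mean b = %.4g, mean b' = %.4g\n",
              mean(object$b), mean(object$b_prime)))
  invisible(object)
}

#' Group mean and SEM of pulse amplitude per run
#'
#' @param run_means matrix or data.frame, subjects x runs, of per-subject
#'   per-run mean pulse amplitudes (mV).
#' @return data.frame with run, mean (mV), sem (mV; NA with a single subject).
#' @export
pulse_run_means <- function(run_means) {
  m <- as.matrix(run_means)
  stopifnot(nrow(m) >= 1)
  sem <- if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m))
         else rep(NA_real_, ncol(m))
  data.frame(run = seq_len(ncol(m)), mean = colMeans(m), sem = sem)
}

#' One-sample t test with Cohen's d
#'
#' Two-sided test of `mean(values) == mu`, reporting Cohen's
#' `d = |mean - mu| / SD`.
#'
#' @param values numeric vector, n >= 2, non-zero variance.
#' @param mu null value.
#' @return an object of class `t_test_result`: list with t, df, p, d, mean,
#'   sem.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance: t statistic undefined")
  tt <- stats::t.test(values, mu = mu)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = abs(mean(values) - mu) / stats::sd(values),
                 mean = mean(values),
                 sem = stats::sd(values) / sqrt(length(values))),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("one-sample t: t(%g) = %.3f, p = %.4g, d = %.2f (mean %.4g, SEM %.4g)\n",
              x$df, x$t, x$p, x$d, x$mean, x$sem))
  invisible(x)
}

#' Friedman rank test for repeated measures
#'
#' Ranks within each subject (mid-ranks for ties) and computes
#' `chi2 = 12*n/(k*(k+1)) * sum((Rbar_j - (k+1)/2)^2)` with `df = k - 1`.
#'
#' @param mat numeric matrix, subjects x conditions; no missing cells.
#' @return an object of class `friedman_result`: list with chi2, df, p.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2 || n < 2) stop("need >= 2 conditions and >= 2 subjects")
  if (anyNA(mat)) stop("missing cells are not supported (no imputation)")
  r <- t(apply(mat, 1, rank))
  rbar <- colMeans(r)
  chi2 <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  structure(list(chi2 = chi2, df = k - 1L,
                 p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE)),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman: chi2 = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Spearman's rho on mid-ranks with a 95% CI from the Fisher z transform
#' (`SE = 1/sqrt(n - 3)`).
#'
#' @param x,y numeric vectors, n >= 4, non-constant.
#' @return list with rho, ci95 (length-2), n.
#' @export
spearman_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rho <- stats::cor(x, y, method = "spearman")
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, rho)))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(rho = rho, ci95 = ci, n = n)
}
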