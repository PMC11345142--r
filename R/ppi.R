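#' Prepulse inhibition percentage
#'
#' `(pulse_mean - ppi_mean) / pulse_mean * 100`: positive values mean the
#' prepulse reduced startle amplitude; negative values indicate facilitation.
#' Scale-invariant: multiplying both means by the same positive factor leaves
#' the percentage unchanged.
#'
#' @param pulse_mean mean pulse-alone amplitude, mV; must be > 0.
#' @param ppi_mean mean amplitude on the PPI condition, mV.
#' @return percentage inhibition. Vectorised.
#' @export
ppi_percent <- function(pulse_mean, ppi_mean) {
  if (any(pulse_mean <= 0, na.rm = TRUE))
    stop("pulse_mean must be positive")
  (pulse_mean - ppi_mean) / pulse_mean * 100
}

#' Per-subject PPI table
#'
#' Computes, for every subject and SOA, the per-run PPI percentage (that run's
#' pulse mean as denominator) and the overall PPI across runs (means of the
#' per-run cell means). Missing cells propagate: a run without a usable pulse
#' or PPI cell yields NA for that run, and the overall value averages the
#' available runs with a warning.
#'
#' @param scores data.frame of trial scores across subjects: columns
#'   `subject`, `run`, `trial_type`, `soa_ms`, `peak_amp`, `responded`,
#'   `rejected`.
#' @param mode averaging mode passed to [condition_means()].
#' @return data.frame of class `ppi_table`: subject, soa_ms, run ("1","2","3",
#'   "overall"), pulse_mean, ppi_mean, ppi_percent.
#' @export
ppi_table <- function(scores, mode = c("amplitude", "magnitude")) {
  mode <- match.arg(mode)
  stopifnot(all(c("subject", "run", "trial_type", "peak_amp",
                  "responded", "rejected") %in% names(scores)))
  soas <- c(30, 60, 120)
  out <- list()
  for (sid in unique(scores$subject)) {
    cm <- condition_means(scores[scores$subject == sid, ], mode = mode)
    pulse <- cm$mean_amp[cm$trial_type == "pulse"][match(1:3, cm$run[cm$trial_type == "pulse"])]
    for (soa in soas) {
      ty <- paste0("ppi_", soa)
      rows <- cm[cm$trial_type == ty, ]
      ppi_m <- rows$mean_amp[match(1:3, rows$run)]
      per_run <- ifelse(!is.na(pulse) & pulse > 0 & !is.na(ppi_m),
                        (pulse - ppi_m) / pulse * 100, NA_real_)
      have <- !is.na(pulse) & !is.na(ppi_m)
      if (!all(have))
        warning("subject ", sid, ", SOA ", soa,
                " ms: overall PPI computed from runs ",
                paste(which(have), collapse = ","))
      p_all <- mean(pulse[have]); b_all <- mean(ppi_m[have])
      overall <- if (any(have) && p_all > 0) (p_all - b_all) / p_all * 100
                 else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        subject = sid, soa_ms = soa, run = c("1", "2", "3", "overall"),
        pulse_mean = c(pulse, p_all), ppi_mean = c(ppi_m, b_all),
        ppi_percent = c(per_run, overall))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ppi_table", "data.frame")
  res
}

# subjects x k matrix of overall PPI% per SOA (columns 30/60/120)
ppi_overall_matrix <- function(ppi_tab) {
  ov <- ppi_tab[ppi_tab$run == "overall", ]
  subj <- unique(ov$subject)
  soas <- sort(unique(ov$soa_ms))
  m <- matrix(NA_real_, length(subj), length(soas),
              dimnames = list(as.character(subj), paste0("soa_", soas)))
  for (i in seq_along(subj))
    for (j in seq_along(soas))
      m[i, j] <- ov$ppi_percent[ov$subject == subj[i] & ov$soa_ms == soas[j]]
  m
}

# orthonormal within-subject contrast matrix, k x (k-1)
ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Greenhouse--Geisser epsilon
#'
#' Sphericity-correction factor estimated from the sample covariance of the
#' condition columns: with orthonormal contrasts C and S the k x k sample
#' covariance, `eps = tr(C'SC)^2 / ((k-1) * tr((C'SC)^2))`, clamped to
#' `[1/(k-1), 1]`.
#'
#' @param mat numeric matrix, subjects x k conditions, complete.
#' @return epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (anyNA(mat)) stop("incomplete matrix")
  if (k < 2 || n <= k) stop("need n > k >= 2")
  if (k == 2) return(1)
  S <- stats::cov(mat)
  eps_from_cov(S, k)
}

eps_from_cov <- function(S, k) {
  if (k == 2) return(1)
  C <- ortho_contrasts(k)
  eps_from_contrast_cov(t(C) %*% S %*% C, k)
}

# epsilon from a covariance already in orthonormal-contrast space
eps_from_contrast_cov <- function(M, k) {
  if (k == 2) return(1)
  if (sum(M * M) == 0) return(1)   # no within-subject variance: trivially spherical
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
  min(1, max(1 / (k - 1), eps))
}

#' Repeated-measures one-way ANOVA with subject-level covariates
#'
#' Multivariate-contrast formulation of the within-subject one-way ANOVA:
#' the subjects x k matrix is projected onto orthonormal condition contrasts
#' and regressed on the (grand-mean-centered) covariate design. The condition
#' main effect and every covariate-by-condition interaction are tested against
#' the pooled within-subject residual, so they share the error degrees of
#' freedom; Greenhouse--Geisser epsilon (estimated from the residual
#' covariance) multiplies both df. Covariate between-subject main effects are
#' tested on the subject means. Bonferroni pairwise paired t tests compare the
#' condition means.
#'
#' @param mat numeric matrix, subjects x k conditions, complete.
#' @param covariates NULL or a data.frame of subject-level covariates (numeric
#'   or factor), one row per subject.
#' @return an object of class `rm_anova_result`: list with `F`, `df1`, `df2`
#'   (epsilon-adjusted), `p`, `epsilon`, `within` (data.frame of the condition
#'   effect and condition x covariate interactions), `between` (covariate main
#'   effects), `pairwise` (Bonferroni-adjusted paired comparisons).
#' @export
rm_anova_covariates <- function(mat, covariates = NULL) {
  Y <- as.matrix(mat)
  n <- nrow(Y); k <- ncol(Y)
  if (anyNA(Y)) stop("incomplete within-subject matrix")
  if (k < 2) stop("need k >= 2 conditions")
  Cc <- ortho_contrasts(k)
  U <- Y %*% Cc                                   # n x (k-1)
  # numerically-zero within-subject variation (identical columns): every
  # within-subject effect is exactly null
  if (sum(U * U) <= 1e-24 * max(1, sum(Y * Y))) U[] <- 0

  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    term_of <- c("(Intercept)")
    terms_lab <- character(0)
  } else {
    cv <- as.data.frame(covariates)
    stopifnot(nrow(cv) == n)
    num <- vapply(cv, is.numeric, TRUE)
    cv[num] <- lapply(cv[num], function(z) z - mean(z))   # grand-mean center
    mf <- stats::model.frame(~ ., data = cv)
    X <- stats::model.matrix(~ ., data = mf)
    asg <- attr(X, "assign")
    terms_lab <- attr(stats::terms(mf), "term.labels")
    term_of <- c("(Intercept)", terms_lab)[asg + 1L]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular covariate design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  p <- ncol(X)
  if (n - p < 1) stop("not enough subjects for the covariate design")
  B <- qr.coef(qrX, U)                            # p x (k-1)
  R <- U - X %*% B
  E <- crossprod(R)                               # residual SSCP
  df_res <- n - p
  eps <- eps_from_contrast_cov(E / df_res, k)

  XtXi <- chol2inv(qr.R(qrX)[seq_len(p), seq_len(p), drop = FALSE])
  ss_term <- function(cols) {                     # trace of hypothesis SSCP
    L <- diag(p)[cols, , drop = FALSE]
    LB <- L %*% B
    Mi <- solve(L %*% XtXi %*% t(L))
    sum(diag(t(LB) %*% Mi %*% LB))
  }
  labs <- c("condition",
            if (length(term_of) > 1) paste0("condition:", unique(term_of[-1])))
  mse_w <- sum(diag(E)) / (df_res * (k - 1))
  within <- do.call(rbind, lapply(seq_along(labs), function(i) {
    term <- if (i == 1) "(Intercept)" else sub("^condition:", "", labs[i])
    cols <- which(term_of == term)
    q <- length(cols)
    ssh <- ss_term(cols)
    msh <- ssh / (q * (k - 1))
    Fv <- if (mse_w > 0) msh / mse_w else if (msh <= 1e-12) 0 else Inf
    df1 <- eps * q * (k - 1); df2 <- eps * df_res * (k - 1)
    data.frame(effect = labs[i], F = Fv, df1 = df1, df2 = df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }))

  between <- NULL
  if (length(term_of) > 1) {
    ybar <- rowMeans(Y)
    Bb <- qr.coef(qrX, ybar)
    rb <- ybar - as.numeric(X %*% Bb)
    mse_b <- sum(rb^2) / df_res
    between <- do.call(rbind, lapply(unique(term_of[-1]), function(term) {
      cols <- which(term_of == term)
      L <- diag(p)[cols, , drop = FALSE]
      Lb <- L %*% Bb
      ssh <- as.numeric(t(Lb) %*% solve(L %*% XtXi %*% t(L)) %*% Lb)
      q <- length(cols)
      Fv <- (ssh / q) / mse_b
      data.frame(effect = term, F = Fv, df1 = q, df2 = df_res,
                 p = stats::pf(Fv, q, df_res, lower.tail = FALSE))
    }))
  }

  pairs <- utils::combn(k, 2)
  n_cmp <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(n_cmp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- stats::t.test(Y[, i1], Y[, i2], paired = TRUE)
    data.frame(comparison = paste(colnames(Y)[i1] %||% i1,
                                  colnames(Y)[i2] %||% i2, sep = " vs "),
               mean_diff = mean(Y[, i1] - Y[, i2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_bonferroni = min(1, tt$p.value * n_cmp))
  }))

  structure(list(F = within$F[1], df1 = within$df1[1], df2 = within$df2[1],
                 p = within$p[1], epsilon = eps, within = within,
                 between = between, pairwise = pairwise,
                 n = n, k = k, df_error_unadj = df_res * (k - 1)),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA (n = %d, k = %d): GG epsilon = %.3f\n", x$n, x$k,
              x$epsilon))
  w <- x$within
  for (i in seq_len(nrow(w)))
    cat(sprintf("  %-28s F = %.3f, df = %.3f, %.3f, p = %.4g\n",
                w$effect[i], w$F[i], w$df1[i], w$df2[i], w$p[i]))
  if (!is.null(x$between)) {
    cat("between-subject covariates:\n")
    b <- x$between
    for (i in seq_len(nrow(b)))
      cat(sprintf("  %-28s F = %.3f, df = %d, %d, p = %.4g\n",
                  b$effect[i], b$F[i], b$df1[i], b$df2[i], b$p[i]))
  }
  invisible(x)
}

#' Intraclass correlation ICC(3,1): two-way mixed, single rater, consistency
#'
#' From the two-way ANOVA decomposition (subjects x raters/runs):
#' `ICC = (BMS - EMS) / (BMS + (k-1)*EMS)` with the standard F-based 95%
#' confidence interval. The consistency definition ignores systematic column
#' offsets.
#'
#' @param mat numeric matrix, subjects x k raters/runs; complete, n >= 3,
#'   k >= 2.
#' @return an object of class `icc_result`: list with icc, ci95, bms, ems, n,
#'   k.
#' @export
icc_consistency_single <- function(mat) {
  m <- as.matrix(mat)
  n <- nrow(m); k <- ncol(m)
  if (anyNA(m)) stop("incomplete matrix")
  if (n < 3 || k < 2) stop("need n >= 3 subjects and k >= 2 columns")
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (bms <= 0 && ems <= 0) stop("degenerate variance: ICC undefined")
  icc <- (bms - ems) / (bms + (k - 1) * ems)
  F0 <- bms / ems
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  FL <- F0 / stats::qf(0.975, df1, df2)
  FU <- F0 * stats::qf(0.975, df2, df1)
  ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  structure(list(icc = icc, ci95 = ci, bms = bms, ems = ems, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) consistency = %.3f, 95%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$icc, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}

#' One-sample t of overall PPI against zero, per SOA
#'
#' @param ppi_tab a [ppi_table()] result.
#' @param mu null value (0 = no inhibition).
#' @return data.frame: soa_ms, n, mean, sem, t, df, p, d.
#' @export
soa_nonzero_tests <- function(ppi_tab, mu = 0) {
  ov <- ppi_tab[ppi_tab$run == "overall", ]
  do.call(rbind, lapply(sort(unique(ov$soa_ms)), function(soa) {
    v <- ov$ppi_percent[ov$soa_ms == soa]
    v <- v[is.finite(v)]
    tt <- one_sample_t(v, mu = mu)
    data.frame(soa_ms = soa, n = length(v), mean = tt$mean, sem = tt$sem,
               t = tt$t, df = tt$df, p = tt$p, d = tt$d)
  }))
}

#' Shapiro--Wilk normality gate
#'
#' Tests normality and returns the flag used to choose between parametric
#' (RM-ANOVA / t) and rank-based (Friedman) paths.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with W, p, parametric (TRUE iff p >= 0.05).
#' @export
shapiro_gate <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant input")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, parametric = sw$p.value >= 0.05)
}
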