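#' Two-sample and paired t tests with effect size
#'
#' `two_sample_ttest` is the pooled-variance Student t test (df = n1+n2-2),
#' matching the degrees of freedom conventionally reported for matched-group
#' designs; Cohen's d is the mean difference over the pooled SD.
#' `paired_ttest` is the one-sample t on the pairwise differences
#' (df = n-1).
#'
#' @param x,y Numeric vectors (equal length for the paired test).
#' @return An object of class `ttest_result`: `t`, `df`, `p` (two-tailed),
#'   `mean_diff`, `cohen_d`.
#' @export
two_sample_ttest <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean(x) - mean(y),
                 cohen_d = (mean(x) - mean(y)) / sqrt(sp2)),
            class = "ttest_result")
}

#' @rdname two_sample_ttest
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::var(d) == 0) stop("zero variance of paired differences")
  ht <- stats::t.test(d)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean(d),
                 cohen_d = mean(d) / stats::sd(d)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.2f, p = %.3f (mean diff %.3f, d = %.2f)\n",
              x$df, x$t, x$p, x$mean_diff, x$cohen_d))
  invisible(x)
}

#' Pearson chi-square on a 2x2 table, without continuity correction
#'
#' The uncorrected Pearson statistic is used (retention tables in this
#' design are reported without Yates' correction).
#'
#' @param table 2x2 matrix of counts.
#' @return An object of class `chisq_result`: `chi2`, `df` (= 1), `p`,
#'   `observed`, `expected`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table")
  # the small-expected-count approximation note is irrelevant here: the
  # statistic itself is exact and callers may enumerate p separately
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic), df = 1L, p = ht$p.value,
                 observed = table, expected = ht$expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("X2(1) = %.2f, p = %.3f\n", x$chi2, x$p))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' `U` counts pairs (x_i, y_j) with x_i > y_j (ties count one half). The
#' two-tailed p value comes from exact enumeration over all assignments of
#' the pooled values to groups when the combined sample size is at most 12
#' (and therefore handles ties exactly), and from the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Numeric vectors.
#' @return An object of class `mwu_result`: `U` (for `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y)
  ustat <- function(xx, yy)
    sum(outer(xx, yy, function(a, b) (a > b) + 0.5 * (a == b)))
  U <- ustat(x, y)
  if (n1 + n2 <= 12L) {
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    us <- apply(combs, 2, function(idx) ustat(pool[idx], pool[-idx]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "tie-corrected normal approximation"
  }
  structure(list(U = U, p = min(p, 1), method = method,
                 n1 = n1, n2 = n2), class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, p = %.3f (%s)\n", x$U, x$p, x$method))
  invisible(x)
}

#' Power and sensitivity for the two-sample t test
#'
#' Power is computed from the noncentral t distribution with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom
#' against the two-tailed rejection region at level `alpha`.
#' `sensitivity_d` inverts the power function by bisection to find the
#' smallest detectable standardized difference.
#'
#' @param n1,n2 Group sizes.
#' @param d Standardized mean difference (Cohen's d).
#' @param alpha Two-tailed significance level.
#' @param power Target power for `sensitivity_d`.
#' @return An object of class `power_result` with fields `n1`, `n2`,
#'   `alpha`, `d`, `power`, `mode`.
#' @examples
#' power_two_sample_t(37, 32, d = 0.70)      # >= 0.80
#' sensitivity_d(37, 32, power = 0.80)       # <= 0.70
#' @export
power_two_sample_t <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2L, n2 >= 2L, alpha > 0, alpha < 1, d >= 0)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  pow <- stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  structure(list(n1 = n1, n2 = n2, alpha = alpha, d = d, power = pow,
                 mode = "power_at_d"), class = "power_result")
}

#' @rdname power_two_sample_t
#' @export
sensitivity_d <- function(n1, n2, alpha = 0.05, power = 0.80) {
  stopifnot(power > alpha, power < 1)
  f <- function(d) power_two_sample_t(n1, n2, d, alpha)$power - power
  hi <- 1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 100) stop("requested power unattainable at these sample sizes")
  }
  d <- stats::uniroot(f, c(0, hi), tol = 1e-6)$root
  structure(list(n1 = n1, n2 = n2, alpha = alpha, d = d, power = power,
                 mode = "sensitivity_d"), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  if (x$mode == "power_at_d")
    cat(sprintf("Power = %.3f at d = %.2f (n = %d, %d; alpha = %.2f two-tailed)\n",
                x$power, x$d, x$n1, x$n2, x$alpha))
  else
    cat(sprintf("Sensitivity d = %.3f at power %.2f (n = %d, %d; alpha = %.2f two-tailed)\n",
                x$d, x$power, x$n1, x$n2, x$alpha))
  invisible(x)
}

# build the standardized design used by the moderation regression:
# continuous predictors z-scored, two-level factors effect-coded +1/-1
.std_design <- function(data, vars) {
  out <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) != 2L)
        stop("predictor ", v, " must be continuous or two-level")
      out[[v]] <- ifelse(as.character(x) == lev[1L], 1, -1)
    } else out[[v]] <- as.numeric(scale(x))
  }
  as.data.frame(out)
}

#' Moderation (group-by-measure interaction) regression
#'
#' Ordinary least squares predicting a follow-up outcome from the
#' standardized baseline score, standardized covariates, effect-coded group
#' (first level alphabetically = +1), standardized neurocognitive
#' measure(s), and group-by-measure interaction term(s). The outcome is
#' standardized, so coefficients are standardized betas. Listwise deletion
#' is applied. Each term's part (semipartial) correlation -- the correlation
#' between the outcome and the predictor's unique component -- is reported
#' signed by its coefficient: `r_part = t * sqrt(1 - R2) / sqrt(df_res)`.
#'
#' @param data A `cohort_table` or data frame.
#' @param outcome Name of the outcome column.
#' @param baseline Name of the baseline-symptom column.
#' @param covariates Covariate column names.
#' @param group Group column name (two levels).
#' @param measures Neurocognitive measure column name(s); each gets a
#'   group-interaction term.
#' @param interactions If `FALSE`, fit without the interaction terms (and,
#'   when `group = NULL`, without group), as in within-group simple-effects
#'   models.
#' @param standardize_outcome If `FALSE`, the outcome enters in its given
#'   units and coefficients are per-SD-of-predictor effects on that scale.
#'   Standardized betas divide by the outcome SD, which under a strong
#'   moderation effect necessarily exceeds the residual-free predictor
#'   scale; generator-recovery checks therefore compare coefficients on the
#'   generative scale.
#' @return An object of class `regression_result`: per-term table (`beta`,
#'   `t`, `df`, `p`, `r_part`), `r_squared`, `F`, df pair, model `p`, `n`.
#' @export
hierarchical_regression <- function(data, outcome, baseline,
                                    covariates = c("sex", "age", "iq",
                                                   "pubertal"),
                                    group = "group", measures = "tau_true",
                                    interactions = TRUE,
                                    standardize_outcome = TRUE) {
  vars <- c(baseline, covariates, measures, if (!is.null(group)) group)
  keep <- stats::complete.cases(data[, c(outcome, vars)])
  df0 <- data[keep, , drop = FALSE]
  X <- .std_design(df0, vars)
  if (!is.null(group) && interactions)
    for (m in measures)
      X[[paste0(group, ":", m)]] <- X[[group]] * X[[m]]
  y <- if (standardize_outcome) as.numeric(scale(df0[[outcome]]))
       else as.numeric(df0[[outcome]])
  if (nrow(X) < ncol(X) + 2L)
    stop("too few complete cases (", nrow(X), ") for ", ncol(X), " terms")
  dat <- cbind(.y = y, X)
  names(dat) <- make.names(names(dat))
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  ct <- sm$coefficients[-1L, , drop = FALSE]  # drop intercept
  df_res <- fit$df.residual
  r2 <- sm$r.squared
  terms_tab <- data.frame(
    term = c(vars, if (!is.null(group) && interactions)
      paste0(group, ":", measures)),
    beta = unname(ct[, 1L]), t = unname(ct[, 3L]), df = df_res,
    p = unname(ct[, 4L]),
    r_part = unname(ct[, 3L]) * sqrt(1 - r2) / sqrt(df_res),
    stringsAsFactors = FALSE)
  structure(list(terms = terms_tab, r_squared = r2,
                 F = unname(sm$fstatistic[1L]),
                 df1 = unname(sm$fstatistic[2L]),
                 df2 = unname(sm$fstatistic[3L]),
                 model_p = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                     sm$fstatistic[3L], lower.tail = FALSE),
                 n = nrow(X), lm = fit),
            class = "regression_result")
}

#' @rdname hierarchical_regression
#' @param which_group Group level to subset for the simple-effects fit.
#' @export
simple_effects <- function(data, outcome, baseline,
                           covariates = c("sex", "age", "iq", "pubertal"),
                           group = "group", measures = "tau_true",
                           which_group, standardize_outcome = TRUE) {
  sub <- data[data[[group]] == which_group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty group: ", which_group)
  hierarchical_regression(sub, outcome, baseline, covariates, group = NULL,
                          measures = measures, interactions = FALSE,
                          standardize_outcome = standardize_outcome)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS (standardized): R2 = %.2f, F(%d, %d) = %.2f, p = %.3g, n = %d\n",
              x$r_squared, x$df1, x$df2, x$F, x$model_p, x$n))
  tab <- transform(x$terms, beta = round(beta, 3), t = round(t, 2),
                   p = signif(p, 3), r_part = round(r_part, 3))
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
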