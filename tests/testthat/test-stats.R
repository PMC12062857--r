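test_that("pooled t test matches closed-form arithmetic and handles edge cases", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  r <- two_sample_ttest(x, y)
  sp <- sqrt((2 * 1 + 2 * 1) / 4)  # both sample variances are 1
  expect_equal(r$t, (2 - 3) / (sp * sqrt(1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$cohen_d, -1)
  same <- two_sample_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "pooled variance")
  # df matches the post-exclusion group sizes convention
  expect_equal(two_sample_ttest(rnorm(24), rnorm(22))$df, 44)
})

test_that("paired t test is the one-sample t on differences", {
  x <- c(5, 6, 9, 4); y <- c(4, 7, 6, 2)
  r <- paired_ttest(x, y)
  d <- x - y
  expect_equal(r$t, mean(d) / (stats::sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(paired_ttest(rnorm(46), rnorm(46))$df, 45)
  expect_error(paired_ttest(x, x), "variance")
})

test_that("chi-square reproduces the retention statistic and the explicit formula", {
  r <- chi_square_2x2(rbind(c(27, 10), c(29, 3)))
  expect_equal(round(r$chi2, 2), 3.50)
  expect_equal(round(r$p, 3), 0.061)
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(20, 20)))$chi2, 0)
  expect_equal(chi_square_2x2(rbind(c(5, 0), c(0, 5)))$chi2, 10)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "margin")
  # fuzz: equals sum((O-E)^2/E) on random tables
  set.seed(4)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_2x2(tab)$chi2, sum((tab - e)^2 / e),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U matches enumeration exactly and wilcox.test approximately", {
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(2.0, 4.4, 6.2, 7.0)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "exact enumeration")
  # independent check: all 70 assignments of pooled ranks
  expect_equal(r$p, stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(r$U, unname(stats::wilcox.test(x, y)$statistic))
  # extreme separation and identical multisets
  expect_equal(mann_whitney_u(c(1, 2), c(5, 6, 7))$U, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  # large-sample branch against the normal-approximation reference
  set.seed(9)
  xx <- rnorm(20); yy <- rnorm(25, 0.5)
  rl <- mann_whitney_u(xx, yy)
  ref <- stats::wilcox.test(xx, yy, exact = FALSE, correct = FALSE)
  expect_equal(rl$p, ref$p.value, tolerance = 1e-10)
})

test_that("noncentral-t power matches its definition and inverts cleanly", {
  r <- power_two_sample_t(37, 32, 0.70)
  expect_gte(r$power, 0.80)
  expect_equal(power_two_sample_t(10, 12, 0)$power, 0.05, tolerance = 1e-10)
  s <- sensitivity_d(37, 32, power = 0.80)
  expect_lte(s$d, 0.70)
  # round trip power(sensitivity_d) = target
  expect_equal(power_two_sample_t(37, 32, s$d)$power, 0.80,
               tolerance = 1e-4)
  # monotone in d and in n
  ds <- seq(0.1, 1.2, by = 0.1)
  pw <- vapply(ds, function(d) power_two_sample_t(20, 25, d)$power, 0)
  expect_true(all(diff(pw) > 0))
  ns <- c(10, 20, 40, 80)
  pn <- vapply(ns, function(n) power_two_sample_t(n, n, 0.5)$power, 0)
  expect_true(all(diff(pn) > 0))
})

test_that("type-I error of the pooled t test is nominal", {
  set.seed(12)
  n <- 10000
  x <- matrix(rnorm(n * 8), n); y <- matrix(rnorm(n * 8), n)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, var); vy <- apply(y, 1, var)
  tt <- (mx - my) / sqrt((7 * vx + 7 * vy) / 14 * (2 / 8))
  rej <- mean(abs(tt) > qt(0.975, 14))
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("regression reduces to the correlation identity and saturates", {
  set.seed(3)
  d <- data.frame(y = rnorm(40), x = rnorm(40))
  r <- hierarchical_regression(d, "y", "x", covariates = character(0),
                               group = NULL, measures = character(0),
                               interactions = FALSE)
  expect_equal(r$terms$beta[1], stats::cor(d$y, d$x), tolerance = 1e-10)
  d$y2 <- d$y
  expect_equal(suppressWarnings(hierarchical_regression(d, "y", "y2",
                                       covariates = character(0),
                                       group = NULL,
                                       measures = character(0),
                                       interactions = FALSE))$r_squared, 1)
})

test_that("part correlations are bounded by zero-order correlations", {
  co <- quiet_cohort(cohort_config(seed = 10), simulate_trials = FALSE)$cohort
  r <- hierarchical_regression(co, "sdq_emotional_followup",
                               "sdq_emotional_baseline")
  cc <- co[stats::complete.cases(co$sdq_emotional_followup), ]
  r0 <- abs(stats::cor(cc$sdq_emotional_followup, cc$sdq_emotional_baseline))
  rp <- abs(r$terms$r_part[r$terms$term == "sdq_emotional_baseline"])
  expect_lte(rp, r0 + 1e-10)
})

test_that("moderation and simple effects recover the generator's structure", {
  cfg <- cohort_config(symptoms = list(residual_sd = 0.1), seed = 7)
  dat <- quiet_cohort(cfg, simulate_trials = FALSE)
  co <- dat$cohort
  co$y_gen <- (co$sdq_emotional_followup - cfg$symptoms$followup_mean) /
    cfg$symptoms$followup_sd
  reg <- hierarchical_regression(co, "y_gen", "sdq_emotional_baseline",
                                 standardize_outcome = FALSE)
  b_int <- reg$terms$beta[reg$terms$term == "group:tau_true"]
  expect_lt(abs(b_int - (-0.80)), 0.1)
  # per-group slopes have the generated signs: MT = b_tau + b_int < 0,
  # NMT = b_tau - b_int > 0
  mt <- simple_effects(co, "y_gen", "sdq_emotional_baseline",
                       which_group = "MT", standardize_outcome = FALSE)
  nmt <- simple_effects(co, "y_gen", "sdq_emotional_baseline",
                        which_group = "NMT", standardize_outcome = FALSE)
  expect_lt(mt$terms$beta[mt$terms$term == "tau_true"], 0)
  expect_gt(nmt$terms$beta[nmt$terms$term == "tau_true"], 0)
  expect_error(simple_effects(co, "y_gen", "sdq_emotional_baseline",
                              which_group = "ZZ"), "empty group")
  # zero interaction: recovered interaction within sampling error of 0
  cfg0 <- cohort_config(symptoms = list(residual_sd = 0.1, beta_int = 0),
                        seed = 8)
  co0 <- quiet_cohort(cfg0, simulate_trials = FALSE)$cohort
  co0$y_gen <- (co0$sdq_emotional_followup - 2.9) / 2.3
  reg0 <- hierarchical_regression(co0, "y_gen", "sdq_emotional_baseline",
                                  standardize_outcome = FALSE)
  expect_lt(abs(reg0$terms$beta[reg0$terms$term == "group:tau_true"]), 0.1)
})
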