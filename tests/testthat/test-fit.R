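test_that("transform maps are mutually inverse", {
  to_nat <- volbandit:::to_natural
  to_tr <- volbandit:::to_transformed
  pn <- c("b", "tau", "alpha_stable", "p_stay")
  x <- c(-2.3, 0.7, 1.1, 0)
  expect_equal(to_tr(to_nat(x, pn), pn), x, tolerance = 1e-12)
  nat <- c(0.2, 3.5, 0.9, 0.5)
  expect_equal(to_nat(to_tr(nat, pn), pn), nat, tolerance = 1e-12)
})

test_that("MAP fitting is deterministic and respects the null closed form", {
  sch <- generate_schedule(task_config(seed = 2))
  rec <- simulate_agent(list(b = .5, tau = .2, alpha_stable = .4,
                             alpha_volatile = .5), winning_spec(), sch,
                        seed = 7)
  ch <- rec[, c("chosen", "outcome")]
  f1 <- fit_participant(winning_spec(), ch, sch, seed = 5)
  f2 <- fit_participant(winning_spec(), ch, sch, seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_true(f1$converged)
  fn <- fit_participant(default_family()$M01, ch, sch)
  expect_length(fn$estimates, 0L)
  expect_equal(fn$loglik, 120 * log(0.5))
})

test_that("near-deterministic data pulls the temperature estimate below the prior median", {
  sch <- generate_schedule(task_config(seed = 3))
  rec <- simulate_agent(list(b = .5, tau = .05, alpha_stable = .4,
                             alpha_volatile = .5), winning_spec(), sch,
                        seed = 11)
  f <- fit_participant(winning_spec(), rec[, c("chosen", "outcome")], sch,
                       seed = 2)
  prior_median_tau <- exp(prior_spec()$location[["tau"]])
  expect_lt(f$estimates[["tau"]], prior_median_tau)
})

test_that("hierarchical draws are reproducible and bounded on the natural scale", {
  dat <- quiet_cohort(cohort_config(n_MT = 4, n_NMT = 4,
                                    random_responder_fraction = 0, seed = 2),
                      followup = FALSE)
  sam <- sampler_config(chains = 2, warmup = 80, iter = 60, seed = 42)
  f1 <- fit_rl(winning_spec(), dat$trials, sampler = sam)
  f2 <- fit_rl(winning_spec(), dat$trials, sampler = sam)
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$pointwise, f2$pointwise)
  th <- f1$draws$theta
  expect_true(all(th[, , , match("tau", f1$param_names)] > 0))
  for (nm in c("b", "alpha_stable", "alpha_volatile")) {
    x <- th[, , , match(nm, f1$param_names)]
    expect_true(all(x > 0 & x < 1))
  }
  expect_equal(dim(f1$pointwise), c(2L * 60L, 8L * 120L))
  est <- coef(f1)
  expect_equal(dim(est), c(8L, 4L))
})

test_that("the null-model hierarchical fit has a closed-form pointwise likelihood", {
  dat <- quiet_cohort(cohort_config(n_MT = 2, n_NMT = 2,
                                    random_responder_fraction = 1, seed = 3),
                      followup = FALSE)
  f <- fit_rl(default_family()$M01, dat$trials,
              sampler = sampler_config(chains = 2, warmup = 10, iter = 20))
  expect_true(all(f$pointwise == log(0.5)))
  expect_equal(compute_waic(f$pointwise)$elpd_waic, 480 * log(0.5))
})

test_that("hierarchical estimates shrink relative to independent MAP fits", {
  dat <- quiet_cohort(cohort_config(n_MT = 8, n_NMT = 8,
                                    random_responder_fraction = 0, seed = 9),
                      followup = FALSE)
  fit <- fit_rl(winning_spec(), dat$trials,
                sampler = sampler_config(chains = 2, warmup = 400,
                                         iter = 300, seed = 1))
  hier <- coef(fit)
  ids <- unique(dat$trials$participant_id)
  map <- t(vapply(ids, function(id) {
    tr <- dat$trials[dat$trials$participant_id == id, ]
    fit_participant(winning_spec(), tr[, c("chosen", "outcome")], tr,
                    seed = 1)$estimates
  }, c(b = 0, tau = 0, alpha_stable = 0, alpha_volatile = 0)))
  # variance across participants is smaller under partial pooling
  shrunk <- vapply(colnames(hier), function(nm)
    stats::var(hier[, nm]) < stats::var(map[, nm]), TRUE)
  expect_gte(sum(shrunk), 3L)
})

test_that("group-mean credible intervals are calibrated at reduced scale", {
  # agents drawn from the model's own hierarchy with known group means;
  # pooled per-parameter coverage of 95% intervals should be near nominal
  reps <- 8L
  cover <- matrix(NA, reps, 4)
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    mu_true <- c(stats::rnorm(1, 0, 0.5), stats::rnorm(1, -1.3, 0.3),
                 stats::rnorm(1, -0.6, 0.4), stats::rnorm(1, -0.4, 0.4))
    hc <- hierarchy_cohort(20, mu_true, c(0.5, 0.3, 0.5, 0.5),
                           seed = 100 + r)
    fit <- fit_rl(hc$spec, hc$trials,
                  sampler = sampler_config(chains = 2, warmup = 600,
                                           iter = 500, seed = 300 + r),
                  save_pointwise = FALSE)
    for (j in 1:4) {
      q <- stats::quantile(as.vector(fit$draws$mu[, , j]), c(.025, .975))
      cover[r, j] <- mu_true[j] >= q[1] && mu_true[j] <= q[2]
    }
  }
  expect_gte(mean(cover), 0.85)
})
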