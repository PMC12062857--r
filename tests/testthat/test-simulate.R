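test_that("simulated choices follow the model's analytic probabilities", {
  # 2-trial schedule; hand-computed choice probabilities for the winner
  win <- winning_spec()
  sch <- toy_schedule(c("A", "A"))
  par <- list(b = 0.7, tau = 0.5, alpha_stable = 0.5, alpha_volatile = 0.5)
  # trial 1: P(A) = 1/(1+exp(-(0.7-0.3)/0.5)) = 1/(1+exp(-0.8))
  p1 <- 1 / (1 + exp(-0.8))
  n <- 4000
  first <- vapply(seq_len(n), function(s)
    simulate_agent(par, win, sch, seed = s)$chosen[1] == "A", TRUE)
  expect_lt(abs(mean(first) - p1), 3 * sqrt(p1 * (1 - p1) / n))
  # null agents choose uniformly
  nullspec <- default_family()$M01
  ch <- simulate_agent(list(), nullspec,
                       generate_schedule(task_config(seed = 2)), seed = 9)
  expect_lt(abs(mean(ch$chosen == "A") - 0.5), 0.15)
  # near-deterministic exploitation of the biased start
  det <- simulate_agent(list(b = 0.9, tau = 1e-4, alpha_stable = 1e-4,
                             alpha_volatile = 1e-4),
                        win, toy_schedule(rep("B", 30)), seed = 1)
  expect_true(all(det$chosen == "A"))
})

test_that("outcomes and coin counts are consistent with the schedule", {
  sch <- generate_schedule(task_config(seed = 6))
  rec <- simulate_agent(list(b = .5, tau = .3, alpha_stable = .4,
                             alpha_volatile = .4), winning_spec(), sch,
                        seed = 3)
  expect_equal(rec$outcome,
               as.integer(rec$chosen == sch$rewarded_option))
  mag <- ifelse(rec$chosen == "A", sch$magnitude_A, sch$magnitude_B)
  expect_equal(rec$coins_won, as.integer(rec$outcome * mag))
  expect_identical(rec,
    simulate_agent(list(b = .5, tau = .3, alpha_stable = .4,
                        alpha_volatile = .4), winning_spec(), sch, seed = 3))
})

test_that("winning-model agents beat chance in both phases", {
  win <- winning_spec()
  acc <- matrix(NA_real_, 200, 2)
  for (s in seq_len(200)) {
    sch <- generate_schedule(task_config(seed = s))
    rec <- simulate_agent(list(b = 0.5, tau = 0.25, alpha_stable = 0.35,
                               alpha_volatile = 0.41), win, sch, seed = s)
    hit <- rec$chosen == sch$high_prob_option
    acc[s, ] <- c(mean(hit[sch$phase == "stable"]),
                  mean(hit[sch$phase == "volatile"]))
  }
  expect_gt(mean(acc[, 1]), 0.5)
  expect_gt(mean(acc[, 2]), 0.5)
})

test_that("cohort structure matches its configuration", {
  cfg <- cohort_config(n_MT = 10, n_NMT = 8, random_responder_fraction = 0.25,
                       seed = 2)
  dat <- quiet_cohort(cfg)
  co <- dat$cohort
  expect_equal(nrow(co), 18L)
  expect_equal(sum(co$group == "MT"), 10L)
  expect_equal(sum(co$responder_type == "random"), round(0.25 * 18))
  # counterbalancing alternates within group
  expect_equal(sum(co$order[co$group == "MT"] == "stable_first"), 5L)
  # trials: one record per scheduled trial per participant
  expect_equal(nrow(dat$trials), 18L * 120L)
  expect_equal(dat$trials$outcome,
               as.integer(dat$trials$chosen == dat$trials$rewarded_option))
  # zero fraction flags everyone as model
  co0 <- quiet_cohort(cohort_config(n_MT = 6, n_NMT = 6,
                                    random_responder_fraction = 0, seed = 3),
                      simulate_trials = FALSE)$cohort
  expect_true(all(co0$responder_type == "model"))
})

test_that("groups are matched on covariates in expectation", {
  diffs <- t(vapply(1:40, function(s) {
    co <- quiet_cohort(cohort_config(seed = s), followup = FALSE,
                       simulate_trials = FALSE)$cohort
    c(age = mean(co$age[co$group == "MT"]) - mean(co$age[co$group == "NMT"]),
      iq = mean(co$iq[co$group == "MT"]) - mean(co$iq[co$group == "NMT"]))
  }, c(age = 0, iq = 0)))
  expect_lt(abs(mean(diffs[, "age"])), 0.25)
  expect_lt(abs(mean(diffs[, "iq"])), 1.2)
  # but temperature is lower in the MT group by construction
  co <- quiet_cohort(cohort_config(seed = 5), followup = FALSE,
                     simulate_trials = FALSE)$cohort
  expect_lt(mean(co$tau_true[co$group == "MT"]),
            mean(co$tau_true[co$group == "NMT"]))
})

test_that("no-effect configuration yields nominal type-I error for temperature", {
  ps <- vapply(1:200, function(s) {
    co <- quiet_cohort(cohort_config(temperature_effect_d = 0, seed = s),
                       followup = FALSE, simulate_trials = FALSE)$cohort
    two_sample_ttest(co$tau_true[co$group == "NMT"],
                     co$tau_true[co$group == "MT"])$p
  }, 0)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("follow-up generation respects retention and the linear model", {
  cfg <- cohort_config(seed = 4)
  dat <- quiet_cohort(cfg, simulate_trials = FALSE)
  co <- dat$cohort
  expect_true(all(is.na(co$sdq_emotional_followup[!co$retained])))
  expect_true(all(!is.na(co$sdq_emotional_followup[co$retained])))
  # noiseless generation: refitting the same design recovers coefficients
  cfg0 <- cohort_config(symptoms = list(residual_sd = 0),
                        retention = list(p_MT = 1, p_NMT = 1), seed = 6)
  co0 <- quiet_cohort(cfg0, simulate_trials = FALSE)$cohort
  co0$y <- (co0$sdq_emotional_followup - cfg0$symptoms$followup_mean) /
    cfg0$symptoms$followup_sd
  g <- ifelse(co0$group == "MT", 1, -1)
  zb <- as.numeric(scale(co0$sdq_emotional_baseline))
  zt <- as.numeric(scale(co0$tau_true))
  f <- stats::lm(co0$y ~ zb + g + zt + I(g * zt))
  expect_equal(unname(coef(f)[-1]),
               with(cfg0$symptoms, c(beta_baseline, beta_group, beta_tau,
                                     beta_int)),
               tolerance = 1e-8)
  # retained counts close to 27/37 and 29/32 in expectation
  ret <- t(vapply(1:60, function(s) {
    co <- quiet_cohort(cohort_config(seed = s), simulate_trials = FALSE)$cohort
    c(mt = sum(co$retained[co$group == "MT"]),
      nmt = sum(co$retained[co$group == "NMT"]))
  }, c(mt = 0, nmt = 0)))
  expect_lt(abs(mean(ret[, "mt"]) - 27), 1.5)
  expect_lt(abs(mean(ret[, "nmt"]) - 29), 1.5)
})

test_that("cohort configuration reads from JSON with partial overrides", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_MT = 8, n_NMT = 6, temperature_effect_d = 0.5,
                            agent = list(tau_sd = 0.2),
                            random_responder_fraction = 0.1, seed = 3),
                       path, auto_unbox = TRUE)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_MT, 8L)
  expect_equal(cfg$agent$tau_sd, 0.2)
  expect_equal(cfg$agent$alpha_stable_mean, 0.35)  # default retained
})

test_that("cohort and trial CSVs round-trip with empty cells for missing follow-up", {
  dat <- quiet_cohort(cohort_config(n_MT = 4, n_NMT = 4, seed = 8))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(dat$cohort, cpath)
  back <- read_cohort_csv(cpath)
  expect_equal(back$participant_id, dat$cohort$participant_id)
  expect_equal(back$retained, dat$cohort$retained)
  expect_equal(back$sdq_emotional_followup, dat$cohort$sdq_emotional_followup,
               tolerance = 1e-9)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(dat$trials, tpath)
  tback <- read_trials_csv(tpath)
  expect_equal(tback$chosen, dat$trials$chosen)
  expect_equal(tback$outcome, dat$trials$outcome)
})
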