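test_that("the candidate family has the documented structure", {
  fam <- default_family()
  expect_length(fam, 12L)
  ids <- vapply(fam, `[[`, "", "model_id")
  expect_equal(anyDuplicated(ids), 0L)
  win <- winning_spec(fam)
  expect_equal(win$n_free_params, 4L)
  expect_true(win$has_bias && win$dual_learning_rate && !win$uses_magnitude)
  expect_equal(sum(vapply(fam, `[[`, FALSE, "winning")), 1L)
  expect_equal(sum(vapply(fam, `[[`, FALSE, "is_null")), 2L)
  rules <- vapply(fam, `[[`, "", "rule")
  expect_equal(sum(rules == "rescorla_wagner"), 8L)
  expect_equal(sum(rules == "win_stay_lose_shift"), 2L)
})

test_that("value initialisation and the delta rule behave as defined", {
  win <- winning_spec()
  expect_equal(initial_state(win, list(b = 0.5)), c(v_A = 0.5, v_B = 0.5))
  expect_equal(initial_state(win, list(b = 0.8)), c(v_A = 0.8, v_B = 0.2))
  nb <- default_family()$M07
  expect_equal(initial_state(nb, list(b = 0.9)), c(v_A = 0.5, v_B = 0.5))
  s <- c(v_A = 0.5, v_B = 0.3)
  expect_equal(rw_update(s, "A", 1, 0.35)[["v_A"]], 0.675)
  expect_equal(rw_update(s, "A", 1, 0.35)[["v_B"]], 0.3)
  expect_equal(rw_update(s, "B", 0, 1e-8)[["v_B"]], 0.3, tolerance = 1e-6)
  expect_error(rw_update(s, "A", 1, 1.2), "alpha")
})

test_that("softmax choice probabilities are correct and bounded", {
  win <- winning_spec()
  expect_equal(choice_prob(c(0.4, 0.4), win, tau = 0.3), 0.5)
  expect_equal(choice_prob(c(1, 0), win, tau = 1), 1 / (1 + exp(-1)))
  expect_equal(choice_prob(c(1, 0), win, tau = 1e6), 0.5, tolerance = 1e-5)
  expect_gt(choice_prob(c(0.6, 0.4), win, tau = 1e-3), 1 - 1e-6)
  expect_error(choice_prob(c(1, 0), win, tau = 0), "tau")
  mag <- default_family()$M05
  # magnitude utility: u = v * m / 100
  p <- choice_prob(c(0.5, 0.5), mag, tau = 1, magnitudes = c(80, 20))
  expect_equal(p, 1 / (1 + exp(-(0.4 - 0.1))))
})

test_that("sequential likelihood matches a hand-rolled two-trial evaluation", {
  win <- winning_spec()
  sch <- toy_schedule(c("A", "B"))
  ch <- toy_choices(c("A", "A"), sch)
  ll <- log_likelihood(win, list(b = 0.5, tau = 1, alpha_stable = 0.5,
                                 alpha_volatile = 0.5), ch, sch)
  # trial 1: v = (.5,.5) -> log .5 ; update vA to .75
  # trial 2: P(A) = 1/(1+exp(-(0.75-0.5)/1))
  expect_equal(ll$pointwise, c(log(0.5), log(1 / (1 + exp(-0.25)))),
               tolerance = 1e-12)
  expect_equal(ll$total, sum(ll$pointwise))
  # null model closed form and empty data
  null <- default_family()$M01
  sch120 <- generate_schedule(task_config(seed = 1))
  ch120 <- toy_choices(rep("A", 120), sch120)
  expect_equal(log_likelihood(null, list(), ch120, sch120)$total,
               120 * log(0.5))
  e <- log_likelihood(null, list(), ch120[0, ], sch120[0, ])
  expect_equal(e$total, 0)
  expect_length(e$pointwise, 0L)
  # biased null
  m02 <- default_family()$M02
  ll2 <- log_likelihood(m02, list(b = 0.7), toy_choices(c("A", "B"), sch),
                        sch)
  expect_equal(ll2$pointwise, c(log(0.7), log(0.3)))
})

test_that("win-stay-lose-shift likelihood follows the stay rule", {
  m11 <- default_family()$M11
  sch <- toy_schedule(c("A", "A", "B"))
  ch <- toy_choices(c("A", "A", "A"), sch)  # outcomes 1, 1, 0
  ll <- log_likelihood(m11, list(p_stay = 0.8), ch, sch)
  expect_equal(ll$pointwise, c(log(0.5), log(0.8), log(0.8)))
})

test_that("pointwise log-probabilities are non-positive and tau drives them to log 0.5", {
  win <- winning_spec()
  sch <- generate_schedule(task_config(seed = 4))
  set.seed(2)
  for (rep in 1:5) {
    par <- list(b = runif(1, .2, .8), tau = runif(1, .05, 1),
                alpha_stable = runif(1, .1, .9),
                alpha_volatile = runif(1, .1, .9))
    ch <- simulate_agent(par, win, sch, seed = rep)
    pw <- log_likelihood(win, par, ch[, c("chosen", "outcome")], sch)$pointwise
    expect_true(all(pw <= 0))
    # monotonicity: larger tau pulls every pointwise probability toward 0.5
    par_hi <- par; par_hi$tau <- 50
    pw_hi <- log_likelihood(win, par_hi, ch[, c("chosen", "outcome")],
                            sch)$pointwise
    expect_true(all(abs(exp(pw_hi) - 0.5) <= abs(exp(pw) - 0.5) + 1e-9))
  }
})

test_that("richer nested models attain at least the poorer model's best likelihood", {
  # grid oracle on 10-trial data: maximise over a parameter grid
  sch <- toy_schedule(c("A", "B", "A", "A", "B", "A", "A", "A", "B", "A"))
  ch <- toy_choices(c("A", "A", "B", "A", "A", "A", "B", "A", "A", "A"), sch)
  single <- default_family()$M03
  dual <- default_family()$M07
  taus <- c(0.05, 0.1, 0.2, 0.5, 1)
  alphas <- seq(0.1, 0.9, by = 0.1)
  best_single <- -Inf
  for (tau in taus) for (a in alphas) {
    v <- log_likelihood(single, list(tau = tau, alpha = a), ch, sch)$total
    best_single <- max(best_single, v)
  }
  best_dual <- -Inf
  for (tau in taus) for (a1 in alphas) for (a2 in alphas) {
    v <- log_likelihood(dual, list(tau = tau, alpha_stable = a1,
                                   alpha_volatile = a2), ch, sch)$total
    best_dual <- max(best_dual, v)
  }
  expect_gte(best_dual, best_single)
})

test_that("the model registry and trial series export to their fixed dialects", {
  fam <- default_family()
  jpath <- withr::local_tempfile(fileext = ".json")
  write_family_json(fam, jpath)
  reg <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(nrow(reg), 12L)
  expect_equal(reg$model_id, names(fam))
  expect_equal(reg$n_free_params[reg$winning], 4L)
  sch <- toy_schedule(c("A", "B"))
  ts <- derive_trial_series(winning_spec(),
                            list(b = .5, tau = 1, alpha_stable = .4,
                                 alpha_volatile = .4),
                            toy_choices(c("A", "B"), sch), sch)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_trial_series_csv(ts, cpath, participant_id = "S9")
  expect_equal(readLines(cpath)[1],
               "participant_id,trial_index,phase,ev_chosen,pe")
  back <- utils::read.csv(cpath)
  expect_equal(back$pe, ts$pe)
})

test_that("trialwise EV and PE series are consistent with the value dynamics", {
  win <- winning_spec()
  sch <- toy_schedule(c("A", "A", "B"))
  ch <- toy_choices(c("A", "A", "A"), sch)
  ts <- derive_trial_series(win, list(b = 0.5, tau = 1, alpha_stable = 0.35,
                                      alpha_volatile = 0.41), ch, sch)
  expect_equal(ts$ev_chosen[1], 0.5)
  expect_equal(ts$pe, ch$outcome - ts$ev_chosen)
  expect_true(all(ts$pe >= -1 & ts$pe <= 1))
  expect_true(all(ts$ev_chosen >= 0 & ts$ev_chosen <= 1))
  # full update (alpha ~ 1): EV equals previous outcome when rechoosing
  ts2 <- derive_trial_series(win, list(b = 0.5, tau = 1,
                                       alpha_stable = 1 - 1e-9,
                                       alpha_volatile = 1 - 1e-9), ch, sch)
  expect_equal(ts2$ev_chosen[2], 1, tolerance = 1e-6)
  expect_equal(ts2$ev_chosen[3], 1, tolerance = 1e-6)
})
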