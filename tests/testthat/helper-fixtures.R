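# Small builders shared across tests; everything is generated in code.

# a minimal hand-written schedule (no magnitudes unless asked)
toy_schedule <- function(rewarded, phase = NULL, magnitudes = FALSE) {
  n <- length(rewarded)
  if (is.null(phase)) phase <- rep("stable", n)
  sch <- data.frame(
    trial_index = seq_len(n), phase = phase,
    block_id = ifelse(phase == "stable", 0L, 1L),
    high_prob_option = "A", rewarded_option = rewarded,
    magnitude_A = if (magnitudes) rep(60L, n) else NA_integer_,
    magnitude_B = if (magnitudes) rep(40L, n) else NA_integer_,
    stringsAsFactors = FALSE)
  structure(sch, class = c("task_schedule", "data.frame"))
}

toy_choices <- function(chosen, schedule) {
  data.frame(chosen = chosen,
             outcome = as.integer(chosen == schedule$rewarded_option),
             stringsAsFactors = FALSE)
}

# one-participant tidy trials table from a schedule + choices
toy_trials <- function(schedule, chosen, id = "P1") {
  ch <- toy_choices(chosen, schedule)
  cbind(participant_id = id, as.data.frame(schedule), ch,
        coins_won = 0L, stringsAsFactors = FALSE)
}

# cohort generation without the odd-group-size counterbalancing warning noise
quiet_cohort <- function(...) suppressWarnings(generate_cohort(...))

# fast row variances for large simulation matrices
matrixStats_rowVars <- function(x)
  rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)

# winning-model trials for N agents drawn from the model's own hierarchy
# (used by calibration tests); returns list(trials, mu_true)
hierarchy_cohort <- function(N, mu_true, sig_true, seed) {
  spec <- winning_spec()
  set.seed(seed)
  trials <- vector("list", N)
  for (i in seq_len(N)) {
    eta <- mu_true + sig_true * stats::rnorm(4)
    par <- list(b = stats::plogis(eta[1]), tau = exp(eta[2]),
                alpha_stable = stats::plogis(eta[3]),
                alpha_volatile = stats::plogis(eta[4]))
    sch <- generate_schedule(task_config(
      order = if (i %% 2) "stable_first" else "volatile_first",
      seed = seed * 1000L + i))
    rec <- simulate_agent(par, spec, sch, seed = seed * 2000L + i,
                          participant_id = sprintf("P%02d", i))
    trials[[i]] <- cbind(rec["participant_id"], as.data.frame(sch),
                         rec[, c("chosen", "outcome")])
  }
  list(trials = do.call(rbind, trials), spec = spec)
}
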