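#' Simulate one agent's choices on a schedule
#'
#' Draws a full choice sequence from a model's own choice probabilities,
#' updating values trial by trial with the model's learning rule. Null
#' (random) agents choose each option with probability 0.5 (or `b` for the
#' biased null); win-stay-lose-shift agents repeat a rewarded choice with
#' probability `p_stay`.
#'
#' @param params Named parameters for `spec` (see [spec_params()]).
#' @param spec A [model_spec()].
#' @param schedule A `task_schedule`.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param participant_id Identifier stamped on the records.
#' @return Data frame of choice records: `participant_id`, `trial_index`,
#'   `chosen`, `outcome`, `coins_won` (`NA` when the schedule carries no
#'   magnitudes).
#' @export
simulate_agent <- function(params, spec, schedule, seed = 1L,
                           participant_id = "P1") {
  if (spec$n_free_params > 0) validate_params(spec, params)
  if (isTRUE(spec$uses_magnitude) && anyNA(schedule$magnitude_A))
    stop("magnitude model simulated on a schedule without magnitudes")
  n <- nrow(schedule)
  par <- as.list(params)
  u <- with_seed(seed, stats::runif(n))
  chosen <- character(n); outcome <- integer(n)
  state <- if (spec$rule == "rescorla_wagner") initial_state(spec, par)
  for (t in seq_len(n)) {
    pA <- switch(spec$rule,
      random = if (spec$has_bias) par$b else 0.5,
      rescorla_wagner = choice_prob(state, spec, par$tau,
        c(schedule$magnitude_A[t], schedule$magnitude_B[t])),
      win_stay_lose_shift = {
        if (t == 1L) { if (spec$has_bias) par$b else 0.5 }
        else {
          p_rep <- if (outcome[t - 1L] == 1L) par$p_stay else 1 - par$p_stay
          if (chosen[t - 1L] == "A") p_rep else 1 - p_rep
        }
      })
    chosen[t] <- if (u[t] < pA) "A" else "B"
    outcome[t] <- as.integer(chosen[t] == schedule$rewarded_option[t])
    if (spec$rule == "rescorla_wagner") {
      alpha <- if (spec$dual_learning_rate) {
        if (schedule$phase[t] == "stable") par$alpha_stable else par$alpha_volatile
      } else par$alpha
      state <- rw_update(state, chosen[t], outcome[t], alpha)
    }
  }
  mag <- ifelse(chosen == "A", schedule$magnitude_A, schedule$magnitude_B)
  data.frame(participant_id = participant_id,
             trial_index = schedule$trial_index,
             chosen = chosen, outcome = outcome,
             coins_won = as.integer(outcome * mag),
             stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' Defaults emulate the structure of a two-group developmental study of this
#' task: 37 maltreated (MT) and 32 non-maltreated (NMT) participants matched
#' on covariates, a standardized group difference of 0.70 in softmax
#' temperature (MT lower), 35% random responders, learning-rate
#' distributions with means 0.35 (stable) and 0.41 (volatile), baseline and
#' follow-up symptom scores with a group-by-temperature interaction
#' (standardized coefficient -0.80), and per-group retention probabilities
#' 27/37 and 29/32.
#'
#' @param n_MT,n_NMT Group sizes.
#' @param temperature_effect_d Standardized NMT-minus-MT difference in
#'   temperature, in pooled-SD units.
#' @param random_responder_fraction Expected fraction of participants whose
#'   choices are simulated from the unbiased null (uniform) model.
#' @param covariates,agent,symptoms,retention Named lists overriding
#'   individual distribution settings (see Details in the package vignette).
#' @param task A [task_config()] used as the schedule template; phase order
#'   is counterbalanced deterministically within each group.
#' @param seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_MT = 37L, n_NMT = 32L,
                          temperature_effect_d = 0.70,
                          random_responder_fraction = 0.35,
                          covariates = list(), agent = list(),
                          symptoms = list(), retention = list(),
                          task = task_config(), seed = 1L) {
  cov_def <- list(sex_female_p = 0.54, age_mean = 13.6, age_sd = 2.1,
                  iq_mean = 101.3, iq_sd = 10.5, pds_mean = 2.45,
                  pds_sd = 0.85, ses_mean = 3.25, ses_sd = 0.9)
  agent_def <- list(tau_mean_NMT = 0.30, tau_sd = 0.10,
                    alpha_stable_mean = 0.35, alpha_stable_sd = 0.07,
                    alpha_volatile_mean = 0.41, alpha_volatile_sd = 0.17,
                    alpha_corr = 0.47, b_logit_mean = 0, b_logit_sd = 0.7)
  sym_def <- list(emo_mean_MT = 2.8, emo_sd_MT = 2.3,
                  emo_mean_NMT = 1.5, emo_sd_NMT = 1.5,
                  total_mean_MT = 11.2, total_sd_MT = 6.8,
                  total_mean_NMT = 6.6, total_sd_NMT = 4.3,
                  beta_baseline = 0.35, beta_group = 0.15, beta_tau = -0.15,
                  beta_int = -0.80, residual_sd = 0.5,
                  followup_mean = 2.9, followup_sd = 2.3)
  ret_def <- list(p_MT = 27 / 37, p_NMT = 29 / 32)
  cfg <- list(n_MT = as.integer(n_MT), n_NMT = as.integer(n_NMT),
              temperature_effect_d = temperature_effect_d,
              random_responder_fraction = random_responder_fraction,
              covariates = utils::modifyList(cov_def, covariates),
              agent = utils::modifyList(agent_def, agent),
              symptoms = utils::modifyList(sym_def, symptoms),
              retention = utils::modifyList(ret_def, retention),
              task = task, seed = as.integer(seed))
  stopifnot(cfg$n_MT >= 2L, cfg$n_NMT >= 2L,
            cfg$random_responder_fraction >= 0,
            cfg$random_responder_fraction <= 1,
            cfg$agent$tau_sd > 0, cfg$symptoms$residual_sd >= 0,
            cfg$retention$p_MT >= 0, cfg$retention$p_MT <= 1,
            cfg$retention$p_NMT >= 0, cfg$retention$p_NMT <= 1)
  structure(cfg, class = "cohort_config")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic cohort with behavioural data
#'
#' Draws participant covariates i.i.d. from distributions shared by both
#' groups (groups matched in expectation), samples true agent parameters
#' (MT temperature lowered by `temperature_effect_d` pooled-SD units;
#' the two learning rates correlated within participant), flags an expected
#' `random_responder_fraction` of participants as uniform choosers, assigns
#' phase order by deterministic alternation within group, and simulates each
#' participant's 120 trials from the winning model (model responders) or the
#' unbiased null (random responders).
#'
#' @param config A [cohort_config()].
#' @param followup If `TRUE`, also generate follow-up symptoms and retention
#'   via [generate_followup_symptoms()].
#' @param simulate_trials If `FALSE`, skip the behavioural simulation and
#'   return only the participant table (useful for replicate studies of the
#'   cohort-level statistics).
#' @return List with elements `cohort` (one row per participant; class
#'   `cohort_table`) and `trials` (trialwise behavioural records joined with
#'   schedule columns; `NULL` when `simulate_trials = FALSE`).
#' @export
generate_cohort <- function(config = cohort_config(), followup = TRUE,
                            simulate_trials = TRUE) {
  n <- config$n_MT + config$n_NMT
  if (config$n_MT %% 2L || config$n_NMT %% 2L)
    warning("odd group size: phase-order counterbalancing is off by one")
  cv <- config$covariates; ag <- config$agent; sy <- config$symptoms
  cohort <- with_seed(config$seed, {
    group <- rep(c("MT", "NMT"), c(config$n_MT, config$n_NMT))
    idx_in_group <- c(seq_len(config$n_MT), seq_len(config$n_NMT))
    tau_mu <- ifelse(group == "MT",
                     ag$tau_mean_NMT - config$temperature_effect_d * ag$tau_sd,
                     ag$tau_mean_NMT)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    a_s <- ag$alpha_stable_mean + ag$alpha_stable_sd * z1
    a_v <- ag$alpha_volatile_mean + ag$alpha_volatile_sd *
      (ag$alpha_corr * z1 + sqrt(1 - ag$alpha_corr^2) * z2)
    data.frame(
      participant_id = sprintf("S%03d", seq_len(n)),
      group = group,
      order = ifelse(idx_in_group %% 2L == 1L, "stable_first",
                     "volatile_first"),
      sex = ifelse(stats::runif(n) < cv$sex_female_p, "F", "M"),
      age = round(stats::rnorm(n, cv$age_mean, cv$age_sd), 1),
      iq = round(stats::rnorm(n, cv$iq_mean, cv$iq_sd), 1),
      pubertal = round(.rtrunc_norm(n, cv$pds_mean, cv$pds_sd, 1, 5), 1),
      ses = round(.rtrunc_norm(n, cv$ses_mean, cv$ses_sd, 1, 5), 1),
      responder_type = {
        rt <- rep("model", n)
        rt[sample.int(n, round(config$random_responder_fraction * n))] <-
          "random"
        rt
      },
      b_true = stats::plogis(stats::rnorm(n, ag$b_logit_mean, ag$b_logit_sd)),
      tau_true = pmax(stats::rnorm(n, tau_mu, ag$tau_sd), 0.02),
      alpha_stable_true = pmin(pmax(a_s, 0.02), 0.95),
      alpha_volatile_true = pmin(pmax(a_v, 0.02), 0.95),
      sdq_emotional_baseline = pmax(stats::rnorm(
        n, ifelse(group == "MT", sy$emo_mean_MT, sy$emo_mean_NMT),
        ifelse(group == "MT", sy$emo_sd_MT, sy$emo_sd_NMT)), 0),
      sdq_total_baseline = pmax(stats::rnorm(
        n, ifelse(group == "MT", sy$total_mean_MT, sy$total_mean_NMT),
        ifelse(group == "MT", sy$total_sd_MT, sy$total_sd_NMT)), 0),
      stringsAsFactors = FALSE)
  })
  win <- winning_spec()
  null <- default_family()[["M01"]]
  trials <- vector("list", n)
  if (simulate_trials) for (i in seq_len(n)) {
    cfg_i <- config$task
    cfg_i$order <- cohort$order[i]
    cfg_i$seed <- config$seed + 13L * i
    sch <- generate_schedule(cfg_i)
    if (cohort$responder_type[i] == "model") {
      par <- list(b = cohort$b_true[i], tau = cohort$tau_true[i],
                  alpha_stable = cohort$alpha_stable_true[i],
                  alpha_volatile = cohort$alpha_volatile_true[i])
      rec <- simulate_agent(par, win, sch, seed = config$seed + 1000L + i,
                            participant_id = cohort$participant_id[i])
    } else {
      rec <- simulate_agent(list(), null, sch, seed = config$seed + 1000L + i,
                            participant_id = cohort$participant_id[i])
    }
    trials[[i]] <- cbind(rec[, "participant_id", drop = FALSE],
                         as.data.frame(sch),
                         rec[, c("chosen", "outcome", "coins_won")])
  }
  trials <- if (simulate_trials) do.call(rbind, trials)
  if (!is.null(trials)) rownames(trials) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  out <- list(cohort = cohort, trials = trials, config = config)
  if (followup)
    out$cohort <- generate_followup_symptoms(out$cohort, config,
                                             seed = config$seed + 5000L)
  out
}

#' Generate follow-up symptoms and retention flags
#'
#' Follow-up internalising symptoms are a linear combination of the
#' standardized baseline score, effect-coded group (MT = +1, NMT = -1),
#' standardized true temperature and the group-by-temperature product with
#' coefficient `beta_int`, plus Gaussian noise, mapped onto a natural SDQ
#' scale. Retention is Bernoulli per group. Follow-up columns are `NA` for
#' non-retained participants.
#'
#' @param cohort A `cohort_table`.
#' @param config The generating [cohort_config()].
#' @param seed Integer seed.
#' @return The cohort with `retained`, `sdq_emotional_followup`,
#'   `sdq_total_followup` columns filled in.
#' @export
generate_followup_symptoms <- function(cohort, config, seed = 1L) {
  sy <- config$symptoms
  g <- ifelse(cohort$group == "MT", 1, -1)
  zb <- as.numeric(scale(cohort$sdq_emotional_baseline))
  zt <- as.numeric(scale(cohort$tau_true))
  n <- nrow(cohort)
  with_seed(seed, {
    y <- sy$beta_baseline * zb + sy$beta_group * g + sy$beta_tau * zt +
      sy$beta_int * g * zt + stats::rnorm(n, 0, sy$residual_sd)
    cohort$retained <- stats::runif(n) <
      ifelse(cohort$group == "MT", config$retention$p_MT,
             config$retention$p_NMT)
    cohort$sdq_emotional_followup <-
      ifelse(cohort$retained, sy$followup_mean + sy$followup_sd * y, NA_real_)
    yt <- sy$beta_baseline * as.numeric(scale(cohort$sdq_total_baseline)) +
      sy$beta_group * g + stats::rnorm(n, 0, sy$residual_sd)
    cohort$sdq_total_followup <-
      ifelse(cohort$retained, 9.5 + 6 * yt, NA_real_)
  })
  cohort
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d MT, %d NMT); %d model / %d random responders\n",
              nrow(x), sum(x$group == "MT"), sum(x$group == "NMT"),
              sum(x$responder_type == "model"),
              sum(x$responder_type == "random")))
  if ("retained" %in% names(x))
    cat(sprintf("Retained at follow-up: %d/%d MT, %d/%d NMT\n",
                sum(x$retained[x$group == "MT"]), sum(x$group == "MT"),
                sum(x$retained[x$group == "NMT"]), sum(x$group == "NMT")))
  print.data.frame(utils::head(as.data.frame(x), 4), ...)
  invisible(x)
}

#' Cohort and trial table CSV round-trips
#'
#' Missing follow-up values are written as empty cells.
#' @param x Cohort or trials data frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("retained" %in% names(df)) df$retained <- as.logical(df$retained)
  structure(df, class = c("cohort_table", "data.frame"))
}

#' @rdname write_cohort_csv
#' @export
write_trials_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort configuration from JSON or YAML
#'
#' Scalar fields use the [cohort_config()] argument names; the nested
#' distribution lists (`covariates`, `agent`, `symptoms`, `retention`) may
#' be partial and override the defaults.
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- .read_config_file(path)
  if (!is.null(vals$task)) vals$task <- do.call(task_config, vals$task)
  do.call(cohort_config, vals)
}
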