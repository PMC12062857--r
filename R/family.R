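#' Candidate model specifications
#'
#' A `model_spec` describes one member of the 12-model candidate family used
#' to analyse choices on the stable/volatile bandit: two null (random-choice)
#' models, eight Rescorla-Wagner variants crossing single vs. phase-specific
#' (dual) learning rates, starting bias on/off and magnitude utility on/off,
#' and two win-stay-lose-shift models. The designated winning model is the
#' Rescorla-Wagner variant with a starting bias, softmax temperature and two
#' phase-specific learning rates (four free parameters per participant).
#'
#' @param model_id Short identifier, e.g. `"M08"`.
#' @param rule Choice rule: `"random"`, `"rescorla_wagner"` or
#'   `"win_stay_lose_shift"`.
#' @param has_bias Whether the model has a starting-bias parameter `b`.
#' @param dual_learning_rate Whether learning rates are phase-specific.
#' @param uses_magnitude Whether utilities are probability-times-magnitude
#'   (`v * m / 100`) rather than probability alone.
#' @param winning Marks the designated winning model.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_id, rule = c("rescorla_wagner", "random",
                                          "win_stay_lose_shift"),
                       has_bias = FALSE, dual_learning_rate = FALSE,
                       uses_magnitude = FALSE, winning = FALSE) {
  rule <- match.arg(rule)
  if (rule != "rescorla_wagner" && (dual_learning_rate || uses_magnitude))
    stop("dual_learning_rate/uses_magnitude apply only to rescorla_wagner models")
  spec <- structure(list(model_id = model_id, rule = rule,
                         is_null = rule == "random",
                         has_bias = has_bias,
                         dual_learning_rate = dual_learning_rate,
                         uses_magnitude = uses_magnitude,
                         winning = winning),
                    class = "model_spec")
  spec$params <- spec_params(spec)
  spec$n_free_params <- length(spec$params)
  spec
}

#' Free parameters of a model spec
#'
#' Canonical order: `b` (bias), `tau` (temperature), learning rate(s),
#' `p_stay` (win-stay probability).
#' @param spec A `model_spec`.
#' @return Character vector of parameter names.
#' @export
spec_params <- function(spec) {
  switch(spec$rule,
    random = if (spec$has_bias) "b" else character(0),
    rescorla_wagner = c(if (spec$has_bias) "b", "tau",
                        if (spec$dual_learning_rate)
                          c("alpha_stable", "alpha_volatile") else "alpha"),
    win_stay_lose_shift = c(if (spec$has_bias) "b", "p_stay"))
}

#' The default 12-model candidate family
#'
#' @return A named list of 12 `model_spec` objects, M01..M12. Exactly one
#'   (`M08`) is flagged as the winning model.
#' @examples
#' fam <- default_family()
#' length(fam)                       # 12
#' winning_spec(fam)$n_free_params   # 4
#' @export
default_family <- function() {
  fam <- list(
    model_spec("M01", "random"),
    model_spec("M02", "random", has_bias = TRUE),
    model_spec("M03", "rescorla_wagner"),
    model_spec("M04", "rescorla_wagner", has_bias = TRUE),
    model_spec("M05", "rescorla_wagner", uses_magnitude = TRUE),
    model_spec("M06", "rescorla_wagner", has_bias = TRUE,
               uses_magnitude = TRUE),
    model_spec("M07", "rescorla_wagner", dual_learning_rate = TRUE),
    model_spec("M08", "rescorla_wagner", has_bias = TRUE,
               dual_learning_rate = TRUE, winning = TRUE),
    model_spec("M09", "rescorla_wagner", dual_learning_rate = TRUE,
               uses_magnitude = TRUE),
    model_spec("M10", "rescorla_wagner", has_bias = TRUE,
               dual_learning_rate = TRUE, uses_magnitude = TRUE),
    model_spec("M11", "win_stay_lose_shift"),
    model_spec("M12", "win_stay_lose_shift", has_bias = TRUE))
  names(fam) <- vapply(fam, `[[`, "", "model_id")
  fam
}

#' @rdname default_family
#' @param family A list of `model_spec`s.
#' @export
winning_spec <- function(family = default_family()) {
  family[[which(vapply(family, `[[`, FALSE, "winning"))]]
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s> rule=%s%s%s%s; %d free parameter(s): %s\n",
              x$model_id, x$rule,
              if (x$has_bias) " +bias" else "",
              if (x$dual_learning_rate) " +dualLR" else "",
              if (x$uses_magnitude) " +magnitude" else "",
              x$n_free_params,
              if (x$n_free_params) paste(x$params, collapse = ", ") else "none"))
  invisible(x)
}

#' Write the model family registry to JSON
#' @param family List of `model_spec`s.
#' @param path Output path.
#' @export
write_family_json <- function(family, path) {
  entries <- lapply(family, function(s)
    s[c("model_id", "rule", "is_null", "has_bias", "dual_learning_rate",
        "uses_magnitude", "winning", "n_free_params", "params")])
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# --- parameter plumbing -----------------------------------------------------

# canonical 5-slot natural-scale parameter vector used by the C++ likelihood
.canonical_slots <- c("b", "tau", "alpha_stable", "alpha_volatile", "p_stay")

# map named free parameters of `spec` into the canonical 5-vector
canonical_par <- function(spec, params) {
  par <- c(b = 0.5, tau = 1, alpha_stable = 0.5, alpha_volatile = 0.5,
           p_stay = 0.5)
  p <- as.list(params)
  if (!is.null(p$alpha)) { p$alpha_stable <- p$alpha; p$alpha_volatile <- p$alpha }
  for (nm in intersect(names(p), names(par))) par[nm] <- p[[nm]]
  unname(par)
}

.rule_code <- function(spec)
  switch(spec$rule, random = 0L, rescorla_wagner = 1L, win_stay_lose_shift = 2L)

validate_params <- function(spec, params) {
  need <- spec$params
  if (!all(need %in% names(params)))
    stop("missing parameter(s): ",
         paste(setdiff(need, names(params)), collapse = ", "))
  unit <- intersect(need, c("b", "alpha", "alpha_stable", "alpha_volatile",
                            "p_stay"))
  for (nm in unit)
    if (params[[nm]] <= 0 || params[[nm]] >= 1)
      stop(nm, " must lie strictly in (0, 1)")
  if ("tau" %in% need && params[["tau"]] <= 0)
    stop("tau must be > 0")
  invisible(params)
}

# --- value dynamics (reference R implementations) ---------------------------

#' Initial value state
#'
#' Starting estimates of the two options' reward probabilities: `(b, 1 - b)`
#' for models with a starting bias, `(0.5, 0.5)` otherwise.
#' @param spec A `model_spec`.
#' @param params Named parameter list/vector.
#' @return Numeric `c(v_A, v_B)`.
#' @export
initial_state <- function(spec, params) {
  if (isTRUE(spec$has_bias)) {
    b <- params[["b"]]
    c(v_A = b, v_B = 1 - b)
  } else c(v_A = 0.5, v_B = 0.5)
}

#' Rescorla-Wagner delta-rule update
#'
#' Only the chosen option's value moves, by `alpha` times the prediction
#' error `r - v_chosen`.
#' @param state Numeric `c(v_A, v_B)`.
#' @param chosen `"A"` or `"B"`.
#' @param r Outcome, 0 or 1.
#' @param alpha Learning rate in (0, 1).
#' @return Updated state.
#' @export
rw_update <- function(state, chosen, r, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  i <- if (chosen == "A") 1L else 2L
  state[i] <- state[i] + alpha * (r - state[i])
  state
}

#' Softmax choice probability of option A
#'
#' Utilities are the value estimates (probability-only models) or
#' `v * magnitude / 100` (magnitude models);
#' `P(A) = exp(u_A / tau) / (exp(u_A / tau) + exp(u_B / tau))`. `tau` is a
#' temperature: larger values give more exploratory (uniform) choice.
#' @param state Numeric `c(v_A, v_B)`.
#' @param spec A `model_spec`.
#' @param tau Temperature, > 0.
#' @param magnitudes Numeric `c(m_A, m_B)`; needed when the spec uses
#'   magnitudes.
#' @return `P(choose A)`.
#' @export
choice_prob <- function(state, spec, tau, magnitudes = c(NA, NA)) {
  if (tau <= 0) stop("tau must be > 0")
  u <- if (isTRUE(spec$uses_magnitude)) {
    if (anyNA(magnitudes))
      stop("magnitude model evaluated on a schedule without magnitudes")
    state * magnitudes / 100
  } else state
  1 / (1 + exp(-(u[1] - u[2]) / tau))
}

# --- likelihood -------------------------------------------------------------

# build integer/numeric vectors the C++ routines expect
.ll_data <- function(choices, schedule) {
  if (nrow(choices) != nrow(schedule))
    stop("choices and schedule are misaligned: ",
         nrow(choices), " choice rows vs ", nrow(schedule), " trials")
  list(choice = ifelse(choices$chosen == "A", 1L, 2L),
       outcome = as.integer(choices$outcome),
       phase = as.integer(schedule$phase == "volatile"),
       magA = as.numeric(ifelse(is.na(schedule$magnitude_A), 50,
                                schedule$magnitude_A)),
       magB = as.numeric(ifelse(is.na(schedule$magnitude_B), 50,
                                schedule$magnitude_B)),
       has_mag = !anyNA(schedule$magnitude_A))
}

#' Trialwise choice log-likelihood
#'
#' Evaluates the model's sequential likelihood of an observed choice
#' sequence: values are initialised from the bias (or 0.5), each trial's
#' choice probability comes from the softmax over current utilities, and the
#' chosen option's value is updated with the phase-appropriate learning rate
#' (`alpha_stable` on stable trials, `alpha_volatile` on volatile trials;
#' single-learning-rate models use one `alpha` throughout).
#'
#' @param spec A `model_spec`.
#' @param params Named parameters for `spec` (see [spec_params()]).
#' @param choices Data frame with columns `chosen` ("A"/"B") and `outcome`
#'   (0/1), one row per trial, aligned with `schedule`.
#' @param schedule A `task_schedule` (or data frame with `phase`,
#'   `magnitude_A`, `magnitude_B`).
#' @return List with `total` (sum) and `pointwise` (per-trial vector of
#'   log-probabilities).
#' @export
log_likelihood <- function(spec, params, choices, schedule) {
  if (nrow(choices) == 0L)
    return(list(total = 0, pointwise = numeric(0)))
  validate_params(spec, params)
  d <- .ll_data(choices, schedule)
  if (isTRUE(spec$uses_magnitude) && !d$has_mag)
    stop("magnitude model evaluated on a schedule without magnitudes")
  pw <- vb_ll_pointwise(.rule_code(spec), spec$has_bias,
                        spec$dual_learning_rate, spec$uses_magnitude,
                        canonical_par(spec, params),
                        d$choice, d$outcome, d$phase, d$magA, d$magB)
  list(total = sum(pw), pointwise = pw)
}

#' Derive trialwise expected-value and prediction-error series
#'
#' For each trial, `ev_chosen` is the value estimate of the chosen option
#' before the outcome is observed, and `pe = r - ev_chosen`. These are the
#' series used as trialwise model-based regressors.
#'
#' @inheritParams log_likelihood
#' @return Data frame with columns `trial_index`, `phase`, `ev_chosen`, `pe`.
#' @export
derive_trial_series <- function(spec, params, choices, schedule) {
  validate_params(spec, params)
  n <- nrow(choices)
  if (n != nrow(schedule)) stop("choices and schedule are misaligned")
  par <- as.list(params)
  state <- initial_state(spec, par)
  ev <- pe <- numeric(n)
  for (t in seq_len(n)) {
    i <- if (choices$chosen[t] == "A") 1L else 2L
    ev[t] <- if (spec$rule == "random") {
      if (spec$has_bias) c(par$b, 1 - par$b)[i] else 0.5
    } else state[i]
    pe[t] <- choices$outcome[t] - ev[t]
    if (spec$rule == "rescorla_wagner") {
      alpha <- if (spec$dual_learning_rate) {
        if (schedule$phase[t] == "stable") par$alpha_stable else par$alpha_volatile
      } else par$alpha
      state <- rw_update(state, choices$chosen[t], choices$outcome[t], alpha)
    }
  }
  data.frame(trial_index = schedule$trial_index, phase = schedule$phase,
             ev_chosen = ev, pe = pe)
}

#' Export trialwise series to CSV
#'
#' Fixed dialect: `participant_id,trial_index,phase,ev_chosen,pe`.
#' @param series A [derive_trial_series()] result (or a row-bound set).
#' @param participant_id Id stamped on the rows when the series lacks one.
#' @param path Output path.
#' @export
write_trial_series_csv <- function(series, path, participant_id = "P1") {
  if (!"participant_id" %in% names(series))
    series <- cbind(participant_id = participant_id, series)
  utils::write.csv(series[, c("participant_id", "trial_index", "phase",
                              "ev_chosen", "pe")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
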