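#' Widely Applicable Information Criterion from pointwise log-likelihoods
#'
#' For each pointwise unit i (trial), `lppd_i = log mean_s exp(loglik_si)`
#' (computed by log-sum-exp) and the effective-parameter penalty
#' `p_i = var_s(loglik_si)`; `elpd_waic = sum(lppd_i - p_i)`,
#' `waic = -2 * elpd_waic`, with the standard error taken over the pointwise
#' elpd contributions.
#'
#' @param pointwise Draws-by-units matrix of log-likelihood values (>= 2
#'   draws).
#' @param groups Optional factor/vector of length `ncol(pointwise)` (e.g.
#'   participant ids); per-group elpd sums are then reported.
#' @return An object of class `waic_result`: `elpd_waic`, `p_waic`, `waic`,
#'   `se`, `pointwise_elpd`, and `group_elpd` when `groups` is given.
#' @export
compute_waic <- function(pointwise, groups = NULL) {
  pointwise <- as.matrix(pointwise)
  if (nrow(pointwise) < 2L)
    stop("WAIC needs at least 2 draws (pointwise variance is undefined)")
  if (any(!is.finite(pointwise)))
    stop("non-finite pointwise log-likelihood values")
  S <- nrow(pointwise)
  mx <- apply(pointwise, 2, max)
  lppd <- mx + log(colMeans(exp(sweep(pointwise, 2, mx))))
  p <- apply(pointwise, 2, stats::var)
  pe <- lppd - p
  n <- length(pe)
  out <- list(elpd_waic = sum(pe), p_waic = sum(p), waic = -2 * sum(pe),
              se = sqrt(n * stats::var(pe)), pointwise_elpd = pe)
  if (!is.null(groups))
    out$group_elpd <- tapply(pe, groups, sum)
  structure(out, class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (elpd %.2f, p_waic %.2f, SE %.2f, n = %d)\n",
              x$waic, x$elpd_waic, x$p_waic, x$se, length(x$pointwise_elpd)))
  invisible(x)
}

# WAIC of one participant's MAP fit via draws from its Laplace approximation
participant_waic <- function(spec, fit, choices, schedule, S = 200L,
                             seed = 1L) {
  d <- .ll_data(choices, schedule)
  draws <- laplace_draws(fit, S = S, seed = seed)
  pw <- vb_ll_pointwise_draws(.rule_code(spec), spec$has_bias,
                              spec$dual_learning_rate, spec$uses_magnitude,
                              draws, d$choice, d$outcome, d$phase,
                              d$magA, d$magB)
  compute_waic(pw)
}

# Laplace approximation to the log marginal evidence of a MAP fit:
# log p(y) ~ log p(y | mode) + log prior(mode) + k/2 log(2 pi)
#            - 1/2 log det H.  Exact (n log 0.5) for the fit-free null.
laplace_evidence <- function(fit) {
  k <- fit$spec$n_free_params
  if (k == 0L) return(fit$log_posterior)
  ld <- determinant(fit$hessian, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)  # not a proper mode
  fit$log_posterior + k / 2 * log(2 * pi) - 0.5 * as.numeric(ld$modulus)
}

#' K-fold cross-validation of trialwise predictive fit
#'
#' Trials are partitioned into K folds within each participant, stratified
#' by phase (each fold receives a near-equal share of stable and volatile
#' trials). For each fold the model is refit by penalised MAP on the
#' remaining trials -- the value dynamics still run over the full sequence,
#' only training-trial log-probabilities enter the objective -- and the
#' held-out trials are scored at the fitted parameters.
#'
#' @param spec A [model_spec()].
#' @param trials Tidy behavioural table (see [fit_rl()]).
#' @param priors A [prior_spec()].
#' @param K Number of folds.
#' @param seed Integer seed for fold assignment (and fit restarts).
#' @return An object of class `kfold_result`: `K`, per-fold held-out log
#'   scores, `elpd_kfold` (their sum), `seed`, and the fold assignment.
#' @export
kfold_cv <- function(spec, trials, priors = prior_spec(), K = 10L,
                     seed = 1L) {
  stopifnot(K >= 2L)
  ids <- unique(trials$participant_id)
  folds <- with_seed(seed, {
    lapply(ids, function(id) {
      tr <- trials[trials$participant_id == id, ]
      n <- nrow(tr)
      if (n < K)
        stop(sprintf("participant %s has %d trials, fewer than K = %d",
                     id, n, K))
      f <- integer(n)
      # round-robin continuing across phases: folds stay balanced overall
      # and near-balanced within phase; a random fold relabelling and
      # within-phase shuffle randomise the assignment
      relab <- sample.int(K)
      counter <- 0L
      for (ph in unique(tr$phase)) {
        idx <- which(tr$phase == ph)
        lab <- relab[((counter + seq_along(idx) - 1L) %% K) + 1L]
        f[idx] <- sample(lab)
        counter <- counter + length(idx)
      }
      f
    })
  })
  names(folds) <- ids
  fold_scores <- numeric(K)
  for (fi in seq_len(K)) {
    for (id in ids) {
      tr <- trials[trials$participant_id == id, ]
      tr <- tr[order(tr$trial_index), ]
      choices <- tr[, c("chosen", "outcome")]
      held <- folds[[id]] == fi
      fit <- fit_participant(spec, choices, tr, priors,
                             include = !held, seed = seed + fi)
      est <- as.list(fit$estimates)
      pw <- if (fit$spec$n_free_params == 0L)
        rep(log(0.5), nrow(tr))
      else log_likelihood(spec, est, choices, tr)$pointwise
      fold_scores[fi] <- fold_scores[fi] + sum(pw[held])
    }
  }
  structure(list(K = K, fold_scores = fold_scores,
                 elpd_kfold = sum(fold_scores), seed = seed, folds = folds),
            class = "kfold_result")
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: elpd %.2f (fold range %.2f .. %.2f)\n",
              x$K, x$elpd_kfold, min(x$fold_scores), max(x$fold_scores)))
  invisible(x)
}

#' Participant-level null-model comparison and exclusion rule
#'
#' Each participant is fit individually (penalised MAP) under every model in
#' the family and each model's complexity-penalised evidence is computed; a
#' participant whose best null-family evidence is at least as good as the
#' best non-null model's evidence is flagged as excluded (random
#' responding): their parameter estimates would be uninterpretable and their
#' evidence would drag the group-level comparison toward over-simple models.
#'
#' The default evidence is the Laplace approximation to the log marginal
#' likelihood (an Occam-penalised, noise-free quantity); `evidence = "waic"`
#' instead computes participant-level WAIC over draws from the Laplace
#' approximation of the posterior. The marginal-likelihood default is better
#' calibrated for this screen: the best-of-many rule takes a maximum over
#' candidate models, and the Monte-Carlo noise in sampled WAIC estimates
#' biases that maximum upward, letting genuinely random responders slip
#' through.
#'
#' @param trials Tidy behavioural table (see [fit_rl()]).
#' @param family List of [model_spec()]s, containing at least one null spec.
#' @param priors A [prior_spec()].
#' @param cohort Optional `cohort_table` used to report post-exclusion group
#'   sizes.
#' @param evidence `"laplace"` (log marginal likelihood) or `"waic"`.
#' @param S Laplace draws per participant-model WAIC (only for
#'   `evidence = "waic"`).
#' @param seed Integer seed.
#' @return An object of class `exclusion_report`: per-participant best model,
#'   evidence difference vs. null, excluded flag; attributes carry the
#'   excluded fraction and post-exclusion group sizes.
#' @export
participant_null_comparison <- function(trials, family = default_family(),
                                        priors = prior_spec(), cohort = NULL,
                                        evidence = c("laplace", "waic"),
                                        S = 200L, seed = 1L) {
  evidence <- match.arg(evidence)
  ids <- unique(trials$participant_id)
  if (length(ids) == 0L) {
    rep0 <- data.frame(participant_id = character(0), best_model = character(0),
                       best_elpd = numeric(0), null_elpd = numeric(0),
                       delta_vs_null = numeric(0), excluded = logical(0))
    return(structure(rep0, excluded_fraction = NaN,
                     class = c("exclusion_report", "data.frame")))
  }
  is_null <- vapply(family, `[[`, FALSE, "is_null")
  if (!any(is_null)) stop("family contains no null model")
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[i], ]
    tr <- tr[order(tr$trial_index), ]
    choices <- tr[, c("chosen", "outcome")]
    elpd <- vapply(seq_along(family), function(m) {
      spec <- family[[m]]
      fit <- fit_participant(spec, choices, tr, priors,
                             seed = seed + 31L * i + m)
      if (!fit$converged && spec$n_free_params > 0L) return(-Inf)
      if (evidence == "laplace") laplace_evidence(fit)
      else participant_waic(spec, fit, choices, tr, S = S,
                            seed = seed + 97L * i + m)$elpd_waic
    }, 0)
    null_e <- max(elpd[is_null])
    alt_e <- max(elpd[!is_null])
    best <- which.max(elpd)
    rows[[i]] <- data.frame(
      participant_id = ids[i],
      best_model = family[[best]]$model_id,
      best_elpd = elpd[best], null_elpd = null_e,
      delta_vs_null = alt_e - null_e,
      excluded = null_e >= alt_e,
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  frac <- mean(rep$excluded)
  sizes <- NULL
  if (!is.null(cohort)) {
    kept <- rep$participant_id[!rep$excluded]
    sizes <- table(cohort$group[cohort$participant_id %in% kept])
  }
  structure(rep, excluded_fraction = frac, group_sizes = sizes,
            class = c("exclusion_report", "data.frame"))
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Null-model comparison: %d/%d participants excluded (%.0f%%)\n",
              sum(x$excluded), nrow(x),
              100 * attr(x, "excluded_fraction")))
  gs <- attr(x, "group_sizes")
  if (!is.null(gs))
    cat("Post-exclusion group sizes:",
        paste(sprintf("%s = %d", names(gs), gs), collapse = ", "), "\n")
  invisible(x)
}

#' Group-level model comparison by WAIC
#'
#' Sums each model's pointwise WAIC over the included participants' trials;
#' models are ranked by WAIC (lower is better), ties broken toward fewer
#' free parameters (parsimony).
#'
#' @param fits Named list of [fit_rl()] objects, all fitted to the identical
#'   participant set with pointwise log-likelihoods saved.
#' @param include Optional character vector of participant ids to keep.
#' @return A data frame of class `model_comparison`, sorted best-first, with
#'   columns `model_id`, `n_params`, `elpd_waic`, `p_waic`, `waic`, `se`,
#'   `delta_waic`.
#' @export
compare_models <- function(fits, include = NULL) {
  idsets <- lapply(fits, `[[`, "participant_ids")
  if (length(unique(vapply(idsets, paste, "", collapse = "|"))) != 1L)
    stop("fits were not computed on the identical participant set")
  rows <- lapply(fits, function(f) {
    if (is.null(f$pointwise))
      stop("fit of ", f$spec$model_id, " has no saved pointwise log-likelihood")
    cols <- rep(f$participant_ids, f$T)  # participant index varies fastest
    keep <- if (is.null(include)) rep(TRUE, length(cols))
            else cols %in% include
    w <- compute_waic(f$pointwise[, keep, drop = FALSE])
    data.frame(model_id = f$spec$model_id, n_params = f$spec$n_free_params,
               elpd_waic = w$elpd_waic, p_waic = w$p_waic, waic = w$waic,
               se = w$se, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$waic, tab$n_params), ]
  tab$delta_waic <- tab$waic - tab$waic[1L]
  rownames(tab) <- NULL
  structure(tab, class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (WAIC, best first):\n")
  print.data.frame(transform(as.data.frame(x),
                             elpd_waic = round(elpd_waic, 1),
                             p_waic = round(p_waic, 1),
                             waic = round(waic, 1), se = round(se, 1),
                             delta_waic = round(delta_waic, 1)))
  invisible(x)
}
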