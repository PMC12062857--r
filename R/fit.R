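# --- data plumbing ----------------------------------------------------------

# Convert a tidy trials table (participant_id + schedule columns + chosen /
# outcome) into the N x T integer matrices the C++ likelihood consumes.
# All participants must have the same number of trials.
trial_matrices <- function(trials) {
  ids <- unique(trials$participant_id)
  Ts <- tapply(trials$trial_index, trials$participant_id, length)
  if (length(unique(Ts)) != 1L)
    stop("participants have unequal trial counts; trial alignment is required")
  T <- as.integer(Ts[[1L]])
  N <- length(ids)
  o <- order(match(trials$participant_id, ids), trials$trial_index)
  tr <- trials[o, ]
  mk <- function(x, mode = "integer")
    matrix(as.vector(x, mode = mode), nrow = N, ncol = T, byrow = TRUE)
  magA <- ifelse(is.na(tr$magnitude_A), 50, tr$magnitude_A)
  magB <- ifelse(is.na(tr$magnitude_B), 50, tr$magnitude_B)
  list(ids = ids, N = N, T = T,
       choice = mk(ifelse(tr$chosen == "A", 1L, 2L)),
       outcome = mk(as.integer(tr$outcome)),
       phase = mk(as.integer(tr$phase == "volatile")),
       magA = mk(magA, "numeric"), magB = mk(magB, "numeric"),
       has_mag = !anyNA(tr$magnitude_A))
}

# natural-scale free-parameter matrix (N x k, columns spec$params) ->
# canonical N x 5 matrix for the C++ layer
build_theta <- function(nat, params) {
  N <- nrow(nat)
  th <- matrix(rep(c(0.5, 1, 0.5, 0.5, 0.5), each = N), N, 5)
  colnames(th) <- .canonical_slots
  for (j in seq_along(params)) {
    nm <- params[j]
    if (nm == "alpha") {
      th[, "alpha_stable"] <- nat[, j]; th[, "alpha_volatile"] <- nat[, j]
    } else th[, nm] <- nat[, j]
  }
  th
}

ll_total_all <- function(spec, theta, d) {
  vb_ll_total_mat(.rule_code(spec), spec$has_bias, spec$dual_learning_rate,
                  spec$uses_magnitude, theta, d$choice, d$outcome, d$phase,
                  d$magA, d$magB)
}

# --- participant-level MAP fit ----------------------------------------------

#' Fit one participant by penalised maximum a posteriori estimation
#'
#' Optimises the transformed-scale posterior (trialwise choice log-likelihood
#' plus Normal prior) with multi-start BFGS; starts are seeded draws from the
#' prior. Models with no free parameters return a closed-form result. An
#' optional trial mask restricts the likelihood to a training subset (used by
#' K-fold cross-validation); all trials still drive the value dynamics, only
#' the masked trials' log-probabilities enter the objective.
#'
#' @param spec A [model_spec()].
#' @param choices Data frame with `chosen`/`outcome`, one row per trial.
#' @param schedule The participant's `task_schedule`.
#' @param priors A [prior_spec()].
#' @param include Optional logical vector (length = trials) marking trials
#'   whose log-probabilities enter the objective.
#' @param n_starts Number of seeded optimisation restarts.
#' @param seed Integer seed for the restarts.
#' @return An object of class `rlmap`: natural-scale `estimates`, transformed
#'   `mode`, `hessian` (of the negative log posterior), `log_posterior`,
#'   `loglik` (included trials), `converged`.
#' @export
fit_participant <- function(spec, choices, schedule, priors = prior_spec(),
                            include = NULL, n_starts = 5L, seed = 1L) {
  n <- nrow(choices)
  if (n < 1L) stop("at least one trial is required")
  if (is.null(include)) include <- rep(TRUE, n)
  k <- spec$n_free_params
  if (k == 0L) {
    ll <- sum(include) * log(0.5)
    return(structure(list(spec = spec, estimates = numeric(0),
                          mode = numeric(0), hessian = matrix(0, 0, 0),
                          log_posterior = ll, loglik = ll, converged = TRUE),
                     class = "rlmap"))
  }
  pn <- spec$params
  d <- .ll_data(choices, schedule)
  loc <- priors$location[pn]; sc <- priors$scale[pn]
  obj <- function(eta) {
    nat <- to_natural(eta, pn)
    names(nat) <- pn
    pw <- vb_ll_pointwise(.rule_code(spec), spec$has_bias,
                          spec$dual_learning_rate, spec$uses_magnitude,
                          canonical_par(spec, as.list(nat)),
                          d$choice, d$outcome, d$phase, d$magA, d$magB)
    -(sum(pw[include]) + sum(stats::dnorm(eta, loc, sc, log = TRUE)))
  }
  starts <- with_seed(seed, {
    s <- matrix(stats::rnorm(n_starts * k, loc, 0.5 * sc),
                n_starts, k, byrow = TRUE)
    s[1L, ] <- loc  # first start at the prior mode
    s
  })
  best <- NULL
  converged <- FALSE
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "BFGS", hessian = FALSE,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0L) converged <- TRUE
  }
  if (is.null(best))
    return(structure(list(spec = spec, estimates = rep(NA_real_, k),
                          mode = rep(NA_real_, k),
                          hessian = matrix(NA_real_, k, k),
                          log_posterior = NA_real_, loglik = NA_real_,
                          converged = FALSE), class = "rlmap"))
  H <- stats::optimHess(best$par, obj)
  nat <- to_natural(best$par, pn)
  names(nat) <- pn
  pw <- log_likelihood(spec, as.list(nat), choices, schedule)$pointwise
  structure(list(spec = spec, estimates = nat,
                 mode = stats::setNames(best$par, pn), hessian = H,
                 log_posterior = -best$value, loglik = sum(pw[include]),
                 converged = converged),
            class = "rlmap")
}

#' @export
print.rlmap <- function(x, ...) {
  cat(sprintf("<rlmap %s> %s; logLik %.2f%s\n", x$spec$model_id,
              if (length(x$estimates))
                paste(sprintf("%s=%.3f", names(x$estimates), x$estimates),
                      collapse = ", ")
              else "no free parameters",
              x$loglik, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# Draws from the Laplace approximation around a MAP fit, as a canonical
# S x 5 natural-scale matrix. Falls back to a ridge-regularised covariance
# when the Hessian is not positive definite.
laplace_draws <- function(fit, S = 200L, seed = 1L) {
  pn <- fit$spec$params
  k <- length(pn)
  if (k == 0L)
    return(matrix(rep(c(0.5, 1, 0.5, 0.5, 0.5), each = S), S, 5))
  H <- fit$hessian
  ch <- tryCatch(chol(solve(H)), error = function(e) NULL)
  if (is.null(ch)) {
    H2 <- H + diag(k) * (0.01 + max(0, -min(eigen(H)$values)))
    ch <- chol(solve(H2))
  }
  eta <- with_seed(seed,
    matrix(stats::rnorm(S * k), S, k) %*% ch +
      matrix(fit$mode, S, k, byrow = TRUE))
  nat <- eta
  for (j in seq_len(k)) nat[, j] <- to_natural(eta[, j], pn[j])
  build_theta(nat, pn)
}

# --- hierarchical Bayesian fit ----------------------------------------------

#' Fit a model hierarchically across participants
#'
#' Non-centered hierarchical model on the transformed scale: participant
#' parameters are `mu + sigma * z` with `z ~ Normal(0, 1)`, group means
#' `mu ~ Normal(location, scale)` and group SDs `sigma ~ half-Normal`.
#' Sampling is by Metropolis-within-Gibbs: a joint random-walk block update
#' of each participant's `z` (all participants proposed and accepted
#' independently in one vectorised step), then scalar random-walk updates of
#' each `mu` and `log sigma`, with proposal scales adapted during warmup
#' toward standard acceptance targets. Likelihoods are evaluated in C++.
#'
#' @param spec A [model_spec()].
#' @param trials Tidy behavioural table: `participant_id`, schedule columns
#'   (`trial_index`, `phase`, `magnitude_A`, `magnitude_B`, ...), `chosen`,
#'   `outcome`. All participants must have the same trial count.
#' @param priors A [prior_spec()].
#' @param sampler A [sampler_config()].
#' @param save_pointwise Keep the per-draw pointwise log-likelihood matrix
#'   (needed for WAIC).
#' @return An object of class `rlfit` with posterior draws of group means,
#'   group SDs and participant parameters (natural scale), the pointwise
#'   log-likelihood array, and split-R-hat / effective-sample-size
#'   diagnostics. Methods: `print`, `summary`, `coef` (posterior-mean
#'   participant parameters), `logLik`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_MT = 4, n_NMT = 4, random_responder_fraction = 0)
#' dat <- generate_cohort(cfg, followup = FALSE)
#' fit <- fit_rl(winning_spec(), dat$trials,
#'               sampler = sampler_config(chains = 2, warmup = 150, iter = 150))
#' summary(fit)
#' }
#' @export
fit_rl <- function(spec, trials, priors = prior_spec(),
                   sampler = sampler_config(), save_pointwise = TRUE) {
  d <- trial_matrices(trials)
  if (d$N < 2L) stop("hierarchical fitting needs at least 2 participants")
  if (isTRUE(spec$uses_magnitude) && !d$has_mag)
    stop("magnitude model fitted on trials without magnitudes")
  pn <- spec$params
  k <- length(pn)
  S <- sampler$iter; C <- sampler$chains
  if (k == 0L) {  # fit-free null model: closed-form posterior
    pw0 <- rep(log(0.5), d$N * d$T)
    pointwise <- if (save_pointwise)
      matrix(pw0, S * C, d$N * d$T, byrow = TRUE) else NULL
    return(structure(list(spec = spec, priors = priors, sampler = sampler,
                          participant_ids = d$ids, N = d$N, T = d$T, k = 0L,
                          param_names = character(0),
                          draws = list(), pointwise = pointwise,
                          diagnostics = list(rhat = numeric(0),
                                             ess = numeric(0),
                                             divergences = 0L),
                          accept = list()),
                     class = "rlfit"))
  }
  loc <- priors$location[pn]; sc <- priors$scale[pn]
  ss <- priors$sd_scale[pn]

  # canonical-slot mapping and transform codes for the C++ sampler
  slot_of <- function(nm) match(nm, .canonical_slots) - 1L
  slot1 <- integer(k); slot2 <- rep(-1L, k); trans <- integer(k)
  for (j in seq_len(k)) {
    nm <- pn[j]
    if (nm == "alpha") {
      slot1[j] <- slot_of("alpha_stable"); slot2[j] <- slot_of("alpha_volatile")
    } else slot1[j] <- slot_of(nm)
    trans[j] <- as.integer(nm == "tau")  # 1 = log, 0 = logit
  }

  mu_draws <- array(NA_real_, c(S, C, k))
  sig_draws <- array(NA_real_, c(S, C, k))
  th_draws <- array(NA_real_, c(S, C, d$N, k))
  pointwise <- if (save_pointwise)
    matrix(NA_real_, S * C, d$N * d$T) else NULL
  acc_block <- numeric(C); acc_scalar <- numeric(C)

  for (ch in seq_len(C)) {
    set.seed(sampler$seed + ch)
    res <- vb_sample_chain(.rule_code(spec), spec$has_bias,
                           spec$dual_learning_rate, spec$uses_magnitude,
                           slot1, slot2, trans,
                           unname(loc), unname(sc), unname(ss),
                           d$choice, d$outcome, d$phase, d$magA, d$magB,
                           sampler$warmup, S,
                           sampler$target_accept_block,
                           sampler$target_accept_scalar, save_pointwise)
    mu_draws[, ch, ] <- res$mu
    sig_draws[, ch, ] <- res$sigma
    th_draws[, ch, , ] <- array(res$theta, c(S, d$N, k))
    if (save_pointwise)
      pointwise[(ch - 1L) * S + seq_len(S), ] <- res$pointwise
    acc_block[ch] <- res$accept_block
    acc_scalar[ch] <- res$accept_scalar
  }
  diag_names <- c(paste0("mu_", pn), paste0("sigma_", pn))
  chains_mat <- function(arr, j) arr[, , j, drop = FALSE][, , 1L]
  rhat <- ess <- stats::setNames(numeric(2L * k), diag_names)
  for (j in seq_len(k)) {
    rhat[j] <- split_rhat(chains_mat(mu_draws, j))
    rhat[k + j] <- split_rhat(chains_mat(sig_draws, j))
    ess[j] <- ess_basic(chains_mat(mu_draws, j))
    ess[k + j] <- ess_basic(chains_mat(sig_draws, j))
  }
  structure(list(spec = spec, priors = priors, sampler = sampler,
                 participant_ids = d$ids, N = d$N, T = d$T, k = k,
                 param_names = pn,
                 draws = list(mu = mu_draws, sigma = sig_draws,
                              theta = th_draws),
                 pointwise = pointwise,
                 diagnostics = list(rhat = rhat, ess = ess,
                                    divergences = 0L,
                                    converged = all(rhat < 1.05,
                                                    na.rm = TRUE)),
                 accept = list(block = acc_block, scalar = acc_scalar)),
            class = "rlfit")
}

# split-R-hat on an iterations x chains matrix
split_rhat <- function(x) {
  S <- nrow(x); C <- ncol(x)
  half <- floor(S / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(S - half + 1):S, , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  means <- colMeans(sub)
  B <- n * stats::var(means)
  W <- mean(apply(sub, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude bulk effective sample size from pooled autocorrelations
ess_basic <- function(x) {
  S <- nrow(x); C <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  v <- mean(apply(x, 2, stats::var))
  if (v == 0) return(S * C)
  rho_sum <- 0
  for (lag in seq_len(min(S - 2L, 100L))) {
    r <- mean(vapply(seq_len(C), function(c)
      mean(xc[1:(S - lag), c] * xc[(1 + lag):S, c]), 0)) / v
    if (r < 0.05) break
    rho_sum <- rho_sum + r
  }
  S * C / (1 + 2 * rho_sum)
}

# group-level posterior summary on the natural scale
group_posterior <- function(fit) {
  pn <- fit$param_names
  out <- lapply(seq_along(pn), function(j) {
    mu_t <- as.vector(fit$draws$mu[, , j])
    mu_nat <- to_natural(mu_t, pn[j])
    c(mean = mean(mu_nat), sd = stats::sd(mu_nat),
      q2.5 = unname(stats::quantile(mu_nat, 0.025)),
      q97.5 = unname(stats::quantile(mu_nat, 0.975)))
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- pn
  tab
}

#' @export
print.rlfit <- function(x, ...) {
  cat(sprintf("<rlfit %s> %d participants x %d trials; %d chains x %d draws\n",
              x$spec$model_id, x$N, x$T, x$sampler$chains, x$sampler$iter))
  if (x$k > 0) {
    cat(sprintf("max split-R-hat %.3f; min ESS %.0f\n",
                max(x$diagnostics$rhat), min(x$diagnostics$ess)))
    if (!x$diagnostics$converged)
      cat("WARNING: R-hat > 1.05 on at least one group-level parameter\n")
  } else cat("null model: no free parameters\n")
  invisible(x)
}

#' @export
summary.rlfit <- function(object, ...) {
  if (object$k == 0L) {
    cat("Null model: every choice has probability 0.5; nothing to estimate.\n")
    return(invisible(NULL))
  }
  tab <- cbind(group_posterior(object),
               rhat = object$diagnostics$rhat[seq_len(object$k)],
               ess = object$diagnostics$ess[seq_len(object$k)])
  cat(sprintf("Hierarchical fit of %s (%d participants, %d trials each)\n",
              object$spec$model_id, object$N, object$T))
  cat("Group-level posterior (natural scale, means mapped from transformed scale):\n")
  print(round(tab, 3))
  invisible(tab)
}

#' @export
coef.rlfit <- function(object, ...) {
  if (object$k == 0L)
    return(matrix(numeric(0), object$N, 0,
                  dimnames = list(object$participant_ids, NULL)))
  est <- apply(object$draws$theta, c(3, 4), mean)
  dimnames(est) <- list(object$participant_ids, object$param_names)
  est
}

#' @export
logLik.rlfit <- function(object, ...) {
  if (is.null(object$pointwise))
    stop("fit was run with save_pointwise = FALSE")
  ll <- mean(rowSums(object$pointwise))
  structure(ll, df = object$k * 2 + object$N * object$k, class = "logLik")
}
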