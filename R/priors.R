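#' Soft prior constraints on model parameters
#'
#' Priors act on transformed scales chosen so every parameter is
#' unconstrained: logit for the unit-interval parameters (bias, learning
#' rates, win-stay probability) and log for the temperature. Participant
#' parameters are Normal around a group mean on the transformed scale; the
#' group SD has a half-Normal prior. Defaults are weakly informative:
#' Normal(0, 1.5) on logit-scale parameters, Normal(-1, 1) on log
#' temperature, half-Normal(1) group SDs.
#'
#' @param location,scale Named numeric vectors (transformed scale) overriding
#'   the default group-mean prior location/scale per parameter.
#' @param sd_scale Named numeric vector overriding the half-Normal scale of
#'   the group SD per parameter.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(location = numeric(), scale = numeric(),
                       sd_scale = numeric()) {
  loc <- c(b = 0, tau = -1, alpha = 0, alpha_stable = 0, alpha_volatile = 0,
           p_stay = 0)
  sc <- c(b = 1.5, tau = 1, alpha = 1.5, alpha_stable = 1.5,
          alpha_volatile = 1.5, p_stay = 1.5)
  ss <- c(b = 1, tau = 1, alpha = 1, alpha_stable = 1, alpha_volatile = 1,
          p_stay = 1)
  loc[names(location)] <- location
  sc[names(scale)] <- scale
  ss[names(sd_scale)] <- sd_scale
  if (any(sc <= 0) || any(ss <= 0)) stop("prior scales must be > 0")
  structure(list(location = loc, scale = sc, sd_scale = ss),
            class = "prior_spec")
}

# transformed <-> natural scale maps, by parameter name
to_natural <- function(x, names) {
  out <- x
  is_tau <- names == "tau"
  out[is_tau] <- exp(x[is_tau])
  out[!is_tau] <- stats::plogis(x[!is_tau])
  out
}

to_transformed <- function(x, names) {
  out <- x
  is_tau <- names == "tau"
  out[is_tau] <- log(x[is_tau])
  out[!is_tau] <- stats::qlogis(x[!is_tau])
  out
}

#' Sampler settings for the hierarchical fit
#'
#' @param chains Number of chains (>= 2 for split-R-hat diagnostics).
#' @param warmup Adaptation sweeps discarded per chain.
#' @param iter Kept sweeps per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param target_accept_block,target_accept_scalar Metropolis acceptance
#'   targets for the per-participant block update and the scalar group-level
#'   updates.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 2L, warmup = 500L, iter = 500L,
                           seed = 1L, target_accept_block = 0.25,
                           target_accept_scalar = 0.44) {
  stopifnot(chains >= 1L, warmup >= 1L, iter >= 1L)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 target_accept_block = target_accept_block,
                 target_accept_scalar = target_accept_scalar),
            class = "sampler_config")
}
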