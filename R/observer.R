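#' @title Ideal-observer models of audiovisual localization
#'
#' @description
#' Seven observer models for categorical audiovisual localization. On every
#' trial the true stimulus azimuths (s_A, s_V) give rise to noisy internal
#' sensations x_A ~ N(s_A + delta_A, sigma_A), x_V ~ N(s_V + delta_V,
#' sigma_V). The Bayesian causal-inference (CI) observers compute the
#' posterior probability that the two cues share a common cause (given a
#' causal prior `p_common` and a Gaussian location prior N(mu_p, sigma_p)),
#' form the optimal fused estimate under a common cause and the prior-shrunk
#' segregated estimates under independent causes, and combine the two via a
#' decision strategy: model averaging ("CI-MA"), probability matching
#' ("CI-PM"), or model selection ("CI-MS"). The baseline observers fix the
#' causal structure: forced fusion ("FF") and segregation ("SG") keep the
#' location prior, while "FFnp" (reliability-weighted averaging) and "SGnp"
#' (identity on the sensations) drop all priors.
#'
#' @name observer_models
NULL

OBSERVER_FAMILIES <- c("CI-MA", "CI-PM", "CI-MS", "FF", "SG", "FFnp", "SGnp")

#' Gaussian likelihood parameters
#'
#' Per-modality bias (delta, degrees) and noise SD (sigma, degrees > 0) of the
#' internal sensory representations.
#'
#' @param delta_A,sigma_A Auditory likelihood bias and SD.
#' @param delta_V,sigma_V Visual likelihood bias and SD.
#' @return A `likelihood_params` list.
#' @export
likelihood_params <- function(delta_A = 0, sigma_A = 6, delta_V = 0, sigma_V = 2) {
  if (sigma_A <= 0 || sigma_V <= 0) stop("sigmas must be > 0", call. = FALSE)
  structure(list(delta_A = delta_A, sigma_A = sigma_A,
                 delta_V = delta_V, sigma_V = sigma_V),
            class = "likelihood_params")
}

#' Prior parameters
#'
#' Gaussian location prior N(mu_p, sigma_p) shared by both modalities, and the
#' causal prior `p_common` = p(C = 1), the prior probability that the two cues
#' share a common cause.
#'
#' @param mu_p Prior mean, degrees.
#' @param sigma_p Prior SD, degrees (> 0).
#' @param p_common Causal prior in [0, 1].
#' @return A `prior_params` list.
#' @export
prior_params <- function(mu_p = 0, sigma_p = 25, p_common = 0.5) {
  if (sigma_p <= 0) stop("sigma_p must be > 0", call. = FALSE)
  if (p_common < 0 || p_common > 1) stop("p_common must be in [0, 1]", call. = FALSE)
  structure(list(mu_p = mu_p, sigma_p = sigma_p, p_common = p_common),
            class = "prior_params")
}

#' Observer specification
#'
#' Bundles a model family with its likelihood and (for prior-carrying
#' families) prior parameters. `FF` implies an effective `p_common` of 1 and
#' `SG` of 0; `FFnp`/`SGnp` carry no prior at all.
#'
#' @param family One of `"CI-MA"`, `"CI-PM"`, `"CI-MS"`, `"FF"`, `"SG"`,
#'   `"FFnp"`, `"SGnp"`.
#' @param likelihood A [likelihood_params()].
#' @param prior A [prior_params()], required except for `FFnp`/`SGnp`.
#' @return An `observer_spec` list.
#' @export
observer_spec <- function(family, likelihood = likelihood_params(), prior = NULL) {
  family <- match.arg(family, OBSERVER_FAMILIES)
  if (family %in% c("FFnp", "SGnp")) {
    if (!is.null(prior)) stop(family, " carries no prior parameters", call. = FALSE)
  } else {
    if (is.null(prior)) stop(family, " requires prior parameters", call. = FALSE)
    if (family == "FF") prior$p_common <- 1
    if (family == "SG") prior$p_common <- 0
  }
  structure(list(family = family, likelihood = likelihood, prior = prior),
            class = "observer_spec")
}

#' Joint likelihood of the sensations under a common cause
#'
#' Closed form of p(x_A, x_V | C = 1) obtained by integrating the product of
#' the two unimodal Gaussian likelihoods against the Gaussian location prior
#' over the single shared source location.
#'
#' @param x_A,x_V Internal sensations, degrees (vectorized).
#' @param lik A [likelihood_params()] (only the sigmas are used; biases enter
#'   at the sampling stage).
#' @param prior A [prior_params()].
#' @return Density value(s), strictly positive.
#' @export
joint_likelihood_common <- function(x_A, x_V, lik, prior) {
  sA2 <- lik$sigma_A^2; sV2 <- lik$sigma_V^2; sP2 <- prior$sigma_p^2
  denom <- sA2 * sV2 + sA2 * sP2 + sV2 * sP2
  q <- ((x_V - x_A)^2 * sP2 +
          (x_A - prior$mu_p)^2 * sV2 +
          (x_V - prior$mu_p)^2 * sA2) / denom
  exp(-q / 2) / (2 * pi * sqrt(denom))
}

#' Joint likelihood of the sensations under independent causes
#'
#' Closed form of p(x_A, x_V | C = 2): the product of the two unimodal
#' sensation marginals, each a Gaussian with variance sigma_m^2 + sigma_p^2
#' centered on the prior mean.
#'
#' @inheritParams joint_likelihood_common
#' @return Density value(s), strictly positive.
#' @export
joint_likelihood_independent <- function(x_A, x_V, lik, prior) {
  vA <- lik$sigma_A^2 + prior$sigma_p^2
  vV <- lik$sigma_V^2 + prior$sigma_p^2
  dnorm(x_A, prior$mu_p, sqrt(vA)) * dnorm(x_V, prior$mu_p, sqrt(vV))
}

#' Posterior probability of a common cause
#'
#' Bayes' rule over the two causal structures:
#' p(C = 1 | x_A, x_V) = L1 Pc / (L1 Pc + L2 (1 - Pc)) with L1, L2 the joint
#' likelihoods under common and independent causes.
#'
#' @inheritParams joint_likelihood_common
#' @return Probabilities in [0, 1] (vectorized).
#' @export
posterior_common_cause <- function(x_A, x_V, lik, prior) {
  pc <- prior$p_common
  if (pc == 1) return(rep(1, length(x_A)))
  if (pc == 0) return(rep(0, length(x_A)))
  l1 <- joint_likelihood_common(x_A, x_V, lik, prior)
  l2 <- joint_likelihood_independent(x_A, x_V, lik, prior)
  l1 * pc / (l1 * pc + l2 * (1 - pc))
}

#' Location estimates under each causal structure
#'
#' With a location prior, the fused estimate (common cause) is the
#' precision-weighted combination of x_A, x_V and the prior mean, and each
#' segregated estimate shrinks its own sensation toward the prior mean.
#' Without a prior (`use_prior = FALSE`) the fused estimate reduces to
#' reliability-weighted averaging of the two sensations and the segregated
#' estimates are the sensations themselves.
#'
#' @inheritParams joint_likelihood_common
#' @param prior A [prior_params()] or `NULL`; must be present iff `use_prior`.
#' @param use_prior Logical.
#' @return A list with numeric vectors `fused`, `seg_A`, `seg_V`.
#' @export
estimate_locations <- function(x_A, x_V, lik, prior = NULL, use_prior = !is.null(prior)) {
  if (use_prior && is.null(prior)) {
    stop("`prior` must be supplied when `use_prior` is TRUE", call. = FALSE)
  }
  wA <- 1 / lik$sigma_A^2
  wV <- 1 / lik$sigma_V^2
  if (use_prior) {
    wP <- 1 / prior$sigma_p^2
    mu <- prior$mu_p
    list(
      fused = (x_A * wA + x_V * wV + mu * wP) / (wA + wV + wP),
      seg_A = (x_A * wA + mu * wP) / (wA + wP),
      seg_V = (x_V * wV + mu * wP) / (wV + wP)
    )
  } else {
    list(
      fused = (x_A * wA + x_V * wV) / (wA + wV),
      seg_A = x_A,
      seg_V = x_V
    )
  }
}

#' Apply a causal-inference decision strategy
#'
#' Combines the fused and segregated estimates given the posterior
#' probability of a common cause. `"MA"` returns posterior-weighted averages;
#' `"PM"` picks the fused estimates iff the posterior exceeds a uniform draw
#' `xi` (one shared draw per trial, so the A and V responses commit to the
#' same causal structure); `"MS"` picks the fused estimates iff the posterior
#' exceeds 0.5 (a posterior of exactly 0.5 segregates).
#'
#' @param strategy `"MA"`, `"PM"` or `"MS"`.
#' @param est A list with vectors `fused`, `seg_A`, `seg_V` as returned by
#'   [estimate_locations()].
#' @param posterior_c1 Posterior probability of a common cause (vectorized).
#' @param xi Uniform draws in [0, 1], required for `"PM"`.
#' @return A list with numeric vectors `s_hat_A`, `s_hat_V`.
#' @export
decide <- function(strategy, est, posterior_c1, xi = NULL) {
  strategy <- match.arg(strategy, c("MA", "PM", "MS"))
  stopifnot(all(posterior_c1 >= 0 & posterior_c1 <= 1))
  if (strategy == "MA") {
    return(list(
      s_hat_A = posterior_c1 * est$fused + (1 - posterior_c1) * est$seg_A,
      s_hat_V = posterior_c1 * est$fused + (1 - posterior_c1) * est$seg_V
    ))
  }
  threshold <- if (strategy == "PM") {
    if (is.null(xi)) stop("PM requires uniform draws `xi`", call. = FALSE)
    xi
  } else {
    0.5
  }
  common <- as.numeric(posterior_c1 > threshold)
  list(
    s_hat_A = est$seg_A + common * (est$fused - est$seg_A),
    s_hat_V = est$seg_V + common * (est$fused - est$seg_V)
  )
}

# Continuous A/V responses of an observer for given sensations.
# x_A, x_V, xi are equal-length vectors; returns list(s_hat_A, s_hat_V).
observer_responses <- function(family, lik, prior, x_A, x_V, xi) {
  switch(family,
    "CI-MA" = ,
    "CI-PM" = ,
    "CI-MS" = {
      est <- estimate_locations(x_A, x_V, lik, prior)
      post <- posterior_common_cause(x_A, x_V, lik, prior)
      decide(sub("CI-", "", family), est, post, xi = xi)
    },
    "FF" = {
      est <- estimate_locations(x_A, x_V, lik, prior)
      list(s_hat_A = est$fused, s_hat_V = est$fused)
    },
    "SG" = {
      est <- estimate_locations(x_A, x_V, lik, prior)
      list(s_hat_A = est$seg_A, s_hat_V = est$seg_V)
    },
    "FFnp" = {
      est <- estimate_locations(x_A, x_V, lik, prior = NULL, use_prior = FALSE)
      list(s_hat_A = est$fused, s_hat_V = est$fused)
    },
    "SGnp" = list(s_hat_A = x_A, s_hat_V = x_V),
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Monte-Carlo predicted response distributions for an AV stimulus pair
#'
#' Simulates `n_sim` trials of the observer: sensations are drawn from the
#' biased Gaussian likelihoods, pushed through the family's estimation and
#' decision chain, and binned into the 12 button positions. The result is the
#' model-predicted response distribution — two normalized 12-bin histograms,
#' one for the A and one for the V response.
#'
#' @param spec An [observer_spec()].
#' @param s_A,s_V True stimulus azimuths, degrees.
#' @param n_sim Number of simulated trials (default 10,000).
#' @param app An [apparatus()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `pair` (c(s_A, s_V)), probability vectors `p_A` and
#'   `p_V` (length `button_count`, summing to 1), and `n_sim`.
#' @export
simulate_av_responses <- function(spec, s_A, s_V, n_sim = 10000,
                                  app = apparatus(), seed = 1) {
  stopifnot(n_sim >= 1)
  draws <- with_seed(seed, list(
    z_A = rnorm(n_sim), z_V = rnorm(n_sim), xi = runif(n_sim)
  ))
  lik <- spec$likelihood
  x_A <- s_A + lik$delta_A + lik$sigma_A * draws$z_A
  x_V <- s_V + lik$delta_V + lik$sigma_V * draws$z_V
  resp <- observer_responses(spec$family, lik, spec$prior, x_A, x_V, draws$xi)
  list(
    pair = c(s_A = s_A, s_V = s_V),
    p_A = tabulate(bin_response(resp$s_hat_A, app), app$button_count) / n_sim,
    p_V = tabulate(bin_response(resp$s_hat_V, app), app$button_count) / n_sim,
    n_sim = as.integer(n_sim)
  )
}
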