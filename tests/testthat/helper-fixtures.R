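# Shared fixtures and independent numerical oracles.

# Trapezoid quadrature on a uniform grid (independent of the closed forms
# under test).
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2) * (x[2] - x[1])

# Quadrature oracle for the common-cause joint likelihood: integrate
# p(x_A | s) p(x_V | s) p(s) over the shared source location s.
quad_likelihood_common <- function(x_A, x_V, sigma_A, sigma_V, mu_p, sigma_p,
                                   lim = 200, step = 0.01) {
  s <- seq(-lim, lim, by = step)
  trapz(s, dnorm(x_A, s, sigma_A) * dnorm(x_V, s, sigma_V) * dnorm(s, mu_p, sigma_p))
}

# Quadrature oracle for the independent-causes joint likelihood: the double
# integral over (s_A, s_V) factorizes into two marginal integrals.
quad_likelihood_independent <- function(x_A, x_V, sigma_A, sigma_V, mu_p, sigma_p,
                                        lim = 200, step = 0.01) {
  s <- seq(-lim, lim, by = step)
  trapz(s, dnorm(x_A, s, sigma_A) * dnorm(s, mu_p, sigma_p)) *
    trapz(s, dnorm(x_V, s, sigma_V) * dnorm(s, mu_p, sigma_p))
}

# Block 1 AV trials with responses generated from a known observer family
# (true likelihood parameters known by construction).
make_av_data <- function(family, seed, lik = likelihood_params(0, 6, 0, 2),
                         prior = prior_params(0, 25, 0.5),
                         app = apparatus()) {
  if (family %in% c("FFnp", "SGnp")) prior <- NULL
  prof <- participant_profile(
    family = family, block1_likelihood = lik,
    block1_prior = prior, seed = seed)
  ds <- simulate_participant(prof, app)
  ds$trials[ds$trials$block == 1 & ds$trials$modality == "AV", ]
}

# Deterministic participant trial table: every response lands on the button
# aligned with its stimulus (plus an optional per-call offset in buttons).
aligned_trials <- function(seed = 1, offset_A = 0L, offset_V = 0L,
                           app = apparatus()) {
  fill <- function(seq) {
    clamp <- function(b) pmin(pmax(b, 1L), app$button_count)
    a <- seq$modality %in% c("A", "AV")
    v <- seq$modality %in% c("V", "AV")
    seq$resp_A[a] <- clamp(bin_response(seq$s_A[a], app) + offset_A)
    seq$resp_V[v] <- clamp(bin_response(seq$s_V[v], app) + offset_V)
    seq
  }
  dplyr::bind_rows(fill(generate_block1(seed, app)),
                   fill(generate_block2(seed + 1, app)))
}
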