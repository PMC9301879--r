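#' @title Synthetic observer cohorts
#'
#' @description
#' Generates complete synthetic participants: seeded Block 1 / Block 2 trial
#' sequences from the design module, AV responses from a ground-truth
#' observer model, and unimodal responses as binned draws from the biased
#' Gaussian likelihood of the active block. Group archetypes (CC, DC, SC)
#' encode the minimal parameter structure that reproduces the qualitative
#' result pattern of the study design: higher visual noise in the cataract
#' groups, and Block 2 likelihood-bias shifts (delta_A rightward in every
#' group; additionally delta_V leftward in CC) as the model-side signature of
#' cumulative recalibration.
#'
#' The static observer models carry no trial history, so by themselves they
#' produce no immediate aftereffect. The generator therefore offers an
#' explicit single-trial recalibration term — an extension beyond the
#' observer models: each unimodal response mean is shifted by
#' `history_gain_m * d`, where `d` is the discrepancy of the nearest
#' preceding AV trial. The archetypes enable a modest auditory gain so that
#' cohorts exhibit the immediate aftereffect alongside the modeled effects.
#'
#' @name synthetic_cohorts
NULL

#' Ground-truth participant profile
#'
#' @param group Group label (`"CC"`, `"DC"`, `"SC"`, or any string).
#' @param family Generating observer family.
#' @param block1_likelihood,block2_likelihood [likelihood_params()] per
#'   block; Block 2 defaults to the Block 1 values.
#' @param block1_prior,block2_prior [prior_params()] per block (`NULL` for
#'   `FFnp`/`SGnp`); Block 2 defaults to Block 1.
#' @param response_order `"A-first"` or `"V-first"`; recorded metadata only,
#'   ignored by all analyses.
#' @param history_gain_A,history_gain_V Single-trial recalibration gains
#'   (fraction of the preceding AV discrepancy added to the unimodal response
#'   mean; 0 disables the term).
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @return A `participant_profile` list.
#' @export
participant_profile <- function(group = "SC", family = "CI-PM",
                                block1_likelihood = likelihood_params(),
                                block2_likelihood = block1_likelihood,
                                block1_prior = prior_params(),
                                block2_prior = block1_prior,
                                response_order = c("A-first", "V-first"),
                                history_gain_A = 0, history_gain_V = 0,
                                seed = 1) {
  family <- match.arg(family, OBSERVER_FAMILIES)
  if (family %in% c("FFnp", "SGnp")) {
    block1_prior <- NULL
    block2_prior <- NULL
  }
  structure(list(group = group, family = family,
                 block1_likelihood = block1_likelihood,
                 block2_likelihood = block2_likelihood,
                 block1_prior = block1_prior, block2_prior = block2_prior,
                 response_order = match.arg(response_order),
                 history_gain_A = history_gain_A,
                 history_gain_V = history_gain_V,
                 seed = as.integer(seed)),
            class = "participant_profile")
}

fill_block_responses <- function(seq, lik, prior, family, gains, app, seed) {
  with_seed(seed, {
    av <- which(seq$modality == "AV")
    x_A <- seq$s_A[av] + lik$delta_A + lik$sigma_A * rnorm(length(av))
    x_V <- seq$s_V[av] + lik$delta_V + lik$sigma_V * rnorm(length(av))
    resp <- observer_responses(family, lik, prior, x_A, x_V, runif(length(av)))
    seq$resp_A[av] <- bin_response(resp$s_hat_A, app)
    seq$resp_V[av] <- bin_response(resp$s_hat_V, app)

    pre <- preceding_av_discrepancy(seq)
    for (m in c("A", "V")) {
      ix <- which(seq$modality == m)
      s <- if (m == "A") seq$s_A[ix] else seq$s_V[ix]
      delta <- if (m == "A") lik$delta_A else lik$delta_V
      sigma <- if (m == "A") lik$sigma_A else lik$sigma_V
      gain <- if (m == "A") gains$A else gains$V
      shift <- gain * ifelse(is.na(pre[ix]), 0, pre[ix])
      r <- bin_response(s + delta + shift + sigma * rnorm(length(ix)), app)
      if (m == "A") seq$resp_A[ix] <- r else seq$resp_V[ix] <- r
    }
    seq
  })
}

#' Simulate one participant
#'
#' Generates both blocks' trial sequences from the profile seed and fills in
#' all responses: AV trials through the profile family's full
#' estimation-and-decision chain, unimodal trials as binned draws from
#' `Normal(s + delta_m + history, sigma_m)` with the active block's
#' likelihood parameters.
#'
#' @param profile A [participant_profile()].
#' @param app An [apparatus()].
#' @return A `participant_dataset`: list with `profile` and `trials` (tibble
#'   of all 480 trials, responses filled).
#' @export
simulate_participant <- function(profile, app = apparatus()) {
  stopifnot(inherits(profile, "participant_profile"))
  gains <- list(A = profile$history_gain_A, V = profile$history_gain_V)
  b1 <- generate_block1(derive_seed(profile$seed, "b1-seq"), app)
  b2 <- generate_block2(derive_seed(profile$seed, "b2-seq"), app)
  b1 <- fill_block_responses(b1, profile$block1_likelihood, profile$block1_prior,
                             profile$family, gains, app,
                             derive_seed(profile$seed, "b1-resp"))
  b2 <- fill_block_responses(b2, profile$block2_likelihood, profile$block2_prior,
                             profile$family, gains, app,
                             derive_seed(profile$seed, "b2-resp"))
  structure(list(profile = profile,
                 trials = dplyr::bind_rows(b1, b2)),
            class = "participant_dataset")
}

#' Default group archetypes
#'
#' Configuration (not ground truth) for the three groups. All share the
#' CI-PM family, auditory noise sigma_A = 6 deg, unbiased likelihoods and a
#' centered location prior (mu_p = 0, sigma_p = 25 deg, p_common = 0.5).
#' Visual noise rises from SC (2 deg) through DC (2.5) to CC (3.5). Block 2
#' shifts: delta_A +3 deg in SC and CC, +2 in DC; delta_V -2 deg in CC only.
#' A single-trial auditory recalibration gain of 0.08 is enabled in every
#' group. Every field can be overridden via `simulate_cohort()`.
#'
#' @return Named list of archetype parameter lists.
#' @export
default_archetypes <- function() {
  base <- list(family = "CI-PM", sigma_A = 6, sigma_V = 2,
               delta_A = 0, delta_V = 0,
               mu_p = 0, sigma_p = 25, p_common = 0.5,
               block2_delta_A_shift = 3, block2_delta_V_shift = 0,
               history_gain_A = 0.08, history_gain_V = 0,
               jitter_rel = 0.15)
  list(
    CC = utils::modifyList(base, list(sigma_V = 3.5, block2_delta_V_shift = -2)),
    DC = utils::modifyList(base, list(sigma_V = 2.5, block2_delta_A_shift = 2)),
    SC = base
  )
}

jitter_pos <- function(x, rel, floor = 1e-3) pmax(x * (1 + rel * rnorm(length(x))), floor)

profile_from_archetype <- function(group, arch, response_order, seed) {
  p <- with_seed(derive_seed(seed, "jitter"), {
    list(
      sigma_A = jitter_pos(arch$sigma_A, arch$jitter_rel, 0.5),
      sigma_V = jitter_pos(arch$sigma_V, arch$jitter_rel, 0.5),
      sigma_p = jitter_pos(arch$sigma_p, arch$jitter_rel, 2),
      p_common = min(max(arch$p_common * (1 + arch$jitter_rel * rnorm(1)), 0.02), 0.98),
      dA_shift = arch$block2_delta_A_shift * (1 + arch$jitter_rel * rnorm(1)),
      dV_shift = arch$block2_delta_V_shift * (1 + arch$jitter_rel * rnorm(1))
    )
  })
  lik1 <- likelihood_params(arch$delta_A, p$sigma_A, arch$delta_V, p$sigma_V)
  lik2 <- likelihood_params(arch$delta_A + p$dA_shift, p$sigma_A,
                            arch$delta_V + p$dV_shift, p$sigma_V)
  has_prior <- !arch$family %in% c("FFnp", "SGnp")
  pri <- if (has_prior) prior_params(arch$mu_p, p$sigma_p, p$p_common) else NULL
  participant_profile(
    group = group, family = arch$family,
    block1_likelihood = lik1, block2_likelihood = lik2,
    block1_prior = pri, block2_prior = pri,
    response_order = response_order,
    history_gain_A = arch$history_gain_A,
    history_gain_V = arch$history_gain_V,
    seed = seed
  )
}

#' Simulate a cohort of synthetic participants
#'
#' Draws per-participant parameters by jittering the group archetypes
#' (relative Gaussian spread `jitter_rel`), counterbalances the response
#' order within group, and simulates each participant from a derived seed.
#'
#' @param n_per_group Named integer vector of group sizes; the default
#'   mirrors the study's 11 CC / 10 DC / 10 SC.
#' @param archetype_overrides Named list of per-group overrides merged into
#'   [default_archetypes()] (e.g. `list(CC = list(p_common = 0.8))`).
#' @param seed Integer master seed.
#' @param app An [apparatus()].
#' @return A `cohort`: list with `participants` (list of
#'   `participant_dataset`) and `metadata` (tibble of the realized
#'   per-participant parameters).
#' @export
simulate_cohort <- function(n_per_group = c(CC = 11, DC = 10, SC = 10),
                            archetype_overrides = list(), seed = 1,
                            app = apparatus()) {
  stopifnot(all(n_per_group >= 1), !is.null(names(n_per_group)))
  arches <- default_archetypes()
  for (g in names(archetype_overrides)) {
    arches[[g]] <- utils::modifyList(arches[[g]] %||% default_archetypes()$SC,
                                     archetype_overrides[[g]])
  }
  participants <- list()
  meta <- list()
  for (g in names(n_per_group)) {
    arch <- arches[[g]]
    if (is.null(arch)) stop("no archetype for group ", g, call. = FALSE)
    for (i in seq_len(n_per_group[[g]])) {
      pid <- sprintf("%s%02d", g, i)
      order <- if (i %% 2 == 1) "A-first" else "V-first"
      prof <- profile_from_archetype(g, arch, order, derive_seed(seed, g, i))
      ds <- simulate_participant(prof, app)
      participants[[pid]] <- ds
      meta[[pid]] <- tibble::tibble(
        participant = pid, group = g, family = prof$family,
        sigma_A = prof$block1_likelihood$sigma_A,
        sigma_V = prof$block1_likelihood$sigma_V,
        delta_A_b2 = prof$block2_likelihood$delta_A,
        delta_V_b2 = prof$block2_likelihood$delta_V,
        sigma_p = prof$block1_prior$sigma_p %||% NA_real_,
        p_common = prof$block1_prior$p_common %||% NA_real_,
        response_order = prof$response_order, seed = prof$seed)
    }
  }
  structure(list(participants = participants,
                 metadata = dplyr::bind_rows(meta)),
            class = "cohort")
}

#' Tidy trial table of a cohort
#'
#' One row per trial across all participants, suitable for serialization as
#' delimiter-separated text and for re-import via [read_trials()].
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @return Tibble with participant, group, response_order and the trial
#'   columns.
#' @export
cohort_trials <- function(cohort) {
  dplyr::bind_rows(lapply(names(cohort$participants), function(pid) {
    ds <- cohort$participants[[pid]]
    dplyr::mutate(ds$trials, participant = pid, group = ds$profile$group,
                  response_order = ds$profile$response_order, .before = 1)
  }))
}
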