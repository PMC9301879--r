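#' @title Three-step maximum-likelihood fitting and BIC model comparison
#'
#' @description
#' Observer models are fitted to one participant's data in three steps.
#' Step 1 estimates the unimodal likelihood bias and SD (delta_m, sigma_m) per
#' modality and block from the unimodal trials by maximum likelihood on a
#' discretized Gaussian (bin probabilities over the button intervals).
#' Step 2 fits the prior parameters of every model family to the Block 1 AV
#' trials by maximizing the multinomial log-likelihood of the observed
#' per-pair response histograms under Monte-Carlo predicted histograms, using
#' a uniform grid search followed by bounded quasi-Newton (L-BFGS-B)
#' refinement, and compares families by BIC. Step 3 refits the prior
#' parameters of the per-participant best family on the Block 2 AV trials
#' with the Block 2 unimodal parameters, without further model comparison.
#'
#' @name fitting
NULL

#' Fitting configuration
#'
#' @param n_sim Monte-Carlo trials per stimulus pair per objective evaluation.
#' @param grid_points Grid values per free prior parameter (endpoints
#'   included); the default 11 divides each range into 10 even portions.
#' @param bounds Named list of `c(min, max)` for `mu_p`, `sigma_p`,
#'   `p_common` (degrees, degrees, probability).
#' @param prob_floor Lower floor applied to predicted bin probabilities inside
#'   the log; defaults to `1 / (2 * n_sim)` so Monte-Carlo zeros never yield
#'   `-Inf`. Applied without renormalization.
#' @param seed Simulation seed. One fixed set of draws is reused for every
#'   parameter evaluation within a fit (common random numbers), which makes
#'   the Monte-Carlo objective deterministic in the parameters.
#' @param maxit Iteration cap for the L-BFGS-B refinement.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_sim = 10000, grid_points = 11,
                       bounds = list(mu_p = c(-20, 20), sigma_p = c(1, 60),
                                     p_common = c(0, 1)),
                       prob_floor = 1 / (2 * n_sim), seed = 1, maxit = 100) {
  stopifnot(n_sim >= 1, grid_points >= 2, prob_floor > 0, prob_floor < 1,
            all(vapply(bounds, function(b) b[1] < b[2], logical(1))))
  structure(list(n_sim = as.integer(n_sim), grid_points = as.integer(grid_points),
                 bounds = bounds, prob_floor = prob_floor,
                 seed = as.integer(seed), maxit = maxit),
            class = "fit_config")
}

#' Reduced-cost preset for desk-scale runs
#'
#' Smaller simulation count and grid than the publication-grade defaults;
#' suitable for smoke tests and recovery experiments, not for final fits.
#'
#' @param ... Overrides passed to [fit_config()].
#' @export
fit_config_test <- function(...) {
  args <- utils::modifyList(list(n_sim = 2000, grid_points = 5, maxit = 20),
                            list(...))
  do.call(fit_config, args)
}

#' Step 1: discretized-Gaussian MLE on unimodal trials
#'
#' Fits the bias `delta` and SD `sigma` of one modality's likelihood to that
#' modality's unimodal trials of one block. For a trial with stimulus `s` and
#' response button `b`, the likelihood contribution is the probability mass
#' of `Normal(s + delta, sigma)` on button b's interval (the outer buttons
#' integrate to +-Inf); errors are pooled across the four stimulus locations.
#' Maximization uses a dense grid followed by L-BFGS-B.
#'
#' @param trials Tibble of unimodal trials of a single modality, with the
#'   stimulus column (`s_A` or `s_V`) and matching response column filled in.
#' @param modality `"A"` or `"V"`.
#' @param app An [apparatus()].
#' @param bounds List with `delta = c(min, max)`, `sigma = c(min, max)`.
#' @return List with `delta`, `sigma` (degrees), `log_lik`, `convergence`
#'   (0 = converged) and `degenerate` (TRUE when all responses share one
#'   error, in which case `sigma` sits at its lower bound).
#' @export
fit_unimodal <- function(trials, modality = c("A", "V"), app = apparatus(),
                         bounds = list(delta = c(-30, 30), sigma = c(0.25, 40))) {
  modality <- match.arg(modality)
  s <- if (modality == "A") trials$s_A else trials$s_V
  b <- if (modality == "A") trials$resp_A else trials$resp_V
  keep <- !is.na(s) & !is.na(b)
  s <- s[keep]; b <- as.integer(b[keep])
  if (length(s) < 2) stop("need at least 2 unimodal responses", call. = FALSE)

  sp <- app$button_spacing
  centers <- button_center(b, app)
  lo <- ifelse(b == 1L, -Inf, centers - sp / 2)
  hi <- ifelse(b == app$button_count, Inf, centers + sp / 2)

  err <- centers - s
  if (length(unique(err)) == 1L) {
    return(list(delta = err[1], sigma = bounds$sigma[1], log_lik = NA_real_,
                convergence = 0L, degenerate = TRUE))
  }

  nll <- function(par) {
    mu <- s + par[1]
    p <- pnorm(hi, mu, par[2]) - pnorm(lo, mu, par[2])
    -sum(log(pmax(p, 1e-300)))
  }
  grid <- expand.grid(
    delta = seq(bounds$delta[1] / 1.5, bounds$delta[2] / 1.5, length.out = 41),
    sigma = exp(seq(log(max(bounds$sigma[1], 0.3)), log(bounds$sigma[2] / 2),
                    length.out = 25))
  )
  vals <- apply(grid, 1, nll)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, nll, method = "L-BFGS-B",
               lower = c(bounds$delta[1], bounds$sigma[1]),
               upper = c(bounds$delta[2], bounds$sigma[2]))
  if (opt$value > min(vals)) {  # keep the grid optimum if refinement failed
    opt <- list(par = start, value = min(vals), convergence = 52L)
  }
  list(delta = opt$par[1], sigma = opt$par[2], log_lik = -opt$value,
       convergence = opt$convergence, degenerate = FALSE)
}

#' Multinomial log-likelihood of a response histogram
#'
#' `sum_i n_i * log(max(p_i, prob_floor))`; the multinomial coefficient is a
#' constant across models and parameter sets and is dropped.
#'
#' @param counts Nonnegative integer vector of observed counts per button.
#' @param predicted Predicted bin probabilities (summing to 1 before
#'   flooring).
#' @param prob_floor Floor applied inside the log.
#' @return Scalar log-likelihood (finite for any `prob_floor > 0`).
#' @export
multinomial_loglik <- function(counts, predicted, prob_floor = 5e-5) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  sum(counts * log(pmax(predicted, prob_floor)))
}

#' Uniform grid of starting parameter vectors
#'
#' Full Cartesian grid over the free parameters, each dimension evenly spaced
#' with endpoints included. With 11 points per parameter this yields 1,331
#' candidates for the three CI prior parameters and 121 for the two FF/SG
#' prior parameters.
#'
#' @param free_params Named list of `c(min, max)` ranges, in parameter order.
#' @param points_per_param Number of grid values per parameter (>= 2).
#' @return A data frame with one row per candidate (zero columns and a single
#'   row when `free_params` is empty).
#' @export
grid_candidates <- function(free_params, points_per_param = 11) {
  stopifnot(points_per_param >= 2)
  if (length(free_params) == 0) return(data.frame(row.names = "1"))
  axes <- lapply(free_params, function(b) seq(b[1], b[2], length.out = points_per_param))
  expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
}

free_param_names <- function(family) {
  switch(family,
    "CI-MA" = , "CI-PM" = , "CI-MS" = c("mu_p", "sigma_p", "p_common"),
    "FF" = , "SG" = c("mu_p", "sigma_p"),
    "FFnp" = , "SGnp" = character(0)
  )
}

# Observed per-pair response histograms of the AV trials.
aggregate_av_counts <- function(av_trials, app) {
  stopifnot(all(av_trials$modality == "AV"))
  if (any(is.na(av_trials$resp_A)) || any(is.na(av_trials$resp_V))) {
    stop("AV trials must carry both responses", call. = FALSE)
  }
  pairs <- unique(av_trials[, c("s_A", "s_V")])
  pairs <- pairs[order(pairs$s_A, pairs$s_V), ]
  key <- paste(av_trials$s_A, av_trials$s_V)
  pair_id <- match(key, paste(pairs$s_A, pairs$s_V))
  nb <- app$button_count
  cnt <- function(resp) {
    m <- matrix(0L, nrow = nb, ncol = nrow(pairs))
    t <- tabulate(resp + nb * (pair_id - 1L), nbins = nb * nrow(pairs))
    m[] <- t
    m
  }
  list(pairs = pairs, counts_A = cnt(av_trials$resp_A),
       counts_V = cnt(av_trials$resp_V))
}

# Fixed Monte-Carlo draws shared by every objective evaluation of a fit.
# The sensations x_A, x_V are precomputed once per fit since the likelihood
# parameters stay fixed while the prior parameters are searched.
make_crn_draws <- function(pairs, lik, n_sim, seed) {
  n_pairs <- nrow(pairs)
  n <- n_pairs * n_sim
  pair_id <- rep(seq_len(n_pairs), each = n_sim)
  d <- with_seed(seed, list(z_A = rnorm(n), z_V = rnorm(n), xi = runif(n)))
  list(
    x_A = pairs$s_A[pair_id] + lik$delta_A + lik$sigma_A * d$z_A,
    x_V = pairs$s_V[pair_id] + lik$delta_V + lik$sigma_V * d$z_V,
    xi = d$xi, pair_id = pair_id, n_pairs = n_pairs, n_sim = n_sim
  )
}

# Summed multinomial log-likelihood of one parameterization under CRN draws.
crn_loglik <- function(family, lik, prior, counts, draws, app, prob_floor) {
  resp <- observer_responses(family, lik, prior, draws$x_A, draws$x_V, draws$xi)
  nb <- app$button_count
  hist_of <- function(loc) {
    b <- bin_response(loc, app)
    m <- matrix(tabulate(b + nb * (draws$pair_id - 1L), nb * draws$n_pairs),
                nrow = nb)
    m / draws$n_sim
  }
  multinomial_loglik(counts$counts_A, hist_of(resp$s_hat_A), prob_floor) +
    multinomial_loglik(counts$counts_V, hist_of(resp$s_hat_V), prob_floor)
}

prior_from_par <- function(family, par_names, par) {
  v <- as.list(setNames(par, par_names))
  switch(family,
    "FF" = prior_params(v$mu_p, v$sigma_p, 1),
    "SG" = prior_params(v$mu_p, v$sigma_p, 0),
    "FFnp" = , "SGnp" = NULL,
    prior_params(v$mu_p, v$sigma_p, v$p_common)
  )
}

#' Step 2: fit one observer family to AV trials
#'
#' Aggregates the AV trials into per-pair response histograms, evaluates the
#' summed multinomial log-likelihood over all pairs and both response
#' modalities on a uniform grid of prior-parameter candidates (Monte-Carlo
#' predicted histograms under common random numbers, so the objective is
#' deterministic in the parameters), and refines the best grid point with
#' L-BFGS-B. For `FFnp`/`SGnp` no parameters are free and only the
#' log-likelihood and BIC are computed.
#'
#' @param family Observer family name.
#' @param av_trials Tibble of AV trials with both responses filled in.
#' @param fixed_likelihood [likelihood_params()] from Step 1 on the same
#'   block (held fixed throughout).
#' @param app An [apparatus()].
#' @param config A [fit_config()].
#' @return A `fit_result` list: `family`, `prior` (fitted [prior_params()] or
#'   `NULL`), `likelihood`, `log_lik`, `k` (free parameters fitted in this
#'   step: 3 for CI families, 2 for FF/SG, 0 for FFnp/SGnp), `N` (number of
#'   localization responses), `bic`, `convergence` (0 = converged; 52 = grid
#'   optimum retained after refinement failed to improve), `grid_log_lik`.
#' @export
fit_model <- function(family, av_trials, fixed_likelihood, app = apparatus(),
                      config = fit_config()) {
  fit_families(family, av_trials, fixed_likelihood, app, config)[[1]]
}

#' Fit several observer families in one pass
#'
#' Same procedure as [fit_model()] for each requested family, but the
#' Monte-Carlo draws, the location estimates and the causal-structure
#' likelihoods are shared across families during the grid search (the three
#' CI families differ only in the decision step, and FF/SG reuse the fused
#' and segregated estimates), which makes fitting the full model set
#' substantially cheaper than seven independent fits. Results are identical
#' to per-family [fit_model()] calls with the same configuration.
#'
#' @inheritParams fit_model
#' @param families Character vector of family names.
#' @return Named list of `fit_result` objects, in the requested order.
#' @export
fit_families <- function(families = OBSERVER_FAMILIES, av_trials,
                         fixed_likelihood, app = apparatus(),
                         config = fit_config()) {
  families <- vapply(families, match.arg, character(1), OBSERVER_FAMILIES,
                     USE.NAMES = FALSE)
  lik <- fixed_likelihood
  counts <- aggregate_av_counts(av_trials, app)
  draws <- make_crn_draws(counts$pairs, lik, config$n_sim, config$seed)
  N <- sum(counts$counts_A) + sum(counts$counts_V)
  nb <- app$button_count
  floor_p <- config$prob_floor

  ll_of <- function(resp) {
    hist_of <- function(loc) {
      b <- bin_response(loc, app)
      matrix(tabulate(b + nb * (draws$pair_id - 1L), nb * draws$n_pairs),
             nrow = nb) / draws$n_sim
    }
    multinomial_loglik(counts$counts_A, hist_of(resp$s_hat_A), floor_p) +
      multinomial_loglik(counts$counts_V, hist_of(resp$s_hat_V), floor_p)
  }

  ci_fams <- intersect(families, c("CI-MA", "CI-PM", "CI-MS"))
  fs_fams <- intersect(families, c("FF", "SG"))
  grid_best <- list()  # per family: list(par, ll)

  if (length(ci_fams) || length(fs_fams)) {
    ms <- grid_candidates(config$bounds[c("mu_p", "sigma_p")],
                          config$grid_points)
    pc_vals <- seq(config$bounds$p_common[1], config$bounds$p_common[2],
                   length.out = config$grid_points)
    track <- function(fam, par, ll) {
      cur <- grid_best[[fam]]
      if (is.null(cur) || ll > cur$ll) grid_best[[fam]] <<- list(par = par, ll = ll)
    }
    for (i in seq_len(nrow(ms))) {
      pri <- prior_params(ms$mu_p[i], ms$sigma_p[i], 0.5)
      est <- estimate_locations(draws$x_A, draws$x_V, lik, pri)
      if ("FF" %in% fs_fams) {
        track("FF", c(ms$mu_p[i], ms$sigma_p[i]),
              ll_of(list(s_hat_A = est$fused, s_hat_V = est$fused)))
      }
      if ("SG" %in% fs_fams) {
        track("SG", c(ms$mu_p[i], ms$sigma_p[i]),
              ll_of(list(s_hat_A = est$seg_A, s_hat_V = est$seg_V)))
      }
      if (length(ci_fams)) {
        l1 <- joint_likelihood_common(draws$x_A, draws$x_V, lik, pri)
        l2 <- joint_likelihood_independent(draws$x_A, draws$x_V, lik, pri)
        for (pc in pc_vals) {
          post <- if (pc == 1) rep(1, length(l1)) else if (pc == 0)
            rep(0, length(l1)) else l1 * pc / (l1 * pc + l2 * (1 - pc))
          for (fam in ci_fams) {
            resp <- decide(sub("CI-", "", fam), est, post, xi = draws$xi)
            track(fam, c(ms$mu_p[i], ms$sigma_p[i], pc), ll_of(resp))
          }
        }
      }
    }
  }

  refine <- function(fam) {
    par_names <- free_param_names(fam)
    objective <- function(par) {
      crn_loglik(fam, lik, prior_from_par(fam, par_names, par),
                 counts, draws, app, floor_p)
    }
    if (length(par_names) == 0) {
      ll <- objective(numeric(0))
      return(new_fit_result(fam, NULL, lik, ll, 0L, N,
                            convergence = 0L, grid_log_lik = ll))
    }
    start <- grid_best[[fam]]$par
    start_ll <- grid_best[[fam]]$ll
    lower <- vapply(config$bounds[par_names], `[`, numeric(1), 1)
    upper <- vapply(config$bounds[par_names], `[`, numeric(1), 2)
    opt <- tryCatch(
      optim(start, function(p) -objective(p), method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = config$maxit,
                           ndeps = rep(1e-2, length(par_names)))),
      error = function(e) NULL
    )
    if (is.null(opt) || -opt$value < start_ll) {
      par <- start; ll <- start_ll; conv <- 52L
    } else {
      par <- opt$par; ll <- -opt$value; conv <- opt$convergence
    }
    new_fit_result(fam, prior_from_par(fam, par_names, par), lik, ll,
                   length(par_names), N, convergence = conv,
                   grid_log_lik = start_ll)
  }

  setNames(lapply(families, refine), families)
}

new_fit_result <- function(family, prior, likelihood, log_lik, k, N,
                           convergence, grid_log_lik) {
  structure(list(family = family, prior = prior, likelihood = likelihood,
                 log_lik = log_lik, k = as.integer(k), N = as.integer(N),
                 bic = bic(log_lik, k, N), convergence = convergence,
                 grid_log_lik = grid_log_lik),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$family, ": LL = ", format(x$log_lik, digits = 6),
      ", k = ", x$k, ", N = ", x$N, ", BIC = ", format(x$bic, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Bayesian information criterion
#'
#' `-2 * log_lik + k * log(N)`; lower is better.
#'
#' @param log_lik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param N Number of data points.
#' @export
bic <- function(log_lik, k, N) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  stopifnot(k >= 0)
  -2 * log_lik + k * log(N)
}

#' Verbal evidence category for a BIC difference
#'
#' For the model with the lower BIC: a difference of 0-2 is weak evidence,
#' 2-6 positive, 6-10 strong, and over 10 very strong.
#'
#' @param bic_difference Absolute BIC difference between two models.
#' @return One of `"weak"`, `"positive"`, `"strong"`, `"very strong"`.
#' @export
classify_evidence <- function(bic_difference) {
  d <- abs(bic_difference)
  cut(d, breaks = c(0, 2, 6, 10, Inf), right = FALSE, include.lowest = TRUE,
      labels = c("weak", "positive", "strong", "very strong")) |>
    as.character()
}

#' Select the best-fitting family by BIC
#'
#' Lowest BIC wins; exact ties resolve toward the family with fewer fitted
#' parameters, then toward the fixed family order CI-MA, CI-PM, CI-MS, FF,
#' SG, FFnp, SGnp.
#'
#' @param fits List of `fit_result` objects.
#' @return The winning family name.
#' @export
select_best <- function(fits) {
  stopifnot(length(fits) >= 1)
  fam <- vapply(fits, function(f) f$family, character(1))
  o <- order(vapply(fits, function(f) f$bic, numeric(1)),
             vapply(fits, function(f) f$k, numeric(1)),
             match(fam, OBSERVER_FAMILIES))
  unname(fam[o[1]])
}

#' Step 3: refit the best family's priors on Block 2
#'
#' Identical procedure to [fit_model()], restricted to the family selected in
#' Step 2 and using the Block 2 unimodal likelihood parameters from Step 1;
#' no model comparison is performed. The participant's best model is assumed
#' unchanged between blocks while its parameters may change.
#'
#' @param best_family Family selected on Block 1.
#' @param block2_av_trials Tibble of Block 2 AV trials with responses.
#' @param block2_likelihood [likelihood_params()] fitted to the Block 2
#'   unimodal trials.
#' @inheritParams fit_model
#' @export
fit_block2_priors <- function(best_family, block2_av_trials, block2_likelihood,
                              app = apparatus(), config = fit_config()) {
  fit_model(best_family, block2_av_trials, block2_likelihood, app, config)
}
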