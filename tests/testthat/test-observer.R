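app <- apparatus()

test_that("common-cause joint likelihood matches its closed form and symmetry", {
  lik <- likelihood_params(0, 1, 0, 1)
  pri <- prior_params(0, 1, 0.5)
  expect_equal(joint_likelihood_common(0, 0, lik, pri), 1 / (2 * pi * sqrt(3)),
               tolerance = 1e-12)
  # symmetric in the two (x, sigma) channels
  lik2 <- likelihood_params(0, 2, 0, 1)
  lik2s <- likelihood_params(0, 1, 0, 2)
  pri2 <- prior_params(0.7, 5, 0.5)
  expect_equal(joint_likelihood_common(1.3, -0.4, lik2, pri2),
               joint_likelihood_common(-0.4, 1.3, lik2s, pri2))
})

test_that("joint likelihoods agree with quadrature oracles", {
  # frozen example against the single-integral oracle
  lik <- likelihood_params(0, 2, 0, 1)
  pri <- prior_params(0, 10, 0.5)
  got <- joint_likelihood_common(1, -1, lik, pri)
  want <- quad_likelihood_common(1, -1, 2, 1, 0, 10)
  expect_equal(got, want, tolerance = 1e-6)

  lik2 <- likelihood_params(0, 2, 0, 1)
  pri2 <- prior_params(1, 5, 0.5)
  got2 <- joint_likelihood_independent(3, -2, lik2, pri2)
  want2 <- quad_likelihood_independent(3, -2, 2, 1, 1, 5)
  expect_equal(got2, want2, tolerance = 1e-6)

  # random-draw property over both structures
  withr::with_seed(11, {
    for (i in 1:20) {
      sA <- runif(1, 0.5, 8); sV <- runif(1, 0.5, 8)
      sP <- runif(1, 2, 40); mP <- runif(1, -10, 10)
      xA <- runif(1, -30, 30); xV <- runif(1, -30, 30)
      l <- likelihood_params(0, sA, 0, sV); p <- prior_params(mP, sP, 0.5)
      expect_equal(joint_likelihood_common(xA, xV, l, p),
                   quad_likelihood_common(xA, xV, sA, sV, mP, sP),
                   tolerance = 1e-5)
      expect_equal(joint_likelihood_independent(xA, xV, l, p),
                   quad_likelihood_independent(xA, xV, sA, sV, mP, sP),
                   tolerance = 1e-5)
    }
  })
})

test_that("independent-causes likelihood factorizes over modalities", {
  lik <- likelihood_params(0, 3, 0, 1.5)
  pri <- prior_params(-2, 8, 0.5)
  v <- joint_likelihood_independent(4, -1, lik, pri)
  mA <- dnorm(4, -2, sqrt(9 + 64))
  mV <- dnorm(-1, -2, sqrt(2.25 + 64))
  expect_equal(v, mA * mV)
})

test_that("causal posterior obeys Bayes' rule and is monotone in the prior", {
  lik <- likelihood_params(0, 1, 0, 1)
  pri <- function(pc) prior_params(0, 1, pc)
  expect_equal(posterior_common_cause(3, -4, lik, pri(1)), 1)
  expect_equal(posterior_common_cause(3, -4, lik, pri(0)), 0)
  l1 <- joint_likelihood_common(0, 0, lik, pri(0.5))
  l2 <- joint_likelihood_independent(0, 0, lik, pri(0.5))
  expect_equal(posterior_common_cause(0, 0, lik, pri(0.5)), l1 / (l1 + l2))
  expect_equal(posterior_common_cause(0, 0, lik, pri(0.5)), 0.5359,
               tolerance = 1e-4)
  post <- vapply(seq(0, 1, 0.1),
                 function(pc) posterior_common_cause(2, -3, lik, pri(pc)),
                 numeric(1))
  expect_true(all(diff(post) >= 0))
})

test_that("location estimates implement precision weighting and shrinkage", {
  lik <- likelihood_params(0, 2, 0, 1)
  est <- estimate_locations(10, 0, lik, use_prior = FALSE)
  expect_equal(est$fused, 2)         # (10/4 + 0) / (1/4 + 1)
  expect_equal(est$seg_A, 10)        # no-prior segregation is the identity
  expect_equal(est$seg_V, 0)
  # equal-precision shrinkage halves the sensation
  likA <- likelihood_params(0, 3, 0, 1)
  priA <- prior_params(0, 3, 0.5)
  expect_equal(estimate_locations(8, 0, likA, priA)$seg_A, 4)
  expect_error(estimate_locations(1, 1, lik, prior = NULL, use_prior = TRUE),
               "prior")
})

test_that("fused estimates converge to reliability weighting as the prior flattens", {
  lik <- likelihood_params(0, 6, 0, 2)
  flat <- prior_params(0, 1e4, 0.5)
  withr::with_seed(4, {
    x_A <- runif(50, -30, 30); x_V <- runif(50, -30, 30)
    with_prior <- estimate_locations(x_A, x_V, lik, flat)$fused
    no_prior <- estimate_locations(x_A, x_V, lik, use_prior = FALSE)$fused
    expect_equal(with_prior, no_prior, tolerance = 1e-3)
  })
})

test_that("decision strategies implement their selection rules", {
  est <- list(fused = 2, seg_A = 5, seg_V = -1)
  # model averaging: posterior-weighted mean
  ma <- decide("MA", est, 0.6)
  expect_equal(ma$s_hat_A, 0.6 * 2 + 0.4 * 5)
  expect_equal(ma$s_hat_V, 0.6 * 2 + 0.4 * (-1))
  # model selection picks the more probable structure; ties segregate
  expect_equal(decide("MS", est, 0.6)$s_hat_A, est$fused)
  expect_equal(decide("MS", est, 0.5)$s_hat_A, est$seg_A)
  expect_equal(decide("MS", est, 0.49)$s_hat_V, est$seg_V)
  # probability matching needs the uniform draw and uses one shared draw
  expect_error(decide("PM", est, 0.6), "xi")
  pm <- decide("PM", list(fused = c(2, 2), seg_A = c(5, 5), seg_V = c(-1, -1)),
               c(0.6, 0.6), xi = c(0.55, 0.65))
  expect_equal(pm$s_hat_A, c(2, 5))
  expect_equal(pm$s_hat_V, c(2, -1))  # same structure within trial
})

test_that("probability matching selects fusion at the posterior rate", {
  est <- list(fused = rep(1, 1e5), seg_A = rep(0, 1e5), seg_V = rep(0, 1e5))
  xi <- withr::with_seed(2, runif(1e5))
  pm <- decide("PM", est, rep(0.6, 1e5), xi = xi)
  expect_equal(mean(pm$s_hat_A == 1), 0.6, tolerance = 0.5 / 60)
})

test_that("model averaging stays between the fused and segregated estimates", {
  lik <- likelihood_params(0, 6, 0, 2)
  pri <- prior_params(0, 25, 0.5)
  withr::with_seed(8, {
    x_A <- runif(200, -30, 30); x_V <- runif(200, -30, 30)
    est <- estimate_locations(x_A, x_V, lik, pri)
    post <- posterior_common_cause(x_A, x_V, lik, pri)
    ma <- decide("MA", est, post)
    lo <- pmin(est$fused, est$seg_A); hi <- pmax(est$fused, est$seg_A)
    expect_true(all(ma$s_hat_A >= lo - 1e-12 & ma$s_hat_A <= hi + 1e-12))
  })
})

test_that("simulated response distributions are normalized histograms", {
  spec <- observer_spec("CI-MA", likelihood_params(), prior_params())
  h <- simulate_av_responses(spec, -5, 5, n_sim = 500, app, seed = 3)
  expect_length(h$p_A, 12)
  expect_equal(sum(h$p_A), 1, tolerance = 1e-12)
  expect_equal(sum(h$p_V), 1, tolerance = 1e-12)
  expect_identical(h, simulate_av_responses(spec, -5, 5, n_sim = 500, app, seed = 3))
})

test_that("degenerate noise concentrates all mass on the aligned button", {
  spec <- observer_spec("FFnp", likelihood_params(0, 0.01, 0, 0.01))
  h <- simulate_av_responses(spec, 5, 5, n_sim = 1000, app, seed = 1)
  expect_equal(h$p_A[8], 1)
  expect_equal(h$p_V[8], 1)
})

test_that("a causal-inference observer with certain fusion equals forced fusion", {
  lik <- likelihood_params(0, 6, 0, 2)
  pri <- prior_params(0, 25, 1)
  ci <- observer_spec("CI-MA", lik, pri)
  ff <- observer_spec("FF", lik, prior_params(0, 25, 0.5))
  h1 <- simulate_av_responses(ci, -15, 15, n_sim = 1e5, app, seed = 6)
  h2 <- simulate_av_responses(ff, -15, 15, n_sim = 1e5, app, seed = 6)
  tv <- function(p, q) sum(abs(p - q)) / 2
  expect_lt(tv(h1$p_A, h2$p_A), 0.01)
  expect_lt(tv(h1$p_V, h2$p_V), 0.01)
})

test_that("mirrored stimulus pairs give mirrored histograms for symmetric observers", {
  spec <- observer_spec("CI-MS", likelihood_params(0, 6, 0, 2),
                        prior_params(0, 25, 0.5))
  h1 <- simulate_av_responses(spec, -15, 5, n_sim = 5e4, app, seed = 9)
  h2 <- simulate_av_responses(spec, 15, -5, n_sim = 5e4, app, seed = 10)
  expect_lt(max(abs(h1$p_A - rev(h2$p_A))), 0.02)
  expect_lt(max(abs(h1$p_V - rev(h2$p_V))), 0.02)
})

test_that("observer specs enforce family/prior contracts", {
  expect_error(observer_spec("FFnp", prior = prior_params()), "no prior")
  expect_error(observer_spec("CI-PM", prior = NULL), "requires prior")
  expect_equal(observer_spec("FF", prior = prior_params(0, 25, 0.3))$prior$p_common, 1)
  expect_equal(observer_spec("SG", prior = prior_params(0, 25, 0.3))$prior$p_common, 0)
})
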