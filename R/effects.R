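#' @title Ventriloquism effect and aftereffect statistics
#'
#' @description
#' Responses are coded as buttons 1..12 (left to right). For each modality
#' and speaker position, the mean coded response over the 10 unimodal Block 1
#' trials serves as that participant's baseline; every response in either
#' block is expressed as a signed localization error (coded response minus
#' baseline; negative = leftward, positive = rightward), converted to degrees
#' via the button spacing. The ventriloquism effect (VE) is the difference in
#' AV-trial errors between rightward- and leftward-discrepancy trials of
#' Block 1; the immediate aftereffect (VAEi) is the same contrast applied to
#' unimodal Block 1 trials classified by the discrepancy of the nearest
#' preceding AV trial; the cumulative aftereffect (VAEc) is the mean unimodal
#' error in Block 2 (against Block 1 baselines). Each is computed separately
#' for A and V responses, with positive values indicating bias toward the V
#' location.
#'
#' @name effects
NULL

#' Signed localization errors against Block 1 unimodal baselines
#'
#' @param trials Tibble of one participant's trials (both blocks), with
#'   responses filled in.
#' @param app An [apparatus()].
#' @return Tibble with one row per response: `block`, `trial`, `modality`
#'   (trial modality), `response_modality` ("A"/"V"), `s` (that response's
#'   stimulus, degrees), `resp`, `error_units` (button units),
#'   `error_deg`, and `preceding_disc` (degrees; `NA` outside unimodal
#'   Block 1 trials).
#' @export
localization_errors <- function(trials, app = apparatus()) {
  trials <- dplyr::arrange(trials, .data$block, .data$trial)
  b1 <- trials[trials$block == 1L, ]
  base <- list()
  for (m in c("A", "V")) {
    uni <- b1[b1$modality == m, ]
    s <- if (m == "A") uni$s_A else uni$s_V
    r <- if (m == "A") uni$resp_A else uni$resp_V
    for (loc in app$speaker_azimuths) {
      rr <- r[s == loc]
      if (length(rr) == 0 || all(is.na(rr))) {
        stop("no Block 1 unimodal ", m, " trials at ", loc,
             " deg: baseline undefined", call. = FALSE)
      }
      base[[paste(m, loc)]] <- mean(rr, na.rm = TRUE)
    }
  }

  pre_all <- unlist(lapply(split(seq_len(nrow(trials)), trials$block), function(ix) {
    preceding_av_discrepancy(trials[ix, ])
  })[as.character(sort(unique(trials$block)))], use.names = FALSE)

  rows <- list()
  for (m in c("A", "V")) {
    has <- if (m == "A") trials$modality %in% c("A", "AV") else
      trials$modality %in% c("V", "AV")
    sub <- trials[has, ]
    s <- if (m == "A") sub$s_A else sub$s_V
    r <- if (m == "A") sub$resp_A else sub$resp_V
    baseline <- unlist(base[paste(m, s)], use.names = FALSE)
    err <- r - baseline
    rows[[m]] <- tibble::tibble(
      block = sub$block, trial = sub$trial, modality = sub$modality,
      response_modality = m, s = s, resp = r,
      error_units = err, error_deg = err * app$button_spacing,
      preceding_disc = ifelse(sub$block == 1L & sub$modality == m,
                              pre_all[has], NA_real_)
    )
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$block, .data$trial)
}

#' Ventriloquism effect (Block 1 AV trials)
#'
#' Mean localization error over rightward-discrepancy AV trials minus the
#' mean over leftward-discrepancy AV trials, per response modality;
#' zero-discrepancy trials are excluded. Trials are pooled with equal weight.
#'
#' @param errors An error table from [localization_errors()].
#' @return Named vector `c(VE_A, VE_V)` in degrees.
#' @export
ventriloquism_effect <- function(errors) {
  av <- errors[errors$block == 1L & errors$modality == "AV", ]
  if (nrow(av) == 0) stop("no Block 1 AV trials", call. = FALSE)
  # discrepancy per AV trial: recover from the paired rows (A and V share trial)
  wide <- tidyr::pivot_wider(av[, c("trial", "response_modality", "s")],
                             names_from = "response_modality", values_from = "s")
  disc <- setNames(wide$V - wide$A, wide$trial)
  av$disc <- disc[as.character(av$trial)]
  out <- vapply(c("A", "V"), function(m) {
    e <- av[av$response_modality == m, ]
    if (!any(e$disc > 0) || !any(e$disc < 0)) {
      return(NA_real_)
    }
    mean(e$error_deg[e$disc > 0]) - mean(e$error_deg[e$disc < 0])
  }, numeric(1))
  setNames(out, c("VE_A", "VE_V"))
}

#' Immediate ventriloquism aftereffect (Block 1 unimodal trials)
#'
#' Unimodal Block 1 errors are classified by the discrepancy of the nearest
#' preceding AV trial (interjacent unimodal trials skipped): rightward =
#' {+10, +20} degrees, leftward = {-10, -20}; trials preceded by a
#' zero-discrepancy AV trial, or with no preceding AV trial, are excluded
#' from the contrast. Returns mean(rightward-preceded) -
#' mean(leftward-preceded) per modality.
#'
#' @inheritParams ventriloquism_effect
#' @return Named vector `c(VAEi_A, VAEi_V)` in degrees.
#' @export
immediate_aftereffect <- function(errors) {
  uni <- errors[errors$block == 1L & errors$modality %in% c("A", "V") &
                  errors$modality == errors$response_modality, ]
  out <- vapply(c("A", "V"), function(m) {
    e <- uni[uni$response_modality == m & !is.na(uni$preceding_disc), ]
    right <- e$error_deg[e$preceding_disc %in% c(10, 20)]
    left <- e$error_deg[e$preceding_disc %in% c(-10, -20)]
    if (length(right) == 0 || length(left) == 0) return(NA_real_)
    mean(right) - mean(left)
  }, numeric(1))
  setNames(out, c("VAEi_A", "VAEi_V"))
}

#' Cumulative ventriloquism aftereffect (Block 2 unimodal trials)
#'
#' Mean signed localization error over all unimodal Block 2 trials, per
#' modality, with baselines taken from Block 1. Under the constant +10 degree
#' discrepancy of Block 2, a positive auditory value indicates recalibration
#' toward the V location and a negative visual value recalibration toward A.
#'
#' @inheritParams ventriloquism_effect
#' @return Named vector `c(VAEc_A, VAEc_V)` in degrees.
#' @export
cumulative_aftereffect <- function(errors) {
  uni <- errors[errors$block == 2L & errors$modality %in% c("A", "V") &
                  errors$modality == errors$response_modality, ]
  out <- vapply(c("A", "V"), function(m) {
    e <- uni$error_deg[uni$response_modality == m]
    if (length(e) == 0) NA_real_ else mean(e)
  }, numeric(1))
  setNames(out, c("VAEc_A", "VAEc_V"))
}

#' Unimodal localization precision (Block 1)
#'
#' Standard deviation of the signed unimodal localization errors per
#' modality, in degrees. Because errors are location-centered responses this
#' pools the per-location response SDs across the four speaker positions.
#'
#' @inheritParams ventriloquism_effect
#' @return Named vector `c(SD_A, SD_V)` in degrees.
#' @export
unimodal_precision <- function(errors) {
  uni <- errors[errors$block == 1L & errors$modality %in% c("A", "V") &
                  errors$modality == errors$response_modality, ]
  out <- vapply(c("A", "V"), function(m) {
    sd(uni$error_deg[uni$response_modality == m])
  }, numeric(1))
  setNames(out, c("SD_A", "SD_V"))
}

#' Per-participant effect summary
#'
#' Runs the whole effect pipeline on one participant's trials.
#'
#' @param trials Tibble of the participant's trials (both blocks).
#' @param app An [apparatus()].
#' @param participant,group Optional labels carried into the output.
#' @return One-row tibble with VE, VAEi, VAEc (A and V) and SD_A, SD_V.
#' @export
effect_summary <- function(trials, app = apparatus(),
                           participant = NA_character_, group = NA_character_) {
  err <- localization_errors(trials, app)
  tibble::tibble(
    participant = participant, group = group,
    !!!as.list(ventriloquism_effect(err)),
    !!!as.list(immediate_aftereffect(err)),
    !!!as.list(cumulative_aftereffect(err)),
    !!!as.list(unimodal_precision(err))
  )
}

# Welch's heteroscedastic one-way ANOVA (Satterthwaite denominator df).
welch_anova <- function(values, groups) {
  ok <- !is.na(values)
  ht <- oneway.test(values[ok] ~ factor(groups[ok]), var.equal = FALSE)
  tibble::tibble(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
                 df2 = unname(ht$parameter[2]), p = ht$p.value)
}

# Games-Howell pairwise comparisons: Welch t per pair referred to the
# studentized-range distribution with q = t * sqrt(2).
games_howell <- function(values, groups) {
  g <- split(values[!is.na(values)], groups[!is.na(values)])
  g <- g[lengths(g) >= 2]
  k <- length(g)
  combos <- utils::combn(names(g), 2, simplify = FALSE)
  rows <- lapply(combos, function(pair) {
    x <- g[[pair[1]]]; y <- g[[pair[2]]]
    vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
    se <- sqrt(vx + vy)
    tstat <- (mean(x) - mean(y)) / se
    df <- se^4 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    # the studentized-range distribution is undefined below 2 df (possible
    # only for near-minimal groups); report NA rather than a NaN
    p <- if (df < 2) NA_real_ else
      ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    tibble::tibble(group1 = pair[1], group2 = pair[2],
                   diff = mean(x) - mean(y), se = se, t = tstat, df = df, p = p)
  })
  dplyr::bind_rows(rows)
}

#' Group-level tests on effect summaries
#'
#' For each effect measure: a Welch heteroscedastic one-way ANOVA across
#' groups, Games-Howell pairwise post-hoc comparisons, one-tailed one-sample
#' t-tests against zero per group (Holm-corrected within each effect type
#' across its six group x modality tests), and Spearman rank correlations
#' between effect pairs (VE-VAEi, VE-VAEc, VAEi-VAEc per modality), overall
#' and within group. Groups with fewer than 2 members are dropped with a
#' warning. Default test directions follow the phenomenology: auditory
#' effects are tested for being greater than zero, visual effects for being
#' less than zero (bias toward the A location); directions are configurable.
#'
#' @param summaries Tibble of per-participant effect summaries (one row per
#'   participant) with a `group` column, as from [effect_summary()].
#' @param effects Character vector of effect columns to test.
#' @param alternatives Named character vector giving the one-sample test
#'   direction ("greater"/"less") per effect column.
#' @return List with tibbles `welch`, `games_howell`, `one_sample`,
#'   `spearman`, and `excluded_groups`.
#' @export
group_tests <- function(summaries,
                        effects = c("VE_A", "VE_V", "VAEi_A", "VAEi_V",
                                    "VAEc_A", "VAEc_V"),
                        alternatives = c(VE_A = "greater", VE_V = "less",
                                         VAEi_A = "greater", VAEi_V = "less",
                                         VAEc_A = "greater", VAEc_V = "less")) {
  sizes <- table(summaries$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ", paste(small, collapse = ", "))
    summaries <- summaries[!summaries$group %in% small, ]
  }
  if (length(unique(summaries$group)) < 2) {
    stop("need at least 2 groups with >= 2 members", call. = FALSE)
  }

  welch <- dplyr::bind_rows(lapply(effects, function(eff) {
    dplyr::mutate(welch_anova(summaries[[eff]], summaries$group),
                  effect = eff, .before = 1)
  }))
  gh <- dplyr::bind_rows(lapply(effects, function(eff) {
    dplyr::mutate(games_howell(summaries[[eff]], summaries$group),
                  effect = eff, .before = 1)
  }))

  one <- dplyr::bind_rows(lapply(effects, function(eff) {
    dplyr::bind_rows(lapply(sort(unique(summaries$group)), function(grp) {
      v <- summaries[[eff]][summaries$group == grp]
      v <- v[!is.na(v)]
      ht <- t.test(v, mu = 0, alternative = alternatives[[eff]])
      tibble::tibble(effect = eff, group = grp, mean = mean(v),
                     t = unname(ht$statistic), df = unname(ht$parameter),
                     alternative = alternatives[[eff]], p = ht$p.value)
    }))
  }))
  # Holm family: the one-sample tests of one effect type (VE, VAEi or VAEc)
  one$family <- sub("_[AV]$", "", one$effect)
  one <- dplyr::bind_rows(lapply(split(one, one$family), function(d) {
    d$p_holm <- p.adjust(d$p, method = "holm")
    d
  }))
  one$family <- NULL

  pairs <- list(c("VE", "VAEi"), c("VE", "VAEc"), c("VAEi", "VAEc"))
  spearman_rows <- list()
  scopes <- c(list(overall = summaries),
              split(summaries, summaries$group))
  for (scope in names(scopes)) {
    d <- scopes[[scope]]
    for (m in c("A", "V")) {
      for (pr in pairs) {
        c1 <- paste0(pr[1], "_", m); c2 <- paste0(pr[2], "_", m)
        if (!all(c(c1, c2) %in% names(d))) next
        ok <- stats::complete.cases(d[[c1]], d[[c2]])
        if (sum(ok) < 3) next
        ht <- suppressWarnings(
          stats::cor.test(d[[c1]][ok], d[[c2]][ok], method = "spearman"))
        spearman_rows[[length(spearman_rows) + 1L]] <- tibble::tibble(
          scope = scope, pair = paste0(c1, "~", c2),
          rho = unname(ht$estimate), p = ht$p.value, n = sum(ok))
      }
    }
  }

  list(welch = welch, games_howell = gh, one_sample = one,
       spearman = dplyr::bind_rows(spearman_rows),
       excluded_groups = small)
}
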