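#' @title End-to-end analysis pipeline
#'
#' @description
#' Orchestrates a full run on a cohort (synthetic or imported): effect
#' statistics per participant, the three-step model fitting with BIC
#' comparison, group-aggregated BIC tables with within-group rankings, and
#' the group-level tests. Every stage is also callable on its own through
#' the exported module functions; [run_analysis()] is their composition with
#' seeded reproducibility.
#'
#' @name pipeline
NULL

#' Write / read a tidy trial table
#'
#' Tab-separated text, one row per trial, missing fields empty. Columns:
#' participant, group, response_order, block, trial, modality, s_A, s_V,
#' resp_A, resp_V.
#'
#' @param trials Tibble as from [cohort_trials()].
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' @rdname write_trials
#' @return `read_trials()` returns the trial tibble with typed columns;
#'   malformed rows (unknown modality, out-of-range responses) raise an
#'   error naming the offending rows.
#' @export
read_trials <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("participant", "group", "block", "trial", "modality",
            "s_A", "s_V", "resp_A", "resp_V")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$modality %in% c("A", "V", "AV"))
  if (length(bad)) {
    stop("malformed modality in row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  for (col in c("resp_A", "resp_V")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 1 | df[[col]] > 12))
    if (length(bad)) {
      stop(col, " out of range in row(s): ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Recognized keys: `apparatus` (speaker_azimuths, button_count,
#' button_spacing_deg), `fit` (n_sim, grid_points, seed, bounds, prob_floor),
#' `archetypes` (per-group overrides), `n_per_group`, `seed`,
#' `retry_budget`, `families`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A nested configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

participant_tables <- function(source) {
  if (inherits(source, "cohort")) {
    trials <- cohort_trials(source)
  } else if (is.character(source) && length(source) == 1) {
    trials <- read_trials(source)
  } else if (is.data.frame(source)) {
    trials <- source
  } else {
    stop("`cohort_source` must be a cohort, a trial table, or a file path",
         call. = FALSE)
  }
  split(trials, trials$participant)
}

fit_params_row <- function(fit) {
  pri <- fit$prior
  tibble::tibble(
    family = fit$family,
    mu_p = pri$mu_p %||% NA_real_, sigma_p = pri$sigma_p %||% NA_real_,
    p_common = pri$p_common %||% NA_real_,
    log_lik = fit$log_lik, k = fit$k, N = fit$N, bic = fit$bic,
    convergence = fit$convergence
  )
}

#' Run the full analysis on a cohort
#'
#' For every participant: computes the effect summary; fits the unimodal
#' likelihood parameters per block (Step 1); fits all requested families to
#' the Block 1 AV trials and selects the best by BIC (Step 2); refits the
#' best family's priors on Block 2 (Step 3). Participants whose sequences
#' fail [validate_sequence()] are excluded and listed in the report.
#'
#' @param cohort_source A `cohort`, a tidy trial table, or a path to one.
#' @param config A [fit_config()] used for Steps 2-3.
#' @param app An [apparatus()].
#' @param families Families entered into the Step 2 comparison.
#' @param groups Optional named vector mapping participant -> group when the
#'   source table lacks a `group` column.
#' @param run_group_tests Whether to run the group-level tests (requires
#'   >= 2 groups with >= 2 members).
#' @param progress Print one line per participant.
#' @return An `analysis_report` list: `effects`, `step1` (unimodal fits),
#'   `fits` (all Step 2 rows with within-participant BIC rank), `best_models`,
#'   `step3`, `bic_table` (group mean +- SEM with within-group rankings),
#'   `group_tests`, `excluded`, `meta`.
#' @export
run_analysis <- function(cohort_source, config = fit_config(),
                         app = apparatus(), families = OBSERVER_FAMILIES,
                         groups = NULL, run_group_tests = TRUE,
                         progress = FALSE) {
  tabs <- participant_tables(cohort_source)
  effects <- list(); step1 <- list(); fits <- list(); step3 <- list()
  best <- list(); excluded <- list()

  for (pid in names(tabs)) {
    tr <- tabs[[pid]]
    grp <- if (!is.null(groups)) groups[[pid]] else
      (tr$group[1] %||% NA_character_)
    ok <- TRUE
    for (b in c(1L, 2L)) {
      rep <- validate_sequence(tr[tr$block == b, ], app)
      if (!rep$passed) {
        excluded[[pid]] <- tibble::tibble(
          participant = pid, block = b,
          reason = paste(rep$violations$label, collapse = "; "))
        ok <- FALSE
      }
    }
    if (!ok) next
    if (progress) message("participant ", pid)

    effects[[pid]] <- effect_summary(tr, app, participant = pid, group = grp)

    lik <- list()
    for (b in c(1L, 2L)) {
      for (m in c("A", "V")) {
        f <- fit_unimodal(tr[tr$block == b & tr$modality == m, ], m, app)
        step1[[paste(pid, b, m)]] <- tibble::tibble(
          participant = pid, group = grp, block = b, modality = m,
          delta = f$delta, sigma = f$sigma, degenerate = f$degenerate)
        lik[[paste(b, m)]] <- f
      }
      lik[[paste0("block", b)]] <- likelihood_params(
        lik[[paste(b, "A")]]$delta, lik[[paste(b, "A")]]$sigma,
        lik[[paste(b, "V")]]$delta, lik[[paste(b, "V")]]$sigma)
    }

    av1 <- tr[tr$block == 1L & tr$modality == "AV", ]
    pfits <- fit_families(families, av1, lik$block1, app,
                          utils::modifyList(config,
                                            list(seed = derive_seed(config$seed, pid))))
    ptab <- dplyr::bind_rows(lapply(pfits, fit_params_row))
    ptab <- dplyr::mutate(ptab, participant = pid, group = grp,
                          rank = rank(.data$bic, ties.method = "first"),
                          .before = 1)
    fits[[pid]] <- ptab
    best_fam <- select_best(pfits)
    best[[pid]] <- tibble::tibble(participant = pid, group = grp,
                                  best_family = best_fam)

    av2 <- tr[tr$block == 2L & tr$modality == "AV", ]
    f3 <- fit_block2_priors(best_fam, av2, lik$block2, app,
                            utils::modifyList(config,
                                              list(seed = derive_seed(config$seed, pid, "b2"))))
    step3[[pid]] <- dplyr::mutate(fit_params_row(f3), participant = pid,
                                  group = grp, .before = 1)
  }

  effects <- dplyr::bind_rows(effects)
  fits <- dplyr::bind_rows(fits)

  bic_table <- NULL
  if (nrow(fits)) {
    bic_table <- fits |>
      dplyr::group_by(.data$group, .data$family) |>
      dplyr::summarise(mean_bic = mean(.data$bic),
                       sem_bic = sd(.data$bic) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop_last") |>
      dplyr::mutate(rank = rank(.data$mean_bic, ties.method = "first")) |>
      dplyr::ungroup()
  }

  gt <- NULL
  if (run_group_tests && nrow(effects) &&
      sum(table(effects$group) >= 2) >= 2) {
    gt <- group_tests(effects)
  }

  structure(list(
    effects = effects,
    step1 = dplyr::bind_rows(step1),
    fits = fits,
    best_models = dplyr::bind_rows(best),
    step3 = dplyr::bind_rows(step3),
    bic_table = bic_table,
    group_tests = gt,
    excluded = dplyr::bind_rows(excluded),
    meta = list(seed = config$seed, n_sim = config$n_sim,
                grid_points = config$grid_points, families = families,
                timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", nrow(x$effects), " participant(s), ",
      length(x$meta$families), " model families, n_sim = ", x$meta$n_sim,
      "\n", sep = "")
  if (!is.null(x$bic_table)) {
    cat("group-mean BIC (rank 1 per group):\n")
    top <- x$bic_table[x$bic_table$rank == 1, ]
    for (i in seq_len(nrow(top))) {
      cat("  ", top$group[i], ": ", top$family[i], " (",
          format(top$mean_bic[i], digits = 6), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Bar-and-dot plot of group effects
#'
#' Group-mean bars with individual participant dots, one panel per effect
#' measure, matching the conventional presentation of ventriloquism effect
#' and aftereffect data (positive = bias toward the V location).
#'
#' @param summaries Effect-summary tibble with a `group` column.
#' @param effects Effect columns to plot.
#' @return A ggplot object.
#' @export
plot_effects <- function(summaries,
                         effects = c("VE_A", "VE_V", "VAEi_A", "VAEi_V",
                                     "VAEc_A", "VAEc_V")) {
  long <- tidyr::pivot_longer(summaries[, c("participant", "group", effects)],
                              dplyr::all_of(effects),
                              names_to = "effect", values_to = "value")
  long$effect <- factor(long$effect, levels = effects)
  means <- dplyr::summarise(dplyr::group_by(long, .data$group, .data$effect),
                            value = mean(.data$value, na.rm = TRUE),
                            .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_col(data = means, fill = "grey80", color = "grey30") +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~effect, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "effect size (deg)") +
    ggplot2::theme_minimal()
}
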