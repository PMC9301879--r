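#' @title Trial sequences for the two-block ventriloquism design
#'
#' @description
#' Each experimental block has 240 trials: 40 unimodal auditory (A), 40
#' unimodal visual (V), and 160 audiovisual (AV) trials. In Block 1 the AV
#' trials cross the four speaker positions factorially (every (s_A, s_V)
#' combination 10 times), giving spatial discrepancies s_V - s_A of
#' -30..+30 degrees; in Block 2 the V stimulus is always 10 degrees to the
#' right of the A stimulus (three location pairs, 53/54/53 trials).
#'
#' A trial sequence is a tibble with one row per trial and columns
#' `block`, `trial`, `modality` ("A", "V", "AV"), `s_A`, `s_V` (degrees; `NA`
#' for the absent modality), `resp_A`, `resp_V` (button indices 1..12, `NA`
#' until responses are filled in).
#'
#' @name trial_sequences
NULL

new_trial_sequence <- function(df, block, seed) {
  df$trial <- seq_len(nrow(df))
  df <- df[, c("block", "trial", "modality", "s_A", "s_V", "resp_A", "resp_V")]
  out <- tibble::as_tibble(df)
  attr(out, "seed") <- seed
  out
}

blank_trials <- function(n, block) {
  data.frame(block = rep(block, n), trial = NA_integer_,
             modality = NA_character_, s_A = NA_real_, s_V = NA_real_,
             resp_A = NA_integer_, resp_V = NA_integer_)
}

# Unimodal stimulus lists: 10 trials at each of the four speaker positions.
unimodal_stimuli <- function(app) rep(app$speaker_azimuths, each = 10)

#' Generate a Block 1 trial sequence
#'
#' Builds the pseudorandom Block 1 order under the design constraints: the
#' 160 AV trials cover all 16 (s_A, s_V) pairs 10 times each; among the 40 A
#' (and, separately, the 40 V) trials exactly 8 are preceded — skipping any
#' interjacent unimodal trials — by an AV trial of each discrepancy in
#' {-20, -10, 0, +10, +20} degrees; and no unimodal trial immediately follows
#' an AV trial with +-30 degrees discrepancy.
#'
#' The sequence is built constructively: the AV trials are shuffled, then for
#' each of the five eligible discrepancy categories 8 A and 8 V trials are
#' attached in short runs behind randomly chosen AV carriers of that
#' category, so every constraint holds by construction. The result is
#' validated before being returned; on the (never observed) chance of a
#' violation the build is retried with a derived seed up to `retry_budget`
#' times.
#'
#' @param seed Integer seed; the sequence is a pure function of it.
#' @param app An [apparatus()].
#' @param retry_budget Maximum number of construction attempts.
#' @return A trial-sequence tibble (see [trial_sequences]).
#' @export
generate_block1 <- function(seed, app = apparatus(), retry_budget = 10000) {
  for (attempt in seq_len(max(1, retry_budget))) {
    seq_seed <- if (attempt == 1) as.integer(seed) else
      derive_seed(seed, "block1-retry", attempt)
    out <- with_seed(seq_seed, build_block1(app))
    out <- new_trial_sequence(out, block = 1L, seed = as.integer(seed))
    if (validate_sequence(out, app)$passed) return(out)
  }
  stop("Block 1 sequence construction failed within the retry budget",
       call. = FALSE)
}

build_block1 <- function(app) {
  sp <- app$speaker_azimuths
  pairs <- expand.grid(s_A = sp, s_V = sp)
  av <- pairs[rep(seq_len(nrow(pairs)), each = 10), ]
  av <- av[sample.int(nrow(av)), ]
  av$disc <- av$s_V - av$s_A

  # Unimodal trials, shuffled stimulus lists.
  uni <- rbind(
    data.frame(modality = "A", s = sample(unimodal_stimuli(app))),
    data.frame(modality = "V", s = sample(unimodal_stimuli(app)))
  )

  # Attach 8 A and 8 V trials behind carriers of each eligible discrepancy.
  carriers <- vector("list", nrow(av))
  next_uni <- list(A = 1L, V = 1L)  # cursor into each modality's stimuli
  for (cat in c(-20, -10, 0, 10, 20)) {
    hosts <- which(av$disc == cat)
    labels <- sample(rep(c("A", "V"), each = 8))
    chosen <- sample(hosts, length(labels), replace = TRUE)
    for (k in seq_along(labels)) {
      m <- labels[k]
      row_id <- which(uni$modality == m)[next_uni[[m]]]
      next_uni[[m]] <- next_uni[[m]] + 1L
      carriers[[chosen[k]]] <- c(carriers[[chosen[k]]], row_id)
    }
  }

  rows <- list()
  for (i in seq_len(nrow(av))) {
    rows[[length(rows) + 1L]] <-
      data.frame(modality = "AV", s_A = av$s_A[i], s_V = av$s_V[i])
    run <- carriers[[i]]
    if (length(run) > 1) run <- sample(run)
    for (r in run) {
      m <- uni$modality[r]
      rows[[length(rows) + 1L]] <- data.frame(
        modality = m,
        s_A = if (m == "A") uni$s[r] else NA_real_,
        s_V = if (m == "V") uni$s[r] else NA_real_
      )
    }
  }
  df <- do.call(rbind, rows)
  df$block <- 1L
  df$resp_A <- NA_integer_
  df$resp_V <- NA_integer_
  df
}

#' Generate a Block 2 trial sequence
#'
#' Block 2 exposes the observer to a constant +10 degree audiovisual
#' discrepancy: the 160 AV trials use only the pairs (-15, -5) x53,
#' (-5, +5) x54 and (+5, +15) x53, interleaved in fully random order with 40
#' A and 40 V unimodal trials (10 per speaker position each).
#'
#' @inheritParams generate_block1
#' @return A trial-sequence tibble (see [trial_sequences]).
#' @export
generate_block2 <- function(seed, app = apparatus()) {
  df <- with_seed(as.integer(seed), {
    av_pairs <- data.frame(s_A = c(-15, -5, 5), s_V = c(-5, 5, 15))
    av <- av_pairs[rep(1:3, times = c(53, 54, 53)), ]
    av$modality <- "AV"
    uni <- rbind(
      data.frame(s_A = unimodal_stimuli(app), s_V = NA_real_, modality = "A"),
      data.frame(s_A = NA_real_, s_V = unimodal_stimuli(app), modality = "V")
    )
    df <- rbind(av, uni)
    df <- df[sample.int(nrow(df)), ]
    df$block <- 2L
    df$resp_A <- NA_integer_
    df$resp_V <- NA_integer_
    df
  })
  new_trial_sequence(df, block = 2L, seed = as.integer(seed))
}

#' Discrepancy of the nearest preceding AV trial
#'
#' For every trial, the signed discrepancy (s_V - s_A, degrees) of the nearest
#' earlier AV trial, skipping any interjacent unimodal trials; `NA` for trials
#' before the first AV trial. This resolves the conditioning used by the
#' immediate ventriloquism aftereffect.
#'
#' @param seq A trial-sequence tibble.
#' @return Numeric vector, one element per trial.
#' @export
preceding_av_discrepancy <- function(seq) {
  disc <- ifelse(seq$modality == "AV", seq$s_V - seq$s_A, NA_real_)
  out <- rep(NA_real_, nrow(seq))
  last <- NA_real_
  for (i in seq_len(nrow(seq))) {
    out[i] <- last
    if (seq$modality[i] == "AV") last <- disc[i]
  }
  out
}

#' Validate a trial sequence against the design constraints
#'
#' Checks the printed composition and ordering constraints for the declared
#' block and reports every violation: total length, unimodal and AV counts,
#' per-location and per-discrepancy counts, the 8-per-cell preceding-AV
#' balance and the no-unimodal-after-±30 rule for Block 1, and the constant
#' +10 degree discrepancy with 53/54/53 pair counts for Block 2.
#'
#' @param seq A trial-sequence tibble.
#' @param app An [apparatus()].
#' @return A list with `passed` (logical) and `violations`, a tibble with
#'   columns `label` and `detail`.
#' @export
validate_sequence <- function(seq, app = apparatus()) {
  stopifnot(nrow(seq) > 0)
  block <- seq$block[1]
  if (!block %in% c(1L, 2L)) stop("unknown block label: ", block, call. = FALSE)
  v <- list()
  note <- function(label, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(label = label, detail = detail)
  }

  if (nrow(seq) != 240) note("length", paste0("expected 240, got ", nrow(seq)))
  n_mod <- table(factor(seq$modality, levels = c("A", "V", "AV")))
  if (n_mod[["AV"]] != 160) note("AV count", paste0("got ", n_mod[["AV"]]))
  for (m in c("A", "V")) {
    if (n_mod[[m]] != 40) note("unimodal count",
                               paste0(m, " trials: got ", n_mod[[m]]))
    s <- if (m == "A") seq$s_A[seq$modality == m] else seq$s_V[seq$modality == m]
    cnt <- table(factor(s, levels = app$speaker_azimuths))
    if (any(cnt != 10)) note("unimodal per-location count",
                             paste0(m, ": ", paste(cnt, collapse = "/")))
  }
  bad_stim <- (seq$modality == "AV" & (is.na(seq$s_A) | is.na(seq$s_V))) |
    (seq$modality == "A" & (is.na(seq$s_A) | !is.na(seq$s_V))) |
    (seq$modality == "V" & (is.na(seq$s_V) | !is.na(seq$s_A)))
  if (any(bad_stim)) note("stimulus fields",
                          paste0(sum(bad_stim), " trial(s) with wrong fields"))
  for (col in c("resp_A", "resp_V")) {
    r <- seq[[col]]
    bad <- !is.na(r) & (r < 1 | r > app$button_count)
    if (any(bad)) note("response range", paste0(col, ": ", sum(bad), " out of range"))
  }

  av <- seq[seq$modality == "AV", ]
  disc <- av$s_V - av$s_A
  if (block == 1L) {
    want <- c("-30" = 10, "-20" = 20, "-10" = 30, "0" = 40,
              "10" = 30, "20" = 20, "30" = 10)
    got <- table(factor(disc, levels = names(want)))
    for (d in names(want)) {
      if (got[[d]] != want[[d]]) {
        note("AV discrepancy count",
             paste0(d, " deg: expected ", want[[d]], ", got ", got[[d]]))
      }
    }
    pre <- preceding_av_discrepancy(seq)
    uni <- seq$modality %in% c("A", "V")
    if (any(uni & is.na(pre))) {
      note("unresolved predecessor",
           paste0(sum(uni & is.na(pre)), " unimodal trial(s) before any AV"))
    }
    for (m in c("A", "V")) {
      cells <- table(factor(pre[seq$modality == m], levels = c(-20, -10, 0, 10, 20)))
      if (any(cells != 8)) {
        note("preceding-AV balance",
             paste0(m, ": counts ", paste(cells, collapse = "/"),
                    " over -20/-10/0/+10/+20"))
      }
    }
    after30 <- which(seq$modality == "AV" & abs(seq$s_V - seq$s_A) == 30) + 1L
    after30 <- after30[after30 <= nrow(seq)]
    n_bad <- sum(seq$modality[after30] %in% c("A", "V"))
    if (n_bad > 0) note("±30-before-unimodal",
                        paste0(n_bad, " unimodal trial(s) right after ±30 AV"))
  } else {
    if (any(disc != 10)) note("constant discrepancy",
                              paste0(sum(disc != 10), " AV trial(s) not +10 deg"))
    want <- c("-15" = 53, "-5" = 54, "5" = 53)
    got <- table(factor(av$s_A, levels = names(want)))
    for (d in names(want)) {
      if (got[[d]] != want[[d]]) {
        note("AV pair count",
             paste0("s_A = ", d, ": expected ", want[[d]], ", got ", got[[d]]))
      }
    }
  }

  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(label = character(), detail = character())
  list(passed = nrow(violations) == 0, violations = violations)
}
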