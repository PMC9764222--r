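# Oddball experimental design: stimulus pairings, hazard-rate predictability,
# amplitude models, run schedules and event tables.

#' Define the three-stimulus set of an oddball arm
#'
#' Each experimental arm uses three stimuli of one kind. Pure tones are
#' characterised by their frequency; FM-sweeps by their frequency span
#' (end minus start frequency; sign encodes sweep direction). The defaults
#' reproduce the stimulus sets of the two arms: pure tones at 1455, 1500
#' and 1600 Hz, and sweeps running 1000 to 1080 Hz, 1070 to 1170 Hz and
#' 1280 to 1200 Hz.
#'
#' @param kind `"pure_tone"` or `"fm_sweep"`.
#' @param freqs For pure tones, the three frequencies in Hz.
#' @param f_start,f_end For sweeps, start and end frequencies in Hz.
#' @return A tibble with one row per stimulus: `stimulus_id`, `kind`, and
#'   `freq` (pure tones) or `f_start`, `f_end`, `span` (sweeps).
#' @export
#' @examples
#' stimulus_set()
#' stimulus_set("fm_sweep")
stimulus_set <- function(kind = c("pure_tone", "fm_sweep"),
                         freqs = c(1455, 1500, 1600),
                         f_start = c(1000, 1070, 1280),
                         f_end = c(1080, 1170, 1200)) {
  kind <- match.arg(kind)
  if (kind == "pure_tone") {
    stopifnot(length(freqs) == 3L)
    tibble::tibble(
      stimulus_id = paste0("tone_", freqs),
      kind = kind,
      freq = as.numeric(freqs)
    )
  } else {
    stopifnot(length(f_start) == 3L, length(f_end) == 3L)
    tibble::tibble(
      stimulus_id = paste0("sweep_", f_start, "_", f_end),
      kind = kind,
      f_start = as.numeric(f_start),
      f_end = as.numeric(f_end),
      span = as.numeric(f_end) - as.numeric(f_start)
    )
  }
}

#' Build the six ordered standard/deviant pairings
#'
#' Three distinct stimuli of one kind yield six ordered (standard, deviant)
#' pairings. Each pairing carries the stimulus distance `delta`: the absolute
#' frequency difference for pure tones, or the absolute difference between
#' frequency spans for FM-sweeps.
#'
#' @param stimuli A 3-row tibble as returned by [stimulus_set()].
#' @return A 6-row tibble with columns `pairing`, `standard_id`, `deviant_id`,
#'   `kind`, the stimulus parameters of both members, and `delta` (Hz).
#' @export
#' @examples
#' build_stimulus_pairings(stimulus_set())
build_stimulus_pairings <- function(stimuli) {
  assert_columns(stimuli, c("stimulus_id", "kind"), "`stimuli`")
  if (nrow(stimuli) != 3L) stop("need exactly 3 stimuli", call. = FALSE)
  if (anyDuplicated(stimuli$stimulus_id) > 0L) {
    stop("duplicate stimuli are not allowed", call. = FALSE)
  }
  if (length(unique(stimuli$kind)) != 1L) {
    stop("all stimuli must be of the same kind", call. = FALSE)
  }
  kind <- stimuli$kind[[1]]
  feature <- if (kind == "pure_tone") "freq" else "span"
  assert_columns(stimuli, feature, "`stimuli`")
  if (anyDuplicated(stimuli[[feature]]) > 0L) {
    stop("stimuli must have distinct ", feature, " values", call. = FALSE)
  }
  grid <- tidyr::expand_grid(std = seq_len(3L), dev = seq_len(3L)) |>
    dplyr::filter(.data$std != .data$dev)
  out <- tibble::tibble(
    pairing = seq_len(nrow(grid)),
    standard_id = stimuli$stimulus_id[grid$std],
    deviant_id = stimuli$stimulus_id[grid$dev],
    kind = kind
  )
  if (kind == "pure_tone") {
    out$f_std <- stimuli$freq[grid$std]
    out$f_dev <- stimuli$freq[grid$dev]
    out$delta <- abs(out$f_std - out$f_dev)
  } else {
    out$span_std <- stimuli$span[grid$std]
    out$span_dev <- stimuli$span[grid$dev]
    out$delta <- abs(out$span_dev - out$span_std)
  }
  out
}

#' Hazard-rate predictability of the sound heard at each trial position
#'
#' In every eight-sound trial the single deviant occupies position 4, 5 or 6
#' with equal prior probability. Because listeners know this rule, the
#' probability of the sound actually heard at a position, given all preceding
#' sounds, follows the hazard rate over the remaining allowed deviant slots:
#' a deviant at position 4 is heard with probability 1/3, at position 5 with
#' 1/2 (given no deviant yet), and at position 6 with certainty. Standards at
#' those positions are heard with the complementary probabilities. The first
#' sound is assigned probability 1/2: either member of the current pairing
#' could open the trial. Positions 2, 3, 7 and 8 are fully predictable.
#'
#' @param position Sound position(s), integers in 1..8. Vectorised.
#' @param deviant_position Position of the deviant in the trial: 4, 5 or 6.
#'   Recycled against `position`.
#' @return Numeric vector of probabilities in (0, 1].
#' @export
#' @examples
#' predictability(4, 4) # 1/3: deviant heard at position 4
#' predictability(4, 5) # 2/3: standard heard at position 4
#' predictability(6, 6) # 1: deviant certain after five standards
predictability <- function(position, deviant_position) {
  position <- as.integer(position)
  deviant_position <- as.integer(deviant_position)
  if (any(!position %in% 1:8)) {
    stop("`position` must be in 1..8", call. = FALSE)
  }
  if (any(!deviant_position %in% 4:6)) {
    stop("`deviant_position` must be 4, 5 or 6", call. = FALSE)
  }
  n <- max(length(position), length(deviant_position))
  position <- rep_len(position, n)
  deviant_position <- rep_len(deviant_position, n)
  p <- rep(1, n)
  p[position == 1L] <- 1 / 2
  p[position == 4L] <- ifelse(deviant_position[position == 4L] == 4L, 1 / 3, 2 / 3)
  at5 <- position == 5L & deviant_position >= 5L
  p[at5] <- 1 / 2
  p
}

#' Amplitude vectors of the habituation model (h1)
#'
#' Under habituation, responses to repeated standards decay asymptotically
#' while the first standard and the deviant evoke full responses, and
#' responses recover one step after the deviant. Counting standards only
#' (the opening standard is the first), the k-th standard before the deviant
#' has amplitude 1/k and the k-th standard overall, when it falls after the
#' deviant, has amplitude 1/(k - 1).
#'
#' @param deviant_position 4, 5 or 6.
#' @return Numeric vector of 8 amplitudes in (0, 1].
#' @export
#' @examples
#' h1_amplitudes(4)
h1_amplitudes <- function(deviant_position) {
  deviant_position <- as.integer(deviant_position)
  if (length(deviant_position) != 1L || !deviant_position %in% 4:6) {
    stop("`deviant_position` must be 4, 5 or 6", call. = FALSE)
  }
  amp <- numeric(8)
  k <- 0L
  for (pos in 1:8) {
    if (pos == deviant_position) {
      amp[pos] <- 1
    } else {
      k <- k + 1L
      amp[pos] <- if (pos < deviant_position) 1 / k else 1 / (k - 1L)
    }
  }
  amp
}

#' Amplitude vectors of the prediction-error model (h2)
#'
#' Under prediction error, the response to each sound scales with its
#' predictability: the amplitude at every position equals
#' [predictability()] of the sound heard there (1/2 for the first sound).
#' The vectors for deviant positions 5 and 6 coincide, since position 6 is
#' fully determined once the deviant has not occurred earlier.
#'
#' @inheritParams h1_amplitudes
#' @return Numeric vector of 8 amplitudes in (0, 1].
#' @export
#' @examples
#' h2_amplitudes(5)
h2_amplitudes <- function(deviant_position) {
  if (length(deviant_position) != 1L || !as.integer(deviant_position) %in% 4:6) {
    stop("`deviant_position` must be 4, 5 or 6", call. = FALSE)
  }
  predictability(1:8, deviant_position)
}

#' Tabulate an amplitude model over all deviant positions
#'
#' @param model `"h1"` (habituation) or `"h2"` (prediction error).
#' @return A tibble of class `amplitude_model` with columns `model`,
#'   `deviant_position`, `position` and `amplitude` (24 rows).
#' @export
#' @examples
#' amplitude_model("h2")
amplitude_model <- function(model = c("h1", "h2")) {
  model <- match.arg(model)
  fn <- if (model == "h1") h1_amplitudes else h2_amplitudes
  out <- purrr::map_dfr(4:6, function(d) {
    tibble::tibble(model = model, deviant_position = d,
                   position = 1:8, amplitude = fn(d))
  })
  class(out) <- c("amplitude_model", class(out))
  out
}

# Duration spanned by the 8 sounds of one trial, onset-to-offset (s).
trial_span <- function(sound_duration = 0.05, isi = 0.7) {
  7 * (sound_duration + isi) + sound_duration
}

#' Generate one pseudorandomised oddball run schedule
#'
#' A run holds 6 blocks of 10 trials. Deviant positions are pseudorandomised
#' so that positions 4, 5 and 6 each occur exactly 20 times, with no position
#' repeating more than `max_consecutive` times in a row, and pairings are
#' balanced across the position cells as evenly as integer constraints allow
#' (each pairing is used 10 times). Inter-trial intervals are solved so that
#' the deviant-to-deviant separation targets a draw from a Gaussian with mean
#' `dev_sep_mean` and sd `dev_sep_sd`, then clipped to `iti_bounds`. Optional
#' null events (silent gaps of one trial duration) are interspersed at rate
#' `null_rate` per trial slot.
#'
#' @param pairings Pairing table from [build_stimulus_pairings()].
#' @param seed Integer seed; identical seeds give bit-identical schedules.
#' @param n_blocks,trials_per_block Block structure (defaults 6 x 10).
#' @param iti_bounds Length-2 numeric, allowed ITI range in seconds
#'   (default 1.5 to 11).
#' @param dev_sep_mean,dev_sep_sd Deviant-separation target distribution in
#'   seconds (defaults 5 and 1).
#' @param null_rate Probability that a trial slot is preceded by a silent
#'   null event (default 0.1).
#' @param sound_duration,isi Sound length and inter-stimulus interval in
#'   seconds (defaults 0.05 and 0.7, i.e. one sound every 0.75 s).
#' @param start_time Onset of the first trial (s), leaving a baseline lead-in.
#' @param max_consecutive Longest allowed run of one deviant position.
#' @return An object of class `run_schedule`: a list with a `trials` tibble
#'   (`trial`, `block`, `pairing`, `standard_id`, `deviant_id`, `delta`,
#'   `deviant_position`, `onset`, `iti_after`), the ITI vector, and the
#'   generating parameters.
#' @export
#' @examples
#' run <- build_run(seed = 1)
#' run
#' table(run$trials$deviant_position)
build_run <- function(pairings = build_stimulus_pairings(stimulus_set()),
                      seed = NULL,
                      n_blocks = 6L, trials_per_block = 10L,
                      iti_bounds = c(1.5, 11),
                      dev_sep_mean = 5, dev_sep_sd = 1,
                      null_rate = 0.1,
                      sound_duration = 0.05, isi = 0.7,
                      start_time = 5, max_consecutive = 3L) {
  assert_columns(pairings, c("pairing", "standard_id", "deviant_id", "delta"),
                 "`pairings`")
  if (dev_sep_sd <= 0) stop("`dev_sep_sd` must be positive", call. = FALSE)
  n_trials <- n_blocks * trials_per_block
  n_pair <- nrow(pairings)
  if (n_trials %% 3L != 0L || n_trials %% n_pair != 0L) {
    stop("trial count must be divisible by 3 deviant positions and by the ",
         "number of pairings", call. = FALSE)
  }
  with_seed(seed, {
    cells <- balanced_cells(n_pair, n_trials)
    order <- pseudorandomize(cells$position, max_consecutive)
    positions <- cells$position[order]
    pairing_idx <- cells$pairing[order]

    span <- trial_span(sound_duration, isi)
    sound_step <- sound_duration + isi
    # Solve each gap so the deviant-to-deviant interval targets N(mu, sd),
    # then clip; null events extend the preceding gap by one trial span.
    targets <- rnorm(n_trials - 1L, dev_sep_mean, dev_sep_sd)
    d_off <- (positions - 1L) * sound_step
    itis <- targets - span - (d_off[-1L] - d_off[-n_trials])
    itis <- pmin(pmax(itis, iti_bounds[1]), iti_bounds[2])
    nulls <- runif(n_trials - 1L) < null_rate
    itis[nulls] <- pmin(itis[nulls] + 8 * sound_step, iti_bounds[2])
    onsets <- start_time + c(0, cumsum(span + itis))

    trials <- tibble::tibble(
      trial = seq_len(n_trials),
      block = rep(seq_len(n_blocks), each = trials_per_block),
      pairing = pairings$pairing[pairing_idx],
      standard_id = pairings$standard_id[pairing_idx],
      deviant_id = pairings$deviant_id[pairing_idx],
      delta = pairings$delta[pairing_idx],
      deviant_position = positions,
      onset = onsets,
      iti_after = c(itis, NA_real_)
    )
    structure(
      list(
        trials = trials,
        itis = itis,
        params = list(
          n_blocks = n_blocks, trials_per_block = trials_per_block,
          iti_bounds = iti_bounds, dev_sep_mean = dev_sep_mean,
          dev_sep_sd = dev_sep_sd, null_rate = null_rate,
          sound_duration = sound_duration, isi = isi,
          start_time = start_time, max_consecutive = max_consecutive
        ),
        seed = seed
      ),
      class = "run_schedule"
    )
  })
}

# Assign pairings x deviant positions as evenly as the integers allow:
# every cell gets floor(n/18); the remaining extras are dealt so that each
# pairing and each position receive their exact marginal totals.
balanced_cells <- function(n_pair, n_trials) {
  base <- n_trials %/% (n_pair * 3L)
  extra_per_pair <- n_trials %/% n_pair - 3L * base
  extra_per_pos <- n_trials %/% 3L - n_pair * base
  counts <- matrix(base, nrow = n_pair, ncol = 3L)
  if (extra_per_pair > 0L) {
    extras <- sample(rep(1:3, times = extra_per_pos)) # one position per slot
    slot <- matrix(extras, nrow = n_pair, ncol = extra_per_pair)
    for (i in seq_len(n_pair)) {
      for (p in slot[i, ]) counts[i, p] <- counts[i, p] + 1L
    }
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  tibble::tibble(
    pairing = rep(idx[, 1L], times = counts[idx]),
    position = rep(3L + idx[, 2L], times = counts[idx])
  )
}

# Rejection-sample a permutation with no deviant position repeated more than
# `max_consecutive` times in a row.
pseudorandomize <- function(positions, max_consecutive, max_tries = 10000L) {
  n <- length(positions)
  for (try in seq_len(max_tries)) {
    ord <- sample.int(n)
    r <- rle(positions[ord])
    if (max(r$lengths) <= max_consecutive) return(ord)
  }
  stop("could not satisfy pseudorandomization constraints", call. = FALSE)
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf(
    "<run_schedule> %d trials in %d blocks; deviant positions: %s\n",
    nrow(x$trials), x$params$n_blocks,
    paste(names(table(x$trials$deviant_position)),
          table(x$trials$deviant_position), sep = "x", collapse = ", ")
  ))
  cat(sprintf("  ITIs in [%.2f, %.2f] s; run ends at %.1f s\n",
              min(x$itis), max(x$itis), run_duration(x)))
  print(x$trials, n = 5)
  invisible(x)
}

# Time at which the hemodynamic response to the last sound has decayed (s).
run_duration <- function(run, hrf_tail = 24) {
  p <- run$params
  max(run$trials$onset) + trial_span(p$sound_duration, p$isi) + hrf_tail
}

#' Expand a run schedule into a per-sound event table
#'
#' One row per presented sound, in the BIDS events dialect: `onset` (s,
#' 0-based), `duration` (s), `trial_type` (std0, std1, std2, dev4, dev5,
#' dev6) and `modulator` (the within-trial index of std1/std2 sounds,
#' counting from 1; `NA` for std0 and deviants).
#'
#' @param run A `run_schedule` from [build_run()].
#' @return A tibble with 8 rows per trial and columns `trial`, `position`,
#'   `onset`, `duration`, `trial_type`, `modulator`.
#' @export
#' @examples
#' head(event_table(build_run(seed = 1)), 8)
event_table <- function(run) {
  stopifnot(inherits(run, "run_schedule"))
  p <- run$params
  step <- p$sound_duration + p$isi
  run$trials |>
    dplyr::reframe(
      trial = rep(.data$trial, each = 8L),
      position = rep(1:8, times = dplyr::n()),
      onset = rep(.data$onset, each = 8L) + (rep(1:8, dplyr::n()) - 1L) * step,
      deviant_position = rep(.data$deviant_position, each = 8L)
    ) |>
    dplyr::mutate(
      duration = p$sound_duration,
      trial_type = dplyr::case_when(
        .data$position == 1L ~ "std0",
        .data$position == .data$deviant_position ~
          paste0("dev", .data$deviant_position),
        .data$position < .data$deviant_position ~ "std1",
        TRUE ~ "std2"
      ),
      modulator = dplyr::case_when(
        .data$trial_type == "std1" ~ .data$position - 1,
        .data$trial_type == "std2" ~ .data$position - .data$deviant_position,
        TRUE ~ NA_real_
      )
    ) |>
    dplyr::select("trial", "position", "onset", "duration", "trial_type",
                  "modulator")
}
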