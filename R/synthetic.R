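# Synthetic BOLD data: HRF, labelled voxel grids, and run simulation.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peaking near 5 s, undershoot
#' near 15 s), rescaled so the peak response is 1. Zero at `t = 0` and
#' negligible beyond ~32 s.
#'
#' @param t Time in seconds (vectorised); must be non-negative.
#' @param peak_shape,under_shape,under_ratio Shape of the response and
#'   undershoot gammas (rate 1) and the undershoot weight.
#' @return Numeric vector of response weights.
#' @export
#' @examples
#' curve(hrf(x), 0, 30, xlab = "time (s)")
hrf <- function(t, peak_shape = 6, under_shape = 16, under_ratio = 1 / 6) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  h <- dgamma(t, peak_shape, 1) - under_ratio * dgamma(t, under_shape, 1)
  peak <- dgamma(peak_shape - 1, peak_shape, 1) -
    under_ratio * dgamma(peak_shape - 1, under_shape, 1)
  h / peak
}

#' Build a labelled 3D voxel grid with block-shaped ROIs
#'
#' A synthetic stand-in for an anatomical parcellation: a regular grid in
#' which named regions of interest occupy non-overlapping rectangular blocks.
#' The default carves eight ROI blocks named after bilateral auditory
#' cortical fields (Te1.0, Te1.1, Te1.2, Te3, left/right) out of a
#' 20 x 20 x 10 grid.
#'
#' @param dim Integer length-3 grid dimensions.
#' @param rois A tibble with columns `roi`, `x0`, `x1`, `y0`, `y1`, `z0`,
#'   `z1` (inclusive voxel index bounds), or `NULL` for an unlabelled grid.
#' @param voxel_size Isotropic voxel size in mm (metadata only).
#' @return A tibble of class `voxel_grid` with one row per voxel: `voxel`
#'   (linear index), `x`, `y`, `z`, `roi` (`NA` outside any ROI). The grid
#'   dimensions and voxel size are kept as attributes.
#' @export
#' @examples
#' grid <- make_roi_grid()
#' dplyr::count(grid, roi)
make_roi_grid <- function(dim = c(20L, 20L, 10L),
                          rois = default_roi_spec(dim),
                          voxel_size = 1.5) {
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  dim <- as.integer(dim)
  coords <- tidyr::expand_grid(z = seq_len(dim[3]), y = seq_len(dim[2]),
                               x = seq_len(dim[1])) |>
    dplyr::select("x", "y", "z")
  grid <- tibble::tibble(
    voxel = seq_len(prod(dim)),
    x = coords$x, y = coords$y, z = coords$z,
    roi = NA_character_
  )
  if (!is.null(rois) && nrow(rois) > 0L) {
    assert_columns(rois, c("roi", "x0", "x1", "y0", "y1", "z0", "z1"), "`rois`")
    if (any(rois$x1 > dim[1] | rois$y1 > dim[2] | rois$z1 > dim[3] |
            rois$x0 < 1 | rois$y0 < 1 | rois$z0 < 1)) {
      stop("ROI block extends outside the grid", call. = FALSE)
    }
    for (i in seq_len(nrow(rois))) {
      inside <- grid$x >= rois$x0[i] & grid$x <= rois$x1[i] &
        grid$y >= rois$y0[i] & grid$y <= rois$y1[i] &
        grid$z >= rois$z0[i] & grid$z <= rois$z1[i]
      if (any(!is.na(grid$roi[inside]))) {
        stop("ROI blocks overlap: ", rois$roi[i], call. = FALSE)
      }
      grid$roi[inside] <- rois$roi[i]
    }
  }
  structure(grid, dim3 = dim, voxel_size = voxel_size,
            class = c("voxel_grid", class(grid)))
}

#' Default ROI block layout
#'
#' Eight equal non-overlapping blocks named after the bilateral auditory
#' fields Te1.0, Te1.1, Te1.2 and Te3.
#'
#' @param dim Grid dimensions the blocks must fit into.
#' @param block Length-3 block extent; defaults to 5 x 5 x 4, shrunk to
#'   half the grid extent on small grids.
#' @return Tibble of block bounds suitable for [make_roi_grid()].
#' @export
default_roi_spec <- function(dim = c(20L, 20L, 10L),
                             block = pmin(c(5L, 5L, 4L),
                                          pmax(1L, as.integer(dim) %/% 2L))) {
  names <- c("Te1.0L", "Te1.0R", "Te1.1L", "Te1.1R",
             "Te1.2L", "Te1.2R", "Te3L", "Te3R")
  if (2 * block[1] > dim[1] || 2 * block[2] > dim[2] || 2 * block[3] > dim[3]) {
    stop("grid too small for the default 8-block ROI layout", call. = FALSE)
  }
  corners <- tidyr::expand_grid(zc = 0:1, yc = 0:1, xc = 0:1)
  tibble::tibble(
    roi = names,
    x0 = 1L + corners$xc * (dim[1] - block[1]),
    y0 = 1L + corners$yc * (dim[2] - block[2]),
    z0 = 1L + corners$zc * (dim[3] - block[3])
  ) |>
    dplyr::mutate(x1 = .data$x0 + block[1] - 1L,
                  y1 = .data$y0 + block[2] - 1L,
                  z1 = .data$z0 + block[3] - 1L) |>
    dplyr::select("roi", "x0", "x1", "y0", "y1", "z0", "z1")
}

#' Generative response profiles per ROI
#'
#' Convenience constructor for the per-ROI profile table consumed by
#' [simulate_run()]. A profile maps the model amplitude of each sound to a
#' neural event amplitude: `baseline + slope_sign * gain * f(a)`, where
#' `f(a) = 1 - a` for the prediction-error model h2 (BOLD increases with
#' surprise) and `f(a) = a` for the habituation model h1. The `null` model
#' evokes nothing (gain 0).
#'
#' @param roi Character vector of ROI names.
#' @param model Generative model per ROI: `"h1"`, `"h2"` or `"null"`.
#' @param gain Peak evoked amplitude in signal units (default 2, i.e. a 2%
#'   signal change against the default baseline of 100).
#' @param baseline Constant signal level (arbitrary units, default 100).
#' @param slope_sign +1 or -1, sign of the amplitude-to-response mapping.
#' @return Tibble with one row per ROI.
#' @export
generative_profiles <- function(roi, model = "h2", gain = 2,
                                baseline = 100, slope_sign = 1) {
  stopifnot(all(model %in% c("h1", "h2", "null")))
  out <- tibble::tibble(roi = roi, model = model, gain = gain,
                        baseline = baseline, slope_sign = slope_sign)
  out$gain[out$model == "null"] <- 0
  out
}

#' Noise specification for simulated runs
#'
#' AR(1) structure plus a slow sinusoidal drift plus white noise, jointly
#' scaled so that the temporal signal-to-noise ratio (baseline mean divided
#' by temporal sd) hits `tsnr`.
#'
#' @param tsnr Target temporal SNR (the two experimental arms ran near 50
#'   and 30).
#' @param ar_coef Lag-1 autoregressive coefficient (default 0.3).
#' @param drift_period Drift period in seconds (default 60).
#' @param prop Length-3 non-negative weights of the AR(1), drift and white
#'   components (proportions of total noise variance).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(tsnr = 50, ar_coef = 0.3, drift_period = 60,
                       prop = c(ar = 0.5, drift = 0.2, white = 0.3)) {
  stopifnot(tsnr > 0, abs(ar_coef) < 1, drift_period > 0,
            length(prop) == 3L, all(prop >= 0), sum(prop) > 0)
  structure(list(tsnr = tsnr, ar_coef = ar_coef, drift_period = drift_period,
                 prop = prop / sum(prop)), class = "noise_spec")
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  as.numeric(stats::filter(rnorm(n, sd = innov_sd), phi,
                           method = "recursive",
                           init = rnorm(1)))
}

#' Simulate one BOLD run on a labelled grid
#'
#' Every voxel of an ROI shares the evoked component implied by that ROI's
#' generative profile: per sound, a neural event of amplitude
#' `slope_sign * gain * f(model amplitude)` (see [generative_profiles()]),
#' convolved with the canonical HRF on a fine microtime grid and sampled at
#' the TR; the profile baseline is added as a constant. Unlabelled voxels
#' are null. Each voxel then receives independent noise per [noise_spec()],
#' scaled so the expected temporal SNR equals the target.
#'
#' @param run A `run_schedule` from [build_run()].
#' @param grid A `voxel_grid` from [make_roi_grid()].
#' @param profiles Per-ROI profile tibble from [generative_profiles()];
#'   every profiled ROI must exist in the grid.
#' @param noise A `noise_spec`, or `NULL` for noise-free data.
#' @param tr Repetition time in seconds (1.6 in the pure-tone arm, 1.9 in
#'   the sweep arm).
#' @param seed Integer seed; identical seeds give identical data.
#' @param microtime Convolution grid step in seconds (default 0.05).
#' @param baseline Baseline for unprofiled (null) voxels.
#' @return An object of class `bold_run`: list with `data` (volumes x voxels
#'   matrix), `tr`, `n_volumes`, `frame_times`, plus the inputs' metadata.
#' @export
#' @examples
#' run <- build_run(seed = 1)
#' grid <- make_roi_grid(c(6, 6, 2), rois = NULL)
#' bold <- simulate_run(run, grid, tr = 1.6, seed = 2)
#' dim(bold$data)
simulate_run <- function(run, grid, profiles = NULL, noise = noise_spec(),
                         tr = 1.6, seed = NULL, microtime = 0.05,
                         baseline = 100) {
  stopifnot(inherits(run, "run_schedule"), inherits(grid, "voxel_grid"))
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (!is.null(profiles)) {
    assert_columns(profiles,
                   c("roi", "model", "gain", "baseline", "slope_sign"),
                   "`profiles`")
    unknown <- setdiff(profiles$roi, grid$roi)
    if (length(unknown) > 0L) {
      stop("profiles name ROI(s) absent from the grid: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  dur <- run_duration(run)
  n_volumes <- ceiling(dur / tr)
  frame_times <- (seq_len(n_volumes) - 1L) * tr
  grid_times <- seq(0, n_volumes * tr, by = microtime)
  events <- event_table(run) |>
    dplyr::left_join(dplyr::select(run$trials, "trial", "deviant_position"),
                     by = "trial")
  vol_idx <- round(frame_times / microtime) + 1L

  n_vox <- nrow(grid)
  data <- matrix(baseline, nrow = n_volumes, ncol = n_vox)
  if (!is.null(profiles)) {
    for (i in seq_len(nrow(profiles))) {
      prof <- profiles[i, ]
      vox <- which(grid$roi %in% prof$roi)
      if (length(vox) == 0L) next
      sig <- evoked_micro(events, prof, grid_times, microtime)[vol_idx]
      data[, vox] <- matrix(prof$baseline + sig, n_volumes, length(vox))
    }
  }
  with_seed(seed, {
    if (!is.null(noise)) {
      stopifnot(inherits(noise, "noise_spec"))
      w <- sqrt(noise$prop)
      drift_phase <- runif(n_vox, 0, 2 * pi)
      means <- colMeans(data)
      for (v in seq_len(n_vox)) {
        raw <- w[1] * ar1_series(n_volumes, noise$ar_coef) +
          w[2] * sqrt(2) *
            sin(2 * pi * frame_times / noise$drift_period + drift_phase[v]) +
          w[3] * rnorm(n_volumes)
        data[, v] <- data[, v] + raw * (means[v] / noise$tsnr)
      }
    }
    structure(
      list(data = data, tr = tr, n_volumes = n_volumes,
           frame_times = frame_times, noise = noise, seed = seed,
           microtime = microtime),
      class = "bold_run"
    )
  })
}

# Evoked microtime signal (baseline excluded) for one profile row.
evoked_micro <- function(events, profile, grid_times, microtime) {
  impulses <- numeric(length(grid_times))
  if (profile$model != "null" && profile$gain != 0) {
    am <- amplitude_model(profile$model)
    if (profile$model == "h2") am$amplitude <- 1 - am$amplitude
    ev <- dplyr::left_join(events, am,
                           by = c("deviant_position", "position"))
    idx <- pmin(floor(ev$onset / microtime) + 1L, length(impulses))
    amp <- profile$slope_sign * profile$gain * ev$amplitude
    for (k in seq_along(idx)) impulses[idx[k]] <- impulses[idx[k]] + amp[k]
  }
  h <- hrf(seq(0, 32, by = microtime))
  convolve(impulses, rev(h), type = "open")[seq_along(impulses)]
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d volumes x %d voxels, TR %.2f s (%.0f s)\n",
              x$n_volumes, ncol(x$data), x$tr, x$n_volumes * x$tr))
  invisible(x)
}

#' Tidy a simulated BOLD run into a long tibble
#'
#' @param x A `bold_run`.
#' @param ... Unused.
#' @return Tibble with columns `volume`, `time`, `voxel`, `signal`.
#' @export
tidy.bold_run <- function(x, ...) {
  tibble::tibble(
    volume = rep(seq_len(x$n_volumes), times = ncol(x$data)),
    time = rep(x$frame_times, times = ncol(x$data)),
    voxel = rep(seq_len(ncol(x$data)), each = x$n_volumes),
    signal = as.vector(x$data)
  )
}
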