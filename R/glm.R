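# First-level GLM: design matrices with parametric modulation, OLS fitting,
# and beta standardization.

CONDITIONS <- c("std0", "std1", "std2", "dev4", "dev5", "dev6")

#' Build a first-level design matrix
#'
#' Six task regressors (std0, std1, std2, dev4, dev5, dev6) are formed by
#' convolving unit impulses at the sound onsets with the canonical HRF on a
#' microtime grid and sampling at the volume times. std1 and std2 each
#' contribute an additional parametric-modulation column in which the event
#' impulses are weighted by the within-trial sound index, z-standardized
#' across the run's events of that condition before convolution. Nuisance
#' columns are an intercept, a linear trend, and a discrete-cosine high-pass
#' set up to `highpass` Hz.
#'
#' @param events Event tibble from [event_table()].
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes; every event must end within
#'   `n_volumes * tr`.
#' @param highpass Highest nuisance cosine frequency in Hz (default 1/120).
#' @param microtime Convolution grid step (s).
#' @return A `design_matrix`: numeric matrix (volumes x columns) with
#'   attributes `task_cols`, `condition_cols` (condition to main-effect
#'   column map), `tr`.
#' @export
#' @examples
#' run <- build_run(seed = 1)
#' X <- build_design_matrix(event_table(run), tr = 1.6, n_volumes = 400)
#' colnames(X)
build_design_matrix <- function(events, tr, n_volumes, highpass = 1 / 120,
                                microtime = 0.05) {
  assert_columns(events, c("onset", "duration", "trial_type", "modulator"),
                 "`events`")
  dur <- n_volumes * tr
  if (any(events$onset + events$duration > dur) || any(events$onset < 0)) {
    stop("events fall outside the run duration", call. = FALSE)
  }
  missing <- setdiff(CONDITIONS, unique(events$trial_type))
  if (length(missing) > 0L) {
    stop("events contain no occurrences of condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frame_times <- (seq_len(n_volumes) - 1L) * tr
  grid_times <- seq(0, dur, by = microtime)
  vol_idx <- round(frame_times / microtime) + 1L
  h <- hrf(seq(0, 32, by = microtime))

  conv_col <- function(onsets, weights) {
    imp <- numeric(length(grid_times))
    idx <- pmin(floor(onsets / microtime) + 1L, length(imp))
    for (k in seq_along(idx)) imp[idx[k]] <- imp[idx[k]] + weights[k]
    convolve(imp, rev(h), type = "open")[seq_along(imp)][vol_idx]
  }

  cols <- list()
  for (cond in CONDITIONS) {
    ev <- events[events$trial_type == cond, ]
    cols[[cond]] <- conv_col(ev$onset, rep(1, nrow(ev)))
    if (cond %in% c("std1", "std2")) {
      m <- ev$modulator
      mz <- (m - mean(m)) / sd(m)
      cols[[paste0(cond, "_mod")]] <- conv_col(ev$onset, mz)
    }
  }
  task_cols <- names(cols)

  cols$intercept <- rep(1, n_volumes)
  cols$trend <- seq(-0.5, 0.5, length.out = n_volumes)
  n_cos <- max(0L, floor(2 * dur * highpass))
  if (n_cos > 0L) {
    for (k in seq_len(n_cos)) {
      cols[[paste0("cos", k)]] <-
        cos(pi * k * (2 * seq_len(n_volumes) - 1) / (2 * n_volumes))
    }
  }
  X <- do.call(cbind, cols)
  structure(
    X,
    task_cols = task_cols,
    condition_cols = setNames(match(CONDITIONS, colnames(X)), CONDITIONS),
    tr = tr,
    class = c("design_matrix", "matrix", "array")
  )
}

#' Fit a voxel-wise ordinary-least-squares GLM
#'
#' @param bold A `bold_run` (or a plain volumes x voxels matrix).
#' @param X A design matrix from [build_design_matrix()] or
#'   [model_design()]; must have full column rank.
#' @return A `glm_fit`: list with `betas` (columns x voxels),
#'   `residual_variance` (per voxel), `dof` (`volumes - rank`), and the
#'   design's metadata.
#' @export
#' @examples
#' run <- build_run(seed = 1)
#' grid <- make_roi_grid(c(4, 4, 1), rois = NULL)
#' bold <- simulate_run(run, grid, tr = 1.6, seed = 2)
#' X <- build_design_matrix(event_table(run), 1.6, bold$n_volumes)
#' fit <- fit_glm(bold, X)
#' fit$dof
fit_glm <- function(bold, X) {
  Y <- if (inherits(bold, "bold_run")) bold$data else as.matrix(bold)
  if (nrow(Y) != nrow(X)) {
    stop("data and design have different numbers of volumes", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  dof <- nrow(Y) - qrX$rank
  rownames(betas) <- colnames(X)
  structure(
    list(betas = betas,
         residual_variance = colSums(res^2) / dof,
         dof = dof,
         task_cols = attr(X, "task_cols"),
         condition_cols = attr(X, "condition_cols")),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors x %d voxels, dof %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Extract per-condition beta estimates as a tidy table
#'
#' Condition estimates are taken from the unmodulated main-effect columns;
#' the parametric modulators are nuisance flexibility, not estimates.
#'
#' @param fit A `glm_fit`.
#' @param grid Optional `voxel_grid` supplying `roi` labels; voxels outside
#'   any ROI are dropped when a grid is given.
#' @return Tibble with columns `voxel`, (`roi`,) `condition`, `beta`.
#' @export
condition_betas <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  conds <- names(fit$condition_cols)
  if (is.null(conds)) {
    stop("fit has no condition columns (single-regressor model design?)",
         call. = FALSE)
  }
  b <- fit$betas[fit$condition_cols, , drop = FALSE]
  out <- tibble::tibble(
    voxel = rep(seq_len(ncol(b)), each = length(conds)),
    condition = rep(conds, times = ncol(b)),
    beta = as.vector(b)
  )
  if (!is.null(grid)) {
    out <- out |>
      dplyr::inner_join(dplyr::select(grid, "voxel", "roi"), by = "voxel") |>
      dplyr::filter(!is.na(.data$roi)) |>
      dplyr::select("voxel", "roi", "condition", "beta")
  }
  out
}

#' Tidy method for first-level fits
#'
#' @param x A `glm_fit`.
#' @param ... Passed to [condition_betas()] (e.g. `grid`).
#' @export
tidy.glm_fit <- function(x, ...) condition_betas(x, ...)

#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(
    n_regressors = nrow(x$betas),
    n_voxels = ncol(x$betas),
    dof = x$dof,
    median_residual_variance = median(x$residual_variance)
  )
}

#' z-standardize beta estimates within grouping slices
#'
#' Mirrors the standardization applied before second-level analyses: within
#' each (participant, run, ROI) slice, the beta values across voxels and
#' conditions are centred to mean 0 and scaled to sd 1. Ranks within a slice
#' are unchanged.
#'
#' @param betas Tidy beta table containing a `beta` column and the grouping
#'   columns.
#' @param grouping Character vector of grouping columns.
#' @return The input tibble with `beta` replaced by its standardized value
#'   and a logical `standardized` attribute-free marker column dropped.
#' @export
standardize_betas <- function(betas,
                              grouping = c("participant", "run", "roi")) {
  assert_columns(betas, c("beta", grouping), "`betas`")
  out <- betas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(.slice_sd = sd(.data$beta)) |>
    dplyr::ungroup()
  if (any(is.na(out$.slice_sd)) || any(out$.slice_sd < 1e-12)) {
    stop("zero-variance slice: cannot z-standardize", call. = FALSE)
  }
  betas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(beta = (.data$beta - mean(.data$beta)) / sd(.data$beta)) |>
    dplyr::ungroup()
}
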