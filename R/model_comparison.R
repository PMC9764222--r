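# Voxel-wise Bayesian comparison of the habituation (h1) and prediction-
# error (h2) amplitude models: single-regressor designs, conjugate linear-
# model evidence, random-effects BMS, and group maps.

#' Single-regressor model design for Bayesian comparison
#'
#' One task regressor whose event impulses carry the per-position amplitudes
#' of the chosen model (h1 or h2), z-standardized across the run's events
#' before convolution with the HRF. Because the amplitudes are centred, the
#' mean response common to every sound is carried by a shared unmodulated
#' all-sounds regressor (the zeroth-order term of a parametric modulation),
#' which — like the intercept, trend and cosine high-pass set — is identical
#' across models, so evidence differences reflect only the amplitude
#' profile.
#'
#' @param run A `run_schedule`.
#' @param model `"h1"` or `"h2"`.
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes the design must cover.
#' @param highpass,microtime As in [build_design_matrix()].
#' @return A `design_matrix` whose single task column is named after the
#'   model.
#' @export
model_design <- function(run, model = c("h1", "h2"), tr, n_volumes,
                         highpass = 1 / 120, microtime = 0.05) {
  model <- match.arg(model)
  stopifnot(inherits(run, "run_schedule"))
  events <- event_table(run) |>
    dplyr::left_join(dplyr::select(run$trials, "trial", "deviant_position"),
                     by = "trial") |>
    dplyr::left_join(amplitude_model(model),
                     by = c("deviant_position", "position"))
  dur <- n_volumes * tr
  if (any(events$onset + events$duration > dur)) {
    stop("events fall outside the run duration", call. = FALSE)
  }
  amp <- events$amplitude
  amp <- (amp - mean(amp)) / sd(amp)

  frame_times <- (seq_len(n_volumes) - 1L) * tr
  grid_times <- seq(0, dur, by = microtime)
  vol_idx <- round(frame_times / microtime) + 1L
  h <- hrf(seq(0, 32, by = microtime))
  conv_imp <- function(weights) {
    imp <- numeric(length(grid_times))
    idx <- pmin(floor(events$onset / microtime) + 1L, length(imp))
    for (k in seq_along(idx)) imp[idx[k]] <- imp[idx[k]] + weights[k]
    convolve(imp, rev(h), type = "open")[seq_along(imp)][vol_idx]
  }
  cols <- list()
  cols[[model]] <- conv_imp(amp)
  cols$sounds <- conv_imp(rep(1, nrow(events)))
  cols$intercept <- rep(1, n_volumes)
  cols$trend <- seq(-0.5, 0.5, length.out = n_volumes)
  n_cos <- max(0L, floor(2 * dur * highpass))
  for (k in seq_len(n_cos)) {
    cols[[paste0("cos", k)]] <-
      cos(pi * k * (2 * seq_len(n_volumes) - 1) / (2 * n_volumes))
  }
  X <- do.call(cbind, cols)
  structure(X, task_cols = model, condition_cols = NULL, tr = tr,
            model = model, class = c("design_matrix", "matrix", "array"))
}

#' Prior specification for the linear-model evidence
#'
#' Conjugate normal-inverse-gamma prior: coefficients
#' `b | s2 ~ N(0, s2 * g * (X'X)^-1)` (a unit-information g-prior with
#' `g = n` by default) and `s2 ~ IG(a0, b0)` with `b0` scaled to half the
#' sample variance of the data, which makes evidence *differences* between
#' models invariant to affine rescaling of the series.
#'
#' @param g g-prior scale; `NULL` means `n` (unit information).
#' @param a0 Inverse-gamma shape (default 1/2).
#' @param b0_scale `b0 = b0_scale * var(y)` (default 1/2).
#' @return List of class `evidence_prior`.
#' @export
evidence_prior <- function(g = NULL, a0 = 0.5, b0_scale = 0.5) {
  stopifnot(a0 > 0, b0_scale > 0)
  structure(list(g = g, a0 = a0, b0_scale = b0_scale),
            class = "evidence_prior")
}

#' Log marginal likelihood of a linear model
#'
#' Closed-form log evidence of `y = X b + e` under the conjugate
#' normal-inverse-gamma prior of [evidence_prior()], with `b` and the noise
#' variance integrated out analytically.
#'
#' @param y Numeric response vector, or a volumes x voxels matrix for a
#'   vectorised per-voxel computation.
#' @param X Full-column-rank design matrix.
#' @param prior An `evidence_prior`.
#' @return Scalar log evidence (or a vector, one per voxel column of `y`).
#' @export
#' @examples
#' X <- cbind(1, sin(1:20))
#' y <- X %*% c(1, 2) + rnorm(20)
#' log_evidence(y, X)
log_evidence <- function(y, X, prior = evidence_prior()) {
  Y <- as.matrix(y)
  n <- nrow(Y)
  if (nrow(X) != n) stop("length mismatch between y and X", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  g <- prior$g %||% n
  a0 <- prior$a0
  b0 <- prior$b0_scale * apply(Y, 2, var)

  # A constant column gets a flat prior and is integrated out in closed
  # form, which makes evidence differences shift-invariant: work with
  # centered data and the remaining (centered) columns under the g-prior.
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    Z <- scale(X[, !const, drop = FALSE], scale = FALSE)
    Yc <- scale(Y, scale = FALSE)
    n_eff <- n - 1L
    base <- -n_eff / 2 * log(2 * pi) - 0.5 * log(n)
  } else {
    Z <- X
    Yc <- Y
    n_eff <- n
    base <- -n / 2 * log(2 * pi)
  }
  p <- ncol(Z)
  an <- a0 + n_eff / 2
  yty <- colSums(Yc^2)
  if (p > 0L) {
    XtX <- crossprod(Z)
    XtY <- crossprod(Z, Yc)
    # V0 = g (Z'Z)^-1  =>  Vn^-1 = (1 + 1/g) Z'Z, mn = g/(g+1) * betahat;
    # det V0 = g^p / det(Z'Z), det Vn = (1 + 1/g)^-p / det(Z'Z), so
    # log det Vn - log det V0 = -p log(1 + g)
    shrink <- g / (g + 1)
    betahat <- solve(XtX, XtY)
    fit_term <- shrink * colSums(XtY * betahat)
    logdet_ratio <- -p * log1p(g)
  } else {
    fit_term <- 0
    logdet_ratio <- 0
  }
  bn <- b0 + 0.5 * (yty - fit_term)
  le <- base + 0.5 * logdet_ratio +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
  if (is.matrix(y) && ncol(y) > 1L) unname(le) else unname(le)[1]
}

#' Per-voxel log-evidence maps for both amplitude models
#'
#' @param bold A `bold_run` (or matrix).
#' @param run The generating `run_schedule`.
#' @param tr Repetition time (s).
#' @param prior An `evidence_prior`.
#' @param ... Passed to [model_design()].
#' @return Tibble: `voxel`, `model`, `log_evidence`.
#' @export
evidence_maps <- function(bold, run, tr = NULL, prior = evidence_prior(),
                          ...) {
  Y <- if (inherits(bold, "bold_run")) bold$data else as.matrix(bold)
  tr <- tr %||% (if (inherits(bold, "bold_run")) bold$tr else
    stop("`tr` required for matrix input", call. = FALSE))
  purrr::map_dfr(c("h1", "h2"), function(m) {
    X <- model_design(run, m, tr = tr, n_volumes = nrow(Y), ...)
    tibble::tibble(voxel = seq_len(ncol(Y)), model = m,
                   log_evidence = log_evidence(Y, X, prior))
  })
}

#' Random-effects Bayesian model selection
#'
#' Variational estimate of the Dirichlet posterior over model frequencies:
#' subject-level model responsibilities and Dirichlet concentrations are
#' updated alternately until the concentrations change by less than `tol`.
#' Expected posterior model probabilities are `r_k = alpha_k / sum(alpha)`;
#' exceedance probabilities are estimated from seeded Dirichlet draws.
#'
#' @param log_evidence Subjects x models matrix of log evidences (column
#'   names label the models).
#' @param alpha0 Dirichlet prior concentration per model (default 1).
#' @param tol Convergence tolerance on the concentrations (default 1e-6).
#' @param n_draws Dirichlet draws for the exceedance probability; 0 skips it.
#' @param seed Seed for the draws.
#' @return List of class `bms_result`: `alpha`, `r` (expected posterior),
#'   `exceedance` (or `NULL`), `responsibilities` (subjects x models).
#' @export
#' @examples
#' le <- cbind(h1 = c(-100, -102), h2 = c(-95, -99))
#' rfx_bms(le, n_draws = 1e4, seed = 1)
rfx_bms <- function(log_evidence, alpha0 = 1, tol = 1e-6, n_draws = 1e6,
                    seed = NULL) {
  le <- as.matrix(log_evidence)
  if (any(!is.finite(le))) stop("non-finite log evidences", call. = FALSE)
  n_sub <- nrow(le)
  n_mod <- ncol(le)
  if (n_mod < 2L) stop("need at least 2 models", call. = FALSE)
  models <- colnames(le) %||% paste0("m", seq_len(n_mod))
  alpha <- rep(alpha0, n_mod)
  repeat {
    lu <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(lu - apply(lu, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  xp <- NULL
  if (n_draws > 0) {
    xp <- with_seed(seed, {
      draws <- matrix(rgamma(n_draws * n_mod, shape = rep(alpha, each = n_draws)),
                      nrow = n_draws)
      best <- max.col(draws, ties.method = "first")
      tabulate(best, n_mod) / n_draws
    })
    names(xp) <- models
  }
  structure(
    list(alpha = setNames(alpha, models),
         r = setNames(alpha / sum(alpha), models),
         exceedance = xp,
         responsibilities = `colnames<-`(u, models)),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = names(x$alpha),
    alpha = unname(x$alpha),
    posterior = unname(x$r),
    exceedance = if (is.null(x$exceedance)) NA_real_ else
      unname(x$exceedance)
  )
}

#' Group posterior and Bayes-factor maps from per-subject evidences
#'
#' Per voxel: the fixed-effects group Bayes factor
#' `K_h2/h1 = exp(sum over subjects of (logE_h2 - logE_h1))`, and the
#' random-effects expected posterior probabilities of each model from
#' [rfx_bms()] (without exceedance sampling). A voxel "favors" h2 when its
#' RFX posterior exceeds 0.5.
#'
#' @param evidence Tidy evidence table with columns `subject`, `voxel`,
#'   `model` (`"h1"`/`"h2"`), `log_evidence`, optionally `roi`.
#' @param alpha0 Dirichlet prior concentration per model.
#' @return A tibble of class `posterior_maps`: `voxel`, (`roi`,) `log_K`,
#'   `K`, `alpha_h1`, `alpha_h2`, `post_h1`, `post_h2`, `favors_h2`.
#' @export
group_maps <- function(evidence, alpha0 = 1) {
  assert_columns(evidence, c("subject", "voxel", "model", "log_evidence"),
                 "`evidence`")
  stopifnot(all(evidence$model %in% c("h1", "h2")))
  have_roi <- "roi" %in% names(evidence)
  keys <- c("voxel", if (have_roi) "roi")
  wide <- evidence |>
    tidyr::pivot_wider(names_from = "model", values_from = "log_evidence")
  if (any(!complete.cases(wide[, c("h1", "h2")]))) {
    stop("each subject x voxel needs both models' evidences", call. = FALSE)
  }
  out <- wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      bms <- rfx_bms(cbind(h1 = df$h1, h2 = df$h2), alpha0 = alpha0,
                     n_draws = 0)
      tibble::tibble(
        log_K = sum(df$h2 - df$h1),
        alpha_h1 = bms$alpha[["h1"]], alpha_h2 = bms$alpha[["h2"]],
        post_h1 = bms$r[["h1"]], post_h2 = bms$r[["h2"]]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(K = exp(.data$log_K), favors_h2 = .data$post_h2 > 0.5) |>
    dplyr::relocate("K", .after = "log_K")
  class(out) <- c("posterior_maps", class(out))
  out
}

#' Per-ROI summary of the model comparison
#'
#' @param maps A `posterior_maps` tibble with an `roi` column.
#' @return Tibble: `roi`, `n_voxels`, `frac_h2` (fraction of voxels whose
#'   RFX posterior favors h2), `median_K`, `median_log_K`.
#' @export
roi_model_summary <- function(maps) {
  assert_columns(maps, c("roi", "favors_h2", "log_K"), "`maps`")
  maps |>
    dplyr::filter(!is.na(.data$roi)) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      frac_h2 = mean(.data$favors_h2),
      median_K = median(.data$K),
      median_log_K = median(.data$log_K),
      .groups = "drop"
    )
}
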