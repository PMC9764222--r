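# Predictability-response statistics within SSA ROIs: pairwise signed-rank
# contrasts, linear mixed-effects models, per-participant Spearman.

# Predictability of the deviant by condition.
DEV_PREDICTABILITY <- c(dev4 = 1 / 3, dev5 = 1 / 2, dev6 = 1)

#' Holm-Bonferroni adjustment with an explicit family size
#'
#' Step-down Holm adjustment in which the correction family may be larger
#' than the number of p-values supplied (e.g. when the same contrasts are
#' run in several ROIs and corrected jointly: families of 30 or 48 tests).
#'
#' @param p Numeric vector of raw p-values.
#' @param family Total family size; defaults to `length(p)`, giving the
#'   ordinary Holm adjustment.
#' @return Adjusted p-values, monotone in the raw values.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))
holm_adjust <- function(p, family = length(p)) {
  stopifnot(family >= length(p))
  ord <- order(p)
  adj <- pmin(1, (family - seq_along(p) + 1) * p[ord])
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Pairwise signed-rank contrasts between conditions
#'
#' Group-level Wilcoxon signed-rank tests on per-participant condition
#' means (betas averaged across runs and voxels within participant and SSA
#' ROI): the ordered deviant contrasts `dev4 > dev5`, `dev4 > dev6`,
#' `dev5 > dev6` (one-sided), the effect-size contrasts `std0 > std2` and
#' `dev4 > std2` (one-sided), and `dev6 != std2` (two-sided; under
#' prediction error fully predictable deviants should not differ from
#' standards). Zero paired differences are dropped; the exact null is used
#' for n <= 25 tie-free samples, otherwise a continuity-corrected normal
#' approximation. P-values are Holm-adjusted over `family` comparisons.
#'
#' @param betas Tidy beta table for one SSA ROI with columns `participant`,
#'   `condition`, `beta` (and optionally `run`, `voxel`, averaged out first).
#' @param family Holm family size (default: the 6 contrasts).
#' @return Tibble: `contrast`, `alternative`, `statistic`, `p_raw`,
#'   `p_holm`, `n_participants`.
#' @export
pairwise_tests <- function(betas, family = 6L) {
  assert_columns(betas, c("participant", "condition", "beta"), "`betas`")
  means <- betas |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(beta = mean(.data$beta), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "beta")
  n <- nrow(means)
  if (n < 5L) stop("need at least 5 participants", call. = FALSE)
  contrasts <- tibble::tribble(
    ~contrast,      ~a,     ~b,     ~alternative,
    "dev4>dev5",    "dev4", "dev5", "greater",
    "dev4>dev6",    "dev4", "dev6", "greater",
    "dev5>dev6",    "dev5", "dev6", "greater",
    "dev6!=std2",   "dev6", "std2", "two.sided",
    "std0>std2",    "std0", "std2", "greater",
    "dev4>std2",    "dev4", "std2", "greater"
  )
  res <- purrr::pmap_dfr(contrasts, function(contrast, a, b, alternative) {
    d <- means[[a]] - means[[b]]
    d <- d[d != 0]
    if (length(d) == 0L) {
      return(tibble::tibble(contrast = contrast, alternative = alternative,
                            statistic = NA_real_, p_raw = 1,
                            n_participants = n))
    }
    exact <- length(d) <= 25L && !any(duplicated(abs(d)))
    w <- suppressWarnings(
      wilcox.test(d, alternative = alternative, exact = exact, correct = TRUE)
    )
    tibble::tibble(contrast = contrast, alternative = alternative,
                   statistic = unname(w$statistic), p_raw = w$p.value,
                   n_participants = n)
  })
  res$p_holm <- holm_adjust(res$p_raw, family = max(family, nrow(res)))
  res
}

#' Fit the group-level predictability mixed model
#'
#' Fits `beta ~ 1 + predictability + (1 + predictability | run) +
#' (1 + predictability | participant)` (plus an analogous session term when
#' a `session` column is present) by REML via `lmerTest`, with deviant
#' predictability coded 1/3, 1/2 and 1 for dev4, dev5 and dev6.
#' Observations are voxel x run level deviant betas. Satterthwaite degrees
#' of freedom and Wald confidence limits are reported; singular fits are
#' flagged, not dropped.
#'
#' @param betas Tidy beta table with `participant`, `run`, `condition`
#'   (dev4/dev5/dev6 rows are used), `beta`, optionally `session`.
#' @return An object of class `oddball_lmm` wrapping the `lmerModLmerTest`
#'   fit; see [tidy.oddball_lmm()].
#' @export
fit_lmm <- function(betas) {
  assert_columns(betas, c("participant", "run", "condition", "beta"),
                 "`betas`")
  data <- betas |>
    dplyr::filter(.data$condition %in% names(DEV_PREDICTABILITY)) |>
    dplyr::mutate(
      predictability = unname(DEV_PREDICTABILITY[.data$condition]),
      participant = factor(.data$participant),
      run = factor(.data$run)
    )
  if (nrow(data) == 0L) stop("no deviant-condition rows", call. = FALSE)
  has_session <- "session" %in% names(data) &&
    length(unique(data$session)) > 1L
  form <- beta ~ 1 + predictability + (1 + predictability | participant)
  # random terms need more than one sampled level
  if (length(unique(data$run)) > 1L) {
    form <- stats::update(form, . ~ . + (1 + predictability | run))
  }
  if (has_session) {
    data$session <- factor(data$session)
    form <- stats::update(form, . ~ . + (1 + predictability | session))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = data, REML = TRUE)
  ))
  structure(
    list(fit = fit, singular = lme4::isSingular(fit),
         n_obs = nrow(data), has_session = has_session),
    class = "oddball_lmm"
  )
}

#' @export
print.oddball_lmm <- function(x, ...) {
  cat(sprintf("<oddball_lmm> %d observations%s\n", x$n_obs,
              if (x$singular) " (singular fit)" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy the predictability mixed model
#'
#' @param x An `oddball_lmm` from [fit_lmm()].
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return Tibble with one row per fixed effect: `term`, `estimate`,
#'   `std_error`, `df`, `statistic`, `p_value`, `conf_low`, `conf_high`,
#'   `singular`.
#' @export
tidy.oddball_lmm <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  df <- s[, "df"]
  half <- qt(1 - (1 - conf_level) / 2, df) * s[, "Std. Error"]
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    df = df,
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"],
    conf_low = s[, "Estimate"] - half,
    conf_high = s[, "Estimate"] + half,
    singular = x$singular
  )
}

#' @export
glance.oddball_lmm <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    sigma = stats::sigma(x$fit),
    logLik = as.numeric(stats::logLik(x$fit)),
    REMLcrit = lme4::REMLcrit(x$fit),
    singular = x$singular
  )
}

#' Mixed-model report across SSA ROIs with Bonferroni correction
#'
#' Fits [fit_lmm()] within each ROI of the supplied beta table and
#' Bonferroni-corrects the fixed-effect p-values for the number of ROIs
#' tested.
#'
#' @param betas Tidy beta table with a `roi` column (deviant conditions
#'   only are used).
#' @param n_rois Correction family; defaults to the number of distinct ROIs.
#' @return Tibble: `roi`, `term`, `estimate`, `df`, `p_value`,
#'   `p_bonferroni`, `conf_low`, `conf_high`, `singular`.
#' @export
lmm_report <- function(betas, n_rois = NULL) {
  assert_columns(betas, "roi", "`betas`")
  rois <- sort(unique(betas$roi))
  n_rois <- n_rois %||% length(rois)
  purrr::map_dfr(rois, function(r) {
    fit <- fit_lmm(dplyr::filter(betas, .data$roi == r))
    dplyr::mutate(tidy(fit), roi = r, .before = 1)
  }) |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$p_value * n_rois)) |>
    dplyr::select("roi", "term", "estimate", "df", "p_value",
                  "p_bonferroni", "conf_low", "conf_high", "singular")
}

#' Per-participant Spearman correlation of predictability and deviant betas
#'
#' Within each participant, deviant betas (dev4, dev5, dev6) are averaged
#' across runs per voxel, and Spearman's rank correlation is computed across
#' all (voxel, deviant condition) observations against deviant
#' predictability (1/3, 1/2, 1). With many voxels sharing three
#' predictability levels the data are heavily tied, so the large-sample
#' approximation is used.
#'
#' @param betas Tidy beta table with `participant`, `voxel`, `condition`,
#'   `beta`, optionally `run`.
#' @return Tibble: `participant`, `rho`, `p_value`, `n_obs`, `defined`.
#' @export
spearman_predictability <- function(betas) {
  assert_columns(betas, c("participant", "voxel", "condition", "beta"),
                 "`betas`")
  betas |>
    dplyr::filter(.data$condition %in% names(DEV_PREDICTABILITY)) |>
    dplyr::group_by(.data$participant, .data$voxel, .data$condition) |>
    dplyr::summarise(beta = mean(.data$beta), .groups = "drop") |>
    dplyr::mutate(predictability = unname(DEV_PREDICTABILITY[.data$condition])) |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(df, key) {
      if (sd(df$beta) == 0 || sd(df$predictability) == 0) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                              n_obs = nrow(df), defined = FALSE))
      }
      ct <- suppressWarnings(
        cor.test(df$beta, df$predictability, method = "spearman",
                 exact = FALSE)
      )
      tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                     n_obs = nrow(df), defined = TRUE)
    }) |>
    dplyr::ungroup()
}
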