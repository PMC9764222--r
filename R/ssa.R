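# SSA detection and quantification: rank-sum contrasts, FDR-controlled
# conjunction, cluster extraction, and the SSA index map.

#' Right-tailed rank-sum test (Wilcoxon/Mann-Whitney)
#'
#' Exact null distribution when both samples are tie-free (via the Wilcoxon
#' distribution), otherwise a normal approximation with tie correction and
#' continuity correction — matching `wilcox.test()`.
#'
#' @param x,y Numeric samples; the alternative is that `x` is stochastically
#'   greater than `y`.
#' @return Tibble with `statistic` (Mann-Whitney U), `p_value`, `exact`.
#' @export
#' @examples
#' rank_sum_test(c(3, 4, 5), c(1, 2))
rank_sum_test <- function(x, y) {
  res <- ranksum_right(matrix(x, ncol = 1), matrix(y, ncol = 1))
  tibble::tibble(statistic = res$u, p_value = res$p, exact = res$exact)
}

# Vectorised right-tailed rank-sum over the columns of X (n1 x V) vs Y
# (n2 x V). Returns U statistics and p-values.
ranksum_right <- function(X, Y) {
  n1 <- nrow(X); n2 <- nrow(Y); n <- n1 + n2
  Z <- rbind(X, Y)
  R <- apply(Z, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, nrow = n)
  U <- colSums(R[seq_len(n1), , drop = FALSE]) - n1 * (n1 + 1) / 2
  ties <- apply(Z, 2, function(z) {
    t <- table(z)
    sum(t^3 - t)
  })
  exact <- ties == 0 & n1 < 50 & n2 < 50
  p <- numeric(ncol(Z))
  if (any(exact)) {
    p[exact] <- pwilcox(U[exact] - 1, n1, n2, lower.tail = FALSE)
  }
  if (any(!exact)) {
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - ties[!exact] / (n * (n - 1))))
    z <- (U[!exact] - mu - 0.5) / sigma
    p[!exact] <- pnorm(z, lower.tail = FALSE)
  }
  list(u = U, p = p, exact = exact)
}

#' Voxel-wise rank-sum contrast across participants
#'
#' Implements the repetition-suppression (adaptation) and neuronal-mismatch
#' (deviant-detection) indices as group-level tests: per voxel, the
#' participant sample of std0 (adaptation) or dev4 (deviant detection) is
#' compared against the participant sample of the averaged adapted standards,
#' `0.5 * std1 + 0.5 * std2`, with a right-tailed rank-sum test. Betas are
#' first averaged across runs within participant.
#'
#' @param betas Tidy beta table with columns `participant`, `voxel`,
#'   `condition`, `beta` and optionally `run`, `roi`.
#' @param contrast `"adaptation"` (std0 greater) or `"deviant_detection"`
#'   (dev4 greater).
#' @return Tibble with one row per voxel: `voxel`, (`roi`,) `statistic`, `p`.
#' @export
voxelwise_contrast_test <- function(betas,
                                    contrast = c("adaptation",
                                                 "deviant_detection")) {
  contrast <- match.arg(contrast)
  assert_columns(betas, c("participant", "voxel", "condition", "beta"),
                 "`betas`")
  target <- if (contrast == "adaptation") "std0" else "dev4"
  have_roi <- "roi" %in% names(betas)
  keys <- c("voxel", if (have_roi) "roi")
  avg <- betas |>
    dplyr::filter(.data$condition %in% c(target, "std1", "std2")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("participant", keys, "condition")))) |>
    dplyr::summarise(beta = mean(.data$beta), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "beta") |>
    dplyr::mutate(reference = 0.5 * .data$std1 + 0.5 * .data$std2)
  n_part <- length(unique(avg$participant))
  if (n_part < 3L) stop("need at least 3 participants", call. = FALSE)
  avg <- dplyr::arrange(avg, .data$voxel, .data$participant)
  vox_tab <- dplyr::distinct(avg, dplyr::across(dplyr::all_of(keys)))
  X <- matrix(avg[[target]], nrow = n_part)
  Y <- matrix(avg$reference, nrow = n_part)
  res <- ranksum_right(X, Y)
  dplyr::bind_cols(vox_tab, tibble::tibble(statistic = res$u, p = res$p))
}

#' Conjunction of adaptation and deviant detection with FDR control
#'
#' The SSA p-value of a voxel is the maximum of its uncorrected adaptation
#' and deviant-detection p-values (a conjunction: both effects must be
#' present). All voxels' SSA p-values are then Benjamini-Hochberg adjusted
#' jointly (or within ROI with `per_roi_fdr = TRUE`) and thresholded at
#' `alpha`. Peak-level family-wise correction is reported per ROI: the
#' smallest SSA p-value Bonferroni-corrected by the ROI's voxel count, then
#' Holm-adjusted across ROIs.
#'
#' @param p_adapt,p_dev Per-voxel p tables from [voxelwise_contrast_test()]
#'   (same voxels, same order not required; joined on `voxel`/`roi`).
#' @param alpha FDR level (default 0.05).
#' @param per_roi_fdr Apply BH within each ROI instead of pooled.
#' @return A tibble of class `contrast_result`: `voxel`, (`roi`,)
#'   `p_adaptation`, `p_deviant_detection`, `p_ssa`, `q_ssa`, `significant`;
#'   the per-ROI peak table is attached as attribute `"peaks"` (see
#'   [peak_table()]).
#' @export
ssa_conjunction <- function(p_adapt, p_dev, alpha = 0.05,
                            per_roi_fdr = FALSE) {
  assert_columns(p_adapt, c("voxel", "p"), "`p_adapt`")
  assert_columns(p_dev, c("voxel", "p"), "`p_dev`")
  if (nrow(p_adapt) != nrow(p_dev)) {
    stop("p-maps cover different numbers of voxels", call. = FALSE)
  }
  keys <- intersect(c("voxel", "roi"), intersect(names(p_adapt), names(p_dev)))
  out <- dplyr::inner_join(
    dplyr::select(p_adapt, dplyr::all_of(keys), p_adaptation = "p"),
    dplyr::select(p_dev, dplyr::all_of(keys), p_deviant_detection = "p"),
    by = keys
  )
  if (nrow(out) != nrow(p_adapt)) {
    stop("p-maps do not align on the same voxels", call. = FALSE)
  }
  out$p_ssa <- pmax(out$p_adaptation, out$p_deviant_detection)
  if (per_roi_fdr && "roi" %in% keys) {
    out <- out |>
      dplyr::group_by(.data$roi) |>
      dplyr::mutate(q_ssa = p.adjust(.data$p_ssa, "BH")) |>
      dplyr::ungroup()
  } else {
    out$q_ssa <- p.adjust(out$p_ssa, "BH")
  }
  out$significant <- out$q_ssa <= alpha
  if ("roi" %in% keys) {
    peaks <- out |>
      dplyr::group_by(.data$roi) |>
      dplyr::summarise(
        n_voxels = dplyr::n(),
        peak_p = min(.data$p_ssa),
        peak_p_bonf = pmin(1, min(.data$p_ssa) * dplyr::n()),
        .groups = "drop"
      ) |>
      dplyr::mutate(peak_p_fwe = p.adjust(.data$peak_p_bonf, "holm"))
    attr(out, "peaks") <- peaks
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("contrast_result", class(out))
  out
}

#' Per-ROI peak-level corrected p-values of a conjunction result
#'
#' @param result A `contrast_result` from [ssa_conjunction()].
#' @return Tibble: `roi`, `n_voxels`, `peak_p`, `peak_p_bonf` (Bonferroni by
#'   ROI voxel count), `peak_p_fwe` (additionally Holm across ROIs).
#' @export
peak_table <- function(result) {
  p <- attr(result, "peaks")
  if (is.null(p)) stop("result carries no ROI information", call. = FALSE)
  p
}

#' Extract connected clusters from a significance mask
#'
#' Connected components are computed within each ROI under 26-connectivity
#' (voxels touching by face, edge or corner). Each cluster reports its size,
#' its peak voxel (smallest SSA p, ties broken by lowest linear voxel
#' index), and the peak's corrected p-value (Bonferroni by ROI voxel count,
#' Holm across the clusters of the table).
#'
#' @param result A `contrast_result` with `significant` and `p_ssa` columns
#'   (or any tibble with `voxel`, `roi`, `significant`, `p_ssa`).
#' @param grid The `voxel_grid` the voxels refer to.
#' @return Tibble: `roi`, `cluster`, `size`, `peak_x`, `peak_y`, `peak_z`,
#'   `peak_p`, `peak_p_fwe`.
#' @export
extract_clusters <- function(result, grid) {
  assert_columns(result, c("voxel", "roi", "significant", "p_ssa"),
                 "`result`")
  stopifnot(inherits(grid, "voxel_grid"))
  sig <- result[result$significant & !is.na(result$roi), ]
  roi_sizes <- result |>
    dplyr::filter(!is.na(.data$roi)) |>
    dplyr::count(.data$roi, name = "n_voxels")
  if (nrow(sig) == 0L) {
    return(tibble::tibble(roi = character(), cluster = integer(),
                          size = integer(), peak_x = integer(),
                          peak_y = integer(), peak_z = integer(),
                          peak_p = numeric(), peak_p_fwe = numeric()))
  }
  sig <- dplyr::inner_join(sig, dplyr::select(grid, "voxel", "x", "y", "z"),
                           by = "voxel")
  out <- sig |>
    dplyr::group_split(.data$roi) |>
    purrr::map_dfr(function(df) {
      labels <- connected_components(df[, c("x", "y", "z")])
      df$cluster <- labels
      df |>
        dplyr::group_by(.data$roi, .data$cluster) |>
        dplyr::arrange(.data$p_ssa, .data$voxel, .by_group = TRUE) |>
        dplyr::summarise(
          size = dplyr::n(),
          peak_x = dplyr::first(.data$x),
          peak_y = dplyr::first(.data$y),
          peak_z = dplyr::first(.data$z),
          peak_p = dplyr::first(.data$p_ssa),
          .groups = "drop"
        )
    }) |>
    dplyr::left_join(roi_sizes, by = "roi") |>
    dplyr::mutate(peak_p_bonf = pmin(1, .data$peak_p * .data$n_voxels),
                  peak_p_fwe = p.adjust(.data$peak_p_bonf, "holm")) |>
    dplyr::select("roi", "cluster", "size", "peak_x", "peak_y", "peak_z",
                  "peak_p", "peak_p_fwe") |>
    dplyr::arrange(.data$roi, dplyr::desc(.data$size))
  out |>
    dplyr::group_by(.data$roi) |>
    dplyr::mutate(cluster = dplyr::row_number()) |>
    dplyr::ungroup()
}

# Label connected components of a voxel coordinate set, 26-connectivity.
# Breadth-first search over a hashed coordinate lookup.
connected_components <- function(coords) {
  n <- nrow(coords)
  key <- paste(coords$x, coords$y, coords$z, sep = ",")
  index <- setNames(seq_len(n), key)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  labels <- integer(n)
  current <- 0L
  for (start in seq_len(n)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0L) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      nb_keys <- paste(coords$x[i] + offsets[, 1],
                       coords$y[i] + offsets[, 2],
                       coords$z[i] + offsets[, 3], sep = ",")
      hits <- index[nb_keys]
      hits <- hits[!is.na(hits)]
      new <- hits[labels[hits] == 0L]
      labels[new] <- current
      queue <- c(queue, new)
    }
  }
  labels
}

#' Compute the voxel-wise SSA index map
#'
#' Per voxel, the dev4, std1 and std2 beta values pooled across participants
#' and runs are min-max normalized to `[0, 1]`, averaged per condition, and
#' combined into
#' `SSAi = (dev4 - 0.5 std1 - 0.5 std2) / (dev4 + 0.5 std1 + 0.5 std2)`,
#' bounded in `[-1, 1]`. Voxels with a zero denominator (or a degenerate
#' constant pool) are flagged undefined.
#'
#' @param betas Tidy beta table with `voxel`, `condition`, `beta` and
#'   optionally `roi`, `participant`, `run`.
#' @return A tibble of class `ssa_map`: `voxel`, (`roi`,) `ssai`, `defined`.
#' @export
ssai_map <- function(betas) {
  assert_columns(betas, c("voxel", "condition", "beta"), "`betas`")
  keys <- c("voxel", intersect("roi", names(betas)))
  out <- betas |>
    dplyr::filter(.data$condition %in% c("dev4", "std1", "std2")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      .range = max(.data$beta) - min(.data$beta),
      .norm = ifelse(.data$.range > 0,
                     (.data$beta - min(.data$beta)) / .data$.range, NA_real_)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "condition")))) |>
    dplyr::summarise(value = mean(.data$.norm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    dplyr::mutate(
      .num = .data$dev4 - 0.5 * .data$std1 - 0.5 * .data$std2,
      .den = .data$dev4 + 0.5 * .data$std1 + 0.5 * .data$std2,
      defined = is.finite(.data$.num) & is.finite(.data$.den) &
        abs(.data$.den) > .Machine$double.eps,
      ssai = ifelse(.data$defined, .data$.num / .data$.den, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(keys), "ssai", "defined")
  class(out) <- c("ssa_map", class(out))
  out
}
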