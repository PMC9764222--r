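test_that("right-tailed rank-sum p-values match exhaustive enumeration", {
  expect_equal(rank_sum_test(c(3, 4, 5), c(1, 2))$p_value,
               ranksum_enum_p(c(3, 4, 5), c(1, 2)))
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    expect_equal(rank_sum_test(x, y)$p_value, ranksum_enum_p(x, y),
                 tolerance = 1e-12)
    # and agree with the reference implementation
    expect_equal(rank_sum_test(x, y)$p_value,
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("identically distributed samples give p of at least one half", {
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 2, 4, 4, 0)
  got <- rank_sum_test(x, y)
  expect_false(got$exact)
  ref <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", correct = TRUE)
  )
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("voxelwise contrasts test the right samples after run-averaging", {
  set.seed(12)
  tbl <- tidyr::expand_grid(participant = 1:8, run = 1:2, voxel = 1:3,
                            roi = "A",
                            condition = c("std0", "std1", "std2", "dev4")) |>
    dplyr::mutate(beta = rnorm(dplyr::n()))
  got <- voxelwise_contrast_test(tbl, "adaptation")
  expect_equal(nrow(got), 3L)
  # oracle for voxel 2: run-average, then right-tailed rank-sum by hand
  avg <- tbl |>
    dplyr::filter(voxel == 2) |>
    dplyr::group_by(participant, condition) |>
    dplyr::summarise(beta = mean(beta), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = beta)
  expect_equal(got$p[got$voxel == 2],
               ranksum_enum_p(avg$std0, 0.5 * avg$std1 + 0.5 * avg$std2))
  # adaptation weights on (std0, std1, std2) are (1, -0.5, -0.5)
  dev <- voxelwise_contrast_test(tbl, "deviant_detection")
  avg4 <- tbl |>
    dplyr::filter(voxel == 1) |>
    dplyr::group_by(participant, condition) |>
    dplyr::summarise(beta = mean(beta), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = beta)
  expect_equal(dev$p[dev$voxel == 1],
               ranksum_enum_p(avg4$dev4, 0.5 * avg4$std1 + 0.5 * avg4$std2))
  small <- dplyr::filter(tbl, participant <= 2)
  expect_error(voxelwise_contrast_test(small), "3 participants")
})

test_that("the SSA conjunction takes the elementwise maximum p-value", {
  pa <- tibble::tibble(voxel = 1:4, roi = "A", p = c(0.01, 0.2, 1, 0.03))
  pd <- tibble::tibble(voxel = 1:4, roi = "A", p = c(0.04, 0.1, 1, 0.5))
  res <- ssa_conjunction(pa, pd)
  expect_equal(res$p_ssa, c(0.04, 0.2, 1, 0.5))
  expect_error(ssa_conjunction(pa, pd[1:3, ]), "different numbers")
})

test_that("BH rejections match the step-up rule by definition", {
  pa <- tibble::tibble(voxel = 1:4, p = c(0.01, 0.02, 0.03, 0.5))
  pd <- tibble::tibble(voxel = 1:4, p = c(0.005, 0.01, 0.02, 0.4))
  res <- ssa_conjunction(pa, pd, alpha = 0.05)
  expect_equal(sum(res$significant), 3L)
  set.seed(3)
  for (i in 1:10) {
    p <- runif(50)^2
    pa <- tibble::tibble(voxel = 1:50, p = p)
    res <- ssa_conjunction(pa, pa, alpha = 0.05)
    expect_equal(res$significant, bh_reject_def(p, 0.05))
  }
  # all p = 1 leaves the mask empty
  ones <- tibble::tibble(voxel = 1:10, p = rep(1, 10))
  expect_equal(sum(ssa_conjunction(ones, ones)$significant), 0L)
})

test_that("peak-level correction is Bonferroni by ROI size then Holm", {
  set.seed(8)
  pa <- tibble::tibble(voxel = 1:60, roi = rep(c("A", "B", "C"), each = 20),
                       p = runif(60))
  res <- ssa_conjunction(pa, pa)
  pk <- peak_table(res)
  by_hand <- tapply(res$p_ssa, res$roi, min) * 20
  expect_equal(pk$peak_p_bonf, unname(pmin(1, by_hand)))
  expect_equal(pk$peak_p_fwe, holm_def(pmin(1, unname(by_hand))))
})

test_that("cluster extraction matches an independent flood fill", {
  dims <- c(12, 12, 6)
  grid <- make_roi_grid(dims, rois = tibble::tibble(
    roi = "A", x0 = 1, x1 = 12, y0 = 1, y1 = 12, z0 = 1, z1 = 6))
  set.seed(21)
  sig <- runif(nrow(grid)) < 0.05
  res <- tibble::tibble(voxel = grid$voxel, roi = grid$roi,
                        significant = sig, p_ssa = runif(nrow(grid)))
  cl <- extract_clusters(res, grid)
  mask <- array(FALSE, dims)
  mask[grid$voxel[sig]] <- TRUE
  labels <- flood_fill_labels(mask)
  expect_equal(nrow(cl), max(labels))
  expect_equal(sort(cl$size), sort(unname(table(labels[labels > 0]))),
               ignore_attr = TRUE)
})

test_that("26-connectivity joins diagonal voxels; disjoint blobs split", {
  grid <- make_roi_grid(c(6, 6, 2), rois = tibble::tibble(
    roi = "A", x0 = 1, x1 = 6, y0 = 1, y1 = 6, z0 = 1, z1 = 2))
  # diagonal pair (1,1,1) and (2,2,2): one cluster under 26-connectivity
  sel <- (grid$x == 1 & grid$y == 1 & grid$z == 1) |
    (grid$x == 2 & grid$y == 2 & grid$z == 2)
  res <- tibble::tibble(voxel = grid$voxel, roi = grid$roi,
                        significant = sel, p_ssa = 0.01)
  expect_equal(nrow(extract_clusters(res, grid)), 1L)
  # two separated 3-voxel bars: two clusters of size 3
  sel2 <- (grid$y == 1 & grid$z == 1 & grid$x <= 3) |
    (grid$y == 5 & grid$z == 2 & grid$x >= 4)
  res2 <- tibble::tibble(voxel = grid$voxel, roi = grid$roi,
                         significant = sel2, p_ssa = 0.01)
  cl2 <- extract_clusters(res2, grid)
  expect_equal(cl2$size, c(3L, 3L))
  # empty mask gives an empty table
  res3 <- dplyr::mutate(res2, significant = FALSE)
  expect_equal(nrow(extract_clusters(res3, grid)), 0L)
})

test_that("cluster peaks take the smallest p, ties broken by voxel index", {
  grid <- make_roi_grid(c(4, 1, 1), rois = tibble::tibble(
    roi = "A", x0 = 1, x1 = 4, y0 = 1, y1 = 1, z0 = 1, z1 = 1))
  res <- tibble::tibble(voxel = 1:4, roi = "A", significant = TRUE,
                        p_ssa = c(0.02, 0.01, 0.01, 0.03))
  cl <- extract_clusters(res, grid)
  expect_equal(cl$peak_x, 2L) # voxel 2 wins the tie with voxel 3
  expect_equal(cl$peak_p, 0.01)
})

test_that("the SSA index reproduces hand-computed values and its bounds", {
  mk <- function(d4, s1, s2) {
    tibble::tibble(voxel = 1, participant = rep(1:4, 3),
                   condition = rep(c("dev4", "std1", "std2"), each = 4),
                   beta = c(d4, s1, s2))
  }
  # equal normalized means: SSAi 0
  v <- c(0.1, 0.4, 0.7, 1.0)
  expect_equal(ssai_map(mk(v, v, v))$ssai, 0)
  # dev4 at the top of the range, standards at the bottom: SSAi 1
  top <- c(1, 1, 1, 1) * 2
  bot <- c(0, 0, 0, 0)
  m <- ssai_map(mk(top, bot, bot))
  expect_equal(m$ssai, 1)
  # direct formula evaluation at normalized means (0.25, 0.5, 0.5)
  tbl <- tibble::tibble(
    voxel = 1, participant = 1,
    condition = c("dev4", "std1", "std2", "dev4", "std1", "std2"),
    run = rep(1:2, each = 3),
    beta = c(0.25, 0.5, 0.5, 0, 1, 0.5) # pooled range already [0, 1]
  )
  pooled <- tbl$beta
  norm <- (pooled - min(pooled)) / diff(range(pooled))
  means <- tapply(norm, tbl$condition, mean)
  expected <- (means[["dev4"]] - 0.5 * means[["std1"]] - 0.5 * means[["std2"]]) /
    (means[["dev4"]] + 0.5 * means[["std1"]] + 0.5 * means[["std2"]])
  expect_equal(ssai_map(tbl)$ssai, expected)
  # bounded wherever defined
  set.seed(9)
  big <- tidyr::expand_grid(voxel = 1:50, participant = 1:5,
                            condition = c("dev4", "std1", "std2")) |>
    dplyr::mutate(beta = rnorm(dplyr::n()))
  m2 <- ssai_map(big)
  expect_true(all(m2$ssai[m2$defined] >= -1 & m2$ssai[m2$defined] <= 1))
})

test_that("degenerate SSA index voxels are flagged undefined", {
  tbl <- tibble::tibble(voxel = 1, participant = 1:3,
                        condition = rep("dev4", 3), beta = c(1, 2, 3)) |>
    dplyr::bind_rows(tibble::tibble(voxel = 1, participant = 1:3,
                                    condition = rep(c("std1"), 3),
                                    beta = c(1, 2, 3)),
                     tibble::tibble(voxel = 1, participant = 1:3,
                                    condition = rep(c("std2"), 3),
                                    beta = c(1, 2, 3)))
  const <- dplyr::mutate(tbl, beta = 5) # constant pool: no range
  m <- ssai_map(const)
  expect_false(m$defined)
  expect_true(is.na(m$ssai))
})

test_that("signal voxels are recovered with high sensitivity", {
  # 19 participants, 2 runs; 200 signal voxels under h1/h2 at defaults,
  # detection via the full conjunction + BH path
  grid <- make_roi_grid(c(10, 20, 1), rois = tibble::tibble(
    roi = c("H1", "H2"), x0 = c(1, 1), x1 = c(10, 10),
    y0 = c(1, 11), y1 = c(10, 20), z0 = 1, z1 = 1))
  profiles <- generative_profiles(c("H1", "H2"), model = c("h1", "h2"))
  betas <- purrr::map_dfr(1:19, function(s) {
    purrr::map_dfr(1:2, function(r) {
      run <- build_run(seed = 1000 + 10 * s + r)
      bold <- simulate_run(run, grid, profiles, noise = noise_spec(),
                           tr = 1.6, seed = 2000 + 10 * s + r)
      X <- build_design_matrix(event_table(run), 1.6, bold$n_volumes)
      condition_betas(fit_glm(bold, X), grid) |>
        dplyr::mutate(participant = s, run = r)
    })
  })
  betas <- standardize_betas(betas)
  res <- ssa_conjunction(voxelwise_contrast_test(betas, "adaptation"),
                         voxelwise_contrast_test(betas, "deviant_detection"))
  expect_gte(mean(res$significant), 0.8)
})
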