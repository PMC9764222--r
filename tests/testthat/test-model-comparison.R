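test_that("model designs carry the standardized amplitude regressor", {
  run <- build_run(seed = 13)
  n_vol <- ceiling(oddbold:::run_duration(run) / 1.6)
  X1 <- model_design(run, "h1", 1.6, n_vol)
  X2 <- model_design(run, "h2", 1.6, n_vol)
  expect_equal(colnames(X1)[1], "h1")
  expect_equal(colnames(X2)[1], "h2")
  # designs differ only in the single task column
  expect_equal(X1[, -1], X2[, -1])
  expect_false(isTRUE(all.equal(X1[, 1], X2[, 1])))
  # pre-standardization amplitudes of a deviant-5 trial follow the model
  ev <- event_table(run) |>
    dplyr::left_join(dplyr::select(run$trials, trial, deviant_position),
                     by = "trial") |>
    dplyr::left_join(amplitude_model("h2"),
                     by = c("deviant_position", "position"))
  t5 <- run$trials$trial[run$trials$deviant_position == 5][1]
  expect_equal(ev$amplitude[ev$trial == t5],
               c(1/2, 1, 1, 2/3, 1/2, 1, 1, 1))
  # post-standardization amplitudes have mean 0 within the run
  amps <- ev$amplitude
  expect_lt(abs(mean((amps - mean(amps)) / sd(amps))), 1e-12)
})

test_that("log evidence matches dense numerical quadrature on toys", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (i in 1:5) {
    n <- 10
    X <- cbind(1, rnorm(n))
    y <- X %*% rnorm(2) + rnorm(n, sd = runif(1, 0.3, 2))
    expect_equal(log_evidence(y, X),
                 log_evidence_quadrature(y, X),
                 tolerance = 1e-6)
  }
  # prior variants round-trip through the same oracle
  X <- cbind(1, sin(1:12), cos(1:12))
  y <- matrix(rnorm(12))
  pr <- evidence_prior(g = 4, a0 = 1.2, b0_scale = 0.8)
  expect_equal(log_evidence(y, X, pr),
               log_evidence_quadrature(y, X, g = 4, a0 = 1.2,
                                       b0 = 0.8 * var(as.numeric(y))),
               tolerance = 1e-6)
})

test_that("identical designs give zero evidence difference", {
  set.seed(1)
  X <- cbind(1, rnorm(20))
  y <- rnorm(20)
  expect_equal(log_evidence(y, X) - log_evidence(y, X), 0)
  expect_error(log_evidence(y, cbind(X, X[, 2])), "rank deficient")
  expect_error(log_evidence(y, X[1:10, ]), "mismatch")
})

test_that("a pure-noise regressor pays an Occam penalty on null data", {
  set.seed(55)
  worse <- 0L
  for (i in 1:100) {
    n <- 40
    X0 <- cbind(intercept = rep(1, n))
    X1 <- cbind(X0, junk = rnorm(n))
    y <- rnorm(n)
    worse <- worse + (log_evidence(y, X1, evidence_prior(g = n)) <
                        log_evidence(y, X0, evidence_prior(g = n)))
  }
  expect_gt(worse, 50)
})

test_that("evidence differences are invariant to affine rescaling", {
  run <- build_run(seed = 17)
  n_vol <- ceiling(oddbold:::run_duration(run) / 1.6)
  X1 <- model_design(run, "h1", 1.6, n_vol)
  X2 <- model_design(run, "h2", 1.6, n_vol)
  set.seed(2)
  y <- 100 + X2[, 1] * 0.5 + rnorm(n_vol)
  d0 <- log_evidence(y, X2) - log_evidence(y, X1)
  y2 <- 7.3 * y - 50
  d1 <- log_evidence(y2, X2) - log_evidence(y2, X1)
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("RFX BMS handles the symmetric and trivial cases exactly", {
  # all subjects indifferent: posterior (0.5, 0.5) exactly
  le <- matrix(c(-100, -100, -50, -50), 2, byrow = TRUE,
               dimnames = list(NULL, c("h1", "h2")))
  r <- rfx_bms(le, n_draws = 0)
  expect_equal(unname(r$r), c(0.5, 0.5))
  # single subject, zero evidence difference: alpha = (1.5, 1.5)
  one <- rfx_bms(matrix(c(0, 0), 1, dimnames = list(NULL, c("h1", "h2"))),
                 n_draws = 0)
  expect_equal(unname(one$alpha), c(1.5, 1.5))
  expect_error(rfx_bms(matrix(c(NA, 1), 1)), "finite")
})

test_that("RFX posteriors match dense grid integration", {
  # 10 subjects favoring h2 by 10 nats each
  le <- cbind(h1 = rep(-105, 10), h2 = rep(-95, 10))
  r <- rfx_bms(le, n_draws = 1e5, seed = 3)
  expect_gt(r$r[["h2"]], 0.9)
  expect_equal(unname(r$r[["h2"]]), rfx_grid_posterior(le), tolerance = 0.02)
  # mixed cohort
  set.seed(6)
  le2 <- cbind(h1 = rnorm(8, -100), h2 = rnorm(8, -100) + c(3, 3, 3, 3, 3, -2, -2, 0))
  r2 <- rfx_bms(le2, n_draws = 0)
  expect_equal(unname(r2$r[["h2"]]), rfx_grid_posterior(le2), tolerance = 0.02)
})

test_that("exceedance probabilities are seeded and consistent", {
  le <- cbind(h1 = rep(-102, 5), h2 = rep(-100, 5))
  a <- rfx_bms(le, n_draws = 2e4, seed = 11)
  b <- rfx_bms(le, n_draws = 2e4, seed = 11)
  expect_identical(a$exceedance, b$exceedance)
  expect_equal(sum(a$exceedance), 1)
  expect_gt(a$exceedance[["h2"]], 0.5)
})

test_that("group maps combine FFX Bayes factors and RFX posteriors", {
  ev <- tidyr::expand_grid(subject = 1:4, voxel = 1:3,
                           model = c("h1", "h2")) |>
    dplyr::mutate(log_evidence = -100 +
                    ifelse(model == "h2",
                           dplyr::case_when(voxel == 1 ~ 1,
                                            voxel == 2 ~ -1,
                                            TRUE ~ 0),
                           0))
  maps <- group_maps(ev)
  # FFX additivity: log K is the sum of per-subject differences
  expect_equal(maps$log_K, c(4, -4, 0))
  expect_equal(maps$K, exp(maps$log_K))
  # zero summed difference gives K = 1
  expect_equal(maps$K[maps$voxel == 3], 1)
  expect_equal(maps$post_h1 + maps$post_h2, rep(1, 3))
  expect_error(group_maps(ev[-1, ]), "both models")
})

test_that("per-ROI summaries count voxels favoring h2", {
  maps <- tibble::tibble(voxel = 1:3, roi = "A",
                         log_K = c(2, 0.5, -1), K = exp(c(2, 0.5, -1)),
                         post_h2 = c(0.9, 0.6, 0.3),
                         favors_h2 = c(TRUE, TRUE, FALSE))
  s <- roi_model_summary(maps)
  expect_equal(s$frac_h2, 2 / 3)
  expect_equal(s$median_K, exp(0.5))
})

test_that("model recovery is symmetric between h1 and h2 cohorts", {
  # same seeds, swapped generative profiles; 6 subjects, 8 voxels, 2 runs
  grid <- make_roi_grid(c(4, 2, 1), rois = tibble::tibble(
    roi = "A", x0 = 1, x1 = 4, y0 = 1, y1 = 2, z0 = 1, z1 = 1))
  run_cohort <- function(model) {
    purrr::map_dfr(1:6, function(s) {
      purrr::map_dfr(1:2, function(r) {
        run <- build_run(seed = 40 + 10 * s + r)
        bold <- simulate_run(run, grid, generative_profiles("A", model),
                             noise = noise_spec(), tr = 1.6,
                             seed = 70 + 10 * s + r)
        evidence_maps(bold, run) |> dplyr::mutate(subject = s)
      }) |>
        dplyr::group_by(subject, voxel, model) |>
        dplyr::summarise(log_evidence = sum(log_evidence), .groups = "drop")
    })
  }
  m_h2 <- group_maps(run_cohort("h2"))
  m_h1 <- group_maps(run_cohort("h1"))
  expect_gt(mean(m_h2$post_h2 > 0.5), 0.8)
  expect_gt(mean(m_h1$post_h1 > 0.5), 0.8)
})
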