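make_trace <- function(rt, intensity, mz = 630.3) {
  structure(list(mz = mz, ppm = 15, drift_center = 3, drift_tol = 0.5,
                 rt = rt, intensity = intensity), class = "xic_trace")
}

test_that("iRT calibration is an exact affine fit with guarded degenerate input", {
  std <- data.frame(irt = c(10, 30, 50, 70, 90),
                    rt = 0.5 * c(10, 30, 50, 70, 90) + 10)
  cal <- fit_irt(std)
  expect_equal(cal$slope, 0.5)
  expect_equal(cal$intercept, 10)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-12)
  expect_equal(predict_rt(cal, c(0, 40)), c(10, 30))

  expect_error(fit_irt(std[1, ]), ">= 2 standards")
  expect_error(fit_irt(data.frame(irt = c(20, 20), rt = c(5, 6))),
               "distinct iRT")

  # noisy standards: slope recovered within 3 standard errors
  set.seed(91)
  slopes <- replicate(60, {
    irt <- seq(10, 100, length.out = 10)
    fit_irt(data.frame(irt = irt, rt = 0.35 * irt + 5 +
                         rnorm(10, 0, 0.1)))$slope
  })
  se <- 0.1 / sqrt(sum((seq(10, 100, length.out = 10) -
                          mean(seq(10, 100, length.out = 10)))^2))
  expect_lt(abs(mean(slopes) - 0.35), 3 * se / sqrt(60))
})

test_that("drift-restricted XICs separate coeluting isobars", {
  grid <- seq(0, 10, by = 0.02)
  peak <- function(apex, area, sd = 0.05) {
    idx <- which(grid >= apex - 5 * sd & grid <= apex + 5 * sd)
    list(idx = idx,
         intensity = area / (sd * sqrt(2 * pi)) *
           exp(-(grid[idx] - apex)^2 / (2 * sd^2)))
  }
  target <- peak(5, 1000)
  isobar <- peak(5.03, 800)
  run <- run_data("r1", "DONOR", group = "RA", sex = "F", batch = 1,
                  time_grid = grid, signals = list(
    c(list(mz = 630.300, drift_ms = 3.3), target, feature_id = "t"),
    c(list(mz = 630.302, drift_ms = 5.1), isobar, feature_id = "i")))

  with_drift <- extract_xic(run, 630.3, ppm = 15, drift_center = 3.3,
                            drift_tol = 0.5)
  without <- extract_xic(run, 630.3, ppm = 15, drift_center = NULL)
  a_with <- integrate_peak(with_drift)$area
  a_without <- integrate_peak(without)$area
  expect_equal(a_with, 1000, tolerance = 1e-3)
  expect_gt(a_without, 1700)  # the merged isobars integrate together

  # a window with nothing in it yields a zero trace, not an error
  void <- extract_xic(run, 900, ppm = 15, drift_center = 3.3)
  expect_true(all(void$intensity == 0))
  expect_equal(integrate_peak(void)$area, 0)

  # linearity: doubling every signal doubles the area
  run2 <- run
  run2$signals <- lapply(run$signals, function(s) {
    s$intensity <- 2 * s$intensity
    s
  })
  expect_equal(integrate_peak(extract_xic(run2, 630.3, 15, 3.3))$area,
               2 * a_with, tolerance = 1e-12)
})

test_that("peak integration matches the analytic Gaussian area", {
  # amplitude 1000, sd 0.05 min, 1.2 s cycle
  sd <- 0.05
  grid <- seq(0, 4, by = 1.2 / 60)
  y <- 1000 * exp(-(grid - 2)^2 / (2 * sd^2))
  y[abs(grid - 2) > 5 * sd] <- 0
  pk <- integrate_peak(make_trace(grid, y), rt_window = c(1, 3))
  analytic <- 1000 * sd * sqrt(2 * pi)
  expect_lt(abs(pk$area - analytic) / analytic, 0.01)
  expect_gte(pk$points_across_peak, 9)
  expect_false(pk$few_points)

  # the same peak sampled at a 6 s cycle has too few points
  grid6 <- seq(0, 4, by = 6 / 60)
  y6 <- 1000 * exp(-(grid6 - 2)^2 / (2 * sd^2))
  y6[abs(grid6 - 2) > 5 * sd] <- 0
  pk6 <- integrate_peak(make_trace(grid6, y6), rt_window = c(1, 3))
  expect_lt(pk6$points_across_peak, 9)
  expect_true(pk6$few_points)

  # a window that excludes the apex integrates only tail
  pk_tail <- integrate_peak(make_trace(grid, y), rt_window = c(2.3, 3.0))
  expect_lt(pk_tail$area, 1e-6 * analytic)

  # flat-zero trace
  pk0 <- integrate_peak(make_trace(grid, numeric(length(grid))))
  expect_equal(pk0$area, 0)
  expect_equal(pk0$points_across_peak, 0)
})

test_that("signal-to-background flags use strict thresholds and a floor", {
  areas <- data.frame(feature_id = c("f1", "f1", "f2"),
                      run_id = c("r1", "r2", "r1"),
                      batch = 1L, area = c(300, 3000, 50))
  nc <- data.frame(feature_id = c("f1", "f2"), batch = 1L,
                   nc_area = c(100, 100))
  sb <- signal_to_background(areas, nc)
  expect_equal(sb$s_b_ratio, c(3, 30, 0.5))
  expect_equal(sb$sb_gt3, c(FALSE, TRUE, FALSE))   # strictly greater
  expect_equal(sb$sb_gt10, c(FALSE, TRUE, FALSE))

  # a zero NC area is floored instead of dividing by zero
  nc0 <- data.frame(feature_id = c("f1", "f2"), batch = 1L,
                    nc_area = c(0, 100))
  sb0 <- signal_to_background(areas, nc0)
  expect_true(all(is.finite(sb0$s_b_ratio)))

  expect_error(signal_to_background(
    areas, data.frame(feature_id = "f1", batch = 1L, nc_area = 100)),
    "missing negative-control")

  # interference: NC apex above the feature apex
  areas$apex_intensity <- c(500, 500, 10)
  nc$nc_apex <- c(100, 200)
  sbi <- signal_to_background(areas, nc)
  expect_equal(sbi$interference, c(FALSE, FALSE, TRUE))
})

test_that("per-batch CVs follow the hand calculation", {
  mat <- rbind(f1 = c(100, 100, 100, 80, 100, 120),
               f2 = c(90, 100, 110, 100, 100, 100),
               f3 = c(0, 0, 0, 1, 1, 1))
  design <- data.frame(run_id = paste0("q", 1:6), sample_type = "SPQC",
                       group = NA, sex = NA, batch = rep(1:2, each = 3))
  colnames(mat) <- design$run_id
  expect_warning(cv <- cv_per_batch(mat, design), "zero mean")
  expect_equal(cv$cv["f1", "batch1"], 0)
  expect_equal(cv$cv["f2", "batch1"], 10, tolerance = 1e-9)
  expect_equal(cv$cv["f1", "batch2"], 20, tolerance = 1e-9)
  expect_true(is.na(cv$cv["f3", "batch1"]))
  # f1 (CV 0) and f2 (CV 10) pass in batch 1; f1 at exactly 20 fails (strict)
  expect_equal(unname(cv$pass_fraction["batch1"]), 1)
  expect_equal(unname(cv$pass_fraction["batch2"]), 2 / 3)

  expect_error(cv_per_batch(mat[, 1:3], design), "fewer than 2")
})

test_that("top-5 normalization is scale-invariant and handles small proteins", {
  runs <- paste0("r", 1:4)
  mod <- matrix(runif(8, 50, 150), 2, 4,
                dimnames = list(c("m1", "m2"), runs))
  peps <- matrix(rep(c(1000, 900, 800, 700, 600, 500, 300, 200, 100), 4),
                 9, 4, dimnames = list(
                   c(paste0("A_p", 1:6), paste0("B_p", 1:3)), runs))
  pep_protein <- setNames(c(rep("A", 6), rep("B", 3)), rownames(peps))
  feature_protein <- c(m1 = "A", m2 = "B")

  out <- top5_normalize(mod, feature_protein, peps, pep_protein)
  # protein A uses its top 5 of 6 peptides, protein B all 3
  expect_equal(out$protein_abundance["A", 1], sum(c(1000, 900, 800, 700, 600)))
  expect_equal(out$protein_abundance["B", 1], sum(c(300, 200, 100)))

  # doubling a protein's peptides and its modified peptide cancels out
  mod2 <- mod
  mod2["m1", ] <- 2 * mod["m1", ]
  peps2 <- peps
  peps2[pep_protein == "A", ] <- 2 * peps[pep_protein == "A", ]
  out2 <- top5_normalize(mod2, feature_protein, peps2, pep_protein)
  expect_equal(out2$adjusted["m1", ], out$adjusted["m1", ])

  # missing protein: unadjusted with a flag
  fp <- c(m1 = "A", m2 = "ZZZ")
  out3 <- top5_normalize(mod, fp, peps, pep_protein)
  expect_equal(out3$unadjusted_features, "m2")
  expect_equal(out3$adjusted["m2", ], mod["m2", ])
})

test_that("the group comparison is exact under zero noise and guarded", {
  design <- data.frame(run_id = paste0("d", 1:12), sample_type = "DONOR",
                       group = rep(c("RA", "CONTROL"), each = 6),
                       sex = "F", batch = rep(1:2, 6))
  # identical group means, zero noise: log2FC exactly 0
  mat <- matrix(100, 2, 12, dimnames = list(c("f1", "f2"), design$run_id))
  res <- differential_test(mat, design)
  expect_equal(res$log2fc, c(0, 0))
  expect_false(any(res$significant))

  # a planted clean 4-fold effect is found
  mat2 <- mat
  set.seed(3)
  noise <- matrix(2^rnorm(24, 0, 0.1), 2, 12)
  mat2[, design$group == "RA"] <- 400
  mat2 <- mat2 * noise
  res2 <- differential_test(mat2, design)
  expect_true(all(res2$significant))
  expect_equal(res2$log2fc, c(2, 2), tolerance = 0.25)

  # BH adjustment is monotone and never below the raw p
  expect_true(all(res2$adj_p >= res2$p_value - 1e-12))

  # a feature missing one group entirely is skipped with a flag
  mat3 <- mat2
  mat3["f1", design$group == "RA"] <- NA
  res3 <- differential_test(mat3, design)
  expect_true(res3$skipped[res3$feature_id == "f1"])

  expect_error(
    differential_test(mat, design[design$group == "RA", , drop = FALSE]),
    "both groups")
})
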