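test_that("block randomization balances every group-by-sex stratum", {
  # 30 same-stratum donors split 15/15
  uni <- data.frame(donor_id = sprintf("d%02d", 1:30), group = "RA",
                    sex = "F")
  b <- block_randomize(uni, 2, seed = 1)
  expect_equal(as.vector(table(b$batch)), c(15L, 15L))

  # the full study design: 39 RA (30 F / 9 M), 29 controls (16 F / 13 M)
  donors <- data.frame(
    donor_id = sprintf("d%02d", 1:68),
    group = c(rep("RA", 39), rep("CONTROL", 29)),
    sex = c(rep("F", 30), rep("M", 9), rep("F", 16), rep("M", 13)))
  b2 <- block_randomize(donors, 2, seed = 42)
  counts <- table(b2$group, b2$sex, b2$batch)
  for (g in dimnames(counts)[[1]]) {
    for (s in dimnames(counts)[[2]]) {
      expect_lte(abs(counts[g, s, 1] - counts[g, s, 2]), 1)
    }
  }

  # deterministic under a seed, different across seeds
  expect_identical(block_randomize(donors, 2, seed = 42)$batch, b2$batch)
  expect_false(identical(block_randomize(donors, 2, seed = 43)$batch,
                         b2$batch))

  expect_error(block_randomize(donors[0, ], 2), "empty donor list")
})

test_that("simulated DDA spectra carry the expected ions", {
  reg <- load_modification_registry()
  p <- peptide_ion("LKCASLQK",
                   mods = data.frame(
                     pos = c(2L, 3L),
                     mass = c(arp_shift(reg$aminoadipic_semialdehyde),
                              reg$carbamidomethyl$delta_mass)),
                   charge = 2L)
  s <- simulate_dda_spectrum(p, include_reporters = TRUE, seed = 8)
  expect_lte(min(abs(s$peaks$mz - 706.355)), 0.025)
  expect_lte(min(abs(s$peaks$mz - 227.08)), 0.025)

  # unlabeled peptides carry no reporter peaks (guard band keeps noise away)
  u <- simulate_dda_spectrum(peptide_ion("LKCASLQK", charge = 2),
                             include_reporters = FALSE, seed = 9)
  expect_true(all(vapply(reporter_ion_table()$mz, function(r) {
    min(abs(u$peaks$mz - r)) > 0.025
  }, logical(1))))

  # zero m/z noise reproduces the chemistry exactly
  s0 <- simulate_dda_spectrum(p, mz_noise_mda = 0, precursor_noise_mda = 0,
                              n_noise_peaks = 0, seed = 10)
  theo <- fragment_table(p, charge = 1L)
  for (m in theo$mz) expect_lt(min(abs(s0$peaks$mz - m)), 1e-9)
  expect_equal(s0$precursor_mz, precursor_mz(p))
})

test_that("the default cohort has the study's shape and determinism", {
  ch <- simulate_cohort(small_cohort_spec(), seed = 19)
  tab <- table(ch$design$sample_type)
  expect_equal(unname(tab["DONOR"]), 12L)
  expect_equal(unname(tab["SPQC"]), 6L)
  expect_equal(unname(tab["EFQC"]), 6L)
  expect_equal(unname(tab["NC"]), 2L)
  expect_equal(length(ch$runs), nrow(ch$design))
  # NC runs carry no group
  expect_true(all(is.na(ch$design$group[ch$design$sample_type == "NC"])))
  # groups balanced within batch by randomization strata
  don <- ch$design[ch$design$sample_type == "DONOR", ]
  expect_lte(abs(sum(don$group[don$batch == 1] == "RA") -
                   sum(don$group[don$batch == 2] == "RA")), 1)

  ch2 <- simulate_cohort(small_cohort_spec(), seed = 19)
  expect_identical(ch$truth$donor_area, ch2$truth$donor_area)
  ch3 <- simulate_cohort(small_cohort_spec(), seed = 20)
  expect_false(identical(ch$truth$donor_area, ch3$truth$donor_area))

  # full-design defaults mirror the study: 68 donors + 6 SPQC + EF-QCs + NCs
  spec <- cohort_spec()
  expect_equal(spec$n_ra + spec$n_control, 68L)
  expect_equal(spec$n_features, 86L)
  expect_equal(spec$batch2_decay, 0.218)
})

test_that("integrated areas recover the planted areas almost exactly", {
  spec <- small_cohort_spec(rt_slope_jitter = 0, rt_intercept_jitter_min = 0,
                            rt_feature_jitter_min = 0)
  ch <- simulate_cohort(spec, seed = 23)
  lib <- ch$library
  for (i in seq_along(lib)) lib[[i]]$feature_id <- ch$features$feature_id[i]
  q <- quantify_cohort(ch$runs, lib, ch$design)
  don_runs <- ch$design$run_id[ch$design$sample_type == "DONOR"]
  got <- q$matrix[, don_runs]
  want <- ch$truth$donor_area[rownames(got), don_runs]
  expect_lt(max(abs(got / want - 1)), 1e-4)

  # and the signal-to-background ratios equal the planted ratios
  sb <- signal_to_background(q$areas[q$areas$sample_type == "DONOR", ],
                             q$nc_areas)
  planted <- ch$truth$sb_ratio[cbind(sb$feature_id, sb$run_id)]
  expect_lt(max(abs(sb$s_b_ratio / planted - 1)), 1e-3)
})

test_that("planted S/B and CV fractions are recovered through the pipeline", {
  ch <- simulate_cohort(small_cohort_spec(), seed = 29)
  lib <- ch$library
  for (i in seq_along(lib)) lib[[i]]$feature_id <- ch$features$feature_id[i]
  q <- quantify_cohort(ch$runs, lib, ch$design)
  sb <- signal_to_background(q$areas[q$areas$sample_type == "DONOR", ],
                             q$nc_areas)
  expect_equal(sum(sb$sb_gt3), unname(ch$truth$sb_counts["gt3"]))
  expect_equal(sum(sb$sb_gt10), unname(ch$truth$sb_counts["gt10"]))

  cv <- cv_per_batch(q$matrix, ch$design, qc_type = "SPQC")
  expect_equal(unname(cv$pass_fraction),
               unname(colMeans(ch$truth$qc_pass)))
})

test_that("unknown-shift planting validates its input", {
  set.seed(31)
  feats <- default_cohort_features(8, 3)
  dda <- simulate_dda_collection(feats, n_unassigned = 3, n_plain = 2)
  dda0 <- plant_unknown_shift(dda, feats, "C3H2N2O", n_sites = 0)
  expect_equal(nrow(dda0$planted), 0)
  expect_error(plant_unknown_shift(dda, feats, "O1N-1H-3", n_sites = 2),
               "positive mass")
  dda2 <- plant_unknown_shift(dda, feats, "C3H2N2O", n_sites = 5, seed = 4)
  expect_equal(nrow(dda2$planted), 5)
  expect_equal(length(dda2$spectra), length(dda$spectra) + 5)
  # every planted spectrum carries reporters and shares its source sequence
  for (k in seq_len(5)) {
    sid <- dda2$planted$spectrum_id[k]
    s <- Filter(function(x) x$id == sid, dda2$spectra)[[1]]
    expect_false(is.null(screen_spectrum(s)))
  }
})
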