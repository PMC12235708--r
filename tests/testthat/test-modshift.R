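reg <- load_modification_registry()
cam <- reg$carbamidomethyl$delta_mass

# the canonical anchor: allysine-modified, carbamidomethylated LKCASLQK
make_anchor <- function(noise = 0, seed = 101) {
  p <- peptide_ion("LKCASLQK",
                   mods = data.frame(
                     pos = c(2L, 3L),
                     mass = c(arp_shift(reg$aminoadipic_semialdehyde), cam),
                     name = c("aminoadipic_semialdehyde", "carbamidomethyl")),
                   charge = 2L)
  sp <- simulate_dda_spectrum(p, include_reporters = TRUE, rt_min = 31.8,
                              mz_noise_mda = noise, precursor_noise_mda = 0,
                              n_noise_peaks = 0, id = "anchor_scan",
                              seed = seed)
  anchor_peptide(p, sp)
}

# a candidate carrying `total` instead of the anchor's site modification
make_candidate <- function(total, noise = 0, seed = 102, rt = 33.4) {
  p <- peptide_ion("LKCASLQK",
                   mods = data.frame(pos = c(2L, 3L), mass = c(total, cam),
                                     name = c("unknown", "carbamidomethyl")),
                   charge = 2L)
  simulate_dda_spectrum(p, include_reporters = TRUE, rt_min = rt,
                        mz_noise_mda = noise, precursor_noise_mda = 0,
                        n_noise_peaks = 0, id = "cand_scan", seed = seed)
}

test_that("an anchor matches its own spectrum completely", {
  a <- make_anchor()
  m <- match_shared_fragments(a, a$spectrum)
  expect_equal(nrow(m), sum(a$observed))
  h <- infer_shift(a, a$spectrum, m)
  expect_true(h$identity)
  expect_equal(h$precursor_delta_da, 0, tolerance = 1e-6)
  # the identity hypothesis inherits the anchor's underivatized delta
  expect_equal(h$underivatized_delta_da,
               reg$aminoadipic_semialdehyde$delta_mass, tolerance = 1e-4)
})

test_that("the shared C-terminal ladder localizes the unknown Lys shift", {
  a <- make_anchor()
  total <- arp_shift(reg$unknown_82)  # +395.138 at Lys2
  cand <- make_candidate(total)

  # the diagnostic y6 ion sits at the printed m/z in both spectra
  y6 <- fragment_mz(a$peptide, "y", 6)
  expect_equal(round(y6, 3), 706.355)
  expect_true(min(abs(cand$peaks$mz - y6)) <= 0.025)

  # precursor drift offset of the two species stays within the gate
  expect_lt(abs(cand$drift_ms - a$spectrum$drift_ms), 0.5)

  m <- match_shared_fragments(a, cand)
  # exactly the unshifted prefix/suffix fragments match: b1 and y1..y6
  expect_setequal(paste0(m$series, m$index),
                  c("b1", paste0("y", 1:6)))

  h <- infer_shift(a, cand, m)
  expect_false(h$ambiguous)
  expect_equal(c(h$site_lo, h$site_hi), c(2L, 2L))
  expect_equal(h$total_mod_mass_da, total, tolerance = 2e-3)
  # underivatized delta falls within the 82.02 +/- 0.01 window
  expect_lt(abs(h$underivatized_delta_da - 82.02), 0.01)
  comps <- propose_compositions(h, tol = 0.01)
  expect_true("C3H2N2O" %in% comps$formula[1:3])
})

test_that("precursor deltas are antisymmetric in anchor and candidate", {
  a <- make_anchor()
  total <- arp_shift(reg$unknown_82)
  cand <- make_candidate(total)
  m <- match_shared_fragments(a, cand)
  h <- infer_shift(a, cand, m)

  p_cand <- peptide_ion("LKCASLQK",
                        mods = data.frame(pos = c(2L, 3L),
                                          mass = c(total, cam)),
                        charge = 2L)
  a2 <- anchor_peptide(p_cand, cand)
  m2 <- match_shared_fragments(a2, a$spectrum)
  h2 <- infer_shift(a2, a$spectrum, m2)
  expect_equal(h2$precursor_delta_da, -h$precursor_delta_da, tolerance = 1e-9)
})

test_that("planted shifts on a 10-mer are localized with mDa accuracy", {
  set.seed(56)
  reg <- load_modification_registry()
  arp <- arp_shift(reg$aminoadipic_semialdehyde)
  base <- peptide_ion("AVLKSTGDYR",
                      mods = data.frame(pos = 4L, mass = arp,
                                        name = "aminoadipic_semialdehyde"),
                      charge = 2L)
  a_sp <- simulate_dda_spectrum(base, TRUE, rt_min = 20, id = "a10",
                                seed = 561)
  a <- anchor_peptide(base, a_sp)
  delta <- monoisotopic_mass("C4H4O3")
  cand_p <- peptide_ion("AVLKSTGDYR",
                        mods = data.frame(pos = 4L, mass = arp + delta,
                                          name = "planted"),
                        charge = 2L)
  errs <- vapply(1:20, function(i) {
    cand <- simulate_dda_spectrum(cand_p, TRUE, rt_min = 21,
                                  id = sprintf("c10_%d", i), seed = 600 + i)
    m <- match_shared_fragments(a, cand)
    h <- infer_shift(a, cand, m)
    expect_equal(c(h$site_lo, h$site_hi), c(4L, 4L))
    h$precursor_delta_da - delta
  }, numeric(1))
  # recovered within 2 mDa given sub-mDa precursor noise
  expect_lt(max(abs(errs)), 2e-3)
})

test_that("the drift gate and guards reject unusable candidates", {
  a <- make_anchor()
  cand <- make_candidate(arp_shift(reg$unknown_82))
  far <- cand
  far$drift_ms <- cand$drift_ms + 2
  expect_equal(nrow(match_shared_fragments(a, far)), 0)

  # absent drift time: constraint skipped with a warning
  nodrift <- cand
  nodrift$drift_ms <- NA_real_
  expect_warning(m <- match_shared_fragments(a, nodrift), "drift time absent")
  expect_gt(nrow(m), 0)

  # too few shared fragments
  m_ok <- match_shared_fragments(a, cand)
  expect_error(infer_shift(a, cand, m_ok[1:2, ]), "shared fragments")

  # inconsistent prefix/suffix evidence (full unshifted ladders on both
  # sides despite a mass difference) is flagged ambiguous, not dropped
  fake <- data.frame(series = rep(c("b", "y"), each = 7),
                     index = rep(1:7, 2),
                     mz_theor = 1:14, mz_obs = 1:14, error_mda = 0)
  h <- infer_shift(a, cand, fake)
  expect_true(h$ambiguous)
  expect_true(is.na(h$site_lo))

  expect_error(anchor_peptide(a$peptide, a$spectrum, passes_fdr = FALSE),
               "FDR")
})

test_that("composition proposals mirror the solver contract", {
  a <- make_anchor()
  cand <- make_candidate(arp_shift(reg$glycoaldehyde_aldimine))
  m <- match_shared_fragments(a, cand)
  h <- infer_shift(a, cand, m)
  expect_equal(h$underivatized_delta_da, 42.0106, tolerance = 2e-3)
  expect_true("C2H2O" %in% propose_compositions(h, tol = 0.01)$formula)

  # tiny tolerance far from any composition: empty, not an error
  h2 <- h
  h2$underivatized_delta_da <- 0.3
  expect_equal(nrow(propose_compositions(h2, tol = 0.001)), 0)

  # negative deltas are reported without composition search
  h3 <- h
  h3$underivatized_delta_da <- -1.03
  expect_equal(nrow(propose_compositions(h3)), 0)
})

test_that("re-scanning recovers planted sites and rejects decoys", {
  set.seed(77)
  feats <- default_cohort_features(16, 4)
  dda <- simulate_dda_collection(feats, n_unassigned = 10, n_plain = 5)
  dda <- plant_unknown_shift(dda, feats, "C3H2N2O", n_sites = 7)
  new_mod <- modification_spec("unknown_82_candidate", c("K", "C"),
                               delta = "C3H2N2O", arp_labelable = TRUE,
                               pathway = "UNKNOWN")
  unassigned <- Filter(function(s) !s$id %in% dda$psm$spectrum_id,
                       dda$spectra)
  hits <- rescan_with_new_mod(dda$psm, unassigned, new_mod)
  # all seven planted sites, at their exact positions, and nothing else
  expect_equal(sort(unique(hits$spectrum_id)), sort(dda$planted$spectrum_id))
  merged <- merge(hits, dda$planted, by = "spectrum_id")
  expect_equal(merged$position.x, merged$position.y)

  # a decoy modification with a different delta matches nothing
  decoy <- modification_spec("decoy", c("K", "C"), delta = "C2H4O2",
                             arp_labelable = TRUE, pathway = "UNKNOWN")
  expect_equal(nrow(rescan_with_new_mod(dda$psm, unassigned, decoy)), 0)

  # nothing planted, nothing found
  dda0 <- simulate_dda_collection(feats, n_unassigned = 4, n_plain = 2)
  un0 <- Filter(function(s) !s$id %in% dda0$psm$spectrum_id, dda0$spectra)
  expect_equal(nrow(rescan_with_new_mod(dda0$psm, un0, new_mod)), 0)

  # a planted delta must have positive mass
  expect_error(plant_unknown_shift(dda, feats, "H-2", n_sites = 1),
               "positive mass")
})
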