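test_that("composition mass arithmetic is linear and reproduces constants", {
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_equal(round(monoisotopic_mass("C3H2N2O"), 2), 82.02)
  expect_equal(round(monoisotopic_mass("C6H10O5"), 3), 162.053)
  expect_equal(monoisotopic_mass(comp()), 0)

  # signed deltas: allysine = O - NH3
  expect_equal(monoisotopic_mass(parse_formula("O1N-1H-3")), -1.031634,
               tolerance = 1e-5)

  # additivity over random composition pairs
  set.seed(41)
  for (i in 1:25) {
    a <- comp(C = sample(-5:20, 1), H = sample(-5:40, 1), N = sample(0:9, 1),
              O = sample(0:10, 1), S = sample(0:3, 1))
    b <- comp(C = sample(0:10, 1), H = sample(0:20, 1), N = sample(-3:5, 1),
              O = sample(-2:8, 1), S = sample(0:2, 1))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b))
    expect_equal(monoisotopic_mass(a - b),
                 monoisotopic_mass(a) - monoisotopic_mass(b))
  }

  expect_error(parse_formula("C2Xe3"), "unknown element")
  expect_error(comp(C = 1.5), "integers")
})

test_that("ARP derivatization chemistry reproduces the printed shift table", {
  expect_equal(monoisotopic_mass(arp_oxime_addition()), 313.1209,
               tolerance = 5e-4)

  reg <- load_modification_registry()
  printed <- c(
    glycoaldehyde_aldimine = 355.1314,  # 4-decimal value, tighter check below
    glyoxal_aldimine = 371.126,
    acrolein_michael = 369.147,
    mda_mg_michael = 385.142,
    mda_mg_schiff = 367.131,
    hexose_glycation = 475.174,
    aminoadipic_semialdehyde = 312.089,
    threonine_oxo = 311.105,
    histidine_oxo = 329.1158,
    methionine_aldehyde = 281.1124,
    unknown_68 = 381.147,
    unknown_70 = 383.138,
    unknown_82 = 395.138,
    unknown_86 = 399.133,
    unknown_96 = 409.142,
    unknown_106 = 419.126
  )
  for (nm in names(printed)) {
    expect_lt(abs(arp_shift(reg[[nm]]) - printed[[nm]]), 1e-3)
  }
  expect_lt(abs(arp_shift(reg$glycoaldehyde_aldimine) - 355.1314), 5e-4)

  # underivatized deltas behind the shifts
  expect_equal(round(reg$hexose_glycation$delta_mass, 3), 162.053)
  expect_equal(round(reg$mda_mg_michael$delta_mass, 3), 72.021)
  expect_equal(round(reg$carbamidomethyl$delta_mass, 3), 57.021)
  expect_equal(round(reg$methionine_oxidation$delta_mass, 3), 15.995)

  # a zero delta leaves the bare oxime addition
  zero <- modification_spec("bare", "K", delta = comp(), arp_labelable = TRUE,
                            pathway = "UNKNOWN")
  expect_equal(round(arp_shift(zero), 3), 313.121)

  # non-labelable modifications are rejected with an explanation
  expect_error(arp_shift(reg$carbamidomethyl), "not ARP-labelable")
})

test_that("peptide and fragment m/z reproduce the worked examples", {
  # lock-mass peptide
  glufib <- peptide_ion("EGVNDNEEGFFSAR", charge = 2)
  expect_equal(round(precursor_mz(glufib), 3), 785.842)
  expect_equal(precursor_mz(glufib) * 2 - 2 * 1.007276,
               oracle_peptide_mass("EGVNDNEEGFFSAR"), tolerance = 1e-4)

  # canonical allysine peptide, bracket notation round trip
  p <- parse_peptide("LK[+312.089]C[+57.021]ASLQK", charge = 2)
  expect_equal(p$sequence, "LKCASLQK")
  expect_equal(p$mods$pos, c(2L, 3L))
  expect_equal(p$mods$mass, c(312.089, 57.021))
  expect_equal(round(precursor_mz(p), 3), 630.315)
  expect_equal(round(fragment_mz(p, "y", 6), 3), 706.355)
  expect_equal(precursor_mz(p) * 2 - 2 * 1.007276,
               oracle_peptide_mass("LKCASLQK", c(312.089, 57.021)),
               tolerance = 1e-4)

  # b2 carries the site modification (hand-summed: L + K + shift + proton)
  reg <- load_modification_registry()
  p_exact <- peptide_ion("LKCASLQK",
                         mods = data.frame(
                           pos = c(2L, 3L),
                           mass = c(arp_shift(reg$aminoadipic_semialdehyde),
                                    reg$carbamidomethyl$delta_mass)),
                         charge = 2)
  expect_equal(round(fragment_mz(p_exact, "b", 2), 3), 554.276)
  expect_equal(round(fragment_mz(p_exact, "y", 6), 3), 706.355)

  expect_equal(format_peptide(p), "LK[+312.089]C[+57.021]ASLQK")

  # unmodified peptide equals sum of residues + water
  q <- peptide_ion("GASP")
  expect_equal(peptide_neutral_mass(q), oracle_peptide_mass("GASP"),
               tolerance = 1e-4)

  expect_error(peptide_ion("ABZ"), "unknown residue")
  expect_error(fragment_mz(q, "y", 4), "out of range")
  expect_error(fragment_mz(q, "b", 0), "out of range")
})

test_that("fragment complementarity holds for random modified peptides", {
  set.seed(7)
  pool <- c("A", "S", "T", "V", "L", "P", "G", "F", "D", "E", "K", "R", "H",
            "M", "W", "Y", "C", "N", "Q", "I")
  for (i in 1:20) {
    n <- sample(5:15, 1)
    sequence <- paste(sample(pool, n, replace = TRUE), collapse = "")
    n_mods <- sample(0:2, 1)
    mods <- if (n_mods > 0) {
      data.frame(pos = sample(n, n_mods), mass = runif(n_mods, -20, 400))
    }
    p <- peptide_ion(sequence, mods = mods, charge = 2)
    target <- peptide_neutral_mass(p) + 2 * 1.007276
    for (k in seq_len(n - 1)) {
      expect_equal(fragment_mz(p, "b", k, 1) + fragment_mz(p, "y", n - k, 1),
                   target, tolerance = 1e-9)
    }
  }
})

test_that("isotope distributions match the brute-force convolution oracle", {
  expect_equal(isotope_distribution(comp(C = 1), 2)$abundance,
               c(0.9893, 0.0107))
  z <- isotope_distribution(comp(), 1)
  expect_equal(z$abundance, 1)

  set.seed(11)
  for (i in 1:15) {
    counts <- c(C = sample(0:40, 1), H = sample(0:60, 1), N = sample(0:12, 1),
                O = sample(0:15, 1), S = sample(0:3, 1))
    n_peaks <- sample(2:6, 1)
    got <- isotope_distribution(do.call(comp, as.list(counts)), n_peaks)
    expect_equal(sum(got$abundance), 1, tolerance = 1e-9)
    expect_equal(got$abundance, oracle_isotope_distribution(counts, n_peaks),
                 tolerance = 1e-9)
  }

  expect_error(isotope_distribution(parse_formula("H-2"), 2), "non-negative")
})

test_that("composition solver equals the exhaustive oracle and honors RDBE", {
  bounds <- list(C = c(0, 8), H = c(0, 12), N = c(0, 4), O = c(0, 5),
                 S = c(0, 1))
  for (target in c(82.0167, 42.0106, 100.016, 57.0215)) {
    got <- solve_composition(target, 0.02, bounds = bounds)
    want <- oracle_solve_composition(target, 0.02, bounds)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got[, c("C", "H", "N", "O", "S")],
                   want[, c("C", "H", "N", "O", "S")],
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
    # and without the RDBE filter
    got2 <- solve_composition(target, 0.02, bounds = bounds,
                              require_integer_rdbe = FALSE)
    want2 <- oracle_solve_composition(target, 0.02, bounds,
                                      require_integer_rdbe = FALSE)
    expect_equal(nrow(got2), nrow(want2))
  }

  # the printed unknown-modification case
  hits <- solve_composition(82.02, 0.01)
  expect_true("C3H2N2O" %in% hits$formula)
  # the radical composition C4H4NO sits within tolerance but has RDBE 3.5
  no_rdbe <- solve_composition(82.02, 0.01, require_integer_rdbe = FALSE)
  expect_true("C4H4NO" %in% no_rdbe$formula)
  expect_false("C4H4NO" %in% hits$formula)

  # water is the top candidate near its own mass
  expect_equal(solve_composition(18.0106, 5e-4)$formula[1], "H2O")

  # an empty result is an answer, not an error
  expect_equal(nrow(solve_composition(0.3, 0.001)), 0)
})

test_that("the reporter-ion table matches the diagnostic ARP fragments", {
  tab <- reporter_ion_table()
  expect_equal(nrow(tab), 4)
  expect_equal(tab$mz, c(332.14, 299.12, 259.12, 227.08))
  # dehydrated protonated biotin computed from composition
  expect_equal(round(tab$mz_calc[4], 2), 227.08)
  expect_equal(round(tab$mz_calc[4], 4), 227.0849)
})
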