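# Independent oracles kept deliberately dumb: they re-derive quantities by
# brute force so package implementations can be checked against them.

# monoisotopic masses re-stated independently (NIST, 6 decimals)
ORACLE_MASS <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
                 S = 31.972071)

# exhaustive nested-loop composition search (no vectorization, no shared code)
oracle_solve_composition <- function(target, tol, bounds,
                                     require_integer_rdbe = TRUE) {
  hits <- list()
  for (nC in bounds$C[1]:bounds$C[2])
    for (nH in bounds$H[1]:bounds$H[2])
      for (nN in bounds$N[1]:bounds$N[2])
        for (nO in bounds$O[1]:bounds$O[2])
          for (nS in bounds$S[1]:bounds$S[2]) {
            m <- nC * ORACLE_MASS[["C"]] + nH * ORACLE_MASS[["H"]] +
              nN * ORACLE_MASS[["N"]] + nO * ORACLE_MASS[["O"]] +
              nS * ORACLE_MASS[["S"]]
            if (abs(m - target) > tol) next
            r <- nC - nH / 2 + nN / 2 + 1
            if (require_integer_rdbe && (abs(r - round(r)) > 1e-9 || r < 0))
              next
            hits[[length(hits) + 1]] <- c(C = nC, H = nH, N = nN, O = nO,
                                          S = nS, mass = m)
          }
  if (length(hits) == 0) {
    return(data.frame(C = integer(), H = integer(), N = integer(),
                      O = integer(), S = integer(), mass = numeric()))
  }
  out <- as.data.frame(do.call(rbind, hits))
  out[order(abs(out$mass - target)), , drop = FALSE]
}

# full atom-by-atom convolution of isotope abundances (untruncated until the
# very end)
oracle_isotope_distribution <- function(counts, n_peaks) {
  tables <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
  )
  dist <- 1
  for (e in names(counts)) {
    n <- counts[[e]]
    if (n <= 0) next
    for (k in seq_len(n)) {
      p <- tables[[e]]
      new <- numeric(length(dist) + length(p) - 1)
      for (i in seq_along(dist))
        for (j in seq_along(p))
          new[i + j - 1] <- new[i + j - 1] + dist[i] * p[j]
      dist <- new
    }
  }
  dist <- c(dist, numeric(max(0, n_peaks - length(dist))))[seq_len(n_peaks)]
  dist / sum(dist)
}

# hand-summed residue masses for the peptides used as worked examples
oracle_peptide_mass <- function(seq_chars, mod_masses = 0) {
  res <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
           V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
           I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
           K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
           F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  sum(res[strsplit(seq_chars, "")[[1]]]) + sum(mod_masses) + 18.010565
}

# a spectrum with chosen reporter peaks (plus a dominating base peak)
make_reporter_spectrum <- function(id = "s1", reporter_mz = numeric(),
                                   rel_int = 0.10, base_mz = 500,
                                   extra = NULL) {
  peaks <- data.frame(mz = base_mz, intensity = 1000)
  if (length(reporter_mz) > 0) {
    peaks <- rbind(peaks, data.frame(mz = reporter_mz,
                                     intensity = 1000 * rel_int))
  }
  if (!is.null(extra)) peaks <- rbind(peaks, extra)
  ms_spectrum(id, precursor_mz = 600, charge = 2, rt_min = 20,
              drift_ms = 3, peaks = peaks)
}

# small cohort spec used across tests (fast but structurally complete)
small_cohort_spec <- function(...) {
  cohort_spec(n_ra = 6, n_control = 6, ra_sex = c(F = 4, M = 2),
              control_sex = c(F = 3, M = 3), n_features = 10,
              n_irt_standards = 4, ...)
}
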