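#' Build an anchor from an identified ARP-peptide and its spectrum
#'
#' An anchor is a confidently identified peptide (FDR-passing PSM) whose
#' annotated theoretical fragments are observed in its own spectrum; it seeds
#' the spectral-similarity search for unknown modification mass shifts.
#'
#' @param peptide a `peptide_ion` (the PSM assignment).
#' @param spectrum the identified `ms_spectrum`.
#' @param passes_fdr FDR flag of the PSM (consumed, not computed).
#' @param frag_tol_mda tolerance used to annotate observed fragments.
#' @param min_observed minimum number of annotated fragments that must be
#'   observed in the spectrum (default 3).
#' @return An object of class `anchor_peptide` with the theoretical fragment
#'   table and the subset observed in the spectrum.
#' @export
anchor_peptide <- function(peptide, spectrum, passes_fdr = TRUE,
                           frag_tol_mda = 25, min_observed = 3L) {
  stopifnot(inherits(peptide, "peptide_ion"), inherits(spectrum, "ms_spectrum"))
  if (!isTRUE(passes_fdr)) {
    stop("anchor peptides must come from FDR-passing PSMs", call. = FALSE)
  }
  theo <- fragment_table(peptide, charge = 1L)
  tol <- frag_tol_mda / 1000
  observed <- vapply(theo$mz, function(m) {
    nrow(spectrum$peaks) > 0 && min(abs(spectrum$peaks$mz - m)) <= tol
  }, logical(1))
  if (sum(observed) < min_observed) {
    stop(sprintf(
      "only %d of %d annotated fragments observed in spectrum '%s' (need >= %d)",
      sum(observed), nrow(theo), spectrum$id, min_observed), call. = FALSE)
  }
  structure(list(peptide = peptide, spectrum = spectrum,
                 fragments = theo, observed = observed),
            class = "anchor_peptide")
}

#' Match an anchor's fragments in an unidentified candidate spectrum
#'
#' A theoretical anchor fragment matches a candidate peak iff their m/z differ
#' by at most `frag_tol_mda` and the candidate's precursor drift time lies
#' within `drift_tol_ms` of the anchor's (fragments covering the unmodified
#' part of a shared sequence keep their m/z, and co-mobility restricts the
#' search the way the ion-mobility dimension does on the instrument). The
#' drift constraint is skipped with a warning when either spectrum lacks a
#' drift time.
#'
#' @param anchor an [anchor_peptide()].
#' @param cand candidate `ms_spectrum` (must have precursor m/z and charge).
#' @param frag_tol_mda fragment m/z tolerance in mDa.
#' @param drift_tol_ms drift-time tolerance in ms.
#' @param min_rel_int candidate peaks below this fraction of the base peak
#'   are not considered fragment evidence (default 2%), so weak background
#'   peaks cannot fake a shared fragment.
#' @return Data frame of matched fragments (`series`, `index`, `mz_theor`,
#'   `mz_obs`, `error_mda`); zero rows when the drift gate fails.
#' @export
match_shared_fragments <- function(anchor, cand, frag_tol_mda = 25,
                                   drift_tol_ms = 0.5, min_rel_int = 0.02) {
  stopifnot(inherits(anchor, "anchor_peptide"), inherits(cand, "ms_spectrum"))
  if (is.na(cand$precursor_mz) || is.na(cand$charge)) {
    stop("candidate spectrum needs precursor m/z and charge", call. = FALSE)
  }
  empty <- data.frame(series = character(), index = integer(),
                      mz_theor = numeric(), mz_obs = numeric(),
                      error_mda = numeric())
  if (is.na(anchor$spectrum$drift_ms) || is.na(cand$drift_ms)) {
    warning("drift time absent; matching on m/z only", call. = FALSE)
  } else if (abs(cand$drift_ms - anchor$spectrum$drift_ms) > drift_tol_ms) {
    return(empty)
  }
  tol <- frag_tol_mda / 1000
  theo <- anchor$fragments[anchor$observed, , drop = FALSE]
  if (nrow(cand$peaks) == 0 || nrow(theo) == 0) return(empty)
  peaks <- cand$peaks[cand$peaks$intensity >=
                        min_rel_int * max(cand$peaks$intensity), ,
                      drop = FALSE]
  if (nrow(peaks) == 0) return(empty)
  rows <- lapply(seq_len(nrow(theo)), function(i) {
    d <- abs(peaks$mz - theo$mz[i])
    j <- which.min(d)
    if (d[j] <= tol) {
      data.frame(series = theo$series[i], index = theo$index[i],
                 mz_theor = theo$mz[i], mz_obs = peaks$mz[j],
                 error_mda = (peaks$mz[j] - theo$mz[i]) * 1000)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

# smallest residue interval consistent with which ion series are unshifted:
# an unshifted b_k places the shift after position k, an unshifted y_k places
# it before position n-k+1. Only the contiguous ladder starting at index 1
# counts as evidence in each series -- an isolated coincidental match beyond a
# gap is not a consistent unshifted prefix/suffix.
.ladder_max <- function(idx) {
  if (length(idx) == 0) return(0L)
  idx <- sort(unique(idx))
  run <- which(idx == seq_along(idx))
  if (length(run) == 0) 0L else max(run)
}

.localize_from_matches <- function(matches, n) {
  b_max <- .ladder_max(matches$index[matches$series == "b"])
  y_max <- .ladder_max(matches$index[matches$series == "y"])
  c(lo = b_max + 1L, hi = n - y_max)
}

#' Infer an unknown modification shift from a shared-fragment match
#'
#' The candidate's precursor mass difference to the anchor is interpreted as
#' an extra (or different) modification on the residues not covered by shared
#' unshifted fragments. The total modification mass at the divergent site is
#' the anchor's own modification mass there plus the precursor delta; the
#' underivatized delta subtracts the ARP oxime net addition (313.1209 Da).
#'
#' @param anchor an [anchor_peptide()].
#' @param cand candidate `ms_spectrum`.
#' @param matches output of [match_shared_fragments()].
#' @param min_shared minimum shared fragments required (default 3).
#' @param identity_tol_da precursor deltas below this absolute value collapse
#'   the hypothesis to the anchor identity.
#' @return An object of class `shift_hypothesis`: `precursor_delta_da`,
#'   `site_lo`/`site_hi` (localized interval, reported as an interval and
#'   never silently assigned when ambiguous), `total_mod_mass_da`,
#'   `underivatized_delta_da`, `ambiguous`, `identity`.
#' @export
infer_shift <- function(anchor, cand, matches, min_shared = 3L,
                        identity_tol_da = 0.01) {
  stopifnot(inherits(anchor, "anchor_peptide"))
  if (nrow(matches) < min_shared) {
    stop(sprintf("only %d shared fragments (need >= %d)", nrow(matches),
                 min_shared), call. = FALSE)
  }
  n <- nchar(anchor$peptide$sequence)
  anchor_neutral <- peptide_neutral_mass(anchor$peptide)
  delta <- (cand$precursor_mz - PROTON_MASS) * cand$charge - anchor_neutral
  if (abs(delta) <= identity_tol_da) {
    # candidate is the anchor species itself
    anchor_mods <- anchor$peptide$mods
    site <- if (nrow(anchor_mods) > 0) anchor_mods$pos[1] else NA_integer_
    total <- if (nrow(anchor_mods) > 0) anchor_mods$mass[1] else 0
    return(structure(list(
      anchor_peptide = format_peptide(anchor$peptide),
      candidate_id = cand$id, precursor_delta_da = delta,
      site_lo = site, site_hi = site, total_mod_mass_da = total,
      underivatized_delta_da = total - ARP_OXIME_MASS,
      n_shared = nrow(matches), matches = matches,
      ambiguous = FALSE, identity = TRUE
    ), class = "shift_hypothesis"))
  }
  iv <- .localize_from_matches(matches, n)
  ambiguous <- iv["lo"] > iv["hi"]
  if (ambiguous) iv <- c(lo = NA_integer_, hi = NA_integer_)
  # the anchor modification at the divergent site (0 when none)
  in_iv <- !ambiguous & anchor$peptide$mods$pos >= iv["lo"] &
    anchor$peptide$mods$pos <= iv["hi"]
  anchor_site_mass <- sum(anchor$peptide$mods$mass[in_iv])
  total <- anchor_site_mass + delta
  structure(list(
    anchor_peptide = format_peptide(anchor$peptide),
    candidate_id = cand$id,
    precursor_delta_da = delta,
    site_lo = unname(iv["lo"]), site_hi = unname(iv["hi"]),
    total_mod_mass_da = total,
    underivatized_delta_da = total - ARP_OXIME_MASS,
    n_shared = nrow(matches),
    matches = matches,
    ambiguous = unname(ambiguous),
    identity = FALSE
  ), class = "shift_hypothesis")
}

#' @export
print.shift_hypothesis <- function(x, ...) {
  cat("<shift_hypothesis> anchor ", x$anchor_peptide, " vs ", x$candidate_id,
      "\n  precursor delta ", sprintf("%+.4f", x$precursor_delta_da),
      " Da; site ", x$site_lo, "-", x$site_hi,
      "; total mod ", sprintf("%+.4f", x$total_mod_mass_da),
      " Da; underivatized ", sprintf("%+.4f", x$underivatized_delta_da),
      " Da\n", sep = "")
  invisible(x)
}

#' Propose elemental compositions for an inferred shift
#'
#' Delegates to [solve_composition()] with the default delta bounds and the
#' integer-RDBE filter. Negative underivatized deltas are reported without a
#' composition search (an empty candidate list).
#'
#' @param h a `shift_hypothesis`.
#' @param tol mass tolerance in Da.
#' @param bounds solver bounds.
#' @return Ranked composition data frame as from [solve_composition()].
#' @export
propose_compositions <- function(h, tol = 0.01,
                                 bounds = default_solver_bounds()) {
  stopifnot(inherits(h, "shift_hypothesis"))
  if (is.na(h$underivatized_delta_da) || h$underivatized_delta_da <= 0) {
    return(solve_composition(1, tol)[0, ])
  }
  solve_composition(h$underivatized_delta_da, tol, bounds = bounds)
}

#' Re-scan unassigned spectra after registering a new modification
#'
#' Once an unknown shift has been characterized, previously unassigned
#' reporter-bearing spectra are re-matched against the identified peptide
#' repertoire allowing the new total shift at Lys/Cys residues (the new
#' modification replaces any ARP modification the peptide already carries at
#' that site; fixed modifications are kept). A spectrum is matched when its
#' precursor m/z agrees within `precursor_ppm` and at least `min_shared`
#' unshifted fragments are observed.
#'
#' @param psm_table PSM table ([read_psm_table()]) providing the peptide
#'   repertoire.
#' @param spectra list of `ms_spectrum` to re-scan (typically reporter-screen
#'   hits without PSM).
#' @param new_mod a `modification_spec` for the new modification
#'   (ARP-labelable).
#' @param registry modification registry (used to tell ARP mods from fixed
#'   ones by mass).
#' @param precursor_ppm precursor tolerance in ppm.
#' @param frag_tol_mda fragment tolerance in mDa.
#' @param min_shared minimum matched unshifted fragments.
#' @param min_rel_int relative-intensity floor for fragment evidence.
#' @return Site-level data frame: `spectrum_id`, `peptide`, `position`,
#'   `residue`, `total_shift_da`, `ppm_error`, `n_shared`.
#' @export
rescan_with_new_mod <- function(psm_table, spectra, new_mod,
                                registry = load_modification_registry(),
                                precursor_ppm = 15, frag_tol_mda = 25,
                                min_shared = 3L, min_rel_int = 0.02) {
  stopifnot(inherits(new_mod, "modification_spec"))
  total_shift <- arp_shift(new_mod)
  fixed_masses <- vapply(Filter(function(m) !m$arp_labelable, registry),
                         function(m) m$delta_mass, numeric(1))
  peptides <- unique(vapply(psm_table$peptide_ion, format_peptide,
                            character(1)))
  rows <- list()
  for (ptxt in peptides) {
    base <- parse_peptide(ptxt)
    residues <- strsplit(base$sequence, "")[[1]]
    sites <- which(residues %in% c("K", "C"))
    for (pos in sites) {
      mods <- base$mods
      at_site <- mods$pos == pos
      # keep fixed modifications (carbamidomethyl etc.) even at the site
      is_fixed <- at_site & vapply(mods$mass, function(m) {
        any(abs(fixed_masses - m) < 0.005)
      }, logical(1))
      mods <- mods[!at_site | is_fixed, , drop = FALSE]
      if (any(mods$pos == pos)) next  # site blocked by a fixed modification
      mods <- rbind(mods, data.frame(pos = pos, mass = total_shift,
                                     name = new_mod$name))
      for (s in spectra) {
        if (is.na(s$charge) || is.na(s$precursor_mz)) next
        variant <- peptide_ion(base$sequence, mods = mods, charge = s$charge)
        mz_theor <- precursor_mz(variant)
        ppm <- (s$precursor_mz - mz_theor) / mz_theor * 1e6
        if (abs(ppm) > precursor_ppm) next
        theo <- fragment_table(variant, charge = 1L)
        tol <- frag_tol_mda / 1000
        pk <- s$peaks[s$peaks$intensity >=
                        min_rel_int * max(s$peaks$intensity), , drop = FALSE]
        n_match <- sum(vapply(theo$mz, function(m) {
          nrow(pk) > 0 && min(abs(pk$mz - m)) <= tol
        }, logical(1)))
        if (n_match < min_shared) next
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id = s$id, peptide = format_peptide(variant),
          position = pos, residue = residues[pos],
          total_shift_da = total_shift, ppm_error = ppm, n_shared = n_match
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(spectrum_id = character(), peptide = character(),
                      position = integer(), residue = character(),
                      total_shift_da = numeric(), ppm_error = numeric(),
                      n_shared = integer()))
  }
  out <- do.call(rbind, rows)
  # a wrong-site variant of the right sequence still shares the terminal
  # fragments; keep only the best-supported site(s) per spectrum
  best <- stats::ave(out$n_shared, out$spectrum_id, FUN = max)
  out <- out[out$n_shared == best, , drop = FALSE]
  rownames(out) <- NULL
  out
}
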