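#' Reporter-ion screening pattern
#'
#' Matching rules for recognizing ARP-peptide spectra by their diagnostic
#' low-mass reporter ions. Defaults: all four ARP reporters, 25 mDa match
#' tolerance (the fragment-level search tolerance), reporters must reach 1% of
#' the base peak, at least 2 reporters present, and the dehydrated-biotin
#' signal at m/z 227.08 -- consistently the most intense reporter -- required
#' as anchor.
#'
#' @param mz reporter m/z values to look for.
#' @param tol_mda match tolerance in mDa (> 0).
#' @param min_rel_int minimum intensity relative to the base peak, in `[0, 1]`.
#' @param min_reporters minimum number of matched reporters
#'   (`1 <= min_reporters <= length(mz)`).
#' @param anchor_mz reporter that must be present; `NULL` disables the anchor
#'   requirement.
#' @return An object of class `reporter_pattern`.
#' @export
reporter_pattern <- function(mz = reporter_ion_table()$mz, tol_mda = 25,
                             min_rel_int = 0.01, min_reporters = 2L,
                             anchor_mz = 227.08) {
  stopifnot(tol_mda > 0, min_rel_int >= 0,
            min_reporters >= 1L, min_reporters <= length(mz))
  if (!is.null(anchor_mz) && !any(abs(mz - anchor_mz) < 1e-6)) {
    stop("anchor m/z must be one of the pattern's reporter m/z values",
         call. = FALSE)
  }
  structure(list(mz = mz, tol_mda = tol_mda, min_rel_int = min_rel_int,
                 min_reporters = as.integer(min_reporters),
                 anchor_mz = anchor_mz),
            class = "reporter_pattern")
}

#' Screen one spectrum for the ARP reporter pattern
#'
#' A reporter matches the nearest peak within tolerance whose intensity
#' reaches the pattern's relative-intensity floor. The spectrum is a hit iff
#' the anchor reporter matches and at least `min_reporters` reporters match.
#'
#' @param s an `ms_spectrum` (peaks sorted by m/z).
#' @param pattern a [reporter_pattern()].
#' @return A list (class `reporter_hit`) with the matched reporter table, or
#'   `NULL` when the spectrum is not a hit (including the empty spectrum).
#' @export
screen_spectrum <- function(s, pattern = reporter_pattern()) {
  stopifnot(inherits(s, "ms_spectrum"), inherits(pattern, "reporter_pattern"))
  if (nrow(s$peaks) == 0) return(NULL)
  base_int <- max(s$peaks$intensity)
  if (base_int <= 0) return(NULL)
  tol <- pattern$tol_mda / 1000
  matches <- lapply(pattern$mz, function(target) {
    d <- abs(s$peaks$mz - target)
    ok <- which(d <= tol & s$peaks$intensity / base_int >= pattern$min_rel_int)
    if (length(ok) == 0) return(NULL)
    i <- ok[which.min(d[ok])]  # nearest peak wins within tolerance
    data.frame(expected_mz = target, observed_mz = s$peaks$mz[i],
               rel_intensity = s$peaks$intensity[i] / base_int)
  })
  matched <- do.call(rbind, matches)
  if (is.null(matched) || nrow(matched) < pattern$min_reporters) return(NULL)
  if (!is.null(pattern$anchor_mz) &&
      !any(abs(matched$expected_mz - pattern$anchor_mz) < 1e-6)) {
    return(NULL)
  }
  structure(list(spectrum_id = s$id, matched = matched, has_psm = NA),
            class = "reporter_hit")
}

#' Screen a spectrum collection and cross-reference PSM assignments
#'
#' Re-implementation of the reporter-pattern screening concept: every spectrum
#' is screened and hits are cross-referenced against the PSM table to count
#' reporter-bearing spectra that carry no peptide assignment -- the pool from
#' which unknown modifications are discovered.
#'
#' @param spectra list of `ms_spectrum` with unique ids.
#' @param psm_table PSM data frame ([read_psm_table()]) or `NULL` when no
#'   identifications are available.
#' @param pattern a [reporter_pattern()].
#' @param out_tsv optional path; when given, per-hit rows are streamed to a
#'   TSV report.
#' @return List with `summary` (`n_screened`, `n_hits`, `n_hits_no_psm`,
#'   `fraction_no_psm` -- `NA` when there are no hits, not 0) and `hits` (data
#'   frame with one row per matched reporter per hit).
#' @export
screen_collection <- function(spectra, psm_table = NULL,
                              pattern = reporter_pattern(), out_tsv = NULL) {
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate spectrum id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  assigned <- character()
  if (!is.null(psm_table) && nrow(psm_table) > 0) {
    assigned <- unique(psm_table$spectrum_id[psm_table$passes_fdr])
  }
  rows <- list()
  n_hits <- 0L
  n_no_psm <- 0L
  for (s in spectra) {
    hit <- screen_spectrum(s, pattern)
    if (is.null(hit)) next
    n_hits <- n_hits + 1L
    has_psm <- s$id %in% assigned
    if (!has_psm) n_no_psm <- n_no_psm + 1L
    rows[[n_hits]] <- data.frame(
      spectrum_id = s$id,
      n_matched = nrow(hit$matched),
      has_psm = has_psm,
      reporters = paste(sprintf("%.2f", hit$matched$expected_mz),
                        collapse = ";"),
      rel_intensities = paste(sprintf("%.4f", hit$matched$rel_intensity),
                              collapse = ";")
    )
  }
  hits <- if (n_hits > 0) do.call(rbind, rows) else
    data.frame(spectrum_id = character(), n_matched = integer(),
               has_psm = logical(), reporters = character(),
               rel_intensities = character())
  if (!is.null(out_tsv)) {
    utils::write.table(hits, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(
    summary = list(
      n_screened = length(spectra),
      n_hits = n_hits,
      n_hits_no_psm = n_no_psm,
      fraction_no_psm = if (n_hits > 0) n_no_psm / n_hits else NA_real_
    ),
    hits = hits
  )
}
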