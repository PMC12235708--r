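#' A centroided fragment ion spectrum
#'
#' @param id spectrum identifier (unique within a file).
#' @param precursor_mz precursor m/z (> 0).
#' @param charge precursor charge; `NA` when unknown.
#' @param rt_min retention time in minutes.
#' @param drift_ms ion-mobility drift time in milliseconds; `NA` when the
#'   acquisition carried no mobility dimension.
#' @param peaks data frame with columns `mz` and `intensity`; sorted ascending
#'   by m/z on construction.
#' @param flags character vector of parser/validator flags.
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(id, precursor_mz, charge = NA_integer_,
                        rt_min = NA_real_, drift_ms = NA_real_,
                        peaks = data.frame(mz = numeric(),
                                           intensity = numeric()),
                        flags = character()) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) > 0) {
    if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
      stop("peaks must have positive m/z and non-negative intensity",
           call. = FALSE)
    }
    peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
    rownames(peaks) <- NULL
  }
  if (!is.na(drift_ms) && drift_ms < 0) {
    stop("drift time must be non-negative", call. = FALSE)
  }
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 rt_min = rt_min, drift_ms = drift_ms, peaks = peaks,
                 flags = flags),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> ", x$id, "  prec m/z ", sprintf("%.4f", x$precursor_mz),
      " z=", ifelse(is.na(x$charge), "?", x$charge),
      "  rt ", sprintf("%.2f", x$rt_min), " min  drift ",
      ifelse(is.na(x$drift_ms), "?", sprintf("%.2f", x$drift_ms)), " ms  ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Write spectra as a Mascot generic format (MGF) file
#'
#' Retention time is written to the standard `RTINSECONDS` field (the package
#' holds it in minutes); drift time goes to an auxiliary `DRIFTTIME` line
#' (milliseconds), omitted when absent. The writer is deterministic: identical
#' input yields byte-identical files.
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output file.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(is.list(spectra))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "ms_spectrum"))
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      paste0("PEPMASS=", sprintf("%.9f", s$precursor_mz)),
      if (!is.na(s$charge)) paste0("CHARGE=", s$charge, "+"),
      if (!is.na(s$rt_min)) paste0("RTINSECONDS=",
                                   sprintf("%.9f", s$rt_min * 60)),
      if (!is.na(s$drift_ms)) paste0("DRIFTTIME=", sprintf("%.9f", s$drift_ms)),
      if (nrow(s$peaks) > 0) sprintf("%.9f %.9f", s$peaks$mz,
                                     s$peaks$intensity),
      "END IONS"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a Mascot generic format (MGF) file
#'
#' Peaks are sorted by m/z on load. A spectrum lacking a `CHARGE` line gets
#' `charge = NA` and the flag `"missing_charge"`; a missing `DRIFTTIME` line
#' yields `drift_ms = NA` (absent, not zero). Malformed `BEGIN IONS`/`END
#' IONS` nesting raises an error naming the offending block.
#'
#' @param path MGF file.
#' @return List of `ms_spectrum`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  spectra <- list()
  in_block <- FALSE
  block_no <- 0L
  hdr <- NULL
  mz <- NULL; int <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (ln == "BEGIN IONS") {
      if (in_block) {
        stop(sprintf("malformed MGF: BEGIN IONS inside block %d", block_no + 1L),
             call. = FALSE)
      }
      in_block <- TRUE
      block_no <- block_no + 1L
      hdr <- list()
      mz <- numeric(); int <- numeric()
    } else if (ln == "END IONS") {
      if (!in_block) {
        stop(sprintf("malformed MGF: END IONS without BEGIN IONS after block %d",
                     block_no), call. = FALSE)
      }
      in_block <- FALSE
      flags <- character()
      charge <- NA_integer_
      if (!is.null(hdr$CHARGE)) {
        charge <- as.integer(sub("[+-]$", "", hdr$CHARGE))
      } else {
        flags <- c(flags, "missing_charge")
      }
      spectra[[length(spectra) + 1L]] <- ms_spectrum(
        id = if (!is.null(hdr$TITLE)) hdr$TITLE else sprintf("scan_%d", block_no),
        precursor_mz = if (!is.null(hdr$PEPMASS))
          as.numeric(strsplit(hdr$PEPMASS, "[ \t]+")[[1]][1]) else NA_real_,
        charge = charge,
        rt_min = if (!is.null(hdr$RTINSECONDS))
          as.numeric(hdr$RTINSECONDS) / 60 else NA_real_,
        drift_ms = if (!is.null(hdr$DRIFTTIME))
          as.numeric(hdr$DRIFTTIME) else NA_real_,
        peaks = data.frame(mz = mz, intensity = int),
        flags = flags
      )
    } else if (in_block) {
      if (grepl("=", ln, fixed = TRUE)) {
        key <- sub("=.*$", "", ln)
        hdr[[key]] <- sub("^[^=]*=", "", ln)
      } else {
        xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        mz <- c(mz, xy[1]); int <- c(int, xy[2])
      }
    }
    # lines outside blocks are comments/garbage and ignored
  }
  if (in_block) {
    stop(sprintf("malformed MGF: block %d has no END IONS", block_no),
         call. = FALSE)
  }
  spectra
}

.check_columns <- function(tab, need, what) {
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("%s lacks mandatory column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

.serialize_fragments <- function(fr) {
  if (is.null(fr) || nrow(fr) == 0) return("")
  paste(sprintf("%s%d^%d@%.9f:%.6f", fr$series, fr$index, fr$charge, fr$mz,
                fr$rel_intensity), collapse = ";")
}

.parse_fragments <- function(s) {
  if (is.na(s) || s == "") {
    return(data.frame(series = character(), index = integer(),
                      charge = integer(), mz = numeric(),
                      rel_intensity = numeric()))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts,
                  regexec("^([by])([0-9]+)\\^([0-9]+)@([0-9.]+):([0-9.eE+-]+)$",
                          parts))
  bad <- vapply(m, length, integer(1)) != 6L
  if (any(bad)) {
    stop(sprintf("cannot parse fragment annotation '%s'", parts[bad][1]),
         call. = FALSE)
  }
  data.frame(
    series = vapply(m, `[[`, character(1), 2L),
    index = as.integer(vapply(m, `[[`, character(1), 3L)),
    charge = as.integer(vapply(m, `[[`, character(1), 4L)),
    mz = as.numeric(vapply(m, `[[`, character(1), 5L)),
    rel_intensity = as.numeric(vapply(m, `[[`, character(1), 6L))
  )
}

#' Write a spectral-library table
#'
#' Tab-separated, one row per library entry. Fragment annotations are packed
#' into a single `fragments` column as `series index^charge@mz:rel_intensity`
#' items separated by `;`.
#'
#' @param entries list of library entries (see [read_library()]).
#' @param path output TSV.
#' @export
write_library <- function(entries, path) {
  tab <- data.frame(
    feature_id = vapply(entries, function(e) {
      if (!is.null(e$feature_id)) e$feature_id else NA_character_
    }, character(1)),
    peptide = vapply(entries, function(e) format_peptide(e$peptide, 4),
                     character(1)),
    charge = vapply(entries, function(e) e$peptide$charge, integer(1)),
    protein = vapply(entries, function(e) e$protein, character(1)),
    irt = vapply(entries, function(e) e$irt, numeric(1)),
    drift_ms = vapply(entries, function(e) e$drift_ms, numeric(1)),
    is_irt_standard = vapply(entries, function(e) isTRUE(e$is_irt_standard),
                             logical(1)),
    fragments = vapply(entries, function(e) .serialize_fragments(e$fragments),
                       character(1))
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectral-library table
#'
#' Mandatory columns: `peptide` (bracket notation), `charge`, `protein`,
#' `irt`, `drift_ms`, `fragments`. Unknown columns are preserved in each
#' entry's `extras`.
#'
#' @param path library TSV.
#' @return List of library entries: each a list with `peptide`
#'   (`peptide_ion`), `protein`, `irt`, `drift_ms`, `is_irt_standard`,
#'   `fragments` (data frame) and `extras`.
#' @export
read_library <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("peptide", "charge", "protein", "irt", "drift_ms", "fragments")
  .check_columns(tab, need, "library table")
  extras_cols <- setdiff(names(tab), c(need, "is_irt_standard", "feature_id"))
  lapply(seq_len(nrow(tab)), function(i) {
    list(
      feature_id = if ("feature_id" %in% names(tab)) tab$feature_id[i]
                   else NA_character_,
      peptide = parse_peptide(tab$peptide[i], charge = tab$charge[i]),
      protein = tab$protein[i],
      irt = tab$irt[i],
      drift_ms = tab$drift_ms[i],
      is_irt_standard = if ("is_irt_standard" %in% names(tab))
        isTRUE(as.logical(tab$is_irt_standard[i])) else FALSE,
      fragments = .parse_fragments(tab$fragments[i]),
      extras = if (length(extras_cols) > 0) as.list(tab[i, extras_cols,
                                                        drop = FALSE])
               else list()
    )
  })
}

#' Read a peptide-spectrum-match (PSM) table
#'
#' Mandatory columns: `spectrum_id`, `peptide` (bracket notation), `charge`,
#' `score`, `passes_fdr`. The FDR flag is consumed, never computed, by this
#' package. A parsed `peptide_ion` per row is attached as the list column
#' `peptide_ion`.
#'
#' @param path PSM TSV.
#' @return Data frame, one peptide per record.
#' @export
read_psm_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .check_columns(tab, c("spectrum_id", "peptide", "charge", "score",
                        "passes_fdr"), "PSM table")
  tab$passes_fdr <- as.logical(tab$passes_fdr)
  tab$peptide_ion <- lapply(seq_len(nrow(tab)), function(i) {
    parse_peptide(tab$peptide[i], charge = tab$charge[i])
  })
  tab
}

#' Write a PSM table
#' @param tab data frame with at least `spectrum_id`, `peptide`, `charge`,
#'   `score`, `passes_fdr`.
#' @param path output TSV.
#' @export
write_psm_table <- function(tab, path) {
  keep <- setdiff(names(tab), "peptide_ion")
  utils::write.table(tab[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a feature-by-run quantitation matrix
#'
#' The matrix is stored as TSV with a leading `feature_id` column; missing
#' cells are written as `NA` and read back as missing, never as zero.
#'
#' @param mat numeric matrix, features in rows (rownames = feature ids), runs
#'   in columns.
#' @param path TSV path.
#' @export
write_quant_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  tab <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_quant_matrix
#' @return `read_quant_matrix()` returns the numeric matrix.
#' @export
read_quant_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  .check_columns(tab, "feature_id", "quantitation matrix")
  mat <- as.matrix(tab[, setdiff(names(tab), "feature_id"), drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- tab$feature_id
  mat
}

#' Read a study-design table
#'
#' Mandatory columns: `run_id`, `sample_type` (DONOR/SPQC/EFQC/NC/BLANK),
#' `group` (RA/CONTROL/NA), `sex`, `batch`.
#'
#' @param path design TSV.
#' @return Data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  .check_columns(tab, c("run_id", "sample_type", "group", "sex", "batch"),
                 "design table")
  tab
}

#' @rdname read_design
#' @param design design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
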