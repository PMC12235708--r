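# Residue elemental compositions for the 20 canonical amino acids
# (residue = amino acid - water); peptide mass = sum(residues) + water.
RESIDUE_FORMULA <- c(
  G = "C2H3NO",    A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",    T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",   N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O",  E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",    R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

RESIDUE_MASS <- local({
  m <- vapply(RESIDUE_FORMULA, function(f) monoisotopic_mass(parse_formula(f)),
              numeric(1))
  names(m) <- names(RESIDUE_FORMULA)
  m
})

#' A (possibly modified) peptide ion
#'
#' Modifications are positional mass deltas; the canonical text form is the
#' bracket notation used throughout the field, e.g.
#' `"LK[+312.089]C[+57.021]ASLQK"`. A modification may carry a registry name,
#' but only its mass enters the arithmetic.
#'
#' @param sequence one-letter residue string (20 canonical residues).
#' @param mods data frame with columns `pos` (1-based residue index), `mass`
#'   (delta in Da) and optionally `name`; or `NULL` for an unmodified peptide.
#' @param charge positive integer charge state.
#' @return An object of class `peptide_ion`.
#' @export
peptide_ion <- function(sequence, mods = NULL, charge = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(RESIDUE_MASS))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(), mass = numeric(), name = character())
  }
  stopifnot(is.data.frame(mods), all(c("pos", "mass") %in% names(mods)))
  if (!"name" %in% names(mods)) mods$name <- NA_character_
  mods <- mods[, c("pos", "mass", "name")]
  if (nrow(mods) > 0) {
    if (any(mods$pos < 1L | mods$pos > nchar(sequence))) {
      stop("modification position outside the sequence", call. = FALSE)
    }
    mods <- mods[order(mods$pos), , drop = FALSE]
    rownames(mods) <- NULL
  }
  if (!(is.numeric(charge) && length(charge) == 1L && charge >= 1)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  p <- structure(list(sequence = sequence, mods = mods,
                      charge = as.integer(charge)),
                 class = "peptide_ion")
  if (peptide_neutral_mass(p) <= 0) {
    stop("peptide neutral mass must be strictly positive", call. = FALSE)
  }
  p
}

#' Parse bracket-notation peptide text
#'
#' Accepts the notation printed in identification reports, e.g.
#' `"LK[+312.089]C[+57.021]ASLQK"`: a bracketed signed mass after a residue
#' modifies that residue. The decimal separator is always `.`.
#'
#' @param text peptide string with optional `[+mass]` / `[-mass]` brackets.
#' @param charge charge state of the ion.
#' @return A `peptide_ion`.
#' @export
parse_peptide <- function(text, charge = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[\u00ad\u200b]", "", text)  # soft hyphens etc. from copy-paste
  seq_chars <- character()
  pos <- integer(); mass <- numeric()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substring(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substring(s, i), fixed = TRUE)
      if (j < 0) stop("unbalanced '[' in peptide notation", call. = FALSE)
      inner <- substring(s, i + 1L, i + j - 2L)
      delta <- suppressWarnings(as.numeric(inner))
      if (is.na(delta)) {
        stop(sprintf("cannot parse modification mass '%s'", inner),
             call. = FALSE)
      }
      if (length(seq_chars) == 0) {
        stop("modification bracket before any residue", call. = FALSE)
      }
      pos <- c(pos, length(seq_chars))
      mass <- c(mass, delta)
      i <- i + j
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  peptide_ion(paste(seq_chars, collapse = ""),
              mods = data.frame(pos = pos, mass = mass,
                                name = rep(NA_character_, length(pos))),
              charge = charge)
}

#' Bracket-notation text form of a peptide ion
#' @param p a `peptide_ion`.
#' @param digits decimals used for the bracketed masses.
#' @export
format_peptide <- function(p, digits = 3) {
  stopifnot(inherits(p, "peptide_ion"))
  residues <- strsplit(p$sequence, "")[[1]]
  out <- residues
  if (nrow(p$mods) > 0) {
    for (k in seq_len(nrow(p$mods))) {
      i <- p$mods$pos[k]
      out[i] <- paste0(out[i], sprintf("[%+.*f]", digits, p$mods$mass[k]))
    }
  }
  paste(out, collapse = "")
}

#' @export
print.peptide_ion <- function(x, ...) {
  cat("<peptide_ion> ", format_peptide(x), "  z=", x$charge,
      "  m/z ", sprintf("%.4f", precursor_mz(x)), "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a peptide ion
#'
#' `sum(residues) + sum(modification deltas) + water`.
#'
#' @param p a `peptide_ion`.
#' @return Mass in Da.
#' @export
peptide_neutral_mass <- function(p) {
  stopifnot(inherits(p, "peptide_ion"))
  residues <- strsplit(p$sequence, "")[[1]]
  sum(RESIDUE_MASS[residues]) + sum(p$mods$mass) + WATER_MASS
}

#' Precursor m/z of a peptide ion
#'
#' `(neutral + z * proton) / z`; the charge is carried by protons.
#'
#' @param p a `peptide_ion`.
#' @param charge optional charge override.
#' @return m/z.
#' @examples
#' precursor_mz(peptide_ion("EGVNDNEEGFFSAR", charge = 2))  # 785.842
#' @export
precursor_mz <- function(p, charge = p$charge) {
  stopifnot(charge >= 1)
  (peptide_neutral_mass(p) + charge * PROTON_MASS) / charge
}

#' b- and y-fragment ion m/z
#'
#' `b_k` sums the first k residues (plus mods in range) plus protons;
#' `y_k` sums the last k residues (plus mods) plus water plus protons.
#'
#' @param p a `peptide_ion`.
#' @param series `"b"` or `"y"`.
#' @param index fragment index k, `1 <= k < nchar(sequence)`.
#' @param charge fragment charge (default 1).
#' @return m/z of the fragment ion.
#' @examples
#' fragment_mz(parse_peptide("LK[+312.089]C[+57.021]ASLQK"), "y", 6)  # 706.355
#' @export
fragment_mz <- function(p, series = c("b", "y"), index, charge = 1L) {
  stopifnot(inherits(p, "peptide_ion"))
  series <- match.arg(series)
  n <- nchar(p$sequence)
  if (!(index >= 1 && index < n)) {
    stop(sprintf("fragment index %d out of range for a %d-mer", index, n),
         call. = FALSE)
  }
  residues <- strsplit(p$sequence, "")[[1]]
  if (series == "b") {
    keep <- seq_len(index)
    base <- sum(RESIDUE_MASS[residues[keep]])
  } else {
    keep <- seq.int(n - index + 1L, n)
    base <- sum(RESIDUE_MASS[residues[keep]]) + WATER_MASS
  }
  modm <- sum(p$mods$mass[p$mods$pos %in% keep])
  (base + modm + charge * PROTON_MASS) / charge
}

#' Theoretical b/y fragment table for a peptide ion
#'
#' Convenience enumeration of all b_k and y_k fragments at a given charge.
#'
#' @param p a `peptide_ion`.
#' @param charge fragment charge.
#' @return Data frame with columns `series`, `index`, `charge`, `mz`.
#' @export
fragment_table <- function(p, charge = 1L) {
  n <- nchar(p$sequence)
  idx <- seq_len(n - 1L)
  rbind(
    data.frame(series = "b", index = idx, charge = charge,
               mz = vapply(idx, function(k) fragment_mz(p, "b", k, charge),
                           numeric(1))),
    data.frame(series = "y", index = idx, charge = charge,
               mz = vapply(idx, function(k) fragment_mz(p, "y", k, charge),
                           numeric(1)))
  )
}
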