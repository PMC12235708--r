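# Relative isotope abundances per element, indexed by nominal mass offset
# (0, +1, +2, ...). Sulfur's +4 slot holds 36S.
ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

# convolve two truncated abundance polynomials, keeping `len` terms
.conv_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    jmax <- min(length(b), len - i + 1L)
    if (jmax < 1L) break
    j <- seq_len(jmax)
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

# p(x)^n by exponentiation-by-squaring with truncation
.conv_pow <- function(p, n, len) {
  result <- c(1, numeric(len - 1L))
  base <- .conv_trunc(p, c(1, numeric(len - 1L)), len)
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .conv_trunc(result, base, len)
    base <- .conv_trunc(base, base, len)
    n <- n %/% 2L
  }
  result
}

#' Aggregated isotope distribution of a composition
#'
#' Nominal-mass (unit-spaced) isotopologue abundances, computed by per-element
#' polynomial convolution of tabulated isotope abundances, then convolved
#' across elements. Abundances are normalized to sum to 1 over the returned
#' peaks. Used to emulate the precursor isotope-pattern checks of
#' peptide-centric DIA validation.
#'
#' @param x an `elem_comp` with non-negative counts (deltas have no isotope
#'   pattern), or a formula string.
#' @param n_peaks number of isotopologue peaks to return (>= 1).
#' @return Data frame with columns `offset` (nominal mass offset) and
#'   `abundance`.
#' @examples
#' isotope_distribution(comp(C = 1), 2)  # 0.9893, 0.0107
#' @export
isotope_distribution <- function(x, n_peaks = 3L) {
  if (is.character(x)) x <- parse_formula(x)
  stopifnot(inherits(x, "elem_comp"), n_peaks >= 1L)
  counts <- unclass(x)
  if (any(counts < 0)) {
    stop("isotope distributions are defined for non-negative counts only",
         call. = FALSE)
  }
  len <- as.integer(n_peaks)
  acc <- c(1, numeric(len - 1L))
  for (e in ELEMENTS) {
    if (counts[[e]] > 0L) {
      acc <- .conv_trunc(acc, .conv_pow(ISOTOPE_ABUNDANCE[[e]], counts[[e]],
                                        len), len)
    }
  }
  data.frame(offset = seq_len(len) - 1L, abundance = acc / sum(acc))
}
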