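# Monoisotopic atomic masses (Da), NIST values truncated at 6 decimals.
# The proton mass carries the charge; electron mass is ignored throughout.
MONOISOTOPIC_MASS <- c(
  C = 12.000000,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  S = 31.972071
)

PROTON_MASS <- 1.007276

ELEMENTS <- names(MONOISOTOPIC_MASS)

#' Elemental composition over C, H, N, O, S
#'
#' Compositions are the currency of all mass arithmetic in the package. Counts
#' are signed integers so that modification deltas (e.g. the allysine delta
#' O - NH3) can be represented; mass is linear in the counts and the zero
#' composition has mass zero. `+` and `-` act element-wise.
#'
#' @param C,H,N,O,S signed integer element counts.
#' @return An object of class `elem_comp` (named integer vector).
#' @examples
#' comp(H = 2, O = 1)              # water
#' comp(C = 3, H = 2, N = 2, O = 1) # the unknown +82.017 modification
#' @export
comp <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  x <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(is.na(x)) || any(x != round(x))) {
    stop("element counts must be integers", call. = FALSE)
  }
  structure(as.integer(round(x)), names = ELEMENTS, class = "elem_comp")
}

#' Parse a molecular formula restricted to C, H, N, O and S
#'
#' Accepts signed counts, e.g. `"C3H2N2O"`, `"H-2"` or `"O1N-1H-3"` (the
#' allysine delta). Element symbols outside C/H/N/O/S are rejected.
#'
#' @param formula formula string.
#' @return An `elem_comp`.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  if (s == "" || s == "0") return(comp())
  m <- gregexpr("[A-Za-z][a-z]?-?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  }
  counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  for (tok in tokens) {
    sym <- sub("^([A-Za-z][a-z]?).*$", "\\1", tok)
    if (!sym %in% ELEMENTS) {
      stop(sprintf("unknown element symbol '%s' in '%s'", sym, formula),
           call. = FALSE)
    }
    num <- substring(tok, nchar(sym) + 1L)
    counts[sym] <- counts[sym] + if (num == "") 1L else as.integer(num)
  }
  do.call(comp, as.list(counts))
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop(sprintf("operation '%s' not defined for elemental compositions",
                 .Generic), call. = FALSE)
  }
  if (.Generic == "==") return(all(unclass(e1) == unclass(e2)))
  if (missing(e2)) {  # unary minus
    return(structure(get(.Generic)(unclass(e1)), names = ELEMENTS,
                     class = "elem_comp"))
  }
  stopifnot(inherits(e1, "elem_comp"), inherits(e2, "elem_comp"))
  structure(get(.Generic)(unclass(e1), unclass(e2)),
            names = ELEMENTS, class = "elem_comp")
}

#' Render a composition as a formula string (CHNOS order, zeros omitted)
#' @param x an `elem_comp`.
#' @export
format_formula <- function(x) {
  stopifnot(inherits(x, "elem_comp"))
  n <- unclass(x)
  parts <- vapply(ELEMENTS, function(e) {
    if (n[[e]] == 0L) "" else if (n[[e]] == 1L) e else paste0(e, n[[e]])
  }, character(1))
  out <- paste0(parts, collapse = "")
  if (out == "") "0" else out
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp> ", format_formula(x), "  (",
      sprintf("%.6f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Exact monoisotopic mass of an elemental composition
#'
#' Mass is the linear form `sum(count_e * atomic_mass_e)`; negative counts
#' (modification deltas) are allowed and yield negative contributions.
#'
#' @param x an `elem_comp`, or a formula string that [parse_formula()] accepts.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C3H2N2O")  # 82.016713, prints as 82.02
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  stopifnot(inherits(x, "elem_comp"))
  sum(unclass(x) * MONOISOTOPIC_MASS)
}

WATER <- NULL     # initialised in .onLoad-free static block below
AMMONIA <- NULL

# static module-level constants (evaluated at install time)
WATER <- structure(c(0L, 2L, 0L, 1L, 0L), names = c("C", "H", "N", "O", "S"),
                   class = "elem_comp")
AMMONIA <- structure(c(0L, 3L, 1L, 0L, 0L), names = c("C", "H", "N", "O", "S"),
                     class = "elem_comp")
WATER_MASS <- sum(unclass(WATER) * MONOISOTOPIC_MASS)
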