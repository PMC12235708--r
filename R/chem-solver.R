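#' Default element count bounds for composition decomposition
#'
#' Bounds sized for modification deltas (not whole peptides): C 0-20, H 0-40,
#' N 0-10, O 0-15, S 0-3.
#'
#' @return Named list of `c(min, max)` integer pairs.
#' @export
default_solver_bounds <- function() {
  list(C = c(0L, 20L), H = c(0L, 40L), N = c(0L, 10L), O = c(0L, 15L),
       S = c(0L, 3L))
}

#' Ring-and-double-bond equivalents
#'
#' `RDBE = C - H/2 + N/2 + 1`; integer and non-negative for even-electron
#' neutral CHNOS compositions.
#'
#' @param C,H,N carbon, hydrogen and nitrogen counts (vectorized).
#' @return RDBE value(s).
#' @export
rdbe <- function(C, H, N) C - H / 2 + N / 2 + 1

#' Decompose an accurate mass into elemental compositions
#'
#' Exhaustive enumeration over per-element count bounds; candidates within
#' `tol` of the target mass are returned ordered by absolute mass error. With
#' `require_integer_rdbe` (the default) compositions whose ring-and-double-bond
#' equivalents are non-integer or negative are excluded: modification deltas
#' are treated as even-electron neutral moieties, which removes radical
#' compositions that otherwise fall inside typical tolerances.
#'
#' @param target target mass in Da.
#' @param tol absolute tolerance in Da (> 0).
#' @param bounds per-element count bounds as in [default_solver_bounds()].
#' @param require_integer_rdbe exclude non-integer / negative RDBE candidates.
#' @return Data frame with columns `formula`, `C`, `H`, `N`, `O`, `S`, `mass`,
#'   `error`, `rdbe`, ordered by `abs(error)`. Zero rows is a valid answer.
#' @examples
#' solve_composition(82.02, 0.01)$formula  # contains "C3H2N2O"
#' @export
solve_composition <- function(target, tol, bounds = default_solver_bounds(),
                              require_integer_rdbe = TRUE) {
  stopifnot(is.numeric(target), length(target) == 1L, tol > 0)
  stopifnot(is.list(bounds), all(ELEMENTS %in% names(bounds)))
  for (e in ELEMENTS) {
    b <- bounds[[e]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2]) {
      stop(sprintf("invalid bounds for element %s", e), call. = FALSE)
    }
  }
  grid <- expand.grid(
    C = seq.int(bounds$C[1], bounds$C[2]),
    H = seq.int(bounds$H[1], bounds$H[2]),
    N = seq.int(bounds$N[1], bounds$N[2]),
    O = seq.int(bounds$O[1], bounds$O[2]),
    S = seq.int(bounds$S[1], bounds$S[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  mass <- as.numeric(as.matrix(grid) %*% MONOISOTOPIC_MASS[names(grid)])
  keep <- abs(mass - target) <= tol
  grid <- grid[keep, , drop = FALSE]
  mass <- mass[keep]
  r <- rdbe(grid$C, grid$H, grid$N)
  if (require_integer_rdbe) {
    ok <- abs(r - round(r)) < 1e-9 & r >= 0
    grid <- grid[ok, , drop = FALSE]
    mass <- mass[ok]
    r <- r[ok]
  }
  err <- mass - target
  ord <- order(abs(err))
  grid <- grid[ord, , drop = FALSE]
  out <- data.frame(
    formula = vapply(seq_len(nrow(grid)), function(i) {
      format_formula(comp(C = grid$C[i], H = grid$H[i], N = grid$N[i],
                          O = grid$O[i], S = grid$S[i]))
    }, character(1)),
    grid,
    mass = mass[ord],
    error = err[ord],
    rdbe = r[ord]
  )
  rownames(out) <- NULL
  out
}
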