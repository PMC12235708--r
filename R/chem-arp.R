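# ARP (aldehyde reactive probe, N'-aminooxymethylcarbonylhydrazino-D-biotin)
# free base C12H21N5O4S. Oxime condensation with a carbonyl releases water,
# so the net mass added to a carbonyl-bearing residue is ARP - H2O.
ARP_COMPOSITION <- parse_formula("C12H21N5O4S")
BIOTIN_COMPOSITION <- parse_formula("C10H16N2O3S")

#' ARP oxime net addition
#'
#' The composition (and mass) added to a residue when its reactive carbonyl is
#' derivatized by ARP: the probe free base minus the water released by oxime
#' formation. Every observed "ARP-related mass shift" equals the underivatized
#' modification delta plus this constant (313.1209 Da).
#'
#' @return An `elem_comp` of mass ~313.1209 Da.
#' @export
arp_oxime_addition <- function() ARP_COMPOSITION - WATER

ARP_OXIME_MASS <- monoisotopic_mass(ARP_COMPOSITION - WATER)

#' A named carbonyl modification
#'
#' @param name registry name.
#' @param targets character vector of one-letter residue codes the modification
#'   occurs on.
#' @param delta underivatized delta as an `elem_comp`, formula string, or
#'   `NULL` when only the mass is known.
#' @param delta_mass underivatized delta mass in Da; required when `delta` is
#'   `NULL`, otherwise derived from the composition.
#' @param arp_labelable does the modification leave a reactive carbonyl that
#'   ARP derivatizes?
#' @param pathway one of `"MCO"` (metal-catalyzed oxidation), `"RCS"` (reactive
#'   carbonyl species adduct), `"UNKNOWN"`, or `"NONE"` for non-carbonyl fixed
#'   modifications carried along for mass arithmetic (e.g. carbamidomethyl).
#' @return An object of class `modification_spec`; field `arp_shift_da` holds
#'   the derived ARP-related mass shift for labelable modifications.
#' @export
modification_spec <- function(name, targets, delta = NULL, delta_mass = NULL,
                              arp_labelable = TRUE,
                              pathway = c("MCO", "RCS", "UNKNOWN", "NONE")) {
  pathway <- match.arg(pathway)
  if (is.character(delta)) delta <- parse_formula(delta)
  if (!is.null(delta)) {
    stopifnot(inherits(delta, "elem_comp"))
    delta_mass <- monoisotopic_mass(delta)
  }
  if (is.null(delta_mass)) {
    stop("either a delta composition or a delta mass is required",
         call. = FALSE)
  }
  structure(list(
    name = name,
    targets = targets,
    delta = delta,
    delta_mass = delta_mass,
    arp_labelable = isTRUE(arp_labelable),
    pathway = pathway,
    arp_shift_da = if (isTRUE(arp_labelable)) delta_mass + ARP_OXIME_MASS
                   else NA_real_
  ), class = "modification_spec")
}

#' @export
print.modification_spec <- function(x, ...) {
  cat("<modification_spec> ", x$name,
      "  targets ", paste(x$targets, collapse = "/"),
      "  delta ", sprintf("%+.4f", x$delta_mass), " Da",
      if (x$arp_labelable) sprintf("  ARP shift %+.4f Da", x$arp_shift_da),
      "  [", x$pathway, "]\n", sep = "")
  invisible(x)
}

#' ARP-related mass shift of a modification
#'
#' Observed shift of an ARP-derivatized modified residue relative to the
#' unmodified residue: underivatized delta plus the oxime net addition.
#'
#' @param mod a `modification_spec` with `arp_labelable = TRUE`.
#' @return Shift in Da.
#' @examples
#' reg <- load_modification_registry()
#' arp_shift(reg$glycoaldehyde_aldimine)  # 355.1314
#' @export
arp_shift <- function(mod) {
  stopifnot(inherits(mod, "modification_spec"))
  if (!mod$arp_labelable) {
    stop(sprintf(
      "modification '%s' carries no reactive carbonyl and is not ARP-labelable",
      mod$name), call. = FALSE)
  }
  mod$delta_mass + ARP_OXIME_MASS
}

#' Load the carbonyl modification registry
#'
#' The bundled registry covers the reactive-carbonyl and metal-catalyzed
#' oxidation chemistry observed on abundant serum proteins (glycoaldehyde /
#' glyoxal aldimines, acrolein and malondialdehyde/methylglyoxal adducts,
#' hexose glycation, allysine, oxo-Thr/His, Met side-chain cleavage), six
#' unknown deltas known only by accurate mass (one with composition C3H2N2O),
#' plus the non-labelable fixed modifications carbamidomethyl and Met
#' oxidation.
#'
#' @param path registry TSV (columns `name`, `targets`, `delta_formula`,
#'   `delta_mass`, `arp_labelable`, `pathway`); defaults to the bundled file.
#' @return Named list of `modification_spec` objects.
#' @export
load_modification_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modification_registry.tsv",
                        package = "arpscreen", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "")
  need <- c("name", "targets", "delta_formula", "delta_mass",
            "arp_labelable", "pathway")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("registry file lacks mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    modification_spec(
      name = tab$name[i],
      targets = strsplit(tab$targets[i], ",", fixed = TRUE)[[1]],
      delta = if (!is.na(tab$delta_formula[i])) tab$delta_formula[i] else NULL,
      delta_mass = if (!is.na(tab$delta_mass[i])) tab$delta_mass[i] else NULL,
      arp_labelable = as.logical(tab$arp_labelable[i]),
      pathway = tab$pathway[i]
    )
  })
  names(out) <- tab$name
  out
}

# Reporter m/z constants as printed in spectra of ARP-peptides; the 227.08
# signal is the protonated, dehydrated biotin moiety and is computable from
# composition, the three larger reporters are stored as constants only.
ARP_REPORTER_MZ <- c(arp_332 = 332.14, arp_299 = 299.12, arp_259 = 259.12,
                     biotin_227 = 227.08)

#' ARP reporter-ion table
#'
#' The four diagnostic low-mass fragments of ARP-peptides. The 227.08 entry
#' (biotin fragment) additionally carries the m/z computed from composition:
#' biotin + proton - water = 227.0849.
#'
#' @return Data frame with columns `label`, `mz`, and `mz_calc` (computed m/z,
#'   `NA` where no composition is assigned).
#' @export
reporter_ion_table <- function() {
  biotin_frag <- monoisotopic_mass(BIOTIN_COMPOSITION) + PROTON_MASS -
    WATER_MASS
  data.frame(
    label = names(ARP_REPORTER_MZ),
    mz = unname(ARP_REPORTER_MZ),
    mz_calc = c(NA_real_, NA_real_, NA_real_, biotin_frag)
  )
}
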