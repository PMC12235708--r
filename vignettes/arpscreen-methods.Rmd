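---
title: "Methods: ARP carbonylation screening and quantitation"
author: "arpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ARP carbonylation screening and quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arpscreen)
```

# Scope

`arpscreen` implements the computational core of a serum protein-carbonylation
screen built around the aldehyde reactive probe (ARP,
N'-aminooxymethylcarbonylhydrazino-D-biotin): exact derivatization mass
chemistry, reporter-ion screening of DDA spectra, spectral-similarity
inference of unknown modification mass shifts under ion-mobility constraints,
and peptide-centric DIA quantitation with negative-control filtering, QC and
a batch-aware two-group comparison. Every stage can be exercised end to end
on seeded synthetic LC-IMS-MS data with ground truth.

# The chemistry model

All mass arithmetic lives on signed elemental compositions over C, H, N, O
and S. Monoisotopic atomic masses are fixed to NIST values at six decimals
(C 12, H 1.007825, N 14.003074, O 15.994915, S 31.972071); the charge is
carried by protons at 1.007276 Da and electron mass is neglected. Mass is
linear in the counts, so modification deltas may be negative (the allysine
delta is O − NH3 = −1.0316 Da).

ARP condenses with a reactive carbonyl as an oxime, releasing water. The net
mass added to a carbonylated residue is therefore the probe free base
(C12H21N5O4S, 331.1314 Da) minus water: **313.1209 Da**, the single constant
that links every underivatized modification delta to its observed
"ARP-related mass shift". This accounting is confirmed redundantly by pairs
of reported shifts the registry was seeded from (e.g. 355.1314 − 42.0106
and 475.174 − 162.053 agree to ≤ 1 mDa).

The modification registry bundles the carbonyl chemistry observed on
abundant serum proteins:

| class | examples (underivatized delta) |
|---|---|
| RCS adducts | glycoaldehyde aldimine C2H2O; glyoxal aldimine C2H2O2; acrolein Michael C3H4O; MDA/MG Michael C3H4O2; MDA/MG Schiff C3H2O; hexose glycation C6H10O5 |
| MCO products | allysine O−NH3; 2-oxo-Thr −H2; oxo-His +O; Met side-chain cleavage O−CH4S |
| unknowns | fixed masses +68.026, +70.017, +82.017 (C3H2N2O), +86.012, +96.021, +106.006 |
| fixed (non-carbonyl) | carbamidomethyl C2H3NO; Met oxidation +O |

Reported values for one species are internally inconsistent: +395.137,
+395.138 and 395.089 Da are all in circulation for the same modification.
The registry stores the value derived from its composition, 313.1209 +
mass(C3H2N2O) = 395.1376 Da, and treats the 395.089 figure as a
typographical error. No compositions are established for the three larger
reporter ions (332.14, 299.12, 259.12), so they are stored as fixed
constants,
while 227.08 is computed from the biotin moiety (C10H16N2O3S + H − H2O =
227.0849).

## Composition decomposition

`solve_composition()` enumerates all CHNOS compositions inside per-element
bounds (defaults C 0–20, H 0–40, N 0–10, O 0–15, S 0–3 — sized for
modification deltas, not peptides) and keeps candidates within a mass
tolerance, ordered by absolute error. By default candidates must have
integer, non-negative ring-and-double-bond equivalents
(RDBE = C − H/2 + N/2 + 1): deltas are modeled as even-electron neutral
moieties, which removes radical compositions such as C4H4NO that otherwise
fall within ±0.01 Da of 82.02. The enumeration is deliberately exhaustive
(≈ 600k grid points at the default bounds, well under a second); a second,
loop-based implementation exists only in the test suite as an oracle.

Isotope patterns are aggregated per nominal mass offset and computed by
per-element polynomial convolution with exponentiation-by-squaring,
truncated to the requested number of peaks and renormalized; the test oracle
convolves atom by atom without truncation.

# Reporter-ion screening

ARP-peptides produce diagnostic low-mass fragments at m/z 332.14, 299.12,
259.12 and 227.08, the last being the dehydrated protonated biotin and
consistently the most intense. The screening rule, applied per spectrum:
a reporter matches the nearest peak within 25 mDa (the fragment-level search
tolerance used throughout) at ≥ 1% of the base peak; a spectrum is a hit iff
the 227.08 anchor matches and at least two reporters match. Published reporter-screening tools do not document their matching
thresholds, so these defaults are this package's choices, and all of them
are parameters. Reporter
intensity ratios are reported but never filtered on (they vary between
modifications). Collection-level screening cross-references the FDR-passing
PSM table and reports the fraction of reporter-bearing spectra without any
assignment — the discovery pool for unknown modifications. With zero hits
that fraction is reported as undefined, not zero.

# Unknown-shift inference

An *anchor* is a confidently identified ARP-peptide whose theoretical b/y
ladder is observed in its own spectrum (≥ 3 annotated fragments). A
candidate is an unassigned reporter-bearing spectrum. Matching requires
co-mobility — |candidate drift − anchor drift| ≤ 0.5 ms (typical reported
precursor–fragment offsets are about 0.2 ms and no operating range is
established, so 0.5 ms is a package default, configurable) — and fragment agreement within 25 mDa.
Candidate peaks below 2% of the base peak are not accepted as fragment
evidence; weak background peaks otherwise occasionally coincide with a
fragment m/z and corrupt localization.

The precursor mass difference Δ = (m/z − proton)·z − anchor neutral mass is
interpreted as a different modification on the residues not covered by
shared unshifted fragments. Localization uses only *contiguous* unshifted
ladders: an unshifted b_k places the shift after position k, an unshifted
y_k before position n−k+1, and the smallest consistent interval is reported
— as an interval, never silently collapsed. An isolated match beyond a gap
in its series is not counted (it is indistinguishable from a chance
coincidence). If both full ladders match despite Δ ≠ 0 the hypothesis is
flagged ambiguous rather than dropped. Precursor deltas below 0.01 Da
collapse the hypothesis to the anchor identity.

The underivatized delta (total site mass − 313.1209) feeds the composition
solver. Negative deltas are reported without a composition search. After a
new modification is characterized, `rescan_with_new_mod()` re-matches the
unassigned pool against the identified peptide repertoire allowing the new
total shift at any Lys/Cys site (replacing an existing ARP modification at
that site, never a fixed one); because a wrong-site variant of the right
sequence still shares the terminal fragments, only the best-supported
site(s) per spectrum are kept. Consensus across spectra uses recurrence:
the modal delta (at 2 decimals) across hypotheses, since chance matches
scatter over the mass axis while a real modification recurs.

# DIA quantitation

Retention time is aligned per run by an affine least-squares fit of observed
apex times against library iRT values for 10 endogenous ARP-peptide
standards. XICs sum signal intensity over a ±15 ppm m/z window restricted to
a ±0.5 ms drift window — the mobility restriction is what removes
integration interference from co-eluting isobars. Peaks are integrated
trapezoidally between valley-to-valley boundaries found by walking outward
from the apex inside a ±0.5 min window around the predicted retention time;
there is no model peak fitting. Features with fewer than 9 points strictly
inside the boundaries are flagged (at the 1.2 s DIA cycle a 0.05 min-sd peak
comfortably exceeds 9 points; a 6 s cycle does not).

Signal-to-background divides each feature's area by the retention-time-
matched window area in the underivatized negative control of the same batch.
Flags use strict inequalities at 3 and 10. The NC floor is a pure division
guard at 1% of the median positive NC area: since genuine matrix background
is present in every NC window, flooring at the median itself would inflate
half of all backgrounds. Interference is flagged when the NC window's apex
exceeds the feature's apex. Per-batch QC reproducibility is the fraction of
features with CV = sd/mean < 20% across the three SPQC replicates of a
batch; zero-mean features are excluded with a warning.

Normalization follows the protein-level top-5 rule: a modified peptide's
area is divided by the summed area of its protein's five most intense
nonenriched peptides (fewer than five: all of them), because tryptic
cleavage is suppressed at modified lysines and unmodified-peptide
normalization would be biased. Features whose protein is missing from the
nonenriched table are passed through unadjusted and flagged.

The group comparison fits, per feature over donor runs,
log2(adjusted area) ~ group + batch, with Benjamini–Hochberg correction
across features, and the conventional decision surface |log2FC| > 1 and
adjusted p < 0.05. An explicit linear model is used rather than a full peptide-level
mixed-model framework: what the analysis requires is the normalization and
a batch-aware comparison, and an explicit model is directly testable (its
type-I error is verified at α = 0.05 by simulation).

# The synthetic cohort

The generator is first-class, tested code; its defaults *are* the study
conditions: 39 RA donors (30 F / 9 M) and 29 controls (16 F / 13 M)
block-randomized into two batches matched for group and sex (within every
group × sex stratum the batch counts differ by ≤ 1), 3 SPQC + 3 EF-QC + 1 NC
run per batch, 86 ARP-peptide features with 10 iRT standards, 1.2 s cycle
over a 45 min gradient, 0.05 min elution peak sd, and a 21.8% batch-2
intensity decay applied to every batch-2 run.

Abundances: each feature has a lognormal NC background level per batch; each
donor × feature pair receives a log-normal true S/B ratio composed of a
between-feature base and inter-donor variation with log2 sd 1.0. Realistic
inter-donor variance is not established for this kind of data, so it is an
exposed parameter (`donor_log2_sd`); 1.0 (donor-to-donor spread of about
2-fold) is the package's default reading of "large variation between
donors". The pooled log ratios are then affinely calibrated (a monotone
map, so log-normality is preserved) such that exactly
`round(0.941 · n_pairs)` pairs exceed ratio 3 and `round(0.767 · n_pairs)`
exceed 10 — the planted fractions are recovered by the pipeline at printed
precision. QC replicates are planted as symmetric (1−d, 1, 1+d) triplets,
whose sample CV equals d exactly, with d drawn below or above the 20%
threshold according to planted per-batch pass counts
(`round(c(0.798, 0.753) · 86)` = 69 and 65 features, i.e. 80.2% and 75.6% —
the closest fractions representable with 86 features). The group effect is
multiplicative and defaults to 1 (the null).

NC runs contain only broad background bumps (Gaussian sd 0.09 min), wide
enough to be visibly background-like but with their ±5 sd support inside the
±0.5 min integration window, so planted ratios are recovered to ~10⁻⁵
relative. DDA spectra carry exact b/y ladders with 3 mDa Gaussian m/z noise
(0.3 mDa on precursors), reporters iff the peptide is ARP-labeled, and weak
background peaks (0.2–1.5% of base) kept ≥ 75 mDa away from reporter m/z.
Drift times follow a simple affine model in m/z per charge state — only
relative offsets matter to any consumer. Feature sets are generated so that
precursors are mutually resolvable (no pair within 25 ppm m/z *and* 0.7 ms
drift), mirroring the manual curation that validated quantifiable peptides;
without this, colliding standards can corrupt a run's iRT calibration.

What the generator does **not** emulate: chimeric spectra, detector
saturation, peak tailing and shape drift, missing values, charge-state
envelopes and co-isolation, EF-QC within-queue signal decay beyond the
batch-2 factor, and real inter-protein abundance structure. Green tests
therefore demonstrate correctness of the implemented inference on data
satisfying its assumptions, not robustness to everything real instruments
produce.

# Numerical choices and degenerate inputs

* Nearest-peak-wins within tolerance for all m/z matching; ties are broken
  by the smaller index (deterministic).
* Trapezoidal integration; a flat-zero trace integrates to 0 with 0 points;
  a window excluding the apex yields degenerate boundaries and ~0 area.
* `fit_irt()` requires ≥ 2 standards with distinct iRT and errors otherwise;
  with exactly 2 the residual sd is reported as 0.
* Missing drift times skip the mobility gate with a warning — absent is
  never treated as zero, in MGF parsing as in matching.
* An empty solver result, an empty reporter-hit set (fraction undefined, not
  0) and an empty rescan are all valid answers, not errors.
* Writers format numbers at fixed precision (9 decimals) so identical inputs
  give byte-identical files; missing quantitation cells round-trip as `NA`.

# Problem sizes used by the tests

The unit suite runs scaled-down cohorts (10–20 features, 12 donors) chosen
to exercise every code path in seconds. The property-level checks use the
full study geometry where it matters: planted-shift recovery on the
86-feature set, calibration of the group test over 500 simulated replicates,
and 20 independently seeded full cohorts (86 × 68 plus QC/NC) for the
end-to-end null analysis. These sizes are the package's choices, balancing
statistical resolution against a test suite that stays pleasant to run.

# Known limitations

* One drift time per spectrum: per-fragment mobility (as printed for a
  worked y6 ion) is not representable in MGF, so the co-mobility gate
  operates at the precursor level.
* Localization needs flanking fragment coverage; with partial ladders the
  reported interval widens accordingly, and intervals are never collapsed by
  heuristics.
* The linear-model comparison assumes log-normal adjusted areas and a fixed
  batch offset; it does not model feature-level correlation beyond the
  shared protein normalization.
* The composition solver is bounded to CHNOS and modification-delta-sized
  molecules by design.
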