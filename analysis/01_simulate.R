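#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the full two-batch cohort (39 RA + 29 control donors, 86
# ARP-peptide features, SPQC/EF-QC/NC runs) plus a DDA spectrum collection
# with 7 planted unknown-shift candidates, and writes every pipeline input
# as plain text under results/data/. The DIA run data themselves are large
# and fully determined by the seed, so downstream stages regenerate them
# with simulate_cohort(seed = SEED) instead of reading them from disk.

suppressPackageStartupMessages(library(arpscreen))

SEED <- 2025
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(cohort_spec(), seed = SEED)
dda <- simulate_dda_collection(cohort$features, n_unassigned = 80,
                               n_plain = 30, seed = SEED + 1)
dda <- plant_unknown_shift(dda, cohort$features, "C3H2N2O", n_sites = 7,
                           seed = SEED + 2)

write_mgf(dda$spectra, file.path(out, "spectra.mgf"))
write_psm_table(dda$psm, file.path(out, "psm.tsv"))
write_design(cohort$design, file.path(out, "design.tsv"))
lib <- cohort$library
for (i in seq_along(lib)) lib[[i]]$feature_id <- cohort$features$feature_id[i]
write_library(lib, file.path(out, "library.tsv"))
write_quant_matrix(cohort$nonenriched$mat, file.path(out, "nonenriched.tsv"))
utils::write.table(
  data.frame(peptide_id = names(cohort$nonenriched$pep_protein),
             protein = unname(cohort$nonenriched$pep_protein)),
  file.path(out, "pep_protein.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(dda$planted, file.path(out, "planted_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(cohort$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)

cat(sprintf(
  "simulated %d runs (%d donors), %d features, %d DDA spectra (%d planted)\n",
  length(cohort$runs), sum(cohort$design$sample_type == "DONOR"),
  nrow(cohort$features), length(dda$spectra), nrow(dda$planted)))
cat(sprintf("planted S/B fractions: %.1f%% > 3, %.1f%% > 10\n",
            100 * cohort$truth$sb_counts["gt3"] / cohort$truth$sb_counts["pairs"],
            100 * cohort$truth$sb_counts["gt10"] / cohort$truth$sb_counts["pairs"]))
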