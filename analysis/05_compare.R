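#!/usr/bin/env Rscript
# Stage 5: top-5 protein normalization and the two-group comparison.
#
# Adjusts each modified peptide's areas by its protein's abundance in the
# nonenriched fraction (sum of the five most intense peptides), then fits
# log2(adjusted area) ~ group + batch per feature over the donor runs with
# Benjamini-Hochberg correction. Under the default (null) cohort the
# expected outcome is the study's negative finding: no feature with
# |log2FC| > 1 at adjusted p < 0.05.

suppressPackageStartupMessages(library(arpscreen))

mat <- read_quant_matrix("results/quant_matrix.tsv")
design <- read_design("results/data/design.tsv")
ne <- read_quant_matrix("results/data/nonenriched.tsv")
pp <- utils::read.delim("results/data/pep_protein.tsv")
pep_protein <- stats::setNames(pp$protein, pp$peptide_id)
lib <- read_library("results/data/library.tsv")
feature_protein <- stats::setNames(
  vapply(lib, `[[`, character(1), "protein"),
  vapply(lib, `[[`, character(1), "feature_id"))

don_runs <- design$run_id[design$sample_type == "DONOR"]
norm <- top5_normalize(mat[, don_runs, drop = FALSE], feature_protein,
                       ne, pep_protein)
res <- differential_test(norm$adjusted, design)
utils::write.table(res, "results/differential.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf("tested %d features (%d skipped)\n", nrow(res), sum(res$skipped)))
cat(sprintf("max |log2FC|: %.2f   min adjusted p: %.3f\n",
            max(abs(res$log2fc), na.rm = TRUE), min(res$adj_p, na.rm = TRUE)))
cat(sprintf("features passing |log2FC| > 1 and adj p < 0.05: %d\n",
            sum(res$significant, na.rm = TRUE)))
if (sum(res$significant, na.rm = TRUE) == 0) {
  cat("consistent with disease-independent basal carbonylation levels\n")
}
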