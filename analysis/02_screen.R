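#!/usr/bin/env Rscript
# Stage 2: reporter-ion screening of the DDA spectra.
#
# Scans every fragment spectrum for the four ARP reporter ions (anchor
# 227.08, >= 2 reporters within 25 mDa at >= 1% of base peak) and
# cross-references the hits against the PSM table. The interesting output is
# the pool of reporter-bearing spectra without any peptide assignment: these
# are the candidates for unknown-modification discovery in stage 3.

suppressPackageStartupMessages(library(arpscreen))

spectra <- read_mgf("results/data/spectra.mgf")
psm <- read_psm_table("results/data/psm.tsv")

res <- screen_collection(spectra, psm, reporter_pattern(),
                         out_tsv = "results/reporter_hits.tsv")

cat(sprintf("screened %d spectra: %d reporter hits, %d (%.1f%%) without PSM\n",
            res$summary$n_screened, res$summary$n_hits,
            res$summary$n_hits_no_psm, 100 * res$summary$fraction_no_psm))
cat("per-spectrum report: results/reporter_hits.tsv\n")
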