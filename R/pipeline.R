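#' Pipeline configuration
#'
#' Collects the tolerances and thresholds of the whole pipeline: 15 ppm
#' precursor / 25 mDa fragment search tolerances, 0.5 ms drift tolerance,
#' reporter-pattern settings, signal-to-background thresholds 3 and 10, 20%
#' CV threshold, and the 2-fold / adjusted-p 0.05 decision surface. The
#' configuration is serialized into the run summary for provenance.
#'
#' @param seed RNG seed for every stochastic stage.
#' @param out_dir output directory for stage tables.
#' @param cohort a [cohort_spec()].
#' @param precursor_ppm,frag_tol_mda,drift_tol_ms search tolerances.
#' @param pattern a [reporter_pattern()].
#' @param n_unassigned_dda,n_plain_dda DDA collection composition.
#' @param plant_delta,plant_sites unknown-shift planting (formula / count;
#'   `plant_sites = 0` disables planting).
#' @param rt_window_min half-width of the integration window around the
#'   predicted retention time.
#' @param min_points minimum points across an LC peak.
#' @param cv_threshold QC CV threshold in percent.
#' @param fc_threshold,alpha differential decision surface.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("arpscreen_"),
                            cohort = cohort_spec(),
                            precursor_ppm = 15, frag_tol_mda = 25,
                            drift_tol_ms = 0.5,
                            pattern = reporter_pattern(),
                            n_unassigned_dda = 80L, n_plain_dda = 30L,
                            plant_delta = "C3H2N2O", plant_sites = 7L,
                            rt_window_min = 0.5, min_points = 9L,
                            cv_threshold = 20, fc_threshold = 2,
                            alpha = 0.05) {
  stopifnot(precursor_ppm > 0, frag_tol_mda > 0, drift_tol_ms > 0,
            cv_threshold > 0, fc_threshold > 0, alpha > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Peptide-centric quantitation of a run set
#'
#' For every run: fit the iRT calibration from the endogenous standard
#' peptides (their apex retention times observed in wide-window XICs), then
#' extract a drift-restricted precursor XIC per library feature around its
#' predicted retention time and integrate it valley-to-valley. NC runs
#' provide the retention-time-matched background areas per batch.
#'
#' @param runs named list of [run_data()] (as from [simulate_cohort()]).
#' @param library list of library entries.
#' @param design design data frame.
#' @param precursor_ppm XIC m/z half-window in ppm.
#' @param drift_tol_ms XIC drift half-window in ms.
#' @param rt_window_min integration half-window around the predicted rt.
#' @param min_points minimum points across the peak.
#' @return List: `areas` (long data frame over non-NC runs), `matrix`
#'   (feature-by-run areas), `nc_areas` (per feature and batch),
#'   `calibrations`.
#' @export
quantify_cohort <- function(runs, library, design, precursor_ppm = 15,
                            drift_tol_ms = 0.5, rt_window_min = 0.5,
                            min_points = 9L) {
  feat_id <- vapply(library, function(e) {
    if (!is.null(e$feature_id)) e$feature_id else format_peptide(e$peptide)
  }, character(1))
  irt <- vapply(library, `[[`, numeric(1), "irt")
  mz <- vapply(library, function(e) precursor_mz(e$peptide), numeric(1))
  drift <- vapply(library, `[[`, numeric(1), "drift_ms")
  is_std <- vapply(library, function(e) isTRUE(e$is_irt_standard), logical(1))
  if (sum(is_std) < 2L) {
    stop("library must flag at least 2 iRT standard entries", call. = FALSE)
  }
  rows <- vector("list", length(runs) * length(library))
  nc_rows <- list()
  calib <- data.frame(run_id = names(runs), slope = NA_real_,
                      intercept = NA_real_, residual_sd = NA_real_)
  ri <- 0L
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    # observed apex rt of the standards over the full gradient
    std_rt <- vapply(which(is_std), function(f) {
      tr <- extract_xic(run, mz[f], ppm = precursor_ppm,
                        drift_center = drift[f], drift_tol = drift_tol_ms)
      integrate_peak(tr, min_points = min_points)$apex_rt
    }, numeric(1))
    cal <- fit_irt(data.frame(irt = irt[is_std], rt = std_rt))
    calib$slope[r] <- cal$slope
    calib$intercept[r] <- cal$intercept
    calib$residual_sd[r] <- cal$residual_sd
    for (f in seq_along(library)) {
      rt_pred <- predict_rt(cal, irt[f])
      tr <- extract_xic(run, mz[f], ppm = precursor_ppm,
                        drift_center = drift[f], drift_tol = drift_tol_ms)
      pk <- integrate_peak(tr, rt_window = c(rt_pred - rt_window_min,
                                             rt_pred + rt_window_min),
                           min_points = min_points)
      if (run$sample_type == "NC") {
        nc_rows[[length(nc_rows) + 1L]] <- data.frame(
          feature_id = feat_id[f], batch = run$batch, nc_area = pk$area,
          nc_apex = pk$apex_intensity)
      } else {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          feature_id = feat_id[f], run_id = run$run_id,
          sample_type = run$sample_type, batch = run$batch,
          area = pk$area, apex_intensity = pk$apex_intensity,
          points_across_peak = pk$points_across_peak,
          few_points = pk$few_points)
      }
    }
  }
  areas <- do.call(rbind, rows[seq_len(ri)])
  nc <- do.call(rbind, nc_rows)
  # average NC replicates within batch (usually a single NC per batch)
  nc <- stats::aggregate(cbind(nc_area, nc_apex) ~ feature_id + batch,
                         data = nc, FUN = mean)
  mat <- matrix(NA_real_, length(library),
                length(unique(areas$run_id)),
                dimnames = list(feat_id, unique(areas$run_id)))
  mat[cbind(match(areas$feature_id, feat_id),
            match(areas$run_id, colnames(mat)))] <- areas$area
  list(areas = areas, matrix = mat, nc_areas = nc, calibrations = calib)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full pipeline on a simulated cohort
#'
#' Orchestrates the stages simulate, screen, infer, quantify, compare and
#' report on a seeded synthetic cohort, writing one TSV per stage plus a
#' JSON/text summary into `config$out_dir`. Outputs are deterministic under a
#' fixed seed and configuration; the configuration and seed are embedded in
#' the summary for provenance.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage results (`cohort`, `dda`,
#'   `screen`, `hypotheses`, `rescan`, `quant`, `sb`, `cv`, `diff`,
#'   `summary`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  ## stage 1: simulate
  cohort <- simulate_cohort(config$cohort, seed = config$seed)
  dda <- simulate_dda_collection(cohort$features,
                                 n_unassigned = config$n_unassigned_dda,
                                 n_plain = config$n_plain_dda)
  if (config$plant_sites > 0L) {
    dda <- plant_unknown_shift(dda, cohort$features, config$plant_delta,
                               n_sites = config$plant_sites)
  }
  write_mgf(dda$spectra, out("spectra.mgf"))
  write_psm_table(dda$psm, out("psm.tsv"))
  write_design(cohort$design, out("design.tsv"))
  lib <- cohort$library
  for (i in seq_along(lib)) lib[[i]]$feature_id <- cohort$features$feature_id[i]
  write_library(lib, out("library.tsv"))
  jsonlite::write_json(cohort$truth, out("truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  ## stage 2: reporter screen
  screen <- screen_collection(dda$spectra, dda$psm, config$pattern,
                              out_tsv = out("reporter_hits.tsv"))

  ## stage 3: unknown-shift inference from unassigned reporter hits
  unassigned_ids <- screen$hits$spectrum_id[!screen$hits$has_psm]
  cand_spectra <- Filter(function(s) s$id %in% unassigned_ids, dda$spectra)
  anchors <- lapply(seq_len(nrow(dda$psm)), function(i) {
    sp <- Filter(function(s) s$id == dda$psm$spectrum_id[i], dda$spectra)[[1]]
    anchor_peptide(dda$psm$peptide_ion[[i]], sp,
                   passes_fdr = dda$psm$passes_fdr[i],
                   frag_tol_mda = config$frag_tol_mda)
  })
  hyp_rows <- list()
  for (a in anchors) {
    for (s in cand_spectra) {
      m <- suppressWarnings(
        match_shared_fragments(a, s, frag_tol_mda = config$frag_tol_mda,
                               drift_tol_ms = config$drift_tol_ms))
      if (nrow(m) < 3L) next
      h <- infer_shift(a, s, m)
      if (h$identity || h$ambiguous) next
      comps <- propose_compositions(h, tol = 0.01)
      hyp_rows[[length(hyp_rows) + 1L]] <- data.frame(
        anchor = h$anchor_peptide, candidate_id = h$candidate_id,
        precursor_delta_da = h$precursor_delta_da,
        site_lo = h$site_lo, site_hi = h$site_hi,
        total_mod_mass_da = h$total_mod_mass_da,
        underivatized_delta_da = h$underivatized_delta_da,
        n_shared = h$n_shared,
        top_compositions = paste(utils::head(comps$formula, 3),
                                 collapse = ";"))
    }
  }
  hypotheses <- if (length(hyp_rows) > 0) do.call(rbind, hyp_rows) else
    data.frame(anchor = character(), candidate_id = character(),
               precursor_delta_da = numeric(), site_lo = integer(),
               site_hi = integer(), total_mod_mass_da = numeric(),
               underivatized_delta_da = numeric(), n_shared = integer(),
               top_compositions = character())
  .write_tsv(hypotheses, out("hypotheses.tsv"))

  ## register the consensus new modification and re-scan; the consensus is
  ## the most recurrent delta across candidate spectra (isolated chance
  ## matches scatter over the mass axis and do not recur)
  rescan <- NULL
  if (nrow(hypotheses) > 0) {
    bin <- round(hypotheses$underivatized_delta_da, 2)
    modal <- as.numeric(names(sort(table(bin), decreasing = TRUE))[1])
    new_mod <- modification_spec(
      "inferred_unknown", targets = c("K", "C"),
      delta_mass = stats::median(
        hypotheses$underivatized_delta_da[bin == modal]),
      arp_labelable = TRUE, pathway = "UNKNOWN")
    rescan <- rescan_with_new_mod(dda$psm, cand_spectra, new_mod,
                                  precursor_ppm = config$precursor_ppm,
                                  frag_tol_mda = config$frag_tol_mda)
    .write_tsv(rescan, out("rescan_sites.tsv"))
  }

  ## stage 4: quantify
  quant <- quantify_cohort(cohort$runs, lib, cohort$design,
                           precursor_ppm = config$precursor_ppm,
                           drift_tol_ms = config$drift_tol_ms,
                           rt_window_min = config$rt_window_min,
                           min_points = config$min_points)
  donor_areas <- quant$areas[quant$areas$sample_type == "DONOR", , drop = FALSE]
  sb <- signal_to_background(donor_areas, quant$nc_areas)
  .write_tsv(sb, out("quant_sb.tsv"))
  write_quant_matrix(quant$matrix, out("quant_matrix.tsv"))
  cv <- cv_per_batch(quant$matrix, cohort$design, qc_type = "SPQC",
                     cv_threshold = config$cv_threshold)

  ## stage 5: compare
  norm <- top5_normalize(
    quant$matrix[, cohort$design$run_id[cohort$design$sample_type == "DONOR"],
                 drop = FALSE],
    cohort$nonenriched$feature_protein,
    cohort$nonenriched$mat, cohort$nonenriched$pep_protein)
  diff <- differential_test(norm$adjusted, cohort$design,
                            fc_threshold = config$fc_threshold,
                            alpha = config$alpha)
  .write_tsv(diff, out("differential.tsv"))

  ## stage 6: report
  summary <- list(
    seed = config$seed,
    n_features = length(lib),
    n_runs = length(cohort$runs),
    screen = screen$summary,
    n_hypotheses = nrow(hypotheses),
    n_rescan_sites = if (is.null(rescan)) 0L else
      length(unique(paste(rescan$peptide, rescan$position))),
    frac_sb_gt3 = mean(sb$sb_gt3),
    frac_sb_gt10 = mean(sb$sb_gt10),
    cv_pass_fraction = as.list(cv$pass_fraction),
    n_significant = sum(diff$significant, na.rm = TRUE),
    config = list(precursor_ppm = config$precursor_ppm,
                  frag_tol_mda = config$frag_tol_mda,
                  drift_tol_ms = config$drift_tol_ms,
                  cv_threshold = config$cv_threshold,
                  fc_threshold = config$fc_threshold,
                  alpha = config$alpha)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  writeLines(c(
    "arpscreen pipeline summary",
    sprintf("seed: %d", config$seed),
    sprintf("features: %d  runs: %d", summary$n_features, summary$n_runs),
    sprintf("reporter hits: %d (%.1f%% without PSM)",
            screen$summary$n_hits, 100 * screen$summary$fraction_no_psm),
    sprintf("shift hypotheses: %d  rescan sites: %d",
            summary$n_hypotheses, summary$n_rescan_sites),
    sprintf("S/B > 3: %.1f%%  S/B > 10: %.1f%%",
            100 * summary$frac_sb_gt3, 100 * summary$frac_sb_gt10),
    sprintf("QC CV < %g%%: %s", config$cv_threshold,
            paste(sprintf("%s %.1f%%", names(cv$pass_fraction),
                          100 * cv$pass_fraction), collapse = "  ")),
    sprintf("differential hits (|log2FC| > %g, adj p < %g): %d",
            log2(config$fc_threshold), config$alpha, summary$n_significant)
  ), out("summary.txt"))
  invisible(list(cohort = cohort, dda = dda, screen = screen,
                 hypotheses = hypotheses, rescan = rescan, quant = quant,
                 sb = sb, cv = cv, diff = diff, summary = summary))
}
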