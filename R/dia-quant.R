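#' Container for one DIA acquisition run
#'
#' A run holds its metadata and its acquisition signals: each signal is an
#' ion current contribution at a fixed (m/z, drift time) coordinate with a
#' retention-time intensity trace on the run's shared time grid (stored
#' sparsely as grid indices plus intensities).
#'
#' @param run_id run identifier.
#' @param sample_type one of `"DONOR"`, `"SPQC"`, `"EFQC"`, `"NC"`, `"BLANK"`.
#' @param group `"RA"`, `"CONTROL"` or `NA` (QC/NC runs).
#' @param sex donor sex or `NA`.
#' @param batch batch number (1 or 2).
#' @param time_grid strictly increasing retention-time grid in minutes.
#' @param signals list of signals: `list(mz =, drift_ms =, idx =, intensity =,
#'   feature_id =)` with `idx` indexing into `time_grid`.
#' @return An object of class `run_data`.
#' @export
run_data <- function(run_id, sample_type, group = NA_character_,
                     sex = NA_character_, batch = 1L,
                     time_grid, signals = list()) {
  stopifnot(all(diff(time_grid) > 0))
  sample_type <- match.arg(sample_type,
                           c("DONOR", "SPQC", "EFQC", "NC", "BLANK"))
  if (sample_type == "NC" && !is.na(group)) {
    stop("negative-control runs carry no group assignment", call. = FALSE)
  }
  structure(list(run_id = run_id, sample_type = sample_type, group = group,
                 sex = sex, batch = as.integer(batch), time_grid = time_grid,
                 signals = signals),
            class = "run_data")
}

#' Fit an indexed retention time (iRT) calibration
#'
#' Affine least-squares fit `rt = slope * irt + intercept` on endogenous
#' standard peptides, used to correct per-run retention-time drifts before
#' XIC extraction.
#'
#' @param standards data frame with columns `irt` and `rt` (observed minutes);
#'   at least 2 standards with distinct iRT.
#' @return An object of class `irt_calibration` with `slope`, `intercept`,
#'   `residual_sd`, `n`.
#' @export
fit_irt <- function(standards) {
  stopifnot(is.data.frame(standards), all(c("irt", "rt") %in% names(standards)))
  ok <- stats::complete.cases(standards[, c("irt", "rt")])
  standards <- standards[ok, , drop = FALSE]
  if (nrow(standards) < 2L || length(unique(standards$irt)) < 2L) {
    stop("iRT calibration needs >= 2 standards with distinct iRT",
         call. = FALSE)
  }
  fit <- stats::lm(rt ~ irt, data = standards)
  res <- stats::residuals(fit)
  structure(list(
    slope = unname(stats::coef(fit)[["irt"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    residual_sd = if (nrow(standards) > 2L) stats::sd(res) else 0,
    n = nrow(standards)
  ), class = "irt_calibration")
}

#' @rdname fit_irt
#' @param cal an `irt_calibration`.
#' @param irt iRT value(s) to map to retention time.
#' @return `predict_rt()` returns retention time(s) in minutes.
#' @export
predict_rt <- function(cal, irt) {
  stopifnot(inherits(cal, "irt_calibration"))
  cal$slope * irt + cal$intercept
}

#' Extract an ion chromatogram (XIC) from a run
#'
#' Sums signal intensity over an m/z ppm window, restricted to a drift-time
#' window, per time point. The drift restriction is what removes integration
#' interference from isobaric precursors that co-elute but differ in mobility.
#' An empty window yields an all-zero trace, not an error.
#'
#' @param run a [run_data()] object.
#' @param mz target m/z.
#' @param ppm half-width of the m/z window in ppm.
#' @param drift_center drift window center in ms; `NULL` disables the drift
#'   restriction.
#' @param drift_tol drift half-window in ms.
#' @return An object of class `xic_trace`: `rt` (the run's grid), `intensity`,
#'   and the window parameters.
#' @export
extract_xic <- function(run, mz, ppm = 15, drift_center = NULL,
                        drift_tol = 0.5) {
  stopifnot(inherits(run, "run_data"))
  intensity <- numeric(length(run$time_grid))
  tol_mz <- mz * ppm * 1e-6
  for (s in run$signals) {
    if (abs(s$mz - mz) > tol_mz) next
    if (!is.null(drift_center) && abs(s$drift_ms - drift_center) > drift_tol)
      next
    intensity[s$idx] <- intensity[s$idx] + s$intensity
  }
  structure(list(mz = mz, ppm = ppm, drift_center = drift_center,
                 drift_tol = drift_tol, rt = run$time_grid,
                 intensity = intensity),
            class = "xic_trace")
}

# trapezoidal integral
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Integrate a chromatographic peak in an XIC
#'
#' Finds the apex inside the retention-time window and walks outward to the
#' flanking valleys (valley-to-valley boundaries; no model peak fitting);
#' integrates trapezoidally between the boundaries. Features whose peak
#' covers fewer than `min_points` sampled points (strictly inside the
#' boundaries) are flagged: sparse sampling degrades LC peak profiling.
#'
#' @param trace an `xic_trace`.
#' @param rt_window `c(lo, hi)` window in minutes within the trace span.
#' @param min_points minimum points across the peak (default 9).
#' @return List: `area`, `points_across_peak`, `bounds`, `apex_rt`,
#'   `apex_intensity`, `few_points` flag.
#' @export
integrate_peak <- function(trace, rt_window = range(trace$rt),
                           min_points = 9L) {
  stopifnot(inherits(trace, "xic_trace"), length(rt_window) == 2L)
  w <- which(trace$rt >= rt_window[1] & trace$rt <= rt_window[2])
  if (length(w) == 0) {
    stop("retention-time window lies outside the trace span", call. = FALSE)
  }
  y <- trace$intensity
  if (all(y[w] == 0)) {
    return(list(area = 0, points_across_peak = 0L,
                bounds = c(NA_real_, NA_real_), apex_rt = NA_real_,
                apex_intensity = 0, few_points = TRUE))
  }
  apex <- w[which.max(y[w])]
  lo <- apex
  while (lo > w[1] && y[lo - 1L] < y[lo]) lo <- lo - 1L
  hi <- apex
  while (hi < w[length(w)] && y[hi + 1L] < y[hi]) hi <- hi + 1L
  inside <- seq.int(lo, hi)
  inside <- inside[inside != lo & inside != hi]
  pts <- length(inside)
  list(
    area = .trapz(trace$rt[lo:hi], y[lo:hi]),
    points_across_peak = pts,
    bounds = c(trace$rt[lo], trace$rt[hi]),
    apex_rt = trace$rt[apex],
    apex_intensity = y[apex],
    few_points = pts < min_points
  )
}

#' Signal-to-background evaluation against the negative control
#'
#' The authenticity filter of ARP-peptide quantitation: each feature's
#' integrated area is divided by the retention-time-matched window area in
#' the underivatized negative control of the same batch. NC areas below a
#' floor are replaced by the floor (default: median positive NC area) to
#' avoid division by zero. Flags use strict inequalities at 3 and 10. The
#' interference flag marks feature/run pairs whose matched NC background apex
#' exceeds the feature apex, mirroring features unquantifiable at the
#' precursor level.
#'
#' @param areas data frame with columns `feature_id`, `run_id`, `batch`,
#'   `area`, and optionally `apex_intensity`.
#' @param nc_areas data frame with columns `feature_id`, `batch`, `nc_area`,
#'   and optionally `nc_apex`.
#' @param floor NC floor; `NULL` uses the median positive NC area.
#' @return `areas` augmented with `nc_area`, `s_b_ratio`, `sb_gt3`, `sb_gt10`,
#'   `interference`.
#' @export
signal_to_background <- function(areas, nc_areas, floor = NULL) {
  .check_columns(areas, c("feature_id", "run_id", "batch", "area"),
                 "area table")
  .check_columns(nc_areas, c("feature_id", "batch", "nc_area"), "NC table")
  key <- paste(areas$feature_id, areas$batch)
  nc_key <- paste(nc_areas$feature_id, nc_areas$batch)
  idx <- match(key, nc_key)
  if (anyNA(idx)) {
    stop(sprintf("missing negative-control area for %s",
                 paste(unique(key[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  nc <- nc_areas$nc_area[idx]
  if (is.null(floor)) {
    # division guard only: 1% of the median background area, so genuine
    # matrix-background areas are never inflated
    pos <- nc_areas$nc_area[nc_areas$nc_area > 0]
    floor <- if (length(pos) > 0) 0.01 * stats::median(pos) else 1
  }
  nc_floored <- pmax(nc, floor)
  areas$nc_area <- nc
  areas$s_b_ratio <- areas$area / nc_floored
  areas$sb_gt3 <- areas$s_b_ratio > 3
  areas$sb_gt10 <- areas$s_b_ratio > 10
  if ("apex_intensity" %in% names(areas) && "nc_apex" %in% names(nc_areas)) {
    areas$interference <- nc_areas$nc_apex[idx] > areas$apex_intensity
  } else {
    areas$interference <- FALSE
  }
  areas
}

#' Per-batch coefficient of variation on QC runs
#'
#' `CV = sd/mean * 100` per feature per batch over the replicate QC runs,
#' plus the per-batch fraction of features with CV below the threshold
#' (intrabatch reproducibility). Features with zero mean have no defined CV
#' and are excluded with a warning.
#'
#' @param mat feature-by-run area matrix (rownames = features).
#' @param design design data frame covering the matrix columns.
#' @param qc_type sample type to use (`"SPQC"` or `"EFQC"`).
#' @param cv_threshold percent threshold (default 20).
#' @return List: `cv` (feature x batch matrix of CV%), `pass_fraction` (named
#'   by batch), `n_features`.
#' @export
cv_per_batch <- function(mat, design, qc_type = "SPQC", cv_threshold = 20) {
  stopifnot(is.matrix(mat))
  runs <- design$run_id[design$sample_type == qc_type]
  batches <- sort(unique(design$batch[design$run_id %in% runs]))
  runs <- intersect(colnames(mat), runs)
  cv <- matrix(NA_real_, nrow = nrow(mat), ncol = length(batches),
               dimnames = list(rownames(mat), paste0("batch", batches)))
  for (bi in seq_along(batches)) {
    b_runs <- intersect(runs, design$run_id[design$batch == batches[bi]])
    if (length(b_runs) < 2L) {
      stop(sprintf("batch %s has fewer than 2 %s replicates", batches[bi],
                   qc_type), call. = FALSE)
    }
    sub <- mat[, b_runs, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    zero <- !is.na(mu) & mu == 0
    if (any(zero)) {
      warning(sprintf("%d feature(s) with zero mean excluded from batch %s CV",
                      sum(zero), batches[bi]), call. = FALSE)
    }
    cvv <- s / mu * 100
    cvv[zero] <- NA_real_
    cv[, bi] <- cvv
  }
  pass <- apply(cv, 2L, function(x) mean(x[!is.na(x)] < cv_threshold))
  list(cv = cv, pass_fraction = pass, n_features = nrow(mat))
}

#' Top-5 protein normalization of modified-peptide areas
#'
#' Each modified peptide's area is divided by its protein's abundance in the
#' same run, where protein abundance is the summed area of the protein's five
#' most intense peptides (by cross-run mean) in the nonenriched fraction;
#' proteins with fewer than five peptides use all of them. Protein-level (not
#' unmodified-peptide) normalization is used because trypsin cleavage is
#' reduced at modified lysines. Features whose protein is absent from the
#' nonenriched table are returned unadjusted and flagged.
#'
#' @param mod_areas feature-by-run matrix of modified-peptide areas.
#' @param feature_protein named character vector mapping feature id to
#'   protein.
#' @param protein_pep_areas peptide-by-run matrix of nonenriched peptide
#'   areas (same run columns).
#' @param pep_protein named character vector mapping nonenriched peptide id
#'   to protein.
#' @return List: `adjusted` (matrix), `protein_abundance` (protein-by-run),
#'   `unadjusted_features` (character).
#' @export
top5_normalize <- function(mod_areas, feature_protein, protein_pep_areas,
                           pep_protein) {
  stopifnot(is.matrix(mod_areas), is.matrix(protein_pep_areas))
  runs <- colnames(mod_areas)
  stopifnot(all(runs %in% colnames(protein_pep_areas)))
  proteins <- unique(feature_protein[rownames(mod_areas)])
  abundance <- matrix(NA_real_, nrow = length(proteins), ncol = length(runs),
                      dimnames = list(proteins, runs))
  for (pr in proteins) {
    peps <- names(pep_protein)[pep_protein == pr]
    peps <- intersect(peps, rownames(protein_pep_areas))
    if (length(peps) == 0) next
    sub <- protein_pep_areas[peps, runs, drop = FALSE]
    top <- order(rowMeans(sub, na.rm = TRUE), decreasing = TRUE)
    top <- top[seq_len(min(5L, length(top)))]
    abundance[pr, ] <- colSums(sub[top, , drop = FALSE], na.rm = TRUE)
  }
  adjusted <- mod_areas
  unadj <- character()
  for (f in rownames(mod_areas)) {
    pr <- feature_protein[[f]]
    if (is.null(pr) || is.na(pr) || !pr %in% proteins ||
        all(is.na(abundance[pr, ]))) {
      unadj <- c(unadj, f)  # reported unadjusted, flagged
      next
    }
    adjusted[f, ] <- mod_areas[f, ] / abundance[pr, ]
  }
  list(adjusted = adjusted, protein_abundance = abundance,
       unadjusted_features = unadj)
}

#' Batch-aware two-group comparison of adjusted areas
#'
#' Per feature, fits the linear model `log2(adjusted area) ~ group + batch`
#' over donor runs and tests the group term; p-values are
#' Benjamini-Hochberg-adjusted across features. The decision surface follows
#' the study convention: `|log2FC| > log2(fc_threshold)` and adjusted
#' p below `alpha`. Features missing an entire group are skipped with a flag.
#'
#' @param adjusted feature-by-run matrix of (normalized) areas.
#' @param design design data frame; only `sample_type == "DONOR"` rows enter.
#' @param groups the two group labels, reference second.
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Data frame: `feature_id`, `log2fc`, `p_value`, `adj_p`,
#'   `batch_estimate`, `skipped`, `significant`.
#' @export
differential_test <- function(adjusted, design, groups = c("RA", "CONTROL"),
                              fc_threshold = 2, alpha = 0.05) {
  stopifnot(is.matrix(adjusted), length(groups) == 2L)
  don <- design[design$sample_type == "DONOR" & design$group %in% groups, ,
                drop = FALSE]
  runs <- intersect(colnames(adjusted), don$run_id)
  don <- don[match(runs, don$run_id), , drop = FALSE]
  if (length(unique(don$group)) < 2L) {
    stop("both groups must be represented among donor runs", call. = FALSE)
  }
  grp <- factor(don$group, levels = rev(groups))  # reference = control
  batch <- factor(don$batch)
  use_batch <- nlevels(batch) > 1L
  out <- lapply(rownames(adjusted), function(f) {
    yv <- adjusted[f, runs]
    ok <- is.finite(yv) & yv > 0
    if (length(unique(grp[ok])) < 2L) {
      return(data.frame(feature_id = f, log2fc = NA_real_,
                        p_value = NA_real_, adj_p = NA_real_,
                        batch_estimate = NA_real_, skipped = TRUE))
    }
    df <- data.frame(y = log2(yv[ok]), group = droplevels(grp[ok]),
                     batch = droplevels(batch[ok]))
    fml <- if (use_batch && nlevels(df$batch) > 1L) y ~ group + batch
           else y ~ group
    fit <- stats::lm(fml, data = df)
    co <- summary(fit)$coefficients
    grow <- grep("^group", rownames(co))
    brow <- grep("^batch", rownames(co))
    data.frame(
      feature_id = f,
      log2fc = co[grow, "Estimate"],
      p_value = co[grow, "Pr(>|t|)"],
      adj_p = NA_real_,
      batch_estimate = if (length(brow) > 0) co[brow[1], "Estimate"]
                       else NA_real_,
      skipped = FALSE
    )
  })
  res <- do.call(rbind, out)
  res$adj_p[!res$skipped] <- stats::p.adjust(res$p_value[!res$skipped],
                                             method = "BH")
  res$significant <- !res$skipped & !is.na(res$adj_p) &
    abs(res$log2fc) > log2(fc_threshold) & res$adj_p < alpha
  rownames(res) <- NULL
  res
}
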