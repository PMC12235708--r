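# Affine drift-time model in m/z per charge state. Only relative offsets
# matter downstream; the slope/intercept are chosen to land doubly protonated
# tryptic peptides in the low-millisecond range typical of traveling-wave IMS.
drift_time_model <- function(mz, charge) 0.9 + 0.0076 * mz / charge

.set_seed_if <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Specification of a synthetic two-batch cohort
#'
#' Defaults mirror the study design this package emulates: 39 RA donors
#' (30 F / 9 M) and 29 healthy controls (16 F / 13 M) block-randomized into
#' two batches, 3 SPQC and 3 EF-QC pool runs plus 1 underivatized negative
#' control per batch, 86 ARP-peptide features with 10 endogenous iRT
#' standards, a 1.2 s DIA cycle, 0.05 min elution peak sd, a 21.8% batch-2
#' intensity decay, planted signal-to-background fractions of 94.1% (> 3) and
#' 76.7% (> 10), planted QC CV pass fractions of 79.8% / 75.3%, and a null
#' group effect.
#'
#' @param n_ra,n_control donor counts per group.
#' @param ra_sex,control_sex named counts `c(F = , M = )` per group.
#' @param n_features number of ARP-peptide features.
#' @param n_irt_standards number of features used as endogenous iRT standards.
#' @param spqc_per_batch,efqc_per_batch,nc_per_batch QC/NC runs per batch.
#' @param cycle_s DIA cycle time in seconds (time-grid spacing).
#' @param gradient_min run length in minutes.
#' @param peak_sd_min chromatographic peak sd in minutes.
#' @param nc_peak_sd_min width of the broad NC background bumps in minutes.
#' @param irt_slope,irt_intercept true iRT-to-rt mapping (min per iRT unit,
#'   min).
#' @param rt_slope_jitter,rt_intercept_jitter_min per-run calibration drift
#'   (relative sd, absolute sd in minutes).
#' @param rt_feature_jitter_min per-feature apex jitter in minutes.
#' @param sb_frac_gt3,sb_frac_gt10 planted fractions of donor feature-run
#'   pairs with signal-to-background ratio above 3 and above 10.
#' @param donor_log2_sd inter-donor biological variation: sd of the log2
#'   signal-to-background ratio within a feature.
#' @param cv_pass_frac planted per-batch fractions of features with QC CV
#'   below 20%.
#' @param batch2_decay fractional intensity decay applied to batch-2 runs.
#' @param replicate_cv lognormal CV of nonenriched peptide areas.
#' @param group_fold_change multiplicative RA-vs-control effect on feature
#'   abundance (1 = the null).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ra = 39L, n_control = 29L,
                        ra_sex = c(F = 30L, M = 9L),
                        control_sex = c(F = 16L, M = 13L),
                        n_features = 86L, n_irt_standards = 10L,
                        spqc_per_batch = 3L, efqc_per_batch = 3L,
                        nc_per_batch = 1L,
                        cycle_s = 1.2, gradient_min = 45,
                        peak_sd_min = 0.05, nc_peak_sd_min = 0.09,
                        irt_slope = 0.35, irt_intercept = 5,
                        rt_slope_jitter = 0.005,
                        rt_intercept_jitter_min = 0.15,
                        rt_feature_jitter_min = 0.01,
                        sb_frac_gt3 = 0.941, sb_frac_gt10 = 0.767,
                        donor_log2_sd = 1.0,
                        cv_pass_frac = c(0.798, 0.753),
                        batch2_decay = 0.218,
                        replicate_cv = 0.10,
                        group_fold_change = 1) {
  stopifnot(sum(ra_sex) == n_ra, sum(control_sex) == n_control,
            n_irt_standards >= 2L, n_irt_standards <= n_features,
            sb_frac_gt10 <= sb_frac_gt3, length(cv_pass_frac) == 2L)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Block-randomize donors into batches
#'
#' Within each group-by-sex stratum donors are shuffled and dealt cyclically
#' across batches, so per-stratum counts differ by at most one between
#' batches (batches matched for clinical classification and sex).
#'
#' @param donors data frame with columns `donor_id`, `group`, `sex`.
#' @param n_batches number of batches (>= 1).
#' @param seed RNG seed; the assignment is deterministic under a fixed seed.
#' @return `donors` with an added integer `batch` column.
#' @export
block_randomize <- function(donors, n_batches = 2L, seed = NULL) {
  stopifnot(is.data.frame(donors),
            all(c("donor_id", "group", "sex") %in% names(donors)))
  if (nrow(donors) == 0) stop("empty donor list", call. = FALSE)
  stopifnot(n_batches >= 1L)
  .set_seed_if(seed)
  donors$batch <- NA_integer_
  strata <- split(seq_len(nrow(donors)),
                  interaction(donors$group, donors$sex, drop = TRUE))
  offset <- 0L
  for (idx in strata) {
    shuffled <- sample(idx)
    donors$batch[shuffled] <-
      ((seq_along(shuffled) - 1L + offset) %% n_batches) + 1L
    offset <- offset + length(idx)  # rotate remainders across strata
  }
  donors
}

#' Generate a default ARP-peptide feature set
#'
#' Random tryptic-like peptides (7-14 residues, K/R C-terminus) each carrying
#' one ARP-derivatized carbonyl modification drawn from the registry, plus
#' carbamidomethyl on any cysteine. The first feature is fixed to the
#' doubly protonated allysine peptide LK[+312.089]C[+57.021]ASLQK so that the
#' canonical shared-fragment discovery case is always present. A subset of
#' features, spread across the iRT range, is flagged as endogenous iRT
#' standards.
#'
#' @param n_features number of features.
#' @param n_irt_standards number of iRT-standard features.
#' @param registry modification registry.
#' @param seed RNG seed (`NULL` uses the ambient RNG stream).
#' @return Data frame with columns `feature_id`, `peptide` (bracket text),
#'   `charge`, `protein`, `irt`, `mz`, `drift_ms`, `is_irt_standard`,
#'   `mod_name`, `mod_pos`, plus the list column `peptide_ion`.
#' @export
default_cohort_features <- function(n_features = 86L, n_irt_standards = 10L,
                                    registry = load_modification_registry(),
                                    seed = NULL) {
  .set_seed_if(seed)
  cam <- registry$carbamidomethyl$delta_mass
  labelable <- Filter(function(m) m$arp_labelable, registry)
  k_mods <- Filter(function(m) "K" %in% m$targets, labelable)
  pool <- c("A", "S", "T", "V", "L", "I", "P", "G", "F", "Y", "D", "E", "N",
            "Q", "H")
  feats <- vector("list", n_features)
  # canonical discovery-case peptide
  allysine <- registry$aminoadipic_semialdehyde
  p1 <- peptide_ion("LKCASLQK",
                    mods = data.frame(pos = c(2L, 3L),
                                      mass = c(arp_shift(allysine), cam),
                                      name = c(allysine$name,
                                               "carbamidomethyl")),
                    charge = 2L)
  feats[[1]] <- list(p = p1, protein = "HSA",
                     mod_name = allysine$name, mod_pos = 2L)
  seqs_seen <- "LKCASLQK"
  i <- 2L
  while (i <= n_features) {
    len <- sample(7:14, 1L)
    body <- sample(pool, len - 2L, replace = TRUE)
    site <- sample(2:(len - 1L), 1L)
    use_cys <- stats::runif(1) < 0.1
    sequence <- paste(c(body[seq_len(site - 1L)], if (use_cys) "C" else "K",
                        if (site <= len - 2L) body[seq.int(site, len - 2L)],
                        sample(c("K", "R"), 1L)), collapse = "")
    if (sequence %in% seqs_seen) next
    mod_pool <- if (use_cys) Filter(function(m) "C" %in% m$targets, labelable)
                else k_mods
    mod <- mod_pool[[sample(length(mod_pool), 1L)]]
    mods <- data.frame(pos = site, mass = arp_shift(mod), name = mod$name)
    # carbamidomethylate any cysteine not carrying the ARP modification
    cys <- setdiff(which(strsplit(sequence, "")[[1]] == "C"), site)
    if (length(cys) > 0) {
      mods <- rbind(mods, data.frame(pos = cys, mass = cam,
                                     name = "carbamidomethyl"))
    }
    charge <- sample(2:3, 1L, prob = c(0.8, 0.2))
    p <- peptide_ion(sequence, mods = mods, charge = charge)
    # only mutually resolvable precursors enter the feature set (the curated
    # study peptides exclude species with unseparable isobaric interference):
    # reject candidates that collide with an accepted feature in both m/z
    # (25 ppm) and drift time (0.7 ms)
    mz_new <- precursor_mz(p)
    drift_new <- drift_time_model(mz_new, charge)
    prev_mz <- vapply(feats[seq_len(i - 1L)],
                      function(f) precursor_mz(f$p), numeric(1))
    prev_drift <- drift_time_model(prev_mz, vapply(feats[seq_len(i - 1L)],
                                                   function(f) f$p$charge,
                                                   numeric(1)))
    if (any(abs(prev_mz - mz_new) < 25e-6 * mz_new &
              abs(prev_drift - drift_new) < 0.7)) next
    feats[[i]] <- list(p = p,
                       protein = if (stats::runif(1) < 0.6) "HSA"
                                 else sprintf("PROT%02d",
                                              sample(2:15, 1L)),
                       mod_name = mod$name, mod_pos = site)
    seqs_seen <- c(seqs_seen, sequence)
    i <- i + 1L
  }
  irt <- stats::runif(n_features, 10, 100)
  std_idx <- unique(c(1L, 2L + round(seq(0, n_features - 3L,
                                         length.out = n_irt_standards - 1L))))
  std_idx <- std_idx[seq_len(min(n_irt_standards, length(std_idx)))]
  irt[std_idx] <- seq(12, 98, length.out = length(std_idx))
  out <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n_features)),
    peptide = vapply(feats, function(f) format_peptide(f$p, 4), character(1)),
    charge = vapply(feats, function(f) f$p$charge, integer(1)),
    protein = vapply(feats, function(f) f$protein, character(1)),
    irt = irt,
    mz = vapply(feats, function(f) precursor_mz(f$p), numeric(1)),
    is_irt_standard = seq_len(n_features) %in% std_idx,
    mod_name = vapply(feats, function(f) f$mod_name, character(1)),
    mod_pos = vapply(feats, function(f) f$mod_pos, integer(1))
  )
  out$drift_ms <- drift_time_model(out$mz, out$charge)
  out$peptide_ion <- lapply(feats, function(f) f$p)
  out
}

#' Simulate a DDA fragment spectrum of a peptide ion
#'
#' b/y ladders at the theoretical m/z plus Gaussian mDa noise; ARP reporter
#' ions added iff requested (the dehydrated-biotin signal at 227.08 is made
#' the most intense reporter); random noise peaks are kept away from the
#' reporter m/z region by a guard band. Precursor drift time follows the
#' charge/mass-dependent affine model. Deterministic under `seed`.
#'
#' @param p a `peptide_ion`.
#' @param include_reporters add the four ARP reporter ions.
#' @param rt_min retention time (minutes); random when `NULL`.
#' @param mz_noise_mda fragment m/z noise sd in mDa.
#' @param precursor_noise_mda precursor m/z noise sd in mDa.
#' @param n_noise_peaks number of random background peaks.
#' @param reporter_guard_mda minimum distance of noise peaks from any
#'   reporter m/z.
#' @param id spectrum id.
#' @param seed RNG seed.
#' @return An `ms_spectrum`.
#' @export
simulate_dda_spectrum <- function(p, include_reporters = TRUE, rt_min = NULL,
                                  mz_noise_mda = 3, precursor_noise_mda = 0.3,
                                  n_noise_peaks = 20L,
                                  reporter_guard_mda = 75,
                                  id = NULL, seed = NULL) {
  stopifnot(inherits(p, "peptide_ion"))
  .set_seed_if(seed)
  base_int <- 1e4
  theo <- fragment_table(p, charge = 1L)
  frag_int <- ifelse(theo$series == "y",
                     stats::runif(nrow(theo), 0.3, 1.0),
                     stats::runif(nrow(theo), 0.1, 0.6)) * base_int
  mz <- theo$mz + stats::rnorm(nrow(theo), 0, mz_noise_mda / 1000)
  int <- frag_int
  if (include_reporters) {
    rep_mz <- reporter_ion_table()$mz
    rep_int <- c(stats::runif(3, 0.1, 0.4), stats::runif(1, 0.6, 0.95)) *
      base_int  # 227.08 most intense reporter
    mz <- c(mz, rep_mz + stats::rnorm(4, 0, mz_noise_mda / 1000))
    int <- c(int, rep_int)
  }
  if (n_noise_peaks > 0) {
    guard <- reporter_guard_mda / 1000
    noise_mz <- numeric(0)
    while (length(noise_mz) < n_noise_peaks) {
      cand <- stats::runif(n_noise_peaks, 150, 1300)
      ok <- vapply(cand, function(m) {
        all(abs(m - reporter_ion_table()$mz) > guard)
      }, logical(1))
      noise_mz <- c(noise_mz, cand[ok])
    }
    noise_mz <- noise_mz[seq_len(n_noise_peaks)]
    mz <- c(mz, noise_mz)
    int <- c(int, stats::runif(n_noise_peaks, 0.002, 0.015) * base_int)
  }
  prec_mz <- precursor_mz(p) + stats::rnorm(1, 0, precursor_noise_mda / 1000)
  ms_spectrum(
    id = if (is.null(id)) sprintf("sim_%s", format_peptide(p)) else id,
    precursor_mz = prec_mz,
    charge = p$charge,
    rt_min = if (is.null(rt_min)) stats::runif(1, 10, 40) else rt_min,
    drift_ms = drift_time_model(prec_mz, p$charge),
    peaks = data.frame(mz = mz, intensity = int)
  )
}

# Log-normal signal-to-background ratios with exact-count planted fractions.
# Each feature has a lognormal base level and each donor adds lognormal
# biological variation; the pooled log ratios are then affinely calibrated
# (a monotone map, so the distribution stays log-normal) so that exactly
# round(frac * n_pairs) pairs exceed the 3 and 10 thresholds. The between-
# feature spread is derived from the planted fractions given the within-
# feature (donor) spread.
.allocate_sb_ratios <- function(n_features, n_donors, frac_gt3, frac_gt10,
                                donor_log2_sd = 1.0) {
  n_pairs <- n_features * n_donors
  z3 <- stats::qnorm(frac_gt3)
  z10 <- stats::qnorm(frac_gt10)
  sigma <- (log(10) - log(3)) / (z3 - z10)
  mu <- log(3) + z3 * sigma
  s_d <- donor_log2_sd * log(2)
  s_f <- sqrt(max(sigma^2 - s_d^2, 0.01))
  base <- stats::rnorm(n_features, mu, s_f)
  lx <- base + matrix(stats::rnorm(n_pairs, 0, s_d), n_features, n_donors)
  sx <- sort(lx)
  n_le3 <- n_pairs - round(frac_gt3 * n_pairs)
  n_le10 <- n_pairs - round(frac_gt10 * n_pairs)
  if (n_le3 < 1L || n_le10 >= n_pairs) {
    stop("planted fractions leave no pairs on one side of a threshold",
         call. = FALSE)
  }
  t3 <- mean(sx[c(n_le3, n_le3 + 1L)])
  t10 <- mean(sx[c(n_le10, n_le10 + 1L)])
  b <- (log(10) - log(3)) / (t10 - t3)
  a <- log(3) - b * t3
  list(ratio = exp(a + b * lx),
       n_gt3 = n_pairs - n_le3, n_gt10 = n_pairs - n_le10,
       n_pairs = n_pairs)
}

.gaussian_signal <- function(time_grid, apex_rt, sd_min, area, mz, drift_ms,
                             feature_id) {
  idx <- which(time_grid >= apex_rt - 5 * sd_min &
                 time_grid <= apex_rt + 5 * sd_min)
  if (length(idx) == 0) return(NULL)
  height <- area / (sd_min * sqrt(2 * pi))
  list(mz = mz, drift_ms = drift_ms, idx = idx,
       intensity = height * exp(-(time_grid[idx] - apex_rt)^2 /
                                  (2 * sd_min^2)),
       feature_id = feature_id)
}

#' Simulate a complete two-batch DIA cohort with ground truth
#'
#' Produces the full run set (donors, SPQC, EF-QC, NC) with Gaussian elution
#' peaks on a shared time grid, a spectral library, a study design table, a
#' nonenriched-fraction protein peptide matrix for normalization, and a
#' ground-truth object sufficient to score any downstream output.
#'
#' Abundance model: each feature has a lognormal negative-control background
#' area per batch (batch 2 scaled down by the decay factor); each donor
#' feature-run pair gets a log-normal true signal-to-background ratio
#' (between-feature base level plus inter-donor variation), affinely
#' calibrated in log space so that exactly the planted fractions of pairs
#' exceed the 3 and 10 thresholds; its true area is background times ratio
#' (times the group fold change for RA donors). SPQC
#' and EF-QC replicate triplets are planted as symmetric `(1-d, 1, 1+d)`
#' multipliers so each feature's per-batch sample CV equals its planted `d`
#' exactly, with `d` drawn below/above the 20% threshold according to the
#' planted per-batch pass counts. NC runs contain only broad background
#' bumps, retention-time matched to the features.
#'
#' @param spec a [cohort_spec()].
#' @param features feature table as from [default_cohort_features()]; `NULL`
#'   generates the default set from the cohort specification within the
#'   seeded stream.
#' @param seed RNG seed; the full cohort is deterministic under it.
#' @return List with `runs` (list of [run_data()]), `design`, `features`,
#'   `library` (entries as in [read_library()]), `nonenriched` (peptide
#'   matrix + maps), and `truth`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), features = NULL, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$spqc_per_batch != 3L || spec$efqc_per_batch != 3L) {
    stop("exact CV planting requires 3 QC replicates per batch", call. = FALSE)
  }
  .set_seed_if(seed)
  if (is.null(features)) {
    features <- default_cohort_features(spec$n_features,
                                        spec$n_irt_standards)
  }
  nf <- nrow(features)
  # donors and block randomization
  donors <- data.frame(
    donor_id = sprintf("D%02d", seq_len(spec$n_ra + spec$n_control)),
    group = c(rep("RA", spec$n_ra), rep("CONTROL", spec$n_control)),
    sex = c(rep(names(spec$ra_sex), spec$ra_sex),
            rep(names(spec$control_sex), spec$control_sex))
  )
  donors <- block_randomize(donors, n_batches = 2L)
  design <- rbind(
    do.call(rbind, lapply(1:2, function(b) {
      rbind(
        data.frame(run_id = sprintf("B%d_SPQC%d", b,
                                    seq_len(spec$spqc_per_batch)),
                   sample_type = "SPQC", group = NA, sex = NA, batch = b),
        data.frame(run_id = sprintf("B%d_EFQC%d", b,
                                    seq_len(spec$efqc_per_batch)),
                   sample_type = "EFQC", group = NA, sex = NA, batch = b),
        data.frame(run_id = donors$donor_id[donors$batch == b],
                   sample_type = "DONOR",
                   group = donors$group[donors$batch == b],
                   sex = donors$sex[donors$batch == b], batch = b),
        data.frame(run_id = sprintf("B%d_NC%d", b, seq_len(spec$nc_per_batch)),
                   sample_type = "NC", group = NA, sex = NA, batch = b)
      )
    }))
  )
  decay <- c(1, 1 - spec$batch2_decay)
  nc_base <- exp(stats::rnorm(nf, log(1e4), 0.4))
  alloc <- .allocate_sb_ratios(nf, nrow(donors), spec$sb_frac_gt3,
                               spec$sb_frac_gt10, spec$donor_log2_sd)
  colnames(alloc$ratio) <- donors$donor_id
  rownames(alloc$ratio) <- features$feature_id
  fold <- rep(spec$group_fold_change, length.out = nf)
  donor_area <- alloc$ratio
  for (j in seq_len(nrow(donors))) {
    b <- donors$batch[j]
    g <- donors$group[j]
    donor_area[, j] <- nc_base * decay[b] * alloc$ratio[, j] *
      ifelse(rep(g == "RA", nf), fold, 1)
  }
  # planted QC CVs: pass features get d below the threshold, failures above
  n_pass <- round(spec$cv_pass_frac * nf)
  qc_pass <- sapply(1:2, function(b) {
    pas <- logical(nf)
    pas[sample(nf, n_pass[b])] <- TRUE
    pas
  })
  qc_d <- matrix(0, nf, 2)
  for (b in 1:2) {
    qc_d[qc_pass[, b], b] <- stats::runif(sum(qc_pass[, b]), 0.02, 0.15)
    qc_d[!qc_pass[, b], b] <- stats::runif(sum(!qc_pass[, b]), 0.25, 0.60)
  }
  qc_base <- sapply(1:2, function(b) {
    in_b <- donors$batch == b
    apply(donor_area[, in_b, drop = FALSE], 1L, stats::median)
  })
  # per-run retention-time calibration drift
  time_grid <- seq(0, spec$gradient_min, by = spec$cycle_s / 60)
  runs <- vector("list", nrow(design))
  calib <- data.frame(run_id = design$run_id, slope = NA_real_,
                      intercept = NA_real_)
  for (r in seq_len(nrow(design))) {
    slope <- spec$irt_slope * (1 + stats::rnorm(1, 0, spec$rt_slope_jitter))
    intercept <- spec$irt_intercept +
      stats::rnorm(1, 0, spec$rt_intercept_jitter_min)
    calib$slope[r] <- slope
    calib$intercept[r] <- intercept
    b <- design$batch[r]
    stype <- design$sample_type[r]
    apex <- slope * features$irt + intercept +
      stats::rnorm(nf, 0, spec$rt_feature_jitter_min)
    area <- switch(stype,
      DONOR = donor_area[, design$run_id[r]],
      SPQC = ,
      EFQC = {
        reps <- design$run_id[design$sample_type == stype & design$batch == b]
        k <- match(design$run_id[r], reps)
        mult <- c(1 - qc_d[, b], rep(1, nf), 1 + qc_d[, b])
        qc_base[, b] * mult[(k - 1L) * nf + seq_len(nf)]
      },
      NC = nc_base * decay[b],
      BLANK = rep(0, nf)
    )
    sd_min <- if (stype == "NC") spec$nc_peak_sd_min else spec$peak_sd_min
    signals <- vector("list", nf)
    for (f in seq_len(nf)) {
      signals[[f]] <- .gaussian_signal(time_grid, apex[f], sd_min, area[f],
                                       features$mz[f], features$drift_ms[f],
                                       features$feature_id[f])
    }
    runs[[r]] <- run_data(design$run_id[r], stype,
                          group = if (is.na(design$group[r])) NA_character_
                                  else design$group[r],
                          sex = design$sex[r], batch = b,
                          time_grid = time_grid,
                          signals = Filter(Negate(is.null), signals))
  }
  names(runs) <- design$run_id
  # spectral library
  library <- lapply(seq_len(nf), function(f) {
    fr <- fragment_table(features$peptide_ion[[f]], charge = 1L)
    fr$rel_intensity <- stats::runif(nrow(fr), 0.2, 1)
    list(peptide = features$peptide_ion[[f]],
         protein = features$protein[f],
         irt = features$irt[f], drift_ms = features$drift_ms[f],
         is_irt_standard = features$is_irt_standard[f],
         fragments = fr)
  })
  # nonenriched-fraction protein peptide areas (for top-5 normalization);
  # one protein deliberately has only 3 peptides
  proteins <- unique(features$protein)
  pep_rows <- list()
  for (pi in seq_along(proteins)) {
    n_pep <- if (pi == length(proteins)) 3L else 6L
    base <- exp(stats::rnorm(n_pep, log(1e6), 0.5))
    for (k in seq_len(n_pep)) {
      pep_rows[[length(pep_rows) + 1L]] <-
        list(id = sprintf("%s_pep%d", proteins[pi], k),
             protein = proteins[pi], base = base[k])
    }
  }
  non_nc <- design$run_id[design$sample_type != "NC"]
  ne_mat <- matrix(NA_real_, length(pep_rows), length(non_nc),
                   dimnames = list(vapply(pep_rows, `[[`, character(1), "id"),
                                   non_nc))
  for (j in seq_along(non_nc)) {
    b <- design$batch[match(non_nc[j], design$run_id)]
    ne_mat[, j] <- vapply(pep_rows, `[[`, numeric(1), "base") * decay[b] *
      exp(stats::rnorm(length(pep_rows), 0, spec$replicate_cv))
  }
  pep_protein <- stats::setNames(
    vapply(pep_rows, `[[`, character(1), "protein"), rownames(ne_mat))
  feature_protein <- stats::setNames(features$protein, features$feature_id)
  truth <- list(
    seed = seed,
    features = features[, setdiff(names(features), "peptide_ion")],
    donors = donors,
    donor_area = donor_area,
    sb_ratio = alloc$ratio,
    sb_counts = c(gt3 = alloc$n_gt3, gt10 = alloc$n_gt10,
                  pairs = alloc$n_pairs),
    qc_pass = qc_pass, qc_d = qc_d,
    nc_area = outer(nc_base, decay),
    batch_decay = decay,
    calibration = calib,
    group_fold_change = fold
  )
  list(runs = runs, design = design, features = features, library = library,
       nonenriched = list(mat = ne_mat, pep_protein = pep_protein,
                          feature_protein = feature_protein),
       truth = truth)
}

#' Simulate a DDA spectrum collection with PSM assignments
#'
#' One reporter-bearing identified spectrum per ARP-peptide feature (with a
#' FDR-passing PSM record), plus a planted number of reporter-bearing spectra
#' without any PSM (the discovery pool for unknown shifts) and plain
#' unlabeled spectra without reporters.
#'
#' @param features feature table ([default_cohort_features()]).
#' @param n_unassigned reporter-bearing spectra without a PSM.
#' @param n_plain unlabeled spectra (no reporters, no PSM).
#' @param seed RNG seed.
#' @param ... further arguments to [simulate_dda_spectrum()].
#' @return List with `spectra` (list of `ms_spectrum`), `psm` (PSM data
#'   frame) and `truth` (`reporter_bearing` + `assigned` logical vectors by
#'   spectrum id).
#' @export
simulate_dda_collection <- function(features, n_unassigned = 80L,
                                    n_plain = 30L, seed = NULL, ...) {
  .set_seed_if(seed)
  nf <- nrow(features)
  spectra <- vector("list", nf + n_unassigned + n_plain)
  reporter_bearing <- logical(length(spectra))
  assigned <- logical(length(spectra))
  for (f in seq_len(nf)) {
    spectra[[f]] <- simulate_dda_spectrum(
      features$peptide_ion[[f]], include_reporters = TRUE,
      id = sprintf("scan_%s", features$feature_id[f]), ...)
    reporter_bearing[f] <- TRUE
    assigned[f] <- TRUE
  }
  pool <- c("A", "S", "T", "V", "L", "I", "P", "G", "F", "Y", "D", "E", "Q")
  registry <- load_modification_registry()
  k_mods <- Filter(function(m) m$arp_labelable && "K" %in% m$targets, registry)
  for (u in seq_len(n_unassigned)) {
    len <- sample(8:13, 1L)
    sequence <- paste(c(sample(pool, len - 2L, replace = TRUE), "K",
                        sample(c("K", "R"), 1L)), collapse = "")
    mod <- k_mods[[sample(length(k_mods), 1L)]]
    p <- peptide_ion(sequence,
                     mods = data.frame(pos = len - 1L,
                                       mass = arp_shift(mod),
                                       name = mod$name),
                     charge = sample(2:3, 1L))
    spectra[[nf + u]] <- simulate_dda_spectrum(
      p, include_reporters = TRUE, id = sprintf("scan_unassigned_%03d", u),
      ...)
    reporter_bearing[nf + u] <- TRUE
  }
  for (v in seq_len(n_plain)) {
    len <- sample(8:13, 1L)
    p <- peptide_ion(paste(c(sample(pool, len - 1L, replace = TRUE),
                             sample(c("K", "R"), 1L)), collapse = ""),
                     charge = 2L)
    spectra[[nf + n_unassigned + v]] <- simulate_dda_spectrum(
      p, include_reporters = FALSE, id = sprintf("scan_plain_%03d", v), ...)
  }
  psm <- data.frame(
    spectrum_id = sprintf("scan_%s", features$feature_id),
    peptide = features$peptide,
    charge = features$charge,
    score = round(stats::runif(nf, 40, 120), 2),
    passes_fdr = TRUE
  )
  psm$peptide_ion <- features$peptide_ion
  ids <- vapply(spectra, function(s) s$id, character(1))
  list(spectra = spectra, psm = psm,
       truth = data.frame(spectrum_id = ids,
                          reporter_bearing = reporter_bearing,
                          assigned = assigned))
}

#' Plant an unknown modification shift into a DDA collection
#'
#' Adds candidate spectra carrying existing library sequences whose ARP
#' modification is replaced by the ARP-derivatized version of a new
#' (unknown) delta composition, sharing the unmodified-side fragment ladder
#' with their source peptides. The planted spectra carry reporters but no
#' PSM, mirroring the discovery path for unknown shifts.
#'
#' @param dda a collection from [simulate_dda_collection()].
#' @param features feature table the collection was built from.
#' @param delta an `elem_comp` (or formula) for the underivatized delta; must
#'   have positive mass.
#' @param n_sites number of features (with a Lys/Cys ARP site) to plant on.
#' @param seed RNG seed.
#' @param ... further arguments to [simulate_dda_spectrum()].
#' @return The updated collection with a `planted` truth data frame
#'   (`spectrum_id`, `source_feature`, `peptide`, `position`,
#'   `total_shift_da`).
#' @export
plant_unknown_shift <- function(dda, features, delta, n_sites = 7L,
                                seed = NULL, ...) {
  if (is.character(delta)) delta <- parse_formula(delta)
  stopifnot(inherits(delta, "elem_comp"))
  delta_mass <- monoisotopic_mass(delta)
  if (delta_mass <= 0) {
    stop("planted delta composition must have positive mass", call. = FALSE)
  }
  .set_seed_if(seed)
  total_shift <- ARP_OXIME_MASS + delta_mass
  planted <- data.frame(spectrum_id = character(), source_feature = character(),
                        peptide = character(), position = integer(),
                        total_shift_da = numeric())
  if (n_sites > 0L) {
    # a source already carrying the planted total shift would yield a
    # mass-identical candidate, not a discoverable unknown
    carries_shift <- vapply(seq_len(nrow(features)), function(f) {
      p <- features$peptide_ion[[f]]
      any(p$mods$pos == features$mod_pos[f] &
            abs(p$mods$mass - total_shift) < 0.02)
    }, logical(1))
    eligible <- which(!is.na(features$mod_pos) & !carries_shift)
    if (length(eligible) < n_sites) {
      stop("not enough features with a modifiable site", call. = FALSE)
    }
    chosen <- sort(sample(eligible, n_sites))
    for (k in seq_along(chosen)) {
      f <- chosen[k]
      base <- features$peptide_ion[[f]]
      mods <- base$mods
      site <- features$mod_pos[f]
      mods <- mods[mods$pos != site, , drop = FALSE]
      mods <- rbind(mods, data.frame(pos = site, mass = total_shift,
                                     name = "planted_unknown"))
      variant <- peptide_ion(base$sequence, mods = mods, charge = base$charge)
      sid <- sprintf("scan_planted_%02d", k)
      dda$spectra[[length(dda$spectra) + 1L]] <-
        simulate_dda_spectrum(variant, include_reporters = TRUE, id = sid, ...)
      dda$truth <- rbind(dda$truth,
                         data.frame(spectrum_id = sid, reporter_bearing = TRUE,
                                    assigned = FALSE))
      planted <- rbind(planted,
                       data.frame(spectrum_id = sid,
                                  source_feature = features$feature_id[f],
                                  peptide = format_peptide(variant, 4),
                                  position = site,
                                  total_shift_da = total_shift))
    }
  }
  dda$planted <- planted
  dda
}
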