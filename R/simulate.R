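#' Default stage-trajectory archetypes
#'
#' Four archetypal metabolite trajectories over the AAH, AIS, MIA, IAC
#' progression, in log2 tumor/NAT units: an AIS-specific peak, an
#' MIA-specific peak, a stepwise increase already present in preneoplasia,
#' and a stepwise decrease emerging with invasion — so the number of
#' tumor-vs-NAT differential metabolites grows along the progression, as
#' observed in resected-lesion cohorts.
#'
#' @param n_per_archetype Metabolites per archetype (default 20).
#' @return List of archetypes, each `list(label, effects, n)` with one
#'   effect per stage.
#' @export
default_archetypes <- function(n_per_archetype = 20) {
  list(
    list(label = "AIS_peak", effects = c(0, 1.0, 0.3, 0.2), n = n_per_archetype),
    list(label = "MIA_peak", effects = c(0, 0.3, 1.0, 0.3), n = n_per_archetype),
    list(label = "up",       effects = c(0.4, 0.6, 0.9, 1.2), n = n_per_archetype),
    list(label = "down",     effects = c(-0.2, -0.5, -0.8, -1.2), n = n_per_archetype)
  )
}

#' Default plasma panel separations
#'
#' Per-metabolite class separations (in within-class SD units, relative to
#' the benign group) for the plasma biomarker markers. The separations are
#' the binormal inversions of the diagnostic performance this study design
#' targets: four markers at d = 0.9 each for benign vs any malignant stage,
#' a cystine/valine pair strongest in the pre-invasive stages, and an
#' asparagine/cystine pair strongest in AIS.
#'
#' @return Data frame with columns `metabolite`, `benign`, `AIS`, `MIA`,
#'   `IAC` (shifts in SD units).
#' @export
default_panel_spec <- function() {
  data.frame(
    metabolite = c("3-chlorotyrosine", "dodecanoylcarnitine", "glutamate",
                   "phosphocholine", "cystine", "valine", "asparagine"),
    benign = 0,
    AIS = c(0.9, -0.9, -0.9, 0.9, -1.4, -1.0, 1.5),
    MIA = c(0.9, -0.9, -0.9, 0.9, -1.0, -1.2, 0.4),
    IAC = c(0.9, -0.9, -0.9, 0.9, -0.4, -0.3, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for the synthetic cohorts
#'
#' Defines the study conditions the generator emulates: a tissue cohort of
#' paired tumor/NAT samples across the four histological stages analyzed in
#' 14 batches with interleaved pooled-QC injections and multiplicative
#' batch effects; four planted trajectory archetypes; three latent invasive
#' subtypes, one carrying an elevated bile-acid block, with subtype-linked
#' hazards; and a plasma cohort with configured marker separations.
#' Abundances are lognormal: all effects act additively on the log2 scale.
#'
#' @param n_per_stage Tissue patients per stage
#'   (default `c(AAH = 12, AIS = 22, MIA = 19, IAC = 128)`).
#' @param n_batches,qc_per_batch Tissue batch layout (default 14 batches,
#'   5 QC injections each).
#' @param batch_effect_sd SD of per-(batch, metabolite) log2 batch effects
#'   (default 0.5).
#' @param drift_slope Per-injection log2 drift within a batch (default 0.002).
#' @param noise_sd Analytical log2 noise SD (default 0.25, ~18% CV).
#' @param trajectory_archetypes See [default_archetypes()].
#' @param n_background Flat (no-effect) detectable tissue metabolites
#'   (default 39, so the default detectable panel has 158 metabolites).
#' @param n_low_abundance Tissue metabolites simulated near or below the
#'   detection threshold, exercising the detection filter (default 30).
#' @param n_subtypes Latent invasive subtypes (default 3).
#' @param subtype_sizes Reference subtype sizes (default `c(33, 63, 30)`),
#'   rescaled to the IAC patient count by largest remainder.
#' @param subtype_block `c(n_metabolites, log2_effect)` for the
#'   bile-acid-like block elevated in the last subtype (default `c(9, 1.5)`;
#'   the 9 members carry bile-acid names).
#' @param subtype_signature `c(n_metabolites, log2_effect)` for the
#'   signature blocks distinguishing the other subtypes (default `c(15, 1)`).
#' @param detection_threshold Peak area below which a value is recorded
#'   missing (default 2000, about three log2 units under the lowest
#'   detectable baseline).
#' @param baseline_log2_range,low_abundance_log2_range Ranges of baseline
#'   log2 peak areas for detectable and low-abundance metabolites.
#' @param hazard_by_subtype Monthly DFS hazards per subtype
#'   (default `c(0.010, 0.022, 0.028)`).
#' @param hazard_other Monthly hazard for pre-invasive patients (default 0.004).
#' @param censor_horizon Upper bound of the independent Uniform(0, horizon)
#'   censoring time, in months (default 120).
#' @param panel_spec See [default_panel_spec()].
#' @param n_plasma_per_stage Plasma patients per stage
#'   (default `c(benign = 10, AIS = 32, MIA = 22, IAC = 28)`).
#' @param n_plasma_batches,plasma_qc_per_batch Plasma batch layout
#'   (default 2 batches, 5 QC each).
#' @param n_plasma_altered Additional plasma metabolites with true stage
#'   effects beyond the panel markers (default 9, giving 16 truly altered).
#' @param plasma_altered_effect Stage-shift magnitude of those metabolites,
#'   in SD units (default 0.8).
#' @param n_plasma_background,n_plasma_low Flat detectable and low-abundance
#'   plasma metabolites (defaults 124 and 25, so the detectable plasma
#'   panel has 140 metabolites).
#' @param plasma_sd Total per-sample log2 SD in plasma (biological plus
#'   analytical, default 0.6); marker shifts are expressed in these units.
#' @param seed Integer master seed; tissue and plasma cohorts use
#'   independent substreams derived from it.
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(n_per_stage = c(AAH = 12, AIS = 22, MIA = 19, IAC = 128),
                       n_batches = 14,
                       qc_per_batch = 5,
                       batch_effect_sd = 0.5,
                       drift_slope = 0.002,
                       noise_sd = 0.25,
                       trajectory_archetypes = default_archetypes(),
                       n_background = 39,
                       n_low_abundance = 30,
                       n_subtypes = 3,
                       subtype_sizes = c(33, 63, 30),
                       subtype_block = c(n_metabolites = 9, log2_effect = 1.5),
                       subtype_signature = c(n_metabolites = 15, log2_effect = 1),
                       detection_threshold = 2000,
                       baseline_log2_range = c(13, 20),
                       low_abundance_log2_range = c(8, 10.5),
                       hazard_by_subtype = c(0.010, 0.022, 0.028),
                       hazard_other = 0.004,
                       censor_horizon = 120,
                       panel_spec = default_panel_spec(),
                       n_plasma_per_stage = c(benign = 10, AIS = 32,
                                              MIA = 22, IAC = 28),
                       n_plasma_batches = 2,
                       plasma_qc_per_batch = 5,
                       n_plasma_altered = 9,
                       plasma_altered_effect = 0.8,
                       n_plasma_background = 124,
                       n_plasma_low = 25,
                       plasma_sd = 0.6,
                       seed = 1) {
  cfg <- list(n_per_stage = n_per_stage, n_batches = n_batches,
              qc_per_batch = qc_per_batch, batch_effect_sd = batch_effect_sd,
              drift_slope = drift_slope, noise_sd = noise_sd,
              trajectory_archetypes = trajectory_archetypes,
              n_background = n_background, n_low_abundance = n_low_abundance,
              n_subtypes = n_subtypes, subtype_sizes = subtype_sizes,
              subtype_block = subtype_block,
              subtype_signature = subtype_signature,
              detection_threshold = detection_threshold,
              baseline_log2_range = baseline_log2_range,
              low_abundance_log2_range = low_abundance_log2_range,
              hazard_by_subtype = hazard_by_subtype,
              hazard_other = hazard_other, censor_horizon = censor_horizon,
              panel_spec = panel_spec,
              n_plasma_per_stage = n_plasma_per_stage,
              n_plasma_batches = n_plasma_batches,
              plasma_qc_per_batch = plasma_qc_per_batch,
              n_plasma_altered = n_plasma_altered,
              plasma_altered_effect = plasma_altered_effect,
              n_plasma_background = n_plasma_background,
              n_plasma_low = n_plasma_low, plasma_sd = plasma_sd,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object (or plain list with the same fields).
#' @return `cfg` invisibly; aborts with a configuration error otherwise.
#' @export
validate_sim_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(all(cfg$n_per_stage >= 1), "n_per_stage entries must be >= 1")
  chk(length(cfg$n_per_stage) >= 2, "need at least two stages")
  chk(cfg$n_batches >= 1, "n_batches must be >= 1")
  chk(cfg$qc_per_batch >= 1, "qc_per_batch must be >= 1")
  chk(cfg$batch_effect_sd >= 0, "batch_effect_sd must be >= 0")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$plasma_sd >= 0, "plasma_sd must be >= 0")
  for (a in cfg$trajectory_archetypes) {
    chk(length(a$effects) == length(cfg$n_per_stage),
        paste0("archetype '", a$label,
               "' must have one stage effect per stage"))
    chk(a$n >= 1, paste0("archetype '", a$label, "' needs n >= 1"))
  }
  chk(cfg$n_subtypes >= 1, "n_subtypes must be >= 1")
  chk(length(cfg$subtype_sizes) == cfg$n_subtypes,
      "subtype_sizes must have one entry per subtype")
  chk(all(cfg$subtype_sizes >= 1), "subtype_sizes must be >= 1")
  chk(cfg$subtype_block[[1]] >= 1 && cfg$subtype_block[[1]] <= 9,
      "subtype_block metabolite count must be between 1 and 9")
  chk(cfg$detection_threshold >= 0, "detection_threshold must be >= 0")
  chk(all(cfg$hazard_by_subtype > 0), "hazards must be positive")
  chk(length(cfg$hazard_by_subtype) == cfg$n_subtypes,
      "hazard_by_subtype must have one entry per subtype")
  chk(cfg$hazard_other > 0, "hazard_other must be positive")
  chk(cfg$censor_horizon > 0, "censor_horizon must be positive")
  chk(all(cfg$n_plasma_per_stage >= 1), "n_plasma_per_stage entries must be >= 1")
  chk(is.data.frame(cfg$panel_spec) &&
        all(c("metabolite", names(cfg$n_plasma_per_stage)) %in%
              colnames(cfg$panel_spec)),
      "panel_spec must be a data frame with metabolite and per-stage columns")
  if (length(errs) > 0L) {
    stop("invalid simulation configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  invisible(cfg)
}

bile_acid_names <- c(
  "cholic acid", "chenodeoxycholic acid", "deoxycholic acid",
  "glycocholic acid", "glycochenodeoxycholic acid", "glycodeoxycholic acid",
  "taurocholic acid", "taurochenodeoxycholic acid", "taurodeoxycholic acid")

# Largest-remainder allocation of reference proportions to a total count.
allocate_sizes <- function(reference, total) {
  raw <- reference / sum(reference) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Injection layout for one batch: QC injections at evenly spaced positions,
# test samples randomized over the remaining positions.
layout_batch <- function(test_ids, n_qc, qc_prefix) {
  n_inj <- length(test_ids) + n_qc
  qc_pos <- unique(round(seq(1, n_inj, length.out = n_qc)))
  while (length(qc_pos) < n_qc) {
    qc_pos <- sort(union(qc_pos, setdiff(seq_len(n_inj), qc_pos)[1]))
  }
  test_pos <- setdiff(seq_len(n_inj), qc_pos)
  ord <- sample(test_ids)
  data.frame(
    sample_id = c(ord, paste0(qc_prefix, "_", seq_len(n_qc))),
    injection_order = c(test_pos, qc_pos),
    stringsAsFactors = FALSE)
}

#' Simulate the tissue cohort
#'
#' Generates a paired tumor/NAT targeted-metabolomics cohort with known
#' ground truth. Tumor abundances carry the stage-trajectory effects of
#' their patient's stage and, for invasive (IAC) patients, the subtype
#' signature/bile-acid block effects; NAT abundances carry none. QC samples
#' are noisy replicates of the pooled mean profile, share their batch's
#' multiplicative effect and drift, and sit at evenly spaced injection
#' positions. Peak areas below the detection threshold are recorded
#' missing. DFS times are exponential with the subtype's hazard, with
#' independent Uniform(0, horizon) censoring.
#'
#' @param config A [sim_config()] object.
#' @return List of class `tissue_cohort` with `peaks` (metabolite x sample
#'   matrix, `NA` = undetected), `samples` (sample table), `clinical`
#'   (clinical table), and `truth` (ground-truth list: per-metabolite
#'   `trajectory` labels partitioning all metabolites, `subtype_role`,
#'   per-patient `subtype`, `batch_factors`, `hazard_by_subtype`,
#'   `stage_effects`, `detectable`).
#' @export
simulate_tissue_cohort <- function(config) {
  validate_sim_config(config)
  stages <- names(config$n_per_stage)
  with_local_seed(derive_seed(config$seed, 1L), {
    patients <- sprintf("P%03d", seq_len(sum(config$n_per_stage)))
    stage_of <- rep(stages, config$n_per_stage)
    names(stage_of) <- patients

    # latent subtypes among invasive patients
    iac <- patients[stage_of == "IAC"]
    sizes <- allocate_sizes(config$subtype_sizes, length(iac))
    subtype <- stats::setNames(rep("none", length(patients)), patients)
    subtype[sample(iac)] <- rep(paste0("S", seq_len(config$n_subtypes)), sizes)

    # metabolite panel
    arch <- config$trajectory_archetypes
    arch_ids <- unlist(lapply(arch, function(a) {
      sprintf("m_%s_%02d", a$label, seq_len(a$n))
    }))
    arch_lab <- unlist(lapply(arch, function(a) rep(a$label, a$n)))
    n_sig <- as.integer(config$subtype_signature[[1]])
    sig_ids <- unlist(lapply(seq_len(max(config$n_subtypes - 1L, 0L)), function(s) {
      sprintf("m_sig%d_%02d", s, seq_len(n_sig))
    }))
    sig_sub <- rep(seq_len(max(config$n_subtypes - 1L, 0L)), each = n_sig)
    block_ids <- bile_acid_names[seq_len(as.integer(config$subtype_block[[1]]))]
    bg_ids <- sprintf("m_bg_%03d", seq_len(config$n_background))
    low_ids <- sprintf("m_low_%02d", seq_len(config$n_low_abundance))
    mets <- c(arch_ids, sig_ids, block_ids, bg_ids, low_ids)
    m <- length(mets)

    trajectory <- stats::setNames(rep("flat", m), mets)
    trajectory[arch_ids] <- arch_lab
    subtype_role <- stats::setNames(rep("none", m), mets)
    subtype_role[sig_ids] <- paste0("signature_S", sig_sub)
    subtype_role[block_ids] <- paste0("block_S", config$n_subtypes)
    low <- stats::setNames(mets %in% low_ids, mets)

    baseline <- stats::setNames(numeric(m), mets)
    baseline[!low] <- stats::runif(sum(!low), config$baseline_log2_range[1],
                                   config$baseline_log2_range[2])
    baseline[low] <- stats::runif(sum(low), config$low_abundance_log2_range[1],
                                  config$low_abundance_log2_range[2])

    # per-stage log2 effects per metabolite (tumor samples only)
    stage_effects <- matrix(0, m, length(stages),
                            dimnames = list(mets, stages))
    off <- 0L
    for (a in arch) {
      stage_effects[off + seq_len(a$n), ] <-
        matrix(a$effects, a$n, length(stages), byrow = TRUE)
      off <- off + a$n
    }

    # subtype log2 effects per metabolite x subtype (tumor samples of IAC)
    subtype_effects <- matrix(0, m, config$n_subtypes,
                              dimnames = list(mets, paste0("S", seq_len(config$n_subtypes))))
    for (s in seq_len(max(config$n_subtypes - 1L, 0L))) {
      subtype_effects[sig_ids[sig_sub == s], s] <- config$subtype_signature[[2]]
    }
    subtype_effects[block_ids, config$n_subtypes] <- config$subtype_block[[2]]

    # batch layout: paired samples share their patient's batch
    batch_of <- stats::setNames(
      rep(seq_len(config$n_batches), length.out = length(patients))[
        order(sample(length(patients)))],
      patients)
    sample_rows <- list()
    for (b in seq_len(config$n_batches)) {
      pats <- patients[batch_of == b]
      ids <- c(paste0("T_", pats), paste0("N_", pats))
      lay <- layout_batch(ids, config$qc_per_batch, sprintf("QC_B%02d", b))
      lay$batch <- b
      sample_rows[[b]] <- lay
    }
    lay <- do.call(rbind, sample_rows)
    is_qc <- grepl("^QC_", lay$sample_id)
    pat <- ifelse(is_qc, NA_character_, sub("^[TN]_", "", lay$sample_id))
    role <- ifelse(is_qc, "QC",
                   ifelse(grepl("^T_", lay$sample_id), "tumor", "NAT"))
    samples <- data.frame(
      sample_id = lay$sample_id,
      patient_id = pat,
      cohort = "tissue",
      role = role,
      stage = ifelse(is_qc, "none", stage_of[pat]),
      batch = lay$batch,
      injection_order = lay$injection_order,
      stringsAsFactors = FALSE)

    # biological signal (log2), before batch/drift/noise
    test <- samples[!is_qc, , drop = FALSE]
    signal <- matrix(baseline, m, nrow(test), dimnames = list(mets, test$sample_id))
    tum_idx <- which(test$role == "tumor")
    for (i in tum_idx) {
      p <- test$patient_id[i]
      signal[, i] <- signal[, i] + stage_effects[, stage_of[p]]
      if (subtype[p] != "none") {
        signal[, i] <- signal[, i] + subtype_effects[, subtype[p]]
      }
    }
    pooled <- rowMeans(signal)

    batch_mat <- matrix(stats::rnorm(m * config$n_batches, 0,
                                     config$batch_effect_sd),
                        m, config$n_batches,
                        dimnames = list(mets, seq_len(config$n_batches)))

    log2val <- matrix(0, m, nrow(samples),
                      dimnames = list(mets, samples$sample_id))
    log2val[, test$sample_id] <- signal
    log2val[, samples$sample_id[is_qc]] <- pooled
    drift <- config$drift_slope * (samples$injection_order - 1)
    log2val <- log2val + batch_mat[, samples$batch, drop = FALSE] +
      matrix(drift, m, nrow(samples), byrow = TRUE) +
      matrix(stats::rnorm(m * nrow(samples), 0, config$noise_sd), m)
    peaks <- 2^log2val
    peaks[peaks < config$detection_threshold] <- NA_real_

    clinical <- simulate_clinical(patients, stage_of, subtype, config)

    truth <- list(trajectory = trajectory,
                  subtype_role = subtype_role,
                  subtype = subtype,
                  batch_factors = 2^batch_mat,
                  stage_effects = stage_effects,
                  subtype_effects = subtype_effects,
                  hazard_by_subtype = stats::setNames(
                    config$hazard_by_subtype,
                    paste0("S", seq_len(config$n_subtypes))),
                  detectable = !low)
    structure(list(peaks = peaks, samples = samples, clinical = clinical,
                   truth = truth, config = config),
              class = "tissue_cohort")
  })
}

# Clinical covariates and survival endpoints linked to stage and subtype.
simulate_clinical <- function(patients, stage_of, subtype, config) {
  n <- length(patients)
  s_idx <- suppressWarnings(as.integer(sub("^S", "", subtype)))
  dfs_rate <- ifelse(is.na(s_idx), config$hazard_other,
                     config$hazard_by_subtype[s_idx])
  dfs_latent <- stats::rexp(n, dfs_rate)
  os_latent <- dfs_latent + stats::rexp(n, dfs_rate * 1.5)
  cens <- stats::runif(n, 0, config$censor_horizon)
  smoking_p <- ifelse(is.na(s_idx), 0.3, c(0.30, 0.45, 0.60)[pmin(s_idx, 3)])
  egfr_p <- ifelse(is.na(s_idx), 0.40, c(0.30, 0.70, 0.50)[pmin(s_idx, 3)])
  kras_p <- ifelse(is.na(s_idx), 0.02, c(0.00, 0.08, 0.12)[pmin(s_idx, 3)])
  braf_p <- ifelse(is.na(s_idx), 0.00, c(0.00, 0.00, 0.08)[pmin(s_idx, 3)])
  size_mu <- c(AAH = 0.8, AIS = 1.2, MIA = 1.6, IAC = 2.6)[stage_of]
  hist_sub <- ifelse(stage_of[patients] != "IAC", "none",
                     ifelse(s_idx == 1 & !is.na(s_idx),
                            sample(c("lepidic", "acinar"), n, TRUE, c(0.7, 0.3)),
                            sample(c("acinar", "papillary", "solid",
                                     "micropapillary"), n, TRUE,
                                   c(0.35, 0.25, 0.25, 0.15))))
  data.frame(
    patient_id = patients,
    age = pmin(pmax(round(stats::rnorm(n, 60, 10)), 30), 85),
    sex = sample(c("F", "M"), n, replace = TRUE),
    smoking = stats::rbinom(n, 1, smoking_p) == 1,
    tumor_size_cm = round(pmax(0.3, stats::rnorm(n, size_mu, 0.6)), 1),
    tnm_stage = ifelse(stage_of[patients] == "IAC",
                       sample(c("IA", "IB", "II", "III"), n, TRUE,
                              c(0.5, 0.25, 0.15, 0.1)), "0"),
    histological_subtype = hist_sub,
    egfr_mutant = stats::rbinom(n, 1, egfr_p) == 1,
    kras_mutant = stats::rbinom(n, 1, kras_p) == 1,
    braf_mutant = stats::rbinom(n, 1, braf_p) == 1,
    dfs_months = pmin(dfs_latent, cens),
    dfs_event = as.integer(dfs_latent <= cens),
    os_months = pmin(os_latent, cens),
    os_event = as.integer(os_latent <= cens),
    stringsAsFactors = FALSE)
}

#' Simulate the plasma cohort
#'
#' One plasma sample per patient over the benign, AIS, MIA, IAC stages,
#' analyzed in a small number of batches with interleaved QC injections.
#' Designated panel metabolites separate the stages by the configured
#' effects in within-class SD units, so the expected single-marker AUC for
#' a contrast at separation d is the binormal value Phi(d / sqrt(2)).
#'
#' @param config A [sim_config()] object.
#' @return List of class `plasma_cohort` with `peaks`, `samples`, and
#'   `truth` (`stage_shifts` in SD units per metabolite x stage,
#'   `panel_metabolites`, `altered`, `batch_factors`, `detectable`).
#' @export
simulate_plasma_cohort <- function(config) {
  validate_sim_config(config)
  stages <- names(config$n_plasma_per_stage)
  with_local_seed(derive_seed(config$seed, 2L), {
    patients <- sprintf("Q%03d", seq_len(sum(config$n_plasma_per_stage)))
    stage_of <- stats::setNames(rep(stages, config$n_plasma_per_stage), patients)

    panel <- config$panel_spec
    panel_ids <- panel$metabolite
    alt_ids <- sprintf("pm_alt_%02d", seq_len(config$n_plasma_altered))
    bg_ids <- sprintf("pm_bg_%03d", seq_len(config$n_plasma_background))
    low_ids <- sprintf("pm_low_%02d", seq_len(config$n_plasma_low))
    mets <- c(panel_ids, alt_ids, bg_ids, low_ids)
    m <- length(mets)
    low <- stats::setNames(mets %in% low_ids, mets)

    shifts <- matrix(0, m, length(stages), dimnames = list(mets, stages))
    shifts[panel_ids, ] <- as.matrix(panel[, stages])
    shapes <- list(c(0, 1, 1, 1), c(0, -1, -1, -1), c(0, 0.5, 1, 1),
                   c(0, 1, 0.5, 0), c(0, -0.5, -1, -1))
    for (i in seq_along(alt_ids)) {
      shifts[alt_ids[i], ] <- config$plasma_altered_effect *
        shapes[[(i - 1L) %% length(shapes) + 1L]]
    }

    baseline <- stats::setNames(numeric(m), mets)
    baseline[!low] <- stats::runif(sum(!low), config$baseline_log2_range[1],
                                   config$baseline_log2_range[2])
    baseline[low] <- stats::runif(sum(low), config$low_abundance_log2_range[1],
                                  config$low_abundance_log2_range[2])

    batch_of <- stats::setNames(
      rep(seq_len(config$n_plasma_batches), length.out = length(patients))[
        order(sample(length(patients)))],
      patients)
    rows <- list()
    for (b in seq_len(config$n_plasma_batches)) {
      ids <- paste0("PL_", patients[batch_of == b])
      lay <- layout_batch(ids, config$plasma_qc_per_batch,
                          sprintf("QC_PB%02d", b))
      lay$batch <- b
      rows[[b]] <- lay
    }
    lay <- do.call(rbind, rows)
    is_qc <- grepl("^QC_", lay$sample_id)
    pat <- ifelse(is_qc, NA_character_, sub("^PL_", "", lay$sample_id))
    samples <- data.frame(
      sample_id = lay$sample_id,
      patient_id = pat,
      cohort = "plasma",
      role = ifelse(is_qc, "QC", "plasma"),
      stage = ifelse(is_qc, "none", stage_of[pat]),
      batch = lay$batch,
      injection_order = lay$injection_order,
      stringsAsFactors = FALSE)

    test <- samples[!is_qc, , drop = FALSE]
    signal <- matrix(baseline, m, nrow(test),
                     dimnames = list(mets, test$sample_id)) +
      config$plasma_sd * shifts[, test$stage, drop = FALSE]
    pooled <- rowMeans(signal)

    batch_mat <- matrix(stats::rnorm(m * config$n_plasma_batches, 0,
                                     config$batch_effect_sd),
                        m, config$n_plasma_batches,
                        dimnames = list(mets, seq_len(config$n_plasma_batches)))
    log2val <- matrix(0, m, nrow(samples),
                      dimnames = list(mets, samples$sample_id))
    log2val[, test$sample_id] <- signal +
      matrix(stats::rnorm(m * nrow(test), 0, config$plasma_sd), m)
    log2val[, samples$sample_id[is_qc]] <- pooled +
      stats::rnorm(m * sum(is_qc), 0, config$noise_sd)
    drift <- config$drift_slope * (samples$injection_order - 1)
    log2val <- log2val + batch_mat[, samples$batch, drop = FALSE] +
      matrix(drift, m, nrow(samples), byrow = TRUE)
    peaks <- 2^log2val
    peaks[peaks < config$detection_threshold] <- NA_real_

    truth <- list(stage_shifts = shifts,
                  panel_metabolites = panel_ids,
                  altered = c(panel_ids, alt_ids),
                  batch_factors = 2^batch_mat,
                  detectable = !low)
    structure(list(peaks = peaks, samples = samples, truth = truth,
                   config = config),
              class = "plasma_cohort")
  })
}
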