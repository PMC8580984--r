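test_that("configuration validation rejects impossible study conditions", {
  expect_s3_class(tiny_config(), "sim_config")
  expect_error(tiny_config(noise_sd = -0.1), "noise_sd")
  expect_error(tiny_config(n_batches = 0), "n_batches")
  expect_error(tiny_config(hazard_by_subtype = c(0.01, -1, 0.02)), "hazard")
  expect_error(
    sim_config(trajectory_archetypes = list(
      list(label = "bad", effects = c(0, 1), n = 5))),
    "one stage effect per stage")
  expect_error(tiny_config(subtype_sizes = c(10, 10)), "subtype_sizes")
})

test_that("seeded simulation is bit-reproducible and streams are independent", {
  cfg <- tiny_config(seed = 42)
  t1 <- simulate_tissue_cohort(cfg)
  t2 <- simulate_tissue_cohort(cfg)
  expect_identical(t1$peaks, t2$peaks)
  expect_identical(t1$clinical, t2$clinical)
  p1 <- simulate_plasma_cohort(cfg)
  p2 <- simulate_plasma_cohort(cfg)
  expect_identical(p1$peaks, p2$peaks)
  # generating the other cohort in between must not perturb the stream
  t3 <- simulate_tissue_cohort(cfg)
  expect_identical(t1$peaks, t3$peaks)
})

test_that("zero-noise simulation is exactly its generative mean", {
  cfg <- noiseless_config()
  tc <- simulate_tissue_cohort(cfg)
  sam <- tc$samples
  # every QC injection is identical
  qc <- sam$sample_id[sam$role == "QC"]
  expect_equal(apply(tc$peaks[, qc], 1, function(r) diff(range(r))),
               setNames(rep(0, nrow(tc$peaks)), rownames(tc$peaks)))
  # tumor/NAT log2 ratio equals the planted stage effect exactly
  stage_of <- stage_of_patients(tc)
  rat <- tumor_nat_ratio(tc$peaks, sam)$ratios
  truth <- tc$truth
  for (lab in c("AIS_peak", "MIA_peak", "up", "down")) {
    mets <- names(truth$trajectory)[truth$trajectory == lab]
    for (st in c("AAH", "AIS", "MIA", "IAC")) {
      pats <- names(stage_of)[stage_of == st]
      # non-IAC patients carry no subtype effect; IAC patients of the
      # archetype metabolites carry none either (disjoint blocks)
      expected <- truth$stage_effects[mets[1], st]
      expect_equal(unname(log2(rat[mets, pats])),
                   matrix(expected, length(mets), length(pats)),
                   tolerance = 1e-9)
    }
  }
})

test_that("empirical tumor/NAT effects match the generative mean at scale", {
  cfg <- sim_config(
    n_per_stage = c(AAH = 2, AIS = 2, MIA = 2, IAC = 1000),
    n_batches = 4, batch_effect_sd = 0, drift_slope = 0, noise_sd = 0.2,
    trajectory_archetypes = list(
      list(label = "up", effects = c(0, 0, 0, 1), n = 1)),
    n_background = 20, n_low_abundance = 2,
    subtype_sizes = c(400, 400, 206),
    subtype_block = c(n_metabolites = 1, log2_effect = 0),
    subtype_signature = c(n_metabolites = 1, log2_effect = 0),
    detection_threshold = 0, seed = 1)
  tc <- simulate_tissue_cohort(cfg)
  rat <- tumor_nat_ratio(tc$peaks, tc$samples)$ratios
  stage_of <- stage_of_patients(tc)
  iac <- names(stage_of)[stage_of == "IAC"]
  lr <- log2(rat["m_up_01", iac])
  # per-patient log2 ratio is N(1, sqrt(2) * 0.2); 3-SE band around 1
  se <- sqrt(2) * 0.2 / sqrt(length(iac))
  expect_lt(abs(mean(lr) - 1), 3 * se)
})

test_that("ground-truth labels partition metabolites and patients", {
  for (s in 1:3) {
    tc <- simulate_tissue_cohort(tiny_config(seed = s))
    expect_setequal(names(tc$truth$trajectory), rownames(tc$peaks))
    expect_false(anyNA(tc$truth$trajectory))
    pats <- unique(tc$samples$patient_id[tc$samples$role == "tumor"])
    expect_setequal(names(tc$truth$subtype), pats)
    # subtype labels cover exactly the invasive patients
    stage_of <- stage_of_patients(tc)
    expect_setequal(names(tc$truth$subtype)[tc$truth$subtype != "none"],
                    names(stage_of)[stage_of == "IAC"])
    # every patient contributes exactly one tumor/NAT pair
    expect_equal(sum(tc$config$n_per_stage) * 2 +
                   tc$config$n_batches * tc$config$qc_per_batch,
                 nrow(tc$samples))
  }
})

test_that("plasma marker separations reproduce the closed-form binormal AUC", {
  d <- 2
  spec <- data.frame(metabolite = "marker", benign = 0, AIS = d, MIA = d,
                     IAC = d, stringsAsFactors = FALSE)
  cfg <- sim_config(
    n_plasma_per_stage = c(benign = 1000, AIS = 400, MIA = 300, IAC = 300),
    panel_spec = spec, n_plasma_altered = 1, n_plasma_background = 10,
    n_plasma_low = 1, batch_effect_sd = 0, drift_slope = 0,
    detection_threshold = 0, seed = 3)
  pc <- simulate_plasma_cohort(cfg)
  sam <- pc$samples
  cols <- sam$sample_id[sam$role != "QC"]
  y <- as.integer(sam$stage[match(cols, sam$sample_id)] != "benign")
  scores <- log2(pc$peaks["marker", cols])
  auc <- roc_auc(scores, y)$auc
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  a <- binormal_auc(d)
  se <- sqrt(a * (1 - a) * (1 + (n1 - 1) * (a / (2 - a) - a^2) / (a * (1 - a)) +
                              (n0 - 1) * (2 * a^2 / (1 + a) - a^2) / (a * (1 - a)))
             / (n0 * n1))
  expect_lt(abs(auc - a), 3 * se)

  # no-signal null: AUC near one half
  spec0 <- spec; spec0[, c("AIS", "MIA", "IAC")] <- 0
  cfg0 <- sim_config(
    n_plasma_per_stage = c(benign = 1000, AIS = 400, MIA = 300, IAC = 300),
    panel_spec = spec0, n_plasma_altered = 1, n_plasma_background = 10,
    n_plasma_low = 1, batch_effect_sd = 0, drift_slope = 0,
    detection_threshold = 0, seed = 4)
  pc0 <- simulate_plasma_cohort(cfg0)
  scores0 <- log2(pc0$peaks["marker", cols])
  expect_lt(abs(roc_auc(scores0, y)$auc - 0.5), 0.05)
})
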