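# Small simulation configurations used across tests; scaled down from the
# defaults so the suite stays fast, but structurally identical.

tiny_config <- function(seed = 1, ...) {
  sim_config(
    n_per_stage = c(AAH = 4, AIS = 6, MIA = 6, IAC = 30),
    n_batches = 4,
    qc_per_batch = 3,
    trajectory_archetypes = default_archetypes(6),
    n_background = 10,
    n_low_abundance = 6,
    subtype_sizes = c(8, 15, 7),
    subtype_block = c(n_metabolites = 6, log2_effect = 1.5),
    subtype_signature = c(n_metabolites = 6, log2_effect = 1),
    n_plasma_per_stage = c(benign = 8, AIS = 10, MIA = 8, IAC = 10),
    n_plasma_altered = 4,
    n_plasma_background = 20,
    n_plasma_low = 5,
    seed = seed,
    ...
  )
}

# A noiseless, batch-free configuration: every stochastic nuisance is off,
# so generated values equal their generative means exactly.
noiseless_config <- function(seed = 1) {
  tiny_config(
    seed = seed,
    batch_effect_sd = 0,
    drift_slope = 0,
    noise_sd = 0,
    plasma_sd = 0,
    detection_threshold = 0
  )
}

stage_of_patients <- function(cohort) {
  sam <- cohort$samples
  stats::setNames(sam$stage[sam$role == "tumor"],
                  sam$patient_id[sam$role == "tumor"])
}
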