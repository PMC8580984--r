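#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic tissue and plasma cohorts.
#
# The generator emulates the study design: 181 patients with paired
# tumor/NAT tissue across AAH/AIS/MIA/IAC (12/22/19/128) in 14 batches
# with interleaved pooled-QC injections, and a 92-patient plasma cohort
# (benign/AIS/MIA/IAC = 10/32/22/28) in 2 batches. Ground truth (trajectory
# archetypes, latent subtypes, batch factors, marker separations, hazards)
# is written alongside so every later stage can be scored.

source(file.path("analysis", "00_common.R"))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
cfg <- sim_config(seed = seed)

tissue <- simulate_tissue_cohort(cfg)
plasma <- simulate_plasma_cohort(cfg)

message(sprintf("tissue cohort: %d metabolites x %d injections (%.1f%% below detection)",
                nrow(tissue$peaks), ncol(tissue$peaks),
                100 * mean(is.na(tissue$peaks))))
message(sprintf("plasma cohort: %d metabolites x %d injections",
                nrow(plasma$peaks), ncol(plasma$peaks)))

write_matrix_csv(tissue$peaks, apath("tissue_peaks.csv"))
write_results(tissue$samples, apath("tissue_samples.csv"))
write_results(tissue$clinical, apath("clinical.csv"))
write_matrix_csv(plasma$peaks, apath("plasma_peaks.csv"))
write_results(plasma$samples, apath("plasma_samples.csv"))

jsonlite::write_json(
  list(seed = seed,
       trajectory = as.list(tissue$truth$trajectory),
       subtype = as.list(tissue$truth$subtype),
       plasma_altered = plasma$truth$altered),
  apath("ground_truth.json"), auto_unbox = TRUE, digits = NA)

message("wrote cohort tables to ", adir)
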