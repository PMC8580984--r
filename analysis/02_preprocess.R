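#!/usr/bin/env Rscript
# Stage 2 — preprocessing chain on both cohorts:
# detection filter (80% rule) -> baseline fill (1000) -> pooled-QC batch
# normalization (QC_all / QC_adj) -> total-signal scaling -> per-patient
# tumor/NAT relative abundances for the tissue cohort.

source(file.path("analysis", "00_common.R"))

for (cohort in c("tissue", "plasma")) {
  peaks <- read_matrix_csv(apath(paste0(cohort, "_peaks.csv")))
  samples <- read_results(apath(paste0(cohort, "_samples.csv")))
  pp <- preprocess_cohort(peaks, samples, ratios = (cohort == "tissue"))
  message(sprintf("%s: %d/%d metabolites detectable; %d dropped",
                  cohort, nrow(pp$filtered), nrow(peaks), length(pp$dropped)))
  write_matrix_csv(pp$normalized, apath(paste0(cohort, "_normalized.csv")))
  write_matrix_csv(pp$scaled, apath(paste0(cohort, "_scaled.csv")))
  write_results(pp$filter_report, apath(paste0(cohort, "_filter_report.csv")))
  if (cohort == "tissue") {
    message(sprintf("tumor/NAT ratio matrix: %d metabolites x %d patients",
                    nrow(pp$ratios), ncol(pp$ratios)))
    write_matrix_csv(pp$ratios, apath("tissue_ratios.csv"))
  }
}
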