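#!/usr/bin/env Rscript
# Stage 8 — survival stratification of invasive patients.
#
# Disease-free and overall survival are compared across the metabolic
# subtypes (log-rank); patients are also dichotomized by mean bile-acid
# log2 relative abundance at the 0.4 quantile, and by the maximally
# selected log-rank cutpoint, and both splits are tested.

source(file.path("analysis", "00_common.R"))

rat <- read_matrix_csv(apath("tissue_ratios.csv"))
subt <- read_results(apath("subtype_assignments.csv"))
clin <- read_results(apath("clinical.csv"))

idx <- match(subt$patient_id, clin$patient_id)
for (ep in c("dfs", "os")) {
  t <- clin[[paste0(ep, "_months")]][idx]
  e <- clin[[paste0(ep, "_event")]][idx]
  lr <- logrank_test(t, e, subt$subtype)
  message(sprintf("%s across subtypes: chi-square %.2f on %d df, log-rank p = %.3g",
                  toupper(ep), lr$chisq, lr$df, lr$p.value))
  km <- lapply(split(seq_along(t), subt$subtype), function(i) {
    k <- km_estimate(t[i], e[i])
    data.frame(endpoint = ep, subtype = subt$subtype[i[1]], time = k$time,
               surv = k$surv, n_risk = k$n_risk)
  })
  write_results(do.call(rbind, km), apath(paste0("km_", ep, "_subtypes.csv")))
}

bile <- intersect(rownames(rat),
                  c("cholic acid", "chenodeoxycholic acid", "deoxycholic acid",
                    "glycocholic acid", "glycochenodeoxycholic acid",
                    "glycodeoxycholic acid", "taurocholic acid",
                    "taurochenodeoxycholic acid", "taurodeoxycholic acid"))
lvl <- colMeans(log2(rat[bile, subt$patient_id, drop = FALSE]))
qs <- quantile_split(lvl, q = 0.4)
lr_b <- logrank_test(clin$dfs_months[idx], clin$dfs_event[idx], qs$labels)
message(sprintf("bile-acid 0.4-quantile split (threshold %.3g): DFS log-rank p = %.3g",
                qs$threshold, lr_b$p.value))

cp <- optimal_cutpoint(lvl, clin$dfs_months[idx], clin$dfs_event[idx])
message(sprintf("maximally selected cutpoint %.3g (standardized statistic %.2f)",
                cp$cutoff, cp$statistic))

write_results(data.frame(
  analysis = c("bile_quantile_DFS", "bile_cutpoint_DFS"),
  threshold = c(qs$threshold, cp$cutoff),
  statistic = c(lr_b$chisq, cp$statistic^2),
  p = c(lr_b$p.value, cp$p_uncorrected)),
  apath("bile_stratification.csv"))
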