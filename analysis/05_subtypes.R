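#!/usr/bin/env Rscript
# Stage 5 — consensus metabolic subtyping of the invasive (IAC) patients.
#
# Patients are clustered on z-scored log2 tumor/NAT profiles by k-means
# over Pearson geometry with 1000 subsampling repetitions for k = 2..6;
# the CDF/delta-area curve plus the within-cluster consensus choose k, and
# patients are assigned by average-linkage cuts of 1 - consensus.

source(file.path("analysis", "00_common.R"))

rat <- read_matrix_csv(apath("tissue_ratios.csv"))
sam <- read_results(apath("tissue_samples.csv"))
gt <- jsonlite::read_json(apath("ground_truth.json"), simplifyVector = TRUE)

stage_of <- setNames(sam$stage[sam$role == "tumor"],
                     sam$patient_id[sam$role == "tumor"])
iac <- colnames(rat)[stage_of[colnames(rat)] == "IAC"]
X <- scale(t(log2(rat[, iac, drop = FALSE])))
X <- X[, apply(X, 2, function(v) all(is.finite(v))), drop = FALSE]

cm <- consensus_cluster(X, k_range = 2:6, reps = 1000, p_item = 0.8,
                        seed = gt$seed)
sk <- select_k(cm)
message(sprintf("delta-area: %s", paste(sprintf("k=%d:%.3f", cm$k_range,
                                                sk$delta), collapse = "  ")))
message(sprintf("chosen k = %d (stable = %s)", sk$chosen_k, sk$stable))

subtypes <- assign_subtypes(cm, sk$chosen_k)
truth <- unlist(gt$subtype)[names(subtypes)]
message(sprintf("subtype sizes %s; recovery ARI = %.3f",
                paste(table(subtypes), collapse = "/"),
                adjusted_rand_index(subtypes, truth)))

write_results(data.frame(patient_id = names(subtypes),
                         subtype = paste0("S", subtypes)),
              apath("subtype_assignments.csv"))
write_results(data.frame(k = cm$k_range, area = unname(sk$area),
                         delta = unname(sk$delta),
                         within_consensus =
                           sk$within_consensus$mean_within_consensus),
              apath("consensus_selection.csv"))
m3 <- cm$consensus[[as.character(sk$chosen_k)]]
write_results(data.frame(patient_id = rownames(m3), m3, check.names = FALSE),
              apath("consensus_matrix.csv"))
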