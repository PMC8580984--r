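#!/usr/bin/env Rscript
# Stage 3 — differential metabolite calling.
#
# Tissue: Wilcoxon signed-rank on paired tumor vs NAT per stage, and
# rank-sum stage contrasts (IAC vs AAH/AIS, IAC vs MIA) on relative
# abundances; gates FDR < 0.05 with fold change > 1.25 or < 0.8.
# Plasma: Kruskal-Wallis screen across benign/AIS/MIA/IAC at raw P < 0.1.

source(file.path("analysis", "00_common.R"))

scaled <- read_matrix_csv(apath("tissue_scaled.csv"))
sam <- read_results(apath("tissue_samples.csv"))
rat <- read_matrix_csv(apath("tissue_ratios.csv"))

tables <- list()
for (st in c("AAH", "AIS", "MIA", "IAC")) {
  tcols <- sam$sample_id[sam$role == "tumor" & sam$stage == st]
  ncols <- paste0("N_", sub("^T_", "", tcols))
  tables[[st]] <- call_differential(scaled[, tcols, drop = FALSE],
                                    scaled[, ncols, drop = FALSE],
                                    comparison = paste0(st, "_tumor_vs_NAT"),
                                    paired = TRUE)
  message(sprintf("%s tumor vs NAT: %d differential metabolites (n = %d pairs)",
                  st, sum(tables[[st]]$direction != "ns"), length(tcols)))
}

stage_of <- setNames(sam$stage[sam$role == "tumor"],
                     sam$patient_id[sam$role == "tumor"])
st <- stage_of[colnames(rat)]
tables$IAC_vs_AAH_AIS <- call_differential(
  rat[, st == "IAC", drop = FALSE],
  rat[, st %in% c("AAH", "AIS"), drop = FALSE],
  comparison = "IAC_vs_AAH_AIS")
tables$IAC_vs_MIA <- call_differential(
  rat[, st == "IAC", drop = FALSE], rat[, st == "MIA", drop = FALSE],
  comparison = "IAC_vs_MIA")
message(sprintf("stage contrasts: %d (IAC vs AAH/AIS), %d (IAC vs MIA)",
                sum(tables$IAC_vs_AAH_AIS$direction != "ns"),
                sum(tables$IAC_vs_MIA$direction != "ns")))

write_results(do.call(rbind, tables), apath("differential_metabolites.csv"))

pscaled <- read_matrix_csv(apath("plasma_scaled.csv"))
psam <- read_results(apath("plasma_samples.csv"))
pcols <- psam$sample_id[psam$role != "QC"]
pkw <- kw_screen(pscaled[, pcols, drop = FALSE],
                 psam$stage[match(pcols, psam$sample_id)])
message(sprintf("plasma screen: %d metabolites altered across stages at raw P < 0.1",
                sum(pkw$p < 0.1)))
write_results(pkw, apath("plasma_stage_screen.csv"))
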