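#!/usr/bin/env Rscript
# Stage 6 — metabolite-set enrichment of the poor-prognosis subtype.
#
# Metabolites differential in the last (bile-acid-elevated) subtype versus
# the other two are tested for over-representation in the synthetic
# pathway collection (one-sided hypergeometric, BH FDR < 0.05). A user GMT
# can be substituted by passing its path as the first argument; the same
# collection ships as inst/extdata/synthetic_pathways.gmt for that route.

source(file.path("analysis", "00_common.R"))

args <- commandArgs(trailingOnly = TRUE)
rat <- read_matrix_csv(apath("tissue_ratios.csv"))
subt <- read_results(apath("subtype_assignments.csv"))

sets <- if (length(args) >= 1) read_gmt(args[[1]]) else synthetic_pathways()
last <- subt$patient_id[subt$subtype == max(subt$subtype)]
rest <- setdiff(subt$patient_id, last)
dt <- call_differential(rat[, last, drop = FALSE], rat[, rest, drop = FALSE],
                        comparison = "last_subtype_vs_rest")

background <- intersect(rownames(rat), unique(unlist(sets)))
diff_ids <- intersect(dt$metabolite[dt$direction != "ns"], background)
message(sprintf("%d differential metabolites against a background of %d",
                length(diff_ids), length(background)))

tab <- enrich(diff_ids, background, sets,
              log2_fc = setNames(dt$log2_fc, dt$metabolite))
sig <- tab[tab$significant, ]
message(sprintf("%d set(s) enriched at FDR < 0.05:", nrow(sig)))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-12s fold enrichment %.2f, mean log2 FC %+.2f, FDR %.2g",
                  sig$set_id[i], sig$fold_enrichment[i], sig$mean_log2_fc[i],
                  sig$fdr[i]))
}
write_results(tab, apath("pathway_enrichment.csv"))
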