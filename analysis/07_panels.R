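#!/usr/bin/env Rscript
# Stage 7 — plasma biomarker panels.
#
# Three logistic-regression panels on log10 scaled abundances, each scored
# by in-sample ROC/AUC (with a 5-fold cross-validated AUC alongside for
# honesty): benign vs AIS/MIA/IAC (4 markers), benign vs AIS/MIA
# (cystine + valine), benign vs AIS (asparagine + cystine).

source(file.path("analysis", "00_common.R"))

pscaled <- read_matrix_csv(apath("plasma_scaled.csv"))
psam <- read_results(apath("plasma_samples.csv"))

rows <- list()
for (nm in names(default_panels())) {
  p <- default_panels()[[nm]]
  ev <- evaluate_panel(pscaled, p$metabolites, psam,
                       list(negative = p$negative, positive = p$positive),
                       cv_folds = 5)
  message(sprintf("%-24s AUC = %.3f (cv %.3f), n = %d vs %d  [%s]",
                  nm, ev$auc, ev$cv_auc,
                  ev$panel$n_per_class["n0"], ev$panel$n_per_class["n1"],
                  paste(p$metabolites, collapse = " + ")))
  rows[[nm]] <- data.frame(panel = nm,
                           metabolites = paste(p$metabolites, collapse = "+"),
                           auc = ev$auc, cv_auc = ev$cv_auc,
                           separation = ev$panel$separation)
  roc <- data.frame(threshold = ev$roc$thresholds, fpr = ev$roc$fpr,
                    tpr = ev$roc$tpr)
  write_results(roc, apath(paste0("roc_", nm, ".csv")))
}
write_results(do.call(rbind, c(rows, list(make.row.names = FALSE))),
              apath("panel_aucs.csv"))
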