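#' Detection filter (the 80% rule)
#'
#' A metabolite is kept when its detection fraction reaches `threshold`
#' (inclusive) in at least one sample group. The default grouping crosses
#' sample role with histological stage (tumor-AAH, NAT-AAH, ...), so a
#' metabolite confined to one stage or one compartment survives. QC columns
#' never enter the detection count but are carried through unchanged.
#'
#' @param matrix Metabolite x sample peak-area matrix with `NA` for
#'   undetected values.
#' @param samples Sample table (see [validate_sample_table()]).
#' @param group_by Either the string `"role_stage"` (default) or the name of
#'   a single column of `samples` used to group the non-QC samples.
#' @param threshold Minimum detection fraction in at least one group
#'   (default 0.8, the 4/5 rule).
#' @param strict If `TRUE`, a separate reading of the rule is applied in
#'   which only metabolites undetected in more than `1 - threshold` of
#'   samples in *every* group are dropped; identical to the default for the
#'   usual case but kept explicit because the published wording admits both
#'   readings. Default `FALSE`.
#' @return A list with `matrix` (rows restricted to retained metabolites),
#'   `dropped` (character vector), and `report` (per-metabolite, per-group
#'   detection fractions).
#' @export
detection_filter <- function(matrix, samples, group_by = "role_stage",
                             threshold = 0.8, strict = FALSE) {
  samples <- as.data.frame(samples)
  validate_sample_table(samples)
  stopifnot(threshold > 0, threshold <= 1)
  test <- samples[samples$role != "QC", , drop = FALSE]
  test <- test[test$sample_id %in% colnames(matrix), , drop = FALSE]
  if (nrow(test) == 0L) stop("no non-QC samples found in the matrix")
  groups <- if (identical(group_by, "role_stage")) {
    interaction(test$role, test$stage, drop = TRUE, sep = "-")
  } else {
    if (!group_by %in% colnames(test)) {
      stop("unknown grouping column '", group_by, "'")
    }
    factor(test[[group_by]])
  }
  if (any(table(groups) == 0L)) stop("empty sample group in detection filter")
  sub <- matrix[, test$sample_id, drop = FALSE]
  det <- !is.na(sub)
  frac <- vapply(levels(groups), function(g) {
    rowMeans(det[, groups == g, drop = FALSE])
  }, numeric(nrow(matrix)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(sub),
                                         dimnames = list(rownames(sub), levels(groups)))
  keep <- apply(frac, 1L, max) >= threshold
  if (strict) {
    # strict mode: drop only metabolites below the fill margin everywhere
    keep <- keep | apply(frac, 1L, max) >= (1 - threshold)
  }
  report <- data.frame(metabolite = rownames(matrix),
                       max_detection = apply(frac, 1L, max),
                       retained = keep, row.names = NULL,
                       check.names = FALSE)
  report <- cbind(report, as.data.frame(frac, check.names = FALSE))
  list(matrix = matrix[keep, , drop = FALSE],
       dropped = rownames(matrix)[!keep],
       report = report)
}

#' Fill missing peak areas with a detection baseline
#'
#' Remaining missing values after the detection filter are replaced by a
#' fixed baseline on the raw peak-area scale (default 1000) so rank-based
#' statistics downstream see a complete matrix. Detected values are never
#' altered.
#'
#' @param matrix Peak-area matrix with `NA` for missing values.
#' @param baseline Non-negative fill value, default 1000.
#' @return The filled matrix.
#' @export
baseline_fill <- function(matrix, baseline = 1000) {
  if (!is.numeric(baseline) || length(baseline) != 1L || is.na(baseline) ||
      baseline < 0) {
    stop("baseline must be a single non-negative number")
  }
  matrix[is.na(matrix)] <- baseline
  matrix
}

#' Pooled-QC anchored batch normalization
#'
#' For each metabolite, the mean peak area over all QC injections (QC_all)
#' and over the QC injections anchoring a group of test samples (QC_adj) are
#' computed; every value in that group is multiplied by QC_all / QC_adj.
#' When QC injections share a batch's multiplicative effect, this equalizes
#' per-batch QC means across batches and removes the batch effect from the
#' test samples.
#'
#' Two anchorings are provided. `"batch"` (default) takes QC_adj as the mean
#' over a batch's QC injections and applies one factor per (metabolite,
#' batch). `"sliding"` takes, per test sample, the `k` QC injections nearest
#' in injection order within its batch, giving a per-sample factor that also
#' tracks within-batch drift.
#'
#' @param matrix Filled peak-area matrix (no `NA`; fill first).
#' @param samples Sample table; QC rows identify the anchors.
#' @param mode `"batch"` or `"sliding"`.
#' @param k Number of nearest QC injections in sliding mode (default 2).
#' @return A list with `matrix` (normalized; QC columns normalized by their
#'   own batch factor so cross-batch QC agreement can be audited) and
#'   `factors` (long data frame: metabolite, group, qc_all, qc_adj, factor).
#' @export
qc_normalize <- function(matrix, samples, mode = c("batch", "sliding"), k = 2) {
  mode <- match.arg(mode)
  samples <- as.data.frame(samples)
  validate_sample_table(samples)
  if (anyNA(matrix)) stop("matrix contains missing values; run baseline_fill() first")
  samples <- samples[samples$sample_id %in% colnames(matrix), , drop = FALSE]
  qc <- samples[samples$role == "QC", , drop = FALSE]
  if (nrow(qc) == 0L) stop("no QC samples available for normalization")
  batches <- unique(samples$batch)
  no_qc <- setdiff(batches, unique(qc$batch))
  if (length(no_qc) > 0L) {
    stop("batch(es) without QC injections: ", paste(no_qc, collapse = ", "))
  }
  qc_all <- rowMeans(matrix[, qc$sample_id, drop = FALSE])
  if (any(qc_all <= 0)) {
    stop("zero QC_all mean for metabolite(s): ",
         paste(rownames(matrix)[qc_all <= 0], collapse = ", "))
  }
  out <- matrix
  if (mode == "batch") {
    fac_list <- vector("list", length(batches))
    for (i in seq_along(batches)) {
      b <- batches[i]
      qc_b <- qc$sample_id[qc$batch == b]
      qc_adj <- rowMeans(matrix[, qc_b, drop = FALSE])
      if (any(qc_adj <= 0)) {
        stop("zero QC_adj mean in batch ", b, " for metabolite(s): ",
             paste(rownames(matrix)[qc_adj <= 0], collapse = ", "))
      }
      fac <- qc_all / qc_adj
      cols <- samples$sample_id[samples$batch == b]
      out[, cols] <- matrix[, cols, drop = FALSE] * fac
      fac_list[[i]] <- data.frame(metabolite = rownames(matrix),
                                  group = as.character(b),
                                  qc_all = qc_all, qc_adj = qc_adj,
                                  factor = fac, row.names = NULL)
    }
    factors <- do.call(rbind, fac_list)
  } else {
    test <- samples[samples$role != "QC", , drop = FALSE]
    fac_list <- vector("list", nrow(test))
    for (i in seq_len(nrow(test))) {
      s <- test[i, ]
      qc_b <- qc[qc$batch == s$batch, , drop = FALSE]
      ord <- order(abs(qc_b$injection_order - s$injection_order))
      near <- qc_b$sample_id[ord[seq_len(min(k, nrow(qc_b)))]]
      qc_adj <- rowMeans(matrix[, near, drop = FALSE])
      if (any(qc_adj <= 0)) {
        stop("zero QC_adj mean near sample ", s$sample_id,
             " for metabolite(s): ",
             paste(rownames(matrix)[qc_adj <= 0], collapse = ", "))
      }
      fac <- qc_all / qc_adj
      out[, s$sample_id] <- matrix[, s$sample_id] * fac
      fac_list[[i]] <- data.frame(metabolite = rownames(matrix),
                                  group = s$sample_id,
                                  qc_all = qc_all, qc_adj = qc_adj,
                                  factor = fac, row.names = NULL)
    }
    # QC columns still get their batch factor so audits remain possible
    for (b in batches) {
      qc_b <- qc$sample_id[qc$batch == b]
      qc_adj <- rowMeans(matrix[, qc_b, drop = FALSE])
      out[, qc_b] <- matrix[, qc_b, drop = FALSE] * (qc_all / qc_adj)
    }
    factors <- do.call(rbind, fac_list)
  }
  list(matrix = out, factors = factors)
}

#' Total-signal scaling
#'
#' Divides each sample's values by that sample's summed signal so each
#' column sums to one, correcting sample-to-sample biomass differences.
#'
#' @param matrix Normalized, filled peak-area matrix.
#' @return The scaled matrix; every column sums to 1.
#' @export
tss_scale <- function(matrix) {
  if (anyNA(matrix)) stop("matrix contains missing values; run baseline_fill() first")
  tot <- colSums(matrix)
  if (any(tot <= 0)) {
    stop("zero total signal in sample(s): ",
         paste(colnames(matrix)[tot <= 0], collapse = ", "))
  }
  sweep(matrix, 2L, tot, "/")
}

#' Per-patient tumor/NAT relative abundance
#'
#' The unit of all stage comparisons: for each patient with both a tumor and
#' an NAT sample, the per-metabolite ratio tumor / NAT.
#'
#' @param matrix Scaled abundance matrix (strictly positive values).
#' @param samples Sample table for a tissue cohort.
#' @return A list with `ratios` (metabolite x patient matrix, entries > 0)
#'   and `excluded` (patients lacking a complete pair, reported not fatal).
#' @export
tumor_nat_ratio <- function(matrix, samples) {
  samples <- as.data.frame(samples)
  validate_sample_table(samples)
  tis <- samples[samples$cohort == "tissue" & samples$role %in% c("tumor", "NAT") &
                   samples$sample_id %in% colnames(matrix), , drop = FALSE]
  tum <- tis[tis$role == "tumor", , drop = FALSE]
  nat <- tis[tis$role == "NAT", , drop = FALSE]
  patients <- union(tum$patient_id, nat$patient_id)
  paired <- intersect(tum$patient_id, nat$patient_id)
  excluded <- setdiff(patients, paired)
  if (length(paired) == 0L) stop("no patient has a complete tumor/NAT pair")
  tcol <- tum$sample_id[match(paired, tum$patient_id)]
  ncol_ <- nat$sample_id[match(paired, nat$patient_id)]
  tval <- matrix[, tcol, drop = FALSE]
  nval <- matrix[, ncol_, drop = FALSE]
  if (any(tval <= 0) || any(nval <= 0)) {
    stop("non-positive abundances; ratios require a filled, scaled matrix")
  }
  ratios <- tval / nval
  colnames(ratios) <- paired
  list(ratios = ratios, excluded = excluded)
}

#' Run the full preprocessing chain
#'
#' Convenience composition in the pipeline's canonical order:
#' detection filter, baseline fill, QC normalization, total-signal scaling,
#' and (for tissue cohorts) the tumor/NAT ratio matrix.
#'
#' @param matrix Raw peak-area matrix with `NA` for undetected values.
#' @param samples Sample table.
#' @param threshold Detection-filter threshold (default 0.8).
#' @param baseline Detection baseline fill value (default 1000).
#' @param group_by Detection-filter grouping (default `"role_stage"`).
#' @param qc_mode QC anchoring mode, `"batch"` or `"sliding"`.
#' @param ratios Compute the tumor/NAT ratio matrix (tissue cohorts only).
#' @return A list with `filtered`, `normalized`, `scaled`, `factors`,
#'   `filter_report`, and, when `ratios = TRUE`, `ratios` and
#'   `excluded_patients`.
#' @export
preprocess_cohort <- function(matrix, samples, threshold = 0.8,
                              baseline = 1000, group_by = "role_stage",
                              qc_mode = "batch", ratios = TRUE) {
  flt <- detection_filter(matrix, samples, group_by = group_by,
                          threshold = threshold)
  filled <- baseline_fill(flt$matrix, baseline = baseline)
  norm <- qc_normalize(filled, samples, mode = qc_mode)
  scaled <- tss_scale(norm$matrix)
  out <- list(filtered = flt$matrix, normalized = norm$matrix,
              scaled = scaled, factors = norm$factors,
              filter_report = flt$report, dropped = flt$dropped)
  if (ratios) {
    rat <- tumor_nat_ratio(scaled, samples)
    out$ratios <- rat$ratios
    out$excluded_patients <- rat$excluded
  }
  out
}
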