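# helpers building minimal matrices/sample tables by hand
mini_samples <- function(n_per_group, roles = "tumor", stages = "IAC",
                         batch = 1, cohort = "tissue") {
  grid <- expand.grid(i = seq_len(n_per_group), role = roles, stage = stages,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d", substr(grid$role, 1, 1), grid$stage, grid$i),
    patient_id = sprintf("P_%s_%d", grid$stage, grid$i),
    cohort = cohort, role = grid$role, stage = grid$stage,
    batch = batch, injection_order = seq_len(nrow(grid)),
    stringsAsFactors = FALSE)
}

test_that("detection filter applies the at-least-80%-in-one-group rule inclusively", {
  sam <- rbind(mini_samples(10, stages = "AAH"), mini_samples(10, stages = "IAC"))
  sam$injection_order <- seq_len(nrow(sam))
  m <- matrix(1000, 3, 20, dimnames = list(c("full", "seven", "eight"),
                                           sam$sample_id))
  # detected in 7/10 of both groups: below threshold everywhere -> dropped
  m["seven", c(1:3, 11:13)] <- NA
  # detected in exactly 8/10 in one group, 0/10 in the other -> retained
  m["eight", c(9:10, 11:20)] <- NA
  res <- detection_filter(m, sam, threshold = 0.8)
  expect_setequal(rownames(res$matrix), c("full", "eight"))
  expect_identical(res$dropped, "seven")
  expect_equal(res$report$max_detection[res$report$metabolite == "eight"], 0.8)
})

test_that("baseline fill replaces only missing cells", {
  m <- matrix(c(5000, NA, 2500, 8000), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  filled <- baseline_fill(m, 1000)
  expect_equal(filled["a", "s2"], 2500)
  expect_equal(filled["b", "s1"], 1000)
  expect_equal(baseline_fill(filled), filled)  # identity with no missing
  all_na <- matrix(NA_real_, 1, 3)
  expect_true(all(baseline_fill(all_na) == 1000))
  expect_error(baseline_fill(m, -1), "non-negative")
})

test_that("QC normalization reproduces hand-computed factors and equalizes QC means", {
  # two batches; QC means 1000 and 4000 -> QC_all 2500, factors 2.5 and 0.625
  sam <- data.frame(
    sample_id = c("t1", "q1", "t2", "q2"),
    patient_id = c("P1", NA, "P2", NA),
    cohort = "tissue", role = c("tumor", "QC", "tumor", "QC"),
    stage = c("IAC", "none", "IAC", "none"),
    batch = c(1, 1, 2, 2), injection_order = 1:4,
    stringsAsFactors = FALSE)
  m <- matrix(c(500, 1000, 800, 4000), 1, 4,
              dimnames = list("met", sam$sample_id))
  res <- qc_normalize(m, sam)
  fac <- res$factors
  expect_equal(fac$factor[fac$group == "1"], 2.5)
  expect_equal(fac$factor[fac$group == "2"], 0.625)
  expect_equal(res$matrix[1, "t1"], 500 * 2.5)
  expect_equal(res$matrix[1, "t2"], 800 * 0.625)
  # post-normalization QC means agree across batches (the fixed point)
  expect_equal(res$matrix[1, "q1"], res$matrix[1, "q2"])

  # single batch: QC_adj = QC_all, factors 1, matrix unchanged
  sam1 <- sam; sam1$batch <- 1
  res1 <- qc_normalize(m, sam1)
  expect_equal(res1$matrix, m)
  expect_true(all(res1$factors$factor == 1))

  # batch without QC is an error naming the batch
  sam_noqc <- sam; sam_noqc$role[4] <- "tumor"; sam_noqc$patient_id[4] <- "P3"
  sam_noqc$stage[4] <- "IAC"
  expect_error(qc_normalize(m, sam_noqc), "2")
})

test_that("a per-batch scale factor is absorbed by QC normalization", {
  cfg <- tiny_config(seed = 3, detection_threshold = 0)
  tc <- simulate_tissue_cohort(cfg)
  pp1 <- preprocess_cohort(tc$peaks, tc$samples)
  # multiply every raw value of batch 2 (QC included) by a constant; this is
  # exactly an extra batch effect shared by the QC injections
  peaks2 <- tc$peaks
  b2 <- tc$samples$sample_id[tc$samples$batch == 2]
  peaks2[, b2] <- peaks2[, b2] * 3.7
  pp2 <- preprocess_cohort(peaks2, tc$samples)
  # the post-normalization matrices agree up to a per-metabolite global
  # factor (QC_all itself moves with the injected constant); no sample- or
  # batch-dependence of that factor remains
  ratio <- pp2$normalized / pp1$normalized
  spread <- apply(ratio, 1, function(r) diff(range(r)) / mean(r))
  expect_lt(max(spread), 1e-10)
  # and the paired tumor/NAT ratios are exactly invariant
  rat1 <- tumor_nat_ratio(pp1$normalized, tc$samples)$ratios
  rat2 <- tumor_nat_ratio(pp2$normalized, tc$samples)$ratios
  expect_equal(rat2, rat1, tolerance = 1e-12)
})

test_that("total-signal scaling and tumor/NAT ratios follow their definitions", {
  m <- matrix(c(2, 3, 5, 4, 4, 2), 3, 2,
              dimnames = list(c("a", "b", "c"), c("T_P1", "N_P1")))
  sc <- tss_scale(m)
  expect_equal(sc[, "T_P1"], c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unname(colSums(sc)), c(1, 1), tolerance = 1e-12)
  expect_equal(tss_scale(matrix(7, 1, 1, dimnames = list("a", "s")))[1, 1], 1)
  zero <- m; zero[, 1] <- 0
  expect_error(tss_scale(zero), "T_P1")

  sam <- data.frame(sample_id = c("T_P1", "N_P1", "T_P2"),
                    patient_id = c("P1", "P1", "P2"),
                    cohort = "tissue", role = c("tumor", "NAT", "tumor"),
                    stage = "IAC", batch = 1, injection_order = 1:3,
                    stringsAsFactors = FALSE)
  m2 <- cbind(m, T_P2 = c(1, 1, 1))
  rat <- tumor_nat_ratio(m2, sam)
  expect_equal(rat$ratios[, "P1"], c(a = 0.5, b = 0.75, c = 2.5))
  expect_identical(rat$excluded, "P2")  # patient lacking NAT reported

  # tumor = NAT gives all-1 ratios
  m3 <- m; m3[, 2] <- m3[, 1]
  rat3 <- tumor_nat_ratio(m3, sam[1:2, ])
  expect_true(all(rat3$ratios == 1))
})

test_that("on synthetic data QC normalization removes the planted batch effects", {
  cfg <- tiny_config(seed = 4)
  tc <- simulate_tissue_cohort(cfg)
  pp <- preprocess_cohort(tc$peaks, tc$samples, ratios = FALSE)
  sam <- tc$samples
  qc <- sam[sam$role == "QC", ]
  means <- sapply(split(qc$sample_id, qc$batch), function(cols) {
    rowMeans(pp$normalized[, cols, drop = FALSE])
  })
  rel_spread <- apply(means, 1, function(r) diff(range(r)) / mean(r))
  expect_lt(max(rel_spread), 1e-10)
})
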