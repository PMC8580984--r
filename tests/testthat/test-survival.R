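test_that("Kaplan-Meier product-limit estimates match hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: survival stays at 1
  kmc <- km_estimate(c(5, 8, 10), c(0, 0, 0))
  expect_true(all(kmc$surv == 1))

  # single subject with an event drops to zero
  km1 <- km_estimate(4, 1)
  expect_equal(km1$surv, 0)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")

  # with no censoring, KM equals 1 - ECDF of the event times
  t <- withr::with_seed(2, round(rexp(40, 0.1), 1))
  km <- km_estimate(t, rep(1, 40))
  ecdf_t <- ecdf(t)
  expect_equal(km$surv, 1 - ecdf_t(km$time), tolerance = 1e-12)
})

test_that("log-rank test matches the hand O-E formula and a permutation oracle", {
  # two identical groups: exchangeable, chi-square 0
  t0 <- c(1, 2, 3, 1, 2, 3); e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("a", "b"), each = 3)
  lr0 <- logrank_test(t0, e0, g0)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p.value, 1)

  # toy data against the standard two-group formula written by hand
  t1 <- c(1, 2, 3, 4); e1 <- c(1, 1, 1, 1); g1 <- c("a", "a", "b", "b")
  lr1 <- logrank_test(t1, e1, g1)
  expect_equal(lr1$chisq, hand_logrank_chisq(t1, e1, g1), tolerance = 1e-10)

  # label swap invariance
  lr1b <- logrank_test(t1, e1, rev(g1))
  expect_equal(lr1b$chisq, lr1$chisq, tolerance = 1e-12)

  # asymptotic p within 0.01 of a permutation p on synthetic data
  dat <- withr::with_seed(13, {
    time <- c(rexp(20, 0.1), rexp(20, 0.25))
    cens <- runif(40, 0, 15)
    list(t = pmin(time, cens), e = as.integer(time <= cens),
         g = rep(1:2, each = 20))
  })
  lr <- logrank_test(dat$t, dat$e, dat$g)
  p_perm <- perm_logrank_p(dat$t, dat$e, dat$g, B = 2e4)
  expect_lt(abs(lr$p.value - p_perm), 0.01)

  expect_error(logrank_test(t1, e1, rep("a", 4)), "two strata")
})

test_that("quantile split uses the interpolated quantile convention", {
  qs <- quantile_split(1:10, q = 0.4)
  expect_equal(qs$threshold, 4.6)
  expect_identical(which(qs$labels == "low"), 1:4)

  qs5 <- quantile_split(1:10, q = 0.5)
  expect_equal(sum(qs5$labels == "low"), 5)

  expect_warning(qc <- quantile_split(rep(2, 5)), "single group")
  expect_true(all(qc$labels == "low"))
  expect_error(quantile_split(numeric(0)), "empty")
  expect_error(quantile_split(1:10, q = 1), "strictly between")
})

test_that("maximally selected cutpoint scans all admissible cutoffs", {
  expect_error(optimal_cutpoint(rep(1, 20), rexp(20), rbinom(20, 1, 0.5)),
               "constant")

  # hazard doubles above v*: the chosen cutoff lands in its neighborhood
  dat <- withr::with_seed(7, {
    x <- runif(200)
    rate <- ifelse(x > 0.5, 0.3, 0.05)
    time <- rexp(200, rate)
    cens <- runif(200, 0, 30)
    list(x = x, t = pmin(time, cens), e = as.integer(time <= cens))
  })
  cp <- optimal_cutpoint(dat$x, dat$t, dat$e)
  xs <- sort(dat$x)
  lo <- xs[max(which(xs <= 0.5)) - 1]
  hi <- xs[min(which(xs > 0.5)) + 1]
  expect_gte(cp$cutoff, lo - 0.02)
  expect_lte(cp$cutoff, hi + 0.02)

  # the scan equals brute-force evaluation over every admissible cutoff
  small <- withr::with_seed(8, {
    x <- rnorm(30); t <- rexp(30, 0.2); e <- rbinom(30, 1, 0.7)
    list(x = x, t = t, e = e)
  })
  cp2 <- optimal_cutpoint(small$x, small$t, small$e, minprop = 0.2)
  brute <- vapply(cp2$scan$cutoff, function(cc) {
    sqrt(hand_logrank_chisq(small$t, small$e, small$x > cc))
  }, numeric(1))
  expect_equal(cp2$scan$statistic, brute, tolerance = 1e-8)
  expect_equal(cp2$cutoff, cp2$scan$cutoff[which.max(brute)])
  # every scanned split respects minprop
  props <- vapply(cp2$scan$cutoff, function(cc) mean(small$x <= cc), numeric(1))
  expect_true(all(props >= 0.2 & props <= 0.8))
})

test_that("histoscore is the proportion-times-intensity product with range checks", {
  expect_equal(histoscore(100, 3), 300)
  expect_equal(histoscore(50, 2), 100)
  expect_equal(histoscore(0, 3), 0)
  expect_equal(histoscore(c(10, 20), c(1, 2)), c(10, 40))
  expect_error(histoscore(120, 2), "\\[0, 100\\]")
  expect_error(histoscore(50, 4), "\\[0, 3\\]")
})

test_that("categorical association reproduces exact Fisher probabilities", {
  a <- rep(c("x", "y"), each = 4)
  b <- c("u", "u", "u", "v", "u", "v", "v", "v")  # table (3,1 / 1,3)
  res <- categorical_association(a, b)
  expect_equal(res$p.value, 0.4857143, tolerance = 1e-6)

  # perfectly dependent 2x2 with margins (5,5)/(5,5): p = 2 / C(10,5)
  a2 <- rep(c("x", "y"), each = 5)
  res2 <- categorical_association(a2, a2)
  expect_equal(res2$p.value, 2 / choose(10, 5), tolerance = 1e-10)

  expect_error(categorical_association(a, b[-1]), "different patient sets")

  # independent labels at moderate n: p roughly uniform over seeds
  ps <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      aa <- sample(c("x", "y"), 100, TRUE)
      bb <- sample(c("u", "v"), 100, TRUE)
      categorical_association(aa, bb)$p.value
    })
  }, numeric(1))
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("planted subtype hazards are detected by the log-rank test with power", {
  ps <- vapply(1:15, function(s) {
    tc <- simulate_tissue_cohort(sim_config(seed = s))
    clin <- tc$clinical
    subt <- tc$truth$subtype
    iacp <- names(subt)[subt != "none"]
    idx <- match(iacp, clin$patient_id)
    logrank_test(clin$dfs_months[idx], clin$dfs_event[idx],
                 subt[iacp])$p.value
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.7)
})
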