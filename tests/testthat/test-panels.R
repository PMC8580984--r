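test_that("logistic fitting is symmetric, flags separation, and matches optim", {
  # mirror-symmetric 1-D data: the ML intercept is exactly zero
  X <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$coefficients[1]), 1e-6)
  expect_false(fit$separation)

  # perfectly separated 1-D data
  Xs <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ys <- c(0, 0, 0, 1, 1, 1)
  fits <- fit_logistic(Xs, ys)
  expect_true(fits$separation)

  expect_error(fit_logistic(X, rep(1, 6)), "both classes")
  expect_error(fit_logistic(cbind(X, 0), y), "zero-variance")

  # log-likelihood agrees with an independent gradient-based optimizer
  for (s in 1:3) {
    dat <- withr::with_seed(s, {
      Xr <- matrix(rnorm(60 * 2), 60, 2)
      yr <- rbinom(60, 1, plogis(0.5 + Xr %*% c(1, -0.7)))
      list(X = Xr, y = yr)
    })
    fit <- fit_logistic(dat$X, dat$y)
    opt <- optim(rep(0, 3), logistic_nll, X = dat$X, y = dat$y,
                 method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-6)
  }
})

test_that("ROC/AUC: trapezoid equals pair counting and behaves under transforms", {
  r <- roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)

  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)  # pure ties
  expect_equal(roc_auc(c(3, 1, 2), c(1, 1, 0))$auc, 0.5)     # one concordant, one discordant

  for (s in 1:5) {
    sc <- withr::with_seed(s, rnorm(50))
    lb <- withr::with_seed(s + 50, rbinom(50, 1, 0.4))
    if (length(unique(lb)) < 2) next
    a <- roc_auc(sc, lb)$auc
    # complement property and monotone invariance
    expect_equal(roc_auc(-sc, lb)$auc, 1 - a, tolerance = 1e-12)
    expect_equal(roc_auc(exp(sc), lb)$auc, a, tolerance = 1e-12)
    # curve monotone from (0,0) to (1,1)
    rr <- roc_auc(sc, lb)
    expect_true(all(diff(rr$tpr) >= 0) && all(diff(rr$fpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  sc <- withr::with_seed(3, c(rnorm(40, 1), rnorm(40)))
  lb <- rep(1:0, each = 40)
  a <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("panel evaluation reproduces the closed-form binormal AUC", {
  d <- 2
  spec <- data.frame(metabolite = "marker", benign = 0, AIS = d, MIA = d,
                     IAC = d, stringsAsFactors = FALSE)
  cfg <- sim_config(
    n_plasma_per_stage = c(benign = 200, AIS = 80, MIA = 60, IAC = 60),
    panel_spec = spec, n_plasma_altered = 1, n_plasma_background = 30,
    n_plasma_low = 2, batch_effect_sd = 0, drift_slope = 0,
    detection_threshold = 0, seed = 12)
  pc <- simulate_plasma_cohort(cfg)
  pp <- preprocess_cohort(pc$peaks, pc$samples, ratios = FALSE)
  ev <- evaluate_panel(pp$scaled, "marker", pc$samples,
                       list(negative = "benign",
                            positive = c("AIS", "MIA", "IAC")))
  expect_lt(abs(ev$auc - binormal_auc(d)), 3 * 0.016)  # Hanley-McNeil SE at n=400

  # adding a pure-noise metabolite barely moves the in-sample AUC
  ev2 <- evaluate_panel(pp$scaled, c("marker", "pm_bg_001"), pc$samples,
                        list(negative = "benign",
                             positive = c("AIS", "MIA", "IAC")))
  expect_lt(abs(ev2$auc - ev$auc), 0.05)

  # identical class distributions: AUC near one half
  ev0 <- evaluate_panel(pp$scaled, "pm_bg_002", pc$samples,
                        list(negative = "benign",
                             positive = c("AIS", "MIA", "IAC")))
  expect_lt(abs(ev0$auc - 0.5), 0.1)

  expect_error(evaluate_panel(pp$scaled, "absent_met", pc$samples,
                              list("benign", "AIS")), "absent_met")
})

test_that("panel screening finds the true marker and validates its inputs", {
  cfg <- tiny_config(seed = 9)
  pc <- simulate_plasma_cohort(cfg)
  pp <- preprocess_cohort(pc$peaks, pc$samples, ratios = FALSE)
  candidates <- c("asparagine", "pm_bg_001", "pm_bg_002", "pm_bg_003")
  scr <- screen_panels(candidates, pp$scaled, pc$samples,
                       list(negative = "benign", positive = "AIS"),
                       max_size = 2)
  best1 <- scr$best_per_size[scr$best_per_size$size == 1, ]
  expect_identical(best1$panel, "asparagine")
  # max_size 1 reduces to the single-marker AUC ordering
  scr1 <- screen_panels(candidates, pp$scaled, pc$samples,
                        list(negative = "benign", positive = "AIS"),
                        max_size = 1)
  singles <- scr$ranking[scr$ranking$size == 1, ]
  expect_equal(scr1$ranking$auc, singles$auc[order(-singles$auc)],
               tolerance = 1e-12)

  expect_error(screen_panels(character(0), pp$scaled, pc$samples,
                             list("benign", "AIS")), "empty")
  many <- rownames(pp$scaled)[1:25]
  expect_error(suppressWarnings(
    screen_panels(many, pp$scaled, pc$samples, list("benign", "AIS"))),
    "confirm")
})
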