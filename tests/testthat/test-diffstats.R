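test_that("signed-rank test matches sign-assignment enumeration and handles degeneracies", {
  d <- c(1, 2, 3, 4, 5)
  res <- signed_rank_test(d)
  expect_equal(res$p.value, 0.0625)  # 2 / 2^5, frozen from the enumeration
  expect_equal(res$p.value, enum_signed_rank_p(d))

  # random instances against the enumeration oracle
  for (s in 1:5) {
    d <- withr::with_seed(s, round(rnorm(8), 2))
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    expect_equal(signed_rank_test(d)$p.value, enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }

  # antisymmetric differences sit at the null center
  d <- c(1.5, -1.5, 2.5, -2.5)
  res <- signed_rank_test(d)
  expect_equal(res$p.value, 1)

  # all-zero differences: undefined result flagged, p = 1
  res0 <- signed_rank_test(rep(0, 6))
  expect_true(res0$degenerate)
  expect_equal(res0$p.value, 1)

  # exact and approximate paths agree near the cutover
  d <- withr::with_seed(99, rnorm(25))
  p_exact <- signed_rank_test(d, exact_limit = 25)$p.value
  p_approx <- signed_rank_test(d, exact_limit = 0)$p.value
  expect_lt(abs(p_exact - p_approx), 0.01)
})

test_that("rank-sum test matches rank-assignment enumeration and its asymptotic path", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)  # 2 / C(6,3), frozen from the enumeration
  expect_equal(res$p.value, enum_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))

  expect_equal(rank_sum_test(c(3, 1, 4), c(4, 1, 3))$p.value, 1)

  gaps <- vapply(1:10, function(s) {
    a <- withr::with_seed(s, rnorm(10)); b <- withr::with_seed(s + 20, rnorm(10))
    abs(rank_sum_test(a, b, exact_limit = 10)$p.value -
          rank_sum_test(a, b, exact_limit = 0)$p.value)
  }, numeric(1))
  expect_lt(median(gaps), 0.005)
  expect_lt(max(gaps), 0.02)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis H matches the hand rank formula and a permutation oracle", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # hand computation: rank sums 3, 7, 11 -> H = 12/(6*7) * 89.5 - 21 = 32/7
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$p.value, pchisq(32 / 7, 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))$p.value, 1)

  vals <- withr::with_seed(21, rnorm(30))
  grp <- rep(1:3, each = 10)
  p_chi <- kruskal_wallis(split(vals, grp))$p.value
  p_perm <- perm_kw_p(vals, grp, B = 2e4)
  expect_lt(abs(p_chi - p_perm), 0.01)
})

test_that("BH adjustment equals the naive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  for (s in 1:10) {
    p <- withr::with_seed(s, runif(sample(2:40, 1)))
    adj <- bh_adjust(p)
    expect_equal(adj, naive_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # order preservation
    expect_true(all(diff(adj[order(p)]) > -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("fold change estimators follow their definitions", {
  expect_equal(fold_change(c(2, 4), c(2, 4), mode = "paired_ratio"), 1)
  expect_equal(fold_change(c(2, 16), c(1, 2), mode = "paired_ratio"), 4)
  expect_equal(fold_change(c(2, 4), c(1, 3), mode = "group_mean"), 1.5)
  expect_error(fold_change(c(-1, 2), c(1, 2)), "positive")
})

test_that("differential calling gates strictly and controls the null", {
  # boundary: FC exactly 1.25 with tiny FDR stays non-significant
  set.seed(5)
  n <- 30
  b <- matrix(2^rnorm(2 * n, 10, 0.1), 2, n,
              dimnames = list(c("shifted", "boundary"), paste0("s", 1:n)))
  a <- b
  a["shifted", ] <- b["shifted", ] * 2       # true 2-fold paired effect
  a["boundary", ] <- b["boundary", ] * 1.25  # lands exactly on the gate
  dt <- call_differential(a, b, paired = TRUE)
  expect_identical(dt$direction[dt$metabolite == "shifted"], "up")
  expect_identical(dt$direction[dt$metabolite == "boundary"], "ns")
  expect_equal(dt$fc[dt$metabolite == "boundary"], 1.25, tolerance = 1e-12)

  # under the complete null, the FDR gate flags (almost) nothing and the
  # raw-p rate sits near its nominal level, averaged over seeds
  flagged <- raw_rate <- numeric(20)
  for (s in 1:20) {
    m <- withr::with_seed(1000 + s,
                          matrix(2^rnorm(100 * 24, 10, 0.3), 100, 24))
    rownames(m) <- paste0("m", 1:100)
    dt <- call_differential(m[, 1:12], m[, 13:24], paired = FALSE)
    flagged[s] <- mean(dt$direction != "ns")
    raw_rate[s] <- mean(dt$p < 0.05)
  }
  expect_lt(mean(flagged), 0.05)
  expect_gt(mean(raw_rate), 0.02)
  expect_lt(mean(raw_rate), 0.08)
})

test_that("differential counts are invariant to row order and monotone transforms", {
  set.seed(11)
  a <- matrix(2^rnorm(50 * 10, 10, 0.4), 50, 10,
              dimnames = list(paste0("m", 1:50), paste0("a", 1:10)))
  b <- matrix(2^rnorm(50 * 10, 10, 0.4), 50, 10,
              dimnames = list(paste0("m", 1:50), paste0("b", 1:10)))
  dt1 <- call_differential(a, b)
  perm <- sample(50)
  dt2 <- call_differential(a[perm, ], b[perm, ])
  expect_equal(dt1[order(dt1$metabolite), c("p", "fdr")],
               dt2[order(dt2$metabolite), c("p", "fdr")],
               ignore_attr = TRUE)
  # a strictly monotone transform applied to both groups leaves ranks, and
  # hence p-values, unchanged
  dt3 <- call_differential(a^1.3, b^1.3)
  expect_equal(dt1[order(dt1$metabolite), "p"],
               dt3[order(dt3$metabolite), "p"], tolerance = 1e-12)
})
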