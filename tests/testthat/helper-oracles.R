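# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: brute force, enumeration, closed
# forms, and permutation, at sizes where they are exact or near-exact.

# Benjamini-Hochberg by literal step-up definition, O(m^2).
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    adj[i] <- min(vapply(r:m, function(j) p[ord[j]] * m / j, numeric(1)), 1)
  }
  adj
}

# Two-sided signed-rank p by enumerating all 2^n sign assignments.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  center <- n * (n + 1) / 4
  mean(abs(v_all - center) >= abs(v_obs - center) - 1e-12)
}

# Two-sided rank-sum p by enumerating all C(nA+nB, nA) rank assignments.
enum_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  center <- na * (length(pooled) + 1) / 2
  mean(abs(w_all - center) >= abs(w_obs - center) - 1e-12)
}

# Hypergeometric upper tail P(X >= x) by exhaustive enumeration of draws.
enum_hyper_tail <- function(N, K, n, x) {
  combos <- utils::combn(N, n)
  in_set <- seq_len(K)
  overlaps <- apply(combos, 2, function(draw) sum(draw %in% in_set))
  mean(overlaps >= x)
}

# Two-group log-rank chi-square from the standard O-E formula, written
# directly from the pooled-event-time definition (no survival:: calls).
hand_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2L)
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    e1 <- d_t * n1 / n_t
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  (o_minus_e)^2 / v
}

# Permutation p for the two-group log-rank test, vectorized over
# permutations via precomputed at-risk indicators.
perm_logrank_p <- function(time, event, group, B = 1e5, seed = 42) {
  g <- as.integer(factor(group)) == 1L
  obs <- hand_logrank_chisq(time, event, group)
  times <- sort(unique(time[event == 1]))
  at_risk <- outer(time, times, ">=")              # n x T
  d_t <- vapply(times, function(t) sum(time == t & event == 1), numeric(1))
  ev_at <- outer(time, times, "==") & event == 1   # n x T
  n_t <- colSums(at_risk)
  stat_for <- function(gg) {
    n1 <- colSums(at_risk[gg, , drop = FALSE])
    d1 <- colSums(ev_at[gg, , drop = FALSE])
    e1 <- d_t * n1 / n_t
    v <- sum(ifelse(n_t > 1,
                    d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1),
                    0))
    sum(d1 - e1)^2 / v
  }
  n <- length(time)
  k <- sum(g)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(B), function(i) {
      gg <- logical(n)
      gg[sample.int(n, k)] <- TRUE
      stat_for(gg) >= obs - 1e-12
    }, logical(1)))
  })
  exceed / B
}

# Permutation p for the Kruskal-Wallis test (tie-free data), permuting
# group labels over fixed ranks.
perm_kw_p <- function(values, group, B = 1e5, seed = 42) {
  r <- rank(values)
  g <- factor(group)
  n <- length(values)
  h_of <- function(rr) {
    sums <- tapply(rr, g, sum)
    ns <- tabulate(g)
    12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  }
  obs <- h_of(r)
  withr::with_seed(seed, {
    mean(vapply(seq_len(B), function(i) h_of(sample(r)) >= obs - 1e-12,
                logical(1)))
  })
}

# Closed-form binormal AUC for two equal-variance Gaussian classes at
# separation d (in SD units).
binormal_auc <- function(d) stats::pnorm(d / sqrt(2))

# Negative log-likelihood of a logistic model, for optim-based cross-checks.
logistic_nll <- function(beta, X, y) {
  eta <- cbind(1, X) %*% beta
  -sum(y * eta - log1p(exp(eta)))
}
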