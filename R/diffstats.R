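#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. The exact null distribution is used for
#' `n <= exact_limit` untied absolute differences; otherwise the normal
#' approximation with tie and continuity correction. When every difference
#' is zero the test is undefined and `p = 1` is reported with a flag.
#'
#' @param x,y Paired numeric vectors of equal length, or a single vector of
#'   differences in `x` with `y = NULL`.
#' @param exact_limit Largest n for exact enumeration (default 25).
#' @return List with `statistic` (V, sum of positive signed ranks),
#'   `p.value` (two-sided), `n_used`, `method`, and `degenerate` flag.
#' @export
signed_rank_test <- function(x, y = NULL, exact_limit = 25) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  exact <- n <= exact_limit && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p.value = min(1, res$p.value),
       n_used = n, method = if (exact) "exact" else "normal approximation",
       degenerate = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test for two unpaired groups
#'
#' Exact enumeration for small tie-free groups, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Exact path used when `min(length(a), length(b))` is at
#'   most this (default 10) and the pooled data are tie-free.
#' @return List with `statistic` (W), `p.value` (two-sided), and `method`.
#' @export
rank_sum_test <- function(a, b, exact_limit = 10) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  exact <- min(length(a), length(b)) <= exact_limit &&
    !any(duplicated(c(a, b)))
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = min(1, res$p.value),
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H with a chi-square reference on k - 1 degrees of freedom.
#' A degenerate input in which all values are identical yields H = 0, p = 1.
#'
#' @param groups List of numeric vectors (at least two non-empty).
#' @return List with `statistic` (H), `df`, and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (sum(lengths(groups) > 0L) < 2L) stop("need at least two non-empty groups")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(vals, g)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted values (FDR), order-preserving and capped at 1.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change between two groups of positive values
#'
#' `paired_ratio` mode returns the geometric mean of per-pair ratios
#' `a_i / b_i` (the natural estimator for tumor/NAT designs);
#' `group_mean` mode returns `mean(a) / mean(b)`.
#'
#' @param a,b Positive numeric vectors; equal length in paired mode.
#' @param mode `"paired_ratio"` or `"group_mean"`.
#' @return A single positive number.
#' @export
fold_change <- function(a, b, mode = c("paired_ratio", "group_mean")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (any(a <= 0) || any(b <= 0)) stop("fold change requires positive values")
  if (mode == "paired_ratio") {
    if (length(a) != length(b)) stop("paired mode requires equal lengths")
    exp(mean(log(a / b)))
  } else {
    mean(a) / mean(b)
  }
}

#' Call differential metabolites between two groups
#'
#' Runs a rank test per metabolite (signed-rank when `paired`, rank-sum
#' otherwise), adjusts with Benjamini-Hochberg, computes fold changes, and
#' gates with strict inequalities: `up` iff the significance gate passes and
#' FC > `fc_up`; `down` iff it passes and FC < `fc_down`; `ns` otherwise.
#' The significance gate is the FDR by default; `gate = "raw"` gates on the
#' unadjusted p (used for the plasma stage screen in this study design).
#'
#' @param a_mat,b_mat Metabolite x sample matrices for the two groups, rows
#'   aligned; in paired mode columns of `a_mat` and `b_mat` must align pair
#'   by pair (e.g. tumor and NAT columns ordered by patient).
#' @param comparison Label stored in the output table.
#' @param paired Use the signed-rank test on per-pair values.
#' @param fc_mode Fold-change estimator; defaults to `"paired_ratio"` when
#'   paired, `"group_mean"` otherwise.
#' @param fdr_cut Significance gate (default 0.05).
#' @param fc_up,fc_down Fold-change gates (defaults 1.25 and 0.8).
#' @param gate `"fdr"` (default) or `"raw"`.
#' @return A `data.frame` (one row per metabolite, sorted by FDR then p)
#'   with columns `metabolite`, `comparison`, `test`, `statistic`, `p`,
#'   `fdr`, `fc`, `log2_fc`, `direction`.
#' @export
call_differential <- function(a_mat, b_mat, comparison = "A_vs_B",
                              paired = FALSE, fc_mode = NULL,
                              fdr_cut = 0.05, fc_up = 1.25, fc_down = 0.8,
                              gate = c("fdr", "raw")) {
  gate <- match.arg(gate)
  if (!identical(rownames(a_mat), rownames(b_mat))) {
    stop("row (metabolite) names of the two matrices must align")
  }
  if (paired && ncol(a_mat) != ncol(b_mat)) {
    stop("paired mode requires equal numbers of columns")
  }
  if (is.null(fc_mode)) fc_mode <- if (paired) "paired_ratio" else "group_mean"
  m <- nrow(a_mat)
  stat <- p <- fc <- numeric(m)
  for (i in seq_len(m)) {
    a <- a_mat[i, ]; b <- b_mat[i, ]
    res <- if (paired) signed_rank_test(a, b) else rank_sum_test(a, b)
    stat[i] <- res$statistic
    p[i] <- res$p.value
    fc[i] <- fold_change(a, b, mode = fc_mode)
  }
  fdr <- bh_adjust(p)
  sig <- if (gate == "fdr") fdr else p
  direction <- rep("ns", m)
  direction[sig < fdr_cut & fc > fc_up] <- "up"
  direction[sig < fdr_cut & fc < fc_down] <- "down"
  out <- data.frame(metabolite = rownames(a_mat), comparison = comparison,
                    test = if (paired) "signed_rank" else "rank_sum",
                    statistic = stat, p = p, fdr = fdr, fc = fc,
                    log2_fc = log2(fc), direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$fdr, out$p), , drop = FALSE]
}

#' Kruskal-Wallis screen across sample groups per metabolite
#'
#' Used both for the tissue trajectory selection (gate on FDR) and the
#' plasma stage screen (gate on raw p).
#'
#' @param mat Metabolite x sample matrix.
#' @param group Factor (or coercible) of length `ncol(mat)`.
#' @return Data frame with `metabolite`, `statistic`, `df`, `p`, `fdr`,
#'   sorted by FDR then p.
#' @export
kw_screen <- function(mat, group) {
  group <- factor(group)
  if (length(group) != ncol(mat)) stop("group length must match columns")
  if (nlevels(group) < 2L) stop("need at least two groups")
  res <- apply(mat, 1L, function(v) {
    kw <- kruskal_wallis(split(v, group))
    c(kw$statistic, kw$df, kw$p.value)
  })
  out <- data.frame(metabolite = rownames(mat), statistic = res[1L, ],
                    df = res[2L, ], p = res[3L, ],
                    fdr = bh_adjust(res[3L, ]), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$fdr, out$p), , drop = FALSE]
}
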