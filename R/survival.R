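#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the curve components.
#' Subjects censored at an event time are counted at risk through that
#' event (the standard convention).
#'
#' @param time Follow-up times in months (>= 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("need at least one subject")
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor),
            class = "km_curve")
}

#' Log-rank test across two or more strata
#'
#' Observed-versus-expected chi-square over the pooled event times with
#' `groups - 1` degrees of freedom, via [survival::survdiff()].
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Stratum labels (factor or coercible), all non-empty.
#' @return List with `chisq`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two strata")
  if (any(table(group) == 0L)) stop("empty stratum")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = unname(fit$chisq), df = df,
       p.value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Dichotomize by a sample quantile
#'
#' Threshold is the linear-interpolation sample quantile (type 7, the
#' common statistical-software default, so thresholds are bit-reproducible);
#' values at or below the threshold are labeled `"low"`, above `"high"`.
#'
#' @param values Numeric vector (non-empty).
#' @param q Quantile in (0, 1); default 0.4.
#' @return List with `threshold` and `labels` (character, `"low"`/`"high"`).
#' @export
quantile_split <- function(values, q = 0.4) {
  if (length(values) == 0L) stop("empty values")
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  thr <- unname(stats::quantile(values, probs = q, type = 7, na.rm = FALSE))
  labels <- ifelse(values <= thr, "low", "high")
  if (length(unique(labels)) == 1L) {
    warning("quantile split produced a single group (constant values?)")
  }
  list(threshold = thr, labels = labels)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every candidate cutoff that leaves at least `minprop` of the
#' subjects on each side and returns the cutoff maximizing the standardized
#' two-group log-rank statistic (the square root of the log-rank
#' chi-square). The reported statistic is uncorrected for maximal
#' selection; an approximate correction over the number of candidate
#' cutoffs (Bonferroni over the scan) is returned alongside for reference
#' but plays no role in the selection.
#'
#' @param values Biomarker values aligned with the survival data.
#' @param time,event Follow-up times and event indicators.
#' @param minprop Minimum proportion of subjects per side (default 0.1).
#' @return List with `cutoff`, `statistic` (standardized log-rank),
#'   `p_uncorrected`, `p_bonferroni`, and `scan` (data frame over all
#'   admissible cutoffs).
#' @export
optimal_cutpoint <- function(values, time, event, minprop = 0.1) {
  n <- length(values)
  stopifnot(length(time) == n, length(event) == n)
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must lie in (0, 0.5)")
  cand <- sort(unique(values))
  cand <- utils::head(cand, -1)  # a cutoff at the maximum leaves one side empty
  admissible <- vapply(cand, function(cc) {
    n_low <- sum(values <= cc)
    n_low >= minprop * n && (n - n_low) >= minprop * n
  }, logical(1))
  cand <- cand[admissible]
  if (length(cand) == 0L) {
    stop("no cutoff satisfies minprop = ", minprop,
         " (constant or near-constant biomarker)")
  }
  stat <- vapply(cand, function(cc) {
    g <- values > cc
    sqrt(logrank_test(time, event, g)$chisq)
  }, numeric(1))
  best <- which.max(stat)
  p_unc <- stats::pchisq(stat[best]^2, 1, lower.tail = FALSE)
  list(cutoff = cand[best], statistic = stat[best],
       p_uncorrected = p_unc,
       p_bonferroni = min(1, p_unc * length(cand)),
       scan = data.frame(cutoff = cand, statistic = stat))
}

#' Immunohistochemistry histoscore
#'
#' Product of the positive-cell proportion (0-100, in percent) and the mean
#' staining intensity (0-3). The formula's actual range is 0-300 even
#' though such scores are conventionally quoted as 1-300; the product is
#' implemented as stated and a zero proportion or intensity yields 0.
#'
#' @param proportion Percent positive tumor cells, in `[0, 100]`.
#' @param intensity Mean staining intensity, in `[0, 3]`.
#' @return The score(s), in `[0, 300]`.
#' @export
histoscore <- function(proportion, intensity) {
  if (any(proportion < 0 | proportion > 100, na.rm = TRUE)) {
    stop("proportion must lie in [0, 100]")
  }
  if (any(intensity < 0 | intensity > 3, na.rm = TRUE)) {
    stop("intensity must lie in [0, 3]")
  }
  proportion * intensity
}

#' Exact test of association between two categorical labelings
#'
#' Fisher's exact test on the r x c contingency table of two labelings of
#' the same patients. Small tables use exact enumeration; larger tables
#' fall back to a seeded Monte-Carlo p (at least 1e5 draws).
#'
#' @param a,b Label vectors over the same patients (equal length).
#' @param mc_draws Monte-Carlo draws for large tables (default 1e5).
#' @param seed Seed for the Monte-Carlo path.
#' @return List with `p.value`, `table`, and `method`.
#' @export
categorical_association <- function(a, b, mc_draws = 1e5, seed = 1) {
  if (length(a) != length(b)) stop("labelings cover different patient sets")
  tab <- table(a, b)
  res <- tryCatch(
    list(p = stats::fisher.test(tab, workspace = 2e7)$p.value,
         method = "exact"),
    error = function(e) {
      p <- with_local_seed(seed, {
        stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value
      })
      list(p = p, method = sprintf("monte-carlo (B = %d)", mc_draws))
    })
  list(p.value = res$p, table = tab, method = res$method)
}
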