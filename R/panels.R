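#' Fit a binary logistic biomarker panel
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (tolerance 1e-8, at most 100 iterations). Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' 0/1 or non-convergence) and flagged; the fit at the iteration cap is
#' still returned.
#'
#' @param X Sample x feature numeric matrix (typically log10 abundances).
#' @param y Binary labels (logical, 0/1, or two-level factor); both classes
#'   must be present.
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `logistic_panel`: `coefficients` (intercept
#'   first), `converged`, `separation`, `log_likelihood`, `n_per_class`,
#'   `fitted`, `features`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(as.logical(y) | y == 1)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- fit$fitted.values
  eps <- .Machine$double.eps
  ll <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  structure(list(coefficients = fit$coefficients,
                 converged = fit$converged,
                 separation = sep_warning || !fit$converged,
                 log_likelihood = ll,
                 n_per_class = c(n0 = sum(y == 0), n1 = sum(y == 1)),
                 fitted = mu,
                 features = colnames(X)),
            class = "logistic_panel")
}

#' ROC curve and AUC
#'
#' The curve is swept over all distinct score thresholds (higher score means
#' more positive). The AUC is computed two ways — trapezoid integration of
#' the curve and Mann-Whitney concordant-pair counting with half credit for
#' ties — and the two must agree to 1e-12, which is asserted internally.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (positives = 1/TRUE/second factor level).
#' @return Object of class `roc_result`: `thresholds`, `tpr`, `fpr`
#'   (non-decreasing from (0,0) to (1,1)), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(as.logical(labels) | labels == 1)
  if (length(scores) != length(labels)) stop("lengths differ")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied thresholds
  last_of_run <- c(diff(s) != 0, TRUE)
  tp <- cumsum(l)[last_of_run]
  fp <- cumsum(1 - l)[last_of_run]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  r <- rank(scores)
  auc_pairs <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  stopifnot(abs(auc_trap - auc_pairs) < 1e-12)
  structure(list(thresholds = c(Inf, s[last_of_run]), tpr = tpr, fpr = fpr,
                 auc = auc_trap),
            class = "roc_result")
}

#' Fit and score a metabolite panel for a stage contrast
#'
#' Builds the design matrix of log10 abundances for the named metabolites,
#' fits the logistic panel for the given two-sided stage contrast, and
#' scores the in-sample fitted probabilities with [roc_auc()]
#' (resubstitution AUC, the headline metric of this workflow).
#'
#' @param matrix Metabolite x sample abundance matrix (strictly positive).
#' @param metabolites Panel member ids; all must be present in `matrix`.
#' @param samples Sample table.
#' @param contrast List of two character vectors of stages,
#'   `list(negative = ..., positive = ...)`; e.g.
#'   `list(negative = "benign", positive = c("AIS", "MIA", "IAC"))`.
#' @param log10_features Transform features to log10 (default TRUE).
#' @param cv_folds Optional stratified k-fold cross-validated AUC computed
#'   alongside (never substituted for the in-sample AUC); `NULL` to skip.
#' @param seed Seed for the cross-validation folds.
#' @return List with `panel` ([fit_logistic()] result), `roc`
#'   ([roc_auc()] result), `auc`, `cv_auc` (or `NA`), `y`, and `samples_used`.
#' @export
evaluate_panel <- function(matrix, metabolites, samples, contrast,
                           log10_features = TRUE, cv_folds = NULL, seed = 1) {
  missing_m <- setdiff(metabolites, rownames(matrix))
  if (length(missing_m) > 0L) {
    stop("metabolite(s) absent from matrix: ",
         paste(missing_m, collapse = ", "))
  }
  samples <- as.data.frame(samples)
  test <- samples[samples$role != "QC" & samples$sample_id %in% colnames(matrix), ,
                  drop = FALSE]
  neg <- test$sample_id[test$stage %in% contrast[[1L]]]
  pos <- test$sample_id[test$stage %in% contrast[[2L]]]
  if (length(neg) == 0L || length(pos) == 0L) {
    stop("both contrast groups must be non-empty")
  }
  cols <- c(neg, pos)
  y <- c(rep(0, length(neg)), rep(1, length(pos)))
  X <- t(matrix[metabolites, cols, drop = FALSE])
  if (log10_features) {
    if (any(X <= 0)) stop("log10 features require strictly positive abundances")
    X <- log10(X)
  }
  panel <- fit_logistic(X, y)
  roc <- roc_auc(panel$fitted, y)
  cv_auc <- NA_real_
  if (!is.null(cv_folds)) {
    folds <- with_local_seed(seed, {
      f <- integer(length(y))
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
      }
      f
    })
    hold_scores <- numeric(length(y))
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) stop("fold lost a class; reduce cv_folds")
      fit_k <- fit_logistic(X[tr, , drop = FALSE], y[tr])
      eta <- cbind(1, X[!tr, , drop = FALSE]) %*% fit_k$coefficients
      hold_scores[!tr] <- stats::plogis(eta)
    }
    cv_auc <- roc_auc(hold_scores, y)$auc
  }
  list(panel = panel, roc = roc, auc = roc$auc, cv_auc = cv_auc, y = y,
       samples_used = cols)
}

#' Exhaustive screen of metabolite panels
#'
#' Evaluates every subset of the candidate metabolites up to `max_size`
#' members, ranked by in-sample AUC, reporting the best panel per size.
#' With more than 20 candidates and `max_size` 4 the subset count explodes;
#' the screen then refuses to run unless `confirm = TRUE`.
#'
#' @param candidates Character vector of candidate metabolite ids (e.g. the
#'   differential metabolites for the contrast); non-empty.
#' @param matrix,samples,contrast As in [evaluate_panel()].
#' @param max_size Largest panel size (default 4).
#' @param confirm Set `TRUE` to allow large screens (> 20 candidates).
#' @param ... Passed to [evaluate_panel()].
#' @return List with `ranking` (data frame of all evaluated panels, sorted
#'   by AUC) and `best_per_size`.
#' @export
screen_panels <- function(candidates, matrix, samples, contrast,
                          max_size = 4, confirm = FALSE, ...) {
  candidates <- unique(candidates)
  if (length(candidates) == 0L) stop("empty candidate list")
  if (length(candidates) > 20L && !confirm) {
    warning("more than 20 candidates: ",
            choose(length(candidates), min(max_size, length(candidates))),
            "+ subsets at max_size ", max_size)
    stop("large screen refused; rerun with confirm = TRUE")
  }
  sizes <- seq_len(min(max_size, length(candidates)))
  rows <- list()
  for (s in sizes) {
    combos <- utils::combn(candidates, s, simplify = FALSE)
    for (cmb in combos) {
      ev <- evaluate_panel(matrix, cmb, samples, contrast, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, panel = paste(cmb, collapse = "+"), auc = ev$auc,
        separation = ev$panel$separation, stringsAsFactors = FALSE)
    }
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$auc, ranking$size), , drop = FALSE]
  rownames(ranking) <- NULL
  best <- do.call(rbind, lapply(split(ranking, ranking$size),
                                function(d) d[which.max(d$auc), , drop = FALSE]))
  rownames(best) <- NULL
  list(ranking = ranking, best_per_size = best)
}
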