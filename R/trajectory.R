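#' Build per-stage mean log2 trajectory profiles
#'
#' For each selected metabolite, the mean over patients of the log2
#' tumor/NAT relative abundance is computed per histological stage, giving
#' one metabolite x stage profile matrix in the fixed progression order.
#'
#' @param ratios Metabolite x patient tumor/NAT ratio matrix.
#' @param samples Sample table (stage read from each patient's tumor row).
#' @param metabolites Character vector of selected metabolites (e.g. the
#'   Kruskal-Wallis FDR < 0.1 hits); must be non-empty.
#' @param stages Stage order; default `c("AAH", "AIS", "MIA", "IAC")`.
#' @return Metabolite x stage matrix of mean log2 relative abundance.
#' @export
build_stage_profiles <- function(ratios, samples, metabolites,
                                 stages = c("AAH", "AIS", "MIA", "IAC")) {
  if (length(metabolites) == 0L) stop("empty metabolite selection")
  missing_m <- setdiff(metabolites, rownames(ratios))
  if (length(missing_m) > 0L) {
    stop("metabolite(s) absent from ratio matrix: ",
         paste(missing_m, collapse = ", "))
  }
  samples <- as.data.frame(samples)
  tum <- samples[samples$role == "tumor", , drop = FALSE]
  stage_of <- stats::setNames(as.character(tum$stage), tum$patient_id)
  pat <- colnames(ratios)
  st <- stage_of[pat]
  prof <- sapply(stages, function(s) {
    cols <- pat[!is.na(st) & st == s]
    if (length(cols) == 0L) stop("no patients in stage ", s)
    rowMeans(log2(ratios[metabolites, cols, drop = FALSE]))
  })
  prof <- matrix(prof, nrow = length(metabolites),
                 dimnames = list(metabolites, stages))
  prof
}

#' Standardize trajectory profiles to shape
#'
#' Rows are centered to mean 0 and scaled to SD 1 so Euclidean distance
#' compares trajectory shapes rather than magnitudes. Constant rows cannot
#' be standardized; they are dropped and reported via the `"dropped"`
#' attribute.
#'
#' @param profiles Metabolite x stage profile matrix (at least 2 stages).
#' @return Standardized matrix with attribute `dropped` naming removed
#'   constant rows.
#' @export
standardize_profiles <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least two stages")
  sds <- apply(profiles, 1L, stats::sd)
  constant <- sds == 0 | is.na(sds)
  out <- profiles[!constant, , drop = FALSE]
  out <- t(scale(t(out)))
  attr(out, "dropped") <- rownames(profiles)[constant]
  out
}

#' Fuzzy c-means clustering
#'
#' Standard alternating optimization: memberships
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m-1)}} followed by
#' membership^m-weighted center updates, until the objective
#' \eqn{J = \sum_{i,k} u_{ik}^m d_{ik}^2} changes by less than `tol`.
#' A point coincident with a center receives full membership there.
#' Centers are initialized as `c` distinct rows of `X` drawn with the given
#' seed, so runs are reproducible.
#'
#' @param X Numeric matrix (items x features), typically standardized
#'   trajectory profiles.
#' @param c Number of clusters (>= 2, <= nrow(X)).
#' @param m Fuzzifier (> 1, default 2).
#' @param tol Convergence tolerance on the objective (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @param seed Integer seed for center initialization.
#' @param nstart Number of seeded random initializations; the run with the
#'   lowest final objective is kept (default 10).
#' @return Object of class `fcm_model`: `centers` (c x features),
#'   `membership` (items x c, rows sum to 1), `objective` (final value),
#'   `objective_trace`, `iterations`, `c`, `m`, `seed`.
#' @export
fuzzy_cmeans <- function(X, c, m = 2, tol = 1e-8, max_iter = 500, seed = 1,
                         nstart = 10) {
  best <- NULL
  for (s in seq_len(nstart)) {
    run <- fcm_single(X, c, m, tol, max_iter, derive_seed(seed, 100L + s))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  best$seed <- seed
  best
}

fcm_single <- function(X, c, m, tol, max_iter, seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (c < 2L) stop("c must be at least 2")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (c > n) stop("c exceeds the number of rows")
  uniq <- X[!duplicated(X), , drop = FALSE]
  if (nrow(uniq) < c) stop("fewer than c distinct rows")
  centers <- with_local_seed(seed, {
    uniq[sample.int(nrow(uniq), c), , drop = FALSE]
  })
  exponent <- 2 / (m - 1)
  trace <- numeric(0)
  obj_prev <- Inf
  iter <- 0L
  membership <- NULL
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    membership <- matrix(0, n, c)
    zero <- d2 <= .Machine$double.eps
    has_zero <- rowSums(zero) > 0L
    if (any(has_zero)) {
      membership[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    if (any(!has_zero)) {
      w <- d2[!has_zero, , drop = FALSE]^(-exponent / 2)
      membership[!has_zero, ] <- w / rowSums(w)
    }
    um <- membership^m
    obj <- sum(um * d2)
    trace <- c(trace, obj)
    if (abs(obj_prev - obj) < tol || iter >= max_iter) break
    obj_prev <- obj
    centers <- (t(um) %*% X) / colSums(um)
  }
  rownames(membership) <- rownames(X)
  colnames(membership) <- paste0("cluster_", seq_len(c))
  rownames(centers) <- colnames(membership)
  structure(list(centers = centers, membership = membership,
                 objective = trace[length(trace)], objective_trace = trace,
                 iterations = iter, c = c, m = m, seed = seed),
            class = "fcm_model")
}

#' Hard cluster assignment from fuzzy memberships
#'
#' Argmax membership per item; items whose maximum membership falls below
#' `min_membership` are left unassigned (`NA`). Ties go to the lowest
#' cluster index and are reported via the `"ties"` attribute.
#'
#' @param model A fitted [fuzzy_cmeans()] model.
#' @param min_membership Minimum membership to assign (default 0).
#' @return Named integer vector of cluster indices (`NA` = unassigned) with
#'   attribute `ties`.
#' @export
assign_clusters <- function(model, min_membership = 0) {
  u <- model$membership
  best <- apply(u, 1L, max)
  lab <- apply(u, 1L, which.max)
  ties <- rownames(u)[apply(u, 1L, function(r) sum(r == max(r)) > 1L)]
  lab[best < min_membership] <- NA_integer_
  structure(stats::setNames(as.integer(lab), rownames(u)), ties = ties)
}

#' Silhouette-over-c diagnostic for fuzzy c-means
#'
#' Mean silhouette width of the hard assignments for each candidate cluster
#' count. Emitted as a diagnostic only; it never auto-selects `c`.
#'
#' @param X Item x feature matrix (standardized profiles).
#' @param c_range Candidate cluster counts (default 2:8).
#' @param ... Passed to [fuzzy_cmeans()].
#' @return Data frame with `c` and `mean_silhouette`.
#' @export
silhouette_over_c <- function(X, c_range = 2:8, ...) {
  d <- as.matrix(stats::dist(X))
  res <- vapply(c_range, function(cc) {
    lab <- assign_clusters(fuzzy_cmeans(X, c = cc, ...))
    sil <- vapply(seq_len(nrow(X)), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      others <- setdiff(unique(lab), lab[i])
      b <- min(vapply(others, function(o) mean(d[i, lab == o]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
  }, numeric(1))
  data.frame(c = c_range, mean_silhouette = res)
}
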