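#' Resampling consensus clustering of patients
#'
#' For each of `reps` repetitions a fraction `p_item` of the patients is
#' subsampled without replacement and partitioned into k groups, for every k
#' in `k_range`, by k-means over correlation geometry: rows are centered and
#' scaled to unit norm so that squared Euclidean distance is monotone in
#' 1 - Pearson correlation ("k-means with Pearson distance"). The consensus
#' matrix entry M_k[i, j] is the fraction of co-samplings of i and j in
#' which they landed in the same cluster. Pairs never co-sampled (rare at
#' the default reps and p_item) get consensus 0 with a warning.
#'
#' @param X Patient x feature numeric matrix (e.g. z-scored log2 tumor/NAT
#'   ratios, one row per patient).
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param reps Resampling repetitions (default 1000).
#' @param p_item Patient subsample fraction (default 0.8).
#' @param seed Integer seed; the whole resampling schedule derives from it.
#' @param nstart Random starts per k-means run (default 1; the resampling
#'   itself averages over starts).
#' @return Object of class `consensus_model` with `consensus` (named list of
#'   patient x patient matrices, symmetric, unit diagonal), `k_range`,
#'   `reps`, `p_item`, `seed`, and `n`.
#' @export
consensus_cluster <- function(X, k_range = 2:6, reps = 1000, p_item = 0.8,
                              seed = 1, nstart = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("item_", seq_len(n))
  if (any(k_range < 2L)) stop("k_range entries must be at least 2")
  if (n < max(k_range)) stop("fewer patients than the largest k")
  if (reps < 1L) stop("reps must be at least 1")
  if (p_item <= 0 || p_item > 1) stop("p_item must lie in (0, 1]")
  n_sub <- ceiling(p_item * n)
  if (n_sub < max(k_range)) stop("subsample smaller than the largest k")
  Xn <- pearson_geometry(X)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)
  with_local_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, n_sub))
      ind <- matrix(0, n, 1); ind[idx] <- 1
      co_sample <- co_sample + ind %*% t(ind)
      for (ki in seq_along(k_range)) {
        k <- k_range[ki]
        km <- stats::kmeans(Xn[idx, , drop = FALSE], centers = k,
                            nstart = nstart, iter.max = 100)
        for (cl in seq_len(k)) {
          v <- matrix(0, n, 1); v[idx[km$cluster == cl]] <- 1
          co_cluster[[ki]] <- co_cluster[[ki]] + v %*% t(v)
        }
      }
    }
  })
  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never)) {
    warning(sum(never), " patient pair(s) were never co-sampled; ",
            "their consensus is reported as 0")
  }
  consensus <- lapply(co_cluster, function(cc) {
    m <- cc / pmax(co_sample, 1)
    m[co_sample == 0] <- 0
    diag(m) <- 1
    dimnames(m) <- list(rownames(X), rownames(X))
    m
  })
  structure(list(consensus = consensus, k_range = k_range, reps = reps,
                 p_item = p_item, seed = seed, n = n),
            class = "consensus_model")
}

# Center rows and scale to unit norm so squared Euclidean distance equals
# 2 * (1 - Pearson correlation) between rows.
pearson_geometry <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  if (any(nrm == 0)) {
    stop("constant patient profile(s): ",
         paste(rownames(X)[nrm == 0], collapse = ", "))
  }
  Xc / nrm
}

#' Consensus CDF, area, and delta-area curves
#'
#' The empirical CDF of the upper-triangle consensus values is evaluated for
#' each k; A(k) is its area by the trapezoid rule on a fixed grid, and the
#' delta-area curve is Delta(2) = A(2), Delta(k) = (A(k) - A(k-1)) / A(k-1)
#' for k > 2 — the standard stability read-out for choosing k.
#'
#' @param model A [consensus_cluster()] result.
#' @param grid Evaluation grid on `[0, 1]` (default 101 points).
#' @return List with `cdf` (grid x k matrix), `grid`, `area` (named A(k)),
#'   and `delta` (named Delta(k)).
#' @export
consensus_cdf_and_delta <- function(model, grid = seq(0, 1, length.out = 101)) {
  ks <- model$k_range
  cdf <- sapply(ks, function(k) {
    m <- model$consensus[[as.character(k)]]
    vals <- m[upper.tri(m)]
    stats::ecdf(vals)(grid)
  })
  colnames(cdf) <- as.character(ks)
  area <- apply(cdf, 2L, function(y) {
    sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  })
  delta <- numeric(length(ks))
  names(delta) <- as.character(ks)
  delta[1L] <- area[1L]
  if (length(ks) > 1L) {
    for (i in 2L:length(ks)) {
      delta[i] <- (area[i] - area[i - 1L]) / area[i - 1L]
    }
  }
  list(cdf = cdf, grid = grid, area = area, delta = delta)
}

#' Choose the number of consensus clusters
#'
#' Makes the usual visual two-factor read-out explicit. Candidate ks are
#' those whose relative delta-area exceeds `delta_threshold` (the delta
#' plot); among them the largest k whose mean within-cluster consensus
#' reaches `consensus_threshold` is chosen (the stability factor). The
#' stability bar matters because the delta-area alone keeps growing when a
#' true cluster is force-split: the split adds area while within-cluster
#' consensus collapses. If no candidate reaches the bar the delta-only
#' choice is returned with `stable = FALSE`, flagging null-like structure.
#'
#' @param model A [consensus_cluster()] result.
#' @param delta_threshold Relative delta-area threshold (default 0.1).
#' @param consensus_threshold Minimum mean within-cluster consensus for a
#'   stable k (default 0.9).
#' @return List with `chosen_k`, `stable`, `delta`, `area`, and
#'   `within_consensus` (data frame of k and mean within-cluster consensus).
#' @export
select_k <- function(model, delta_threshold = 0.1, consensus_threshold = 0.9) {
  cd <- consensus_cdf_and_delta(model)
  ks <- model$k_range
  within <- vapply(ks, function(k) {
    lab <- assign_subtypes(model, k)
    m <- model$consensus[[as.character(k)]]
    vals <- vapply(unique(lab), function(cl) {
      idx <- which(lab == cl)
      if (length(idx) < 2L) return(1)
      sub <- m[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  pass_delta <- cd$delta > delta_threshold
  pass_both <- pass_delta & within >= consensus_threshold
  stable <- any(pass_both)
  chosen <- if (stable) {
    max(ks[pass_both])
  } else if (any(pass_delta)) {
    max(ks[pass_delta])
  } else {
    min(ks)
  }
  list(chosen_k = chosen, stable = stable, delta = cd$delta, area = cd$area,
       within_consensus = data.frame(k = ks, mean_within_consensus = within))
}

#' Final subtype assignment from a consensus matrix
#'
#' Average-linkage hierarchical clustering on 1 - M_k, cut at k; cluster
#' labels are renumbered by descending size so subtype 1 is always the
#' largest.
#'
#' @param model A [consensus_cluster()] result.
#' @param k Number of subtypes; must lie in the model's `k_range`.
#' @return Named integer vector of subtype labels (1 = largest).
#' @export
assign_subtypes <- function(model, k) {
  if (!k %in% model$k_range) {
    stop("k = ", k, " is outside the model's k_range")
  }
  m <- model$consensus[[as.character(k)]]
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  lab <- stats::cutree(hc, k = k)
  sizes <- sort(table(lab), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- relabel[as.character(lab)]
  stats::setNames(as.integer(out), names(lab))
}
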