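#' Metabolite-set over-representation analysis
#'
#' One-sided hypergeometric (Fisher) test per set: with N background
#' metabolites, K of them in the set, and n differential, the p-value is
#' P(X >= overlap). BH adjustment is applied across all tested sets. Fold
#' enrichment is (overlap / n) / (K / N); the mean log2 fold change of the
#' overlapping metabolites is reported when per-metabolite log2 fold
#' changes are supplied.
#'
#' @param diff_set Character vector of differential metabolite ids; must be
#'   a subset of `background`.
#' @param background Character vector of background metabolite ids (the
#'   tested universe).
#' @param sets Named list of metabolite sets (see [read_gmt()]).
#' @param log2_fc Optional named numeric vector of per-metabolite log2 fold
#'   changes used for the `mean_log2_fc` column.
#' @param fdr_cut Significance gate used for the `significant` column
#'   (default 0.05).
#' @param min_set_size Sets with fewer background members are skipped and
#'   reported (default 2).
#' @return Data frame sorted by FDR with one row per tested set and an
#'   attribute `skipped` naming sets below `min_set_size`.
#' @export
enrich <- function(diff_set, background, sets, log2_fc = NULL,
                   fdr_cut = 0.05, min_set_size = 2) {
  background <- unique(background)
  diff_set <- unique(diff_set)
  if (length(background) == 0L) stop("background is empty")
  outside <- setdiff(diff_set, background)
  if (length(outside) > 0L) {
    stop("differential metabolite(s) absent from background: ",
         paste(outside, collapse = ", "))
  }
  N <- length(background)
  n <- length(diff_set)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    hit <- intersect(members, diff_set)
    x <- length(hit)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n == 0L) 0 else (x / n) / (K / N)
    mfc <- if (!is.null(log2_fc) && x > 0) mean(log2_fc[hit], na.rm = TRUE)
           else NA_real_
    desc <- attr(sets, "description")
    data.frame(set_id = id,
               set_name = if (!is.null(desc)) unname(desc[id]) else id,
               overlap = x, set_size = K, background_size = N,
               differential_count = n, p = p, fold_enrichment = fe,
               mean_log2_fc = mfc, stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(rows, is.null, logical(1))]
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(set_id = character(0), set_name = character(0),
                      overlap = integer(0), set_size = integer(0),
                      background_size = integer(0),
                      differential_count = integer(0), p = numeric(0),
                      fold_enrichment = numeric(0), mean_log2_fc = numeric(0),
                      fdr = numeric(0), significant = logical(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cut
  out <- out[order(out$fdr, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
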