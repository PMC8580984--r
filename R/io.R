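#' Read a peak-area matrix from delimited text
#'
#' Reads a wide metabolite-by-sample table of LC-MS peak areas. Supplementary
#' exports in metabolomics come in both orientations, so an orientation flag
#' normalizes the result to metabolites in rows and samples in columns.
#' Missing measurements (empty cells, `"NA"`, `"NaN"`, and optionally literal
#' zeros) become `NA`.
#'
#' @param path Path to a delimited text file with one header row and the
#'   feature/sample ids in the first column.
#' @param orientation `"metabolites_in_rows"` (default) or
#'   `"samples_in_rows"`; the latter is transposed after reading.
#' @param sep Field delimiter; `","` by default, use `"\t"` for TSV.
#' @param missing_values Character vector of cell values treated as missing.
#' @param zero_as_missing If `TRUE`, numeric zeros are also recorded missing
#'   (some peak-integration exports write 0 for undetected transitions).
#' @return A numeric matrix (metabolites x samples) with `NA` for missing
#'   peak areas.
#' @export
read_peak_matrix <- function(path,
                             orientation = c("metabolites_in_rows", "samples_in_rows"),
                             sep = ",",
                             missing_values = c("", "NA", "NaN"),
                             zero_as_missing = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("peak matrix file must have an id column and at least one data column")
  }
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicated row id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  cols <- colnames(raw)[-1L]
  dupc <- cols[duplicated(cols)]
  if (length(dupc) > 0L) {
    stop("duplicated column id(s) in ", path, ": ", paste(unique(dupc), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- raw[[j + 1L]]
    is_missing <- cell %in% missing_values
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric value %s at row '%s', column '%s'",
                   dQuote(cell[i]), ids[i], cols[j]))
    }
    val[is_missing] <- NA_real_
    mat[, j] <- val
  }
  if (zero_as_missing) mat[!is.na(mat) & mat == 0] <- NA_real_
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative peak area at metabolite '%s', sample '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  if (orientation == "samples_in_rows") mat <- t(mat)
  mat
}

#' Read metabolite sets from a GMT file
#'
#' Standard GMT: one set per line, `set id <TAB> description <TAB> members...`.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (member ids), with a
#'   `description` attribute carrying the per-set description, in file order.
#' @examples
#' gmt <- system.file("extdata", "synthetic_pathways.gmt", package = "luadmet")
#' sets <- read_gmt(gmt)
#' names(sets)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    stop("malformed GMT line ", which(nfield < 3L)[1L],
         ": expected at least 3 tab-separated fields")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)][nzchar(p[-c(1L, 2L)])]))
  if (any(lengths(sets) == 0L)) {
    stop("set '", ids[which(lengths(sets) == 0L)[1L]], "' has no members")
  }
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), ids)
  sets
}

#' Write a result table as UTF-8 CSV
#'
#' Deterministic column order (as supplied), UTF-8 encoding, round-trippable
#' with [read_results()].
#'
#' @param table A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.csv(table, con, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}

#' Validate a sample metadata table
#'
#' Checks the invariants of the per-sample annotation table that drives
#' pairing and QC anchoring: unique sample ids, QC rows carry no patient id,
#' and in a tissue cohort every tumor sample has exactly one NAT sample from
#' the same patient.
#'
#' @param samples Data frame with columns `sample_id`, `patient_id`,
#'   `cohort` (`tissue`/`plasma`), `role` (`tumor`/`NAT`/`plasma`/`QC`),
#'   `stage` (`AAH`/`AIS`/`MIA`/`IAC`/`benign`/`none`), `batch`,
#'   `injection_order`.
#' @return `samples`, invisibly, after validation.
#' @export
validate_sample_table <- function(samples) {
  required <- c("sample_id", "patient_id", "cohort", "role", "stage",
                "batch", "injection_order")
  missing_cols <- setdiff(required, colnames(samples))
  if (length(missing_cols) > 0L) {
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  qc <- samples$role == "QC"
  if (any(qc & !is.na(samples$patient_id) & nzchar(samples$patient_id))) {
    stop("QC samples must not carry a patient id")
  }
  tissue <- samples[samples$cohort == "tissue" & !qc, , drop = FALSE]
  if (nrow(tissue) > 0L) {
    tum <- tissue$patient_id[tissue$role == "tumor"]
    nat <- tissue$patient_id[tissue$role == "NAT"]
    if (anyDuplicated(tum) || anyDuplicated(nat)) {
      stop("tissue cohort has a patient with replicate tumor or NAT samples")
    }
  }
  invisible(samples)
}

#' Write metabolite sets to a GMT file
#'
#' Inverse of [read_gmt()]: one set per line,
#' `set id <TAB> description <TAB> members...`.
#'
#' @param sets Named list of character vectors, optionally with a
#'   `description` attribute.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(desc[id]), sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
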