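# Shared setup for the numbered analysis drivers. Each driver is a thin
# narrative over the package functions: it loads its inputs from
# results/analysis/, performs one stage, reports what it found, and writes
# its tables back. Run the scripts in order from the repository root:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_preprocess.R
#   ...
#
# A global seed can be supplied as the first command-line argument of
# 01_simulate.R; later stages derive their seeds from the files on disk.

library(luadmet)

adir <- file.path("results", "analysis")
dir.create(adir, showWarnings = FALSE, recursive = TRUE)

apath <- function(...) file.path(adir, ...)

write_matrix_csv <- function(mat, path) {
  write_results(data.frame(metabolite = rownames(mat), mat,
                           check.names = FALSE), path)
}

read_matrix_csv <- function(path) {
  tab <- read_results(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
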