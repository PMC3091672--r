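#' Construct a TagCountMatrix
#'
#' @param counts integer matrix of tag counts with 22-nt tag sequences as row
#'   names and library names as column names.
#' @param rowData optional \code{DataFrame} of per-tag metadata.
#' @return a \linkS4class{TagCountMatrix}.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 5L), 2,
#'             dimnames = list(c("ACGTACGTACGTACGTACGTAC",
#'                               "TTGCATTGCATTGCATTGCATT"), c("C2h", "LowCa2h")))
#' tagCountMatrix(m)
#' @export
tagCountMatrix <- function(counts, rowData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  args <- list(assays = list(counts = counts))
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("TagCountMatrix", se)
}

#' Read / write a tag-count matrix as TSV
#'
#' The on-disk format is a tab-separated table with a `tag` column followed by
#' one integer column per library; comment lines starting with `#` carry
#' provenance (package version and seed) and are ignored on reading.
#'
#' @param x a \linkS4class{TagCountMatrix}.
#' @param file path of the TSV file.
#' @param comments character vector of provenance lines to embed (without the
#'   leading `# `).
#' @return `readTagCountMatrix()` returns a \linkS4class{TagCountMatrix};
#'   `writeTagCountMatrix()` returns `file` invisibly.
#' @export
writeTagCountMatrix <- function(x, file, comments = character(0)) {
  df <- data.frame(tag = tagSequences(x), tagCounts(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, file, comments)
}

#' @rdname writeTagCountMatrix
#' @export
readTagCountMatrix <- function(file) {
  df <- read.delim(file, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$tag
  tagCountMatrix(m)
}

# shared TSV writer with provenance header
writeTsv <- function(df, file, comments = character(0)) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}
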