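#' Demultiplex ditag reads and apply quality-control filters
#'
#' Assigns each read to a library by exact match of the 5' linker (with the
#' reverse-complemented linker expected at the 3' end) and applies the
#' stringent ditag QC filters: reads with a truncated or unidentifiable
#' linker are flagged \code{incomplete_linker}; reads with a linker copy
#' inside the ditag region \code{internal_linker}; reads with a non-ACGT base
#' in the ditag region \code{ambiguous_base}; and, within each library, every
#' repeat of an already-seen read sequence \code{duplicate} (the first
#' occurrence is kept).  Only \code{pass} reads enter tag counting.
#'
#' @param reads a character vector of read sequences (optionally named with
#'   read ids), a \code{DNAStringSet}, or the reads \code{DataFrame} produced
#'   by [generateDitagReads()].
#' @param linkers named character vector, library name -> linker sequence;
#'   linkers must be distinct and none may be a prefix of another.
#' @return a \code{DataFrame} with columns \code{id}, \code{library} (NA when
#'   unassigned), \code{qcStatus} and \code{interior} (the ditag region for
#'   passing reads).
#' @export
demultiplexReads <- function(reads, linkers) {
  if (is(reads, "DataFrame") || is.data.frame(reads)) {
    ids <- reads$id; seqs <- as.character(reads$sequence)
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("read%06d", seq_along(seqs))
  }
  if (length(linkers) == 0L || is.null(names(linkers)))
    stop("named, nonempty linkers are required")
  if (anyDuplicated(linkers)) stop("linkers must be mutually distinct")
  n <- length(seqs)
  lib <- rep(NA_character_, n)
  status <- rep("incomplete_linker", n)
  interior <- rep(NA_character_, n)

  hits <- vapply(linkers, function(L) startsWith(seqs, L), logical(n))
  if (n == 1L) hits <- matrix(hits, nrow = 1L)
  nhit <- rowSums(hits)
  # a read matching two libraries' linkers is unassignable; treated like an
  # incomplete linker
  single <- which(nhit == 1L)
  for (j in seq_along(linkers)) {
    L <- linkers[[j]]; rcL <- revComp(L)
    sel <- single[hits[single, j]]
    if (!length(sel)) next
    ok <- endsWith(seqs[sel], rcL)
    sel <- sel[ok]
    if (!length(sel)) next
    inner <- substr(seqs[sel], nchar(L) + 1L, nchar(seqs[sel]) - nchar(rcL))
    lib[sel] <- names(linkers)[j]
    interior[sel] <- inner
    st <- rep("pass", length(sel))
    # interior linker contamination (any library's linker or its complement)
    contam <- Reduce(`|`, lapply(linkers, function(LL)
      grepl(LL, inner, fixed = TRUE) | grepl(revComp(LL), inner, fixed = TRUE)))
    st[contam] <- "internal_linker"
    amb <- !contam & grepl("[^ACGT]", inner)
    st[amb] <- "ambiguous_base"
    short <- st == "pass" & nchar(inner) != 52L
    st[short] <- "incomplete_linker"
    status[sel] <- st
  }
  # per-library deduplication of passing reads, first occurrence retained
  for (lb in unique(lib[!is.na(lib)])) {
    sel <- which(lib == lb & status == "pass")
    dup <- sel[duplicated(seqs[sel])]
    status[dup] <- "duplicate"
  }
  S4Vectors::DataFrame(id = ids, library = lib, qcStatus = status,
                       interior = interior)
}

#' Extract mono-tags from passing ditags and build the count matrix
#'
#' Splits each 52-nt ditag region into two 26-nt tags (the downstream tag is
#' reverse-complemented back to the transcript sense strand).  Both tags must
#' begin with the anchoring-enzyme site CATG; ditags violating this are
#' discarded and tallied.  Tags are keyed by their printed 22-nt suffix.
#'
#' @param ditags the `DataFrame` from [demultiplexReads()] (only `pass` rows
#'   are used), or any data frame with `library`, `qcStatus` and `interior`.
#' @param libraries optional character vector fixing the library column order
#'   of the result (defaults to order of appearance).
#' @return a \linkS4class{TagCountMatrix}; the number of CATG-violating
#'   ditags per library is recorded in
#'   `metadata(x)$rejectedDitags`.
#' @export
extractMonotags <- function(ditags, libraries = NULL) {
  pass <- ditags[!is.na(ditags$library) & ditags$qcStatus == "pass", ,
                 drop = FALSE]
  if (is.null(libraries))
    libraries <- unique(pass$library)
  rejects <- setNames(integer(length(libraries)), libraries)
  if (nrow(pass)) {
    tagA <- substr(pass$interior, 1L, 26L)
    tagB <- revComp(substr(pass$interior, 27L, 52L))
    anchored <- startsWith(tagA, "CATG") & startsWith(tagB, "CATG")
    bad <- table(pass$library[!anchored])
    rejects[names(bad)] <- as.integer(bad)
    tags <- c(substr(tagA[anchored], 5L, 26L),
              substr(tagB[anchored], 5L, 26L))
    libs <- rep(pass$library[anchored], 2L)
    allTags <- sort(unique(tags))
    m <- matrix(0L, length(allTags), length(libraries),
                dimnames = list(allTags, libraries))
    tb <- table(factor(tags, levels = allTags),
                factor(libs, levels = libraries))
    m[] <- as.integer(tb)
  } else {
    m <- matrix(integer(0), 0L, length(libraries),
                dimnames = list(character(0), libraries))
  }
  x <- tagCountMatrix(m)
  S4Vectors::metadata(x)$rejectedDitags <- rejects
  x
}

#' Per-library extraction summary
#'
#' Computes the per-library accounting of a tag-count matrix: total extracted
#' tags, number of unitags (distinct tags observed), percentage of unitags
#' (rounded half away from zero to one decimal), and the distribution of
#' unitags over the abundance classes 1, 2--4, 5--9, 10--100 and >100.
#'
#' @param x a \linkS4class{TagCountMatrix}.
#' @param library library name.
#' @return a list with \code{totalTags}, \code{unitags}, \code{pctUnitags}
#'   and \code{abundanceClasses} (a named integer vector whose entries sum to
#'   \code{unitags}).
#' @examples
#' m <- matrix(c(1L, 1L, 3L, 7L, 150L), 5, 1,
#'             dimnames = list(replicate(5, paste(sample(c("A","C","G","T"),
#'                             22, TRUE), collapse = "")), "L1"))
#' summarizeLibrary(tagCountMatrix(m), "L1")$abundanceClasses
#' @export
summarizeLibrary <- function(x, library) {
  if (!library %in% libraryNames(x))
    stop("unknown library: ", library)
  cnt <- tagCounts(x)[, library]
  cnt <- cnt[cnt > 0L]
  classes <- c("1" = sum(cnt == 1L),
               "2-4" = sum(cnt >= 2L & cnt <= 4L),
               "5-9" = sum(cnt >= 5L & cnt <= 9L),
               "10-100" = sum(cnt >= 10L & cnt <= 100L),
               ">100" = sum(cnt > 100L))
  total <- sum(cnt)
  uni <- length(cnt)
  list(totalTags = total, unitags = uni,
       pctUnitags = if (total > 0) roundHalfUp(100 * uni / total, 1) else 0,
       abundanceClasses = classes)
}

#' Extraction summary table across libraries
#'
#' One row per library plus pooled totals; the pooled singleton percentage is
#' the class-1 unitag sum over the all-class unitag sum, across libraries.
#'
#' @param x a \linkS4class{TagCountMatrix}.
#' @return a data.frame with library rows and a `pooled` attribute list
#'   containing `pctSingletons`.
#' @export
summarizeLibraries <- function(x) {
  ss <- lapply(libraryNames(x), function(l) summarizeLibrary(x, l))
  df <- data.frame(
    library = libraryNames(x),
    totalTags = vapply(ss, `[[`, numeric(1), "totalTags"),
    unitags = vapply(ss, `[[`, numeric(1), "unitags"),
    pctUnitags = vapply(ss, `[[`, numeric(1), "pctUnitags"),
    t(vapply(ss, `[[`, numeric(5), "abundanceClasses")),
    check.names = FALSE, stringsAsFactors = FALSE)
  classSums <- colSums(df[, c("1", "2-4", "5-9", "10-100", ">100"),
                          drop = FALSE])
  attr(df, "pooled") <- list(
    classSums = classSums,
    pctSingletons = roundHalfUp(100 * classSums[["1"]] / sum(classSums), 1))
  df
}
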