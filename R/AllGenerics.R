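#' Accessors for TagCountMatrix and friends
#'
#' `tagSequences()` returns the 22-nt printed tag sequences, `libraryNames()`
#' the library names, `tagCounts()` the integer count matrix and
#' `libraryTotals()` the per-library total tag counts (column sums).
#'
#' @param x a \linkS4class{TagCountMatrix}.
#' @return character, character, matrix and named numeric respectively.
#' @examples
#' tcm <- tagCountMatrix(matrix(c(1L, 2L, 0L, 3L), 2,
#'                              dimnames = list(c("AAAAAAAAAAAAAAAAAAAAAA",
#'                                                "CCCCCCCCCCCCCCCCCCCCCC"),
#'                                              c("L1", "L2"))))
#' libraryTotals(tcm)
#' @name TagCountMatrix-accessors
NULL

#' @rdname TagCountMatrix-accessors
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname TagCountMatrix-accessors
#' @export
setGeneric("libraryNames", function(x) standardGeneric("libraryNames"))

#' @rdname TagCountMatrix-accessors
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname TagCountMatrix-accessors
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @rdname TagCountMatrix-accessors
setMethod("tagSequences", "TagCountMatrix", function(x) rownames(x))

#' @rdname TagCountMatrix-accessors
setMethod("libraryNames", "TagCountMatrix", function(x) colnames(x))

#' @rdname TagCountMatrix-accessors
setMethod("tagCounts", "TagCountMatrix",
          function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname TagCountMatrix-accessors
setMethod("libraryTotals", "TagCountMatrix",
          function(x) colSums(SummarizedExperiment::assay(x, "counts")))

#' Accessors for ClusterModel and GapResult
#'
#' @param x a \linkS4class{ClusterModel} or \linkS4class{GapResult}.
#' @return `clusterAssignments()` the named tag->cluster vector,
#'   `clusterCentroids()` the centroid matrix, `selectedK()` the
#'   Gap-selected number of clusters.
#' @name cluster-accessors
NULL

#' @rdname cluster-accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname cluster-accessors
#' @export
setGeneric("clusterCentroids",
           function(x) standardGeneric("clusterCentroids"))

#' @rdname cluster-accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname cluster-accessors
setMethod("clusterAssignments", "ClusterModel", function(x) x@assignments)

#' @rdname cluster-accessors
setMethod("clusterCentroids", "ClusterModel", function(x) x@centroids)

#' @rdname cluster-accessors
setMethod("selectedK", "GapResult", function(x) x@selectedK)
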