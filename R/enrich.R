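#' Build a tag -> GO-term map from annotation records
#'
#' Retrieves the GO terms of significant protein hits (E-value below `eGo`);
#' tags without qualifying hits map to the empty set.  Terms are stored as
#' \code{"<namespace>:GO:<id>"} with namespace P (process), F (function) or
#' C (component).
#'
#' @param records annotation `DataFrame` from [annotateTags()] (columns
#'   `tag`, `goTerms`, `evalue`).
#' @param eGo E-value threshold (default 1e-10).
#' @return named list, tag -> character vector of GO terms.
#' @export
goAnnotationMap <- function(records, eGo = 1e-10) {
  records <- as.data.frame(records)
  terms <- ifelse(!is.na(records$evalue) & records$evalue < eGo,
                  records$goTerms, "")
  out <- strsplit(terms, ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- records$tag
  out
}

#' Background tag set from control libraries
#'
#' The enrichment background is the normal transcriptome at the analysis'
#' time scope: every tag with at least one count in the scoped control
#' libraries, carrying its GO annotation.
#'
#' @param goMap tag -> GO terms map ([goAnnotationMap()]); tags absent from
#'   the map get the empty set.
#' @param x a \linkS4class{TagCountMatrix}.
#' @param controlLibraries character vector of control library names (e.g.
#'   both control libraries for the low-calcium analysis, the 12 h control
#'   only for the 12 h analysis).
#' @return named list, tag -> GO terms, restricted to background tags.
#' @export
buildBackground <- function(goMap, x, controlLibraries) {
  if (!length(controlLibraries))
    stop("at least one control library is required")
  miss <- setdiff(controlLibraries, libraryNames(x))
  if (length(miss)) stop("unknown control libraries: ",
                         paste(miss, collapse = ", "))
  cnt <- tagCounts(x)[, controlLibraries, drop = FALSE]
  tags <- rownames(cnt)[rowSums(cnt) > 0L]
  out <- goMap[tags]
  names(out) <- tags
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' One-tailed proportion test for enrichment
#'
#' Pooled two-proportion z statistic with the upper-tail (enrichment
#' direction) normal probability:
#' \deqn{z = \frac{x_1/n_1 - x_2/n_2}{\sqrt{p_0(1-p_0)(1/n_1+1/n_2)}}.}
#' Degenerate pooled proportions (0 or 1) give p = 1 (no evidence of
#' enrichment).
#'
#' @param x1,n1 term count and size of the study list.
#' @param x2,n2 term count and size of the background.
#' @return one-tailed p-value (vectorized).
#' @examples
#' proportionTest(10, 100, 100, 1000)   # equal proportions: p = 0.5
#' @export
proportionTest <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("set sizes must be positive")
  p0 <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  p <- pnorm(z, lower.tail = FALSE)
  p[p0 <= 0 | p0 >= 1] <- 1
  p
}

#' GO-term enrichment of a tag list against a background
#'
#' Tests every GO term present in the list or the background by a one-tailed
#' proportion test of the term's tag share in the list against its share in
#' the background, adjusts the p-values across all tested terms by
#' Benjamini-Hochberg, and flags terms with adjusted p below `fdr` whose list
#' proportion exceeds the background proportion.  The counting unit is the
#' tag.  An exact hypergeometric test is available for sensitivity analysis.
#'
#' @param tags character vector of study-list tags.
#' @param goMap tag -> GO-term map covering the list (see
#'   [goAnnotationMap()]).
#' @param background background map from [buildBackground()].
#' @param fdr adjusted-p threshold (default 0.01).
#' @param method "ztest" (default) or "hypergeometric".
#' @return a `DataFrame` sorted by adjusted p: goId, namespace, x1, n1, x2,
#'   n2, p, padj, enriched.
#' @export
enrichTags <- function(tags, goMap, background, fdr = 0.01,
                       method = c("ztest", "hypergeometric")) {
  method <- match.arg(method)
  listSets <- goMap[tags]
  listSets[vapply(listSets, is.null, logical(1))] <- list(character(0))
  n1 <- length(tags); n2 <- length(background)
  if (n1 == 0L)
    return(S4Vectors::DataFrame(goId = character(0),
                                namespace = character(0),
                                x1 = integer(0), n1 = integer(0),
                                x2 = integer(0), n2 = integer(0),
                                p = numeric(0), padj = numeric(0),
                                enriched = logical(0)))
  listCounts <- table(unlist(lapply(listSets, unique)))
  bgCounts <- table(unlist(lapply(background, unique)))
  terms <- sort(union(names(listCounts), names(bgCounts)))
  x1 <- as.integer(listCounts[terms]); x1[is.na(x1)] <- 0L
  x2 <- as.integer(bgCounts[terms]); x2[is.na(x2)] <- 0L
  p <- if (method == "ztest") proportionTest(x1, n1, x2, n2) else
    phyper(x1 - 1L, x2, n2 - x2, n1, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  ns <- substr(terms, 1L, 1L)
  out <- S4Vectors::DataFrame(
    goId = sub("^[PFC]:", "", terms), namespace = ns,
    x1 = x1, n1 = n1, x2 = x2, n2 = n2, p = p, padj = padj,
    enriched = padj < fdr & x1 / n1 > x2 / n2)
  out[order(out$padj, out$p), ]
}
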