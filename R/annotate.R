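#' Build an exact-match tag index over a reference dataset
#'
#' Prepares a DNA dataset for exact fixed-length tag mapping on both strands.
#' At full stringency (26/26 identity) exact substring search is equivalent
#' to an alignment search that only accepts perfect matches, and it is
#' bit-reproducible.
#'
#' @param subject a \code{DNAStringSet} (or named character vector) of
#'   reference sequences; ambiguity codes are allowed but never match.
#' @param dataset dataset label ("ncbi", "ensembl" or "genome").
#' @return a \linkS4class{TagIndex}.
#' @export
buildTagIndex <- function(subject, dataset = "ncbi") {
  if (!is(subject, "DNAStringSet"))
    subject <- Biostrings::DNAStringSet(subject)
  if (length(subject) == 0L)
    warning("empty reference dataset: '", dataset, "'")
  new("TagIndex", subject = subject, dataset = dataset)
}

#' Map tags to reference datasets by exact match
#'
#' Maps 22-nt printed tags (the anchoring site CATG is prepended internally,
#' giving the 26-nt query) to one or more indexed datasets.  At stringency 26
#' the full 26-nt identity is required; at reduced stringency 24 only the
#' 5'-most 24 nt (CATG + 20) must match, trimming from the 3' end where
#' sequencing errors and polymorphisms concentrate.  Both strands are
#' searched; a minus-strand hit means the reverse complement of the query
#' occurs on the deposited strand.
#'
#' @param tags character vector of 22-nt printed tags (A/C/G/T only).
#' @param indexes a \linkS4class{TagIndex} or a (preferably named) list of
#'   them, e.g. the three datasets in preference order.
#' @param stringency 26 (perfect match) or 24 (reduced).
#' @return a \code{DataFrame} of hits: \code{tag}, \code{dataset},
#'   \code{seqId}, \code{start}, \code{end} (1-based, closed, on the
#'   deposited strand, spanning the matched \code{stringency}-nt region),
#'   \code{strand}.
#' @export
mapTags <- function(tags, indexes, stringency = 26) {
  stringency <- match.arg(as.character(stringency), c("26", "24"))
  w <- as.integer(stringency)
  if (any(grepl("[^ACGT]", tags))) stop("tags must be A/C/G/T only")
  if (is(indexes, "TagIndex")) indexes <- list(indexes)
  if (is.null(names(indexes)))
    names(indexes) <- vapply(indexes, function(i) i@dataset, character(1))
  query <- substr(paste0("CATG", tags), 1L, w)
  out <- list()
  for (ds in names(indexes)) {
    idx <- indexes[[ds]]
    if (length(idx@subject) == 0L) next
    qSet <- Biostrings::DNAStringSet(query)
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") qSet else Biostrings::reverseComplement(qSet)
      pd <- Biostrings::PDict(qs)
      for (si in seq_along(idx@subject)) {
        mi <- Biostrings::matchPDict(pd, idx@subject[[si]])
        cnt <- S4Vectors::elementNROWS(mi)
        hitQ <- which(cnt > 0L)
        if (!length(hitQ)) next
        starts <- lapply(hitQ, function(q) IRanges::start(mi[[q]]))
        ntag <- rep(hitQ, lengths(starts))
        st <- unlist(starts, use.names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          tag = tags[ntag], dataset = ds,
          seqId = names(idx@subject)[si],
          start = st, end = st + w - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(0), dataset = character(0),
               seqId = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  gh <- hits[hits$dataset == "genome", , drop = FALSE]
  key <- paste(gh$tag, gh$seqId, gh$start, gh$strand)
  ng <- table(gh$tag[!duplicated(key)])
  hits$nGenomicLocations <- as.integer(ng[hits$tag])
  hits$nGenomicLocations[is.na(hits$nGenomicLocations)] <- 0L
  S4Vectors::DataFrame(hits)
}

#' Extract the DNA fragment upstream of a genomic tag match
#'
#' Returns the `length` nucleotides 5' of the tag site in transcript
#' orientation: for a plus-strand hit the fragment covers
#' \code{[start - length, start - 1]} in sequence coordinates; for a
#' minus-strand hit it is the reverse complement of
#' \code{[end + 1, end + length]}.  Fragments are truncated at sequence
#' boundaries.
#'
#' @param genome a \code{DNAStringSet} (the genome dataset) or
#'   \linkS4class{TagIndex}.
#' @param seqId,start,end,strand hit coordinates as returned by [mapTags()]
#'   (1-based, closed).
#' @param length fragment length (default 1000).
#' @return a list with `fragment` (character), `length` (realized length) and
#'   `truncated` (logical).
#' @export
extractUpstreamFragment <- function(genome, seqId, start, end, strand,
                                    length = 1000) {
  if (is(genome, "TagIndex")) genome <- genome@subject
  seq <- genome[[seqId]]
  n <- base::length(seq)
  if (strand == "+") {
    from <- max(1L, start - length); to <- start - 1L
    frag <- if (to >= from) as.character(Biostrings::subseq(seq, from, to))
      else ""
  } else {
    from <- end + 1L; to <- min(n, end + length)
    frag <- if (to >= from)
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(seq, from, to))) else ""
  }
  list(fragment = frag, length = nchar(frag),
       truncated = nchar(frag) < length)
}

#' Assign a protein to a tag from its DNA hits
#'
#' Follows the hierarchical preference order curated cDNAs > predicted cDNAs
#' > genomic upstream fragments: the first dataset in that order containing a
#' hit whose protein-mapping row has E-value below `eMax` supplies the
#' assignment; ties within a dataset are broken by lowest E-value, then
#' lexicographic protein id.  GO terms are attached only when the chosen
#' row's E-value is below `eGo`.  Genome-dataset rows are keyed by the
#' upstream-fragment convention \code{"<seqId>:<start>:<strand>"}.
#'
#' @param hits hit rows of one tag as returned by [mapTags()].
#' @param blastx the protein mapping table (`DataFrame`/data.frame with
#'   columns dnaId, dataset, proteinId, evalue, proteinOrientation,
#'   geneSymbol, goTerms).
#' @param eMax identity-assignment threshold (default 1e-5).
#' @param eGo GO-retrieval threshold (default 1e-10).
#' @return a one-row \code{DataFrame} (proteinId, evalue, dataset,
#'   proteinOrientation, geneSymbol, goTerms) or `NULL` when no qualifying
#'   row exists.
#' @export
assignProtein <- function(hits, blastx, eMax = 1e-5, eGo = 1e-10) {
  if (nrow(hits) == 0L) return(NULL)
  blastx <- as.data.frame(blastx)
  for (ds in c("ncbi", "ensembl", "genome")) {
    h <- hits[hits$dataset == ds, , drop = FALSE]
    if (nrow(h) == 0L) next
    keys <- if (ds == "genome")
      sprintf("%s:%d:%s", h$seqId, h$start, h$strand) else h$seqId
    rows <- blastx[blastx$dataset == ds & blastx$dnaId %in% keys &
                     blastx$evalue < eMax, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$evalue, rows$proteinId), , drop = FALSE]
    best <- rows[1L, , drop = FALSE]
    hitStrand <- h$strand[match(best$dnaId,
                                if (ds == "genome") keys else h$seqId)]
    return(S4Vectors::DataFrame(
      proteinId = best$proteinId, evalue = best$evalue, dataset = ds,
      dnaStrand = hitStrand,
      proteinOrientation = best$proteinOrientation,
      geneSymbol = best$geneSymbol,
      goTerms = if (best$evalue < eGo) best$goTerms else ""))
  }
  NULL
}

#' Antisense call from mapping and protein orientations
#'
#' A tag is flagged as putatively derived from a natural antisense transcript
#' when its tag-to-DNA orientation and the DNA-to-protein orientation are
#' discordant (an inverted match to a sense cDNA, or a direct match to an
#' antisense cDNA).
#'
#' @param tagStrand "+" or "-" (vectorized).
#' @param proteinOrientation "+" or "-".
#' @return logical.
#' @export
detectAntisense <- function(tagStrand, proteinOrientation) {
  tagStrand != proteinOrientation
}

#' Annotate a set of tags against the three reference datasets
#'
#' Runs exact mapping, hierarchical protein assignment and antisense
#' detection for each tag.  Tags matching more than one genomic location are
#' annotated but flagged `ambiguous` (and should be excluded from gene-level
#' aggregation).
#'
#' @param tags character vector of printed 22-nt tags.
#' @param reference a \linkS4class{ReferenceSet}, or a named list with
#'   elements `ncbi`, `ensembl`, `genome` (DNAStringSet) and `blastx`.
#' @param stringency 26 or 24.
#' @param eMax,eGo E-value thresholds for protein assignment and GO
#'   retrieval.
#' @return a \code{DataFrame}, one row per tag: per-dataset hit counts,
#'   `nGenomicLocations`, assignment columns, `antisense`, `ambiguous` and
#'   `status` in \{annotated_protein, anonymous_dna, unannotated\}.
#' @export
annotateTags <- function(tags, reference, stringency = 26,
                         eMax = 1e-5, eGo = 1e-10) {
  if (is(reference, "ReferenceSet"))
    reference <- list(ncbi = reference@ncbi, ensembl = reference@ensembl,
                      genome = reference@genome, blastx = reference@blastx)
  idx <- list(ncbi = buildTagIndex(reference$ncbi, "ncbi"),
              ensembl = buildTagIndex(reference$ensembl, "ensembl"),
              genome = buildTagIndex(reference$genome, "genome"))
  hits <- suppressWarnings(mapTags(tags, idx, stringency))
  res <- lapply(tags, function(tg) {
    h <- hits[hits$tag == tg, , drop = FALSE]
    nH <- c(ncbi = sum(h$dataset == "ncbi"),
            ensembl = sum(h$dataset == "ensembl"),
            genome = sum(h$dataset == "genome"))
    nLoc <- if (nrow(h)) max(h$nGenomicLocations) else 0L
    asg <- assignProtein(h, reference$blastx, eMax, eGo)
    if (!is.null(asg)) {
      S4Vectors::DataFrame(
        tag = tg, nNcbi = nH[["ncbi"]], nEnsembl = nH[["ensembl"]],
        nGenome = nH[["genome"]], nGenomicLocations = nLoc,
        dataset = asg$dataset, proteinId = asg$proteinId,
        evalue = asg$evalue, dnaStrand = asg$dnaStrand,
        proteinOrientation = asg$proteinOrientation,
        geneSymbol = asg$geneSymbol, goTerms = asg$goTerms,
        antisense = detectAntisense(asg$dnaStrand, asg$proteinOrientation),
        ambiguous = nLoc > 1L, status = "annotated_protein")
    } else {
      S4Vectors::DataFrame(
        tag = tg, nNcbi = nH[["ncbi"]], nEnsembl = nH[["ensembl"]],
        nGenome = nH[["genome"]], nGenomicLocations = nLoc,
        dataset = NA_character_, proteinId = NA_character_,
        evalue = NA_real_, dnaStrand = NA_character_,
        proteinOrientation = NA_character_,
        geneSymbol = NA_character_, goTerms = "",
        antisense = FALSE, ambiguous = nLoc > 1L,
        status = if (nrow(h)) "anonymous_dna" else "unannotated")
    }
  })
  do.call(rbind, res)
}

#' Annotation summary in the style of a tag-annotation report table
#'
#' Counts and percentages (one decimal, half away from zero) of tags with a
#' DNA match, protein-assigned DNAs, anonymous-DNA tags and unannotated tags;
#' plus multi-tag gene accounting and antisense counts.
#'
#' @param records annotation `DataFrame` from [annotateTags()] (columns
#'   `status`, `geneSymbol`, `antisense`; a plain data.frame works too).
#' @return a list with `blastn` (matched / unmatched / total with
#'   percentages), `blastx`, `global`, `genes` (n, multiTag, pctMultiTag,
#'   meanTagsPerGene) and `antisense` counts.
#' @export
annotationSummary <- function(records) {
  records <- as.data.frame(records)
  total <- nrow(records)
  matched <- sum(records$status != "unannotated")
  prot <- sum(records$status == "annotated_protein")
  anon <- sum(records$status == "anonymous_dna")
  pct <- function(a, b) if (b > 0) roundHalfUp(100 * a / b, 1) else 0
  genes <- table(records$geneSymbol[records$status == "annotated_protein" &
                                      !is.na(records$geneSymbol)])
  list(
    blastn = list(matched = matched, unmatched = total - matched,
                  total = total, pctMatched = pct(matched, total),
                  pctUnmatched = pct(total - matched, total)),
    blastx = list(assigned = prot, anonymous = anon, total = matched,
                  pctAssigned = pct(prot, matched),
                  pctAnonymous = pct(anon, matched)),
    global = list(unannotated = total - matched, anonymousDna = anon,
                  proteinAssigned = prot,
                  pctUnannotated = pct(total - matched, total),
                  pctAnonymousDna = pct(anon, total),
                  pctProteinAssigned = pct(prot, total)),
    genes = list(n = length(genes), multiTag = sum(genes > 1L),
                 pctMultiTag = pct(sum(genes > 1L), length(genes)),
                 meanTagsPerGene = if (length(genes))
                   round(mean(genes), 1) else NA_real_),
    antisense = list(tags = sum(records$antisense),
                     pctOfAnnotated = pct(sum(records$antisense), matched)))
}
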