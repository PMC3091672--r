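#' SimulationConfig: study conditions for the synthetic SuperSAGE experiment
#'
#' An object describing the simulated experiment: library structure, the
#' heavy-tailed transcript-abundance law, planted differential expression,
#' ditag read geometry and corruption rates.  The defaults emulate a
#' five-library gill SuperSAGE study (control and calcium-challenged water at
#' 2 h and 12 h) with 60,000--87,000 tags per library and roughly 70% of
#' unitags observed as singletons.
#'
#' @slot libraryNames character, one name per library; the default five names
#'   carry the experimental roles (C2h, LowCa2h, C12h, HighCa12h, LowCa12h).
#' @slot libraryDepths integer target total tag counts, one per library.
#' @slot nTranscripts number of transcripts in the simulated transcriptome.
#' @slot abundanceMeanlog,abundanceSdlog parameters of the discretized
#'   log-normal law for transcript frequencies (frequencies are renormalized,
#'   so only \code{abundanceSdlog} shapes the distribution).
#' @slot deFraction fraction of transcripts planted as differentially
#'   expressed (among transcripts with base frequency at least
#'   \code{deMinFreq}).
#' @slot deFoldRange numeric length 2, the range of planted multiplicative
#'   effects (minimum must be >= 2 when planting detectable effects).
#' @slot deClassMix proportions of the four differential-expression classes
#'   among planted tags.
#' @slot deMinFreq,deMaxFreq base-frequency band of transcripts eligible for
#'   planting; below the floor an effect is unrecoverable sampling noise,
#'   above the cap it would displace a large share of the library's mass.
#' @slot linkers per-library linker/barcode sequences flanking each ditag.
#' @slot duplicateDitagRate fraction of extra exact-duplicate ditag reads
#'   (PCR/emulsion duplicates) emitted per library.
#' @slot contaminatedLinkerRate fraction of reads with a linker copy inserted
#'   inside the ditag region.
#' @slot incompleteLinkerRate fraction of reads with a truncated 5' linker.
#' @slot ambiguousBaseRate fraction of reads with an ambiguous (N) base in the
#'   ditag region.
#' @slot sequencingErrorRate per-base substitution probability in the ditag
#'   region (these reads still pass linker/ambiguity QC but corrupt tags).
#' @slot antisenseFraction fraction of transcripts expressed antisense to a
#'   deposited sense cDNA.
#' @slot unmappableFraction fraction of transcripts absent from every
#'   reference DNA dataset.
#' @slot ncbiFraction,ensemblFraction membership probabilities of mappable
#'   transcripts in the curated and the predicted cDNA datasets (the genome
#'   contains every mappable transcript).
#' @slot noProteinFraction fraction of reference DNAs without a significant
#'   protein match.
#' @slot seed integer seed; identical config + seed gives identical output.
#'
#' @seealso [simulationConfig()] for the user constructor.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @export
setClass("SimulationConfig", representation(
  libraryNames = "character",
  libraryDepths = "numeric",
  nTranscripts = "numeric",
  abundanceMeanlog = "numeric",
  abundanceSdlog = "numeric",
  deFraction = "numeric",
  deFoldRange = "numeric",
  deClassMix = "numeric",
  deMinFreq = "numeric",
  deMaxFreq = "numeric",
  linkers = "character",
  duplicateDitagRate = "numeric",
  contaminatedLinkerRate = "numeric",
  incompleteLinkerRate = "numeric",
  ambiguousBaseRate = "numeric",
  sequencingErrorRate = "numeric",
  antisenseFraction = "numeric",
  unmappableFraction = "numeric",
  ncbiFraction = "numeric",
  ensemblFraction = "numeric",
  noProteinFraction = "numeric",
  seed = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  nl <- length(object@libraryNames)
  if (nl < 1L) msg <- c(msg, "at least one library is required")
  if (anyDuplicated(object@libraryNames))
    msg <- c(msg, "library names must be distinct")
  if (length(object@libraryDepths) != nl)
    msg <- c(msg, "libraryDepths must have one entry per library")
  if (any(object@libraryDepths <= 0))
    msg <- c(msg, "library depths must be positive")
  if (object@nTranscripts <= 0)
    msg <- c(msg, "nTranscripts must be positive")
  rates <- c(object@duplicateDitagRate, object@contaminatedLinkerRate,
             object@incompleteLinkerRate, object@ambiguousBaseRate,
             object@sequencingErrorRate, object@antisenseFraction,
             object@unmappableFraction, object@ncbiFraction,
             object@ensemblFraction, object@noProteinFraction,
             object@deFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "all rates and fractions must lie in [0, 1]")
  if (length(object@deFoldRange) != 2L ||
      object@deFoldRange[1] > object@deFoldRange[2])
    msg <- c(msg, "deFoldRange must be an increasing pair")
  if (object@deFraction > 0 && object@deFoldRange[1] < 2)
    msg <- c(msg, "deFoldRange minimum must be >= 2 when planting effects")
  if (object@deMaxFreq < object@deMinFreq)
    msg <- c(msg, "deMaxFreq must be at least deMinFreq")
  if (length(object@deClassMix) != 4L || any(object@deClassMix < 0) ||
      sum(object@deClassMix) <= 0)
    msg <- c(msg, "deClassMix must be 4 nonnegative proportions")
  if (length(object@linkers) != nl)
    msg <- c(msg, "one linker per library is required")
  if (anyDuplicated(object@linkers))
    msg <- c(msg, "linkers must be mutually distinct")
  if (any(nchar(object@linkers) < 6L))
    msg <- c(msg, "linkers shorter than 6 nt cannot identify libraries")
  if (object@deFraction > 0 && !all(sageRoles() %in% object@libraryNames))
    msg <- c(msg, paste("planting the four DE classes requires the five",
                        "role libraries:", paste(sageRoles(), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' TagCountMatrix: tags by libraries count table
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one `counts` assay of
#' nonnegative integers with 22-nt printed tag sequences as row names (the
#' leading anchoring-enzyme site CATG is implicit) and library names as column
#' names.  Per-library totals are the column sums.
#'
#' @seealso [tagCountMatrix()], [libraryTotals()], [summarizeLibrary()]
#' @export
setClass("TagCountMatrix", contains = "SummarizedExperiment")

setValidity("TagCountMatrix", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("tag row names and library column names are required")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate tag rows")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate library columns")
  if (any(m < 0) || any(m != floor(m)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (nrow(m) > 0) {
    nc <- nchar(rownames(m))
    if (length(unique(nc)) != 1L)
      msg <- c(msg, "tags must have uniform length")
    if (any(grepl("[^ACGT]", rownames(m))))
      msg <- c(msg, "tags must be uppercase DNA (A/C/G/T)")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: the three DNA datasets plus the protein mapping table
#'
#' Holds the simulated curated cDNAs ("ncbi"), predicted cDNAs ("ensembl") and
#' genome datasets as \code{DNAStringSet}s, together with a precomputed
#' DNA-to-protein mapping table (a stand-in for translated-search output) and
#' the simulation truth table.
#'
#' @slot ncbi,ensembl,genome \code{DNAStringSet} reference collections.
#' @slot blastx \code{DataFrame} with columns dnaId, dataset, proteinId,
#'   evalue, proteinOrientation, geneSymbol, goTerms.
#' @slot truth per-transcript truth \code{DataFrame}.
#' @export
setClass("ReferenceSet", representation(
  ncbi = "DNAStringSet", ensembl = "DNAStringSet", genome = "DNAStringSet",
  blastx = "DataFrame", truth = "DataFrame"))

#' TagIndex: exact-match index over one reference dataset
#'
#' Supports exact mapping of fixed-length tags to both strands of a DNA
#' dataset.  At the perfect-match stringency used for 26-nt tags this is
#' equivalent to an alignment search that accepts 26/26 identities only.
#'
#' @slot subject the indexed \code{DNAStringSet}.
#' @slot dataset dataset label ("ncbi", "ensembl" or "genome").
#' @export
setClass("TagIndex", representation(subject = "DNAStringSet",
                                    dataset = "character"))

#' ClusterModel: a fitted K-means partition of expression profiles
#'
#' @slot K number of clusters.
#' @slot assignments named integer vector, tag -> cluster in 1..K.
#' @slot centroids K x L matrix of mean normalized profiles (percent).
#' @slot withinDispersion total within-cluster dispersion W_K under the model
#'   distance.
#' @slot distance "chisq" (chi-square divergence between profile shapes) or
#'   "euclidean".
#' @slot seed,nRestarts fitting parameters.
#' @export
setClass("ClusterModel", representation(
  K = "integer", assignments = "integer", centroids = "matrix",
  withinDispersion = "numeric", distance = "character",
  seed = "numeric", nRestarts = "integer"))

#' GapResult: Gap-statistic model selection over a range of K
#'
#' @slot K candidate cluster numbers.
#' @slot gap Gap(K) values; @slot se their standard errors (B reference sets).
#' @slot logW,ElogW observed and expected-reference log within-dispersion.
#' @slot B number of reference datasets.
#' @slot selectedK smallest K with Gap(K) >= Gap(K+1) - se(K+1).
#' @export
setClass("GapResult", representation(
  K = "integer", gap = "numeric", se = "numeric", logW = "numeric",
  ElogW = "numeric", B = "integer", selectedK = "integer"))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@libraryNames), "libraries, depths",
      paste(object@libraryDepths, collapse = "/"), "\n")
  cat("  transcripts:", object@nTranscripts,
      sprintf("(log-normal sdlog %.2f)", object@abundanceSdlog), "\n")
  cat(sprintf("  planted DE: %.1f%% at fold %g-%g (class mix %s)\n",
              100 * object@deFraction, object@deFoldRange[1],
              object@deFoldRange[2],
              paste(object@deClassMix, collapse = ":")))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "TagCountMatrix", function(object) {
  cat("TagCountMatrix:", nrow(object), "tags x", ncol(object), "libraries\n")
  tot <- libraryTotals(object)
  cat("  totals:", paste(names(tot), tot, sep = "=", collapse = " "), "\n")
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet: ncbi", length(object@ncbi), "| ensembl",
      length(object@ensembl), "| genome", length(object@genome),
      "sequences;", nrow(object@blastx), "protein mapping rows\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: K =", object@K, "(", object@distance, "distance ),",
      length(object@assignments), "profiles, W_K =",
      format(object@withinDispersion, digits = 6), "\n")
  print(table(cluster = object@assignments))
})

setMethod("show", "GapResult", function(object) {
  cat("GapResult over K =", paste(range(object@K), collapse = ".."),
      "( B =", object@B, "): selected K =", object@selectedK, "\n")
})
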