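#' Create a simulation configuration
#'
#' Builds a \linkS4class{SimulationConfig} describing the synthetic SuperSAGE
#' experiment.  The defaults reproduce the structure of a five-library gill
#' study: control and low-calcium water at 2 h and 12 h plus high-calcium
#' water at 12 h, 60,142--87,388 tags per library, and a discretized
#' log-normal transcript-abundance law over 700,000 transcripts calibrated so
#' that roughly 38\% of extracted tags are unitags and close to 70\% of
#' unitags are singletons at these depths.
#'
#' @param libraryNames,libraryDepths library structure; defaults are the five
#'   role libraries at sequencing-scale per-library depths.
#' @param nTranscripts,abundanceMeanlog,abundanceSdlog abundance law.
#' @param deFraction,deFoldRange,deClassMix,deMinFreq,deMaxFreq planted
#'   differential expression: fraction of transcripts, multiplicative effect
#'   range, mix of the four decision-rule classes, and the base-frequency
#'   band eligible for planting.  The band keeps planted effects both
#'   detectable (above the sampling-noise floor) and compositionally small
#'   (planting large effects on the most abundant transcripts would displace
#'   a sizable share of each library's mass).
#' @param linkers per-library linker/barcode sequences (14 nt defaults; the
#'   real barcodes are instrument-batch specific and therefore configurable).
#' @param duplicateDitagRate,contaminatedLinkerRate,incompleteLinkerRate,ambiguousBaseRate,sequencingErrorRate
#'   read corruption rates in `[0, 1]`.
#' @param antisenseFraction fraction of transcripts expressed antisense to a
#'   deposited sense cDNA (default 0.09, matching the reported share of
#'   antisense-derived tags).
#' @param unmappableFraction fraction of transcripts absent from all three
#'   reference datasets (default 0.35, the reported unannotated share).
#' @param ncbiFraction,ensemblFraction cDNA dataset membership probabilities
#'   for mappable transcripts.
#' @param noProteinFraction fraction of reference DNAs without a significant
#'   protein match (default 0.43).
#' @param seed integer random seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nTranscripts = 2000,
#'                         libraryDepths = rep(2000, 5), seed = 7)
#' cfg
#' @export
simulationConfig <- function(libraryNames = sageRoles(),
                             libraryDepths = c(65378, 87388, 67996, 60142, 63471),
                             nTranscripts = 700000,
                             abundanceMeanlog = 0,
                             abundanceSdlog = 2.7,
                             deFraction = 2e-4,
                             deFoldRange = c(4, 16),
                             deClassMix = c(0.25, 0.25, 0.25, 0.25),
                             deMinFreq = 1e-4,
                             deMaxFreq = 1e-3,
                             linkers = defaultLinkers(length(libraryNames)),
                             duplicateDitagRate = 0.05,
                             contaminatedLinkerRate = 0.01,
                             incompleteLinkerRate = 0.01,
                             ambiguousBaseRate = 0.01,
                             sequencingErrorRate = 0,
                             antisenseFraction = 0.09,
                             unmappableFraction = 0.35,
                             ncbiFraction = 0.55,
                             ensemblFraction = 0.45,
                             noProteinFraction = 0.43,
                             seed = 1L) {
  new("SimulationConfig",
      libraryNames = libraryNames, libraryDepths = libraryDepths,
      nTranscripts = nTranscripts, abundanceMeanlog = abundanceMeanlog,
      abundanceSdlog = abundanceSdlog, deFraction = deFraction,
      deFoldRange = as.numeric(deFoldRange), deClassMix = deClassMix,
      deMinFreq = deMinFreq, deMaxFreq = deMaxFreq, linkers = linkers,
      duplicateDitagRate = duplicateDitagRate,
      contaminatedLinkerRate = contaminatedLinkerRate,
      incompleteLinkerRate = incompleteLinkerRate,
      ambiguousBaseRate = ambiguousBaseRate,
      sequencingErrorRate = sequencingErrorRate,
      antisenseFraction = antisenseFraction,
      unmappableFraction = unmappableFraction,
      ncbiFraction = ncbiFraction, ensemblFraction = ensemblFraction,
      noProteinFraction = noProteinFraction, seed = seed)
}

#' Default per-library linker sequences
#'
#' Fixed 14-nt barcodes free of the anchoring-enzyme site, mutually distinct.
#' Real linker sequences are run-specific, so these exist only to make the
#' simulated reads demultiplexable out of the box.
#'
#' @param n number of libraries (at most 8).
#' @return character vector of linkers.
#' @export
defaultLinkers <- function(n) {
  pool <- c("TTCCGGAACCTAGT", "GGTTAACCGGTTCA", "AACCGGTTAAGGCT",
            "CCGGAATTCCAAGT", "TTGGCCAATTGGAC", "AAGGTTCCAAGGTC",
            "GGCCTTAAGGCCAT", "CCAATTGGCCTTGA")
  if (n > length(pool)) stop("at most ", length(pool), " default linkers")
  pool[seq_len(n)]
}

# ---------------------------------------------------------------------------
# Truth simulation: everything about the transcriptome that is independent of
# counting noise.  Deterministic in (config, config@seed).
# ---------------------------------------------------------------------------
simulateTruth <- function(config) {
  n <- as.integer(config@nTranscripts)
  withSeed(config@seed, {
    f <- exp(rnorm(n, config@abundanceMeanlog, config@abundanceSdlog))
    baseFreq <- f / sum(f)

    tags <- randomDNA(n, 22L)
    repeat {                       # unique tags without an internal CATG
      bad <- grepl("CATG", tags, fixed = TRUE) | duplicated(tags)
      if (!any(bad)) break
      tags[bad] <- randomDNA(sum(bad), 22L)
    }

    deClass <- integer(n); fold <- rep(1, n)
    direction <- character(n); timepoint <- character(n)
    if (config@deFraction > 0) {
      eligible <- which(baseFreq >= config@deMinFreq &
                          baseFreq <= config@deMaxFreq)
      nDE <- min(length(eligible), round(config@deFraction * n))
      idx <- sample(eligible, nDE)
      mix <- config@deClassMix / sum(config@deClassMix)
      deClass[idx] <- sample(1:4, nDE, replace = TRUE, prob = mix)
      fold[idx] <- runif(nDE, config@deFoldRange[1], config@deFoldRange[2])
      direction[idx] <- sample(c("up", "down"), nDE, replace = TRUE)
      timepoint[idx] <- sample(c("2h", "12h"), nDE, replace = TRUE)
      timepoint[deClass == 1L] <- "both"
      timepoint[deClass %in% 3:4] <- "12h"
    }

    unmappable <- runif(n) < config@unmappableFraction
    antisense <- !unmappable & runif(n) < config@antisenseFraction
    inNcbi <- !unmappable & runif(n) < config@ncbiFraction
    inEnsembl <- !unmappable & runif(n) < config@ensemblFraction
    # an antisense tag needs a deposited sense cDNA to be recognizable
    inNcbi[antisense & !inNcbi & !inEnsembl] <- TRUE
    hasProtein <- !unmappable & runif(n) >= config@noProteinFraction
    geneSymbol <- sprintf("gene%05d",
                          sample.int(max(1L, as.integer(0.88 * n)), n,
                                     replace = TRUE))
    geneSymbol[unmappable] <- NA_character_

    list(tags = tags, baseFreq = baseFreq, deClass = deClass, fold = fold,
         direction = direction, timepoint = timepoint,
         unmappable = unmappable, antisense = antisense,
         inNcbi = inNcbi, inEnsembl = inEnsembl, hasProtein = hasProtein,
         geneSymbol = geneSymbol)
  })
}

# per-library expected frequency matrix (columns in config library order).
# Planted transcripts keep their exact fold relative to the control
# frequency; the non-planted background absorbs the compositional shift, so
# each column still sums to one while planted ratios stay interpretable.
expectedFrequencies <- function(config, truth) {
  libs <- config@libraryNames
  FR <- matrix(truth$baseFreq, length(truth$baseFreq), length(libs),
               dimnames = list(NULL, libs))
  de <- which(truth$deClass > 0L)
  if (length(de)) {
    mult <- ifelse(truth$direction[de] == "up", truth$fold[de],
                   1 / truth$fold[de])
    cls <- truth$deClass[de]
    apply1 <- function(lib, sel, m) {
      FR[de[sel], lib] <<- truth$baseFreq[de[sel]] * m[sel]
    }
    apply1("LowCa2h",  cls == 1L | (cls == 2L & truth$timepoint[de] == "2h"),
           mult)
    apply1("LowCa12h", cls == 1L | (cls == 2L & truth$timepoint[de] == "12h") |
             cls == 3L | cls == 4L, mult)
    # class 3 is the challenge-discordant 12 h response: the high-calcium
    # effect runs opposite to the low-calcium one
    apply1("HighCa12h", cls == 3L, 1 / mult)
    apply1("HighCa12h", cls == 4L, mult)
    deBase <- sum(truth$baseFreq[de])
    for (lib in libs) {
      deMass <- sum(FR[de, lib])
      if (deMass >= 0.9)
        stop("planted differential expression carries ", round(deMass, 2),
             " of the library mass; reduce deFraction or deFoldRange")
      FR[-de, lib] <- FR[-de, lib] * (1 - deMass) / (1 - deBase)
    }
  }
  FR
}

#' Generate a synthetic tag-count matrix with its truth table
#'
#' Draws per-library tag counts as multinomial samples of the configured
#' library depths over per-library expected tag frequencies.  Differentially
#' expressed tags are planted according to the four decision-rule classes:
#' class 1 responds to low calcium at both time points, class 2 at exactly one
#' time point, class 3 discordantly to the low- and high-calcium challenges at
#' 12 h, and class 4 concordantly to both challenges at 12 h.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a list with elements \code{counts} (a
#'   \linkS4class{TagCountMatrix} restricted to tags observed in at least one
#'   library or planted as differentially expressed) and \code{truth} (a
#'   \code{DataFrame} with one row per retained tag: expected frequencies,
#'   planted class/fold/direction, and annotation ground truth).
#' @examples
#' sim <- generateCountMatrix(simulationConfig(nTranscripts = 1000,
#'                                             libraryDepths = rep(1000, 5),
#'                                             seed = 42))
#' sim$counts
#' @export
generateCountMatrix <- function(config) {
  truth <- simulateTruth(config)
  FR <- expectedFrequencies(config, truth)
  counts <- withSeed(config@seed + 1L, {
    vapply(seq_along(config@libraryNames),
           function(j) rmultinom(1, config@libraryDepths[j], FR[, j])[, 1L],
           integer(nrow(FR)))
  })
  colnames(counts) <- config@libraryNames
  keep <- rowSums(counts) > 0L | truth$deClass > 0L
  counts <- counts[keep, , drop = FALSE]
  rownames(counts) <- truth$tags[keep]

  tt <- S4Vectors::DataFrame(
    tag = truth$tags[keep], transcript = which(keep),
    baseFreq = truth$baseFreq[keep],
    expectedFreq = I(FR[keep, , drop = FALSE]),
    deClass = truth$deClass[keep], fold = truth$fold[keep],
    direction = truth$direction[keep], timepoint = truth$timepoint[keep],
    unmappable = truth$unmappable[keep], antisense = truth$antisense[keep],
    inNcbi = truth$inNcbi[keep], inEnsembl = truth$inEnsembl[keep],
    hasProtein = truth$hasProtein[keep], geneSymbol = truth$geneSymbol[keep])

  list(counts = tagCountMatrix(counts), truth = tt)
}

# ---------------------------------------------------------------------------
# Reference generation
# ---------------------------------------------------------------------------

#' Generate the three reference DNA datasets and the protein mapping table
#'
#' Builds, for every mappable transcript, a cDNA carrying the 26-nt tag
#' (CATG + 22 nt) at its 3'-most anchoring-enzyme site; deposits it in the
#' curated-cDNA ("ncbi") and/or predicted-cDNA ("ensembl") datasets and embeds
#' it in the genome dataset.  Antisense transcripts are deposited
#' reverse-complemented, so their tags map to the minus strand of a
#' protein-coding sense cDNA.  A fraction of DNAs carries no protein match,
#' emulating DNAs with no significant translated-search hit.  Genome protein
#' rows are keyed by the upstream-fragment convention
#' \code{"<chrom>:<tagStart>:<strand>"}.
#'
#' Sequence construction is intended for annotation-scale configurations (a
#' few thousand transcripts); the transcript count of the default
#' counting-scale configuration would produce a multi-hundred-megabyte
#' reference.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{ReferenceSet}; its truth table records, per
#'   transcript, the tag, dataset membership, genomic location and strand.
#' @export
generateReference <- function(config) {
  if (config@nTranscripts < 1) stop("nTranscripts must be positive")
  truth <- simulateTruth(config)
  n <- length(truth$tags)
  withSeed(config@seed + 2L, {
    mappable <- which(!truth$unmappable)
    m <- length(mappable)
    upLen <- sample(80:300, m, replace = TRUE)
    tailLen <- sample(20:80, m, replace = TRUE)
    up5 <- vapply(upLen, function(l) randomDNA(1L, l), character(1))
    tails <- paste0("TT", scrubCATG(vapply(tailLen, function(l)
      randomDNA(1L, l), character(1))))
    mrna <- paste0(up5, "CATG", truth$tags[mappable], tails)
    anchorStart <- nchar(up5) + 1L          # start of the 26-nt tag site
    entry <- ifelse(truth$antisense[mappable], revComp(mrna), mrna)
    entryLen <- nchar(entry)
    # tag-site coordinates on the deposited (+) strand of each entry
    tagStart <- ifelse(truth$antisense[mappable],
                       entryLen - (anchorStart + 25L) + 1L, anchorStart)
    tagStrand <- ifelse(truth$antisense[mappable], "-", "+")

    ids <- sprintf("dna%05d", mappable)
    ncbi <- Biostrings::DNAStringSet(setNames(
      entry[truth$inNcbi[mappable]], ids[truth$inNcbi[mappable]]))
    ensembl <- Biostrings::DNAStringSet(setNames(
      entry[truth$inEnsembl[mappable]], ids[truth$inEnsembl[mappable]]))

    # genome: embed every mappable entry (plus a second copy for a small
    # fraction, exercising multi-location ambiguity), with random spacers
    dupSel <- if (m > 0)
      sample(m, max(0L, floor(0.02 * m))) else integer(0)
    gIdx <- c(seq_len(m), dupSel)
    perChrom <- 200L
    nChrom <- max(1L, ceiling(length(gIdx) / perChrom))
    chromOf <- rep(seq_len(nChrom), each = perChrom)[seq_along(gIdx)]
    genomeSeqs <- character(nChrom)
    gChrom <- character(length(gIdx)); gStart <- integer(length(gIdx))
    for (cc in seq_len(nChrom)) {
      members <- which(chromOf == cc)
      pos <- 0L; parts <- character(0)
      for (k in members) {
        spacer <- randomDNA(1L, sample(50:150, 1L))
        parts <- c(parts, spacer, entry[gIdx[k]])
        gChrom[k] <- sprintf("chr%02d", cc)
        gStart[k] <- pos + nchar(spacer) + 1L   # entry start in chromosome
        pos <- pos + nchar(spacer) + entryLen[gIdx[k]]
      }
      genomeSeqs[cc] <- paste(parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(setNames(
      genomeSeqs, sprintf("chr%02d", seq_len(nChrom))))

    # genomic tag-site coordinates (first copy per transcript)
    first <- match(seq_len(m), gIdx)
    genomeChrom <- gChrom[first]
    genomeTagStart <- gStart[first] + tagStart - 1L

    # protein mapping table; GO vocabularies with P/F/C namespaces
    goPool <- sprintf("%s:GO:%07d",
                      sample(c("P", "F", "C"), 240, replace = TRUE),
                      seq_len(240))
    rows <- list()
    withProt <- which(truth$hasProtein[mappable])
    if (length(withProt)) {
      prot <- sprintf("prot%05d", mappable[withProt])
      ev <- 10^-runif(length(withProt), 6, 60)
      goStr <- vapply(seq_along(withProt), function(i)
        paste(sample(goPool, sample(1:4, 1L)), collapse = ";"), character(1))
      mk <- function(dnaId, dataset, sel)
        data.frame(dnaId = dnaId, dataset = dataset,
                   proteinId = prot[sel], evalue = ev[sel],
                   proteinOrientation = "+",
                   geneSymbol = truth$geneSymbol[mappable[withProt]][sel],
                   goTerms = goStr[sel], stringsAsFactors = FALSE)
      selN <- truth$inNcbi[mappable][withProt]
      selE <- truth$inEnsembl[mappable][withProt]
      rows$ncbi <- mk(ids[withProt][selN], "ncbi", selN)
      rows$ens  <- mk(ids[withProt][selE], "ensembl", selE)
      fragKey <- sprintf("%s:%d:%s", genomeChrom[withProt],
                         genomeTagStart[withProt], tagStrand[withProt])
      # genomic fragments have a lower translated-search success rate; keep a
      # random 60% of them
      selG <- runif(length(withProt)) < 0.6
      rows$gen <- mk(fragKey[selG], "genome", selG)
    }
    # DNAs without a significant protein hit: half absent from the table,
    # half present with a non-significant E-value
    noProt <- which(!truth$hasProtein[mappable])
    if (length(noProt)) {
      weak <- noProt[runif(length(noProt)) < 0.5]
      if (length(weak))
        rows$weak <- data.frame(
          dnaId = ids[weak], dataset = ifelse(truth$inNcbi[mappable][weak],
                                              "ncbi", "ensembl"),
          proteinId = sprintf("prot%05d", mappable[weak]),
          evalue = 10^-runif(length(weak), 1, 4.5),
          proteinOrientation = "+",
          geneSymbol = truth$geneSymbol[mappable[weak]],
          goTerms = "", stringsAsFactors = FALSE)
    }
    blastx <- S4Vectors::DataFrame(do.call(rbind, rows))

    tt <- S4Vectors::DataFrame(
      tag = truth$tags, transcript = seq_len(n),
      baseFreq = truth$baseFreq, deClass = truth$deClass,
      unmappable = truth$unmappable, antisense = truth$antisense,
      inNcbi = truth$inNcbi, inEnsembl = truth$inEnsembl,
      hasProtein = truth$hasProtein, geneSymbol = truth$geneSymbol,
      dnaId = NA_character_, genomeChrom = NA_character_,
      genomeStart = NA_integer_, strand = NA_character_)
    tt$dnaId[mappable] <- ids
    tt$genomeChrom[mappable] <- genomeChrom
    tt$genomeStart[mappable] <- genomeTagStart
    tt$strand[mappable] <- tagStrand
    tt$nGenomicLocations <- ifelse(tt$unmappable, 0L, 1L)
    tt$nGenomicLocations[mappable[dupSel]] <- 2L

    new("ReferenceSet", ncbi = ncbi, ensembl = ensembl, genome = genome,
        blastx = blastx, truth = tt)
  })
}

# ---------------------------------------------------------------------------
# Ditag read generation
# ---------------------------------------------------------------------------

#' Generate ditag reads encoding a tag-count matrix
#'
#' Each sequenced unit is \code{linker + tagA + reverseComplement(tagB) +
#' reverseComplement(linker)}, pairing the 26-nt tags (CATG + printed 22 nt)
#' of one library uniformly at random without replacement.  Coincidentally
#' identical pairings are re-paired, so genuine ditags are unique within a
#' library and exact duplicates arise only from \code{duplicateDitagRate}
#' (the PCR/emulsion-duplicate reading of the deduplication QC step).  The
#' remaining corruption rates produce reads with truncated 5' linkers,
#' internal linker contamination and ambiguous bases; each read carries its
#' intended QC outcome in \code{qcTruth}.
#'
#' With all corruption rates zero, [demultiplexReads()] +
#' [extractMonotags()] reproduce \code{emittedCounts} exactly.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param counts a \linkS4class{TagCountMatrix} whose libraries match the
#'   configuration.
#' @return a list with \code{reads} (a \code{DataFrame}: id, library,
#'   sequence, qcTruth, erroneous), \code{emittedCounts} (the integer matrix
#'   encoded in all genuine ditags; it differs from \code{tagCounts(counts)}
#'   only when a library total is odd, in which case one random tag instance
#'   cannot be paired) and \code{passCounts} (the counts encoded in reads
#'   whose intended QC outcome is \code{pass}; with
#'   \code{sequencingErrorRate = 0}, extraction of the demultiplexed stream
#'   reproduces \code{passCounts} exactly).
#' @export
generateDitagReads <- function(config, counts) {
  libs <- libraryNames(counts)
  if (!all(libs %in% config@libraryNames))
    stop("count matrix contains libraries unknown to the configuration: ",
         paste(setdiff(libs, config@libraryNames), collapse = ", "))
  if (any(tagCounts(counts) < 0)) stop("counts must be nonnegative")
  linkers <- setNames(config@linkers, config@libraryNames)[libs]
  M <- tagCounts(counts)
  tags26 <- paste0("CATG", rownames(M))
  emitted <- M
  passCounts <- matrix(0L, nrow(M), ncol(M), dimnames = dimnames(M))

  withSeed(config@seed + 3L, {
    out <- vector("list", length(libs))
    for (j in seq_along(libs)) {
      lib <- libs[j]; L <- linkers[[j]]
      reps <- rep.int(seq_len(nrow(M)), M[, j])
      if (length(reps) %% 2L == 1L) {       # odd totals leave one tag unpaired
        drop <- sample(length(reps), 1L)
        emitted[reps[drop], j] <- emitted[reps[drop], j] - 1L
        reps <- reps[-drop]
      }
      nd <- length(reps) %/% 2L
      if (nd == 0L) { out[[j]] <- NULL; next }
      reps <- reps[sample.int(length(reps))]
      A <- reps[seq_len(nd)]; B <- reps[nd + seq_len(nd)]
      # re-pair coincidental duplicates (identical ordered tag pairs)
      for (iter in seq_len(100L)) {
        key <- paste(A, B)
        dup <- which(duplicated(key))
        if (!length(dup)) break
        swap <- sample(nd, length(dup), replace = TRUE)
        tmp <- B[dup]; B[dup] <- B[swap]; B[swap] <- tmp
      }
      key <- paste(A, B)
      if (anyDuplicated(key)) {             # irreparable: drop extra copies
        dup <- which(duplicated(key))
        for (d in dup) {
          emitted[A[d], j] <- emitted[A[d], j] - 1L
          emitted[B[d], j] <- emitted[B[d], j] - 1L
        }
        A <- A[-dup]; B <- B[-dup]; nd <- length(A)
      }
      interior <- paste0(tags26[A], revComp(tags26[B]))
      qc <- rep("pass", nd); err <- rep(FALSE, nd)

      nInc <- round(config@incompleteLinkerRate * nd)
      nInt <- round(config@contaminatedLinkerRate * nd)
      nAmb <- round(config@ambiguousBaseRate * nd)
      pick <- sample(nd, min(nd, nInc + nInt + nAmb))
      iInc <- head(pick, nInc)
      iInt <- head(pick[-seq_len(min(length(pick), nInc))], nInt)
      iAmb <- utils::tail(pick, max(0L, length(pick) - nInc - nInt))
      if (length(iInt)) {                   # linker copy inside the ditag
        at <- sample(seq_len(51L), length(iInt), replace = TRUE)
        interior[iInt] <- paste0(substr(interior[iInt], 1L, at), L,
                                 substr(interior[iInt], at + 1L, 52L))
        qc[iInt] <- "internal_linker"
      }
      if (length(iAmb)) {
        at <- sample(seq_len(52L), length(iAmb), replace = TRUE)
        substr(interior[iAmb], at, at) <- "N"
        qc[iAmb] <- "ambiguous_base"
      }
      if (config@sequencingErrorRate > 0) {
        clean <- setdiff(seq_len(nd), c(iInc, iInt, iAmb))
        nerr <- rbinom(length(clean), 52L, config@sequencingErrorRate)
        hit <- clean[nerr > 0L]
        for (i in hit) {
          at <- sample(52L, nerr[match(i, clean)])
          for (a in at) {
            old <- substr(interior[i], a, a)
            substr(interior[i], a, a) <-
              sample(setdiff(DNA_BASES_CHR, old), 1L)
          }
          err[i] <- TRUE
        }
      }
      reads <- paste0(L, interior, revComp(L))
      if (length(iInc)) {                   # truncate the 5' linker
        cut <- sample(seq_len(nchar(L) - 1L), length(iInc), replace = TRUE)
        reads[iInc] <- substring(reads[iInc], cut + 1L)
        qc[iInc] <- "incomplete_linker"
      }
      keep <- which(qc == "pass")
      passTab <- table(factor(c(A[keep], B[keep]), levels = seq_len(nrow(M))))
      passCounts[, j] <- passCounts[, j] + as.integer(passTab)
      ndup <- round(config@duplicateDitagRate * nd)
      cleanPass <- which(qc == "pass")
      dupFrom <- if (ndup > 0L && length(cleanPass))
        sample(cleanPass, ndup, replace = TRUE) else integer(0)
      seqs <- c(reads, reads[dupFrom])
      out[[j]] <- data.frame(
        id = sprintf("%s_read%06d", lib, seq_along(seqs)),
        library = lib, sequence = seqs,
        qcTruth = c(qc, rep("duplicate", length(dupFrom))),
        erroneous = c(err, err[dupFrom]), stringsAsFactors = FALSE)
    }
    reads <- S4Vectors::DataFrame(do.call(rbind, out))
    list(reads = reads, emittedCounts = emitted, passCounts = passCounts)
  })
}

#' Write simulated reads or references as FASTA
#'
#' @param x reads `DataFrame` from [generateDitagReads()] or a named character
#'   vector / `DNAStringSet`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFasta <- function(x, file) {
  if (is(x, "DataFrame") || is.data.frame(x))
    x <- setNames(as.character(x$sequence), x$id)
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
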