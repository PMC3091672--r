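naiveScan <- function(tags, seqs) {
  # brute-force substring scan on both strands
  out <- list()
  for (tg in tags) {
    q <- paste0("CATG", tg)
    rq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    for (id in names(seqs)) {
      s <- seqs[[id]]
      for (st in c("+", "-")) {
        pat <- if (st == "+") q else rq
        at <- gregexpr(pat, s, fixed = TRUE)[[1]]
        if (at[1] > 0)
          out[[length(out) + 1]] <- data.frame(
            tag = tg, seqId = id, start = as.integer(at), strand = st,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(0), seqId = character(0),
               start = integer(0), strand = character(0))
}

test_that("exact-match mapping equals a naive substring scan on both strands", {
  cfg <- refConfig(seed = 19, n = 250)
  ref <- generateReference(cfg)
  tt <- ref@truth
  withr::with_seed(3, {
    queried <- c(sample(tt$tag, 150), randomTags(100, seed = 44))
  })
  idx <- list(ncbi = buildTagIndex(ref@ncbi, "ncbi"))
  hits <- mapTags(queried, idx)
  seqs <- as.character(ref@ncbi)
  oracle <- naiveScan(queried, seqs)
  got <- as.data.frame(hits)[, c("tag", "seqId", "start", "strand")]
  keyG <- sort(paste(got$tag, got$seqId, got$start, got$strand))
  keyO <- sort(paste(oracle$tag, oracle$seqId, oracle$start, oracle$strand))
  expect_identical(keyG, keyO)
})

test_that("strand, stringency and coordinates follow the mapping contract", {
  tag <- randomTags(1, seed = 61)
  tag26 <- paste0("CATG", tag)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  sense <- paste0(randomTags(1, seed = 62), tag26, "TT",
                  randomTags(1, seed = 63))
  anti <- paste0(randomTags(1, seed = 64), rc(tag26),
                 randomTags(1, seed = 65))
  idx <- buildTagIndex(c(sense = sense, anti = anti), "ncbi")
  hits <- as.data.frame(mapTags(tag, idx))
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$strand[hits$seqId == "sense"], "+")
  expect_identical(hits$strand[hits$seqId == "anti"], "-")
  expect_identical(hits$start[hits$seqId == "sense"], 23L)  # after 22-nt 5' UTR
  expect_identical(substr(sense, hits$start[1], hits$end[1]), tag26)

  # one mismatch at 26-mer position 25: lost at 26/26, rescued at 24/24
  mut <- tag26
  substr(mut, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 25, 25))[1]
  idx2 <- buildTagIndex(c(m = paste0("GGGG", mut, "GGGG")), "ncbi")
  expect_identical(nrow(mapTags(tag, idx2, stringency = 26)), 0L)
  expect_identical(nrow(mapTags(tag, idx2, stringency = 24)), 1L)

  expect_error(mapTags("ACGTN", idx), "A/C/G/T")
})

test_that("upstream fragments are strand-aware and truncate at boundaries", {
  withr::with_seed(71, {
    chrom <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  })
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  # plus strand: hit starting at 1501 -> fragment covers [501, 1500]
  fr <- extractUpstreamFragment(genome, "chr1", 1501, 1526, "+", length = 1000)
  expect_identical(fr$fragment, substr(chrom, 501, 1500))
  expect_false(fr$truncated)
  # near the boundary: only 200 nt available
  fr2 <- extractUpstreamFragment(genome, "chr1", 201, 226, "+", length = 1000)
  expect_identical(fr2$length, 200L)
  expect_true(fr2$truncated)
  # minus strand: reverse complement of the 1000 nt 3' of the site
  fr3 <- extractUpstreamFragment(genome, "chr1", 501, 526, "-", length = 1000)
  naive <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 527, 1526))))
  expect_identical(fr3$fragment, naive)
})

test_that("protein assignment follows the dataset hierarchy and E-value thresholds", {
  hits <- data.frame(
    tag = "T", dataset = c("ncbi", "genome"), seqId = c("cdna1", "chr1"),
    start = c(10L, 500L), end = c(35L, 525L), strand = "+",
    stringsAsFactors = FALSE)
  bx <- data.frame(
    dnaId = c("cdna1", "chr1:500:+"), dataset = c("ncbi", "genome"),
    proteinId = c("protA", "protB"), evalue = c(1e-20, 1e-40),
    proteinOrientation = "+", geneSymbol = c("ga", "gb"),
    goTerms = c("P:GO:0000001", ""), stringsAsFactors = FALSE)
  asg <- assignProtein(hits, bx)
  expect_identical(asg$proteinId, "protA")     # curated cDNA wins over genome
  expect_identical(asg$goTerms, "P:GO:0000001")

  # E-value above threshold: no assignment
  bx2 <- transform(bx, evalue = c(1e-3, 1e-3))
  expect_null(assignProtein(hits, bx2))

  # tie break within a dataset: lowest E, then lexicographic protein id
  hits2 <- data.frame(tag = "T", dataset = "ncbi",
                      seqId = c("c1", "c2", "c3"), start = 1L, end = 26L,
                      strand = "+", stringsAsFactors = FALSE)
  bx3 <- data.frame(dnaId = c("c1", "c2", "c3"), dataset = "ncbi",
                    proteinId = c("pZ", "pA", "pB"),
                    evalue = c(1e-30, 1e-30, 1e-20),
                    proteinOrientation = "+", geneSymbol = "g",
                    goTerms = "", stringsAsFactors = FALSE)
  expect_identical(assignProtein(hits2, bx3)$proteinId, "pA")
})

test_that("antisense detection flags orientation discordance", {
  expect_false(detectAntisense("+", "+"))
  expect_true(detectAntisense("-", "+"))
  expect_true(detectAntisense("+", "-"))
})

test_that("full annotation agrees with simulation truth", {
  cfg <- refConfig(seed = 29, n = 400, unmappableFraction = 0.35,
                   antisenseFraction = 0.1)
  ref <- generateReference(cfg)
  tt <- ref@truth
  ann <- annotateTags(tt$tag, ref)
  expect_identical(ann$tag, tt$tag)
  # mapped/unmapped status agrees exactly with planted mappability
  expect_identical(ann$status == "unannotated", as.logical(tt$unmappable))
  # protein-annotated tags carry the planted protein and gene
  prot <- which(ann$status == "annotated_protein" & !ann$ambiguous)
  expect_gt(length(prot), 50)
  expect_identical(ann$geneSymbol[prot], tt$geneSymbol[prot])
  # antisense flags match the planted orientation for annotated tags
  expect_identical(ann$antisense[prot], as.logical(tt$antisense[prot]))
  flagged <- mean(tt$antisense[!tt$unmappable])
  expect_lt(abs(flagged - 0.1),
            4 * sqrt(0.1 * 0.9 / sum(!tt$unmappable)))
  # multi-location tags are flagged ambiguous
  expect_true(all(ann$ambiguous[ann$nGenomicLocations > 1L]))
})

test_that("annotation summaries reproduce the printed report arithmetic", {
  records <- data.frame(
    status = c(rep("annotated_protein", 497), rep("anonymous_dna", 372),
               rep("unannotated", 470)),
    geneSymbol = NA_character_, antisense = FALSE,
    stringsAsFactors = FALSE)
  s <- annotationSummary(records)
  expect_equal(s$blastn$matched, 869)
  expect_equal(s$blastn$total, 1339)
  expect_equal(s$blastn$pctMatched, 64.9)
  expect_equal(s$blastx$pctAssigned, 57.2)
  expect_equal(s$global$pctUnannotated, 35.1)

  none <- data.frame(status = rep("unannotated", 10),
                     geneSymbol = NA_character_, antisense = FALSE)
  s0 <- annotationSummary(none)
  expect_equal(s0$blastn$pctMatched, 0)
  expect_equal(s0$genes$n, 0)
})
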