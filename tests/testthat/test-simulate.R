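test_that("identical configuration and seed give identical outputs", {
  cfg <- flatConfig(seed = 11)
  a <- generateCountMatrix(cfg)
  b <- generateCountMatrix(cfg)
  expect_identical(tagCounts(a$counts), tagCounts(b$counts))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))

  rcfg <- refConfig(seed = 5, n = 300)
  r1 <- generateReference(rcfg)
  r2 <- generateReference(rcfg)
  expect_identical(as.character(r1@ncbi), as.character(r2@ncbi))
  expect_identical(as.character(r1@genome), as.character(r2@genome))

  d1 <- generateDitagReads(cfg, a$counts)
  d2 <- generateDitagReads(cfg, b$counts)
  expect_identical(as.data.frame(d1$reads), as.data.frame(d2$reads))
})

test_that("count matrices conserve depths and record a unique truth row per tag", {
  cfg <- simulationConfig(nTranscripts = 5000, libraryDepths = rep(8000, 5),
                          deFraction = 0.05, deMinFreq = 5e-4, seed = 21)
  sim <- generateCountMatrix(cfg)
  expect_equal(unname(libraryTotals(sim$counts)), cfg@libraryDepths)
  expect_false(anyDuplicated(sim$truth$tag) > 0)
  expect_setequal(sim$truth$tag, tagSequences(sim$counts))
  # every planted tag has exactly one class with fold and direction recorded
  planted <- sim$truth[sim$truth$deClass > 0L, ]
  expect_true(all(planted$deClass %in% 1:4))
  expect_true(all(planted$fold >= cfg@deFoldRange[1]))
  expect_true(all(planted$direction %in% c("up", "down")))
  # class proportions follow the configured mix within multinomial error
  mix <- table(factor(planted$deClass, levels = 1:4)) / nrow(planted)
  expect_true(all(abs(mix - 0.25) < 4 * sqrt(0.25 * 0.75 / nrow(planted))))
})

test_that("null configurations plant no expression differences", {
  cfg <- flatConfig(seed = 9)
  sim <- generateCountMatrix(cfg)
  ef <- sim$truth$expectedFreq
  expect_true(all(abs(ef - ef[, 1]) < 1e-12))
})

test_that("unmappable fraction matches its binomial draw", {
  cfg <- refConfig(seed = 13, n = 1000, unmappableFraction = 0.35)
  ref <- generateReference(cfg)
  frac <- mean(ref@truth$unmappable)
  expect_lt(abs(frac - 0.35), 4 * sqrt(0.35 * 0.65 / 1000))
  # unmappable transcripts are absent from every dataset
  expect_true(all(is.na(ref@truth$dnaId[ref@truth$unmappable])))
})

test_that("references anchor every tag at the 3'-most CATG and embed cDNAs in the genome", {
  cfg <- refConfig(seed = 17, n = 300, antisenseFraction = 0,
                   unmappableFraction = 0)
  ref <- generateReference(cfg)
  tt <- ref@truth
  seqs <- as.character(c(ref@ncbi, ref@ensembl))
  genome <- paste(as.character(ref@genome), collapse = "\n")
  ids <- intersect(names(seqs), tt$dnaId)
  for (id in sample(ids, 40)) {
    s <- seqs[[id]]
    tag26 <- paste0("CATG", tt$tag[match(id, tt$dnaId)])
    # the 26-mer is present and its CATG is the last occurrence
    at <- gregexpr(tag26, s, fixed = TRUE)[[1]]
    expect_true(at[1] > 0)
    lastCATG <- max(gregexpr("CATG", s, fixed = TRUE)[[1]])
    expect_identical(lastCATG, at[length(at)])
    expect_true(grepl(s, genome, fixed = TRUE))
  }
  # with no antisense and no unmappable transcripts, every truth strand is +
  expect_true(all(tt$strand == "+"))
})

test_that("ditag corruption rates are realized and bookkept", {
  cfg <- flatConfig(seed = 23, depth = 2000)
  cfg@duplicateDitagRate <- 0.2
  cfg@ambiguousBaseRate <- 0.05
  cfg@contaminatedLinkerRate <- 0.05
  cfg@incompleteLinkerRate <- 0.05
  sim <- generateCountMatrix(flatConfig(seed = 23, depth = 2000))
  rd <- generateDitagReads(cfg, sim$counts)
  qc <- table(rd$reads$qcTruth)
  nd <- sum(rd$emittedCounts) / 2
  expect_equal(unname(qc[["duplicate"]]), round(0.2 * nd / 5) * 5,
               tolerance = 0.02)
  # every ambiguous base sits in a read flagged as QC-discardable
  hasN <- grepl("N", rd$reads$sequence, fixed = TRUE)
  expect_true(all(rd$reads$qcTruth[hasN] == "ambiguous_base"))
  # duplicate reads are byte-copies of a pass read from the same library
  dups <- rd$reads[rd$reads$qcTruth == "duplicate", ]
  pass <- rd$reads[rd$reads$qcTruth == "pass", ]
  key <- paste(pass$library, pass$sequence)
  expect_true(all(paste(dups$library, dups$sequence) %in% key))
})

test_that("the abundance law reproduces the sequencing-scale singleton regime", {
  # single deep library; no planting
  singleton <- vapply(1:5, function(s) {
    cfg <- simulationConfig(libraryNames = "L1", libraryDepths = 68875,
                            deFraction = 0, linkers = defaultLinkers(1),
                            seed = 100 + s)
    sim <- generateCountMatrix(cfg)
    ss <- summarizeLibrary(sim$counts, "L1")
    ss$abundanceClasses[["1"]] / ss$unitags
  }, numeric(1))
  expect_true(all(singleton > 0.69 - 0.05 & singleton < 0.69 + 0.05))
  expect_gt(mean(singleton), 0.60)
  expect_lt(mean(singleton), 0.78)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(libraryDepths = rep(-1, 5)), "positive")
  expect_error(simulationConfig(nTranscripts = 0), "positive")
  expect_error(simulationConfig(duplicateDitagRate = 1.5), "rates")
  expect_error(simulationConfig(deFoldRange = c(1.5, 3)), ">= 2")
  expect_error(simulationConfig(libraryNames = c("A", "B"),
                                libraryDepths = c(100, 100),
                                linkers = c("TTCCGGAACCTAGT",
                                            "TTCCGGAACCTAGT")),
               "distinct")
  # planting the four classes needs the five role libraries
  expect_error(simulationConfig(libraryNames = c("A", "B"),
                                libraryDepths = c(100, 100),
                                deFraction = 0.1),
               "role")
})
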