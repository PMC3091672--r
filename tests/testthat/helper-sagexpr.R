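# Shared fixtures, all generated in code.

# a small, flat-abundance configuration for exact round-trip / QC tests
# (flat enough that uniform ditag pairing is always feasible)
flatConfig <- function(seed = 3, depth = 2000, ...) {
  simulationConfig(nTranscripts = 2000, libraryDepths = rep(depth, 5),
                   abundanceSdlog = 1.2, deFraction = 0,
                   duplicateDitagRate = 0, contaminatedLinkerRate = 0,
                   incompleteLinkerRate = 0, ambiguousBaseRate = 0,
                   seed = seed, ...)
}

# annotation-scale configuration: small transcriptome, sequences feasible
refConfig <- function(seed = 7, n = 800, ...) {
  simulationConfig(nTranscripts = n, libraryDepths = rep(1500, 5),
                   abundanceSdlog = 1.2, deFraction = 0, seed = seed, ...)
}

# null count matrix at sequencing-scale depths: `ntags` tags of equal
# frequency, multinomially sampled per library
nullMatrix <- function(ntags = 10000, depths = c(C2h = 65378, LowCa2h = 87388,
                                                 C12h = 67996,
                                                 HighCa12h = 60142,
                                                 LowCa12h = 63471),
                       seed = 1) {
  withr::with_seed(seed, {
    m <- vapply(depths, function(d) rmultinom(1, d, rep(1, ntags))[, 1L],
                integer(ntags))
    rownames(m) <- paste0("tag", seq_len(ntags))
    m
  })
}

# expected-frequency matrix for planted single-class tags over the five
# role libraries; `cls` in 1:4, random direction
plantedMatrix <- function(nPlanted = 1000, cls = 1, fold = 10,
                          baseFreq = 4e-4, depth = 70000, seed = 1) {
  roles <- c("C2h", "LowCa2h", "C12h", "HighCa12h", "LowCa12h")
  withr::with_seed(seed, {
    up <- sample(c(TRUE, FALSE), nPlanted, TRUE)
    f1 <- ifelse(up, baseFreq * fold, baseFreq / fold)
    FR <- matrix(baseFreq, nPlanted, 5, dimnames = list(NULL, roles))
    if (cls == 1) { FR[, "LowCa2h"] <- f1; FR[, "LowCa12h"] <- f1 }
    if (cls == 2) {
      tp <- sample(c("LowCa2h", "LowCa12h"), nPlanted, TRUE)
      FR[cbind(seq_len(nPlanted), match(tp, roles))] <- f1
    }
    if (cls == 3) {
      FR[, "LowCa12h"] <- f1
      FR[, "HighCa12h"] <- ifelse(up, baseFreq / fold, baseFreq * fold)
    }
    if (cls == 4) { FR[, "LowCa12h"] <- f1; FR[, "HighCa12h"] <- f1 }
    m <- vapply(seq_len(5), function(j) rbinom(nPlanted, depth, FR[, j]),
                integer(nPlanted))
    dimnames(m) <- list(paste0("tag", seq_len(nPlanted)), roles)
    m
  })
}

# six well-separated expression patterns over five libraries with
# count-sampling noise, in the size regime of a clustering analysis
sixPatternProfiles <- function(seed, n = 1200, depth = 100) {
  withr::with_seed(seed, {
    pat <- rbind(c(80, 5, 5, 5, 5), c(5, 80, 5, 5, 5), c(5, 5, 80, 5, 5),
                 c(5, 5, 5, 80, 5), c(5, 5, 5, 5, 80), c(20, 20, 20, 20, 20))
    z <- sample(6, n, TRUE)
    cnt <- matrix(rpois(n * 5, depth * pat[z, ] / 100), n)
    cnt[rowSums(cnt) == 0, 1] <- 1L
    P <- 100 * cnt / rowSums(cnt)
    rownames(P) <- paste0("t", seq_len(n))
    list(profiles = P, truth = z)
  })
}

# abundance-class library column: counts realizing given class counts and,
# optionally, an exact library total (absorbed into the >100 class)
abundanceColumn <- function(n1, n24, n59, n10, n100, total = NULL) {
  counts <- c(rep(1L, n1), rep(2L, n24), rep(5L, n59), rep(10L, n10))
  if (n100 > 0) {
    if (is.null(total)) {
      counts <- c(counts, rep(101L, n100))
    } else {
      rest <- total - sum(counts)
      base <- rest %/% n100
      extra <- rest - base * n100
      big <- rep(base, n100)
      big[1] <- big[1] + extra
      stopifnot(all(big > 100))
      counts <- c(counts, as.integer(big))
    }
  }
  counts
}

randomTags <- function(n, len = 22, seed = NULL) {
  draw <- function() {
    m <- matrix(sample(c("A", "C", "G", "T"), n * len, TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  f <- function() {
    tags <- draw()
    while (anyDuplicated(tags) || any(grepl("CATG", tags, fixed = TRUE))) {
      bad <- duplicated(tags) | grepl("CATG", tags, fixed = TRUE)
      sub <- matrix(sample(c("A", "C", "G", "T"), sum(bad) * len, TRUE),
                    nrow = sum(bad))
      tags[bad] <- do.call(paste0, as.data.frame(sub,
                                                 stringsAsFactors = FALSE))
    }
    tags
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}
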