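test_that("profile normalization produces percent shares", {
  P <- normalizeProfiles(rbind(c(10, 30, 60), c(0, 0, 5)))
  expect_equal(P[1, ], c(10, 30, 60))
  expect_equal(P[2, ], c(0, 0, 100))
  withr::with_seed(2, {
    Q <- normalizeProfiles(matrix(runif(300, 0.1, 5), 60))
    expect_equal(rowSums(Q), rep(100, 60))
  })
  expect_error(normalizeProfiles(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("K-means honours the basic contracts", {
  d <- sixPatternProfiles(1, n = 300)
  # K = 1: a single cluster whose centroid is the global mean
  m1 <- chisqKmeans(d$profiles, 1, seed = 1, nRestarts = 2)
  expect_true(all(clusterAssignments(m1) == 1L))
  expect_equal(unname(clusterCentroids(m1)[1, ]),
               unname(colMeans(d$profiles)))
  # duplicated profiles always co-cluster (distance zero)
  P <- d$profiles[rep(1:30, each = 4), ]
  rownames(P) <- paste0("p", seq_len(nrow(P)))
  m <- chisqKmeans(P, 3, seed = 2, nRestarts = 5)
  grp <- matrix(clusterAssignments(m), nrow = 4)
  expect_true(all(apply(grp, 2, function(v) length(unique(v)) == 1L)))
  # determinism and restart dominance
  mA <- chisqKmeans(d$profiles, 4, seed = 9, nRestarts = 10)
  mB <- chisqKmeans(d$profiles, 4, seed = 9, nRestarts = 10)
  expect_identical(clusterAssignments(mA), clusterAssignments(mB))
  mSingle <- chisqKmeans(d$profiles, 4, seed = 10, nRestarts = 1)
  expect_lte(mA@withinDispersion, mSingle@withinDispersion)
  expect_error(chisqKmeans(d$profiles, nrow(d$profiles) + 1), "k must lie")
})

test_that("two well-separated planted groups are recovered exactly", {
  skip_if_not_installed("mclust")
  withr::with_seed(5, {
    pat <- rbind(c(70, 10, 10, 5, 5), c(5, 5, 10, 10, 70))
    z <- rep(1:2, each = 150)
    cnt <- matrix(rpois(300 * 5, 80 * pat[z, ] / 100), 300)
    cnt[rowSums(cnt) == 0, 1] <- 1L
    P <- normalizeProfiles(cnt)
    rownames(P) <- paste0("t", 1:300)
  })
  m <- chisqKmeans(P, 2, seed = 3, nRestarts = 10)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(m), z), 1)
})

test_that("the Gap statistic selects one cluster for unstructured data", {
  withr::with_seed(11, {
    blob <- matrix(rnorm(400 * 4, 25, 1.5), 400)
    blob[blob < 0.1] <- 0.1
    blob <- normalizeProfiles(blob)
    rownames(blob) <- paste0("t", 1:400)
  })
  gap <- gapStatistic(blob, kRange = 1:5, B = 15, seed = 4, nRestarts = 5)
  expect_identical(selectedK(gap), 1L)
  expect_true(all(is.finite(gap@gap)))
  # degenerate data: all profiles identical
  same <- matrix(25, 50, 4, dimnames = list(paste0("t", 1:50), NULL))
  expect_identical(selectedK(gapStatistic(same, kRange = 1:4, B = 10)), 1L)
  expect_error(gapStatistic(blob, B = 5), "10")
})

test_that("cross-tabulation counts shared tags with zero rows for absentees", {
  a <- setNames(c(1L, 1L, 2L, 2L, 3L), paste0("t", 1:5))
  # identical partitions give a diagonal table
  ct <- crossTabulate(a, a)
  off <- ct[-1, -1]
  expect_equal(sum(off) - sum(diag(off)), 0)
  expect_equal(diag(off), c(`1` = 2L, `2` = 2L, `3` = 1L), ignore_attr = TRUE)
  # disjoint tag sets put all mass in row/column zero
  b <- setNames(c(1L, 2L), c("u1", "u2"))
  ct2 <- crossTabulate(a, b)
  expect_equal(sum(ct2["0", ]), 2)
  expect_equal(sum(ct2[, "0"]), 5)
  expect_equal(sum(ct2), 7)
  # random overlapping partitions equal brute-force pair counting
  withr::with_seed(21, {
    ta <- paste0("t", sample(40, 30)); tb <- paste0("t", sample(40, 30))
    pa <- setNames(sample(3, 30, TRUE), ta)
    pb <- setNames(sample(4, 30, TRUE), tb)
  })
  ct3 <- crossTabulate(pa, pb)
  for (i in 0:3) for (j in 0:4) {
    tags <- union(names(pa), names(pb))
    ai <- ifelse(tags %in% names(pa), pa[tags], 0L)
    bi <- ifelse(tags %in% names(pb), pb[tags], 0L)
    expect_equal(ct3[as.character(i), as.character(j)],
                 sum(ai == i & bi == j), ignore_attr = TRUE)
  }
  expect_equal(sum(ct3), length(union(names(pa), names(pb))))
})

test_that("cluster-size summaries pool models as reported", {
  # 1,208 + 1,098 tags in six clusters each: mean size 192 after rounding
  withr::with_seed(31, {
    a <- sample(6, 1208, TRUE)
    b <- sample(6, 1098, TRUE)
  })
  s <- summarizeClusters(list(a, b))
  expect_equal(round(s$mean), 192)
  expect_equal(sum(unlist(s$sizes)), 2306)
  # single cluster: mean n, SD 0
  s1 <- summarizeClusters(rep(1L, 17))
  expect_equal(s1$mean, 17)
  expect_equal(s1$sd, 0)
})

test_that("tag selection applies the analysis inclusion rules", {
  roles <- c(C2h = "C2h", LowCa2h = "LowCa2h", C12h = "C12h",
             HighCa12h = "HighCa12h", LowCa12h = "LowCa12h")
  m <- nullMatrix(ntags = 8, seed = 3)
  rownames(m) <- paste0("t", 1:8)
  de <- S4Vectors::DataFrame(
    tag = rownames(m),
    class1 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    class2 = FALSE,
    class3 = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    class4 = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    retained = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # tag 2: class-3 only -> excluded from the low-calcium analysis but kept
  # in the 12 h analysis
  lowca <- selectClusterTags(de, m, "lowca")
  h12 <- selectClusterTags(de, m, "12h")
  expect_false("t2" %in% rownames(lowca))
  expect_true("t2" %in% rownames(h12))
  expect_false("t8" %in% rownames(h12))      # not retained
  expect_identical(colnames(lowca), c("C2h", "LowCa2h", "C12h", "LowCa12h"))
  expect_identical(colnames(h12), c("C12h", "LowCa12h", "HighCa12h"))
  # all-zero tags over the analysis libraries are dropped
  m2 <- m; m2["t4", c("C12h", "LowCa12h", "HighCa12h")] <- 0L
  expect_false("t4" %in% rownames(selectClusterTags(de, m2, "12h")))
})
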