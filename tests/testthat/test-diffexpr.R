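test_that("the pairwise Z-test matches its closed form and is antisymmetric", {
  expect_equal(zTest(5, 100, 5, 100)$z, 0)
  expect_equal(zTest(5, 100, 5, 100)$p, 1)
  expect_equal(zTest(0, 100, 0, 100)$z, 0)
  expect_equal(zTest(0, 100, 0, 100)$p, 1)

  # hand-evaluated closed form at sequencing-scale totals
  c1 <- 5; n1 <- 65378; c2 <- 50; n2 <- 87388
  p0 <- (c1 + c2) / (n1 + n2)
  zExp <- (c1 / n1 - c2 / n2) / sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  zt <- zTest(c1, n1, c2, n2)
  expect_equal(zt$z, zExp, tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-abs(zExp)), tolerance = 1e-12)

  withr::with_seed(4, {
    a <- rpois(200, 8); b <- rpois(200, 8)
    expect_equal(zTest(a, 5000, b, 6000)$z, -zTest(b, 6000, a, 5000)$z)
  })
  expect_error(zTest(5, 0, 1, 10), "positive")
})

test_that("replicated G-tests are additive, nonnegative and calibrated on planted tables", {
  withr::with_seed(8, {
    M <- matrix(rpois(4000, 6), ncol = 4)
    totals <- colSums(M) + round(runif(4, 50000, 90000))
    g <- gTest(M[1, ], totals, list(1:2, 3:4))
    expect_equal(g$dfTotal, 3L)
    expect_equal(g$dfPooled + g$dfHeterogeneity, g$dfTotal)
    gm <- sagexpr:::gTestMatrix(M, totals, list(1:2, 3:4))
    expect_lt(max(abs(gm$Gtotal - (gm$Gpooled + gm$Gheterogeneity))), 1e-9)
    expect_true(all(gm$Gtotal > -1e-9 & gm$Gpooled > -1e-9))
  })

  # identical proportions in all libraries: no rule passes
  g0 <- gTest(c(10, 10, 10, 10), rep(50000, 4), list(1:2, 3:4))
  expect_false(g0$passAllRules)
  expect_lt(g0$Gtotal, 0.01)

  # two groups, within-group identical, 10-fold different between groups
  g1 <- gTest(c(5, 5, 50, 50), rep(70000, 4), list(1:2, 3:4))
  expect_true(g1$passIntrinsic)
  expect_false(g1$failHomogeneity)
  expect_true(g1$passAllRules)
  expect_lt(g1$Gheterogeneity, 1)

  expect_error(gTest(c(1, 2), c(1000, 2000), list("A", "B")), "absent")
})

test_that("zero-substitution fold changes reproduce every checkable printed value", {
  # (control, treatment, printed fold) from the top-regulated tag report
  rows <- rbind(
    c(1, 113, 113), c(0, 38, 110), c(0, 33, 96), c(1, 69, 69), c(0, 23, 67),
    c(0, 20, 58), c(0, 17, 49), c(3, 144, 48), c(0, 15, 43),
    c(0, 12, 35), c(0, 10, 29), c(0, 9, 26), c(0, 8, 23), c(0, 7, 20),
    c(0, 6, 17),
    c(0, 69, 200), c(0, 28, 81), c(0, 13, 38),
    c(21, 0, 61), c(15, 0, 43), c(12, 0, 35), c(11, 0, 32), c(8, 0, 23),
    c(7, 0, 20),
    c(47, 1, 47), c(28, 1, 28), c(9, 0, 26), c(6, 0, 17),
    c(47, 0, 136))
  fc <- foldChange(rows[, 1], rows[, 2])
  expect_identical(fc$fold, rows[, 3])
  expect_identical(fc$direction, ifelse(rows[, 2] >= rows[, 1], "up", "down"))

  expect_equal(foldChange(5, 5)$fold, 1)
  expect_error(foldChange(-1, 3), "nonnegative")

  # independent oracle on random pairs
  withr::with_seed(99, {
    a <- rpois(10000, 3); b <- rpois(10000, 3)
    zs <- 0.345
    a2 <- pmax(a, zs); b2 <- pmax(b, zs)
    oracle <- floor(pmax(a2, b2) / pmin(a2, b2) + 0.5)
    expect_identical(foldChange(a, b)$fold, oracle)
  })
})

test_that("classifyTags assigns no class under equality and rejects lone singletons", {
  m <- nullMatrix(ntags = 50, seed = 2)
  # a flat tag and a singleton observed in exactly one library
  m[1, ] <- c(7L, 9L, 7L, 6L, 7L)
  m[2, ] <- c(0L, 1L, 0L, 0L, 0L)
  de <- classifyTags(m)
  expect_identical(de$deClass[1], "")
  expect_false(de$retained[1])
  expect_false(de$retained[2])
})

test_that("planted classes are recovered without cross-class confusion", {
  for (cls in 1:4) {
    m <- plantedMatrix(nPlanted = 400, cls = cls, seed = 40 + cls)
    de <- classifyTags(m)
    sens <- mean(de[[paste0("class", cls)]])
    expect_gt(sens, 0.85)
    if (cls == 1) {
      # low-calcium tags must not masquerade as the 12 h challenge classes
      expect_lt(mean(de$class3), 0.1)
      expect_lt(mean(de$class4), 0.1)
    }
    expect_gt(mean(de$retained), 0.8)
  }
})

test_that("classification is invariant to library column order", {
  m <- plantedMatrix(nPlanted = 200, cls = 1, seed = 77)
  de1 <- classifyTags(m)
  perm <- m[, c(3, 1, 5, 2, 4)]
  de2 <- classifyTags(perm)
  expect_identical(de1$deClass, de2$deClass)
  expect_identical(de1$retained, de2$retained)
})

test_that("gene-level aggregation sums tag counts per gene", {
  m <- matrix(c(3L, 4L, 1L, 10L, 2L, 0L), 3, 2,
              dimnames = list(randomTags(3, seed = 3), c("A", "B")))
  ann <- setNames(c("g1", "g1", "g2"), rownames(m))
  agg <- geneLevelExpression(m, ann)
  expect_equal(agg["g1", "A"], 7)
  expect_equal(agg["g1", "B"], 12)
  expect_equal(agg["g2", "B"], 0)
  expect_identical(nrow(geneLevelExpression(m, c(x = "g"))), 0L)
})

test_that("fold-change concordance behaves like a Pearson correlation", {
  x <- c(-2, -1, 0.5, 1, 2, 3.5, 4, 5)
  expect_equal(concordanceCorrelation(x, x)$r, 1)
  expect_equal(concordanceCorrelation(x, -x)$r, -1)
  withr::with_seed(12, {
    r <- concordanceCorrelation(rnorm(16), rnorm(16))
    expect_lt(abs(r$r), 0.5)
    expect_gt(r$p, 0.05)
  })
  expect_error(concordanceCorrelation(rep(1, 5), rnorm(5)), "constant")
})
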