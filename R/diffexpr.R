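#' Pairwise two-proportion Z-test for tag counts
#'
#' The classical SAGE pairwise test: for tag counts \eqn{c_1, c_2} in
#' libraries of \eqn{n_1, n_2} total tags,
#' \deqn{z = \frac{c_1/n_1 - c_2/n_2}{\sqrt{p_0 (1-p_0)(1/n_1 + 1/n_2)}},
#'   \quad p_0 = \frac{c_1 + c_2}{n_1 + n_2},}
#' with a two-sided p-value from the standard normal.  The degenerate case
#' \eqn{c_1 = c_2 = 0} is defined as \eqn{z = 0, p = 1}.
#'
#' @param c1,c2 tag counts (vectorized).
#' @param n1,n2 library totals (positive).
#' @return a \code{DataFrame} with columns \code{z} and \code{p}.
#' @examples
#' zTest(5, 100, 5, 100)    # equal proportions: z = 0, p = 1
#' @export
zTest <- function(c1, n1, c2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  if (any(c1 < 0) || any(c2 < 0) || any(c1 > n1) || any(c2 > n2))
    stop("counts must lie in [0, total]")
  p0 <- (c1 + c2) / (n1 + n2)
  se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  z <- (c1 / n1 - c2 / n2) / se
  z[c1 + c2 == 0] <- 0
  z[!is.finite(z)] <- 0
  S4Vectors::DataFrame(z = z, p = 2 * pnorm(-abs(z)))
}

# vectorized replicated G-test over a tags x libraries count matrix.
# Each tag is a 2 x L table (tag vs all-other-tags); zero tag cells are
# replaced by the zero-substitution constant before expected frequencies are
# formed.  G_total (full table), G_pooled (columns pooled by group) and
# G_heterogeneity (their difference, equal to the sum of within-group G's)
# are exactly additive.
gTestMatrix <- function(M, totals, groups, zeroSub = 0.345, alpha = 0.05) {
  M <- as.matrix(M)
  L <- ncol(M); G <- length(groups)
  if (L < 2L) stop("at least two libraries are required")
  if (any(totals <= 0)) stop("library totals must be positive")
  gidx <- lapply(groups, function(g) {
    if (is.character(g)) match(g, colnames(M)) else as.integer(g)
  })
  if (anyNA(unlist(gidx)))
    stop("design references a library absent from the matrix")
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  Cp <- pmax(M, zeroSub)
  O <- sweep(-Cp, 2, totals, `+`)
  N <- sum(totals)
  r1 <- rowSums(Cp); r2 <- rowSums(O)
  Gtot <- 2 * (rowSums(xlx(Cp)) + rowSums(xlx(O)) - xlx(r1) - xlx(r2) -
                 sum(xlx(totals)) + xlx(N))
  Cg <- vapply(gidx, function(g) rowSums(Cp[, g, drop = FALSE]),
               numeric(nrow(M)))
  Og <- vapply(gidx, function(g) rowSums(O[, g, drop = FALSE]),
               numeric(nrow(M)))
  if (nrow(M) == 1L) { Cg <- matrix(Cg, 1L); Og <- matrix(Og, 1L) }
  ng <- vapply(gidx, function(g) sum(totals[g]), numeric(1))
  Gpool <- 2 * (rowSums(xlx(Cg)) + rowSums(xlx(Og)) - xlx(r1) - xlx(r2) -
                  sum(xlx(ng)) + xlx(N))
  Ghet <- Gtot - Gpool
  dfTot <- L - 1L; dfPool <- G - 1L; dfHet <- L - G
  pTot <- pchisq(pmax(Gtot, 0), dfTot, lower.tail = FALSE)
  pPool <- pchisq(pmax(Gpool, 0), dfPool, lower.tail = FALSE)
  pHet <- if (dfHet > 0)
    pchisq(pmax(Ghet, 0), dfHet, lower.tail = FALSE) else rep(1, nrow(M))
  S4Vectors::DataFrame(
    Gtotal = Gtot, Gpooled = Gpool, Gheterogeneity = Ghet,
    dfTotal = dfTot, dfPooled = dfPool, dfHeterogeneity = dfHet,
    pTotal = pTot, pPooled = pPool, pHeterogeneity = pHet,
    passIntrinsic = pPool < alpha,
    failHomogeneity = dfHet > 0 & pHet < alpha,
    passAllRules = pPool < alpha & pTot < alpha &
      !(dfHet > 0 & pHet < alpha))
}

#' Replicated G-test for one tag across libraries
#'
#' Computes the likelihood-ratio (G) statistic for the 2 x L table of a tag's
#' counts against all other tags, decomposed into a pooled between-group
#' component and a within-group heterogeneity component
#' (\eqn{G_{total} = G_{pooled} + G_{het}} exactly).  Zero tag counts are
#' replaced by the zero-substitution constant before expected frequencies are
#' computed.  `passIntrinsic` records significance of the pooled
#' (between-group) component, `failHomogeneity` significance of the
#' heterogeneity component, and `passAllRules` the full decision-rule set
#' (pooled and total significant, heterogeneity not).
#'
#' @param counts tag count per library (length >= 2).
#' @param totals per-library total tag counts.
#' @param groups list of library index (or name) vectors defining the groups.
#' @param zeroSub zero-substitution constant (default 0.345).
#' @param alpha significance level for the rule flags.
#' @return a one-row \code{DataFrame} with statistics, degrees of freedom,
#'   p-values and rule flags.
#' @examples
#' gTest(c(2, 3, 30, 28), rep(70000, 4), list(1:2, 3:4))
#' @export
gTest <- function(counts, totals, groups, zeroSub = 0.345, alpha = 0.05) {
  gTestMatrix(matrix(counts, nrow = 1L,
                     dimnames = list(NULL, names(counts))),
              totals, groups, zeroSub, alpha)
}

#' Zero-substitution expression ratio and reported fold change
#'
#' The expression ratio is the raw count ratio treatment/control, with the
#' zero-substitution constant (default 0.345) put in place of zero counts
#' before the ratio is formed; no library-size normalization is applied.  The
#' reported fold is \code{max(R, 1/R)} rounded to the nearest integer (half
#' away from zero), with the direction `up` when \eqn{R \ge 1}.
#'
#' @param control,treatment nonnegative integer counts (vectorized).
#' @param zeroSub zero-substitution constant.
#' @return a \code{DataFrame} with columns \code{R}, \code{direction} and
#'   \code{fold}.
#' @examples
#' foldChange(0, 38)$fold    # 110
#' foldChange(21, 0)$fold    # 61
#' @export
foldChange <- function(control, treatment, zeroSub = 0.345) {
  if (any(control < 0) || any(treatment < 0))
    stop("counts must be nonnegative")
  a <- ifelse(control == 0, zeroSub, control)
  b <- ifelse(treatment == 0, zeroSub, treatment)
  R <- b / a
  S4Vectors::DataFrame(R = R,
                       direction = ifelse(R >= 1, "up", "down"),
                       fold = roundHalfUp(pmax(R, 1 / R)))
}

#' The four multi-library comparison designs
#'
#' Returns the library groupings of the four replicated G-tests used for
#' differential-expression calling, in terms of the five library roles:
#' design 1 compares the control group against the low-calcium group across
#' both time points; design 2 the pooled 2 h libraries against the pooled
#' 12 h libraries; design 3 covers the two 12 h challenge contrasts
#' (control vs low calcium and control vs high calcium); design 4 the control
#' against the pooled calcium-altered libraries at 12 h.
#'
#' @param roles named character vector mapping roles
#'   (C2h, LowCa2h, C12h, HighCa12h, LowCa12h) to library names; defaults to
#'   the identity mapping.
#' @return a named list of designs, each a list of library-name groups.
#' @export
sageDesigns <- function(roles = NULL) {
  r <- if (is.null(roles)) setNames(sageRoles(), sageRoles()) else roles
  list(
    GTest1 = list(Control = unname(r[c("C2h", "C12h")]),
                  LowCa = unname(r[c("LowCa2h", "LowCa12h")])),
    GTest2 = list(H2 = unname(r[c("C2h", "LowCa2h")]),
                  H12 = unname(r[c("C12h", "LowCa12h")])),
    GTest3 = list(CvsLow12 = unname(r[c("C12h", "LowCa12h")]),
                  CvsHigh12 = unname(r[c("C12h", "HighCa12h")])),
    GTest4 = list(Control = unname(r["C12h"]),
                  Altered = unname(r[c("LowCa12h", "HighCa12h")])))
}

#' Call differentially expressed tags by the four-class decision rules
#'
#' Applies the combination of replicated G-tests and pairwise Z-tests that
#' assigns each tag to the four differential-expression classes:
#' \describe{
#'   \item{class 1}{responds to low calcium independently of exposure time:
#'     all rules of the control-vs-low-calcium replicated G-test pass
#'     (pooled and total G significant, heterogeneity not) and the pairwise
#'     Z-test control vs low calcium is significant at both time points.}
#'   \item{class 2}{time-dependent low-calcium response: the pooled
#'     (intrinsic) components of both the challenge design and the
#'     time-pooling design are significant, the challenge design fails its
#'     homogeneity rule (so class 1 is not met), the time design's
#'     heterogeneity is significant, and at least one per-time Z-test
#'     confirms the effect.}
#'   \item{class 3}{challenge-discordant response at 12 h: both pairwise 12 h
#'     G-tests (control vs low, control vs high) are significant, the
#'     treatment-heterogeneity component of the pooled 12 h design is
#'     significant, both 12 h Z-tests confirm, and the control libraries are
#'     homogeneous.}
#'   \item{class 4}{global response to altered water at 12 h: the pooled
#'     12 h design passes all rules (treatments concordant), both pairwise
#'     12 h G-tests and both 12 h Z-tests confirm, and the control libraries
#'     are homogeneous.}
#' }
#' A tag is `retained` when it has at least one class and its maximum
#' treatment-vs-control expression ratio (zero-substituted) reaches
#' `minFold`.
#'
#' @param x a \linkS4class{TagCountMatrix} containing the five role
#'   libraries (or a plain count matrix with totals taken as column sums).
#' @param roles named character vector mapping the five roles to library
#'   names; defaults to libraries named after the roles themselves.
#' @param alpha per-test significance level.
#' @param minFold retention threshold on the reported fold.
#' @param zeroSub zero-substitution constant.
#' @return a \code{DataFrame}, one row per tag: counts, Z-test and G-test
#'   p-values, class flags \code{class1..class4}, \code{deClass} (comma-joined
#'   labels), per-contrast folds, \code{maxFold}, \code{direction} of the
#'   largest contrast and \code{retained}.
#' @export
classifyTags <- function(x, roles = NULL, alpha = 0.05, minFold = 2,
                         zeroSub = 0.345) {
  M <- if (is(x, "TagCountMatrix")) tagCounts(x) else as.matrix(x)
  totals <- colSums(M)
  roles <- resolveRoles(roles, colnames(M))
  cn <- function(role) M[, roles[[role]]]
  nn <- function(role) totals[[roles[[role]]]]

  designs <- sageDesigns(roles)
  g1 <- gTestMatrix(M[, unlist(designs$GTest1), drop = FALSE],
                    totals[unlist(designs$GTest1)],
                    designs$GTest1, zeroSub, alpha)
  g2 <- gTestMatrix(M[, unlist(designs$GTest2), drop = FALSE],
                    totals[unlist(designs$GTest2)],
                    designs$GTest2, zeroSub, alpha)
  pair <- function(a, b)
    gTestMatrix(M[, c(roles[[a]], roles[[b]]), drop = FALSE],
                totals[c(roles[[a]], roles[[b]])], list(1L, 2L),
                zeroSub, alpha)
  gCL12 <- pair("C12h", "LowCa12h")
  gCH12 <- pair("C12h", "HighCa12h")
  gCC <- pair("C2h", "C12h")          # control-homogeneity rule
  lib34 <- c(roles[["C12h"]], roles[["LowCa12h"]], roles[["HighCa12h"]])
  g34 <- gTestMatrix(M[, lib34, drop = FALSE], totals[lib34],
                     list(1L, 2:3), zeroSub, alpha)

  z2h <- zTest(cn("C2h"), nn("C2h"), cn("LowCa2h"), nn("LowCa2h"))
  z12h <- zTest(cn("C12h"), nn("C12h"), cn("LowCa12h"), nn("LowCa12h"))
  zH12 <- zTest(cn("C12h"), nn("C12h"), cn("HighCa12h"), nn("HighCa12h"))

  ctlOK <- gCC$pTotal >= alpha
  class1 <- g1$passAllRules & z2h$p < alpha & z12h$p < alpha
  class2 <- g1$passIntrinsic & g2$passIntrinsic & !g1$passAllRules &
    g2$failHomogeneity & (z2h$p < alpha | z12h$p < alpha)
  class3 <- gCL12$pTotal < alpha & gCH12$pTotal < alpha &
    g34$pTotal < alpha & g34$failHomogeneity &
    z12h$p < alpha & zH12$p < alpha & ctlOK
  class4 <- g34$passAllRules & gCL12$pTotal < alpha & gCH12$pTotal < alpha &
    z12h$p < alpha & zH12$p < alpha & ctlOK

  fL2 <- foldChange(cn("C2h"), cn("LowCa2h"), zeroSub)
  fL12 <- foldChange(cn("C12h"), cn("LowCa12h"), zeroSub)
  fH12 <- foldChange(cn("C12h"), cn("HighCa12h"), zeroSub)
  folds <- cbind(fL2$fold, fL12$fold, fH12$fold)
  best <- max.col(folds, ties.method = "first")
  maxFold <- folds[cbind(seq_len(nrow(folds)), best)]
  direction <- cbind(fL2$direction, fL12$direction,
                     fH12$direction)[cbind(seq_len(nrow(folds)), best)]
  anyClass <- class1 | class2 | class3 | class4
  labs <- cbind(class1, class2, class3, class4)
  deClass <- unname(apply(labs, 1L, function(v)
    paste(which(v), collapse = ",")))

  S4Vectors::DataFrame(
    tag = rownames(M),
    M[, unname(roles), drop = FALSE],
    zP2h = z2h$p, zP12h = z12h$p, zPHigh12h = zH12$p,
    g1Pooled = g1$pPooled, g1Het = g1$pHeterogeneity,
    g2Pooled = g2$pPooled, g2Het = g2$pHeterogeneity,
    g34Pooled = g34$pPooled, g34Het = g34$pHeterogeneity,
    gPairLow12 = gCL12$pTotal, gPairHigh12 = gCH12$pTotal,
    gControlHom = gCC$pTotal,
    class1 = class1, class2 = class2, class3 = class3, class4 = class4,
    deClass = deClass,
    foldLow2h = fL2$fold, foldLow12h = fL12$fold, foldHigh12h = fH12$fold,
    maxFold = maxFold, direction = direction,
    retained = anyClass & maxFold >= minFold)
}

#' Gene-level expression by tag aggregation
#'
#' Sums the counts of all tags annotated to the same gene, per library
#' (the cumulative SuperSAGE signal of a gene).  Unannotated tags are
#' skipped; ambiguous multi-location tags should be excluded from the
#' annotation beforehand.
#'
#' @param x a \linkS4class{TagCountMatrix} (or count matrix).
#' @param annotation named character vector tag -> gene symbol (NA entries
#'   are dropped), or an annotation `DataFrame` with `tag` and `geneSymbol`
#'   columns.
#' @return an integer matrix, genes x libraries.
#' @export
geneLevelExpression <- function(x, annotation) {
  M <- if (is(x, "TagCountMatrix")) tagCounts(x) else as.matrix(x)
  if (!is.null(dim(annotation)))
    annotation <- setNames(as.character(annotation$geneSymbol),
                           annotation$tag)
  annotation <- annotation[!is.na(annotation)]
  common <- intersect(rownames(M), names(annotation))
  if (!length(common))
    return(matrix(integer(0), 0L, ncol(M),
                  dimnames = list(character(0), colnames(M))))
  rowsum(M[common, , drop = FALSE], annotation[common])
}

#' Concordance of log2 fold changes between two platforms
#'
#' Pearson correlation of paired per-gene log2 fold changes (e.g. tag-count
#' derived vs qPCR derived) with its two-sided p-value.
#'
#' @param x,y paired finite numeric vectors of log2 fold changes, length >= 3.
#' @return a list with `r`, `p` and `n`.
#' @export
concordanceCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("paired vectors of length >= 3 are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("fold changes must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant fold changes")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
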