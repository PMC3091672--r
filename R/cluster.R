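#' Select differentially expressed tags for a clustering analysis
#'
#' The low-calcium analysis keeps all retained tags except those significant
#' only for the high-calcium challenge (class set = \{3\}) and those with
#' zero counts across every control and low-calcium library; the 12 h
#' analysis keeps all retained tags except those with zero counts across the
#' three 12 h libraries.
#'
#' @param records `DataFrame` from [classifyTags()].
#' @param x the \linkS4class{TagCountMatrix} the records were computed from.
#' @param analysis "lowca" or "12h".
#' @param roles role -> library-name mapping (see [classifyTags()]).
#' @return the analysis count matrix (tags x analysis libraries) ready for
#'   [normalizeProfiles()].
#' @export
selectClusterTags <- function(records, x, analysis = c("lowca", "12h"),
                              roles = NULL) {
  analysis <- match.arg(analysis)
  M <- if (is(x, "TagCountMatrix")) tagCounts(x) else as.matrix(x)
  roles <- resolveRoles(roles, colnames(M))
  de <- records$tag[records$retained]
  if (analysis == "lowca") {
    libs <- unname(roles[c("C2h", "LowCa2h", "C12h", "LowCa12h")])
    onlyHigh <- records$tag[records$retained & records$class3 &
                              !records$class1 & !records$class2 &
                              !records$class4]
    de <- setdiff(de, onlyHigh)
  } else {
    libs <- unname(roles[c("C12h", "LowCa12h", "HighCa12h")])
  }
  sub <- M[de, libs, drop = FALSE]
  sub[rowSums(sub) > 0L, , drop = FALSE]
}

#' Normalize count profiles to percentages
#'
#' Divides each tag's counts over the analyzed libraries by their sum and
#' scales to 100, so every profile describes the shape of expression across
#' libraries independently of abundance.
#'
#' @param counts matrix of nonnegative counts, tags x libraries.
#' @return matrix of the same shape; rows sum to 100.
#' @examples
#' normalizeProfiles(rbind(c(10, 30, 60), c(0, 0, 5)))
#' @export
normalizeProfiles <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("all-zero profiles cannot be normalized; exclude them first")
  100 * counts / rs
}

# distance matrix profiles x centroids; "chisq" is the Pearson chi-square
# divergence of a profile against the centroid taken as reference shape
profileDistances <- function(P, C, distance, eps = 1e-8) {
  if (distance == "chisq") {
    Cc <- pmax(C, eps)
    (P^2) %*% t(1 / Cc) - 2 * P %*% t(C / Cc) +
      matrix(rowSums(C^2 / Cc), nrow(P), nrow(C), byrow = TRUE)
  } else {
    outer(rowSums(P^2), rep(1, nrow(C))) - 2 * P %*% t(C) +
      matrix(rowSums(C^2), nrow(P), nrow(C), byrow = TRUE)
  }
}

# kmeans++-style seeding: subsequent centers drawn with probability
# proportional to the distance to the nearest center already chosen
seedCenters <- function(P, k, distance) {
  n <- nrow(P)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  nearest <- rep(Inf, n)
  if (k > 1L) for (i in 2:k) {
    d <- profileDistances(P, P[idx[i - 1L], , drop = FALSE], distance)[, 1L]
    nearest <- pmax(pmin(nearest, d), 0)
    prob <- if (sum(nearest) > 0) nearest else rep(1, n)
    idx[i] <- sample.int(n, 1L, prob = prob)
  }
  P[idx, , drop = FALSE]
}

kmeansOnce <- function(P, k, distance, maxIter = 100L) {
  n <- nrow(P)
  centers <- seedCenters(P, k, distance)
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    D <- profileDistances(P, centers, distance)
    newAssign <- max.col(-D, ties.method = "first")
    # re-seed empty clusters with the worst-fitted profile
    for (kk in setdiff(seq_len(k), unique(newAssign))) {
      far <- which.max(D[cbind(seq_len(n), newAssign)])
      newAssign[far] <- kk
      D[far, ] <- 0
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    centers <- rowsum(P, assign) / as.vector(table(assign))
  }
  W <- sum(profileDistances(P, centers, distance)[cbind(seq_len(n), assign)])
  list(assignments = assign, centroids = centers, W = W)
}

#' K-means clustering of expression profiles under a chi-square distance
#'
#' Iterative assignment/update K-means where the distance between a profile
#' and a centroid is the Pearson chi-square divergence of the profile against
#' the centroid's shape (a count-profile-appropriate distance); Euclidean
#' distance on the normalized profiles is available as a fallback.  Centroids
#' are member means.  The best of `nRestarts` seeded restarts (by total
#' within-cluster dispersion) is returned; ties in assignment go to the
#' lowest cluster index.
#'
#' @param profiles normalized profile matrix (rows sum to 100) with tag row
#'   names.
#' @param k number of clusters (1 <= k <= number of profiles).
#' @param seed integer seed; the fit is deterministic given `seed`.
#' @param nRestarts random restarts (default 50).
#' @param distance "chisq" (default) or "euclidean".
#' @return a \linkS4class{ClusterModel}.
#' @export
chisqKmeans <- function(profiles, k, seed = 1L, nRestarts = 50L,
                        distance = c("chisq", "euclidean")) {
  distance <- match.arg(distance)
  P <- as.matrix(profiles)
  if (k < 1L || k > nrow(P)) stop("k must lie in [1, number of profiles]")
  best <- withSeed(seed, {
    fits <- lapply(seq_len(nRestarts), function(r) kmeansOnce(P, k, distance))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "W"))]]
  })
  assignments <- setNames(as.integer(best$assignments), rownames(P))
  new("ClusterModel", K = as.integer(k), assignments = assignments,
      centroids = best$centroids, withinDispersion = best$W,
      distance = distance, seed = as.numeric(seed),
      nRestarts = as.integer(nRestarts))
}

#' Gap-statistic selection of the number of clusters
#'
#' Computes \eqn{Gap(K) = E^*[\log W_K] - \log W_K} where the expectation is
#' over `B` reference datasets drawn uniformly over the per-dimension range
#' of the normalized data (and renormalized to valid profiles), and selects
#' the smallest K with \eqn{Gap(K) \ge Gap(K+1) - s_{K+1}} (the
#' one-standard-error rule).  Degenerate data (all profiles identical)
#' selects K = 1.
#'
#' @param profiles normalized profile matrix.
#' @param kRange candidate K values (default 1:10).
#' @param B number of reference datasets (>= 10, default 50).
#' @param seed integer seed.
#' @param nRestarts restarts per K-means fit of the observed data; the
#'   structureless uniform reference fits use `max(2, nRestarts %/% 10)`.
#' @param distance "chisq" or "euclidean".
#' @return a \linkS4class{GapResult}.
#' @export
gapStatistic <- function(profiles, kRange = 1:10, B = 50L, seed = 1L,
                         nRestarts = 20L, distance = c("chisq", "euclidean")) {
  distance <- match.arg(distance)
  P <- as.matrix(profiles)
  if (B < 10L) stop("at least 10 reference datasets are required")
  kRange <- sort(as.integer(kRange))
  kRange <- kRange[kRange <= nrow(P)]
  if (max(kRange) < 1L) stop("empty K range")
  if (all(apply(P, 2, function(col) diff(range(col)) == 0)))
    return(new("GapResult", K = kRange, gap = rep(0, length(kRange)),
               se = rep(0, length(kRange)), logW = rep(NA_real_,
               length(kRange)), ElogW = rep(NA_real_, length(kRange)),
               B = as.integer(B), selectedK = 1L))
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  refRestarts <- max(2L, nRestarts %/% 10L)
  res <- withSeed(seed, {
    logW <- vapply(kRange, function(k)
      log(max(kmeansBest(P, k, nRestarts, distance)$W, 1e-12)), numeric(1))
    refW <- matrix(NA_real_, B, length(kRange))
    for (b in seq_len(B)) {
      R <- vapply(seq_along(lo), function(j)
        runif(nrow(P), lo[j], hi[j]), numeric(nrow(P)))
      R <- 100 * R / rowSums(R)
      refW[b, ] <- vapply(kRange, function(k)
        log(max(kmeansBest(R, k, refRestarts, distance)$W, 1e-12)),
        numeric(1))
    }
    list(logW = logW, ElogW = colMeans(refW),
         se = apply(refW, 2, sd) * sqrt(1 + 1 / B))
  })
  gap <- res$ElogW - res$logW
  selected <- kRange[length(kRange)]
  for (i in seq_len(length(kRange) - 1L)) {
    if (gap[i] >= gap[i + 1L] - res$se[i + 1L]) { selected <- kRange[i]; break }
  }
  new("GapResult", K = kRange, gap = gap, se = res$se, logW = res$logW,
      ElogW = res$ElogW, B = as.integer(B), selectedK = as.integer(selected))
}

# best-of-restarts K-means core (no object wrapping)
kmeansBest <- function(P, k, nRestarts, distance) {
  fits <- lapply(seq_len(nRestarts), function(r) kmeansOnce(P, k, distance))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "W"))]]
}

#' Cross-tabulate two cluster partitions
#'
#' Entry (i, j) counts the tags assigned to cluster i of the first analysis
#' and cluster j of the second; row and column "0" collect tags analyzed in
#' only one of the two.
#'
#' @param a,b \linkS4class{ClusterModel}s or named assignment vectors.
#' @return an integer matrix with dimnames `0..K`.
#' @export
crossTabulate <- function(a, b) {
  if (is(a, "ClusterModel")) a <- clusterAssignments(a)
  if (is(b, "ClusterModel")) b <- clusterAssignments(b)
  tags <- union(names(a), names(b))
  ai <- ifelse(tags %in% names(a), a[tags], 0L)
  bi <- ifelse(tags %in% names(b), b[tags], 0L)
  ka <- max(c(0L, a)); kb <- max(c(0L, b))
  tb <- table(factor(ai, levels = 0:ka), factor(bi, levels = 0:kb))
  m <- matrix(as.integer(tb), nrow = ka + 1L,
              dimnames = list(0:ka, 0:kb))
  m
}

#' Cluster-size summary across analyses
#'
#' Pools the cluster sizes of one or more fitted models and reports their
#' mean and standard deviation.
#'
#' @param models a \linkS4class{ClusterModel}, a cluster-assignment vector,
#'   or a list mixing the two.
#' @return a list with `sizes` (per model), `mean` and `sd`.
#' @export
summarizeClusters <- function(models) {
  if (!is.list(models)) models <- list(models)
  sizes <- lapply(models, function(m) {
    v <- if (is(m, "ClusterModel")) clusterAssignments(m) else as.integer(m)
    as.integer(table(factor(v, levels = seq_len(max(v)))))
  })
  all <- unlist(sizes)
  list(sizes = sizes, mean = mean(all),
       sd = if (length(all) > 1L) sd(all) else 0)
}
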