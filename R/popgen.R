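# SNP/sample filtering, identity-by-state distance, relatedness proxy,
# clone/sibling pruning, principal-coordinate ordination and the Procrustes
# isolation-by-distance test.

#' Filter samples by sequencing coverage
#'
#' Retains samples having at least `minFraction` of sites covered at total
#' read depth >= `minDepth` (the boundary is inclusive: a sample with exactly
#' a quarter of sites at 5x is kept). Sample order is preserved.
#'
#' @param x a [ReadCountMatrix-class]
#' @param minFraction minimum fraction of sites at depth (default 0.25)
#' @param minDepth minimum total read depth per site (default 5)
#' @return the filtered ReadCountMatrix
#' @export
filterSamplesByCoverage <- function(x, minFraction = 0.25, minDepth = 5) {
  ac <- alleleCounts(x)
  tot <- ac$alleleA + ac$alleleB
  frac <- colMeans(tot >= minDepth)
  keep <- frac >= minFraction
  if (!any(keep))
    stop(sprintf("all %d samples dropped by coverage filter (max fraction %.3f < %.3f)",
                 ncol(x), max(frac), minFraction))
  x[, keep]
}

#' Filter SNP sites by missingness and minor allele frequency
#'
#' Retains sites genotyped (>= 1 read) in at least `minGenotypedFraction` of
#' samples and with pooled minor allele frequency >= `minMaf`. The allele
#' frequency of a site is the mean over genotyped samples of each sample's
#' allele-B read proportion, which avoids weighting samples by coverage.
#' Boundaries are inclusive (a site at exactly 75 percent genotyped or MAF
#' exactly 0.05 is kept).
#'
#' @param x a [ReadCountMatrix-class] with >= 2 samples
#' @param minGenotypedFraction minimum genotyped fraction (default 0.75)
#' @param minMaf minimum minor allele frequency (default 0.05)
#' @return the filtered ReadCountMatrix
#' @export
filterSites <- function(x, minGenotypedFraction = 0.75, minMaf = 0.05) {
  if (ncol(x) < 2) stop("at least 2 samples required")
  ac <- alleleCounts(x)
  tot <- ac$alleleA + ac$alleleB
  genoFrac <- rowMeans(tot >= 1)
  pB <- ac$alleleB / ifelse(tot > 0, tot, NA)
  f <- rowMeans(pB, na.rm = TRUE)
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep <- genoFrac >= minGenotypedFraction & maf >= minMaf
  if (!any(keep))
    stop("all sites removed by missingness/MAF filter")
  x[keep, ]
}

#' Identity-by-state genetic distance
#'
#' For every pair of samples, walks the sites covered by at least one read in
#' both, draws one read from each sample (uniformly over its reads, i.e.
#' allele A with probability `countA / (countA + countB)`), and records a
#' mismatch when the drawn alleles differ. The IBS distance is the fraction
#' of mismatches. Entirely model-free and robust to coverage differences.
#'
#' Sampling uses one RNG stream seeded with `seed`; pairs are processed in
#' sorted-sample-id order, and within each pair the draws for the
#' lexicographically first sample precede those of the second (one `runif`
#' per shared site each). This makes the stochastic distance exactly
#' reproducible and replayable.
#'
#' @param x a [ReadCountMatrix-class] with >= 2 samples
#' @param seed integer seed
#' @return a [DistanceMatrix-class] of kind `"ibs"`
#' @export
ibsDistance <- function(x, seed = 1) {
  if (ncol(x) < 2) stop("at least 2 samples required")
  ac <- alleleCounts(x)
  tot <- ac$alleleA + ac$alleleB
  pA <- ac$alleleA / ifelse(tot > 0, tot, NA)
  ids <- colnames(x)
  ord <- order(ids)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  withSeed(seed, {
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        i <- ord[a]; j <- ord[b]
        shared <- which(tot[, i] > 0 & tot[, j] > 0)
        if (!length(shared))
          stop("samples ", ids[i], " and ", ids[j], " share no covered sites")
        ai <- stats::runif(length(shared)) < pA[shared, i]
        aj <- stats::runif(length(shared)) < pA[shared, j]
        d <- mean(ai != aj)
        D[i, j] <- D[j, i] <- d
      }
    }
  })
  DistanceMatrix(D, kind = "ibs")
}

# Maximum-likelihood-style hard dosage call from read counts: 0/1/2 copies of
# allele B, NA when the site is uncovered.
dosageCalls <- function(x) {
  ac <- alleleCounts(x)
  tot <- ac$alleleA + ac$alleleB
  g <- matrix(NA_integer_, nrow(x), ncol(x), dimnames = dimnames(ac$alleleA))
  g[tot > 0 & ac$alleleB == 0] <- 0L
  g[tot > 0 & ac$alleleA == 0 & ac$alleleB > 0] <- 2L
  g[ac$alleleA > 0 & ac$alleleB > 0] <- 1L
  g
}

#' Allele-sharing relatedness similarity
#'
#' Pairwise allele-sharing similarity from hard dosage calls: the mean over
#' sites genotyped in both samples of the fraction of alleles shared,
#' `1 - |g_i - g_j| / 2`. Clonal pairs approach 1; unrelated individuals in a
#' p = 0.5 population average 0.625 under Hardy-Weinberg. This is a
#' deliberately simple stand-in for likelihood-based kinship estimation: the
#' pipeline only needs a similarity scale on which the > 0.8 pruning rule can
#' act.
#'
#' @param x a filtered [ReadCountMatrix-class]
#' @return a [DistanceMatrix-class] of kind `"relatedness-dissimilarity"`
#'   (store = 1 - similarity)
#' @export
relatednessSimilarity <- function(x) {
  if (ncol(x) < 2) stop("at least 2 samples required")
  g <- dosageCalls(x)
  ids <- colnames(x)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(ok))
        stop("samples ", ids[i], " and ", ids[j], " share no genotyped sites")
      sim <- mean(1 - abs(g[ok, i] - g[ok, j]) / 2)
      D[i, j] <- D[j, i] <- 1 - sim
    }
  }
  DistanceMatrix(D, kind = "relatedness-dissimilarity")
}

#' Collapse clonal / highly related groups to one representative
#'
#' Builds single-linkage groups of samples connected by pairwise similarity
#' strictly greater than `threshold` (transitive closure, the automated
#' analog of pruning dendrogram branches above 0.8 similarity) and retains
#' from each group the member with the highest sequencing coverage, breaking
#' ties by lexicographic sample id.
#'
#' @param similarity a [DistanceMatrix-class] holding 1 - similarity (as from
#'   [relatednessSimilarity()]), or a similarity matrix
#' @param coverage named per-sample coverage vector (e.g. [sampleCoverage()])
#' @param threshold similarity above which samples are considered redundant
#' @return list with `retained` (sample ids) and `groups` (data.frame:
#'   sample, group, representative)
#' @export
pruneRedundant <- function(similarity, coverage, threshold = 0.8) {
  sim <- if (methods::is(similarity, "DistanceMatrix"))
    1 - distMatrix(similarity) else similarity
  ids <- rownames(sim)
  n <- length(ids)
  # union-find over pairs exceeding the threshold (single-linkage closure)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (sim[i, j] > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  uroots <- sort(unique(root))
  rep_of <- vapply(uroots, function(r) {
    g <- which(root == r)
    cv <- coverage[ids[g]]
    sort(ids[g[cv == max(cv)]])[1]
  }, character(1))
  tab <- data.frame(sample = ids,
                    group = match(root, uroots),
                    representative = rep_of[match(root, uroots)],
                    stringsAsFactors = FALSE)
  list(retained = sort(unique(tab$representative)), groups = tab)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: the squared distance matrix is double-centered
#' (`-D^2/2`), eigen-decomposed, and axes with positive eigenvalues retained.
#' Scores are scaled so that the sum of squares on each axis equals its
#' eigenvalue; variance proportions are taken over the positive spectrum.
#' Negative eigenvalues (non-Euclidean part) are dropped, not corrected, and
#' visible only through the variance proportions summing over the positive
#' part.
#'
#' @param d a [DistanceMatrix-class] or symmetric matrix
#' @param nAxes maximum number of axes to return (default: all positive)
#' @return an [Ordination-class]
#' @export
pcoa <- function(d, nAxes = NULL) {
  m <- if (methods::is(d, "DistanceMatrix")) distMatrix(d) else d
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-9 & e$values > 0)
  if (!length(pos)) stop("no positive eigenvalues")
  if (!is.null(nAxes)) pos <- pos[seq_len(min(nAxes, length(pos)))]
  lam <- e$values[pos]
  sc <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(pos))
  rownames(sc) <- rownames(m)
  colnames(sc) <- paste0("gPC", seq_along(pos))
  methods::new("Ordination", scores = sc, eigenvalues = lam,
               varianceExplained = lam / sum(e$values[e$values > 0]),
               covariates = list())
}

#' Procrustes association test between two ordinations
#'
#' Finds the optimal translation, rotation and scaling of ordination B onto
#' ordination A and tests the Procrustes correlation statistic
#' `sqrt(1 - m12^2)` by row permutation of B (as in `vegan::protest`, which
#' performs the computation). Used to test isolation by distance between a
#' genetic ordination and an ordination of geographic coordinates.
#'
#' @param a,b [Ordination-class] objects (or score matrices) over the same
#'   samples
#' @param nPerm number of permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @return list with `statistic` (Procrustes correlation), `pValue`
#'   (`(1 + #perms >= observed) / (nPerm + 1)`), and `nPerm`
#' @export
procrustesTest <- function(a, b, nPerm = 999, seed = 1) {
  A <- if (methods::is(a, "Ordination")) scores(a) else a
  B <- if (methods::is(b, "Ordination")) scores(b) else b
  if (nrow(A) < 3) stop("at least 3 samples required")
  if (!identical(rownames(A), rownames(B))) {
    if (!setequal(rownames(A), rownames(B)))
      stop("ordinations must contain the same samples")
    B <- B[rownames(A), , drop = FALSE]
  }
  pr <- withSeed(seed,
    vegan::protest(A, B, permutations = nPerm))
  list(statistic = unname(pr$t0), pValue = unname(pr$signif), nPerm = nPerm)
}
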