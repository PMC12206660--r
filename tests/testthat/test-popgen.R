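# Filtering, IBS distance, relatedness proxy, clone pruning, PCoA,
# Procrustes.

test_that("coverage filter matches hand enumeration with inclusive boundary", {
  # 4 samples x 20 sites; fractions of sites at >= 5x: 1.00, 0.25, 0.24-ish
  # (impossible at 20 sites, use 0.20), 0.30
  nS <- 20
  mk <- function(nHigh) c(rep(5L, nHigh), rep(2L, nS - nHigh))
  a <- cbind(mk(20), mk(5), mk(4), mk(6))
  b <- matrix(0L, nS, 4)
  rcm <- toyCounts(a, b, ids = c("all5x", "quarter", "below", "above"))
  kept <- colnames(filterSamplesByCoverage(rcm, 0.25, 5))
  # brute-force oracle
  tot <- a + b
  oracle <- colnames(rcm)[colMeans(tot >= 5) >= 0.25]
  expect_identical(kept, oracle)
  expect_identical(kept, c("all5x", "quarter", "above"))
  # empty result errors with counts
  expect_error(filterSamplesByCoverage(rcm, 1.01, 5), "dropped")
})

test_that("site filter reproduces hand enumeration of a printed 6x10 matrix", {
  # 10 sites x 6 samples of B-dosage genotypes; NA = missing
  g <- rbind(
    c(1, 1, 1, 1, 1, 1),    # all het, MAF 0.5          -> keep
    c(0, 0, 0, 0, 0, 0),    # monomorphic               -> drop (MAF 0)
    c(1, 0, 0, 0, 0, 0),    # MAF 1/12 = 0.083          -> keep
    c(NA, NA, 1, 1, 0, 2),  # 4/6 genotyped = 0.667     -> drop
    c(NA, 1, 1, 0, 2, 0),   # 5/6 = 0.833, MAF 0.4      -> keep
    c(2, 2, 2, 2, 2, 2),    # monomorphic other allele  -> drop
    c(NA, NA, NA, 1, 1, 1), # 0.5 genotyped             -> drop
    c(0, 0, 0, 0, 0, 1),    # MAF 1/12 < 0.05? = 0.083  -> keep
    c(2, 2, 2, 2, 2, 1),    # MAF 1/12 = 0.083          -> keep
    c(1, 1, 0, 0, 2, 2))    # MAF 0.5                   -> keep
  rcm <- countsFromDosage(g)
  kept <- rownames(filterSites(rcm, 0.75, 0.05))
  # brute-force oracle from definitions
  geno <- !is.na(g)
  f <- rowMeans(g / 2, na.rm = TRUE)
  oracle <- rownames(rcm)[rowMeans(geno) >= 0.75 & pmin(f, 1 - f) >= 0.05]
  expect_identical(kept, oracle)
  expect_identical(kept, paste0("L", c(1, 3, 5, 8, 9, 10)))
  # exact-boundary MAF 0.05: one het among 10 samples pools to exactly 0.05
  g2 <- matrix(0, 4, 10); g2[1, 1] <- 1
  g2[4, ] <- 1  # keeps the matrix non-empty after filtering
  rcm2 <- countsFromDosage(g2)
  expect_true("L1" %in% rownames(filterSites(rcm2, 0.75, 0.05)))
  expect_error(filterSites(countsFromDosage(matrix(0, 3, 4))), "removed")
})

test_that("IBS equals a step-by-step replay of the documented RNG scheme", {
  set.seed(99)
  a <- matrix(rpois(15, 4), 5, 3); b <- matrix(rpois(15, 4), 5, 3)
  rcm <- toyCounts(a, b, ids = c("b", "c", "a"))  # unsorted on purpose
  d <- distMatrix(ibsDistance(rcm, seed = 42))
  # oracle: same stream, pairs in sorted-id order, first sample's draws first
  tot <- a + b
  pA <- a / ifelse(tot > 0, tot, NA)
  colnames(pA) <- colnames(tot) <- c("b", "c", "a")
  ids <- sort(c("b", "c", "a"))
  oracle <- matrix(0, 3, 3, dimnames = list(ids, ids))
  set.seed(42)
  for (x in 1:2) for (y in (x + 1):3) {
    i <- ids[x]; j <- ids[y]
    shared <- which(tot[, i] > 0 & tot[, j] > 0)
    ai <- runif(length(shared)) < pA[shared, i]
    aj <- runif(length(shared)) < pA[shared, j]
    oracle[i, j] <- oracle[j, i] <- mean(ai != aj)
  }
  expect_equal(d[ids, ids], oracle)
})

test_that("IBS hits closed-form expectations and its invariants", {
  # identical homozygotes: distance 0
  g <- matrix(c(0, 0, 2, 2, 0), ncol = 1)
  rcm <- countsFromDosage(cbind(g, g))
  expect_equal(distMatrix(ibsDistance(rcm, seed = 1))[1, 2], 0)
  # all-heterozygous pair: expectation 1/2 per site
  n <- 1000
  rcm2 <- toyCounts(matrix(1L, n, 2), matrix(1L, n, 2))
  d <- distMatrix(ibsDistance(rcm2, seed = 5))[1, 2]
  expect_lt(abs(d - 0.5), 3 * sqrt(0.25 / n))
  # coverage rescaling leaves the expectation invariant
  rcm3 <- toyCounts(matrix(10L, n, 2), matrix(10L, n, 2))
  d3 <- distMatrix(ibsDistance(rcm3, seed = 5))[1, 2]
  expect_lt(abs(d3 - 0.5), 3 * sqrt(0.25 / n))
  # symmetry / zero diagonal / range enforced by the class
  sim <- smallSimulation()
  dd <- ibsDistance(sim$simd$counts[1:200, 1:12], seed = 2)
  m <- distMatrix(dd)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0) && min(m) >= 0 && max(m) <= 1)
  # a pair with no shared coverage errors, naming the pair
  a <- rbind(c(2L, 0L), c(0L, 3L))
  rcm4 <- toyCounts(a, matrix(0L, 2, 2))
  expect_error(ibsDistance(rcm4, seed = 1), "share no covered sites")
})

test_that("relatedness similarity matches enumeration oracles", {
  # identical genotypes: similarity 1 (distance 0)
  g <- matrix(c(0, 1, 2, 1, 0), ncol = 1)
  rcm <- countsFromDosage(cbind(g, g))
  expect_equal(distMatrix(relatednessSimilarity(rcm))[1, 2], 0)
  # printed parent-offspring 10-site example, hand computation:
  par <- c(0, 0, 1, 1, 2, 2, 1, 0, 2, 1)
  off <- c(0, 1, 1, 2, 1, 2, 0, 0, 2, 1)
  # shared fractions: 1,.5,1,.5,.5,1,.5,1,1,1 -> mean = 0.8
  rcm2 <- countsFromDosage(cbind(par, off))
  expect_equal(1 - distMatrix(relatednessSimilarity(rcm2))[1, 2], 0.8)
  # HWE p=0.5 expectation: enumerate genotype-pair probabilities
  gp <- c(0.25, 0.5, 0.25)
  expct <- sum(outer(gp, gp) * (1 - abs(outer(0:2, 0:2, "-")) / 2))
  expect_equal(expct, 0.625)  # the enumerated value
  set.seed(8)
  G <- matrix(rbinom(4000 * 20, 2, 0.5), 4000, 20)
  sim <- 1 - distMatrix(relatednessSimilarity(countsFromDosage(G)))
  offd <- sim[lower.tri(sim)]
  expect_lt(abs(mean(offd) - 0.625), 0.01)
})

test_that("redundant samples collapse to the highest-coverage representative", {
  ids <- c("a", "b", "c", "d", "e")
  sim <- diag(5); dimnames(sim) <- list(ids, ids)
  cov <- setNames(c(10, 20, 15, 7, 9), ids)
  # no pair above threshold: all retained
  pr0 <- pruneRedundant(sim, cov, 0.8)
  expect_identical(pr0$retained, ids)
  # clone pair (a,b): higher coverage b retained
  sim1 <- sim; sim1["a", "b"] <- sim1["b", "a"] <- 0.95
  pr1 <- pruneRedundant(sim1, cov, 0.8)
  expect_true("b" %in% pr1$retained && !"a" %in% pr1$retained)
  # chain a~b~c at 0.85: single-linkage closure keeps one of three
  sim2 <- sim
  sim2["a", "b"] <- sim2["b", "a"] <- 0.85
  sim2["b", "c"] <- sim2["c", "b"] <- 0.85
  pr2 <- pruneRedundant(sim2, cov, 0.8)
  expect_identical(sort(pr2$retained), c("b", "d", "e"))
  expect_equal(length(unique(pr2$groups$group[1:3])), 1)
  # tie on coverage: lexicographically first id wins
  cov2 <- setNames(rep(5, 5), ids)
  pr3 <- pruneRedundant(sim1, cov2, 0.8)
  expect_true("a" %in% pr3$retained && !"b" %in% pr3$retained)
})

test_that("PCoA embeds Euclidean distances isometrically", {
  set.seed(4)
  X <- cbind(rnorm(12), rnorm(12))
  rownames(X) <- paste0("p", 1:12)
  D <- as.matrix(dist(X))
  ord <- pcoa(DistanceMatrix(D, kind = "euclidean"))
  Drec <- as.matrix(dist(scores(ord)))
  expect_lt(max(abs(Drec - D)), 1e-8)
  # 3-point equilateral: two equal positive eigenvalues
  De <- matrix(1, 3, 3) - diag(3)
  dimnames(De) <- list(letters[1:3], letters[1:3])
  orde <- pcoa(DistanceMatrix(De, kind = "euclidean"))
  expect_equal(length(eigenvalues(orde)), 2)
  expect_equal(eigenvalues(orde)[1], eigenvalues(orde)[2], tolerance = 1e-10)
  # random IBS-like matrix: positive part reconstructs its own distances
  set.seed(11)
  M <- matrix(runif(64, 0.2, 0.5), 8, 8); M <- (M + t(M)) / 2; diag(M) <- 0
  dimnames(M) <- list(paste0("s", 1:8), paste0("s", 1:8))
  o <- pcoa(DistanceMatrix(M, kind = "ibs"))
  # reconstruction from the positive spectrum dominates the original
  expect_lt(mean(abs(as.matrix(dist(scores(o))) - M)), 0.05)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Procrustes test recognizes exact and null associations", {
  set.seed(21)
  A <- cbind(rnorm(15), rnorm(15)); rownames(A) <- paste0("s", 1:15)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  B <- 3 * A %*% R + 5
  rownames(B) <- rownames(A)
  pt <- procrustesTest(A, B, nPerm = 199, seed = 1)
  expect_equal(pt$statistic, 1, tolerance = 1e-10)
  expect_equal(pt$pValue, 1 / 200)
  # statistic equals the SVD-based closed form on a printed 4x2 toy
  A4 <- matrix(c(0, 1, 2, 4, 1, 3, 2, 0), 4, 2,
               dimnames = list(paste0("s", 1:4), NULL))
  B4 <- matrix(c(2, 1, 0, 1, 0, 2, 3, 1), 4, 2,
               dimnames = list(paste0("s", 1:4), NULL))
  ptc <- procrustesTest(A4, B4, nPerm = 49, seed = 2)
  ac <- scale(A4, scale = FALSE); bc <- scale(B4, scale = FALSE)
  ac <- ac / sqrt(sum(ac^2)); bc <- bc / sqrt(sum(bc^2))
  m12sq <- 1 - sum(svd(crossprod(ac, bc))$d)^2
  expect_equal(ptc$statistic, sqrt(1 - m12sq), tolerance = 1e-10)
  expect_error(procrustesTest(A4[1:2, ], B4[1:2, ]), "3 samples")
})
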