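# Linkage-method selection, k choice, lineage assignment.

test_that("all linkage methods first merge the closest pair", {
  D <- matrix(5, 3, 3); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  for (m in c("single", "complete", "upgma", "ward")) {
    h <- buildTree(DistanceMatrix(D, "euclidean"), m)
    expect_identical(sort(h$labels[-h$merge[1, ]]), c("a", "b"))
  }
  expect_error(buildTree(DistanceMatrix(D, "euclidean"), "centroid"))
})

test_that("UPGMA heights match hand computation on a printed 4-point matrix", {
  # d(a,b)=2, d(c,d)=4, cross distances 6/10/6/10; UPGMA merges at
  # 2, then 4, then mean(6,10,6,10) = 8
  D <- matrix(c(0, 2, 6, 10,
                2, 0, 6, 10,
                6, 6, 0, 4,
                10, 10, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  h <- buildTree(DistanceMatrix(D, "euclidean"), "upgma")
  expect_equal(sort(h$height), c(2, 4, 8))
  # single vs complete topologies diverge on a chained metric
  pts <- c(0, 1.0, 2.1, 3.3)
  Dc <- as.matrix(dist(pts))
  dimnames(Dc) <- list(letters[1:4], letters[1:4])
  hs <- buildTree(DistanceMatrix(Dc, "euclidean"), "single")
  hc <- buildTree(DistanceMatrix(Dc, "euclidean"), "complete")
  # single linkage chains: last merge at the smallest gap chain (height 1.2);
  # complete linkage's last merge spans the full range (3.3)
  expect_equal(max(hs$height), 1.2)
  expect_equal(max(hc$height), 3.3)
})

test_that("cophenetic correlation is exact for ultrametric input and drives method choice", {
  # build an ultrametric distance matrix directly (two pairs at 1, all else 4)
  D <- matrix(4, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  dimnames(D) <- list(letters[1:4], letters[1:4])
  dm <- DistanceMatrix(D, "euclidean")
  tr <- buildTree(dm, "upgma")
  expect_equal(copheneticCorrelation(tr, dm), 1)
  # selection picks the max-r method; on ultrametric data UPGMA attains r = 1
  sel <- selectClusteringMethod(dm)
  expect_equal(max(sel$report$copheneticR), 1)
  expect_equal(sel$report$copheneticR[sel$report$method == sel$method],
               max(sel$report$copheneticR))
  # 5-point toy equals a brute-force pairwise enumeration
  set.seed(3)
  M <- as.matrix(dist(cbind(runif(5), runif(5))))
  dimnames(M) <- list(paste0("s", 1:5), paste0("s", 1:5))
  dm5 <- DistanceMatrix(M, "euclidean")
  t5 <- buildTree(dm5, "upgma")
  # oracle: cophenetic distance = lowest cut height at which the pair merges
  o <- matrix(0, 5, 5, dimnames = dimnames(M))
  hts <- sort(unique(t5$height))
  for (i in 1:4) for (j in (i + 1):5) {
    for (h in hts) {
      cl <- cutree(t5, h = h)
      if (cl[rownames(M)[i]] == cl[rownames(M)[j]]) { o[i, j] <- o[j, i] <- h; break }
    }
  }
  lo <- lower.tri(M)
  expect_equal(copheneticCorrelation(t5, dm5), cor(o[lo], M[lo]),
               tolerance = 1e-12)
  expect_error(copheneticCorrelation(t5, DistanceMatrix(matrix(0, 5, 5,
    dimnames = dimnames(M)), "euclidean")), "constant")
})

test_that("silhouette criterion recovers planted k and matches brute force", {
  # three tight planted blobs
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10),
             matrix(rnorm(20, 10, 0.1), 10))
  rownames(X) <- paste0("s", 1:30)
  D <- as.matrix(dist(X))
  dm <- DistanceMatrix(D, "euclidean")
  tr <- buildTree(dm, "upgma")
  ch <- chooseKSilhouette(tr, dm, 2:8)
  expect_equal(ch$bestK, 3)
  # brute-force silhouette on a 6-point toy
  D6 <- as.matrix(dist(c(0, 0.1, 0.2, 5, 5.1, 9)))
  dimnames(D6) <- list(paste0("s", 1:6), paste0("s", 1:6))
  dm6 <- DistanceMatrix(D6, "euclidean")
  t6 <- buildTree(dm6, "upgma")
  lab <- cutree(t6, k = 3)
  sil <- vapply(1:6, function(i) {
    own <- which(lab == lab[i] & seq_len(6) != i)
    if (!length(own)) return(0)  # singleton convention
    a <- mean(D6[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(D6[i, lab == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  got <- chooseKSilhouette(t6, dm6, 2:4)
  expect_equal(unname(got$widths["3"]), mean(sil), tolerance = 1e-12)
})

test_that("membership Mantel r equals direct correlation and is maximal at planted k", {
  set.seed(6)
  X <- rbind(matrix(rnorm(16, 0, 0.2), 8), matrix(rnorm(16, 4, 0.2), 8),
             matrix(rnorm(16, 8, 0.2), 8))
  rownames(X) <- paste0("s", 1:24)
  dm <- DistanceMatrix(as.matrix(dist(X)), "euclidean")
  tr <- buildTree(dm, "upgma")
  rs <- vapply(2:6, function(k)
    mantelMembership(dm, cutree(tr, k = k), nPerm = 0, seed = 1)$r, numeric(1))
  expect_equal(which.max(rs) + 1, 3)
  # 5-point toy: r equals plain correlation of vectorized matrices
  M <- as.matrix(dist(c(0, 1, 2, 6, 7)))
  dimnames(M) <- list(paste0("s", 1:5), paste0("s", 1:5))
  lab <- c(1, 1, 1, 2, 2)
  got <- mantelMembership(DistanceMatrix(M, "euclidean"), lab, nPerm = 99,
                          seed = 2)
  B <- outer(lab, lab, function(a, b) as.numeric(a != b))
  lo <- lower.tri(M)
  expect_equal(got$r, cor(M[lo], B[lo]), tolerance = 1e-12)
  # exact enumeration over 5! permutations: 3!*2! of 120 preserve the
  # partition, so the smallest attainable p here is 0.1
  expect_lte(got$pValue, 0.1)
  expect_error(mantelMembership(DistanceMatrix(M, "euclidean"),
                                rep(1, 5)), "2 clusters")
})

test_that("lineage assignment applies the hard/fallback/gray thresholds", {
  soft <- rbind(a = c(0.95, 0.03, 0.02),
                b = c(0.70, 0.20, 0.10),
                c = c(0.40, 0.35, 0.25),
                d = c(0.05, 0.91, 0.04))
  colnames(soft) <- paste0("lin", 1:3)
  asg <- assignLineages(soft)
  expect_identical(asg$hard$lin1, "a")
  expect_identical(asg$hard$lin2, "d")
  expect_identical(sort(asg$fallback$lin1), c("a", "b"))
  expect_identical(asg$gray, "c")
  expect_identical(unname(asg$labels["c"]), "lin1")
  # one-hot rows partition the samples at every threshold
  oh <- diag(3)[c(1, 2, 3, 1), ]
  rownames(oh) <- letters[1:4]; colnames(oh) <- paste0("lin", 1:3)
  a2 <- assignLineages(oh)
  expect_identical(sort(unlist(a2$hard, use.names = FALSE)), letters[1:4])
  expect_length(a2$gray, 0)
  expect_error(assignLineages(soft, hardThreshold = 1.2), "thresholds")
  expect_error(assignLineages(soft * 2), "sum to 1")
})

test_that("newick export round-trips through ape", {
  D <- as.matrix(dist(c(0, 1, 3, 7)))
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- buildTree(DistanceMatrix(D, "euclidean"), "upgma")
  f <- tempfile(fileext = ".nwk")
  exportNewick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, letters[1:4])
  # cophenetic distances survive the round trip
  expect_equal(as.matrix(ape::cophenetic.phylo(ph))[letters[1:4], letters[1:4]],
               as.matrix(cophenetic(tr))[letters[1:4], letters[1:4]],
               tolerance = 1e-8)
})
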