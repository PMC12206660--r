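# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# A tiny ReadCountMatrix from explicit count matrices.
toyCounts <- function(a, b, ids = NULL, snps = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(a)))
  if (is.null(snps)) snps <- paste0("L", seq_len(nrow(a)))
  dimnames(a) <- dimnames(b) <- list(snps, ids)
  ReadCountMatrix(a, b)
}

# Genotype-style counts (2,0)/(1,1)/(0,2) from a dosage matrix (NA = missing).
countsFromDosage <- function(g, ids = NULL) {
  gg <- g
  gg[is.na(gg)] <- -1
  a <- matrix(0L, nrow(g), ncol(g))
  b <- matrix(0L, nrow(g), ncol(g))
  a[gg == 0] <- 2L; a[gg == 1] <- 1L
  b[gg == 1] <- 1L; b[gg == 2] <- 2L
  toyCounts(a, b, ids = ids)
}

# Wrap a response matrix as an Ordination (for constructed forest cases).
asOrdination <- function(Y, ids = NULL) {
  Y <- as.matrix(Y)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(Y)))
  Y <- scale(Y, center = TRUE, scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  rownames(Y) <- ids
  colnames(Y) <- paste0("gPC", seq_len(ncol(Y)))
  lam <- colSums(Y^2)
  ord <- sort(lam, decreasing = TRUE, index.return = TRUE)$ix
  Y <- Y[, ord, drop = FALSE]
  colnames(Y) <- paste0("gPC", seq_len(ncol(Y)))
  lam <- lam[ord]
  methods::new("Ordination", scores = Y, eigenvalues = unname(lam),
               varianceExplained = unname(lam / sum(lam)), covariates = list())
}

# Jackknife-style replicate ordinations of a single response vector.
jackknifeResponses <- function(y, ids, nRep, nKeep, seed) {
  lapply(seq_len(nRep), function(r) {
    set.seed(seed * 1000 + r)
    keep <- sort(sample(length(y), nKeep))
    o <- asOrdination(cbind(y[keep]), ids[keep])
    attr(o, "kept") <- ids[keep]
    o
  })
}

# A small seascape + genotype dataset reused across tests (computed once).
.fixtureCache <- new.env(parent = emptyenv())

smallSimulation <- function() {
  if (is.null(.fixtureCache$sim)) {
    sc <- seascapeConfig(gridNx = 40, gridNy = 30, cellSize = 2, nEnv = 8,
                         nStations = 80, nTimes = 4, spatialRange = 30,
                         seed = 5)
    sea <- makeSeascape(sc)
    mc <- metapopConfig(nSites = 25, nSnps = 1000, coloniesPerSite = c(4, 4),
                        coverageMean = 15, seed = 9)
    simd <- simulateGenotypes(mc, sea$stack)
    .fixtureCache$sim <- list(sea = sea, simd = simd, scfg = sc, mcfg = mc)
  }
  .fixtureCache$sim
}

# Plain grid spec helper.
toyGrid <- function(nx = 20, ny = 15, cellSize = 2)
  list(xll = 0, yll = 0, cellSize = cellSize, nx = nx, ny = ny)

# Single-layer stack from a matrix.
stackFromLayers <- function(layers, grid) {
  methods::new("EnvRasterStack", layers = layers, grid = grid,
               nodata = matrix(FALSE, grid$ny, grid$nx),
               provenance = data.frame(layer = names(layers),
                                       slice = "present", statistic = "value",
                                       stringsAsFactors = FALSE))
}

# Hudson's FST from a dosage matrix and population labels (oracle).
hudsonFst <- function(g, pop) {
  pops <- sort(unique(pop))
  ps <- vapply(pops, function(l) rowMeans(g[, pop == l, drop = FALSE]) / 2,
               numeric(nrow(g)))
  ns <- as.vector(table(pop))[order(pops)] * 2
  num <- den <- 0
  for (i in seq_len(ncol(ps) - 1)) for (j in seq(i + 1, ncol(ps))) {
    p1 <- ps[, i]; p2 <- ps[, j]
    num <- num + sum((p1 - p2)^2 - p1 * (1 - p1) / (ns[i] - 1) -
                       p2 * (1 - p2) / (ns[j] - 1))
    den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
  }
  num / den
}

# Adjusted Rand index between two labelings (oracle for map clustering).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  ai <- sum(comb2(rowSums(tab)))
  bj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- ai * bj / n2
  (sumij - exp_) / ((ai + bj) / 2 - exp_)
}
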