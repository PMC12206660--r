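# Conditioned ordination, jackknifing, forest fits, importance accounting,
# turnover curves, step detection.

test_that("conditioning removes exactly the covariate-aligned variance", {
  set.seed(2)
  n <- 40
  ids <- sprintf("s%03d", 1:n)
  lon <- runif(n, -10, 10)
  noise <- matrix(rnorm(n * 3), n)
  # axis 1 is an exact linear function of longitude
  X <- cbind(3 * lon, noise)
  rownames(X) <- ids
  D <- as.matrix(dist(X))
  dm <- DistanceMatrix(D / max(D), "ibs")
  cov <- data.frame(lon = lon, row.names = ids)
  ord <- conditionOrdination(dm, cov)
  expect_lt(max(abs(cor(scores(ord), lon))), 0.1)
  expect_identical(ord@covariates$names, "lon")
  # residual variance along the removed direction is gone: leading residual
  # eigenvalue far below the unconditioned one
  ord0 <- pcoa(dm)
  expect_lt(eigenvalues(ord)[1], 0.5 * eigenvalues(ord0)[1])
  # zero covariates: unchanged ordination
  ordz <- conditionOrdination(dm, NULL)
  expect_equal(scores(ordz), scores(ord0))
  # covariate exactly orthogonal to the score space (the ordination is
  # rank-4, so such a direction exists): distances preserved to 1e-8
  set.seed(7)
  z <- resid(lm(rnorm(n) ~ scores(ord0)))
  covo <- data.frame(z = z, row.names = ids)
  ordo <- conditionOrdination(dm, covo)
  expect_lt(max(abs(as.matrix(dist(scores(ordo))) -
                    as.matrix(dist(scores(ord0))))), 1e-8)
  # collinear covariates dropped with warning
  cov2 <- data.frame(lon = lon, lon2 = 2 * lon, row.names = ids)
  expect_warning(conditionOrdination(dm, cov2), "collinear")
})

test_that("jackknife replicates are seeded, sized, and stable", {
  sim <- smallSimulation()
  rcm <- filterSites(filterSamplesByCoverage(sim$simd$counts))
  d <- ibsDistance(rcm[, 1:40], seed = 3)
  meta <- as.data.frame(SummarizedExperiment::colData(rcm))[1:40, ]
  cov <- data.frame(x = meta$x_km, y = meta$y_km,
                    row.names = colnames(rcm)[1:40])
  cfg <- forestConfig(nJackknife = 5, dropFraction = 0.2, seed = 13)
  jk <- jackknifeOrdinations(d, cov, cfg)
  expect_length(jk, 5)
  expect_true(all(vapply(jk, function(o) nrow(scores(o)) == 32, logical(1))))
  jk2 <- jackknifeOrdinations(d, cov, cfg)
  expect_identical(lapply(jk, function(o) attr(o, "kept")),
                   lapply(jk2, function(o) attr(o, "kept")))
  expect_identical(scores(jk[[3]]), scores(jk2[[3]]))
  # vanishing drop fraction: replicates equal the full ordination
  cfg0 <- forestConfig(nJackknife = 2, dropFraction = 0.005, seed = 13)
  jk0 <- jackknifeOrdinations(d, cov, cfg0)
  full <- conditionOrdination(d, cov)
  expect_equal(scores(jk0[[1]]), scores(full))
  # replicates below 10 samples are refused
  tiny <- d[sampleNames(d)[1:8]]
  expect_error(jackknifeOrdinations(tiny, cov[1:8, ], cfg), "10 samples")
})

test_that("forest importance conserves variance and finds a planted driver", {
  set.seed(10)
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  depth <- runif(n, 0, 30)
  env <- data.frame(depth = depth,
                    matrix(runif(n * 5), n,
                           dimnames = list(NULL, paste0("n", 1:5))))
  rownames(env) <- ids
  y <- ifelse(depth > 11, 2, 0) + rnorm(n, 0, 0.2)
  ord <- asOrdination(cbind(y, rnorm(n, 0, 0.2)), ids)
  cfg <- forestConfig(nTrees = 300, seed = 5)
  fit <- fitForest(ord, env, mtry = "high", config = cfg)
  expect_equal(sum(fit$importance$importance), fit$totalExplained,
               tolerance = 1e-9)
  expect_identical(
    fit$importance$predictor[which.max(fit$importance$importance)], "depth")
  dimp <- fit$importance$importance[fit$importance$predictor == "depth"]
  expect_gte(dimp, 0.9 * fit$totalExplained)
  # pure-noise response: total explained ~ 0 (negative OOB R2 truncated)
  ordn <- asOrdination(cbind(rnorm(n)), ids)
  fitn <- fitForest(ordn, env, mtry = "high", config = cfg)
  expect_lt(fitn$totalExplained, 0.05)
  expect_true(all(fitn$importance$importance >= 0))
})

test_that("turnover curves are monotone, conserve importance, localize steps", {
  set.seed(11)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  depth <- runif(n, 0, 30)
  env <- data.frame(depth = depth,
                    matrix(runif(n * 4), n,
                           dimnames = list(NULL, paste0("n", 1:4))))
  rownames(env) <- ids
  y <- ifelse(depth > 11, 1, 0) + rnorm(n, 0, 0.25)
  model <- buildForestModel(asOrdination(cbind(y), ids), env,
                            forestConfig(nTrees = 300, seed = 6))
  imp <- importanceTable(model)
  expect_equal(sum(imp$importance), totalExplained(model), tolerance = 1e-9)
  tc <- turnoverCurve(model, "depth")
  expect_true(all(diff(tc@cumulative) >= -1e-12))
  expect_equal(tc@cumulative[1], 0)
  expect_equal(max(tc@cumulative),
               imp$importance[imp$predictor == "depth"], tolerance = 1e-9)
  # >= 80% of cumulative importance within +-1 m of the planted 11 m step
  gains <- diff(tc@cumulative); gth <- tc@thresholds[-1]
  expect_gte(sum(gains[abs(gth - 11) <= 1]) / max(tc@cumulative), 0.8)
  ls <- largestStep(tc)
  expect_lt(abs(ls$location - 11), 1.5)
  # linear response: accrual is diffuse relative to a step response. A sharp
  # 5%-window cannot capture most of the importance (for the step it captures
  # >= 80%), and the gain-weighted split locations span the range. Exact
  # uniformity is not expected: the root split of a linear response removes
  # ~3/4 of the sum of squares near mid-range by variance decomposition.
  y2 <- depth / 30 + rnorm(n, 0, 0.15)
  m2 <- buildForestModel(asOrdination(cbind(y2), ids), env,
                         forestConfig(nTrees = 300, seed = 7), mtry = "low")
  t2 <- turnoverCurve(m2, "depth")
  lsLin <- largestStep(t2)
  expect_lt(lsLin$step / max(t2@cumulative), 0.5)
  g2 <- diff(t2@cumulative); gt2 <- t2@thresholds[-1]
  qs <- cumsum(g2) / sum(g2)
  spread <- gt2[min(which(qs >= 0.9))] - gt2[min(which(qs >= 0.1))]
  expect_gt(spread / diff(range(depth)), 0.3)
  # a predictor that can never be split on yields a flat zero curve + warning
  envc <- cbind(env, flat = rep(1, n))
  mc <- buildForestModel(asOrdination(cbind(y2), ids), envc,
                         forestConfig(nTrees = 100, seed = 8))
  expect_warning(tcn <- turnoverCurve(mc, "flat"), "never split")
  expect_equal(max(tcn@cumulative), 0)
})

test_that("largestStep ranks a 0.3 step above a 0.1 step and handles flats", {
  tc <- methods::new("TurnoverCurve", predictor = "depth",
                     thresholds = c(0, 5, 5.2, 14.8, 15, 30),
                     cumulative = c(0, 0.15, 0.3, 0.32, 0.42, 0.44))
  ls <- largestStep(tc, window = 0.05)
  expect_lt(abs(ls$location - 5.1), 1)
  expect_gt(ls$step, 0.25)
  flat <- methods::new("TurnoverCurve", predictor = "x",
                       thresholds = 0, cumulative = 0)
  expect_true(is.na(largestStep(flat)$location))
})

test_that("mtry selection keeps causal drivers and drops proxies and decoys", {
  hits <- t(vapply(1:10, function(s) {
    set.seed(s)
    n <- 100
    ids <- sprintf("s%03d", 1:n)
    depth <- runif(n, 0, 30)
    proxy <- 0.9 * scale(depth)[, 1] + sqrt(1 - 0.81) * rnorm(n)
    env <- data.frame(depth = depth, proxy = proxy,
                      matrix(runif(n * 6), n,
                             dimnames = list(NULL, paste0("n", 1:6))))
    rownames(env) <- ids
    y <- ifelse(depth > 11, 1, 0) + rnorm(n, 0, 0.3)
    cfg <- forestConfig(nJackknife = 8, nTrees = 200, seed = s)
    jk <- jackknifeResponses(y, ids, 8, 80, s)
    sel <- mtrySelect(jk, env, cfg)
    c(causal = "depth" %in% sel$retained,
      proxyDropped = !"proxy" %in% sel$retained,
      noiseDropped = !any(paste0("n", 1:6) %in% sel$retained))
  }, logical(3)))
  expect_gte(mean(hits[, "causal"] & hits[, "proxyDropped"]), 0.8)
  expect_gte(mean(hits[, "noiseDropped"]), 0.8)
  # single informative predictor above the decoy floor is always retained
  set.seed(77)
  n <- 80; ids <- sprintf("s%03d", 1:n)
  depth <- runif(n, 0, 30)
  env1 <- data.frame(depth = depth); rownames(env1) <- ids
  y <- depth / 10 + rnorm(n, 0, 0.3)
  sel1 <- mtrySelect(jackknifeResponses(y, ids, 6, 64, 77), env1,
                     forestConfig(nJackknife = 6, nTrees = 200, seed = 77))
  expect_identical(sel1$retained, "depth")
})
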