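# Seascape projection: range rule, neighborhoods, offset, mismatch.

# A deterministic two-habitat model: response is a step in depth at 11 m.
.twoHabitatModel <- function(seed = 1, nTrees = 300) {
  set.seed(seed)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  depth <- runif(n, 0, 30)
  k490 <- runif(n, 0, 1)
  env <- data.frame(depth = depth, k490 = k490)
  rownames(env) <- ids
  y <- ifelse(depth > 11, 1, 0) + rnorm(n, 0, 0.15)
  buildForestModel(asOrdination(cbind(y), ids), env,
                   forestConfig(nTrees = nTrees, seed = seed))
}

.habitatStack <- function(grid = toyGrid(20, 15, 2), seed = 2) {
  set.seed(seed)
  depth <- matrix(runif(grid$ny * grid$nx, 2, 28), grid$ny, grid$nx)
  k490 <- matrix(runif(grid$ny * grid$nx), grid$ny, grid$nx)
  stackFromLayers(list(depth = depth, k490 = k490), grid)
}

test_that("the 10% margin rule clamps and masks cell-exactly", {
  model <- .twoHabitatModel()
  rng <- trainingRanges(model)
  lo <- rng["min", "depth"]; hi <- rng["max", "depth"]
  span <- hi - lo
  grid <- toyGrid(10, 6, 2)
  # craft depths: inside, within upper margin (clamp), beyond (mask)
  depth <- matrix(15, grid$ny, grid$nx)
  depth[1, 1] <- hi + 0.05 * span     # clamp
  depth[2, 2] <- hi + 0.15 * span     # mask
  depth[3, 3] <- lo - 0.08 * span     # clamp low
  depth[4, 4] <- lo - 0.2 * span      # mask low
  k <- matrix(0.5, grid$ny, grid$nx)
  st <- stackFromLayers(list(depth = depth, k490 = k), grid)
  pg <- predictGpcs(model, st, margin = 0.10)
  nCell <- grid$ny * grid$nx
  maskIdx <- setdiff(seq_len(nCell), pg@cellIndex)
  # exactly the two out-of-range cells are masked
  expect_setequal(maskIdx, c((2 - 1) * grid$ny + 2, (4 - 1) * grid$ny + 4))
  # exactly the two margin cells are clamped
  clampCells <- pg@cellIndex[pg@clamped]
  expect_setequal(clampCells, c((1 - 1) * grid$ny + 1, (3 - 1) * grid$ny + 3))
  # clamped prediction equals the prediction at the training max
  st2 <- st
  st2@layers$depth[1, 1] <- hi
  pg2 <- predictGpcs(model, st2, margin = 0.10)
  expect_equal(pg@predictions[match((1 - 1) * grid$ny + 1, pg@cellIndex), ],
               pg2@predictions[match((1 - 1) * grid$ny + 1, pg2@cellIndex), ])
  # all cells out of range: informative error
  stBad <- stackFromLayers(list(depth = matrix(1e4, grid$ny, grid$nx),
                                k490 = k), grid)
  expect_error(predictGpcs(model, stBad), "depth")
  # missing retained predictor: error
  expect_error(predictGpcs(model, stackFromLayers(list(
    depth = depth), grid)), "k490")
})

test_that("in-range raster prediction equals in-sample forest predictions", {
  model <- .twoHabitatModel()
  grid <- toyGrid(8, 5, 1)
  set.seed(3)
  depth <- matrix(runif(40, 5, 25), 5, 8)
  k <- matrix(runif(40, 0.2, 0.8), 5, 8)
  st <- stackFromLayers(list(depth = depth, k490 = k), grid)
  pg <- predictGpcs(model, st)
  df <- data.frame(depth = as.vector(depth), k490 = as.vector(k))
  direct <- predict(model@forests[[1]], data = df,
                    num.threads = 1)$predictions
  expect_equal(unname(pg@predictions[, 1]), unname(direct))
})

test_that("adaptive neighborhoods recover a planted habitat split", {
  model <- .twoHabitatModel()
  grid <- toyGrid(20, 15, 2)
  st <- .habitatStack(grid)
  pg <- predictGpcs(model, st)
  nb <- adaptiveNeighborhoods(pg, model, st, nFine = 25, nFinal = 2, seed = 4)
  truthLab <- as.integer(as.vector(getLayer(st, "depth"))[pg@cellIndex] > 11)
  got <- nb@clusterIds[pg@cellIndex]
  expect_gte(adjustedRand(got, truthLab), 0.9)
  # identity merge when nFinal = nFine
  nbi <- adaptiveNeighborhoods(pg, model, st, nFine = 10, nFinal = 10,
                               seed = 4)
  expect_equal(nrow(nbi@centroids), 10)
  expect_error(adaptiveNeighborhoods(pg, model, st, nFine = 5, nFinal = 6),
               "exceed")
  # permutation invariance of the partition (same data, same seed)
  nb2 <- adaptiveNeighborhoods(pg, model, st, nFine = 25, nFinal = 2, seed = 4)
  expect_gte(adjustedRand(nb@clusterIds[pg@cellIndex],
                          nb2@clusterIds[pg@cellIndex]), 0.999)
})

test_that("environmental arrows align with the axis a predictor drives", {
  # response linear in depth: depth's arrow must parallel predicted axis 1
  set.seed(5)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  depth <- runif(n, 0, 30)
  k490 <- runif(n, 0, 1)
  env <- data.frame(depth = depth, k490 = k490)
  rownames(env) <- ids
  y <- depth / 10 + rnorm(n, 0, 0.1)
  model <- buildForestModel(asOrdination(cbind(y, rnorm(n, 0, 0.05)), ids),
                            env, forestConfig(nTrees = 300, seed = 5))
  st <- .habitatStack()
  pg <- predictGpcs(model, st)
  nb <- adaptiveNeighborhoods(pg, model, st, nFine = 20, nFinal = 4, seed = 6)
  arrow <- nb@arrows[nb@arrows$predictor == "depth", ]
  ang <- atan2(abs(arrow$axis2), abs(arrow$axis1)) * 180 / pi
  expect_lt(ang, 5)
})

test_that("genetic offset is a metric response to environmental change", {
  model <- .twoHabitatModel()
  st <- .habitatStack()
  # identical stacks: offset identically zero
  off0 <- geneticOffset(model, st, st)
  expect_equal(max(getLayer(off0, "offset"), na.rm = TRUE), 0)
  # perturbing a retained predictor: median offset increases monotonically
  med <- vapply(c(0.5, 1, 2, 3, 4), function(delta) {
    st2 <- st
    st2@layers$depth <- st2@layers$depth + delta
    off <- geneticOffset(model, st, st2)
    median(getLayer(off, "offset"), na.rm = TRUE)
  }, numeric(1))
  expect_gt(cor(c(0.5, 1, 2, 3, 4), med, method = "spearman"), 0.9)
  # symmetry
  st3 <- st; st3@layers$depth <- st3@layers$depth + 2
  oAB <- getLayer(geneticOffset(model, st, st3), "offset")
  oBA <- getLayer(geneticOffset(model, st3, st), "offset")
  expect_equal(oAB, oBA)
  # grid mismatch rejected
  stG <- .habitatStack(toyGrid(10, 10, 3))
  expect_error(geneticOffset(model, st, stG), "grid")
})

test_that("perturbing a predictor outside the model leaves offset at zero", {
  model <- .twoHabitatModel()
  # retain only depth: k490 becomes a non-model layer
  set.seed(8)
  n <- 150; ids <- sprintf("s%03d", 1:n)
  depth <- runif(n, 0, 30)
  env <- data.frame(depth = depth); rownames(env) <- ids
  y <- ifelse(depth > 11, 1, 0) + rnorm(n, 0, 0.15)
  mD <- buildForestModel(asOrdination(cbind(y), ids), env,
                         forestConfig(nTrees = 200, seed = 8))
  st <- .habitatStack()
  st2 <- st
  st2@layers$k490 <- st2@layers$k490 + 10
  off <- geneticOffset(mD, st, st2)
  expect_equal(max(getLayer(off, "offset"), na.rm = TRUE), 0)
})

test_that("environmental mismatch is zero at home and high across habitats", {
  model <- .twoHabitatModel()
  st <- .habitatStack()
  pg <- predictGpcs(model, st)
  depthAt <- as.vector(getLayer(st, "depth"))[pg@cellIndex]
  # focal in the shallow habitat
  focalRow <- which(depthAt < 8)[1]
  mm <- envMismatch(pg, focal = pg@predictions[focalRow, ], seed = 2)
  v <- getLayer(mm, "mismatch")[pg@cellIndex]
  expect_equal(v[focalRow], 0)
  expect_gt(mean(v[depthAt > 14]), mean(v[depthAt < 8]))
  # focal by location resolves to its own cell (mismatch 0 there)
  ci <- pg@cellIndex[focalRow]
  row <- (ci - 1) %% pg@grid$ny + 1
  col <- (ci - 1) %/% pg@grid$ny + 1
  x <- pg@grid$xll + (col - 0.5) * pg@grid$cellSize
  y <- pg@grid$yll + (pg@grid$ny - row + 0.5) * pg@grid$cellSize
  mm2 <- envMismatch(pg, location = c(x, y), seed = 2)
  expect_equal(getLayer(mm2, "mismatch")[ci], 0)
  # scale quantile 1 with exact pairwise max: all values <= 1
  mm3 <- envMismatch(pg, focal = pg@predictions[focalRow, ],
                     scaleQuantile = 1, seed = 2)
  expect_lte(max(getLayer(mm3, "mismatch"), na.rm = TRUE), 1 + 1e-12)
  expect_error(envMismatch(pg, focal = c(1, 2, 3, 4, 5, 6, 7)), "length")
})
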