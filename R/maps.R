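# Seascape-wide projection of the fitted model: predicted-gPC rasters with
# the extended-range rule, adaptive-neighborhood clustering, genetic offset
# between time slices, and environmental mismatch for a focal coral.

#' Predict gPC scores across a seascape
#'
#' Builds the per-cell predictor vectors from the raster stack and predicts
#' each modeled gPC with the fitted forests. The model does not extrapolate:
#' a cell where any retained predictor deviates beyond 10 percent of the
#' sampled range outside the training min/max (`margin`) is masked out;
#' values within the margin are clamped to the training minimum or maximum
#' (and logged as clamped). Cells on the stack's nodata mask are never
#' predicted.
#'
#' @param model a [ForestModel-class]
#' @param stack an [EnvRasterStack-class] containing all retained predictors
#' @param margin allowed relative range extension (default 0.10)
#' @return a [PredictionGrid-class]
#' @export
predictGpcs <- function(model, stack, margin = 0.10) {
  preds <- model@retained
  missing <- setdiff(preds, layerNames(stack))
  if (length(missing))
    stop("stack lacks retained predictor(s): ", paste(missing, collapse = ", "))
  grid <- gridSpec(stack)
  nCell <- grid$ny * grid$nx
  X <- matrix(NA_real_, nCell, length(preds), dimnames = list(NULL, preds))
  for (p in preds) X[, p] <- as.vector(getLayer(stack, p))
  valid <- !as.vector(stack@nodata) & stats::complete.cases(X)
  clamped <- rep(FALSE, nCell)
  offending <- character(0)
  for (p in preds) {
    lo <- model@ranges["min", p]; hi <- model@ranges["max", p]
    ext <- margin * (hi - lo)
    out <- valid & (X[, p] < lo - ext | X[, p] > hi + ext)
    valid <- valid & !out
    if (any(out)) offending <- c(offending, p)
    inMargin <- valid & (X[, p] < lo | X[, p] > hi)
    clamped <- clamped | inMargin
    X[inMargin, p] <- pmin(pmax(X[inMargin, p], lo), hi)
  }
  if (!any(valid))
    stop("all cells masked; offending predictor(s): ",
         paste(unique(offending), collapse = ", "))
  idx <- which(valid)
  df <- as.data.frame(X[idx, , drop = FALSE])
  P <- vapply(model@forests, function(rf)
    stats::predict(rf, data = df, num.threads = 1)$predictions,
    numeric(length(idx)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(idx))
  colnames(P) <- paste0("gPC", seq_len(ncol(P)))
  mask <- matrix(FALSE, grid$ny, grid$nx)
  mask[idx] <- TRUE
  methods::new("PredictionGrid", grid = grid, predictions = P,
               cellIndex = as.integer(idx), mask = mask,
               clamped = clamped[idx])
}

#' Cluster the seascape into adaptive neighborhoods
#'
#' Two-step spatial clustering of the predictions. Step 1: each retained
#' predictor raster is transformed through its turnover curve (cumulative-
#' importance scale, a step function over the split thresholds) and the
#' transformed cell vectors are k-means clustered into `nFine` fine clusters.
#' Step 2: the fine clusters are merged hierarchically (Ward on their mean
#' predicted-gPC centroids) down to `nFinal` neighborhoods. Cells are colored
#' by the first three principal axes of the predicted gPCs (min-max scaled to
#' RGB), and an environmental vector per predictor is fitted by least-squares
#' regression on the two leading predicted axes.
#'
#' @param pg a [PredictionGrid-class]
#' @param model the [ForestModel-class] behind it
#' @param nFine number of fine turnover-space clusters (default 30)
#' @param nFinal number of final neighborhoods (<= nFine)
#' @param stack the [EnvRasterStack-class] used for prediction (for the
#'   turnover transform and arrows)
#' @param seed integer seed for k-means
#' @return a [NeighborhoodMap-class]
#' @export
adaptiveNeighborhoods <- function(pg, model, stack, nFine = 30, nFinal = 8,
                                  seed = 1) {
  if (nFinal > nFine) stop("nFinal must not exceed nFine")
  idx <- pg@cellIndex
  if (length(idx) < nFine) stop("fewer valid cells than fine clusters")
  preds <- model@retained
  TX <- matrix(0, length(idx), length(preds), dimnames = list(NULL, preds))
  for (p in preds) {
    tc <- suppressWarnings(turnoverCurve(model, p))
    v <- as.vector(getLayer(stack, p))[idx]
    if (length(tc@thresholds) > 1) {
      f <- stats::stepfun(tc@thresholds[-1], tc@cumulative)
      TX[, p] <- f(v)
    }
  }
  km <- withSeed(seed, stats::kmeans(TX, centers = nFine, nstart = 5,
                                     iter.max = 50))
  fine <- km$cluster
  P <- pg@predictions
  cent <- do.call(rbind, lapply(seq_len(nFine), function(k)
    colMeans(P[fine == k, , drop = FALSE])))
  merge <- if (nFinal == nFine) seq_len(nFine) else
    stats::cutree(stats::hclust(stats::dist(cent), method = "ward.D2"),
                  k = nFinal)
  final <- merge[fine]
  centroids <- do.call(rbind, lapply(seq_len(nFinal), function(k)
    colMeans(P[final == k, , drop = FALSE])))
  rownames(centroids) <- paste0("nbhd", seq_len(nFinal))
  # RGB from the first three principal axes of the predictions
  pca <- stats::prcomp(P, center = TRUE, scale. = FALSE)
  nAx <- min(3, ncol(pca$x))
  ax <- pca$x[, seq_len(nAx), drop = FALSE]
  rgb <- matrix(0.5, length(idx), 3)
  for (j in seq_len(nAx)) {
    rj <- range(ax[, j])
    rgb[, j] <- if (diff(rj) > 0) (ax[, j] - rj[1]) / diff(rj) else 0.5
  }
  # environmental arrows on the two leading predicted axes
  nArrow <- min(2, ncol(pca$x))
  arrows <- do.call(rbind, lapply(preds, function(p) {
    v <- as.vector(getLayer(stack, p))[idx]
    cf <- stats::coef(stats::lm(v ~ pca$x[, seq_len(nArrow)]))[-1]
    data.frame(predictor = p, axis1 = unname(cf[1]),
               axis2 = if (nArrow > 1) unname(cf[2]) else 0,
               stringsAsFactors = FALSE)
  }))
  ids <- matrix(NA_integer_, pg@grid$ny, pg@grid$nx)
  ids[idx] <- final
  methods::new("NeighborhoodMap", grid = pg@grid, clusterIds = ids,
               centroids = centroids, rgb = rgb, arrows = arrows)
}

#' Genetic offset between two environmental states
#'
#' Predicts gPC scores under two raster stacks of the same grid (e.g. past
#' and present time slices) and returns the per-cell Euclidean distance
#' between the two prediction vectors: how much adaptive reshuffling the
#' environmental change at that location implies. The output mask is the
#' intersection of the two prediction masks.
#'
#' @param model a [ForestModel-class]
#' @param past,present [EnvRasterStack-class] objects on the same grid
#' @param margin range-extension margin passed to [predictGpcs()]
#' @return an [EnvRasterStack-class] with one layer `offset`
#' @export
geneticOffset <- function(model, past, present, margin = 0.10) {
  g1 <- gridSpec(past); g2 <- gridSpec(present)
  if (!isTRUE(all.equal(g1, g2))) stop("time-slice stacks must share one grid")
  p1 <- predictGpcs(model, past, margin)
  p2 <- predictGpcs(model, present, margin)
  common <- intersect(p1@cellIndex, p2@cellIndex)
  off <- matrix(NA_real_, g1$ny, g1$nx)
  i1 <- match(common, p1@cellIndex)
  i2 <- match(common, p2@cellIndex)
  off[common] <- sqrt(rowSums((p1@predictions[i1, , drop = FALSE] -
                               p2@predictions[i2, , drop = FALSE])^2))
  methods::new("EnvRasterStack", layers = list(offset = off), grid = g1,
               nodata = is.na(off),
               provenance = data.frame(layer = "offset", slice = "delta",
                                       statistic = "euclidean",
                                       stringsAsFactors = FALSE))
}

#' Environmental mismatch for a focal coral
#'
#' Euclidean distance in predicted-gPC space between a focal vector (a
#' genotype's environment-associated profile, or the prediction at its
#' sampling location) and the prediction at every other cell, scaled by the
#' `scaleQuantile` quantile of the pairwise prediction distances across the
#' modeled range (estimated from at most `maxCells` random cells when the
#' grid is large). Low values mark areas where the focal coral would be well
#' matched if transplanted.
#'
#' @param pg a [PredictionGrid-class]
#' @param focal numeric gPC vector of length `ncol(predictions)`; omit and
#'   give `location` instead to use the prediction at a cell
#' @param location optional `c(x, y)` km location whose cell prediction
#'   becomes the focal vector (error when the cell is masked)
#' @param scaleQuantile quantile of pairwise prediction distances used as the
#'   scale (default 0.90)
#' @param maxCells cells subsampled for the pairwise-distance quantile
#' @param seed seed for the subsample
#' @return an [EnvRasterStack-class] with one layer `mismatch`
#' @export
envMismatch <- function(pg, focal = NULL, location = NULL,
                        scaleQuantile = 0.90, maxCells = 2000, seed = 1) {
  P <- pg@predictions
  if (is.null(focal)) {
    if (is.null(location)) stop("either focal or location is required")
    focal <- .focalFromLocation(pg, location)
  }
  if (length(focal) != ncol(P))
    stop("focal vector length must equal the number of modeled gPCs")
  d <- sqrt(colSums((t(P) - focal)^2))
  scl <- withSeed(seed, {
    idx <- if (nrow(P) > maxCells) sample.int(nrow(P), maxCells)
           else seq_len(nrow(P))
    stats::quantile(stats::dist(P[idx, , drop = FALSE]), scaleQuantile,
                    type = 7, names = FALSE)
  })
  if (scl <= 0) scl <- 1
  m <- matrix(NA_real_, pg@grid$ny, pg@grid$nx)
  m[pg@cellIndex] <- d / scl
  methods::new("EnvRasterStack", layers = list(mismatch = m), grid = pg@grid,
               nodata = is.na(m),
               provenance = data.frame(layer = "mismatch", slice = "present",
                                       statistic = "euclidean",
                                       stringsAsFactors = FALSE))
}

# Prediction vector at the cell containing a km location; error when the
# location is masked.
.focalFromLocation <- function(pg, loc) {
  cell <- pointToCell(pg@grid, loc[1], loc[2])
  if (is.na(cell$row)) stop("focal location falls outside the grid")
  ci <- (cell$col - 1L) * pg@grid$ny + cell$row
  pos <- match(ci, pg@cellIndex)
  if (is.na(pos)) stop("focal location falls on a masked cell")
  pg@predictions[pos, ]
}

#' Focal prediction at a location
#'
#' Convenience accessor: the predicted gPC vector at the cell containing a
#' km location.
#'
#' @param pg a [PredictionGrid-class]
#' @param x,y location in km
#' @return numeric gPC vector
#' @export
focalPrediction <- function(pg, x, y) .focalFromLocation(pg, c(x, y))
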