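# Constructors, accessors and show methods for the core containers.

#' Construct a ReadCountMatrix
#'
#' @param alleleA,alleleB sites x samples matrices of per-allele read depths
#'   (or genotype pseudo-counts)
#' @param sampleData optional data.frame of per-sample metadata (site, lat,
#'   lon, depth, lineage, ...), rownames = sample ids
#' @param siteData optional data.frame of per-SNP metadata
#' @return a [ReadCountMatrix-class]
#' @examples
#' a <- matrix(c(2, 0, 1, 2, 0, 1), 3, 2, dimnames = list(paste0("L", 1:3), c("s1", "s2")))
#' b <- 2L - a
#' rcm <- ReadCountMatrix(a, b)
#' sampleCoverage(rcm)
#' @export
ReadCountMatrix <- function(alleleA, alleleB, sampleData = NULL,
                            siteData = NULL) {
  stopifnot(identical(dim(alleleA), dim(alleleB)))
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  if (is.null(rownames(alleleA)))
    rownames(alleleA) <- rownames(alleleB) <- paste0("snp", seq_len(nrow(alleleA)))
  if (is.null(colnames(alleleA)))
    colnames(alleleA) <- colnames(alleleB) <- paste0("ind", seq_len(ncol(alleleA)))
  dimnames(alleleB) <- dimnames(alleleA)
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(alleleA))
  } else S4Vectors::DataFrame(sampleData, row.names = colnames(alleleA))
  rd <- if (is.null(siteData)) {
    S4Vectors::DataFrame(row.names = rownames(alleleA))
  } else S4Vectors::DataFrame(siteData, row.names = rownames(alleleA))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(alleleA = alleleA, alleleB = alleleB),
    colData = cd, rowData = rd)
  methods::new("ReadCountMatrix", se)
}

#' @rdname ReadCountMatrix-class
#' @export
setMethod("alleleCounts", "ReadCountMatrix", function(x) {
  list(alleleA = SummarizedExperiment::assay(x, "alleleA"),
       alleleB = SummarizedExperiment::assay(x, "alleleB"))
})

#' @rdname ReadCountMatrix-class
#' @export
setMethod("sampleCoverage", "ReadCountMatrix", function(x) {
  ac <- alleleCounts(x)
  colMeans(ac$alleleA + ac$alleleB)
})

setMethod("show", "ReadCountMatrix", function(object) {
  cat("ReadCountMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  cov <- sampleCoverage(object)
  cat("  mean coverage per sample:", round(mean(cov), 2), "\n")
  methods::callNextMethod()
})

#' Construct a DistanceMatrix
#'
#' @param m symmetric numeric matrix with zero diagonal and sample-id dimnames
#' @param kind one of `"ibs"`, `"relatedness-dissimilarity"`,
#'   `"binary-membership"`, `"geographic"`, `"euclidean"`
#' @return a [DistanceMatrix-class]
#' @export
DistanceMatrix <- function(m, kind = "ibs") {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  methods::new("DistanceMatrix", distance = m, kind = kind)
}

#' @rdname DistanceMatrix-class
#' @export
setMethod("distMatrix", "DistanceMatrix", function(x) x@distance)

#' @rdname DistanceMatrix-class
#' @export
setMethod("distKind", "DistanceMatrix", function(x) x@kind)

#' @rdname DistanceMatrix-class
#' @export
setMethod("sampleNames", "DistanceMatrix", function(object)
  rownames(object@distance))

#' @rdname DistanceMatrix-class
#' @param i,j,...,drop sample-id or index subset (applied symmetrically)
#' @export
setMethod("[", "DistanceMatrix", function(x, i, j, ..., drop = TRUE) {
  DistanceMatrix(x@distance[i, i, drop = FALSE], kind = x@kind)
})

setMethod("show", "DistanceMatrix", function(object) {
  n <- nrow(object@distance)
  off <- object@distance[upper.tri(object@distance)]
  cat(sprintf("DistanceMatrix (%s): %d samples, mean %.4f, range [%.4f, %.4f]\n",
              object@kind, n, mean(off), min(off), max(off)))
})

#' @rdname Ordination-class
#' @export
setMethod("scores", "Ordination", function(x) x@scores)

#' @rdname Ordination-class
#' @export
setMethod("eigenvalues", "Ordination", function(x) x@eigenvalues)

#' @rdname Ordination-class
#' @export
setMethod("varianceExplained", "Ordination", function(x) x@varianceExplained)

setMethod("show", "Ordination", function(object) {
  cat(sprintf("Ordination: %d samples x %d axes\n",
              nrow(object@scores), ncol(object@scores)))
  k <- min(3, ncol(object@scores))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varianceExplained[seq_len(k)]),
            collapse = ", "),
      if (ncol(object@scores) > k) "...\n" else "\n")
  if (length(object@covariates))
    cat("  conditioned on:", paste(object@covariates$names, collapse = ", "), "\n")
})

#' @rdname EnvRasterStack-class
#' @export
setMethod("layerNames", "EnvRasterStack", function(x) names(x@layers))

#' @rdname EnvRasterStack-class
#' @export
setMethod("getLayer", "EnvRasterStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "' in stack")
  x@layers[[name]]
})

#' @rdname EnvRasterStack-class
#' @export
setMethod("gridSpec", "EnvRasterStack", function(x) x@grid)

setMethod("show", "EnvRasterStack", function(object) {
  g <- object@grid
  cat(sprintf("EnvRasterStack: %d layers on %d x %d grid (%.3f km cells)\n",
              length(object@layers), g$nx, g$ny, g$cellSize))
  cat("  layers:", paste(utils::head(names(object@layers), 8), collapse = ", "),
      if (length(object@layers) > 8) "...\n" else "\n")
  cat("  nodata cells:", sum(object@nodata), "\n")
})

#' @rdname ForestModel-class
#' @export
setMethod("importanceTable", "ForestModel", function(x) x@importance)

#' @rdname ForestModel-class
#' @export
setMethod("retainedPredictors", "ForestModel", function(x) x@retained)

#' @rdname ForestModel-class
#' @export
setMethod("totalExplained", "ForestModel", function(x) x@totalExplained)

#' @rdname ForestModel-class
#' @export
setMethod("trainingRanges", "ForestModel", function(x) x@ranges)

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: %d gPCs, %d predictors, %.1f%% variance explained\n",
              length(object@forests), nrow(object@importance),
              100 * object@totalExplained))
  imp <- object@importance[order(-object@importance$importance), ]
  top <- utils::head(imp, 5)
  cat("  top predictors:",
      paste(sprintf("%s (%.3f)", top$predictor, top$importance), collapse = ", "),
      "\n")
})

setMethod("show", "TurnoverCurve", function(object) {
  cat(sprintf("TurnoverCurve for '%s': %d split thresholds, total importance %.4f\n",
              object@predictor, length(object@thresholds),
              if (length(object@cumulative)) max(object@cumulative) else 0))
})

setMethod("show", "PredictionGrid", function(object) {
  cat(sprintf("PredictionGrid: %d valid cells x %d gPCs (%d clamped, %d masked out)\n",
              nrow(object@predictions), ncol(object@predictions),
              sum(object@clamped),
              prod(dim(object@mask)) - nrow(object@predictions)))
})

setMethod("show", "NeighborhoodMap", function(object) {
  cat(sprintf("NeighborhoodMap: %d neighborhoods over %d valid cells\n",
              nrow(object@centroids), sum(!is.na(object@clusterIds))))
})
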