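#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cov dist quantile median sd var rnorm runif rbinom
#'   rpois rbeta rmultinom lm coef resid fft hclust cutree cophenetic as.dist
#'   kmeans prcomp predict setNames aggregate complete.cases weighted.mean
#' @importFrom utils head tail read.table write.table read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# ReadCountMatrix: sites x samples container of per-allele read depths.
# Genotype-only data are a special case with counts (2,0)/(1,1)/(0,2).
# ---------------------------------------------------------------------------

#' Per-allele read counts for biallelic SNPs
#'
#' `ReadCountMatrix` extends [SummarizedExperiment::SummarizedExperiment] with
#' two integer assays, `alleleA` and `alleleB`, holding per-sample read depths
#' for the two alleles of each biallelic site. Rows are SNP sites, columns are
#' individual samples. A site with both counts zero for a sample is missing
#' for that sample. Hard genotype calls are represented with pseudo-counts
#' `(2,0)`, `(1,1)`, `(0,2)`.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("ReadCountMatrix", contains = "SummarizedExperiment")

setValidity("ReadCountMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("alleleA", "alleleB") %in% an))
    return("assays 'alleleA' and 'alleleB' are required")
  a <- SummarizedExperiment::assay(object, "alleleA")
  b <- SummarizedExperiment::assay(object, "alleleB")
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    return("read counts must be non-negative")
  if (is.null(colnames(object)) || is.null(rownames(object)))
    return("sample and site names are required (dimnames)")
  TRUE
})

# ---------------------------------------------------------------------------
# DistanceMatrix
# ---------------------------------------------------------------------------

#' Pairwise sample distances with provenance
#'
#' Symmetric matrix of pairwise distances between samples with a `kind` tag
#' recording what the distances are: `"ibs"` (identity-by-state mismatch
#' fraction, values in \[0,1\]), `"relatedness-dissimilarity"`,
#' `"binary-membership"` or `"geographic"`.
#'
#' @slot distance symmetric numeric matrix, zero diagonal, dimnames = sample ids
#' @slot kind character scalar tag
#' @export
setClass("DistanceMatrix",
  representation(distance = "matrix", kind = "character"))

setValidity("DistanceMatrix", function(object) {
  m <- object@distance
  if (nrow(m) != ncol(m)) return("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("dimnames must be identical sample ids")
  if (max(abs(m - t(m))) > 1e-8) return("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) return("diagonal must be zero")
  if (!object@kind %in% c("ibs", "relatedness-dissimilarity",
                          "binary-membership", "geographic", "euclidean"))
    return("unknown kind tag")
  if (object@kind == "ibs" && (min(m) < 0 || max(m) > 1))
    return("ibs distances must lie in [0,1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Ordination
# ---------------------------------------------------------------------------

#' Principal-coordinate ordination of samples
#'
#' Sample scores on principal axes (the genetic PCs, "gPCs"), eigenvalues of
#' the positive spectrum, per-axis variance proportions, and a record of any
#' covariates regressed out of the scores before re-rotation.
#'
#' @slot scores samples x axes numeric matrix, rownames = sample ids
#' @slot eigenvalues positive eigenvalues, non-increasing
#' @slot varianceExplained proportion of positive-eigenvalue variance per axis
#' @slot covariates list with `names` and `coefficients` of regressed-out terms
#'   (empty list when the ordination is unconditioned)
#' @export
setClass("Ordination",
  representation(scores = "matrix", eigenvalues = "numeric",
                 varianceExplained = "numeric", covariates = "list"))

setValidity("Ordination", function(object) {
  if (ncol(object@scores) != length(object@eigenvalues))
    return("one eigenvalue per axis required")
  ev <- object@eigenvalues
  if (length(ev) > 1 && any(diff(ev) > 1e-8 * max(abs(ev))))
    return("axes must be ordered by non-increasing eigenvalue")
  if (is.null(rownames(object@scores)))
    return("scores must carry sample ids as rownames")
  cm <- colMeans(object@scores)
  if (length(cm) && max(abs(cm)) > 1e-6 * (1 + max(abs(object@scores))))
    return("score columns must be centered")
  TRUE
})

# ---------------------------------------------------------------------------
# EnvRasterStack
# ---------------------------------------------------------------------------

#' Named environmental layers on a common grid
#'
#' A stack of named raster layers sharing one grid specification and one
#' nodata mask. Matrices are stored with `ny` rows (row 1 = northernmost) and
#' `nx` columns, matching ESRI ASCII grid order. Cell centers are at
#' `x = xll + (col - 0.5) * cellSize`, `y = yll + (ny - row + 0.5) * cellSize`.
#' Coordinates are in km on a local projected plane.
#'
#' @slot layers named list of ny x nx numeric matrices
#' @slot grid list with `xll`, `yll`, `cellSize` (km), `nx`, `ny`
#' @slot nodata logical ny x nx matrix, TRUE where cells carry no data
#' @slot provenance data.frame with one row per layer (`layer`, `slice`,
#'   `statistic`), possibly zero rows
#' @export
setClass("EnvRasterStack",
  representation(layers = "list", grid = "list", nodata = "matrix",
                 provenance = "data.frame"))

setValidity("EnvRasterStack", function(object) {
  g <- object@grid
  need <- c("xll", "yll", "cellSize", "nx", "ny")
  if (!all(need %in% names(g))) return("grid needs xll/yll/cellSize/nx/ny")
  if (length(object@layers) == 0) return("at least one layer required")
  if (is.null(names(object@layers)) || any(names(object@layers) == ""))
    return("layers must be named")
  ok <- vapply(object@layers, function(m)
    is.matrix(m) && nrow(m) == g$ny && ncol(m) == g$nx, logical(1))
  if (!all(ok)) return("all layers must be ny x nx matrices on the grid")
  if (!all(dim(object@nodata) == c(g$ny, g$nx)))
    return("nodata mask must match grid dimensions")
  TRUE
})

# ---------------------------------------------------------------------------
# ForestModel and TurnoverCurve
# ---------------------------------------------------------------------------

#' Random-forest genotype-environment association model
#'
#' Per-gPC regression forests together with a per-predictor importance table
#' in R-squared units, the per-split impurity accounting used to build
#' turnover curves, the retained predictor set, the training range of every
#' predictor, and the total proportion of genetic variance explained.
#'
#' @slot forests list of `ranger` objects, one per modeled gPC
#' @slot importance data.frame (`predictor`, `importance`), importance in R^2
#'   units summing to `totalExplained`
#' @slot splits data.frame (`predictor`, `threshold`, `gain`) of every split in
#'   every tree, `gain` scaled so that per-predictor sums equal the importance
#'   table
#' @slot retained character vector of predictor names used by the model
#' @slot ranges 2 x p matrix (rows `min`, `max`) of training predictor ranges
#' @slot totalExplained proportion of ordination variance explained, in \[0,1\]
#' @slot gpcWeights variance share of each modeled gPC
#' @slot oobR2 out-of-bag R^2 per gPC (negatives truncated to 0)
#' @slot covariates covariate record inherited from the ordination
#' @export
setClass("ForestModel",
  representation(forests = "list", importance = "data.frame",
                 splits = "data.frame", retained = "character",
                 ranges = "matrix", totalExplained = "numeric",
                 gpcWeights = "numeric", oobR2 = "numeric",
                 covariates = "list"))

setValidity("ForestModel", function(object) {
  if (any(object@importance$importance < -1e-12))
    return("importances must be non-negative")
  if (object@totalExplained < -1e-12 || object@totalExplained > 1 + 1e-12)
    return("total explained must lie in [0,1]")
  if (!identical(rownames(object@ranges), c("min", "max")))
    return("ranges must have rows 'min' and 'max'")
  TRUE
})

#' Cumulative-importance turnover curve for one predictor
#'
#' Split thresholds of one predictor pooled over all trees and gPC forests,
#' with cumulative importance (R^2 units) accrued along the predictor range.
#' The curve is non-decreasing, starts at 0, and terminates at the predictor's
#' total importance.
#'
#' @slot predictor predictor name
#' @slot thresholds ordered split thresholds
#' @slot cumulative cumulative importance at each threshold
#' @export
setClass("TurnoverCurve",
  representation(predictor = "character", thresholds = "numeric",
                 cumulative = "numeric"))

setValidity("TurnoverCurve", function(object) {
  if (length(object@thresholds) != length(object@cumulative))
    return("thresholds and cumulative must align")
  if (length(object@cumulative)) {
    if (is.unsorted(object@thresholds)) return("thresholds must be ordered")
    if (any(diff(object@cumulative) < -1e-12))
      return("cumulative importance must be non-decreasing")
    if (object@cumulative[1] < -1e-12) return("curve must start at >= 0")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# PredictionGrid and NeighborhoodMap
# ---------------------------------------------------------------------------

#' Seascape-wide gPC predictions
#'
#' Per-cell predicted gPC vectors on a raster grid, with a validity mask
#' (cells dropped because a predictor fell beyond the extended training
#' range) and a log of cells where clamping to the training range applied.
#'
#' @slot grid grid spec as in [EnvRasterStack-class]
#' @slot predictions valid-cell x gPC matrix of predictions
#' @slot cellIndex integer index (into the ny*nx column-major cell vector) of
#'   each prediction row
#' @slot mask logical ny x nx matrix, TRUE where predictions exist
#' @slot clamped logical vector per prediction row, TRUE where any predictor
#'   was clamped into the training range
#' @export
setClass("PredictionGrid",
  representation(grid = "list", predictions = "matrix",
                 cellIndex = "integer", mask = "matrix", clamped = "logical"))

setValidity("PredictionGrid", function(object) {
  if (nrow(object@predictions) != length(object@cellIndex))
    return("one cell index per prediction row required")
  if (sum(object@mask) != nrow(object@predictions))
    return("mask must flag exactly the predicted cells")
  TRUE
})

#' Adaptive-neighborhood map
#'
#' Spatial clusters of predicted environment-associated genetic composition:
#' per-cell cluster ids, cluster centroids in gPC space, RGB coloring from the
#' first three principal axes of the predictions, and environmental vectors
#' fitted to the two leading predicted axes.
#'
#' @slot grid grid spec
#' @slot clusterIds integer ny x nx matrix (NA outside the valid mask)
#' @slot centroids cluster x gPC matrix of mean predictions
#' @slot rgb valid-cell x 3 matrix in \[0,1\] (axis-wise min-max scaling)
#' @slot arrows data.frame (`predictor`, `axis1`, `axis2`) regression loadings
#' @export
setClass("NeighborhoodMap",
  representation(grid = "list", clusterIds = "matrix", centroids = "matrix",
                 rgb = "matrix", arrows = "data.frame"))

# ---------------------------------------------------------------------------
# Configuration objects
# ---------------------------------------------------------------------------

#' Synthetic seascape configuration
#'
#' Parameters of the synthetic seascape generator: grid geometry, number of
#' environmental layers, spatial autocorrelation scale, collinear layer
#' groups, the inshore-offshore depth trend, and the random seed.
#'
#' @slot gridNx,gridNy cell counts (>= 8)
#' @slot cellSize cell size in km
#' @slot nEnv number of environmental layers (including depth)
#' @slot spatialRange autocorrelation scale in km (> 0)
#' @slot collinearGroups list of `c(size, r)` pairs: group size and target
#'   within-group absolute Pearson correlation
#' @slot depthGradient amplitude of the monotone inshore-offshore depth trend (m)
#' @slot nStations number of monitoring stations
#' @slot stationNoiseSd station measurement noise sd
#' @slot nTimes time points per slice in station series
#' @slot seed integer seed
#' @export
setClass("SeascapeConfig",
  representation(gridNx = "numeric", gridNy = "numeric", cellSize = "numeric",
                 nEnv = "numeric", spatialRange = "numeric",
                 collinearGroups = "list", depthGradient = "numeric",
                 nStations = "numeric", stationNoiseSd = "numeric",
                 nTimes = "numeric", seed = "numeric"))

setValidity("SeascapeConfig", function(object) {
  if (object@gridNx < 8 || object@gridNy < 8) return("grid dims must be >= 8")
  if (object@spatialRange <= 0) return("spatialRange must be > 0")
  for (g in object@collinearGroups) {
    if (length(g) != 2) return("collinear groups are c(size, r) pairs")
    if (g[2] < 0 || g[2] > 1) return("|r| targets must lie in [0,1]")
  }
  if (object@nEnv < 1) return("nEnv must be >= 1")
  TRUE
})

#' Synthetic metapopulation configuration
#'
#' Parameters of the coral metapopulation generator: lineage number and
#' divergence, site and colony counts, depth niches per lineage, causal loci
#' and their environmental drivers, isolation-by-distance scale, clone and
#' sibling fractions, admixture, and sequencing coverage.
#'
#' @slot nLineages number of cryptic lineages
#' @slot nSites number of sampling sites
#' @slot coloniesPerSite integer range `c(lo, hi)` of colonies sampled per site
#' @slot nSnps number of biallelic SNPs
#' @slot fst target between-lineage FST in (0,1)
#' @slot depthNiches nLineages x 2 matrix (center m, sd m) of lineage depth niches
#' @slot nCausal number of environment-linked loci
#' @slot causalEnv names of the driving environmental layers
#' @slot clineSlope slope of logit allele frequency per sd of the driver
#' @slot ibdScale isolation-by-distance autocorrelation scale, km
#' @slot cloneFraction fraction of individuals that are clonal replicates
#' @slot sibFraction fraction that are half-sib-like relatives
#' @slot admixFraction fraction with Dirichlet-admixed ancestry
#' @slot coverageMean mean sequencing depth per site per individual (Poisson)
#' @slot seed integer seed
#' @export
setClass("MetapopConfig",
  representation(nLineages = "numeric", nSites = "numeric",
                 coloniesPerSite = "numeric", nSnps = "numeric",
                 fst = "numeric", depthNiches = "matrix",
                 nCausal = "numeric", causalEnv = "character",
                 clineSlope = "numeric", ibdScale = "numeric",
                 cloneFraction = "numeric", sibFraction = "numeric",
                 admixFraction = "numeric", coverageMean = "numeric",
                 seed = "numeric"))

setValidity("MetapopConfig", function(object) {
  if (object@fst <= 0 || object@fst >= 1) return("fst must lie in (0,1)")
  if (object@nCausal > object@nSnps) return("nCausal must be <= nSnps")
  if (nrow(object@depthNiches) != object@nLineages)
    return("one depth niche (center, sd) per lineage required")
  if (length(object@coloniesPerSite) != 2 ||
      object@coloniesPerSite[1] > object@coloniesPerSite[2])
    return("coloniesPerSite must be c(lo, hi)")
  TRUE
})

#' Forest-fitting configuration
#'
#' @slot nTrees trees per forest
#' @slot mtryLow,mtryHigh mtry as fractions of the predictor count,
#'   0 < low < high <= 1
#' @slot nJackknife number of ordination jackknife replicates (>= 2)
#' @slot dropFraction fraction of samples dropped per replicate, in (0, 0.5)
#' @slot nGpcs number of leading gPCs to model; `NA` = axes covering 75% of
#'   positive-eigenvalue variance
#' @slot retainVote fraction of replicates in which importance must not drop
#'   from mtryLow to mtryHigh for a predictor to be retained
#' @slot seed integer seed
#' @export
setClass("ForestConfig",
  representation(nTrees = "numeric", mtryLow = "numeric", mtryHigh = "numeric",
                 nJackknife = "numeric", dropFraction = "numeric",
                 nGpcs = "numeric", retainVote = "numeric", seed = "numeric"))

setValidity("ForestConfig", function(object) {
  if (!(object@mtryLow > 0 && object@mtryLow < object@mtryHigh &&
        object@mtryHigh <= 1))
    return("need 0 < mtryLow < mtryHigh <= 1")
  if (object@nJackknife < 2) return("nJackknife must be >= 2")
  if (object@dropFraction <= 0 || object@dropFraction >= 0.5)
    return("dropFraction must lie in (0, 0.5)")
  TRUE
})
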