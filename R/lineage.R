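# Cryptic lineage delineation: linkage-method selection by cophenetic
# correlation, choice of the number of lineages by silhouette width and
# Mantel correlation, and threshold-based assignment of samples to lineages.

.linkageMap <- c(single = "single", complete = "complete",
                 upgma = "average", ward = "ward.D2")

#' Agglomerative clustering of a distance matrix
#'
#' Standard Lance-Williams agglomeration via [stats::hclust]. Supported
#' methods: `"single"` (nearest neighbor), `"complete"` (furthest neighbor),
#' `"upgma"` (mean distance) and `"ward"` (least squares, implemented as
#' Ward's criterion on squared distances, `ward.D2`).
#'
#' @param d a [DistanceMatrix-class] or symmetric matrix
#' @param method one of `"single"`, `"complete"`, `"upgma"`, `"ward"`
#' @return an [stats::hclust] tree
#' @export
buildTree <- function(d, method = c("upgma", "single", "complete", "ward")) {
  method <- match.arg(method)
  m <- if (methods::is(d, "DistanceMatrix")) distMatrix(d) else d
  h <- stats::hclust(stats::as.dist(m), method = .linkageMap[[method]])
  h$method.tag <- method
  h
}

#' Cophenetic correlation of a tree with its source distances
#'
#' Pearson correlation between the cophenetic distances implied by the tree
#' (the merge height joining each pair of leaves) and the original pairwise
#' distances. The linkage method maximizing this correlation is the one that
#' best preserves the distance structure.
#'
#' @param tree an [stats::hclust] tree
#' @param d the [DistanceMatrix-class] the tree was built from
#' @return Pearson r
#' @export
copheneticCorrelation <- function(tree, d) {
  m <- if (methods::is(d, "DistanceMatrix")) distMatrix(d) else d
  cd <- as.matrix(stats::cophenetic(tree))
  cd <- cd[rownames(m), colnames(m)]
  lo <- lower.tri(m)
  if (stats::sd(m[lo]) == 0)
    stop("cophenetic correlation undefined for constant distances")
  stats::cor(cd[lo], m[lo])
}

#' Select the linkage method by cophenetic correlation
#'
#' Builds a tree with each candidate linkage method and retains the one with
#' the highest cophenetic correlation against the original distances.
#'
#' @param d a [DistanceMatrix-class]
#' @param methods candidate methods (default all four)
#' @return list with `method` (chosen tag), `tree` (its hclust), and `report`
#'   (data.frame: method, copheneticR)
#' @export
selectClusteringMethod <- function(d,
    methods = c("single", "complete", "upgma", "ward")) {
  trees <- lapply(methods, function(mm) buildTree(d, mm))
  r <- vapply(trees, copheneticCorrelation, numeric(1), d = d)
  best <- which.max(r)
  list(method = methods[best], tree = trees[[best]],
       report = data.frame(method = methods, copheneticR = r,
                           stringsAsFactors = FALSE))
}

# Mean silhouette width of a hard labeling against a distance matrix.
# Singleton clusters contribute width 0 (the common convention).
meanSilhouette <- function(labels, m) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::as.dist(m))
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters by silhouette width
#'
#' Cuts the tree at each k in `kRange` and computes the mean silhouette width
#' from the original distances (singleton silhouettes counted as 0). The best
#' k maximizes the mean width; ties resolve to the smaller k.
#'
#' @param tree an [stats::hclust] tree
#' @param d the source [DistanceMatrix-class]
#' @param kRange candidate cluster numbers, within `[2, n - 1]`
#' @return list with `widths` (named per-k vector) and `bestK`
#' @export
chooseKSilhouette <- function(tree, d, kRange = 2:8) {
  m <- if (methods::is(d, "DistanceMatrix")) distMatrix(d) else d
  n <- nrow(m)
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) stop("kRange must contain values in [2, n-1]")
  widths <- vapply(kRange, function(k)
    meanSilhouette(stats::cutree(tree, k = k), m), numeric(1))
  names(widths) <- kRange
  list(widths = widths, bestK = kRange[which.max(widths)])
}

#' Mantel correlation between distances and cluster membership
#'
#' Correlates the genetic distance matrix with the binary membership
#' dissimilarity (0 to members of the same cluster, 1 otherwise) and tests it
#' by label permutation (`vegan::mantel`).
#'
#' @param d a [DistanceMatrix-class]
#' @param labels hard cluster labels aligned with the samples
#' @param nPerm permutations (default 999)
#' @param seed integer seed
#' @return list with `r` and `pValue`
#' @export
mantelMembership <- function(d, labels, nPerm = 999, seed = 1) {
  m <- if (methods::is(d, "DistanceMatrix")) distMatrix(d) else d
  if (length(unique(labels)) < 2)
    stop("at least 2 clusters required for the membership Mantel test")
  B <- outer(labels, labels, FUN = function(a, b) as.numeric(a != b))
  dimnames(B) <- dimnames(m)
  mt <- withSeed(seed,
    vegan::mantel(stats::as.dist(m), stats::as.dist(B), permutations = nPerm))
  list(r = unname(mt$statistic), pValue = unname(mt$signif))
}

#' Full clustering report: method selection, k choice, labels
#'
#' Runs [selectClusteringMethod()], evaluates silhouette widths and Mantel
#' correlations across `kRange`, picks the best k by silhouette (ties to the
#' smaller k), and cuts the chosen tree.
#'
#' @param d a [DistanceMatrix-class]
#' @param kRange candidate cluster numbers
#' @param nPerm Mantel permutations
#' @param seed integer seed
#' @return list: `method`, `tree`, `methodReport`, `silhouette` (per k),
#'   `mantelR` (per k), `bestK`, `labels`
#' @export
clusteringReport <- function(d, kRange = 2:8, nPerm = 999, seed = 1) {
  sel <- selectClusteringMethod(d)
  sil <- chooseKSilhouette(sel$tree, d, kRange)
  kR <- as.integer(names(sil$widths))
  mr <- vapply(seq_along(kR), function(i)
    mantelMembership(d, stats::cutree(sel$tree, k = kR[i]), nPerm = nPerm,
                     seed = childSeed(seed, i))$r, numeric(1))
  names(mr) <- kR
  labels <- stats::cutree(sel$tree, k = sil$bestK)
  list(method = sel$method, tree = sel$tree, methodReport = sel$report,
       silhouette = sil$widths, mantelR = mr, bestK = sil$bestK,
       labels = labels)
}

#' Assign samples to lineages from soft admixture proportions
#'
#' Applies the assignment thresholds used when subsetting lineages for
#' genotype-environment analysis: a `hard` subset per lineage (assignment
#' probability > `hardThreshold`), a more permissive `fallback` subset
#' (> `fallbackThreshold`), and a `gray` class of samples whose maximum
#' assignment is below `grayThreshold`.
#'
#' @param soft samples x lineages matrix of assignment probabilities (rows
#'   sum to 1), e.g. from external admixture software or synthetic truth
#' @param hardThreshold,fallbackThreshold,grayThreshold thresholds in (0, 1]
#' @return list: `hard` and `fallback` (lists of sample-id vectors per
#'   lineage), `gray` (sample ids), `labels` (argmax lineage per sample)
#' @export
assignLineages <- function(soft, hardThreshold = 0.9, fallbackThreshold = 0.6,
                           grayThreshold = 0.5) {
  th <- c(hardThreshold, fallbackThreshold, grayThreshold)
  if (any(th <= 0 | th > 1)) stop("thresholds must lie in (0, 1]")
  if (max(abs(rowSums(soft) - 1)) > 1e-6)
    stop("soft assignment rows must sum to 1")
  ids <- rownames(soft)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(soft)))
  lin <- colnames(soft)
  if (is.null(lin)) lin <- paste0("lineage", seq_len(ncol(soft)))
  hard <- lapply(seq_len(ncol(soft)), function(l) ids[soft[, l] > hardThreshold])
  fallback <- lapply(seq_len(ncol(soft)), function(l)
    ids[soft[, l] > fallbackThreshold])
  names(hard) <- names(fallback) <- lin
  gray <- ids[apply(soft, 1, max) < grayThreshold]
  labels <- stats::setNames(lin[max.col(soft)], ids)
  list(hard = hard, fallback = fallback, gray = gray, labels = labels)
}

#' Export a clustering tree as Newick
#'
#' Writes the dendrogram with merge heights as branch lengths.
#'
#' @param tree an [stats::hclust] tree
#' @param path output file
#' @return the path, invisibly
#' @export
exportNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
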