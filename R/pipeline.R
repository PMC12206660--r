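# End-to-end orchestration: a declarative YAML/list configuration drives
# simulate -> filter -> distance -> prune -> cluster -> per-lineage subset ->
# environmental layers -> conditioned ordination -> forest fitting and
# predictor selection -> maps -> offset & mismatch, with every stage logged
# (parameters, seeds, content hashes) and intermediate artifacts written.

#' Default pipeline configuration
#'
#' The full nested configuration with the study-condition defaults: filtering
#' thresholds (a quarter of sites at 5x; 75 percent genotyped; MAF 0.05),
#' clone-similarity pruning at 0.8, collinearity pruning at 0.9, the 10
#' percent prediction-range margin, and 0.9/0.6/0.5 lineage-assignment
#' thresholds.
#'
#' @return nested named list, the schema against which user configs are
#'   validated
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    outDir = NULL,
    simulate = list(enabled = TRUE,
                    seascape = list(gridNx = 60, gridNy = 50, cellSize = 2,
                                    nEnv = 20, spatialRange = 30,
                                    depthGradient = 25, nStations = 224,
                                    stationNoiseSd = 0.1, nTimes = 24),
                    metapop = list(nLineages = 3, nSites = 65,
                                   coloniesPerSiteLo = 4, coloniesPerSiteHi = 5,
                                   nSnps = 3000, fst = 0.15, nCausal = 150,
                                   causalEnv = "env01", clineSlope = 1.5,
                                   ibdScale = 100, cloneFraction = 0.05,
                                   sibFraction = 0.05, admixFraction = 0.1,
                                   coverageMean = 10)),
    input = list(genotypes = NULL, sites = NULL, stack = NULL),
    filter = list(minFraction = 0.25, minDepth = 5,
                  minGenotypedFraction = 0.75, minMaf = 0.05),
    prune = list(similarityThreshold = 0.8),
    cluster = list(kRange = c(2, 6), nPerm = 999),
    assign = list(hardThreshold = 0.9, fallbackThreshold = 0.6,
                  grayThreshold = 0.5),
    env = list(krige = TRUE, kernelSigmaKm = 5, collinearThreshold = 0.9),
    forest = list(nTrees = 300, mtryLow = 0.25, mtryHigh = 0.75,
                  nJackknife = 25, dropFraction = 0.2, nGpcs = 10,
                  retainVote = 0.5),
    lineages = "largest",
    maps = list(margin = 0.10, nFine = 30, nFinal = 6),
    offset = list(predictor = NULL, delta = 0.5),
    mismatch = list(scaleQuantile = 0.90))
}

# Recursively validate a user config against the default schema: unknown
# keys are rejected, known keys override defaults.
.mergeConfig <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(default)) return(user)
  extra <- setdiff(names(user), names(default))
  if (length(extra))
    stop("unknown config key(s): ",
         paste(paste0(path, extra), collapse = ", "))
  for (k in names(user))
    default[[k]] <- .mergeConfig(default[[k]], user[[k]],
                                 paste0(path, k, "."))
  default
}

#' Load and validate a pipeline configuration
#'
#' @param config path to a YAML file, or a nested list; keys absent from the
#'   default schema are rejected before execution
#' @return the merged configuration list
#' @export
loadPipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .mergeConfig(defaultPipelineConfig(), config)
}

.log <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE)
  message(msg)
}

.hashFile <- function(path) unname(tools::md5sum(path))

#' Run the full seascape-genomics pipeline
#'
#' Executes every stage in order on a synthetic or user-supplied dataset:
#' simulate (optional) -> coverage/site filtering -> IBS distance -> clone
#' pruning -> clustering and lineage assignment -> environmental layer
#' construction (station summaries, kriging, collinearity pruning, site
#' extraction) -> conditioned ordination -> jackknifed mtry predictor
#' selection -> final forest model with turnover curves -> seascape maps ->
#' genetic offset and environmental mismatch. Every stage logs its
#' parameters and seeds; artifacts are written under `outDir` when given.
#' Reruns with the same configuration reproduce all outputs.
#'
#' @param config a YAML path or nested list (see [defaultPipelineConfig()])
#' @return a result bundle: all intermediate objects plus a `log` of stage
#'   records
#' @export
runPipeline <- function(config = list()) {
  cfg <- loadPipelineConfig(config)
  seed <- cfg$seed
  outDir <- cfg$outDir
  log <- NULL
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    log <- file.path(outDir, "pipeline.log")
    cat("", file = log)
  }
  bundle <- list(config = cfg)

  # ---- stage 1: data -------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    .log(log, "simulate", "seed=", seed)
    sc <- cfg$simulate$seascape
    scfg <- seascapeConfig(gridNx = sc$gridNx, gridNy = sc$gridNy,
                           cellSize = sc$cellSize, nEnv = sc$nEnv,
                           spatialRange = sc$spatialRange,
                           depthGradient = sc$depthGradient,
                           nStations = sc$nStations,
                           stationNoiseSd = sc$stationNoiseSd,
                           nTimes = sc$nTimes, seed = childSeed(seed, 11))
    sea <- makeSeascape(scfg)
    mp <- cfg$simulate$metapop
    mcfg <- metapopConfig(nLineages = mp$nLineages, nSites = mp$nSites,
                          coloniesPerSite = c(mp$coloniesPerSiteLo,
                                              mp$coloniesPerSiteHi),
                          nSnps = mp$nSnps, fst = mp$fst,
                          nCausal = mp$nCausal, causalEnv = mp$causalEnv,
                          clineSlope = mp$clineSlope, ibdScale = mp$ibdScale,
                          cloneFraction = mp$cloneFraction,
                          sibFraction = mp$sibFraction,
                          admixFraction = mp$admixFraction,
                          coverageMean = mp$coverageMean,
                          seed = childSeed(seed, 12))
    simd <- simulateGenotypes(mcfg, sea$stack)
    counts <- simd$counts
    sites <- simd$sites
    stations <- sea$stations
    trueStack <- sea$stack
    bundle$truth <- simd$truth
  } else {
    .log(log, "load", cfg$input$genotypes)
    counts <- loadGenotypes(cfg$input$genotypes)
    sites <- utils::read.csv(cfg$input$sites, stringsAsFactors = FALSE)
    trueStack <- readRasterStack(cfg$input$stack)
    stations <- NULL
  }

  # ---- stage 2: filtering --------------------------------------------------
  n0 <- ncol(counts)
  counts <- filterSamplesByCoverage(counts, cfg$filter$minFraction,
                                    cfg$filter$minDepth)
  counts <- filterSites(counts, cfg$filter$minGenotypedFraction,
                        cfg$filter$minMaf)
  .log(log, "filter", sprintf("%d/%d samples, %d sites retained",
                              ncol(counts), n0, nrow(counts)))

  # ---- stage 3: distances and pruning -------------------------------------
  ibsSeed <- childSeed(seed, 21)
  .log(log, "ibs", "seed=", ibsSeed)
  ibs <- ibsDistance(counts, seed = ibsSeed)
  rel <- relatednessSimilarity(counts)
  pr <- pruneRedundant(rel, sampleCoverage(counts),
                       cfg$prune$similarityThreshold)
  counts <- counts[, pr$retained]
  ibs <- ibs[pr$retained]
  .log(log, "prune", sprintf("%d samples after clone/sib pruning",
                             ncol(counts)))

  # ---- stage 4: clustering and lineages -----------------------------------
  kR <- seq(cfg$cluster$kRange[1], cfg$cluster$kRange[2])
  cl <- clusteringReport(ibs, kRange = kR, nPerm = cfg$cluster$nPerm,
                         seed = childSeed(seed, 31))
  .log(log, "cluster", sprintf("method=%s k=%d", cl$method, cl$bestK))
  soft <- if (!is.null(bundle$truth)) {
    bundle$truth$admixture[colnames(counts), , drop = FALSE]
  } else {
    s <- matrix(0, ncol(counts), cl$bestK,
                dimnames = list(colnames(counts), NULL))
    s[cbind(seq_len(ncol(counts)), cl$labels)] <- 1
    s
  }
  colnames(soft) <- paste0("lineage", seq_len(ncol(soft)))
  asg <- assignLineages(soft, cfg$assign$hardThreshold,
                        cfg$assign$fallbackThreshold,
                        cfg$assign$grayThreshold)

  # ---- stage 5: environmental layers --------------------------------------
  grid <- gridSpec(trueStack)
  if (!is.null(stations) && isTRUE(cfg$env$krige)) {
    summ <- sliceSummaries(stations)
    pres <- summ[summ$slice == "present", ]
    layers <- list(depth = getLayer(trueStack, "depth"))
    for (p in setdiff(unique(pres$parameter), "depth")) {
      sub <- pres[pres$parameter == p, ]
      layers[[paste0(p, "_median")]] <-
        smoothKrige(cbind(sub$x_km, sub$y_km), sub$median, grid,
                    cfg$env$kernelSigmaKm)
    }
    prov <- data.frame(layer = names(layers), slice = "present",
                       statistic = c("value", rep("median",
                                                  length(layers) - 1)),
                       stringsAsFactors = FALSE)
    workStack <- methods::new("EnvRasterStack", layers = layers, grid = grid,
                              nodata = trueStack@nodata, provenance = prov)
    .log(log, "env", sprintf("kriged %d station parameters",
                             length(layers) - 1))
  } else {
    workStack <- trueStack
  }
  siteEnv <- extractSiteEnv(workStack, sites)
  pc <- pruneCollinear(siteEnv, cfg$env$collinearThreshold)
  siteEnv <- siteEnv[, pc$retained, drop = FALSE]
  .log(log, "env", sprintf("%d predictors after collinearity pruning",
                           length(pc$retained)))

  # sample-level predictor table
  meta <- as.data.frame(SummarizedExperiment::colData(counts))
  env <- siteEnv[meta$site, , drop = FALSE]
  rownames(env) <- colnames(counts)
  if ("depth" %in% colnames(env)) env$depth <- meta$depth_m

  # ---- stage 6: ordination and forests ------------------------------------
  # full-set analysis conditions on geographic coordinates (isolation by
  # distance); other-lineage assignment covariates enter the per-lineage
  # analyses below
  covars <- data.frame(x = meta$x_km, y = meta$y_km,
                       row.names = colnames(counts))
  ord <- conditionOrdination(ibs, covars)
  fcfg <- forestConfig(nTrees = cfg$forest$nTrees,
                       mtryLow = cfg$forest$mtryLow,
                       mtryHigh = cfg$forest$mtryHigh,
                       nJackknife = cfg$forest$nJackknife,
                       dropFraction = cfg$forest$dropFraction,
                       nGpcs = if (is.null(cfg$forest$nGpcs) ||
                                   is.na(cfg$forest$nGpcs)) NA_real_
                               else cfg$forest$nGpcs,
                       retainVote = cfg$forest$retainVote,
                       seed = childSeed(seed, 41))
  jk <- jackknifeOrdinations(ibs, covars, fcfg)
  sel <- mtrySelect(jk, env, fcfg)
  .log(log, "mtry", sprintf("retained %d/%d predictors: %s",
                            length(sel$retained), ncol(env),
                            paste(sel$retained, collapse = ", ")))
  retained <- if (length(sel$retained)) sel$retained else
    sel$decision$predictor[which.max(sel$decision$medianImportance)]
  model <- buildForestModel(ord, env, fcfg, predictors = retained)
  .log(log, "forest", sprintf("total explained %.3f", totalExplained(model)))
  curves <- lapply(retained, function(p) turnoverCurve(model, p))
  names(curves) <- retained
  steps <- lapply(curves, largestStep)

  # ---- stage 6b: per-lineage analysis -------------------------------------
  # subsets the focal lineage (fallback threshold), conditions on coordinates
  # plus assignment probabilities to the other cryptic lineages, and refits
  lineageFits <- list()
  if (!identical(cfg$lineages, "none") && ncol(soft) > 1) {
    focal <- if (identical(cfg$lineages, "largest"))
      colnames(soft)[which.max(colSums(soft))] else cfg$lineages
    for (lf in intersect(focal, colnames(soft))) {
      members <- intersect(asg$fallback[[lf]], colnames(counts))
      if (length(members) < 20) {
        .log(log, "lineage", lf, ": too few members, skipped")
        next
      }
      ibsL <- ibs[members]
      covL <- covars[members, , drop = FALSE]
      for (ol in setdiff(colnames(soft), lf))
        covL[[ol]] <- soft[members, ol]
      ordL <- conditionOrdination(ibsL, covL)
      fcfgL <- fcfg
      fcfgL@seed <- childSeed(seed, 42)
      jkL <- jackknifeOrdinations(ibsL, covL, fcfgL)
      selL <- mtrySelect(jkL, env[members, , drop = FALSE], fcfgL)
      retL <- if (length(selL$retained)) selL$retained else
        selL$decision$predictor[which.max(selL$decision$medianImportance)]
      modelL <- buildForestModel(ordL, env[members, , drop = FALSE], fcfgL,
                                 predictors = retL)
      .log(log, "lineage", sprintf("%s: n=%d, retained %s, explained %.3f",
                                   lf, length(members),
                                   paste(retL, collapse = ","),
                                   totalExplained(modelL)))
      lineageFits[[lf]] <- list(members = members, selection = selL,
                                model = modelL)
    }
  }

  # ---- stage 7: maps, offset, mismatch ------------------------------------
  pg <- predictGpcs(model, workStack, cfg$maps$margin)
  nFine <- min(cfg$maps$nFine, nrow(pg@predictions))
  nb <- adaptiveNeighborhoods(pg, model, workStack, nFine = nFine,
                              nFinal = min(cfg$maps$nFinal, nFine),
                              seed = childSeed(seed, 51))
  offPred <- cfg$offset$predictor
  if (is.null(offPred)) {
    # default: perturb the most important retained predictor
    imp <- importanceTable(model)
    offPred <- imp$predictor[which.max(imp$importance)]
  }
  offLayer <- intersect(c(offPred, paste0(offPred, "_median")),
                        layerNames(workStack))[1]
  futureStack <- workStack
  if (!is.na(offLayer)) {
    lay <- getLayer(workStack, offLayer)
    futureStack@layers[[offLayer]] <-
      lay + cfg$offset$delta * stats::sd(as.vector(lay), na.rm = TRUE)
  }
  off <- geneticOffset(model, workStack, futureStack, cfg$maps$margin)
  mm <- envMismatch(pg, focal = pg@predictions[1, ],
                    scaleQuantile = cfg$mismatch$scaleQuantile,
                    seed = childSeed(seed, 61))

  bundle <- c(bundle, list(
    counts = counts, sites = sites, ibs = ibs, pruning = pr,
    clustering = cl, assignments = asg, stack = workStack, siteEnv = siteEnv,
    collinearity = pc, ordination = ord, selection = sel, model = model,
    turnoverCurves = curves, steps = steps, lineageFits = lineageFits,
    predictions = pg, neighborhoods = nb, offset = off, mismatch = mm))

  # ---- artifacts -----------------------------------------------------------
  if (!is.null(outDir)) {
    writeDistanceMatrix(ibs, file.path(outDir, "ibs_distance.csv"))
    utils::write.csv(importanceTable(model),
                     file.path(outDir, "importance.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(sel$decision, file.path(outDir, "mtry_decision.csv"),
                     row.names = FALSE, quote = FALSE)
    for (p in names(curves)) {
      tc <- curves[[p]]
      utils::write.csv(data.frame(threshold = tc@thresholds,
                                  cumulative = tc@cumulative),
                       file.path(outDir, paste0("turnover_", p, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    writeOrdination(ord, file.path(outDir, "ordination_scores.csv"),
                    file.path(outDir, "ordination_meta.json"))
    writeRasterStack(off, outDir, "offset")
    writeRasterStack(mm, outDir, "mismatch")
    exportNewick(cl$tree, file.path(outDir, "dendrogram.nwk"))
    jsonlite::write_json(
      list(method = cl$method, bestK = cl$bestK,
           silhouette = as.list(cl$silhouette),
           mantelR = as.list(cl$mantelR),
           totalExplained = totalExplained(model),
           retained = retained,
           steps = lapply(steps, function(s) s["location"])),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    for (f in list.files(outDir, full.names = TRUE))
      if (!grepl("pipeline\\.log$", f))
        .log(log, "artifact", basename(f), " md5=", .hashFile(f))
  }
  bundle
}
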