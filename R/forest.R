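# Random-forest genotype-environment association on genetic principal
# coordinates: covariate-conditioned ordination, jackknifed forest fits at
# two mtry settings, selection of truly influential predictors, per-split
# importance accounting, turnover curves and threshold detection.

#' Condition an ordination on covariates
#'
#' Regresses each principal-coordinate axis on the covariates (ordinary least
#' squares with intercept; collinear covariate columns are dropped with a
#' warning), then re-orthogonalizes the residual scores by principal-component
#' rotation. The eigenvalue record is updated to the residual variances, so
#' downstream forests model only the genetic variation not explained by the
#' covariates (e.g. geographic coordinates for isolation by distance, and
#' assignment probabilities to other cryptic lineages).
#'
#' @param d a [DistanceMatrix-class] or an [Ordination-class]
#' @param covariates data.frame/matrix of numeric covariates aligned with the
#'   samples (zero columns allowed: the ordination is returned unchanged)
#' @return an [Ordination-class] with a covariate record
#' @export
conditionOrdination <- function(d, covariates = NULL) {
  ord <- if (methods::is(d, "Ordination")) d else pcoa(d)
  S <- scores(ord)
  if (is.null(covariates) || NCOL(covariates) == 0) return(ord)
  X <- as.matrix(covariates)
  if (nrow(X) != nrow(S)) stop("covariates must align with samples")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("cov", seq_len(ncol(X)))
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping collinear covariate column(s): ",
            paste(dropped, collapse = ", "))
    Xi <- Xi[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(Xi)
  }
  beta <- qr.coef(qrX, S)
  R <- S - Xi %*% beta
  sv <- svd(R)
  keep <- which(sv$d^2 > max(sv$d^2) * 1e-10)
  sc <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  rownames(sc) <- rownames(S)
  colnames(sc) <- paste0("gPC", seq_along(keep))
  lam <- sv$d[keep]^2
  methods::new("Ordination", scores = sc, eigenvalues = lam,
               varianceExplained = lam / sum(lam),
               covariates = list(names = cn, coefficients = beta))
}

#' Jackknife replicate ordinations
#'
#' Generates `nJackknife` replicate conditioned ordinations, each dropping a
#' seeded random `dropFraction` of the samples and recomputing the PCoA and
#' covariate conditioning on the remainder. Models the uncertainty of
#' reconstructing gPCs.
#'
#' @param d a [DistanceMatrix-class]
#' @param covariates covariate data.frame aligned with the samples (rownames
#'   = sample ids), or NULL
#' @param config a [forestConfig()]
#' @return list of [Ordination-class] replicates (attribute `kept` holds the
#'   retained sample ids of each)
#' @export
jackknifeOrdinations <- function(d, covariates, config) {
  ids <- sampleNames(d)
  n <- length(ids)
  nKeep <- round(n * (1 - config@dropFraction))
  if (nKeep < 10) stop("jackknife replicates would retain fewer than 10 samples")
  withSeed(childSeed(config@seed, 1), {
    lapply(seq_len(config@nJackknife), function(r) {
      keep <- sort(sample.int(n, nKeep))
      dm <- d[ids[keep]]
      cv <- if (is.null(covariates)) NULL else
        covariates[ids[keep], , drop = FALSE]
      o <- conditionOrdination(dm, cv)
      attr(o, "kept") <- ids[keep]
      o
    })
  })
}

# Number of leading gPCs to model: explicit config value, or the smaller of
# (a) the axes covering 75% of positive-eigenvalue variance and (b) the axes
# with above-average eigenvalue (Kaiser-Guttman). A flat PCoA spectrum would
# otherwise drag dozens of sampling-noise axes into the forests, diluting
# importance.
.nGpcsUsed <- function(ord, config) {
  k <- ncol(scores(ord))
  if (!is.na(config@nGpcs)) return(min(config@nGpcs, k))
  ve <- eigenvalues(ord) / sum(eigenvalues(ord))
  n75 <- min(which(cumsum(ve) >= 0.75))
  kaiser <- sum(ve > 1 / k)
  max(1, min(n75, kaiser))
}

.mtryCount <- function(frac, p, n) {
  m <- max(1, ceiling(frac * p))
  if (n < 2 * m) {
    warning("fewer samples than 2*mtry predictors; clipping mtry")
    m <- max(1, floor(n / 2))
  }
  min(m, p)
}

#' Fit per-gPC random forests on environmental predictors
#'
#' One regression forest per modeled gPC (leading axes per the config).
#' Forest-level fit is the out-of-bag R-squared (negatives truncated to 0);
#' per-predictor importance within a forest is its impurity-reduction share
#' normalized so forest importances sum to that forest's R-squared. Axis
#' importances are combined weighted by each gPC's share of ordination
#' variance, so the summed importance over predictors equals the total
#' proportion of variance explained.
#'
#' @param ord an [Ordination-class] (typically conditioned)
#' @param env data.frame of site/sample-level predictors aligned with the
#'   ordination samples (rownames = sample ids)
#' @param mtry `"low"`, `"high"`, or a numeric fraction of the predictor count
#' @param config a [forestConfig()]
#' @param seed seed for the forests (default derived from config)
#' @return list: `importance` (data.frame predictor/importance), `oobR2`
#'   (per gPC, truncated), `totalExplained`, `weights` (gPC variance shares),
#'   `forests` (ranger objects), `env`, `scores` (training data retained for
#'   split accounting)
#' @export
fitForest <- function(ord, env, mtry = "high", config = forestConfig(),
                      seed = NULL) {
  env <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  S <- scores(ord)
  if (!is.null(rownames(env)) && !identical(rownames(env), rownames(S))) {
    if (!all(rownames(S) %in% rownames(env)))
      stop("predictor table must cover all ordination samples")
    env <- env[rownames(S), , drop = FALSE]
  }
  if (nrow(env) != nrow(S)) stop("samples misaligned between ordination and predictors")
  p <- ncol(env)
  frac <- if (is.character(mtry))
    switch(match.arg(mtry, c("low", "high")), low = config@mtryLow,
           high = config@mtryHigh) else mtry
  mtryN <- .mtryCount(frac, p, nrow(env))
  nG <- .nGpcsUsed(ord, config)
  lam <- eigenvalues(ord)[seq_len(nG)]
  w <- lam / sum(lam)
  if (is.null(seed)) seed <- childSeed(config@seed, 2)
  forests <- vector("list", nG)
  oob <- numeric(nG)
  impShare <- matrix(0, p, nG, dimnames = list(colnames(env), NULL))
  for (g in seq_len(nG)) {
    y <- S[, g]
    rf <- ranger::ranger(x = env, y = y, num.trees = config@nTrees,
                         mtry = mtryN, importance = "impurity",
                         seed = childSeed(seed, g), num.threads = 1)
    forests[[g]] <- rf
    oob[g] <- max(0, rf$r.squared)
    imp <- rf$variable.importance
    if (sum(imp) > 0) impShare[names(imp), g] <- imp / sum(imp)
  }
  combined <- as.vector(impShare %*% (w * oob))
  total <- sum(w * oob)
  list(importance = data.frame(predictor = colnames(env),
                               importance = combined,
                               stringsAsFactors = FALSE),
       oobR2 = oob, totalExplained = total, weights = w,
       forests = forests, env = env, scores = S[, seq_len(nG), drop = FALSE],
       mtry = mtryN)
}

#' Select truly influential predictors by the mtry contrast
#'
#' Correlated proxy predictors share importance at low mtry but are
#' outcompeted by the true driver when mtry is high. On each jackknife
#' replicate the forests are fitted at both mtry settings with a seeded
#' random-normal decoy predictor appended; a predictor is retained when (a)
#' its importance at the high mtry is at least its importance at the low mtry
#' in at least `retainVote` of replicates, and (b) its median importance
#' (high mtry) exceeds the decoy floor, the median importance of the decoy.
#'
#' @param ordinations list of jackknife [Ordination-class] replicates (from
#'   [jackknifeOrdinations()])
#' @param env predictor data.frame with rownames = sample ids
#' @param config a [forestConfig()]
#' @return list: `retained` predictor names, `decision` data.frame
#'   (predictor, voteFraction, medianImportance, decoyFloor, retained),
#'   `importanceLow`/`importanceHigh` (replicate x predictor matrices)
#' @export
mtrySelect <- function(ordinations, env, config) {
  env <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  nR <- length(ordinations)
  preds <- colnames(env)
  impL <- impH <- matrix(NA_real_, nR, length(preds) + 1,
                         dimnames = list(NULL, c(preds, ".decoy")))
  for (r in seq_len(nR)) {
    o <- ordinations[[r]]
    kept <- attr(o, "kept")
    if (is.null(kept)) kept <- rownames(scores(o))
    e <- env[kept, , drop = FALSE]
    e$.decoy <- withSeed(childSeed(config@seed, 100 + r),
                         stats::rnorm(nrow(e)))
    fl <- fitForest(o, e, mtry = "low", config = config,
                    seed = childSeed(config@seed, 200 + r))
    fh <- fitForest(o, e, mtry = "high", config = config,
                    seed = childSeed(config@seed, 300 + r))
    impL[r, fl$importance$predictor] <- fl$importance$importance
    impH[r, fh$importance$predictor] <- fh$importance$importance
  }
  floorImp <- stats::median(impH[, ".decoy"])
  vote <- colMeans(impH[, preds, drop = FALSE] >=
                     impL[, preds, drop = FALSE] - 1e-12)
  medImp <- apply(impH[, preds, drop = FALSE], 2, stats::median)
  keep <- vote >= config@retainVote & medImp > floorImp
  decision <- data.frame(predictor = preds, voteFraction = unname(vote),
                         medianImportance = unname(medImp),
                         decoyFloor = floorImp, retained = unname(keep),
                         stringsAsFactors = FALSE)
  list(retained = preds[keep], decision = decision,
       importanceLow = impL, importanceHigh = impH)
}

# ---------------------------------------------------------------------------
# Per-split impurity accounting (for turnover curves)
# ---------------------------------------------------------------------------

# Push the training data through one ranger tree and compute the sum-of-
# squares reduction of every split. Returns data.frame(predictor, threshold,
# gain). SS(node) - SS(left) - SS(right) is accumulated from sums and
# sums-of-squares so the walk stays O(n log n) per tree.
.treeSplitGains <- function(rf, treeNum, X, y) {
  ti <- ranger::treeInfo(rf, treeNum)
  nNodes <- nrow(ti)
  splitCol <- match(ti$splitvarName, colnames(X))
  rowsAt <- vector("list", nNodes)
  rowsAt[[1]] <- seq_len(nrow(X))
  pred <- character(nNodes); thr <- numeric(nNodes); gain <- numeric(nNodes)
  nOut <- 0L
  ss <- function(idx) {
    n <- length(idx)
    if (n < 2) return(0)
    yy <- y[idx]
    sum(yy * yy) - sum(yy)^2 / n
  }
  for (nd in seq_len(nNodes)) {
    rows <- rowsAt[[nd]]
    rowsAt[nd] <- list(NULL)
    if (ti$terminal[nd] || is.null(rows) || length(rows) < 2) next
    v <- X[rows, splitCol[nd]]
    isLeft <- v <= ti$splitval[nd]
    left <- rows[isLeft]
    right <- rows[!isLeft]
    rowsAt[[ti$leftChild[nd] + 1]] <- left
    rowsAt[[ti$rightChild[nd] + 1]] <- right
    g <- ss(rows) - ss(left) - ss(right)
    if (is.finite(g) && g > 0) {
      nOut <- nOut + 1L
      pred[nOut] <- ti$splitvarName[nd]
      thr[nOut] <- ti$splitval[nd]
      gain[nOut] <- g
    }
  }
  if (!nOut) return(NULL)
  data.frame(predictor = pred[seq_len(nOut)], threshold = thr[seq_len(nOut)],
             gain = gain[seq_len(nOut)], stringsAsFactors = FALSE)
}

# Split gains pooled across all trees of all gPC forests of a fit, with each
# forest's gains rescaled so per-predictor totals match the fit's combined
# importance table exactly.
.fitSplitGains <- function(fit) {
  all <- list()
  Xm <- as.matrix(fit$env)
  for (g in seq_along(fit$forests)) {
    rf <- fit$forests[[g]]
    gains <- do.call(rbind, lapply(seq_len(rf$num.trees), function(t)
      .treeSplitGains(rf, t, Xm, fit$scores[, g])))
    if (is.null(gains) || !nrow(gains)) next
    # scale this forest's gains to its contribution in R^2 units
    tot <- sum(gains$gain)
    gains$gain <- gains$gain / tot * (fit$weights[g] * fit$oobR2[g])
    all[[g]] <- gains
  }
  gains <- do.call(rbind, all)
  if (is.null(gains))
    return(data.frame(predictor = character(), threshold = numeric(),
                      gain = numeric(), stringsAsFactors = FALSE))
  # final exact rescale per predictor onto the importance table
  imp <- stats::setNames(fit$importance$importance, fit$importance$predictor)
  bypred <- split(gains, gains$predictor)
  out <- lapply(names(bypred), function(pn) {
    gg <- bypred[[pn]]
    tt <- sum(gg$gain)
    if (tt > 0 && !is.na(imp[pn])) gg$gain <- gg$gain / tt * imp[pn]
    gg
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the final forest model on retained predictors
#'
#' Refits the per-gPC forests on the retained predictor set at the high mtry
#' setting, runs the per-split impurity accounting that supports turnover
#' curves (every split's sum-of-squares reduction is recovered by pushing the
#' training data through the fitted trees, then rescaled so per-predictor
#' totals equal the importance table exactly), and records training predictor
#' ranges for the prediction-range rule.
#'
#' @param ord conditioned [Ordination-class]
#' @param env predictor data.frame
#' @param config a [forestConfig()]
#' @param predictors predictor subset to use (default: all columns of `env`)
#' @param mtry `"low"`, `"high"` or fraction (default `"high"`)
#' @return a [ForestModel-class]
#' @export
buildForestModel <- function(ord, env, config = forestConfig(),
                             predictors = NULL, mtry = "high") {
  env <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(predictors)) {
    missing <- setdiff(predictors, colnames(env))
    if (length(missing)) stop("unknown predictor(s): ",
                              paste(missing, collapse = ", "))
    env <- env[, predictors, drop = FALSE]
  }
  fit <- fitForest(ord, env, mtry = mtry, config = config)
  splits <- .fitSplitGains(fit)
  rng <- rbind(min = apply(fit$env, 2, min), max = apply(fit$env, 2, max))
  methods::new("ForestModel", forests = fit$forests,
               importance = fit$importance, splits = splits,
               retained = colnames(fit$env), ranges = rng,
               totalExplained = fit$totalExplained,
               gpcWeights = fit$weights, oobR2 = fit$oobR2,
               covariates = if (methods::is(ord, "Ordination"))
                 ord@covariates else list())
}

#' Turnover curve of a predictor
#'
#' Pools every split on the predictor across all trees and gPC forests; each
#' split contributes its normalized importance share at its threshold. The
#' cumulative sum over sorted thresholds is the turnover curve: cumulative
#' genetic variation captured as one moves across the predictor range. The
#' curve starts at 0 at the training-range minimum and terminates at the
#' predictor's total importance.
#'
#' @param model a [ForestModel-class]
#' @param predictor predictor name (must be in the retained set)
#' @return a [TurnoverCurve-class]
#' @export
turnoverCurve <- function(model, predictor) {
  if (!predictor %in% model@retained)
    stop("predictor '", predictor, "' is not in the model's retained set")
  sp <- model@splits[model@splits$predictor == predictor, , drop = FALSE]
  lo <- model@ranges["min", predictor]
  if (!nrow(sp)) {
    warning("predictor '", predictor, "' was never split on; flat curve")
    return(methods::new("TurnoverCurve", predictor = predictor,
                        thresholds = lo, cumulative = 0))
  }
  agg <- stats::aggregate(gain ~ threshold, data = sp, FUN = sum)
  agg <- agg[order(agg$threshold), ]
  methods::new("TurnoverCurve", predictor = predictor,
               thresholds = c(lo, agg$threshold),
               cumulative = c(0, cumsum(agg$gain)))
}

#' Locate the largest turnover step
#'
#' Slides a window of `window` times the predictor range along the turnover
#' curve and reports the window accruing the largest cumulative-importance
#' gain; the reported threshold is the gain-weighted mean split location
#' inside that window (ties resolve to the lower value). Large steps mark
#' putative adaptive thresholds along the gradient.
#'
#' @param curve a [TurnoverCurve-class]
#' @param window window width as a fraction of the predictor range
#'   (default 0.05)
#' @return list: `location`, `step` (gain inside the window), `window` (km/m/
#'   units of the predictor); `location` is `NA` for a flat curve
#' @export
largestStep <- function(curve, window = 0.05) {
  th <- curve@thresholds
  cum <- curve@cumulative
  if (length(th) < 2 || max(cum) <= 0)
    return(list(location = NA_real_, step = 0,
                window = if (length(th) > 1) window * diff(range(th)) else 0))
  gains <- diff(cum)
  gth <- th[-1]
  w <- window * diff(range(th))
  best <- list(gain = -Inf, loc = NA_real_)
  for (i in seq_along(gth)) {
    inWin <- gth >= gth[i] & gth <= gth[i] + w
    g <- sum(gains[inWin])
    if (g > best$gain + 1e-12) {
      best <- list(gain = g,
                   loc = sum(gth[inWin] * gains[inWin]) / sum(gains[inWin]))
    }
  }
  list(location = best$loc, step = best$gain, window = w)
}
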