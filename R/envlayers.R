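# Environmental raster construction: station time-series summaries,
# satellite-style thermal summaries, Gaussian-kernel smoothing followed by
# ordinary kriging, multicollinearity pruning, and site-level extraction.

#' Per-station time-slice summaries
#'
#' For each station, parameter and time slice, computes the median and the
#' 0.1-0.9 interquantile range (q90 - q10, linear-interpolation quantiles,
#' type 7) of the measured values. Default slices are 1995-2007 ("past") and
#' 2008-2021 ("present"), boundaries inclusive. When both bottom and surface
#' measurements exist for a station-parameter, surface rows are discarded.
#' Station-parameter combinations with no data in a slice are absent from the
#' output.
#'
#' @param stations long data.frame: `station`, `x_km`, `y_km`, `date`,
#'   `parameter`, `value`, optional `depth_flag` (`"bottom"`/`"surface"`)
#' @param slices named list of `c(start, end)` date pairs
#' @return data.frame: station, x_km, y_km, parameter, slice, median, range
#' @export
sliceSummaries <- function(stations,
    slices = list(past = c("1995-01-01", "2007-12-31"),
                  present = c("2008-01-01", "2021-12-31"))) {
  stopifnot(all(c("station", "date", "parameter", "value") %in% names(stations)))
  stations$date <- as.Date(stations$date)
  if ("depth_flag" %in% names(stations)) {
    # bottom-over-surface preference, per station-parameter
    key <- paste(stations$station, stations$parameter)
    hasBottom <- key %in% key[stations$depth_flag == "bottom"]
    drop <- hasBottom & stations$depth_flag == "surface"
    stations <- stations[!drop, , drop = FALSE]
  }
  out <- list()
  for (sl in names(slices)) {
    lim <- as.Date(slices[[sl]])
    sub <- stations[stations$date >= lim[1] & stations$date <= lim[2], ,
                    drop = FALSE]
    if (!nrow(sub)) next
    agg <- do.call(rbind, lapply(
      split(sub, paste(sub$station, sub$parameter, sep = "\r")),
      function(g) {
        q <- stats::quantile(g$value, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
        data.frame(station = g$station[1],
                   x_km = if ("x_km" %in% names(g)) g$x_km[1] else NA_real_,
                   y_km = if ("y_km" %in% names(g)) g$y_km[1] else NA_real_,
                   parameter = g$parameter[1], slice = sl,
                   median = q[2], range = q[3] - q[1],
                   stringsAsFactors = FALSE)
      }))
    out[[sl]] <- agg
  }
  if (!length(out)) stop("no station data fall inside any slice")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$slice, res$parameter, res$station), ]
}

#' Thermal summaries of a gridded time series
#'
#' From a gridded daily or monthly series: computes monthly means per cell,
#' takes the per-year minimum and maximum monthly mean, and averages those
#' extremes across years (`sst_min`, `sst_max`). For thermal-anomaly input
#' the same machinery yields the across-year mean of the yearly maximum
#' monthly mean (`dhw_max`). Months with no data are excluded from that
#' year's extremes with a warning.
#'
#' @param series ny x nx x T array of gridded values
#' @param dates Date vector of length T
#' @param statistic `"minmax"` (returns `min` and `max` layers) or `"max"`
#'   (returns `max` only, the anomaly convention)
#' @return named list of ny x nx matrices (`min` and/or `max`)
#' @export
thermalSummaries <- function(series, dates, statistic = c("minmax", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(length(dates) == dim(series)[3])
  dates <- as.Date(dates)
  yr <- format(dates, "%Y"); mo <- format(dates, "%m")
  years <- unique(yr)
  if (length(unique(paste(yr, mo))) < 12)
    warning("series covers fewer than 12 distinct months")
  ny <- dim(series)[1]; nx <- dim(series)[2]
  yearMin <- array(NA_real_, c(ny, nx, length(years)))
  yearMax <- array(NA_real_, c(ny, nx, length(years)))
  for (k in seq_along(years)) {
    mos <- unique(mo[yr == years[k]])
    if (length(mos) < 12)
      warning(sprintf("year %s has data for only %d months", years[k],
                      length(mos)))
    mm <- array(NA_real_, c(ny, nx, length(mos)))
    for (j in seq_along(mos)) {
      idx <- which(yr == years[k] & mo == mos[j])
      mm[, , j] <- apply(series[, , idx, drop = FALSE], c(1, 2), mean)
    }
    yearMin[, , k] <- apply(mm, c(1, 2), min)
    yearMax[, , k] <- apply(mm, c(1, 2), max)
  }
  out <- list(max = apply(yearMax, c(1, 2), mean))
  if (statistic == "minmax")
    out <- list(min = apply(yearMin, c(1, 2), mean), max = out$max)
  out
}

# ---------------------------------------------------------------------------
# Variogram fitting and ordinary kriging
# ---------------------------------------------------------------------------

.vgModel <- function(h, p, model) {
  n <- p[1]; s <- p[2]; r <- p[3]
  switch(model,
    spherical = ifelse(h <= 0, 0,
      ifelse(h < r, n + s * (1.5 * h / r - 0.5 * (h / r)^3), n + s)),
    exponential = ifelse(h <= 0, 0, n + s * (1 - exp(-3 * h / r))),
    gaussian = ifelse(h <= 0, 0, n + s * (1 - exp(-3 * h^2 / r^2))))
}

# Empirical semivariogram (equal-width bins to half the max distance) and
# weighted least-squares fit of candidate models; returns the best model.
.fitVariogram <- function(xy, v, models = c("spherical", "exponential",
                                            "gaussian"),
                          nBins = 15, fixNugget = NULL) {
  D <- as.matrix(stats::dist(xy))
  lo <- lower.tri(D)
  h <- D[lo]
  g <- 0.5 * (outer(v, v, "-")[lo])^2
  hmax <- max(h) / 2
  bins <- cut(h, breaks = seq(0, hmax, length.out = nBins + 1),
              include.lowest = TRUE)
  hb <- tapply(h[!is.na(bins)], bins[!is.na(bins)], mean)
  gb <- tapply(g[!is.na(bins)], bins[!is.na(bins)], mean)
  nb <- tapply(g[!is.na(bins)], bins[!is.na(bins)], length)
  ok <- !is.na(hb)
  hb <- hb[ok]; gb <- gb[ok]; nb <- nb[ok]
  best <- NULL
  for (mdl in models) {
    obj <- function(par) {
      p <- c(if (is.null(fixNugget)) exp(par[1]) - 1e-9 else fixNugget,
             exp(par[2]), exp(par[3]))
      sum(nb * (.vgModel(hb, p, mdl) - gb)^2)
    }
    init <- c(log(max(min(gb), 1e-6)), log(max(stats::var(v), 1e-9)),
              log(hmax / 2))
    fit <- try(stats::optim(if (is.null(fixNugget)) init else init[2:3],
      function(par) obj(if (is.null(fixNugget)) par else c(NA, par)),
      method = "Nelder-Mead"), silent = TRUE)
    if (inherits(fit, "try-error")) next
    par <- fit$par
    p <- if (is.null(fixNugget))
      c(exp(par[1]) - 1e-9, exp(par[2]), exp(par[3]))
    else c(fixNugget, exp(par[1]), exp(par[2]))
    if (is.null(best) || fit$value < best$sse)
      best <- list(model = mdl, nugget = max(p[1], 0), sill = p[2],
                   range = p[3], sse = fit$value)
  }
  if (is.null(best)) stop("variogram fitting failed for all models")
  best
}

#' Gaussian-kernel smoothing followed by ordinary kriging
#'
#' Two-step interpolation of station values onto a raster grid. Step 1:
#' Nadaraya-Watson smoothing of the station values at the station locations
#' with a Gaussian kernel of bandwidth `kernelSigmaKm` (a bandwidth of 0
#' leaves the values untouched). Step 2: ordinary kriging of the smoothed
#' values onto the grid, with a semivariogram fitted automatically by
#' weighted least squares over spherical, exponential and Gaussian models
#' (the best-fitting model wins). The pre-smoothing regularizes the
#' variogram: raw station data occasionally produce degenerate interpolation.
#' A singular kriging system falls back to inverse-distance weighting of the
#' smoothed values with a warning. A constant field short-circuits to a
#' constant surface (kriging exactness).
#'
#' @param xy stations x 2 matrix of km coordinates
#' @param values station values
#' @param grid grid spec (`xll`, `yll`, `cellSize`, `nx`, `ny`)
#' @param kernelSigmaKm Gaussian kernel bandwidth in km (default 5)
#' @param nugget fixed nugget (`NULL` to fit; set 0 for exact interpolation)
#' @return ny x nx matrix of interpolated values
#' @export
smoothKrige <- function(xy, values, grid, kernelSigmaKm = 5, nugget = NULL) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 5) stop("at least 5 stations required")
  if (stats::sd(values) < 1e-12) {
    return(matrix(values[1], grid$ny, grid$nx))
  }
  # step 1: Gaussian-kernel smoothing at station locations
  sm <- values
  if (kernelSigmaKm > 0) {
    D2 <- as.matrix(stats::dist(xy))^2
    W <- exp(-D2 / (2 * kernelSigmaKm^2))
    sm <- as.vector(W %*% values / rowSums(W))
  }
  # step 2: ordinary kriging of smoothed values
  vg <- .fitVariogram(xy, sm, fixNugget = nugget)
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  Gamma <- .vgModel(D, c(vg$nugget, vg$sill, vg$range), vg$model)
  diag(Gamma) <- 0
  A <- rbind(cbind(Gamma, 1), c(rep(1, n), 0))
  cc <- gridCoords(grid)
  gx <- rep(cc$x, each = grid$ny)
  gy <- rep(cc$y, times = grid$nx)
  # distances stations x cells
  DS <- sqrt(outer(xy[, 1], gx, "-")^2 + outer(xy[, 2], gy, "-")^2)
  G0 <- .vgModel(DS, c(vg$nugget, vg$sill, vg$range), vg$model)
  G0[DS == 0] <- 0
  rhs <- rbind(G0, 1)
  Wk <- try(solve(A, rhs), silent = TRUE)
  if (inherits(Wk, "try-error")) {
    warning("singular kriging system; falling back to inverse-distance weighting")
    wi <- 1 / pmax(DS, 1e-6)^2
    pred <- as.vector(crossprod(wi, sm) / colSums(wi))
  } else {
    pred <- as.vector(crossprod(Wk[seq_len(n), , drop = FALSE], sm))
  }
  matrix(pred, grid$ny, grid$nx)
}

#' Prune multicollinear predictors
#'
#' Complete-linkage hierarchical clustering of predictors on `1 - |r|`
#' (Pearson), cut at `1 - threshold` so that groups contain predictors with
#' pairwise absolute correlation at or above the threshold; one
#' representative per group is kept, chosen as the member with the highest
#' mean absolute correlation to the rest of its group (the most central).
#' Because complete-linkage groups do not guarantee that representatives of
#' different groups are themselves below the threshold, a final greedy sweep
#' drops offending members (the one with the higher mean |r| to the other
#' retained predictors) until no retained pair reaches the threshold.
#' Constant predictors are dropped with a warning before correlation.
#'
#' @param siteEnv data.frame of site-level predictor values (numeric columns)
#' @param threshold absolute correlation at or above which predictors are
#'   considered redundant (default 0.9)
#' @return list: `retained` (predictor names), `groups` (data.frame:
#'   predictor, group, representative), `tree` (hclust, NULL when < 3
#'   non-constant predictors)
#' @export
pruneCollinear <- function(siteEnv, threshold = 0.9) {
  num <- siteEnv[vapply(siteEnv, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("at least 2 numeric predictors required")
  cons <- vapply(num, function(v) stats::sd(v) < 1e-12, logical(1))
  if (any(cons)) {
    warning("dropping constant predictor(s): ",
            paste(names(num)[cons], collapse = ", "))
    num <- num[!cons]
  }
  p <- ncol(num)
  C <- abs(stats::cor(num))
  tree <- NULL
  if (p > 2) {
    tree <- stats::hclust(stats::as.dist(1 - C), method = "complete")
    grp <- stats::cutree(tree, h = 1 - threshold)
  } else {
    grp <- if (C[1, 2] >= threshold) c(1L, 1L) else c(1L, 2L)
    names(grp) <- colnames(num)
  }
  reps <- vapply(sort(unique(grp)), function(g) {
    mem <- names(grp)[grp == g]
    if (length(mem) == 1) return(mem)
    cent <- rowMeans(C[mem, mem, drop = FALSE]) # includes self; same ranking
    sort(mem[cent == max(cent)])[1]
  }, character(1))
  retained <- unname(reps)
  # greedy sweep: enforce that no retained pair reaches the threshold
  repeat {
    Cr <- C[retained, retained, drop = FALSE]
    diag(Cr) <- 0
    if (length(retained) < 2 || max(Cr) < threshold) break
    worst <- which(Cr == max(Cr), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    meanR <- vapply(pair, function(v)
      mean(C[v, setdiff(retained, v)]), numeric(1))
    dropv <- pair[which.max(meanR)]
    retained <- setdiff(retained, dropv)
  }
  groups <- data.frame(predictor = names(grp), group = as.integer(grp),
                       representative = reps[grp], stringsAsFactors = FALSE)
  list(retained = retained, groups = groups, tree = tree)
}

#' Extract predictor values at sampling sites
#'
#' Nearest-cell lookup of every layer at the site coordinates. Sites falling
#' outside the grid or on nodata cells are excluded with a warning (and
#' reported in the `excluded` attribute). When the site table carries an
#' in-situ `depth_m` column, it overrides the raster depth at those sites.
#'
#' @param stack an [EnvRasterStack-class]
#' @param sites data.frame with `site`, `x_km`, `y_km`, optional `depth_m`
#' @return data.frame of site rows x predictors (rownames = site ids), with
#'   attribute `excluded` naming dropped sites
#' @export
extractSiteEnv <- function(stack, sites) {
  grid <- gridSpec(stack)
  cell <- pointToCell(grid, sites$x_km, sites$y_km)
  off <- is.na(cell$row)
  nod <- !off & stack@nodata[cbind(cell$row, cell$col)]
  bad <- off | nod
  if (any(bad))
    warning(sum(bad), " site(s) outside the grid or on nodata cells excluded: ",
            paste(sites$site[bad], collapse = ", "))
  keep <- which(!bad)
  out <- data.frame(row.names = sites$site[keep])
  for (nm in layerNames(stack))
    out[[nm]] <- getLayer(stack, nm)[cbind(cell$row[keep], cell$col[keep])]
  if ("depth_m" %in% names(sites) && "depth" %in% names(out)) {
    insitu <- sites$depth_m[keep]
    out$depth <- ifelse(is.na(insitu), out$depth, insitu)
  }
  attr(out, "excluded") <- sites$site[bad]
  out
}
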