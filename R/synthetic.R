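# Synthetic seascape and coral-metapopulation generator: the test bed that
# plants known lineage structure, depth niches, environmental clines,
# isolation by distance and clones into data with the statistical shape the
# downstream analysis assumes.

#' Seascape generator configuration
#'
#' @param gridNx,gridNy grid cell counts (>= 8)
#' @param cellSize cell size in km
#' @param nEnv number of environmental layers including depth
#' @param spatialRange spatial autocorrelation scale of the layers, km
#' @param collinearGroups list of `c(size, r)` pairs; each group of `size`
#'   non-depth layers is built to achieve pairwise absolute Pearson
#'   correlation `r` across cells
#' @param depthGradient amplitude of the monotone inshore-to-offshore depth
#'   trend, m
#' @param nStations number of monitoring stations
#' @param stationNoiseSd measurement noise sd added to station samples
#' @param nTimes time points per slice in the station series
#' @param seed integer seed
#' @return a validated [SeascapeConfig-class]
#' @export
seascapeConfig <- function(gridNx = 60, gridNy = 50, cellSize = 2, nEnv = 20,
                           spatialRange = 30, collinearGroups = list(c(3, 0.95)),
                           depthGradient = 25, nStations = 224,
                           stationNoiseSd = 0.1, nTimes = 24, seed = 101) {
  methods::new("SeascapeConfig", gridNx = gridNx, gridNy = gridNy,
               cellSize = cellSize, nEnv = nEnv, spatialRange = spatialRange,
               collinearGroups = collinearGroups, depthGradient = depthGradient,
               nStations = nStations, stationNoiseSd = stationNoiseSd,
               nTimes = nTimes, seed = seed)
}

#' Metapopulation generator configuration
#'
#' Defaults emulate the study design: 65 sites of 4-5 colonies (~290
#' individuals), three cryptic lineages with shallow / broad / deep depth
#' niches, 3000 SNPs at between-lineage FST 0.15, environment-linked loci
#' driven by one seascape layer, isolation by distance at 100 km, and a few
#' percent of clones and close relatives at 10x mean coverage.
#'
#' @param nLineages number of cryptic lineages
#' @param nSites number of sampling sites
#' @param coloniesPerSite `c(lo, hi)` colonies sampled per site
#' @param nSnps number of biallelic SNPs
#' @param fst target between-lineage FST (Balding-Nichols divergence)
#' @param depthNiches nLineages x 2 matrix: depth niche center and sd (m)
#' @param nCausal number of environment-linked loci
#' @param causalEnv layer name(s) driving the causal loci
#' @param clineSlope slope of logit allele frequency per sd of the driver
#' @param ibdScale isolation-by-distance autocorrelation scale, km
#' @param cloneFraction fraction of individuals that are clonal replicates
#' @param sibFraction fraction that are close relatives of a site-mate
#' @param admixFraction fraction with Dirichlet-admixed ancestry
#' @param coverageMean mean read depth per site per individual (Poisson;
#'   zero draws are missing data)
#' @param seed integer seed
#' @return a validated [MetapopConfig-class]
#' @export
metapopConfig <- function(nLineages = 3, nSites = 65, coloniesPerSite = c(4, 5),
                          nSnps = 3000, fst = 0.15,
                          depthNiches = cbind(center = c(3, 8, 18),
                                              sd = c(2, 6, 4)),
                          nCausal = 150, causalEnv = "env01", clineSlope = 1.5,
                          ibdScale = 100, cloneFraction = 0.05,
                          sibFraction = 0.05, admixFraction = 0.1,
                          coverageMean = 10, seed = 42) {
  methods::new("MetapopConfig", nLineages = nLineages, nSites = nSites,
               coloniesPerSite = coloniesPerSite, nSnps = nSnps, fst = fst,
               depthNiches = depthNiches, nCausal = nCausal,
               causalEnv = causalEnv, clineSlope = clineSlope,
               ibdScale = ibdScale, cloneFraction = cloneFraction,
               sibFraction = sibFraction, admixFraction = admixFraction,
               coverageMean = coverageMean, seed = seed)
}

#' Forest configuration
#'
#' @param nTrees trees per regression forest
#' @param mtryLow,mtryHigh mtry as fractions of the predictor count; defaults
#'   1/4 and 3/4 give a wide contrast for proxy elimination
#' @param nJackknife ordination jackknife replicates
#' @param dropFraction fraction of samples dropped per replicate
#' @param nGpcs number of leading gPCs to model; `NA` selects the axes
#'   covering 75 percent of positive-eigenvalue variance
#' @param retainVote fraction of replicates in which a predictor's importance
#'   must not drop from mtryLow to mtryHigh to be retained
#' @param seed integer seed
#' @return a validated [ForestConfig-class]
#' @export
forestConfig <- function(nTrees = 300, mtryLow = 0.25, mtryHigh = 0.75,
                         nJackknife = 25, dropFraction = 0.2, nGpcs = NA_real_,
                         retainVote = 0.5, seed = 7) {
  methods::new("ForestConfig", nTrees = nTrees, mtryLow = mtryLow,
               mtryHigh = mtryHigh, nJackknife = nJackknife,
               dropFraction = dropFraction, nGpcs = nGpcs,
               retainVote = retainVote, seed = seed)
}

#' Spatially autocorrelated Gaussian random field
#'
#' Synthesizes a zero-mean, unit-variance surface with Gaussian-shaped
#' spatial covariance by FFT spectral synthesis (circulant embedding on the
#' grid torus): the covariance kernel's spectrum is computed by FFT, white
#' noise is colored by its square root, and the result is standardized to
#' exact mean 0 and sd 1. As `rangeKm` approaches zero the kernel becomes a
#' delta function and the field degenerates to i.i.d. standard normal cells.
#' Deterministic given `seed`.
#'
#' @param nx,ny grid cell counts (positive)
#' @param rangeKm autocorrelation scale in km (> 0)
#' @param cellSize cell size in km
#' @param seed integer seed
#' @return an ny x nx numeric matrix
#' @examples
#' f <- gaussianRandomField(32, 32, rangeKm = 50, cellSize = 2, seed = 1)
#' round(c(mean(f), sd(f)), 10)
#' @export
gaussianRandomField <- function(nx, ny, rangeKm, cellSize = 1, seed = 1) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be positive")
  if (rangeKm <= 0) stop("rangeKm must be > 0")
  # toroidal distances from the (1,1) corner
  dx <- pmin(seq_len(nx) - 1, nx - (seq_len(nx) - 1)) * cellSize
  dy <- pmin(seq_len(ny) - 1, ny - (seq_len(ny) - 1)) * cellSize
  h2 <- outer(dy^2, dx^2, "+")
  covk <- exp(-h2 / rangeKm^2)
  spec <- Re(stats::fft(covk))
  spec[spec < 0] <- 0
  field <- withSeed(seed, {
    z <- matrix(stats::rnorm(nx * ny), ny, nx)
    Re(stats::fft(sqrt(spec) * stats::fft(z), inverse = TRUE)) / (nx * ny)
  })
  (field - mean(field)) / stats::sd(field)
}

# Standardize a vector to empirical mean 0, sd 1.
.std <- function(v) (v - mean(v)) / stats::sd(v)

# Empirically orthogonalize field f against columns of B (cell vectors),
# returning a standardized residual field.
.orthField <- function(f, B) {
  r <- stats::lm.fit(cbind(1, B), f)$residuals
  .std(r)
}

#' Generate a synthetic seascape
#'
#' Builds an [EnvRasterStack-class] of `nEnv` spatially autocorrelated layers
#' including a strictly positive `depth` layer (monotone inshore-to-offshore
#' trend plus field noise), with configured groups of collinear layers, and a
#' monitoring-station table sampling the layers at random station locations
#' with additive noise over two time slices ("past": 1995-2007, "present":
#' 2008-2021).
#'
#' Collinear groups are constructed by mixing a shared base field with
#' empirically orthogonalized noise fields, so realized pairwise |r| across
#' cells matches the target almost exactly.
#'
#' @param config a [seascapeConfig()]
#' @return list with `stack` (EnvRasterStack) and `stations` (long-format
#'   data.frame: station, x_km, y_km, lat, lon, date, slice, parameter, value,
#'   depth_flag)
#' @export
makeSeascape <- function(config) {
  methods::validObject(config)
  nx <- config@gridNx; ny <- config@gridNy; cs <- config@cellSize
  sizes <- vapply(config@collinearGroups, `[`, numeric(1), 1)
  if (sum(sizes) > max(config@nEnv - 1, 0))
    stop("collinear group sizes exceed the number of non-depth layers")

  grid <- list(xll = 0, yll = 0, cellSize = cs, nx = nx, ny = ny)
  xs <- gridCoords(grid)$x

  # depth: monotone west-east (inshore -> offshore) trend plus short-range
  # bathymetric relief, floored at 0.5 m so all depths are positive. The
  # relief term is deliberately large (reef-scale bathymetry is far from a
  # pure function of long-shore position), so depth carries information not
  # reducible to the coordinates.
  trend <- matrix(rep((xs - min(xs)) / (max(xs) - min(xs)), each = ny), ny, nx)
  dfield <- gaussianRandomField(nx, ny, config@spatialRange / 3, cs,
                                childSeed(config@seed, 1))
  depth <- 1.5 + config@depthGradient * trend + 0.35 * config@depthGradient * dfield
  depth <- pmax(depth, 0.5)

  layers <- list(depth = depth)
  nOther <- config@nEnv - 1
  if (nOther > 0) {
    nm <- sprintf("env%02d", seq_len(nOther))
    fields <- vector("list", nOther)
    idx <- 1
    fseed <- 100
    for (g in config@collinearGroups) {
      size <- g[1]; r <- g[2]
      base <- .std(as.vector(gaussianRandomField(nx, ny, config@spatialRange,
                                                 cs, childSeed(config@seed, fseed))))
      fseed <- fseed + 1
      # equicorrelated construction: each member mixes the shared base field
      # with its own noise field, empirically orthogonalized against the base
      # and all previously built members, so realized pairwise r is exact
      for (m in seq_len(size)) {
        e <- as.vector(gaussianRandomField(nx, ny, config@spatialRange, cs,
                                           childSeed(config@seed, fseed)))
        fseed <- fseed + 1
        prev <- if (idx > 1) do.call(cbind, fields[seq_len(idx - 1)]) else NULL
        e <- .orthField(e, cbind(base, prev))
        fields[[idx]] <- sqrt(r) * base + sqrt(1 - r) * e
        idx <- idx + 1
      }
    }
    while (idx <= nOther) {
      e <- as.vector(gaussianRandomField(nx, ny, config@spatialRange, cs,
                                         childSeed(config@seed, fseed)))
      fseed <- fseed + 1
      fields[[idx]] <- if (idx > 1)
        .orthField(e, do.call(cbind, fields[seq_len(idx - 1)])) else .std(e)
      idx <- idx + 1
    }
    for (i in seq_len(nOther))
      layers[[nm[i]]] <- matrix(fields[[i]], ny, nx)
  }

  nodata <- matrix(FALSE, ny, nx)
  prov <- data.frame(layer = names(layers),
                     slice = "present", statistic = "value",
                     stringsAsFactors = FALSE)
  stack <- methods::new("EnvRasterStack", layers = layers, grid = grid,
                        nodata = nodata, provenance = prov)

  stations <- withSeed(childSeed(config@seed, 2), {
    sx <- stats::runif(config@nStations, 0, nx * cs)
    sy <- stats::runif(config@nStations, 0, ny * cs)
    cell <- pointToCell(grid, sx, sy)
    slices <- list(past = seq(as.Date("1995-06-01"), as.Date("2007-06-01"),
                              length.out = config@nTimes),
                   present = seq(as.Date("2008-06-01"), as.Date("2021-06-01"),
                                 length.out = config@nTimes))
    rows <- list()
    for (p in names(layers)) {
      lay <- layers[[p]]
      v0 <- lay[cbind(cell$row, cell$col)]
      for (sl in names(slices)) {
        for (d in slices[[sl]]) {
          rows[[length(rows) + 1]] <- data.frame(
            station = sprintf("st%03d", seq_len(config@nStations)),
            x_km = sx, y_km = sy, date = as.Date(d, origin = "1970-01-01"),
            slice = sl, parameter = p,
            value = v0 + stats::rnorm(config@nStations, 0, config@stationNoiseSd),
            depth_flag = "bottom", stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    ll <- kmToLatLon(out$x_km, out$y_km)
    out$lat <- ll$lat; out$lon <- ll$lon
    out
  })

  list(stack = stack, stations = stations)
}

#' Simulate coral genotypes over a seascape
#'
#' Plants a metapopulation of `nLineages` cryptic lineages on a synthetic
#' seascape. Lineage allele frequencies diverge from shared ancestral
#' frequencies by Balding-Nichols beta draws calibrated to the target FST.
#' Individuals are placed at sampling sites; each individual's lineage is
#' drawn in proportion to the lineage's Gaussian depth-niche density at the
#' site depth. Causal loci receive within-lineage allele-frequency clines,
#' linear on the logit scale in the standardized driving layer; neutral loci
#' receive spatially autocorrelated drift at scale `ibdScale` (isolation by
#' distance). A configured fraction of individuals carries Dirichlet-admixed
#' ancestry with per-locus mosaic genotypes. Clones duplicate a site-mate's
#' genotype exactly; siblings share roughly half their alleles. Read counts
#' are Poisson per individual per site at `coverageMean`, with alleles
#' sampled binomially from the true genotype (a zero draw is missing data).
#'
#' @param config a [metapopConfig()]
#' @param seascape an [EnvRasterStack-class] containing `depth` and all
#'   `causalEnv` layers
#' @return list with `counts` (a [ReadCountMatrix-class]), `sites` (data.frame
#'   site, x_km, y_km, lat, lon, depth_m), and `truth` (list: lineage labels,
#'   admixture matrix, causal locus indices and drivers, clone/sib groups,
#'   per-site true environmental values, true genotypes)
#' @export
simulateGenotypes <- function(config, seascape) {
  methods::validObject(config)
  missingEnv <- setdiff(config@causalEnv, layerNames(seascape))
  if (length(missingEnv))
    stop("causal env layer(s) absent from seascape: ",
         paste(missingEnv, collapse = ", "))
  grid <- gridSpec(seascape)
  L <- config@nLineages
  S <- config@nSnps

  withSeed(config@seed, {
    # ---- sites -----------------------------------------------------------
    sx <- stats::runif(config@nSites, 0, grid$nx * grid$cellSize)
    sy <- stats::runif(config@nSites, 0, grid$ny * grid$cellSize)
    cell <- pointToCell(grid, sx, sy)
    depthL <- getLayer(seascape, "depth")
    siteDepth <- depthL[cbind(cell$row, cell$col)]
    siteEnv <- data.frame(site = sprintf("s%02d", seq_len(config@nSites)),
                          x_km = sx, y_km = sy, depth_m = siteDepth)
    for (p in setdiff(layerNames(seascape), "depth"))
      siteEnv[[p]] <- getLayer(seascape, p)[cbind(cell$row, cell$col)]
    ll <- kmToLatLon(sx, sy)
    sites <- data.frame(site = siteEnv$site, x_km = sx, y_km = sy,
                        lat = ll$lat, lon = ll$lon, depth_m = siteDepth)

    # ---- lineage allele frequencies (Balding-Nichols) --------------------
    p0 <- stats::runif(S, 0.1, 0.9)
    theta <- (1 - config@fst) / config@fst
    pl <- matrix(0, S, L)
    for (l in seq_len(L))
      pl[, l] <- stats::rbeta(S, p0 * theta, (1 - p0) * theta)
    pl <- pmin(pmax(pl, 1e-4), 1 - 1e-4)

    # ---- per-site frequency perturbations --------------------------------
    causal <- sort(sample.int(S, config@nCausal))
    causalDriver <- sample(config@causalEnv, config@nCausal, replace = TRUE)
    # spatially autocorrelated site effects for neutral loci (IBD)
    D <- as.matrix(stats::dist(cbind(sx, sy)))
    Sigma <- exp(-D / config@ibdScale)
    Lc <- chol(Sigma + diag(1e-6, config@nSites))
    # logit-scale sd of the spatial drift: weak relative to between-lineage
    # divergence, matching a system where isolation by distance is detectable
    # but cryptic-lineage structure dominates
    sigmaIbd <- 0.1
    # logit-scale per-locus-per-site offsets, same for all lineages
    Z <- matrix(stats::rnorm(S * config@nSites), S, config@nSites)
    U <- sigmaIbd * Z %*% Lc            # S x nSites
    # causal loci: replace drift with environmental cline
    for (i in seq_along(causal)) {
      z <- .std(siteEnv[[causalDriver[i]]])
      U[causal[i], ] <- config@clineSlope * z
    }
    # p[locus, site, lineage] on demand via logit
    logitPl <- logit(pl)

    # ---- individuals -----------------------------------------------------
    colRange <- seq(config@coloniesPerSite[1], config@coloniesPerSite[2])
    nCol <- if (length(colRange) == 1) rep(colRange, config@nSites)
            else sample(colRange, config@nSites, replace = TRUE)
    indSite <- rep(seq_len(config@nSites), nCol)
    N <- length(indSite)
    nicheDens <- function(d)
      vapply(seq_len(L), function(l)
        stats::dnorm(d, config@depthNiches[l, 1], config@depthNiches[l, 2]) + 1e-9,
        numeric(1))
    admixed <- stats::runif(N) < config@admixFraction
    Q <- matrix(0, N, L)
    for (i in seq_len(N)) {
      if (admixed[i]) {
        g <- stats::rgamma(L, shape = 1)
        Q[i, ] <- g / sum(g)
      } else {
        w <- nicheDens(siteDepth[indSite[i]])
        Q[i, sample.int(L, 1, prob = w)] <- 1
      }
    }
    lineage <- max.col(Q)

    # ---- genotypes -------------------------------------------------------
    G <- matrix(0L, S, N)
    for (i in seq_len(N)) {
      anc <- if (admixed[i]) sample.int(L, S, replace = TRUE, prob = Q[i, ])
             else rep(lineage[i], S)
      pvec <- invlogit(logitPl[cbind(seq_len(S), anc)] + U[, indSite[i]])
      G[, i] <- stats::rbinom(S, 2L, pvec)
    }

    # ---- clones and siblings --------------------------------------------
    nClone <- round(config@cloneFraction * N)
    nSib <- round(config@sibFraction * N)
    cloneGroups <- list(); sibGroups <- list()
    pool <- seq_len(N)
    pick <- if (nClone + nSib > 0)
      sample(pool, nClone + nSib) else integer(0)
    cloneIds <- utils::head(pick, nClone)
    sibIds <- utils::tail(pick, nSib)
    for (i in cloneIds) {
      mates <- setdiff(which(indSite == indSite[i]), c(i, cloneIds))
      src <- if (length(mates)) mates[1] else setdiff(seq_len(N), i)[1]
      G[, i] <- G[, src]
      Q[i, ] <- Q[src, ]; lineage[i] <- lineage[src]
      cloneGroups[[length(cloneGroups) + 1]] <- c(src, i)
    }
    for (i in sibIds) {
      mates <- setdiff(which(indSite == indSite[i]), c(i, cloneIds, sibIds))
      src <- if (length(mates)) mates[1] else setdiff(seq_len(N), i)[1]
      # one allele inherited from the relative, one drawn from lineage freqs
      inherited <- stats::rbinom(S, 1L, G[, src] / 2)
      pvec <- invlogit(logitPl[cbind(seq_len(S), rep(lineage[src], S))] +
                         U[, indSite[i]])
      G[, i] <- inherited + stats::rbinom(S, 1L, pvec)
      Q[i, ] <- Q[src, ]; lineage[i] <- lineage[src]
      sibGroups[[length(sibGroups) + 1]] <- c(src, i)
    }

    # ---- read counts -----------------------------------------------------
    tot <- matrix(stats::rpois(S * N, config@coverageMean), S, N)
    cntB <- matrix(stats::rbinom(S * N, as.vector(tot), as.vector(G) / 2), S, N)
    cntA <- tot - cntB
    ids <- sprintf("i%03d", seq_len(N))
    dimnames(cntA) <- dimnames(cntB) <-
      list(sprintf("snp%04d", seq_len(S)), ids)

    sampleData <- data.frame(
      site = sites$site[indSite], x_km = sx[indSite], y_km = sy[indSite],
      lat = sites$lat[indSite], lon = sites$lon[indSite],
      depth_m = siteDepth[indSite], lineage = lineage,
      row.names = ids)
    counts <- ReadCountMatrix(cntA, cntB, sampleData = sampleData)

    truth <- list(lineage = stats::setNames(lineage, ids),
                  admixture = `rownames<-`(Q, ids),
                  causalLoci = causal, causalDriver = causalDriver,
                  cloneGroups = lapply(cloneGroups, function(g) ids[g]),
                  sibGroups = lapply(sibGroups, function(g) ids[g]),
                  siteEnv = siteEnv, genotypes = G, indSite = indSite)
    list(counts = counts, sites = sites, truth = truth)
  })
}
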