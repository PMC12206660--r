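# Format round-tripping: VCF / TSV genotype input, ESRI ASCII grid raster
# stacks with a JSON sidecar, distance matrices and ordinations as CSV/JSON.

#' Load genotypes into a ReadCountMatrix
#'
#' Reads biallelic SNP calls from VCF (via `vcfR`; the `AD` field supplies
#' per-allele read depths, and records with `GT` only are converted with the
#' pseudo-count convention `0/0 -> (2,0)`, `0/1 -> (1,1)`, `1/1 -> (0,2)`,
#' missing `./.` -> `(0,0)`), or a wide TSV read-count table as written by
#' [writeReadCounts()]. Multi-allelic VCF records are skipped with a message.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`
#' @return a [ReadCountMatrix-class]
#' @export
loadGenotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") .loadVcf(path) else .loadTsv(path)
}

.loadVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt)
  nSkip <- sum(!biallelic)
  if (nSkip) message(nSkip, " multi-allelic record(s) skipped")
  if (!any(biallelic)) stop("no biallelic records in ", path)
  v <- v[biallelic, ]
  ids <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = ":")
  gt <- vcfR::extract.gt(v, element = "GT")
  hasAD <- "AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if (hasAD) {
    ad <- vcfR::extract.gt(v, element = "AD")
    a <- suppressWarnings(
      matrix(as.integer(sub(",.*", "", ad)), nrow(ad), ncol(ad)))
    b <- suppressWarnings(
      matrix(as.integer(sub("^[^,]*,", "", ad)), nrow(ad), ncol(ad)))
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
  } else {
    gclean <- gsub("\\|", "/", gt)
    a <- matrix(0L, nrow(gt), ncol(gt))
    b <- matrix(0L, nrow(gt), ncol(gt))
    a[gclean == "0/0"] <- 2L
    a[gclean %in% c("0/1", "1/0")] <- 1L
    b[gclean %in% c("0/1", "1/0")] <- 1L
    b[gclean == "1/1"] <- 2L
  }
  dimnames(a) <- dimnames(b) <- list(ids, colnames(gt))
  ReadCountMatrix(a, b)
}

.loadTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  cn <- colnames(tab)
  if (cn[1] != "site") stop("malformed read-count table: first column must be 'site'")
  aCols <- grep("\\.A$", cn, value = TRUE)
  bCols <- grep("\\.B$", cn, value = TRUE)
  samples <- sub("\\.A$", "", aCols)
  if (!identical(samples, sub("\\.B$", "", bCols)))
    stop("malformed read-count table: unmatched .A/.B column pairs")
  a <- as.matrix(tab[aCols]); b <- as.matrix(tab[bCols])
  dimnames(a) <- dimnames(b) <- list(tab$site, samples)
  ReadCountMatrix(a, b)
}

#' Write a ReadCountMatrix as a TSV read-count table
#'
#' Wide format: a `site` column, then `<sample>.A` / `<sample>.B` column
#' pairs of integer read counts. Round-trips exactly through
#' [loadGenotypes()].
#'
#' @param x a [ReadCountMatrix-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeReadCounts <- function(x, path) {
  ac <- alleleCounts(x)
  a <- ac$alleleA; b <- ac$alleleB
  out <- data.frame(site = rownames(a), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in colnames(a)) {
    out[[paste0(s, ".A")]] <- a[, s]
    out[[paste0(s, ".B")]] <- b[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ReadCountMatrix as an uncompressed VCF
#'
#' Plain-text VCF 4.2 with `GT:AD` per sample; the genotype call is derived
#' from the counts (both alleles seen -> `0/1`; zero total -> `./.`).
#'
#' @param x a [ReadCountMatrix-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeVcf <- function(x, path) {
  ac <- alleleCounts(x)
  a <- ac$alleleA; b <- ac$alleleB
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(a)), collapse = "\t")), con)
  ids <- rownames(a)
  chrom <- sub(":.*", "", ids)
  pos <- suppressWarnings(as.integer(sub(".*:", "", ids)))
  if (any(is.na(pos))) { chrom <- ids; pos <- seq_along(ids) }
  gt <- function(ca, cb) {
    ifelse(ca + cb == 0, "./.",
      ifelse(ca > 0 & cb > 0, "0/1", ifelse(cb == 0, "0/0", "1/1")))
  }
  for (i in seq_along(ids)) {
    fields <- paste0(gt(a[i, ], b[i, ]), ":", a[i, ], ",", b[i, ])
    writeLines(paste(c(chrom[i], pos[i], ids[i], "A", "C", ".", "PASS", ".",
                       "GT:AD", fields), collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid raster IO with a JSON sidecar naming the layers
# ---------------------------------------------------------------------------

.writeAsc <- function(m, grid, path, nodataValue = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$nx),
               sprintf("nrows %d", grid$ny),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               sprintf("cellsize %.10g", grid$cellSize),
               sprintf("NODATA_value %d", nodataValue)), con)
  m[is.na(m)] <- nodataValue
  for (r in seq_len(grid$ny))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
}

.readAsc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("invalid .asc header in ", path)
  dat <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(dat, vals["nrows"], vals["ncols"], byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA
  list(m = m, grid = list(xll = unname(vals["xllcorner"]),
                          yll = unname(vals["yllcorner"]),
                          cellSize = unname(vals["cellsize"]),
                          nx = as.integer(vals["ncols"]),
                          ny = as.integer(vals["nrows"])))
}

#' Write an EnvRasterStack to a directory
#'
#' One ESRI ASCII grid (`<name>_<layer>.asc`) per layer plus a JSON sidecar
#' (`<name>.json`) recording grid spec, layer names and provenance. Values
#' are written with 17 significant digits, so doubles round-trip exactly.
#'
#' @param stack an [EnvRasterStack-class]
#' @param dir output directory (created if needed)
#' @param name stack name used as the file prefix
#' @return the sidecar path, invisibly
#' @export
writeRasterStack <- function(stack, dir, name = "stack") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- gridSpec(stack)
  files <- character(0)
  for (nm in layerNames(stack)) {
    f <- file.path(dir, paste0(name, "_", nm, ".asc"))
    m <- getLayer(stack, nm)
    m[stack@nodata] <- NA
    .writeAsc(m, grid, f)
    files[nm] <- basename(f)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(grid = grid, layers = as.list(files),
                            provenance = stack@provenance),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read an EnvRasterStack from its JSON sidecar
#'
#' @param sidecar path to the JSON written by [writeRasterStack()]
#' @return an [EnvRasterStack-class]
#' @export
readRasterStack <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  layers <- list()
  grid <- NULL
  for (nm in names(meta$layers)) {
    asc <- .readAsc(file.path(dir, meta$layers[[nm]]))
    if (is.null(grid)) grid <- asc$grid
    else if (!isTRUE(all.equal(grid, asc$grid)))
      stop("grid mismatch across layers in ", sidecar)
    layers[[nm]] <- asc$m
  }
  nodata <- Reduce(`|`, lapply(layers, is.na))
  prov <- as.data.frame(meta$provenance)
  if (!nrow(prov))
    prov <- data.frame(layer = character(), slice = character(),
                       statistic = character(), stringsAsFactors = FALSE)
  methods::new("EnvRasterStack", layers = layers, grid = grid,
               nodata = nodata, provenance = prov)
}

#' Write a DistanceMatrix as square CSV
#'
#' @param d a [DistanceMatrix-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeDistanceMatrix <- function(d, path) {
  utils::write.csv(distMatrix(d), path, quote = FALSE)
  invisible(path)
}

#' Write an Ordination (scores CSV + eigenvalue/covariate JSON)
#'
#' @param ord an [Ordination-class]
#' @param scoresPath CSV path for the scores
#' @param metaPath JSON path for eigenvalues, variance proportions and the
#'   covariate record
#' @return invisibly, the two paths
#' @export
writeOrdination <- function(ord, scoresPath, metaPath) {
  utils::write.csv(scores(ord), scoresPath, quote = FALSE)
  jsonlite::write_json(list(eigenvalues = eigenvalues(ord),
                            varianceExplained = varianceExplained(ord),
                            covariates = if (length(ord@covariates))
                              ord@covariates["names"] else list()),
                       metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(scoresPath, metaPath))
}
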