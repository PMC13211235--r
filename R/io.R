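#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text single-band raster (Arc/Info ASCII grid convention: header of
#' ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value, then rows from
#' north to south). Row 1 of the matrix is the northern edge.
#'
#' @param raster Numeric matrix (`NA` = missing).
#' @param path Output file path.
#' @param geometry Grid geometry (list with `cell_size_km`, `origin`);
#'   defaults to a unit grid at the origin.
#' @param nodata NODATA sentinel written for `NA` (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, geometry = NULL, nodata = -9999) {
  cs <- if (is.null(geometry)) 1 else geometry$cell_size_km
  org <- if (is.null(geometry)) c(0, 0) else geometry$origin
  hdr <- c(paste("ncols", ncol(raster)), paste("nrows", nrow(raster)),
           paste("xllcorner", org[1]), paste("yllcorner", org[2]),
           paste("cellsize", cs), paste("NODATA_value", nodata))
  m <- raster
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any Arc/Info ASCII
#'   grid).
#' @return Numeric matrix with attribute `geometry` (rows, cols,
#'   cell_size_km, origin); NODATA cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.numeric(parts[1])))) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i + 1L):(i + nr)]), "\\s+")))
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  attr(m, "geometry") <- list(rows = nr, cols = nc,
                              cell_size_km = hdr$cellsize %||% 1,
                              origin = c(hdr$xllcorner %||% 0,
                                         hdr$yllcorner %||% 0))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an NDVI cube as a long-format CSV with a JSON header sidecar
#'
#' The cube goes to `<path>.csv` (columns row, col, year, doy, ndvi) and
#' the band -> DOY mapping plus grid geometry to `<path>.json`.
#'
#' @param cube An `ndvi_cube`.
#' @param path Path stem (no extension).
#' @return The stem, invisibly.
#' @export
write_ndvi_cube <- function(cube, path) {
  stopifnot(inherits(cube, "ndvi_cube"))
  d <- dim(cube$values)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                     year = cube$years, doy = cube$composite_days)
  idx$ndvi <- as.vector(cube$values)
  utils::write.csv(idx, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(composite_days = cube$composite_days, years = cube$years,
         geometry = cube$geometry),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an NDVI cube written by [write_ndvi_cube()]
#' @param path Path stem (no extension).
#' @return An `ndvi_cube`.
#' @export
read_ndvi_cube <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"))
  nr <- meta$geometry$rows; nc <- meta$geometry$cols
  ny <- length(meta$years); nd <- length(meta$composite_days)
  vals <- array(NA_real_, c(nr, nc, ny, nd))
  yi <- match(df$year, meta$years); di <- match(df$doy, meta$composite_days)
  vals[cbind(df$row, df$col, yi, di)] <- df$ndvi
  geometry <- meta$geometry
  geometry$origin <- as.numeric(geometry$origin)
  structure(list(values = vals, composite_days = meta$composite_days,
                 years = meta$years, geometry = geometry, preset = NULL,
                 seed = NA_integer_),
            class = "ndvi_cube")
}

#' Fill missing raster cells by inverse distance weighting
#'
#' Each missing cell receives the IDW mean of its `k_neighbors` nearest
#' non-missing cells (cell-center Euclidean distance, weight
#' `d^(-power)`); non-missing cells are untouched.
#'
#' @param raster Numeric matrix with `NA` holes.
#' @param power IDW power (default 2).
#' @param k_neighbors Number of neighbors (default 12).
#' @return Filled matrix.
#' @export
idw_fill <- function(raster, power = 2, k_neighbors = 12L) {
  miss <- which(is.na(raster), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(raster)
  valid <- which(!is.na(raster), arr.ind = TRUE)
  if (nrow(valid) == 0L) stop("all cells missing")
  vv <- raster[valid]
  k <- min(k_neighbors, nrow(valid))
  out <- raster
  for (i in seq_len(nrow(miss))) {
    d2 <- (valid[, 1] - miss[i, 1])^2 + (valid[, 2] - miss[i, 2])^2
    nb <- order(d2)[seq_len(k)]
    w <- d2[nb]^(-power / 2)
    out[miss[i, 1], miss[i, 2]] <- sum(w * vv[nb]) / sum(w)
  }
  out
}

#' Nearest-neighbor resampling onto a target geometry
#'
#' Each target cell takes the value of the source cell whose center is
#' nearest to the target cell center. The result carries a
#' `resample_count` attribute; resampling a raster that was already
#' resampled once raises a warning, so a pipeline can guarantee the
#' single-pass resampling rule.
#'
#' @param raster Source matrix.
#' @param src_geometry,target_geometry Grid geometries (lists with `rows`,
#'   `cols`, `cell_size_km`, `origin`).
#' @return Matrix on the target geometry (attributes `geometry`,
#'   `resample_count`).
#' @export
resample_nearest <- function(raster, src_geometry, target_geometry) {
  sg <- src_geometry; tg <- target_geometry
  sx <- sg$origin[1] + c(0, sg$cols * sg$cell_size_km)
  sy <- sg$origin[2] + c(0, sg$rows * sg$cell_size_km)
  tx <- tg$origin[1] + c(0, tg$cols * tg$cell_size_km)
  ty <- tg$origin[2] + c(0, tg$rows * tg$cell_size_km)
  if (tx[1] >= sx[2] || tx[2] <= sx[1] || ty[1] >= sy[2] || ty[2] <= sy[1])
    stop("source and target extents are disjoint")
  prior <- attr(raster, "resample_count") %||% 0L
  if (prior >= 1L)
    warning("raster has already been resampled ", prior,
            " time(s); single-pass resampling is violated")
  # target cell centers in km (y northward; row 1 = north)
  tcx <- tg$origin[1] + (seq_len(tg$cols) - 0.5) * tg$cell_size_km
  tcy <- tg$origin[2] + (tg$rows - seq_len(tg$rows) + 0.5) * tg$cell_size_km
  # nearest source center index along each axis
  scol <- pmin(pmax(round((tcx - sg$origin[1]) / sg$cell_size_km + 0.5), 1L),
               sg$cols)
  srowk <- pmin(pmax(round((tcy - sg$origin[2]) / sg$cell_size_km + 0.5), 1L),
                sg$rows)
  srow <- sg$rows - srowk + 1L
  out <- raster[srow, scol, drop = FALSE]
  attr(out, "geometry") <- tg
  attr(out, "resample_count") <- prior + 1L
  out
}
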