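#' Scene configuration for synthetic cold-desert scenes
#'
#' Defines the grid geometry, calendar and composite schedule shared by all
#' synthetic generators. The composite schedule defaults to the 8-day
#' compositing grid spanning day-of-year (DOY) 65 to 225, the window that
#' covers the whole life cycle of early-spring ephemeral plants from
#' regreening to complete senescence.
#'
#' @param grid_rows,grid_cols Grid size in cells; at least 8 in each dimension
#'   so that patch-based models have room to operate. Row 1 is the northern
#'   edge of the scene.
#' @param cell_size_km Cell edge length in km (default 1, the working
#'   resolution of the analysis).
#' @param years Ordered integer vector of calendar years.
#' @param composite_days Strictly increasing, equally spaced DOY vector.
#' @param seed Master integer seed; every generator derives fixed substreams
#'   from it (see Details).
#'
#' @details All randomness flows from `seed` through fixed offsets: the NDVI
#'   cube uses `seed + 11`, environmental rasters `seed + 23 + i` per
#'   variable `i`, occurrence sampling `seed + 41`. Two calls with the same
#'   configuration therefore produce bit-identical scenes.
#'
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 48L, grid_cols = 48L, cell_size_km = 1,
                         years = 2001:2022,
                         composite_days = seq(65L, 225L, by = 8L),
                         seed = 1L) {
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (grid_rows < 8L || grid_cols < 8L)
    stop("grid must be at least 8x8")
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  composite_days <- as.integer(composite_days)
  d <- diff(composite_days)
  if (length(composite_days) < 3L || any(d <= 0L) || length(unique(d)) != 1L)
    stop("composite_days must be strictly increasing and equally spaced")
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 cell_size_km = cell_size_km, years = years,
                 composite_days = composite_days, seed = as.integer(seed)),
            class = "scene_config")
}

#' Geometry of a scene_config as used by spatial operations
#' @param config A `scene_config`.
#' @return List with `rows`, `cols`, `cell_size_km`, `origin` (km coordinates
#'   of the south-west corner).
#' @export
scene_geometry <- function(config) {
  list(rows = config$grid_rows, cols = config$grid_cols,
       cell_size_km = config$cell_size_km, origin = c(0, 0))
}

#' Phenology preset for the synthetic seasonal NDVI curve
#'
#' Parameterizes the piecewise-linear seasonal curve typical of early-spring
#' ephemeral plants: a flat background until regreening onset, a rapid linear
#' rise to the spring peak, a rapid fall to a post-peak minimum, then a mild
#' secondary rise as xerophytic shrubs green up over summer. The default peak
#' and post-peak minimum sit on DOY 137 and DOY 161, the dates where a
#' cold-desert ephemeral signal peaks in mid May and bottoms out in mid June
#' on the 8-day composite grid.
#'
#' @param onset_doy,peak_doy,trough_doy Day-of-year of regreening onset,
#'   spring peak, and post-peak minimum; must be strictly increasing and lie
#'   on the composite grid of the scene they are used with.
#' @param peak_ndvi Peak NDVI reached by the strongest (southernmost) pixels.
#' @param base_ndvi Bare-background NDVI before onset (also the value reached
#'   at the post-peak minimum).
#' @param xero_summer_ndvi NDVI level approached by the late-summer xerophyte
#'   signal at the end of the window.
#' @param noise_sd Standard deviation of additive Gaussian observation noise
#'   on each composite, and of the interannual amplitude wobble. 0 gives a
#'   fully deterministic cube.
#' @return Object of class `phenology_preset`.
#' @export
phenology_preset <- function(onset_doy = 89L, peak_doy = 137L, trough_doy = 161L,
                             peak_ndvi = 0.18, base_ndvi = 0.05,
                             xero_summer_ndvi = 0.08, noise_sd = 0.02) {
  if (!(onset_doy < peak_doy && peak_doy < trough_doy))
    stop("need onset_doy < peak_doy < trough_doy")
  if (!(base_ndvi >= 0 && base_ndvi < peak_ndvi && peak_ndvi <= 1))
    stop("need 0 <= base_ndvi < peak_ndvi <= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (xero_summer_ndvi < base_ndvi || xero_summer_ndvi >= peak_ndvi)
    stop("xero_summer_ndvi must lie in [base_ndvi, peak_ndvi)")
  structure(list(onset_doy = as.integer(onset_doy), peak_doy = as.integer(peak_doy),
                 trough_doy = as.integer(trough_doy), peak_ndvi = peak_ndvi,
                 base_ndvi = base_ndvi, xero_summer_ndvi = xero_summer_ndvi,
                 noise_sd = noise_sd),
            class = "phenology_preset")
}

#' Environmental-variable specification for the synthetic scene
#'
#' Describes the 15 environmental variables used by the driver analysis
#' (4 temperature, 4 precipitation, 4 snow, 3 topography), each with a
#' spatial pattern, marginal mean/sd in its physical units, a signed linear
#' effect coefficient on the ephemeral NDVI amplitude (per standardized
#' unit), and the fraction of spatial variance that is unstructured noise.
#'
#' The default effects encode the qualitative driver structure of
#' cold-desert ephemerals: snow and precipitation promote the spring signal,
#' temperature suppresses it, topography has a small negative role.
#'
#' @param table Optional replacement data.frame with columns
#'   `variable`, `category`, `pattern` ("gradient" or "patchy"), `mean`,
#'   `sd`, `effect`, `noise_frac`.
#' @return Object of class `env_effect_spec` (a data.frame).
#' @export
env_effect_spec <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      variable = c("Temp_year", "Temp_AU", "Temp_SP", "Temp_GS",
                   "Pre_year", "Pre_AU", "Pre_SP", "Pre_GS",
                   "Snowmelt", "Snowday", "Snowstart", "Snowend",
                   "Elevation", "Slope", "Aspect"),
      category = rep(c("temperature", "precipitation", "snow", "topography"),
                     c(4L, 4L, 4L, 3L)),
      pattern = c("gradient", "gradient", "patchy", "gradient",
                  "gradient", "patchy", "patchy", "gradient",
                  "gradient", "gradient", "patchy", "patchy",
                  "gradient", "patchy", "patchy"),
      mean = c(7, -10, 25, 15,
               150, 40, 30, 60,
               80, 80, 330, 75,
               450, 5, 180),
      sd = c(1, 1.5, 1, 1,
             30, 10, 10, 15,
             20, 15, 10, 10,
             80, 2, 90),
      effect = c(-0.004, -0.006, -0.002, -0.004,
                 0.006, 0.010, 0.003, 0.005,
                 0.005, 0.008, 0.003, 0.010,
                 -0.004, -0.002, -0.001),
      noise_frac = 0.3,
      stringsAsFactors = FALSE)
  }
  need <- c("variable", "category", "pattern", "mean", "sd", "effect", "noise_frac")
  if (!all(need %in% names(table))) stop("missing columns in env spec table")
  if (anyDuplicated(table$variable)) stop("duplicate variable names")
  bad <- setdiff(unique(table$category),
                 c("temperature", "precipitation", "snow", "topography"))
  if (length(bad)) stop("unknown category name: ", paste(bad, collapse = ", "))
  if (!all(table$pattern %in% c("gradient", "patchy")))
    stop("pattern must be 'gradient' or 'patchy'")
  if (any(!is.finite(table$effect))) stop("effect coefficients must be finite")
  class(table) <- c("env_effect_spec", "data.frame")
  table
}

# smooth patchy field: iid normal smoothed with a separable moving average,
# then re-standardized; deterministic under the current RNG state
.patchy_field <- function(nr, nc, halfwidth = 3L) {
  z <- matrix(stats::rnorm((nr + 2L * halfwidth) * (nc + 2L * halfwidth)),
              nr + 2L * halfwidth, nc + 2L * halfwidth)
  k <- rep(1, 2L * halfwidth + 1L)
  z <- apply(z, 2L, function(col) stats::filter(col, k, sides = 2L))
  z <- t(apply(z, 1L, function(row) stats::filter(row, k, sides = 2L)))
  z <- z[halfwidth + seq_len(nr), halfwidth + seq_len(nc)]
  (z - mean(z)) / stats::sd(z)
}

# standardized spatial field with the requested pattern; gradient runs
# north (row 1, low) to south (row nr, high)
.spatial_field <- function(nr, nc, pattern, noise_frac) {
  if (pattern == "gradient") {
    g <- matrix(rep(seq_len(nr), nc), nr, nc)
    g <- (g - mean(g)) / stats::sd(g)
    base <- g
  } else {
    base <- .patchy_field(nr, nc)
  }
  if (noise_frac > 0) {
    e <- matrix(stats::rnorm(nr * nc), nr, nc)
    f <- sqrt(1 - noise_frac^2) * base + noise_frac * e
    (f - mean(f)) / stats::sd(f)
  } else base
}

#' Generate environmental raster sets (historical and future variants)
#'
#' Draws one raster per variable in the spec, as `mean + sd * field` where
#' the field is a standardized gradient or smoothed patchy surface plus
#' unstructured noise. The future variant applies additive deltas to the
#' four substituted climate variables only (`Pre_AU`, `Pre_SP`, `Pre_year`,
#' `Temp_AU`); all other variables are held at their historical rasters.
#'
#' @param config A [scene_config()].
#' @param spec An [env_effect_spec()].
#' @param future_delta Named numeric vector of additive deltas; names must be
#'   a subset of the four substitutable variables. `NULL` for no future set.
#' @return List with elements `historical` (named list of matrices), `future`
#'   (or `NULL`), `spec`, and `geometry`.
#' @export
gen_env_rasters <- function(config, spec = env_effect_spec(), future_delta = NULL) {
  stopifnot(inherits(config, "scene_config"), inherits(spec, "env_effect_spec"))
  nr <- config$grid_rows; nc <- config$grid_cols
  hist <- vector("list", nrow(spec))
  names(hist) <- spec$variable
  for (i in seq_len(nrow(spec))) {
    set.seed(config$seed + 23L + i)
    f <- .spatial_field(nr, nc, spec$pattern[i], spec$noise_frac[i])
    hist[[i]] <- spec$mean[i] + spec$sd[i] * f
  }
  fut <- NULL
  if (!is.null(future_delta)) {
    allowed <- c("Pre_AU", "Pre_SP", "Pre_year", "Temp_AU")
    if (is.null(names(future_delta)) || !all(names(future_delta) %in% allowed))
      stop("future_delta names must be among: ", paste(allowed, collapse = ", "))
    fut <- hist
    for (v in names(future_delta)) fut[[v]] <- fut[[v]] + future_delta[[v]]
  }
  list(historical = hist, future = fut, spec = spec,
       geometry = scene_geometry(config))
}

#' Default future-scenario deltas for the synthetic scene
#'
#' Additive changes to the four substituted climate variables under three
#' emission scenarios and two future periods (T1 = 2041-2060,
#' T2 = 2081-2100). Magnitudes grow with emissions and with horizon,
#' emulating the warmer-and-wetter trajectory projected for the region.
#'
#' @return Named list (scenario_period) of named delta vectors.
#' @export
default_scenario_deltas <- function() {
  mk <- function(s) c(Pre_AU = 6 * s, Pre_SP = 4 * s, Pre_year = 15 * s,
                      Temp_AU = 1.2 * s)
  list(SSP126_T1 = mk(0.6), SSP370_T1 = mk(1.0), SSP585_T1 = mk(1.4),
       SSP126_T2 = mk(1.0), SSP370_T2 = mk(1.6), SSP585_T2 = mk(2.2))
}

#' Generate a synthetic NDVI cube
#'
#' Builds a per-pixel, per-year seasonal NDVI curve: flat background to the
#' regreening onset, linear rise to the spring peak, linear fall to the
#' post-peak minimum, then a mild secondary (xerophyte) rise to the end of
#' the window. The peak amplitude varies south-high/north-low across the
#' scene, is modulated linearly by any supplied environmental rasters, and
#' carries a small deterministic interannual trend-plus-cycle so that the
#' annual series has temporal structure even without noise.
#'
#' @param config A [scene_config()].
#' @param preset A [phenology_preset()]; its three key DOYs must lie on
#'   `config$composite_days`.
#' @param env Optional result of [gen_env_rasters()] (its `spec` effect
#'   coefficients modulate amplitude) or `NULL`.
#' @return Object of class `ndvi_cube`: list with `values` (array
#'   rows x cols x years x composites), `composite_days`, `years`,
#'   `geometry`, `preset`.
#' @export
gen_ndvi_cube <- function(config, preset = phenology_preset(), env = NULL) {
  stopifnot(inherits(config, "scene_config"), inherits(preset, "phenology_preset"))
  days <- config$composite_days
  key <- c(preset$onset_doy, preset$peak_doy, preset$trough_doy)
  if (!all(key %in% days))
    stop("preset DOYs (", paste(key, collapse = ", "),
         ") must lie on the composite grid")
  nr <- config$grid_rows; nc <- config$grid_cols
  ny <- length(config$years); nd <- length(days)

  # seasonal template: value(d) = c0(d) + c1(d) * amplitude
  c0 <- numeric(nd); c1 <- numeric(nd)
  on <- preset$onset_doy; pk <- preset$peak_doy; tr <- preset$trough_doy
  b <- preset$base_ndvi; xs <- preset$xero_summer_ndvi; last <- days[nd]
  for (i in seq_len(nd)) {
    d <- days[i]
    if (d <= on) { c0[i] <- b; c1[i] <- 0 }
    else if (d <= pk) { t <- (d - on) / (pk - on); c0[i] <- b * (1 - t); c1[i] <- t }
    else if (d <= tr) { s <- (d - pk) / (tr - pk); c0[i] <- b * s; c1[i] <- 1 - s }
    else { s <- (d - tr) / (last - tr); c0[i] <- b + (xs - b) * s; c1[i] <- 0 }
  }

  # base amplitude: south-high / north-low gradient
  sgrad <- (matrix(rep(seq_len(nr), nc), nr, nc) - 0.5) / nr
  amp0 <- b + (preset$peak_ndvi - b) * (0.55 + 0.45 * sgrad)

  # environmental modulation (linear in the standardized raster values)
  if (!is.null(env)) {
    sp <- env$spec
    for (i in seq_len(nrow(sp))) {
      if (sp$effect[i] == 0) next
      z <- (env$historical[[sp$variable[i]]] - sp$mean[i]) / sp$sd[i]
      amp0 <- amp0 + sp$effect[i] * z
    }
  }

  # deterministic interannual component: slow trend + a ~3-year oscillation
  yr <- seq_len(ny) - 1L
  year_det <- 0.0015 * yr + 0.01 * sin(2 * pi * yr / 3)

  set.seed(config$seed + 11L)
  year_rnd <- if (preset$noise_sd > 0) stats::rnorm(ny, 0, preset$noise_sd) else numeric(ny)

  vals <- array(NA_real_, dim = c(nr, nc, ny, nd))
  # floor keeps the spring peak above both the background and the late
  # xerophyte signal, so the seasonal maximum stays on the preset peak DOY
  lo <- max(b + 0.02, xs + 0.01); hi <- 0.95
  for (y in seq_len(ny)) {
    amp <- amp0 + year_det[y] + year_rnd[y]
    amp[amp < lo] <- lo; amp[amp > hi] <- hi
    slab <- outer(as.vector(amp), c1) + rep(c0, each = nr * nc)
    if (preset$noise_sd > 0)
      slab <- slab + stats::rnorm(length(slab), 0, preset$noise_sd)
    vals[, , y, ] <- array(slab, dim = c(nr, nc, nd))
  }
  structure(list(values = vals, composite_days = days, years = config$years,
                 geometry = scene_geometry(config), preset = preset,
                 seed = config$seed),
            class = "ndvi_cube")
}

#' @export
print.ndvi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("<ndvi_cube> ", d[1], "x", d[2], " grid, ", d[3], " years (",
      x$years[1], "-", x$years[length(x$years)], "), ", d[4],
      " composites (DOY ", x$composite_days[1], "-",
      x$composite_days[length(x$composite_days)], ")\n", sep = "")
  invisible(x)
}

#' Reference family roster for occurrence validation
#'
#' Eleven plant families of early-spring ephemerals with validation point
#' counts shaped like a published cold-desert validation table: per family,
#' the number of occurrence points and how many fall inside the extracted
#' distribution. The family rows total 190 points (152 inside).
#'
#' @return data.frame with columns `family`, `n`, `inside`.
#' @export
ephemeral_families <- function() {
  data.frame(
    family = c("Brassicaceae", "Compositae", "Gramineae", "Boraginaceae",
               "Liliaceae", "Umbelliferae", "Geraniaceae", "Chenopodiaceae",
               "Leguminosae", "Plantaninaceae", "Papaveraceae"),
    n = c(50L, 29L, 26L, 14L, 13L, 11L, 19L, 11L, 7L, 5L, 5L),
    inside = c(48L, 25L, 21L, 12L, 8L, 8L, 14L, 10L, 2L, 1L, 3L),
    stringsAsFactors = FALSE)
}

# uniform coordinate inside the given cells (row, col), geometry in km;
# y grows northward, row 1 is the northern edge
.cell_to_xy <- function(row, col, geom, jitter = TRUE) {
  cs <- geom$cell_size_km
  u <- if (jitter) stats::runif(length(row)) else rep(0.5, length(row))
  v <- if (jitter) stats::runif(length(row)) else rep(0.5, length(row))
  x <- geom$origin[1] + (col - 1 + u) * cs
  y <- geom$origin[2] + (geom$rows - row + v) * cs
  cbind(x = x, y = y)
}

#' Generate synthetic species occurrence points
#'
#' Samples occurrence points on the scene grid so that, in expectation, a
#' fraction `inside_prob` falls in masked (distribution) cells. Each point
#' carries a family label; duplicate points within one grid cell and family
#' are removed, mirroring the deduplication applied to herbarium records.
#'
#' @param mask A [build_distribution_mask()] result (class `dist_mask`).
#' @param n_points Number of points to draw (before deduplication); ignored
#'   when `families` is a data.frame roster with per-family counts.
#' @param inside_prob Probability that a point is placed in a masked cell.
#' @param families Character vector of family labels to sample from, or a
#'   data.frame with columns `family` and `n` (then counts are taken
#'   verbatim). Defaults to [ephemeral_families()].
#' @param seed Integer seed.
#' @return data.frame (`occurrence_table`) with columns `x`, `y` (km),
#'   `family`.
#' @export
gen_occurrences <- function(mask, n_points = 185L, inside_prob = 0.8216,
                            families = ephemeral_families(), seed = 1L) {
  stopifnot(inherits(mask, "dist_mask"))
  if (inside_prob < 0 || inside_prob > 1) stop("inside_prob must be in [0, 1]")
  if (is.data.frame(families)) {
    fam <- rep(families$family, families$n)
  } else {
    if (n_points <= 0) stop("n_points must be positive")
    fam <- rep_len(families, n_points)
  }
  n <- length(fam)
  m <- mask$mask
  in_cells <- which(m); out_cells <- which(!m)
  if (inside_prob > 0 && length(in_cells) == 0L)
    stop("mask is empty but inside_prob > 0")
  if (inside_prob < 1 && length(out_cells) == 0L)
    stop("mask covers the whole scene but inside_prob < 1")
  set.seed(seed + 41L)
  inside <- stats::runif(n) < inside_prob
  cell <- integer(n)
  cell[inside] <- sample(in_cells, sum(inside), replace = TRUE)
  cell[!inside] <- sample(out_cells, sum(!inside), replace = TRUE)
  row <- (cell - 1L) %% mask$geometry$rows + 1L
  col <- (cell - 1L) %/% mask$geometry$rows + 1L
  xy <- .cell_to_xy(row, col, mask$geometry)
  occ <- data.frame(x = xy[, 1], y = xy[, 2], family = fam,
                    stringsAsFactors = FALSE)
  dup <- duplicated(data.frame(cell, fam))
  occ <- occ[!dup, , drop = FALSE]
  rownames(occ) <- NULL
  class(occ) <- c("occurrence_table", "data.frame")
  occ
}

#' Construct occurrence points from a per-family count table
#'
#' Deterministically places, for each family, `inside` points in masked
#' cells and `n - inside` points in unmasked cells, producing an occurrence
#' table whose validation report reproduces the given counts exactly.
#' Useful for building validation-shaped reference reports.
#'
#' @param mask A `dist_mask`.
#' @param counts data.frame with columns `family`, `n`, `inside`.
#' @return An `occurrence_table` data.frame.
#' @export
occurrences_from_counts <- function(mask, counts) {
  stopifnot(inherits(mask, "dist_mask"),
            all(c("family", "n", "inside") %in% names(counts)))
  if (any(counts$inside > counts$n) || any(counts$n < 0))
    stop("need 0 <= inside <= n per family")
  m <- mask$mask
  in_cells <- which(m); out_cells <- which(!m)
  if (sum(counts$inside) > 0 && length(in_cells) == 0L) stop("mask is empty")
  if (sum(counts$n - counts$inside) > 0 && length(out_cells) == 0L)
    stop("mask has no outside cells")
  pick <- function(cells, k) cells[((seq_len(k) - 1L) %% length(cells)) + 1L]
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    ci <- pick(in_cells, counts$inside[i])
    co <- pick(out_cells, counts$n[i] - counts$inside[i])
    cell <- c(ci, co)
    if (length(cell) == 0L) next
    row <- (cell - 1L) %% mask$geometry$rows + 1L
    col <- (cell - 1L) %/% mask$geometry$rows + 1L
    xy <- .cell_to_xy(row, col, mask$geometry, jitter = FALSE)
    rows[[i]] <- data.frame(x = xy[, 1], y = xy[, 2],
                            family = counts$family[i],
                            stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, rows)
  rownames(occ) <- NULL
  class(occ) <- c("occurrence_table", "data.frame")
  occ
}
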