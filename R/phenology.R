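#' NDVI from red and near-infrared reflectance
#'
#' Standard normalized difference: `(nir - red) / (nir + red)`. Cells where
#' both bands are zero have an undefined index and are returned as `NA`
#' (flagged missing), never silently zero.
#'
#' @param nir,red Numeric vectors/matrices of surface reflectance in
#'   \[0, 1\], same shape.
#' @return NDVI values in \[-1, 1\], same shape as the inputs.
#' @export
compute_ndvi <- function(nir, red) {
  if (!identical(dim(nir), dim(red)) || length(nir) != length(red))
    stop("nir and red must have the same shape")
  rng <- range(c(nir, red), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("reflectances must lie in [0, 1]")
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}

#' Detect the three life-cycle key points of one pixel-year NDVI series
#'
#' Finds, on one seasonal NDVI series over the composite grid: the peak
#' growth point `DOYa` (global maximum, earliest composite on ties), the
#' post-peak minimum `DOYb` (minimum over composites strictly after the
#' peak, earliest on ties), and the regreening onset `DOYc` (minimum over
#' composites strictly before the peak, latest on ties — the last background
#' composite before the rise).
#'
#' @param x Numeric NDVI series, one value per composite (NA = missing).
#' @param doys Day-of-year of each composite (same length as `x`).
#' @param min_obs Minimum number of non-missing composites required.
#' @return List of class `pheno_keypoints` with `doy_c`, `ndvi_c`, `doy_a`,
#'   `ndvi_a`, `doy_b`, `ndvi_b` and `status` in `"ok"`, `"degenerate"`
#'   (flat or monotone series with no usable peak), `"no_phenology"`
#'   (too few observations).
#' @export
detect_key_points <- function(x, doys, min_obs = 5L) {
  if (length(x) != length(doys)) stop("x and doys must have the same length")
  out <- list(doy_c = NA_integer_, ndvi_c = NA_real_,
              doy_a = NA_integer_, ndvi_a = NA_real_,
              doy_b = NA_integer_, ndvi_b = NA_real_,
              status = "no_phenology")
  class(out) <- "pheno_keypoints"
  ok <- which(!is.na(x))
  if (length(ok) < min_obs) return(out)
  ia <- ok[which.max(x[ok])]                     # earliest tie
  before <- ok[ok < ia]; after <- ok[ok > ia]
  if (max(x[ok]) - min(x[ok]) == 0 ||
      length(before) == 0L || length(after) == 0L) {
    out$status <- "degenerate"
    out$doy_a <- doys[ia]; out$ndvi_a <- x[ia]
    return(out)
  }
  ib <- after[which.min(x[after])]               # earliest tie
  xc <- x[before]
  ic <- before[max(which(xc == min(xc)))]        # latest tie
  out$doy_a <- doys[ia]; out$ndvi_a <- x[ia]
  out$doy_b <- doys[ib]; out$ndvi_b <- x[ib]
  out$doy_c <- doys[ic]; out$ndvi_c <- x[ic]
  out$status <- "ok"
  out
}

#' @export
print.pheno_keypoints <- function(x, ...) {
  cat("<pheno_keypoints> status:", x$status, "\n")
  if (x$status == "ok")
    cat(sprintf("  onset  DOYc=%d (NDVI %.4f)\n  peak   DOYa=%d (NDVI %.4f)\n  trough DOYb=%d (NDVI %.4f)\n",
                x$doy_c, x$ndvi_c, x$doy_a, x$ndvi_a, x$doy_b, x$ndvi_b))
  invisible(x)
}

#' Key points for every pixel-year of a cube (vectorized)
#'
#' Applies the same rules as [detect_key_points()] to every pixel-year
#' series of an NDVI cube using a vectorized argmax/argmin scan.
#'
#' @param cube An `ndvi_cube`.
#' @param min_obs Minimum non-missing composites per series.
#' @return List of class `pheno_keypoints_cube` with arrays
#'   (rows x cols x years) `doy_c`, `ndvi_c`, `doy_a`, `ndvi_a`, `doy_b`,
#'   `ndvi_b`, and a character array `status`.
#' @export
extract_key_points <- function(cube, min_obs = 5L) {
  stopifnot(inherits(cube, "ndvi_cube"))
  d <- dim(cube$values)
  ns <- d[1] * d[2] * d[3]; nd <- d[4]
  m <- matrix(cube$values, ns, nd)
  doys <- cube$composite_days
  nonmiss <- rowSums(!is.na(m))
  mm <- m; mm[is.na(mm)] <- -Inf
  ia <- max.col(mm, ties.method = "first")
  vmax <- mm[cbind(seq_len(ns), ia)]
  mInf <- ifelse(is.na(m), Inf, m)
  vmin <- mInf[cbind(seq_len(ns), max.col(-mInf, ties.method = "first"))]
  colidx <- matrix(rep(seq_len(nd), each = ns), ns, nd)
  after <- mm; after[colidx <= ia | is.na(m)] <- Inf
  ib <- max.col(-after, ties.method = "first")
  has_after <- is.finite(after[cbind(seq_len(ns), ib)])
  before <- mm; before[colidx >= ia | is.na(m)] <- Inf
  ic <- max.col(-before, ties.method = "last")
  has_before <- is.finite(before[cbind(seq_len(ns), ic)])

  status <- rep("ok", ns)
  status[vmax - vmin == 0 | !has_after | !has_before] <- "degenerate"
  status[nonmiss < min_obs] <- "no_phenology"
  okv <- status == "ok"
  shape <- d[1:3]
  arr <- function(v) array(v, dim = shape)
  take <- function(idx, keep) {
    v <- m[cbind(seq_len(ns), idx)]; v[!keep] <- NA_real_; v
  }
  dtake <- function(idx, keep) {
    v <- doys[idx]; v[!keep] <- NA_integer_; v
  }
  structure(list(
    doy_c = arr(dtake(ic, okv)), ndvi_c = arr(take(ic, okv)),
    doy_a = arr(dtake(ia, okv | status == "degenerate")),
    ndvi_a = arr(take(ia, okv | status == "degenerate")),
    doy_b = arr(dtake(ib, okv)), ndvi_b = arr(take(ib, okv)),
    status = arr(status), years = cube$years, geometry = cube$geometry),
    class = "pheno_keypoints_cube")
}

#' Life-cycle NDVI increment of ephemeral plants
#'
#' The ephemeral contribution of one pixel-year:
#' `(NDVIa - NDVIc) + (NDVIa - NDVIb)` — the regreening rise plus the
#' senescence decline around the spring peak. Degenerate or missing key
#' points give `NA`.
#'
#' @param points A `pheno_keypoints` entry (from [detect_key_points()]).
#' @return Scalar NDVI increment (>= 0 when the key-point ordering holds).
#' @export
ephemeral_increment <- function(points) {
  stopifnot(inherits(points, "pheno_keypoints"))
  if (points$status != "ok") return(NA_real_)
  (points$ndvi_a - points$ndvi_c) + (points$ndvi_a - points$ndvi_b)
}

#' Per-pixel ephemeral NDVI map from a cube
#'
#' Computes, for every pixel-year, the life-cycle increment and the
#' senescence decline `NDVIa - NDVIb`, plus each pixel's multi-year mean
#' decline (the masking statistic).
#'
#' @param cube An `ndvi_cube`, or a precomputed `pheno_keypoints_cube`.
#' @return Object of class `eph_map`: list with arrays `eph`
#'   (rows x cols x years), `decline` (same), matrix
#'   `multiyear_mean_decline`, plus `years` and `geometry`.
#' @export
ephemeral_ndvi_map <- function(cube) {
  kp <- if (inherits(cube, "pheno_keypoints_cube")) cube else extract_key_points(cube)
  rise <- kp$ndvi_a - kp$ndvi_c
  decline <- kp$ndvi_a - kp$ndvi_b
  eph <- rise + decline
  mmd <- apply(decline, c(1L, 2L), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(eph = eph, decline = decline, multiyear_mean_decline = mmd,
                 years = kp$years, geometry = kp$geometry),
            class = "eph_map")
}

#' Distribution mask from the multi-year mean senescence decline
#'
#' In the default `global_mean` mode the threshold is the spatial mean (over
#' valid pixels) of the per-pixel multi-year mean decline, and a pixel is in
#' the distribution area iff its multi-year mean decline strictly exceeds
#' that threshold. In `per_pixel` mode each pixel is compared against its
#' own multi-year mean: it is in-mask iff its annual decline exceeds its own
#' mean in at least half of the years (an alternative self-thresholding
#' reading, kept for sensitivity analysis).
#'
#' @param eph An `eph_map`.
#' @param mode `"global_mean"` (default) or `"per_pixel"`.
#' @param threshold Optional explicit threshold overriding the global mean.
#' @return Object of class `dist_mask`: list with logical matrix `mask`,
#'   `threshold_value`, `mode`, `geometry`.
#' @export
build_distribution_mask <- function(eph, mode = c("global_mean", "per_pixel"),
                                    threshold = NULL) {
  stopifnot(inherits(eph, "eph_map"))
  mode <- match.arg(mode)
  mmd <- eph$multiyear_mean_decline
  if (all(is.na(mmd))) stop("no valid pixels")
  if (mode == "global_mean") {
    thr <- if (is.null(threshold)) mean(mmd, na.rm = TRUE) else threshold
    mask <- !is.na(mmd) & mmd > thr
  } else {
    nyr <- dim(eph$decline)[3]
    exceed <- sweep(eph$decline, c(1L, 2L), mmd, FUN = ">")
    frac <- apply(exceed, c(1L, 2L), function(v) mean(v, na.rm = TRUE))
    mask <- !is.na(frac) & frac >= 0.5
    thr <- NA_real_
  }
  structure(list(mask = mask, threshold_value = thr, mode = mode,
                 geometry = eph$geometry),
            class = "dist_mask")
}

#' @export
print.dist_mask <- function(x, ...) {
  cat("<dist_mask> ", sum(x$mask), "/", length(x$mask), " pixels in-mask (mode ",
      x$mode, ", threshold ",
      if (is.na(x$threshold_value)) "per-pixel" else signif(x$threshold_value, 4),
      ")\n", sep = "")
  invisible(x)
}

#' Jenks natural-breaks classification (exact optimum)
#'
#' Exact Fisher dynamic-programming solution of the 1-D natural-breaks
#' problem: partitions sorted values into `k` contiguous classes minimizing
#' the total within-class sum of squared deviations from class means.
#' Deterministic; suitable for the value counts arising from scene-sized
#' rasters (use sampling for very large inputs).
#'
#' @param values Numeric vector (NAs dropped).
#' @param k Number of classes (>= 2, <= number of distinct values).
#' @return List with `breaks` (length k+1: min, k-1 interior cut values —
#'   the largest member of each lower class — and max), `objective` (optimal
#'   within-class SSD), and `assign_fun`, a function mapping values to class
#'   index 1..k (value <= cut goes to the lower class).
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (k < 2) stop("k must be >= 2")
  if (length(unique(x)) < k) stop("need at least k distinct values")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) { # within-class SSD of x[i..j], vectorized over i
    s <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    s2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    pmax(0, s2 - s^2 / (j - i + 1))
  }
  # D[m, j]: optimal SSD of first j values in m classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)  # last class of optimum starts at B[m, j]
  D[1, ] <- vapply(seq_len(n), function(j) ssd(1L, j), numeric(1))
  B[1, ] <- 1L
  for (m in 2:k) {
    for (j in m:n) {
      i <- m:j                     # candidate starts of the last class
      cand <- D[m - 1, i - 1] + ssd(i, j)
      best <- which.min(cand)
      D[m, j] <- cand[best]
      B[m, j] <- i[best]
    }
  }
  starts <- integer(k); j <- n
  for (m in k:1) { starts[m] <- B[m, j]; j <- starts[m] - 1L }
  cuts <- x[starts[-1] - 1L]       # largest member of each lower class
  breaks <- c(x[1], cuts, x[n])
  assign_fun <- function(v) {
    idx <- findInterval(v, c(-Inf, cuts, Inf), left.open = TRUE)
    idx
  }
  list(breaks = breaks, objective = D[k, n], assign_fun = assign_fun)
}

.class_labels <- c("Sparse", "Less", "Medium")

#' Classify the ephemeral NDVI field into vigor classes
#'
#' Labels each masked pixel `Sparse`, `Less` or `Medium` by two ordered
#' cutpoints (default the natural-breaks thresholds 0.1564 and 0.1878 on
#' the multi-year mean ephemeral increment: Medium strictly above the upper
#' cut, Sparse at or below the lower cut). Pixels outside the mask are
#' `Unclassified`. Alternatively recomputes the cutpoints by Jenks
#' natural breaks on the masked values.
#'
#' @param values Numeric matrix of per-pixel values (e.g. the multi-year
#'   mean ephemeral increment), or an `eph_map` (then its temporal mean
#'   `eph` field is used).
#' @param mask A `dist_mask` (or logical matrix); `NULL` classifies all
#'   finite pixels.
#' @param thresholds Ordered numeric pair `(t_low, t_high)`.
#' @param method `"fixed"` (use `thresholds`) or `"jenks"` (recompute 3-class
#'   breaks from the masked values).
#' @return Object of class `class_map`: list with factor matrix `labels`
#'   (levels Unclassified, Sparse, Less, Medium), integer matrix `codes`
#'   (0-3), `thresholds`, `geometry`.
#' @export
classify_ndvi <- function(values, mask = NULL,
                          thresholds = c(0.1564, 0.1878),
                          method = c("fixed", "jenks")) {
  method <- match.arg(method)
  geometry <- NULL
  if (inherits(values, "eph_map")) {
    geometry <- values$geometry
    values <- apply(values$eph, c(1L, 2L), mean, na.rm = TRUE)
  }
  if (inherits(mask, "dist_mask")) { geometry <- mask$geometry; mask <- mask$mask }
  if (is.null(mask)) mask <- is.finite(values)
  if (!identical(dim(values), dim(mask))) stop("values and mask shapes differ")
  inmask <- mask & is.finite(values)
  if (method == "jenks") {
    jb <- jenks_breaks(values[inmask], 3L)
    thresholds <- jb$breaks[2:3]
  }
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be two increasing values")
  codes <- matrix(0L, nrow(values), ncol(values))
  codes[inmask] <- 1L
  codes[inmask & values > thresholds[1]] <- 2L
  codes[inmask & values > thresholds[2]] <- 3L
  labels <- matrix(factor(c("Unclassified", .class_labels)[codes + 1L],
                          levels = c("Unclassified", .class_labels)),
                   nrow(values), ncol(values))
  structure(list(labels = labels, codes = codes, thresholds = thresholds,
                 geometry = geometry),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map> thresholds (", paste(signif(x$thresholds, 4), collapse = ", "),
      ")\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Validate the distribution mask against occurrence points
#'
#' Projects each occurrence point onto the mask grid (half-open cell bounds
#' `[x, x + cell)`) and tabulates, per family and overall, how many points
#' fall inside the extracted distribution. Off-grid points count as outside
#' and are tallied in a warning attribute.
#'
#' @param mask A `dist_mask`.
#' @param occ An occurrence table (columns `x`, `y` in km, `family`).
#' @return data.frame of class `accuracy_report` with columns `family`, `n`,
#'   `inside`, `outside`, `accuracy_pct` (rounded to 2 decimals), family
#'   rows first and a `Sum` row last; attribute `off_grid` counts off-scene
#'   points.
#' @export
validate_occurrences <- function(mask, occ) {
  stopifnot(inherits(mask, "dist_mask"))
  g <- mask$geometry; cs <- g$cell_size_km
  col <- floor((occ$x - g$origin[1]) / cs) + 1L
  rowk <- floor((occ$y - g$origin[2]) / cs) + 1L   # 1 = southern row band
  row <- g$rows - rowk + 1L
  on_grid <- col >= 1L & col <= g$cols & row >= 1L & row <= g$rows
  inside <- rep(FALSE, nrow(occ))
  inside[on_grid] <- mask$mask[cbind(row[on_grid], col[on_grid])]
  if (any(!on_grid))
    warning(sum(!on_grid), " occurrence point(s) off-grid; counted as outside")
  fam <- as.character(occ$family)
  fams <- unique(fam)
  per <- data.frame(
    family = fams,
    n = as.integer(vapply(fams, function(f) sum(fam == f), 0L)),
    inside = as.integer(vapply(fams, function(f) sum(inside[fam == f]), 0L)),
    stringsAsFactors = FALSE)
  per$outside <- per$n - per$inside
  tot <- data.frame(family = "Sum", n = sum(per$n), inside = sum(per$inside),
                    outside = sum(per$outside), stringsAsFactors = FALSE)
  rep_ <- rbind(per, tot)
  rep_$accuracy_pct <- round(100 * rep_$inside / rep_$n, 2)
  rownames(rep_) <- NULL
  attr(rep_, "off_grid") <- sum(!on_grid)
  class(rep_) <- c("accuracy_report", "data.frame")
  rep_
}
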