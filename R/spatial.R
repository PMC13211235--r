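#' Class transition matrix between two period maps
#'
#' Entry (i, j) is the area (km^2) of pixels labelled class i in the first
#' period and class j in the second. Pixels `Unclassified` in either period
#' are excluded from the matrix and tallied separately, so the grand total
#' equals the jointly classified area.
#'
#' @param map_t1,map_t2 `class_map` objects on the same grid.
#' @param cell_area_km2 Area of one cell (km^2).
#' @param periods Optional character pair of period labels.
#' @return Object of class `transition_matrix`: list with 3x3 matrix `area`
#'   (Sparse/Less/Medium), `cell_area_km2`, `excluded_km2`, `periods`.
#' @export
transition_matrix <- function(map_t1, map_t2, cell_area_km2 = 1,
                              periods = c("t1", "t2")) {
  stopifnot(inherits(map_t1, "class_map"), inherits(map_t2, "class_map"))
  if (!identical(dim(map_t1$codes), dim(map_t2$codes)))
    stop("grids differ between the two maps")
  c1 <- map_t1$codes; c2 <- map_t2$codes
  both <- c1 > 0L & c2 > 0L
  tab <- table(factor(c1[both], levels = 1:3), factor(c2[both], levels = 1:3))
  area <- matrix(as.numeric(tab) * cell_area_km2, 3L, 3L,
                 dimnames = list(source = .class_labels,
                                 destination = .class_labels))
  structure(list(area = area, cell_area_km2 = cell_area_km2,
                 excluded_km2 = sum(!both) * cell_area_km2,
                 periods = periods),
            class = "transition_matrix")
}

#' Transition matrix from printed per-flow areas
#'
#' Wraps an already-tabulated 3x3 area matrix (e.g. transcribed from a
#' published transfer table) in the `transition_matrix` container so that
#' share and accounting operations apply to it.
#'
#' @param area 3x3 numeric matrix of km^2, source classes in rows
#'   (Sparse, Less, Medium) and destination classes in columns.
#' @param periods Optional period labels.
#' @param cell_area_km2 Cell area used to produce the table.
#' @return A `transition_matrix`.
#' @export
as_transition_matrix <- function(area, periods = c("t1", "t2"),
                                 cell_area_km2 = NA_real_) {
  area <- as.matrix(area)
  if (!all(dim(area) == c(3L, 3L))) stop("area must be 3x3")
  if (any(area < 0)) stop("areas must be nonnegative")
  dimnames(area) <- list(source = .class_labels, destination = .class_labels)
  structure(list(area = area, cell_area_km2 = cell_area_km2,
                 excluded_km2 = 0, periods = periods),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", x$periods[1], " -> ", x$periods[2],
      " (total ", format(sum(x$area), big.mark = ","), " km^2, excluded ",
      format(x$excluded_km2, big.mark = ","), " km^2)\n", sep = "")
  print(x$area)
  invisible(x)
}

#' Class share of a transition matrix along one axis
#'
#' Percentage of the jointly classified area held by one class as source
#' (row sum) or destination (column sum).
#'
#' @param matrix A `transition_matrix`.
#' @param class One of `"Sparse"`, `"Less"`, `"Medium"`.
#' @param axis `"source"` or `"destination"`.
#' @return Percentage of the grand total.
#' @export
class_share <- function(matrix, class, axis = c("source", "destination")) {
  stopifnot(inherits(matrix, "transition_matrix"))
  axis <- match.arg(axis)
  class <- match.arg(class, .class_labels)
  tot <- sum(matrix$area)
  if (tot <= 0) stop("transition matrix has zero total area")
  s <- if (axis == "source") sum(matrix$area[class, ]) else sum(matrix$area[, class])
  100 * s / tot
}

# cell-center coordinates (km) of a grid; y grows northward, row 1 = north
.cell_centers <- function(geometry) {
  cs <- geometry$cell_size_km
  x <- geometry$origin[1] + (col(matrix(0, geometry$rows, geometry$cols)) - 0.5) * cs
  y <- geometry$origin[2] + (geometry$rows -
         row(matrix(0, geometry$rows, geometry$cols)) + 0.5) * cs
  list(x = x, y = y)
}

#' Weighted centroid shift between two periods
#'
#' Computes the weight-weighted mean of cell-center coordinates (planar km)
#' in each period, the Euclidean displacement between the two centroids, and
#' the bearing of the movement in degrees clockwise from north.
#'
#' @param weights_t1,weights_t2 Nonnegative weight matrices (e.g. class
#'   indicators or NDVI values); NAs treated as zero.
#' @param geometry Grid geometry (list with `rows`, `cols`, `cell_size_km`,
#'   `origin`), e.g. from [scene_geometry()] or a `class_map$geometry`.
#' @return List of class `centroid_shift` with `centroid1`, `centroid2`
#'   (named x/y, km), `distance_km`, `bearing_deg`.
#' @export
centroid_shift <- function(weights_t1, weights_t2, geometry) {
  cc <- .cell_centers(geometry)
  one <- function(w) {
    w[is.na(w)] <- 0
    if (any(w < 0)) stop("weights must be nonnegative")
    tw <- sum(w)
    if (tw <= 0) stop("all-zero weights")
    c(x = sum(w * cc$x) / tw, y = sum(w * cc$y) / tw)
  }
  c1 <- one(weights_t1); c2 <- one(weights_t2)
  dx <- c2["x"] - c1["x"]; dy <- c2["y"] - c1["y"]
  dist <- sqrt(dx^2 + dy^2)
  bearing <- if (dist == 0) NA_real_ else (atan2(dx, dy) * 180 / pi) %% 360
  structure(list(centroid1 = c1, centroid2 = c2,
                 distance_km = unname(dist), bearing_deg = unname(bearing)),
            class = "centroid_shift")
}

#' @export
print.centroid_shift <- function(x, ...) {
  cat(sprintf("<centroid_shift> (%.2f, %.2f) -> (%.2f, %.2f) km: %.2f km",
              x$centroid1["x"], x$centroid1["y"],
              x$centroid2["x"], x$centroid2["y"], x$distance_km))
  if (!is.na(x$bearing_deg)) cat(sprintf(" at %.1f deg", x$bearing_deg))
  cat("\n"); invisible(x)
}

#' Centroid track of one class across period maps
#'
#' Follows the area-weighted centroid of one class through a list of period
#' `class_map`s (indicator weights by default; supply `value_maps` for
#' NDVI-weighted centroids).
#'
#' @param maps Named list of `class_map` objects in period order.
#' @param class Class label to track.
#' @param value_maps Optional list of matrices used as weights within the
#'   class (same order as `maps`).
#' @return data.frame: period, x_km, y_km, dist_km (from previous period,
#'   NA for the first), bearing_deg.
#' @export
centroid_track <- function(maps, class = "Medium", value_maps = NULL) {
  class <- match.arg(class, .class_labels)
  code <- match(class, .class_labels)
  geom <- maps[[1]]$geometry
  cents <- lapply(seq_along(maps), function(i) {
    w <- (maps[[i]]$codes == code) * 1
    if (!is.null(value_maps)) w <- w * pmax(value_maps[[i]], 0)
    w
  })
  nms <- names(maps); if (is.null(nms)) nms <- paste0("P", seq_along(maps))
  out <- data.frame(period = nms, x_km = NA_real_, y_km = NA_real_,
                    dist_km = NA_real_, bearing_deg = NA_real_,
                    stringsAsFactors = FALSE)
  cc <- .cell_centers(geom)
  for (i in seq_along(cents)) {
    w <- cents[[i]]; tw <- sum(w)
    if (tw <= 0) next
    out$x_km[i] <- sum(w * cc$x) / tw
    out$y_km[i] <- sum(w * cc$y) / tw
    if (i > 1 && !is.na(out$x_km[i - 1])) {
      dx <- out$x_km[i] - out$x_km[i - 1]; dy <- out$y_km[i] - out$y_km[i - 1]
      out$dist_km[i] <- sqrt(dx^2 + dy^2)
      out$bearing_deg[i] <- if (out$dist_km[i] == 0) NA_real_
                            else (atan2(dx, dy) * 180 / pi) %% 360
    }
  }
  out
}

#' Coefficient-of-variation stability map
#'
#' Per-pixel sample coefficient of variation (sd / mean, n-1 denominator)
#' of the annual ephemeral NDVI increment. Pixels with zero temporal mean
#' are flagged undefined (`NA`).
#'
#' @param stack 3-D array (rows x cols x years), or an `eph_map` (its `eph`
#'   field is used). At least 3 years required.
#' @return Matrix of CV values (NA where undefined).
#' @export
cv_map <- function(stack) {
  if (inherits(stack, "eph_map")) stack <- stack$eph
  if (length(dim(stack)) != 3L || dim(stack)[3] < 3L)
    stop("need a rows x cols x years array with >= 3 years")
  mu <- apply(stack, c(1L, 2L), mean, na.rm = TRUE)
  sdv <- apply(stack, c(1L, 2L), stats::sd, na.rm = TRUE)
  out <- sdv / mu
  out[!is.finite(out) | mu == 0] <- NA_real_
  out
}
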