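#' Regional annual mean series of the ephemeral NDVI increment
#'
#' @param eph An `eph_map`.
#' @param mask Optional `dist_mask` (or logical matrix) restricting the
#'   spatial mean.
#' @return data.frame with columns `year`, `value`.
#' @export
annual_mean_series <- function(eph, mask = NULL) {
  stopifnot(inherits(eph, "eph_map"))
  if (inherits(mask, "dist_mask")) mask <- mask$mask
  v <- vapply(seq_along(eph$years), function(y) {
    slab <- eph$eph[, , y]
    if (!is.null(mask)) slab[!mask] <- NA_real_
    mean(slab, na.rm = TRUE)
  }, numeric(1))
  data.frame(year = eph$years, value = v)
}

# closed-form least-squares fit of y on x: slope, intercept, SSE, p-value
.seg_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  a <- my - b * mx
  r <- y - a - b * x
  sse <- sum(r^2)
  p <- NA_real_
  if (n > 2 && sxx > 0) {
    s2 <- sse / (n - 2)
    if (s2 > 0) {
      tstat <- b / sqrt(s2 / sxx)
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    } else p <- 0
  }
  list(slope = b, intercept = a, sse = sse, p = p)
}

#' Piecewise linear segmentation of an annual series
#'
#' Exhaustive search over all admissible breakpoint placements: the series
#' is partitioned into `n_breaks + 1` contiguous segments of length at least
#' `min_len`, each fitted by least squares, and the placement minimizing the
#' total residual sum of squares is returned (earliest breakpoints on ties).
#' Segments are labelled `P1`, `P2`, ...
#'
#' @param series data.frame with `year` and `value` columns (years
#'   consecutive), or a numeric vector with `years` supplied.
#' @param n_breaks Number of breakpoints (0-4).
#' @param min_len Minimum segment length in years (default 3).
#' @param years Year vector when `series` is a plain numeric vector.
#' @return Object of class `segmentation`: list with `segments` (data.frame:
#'   segment, start_year, end_year, slope, intercept, p_value), `breaks`
#'   (years ending each non-final segment), `sse`.
#' @export
piecewise_segments <- function(series, n_breaks = 3L, min_len = 3L, years = NULL) {
  if (is.data.frame(series)) { years <- series$year; y <- series$value }
  else y <- as.numeric(series)
  n <- length(y)
  if (is.null(years)) years <- seq_len(n)
  if (any(diff(years) != 1)) stop("years must be consecutive")
  if (n_breaks < 0 || n_breaks > 4) stop("n_breaks must be in 0..4")
  k <- n_breaks + 1L
  if (k * min_len > n) stop("series too short for ", n_breaks,
                            " breaks at min_len ", min_len)
  x <- as.numeric(years)
  seg_sse <- function(i, j) .seg_fit(x[i:j], y[i:j])$sse
  best <- NULL; best_sse <- Inf
  if (n_breaks == 0L) {
    best <- integer(0); best_sse <- seg_sse(1L, n)
  } else {
    # breakpoints = indices of the last year of each non-final segment
    cand <- utils::combn(seq_len(n - 1L), n_breaks)
    for (ci in seq_len(ncol(cand))) {
      b <- cand[, ci]
      bounds <- c(0L, b, n)
      lens <- diff(bounds)
      if (any(lens < min_len)) next
      tot <- 0
      for (s in seq_len(k)) tot <- tot + seg_sse(bounds[s] + 1L, bounds[s + 1L])
      if (tot < best_sse - 1e-12) { best_sse <- tot; best <- b }
    }
    if (is.null(best)) stop("no admissible breakpoint placement")
  }
  bounds <- c(0L, best, n)
  segs <- lapply(seq_len(k), function(s) {
    i <- bounds[s] + 1L; j <- bounds[s + 1L]
    f <- .seg_fit(x[i:j], y[i:j])
    data.frame(segment = paste0("P", s), start_year = years[i],
               end_year = years[j], slope = f$slope, intercept = f$intercept,
               p_value = f$p, stringsAsFactors = FALSE)
  })
  structure(list(segments = do.call(rbind, segs),
                 breaks = if (length(best)) years[best] else numeric(0),
                 sse = best_sse, series = data.frame(year = years, value = y)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> ", nrow(x$segments), " segments, SSE ",
      signif(x$sse, 5), "\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' @export
plot.segmentation <- function(x, ...) {
  s <- x$series
  graphics::plot(s$year, s$value, type = "b", xlab = "year", ylab = "value", ...)
  for (i in seq_len(nrow(x$segments))) {
    seg <- x$segments[i, ]
    xs <- seg$start_year:seg$end_year
    graphics::lines(xs, seg$intercept + seg$slope * xs, col = 2, lwd = 2)
  }
  if (length(x$breaks))
    graphics::abline(v = x$breaks + 0.5, lty = 3, col = "grey40")
  invisible(x)
}

# --- empirical mode decomposition -----------------------------------------

# indices of strict local maxima/minima of a series
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  s <- sign(d)
  # collapse flats: carry previous sign over zero runs
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  ds <- diff(s)
  list(max = which(ds < 0) + 1L, min = which(ds > 0) + 1L)
}

# cubic-spline envelope through extrema, mirror-extended at the ends
.envelope <- function(idx, val, n) {
  k <- length(idx)
  # mirror up to 2 end extrema about the series boundaries
  m <- min(2L, k)
  li <- 2L - rev(idx[seq_len(m)])
  lv <- rev(val[seq_len(m)])
  rsel <- k - seq_len(m) + 1L
  ri <- 2L * n - idx[rsel]
  rv <- val[rsel]
  xs <- c(li, idx, ri); ys <- c(lv, val, rv)
  o <- order(xs); xs <- xs[o]; ys <- ys[o]
  keep <- !duplicated(xs)
  f <- stats::splinefun(xs[keep], ys[keep], method = "fmm")
  f(seq_len(n))
}

#' Empirical mode decomposition (single realization)
#'
#' Standard sifting: cubic-spline envelopes through the local maxima and
#' minima (mirror-extended at the boundaries), subtract the envelope mean,
#' and stop sifting a component when the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2)` drops below `sd_tol` (or after
#' `max_sift` iterations). Components are extracted until the residual is
#' monotone or has fewer than 3 extrema. The components plus residual
#' reconstruct the input exactly (the residual is defined by subtraction).
#'
#' @param signal Numeric series (length >= 8).
#' @param sd_tol Cauchy sifting tolerance (default 0.2).
#' @param max_sift Maximum sifting iterations per component.
#' @param max_imf Maximum number of components.
#' @return Object of class `imf_set`: list with matrix `imfs` (one column
#'   per component; zero columns allowed), `residual`, `signal`.
#' @export
emd <- function(signal, sd_tol = 0.2, max_sift = 100L, max_imf = 10L) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 8L) stop("signal too short (need >= 8)")
  imfs <- NULL
  res <- x
  for (k in seq_len(max_imf)) {
    ex <- .local_extrema(res)
    if (length(ex$max) + length(ex$min) < 3L) break
    h <- res
    for (it in seq_len(max_sift)) {
      e <- .local_extrema(h)
      if (length(e$max) < 2L || length(e$min) < 2L) break
      up <- .envelope(e$max, h[e$max], n)
      lo <- .envelope(e$min, h[e$min], n)
      m <- (up + lo) / 2
      h1 <- h - m
      crit <- sum((h - h1)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h1
      if (crit < sd_tol) break
    }
    imfs <- cbind(imfs, h)
    res <- res - h
  }
  if (is.null(imfs)) imfs <- matrix(numeric(0), nrow = n, ncol = 0L)
  colnames(imfs) <- if (ncol(imfs)) paste0("IMF", seq_len(ncol(imfs))) else character(0)
  structure(list(imfs = imfs, residual = res, signal = x), class = "imf_set")
}

#' Ensemble empirical mode decomposition
#'
#' Averages [emd()] over an ensemble of white-noise-perturbed copies of the
#' signal (noise sd = `noise_sd_frac` x sd(signal)). Component counts are
#' aligned by zero-padding to the ensemble maximum. With
#' `noise_sd_frac = 0` the result equals a single [emd()]. The ensemble
#' mean reconstructs the input up to the averaged noise, whose amplitude
#' shrinks like `noise_sd / sqrt(ensemble_size)`.
#'
#' @param signal Numeric series.
#' @param ensemble_size Number of noise realizations (>= 2; 100 by default).
#' @param noise_sd_frac Noise sd as a fraction of the signal sd (>= 0).
#' @param seed Integer seed.
#' @inheritParams emd
#' @return An `imf_set` (see [emd()]).
#' @export
eemd <- function(signal, ensemble_size = 100L, noise_sd_frac = 0.2, seed = 1L,
                 sd_tol = 0.2, max_sift = 100L, max_imf = 10L) {
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  if (noise_sd_frac == 0) return(emd(signal, sd_tol, max_sift, max_imf))
  if (ensemble_size < 2L) stop("ensemble_size must be >= 2")
  x <- as.numeric(signal); n <- length(x)
  nsd <- noise_sd_frac * stats::sd(x)
  set.seed(seed)
  runs <- vector("list", ensemble_size)
  for (r in seq_len(ensemble_size))
    runs[[r]] <- emd(x + stats::rnorm(n, 0, nsd), sd_tol, max_sift, max_imf)
  kmax <- max(vapply(runs, function(d) ncol(d$imfs), 0L))
  imfs <- matrix(0, n, kmax)
  res <- numeric(n)
  for (r in runs) {
    k <- ncol(r$imfs)
    if (k) imfs[, seq_len(k)] <- imfs[, seq_len(k)] + r$imfs
    res <- res + r$residual
  }
  imfs <- imfs / ensemble_size
  res <- res / ensemble_size
  if (kmax) colnames(imfs) <- paste0("IMF", seq_len(kmax))
  structure(list(imfs = imfs, residual = res, signal = x), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", ncol(x$imfs), " IMF(s) + residual, length ",
      length(x$signal), "\n", sep = "")
  if (ncol(x$imfs)) {
    vc <- variance_contribution(x)
    per <- vapply(seq_len(ncol(x$imfs)),
                  function(k) mean_period(x$imfs[, k]), numeric(1))
    print(data.frame(component = c(colnames(x$imfs), "Res"),
                     period_years = c(round(per, 1), NA),
                     variance_pct = round(vc, 2)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.imf_set <- function(x, ...) {
  k <- ncol(x$imfs)
  op <- graphics::par(mfrow = c(k + 2L, 1L), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$signal, type = "l", ylab = "signal", ...)
  for (i in seq_len(k))
    graphics::plot(x$imfs[, i], type = "l", ylab = colnames(x$imfs)[i])
  graphics::plot(x$residual, type = "l", ylab = "Res", col = 2)
  invisible(x)
}

#' Variance contribution rate of each component
#'
#' Variance of each IMF and of the residual as a percentage of the summed
#' component variances; the shares add to 100.
#'
#' @param imfset An `imf_set`.
#' @return Named numeric vector of percentages (IMF1..IMFk, Res).
#' @export
variance_contribution <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  comps <- cbind(imfset$imfs, Res = imfset$residual)
  v <- apply(comps, 2L, stats::var)
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance")
  100 * v / tot
}

#' Mean period of an oscillatory component
#'
#' Series length (in years) divided by the number of local maxima.
#'
#' @param imf Numeric component series.
#' @return Mean period in years, or `NA` (with a warning) when the component
#'   has no local maximum.
#' @export
mean_period <- function(imf) {
  npk <- length(.local_extrema(imf)$max)
  if (npk == 0L) { warning("component has no local maxima"); return(NA_real_) }
  length(imf) / npk
}
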