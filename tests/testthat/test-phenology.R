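test_that("NDVI arithmetic and degenerate reflectances behave", {
  expect_equal(compute_ndvi(0.3, 0.1), 0.5)
  expect_equal(compute_ndvi(0.2, 0.2), 0)
  expect_true(is.na(compute_ndvi(0, 0)))
  expect_error(compute_ndvi(matrix(0.1, 2, 2), matrix(0.1, 2, 3)), "shape")
  expect_error(compute_ndvi(1.2, 0.1), "\\[0, 1\\]")
})

test_that("key-point detection equals the brute-force scan oracle on random series", {
  doys <- seq(65L, 225L, by = 8L)
  set.seed(100)
  for (rep in 1:300) {
    n <- sample(5:21, 1)
    # coarse rounding induces plenty of ties
    x <- round(runif(n), sample(1:2, 1))
    d <- doys[seq_len(n)]
    got <- detect_key_points(x, d)
    want <- oracle_key_points(x, d)
    if (is.null(want)) {
      expect_true(got$status %in% c("degenerate", "no_phenology"))
    } else {
      expect_equal(got$status, "ok")
      expect_equal(got[c("doy_c", "doy_a", "doy_b")],
                   want[c("doy_c", "doy_a", "doy_b")])
      expect_equal(got[c("ndvi_c", "ndvi_a", "ndvi_b")],
                   want[c("ndvi_c", "ndvi_a", "ndvi_b")])
    }
  }
})

test_that("flat, monotone and missing series are flagged, not mis-detected", {
  doys <- seq(65L, 225L, by = 8L)
  expect_equal(detect_key_points(rep(0.2, 21), doys)$status, "degenerate")
  expect_equal(detect_key_points(seq(0, 1, length.out = 21), doys)$status,
               "degenerate")
  expect_equal(detect_key_points(rep(NA_real_, 21), doys)$status,
               "no_phenology")
  expect_equal(detect_key_points(c(0.1, 0.2, NA, NA, NA, NA, rep(NA, 15)),
                                 doys)$status, "no_phenology")
})

test_that("vectorized cube extraction agrees with the per-series function", {
  sc <- scene_config(8L, 8L, years = 2001:2004, seed = 21L)
  cube <- gen_ndvi_cube(sc, phenology_preset(noise_sd = 0.05))
  kp <- extract_key_points(cube)
  for (i in c(1L, 5L, 8L)) for (j in c(2L, 8L)) for (y in 1:4) {
    one <- detect_key_points(cube$values[i, j, y, ], cube$composite_days)
    expect_equal(kp$status[i, j, y], one$status)
    if (one$status == "ok") {
      expect_equal(kp$doy_a[i, j, y], one$doy_a)
      expect_equal(kp$doy_b[i, j, y], one$doy_b)
      expect_equal(kp$doy_c[i, j, y], one$doy_c)
    }
  }
})

test_that("the life-cycle increment is the rise plus the decline", {
  mk <- function(c, a, b) {
    x <- structure(list(doy_c = 89L, ndvi_c = c, doy_a = 137L, ndvi_a = a,
                        doy_b = 161L, ndvi_b = b, status = "ok"),
                   class = "pheno_keypoints")
    x
  }
  expect_equal(ephemeral_increment(mk(0.1, 0.5, 0.2)), 0.7)
  expect_equal(ephemeral_increment(mk(0.0, 0.3, 0.1)), 0.5)
  expect_equal(ephemeral_increment(mk(0.2, 0.2, 0.2)), 0)
  flat <- detect_key_points(rep(0.2, 21), seq(65, 225, by = 8))
  expect_true(is.na(ephemeral_increment(flat)))
})

test_that("the distribution mask thresholds the multi-year mean decline", {
  mk_eph <- function(mmd) {
    structure(list(eph = array(mmd, c(dim(mmd), 1)),
                   decline = array(mmd, c(dim(mmd), 1)),
                   multiyear_mean_decline = mmd, years = 2001L,
                   geometry = list(rows = nrow(mmd), cols = ncol(mmd),
                                   cell_size_km = 1, origin = c(0, 0))),
              class = "eph_map")
  }
  same <- mk_eph(matrix(0.3, 5, 5))
  expect_equal(sum(build_distribution_mask(same)$mask), 0)
  one <- matrix(0, 5, 5); one[2, 3] <- 1
  m1 <- build_distribution_mask(mk_eph(one))
  expect_identical(which(m1$mask), which(one == 1))
  set.seed(8)
  rnd <- matrix(runif(100), 10, 10)
  got <- build_distribution_mask(mk_eph(rnd))
  expect_identical(got$mask, rnd > mean(rnd))
  # monotonicity: raising the threshold never adds pixels
  ths <- sort(runif(5))
  masks <- lapply(ths, function(t)
    build_distribution_mask(mk_eph(rnd), threshold = t)$mask)
  for (i in 2:5) expect_true(all(masks[[i]] <= masks[[i - 1]]))
  # per-pixel self-threshold mode runs and returns a logical mask
  pp <- build_distribution_mask(mk_eph(rnd), mode = "per_pixel")
  expect_type(pp$mask, "logical")
  expect_equal(dim(pp$mask), dim(rnd))
})

test_that("natural-breaks classes are the exact dynamic-programming optimum", {
  jb <- jenks_breaks(c(1, 1, 1, 5, 5, 5, 9, 9, 9), 3)
  expect_equal(jb$objective, 0)
  expect_equal(jb$assign_fun(c(1, 5, 9)), c(1, 2, 3))
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    x <- round(runif(n, 0, 10), 2)
    if (length(unique(x)) < k) next
    expect_equal(jenks_breaks(x, k)$objective, oracle_jenks_objective(x, k),
                 tolerance = 1e-10)
  }
  expect_equal(jenks_breaks(c(2, 4, 7, 9), 4)$objective, 0)
  expect_error(jenks_breaks(1:10, 1), "k must be")
})

test_that("vigor classification matches the published cutpoints and is total", {
  v <- matrix(c(0.20, 0.16, 0.10, 0.19, 0.1564, 0.1878), 2, 3)
  cm <- classify_ndvi(v)
  expect_equal(as.character(cm$labels[1, 1]), "Medium")
  expect_equal(as.character(cm$labels[2, 1]), "Less")
  expect_equal(as.character(cm$labels[1, 2]), "Sparse")
  expect_equal(as.character(cm$labels[2, 2]), "Medium")   # strictly above
  expect_equal(as.character(cm$labels[1, 3]), "Sparse")   # at lower cut
  expect_equal(as.character(cm$labels[2, 3]), "Less")     # at upper cut
  set.seed(5)
  vals <- matrix(runif(64, 0, 0.4), 8, 8)
  mask <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE), 8, 8)
  cm2 <- classify_ndvi(vals, mask)
  expect_equal(sum(cm2$codes > 0), sum(mask))
  expect_true(all(cm2$codes[!mask] == 0))
  expect_error(classify_ndvi(vals, mask, thresholds = c(0.3, 0.1)),
               "increasing")
})

test_that("jenks-mode classification recomputes the cutpoints from the data", {
  set.seed(9)
  vals <- matrix(c(rnorm(40, 0.1, 0.005), rnorm(40, 0.2, 0.005),
                   rnorm(20, 0.32, 0.005)), 10, 10)
  cm <- classify_ndvi(vals, method = "jenks")
  expect_equal(unname(table(cm$labels)[c("Sparse", "Less", "Medium")]),
               c(40L, 40L, 20L), ignore_attr = TRUE)
})

test_that("occurrence validation reports per-family and overall accuracy", {
  m <- half_mask(10L, 10L)
  occ <- occurrences_from_counts(
    m, data.frame(family = c("A", "B", "C"), n = c(4L, 3L, 3L),
                  inside = c(4L, 2L, 0L)))
  acc <- validate_occurrences(m, occ)
  expect_equal(acc$family, c("A", "B", "C", "Sum"))
  expect_equal(acc$accuracy_pct, c(100, 66.67, 0, 60))
  # off-grid points count as outside, with a warning
  occ2 <- rbind(occ, data.frame(x = -5, y = -5, family = "A"))
  expect_warning(acc2 <- validate_occurrences(m, occ2), "off-grid")
  expect_equal(acc2$inside[acc2$family == "A"], 4L)
  expect_equal(acc2$n[acc2$family == "A"], 5L)
  expect_equal(attr(acc2, "off_grid"), 1L)
})
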