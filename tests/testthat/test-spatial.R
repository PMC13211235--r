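mk_class_map <- function(codes, cell = 1) {
  structure(list(labels = NULL, codes = codes,
                 thresholds = c(0.1564, 0.1878),
                 geometry = list(rows = nrow(codes), cols = ncol(codes),
                                 cell_size_km = cell, origin = c(0, 0))),
            class = "class_map")
}

test_that("identical maps give a purely diagonal transition matrix", {
  set.seed(3)
  codes <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  cm <- mk_class_map(codes)
  tm <- transition_matrix(cm, cm, cell_area_km2 = 2)
  expect_equal(sum(tm$area) , sum(codes > 0) * 2)
  expect_equal(tm$area[upper.tri(tm$area)], rep(0, 3))
  expect_equal(tm$area[lower.tri(tm$area)], rep(0, 3))
  expect_error(transition_matrix(cm, mk_class_map(matrix(0L, 5, 5))),
               "grids differ")
})

test_that("transition accounting conserves the jointly classified class areas", {
  set.seed(14)
  for (rep in 1:5) {
    c1 <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    c2 <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    tm <- transition_matrix(mk_class_map(c1), mk_class_map(c2))
    both <- c1 > 0 & c2 > 0
    for (k in 1:3) {
      expect_equal(sum(tm$area[k, ]), sum(c1 == k & both))
      expect_equal(sum(tm$area[, k]), sum(c2 == k & both))
    }
    expect_equal(tm$excluded_km2, sum(!both))
  }
})

test_that("class shares normalize per axis and agree between axes when static", {
  tt <- transfer_tables()
  tm <- as_transition_matrix(tt$P1_P2)
  src <- vapply(c("Sparse", "Less", "Medium"),
                function(k) class_share(tm, k, "source"), numeric(1))
  dst <- vapply(c("Sparse", "Less", "Medium"),
                function(k) class_share(tm, k, "destination"), numeric(1))
  expect_equal(sum(src), 100)
  expect_equal(sum(dst), 100)
  diag_tm <- as_transition_matrix(diag(c(10, 20, 30)))
  for (k in c("Sparse", "Less", "Medium"))
    expect_equal(class_share(diag_tm, k, "source"),
                 class_share(diag_tm, k, "destination"))
  expect_error(class_share(as_transition_matrix(matrix(0, 3, 3)), "Less"),
               "zero total")
})

test_that("centroid shift matches hand geometry and a brute-force oracle", {
  g <- list(rows = 5, cols = 5, cell_size_km = 1, origin = c(0, 0))
  w <- matrix(0, 5, 5); w[3, 2] <- 1
  w2 <- matrix(0, 5, 5); w2[3, 3] <- 1
  cs <- centroid_shift(w, w2, g)
  expect_equal(cs$distance_km, 1)
  expect_equal(cs$bearing_deg, 90)
  expect_equal(centroid_shift(w, w, g)$distance_km, 0)
  # one cell north
  w3 <- matrix(0, 5, 5); w3[2, 2] <- 1
  expect_equal(centroid_shift(w, w3, g)$bearing_deg, 0)
  set.seed(23)
  a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
  got <- centroid_shift(a, b, g)
  # brute-force weighted means over explicit cell centers
  xs <- (col(a) - 0.5); ys <- (5 - row(a) + 0.5)
  c1 <- c(sum(a * xs), sum(a * ys)) / sum(a)
  c2 <- c(sum(b * xs), sum(b * ys)) / sum(b)
  expect_equal(unname(got$centroid1), c1)
  expect_equal(unname(got$distance_km), sqrt(sum((c2 - c1)^2)))
  expect_error(centroid_shift(a * 0, b, g), "all-zero")
})

test_that("the centroid of combined weights lies between the component centroids", {
  g <- list(rows = 8, cols = 8, cell_size_km = 1, origin = c(0, 0))
  set.seed(4)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  ca <- centroid_shift(a, a, g)$centroid1
  cb <- centroid_shift(b, b, g)$centroid1
  cu <- centroid_shift(a + b, a + b, g)$centroid1
  lam <- sum(a) / (sum(a) + sum(b))
  expect_equal(unname(cu), unname(lam * ca + (1 - lam) * cb))
})

test_that("centroid tracking follows a moving class across periods", {
  mk <- function(col0) {
    codes <- matrix(1L, 6, 6)
    codes[, col0] <- 3L
    mk_class_map(codes)
  }
  tr <- centroid_track(list(P1 = mk(2), P2 = mk(4)), "Medium")
  expect_equal(tr$dist_km[2], 2)
  expect_equal(tr$bearing_deg[2], 90)
})

test_that("CV maps use the sample standard deviation and flag zero means", {
  st <- array(0, c(2, 2, 3))
  st[1, 1, ] <- 5                 # constant
  st[1, 2, ] <- c(1, 3, 2)
  st[2, 1, ] <- c(-1, 1, 0)       # mean zero
  st[2, 2, ] <- c(2, 6, 4)
  cv <- cv_map(st)
  expect_equal(cv[1, 1], 0)
  expect_equal(cv[1, 2], sd(c(1, 3, 2)) / 2)
  expect_true(is.na(cv[2, 1]))
  expect_equal(cv[2, 2], cv[1, 2])          # scale invariance
  two <- array(c(1, 3), c(1, 1, 2))
  expect_error(cv_map(two), ">= 3 years")
})
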