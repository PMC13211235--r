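test_that("segmentation recovers constructed breakpoints exactly at zero noise", {
  years <- 2001:2022
  y <- numeric(22)
  y[1:7] <- 0.10 + 0.004 * (1:7)            # P1: rise
  y[8:12] <- 0.16 - 0.006 * (1:5)           # P2: fall from a jump
  y[13:15] <- 0.21 + 0.010 * (1:3)          # P3: steep rise
  y[16:22] <- 0.14 + 0.002 * (1:7)          # P4: slow rise
  seg <- piecewise_segments(data.frame(year = years, value = y), n_breaks = 3)
  expect_equal(seg$breaks, c(2007, 2012, 2015))
  expect_equal(seg$segments$segment, paste0("P", 1:4))
  expect_equal(seg$segments$slope, c(0.004, -0.006, 0.010, 0.002),
               tolerance = 1e-10)
})

test_that("unsegmented fits match closed-form least squares", {
  years <- 2001:2010
  y <- 0.3 + 0.02 * (years - 2000)
  seg <- piecewise_segments(data.frame(year = years, value = y), n_breaks = 0)
  expect_equal(seg$segments$slope, 0.02, tolerance = 1e-12)
  flat <- piecewise_segments(data.frame(year = years, value = rep(1, 10)),
                             n_breaks = 2, min_len = 3)
  expect_true(all(abs(flat$segments$slope) < 1e-12))
  expect_error(piecewise_segments(data.frame(year = 2001:2005,
                                             value = rnorm(5)),
                                  n_breaks = 3), "too short")
})

test_that("segmentation minimizes SSE over an independent lm() enumeration", {
  set.seed(31)
  years <- 2001:2016
  y <- cumsum(rnorm(16, 0, 0.05))
  seg <- piecewise_segments(data.frame(year = years, value = y),
                            n_breaks = 2, min_len = 3)
  # oracle: brute force with lm()
  best <- Inf
  for (b1 in 3:10) for (b2 in (b1 + 3):13) {
    bounds <- c(0, b1, b2, 16)
    tot <- 0
    for (s in 1:3) {
      i <- (bounds[s] + 1):bounds[s + 1]
      tot <- tot + sum(resid(lm(y[i] ~ years[i]))^2)
    }
    best <- min(best, tot)
  }
  expect_equal(seg$sse, best, tolerance = 1e-10)
})

test_that("EMD reconstructs its input exactly and handles degenerate signals", {
  set.seed(12)
  for (x in list(rnorm(22), sin(2 * pi * (1:64) / 7) + 0.1 * (1:64),
                 cumsum(rnorm(40)))) {
    d <- emd(x)
    recon <- if (ncol(d$imfs)) rowSums(d$imfs) + d$residual else d$residual
    expect_lt(max(abs(x - recon)), 1e-9)
  }
  ramp <- seq(0, 1, length.out = 20)
  dr <- emd(ramp)
  expect_equal(ncol(dr$imfs), 0L)
  expect_equal(dr$residual, ramp)
  dc <- emd(rep(2, 20))
  expect_equal(ncol(dc$imfs), 0L)
})

test_that("a pure sinusoid yields one dominant mode and a small residual", {
  t <- 1:60
  x <- sin(2 * pi * t / 20)   # 3 full cycles
  d <- emd(x)
  expect_gte(ncol(d$imfs), 1L)
  vc <- variance_contribution(d)
  expect_gt(vc[1], 90)
  expect_lt(max(abs(d$residual - mean(d$residual))), 0.05)
})

test_that("ensemble decomposition is seeded and collapses to EMD at zero noise", {
  x <- sin(2 * pi * (1:32) / 4) + 0.5 * sin(2 * pi * (1:32) / 16)
  expect_identical(eemd(x, 10, 0, seed = 1), emd(x))
  e1 <- eemd(x, 10, 0.2, seed = 4)
  e2 <- eemd(x, 10, 0.2, seed = 4)
  expect_identical(e1, e2)
  expect_false(identical(e1, eemd(x, 10, 0.2, seed = 5)))
  expect_error(eemd(x, 10, -0.1), "noise_sd_frac")
})

test_that("EEMD reconstruction error shrinks as the ensemble grows", {
  set.seed(2)
  x <- sin(2 * pi * (1:48) / 6) + 0.3 * (1:48) / 48 + rnorm(48, 0, 0.05)
  err <- vapply(c(5L, 40L, 320L), function(m) {
    d <- eemd(x, m, 0.2, seed = 9)
    max(abs(x - rowSums(d$imfs) - d$residual))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("mode periods are detected from the two-tone construction", {
  t <- 1:64
  x <- sin(2 * pi * t / 4) + sin(2 * pi * t / 16)
  d <- eemd(x, 50, 0.1, seed = 3)
  p1 <- mean_period(d$imfs[, 1])
  expect_gte(p1, 3); expect_lte(p1, 5)
})

test_that("variance contributions normalize, split evenly and are scale-invariant", {
  t <- 1:64
  s1 <- sin(2 * pi * t / 4); s2 <- cos(2 * pi * t / 16)
  fake <- structure(list(imfs = cbind(IMF1 = s1), residual = s2,
                         signal = s1 + s2), class = "imf_set")
  vc <- variance_contribution(fake)
  expect_equal(sum(vc), 100, tolerance = 0.05)
  expect_equal(unname(vc[1]), 50, tolerance = 1)
  fake10 <- structure(list(imfs = cbind(IMF1 = 10 * s1), residual = 10 * s2,
                           signal = 10 * (s1 + s2)), class = "imf_set")
  expect_equal(variance_contribution(fake10), vc)
  zero <- structure(list(imfs = cbind(IMF1 = rep(0, 8)),
                         residual = rep(0, 8), signal = rep(0, 8)),
                    class = "imf_set")
  expect_error(variance_contribution(zero), "zero total variance")
})

test_that("mean period equals series length over the peak count", {
  expect_equal(mean_period(cos(2 * pi * ((1:21) - 2) / 3)), 3)  # 7 peaks
  expect_equal(mean_period(cos(2 * pi * ((1:16) - 2) / 4)), 4)  # 4 peaks
  set.seed(44)
  for (rep in 1:20) {
    x <- rnorm(30)
    npk <- sum(diff(sign(diff(x))) < 0)   # independent strict peak count
    if (npk == 0) next
    expect_equal(mean_period(x), 30 / npk)
  }
  expect_warning(mean_period(1:10), "no local maxima")
})
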