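test_that("the driver table pairs the period response with env rasters", {
  sc <- tiny_scene(12L, 12L, years = 2001:2008, seed = 6L)
  env <- gen_env_rasters(sc)
  cube <- gen_ndvi_cube(sc, phenology_preset(noise_sd = 0), env)
  eph <- ephemeral_ndvi_map(cube)
  mask <- build_distribution_mask(eph)
  dt <- build_driver_table(eph, env, mask)
  expect_equal(nrow(dt), sum(mask$mask))
  expect_equal(names(dt)[1], "NDVIeph")
  cats <- attr(dt, "categories")
  expect_equal(sort(unique(unname(cats))),
               c("precipitation", "snow", "temperature", "topography"))
  expect_equal(length(cats), ncol(dt) - 1L)
  # subsetting years changes the response
  dt2 <- build_driver_table(eph, env, mask, years = 2001:2004)
  expect_false(isTRUE(all.equal(dt$NDVIeph, dt2$NDVIeph)))
})

test_that("random-forest importances normalize and find the generating variable", {
  sc <- tiny_scene(16L, 16L, seed = 8L)
  env <- gen_env_rasters(sc)
  dt <- data.frame(NDVIeph = as.vector(env$historical$Snowend))
  for (v in env$spec$variable) dt[[v]] <- as.vector(env$historical[[v]])
  attr(dt, "categories") <- stats::setNames(env$spec$category,
                                            env$spec$variable)
  # full candidate set per split: the identification setting for a
  # single-generating-variable construction
  imp <- rf_group_importance(dt, n_trees = 300, seed = 2,
                             mtry = ncol(dt) - 1L)
  expect_equal(sum(imp$variable$importance_pct), 100, tolerance = 0.01)
  expect_equal(sum(imp$category$contribution_pct), 100, tolerance = 0.01)
  snow <- imp$category$contribution_pct[imp$category$category == "snow"]
  expect_gt(snow, 90)
  imp2 <- rf_group_importance(dt, n_trees = 300, seed = 2,
                              mtry = ncol(dt) - 1L)
  expect_identical(imp$variable, imp2$variable)
  dt$NDVIeph <- 1
  expect_error(rf_group_importance(dt, n_trees = 50, seed = 1),
               "constant response")
})

test_that("correlation matrices match the textbook formula", {
  x <- 1:10
  expect_equal(pearson_matrix(data.frame(x = x, y = 2 * x))$r["x", "y"], 1)
  expect_equal(pearson_matrix(data.frame(x = x, y = -x))$r["x", "y"], -1)
  set.seed(19)
  df <- as.data.frame(matrix(rnorm(30), 10, 3))
  pm <- pearson_matrix(df)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    xi <- df[[i]]; xj <- df[[j]]
    r_direct <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(pm$r[i, j], r_direct)
    expect_equal(pm$p[i, j], cor.test(xi, xj)$p.value)
  }
  dfz <- data.frame(a = rnorm(10), z = rep(1, 10))
  pz <- pearson_matrix(dfz)
  expect_true(is.na(pz$r["a", "z"]))
})

test_that("effect decomposition matches hand computation and a path-enumeration oracle", {
  B <- matrix(0, 3, 3, dimnames = list(c("a", "b", "y"), c("a", "b", "y")))
  B["a", "b"] <- 0.5; B["b", "y"] <- 0.4; B["a", "y"] <- 0.1
  ef <- effect_decomposition(B)
  expect_equal(ef$indirect["a", "y"], 0.2)
  expect_equal(ef$total["a", "y"], 0.3)
  expect_equal(ef$indirect["b", "y"], 0)
  set.seed(27)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    M <- matrix(0, k, k)
    M[upper.tri(M)] <- round(runif(k * (k - 1) / 2, -1, 1), 2) *
      rbinom(k * (k - 1) / 2, 1, 0.7)
    tot <- effect_decomposition(M)$total
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      expect_equal(tot[i, j], oracle_total_effect(M, i, j), tolerance = 1e-12)
  }
  cyc <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(effect_decomposition(cyc), "cyclic")
})

test_that("PLS-PM with single-indicator blocks equals closed-form path analysis", {
  set.seed(51)
  n <- 400
  a <- rnorm(n)
  b <- 0.5 * a + rnorm(n, 0, sqrt(0.75))
  y <- 0.4 * b + 0.1 * a + rnorm(n, 0, 0.6)
  df <- data.frame(a = a, b = b, y = y)
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "y"), c("a", "b", "y")))
  A["a", "b"] <- 1; A["b", "y"] <- 1; A["a", "y"] <- 1
  fit <- plspm_fit(df, list(a = "a", b = "b", y = "y"), A, boot = 0)
  expect_true(fit$converged)
  zs <- scale(df)
  cf_y <- coef(lm(zs[, "y"] ~ zs[, "a"] + zs[, "b"] - 1))
  cf_b <- coef(lm(zs[, "b"] ~ zs[, "a"] - 1))
  expect_equal(unname(fit$path_matrix["a", "y"]), unname(cf_y[1]),
               tolerance = 1e-6)
  expect_equal(unname(fit$path_matrix["b", "y"]), unname(cf_y[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit$path_matrix["a", "b"]), unname(cf_b),
               tolerance = 1e-6)
  # single-indicator blocks: communality 1, GoF = sqrt(mean R^2)
  expect_equal(fit$gof, sqrt(mean(fit$r2[c("b", "y")])), tolerance = 1e-6)
})

test_that("PLS-PM recovers generating chain effects within sampling error", {
  set.seed(77)
  n <- 2000
  a <- rnorm(n)
  b <- 0.5 * a + rnorm(n, 0, sqrt(1 - 0.25))
  y <- 0.4 * b + rnorm(n, 0, sqrt(1 - 0.16))
  df <- data.frame(a = a, b = b, y = y)
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "y"), c("a", "b", "y")))
  A["a", "b"] <- 1; A["b", "y"] <- 1; A["a", "y"] <- 1
  fit <- plspm_fit(df, list(a = "a", b = "b", y = "y"), A, boot = 100,
                   seed = 3)
  ind_a <- fit$effects$indirect[fit$effects$latent == "a"]
  expect_equal(ind_a, 0.2, tolerance = 0.05)
  # the strong b -> y path is bootstrap-significant, and p-values exist
  bt <- fit$boot
  expect_lt(bt$p_value[bt$from == "b" & bt$to == "y"], 0.01)
})

test_that("independent blocks produce near-zero path coefficients", {
  set.seed(88)
  n <- 600
  df <- data.frame(a = rnorm(n), b = rnorm(n), y = rnorm(n))
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "y"), c("a", "b", "y")))
  A["a", "y"] <- 1; A["b", "y"] <- 1
  fit <- plspm_fit(df, list(a = "a", b = "b", y = "y"), A, boot = 0)
  expect_true(all(abs(fit$path_matrix[A == 1]) < 3 / sqrt(n)))
})

test_that("multi-indicator blocks carry generating signs through total effects", {
  set.seed(31)
  n <- 800
  snow_f <- rnorm(n); temp_f <- rnorm(n)
  df <- data.frame(
    Snowday = snow_f + rnorm(n, 0, 0.4),
    Snowend = snow_f + rnorm(n, 0, 0.4),
    Temp_AU = temp_f + rnorm(n, 0, 0.4),
    Temp_GS = temp_f + rnorm(n, 0, 0.4))
  df$NDVIeph <- 0.5 * snow_f - 0.4 * temp_f + rnorm(n, 0, 0.5)
  A <- matrix(0, 3, 3, dimnames = list(c("snow", "temperature", "NDVI"),
                                       c("snow", "temperature", "NDVI")))
  A["snow", "NDVI"] <- 1; A["temperature", "NDVI"] <- 1
  fit <- plspm_fit(df, list(snow = c("Snowday", "Snowend"),
                            temperature = c("Temp_AU", "Temp_GS"),
                            NDVI = "NDVIeph"), A, boot = 0)
  ef <- fit$effects
  expect_gt(ef$total[ef$latent == "snow"], 0)
  expect_lt(ef$total[ef$latent == "temperature"], 0)
  expect_true(all(fit$loadings$snow > 0.7))
  expect_error(plspm_fit(df, list(snow = "Snowday", NDVI = "NDVIeph"),
                         matrix(c(0, 1, 1, 0), 2, 2,
                                dimnames = list(c("snow", "NDVI"),
                                                c("snow", "NDVI")))),
               "cyclic")
})
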