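#' Pixel-level driver table
#'
#' Assembles the modeling table for driver analysis: one row per masked
#' pixel, the period-mean ephemeral NDVI increment as response, and the
#' environmental rasters as predictors. The variable -> factor-category map
#' is attached as attribute `categories`.
#'
#' @param eph An `eph_map`.
#' @param env Result of [gen_env_rasters()] (or a named list of matrices,
#'   with `categories` supplied).
#' @param mask Optional `dist_mask` restricting rows.
#' @param years Optional subset of years for the period mean (values of
#'   `eph$years`); default all.
#' @param aspect_as_northness Encode the circular `Aspect` variable as
#'   northness `cos(aspect * pi / 180)` (default TRUE).
#' @param categories Named character vector variable -> category, required
#'   when `env` is a plain list.
#' @return data.frame with column `NDVIeph` plus one column per variable;
#'   attribute `categories`.
#' @export
build_driver_table <- function(eph, env, mask = NULL, years = NULL,
                               aspect_as_northness = TRUE, categories = NULL) {
  stopifnot(inherits(eph, "eph_map"))
  if (is.list(env) && !is.null(env$historical)) {
    rasters <- env$historical
    categories <- stats::setNames(env$spec$category, env$spec$variable)
  } else {
    rasters <- env
    if (is.null(categories)) stop("categories required for a plain raster list")
  }
  sel <- if (is.null(years)) seq_along(eph$years) else match(years, eph$years)
  if (anyNA(sel)) stop("unknown years requested")
  resp <- apply(eph$eph[, , sel, drop = FALSE], c(1L, 2L), mean, na.rm = TRUE)
  keep <- is.finite(resp)
  if (inherits(mask, "dist_mask")) keep <- keep & mask$mask
  else if (is.matrix(mask)) keep <- keep & mask
  df <- data.frame(NDVIeph = resp[keep])
  for (v in names(rasters)) {
    col <- rasters[[v]][keep]
    if (v == "Aspect" && aspect_as_northness) col <- cos(col * pi / 180)
    df[[v]] <- col
  }
  const <- vapply(df, function(c) stats::sd(c) == 0 || !any(is.finite(c)), TRUE)
  if (any(const[-1])) {
    warning("dropping constant columns: ",
            paste(names(df)[-1][const[-1]], collapse = ", "))
    df <- df[, !const | names(df) == "NDVIeph", drop = FALSE]
  }
  attr(df, "categories") <- categories[names(df)[-1]]
  df
}

#' Grouped random-forest importance of environmental drivers
#'
#' Fits a random forest regression of the response on all environmental
#' variables and reports per-variable Gini (node-impurity) importance
#' normalized to sum to 100%, plus per-category contributions obtained by
#' summing member variables.
#'
#' @param table Driver table from [build_driver_table()] (or any data.frame
#'   with a `categories` attribute / `categories` argument).
#' @param response Response column name (default `"NDVIeph"`).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @param mtry Number of candidate variables per split; default one third of
#'   the predictors (regression-forest convention). Feature subsampling
#'   spreads impurity credit across competing variables by design; use
#'   `mtry = ncol(table) - 1` when the goal is to identify a single
#'   generating variable rather than to average over an ensemble.
#' @param categories Named character vector variable -> category (defaults
#'   to the table attribute).
#' @return Object of class `rf_importance`: list with `variable`
#'   (data.frame: variable, category, importance_pct) and `category`
#'   (data.frame: category, contribution_pct), plus the fitted forest.
#' @export
rf_group_importance <- function(table, response = "NDVIeph", n_trees = 500L,
                                seed = 1L, mtry = NULL, categories = NULL) {
  if (is.null(categories)) categories <- attr(table, "categories")
  if (is.null(categories)) stop("no variable -> category map available")
  if (nrow(table) < 50L) stop("need at least 50 rows")
  y <- table[[response]]
  if (stats::sd(y) == 0) stop("constant response")
  xv <- setdiff(names(table), response)
  x <- table[, xv, drop = FALSE]
  if (is.null(mtry)) mtry <- max(1L, ceiling(length(xv) / 3))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry, importance = FALSE)
  imp <- fit$importance[, "IncNodePurity"]
  pct <- 100 * imp / sum(imp)
  vt <- data.frame(variable = names(pct),
                   category = unname(categories[names(pct)]),
                   importance_pct = unname(pct), stringsAsFactors = FALSE)
  ct <- stats::aggregate(importance_pct ~ category, vt, sum)
  names(ct)[2] <- "contribution_pct"
  ct <- ct[order(-ct$contribution_pct), ]
  rownames(ct) <- NULL
  structure(list(variable = vt[order(-vt$importance_pct), ],
                 category = ct, forest = fit, seed = seed),
            class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat("<rf_importance> category contributions (%):\n")
  print(x$category, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix with p-values
#'
#' Product-moment correlations between all columns, with two-sided p-values
#' from the t distribution. Zero-variance columns yield flagged (`NA`)
#' entries.
#'
#' @param table Numeric data.frame or matrix (>= 3 rows).
#' @return List with matrices `r` and `p`, and `n`.
#' @export
pearson_matrix <- function(table) {
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 rows")
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

# topological order of an acyclic adjacency matrix (from, to); error on cycle
.topo_order <- function(adj) {
  k <- nrow(adj)
  remaining <- seq_len(k)
  order <- integer(0)
  while (length(remaining)) {
    indeg <- colSums(adj[remaining, remaining, drop = FALSE] != 0)
    src <- remaining[indeg == 0]
    if (!length(src)) stop("inner adjacency is cyclic")
    order <- c(order, src)
    remaining <- setdiff(remaining, src)
  }
  order
}

#' Direct, indirect and total effects from a path-coefficient matrix
#'
#' For an acyclic coefficient matrix `B` (entry `[i, j]` = direct effect of
#' latent i on latent j), the total-effects matrix is
#' `solve(I - B) - I = B + B^2 + ...` (the sum of coefficient products over
#' all directed paths); indirect effects are total minus direct.
#'
#' @param coefs Square numeric matrix of path coefficients (from x to),
#'   acyclic, or a `plspm` fit (its coefficient matrix is used).
#' @return List with matrices `direct`, `indirect`, `total`.
#' @export
effect_decomposition <- function(coefs) {
  if (inherits(coefs, "plspm")) coefs <- coefs$path_matrix
  B <- as.matrix(coefs)
  if (nrow(B) != ncol(B)) stop("coefficient matrix must be square")
  .topo_order(B != 0)  # validates acyclicity
  k <- nrow(B)
  total <- solve(diag(k) - B) - diag(k)
  list(direct = B, indirect = total - B, total = total)
}

#' Partial least squares path modeling (PLS-PM / PLS-SEM)
#'
#' Estimates a structural equation model by partial least squares: latent
#' variables are iteratively estimated by alternating outer approximation
#' (Mode A: outer weights proportional to the correlation of each indicator
#' with the inner estimate) and inner approximation (path weighting scheme:
#' predecessors weighted by their regression coefficients, successors by
#' correlations), until the maximum change in outer weights falls below
#' `tol`. Path coefficients are then the least-squares coefficients of each
#' endogenous latent on its predecessors (all latents standardized), effects
#' are decomposed into direct/indirect/total, the goodness of fit is
#' `sqrt(mean communality x mean R^2)`, and coefficient p-values come from a
#' seeded nonparametric bootstrap.
#'
#' @param data data.frame holding all manifest variables.
#' @param blocks Named list: latent name -> character vector of indicator
#'   columns (reflective blocks).
#' @param path_matrix Square 0/1 adjacency over the latents, entry
#'   `[i, j] = 1` meaning i -> j; must be acyclic with a single sink.
#' @param scheme Inner weighting scheme: `"path"` (default), `"centroid"`
#'   or `"factorial"`.
#' @param max_iter,tol Outer/inner alternation control.
#' @param boot Number of bootstrap resamples for coefficient p-values
#'   (0 disables).
#' @param seed Seed for the bootstrap.
#' @return Object of class `plspm`: latent scores, outer weights and
#'   loadings, `path_matrix` (with coefficients), `effects` (direct /
#'   indirect / total on the sink), `r2`, `gof`, `boot` (coefficient SEs and
#'   p-values), `converged`, `iterations`.
#' @export
plspm_fit <- function(data, blocks, path_matrix,
                      scheme = c("path", "centroid", "factorial"),
                      max_iter = 300L, tol = 1e-6, boot = 200L, seed = 1L) {
  scheme <- match.arg(scheme)
  lat <- names(blocks)
  A <- as.matrix(path_matrix)
  if (is.null(rownames(A))) dimnames(A) <- list(lat, lat)
  A <- A[lat, lat]
  .topo_order(A != 0)
  sinks <- lat[rowSums(A != 0) == 0]
  if (length(sinks) != 1L)
    stop("path matrix must have exactly one sink latent (got: ",
         paste(sinks, collapse = ", "), ")")
  miss <- setdiff(unlist(blocks), names(data))
  if (length(miss)) stop("missing indicators: ", paste(miss, collapse = ", "))

  core <- function(df) {
    n <- nrow(df)
    X <- lapply(blocks, function(v) scale(as.matrix(df[, v, drop = FALSE])))
    w <- lapply(X, function(x) rep(1 / sqrt(ncol(x)), ncol(x)))
    LV <- sapply(seq_along(X), function(b) {
      z <- X[[b]] %*% w[[b]]; as.numeric(scale(z))
    })
    colnames(LV) <- lat
    converged <- FALSE; it <- 0L
    for (it in seq_len(max_iter)) {
      # inner estimation
      E <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
      for (j in seq_along(lat)) {
        preds <- which(A[, j] != 0)   # antecedents of j
        succs <- which(A[j, ] != 0)   # consequents of j
        nb <- c(preds, succs)
        if (!length(nb)) next
        if (scheme == "path") {
          if (length(preds))
            E[preds, j] <- stats::coef(
              stats::lm.fit(LV[, preds, drop = FALSE], LV[, j]))
          if (length(succs))
            E[succs, j] <- stats::cor(LV[, succs, drop = FALSE], LV[, j])
        } else {
          cors <- stats::cor(LV[, nb, drop = FALSE], LV[, j])
          E[nb, j] <- if (scheme == "centroid") sign(cors) else cors
        }
      }
      Z <- LV %*% E
      # guard isolated latents (none in valid models)
      w_new <- vector("list", length(X))
      delta <- 0
      for (b in seq_along(X)) {
        zb <- scale(Z[, b])
        wb <- as.numeric(stats::cor(X[[b]], zb))      # Mode A
        lv <- as.numeric(scale(X[[b]] %*% wb))
        if (sum(stats::cor(X[[b]], lv)) < 0) { wb <- -wb; lv <- -lv }
        delta <- max(delta, max(abs(wb - w[[b]])))
        w_new[[b]] <- wb
        LV[, b] <- lv
      }
      w <- w_new
      if (delta < tol) { converged <- TRUE; break }
    }
    # path coefficients
    B <- A * 0
    r2 <- stats::setNames(rep(NA_real_, length(lat)), lat)
    for (j in seq_along(lat)) {
      preds <- which(A[, j] != 0)
      if (!length(preds)) next
      cf <- stats::coef(stats::lm.fit(LV[, preds, drop = FALSE], LV[, j]))
      B[preds, j] <- cf
      fitted <- LV[, preds, drop = FALSE] %*% cf
      r2[j] <- 1 - sum((LV[, j] - fitted)^2) / sum(LV[, j]^2)
    }
    loadings <- lapply(seq_along(X), function(b)
      as.numeric(stats::cor(X[[b]], LV[, b])))
    names(loadings) <- lat
    list(B = B, r2 = r2, LV = LV, w = w, loadings = loadings,
         converged = converged, iterations = it)
  }

  fit <- core(data)
  if (!fit$converged)
    warning("PLS-PM did not converge in ", max_iter, " iterations")
  comm <- unlist(lapply(fit$loadings, function(l) l^2))
  endo <- !is.na(fit$r2)
  gof <- sqrt(mean(comm) * mean(fit$r2[endo]))
  eff <- effect_decomposition(fit$B)
  sink <- sinks

  boot_out <- NULL
  if (boot > 0) {
    set.seed(seed)
    est <- fit$B[A != 0]
    bs <- matrix(NA_real_, boot, length(est))
    n <- nrow(data)
    for (r in seq_len(boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      br <- tryCatch(core(data[idx, , drop = FALSE]), error = function(e) NULL)
      if (!is.null(br)) bs[r, ] <- br$B[A != 0]
    }
    se <- apply(bs, 2L, stats::sd, na.rm = TRUE)
    pv <- 2 * stats::pnorm(-abs(est / pmax(se, .Machine$double.eps)))
    ij <- which(A != 0, arr.ind = TRUE)
    boot_out <- data.frame(from = lat[ij[, 1]], to = lat[ij[, 2]],
                           estimate = est, se = se, p_value = pv,
                           stringsAsFactors = FALSE)
  }

  structure(list(blocks = blocks, scheme = scheme, path_matrix = fit$B,
                 adjacency = A, scores = fit$LV, outer_weights = fit$w,
                 loadings = fit$loadings, r2 = fit$r2, gof = gof,
                 effects = data.frame(
                   latent = lat,
                   direct = eff$direct[, sink],
                   indirect = eff$indirect[, sink],
                   total = eff$total[, sink],
                   stringsAsFactors = FALSE),
                 sink = sink, boot = boot_out,
                 converged = fit$converged, iterations = fit$iterations),
            class = "plspm")
}

#' @export
print.plspm <- function(x, ...) {
  cat("<plspm> scheme:", x$scheme, "| GoF:", round(x$gof, 4),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  cat("path coefficients (from rows to columns):\n")
  print(round(x$path_matrix, 4))
  invisible(x)
}

#' @export
summary.plspm <- function(object, ...) {
  cat("PLS path model —", length(object$blocks), "latents, sink:",
    object$sink, "\n")
  cat("converged:", object$converged, "in", object$iterations,
      "iterations | GoF:", round(object$gof, 4), "\n\n")
  cat("Effects on", object$sink, ":\n")
  ef <- object$effects
  ef <- ef[ef$latent != object$sink, ]
  print(ef, row.names = FALSE)
  if (!is.null(object$boot)) {
    cat("\nBootstrap path coefficients:\n")
    print(object$boot, row.names = FALSE)
  }
  cat("\nR^2:\n")
  print(round(object$r2[!is.na(object$r2)], 4))
  invisible(object)
}
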