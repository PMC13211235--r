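.projection_vars <- c("Pre_AU", "Pre_SP", "Pre_GS", "Pre_year",
                      "Snowday", "Snowstart", "Snowend", "Snowmelt",
                      "Temp_AU", "Temp_GS", "Elevation", "Aspect")

#' Predictor stack for the projection model
#'
#' Bundles the 12 co-registered environmental rasters used by the
#' convolutional regressor. Exactly these variables are accepted:
#' `Pre_AU, Pre_SP, Pre_GS, Pre_year, Snowday, Snowstart, Snowend,
#' Snowmelt, Temp_AU, Temp_GS, Elevation, Aspect`. A future variant is
#' expected to differ only in `Pre_AU`, `Pre_SP`, `Pre_year`, `Temp_AU`.
#'
#' @param rasters Named list of matrices (same shape) covering exactly the
#'   12 variables.
#' @param geometry Optional grid geometry.
#' @return Object of class `predictor_stack`.
#' @export
predictor_stack <- function(rasters, geometry = NULL) {
  nm <- names(rasters)
  if (!setequal(nm, .projection_vars))
    stop("predictor stack must contain exactly: ",
         paste(.projection_vars, collapse = ", "))
  rasters <- rasters[.projection_vars]
  d <- dim(rasters[[1]])
  if (!all(vapply(rasters, function(r) identical(dim(r), d), TRUE)))
    stop("rasters must share one grid")
  structure(list(rasters = rasters, dim = d, geometry = geometry),
            class = "predictor_stack")
}

# reflect index i about the [1, n] range (single-level mirror)
.reflect <- function(i, n) ifelse(i < 1L, 2L - i, ifelse(i > n, 2L * n - i, i))

# padded copies of all stack rasters (mirror padding of width pad)
.pad_stack <- function(stack, pad) {
  d <- stack$dim
  ri <- .reflect(seq_len(d[1] + 2L * pad) - pad, d[1])
  ci <- .reflect(seq_len(d[2] + 2L * pad) - pad, d[2])
  lapply(stack$rasters, function(r) r[ri, ci, drop = FALSE])
}

# patch matrix for the given center cells; columns ordered (row-offset
# fastest, then col-offset, then channel) — the layout assumed by the conv
.stack_patches <- function(stack, centers_rc, patch_size) {
  pad <- (patch_size - 1L) %/% 2L
  padded <- .pad_stack(stack, pad)
  n <- nrow(centers_rc)
  x <- matrix(0, n, patch_size^2 * length(padded))
  col <- 0L
  for (ch in seq_along(padded)) {
    Mp <- padded[[ch]]
    for (b in 0:(patch_size - 1L)) for (a in 0:(patch_size - 1L)) {
      col <- col + 1L
      x[, col] <- Mp[cbind(centers_rc[, 1] + a, centers_rc[, 2] + b)]
    }
  }
  x
}

#' Extract training patches from a predictor stack
#'
#' One sample per valid (non-missing) target pixel: the
#' `patch_size x patch_size x 12` predictor window centered on the pixel
#' (mirror padding at the scene edges) and the scalar NDVI target.
#'
#' @param stack A [predictor_stack()].
#' @param target Matrix of target values (e.g. multi-year mean ephemeral
#'   NDVI increment); `NA` pixels are skipped.
#' @param patch_size Odd window size >= 1 (default 5).
#' @return Object of class `patch_samples`: list with matrix `x`
#'   (n x patch_size^2*12), vector `y`, `centers` (row/col), `patch_size`,
#'   `channels`, `var_names`.
#' @export
extract_patches <- function(stack, target, patch_size = 5L) {
  stopifnot(inherits(stack, "predictor_stack"))
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 1")
  if (patch_size > min(stack$dim)) stop("patch larger than grid")
  if (!identical(dim(target), stack$dim)) stop("target grid mismatch")
  valid <- which(is.finite(target), arr.ind = TRUE)
  if (nrow(valid) == 0L) stop("no valid target pixels")
  x <- .stack_patches(stack, valid, patch_size)
  structure(list(x = x, y = target[valid], centers = valid,
                 patch_size = patch_size, channels = length(stack$rasters),
                 var_names = names(stack$rasters)),
            class = "patch_samples")
}

#' Architecture and training configuration of the convolutional regressor
#'
#' Defaults: two 3x3 convolution stages (16 and 32 filters, ReLU), global
#' max pooling over the remaining spatial positions, a dense layer of 64
#' units, scalar linear output; mean-squared-error objective, Adam
#' optimizer, early stopping on a 10% validation split.
#'
#' @param filters Integer pair of filter counts for the two conv stages.
#' @param kernel Convolution kernel size (odd).
#' @param dense Width of the dense head.
#' @param lr Adam learning rate.
#' @param epochs Maximum epochs.
#' @param batch Minibatch size.
#' @param patience Early-stopping patience (epochs without val improvement).
#' @param val_frac Fraction of training data held out for early stopping.
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(filters = c(16L, 32L), kernel = 3L, dense = 64L,
                       lr = 6e-3, epochs = 250L, batch = 32L,
                       patience = 25L, val_frac = 0.1) {
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 dense = as.integer(dense), lr = lr,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 patience = as.integer(patience), val_frac = val_frac),
            class = "cnn_config")
}

# im2col index table: rows = output positions (column-major over the output
# grid), cols = window elements ordered (row-offset, col-offset, channel)
.im2col_idx <- function(h, w, c, k) {
  oh <- h - k + 1L; ow <- w - k + 1L
  idx <- matrix(0L, oh * ow, k * k * c)
  p <- 0L
  pos <- matrix(0L, oh * ow, 2L)
  for (oj in seq_len(ow)) for (oi in seq_len(oh)) {
    p <- p + 1L; pos[p, ] <- c(oi, oj)
  }
  e <- 0L
  for (ch in seq_len(c)) for (cc in 0:(k - 1L)) for (rr in 0:(k - 1L)) {
    e <- e + 1L
    idx[, e] <- ((ch - 1L) * w + (pos[, 2] + cc - 1L)) * h + (pos[, 1] + rr)
  }
  list(idx = idx, oh = oh, ow = ow)
}

.conv_fwd <- function(X, ic, W, b) {
  n <- nrow(X); m <- nrow(ic$idx); kkc <- ncol(ic$idx)
  Xcol <- matrix(0, n * m, kkc)
  for (p in seq_len(m)) Xcol[(p - 1L) * n + seq_len(n), ] <- X[, ic$idx[p, ]]
  Z <- sweep(Xcol %*% W, 2L, b, "+")
  list(Z = Z, Xcol = Xcol)
}

.conv_bwd <- function(dZ, cache, ic, W, n, in_cols) {
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, W)
  dX <- matrix(0, n, in_cols)
  for (p in seq_len(nrow(ic$idx))) {
    rows <- (p - 1L) * n + seq_len(n)
    cols <- ic$idx[p, ]
    dX[, cols] <- dX[, cols] + dXcol[rows, ]
  }
  list(dW = dW, db = db, dX = dX)
}

# (n*m) x f conv output -> n x (m*f) feature matrix (position-major layout)
.conv_reshape <- function(Z, n, m, f) { dim(Z) <- c(n, m * f); Z }

.cnn_init <- function(ps, channels, cfg, seed) {
  set.seed(seed)
  k <- cfg$kernel
  f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  s1 <- ps - k + 1L; s2 <- s1 - k + 1L
  if (s2 < 1L) stop("patch_size too small for two ", k, "x", k, " convolutions")
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  list(
    W1 = he(k * k * channels, k * k * channels, f1), b1 = numeric(f1),
    W2 = he(k * k * f1, k * k * f1, f2), b2 = numeric(f2),
    W3 = he(f2, f2, cfg$dense), b3 = numeric(cfg$dense),
    W4 = he(cfg$dense, cfg$dense, 1L), b4 = numeric(1L),
    ic1 = .im2col_idx(ps, ps, channels, k),
    ic2 = .im2col_idx(s1, s1, f1, k),
    dims = list(ps = ps, channels = channels, s1 = s1, s2 = s2,
                f1 = f1, f2 = f2))
}

.cnn_forward <- function(par, X, cache = FALSE) {
  d <- par$dims; n <- nrow(X)
  m1 <- d$s1^2; m2 <- d$s2^2
  c1 <- .conv_fwd(X, par$ic1, par$W1, par$b1)
  A1 <- pmax(c1$Z, 0)
  H1 <- .conv_reshape(A1, n, m1, d$f1)
  c2 <- .conv_fwd(H1, par$ic2, par$W2, par$b2)
  A2 <- pmax(c2$Z, 0)
  # global max pool over the m2 spatial positions
  A2a <- A2; dim(A2a) <- c(n, m2, d$f2)
  P <- A2a[, 1L, ]; if (is.null(dim(P))) P <- matrix(P, n, d$f2)
  argm <- matrix(1L, n, d$f2)
  if (m2 > 1L) for (p in 2:m2) {
    cur <- A2a[, p, ]
    upd <- cur > P
    P[upd] <- cur[upd]
    argm[upd] <- p
  }
  H3 <- sweep(P %*% par$W3, 2L, par$b3, "+")
  A3 <- pmax(H3, 0)
  out <- as.numeric(A3 %*% par$W4 + par$b4)
  if (!cache) return(out)
  list(out = out, X = X, c1 = c1, A1 = A1, H1 = H1, c2 = c2, A2 = A2,
       P = P, argm = argm, H3 = H3, A3 = A3)
}

.cnn_backward <- function(par, fw, dout) {
  d <- par$dims; n <- length(dout)
  m1 <- d$s1^2; m2 <- d$s2^2
  g <- list()
  dA3 <- dout %o% as.numeric(par$W4)
  g$W4 <- crossprod(fw$A3, matrix(dout, n, 1L)); g$b4 <- sum(dout)
  dH3 <- dA3 * (fw$H3 > 0)
  g$W3 <- crossprod(fw$P, dH3); g$b3 <- colSums(dH3)
  dP <- tcrossprod(dH3, par$W3)
  # un-pool: route gradient to the argmax position
  dA2 <- matrix(0, n * m2, d$f2)
  rows <- rep(seq_len(n), d$f2)
  cols <- rep(seq_len(d$f2), each = n)
  dA2[cbind((as.vector(fw$argm) - 1L) * n + rows, cols)] <- as.vector(dP)
  dZ2 <- dA2 * (fw$c2$Z > 0)
  bk2 <- .conv_bwd(dZ2, fw$c2, par$ic2, par$W2, n, m1 * d$f1)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  dA1 <- bk2$dX
  dim(dA1) <- c(n * m1, d$f1)
  dZ1 <- dA1 * (fw$c1$Z > 0)
  bk1 <- .conv_bwd(dZ1, fw$c1, par$ic1, par$W1, n, d$ps^2 * d$channels)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

.cnn_train <- function(x, y, cfg, seed, ps, channels) {
  n <- nrow(x)
  par <- .cnn_init(ps, channels, cfg, seed)
  # standardized target: keeps the loss surface well-conditioned regardless
  # of the physical scale of NDVI; predictions are un-scaled on the way out
  par$y_mean <- mean(y); par$y_sd <- stats::sd(y)
  if (par$y_sd == 0) par$y_sd <- 1
  y <- (y - par$y_mean) / par$y_sd
  set.seed(seed + 1L)
  nval <- max(1L, round(cfg$val_frac * n))
  vidx <- sample.int(n, nval)
  tx <- x[-vidx, , drop = FALSE]; ty <- y[-vidx]
  vx <- x[vidx, , drop = FALSE]; vy <- y[vidx]
  pn <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  mom <- lapply(par[pn], function(p) p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
  best <- Inf; best_par <- par[pn]; wait <- 0L
  nt <- nrow(tx)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(nt)
    for (start in seq(1L, nt, by = cfg$batch)) {
      bi <- ord[start:min(start + cfg$batch - 1L, nt)]
      fw <- .cnn_forward(par, tx[bi, , drop = FALSE], cache = TRUE)
      resid <- fw$out - ty[bi]
      dout <- 2 * resid / length(bi)
      g <- .cnn_backward(par, fw, dout)
      t <- t + 1L
      for (p in pn) {
        mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * g[[p]]
        vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * g[[p]]^2
        mhat <- mom[[p]] / (1 - beta1^t)
        vhat <- vel[[p]] / (1 - beta2^t)
        par[[p]] <- par[[p]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vpred <- .cnn_forward(par, vx)
    vloss <- mean((vpred - vy)^2)
    if (vloss < best - 1e-12) {
      best <- vloss; best_par <- par[pn]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  par[pn] <- best_par
  par
}

# forward pass on the physical target scale
.cnn_predict <- function(par, X) {
  .cnn_forward(par, X) * par$y_sd + par$y_mean
}

# per-channel normalization statistics (over all positions of a channel)
.channel_norm <- function(x, ps, channels) {
  cols_per <- ps^2
  mu <- numeric(channels); sdv <- numeric(channels)
  for (ch in seq_len(channels)) {
    cc <- (ch - 1L) * cols_per + seq_len(cols_per)
    v <- x[, cc]
    mu[ch] <- mean(v); sdv[ch] <- stats::sd(as.numeric(v))
    if (sdv[ch] == 0) sdv[ch] <- 1
  }
  list(mean = mu, sd = sdv)
}

.apply_norm <- function(x, norm, ps, channels) {
  cols_per <- ps^2
  for (ch in seq_len(channels)) {
    cc <- (ch - 1L) * cols_per + seq_len(cols_per)
    x[, cc] <- (x[, cc] - norm$mean[ch]) / norm$sd[ch]
  }
  x
}

#' Train the convolutional regressor with k-fold cross-validation
#'
#' Assigns samples to folds (seeded), trains the network on each
#' training split (with per-channel z-score normalization computed from
#' that split only), evaluates R^2 and RMSE on the held-out fold, then
#' trains a final model on all samples for projection use.
#'
#' @param samples A [extract_patches()] result.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling folds, initialization and batching.
#' @param config A [cnn_config()].
#' @return Object of class `cnn_cv`: list with `model` (class `cnn_model`),
#'   `metrics` (per-fold data.frame), `summary` (mean/sd of R^2 and RMSE).
#' @export
train_cv <- function(samples, folds = 5L, seed = 1L, config = cnn_config()) {
  stopifnot(inherits(samples, "patch_samples"))
  n <- nrow(samples$x)
  if (n < 200L) stop("need at least 200 samples")
  if (stats::sd(samples$y) == 0) stop("degenerate (constant) target")
  ps <- samples$patch_size; channels <- samples$channels
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  met <- data.frame(fold = seq_len(folds), r2 = NA_real_, rmse = NA_real_)
  for (f in seq_len(folds)) {
    tr <- fold != f
    norm <- .channel_norm(samples$x[tr, , drop = FALSE], ps, channels)
    tx <- .apply_norm(samples$x[tr, , drop = FALSE], norm, ps, channels)
    par <- .cnn_train(tx, samples$y[tr], config, seed + 100L * f, ps, channels)
    tex <- .apply_norm(samples$x[!tr, , drop = FALSE], norm, ps, channels)
    pred <- .cnn_predict(par, tex)
    truth <- samples$y[!tr]
    met$rmse[f] <- sqrt(mean((pred - truth)^2))
    met$r2[f] <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  }
  norm <- .channel_norm(samples$x, ps, channels)
  fx <- .apply_norm(samples$x, norm, ps, channels)
  par <- .cnn_train(fx, samples$y, config, seed + 999L, ps, channels)
  model <- structure(list(par = par, norm = norm, config = config,
                          patch_size = ps, channels = channels,
                          var_names = samples$var_names, seed = seed),
                     class = "cnn_model")
  structure(list(model = model,
                 metrics = met,
                 summary = data.frame(
                   metric = c("r2", "rmse"),
                   mean = c(mean(met$r2), mean(met$rmse)),
                   sd = c(stats::sd(met$r2), stats::sd(met$rmse)))),
            class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cnn_cv> %d-fold CV: R^2 = %.3f +- %.3f, RMSE = %.4f +- %.4f\n",
              nrow(x$metrics), s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
  invisible(x)
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat("<cnn_model> patch ", x$patch_size, "x", x$patch_size, "x", x$channels,
      " -> conv", cfg$kernel, "x", cfg$kernel, "(", cfg$filters[1],
      ") -> conv(", cfg$filters[2], ") -> maxpool -> dense(", cfg$dense,
      ") -> 1\n", sep = "")
  invisible(x)
}

#' Predict an NDVI raster from a predictor stack
#'
#' @param object A `cnn_model`.
#' @param stack A [predictor_stack()] with the training variable roster.
#' @param ... Unused.
#' @return Matrix of predicted NDVI with the stack's grid shape.
#' @export
predict.cnn_model <- function(object, stack, ...) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (!identical(names(stack$rasters), object$var_names))
    stop("variable roster mismatch with the trained model")
  d <- stack$dim
  centers <- as.matrix(expand.grid(row = seq_len(d[1]), col = seq_len(d[2])))
  x <- .stack_patches(stack, centers, object$patch_size)
  x <- .apply_norm(x, object$norm, object$patch_size, object$channels)
  pred <- numeric(nrow(x))
  for (start in seq(1L, nrow(x), by = 4096L)) {
    sel <- start:min(start + 4095L, nrow(x))
    pred[sel] <- .cnn_predict(object$par, x[sel, , drop = FALSE])
  }
  matrix(pred, d[1], d[2])
}

#' Project the ephemeral NDVI distribution under a climate scenario
#'
#' Predicts the NDVI raster from a (future) predictor stack, classifies it
#' with the vigor-class thresholds, and tabulates class areas, shares and
#' the scene-mean NDVI.
#'
#' @param model A trained `cnn_model` (from [train_cv()]`$model`).
#' @param future_stack A [predictor_stack()]; must carry exactly the
#'   training variable roster.
#' @param thresholds Class cutpoints (default `c(0.1564, 0.1878)`).
#' @param cell_area_km2 Cell area for the area table.
#' @param scenario,period Labels recorded in the output table.
#' @return Object of class `projection_result`: list with `prediction`
#'   (matrix), `class_map`, `table` (scenario, period, class, area_km2,
#'   share_pct), `mean_ndvi`.
#' @export
project_scenario <- function(model, future_stack,
                             thresholds = c(0.1564, 0.1878),
                             cell_area_km2 = 1,
                             scenario = "scenario", period = "period") {
  pred <- predict(model, future_stack)
  cm <- classify_ndvi(pred, mask = NULL, thresholds = thresholds)
  counts <- vapply(1:3, function(k) sum(cm$codes == k), 0L)
  tab <- data.frame(scenario = scenario, period = period,
                    class = .class_labels,
                    area_km2 = counts * cell_area_km2,
                    share_pct = 100 * counts / sum(counts),
                    stringsAsFactors = FALSE)
  structure(list(prediction = pred, class_map = cm, table = tab,
                 mean_ndvi = mean(pred), scenario = scenario,
                 period = period),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result> ", x$scenario, "/", x$period,
      " mean NDVI ", round(x$mean_ndvi, 4), "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
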