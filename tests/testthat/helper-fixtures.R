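# shared tiny fixtures, built in code

tiny_scene <- function(rows = 10L, cols = 10L, years = 2001:2010, seed = 7L)
  scene_config(rows, cols, years = years, seed = seed)

noise_free_cube <- function(rows = 10L, cols = 10L, years = 2001:2010,
                            seed = 7L, env = NULL)
  gen_ndvi_cube(scene_config(rows, cols, years = years, seed = seed),
                phenology_preset(noise_sd = 0), env = env)

# a simple deterministic mask: southern half of the scene in-mask
half_mask <- function(rows = 10L, cols = 10L, cell = 1) {
  m <- matrix(FALSE, rows, cols)
  m[(rows %/% 2 + 1):rows, ] <- TRUE
  structure(list(mask = m, threshold_value = 0, mode = "global_mean",
                 geometry = list(rows = rows, cols = cols,
                                 cell_size_km = cell, origin = c(0, 0))),
            class = "dist_mask")
}

# printed transfer-area matrices of the three period pairs (km^2),
# source classes in rows (Sparse, Less, Medium)
transfer_tables <- function() {
  list(
    P1_P2 = matrix(c(7669, 1261.5, 46.5,
                     4049.75, 12025.75, 1668.5,
                     269.25, 3535, 4157.75), 3, 3, byrow = TRUE),
    P2_P3 = matrix(c(10934.25, 1050.25, 3.5,
                     5231.5, 11367, 223.75,
                     167.25, 3171.75, 2533.75), 3, 3, byrow = TRUE),
    P3_P4 = matrix(c(4167.25, 10006.25, 2159.5,
                     37, 7531.5, 8020.5,
                     2, 672.5, 2691.75), 3, 3, byrow = TRUE))
}

# brute-force key-point oracle: literal argmax/argmin scans
oracle_key_points <- function(x, doys) {
  ok <- which(!is.na(x))
  ia <- ok[x[ok] == max(x[ok])][1]
  before <- ok[ok < ia]; after <- ok[ok > ia]
  if (max(x[ok]) == min(x[ok]) || !length(before) || !length(after))
    return(NULL)
  ib <- after[x[after] == min(x[after])][1]
  cb <- before[x[before] == min(x[before])]
  ic <- cb[length(cb)]
  list(doy_c = doys[ic], doy_a = doys[ia], doy_b = doys[ib],
       ndvi_c = x[ic], ndvi_a = x[ia], ndvi_b = x[ib])
}

# exhaustive-partition Jenks oracle for small n
oracle_jenks_objective <- function(x, k) {
  x <- sort(x); n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(seq_len(n - 1L), k - 1L)
  for (ci in seq_len(ncol(splits))) {
    b <- c(0L, splits[, ci], n)
    tot <- 0
    for (s in seq_len(k)) tot <- tot + ssd(x[(b[s] + 1L):b[s + 1L]])
    best <- min(best, tot)
  }
  best
}

# path-enumeration oracle for effect decomposition (DFS over all routes)
oracle_total_effect <- function(B, from, to) {
  k <- nrow(B)
  total <- 0
  walk <- function(node, prod) {
    for (nxt in seq_len(k)) {
      if (B[node, nxt] != 0) {
        p <- prod * B[node, nxt]
        if (nxt == to) total <<- total + p
        else walk(nxt, p)
      }
    }
  }
  walk(from, 1)
  total
}
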