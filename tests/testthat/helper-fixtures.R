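# Shared fixtures and independent oracles, built in code at test time.

# a small valid frame (>= 8x8) with given fill
make_frame <- function(fill = 25, nr = 10, nc = 12, ...) {
  thermal_frame(matrix(fill, nr, nc), ...)
}

# type-7 quantile by explicit sort-and-interpolate, independent of stats::quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, n)] - x[lo + 1])
}

# brute-force 2D correlation with edge replication (double loop)
oracle_convolve <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  kr <- (nrow(k) - 1) / 2; kc <- (ncol(k) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      r <- min(max(i + a - 1 - kr, 1), H)
      c_ <- min(max(j + b - 1 - kc, 1), W)
      acc <- acc + k[a, b] * m[r, c_]
    }
    out[i, j] <- acc
  }
  out
}

# supremum ECDF gap, independent of stats::ks.test
oracle_ks_stat <- function(a, b) {
  g <- sort(c(a, b))
  max(abs(ecdf(a)(g) - ecdf(b)(g)))
}

# small feature table with a known class offset on mean/median only
make_tabular_cohort <- function(n_per_class, offset, seed, noise = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    treatment <- rep(c("WW", "DD"), each = n_per_class)
    shift <- ifelse(treatment == "DD", offset, 0)
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      treatment = treatment,
      mean = rnorm(n, 25 + shift, noise),
      median = rnorm(n, 25 + shift, noise),
      std = rnorm(n, 1, 0.2),
      p25 = rnorm(n, 24, noise),
      p75 = rnorm(n, 26, noise),
      iqr = rnorm(n, 2, 0.3),
      max = rnorm(n, 28, noise),
      min = rnorm(n, 22, noise),
      range = rnorm(n, 6, 0.5)
    )
  })
}

# 20-scene seeded segmentation benchmark, mixing geometries and rotations
iou_benchmark <- function(noise_sd, blur_sigma, leaf_temp_sd = 0.3, offset = 3) {
  vapply(1:20, function(i) {
    geom <- c("ellipse", "lobed", "okra")[(i %% 3) + 1]
    sp <- leaf_scene_spec(
      noise_sd = noise_sd, blur_sigma = blur_sigma, leaf_temp_sd = leaf_temp_sd,
      background_temp = 22, leaf_temp_mean = 22 + offset,
      leaf_geometry = geom, rotation = i * 0.3, seed = i
    )
    s <- generate_leaf_scene(sp)
    mask_iou(segment_leaf(s$frame), s$truth_mask)
  }, numeric(1))
}
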