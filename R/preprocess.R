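#' High-pass filter a thermal frame in the Fourier domain
#'
#' Computes the 2D FFT of the frame, zeroes every Fourier coefficient whose
#' magnitude is at least that of the DC (zero-frequency) coefficient, and
#' returns the real part of the inverse transform. In natural thermal images
#' the DC magnitude dominates the spectrum, so this removes the DC term (the
#' image mean, scaled) and with it the flat backdrop, leaving the spatial
#' structure of the leaf; any pathological coefficient of equal or greater
#' magnitude is removed too, which keeps the rule well-defined for all
#' inputs. When the DC magnitude is already numerically zero (an image that
#' has been high-pass filtered before) only the DC coefficient itself is
#' removed, so the filter is idempotent. When only DC is removed the output
#' has zero mean to numerical tolerance.
#'
#' @param frame A [thermal_frame()] or numeric matrix, at least 8 x 8.
#' @return A `filtered_image`: list with `values`, the high-pass residual
#'   (same shape as the input, units of degrees Celsius about zero).
#' @export
highpass_fft <- function(frame) {
  m <- if (inherits(frame, "thermal_frame")) frame$values else frame
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) < 8L || ncol(m) < 8L) {
    rlang::abort("frame must be at least 8 x 8 for spectral filtering",
                 class = "thermoleaf_size_error")
  }
  F <- stats::fft(m)
  dc_mag <- Mod(F[1, 1])
  # degenerate case: an already high-passed image has a (numerically) zero
  # DC, and the >= rule would then wipe the whole spectrum; remove only DC
  if (dc_mag > 1e-12 * max(Mod(F))) {
    F[Mod(F) >= dc_mag] <- 0 + 0i
  } else {
    F[1, 1] <- 0 + 0i
  }
  out <- Re(stats::fft(F, inverse = TRUE)) / length(m)
  structure(list(values = out), class = "filtered_image")
}

# Sobel row/col derivative kernels (dy responds to vertical change across rows)
sobel_y <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
sobel_x <- t(sobel_y)

# 2D correlation with edge replication; k must be odd-sized and small
convolve_replicate <- function(m, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(rep(1L, kr), seq_len(H), rep(H, kr)),
           c(rep(1L, kc), seq_len(W), rep(W, kc)), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * pad[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
      }
    }
  }
  out
}

#' Gradient magnitude of a filtered image
#'
#' Per-pixel gradient magnitude `sqrt(gx^2 + gy^2)` with the Sobel 3x3
#' operator by default (central differences selectable); image borders are
#' handled by edge replication, so a flat image yields an exactly zero
#' gradient everywhere including the border. The gradient is translation
#' invariant (adding a constant changes nothing) and positively homogeneous.
#'
#' @param filtered A `filtered_image` from [highpass_fft()], or a numeric
#'   matrix.
#' @param method `"sobel"` (default) or `"central"` differences.
#' @return A `gradient_image`: list with `values`, non-negative magnitudes of
#'   the same shape as the input.
#' @export
gradient_magnitude <- function(filtered, method = c("sobel", "central")) {
  method <- rlang::arg_match(method)
  m <- if (is.list(filtered)) filtered$values else filtered
  stopifnot(is.matrix(m), is.numeric(m))
  if (method == "sobel") {
    gx <- convolve_replicate(m, sobel_x)
    gy <- convolve_replicate(m, sobel_y)
  } else {
    gx <- convolve_replicate(m, matrix(c(-0.5, 0, 0.5), 1, 3))
    gy <- convolve_replicate(m, matrix(c(-0.5, 0, 0.5), 3, 1))
  }
  structure(list(values = sqrt(gx^2 + gy^2)), class = "gradient_image")
}
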