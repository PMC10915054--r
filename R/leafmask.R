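#' Binary leaf mask
#'
#' A logical grid aligned to a thermal frame; after refinement it has
#' exactly one connected component (the leaf).
#'
#' @param values Logical (or 0/1 numeric) matrix.
#' @return A `leaf_mask` object.
#' @export
leaf_mask <- function(values) {
  if (is.numeric(values)) values <- values != 0
  stopifnot(is.matrix(values), is.logical(values))
  structure(list(values = values), class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d x %d px, %d on (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$values), 100 * mean(x$values)))
  invisible(x)
}

#' Intersection-over-union of two masks
#'
#' @param a,b `leaf_mask` objects or logical matrices of equal shape.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  av <- if (inherits(a, "leaf_mask")) a$values else a
  bv <- if (inherits(b, "leaf_mask")) b$values else b
  stopifnot(identical(dim(av), dim(bv)))
  un <- sum(av | bv)
  if (un == 0) return(1)
  sum(av & bv) / un
}

#' Tukey fences of a gradient image
#'
#' Computes the first and third quartiles of all gradient values (linear
#' interpolation, quantile type 7), the interquartile range
#' `IQR = q3 - q1`, and the fences `thr_dw = q1 - multiplier * IQR` and
#' `thr_up = q3 + multiplier * IQR`. These robust fences drive the
#' binarization of the gradient image: gradient magnitudes are mostly small
#' and homogeneous except along the leaf outline, which shows up as upper
#' outliers.
#'
#' @param gradient A `gradient_image` or numeric matrix.
#' @param multiplier Fence multiplier, 1.5 by default.
#' @return A one-row tibble with columns `q1`, `q3`, `iqr`, `thr_dw`,
#'   `thr_up`, `multiplier`.
#' @export
compute_fences <- function(gradient, multiplier = 1.5) {
  v <- if (is.list(gradient)) gradient$values else gradient
  stopifnot(length(v) > 0)
  q <- stats::quantile(as.numeric(v), c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  tibble::tibble(
    q1 = q[1], q3 = q[2], iqr = iqr,
    thr_dw = q[1] - multiplier * iqr,
    thr_up = q[2] + multiplier * iqr,
    multiplier = multiplier
  )
}

#' Binarize a gradient image against quartile fences
#'
#' In the default `two_sided` mode a pixel is on when its gradient value
#' lies outside the fences (`< thr_dw` or `> thr_up`) — the standard Tukey
#' outlier rule. `low_only` keeps only the lower test (`< thr_dw`); since
#' gradient magnitudes are non-negative and `thr_dw` is typically negative,
#' that reading is usually vacuous and is provided for comparison only.
#'
#' @param gradient A `gradient_image` or numeric matrix.
#' @param fences One-row tibble from [compute_fences()].
#' @param mode `"two_sided"` (default) or `"low_only"`.
#' @return A raw (unrefined) [leaf_mask()].
#' @export
binarize_gradient <- function(gradient, fences, mode = c("two_sided", "low_only")) {
  mode <- rlang::arg_match(mode)
  v <- if (is.list(gradient) && !is.data.frame(gradient)) gradient$values else gradient
  on <- if (mode == "two_sided") {
    v < fences$thr_dw | v > fences$thr_up
  } else {
    v < fences$thr_dw
  }
  leaf_mask(on)
}

#' Morphologically refine a raw mask and keep the largest blob
#'
#' Applies dilation with a disc structuring element, flood-fill hole
#' filling, erosion with the same element, then connected-component
#' labeling, keeping only the component with the most pixels. Component-size
#' ties break toward the smallest label (scan order). The raw mask produced
#' by fence binarization is an outline ring around the leaf edge; dilation
#' closes gaps in the ring, hole filling recovers the leaf interior, and
#' erosion restores the boundary position.
#'
#' Because the gradient ring straddles the true edge, its filled interior
#' overshoots the leaf by about one pixel all around; the erosion element is
#' therefore one pixel larger than the dilation element by default
#' (`erode_radius = struct_radius + 1`), which re-centers the recovered
#' boundary on the true one. Set `erode_radius = struct_radius` for a
#' strictly symmetric morphological closing.
#'
#' @param raw A raw [leaf_mask()].
#' @param struct_radius Disc radius in pixels for the dilation element.
#' @param erode_radius Disc radius for the erosion element; default
#'   `struct_radius + 1` (boundary de-biasing, see Details).
#' @param connectivity Pixel connectivity for blob analysis; 8 (default) or 4.
#' @param min_area Minimum pixel count for the surviving component; smaller
#'   results are treated as segmentation failures.
#' @return A refined [leaf_mask()] with exactly one connected component.
#' @export
refine_mask <- function(raw, struct_radius = 3L, erode_radius = struct_radius + 1L,
                        connectivity = c(8, 4), min_area = 50L) {
  connectivity <- as.integer(connectivity[1])
  stopifnot(connectivity %in% c(4L, 8L))
  m <- (if (inherits(raw, "leaf_mask")) raw$values else raw) * 1
  n_raw <- sum(m)
  fail <- function(sizes) {
    rlang::abort(
      sprintf(
        "segmentation failure: %d raw on-pixels, component sizes [%s], min_area %d",
        n_raw, paste(sizes, collapse = ", "), min_area
      ),
      class = "thermoleaf_segmentation_error",
      raw_on = n_raw, component_sizes = sizes
    )
  }
  if (n_raw == 0) fail(integer())
  brush <- EBImage::makeBrush(2L * as.integer(struct_radius) + 1L, shape = "disc")
  ebrush <- EBImage::makeBrush(2L * as.integer(erode_radius) + 1L, shape = "disc")
  m <- EBImage::dilate(m, brush)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, ebrush)
  if (connectivity == 8L) {
    lab <- EBImage::bwlabel(m)
  } else {
    lab <- label_components4(m != 0)
  }
  n_comp <- max(lab)
  if (n_comp == 0) fail(integer())
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  best <- which.max(sizes)   # ties -> smallest label
  if (sizes[best] < min_area) fail(sizes)
  out <- lab == best
  if (all(out)) {
    rlang::abort("segmentation failure: mask covers the whole frame",
                 class = "thermoleaf_segmentation_error")
  }
  leaf_mask(out)
}

# 4-connectivity labeling by iterative flood fill (small images only)
label_components4 <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (s in which(bin & lab == 0L)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    while (length(stack) > 0) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !bin[p]) next
      lab[p] <- nxt
      r <- (p - 1L) %% H + 1L; c_ <- (p - 1L) %/% H + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < H) stack <- c(stack, p + 1L)
      if (c_ > 1L) stack <- c(stack, p - H)
      if (c_ < W) stack <- c(stack, p + H)
    }
  }
  lab
}

#' Segment the leaf in a thermal frame
#'
#' The full deterministic segmentation chain: FFT high-pass filter,
#' gradient magnitude, quartile fences, fence binarization, morphological
#' refinement with largest-component selection. No stage uses the treatment
#' label, and because the DC component is removed upstream the result is
#' invariant to adding a constant temperature to the whole frame.
#'
#' Gradient magnitudes below `noise_floor` times the gradient maximum are
#' zeroed before the fences are computed: on (near-)noiseless frames the
#' inverse FFT leaves round-off residue of order 1e-15 everywhere, and
#' without the floor the quartile fences would chase that residue instead
#' of real structure.
#'
#' @param frame A [thermal_frame()].
#' @param mode Binarization mode, see [binarize_gradient()].
#' @param multiplier Fence multiplier, see [compute_fences()].
#' @param struct_radius,erode_radius,connectivity,min_area See
#'   [refine_mask()].
#' @param gradient_method See [gradient_magnitude()].
#' @param noise_floor Relative numerical floor on gradient magnitudes (see
#'   Details).
#' @return A refined [leaf_mask()].
#' @export
segment_leaf <- function(frame, mode = c("two_sided", "low_only"),
                         multiplier = 1.5, struct_radius = 3L,
                         erode_radius = struct_radius + 1L,
                         connectivity = 8, min_area = 50L,
                         gradient_method = "sobel", noise_floor = 1e-9) {
  mode <- rlang::arg_match(mode)
  filt <- highpass_fft(frame)
  grad <- gradient_magnitude(filt, method = gradient_method)
  g <- grad$values
  g[g < noise_floor * max(g)] <- 0
  grad$values <- g
  fences <- compute_fences(grad, multiplier = multiplier)
  raw <- binarize_gradient(grad, fences, mode = mode)
  refine_mask(raw, struct_radius = struct_radius, erode_radius = erode_radius,
              connectivity = connectivity, min_area = min_area)
}
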