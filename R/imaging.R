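# Local adaptive thresholding over disk neighborhoods, computed by shifting
# a replicate-padded copy of the image once per neighborhood offset and
# folding with pmin/pmax/sum. Exact (no approximation), so masks are
# bit-comparable to per-pixel oracles.

channel_pixels <- function(channel) {
  if (inherits(channel, "cell_image")) stopf(
    "pass a single channel matrix (image$signal or image$dapi), not the image")
  m <- as.matrix(channel)
  if (any(!is.finite(m))) stopf("channel contains non-finite pixels")
  m
}

# Offsets (dy, dx) of the disk neighborhood dy^2 + dx^2 <= radius^2.
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# Offsets of a (2r+1) square window.
square_offsets <- function(radius) {
  r <- floor(radius)
  expand.grid(dy = -r:r, dx = -r:r)
}

pad_replicate <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  m[c(rep(1L, r), seq_len(h), rep(h, r)),
    c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
}

# Apply stats over the neighborhood of every pixel (replicate padding).
# Returns requested components among local min, max, mean.
local_stats <- function(m, offsets, what = c("min", "max", "mean")) {
  h <- nrow(m); w <- ncol(m)
  r <- max(abs(unlist(offsets)))
  p <- pad_replicate(m, r)
  lmin <- if ("min" %in% what) matrix(Inf, h, w)
  lmax <- if ("max" %in% what) matrix(-Inf, h, w)
  lsum <- if ("mean" %in% what) matrix(0, h, w)
  for (i in seq_len(nrow(offsets))) {
    s <- p[r + offsets$dy[i] + seq_len(h), r + offsets$dx[i] + seq_len(w)]
    if (!is.null(lmin)) lmin <- pmin(lmin, s)
    if (!is.null(lmax)) lmax <- pmax(lmax, s)
    if (!is.null(lsum)) lsum <- lsum + s
  }
  out <- list()
  if (!is.null(lmin)) out$min <- lmin
  if (!is.null(lmax)) out$max <- lmax
  if (!is.null(lsum)) out$mean <- lsum / nrow(offsets)
  out
}

check_radius <- function(radius, m) {
  if (radius < 1) stopf("radius must be >= 1")
  if (radius > min(dim(m)) / 2) {
    warnf("radius %g exceeds half the smaller image dimension (%d x %d)",
          radius, nrow(m), ncol(m))
  }
}

#' Bernsen local adaptive threshold
#'
#' For each pixel the neighborhood mid-range `(local_max + local_min) / 2`
#' is computed over a disk of the given radius (replicate padding at the
#' borders). Where the local contrast `local_max - local_min` reaches
#' `contrast_min`, the pixel is foreground iff its value exceeds the
#' mid-range; in low-contrast regions the whole neighborhood is assigned by
#' comparing the mid-range against the `midgray` constant.
#'
#' @param channel 2-D intensity matrix (one image channel).
#' @param radius Neighborhood radius in pixels (default 15).
#' @param contrast_min Minimum local contrast (default 15).
#' @param midgray Mid-gray constant deciding low-contrast regions; defaults
#'   to half the bit-depth maximum (127.5 for 8-bit).
#' @param bit_depth Used only for the `midgray` default.
#' @param shape `"disk"` (default) or `"square"` neighborhood.
#' @return Logical matrix (TRUE = foreground) with the threshold parameters
#'   attached as attribute `"params"`.
#' @export
bernsen_mask <- function(channel, radius = 15, contrast_min = 15,
                         midgray = NULL, bit_depth = 8,
                         shape = c("disk", "square")) {
  m <- channel_pixels(channel)
  shape <- match.arg(shape)
  check_radius(radius, m)
  if (is.null(midgray)) midgray <- (2^bit_depth - 1) / 2
  offs <- if (shape == "disk") disk_offsets(radius) else square_offsets(radius)
  st <- local_stats(m, offs, c("min", "max"))
  midrange <- (st$max + st$min) / 2
  high_contrast <- (st$max - st$min) >= contrast_min
  mask <- ifelse(high_contrast, m > midrange, midrange >= midgray)
  structure(mask, params = list(method = "bernsen", radius = radius,
                                contrast_min = contrast_min,
                                midgray = midgray, shape = shape))
}

#' Local-mean adaptive threshold
#'
#' A pixel is foreground iff its value strictly exceeds the mean of its
#' disk neighborhood minus the offset `c` (replicate padding at borders).
#' With a negative `c` the threshold sits above the local mean, which
#' suppresses speckle in flat background regions.
#'
#' @inheritParams bernsen_mask
#' @param c Intensity offset subtracted from the local mean (default 0).
#' @return Logical matrix with attribute `"params"`.
#' @export
local_mean_mask <- function(channel, radius = 15, c = 0,
                            shape = c("disk", "square")) {
  m <- channel_pixels(channel)
  shape <- match.arg(shape)
  check_radius(radius, m)
  offs <- if (shape == "disk") disk_offsets(radius) else square_offsets(radius)
  st <- local_stats(m, offs, "mean")
  mask <- m > (st$mean - c)
  structure(mask, params = list(method = "local_mean", radius = radius,
                                c = c, shape = shape))
}
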