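#' Specification of a synthetic two-channel cell image
#'
#' Each cell is a concentric pair of disks: the nucleus (radius
#' `nucleus_radius`) inside the cell body (radius `cytoplasm_radius`). The
#' DAPI channel shows nuclei only; the signal channel shows the nucleus at
#' `true_nc_ratio * cytoplasm_mean`, the cytoplasmic annulus at
#' `cytoplasm_mean`, and `background_mean` elsewhere. The composed image is
#' multiplied by a linear illumination ramp, Gaussian noise is added, and
#' pixel values are clipped and quantized to the bit depth. The concentric
#' geometry makes exact oracle ratios available from the truth table.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_cells Number of cells to place (non-overlapping, away from the
#'   border so no nucleus or cell body touches it).
#' @param nucleus_radius,cytoplasm_radius Disk radii in pixels
#'   (`cytoplasm_radius > nucleus_radius > 0`).
#' @param true_nc_ratio True nuclear/cytoplasmic mean-intensity ratio;
#'   a single value or one per cell (recycled).
#' @param cytoplasm_mean,background_mean,dapi_mean Intensities (pre-noise,
#'   pre-illumination) of the cytoplasmic annulus, the background, and the
#'   DAPI nucleus.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param illumination_gradient Fractional intensity change across the image
#'   width (0 = flat field); the ramp is centered at 1.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed.
#' @return A validated list of class `image_spec`.
#' @export
image_spec <- function(image_size = c(256, 256),
                       n_cells = 12,
                       nucleus_radius = 8,
                       cytoplasm_radius = 16,
                       true_nc_ratio = 2,
                       cytoplasm_mean = 50,
                       background_mean = 5,
                       dapi_mean = 120,
                       noise_sd = 0,
                       illumination_gradient = 0,
                       bit_depth = 8,
                       seed = 1L) {
  if (!bit_depth %in% c(8, 16)) stopf("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (length(image_size) != 2L || any(image_size < 8)) {
    stopf("image_size must be c(height, width), each >= 8")
  }
  if (!(cytoplasm_radius > nucleus_radius && nucleus_radius > 0)) {
    stopf("need cytoplasm_radius > nucleus_radius > 0")
  }
  n_cells <- check_count(n_cells, "n_cells")
  true_nc_ratio <- rep_len(as.numeric(true_nc_ratio), n_cells)
  if (any(true_nc_ratio < 0)) stopf("true_nc_ratio must be >= 0")
  means <- c(cytoplasm_mean, background_mean, dapi_mean,
             true_nc_ratio * cytoplasm_mean)
  if (any(means < 0) || any(means > maxval)) {
    stopf("all mean intensities must lie in [0, %d]", maxval)
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(
    image_size = as.integer(image_size), n_cells = n_cells,
    nucleus_radius = nucleus_radius, cytoplasm_radius = cytoplasm_radius,
    true_nc_ratio = true_nc_ratio, cytoplasm_mean = cytoplasm_mean,
    background_mean = background_mean, dapi_mean = dapi_mean,
    noise_sd = noise_sd, illumination_gradient = illumination_gradient,
    bit_depth = bit_depth, seed = check_count(seed, "seed", min = 0L)
  ), class = "image_spec")
}

# Logical disk mask of a full image: (row - cy)^2 + (col - cx)^2 <= r^2
disk_mask <- function(h, w, cy, cx, r) {
  dy <- (seq_len(h) - cy)^2
  dx <- (seq_len(w) - cx)^2
  outer(dy, dx, "+") <= r^2
}

# Rejection-sample non-overlapping centers with a border margin.
place_cells <- function(h, w, n, r_cell, max_tries = 2000L) {
  margin <- r_cell + 2
  if (h - 2 * margin < 1 || w - 2 * margin < 1) {
    stopf("image too small for cells of radius %g", r_cell)
  }
  cy <- numeric(0); cx <- numeric(0)
  tries <- 0L
  while (length(cy) < n) {
    y <- runif(1, margin, h - margin)
    x <- runif(1, margin, w - margin)
    if (!length(cy) || all((cy - y)^2 + (cx - x)^2 > (2 * r_cell + 2)^2)) {
      cy <- c(cy, y); cx <- c(cx, x)
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        stopf("could not place %d non-overlapping cells after %d retries",
              n, max_tries)
      }
    }
  }
  data.frame(cy = round(cy), cx = round(cx))
}

#' Simulate a two-channel cell image with known nuclear/cytoplasmic ratio
#'
#' @param spec An [image_spec()].
#' @return A list with `image` (class `cell_image`: `dapi` and `signal`
#'   integer matrices plus `bit_depth`) and `truth` (a data.frame with one
#'   row per cell: center, radii, true nuclear and cytoplasmic means and
#'   their ratio).
#' @export
simulate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  maxval <- 2^spec$bit_depth - 1
  set.seed(substream_seed(spec$seed, 1L))
  centers <- place_cells(h, w, spec$n_cells, spec$cytoplasm_radius)

  dapi <- matrix(spec$background_mean, h, w)
  signal <- matrix(spec$background_mean, h, w)
  nuc_means <- spec$true_nc_ratio * spec$cytoplasm_mean
  for (i in seq_len(spec$n_cells)) {
    cellm <- disk_mask(h, w, centers$cy[i], centers$cx[i],
                       spec$cytoplasm_radius)
    nucm <- disk_mask(h, w, centers$cy[i], centers$cx[i],
                      spec$nucleus_radius)
    signal[cellm] <- spec$cytoplasm_mean
    signal[nucm] <- nuc_means[i]
    dapi[nucm] <- spec$dapi_mean
  }
  # Linear ramp along image width, centered at 1
  ramp <- 1 + spec$illumination_gradient *
    ((seq_len(w) - 1) / (w - 1) - 0.5)
  illum <- matrix(ramp, h, w, byrow = TRUE)
  quantize <- function(ch, sub) {
    ch <- ch * illum
    if (spec$noise_sd > 0) {
      set.seed(substream_seed(spec$seed, sub))
      ch <- ch + rnorm(length(ch), 0, spec$noise_sd)
    }
    matrix(as.integer(pmin(pmax(round(ch), 0), maxval)), h, w)
  }
  image <- structure(
    list(dapi = quantize(dapi, 2L), signal = quantize(signal, 3L),
         bit_depth = spec$bit_depth),
    class = "cell_image"
  )
  truth <- data.frame(
    cell = seq_len(spec$n_cells),
    cy = centers$cy, cx = centers$cx,
    nucleus_radius = spec$nucleus_radius,
    cytoplasm_radius = spec$cytoplasm_radius,
    nuclear_true_mean = nuc_means,
    cytoplasm_true_mean = spec$cytoplasm_mean,
    true_nc_ratio = spec$true_nc_ratio
  )
  list(image = image, truth = truth)
}

#' @method print cell_image
#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("cell_image: %d x %d, %d-bit, channels: dapi, signal\n",
              nrow(x$dapi), ncol(x$dapi), x$bit_depth))
  invisible(x)
}

#' Oracle masks from an image truth table
#'
#' Reconstructs the exact nucleus mask and whole-cell mask from the truth
#' geometry of [simulate_cell_image()], bypassing thresholding. Used to
#' separate ratio-measurement error from segmentation error.
#'
#' @param truth Truth data.frame from [simulate_cell_image()].
#' @param dim Image dimensions `c(height, width)`.
#' @return List with logical matrices `nucleus` and `cell`.
#' @export
truth_masks <- function(truth, dim) {
  h <- dim[1]; w <- dim[2]
  nucleus <- matrix(FALSE, h, w)
  cell <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(truth))) {
    nucleus <- nucleus | disk_mask(h, w, truth$cy[i], truth$cx[i],
                                   truth$nucleus_radius[i])
    cell <- cell | disk_mask(h, w, truth$cy[i], truth$cx[i],
                             truth$cytoplasm_radius[i])
  }
  list(nucleus = nucleus, cell = cell)
}
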