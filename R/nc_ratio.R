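#' Per-cell nuclear/cytoplasmic mean-intensity ratios
#'
#' Nuclei are the 8-connected components of the DAPI mask (components
#' touching the image border are excluded by default, since partial cells
#' bias the means). For each nucleus, the nuclear signal region is the
#' intersection of the whole-signal mask with the nucleus; the cell's
#' signal component is the connected component of the signal mask with the
#' largest overlap with that nucleus; and the cytoplasmic signal region is
#' that component minus the nuclear region. The record carries the mean
#' signal intensity per pixel over each region and their ratio.
#'
#' @param signal Signal-channel intensity matrix (or a `cell_image`, whose
#'   `$signal` is used).
#' @param signal_mask Logical matrix: whole-signal mask (e.g. from
#'   [bernsen_mask()] + [refine_mask()]).
#' @param dapi_mask Logical matrix: nuclear mask (e.g. from
#'   [local_mean_mask()]).
#' @param min_px Minimum pixel count for each region; below it the ratio is
#'   reported as `NA` with a reason code (default 10).
#' @param exclude_border Drop nuclei touching the image border
#'   (default TRUE).
#' @return Data.frame of class `nc_ratio_table`: `cell_id`, `centroid_y`,
#'   `centroid_x` (nucleus centroid, for joining to ground truth or other
#'   per-cell data), `nuclear_mean`, `cytoplasmic_mean`, `ratio`,
#'   `nuclear_px`, `cytoplasmic_px`, `reason` (`"ok"` or why the ratio is
#'   undefined).
#' @export
nc_ratio <- function(signal, signal_mask, dapi_mask, min_px = 10,
                     exclude_border = TRUE) {
  if (inherits(signal, "cell_image")) signal <- signal$signal
  signal <- as.matrix(signal)
  signal_mask <- as.logical_mask(signal_mask)
  dapi_mask <- as.logical_mask(dapi_mask)
  if (!identical(dim(signal), dim(signal_mask)) ||
      !identical(dim(signal), dim(dapi_mask))) {
    stopf("signal, signal_mask and dapi_mask must share one shape")
  }
  h <- nrow(signal); w <- ncol(signal)
  nuclei <- label_components(dapi_mask, connectivity = 8)
  n_nuc <- max(nuclei)
  if (n_nuc == 0) {
    warnf("no nuclei found in the DAPI mask")
    return(empty_nc_table())
  }
  if (exclude_border) {
    border_ids <- unique(c(nuclei[1, ], nuclei[h, ], nuclei[, 1], nuclei[, w]))
    border_ids <- border_ids[border_ids > 0]
  } else border_ids <- integer(0)
  sig_comp <- label_components(signal_mask, connectivity = 8)

  rows <- lapply(setdiff(seq_len(n_nuc), border_ids), function(i) {
    nuc <- nuclei == i
    ctr <- which(nuc, arr.ind = TRUE)
    cy <- mean(ctr[, 1]); cx <- mean(ctr[, 2])
    nuc_sig <- nuc & signal_mask
    if (!any(nuc_sig)) {
      return(nc_row(i, cy, cx, NA, NA, NA, 0L, 0L, "empty nuclear region"))
    }
    comp_ids <- sig_comp[nuc_sig]
    comp_ids <- comp_ids[comp_ids > 0]
    best <- as.integer(names(which.max(table(comp_ids))))
    comp <- sig_comp == best
    cyto <- comp & !nuc
    npx <- sum(nuc_sig & comp); cpx <- sum(cyto)
    nmean <- mean(signal[nuc_sig & comp])
    cmean <- if (cpx > 0) mean(signal[cyto]) else NA_real_
    if (npx < min_px) {
      nc_row(i, cy, cx, nmean, cmean, NA, npx, cpx,
             "nuclear region below min_px")
    } else if (cpx < min_px) {
      nc_row(i, cy, cx, nmean, cmean, NA, npx, cpx,
             "cytoplasmic region below min_px")
    } else {
      nc_row(i, cy, cx, nmean, cmean, nmean / cmean, npx, cpx, "ok")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nc_ratio_table", "data.frame")
  out
}

nc_row <- function(id, cy, cx, nmean, cmean, ratio, npx, cpx, reason) {
  data.frame(cell_id = id, centroid_y = cy, centroid_x = cx,
             nuclear_mean = nmean, cytoplasmic_mean = cmean,
             ratio = ratio, nuclear_px = npx, cytoplasmic_px = cpx,
             reason = reason, stringsAsFactors = FALSE)
}

empty_nc_table <- function() {
  out <- nc_row(integer(0), numeric(0), numeric(0), numeric(0), numeric(0),
                numeric(0), integer(0), integer(0), character(0))
  class(out) <- c("nc_ratio_table", "data.frame")
  out
}

#' Parameters of the mask-based N/C quantification pipeline
#'
#' Defaults follow the reference auto-local-threshold conventions (radius
#' 15 px, contrast 15, mid-gray at half the bit-depth maximum); all values
#' are recorded with the output so every run declares its configuration.
#'
#' @param bernsen_radius,contrast_min,midgray Signal-channel Bernsen
#'   threshold parameters (see [bernsen_mask()]).
#' @param mean_radius,mean_c DAPI-channel local-mean threshold parameters
#'   (see [local_mean_mask()]).
#' @param refine_ops Morphological refinements applied to the signal mask,
#'   in order (see [refine_mask()]).
#' @param dapi_refine_ops Refinements applied to the DAPI mask (an
#'   erode/dilate opening removes single-pixel noise speckle).
#' @param min_px Minimum region size for a defined ratio.
#' @param bit_depth Image bit depth (for the `midgray` default).
#' @return List of class `nc_params`.
#' @export
nc_params <- function(bernsen_radius = 15, contrast_min = 15, midgray = NULL,
                      mean_radius = 15, mean_c = 0,
                      refine_ops = "fill_holes",
                      dapi_refine_ops = c("erode", "dilate"),
                      min_px = 10, bit_depth = 8) {
  if (is.null(midgray)) midgray <- (2^bit_depth - 1) / 2
  structure(list(bernsen_radius = bernsen_radius, contrast_min = contrast_min,
                 midgray = midgray, mean_radius = mean_radius,
                 mean_c = mean_c, refine_ops = refine_ops,
                 dapi_refine_ops = dapi_refine_ops, min_px = min_px,
                 bit_depth = bit_depth),
            class = "nc_params")
}

#' Full N/C quantification of a two-channel image
#'
#' Bernsen threshold on the signal channel (then the configured
#' morphological refinements), local-mean threshold on the DAPI channel,
#' and per-cell ratio extraction via [nc_ratio()].
#'
#' @param image A `cell_image` (see [simulate_cell_image()] /
#'   [read_image_tiff()]).
#' @param params An [nc_params()].
#' @return An `nc_ratio_table` with the masks attached as attribute
#'   `"masks"` and the configuration as attribute `"params"`.
#' @export
quantify_nc <- function(image, params = nc_params()) {
  stopifnot(inherits(image, "cell_image"), inherits(params, "nc_params"))
  smask <- bernsen_mask(image$signal, radius = params$bernsen_radius,
                        contrast_min = params$contrast_min,
                        midgray = params$midgray,
                        bit_depth = image$bit_depth)
  smask <- refine_mask(smask, params$refine_ops)
  dmask <- local_mean_mask(image$dapi, radius = params$mean_radius,
                           c = params$mean_c)
  dmask <- refine_mask(dmask, params$dapi_refine_ops)
  out <- nc_ratio(image, smask, dmask, min_px = params$min_px)
  attr(out, "masks") <- list(signal = smask, dapi = dmask)
  attr(out, "params") <- params
  out
}
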