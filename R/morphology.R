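# Binary morphology and connected components with explicit, deterministic
# semantics: logical-matrix masks, offset-shift implementation, replicate
# padding for erosion/dilation, zero padding for labeling.

#' Structuring elements for binary morphology
#'
#' `box_element(3)` is the classic 3x3 square; `disk_element(r)` the disk
#' of radius r.
#'
#' @param size Odd side length of the box.
#' @param radius Disk radius in pixels.
#' @return Logical matrix with odd dimensions; the origin is the center.
#' @export
box_element <- function(size = 3) {
  size <- check_count(size, "size")
  if (size %% 2 == 0) stopf("structuring element size must be odd")
  matrix(TRUE, size, size)
}

#' @rdname box_element
#' @export
disk_element <- function(radius = 1) {
  r <- floor(radius)
  d <- outer((-r:r)^2, (-r:r)^2, "+") <= radius^2
  d
}

se_offsets <- function(se) {
  se <- as.matrix(se)
  if (any(dim(se) %% 2 == 0)) stopf("structuring element must have odd dims")
  cy <- (nrow(se) + 1L) / 2L; cx <- (ncol(se) + 1L) / 2L
  idx <- which(se, arr.ind = TRUE)
  data.frame(dy = idx[, 1] - cy, dx = idx[, 2] - cx)
}

shift_mask <- function(mask, dy, dx, fill) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  out[oky, okx] <- mask[ys[oky], xs[okx], drop = FALSE]
  out
}

#' Binary erosion and dilation
#'
#' Erosion keeps a pixel iff every structuring-element neighbor is
#' foreground; dilation sets a pixel iff any neighbor is. Borders use
#' replicate padding (the edge value extends outward).
#'
#' @param mask Logical matrix.
#' @param se Structuring element (default [box_element()] 3x3).
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, se = box_element(3)) {
  morph(mask, se, all)
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, se = box_element(3)) {
  morph(mask, se, any)
}

morph <- function(mask, se, fold) {
  mask <- as.logical_mask(mask)
  offs <- se_offsets(se)
  r <- max(abs(unlist(offs)), 1)
  p <- pad_replicate(mask, r)
  h <- nrow(mask); w <- ncol(mask)
  acc <- NULL
  for (i in seq_len(nrow(offs))) {
    s <- p[r + offs$dy[i] + seq_len(h), r + offs$dx[i] + seq_len(w)]
    acc <- if (is.null(acc)) s
    else if (identical(fold, all)) acc & s else acc | s
  }
  acc
}

as.logical_mask <- function(mask) {
  m <- as.matrix(mask)
  storage.mode(m) <- "logical"
  m
}

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border (4-connectivity
#' on the background, the dual of 8-connected foreground) become
#' foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  mask <- as.logical_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- bg[, 1]; reach[, w] <- bg[, w]
  offs <- data.frame(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
  repeat {
    grown <- reach
    for (i in 1:4) {
      grown <- grown | shift_mask(reach, offs$dy[i], offs$dx[i], FALSE)
    }
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

#' Apply an ordered sequence of morphological refinements
#'
#' @param mask Logical matrix.
#' @param ops Character vector drawn from `"erode"`, `"dilate"`,
#'   `"fill_holes"`, applied in order; empty means identity.
#' @param se Structuring element for erode/dilate.
#' @return Logical matrix.
#' @export
refine_mask <- function(mask, ops = character(0), se = box_element(3)) {
  mask <- as.logical_mask(mask)
  for (op in ops) {
    mask <- switch(op,
      erode = erode_mask(mask, se),
      dilate = dilate_mask(mask, se),
      fill_holes = fill_holes(mask),
      stopf("unknown refinement op '%s'", op))
  }
  mask
}

#' Label connected components of a binary mask
#'
#' Iterative label propagation: every foreground pixel starts with a unique
#' id and repeatedly adopts the maximum id among its neighbors until
#' stable, then labels are renumbered 1..k in first-pixel order.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as.logical_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0, h, w)
  lab[mask] <- seq_len(sum(mask))
  offs <- if (connectivity == 8) {
    expand.grid(dy = -1:1, dx = -1:1)[-5, ]
  } else if (connectivity == 4) {
    data.frame(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
  } else stopf("connectivity must be 4 or 8")
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      new <- pmax(new, shift_mask(lab, offs$dy[i], offs$dx[i], 0))
    }
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- unique(lab[lab > 0])
  out <- matrix(0L, h, w)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}
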