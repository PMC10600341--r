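# Readers/writers for the standard exchange formats used around the
# pipeline: 10x-style MTX triplets, GMT gene sets, multi-page TIFF images.

#' Write a count matrix as an MTX triplet plus cell metadata
#'
#' Writes `matrix.mtx` (genes x cells, Matrix Market), `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.csv` (barcode, group, and optionally
#' true_phase) into `dir`, following the 10x Genomics layout.
#'
#' @param x A [count_matrix()].
#' @param dir Output directory (created if missing).
#' @param true_phase Optional per-cell true phase labels to record.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir, true_phase = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(x$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "features.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  meta <- data.frame(barcode = x$cell_ids, group = as.character(x$group))
  if (!is.null(true_phase)) meta$true_phase <- true_phase[x$cell_ids]
  write.csv(meta, file.path(dir, "cell_metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an MTX triplet directory back into a count matrix
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   and optionally `cell_metadata.csv`.
#' @return A [count_matrix()]; if metadata includes `true_phase` it is
#'   attached as attribute `"true_phase"`.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- t(m)
  dimnames(counts) <- list(cells, genes)
  group <- "all"
  tp <- NULL
  meta_path <- file.path(dir, "cell_metadata.csv")
  if (file.exists(meta_path)) {
    meta <- read.csv(meta_path)
    group <- meta$group[match(cells, meta$barcode)]
    if ("true_phase" %in% names(meta)) {
      tp <- setNames(meta$true_phase[match(cells, meta$barcode)], cells)
    }
  }
  out <- count_matrix(counts, group = group)
  if (!is.null(tp)) attr(out, "true_phase") <- tp
  out
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated — name, description, then member
#' genes. Lines whose names are not cell-cycle phases are kept too; use
#' [phase_gene_sets()] on the result to enforce the five-phase contract.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stopf("malformed GMT line: %s", substr(ln, 1, 60))
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (e.g. a [phase_gene_sets()]).
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "germcycle") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a two-channel image as a multi-page TIFF
#'
#' Page 0 is DAPI, page 1 the signal channel, stored at the image's bit
#' depth.
#'
#' @param image A `cell_image` from [simulate_cell_image()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "cell_image"))
  maxval <- 2^image$bit_depth - 1
  pages <- list(image$dapi / maxval, image$signal / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = image$bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF as a two-channel image
#'
#' @param path TIFF path (page order: DAPI, signal — configurable).
#' @param dapi_page,signal_page 1-based page indices.
#' @param bit_depth Bit depth used to rescale to integer intensities.
#' @return A `cell_image`.
#' @export
read_image_tiff <- function(path, dapi_page = 1L, signal_page = 2L,
                            bit_depth = 8) {
  pages <- tiff::readTIFF(path, all = TRUE)
  maxval <- 2^bit_depth - 1
  to_int <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.integer(round(p * maxval)), nrow(p), ncol(p))
  }
  structure(list(dapi = to_int(pages[[dapi_page]]),
                 signal = to_int(pages[[signal_page]]),
                 bit_depth = bit_depth),
            class = "cell_image")
}
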