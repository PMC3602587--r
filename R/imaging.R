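#' Count nuclei by thresholding, connected components and clump breaking
#'
#' Transparent object-based segmentation for whole-well nuclei images:
#' foreground by Otsu (on the max-normalized image, making the count
#' invariant to positive intensity rescaling) or a fixed intensity threshold;
#' 8-connected components; objects below `min_area` removed; and, when
#' `clump_breaking` is on, concave multi-nucleus objects split by a
#' distance-transform watershed whose seed neighborhood radius is
#' `min_seed_distance` pixels.
#'
#' @param pixels 2-D non-negative intensity matrix (grayscale image).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold raw-intensity threshold, required when
#'   `threshold_method = "fixed"`.
#' @param min_area minimum object area in pixels (default 4).
#' @param clump_breaking split touching nuclei (default `TRUE`).
#' @param min_seed_distance minimum separation of watershed seeds, pixels.
#' @param watershed_tolerance minimum distance-map depth separating two
#'   objects; touching round nuclei meet in a shallow saddle, so the default
#'   (0.5 px) is deliberately small.
#' @return list of class `nuclei_count`: `count`, `object_areas` (named
#'   integer vector), `label_map` (integer matrix, 0 = background).
#' @export
segment_nuclei <- function(pixels, threshold_method = c("otsu", "fixed"),
                           fixed_threshold = NULL, min_area = 4,
                           clump_breaking = TRUE, min_seed_distance = 2,
                           watershed_tolerance = 0.5) {
  threshold_method <- match.arg(threshold_method)
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("empty image", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  mx <- max(pixels)
  if (threshold_method == "otsu") {
    if (mx == 0) {
      return(structure(list(count = 0L, object_areas = integer(0),
                            label_map = matrix(0L, nrow(pixels), ncol(pixels))),
                       class = "nuclei_count"))
    }
    norm <- pixels / mx
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else {
    if (is.null(fixed_threshold)) {
      stop("fixed_threshold required for threshold_method = 'fixed'",
           call. = FALSE)
    }
    mask <- pixels > fixed_threshold
  }
  mask <- matrix(as.numeric(mask), nrow(pixels), ncol(pixels))
  if (clump_breaking) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = watershed_tolerance,
                              ext = min_seed_distance)
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(pixels))
  } else {
    lab <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask))),
                  nrow(pixels))
    lab <- .merge_diagonal_labels(lab)
  }
  lab <- .drop_small_objects(lab, min_area)
  areas <- table(lab[lab > 0L])
  structure(list(count = length(areas),
                 object_areas = stats::setNames(as.integer(areas),
                                                names(areas)),
                 label_map = lab),
            class = "nuclei_count")
}

# bwlabel is 4-connective; union labels that touch diagonally to get
# 8-connectivity.
.merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) == 0L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

.drop_small_objects <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Nuclei-count proliferation readout as percent inhibition
#'
#' Applies the screen's %I normalization with nuclei counts in place of
#' fluorescence: 0% at the vehicle high-control mean count, 100% at the
#' full-kill low-control mean count.
#'
#' @param counts sample nuclei counts.
#' @param high_counts,low_counts control nuclei counts (vectors; means used).
#' @return percent inhibition, same length as `counts`.
#' @export
proliferation_inhibition <- function(counts, high_counts, low_counts) {
  percent_inhibition(counts, mean(high_counts), mean(low_counts))
}

#' Read a grayscale image file
#'
#' 8/16-bit grayscale PNG or TIFF; multi-channel images are averaged to one
#' channel.
#' @param path image path (extension decides the reader).
#' @return numeric intensity matrix in [0, 1].
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale PNG
#' @param pixels intensity matrix; rescaled to [0, 1] by its maximum.
#' @param path output path (.png).
#' @export
write_image_gray <- function(pixels, path) {
  mx <- max(pixels)
  png::writePNG(if (mx > 0) pixels / mx else pixels, path)
  invisible(path)
}
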