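#' Calibrated intensity image
#'
#' Container for a single-channel image with a physical pixel calibration.
#' Intensities are stored as doubles in \[0, 1\] regardless of the source bit
#' depth, so that thresholds are comparable across 8- and 16-bit acquisitions.
#' Pixels are addressed R-natively as `pixels[row, col]`, 1-based, with the
#' origin at the top-left of the image.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\], at least 2 x 2.
#' @param pixel_size_mm edge length of one pixel in mm (> 0). There is no
#'   default: the camera calibration must be supplied by the user.
#' @param bit_depth_src integer bit depth of the source file (8 or 16);
#'   provenance only, `NA` when unknown.
#' @return An object of class `intensity_grid`.
#' @export
intensity_grid <- function(pixels, pixel_size_mm, bit_depth_src = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2 pixels")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a single positive number")
  structure(
    list(pixels = unname(pixels),
         pixel_size_mm = as.numeric(pixel_size_mm),
         bit_depth_src = as.integer(bit_depth_src)),
    class = "intensity_grid")
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("<intensity_grid> %d x %d px, %.4g mm/px (%.3g x %.3g mm), range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              nrow(x$pixels) * x$pixel_size_mm, ncol(x$pixels) * x$pixel_size_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_grid <- function(x) dim(x$pixels)

# Accept either an intensity_grid or a bare numeric matrix.
as_pixels <- function(x) {
  if (inherits(x, "intensity_grid")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an intensity_grid or a numeric matrix")
}

as_mask <- function(mask) {
  if (inherits(mask, "colony_mask")) mask <- mask$mask
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  if (is.matrix(mask) && is.numeric(mask)) return(mask > 0)
  stop("expected a logical matrix mask")
}

#' Read a grayscale image with physical calibration
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF and rescales intensities
#' to \[0, 1\] by the source bit depth's maximum.
#'
#' @param path path to a PNG or TIFF file.
#' @param pixel_size_mm pixel calibration in mm (mandatory; acquisition
#'   hardware is not parsed for metadata).
#' @return An [intensity_grid].
#' @export
read_image <- function(path, pixel_size_mm) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    hdr <- readBin(path, "raw", n = 26L)
    depth <- as.integer(hdr[25L])
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(px, "bits.per.sample")
    if (is.null(depth)) depth <- NA_integer_
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    else stop("multi-channel image: supply single-channel grayscale input")
  }
  attributes(px) <- list(dim = dim(px))
  intensity_grid(px, pixel_size_mm, bit_depth_src = depth)
}

#' Write an intensity grid to PNG or TIFF
#'
#' @param grid an [intensity_grid] or numeric matrix in \[0, 1\].
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @param bits target bit depth, 8 or 16 (16 only for TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path, bits = 8L) {
  px <- as_pixels(grid)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) stop("PNG output is written at 8 bit; use TIFF for 16 bit")
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Otsu's threshold
#'
#' Histogram-based global threshold maximizing the between-class intensity
#' variance. The histogram uses `n_bins` equal-width bins spanning the
#' observed intensity range, so the returned threshold is equivariant under
#' affine rescaling of the intensities. Candidate thresholds are the interior
#' bin boundaries; among tied maxima the middle boundary is taken, making the
#' result deterministic (and centred for two-level images).
#'
#' @param grid an [intensity_grid] or numeric matrix.
#' @param n_bins number of histogram bins (default 256, the 8-bit convention).
#' @return Threshold value strictly between the image minimum and maximum.
#' @export
otsu_threshold <- function(grid, n_bins = 256L) {
  otsu_core(as.vector(as_pixels(grid)), n_bins)$threshold
}

# Otsu workhorse: threshold plus the separability measure
# eta = between-class variance at the optimum / total (binned) variance.
# eta ~ 1 for a cleanly bimodal histogram, ~0.64 for pure Gaussian noise.
otsu_core <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0)
    stop("degenerate input: constant image has no Otsu threshold")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  span <- hi - lo
  idx <- pmin(floor((v - lo) / span * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * span / n_bins
  n <- length(v)
  w1 <- cumsum(counts)[-n_bins] / n
  s1 <- cumsum(counts * mids)[-n_bins]
  mu <- sum(counts * mids) / n
  mu1 <- ifelse(w1 > 0, s1 / (n * w1), 0)
  w2 <- 1 - w1
  mu2 <- ifelse(w2 > 0, (mu - w1 * mu1) / w2, 0)
  sigma_b <- w1 * w2 * (mu1 - mu2)^2
  top <- max(sigma_b)
  ties <- which(sigma_b >= top - 1e-12 * max(top, 1))
  k <- ties[ceiling(length(ties) / 2)]
  sigma_tot <- sum(counts * (mids - mu)^2) / n
  list(threshold = lo + k / n_bins * span,
       eta = if (sigma_tot > 0) sigma_b[k] / sigma_tot else 0)
}

#' Connected-component labelling
#'
#' Labels the `TRUE` pixels of a mask such that two pixels share a label iff
#' they are connected under the chosen neighbourhood. Labels are consecutive
#' integers 1..n assigned in column-major order of each component's first
#' pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default, edge+corner adjacency) or 4 (edge only).
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
connected_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (!any(mask)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "n_labels") <- 0L
    return(out)
  }
  lab <- EBImage::bwlabel(mask)  # 4-connected base labelling
  if (connectivity == 8L && max(lab) > 1L)
    lab <- merge_diagonal_labels(lab)
  relabel_consecutive(lab)
}

# Upgrade a 4-connected labelling to 8-connectivity: union-find over the
# label graph, joining labels that touch diagonally.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  n <- max(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),   # \ diagonal
    cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))   # / diagonal
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  pos <- lab > 0L
  lab[pos] <- root[lab[pos]]
  lab
}

# Renumber positive labels to 1..n in column-major order of first occurrence.
relabel_consecutive <- function(lab) {
  lab <- matrix(as.numeric(lab), nrow(lab), ncol(lab))
  pos <- lab > 0
  u <- unique(lab[pos])           # column-major first-occurrence order
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[pos] <- as.integer(match(lab[pos], u))
  attr(out, "n_labels") <- length(u)
  out
}

#' Watershed dissection of touching objects
#'
#' Partitions the `TRUE` pixels of a mask into objects by flooding the
#' Euclidean distance transform of the mask interior; touching convex blobs
#' (e.g. two overlapping cell aggregates) are split at the waist between
#' their distance-map maxima. Maxima whose height above the separating saddle
#' is below `tolerance` are merged, so an isolated round object yields a
#' single label.
#'
#' @param mask logical matrix.
#' @param tolerance minimum depth (in px of distance-map height) separating
#'   two retained catchment basins; default 1.
#' @return Integer label matrix (0 = background) with attribute `n_labels`;
#'   the positive labels partition the mask.
#' @export
watershed_split <- function(mask, tolerance = 1) {
  mask <- as_mask(mask)
  if (!any(mask)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "n_labels") <- 0L
    return(out)
  }
  d <- EBImage::distmap(mask)
  w <- EBImage::watershed(d, tolerance = tolerance, ext = 1L)
  relabel_consecutive(as.matrix(w))
}

#' Euclidean distance to the mask boundary
#'
#' For each `TRUE` pixel, the Euclidean distance to the nearest `FALSE`
#' pixel; `FALSE` pixels map to 0. The image border is not treated as
#' background: distances are measured to actual `FALSE` pixels only.
#'
#' @param mask logical matrix with at least one `TRUE` and one `FALSE` pixel.
#' @return Numeric matrix of distances.
#' @export
distance_to_boundary <- function(mask) {
  mask <- as_mask(mask)
  if (all(mask) || !any(mask))
    stop("degenerate input: mask must contain both TRUE and FALSE pixels")
  as.matrix(EBImage::distmap(mask))
}

#' Clean a mask to one filled component
#'
#' Keeps only the largest connected component (8-connectivity; ties broken
#' toward the first in column-major order) and fills its interior holes,
#' i.e. background regions not reachable from the image border.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return Logical matrix.
#' @export
fill_holes_and_largest <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("degenerate input: empty mask")
  lab <- connected_components(mask, 8L)
  n <- attr(lab, "n_labels")
  if (n > 1L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which.max(areas)
    mask <- lab == keep
  }
  as.matrix(EBImage::fillHull(mask)) > 0
}

#' Read a flat key-value analysis configuration
#'
#' Reads a YAML file of scalar analysis parameters (e.g. `pixel_size_mm`,
#' `otsu_bins`, `watershed_tolerance`, `connectivity`, `edge_depth_px`).
#'
#' @param path path to a YAML file.
#' @return Named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
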