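# Competitive-biofilm segregation analysis: paired RFP/GFP colony images are
# fused, the colony footprint is found by iteratively expanding the brightest
# region with Otsu's threshold, channels are normalised for autofluorescence
# and gain, and genotype fractions are read off the whole colony and a ring
# 50 px inside the colony edge.

#' Fuse two fluorescence channels into one gray-level image
#'
#' Pixelwise mean of the RFP and GFP channels; the fused image drives colony
#' edge detection, which must not prefer either genotype.
#'
#' @param rfp,gfp [intensity_grid]s (or matrices) of the same shape.
#' @return Fused [intensity_grid].
#' @export
fuse_channels <- function(rfp, gfp) {
  r <- as_pixels(rfp); g <- as_pixels(gfp)
  if (!identical(dim(r), dim(g))) stop("channels differ in shape")
  psz <- if (inherits(rfp, "intensity_grid")) rfp$pixel_size_mm else 1
  intensity_grid((r + g) / 2, psz)
}

#' Detect the colony footprint by iterative Otsu expansion
#'
#' Starts from the brightest region (pixels above the whole-image Otsu
#' threshold) and grows it outwards: at each iteration Otsu's threshold is
#' recomputed on the pixels still outside the mask, and newly-above-threshold
#' pixels 8-connected to the current mask are accreted. This captures dimmer
#' colony peripheries that a single global threshold misses.
#'
#' Expansion needs a stopping rule, and two guards are applied. First, the
#' outside histogram must still be genuinely bimodal: Otsu's separability
#' measure eta (between-class variance at the optimum over total variance)
#' must reach `min_separability`; once only featureless background remains,
#' eta falls toward its pure-Gaussian-noise level (~0.64) and growth stops
#' instead of accreting a noise halo. Second, growth stops when an iteration
#' adds less than `stop_fraction` of the current area, when the remaining
#' outside pixels are effectively constant, or after `max_iter` iterations.
#' The final mask is reduced to its largest connected component with holes
#' filled.
#'
#' @param fused fused gray-level [intensity_grid] (or matrix).
#' @param max_iter maximum expansion iterations; default 10.
#' @param stop_fraction relative added-area stopping threshold; default
#'   0.005.
#' @param min_separability minimum Otsu separability (eta) of the outside
#'   pixels required to keep expanding; default 0.8.
#' @return Object of class `colony_mask`: list with `mask` (logical matrix),
#'   `n_iterations` and `area_px`.
#' @export
detect_colony <- function(fused, max_iter = 10L, stop_fraction = 0.005,
                          min_separability = 0.8) {
  px <- as_pixels(fused)
  t1 <- otsu_threshold(px)  # errors on constant image
  mask <- px > t1
  iter <- 1L
  while (iter < max_iter) {
    outside <- px[!mask]
    if (length(outside) < 2L || diff(range(outside)) < 1e-6) break
    ot <- tryCatch(otsu_core(outside), error = function(e) NULL)
    if (is.null(ot) || ot$eta < min_separability) break
    tk <- ot$threshold
    cand <- !mask & px > tk
    if (!any(cand)) break
    # accrete candidate components 8-connected to the current mask
    lab <- connected_components(cand | mask, 8L)
    touch <- unique(lab[mask & lab > 0L])
    added <- cand & matrix(lab %in% touch, nrow(px), ncol(px))
    n_added <- sum(added)
    iter <- iter + 1L
    if (n_added == 0L) break
    mask <- mask | added
    if (n_added < stop_fraction * sum(mask)) break
  }
  mask <- fill_holes_and_largest(mask)
  structure(list(mask = mask, n_iterations = iter, area_px = sum(mask)),
            class = "colony_mask")
}

#' @export
print.colony_mask <- function(x, ...) {
  cat(sprintf("<colony_mask> %d px after %d Otsu iteration(s)\n",
              x$area_px, x$n_iterations))
  invisible(x)
}

#' Normalise fluorescence channels inside a colony
#'
#' Per channel: the median intensity outside the colony (medium
#' autofluorescence) is subtracted and clamped at zero, then intensities are
#' divided by the channel's 99th percentile inside the colony, equalising the
#' different magnitudes of RFP and GFP fluorescence.
#'
#' @param rfp,gfp channel [intensity_grid]s (or matrices).
#' @param colony a [detect_colony()] result (or logical matrix).
#' @return List with matrices `rfp` and `gfp`, non-negative, ~1 at full
#'   signal.
#' @export
normalize_channels <- function(rfp, gfp, colony) {
  mask <- as_mask(colony)
  if (mean(!mask) < 0.01)
    stop("colony mask leaves less than 1% background for autofluorescence")
  norm1 <- function(ch, name) {
    px <- as_pixels(ch)
    if (!identical(dim(px), dim(mask))) stop("channel/mask shape mismatch")
    bg <- stats::median(px[!mask])
    px <- pmax(px - bg, 0)
    top <- stats::quantile(px[mask], 0.99, names = FALSE, type = 7)
    if (!is.finite(top) || top <= 0)
      stop("degenerate ", name, " channel: no signal above autofluorescence")
    px / top
  }
  list(rfp = norm1(rfp, "RFP"), gfp = norm1(gfp, "GFP"))
}

#' Ring of pixels at a fixed depth inside the colony edge
#'
#' A one-pixel-wide contour `depth_px` inside the colony edge: colony pixels
#' whose Euclidean distance to the edge contour lies in
#' \[depth - 0.5, depth + 0.5). The boundary pixels of the mask (distance 1
#' to the nearest background pixel) sit at depth 0, so `depth_px = 0` selects
#' the boundary contour itself.
#'
#' @param colony a `colony_mask` or logical matrix.
#' @param depth_px distance from the edge, px (>= 0, < colony inradius).
#' @return Logical matrix selecting the ring.
#' @export
edge_ring <- function(colony, depth_px) {
  mask <- as_mask(colony)
  stopifnot(depth_px >= 0)
  d <- distance_to_boundary(mask) - 1  # boundary contour at depth 0
  ring <- mask & d >= depth_px - 0.5 & d < depth_px + 0.5
  if (!any(ring))
    stop("empty ring: depth ", depth_px, " px is at or beyond the colony inradius")
  ring
}

#' Fraction of region pixels dominated by the RFP channel
#'
#' Counts region pixels whose normalised RFP intensity strictly exceeds the
#' normalised GFP intensity, over all region pixels; ties count against RFP.
#'
#' @param rfp_norm,gfp_norm normalised channel matrices (see
#'   [normalize_channels()]).
#' @param region non-empty logical matrix.
#' @return Fraction in \[0, 1\].
#' @export
red_fraction <- function(rfp_norm, gfp_norm, region) {
  region <- as_mask(region)
  if (!any(region)) stop("empty region")
  r <- as_pixels(rfp_norm); g <- as_pixels(gfp_norm)
  mean(r[region] > g[region])
}

#' Genotype segregation metrics for a competing colony pair
#'
#' Computes the RFP pixel fraction on the 50-px edge ring and over the whole
#' colony, identifies the superior (majority-at-the-edge) channel, and forms
#' the genotypic dominance ratio superior/inferior from the edge fractions.
#' A fully monopolised edge (inferior fraction 0) is reported at `ratio_cap`.
#' The ratio is banded into five categories by `category_bounds` (half-open
#' bins; category 1 = balanced, category 5 = fully dominated edge).
#'
#' @param rfp_norm,gfp_norm normalised channels from [normalize_channels()].
#' @param colony a `colony_mask` (or logical matrix).
#' @param depth_px edge-ring depth; default 50 px.
#' @param category_bounds 4 ascending ratio bounds; default
#'   `c(1.5, 4, 20, 100)`.
#' @param ratio_cap ratio reported for a fully monopolised edge; default
#'   1000.
#' @return Object of class `segregation_result`: edge and whole-colony RFP
#'   fractions, `superior_channel`, `genotype_ratio`, `ratio_category`,
#'   `edge_depth_px`, `colony_area_px`.
#' @export
segregation_metrics <- function(rfp_norm, gfp_norm, colony, depth_px = 50L,
                                category_bounds = c(1.5, 4, 20, 100),
                                ratio_cap = 1000) {
  stopifnot(length(category_bounds) == 4L, all(diff(category_bounds) > 0),
            ratio_cap > max(category_bounds))
  mask <- as_mask(colony)
  ring <- edge_ring(mask, depth_px)
  f_edge <- red_fraction(rfp_norm, gfp_norm, ring)
  f_whole <- red_fraction(rfp_norm, gfp_norm, mask)
  superior <- if (f_edge >= 0.5) "RFP" else "GFP"
  hi <- max(f_edge, 1 - f_edge); lo <- min(f_edge, 1 - f_edge)
  ratio <- if (lo == 0) ratio_cap else min(hi / lo, ratio_cap)
  category <- findInterval(ratio, category_bounds) + 1L
  structure(list(edge_red_fraction = f_edge,
                 whole_red_fraction = f_whole,
                 superior_channel = superior,
                 genotype_ratio = ratio,
                 ratio_category = category,
                 edge_depth_px = as.integer(depth_px),
                 colony_area_px = sum(mask)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Biofilm segregation (edge ring at %d px, colony %d px)\n",
    "  RFP fraction: edge %.3f, whole colony %.3f\n",
    "  superior channel %s, genotype ratio %.3g (category %d/5)\n"),
    x$edge_depth_px, x$colony_area_px, x$edge_red_fraction,
    x$whole_red_fraction, x$superior_channel, x$genotype_ratio,
    x$ratio_category))
  invisible(x)
}

#' Full segregation pipeline from raw channel images
#'
#' Convenience wrapper chaining [fuse_channels()], [detect_colony()],
#' [normalize_channels()] and [segregation_metrics()].
#'
#' @param rfp,gfp raw channel [intensity_grid]s.
#' @param depth_px,category_bounds,ratio_cap see [segregation_metrics()].
#' @param max_iter,stop_fraction see [detect_colony()].
#' @return A `segregation_result` with the `colony_mask` attached as
#'   attribute `colony`.
#' @export
analyze_biofilm <- function(rfp, gfp, depth_px = 50L,
                            category_bounds = c(1.5, 4, 20, 100),
                            ratio_cap = 1000,
                            max_iter = 10L, stop_fraction = 0.005) {
  fused <- fuse_channels(rfp, gfp)
  colony <- detect_colony(fused, max_iter = max_iter,
                          stop_fraction = stop_fraction)
  norm <- normalize_channels(rfp, gfp, colony)
  res <- segregation_metrics(norm$rfp, norm$gfp, colony, depth_px,
                             category_bounds, ratio_cap)
  attr(res, "colony") <- colony
  res
}
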