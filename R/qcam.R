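# Quantitative cell aggregation microscopy (QCAM): plate-scan images of
# spread cell aggregates are background-corrected, segmented at one global
# threshold shared by all images, dissected by watershed, filtered for dust,
# and summarised as total aggregate area per size class per cm^2 of field.

#' Size-class boundaries for aggregate areas
#'
#' Three strictly increasing positive bounds (mm^2) split object areas into
#' classes I (< b1), II (\[b1, b2)), III (\[b2, b3)) and IV (>= b3); bins are
#' half-open so every area maps to exactly one class. The defaults are
#' logarithmic decades (0.001, 0.01, 0.1), placing large aggregates of up to
#' ~1 mm^2 in class IV; they are configurable.
#'
#' @param bounds_mm2 numeric vector of 3 increasing positive bounds.
#' @return Object of class `size_class_config`.
#' @export
size_class_config <- function(bounds_mm2 = c(0.001, 0.01, 0.1)) {
  stopifnot(length(bounds_mm2) == 3L, all(bounds_mm2 > 0),
            all(diff(bounds_mm2) > 0))
  structure(list(bounds_mm2 = as.numeric(bounds_mm2)),
            class = "size_class_config")
}

size_class_labels <- c("I", "II", "III", "IV")

classify_area <- function(area_mm2, classes) {
  idx <- findInterval(area_mm2, classes$bounds_mm2) + 1L
  factor(size_class_labels[idx], levels = size_class_labels)
}

#' Background correction of an aggregate scene
#'
#' Subtracts the scene from an averaged cell-free background image, which
#' both corrects the inhomogeneous illumination of the agar and inverts the
#' intensity scale: aggregates (darker than the agar) come out bright, agar
#' regions come out near zero. Negative differences are clamped to 0.
#'
#' @param scene,background [intensity_grid]s of the same shape and pixel
#'   size.
#' @return Corrected [intensity_grid].
#' @export
background_correct <- function(scene, background) {
  s <- as_pixels(scene); b <- as_pixels(background)
  if (!identical(dim(s), dim(b)))
    stop("scene and background differ in shape")
  psz <- if (inherits(scene, "intensity_grid")) scene$pixel_size_mm
         else if (inherits(background, "intensity_grid")) background$pixel_size_mm
         else stop("at least one input must carry a pixel size")
  if (inherits(scene, "intensity_grid") &&
      inherits(background, "intensity_grid") &&
      !isTRUE(all.equal(scene$pixel_size_mm, background$pixel_size_mm)))
    stop("scene and background differ in pixel size")
  intensity_grid(pmin(pmax(b - s, 0), 1), psz)
}

#' Segment cell aggregates at a global threshold
#'
#' Thresholds the background-corrected image at one manually chosen global
#' value (identical across all images of an experiment), dissects touching
#' aggregates by watershed on the distance transform, and removes objects
#' smaller than `min_object_area_px` — the automated stand-in for manual
#' removal of dust specks. Surviving labels are renumbered 1..L.
#'
#' @param corrected background-corrected [intensity_grid] (or matrix).
#' @param global_threshold threshold strictly in (0, 1).
#' @param min_object_area_px smallest retained object, px; default 5.
#' @param ws_tolerance watershed basin-merging tolerance; default 1.
#' @return Integer label matrix with attribute `n_labels`.
#' @export
segment_aggregates <- function(corrected, global_threshold,
                               min_object_area_px = 5L,
                               ws_tolerance = 1) {
  if (!is.numeric(global_threshold) || length(global_threshold) != 1L ||
      global_threshold <= 0 || global_threshold >= 1)
    stop("`global_threshold` must lie strictly in (0, 1)")
  px <- as_pixels(corrected)
  mask <- px > global_threshold
  lab <- watershed_split(mask, tolerance = ws_tolerance)
  n <- attr(lab, "n_labels")
  if (n > 0L && min_object_area_px > 1L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    drop <- which(areas < min_object_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_consecutive(lab)
}

#' Measure labelled aggregates
#'
#' @param labels integer label matrix (0 = background).
#' @param pixel_size_mm pixel calibration, mm.
#' @param classes a [size_class_config].
#' @return Data frame with one row per label: `label`, `area_px`,
#'   `area_mm2` (= area_px * pixel_size_mm^2) and `size_class`.
#' @export
measure_aggregates <- function(labels, pixel_size_mm,
                               classes = size_class_config()) {
  stopifnot(pixel_size_mm > 0)
  n <- max(0L, max(labels))
  areas <- if (n > 0L) tabulate(labels[labels > 0L], nbins = n) else integer()
  if (any(areas == 0L)) stop("label grid has gaps: labels must be 1..n")
  area_mm2 <- areas * pixel_size_mm^2
  data.frame(label = seq_len(n),
             area_px = areas,
             area_mm2 = area_mm2,
             size_class = classify_area(area_mm2, classes))
}

#' Per-size-class aggregate area statistic
#'
#' The aggregation read-out: total area (mm^2) covered by all aggregates of
#' each size class, normalised per 1 cm^2 of imaged field, plus object
#' counts. Classes with no members report 0.
#'
#' @param objects data frame from [measure_aggregates()].
#' @param imaged_area_cm2 area of the imaged field, cm^2 (> 0).
#' @return Object of class `aggregate_size_distribution`: a data frame with
#'   columns `size_class`, `n_objects`, `total_area_mm2`,
#'   `normalized_mm2_per_cm2`; attribute `imaged_area_cm2`.
#' @export
size_distribution <- function(objects, imaged_area_cm2) {
  stopifnot(is.numeric(imaged_area_cm2), imaged_area_cm2 > 0)
  cls <- factor(objects$size_class, levels = size_class_labels)
  out <- data.frame(
    size_class = factor(size_class_labels, levels = size_class_labels),
    n_objects = as.integer(tapply(objects$area_mm2, cls, length,
                                  default = 0L)),
    total_area_mm2 = as.numeric(tapply(objects$area_mm2, cls, sum,
                                       default = 0)))
  out$normalized_mm2_per_cm2 <- out$total_area_mm2 / imaged_area_cm2
  rownames(out) <- NULL
  structure(out, imaged_area_cm2 = imaged_area_cm2,
            class = c("aggregate_size_distribution", "data.frame"))
}

#' @export
print.aggregate_size_distribution <- function(x, ...) {
  cat(sprintf("Aggregate size distribution (field %.3g cm^2)\n",
              attr(x, "imaged_area_cm2")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full aggregation-microscopy pipeline over replicate images
#'
#' Applies background correction, global-threshold segmentation, watershed
#' dissection, dust filtering and size-class summarisation to each scene, and
#' reports across-replicate mean and SD of the normalised per-class areas.
#'
#' @param scenes list of [intensity_grid]s, or character vector of image
#'   paths (read with `pixel_size_mm`).
#' @param background the averaged cell-free background image (grid or path).
#' @param pixel_size_mm pixel calibration, mm (used for paths and area
#'   conversion).
#' @param global_threshold shared global threshold in (0, 1).
#' @param min_object_area_px dust filter, px; default 5.
#' @param classes a [size_class_config].
#' @param imaged_area_cm2 field area per image, cm^2; default computed from
#'   the image dimensions and `pixel_size_mm`.
#' @param ws_tolerance watershed tolerance; default 1.
#' @return Object of class `qcam_result`: list with `per_image` (data frame
#'   of per-image, per-class rows), `summary` (per-class mean and SD of the
#'   normalised areas) and `n_images`.
#' @export
run_qcam <- function(scenes, background, pixel_size_mm,
                     global_threshold, min_object_area_px = 5L,
                     classes = size_class_config(),
                     imaged_area_cm2 = NULL,
                     ws_tolerance = 1) {
  if (inherits(scenes, "intensity_grid")) scenes <- list(scenes)
  if (length(scenes) < 1L) stop("need at least one scene")
  load1 <- function(x) if (is.character(x)) read_image(x, pixel_size_mm) else x
  background <- load1(background)
  names_in <- if (is.character(scenes)) basename(scenes)
              else if (!is.null(names(scenes))) names(scenes)
              else sprintf("image%02d", seq_along(scenes))
  if (is.character(scenes)) scenes <- lapply(scenes, load1)

  per_image <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    g <- scenes[[i]]
    if (is.null(imaged_area_cm2)) {
      d <- dim(as_pixels(g))
      field <- prod(d) * pixel_size_mm^2 / 100  # mm^2 -> cm^2
    } else field <- imaged_area_cm2
    corrected <- background_correct(g, background)
    lab <- tryCatch(
      segment_aggregates(corrected, global_threshold, min_object_area_px,
                         ws_tolerance),
      error = function(e) stop("image '", names_in[i],
                               "' failed at segmentation: ",
                               conditionMessage(e)))
    objs <- measure_aggregates(lab, pixel_size_mm, classes)
    dist <- size_distribution(objs, field)
    cbind(image = names_in[i], as.data.frame(dist))
  }))

  if (length(scenes) < 2L)
    warning("only one image: replicate SD is undefined and reported as 0")
  agg <- function(f, default = 0) as.numeric(tapply(
    per_image$normalized_mm2_per_cm2, per_image$size_class, f,
    default = default))
  summary <- data.frame(
    size_class = factor(size_class_labels, levels = size_class_labels),
    mean_normalized_mm2_per_cm2 = agg(mean),
    sd_normalized_mm2_per_cm2 = if (length(scenes) < 2L)
      rep(0, 4L) else agg(stats::sd))
  structure(list(per_image = per_image, summary = summary,
                 n_images = length(scenes),
                 global_threshold = global_threshold),
            class = "qcam_result")
}

#' @export
print.qcam_result <- function(x, ...) {
  cat(sprintf("QCAM analysis: %d image(s), global threshold %.3g\n",
              x$n_images, x$global_threshold))
  cat("Across-replicate summary (normalised mm^2 per cm^2):\n")
  print.data.frame(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.qcam_result <- function(object, ...) object$summary
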