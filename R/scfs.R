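# Single-cell force spectroscopy analytics: vendor-neutral force-distance
# curve I/O, linear baseline correction on the fully-separated retract tail,
# maximum adhesion force (F_max) extraction, and group/kinetics summaries.

#' Force-distance curve
#'
#' One approach/retract cycle of a single-cell force spectroscopy
#' measurement. Separations are in um, forces in nN; each segment must hold
#' at least 25 samples with monotone separations (approach decreasing toward
#' contact, retract increasing away from it).
#'
#' @param approach,retract data frames with numeric columns `separation_um`
#'   and `force_nN`.
#' @param contact_time_s cell-cell contact time, s (> 0).
#' @param metadata named list of labels (probe, target, variant, ...).
#' @return Object of class `force_curve`.
#' @export
force_curve <- function(approach, retract, contact_time_s,
                        metadata = list()) {
  check_seg <- function(seg, name, direction) {
    if (!is.data.frame(seg) ||
        !all(c("separation_um", "force_nN") %in% names(seg)))
      stop(name, " segment needs columns separation_um and force_nN")
    if (nrow(seg) < 25L)
      stop(name, " segment has fewer than 25 samples")
    if (any(!is.finite(seg$separation_um)) || any(!is.finite(seg$force_nN)))
      stop(name, " segment contains non-finite values")
    d <- diff(seg$separation_um)
    ok <- if (direction > 0) all(d >= 0) else all(d <= 0)
    if (!ok) stop(name, " separations are not monotone")
    seg[, c("separation_um", "force_nN")]
  }
  stopifnot(is.numeric(contact_time_s), contact_time_s > 0)
  structure(list(approach = check_seg(approach, "approach", -1),
                 retract = check_seg(retract, "retract", +1),
                 contact_time_s = as.numeric(contact_time_s),
                 metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(paste0("<force_curve> %d+%d samples, contact %.3g s, ",
                     "retract force range [%.3g, %.3g] nN\n"),
              nrow(x$approach), nrow(x$retract), x$contact_time_s,
              min(x$retract$force_nN), max(x$retract$force_nN)))
  invisible(x)
}

# Metadata keys serialized into curve file headers.
curve_meta_keys <- c("probe", "target", "variant", "speed_um_s",
                     "contact_force_nN")

#' Write a force curve to a delimited file
#'
#' The on-disk format is CSV with leading `# key: value` header lines
#' (`contact_time_s` plus any metadata) and columns `separation_um`,
#' `force_nN`, `segment` (approach/retract).
#'
#' @param curve a [force_curve].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact_time_s: %.10g", curve$contact_time_s), con)
  for (k in names(curve$metadata))
    writeLines(sprintf("# %s: %s", k, format(curve$metadata[[k]])), con)
  tab <- rbind(cbind(curve$approach, segment = "approach"),
               cbind(curve$retract, segment = "retract"))
  writeLines("separation_um,force_nN,segment", con)
  writeLines(sprintf("%.17g,%.17g,%s", tab$separation_um, tab$force_nN,
                     tab$segment), con)
  invisible(path)
}

#' Load force curves from a file or directory
#'
#' Reads one curve per file in the format written by [write_curve()]. A
#' directory is scanned for `*.csv` in sorted-path order. Malformed numeric
#' rows are reported with their line numbers.
#'
#' @param path a curve file or a directory of curve files.
#' @return A list of [force_curve]s (a single file still yields a list of 1).
#' @export
load_curves <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no .csv curve files in ", path)
    return(lapply(files, load_one_curve))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  list(load_one_curve(path))
}

load_one_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (i in hdr) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(meta$contact_time_s))
    stop(path, ": missing header metadata key contact_time_s")
  body_start <- if (length(hdr)) max(hdr) + 1L else 1L
  tab <- utils::read.csv(text = lines[body_start:length(lines)],
                         stringsAsFactors = FALSE)
  need <- c("separation_um", "force_nN", "segment")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(path, ": format error, missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$separation_um))) |
               !is.finite(suppressWarnings(as.numeric(tab$force_nN))) |
               !tab$segment %in% c("approach", "retract"))
  if (length(bad))
    stop(path, ": malformed data row(s) at line ",
         paste(bad + body_start, collapse = ", "))
  ct <- as.numeric(meta$contact_time_s)
  keep <- meta[setdiff(names(meta), "contact_time_s")]
  num <- suppressWarnings(lapply(keep, as.numeric))
  for (k in names(keep)) if (!is.na(num[[k]])) keep[[k]] <- num[[k]]
  force_curve(approach = tab[tab$segment == "approach", ],
              retract = tab[tab$segment == "retract", ],
              contact_time_s = ct, metadata = keep)
}

#' Baseline-correct a force curve
#'
#' Fits a least-squares line (force vs separation) to the final
#' `tail_fraction` of the retract segment — the fully separated regime where
#' the cantilever is free — and subtracts it from both segments, removing
#' constant offsets and linear drift. After correction the retract tail has
#' mean ~0 and F_max is measured relative to the free-cantilever level.
#'
#' @param curve a [force_curve].
#' @param tail_fraction fraction (0, 0.5\] of the retract samples, taken at
#'   the largest separations; default 0.4. A long tail matters: the fitted
#'   line is extrapolated back to the adhesion well, and the extrapolation
#'   variance of a short far-away tail would dominate the F_max noise.
#' @return The corrected [force_curve], with attribute `baseline` =
#'   `c(intercept_nN, slope_nN_per_um)`.
#' @export
baseline_correct <- function(curve, tail_fraction = 0.4) {
  stopifnot(inherits(curve, "force_curve"),
            tail_fraction > 0, tail_fraction <= 0.5)
  ret <- curve$retract
  n <- nrow(ret)
  n_tail <- floor(tail_fraction * n)
  if (n_tail < 10L)
    stop("baseline tail has fewer than 10 samples; increase tail_fraction")
  ord <- order(ret$separation_um)
  tail_idx <- ord[(n - n_tail + 1L):n]
  fit <- stats::lm.fit(cbind(1, ret$separation_um[tail_idx]),
                       ret$force_nN[tail_idx])
  b <- fit$coefficients
  correct <- function(seg) {
    seg$force_nN <- seg$force_nN - (b[1L] + b[2L] * seg$separation_um)
    seg
  }
  out <- force_curve(correct(curve$approach), correct(ret),
                     curve$contact_time_s, curve$metadata)
  attr(out, "baseline") <- c(intercept_nN = unname(b[1L]),
                             slope_nN_per_um = unname(b[2L]))
  out
}

#' Extract the maximum adhesion force from a retract segment
#'
#' F_max is the deepest force excursion below the corrected baseline during
#' retraction, reported as a positive magnitude:
#' `max(0, -min(retract force))`. Apply [baseline_correct()] first so the
#' free-cantilever level is zero.
#'
#' @param curve a baseline-corrected [force_curve].
#' @return Object of class `fmax_result`: `fmax_nN`, `min_index`,
#'   `min_separation_um`, `baseline_intercept_nN`, `baseline_slope_nN_per_um`
#'   (the latter two taken from the correction attribute, 0 if absent).
#' @export
extract_fmax <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  f <- curve$retract$force_nN
  i <- which.min(f)
  bl <- attr(curve, "baseline")
  if (is.null(bl)) bl <- c(intercept_nN = 0, slope_nN_per_um = 0)
  structure(list(fmax_nN = max(0, -f[i]),
                 min_index = i,
                 min_separation_um = curve$retract$separation_um[i],
                 baseline_intercept_nN = unname(bl[1L]),
                 baseline_slope_nN_per_um = unname(bl[2L]),
                 contact_time_s = curve$contact_time_s,
                 metadata = curve$metadata),
            class = "fmax_result")
}

#' @export
print.fmax_result <- function(x, ...) {
  cat(sprintf("F_max = %.4g nN at separation %.3g um (contact %.3g s)\n",
              x$fmax_nN, x$min_separation_um, x$contact_time_s))
  invisible(x)
}

#' Analyze a set of curves end to end
#'
#' Baseline-corrects each curve and extracts F_max, returning a tidy table.
#'
#' @param curves list of [force_curve]s (e.g. from [load_curves()]).
#' @param tail_fraction see [baseline_correct()].
#' @return Data frame with one row per curve: `fmax_nN`, `contact_time_s`,
#'   `min_separation_um` and any shared metadata labels (`probe`, `target`,
#'   `variant`).
#' @export
analyze_curves <- function(curves, tail_fraction = 0.4) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    r <- extract_fmax(baseline_correct(cv, tail_fraction))
    md <- r$metadata
    data.frame(fmax_nN = r$fmax_nN,
               contact_time_s = r$contact_time_s,
               min_separation_um = r$min_separation_um,
               probe = if (is.null(md$probe)) NA_character_ else as.character(md$probe),
               target = if (is.null(md$target)) NA_character_ else as.character(md$target),
               variant = if (is.null(md$variant)) NA_character_ else as.character(md$variant))
  })
  do.call(rbind, rows)
}

#' Per-group F_max summaries
#'
#' Mean and sample SD (n - 1 denominator) of F_max per group. Groups with
#' fewer than 15 measurements trigger a warning (the convention of at least
#' 15 independent measurements per reported average); single-member groups
#' report SD 0 with a warning.
#'
#' @param fmax_nN numeric vector of F_max values.
#' @param group vector of group labels (variant pair, contact time, ...).
#' @return Data frame with columns `group`, `n`, `mean_nN`, `sd_nN`.
#' @export
summarize_groups <- function(fmax_nN, group) {
  stopifnot(length(fmax_nN) == length(group), length(fmax_nN) >= 1L)
  group <- as.character(group)
  gs <- unique(group)
  out <- do.call(rbind, lapply(gs, function(g) {
    v <- fmax_nN[group == g]
    data.frame(group = g, n = length(v), mean_nN = mean(v),
               sd_nN = if (length(v) > 1L) stats::sd(v) else 0)
  }))
  small <- out$group[out$n < 15L]
  if (length(small))
    warning("group(s) with fewer than 15 measurements: ",
            paste(small, collapse = ", "),
            " (averages are conventionally based on >= 15)")
  if (any(out$n == 1L))
    warning("single-measurement group(s): SD undefined, reported as 0")
  out
}

#' Adhesion kinetics across contact times
#'
#' Summarises F_max per contact time, ordered by increasing contact time, to
#' expose the build-up of adhesion strength with contact duration.
#'
#' @param fmax_nN numeric vector of F_max values.
#' @param contact_time_s matching vector of contact times, s; at least two
#'   distinct values.
#' @return Data frame with columns `contact_time_s`, `n`, `mean_nN`,
#'   `sd_nN`, sorted by contact time.
#' @export
adhesion_kinetics <- function(fmax_nN, contact_time_s) {
  stopifnot(length(fmax_nN) == length(contact_time_s))
  times <- sort(unique(contact_time_s))
  if (length(times) < 2L)
    stop("adhesion kinetics need at least two distinct contact times")
  out <- do.call(rbind, lapply(times, function(tt) {
    v <- fmax_nN[contact_time_s == tt]
    data.frame(contact_time_s = tt, n = length(v), mean_nN = mean(v),
               sd_nN = if (length(v) > 1L) stats::sd(v) else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Read a tabular F_max measurement file
#'
#' Parses a delimited export of single-cell adhesion measurements (one row
#' per measurement) such as published source-data tables. Column names are
#' matched case-insensitively after stripping non-alphanumerics, so
#' `Fmax (nN)`, `fmax_nN` and `F_max` all resolve; the same applies to the
#' contact-time and group/variant columns.
#'
#' @param path CSV/TSV file.
#' @param fmax_col,time_col,group_col column name hints; defaults cover the
#'   common spellings.
#' @return Data frame with columns `fmax_nN`, `contact_time_s` (NA if
#'   absent) and `group` (NA if absent).
#' @export
load_fmax_table <- function(path, fmax_col = NULL, time_col = NULL,
                            group_col = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  cols <- canon(names(tab))
  pick <- function(hint, keys) {
    if (!is.null(hint)) {
      i <- match(canon(hint), cols)
      if (is.na(i)) stop("column not found: ", hint)
      return(i)
    }
    i <- which(vapply(cols, function(cc)
      any(startsWith(cc, keys)), logical(1)))
    if (length(i)) i[1L] else NA_integer_
  }
  fi <- pick(fmax_col, c("fmax", "maxadhesionforce", "maximumadhesionforce",
                         "adhesionforce", "force"))
  if (is.na(fi)) stop("format error: no F_max column recognised in ", path)
  ti <- pick(time_col, c("contacttime", "time"))
  gi <- pick(group_col, c("group", "variant", "strain", "interaction",
                          "pair", "condition"))
  data.frame(
    fmax_nN = as.numeric(tab[[fi]]),
    contact_time_s = if (is.na(ti)) NA_real_ else as.numeric(tab[[ti]]),
    group = if (is.na(gi)) NA_character_ else as.character(tab[[gi]]),
    stringsAsFactors = FALSE)
}
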