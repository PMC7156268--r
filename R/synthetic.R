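# Seeded ground-truth generators for the three assays. Every generator is a
# pure function of its arguments (seed included): same spec, same bits. The
# global RNG state is saved and restored, so generators never perturb a
# user's random stream.

with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  code
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a plate-scan scene of cell aggregates with known truth
#'
#' Renders cell aggregates as objects *darker* than an inhomogeneous bright
#' agar background (clumps absorb light on a plate scan), exactly the input
#' regime of the aggregation-microscopy pipeline: background subtraction then
#' inverts the contrast. The paired `background` grid is the cell-free plate
#' image used for that correction.
#'
#' Objects are discs or randomly oriented elliptical blobs matched to their
#' target areas. The first `2 * overlap_pairs` objects are placed as touching
#' pairs (their masks merge into one connected component), so watershed
#' dissection is exercised; all remaining objects are placed without contact.
#'
#' @param field_size_px integer (rows, cols) of the field; default
#'   `c(600, 600)`.
#' @param pixel_size_mm pixel calibration; default 0.01 mm/px, so the default
#'   field covers 0.36 cm^2.
#' @param objects data frame with columns `target_area_mm2` (> 0) and `shape`
#'   ("disc" or "blob").
#' @param overlap_pairs number of deliberately touching object pairs taken
#'   from the head of `objects`.
#' @param background_gradient_amplitude peak-to-peak amplitude of the smooth
#'   background inhomogeneity, in intensity units (0 to 0.3); default 0.1.
#' @param contrast intensity drop of an aggregate below the local background;
#'   default 0.3.
#' @param noise_sd SD of additive Gaussian pixel noise (clipped to \[0, 1\]);
#'   default 0.01.
#' @param seed integer RNG seed.
#' @return List with elements `background` and `scene` ([intensity_grid]s)
#'   and `truth`: a list holding `labels` (integer matrix, one label per
#'   object), `objects` (data frame: label, target_area_mm2, area_px,
#'   area_mm2) and `contrast`.
#' @export
gen_aggregate_scene <- function(field_size_px = c(600L, 600L),
                                pixel_size_mm = 0.01,
                                objects,
                                overlap_pairs = 0L,
                                background_gradient_amplitude = 0.1,
                                contrast = 0.3,
                                noise_sd = 0.01,
                                seed = 1L) {
  stopifnot(length(field_size_px) == 2L, all(field_size_px >= 32L),
            pixel_size_mm > 0, contrast > 0, contrast <= 0.5,
            background_gradient_amplitude >= 0,
            background_gradient_amplitude <= 0.3,
            noise_sd >= 0)
  if (missing(objects) || is.null(objects))
    objects <- data.frame(target_area_mm2 = numeric(), shape = character())
  stopifnot(all(objects$target_area_mm2 > 0),
            all(objects$shape %in% c("disc", "blob")))
  n_obj <- nrow(objects)
  overlap_pairs <- as.integer(overlap_pairs)
  stopifnot(overlap_pairs >= 0, 2L * overlap_pairs <= n_obj)

  nr <- field_size_px[1L]; nc <- field_size_px[2L]
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  with_seed(seed, {
    # smooth bright background: plane tilt plus a broad radial bump
    a <- background_gradient_amplitude
    plane <- (rowg / nr + colg / nc) / 2
    bump <- exp(-(((rowg - nr / 2)^2 + (colg - nc / 2)^2) / (0.5 * (nr^2 + nc^2))))
    bg <- 0.82 + a * (plane - 0.5) + 0.3 * a * (bump - mean(bump))
    bg <- clip01(bg)

    r_eq <- sqrt(objects$target_area_mm2 / pixel_size_mm^2 / pi)
    if (n_obj > 0 && 2 * max(r_eq) + 8 > min(nr, nc))
      stop("placement error: field too small for the largest object")

    labels <- matrix(0L, nr, nc)
    centers <- matrix(NA_real_, n_obj, 2L)
    radii <- numeric(n_obj)
    realized <- integer(n_obj)

    place_one <- function(i, partner = NA_integer_) {
      r <- r_eq[i]
      shape <- objects$shape[i]
      s <- if (shape == "blob") runif(1, 1.1, 1.6) else 1
      ax <- r * s; bx <- r / s
      th <- runif(1, 0, pi)
      rmax <- max(ax, bx)
      for (try in seq_len(500L)) {
        if (!is.na(partner)) {
          # tangent placement next to an already placed partner
          ang <- runif(1, 0, 2 * pi)
          d <- radii[partner] + rmax - 1
          cy <- centers[partner, 1L] + d * cos(ang)
          cx <- centers[partner, 2L] + d * sin(ang)
        } else {
          cy <- runif(1, rmax + 3, nr - rmax - 3)
          cx <- runif(1, rmax + 3, nc - rmax - 3)
        }
        if (cy < rmax + 2 || cy > nr - rmax - 2 ||
            cx < rmax + 2 || cx > nc - rmax - 2) next
        placed <- which(!is.na(centers[, 1L]))
        if (!is.na(partner)) placed <- setdiff(placed, partner)
        clear <- TRUE
        for (j in placed) {
          gap <- sqrt((cy - centers[j, 1L])^2 + (cx - centers[j, 2L])^2) -
            (rmax + radii[j])
          if (gap < 3) { clear <- FALSE; break }
        }
        if (!clear) next
        dy <- rowg - cy; dx <- colg - cx
        u <- dy * cos(th) + dx * sin(th)
        v <- -dy * sin(th) + dx * cos(th)
        px <- (u / ax)^2 + (v / bx)^2 <= 1
        labels[px] <<- i
        centers[i, ] <<- c(cy, cx)
        radii[i] <<- rmax
        return(invisible())
      }
      stop("placement error: could not place object ", i,
           " without unintended overlap")
    }

    i <- 1L
    while (i <= 2L * overlap_pairs) {
      place_one(i)
      place_one(i + 1L, partner = i)
      i <- i + 2L
    }
    while (i <= n_obj) { place_one(i); i <- i + 1L }

    realized <- tabulate(labels[labels > 0L], nbins = n_obj)
    scene <- bg - contrast * (labels > 0L)
    if (noise_sd > 0) scene <- scene + rnorm(nr * nc, 0, noise_sd)
    scene <- clip01(scene)

    list(background = intensity_grid(bg, pixel_size_mm),
         scene = intensity_grid(scene, pixel_size_mm),
         truth = list(
           labels = labels,
           objects = if (n_obj > 0) data.frame(
             label = seq_len(n_obj),
             target_area_mm2 = objects$target_area_mm2,
             shape = objects$shape,
             area_px = realized,
             area_mm2 = realized * pixel_size_mm^2
           ) else data.frame(label = integer(), target_area_mm2 = numeric(),
                             shape = character(), area_px = integer(),
                             area_mm2 = numeric()),
           contrast = contrast))
  })
}

#' Simulate a two-channel (RFP/GFP) sectored biofilm colony
#'
#' Emulates a mixed-inoculum mat biofilm imaged separately through RFP and
#' GFP filters: a circular colony with a well-mixed core (each pixel one of
#' the two genotypes at random, as in the founding 1:1 inoculum) surrounded
#' by radial single-genotype sectors, the drift pattern of range expansion.
#' Each angular wedge gives its first `edge_monopolization` fraction of arc to
#' the RFP genotype, so that fraction of the outer rim — and of any ring
#' concentric with it outside the core — is RFP territory.
#'
#' Channel intensities are `autofluorescence + gain * indicator + noise`,
#' clipped to \[0, 1\]; autofluorescence also covers the agar outside the
#' colony.
#'
#' @param radius_px colony radius (>= 60 px so a 50-px edge ring exists);
#'   default 150.
#' @param mixed_core_radius_px radius of the mixed core (< `radius_px`);
#'   default 40.
#' @param n_sectors number of angular wedges; default 12.
#' @param edge_monopolization fraction of the rim occupied by the RFP
#'   genotype, in \[0, 1\].
#' @param gains per-channel fluorophore gain `c(rfp, gfp)`, each > its
#'   autofluorescence; default `c(0.6, 0.45)` (RFP and GFP are imaged at
#'   different magnitudes).
#' @param autofluorescence per-channel medium autofluorescence `c(rfp, gfp)`;
#'   default `c(0.08, 0.06)`.
#' @param noise_sd SD of additive Gaussian noise; default 0.02.
#' @param margin_px agar margin around the colony; default 25.
#' @param seed integer RNG seed.
#' @return List with `rfp` and `gfp` ([intensity_grid]s, pixel size fixed at
#'   0.05 mm/px) and `truth`: `genotype` (integer matrix: 1 = RFP, 2 = GFP,
#'   0 = outside), `colony_mask`, `edge_fraction_rfp` (realized on the 1-px
#'   rim), `whole_fraction_rfp`, and the nominal `edge_monopolization`.
#' @export
gen_biofilm_pair <- function(radius_px = 150L,
                             mixed_core_radius_px = 40L,
                             n_sectors = 12L,
                             edge_monopolization = 0.5,
                             gains = c(rfp = 0.6, gfp = 0.45),
                             autofluorescence = c(rfp = 0.08, gfp = 0.06),
                             noise_sd = 0.02,
                             margin_px = 25L,
                             seed = 1L) {
  stopifnot(radius_px >= 60L, mixed_core_radius_px >= 0L,
            mixed_core_radius_px < radius_px, n_sectors >= 1L,
            edge_monopolization >= 0, edge_monopolization <= 1,
            length(gains) == 2L, all(gains > 0),
            length(autofluorescence) == 2L, all(autofluorescence >= 0),
            all(gains > autofluorescence), noise_sd >= 0)
  n <- 2L * (radius_px + margin_px) + 1L
  ctr <- radius_px + margin_px + 1
  rowg <- matrix(seq_len(n), n, n)
  colg <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rowg - ctr)^2 + (colg - ctr)^2)
  theta <- atan2(colg - ctr, rowg - ctr) %% (2 * pi)
  inside <- rad <= radius_px
  core <- rad <= mixed_core_radius_px

  with_seed(seed, {
    wedge_pos <- (theta %% (2 * pi / n_sectors)) / (2 * pi / n_sectors)
    geno <- matrix(0L, n, n)
    geno[inside] <- ifelse(wedge_pos[inside] < edge_monopolization, 1L, 2L)
    if (any(core)) geno[core] <- sample(1:2, sum(core), replace = TRUE)

    render <- function(gain, auto, which_geno) {
      img <- auto + gain * (geno == which_geno)
      if (noise_sd > 0) img <- img + rnorm(n * n, 0, noise_sd)
      clip01(img)
    }
    rfp <- render(gains[[1L]], autofluorescence[[1L]], 1L)
    gfp <- render(gains[[2L]], autofluorescence[[2L]], 2L)

    rim <- inside & distance_to_boundary(inside) <= 1
    list(rfp = intensity_grid(rfp, 0.05),
         gfp = intensity_grid(gfp, 0.05),
         truth = list(genotype = geno,
                      colony_mask = inside,
                      edge_fraction_rfp = mean(geno[rim] == 1L),
                      whole_fraction_rfp = mean(geno[inside] == 1L),
                      edge_monopolization = edge_monopolization))
  })
}

#' Simulate a single-cell force spectroscopy force-distance curve
#'
#' Builds one approach/retract cycle as recorded in cell-cell adhesion
#' spectroscopy: the approach ramps to the preset contact force at zero
#' separation; the retract releases the contact force, descends into an
#' adhesion well of depth `true_fmax_nN` below the free-cantilever baseline,
#' then returns to baseline through `rupture_steps` discrete unbinding steps
#' and stays flat once the cells are fully separated. Optional linear drift
#' (in separation) and Gaussian force noise are superimposed. The well vertex
#' is snapped onto the sampling grid, so with zero noise the constructed
#' minimum equals `-true_fmax_nN` exactly.
#'
#' @param true_fmax_nN depth of the adhesion well (>= 0), nN.
#' @param contact_force_nN preset contact force; default 1 nN.
#' @param speed_um_s approach/retract velocity; default 5 um/s (metadata
#'   only; the curve is parameterized by separation).
#' @param contact_time_s cell-cell contact time, s; default 20.
#' @param n_samples samples per segment (>= 50); default 400.
#' @param s_max_um maximum separation, um; default 10.
#' @param drift_nN_per_um linear baseline drift; default 0.
#' @param noise_sd_nN SD of additive Gaussian force noise; default 0.
#' @param rupture_steps number of discrete unbinding steps (1-3); default 2.
#' @param probe,target,variant metadata labels.
#' @param seed integer RNG seed.
#' @return List with `curve` (a [force_curve]) and `truth`: `true_fmax_nN`,
#'   `min_separation_um`, `baseline_intercept_nN` (0) and
#'   `baseline_slope_nN_per_um`.
#' @export
gen_force_curve <- function(true_fmax_nN,
                            contact_force_nN = 1,
                            speed_um_s = 5,
                            contact_time_s = 20,
                            n_samples = 400L,
                            s_max_um = 10,
                            drift_nN_per_um = 0,
                            noise_sd_nN = 0,
                            rupture_steps = 2L,
                            probe = "probe1", target = "target1",
                            variant = "ScFlo11A",
                            seed = 1L) {
  stopifnot(true_fmax_nN >= 0, n_samples >= 50L, s_max_um > 2.5,
            noise_sd_nN >= 0, rupture_steps >= 1L, rupture_steps <= 3L,
            contact_time_s > 0)
  s <- seq(0, s_max_um, length.out = n_samples)
  snap <- function(x) s[which.min(abs(s - x))]
  s_c <- snap(0.5)          # contact force released
  s_min <- snap(1.5)        # adhesion well vertex
  s_rup <- snap(2.5)        # fully separated

  retract_shape <- function(si) {
    if (si <= s_c) contact_force_nN * (1 - si / s_c)
    else if (si <= s_min) -true_fmax_nN * (si - s_c) / (s_min - s_c)
    else if (si < s_rup) {
      k <- ceiling((si - s_min) / (s_rup - s_min) * rupture_steps)
      -true_fmax_nN * (rupture_steps - k) / rupture_steps
    } else 0
  }
  approach_shape <- function(si) contact_force_nN * max(0, 1 - si / s_c)

  with_seed(seed, {
    app_s <- rev(s)  # approach recorded from far to contact
    app_f <- vapply(app_s, approach_shape, numeric(1)) + drift_nN_per_um * app_s
    ret_f <- vapply(s, retract_shape, numeric(1)) + drift_nN_per_um * s
    if (noise_sd_nN > 0) {
      app_f <- app_f + rnorm(n_samples, 0, noise_sd_nN)
      ret_f <- ret_f + rnorm(n_samples, 0, noise_sd_nN)
    }
    curve <- force_curve(
      approach = data.frame(separation_um = app_s, force_nN = app_f),
      retract = data.frame(separation_um = s, force_nN = ret_f),
      contact_time_s = contact_time_s,
      metadata = list(probe = probe, target = target, variant = variant,
                      speed_um_s = speed_um_s,
                      contact_force_nN = contact_force_nN))
    list(curve = curve,
         truth = list(true_fmax_nN = true_fmax_nN,
                      min_separation_um = s_min,
                      baseline_intercept_nN = 0,
                      baseline_slope_nN_per_um = drift_nN_per_um))
  })
}

#' Null replicate pairs for test calibration
#'
#' Draws `n_reps` pairs of samples from one common standard normal
#' distribution, for empirical type-I-error calibration of the two-group
#' tests.
#'
#' @param n_per_group sample size per group (>= 3).
#' @param n_reps number of replicate pairs.
#' @param seed integer RNG seed.
#' @return List of length `n_reps`; each element is `list(a =, b =)` of
#'   `n_per_group` values.
#' @export
gen_null_groups <- function(n_per_group, n_reps, seed = 1L) {
  stopifnot(n_per_group >= 3L, n_reps >= 1L)
  with_seed(seed, {
    lapply(seq_len(n_reps), function(i)
      list(a = rnorm(n_per_group), b = rnorm(n_per_group)))
  })
}
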