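#' Specify a single synthetic lesion phantom
#'
#' A phantom is a spherically symmetric lesion with a monotone radial uptake
#' profile, placed in a homogeneous background, whose metabolic compartments
#' have analytically known volumes. The central compartment is the 80-100%
#' isocontour band of the lesion maximum, the peripheral compartment the
#' 60-75% band, and a 75-80% "gap" band separates them (part of the total
#' 60-100% volume but of neither named compartment).
#'
#' By default the lesion center is snapped to the voxel center nearest the
#' grid centroid so that the rendered maximum equals `suv_max` exactly.
#'
#' @param v_central True volume (cm^3) of the 80-100% band.
#' @param v_peripheral True volume (cm^3) of the 60-75% band.
#' @param gap_fraction Volume of the 75-80% band as a fraction of
#'   `v_peripheral` (default 0.25; freely configurable).
#' @param suv_max Peak lesion SUV. Must satisfy `0.6 * suv_max >
#'   background_suv` so the 60% isocontour excludes background.
#' @param background_suv Homogeneous background SUV (default 1).
#' @param noise_sd Additive Gaussian noise SD in SUV units (default 0:
#'   the calibrated cohort is defined on the analytic profile).
#' @param vessel Optional list `list(center_mm =, radius_mm =, suv =)`
#'   describing a hot spherical blood-pool blob burned into the image.
#' @param grid_shape Integer length-3 grid size (default 96 x 96 x 64).
#' @param spacing_mm Voxel spacing in mm (default 1.0 x 1.0 x 2.3, a typical
#'   PET reconstruction voxel).
#' @param center_mm Lesion center in mm, or `NULL` to snap to the voxel
#'   center nearest the grid centroid.
#' @param seed Integer seed for the phantom's noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(v_central, v_peripheral, gap_fraction = 0.25,
                         suv_max = 3, background_suv = 1, noise_sd = 0,
                         vessel = NULL, grid_shape = c(96L, 96L, 64L),
                         spacing_mm = c(1, 1, 2.3), center_mm = NULL,
                         seed = 1L) {
  if (v_central <= 0 || v_peripheral <= 0) {
    stop("compartment volumes must be positive")
  }
  if (gap_fraction <= 0 || gap_fraction >= 1) stop("gap_fraction must be in (0, 1)")
  if (0.6 * suv_max <= background_suv) {
    stop("0.6 * suv_max must exceed background_suv (60% isocontour must clear background)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(spacing_mm) == 3, all(spacing_mm > 0))
  if (is.null(center_mm)) {
    center_mm <- round((grid_shape - 1) / 2) * spacing_mm
  }
  if (!is.null(vessel)) {
    stopifnot(is.list(vessel),
              all(c("center_mm", "radius_mm", "suv") %in% names(vessel)))
  }
  structure(
    list(v_central = v_central, v_peripheral = v_peripheral,
         gap_fraction = gap_fraction, suv_max = suv_max,
         background_suv = background_suv, noise_sd = noise_sd,
         vessel = vessel, grid_shape = grid_shape,
         spacing_mm = as.numeric(spacing_mm),
         center_mm = as.numeric(center_mm), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

sphere_radius_mm <- function(v_cm3) (3 * v_cm3 * 1000 / (4 * pi))^(1 / 3)

# Smallest distance from the lesion center to any grid face (mm).
grid_margin_mm <- function(grid_shape, spacing_mm, center_mm) {
  extent_hi <- (grid_shape - 1) * spacing_mm
  min(pmin(center_mm, extent_hi - center_mm))
}

# Volume-weighted mean of a profile linear in radius (f1 at r1, f2 at r2)
# over the spherical shell r1..r2: closed-form integral of f(r) r^2.
linear_band_mean <- function(r1, r2, f1, f2) {
  b <- (f2 - f1) / (r2 - r1)
  a <- f1 - b * r1
  (a * (r2^3 - r1^3) / 3 + b * (r2^4 - r1^4) / 4) / ((r2^3 - r1^3) / 3)
}

#' Radial uptake profile and analytic ground truth of a phantom
#'
#' Solves the isocontour radii so that the sphere of radius `r80` has volume
#' `v_central`, the shell `r80..r75` has volume `gap_fraction * v_peripheral`,
#' and the shell `r75..r60` has volume `v_peripheral`. The fraction-of-maximum
#' profile is piecewise linear through (0, 1), (r80, 0.80), (r75, 0.75),
#' (r60, 0.60) and decays linearly to the background fraction
#' `background_suv / suv_max` at `1.3 * r60` (constant beyond), so the
#' far-field voxel value equals the background SUV exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `profile` (a function of radius in mm returning the
#'   fraction of maximum) and `ground_truth`, a one-row tibble with the radii
#'   (mm), the band volumes (cm^3), the true volumetric CU ratio
#'   `v_peripheral / v_central` and the true SUV CU ratio (ratio of
#'   volume-averaged profile over the peripheral vs central band).
#' @export
radial_profile <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r80 <- sphere_radius_mm(spec$v_central)
  v_gap <- spec$gap_fraction * spec$v_peripheral
  r75 <- (r80^3 + 3 * v_gap * 1000 / (4 * pi))^(1 / 3)
  r60 <- (r75^3 + 3 * spec$v_peripheral * 1000 / (4 * pi))^(1 / 3)
  margin <- grid_margin_mm(spec$grid_shape, spec$spacing_mm, spec$center_mm)
  if (1.3 * r60 > margin) {
    stop(sprintf("lesion clipped by grid boundary: outer radius 1.3*r60 = %.1f mm exceeds the %.1f mm margin from the lesion center",
                 1.3 * r60, margin))
  }
  bf <- spec$background_suv / spec$suv_max
  knots_r <- c(0, r80, r75, r60, 1.3 * r60)
  knots_f <- c(1, 0.80, 0.75, 0.60, bf)
  profile <- function(r) {
    stats::approx(knots_r, knots_f, xout = r, rule = 2)$y
  }
  suv_cu_true <- linear_band_mean(r75, r60, 0.75, 0.60) /
    linear_band_mean(0, r80, 1, 0.80)
  gt <- tibble::tibble(
    r80 = r80, r75 = r75, r60 = r60,
    v_central = spec$v_central, v_gap = v_gap,
    v_peripheral = spec$v_peripheral,
    v_mtv60 = spec$v_central + v_gap + spec$v_peripheral,
    volumetric_cu_true = spec$v_peripheral / spec$v_central,
    suv_cu_true = suv_cu_true
  )
  list(profile = profile, ground_truth = gt)
}

#' Render a phantom to an SUV volume
#'
#' Evaluates `suv_max * profile(distance to lesion center)` at every voxel
#' center (no anti-aliasing), adds seeded Gaussian noise if `noise_sd > 0`
#' (clamped at zero), and burns in the optional vessel sphere. The true lesion
#' mask is the set of voxels within `r60` of the center.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` ([suv_volume()]), `lesion` ([binary_mask()]),
#'   `ground_truth` (tibble, see [radial_profile()]) and `spec`.
#' @export
render_phantom <- function(spec) {
  rp <- radial_profile(spec)
  gt <- rp$ground_truth
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  extent_hi <- (d - 1) * sp
  r_out <- 1.3 * gt$r60
  if (any(spec$center_mm - r_out < 0) || any(spec$center_mm + r_out > extent_hi)) {
    stop(sprintf("lesion clipped by grid boundary: outer radius %.1f mm around center (%s) mm does not fit",
                 r_out, paste(round(spec$center_mm, 1), collapse = ", ")))
  }
  vals <- array(spec$background_suv, d)
  # evaluate the profile only inside the bounding box of the outer radius
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor((spec$center_mm[a] - r_out) / sp[a]) + 1L)
    hi <- min(d[a], ceiling((spec$center_mm[a] + r_out) / sp[a]) + 1L)
    lo:hi
  })
  dx2 <- (axis_coords(d[1], sp[1], 0)[rng[[1]]] - spec$center_mm[1])^2
  dy2 <- (axis_coords(d[2], sp[2], 0)[rng[[2]]] - spec$center_mm[2])^2
  dz2 <- (axis_coords(d[3], sp[3], 0)[rng[[3]]] - spec$center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  dist <- sqrt(d2)
  vals[rng[[1]], rng[[2]], rng[[3]]] <- spec$suv_max * rp$profile(dist)
  lesion <- array(FALSE, d)
  lesion[rng[[1]], rng[[2]], rng[[3]]] <- dist <= gt$r60
  if (spec$noise_sd > 0) {
    vals <- withr::with_seed(spec$seed, {
      vals + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    })
    vals[vals < 0] <- 0
  }
  if (!is.null(spec$vessel)) {
    vs <- spec$vessel
    vx2 <- (axis_coords(d[1], sp[1], 0) - vs$center_mm[1])^2
    vy2 <- (axis_coords(d[2], sp[2], 0) - vs$center_mm[2])^2
    vz2 <- (axis_coords(d[3], sp[3], 0) - vs$center_mm[3])^2
    vd2 <- outer(outer(vx2, vy2, `+`), vz2, `+`)
    vmask <- vd2 <= vs$radius_mm^2
    vals[vmask] <- pmax(vals[vmask], vs$suv)
  }
  list(
    volume = suv_volume(vals, spacing_mm = sp),
    lesion = binary_mask(lesion, spacing_mm = sp, label = "lesion"),
    ground_truth = gt,
    spec = spec
  )
}

#' Parameters of a calibrated two-genotype cohort
#'
#' Defaults reproduce a 21 IDH-mutant vs 31 wild-type glioma cohort: the
#' volumetric CU ratio is log-normal per genotype with medians 7.84 (mutant)
#' and 3.92 (wild-type) and a common log-SD chosen so the population AUC of
#' the two distributions is 0.88, i.e.
#' `sigma_log_cu = (log(7.84) - log(3.92)) / (sqrt(2) * qnorm(0.88))`.
#' Central-compartment volumes are log-normal with medians chosen so the
#' median peripheral volume (`CU x v_central`, a product of independent
#' log-normals) is 5.33 cm^3 (mutant) and 2.78 cm^3 (wild-type).
#'
#' @param n_mut,n_wt Group sizes (default 21 and 31).
#' @param log_median_cu_mut,log_median_cu_wt Natural-log medians of the
#'   volumetric CU ratio per genotype.
#' @param sigma_log_cu Common log-SD of the CU ratio.
#' @param median_vc_mut,median_vc_wt Median central-compartment volume (cm^3).
#' @param sigma_log_vc Log-SD of the central volume (default 0.5; spread
#'   only, medians untouched).
#' @param suvmax_range Peak SUV as uniform multiples of background
#'   (default 2 to 4).
#' @param background_suv Background SUV (default 1).
#' @param gap_fraction See [phantom_spec()].
#' @param grid_shape,spacing_mm Rendering grid (defaults as [phantom_spec()]).
#' @param seed Integer seed for the single cohort-level random stream.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_mut = 21L, n_wt = 31L,
                          log_median_cu_mut = log(7.84),
                          log_median_cu_wt = log(3.92),
                          sigma_log_cu =
                            (log(7.84) - log(3.92)) / (sqrt(2) * stats::qnorm(0.88)),
                          median_vc_mut = 5.33 / 7.84,
                          median_vc_wt = 2.78 / 3.92,
                          sigma_log_vc = 0.5,
                          suvmax_range = c(2, 4),
                          background_suv = 1,
                          gap_fraction = 0.25,
                          grid_shape = c(96L, 96L, 64L),
                          spacing_mm = c(1, 1, 2.3),
                          seed = 1L) {
  stopifnot(n_mut >= 2, n_wt >= 2, sigma_log_cu > 0, sigma_log_vc > 0,
            median_vc_mut > 0, median_vc_wt > 0,
            length(suvmax_range) == 2, suvmax_range[1] > 0,
            suvmax_range[2] >= suvmax_range[1])
  if (exp(log_median_cu_mut) <= exp(log_median_cu_wt)) {
    stop("default direction requires the mutant CU median to exceed the wild-type median")
  }
  structure(
    list(n_mut = as.integer(n_mut), n_wt = as.integer(n_wt),
         log_median_cu_mut = log_median_cu_mut,
         log_median_cu_wt = log_median_cu_wt,
         sigma_log_cu = sigma_log_cu,
         median_vc_mut = median_vc_mut, median_vc_wt = median_vc_wt,
         sigma_log_vc = sigma_log_vc, suvmax_range = suvmax_range,
         background_suv = background_suv, gap_fraction = gap_fraction,
         grid_shape = as.integer(grid_shape),
         spacing_mm = as.numeric(spacing_mm), seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Closed-form population AUC of the calibrated generator
#'
#' For two equal-variance log-normal CU distributions the population AUC is
#' `pnorm((log_median_mut - log_median_wt) / (sqrt(2) * sigma_log_cu))`.
#'
#' @param params A [cohort_params()].
#' @return The population AUC (numeric scalar).
#' @export
population_auc <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  stats::pnorm((params$log_median_cu_mut - params$log_median_cu_wt) /
                 (sqrt(2) * params$sigma_log_cu))
}

#' Sample a two-genotype phantom cohort
#'
#' Per subject, the true volumetric CU ratio and the central-compartment
#' volume are drawn log-normally with the genotype's log-median and the
#' common log-SDs; the peripheral volume is `CU x v_central`; the peak SUV is
#' a uniform multiple of background. All draws come from one seeded stream.
#' Specs violating the phantom invariants (e.g. lesions too large for the
#' grid) are redrawn, up to 100 retries per subject.
#'
#' @param params A [cohort_params()].
#' @return A tibble with one row per subject: `subject_id`, `genotype`
#'   (`"mutant"`/`"wildtype"`), the sampled generative parameters, the
#'   analytic ground-truth columns of [radial_profile()], and a `spec`
#'   list-column of [phantom_spec()] objects.
#' @export
sample_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_mut + params$n_wt
  genotype <- rep(c("mutant", "wildtype"), c(params$n_mut, params$n_wt))
  default_center <- round((params$grid_shape - 1) / 2) * params$spacing_mm
  margin <- grid_margin_mm(params$grid_shape, params$spacing_mm, default_center)
  cu <- vc <- suv_max <- sub_seed <- numeric(n)
  withr::with_seed(params$seed, {
    for (i in seq_len(n)) {
      mut <- genotype[i] == "mutant"
      lm_cu <- if (mut) params$log_median_cu_mut else params$log_median_cu_wt
      med_vc <- if (mut) params$median_vc_mut else params$median_vc_wt
      ok <- FALSE
      for (try in seq_len(100)) {
        cu[i] <- exp(stats::rnorm(1, lm_cu, params$sigma_log_cu))
        vc[i] <- exp(stats::rnorm(1, log(med_vc), params$sigma_log_vc))
        suv_max[i] <- params$background_suv *
          stats::runif(1, params$suvmax_range[1], params$suvmax_range[2])
        sub_seed[i] <- sample.int(.Machine$integer.max - 1L, 1)
        v_mtv60 <- vc[i] + (1 + params$gap_fraction) * cu[i] * vc[i]
        r60 <- sphere_radius_mm(v_mtv60)
        fits <- 1.3 * r60 <= margin &&
          0.6 * suv_max[i] > params$background_suv
        if (fits) { ok <- TRUE; break }
      }
      if (!ok) {
        stop(sprintf("could not sample a valid phantom for subject %d after 100 retries", i))
      }
    }
  })
  vp <- cu * vc
  v_gap <- params$gap_fraction * vp
  r80 <- sphere_radius_mm(vc)
  r75 <- (r80^3 + 3 * v_gap * 1000 / (4 * pi))^(1 / 3)
  r60 <- (r75^3 + 3 * vp * 1000 / (4 * pi))^(1 / 3)
  specs <- purrr::map(seq_len(n), function(i) {
    phantom_spec(
      v_central = vc[i], v_peripheral = vp[i],
      gap_fraction = params$gap_fraction, suv_max = suv_max[i],
      background_suv = params$background_suv, noise_sd = 0,
      grid_shape = params$grid_shape, spacing_mm = params$spacing_mm,
      seed = as.integer(sub_seed[i]))
  })
  out <- tibble::tibble(
    subject_id = sprintf("sub-%05d", seq_len(n)),
    genotype = genotype,
    cu_true = cu, suv_max = suv_max,
    background_suv = params$background_suv,
    r80 = r80, r75 = r75, r60 = r60,
    v_central = vc, v_gap = v_gap, v_peripheral = vp,
    v_mtv60 = vc + v_gap + vp,
    volumetric_cu_true = vp / vc,
    suv_cu_true = linear_band_mean(r75, r60, 0.75, 0.60) /
      linear_band_mean(0, r80, 1, 0.80),
    spec = specs
  )
  attr(out, "params") <- params
  class(out) <- c("cu_cohort", class(out))
  out
}

#' Write a sampled cohort to disk as NIfTI images plus a manifest
#'
#' Renders every subject's phantom, writes the SUV volume and true lesion
#' mask as NIfTI files, and writes a CSV manifest loadable by
#' [load_manifest()] that also records the genotype (as the `idh` label:
#' mutant = positive), the true CU ratio and the true band volumes.
#'
#' @param cohort A tibble from [sample_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory '%s'", out_dir))
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sid <- cohort$subject_id[i]
    ph <- render_phantom(cohort$spec[[i]])
    image_path <- file.path(out_dir, sprintf("%s_suv.nii.gz", sid))
    mask_path <- file.path(out_dir, sprintf("%s_lesion.nii.gz", sid))
    write_nifti_volume(ph$volume, image_path)
    write_nifti_volume(ph$lesion, mask_path)
    tibble::tibble(
      subject_id = sid,
      image_path = basename(image_path),
      lesion_mask_path = basename(mask_path),
      idh = ifelse(cohort$genotype[i] == "mutant", "positive", "negative"),
      mgmt = "unknown", atrx = "unknown", loh1p19q = "unknown",
      genotype = cohort$genotype[i],
      cu_true = cohort$cu_true[i],
      true_v_central = cohort$v_central[i],
      true_v_gap = cohort$v_gap[i],
      true_v_peripheral = cohort$v_peripheral[i],
      seed = cohort$spec[[i]]$seed
    )
  })
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}
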