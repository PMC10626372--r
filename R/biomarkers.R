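#' Mask volume in cubic centimetres
#'
#' Voxel count times voxel volume (product of spacings, mm^3), divided by
#' 1000. Volumes are kept at full double precision; rounding happens only at
#' the report layer.
#'
#' @param mask A [binary_mask()].
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$spacing_mm) / 1000
}

#' Mean SUV within a mask
#'
#' @param volume An [suv_volume()].
#' @param mask A non-empty [binary_mask()].
#' @return Arithmetic mean SUV.
#' @export
mean_suv <- function(volume, mask) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "binary_mask"))
  check_same_geometry(volume, mask)
  if (!any(mask$values)) stop("cannot take mean SUV of an empty mask")
  mean(volume$values[mask$values])
}

#' Compartmental uptake (CU) ratios
#'
#' The peripheral-over-central ratios: `cu_volumetric` is the ratio of the
#' 60-75% band volume to the 80-100% band volume; `cu_suv` is the ratio of
#' their mean SUVs. Both are invariant under global positive rescaling of the
#' SUV volume. An empty compartment is an error, never a silent `NaN`.
#'
#' @param set A [extract_compartments()] result.
#' @param volume The companion [suv_volume()].
#' @return A one-row tibble with `cu_volumetric` and `cu_suv`.
#' @export
cu_ratios <- function(set, volume) {
  stopifnot(inherits(set, "compartment_set"))
  if (!any(set$roi80$values)) stop("central compartment (ROI80) is empty")
  if (!any(set$roi60$values)) stop("peripheral compartment (ROI60) is empty")
  tibble::tibble(
    cu_volumetric = mask_volume_cm3(set$roi60) / mask_volume_cm3(set$roi80),
    cu_suv = mean_suv(volume, set$roi60) / mean_suv(volume, set$roi80)
  )
}

#' Mean target-to-background ratio
#'
#' Mean SUV of the central compartment (ROI80, a 3D VOI) divided by the mean
#' SUV of the contralateral background.
#'
#' @inheritParams cu_ratios
#' @param background A [background_roi()] or a positive numeric background
#'   mean.
#' @return TBR (numeric scalar).
#' @export
tbr_mean <- function(set, volume, background) {
  stopifnot(inherits(set, "compartment_set"))
  bg <- if (inherits(background, "background_roi")) background$mean_suv
  else as.numeric(background)
  if (bg <= 0) stop("background mean must be positive")
  if (!any(set$roi80$values)) stop("central compartment (ROI80) is empty")
  mean_suv(volume, set$roi80) / bg
}

#' Dice coefficient between two masks
#'
#' `2|X n Y| / (|X| + |Y|)` on the voxel sets of co-registered masks; a
#' geometry mismatch is an error, never an implicit interpolation.
#'
#' @param a,b [binary_mask()]s with identical geometry, not both empty.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_geometry(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a$values & b$values) / (na + nb)
}

#' Jaccard index between two masks
#'
#' `|X n Y| / |X u Y|`; related to Dice by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_geometry(a, b)
  u <- sum(a$values | b$values)
  if (u == 0) stop("Jaccard undefined: both masks are empty")
  sum(a$values & b$values) / u
}

#' Assemble the per-subject biomarker record
#'
#' One row of the cohort table: compartment volumes (cm^3), band mean SUVs,
#' CU ratios, TBR, optional Dice/Jaccard overlaps with contrast-enhancing and
#' T2 lesion masks, molecular labels, and provenance (SUVmax, thresholds).
#' Overlap columns are absent (not zero) when the optional masks are missing.
#'
#' @param volume An [suv_volume()].
#' @param set A [extract_compartments()] result.
#' @param background A [background_roi()] or numeric background mean
#'   (defaults to the one stored in `set`).
#' @param subject_id Subject identifier.
#' @param ce_mask,t2_mask Optional contrast-enhancing / T2 lesion
#'   [binary_mask()]s for overlap indices.
#' @param labels Named list/vector of molecular labels (e.g.
#'   `c(idh = "positive")`); stored as columns.
#' @return A one-row tibble of class `lesion_record`.
#' @export
lesion_record <- function(volume, set, background = NULL,
                          subject_id = "subject", ce_mask = NULL,
                          t2_mask = NULL, labels = NULL) {
  stopifnot(inherits(set, "compartment_set"))
  bg_mean <- if (is.null(background)) set$background_mean
  else if (inherits(background, "background_roi")) background$mean_suv
  else as.numeric(background)
  ratios <- cu_ratios(set, volume)
  rec <- tibble::tibble(
    subject_id = subject_id,
    suv_max = set$suv_max,
    v_mtv60_cm3 = mask_volume_cm3(set$mtv60),
    v_mtv_abs_cm3 = mask_volume_cm3(set$mtv_abs),
    v_roi60_cm3 = mask_volume_cm3(set$roi60),
    v_roi80_cm3 = mask_volume_cm3(set$roi80),
    suv_mean_roi60 = mean_suv(volume, set$roi60),
    suv_mean_roi80 = mean_suv(volume, set$roi80),
    background_mean = bg_mean,
    cu_volumetric = ratios$cu_volumetric,
    cu_suv = ratios$cu_suv,
    tbr_mean = tbr_mean(set, volume, bg_mean)
  )
  if (!is.null(ce_mask)) {
    rec$dice_mtv60_ce <- dice(set$mtv60, ce_mask)
    rec$jaccard_mtv60_ce <- jaccard(set$mtv60, ce_mask)
  }
  if (!is.null(t2_mask)) {
    rec$dice_t2_mtv60 <- dice(t2_mask, set$mtv60)
    rec$jaccard_t2_mtv60 <- jaccard(t2_mask, set$mtv60)
  }
  if (!is.null(ce_mask) && !is.null(t2_mask)) {
    rec$dice_t2_ce <- dice(t2_mask, ce_mask)
    rec$jaccard_t2_ce <- jaccard(t2_mask, ce_mask)
  }
  if (!is.null(labels)) {
    for (nm in names(labels)) rec[[nm]] <- unname(labels[[nm]])
  }
  class(rec) <- c("lesion_record", class(rec))
  rec
}
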