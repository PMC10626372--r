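#' Select the target lesion from a multifocal mask
#'
#' Multifocal disease is reduced to the most prominent lesion: the
#' 26-connected component with the largest voxel volume. Ties are broken by
#' the higher contained SUV maximum (when a volume is supplied), then by the
#' lowest linear voxel index, so the choice is deterministic.
#'
#' @param mask A non-empty [binary_mask()].
#' @param volume Optional companion [suv_volume()] used for the SUVmax
#'   tie-break.
#' @return A [binary_mask()] containing a single connected component.
#' @export
select_target_lesion <- function(mask, volume = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("lesion mask is empty")
  if (!is.null(volume)) check_same_geometry(volume, mask)
  labels <- label_components_26(mask$values)
  ncomp <- max(labels)
  if (ncomp == 1) return(mask)
  sizes <- tabulate(labels[labels > 0], nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1 && !is.null(volume)) {
    peaks <- vapply(best, function(k) max(volume$values[labels == k]), 0)
    best <- best[peaks == max(peaks)]
  }
  if (length(best) > 1) {
    first_idx <- vapply(best, function(k) min(which(labels == k)), 0L)
    best <- best[which.min(first_idx)]
  }
  out <- mask
  out$values <- labels == best[1]
  out
}

#' Remove excluded regions (e.g. large vessels) from a mask
#'
#' @param mask,exclusion [binary_mask()]s with identical geometry.
#' @return The set difference `mask \ exclusion` as a [binary_mask()]. Warns
#'   if the result is empty.
#' @export
exclude_regions <- function(mask, exclusion) {
  stopifnot(inherits(mask, "binary_mask"), inherits(exclusion, "binary_mask"))
  check_same_geometry(mask, exclusion)
  out <- mask
  out$values <- mask$values & !exclusion$values
  if (!any(out$values)) warning("exclusion removed the entire mask")
  out
}

#' Maximum lesion SUV
#'
#' The reference maximum for isocontouring. Default: the single hottest voxel
#' within the lesion. `robust_peak = TRUE` instead reports the highest mean
#' over each voxel's 26-neighbourhood (restricted to the lesion), a
#' noise-robust peak variant.
#'
#' @param volume An [suv_volume()].
#' @param lesion A non-empty [binary_mask()].
#' @param robust_peak Use the neighbourhood-averaged peak (default `FALSE`).
#' @return The lesion SUV maximum (numeric scalar).
#' @export
lesion_suv_max <- function(volume, lesion, robust_peak = FALSE) {
  stopifnot(inherits(volume, "suv_volume"), inherits(lesion, "binary_mask"))
  check_same_geometry(volume, lesion)
  if (!any(lesion$values)) stop("lesion mask is empty")
  if (!robust_peak) return(max(volume$values[lesion$values]))
  d <- dim(volume$values)
  idx <- which(lesion$values)
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  peaks <- vapply(seq_along(idx), function(r) {
    nb <- sweep(offs, 2, co[r, ], `+`)
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    lin <- (nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]
    lin <- lin[lesion$values[lin]]
    mean(volume$values[lin])
  }, 0)
  max(peaks)
}

#' Relative isocontour band mask
#'
#' Selects voxels of the search region whose SUV lies within
#' `[lower_frac * suv_max, upper_frac * suv_max]`, both bounds inclusive
#' (closed percentage bands: a voxel at exactly 75% of maximum is peripheral,
#' at exactly 80% central).
#'
#' @param volume An [suv_volume()].
#' @param search_mask A [binary_mask()] delimiting the search region.
#' @param lower_frac,upper_frac Band bounds as fractions of `suv_max`, with
#'   `0 < lower_frac <= upper_frac <= 1`.
#' @param suv_max Reference maximum, see [lesion_suv_max()].
#' @param label Label for the returned mask.
#' @return A [binary_mask()].
#' @export
isocontour_mask <- function(volume, search_mask, lower_frac, upper_frac,
                            suv_max, label = "mtv60") {
  stopifnot(inherits(volume, "suv_volume"), inherits(search_mask, "binary_mask"))
  check_same_geometry(volume, search_mask)
  if (!(lower_frac > 0 && lower_frac <= upper_frac && upper_frac <= 1)) {
    stop("require 0 < lower_frac <= upper_frac <= 1")
  }
  lo <- lower_frac * suv_max
  hi <- upper_frac * suv_max
  out <- search_mask
  out$values <- search_mask$values & volume$values >= lo & volume$values <= hi
  out$label <- label
  out
}

#' Absolute-threshold metabolic tumor volume
#'
#' The clinically established MTV definition: voxels of the search region
#' with SUV at or above `k` times the contralateral background mean
#' (default `k = 1.8`).
#'
#' @inheritParams isocontour_mask
#' @param background_mean Mean SUV of the healthy contralateral background
#'   (> 0).
#' @param k Threshold multiplier (default 1.8).
#' @return A [binary_mask()] labelled `"mtv_abs"`.
#' @export
absolute_mtv <- function(volume, search_mask, background_mean, k = 1.8) {
  stopifnot(inherits(volume, "suv_volume"), inherits(search_mask, "binary_mask"))
  check_same_geometry(volume, search_mask)
  if (background_mean <= 0) stop("background_mean must be positive")
  out <- search_mask
  out$values <- search_mask$values & volume$values >= k * background_mean
  out$label <- "mtv_abs"
  out
}

#' Mirrored contralateral background ROI
#'
#' Estimates nonspecific background uptake from a 2D region of the same size
#' as the tumor's in-plane extent, mirrored to the unaffected hemisphere. The
#' representative axial slice is the one maximizing mean SUV within the total
#' metabolic tumor volume; the tumor's in-slice mask is mirrored across the
#' mid-plane of the left-right axis (from the orientation code). If the
#' mirrored region touches the tumor or exits the grid it is shifted along
#' the nearest valid in-plane position (shifts ordered by increasing
#' magnitude, preferring purely lateral moves away from the midline), so
#' that even lesions straddling the midline receive a disjoint equal-area
#' background region whenever one fits in the grid.
#'
#' @param volume An [suv_volume()].
#' @param tumor_mask The anatomical lesion [binary_mask()].
#' @param mtv60 The total (60-100%) metabolic compartment [binary_mask()].
#' @return A list of class `background_roi` with `slice_index`, `mask2d`
#'   (in-plane logical matrix), `mean_suv`, `area_mm2` and `lr_axis`.
#' @export
background_roi <- function(volume, tumor_mask, mtv60) {
  stopifnot(inherits(volume, "suv_volume"), inherits(tumor_mask, "binary_mask"),
            inherits(mtv60, "binary_mask"))
  check_same_geometry(volume, tumor_mask)
  check_same_geometry(volume, mtv60)
  if (!any(tumor_mask$values)) stop("tumor mask is empty")
  d <- dim(volume$values)
  # representative slice: axial (3rd axis) slice with highest mean uptake in mtv60
  ref <- if (any(mtv60$values)) mtv60$values else tumor_mask$values
  slice_means <- vapply(seq_len(d[3]), function(k) {
    m <- ref[, , k]
    if (any(m)) mean(volume$values[, , k][m]) else -Inf
  }, 0)
  slice_index <- which.max(slice_means)
  tum2d <- tumor_mask$values[, , slice_index]
  if (!any(tum2d)) tum2d <- ref[, , slice_index]
  ax <- lr_axis(volume$axis_codes)
  if (ax == 3) stop("left-right axis coincides with the slice axis; cannot mirror in-plane")
  ap <- setdiff(1:2, ax)  # in-plane secondary axis for midline lesions
  n_lr <- d[ax]
  tum_slice <- tumor_mask$values[, , slice_index]
  src <- which(tum2d, arr.ind = TRUE)
  mirrored <- src
  mirrored[, ax] <- n_lr + 1L - src[, ax]
  # candidate in-plane shifts of the mirrored region, by increasing
  # magnitude; ties prefer purely lateral moves, then the direction away
  # from the mirrored centroid's side of the tumor
  away <- sign((d[1:2] + 1) / 2 - colMeans(mirrored)[1:2])
  away[away == 0] <- 1
  away <- -away  # away from midline = towards the mirrored side
  sh <- expand.grid(dx = -(d[1] - 1):(d[1] - 1), dy = -(d[2] - 1):(d[2] - 1))
  lat <- if (ax == 1) sh$dx else sh$dy
  med <- if (ax == 1) sh$dy else sh$dx
  ord <- order(sh$dx^2 + sh$dy^2, med^2,
               -sign(sh$dx) * away[1], -sign(sh$dy) * away[2])
  sh <- sh[ord, ]
  placed <- NULL
  for (i in seq_len(nrow(sh))) {
    di <- mirrored[, 1] + sh$dx[i]
    dj <- mirrored[, 2] + sh$dy[i]
    if (min(di) < 1L || max(di) > d[1] || min(dj) < 1L || max(dj) > d[2]) next
    if (any(tum_slice[cbind(di, dj)])) next
    placed <- matrix(FALSE, d[1], d[2])
    placed[cbind(di, dj)] <- TRUE
    break
  }
  if (is.null(placed)) {
    stop("no valid contralateral background placement; supply a manual background mask")
  }
  inplane <- prod(volume$spacing_mm[1:2])
  structure(
    list(slice_index = slice_index, mask2d = placed,
         mean_suv = mean(volume$values[, , slice_index][placed]),
         area_mm2 = sum(placed) * inplane,
         lr_axis = ax),
    class = "background_roi"
  )
}

#' Extract the metabolic compartments of a lesion
#'
#' The full segmentation chain: apply the vessel/exclusion mask, select the
#' target lesion (largest 26-connected component), measure the lesion SUV
#' maximum, and threshold relative isocontour bands within the target lesion
#' dilated by a small margin (default 2 voxels, so isocontours may slightly
#' exceed the anatomical mask). Yields the total 60-100% compartment (MTV60),
#' the peripheral 60-75% band (ROI60), the central 80-100% band (ROI80), the
#' absolute-threshold MTV (1.8 x background mean) and the background ROI.
#'
#' @param volume An [suv_volume()].
#' @param lesion Anatomical lesion [binary_mask()] (non-empty).
#' @param exclusion Optional exclusion [binary_mask()] (e.g. large vessels).
#' @param background Optional precomputed [background_roi()] or a numeric
#'   background mean; computed from a mirrored contralateral ROI when `NULL`.
#' @param dilate_voxels Dilation margin of the search region (default 2).
#' @param robust_peak See [lesion_suv_max()].
#' @param suvmax_before_exclusion Measure the reference maximum before
#'   applying the exclusion mask (default `FALSE`: after exclusion).
#' @param k_abs Multiplier for the absolute MTV threshold (default 1.8).
#' @return A list of class `compartment_set` with elements `suv_max`,
#'   `mtv60`, `roi60`, `roi80`, `mtv_abs`, `background`
#'   (a [background_roi()] or `NULL`), `background_mean` and
#'   `thresholds_used` (named numeric: the absolute SUV cutoffs applied).
#' @export
extract_compartments <- function(volume, lesion, exclusion = NULL,
                                 background = NULL, dilate_voxels = 2L,
                                 robust_peak = FALSE,
                                 suvmax_before_exclusion = FALSE,
                                 k_abs = 1.8) {
  stopifnot(inherits(volume, "suv_volume"), inherits(lesion, "binary_mask"))
  check_same_geometry(volume, lesion)
  if (!any(lesion$values)) stop("lesion mask is empty")
  suv_max_pre <- if (suvmax_before_exclusion) {
    lesion_suv_max(volume, select_target_lesion(lesion, volume), robust_peak)
  } else NULL
  work <- lesion
  if (!is.null(exclusion)) work <- exclude_regions(work, exclusion)
  if (!any(work$values)) stop("lesion empty after exclusion")
  target <- select_target_lesion(work, volume)
  suv_max <- if (!is.null(suv_max_pre)) suv_max_pre
  else lesion_suv_max(volume, target, robust_peak)
  search <- target
  search$values <- dilate_box(target$values, as.integer(dilate_voxels))
  if (!is.null(exclusion)) search$values <- search$values & !exclusion$values
  mtv60 <- isocontour_mask(volume, search, 0.60, 1.00, suv_max, label = "mtv60")
  roi60 <- isocontour_mask(volume, search, 0.60, 0.75, suv_max, label = "roi60")
  roi80 <- isocontour_mask(volume, search, 0.80, 1.00, suv_max, label = "roi80")
  if (!any(roi80$values)) {
    stop("no central compartment: ROI80 is empty, CU ratio undefined")
  }
  if (!any(roi60$values)) {
    warning("peripheral compartment (ROI60) is empty")
  }
  bg <- NULL
  if (is.null(background)) {
    bg <- background_roi(volume, target, mtv60)
    background_mean <- bg$mean_suv
  } else if (inherits(background, "background_roi")) {
    bg <- background
    background_mean <- bg$mean_suv
  } else {
    background_mean <- as.numeric(background)
  }
  if (background_mean <= 0) stop("background mean must be positive")
  mtv_abs <- absolute_mtv(volume, search, background_mean, k = k_abs)
  structure(
    list(suv_max = suv_max, mtv60 = mtv60, roi60 = roi60, roi80 = roi80,
         mtv_abs = mtv_abs, background = bg, background_mean = background_mean,
         thresholds_used = c(mtv60 = 0.60 * suv_max, roi60_upper = 0.75 * suv_max,
                             roi80 = 0.80 * suv_max,
                             mtv_abs = k_abs * background_mean)),
    class = "compartment_set"
  )
}

#' @export
print.compartment_set <- function(x, ...) {
  cat(sprintf(
    "<compartment_set> SUVmax %.3g | MTV60 %d vx | ROI60 %d vx | ROI80 %d vx | MTVabs %d vx\n",
    x$suv_max, sum(x$mtv60$values), sum(x$roi60$values), sum(x$roi80$values),
    sum(x$mtv_abs$values)))
  invisible(x)
}
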