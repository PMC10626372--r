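#' SUV volume container
#'
#' A 3D grid of standardized uptake values (SUV) together with its voxel
#' geometry. SUV is dimensionless (tracer concentration normalized by injected
#' dose and body weight); spacing is in millimetres. Orientation is carried as
#' a three-letter NIfTI-style code (e.g. `"RAS"`), one letter per array axis.
#'
#' @param values 3D numeric array of non-negative, finite SUV values.
#' @param spacing_mm Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin_mm Numeric length-3, world coordinate (mm) of voxel (1,1,1).
#' @param axis_codes Three-letter orientation string, one of R/L, A/P, S/I per
#'   axis.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                       axis_codes = "RAS") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("SUV volume contains non-finite values")
  if (any(values < 0)) stop("SUV values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive values")
  }
  check_axis_codes(axis_codes)
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), axis_codes = axis_codes),
    class = "suv_volume"
  )
}

#' Binary mask container
#'
#' A 3D binary region sharing the geometry of a companion [suv_volume()].
#' Values are strictly 0/1 (stored as logical); anything else is rejected
#' rather than thresholded.
#'
#' @param values 3D logical array, or numeric array containing only 0 and 1.
#' @inheritParams suv_volume
#' @param label Role of the mask, one of `"lesion"`, `"exclusion"`,
#'   `"contrast_enhancing"`, `"t2"`, `"mtv60"`, `"roi60"`, `"roi80"`,
#'   `"mtv_abs"`, `"background"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                        axis_codes = "RAS", label = "lesion") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (is.logical(values)) {
    if (anyNA(values)) stop("mask contains NA")
    lg <- values
  } else {
    if (!all(values %in% c(0, 1))) {
      stop("mask is not binary: values other than 0/1 present")
    }
    lg <- array(values == 1, dim = dim(values))
  }
  if (length(label) != 1 || !label %in% mask_labels()) {
    stop(sprintf("invalid mask label '%s'; must be one of: %s",
                 paste(label, collapse = ","),
                 paste(mask_labels(), collapse = ", ")))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive values")
  }
  check_axis_codes(axis_codes)
  structure(
    list(values = lg, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), axis_codes = axis_codes,
         label = label),
    class = "binary_mask"
  )
}

mask_labels <- function() {
  c("lesion", "exclusion", "contrast_enhancing", "t2",
    "mtv60", "roi60", "roi80", "mtv_abs", "background")
}

check_axis_codes <- function(axis_codes) {
  if (!is.character(axis_codes) || length(axis_codes) != 1 ||
      nchar(axis_codes) != 3 ||
      !all(strsplit(axis_codes, "")[[1]] %in% c("R", "L", "A", "P", "S", "I"))) {
    stop("axis_codes must be a three-letter string over {R,L,A,P,S,I}")
  }
  invisible(axis_codes)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s voxels @ %s mm, range [%.3g, %.3g], %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing_mm, collapse = "x"),
              min(x$values), max(x$values), x$axis_codes))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s> %s voxels @ %s mm, %d set\n",
              x$label, paste(dim(x$values), collapse = "x"),
              paste(x$spacing_mm, collapse = "x"), sum(x$values)))
  invisible(x)
}

# Geometry must agree between a volume and its masks: identical shape, spacing
# within 1e-4 relative, identical orientation. No resampling is ever attempted;
# inputs are assumed co-registered.
check_same_geometry <- function(a, b, tol = 1e-4) {
  da <- dim(a$values); db <- dim(b$values)
  if (!identical(da, db)) {
    stop(sprintf("geometry mismatch: shape %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  rel <- abs(a$spacing_mm - b$spacing_mm) / a$spacing_mm
  if (any(rel > tol)) {
    stop(sprintf("geometry mismatch: spacing %s vs %s mm",
                 paste(a$spacing_mm, collapse = "x"),
                 paste(b$spacing_mm, collapse = "x")))
  }
  if (!identical(a$axis_codes, b$axis_codes)) {
    stop(sprintf("geometry mismatch: orientation %s vs %s",
                 a$axis_codes, b$axis_codes))
  }
  invisible(TRUE)
}

# World coordinates (mm) of the voxel centers along one axis, 1-based indices.
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# Which array axis is the anatomical left-right axis, from the orientation
# code. Falls back to axis 1 if no R/L letter is present.
lr_axis <- function(axis_codes) {
  letters3 <- strsplit(axis_codes, "")[[1]]
  ax <- which(letters3 %in% c("R", "L"))
  if (length(ax) != 1) 1L else ax
}

# --- morphology -------------------------------------------------------------

# Chebyshev (box) binary dilation by `r` voxels, separable along the three
# axes. Operates on a cropped bounding box for speed.
dilate_box <- function(arr, r) {
  if (r <= 0 || !any(arr)) return(arr)
  d <- dim(arr)
  bb <- mask_bbox(arr, pad = r, dims = d)
  sub <- arr[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  for (axis in 1:3) sub <- dilate_axis(sub, r, axis)
  out <- array(FALSE, d)
  out[bb[[1]], bb[[2]], bb[[3]]] <- sub
  out
}

dilate_axis <- function(arr, r, axis) {
  out <- arr
  n <- dim(arr)[axis]
  for (s in seq_len(min(r, n - 1))) {
    if (axis == 1) {
      out[seq_len(n - s), , ] <- out[seq_len(n - s), , ] | arr[(s + 1):n, , ]
      out[(s + 1):n, , ] <- out[(s + 1):n, , ] | arr[seq_len(n - s), , ]
    } else if (axis == 2) {
      out[, seq_len(n - s), ] <- out[, seq_len(n - s), ] | arr[, (s + 1):n, ]
      out[, (s + 1):n, ] <- out[, (s + 1):n, ] | arr[, seq_len(n - s), ]
    } else {
      out[, , seq_len(n - s)] <- out[, , seq_len(n - s)] | arr[, , (s + 1):n]
      out[, , (s + 1):n] <- out[, , (s + 1):n] | arr[, , seq_len(n - s)]
    }
  }
  out
}

mask_bbox <- function(arr, pad = 0L, dims = dim(arr)) {
  idx <- which(arr)
  co <- arrayInd(idx, dims)
  lapply(1:3, function(a) {
    max(1L, min(co[, a]) - pad):min(dims[a], max(co[, a]) + pad)
  })
}

# 26-connected component labelling by geodesic dilation growth (dilate the
# current component by one voxel, intersect with the mask, repeat to
# stability). Returns an integer array, 0 = background.
label_components_26 <- function(arr) {
  d <- dim(arr)
  labels <- array(0L, d)
  remaining <- arr
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    seed <- which(remaining)[1]
    bb <- mask_bbox(remaining, pad = 0L, dims = d)
    sub_mask <- remaining[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
    cur <- array(FALSE, dim(sub_mask))
    co <- arrayInd(seed, d)
    cur[co[1] - bb[[1]][1] + 1, co[2] - bb[[2]][1] + 1, co[3] - bb[[3]][1] + 1] <- TRUE
    repeat {
      grown <- cur
      for (axis in 1:3) grown <- dilate_axis(grown, 1L, axis)
      grown <- grown & sub_mask
      if (sum(grown) == sum(cur)) break
      cur <- grown
    }
    full <- array(FALSE, d)
    full[bb[[1]], bb[[2]], bb[[3]]] <- cur
    labels[full] <- comp
    remaining <- remaining & !full
  }
  labels
}
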