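#' Read an SUV volume from a NIfTI file
#'
#' Voxel data, spacing and orientation are taken from the NIfTI header without
#' any resampling or reorientation; inputs are assumed co-registered upstream.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return An [suv_volume()].
#' @export
read_suv_volume <- function(path) {
  img <- read_nifti_3d(path)
  suv_volume(values = array(as.double(img), dim(img)),
             spacing_mm = RNifti::pixdim(img)[1:3],
             origin_mm = nifti_origin_mm(img),
             axis_codes = RNifti::orientation(img))
}

#' Read a binary mask from a NIfTI file
#'
#' The mask must be strictly binary: any value other than 0 or 1 is a hard
#' error, never an implicit threshold.
#'
#' @inheritParams read_suv_volume
#' @param label Mask role, see [binary_mask()].
#' @param reference Optional [suv_volume()] whose geometry the mask must
#'   match (shape, spacing within 1e-4 relative, orientation).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, label = "lesion", reference = NULL) {
  img <- read_nifti_3d(path)
  vals <- array(as.double(img), dim(img))
  if (!all(vals %in% c(0, 1))) {
    stop(sprintf("mask '%s' is not binary (contains values other than 0/1)", path))
  }
  m <- binary_mask(values = vals,
                   spacing_mm = RNifti::pixdim(img)[1:3],
                   origin_mm = nifti_origin_mm(img),
                   axis_codes = RNifti::orientation(img),
                   label = label)
  if (!is.null(reference)) check_same_geometry(reference, m)
  m
}

#' Write a volume or mask to NIfTI
#'
#' SUV volumes are written as float64 (lossless round trip); masks as uint8.
#'
#' @param x An [suv_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$values), dim(x$values))
    dtype <- "uint8"
  } else if (inherits(x, "suv_volume")) {
    arr <- x$values
    dtype <- "double"
  } else {
    stop("x must be an suv_volume or binary_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = dtype); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("failed to write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "binary_mask"))
  write_nifti_volume(x, path)
}

read_nifti_3d <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  # tolerate trailing singleton 4th dimension, reject anything else
  if (length(d) == 4 && d[4] == 1) {
    img <- RNifti::asNifti(array(as.array(img), d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3) {
    stop(sprintf("'%s' is not a 3D image (dims: %s)", path,
                 paste(d, collapse = "x")))
  }
  img
}

nifti_origin_mm <- function(img) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error")) return(c(0, 0, 0))
  as.numeric(xf[1:3, 4])
}

# --- cohort manifest --------------------------------------------------------

manifest_label_cols <- function() c("idh", "mgmt", "atrx", "loh1p19q")

#' Load and validate a cohort manifest
#'
#' The manifest is an RFC-4180 CSV with one row per subject mapping subject ID
#' to image/mask paths and molecular labels. Required columns: `subject_id`,
#' `image_path`, `lesion_mask_path`. Optional mask columns:
#' `exclusion_mask_path`, `ce_mask_path`, `t2_mask_path`. Molecular label
#' columns (`idh`, `mgmt`, `atrx`, `loh1p19q`) are restricted to
#' `positive`/`negative`/`unknown`; empty cells, `NA` and "Not applicable"
#' are stored as `"unknown"`. Relative paths are resolved against the
#' manifest's directory; all referenced files must exist.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of class `cu_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  mf <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(mf) == 0) stop("manifest contains no subjects")
  req <- c("subject_id", "image_path", "lesion_mask_path")
  missing_cols <- setdiff(req, names(mf))
  if (length(missing_cols)) {
    stop(sprintf("manifest missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  mf$subject_id <- as.character(mf$subject_id)
  if (anyDuplicated(mf$subject_id)) {
    dup <- unique(mf$subject_id[duplicated(mf$subject_id)])
    stop(sprintf("duplicate subject_id in manifest: %s",
                 paste(dup, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  path_cols <- intersect(
    c("image_path", "lesion_mask_path", "exclusion_mask_path",
      "ce_mask_path", "t2_mask_path"), names(mf))
  for (pc in path_cols) {
    p <- mf[[pc]]
    resolved <- ifelse(is.na(p) | p == "", NA_character_,
                       ifelse(grepl("^/", p), p, file.path(base, p)))
    if (pc %in% req && anyNA(resolved)) {
      stop(sprintf("manifest column '%s' has empty entries", pc))
    }
    missing_files <- resolved[!is.na(resolved) & !file.exists(resolved)]
    if (length(missing_files)) {
      stop(sprintf("manifest references missing file(s): %s",
                   paste(utils::head(missing_files, 5), collapse = ", ")))
    }
    mf[[pc]] <- resolved
  }
  for (lc in manifest_label_cols()) {
    if (!lc %in% names(mf)) {
      mf[[lc]] <- "unknown"
    } else {
      v <- tolower(trimws(as.character(mf[[lc]])))
      v[is.na(v) | v %in% c("", "na", "not applicable", "n/a", "unknown")] <- "unknown"
      bad <- setdiff(unique(v), c("positive", "negative", "unknown"))
      if (length(bad)) {
        stop(sprintf("manifest column '%s' has labels outside positive/negative/unknown: %s",
                     lc, paste(bad, collapse = ", ")))
      }
      mf[[lc]] <- v
    }
  }
  class(mf) <- c("cu_manifest", class(mf))
  mf
}
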