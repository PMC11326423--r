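# Loading, cropping and tensor preparation for normalized grey-matter maps.
#
# Inputs are grey-matter probability maps already normalized to template
# space (segmentation/normalization is upstream and out of scope). The
# hippocampal region of interest is expressed as half-open voxel-index
# slices on the template grid; the default box [24,96) x [54,107) x [16,49)
# covers both hippocampi and the surrounding sulci and yields crops of
# 72 x 53 x 33 voxels.

#' Region-of-interest box on the template grid
#'
#' Half-open voxel-index intervals (0-based, slice convention): a range
#' `c(a, b)` selects voxels `a, a+1, ..., b-1`.
#'
#' @param x,y,z Integer length-2 vectors `c(from, to)`, half-open.
#' @return An object of class `roi_box` with an `extents` field.
#' @export
roi_box <- function(x = c(24L, 96L), y = c(54L, 107L), z = c(16L, 49L)) {
  for (r in list(x = x, y = y, z = z)) {
    if (length(r) != 2L || any(!is.finite(r)) || r[2] <= r[1] || any(r < 0)) {
      stop_input("ROI ranges must be half-open intervals c(from, to) with to > from >= 0")
    }
  }
  structure(list(x = as.integer(x), y = as.integer(y), z = as.integer(z),
                 extents = c(x[2] - x[1], y[2] - y[1], z[2] - z[1])),
            class = "roi_box")
}

#' Default hippocampal ROI
#' @return The `roi_box` `[24,96) x [54,107) x [16,49)` (extents 72 x 53 x 33).
#' @export
default_roi <- function() roi_box()

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("ROI box [%d,%d) x [%d,%d) x [%d,%d), extents %s\n",
              x$x[1], x$x[2], x$y[1], x$y[2], x$z[1], x$z[2],
              paste(x$extents, collapse = " x ")))
  invisible(x)
}

#' Construct a grey-matter crop
#'
#' A `gm_crop` is a 3D array of grey-matter probabilities over the
#' hippocampal ROI, carrying provenance metadata.
#'
#' @param voxels 3D numeric array.
#' @param hemisphere `"left"` or `"right"`.
#' @param subject_id,cohort Optional identifiers.
#' @param roi Optional `roi_box` the crop was extracted with.
#' @return A `gm_crop` object.
#' @export
gm_crop <- function(voxels, hemisphere = "left", subject_id = NA_character_,
                    cohort = NA_character_, roi = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_input("`voxels` must be a 3D array")
  }
  if (any(!is.finite(voxels))) stop_input("crop contains non-finite voxels")
  if (!hemisphere %in% c("left", "right")) stop_input("hemisphere must be 'left' or 'right'")
  structure(voxels,
            hemisphere = hemisphere, subject_id = subject_id,
            cohort = cohort, roi = roi, class = c("gm_crop", "array"))
}

#' @export
print.gm_crop <- function(x, ...) {
  cat(sprintf("grey-matter crop %s, hemisphere %s, subject %s, range [%.3f, %.3f]\n",
              paste(dim(x), collapse = " x "), attr(x, "hemisphere"),
              attr(x, "subject_id"), min(x), max(x)))
  invisible(x)
}

#' Load a normalized grey-matter volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file holding a 3D volume.
#' @return The voxel array (class `niftiImage`) with header metadata attached.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop_input("cannot read volume: file not found: ", path)
  vol <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_input("cannot read volume ", path, ": ",
                                                 conditionMessage(e)))
  if (length(dim(vol)) != 3L) {
    stop_input("volume ", path, " is ", length(dim(vol)), "-dimensional; expected 3D")
  }
  vol
}

#' Crop the hippocampal ROI out of a full volume
#'
#' @param volume 3D array (e.g. from [load_volume()]).
#' @param roi An [roi_box()]; default [default_roi()].
#' @param hemisphere,subject_id,cohort Metadata forwarded to [gm_crop()].
#' @return A `gm_crop` whose extents equal the ROI extents.
#' @export
crop_roi <- function(volume, roi = default_roi(), hemisphere = "left",
                     subject_id = NA_character_, cohort = NA_character_) {
  d <- dim(volume)
  if (length(d) != 3L) stop_input("`volume` must be 3D")
  rng <- list(x = roi$x, y = roi$y, z = roi$z)
  for (ax in 1:3) {
    r <- rng[[ax]]
    if (r[2] > d[ax]) {
      stop_input("ROI exceeds volume bounds on axis ", c("x", "y", "z")[ax],
                 ": [", r[1], ",", r[2], ") vs extent ", d[ax])
    }
  }
  sub <- volume[(roi$x[1] + 1L):roi$x[2],
                (roi$y[1] + 1L):roi$y[2],
                (roi$z[1] + 1L):roi$z[2], drop = FALSE]
  gm_crop(unclass(as.array(sub)), hemisphere = hemisphere,
          subject_id = subject_id, cohort = cohort, roi = roi)
}

#' Mirror a crop across the left-right axis
#'
#' Right-hemisphere crops are mapped into the left-hemisphere frame (and
#' vice versa) by reversing the first (left-right) axis and toggling the
#' hemisphere label. Models are trained in a single canonical orientation.
#'
#' @param crop A `gm_crop`.
#' @return The mirrored `gm_crop`.
#' @export
mirror_hemisphere <- function(crop) {
  d <- dim(crop)
  flipped <- crop[d[1]:1, , , drop = FALSE]
  gm_crop(unclass(as.array(flipped)),
          hemisphere = if (attr(crop, "hemisphere") == "left") "right" else "left",
          subject_id = attr(crop, "subject_id"), cohort = attr(crop, "cohort"),
          roi = attr(crop, "roi"))
}

#' Min-max intensity normalization
#'
#' Rescales a crop to `[0, 1]`. Constant crops (no contrast) map to all
#' zeros rather than erroring, so degenerate phantoms cannot poison a batch.
#'
#' @param crop A `gm_crop`.
#' @return The normalized `gm_crop`.
#' @export
normalize_intensity <- function(crop) {
  if (any(!is.finite(crop))) stop_input("crop contains non-finite voxels")
  lo <- min(crop); hi <- max(crop)
  vox <- if (hi > lo) (unclass(as.array(crop)) - lo) / (hi - lo) else array(0, dim(crop))
  gm_crop(vox, hemisphere = attr(crop, "hemisphere"),
          subject_id = attr(crop, "subject_id"), cohort = attr(crop, "cohort"),
          roi = attr(crop, "roi"))
}

#' Flatten a crop to a feature vector
#'
#' Column-major order: the x (left-right) index varies fastest, then y,
#' then z. `flatten_crop` and `array(v, dim)` are exact inverses.
#'
#' @param crop A `gm_crop` (or any 3D array).
#' @return Numeric vector of length `prod(dim(crop))`.
#' @export
flatten_crop <- function(crop) as.vector(unclass(as.array(crop)))

#' Stack crops into a feature matrix
#'
#' Binds a list of equally-sized crops into the voxels-x-n matrix consumed
#' by the models (one flattened crop per column, extents recorded in the
#' `input_dims` attribute).
#'
#' @param crops Non-empty list of `gm_crop`s with identical extents.
#' @return Numeric matrix with an `input_dims` attribute.
#' @export
crops_to_matrix <- function(crops) {
  if (!length(crops)) stop_input("`crops` must contain at least one crop (non-empty)")
  d <- dim(crops[[1]])
  X <- vapply(crops, function(cr) {
    if (!identical(dim(cr), d)) stop_input("crops have inconsistent extents")
    flatten_crop(cr)
  }, numeric(prod(d)))
  structure(matrix(X, nrow = prod(d)), input_dims = d)
}
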