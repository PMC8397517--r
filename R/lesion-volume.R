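#' Binary lesion volume on a template grid
#'
#' Container for one patient's lesion mask: a 3D binary array plus the 4x4
#' affine mapping 0-based voxel indices to template (MNI-style) mm
#' coordinates. Masks read from scanner exports with arbitrary nonzero
#' values are binarised at > 0.
#'
#' @param grid 3D array; nonzero entries mark lesioned voxels.
#' @param affine 4x4 numeric voxel-index-to-mm transform (0-based indices).
#' @param patient_id Identifier string.
#' @return An object of class `lesion_volume` with elements `patient_id`,
#'   `grid` (integer 0/1 array), `affine`, and `voxel_size` (mm per axis,
#'   derived from the affine).
#' @export
lesion_volume <- function(grid, affine, patient_id = "unknown") {
  if (length(dim(grid)) != 3L)
    validation_error("lesion grid must be a 3D array")
  if (!is.matrix(affine) || any(dim(affine) != 4L))
    validation_error("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    validation_error("affine must be invertible")
  g <- array(as.integer(grid != 0 & !is.na(grid)), dim = dim(grid))
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) validation_error("voxel sizes must be strictly positive")
  structure(list(patient_id = as.character(patient_id), grid = g,
                 affine = affine, voxel_size = vs),
            class = "lesion_volume")
}

#' Read a lesion mask from a NIfTI file
#'
#' Any nonzero voxel value is treated as lesioned (scanner exports vary in
#' how they encode the mask). The affine is taken from the image header.
#'
#' @param path Path to a single-volume 3D NIfTI file.
#' @param patient_id Identifier; defaults to the file name without extension.
#' @return A [lesion_volume()].
#' @export
read_lesion_volume <- function(path, patient_id = NULL) {
  if (!file.exists(path)) validation_error(paste("file not found:", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    validation_error(paste("unreadable NIfTI file:", path,
                                           "-", conditionMessage(e))))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { arr <- arr[, , , 1L]; d <- dim(arr) }
  if (length(d) != 3L)
    validation_error(paste0("expected a single 3D volume, got ",
                            length(d), "D: ", path))
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_volume(arr, structure(unclass(RNifti::xform(img)), dim = c(4L, 4L)),
                patient_id)
}

#' Write a lesion mask to a NIfTI file (uint8)
#'
#' @param v A [lesion_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_lesion_volume <- function(v, path) {
  stopifnot(inherits(v, "lesion_volume"))
  write_nifti_array(v$grid, v$affine, path, datatype = "uint8")
}

## Shared NIfTI writer: attach the affine as both sform and qform (pixdim
## must be set first or the writer rebuilds the rotation at unit scale).
write_nifti_array <- function(arr, affine, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Lesion volume in cubic centimetres
#'
#' Count of lesioned voxels times the voxel volume in mm^3, divided by 1000.
#'
#' @param v A [lesion_volume()].
#' @return Volume in cc.
#' @export
lesion_volume_cc <- function(v) {
  stopifnot(inherits(v, "lesion_volume"))
  sum(v$grid) * prod(v$voxel_size) / 1000
}

#' Lesion overlay: per-voxel patient counts
#'
#' @param volumes List of [lesion_volume()] objects on the same grid and
#'   affine.
#' @return Object of class `lesion_overlay`: list with `counts` (3D integer
#'   array), `affine`, `n_patients`.
#' @export
compute_overlay <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  ref <- volumes[[1L]]
  for (v in volumes) {
    stopifnot(inherits(v, "lesion_volume"))
    if (!identical(dim(v$grid), dim(ref$grid)))
      validation_error(paste("grid shape mismatch for patient", v$patient_id))
    if (max(abs(v$affine - ref$affine)) > 1e-6)
      validation_error(paste("affine mismatch for patient", v$patient_id))
  }
  counts <- Reduce(`+`, lapply(volumes, `[[`, "grid"))
  structure(list(counts = counts, affine = ref$affine,
                 n_patients = length(volumes)),
            class = "lesion_overlay")
}

#' Write an overlay as int16 NIfTI
#'
#' @param overlay A `lesion_overlay`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  stopifnot(inherits(overlay, "lesion_overlay"))
  write_nifti_array(overlay$counts, overlay$affine, path, datatype = "int16")
}

#' Analyzable-voxel mask from a lesion overlay
#'
#' Voxel-wise lesion-symptom mapping is restricted to voxels lesioned in at
#' least `min_n` patients, to avoid regression estimates driven by a handful
#' of cases.
#'
#' @param overlay A `lesion_overlay` (or a plain 3D count array).
#' @param min_n Minimum number of lesioned patients per voxel (default 5).
#' @return 3D logical array; `TRUE` marks analyzable voxels. Carries the
#'   affine as attribute `"affine"` when the input had one.
#' @export
coverage_mask <- function(overlay, min_n = 5L) {
  if (min_n < 1L) stop("min_n must be >= 1")
  counts <- if (inherits(overlay, "lesion_overlay")) overlay$counts else overlay
  m <- counts >= min_n
  if (inherits(overlay, "lesion_overlay")) attr(m, "affine") <- overlay$affine
  m
}

#' @export
print.lesion_volume <- function(x, ...) {
  cat(sprintf("Lesion volume '%s': %d voxels (%.2f cc) on %s grid @ %s mm\n",
              x$patient_id, sum(x$grid), lesion_volume_cc(x),
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.lesion_overlay <- function(x, ...) {
  cat(sprintf("Lesion overlay of %d patients, max overlap %d, %s grid\n",
              x$n_patients, max(x$counts), paste(dim(x$counts), collapse = "x")))
  invisible(x)
}

#' Look up region labels at template coordinates
#'
#' Generic labelled-ROI lookup: given an integer-labelled parcellation
#' volume on the analysis grid, returns the region containing each
#' coordinate — the usual way peak coordinates are given anatomical names.
#'
#' @param label_array 3D integer array of region codes (0 = unlabelled).
#' @param affine 4x4 voxel-to-mm affine of the label volume.
#' @param mm Matrix (or vector) of mm coordinates, one row per query.
#' @param names Optional named character vector mapping codes to region
#'   names (e.g. `c("17" = "posterior MTG")`).
#' @return data.frame with `x`, `y`, `z`, `code` and (when `names` is
#'   given) `region`; coordinates outside the grid get code `NA`.
#' @export
lookup_roi_label <- function(label_array, affine, mm, names = NULL) {
  stopifnot(length(dim(label_array)) == 3L)
  mm <- rbind(mm)
  ijk0 <- round(t(solve(affine) %*% t(cbind(mm, 1)))[, 1:3, drop = FALSE])
  d <- dim(label_array)
  inside <- ijk0[, 1] >= 0 & ijk0[, 1] < d[1] &
    ijk0[, 2] >= 0 & ijk0[, 2] < d[2] &
    ijk0[, 3] >= 0 & ijk0[, 3] < d[3]
  code <- rep(NA_integer_, nrow(mm))
  code[inside] <- label_array[ijk0[inside, , drop = FALSE] + 1L]
  out <- data.frame(x = mm[, 1], y = mm[, 2], z = mm[, 3], code = code)
  if (!is.null(names)) out$region <- unname(names[as.character(code)])
  out
}

## 0-based voxel index (i, j, k) -> template mm coordinates.
voxel_to_mm <- function(ijk, affine) {
  ijk <- rbind(ijk)
  mm <- t(affine %*% t(cbind(ijk, 1)))
  mm[, 1:3, drop = FALSE]
}
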