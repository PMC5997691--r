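#' Construct an image volume
#'
#' A 3D scalar grid of CT intensities (Hounsfield units) together with its
#' physical voxel spacing and origin. This is the unit on which all radiomic
#' features are computed.
#'
#' @param voxels 3D numeric array of HU intensities.
#' @param spacing numeric length-3 voxel spacing `(dx, dy, dz)` in mm; all > 0.
#' @param origin numeric length-3 physical offset in mm.
#' @return An object of class `image_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stopf("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be three positive finite values (mm)")
  if (any(!is.finite(voxels)))
    stopf("image intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' Voxels with value > 0 are foreground. The mask must live on the same grid
#' (shape and spacing) as its paired [image_volume()].
#'
#' @param voxels 3D array; any value > 0 is foreground.
#' @inheritParams image_volume
#' @return An object of class `roi_mask`; `voxels` is stored binarized (0/1).
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stopf("`voxels` must be a 3D array")
  bin <- array(as.integer(voxels > 0), dim = dim(voxels))
  if (sum(bin) < 1)
    stopf("empty ROI: mask has no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("`spacing` must be three positive values (mm)")
  structure(list(voxels = bin, spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

check_alignment <- function(image, mask, tol = 1e-4) {
  if (!identical(dim(image$voxels), dim(mask$voxels)))
    stopf("alignment error: image grid %s vs mask grid %s",
          paste(dim(image$voxels), collapse = "x"),
          paste(dim(mask$voxels), collapse = "x"))
  if (any(abs(image$spacing - mask$spacing) > tol))
    stopf("alignment error: voxel spacings differ by more than %g mm", tol)
  invisible(TRUE)
}

#' Construct a lesion record
#'
#' One segmented lesion of a patient: identifiers, RECIST-style longest axial
#' diameter, and (optionally deferred) image/mask pair.
#'
#' @param patient_id,lesion_id character identifiers.
#' @param lesion_type one of `"primary"`, `"node"`, `"lung_met"`, `"pleural"`,
#'   `"distant"`.
#' @param size_mm longest axial diameter in mm.
#' @param image an [image_volume()] or `NULL` (metadata-only record).
#' @param mask an [roi_mask()] or `NULL`.
#' @return An object of class `lesion_record`.
#' @export
lesion_record <- function(patient_id, lesion_id, lesion_type, size_mm,
                          image = NULL, mask = NULL) {
  lesion_type <- match.arg(lesion_type,
                           c("primary", "node", "lung_met", "pleural", "distant"))
  if (!is.null(image) && !is.null(mask)) check_alignment(image, mask)
  structure(list(patient_id = as.character(patient_id),
                 lesion_id = as.character(lesion_id),
                 lesion_type = lesion_type,
                 size_mm = as.numeric(size_mm),
                 image = image, mask = mask),
            class = "lesion_record")
}

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(3)])
}

nifti_origin <- function(img) {
  h <- RNifti::niftiHeader(img)
  as.numeric(c(h$qoffset_x, h$qoffset_y, h$qoffset_z))
}

#' Read an aligned image/mask lesion pair from NIfTI files
#'
#' Reads a CT volume and its binary segmentation, enforces grid alignment
#' (identical shape, spacings within 1e-4 mm) and binarizes the mask at > 0.
#'
#' @param image_path,mask_path paths to NIfTI-1 files (`.nii` / `.nii.gz`).
#' @return A list with elements `image` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
read_lesion <- function(image_path, mask_path) {
  if (!file.exists(image_path)) stopf("image file not found: %s", image_path)
  if (!file.exists(mask_path)) stopf("mask file not found: %s", mask_path)
  iimg <- RNifti::readNifti(image_path)
  imsk <- RNifti::readNifti(mask_path)
  img <- image_volume(array(as.numeric(iimg), dim = dim(iimg)),
                      spacing = nifti_spacing(iimg), origin = nifti_origin(iimg))
  if (sum(imsk > 0) < 1) stopf("empty ROI: mask %s has no foreground", mask_path)
  msk <- roi_mask(array(as.numeric(imsk), dim = dim(imsk)),
                  spacing = nifti_spacing(imsk), origin = nifti_origin(imsk))
  check_alignment(img, msk)
  list(image = img, mask = msk)
}

#' Write an image volume or ROI mask to a NIfTI file
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply the five-lesion cap to a patient's lesions
#'
#' At most five lesions per patient enter the analysis, the primary lung
#' lesion always among them. Non-primary lesions are ranked by longest
#' diameter (descending), ties broken by lesion id (lexicographic), so the
#' selection is deterministic.
#'
#' @param lesions list of [lesion_record()]s sharing one `patient_id`.
#' @param max_lesions cap on the number of retained lesions (default 5).
#' @return A list of at most `max_lesions` lesion records; the primary first,
#'   then the largest non-primary lesions.
#' @export
select_lesions <- function(lesions, max_lesions = 5L) {
  if (length(lesions) == 0) stopf("no lesions supplied")
  pid <- unique(vapply(lesions, function(l) l$patient_id, character(1)))
  if (length(pid) != 1)
    stopf("lesions belong to %d different patients", length(pid))
  types <- vapply(lesions, function(l) l$lesion_type, character(1))
  prim <- which(types == "primary")
  if (length(prim) == 0) stopf("missing primary lesion for patient %s", pid)
  if (length(prim) > 1) stopf("patient %s has %d primary lesions", pid, length(prim))
  others <- setdiff(seq_along(lesions), prim)
  if (length(others) > 0) {
    sizes <- vapply(lesions[others], function(l) l$size_mm, numeric(1))
    ids <- vapply(lesions[others], function(l) l$lesion_id, character(1))
    others <- others[order(-sizes, ids)]
  }
  keep <- c(prim, utils::head(others, max_lesions - 1L))
  lesions[keep]
}

#' Write a feature table to CSV
#'
#' One row per lesion (or patient); identifier columns first, then the 60
#' features in canonical panel order. Values round-trip losslessly to at
#' least 12 significant digits.
#'
#' @param vectors list of [feature_vector()]s sharing one key set.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(vectors, path) {
  if (length(vectors) == 0) stopf("no feature vectors supplied")
  ref <- names(vectors[[1]]$values)
  for (v in vectors) {
    if (!identical(names(v$values), ref))
      stopf("schema error: feature vectors do not share one key set")
  }
  df <- data.frame(
    patient_id = vapply(vectors, function(v) v$patient_id %||% NA_character_, character(1)),
    lesion_id = vapply(vectors, function(v) v$lesion_id %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  vals <- do.call(rbind, lapply(vectors, function(v) v$values))
  colnames(vals) <- ref
  df <- cbind(df, as.data.frame(vals))
  utils::write.csv(format(df, digits = 15, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A data.frame with `patient_id`, `lesion_id` and numeric feature
#'   columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in setdiff(names(df), c("patient_id", "lesion_id")))
    df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Validate a clinical cohort table
#'
#' Checks the per-patient covariate table: binary TS label, non-negative
#' survival times, binary event flags.
#'
#' @param clinical data.frame with columns `patient_id`, `age`, `sex`,
#'   `smoking`, `ts_label`, `os_time`, `os_event`, `pfs_time`, `pfs_event`
#'   (optional: `egfr`, `suvmax`, `opacity`).
#' @return The validated data.frame, invisibly classed `cohort_table`.
#' @export
validate_cohort <- function(clinical) {
  need <- c("patient_id", "age", "sex", "smoking", "ts_label",
            "os_time", "os_event", "pfs_time", "pfs_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stopf("cohort table missing columns: %s", paste(miss, collapse = ", "))
  if (!all(clinical$ts_label %in% c(0, 1))) stopf("ts_label must be 0/1")
  if (any(clinical$os_time < 0) || any(clinical$pfs_time < 0))
    stopf("survival times must be >= 0")
  if (!all(clinical$os_event %in% c(0, 1)) || !all(clinical$pfs_event %in% c(0, 1)))
    stopf("event flags must be 0/1")
  class(clinical) <- unique(c("cohort_table", class(clinical)))
  invisible(clinical)
}
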