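# Imaging layer: containers for volumes and masks, NIfTI I/O, intensity
# normalization, gray-level discretization, and slice-wise Haar sub-bands.

#' Construct an image volume
#'
#' A 3D real-valued image with voxel spacing in millimetres. The axial plane
#' is spanned by the first two axes; the third axis indexes slices.
#'
#' @param voxels 3D numeric array of intensities (finite values).
#' @param spacing numeric length-3, mm per axis (positive).
#' @param sequence optional sequence name (e.g. `"sag_T2"`).
#' @return An object of class `image_volume` with fields `voxels`,
#'   `spacing`, `sequence`.
#' @export
image_volume <- function(voxels, spacing, sequence = NA_character_) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("voxels must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 sequence = as.character(sequence)),
            class = "image_volume")
}

#' Construct a habitat mask
#'
#' A binary 3D region of interest delineating one tumor habitat.
#'
#' @param voxels 3D logical (or 0/1) array.
#' @param spacing numeric length-3, mm per axis.
#' @return An object of class `habitat_mask` with fields `voxels` (logical
#'   array) and `spacing`.
#' @export
habitat_mask <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask must not contain NA")
  if (!any(voxels)) stop("mask is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing), class = "habitat_mask")
}

#' Z-score normalize an image volume
#'
#' Rescales intensities so the whole volume has mean 0 and standard
#' deviation 1 (population SD). Normalization statistics are computed over
#' the full volume, not the ROI, so tumor-to-background contrast is
#' preserved. The operation is idempotent and invariant to affine intensity
#' transforms of the input.
#'
#' @param volume an [image_volume].
#' @return A normalized [image_volume].
#' @export
znorm_volume <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0)
    stop("cannot z-normalize a constant volume")
  image_volume((v - m) / s, volume$spacing, volume$sequence)
}

#' Discretize ROI intensities into gray levels
#'
#' Equal-width binning of in-mask intensities over their observed range:
#' `level = floor(n_bins * (x - min) / (max - min)) + 1`, capped at
#' `n_bins`. Voxels outside the mask carry `NA`. A constant ROI maps every
#' voxel to level 1 and is flagged.
#'
#' @param volume an [image_volume].
#' @param mask a [habitat_mask] with the same array shape.
#' @param n_bins number of gray levels (>= 2).
#' @return An object of class `discretized_roi`: fields `gray_levels`
#'   (integer array, `NA` outside the mask), `n_bins`, `mask`, and
#'   `constant` (logical flag).
#' @export
discretize_roi <- function(volume, mask, n_bins = 32L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "habitat_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("volume and mask shapes differ")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  x <- volume$voxels[mask$voxels]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim = dim(volume$voxels))
  if (hi == lo) {
    lev[mask$voxels] <- 1L
    constant <- TRUE
  } else {
    lev[mask$voxels] <- pmin(
      as.integer(floor(n_bins * (x - lo) / (hi - lo))) + 1L, n_bins)
    constant <- FALSE
  }
  structure(list(gray_levels = lev, n_bins = n_bins, mask = mask,
                 constant = constant),
            class = "discretized_roi")
}

# Circular shift of a 3D array by +1 along one axis (periodic boundary).
shift_axis <- function(a, axis) {
  n <- dim(a)[axis]
  idx <- c(seq_len(n)[-1L], 1L)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Slice-wise undecimated Haar wavelet sub-bands
#'
#' Computes the four single-level 2D Haar sub-bands of every axial slice
#' using the undecimated (stationary) transform with periodic boundary, so
#' each sub-band has the same shape as the input and stays voxel-aligned
#' with the habitat mask. Filters are the orthonormal Haar pair
#' `(1, 1)/sqrt(2)` and `(1, -1)/sqrt(2)`; sub-band `AB` applies filter `A`
#' along the first in-plane axis and `B` along the second. `XLL` is a
#' smoothed version of the input; the detail bands of a constant slice are
#' identically zero.
#'
#' @param volume an [image_volume] with in-plane dimensions >= 2.
#' @return A named list of four [image_volume]s: `XLL`, `XLH`, `XHL`, `XHH`.
#' @export
wavelet_subbands <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$voxels)
  if (d[1] < 2L || d[2] < 2L)
    stop("in-plane dimensions must be >= 2")
  s <- 1 / sqrt(2)
  v <- volume$voxels
  v1 <- shift_axis(v, 1L)
  L <- (v + v1) * s
  H <- (v - v1) * s
  out <- list(XLL = (L + shift_axis(L, 2L)) * s,
              XLH = (L - shift_axis(L, 2L)) * s,
              XHL = (H + shift_axis(H, 2L)) * s,
              XHH = (H - shift_axis(H, 2L)) * s)
  lapply(out, image_volume, spacing = volume$spacing,
         sequence = volume$sequence)
}

# ---- NIfTI I/O ------------------------------------------------------------

write_nifti_volume <- function(voxels, spacing, path) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(voxels = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Load one study from a cohort manifest
#'
#' Reads the NIfTI volumes and masks of all sequences of one patient, plus
#' the clinical covariates and response label, from a directory written by
#' [write_cohort()].
#'
#' @param manifest path to the manifest JSON, or the parsed manifest list.
#' @param patient_id the patient to load.
#' @return A `habitat_study` object (fields `patient_id`, `label`,
#'   `volumes`, `masks`, `clinical`).
#' @export
load_study <- function(manifest, patient_id) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  } else {
    dir <- manifest$directory %||% "."
  }
  entry <- NULL
  for (p in manifest$patients)
    if (identical(p$patient_id, patient_id)) entry <- p
  if (is.null(entry))
    stop("patient '", patient_id, "' not found in manifest")
  clin <- read.csv(file.path(dir, manifest$clinical_file),
                   stringsAsFactors = FALSE)
  row <- clin[clin$patient_id == patient_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("clinical table has ", nrow(row), " rows for patient '",
         patient_id, "'")
  volumes <- list(); masks <- list()
  for (sq in names(entry$sequences)) {
    files <- entry$sequences[[sq]]
    vpath <- file.path(dir, files$volume)
    mpath <- file.path(dir, files$mask)
    if (!file.exists(vpath))
      stop("missing volume file for patient '", patient_id,
           "', sequence '", sq, "'")
    if (!file.exists(mpath))
      stop("missing mask file for patient '", patient_id,
           "', sequence '", sq, "'")
    v <- read_nifti_volume(vpath)
    m <- read_nifti_volume(mpath)
    if (!identical(dim(v$voxels), dim(m$voxels)))
      stop("volume/mask shape mismatch for patient '", patient_id,
           "', sequence '", sq, "'")
    volumes[[sq]] <- image_volume(v$voxels, v$spacing, sq)
    masks[[sq]] <- habitat_mask(m$voxels > 0.5, m$spacing)
  }
  covnames <- setdiff(names(row), c("patient_id", "label"))
  structure(list(patient_id = patient_id,
                 label = as.integer(row$label),
                 volumes = volumes, masks = masks,
                 clinical = as.list(row[covnames])),
            class = "habitat_study")
}
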