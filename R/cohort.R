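# Synthetic cohort generator: NIfTI-backed studies with the statistical
# structure the analysis assumes -- nine co-registered pseudo-sequences per
# patient, single-habitat ellipsoidal 3D masks, binary responder labels with
# planted texture differences in a configurable subset of habitats, a
# second-radiologist mask perturbation, and clinical covariates with no
# group effect.

#' Default sequence names of the nine-habitat protocol
#' @export
HABITAT_SEQUENCES <- c("sag_T2", "ax_T1", "ax_T2FS", "dwi_b0", "dwi_b800",
                       "adc", "sag_T1c", "ax_T1c", "cor_T1c")

#' Synthetic cohort configuration
#'
#' Defines the study conditions of a simulated multi-sequence MRI cohort.
#' Responder status shifts the latent texture parameters (in-plane
#' correlation length and texture amplitude of the intratumoral signal) of
#' the habitats listed in `effect_habitats` by `effect_size` standardized
#' units; all other habitats, the tumor geometry, and the clinical
#' covariates carry no group effect. Covariate distributions follow typical
#' cervical-cancer cohort summaries (age ~ 52 +/- 9 years, 0-6 pregnancies,
#' rare positive family history).
#'
#' @param n_patients number of patients.
#' @param prevalence_responder responder fraction in (0, 1).
#' @param sequences character vector of exactly 9 distinct sequence names.
#' @param volume_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per axis (slice thickness is
#'   the third entry; default 4 mm).
#' @param effect_habitats subset of `sequences` carrying the planted effect.
#' @param effect_size standardized mean shift of the texture-controlling
#'   parameters between responders and non-responders (>= 0).
#' @param noise_sd additive Gaussian noise SD.
#' @param min_mask_slices minimum number of axial slices every mask spans.
#' @param tumor_contrast mean tumor-over-background intensity offset.
#' @param texture_sigma0,texture_sigma_sd population mean and SD of the
#'   in-plane correlation length (voxels) of the intratumoral texture.
#' @param texture_amp0,texture_amp_sd population mean and SD of the texture
#'   amplitude.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 120L,
                          prevalence_responder = 71 / 120,
                          sequences = HABITAT_SEQUENCES,
                          volume_shape = c(64L, 64L, 32L),
                          voxel_spacing = c(0.7, 0.7, 4.0),
                          effect_habitats = c("sag_T2", "ax_T1c", "adc"),
                          effect_size = 1.5,
                          noise_sd = 0.3,
                          min_mask_slices = 4L,
                          tumor_contrast = 2.0,
                          texture_sigma0 = 1.0,
                          texture_sigma_sd = 0.3,
                          texture_amp0 = 1.0,
                          texture_amp_sd = 0.25,
                          seed = 1L) {
  if (length(sequences) != 9L || anyDuplicated(sequences))
    stop("sequences must be 9 distinct names")
  if (!all(effect_habitats %in% sequences))
    stop("effect_habitats must be a subset of sequences")
  if (prevalence_responder <= 0 || prevalence_responder >= 1)
    stop("prevalence_responder must lie in (0, 1)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    stop("volume_shape must be 3 dimensions of at least 8 voxels")
  if (volume_shape[3] < min_mask_slices + 2L)
    stop("volume too shallow to fit a mask spanning ", min_mask_slices,
         " slices")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_responder = prevalence_responder,
                 sequences = sequences,
                 volume_shape = volume_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 effect_habitats = effect_habitats,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 min_mask_slices = as.integer(min_mask_slices),
                 tumor_contrast = tumor_contrast,
                 texture_sigma0 = texture_sigma0,
                 texture_sigma_sd = texture_sigma_sd,
                 texture_amp0 = texture_amp0,
                 texture_amp_sd = texture_amp_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Zero-filled shift of a 3D array along one axis by a signed offset.
shift_fill <- function(a, axis, off) {
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(off) >= n) return(out)
  src <- if (off > 0) seq_len(n - off) else seq(1 - off, n)
  dst <- if (off > 0) seq(1 + off, n) else seq_len(n + off)
  switch(axis,
         out[dst, , ] <- a[src, , ],
         out[, dst, ] <- a[, src, ],
         out[, , dst] <- a[, , src])
  out
}

# Separable in-plane Gaussian smoothing (axes 1 and 2), zero-padded.
smooth_inplane <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:2) {
    acc <- array(0, dim(a))
    for (i in seq_along(k))
      acc <- acc + k[i] * shift_fill(a, axis, i - r - 1L)
    a <- acc
  }
  a
}

# Random ellipsoid mask spanning at least min_slices axial slices.
# Geometry is label-independent: tumor size and position carry no signal.
random_ellipsoid_mask <- function(shape, min_slices) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  for (try in 1:50) {
    rx <- runif(1, 0.14, 0.22) * nx
    ry <- runif(1, 0.14, 0.22) * ny
    rz <- runif(1, min_slices / 2 + 0.6,
                min(nz / 2 - 1, min_slices / 2 + 2.5))
    cx <- nx / 2 + runif(1, -0.08, 0.08) * nx
    cy <- ny / 2 + runif(1, -0.08, 0.08) * ny
    cz <- nz / 2 + runif(1, -0.1, 0.1) * nz
    if (cx - rx < 2 || cx + rx > nx - 1 || cy - ry < 2 ||
        cy + ry > ny - 1 || cz - rz < 2 || cz + rz > nz - 1) next
    xs <- (seq_len(nx) - cx) / rx
    ys <- (seq_len(ny) - cy) / ry
    zs <- (seq_len(nz) - cz) / rz
    m <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`) < 1
    if (!any(m)) next
    span <- sum(apply(m, 3, any))
    if (span >= min_slices) return(m)
  }
  stop("could not fit a mask spanning ", min_slices,
       " slices in a volume of shape ", paste(shape, collapse = "x"))
}

# One synthetic sequence: noisy background plus a textured tumor blob whose
# texture correlation length and amplitude are patient- (and, in effect
# habitats, group-) specific. Altering the correlation length changes GLCM
# contrast/variance and GLRLM run statistics; altering the amplitude changes
# the texture-to-noise ratio.
simulate_sequence <- function(config, mask, label, effect) {
  shape <- config$volume_shape
  z <- rnorm(2)
  sigma <- max(0.4, config$texture_sigma0 +
                 config$texture_sigma_sd * (z[1] + effect * label))
  amp <- max(0.2, config$texture_amp0 +
               config$texture_amp_sd * (z[2] + effect * label))
  field <- smooth_inplane(array(rnorm(prod(shape)), shape), sigma)
  field <- field / max(sd(field), 1e-12)
  vox <- array(0, shape)
  vox[mask] <- config$tumor_contrast + amp * field[mask]
  vox + rnorm(prod(shape), sd = config$noise_sd)
}

simulate_clinical <- function() {
  list(age = round(rnorm(1, 52, 9), 1),
       pregnancy_num = max(0L, as.integer(round(rnorm(1, 3, 1.6)))),
       parturition_num = max(0L, as.integer(round(rnorm(1, 1.4, 0.8)))),
       abortion_num = max(0L, as.integer(round(rnorm(1, 1.7, 1.5)))),
       first_intercourse_age = round(rnorm(1, 23, 3), 1),
       family_history = rbinom(1, 1, 0.06))
}

#' Generate a synthetic multi-habitat cohort
#'
#' Draws `n_patients` studies. Each study has one binary responder label,
#' nine image volumes with matching single-component ellipsoidal masks, and
#' six clinical covariates with no group effect. In the habitats listed in
#' `config$effect_habitats`, the latent texture parameters differ between
#' responders and non-responders by `config$effect_size` standardized units;
#' with `effect_size = 0` the cohort carries no signal at all. The cohort is
#' bit-for-bit reproducible from the config (including its seed).
#'
#' @param config a [cohort_config].
#' @return A list of `habitat_study` objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) {
      label <- rbinom(1, 1, config$prevalence_responder)
      clinical <- simulate_clinical()
      base_mask <- random_ellipsoid_mask(config$volume_shape,
                                         config$min_mask_slices)
      volumes <- list(); masks <- list()
      for (sq in config$sequences) {
        effect <- if (sq %in% config$effect_habitats)
          config$effect_size else 0
        vox <- simulate_sequence(config, base_mask, label, effect)
        volumes[[sq]] <- image_volume(vox, config$voxel_spacing, sq)
        masks[[sq]] <- habitat_mask(base_mask, config$voxel_spacing)
      }
      structure(list(patient_id = sprintf("P%03d", i),
                     label = label,
                     volumes = volumes, masks = masks,
                     clinical = clinical),
                class = "habitat_study")
    })
  })
}

#' Extract the clinical covariate table of a cohort
#'
#' @param cohort list of `habitat_study` objects.
#' @return data.frame with `patient_id`, `label`, and the six covariates.
#' @export
cohort_clinical <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id, label = s$label,
               as.data.frame(s$clinical), stringsAsFactors = FALSE)))
}

# Count of 6-connected neighbors inside the mask, per voxel.
neighbor6_count <- function(m) {
  mm <- array(as.numeric(m), dim(m))
  shift_fill(mm, 1, 1) + shift_fill(mm, 1, -1) +
    shift_fill(mm, 2, 1) + shift_fill(mm, 2, -1) +
    shift_fill(mm, 3, 1) + shift_fill(mm, 3, -1)
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

#' Perturb a habitat mask (simulated re-segmentation)
#'
#' Emulates a second radiologist's delineation of the same habitat: a random
#' fraction of boundary voxels is added (dilation candidates) and removed
#' (erosion candidates), then the largest connected component is kept. The
#' result is guaranteed non-empty, single-component, and within a Dice
#' overlap floor of the input; otherwise the perturbation is retried and
#' finally fails.
#'
#' @param mask a [habitat_mask].
#' @param seed integer seed; fixed seed gives an identical perturbed mask.
#' @param fraction fraction of boundary voxels flipped (0 = identity).
#' @param dice_floor minimum Dice overlap with the input (default 0.8).
#' @param max_tries retries before failing.
#' @return A perturbed [habitat_mask].
#' @export
perturb_mask <- function(mask, seed, fraction = 0.2, dice_floor = 0.8,
                         max_tries = 10L) {
  stopifnot(inherits(mask, "habitat_mask"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction == 0) return(mask)
  m0 <- mask$voxels
  for (try in seq_len(max_tries)) {
    out <- with_seed(child_seed(seed, "perturb", try - 1L), {
      nb <- neighbor6_count(m0)
      dilat <- which(!m0 & nb > 0)        # background touching the mask
      erod <- which(m0 & nb < 6)          # mask voxels touching background
      m <- m0
      if (length(dilat))
        m[sample(dilat, round(fraction * length(dilat)))] <- TRUE
      if (length(erod))
        m[sample(erod, round(fraction * length(erod)))] <- FALSE
      m
    })
    if (!any(out)) next
    lab <- cpp_label_components(out, dim(out))
    keep <- which.max(tabulate(lab[lab > 0]))
    out <- array(lab == keep, dim(out))
    if (!any(out)) next
    if (dice_overlap(m0, out) >= dice_floor)
      return(habitat_mask(out, mask$spacing))
  }
  stop("mask perturbation failed to satisfy the Dice floor of ", dice_floor,
       " after ", max_tries, " tries")
}

#' Write a cohort to disk as NIfTI + CSV + manifest
#'
#' One `.nii.gz` per volume and per mask, one CSV of clinical covariates and
#' labels, and one JSON manifest linking each patient to its files. The
#' written cohort round-trips losslessly through [load_study()].
#'
#' @param cohort list of `habitat_study` objects.
#' @param directory output directory (created if absent).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory '", directory, "'")
  entries <- lapply(cohort, function(s) {
    seqs <- list()
    for (sq in names(s$volumes)) {
      vfile <- sprintf("%s_%s_vol.nii.gz", s$patient_id, sq)
      mfile <- sprintf("%s_%s_mask.nii.gz", s$patient_id, sq)
      write_nifti_volume(s$volumes[[sq]]$voxels, s$volumes[[sq]]$spacing,
                         file.path(directory, vfile))
      write_nifti_volume(array(as.numeric(s$masks[[sq]]$voxels),
                               dim(s$masks[[sq]]$voxels)),
                         s$masks[[sq]]$spacing,
                         file.path(directory, mfile))
      seqs[[sq]] <- list(volume = vfile, mask = mfile)
    }
    list(patient_id = s$patient_id, label = s$label, sequences = seqs)
  })
  clin <- cohort_clinical(cohort)
  write.csv(clin, file.path(directory, "clinical.csv"), row.names = FALSE)
  manifest <- list(n_patients = length(cohort),
                   sequences = names(cohort[[1]]$volumes),
                   clinical_file = "clinical.csv",
                   patients = entries)
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
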