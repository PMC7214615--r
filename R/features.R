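# Radiomic feature extraction: 114 3D descriptors per habitat.
# 14 shape features from the mask, plus 7 histogram + 7 GLCM + 6 GLRLM
# features on each of 5 images (original X and Haar sub-bands XLL, XLH,
# XHL, XHH): 14 + 5 * 20 = 114.

# The 13 unique 3D direction offsets at distance 1 (one per opposite pair
# of the 26-neighborhood).
DIRECTIONS_13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
storage.mode(DIRECTIONS_13) <- "integer"

SHAPE_FEATURES <- c("Voxel_count", "Volume", "Surface_area",
                    "Surface_to_volume_ratio", "Sphericity", "Compactness1",
                    "Compactness2", "Spherical_disproportion",
                    "Max_3D_diameter", "Major_axis", "Minor_axis",
                    "Least_axis", "Elongation", "Flatness")
HIST_FEATURES <- c("H_mean", "H_variance", "H_skewness", "H_kurtosis",
                   "H_entropy", "H_energy", "H_range")
GLCM_FEATURES <- c("GLCM_energy", "GLCM_contrast", "GLCM_correlation",
                   "GLCM_variance", "GLCM_dissimilarity",
                   "GLCM_homogeneity1", "GLCM_homogeneity2")
GLRLM_FEATURES <- c("GLRLM_SRE", "GLRLM_LRE", "GLRLM_RP", "GLRLM_RLN",
                    "GLRLM_SRLGLE", "GLRLM_LRHGLE")

#' Canonical names of the 114 per-habitat descriptors
#'
#' Shape names are bare; histogram/GLCM/GLRLM names are prefixed by the
#' image they are computed on (`X` = original, `XLL`/`XLH`/`XHL`/`XHH` =
#' Haar sub-bands), e.g. `X_GLRLM_LRHGLE`, `XLL_H_skewness`.
#'
#' @return Character vector of length 114.
#' @export
feature_names <- function() {
  imgs <- c("X", "XLL", "XLH", "XHL", "XHH")
  c(SHAPE_FEATURES,
    unlist(lapply(imgs, function(p)
      paste(p, c(HIST_FEATURES, GLCM_FEATURES, GLRLM_FEATURES),
            sep = "_"))))
}

#' Feature extraction configuration
#'
#' @param n_bins gray levels for discretization (default 32, equal-width
#'   over the in-mask intensity range, recomputed per image).
#' @param directions integer matrix of 3D offsets (default: the 13 unique
#'   distance-1 directions).
#' @return A `feature_config` list.
#' @export
feature_config <- function(n_bins = 32L, directions = DIRECTIONS_13) {
  structure(list(n_bins = as.integer(n_bins),
                 directions = directions),
            class = "feature_config")
}

#' Shape features of a habitat mask
#'
#' Fourteen intensity-independent descriptors of the 3D region: voxel
#' count, physical volume, surface area from exposed voxel faces,
#' surface-to-volume ratio, sphericity and related compactness measures,
#' maximum 3D diameter (largest pairwise distance between surface voxel
#' centers), and principal-axis lengths (4 x sqrt of the eigenvalues of the
#' spacing-weighted coordinate covariance) with elongation and flatness
#' ratios.
#'
#' @param mask a [habitat_mask].
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "habitat_mask"))
  m <- mask$voxels
  sp <- mask$spacing
  nv <- sum(m)
  vol <- nv * prod(sp)
  # exposed faces per axis: a face is exposed when the neighbor across it
  # is background or out of bounds
  area <- 0
  for (axis in 1:3) {
    nplus <- sum(m & !shift_fill(array(as.numeric(m), dim(m)), axis, -1))
    nminus <- sum(m & !shift_fill(array(as.numeric(m), dim(m)), axis, 1))
    area <- area + (nplus + nminus) * prod(sp[-axis])
  }
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  # surface voxels only: the diameter is attained on the boundary
  boundary <- m & (neighbor6_count(m) < 6)
  bidx <- which(boundary, arr.ind = TRUE)
  bcoord <- sweep(bidx, 2, sp, `*`)
  maxdiam <- if (nrow(bcoord) > 1)
    cpp_max_pairwise_dist(bcoord) else 0
  idx <- which(m, arr.ind = TRUE)
  coord <- sweep(idx, 2, sp, `*`)
  if (nrow(coord) > 1) {
    ev <- sort(eigen(stats::cov(coord), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  c(Voxel_count = nv,
    Volume = vol,
    Surface_area = area,
    Surface_to_volume_ratio = area / vol,
    Sphericity = sphericity,
    Compactness1 = vol / (sqrt(pi) * area^(3 / 2)),
    Compactness2 = 36 * pi * vol^2 / area^3,
    Spherical_disproportion = area / (4 * pi * r_eq^2),
    Max_3D_diameter = maxdiam,
    Major_axis = axes[1],
    Minor_axis = axes[2],
    Least_axis = axes[3],
    Elongation = elong,
    Flatness = flat)
}

#' Histogram features of an ROI
#'
#' First-order statistics of the in-mask intensities: population moments
#' (mean, variance, skewness, kurtosis), range, and entropy/energy of the
#' discretized gray-level histogram (log base 2 entropy). A constant ROI
#' has variance 0, skewness and kurtosis defined as 0, entropy 0, energy 1.
#'
#' @param volume an [image_volume].
#' @param mask a [habitat_mask].
#' @param droi optional precomputed [discretize_roi()] result (same
#'   `n_bins` as used for the texture matrices).
#' @param n_bins gray levels if `droi` is not supplied.
#' @return Named numeric vector of length 7 (unprefixed `H_*` names).
#' @export
histogram_features <- function(volume, mask, droi = NULL, n_bins = 32L) {
  x <- volume$voxels[mask$voxels]
  if (length(x) == 0) stop("empty ROI")
  if (is.null(droi)) droi <- discretize_roi(volume, mask, n_bins)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 0) {
    sk <- mean((x - m)^3) / v^1.5
    ku <- mean((x - m)^4) / v^2
  } else {
    sk <- 0; ku <- 0
  }
  lev <- droi$gray_levels[mask$voxels]
  p <- tabulate(lev, nbins = droi$n_bins) / length(lev)
  p <- p[p > 0]
  c(H_mean = m, H_variance = v, H_skewness = sk, H_kurtosis = ku,
    H_entropy = -sum(p * log2(p)), H_energy = sum(p^2),
    H_range = max(x) - min(x))
}

#' GLCM features of a discretized ROI
#'
#' Builds the symmetric normalized gray-level co-occurrence matrix at
#' distance 1 for each 3D direction, restricted to voxel pairs with both
#' ends inside the mask, computes seven standard descriptors per direction,
#' and returns their unweighted mean over directions. Directions
#' contributing no in-mask pair are dropped from the average. On a constant
#' ROI energy and the homogeneities are 1, contrast/dissimilarity/variance
#' are 0, and correlation is defined as 1.
#'
#' @param droi a [discretize_roi()] result.
#' @param directions integer matrix of offsets (default the 13 unique
#'   distance-1 directions).
#' @return Named numeric vector of length 7.
#' @export
glcm_features <- function(droi, directions = DIRECTIONS_13) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- droi$gray_levels
  lev[is.na(lev)] <- 0L
  n <- droi$n_bins
  counts <- cpp_glcm_counts(lev, droi$mask$voxels, dim(lev),
                            n, directions)
  M <- matrix(as.numeric(counts), n * n, dim(counts)[3])
  tot <- colSums(M)
  M <- M[, tot > 0, drop = FALSE]
  if (ncol(M) == 0L)
    stop("no in-mask voxel pairs in any direction")
  P <- M / rep(tot[tot > 0], each = n * n)
  W <- glcm_weights(n)  # one GEMM for all moment sums, all directions
  S <- crossprod(W, P)
  mu <- S["i", ]
  sig2 <- S["i2", ] - mu^2
  corr <- ifelse(sig2 > 0, (S["ij", ] - mu^2) / sig2, 1)
  f <- cbind(GLCM_energy = colSums(P^2),
             GLCM_contrast = S["d2", ],
             GLCM_correlation = corr,
             GLCM_variance = sig2,
             GLCM_dissimilarity = S["ad", ],
             GLCM_homogeneity1 = S["h1", ],
             GLCM_homogeneity2 = S["h2", ])
  colMeans(f)
}

# Per-cell weight matrices, cached per gray-level count / run length.
.weight_cache <- new.env(parent = emptyenv())

glcm_weights <- function(n) {
  key <- paste0("glcm", n)
  w <- .weight_cache[[key]]
  if (is.null(w)) {
    iv <- rep(seq_len(n), n)          # row (i) index per cell
    jv <- rep(seq_len(n), each = n)   # column (j) index per cell
    dd <- iv - jv
    w <- cbind(i = iv, i2 = iv^2, ij = iv * jv, d2 = dd^2, ad = abs(dd),
               h1 = 1 / (1 + abs(dd)), h2 = 1 / (1 + dd^2))
    .weight_cache[[key]] <- w
  }
  w
}

glrlm_weights <- function(nb, maxlen) {
  key <- paste0("glrlm", nb, "x", maxlen)
  w <- .weight_cache[[key]]
  if (is.null(w)) {
    iv <- rep(seq_len(nb), maxlen)
    jv <- rep(seq_len(maxlen), each = nb)
    w <- cbind(sre = 1 / jv^2, lre = jv^2, srlgle = 1 / (iv^2 * jv^2),
               lrhgle = iv^2 * jv^2)
    .weight_cache[[key]] <- w
  }
  w
}

#' GLRLM features of a discretized ROI
#'
#' Builds the gray-level run-length matrix per direction (a run is a
#' maximal streak of consecutive in-mask voxels with equal level; leaving
#' the mask terminates the run), computes six standard descriptors, and
#' averages them over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 6.
#' @export
glrlm_features <- function(droi, directions = DIRECTIONS_13) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- droi$gray_levels
  lev[is.na(lev)] <- 0L
  nvox <- sum(droi$mask$voxels)
  maxlen <- max(dim(lev))
  counts <- cpp_glrlm_counts(lev, droi$mask$voxels, dim(lev),
                             droi$n_bins, maxlen, directions)
  nb <- droi$n_bins
  M <- matrix(as.numeric(counts), nb * maxlen, dim(counts)[3])
  nr <- colSums(M)
  S <- crossprod(glrlm_weights(nb, maxlen), M)
  # run counts summed over gray level, per run length
  per_len <- rowsum(M, rep(seq_len(maxlen), each = nb))
  f <- cbind(GLRLM_SRE = S["sre", ] / nr,
             GLRLM_LRE = S["lre", ] / nr,
             GLRLM_RP = nr / nvox,
             GLRLM_RLN = colSums(per_len^2) / nr,
             GLRLM_SRLGLE = S["srlgle", ] / nr,
             GLRLM_LRHGLE = S["lrhgle", ] / nr)
  colMeans(f)
}

# Crop a (volume, mask) pair to the mask bounding box plus a margin,
# clamped to the volume. Shape features are translation-invariant and the
# intensity features only read in-mask voxels, so cropping is lossless.
crop_to_mask <- function(volume, mask, margin = 2L) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  d <- dim(mask$voxels)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  v <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(volume = structure(list(voxels = v, spacing = volume$spacing,
                               sequence = volume$sequence),
                          class = "image_volume"),
       mask = structure(list(voxels = m, spacing = mask$spacing),
                        class = "habitat_mask"))
}

#' Extract the 114-descriptor feature vector of one habitat
#'
#' Z-normalizes the volume, computes the four Haar sub-band images, and
#' assembles 14 shape features plus, for each of the 5 images (original and
#' sub-bands), 7 histogram, 7 GLCM, and 6 GLRLM features, each discretized
#' independently to `config$n_bins` equal-width gray levels over the
#' in-mask range.
#'
#' @param volume an [image_volume].
#' @param mask the matching [habitat_mask].
#' @param config a [feature_config].
#' @return Named numeric vector of length 114 with attribute `habitat` set
#'   to the volume's sequence name. Errors on any non-finite feature value,
#'   naming the feature.
#' @export
extract_habitat_vector <- function(volume, mask, config = feature_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "habitat_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("volume and mask shapes differ for sequence '",
         volume$sequence, "'")
  norm <- znorm_volume(volume)
  # crop to the mask bounding box with a 2-voxel margin after whole-volume
  # normalization: every feature reads in-mask voxels only and the Haar
  # filters reach 1 voxel, so the margin supplies the true neighborhood;
  # sub-bands are defined on this cropped frame
  cr <- crop_to_mask(norm, mask, margin = 2L)
  norm <- cr$volume; mask <- cr$mask
  images <- c(list(X = norm), wavelet_subbands(norm))
  out <- shape_features(mask)
  for (nm in names(images)) {
    img <- images[[nm]]
    droi <- discretize_roi(img, mask, config$n_bins)
    block <- c(histogram_features(img, mask, droi),
               glcm_features(droi, config$directions),
               glrlm_features(droi, config$directions))
    names(block) <- paste(nm, names(block), sep = "_")
    out <- c(out, block)
  }
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  attr(out, "habitat") <- volume$sequence
  out
}

#' Extract the patients-by-features table of one habitat
#'
#' @param cohort list of `habitat_study` objects.
#' @param sequence habitat (sequence) name to extract.
#' @param config a [feature_config].
#' @param masks optional named list (by patient id) of replacement
#'   [habitat_mask]s for this sequence (used for re-segmentation analyses).
#' @return data.frame with one row per patient (rownames = patient ids) and
#'   114 feature columns, in cohort order.
#' @export
extract_feature_table <- function(cohort, sequence,
                                  config = feature_config(),
                                  masks = NULL) {
  rows <- lapply(cohort, function(s) {
    if (is.null(s$volumes[[sequence]]))
      stop("patient '", s$patient_id, "' is missing sequence '",
           sequence, "'")
    msk <- if (!is.null(masks)) masks[[s$patient_id]]
           else s$masks[[sequence]]
    extract_habitat_vector(s$volumes[[sequence]], msk, config)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- vapply(cohort, `[[`, "", "patient_id")
  tab
}

#' Extract feature tables for all habitats of a cohort
#'
#' @inheritParams extract_feature_table
#' @param masks optional list of per-patient mask lists (e.g. perturbed
#'   re-segmentations), indexed `masks[[patient_id]][[sequence]]`.
#' @return Named list of per-habitat feature tables (9 x 114 = 1026
#'   features in total).
#' @export
extract_all_tables <- function(cohort, config = feature_config(),
                               masks = NULL) {
  seqs <- names(cohort[[1]]$volumes)
  setNames(lapply(seqs, function(sq) {
    sq_masks <- if (!is.null(masks))
      setNames(lapply(masks, `[[`, sq), names(masks)) else NULL
    extract_feature_table(cohort, sq, config, masks = sq_masks)
  }), seqs)
}
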