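# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive enumeration and must stay
# independent of the code paths they check.

# Build a single-sequence volume/mask pair from plain arrays.
make_vol <- function(a, spacing = c(1, 1, 1), sequence = "toy") {
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  image_volume(a, spacing, sequence)
}
make_msk <- function(a, spacing = c(1, 1, 1)) {
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  habitat_mask(a, spacing)
}

# Symmetric GLCM counts by explicit enumeration of all voxel pairs.
brute_glcm <- function(levels, mask, nbins, off) {
  d <- dim(levels)
  cm <- matrix(0, nbins, nbins)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
        z2 < 1 || z2 > d[3]) next
    if (!mask[x2, y2, z2]) next
    i <- levels[x, y, z]; j <- levels[x2, y2, z2]
    cm[i, j] <- cm[i, j] + 1
    cm[j, i] <- cm[j, i] + 1
  }
  cm
}

glcm_feats_from_matrix <- function(cm) {
  P <- cm / sum(cm)
  n <- nrow(P)
  I <- matrix(seq_len(n), n, n); J <- t(I)
  mu <- sum(P * I)
  sig2 <- sum(P * (I - mu)^2)
  corr <- if (sig2 > 0) (sum(P * I * J) - mu^2) / sig2 else 1
  c(GLCM_energy = sum(P^2), GLCM_contrast = sum(P * (I - J)^2),
    GLCM_correlation = corr, GLCM_variance = sig2,
    GLCM_dissimilarity = sum(P * abs(I - J)),
    GLCM_homogeneity1 = sum(P / (1 + abs(I - J))),
    GLCM_homogeneity2 = sum(P / (1 + (I - J)^2)))
}

# Direction-averaged GLCM features by brute force.
brute_glcm_features <- function(levels, mask, nbins,
                                dirs = habitomics:::DIRECTIONS_13) {
  fs <- NULL; used <- 0
  for (d in seq_len(nrow(dirs))) {
    cm <- brute_glcm(levels, mask, nbins, dirs[d, ])
    if (sum(cm) == 0) next
    f <- glcm_feats_from_matrix(cm)
    fs <- if (is.null(fs)) f else fs + f
    used <- used + 1
  }
  fs / used
}

# Run-length counts by whole-line extraction and rle: every maximal grid
# line along the offset is walked across the volume; out-of-mask voxels
# split the line and equal-level streaks are counted with rle.
brute_glrlm <- function(levels, mask, nbins, off, maxlen) {
  d <- dim(levels)
  rl <- matrix(0, nbins, maxlen)
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (inb(p - off)) next  # not the start of a grid line
    vals <- integer(0); ok <- logical(0)
    q <- p
    while (inb(q)) {
      vals <- c(vals, levels[q[1], q[2], q[3]])
      ok <- c(ok, mask[q[1], q[2], q[3]])
      q <- q + off
    }
    vals[!ok] <- NA
    r <- rle(vals)
    for (k in seq_along(r$lengths)) {
      v <- r$values[k]
      if (!is.na(v)) rl[v, r$lengths[k]] <- rl[v, r$lengths[k]] + 1
    }
  }
  rl
}

glrlm_feats_from_matrix <- function(rl, nvox) {
  nr <- sum(rl)
  ii <- matrix(seq_len(nrow(rl)), nrow(rl), ncol(rl))
  jj <- matrix(seq_len(ncol(rl)), nrow(rl), ncol(rl), byrow = TRUE)
  c(GLRLM_SRE = sum(rl / jj^2) / nr, GLRLM_LRE = sum(rl * jj^2) / nr,
    GLRLM_RP = nr / nvox, GLRLM_RLN = sum(colSums(rl)^2) / nr,
    GLRLM_SRLGLE = sum(rl / (ii^2 * jj^2)) / nr,
    GLRLM_LRHGLE = sum(rl * ii^2 * jj^2) / nr)
}

brute_glrlm_features <- function(levels, mask, nbins,
                                 dirs = habitomics:::DIRECTIONS_13) {
  maxlen <- max(dim(levels))
  nvox <- sum(mask)
  fs <- NULL
  for (d in seq_len(nrow(dirs))) {
    rl <- brute_glrlm(levels, mask, nbins, dirs[d, ], maxlen)
    f <- glrlm_feats_from_matrix(rl, nvox)
    fs <- if (is.null(fs)) f else fs + f
  }
  fs / nrow(dirs)
}

# Tie-corrected AUC by explicit pair counting.
brute_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Youden-optimal threshold by exhaustive scan (lowest threshold on ties).
brute_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  best_t <- NA; best_j <- -Inf
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-9) { best_j <- j; best_t <- t }
  }
  list(cutoff = best_t, youden = best_j)
}

# Logistic regression by Newton-Raphson iteration.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- t(X) %*% (X * W)
    g <- t(X) %*% (y - p)
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  list(coef = beta, se = se)
}

# ICC(2,1) through R's ANOVA machinery (independent of the closed form).
aov_icc <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(v ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Decimated orthonormal single-level 2D Haar transform (even dimensions).
haar_decimated_2d <- function(a) {
  n1 <- nrow(a); n2 <- ncol(a)
  o1 <- seq(1, n1, 2); o2 <- seq(1, n2, 2)
  A <- a[o1, o2, drop = FALSE]; B <- a[o1 + 1, o2, drop = FALSE]
  C <- a[o1, o2 + 1, drop = FALSE]; D <- a[o1 + 1, o2 + 1, drop = FALSE]
  list(LL = (A + B + C + D) / 2, LH = (A + B - C - D) / 2,
       HL = (A - B + C - D) / 2, HH = (A - B - C + D) / 2)
}

# Random small ROI fixture: levels in 1..nbins on a random mask.
random_small_roi <- function(nbins = 4, dmax = c(6, 6, 4)) {
  d <- c(sample(2:dmax[1], 1), sample(2:dmax[2], 1), sample(2:dmax[3], 1))
  mask <- array(runif(prod(d)) < 0.7, d)
  if (!any(mask)) mask[1] <- TRUE
  levels <- array(sample.int(nbins, prod(d), replace = TRUE), d)
  list(levels = levels, mask = mask, nbins = nbins, dims = d)
}

# Wrap raw levels/mask into the discretized-ROI container.
roi_as_droi <- function(levels, mask, nbins, spacing = c(1, 1, 1)) {
  lev <- levels
  lev[!mask] <- NA_integer_
  structure(list(gray_levels = lev, n_bins = as.integer(nbins),
                 mask = make_msk(mask, spacing), constant = FALSE),
            class = "discretized_roi")
}
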