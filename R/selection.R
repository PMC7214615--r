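# Three-step feature selection and per-habitat signature construction:
# (1) ICC stability filter against a re-segmentation, (2) pairwise Pearson
# redundancy pruning keeping the more stable member, (3) LASSO logistic
# regression yielding a sparse linear signature.

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC for
#' two raters, computed from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`.
#'
#' @param x,y paired measurements (same subjects, two raters), n >= 3.
#' @return ICC value in (-Inf, 1].
#' @export
icc_2_1 <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("ICC requires at least 3 subject pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  if (ssr + ssc + sse < .Machine$double.eps * max(1, abs(grand)))
    stop("degenerate ICC: zero total variance")
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' ICC stability filter against a re-segmentation
#'
#' Computes the per-feature ICC(2,1) between the feature values obtained
#' under the primary segmentation and under a second radiologist's
#' re-segmentation, over the patients present in both tables. Features with
#' ICC below the threshold are removed; features with (numerically) zero
#' total variance are flagged degenerate and removed.
#'
#' @param table_r1,table_r2 feature tables (rownames = patient ids, same
#'   columns); `table_r2` typically covers a re-segmented subset.
#' @param threshold retention threshold (default 0.8; features with ICC
#'   below it are removed).
#' @return A `stability_report` data.frame: `feature`, `icc`, `retained`,
#'   `degenerate`.
#' @export
stability_filter <- function(table_r1, table_r2, threshold = 0.8) {
  common <- intersect(rownames(table_r1), rownames(table_r2))
  if (length(common) < 3)
    stop("stability filter needs at least 3 overlapping patients, got ",
         length(common))
  stopifnot(identical(colnames(table_r1), colnames(table_r2)))
  feats <- colnames(table_r1)
  icc <- vapply(feats, function(f) {
    tryCatch(icc_2_1(table_r1[common, f], table_r2[common, f]),
             error = function(e) NA_real_)
  }, numeric(1))
  degenerate <- is.na(icc)
  structure(data.frame(feature = feats, icc = icc,
                       retained = !degenerate & icc >= threshold,
                       degenerate = degenerate,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("stability_report", "data.frame"),
            threshold = threshold)
}

#' Correlation redundancy filter
#'
#' Greedy elimination: features are visited in decreasing ICC order (ties
#' broken by name); a feature is kept only if its absolute Pearson
#' correlation with every already-kept feature is at most `r_threshold`, so
#' of any highly correlated pair the more stable member survives. The
#' output set always satisfies max pairwise |r| <= `r_threshold`.
#'
#' @param table feature table restricted to stability-retained features.
#' @param iccs named ICC values for the columns of `table`.
#' @param r_threshold absolute-correlation threshold (default 0.6).
#' @return Character vector of retained feature names.
#' @export
redundancy_filter <- function(table, iccs, r_threshold = 0.6) {
  feats <- colnames(table)
  stopifnot(all(feats %in% names(iccs)))
  ord <- feats[order(-iccs[feats], feats)]
  cm <- abs(cor(as.matrix(table)))
  cm[is.na(cm)] <- 1  # zero-variance columns treated as redundant
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0 || all(cm[f, kept] <= r_threshold))
      kept <- c(kept, f)
  }
  feats[feats %in% kept]
}

#' Fit a habitat signature by LASSO logistic regression
#'
#' Features are z-scored with training means/SDs (stored in the signature),
#' then an L1-penalized logistic regression is fitted; the penalty is
#' chosen by stratified cross-validated binomial deviance with the 1-SE
#' rule, which favors sparse signatures. The signature is the set of
#' features with non-zero coefficients together with the linear predictor.
#' If the LASSO shrinks every coefficient to zero the signature is empty
#' (flagged; its score is the intercept). With fewer than two candidate
#' features an unpenalized univariate logistic fit is used instead.
#'
#' @param table training feature table (rows = patients).
#' @param labels binary response labels (1 = responder), in row order.
#' @param cv_folds number of CV folds for the penalty path (default 10).
#' @param seed seed for the fold assignment.
#' @param habitat optional habitat name stored in the signature.
#' @return A `habitat_signature`: `habitat`, `features`, `coefficients`,
#'   `intercept`, `center`, `scale`, `lambda`, `training_auc`, `empty`.
#' @export
fit_habitat_signature <- function(table, labels, cv_folds = 10L,
                                  seed = 1L, habitat = NA_character_) {
  stopifnot(nrow(table) == length(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present to fit a signature")
  X <- as.matrix(table)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  ok <- scl > 0
  X <- X[, ok, drop = FALSE]
  ctr <- ctr[ok]; scl <- scl[ok]
  Xs <- scale(X, center = ctr, scale = scl)
  if (ncol(Xs) >= 2) {
    foldid <- stratified_folds(labels, cv_folds, seed)
    cvfit <- with_seed(child_seed(seed, "lasso"),
      glmnet::cv.glmnet(Xs, labels, family = "binomial", alpha = 1,
                        foldid = foldid, type.measure = "deviance",
                        standardize = FALSE))
    lambda <- cvfit$lambda.1se
    cf <- as.numeric(coef(cvfit, s = lambda))
  } else if (ncol(Xs) == 1) {
    fit <- glm(labels ~ Xs, family = binomial())
    cf <- as.numeric(coef(fit))
    lambda <- 0
  } else stop("no non-constant features to fit")
  intercept <- cf[1]
  beta <- cf[-1]
  nz <- which(beta != 0)
  sig <- structure(list(habitat = habitat,
                        features = colnames(Xs)[nz],
                        coefficients = beta[nz],
                        intercept = intercept,
                        center = ctr[nz], scale = scl[nz],
                        lambda = lambda,
                        empty = length(nz) == 0L),
                   class = "habitat_signature")
  sig$training_auc <- if (sig$empty) 0.5
  else auc_mw(signature_score(sig, table), labels)
  sig
}

#' Score patients with a habitat signature
#'
#' Linear predictor `intercept + sum(coef * (x - center) / scale)` of the
#' stored LASSO fit; an empty signature scores every patient at the
#' intercept.
#'
#' @param sig a `habitat_signature`.
#' @param x a named feature vector, or a feature table (rows = patients).
#' @return Numeric score(s).
#' @export
signature_score <- function(sig, x) {
  stopifnot(inherits(sig, "habitat_signature"))
  if (is.null(dim(x))) x <- as.data.frame(as.list(x), check.names = FALSE)
  missing <- setdiff(sig$features, colnames(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  if (sig$empty) return(rep(sig$intercept, nrow(x)))
  Xs <- scale(as.matrix(x[, sig$features, drop = FALSE]),
              center = sig$center, scale = sig$scale)
  as.numeric(sig$intercept + Xs %*% sig$coefficients)
}
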