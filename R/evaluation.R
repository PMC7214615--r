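# Evaluation battery: ROC/AUC with DeLong inference, Youden cutoff and
# accuracies, Hosmer-Lemeshow calibration, inter-radiologist consistency,
# repeated random-split validation, and the clinical univariate /
# multivariable statistics.

make_roc <- function(scores, labels) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' ROC analysis with DeLong confidence interval
#'
#' Empirical ROC curve and trapezoidal AUC (equal to the tie-corrected
#' Mann-Whitney statistic), with a 95% CI `AUC +/- 1.96 SE` from DeLong's
#' structural components, truncated to \[0, 1\].
#'
#' @param scores numeric scores (higher = more responder-like).
#' @param labels binary labels (1 = responder).
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `se`, and `curve`
#'   (data.frame of fpr, tpr, threshold, from (0,0) to (1,1)).
#' @export
roc_auc_ci <- function(scores, labels) {
  r <- make_roc(scores, labels)
  auc <- as.numeric(pROC::auc(r))
  se <- sqrt(pROC::var(r, method = "delong"))
  co <- pROC::coords(r, "all", ret = c("threshold", "specificity",
                                       "sensitivity"), transpose = FALSE)
  curve <- data.frame(fpr = 1 - co$specificity, tpr = co$sensitivity,
                      threshold = co$threshold)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  structure(list(auc = auc,
                 ci_low = max(0, auc - 1.96 * se),
                 ci_high = min(1, auc + 1.96 * se),
                 se = se, curve = curve),
            class = "roc_result")
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided p-value of the paired DeLong z-statistic comparing the ROC
#' curves of two score vectors on the same patients. If the variance of
#' the AUC difference is zero (e.g. identical scores) the p-value is 1,
#' flagged.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels (1 = responder).
#' @return p-value with attribute `flag` when degenerate.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  ra <- make_roc(scores_a, labels)
  rb <- make_roc(scores_b, labels)
  p <- tryCatch({
    tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    as.numeric(tt$p.value)
  }, error = function(e) NA_real_)
  if (!is.finite(p)) {
    p <- 1
    attr(p, "flag") <- "zero-variance AUC difference"
  }
  p
}

#' Youden cutoff and accuracies
#'
#' The cutoff is the observed training score maximizing Youden's index
#' (sensitivity + specificity - 1); ties are broken toward the lower
#' threshold. Patients with score >= cutoff are classified responders; the
#' accuracy at this single training-derived cutoff is reported for both
#' sets. Test labels never influence the cutoff.
#'
#' @param train_scores,train_labels training scores and labels.
#' @param test_scores,test_labels test scores and labels.
#' @return List: `cutoff`, `youden`, `train_accuracy`, `test_accuracy`,
#'   `train_sensitivity`, `train_specificity`.
#' @export
threshold_metrics <- function(train_scores, train_labels,
                              test_scores, test_labels) {
  if (length(unique(train_labels)) < 2)
    stop("both classes must be present in the training set")
  thr <- sort(unique(train_scores))
  n1 <- sum(train_labels == 1); n0 <- sum(train_labels == 0)
  youden <- vapply(thr, function(t) {
    sens <- sum(train_scores >= t & train_labels == 1) / n1
    spec <- sum(train_scores < t & train_labels == 0) / n0
    sens + spec - 1
  }, numeric(1))
  # ties (up to floating-point noise in the rational sens/spec sums) break
  # toward the lower threshold
  best <- thr[youden >= max(youden) - 1e-9][1]
  acc <- function(s, y) mean((s >= best) == (y == 1))
  list(cutoff = best,
       youden = max(youden),
       train_accuracy = acc(train_scores, train_labels),
       test_accuracy = acc(test_scores, test_labels),
       train_sensitivity = sum(train_scores >= best & train_labels == 1) / n1,
       train_specificity = sum(train_scores < best & train_labels == 0) / n0)
}

#' Hosmer-Lemeshow calibration test
#'
#' Splits patients into `g` risk bins of (near-)equal count by sorted
#' predicted probability, keeping ties in one bin; computes the
#' Hosmer-Lemeshow chi-square statistic
#' `sum (O - E)^2 / (E (1 - E / n_bin))` over bins for the event class,
#' with `g - 2` degrees of freedom. Bins with expected count 0 or n_bin
#' are merged with their neighbor (flagged).
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes.
#' @param g number of risk bins (default 10).
#' @return A `calibration_result`: `bins` (data.frame of mean predicted,
#'   observed rate, n), `hl_statistic`, `hl_p`, `df`, `merged` flag.
#' @export
hosmer_lemeshow <- function(scores, labels, g = 10L) {
  n <- length(scores)
  if (g < 3) stop("g must be >= 3")
  if (n < 2 * g) stop("need at least 2g observations")
  qs <- unique(quantile(scores, probs = seq(0, 1, length.out = g + 1),
                        type = 7))
  if (length(qs) < 3) {
    # fewer than 2 distinct risk bins (e.g. constant scores): the test is
    # undefined; report a degenerate result rather than failing
    return(structure(list(bins = data.frame(mean_pred = mean(scores),
                                            obs_rate = mean(labels),
                                            n = n),
                          hl_statistic = NA_real_, hl_p = NA_real_,
                          df = NA_integer_, merged = FALSE,
                          degenerate = TRUE),
                     class = "calibration_result"))
  }
  bin <- cut(scores, breaks = qs, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    n = as.numeric(tapply(scores, bin, length)),
    obs = as.numeric(tapply(labels, bin, sum)),
    exp = as.numeric(tapply(scores, bin, sum)),
    mean_pred = as.numeric(tapply(scores, bin, mean)),
    obs_rate = as.numeric(tapply(labels, bin, mean)))
  # merge degenerate bins (expected count 0 or equal to bin size)
  merged <- FALSE
  i <- 1
  while (i <= nrow(tab)) {
    if (nrow(tab) > 1 && (tab$exp[i] <= 0 || tab$exp[i] >= tab$n[i])) {
      j <- if (i == nrow(tab)) i - 1 else i + 1
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$obs[j] <- tab$obs[j] + tab$obs[i]
      tab$exp[j] <- tab$exp[j] + tab$exp[i]
      tab <- tab[-i, , drop = FALSE]
      merged <- TRUE
      i <- 1
    } else i <- i + 1
  }
  tab$mean_pred <- tab$exp / tab$n
  tab$obs_rate <- tab$obs / tab$n
  hl <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n)))
  df <- max(1L, nrow(tab) - 2L)
  structure(list(bins = tab[, c("mean_pred", "obs_rate", "n")],
                 hl_statistic = hl,
                 hl_p = pchisq(hl, df = df, lower.tail = FALSE),
                 df = df, merged = merged, degenerate = FALSE),
            class = "calibration_result")
}

#' Inter-radiologist consistency of the radiomic score
#'
#' Runs the frozen feature -> signature -> model chain on the feature
#' tables obtained under two segmentations of the same patients and
#' compares the resulting radiomic scores: ICC(2,1) of the paired scores
#' and the DeLong test between the two ROC curves.
#'
#' @param model a fitted `radiomic_model`.
#' @param signatures named list of `habitat_signature`s.
#' @param tables_r1,tables_r2 named lists of per-habitat feature tables
#'   under the two segmentations (same patients, same order).
#' @param clinical clinical covariates for those patients (or `NULL`).
#' @param labels binary labels for those patients.
#' @return List: `icc`, `delong_p`, `scores_r1`, `scores_r2`, per-set AUCs.
#' @export
consistency_analysis <- function(model, signatures, tables_r1, tables_r2,
                                 clinical, labels) {
  score_set <- function(tables) {
    ss <- signature_score_table(signatures, tables)
    predict_scores(model, ss, clinical)
  }
  s1 <- score_set(tables_r1)
  s2 <- score_set(tables_r2)
  icc <- if (isTRUE(all.equal(s1, s2))) 1 else icc_2_1(s1, s2)
  single_class <- length(unique(labels)) < 2
  list(icc = icc,
       delong_p = if (single_class) NA_real_
                  else delong_test(s1, s2, labels),
       auc_r1 = if (single_class) NA_real_ else auc_mw(s1, labels),
       auc_r2 = if (single_class) NA_real_ else auc_mw(s2, labels),
       scores_r1 = s1, scores_r2 = s2)
}

#' Per-habitat signature score table
#'
#' @param signatures named list of `habitat_signature`s.
#' @param tables named list of per-habitat feature tables (same names).
#' @return data.frame of signature scores, one column per habitat.
#' @export
signature_score_table <- function(signatures, tables) {
  stopifnot(all(names(signatures) %in% names(tables)))
  out <- as.data.frame(lapply(names(signatures), function(h)
    signature_score(signatures[[h]], tables[[h]])),
    col.names = names(signatures))
  rownames(out) <- rownames(tables[[1]])
  out
}

#' Univariate clinical statistics
#'
#' For each covariate, compares responders and non-responders: continuous
#' covariates use the two-sample t-test when both groups pass a
#' Shapiro-Wilk normality check at alpha = 0.05, otherwise the
#' Mann-Whitney U test; binary covariates use the chi-square test unless
#' any expected cell is below 5, then Fisher's exact test. Constant
#' covariates get p = 1, flagged.
#'
#' @param clinical data.frame of covariates.
#' @param labels binary labels.
#' @param categorical names of categorical covariates (default
#'   `"family_history"`).
#' @return data.frame: covariate, test used, p-value.
#' @export
clinical_univariate <- function(clinical, labels,
                                categorical = "family_history") {
  rows <- lapply(names(clinical), function(v) {
    x <- clinical[[v]]
    g1 <- x[labels == 1]; g0 <- x[labels == 0]
    if (length(unique(x)) < 2)
      return(data.frame(covariate = v, test = "constant", p = 1))
    if (v %in% categorical) {
      tab <- table(factor(x, levels = sort(unique(x))),
                   factor(labels, levels = c(0, 1)))
      expctd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expctd < 5)) {
        p <- fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- chisq.test(tab, correct = FALSE)$p.value
        test <- "chisq"
      }
    } else {
      normal <- function(z) {
        z <- z[!is.na(z)]
        if (length(unique(z)) < 3 || length(z) < 3 || length(z) > 5000)
          return(FALSE)
        shapiro.test(z)$p.value >= 0.05
      }
      if (normal(g1) && normal(g0)) {
        p <- t.test(g1, g0)$p.value
        test <- "t"
      } else {
        p <- suppressWarnings(wilcox.test(g1, g0)$p.value)
        test <- "mann-whitney"
      }
    }
    data.frame(covariate = v, test = test, p = p)
  })
  do.call(rbind, rows)
}

#' Multivariable logistic regression
#'
#' Unpenalized logistic fit of the response on the radiomic score plus all
#' clinical covariates, with per-coefficient Wald z p-values. If the fit
#' shows (quasi-)complete separation the p-values are suppressed and the
#' result flagged.
#'
#' @param radiomic_scores numeric radiomic score per patient.
#' @param clinical data.frame of clinical covariates.
#' @param labels binary labels.
#' @return data.frame of term, estimate, se, z, p; attribute `separation`.
#' @export
multivariable_logistic <- function(radiomic_scores, clinical, labels) {
  dat <- data.frame(label = labels, radiomic_score = radiomic_scores,
                    clinical)
  if (nrow(dat) <= ncol(dat))
    stop("too few patients for the number of predictors")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(label ~ ., data = dat, family = binomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    z = sm[, 3], p = sm[, 4], row.names = NULL)
  if (sep) out$p <- NA_real_
  attr(out, "separation") <- sep
  out
}
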