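# Radiomic model building: exhaustive grid search over learner family,
# hyperparameters, and variable subsets (habitat signatures, optionally
# augmented with the clinical covariate block), scored by mean accuracy
# over repeated stratified 3-fold cross-validation on the training set,
# then a final refit on all training rows.

#' Model grid configuration
#'
#' @param families learner families to search, a subset of
#'   `c("LR", "SVM", "RF")` (complexity order LR < SVM < RF for
#'   tie-breaking).
#' @param subset_max maximum number of signatures per candidate subset.
#' @param include_clinical if `TRUE`, every signature subset is also tried
#'   augmented with the full clinical covariate block (all-or-nothing).
#' @param cv_folds folds of the inner CV (default 3).
#' @param cv_repeats repeats of the inner CV (default 10).
#' @param lr_penalty logistic-regression penalties: `"none"` and/or L2
#'   strength(s) as numbers.
#' @param svm_cost,svm_gamma_mult radial-SVM cost grid and multipliers of
#'   the scale-based kernel width `1 / (p * var(X))`.
#' @param rf_ntree,rf_mtry random-forest tree counts and mtry rules
#'   (`"sqrt"` or `"all"`).
#' @return A `model_grid_config` list.
#' @export
model_grid_config <- function(families = c("LR", "SVM", "RF"),
                              subset_max = 4L,
                              include_clinical = TRUE,
                              cv_folds = 3L,
                              cv_repeats = 10L,
                              lr_penalty = list("none", 1.0),
                              svm_cost = c(0.1, 1, 10),
                              svm_gamma_mult = c(0.5, 1, 2),
                              rf_ntree = c(100L, 300L),
                              rf_mtry = c("sqrt", "all")) {
  structure(list(families = families, subset_max = as.integer(subset_max),
                 include_clinical = include_clinical,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 lr_penalty = lr_penalty, svm_cost = svm_cost,
                 svm_gamma_mult = svm_gamma_mult,
                 rf_ntree = as.integer(rf_ntree), rf_mtry = rf_mtry),
            class = "model_grid_config")
}

# A reduced grid for quick runs: same families and search structure,
# smaller hyperparameter grids and fewer CV repeats.
#' @rdname model_grid_config
#' @param ... overrides passed to [model_grid_config()].
#' @export
model_grid_config_light <- function(...) {
  defaults <- list(subset_max = 3L, cv_repeats = 2L,
                   lr_penalty = list("none"),
                   svm_cost = c(1, 10), svm_gamma_mult = 1,
                   rf_ntree = 100L, rf_mtry = "sqrt")
  do.call(model_grid_config, utils::modifyList(defaults, list(...)))
}

# Enumerate family x hyperparameter cells of the grid.
learner_grid <- function(config) {
  cells <- list()
  if ("LR" %in% config$families)
    for (p in config$lr_penalty)
      cells[[length(cells) + 1L]] <- list(family = "LR",
                                          hyper = list(penalty = p))
  if ("SVM" %in% config$families)
    for (cost in config$svm_cost)
      for (gm in config$svm_gamma_mult)
        cells[[length(cells) + 1L]] <- list(
          family = "SVM", hyper = list(cost = cost, gamma_mult = gm))
  if ("RF" %in% config$families)
    for (nt in config$rf_ntree)
      for (mt in config$rf_mtry)
        cells[[length(cells) + 1L]] <- list(
          family = "RF", hyper = list(ntree = nt, mtry = mt))
  cells
}

# Enumerate candidate variable sets: signature subsets of size 1..max,
# each optionally augmented with the clinical block.
variable_sets <- function(sig_names, clin_names, config) {
  sets <- list()
  for (k in seq_len(min(config$subset_max, length(sig_names))))
    sets <- c(sets, utils::combn(sig_names, k, simplify = FALSE))
  out <- lapply(sets, function(s) list(signatures = s, clinical = FALSE))
  if (config$include_clinical && length(clin_names))
    out <- c(out, lapply(sets, function(s)
      list(signatures = s, clinical = TRUE)))
  out
}

# prob_model: whether the SVM carries a Platt probability model (needed
# for probability output; skipped during CV scoring where the class
# prediction at decision threshold 0 is sufficient).
fit_learner <- function(family, hyper, X, y, prob_model = TRUE) {
  yf <- factor(y, levels = c(0, 1))
  if (family == "LR") {
    if (identical(hyper$penalty, "none")) {
      fit <- suppressWarnings(
        glm.fit(cbind(1, X), y, family = binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0  # aliased columns (e.g. constant scores)
      list(kind = "glm", coef = cf)
    } else {
      # ridge logistic; glmnet needs >= 2 columns
      X2 <- if (ncol(X) == 1) cbind(X, 0) else X
      fit <- glmnet::glmnet(X2, y, family = "binomial", alpha = 0,
                            lambda = as.numeric(hyper$penalty),
                            standardize = TRUE)
      list(kind = "ridge", fit = fit, pad = ncol(X) == 1)
    }
  } else if (family == "SVM") {
    v <- var(as.vector(X))
    if (!is.finite(v) || v < 1e-8) v <- 1  # degenerate (constant) design
    gamma <- hyper$gamma_mult / (ncol(X) * v)
    fit <- e1071::svm(X, yf, kernel = "radial", cost = hyper$cost,
                      gamma = gamma, probability = prob_model)
    list(kind = "svm", fit = fit)
  } else if (family == "RF") {
    # randomForest stalls on all-constant designs (e.g. a candidate subset
    # of empty signatures); drop constant columns, fall back to the
    # training prevalence if nothing varies
    keep <- apply(X, 2, function(col) diff(range(col)) > 0)
    if (!any(keep))
      return(list(kind = "const", prob = mean(y == 1)))
    Xr <- X[, keep, drop = FALSE]
    mtry <- if (identical(hyper$mtry, "all")) ncol(Xr)
            else max(1L, floor(sqrt(ncol(Xr))))
    fit <- randomForest::randomForest(Xr, yf, ntree = hyper$ntree,
                                      mtry = mtry)
    list(kind = "rf", fit = fit, keep = keep)
  } else stop("unknown family '", family, "'")
}

# Hard 0/1 class prediction (probability threshold 0.5; for the SVM, the
# native decision rule, which classifies at decision value 0).
predict_class <- function(obj, X) {
  if (obj$kind == "svm")
    as.integer(as.character(predict(obj$fit, X)))
  else as.integer(predict_prob(obj, X) >= 0.5)
}

predict_prob <- function(obj, X) {
  switch(obj$kind,
    glm = as.numeric(plogis(cbind(1, X) %*% obj$coef)),
    ridge = {
      X2 <- if (obj$pad) cbind(X, 0) else X
      as.numeric(predict(obj$fit, X2, type = "response"))
    },
    svm = {
      pr <- attr(predict(obj$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    rf = as.numeric(predict(obj$fit, X[, obj$keep, drop = FALSE],
                            type = "prob")[, "1"]),
    const = rep(obj$prob, nrow(X)))
}

build_design <- function(vars, signature_scores, clinical) {
  X <- as.matrix(signature_scores[, vars$signatures, drop = FALSE])
  if (isTRUE(vars$clinical)) {
    if (is.null(clinical)) stop("clinical covariates not supplied")
    X <- cbind(X, as.matrix(clinical))
  }
  X
}

#' Grid search for the fused radiomic model
#'
#' Exhaustively scores every combination of learner family, hyperparameter
#' cell, and candidate variable set (signature subsets of size 1 to
#' `subset_max`, each optionally augmented with the clinical block) by the
#' mean accuracy at probability threshold 0.5 over `cv_repeats` repeats of
#' seeded stratified `cv_folds`-fold cross-validation of the training set.
#' Ties are broken by fewer input variables, then simpler family
#' (LR < SVM < RF), then lexicographic variable names, so the selection is
#' deterministic.
#'
#' @param signature_scores data.frame/matrix of per-habitat signature
#'   scores (columns named by habitat), training rows.
#' @param clinical data.frame of clinical covariates (or `NULL`).
#' @param labels binary labels (1 = responder).
#' @param config a [model_grid_config()].
#' @param seed seed for fold assignment and the stochastic learners.
#' @return A `model_spec`: `family`, `hyper`, `variables` (list with
#'   `signatures`, `clinical`), `cv_mean_accuracy`.
#' @export
grid_search_select <- function(signature_scores, clinical, labels,
                               config = model_grid_config(), seed = 1L) {
  stopifnot(length(unique(labels)) == 2)
  n <- length(labels)
  if (n < 3L * config$cv_folds)
    stop("need at least ", 3L * config$cv_folds, " patients")
  sets <- variable_sets(colnames(signature_scores),
                        colnames(clinical), config)
  cells <- learner_grid(config)
  if (!length(sets) || !length(cells)) stop("empty search grid")
  folds <- lapply(seq_len(config$cv_repeats), function(r)
    stratified_folds(labels, config$cv_folds, child_seed(seed, "cvfold", r)))
  family_rank <- c(LR = 1, SVM = 2, RF = 3)

  best <- NULL
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    for (si in seq_along(sets)) {
      X <- build_design(sets[[si]], signature_scores, clinical)
      correct <- 0L; total <- 0L
      with_seed(child_seed(seed, "cvfit", ci * 10000L + si), {
        for (fold_assign in folds)
          for (k in seq_len(config$cv_folds)) {
            tr <- fold_assign != k
            if (length(unique(labels[tr])) < 2) next
            fit <- fit_learner(cell$family, cell$hyper,
                               X[tr, , drop = FALSE], labels[tr],
                               prob_model = FALSE)
            cl <- predict_class(fit, X[!tr, , drop = FALSE])
            correct <- correct + sum(cl == labels[!tr])
            total <- total + sum(!tr)
          }
      })
      acc <- correct / total
      cand <- list(family = cell$family, hyper = cell$hyper,
                   variables = sets[[si]], cv_mean_accuracy = acc,
                   n_vars = ncol(X))
      if (is.null(best) ||
          acc > best$cv_mean_accuracy + 1e-12 ||
          (abs(acc - best$cv_mean_accuracy) <= 1e-12 &&
           (cand$n_vars < best$n_vars ||
            (cand$n_vars == best$n_vars &&
             (family_rank[cand$family] < family_rank[best$family] ||
              (cand$family == best$family &&
               paste(cand$variables$signatures, collapse = ",") <
               paste(best$variables$signatures, collapse = ",")))))))
        best <- cand
    }
  }
  structure(best[c("family", "hyper", "variables", "cv_mean_accuracy")],
            class = "model_spec")
}

#' Fit the final radiomic model
#'
#' Retrains the grid-selected learner on all training rows, using exactly
#' the variables stored in the selected `model_spec`.
#'
#' @param spec a `model_spec` from [grid_search_select()].
#' @param signature_scores,clinical,labels training data (as in
#'   [grid_search_select()]).
#' @param seed seed for the stochastic learners.
#' @return A `radiomic_model` wrapping the fitted learner.
#' @export
fit_final_model <- function(spec, signature_scores, clinical, labels,
                            seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(unique(labels)) < 2)
    stop("both classes must be present to fit the final model")
  X <- build_design(spec$variables, signature_scores, clinical)
  fit <- with_seed(child_seed(seed, "final_fit"),
                   fit_learner(spec$family, spec$hyper, X, labels))
  structure(list(spec = spec, fit = fit, seed = seed),
            class = "radiomic_model")
}

#' Predict response probabilities with the radiomic model
#'
#' @param model a `radiomic_model`.
#' @param signature_scores data.frame/matrix of signature scores containing
#'   the model's signature variables.
#' @param clinical clinical covariates (required only if the model uses the
#'   clinical block).
#' @return Probabilities in \[0, 1\], one per row.
#' @export
predict_scores <- function(model, signature_scores, clinical = NULL) {
  stopifnot(inherits(model, "radiomic_model"))
  vars <- model$spec$variables
  missing <- setdiff(vars$signatures, colnames(signature_scores))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  X <- build_design(vars, signature_scores, clinical)
  p <- predict_prob(model$fit, X)
  pmin(pmax(p, 0), 1)
}
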