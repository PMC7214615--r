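# Pipeline orchestration: QC filter, seeded train/test split, the
# selection -> signatures -> grid search -> final model chain, the full
# evaluation report, and repeated random-split validation.

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. Defaults mirror the standard
#' workflow: ICC threshold 0.8, absolute-correlation threshold 0.6, 10-fold
#' CV for the LASSO penalty, a 60/60 train/test split of a 120-patient
#' cohort, 25 re-segmented training patients for the stability filter,
#' repeated stratified 3-fold CV for the model grid, 20 repeated random
#' splits, and 10 Hosmer-Lemeshow bins.
#'
#' @param cohort a [cohort_config()] (or `NULL` when a cohort is supplied
#'   to [run_pipeline()] directly).
#' @param train_size patients in the training set (the rest form the test
#'   set).
#' @param icc_threshold stability (ICC) retention threshold.
#' @param r_threshold redundancy (absolute Pearson) threshold.
#' @param lasso_folds CV folds for the LASSO penalty path.
#' @param n_resegment training patients re-segmented for the stability
#'   filter.
#' @param perturb_fraction,dice_floor re-segmentation perturbation strength
#'   and Dice floor (see [perturb_mask()]).
#' @param feature a [feature_config()].
#' @param grid a [model_grid_config()].
#' @param n_repeated_splits repeated random splits (0 to skip).
#' @param hl_bins Hosmer-Lemeshow risk bins.
#' @param qc_min_slices,qc_max_slices mask slice-count QC rule bounds.
#' @param output_dir optional directory for run artifacts.
#' @param seed master seed; every stochastic step consumes a named child
#'   seed derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            train_size = 60L,
                            icc_threshold = 0.8,
                            r_threshold = 0.6,
                            lasso_folds = 10L,
                            n_resegment = 25L,
                            perturb_fraction = 0.2,
                            dice_floor = 0.8,
                            feature = feature_config(),
                            grid = model_grid_config(),
                            n_repeated_splits = 20L,
                            hl_bins = 10L,
                            qc_min_slices = 4L,
                            qc_max_slices = Inf,
                            output_dir = NULL,
                            seed = 1L) {
  if (icc_threshold <= 0 || icc_threshold >= 1)
    stop("icc_threshold must be in (0, 1)")
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must be in (0, 1)")
  structure(list(cohort = cohort, train_size = as.integer(train_size),
                 icc_threshold = icc_threshold, r_threshold = r_threshold,
                 lasso_folds = as.integer(lasso_folds),
                 n_resegment = as.integer(n_resegment),
                 perturb_fraction = perturb_fraction,
                 dice_floor = dice_floor,
                 feature = feature, grid = grid,
                 n_repeated_splits = as.integer(n_repeated_splits),
                 hl_bins = as.integer(hl_bins),
                 qc_min_slices = qc_min_slices,
                 qc_max_slices = qc_max_slices,
                 output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

mask_slice_span <- function(mask) sum(apply(mask$voxels, 3, any))

#' Quality-control filter
#'
#' Excludes patients with missing clinical covariates and patients whose
#' habitat masks violate the configurable slice-count rule, logging a
#' reason per exclusion.
#'
#' @param cohort list of `habitat_study` objects.
#' @param min_slices,max_slices inclusive bounds on the number of axial
#'   slices every habitat mask must span.
#' @return List: `cohort` (retained studies), `exclusions` (data.frame of
#'   patient_id, reason).
#' @export
qc_filter <- function(cohort, min_slices = 4L, max_slices = Inf) {
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    if (anyNA(unlist(s$clinical))) {
      ids <- c(ids, s$patient_id)
      reasons <- c(reasons, "missing clinical data")
      next
    }
    spans <- vapply(s$masks, mask_slice_span, numeric(1))
    if (any(spans < min_slices) || any(spans > max_slices)) {
      ids <- c(ids, s$patient_id)
      reasons <- c(reasons, "mask slice count outside QC bounds")
      next
    }
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("QC filter removed every patient")
  list(cohort = cohort[keep],
       exclusions = data.frame(patient_id = ids, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Perturbed re-segmentation of every mask of a cohort
#'
#' Applies [perturb_mask()] to each habitat mask of each patient with
#' deterministic per-patient, per-sequence child seeds.
#'
#' @param cohort list of `habitat_study` objects.
#' @param seed master seed.
#' @param fraction,dice_floor see [perturb_mask()].
#' @return Named list (by patient id) of per-sequence mask lists.
#' @export
perturb_cohort_masks <- function(cohort, seed, fraction = 0.2,
                                 dice_floor = 0.8) {
  out <- lapply(cohort, function(s) {
    masks <- lapply(names(s$masks), function(sq)
      perturb_mask(s$masks[[sq]],
                   seed = child_seed(seed, paste0(s$patient_id, sq)),
                   fraction = fraction, dice_floor = dice_floor))
    setNames(masks, names(s$masks))
  })
  setNames(out, vapply(cohort, `[[`, "", "patient_id"))
}

# Train the whole selection + modeling chain on the given training rows of
# precomputed per-habitat feature tables. Test rows are only ever scored.
# `labels` must be named by patient id; `train_idx` holds patient ids.
# `tables_r2` holds only the re-segmented patients (rownames); the
# stability filter runs on the overlap of the training set with them.
train_on_split <- function(tables_r1, tables_r2, clinical, labels,
                           train_idx, config, seed) {
  stopifnot(!is.null(names(labels)), all(train_idx %in% names(labels)))
  habitats <- names(tables_r1)
  reseg_idx <- intersect(train_idx, rownames(tables_r2[[1]]))
  if (length(reseg_idx) < 3)
    stop("fewer than 3 re-segmented patients fall in the training set")
  signatures <- list()
  stability <- list()
  for (h in habitats) {
    t1 <- tables_r1[[h]]
    t2 <- tables_r2[[h]]
    rep_h <- stability_filter(t1[reseg_idx, , drop = FALSE],
                              t2[reseg_idx, , drop = FALSE],
                              threshold = config$icc_threshold)
    stability[[h]] <- rep_h
    stable <- rep_h$feature[rep_h$retained]
    train_tab <- t1[train_idx, , drop = FALSE]
    if (length(stable) >= 1) {
      iccs <- setNames(rep_h$icc, rep_h$feature)
      kept <- redundancy_filter(train_tab[, stable, drop = FALSE],
                                iccs, r_threshold = config$r_threshold)
    } else kept <- character(0)
    if (length(kept) >= 1) {
      signatures[[h]] <- fit_habitat_signature(
        train_tab[, kept, drop = FALSE], labels[train_idx],
        cv_folds = config$lasso_folds,
        seed = child_seed(seed, paste0("lasso_", h)), habitat = h)
    } else {
      # nothing survived the filters: constant (empty) signature
      prev <- mean(labels[train_idx])
      signatures[[h]] <- structure(
        list(habitat = h, features = character(0),
             coefficients = numeric(0),
             intercept = log(prev / (1 - prev)),
             center = numeric(0), scale = numeric(0),
             lambda = Inf, empty = TRUE, training_auc = 0.5),
        class = "habitat_signature")
    }
  }
  scores_all <- signature_score_table(signatures, tables_r1)
  spec <- grid_search_select(scores_all[train_idx, , drop = FALSE],
                             clinical[train_idx, , drop = FALSE],
                             labels[train_idx], config$grid,
                             seed = child_seed(seed, "grid"))
  model <- fit_final_model(spec, scores_all[train_idx, , drop = FALSE],
                           clinical[train_idx, , drop = FALSE],
                           labels[train_idx],
                           seed = child_seed(seed, "final"))
  pred_all <- predict_scores(model, scores_all, clinical)
  list(signatures = signatures, stability = stability, spec = spec,
       model = model, signature_scores = scores_all,
       radiomic_scores = pred_all, reseg_idx = reseg_idx)
}

#' Repeated random-split validation
#'
#' Repeatedly splits the patients into training and test halves; for each
#' split the entire selection + modeling chain (stability filter,
#' redundancy pruning, LASSO signatures, model grid search, final refit)
#' is rebuilt on the training half only, and the held-out AUC is recorded.
#' A split leaving a single-class training set is resampled (flagged).
#'
#' @param tables_r1,tables_r2 per-habitat feature tables under the two
#'   segmentations (full cohort).
#' @param clinical clinical covariate data.frame (full cohort).
#' @param labels binary labels.
#' @param config a [pipeline_config()].
#' @param n_splits number of repeated splits (default from config).
#' @param seed master seed for the split sequence.
#' @return List: `aucs` (length `n_splits`), `mean`, `range`, `resampled`.
#' @export
repeated_split_eval <- function(tables_r1, tables_r2, clinical, labels,
                                config, n_splits = NULL, seed = NULL) {
  n_splits <- n_splits %||% config$n_repeated_splits
  seed <- seed %||% child_seed(config$seed, "repeated_splits")
  n <- length(labels)
  ids <- rownames(tables_r1[[1]])
  labels <- setNames(as.integer(labels), ids)
  aucs <- numeric(n_splits)
  resampled <- 0L
  for (s in seq_len(n_splits)) {
    attempt <- 0L
    repeat {
      train_rows <- with_seed(child_seed(seed, "split", s * 100L + attempt),
                              sample(n, config$train_size))
      if (length(unique(labels[train_rows])) == 2 &&
          length(unique(labels[-train_rows])) == 2) break
      attempt <- attempt + 1L
      resampled <- resampled + 1L
      if (attempt > 50L) stop("could not draw a two-class split")
    }
    train_idx <- ids[train_rows]
    test_idx <- ids[-train_rows]
    fitted <- train_on_split(tables_r1, tables_r2, clinical, labels,
                             train_idx, config,
                             seed = child_seed(seed, "refit", s))
    aucs[s] <- auc_mw(fitted$radiomic_scores[match(test_idx, ids)],
                      labels[test_idx])
  }
  list(aucs = aucs, mean = mean(aucs), range = range(aucs),
       resampled = resampled)
}

#' Run the full multi-habitat radiomics pipeline
#'
#' Generates (or accepts) a cohort, applies QC, extracts the per-habitat
#' feature tables under the primary and a perturbed re-segmentation,
#' splits into training and test sets, builds the nine habitat signatures
#' and the fused radiomic model on the training set, and assembles the
#' evaluation report: ROC/AUC with DeLong CIs for both sets, Youden cutoff
#' and accuracies, Hosmer-Lemeshow calibration, inter-radiologist
#' consistency (score ICC and DeLong p), clinical univariate statistics,
#' multivariable logistic regression, and (optionally) repeated
#' random-split AUCs. Every stochastic step consumes a named child seed of
#' `config$seed`, so the report is a pure function of (cohort, config).
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (list of `habitat_study`);
#'   generated from `config$cohort` when omitted.
#' @return An `evaluation_report` list; artifacts are written under
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  qc <- qc_filter(cohort, config$qc_min_slices, config$qc_max_slices)
  cohort <- qc$cohort
  n <- length(cohort)
  if (config$train_size >= n)
    stop("train_size must be smaller than the post-QC cohort (", n, ")")
  ids <- vapply(cohort, `[[`, "", "patient_id")
  labels <- setNames(vapply(cohort, `[[`, 0L, "label"), ids)
  clinical <- cohort_clinical(cohort)
  rownames(clinical) <- clinical$patient_id
  clinical <- clinical[, setdiff(names(clinical), c("patient_id", "label")),
                       drop = FALSE]

  train_rows <- with_seed(child_seed(config$seed, "split"),
                          sample(n, config$train_size))
  train_idx <- ids[sort(train_rows)]
  test_idx <- setdiff(ids, train_idx)
  if (length(unique(labels[match(train_idx, ids)])) < 2)
    stop("training split contains a single class; choose another seed")

  # only a fixed training subset is re-segmented (mirroring a second
  # radiologist re-delineating part of the cohort); repeated splits reuse
  # the overlap of their training set with this subset
  reseg_ids <- with_seed(child_seed(config$seed, "resegment"),
                         sort(sample(train_idx,
                                     min(config$n_resegment,
                                         length(train_idx)))))
  reseg_cohort <- cohort[match(reseg_ids, ids)]
  masks_r2 <- perturb_cohort_masks(reseg_cohort,
                                   seed = child_seed(config$seed, "reseg"),
                                   fraction = config$perturb_fraction,
                                   dice_floor = config$dice_floor)
  tables_r1 <- extract_all_tables(cohort, config$feature)
  tables_r2 <- extract_all_tables(reseg_cohort, config$feature,
                                  masks = masks_r2)

  fitted <- train_on_split(tables_r1, tables_r2, clinical, labels,
                           train_idx, config,
                           seed = child_seed(config$seed, "train"))

  tr <- match(train_idx, ids); te <- match(test_idx, ids)
  sc <- fitted$radiomic_scores
  roc_train <- roc_auc_ci(sc[tr], labels[tr])
  roc_test <- roc_auc_ci(sc[te], labels[te])
  thr <- threshold_metrics(sc[tr], labels[tr], sc[te], labels[te])
  hl_train <- hosmer_lemeshow(sc[tr], labels[tr], config$hl_bins)
  hl_test <- hosmer_lemeshow(sc[te], labels[te], config$hl_bins)

  rg <- match(reseg_ids, ids)
  consistency <- consistency_analysis(
    fitted$model, fitted$signatures,
    lapply(tables_r1, function(t) t[reseg_ids, , drop = FALSE]),
    tables_r2, clinical[reseg_ids, , drop = FALSE], labels[rg])

  clin_train <- clinical_univariate(clinical[tr, , drop = FALSE],
                                    labels[tr])
  clin_test <- clinical_univariate(clinical[te, , drop = FALSE],
                                   labels[te])
  mv <- multivariable_logistic(sc[tr], clinical[tr, , drop = FALSE],
                               labels[tr])

  splits <- if (config$n_repeated_splits > 0)
    repeated_split_eval(tables_r1, tables_r2, clinical, labels, config)
  else NULL

  report <- structure(list(
    n_patients = n,
    train_ids = train_idx, test_ids = test_idx,
    signatures = fitted$signatures,
    signature_training_aucs = vapply(fitted$signatures, `[[`, 0,
                                     "training_auc"),
    model_spec = fitted$spec,
    model = fitted$model,
    radiomic_scores = setNames(sc, ids),
    roc_train = roc_train, roc_test = roc_test,
    cutoff = thr$cutoff,
    train_accuracy = thr$train_accuracy,
    test_accuracy = thr$test_accuracy,
    calibration_train = hl_train, calibration_test = hl_test,
    consistency_icc = consistency$icc,
    delong_p_consistency = consistency$delong_p,
    clinical_univariate_train = clin_train,
    clinical_univariate_test = clin_test,
    multivariable = mv,
    repeated_splits = splits,
    exclusions = qc$exclusions,
    seed = config$seed), class = "evaluation_report")
  if (!is.null(config$output_dir))
    write_report_artifacts(report, fitted, tables_r1, config)
  report
}

#' @param x an `evaluation_report`.
#' @param ... unused.
#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat("Multi-habitat radiomics evaluation report\n")
  cat(sprintf("  patients: %d (train %d / test %d)\n", x$n_patients,
              length(x$train_ids), length(x$test_ids)))
  cat(sprintf("  model: %s on {%s}%s\n", x$model_spec$family,
              paste(x$model_spec$variables$signatures, collapse = ", "),
              if (isTRUE(x$model_spec$variables$clinical))
                " + clinical" else ""))
  cat(sprintf("  train AUC %.3f (95%% CI %.3f-%.3f)\n", x$roc_train$auc,
              x$roc_train$ci_low, x$roc_train$ci_high))
  cat(sprintf("  test  AUC %.3f (95%% CI %.3f-%.3f)\n", x$roc_test$auc,
              x$roc_test$ci_low, x$roc_test$ci_high))
  cat(sprintf("  cutoff %.3f; accuracy train %.3f / test %.3f\n",
              x$cutoff, x$train_accuracy, x$test_accuracy))
  cat(sprintf("  Hosmer-Lemeshow p: train %.3f / test %.3f\n",
              x$calibration_train$hl_p, x$calibration_test$hl_p))
  cat(sprintf("  consistency ICC %.3f (DeLong p %.3f)\n",
              x$consistency_icc, x$delong_p_consistency))
  if (!is.null(x$repeated_splits))
    cat(sprintf("  repeated-split AUC mean %.3f (range %.3f-%.3f, n=%d)\n",
                x$repeated_splits$mean, x$repeated_splits$range[1],
                x$repeated_splits$range[2], length(x$repeated_splits$aucs)))
  invisible(x)
}

signature_to_list <- function(sig) {
  sig[c("habitat", "features", "coefficients", "intercept", "center",
        "scale", "lambda", "empty", "training_auc")]
}

write_report_artifacts <- function(report, fitted, tables_r1, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  for (h in names(tables_r1))
    write.csv(tables_r1[[h]], out(sprintf("features_%s.csv", h)))
  stab <- do.call(rbind, lapply(names(fitted$stability), function(h)
    cbind(habitat = h, fitted$stability[[h]])))
  write.csv(stab, out("stability_report.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(fitted$signatures, signature_to_list),
                       out("signatures.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(report$model_spec[c("family", "hyper", "variables",
                                           "cv_mean_accuracy")],
                       out("model_spec.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(data.frame(patient_id = names(report$radiomic_scores),
                       score = as.numeric(report$radiomic_scores)),
            out("radiomic_scores.csv"), row.names = FALSE)
  summary <- list(
    n_patients = report$n_patients,
    train_auc = report$roc_train$auc,
    train_auc_ci = c(report$roc_train$ci_low, report$roc_train$ci_high),
    test_auc = report$roc_test$auc,
    test_auc_ci = c(report$roc_test$ci_low, report$roc_test$ci_high),
    cutoff = report$cutoff,
    train_accuracy = report$train_accuracy,
    test_accuracy = report$test_accuracy,
    hl_p_train = report$calibration_train$hl_p,
    hl_p_test = report$calibration_test$hl_p,
    consistency_icc = report$consistency_icc,
    delong_p_consistency = report$delong_p_consistency,
    repeated_split_aucs = report$repeated_splits$aucs,
    seed = report$seed)
  jsonlite::write_json(summary, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$output_dir)
}
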