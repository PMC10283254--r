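# Cross-validated random-forest subtype classifier with per-fold feature
# screening, a selection ledger, and clinical-consistency checks.

#' Classifier configuration
#'
#' @param n_folds number of stratified cross-validation folds.
#' @param selection_threshold minimum number of folds a feature must be
#'   selected in to enter the ledger.
#' @param num_trees forest size (>= 100).
#' @param screen_size inner feature-screen size: the number of
#'   top-importance features kept within each training fold.
#' @param seed master seed (folds and forests derive from it).
#' @param fold_assignment optional precomputed integer fold id per subject
#'   (overrides the stratified split; mainly for leakage tests).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_folds = 5L, selection_threshold = 3L,
                              num_trees = 500L, screen_size = 50L,
                              seed = 1L, fold_assignment = NULL) {
  if (selection_threshold > n_folds)
    stop("selection_threshold cannot exceed n_folds")
  if (num_trees < 100) stop("forest size must be >= 100")
  structure(list(n_folds = as.integer(n_folds),
                 selection_threshold = as.integer(selection_threshold),
                 num_trees = as.integer(num_trees),
                 screen_size = as.integer(screen_size),
                 seed = as.integer(seed),
                 fold_assignment = fold_assignment),
            class = "classifier_config")
}

stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, 1L), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated random-forest subtype classifier
#'
#' Stratified k-fold cross-validation. Within each fold, feature screening
#' touches the training rows only: a forest ranks all features by impurity
#' importance, the top `screen_size` are kept as that fold's selected set,
#' a second forest is refit on the screened set, and validation subjects
#' are scored out-of-fold. The per-fold AUC is the rank (Mann-Whitney)
#' AUC of the predicted probability of subtype-1 membership.
#'
#' @param x numeric matrix, subjects x features (typically the combined
#'   protein + miRNA blocks); rownames are subject IDs.
#' @param labels subtype labels (values 1/2; named vector or
#'   `cluster_assignment`).
#' @param config a [classifier_config()].
#' @param modality optional named vector feature -> modality for the
#'   ledger.
#' @return An object of class `classifier_report`: `fold_auc`, `mean_auc`,
#'   `sd_auc`, `selections` (per-fold data.frames of feature/importance),
#'   `fold` (assignment per subject), `oof_prob` (out-of-fold probability
#'   of subtype 1), `predicted` (per fold, train and validation predicted
#'   labels), `labels`, `config`.
#' @export
run_cv_classifier <- function(x, labels, config = classifier_config(),
                              modality = NULL) {
  labels <- as_labels(labels)
  if (!is.null(names(labels)) && !is.null(rownames(x)))
    labels <- labels[rownames(x)]
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  if (min(table(labels)) < config$n_folds)
    stop("more folds than minority-class subjects")
  n <- nrow(x)
  fold <- config$fold_assignment %||%
    stratified_folds(labels, config$n_folds, config$seed)
  y <- factor(labels)
  fold_auc <- numeric(config$n_folds)
  selections <- vector("list", config$n_folds)
  predicted <- vector("list", config$n_folds)
  oof <- rep(NA_real_, n)

  for (f in seq_len(config$n_folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    if (length(unique(y[tr])) < 2) stop("training fold with a single class")
    screen <- ranger::ranger(
      x = x[tr, , drop = FALSE], y = y[tr],
      num.trees = config$num_trees, importance = "impurity",
      seed = derive_seed(config$seed, 10L + f), num.threads = 1)
    imp <- sort(screen$variable.importance, decreasing = TRUE)
    keep <- names(imp)[seq_len(min(config$screen_size, length(imp)))]
    fit <- ranger::ranger(
      x = x[tr, keep, drop = FALSE], y = y[tr],
      num.trees = config$num_trees, importance = "impurity",
      probability = TRUE,
      seed = derive_seed(config$seed, 100L + f), num.threads = 1)
    selections[[f]] <- data.frame(
      feature = keep,
      importance = unname(fit$variable.importance[keep]),
      modality = if (is.null(modality)) NA_character_
                 else unname(modality[keep]),
      fold = f, stringsAsFactors = FALSE)
    prob_va <- stats::predict(fit, data = x[va, keep, drop = FALSE],
                              num.threads = 1)$predictions[, "1"]
    prob_tr <- stats::predict(fit, data = x[tr, keep, drop = FALSE],
                              num.threads = 1)$predictions[, "1"]
    oof[va] <- prob_va
    fold_auc[f] <- auc_rank(prob_va, y[va] == "1")
    predicted[[f]] <- list(
      train = stats::setNames(ifelse(prob_tr > 0.5, 1L, 2L), rownames(x)[tr]),
      validation = stats::setNames(ifelse(prob_va > 0.5, 1L, 2L),
                                   rownames(x)[va]))
  }
  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 sd_auc = stats::sd(fold_auc[!is.na(fold_auc)]),
                 selections = selections, fold = fold, oof_prob = oof,
                 predicted = predicted,
                 labels = stats::setNames(labels, rownames(x)),
                 config = config),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d folds, AUC %.3f (sd %.3f)\n",
              x$config$n_folds, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Tally features selected across cross-validation folds
#'
#' Features selected in at least `selection_threshold` folds, with the
#' mean and SD of their importance across the folds where selected, sorted
#' by mean importance (descending). Features selected in every fold are
#' flagged.
#'
#' @param report a `classifier_report`.
#' @return data.frame: `feature`, `modality`, `n_selected`,
#'   `importance_mean`, `importance_sd`, `all_folds`.
#' @export
tally_selected_features <- function(report) {
  sel <- do.call(rbind, report$selections)
  agg <- stats::aggregate(importance ~ feature, data = sel,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = if (length(v) > 1) stats::sd(v) else NA_real_))
  out <- data.frame(feature = agg$feature,
                    n_selected = agg$importance[, "n"],
                    importance_mean = agg$importance[, "mean"],
                    importance_sd = agg$importance[, "sd"],
                    stringsAsFactors = FALSE)
  out$modality <- sel$modality[match(out$feature, sel$feature)]
  out <- out[out$n_selected >= report$config$selection_threshold, ]
  out$all_folds <- out$n_selected == report$config$n_folds
  out <- out[order(-out$importance_mean), ]
  rownames(out) <- NULL
  out[, c("feature", "modality", "n_selected", "importance_mean",
          "importance_sd", "all_folds")]
}

#' Per-fold clinical consistency of predicted subtypes
#'
#' For every fold and endpoint, fits a Cox model of predicted subtype-1
#' membership separately in the training and in the validation subjects,
#' and summarizes whether all estimable hazard ratios point the same way.
#' Cells with no events or a single predicted class are reported as NA.
#'
#' @param report a `classifier_report`.
#' @param outcomes_list named list of outcome tables (one per endpoint).
#' @return data.frame (`fold`, `endpoint`, `subset`, `hr`, `p`,
#'   `n_events`) with attribute `"direction_consistent"`.
#' @export
validate_clinical_consistency <- function(report, outcomes_list) {
  rows <- list()
  for (f in seq_along(report$predicted)) {
    for (ep in names(outcomes_list)) {
      oc <- outcomes_list[[ep]]
      for (subset in c("train", "validation")) {
        pred <- report$predicted[[f]][[if (subset == "train") "train" else "validation"]]
        oci <- oc[oc$subject %in% names(pred), ]
        hr <- p <- NA_real_
        ne <- sum(oci$event)
        if (ne > 0 && length(unique(pred)) > 1) {
          fit <- tryCatch(cox_fit(oci, pred, comparison = 1),
                          error = function(e) NULL)
          if (!is.null(fit)) { hr <- fit$hr; p <- fit$p }
        }
        rows[[length(rows) + 1]] <- data.frame(
          fold = f, endpoint = ep, subset = subset, hr = hr, p = p,
          n_events = ne, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  est <- out$hr[!is.na(out$hr)]
  attr(out, "direction_consistent") <-
    length(est) > 0 && (all(est > 1) || all(est < 1))
  out
}
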