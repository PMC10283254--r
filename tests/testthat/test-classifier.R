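make_classifier_data <- function(n = 60, f = 30, separable = TRUE, seed = 1) {
  set.seed(seed)
  labels <- setNames(rep(1:2, length.out = n), sprintf("S%03d", 1:n))
  x <- matrix(rnorm(n * f), n, f,
              dimnames = list(names(labels), sprintf("F%03d", 1:f)))
  if (separable)
    x[, 1] <- ifelse(labels == 1, 1, -1) + rnorm(n, 0, 0.05)
  list(x = x, labels = labels)
}

test_that("a perfectly separating feature is selected in every fold with AUC 1", {
  d <- make_classifier_data(separable = TRUE, seed = 2)
  rep <- run_cv_classifier(d$x, d$labels,
                           classifier_config(screen_size = 5, seed = 11))
  expect_equal(rep$mean_auc, 1)
  tally <- tally_selected_features(rep)
  expect_true("F001" %in% tally$feature[tally$n_selected == 5])
  expect_true(tally$all_folds[tally$feature == "F001"])
  expect_identical(tally$feature[1], "F001")  # top importance
})

test_that("permuted labels give chance-level AUC", {
  aucs <- vapply(1:10, function(seed) {
    d <- make_classifier_data(n = 80, separable = FALSE, seed = seed)
    run_cv_classifier(d$x, d$labels,
                      classifier_config(screen_size = 10,
                                        seed = seed))$mean_auc
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("the report is bit-reproducible under a fixed master seed", {
  d <- make_classifier_data(seed = 5)
  cfg <- classifier_config(screen_size = 8, seed = 77)
  r1 <- run_cv_classifier(d$x, d$labels, cfg)
  r2 <- run_cv_classifier(d$x, d$labels, cfg)
  expect_identical(r1$fold_auc, r2$fold_auc)
  expect_identical(tally_selected_features(r1), tally_selected_features(r2))
  expect_identical(r1$fold, r2$fold)
})

test_that("the selection tally applies the >= 3-of-5 threshold", {
  d <- make_classifier_data(seed = 6)
  rep <- run_cv_classifier(d$x, d$labels,
                           classifier_config(screen_size = 6, seed = 3))
  # fabricate controlled selections to pin the threshold behaviour
  rep$selections <- list(
    data.frame(feature = c("A", "B", "C"), importance = 1, modality = "protein",
               fold = 1),
    data.frame(feature = c("A", "B"), importance = 1, modality = "protein",
               fold = 2),
    data.frame(feature = c("A", "B"), importance = 1, modality = "protein",
               fold = 3),
    data.frame(feature = "A", importance = 1, modality = "protein", fold = 4),
    data.frame(feature = "A", importance = 1, modality = "protein", fold = 5))
  tally <- tally_selected_features(rep)
  expect_setequal(tally$feature, c("A", "B"))       # C selected twice: out
  expect_identical(tally$n_selected[tally$feature == "A"], 5)
  expect_true(tally$all_folds[tally$feature == "A"])
  expect_false(tally$all_folds[tally$feature == "B"])
})

test_that("feature screening cannot leak validation-only signal", {
  n <- 100
  labels <- setNames(rep(1:2, length.out = n), sprintf("S%03d", 1:n))
  set.seed(12)
  x <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(names(labels), sprintf("F%03d", 1:40)))
  fold <- rep(1:5, length.out = n)
  # plant the label signal only in the rows of fold 1: any fold trained
  # without leakage never sees a generalizable pattern
  x[fold == 1, 1] <- ifelse(labels[fold == 1] == 1, 2, -2)
  cfg <- classifier_config(screen_size = 10, seed = 8,
                           fold_assignment = fold)
  rep <- run_cv_classifier(x, labels, cfg)
  expect_gt(rep$mean_auc, 0.35)
  expect_lt(rep$mean_auc, 0.65)
})

test_that("clinical consistency reports per-fold HRs and handles empty cells", {
  cfg <- sim_config(n_subjects = 100,
                    n_features = c(protein = 60, mirna = 30, torna = 5),
                    effect_size = 3, seed = 41)
  study <- simulate_study(cfg)
  x <- standardize_features(study$blocks$protein)$values
  rep <- run_cv_classifier(x, study$true_labels,
                           classifier_config(screen_size = 15, seed = 21))
  outcomes <- list(
    transplant_free = derive_transplant_free_outcome(study$clinical,
                                                     study$events))
  cc <- suppressMessages(validate_clinical_consistency(rep, outcomes))
  expect_identical(nrow(cc), 10L)  # 5 folds x 1 endpoint x train/validation
  expect_true(all(cc$hr[cc$subset == "train"] > 1, na.rm = TRUE))
  # no-event subset: HR becomes NA but the run continues
  oc0 <- outcomes$transplant_free
  oc0$event <- FALSE
  cc0 <- validate_clinical_consistency(rep, list(transplant_free = oc0))
  expect_true(all(is.na(cc0$hr)))
})

test_that("the rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    scores <- rnorm(60)
    pos <- runif(60) < 0.4
    if (sum(pos) == 0 || sum(pos) == 60) next
    expect_equal(snfsubtypes:::auc_rank(scores, pos),
                 as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

# all permutations of 1..k (tiny k), enumerated recursively
gtools_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(j, matrix(ifelse(sub >= j, sub + 1, sub), nrow(sub)))
  }))
}

test_that("label matching maximizes agreement on the confusion matrix", {
  # permuted labels map back exactly
  set.seed(15)
  for (k in 2:5) {
    ref <- sample(1:k, 60, TRUE)
    perm <- sample(1:k)
    shuffled <- perm[ref]
    expect_identical(match_labels(shuffled, ref), ref)
  }
  # brute-force oracle over all pairings on random labelings
  for (i in 1:10) {
    k <- sample(2:4, 1)
    a <- sample(1:k, 40, TRUE); b <- sample(1:k, 40, TRUE)
    best <- max(apply(gtools_perms(k), 1, function(p) mean(p[a] == b)))
    expect_equal(mean(match_labels(a, b) == b), best, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected", {
  d <- make_classifier_data(seed = 3)
  one <- d$labels; one[] <- 1L
  expect_error(run_cv_classifier(d$x, one, classifier_config()), "2 classes")
  few <- d$labels; few[5:60] <- 2L
  expect_error(run_cv_classifier(d$x, few, classifier_config()),
               "minority")
  expect_error(classifier_config(selection_threshold = 6), "exceed")
  expect_error(classifier_config(num_trees = 10), ">= 100")
})
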