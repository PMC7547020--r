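# ROC/AUC against the pairwise oracle, accuracy, CV plan construction,
# leakage scanning, and cross-validated pipeline metrics.

test_that("AUC equals the brute-force pairwise oracle", {
  # degenerate endpoints
  labels <- rep(c("ACP", "NOTACP"), each = 5)
  expect_equal(roc_auc(labels, c(rep(1, 5), rep(0, 5)))$auc, 1.0)
  expect_equal(roc_auc(labels, c(rep(0, 5), rep(1, 5)))$auc, 0.0)
  # random instances incl. heavy ties
  set.seed(50)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    labels <- sample(c("ACP", "NOTACP"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("ACP", "NOTACP")
    scores <- if (i %% 2 == 0) rnorm(n) else
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    roc <- roc_auc(labels, scores)
    expect_equal(roc$auc, pairwise_auc_oracle(labels, scores),
                 tolerance = 1e-12)
    # curve invariants
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]),
                 c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
  expect_error(roc_auc(rep("ACP", 4), 1:4), "both classes")
})

test_that("accuracy is the matched fraction", {
  expect_equal(accuracy(c("ACP", "ACP"), c("ACP", "ACP")), 1.0)
  expect_equal(accuracy(c("ACP", "ACP"), c("NOTACP", "NOTACP")), 0.0)
  expect_equal(accuracy(c("ACP", "ACP", "NOTACP"),
                        c("ACP", "ACP", "ACP")), 2 / 3,
               tolerance = 1e-12)
})

test_that("CV plans partition correctly in all three scenarios", {
  set.seed(51)
  ds <- small_phantom(train_per_class = 6, test_per_class = 2,
                      images_train = 2)
  man <- ds$manifest[ds$manifest$modality == "CT", ]
  imgs <- ds$images[man$image_id]
  # add some augmented data so scenario 1 has provenance to leak
  set.seed(52)
  aug <- oversample_class_balanced(man, imgs, 20L)

  # scenario 3: patient-level folds, originals only, balanced sizes
  set.seed(53)
  p3 <- make_cv_plan(aug$manifest, k = 4, scenario = 3)
  train_orig <- aug$manifest[aug$manifest$split == "train" &
                               is.na(aug$manifest$parent_image_id), ]
  all_val <- unlist(lapply(p3$folds, `[[`, "val_ids"))
  expect_setequal(all_val, train_orig$image_id)
  expect_equal(anyDuplicated(all_val), 0L)
  fold_sizes <- table(p3$fold_of)
  expect_lte(max(fold_sizes) - min(fold_sizes), 1L)
  expect_length(scan_patient_leakage(p3, aug$manifest), 0L)
  expect_equal(nrow(scan_leakage(p3, aug$manifest)), 0L)

  # scenario 2: augmented only as descendants of training-fold originals
  set.seed(54)
  p2 <- make_cv_plan(aug$manifest, k = 4, scenario = 2, aug_target = 15L)
  expect_length(scan_patient_leakage(p2, aug$manifest), 0L)
  expect_equal(nrow(scan_leakage(p2, aug$manifest)), 0L)

  # scenario 1: image-level pooling makes provenance leakage detectable
  set.seed(55)
  p1 <- make_cv_plan(aug$manifest, k = 4, scenario = 1)
  expect_gt(nrow(scan_leakage(p1, aug$manifest)), 0L)

  # 53 patients into 5 patient-level folds -> sizes 11,11,11,10,10
  counts <- table(deal_53 <- local({
    set.seed(56)
    big <- generate_phantom_dataset(phantom_config(seed = 6,
                                                   images_train = 1))
    bm <- big$manifest[big$manifest$modality == "CT", ]
    plan <- make_cv_plan(bm, k = 5, scenario = 3)
    plan$fold_of
  }))
  expect_setequal(as.integer(counts), c(11L, 11L, 11L, 10L, 10L))

  expect_error(make_cv_plan(man, k = 50, scenario = 3), "patients")
})

test_that("cross-validated pipeline recovers strong signal and stays honest", {
  set.seed(57)
  ds <- small_phantom(train_per_class = 8, test_per_class = 2,
                      images_train = 2, signal = 40)
  man <- ds$manifest[ds$manifest$modality == "CT", ]
  imgs <- ds$images[man$image_id]
  spec <- mock_extractor(24, seed = 9)
  config <- classifier_config(epochs = 60)
  set.seed(58)
  plan <- make_cv_plan(man, k = 4, scenario = 3)
  res <- run_cv(plan, man, imgs, spec, config)
  expect_true(all(res$per_fold$valid))
  expect_gte(res$mean_auc, 0.9)
  expect_gte(res$pooled_auc, 0.9)
  # every validation image used exactly once
  expect_equal(sum(res$per_fold$n_val),
               sum(man$split == "train"))
})

test_that("image-level pooling of augmented data inflates scenario-1 metrics", {
  # moderate signal so there is headroom; paired seeds, median comparison
  deltas <- vapply(1:5, function(s) {
    ds <- small_phantom(train_per_class = 6, test_per_class = 2,
                        images_train = 2, signal = 12, seed = 60 + s)
    man <- ds$manifest[ds$manifest$modality == "CT", ]
    imgs <- ds$images[man$image_id]
    set.seed(70 + s)
    aug <- oversample_class_balanced(man, imgs, 30L)
    spec <- mock_extractor(24, seed = 9)
    config <- classifier_config(epochs = 40, seed = s)
    set.seed(80 + s)
    p1 <- make_cv_plan(aug$manifest, k = 3, scenario = 1)
    a1 <- run_cv(p1, aug$manifest, aug$images, spec, config)$pooled_auc
    set.seed(80 + s)
    p2 <- make_cv_plan(aug$manifest, k = 3, scenario = 2, aug_target = 30L)
    a2 <- run_cv(p2, aug$manifest, aug$images, spec, config)$pooled_auc
    a1 - a2
  }, numeric(1))
  expect_gte(stats::median(deltas), 0)
})
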