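# ROC/AUC and accuracy metrics, and the three five-fold cross-validation
# designs with patient-level grouping and augmentation-provenance awareness.

#' Threshold-swept ROC curve with trapezoidal AUC
#'
#' ACP is the positive class. Scores are swept from high to low; tied scores
#' are grouped into a single threshold step, which makes the trapezoidal
#' area equal to the tie-corrected Mann-Whitney probability
#' P(score_pos > score_neg) + 0.5 P(equal).
#'
#' @param labels character vector of "ACP"/"NOTACP" (both classes required).
#' @param scores numeric vector of ACP scores, same length.
#' @return a `roc_curve`: list with `thresholds` (descending unique scores,
#'   led by an `Inf` sentinel), `fpr`, `tpr` (non-decreasing, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  pos <- labels == "ACP"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present (got ", n_pos, " ACP, ",
         n_neg, " NOTACP)")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group ties: cumulative counts at the last index of each tied block
  last_of_block <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(p)[last_of_block]
  fp <- cumsum(!p)[last_of_block]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[last_of_block]),
                 fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Classification accuracy
#' @param labels true class labels.
#' @param predicted predicted class labels, same length.
#' @return fraction of matches in [0, 1].
#' @export
accuracy <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  mean(as.character(labels) == as.character(predicted))
}

#' Write ROC points to a TSV file
#' @param roc a `roc_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- cross-validation plans ------------------------------------------------

# Deal units (patients or images) into k folds round-robin after a seeded
# shuffle, stratified by class so each fold's class ratio stays within one
# unit of the global ratio. The round-robin pointer continues across classes
# so total fold sizes also stay within one unit.
deal_folds <- function(units, classes, k) {
  fold <- integer(length(units))
  names(fold) <- units
  ptr <- 0L
  for (cls in unique(classes)) {
    members <- units[classes == cls]
    members <- members[sample.int(length(members))]
    fold[members] <- (ptr + seq_along(members) - 1L) %% k + 1L
    ptr <- (ptr + length(members)) %% k
  }
  fold
}

#' Build a five-fold cross-validation plan
#'
#' Three designs differing in what is split and when augmentation happens:
#' \describe{
#'   \item{scenario 1}{originals and already-augmented images are pooled,
#'     then folds are cut at the image level. Augmented descendants of one
#'     original can land on both sides of a fold boundary - this is the
#'     leakage-prone design kept for comparison.}
#'   \item{scenario 2}{folds are cut at the patient level over original
#'     images only; each fold's training portion is then oversampled to
#'     `aug_target` per class per modality, so augmented images only ever
#'     descend from training-fold originals.}
#'   \item{scenario 3}{patient-level folds over original images, no
#'     augmentation.}
#' }
#'
#' @param manifest dataset manifest (train split is used; augmented records
#'   are recognized by a non-missing `parent_image_id`).
#' @param k number of folds (default 5).
#' @param scenario 1, 2 or 3.
#' @param aug_target scenario 2 per-class per-modality training target
#'   (NULL skips oversampling in the plan; [run_cv()] then augments).
#' @return a `split_plan`: list with `scenario`, `k`, `fold_of` (named
#'   integer vector: image_id or patient_id -> fold) and `folds` (list of
#'   per-fold lists with `val_ids` and `train_ids` of image ids).
#' @export
make_cv_plan <- function(manifest, k = 5L, scenario = 2L,
                         aug_target = NULL) {
  check_manifest(manifest)
  stopifnot(scenario %in% 1:3, k >= 2L)
  train <- manifest[manifest$split == "train", , drop = FALSE]
  is_aug <- !is.na(train$parent_image_id)
  if (scenario == 1L) {
    pool <- train  # originals + augmented, split at image level
    fold_of <- deal_folds(pool$image_id, pool$class, k)
    folds <- lapply(seq_len(k), function(f) {
      val <- pool$image_id[fold_of[pool$image_id] == f]
      list(val_ids = val, train_ids = setdiff(pool$image_id, val))
    })
  } else {
    originals <- train[!is_aug, , drop = FALSE]
    pat_class <- tapply(originals$class, originals$patient_id,
                        function(x) x[1])
    patients <- names(pat_class)
    if (k > length(patients))
      stop("k = ", k, " exceeds the ", length(patients),
           " available patients")
    fold_of <- deal_folds(patients, as.character(pat_class), k)
    folds <- lapply(seq_len(k), function(f) {
      val_pat <- patients[fold_of[patients] == f]
      val <- originals$image_id[originals$patient_id %in% val_pat]
      list(val_ids = val, train_ids = setdiff(originals$image_id, val))
    })
  }
  structure(list(scenario = as.integer(scenario), k = as.integer(k),
                 fold_of = fold_of, folds = folds,
                 aug_target = aug_target),
            class = "split_plan")
}

#' Scan a plan for augmentation-provenance leakage
#'
#' Returns every validation image that shares an original ancestor with a
#' training image of the same fold. Scenario 2/3 plans must always come back
#' empty; scenario 1 with augmented data generally does not.
#'
#' @param plan a `split_plan`.
#' @param manifest the manifest the plan was built from.
#' @return data.frame with columns `fold`, `val_id`, `shared_parent` (zero
#'   rows when clean).
#' @export
scan_leakage <- function(plan, manifest) {
  root_of <- manifest$image_id
  names(root_of) <- manifest$image_id
  parent <- stats::setNames(manifest$parent_image_id, manifest$image_id)
  for (id in manifest$image_id) {  # one hop: parents are always originals
    p <- parent[[id]]
    if (!is.na(p)) root_of[[id]] <- p
  }
  hits <- list()
  for (f in seq_along(plan$folds)) {
    val_roots <- root_of[plan$folds[[f]]$val_ids]
    train_roots <- root_of[plan$folds[[f]]$train_ids]
    shared <- intersect(val_roots, train_roots)
    if (length(shared)) {
      bad <- plan$folds[[f]]$val_ids[val_roots %in% shared]
      hits[[length(hits) + 1L]] <- data.frame(
        fold = f, val_id = bad,
        shared_parent = root_of[bad], stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(fold = integer(), val_id = character(),
                  shared_parent = character(), stringsAsFactors = FALSE)
}

#' Scan a plan for patient-level leakage
#'
#' @param plan a `split_plan`.
#' @param manifest the manifest the plan was built from.
#' @return character vector of patients appearing in both the training and
#'   validation side of any fold (empty for scenarios 2-3 by construction).
#' @export
scan_patient_leakage <- function(plan, manifest) {
  pat <- stats::setNames(manifest$patient_id, manifest$image_id)
  bad <- character()
  for (f in seq_along(plan$folds)) {
    both <- intersect(unique(pat[plan$folds[[f]]$val_ids]),
                      unique(pat[plan$folds[[f]]$train_ids]))
    bad <- union(bad, both)
  }
  bad
}

#' Run cross-validation for one genome
#'
#' Trains one classifier per fold on the fold's training images and scores
#' its validation images. For scenario 2 the training portion is oversampled
#' per fold (pipeline-augmented) before embedding, so synthetic images never
#' descend from validation originals.
#'
#' @param plan a `split_plan` from [make_cv_plan()].
#' @param manifest dataset manifest.
#' @param images named list of image matrices.
#' @param spec extractor spec used to embed.
#' @param config a [classifier_config()] (one shared config; per-fold seeds
#'   are derived from it).
#' @param standardize standardize embeddings feature-wise by each fold's
#'   training statistics before fitting (recommended: keeps first-order
#'   optimizers well-conditioned on raw pooled-statistic embeddings).
#' @return list with `per_fold` data.frame (fold, n_val, auc, accuracy,
#'   valid), `mean_auc`, `mean_accuracy` (over valid folds), and pooled
#'   metrics `pooled_auc`, `pooled_accuracy` computed from all validation
#'   predictions at once.
#' @export
run_cv <- function(plan, manifest, images, spec, config,
                   standardize = TRUE) {
  per_fold <- data.frame(fold = seq_len(plan$k), n_val = 0L,
                         auc = NA_real_, accuracy = NA_real_,
                         valid = FALSE)
  pooled_scores <- numeric(); pooled_pred <- character()
  pooled_labels <- character()
  for (f in seq_len(plan$k)) {
    tr_ids <- plan$folds[[f]]$train_ids
    va_ids <- plan$folds[[f]]$val_ids
    tr_man <- manifest[manifest$image_id %in% tr_ids, , drop = FALSE]
    va_man <- manifest[manifest$image_id %in% va_ids, , drop = FALSE]
    tr_imgs <- images[tr_man$image_id]
    if (plan$scenario == 2L && !is.null(plan$aug_target)) {
      tr_man$split <- "train"  # oversampler works on the train split
      aug <- with_seed(derive_seed(config$seed, paste0("cvfold", f)),
                      oversample_class_balanced(tr_man, tr_imgs,
                                                plan$aug_target))
      tr_man <- aug$manifest
      tr_imgs <- aug$images
    }
    per_fold$n_val[f] <- nrow(va_man)
    if (length(unique(va_man$class)) < 2L ||
        length(unique(tr_man$class)) < 2L)
      next  # invalid fold: a single class ends up on one side
    emb_tr <- embed_dataset(tr_imgs, tr_man, spec)
    emb_va <- embed_dataset(images[va_man$image_id], va_man, spec)
    if (standardize) {
      mu <- colMeans(emb_tr)
      sd_ <- apply(emb_tr, 2L, stats::sd)
      sd_[!is.finite(sd_) | sd_ < 1e-9] <- 1
      emb_tr <- sweep(sweep(emb_tr, 2L, mu), 2L, sd_, "/")
      emb_va <- sweep(sweep(emb_va, 2L, mu), 2L, sd_, "/")
    }
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, paste0("train-fold", f))
    clf <- train_classifier(emb_tr, tr_man$class, fold_config)
    scores <- predict_scores(clf, emb_va)
    pred <- predict_classes(clf, emb_va)
    per_fold$auc[f] <- roc_auc(va_man$class, scores)$auc
    per_fold$accuracy[f] <- accuracy(va_man$class, pred)
    per_fold$valid[f] <- TRUE
    pooled_scores <- c(pooled_scores, scores)
    pooled_pred <- c(pooled_pred, pred)
    pooled_labels <- c(pooled_labels, va_man$class)
  }
  ok <- per_fold$valid
  list(per_fold = per_fold,
       mean_auc = mean(per_fold$auc[ok]),
       mean_accuracy = mean(per_fold$accuracy[ok]),
       pooled_auc = if (length(unique(pooled_labels)) == 2L)
         roc_auc(pooled_labels, pooled_scores)$auc else NA_real_,
       pooled_accuracy = accuracy(pooled_labels, pooled_pred))
}
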