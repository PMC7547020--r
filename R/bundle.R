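# Data bundle: resolves a genome's train/test dataset variants ("original",
# "aug100", ... ) and its network choice into embedding matrices + labels,
# with lazy caching, so the GA's fitness function is a pure lookup + train +
# score.

#' Build a data bundle over a dataset
#'
#' Precomputes (lazily, with caching) the augmented dataset variants and
#' their embeddings under each requested extractor. Augmented variants are
#' generated once under seeds derived from `seed`, so every genome sharing a
#' variant sees identical data regardless of evaluation order.
#'
#' Embeddings are optionally standardized feature-wise: training-variant
#' means and standard deviations are applied to both train and test rows
#' (constant features pass through), which keeps gradient descent
#' well-conditioned across optimizers and learning rates.
#'
#' @param manifest dataset manifest of original images.
#' @param images named list of image matrices.
#' @param extractors named list of `extractor_spec` objects; names must
#'   cover every label of the search space's network axis that will be
#'   evaluated.
#' @param train_targets named integer vector mapping augmented train-variant
#'   labels to per-class per-modality targets (default
#'   `c(aug100 = 100, aug1000 = 1000)`).
#' @param test_reps named integer vector mapping augmented test-variant
#'   labels to replications per test image (default
#'   `c(aug10 = 10, aug100 = 100)`).
#' @param modality restrict the bundle to "CT", "MRI", or "both"
#'   (patient-wise CT-MRI concatenation).
#' @param standardize standardize embeddings by training statistics.
#' @param seed seed for the augmentation randomness.
#' @return a `data_bundle` with a `$resolve(space, genome)` method returning
#'   `list(train = list(x, y), test = list(x, y))`.
#' @export
make_data_bundle <- function(manifest, images, extractors,
                             train_targets = c(aug100 = 100L,
                                               aug1000 = 1000L),
                             test_reps = c(aug10 = 10L, aug100 = 100L),
                             modality = c("CT", "MRI", "both"),
                             standardize = TRUE, seed = 1L) {
  modality <- match.arg(modality)
  check_manifest(manifest)
  if (modality != "both") {
    keep <- manifest$modality == modality
    manifest <- manifest[keep, , drop = FALSE]
    images <- images[manifest$image_id]
  }
  variant_cache <- new.env(parent = emptyenv())
  emb_cache <- new.env(parent = emptyenv())

  get_variant <- function(which, label) {   # which: "train" | "test"
    key <- paste(which, label, sep = "/")
    if (!is.null(variant_cache[[key]])) return(variant_cache[[key]])
    ds <- if (label == "original") {
      list(manifest = manifest, images = images)
    } else if (which == "train") {
      target <- train_targets[[label]]
      if (is.null(target)) stop("unknown train dataset variant: ", label)
      with_seed(derive_seed(seed, key),
                oversample_class_balanced(manifest, images, target))
    } else {
      reps <- test_reps[[label]]
      if (is.null(reps)) stop("unknown test dataset variant: ", label)
      with_seed(derive_seed(seed, key),
                augment_test_set(manifest, images, reps))
    }
    split_name <- which
    m <- ds$manifest[ds$manifest$split == split_name, , drop = FALSE]
    ds <- list(manifest = m, images = ds$images[m$image_id])
    variant_cache[[key]] <- ds
    ds
  }

  get_embeddings <- function(which, label, network) {
    key <- paste(which, label, network, sep = "/")
    if (!is.null(emb_cache[[key]])) return(emb_cache[[key]])
    spec <- extractors[[network]]
    if (is.null(spec)) stop("no extractor registered for network: ", network)
    ds <- get_variant(which, label)
    if (modality == "both") {
      m <- ds$manifest
      emb_ct <- embed_dataset(ds$images, m[m$modality == "CT", ], spec)
      emb_mri <- embed_dataset(ds$images, m[m$modality == "MRI", ], spec)
      x <- concat_ct_mri(emb_ct, emb_mri, m)
      y <- attr(x, "class")
    } else {
      x <- embed_dataset(ds$images, ds$manifest, spec)
      y <- ds$manifest$class
    }
    out <- list(x = x, y = y)
    emb_cache[[key]] <- out
    out
  }

  resolve <- function(space, g) {
    network <- g$choices[["network"]]
    tr <- get_embeddings("train", g$choices[["train_dataset"]], network)
    te <- get_embeddings("test", g$choices[["test_dataset"]], network)
    if (standardize) {
      mu <- colMeans(tr$x)
      sd_ <- apply(tr$x, 2L, stats::sd)
      sd_[!is.finite(sd_) | sd_ < 1e-9] <- 1
      tr <- list(x = sweep(sweep(tr$x, 2L, mu), 2L, sd_, "/"), y = tr$y)
      te <- list(x = sweep(sweep(te$x, 2L, mu), 2L, sd_, "/"), y = te$y)
    }
    list(train = tr, test = te)
  }
  structure(list(resolve = resolve, modality = modality),
            class = "data_bundle")
}

#' Fitness function over genomes backed by a data bundle
#'
#' Returns the closure the GA evaluates: resolve the genome's data, train
#' the classification head per the genome's hyperparameters, score the test
#' variant, and report AUC (the fitness) plus accuracy. The training seed is
#' drawn from the RNG stream active at call time, which
#' [evaluate_individual()] scopes to the individual's derived seed - making
#' fitness a pure function of (genome, bundle, eval seed).
#'
#' @param space the `search_space` genomes come from.
#' @param bundle a `data_bundle`.
#' @return function(genome) -> list(auc, accuracy).
#' @export
bundle_fitness <- function(space, bundle) {
  force(space); force(bundle)
  function(g) {
    data <- bundle$resolve(space, g)
    config <- config_from_genome(
      space, g, seed = sample.int(2147483646L, 1L))
    clf <- train_classifier(data$train$x, data$train$y, config)
    scores <- predict_scores(clf, data$test$x)
    list(auc = roc_auc(data$test$y, scores)$auc,
         accuracy = accuracy(data$test$y, predict_classes(clf, data$test$x)))
  }
}

#' Mock extractors for every network of a space
#'
#' Assigns each label of the space's network axis its own deterministic mock
#' extractor (distinct seeds, hence distinct projections), so the network
#' axis is meaningful in end-to-end tests without any pretrained weights.
#'
#' @param space a `search_space` with a `network` axis.
#' @param dim mock embedding dimension.
#' @param seed base seed.
#' @return named list of `extractor_spec`s keyed by network label.
#' @export
mock_extractors_for_space <- function(space, dim = 32L, seed = 1L) {
  labels <- axis_labels(space, "network")
  stats::setNames(lapply(seq_along(labels), function(i)
    mock_extractor(dim, derive_seed(seed, labels[i]), name = labels[i])),
    labels)
}
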