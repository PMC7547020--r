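# Shared fixtures: small phantom datasets, toy search spaces, and the
# standard embed-train-score protocol used across tests.

# Small patient-structured phantom (both modalities), cheap enough to
# regenerate per test.
small_phantom <- function(signal = 40, confound = 0, seed = 1,
                          train_per_class = 8, test_per_class = 6,
                          images_train = 2) {
  generate_phantom_dataset(phantom_config(
    train_acp = train_per_class, train_notacp = train_per_class,
    test_acp = test_per_class, test_notacp = test_per_class,
    images_train = images_train,
    signal_amplitude = signal, confound_amplitude = confound, seed = seed))
}

# Tiny 6-axis / 4-variant toy space for GA tests (4096 genomes).
toy_space <- function(n_axes = 6L, n_variants = 4L) {
  search_space(lapply(seq_len(n_axes), function(i)
    feature_axis(paste0("a", i),
                 stats::setNames(as.list(seq_len(n_variants)),
                                 paste0("v", seq_len(n_variants))))))
}

# Feature-wise standardization by training statistics.
standardize_pair <- function(X, Xt) {
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[!is.finite(s) | s < 1e-9] <- 1
  list(train = sweep(sweep(X, 2L, mu), 2L, s, "/"),
       test = sweep(sweep(Xt, 2L, mu), 2L, s, "/"))
}

# End-to-end protocol: CT-only baseline classifier on mock embeddings,
# returns test AUC and accuracy.
phantom_pipeline_auc <- function(ds, seed = 1, obfuscate_roi = NULL,
                                 dim = 32L, config = NULL) {
  if (!is.null(obfuscate_roi))
    ds$images <- obfuscate_dataset(ds$images, obfuscate_roi)
  m <- ds$manifest[ds$manifest$modality == "CT", ]
  tr <- m[m$split == "train", ]
  te <- m[m$split == "test", ]
  spec <- mock_extractor(dim, seed = 11)
  std <- standardize_pair(embed_dataset(ds$images, tr, spec),
                          embed_dataset(ds$images, te, spec))
  config <- config %||% classifier_config(seed = seed)
  clf <- train_classifier(std$train, tr$class, config)
  list(auc = roc_auc(te$class, predict_scores(clf, std$test))$auc,
       accuracy = accuracy(te$class, predict_classes(clf, std$test)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genome with some axes pinned.
random_genome_with <- function(space, ...) {
  g <- random_genome(space)
  pins <- list(...)
  for (ax in names(pins)) g$choices[[ax]] <- pins[[ax]]
  genome(space, g$choices)
}

# Logical ROI mask matrix at full image size (wraps the internal builder).
mask_matrix_for_tests <- function(mask, n = 299L) {
  gaclassify:::mask_matrix(mask, n, n)
}

# Independent AUC oracle: tie-corrected pairwise comparison probability
# (Mann-Whitney), brute force over all positive/negative pairs.
pairwise_auc_oracle <- function(labels, scores) {
  pos <- scores[labels == "ACP"]
  neg <- scores[labels == "NOTACP"]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
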