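# Feature-extraction layer: registry of the twelve pretrained ImageNet
# networks used for transfer learning, a deterministic locality-sensitive
# mock extractor, an adapter for externally computed embedding tables, and
# CT-MRI embedding concatenation.

#' Registry of pretrained embedding networks
#'
#' The twelve publicly available ImageNet-trained classification networks
#' whose penultimate-layer activations serve as image signatures, with their
#' fixed output vector lengths. The networks themselves are not bundled:
#' vectors computed externally are read through
#' [external_extractor()]; the mock backend stands in during testing.
#'
#' @return data.frame with columns `name` and `output_dim`.
#' @export
#' @examples
#' extractor_registry()
extractor_registry <- function() {
  data.frame(
    name = c("Inception V1", "Inception V2", "Inception V3",
             "Inception ResNet V2",
             "ResNet V1 50", "ResNet V1 101", "ResNet V1 152",
             "ResNet V2 50", "ResNet V2 101", "ResNet V2 152",
             "NASNet-A Large", "PNASNet-5 Large"),
    output_dim = c(1024L, 1024L, 2048L, 1536L,
                   2048L, 2048L, 2048L,
                   2048L, 2048L, 2048L,
                   4032L, 4320L),
    stringsAsFactors = FALSE)
}

#' Look up a registered extractor by name
#' @param name network name as listed in [extractor_registry()].
#' @return one-row data.frame with `name` and `output_dim`.
#' @export
extractor_info <- function(name) {
  reg <- extractor_registry()
  i <- match(name, reg$name)
  if (is.na(i))
    stop("unknown extractor '", name, "'; valid names: ",
         paste(reg$name, collapse = ", "))
  reg[i, , drop = FALSE]
}

#' Pooled grid statistics of an image
#'
#' Partitions the image into a `cells` x `cells` grid and computes the mean
#' and standard deviation of each cell, giving 2 * cells^2 locality-sensitive
#' raw features. This is the pre-projection stage of the mock extractor;
#' exposed so locality properties can be checked directly.
#'
#' @param img numeric matrix.
#' @param cells grid cells per side (default 8).
#' @return numeric vector of length 2 * cells^2: all cell means (row-major),
#'   then all cell standard deviations.
#' @export
grid_cell_stats <- function(img, cells = 8L) {
  nr <- nrow(img); nc <- ncol(img)
  rb <- floor(seq(0, nr, length.out = cells + 1L))
  cb <- floor(seq(0, nc, length.out = cells + 1L))
  mu <- matrix(0, cells, cells)
  sd_ <- matrix(0, cells, cells)
  for (i in seq_len(cells)) {
    for (j in seq_len(cells)) {
      block <- img[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      mu[i, j] <- mean(block)
      v <- stats::var(as.vector(block))
      sd_[i, j] <- if (is.na(v)) 0 else sqrt(v)
    }
  }
  c(as.vector(t(mu)), as.vector(t(sd_)))
}

#' Deterministic mock feature extractor
#'
#' A stand-in backend for the pretrained networks: per-cell mean and
#' standard deviation on an 8x8 grid (128 raw features) followed by a fixed,
#' seed-derived Gaussian linear map to `dim` outputs. Deterministic given
#' (dim, seed); locality-sensitive, so obfuscating a region genuinely
#' removes the information the extractor saw there.
#'
#' @param dim output vector length (>= 2).
#' @param seed integer seed for the projection matrix.
#' @param name spec name (defaults to "mock<dim>").
#' @return an `extractor_spec` with backend "mock".
#' @export
mock_extractor <- function(dim = 64L, seed = 1L,
                           name = paste0("mock", dim)) {
  stopifnot(dim >= 2L)
  proj <- with_seed(derive_seed(seed, "mock-projection"),
                   matrix(stats::rnorm(128L * dim), 128L, dim) / sqrt(128))
  structure(list(name = name, output_dim = as.integer(dim),
                 backend = "mock", projection = proj),
            class = "extractor_spec")
}

#' External embedding-table extractor
#'
#' Adapter for vectors computed outside this package by a real pretrained
#' network. The table is delimited text whose first column is `image_id` and
#' whose remaining columns are the embedding vector; every image id to be
#' embedded must be present.
#'
#' @param path path to the delimited table (header row required).
#' @param name extractor name; must match [extractor_registry()] if
#'   `check_registry` is TRUE.
#' @param sep field separator (default tab).
#' @param check_registry validate name and dimension against the registry.
#' @return an `extractor_spec` with backend "external".
#' @export
external_extractor <- function(path, name, sep = "\t",
                               check_registry = TRUE) {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("embedding table needs image_id + vector columns")
  ids <- as.character(tab[[1L]])
  vecs <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vecs) <- "double"
  if (any(!is.finite(vecs))) stop("non-finite embedding values in ", path)
  if (check_registry) {
    info <- extractor_info(name)
    if (ncol(vecs) != info$output_dim)
      stop("table dimension ", ncol(vecs), " does not match registry (",
           info$output_dim, ") for ", name)
  }
  rownames(vecs) <- ids
  structure(list(name = name, output_dim = ncol(vecs),
                 backend = "external", table = vecs),
            class = "extractor_spec")
}

# Embed one image with a spec.
embed_image <- function(img, spec) {
  switch(spec$backend,
    mock = as.vector(grid_cell_stats(img, 8L) %*% spec$projection),
    stop("backend '", spec$backend,
         "' cannot embed raw images; use embed_dataset with a manifest"))
}

#' Embed every image of a dataset
#'
#' Produces one embedding row per manifest record, in manifest order, with
#' rows named by image_id. The mock backend computes embeddings from pixel
#' data; the external backend looks rows up in its precomputed table and
#' fails loudly on a missing image id.
#'
#' @param images named list of image matrices keyed by image_id (may be NULL
#'   for the external backend).
#' @param manifest dataset manifest; defines row order.
#' @param spec an `extractor_spec`.
#' @return numeric matrix, `nrow(manifest)` x `spec$output_dim`.
#' @export
embed_dataset <- function(images, manifest, spec) {
  stopifnot(inherits(spec, "extractor_spec"))
  ids <- manifest$image_id
  if (spec$backend == "external") {
    missing <- setdiff(ids, rownames(spec$table))
    if (length(missing))
      stop("embedding table missing image_id: ", missing[1])
    out <- spec$table[ids, , drop = FALSE]
  } else {
    out <- matrix(0, length(ids), spec$output_dim,
                  dimnames = list(ids, NULL))
    for (i in seq_along(ids)) {
      img <- images[[ids[i]]]
      if (is.null(img)) stop("no image for manifest record: ", ids[i])
      out[i, ] <- embed_image(img, spec)
    }
  }
  out
}

#' Concatenate CT and MRI embeddings patient-wise
#'
#' Pairs each patient's CT and MRI rows and concatenates the vectors along
#' the feature axis, giving one row per (patient, within-patient index) pair
#' labelled by patient id. Within a patient and modality, rows are matched
#' by index after sorting image ids, so the single-test-image case pairs the
#' two representative images and the multi-image training case pairs images
#' positionally; a patient present in only one modality is an error.
#'
#' @param emb_ct embedding matrix for CT images (rownames = image ids).
#' @param emb_mri embedding matrix for MRI images.
#' @param manifest manifest covering all embedded images.
#' @return matrix with `dim_ct + dim_mri` columns; rownames
#'   `patient_id#index`; attribute `patient_id` and `class` vectors aligned
#'   to rows.
#' @export
concat_ct_mri <- function(emb_ct, emb_mri, manifest) {
  info <- manifest[, c("image_id", "patient_id", "class", "modality")]
  by_pat <- function(emb, mod) {
    ids <- rownames(emb)
    sub <- info[match(ids, info$image_id), , drop = FALSE]
    if (any(is.na(sub$image_id)))
      stop("embedding row not present in manifest: ",
           ids[is.na(sub$image_id)][1])
    if (any(sub$modality != mod))
      stop("embedding matrix for ", mod, " contains other-modality rows")
    split(data.frame(image_id = sub$image_id, class = sub$class,
                     stringsAsFactors = FALSE),
          sub$patient_id)
  }
  ct <- by_pat(emb_ct, "CT")
  mri <- by_pat(emb_mri, "MRI")
  only_ct <- setdiff(names(ct), names(mri))
  only_mri <- setdiff(names(mri), names(ct))
  if (length(only_ct) || length(only_mri))
    stop("patient(s) present in one modality only: ",
         paste(c(only_ct, only_mri), collapse = ", "))
  patients <- sort(names(ct))
  if (length(patients) == 0L) stop("zero patients in common")
  rows <- list(); labels <- character(); classes <- character()
  pats <- character()
  for (p in patients) {
    ids_ct <- sort(ct[[p]]$image_id)
    ids_mri <- sort(mri[[p]]$image_id)
    n <- min(length(ids_ct), length(ids_mri))
    for (k in seq_len(n)) {
      rows[[length(rows) + 1L]] <-
        c(emb_ct[ids_ct[k], ], emb_mri[ids_mri[k], ])
      labels <- c(labels, sprintf("%s#%d", p, k))
      classes <- c(classes, ct[[p]]$class[match(ids_ct[k], ct[[p]]$image_id)])
      pats <- c(pats, p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- labels
  attr(out, "patient_id") <- pats
  attr(out, "class") <- classes
  out
}
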