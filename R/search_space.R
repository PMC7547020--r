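# Declarative categorical hyperparameter search space: named axes, each with a
# fixed list of labelled variants, and genomes (one variant chosen per axis).

#' Construct a model-feature axis
#'
#' An axis is one categorical hyperparameter dimension of the search space,
#' e.g. the learning rate or the pretrained feature-extraction network. Each
#' variant pairs a unique label with an arbitrary immutable payload (a number,
#' an optimizer spec, a dataset-variant tag).
#'
#' @param name axis identifier (character scalar).
#' @param variants named list: label -> payload. Labels must be unique and
#'   non-empty.
#' @return an object of class `feature_axis`.
#' @export
#' @examples
#' feature_axis("learning_rate", list(`0.01` = 0.01, `0.1` = 0.1))
feature_axis <- function(name, variants) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(variants) || length(variants) == 0L)
    stop("axis '", name, "' needs at least one variant")
  labels <- names(variants)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("axis '", name, "': all variants must be labelled")
  if (anyDuplicated(labels))
    stop("axis '", name, "': duplicate variant labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(list(name = name, variants = variants), class = "feature_axis")
}

#' Construct a search space from an ordered list of axes
#'
#' @param axes list of [feature_axis()] objects with unique names; order is
#'   preserved and significant for serialization.
#' @return an object of class `search_space`.
#' @export
search_space <- function(axes) {
  stopifnot(is.list(axes), length(axes) >= 1L)
  ok <- vapply(axes, inherits, logical(1), "feature_axis")
  if (!all(ok)) stop("all elements must be feature_axis objects")
  nms <- vapply(axes, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate axis names: ", paste(nms[duplicated(nms)], collapse = ", "))
  names(axes) <- nms
  structure(list(axes = axes), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  sizes <- vapply(x$axes, function(a) length(a$variants), integer(1))
  cat("search_space with", length(x$axes), "axes,",
      format(cardinality(x), big.mark = ","), "genomes\n")
  for (a in x$axes)
    cat(sprintf("  %-22s (%d) %s\n", a$name, length(a$variants),
                paste(utils::head(names(a$variants), 6L), collapse = ", ")))
  invisible(x)
}

#' Axis labels of a search space
#' @param space a `search_space`.
#' @param axis axis name.
#' @return character vector of variant labels.
#' @export
axis_labels <- function(space, axis) {
  stopifnot(inherits(space, "search_space"))
  ax <- space$axes[[axis]]
  if (is.null(ax)) stop("unknown axis: ", axis)
  names(ax$variants)
}

#' Resolve a genome choice to its payload
#' @param space a `search_space`.
#' @param genome a `genome`.
#' @param axis axis name.
#' @return the payload stored for the chosen variant.
#' @export
genome_payload <- function(space, genome, axis) {
  ax <- space$axes[[axis]]
  if (is.null(ax)) stop("unknown axis: ", axis)
  ax$variants[[genome$choices[[axis]]]]
}

#' The nine optimizer families explored during architecture search
#' @return character vector of optimizer family names.
#' @export
optimizer_base_names <- function() {
  c("Gradient Descent", "Adam", "Adagrad", "Adadelta", "RMSProp",
    "Momentum", "FTRL", "Proximal Adagrad", "Proximal Adadelta")
}

#' Expand optimizer families into concrete optimizer specs
#'
#' Non-proximal families yield a single spec. The proximal families each
#' yield four: no regularization, l1, l2, and l1+l2 (the proximal operator is
#' what differs), so the nine families expand to fifteen optimizer variants.
#'
#' @param base_names character vector of family names (see
#'   [optimizer_base_names()]).
#' @return named list of optimizer specs, each a list with fields `name`,
#'   `family`, `proximal_l1`, `proximal_l2`.
#' @export
#' @examples
#' length(expand_optimizer_variants(optimizer_base_names()))  # 15
expand_optimizer_variants <- function(base_names) {
  known <- optimizer_base_names()
  bad <- setdiff(base_names, known)
  if (length(bad))
    stop("unknown optimizer name(s): ", paste(bad, collapse = ", "))
  proximal <- c("Proximal Adagrad", "Proximal Adadelta")
  specs <- list()
  for (nm in base_names) {
    if (nm %in% proximal) {
      for (reg in c("none", "l1", "l2", "l1l2")) {
        label <- if (reg == "none") nm else paste0(nm, " (", reg, ")")
        specs[[label]] <- list(name = label, family = nm,
                               proximal_l1 = reg %in% c("l1", "l1l2"),
                               proximal_l2 = reg %in% c("l2", "l1l2"))
      }
    } else {
      specs[[nm]] <- list(name = nm, family = nm,
                          proximal_l1 = FALSE, proximal_l2 = FALSE)
    }
  }
  specs
}

#' Build the first-phase ten-axis search space
#'
#' The default space searched during the first optimization phase: 12
#' pretrained embedding networks x 7 learning rates x 3 batch sizes x 5 epoch
#' counts x 15 optimizers x 7 activations x 4 dropout keep probabilities x 4
#' regularization modes x 3 training-dataset variants x 3 test-dataset
#' variants = 19,051,200 configurations.
#'
#' Where the protocol leaves a set underdetermined the defaults are: batch
#' sizes {5, 20, 120} (three values spanning the explored 2..120 range),
#' epochs {10, 25, 50, 100, 125} (100 is the baseline duration), and identity
#' (linear) as the seventh activation alongside softmax, softplus, softsign,
#' ReLU, leaky ReLU and log-softmax. All three are overridable.
#'
#' @param batch_sizes integer vector for the batch-size axis.
#' @param epochs integer vector for the epoch axis.
#' @param activations character vector for the activation axis.
#' @return a `search_space` with 10 axes.
#' @export
#' @examples
#' cardinality(build_phase1_space())  # 19,051,200
build_phase1_space <- function(batch_sizes = c(5L, 20L, 120L),
                               epochs = c(10L, 25L, 50L, 100L, 125L),
                               activations = c("softmax", "softplus",
                                               "softsign", "relu",
                                               "leaky_relu", "log_softmax",
                                               "identity")) {
  registry <- extractor_registry()
  networks <- stats::setNames(
    lapply(registry$name, function(n) list(network = n)), registry$name)
  lr <- c(0.00001, 0.0001, 0.001, 0.005, 0.01, 0.05, 0.1)
  lr_variants <- stats::setNames(as.list(lr), format(lr, scientific = FALSE,
                                                     trim = TRUE, drop0trailing = TRUE))
  keep <- c(0.25, 0.5, 0.75, 1.0)
  optimizers <- expand_optimizer_variants(optimizer_base_names())
  reg_modes <- list(none = list(mode = "none"),
                    l1 = list(mode = "l1"),
                    l2 = list(mode = "l2"),
                    l1l2 = list(mode = "l1l2"))
  search_space(list(
    feature_axis("network", networks),
    feature_axis("learning_rate", lr_variants),
    feature_axis("batch_size",
                 stats::setNames(as.list(as.integer(batch_sizes)),
                                 as.character(batch_sizes))),
    feature_axis("epochs",
                 stats::setNames(as.list(as.integer(epochs)),
                                 as.character(epochs))),
    feature_axis("optimizer", optimizers),
    feature_axis("activation",
                 stats::setNames(as.list(activations), activations)),
    feature_axis("dropout_keep",
                 stats::setNames(as.list(keep), as.character(keep))),
    feature_axis("regularization", reg_modes),
    feature_axis("train_dataset",
                 list(original = "original", aug100 = "aug100",
                      aug1000 = "aug1000")),
    feature_axis("test_dataset",
                 list(original = "original", aug10 = "aug10",
                      aug100 = "aug100"))
  ))
}

#' Number of distinct genomes in a search space
#'
#' Exact product of the per-axis variant counts. Returned as a double; the
#' spaces in scope are far below 2^53 so the product is exact.
#'
#' @param space a `search_space`.
#' @return the number of genomes.
#' @export
cardinality <- function(space) {
  stopifnot(inherits(space, "search_space"))
  prod(vapply(space$axes, function(a) as.double(length(a$variants)),
              double(1)))
}

#' Sample a genome uniformly at random
#'
#' Each axis choice is drawn uniformly and independently from that axis's
#' variants using R's current random stream.
#'
#' @param space a `search_space`.
#' @return a `genome`.
#' @export
random_genome <- function(space) {
  stopifnot(inherits(space, "search_space"))
  choices <- lapply(space$axes, function(a) {
    labs <- names(a$variants)
    labs[[sample.int(length(labs), 1L)]]
  })
  genome(space, choices)
}

#' Construct and validate a genome
#'
#' @param space the `search_space` the genome belongs to.
#' @param choices named list or character vector, axis name -> variant label,
#'   exactly one entry per axis.
#' @return an object of class `genome`.
#' @export
genome <- function(space, choices) {
  stopifnot(inherits(space, "search_space"))
  choices <- as.list(choices)
  axis_names <- names(space$axes)
  missing <- setdiff(axis_names, names(choices))
  extra <- setdiff(names(choices), axis_names)
  if (length(missing)) stop("genome missing axes: ",
                            paste(missing, collapse = ", "))
  if (length(extra)) stop("genome has unknown axes: ",
                          paste(extra, collapse = ", "))
  choices <- choices[axis_names]  # canonical axis order
  for (nm in axis_names) {
    lab <- choices[[nm]]
    if (!is.character(lab) || length(lab) != 1L ||
        !(lab %in% names(space$axes[[nm]]$variants)))
      stop("axis '", nm, "': unknown variant label '", lab, "'")
  }
  structure(list(choices = choices), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", genome_key(x), "\n")
  invisible(x)
}

#' Canonical flat serialization of a genome
#'
#' `axis=label` pairs joined by `;` in axis order. Stable across sessions;
#' used as the cache / seed-derivation key and in GA logs.
#'
#' @param g a `genome`.
#' @return character scalar.
#' @export
genome_key <- function(g) {
  stopifnot(inherits(g, "genome"))
  paste(sprintf("%s=%s", names(g$choices), unlist(g$choices)), collapse = ";")
}

#' Parse a genome from its flat serialization
#'
#' Inverse of [genome_key()]; validates against the space.
#'
#' @param space a `search_space`.
#' @param key string produced by [genome_key()].
#' @return a `genome`.
#' @export
parse_genome <- function(space, key) {
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed genome key near: ", parts[bad][1])
  genome(space, stats::setNames(lapply(kv, `[[`, 2L),
                                vapply(kv, `[[`, character(1), 1L)))
}

#' Restrict a search space to subsets of variant labels
#'
#' Produces the smaller second-phase space: each axis named in `keep` is
#' shrunk to the listed labels (original order preserved); unnamed axes pass
#' through unchanged.
#'
#' @param space parent `search_space`.
#' @param keep named list, axis name -> character vector of labels to keep.
#' @return a `search_space` whose cardinality divides / is bounded by the
#'   parent's.
#' @export
restrict_space <- function(space, keep) {
  stopifnot(inherits(space, "search_space"), is.list(keep))
  bad_axes <- setdiff(names(keep), names(space$axes))
  if (length(bad_axes)) stop("unknown axis in keep: ",
                             paste(bad_axes, collapse = ", "))
  axes <- lapply(space$axes, function(a) {
    sel <- keep[[a$name]]
    if (is.null(sel)) return(a)
    unknown <- setdiff(sel, names(a$variants))
    if (length(unknown))
      stop("axis '", a$name, "': unknown label(s) in keep: ",
           paste(unknown, collapse = ", "))
    feature_axis(a$name, a$variants[names(a$variants) %in% sel])
  })
  search_space(unname(axes))
}

#' Enumerate every genome of a small space
#'
#' Brute-force cross product; guarded to spaces with at most `limit` genomes.
#' Intended for exhaustive oracles in tests and for defining hidden-optimum
#' fitness landscapes.
#'
#' @param space a `search_space`.
#' @param limit refuse to enumerate more than this many genomes.
#' @return list of `genome` objects.
#' @export
enumerate_genomes <- function(space, limit = 1e5) {
  n <- cardinality(space)
  if (n > limit) stop("space too large to enumerate: ", n)
  grids <- lapply(space$axes, function(a) names(a$variants))
  grid <- expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) genome(space, as.list(grid[i, ])))
}
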