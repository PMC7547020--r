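# Single fully-connected classification head: y_hat = g(w x + b), trained
# with categorical cross-entropy under genome-selected dropout, activation,
# regularization, optimizer, learning rate, batch size and epoch count.
#
# Class encoding is fixed throughout: column 1 = NOTACP, column 2 = ACP; ACP
# is the positive class whose score feeds the ROC.

CLASS_LEVELS <- c("NOTACP", "ACP")

activation_names <- function() {
  c("softmax", "softplus", "softsign", "relu", "leaky_relu",
    "log_softmax", "identity")
}

# Numerically safe row softmax.
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

row_log_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  z - log(rowSums(exp(z)))
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

# Elementwise activation and its derivative; softmax/log_softmax are handled
# as identity here (their normalization is applied downstream).
act_elementwise <- function(z, activation) {
  switch(activation,
    softmax = , log_softmax = , identity = z,
    relu = pmax(z, 0),
    leaky_relu = ifelse(z > 0, z, 0.2 * z),
    softplus = softplus(z),
    softsign = z / (1 + abs(z)),
    stop("unknown activation: ", activation))
}

act_derivative <- function(z, activation) {
  switch(activation,
    softmax = , log_softmax = , identity = array(1, dim(z)),
    relu = (z > 0) * 1,
    leaky_relu = ifelse(z > 0, 1, 0.2),
    softplus = 1 / (1 + exp(-pmin(pmax(z, -30), 30))),
    softsign = 1 / (1 + abs(z))^2,
    stop("unknown activation: ", activation))
}

#' Forward pass of the classification head
#'
#' Computes `g(x w + b)`. For `softmax` the rows are probability vectors; for
#' `log_softmax`, log-probabilities; the remaining activations return
#' unnormalized scores whose ACP column is used for ranking.
#'
#' @param x numeric matrix (n x d) of embedding rows (a single vector is
#'   promoted to one row).
#' @param w weight matrix (d x 2).
#' @param b bias vector (length 2).
#' @param activation one of softmax, softplus, softsign, relu, leaky_relu,
#'   log_softmax, identity.
#' @return n x 2 matrix of class scores, columns (NOTACP, ACP).
#' @export
forward <- function(x, w, b, activation = "softmax") {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(w))
    stop("dimension mismatch: x has ", ncol(x), " features, w expects ",
         nrow(w))
  stopifnot(ncol(w) == 2L, length(b) == 2L)
  z <- x %*% w + matrix(b, nrow(x), 2L, byrow = TRUE)
  out <- switch(activation,
    softmax = row_softmax(z),
    log_softmax = row_log_softmax(z),
    act_elementwise(z, activation))
  colnames(out) <- CLASS_LEVELS
  out
}

#' Categorical cross-entropy loss with optional weight penalties
#'
#' Mean cross-entropy over the batch (the two-class case reduces to the
#' Bernoulli form), with predicted probabilities clipped to
#' [1e-12, 1 - 1e-12], plus `coefficient * sum(|w|)` for l1 and/or
#' `coefficient * sum(w^2)` for l2 penalties.
#'
#' @param y one-hot label matrix (n x 2).
#' @param yhat predicted probability matrix (n x 2); rows must sum to 1
#'   within 1e-6.
#' @param w weight matrix entering the penalty (optional, required when
#'   `reg_mode != "none"`).
#' @param reg_mode "none", "l1", "l2" or "l1l2".
#' @param l1 l1 penalty coefficient.
#' @param l2 l2 penalty coefficient.
#' @return scalar loss, always >= 0.
#' @export
cross_entropy_loss <- function(y, yhat, w = NULL, reg_mode = "none",
                               l1 = 0.01, l2 = 0.01) {
  stopifnot(is.matrix(y), is.matrix(yhat), all(dim(y) == dim(yhat)))
  if (any(abs(rowSums(yhat) - 1) > 1e-6))
    stop("yhat rows are not probability vectors")
  if (any(yhat < -1e-9) || any(yhat > 1 + 1e-9))
    stop("yhat outside [0, 1]")
  eps <- 1e-12
  p <- pmin(pmax(yhat, eps), 1 - eps)
  ce <- -mean(rowSums(y * log(p)))
  pen <- 0
  if (reg_mode %in% c("l1", "l1l2")) pen <- pen + l1 * sum(abs(w))
  if (reg_mode %in% c("l2", "l1l2")) pen <- pen + l2 * sum(w^2)
  ce + pen
}

#' Inverted dropout
#'
#' In the training phase each feature is zeroed independently with
#' probability `1 - keep_prob` and survivors are scaled by `1 / keep_prob`
#' so activations keep their expectation; in the eval phase (and whenever
#' `keep_prob = 1`) the input passes through unchanged.
#'
#' @param x numeric matrix or vector.
#' @param keep_prob probability in (0, 1] that a feature survives.
#' @param phase "train" or "eval".
#' @return x with dropout applied.
#' @export
apply_dropout <- function(x, keep_prob, phase = c("train", "eval")) {
  phase <- match.arg(phase)
  stopifnot(keep_prob > 0, keep_prob <= 1)
  if (phase == "eval" || keep_prob == 1) return(x)
  mask <- stats::runif(length(x)) < keep_prob
  x * mask / keep_prob
}

#' Classifier training configuration
#'
#' Bundles every hyperparameter of the classification head. The defaults
#' reproduce the baseline protocol: softmax activation, plain gradient
#' descent, learning rate 0.01, whole-batch training (`batch_size = NULL`),
#' 100 epochs, no dropout, no regularization.
#'
#' @param activation activation function name.
#' @param keep_prob dropout keep probability in (0, 1].
#' @param reg_mode "none", "l1", "l2" or "l1l2" (loss-penalty path).
#' @param reg_l1,reg_l2 penalty coefficients.
#' @param optimizer an optimizer spec (list with `family`, `proximal_l1`,
#'   `proximal_l2`) or a family name string.
#' @param learning_rate positive step size.
#' @param batch_size mini-batch size; NULL means whole-batch.
#' @param epochs training epochs (>= 1).
#' @param seed integer seed controlling shuffling, dropout and any random
#'   init.
#' @param init "zero" (default, deterministic convex start) or "gaussian".
#' @return a `classifier_config` object.
#' @export
classifier_config <- function(activation = "softmax", keep_prob = 1,
                              reg_mode = "none", reg_l1 = 0.01,
                              reg_l2 = 0.01, optimizer = "Gradient Descent",
                              learning_rate = 0.01, batch_size = NULL,
                              epochs = 100L, seed = 1L, init = "zero") {
  stopifnot(activation %in% activation_names(),
            keep_prob > 0, keep_prob <= 1,
            reg_mode %in% c("none", "l1", "l2", "l1l2"),
            learning_rate > 0, epochs >= 1,
            is.null(batch_size) || batch_size >= 1,
            init %in% c("zero", "gaussian"))
  if (is.character(optimizer))
    optimizer <- list(name = optimizer, family = optimizer,
                      proximal_l1 = FALSE, proximal_l2 = FALSE)
  structure(list(activation = activation, keep_prob = keep_prob,
                 reg_mode = reg_mode, reg_l1 = reg_l1, reg_l2 = reg_l2,
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init = init),
            class = "classifier_config")
}

#' Build a classifier config from a genome
#'
#' Resolves the genome's axis payloads (activation, dropout keep,
#' regularization, optimizer, learning rate, batch size, epochs) into a
#' [classifier_config()].
#'
#' @param space the `search_space` the genome belongs to.
#' @param g a `genome`.
#' @param seed training seed.
#' @return a `classifier_config`.
#' @export
config_from_genome <- function(space, g, seed = 1L) {
  reg <- genome_payload(space, g, "regularization")
  classifier_config(
    activation = genome_payload(space, g, "activation"),
    keep_prob = genome_payload(space, g, "dropout_keep"),
    reg_mode = reg$mode,
    optimizer = genome_payload(space, g, "optimizer"),
    learning_rate = genome_payload(space, g, "learning_rate"),
    batch_size = genome_payload(space, g, "batch_size"),
    epochs = genome_payload(space, g, "epochs"),
    seed = seed)
}

## ---- optimizer catalogue ---------------------------------------------------

# Canonical first-order update rules with fixed default hyperparameters
# (momentum 0.9; Adam beta1 0.9, beta2 0.999, eps 1e-8; RMSProp decay 0.9;
# Adadelta rho 0.95; Adagrad initial accumulator 0.1; FTRL beta 1, power
# -0.5). Proximal variants apply the base adaptive step, then per-coordinate
# soft-thresholding (l1) and/or shrinkage (l2) with default strength 0.001.
# Returned object keeps per-parameter state in its own environment.
make_optimizer <- function(spec, lr, prox_strength = 0.001) {
  family <- spec$family
  st <- new.env(parent = emptyenv())
  get_state <- function(key, init) {
    if (is.null(st[[key]])) st[[key]] <- init
    st[[key]]
  }
  prox <- function(p, eff_lr) {
    if (isTRUE(spec$proximal_l1)) {
      thr <- eff_lr * prox_strength
      p <- sign(p) * pmax(abs(p) - thr, 0)
    }
    if (isTRUE(spec$proximal_l2))
      p <- p / (1 + eff_lr * prox_strength)
    p
  }
  step <- switch(family,
    "Gradient Descent" = function(name, p, g) p - lr * g,
    "Momentum" = function(name, p, g) {
      v <- 0.9 * get_state(paste0(name, ".v"), 0 * g) + g
      st[[paste0(name, ".v")]] <- v
      p - lr * v
    },
    "Adam" = function(name, p, g) {
      t <- get_state(paste0(name, ".t"), 0) + 1
      m <- 0.9 * get_state(paste0(name, ".m"), 0 * g) + 0.1 * g
      v <- 0.999 * get_state(paste0(name, ".v"), 0 * g) + 0.001 * g^2
      st[[paste0(name, ".t")]] <- t
      st[[paste0(name, ".m")]] <- m
      st[[paste0(name, ".v")]] <- v
      mhat <- m / (1 - 0.9^t)
      vhat <- v / (1 - 0.999^t)
      p - lr * mhat / (sqrt(vhat) + 1e-8)
    },
    "RMSProp" = function(name, p, g) {
      v <- 0.9 * get_state(paste0(name, ".v"), 0 * g) + 0.1 * g^2
      st[[paste0(name, ".v")]] <- v
      p - lr * g / (sqrt(v) + 1e-8)
    },
    "Adagrad" = ,
    "Proximal Adagrad" = function(name, p, g) {
      acc <- get_state(paste0(name, ".acc"), 0 * g + 0.1) + g^2
      st[[paste0(name, ".acc")]] <- acc
      eff <- lr / sqrt(acc)
      prox(p - eff * g, eff)
    },
    "Adadelta" = ,
    "Proximal Adadelta" = function(name, p, g) {
      rho <- 0.95; eps <- 1e-8
      eg <- rho * get_state(paste0(name, ".eg"), 0 * g) + (1 - rho) * g^2
      edx <- get_state(paste0(name, ".edx"), 0 * g)
      dx <- -sqrt(edx + eps) / sqrt(eg + eps) * g
      st[[paste0(name, ".eg")]] <- eg
      st[[paste0(name, ".edx")]] <- rho * edx + (1 - rho) * dx^2
      eff <- lr * sqrt(edx + eps) / sqrt(eg + eps)
      prox(p + lr * dx, eff)
    },
    "FTRL" = function(name, p, g) {
      n <- get_state(paste0(name, ".n"), 0 * g)
      z <- get_state(paste0(name, ".z"), 0 * g)
      sigma <- (sqrt(n + g^2) - sqrt(n)) / lr
      z <- z + g - sigma * p
      n <- n + g^2
      st[[paste0(name, ".n")]] <- n
      st[[paste0(name, ".z")]] <- z
      -z / ((1 + sqrt(n)) / lr)
    },
    stop("unknown optimizer family: ", family))
  list(step = step)
}

## ---- training --------------------------------------------------------------

one_hot <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  y <- matrix(0, length(labels), 2L, dimnames = list(NULL, CLASS_LEVELS))
  y[cbind(seq_along(labels), match(labels, CLASS_LEVELS))] <- 1
  y
}

# Probabilities and gradient wrt (w, b) for one batch, sharing the chain-rule
# path: a = g(z) elementwise (identity for softmax/log_softmax), p =
# softmax(a), dL/dz = (p - y) * g'(z) / n.
batch_grad <- function(x, y, w, b, config) {
  z <- x %*% w + matrix(b, nrow(x), 2L, byrow = TRUE)
  a <- act_elementwise(z, config$activation)
  p <- row_softmax(a)
  dz <- (p - y) * act_derivative(z, config$activation) / nrow(x)
  gw <- crossprod(x, dz)
  gb <- colSums(dz)
  if (config$reg_mode %in% c("l1", "l1l2"))
    gw <- gw + config$reg_l1 * sign(w)
  if (config$reg_mode %in% c("l2", "l1l2"))
    gw <- gw + 2 * config$reg_l2 * w
  list(p = p, gw = gw, gb = gb)
}

# Training-path probabilities (no dropout, eval phase) for loss tracing.
trace_probs <- function(x, w, b, activation) {
  z <- x %*% w + matrix(b, nrow(x), 2L, byrow = TRUE)
  row_softmax(act_elementwise(z, activation))
}

#' Train the classification head
#'
#' Gradient-based minimization of the cross-entropy loss over the embedding
#' rows. Parameters start at zero (configurable seeded-Gaussian init);
#' mini-batches are formed by a seeded shuffle each epoch (a batch size
#' equal to or above the dataset size reproduces whole-batch training);
#' updates follow the configured optimizer's canonical rule. The entire run
#' is deterministic for a fixed config.
#'
#' @param embeddings numeric matrix, one row per example.
#' @param labels character vector of "ACP" / "NOTACP", one per row.
#' @param config a [classifier_config()].
#' @return a `trained_classifier`: list with `w`, `b`, `config`,
#'   `loss_trace` (per-epoch full-data loss including penalty).
#' @export
train_classifier <- function(embeddings, labels, config) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.matrix(embeddings)
  y <- one_hot(labels)
  if (nrow(x) != nrow(y)) stop("embeddings/labels length mismatch")
  if (any(colSums(y) == 0)) stop("need at least one example per class")
  d <- ncol(x)
  n <- nrow(x)
  bs <- min(config$batch_size %||% n, n)
  with_seed(config$seed, {
    if (config$init == "gaussian") {
      w <- matrix(stats::rnorm(d * 2L, sd = 0.01), d, 2L)
      b <- stats::rnorm(2L, sd = 0.01)
    } else {
      w <- matrix(0, d, 2L)
      b <- c(0, 0)
    }
    opt <- make_optimizer(config$optimizer, config$learning_rate)
    loss_trace <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        take <- idx[start:min(start + bs - 1L, n)]
        xb <- apply_dropout(x[take, , drop = FALSE], config$keep_prob,
                            "train")
        gr <- batch_grad(xb, y[take, , drop = FALSE], w, b, config)
        w <- opt$step("w", w, gr$gw)
        b <- opt$step("b", b, gr$gb)
      }
      p_full <- trace_probs(x, w, b, config$activation)
      loss_trace[epoch] <- cross_entropy_loss(
        y, p_full, w, config$reg_mode, config$reg_l1, config$reg_l2)
      if (!is.finite(loss_trace[epoch]) || any(!is.finite(w)) ||
          any(!is.finite(b)))
        stop("non-finite loss at epoch ", epoch, " (optimizer ",
             config$optimizer$name, ", lr ", config$learning_rate, ")")
    }
    structure(list(w = w, b = b, config = config, loss_trace = loss_trace),
              class = "trained_classifier")
  })
}

#' Positive-class scores for ranking and thresholding
#'
#' Eval-phase forward pass (dropout off). Softmax / log-softmax activations
#' yield calibrated (log-)probabilities of the ACP class; the remaining
#' activations yield monotone unnormalized ACP scores, which is all the ROC
#' needs.
#'
#' @param clf a `trained_classifier`.
#' @param embeddings numeric matrix of rows to score.
#' @return numeric vector, one ACP score per row.
#' @export
predict_scores <- function(clf, embeddings) {
  stopifnot(inherits(clf, "trained_classifier"))
  out <- forward(as.matrix(embeddings), clf$w, clf$b,
                 clf$config$activation)
  as.vector(out[, "ACP"])
}

#' Hard class predictions
#'
#' Argmax over the two class scores; for softmax this is the 0.5 probability
#' threshold.
#'
#' @param clf a `trained_classifier`.
#' @param embeddings numeric matrix of rows to classify.
#' @return character vector of "ACP"/"NOTACP".
#' @export
predict_classes <- function(clf, embeddings) {
  out <- forward(as.matrix(embeddings), clf$w, clf$b,
                 clf$config$activation)
  CLASS_LEVELS[max.col(out, ties.method = "first")]
}
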