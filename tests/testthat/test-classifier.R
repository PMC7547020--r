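# Forward pass, loss, dropout, gradients, optimizers and training behavior.

test_that("forward pass honors the activation contracts", {
  w <- matrix(0, 4, 2); b <- c(0, 0)
  x <- matrix(rnorm(8), 2, 4)
  out <- forward(x, w, b, "softmax")
  expect_equal(unname(out), matrix(0.5, 2, 2))
  # relu zeroes negative preactivations
  w2 <- matrix(c(-1, 0, 0, 0, 0, -1, 0, 0), 4, 2)
  xpos <- matrix(abs(rnorm(8)) + 1, 2, 4)
  expect_true(all(forward(xpos, w2, b, "relu") == 0))
  # softmax rows normalize
  set.seed(30)
  wr <- matrix(rnorm(8), 4, 2); br <- rnorm(2)
  p <- forward(matrix(rnorm(40), 10, 4), wr, br, "softmax")
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # log_softmax exponentiates to softmax
  lp <- forward(matrix(1:8, 2, 4), wr, br, "log_softmax")
  sp <- forward(matrix(1:8, 2, 4), wr, br, "softmax")
  expect_equal(exp(lp), sp, tolerance = 1e-12)
  expect_error(forward(matrix(0, 1, 3), w, b), "dimension mismatch")
})

test_that("cross-entropy matches closed forms and adds penalties", {
  y <- matrix(c(0, 1), 1, 2)
  expect_equal(cross_entropy_loss(y, matrix(c(0, 1), 1, 2)), 0,
               tolerance = 1e-9)
  expect_equal(cross_entropy_loss(y, matrix(c(0.5, 0.5), 1, 2)), log(2),
               tolerance = 1e-12)
  # hand-computed batch of 2
  y2 <- rbind(c(0, 1), c(1, 0))
  yhat2 <- rbind(c(0.1, 0.9), c(0.6, 0.4))
  expect_equal(cross_entropy_loss(y2, yhat2),
               -0.5 * (log(0.9) + log(0.6)), tolerance = 1e-12)
  # penalties
  w <- matrix(c(1, -2, 0.5, 3), 2, 2)
  base <- cross_entropy_loss(y2, yhat2)
  expect_equal(cross_entropy_loss(y2, yhat2, w, "l1", l1 = 0.01),
               base + 0.01 * sum(abs(w)), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(y2, yhat2, w, "l2", l2 = 0.05),
               base + 0.05 * sum(w^2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(y2, yhat2, w, "l1l2"),
               base + 0.01 * sum(abs(w)) + 0.01 * sum(w^2),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(y2, rbind(c(0.5, 0.9), c(0.5, 0.5))),
               "probability")
})

test_that("dropout scales survivors and is identity when it must be", {
  x <- matrix(rnorm(100), 10, 10)
  expect_identical(apply_dropout(x, 1.0, "train"), x)
  expect_identical(apply_dropout(x, 0.3, "eval"), x)
  set.seed(31)
  big <- matrix(1, 1, 1e5)
  out <- apply_dropout(big, 0.5, "train")
  zero_frac <- mean(out == 0)
  # binomial 3-sigma band around 0.5 for n = 1e5
  expect_lt(abs(zero_frac - 0.5), 3 * sqrt(0.25 / 1e5))
  # survivors scaled by 1/keep so the mean is preserved in expectation
  expect_equal(mean(out), 1, tolerance = 0.02)
  expect_true(all(out[out != 0] == 2))
})

test_that("analytic gradients match central finite differences", {
  set.seed(32)
  x <- matrix(rnorm(20), 5, 4)
  y <- gaclassify:::one_hot(sample(c("ACP", "NOTACP"), 5, replace = TRUE,
                                   prob = c(0.5, 0.5)))
  for (act in c("softmax", "relu", "softplus", "softsign", "leaky_relu",
                "identity")) {
    for (reg in c("none", "l1l2")) {
      config <- classifier_config(activation = act, reg_mode = reg,
                                  reg_l1 = 0.02, reg_l2 = 0.03)
      w <- matrix(rnorm(8, sd = 0.5), 4, 2); b <- rnorm(2, sd = 0.1)
      loss_at <- function(w, b) {
        p <- gaclassify:::trace_probs(x, w, b, act)
        cross_entropy_loss(y, p, w, reg, 0.02, 0.03)
      }
      gr <- gaclassify:::batch_grad(x, y, w, b, config)
      h <- 1e-6
      num_gw <- w
      for (i in seq_along(w)) {
        wp <- w; wm <- w
        wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
        num_gw[i] <- (loss_at(wp, b) - loss_at(wm, b)) / (2 * h)
      }
      num_gb <- vapply(1:2, function(i) {
        bp <- b; bm <- b
        bp[i] <- bp[i] + h; bm[i] <- bm[i] - h
        (loss_at(w, bp) - loss_at(w, bm)) / (2 * h)
      }, numeric(1))
      scale <- pmax(abs(num_gw), 1e-3)
      expect_lt(max(abs(gr$gw - num_gw) / scale), 1e-5)
      expect_lt(max(abs(gr$gb - num_gb) / pmax(abs(num_gb), 1e-3)), 1e-5)
    }
  }
})

test_that("training separates separable data and is seed-deterministic", {
  set.seed(33)
  n <- 30
  # guaranteed margin on the first coordinate, noise on the rest
  x <- cbind(c(runif(n, 0.5, 1.5), runif(n, -1.5, -0.5)),
             matrix(rnorm(2 * n * 3, sd = 0.5), 2 * n, 3))
  labels <- rep(c("ACP", "NOTACP"), each = n)
  config <- classifier_config()  # SGD, lr 0.01, 100 epochs, whole batch
  clf <- train_classifier(x, labels, config)
  expect_equal(accuracy(labels, predict_classes(clf, x)), 1.0)
  expect_length(clf$loss_trace, 100L)
  # loss non-increasing for whole-batch SGD on the convex problem
  expect_true(all(diff(clf$loss_trace) <= 1e-9))
  # determinism
  clf2 <- train_classifier(x, labels, config)
  expect_identical(clf$w, clf2$w)
  expect_identical(clf$b, clf2$b)
  # regularization mode none ignores coefficients
  c1 <- classifier_config(reg_l1 = 0.5, reg_l2 = 0.9)
  expect_identical(train_classifier(x, labels, c1)$w, clf$w)
})

test_that("every optimizer family trains the toy problem without blowing up", {
  set.seed(34)
  n <- 20
  x <- rbind(matrix(rnorm(n * 3, mean = 1.5), n, 3),
             matrix(rnorm(n * 3, mean = -1.5), n, 3))
  labels <- rep(c("ACP", "NOTACP"), each = n)
  for (spec in expand_optimizer_variants(optimizer_base_names())) {
    config <- classifier_config(optimizer = spec, learning_rate = 0.05,
                                epochs = 50, batch_size = 10)
    clf <- train_classifier(x, labels, config)
    expect_true(all(is.finite(clf$w)), info = spec$name)
    acc <- accuracy(labels, predict_classes(clf, x))
    expect_gte(acc, 0.9)
  }
})

test_that("prediction scores are monotone and robust to extreme inputs", {
  set.seed(35)
  x <- matrix(rnorm(12), 3, 4)
  clf <- train_classifier(rbind(x, -x),
                          rep(c("ACP", "NOTACP"), each = 3),
                          classifier_config(epochs = 5))
  # w = 0 init, zero epochs of movement -> equal scores
  clf0 <- clf; clf0$w <- matrix(0, 4, 2); clf0$b <- c(0, 0)
  expect_true(all(predict_scores(clf0, x) == predict_scores(clf0, x)[1]))
  # softmax shift invariance preserves ranking
  s1 <- predict_scores(clf, x)
  clf_shift <- clf; clf_shift$b <- clf$b + 5
  expect_identical(order(predict_scores(clf_shift, x)), order(s1))
  # extreme embeddings stay finite
  extreme <- matrix(c(1e6, -1e6, 1e6, -1e6), 1, 4)
  expect_true(is.finite(predict_scores(clf, extreme)))
})
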