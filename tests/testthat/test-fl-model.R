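test_that("parameter counts follow the closed-form layer arithmetic", {
  dense_only <- model_spec(tabular_input_dim = 3L, image_input_shape = NULL,
                           tabular_units = 8L, merge_units = integer(0))
  # dense 3->8 (3*8+8) plus head 8->1 (8+1)
  expect_equal(param_count(dense_only), 32 + 9)
  spec <- tiny_model_spec()
  # conv 3x3x1x2+2; img dense (3*3*2=18 -> 3): 18*3+3; tab 2->3: 9;
  # merge (3+3)->2: 14; head 2->1: 3
  expect_equal(param_count(spec), (9 * 2 + 2) + (18 * 3 + 3) +
                 (2 * 3 + 3) + (6 * 2 + 2) + 3)
  w <- build_model(spec, seed = 1)
  expect_equal(sum(vapply(w, length, 0L)), param_count(spec))
})

test_that("initialization is seed-reproducible and seed-sensitive", {
  spec <- tiny_model_spec()
  expect_identical(build_model(spec, 7L), build_model(spec, 7L))
  expect_false(identical(build_model(spec, 7L), build_model(spec, 8L)))
})

test_that("forward pass is analytic at zero weights and batch-equivariant", {
  spec <- tiny_model_spec()
  w <- build_model(spec, 1L)
  zero <- w
  for (nm in names(zero)) zero[[nm]][] <- 0
  class(zero) <- "model_weights"
  set.seed(2)
  xtab <- matrix(rnorm(8), 4, 2)
  ximg <- array(rnorm(8 * 8 * 4), c(8, 8, 1, 4))
  p0 <- forward_pass(zero, spec, xtab, ximg)$p
  expect_equal(p0, rep(0.5, 4))
  p <- forward_pass(w, spec, xtab, ximg)$p
  expect_true(all(p > 0 & p < 1))
  # duplicated row gives duplicated output
  p2 <- forward_pass(w, spec, xtab[c(1, 1, 3, 4), ],
                     ximg[, , , c(1, 1, 3, 4), drop = FALSE])$p
  expect_equal(p2[1], p2[2])
  expect_equal(p2[1], p[1])
  expect_error(forward_pass(w, spec, xtab[, 1, drop = FALSE], ximg),
               "shape mismatch")
})

test_that("analytic gradients match finite differences on a tiny model", {
  spec <- tiny_model_spec()
  set.seed(42)
  w <- build_model(spec, 3L)
  n <- 5
  xtab <- matrix(rnorm(n * 2), n)
  ximg <- array(rnorm(8 * 8 * n), c(8, 8, 1, n))
  y <- c(1, 0, 1, 1, 0)
  ga <- unlist(loss_and_grads(w, spec, xtab, ximg, y)$grads)
  wv <- unlist(w)
  f <- function(v) {
    w2 <- w
    i <- 1
    for (nm in names(w2)) {
      k <- length(w2[[nm]]); w2[[nm]][] <- v[i:(i + k - 1)]; i <- i + k
    }
    bce_loss(y, forward_pass(w2, spec, xtab, ximg)$p)
  }
  h <- 1e-6
  idx <- sample(length(wv), 40)
  for (i in idx) {
    up <- wv; up[i] <- up[i] + h
    dn <- wv; dn[i] <- dn[i] - h
    gn <- (f(up) - f(dn)) / (2 * h)
    expect_equal(unname(ga[i]), gn, tolerance = 1e-4)
  }
})

test_that("AUC agrees with exhaustive pair counting and is rank-invariant", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(.1, .4, .35, .8)), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c(.1, .2, .7, .8)), 1.0)
  # brute-force pair oracle on random data with ties
  set.seed(9)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    y <- rbinom(n, 1, .5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 1)
    pos <- p[y == 1]; neg <- p[y == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(y, p), brute)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc_score(y, qlogis(pmin(pmax(p, .01), .99))),
                 auc_score(y, p))
  }
  expect_error(auc_score(c(1, 1), c(.2, .3)), "both classes")
})

test_that("AUC agrees with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, .4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)
    expect_equal(auc_score(y, p),
                 as.numeric(pROC::auc(response = y, predictor = p,
                                      quiet = TRUE, direction = "<",
                                      levels = c(0, 1))),
                 tolerance = 1e-12)
  }
})

test_that("compute_metrics returns F1 at 0.5 and coherent curve points", {
  m <- compute_metrics(c(1, 1, 0, 0), c(.9, .9, .1, .1))
  expect_equal(m$f1, 1.0)
  expect_equal(m$auc, 1.0)
  m2 <- compute_metrics(c(0, 0, 1, 1), c(.1, .4, .35, .8))
  expect_equal(m2$auc, 0.75)
  # ROC starts at (0,0) and ends at (1,1); both curves are monotone in
  # threshold order
  expect_equal(unlist(m2$roc[1, 1:2], use.names = FALSE), c(0, 0))
  expect_equal(unlist(m2$roc[nrow(m2$roc), 1:2], use.names = FALSE),
               c(1, 1))
  expect_true(all(diff(m2$roc$fpr) >= 0) && all(diff(m2$roc$tpr) >= 0))
  expect_true(all(m2$pr$precision >= 0 & m2$pr$precision <= 1))
  expect_warning(compute_metrics(c(1, 1), c(.2, .8)), "single-class")
})

test_that("centralized training is reproducible and learns separable data", {
  spec <- model_spec(tabular_input_dim = 2L, image_input_shape = NULL,
                     tabular_units = integer(0), merge_units = integer(0))
  set.seed(12)
  n <- 60
  x <- matrix(rnorm(n * 2), n)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  data <- list(train = list(xtab = x, ximg = NULL, y = y))
  cfg <- training_config(optimizer = "sgd", learning_rate = 0.5,
                         batch_size = Inf, seed = 4)
  fit <- train_centralized(data, spec, cfg, epochs = 5L)
  expect_true(all(diff(fit$history$train_loss) < 0))
  fit2 <- train_centralized(data, spec, cfg, epochs = 5L)
  expect_identical(fit$weights, fit2$weights)
  expect_error(train_centralized(data, spec, cfg, epochs = 0L))
  expect_error(local_train(build_model(spec, 1), spec, data$train, 0L, cfg))
})

test_that("local_train reports the local sample count and final loss", {
  spec <- model_spec(tabular_input_dim = 2L, image_input_shape = NULL,
                     tabular_units = integer(0), merge_units = integer(0))
  d <- random_tab_data(23, 2L, seed = 5)
  cfg <- training_config(learning_rate = .01, seed = 5)
  up <- local_train(build_model(spec, 1), spec, d, 2L, cfg)
  expect_equal(up$n_samples, 23L)
  expect_true(is.finite(up$local_loss))
  # evaluation returns the full metric set
  ev <- local_evaluate(up$weights, spec, d)
  expect_named(ev, c("auc", "f1", "loss", "roc", "pr", "n"),
               ignore.order = TRUE)
  expect_error(local_evaluate(up$weights, spec,
                              list(xtab = NULL, ximg = NULL, y = NULL)),
               "empty")
})
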