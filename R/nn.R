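#' Multi-input model specification
#'
#' Describes the demo mortality model: a convolutional branch for the
#' chest-image proxy and a fully connected branch for the clinical
#' variables, concatenated and passed through dense layers to a single
#' sigmoid output. Either branch can be reduced or removed (e.g.
#' `image_input_shape = NULL`, `tabular_units = integer(0)` gives a plain
#' logistic model on the tabular inputs).
#'
#' @param tabular_input_dim number of clinical inputs (demo: 3 — age,
#'   sex, pH).
#' @param image_input_shape `c(height, width, channels)` or `NULL` to
#'   disable the image branch.
#' @param conv_filters filters per conv block (3x3 kernels, ReLU, 2x2
#'   max-pool after each block).
#' @param kernel square kernel size.
#' @param image_dense units of the dense layer after flattening (0 = none).
#' @param tabular_units dense-layer widths of the tabular branch.
#' @param merge_units dense-layer widths after concatenation.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(tabular_input_dim = 3L,
                       image_input_shape = c(64L, 64L, 1L),
                       conv_filters = c(8L, 16L),
                       kernel = 3L,
                       image_dense = 16L,
                       tabular_units = c(16L, 8L),
                       merge_units = 8L) {
  stopifnot(is_count(tabular_input_dim, min = 0))
  if (!is.null(image_input_shape)) {
    stopifnot(length(image_input_shape) == 3L, all(image_input_shape >= 1))
    h <- image_input_shape[1]; w <- image_input_shape[2]
    for (f in conv_filters) {
      h <- (h - kernel + 1) %/% 2; w <- (w - kernel + 1) %/% 2
      if (h < 1 || w < 1) stop("image too small for the conv stack")
    }
  }
  if (tabular_input_dim == 0 && is.null(image_input_shape))
    stop("model needs at least one input branch")
  structure(list(tabular_input_dim = as.integer(tabular_input_dim),
                 image_input_shape = if (!is.null(image_input_shape))
                   as.integer(image_input_shape),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 image_dense = as.integer(image_dense),
                 tabular_units = as.integer(tabular_units),
                 merge_units = as.integer(merge_units)),
            class = "model_spec")
}

# ordered layer shapes derived from the spec
spec_shapes <- function(spec) {
  shapes <- list()
  img_out <- 0L
  if (!is.null(spec$image_input_shape)) {
    h <- spec$image_input_shape[1]; w <- spec$image_input_shape[2]
    cin <- spec$image_input_shape[3]
    for (i in seq_along(spec$conv_filters)) {
      f <- spec$conv_filters[i]
      shapes[[sprintf("conv%d_w", i)]] <- c(spec$kernel, spec$kernel, cin, f)
      shapes[[sprintf("conv%d_b", i)]] <- f
      h <- (h - spec$kernel + 1) %/% 2
      w <- (w - spec$kernel + 1) %/% 2
      cin <- f
    }
    flat <- h * w * cin
    if (spec$image_dense > 0) {
      shapes[["img_dense_w"]] <- c(flat, spec$image_dense)
      shapes[["img_dense_b"]] <- spec$image_dense
      img_out <- spec$image_dense
    } else img_out <- flat
  }
  tab_out <- spec$tabular_input_dim
  din <- spec$tabular_input_dim
  for (i in seq_along(spec$tabular_units)) {
    u <- spec$tabular_units[i]
    shapes[[sprintf("tab%d_w", i)]] <- c(din, u)
    shapes[[sprintf("tab%d_b", i)]] <- u
    din <- u; tab_out <- u
  }
  din <- img_out + tab_out
  for (i in seq_along(spec$merge_units)) {
    u <- spec$merge_units[i]
    shapes[[sprintf("merge%d_w", i)]] <- c(din, u)
    shapes[[sprintf("merge%d_b", i)]] <- u
    din <- u
  }
  shapes[["out_w"]] <- c(din, 1L)
  shapes[["out_b"]] <- 1L
  shapes
}

#' Number of trainable parameters implied by a spec
#' @param spec a `model_spec`.
#' @export
param_count <- function(spec)
  sum(vapply(spec_shapes(spec), prod, 0))

#' Initialize model weights
#'
#' Glorot-uniform initialization for weight tensors, zeros for biases;
#' fully reproducible given the seed.
#'
#' @param spec a `model_spec`.
#' @param seed integer seed.
#' @return named ordered list of arrays (class `model_weights`).
#' @export
build_model <- function(spec, seed = 1L) {
  shapes <- spec_shapes(spec)
  with_seed(seed, {
    w <- lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (length(sh) == 1L) return(numeric(sh))  # bias
      fan <- if (length(sh) == 4L)
        c(prod(sh[1:3]), prod(sh[c(1, 2, 4)])) else c(sh[1], sh[2])
      lim <- sqrt(6 / sum(fan))
      array(runif(prod(sh), -lim, lim), dim = sh)
    })
    names(w) <- names(shapes)
    structure(w, class = "model_weights")
  })
}

check_weights <- function(weights, spec) {
  shapes <- spec_shapes(spec)
  if (!identical(names(weights), names(shapes)))
    stop("weight tensors do not match the model spec")
  for (nm in names(shapes)) {
    got <- dim(weights[[nm]]) %||% length(weights[[nm]])
    if (!identical(as.integer(got), as.integer(shapes[[nm]])))
      stop("shape mismatch in tensor ", nm)
  }
  invisible(TRUE)
}

dense_fwd <- function(x, w, b) sweep(x %*% w, 2L, b, `+`)

#' Forward pass of the multi-input model
#'
#' @param weights `model_weights` from [build_model()].
#' @param spec the matching `model_spec`.
#' @param xtab numeric matrix `N x tabular_input_dim`.
#' @param ximg image array `(H, W, C, N)` or `NULL` if the image branch is
#'   disabled.
#' @param want_cache keep intermediate activations for backprop.
#' @return list with `p` (probabilities in (0,1)) and optionally `cache`.
#' @export
forward_pass <- function(weights, spec, xtab, ximg = NULL,
                         want_cache = FALSE) {
  check_weights(weights, spec)
  n <- if (!is.null(xtab)) nrow(xtab) else dim(ximg)[4]
  cache <- list(n = n)
  h_img <- NULL
  if (!is.null(spec$image_input_shape)) {
    if (is.null(ximg)) stop("model expects an image input")
    if (!identical(as.integer(dim(ximg)[1:3]),
                   as.integer(spec$image_input_shape)))
      stop("image batch shape mismatch")
    a <- ximg
    conv_caches <- list()
    for (i in seq_along(spec$conv_filters)) {
      cv <- .conv2d_forward(a, weights[[sprintf("conv%d_w", i)]],
                            weights[[sprintf("conv%d_b", i)]])
      z <- cv$y
      r <- z; r[r < 0] <- 0
      pl <- .maxpool2_forward(r)
      conv_caches[[i]] <- list(patches = cv$patches, z = z,
                               which = pl$which, xdim = dim(a),
                               rdim = dim(z))
      a <- pl$y
    }
    flat <- t(matrix(a, prod(dim(a)[1:3]), n))
    cache$conv <- conv_caches
    cache$flat <- flat
    cache$adim <- dim(a)
    if (spec$image_dense > 0) {
      zi <- dense_fwd(flat, weights$img_dense_w, weights$img_dense_b)
      hi <- zi; hi[hi < 0] <- 0
      cache$img_z <- zi
      h_img <- hi
    } else h_img <- flat
  }
  h_tab <- NULL
  if (spec$tabular_input_dim > 0) {
    if (is.null(xtab)) stop("model expects a tabular input")
    if (ncol(xtab) != spec$tabular_input_dim)
      stop("tabular batch shape mismatch")
    h <- xtab
    tz <- list()
    for (i in seq_along(spec$tabular_units)) {
      z <- dense_fwd(h, weights[[sprintf("tab%d_w", i)]],
                     weights[[sprintf("tab%d_b", i)]])
      tz[[i]] <- list(x = h, z = z)
      h <- z; h[h < 0] <- 0
    }
    cache$tab <- tz
    cache$xtab <- xtab
    h_tab <- h
  }
  h <- if (!is.null(h_img) && !is.null(h_tab)) cbind(h_img, h_tab)
       else h_img %||% h_tab
  cache$img_width <- if (!is.null(h_img)) ncol(h_img) else 0L
  mz <- list()
  for (i in seq_along(spec$merge_units)) {
    z <- dense_fwd(h, weights[[sprintf("merge%d_w", i)]],
                   weights[[sprintf("merge%d_b", i)]])
    mz[[i]] <- list(x = h, z = z)
    h <- z; h[h < 0] <- 0
  }
  cache$merge <- mz
  cache$head_x <- h
  logit <- dense_fwd(h, weights$out_w, weights$out_b)
  p <- plogis(as.numeric(logit))
  if (want_cache) list(p = p, cache = cache) else list(p = p)
}

# gradient of mean-BCE wrt all weights; dlogit = (p - y)/n
backward_pass <- function(weights, spec, cache, dlogit) {
  g <- setNames(vector("list", length(weights)), names(weights))
  dl <- matrix(dlogit, ncol = 1L)
  g$out_w <- t(cache$head_x) %*% dl
  g$out_b <- sum(dl)
  dh <- dl %*% t(weights$out_w)
  for (i in rev(seq_along(spec$merge_units))) {
    mc <- cache$merge[[i]]
    dz <- dh * (mc$z > 0)
    g[[sprintf("merge%d_w", i)]] <- t(mc$x) %*% dz
    g[[sprintf("merge%d_b", i)]] <- colSums(dz)
    dh <- dz %*% t(weights[[sprintf("merge%d_w", i)]])
  }
  iw <- cache$img_width
  d_img <- if (iw > 0) dh[, seq_len(iw), drop = FALSE]
  d_tab <- if (ncol(dh) > iw) dh[, (iw + 1L):ncol(dh), drop = FALSE]
  if (spec$tabular_input_dim > 0 && length(spec$tabular_units)) {
    for (i in rev(seq_along(spec$tabular_units))) {
      tc <- cache$tab[[i]]
      dz <- d_tab * (tc$z > 0)
      g[[sprintf("tab%d_w", i)]] <- t(tc$x) %*% dz
      g[[sprintf("tab%d_b", i)]] <- colSums(dz)
      d_tab <- dz %*% t(weights[[sprintf("tab%d_w", i)]])
    }
  }
  if (!is.null(spec$image_input_shape)) {
    if (spec$image_dense > 0) {
      dz <- d_img * (cache$img_z > 0)
      g$img_dense_w <- t(cache$flat) %*% dz
      g$img_dense_b <- colSums(dz)
      dflat <- dz %*% t(weights$img_dense_w)
    } else dflat <- d_img
    da <- array(t(dflat), dim = cache$adim)
    for (i in rev(seq_along(spec$conv_filters))) {
      cc <- cache$conv[[i]]
      dr <- .maxpool2_backward(cc$which, da, as.integer(cc$rdim))
      dz <- dr * (cc$z > 0)
      bw <- .conv2d_backward(cc$patches, weights[[sprintf("conv%d_w", i)]],
                             dz, as.integer(cc$xdim))
      g[[sprintf("conv%d_w", i)]] <- bw$dw
      g[[sprintf("conv%d_b", i)]] <- bw$db
      da <- bw$dx
    }
  }
  g
}

#' Loss and gradients on a batch
#' @inheritParams forward_pass
#' @param y 0/1 outcome vector.
#' @return list `loss`, `grads`, `p`.
#' @export
loss_and_grads <- function(weights, spec, xtab, ximg, y) {
  fw <- forward_pass(weights, spec, xtab, ximg, want_cache = TRUE)
  n <- length(y)
  dlogit <- (fw$p - y) / n
  list(loss = bce_loss(y, fw$p),
       grads = backward_pass(weights, spec, fw$cache, dlogit),
       p = fw$p)
}

#' Training configuration
#'
#' Defaults follow the demonstration protocol: Adam, learning rate 1e-5,
#' binary cross-entropy, 4 local epochs per federated round.
#'
#' @param optimizer `"adam"` or `"sgd"` (plain gradient descent).
#' @param learning_rate step size (> 0).
#' @param epochs_per_round local epochs per federated round (>= 1; 1 is
#'   FedSGD, > 1 FedAVG).
#' @param rounds number of federated rounds.
#' @param batch_size mini-batch size; `Inf` for full batch.
#' @param seed integer seed controlling initialization and shuffling.
#' @param average `"weighted"` (by local sample size, standard FedAVG) or
#'   `"unweighted"` site averaging.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @return object of class `training_config`.
#' @export
training_config <- function(optimizer = c("adam", "sgd"),
                            learning_rate = 1e-5,
                            epochs_per_round = 4L,
                            rounds = 10L,
                            batch_size = 32L,
                            seed = 1L,
                            average = c("weighted", "unweighted"),
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  optimizer <- match.arg(optimizer)
  average <- match.arg(average)
  stopifnot(learning_rate > 0, is_count(epochs_per_round),
            is_count(rounds), batch_size >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 loss = "bce", epochs_per_round = as.integer(epochs_per_round),
                 rounds = as.integer(rounds), batch_size = batch_size,
                 seed = as.integer(seed), average = average,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "training_config")
}

opt_init <- function(weights, config) {
  if (config$optimizer == "sgd") return(list(kind = "sgd"))
  zeros <- lapply(weights, function(w) { w[] <- 0; w })
  list(kind = "adam", m = zeros, v = zeros, t = 0L)
}

opt_step <- function(weights, grads, state, config) {
  lr <- config$learning_rate
  if (state$kind == "sgd") {
    for (nm in names(weights))
      weights[[nm]] <- weights[[nm]] - lr * grads[[nm]]
    return(list(weights = weights, state = state))
  }
  state$t <- state$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) +
                                      config$eps)
  }
  list(weights = weights, state = state)
}

subset_batch <- function(data, idx) {
  list(xtab = if (!is.null(data$xtab)) data$xtab[idx, , drop = FALSE],
       ximg = if (!is.null(data$ximg)) data$ximg[, , , idx, drop = FALSE],
       y = data$y[idx])
}

data_size <- function(data)
  if (!is.null(data$y)) length(data$y) else 0L

# shared mini-batch engine: `epochs` passes with a fresh optimizer state.
train_epochs <- function(weights, spec, data, epochs, config) {
  n <- data_size(data)
  state <- opt_init(weights, config)
  bs <- min(config$batch_size, n)
  epoch_losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- if (bs < n)
      with_seed(config$seed + 7919L * ep, sample.int(n)) else seq_len(n)
    starts <- seq(1L, n, by = bs)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + bs - 1L, n)]
      b <- subset_batch(data, idx)
      lg <- loss_and_grads(weights, spec, b$xtab, b$ximg, b$y)
      if (!is.finite(lg$loss)) stop("non-finite training loss; aborting")
      st <- opt_step(weights, lg$grads, state, config)
      weights <- st$weights; state <- st$state
      batch_losses[bi] <- lg$loss
    }
    epoch_losses[ep] <- mean(batch_losses)
  }
  list(weights = weights, epoch_losses = epoch_losses)
}

#' Site-local training step
#'
#' Runs `epochs` passes of the configured optimizer over the site's local
#' training split, starting from the broadcast weights, and returns the
#' updated weights together with the local sample count — the only
#' training payload that crosses the site boundary. Optimizer state is
#' site-local and reset at every call (i.e. every federated round).
#'
#' @param weights broadcast `model_weights`.
#' @param spec `model_spec`.
#' @param data list with `xtab`, `ximg`, `y` (the local training split).
#' @param epochs local epochs (>= 1; 1 = FedSGD).
#' @param config `training_config`.
#' @return site update: list `weights`, `n_samples`, `local_loss`; or
#'   `list(abstained = TRUE)` when the site has no local data.
#' @export
local_train <- function(weights, spec, data, epochs, config) {
  stopifnot(is_count(epochs))
  check_weights(weights, spec)
  n <- data_size(data)
  if (n == 0L) return(list(abstained = TRUE, n_samples = 0L))
  fit <- train_epochs(weights, spec, data, epochs, config)
  list(weights = fit$weights, n_samples = n,
       local_loss = fit$epoch_losses[epochs])
}

#' Site-local evaluation
#' @inheritParams local_train
#' @param data list with `xtab`, `ximg`, `y` (a held-out split).
#' @return metrics list from [compute_metrics()] plus `n`.
#' @export
local_evaluate <- function(weights, spec, data) {
  n <- data_size(data)
  if (n == 0L) stop("cannot evaluate on an empty split")
  p <- forward_pass(weights, spec, data$xtab, data$ximg)$p
  c(compute_metrics(data$y, p), list(n = n))
}

#' Centralized (pooled) training baseline
#'
#' Standard mini-batch training on pooled data, the offline arm the
#' federated run is compared against.
#'
#' @param data list with `train` and optionally `validation`, each a list
#'   `xtab`, `ximg`, `y`.
#' @param spec `model_spec`.
#' @param config `training_config`.
#' @param epochs total epochs (default: matched budget
#'   `rounds * epochs_per_round`).
#' @return list `weights`, `history` (data.frame epoch/train_loss/
#'   val_loss).
#' @export
train_centralized <- function(data, spec, config,
                              epochs = config$rounds *
                                config$epochs_per_round) {
  stopifnot(is_count(epochs))
  weights <- build_model(spec, seed = config$seed)
  n <- data_size(data$train)
  if (n == 0L) stop("empty training split")
  state <- opt_init(weights, config)
  bs <- min(config$batch_size, n)
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  for (ep in seq_len(epochs)) {
    perm <- if (bs < n)
      with_seed(config$seed + 7919L * ep, sample.int(n)) else seq_len(n)
    starts <- seq(1L, n, by = bs)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + bs - 1L, n)]
      b <- subset_batch(data$train, idx)
      lg <- loss_and_grads(weights, spec, b$xtab, b$ximg, b$y)
      if (!is.finite(lg$loss)) stop("non-finite training loss; aborting")
      st <- opt_step(weights, lg$grads, state, config)
      weights <- st$weights; state <- st$state
      losses[bi] <- lg$loss
    }
    hist$train_loss[ep] <- mean(losses)
    if (!is.null(data$validation) && data_size(data$validation) > 0) {
      pv <- forward_pass(weights, spec, data$validation$xtab,
                         data$validation$ximg)$p
      hist$val_loss[ep] <- bce_loss(data$validation$y, pv)
    }
  }
  list(weights = weights, history = hist)
}
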