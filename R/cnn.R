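#' Configuration of the dendritic-feature patch classifier
#'
#' Six convolutional blocks (3x3 convolution, batch normalization, swish
#' activation, 2x2 max pooling) followed by three fully connected layers.
#' Patches are resampled to a fixed square network input and standardized
#' per patch, which makes the classifier invariant to absolute intensity
#' scale. The `small` profile shrinks the first fully connected layer for
#' desk-scale training.
#'
#' @param n_classes 9 (full dendritic-feature set) or 2 (spine/non-spine).
#' @param conv_widths Channel widths of the six blocks.
#' @param fc_sizes Sizes of the three fully connected layers (the last must
#'   equal `n_classes`).
#' @param input_px Network input side in pixels (patches are resampled).
#' @param small Use the reduced profile.
#' @param seed Seed controlling initialization and batching.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes = 9L,
                              conv_widths = c(16L, 32L, 48L, 64L, 96L, 128L),
                              fc_sizes = c(4096L, 256L, n_classes),
                              input_px = 32L, small = FALSE, seed = 42L) {
  if (small) {
    conv_widths <- c(8L, 12L, 16L, 24L, 32L, 48L)
    fc_sizes <- c(256L, 256L, n_classes)
  }
  stopifnot(length(conv_widths) == 6L, length(fc_sizes) == 3L,
            fc_sizes[3] == n_classes, n_classes %in% c(2L, 9L),
            input_px %in% c(32L, 64L))
  structure(list(n_classes = as.integer(n_classes),
                 conv_blocks = 6L,
                 conv_widths = as.integer(conv_widths),
                 fc_sizes = as.integer(fc_sizes),
                 activation = "swish", pooling = "max",
                 normalization = "batch",
                 input_px = as.integer(input_px), small = small,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' The nine dendritic-feature class names
#' @return Character vector indexed by class label.
#' @export
patch_class_names <- function() {
  c("spine head", "multiple overlapping spines", "spine-dendrite junction",
    "dendrite edge", "dendrite", "spine neck", "spine head edge",
    "bouton/axon", "noise")
}

# ---- internal network machinery -------------------------------------------
# Activations travel as matrices with rows ordered (h, w, n) and one
# column per channel; H, W, N are carried alongside.

swish_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, s = s)
}

swish_bwd <- function(dy, x, s) dy * (s + x * s * (1 - s))

im2col <- function(M, H, W, N) {
  C <- ncol(M)
  A <- array(M, c(H, W, N, C))
  P <- array(0, c(H + 2L, W + 2L, N, C))
  P[2:(H + 1L), 2:(W + 1L), , ] <- A
  blocks <- vector("list", 9L)
  idx <- 1L
  for (dj in 0:2) for (di in 0:2) {
    sl <- P[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
    blocks[[idx]] <- matrix(sl, H * W * N, C)
    idx <- idx + 1L
  }
  do.call(cbind, blocks)
}

col2im <- function(dX, H, W, N, C) {
  P <- array(0, c(H + 2L, W + 2L, N, C))
  idx <- 1L
  for (dj in 0:2) for (di in 0:2) {
    blk <- array(dX[, (idx - 1L) * C + seq_len(C)], c(H, W, N, C))
    P[di + seq_len(H), dj + seq_len(W), , ] <-
      P[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] + blk
    idx <- idx + 1L
  }
  matrix(P[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], H * W * N, C)
}

maxpool_fwd <- function(M, H, W, N) {
  C <- ncol(M)
  A <- array(M, c(H, W, N, C))
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  subs <- list(A[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
               A[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
               A[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE],
               A[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE])
  Y <- pmax(subs[[1]], subs[[2]], subs[[3]], subs[[4]])
  # first-takes-it argmax masks
  claimed <- array(FALSE, dim(Y))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    masks[[k]] <- (subs[[k]] >= Y) & !claimed
    claimed <- claimed | masks[[k]]
  }
  list(y = matrix(Y, H2 * W2 * N, C), masks = masks, H2 = H2, W2 = W2)
}

maxpool_bwd <- function(dY, cache, H, W, N) {
  C <- ncol(dY)
  H2 <- cache$H2
  W2 <- cache$W2
  dA <- array(0, c(H, W, N, C))
  dYa <- array(dY, c(H2, W2, N, C))
  sel <- list(list(seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)),
              list(seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)),
              list(seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)),
              list(seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)))
  for (k in 1:4) {
    contrib <- dYa * cache$masks[[k]]
    dA[sel[[k]][[1]], sel[[k]][[2]], , ] <-
      dA[sel[[k]][[1]], sel[[k]][[2]], , , drop = FALSE] + contrib
  }
  matrix(dA, H * W * N, C)
}

bn_fwd <- function(M, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(sweep(M, 2, mu)^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  xhat <- sweep(sweep(M, 2, mu), 2, sqrt(v + eps), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, var = v, run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma, eps = 1e-5) {
  m <- nrow(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  xhat <- cache$xhat
  istd <- 1 / sqrt(cache$var + eps)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dY), byrow = TRUE) -
                sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
              2, istd, "*")
  list(dx = dx, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

init_params <- function(config) {
  set.seed(config$seed)
  widths <- config$conv_widths
  cin <- 1L
  params <- list(conv = list(), bn = list(), fc = list())
  for (b in 1:6) {
    cout <- widths[b]
    params$conv[[b]] <- list(
      W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                 9L * cin, cout),
      b = rep(0, cout))
    params$bn[[b]] <- list(gamma = rep(1, cout), beta = rep(0, cout),
                           run_mean = rep(0, cout), run_var = rep(1, cout))
    cin <- cout
  }
  sizes <- c(widths[6], config$fc_sizes)
  for (l in 1:3) {
    params$fc[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                              sqrt(2 / sizes[l])), sizes[l], sizes[l + 1]),
      b = rep(0, sizes[l + 1]))
  }
  params
}

# forward pass; X is [H, W, 1, N]; returns logits and (optionally) caches
net_forward <- function(params, X, config, training = FALSE) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; N <- d[4]
  M <- matrix(aperm(X, c(1, 2, 4, 3)), H * W * N, d[3])
  caches <- list()
  for (b in 1:6) {
    cols <- im2col(M, H, W, N)
    pre <- sweep(cols %*% params$conv[[b]]$W, 2, params$conv[[b]]$b, "+")
    bn <- bn_fwd(pre, params$bn[[b]]$gamma, params$bn[[b]]$beta,
                 params$bn[[b]]$run_mean, params$bn[[b]]$run_var, training)
    if (training) {
      params$bn[[b]]$run_mean <- bn$run_mean
      params$bn[[b]]$run_var <- bn$run_var
    }
    act <- swish_fwd(bn$y)
    if (H >= 2L && W >= 2L) {
      pool <- maxpool_fwd(act$y, H, W, N)
      if (training)
        caches[[b]] <- list(cols = cols, bn = bn, act = act, pool = pool,
                            H = H, W = W, Cin = ncol(M))
      M <- pool$y
      H <- pool$H2
      W <- pool$W2
    } else {
      if (training)
        caches[[b]] <- list(cols = cols, bn = bn, act = act, pool = NULL,
                            H = H, W = W, Cin = ncol(M))
      M <- act$y
    }
  }
  # spatial size is 1x1 here: rows are samples
  feats <- M
  fc_caches <- list()
  for (l in 1:3) {
    pre <- sweep(feats %*% params$fc[[l]]$W, 2, params$fc[[l]]$b, "+")
    if (l < 3L) {
      act <- swish_fwd(pre)
      if (training) fc_caches[[l]] <- list(x = feats, pre = pre, act = act)
      feats <- act$y
    } else {
      if (training) fc_caches[[l]] <- list(x = feats, pre = pre)
      feats <- pre
    }
  }
  list(logits = feats, caches = caches, fc_caches = fc_caches,
       params = params)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

net_backward <- function(params, fwd, X, y_onehot, class_w) {
  N <- nrow(fwd$logits)
  p <- softmax(fwd$logits)
  wrow <- class_w[max.col(y_onehot)]
  dlogits <- (p - y_onehot) * wrow / sum(wrow)
  grads <- list(conv = vector("list", 6L), bn = vector("list", 6L),
                fc = vector("list", 3L))
  d <- dlogits
  for (l in 3:1) {
    cache <- fwd$fc_caches[[l]]
    grads$fc[[l]] <- list(W = crossprod(cache$x, d), b = colSums(d))
    d <- d %*% t(params$fc[[l]]$W)
    if (l > 1L) {
      pc <- fwd$fc_caches[[l - 1L]]
      d <- swish_bwd(d, pc$pre, pc$act$s)
    }
  }
  # into conv stack (spatial 1x1: rows already samples)
  for (b in 6:1) {
    cache <- fwd$caches[[b]]
    H <- cache$H
    W <- cache$W
    n <- N
    if (!is.null(cache$pool)) d <- maxpool_bwd(d, cache$pool, H, W, n)
    d <- swish_bwd(d, cache$bn$y, cache$act$s)
    bnb <- bn_bwd(d, cache$bn, params$bn[[b]]$gamma)
    grads$bn[[b]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    d <- bnb$dx
    grads$conv[[b]] <- list(W = crossprod(cache$cols, d), b = colSums(d))
    if (b > 1L) {
      dX <- d %*% t(params$conv[[b]]$W)
      d <- col2im(dX, H, W, n, cache$Cin)
    }
  }
  list(grads = grads, loss = -sum(wrow * log(pmax(p[y_onehot > 0], 1e-12))) /
         sum(wrow))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  res <- list(p = params, s = state)
  for (grp in c("conv", "bn", "fc")) {
    for (i in seq_along(params[[grp]])) {
      for (nm in names(grads[[grp]][[i]])) {
        r <- walk(params[[grp]][[i]][[nm]], grads[[grp]][[i]][[nm]],
                  state[[grp]][[i]][[nm]])
        res$p[[grp]][[i]][[nm]] <- r$p
        res$s[[grp]][[i]][[nm]] <- r$s
      }
    }
  }
  res
}

# patches (list with $pixels) -> standardized network input [px, px, 1, N]
patches_to_input <- function(patches, input_px) {
  N <- length(patches)
  X <- array(0, c(input_px, input_px, 1L, N))
  for (i in seq_len(N)) {
    p <- patches[[i]]$pixels
    if (!all(dim(p) == input_px))
      p <- ebi_mat(EBImage::resize(EBImage::Image(p), w = input_px,
                                     h = input_px))
    s <- stats::sd(p)
    X[, , 1L, i] <- (p - mean(p)) / (s + 1e-6)
  }
  X
}

#' Train the dendritic-feature patch classifier
#'
#' Deterministic given the config seed: the train/validation split, the
#' initialization and the batch order all derive from it. Classes are
#' weighted inversely to their frequency. The checkpoint with the best
#' validation accuracy is returned together with train and validation
#' confusion matrices.
#'
#' @param patches List of labelled patches (each with `pixels` and `label`).
#' @param config A [classifier_config()].
#' @param split Validation fraction in (0, 1).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param verbose Print per-epoch accuracy.
#' @return An object of class `spine_classifier` with `params`, `config`,
#'   `train_confusion`, `val_confusion`, `history`.
#' @export
train_classifier <- function(patches, config = classifier_config(),
                             split = 0.3, epochs = 20L, batch_size = 32L,
                             lr = 1e-3, verbose = FALSE) {
  stopifnot(split > 0, split < 1)
  labels <- vapply(patches, function(p) as.integer(p$label), integer(1))
  if (length(unique(labels)) < 2L)
    stop("training requires at least 2 classes")
  if (any(labels < 1L | labels > config$n_classes))
    stop("labels must be in 1..n_classes")
  set.seed(config$seed)
  N <- length(patches)
  val_idx <- sample.int(N, max(1L, round(split * N)))
  train_idx <- setdiff(seq_len(N), val_idx)
  X <- patches_to_input(patches, config$input_px)
  Y <- matrix(0, N, config$n_classes)
  Y[cbind(seq_len(N), labels)] <- 1
  freq <- tabulate(labels[train_idx], config$n_classes)
  class_w <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)
  class_w <- class_w / mean(class_w[freq > 0])
  params <- init_params(config)
  state <- NULL
  best <- list(acc = -1, params = params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_acc = numeric(0))
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      if (length(bi) < 2L) next
      fwd <- net_forward(params, X[, , , bi, drop = FALSE], config,
                         training = TRUE)
      params <- fwd$params  # running BN stats
      bwd <- net_backward(params, fwd, NULL, Y[bi, , drop = FALSE], class_w)
      step <- step + 1L
      if (is.null(state)) state <- build_adam_state(params)
      upd <- adam_step(params, bwd$grads, state, lr, step)
      params <- upd$p
      state <- upd$s
      ep_loss <- ep_loss + bwd$loss
      nb <- nb + 1L
    }
    val_pred <- predict_batches(params, X, config, val_idx)
    val_acc <- mean(val_pred == labels[val_idx])
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         val_acc = val_acc))
    if (val_acc > best$acc) best <- list(acc = val_acc, params = params)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val acc %.3f", ep,
                      ep_loss / nb, val_acc))
  }
  params <- best$params
  lv <- seq_len(config$n_classes)
  tr_pred <- predict_batches(params, X, config, train_idx)
  val_pred <- predict_batches(params, X, config, val_idx)
  structure(list(
    params = params, config = config,
    train_confusion = table(truth = factor(labels[train_idx], lv),
                            predicted = factor(tr_pred, lv)),
    val_confusion = table(truth = factor(labels[val_idx], lv),
                          predicted = factor(val_pred, lv)),
    val_accuracy = best$acc, history = history),
    class = "spine_classifier")
}

build_adam_state <- function(params) {
  st <- params
  for (grp in c("conv", "bn", "fc"))
    for (i in seq_along(params[[grp]]))
      for (nm in names(params[[grp]][[i]]))
        st[[grp]][[i]][[nm]] <- list(m = params[[grp]][[i]][[nm]] * 0,
                                     v = params[[grp]][[i]][[nm]] * 0)
  st
}

predict_batches <- function(params, X, config, idx, chunk = 256L) {
  out <- integer(length(idx))
  for (b0 in seq(1L, length(idx), by = chunk)) {
    bi <- idx[b0:min(b0 + chunk - 1L, length(idx))]
    lg <- net_forward(params, X[, , , bi, drop = FALSE], config)$logits
    out[b0:(b0 + length(bi) - 1L)] <- max.col(lg, ties.method = "first")
  }
  out
}

#' @export
print.spine_classifier <- function(x, ...) {
  cat(sprintf("<spine_classifier> %d classes, val accuracy %.3f\n",
              x$config$n_classes, x$val_accuracy))
  invisible(x)
}

#' Class probabilities for a set of patches
#'
#' @param classifier A trained [train_classifier()] result.
#' @param patches List of patches (each with `pixels`).
#' @return Matrix `N x n_classes` of probabilities (rows sum to 1).
#' @export
classify_patches <- function(classifier, patches) {
  stopifnot(inherits(classifier, "spine_classifier"))
  X <- patches_to_input(patches, classifier$config$input_px)
  probs <- matrix(0, length(patches), classifier$config$n_classes)
  for (b0 in seq(1L, length(patches), by = 256L)) {
    bi <- b0:min(b0 + 255L, length(patches))
    lg <- net_forward(classifier$params, X[, , , bi, drop = FALSE],
                      classifier$config)$logits
    probs[bi, ] <- softmax(lg)
  }
  probs
}
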