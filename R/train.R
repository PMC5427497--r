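# Forward/backward engine and SGD training loop.
#
# Activations flow as (H, W, N, C) tensors through the conv stack; each
# convolution is an im2col + GEMM with "same" zero padding, and the GEMM
# output matrix ((H*W*N) x C_out) is reshape-identical to the next
# tensor, so no transposition happens inside the stack.  Batch norm
# operates on that (positions x channels) matrix view: conv batch norm
# normalizes per channel over batch and space, FC batch norm per unit
# over the batch.  Both batch-norm affine steps and the ReLU are fused
# single-pass C++ kernels.  Dropout is inverted (scaled by 1/(1-p) at
# train time) so inference needs no rescaling.  Under batch norm the
# conv/FC bias is algebraically absorbed by the batch-norm shift; the
# bias parameters exist (and are counted) but receive no updates.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9   # running-statistics update: r <- 0.9 r + 0.1 batch

# list of (C,H,W) arrays -> (H,W,N,C) batch tensor
images_to_tensor <- function(images) {
  d <- dim(images[[1]])
  arr <- vapply(images, function(im) aperm(im, c(2, 3, 1)),
                array(0, c(d[2], d[3], d[1])))
  aperm(arr, c(1, 2, 4, 3))
}

# subtract a (C,H,W) mean image from a (H,W,N,C) tensor in place-ish
subtract_mean_tensor <- function(X, pixel_mean) {
  pm <- aperm(pixel_mean, c(2, 3, 1))  # (H,W,C)
  for (c in seq_len(dim(X)[4]))
    X[, , , c] <- X[, , , c] - as.vector(pm[, , c])
  X
}

# Forward pass.  mode "train" keeps caches for the backward pass and uses
# batch statistics + dropout; mode "eval" uses running statistics.
# `collect` (integer) extracts the post-activation output of that weighted
# layer: conv outputs are taken after pooling and either global-average
# pooled per channel (`pool_channels`) or flattened; the final FC layer
# yields pre-softmax logits.
net_forward <- function(layers, config, X, mode = "eval", collect = NULL,
                        pool_channels = TRUE, bn_momentum = BN_MOMENTUM) {
  train <- identical(mode, "train")
  caches <- if (train) vector("list", length(layers))
  collected <- NULL
  N <- dim(X)[3]
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      d <- dim(X)  # (H, W, N, C)
      cols <- cpp_im2col(X, d[1], d[2], d[4], d[3], config$filter_size)
      Z <- cols %*% l$W
      cout <- ncol(l$W)
      cache <- if (train) list(in_dim = d, cols = cols)
      if (!is.null(l$bn)) {
        if (train) {
          mo <- cpp_col_moments(Z)
          mu <- mo$mu
          v <- mo$msq - mu * mu
          invstd <- 1 / sqrt(v + BN_EPS)
          Zhat <- cpp_colscale_shift(Z, invstd, -mu * invstd, FALSE)
          A <- cpp_colscale_shift(Zhat, l$bn$gamma, l$bn$beta, TRUE)
          layers[[i]]$bn$rmean <- bn_momentum * l$bn$rmean + (1 - bn_momentum) * mu
          layers[[i]]$bn$rvar <- bn_momentum * l$bn$rvar + (1 - bn_momentum) * v
          cache$Zhat <- Zhat; cache$invstd <- invstd
        } else {
          sc <- l$bn$gamma / sqrt(l$bn$rvar + BN_EPS)
          A <- cpp_colscale_shift(Z, sc, l$bn$beta - l$bn$rmean * sc, TRUE)
        }
      } else {
        A <- cpp_colscale_shift(Z, rep(1, cout), l$b, TRUE)
      }
      if (train) cache$act <- A
      dim(A) <- c(d[1], d[2], d[3], cout)
      if (l$pool_after) {
        pl <- cpp_maxpool(A, d[1], d[2], as.numeric(d[3]) * cout)
        if (train) {
          cache$pool_idx <- pl$idx
          cache$prepool_dim <- c(d[1], d[2], d[3], cout)
        }
        A <- pl$out
        dim(A) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], cout)
      }
      X <- A
      if (train) caches[[i]] <- cache
      if (!is.null(collect) && i == collect) {
        dd <- dim(X)
        collected <- if (pool_channels) cpp_gap(X, dd[1], dd[2], dd[3], dd[4])
                     else t(matrix(aperm(X, c(1, 2, 4, 3)), ncol = dd[3]))
        if (!train) break
      }
      if (i == length(layers) || layers[[i + 1]]$type == "fc") {
        flat_dim <- dim(X)
        X <- t(matrix(aperm(X, c(1, 2, 4, 3)), ncol = N))
        if (train) caches[[i]]$flat_dim <- flat_dim
      }
    } else {
      cache <- if (train) list(Xin = X)
      Z <- X %*% l$W
      if (!is.null(l$bn)) {
        if (train) {
          mo <- cpp_col_moments(Z)
          mu <- mo$mu
          v <- mo$msq - mu * mu
          invstd <- 1 / sqrt(v + BN_EPS)
          Zhat <- cpp_colscale_shift(Z, invstd, -mu * invstd, FALSE)
          Z <- cpp_colscale_shift(Zhat, l$bn$gamma, l$bn$beta, !l$last)
          layers[[i]]$bn$rmean <- bn_momentum * l$bn$rmean + (1 - bn_momentum) * mu
          layers[[i]]$bn$rvar <- bn_momentum * l$bn$rvar + (1 - bn_momentum) * v
          cache$Zhat <- Zhat; cache$invstd <- invstd
        } else {
          sc <- l$bn$gamma / sqrt(l$bn$rvar + BN_EPS)
          Z <- cpp_colscale_shift(Z, sc, l$bn$beta - l$bn$rmean * sc, !l$last)
        }
      } else {
        Z <- cpp_colscale_shift(Z, rep(1, ncol(Z)), l$b, !l$last)
      }
      if (!l$last) {
        if (train) cache$relu_out <- Z
        if (!is.null(collect) && i == collect) collected <- Z
        if (l$dropout && train && config$dropout_rate > 0) {
          p <- config$dropout_rate
          mask <- matrix((runif(length(Z)) >= p) / (1 - p), nrow(Z))
          Z <- Z * mask
          cache$drop_mask <- mask
        }
      } else if (!is.null(collect) && i == collect) {
        collected <- Z   # logits
      }
      X <- Z
      if (train) caches[[i]] <- cache
    }
  }
  list(logits = X, caches = caches, layers = layers, collected = collected)
}

# "Precise" batch-norm statistics: replace the momentum running averages
# by plain averages of batch statistics over a few forward passes (no
# dropout, no weight updates), removing checkpoint noise when epochs are
# only a handful of iterations long.
refresh_bn_stats <- function(layers, config, X, batch = 50L,
                             max_batches = 6L) {
  cfg <- config
  cfg$dropout_rate <- 0
  n <- dim(X)[3]
  m <- min(n, batch * max_batches)
  # strided subsample so each statistics batch spans the (class-sorted)
  # training tensor rather than a single class block
  idx <- unique(round(seq(1, n, length.out = m)))
  idx <- idx[order(seq_along(idx) %% max_batches)]
  starts <- seq(1, length(idx), by = batch)
  for (bi in seq_along(starts)) {
    take <- idx[starts[bi]:min(starts[bi] + batch - 1, length(idx))]
    layers <- net_forward(layers, cfg,
                          X[, , take, , drop = FALSE],
                          mode = "train",
                          bn_momentum = (bi - 1) / bi)$layers
  }
  layers
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Backward pass; returns gradients parallel to `layers`.
net_backward <- function(layers, config, caches, dlogits) {
  grads <- vector("list", length(layers))
  dX <- dlogits
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cache <- caches[[i]]
    if (l$type == "fc") {
      dZ <- dX
      g <- list()
      if (l$last) {
        g$db <- colSums(dZ)
      } else {
        if (!is.null(cache$drop_mask)) dZ <- dZ * cache$drop_mask
        if (!is.null(l$bn)) {
          bb <- cpp_bn_relu_backward(dZ, cache$relu_out, cache$Zhat,
                                     l$bn$gamma, cache$invstd)
          dZ <- bb$dZ
          g$dgamma <- bb$dgamma; g$dbeta <- bb$dbeta
          g$db <- numeric(length(l$b))
        } else {
          dZ <- dZ * (cache$relu_out > 0)
          g$db <- colSums(dZ)
        }
      }
      g$dW <- crossprod(cache$Xin, dZ)
      grads[[i]] <- g
      dX <- tcrossprod(dZ, l$W)
    } else {
      if (!is.null(cache$flat_dim)) {
        fd <- cache$flat_dim
        dX <- aperm(array(t(dX), c(fd[1], fd[2], fd[4], fd[3])), c(1, 2, 4, 3))
      }
      cout <- ncol(l$W)
      if (l$pool_after) {
        pre <- cache$prepool_dim
        dX <- cpp_maxpool_backward(dX, cache$pool_idx, prod(pre))
      }
      d <- cache$in_dim
      dA <- dX
      dim(dA) <- c(length(dA) %/% cout, cout)
      g <- list()
      if (!is.null(l$bn)) {
        bb <- cpp_bn_relu_backward(dA, cache$act, cache$Zhat,
                                   l$bn$gamma, cache$invstd)
        dZ <- bb$dZ
        g$dgamma <- bb$dgamma; g$dbeta <- bb$dbeta
        g$db <- numeric(length(l$b))
      } else {
        dZ <- dA * (cache$act > 0)
        g$db <- colSums(dZ)
      }
      g$dW <- crossprod(cache$cols, dZ)
      grads[[i]] <- g
      if (i > 1) {
        dcols <- tcrossprod(dZ, l$W)
        dX <- cpp_col2im(dcols, d[1], d[2], d[4], d[3],
                         config$filter_size)
        dim(dX) <- d
      }
    }
  }
  grads
}

init_velocity <- function(layers) {
  lapply(layers, function(l) {
    v <- list(W = l$W * 0, b = l$b * 0)
    if (!is.null(l$bn)) { v$gamma <- l$bn$gamma * 0; v$beta <- l$bn$beta * 0 }
    v
  })
}

sgd_update <- function(layers, grads, vel, lr, momentum, weight_decay) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    vel[[i]]$W <- momentum * vel[[i]]$W - lr * (g$dW + weight_decay * layers[[i]]$W)
    layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
    vel[[i]]$b <- momentum * vel[[i]]$b - lr * g$db
    layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
    if (!is.null(layers[[i]]$bn)) {
      vel[[i]]$gamma <- momentum * vel[[i]]$gamma - lr * g$dgamma
      layers[[i]]$bn$gamma <- layers[[i]]$bn$gamma + vel[[i]]$gamma
      vel[[i]]$beta <- momentum * vel[[i]]$beta - lr * g$dbeta
      layers[[i]]$bn$beta <- layers[[i]]$bn$beta + vel[[i]]$beta
    }
  }
  list(layers = layers, vel = vel)
}

eval_network <- function(layers, config, X, y_idx, batch = 128L) {
  n <- dim(X)[3]
  loss <- 0; correct <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    idx <- s:e
    logits <- net_forward(layers, config,
                          X[, , idx, , drop = FALSE], mode = "eval")$logits
    P <- softmax_rows(logits)
    loss <- loss + sum(-log(pmax(P[cbind(seq_along(idx), y_idx[idx])], 1e-12)))
    correct <- correct + sum(max.col(P, ties.method = "first") == y_idx[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the convolutional network
#'
#' Minimizes cross-entropy by SGD with momentum on the training fold of a
#' dataset, halving the learning rate every `lr_halving_interval`
#' iterations, with weight decay on the weight matrices and dropout on the
#' first two FC layers.  The per-pixel training-set mean is subtracted
#' from every image.  At every `checkpoint_every` epochs the validation
#' fold is scored and the checkpoint with the lowest validation loss is
#' returned.
#'
#' @param network A `cell_cnn` from [build_network()].
#' @param data A `cell_dataset` (or list with `manifest` and `images`).
#' @param config A [train_config()].
#' @param classes Class label order; defaults to the sorted unique labels.
#' @return A `trained_cnn`: the selected layers plus `pixel_mean`,
#'   `classes`, and `history` (per-iteration training loss; per-checkpoint
#'   validation loss/accuracy).
#' @export
train_network <- function(network, data, config = train_config(),
                          classes = NULL) {
  stopifnot(inherits(network, "cell_cnn"), inherits(config, "train_config"))
  man <- data$manifest
  if (is.null(classes)) classes <- sort(unique(man$label))
  if (length(classes) != network$config$n_classes)
    stop("network has ", network$config$n_classes, " outputs but data has ",
         length(classes), " classes")
  tr <- which(man$fold == "train")
  va <- which(man$fold == "val")
  if (length(tr) == 0) stop("training fold is empty")
  Xtr <- images_to_tensor(data$images[man$cell_id[tr]])
  pixel_mean <- aperm(apply(Xtr, c(1, 2, 4), mean), c(3, 1, 2))
  Xtr <- subtract_mean_tensor(Xtr, pixel_mean)
  # one global scale so inputs are O(1): conditions the optimizer and the
  # weight-decay penalty; absorbed by the first batch norm, so it changes
  # numerics, not the model family
  pixel_scale <- sd(Xtr)
  if (!is.finite(pixel_scale) || pixel_scale == 0) pixel_scale <- 1
  Xtr <- Xtr / pixel_scale
  ytr <- match(man$label[tr], classes)
  if (anyNA(ytr)) stop("labels outside the class vocabulary")
  has_val <- length(va) > 0
  if (has_val) {
    Xva <- subtract_mean_tensor(images_to_tensor(data$images[man$cell_id[va]]),
                                pixel_mean) / pixel_scale
    yva <- match(man$label[va], classes)
  }
  n <- length(tr); K <- length(classes)
  layers <- network$layers
  vel <- init_velocity(layers)
  iter_loss <- numeric(0)
  val_hist <- list()
  best <- list(loss = Inf, layers = layers)
  iter <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        nb <- length(idx)
        Xb <- Xtr[, , idx, , drop = FALSE]
        fw <- net_forward(layers, network$config, Xb, mode = "train")
        layers <- fw$layers   # running BN stats updated
        P <- softmax_rows(fw$logits)
        Y <- matrix(0, nb, K); Y[cbind(seq_len(nb), ytr[idx])] <- 1
        loss <- mean(-log(pmax(P[Y == 1], 1e-12)))
        iter_loss <- c(iter_loss, loss)
        dlogits <- (P - Y) / nb
        grads <- net_backward(layers, network$config, fw$caches, dlogits)
        if (is.finite(config$grad_clip)) {
          gn <- sqrt(sum(vapply(grads, function(g)
            sum(g$dW^2) + sum(g$db^2) + sum(g$dgamma^2) + sum(g$dbeta^2),
            0)))
          if (gn > config$grad_clip) {
            sc <- config$grad_clip / gn
            grads <- lapply(grads, function(g) lapply(g, `*`, sc))
          }
        }
        lr <- learning_rate_at(iter, config$initial_lr,
                               config$lr_halving_interval)
        # linear warmup guards the cold batch-norm statistics
        if (config$warmup_iters > 0 && iter < config$warmup_iters)
          lr <- lr * (iter + 1) / config$warmup_iters
        up <- sgd_update(layers, grads, vel, lr, config$momentum,
                         config$weight_decay)
        layers <- up$layers; vel <- up$vel
        iter <- iter + 1L
      }
      if (epoch %% config$checkpoint_every == 0 || epoch == config$epochs) {
        layers <- refresh_bn_stats(layers, network$config, Xtr,
                                   batch = config$batch_size)
        if (has_val) {
          ev <- eval_network(layers, network$config, Xva, yva)
          val_hist[[length(val_hist) + 1]] <-
            data.frame(epoch = epoch, iteration = iter,
                       val_loss = ev$loss, val_acc = ev$acc)
          if (ev$loss < best$loss) best <- list(loss = ev$loss, layers = layers)
          if (config$verbose)
            message(sprintf("epoch %d  iter %d  train loss %.4f  val loss %.4f  val acc %.3f",
                            epoch, iter, loss, ev$loss, ev$acc))
        } else {
          best <- list(loss = loss, layers = layers)
        }
      }
    }
  })
  structure(list(config = network$config,
                 layers = if (has_val) best$layers else layers,
                 pixel_mean = pixel_mean, pixel_scale = pixel_scale,
                 classes = classes,
                 history = list(iter_loss = iter_loss,
                                val = if (length(val_hist))
                                  do.call(rbind, val_hist))),
            class = "trained_cnn")
}

resolve_images <- function(images) {
  if (inherits(images, "cell_dataset")) return(images$images)
  if (inherits(images, "cell_image")) return(list(images$pixels))
  if (is.list(images) && length(images) && inherits(images[[1]], "cell_image"))
    return(lapply(images, `[[`, "pixels"))
  if (is.array(images) && length(dim(images)) == 3) return(list(images))
  images
}

#' Per-cell class probabilities from a trained network
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' dropout) after subtracting the network's own pixel mean; outputs one
#' softmax simplex row per image.  Inference is deterministic and
#' per-image, so duplicated inputs give identical rows and batch order
#' does not affect results.
#'
#' @param trained A `trained_cnn`.
#' @param images A `cell_dataset`, list of `cell_image`s, or list of
#'   2x64x64 arrays.
#' @param batch Images scored per forward pass.
#' @return Numeric matrix n x K with columns named by class.
#' @export
predict_proba <- function(trained, images, batch = 128L) {
  stopifnot(inherits(trained, "trained_cnn"))
  imgs <- resolve_images(images)
  if (!identical(dim(imgs[[1]]), dim(trained$pixel_mean)))
    stop("image channels/size ", paste(dim(imgs[[1]]), collapse = "x"),
         " do not match the network input ",
         paste(dim(trained$pixel_mean), collapse = "x"))
  X <- subtract_mean_tensor(images_to_tensor(imgs), trained$pixel_mean) /
    (trained$pixel_scale %||% 1)
  n <- dim(X)[3]
  out <- matrix(NA_real_, n, length(trained$classes),
                dimnames = list(names(imgs), trained$classes))
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    logits <- net_forward(trained$layers, trained$config,
                          X[, , s:e, , drop = FALSE], mode = "eval")$logits
    out[s:e, ] <- softmax_rows(logits)
  }
  out
}

#' Hard class calls from probabilities
#'
#' Argmax per row; exact ties resolve to the lowest class index.
#'
#' @param probs Matrix of class probabilities with class columns.
#' @return Character vector of class labels.
#' @export
predict_class <- function(probs) {
  colnames(probs)[max.col(probs, ties.method = "first")]
}

#' Extract per-layer activations as a feature matrix
#'
#' Post-activation outputs of the requested weighted layer (1-based over
#' conv then FC layers), in inference mode.  Convolutional outputs are
#' taken after their pooling step and global-average pooled per channel by
#' default (or flattened); the final FC layer yields pre-softmax logits.
#'
#' @param trained A `trained_cnn`.
#' @param images Images as in [predict_proba()].
#' @param layer_index Integer in 1..(n conv + n FC layers).
#' @param pool_channels Global-average pool conv feature maps per channel.
#' @param batch Images per forward pass.
#' @return Numeric matrix n x width.
#' @export
extract_activations <- function(trained, images, layer_index,
                                pool_channels = TRUE, batch = 128L) {
  stopifnot(inherits(trained, "trained_cnn"))
  n_layers <- length(trained$layers)
  if (!(layer_index >= 1 && layer_index <= n_layers))
    stop("layer_index must be in 1..", n_layers)
  imgs <- resolve_images(images)
  X <- subtract_mean_tensor(images_to_tensor(imgs), trained$pixel_mean) /
    (trained$pixel_scale %||% 1)
  n <- dim(X)[3]
  rows <- vector("list", ceiling(n / batch))
  j <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    fw <- net_forward(trained$layers, trained$config,
                      X[, , s:e, , drop = FALSE], mode = "eval",
                      collect = layer_index, pool_channels = pool_channels)
    j <- j + 1
    rows[[j]] <- fw$collected
  }
  out <- do.call(rbind, rows)
  rownames(out) <- names(imgs)
  out
}
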