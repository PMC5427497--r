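# Network architecture: eight "same" 3x3 convolutions (each followed by
# batch normalization and ReLU, with 2x2/stride-2 max pooling after the
# designated conv layers) feeding three fully connected layers.  The first
# two FC layers carry batch normalization and dropout; the last produces
# class logits passed through softmax.

#' Convolutional network configuration
#'
#' The default is the full 11-layer architecture: conv widths
#' 64,64,128,128,256,256,256,256 with 3x3 filters at stride 1, pooling
#' after conv layers 2, 4 and 8, and fully connected widths 512, 512 and
#' `n_classes`.  On a 64x64 input the three poolings leave an 8x8x256
#' activation before flattening.
#'
#' @param conv_widths Integer vector of conv layer output channels.
#' @param pool_positions Indices of conv layers followed by 2x2 max pooling.
#' @param fc_widths Integer vector of fully connected widths; the last
#'   entry is the number of classes.
#' @param input_shape Channels x height x width of the input patch.
#' @param batchnorm Apply batch normalization before each activation
#'   (all conv layers and the first two FC layers).
#' @param dropout_rate Dropout probability on the first two FC layers
#'   during training.
#' @return A `network_config` object.
#' @export
network_config <- function(conv_widths = c(64, 64, 128, 128, 256, 256, 256, 256),
                           pool_positions = c(2, 4, 8),
                           fc_widths = c(512, 512, 12),
                           input_shape = c(2, 64, 64),
                           batchnorm = TRUE,
                           dropout_rate = 0.5) {
  stopifnot(length(conv_widths) >= 1, length(fc_widths) >= 1,
            all(conv_widths >= 1), all(fc_widths >= 1),
            all(pool_positions %in% seq_along(conv_widths)),
            length(input_shape) == 3,
            dropout_rate >= 0, dropout_rate < 1)
  np <- length(pool_positions)
  side <- input_shape[2]
  if (input_shape[2] != input_shape[3])
    stop("input must be square")
  if (side %% (2^np) != 0)
    stop("input size ", side, " not divisible by 2^", np, " poolings")
  structure(list(conv_widths = as.integer(conv_widths),
                 filter_size = 3L, conv_stride = 1L,
                 pool_size = 2L, pool_stride = 2L,
                 pool_positions = sort(as.integer(pool_positions)),
                 fc_widths = as.integer(fc_widths),
                 n_classes = as.integer(fc_widths[length(fc_widths)]),
                 input_shape = as.integer(input_shape),
                 batchnorm = isTRUE(batchnorm),
                 dropout_rate = dropout_rate),
            class = "network_config")
}

#' Desk-scale network preset
#'
#' Same topology as the full architecture (eight 3x3 convs, three 2x2
#' poolings, three FC layers) with conv widths divided by 8, FC widths
#' 64, 64, `n_classes`, and the poolings moved early (after conv layers
#' 1, 2 and 8) so that the expensive full-resolution maps shrink as soon
#' as possible; sized so training runs in minutes on one CPU.
#'
#' @param n_classes Number of output classes.
#' @return A `network_config`.
#' @export
small_network_config <- function(n_classes = 12) {
  network_config(conv_widths = c(8, 8, 16, 16, 32, 32, 32, 32),
                 pool_positions = c(1, 2, 8),
                 fc_widths = c(64, 64, n_classes),
                 dropout_rate = 0.15)
}

#' Desk-scale training preset
#'
#' The schedule used by the bundled desk-scale studies: 14 epochs at
#' batch 50, initial learning rate 0.1 halved every 150 iterations, a
#' 20-iteration linear warmup, gradient-norm clipping at 5, checkpoints
#' (with refreshed batch-norm statistics) every second epoch.
#'
#' @param seed Integer seed.
#' @param epochs Training epochs.
#' @return A [train_config()].
#' @export
small_train_config <- function(seed = 1L, epochs = 14L) {
  train_config(epochs = epochs, batch_size = 50L, initial_lr = 0.1,
               lr_halving_interval = 150L, warmup_iters = 20L,
               grad_clip = 5, checkpoint_every = 2L, seed = seed)
}

# spatial side length entering conv layer i (after pools before it)
conv_sides <- function(config) {
  side <- config$input_shape[2]
  sides <- integer(length(config$conv_widths))
  for (i in seq_along(config$conv_widths)) {
    sides[i] <- side
    if (i %in% config$pool_positions) side <- side %/% 2L
  }
  attr(sides, "final") <- side
  sides
}

flatten_width <- function(config) {
  final <- attr(conv_sides(config), "final")
  tail_w <- config$conv_widths[length(config$conv_widths)]
  as.integer(final * final * tail_w)
}

#' Build an untrained network
#'
#' Allocates conv and FC weights with Glorot-normal initialization
#' (sd = sqrt(2 / (fan_in + fan_out))), zero biases, and unit-scale
#' batch-norm parameters with zero running means / unit running variances.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `cell_cnn` object (list of layer parameter sets).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  k <- config$filter_size
  with_seed(seed, {
    layers <- list()
    cin <- config$input_shape[1]
    for (i in seq_along(config$conv_widths)) {
      cout <- config$conv_widths[i]
      fan_in <- k * k * cin; fan_out <- k * k * cout
      sdv <- sqrt(2 / (fan_in + fan_out))
      layers[[length(layers) + 1]] <- list(
        type = "conv",
        W = matrix(rnorm(k * k * cin * cout, 0, sdv), k * k * cin, cout),
        b = numeric(cout),
        bn = if (config$batchnorm) list(gamma = rep(1, cout), beta = numeric(cout),
                                        rmean = numeric(cout), rvar = rep(1, cout)),
        pool_after = i %in% config$pool_positions)
      cin <- cout
    }
    din <- flatten_width(config)
    nf <- length(config$fc_widths)
    for (j in seq_len(nf)) {
      dout <- config$fc_widths[j]
      last <- j == nf
      sdv <- sqrt(2 / (din + dout))
      layers[[length(layers) + 1]] <- list(
        type = "fc",
        W = matrix(rnorm(din * dout, 0, sdv), din, dout),
        b = numeric(dout),
        bn = if (config$batchnorm && !last)
          list(gamma = rep(1, dout), beta = numeric(dout),
               rmean = numeric(dout), rvar = rep(1, dout)),
        dropout = !last && j <= 2,
        last = last)
      din <- dout
    }
    structure(list(config = config, layers = layers), class = "cell_cnn")
  })
}

#' Count learnable parameters by walking the weight arrays
#'
#' Sums every learnable scalar actually allocated in the network: conv and
#' FC weights and biases plus batch-norm scale and shift parameters
#' (running statistics are not learnable and are excluded).
#'
#' @param network A `cell_cnn` or `trained_cnn`.
#' @return Integer total.
#' @export
count_parameters <- function(network) {
  total <- 0
  for (l in network$layers) {
    total <- total + length(l$W) + length(l$b)
    if (!is.null(l$bn)) total <- total + length(l$bn$gamma) + length(l$bn$beta)
  }
  as.integer(total)
}

#' Closed-form parameter count from a configuration
#'
#' Layer-by-layer arithmetic oracle: each conv layer contributes
#' `k^2 * c_in * c_out + c_out` weights and biases (+ `2 c_out` for batch
#' norm), each FC layer `d_in * d_out + d_out` (+ `2 d_out` batch norm on
#' all but the last).  Independent of [build_network()].
#'
#' @param config A [network_config()].
#' @return Integer total.
#' @export
parameter_count_formula <- function(config) {
  k <- config$filter_size
  total <- 0
  cin <- config$input_shape[1]
  for (cout in config$conv_widths) {
    total <- total + k * k * cin * cout + cout +
      if (config$batchnorm) 2 * cout else 0
    cin <- cout
  }
  din <- flatten_width(config)
  nf <- length(config$fc_widths)
  for (j in seq_len(nf)) {
    dout <- config$fc_widths[j]
    total <- total + din * dout + dout +
      if (config$batchnorm && j < nf) 2 * dout else 0
    din <- dout
  }
  as.integer(total)
}

#' Training iterations for a given epoch budget
#'
#' `ceiling(n_train / batch_size) * epochs`; the last incomplete
#' mini-batch of each epoch is used.  With 65,000 training images at batch
#' size 100, 25 epochs correspond to 16,250 iterations.
#'
#' @param n_train Number of training images.
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training data.
#' @return Integer iteration count.
#' @export
iteration_schedule <- function(n_train, batch_size, epochs) {
  stopifnot(n_train >= 1, epochs >= 1)
  if (batch_size < 1) stop("batch_size must be >= 1")
  as.integer(ceiling(n_train / batch_size) * epochs)
}

#' Learning rate at a given iteration
#'
#' Step decay: `initial_lr * 0.5 ^ floor(iteration / interval)`.
#'
#' @param iteration 0-based iteration index.
#' @param initial_lr Initial learning rate.
#' @param interval Iterations between halvings.
#' @return Numeric learning rate.
#' @export
learning_rate_at <- function(iteration, initial_lr = 0.1, interval = 16250) {
  initial_lr * 0.5^floor(iteration / interval)
}

#' Subtract the per-pixel training-set mean
#'
#' @param images A 2x64x64 array, a list of such arrays, or a
#'   (H, W, C, N) batch tensor.
#' @param pixel_mean A 2x64x64 array (the training-fold mean image).
#' @return Same structure as `images`, mean-subtracted; no rescaling.
#' @export
preprocess <- function(images, pixel_mean) {
  stopifnot(length(dim(pixel_mean)) == 3)
  sub1 <- function(img) {
    if (!identical(dim(img), dim(pixel_mean)))
      stop("image shape ", paste(dim(img), collapse = "x"),
           " does not match pixel mean ",
           paste(dim(pixel_mean), collapse = "x"))
    img - pixel_mean
  }
  if (is.list(images)) return(lapply(images, sub1))
  d <- dim(images)
  if (length(d) == 3) return(sub1(images))
  if (length(d) == 4) return(subtract_mean_tensor(images, pixel_mean))
  stop("images must be a 3-d array, list of arrays, or 4-d batch tensor")
}

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD with momentum 0.9, initial
#' learning rate 0.1 halved every `lr_halving_interval` iterations
#' (16,250 at full scale), mini-batch size 100, weight decay 5e-4,
#' dropout handled by the network config.
#'
#' @param epochs Passes over the training fold.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty applied to conv/FC weight matrices.
#' @param lr_halving_interval Iterations between learning-rate halvings.
#' @param warmup_iters Linear learning-rate warmup length (0 = none),
#'   protecting the cold batch-norm statistics early on.
#' @param grad_clip Global gradient-norm ceiling (Inf = no clipping).
#' @param checkpoint_every Validation / model-selection cadence in epochs.
#' @param seed Seed for shuffling, dropout and (via [build_network()]) init.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 10L, batch_size = 100L, initial_lr = 0.1,
                         momentum = 0.9, weight_decay = 5e-4,
                         lr_halving_interval = 16250L, warmup_iters = 0L,
                         grad_clip = Inf, checkpoint_every = 1L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_lr > 0, momentum >= 0,
            momentum < 1, weight_decay >= 0, lr_halving_interval >= 1,
            warmup_iters >= 0, grad_clip > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 lr_halving_interval = as.integer(lr_halving_interval),
                 warmup_iters = as.integer(warmup_iters),
                 grad_clip = grad_clip,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}
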