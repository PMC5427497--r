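# Transfer learning and interpretability: random-forest learning curves
# on features from different sources (network activations vs classic
# features), neuron-class mutual information, strongest feature
# correlations, and maximally activating input patches.

#' Learning curves for transfer to unseen classes
#'
#' For each feature source, training-set size and repetition: draw a
#' stratified subsample (`size` images per class) from the training
#' indices, fit a random forest for each candidate `mtry`, pick the best
#' on the validation set, and record test accuracy.
#'
#' @param features_by_source Named list of feature matrices over the same
#'   cells in the same order (e.g. `list(deep = ..., classic = ...)`).
#' @param labels Class labels, one per row.
#' @param train_idx,val_idx,test_idx Row index vectors for the three folds.
#' @param sizes Training images per class (default: the reference ladder
#'   1, 3, 5, 10, 25, 50, 100, 250, 500).
#' @param n_reps Repetitions per size with different derived seeds.
#' @param n_trees Forest size.
#' @param mtry_fractions Candidate features-per-split settings.
#' @param seed Master seed.
#' @return A `learning_curve` data.frame: source, size, rep, accuracy.
#' @export
transfer_learning_curve <- function(features_by_source, labels,
                                    train_idx, val_idx, test_idx,
                                    sizes = c(1, 3, 5, 10, 25, 50, 100, 250, 500),
                                    n_reps = 3, n_trees = 100,
                                    mtry_fractions = c("sqrt", 0.25),
                                    seed = 1L) {
  stopifnot(is.list(features_by_source), length(names(features_by_source)) > 0)
  labels <- factor(labels)
  sizes <- sort(unique(sizes))
  per_class_avail <- min(table(labels[train_idx]))
  if (max(sizes) > per_class_avail)
    stop("size ", max(sizes), " exceeds available training cells per class (",
         per_class_avail, ")")
  out <- list()
  for (src in names(features_by_source)) {
    FX <- features_by_source[[src]]
    stopifnot(nrow(FX) == length(labels))
    for (size in sizes) for (rep_ in seq_len(n_reps)) {
      sub <- with_seed(derive_seed(seed, size * 131L + rep_, 11L), {
        unlist(lapply(split(train_idx, labels[train_idx]), function(ix)
          ix[sample.int(length(ix), min(size, length(ix)))]),
          use.names = FALSE)
      })
      best <- list(acc = -1, fit = NULL)
      for (mf in mtry_fractions) {
        fit <- with_seed(derive_seed(seed, size * 131L + rep_, 13L),
          randomForest::randomForest(
            x = FX[sub, , drop = FALSE], y = droplevels(labels[sub]),
            ntree = n_trees,
            mtry = resolve_mtry(mf, ncol(FX))))
        va <- mean(as.character(predict(fit, FX[val_idx, , drop = FALSE])) ==
                     as.character(labels[val_idx]))
        if (va > best$acc) best <- list(acc = va, fit = fit)
      }
      acc <- mean(as.character(predict(best$fit,
                                       FX[test_idx, , drop = FALSE])) ==
                    as.character(labels[test_idx]))
      out[[length(out) + 1]] <- data.frame(source = src, size = size,
                                           rep = rep_, accuracy = acc)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("learning_curve", class(res))
  res
}

#' Mutual information between neuron activations and class labels
#'
#' Each neuron's output is discretized into `n_bins` equal-frequency bins
#' and the mutual information (in bits) with the class label is computed
#' from the empirical joint distribution.  Constant neurons have MI 0 by
#' convention.
#'
#' @param activations n x m activation matrix.
#' @param labels Class label per row.
#' @param n_bins Number of equal-frequency bins (>= 2).
#' @return Numeric vector of MI values (bits), one per neuron.
#' @export
neuron_class_mutual_information <- function(activations, labels,
                                            n_bins = 16) {
  stopifnot(n_bins >= 2, nrow(activations) == length(labels))
  y <- as.integer(factor(labels))
  K <- max(y)
  n <- length(y)
  apply(activations, 2, function(a) {
    if (max(a) - min(a) < 1e-12) return(0)
    # equal-frequency binning; tied values always share a bin, so a
    # neuron that is constant within classes is binned by value
    brk <- unique(stats::quantile(a, probs = seq_len(n_bins - 1) / n_bins,
                                  type = 1, names = FALSE))
    b <- findInterval(a, brk, left.open = TRUE)
    joint <- table(b, y) / n
    pb <- rowSums(joint); py <- colSums(joint)
    e <- outer(pb, py)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / e[nz]))
  })
}

#' Strongest absolute Pearson correlation to a classic feature
#'
#' For each neuron, the maximum |r| over all classic features computed on
#' the same cells.  Zero-variance neurons or features are skipped (NA for
#' a fully constant neuron).
#'
#' @param activations n x m activation matrix.
#' @param feature_table n x p classic feature matrix (same row order).
#' @return Numeric vector of max |r| per neuron.
#' @export
max_feature_correlation <- function(activations, feature_table) {
  stopifnot(nrow(activations) == nrow(feature_table))
  keep_f <- apply(feature_table, 2, function(x) stats::sd(x) > 0)
  FT <- feature_table[, keep_f, drop = FALSE]
  vapply(seq_len(ncol(activations)), function(j) {
    a <- activations[, j]
    if (stats::sd(a) == 0) return(NA_real_)
    max(abs(suppressWarnings(stats::cor(a, FT))), na.rm = TRUE)
  }, 0)
}

#' Receptive field of a network layer
#'
#' Size (pixels), effective stride and offset of one unit of the
#' post-pooling output of conv layer `layer_index`, from the standard
#' recursion for stacked 3x3/stride-1 convolutions and 2x2/stride-2
#' poolings.
#'
#' @param config A [network_config()].
#' @param layer_index Conv layer index (FC layers see the whole image).
#' @param include_pool Include the pooling step that directly follows the
#'   queried conv layer (`TRUE` matches the maps that
#'   [extract_activations()] returns; `FALSE` gives the receptive field
#'   of the convolution output itself, e.g. 3 then 5 for two stacked
#'   3x3 convolutions).
#' @return List with `size`, `stride`, `offset` (centre of unit 0).
#' @export
receptive_field <- function(config, layer_index, include_pool = TRUE) {
  n_conv <- length(config$conv_widths)
  if (layer_index > n_conv)
    return(list(size = config$input_shape[2], stride = NA, offset = NA))
  r <- 1; j <- 1; start <- 0.5
  for (i in seq_len(layer_index)) {
    r <- r + (config$filter_size - 1) * j      # "same" conv, stride 1
    if (i %in% config$pool_positions &&
        (include_pool || i < layer_index)) {
      start <- start + j / 2
      r <- r + j
      j <- j * 2
    }
  }
  list(size = r, stride = j, offset = start)
}

#' Input patches that maximally activate a neuron
#'
#' Scores every spatial position of the requested conv channel (or an FC
#' unit) over a set of images and returns the `k` highest-activating
#' input crops, clipped at image borders, with their activation values in
#' decreasing order.
#'
#' @param trained A `trained_cnn`.
#' @param images Images as in [predict_proba()].
#' @param layer_index Weighted layer index.
#' @param neuron Channel (conv) or unit (FC) index.
#' @param k Number of patches.
#' @return List of `k` entries: `image_id`, `activation`, `crop`
#'   (2 x h x w array), `center` (y, x, 1-based).
#' @export
top_activating_patches <- function(trained, images, layer_index, neuron,
                                   k = 4) {
  imgs <- resolve_images(images)
  n <- length(imgs)
  if (k > n * 1000) k <- n  # bounded below anyway
  config <- trained$config
  n_conv <- length(config$conv_widths)
  acts <- extract_activations(trained, images, layer_index,
                              pool_channels = FALSE)
  if (layer_index > n_conv) {
    if (neuron > ncol(acts)) stop("neuron index out of range")
    v <- acts[, neuron]
    o <- order(v, decreasing = TRUE)[seq_len(min(k, n))]
    return(lapply(o, function(i) list(image_id = names(imgs)[i] %||% i,
                                      activation = v[i],
                                      crop = imgs[[i]],
                                      center = c(NA, NA))))
  }
  sides <- conv_sides(config)
  side <- sides[layer_index] %/%
    (if (layer_index %in% config$pool_positions) 2L else 1L)
  ch <- config$conv_widths[layer_index]
  if (neuron > ch) stop("neuron index out of range (", ch, " channels)")
  # columns of `acts` are ordered (h, w, channel)
  cols <- ((neuron - 1) * side * side + 1):(neuron * side * side)
  A <- acts[, cols, drop = FALSE]
  if (k > length(A)) {
    warning("k exceeds available positions; returning all")
    k <- length(A)
  }
  rf <- receptive_field(config, layer_index)
  o <- order(A, decreasing = TRUE)[seq_len(k)]
  img_side <- config$input_shape[2]
  half <- (rf$size - 1) / 2
  lapply(o, function(lin) {
    i <- ((lin - 1) %% n) + 1          # row (image)
    pos <- ((lin - 1) %/% n) + 1       # column within channel block
    h <- ((pos - 1) %% side) + 1
    w <- ((pos - 1) %/% side) + 1
    cy <- rf$offset + (h - 1) * rf$stride + 0.5  # 1-based pixel centre
    cx <- rf$offset + (w - 1) * rf$stride + 0.5
    ys <- max(1, round(cy - half)):min(img_side, round(cy + half))
    xs <- max(1, round(cx - half)):min(img_side, round(cx + half))
    list(image_id = names(imgs)[i] %||% i,
         activation = A[i, pos],
         crop = imgs[[i]][, ys, xs, drop = FALSE],
         center = c(y = cy, x = cx))
  })
}
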