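# Mutual information, feature correlations, receptive fields, maximally
# activating patches, embeddings, learning-curve mechanics.

test_that("mutual information hits the closed form and the null", {
  set.seed(6)
  n <- 1200
  y <- rep(1:12, each = 100)
  # neuron equal to the class index: MI = H(class) = log2(12) exactly
  act <- cbind(as.numeric(y) + 0)
  mi <- neuron_class_mutual_information(act, y, n_bins = 16)
  expect_equal(mi, log2(12), tolerance = 1e-10)
  # label-independent neurons: median MI near zero; the plug-in
  # estimator's bias is ~ (bins-1)(classes-1)/(2 n ln 2), so the null is
  # checked against 4 classes where that bias is well below 0.05 bits
  y4 <- rep(1:4, each = 300)
  noise <- matrix(stats::rnorm(n * 20), n)
  mi0 <- neuron_class_mutual_information(noise, y4, n_bins = 16)
  expect_lt(stats::median(mi0), 0.05)
  # and far below the informative-neuron MI under the 12-class label
  mi12 <- neuron_class_mutual_information(noise, y, n_bins = 16)
  expect_lt(stats::median(mi12), 0.2)
  expect_gt(mi[1], 10 * stats::median(mi12))
  # constant neuron: MI = 0 by convention, and MI is always within bounds
  cst <- cbind(rep(1, n))
  expect_equal(neuron_class_mutual_information(cst, y), 0)
  expect_true(all(mi12 >= 0))
  expect_true(all(mi12 <= min(log2(16), log2(12)) + 1e-9))
  expect_error(neuron_class_mutual_information(noise, y, n_bins = 1),
               "n_bins")
})

test_that("max feature correlation finds planted copies and rejects noise", {
  set.seed(4)
  n <- 1000
  FT <- matrix(stats::rnorm(n * 250), n)
  colnames(FT) <- paste0("f", 1:250)
  act <- cbind(copy = FT[, 17], noise = stats::rnorm(n),
               flat = rep(2, n))
  r <- max_feature_correlation(act, FT)
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_lt(r[2], 0.2)
  expect_true(is.na(r[3]))
})

test_that("receptive fields follow the stacked-convolution recursion", {
  cfg <- network_config()   # pools after 2, 4, 8
  expect_equal(receptive_field(cfg, 1)$size, 3)
  # two stacked 3x3 convolutions see 5x5 of the input
  expect_equal(receptive_field(cfg, 2, include_pool = FALSE)$size, 5)
  expect_equal(receptive_field(cfg, 2)$size, 6)   # with the 2x2 pool
  rf3 <- receptive_field(cfg, 3)
  expect_equal(rf3$size, 5 + 1 + 2 * 2)           # pool then 3x3 at stride 2
  expect_equal(rf3$stride, 2)
  # FC layers see the whole input
  expect_equal(receptive_field(cfg, 9)$size, 64)
})

test_that("top activating patches find a planted edge with a planted kernel", {
  cfg <- network_config(conv_widths = 4, pool_positions = 1,
                        fc_widths = c(8, 2), input_shape = c(2, 64, 64),
                        batchnorm = FALSE)
  net <- build_network(cfg, seed = 1)
  # plant a vertical edge detector on the green channel of channel 1
  W <- matrix(0, 18, 4)
  # rows are (kh, kw, channel): green = channel 2 block (rows 10..18)
  W[9 + c(1, 2, 3), 1] <- -1   # left column
  W[9 + c(7, 8, 9), 1] <- 1    # right column
  net$layers[[1]]$W <- W
  trained <- structure(list(config = cfg, layers = net$layers,
                            pixel_mean = array(0, c(2, 64, 64)),
                            pixel_scale = 1,
                            classes = c("a", "b")), class = "trained_cnn")
  img <- array(0, c(2, 64, 64))
  img[2, , 40:64] <- 100       # strong vertical edge at column 40
  patches <- top_activating_patches(trained, list(edge = img), 1, 1, k = 5)
  acts <- vapply(patches, `[[`, 0, "activation")
  expect_true(all(diff(acts) <= 0))          # non-increasing by rank
  # the top patch straddles the edge column
  expect_true(all(vapply(patches, function(p) abs(p$center["x"] - 39.5) <= 2,
                         TRUE)))
  expect_error(top_activating_patches(trained, list(edge = img), 1, 99),
               "out of range")
})

test_that("t-SNE embeddings have the right shape and reproducibility", {
  set.seed(12)
  X <- rbind(matrix(stats::rnorm(50 * 5), 50),
             matrix(stats::rnorm(50 * 5, mean = 6), 50))
  Y1 <- embed_2d(X, seed = 3, n_iter = 150)
  expect_equal(dim(Y1), c(100, 2))
  Y2 <- embed_2d(X, seed = 3, n_iter = 150)
  expect_identical(unclass(Y1), unclass(Y2))
  expect_error(embed_2d(matrix(1, 30, 4)), "constant")
  expect_error(embed_2d(X[1:2, ]), "at least 3")
  # two well-separated blobs stay separated in the embedding
  d_within <- stats::dist(Y1[1:50, ])
  centroid1 <- colMeans(Y1[1:50, ]); centroid2 <- colMeans(Y1[51:100, ])
  expect_gt(sqrt(sum((centroid1 - centroid2)^2)), stats::median(d_within))
  # subsampling cap records which rows were used
  Y3 <- embed_2d(X, seed = 3, n_iter = 50, max_points = 40)
  expect_equal(nrow(Y3), 40)
  expect_length(attr(Y3, "sampled_rows"), 40)
})

test_that("learning-curve machinery validates sizes and improves with data", {
  set.seed(8)
  n_per <- 40
  y <- rep(c("w", "x", "y", "z"), each = n_per)
  X <- matrix(stats::rnorm(length(y) * 10), ncol = 10)
  X[, 1] <- X[, 1] + 3 * as.integer(factor(y))   # informative feature
  idx <- seq_along(y)
  tr <- idx[idx %% 2 == 1]; rest <- idx[idx %% 2 == 0]
  va <- rest[seq(1, length(rest), 2)]; te <- rest[seq(2, length(rest), 2)]
  lc <- transfer_learning_curve(list(src = X), y, tr, va, te,
                                sizes = c(2, 10), n_reps = 2,
                                n_trees = 50, seed = 3)
  agg <- tapply(lc$accuracy, lc$size, mean)
  expect_gt(agg["10"], agg["2"])
  expect_equal(nrow(lc), 4)      # 2 sizes x 2 reps x 1 source
  expect_error(transfer_learning_curve(list(src = X), y, tr, va, te,
                                       sizes = 1000), "exceeds")
  # default size ladder is the reference one
  expect_equal(eval(formals(transfer_learning_curve)$sizes),
               c(1, 3, 5, 10, 25, 50, 100, 250, 500))
})
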