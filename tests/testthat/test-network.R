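# Architecture arithmetic, parameter counting, preprocessing, and the
# forward pass contracts.

ref_cfg <- network_config()

test_that("the reference architecture has the documented geometry", {
  expect_length(ref_cfg$conv_widths, 8)
  expect_length(ref_cfg$fc_widths, 3)
  expect_length(ref_cfg$pool_positions, 3)
  sides <- yeastloc:::conv_sides(ref_cfg)
  expect_equal(attr(sides, "final"), 8)          # 64 -> 32 -> 16 -> 8
  expect_equal(yeastloc:::flatten_width(ref_cfg), 8 * 8 * 256)
  # four poolings are allowed and give 4x4
  cfg4 <- network_config(pool_positions = c(2, 4, 6, 8))
  expect_equal(attr(yeastloc:::conv_sides(cfg4), "final"), 4)
  # input not divisible by 2^pools is rejected
  expect_error(network_config(input_shape = c(2, 60, 60)), "divisible")
})

test_that("parameter counts agree between the weight walk and the formula", {
  cfgs <- list(
    ref_cfg,
    small_network_config(12),
    network_config(conv_widths = c(4, 8), pool_positions = c(1, 2),
                   fc_widths = c(16, 5), batchnorm = FALSE),
    network_config(conv_widths = c(3, 3, 6), pool_positions = 3,
                   fc_widths = c(10, 7, 4), input_shape = c(2, 32, 32)))
  for (cfg in cfgs) {
    net <- build_network(cfg, seed = 2)
    expect_identical(count_parameters(net), parameter_count_formula(cfg))
  }
  # layer-wise oracle values: one 3x3 conv, 2 -> 64 channels = 1216
  # weights+biases; an FC layer 16384 -> 512 = 8,389,120
  lone <- network_config(conv_widths = 64, pool_positions = 1,
                         fc_widths = 4, input_shape = c(2, 8, 8),
                         batchnorm = FALSE)
  # total = conv (1216) + fc (4*4*64*4 + 4)
  expect_identical(parameter_count_formula(lone),
                   as.integer(3 * 3 * 2 * 64 + 64 + 16 * 64 * 4 + 4))
  expect_identical(16384L * 512L + 512L, 8389120L)
  # full configuration exceeds ten million learnable parameters
  expect_gt(parameter_count_formula(ref_cfg), 1e7)
})

test_that("iteration schedule reproduces the published training lengths", {
  expect_identical(iteration_schedule(65000, 100, 25), 16250L)
  expect_identical(iteration_schedule(65000, 100, 300), 195000L)
  expect_identical(iteration_schedule(100, 10, 1), 10L)
  expect_identical(iteration_schedule(101, 10, 1), 11L)  # ceil convention
  expect_error(iteration_schedule(100, 0, 1), "batch_size")
})

test_that("learning rate halves at the configured interval", {
  expect_equal(learning_rate_at(0), 0.1)
  expect_equal(learning_rate_at(16249), 0.1)
  expect_equal(learning_rate_at(16250), 0.05)
  expect_equal(learning_rate_at(48750), 0.0125)
  expect_equal(learning_rate_at(7, 0.2, 2), 0.2 * 0.5^3)
})

test_that("preprocessing subtracts the pixel mean and nothing else", {
  pm <- array(stats::runif(2 * 64 * 64, 0, 100), c(2, 64, 64))
  expect_equal(preprocess(pm, pm), pm * 0)
  img <- array(stats::runif(2 * 64 * 64), c(2, 64, 64))
  expect_equal(preprocess(img, array(0, c(2, 64, 64))), img)
  expect_error(preprocess(array(0, c(2, 32, 32)), pm), "does not match")
  # the preprocessed training fold averages to zero by construction
  imgs <- lapply(1:7, function(s) render_cell("nucleus", seed = s)$pixels)
  mean_img <- Reduce(`+`, imgs) / length(imgs)
  centred <- preprocess(imgs, mean_img)
  expect_lt(max(abs(Reduce(`+`, centred) / length(imgs))), 1e-6)
})

tiny_cfg <- network_config(conv_widths = c(4, 8), pool_positions = c(1, 2),
                           fc_widths = c(16, 3), input_shape = c(2, 64, 64))

tiny_trained <- function() {
  spec <- dataset_spec(classes = c("cellPeriphery", "nucleus", "vacuole"),
                       proteins_per_class = 3, cells_per_protein = 8,
                       fold_fractions = c(0.67, 0.33, 0), seed = 77)
  ds <- generate_dataset(spec)
  net <- build_network(tiny_cfg, seed = 4)
  list(ds = ds,
       cnn = train_network(net, ds, train_config(epochs = 2, batch_size = 24,
                                                 initial_lr = 0.05,
                                                 lr_halving_interval = 1000,
                                                 seed = 11)))
}

test_that("softmax outputs are simplices and inference is order invariant", {
  tt <- tiny_trained()
  imgs <- tt$ds$images[1:10]
  P <- predict_proba(tt$cnn, imgs)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  # duplicated input rows give identical outputs
  Pdup <- predict_proba(tt$cnn, imgs[c(1, 1, 2)])
  expect_equal(Pdup[1, ], Pdup[2, ], tolerance = 1e-12)
  # permuting the batch permutes, not changes, the rows
  perm <- c(4, 1, 3, 2, 5, 10, 7, 6, 9, 8)
  P2 <- predict_proba(tt$cnn, imgs[perm])
  expect_equal(P2, P[perm, ], tolerance = 1e-10)
  # channel-count mismatch is rejected
  bad <- list(array(0, c(3, 64, 64)))
  expect_error(predict_proba(tt$cnn, bad), "match")
})

test_that("activation extraction honours layer widths and rectification", {
  tt <- tiny_trained()
  imgs <- tt$ds$images[1:6]
  a1 <- extract_activations(tt$cnn, imgs, 1)
  expect_equal(dim(a1), c(6, 4))      # global-average pooled channels
  expect_true(all(a1 >= 0))           # ReLU outputs
  a3 <- extract_activations(tt$cnn, imgs, 3)
  expect_equal(ncol(a3), 16)          # first FC width
  expect_true(all(a3 >= 0))
  a4 <- extract_activations(tt$cnn, imgs, 4)
  expect_equal(ncol(a4), 3)           # logits width = n_classes
  P <- predict_proba(tt$cnn, imgs)
  expect_equal(unname(yeastloc:::softmax_rows(a4)), unname(P),
               tolerance = 1e-10)
  flat <- extract_activations(tt$cnn, imgs, 2, pool_channels = FALSE)
  expect_equal(ncol(flat), 16 * 16 * 8)
  expect_error(extract_activations(tt$cnn, imgs, 9), "layer_index")
})

test_that("the reference configuration exposes a 512-wide first FC layer", {
  net <- build_network(network_config(), seed = 6)
  trained <- structure(list(config = net$config, layers = net$layers,
                            pixel_mean = array(0, c(2, 64, 64)),
                            pixel_scale = 1, classes = core_classes()),
                       class = "trained_cnn")
  imgs <- list(a = render_cell("er", seed = 1)$pixels,
               b = render_cell("golgi", seed = 2)$pixels)
  a9 <- extract_activations(trained, imgs, 9)
  expect_equal(dim(a9), c(2, 512))
  expect_true(all(a9 >= 0))
  a11 <- extract_activations(trained, imgs, 11)
  expect_equal(ncol(a11), 12)     # pre-softmax logits width
})

test_that("training is reproducible and learns a separable problem", {
  spec <- dataset_spec(classes = c("nucleus", "cytoplasm"),
                       proteins_per_class = 4, cells_per_protein = 10,
                       fold_fractions = c(0.75, 0.25, 0), seed = 55)
  ds <- generate_dataset(spec)
  cfg2 <- network_config(conv_widths = c(4, 8), pool_positions = c(1, 2),
                         fc_widths = c(16, 2), input_shape = c(2, 64, 64))
  tc <- train_config(epochs = 4, batch_size = 30, initial_lr = 0.05,
                     lr_halving_interval = 1000, seed = 9)
  r1 <- train_network(build_network(cfg2, seed = 3), ds, tc)
  r2 <- train_network(build_network(cfg2, seed = 3), ds, tc)
  expect_identical(r1$history$iter_loss, r2$history$iter_loss)
  # the loss trends down: late smoothed loss below early smoothed loss
  il <- r1$history$iter_loss
  expect_lt(mean(utils::tail(il, 5)), mean(utils::head(il, 5)))
  # two visually distinct classes are learned essentially perfectly
  tr_ids <- ds$manifest$cell_id[ds$manifest$fold == "train"]
  P <- predict_proba(r1, ds$images[tr_ids])
  acc <- mean(predict_class(P) ==
                ds$manifest$label[ds$manifest$fold == "train"])
  expect_gte(acc, 0.99)
  # empty training fold is rejected
  bad <- ds; bad$manifest$fold <- "test"
  expect_error(train_network(build_network(cfg2, 3), bad, tc), "empty")
})
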