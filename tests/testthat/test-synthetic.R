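# Synthetic two-channel microscopy generator.

noise_free <- render_params(clutter_prob = 0)

test_that("renders are deterministic and well-formed for every class", {
  for (lab in c(core_classes(), transfer_classes())) {
    img <- render_cell(lab, seed = 17)
    expect_s3_class(img, "cell_image")
    expect_identical(dim(img$pixels), c(2L, 64L, 64L))
    expect_true(all(img$pixels >= 0))
    expect_true(img$quality)
  }
  a <- render_cell("mitochondrion", seed = 5)
  b <- render_cell("mitochondrion", seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, render_cell("mitochondrion", seed = 6)$pixels))
  expect_error(render_cell("lysosome"), "unknown label")
})

test_that("spindle pole renders show one or two puncta above half-max", {
  cc <- vapply(1:25, function(s) {
    g <- render_cell("spindlePole", noise_free, seed = s,
                     noiseless = TRUE)$pixels[2, , ]
    max(EBImage::bwlabel(g > max(g) / 2))
  }, 0)
  expect_true(all(cc %in% c(1, 2)))
})

test_that("puncta counts stay inside the configured per-class ranges", {
  pr <- noise_free$puncta_count_range
  for (cl in c("endosome", "golgi", "peroxisome", "spindlePole",
               "lipidParticle")) {
    cc <- vapply(1:100, function(s) {
      g <- render_cell(cl, noise_free, seed = s,
                       noiseless = TRUE)$pixels[2, , ]
      max(EBImage::bwlabel(g > max(g) / 2))
    }, 0)
    expect_gte(min(cc), pr[[cl]][1])
    expect_lte(max(cc), pr[[cl]][2])
  }
})

test_that("nuclear vs cytoplasmic signal lands in the right masks", {
  for (s in 1:5) {
    ni <- render_cell("nucleus", seed = s, noiseless = TRUE,
                      keep_masks = TRUE)
    ci <- render_cell("cytoplasm", seed = s, noiseless = TRUE,
                      keep_masks = TRUE)
    sn <- mask_intensity_stats(ni)
    sc <- mask_intensity_stats(ci)
    expect_gt(sn["nucleus"], sc["nucleus"])
    expect_gt(sc["cytoplasm"], sn["cytoplasm"])
  }
})

test_that("artifact renders have the documented failure modes", {
  p <- render_params()
  emp <- render_artifact("empty", seed = 3, params = p)
  expect_identical(emp$label, "nonCell")
  expect_false(emp$quality)
  # near-background: no pixel beyond background + gradient + noise tails
  noise_sd <- sqrt(p$noise_model$gaussian_sd^2 +
                     p$noise_model$poisson_scaling * p$background_level)
  ceiling_ <- p$background_level + p$background_gradient_amplitude / 2 +
    5 * noise_sd
  expect_lt(max(emp$pixels[2, , ]), ceiling_)

  # low-signal artifact is paired-wise dimmer than a real cell
  for (s in 1:5) {
    low <- render_artifact("low_signal", seed = s, params = p)
    cell <- render_cell("cytoplasm", p, seed = s)
    expect_lt(stats::quantile(low$pixels[2, , ], 0.99),
              stats::quantile(cell$pixels[2, , ], 0.99))
  }

  deb <- render_artifact("debris", seed = 9)
  expect_identical(deb$label, "nonCell")
  expect_identical(render_artifact("debris", seed = 9)$pixels, deb$pixels)
  expect_error(render_artifact("smudge"), "arg")
})

test_that("datasets have protein-disjoint folds and the requested sizes", {
  spec <- dataset_spec(classes = core_classes(), proteins_per_class = 5,
                       cells_per_protein = 20,
                       fold_fractions = c(0.72, 0.14, 0.14), seed = 31)
  ds <- generate_dataset(spec, render = FALSE)
  man <- ds$manifest
  expect_equal(nrow(man), 1200)
  folds_per_protein <- tapply(man$fold, man$protein_id,
                              function(x) length(unique(x)))
  expect_true(all(folds_per_protein == 1))
  by_fold <- split(man$protein_id, man$fold)
  expect_length(intersect(by_fold$train, by_fold$test), 0)
  expect_length(intersect(by_fold$train, by_fold$val), 0)
  expect_length(intersect(by_fold$val, by_fold$test), 0)
  # determinism of the whole manifest
  ds2 <- generate_dataset(spec, render = FALSE)
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("the transfer-fold layout reaches exact per-class cell counts", {
  # 4 classes, 1000/500/1000 train/val/test cells per class
  spec <- dataset_spec(classes = transfer_classes(), proteins_per_class = 5,
                       cells_per_protein = 500,
                       fold_fractions = c(0.4, 0.2, 0.4), seed = 8)
  man <- generate_dataset(spec, render = FALSE)$manifest
  counts <- table(man$label, man$fold)
  expect_true(all(counts[, "train"] == 1000))
  expect_true(all(counts[, "val"] == 500))
  expect_true(all(counts[, "test"] == 1000))
})

test_that("invalid fold fractions are rejected", {
  expect_error(dataset_spec(fold_fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("mixture proteins mix the two labels at the requested rate", {
  expect_error(generate_mixture_protein(c("nucleus", "nucleus"), 0.5, 5),
               "distinct")
  expect_error(generate_mixture_protein(c("nucleus", "cytoplasm"), 1, 5),
               "strictly between")
  expect_length(generate_mixture_protein(c("nucleus", "cytoplasm"), 0.5, 0),
                0)
  cells <- generate_mixture_protein(c("nucleus", "cytoplasm"), 0.999, 50,
                                    seed = 2, render = FALSE)
  n1 <- sum(vapply(cells, `[[`, "", "label") == "nucleus")
  expect_gte(n1, 40)   # P(Binom(50, 0.999) < 40) is negligible
  big <- generate_mixture_protein(c("nucleus", "cytoplasm"), 0.5, 1000,
                                  seed = 3, render = FALSE)
  nb <- sum(vapply(big, `[[`, "", "label") == "nucleus")
  expect_true(abs(nb - 500) <= 50)   # binomial 95% band
  expect_true(all(vapply(cells, `[[`, "", "protein_id") == "mixture_p01"))
})

test_that("masked mean-intensity statistics separate the diffuse archetypes", {
  skip_if_not_installed("MASS")
  classes <- c("cytoplasm", "nucleus", "cellPeriphery", "vacuole")
  per_class <- 200
  stats_ <- list(); y <- character(0)
  for (cl in classes) {
    for (s in seq_len(per_class)) {
      img <- render_cell(cl, seed = 1000 + s, noiseless = TRUE,
                         keep_masks = TRUE)
      stats_[[length(stats_) + 1]] <- mask_intensity_stats(img)
      y <- c(y, cl)
    }
  }
  X <- do.call(rbind, stats_)
  tr <- rep(c(TRUE, FALSE), length.out = nrow(X))
  fit <- MASS::lda(X[tr, ], grouping = y[tr])
  acc <- mean(predict(fit, X[!tr, ])$class == y[!tr])
  expect_gt(acc, 0.95)
})
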