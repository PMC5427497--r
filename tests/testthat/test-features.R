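# Hand-crafted feature families: Haralick/GLCM, Zernike, Gabor,
# intensity/geometry, and the per-dataset feature table.

rot90 <- function(m) t(m[nrow(m):1, ])

test_that("GLCM contrast matches the hand-enumerated 2x2 example", {
  # [[0,1],[0,1]] with horizontal offset, 2 levels, symmetric GLCM:
  # pairs {(0,1),(1,0)} each weight 0.5 -> contrast = sum P (i-j)^2 = 1
  img <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  h <- haralick_features(img, n_gray_levels = 2, offsets = list(c(0, 1)))
  expect_equal(unname(h["contrast"]), 1)
  expect_equal(unname(h["asm"]), 0.5)  # two equal cells of 0.5
})

test_that("constant images give convention values, not NaN", {
  h <- haralick_features(matrix(7, 16, 16))
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["asm"]), 1)
  expect_equal(unname(h["correlation"]), 0)
  expect_false(anyNA(h))
})

test_that("checkerboard has strictly higher contrast than a flat image", {
  checker <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_gt(haralick_features(checker)["contrast"],
            haralick_features(matrix(0.5, 16, 16))["contrast"])
})

test_that("the co-occurrence matrix is a normalized symmetric distribution", {
  set.seed(1)
  img <- matrix(stats::runif(64 * 64), 64)
  q <- yeastloc:::quantize_channel(img, 32)
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    P <- yeastloc:::glcm(q, 32, off)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("Zernike magnitudes are rotation invariant and vanish for zero images", {
  expect_equal(max(zernike_moments(matrix(0, 64, 64))), 0)
  set.seed(2)
  img <- matrix(stats::runif(64 * 64), 64)
  z1 <- zernike_moments(img)
  z2 <- zernike_moments(rot90(img))
  expect_equal(z1, z2, tolerance = 1e-6)
  # centred radially symmetric disk: odd angular moment ~ 0
  ctr <- 31.5
  d <- sqrt(outer((0:63 - ctr)^2, (0:63 - ctr)^2, "+"))
  disk <- (d <= 12) * 1
  z <- zernike_moments(disk)
  expect_lt(z["zer_n1_m1"], 1e-10)
  expect_error(zernike_moments(img, radius = 60), "exceeds")
})

test_that("Gabor bank is DC-free, orientation selective and quadratic in intensity", {
  g0 <- gabor_responses(matrix(5, 64, 64))
  expect_lt(max(g0[grep("energy", names(g0))]), 1e-20)
  xs <- matrix(rep(0:63, each = 64), 64)
  grating <- sin(2 * pi * 0.2 * xs)
  g <- gabor_responses(grating)
  expect_gt(g["gab_f0.200_o0.00_energy"], 100 * g["gab_f0.200_o1.57_energy"])
  g2 <- gabor_responses(2 * grating)
  expect_equal(unname(g2["gab_f0.200_o0.00_energy"] /
                        g["gab_f0.200_o0.00_energy"]), 4, tolerance = 1e-10)
  expect_error(gabor_responses(grating, frequencies = numeric(0)),
               "non-empty")
})

test_that("intensity features handle constants and a known disk mask", {
  px <- array(0, c(2, 64, 64))
  px[1, , ] <- 7
  ctr <- 31.5
  d <- sqrt(outer((0:63 - ctr)^2, (0:63 - ctr)^2, "+"))
  px[2, , ] <- (d <= 10) * 1000
  f <- intensity_geometry_features(px)
  expect_equal(unname(f["red_sd"]), 0)
  expect_equal(unname(f["red_mean"]), 7)
  # rasterized disk of radius 10: area within 5% of pi * 100
  expect_lt(abs(f["green_area"] * 64 * 64 - pi * 100) / (pi * 100), 0.05)
  expect_false(anyNA(f))
})

test_that("swapping channels swaps the channel-tagged features exactly", {
  img <- render_cell("er", seed = 33)$pixels
  swapped <- img[2:1, , ]
  f1 <- cell_features(img)
  f2 <- cell_features(swapped)
  red_tags <- grep("^red_", names(f1), value = TRUE)
  for (tag in red_tags) {
    green_tag <- sub("^red_", "green_", tag)
    expect_equal(unname(f1[tag]), unname(f2[green_tag]))
    expect_equal(unname(f1[green_tag]), unname(f2[tag]))
  }
})

test_that("every feature is finite on default renders of every class", {
  for (lab in c(core_classes(), transfer_classes())) {
    f <- cell_features(render_cell(lab, seed = 5)$pixels)
    expect_true(all(is.finite(f)), label = paste("finite features for", lab))
  }
  # artifacts too (the quality filter consumes these)
  for (kind in c("empty", "low_signal", "debris"))
    expect_true(all(is.finite(cell_features(render_artifact(kind, 3)$pixels))))
})

test_that("the feature table is deterministic, keyed and order-independent", {
  spec <- dataset_spec(classes = c("nucleus", "vacuole"),
                       proteins_per_class = 1, cells_per_protein = 5,
                       fold_fractions = c(1, 0, 0), seed = 21)
  ds <- generate_dataset(spec)
  t1 <- extract_feature_table(ds)
  expect_equal(nrow(t1), 10)
  expect_identical(rownames(t1), ds$manifest$cell_id)
  t2 <- extract_feature_table(ds)
  expect_identical(t1, t2)
  # shuffled manifest: same per-cell values, different order
  ds2 <- ds
  perm <- c(7, 2, 9, 1, 10, 3, 5, 8, 4, 6)
  ds2$manifest <- ds$manifest[perm, ]
  t3 <- extract_feature_table(ds2)
  expect_identical(t3[rownames(t1), ], t1[, ])
  expect_gte(ncol(t1), 200)

  # unreadable image: row skipped with a warning and listed as a reject
  ds3 <- ds
  ds3$images[[ds$manifest$cell_id[4]]] <- "not an image"
  expect_warning(t4 <- extract_feature_table(ds3), "skipping")
  expect_equal(nrow(t4), 9)
  expect_identical(attr(t4, "rejects"), ds$manifest$cell_id[4])
})
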