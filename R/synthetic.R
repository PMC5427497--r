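# Synthetic two-channel yeast microscopy generator.
#
# Each 64x64 patch has a red channel (cytosolic marker filling the cell
# body) and a green channel rendering one of the localization archetypes:
# rings, diffuse fills, puncta, tubules, crescents or bands.  Patterns are
# parametric cartoons built from soft-edged disks, annuli, Gaussian spots
# and random-walk threads; an intensity model (per-cell brightness jitter,
# linear background gradient, Gaussian read noise, signal-scaled Poisson
# noise) is layered on top.  All renders are pure functions of
# (label, params, seed).

IMG_SIDE <- 64L

# pixel-centre coordinate grids; row = y, col = x, origin top-left, 0-based
.grid <- local({
  x <- matrix(rep(0:(IMG_SIDE - 1), each = IMG_SIDE), IMG_SIDE)
  list(x = x, y = t(x))
})

#' Rendering parameters for the synthetic generator
#'
#' Defaults define the package's standard difficulty: cells of radius
#' 17--22 px, nucleus at 0.34 of the cell radius placed off-centre,
#' class-specific puncta count ranges, green signal-to-background of 6,
#' Gaussian read noise (sd 120 a.u. on the 16-bit scale), Poisson noise
#' with variance 2 x intensity, a linear background gradient of amplitude
#' 150 a.u., and 35% log-normal per-cell brightness jitter.
#'
#' @param cell_radius_range Numeric length-2, semi-major axis range in px.
#' @param nucleus_radius_fraction Nucleus radius as a fraction of cell radius.
#' @param puncta_count_range Named list of integer ranges per punctate class.
#' @param signal_to_background Peak green signal over background level (>1
#'   for good-quality cells).
#' @param noise_model List with `gaussian_sd` and `poisson_scaling`.
#' @param background_gradient_amplitude Peak-to-peak linear gradient, a.u.
#' @param background_level Mean background intensity, a.u.
#' @param intensity_jitter Log-normal sd of per-cell brightness scaling.
#' @return An object of class `render_params`.
#' @export
render_params <- function(cell_radius_range = c(15, 24),
                          nucleus_radius_fraction = 0.34,
                          puncta_count_range = list(
                            endosome = c(4L, 7L),
                            golgi = c(2L, 4L),
                            peroxisome = c(1L, 4L),
                            spindlePole = c(1L, 2L),
                            lipidParticle = c(4L, 10L),
                            actin = c(5L, 9L)),
                          signal_to_background = 10,
                          noise_model = list(gaussian_sd = 100,
                                             poisson_scaling = 2),
                          background_gradient_amplitude = 150,
                          background_level = 400,
                          intensity_jitter = 0.2,
                          blur_sigma_range = c(0.4, 1.6),
                          clutter_prob = 0.75,
                          clutter_max = 2L) {
  stopifnot(length(cell_radius_range) == 2,
            diff(cell_radius_range) >= 0,
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            signal_to_background > 0,
            is.list(noise_model),
            all(c("gaussian_sd", "poisson_scaling") %in% names(noise_model)))
  for (r in puncta_count_range)
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1)
      stop("puncta_count_range entries must be non-empty integer ranges")
  structure(list(cell_radius_range = cell_radius_range,
                 nucleus_radius_fraction = nucleus_radius_fraction,
                 puncta_count_range = puncta_count_range,
                 signal_to_background = signal_to_background,
                 noise_model = noise_model,
                 background_gradient_amplitude = background_gradient_amplitude,
                 background_level = background_level,
                 intensity_jitter = intensity_jitter,
                 blur_sigma_range = blur_sigma_range,
                 clutter_prob = clutter_prob,
                 clutter_max = as.integer(clutter_max)),
            class = "render_params")
}

## ---- drawing primitives (all return 64x64 matrices in [0,1]) ----

soft_disk <- function(cx, cy, r, soft = 1) {
  d <- sqrt((.grid$x - cx)^2 + (.grid$y - cy)^2)
  1 / (1 + exp((d - r) / soft))
}

soft_ellipse <- function(cx, cy, a, b, theta, soft = 1) {
  u <- (.grid$x - cx) * cos(theta) + (.grid$y - cy) * sin(theta)
  v <- -(.grid$x - cx) * sin(theta) + (.grid$y - cy) * cos(theta)
  rr <- sqrt((u / a)^2 + (v / b)^2)
  1 / (1 + exp((rr - 1) * a / soft))
}

soft_annulus <- function(cx, cy, r_in, r_out, soft = 1) {
  pmax(soft_disk(cx, cy, r_out, soft) - soft_disk(cx, cy, r_in, soft), 0)
}

gauss_spot <- function(cx, cy, sigma) {
  exp(-((.grid$x - cx)^2 + (.grid$y - cy)^2) / (2 * sigma^2))
}

# oriented soft-edged bar centred at (cx, cy)
soft_band <- function(cx, cy, theta, half_len, half_wid, soft = 0.8) {
  u <- (.grid$x - cx) * cos(theta) + (.grid$y - cy) * sin(theta)
  v <- -(.grid$x - cx) * sin(theta) + (.grid$y - cy) * cos(theta)
  (1 / (1 + exp((abs(u) - half_len) / soft))) *
    (1 / (1 + exp((abs(v) - half_wid) / soft)))
}

# curvilinear tubule: a momentum random walk stamped with Gaussian cross
# section; steered back toward the cell centre when it strays outside
# `max_r` of (ccx, ccy).  `straightness` in [0,1]: 1 = straight line.
thread_mask <- function(x0, y0, angle, n_steps, sigma, straightness,
                        ccx, ccy, max_r) {
  acc <- matrix(0, IMG_SIDE, IMG_SIDE)
  x <- x0; y <- y0; a <- angle
  turn_sd <- (1 - straightness) * 0.6
  for (i in seq_len(n_steps)) {
    acc <- acc + gauss_spot(x, y, sigma)
    a <- a + rnorm(1, 0, turn_sd)
    dx <- x + cos(a) - ccx; dy <- y + sin(a) - ccy
    if (sqrt(dx^2 + dy^2) > max_r) {
      # steer toward centre
      a_home <- atan2(ccy - y, ccx - x)
      a <- a + 0.5 * (((a_home - a + pi) %% (2 * pi)) - pi)
    }
    x <- x + cos(a); y <- y + sin(a)
  }
  pmin(acc, 1.8) / 1.8
}

# sample `n` puncta centres inside the radial band [r_lo, r_hi] (fractions
# of `r`) around (cx, cy), optionally restricted to the half-plane toward
# `side_angle`, keeping centres >= min_sep apart (rejection with fallback).
sample_puncta <- function(n, cx, cy, r, r_lo, r_hi, min_sep,
                          side_angle = NULL) {
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      ang <- if (is.null(side_angle)) runif(1, 0, 2 * pi) else
        side_angle + runif(1, -pi / 2, pi / 2)
      rad <- r * sqrt(runif(1, r_lo^2, r_hi^2))
      p <- c(cx + rad * cos(ang), cy + rad * sin(ang))
      ok <- i == 1 ||
        all(sqrt(rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                            matrix(p, i - 1, 2, byrow = TRUE))^2)) >= min_sep)
      if (ok) break
    }
    pts[i, ] <- p
  }
  pts
}

stamp_puncta <- function(pts, sigma, amp_range = c(0.9, 1.1)) {
  acc <- matrix(0, IMG_SIDE, IMG_SIDE)
  for (i in seq_len(nrow(pts))) {
    amp <- runif(1, amp_range[1], amp_range[2])
    acc <- acc + amp * gauss_spot(pts[i, 1], pts[i, 2], sigma)
  }
  acc
}

## ---- geometry of one cell ----

sample_cell_geometry <- function(params, with_bud = FALSE) {
  a <- runif(1, params$cell_radius_range[1], params$cell_radius_range[2])
  b <- a * runif(1, 0.78, 0.98)
  theta <- runif(1, 0, pi)
  # centring error of the upstream segmentation: the cell midpoint is
  # only approximately the patch midpoint
  cx <- 31.5 + runif(1, -4, 4)
  cy <- 31.5 + runif(1, -4, 4)
  # nucleus off-centre with random orientation (nucleolus crescents vary)
  rn <- a * params$nucleus_radius_fraction
  na_ <- runif(1, 0, 2 * pi)
  nd <- runif(1, 0.15, 0.38) * a
  ncx <- cx + nd * cos(na_); ncy <- cy + nd * sin(na_)
  g <- list(cx = cx, cy = cy, a = a, b = b, theta = theta,
            rn = rn, ncx = ncx, ncy = ncy, nucleus_angle = na_)
  if (with_bud) {
    bud_angle <- runif(1, 0, 2 * pi)
    rb <- a * runif(1, 0.40, 0.55)
    # bud centre sits just outside the mother boundary
    g$bud_angle <- bud_angle
    g$rb <- rb
    g$bcx <- cx + (a * 0.92 + rb * 0.55) * cos(bud_angle)
    g$bcy <- cy + (a * 0.92 + rb * 0.55) * sin(bud_angle)
  }
  g
}

cell_masks <- function(g) {
  cell <- soft_ellipse(g$cx, g$cy, g$a, g$b, g$theta, soft = 1.2)
  if (!is.null(g$rb))
    cell <- pmax(cell, soft_disk(g$bcx, g$bcy, g$rb, soft = 1.2))
  nucleus <- soft_disk(g$ncx, g$ncy, g$rn, soft = 0.9)
  list(cell = cell, nucleus = nucleus)
}

## ---- green-channel archetypes ----

render_green_pattern <- function(label, g, m, params) {
  cx <- g$cx; cy <- g$cy; a <- g$a
  ncx <- g$ncx; ncy <- g$ncy; rn <- g$rn
  # Variable cytosolic pool: a random fraction of the tagged protein is
  # diffuse in the cytoplasm, diluting the compartment pattern (strong
  # within-class heterogeneity, as in real expression data).
  haze <- runif(1, 0.05, 0.4) * m$cell
  pr <- params$puncta_count_range
  # Punctate classes share punctum size and brightness and differ mainly
  # in spatial arrangement -- endosomes on a mid-radius ring, Golgi
  # clustered around the nucleus, peroxisomes anywhere in the cytoplasm,
  # spindle poles on the nuclear rim -- mirroring the fact that punctate
  # compartments are hard to tell apart from texture alone.
  punct <- function(class, r_lo, r_hi, sigma, min_sep, side = NULL,
                    amp_range = c(0.9, 1.1), centre = c(cx, cy)) {
    k <- sample(pr[[class]][1]:pr[[class]][2], 1)
    pts <- sample_puncta(k, centre[1], centre[2], a, r_lo, min(r_hi, 0.8),
                         min_sep, side)
    stamp_puncta(pts, sigma, amp_range)
  }
  pat <- switch(label,
    cellPeriphery = {
      edge <- soft_ellipse(cx, cy, a, g$b, g$theta, 1.2) -
        soft_ellipse(cx, cy, a * 0.82, g$b * 0.82, g$theta, 1.2)
      pmax(edge, 0)
    },
    cytoplasm = m$cell * (1 - 0.92 * m$nucleus),
    nucleus = m$nucleus,
    nucleolus = {
      # crescent: off-centre blob clipped by the nuclear boundary
      ca <- g$nucleus_angle + runif(1, -0.6, 0.6)
      off <- rn * 0.55
      blob <- soft_disk(ncx + off * cos(ca), ncy + off * sin(ca),
                        rn * 0.62, 0.7)
      bite <- soft_disk(ncx + 1.9 * off * cos(ca), ncy + 1.9 * off * sin(ca),
                        rn * 0.55, 0.7)
      pmax(blob * m$nucleus - 0.8 * bite, 0)
    },
    nuclearPeriphery = soft_annulus(ncx, ncy, rn * 0.80, rn * 1.22, 0.8),
    er = {
      ring <- soft_annulus(ncx, ncy, rn * 0.85, rn * 1.35, 0.9)
      strands <- matrix(0, IMG_SIDE, IMG_SIDE)
      for (i in seq_len(sample(1:2, 1))) {
        sa <- runif(1, 0, 2 * pi)
        strands <- strands + thread_mask(ncx + rn * 1.2 * cos(sa),
                                         ncy + rn * 1.2 * sin(sa),
                                         sa, n_steps = round(a * 0.7),
                                         sigma = 0.9, straightness = 0.8,
                                         cx, cy, a * 0.92)
      }
      pmax(ring, 0) + pmin(strands, 1) * 0.6 * m$cell
    },
    mitochondrion = {
      tub <- matrix(0, IMG_SIDE, IMG_SIDE)
      for (i in seq_len(sample(3:5, 1))) {
        sa <- runif(1, 0, 2 * pi)
        r0 <- runif(1, 0.3, 0.75) * a
        tub <- tub + thread_mask(cx + r0 * cos(sa), cy + r0 * sin(sa),
                                 runif(1, 0, 2 * pi),
                                 n_steps = round(a * 1.5), sigma = 1.1,
                                 straightness = 0.55, cx, cy, a * 0.88)
      }
      pmin(tub, 1) * pmax(m$cell, 0.15)
    },
    vacuole = {
      va <- g$nucleus_angle + pi + runif(1, -0.7, 0.7)
      rv <- a * runif(1, 0.38, 0.5)
      vd <- a * 0.42
      vcx <- cx + vd * cos(va); vcy <- cy + vd * sin(va)
      rim <- soft_annulus(vcx, vcy, rv * 0.82, rv * 1.1, 0.8)
      lumen <- soft_disk(vcx, vcy, rv * 0.82, 0.8)
      0.45 * rim + 0.06 * lumen + 0.3 * m$cell * (1 - lumen)
    },
    endosome = punct("endosome", 0.25, 0.65, 0.95, 5, amp_range = c(0.8, 1.2),
                     side = g$nucleus_angle + pi),
    golgi = punct("golgi", 0.4, 0.6, 1.7, 8, centre = c(ncx, ncy),
                  amp_range = c(0.8, 1.2)),
    peroxisome = punct("peroxisome", 0.62, 0.8, 1.2, 6,
                       amp_range = c(0.8, 1.2)),
    spindlePole = {
      k <- sample(pr$spindlePole[1]:pr$spindlePole[2], 1)
      a1 <- runif(1, 0, 2 * pi)
      angs <- if (k == 2) c(a1, a1 + pi + runif(1, -0.5, 0.5)) else a1
      acc <- matrix(0, IMG_SIDE, IMG_SIDE)
      for (an in angs)
        acc <- acc + runif(1, 0.9, 1.1) *
          gauss_spot(ncx + rn * 1.25 * cos(an), ncy + rn * 1.25 * sin(an), 1.2)
      acc
    },
    lipidParticle = punct("lipidParticle", 0.2, 0.8, 1.0, 5),
    actin = {
      side <- runif(1, 0, 2 * pi)
      patches <- punct("actin", 0.45, 0.95, 1.2, 5, side = side)
      cable <- thread_mask(cx - 0.6 * a * cos(side), cy - 0.6 * a * sin(side),
                           side, n_steps = round(a * 1.2), sigma = 0.9,
                           straightness = 0.85, cx, cy, a * 0.92)
      patches + 0.55 * cable * m$cell
    },
    budNeck = {
      neck_x <- g$cx + g$a * 0.92 * cos(g$bud_angle)
      neck_y <- g$cy + g$a * 0.92 * sin(g$bud_angle)
      soft_band(neck_x, neck_y, g$bud_angle + pi / 2,
                half_len = g$rb * 0.75, half_wid = 1.6)
    },
    microtubule = {
      sa <- runif(1, 0, 2 * pi)
      acc <- matrix(0, IMG_SIDE, IMG_SIDE)
      for (i in seq_len(sample(1:2, 1)))
        acc <- acc + thread_mask(ncx + rn * 1.1 * cos(sa), ncy + rn * 1.1 * sin(sa),
                                 sa + (i - 1) * pi + runif(1, -0.3, 0.3),
                                 n_steps = round(a * 1.5), sigma = 0.9,
                                 straightness = 0.92, cx, cy, a * 0.95)
      pmin(acc, 1)
    },
    stop("unknown label: ", label)
  )
  pmin(pat + haze, 1.3)
}

## ---- intensity / noise model ----

# Gaussian blur via FFT with a cached circular kernel (sigma quantized to
# 0.05 px).  Circular wrap-around only affects content touching the patch
# border (neighbour-cell slivers), which is incidental clutter anyway.
.blur_cache <- new.env(parent = emptyenv())

blur_mat <- function(m, sigma) {
  if (sigma <= 0.01) return(m)
  sq <- round(sigma / 0.05) * 0.05
  key <- sprintf("%.2f", sq)
  K <- .blur_cache[[key]]
  if (is.null(K)) {
    n <- IMG_SIDE
    d <- c(0:(n / 2), (n / 2 - 1):1)
    g1 <- exp(-d^2 / (2 * sq^2))
    k2 <- outer(g1, g1)
    K <- stats::fft(k2 / sum(k2))
    .blur_cache[[key]] <- K
  }
  Re(stats::fft(stats::fft(m) * K, inverse = TRUE)) / length(m)
}

linear_gradient <- function(amplitude) {
  ang <- runif(1, 0, 2 * pi)
  u <- ((.grid$x - 31.5) * cos(ang) + (.grid$y - 31.5) * sin(ang)) / IMG_SIDE
  amplitude * u
}

apply_noise <- function(img, params) {
  nm <- params$noise_model
  img <- img + linear_gradient(params$background_gradient_amplitude)
  n <- length(img)
  img <- img +
    sqrt(pmax(img, 0) * nm$poisson_scaling) * rnorm(n) +
    rnorm(n, 0, nm$gaussian_sd)
  pmin(pmax(img, 0), 65535)
}

## ---- public render operations ----

#' Render one synthetic cell image
#'
#' Draws a two-channel 64x64 patch for the requested localization class:
#' the red channel fills the simulated cell body (cytosolic marker, dimmed
#' inside the nucleus and vacuole lumen), the green channel renders the
#' class archetype, then the intensity model (brightness jitter, background
#' gradient, Gaussian + Poisson noise) is applied unless `noiseless`.
#'
#' @param label One of `core_classes()` or `transfer_classes()`.
#' @param params A [render_params()] object.
#' @param seed Integer seed; renders are bit-identical for identical inputs.
#' @param noiseless Skip jitter/gradient/noise (used for geometric checks).
#' @param keep_masks Attach the generating cell and nucleus masks as the
#'   `"masks"` attribute.
#' @return A `cell_image`: list with `pixels` (2 x 64 x 64 array, channel 1
#'   red, channel 2 green), `label`, `protein_id`, `fold`, `quality`.
#' @export
render_cell <- function(label, params = render_params(), seed = 1L,
                        noiseless = FALSE, keep_masks = FALSE) {
  vocab <- c(core_classes(), transfer_classes())
  if (!is.character(label) || length(label) != 1 || !(label %in% vocab))
    stop("unknown label '", label, "'; must be one of: ",
         paste(vocab, collapse = ", "))
  with_seed(seed, {
    g <- sample_cell_geometry(params, with_bud = identical(label, "budNeck"))
    m <- cell_masks(g)
    bg <- params$background_level
    amp_g <- bg * (params$signal_to_background - 1)
    amp_r <- bg * 3.5
    red_pat <- m$cell * (1 - 0.35 * m$nucleus)
    green_pat <- render_green_pattern(label, g, m, params)
    # Partial neighbouring cells at the patch border: every cell in a
    # screen image carries the same tagged protein, so neighbours show the
    # same localization pattern, just centred outside the patch.
    n_nb <- if (runif(1) < params$clutter_prob)
      sample.int(params$clutter_max, 1) else 0L
    for (nb in seq_len(n_nb)) {
      ang <- runif(1, 0, 2 * pi)
      dist <- runif(1, 1.35, 1.7) * g$a
      gn <- sample_cell_geometry(params,
                                 with_bud = identical(label, "budNeck"))
      dx <- g$cx + dist * cos(ang) - gn$cx
      dy <- g$cy + dist * sin(ang) - gn$cy
      gn$cx <- gn$cx + dx; gn$cy <- gn$cy + dy
      gn$ncx <- gn$ncx + dx; gn$ncy <- gn$ncy + dy
      if (!is.null(gn$rb)) {
        gn$bcx <- gn$bcx + dx; gn$bcy <- gn$bcy + dy
      }
      mn <- cell_masks(gn)
      amp_nb <- runif(1, 0.8, 1.1)
      red_pat <- pmax(red_pat, amp_nb * mn$cell * (1 - 0.35 * mn$nucleus))
      green_pat <- pmax(green_pat,
                        amp_nb * render_green_pattern(label, gn, mn, params))
    }
    # independent per-channel brightness jitter (illumination and
    # expression-level variation across cells and wells)
    scale_r <- if (noiseless) 1 else exp(rnorm(1, 0, params$intensity_jitter))
    scale_g <- if (noiseless) 1 else exp(rnorm(1, 0, params$intensity_jitter))
    if (!noiseless) {
      # focal-plane variation: one defocus blur per cell, both channels
      bs <- runif(1, params$blur_sigma_range[1], params$blur_sigma_range[2])
      red_pat <- blur_mat(red_pat, bs)
      green_pat <- blur_mat(green_pat, bs)
    }
    red <- bg + amp_r * red_pat * scale_r
    green <- bg + amp_g * green_pat * scale_g
    if (!noiseless) {
      red <- apply_noise(red, params)
      green <- apply_noise(green, params)
    }
    px <- array(0, c(2L, IMG_SIDE, IMG_SIDE))
    px[1, , ] <- red
    px[2, , ] <- green
    out <- structure(list(pixels = px, label = label, protein_id = NA_character_,
                          fold = "none", quality = TRUE),
                     class = "cell_image")
    if (keep_masks) attr(out, "masks") <- m
    out
  })
}

#' Render a non-cell artifact image
#'
#' Produces the image-quality failure modes seen in screens: `"empty"`
#' (background only), `"low_signal"` (a cell whose green signal sits below
#' the quality threshold), `"debris"` (red streaks/blobs lacking a
#' cell-shaped component).
#'
#' @param kind One of `"empty"`, `"low_signal"`, `"debris"`.
#' @param seed Integer seed.
#' @param params A [render_params()] object.
#' @return A `cell_image` with `label = "nonCell"`, `quality = FALSE`.
#' @export
render_artifact <- function(kind = c("empty", "low_signal", "debris"),
                            seed = 1L, params = render_params()) {
  kind <- match.arg(kind)
  bg <- params$background_level
  img <- switch(kind,
    empty = with_seed(seed, {
      px <- array(0, c(2L, IMG_SIDE, IMG_SIDE))
      px[1, , ] <- apply_noise(matrix(bg, IMG_SIDE, IMG_SIDE), params)
      px[2, , ] <- apply_noise(matrix(bg, IMG_SIDE, IMG_SIDE), params)
      px
    }),
    low_signal = {
      p2 <- params
      p2$signal_to_background <- 1.25
      p2$intensity_jitter <- 0.1
      lab <- with_seed(derive_seed(seed, 1L),
                       sample(core_classes(), 1))
      render_cell(lab, p2, seed)$pixels
    },
    debris = with_seed(seed, {
      acc <- matrix(0, IMG_SIDE, IMG_SIDE)
      for (i in seq_len(sample(2:4, 1))) {
        x0 <- runif(1, 8, 56); y0 <- runif(1, 8, 56)
        acc <- acc + thread_mask(x0, y0, runif(1, 0, 2 * pi),
                                 n_steps = sample(15:40, 1),
                                 sigma = runif(1, 1.5, 3),
                                 straightness = 0.6, 31.5, 31.5, 40)
      }
      red <- bg + bg * 3.5 * pmin(acc, 1)
      green <- matrix(bg, IMG_SIDE, IMG_SIDE) + bg * 0.4 * pmin(acc, 1)
      px <- array(0, c(2L, IMG_SIDE, IMG_SIDE))
      px[1, , ] <- apply_noise(red, params)
      px[2, , ] <- apply_noise(green, params)
      px
    })
  )
  structure(list(pixels = img, label = "nonCell", protein_id = NA_character_,
                 fold = "none", quality = FALSE),
            class = "cell_image")
}

#' Dataset specification
#'
#' @param classes Character vector of class labels to simulate.
#' @param proteins_per_class Number of distinct proteins per class.
#' @param cells_per_protein Cells imaged per protein.
#' @param fold_fractions Length-3 proportions (train/val/test) summing to 1;
#'   folds are assigned at the protein level so no protein spans folds.
#' @param seed Master seed; all per-cell seeds derive from it by a
#'   counter-based scheme (see [render_cell()]).
#' @param params A [render_params()] object.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(classes = core_classes(), proteins_per_class = 5L,
                         cells_per_protein = 20L,
                         fold_fractions = c(train = 0.72, val = 0.14, test = 0.14),
                         seed = 1L, params = render_params()) {
  if (abs(sum(fold_fractions) - 1) > 1e-9)
    stop("fold_fractions must sum to 1 (got ", sum(fold_fractions), ")")
  stopifnot(length(fold_fractions) == 3, proteins_per_class >= 1,
            cells_per_protein >= 1, length(classes) >= 1)
  names(fold_fractions) <- c("train", "val", "test")
  structure(list(classes = classes, proteins_per_class = proteins_per_class,
                 cells_per_protein = cells_per_protein,
                 fold_fractions = fold_fractions, seed = as.integer(seed),
                 params = params),
            class = "dataset_spec")
}

# largest-remainder apportionment of n items into fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic dataset
#'
#' Renders `cells_per_protein` images for each of
#' `proteins_per_class x length(classes)` simulated proteins and assigns
#' every protein (hence all its cells) to exactly one fold by
#' largest-remainder apportionment of `fold_fractions` within each class,
#' so folds are protein-disjoint by construction.
#'
#' @param spec A [dataset_spec()].
#' @param dir Optional directory; when given, images are written as 2-page
#'   16-bit TIFFs and the manifest as `manifest.tsv`.
#' @param render Render pixel data (default).  `render = FALSE` builds the
#'   manifest only (fold/arithmetic checks at sizes where rendering every
#'   cell would be wasteful).
#' @return A `cell_dataset`: list with `manifest` (data.frame with columns
#'   cell_id, image, protein_id, label, fold, quality), `images` (named
#'   list of 2x64x64 arrays), `classes`, `spec`.
#' @export
generate_dataset <- function(spec, dir = NULL, render = TRUE) {
  stopifnot(inherits(spec, "dataset_spec"))
  rows <- list(); images <- list()
  counter <- 0L
  for (ci in seq_along(spec$classes)) {
    label <- spec$classes[ci]
    np <- spec$proteins_per_class
    n_fold <- apportion(np, spec$fold_fractions)
    fold_of <- rep(c("train", "val", "test"), n_fold)
    # shuffle which proteins land in which fold, deterministically
    fold_of <- with_seed(derive_seed(spec$seed, ci, 7L), sample(fold_of))
    for (pi in seq_len(np)) {
      pid <- sprintf("%s_p%02d", label, pi)
      for (k in seq_len(spec$cells_per_protein)) {
        counter <- counter + 1L
        cid <- sprintf("cell%06d", counter)
        rows[[counter]] <- data.frame(
          cell_id = cid, image = paste0(cid, ".tif"), protein_id = pid,
          label = label, fold = fold_of[pi], quality = TRUE,
          stringsAsFactors = FALSE)
        if (render)
          images[[cid]] <- render_cell(label, spec$params,
                                       seed = derive_seed(spec$seed,
                                                          counter))$pixels
      }
    }
  }
  manifest <- do.call(rbind, rows)
  ds <- structure(list(manifest = manifest, images = images,
                       classes = spec$classes, spec = spec),
                  class = "cell_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Generate cells for a protein localized to two compartments
#'
#' Each cell is independently rendered from `labels[1]` with probability
#' `fraction`, otherwise from `labels[2]`; all cells share one protein id.
#'
#' @param labels Two distinct compartment labels.
#' @param fraction Probability of the first label, in (0, 1).
#' @param n_cells Number of cells.
#' @param seed Master seed.
#' @param params A [render_params()].
#' @param protein_id Protein identifier shared by all cells.
#' @param render Render pixels (`FALSE` gives label-only stubs for
#'   checking the mixing process at scale).
#' @return List of `cell_image` objects (empty when `n_cells = 0`).
#' @export
generate_mixture_protein <- function(labels, fraction, n_cells, seed = 1L,
                                     params = render_params(),
                                     protein_id = "mixture_p01",
                                     render = TRUE) {
  if (length(labels) != 2 || labels[1] == labels[2])
    stop("labels must be two distinct compartments")
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be strictly between 0 and 1")
  if (n_cells == 0) return(list())
  pick <- with_seed(derive_seed(seed, 0L, 3L),
                    rbinom(n_cells, 1, fraction))
  lapply(seq_len(n_cells), function(i) {
    lab <- if (pick[i] == 1) labels[1] else labels[2]
    img <- if (render) render_cell(lab, params, seed = derive_seed(seed, i))
           else structure(list(pixels = NULL, label = lab,
                               protein_id = NA_character_, fold = "none",
                               quality = TRUE), class = "cell_image")
    img$protein_id <- protein_id
    img
  })
}

#' Masked mean-intensity summary statistics
#'
#' Five green-channel means over generator masks (nucleus, cytoplasm
#' excluding nucleus, peripheral band, perinuclear annulus, whole cell),
#' used to verify that archetypes are linearly separable.  Requires the
#' image to carry its `"masks"` attribute (`keep_masks = TRUE`).
#'
#' @param img A `cell_image` rendered with `keep_masks = TRUE`.
#' @return Named numeric vector of length 5.
#' @export
mask_intensity_stats <- function(img) {
  m <- attr(img, "masks")
  if (is.null(m)) stop("image lacks masks; render with keep_masks = TRUE")
  g <- img$pixels[2, , ]
  cell <- m$cell > 0.5; nuc <- m$nucleus > 0.5
  interior <- m$cell > 0.9
  periph <- cell & !interior
  wmean <- function(mask) if (any(mask)) mean(g[mask]) else 0
  perinuc <- (soften_outline(m$nucleus)) & cell
  c(nucleus = wmean(nuc & cell),
    cytoplasm = wmean(interior & !nuc),
    periphery = wmean(periph),
    perinuclear = wmean(perinuc),
    whole_cell = wmean(cell))
}

# band around the 0.5 contour of a soft mask
soften_outline <- function(soft_mask) soft_mask > 0.15 & soft_mask < 0.85
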