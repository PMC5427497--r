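# Hand-crafted feature families for the baseline classifier: per channel
# and per scale (full resolution and 2x downsampled), Haralick co-occurrence
# statistics, Gabor filter-bank responses, Zernike moment magnitudes, and
# intensity/geometry summaries, plus cross-channel features.  These
# families stand in for the CellProfiler-style measurement battery used by
# classic localization pipelines.

#' Haralick texture features
#'
#' Quantizes the channel to `n_gray_levels` by channel min--max, builds the
#' symmetric normalized gray-level co-occurrence matrix for each offset
#' (default: 4 directions at distance 1), computes 13 Haralick statistics
#' per offset and averages them over offsets.
#'
#' A constant image yields the single-cell GLCM, for which the statistics
#' are defined by convention (contrast 0, angular second moment 1,
#' correlation 0) rather than NaN.
#'
#' @param channel Numeric matrix (one image channel).
#' @param n_gray_levels Number of quantization levels (default 32).
#' @param offsets List of integer c(dy, dx) offsets.
#' @return Named numeric vector of 13 features.
#' @export
haralick_features <- function(channel, n_gray_levels = 32,
                              offsets = list(c(0, 1), c(1, 0),
                                             c(1, 1), c(1, -1))) {
  stopifnot(is.matrix(channel), n_gray_levels >= 1, length(offsets) >= 1)
  q <- quantize_channel(channel, n_gray_levels)
  per <- vapply(offsets, function(off) {
    P <- glcm(q, n_gray_levels, off)
    haralick_stats(P)
  }, numeric(13))
  rowMeans(per)
}

quantize_channel <- function(channel, n_levels) {
  rng <- range(channel)
  if (rng[1] == rng[2]) return(matrix(1L, nrow(channel), ncol(channel)))
  q <- floor((channel - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L
  q[q > n_levels] <- n_levels
  q
}

# symmetric, normalized co-occurrence matrix for one offset
glcm <- function(q, n_levels, offset) {
  dy <- offset[1]; dx <- offset[2]
  H <- nrow(q); W <- ncol(q)
  ys <- seq_len(H); xs <- seq_len(W)
  y1 <- ys[ys + dy >= 1 & ys + dy <= H]
  x1 <- xs[xs + dx >= 1 & xs + dx <= W]
  a <- q[y1, x1, drop = FALSE]
  b <- q[y1 + dy, x1 + dx, drop = FALSE]
  tab <- matrix(tabulate(a + (b - 1L) * n_levels, nbins = n_levels^2),
                n_levels, n_levels)
  counts <- tab + t(tab)
  counts / sum(counts)
}

haralick_stats <- function(P) {
  n <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  idm <- sum(P / (1 + (i - j)^2))
  ent <- -sum(P[P > 0] * log2(P[P > 0]))
  # sum / difference distributions
  k_sum <- 2:(2 * n)
  p_sum <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  if (length(p_sum) < length(k_sum)) {  # guard: all sums present for n>=1
    full <- numeric(length(k_sum))
    full[sort(unique(as.vector(i + j))) - 1] <- p_sum
    p_sum <- full
  }
  k_dif <- 0:(n - 1)
  p_dif <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  if (length(p_dif) < n) {
    full <- numeric(n)
    full[sort(unique(as.vector(abs(i - j)))) + 1] <- p_dif
    p_dif <- full
  }
  sum_avg <- sum(k_sum * p_sum)
  sum_var <- sum((k_sum - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0]))
  dif_avg <- sum(k_dif * p_dif)
  dif_var <- sum((k_dif - dif_avg)^2 * p_dif)
  dif_ent <- -sum(p_dif[p_dif > 0] * log2(p_dif[p_dif > 0]))
  # information measures of correlation
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  pxy <- outer(px, px)
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = sig2, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = ent, dif_var = dif_var, dif_ent = dif_ent,
    imc1 = imc1, imc2 = imc2)
}

# cached Zernike polynomial basis over a centred disk
.zernike_cache <- new.env(parent = emptyenv())

zernike_basis <- function(side, radius, max_order) {
  key <- paste(side, radius, max_order, sep = "_")
  if (!is.null(.zernike_cache[[key]])) return(.zernike_cache[[key]])
  ctr <- (side - 1) / 2
  xs <- (0:(side - 1) - ctr) / radius
  X <- matrix(rep(xs, each = side), side)
  Y <- t(X)
  rho <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  inside <- rho <= 1
  nm <- list(); basis <- list()
  for (n in 0:max_order) for (m in seq(n %% 2, n, by = 2)) {
    # radial polynomial R_n^m
    R <- matrix(0, side, side)
    for (s in 0:((n - m) / 2)) {
      coef <- (-1)^s * factorial(n - s) /
        (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
      R <- R + coef * rho^(n - 2 * s)
    }
    Vre <- R * cos(m * theta) * inside
    Vim <- R * sin(m * theta) * inside
    nm[[length(nm) + 1]] <- c(n, m)
    basis[[length(basis) + 1]] <- complex(real = Vre, imaginary = -Vim)
  }
  B <- do.call(cbind, lapply(basis, as.vector))
  out <- list(B = B, nm = nm, n_inside = sum(inside))
  .zernike_cache[[key]] <- out
  out
}

#' Zernike moment magnitudes
#'
#' Moments over a disk of `radius` pixels centred on the patch centre, for
#' all (n, m) with n <= `max_order`, m >= 0 and n - m even.  Magnitudes
#' only, which makes them rotation invariant.
#'
#' @param channel Numeric matrix.
#' @param radius Disk radius in pixels (must fit inside the patch).
#' @param max_order Maximum radial order n.
#' @return Named numeric vector `zer_n<k>_m<l>`.
#' @export
zernike_moments <- function(channel, radius = 32, max_order = 9) {
  side <- nrow(channel)
  if (radius > side / 2 + 0.5)
    stop("radius ", radius, " exceeds patch half-side")
  zb <- zernike_basis(side, radius, max_order)
  v <- as.vector(channel)
  mom <- abs(crossprod(zb$B, v)) / zb$n_inside
  nm <- vapply(zb$nm, function(p) sprintf("zer_n%d_m%d", p[1], p[2]), "")
  stats::setNames(as.vector(mom), nm)
}

# cached zero-mean Gabor filter bank in the frequency domain
.gabor_cache <- new.env(parent = emptyenv())

gabor_bank_fft <- function(side, frequencies, orientations) {
  key <- paste(side, paste(frequencies, collapse = ","),
               paste(round(orientations, 4), collapse = ","), sep = "_")
  if (!is.null(.gabor_cache[[key]])) return(.gabor_cache[[key]])
  ctr <- (side - 1) / 2
  xs <- 0:(side - 1) - ctr
  X <- matrix(rep(xs, each = side), side)
  Y <- t(X)
  bank <- list()
  for (f in frequencies) for (th in orientations) {
    sigma <- 1 / (2 * f)      # bandwidth tied to wavelength
    u <- X * cos(th) + Y * sin(th)
    v <- -X * sin(th) + Y * cos(th)
    g <- exp(-(u^2 + v^2) / (2 * sigma^2)) * cos(2 * pi * f * u)
    g <- g - mean(g)          # DC-free
    bank[[sprintf("f%.3f_o%.2f", f, th)]] <- stats::fft(g)
  }
  .gabor_cache[[key]] <- bank
  bank
}

#' Gabor filter-bank responses
#'
#' Convolves the channel (circularly, via FFT) with a zero-mean Gabor bank
#' and reports mean absolute response and mean energy per
#' (frequency, orientation).
#'
#' @param channel Numeric matrix.
#' @param frequencies Spatial frequencies in cycles/pixel.
#' @param orientations Orientations in radians.
#' @return Named numeric vector, 2 entries per filter.
#' @export
gabor_responses <- function(channel, frequencies = c(0.1, 0.2, 0.3),
                            orientations = seq(0, 3) * pi / 4) {
  if (length(frequencies) == 0 || length(orientations) == 0)
    stop("filter bank must be non-empty")
  side <- nrow(channel)
  bank <- gabor_bank_fft(side, frequencies, orientations)
  Fimg <- stats::fft(channel)
  out <- numeric(0)
  for (nm in names(bank)) {
    resp <- Re(stats::fft(Fimg * bank[[nm]], inverse = TRUE)) / length(channel)
    out[paste0("gab_", nm, "_mag")] <- mean(abs(resp))
    out[paste0("gab_", nm, "_energy")] <- mean(resp^2)
  }
  out
}

#' Intensity and geometry features for a two-channel image
#'
#' Per channel: intensity summaries (mean, median, sd, min, max, quartile
#' and decile quantiles) and Otsu-mask geometry (area fraction, perimeter,
#' eccentricity, centroid offset from the patch centre); plus cross-channel
#' green--red Pearson correlation and mean-intensity ratio.  Degenerate
#' (empty) masks yield sentinel zeros, never NaN.
#'
#' @param pixels 2 x H x W array (channel 1 red, channel 2 green).
#' @return Named numeric vector.
#' @export
intensity_geometry_features <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[1] == 2)
  out <- numeric(0)
  for (ch in 1:2) {
    tag <- c("red", "green")[ch]
    m <- pixels[ch, , ]
    qs <- stats::quantile(m, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
    out[paste0(tag, c("_mean", "_median", "_sd", "_min", "_max",
                      "_q10", "_q25", "_q75", "_q90"))] <-
      c(mean(m), stats::median(m), stats::sd(m), min(m), max(m), qs)
    out <- c(out, mask_geometry(m, tag))
  }
  r <- pixels[1, , ]; g <- pixels[2, , ]
  out["gr_cor"] <- if (stats::sd(r) > 0 && stats::sd(g) > 0)
    stats::cor(as.vector(g), as.vector(r)) else 0
  out["gr_ratio"] <- if (mean(r) > 0) mean(g) / mean(r) else 0
  out
}

mask_geometry <- function(m, tag) {
  rng <- range(m)
  feats <- c(area = 0, perimeter = 0, eccentricity = 0, centroid_offset = 0)
  if (rng[2] > rng[1]) {
    mn <- (m - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(mn), range = c(0, 1))
    mask <- mn > th
    if (any(mask)) {
      area <- sum(mask)
      er <- mask & !(rbind(FALSE, mask[-nrow(mask), ]) &
                     rbind(mask[-1, ], FALSE) &
                     cbind(FALSE, mask[, -ncol(mask)]) &
                     cbind(mask[, -1], FALSE))
      ys <- row(mask)[mask]; xs <- col(mask)[mask]
      myy <- mean(ys); mxx <- mean(xs)
      cyy <- ys - myy; cxx <- xs - mxx
      sxx <- mean(cxx^2); syy <- mean(cyy^2); sxy <- mean(cxx * cyy)
      tr2 <- (sxx + syy) / 2
      det_ <- sqrt(max(0, ((sxx - syy) / 2)^2 + sxy^2))
      l1 <- tr2 + det_; l2 <- max(tr2 - det_, 0)
      ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
      ctr <- (nrow(m) + 1) / 2
      feats <- c(area = area / length(m), perimeter = sum(er),
                 eccentricity = ecc,
                 centroid_offset = sqrt((myy - ctr)^2 + (mxx - ctr)^2))
    }
  }
  stats::setNames(feats, paste0(tag, "_", names(feats)))
}

downsample2 <- function(m) {
  H <- nrow(m) %/% 2L; W <- ncol(m) %/% 2L
  0.25 * (m[2 * seq_len(H) - 1, 2 * seq_len(W) - 1] +
          m[2 * seq_len(H), 2 * seq_len(W) - 1] +
          m[2 * seq_len(H) - 1, 2 * seq_len(W)] +
          m[2 * seq_len(H), 2 * seq_len(W)])
}

#' Full feature vector for one cell image
#'
#' Concatenates, per channel and per scale (full resolution and 2x
#' box-downsampled), the Haralick, Gabor and Zernike families, plus the
#' intensity/geometry block.  Feature names are stable and identical
#' across cells.
#'
#' @param pixels 2 x 64 x 64 array, or a `cell_image`.
#' @return Named numeric vector (~330 features).
#' @export
cell_features <- function(pixels) {
  if (inherits(pixels, "cell_image")) pixels <- pixels$pixels
  out <- intensity_geometry_features(pixels)
  for (ch in 1:2) {
    tag <- c("red", "green")[ch]
    m <- pixels[ch, , ]
    for (sc in 1:2) {
      if (sc == 2) m <- downsample2(m)
      pre <- sprintf("%s_s%d_", tag, sc)
      h <- haralick_features(m)
      g <- gabor_responses(m)
      z <- zernike_moments(m, radius = ncol(m) / 2, max_order = 9)
      block <- c(h, g, z)
      names(block) <- paste0(pre, names(block))
      out <- c(out, block)
    }
  }
  out
}

#' Feature table for a whole dataset
#'
#' One row per cell in manifest order, fixed column set; row names are the
#' cell ids.  Unreadable images are skipped with a warning and reported in
#' the `"rejects"` attribute.
#'
#' @param data A `cell_dataset`, or list with `manifest` and `images`.
#' @return Numeric matrix n_cells x n_features with a `"rejects"` attribute.
#' @export
extract_feature_table <- function(data) {
  man <- data$manifest
  rows <- vector("list", nrow(man))
  ok <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    px <- data$images[[man$cell_id[i]]]
    res <- tryCatch(cell_features(px), error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping cell ", man$cell_id[i], ": ", conditionMessage(res))
    } else {
      rows[[i]] <- res; ok[i] <- TRUE
    }
  }
  tab <- do.call(rbind, rows[ok])
  rownames(tab) <- man$cell_id[ok]
  attr(tab, "rejects") <- man$cell_id[!ok]
  tab
}
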