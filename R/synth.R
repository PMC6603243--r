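#' @title Synthetic inputs: power-law fields, maximum-entropy textures, phantoms
#' @description Generators that emulate the statistical structure the analysis
#'   pipeline assumes, standing in for restricted MRI databases: stationary
#'   Gaussian random fields with power-law spectra (optionally with extra
#'   power on the frequency axes), binary textures with one prescribed local
#'   statistic, and multi-slice brain-like phantom volumes with tissue-class
#'   contrast and additive white noise.
#' @name synth
NULL

# Target power spectrum P(k) = |k|^(-slope) (in FFT bin order), with axis
# bins multiplied by axis_gain and DC set to 0. This is the spectrum the
# generated fields realize exactly in expectation (up to the n^2 periodogram
# factor of the unnormalized-FFT convention).
power_law_spectrum <- function(height, width, slope, axis_gain = 1,
                               pixel_mm = 1) {
  pm <- as_pixel_mm(pixel_mm)
  ky <- matrix(fft_freq(height, pm[1]), height, width)
  kx <- matrix(fft_freq(width, pm[2]), height, width, byrow = TRUE)
  km <- sqrt(kx^2 + ky^2)
  P <- matrix(0, height, width)
  off <- km > 0
  P[off] <- km[off]^(-slope)
  ax <- off & (kx == 0 | ky == 0)
  P[ax] <- P[ax] * axis_gain
  P
}

#' Generate a Gaussian random field with a power-law spectrum
#'
#' Builds a real, periodic, stationary Gaussian field by shaping white
#' Gaussian noise in the frequency domain with amplitude
#' \code{|k|^(-slope/2)} (times \code{sqrt(axis_gain)} on the two frequency
#' axes; DC amplitude 0). The circulant construction makes the unwindowed
#' periodogram unbiased: its expectation equals the target spectrum exactly,
#' bin by bin, so slope-recovery checks are exact in expectation.
#'
#' @param height,width grid size in pixels (>= 8).
#' @param slope exponent lambda of P(k) proportional to |k|^-lambda;
#'   lambda >= 0 (0 gives white noise).
#' @param axis_gain multiplicative power excess (>= 1) on the horizontal and
#'   vertical frequency axes, emulating axis-aligned anisotropy.
#' @param pixel_mm in-plane pixel size in mm (scalar or c(row, col)).
#' @param seed optional integer seed; given the same seed the output is
#'   bit-identical across calls.
#' @return A \code{height x width} numeric matrix with attribute
#'   \code{pixel_mm}.
#' @examples
#' f <- gen_power_law_field(64, 64, slope = 3, seed = 1)
#' @export
gen_power_law_field <- function(height, width, slope, axis_gain = 1,
                                pixel_mm = 1, seed = NULL) {
  stopifnot(height >= 8, width >= 8, is.finite(slope), slope >= 0,
            is.finite(axis_gain), axis_gain >= 1)
  amp <- sqrt(power_law_spectrum(height, width, slope, axis_gain, pixel_mm))
  f <- with_seed_opt(seed, {
    w <- matrix(stats::rnorm(height * width), height, width)
    stats::fft(stats::fft(w) * amp, inverse = TRUE) / (height * width)
  })
  # amp is symmetric under k -> -k, so the result is real up to rounding
  stopifnot(max(abs(Im(f))) < 1e-8 * (1 + max(abs(Re(f)))))
  structure(Re(f), pixel_mm = as_pixel_mm(pixel_mm))
}

TEXTURE_COORDS <- c("beta_h", "beta_v", "beta_md", "beta_ad",
                    "theta_tl", "theta_tr", "theta_br", "theta_bl", "alpha")

#' Generate a maximum-entropy binary texture with one prescribed statistic
#'
#' One-sided Markov constructions realizing the most random stationary
#' binary ensemble consistent with a prescribed value of a single local
#' statistic (see \link{texstats} for coordinate definitions):
#' \itemize{
#'   \item \code{beta_h}: each row an independent chain; first pixel a fair
#'     coin, each next pixel equal to its left neighbor with probability
#'     (1 + value)/2. \code{beta_v}, \code{beta_md}, \code{beta_ad}: the same
#'     recursion down columns / along the two diagonal directions.
#'   \item \code{alpha}: first row and column i.i.d. fair coins; each interior
#'     pixel completes its 2x2 block with an even number of white pixels with
#'     probability (1 + value)/2.
#'   \item \code{theta_*}: the canonical orientation \code{theta_br} is
#'     generated like alpha but with the three-cell L parity (odd number of
#'     white with probability (1 + value)/2); the other three orientations
#'     are obtained by mirroring the generated texture horizontally and/or
#'     vertically.
#' }
#' The measured target coordinate converges to \code{value}. All other
#' coordinates converge to 0, with one structural exception: for
#' \code{beta_h} and \code{beta_v} the independent parallel chains force
#' \code{alpha = value^2} (no stationary ensemble with an edge beta of
#' magnitude > 1/2 and alpha = 0 exists, since the implied block
#' probabilities would be negative).
#'
#' @param coordinate one of \code{"beta_h"}, \code{"beta_v"},
#'   \code{"beta_md"}, \code{"beta_ad"}, \code{"theta_tl"},
#'   \code{"theta_tr"}, \code{"theta_br"}, \code{"theta_bl"}, \code{"alpha"}.
#' @param value target value in [-1, 1] (the endpoints give the degenerate
#'   deterministic recursions).
#' @param height,width image size in pixels (>= 2).
#' @param seed optional integer seed (bit-identical reruns).
#' @return A \code{height x width} matrix with values in \{-1, +1\}.
#' @examples
#' tex <- gen_texture("theta_br", -0.4, 128, 128, seed = 7)
#' stats_for_roi(tex)["theta_br"]
#' @export
gen_texture <- function(coordinate, value, height, width, seed = NULL) {
  coordinate <- match.arg(coordinate, TEXTURE_COORDS)
  stopifnot(is.finite(value), abs(value) <= 1, height >= 2, width >= 2)
  with_seed_opt(seed, switch(
    coordinate,
    beta_h  = gen_chain_rows(height, width, value),
    beta_v  = t(gen_chain_rows(width, height, value)),
    beta_md = gen_chain_diag(height, width, value, anti = FALSE),
    beta_ad = gen_chain_diag(height, width, value, anti = TRUE),
    alpha   = gen_parity4(height, width, value),
    theta_br = gen_theta_br(height, width, value),
    theta_bl = mirror_h(gen_theta_br(height, width, value)),
    theta_tr = mirror_v(gen_theta_br(height, width, value)),
    theta_tl = mirror_v(mirror_h(gen_theta_br(height, width, value)))
  ))
}

mirror_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
mirror_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# Independent left-to-right Markov chains along rows.
gen_chain_rows <- function(H, W, b) {
  keep <- (1 + b) / 2
  m <- matrix(0, H, W)
  m[, 1] <- rand_sign(H, 0.5)
  if (W > 1)
    for (j in 2:W) m[, j] <- m[, j - 1] * rand_sign(H, keep)
  m
}

# Independent chains along parallel diagonals; anti = TRUE runs along the
# anti-diagonal (TR-BL) direction.
gen_chain_diag <- function(H, W, b, anti = FALSE) {
  keep <- (1 + b) / 2
  m <- matrix(0, H, W)
  m[1, ] <- rand_sign(W, 0.5)
  if (H > 1) {
    for (i in 2:H) {
      if (!anti) {
        m[i, 1] <- rand_sign(1, 0.5)
        if (W > 1) m[i, 2:W] <- m[i - 1, 1:(W - 1)] * rand_sign(W - 1, keep)
      } else {
        m[i, W] <- rand_sign(1, 0.5)
        if (W > 1) m[i, 1:(W - 1)] <- m[i - 1, 2:W] * rand_sign(W - 1, keep)
      }
    }
  }
  m
}

# Four-point parity recursion. With s in {-1,+1}, the product of the four
# block cells is +1 iff the number of white pixels is even, so
# s(i,j) = s(i-1,j-1) s(i-1,j) s(i,j-1) eps with P(eps = +1) = (1+a)/2.
# The horizontal pair products r(i,j) = s(i,j) s(i,j-1) then satisfy
# r(i,j) = r(i-1,j) eps, which vectorizes as cumulative products.
gen_parity4 <- function(H, W, a) {
  pe <- (1 + a) / 2
  m <- matrix(0, H, W)
  m[1, ] <- rand_sign(W, 0.5)
  m[, 1] <- rand_sign(H, 0.5)
  m[1, 1] <- m[1, 1] # first row/col fixed; interior derived
  if (H > 1 && W > 1) {
    r1 <- m[1, -1] * m[1, -W]
    eps <- matrix(rand_sign((H - 1) * (W - 1), pe), H - 1, W - 1)
    r <- apply(rbind(r1, eps), 2, cumprod)[-1, , drop = FALSE]
    for (i in 2:H) m[i, ] <- cumprod(c(m[i, 1], r[i - 1, ]))
  }
  m
}

# Three-point parity recursion, canonical orientation with the L vertex at
# BR: the product over {TR, BL, BR} is +1 iff the L holds an odd number of
# white pixels, so s(i,j) = s(i-1,j) s(i,j-1) eps with P(eps = +1) = (1+t)/2.
gen_theta_br <- function(H, W, t) {
  pe <- (1 + t) / 2
  m <- matrix(0, H, W)
  m[1, ] <- rand_sign(W, 0.5)
  m[, 1] <- rand_sign(H, 0.5)
  if (H > 1 && W > 1) {
    for (i in 2:H) {
      a <- m[i - 1, 2:W] * rand_sign(W - 1, pe)
      m[i, ] <- cumprod(c(m[i, 1], a))
    }
  }
  m
}

# Tissue intensity tables (fraction of the most intense tissue).
phantom_tissues <- function(style) {
  switch(style,
         T1 = c(csf = 0.15, gm = 0.55, wm = 0.90, rim = 0.30),
         FLAIR = c(csf = 0.10, wm = 0.45, gm = 0.65, lesion = 0.95,
                   rim = 0.30))
}

#' Generate a brain-like phantom volume
#'
#' Builds a stack of slices made of nested ellipses: background 0, an
#' elliptical rim ("skull"), and an interior filled with tissue classes with
#' random elliptical blob substructure. The intensity ordering follows the
#' requested sequence style: T1-like has white matter brightest among brain
#' tissues and CSF darkest; FLAIR-like has CSF darkest with bright lesion
#' blobs. Gaussian white noise with standard deviation
#' \code{noise_frac * max(tissue intensity)} is added to every pixel. The
#' returned parenchyma mask covers the interior (excluding rim and
#' background); on central slices of a >= 128-pixel grid it admits a 64x64
#' ROI. Slice ellipses shrink away from the central slice. The geometry is a
#' configuration stand-in, with no claim of anatomical realism.
#'
#' @param n_slices number of slices.
#' @param height,width slice size in pixels (>= 32).
#' @param style \code{"T1"} or \code{"FLAIR"} (tissue-intensity ordering).
#' @param noise_frac noise SD as a fraction of the most intense tissue
#'   value (>= 0); the study conditions use 0, 0.03, 0.05, 0.07.
#' @param n_blobs number of substructure blobs per slice.
#' @param pixel_mm in-plane pixel size in mm.
#' @param id volume identifier string.
#' @param seed optional integer seed.
#' @return A [brain_volume] object; the noiseless slices are attached as
#'   attribute \code{clean} for noise calibration checks.
#' @export
gen_phantom_volume <- function(n_slices = 5, height = 128, width = 128,
                               style = c("T1", "FLAIR"), noise_frac = 0,
                               n_blobs = 12, pixel_mm = 1,
                               id = paste0("phantom-", style, "-",
                                           noise_frac),
                               seed = NULL) {
  style <- match.arg(style)
  stopifnot(n_slices >= 1, height >= 32, width >= 32, noise_frac >= 0)
  tissues <- phantom_tissues(style)
  max_tissue <- max(tissues)
  force(id)
  res <- with_seed_opt(seed, {
    slices <- vector("list", n_slices)
    clean <- vector("list", n_slices)
    masks <- vector("list", n_slices)
    yc <- (height + 1) / 2
    xc <- (width + 1) / 2
    y <- matrix(seq_len(height), height, width)
    x <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (k in seq_len(n_slices)) {
      # through-slice shrink: central slice largest
      z <- if (n_slices == 1) 0 else (2 * (k - (n_slices + 1) / 2)) / (n_slices + 1)
      sc <- sqrt(max(0.35, 1 - z^2))
      a <- 0.46 * height * sc   # semi-axis, rows
      b <- 0.44 * width * sc    # semi-axis, cols
      rim_px <- 3
      r_out <- ((y - yc) / a)^2 + ((x - xc) / b)^2
      r_in <- ((y - yc) / (a - rim_px))^2 + ((x - xc) / (b - rim_px))^2
      img <- matrix(0, height, width)
      base <- if (style == "T1") tissues["gm"] else tissues["wm"]
      img[r_in <= 1] <- base
      # blob substructure within the interior
      blob_classes <- if (style == "T1") c("wm", "csf") else c("csf", "lesion", "gm")
      for (bi in seq_len(n_blobs)) {
        th <- stats::runif(1, 0, 2 * pi)
        rr <- sqrt(stats::runif(1)) * 0.75
        cy <- yc + rr * (a - rim_px) * sin(th)
        cx <- xc + rr * (b - rim_px) * cos(th)
        ba <- stats::runif(1, 3, 0.12 * height)
        bb <- stats::runif(1, 3, 0.12 * width)
        cls <- sample(blob_classes, 1)
        inside <- (((y - cy) / ba)^2 + ((x - cx) / bb)^2 <= 1) & (r_in <= 1)
        img[inside] <- tissues[cls]
      }
      img[r_out <= 1 & r_in > 1] <- tissues["rim"]
      clean[[k]] <- img
      noisy <- img
      if (noise_frac > 0)
        noisy <- img + matrix(stats::rnorm(height * width,
                                           sd = noise_frac * max_tissue),
                              height, width)
      slices[[k]] <- noisy
      masks[[k]] <- (r_in <= 1) * 1
    }
    list(slices = slices, clean = clean, masks = masks)
  })
  vol <- brain_volume(res$slices, res$masks, pixel_mm = pixel_mm, id = id)
  attr(vol, "clean") <- res$clean
  vol
}
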