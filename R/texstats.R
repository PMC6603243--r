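#' @title Local multipoint statistics of binary images
#' @description Tabulation of 2x2 block colorings of a binary (+1/-1) image
#'   and the linear transform between the 16 block probabilities and the ten
#'   independent local statistics (gamma; beta_h, beta_v, beta_md, beta_ad;
#'   theta_tl, theta_tr, theta_br, theta_bl; alpha).
#' @details Pixels take values +1 (white) and -1 (black). A block coloring is
#'   indexed by the 4-bit word (TL, TR, BL, BR), most significant bit first,
#'   with bit 1 meaning white, so index 0 is all-black and index 15 all-white.
#'   Each statistic is the expectation, over the block distribution, of the
#'   product of pixel values over a template of cells:
#'   \itemize{
#'     \item \code{gamma}: single cell (the four single-cell templates averaged);
#'       equals P(white) - P(black).
#'     \item \code{beta_h}, \code{beta_v}: the two horizontal (resp. vertical)
#'       edge pairs, averaged; probability that the two pixels match minus the
#'       probability that they mismatch.
#'     \item \code{beta_md} (main diagonal, TL-BR), \code{beta_ad}
#'       (anti-diagonal, TR-BL): the diagonal pairs.
#'     \item \code{theta_tl/tr/br/bl}: the four L-shaped (glider) triples, named
#'       by the corner of the 2x2 block at the L's vertex
#'       (\code{theta_tl} = \{TL,TR,BL\}, \code{theta_tr} = \{TL,TR,BR\},
#'       \code{theta_br} = \{TR,BL,BR\}, \code{theta_bl} = \{TL,BL,BR\});
#'       fraction of Ls with an odd number of white pixels minus even.
#'     \item \code{alpha}: all four cells; probability of an even number of
#'       white pixels in the block minus odd.
#'   }
#'   All ten lie in [-1, 1]; 0 indicates maximum randomness.
#' @name texstats
NULL

STAT_NAMES <- c("gamma", "beta_h", "beta_v", "beta_md", "beta_ad",
                "theta_tl", "theta_tr", "theta_br", "theta_bl", "alpha")

# +/-1 cell values for the 16 block colorings, rows indexed 0:15 by the
# 4-bit word (TL,TR,BL,BR), bit 1 = white = +1.
coloring_signs <- function() {
  idx <- 0:15
  cbind(TL = ifelse(bitwAnd(idx, 8L) > 0L, 1, -1),
        TR = ifelse(bitwAnd(idx, 4L) > 0L, 1, -1),
        BL = ifelse(bitwAnd(idx, 2L) > 0L, 1, -1),
        BR = ifelse(bitwAnd(idx, 1L) > 0L, 1, -1))
}

# 16 x 10 matrix T with stats = t(T) %*% probs; also the kernel of the
# inverse map probs = (1/16) (1 + T %*% stats).
stats_templates <- function() {
  s <- coloring_signs()
  cbind(gamma    = (s[, "TL"] + s[, "TR"] + s[, "BL"] + s[, "BR"]) / 4,
        beta_h   = (s[, "TL"] * s[, "TR"] + s[, "BL"] * s[, "BR"]) / 2,
        beta_v   = (s[, "TL"] * s[, "BL"] + s[, "TR"] * s[, "BR"]) / 2,
        beta_md  = s[, "TL"] * s[, "BR"],
        beta_ad  = s[, "TR"] * s[, "BL"],
        theta_tl = s[, "TL"] * s[, "TR"] * s[, "BL"],
        theta_tr = s[, "TL"] * s[, "TR"] * s[, "BR"],
        theta_br = s[, "TR"] * s[, "BL"] * s[, "BR"],
        theta_bl = s[, "TL"] * s[, "BL"] * s[, "BR"],
        alpha    = s[, "TL"] * s[, "TR"] * s[, "BL"] * s[, "BR"])
}

#' Tabulate 2x2 block colorings of a binary image
#'
#' Counts every overlapping (sliding) 2x2 neighborhood of a +1/-1 image —
#' there are (H-1)(W-1) of them — and normalizes the counts to the 16 block
#' probabilities. Overlap enforces the stationarity constraint that the right
#' column of one block is the left column of the next.
#'
#' @param image numeric matrix with values in \{-1, +1\} (+1 = white), at
#'   least 2x2.
#' @return A list of class \code{"block_distribution"} with elements
#'   \code{probs} (named numeric(16), summing to 1), \code{counts}
#'   (integer(16)), and \code{n_blocks}.
#' @examples
#' img <- matrix(rep(c(1, -1), length.out = 64), 8, 8) # checkerboard
#' block_counts(img)$probs
#' @export
block_counts <- function(image) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("image must be at least 2x2")
  if (!is_binary_pm1(image))
    stop("image values must be -1 or +1")
  H <- nrow(image); W <- ncol(image)
  tl <- image[-H, -W]; tr <- image[-H, -1]
  bl <- image[-1, -W]; br <- image[-1, -1]
  idx <- 8L * (tl > 0) + 4L * (tr > 0) + 2L * (bl > 0) + (br > 0)
  counts <- tabulate(idx + 1L, nbins = 16L)
  n <- (H - 1L) * (W - 1L)
  names(counts) <- coloring_labels()
  structure(list(probs = counts / n, counts = counts, n_blocks = n),
            class = "block_distribution")
}

coloring_labels <- function() {
  vapply(0:15, function(i) paste(as.integer(intToBits(i)[4:1]), collapse = ""), "")
}

#' Convert 2x2 block probabilities to the ten local statistics
#'
#' Linear transform of the 16 (interdependent) block probabilities into the
#' ten independent texture coordinates; see \link{texstats} for definitions.
#'
#' @param d a \code{"block_distribution"} (from [block_counts()]) or a
#'   numeric vector of 16 probabilities in coloring-index order.
#' @return Named numeric vector of the ten statistics, each in [-1, 1].
#' @export
probs_to_stats <- function(d) {
  p <- if (inherits(d, "block_distribution")) d$probs else d
  stopifnot(is.numeric(p), length(p) == 16L)
  if (abs(sum(p) - 1) > 1e-9)
    stop("block probabilities must sum to 1")
  s <- drop(crossprod(stats_templates(), p))
  names(s) <- STAT_NAMES
  s
}

#' Reconstruct 2x2 block probabilities from the ten local statistics
#'
#' Inverse of [probs_to_stats()] under stationarity:
#' \code{p = (1/16) * (1 + T stats)} where T evaluates each template product
#' at the coloring's +/-1 cell values. Not every point of the [-1,1]^10 cube
#' is realizable; if any reconstructed probability is negative the vector is
#' returned with attribute \code{realizable = FALSE} and a warning.
#'
#' @param s named or positional numeric vector of the ten statistics in the
#'   order \code{gamma, beta_h, beta_v, beta_md, beta_ad, theta_tl, theta_tr,
#'   theta_br, theta_bl, alpha}; each must lie in [-1, 1].
#' @return Named numeric vector of 16 probabilities summing to 1, with
#'   attribute \code{realizable}.
#' @export
stats_to_probs <- function(s) {
  stopifnot(is.numeric(s), length(s) == 10L)
  if (!is.null(names(s))) {
    if (!setequal(names(s), STAT_NAMES))
      stop("names must be exactly the ten statistic names")
    s <- s[STAT_NAMES]
  }
  if (any(!is.finite(s)) || any(abs(s) > 1 + 1e-12))
    stop("statistics must be finite and in [-1, 1]")
  # inverse kernel: the character-basis expansion needs the SUM over each
  # template group, so the averaged gamma and edge-beta columns are rescaled
  kernel <- stats_templates() %*% diag(c(4, 2, 2, rep(1, 7)))
  p <- drop(1 + kernel %*% s) / 16
  names(p) <- coloring_labels()
  realizable <- all(p >= -1e-12)
  if (!realizable)
    warning("statistic combination is not realizable: negative block probability")
  structure(p, realizable = realizable)
}

#' Ten local statistics of one binarized ROI
#'
#' Composition of [block_counts()] and [probs_to_stats()].
#'
#' @inheritParams block_counts
#' @return Named numeric vector of the ten statistics.
#' @export
stats_for_roi <- function(image) {
  probs_to_stats(block_counts(image))
}

#' @export
print.block_distribution <- function(x, ...) {
  cat("2x2 block coloring distribution over", x$n_blocks, "sliding blocks\n")
  print(round(x$probs, 4))
  invisible(x)
}
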