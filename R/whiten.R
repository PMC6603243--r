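#' @title Spectral whitening and median binarization
#' @description Whitens ROIs by attenuating each Fourier component with the
#'   inverse square root of the database-mean power spectrum (DC gain 0, so
#'   the mean is removed), trims a one-pixel border to avoid wrap-around
#'   edge artifacts of the periodic filtering, and binarizes at the median,
#'   where the median is pooled over all of a brain's (trimmed) whitened
#'   ROIs. Binarization at the pooled median forces the one-point statistic
#'   gamma to zero up to the integer rounding of the pixel count, and makes
#'   the result invariant to any positive rescaling of the whitened values.
#' @name whiten
NULL

#' Build a whitening filter from an ensemble spectrum
#'
#' Per-bin gain \code{power^(-1/2)} with the DC gain set to 0 (mean
#' removal). The filter must be built at the same (R, N) scale as the ROIs
#' it will be applied to, without padding.
#'
#' @param spec a \code{"spectrum2d"} from [mean_spectrum()] (pad 1); every
#'   non-DC bin must have positive power.
#' @return An object of class \code{"whitening_filter"}: list with
#'   \code{gain} (DC-centered), \code{k_row}, \code{k_col},
#'   \code{pixel_mm}, \code{n_rois}.
#' @export
build_whitening_filter <- function(spec) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (spec$pad != 1)
    stop("whitening filters are built from unpadded spectra")
  dc <- cbind(which(spec$k_row == 0), which(spec$k_col == 0))
  pow <- spec$power
  off_dc <- pow
  off_dc[dc] <- 1
  if (any(off_dc <= 0))
    stop("zero power at a non-DC bin: degenerate ensemble")
  gain <- pow^(-1 / 2)
  gain[dc] <- 0
  structure(list(gain = gain, k_row = spec$k_row, k_col = spec$k_col,
                 pixel_mm = spec$pixel_mm, n_rois = spec$n_rois),
            class = "whitening_filter")
}

#' Whiten one ROI
#'
#' Multiplies the ROI's Fourier transform by the filter gain and transforms
#' back. The gain grid is real and symmetric under k -> -k (it derives from
#' a mean periodogram of real patches), so the output is real to machine
#' precision; the imaginary residue is asserted below 1e-10 (relative) and
#' dropped. The output has mean 0 because the DC gain is 0.
#'
#' @param roi a \code{"roi"} object or square numeric matrix.
#' @param filter a \code{"whitening_filter"} of matching shape.
#' @return Whitened numeric matrix; provenance attributes \code{volume_id}
#'   and \code{slice} are carried over when present.
#' @export
whiten_roi <- function(roi, filter) {
  stopifnot(inherits(filter, "whitening_filter"))
  m <- if (inherits(roi, "roi")) roi$pixels else roi
  stopifnot(is.matrix(m))
  if (!identical(dim(m), dim(filter$gain)))
    stop("ROI and filter shapes do not match")
  gain <- ifftshift2(filter$gain)
  w <- stats::fft(stats::fft(m) * gain, inverse = TRUE) / length(m)
  scale <- max(abs(Re(w)), 1e-300)
  stopifnot(max(abs(Im(w))) / scale < 1e-10)
  out <- Re(w)
  if (inherits(roi, "roi")) {
    attr(out, "volume_id") <- roi$volume_id
    attr(out, "slice") <- roi$slice
  }
  out
}

#' Trim, pool, and binarize whitened ROIs at the per-brain median
#'
#' Removes a \code{trim}-pixel border from each whitened ROI, pools the
#' surviving pixel values within each brain (volume id), and binarizes each
#' trimmed ROI at its brain's pooled median: values strictly above the
#' median become +1 (white), all others -1 (black) — ties go to black. With
#' continuous-valued input this leaves at most a one-pixel white/black
#' imbalance per brain, so the pooled gamma is bounded by 2 divided by the
#' pooled pixel count.
#'
#' @param whitened list of whitened ROI matrices (from [whiten_roi()]).
#' @param ids character vector of volume ids, one per ROI; defaults to the
#'   \code{volume_id} attributes.
#' @param trim border width removed before pooling and binarization
#'   (default 1).
#' @return List of \code{(R - 2 trim) x (R - 2 trim)} matrices with values
#'   in \{-1, +1\}, provenance attributes preserved, and attribute
#'   \code{threshold} (the brain's pooled median) on each.
#' @export
binarize_per_brain <- function(whitened, ids = NULL, trim = 1) {
  stopifnot(is.list(whitened), length(whitened) >= 1, trim >= 0)
  if (is.null(ids))
    ids <- vapply(whitened, function(w) {
      id <- attr(w, "volume_id")
      if (is.null(id)) "volume" else id
    }, "")
  stopifnot(length(ids) == length(whitened))
  trimmed <- lapply(whitened, function(w) {
    H <- nrow(w); W <- ncol(w)
    if (H - 2 * trim < 2 || W - 2 * trim < 2)
      stop("ROI too small to trim")
    t_w <- w[(1 + trim):(H - trim), (1 + trim):(W - trim), drop = FALSE]
    attributes(t_w)$volume_id <- attr(w, "volume_id")
    attributes(t_w)$slice <- attr(w, "slice")
    t_w
  })
  out <- vector("list", length(trimmed))
  for (id in unique(ids)) {
    sel <- which(ids == id)
    thr <- stats::median(unlist(lapply(trimmed[sel], as.numeric)))
    for (i in sel) {
      b <- ifelse(trimmed[[i]] > thr, 1, -1)
      attr(b, "volume_id") <- attr(trimmed[[i]], "volume_id")
      attr(b, "slice") <- attr(trimmed[[i]], "slice")
      attr(b, "threshold") <- thr
      out[[i]] <- b
    }
  }
  out
}
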