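#' @title Ensemble summaries and bootstrap confidence intervals
#' @description Summarizes the ten local statistics across ROIs (mean, SD,
#'   skewness, excess kurtosis, covariance) and attaches percentile
#'   bootstrap confidence intervals obtained by resampling eligible slices
#'   with replacement, re-drawing a fresh random ROI for every drawn slice
#'   and re-running the whitening/binarization/tabulation pipeline on each
#'   resample.
#' @name aggregate
NULL

#' Point summaries of local statistics across ROIs
#'
#' Sample mean, SD (n-1 denominator), skewness and excess kurtosis
#' (bias-uncorrected moment ratios: m3/m2^(3/2) and m4/m2^2 - 3), and the
#' covariance matrix across rows. gamma is summarized like the others but
#' excluded from the covariance matrix (it is forced to ~0 by median
#' binarization).
#'
#' @param stats_rows numeric matrix with one row per ROI and the ten
#'   statistics as columns (>= 2 rows), e.g. stacked [stats_for_roi()]
#'   results.
#' @return An object of class \code{"stats_summary"}: list with \code{n},
#'   \code{mean}, \code{sd}, \code{skewness}, \code{kurtosis} (excess),
#'   and \code{cov} (9 x 9, gamma excluded).
#' @export
summarize_stats <- function(stats_rows) {
  stats_rows <- as.matrix(stats_rows)
  if (nrow(stats_rows) < 2) stop("need at least 2 rows")
  if (is.null(colnames(stats_rows)) && ncol(stats_rows) == 10L)
    colnames(stats_rows) <- STAT_NAMES
  structure(list(
    n = nrow(stats_rows),
    mean = colMeans(stats_rows),
    sd = apply(stats_rows, 2, stats::sd),
    skewness = apply(stats_rows, 2, e1071::skewness, type = 1),
    kurtosis = apply(stats_rows, 2, e1071::kurtosis, type = 1),
    cov = stats::cov(stats_rows[, setdiff(colnames(stats_rows), "gamma"),
                                drop = FALSE])
  ), class = "stats_summary")
}

#' @export
print.stats_summary <- function(x, ...) {
  cat("summary over", x$n, "ROIs\n")
  print(round(rbind(mean = x$mean, sd = x$sd, skewness = x$skewness,
                    ex_kurtosis = x$kurtosis), 4))
  invisible(x)
}

# One full pipeline pass over a set of (volume, slice, rect) draws:
# ROI extraction -> mean spectrum -> whitening filter -> whiten -> trim +
# per-brain median binarization -> ten statistics per ROI. For binary
# texture inputs (whiten = FALSE) the ROIs are used directly.
pipeline_stats_pass <- function(volumes, frame, R, N, whiten = TRUE,
                                trim = 1) {
  rois <- lapply(seq_len(nrow(frame)), function(i) {
    vol <- volumes[[frame$volume[i]]]
    rect <- list(top = frame$top[i], left = frame$left[i],
                 height = frame$height[i], width = frame$width[i])
    draw_roi_in_rect(vol, frame$volume[i], frame$slice[i], rect, R, N)
  })
  if (!whiten) {
    S <- t(vapply(rois, function(r) stats_for_roi(r$pixels),
                  numeric(10)))
    colnames(S) <- STAT_NAMES
    return(list(stats = S, rois = rois, spectrum = NULL, filter = NULL,
                binarized = NULL))
  }
  pgs <- lapply(rois, roi_periodogram, pad = 1)
  spec <- mean_spectrum(pgs)
  filt <- build_whitening_filter(spec)
  wh <- lapply(rois, whiten_roi, filter = filt)
  ids <- vapply(rois, function(r) r$volume_id, "")
  bin <- binarize_per_brain(wh, ids = ids, trim = trim)
  S <- t(vapply(bin, stats_for_roi, numeric(10)))
  colnames(S) <- STAT_NAMES
  list(stats = S, rois = rois, spectrum = spec, filter = filt,
       binarized = bin)
}

#' Bootstrap summary of local statistics over a slice ensemble
#'
#' Point estimates plus percentile bootstrap confidence intervals. The
#' resampling unit is the eligible slice, pooled across volumes. Each of
#' the B resamples draws slices with replacement, draws a fresh random ROI
#' from each drawn slice's maximal rectangle, recomputes the whitening
#' filter and per-brain medians on the resample, and summarizes; the CI for
#' every summary quantity is the percentile interval of its B replicates.
#'
#' @param volumes a [brain_volume] or list of them.
#' @param R ROI side in pixels; @param N downsampling factor.
#' @param B number of bootstrap resamples (protocol default: 500).
#' @param conf confidence level for the percentile intervals.
#' @param whiten if FALSE the input slices must already be binary (+1/-1)
#'   textures; whitening and binarization are skipped.
#' @param freeze_filter if TRUE, the whitening filter and per-brain
#'   thresholds from the point-estimate pass are reused in every resample
#'   (a documented speed switch; default FALSE re-estimates both per
#'   resample).
#' @param seed optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return An object of class \code{"summary_table"}: list with
#'   \code{point} (a \code{"stats_summary"}), \code{ci} (list of 2 x 10
#'   matrices for mean, sd, skewness, kurtosis), \code{B}, \code{conf},
#'   \code{n_rois}, \code{n_volumes}, \code{scale} (c(R, N)).
#' @export
bootstrap_summary <- function(volumes, R, N = 1, B = 500, conf = 0.95,
                              whiten = TRUE, freeze_filter = FALSE,
                              seed = NULL) {
  if (inherits(volumes, "brain_volume")) volumes <- list(volumes)
  stopifnot(B >= 2)
  frame <- eligible_slices(volumes, R * N)
  if (nrow(frame) == 0) stop("no eligible slices")
  with_seed_opt(seed, {
    point_pass <- pipeline_stats_pass(volumes, frame, R, N, whiten = whiten)
    point <- summarize_stats(point_pass$stats)
    frozen <- if (freeze_filter && whiten) point_pass$filter else NULL
    reps <- replicate(B, {
      draw <- frame[sample.int(nrow(frame), replace = TRUE), , drop = FALSE]
      if (is.null(frozen)) {
        S <- pipeline_stats_pass(volumes, draw, R, N, whiten = whiten)$stats
      } else {
        rois <- lapply(seq_len(nrow(draw)), function(i) {
          vol <- volumes[[draw$volume[i]]]
          rect <- list(top = draw$top[i], left = draw$left[i],
                       height = draw$height[i], width = draw$width[i])
          draw_roi_in_rect(vol, draw$volume[i], draw$slice[i], rect, R, N)
        })
        wh <- lapply(rois, whiten_roi, filter = frozen)
        ids <- vapply(rois, function(r) r$volume_id, "")
        bin <- binarize_per_brain(wh, ids = ids)
        S <- t(vapply(bin, stats_for_roi, numeric(10)))
        colnames(S) <- STAT_NAMES
      }
      sm <- summarize_stats(S)
      rbind(mean = sm$mean, sd = sm$sd, skewness = sm$skewness,
            kurtosis = sm$kurtosis)
    }, simplify = "array")
    pr <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- lapply(rownames(reps[, , 1]), function(q) {
      # degenerate resamples can yield NaN moment ratios (zero variance)
      apply(reps[q, , , drop = TRUE], 1, stats::quantile, probs = pr,
            names = FALSE, type = 7, na.rm = TRUE)
    })
    names(ci) <- rownames(reps[, , 1])
    ci <- lapply(ci, function(m) {
      rownames(m) <- c("lower", "upper")
      colnames(m) <- STAT_NAMES
      m
    })
    structure(list(point = point, ci = ci, B = B, conf = conf,
                   n_rois = nrow(frame),
                   n_volumes = length(volumes),
                   n_discarded = attr(frame, "n_discarded"),
                   scale = c(R = R, N = N)),
              class = "summary_table")
  })
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("summary_table: (R, N) = (%d, %d), %d ROIs from %d volume(s), B = %d\n",
              x$scale["R"], x$scale["N"], x$n_rois, x$n_volumes, x$B))
  tab <- rbind(mean = x$point$mean,
               ci_lo = x$ci$mean["lower", ],
               ci_hi = x$ci$mean["upper", ],
               sd = x$point$sd)
  print(round(tab, 4))
  invisible(x)
}
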