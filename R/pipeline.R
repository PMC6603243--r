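#' @title End-to-end pipeline and NIfTI / CSV / JSON input-output
#' @description Reads NIfTI volumes with their parenchyma masks, runs the
#'   stage order ROIs -> spectra -> slope fit -> whitening -> binarization
#'   -> block statistics -> summaries per (R, N) scale, and writes the
#'   artifacts (per-ROI statistics CSV, summary CSV, slope JSON, spectrum
#'   text grid, run manifest JSON). Every run is reproducible from its
#'   manifest: the manifest echoes the configuration and seed.
#' @name cli_io
NULL

#' Read a NIfTI volume and mask as a brain_volume
#'
#' Slices are taken along \code{axis} (default 1, the first voxel axis —
#' sagittal for standard RAS-ordered structural volumes); the two remaining
#' axes give the in-plane pixel sizes, which may differ (the frequency axes
#' are then scaled independently downstream). The mask is binarized at 0.5.
#' A missing or zero pixel-size entry in the header is an explicit error:
#' there is no silent default.
#'
#' @param image_path,mask_path paths to NIfTI files (.nii or .nii.gz) of
#'   identical shape.
#' @param axis slice axis, 1-3.
#' @param id volume id; defaults to the image file name.
#' @return A [brain_volume].
#' @export
read_volume <- function(image_path, mask_path, axis = 1,
                        id = basename(image_path)) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop("image and mask shapes do not match")
  stopifnot(length(dim(img)) == 3, axis %in% 1:3)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI header lacks valid pixel-size metadata")
  in_plane <- pd[setdiff(1:3, axis)]
  n <- dim(img)[axis]
  take <- function(a, k) switch(axis, a[k, , ], a[, k, ], a[, , k])
  slices <- lapply(seq_len(n), function(k) take(img, k))
  masks <- lapply(seq_len(n), function(k) take(msk, k))
  brain_volume(slices, masks, pixel_mm = in_plane, id = id)
}

#' Write a brain_volume as NIfTI image + mask
#'
#' Inverse of [read_volume()] for synthetic volumes: slices are stacked
#' along the first axis and the in-plane pixel sizes stored in the header.
#'
#' @param volume a [brain_volume].
#' @param image_path,mask_path output paths (.nii or .nii.gz).
#' @export
write_volume <- function(volume, image_path, mask_path) {
  stopifnot(inherits(volume, "brain_volume"))
  d <- dim(volume$slices[[1]])
  n <- length(volume$slices)
  img <- array(0, c(n, d))
  msk <- array(0, c(n, d))
  for (k in seq_len(n)) {
    img[k, , ] <- volume$slices[[k]]
    msk[k, , ] <- volume$masks[[k]]
  }
  pd <- c(1, volume$pixel_mm)
  img <- RNifti::asNifti(img)
  msk <- RNifti::asNifti(msk)
  RNifti::pixdim(img) <- pd
  RNifti::pixdim(msk) <- pd
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}

#' Run the full analysis pipeline
#'
#' For each (R, N) scale: draws one random ROI per eligible slice, computes
#' the ensemble mean spectrum (from the same ROI draw used for the
#' statistics), fits the power-law slope over the default (or supplied)
#' band, whitens with the inverse square root of the mean spectrum,
#' binarizes at per-brain medians, tabulates the ten local statistics per
#' ROI, summarizes them, and optionally attaches bootstrap confidence
#' intervals. If \code{out_dir} is given, all artifacts are written there.
#'
#' @param volumes a [brain_volume] or list of them (or character paths
#'   handled by [read_volume()] supplied as \code{list(c(image, mask))}).
#' @param scales list of c(R, N) pairs; default the study protocol
#'   \code{list(c(64, 1), c(32, 2))}.
#' @param pad pad factor for the spectrum estimate used in the slope fit
#'   (the whitening filter is always built unpadded).
#' @param band optional c(f_lo, f_hi) override in cycles/mm.
#' @param bootstrap_B if > 0, run [bootstrap_summary()] with this many
#'   resamples.
#' @param whiten FALSE for already-binary texture inputs.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed integer seed; the same configuration and seed give
#'   bit-identical outputs.
#' @return Named list, one element per scale (\code{"R64N1"}, ...), each a
#'   list with \code{spectrum}, \code{slope}, \code{records} (per-ROI data
#'   frame), \code{summary}, \code{bootstrap} (or NULL), \code{n_discarded}.
#' @export
run_pipeline <- function(volumes, scales = list(c(64, 1), c(32, 2)),
                         pad = 1, band = NULL, bootstrap_B = 0,
                         whiten = TRUE, out_dir = NULL, seed = NULL) {
  if (inherits(volumes, "brain_volume")) volumes <- list(volumes)
  volumes <- lapply(volumes, function(v) {
    if (inherits(v, "brain_volume")) v
    else if (is.character(v) && length(v) == 2) read_volume(v[1], v[2])
    else stop("volumes must be brain_volume objects or c(image, mask) paths")
  })
  results <- with_seed_opt(seed, {
    out <- list()
    for (sc in scales) {
      R <- sc[1]; N <- sc[2]
      frame <- eligible_slices(volumes, R * N)
      if (nrow(frame) == 0)
        stop(sprintf("no slice admits an ROI at (R, N) = (%d, %d)", R, N))
      pass <- pipeline_stats_pass(volumes, frame, R, N, whiten = whiten)
      spec <- if (whiten) {
        if (pad > 1) mean_spectrum(lapply(pass$rois, roi_periodogram,
                                          pad = pad))
        else pass$spectrum
      } else {
        mean_spectrum(lapply(pass$rois, roi_periodogram, pad = pad))
      }
      slope <- if (is.null(band)) fit_spectral_slope(spec)
               else fit_spectral_slope(spec, band[1], band[2])
      records <- data.frame(
        volume_id = vapply(pass$rois, function(r) r$volume_id, ""),
        slice = vapply(pass$rois, function(r) r$slice, 1L),
        top = vapply(pass$rois, function(r) r$top, 1L),
        left = vapply(pass$rois, function(r) r$left, 1L),
        R = R, N = N, stringsAsFactors = FALSE)
      records <- cbind(records, as.data.frame(pass$stats))
      boot <- NULL
      if (bootstrap_B > 0)
        boot <- bootstrap_summary(volumes, R, N, B = bootstrap_B,
                                  whiten = whiten)
      label <- sprintf("R%dN%d", R, N)
      out[[label]] <- list(spectrum = spec, slope = slope,
                           records = records,
                           summary = summarize_stats(pass$stats),
                           bootstrap = boot,
                           n_eligible = nrow(frame),
                           n_discarded = attr(frame, "n_discarded"))
    }
    out
  })
  if (!is.null(out_dir))
    write_run_artifacts(results, out_dir,
                        config = list(scales = scales, pad = pad,
                                      band = band,
                                      bootstrap_B = bootstrap_B,
                                      whiten = whiten, seed = seed,
                                      volume_ids = vapply(volumes,
                                                          function(v) v$id,
                                                          "")))
  results
}

write_run_artifacts <- function(results, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "mritexture",
    version = as.character(utils::packageVersion("mritexture")),
    r_version = R.version.string,
    config = config,
    scales_run = names(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  for (label in names(results)) {
    res <- results[[label]]
    write_stats_csv(res$records,
                    file.path(out_dir, paste0("stats_", label, ".csv")))
    jsonlite::write_json(
      list(slope = res$slope$slope, intercept = res$slope$intercept,
           ci = res$slope$ci, band = as.list(res$slope$band),
           n_bins = res$slope$n_bins),
      file.path(out_dir, paste0("slope_", label, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.table(format(res$spectrum$power, digits = 12),
                       file.path(out_dir, paste0("spectrum_", label, ".txt")),
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    sm <- res$summary
    sm_df <- data.frame(statistic = names(sm$mean), mean = sm$mean,
                        sd = sm$sd, skewness = sm$skewness,
                        ex_kurtosis = sm$kurtosis, row.names = NULL)
    if (!is.null(res$bootstrap)) {
      sm_df$mean_ci_lo <- res$bootstrap$ci$mean["lower", names(sm$mean)]
      sm_df$mean_ci_hi <- res$bootstrap$ci$mean["upper", names(sm$mean)]
    }
    write_stats_csv(sm_df, file.path(out_dir,
                                     paste0("summary_", label, ".csv")))
  }
  invisible(out_dir)
}

# CSV writer preserving >= 12 significant digits on numeric columns.
write_stats_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x), as.character(x), sprintf("%.15g", x))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a per-ROI statistics CSV
#'
#' @param path CSV written by [run_pipeline()].
#' @return Data frame; numeric values round-trip within 1e-10.
#' @export
read_stats_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
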