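#' @title ROI extraction inside brain parenchyma
#' @description Randomized square region-of-interest extraction from masked
#'   slices: convex hull of the parenchyma mask, largest inscribed
#'   axis-aligned rectangle, uniform placement of an RxR patch inside it,
#'   and block-average downsampling. Conventions used throughout: matrices
#'   are row-major images with 1-based row/column indices; a rectangle is
#'   the closed pixel range \code{[top, top+height-1] x [left, left+width-1]}.
#' @name roi
NULL

#' Brain volume container
#'
#' A stack of 2-D grayscale slices with binary parenchyma masks and the
#' in-plane pixel size. Skull stripping is the caller's job: the mask is the
#' input contract.
#'
#' @param slices list of numeric matrices (or a single matrix).
#' @param masks list of same-shaped 0/1 matrices (1 = parenchyma); values
#'   are binarized at 0.5.
#' @param pixel_mm in-plane pixel size in mm, scalar or c(row, col).
#' @param id volume identifier string.
#' @return An object of class \code{"brain_volume"} with elements
#'   \code{slices}, \code{masks}, \code{pixel_mm}, \code{id}.
#' @export
brain_volume <- function(slices, masks, pixel_mm = 1, id = "volume") {
  if (is.matrix(slices)) slices <- list(slices)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(slices) == length(masks), length(slices) >= 1)
  masks <- lapply(masks, function(m) (m > 0.5) * 1)
  for (k in seq_along(slices)) {
    stopifnot(is.matrix(slices[[k]]), all(is.finite(slices[[k]])),
              identical(dim(slices[[k]]), dim(masks[[k]])))
  }
  structure(list(slices = slices, masks = masks,
                 pixel_mm = as_pixel_mm(pixel_mm), id = as.character(id)),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("brain_volume '%s': %d slice(s) of %d x %d, pixel %g x %g mm\n",
              x$id, length(x$slices), d[1], d[2],
              x$pixel_mm[1], x$pixel_mm[2]))
  invisible(x)
}

#' Filled convex hull of a binary mask
#'
#' Rasterizes the convex hull of the set pixels: a pixel belongs to the hull
#' iff its center lies inside or on the convex polygon spanned by the set
#' pixels' centers. The hull of an empty mask is empty; the operation is
#' idempotent and contains the input mask.
#'
#' @param mask 0/1 numeric matrix.
#' @return 0/1 matrix of the same shape.
#' @export
convex_hull_mask <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask * 0)
  out <- matrix(0, nrow(mask), ncol(mask))
  pts <- cbind(x = idx[, "col"], y = idx[, "row"])
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  # restrict the candidate grid to the hull's bounding box
  rr <- range(pts[, "y"]); cc <- range(pts[, "x"])
  rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
  py <- matrix(rows, length(rows), length(cols))
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- matrix(TRUE, length(rows), length(cols))
  n <- nrow(hull)
  if (n >= 3) {
    # orient the polygon counter-clockwise in (x, row) coordinates so that
    # interior points have non-negative cross products on every edge
    nxt <- c(seq_len(n)[-1], 1L)
    signed_area <- sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])
    if (signed_area < 0) {
      hull <- hull[rev(seq_len(n)), , drop = FALSE]
    }
    for (v in seq_len(n)) {
      a <- hull[v, ]; b <- hull[if (v == n) 1 else v + 1, ]
      cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      inside <- inside & (cr >= -1e-9)
    }
  } else {
    # degenerate hull: all set pixels collinear; keep centers on the segment
    a <- hull[1, ]; b <- hull[min(2, n), ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- abs(cr) <= 1e-9
  }
  out[rows, cols][inside] <- 1
  out
}

#' Largest axis-aligned rectangle of set pixels
#'
#' Maximum-area all-ones rectangle of a binary mask, computed in O(H W) by
#' the per-row height histogram with a stack-based largest-rectangle-in-
#' histogram pass. Ties are broken deterministically by area, then height,
#' then topmost, then leftmost.
#'
#' @param mask 0/1 numeric matrix.
#' @return A list \code{(top, left, height, width)} with 1-based closed
#'   indices, or \code{NULL} for an empty mask.
#' @export
largest_inscribed_rectangle <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask > 0)) return(NULL)
  heights <- integer(W)
  best <- list(area = 0L, height = 0L, top = Inf, left = Inf, width = 0L)
  consider <- function(area, height, top, left, width) {
    if (area > best$area ||
        (area == best$area && (height > best$height ||
          (height == best$height && (top < best$top ||
            (top == best$top && left < best$left)))))) {
      best <<- list(area = area, height = height, top = top, left = left,
                    width = width)
    }
  }
  for (i in seq_len(H)) {
    heights <- ifelse(mask[i, ] > 0, heights + 1L, 0L)
    # largest rectangle in histogram `heights`, sentinel 0 at the end
    h <- c(heights, 0L)
    stack <- integer(0)
    for (j in seq_along(h)) {
      while (length(stack) && h[stack[length(stack)]] > h[j]) {
        ht <- h[stack[length(stack)]]
        stack <- stack[-length(stack)]
        left <- if (length(stack)) stack[length(stack)] + 1L else 1L
        width <- j - left
        consider(ht * width, ht, i - ht + 1L, left, width)
      }
      stack <- c(stack, j)
    }
  }
  if (best$area == 0L) return(NULL)
  list(top = best$top, left = best$left, height = best$height,
       width = best$width)
}

#' Slices eligible to host an ROI, with their maximal rectangles
#'
#' For every slice of every volume, computes the convex hull of the
#' parenchyma mask and its largest inscribed rectangle, and keeps the slices
#' whose rectangle admits a \code{side x side} patch. This is the sampling
#' frame for [sample_roi()] and the bootstrap.
#'
#' @param volumes a [brain_volume] or list of them.
#' @param side required patch side in pixels (ROI size times downsampling
#'   factor).
#' @return A data frame with one row per eligible slice: \code{volume} (index
#'   into the list), \code{volume_id}, \code{slice}, and the rectangle
#'   \code{top, left, height, width}; attribute \code{n_discarded} counts the
#'   slices whose hulls were too small.
#' @export
eligible_slices <- function(volumes, side) {
  if (inherits(volumes, "brain_volume")) volumes <- list(volumes)
  rows <- list()
  discarded <- 0L
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    for (k in seq_along(vol$slices)) {
      rect <- largest_inscribed_rectangle(convex_hull_mask(vol$masks[[k]]))
      if (is.null(rect) || rect$height < side || rect$width < side) {
        discarded <- discarded + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(volume = v, volume_id = vol$id, slice = k,
                   top = rect$top, left = rect$left,
                   height = rect$height, width = rect$width,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(volume = integer(0), volume_id = character(0),
               slice = integer(0), top = integer(0), left = integer(0),
               height = integer(0), width = integer(0))
  attr(out, "n_discarded") <- discarded
  out
}

# Draw one side x side patch uniformly inside a rectangle of a slice and
# downsample by N. Uses the current RNG stream.
draw_roi_in_rect <- function(vol, v_index, slice_index, rect, R, N) {
  side <- R * N
  top <- rect$top + sample.int(rect$height - side + 1L, 1L) - 1L
  left <- rect$left + sample.int(rect$width - side + 1L, 1L) - 1L
  patch <- vol$slices[[slice_index]][top:(top + side - 1L),
                                     left:(left + side - 1L)]
  if (N > 1) patch <- downsample_blocks(patch, N)
  structure(list(pixels = patch, R = R, N = N,
                 pixel_mm = vol$pixel_mm * N,
                 volume_id = vol$id, slice = slice_index,
                 top = top, left = left),
            class = "roi")
}

#' Sample one random ROI from a slice
#'
#' Computes the convex hull of the slice's parenchyma mask and its largest
#' inscribed rectangle; if the rectangle cannot hold an \code{(R N) x (R N)}
#' patch the slice is discarded (returns \code{NULL}). Otherwise the
#' top-left offset is drawn uniformly over all admissible positions and the
#' patch is extracted (and, for \code{N > 1}, downsampled by \code{N x N}
#' block averaging to \code{R x R}). The standard protocol uses
#' \code{(R, N) = (64, 1)} and \code{(32, 2)}.
#'
#' @param volume a [brain_volume].
#' @param slice_index slice number (1-based).
#' @param R ROI side in pixels after downsampling (>= 2).
#' @param N block-averaging downsampling factor (>= 1).
#' @param seed optional integer seed; by default the current RNG stream is
#'   used (so repeated passes draw fresh ROIs).
#' @return An object of class \code{"roi"} (fields \code{pixels}, \code{R},
#'   \code{N}, \code{pixel_mm} — the effective pixel size \code{N *
#'   pixel_mm} — and provenance \code{volume_id}, \code{slice}, \code{top},
#'   \code{left}), or \code{NULL} if the slice is discarded.
#' @export
sample_roi <- function(volume, slice_index, R, N = 1, seed = NULL) {
  stopifnot(inherits(volume, "brain_volume"), R >= 2, N >= 1)
  if (slice_index < 1 || slice_index > length(volume$slices))
    stop("slice index out of range")
  side <- R * N
  rect <- largest_inscribed_rectangle(
    convex_hull_mask(volume$masks[[slice_index]]))
  if (is.null(rect) || rect$height < side || rect$width < side)
    return(NULL)
  with_seed_opt(seed,
                draw_roi_in_rect(volume, 1L, slice_index, rect, R, N))
}

#' Downsample an image by block averaging
#'
#' Replaces each non-overlapping \code{N x N} block by its mean, so the
#' grand mean of the image is conserved exactly.
#'
#' @param image numeric matrix whose dimensions are divisible by \code{N}.
#' @param N block size (1 returns the input unchanged).
#' @return An \code{(H/N) x (W/N)} matrix.
#' @export
downsample_blocks <- function(image, N) {
  stopifnot(is.matrix(image), N >= 1, N == round(N))
  if (N == 1) return(image)
  H <- nrow(image); W <- ncol(image)
  if (H %% N != 0 || W %% N != 0)
    stop("image dimensions must be divisible by N")
  # average rows within blocks, then columns
  rowsum_mat <- function(m, n) {
    g <- rep(seq_len(nrow(m) / n), each = n)
    rowsum(m, g) / n
  }
  unname(t(rowsum_mat(t(rowsum_mat(image, N)), N)))
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi %dx%d (N=%d) from '%s' slice %d at (%d, %d)\n",
              x$R, x$R, x$N, x$volume_id, x$slice, x$top, x$left))
  invisible(x)
}
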