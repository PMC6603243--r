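# Independent oracles used across test files. These deliberately avoid the
# package's vectorized code paths.

# Naive double-loop tabulation of sliding 2x2 blocks.
naive_block_counts <- function(img) {
  counts <- integer(16)
  for (i in seq_len(nrow(img) - 1)) {
    for (j in seq_len(ncol(img) - 1)) {
      idx <- 8 * (img[i, j] > 0) + 4 * (img[i, j + 1] > 0) +
        2 * (img[i + 1, j] > 0) + (img[i + 1, j + 1] > 0)
      counts[idx + 1] <- counts[idx + 1] + 1L
    }
  }
  counts
}

# Statistics by explicit enumeration over the 16 colorings (independent of
# the package's template matrix).
naive_probs_to_stats <- function(p) {
  s <- numeric(10)
  for (idx in 0:15) {
    tl <- if (bitwAnd(idx, 8L) > 0) 1 else -1
    tr <- if (bitwAnd(idx, 4L) > 0) 1 else -1
    bl <- if (bitwAnd(idx, 2L) > 0) 1 else -1
    br <- if (bitwAnd(idx, 1L) > 0) 1 else -1
    w <- p[idx + 1]
    s <- s + w * c((tl + tr + bl + br) / 4,
                   (tl * tr + bl * br) / 2,
                   (tl * bl + tr * br) / 2,
                   tl * br, tr * bl,
                   tl * tr * bl, tl * tr * br, tr * bl * br, tl * bl * br,
                   tl * tr * bl * br)
  }
  names(s) <- c("gamma", "beta_h", "beta_v", "beta_md", "beta_ad",
                "theta_tl", "theta_tr", "theta_br", "theta_bl", "alpha")
  s
}

# Exhaustive O(H^2 W^2) maximum all-ones rectangle search.
brute_force_max_rect <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  cs <- matrix(0, H + 1, W + 1)  # cs[i+1, j+1] = sum of mask[1:i, 1:j]
  for (i in seq_len(H)) for (j in seq_len(W))
    cs[i + 1, j + 1] <- mask[i, j] + cs[i, j + 1] + cs[i + 1, j] - cs[i, j]
  best <- 0L
  for (t in seq_len(H)) for (b in t:H) for (l in seq_len(W)) for (r in l:W) {
    area <- (b - t + 1L) * (r - l + 1L)
    if (area <= best) next
    s <- cs[b + 1, r + 1] - cs[t, r + 1] - cs[b + 1, l] + cs[t, l]
    if (s == area) best <- area
  }
  best
}

random_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1, p), h, w)
}

random_binary_image <- function(h, w) {
  matrix(sample(c(-1, 1), h * w, replace = TRUE), h, w)
}

# A small all-parenchyma volume whose slices are binary textures.
texture_volume <- function(coordinate, value, n_slices, h, w, id = "tex") {
  slices <- replicate(n_slices, mritexture::gen_texture(coordinate, value,
                                                        h, w),
                      simplify = FALSE)
  masks <- replicate(n_slices, matrix(1, h, w), simplify = FALSE)
  mritexture::brain_volume(slices, masks, id = id)
}

# A volume of power-law Gaussian fields with a full mask.
field_volume <- function(n_slices, h, w, slope, id = "field") {
  slices <- replicate(n_slices,
                      mritexture::gen_power_law_field(h, w, slope),
                      simplify = FALSE)
  masks <- replicate(n_slices, matrix(1, h, w), simplify = FALSE)
  mritexture::brain_volume(slices, masks, id = id)
}
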