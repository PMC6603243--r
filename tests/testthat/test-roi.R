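test_that("convex hull is idempotent, monotone, and exact on convex sets", {
  # filled rectangle is its own hull
  m <- matrix(0, 8, 9); m[3:6, 2:7] <- 1
  expect_equal(convex_hull_mask(m), m)

  # empty in, empty out
  expect_equal(convex_hull_mask(matrix(0, 5, 5)), matrix(0, 5, 5))

  # single pixel
  one <- matrix(0, 5, 5); one[3, 4] <- 1
  expect_equal(convex_hull_mask(one), one)

  # idempotence and monotonicity on random masks
  withr::with_seed(14, {
    for (i in 1:30) {
      m <- random_mask(12, 12, 0.2)
      h <- convex_hull_mask(m)
      expect_true(all(h >= m))          # hull contains the mask
      expect_equal(convex_hull_mask(h), h)
    }
  })
})

test_that("convex hull rasterization matches a point-in-polygon oracle", {
  in_hull_oracle <- function(mask) {
    idx <- which(mask > 0, arr.ind = TRUE)
    pts <- cbind(idx[, "col"], idx[, "row"])
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    out <- matrix(0, nrow(mask), ncol(mask))
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      out[i, j] <- pracma::inpolygon(j, i, pts[hull, 1], pts[hull, 2],
                                     boundary = TRUE)
    }
    out
  }
  # two diagonal corner pixels of a 5x5 grid: hull is the connecting band
  two <- matrix(0, 5, 5); two[1, 1] <- 1; two[5, 5] <- 1
  got <- convex_hull_mask(two)
  expect_equal(got, diag(5))  # centers on the segment are exactly the diagonal
  withr::with_seed(15, {
    for (i in 1:20) {
      m <- random_mask(9, 9, 0.15)
      if (sum(m) < 3) next
      expect_equal(convex_hull_mask(m), in_hull_oracle(m))
    }
  })
})

test_that("largest inscribed rectangle is exact on known masks", {
  full <- matrix(1, 5, 5)
  expect_equal(largest_inscribed_rectangle(full),
               list(top = 1, left = 1, height = 5, width = 5))

  one <- matrix(0, 6, 6); one[4, 2] <- 1
  expect_equal(largest_inscribed_rectangle(one),
               list(top = 4, left = 2, height = 1, width = 1))

  # L-shaped mask: 7x7 minus its top-right 3x4 block
  L <- matrix(1, 7, 7); L[1:3, 4:7] <- 0
  r <- largest_inscribed_rectangle(L)
  expect_equal(r$height * r$width, brute_force_max_rect(L))

  expect_null(largest_inscribed_rectangle(matrix(0, 4, 4)))
})

test_that("largest inscribed rectangle matches brute force on random masks", {
  withr::with_seed(16, {
    for (i in 1:200) {
      m <- random_mask(12, 12, runif(1, 0.3, 0.9))
      r <- largest_inscribed_rectangle(m)
      area <- if (is.null(r)) 0L else r$height * r$width
      expect_identical(area, brute_force_max_rect(m))
      if (!is.null(r)) {
        patch <- m[r$top:(r$top + r$height - 1), r$left:(r$left + r$width - 1)]
        expect_true(all(patch == 1))    # returned rectangle is all ones
      }
    }
  })
})

test_that("sample_roi draws uniformly inside the maximal rectangle", {
  # rectangle exactly R x R: the unique ROI is drawn with probability 1
  vol <- brain_volume(matrix(rnorm(100), 10, 10),
                      {m <- matrix(0, 10, 10); m[2:9, 3:10] <- 1; m},
                      id = "v")
  r <- sample_roi(vol, 1, 8, seed = 1)
  expect_equal(c(r$top, r$left), c(2, 3))
  expect_equal(dim(r$pixels), c(8, 8))

  # discard rule: hull one pixel too small in one dimension
  small <- brain_volume(matrix(0, 63, 200) + 1:63 %o% rep(1, 200) * 0 + 1,
                        matrix(1, 63, 200), id = "s")
  expect_null(sample_roi(small, 1, 64))

  # uniformity over the (R+4) x (R+9) admissible offsets
  vol2 <- brain_volume(matrix(rnorm(12 * 17), 12, 17), matrix(1, 12, 17),
                       id = "u")
  withr::with_seed(17, {
    draws <- replicate(10000, {
      r <- sample_roi(vol2, 1, 8)
      (r$top - 1) * 10 + r$left
    })
  })
  counts <- table(factor(draws, levels = sort(unique(draws))))
  expect_equal(length(counts), 50)     # 5 x 10 admissible positions
  expect_gt(chisq.test(counts)$p.value, 1e-4)

  expect_error(sample_roi(vol, 5, 8), "out of range")
})

test_that("sampled ROIs stay inside the hull rectangle", {
  withr::with_seed(18, {
    for (i in 1:20) {
      m <- matrix(0, 20, 20)
      m[sample(4:16, 1):17, sample(3:12, 1):18] <- 1
      vol <- brain_volume(matrix(rnorm(400), 20, 20), m, id = "p")
      rect <- largest_inscribed_rectangle(convex_hull_mask(m))
      r <- sample_roi(vol, 1, 4)
      if (is.null(r)) next
      expect_gte(r$top, rect$top)
      expect_gte(r$left, rect$left)
      expect_lte(r$top + 3, rect$top + rect$height - 1)
      expect_lte(r$left + 3, rect$left + rect$width - 1)
    }
  })
})

test_that("block downsampling averages and conserves the grand mean", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  expect_identical(downsample_blocks(img, 1), img)
  expect_equal(downsample_blocks(rbind(c(0, 1), c(1, 0)), 2),
               matrix(0.5, 1, 1))
  expect_equal(downsample_blocks(matrix(7, 6, 6), 3), matrix(7, 2, 2))
  ds <- downsample_blocks(img, 4)
  expect_equal(mean(ds), mean(img), tolerance = 1e-14)
  expect_equal(dim(ds), c(16, 16))
  expect_error(downsample_blocks(matrix(0, 5, 5), 2), "divisible")
})

test_that("ROI carries provenance and effective pixel size", {
  vol <- brain_volume(matrix(rnorm(80 * 80), 80, 80), matrix(1, 80, 80),
                      pixel_mm = 1, id = "prov")
  r <- sample_roi(vol, 1, 32, N = 2, seed = 2)
  expect_equal(dim(r$pixels), c(32, 32))
  expect_equal(r$pixel_mm, c(2, 2))
  expect_equal(r$volume_id, "prov")
  # downsampled patch equals block-averaging the raw patch
  raw <- vol$slices[[1]][r$top:(r$top + 63), r$left:(r$left + 63)]
  expect_equal(r$pixels, downsample_blocks(raw, 2))
})
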