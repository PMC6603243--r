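test_that("block_counts tabulates sliding 2x2 neighborhoods", {
  # 3x3 all-white: 4 blocks, all in the all-white coloring
  d <- block_counts(matrix(1, 3, 3))
  expect_equal(d$n_blocks, 4)
  expect_equal(unname(d$probs[16]), 1)
  expect_equal(sum(d$probs), 1)

  # 2x3 image W,B,W / W,B,W: two windows, colorings 1010 and 0101
  img <- rbind(c(1, -1, 1), c(1, -1, 1))
  d <- block_counts(img)
  expect_equal(d$n_blocks, 2)
  expect_equal(unname(d$probs[c("1010", "0101")]), c(0.5, 0.5))
  expect_equal(sum(d$probs), 1)

  # odd-sized checkerboard: exactly the two alternating colorings, half each
  cb <- outer(1:9, 1:9, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  d <- block_counts(cb)
  expect_equal(unname(d$probs[c("1001", "0110")]), c(0.5, 0.5))
  expect_equal(sum(d$counts > 0), 2)

  expect_error(block_counts(matrix(1, 1, 5)), "2x2")
  expect_error(block_counts(matrix(c(0, 1, 1, 1), 2, 2)), "-1 or \\+1")
})

test_that("block_counts matches a naive double-loop tabulation", {
  withr::with_seed(42, {
    for (i in 1:100) {
      img <- random_binary_image(10, 10)
      expect_identical(unname(block_counts(img)$counts),
                       naive_block_counts(img))
    }
  })
})

test_that("probs_to_stats maps canonical distributions correctly", {
  nm <- names(probs_to_stats(rep(1 / 16, 16)))

  # maximum entropy: all ten statistics zero
  expect_equal(unname(probs_to_stats(rep(1 / 16, 16))), rep(0, 10))

  # all-white with probability 1: every statistic at +1
  p <- rep(0, 16); p[16] <- 1
  expect_equal(unname(probs_to_stats(p)), rep(1, 10))

  # half all-white, half all-black: gamma 0, betas +1, thetas 0, alpha +1
  p <- rep(0, 16); p[1] <- 0.5; p[16] <- 0.5
  expect_equal(probs_to_stats(p),
               c(gamma = 0, beta_h = 1, beta_v = 1, beta_md = 1,
                 beta_ad = 1, theta_tl = 0, theta_tr = 0, theta_br = 0,
                 theta_bl = 0, alpha = 1))

  # checkerboard distribution: betas (edge -1, diagonal +1), thetas 0
  cb <- outer(1:9, 1:9, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  expect_equal(probs_to_stats(block_counts(cb)),
               c(gamma = 0, beta_h = -1, beta_v = -1, beta_md = 1,
                 beta_ad = 1, theta_tl = 0, theta_tr = 0, theta_br = 0,
                 theta_bl = 0, alpha = 1))

  expect_error(probs_to_stats(rep(1 / 8, 16)), "sum to 1")
})

test_that("probs_to_stats is linear and matches enumeration oracle", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- as.numeric(stats::rmultinom(1, 500, rep(1, 16))) / 500
      q <- as.numeric(stats::rmultinom(1, 500, 1:16)) / 500
      expect_equal(unname(probs_to_stats(p)), unname(naive_probs_to_stats(p)),
                   tolerance = 1e-12)
      a <- runif(1)
      expect_equal(probs_to_stats(a * p + (1 - a) * q),
                   a * probs_to_stats(p) + (1 - a) * probs_to_stats(q),
                   tolerance = 1e-12)
    }
  })
})

test_that("stats_to_probs inverts probs_to_stats on realizable vectors", {
  # all-zero statistics give the uniform distribution
  expect_equal(as.vector(stats_to_probs(rep(0, 10))), rep(1 / 16, 16))

  # alpha = 1 concentrates on the eight even-parity colorings
  s <- c(rep(0, 9), 1)
  p <- stats_to_probs(s)
  even <- vapply(0:15, function(i) sum(as.integer(intToBits(i)[1:4])) %% 2 == 0,
                 TRUE)
  expect_equal(as.vector(p[even]), rep(1 / 8, 8))
  expect_equal(as.vector(p[!even]), rep(0, 8))

  # round trip on 100 random realizable vectors
  withr::with_seed(11, {
    kept <- 0
    while (kept < 100) {
      s <- runif(10, -0.35, 0.35)
      p <- suppressWarnings(stats_to_probs(s))
      if (!attr(p, "realizable")) next
      kept <- kept + 1
      expect_equal(unname(probs_to_stats(as.numeric(p))), unname(s),
                   tolerance = 1e-12)
    }
  })

  expect_warning(stats_to_probs(c(0, 0.9, 0, 0, 0, 0, 0, 0, 0, 0)),
                 "realizable")
  expect_error(stats_to_probs(c(2, rep(0, 9))), "\\[-1, 1\\]")
})

test_that("stats_for_roi fixed points: stripes, coin flips", {
  # horizontal stripes (rows alternate), odd height for exact phase balance
  stripes <- matrix(rep(c(1, -1), length.out = 9), 9, 8)
  expect_equal(stats_for_roi(stripes),
               c(gamma = 0, beta_h = 1, beta_v = -1, beta_md = -1,
                 beta_ad = -1, theta_tl = 0, theta_tr = 0, theta_br = 0,
                 theta_bl = 0, alpha = 1),
               tolerance = 1e-12)

  # i.i.d. fair coin: all statistics near zero
  withr::with_seed(3, {
    img <- random_binary_image(30, 30)
    expect_true(all(abs(stats_for_roi(img)) < 3 / sqrt(29^2)))
  })
})

test_that("mirroring images permutes the statistics as expected", {
  flip_h <- function(m) m[, rev(seq_len(ncol(m)))]
  flip_v <- function(m) m[rev(seq_len(nrow(m))), ]
  perm_h <- c(gamma = "gamma", beta_h = "beta_h", beta_v = "beta_v",
              beta_md = "beta_ad", beta_ad = "beta_md",
              theta_tl = "theta_tr", theta_tr = "theta_tl",
              theta_br = "theta_bl", theta_bl = "theta_br",
              alpha = "alpha")
  perm_v <- c(gamma = "gamma", beta_h = "beta_h", beta_v = "beta_v",
              beta_md = "beta_ad", beta_ad = "beta_md",
              theta_tl = "theta_bl", theta_bl = "theta_tl",
              theta_tr = "theta_br", theta_br = "theta_tr",
              alpha = "alpha")
  withr::with_seed(5, {
    for (i in 1:10) {
      img <- random_binary_image(12, 15)
      s <- stats_for_roi(img)
      expect_equal(stats_for_roi(flip_h(img)),
                   setNames(s[perm_h[names(s)]], names(s)),
                   tolerance = 1e-12)
      expect_equal(stats_for_roi(flip_v(img)),
                   setNames(s[perm_v[names(s)]], names(s)),
                   tolerance = 1e-12)
    }
  })
})
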