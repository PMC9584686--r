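test_that("butterworth low-pass preserves DC and matches the brute-force DFT oracle", {
  cfg <- lin_config(cutoff = 2, butterworth_order = 2)
  # constant image: only the zero frequency is populated, gain exactly 1
  expect_equal(butterworth_lowpass(matrix(100, 6, 9), cfg),
               matrix(100, 6, 9), tolerance = 1e-12)
  # transfer function at D = D0 is 1/2 for any order
  for (ord in c(1, 2, 5)) expect_equal(1 / (1 + 1^(2 * ord)), 0.5)
  for (seed in 1:3) {
    img <- random_image(8, 8, seed)
    got <- butterworth_lowpass(img, cfg)
    expect_lt(max(abs(got - oracle_butterworth(img, 2, 2))), 1e-9)
  }
  # non-square images are supported
  img <- random_image(5, 9, 99)
  cfg2 <- lin_config(cutoff = 3, butterworth_order = 1)
  expect_lt(max(abs(butterworth_lowpass(img, cfg2) -
                      oracle_butterworth(img, 3, 1))), 1e-9)
})

test_that("butterworth rejects empty images and bad cutoffs", {
  expect_error(butterworth_lowpass(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(lin_config(cutoff = -1), "cutoff")
})

test_that("pair entropy matches exhaustive tuple enumeration", {
  # constant image: a single tuple with probability one
  expect_identical(pair_entropy(matrix(7, 5, 5)), 0)
  # the 2x2 checker: two tuple types, each with probability 1/2
  m <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(pair_entropy(m, neighborhood_radius = 1),
               oracle_pair_entropy(m))
  for (seed in 1:5) {
    img <- random_image(6, 7, seed + 10)
    expect_equal(pair_entropy(img), oracle_pair_entropy(img), tolerance = 1e-12)
  }
})

test_that("pair entropy is bounded by the log of the number of distinct tuples", {
  for (seed in 1:5) {
    img <- random_image(8, 8, seed + 20)
    h <- pair_entropy(img)
    codes <- paste(round(img), round(spikelin:::neighbor_mean(round(img))))
    expect_gte(h, 0)
    expect_lte(h, log2(length(unique(codes))) + 1e-12)
    expect_lte(h, 16)
  }
})

test_that("inhibition kernel follows A*exp(-d*H) and its symmetries", {
  cfg <- lin_config("adaptive", radius = 1, amplitude = 1,
                    include_center = FALSE)
  # H = 0: every off-centre tap is exp(0) = 1, centre forced to 0
  k0 <- inhibition_kernel(cfg, 0)
  expect_equal(k0, matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3))
  # direct evaluation at offset (1, 0), H = 0.5
  k <- inhibition_kernel(lin_config("adaptive", radius = 1), 0.5)
  expect_equal(k[3, 2], exp(-0.5), tolerance = 1e-9)
  expect_equal(k[3, 2], 0.60653, tolerance = 1e-5)
  # square symmetries: invariant under transpose and flips
  k2 <- inhibition_kernel(lin_config("adaptive", radius = 2), 1.3)
  expect_equal(k2, t(k2))
  expect_equal(k2, k2[5:1, ])
  expect_equal(k2, k2[, 5:1])
  # strictly decreasing in H and in distance
  hs <- c(0.1, 0.5, 1, 2)
  vals <- vapply(hs, function(h)
    inhibition_kernel(lin_config("adaptive", radius = 2), h)[3, 4], numeric(1))
  expect_true(all(diff(vals) < 0))
  k3 <- inhibition_kernel(lin_config("adaptive", radius = 2), 1)
  expect_gt(k3[3, 4], k3[3, 5])   # d = 1 vs d = 2
  # traditional mode ignores the entropy
  kt <- inhibition_kernel(lin_config("traditional", radius = 1,
                                     fixed_coefficient = 0.3), 5)
  expect_equal(kt, matrix(0.3, 3, 3))
  expect_error(inhibition_kernel(cfg, -1), "non-negative")
})

test_that("apply_lin equals the double-loop oracle in both modes", {
  # zero inhibition leaves the image untouched
  img <- random_image(6, 6, 1)
  cfg0 <- lin_config("traditional", fixed_coefficient = 0)
  expect_equal(apply_lin(img, cfg0), img)
  # constant image, full 3x3 field with coefficient k: G = c * (1 - 9k)
  cfg1 <- lin_config("traditional", radius = 1, fixed_coefficient = 0.05,
                     include_center = TRUE)
  expect_equal(apply_lin(matrix(80, 9, 9), cfg1)[5, 5], 80 * (1 - 9 * 0.05),
               tolerance = 1e-12)
  # property sweep: random images up to 16x16, several configs
  set.seed(42)
  for (i in 1:25) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    cfg <- lin_config(mode = sample(c("traditional", "adaptive"), 1),
                      radius = sample(0:2, 1),
                      fixed_coefficient = runif(1, 0, 0.2),
                      cutoff = runif(1, 1, 6),
                      include_center = sample(c(TRUE, FALSE), 1),
                      inhibit_filtered = sample(c(TRUE, FALSE), 1),
                      clamp_output = sample(c(TRUE, FALSE), 1))
    expect_lt(max(abs(apply_lin(img, cfg) - oracle_lin(img, cfg))), 1e-9)
  }
})

test_that("a step edge gains a darker dark side and brighter bright side", {
  # 1D step embedded in 2D: dark half 20, bright half 200
  img <- cbind(matrix(20, 9, 6), matrix(200, 9, 6))
  cfg <- lin_config("traditional", radius = 2, fixed_coefficient = 0.02,
                    include_center = TRUE)
  g <- apply_lin(img, cfg)
  mid <- 5
  row <- g[mid, 3:10]
  interior_dark <- row[2]     # away from both edge and border
  edge_dark <- row[4]         # last dark column before the step
  edge_bright <- row[5]
  interior_bright <- row[7]
  expect_lt(edge_dark, interior_dark)
  expect_gt(edge_bright, interior_bright)
})

test_that("windowed adaptive inhibition suppresses smooth background more than textured target", {
  spec <- synth_spec(seed = 7, samples_per_class = 5)
  d <- make_images(spec)
  cfg <- lin_config("adaptive", include_center = FALSE, window = 9)
  wins <- 0
  n <- length(d$labels)
  for (i in seq_len(n)) {
    img <- d$images[, , i]; msk <- d$masks[, , i]
    g <- apply_lin(img, cfg)
    red <- abs(img - g)
    if (mean(red[!msk]) > mean(red[msk])) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.9 * n))
})

test_that("windowed entropy map is low on background, high on target", {
  spec <- synth_spec(seed = 3, samples_per_class = 2)
  d <- make_images(spec)
  hm <- pair_entropy_map(d$images[, , 1], window = 9)
  msk <- d$masks[, , 1]
  expect_gt(median(hm[msk]), median(hm[!msk]) + 1)
})
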