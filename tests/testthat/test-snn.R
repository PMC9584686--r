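small_config <- function(seed = 1, branches = list(
                           list(kernel_size = 3, out_channels = 2),
                           list(kernel_size = 5, out_channels = 2))) {
  network_config(num_classes = 3, branches = branches, timesteps = 6,
                 input_shape = c(1, 10, 10), seed = seed)
}

test_that("build_network is seeded and its parameter count follows the shapes", {
  cfg <- small_config()
  net1 <- build_network(cfg)
  net2 <- build_network(cfg)
  expect_identical(net1$branches[[1]]$kernel, net2$branches[[1]]$kernel)
  expect_identical(net1$fc[[1]]$W, net2$fc[[1]]$W)
  # hand-computed shape arithmetic: conv 3x3x1x2 + 5x5x1x2 = 68;
  # pooled features 4*4*2 + 3*3*2 = 50; dense 3*50 = 150
  expect_identical(n_parameters(net1), 9 * 2 + 25 * 2 + 3 * 50)
  # weights within the documented init range, taus jittered around tau_init
  expect_true(all(abs(net1$fc[[1]]$W) <= 0.1))
  expect_true(all(net1$branches[[1]]$tau >= 9 & net1$branches[[1]]$tau <= 11))
  expect_gt(sd(net1$branches[[1]]$tau), 0)   # neuron diversity at init
  expect_error(network_config(num_classes = 0), ">= 1")
  expect_error(network_config(num_classes = 2, branches = list(
    list(kernel_size = 4, out_channels = 2))), "odd")
})

test_that("forward pass equals the plain-R reference network", {
  net <- build_network(small_config())
  img <- random_image(10, 10, 4)
  x <- rate_encode(img, timesteps = 6, seed = 3)
  got <- snn_forward(net, x)
  ref <- oracle_forward(net, x)
  expect_identical(got$counts, ref$counts)
  expect_identical(got$output_spikes == 1, ref$output_spikes == 1)
  # single-branch network against the same reference (the non-parallel
  # ablation axis)
  net1 <- build_network(small_config(branches = list(
    list(kernel_size = 3, out_channels = 4))))
  got1 <- snn_forward(net1, x)
  expect_identical(got1$counts, oracle_forward(net1, x)$counts)
})

test_that("forward pass resets state and is silent without drive", {
  net <- build_network(small_config())
  x <- rate_encode(random_image(10, 10, 8), timesteps = 6, seed = 1)
  a <- snn_forward(net, x)
  b <- snn_forward(net, x)
  expect_identical(a$counts, b$counts)   # state reset between presentations
  zero <- array(0, dim = c(6, 1, 10, 10))
  expect_identical(sum(snn_forward(net, zero)$counts), 0)
  expect_error(snn_forward(net, array(0, dim = c(5, 1, 10, 10))), "shape")
})

test_that("more input spikes never yield fewer output spikes for non-negative weights", {
  set.seed(21)
  for (rep in 1:5) {
    cfg <- network_config(num_classes = 2, branches = list(
      list(kernel_size = 3, out_channels = 2)), timesteps = 5,
      input_shape = c(1, 8, 8), seed = rep)
    net <- build_network(cfg)
    net$branches[[1]]$kernel <- abs(net$branches[[1]]$kernel)
    net$fc[[1]]$W <- abs(net$fc[[1]]$W)
    base <- array(as.numeric(runif(5 * 64) < 0.2), dim = c(5, 1, 8, 8))
    extra <- pmin(base + array(as.numeric(runif(5 * 64) < 0.3),
                               dim = c(5, 1, 8, 8)), 1)
    expect_gte(sum(snn_forward(net, extra)$counts),
               sum(snn_forward(net, base)$counts))
  }
})

test_that("predict takes the argmax with documented tie-breaks", {
  net <- build_network(small_config())
  # synthetic counts through the exported surface: check the rules directly
  # on crafted forwards is brittle, so probe the documented behaviour
  x <- rate_encode(matrix(255, 10, 10), timesteps = 6, seed = 2)
  p <- suppressWarnings(predict(net, x))
  expect_true(p %in% 0:2)
  zero <- array(0, dim = c(6, 1, 10, 10))
  expect_warning(p0 <- predict(net, zero), "class 0")
  expect_identical(p0, 0L)
  # list input vectorises
  expect_length(suppressWarnings(predict(net, list(x, x))), 2)
})

test_that("network containers round-trip through the binary serialisation", {
  net <- build_network(small_config())
  path <- tempfile(fileext = ".bin")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$branches[[1]]$kernel, net$branches[[1]]$kernel)
  expect_equal(back$branches[[2]]$tau, net$branches[[2]]$tau)
  expect_equal(back$fc[[1]]$W, net$fc[[1]]$W)
  expect_identical(back$config$num_classes, net$config$num_classes)
  # identical behaviour after the round trip
  x <- rate_encode(random_image(10, 10, 5), timesteps = 6, seed = 1)
  expect_identical(snn_forward(back, x)$counts, snn_forward(net, x)$counts)
})
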