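# a small but learnable task shared across the training tests: 40 images,
# enhanced and encoded once
learn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synth_spec(seed = 11, samples_per_class = 20)
      d <- make_images(spec)
      lin <- lin_config("adaptive", include_center = FALSE,
                        clamp_output = TRUE, window = 9)
      imgs <- vapply(seq_len(40), function(i) apply_lin(d$images[, , i], lin),
                     matrix(0, 28, 28))
      cache <<- list(inputs = encode_dataset(imgs, timesteps = 20, seed = 2),
                     labels = d$labels)
    }
    cache
  }
})

test_that("output error is the mean summed squared deviation", {
  d <- rbind(c(1, 0), c(0, 1))
  expect_identical(output_error(d, d), 0)
  # one sample, two outputs, fully wrong: (1-0)^2 + (0-1)^2 = 2
  expect_identical(output_error(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 2)
  # invariant under permuting samples
  o <- rbind(c(0.4, 0.2), c(0.9, 0.3))
  expect_equal(output_error(d, o), output_error(d[2:1, ], o[2:1, ]))
  expect_error(output_error(d, o[, 1, drop = FALSE]), "identical shapes")
})

test_that("the teaching signal follows the desired-spike cases", {
  expect_identical(alpha_signal(1), 1)
  expect_identical(alpha_signal(0), -1)
  expect_identical(alpha_signal(1, defined = FALSE), 0)
  expect_identical(alpha_signal(c(1, 0, 1), defined = c(TRUE, TRUE, FALSE)),
                   c(1, -1, 0))
})

test_that("the windowed weight change counts presynaptic spikes in [t-eps, t]", {
  cfg <- train_config(learning_rate = 0.1, window = 3)
  s <- c(1, 0, 1, 1, 0, 1)
  expect_identical(delta_w(cfg, 0, s, 4), 0)
  # eta=0.1, alpha=+1, spikes at steps 2,3,5 within [2,5]: 3 spikes -> 0.3
  expect_equal(delta_w(cfg, 1, s, 5), 0.3, tolerance = 1e-12)
  expect_identical(delta_w(cfg, -1, rep(0, 6), 5), 0)
  # window clipped at zero
  expect_equal(delta_w(cfg, 1, s, 1), 0.1 * sum(s[1:2]), tolerance = 1e-12)
  expect_error(delta_w(cfg, 1, s, -1), ">= 0")
})

test_that("apply_update is element-wise, clipped, and invertible", {
  w <- matrix(c(0.5, -0.2), 1)
  d <- matrix(c(0.3, 0.1), 1)
  expect_equal(apply_update(w, d), matrix(c(0.8, -0.1), 1))
  expect_identical(apply_update(w, d * 0), w)
  expect_lt(max(abs(apply_update(apply_update(w, d), -d) - w)), 1e-12)
  expect_equal(apply_update(matrix(0.9), matrix(0.5), clip = c(-1, 1)),
               matrix(1))
})

test_that("training converges on the separable synthetic task", {
  fx <- learn_fixture()
  net <- build_network(network_config(num_classes = 2, seed = 1))
  fit <- snn_train(net, fx$inputs, fx$labels,
                   train_config(epochs = 15, seed = 1))
  h <- fit$history
  expect_gte(tail(h$train_acc, 1), 0.9)
  # the output error decays compared to the start of training
  expect_lt(median(tail(h$error, 5)), median(head(h$error, 5)))
  # neuron diversity is preserved through training
  expect_gt(tail(h$tau_sd, 1), 0)
})

test_that("zero learning signal leaves the network untouched", {
  fx <- learn_fixture()
  net <- build_network(network_config(num_classes = 2, seed = 3))
  # smallest positive rate with gating on a trivially mislabelled... instead
  # exercise the documented contract: eta -> 0^+ makes all deltas vanish
  fit <- snn_train(net, fx$inputs[1:4], fx$labels[1:4],
                   train_config(epochs = 2, seed = 1, learning_rate = 1e-300))
  expect_equal(fit$network$fc[[1]]$W, net$fc[[1]]$W, tolerance = 1e-12)
  expect_equal(fit$network$branches[[1]]$kernel, net$branches[[1]]$kernel,
               tolerance = 1e-12)
})

test_that("training is deterministic given seeds and shuffles otherwise", {
  fx <- learn_fixture()
  net <- build_network(network_config(num_classes = 2, seed = 5))
  f1 <- snn_train(net, fx$inputs, fx$labels, train_config(epochs = 3, seed = 9))
  f2 <- snn_train(net, fx$inputs, fx$labels, train_config(epochs = 3, seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$fc[[1]]$W, f2$network$fc[[1]]$W)
})

test_that("label shuffling reduces accuracy to about chance", {
  fx <- learn_fixture()
  set.seed(4)
  shuffled <- sample(fx$labels)
  net <- build_network(network_config(num_classes = 2, seed = 2))
  fit <- snn_train(net, fx$inputs, shuffled, train_config(epochs = 10, seed = 2))
  # with 40 samples, chance is 0.5 +- ~0.08 sd; allow a generous band
  expect_lt(tail(fit$history$train_acc, 1), 0.75)
})

test_that("the per-epoch tau trajectory replays the anchored evolution rule", {
  fx <- learn_fixture()
  cfg <- network_config(num_classes = 2, seed = 7)
  net <- build_network(cfg)
  tau_init_out <- net$fc[[1]]$tau_init
  fit <- snn_train(net, fx$inputs, fx$labels, train_config(epochs = 8, seed = 7))
  rule <- cfg$tau_rule
  replay <- t(vapply(fit$history$error, function(E)
    evolve_tau(rule, tau_init_out, E, tau_init = tau_init_out),
    numeric(length(tau_init_out))))
  expect_identical(unname(fit$tau_trace), unname(replay))
  # final network tau equals the last replayed row exactly
  expect_identical(fit$network$fc[[1]]$tau, replay[nrow(replay), ])
  # anchored with negative rate: tau below tau_init while E > 0, and E = 0
  # restores tau_init exactly
  expect_true(all(fit$tau_trace <= tau_init_out[col(fit$tau_trace)] + 1e-12))
  expect_identical(evolve_tau(rule, fit$network$fc[[1]]$tau, 0,
                              tau_init = tau_init_out), tau_init_out)
})

test_that("tau moves with the error and recovers as the error vanishes", {
  rule <- tau_rule(rate = -0.1, tau_init = 10, tau_bounds = c(1, 100))
  errors <- c(2, 1.5, 1, 0.5, 0.1, 0)
  taus <- vapply(errors, function(E) evolve_tau(rule, 10, E), numeric(1))
  expect_true(all(diff(taus) > 0))       # tau rises back as E decays
  expect_identical(taus[length(taus)], 10)
})
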