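# Supervised STDP-based training. The output layer's desired spike train is
# one-hot per time step (the target class should spike at every step, the
# others never). The teaching signal alpha is +1 where the desired spike is
# 1, -1 where it is 0, and 0 otherwise; the weight change for synapse
# (i <- h) at step t is
#     dw_ih(t) = eta * alpha_i(t) * sum_{f = t-eps..t} s_h(f)
# i.e. the presynaptic spike count inside a sliding window of eps steps.
# Under the default `error` gating the signal is applied only at steps
# where the actual output spike differs from the desired one (the rule's
# "otherwise -> 0" case covers correct outputs), which makes the update
# error-driven and lets the output error E actually decay; `gating = "none"`
# applies the signal at every step regardless of the output. Hidden layers
# receive the downstream alphas through the transposed forward weights,
# thresholded to {-1, 0, +1} by sign, and apply the same windowed rule.
# After each epoch the quadratic output error E drives the per-neuron
# time-constant evolution.

#' Training configuration
#'
#' @param learning_rate Positive step size `eta` (default 0.001).
#' @param window Sliding-window length `eps` in time steps over which
#'   presynaptic spikes are counted (default 5; must not exceed the
#'   network's `timesteps`).
#' @param epochs Number of passes over the data (default 30).
#' @param seed Integer seed driving the per-epoch sample order.
#' @param gating `"error"` (default): the teaching signal acts only at time
#'   steps where the output spike differs from the desired spike, so
#'   updates vanish as the output becomes correct. `"none"`: the signal acts
#'   at every step based on the desired spike alone.
#' @param train_conv Also update convolution kernels (default `TRUE`); when
#'   `FALSE` the branches act as fixed random feature extractors.
#' @param weight_clip Length-2 range to which every weight is clipped after
#'   each sample, keeping the spiking dynamics bounded (default
#'   `c(-1, 1)`).
#' @param shuffle Reshuffle the sample order each epoch (default `TRUE`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, window = 5L, epochs = 30L,
                         seed = 0L, gating = c("error", "none"),
                         train_conv = TRUE, weight_clip = c(-1, 1),
                         shuffle = TRUE) {
  gating <- match.arg(gating)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (window < 0) stop("`window` must be >= 0", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (length(weight_clip) != 2 || weight_clip[1] >= weight_clip[2])
    stop("`weight_clip` must be an increasing length-2 range", call. = FALSE)
  structure(list(learning_rate = learning_rate, window = as.integer(window),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 gating = gating, train_conv = isTRUE(train_conv),
                 weight_clip = weight_clip, shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Quadratic output error between desired and actual spike trains
#'
#' Mean over samples of the summed squared difference between the desired
#' outputs (1 for the target class, 0 otherwise) and the actual outputs
#' (spike counts normalised by the number of time steps).
#'
#' @param desired Numeric matrix `n_samples x n_classes` of desired outputs
#'   (typically one-hot rows).
#' @param actual Matrix of the same shape holding normalised spike counts.
#' @return Non-negative scalar error.
#' @export
output_error <- function(desired, actual) {
  if (!identical(dim(desired), dim(actual)))
    stop("`desired` and `actual` must have identical shapes", call. = FALSE)
  if (length(desired) == 0) stop("empty inputs", call. = FALSE)
  mean(rowSums((desired - actual)^2))
}

#' Teaching signal for one neuron at one time step
#'
#' +1 when the desired output spike is 1, -1 when it is 0, and 0 for
#' neurons with no defined desired output at this step.
#'
#' @param desired_spike 0/1 desired spike value (vectorised).
#' @param defined Whether a desired output exists for this neuron/step
#'   (default `TRUE`).
#' @return Values in `{-1, 0, 1}`.
#' @export
alpha_signal <- function(desired_spike, defined = TRUE) {
  ifelse(!defined, 0, ifelse(desired_spike == 1, 1, -1))
}

#' Windowed weight change for one synapse
#'
#' `eta * alpha * (number of presynaptic spikes in the window [t-eps, t])`,
#' with the window clipped at step 0.
#'
#' @param config A [train_config()] (supplies `eta` and `eps`).
#' @param alpha Teaching signal in `{-1, 0, 1}`.
#' @param presyn_spikes Binary vector of presynaptic spikes, step 0 first.
#' @param t Time step (0-based).
#' @return The weight change (scalar).
#' @export
delta_w <- function(config, alpha, presyn_spikes, t) {
  if (t < 0) stop("`t` must be >= 0", call. = FALSE)
  lo <- max(0L, t - config$window)
  config$learning_rate * alpha *
    sum(presyn_spikes[(lo + 1L):(t + 1L)])
}

#' Element-wise weight update
#'
#' Adds the accumulated changes to the weights, optionally clipping to a
#' range.
#'
#' @param weights Numeric array or matrix.
#' @param deltas Same-shape array of accumulated changes.
#' @param clip Optional length-2 range.
#' @return Updated weights.
#' @export
apply_update <- function(weights, deltas, clip = NULL) {
  if (!identical(dim(weights), dim(deltas)))
    stop("`weights` and `deltas` must have identical shapes", call. = FALSE)
  out <- weights + deltas
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  out
}

#' Train a spiking network with the windowed STDP rule
#'
#' Per sample the network runs forward over all time steps while windowed
#' presynaptic spike counts are accumulated; output-layer weights change by
#' `eta * alpha * count`, hidden layers receive sign-thresholded downstream
#' alphas through the transposed weights, and convolution kernels correlate
#' their pooled units' alphas with the windowed input counts. Updates are
#' applied per sample (online). At each epoch end the quadratic output
#' error E is computed and every neuron's membrane time constant evolves
#' under the network's [tau_rule()]. Deterministic given the seeds.
#'
#' @param network A [build_network()] result.
#' @param inputs List of spike tensors `(timesteps, channels, height,
#'   width)`.
#' @param labels Integer class labels (0-based), one per input.
#' @param config A [train_config()].
#' @return An object of class `spikelin_fit`: the trained `network`, a
#'   `history` tibble (`epoch`, `error`, `train_acc`, `tau_mean`,
#'   `tau_sd`), and `tau_trace` (`epochs x num_classes` matrix of
#'   output-layer time constants).
#' @export
snn_train <- function(network, inputs, labels, config = train_config()) {
  if (!inherits(network, "spikelin_network"))
    stop("`network` must be a spikelin_network", call. = FALSE)
  if (!is.list(inputs) || length(inputs) == 0)
    stop("`inputs` must be a non-empty list of spike tensors", call. = FALSE)
  if (length(labels) != length(inputs))
    stop("`labels` must match `inputs` in length", call. = FALSE)
  if (any(labels < 0 | labels >= network$config$num_classes))
    stop("labels outside 0..num_classes-1", call. = FALSE)
  if (config$window > network$config$timesteps)
    stop("`window` must not exceed the network's timesteps", call. = FALSE)

  n <- length(inputs)
  order_mat <- with_preserved_seed(config$seed, {
    t(vapply(seq_len(config$epochs), function(e) {
      if (config$shuffle) sample.int(n) - 1L else seq_len(n) - 1L
    }, integer(n)))
  })
  rule <- network$config$tau_rule

  # deep-copy weights/taus: the C++ trainer updates them in place
  branches <- lapply(network$branches, function(b) {
    list(kernel = b$kernel + 0, tau = b$tau + 0, tau_init = b$tau_init,
         out_dim = b$out_dim, pooled_dim = b$pooled_dim)
  })
  fc <- lapply(network$fc, function(f)
    list(W = f$W + 0, tau = f$tau + 0, tau_init = f$tau_init))

  res <- snn_train_cpp(branches, fc, inputs, as.integer(labels), order_mat,
                       cpp_params(network, list(
                         window = config$window,
                         learning_rate = config$learning_rate,
                         gated = config$gating == "error",
                         clip_lo = config$weight_clip[1],
                         clip_hi = config$weight_clip[2],
                         train_conv = config$train_conv,
                         tau_rate = rule$rate,
                         tau_lo = rule$tau_bounds[1],
                         tau_hi = rule$tau_bounds[2],
                         tau_mode = if (rule$mode == "anchored") 0L else 1L)))

  trained <- network
  trained$branches <- res$branches
  trained$fc <- res$fc
  history <- tibble::tibble(epoch = seq_len(config$epochs),
                            error = as.numeric(res$E),
                            train_acc = as.numeric(res$acc),
                            tau_mean = as.numeric(res$tau_mean),
                            tau_sd = as.numeric(res$tau_sd))
  structure(list(network = trained, history = history,
                 tau_trace = res$tau_trace, train_config = config),
            class = "spikelin_fit")
}

#' @export
print.spikelin_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<spikelin_fit> %d epochs: error %.4f -> %.4f, accuracy %.3f -> %.3f\n",
              nrow(h), h$error[1], tail(h$error, 1),
              h$train_acc[1], tail(h$train_acc, 1)))
  invisible(x)
}

#' Enhance, encode and train in one call
#'
#' Convenience pipeline for static images: optionally applies
#' lateral-inhibition enhancement (clamped to `[0, 255]`), rate-encodes
#' every image, and trains the network.
#'
#' @param images 3D array `(height, width, n)` of grayscale images.
#' @param labels Integer class labels (0-based).
#' @param net_config A [network_config()].
#' @param tr_config A [train_config()].
#' @param lin A [lin_config()], or `NULL` to skip enhancement. The default
#'   is the windowed adaptive configuration (sliding-window entropy, centre
#'   tap excluded, output clamped), which suppresses smooth backgrounds
#'   while preserving textured targets.
#' @param max_rate Peak spike probability for [rate_encode()].
#' @param encode_seed Seed for the spike encoders.
#' @return A `spikelin_fit` (with the encoded `inputs` attached for
#'   later evaluation).
#' @export
snn_fit_images <- function(images, labels, net_config,
                           tr_config = train_config(),
                           lin = lin_config("adaptive", include_center = FALSE,
                                            clamp_output = TRUE, window = 9),
                           max_rate = 1, encode_seed = tr_config$seed) {
  if (!is.null(lin)) {
    lin$clamp_output <- TRUE
    images <- vapply(seq_len(dim(images)[3]),
                     function(i) apply_lin(images[, , i], lin),
                     matrix(0, dim(images)[1], dim(images)[2]))
  }
  inputs <- encode_dataset(images, timesteps = net_config$timesteps,
                           max_rate = max_rate, seed = encode_seed)
  net <- build_network(net_config)
  fit <- snn_train(net, inputs, labels, tr_config)
  fit$inputs <- inputs
  fit$labels <- as.integer(labels)
  fit
}
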