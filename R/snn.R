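# Parallel convolutional spiking network: spike encoding -> (optional
# lateral-inhibition enhancement) -> parallel spiking-conv branches with
# different kernel sizes -> 2x2 pooling -> channel concatenation -> fully
# connected spiking output layer(s). Every neuron is a leaky
# integrate-and-fire unit with its own membrane time constant.

#' Network architecture and neuron defaults
#'
#' @param num_classes Number of output classes (>= 1).
#' @param branches List of branch specs, each `list(kernel_size, out_channels)`
#'   with an odd kernel size. The default realises the minimal parallel
#'   architecture: two branches with 3x3 and 5x5 kernels, 8 channels each,
#'   merged by channel concatenation after pooling.
#' @param pool `"max"` (binary OR over 2x2 spike blocks, default) or
#'   `"avg"` (graded 2x2 mean fed onward as current).
#' @param fc_sizes Integer sizes of the fully connected layers; the last
#'   must equal `num_classes`. Default: a single output layer.
#' @param timesteps Simulation steps per sample (default 20).
#' @param input_shape `c(channels, height, width)` of the input spike
#'   tensor (default `c(1, 28, 28)`; event input uses 2 channels).
#' @param neuron A [lif_params()] shared by all neurons except for the
#'   per-neuron jittered time constant. The default
#'   (`tau_m = 10`, `dt = 1`, `threshold = 0.1`) keeps randomly initialised
#'   weights supra-threshold often enough to bootstrap learning.
#' @param tau_rule A [tau_rule()] controlling time-constant evolution.
#' @param seed Integer seed for weight initialisation and tau jitter.
#' @return An object of class `network_config`.
#' @export
network_config <- function(num_classes,
                           branches = list(list(kernel_size = 3L, out_channels = 8L),
                                           list(kernel_size = 5L, out_channels = 8L)),
                           pool = c("max", "avg"), fc_sizes = NULL,
                           timesteps = 20L, input_shape = c(1L, 28L, 28L),
                           neuron = lif_params(resistance = 1, tau_m = 10,
                                               threshold = 0.1, dt = 1),
                           tau_rule = spikelin::tau_rule(), seed = 0L) {
  pool <- match.arg(pool)
  if (num_classes < 1) stop("`num_classes` must be >= 1", call. = FALSE)
  if (length(branches) < 1) stop("need at least one branch", call. = FALSE)
  for (b in branches) {
    if (b$kernel_size %% 2 == 0 || b$kernel_size < 1)
      stop("kernel sizes must be odd positive integers", call. = FALSE)
    if (b$out_channels < 1) stop("`out_channels` must be >= 1", call. = FALSE)
  }
  fc_sizes <- as.integer(fc_sizes %||% num_classes)
  if (tail(fc_sizes, 1) != num_classes)
    stop("last `fc_sizes` entry must equal `num_classes`", call. = FALSE)
  structure(list(num_classes = as.integer(num_classes), branches = branches,
                 pool = pool, fc_sizes = fc_sizes,
                 timesteps = as.integer(timesteps),
                 input_shape = as.integer(input_shape), neuron = neuron,
                 tau_rule = tau_rule, seed = as.integer(seed)),
            class = "network_config")
}

#' Build a parallel convolutional spiking network
#'
#' Instantiates all layers with seeded uniform weights in `[-0.1, 0.1]` and
#' per-neuron membrane time constants jittered uniformly in
#' `[0.9, 1.1] * tau_init` (the source of neuron diversity). The same seed
#' always yields bitwise-identical weights.
#'
#' @param config A [network_config()].
#' @return An object of class `spikelin_network`.
#' @export
build_network <- function(config) {
  C <- config$input_shape[1]; H <- config$input_shape[2]
  W <- config$input_shape[3]
  tau0 <- config$tau_rule$tau_init
  net <- with_preserved_seed(config$seed, {
    branches <- lapply(config$branches, function(b) {
      k <- as.integer(b$kernel_size); co <- as.integer(b$out_channels)
      oh <- H - k + 1L; ow <- W - k + 1L
      if (oh < 1L || ow < 1L)
        stop("kernel size exceeds input size", call. = FALSE)
      kernel <- array(stats::runif(k * k * C * co, -0.1, 0.1),
                      dim = c(k, k, C, co))
      tau <- array(tau0 * stats::runif(oh * ow * co, 0.9, 1.1),
                   dim = c(oh, ow, co))
      list(kernel = kernel, tau = tau, tau_init = tau,
           out_dim = c(oh, ow, co), pooled_dim = c(oh %/% 2L, ow %/% 2L, co))
    })
    n_feat <- sum(vapply(branches, function(b) prod(b$pooled_dim), numeric(1)))
    sizes <- c(n_feat, config$fc_sizes)
    fc <- lapply(seq_along(config$fc_sizes), function(l) {
      Wm <- matrix(stats::runif(sizes[l + 1] * sizes[l], -0.1, 0.1),
                   nrow = sizes[l + 1], ncol = sizes[l])
      tau <- tau0 * stats::runif(sizes[l + 1], 0.9, 1.1)
      list(W = Wm, tau = tau, tau_init = tau)
    })
    list(branches = branches, fc = fc, n_features = n_feat)
  })
  structure(list(config = config, branches = net$branches, fc = net$fc,
                 n_features = net$n_features),
            class = "spikelin_network")
}

#' @export
print.spikelin_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spikelin_network> %d branch(es), %d features, fc %s, %d classes\n",
              length(x$branches), x$n_features,
              paste(cfg$fc_sizes, collapse = "-"), cfg$num_classes))
  cat(sprintf("  parameters: %d\n", n_parameters(x)))
  invisible(x)
}

#' Total trainable parameter count of a network
#' @param network A `spikelin_network`.
#' @return Integer: conv kernel entries plus dense weight entries.
#' @export
n_parameters <- function(network) {
  sum(vapply(network$branches, function(b) length(b$kernel), numeric(1))) +
    sum(vapply(network$fc, function(f) length(f$W), numeric(1)))
}

cpp_params <- function(network, extra = list()) {
  cfg <- network$config
  c(list(timesteps = cfg$timesteps, in_channels = cfg$input_shape[1],
         in_height = cfg$input_shape[2], in_width = cfg$input_shape[3],
         dt = cfg$neuron$dt, resistance = cfg$neuron$resistance,
         threshold = cfg$neuron$threshold, reset = cfg$neuron$reset_potential,
         pool = if (cfg$pool == "max") 0L else 1L),
    extra)
}

#' Run a spike tensor through the network
#'
#' Per time step, each branch convolves the incoming spikes with its
#' kernels to form the input current, updates the LIF membranes, emits
#' binary spikes on threshold crossing (with reset), pools the spike maps
#' 2x2, and the concatenated branch features drive the fully connected
#' spiking layers. Membrane state starts from the reset potential, so two
#' consecutive calls on the same input are identical.
#'
#' @param network A [build_network()] result.
#' @param input Binary spike tensor `(timesteps, channels, height, width)`.
#' @return A list with `counts` (output spikes accumulated over all time
#'   steps, one per class) and `output_spikes` (`timesteps x num_classes`
#'   binary matrix).
#' @export
snn_forward <- function(network, input) {
  if (!is.array(input) || length(dim(input)) != 4)
    stop("`input` must be a 4D spike tensor", call. = FALSE)
  snn_forward_cpp(network$branches, network$fc, input, cpp_params(network))
}

#' Predict the class of a spike tensor
#'
#' The class with the largest accumulated output spike count wins; ties are
#' broken toward the lowest class index. If no output neuron spiked at all,
#' class 0 is returned with a warning.
#'
#' @param object A `spikelin_network`.
#' @param input A spike tensor, or a list of spike tensors.
#' @param ... Unused.
#' @return Integer class index (0-based), vectorised over list input.
#' @export
predict.spikelin_network <- function(object, input, ...) {
  one <- function(x) {
    counts <- snn_forward(object, x)$counts
    if (all(counts == 0)) {
      warning("no output spikes; defaulting to class 0", call. = FALSE)
      return(0L)
    }
    which.max(counts) - 1L
  }
  if (is.list(input)) vapply(input, one, integer(1)) else one(input)
}
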