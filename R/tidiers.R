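# broom-style accessors and ggplot2 methods for fitted objects

#' Tidy the training history of a fit
#'
#' @param x A `spikelin_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `error`, `train_acc`,
#'   `tau_mean`, `tau_sd`).
#' @export
tidy.spikelin_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `spikelin_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, final error, final training
#'   accuracy, final tau mean/sd and the parameter count.
#' @export
glance.spikelin_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_error = tail(h$error, 1),
                 final_train_acc = tail(h$train_acc, 1),
                 tau_mean = tail(h$tau_mean, 1),
                 tau_sd = tail(h$tau_sd, 1),
                 n_parameters = n_parameters(x$network))
}

#' Tidy a membrane trace
#'
#' @param x A `lif_trace` from [lif_simulate()].
#' @param ... Unused.
#' @return A tibble with `time`, `membrane` and a logical `spike` column
#'   marking the steps at which the neuron fired.
#' @export
tidy.lif_trace <- function(x, ...) {
  tr <- x$trace
  tr$spike <- tr$time %in% x$spikes
  tr
}

#' Plot a training history
#'
#' Error and training accuracy per epoch, one panel each.
#'
#' @param object A `spikelin_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spikelin_fit <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  h <- object$history
  long <- tibble::tibble(
    epoch = rep(h$epoch, 2),
    value = c(h$error, h$train_acc),
    metric = rep(c("output error", "training accuracy"), each = nrow(h)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot a membrane trace with spike markers
#'
#' @param object A `lif_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lif_trace <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$time, y = .data$membrane)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$spikes, linetype = "dotted",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = object$params$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "time", y = "membrane potential")
}

#' @importFrom rlang .data
NULL
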