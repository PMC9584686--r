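# Evaluation: classification accuracy and the Gaussian-approximation
# (Wilson-score) confidence interval for a proportion,
#   l, u = (2np + z^2 -/+ z*sqrt(z^2 + 4np(1-p))) / (2(n + z^2)),
# which stays inside [0, 1] even at extreme accuracies.

#' Classification accuracy
#'
#' @param predictions Integer class indices.
#' @param labels Integer class indices of the same length.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0 || length(predictions) != length(labels))
    stop("`predictions` and `labels` must be non-empty and equally long",
         call. = FALSE)
  mean(predictions == labels)
}

#' Wilson-score confidence interval for a classification accuracy
#'
#' @param p Observed accuracy in `[0, 1]` (vectorised).
#' @param n Positive sample size.
#' @param z Positive Gaussian critical value (default 1.96, the two-sided
#'   95% level).
#' @return A tibble of class `spikelin_ci` with columns `lower`, `upper`,
#'   `p`, `n`, `z`. Bounds are exact; round to 4 decimals for table-style
#'   reporting.
#' @export
confidence_interval <- function(p, n, z = 1.96) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (z <= 0) stop("`z` must be > 0", call. = FALSE)
  s <- z * sqrt(z^2 + 4 * n * p * (1 - p))
  denom <- 2 * (n + z^2)
  out <- tibble::tibble(lower = (2 * n * p + z^2 - s) / denom,
                        upper = (2 * n * p + z^2 + s) / denom,
                        p = p, n = as.integer(n), z = z)
  class(out) <- c("spikelin_ci", class(out))
  out
}

#' Evaluate a trained network on encoded inputs
#'
#' @param fit A `spikelin_fit` (uses its attached inputs/labels unless
#'   overridden).
#' @param inputs Optional list of spike tensors.
#' @param labels Optional integer labels.
#' @param z Gaussian critical value for the confidence interval.
#' @return A list with `accuracy`, `ci` (a [confidence_interval()] row) and
#'   `predictions`.
#' @export
evaluate_fit <- function(fit, inputs = fit$inputs, labels = fit$labels,
                         z = 1.96) {
  if (is.null(inputs) || is.null(labels))
    stop("no inputs/labels attached to the fit; pass them explicitly",
         call. = FALSE)
  preds <- predict(fit$network, inputs)
  acc <- accuracy(preds, labels)
  list(accuracy = acc,
       ci = confidence_interval(acc, length(labels), z),
       predictions = preds)
}
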