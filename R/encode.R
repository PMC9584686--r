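# Spike encoding: static images and event streams are turned into binary
# spike tensors indexed (time step, channel, row, col), the common input
# format of the spiking network.

#' Rate-encode a grayscale image into a spike tensor
#'
#' Each pixel of intensity `v` emits an independent Bernoulli spike per time
#' step with probability `(v/255) * max_rate` (rate coding, matching the
#' firing-rate view of the LIF neuron). Deterministic for a given `seed`.
#'
#' @param image Numeric matrix, values in `[0, 255]` (clipped if outside).
#' @param timesteps Number of time steps (default 20).
#' @param max_rate Spike probability per step of a full-intensity pixel, in
#'   `(0, 1]`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A binary array with dimensions `(timesteps, 1, nrow, ncol)`.
#' @export
rate_encode <- function(image, timesteps = 20L, max_rate = 1, seed = NULL) {
  check_image(image)
  if (max_rate <= 0 || max_rate > 1)
    stop("`max_rate` must be in (0, 1]", call. = FALSE)
  timesteps <- as.integer(timesteps)
  if (timesteps < 1L) stop("`timesteps` must be >= 1", call. = FALSE)
  p <- pmin(pmax(image, 0), 255) / 255 * max_rate
  h <- nrow(image); w <- ncol(image)
  spikes <- with_preserved_seed(seed, {
    u <- stats::runif(timesteps * h * w)
    # dim (T, h, w): pixel probability broadcast across the time axis
    as.numeric(u < rep(as.vector(p), each = timesteps))
  })
  array(spikes, dim = c(timesteps, 1L, h, w))
}

#' Construct an event stream
#'
#' Address-event records from a dynamic vision sensor: per-pixel brightness
#' changes with microsecond timestamps. Coordinates are zero-based with the
#' origin at the top-left; `x` indexes columns, `y` rows.
#'
#' @param t Non-negative timestamps (microseconds); sorted on construction.
#' @param x,y Integer pixel coordinates in `[0, width-1]` / `[0, height-1]`.
#' @param polarity 1 for brightness increase (ON), 0 for decrease (OFF).
#' @param sensor_size `c(height, width)` of the sensor.
#' @return A tibble of class `event_stream` with columns `t`, `x`, `y`,
#'   `polarity` and a `sensor_size` attribute.
#' @export
event_stream <- function(t = numeric(), x = integer(), y = integer(),
                         polarity = integer(), sensor_size) {
  if (length(sensor_size) != 2 || any(sensor_size < 1))
    stop("`sensor_size` must be c(height, width)", call. = FALSE)
  if (any(t < 0)) stop("timestamps must be >= 0", call. = FALSE)
  if (any(x < 0 | x >= sensor_size[2]) || any(y < 0 | y >= sensor_size[1]))
    stop("event coordinates outside `sensor_size`", call. = FALSE)
  if (!all(polarity %in% c(0L, 1L)))
    stop("`polarity` must be 0 or 1", call. = FALSE)
  ord <- order(t)
  out <- tibble::tibble(t = as.numeric(t)[ord], x = as.integer(x)[ord],
                        y = as.integer(y)[ord],
                        polarity = as.integer(polarity)[ord])
  attr(out, "sensor_size") <- as.integer(sensor_size)
  class(out) <- c("event_stream", class(out))
  out
}

#' Bin an event stream into a spike tensor
#'
#' Events are binned into `timesteps` frames of `window` microseconds;
#' polarity maps to two channels (OFF = channel 1, ON = channel 2). A cell
#' is 1 if at least one event of that polarity falls in the bin (binary OR,
#' so duplicated events are idempotent). Events beyond the covered span are
#' dropped.
#'
#' @param stream An [event_stream()].
#' @param timesteps Number of time bins (default 20).
#' @param window Bin width in microseconds; `NULL` spreads the stream's full
#'   duration over `timesteps` bins.
#' @return A binary array `(timesteps, 2, height, width)`.
#' @export
events_to_tensor <- function(stream, timesteps = 20L, window = NULL) {
  sz <- attr(stream, "sensor_size")
  if (is.null(sz)) stop("`stream` must be an event_stream", call. = FALSE)
  timesteps <- as.integer(timesteps)
  out <- array(0, dim = c(timesteps, 2L, sz[1], sz[2]))
  if (nrow(stream) == 0) return(out)
  window <- window %||% ((max(stream$t) + 1) / timesteps)
  if (window <= 0) stop("`window` must be > 0", call. = FALSE)
  bin <- floor(stream$t / window) + 1
  keep <- bin <= timesteps
  idx <- cbind(bin[keep], stream$polarity[keep] + 1L,
               stream$y[keep] + 1L, stream$x[keep] + 1L)
  out[idx] <- 1
  out
}

#' Encode a list or stack of images into spike tensors
#'
#' Convenience wrapper around [rate_encode()]: each image gets its own
#' deterministic sub-seed derived from `seed`.
#'
#' @param images A 3D array `(height, width, n)` or a list of matrices.
#' @inheritParams rate_encode
#' @return A list of spike tensors.
#' @export
encode_dataset <- function(images, timesteps = 20L, max_rate = 1, seed = 0L) {
  imgs <- if (is.list(images)) images else
    lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  lapply(seq_along(imgs), function(i)
    rate_encode(imgs[[i]], timesteps, max_rate, seed = seed + i - 1L))
}
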