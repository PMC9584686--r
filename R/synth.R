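# Seeded synthetic data with the statistical structure the method assumes:
# a smooth, low pair-entropy background and a textured, high pair-entropy
# target patch whose shape carries the class label; event-stream versions
# are produced by translating the scene along a saccade-like path.

#' Specification of the synthetic image generator
#'
#' Each image is a near-uniform background plus one shaped patch of
#' high-variance texture at a jittered location. Shapes (`bar`, `cross`,
#' `square`, `ring`) define the classes. The texture/background variance
#' contrast realises the premise that the target region carries more
#' information (higher pair entropy) than the background.
#'
#' @param image_size Side length of the square images (default 28).
#' @param classes Character vector of 2-4 shape names among `"bar"`,
#'   `"cross"`, `"square"`, `"ring"`.
#' @param background_noise_sd Gaussian noise sd of the background (small,
#'   keeps background entropy low; default 0.5).
#' @param target_texture_sd Texture sd inside the target patch (must exceed
#'   `background_noise_sd`; default 40).
#' @param samples_per_class Images per class (default 100).
#' @param seed Integer seed (default 0).
#' @param target_size Side of the square patch housing the shape
#'   (default 12).
#' @param background_level Mean background gray level (default 40).
#' @param target_level Mean gray level of the textured shape (default 128).
#' @param jitter Maximum absolute patch displacement from the centre, in
#'   pixels per axis (default 3).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(image_size = 28L, classes = c("bar", "cross"),
                       background_noise_sd = 0.5, target_texture_sd = 40,
                       samples_per_class = 100L, seed = 0L,
                       target_size = 12L, background_level = 40,
                       target_level = 128, jitter = 3L) {
  known <- c("bar", "cross", "square", "ring")
  if (!all(classes %in% known) || length(classes) < 2 || length(classes) > 4)
    stop("`classes` must be 2-4 of: ", paste(known, collapse = ", "),
         call. = FALSE)
  if (target_texture_sd <= background_noise_sd)
    stop("`target_texture_sd` must exceed `background_noise_sd`",
         call. = FALSE)
  if (background_noise_sd < 0)
    stop("`background_noise_sd` must be >= 0", call. = FALSE)
  if (samples_per_class < 0)
    stop("`samples_per_class` must be >= 0", call. = FALSE)
  if (target_size + 2L * jitter >= image_size)
    stop("target patch (with jitter) does not fit inside the image",
         call. = FALSE)
  structure(list(image_size = as.integer(image_size), classes = classes,
                 background_noise_sd = background_noise_sd,
                 target_texture_sd = target_texture_sd,
                 samples_per_class = as.integer(samples_per_class),
                 seed = as.integer(seed), target_size = as.integer(target_size),
                 background_level = background_level,
                 target_level = target_level, jitter = as.integer(jitter)),
            class = "synth_spec")
}

# binary shape masks on a s x s patch
shape_mask <- function(shape, s) {
  m <- matrix(FALSE, s, s)
  th <- max(2L, round(s / 3))          # bar/arm thickness
  mid <- (s - th) %/% 2L
  band <- (mid + 1L):(mid + th)
  cx <- (s + 1) / 2
  switch(shape,
    bar = { m[, band] <- TRUE; m },
    cross = { m[, band] <- TRUE; m[band, ] <- TRUE; m },
    square = {
      w <- 2L
      m[c(seq_len(w), (s - w + 1L):s), ] <- TRUE
      m[, c(seq_len(w), (s - w + 1L):s)] <- TRUE
      m
    },
    ring = {
      d <- sqrt(outer((seq_len(s) - cx)^2, (seq_len(s) - cx)^2, `+`))
      m[d <= s / 2 - 0.5 & d >= s / 2 - 2.5] <- TRUE
      m
    },
    stop("unknown shape: ", shape, call. = FALSE))
}

#' Generate labelled synthetic images with target masks
#'
#' @param spec A [synth_spec()].
#' @return A list with `images` (array `(size, size, n)`, 8-bit-range
#'   integers), `labels` (integer classes, 0-based, in `seq_along(classes)
#'   - 1`), and `masks` (logical array marking target pixels). Bitwise
#'   reproducible for a given `spec$seed`.
#' @export
make_images <- function(spec) {
  n <- spec$samples_per_class * length(spec$classes)
  sz <- spec$image_size; ts <- spec$target_size
  images <- array(0, dim = c(sz, sz, n))
  masks <- array(FALSE, dim = c(sz, sz, n))
  labels <- rep(seq_along(spec$classes) - 1L, each = spec$samples_per_class)
  if (n == 0) return(list(images = images, labels = integer(0), masks = masks))
  base_row <- (sz - ts) %/% 2L
  with_preserved_seed(spec$seed, {
    for (i in seq_len(n)) {
      img <- spec$background_level +
        stats::rnorm(sz * sz, sd = spec$background_noise_sd)
      dim(img) <- c(sz, sz)
      sh <- shape_mask(spec$classes[labels[i] + 1L], ts)
      dr <- sample(-spec$jitter:spec$jitter, 1)
      dc <- sample(-spec$jitter:spec$jitter, 1)
      r0 <- base_row + dr; c0 <- base_row + dc
      patch_rows <- (r0 + 1L):(r0 + ts); patch_cols <- (c0 + 1L):(c0 + ts)
      tex <- spec$target_level +
        stats::rnorm(sum(sh), sd = spec$target_texture_sd)
      sub <- img[patch_rows, patch_cols]
      sub[sh] <- tex
      img[patch_rows, patch_cols] <- sub
      msk <- matrix(FALSE, sz, sz)
      msk[patch_rows, patch_cols] <- sh
      images[, , i] <- round(pmin(pmax(img, 0), 255))
      masks[, , i] <- msk
    }
  })
  list(images = images, labels = labels, masks = masks)
}

# emit ON/OFF events from consecutive frames: a pixel whose intensity rises
# (falls) by more than `threshold` gray levels produces one ON (OFF) event
frames_to_events <- function(frames, threshold = 10, dwell = 1000) {
  sz <- dim(frames)[1:2]
  n <- dim(frames)[3]
  ts <- xs <- ys <- ps <- list()
  for (s in seq_len(n - 1)) {
    d <- frames[, , s + 1] - frames[, , s]
    on <- which(d > threshold, arr.ind = TRUE)
    off <- which(d < -threshold, arr.ind = TRUE)
    k <- s
    if (nrow(on)) {
      ts[[length(ts) + 1]] <- rep((k - 1) * dwell, nrow(on))
      ys[[length(ys) + 1]] <- on[, 1] - 1L
      xs[[length(xs) + 1]] <- on[, 2] - 1L
      ps[[length(ps) + 1]] <- rep(1L, nrow(on))
    }
    if (nrow(off)) {
      ts[[length(ts) + 1]] <- rep((k - 1) * dwell, nrow(off))
      ys[[length(ys) + 1]] <- off[, 1] - 1L
      xs[[length(xs) + 1]] <- off[, 2] - 1L
      ps[[length(ps) + 1]] <- rep(0L, nrow(off))
    }
  }
  event_stream(t = unlist(ts) %||% numeric(), x = unlist(xs) %||% integer(),
               y = unlist(ys) %||% integer(),
               polarity = unlist(ps) %||% integer(), sensor_size = sz)
}

# translation offsets of a 3-segment saccade-like path
saccade_path <- function(n_steps, amplitude = 1) {
  seg <- n_steps %/% 3
  steps <- rbind(
    matrix(rep(c(1, 0), seg), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), seg), ncol = 2, byrow = TRUE),
    matrix(rep(c(-1, -1), n_steps - 2 * seg), ncol = 2, byrow = TRUE))
  apply(steps * amplitude, 2, cumsum)
}

#' Generate labelled event streams by translating synthetic scenes
#'
#' Emulates saccade-driven neuromorphic capture: each synthetic image is
#' placed on a padded constant canvas and translated along a 3-segment path;
#' pixels whose intensity rises (falls) by more than the contrast threshold
#' between consecutive positions emit ON (OFF) events, with timestamps
#' advancing by `dwell` microseconds per step.
#'
#' @param spec A [synth_spec()].
#' @param n_steps Number of path steps (>= 2, default 12).
#' @param dwell Microseconds per step (default 1000).
#' @param amplitude Pixels moved per step (0 gives a static scene and hence
#'   an empty stream).
#' @param threshold Contrast threshold in gray levels (default 10).
#' @return A list with `streams` (list of [event_stream()]s), `labels`, and
#'   `sensor_size`.
#' @export
make_events <- function(spec, n_steps = 12L, dwell = 1000, amplitude = 1,
                        threshold = 10) {
  if (n_steps < 2) stop("`n_steps` must be >= 2", call. = FALSE)
  imgset <- make_images(spec)
  n <- length(imgset$labels)
  pad <- max(2L, ceiling(abs(amplitude)) * ceiling(n_steps / 2))
  sz <- spec$image_size + 2L * pad
  path <- saccade_path(n_steps, amplitude)
  path <- rbind(c(0, 0), path)
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    frames <- array(spec$background_level, dim = c(sz, sz, nrow(path)))
    for (s in seq_len(nrow(path))) {
      dr <- round(path[s, 1]); dc <- round(path[s, 2])
      rows <- (pad + 1L + dr):(pad + spec$image_size + dr)
      cols <- (pad + 1L + dc):(pad + spec$image_size + dc)
      rows <- pmin(pmax(rows, 1L), sz); cols <- pmin(pmax(cols, 1L), sz)
      frames[rows, cols, s] <- imgset$images[, , i]
    }
    streams[[i]] <- frames_to_events(frames, threshold = threshold,
                                     dwell = dwell)
  }
  list(streams = streams, labels = imgset$labels,
       sensor_size = c(sz, sz))
}
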