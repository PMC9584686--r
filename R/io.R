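# Readers and writers for the formats the toolchain touches:
#   - IDX (MNIST dialect): 4-byte magic (0x00 0x00 dtype rank), big-endian
#     32-bit dimensions, row-major unsigned-byte payload.
#   - 5-byte address-event binary (N-MNIST dialect): byte 0 = x, byte 1 = y,
#     byte 2 bit 7 = polarity, remaining 23 bits = big-endian timestamp (us).
#   - PGM (P2/P5) and PNG 8-bit grayscale images.
#   - NPY float64 dumps for unclamped enhancement output.
#   - CSV event dialect (t,x,y,p) for plain-text fixtures.

#' Read an IDX-format array
#'
#' @param path Path to an IDX file (unsigned-byte payload, dtype code 0x08).
#' @return An integer array with the dimensions declared in the header
#'   (row-major order preserved: the first dimension varies slowest).
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || magic[1] != 0 || magic[2] != 0)
    stop("bad IDX magic at byte offset 0 in ", path, call. = FALSE)
  if (as.integer(magic[3]) != 0x08)
    stop(sprintf("unsupported IDX dtype 0x%02x at byte offset 2",
                 as.integer(magic[3])), call. = FALSE)
  rank <- as.integer(magic[4])
  dims <- readBin(con, "integer", rank, size = 4, endian = "big")
  if (length(dims) < rank || any(dims < 0))
    stop("truncated IDX dimension header at byte offset 4", call. = FALSE)
  n <- prod(dims)
  payload <- readBin(con, "raw", n)
  if (length(payload) < n)
    stop(sprintf("truncated IDX payload at byte offset %d: expected %d bytes, got %d",
                 4 + 4 * rank, n, length(payload)), call. = FALSE)
  # stored row-major; R arrays are column-major, so fill reversed and permute
  arr <- array(as.integer(payload), dim = rev(dims))
  if (rank > 1) arr <- aperm(arr, rev(seq_len(rank)))
  arr
}

#' Write an array in IDX format
#'
#' @param array Integer array with values in `[0, 255]`.
#' @param path Destination path.
#' @return `path`, invisibly. Round-trips losslessly through [read_idx()].
#' @export
write_idx <- function(array, path) {
  v <- as.integer(array)
  if (any(v < 0 | v > 255)) stop("values must be in [0, 255]", call. = FALSE)
  dims <- dim(array) %||% length(array)
  rank <- length(dims)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0, 0, 0x08, rank)), con)
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  arr <- array(v, dim = dims)
  if (rank > 1) arr <- aperm(arr, rev(seq_len(rank)))  # to row-major
  writeBin(as.raw(arr), con)
  invisible(path)
}

#' Read a 5-byte address-event binary file
#'
#' @param path Path to the binary file (length divisible by 5).
#' @param sensor_size `c(height, width)` of the sensor.
#' @return An [event_stream()], time-sorted. Streams with timestamps beyond
#'   the 23-bit range cannot occur in this format; coordinates outside
#'   `sensor_size` raise an error.
#' @export
read_aer <- function(path, sensor_size = c(34L, 34L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) %% 5 != 0)
    stop("AER file length ", length(bytes), " is not divisible by 5",
         call. = FALSE)
  n <- length(bytes) %/% 5
  if (n == 0)
    return(event_stream(sensor_size = sensor_size))
  m <- matrix(as.integer(bytes), nrow = 5)
  x <- m[1, ]; y <- m[2, ]
  polarity <- m[3, ] %/% 128L
  t <- (m[3, ] %% 128L) * 65536 + m[4, ] * 256 + m[5, ]
  event_stream(t = t, x = x, y = y, polarity = polarity,
               sensor_size = sensor_size)
}

#' Write an event stream as 5-byte address-event binary
#'
#' @param stream An [event_stream()]; timestamps must fit in 23 bits
#'   (< 2^23 microseconds), otherwise an error is raised since the format
#'   does not represent wrap-around.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_aer <- function(stream, path) {
  if (nrow(stream) > 0 && max(stream$t) >= 2^23)
    stop("timestamps exceed the 23-bit range of the 5-byte AER format",
         call. = FALSE)
  if (nrow(stream) > 0 && (max(stream$x) > 255 || max(stream$y) > 255))
    stop("coordinates exceed the 1-byte range of the 5-byte AER format",
         call. = FALSE)
  t <- as.integer(round(stream$t))
  bytes <- rbind(stream$x, stream$y,
                 stream$polarity * 128L + t %/% 65536L,
                 (t %/% 256L) %% 256L, t %% 256L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(path)
}

#' Read events from the plain CSV dialect
#'
#' Columns `t,x,y,p` with a header row.
#'
#' @inheritParams read_aer
#' @return An [event_stream()].
#' @export
read_events_csv <- function(path, sensor_size) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  event_stream(t = d$t, x = d$x, y = d$y, polarity = d$p,
               sensor_size = sensor_size)
}

#' Write events to the plain CSV dialect
#' @param stream An [event_stream()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(stream, path) {
  utils::write.csv(data.frame(t = stream$t, x = stream$x, y = stream$y,
                              p = stream$polarity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an 8-bit grayscale image (PNG or PGM)
#'
#' @param path File ending in `.png`, or a PGM file (plain `P2` or raw
#'   `P5`).
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img * 255)
  }
  read_pgm(path)
}

#' Write an 8-bit grayscale image (PNG or PGM by extension)
#'
#' @param image Numeric matrix; values are clipped to `[0, 255]` and
#'   rounded.
#' @param path Destination ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- round(pmin(pmax(image, 0), 255))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img / 255, path)
  } else {
    write_pgm(img, path)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic ", magic, "): ", path, call. = FALSE)
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment until end of line
  while (length(tokens) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1))
        if (c2 == "\n" || c2 == "") break
      }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1))
        if (grepl("[0-9]", c2)) num <- paste0(num, c2) else break
      }
      tokens <- c(tokens, num)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", w * h))
  } else {
    v <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(v) < w * h) stop("truncated PGM payload", call. = FALSE)
  matrix(v * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path, ascii = FALSE) {
  h <- nrow(image); w <- ncol(image)
  v <- as.integer(t(image))
  if (ascii) {
    writeLines(c("P2", paste(w, h), "255",
                 paste(v, collapse = " ")), path)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", w, h)), con)
    writeBin(as.raw(v), con)
  }
  invisible(path)
}

#' Dump a real-valued matrix as NPY (float64)
#'
#' For unclamped enhancement output that does not fit 8-bit formats.
#'
#' @param x Numeric matrix or array.
#' @param path Destination `.npy` path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  dims <- dim(x) %||% length(x)
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%s), }",
                    paste0(paste(dims, collapse = ", "),
                           if (length(dims) == 1) "," else ""))
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

#' Serialise a network to a flat binary container with a JSON header
#'
#' Layout: 8-byte little-endian header length, a JSON header describing the
#' layer shapes, seeds and time constants, then all weights as little-endian
#' float64 in header order.
#'
#' @param network A `spikelin_network`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  cfg <- network$config
  header <- list(
    format = "spikelin-net-1",
    num_classes = cfg$num_classes,
    timesteps = cfg$timesteps,
    input_shape = cfg$input_shape,
    pool = cfg$pool,
    fc_sizes = cfg$fc_sizes,
    seed = cfg$seed,
    neuron = cfg$neuron[c("resistance", "tau_m", "threshold",
                          "reset_potential", "dt")],
    tau_rule = unclass(cfg$tau_rule),
    branches = lapply(network$branches, function(b)
      list(kernel_dim = dim(b$kernel), out_dim = b$out_dim,
           pooled_dim = b$pooled_dim)),
    fc_dims = lapply(network$fc, function(f) dim(f$W)))
  hj <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(nchar(hj, type = "bytes")), con, size = 8,
           endian = "little")
  writeBin(charToRaw(hj), con)
  for (b in network$branches) {
    writeBin(as.numeric(b$kernel), con, size = 8, endian = "little")
    writeBin(as.numeric(b$tau), con, size = 8, endian = "little")
    writeBin(as.numeric(b$tau_init), con, size = 8, endian = "little")
  }
  for (f in network$fc) {
    writeBin(as.numeric(f$W), con, size = 8, endian = "little")
    writeBin(as.numeric(f$tau), con, size = 8, endian = "little")
    writeBin(as.numeric(f$tau_init), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a network serialised by [write_network()]
#'
#' @param path Path to the container.
#' @return A `spikelin_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  hlen <- readBin(con, "numeric", 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = FALSE)
  if (!identical(header$format, "spikelin-net-1"))
    stop("not a spikelin network container: ", path, call. = FALSE)
  nr <- header$neuron
  tr <- header$tau_rule
  branch_dims <- lapply(header$branches, function(b)
    lapply(b, function(v) as.integer(unlist(v))))
  branches_spec <- lapply(branch_dims, function(b)
    list(kernel_size = b$kernel_dim[1], out_channels = b$kernel_dim[4]))
  cfg <- network_config(
    num_classes = header$num_classes, branches = branches_spec,
    pool = header$pool, fc_sizes = as.integer(unlist(header$fc_sizes)),
    timesteps = header$timesteps,
    input_shape = as.integer(unlist(header$input_shape)),
    neuron = lif_params(resistance = nr$resistance, tau_m = nr$tau_m,
                        threshold = nr$threshold,
                        reset_potential = nr$reset_potential, dt = nr$dt),
    tau_rule = tau_rule(rate = tr$rate, tau_init = tr$tau_init,
                        tau_bounds = as.numeric(unlist(tr$tau_bounds)),
                        mode = tr$mode),
    seed = header$seed)
  read_block <- function(n) readBin(con, "numeric", n, size = 8,
                                    endian = "little")
  branches <- lapply(branch_dims, function(b) {
    list(kernel = array(read_block(prod(b$kernel_dim)), dim = b$kernel_dim),
         tau = array(read_block(prod(b$out_dim)), dim = b$out_dim),
         tau_init = array(read_block(prod(b$out_dim)), dim = b$out_dim),
         out_dim = b$out_dim, pooled_dim = b$pooled_dim)
  })
  fc <- lapply(header$fc_dims, function(d) {
    d <- as.integer(unlist(d))
    list(W = matrix(read_block(prod(d)), nrow = d[1], ncol = d[2]),
         tau = read_block(d[1]), tau_init = read_block(d[1]))
  })
  structure(list(config = cfg, branches = branches, fc = fc,
                 n_features = ncol(fc[[1]]$W)),
            class = "spikelin_network")
}
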