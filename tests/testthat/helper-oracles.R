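# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (naive loops, explicit
# DFTs) and share no code with the implementation paths they check.

# full O(n^4) centred-DFT low-pass: forward DFT by summation, multiply by
# the transfer function, invert by summation
oracle_butterworth <- function(img, d0, order) {
  h <- nrow(img); w <- ncol(img)
  Fm <- matrix(0 + 0i, h, w)
  for (u in 0:(h - 1)) for (v in 0:(w - 1)) {
    s <- 0 + 0i
    for (x in 0:(h - 1)) for (y in 0:(w - 1))
      s <- s + img[x + 1, y + 1] * exp(-2i * pi * (u * x / h + v * y / w))
    Fm[u + 1, v + 1] <- s
  }
  fu <- 0:(h - 1); fu <- ifelse(fu > h / 2, fu - h, fu)
  fv <- 0:(w - 1); fv <- ifelse(fv > w / 2, fv - w, fv)
  D <- sqrt(outer(fu^2, fv^2, `+`))
  Fm <- Fm / (1 + (D / d0)^(2 * order))
  out <- matrix(0, h, w)
  for (x in 0:(h - 1)) for (y in 0:(w - 1)) {
    s <- 0 + 0i
    for (u in 0:(h - 1)) for (v in 0:(w - 1))
      s <- s + Fm[u + 1, v + 1] * exp(2i * pi * (u * x / h + v * y / w))
    out[x + 1, y + 1] <- Re(s) / (h * w)
  }
  out
}

# exhaustive tuple enumeration for the pair entropy
oracle_pair_entropy <- function(img, radius = 1L, base = 2) {
  h <- nrow(img); w <- ncol(img)
  q <- round(pmin(pmax(img, 0), 255))
  tuples <- character(0)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) vals <- c(vals, q[ii, jj])
    }
    tuples <- c(tuples, paste(q[i, j], round(mean(vals))))
  }
  p <- table(tuples) / length(tuples)
  -sum(p * log(p, base = base))
}

# double-nested-loop lateral inhibition with explicit zero padding
oracle_lin <- function(img, cfg) {
  r <- cfg$radius
  adaptive <- cfg$mode == "adaptive"
  H <- if (adaptive) pair_entropy(img, base = cfg$entropy_base) else 0
  k <- inhibition_kernel(cfg, H)
  base <- if (adaptive) butterworth_lowpass(img, cfg) else img
  nb <- if (adaptive && cfg$inhibit_filtered) base else img
  out <- matrix(0, nrow(img), ncol(img))
  for (x in seq_len(nrow(img))) for (y in seq_len(ncol(img))) {
    s <- 0
    for (m in -r:r) for (n in -r:r) {
      xx <- x + m; yy <- y + n
      v <- if (xx >= 1 && xx <= nrow(img) && yy >= 1 && yy <= ncol(img))
        nb[xx, yy] else 0
      s <- s + k[m + r + 1, n + r + 1] * v
    }
    out[x, y] <- base[x, y] - s
  }
  if (cfg$clamp_output) out <- pmin(pmax(out, 0), 255)
  out
}

# plain-R reference network forward pass (naive convolution; independent of
# the compiled path)
oracle_forward <- function(net, input) {
  cfg <- net$config
  T <- cfg$timesteps; C <- cfg$input_shape[1]
  vth <- cfg$neuron$threshold; dt <- cfg$neuron$dt
  Rm <- cfg$neuron$resistance; vr <- cfg$neuron$reset_potential
  Vb <- lapply(net$branches, function(b) array(vr, dim = b$out_dim))
  Vf <- lapply(net$fc, function(f) rep(vr, nrow(f$W)))
  counts <- numeric(cfg$num_classes)
  outsp <- matrix(0L, T, cfg$num_classes)
  for (t in seq_len(T)) {
    feats <- c()
    for (bi in seq_along(net$branches)) {
      b <- net$branches[[bi]]
      k <- dim(b$kernel)[1]
      oh <- b$out_dim[1]; ow <- b$out_dim[2]; co <- b$out_dim[3]
      I <- array(0, dim = b$out_dim)
      for (cc in seq_len(co)) {
        acc <- matrix(0, oh, ow)
        for (ci in seq_len(C)) for (dm in seq_len(k)) for (dn in seq_len(k))
          acc <- acc + b$kernel[dm, dn, ci, cc] *
            input[t, ci, dm:(dm + oh - 1), dn:(dn + ow - 1)]
        I[, , cc] <- acc
      }
      V <- Vb[[bi]] + (dt / b$tau) * (-Vb[[bi]] + Rm * I)
      sp <- (V >= vth) * 1
      V[sp == 1] <- vr
      Vb[[bi]] <- V
      ph <- b$pooled_dim[1]; pw <- b$pooled_dim[2]
      P <- array(0, dim = b$pooled_dim)
      for (cc in seq_len(co)) {
        m <- sp[, , cc]
        P[, , cc] <- pmax(m[seq(1, 2 * ph - 1, 2), seq(1, 2 * pw - 1, 2)],
                          m[seq(2, 2 * ph, 2), seq(1, 2 * pw - 1, 2)],
                          m[seq(1, 2 * ph - 1, 2), seq(2, 2 * pw, 2)],
                          m[seq(2, 2 * ph, 2), seq(2, 2 * pw, 2)])
      }
      feats <- c(feats, as.vector(P))
    }
    x <- feats
    for (li in seq_along(net$fc)) {
      f <- net$fc[[li]]
      I <- as.vector(f$W %*% x)
      V <- Vf[[li]] + (dt / f$tau) * (-Vf[[li]] + Rm * I)
      sp <- (V >= vth) * 1
      V[sp == 1] <- vr
      Vf[[li]] <- V
      x <- sp
    }
    counts <- counts + x
    outsp[t, ] <- x
  }
  list(counts = counts, output_spikes = outsp)
}

# shared small fixtures
random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
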