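# shared fixtures, built in code at test time

# small deterministic sinogram stack with distinct values
toy_stack <- function(h = 2L, t = 3L, w = 4L) {
  sinogram_stack(array(seq_len(h * t * w), c(h, t, w)))
}

# per-column affine ramp sinogram: row t carries t * slope + offset, so the
# exact midpoint of two rows is the mean of their values
ramp_sinogram <- function(n_rows, w = 32L, seed = 1L) {
  set.seed(seed)
  slope <- runif(w, 0.2, 1)
  offset <- runif(w)
  (seq_len(n_rows) / n_rows) %o% slope + matrix(offset, n_rows, w, byrow = TRUE)
}

# reduced-size network for fast tests
tiny_config <- function(variant = "udnn", n_out = 1L)
  udnn_config(variant, n_out = n_out, feature_scale = 1 / 16)

# brute-force dense convolution oracle (independent of the C++ path)
naive_conv3 <- function(x, w, b, ph, pw) {
  d <- dim(w); H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(0, c(H + 2 * ph, W + 2 * pw, cin))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  Ho <- H + 2 * ph - d[1] + 1; Wo <- W + 2 * pw - d[2] + 1
  out <- array(0, c(Ho, Wo, d[4]))
  for (co in seq_len(d[4])) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- b[co]
    for (c in seq_len(cin))
      s <- s + sum(xp[i:(i + d[1] - 1), j:(j + d[2] - 1), c] * w[, , c, co])
    out[i, j, co] <- s
  }
  out
}
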