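# camera presets shared across tests

noiseless_camera <- function(...) {
  camera_model(read_noise_sd = 0, poisson_scale = 0, ...)
}

# pure geometry: no blur, no vignette, no noise
exact_camera <- function(...) {
  noiseless_camera(blur_sigma0 = 0, defocus_slope = 0,
                   vignette_strength = 0, ...)
}

# direct evaluation of the percentile-extrema contrast transfer function,
# kept deliberately naive and separate from compute_ctf()
brute_force_ctf <- function(values) {
  k <- max(1, ceiling(0.2 * length(values)))
  v <- sort(values)
  lo <- mean(v[1:k])
  hi <- mean(v[(length(v) - k + 1):length(v)])
  100 * (hi - lo) / (hi + lo)
}

# independent separable Gaussian convolution (zero padding); used as the
# blur oracle, never the package's own filter
oracle_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) { # convolve each column of x with k
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (j in seq_len(ncol(x))) {
      padded <- c(rep(0, half), x[, j], rep(0, half))
      out[, j] <- stats::convolve(padded, rev(k), type = "filter")
    }
    out
  }
  t(pad_conv(t(pad_conv(m))))
}
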