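# Independent oracles used across tests (kept free of the package's own
# solution paths).

## dense normal-equations least squares: (B'B)^-1 B' s
ls_oracle <- function(B, s) solve(crossprod(B), crossprod(B, s))[, 1]

## periodogram spectral centroid (Hz)
spectral_centroid <- function(x, fs) {
  n <- length(x)
  X <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  sum(f[half] * X[half]) / sum(X[half])
}

## fraction of periodogram power inside [lo, hi] Hz
band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  sum(X[half][f[half] >= lo & f[half] <= hi]) / sum(X[half])
}

## brute-force LSSVM KKT solve from explicit kernel evaluations
lssvm_oracle <- function(X, y01, kind, gamma, sigma = 1) {
  m <- nrow(X)
  ys <- ifelse(y01 == 1, 1, -1)
  K <- matrix(0, m, m)
  for (i in seq_len(m)) for (l in seq_len(m))
    K[i, l] <- tfarr::kernel_eval(kind, X[i, ], X[l, ], sigma = sigma)
  A <- rbind(c(0, ys), cbind(ys, (ys %o% ys) * K + diag(1 / gamma, m)))
  sol <- qr.solve(A, c(0, rep(1, m)))
  list(b = sol[1], beta = sol[-1])
}

## in-span test signal: per-mode polynomial envelopes on the grid
## returns the signal plus the envelope functions for checking recovery
inspan_signal <- function(n, fs, freqs, K, seed) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    Tdur <- n / fs
    envs <- lapply(seq_along(freqs), function(ji) {
      cf <- runif(K + 1, -1, 1)
      th <- runif(1, -pi, pi)
      q <- function(tt) {
        out <- 0
        for (k in 0:K) out <- out + cf[k + 1] * (tt / Tdur)^k
        out
      }
      list(q = q, theta = if (ji == 1) 0 else th)
    })
    x <- numeric(n)
    for (ji in seq_along(freqs)) {
      e <- envs[[ji]]
      x <- x + e$q(t) * cos(2 * pi * freqs[ji] * t + e$theta)
    }
    list(x = x, envs = envs, t = t)
  })
}
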