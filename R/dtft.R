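#' Construct a Taylor-Fourier basis
#'
#' Builds the design matrix of the digital Taylor-Fourier transform: real
#' cosine/sine carriers at harmonically spaced center frequencies
#' `f_j = j * grid_spacing` (j = 0, ..., n_modes - 1), each multiplied by
#' normalized powers of centered time up to `taylor_order`, so the
#' least-squares fit of a window estimates each mode's complex envelope as
#' a degree-`taylor_order` polynomial. The window spans
#' `C = taylor_order + 1` cycles of the grid spacing
#' (`L = C * fs / grid_spacing` samples); time is referenced so that t = 0
#' falls on sample `L/2`, making the order-0 coefficient the phasor at an
#' output sample.
#'
#' @param fs Sampling rate in Hz; `fs / grid_spacing` must be an integer.
#' @param grid_spacing Frequency spacing of the mode grid in Hz.
#' @param n_modes Number of modes J (center frequencies 0 to
#'   `(J-1)*grid_spacing`); `n_modes * grid_spacing` must stay below the
#'   Nyquist frequency.
#' @param taylor_order Degree K of the per-mode envelope polynomial
#'   (K >= 0).
#' @return A `tf_basis` object holding the design matrix `B`
#'   (`L x (2*n_modes - 1)*(K + 1)`), its Moore-Penrose pseudoinverse
#'   `B_pinv`, the per-(mode, order) estimator taps and the column
#'   bookkeeping.
#' @export
#' @examples
#' b <- build_basis(fs = 250, grid_spacing = 5, n_modes = 10, taylor_order = 2)
#' b$L              # 150-sample window
#' ncol(b$B)        # 57 columns
build_basis <- function(fs = 250, grid_spacing = 5, n_modes = 10,
                        taylor_order = 2) {
  if (abs(fs / grid_spacing - round(fs / grid_spacing)) > 1e-9)
    abort("`fs / grid_spacing` must be an integer (samples per cycle).",
          class = "tfarr_invalid_input")
  if (n_modes < 1 || taylor_order < 0)
    abort("`n_modes` must be >= 1 and `taylor_order` >= 0.",
          class = "tfarr_invalid_input")
  if (n_modes * grid_spacing >= fs / 2)
    abort("Highest mode frequency must lie below Nyquist.",
          class = "tfarr_invalid_input")
  N <- as.integer(round(fs / grid_spacing))
  K <- as.integer(taylor_order)
  C <- K + 1L
  L <- C * N
  Ts <- 1 / fs
  ## t = 0 on sample L/2 so the window-center estimate is an output sample
  t_n <- (seq_len(L) - 1 - L / 2) * Ts
  half <- L * Ts / 2
  tau <- t_n / half
  freqs <- (seq_len(n_modes) - 1) * grid_spacing
  n_cols <- (2L * n_modes - 1L) * C
  B <- matrix(0, L, n_cols)
  idx <- vector("list", n_cols)
  col <- 0L
  for (j in seq_len(n_modes) - 1L) {
    for (k in 0:K) {
      tk <- tau^k
      if (j == 0L) {
        col <- col + 1L
        B[, col] <- tk
        idx[[col]] <- list(mode = j, order = k, part = "cos")
      } else {
        w <- 2 * pi * freqs[j + 1] * t_n
        col <- col + 1L
        B[, col] <- tk * cos(w)
        idx[[col]] <- list(mode = j, order = k, part = "cos")
        col <- col + 1L
        B[, col] <- tk * sin(w)
        idx[[col]] <- list(mode = j, order = k, part = "sin")
      }
    }
  }
  columns <- purrr::list_rbind(purrr::map(idx, tibble::as_tibble))
  if (L <= n_cols)
    abort("Window shorter than the number of basis columns.",
          class = "tfarr_invalid_input")
  sv <- svd(B)
  tol <- 1e-10 * sv$d[1]
  if (any(sv$d <= tol))
    abort("Taylor-Fourier basis is rank deficient.",
          class = "tfarr_rank_error")
  B_pinv <- sv$v %*% (t(sv$u) / sv$d)
  ## complex estimator taps per (mode, order): cos row - i * sin row
  taps <- vector("list", n_modes)
  for (j in seq_len(n_modes) - 1L) {
    tj <- vector("list", C)
    for (k in 0:K) {
      ic <- which(columns$mode == j & columns$order == k &
                    columns$part == "cos")
      if (j == 0L) {
        tj[[k + 1]] <- as.complex(B_pinv[ic, ])
      } else {
        is_ <- which(columns$mode == j & columns$order == k &
                       columns$part == "sin")
        tj[[k + 1]] <- complex(real = B_pinv[ic, ],
                               imaginary = -B_pinv[is_, ])
      }
    }
    taps[[j + 1]] <- tj
  }
  structure(
    list(fs = fs, Ts = Ts, grid_spacing = grid_spacing, n_modes = n_modes,
         taylor_order = K, C = C, N = N, L = L, t_n = t_n, tau = tau,
         half_window = half, freqs = freqs, B = B, B_pinv = B_pinv,
         columns = columns, estimator_taps = taps,
         condition_number = sv$d[1] / sv$d[length(sv$d)]),
    class = "tf_basis")
}

#' @export
print.tf_basis <- function(x, ...) {
  cat(sprintf(paste0("<tf_basis> %d modes (0-%g Hz, %g Hz grid), K = %d, ",
                     "L = %d samples @ %g Hz\n  condition number %.3g\n"),
              x$n_modes, max(x$freqs), x$grid_spacing, x$taylor_order,
              x$L, x$fs, x$condition_number))
  invisible(x)
}

#' Least-squares analysis of one window
#'
#' Projects a window of `basis$L` samples onto the Taylor-Fourier basis and
#' returns the envelope coefficients: the complex
#' `xi[j+1, k+1] = c_{j,k} - i s_{j,k}` per mode j and Taylor order k (real
#' for the DC mode), plus the raw real column coefficients used by
#' [synthesize_window()].
#'
#' @param basis A [build_basis()] object.
#' @param window_samples Numeric vector of exactly `basis$L` samples.
#' @return A `tf_coef` object with elements `raw` (real coefficient vector)
#'   and `xi` (`n_modes x (K+1)` complex matrix).
#' @export
analyze_window <- function(basis, window_samples) {
  stopifnot(inherits(basis, "tf_basis"))
  if (length(window_samples) != basis$L)
    abort(sprintf("Window must have %d samples.", basis$L),
          class = "tfarr_invalid_input")
  raw <- drop(basis$B_pinv %*% window_samples)
  xi <- .coef_to_xi(basis, raw)
  structure(list(raw = raw, xi = xi, basis_dims = dim(basis$B)),
            class = "tf_coef")
}

.coef_to_xi <- function(basis, raw) {
  J <- basis$n_modes
  K <- basis$taylor_order
  xi <- matrix(complex(real = 0, imaginary = 0), J, K + 1,
               dimnames = list(paste0("mode", seq_len(J) - 1),
                               paste0("k", 0:K)))
  cols <- basis$columns
  for (j in seq_len(J) - 1L) {
    for (k in 0:K) {
      ic <- which(cols$mode == j & cols$order == k & cols$part == "cos")
      if (j == 0L) {
        xi[j + 1, k + 1] <- as.complex(raw[ic])
      } else {
        is_ <- which(cols$mode == j & cols$order == k & cols$part == "sin")
        xi[j + 1, k + 1] <- complex(real = raw[ic], imaginary = -raw[is_])
      }
    }
  }
  xi
}

#' Synthesize a window from Taylor-Fourier coefficients
#'
#' Returns `B %*% coefficients`; composed with [analyze_window()] this is
#' the orthogonal projection onto the basis span, so any in-span window is
#' reproduced exactly.
#'
#' @param basis A [build_basis()] object.
#' @param coefficients A `tf_coef` object or a raw real coefficient vector
#'   of length `ncol(basis$B)`.
#' @return Numeric vector of `basis$L` samples.
#' @export
synthesize_window <- function(basis, coefficients) {
  stopifnot(inherits(basis, "tf_basis"))
  raw <- if (inherits(coefficients, "tf_coef")) coefficients$raw
         else coefficients
  if (length(raw) != ncol(basis$B))
    abort(sprintf("Expected %d coefficients.", ncol(basis$B)),
          class = "tfarr_invalid_input")
  drop(basis$B %*% raw)
}

.reflect_pad <- function(x, left, right) {
  n <- length(x)
  if (left >= n || right >= n)
    abort("Frame shorter than the analysis window.",
          class = "tfarr_invalid_input")
  c(x[(left + 1):2], x, x[(n - 1):(n - right)])
}

#' Decompose a frame into oscillatory modes
#'
#' Slides the Taylor-Fourier analysis window one sample at a time across
#' the frame (reflection-padded so the output has the frame's length) and
#' takes, at each position, the window-center envelope estimate of every
#' mode. This is FIR filtering with the order-0 estimator taps — the
#' maximally flat harmonic filter bank. Per mode j the result is the
#' dynamic phasor `p_j(n)` referenced to the global time origin, the
#' instantaneous amplitude `a_hat = Mod(p)`, the phase
#' `phi_hat = Arg(p)` in (-pi, pi], and the real mode waveform
#' `m_j(n) = a_hat * cos(2 pi f_j n Ts + phi_hat)` (the DC mode waveform is
#' the real envelope itself).
#'
#' @param basis A [build_basis()] object.
#' @param frame Numeric vector, at least `basis$L` samples.
#' @return A `tf_decomposition` with `P x J` matrices `phasor` (complex),
#'   `amplitude`, `phase` and `modes`, plus the input frame and grid
#'   metadata.
#' @export
#' @examples
#' b <- build_basis(taylor_order = 2)
#' t <- (0:999) / 250
#' d <- decompose(b, cos(2 * pi * 5 * t))
#' range(d$amplitude[200:800, 2])   # unit amplitude in mode 1
decompose <- function(basis, frame) {
  stopifnot(inherits(basis, "tf_basis"))
  P <- length(frame)
  L <- basis$L
  if (P < L)
    abort("Frame shorter than the analysis window.",
          class = "tfarr_invalid_input")
  if (!all(is.finite(frame)))
    abort("Frame must be finite.", class = "tfarr_invalid_input")
  ## pad so output sample n is the window-center sample (local index L/2)
  left <- L / 2
  right <- L / 2 - 1
  xp <- .reflect_pad(frame, left, right)
  ## sliding windows as rows: P x L
  idx <- outer(seq_len(P) - 1L, seq_len(L), "+")
  X <- matrix(xp[idx], P, L)
  coefs <- X %*% t(basis$B_pinv)          # P x n_cols, raw per-window coefs
  J <- basis$n_modes
  cols <- basis$columns
  phasor <- matrix(complex(real = 0, imaginary = 0), P, J)
  n_glob <- seq_len(P) - 1
  for (j in seq_len(J) - 1L) {
    ic <- which(cols$mode == j & cols$order == 0 & cols$part == "cos")
    if (j == 0L) {
      p_loc <- as.complex(coefs[, ic])
    } else {
      is_ <- which(cols$mode == j & cols$order == 0 & cols$part == "sin")
      p_loc <- complex(real = coefs[, ic], imaginary = -coefs[, is_])
    }
    ## re-reference the local (window-centered) phasor to the global origin
    phasor[, j + 1] <- p_loc *
      exp(-2i * pi * basis$freqs[j + 1] * n_glob * basis$Ts)
  }
  amplitude <- Mod(phasor)
  phase <- Arg(phasor)
  modes <- matrix(0, P, J)
  modes[, 1] <- Re(phasor[, 1])
  for (j in seq_len(J - 1)) {
    modes[, j + 1] <- amplitude[, j + 1] *
      cos(2 * pi * basis$freqs[j + 1] * n_glob * basis$Ts + phase[, j + 1])
  }
  dimnames(phasor) <- dimnames(amplitude) <- dimnames(phase) <-
    dimnames(modes) <- list(NULL, paste0("mode", seq_len(J) - 1))
  structure(
    list(fs = basis$fs, freqs = basis$freqs, taylor_order = basis$taylor_order,
         L = basis$L, frame = frame, phasor = phasor, amplitude = amplitude,
         phase = phase, modes = modes),
    class = "tf_decomposition")
}

#' @export
print.tf_decomposition <- function(x, ...) {
  cat(sprintf("<tf_decomposition> %d samples @ %g Hz, %d modes (%g-%g Hz)\n",
              nrow(x$amplitude), x$fs, length(x$freqs), min(x$freqs),
              max(x$freqs)))
  invisible(x)
}

#' Tidy a mode decomposition into a long tibble
#'
#' @param x A `tf_decomposition`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `time`, `mode`, `frequency`,
#'   `amplitude`, `phase`, `value`.
#' @export
tidy.tf_decomposition <- function(x, ...) {
  P <- nrow(x$amplitude)
  J <- length(x$freqs)
  tibble::tibble(
    sample = rep(seq_len(P) - 1L, J),
    time = rep((seq_len(P) - 1) / x$fs, J),
    mode = rep(seq_len(J) - 1L, each = P),
    frequency = rep(x$freqs, each = P),
    amplitude = as.vector(x$amplitude),
    phase = as.vector(x$phase),
    value = as.vector(x$modes))
}

#' Reconstruct a frame from its mode decomposition
#'
#' Sums the per-mode waveforms; for signals inside the basis span the
#' reconstruction matches the frame on interior samples to numerical
#' precision.
#'
#' @param decomp A `tf_decomposition`.
#' @return Numeric vector of frame samples.
#' @export
reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "tf_decomposition"))
  rowSums(decomp$modes)
}

#' Frequency response of one mode's estimator filter
#'
#' Evaluates the order-0 estimator taps of mode `mode_j` on a frequency
#' grid. `gain` is the modulus of the response to a real unit cosine at
#' each frequency (1 at the mode's own center frequency, 0 at every other
#' grid frequency); `response` is the complex transfer function
#' `H_j(f) = sum_n h_j(n) exp(-2i pi f n Ts)` of the taps as an FIR filter.
#'
#' @param basis A [build_basis()] object.
#' @param mode_j Mode index, 0-based.
#' @param freq_grid Numeric vector of frequencies (Hz).
#' @return Tibble with columns `frequency`, `gain`, `response`.
#' @export
#' @examples
#' b <- build_basis()
#' filter_response(b, 1, c(0, 5, 10))$gain
filter_response <- function(basis, mode_j, freq_grid) {
  stopifnot(inherits(basis, "tf_basis"))
  if (mode_j < 0 || mode_j >= basis$n_modes)
    abort("Mode index out of range.", class = "tfarr_invalid_input")
  h <- basis$estimator_taps[[mode_j + 1]][[1]]
  n0 <- seq_len(basis$L) - 1
  gain <- purrr::map_dbl(freq_grid, function(f)
    Mod(sum(h * cos(2 * pi * f * basis$t_n))))
  resp <- vapply(freq_grid, function(f)
    sum(h * exp(-2i * pi * f * n0 * basis$Ts)), complex(1))
  tibble::tibble(frequency = freq_grid, gain = gain, response = resp)
}
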