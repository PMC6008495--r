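#' Specify a synthetic cardiac rhythm
#'
#' Describes one surrogate single-lead ECG segment: a normal-sinus (NSR)
#' quasi-periodic PQRST train, a monomorphic wide-complex ventricular
#' tachycardia (VT)-like oscillation, or an irregular broadband ventricular
#' fibrillation (VF)-like oscillation with no isoelectric baseline.
#'
#' @param rhythm_class One of `"NSR"`, `"VT"`, `"VF"`.
#' @param fs Sampling rate in Hz.
#' @param duration Segment length in seconds; `duration * fs` must round to a
#'   positive integer.
#' @param heart_rate Beats per minute; used by NSR and VT (ignored for VF).
#'   Defaults: 75 bpm for NSR, 200 bpm for VT.
#' @param dominant_band Two-element numeric, the frequency band (Hz) that
#'   confines the VF instantaneous frequencies. Default `c(3, 8)`.
#' @param noise_snr Signal-to-noise ratio in dB for additive white noise, or
#'   `NULL`/`Inf` for a clean signal.
#' @param seed Integer seed; generation is a pure function of the spec
#'   including the seed.
#'
#' @return An object of class `rhythm_spec`.
#' @seealso [gen_rhythm()], [gen_dataset()]
#' @export
#' @examples
#' rhythm_spec("VF", fs = 250, duration = 8, seed = 7)
rhythm_spec <- function(rhythm_class = c("NSR", "VT", "VF"), fs = 250,
                        duration = 8,
                        heart_rate = NULL,
                        dominant_band = c(3, 8),
                        noise_snr = NULL, seed = 1L) {
  rhythm_class <- match.arg(rhythm_class)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    abort("`fs` must be a positive finite number.", class = "tfarr_invalid_spec")
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0)
    abort("`duration` must be a positive finite number.",
          class = "tfarr_invalid_spec")
  n <- round(duration * fs)
  if (n < 1)
    abort("`duration * fs` must round to a positive number of samples.",
          class = "tfarr_invalid_spec")
  if (is.null(heart_rate))
    heart_rate <- switch(rhythm_class, NSR = 75, VT = 200, VF = NA_real_)
  if (rhythm_class != "VF") {
    if (!is.finite(heart_rate) || heart_rate <= 0)
      abort("`heart_rate` must be positive.", class = "tfarr_invalid_spec")
    ## highest generated frequency: 3rd harmonic for VT, QRS bump bandwidth
    ## (~ 45 Hz) for NSR; both require fs comfortably above 2 x content
    f_hi <- if (rhythm_class == "VT") 3 * heart_rate / 60 else 45
    if (fs <= 2 * f_hi)
      abort("`fs` must exceed twice the highest generated frequency.",
            class = "tfarr_invalid_spec")
  } else {
    if (length(dominant_band) != 2 || !all(is.finite(dominant_band)) ||
        dominant_band[1] <= 0 || dominant_band[2] <= dominant_band[1])
      abort("`dominant_band` must be an increasing positive pair (Hz).",
            class = "tfarr_invalid_spec")
    if (fs <= 2 * dominant_band[2])
      abort("`fs` must exceed twice the upper dominant-band edge.",
            class = "tfarr_invalid_spec")
  }
  structure(
    list(rhythm_class = rhythm_class, fs = fs, duration = duration,
         n_samples = n, heart_rate = heart_rate,
         dominant_band = dominant_band, noise_snr = noise_snr,
         seed = as.integer(seed)),
    class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec> %s, fs = %g Hz, %g s (%d samples), seed = %d\n",
              x$rhythm_class, x$fs, x$duration, x$n_samples, x$seed))
  invisible(x)
}

## PQRST bump parameters (mV, seconds): amplitude, Gaussian width, offset
## from the R peak.
.pqrst <- data.frame(
  wave  = c("P", "Q", "R", "S", "T"),
  amp   = c(0.15, -0.15, 1.0, -0.25, 0.35),
  width = c(0.05, 0.01, 0.012, 0.01, 0.07),
  off   = c(-0.2, -0.03, 0, 0.03, 0.25))

.gen_nsr <- function(spec) {
  n <- spec$n_samples
  t <- (seq_len(n) - 1) / spec$fs
  rr <- 60 / spec$heart_rate
  ## enough beats to cover the segment with margin for P/T tails
  n_beats <- ceiling(spec$duration / rr) + 2
  jitter <- runif(n_beats, -0.05, 0.05) * rr
  centers <- rr / 2 + (seq_len(n_beats) - 1) * rr + jitter
  x <- numeric(n)
  for (b in centers) {
    for (w in seq_len(nrow(.pqrst))) {
      mu <- b + .pqrst$off[w]
      ## skip bumps entirely outside the segment
      if (mu < -0.5 || mu > spec$duration + 0.5) next
      x <- x + .pqrst$amp[w] * exp(-(t - mu)^2 / (2 * .pqrst$width[w]^2))
    }
  }
  x
}

.gen_vt <- function(spec) {
  t <- (seq_len(spec$n_samples) - 1) / spec$fs
  f0 <- spec$heart_rate / 60
  ph <- runif(1, 0, 2 * pi)
  ph_am <- runif(1, 0, 2 * pi)
  am <- 1 + 0.25 * sin(2 * pi * 0.2 * t + ph_am)
  am * (sin(2 * pi * f0 * t + ph) +
          0.40 * sin(2 * pi * 2 * f0 * t + 2 * ph + 0.5) +
          0.15 * sin(2 * pi * 3 * f0 * t + 3 * ph + 1.1))
}

.gen_vf <- function(spec) {
  n <- spec$n_samples
  lo <- spec$dominant_band[1]
  hi <- spec$dominant_band[2]
  t <- (seq_len(n) - 1) / spec$fs
  x <- numeric(n)
  rel_amp <- c(1, 0.7, 0.5)
  for (k in 1:3) {
    ## instantaneous frequency: reflected random walk inside the band
    f <- numeric(n)
    f[1] <- runif(1, lo, hi)
    steps <- rnorm(n - 1, 0, 0.05)
    for (i in 2:n) {
      fi <- f[i - 1] + steps[i - 1]
      if (fi > hi) fi <- 2 * hi - fi
      if (fi < lo) fi <- 2 * lo - fi
      f[i] <- min(max(fi, lo), hi)
    }
    phase <- 2 * pi * cumsum(f) / spec$fs + runif(1, 0, 2 * pi)
    f_am <- runif(1, 0.1, 0.5)
    am <- 0.6 + 0.4 * sin(2 * pi * f_am * t + runif(1, 0, 2 * pi))
    x <- x + 0.4 * rel_amp[k] * am * sin(phase)
  }
  x
}

#' Generate a synthetic rhythm
#'
#' Renders the waveform described by a [rhythm_spec()]. NSR is a train of
#' five-Gaussian PQRST beats with ±5% RR jitter; VT is a monomorphic
#' fundamental-plus-harmonics oscillation with slow amplitude modulation; VF
#' is a three-component sinusoid mixture whose instantaneous frequencies
#' perform seeded random walks confined to the dominant band, with random
#' amplitude modulation and no flat baseline. Equal specs (including seed)
#' give bit-identical output.
#'
#' @param spec A [rhythm_spec()].
#' @return Numeric vector of `round(duration * fs)` samples (mV).
#' @export
#' @examples
#' x <- gen_rhythm(rhythm_spec("NSR", fs = 250, duration = 8,
#'                             heart_rate = 60, seed = 1))
#' length(x)
gen_rhythm <- function(spec) {
  stopifnot(inherits(spec, "rhythm_spec"))
  x <- withr::with_seed(spec$seed, switch(spec$rhythm_class,
    NSR = .gen_nsr(spec),
    VT  = .gen_vt(spec),
    VF  = .gen_vf(spec)))
  if (!is.null(spec$noise_snr) && is.finite(spec$noise_snr))
    x <- add_noise(x, spec$fs, spec$noise_snr, seed = spec$seed + 1L)
  x
}

#' Add calibrated white noise (and optional baseline wander) to a signal
#'
#' Scales zero-mean Gaussian noise so that the realised signal-to-noise
#' ratio `10*log10(P_signal / P_noise)` matches `snr_db`. `snr_db = NULL` or
#' `Inf` returns the input unchanged.
#'
#' @param signal Finite numeric vector with non-zero power.
#' @param fs Sampling rate (Hz), used for the baseline wander term.
#' @param snr_db Target SNR in dB, or `NULL`/`Inf` for no noise.
#' @param seed Integer seed for the noise draw.
#' @param baseline_wander If `TRUE`, also adds a 0.3 Hz sinusoidal baseline
#'   drift of amplitude 0.1 mV.
#' @return Numeric vector, same length as `signal`.
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * (0:999) / 250)
#' y <- add_noise(x, 250, snr_db = 10, seed = 1)
add_noise <- function(signal, fs, snr_db, seed = 1L, baseline_wander = FALSE) {
  if (!all(is.finite(signal)))
    abort("`signal` must be finite.", class = "tfarr_invalid_input")
  out <- signal
  if (!is.null(snr_db) && is.finite(snr_db)) {
    p_sig <- mean(signal^2)
    if (p_sig == 0)
      abort("Zero-power signal: SNR is undefined.",
            class = "tfarr_invalid_input")
    p_noise <- p_sig / 10^(snr_db / 10)
    noise <- withr::with_seed(as.integer(seed),
                              rnorm(length(signal), 0, sqrt(p_noise)))
    out <- out + noise
  }
  if (isTRUE(baseline_wander)) {
    t <- (seq_along(signal) - 1) / fs
    out <- out + 0.1 * sin(2 * pi * 0.3 * t)
  }
  out
}

## deterministic per-frame seed from master seed, class index and frame index;
## kept below 2^31 - 1 (exact in double arithmetic well below 2^53)
.frame_seed <- function(seed, class_idx, i) {
  as.integer((as.double(seed) * 7919 + class_idx * 104729 + i * 7) %%
               2147483647)
}

#' Generate a labeled dataset of synthetic ECG frames
#'
#' Draws `n_per_class` frames per rhythm class, each of `frame_s * fs`
#' samples, with per-frame seeds derived deterministically from the master
#' seed so frames are reproducible yet mutually independent. Heart rate is
#' redrawn per frame (NSR uniform on 60–100 bpm, VT on 150–240 bpm); VF uses
#' the 3–8 Hz dominant band. White noise at `noise_snr` dB is added to every
#' frame.
#'
#' @param n_per_class Frames per class.
#' @param classes Character subset of `c("NSR", "VT", "VF")`.
#' @param frame_s Frame duration in seconds (4, 5 and 8 are the conventional
#'   analysis windows; any positive value is accepted).
#' @param fs Sampling rate (Hz).
#' @param seed Master integer seed.
#' @param noise_snr Per-frame additive-noise SNR in dB (`NULL` for clean).
#' @return A tibble with columns `frame_id`, `rhythm` (factor), `seed` and
#'   `signal` (list-column of numeric vectors).
#' @export
#' @examples
#' ds <- gen_dataset(5, classes = c("NSR", "VF"), frame_s = 4, seed = 1)
#' dplyr::count(ds, rhythm)
gen_dataset <- function(n_per_class, classes = c("NSR", "VT", "VF"),
                        frame_s = 4, fs = 250, seed = 1L, noise_snr = 20) {
  classes <- unique(as.character(classes))
  if (length(classes) == 0)
    abort("`classes` must name at least one rhythm class.",
          class = "tfarr_invalid_spec")
  if (!all(classes %in% c("NSR", "VT", "VF")))
    abort("`classes` must be a subset of NSR, VT, VF.",
          class = "tfarr_invalid_spec")
  if (n_per_class < 1)
    abort("`n_per_class` must be at least 1.", class = "tfarr_invalid_spec")
  rows <- purrr::map(seq_along(classes), function(ci) {
    cls <- classes[ci]
    purrr::map(seq_len(n_per_class), function(i) {
      fseed <- .frame_seed(seed, ci, i)
      hr <- withr::with_seed(fseed, switch(cls,
        NSR = runif(1, 60, 100),
        VT  = runif(1, 150, 240),
        VF  = NA_real_))
      spec <- rhythm_spec(cls, fs = fs, duration = frame_s,
                          heart_rate = if (cls == "VF") NULL else hr,
                          noise_snr = noise_snr, seed = fseed + 1L)
      tibble::tibble(rhythm = cls, seed = fseed, signal = list(gen_rhythm(spec)))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows$frame_id <- seq_len(nrow(rows))
  rows$rhythm <- factor(rows$rhythm, levels = classes)
  rows[, c("frame_id", "rhythm", "seed", "signal")]
}
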