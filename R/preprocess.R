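#' Zero-phase Butterworth band-pass filter
#'
#' Conditions an ECG trace with a Butterworth band-pass (default corners
#' 0.5 and 45 Hz, order 4) applied forward and backward so the effective
#' magnitude response is squared and the phase response cancels (no
#' waveform delay).
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate (Hz); must exceed `2 * high_hz`.
#' @param low_hz,high_hz Corner frequencies in Hz.
#' @param order Butterworth prototype order (band-pass filter order is
#'   twice this).
#' @return Filtered numeric vector, same length as the input.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:1999) / 250)
#' y <- bandpass(x, 250)
bandpass <- function(signal, fs, low_hz = 0.5, high_hz = 45, order = 4) {
  if (fs <= 2 * high_hz)
    abort("`fs` must exceed twice the upper corner frequency.",
          class = "tfarr_invalid_input")
  flt_order <- 2 * order
  if (length(signal) <= 3 * flt_order)
    abort("Signal too short for the filter order.",
          class = "tfarr_invalid_input")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  .zero_phase(bf, signal, fs)
}

## factor the design into second-order sections (conjugate pole pairs, one
## z = +1 and one z = -1 zero each for a band-pass) for numerical stability
.butter_sos <- function(bf) {
  zp <- signal::as.Zpg(bf)
  p <- zp$pole
  p <- p[order(Im(p))]
  pairs <- Mod(Im(p)) > 1e-12
  cpx <- p[Im(p) > 1e-12]
  secs <- list()
  for (pk in cpx) {
    a <- c(1, -2 * Re(pk), Mod(pk)^2)
    secs[[length(secs) + 1]] <- list(b = c(1, 0, -1), a = a)
  }
  rp <- Re(p[!pairs])
  if (length(rp) %% 2 == 1) rp <- c(rp, 0)
  while (length(rp) >= 2) {
    secs[[length(secs) + 1]] <-
      list(b = c(1, 0, -1), a = c(1, -(rp[1] + rp[2]), rp[1] * rp[2]))
    rp <- rp[-(1:2)]
  }
  secs[[1]]$b <- secs[[1]]$b * zp$gain
  secs
}

## forward-backward cascade filtering with odd-extension padding and
## steady-state initial conditions per section: edge transients are
## suppressed, a constant input maps exactly to its DC gain, and the whole
## operation is linear in the input by construction
.zero_phase <- function(bf, x, fs) {
  secs <- .butter_sos(bf)
  m <- length(x)
  pad <- min(m - 1, max(27L, as.integer(round(2 * fs))))
  one_pass <- function(v) {
    for (s in secs) {
      dc <- sum(s$b) / sum(s$a)
      v <- as.numeric(signal::filter(s$b, s$a, v,
                                     init.x = rep(v[1], 2),
                                     init.y = rep(dc * v[1], 2)))
    }
    v
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[m] - x[(m - 1):(m - pad)])
  y <- rev(one_pass(rev(one_pass(ext))))
  y[(pad + 1):(pad + m)]
}

#' Partition a signal into fixed-duration non-overlapping frames
#'
#' A trailing partial frame is discarded. `start_sample` is the 0-based
#' index of the first sample of each frame.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param window_s Frame duration in seconds; `window_s * fs` must be an
#'   integer (1000, 1250 and 2000 samples for the 4, 5 and 8 s windows at
#'   250 Hz).
#' @return Tibble with columns `frame_id`, `start_sample` and `signal`
#'   (list-column); zero rows when the signal is shorter than one window.
#' @export
#' @examples
#' frame_signal(rnorm(2100), fs = 250, window_s = 4)
frame_signal <- function(signal, fs, window_s) {
  nf <- window_s * fs
  if (abs(nf - round(nf)) > 1e-9)
    abort("`window_s * fs` must be an integer number of samples.",
          class = "tfarr_invalid_input")
  nf <- as.integer(round(nf))
  n_frames <- length(signal) %/% nf
  if (n_frames == 0)
    return(tibble::tibble(frame_id = integer(0), start_sample = integer(0),
                          signal = list()))
  starts <- (seq_len(n_frames) - 1L) * nf
  tibble::tibble(
    frame_id = seq_len(n_frames),
    start_sample = starts,
    signal = purrr::map(starts, ~ signal[(.x + 1):(.x + nf)]))
}

#' Label frames with the rhythm episode covering most of their samples
#'
#' Each frame receives the rhythm code of the episode overlapping the
#' majority of its samples; an exact tie goes to the episode covering the
#' frame's first sample. Frames entirely outside the annotated span get
#' `NA`.
#'
#' @param frames Tibble from [frame_signal()] (needs `start_sample` and
#'   `signal`).
#' @param episodes Tibble from [episodes_from_annotations()].
#' @return `frames` with an added `rhythm` column.
#' @export
label_frames <- function(frames, episodes) {
  n <- nrow(frames)
  rhythm <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f0 <- frames$start_sample[i]
    f1 <- f0 + length(frames$signal[[i]])
    ov <- pmax(0, pmin(episodes$end_sample, f1) -
                  pmax(episodes$start_sample, f0))
    if (all(ov == 0)) next
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      covers <- which(episodes$start_sample <= f0 & episodes$end_sample > f0)
      best <- if (length(covers)) covers[1] else best[1]
    }
    rhythm[i] <- episodes$rhythm[best]
  }
  frames$rhythm <- rhythm
  frames
}

#' Binary classification task schemes
#'
#' Defines which rhythm codes count as positive (label 1), negative
#' (label 0) or discarded for each clinical task: shockable vs.
#' non-shockable (VF, VT and ventricular flutter are shockable), VF vs.
#' non-VF, and VT vs. VF.
#'
#' @param name One of `"shock_vs_nonshock"`, `"vf_vs_nonvf"`, `"vt_vs_vf"`.
#' @return A `task_scheme` object with `positive`, `negative` and
#'   `discard` code sets.
#' @export
#' @examples
#' task_scheme("vf_vs_nonvf")
task_scheme <- function(name = c("shock_vs_nonshock", "vf_vs_nonvf",
                                 "vt_vs_vf")) {
  name <- match.arg(name)
  sets <- switch(name,
    shock_vs_nonshock = list(positive = c("VF", "VT", "VFL"),
                             negative = c("NSR", "OTHER"),
                             discard = c("NOISE")),
    vf_vs_nonvf = list(positive = "VF",
                       negative = c("NSR", "VT", "VFL", "OTHER"),
                       discard = c("NOISE")),
    vt_vs_vf = list(positive = "VF",
                    negative = "VT",
                    discard = c("NSR", "VFL", "OTHER", "NOISE")))
  structure(c(list(name = name), sets), class = "task_scheme")
}

#' @export
print.task_scheme <- function(x, ...) {
  cat(sprintf("<task_scheme> %s\n  positive (1): %s\n  negative (0): %s\n  discard: %s\n",
              x$name, paste(x$positive, collapse = ", "),
              paste(x$negative, collapse = ", "),
              paste(x$discard, collapse = ", ")))
  invisible(x)
}

#' Map rhythm codes to binary task labels
#'
#' @param rhythm_code Character vector of rhythm codes (`NA` allowed).
#' @param scheme A [task_scheme()] or a scheme name.
#' @return Integer vector: 1 (positive), 0 (negative) or `NA` (discard).
#' @export
#' @examples
#' make_task_labels(c("VFL", "NSR", "NOISE"), "shock_vs_nonshock")
make_task_labels <- function(rhythm_code, scheme) {
  if (is.character(scheme)) scheme <- task_scheme(scheme)
  stopifnot(inherits(scheme, "task_scheme"))
  out <- rep(NA_integer_, length(rhythm_code))
  out[rhythm_code %in% scheme$positive] <- 1L
  out[rhythm_code %in% scheme$negative] <- 0L
  out
}
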