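#' Magnitude feature of one mode
#'
#' The Euclidean (L2) norm of the mode's per-sample instantaneous-amplitude
#' series over the whole frame.
#'
#' @param decomp A `tf_decomposition` from [decompose()].
#' @param mode_j Mode index, 0-based.
#' @return Non-negative scalar.
#' @export
magnitude_feature <- function(decomp, mode_j) {
  stopifnot(inherits(decomp, "tf_decomposition"))
  if (mode_j < 0 || mode_j >= length(decomp$freqs))
    abort("Mode index out of range.", class = "tfarr_invalid_input")
  sqrt(sum(decomp$amplitude[, mode_j + 1]^2))
}

## wrap angles to (-pi, pi]
.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Phase-difference feature of one mode
#'
#' Mean absolute successive difference of the mode's per-sample phase
#' series, with each difference wrapped to (-pi, pi] before the absolute
#' value, so benign crossings of the ±pi branch cut do not contribute
#' ~2*pi outliers. Differences adjacent to samples whose amplitude is
#' below `amp_tol` (phase undefined for a vanishing phasor) are skipped;
#' an all-degenerate series yields 0.
#'
#' @param decomp A `tf_decomposition`.
#' @param mode_j Mode index, 0-based.
#' @param amp_tol Amplitude below which the phase is treated as undefined.
#' @return Scalar in `[0, pi]` (radians per sample).
#' @export
phase_difference_feature <- function(decomp, mode_j, amp_tol = 1e-12) {
  stopifnot(inherits(decomp, "tf_decomposition"))
  if (mode_j < 0 || mode_j >= length(decomp$freqs))
    abort("Mode index out of range.", class = "tfarr_invalid_input")
  phi <- decomp$phase[, mode_j + 1]
  if (length(phi) < 2)
    abort("Phase series must have at least 2 samples.",
          class = "tfarr_invalid_input")
  a <- decomp$amplitude[, mode_j + 1]
  d <- abs(.wrap_pi(diff(phi)))
  ok <- (a[-length(a)] >= amp_tol) & (a[-1] >= amp_tol)
  if (!any(ok)) return(0)
  mean(d[ok])
}

#' Taylor-Fourier feature vector of one frame
#'
#' Decomposes the frame and assembles the 2J-dimensional feature vector
#' `[MF_0..MF_{J-1}, PD_0..PD_{J-1}]` (20 features for the default
#' 10-mode grid): the magnitude feature and phase-difference feature of
#' every mode.
#'
#' @param frame Numeric vector, at least `basis$L` samples.
#' @param basis A [build_basis()] object.
#' @return Named numeric vector (`mf_0..`, `pd_0..`).
#' @export
#' @examples
#' b <- build_basis()
#' fv <- feature_vector(gen_rhythm(rhythm_spec("VF", seed = 3)), b)
#' length(fv)
feature_vector <- function(frame, basis) {
  d <- decompose(basis, frame)
  J <- length(d$freqs)
  mf <- vapply(seq_len(J) - 1L, function(j) magnitude_feature(d, j),
               numeric(1))
  pd <- vapply(seq_len(J) - 1L, function(j) phase_difference_feature(d, j),
               numeric(1))
  stats::setNames(c(mf, pd),
                  c(paste0("mf_", seq_len(J) - 1),
                    paste0("pd_", seq_len(J) - 1)))
}

#' Feature matrix for a dataset of frames
#'
#' Maps [feature_vector()] over a tibble of frames (a `signal`
#' list-column, as produced by [gen_dataset()] or [frame_signal()]),
#' keeping any identifier/label columns.
#'
#' @param frames Tibble with a `signal` list-column.
#' @param basis A [build_basis()] object.
#' @return Tibble: the non-signal columns of `frames` followed by the
#'   feature columns `mf_0..` and `pd_0..`.
#' @export
feature_matrix <- function(frames, basis) {
  feats <- purrr::map(frames$signal, feature_vector, basis = basis)
  fm <- tibble::as_tibble(do.call(rbind, feats))
  dplyr::bind_cols(dplyr::select(frames, -"signal"), fm)
}

#' Screen features with per-column Welch t-tests
#'
#' Runs a two-sample unequal-variance (Welch) t-test on every feature
#' column between the two label groups. Degenerate columns (zero variance
#' in both groups) return p = 1 when the group means agree and p = 0
#' otherwise.
#'
#' @param features Tibble or matrix of feature columns (any non-numeric
#'   columns and the label column are ignored as features).
#' @param labels Binary vector (0/1) of the same length; if `NULL`,
#'   `features` must contain a `label` column.
#' @param alpha Significance threshold used for the `significant` flag.
#' @return Tibble with columns `feature`, `statistic`, `p_value`,
#'   `significant`; the count of significant features is attached as the
#'   attribute `n_significant`.
#' @export
feature_ttest <- function(features, labels = NULL, alpha = 0.001) {
  if (is.null(labels)) {
    if (!"label" %in% names(features))
      abort("Provide `labels` or a `label` column.",
            class = "tfarr_invalid_input")
    labels <- features$label
    features <- dplyr::select(features, -"label")
  }
  fm <- as.matrix(dplyr::select(tibble::as_tibble(features),
                                dplyr::where(is.numeric)))
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) < 2)
    abort("Both classes must be present.", class = "tfarr_invalid_input")
  keep <- !is.na(labels)
  fm <- fm[keep, , drop = FALSE]
  labels <- labels[keep]
  if (min(table(labels)) < 2)
    abort("Each class needs at least 2 rows.", class = "tfarr_invalid_input")
  res <- purrr::map(colnames(fm), function(cn) {
    x <- fm[labels == 1, cn]
    y <- fm[labels == 0, cn]
    if (var(x) < 1e-24 && var(y) < 1e-24) {
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      tibble::tibble(feature = cn, statistic = NA_real_, p_value = p)
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      tibble::tibble(feature = cn, statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    }
  }) |> purrr::list_rbind()
  res$significant <- res$p_value < alpha
  attr(res, "n_significant") <- sum(res$significant)
  res
}
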