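basis_f <- build_basis(fs = 250, grid_spacing = 5, n_modes = 10,
                       taylor_order = 2)

test_that("magnitude feature follows its closed forms", {
  d0 <- decompose(basis_f, numeric(1000))
  for (j in 0:9) expect_equal(magnitude_feature(d0, j), 0)

  t <- (0:999) / 250
  d <- decompose(basis_f, cos(2 * pi * 5 * t))
  expect_lt(abs(magnitude_feature(d, 1) - sqrt(1000)) / sqrt(1000), 0.01)

  ## brute-force oracle on a random frame
  x <- withr::with_seed(9, rnorm(800))
  dr <- decompose(basis_f, x)
  for (j in c(0, 3, 7))
    expect_equal(magnitude_feature(dr, j),
                 sqrt(sum(dr$amplitude[, j + 1]^2)))
  expect_error(magnitude_feature(dr, 10), class = "tfarr_invalid_input")
})

test_that("phase-difference feature handles ramps and the wrap rule", {
  ## craft a decomposition with a prescribed phase series
  d <- decompose(basis_f, numeric(200))
  fake <- function(phi, amp = 1) {
    d$phase[, 2] <- phi
    d$amplitude[, 2] <- amp
    d
  }
  P <- 200
  expect_equal(phase_difference_feature(fake(rep(0.7, P)), 1), 0)
  expect_equal(phase_difference_feature(fake(0.01 * seq_len(P)), 1), 0.01)
  ## alternating +/- pi boundary: wrapped difference is 0.1, not ~2 pi
  alt <- rep(c(pi - 0.05, -pi + 0.05), length.out = P)
  expect_equal(phase_difference_feature(fake(alt), 1), 0.1)
  ## hand-checked 3-term series
  d3 <- fake(c(pi - 0.05, -pi + 0.05, pi - 0.05, rep(0, P - 3)),
             amp = c(rep(1, 3), rep(0, P - 3)))
  expect_equal(phase_difference_feature(d3, 1), 0.1)
  ## degenerate phasor: all differences skipped
  expect_equal(phase_difference_feature(fake(rnorm(P), amp = 0), 1), 0)
  ## brute-force oracle on a random frame
  x <- withr::with_seed(21, rnorm(600))
  dr <- decompose(basis_f, x)
  for (j in c(1, 5)) {
    phi <- dr$phase[, j + 1]
    dd <- diff(phi)
    dd <- (dd + pi) %% (2 * pi) - pi
    dd[dd == -pi] <- pi
    expect_equal(phase_difference_feature(dr, j), mean(abs(dd)))
  }
})

test_that("feature vectors have the fixed 20-dim layout and invariances", {
  x <- gen_rhythm(rhythm_spec("VF", fs = 250, duration = 4, seed = 5))
  fv <- feature_vector(x, basis_f)
  expect_length(fv, 20)
  expect_named(fv, c(paste0("mf_", 0:9), paste0("pd_", 0:9)))
  expect_true(all(fv[1:10] >= 0))
  expect_true(all(fv[11:20] >= 0 & fv[11:20] <= pi))

  fv0 <- feature_vector(numeric(1000), basis_f)
  expect_true(all(fv0 == 0))

  ## MF homogeneity and PD scale invariance
  fv2 <- feature_vector(2 * x, basis_f)
  expect_lt(max(abs(fv2[1:10] - 2 * fv[1:10]) / pmax(fv[1:10], 1e-12)),
            1e-9)
  expect_lt(max(abs(fv2[11:20] - fv[11:20])), 1e-9)
})

test_that("PD stays within [0, pi] over random frames", {
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(500))
    fv <- feature_vector(x, basis_f)
    expect_true(all(fv[11:20] >= 0 & fv[11:20] <= pi))
  }
})

test_that("feature_matrix maps a frame dataset to a labeled tibble", {
  ds <- gen_dataset(4, classes = c("NSR", "VF"), frame_s = 4, seed = 2)
  fm <- feature_matrix(ds, basis_f)
  expect_equal(nrow(fm), 8)
  expect_true(all(c(paste0("mf_", 0:9), paste0("pd_", 0:9), "rhythm")
                  %in% names(fm)))
})

test_that("Welch screening flags a shifted feature and respects the null", {
  withr::with_seed(77, {
    z <- matrix(rnorm(100 * 20), 100, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    y <- rep(c(0, 1), each = 50)
    z[y == 1, 3] <- z[y == 1, 3] + 5      # 5-SD mean shift on one feature
    res <- feature_ttest(tibble::as_tibble(z), y)
  })
  expect_equal(nrow(res), 20)
  expect_lt(res$p_value[3], 1e-10)
  expect_equal(attr(res, "n_significant"), sum(res$p_value < 0.001))

  ## degenerate columns
  zc <- tibble::tibble(a = rep(1, 40), b = rep(c(0, 1), each = 20))
  yc <- rep(c(0, 1), each = 20)
  rc <- feature_ttest(zc, yc)
  expect_equal(rc$p_value[rc$feature == "a"], 1)
  expect_equal(rc$p_value[rc$feature == "b"], 0)

  expect_error(feature_ttest(tibble::as_tibble(z), rep(1, 100)),
               class = "tfarr_invalid_input")
})
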