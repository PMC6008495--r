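basis_k2 <- build_basis(fs = 250, grid_spacing = 5, n_modes = 10,
                        taylor_order = 2)

test_that("basis geometry and conditioning match the construction", {
  expect_equal(basis_k2$L, 150)
  expect_equal(ncol(basis_k2$B), 57)
  expect_equal(qr(basis_k2$B)$rank, 57)
  ## pseudoinverse property B B+ B = B
  expect_lt(max(abs(basis_k2$B %*% basis_k2$B_pinv %*% basis_k2$B -
                      basis_k2$B)), 1e-8)

  dc <- build_basis(fs = 250, grid_spacing = 5, n_modes = 1,
                    taylor_order = 0)
  expect_equal(ncol(dc$B), 1)
  expect_equal(as.numeric(dc$B_pinv), rep(1 / 50, 50))

  expect_error(build_basis(fs = 250, grid_spacing = 7),
               class = "tfarr_invalid_input")
  expect_error(build_basis(n_modes = 30), class = "tfarr_invalid_input")
})

test_that("analysis recovers basis-span coefficients exactly", {
  b <- basis_k2
  w <- cos(2 * pi * 5 * b$t_n)
  cf <- analyze_window(b, w)
  expect_lt(Mod(cf$xi[2, 1] - (1 + 0i)), 1e-9)
  expect_lt(max(Mod(cf$xi)[-2]), 1e-9)
  expect_lt(max(Mod(cf$xi[2, -1])), 1e-9)

  expect_equal(analyze_window(b, numeric(150))$raw, rep(0, 57))

  ## ramped 10 Hz carrier: the k=1 envelope coefficient matches a dense
  ## normal-equations oracle
  w2 <- (b$t_n / b$half_window) * cos(2 * pi * 10 * b$t_n)
  cf2 <- analyze_window(b, w2)
  oracle <- ls_oracle(b$B, w2)
  expect_lt(max(abs(cf2$raw - oracle)), 1e-8)
  expect_lt(Mod(cf2$xi[3, 2] - (1 + 0i)), 1e-8)

  expect_error(analyze_window(b, numeric(100)),
               class = "tfarr_invalid_input")
})

test_that("synthesis is the adjoint projection: Pythagoras and idempotence", {
  b <- basis_k2
  ## in-span round trip
  raw <- withr::with_seed(1, rnorm(ncol(b$B)))
  s_in <- synthesize_window(b, raw)
  rt <- synthesize_window(b, analyze_window(b, s_in))
  expect_lt(sqrt(sum((rt - s_in)^2)) / sqrt(sum(s_in^2)), 1e-8)
  expect_equal(synthesize_window(b, rep(0, 57)), rep(0, 150))

  for (i in 1:20) {
    s <- withr::with_seed(100 + i, rnorm(b$L))
    cf <- analyze_window(b, s)
    shat <- synthesize_window(b, cf)
    ## energy split
    expect_lt(abs(sum(s^2) - sum(shat^2) - sum((s - shat)^2)) / sum(s^2),
              1e-8)
    ## residual orthogonal to the column space
    expect_lt(max(abs(crossprod(b$B, s - shat))) /
                (sqrt(sum(s^2)) * max(sqrt(colSums(b$B^2)))), 1e-8)
    ## projection idempotence
    cf2 <- analyze_window(b, shat)
    expect_lt(max(abs(cf2$raw - cf$raw)), 1e-8)
  }
  expect_error(synthesize_window(b, rep(0, 10)),
               class = "tfarr_invalid_input")
})

test_that("decompose recovers grid carriers away from the padded edges", {
  b <- basis_k2
  t <- (0:999) / 250
  d <- decompose(b, cos(2 * pi * 5 * t))
  interior <- (b$L + 1):(1000 - b$L)
  expect_lt(max(abs(d$amplitude[interior, 2] - 1)), 1e-6)
  expect_lt(max(d$amplitude[interior, -2]), 1e-6)

  d0 <- decompose(b, numeric(1000))
  expect_equal(max(d0$amplitude), 0)
  expect_equal(max(abs(d0$modes)), 0)

  d2 <- decompose(b, cos(2 * pi * 5 * t) + 0.5 * cos(2 * pi * 20 * t + 1))
  expect_lt(max(abs(d2$amplitude[interior, 2] - 1)), 1e-6)
  expect_lt(max(abs(d2$amplitude[interior, 5] - 0.5)), 1e-6)
  expect_lt(max(abs(d2$phase[interior, 5] - 1)), 1e-6)

  expect_error(decompose(b, numeric(100)), class = "tfarr_invalid_input")
})

test_that("decompose is linear in the input frame", {
  b <- basis_k2
  x <- withr::with_seed(3, rnorm(600))
  y <- withr::with_seed(4, rnorm(600))
  da <- decompose(b, 2 * x - 0.5 * y)
  db <- 2 * decompose(b, x)$phasor - 0.5 * decompose(b, y)$phasor
  expect_lt(max(Mod(da$phasor - db)) / max(Mod(db)), 1e-9)
})

test_that("reconstruction matches in-span frames on interior samples", {
  b <- basis_k2
  sig <- inspan_signal(1000, 250, b$freqs, K = 2, seed = 42)
  d <- decompose(b, sig$x)
  r <- reconstruct(d)
  interior <- (b$L + 1):(1000 - b$L)
  rel <- sqrt(mean((r - sig$x)[interior]^2)) / sqrt(mean(sig$x[interior]^2))
  expect_lt(rel, 1e-6)
  expect_equal(reconstruct(decompose(b, numeric(500))), rep(0, 500))
})

test_that("tidy() flattens a decomposition to one row per sample and mode", {
  d <- decompose(basis_k2, numeric(200))
  td <- tidy(d)
  expect_equal(nrow(td), 200 * 10)
  expect_named(td, c("sample", "time", "mode", "frequency", "amplitude",
                     "phase", "value"))
})

test_that("mode filters are selective and maximally flat at their center", {
  b <- basis_k2
  for (j in c(0, 1, 4, 9)) {
    r <- filter_response(b, j, b$freqs)
    expect_lt(abs(r$gain[j + 1] - 1), 1e-8)
    expect_lt(max(r$gain[-(j + 1)]), 1e-8)
  }
  ## numerical first derivative of the gain at the center frequency
  for (j in c(1, 5)) {
    g <- filter_response(b, j, b$freqs[j + 1] + c(-0.01, 0.01))$gain
    expect_lt(abs(g[2] - g[1]) / 0.02, 1e-3)
  }
  expect_error(filter_response(b, 10, 5), class = "tfarr_invalid_input")
})

test_that("analysis matches the dense least-squares oracle on random windows", {
  b <- basis_k2
  for (i in 1:25) {
    s <- withr::with_seed(500 + i, rnorm(b$L))
    expect_lt(max(abs(analyze_window(b, s)$raw - ls_oracle(b$B, s))), 1e-8)
  }
})
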