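test_that("kernel evaluations match closed forms", {
  expect_equal(kernel_eval("rbf", c(1, 2), c(1, 2), sigma = 0.7), 1)
  expect_equal(kernel_eval("linear", c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_eval("rbf", c(0, 0), c(1, 1), sigma = 1), exp(-1))
  expect_error(kernel_eval("linear", 1:2, 1:3),
               class = "tfarr_invalid_input")
  expect_error(kernel_eval("rbf", 1, 1, sigma = 0),
               class = "tfarr_invalid_input")
})

test_that("two separable points are classified with zero bias", {
  X <- matrix(c(1, -1), ncol = 1)
  m <- lssvm(X, c(1, 0), kernel = "linear", gamma = 10)
  expect_equal(predict(m, X), c(1L, 0L))
  expect_lt(abs(m$b), 1e-10)           # symmetric problem
  ## brute force on the standardized coordinates
  o <- lssvm_oracle(m$x_std, c(1, 0), "linear", 10)
  expect_lt(abs(m$b - o$b), 1e-8)
  expect_lt(max(abs(m$beta - o$beta)), 1e-8)
})

test_that("RBF with a narrow bandwidth interpolates the XOR set", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(0, 0, 1, 1)
  m <- lssvm(X, y, kernel = "rbf", gamma = 100, sigma = 0.5)
  expect_equal(predict(m, X), as.integer(y))
  o <- lssvm_oracle(m$x_std, y, "rbf", 100,
                    sigma = m$sigma)
  expect_lt(abs(m$b - o$b), 1e-8)
  expect_lt(max(abs(m$beta - o$beta)), 1e-8)
})

test_that("KKT residual is tiny for random training sets", {
  withr::with_seed(10, {
    for (i in 1:5) {
      X <- matrix(rnorm(40), 20, 2)
      y <- rep(c(0, 1), 10)
      m <- lssvm(X, y, kernel = "rbf", gamma = 5)
      expect_lt(m$kkt_residual, 1e-8)
      o <- lssvm_oracle(m$x_std, y, "rbf", 5, sigma = m$sigma)
      expect_lt(max(abs(c(m$b, m$beta) - c(o$b, o$beta))), 1e-8)
    }
  })
})

test_that("large gamma drives training error to zero on separable data", {
  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
    y <- rep(c(0, 1), each = 30)
  })
  m <- lssvm(X, y, kernel = "rbf", gamma = 1e6)
  expect_equal(mean(predict(m, X) != y), 0)
})

test_that("standardization absorbs feature rescaling", {
  withr::with_seed(4, {
    X <- matrix(rnorm(200), 50, 4)
    y <- as.integer(X[, 1] + 0.2 * rnorm(50) > 0)
    Xtest <- matrix(rnorm(80), 20, 4)
  })
  m1 <- lssvm(X, y, kernel = "rbf", gamma = 10)
  X2 <- X; X2[, 2] <- X2[, 2] * 1000
  Xt2 <- Xtest; Xt2[, 2] <- Xt2[, 2] * 1000
  m2 <- lssvm(X2, y, kernel = "rbf", gamma = 10)
  expect_equal(predict(m1, Xtest), predict(m2, Xt2))
})

test_that("prediction applies the sign rule with ties going to class 1", {
  m <- structure(list(kernel = "linear", gamma = 1, sigma = NULL,
                      x_std = matrix(0, 1, 2), y_signed = 1, beta = 0,
                      b = -1, center = c(0, 0), scale = c(1, 1), n = 1,
                      p = 2, kkt_residual = 0, feature_names = NULL),
                 class = "lssvm")
  expect_equal(predict(m, matrix(rnorm(10), 5, 2)), rep(0L, 5))
  m$b <- 0
  expect_equal(predict(m, matrix(0, 1, 2)), 1L)   # decision exactly zero
  expect_error(predict(m, matrix(0, 1, 3)), class = "tfarr_invalid_input")
})

test_that("degenerate training inputs raise errors", {
  expect_error(lssvm(matrix(1:4, 2), c(1, 1)), class = "tfarr_invalid_input")
  expect_error(lssvm(matrix(1:4, 2), c(0, 1), gamma = -1),
               class = "tfarr_invalid_input")
})

test_that("evaluation reports the standard confusion-derived rates", {
  rep1 <- eval_report(tp = 10, tn = 10, fp = 0, fn = 0)
  expect_equal(glance(rep1)$accuracy, 100)
  rep2 <- eval_report(tp = 10, tn = 0, fp = 10, fn = 0)
  expect_equal(rep2$accuracy, 50)
  expect_equal(rep2$sensitivity, 100)
  expect_equal(rep2$specificity, 0)
  rep3 <- eval_report(tp = 86, fn = 14, tn = 94, fp = 6)
  expect_equal(rep3$sensitivity, 86)
  expect_equal(rep3$specificity, 94)
  expect_equal(rep3$accuracy, 90)
  expect_warning(eval_report(tp = 0, tn = 5, fp = 0, fn = 0),
                 "sensitivity")
  expect_equal(tidy(rep3)$count, c(86, 94, 6, 14))
})

test_that("stratified hold-out splits and reports deterministically", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(2000, -3), 100, 20),
               matrix(rnorm(2000, 3), 100, 20))
    y <- rep(c(0, 1), each = 100)
  })
  r1 <- holdout_experiment(X, y, kernel = "rbf", gamma = 10, seed = 1)
  m <- attr(r1, "model")
  expect_equal(m$n, 130)               # 65 per class
  expect_equal(with(r1, tp + tn + fp + fn), 70)
  r2 <- holdout_experiment(X, y, kernel = "rbf", gamma = 10, seed = 1)
  expect_equal(glance(r1), glance(r2))
  expect_gte(r1$accuracy, 99)
})

test_that("stratified k-fold partitions every row exactly once", {
  withr::with_seed(9, {
    X <- rbind(matrix(rnorm(1000, -3), 50, 20),
               matrix(rnorm(1000, 3), 50, 20))
    y <- rep(c(0, 1), each = 50)
  })
  cv <- cross_validate(X, y, k_folds = 5, kernel = "rbf", gamma = 10,
                       seed = 2)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(sum(tidy(cv)$n), 100)
  cv2 <- cross_validate(X, y, k_folds = 5, kernel = "rbf", gamma = 10,
                        seed = 2)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_gte(glance(cv)$accuracy, 99)
  expect_error(cross_validate(X[1:6, ], y[c(1:3, 51:53)], k_folds = 5),
               class = "tfarr_invalid_input")
})

test_that("models round-trip through JSON with identical predictions", {
  withr::with_seed(12, {
    X <- matrix(rnorm(200), 50, 4)
    y <- rep(c(0, 1), 25)
    Xt <- matrix(rnorm(40), 10, 4)
  })
  m <- lssvm(X, y, kernel = "rbf", gamma = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_lssvm(m, f)
  m2 <- read_lssvm(f)
  expect_equal(predict(m, Xt, type = "decision"),
               predict(m2, Xt, type = "decision"), tolerance = 1e-12)
})
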