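#' Evaluate a kernel function
#'
#' @param kind `"linear"` (dot product) or `"rbf"`
#'   (`exp(-||u - v||^2 / (2 sigma^2))`).
#' @param u,v Numeric vectors of equal length.
#' @param sigma RBF bandwidth (> 0); ignored for the linear kernel.
#' @return Scalar kernel value.
#' @export
#' @examples
#' kernel_eval("rbf", c(0, 0), c(1, 1), sigma = 1)   # exp(-1)
kernel_eval <- function(kind = c("linear", "rbf"), u, v, sigma = 1) {
  kind <- match.arg(kind)
  if (length(u) != length(v))
    abort("`u` and `v` must have the same dimension.",
          class = "tfarr_invalid_input")
  if (kind == "linear") sum(u * v)
  else {
    if (sigma <= 0) abort("`sigma` must be positive.",
                          class = "tfarr_invalid_input")
    exp(-sum((u - v)^2) / (2 * sigma^2))
  }
}

.kernel_matrix <- function(kind, X, Y = NULL, sigma = 1) {
  if (is.null(Y)) Y <- X
  if (kind == "linear") return(tcrossprod(X, Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

.median_sigma <- function(X) {
  n <- nrow(X)
  ## deterministic evenly spaced subsample keeps training a pure function
  idx <- if (n > 200) unique(round(seq(1, n, length.out = 200)))
         else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  m <- median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

.as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(dplyr::select(tibble::as_tibble(x), dplyr::where(is.numeric)))
}

#' Train a least-squares support vector machine
#'
#' LSSVM replaces the SVM's inequality constraints by equality constraints
#' with squared slack penalty weighted by `gamma`; training then reduces to
#' one symmetric `(m+1) x (m+1)` linear (KKT) system
#' `[[0, y'], [y, Omega + I/gamma]] [b; beta] = [0; 1]` with
#' `Omega_il = y_i y_l K(z_i, z_l)`. Labels 0/1 are mapped to -1/+1 and
#' features are standardized by the training mean and standard deviation
#' before kernel evaluation.
#'
#' @param x Feature matrix or tibble (numeric columns are used).
#' @param y Binary labels (0/1, logical, or a 2-level factor).
#' @param kernel `"rbf"` or `"linear"`.
#' @param gamma Regularization weight (> 0); larger fits the training data
#'   harder.
#' @param sigma RBF bandwidth; `NULL` uses the median pairwise distance of
#'   the standardized training inputs (median heuristic).
#' @return An object of class `lssvm` with dual coefficients `beta`, bias
#'   `b`, the stored (standardized) training inputs and the standardizer.
#' @export
#' @examples
#' m <- lssvm(matrix(c(1, -1), ncol = 1), c(1, 0), kernel = "linear",
#'            gamma = 10)
#' predict(m, matrix(c(1, -1), ncol = 1))
lssvm <- function(x, y, kernel = c("rbf", "linear"), gamma = 10,
                  sigma = NULL) {
  kernel <- match.arg(kernel)
  X <- .as_feature_matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    abort("Labels must be 0/1.", class = "tfarr_invalid_input")
  if (length(y) != nrow(X))
    abort("Row/label count mismatch.", class = "tfarr_invalid_input")
  if (length(unique(y)) < 2)
    abort("Both classes must be present in the training data.",
          class = "tfarr_invalid_input")
  if (gamma <= 0)
    abort("`gamma` must be positive.", class = "tfarr_invalid_input")
  ys <- ifelse(y == 1L, 1, -1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  if (kernel == "rbf" && is.null(sigma)) sigma <- .median_sigma(Xs)
  m <- nrow(Xs)
  K <- .kernel_matrix(kernel, Xs, sigma = sigma)
  Omega <- (ys %o% ys) * K
  A <- rbind(c(0, ys), cbind(ys, Omega + diag(1 / gamma, m)))
  rhs <- c(0, rep(1, m))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    abort(paste0("Singular KKT system (condition estimate ",
                 format(kappa(A), digits = 3), "): ",
                 conditionMessage(e)),
          class = "tfarr_singular_system"))
  res_norm <- sqrt(sum((A %*% sol - rhs)^2)) / sqrt(sum(rhs^2))
  structure(
    list(kernel = kernel, gamma = gamma, sigma = sigma,
         x_std = Xs, y_signed = ys, beta = sol[-1], b = sol[1],
         center = ctr, scale = scl, n = m, p = ncol(Xs),
         kkt_residual = res_norm,
         feature_names = colnames(X)),
    class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf(
    "<lssvm> %s kernel%s, gamma = %g, %d x %d training set, |b| = %.4g\n",
    x$kernel,
    if (x$kernel == "rbf") sprintf(" (sigma = %.4g)", x$sigma) else "",
    x$gamma, x$n, x$p, abs(x$b)))
  invisible(x)
}

#' Decision values and class predictions for an LSSVM
#'
#' The decision value for a test vector z is
#' `sum_i beta_i y_i K(z, z_i) + b` on standardized coordinates; class 1
#' is predicted for decision values >= 0 (the exact-zero tie goes to
#' class 1).
#'
#' @param object An [lssvm()] model.
#' @param newdata Feature matrix or tibble.
#' @param type `"class"` (0/1 integer) or `"decision"` (raw values).
#' @param ... Unused.
#' @return Integer or numeric vector, one value per row of `newdata`.
#' @export
predict.lssvm <- function(object, newdata, type = c("class", "decision"),
                          ...) {
  type <- match.arg(type)
  X <- .as_feature_matrix(newdata)
  if (ncol(X) != object$p)
    abort("Feature dimension mismatch.", class = "tfarr_invalid_input")
  Xs <- scale(X, center = object$center, scale = object$scale)
  K <- .kernel_matrix(object$kernel, Xs, object$x_std, sigma = object$sigma)
  dec <- drop(K %*% (object$beta * object$y_signed)) + object$b
  if (type == "decision") return(dec)
  as.integer(dec >= 0)
}

#' Tidy an LSSVM model: one row per training instance
#'
#' @param x An [lssvm()] model.
#' @param ... Unused.
#' @return Tibble with columns `index`, `beta`, `y`.
#' @export
tidy.lssvm <- function(x, ...) {
  tibble::tibble(index = seq_len(x$n), beta = x$beta,
                 y = as.integer(x$y_signed == 1))
}

#' One-row model summary for an LSSVM
#'
#' @param x An [lssvm()] model.
#' @param ... Unused.
#' @return Tibble with kernel spec, hyperparameters, training size and
#'   KKT residual.
#' @export
glance.lssvm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, gamma = x$gamma,
                 sigma = if (x$kernel == "rbf") x$sigma else NA_real_,
                 n = x$n, p = x$p, b = x$b, kkt_residual = x$kkt_residual)
}

#' Confusion counts and accuracy/sensitivity/specificity
#'
#' Positive class is label 1. Sensitivity is the true-positive rate over
#' positives, specificity the true-negative rate over negatives; all three
#' summary measures are percentages. With no positives (or no negatives)
#' in the test set the corresponding rate is `NaN` and a warning is
#' raised.
#'
#' @param model An [lssvm()] model.
#' @param x_test,y_test Test features and 0/1 labels.
#' @return An `eval_report` with `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate <- function(model, x_test, y_test) {
  if (is.factor(y_test)) y_test <- as.integer(y_test) - 1L
  y_test <- as.integer(y_test)
  if (length(y_test) == 0)
    abort("Empty test set.", class = "tfarr_invalid_input")
  pred <- predict(model, x_test)
  eval_report(tp = sum(pred == 1 & y_test == 1),
              tn = sum(pred == 0 & y_test == 0),
              fp = sum(pred == 1 & y_test == 0),
              fn = sum(pred == 0 & y_test == 1))
}

#' Build an evaluation report from confusion counts
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return An `eval_report` object.
#' @export
eval_report <- function(tp, tn, fp, fn) {
  if (tp + fn == 0)
    warn("No positive instances in the test set: sensitivity is undefined.")
  if (tn + fp == 0)
    warn("No negative instances in the test set: specificity is undefined.")
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
         sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NaN,
         specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NaN),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> Acc %.2f%%  Sen %.2f%%  Spe %.2f%%  ",
                     "(tp %d, tn %d, fp %d, fn %d)\n"),
              x$accuracy, x$sensitivity, x$specificity,
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(outcome = c("tp", "tn", "fp", "fn"),
                 count = c(x$tp, x$tn, x$fp, x$fn))
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity,
                 n = x$tp + x$tn + x$fp + x$fn)
}

.stratified_split <- function(y, train_frac, seed) {
  withr::with_seed(as.integer(seed), {
    train_idx <- integer(0)
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      n_tr <- floor(train_frac * length(idx))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    sort(train_idx)
  })
}

#' Seeded stratified hold-out experiment
#'
#' Splits the data into a stratified train/test partition (default 65%
#' training), trains an LSSVM on the training part and evaluates on the
#' held-out part.
#'
#' @param x,y Features and 0/1 labels.
#' @param train_frac Training fraction per class.
#' @param kernel,gamma,sigma Passed to [lssvm()].
#' @param seed Integer seed controlling the split.
#' @return An `eval_report` with the fitted model attached as attribute
#'   `model`.
#' @export
holdout_experiment <- function(x, y, train_frac = 0.65,
                               kernel = c("rbf", "linear"), gamma = 10,
                               sigma = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- .as_feature_matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2)
    abort("Both classes must be present.", class = "tfarr_invalid_input")
  tr <- .stratified_split(y, train_frac, seed)
  te <- setdiff(seq_along(y), tr)
  if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2)
    abort("A class is absent from one side of the split.",
          class = "tfarr_invalid_input")
  model <- lssvm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                 gamma = gamma, sigma = sigma)
  rep <- evaluate(model, X[te, , drop = FALSE], y[te])
  attr(rep, "model") <- model
  rep
}

#' Seeded stratified k-fold cross-validation
#'
#' @param x,y Features and 0/1 labels.
#' @param k_folds Number of folds (each class must have at least this many
#'   rows).
#' @param kernel,gamma,sigma Passed to [lssvm()].
#' @param seed Integer seed controlling fold assignment.
#' @return A `cv_result`: per-fold `eval_report`s plus mean and standard
#'   deviation of accuracy/sensitivity/specificity.
#' @export
cross_validate <- function(x, y, k_folds = 5, kernel = c("rbf", "linear"),
                           gamma = 10, sigma = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- .as_feature_matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (any(table(y) < k_folds))
    abort("Each class needs at least `k_folds` rows.",
          class = "tfarr_invalid_input")
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  reports <- purrr::map(seq_len(k_folds), function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- lssvm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                   gamma = gamma, sigma = sigma)
    evaluate(model, X[te, , drop = FALSE], y[te])
  })
  metrics <- purrr::map(reports, glance) |> purrr::list_rbind()
  structure(list(folds = reports, fold_assignment = fold,
                 metrics = metrics,
                 mean = colMeans(metrics[, 1:3]),
                 sd = apply(metrics[, 1:3], 2, sd)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("<cv_result> %d folds: Acc %.2f ± %.2f%%, ",
                     "Sen %.2f ± %.2f%%, Spe %.2f ± %.2f%%\n"),
              length(x$folds),
              x$mean["accuracy"], x$sd["accuracy"],
              x$mean["sensitivity"], x$sd["sensitivity"],
              x$mean["specificity"], x$sd["specificity"]))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(fold = seq_along(x$folds)), x$metrics)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(accuracy = x$mean["accuracy"],
                 sensitivity = x$mean["sensitivity"],
                 specificity = x$mean["specificity"],
                 accuracy_sd = x$sd["accuracy"],
                 k_folds = length(x$folds))
}

#' Serialize an LSSVM model to JSON
#'
#' @param model An [lssvm()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lssvm <- function(model, path) {
  obj <- list(kernel = model$kernel, gamma = model$gamma,
              sigma = model$sigma, beta = model$beta, b = model$b,
              center = model$center, scale = model$scale,
              x_std = model$x_std, y_signed = model$y_signed,
              feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an LSSVM model from JSON
#'
#' @param path Path written by [write_lssvm()].
#' @return An [lssvm()] model.
#' @export
read_lssvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(kernel = obj$kernel, gamma = obj$gamma, sigma = obj$sigma,
         x_std = as.matrix(obj$x_std), y_signed = as.numeric(obj$y_signed),
         beta = as.numeric(obj$beta), b = obj$b,
         center = as.numeric(obj$center), scale = as.numeric(obj$scale),
         n = length(obj$beta), p = length(obj$center),
         kkt_residual = NA_real_, feature_names = obj$feature_names),
    class = "lssvm")
}
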