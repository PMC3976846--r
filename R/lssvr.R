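#' @include AllClasses.R
NULL

#' LS-SVR configuration
#'
#' Bundles the Gaussian RBF width \eqn{\sigma^2}, the regularization
#' \eqn{\gamma}, the hyperparameter grids, the number of cross-validation
#' folds and the fold-shuffling seed. The default grids are logarithmic
#' with 7 points per axis spanning \eqn{\sigma^2 \in [0.1, 10^5]} and
#' \eqn{\gamma \in [0.1, 10^4]}.
#'
#' @param sigma2,gamma optional fixed kernel width / regularization; filled
#'   in by [gridSearchLSSVR()] when `NULL`.
#' @param sigma2Grid,gammaGrid positive numeric grids for the search.
#' @param folds number of cross-validation folds (>= 2); 10 is the
#'   hyperparameter-search default, subset evaluation uses 5.
#' @param seed integer seed for the shuffled fold assignment.
#' @return A list of class `lssvrConfig`.
#' @export
lssvrConfig <- function(sigma2 = NULL, gamma = NULL,
                        sigma2Grid = 10^seq(log10(0.1), log10(1e5),
                                            length.out = 7),
                        gammaGrid = 10^seq(log10(0.1), log10(1e4),
                                           length.out = 7),
                        folds = 10L, seed = 1L) {
  stopifnot(length(sigma2Grid) > 0, length(gammaGrid) > 0,
            all(sigma2Grid > 0), all(gammaGrid > 0), folds >= 2)
  structure(list(sigma2 = sigma2, gamma = gamma,
                 sigma2Grid = sort(sigma2Grid), gammaGrid = sort(gammaGrid),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "lssvrConfig")
}

#' Gaussian RBF kernel
#'
#' \eqn{k(x, z) = \exp(-\|x - z\|^2 / \sigma^2)}; note the direct-divisor
#' convention for \eqn{\sigma^2} (not \eqn{2\sigma^2}).
#'
#' @param x,z numeric vectors of equal length.
#' @param sigma2 positive kernel width.
#' @return kernel value in `(0, 1]`.
#' @examples
#' rbfKernel(c(0, 0), c(1, 0), sigma2 = 1)  # exp(-1)
#' @export
rbfKernel <- function(x, z, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (length(x) != length(z)) stop("x and z must have equal dimension")
  exp(-sum((x - z)^2) / sigma2)
}

# full pairwise squared-distance matrix between rows of A and rows of B
crossdist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Solve the LS-SVM dual from a precomputed training kernel matrix.
# The bordered system [[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]
# is solved through the Schur complement of the SPD block A = K + I/gamma:
#   A z1 = 1, A z2 = y, b = (1'z2)/(1'z1), alpha = z2 - b z1.
solveLSSVRKernel <- function(K, y, gamma) {
  n <- length(y)
  A <- K
  diag(A) <- diag(A) + 1 / gamma
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) {
    z <- backsolve(ch, backsolve(ch, cbind(1, y), transpose = TRUE))
  } else {
    z <- tryCatch(solve(A, cbind(1, y)), error = function(e)
      stop("singular LS-SVR system (reciprocal condition number ~ ",
           format(rcond(A), digits = 3), ")"))
  }
  b <- sum(z[, 2]) / sum(z[, 1])
  alpha <- z[, 2] - b * z[, 1]
  list(alpha = alpha, bias = b)
}

#' Fit a least-squares support vector regression model
#'
#' Solves the LS-SVM dual linear system
#' \deqn{\begin{bmatrix} 0 & 1^\top \\ 1 & K + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' with Gaussian RBF kernel entries \eqn{K_{ij} = k(x_i, x_j)}. As
#' \eqn{\gamma \to \infty} the fit interpolates the training targets.
#'
#' @param X numeric matrix of inputs, samples x features.
#' @param y numeric target vector.
#' @param config an [lssvrConfig()] with `sigma2` and `gamma` set.
#' @return An [LSSVRModel-class].
#' @export
fitLSSVR <- function(X, y, config) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < 2) stop("at least 2 training samples are required")
  sigma2 <- config$sigma2
  gamma <- config$gamma
  if (is.null(sigma2) || is.null(gamma))
    stop("config must carry fixed sigma2 and gamma (run gridSearchLSSVR)")
  if (sigma2 <= 0 || gamma <= 0) stop("sigma2 and gamma must be positive")
  K <- exp(-crossdist2(X, X) / sigma2)
  sol <- solveLSSVRKernel(K, y, gamma)
  new("LSSVRModel", trainingInputs = X, alpha = sol$alpha, bias = sol$bias,
      sigma2 = sigma2, gamma = gamma)
}

#' Predict from a fitted LS-SVR model
#'
#' Standard dual predictor \eqn{\hat y(x) = \sum_i \alpha_i k(x_i, x) + b}.
#'
#' @param object an [LSSVRModel-class].
#' @param newdata numeric matrix of query inputs (samples x features).
#' @return numeric vector of predictions (length `nrow(newdata)`).
#' @export
setMethod("predict", "LSSVRModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != ncol(object@trainingInputs))
    stop("feature dimension mismatch with training inputs")
  K <- exp(-crossdist2(newdata, object@trainingInputs) / object@sigma2)
  as.numeric(K %*% object@alpha + object@bias)
})

setMethod("show", "LSSVRModel", function(object) {
  cat("LSSVRModel:", nrow(object@trainingInputs), "support points,",
      ncol(object@trainingInputs), "features\n")
  cat("  sigma2 =", format(object@sigma2, digits = 4),
      " gamma =", format(object@gamma, digits = 4),
      " bias =", format(object@bias, digits = 4), "\n")
})

# CV fold loop over a precomputed full kernel matrix; returns mean of the
# per-fold held-out MSEs. `folds` is a list of index vectors. The loop is
# compiled (src/cv_lssvr.cpp): it sits inside the swarm's fitness function
# and dominates the run time of a search.
cvMSEKernel <- function(K, y, gamma, folds) {
  cvMSEKernelCpp(K, as.numeric(y), gamma,
                 lapply(folds, function(te) as.integer(te) - 1L))
}

#' Cross-validated mean squared error of an LS-SVR model
#'
#' Folds are a seeded shuffled partition of the samples, so the value is
#' deterministic for a fixed `config$seed`.
#'
#' @inheritParams fitLSSVR
#' @return mean held-out MSE over the folds.
#' @export
cvMSE <- function(X, y, config) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("rows of X must match length of y")
  folds <- makeFolds(n, config$folds, config$seed)
  K <- exp(-crossdist2(X, X) / config$sigma2)
  cvMSEKernel(K, y, config$gamma, folds)
}

#' Grid search for LS-SVR hyperparameters
#'
#' Evaluates every \eqn{(\sigma^2, \gamma)} grid cell by cross-validated
#' MSE and returns the config with the minimizing pair filled in. Ties go
#' to the smallest \eqn{\sigma^2}, then the smallest \eqn{\gamma}.
#'
#' @inheritParams fitLSSVR
#' @return The input config with `sigma2`, `gamma` set and the winning
#'   cross-validated MSE in element `cv`.
#' @export
gridSearchLSSVR <- function(X, y, config) {
  X <- as.matrix(X)
  n <- length(y)
  folds <- makeFolds(n, config$folds, config$seed)
  d2 <- crossdist2(X, X)
  best <- NULL
  for (s2 in config$sigma2Grid) {
    K <- exp(-d2 / s2)
    for (g in config$gammaGrid) {
      err <- cvMSEKernel(K, y, g, folds)
      if (is.null(best) || err < best$cv)
        best <- list(sigma2 = s2, gamma = g, cv = err)
    }
  }
  config$sigma2 <- best$sigma2
  config$gamma <- best$gamma
  config$cv <- best$cv
  config
}

#' Regression accuracy metrics
#'
#' Mean squared error, its root, and the mean relative percentage error
#' \eqn{\mathrm{MRPE} = \frac{1}{n}\sum_i |y_i' - y_i| / |y_i| \times
#' 100\%}. MRPE is undefined when any observed value is zero; in that case
#' it is reported as `NA` with `mrpeDefined = FALSE` while MSE and RMSE are
#' still returned.
#'
#' @param y observed values.
#' @param yPred predicted values.
#' @return list with `mse`, `rmse`, `mrpe`, `mrpeDefined`.
#' @examples
#' regressionMetrics(c(1, 2), c(2, 2))  # mse 0.5, rmse ~0.707, mrpe 50
#' @export
regressionMetrics <- function(y, yPred) {
  if (length(y) != length(yPred)) stop("y and yPred must have equal length")
  mse <- mean((y - yPred)^2)
  rmse <- sqrt(mse)
  if (any(y == 0)) {
    list(mse = mse, rmse = rmse, mrpe = NA_real_, mrpeDefined = FALSE)
  } else {
    list(mse = mse, rmse = rmse,
         mrpe = mean(abs((yPred - y) / y)) * 100, mrpeDefined = TRUE)
  }
}
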