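#' Regression model specification
#'
#' The pipeline restricts itself to two simple models suited to small
#' cohorts: ordinary linear regression (`"lr"`, parameterless; minimum-norm
#' least squares when features outnumber subjects) and linear-kernel
#' epsilon-insensitive support vector regression (`"svr"`, with cost `C`
#' and tube half-width `epsilon`).
#'
#' `epsilon` is interpreted in standardized-response units: the effective
#' tube width at fit time is `epsilon * sd(y_train)`, so the grid keeps its
#' meaning whatever the score scale. A `gamma` value is accepted for
#' config fidelity but is inert under the linear kernel; a note is emitted
#' if one is supplied.
#'
#' @param kind `"svr"` or `"lr"`.
#' @param C positive SVR cost.
#' @param epsilon nonnegative SVR tube half-width (standardized-y units).
#' @param gamma optional; ignored for the linear kernel.
#' @return a `"model_spec"` object.
#' @export
model_spec <- function(kind = c("svr", "lr"), C = 1, epsilon = 0.1,
                       gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "svr") {
    check_scalar(C, "C", lower = 1e-12)
    check_scalar(epsilon, "epsilon", lower = 0)
    if (!is.null(gamma)) {
      message("note: 'gamma' has no effect under the linear kernel; ",
              "accepted and ignored")
    }
  } else {
    C <- NA_real_
    epsilon <- NA_real_
  }
  structure(list(kind = kind, C = C, epsilon = epsilon, gamma = gamma),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  if (x$kind == "lr") {
    cat("model spec: linear regression\n")
  } else {
    cat(sprintf("model spec: linear SVR (C = %g, epsilon = %g)\n",
                x$C, x$epsilon))
  }
  invisible(x)
}

#' Default SVR hyperparameter grid
#'
#' Geometric cost grid `2^-5, 2^-3, ..., 2^5` crossed with tube widths
#' 0.01, 0.1 and 1 (standardized-y units), ordered so that ties during
#' tuning resolve toward smaller C, then smaller epsilon.
#'
#' @param C,epsilon candidate values.
#' @return data.frame with columns `C` and `epsilon`.
#' @export
svr_grid <- function(C = 2^seq(-5, 5, by = 2), epsilon = c(0.01, 0.1, 1)) {
  g <- expand.grid(epsilon = epsilon, C = C)[, c("C", "epsilon")]
  g <- g[order(g$C, g$epsilon), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Fit a regression model on selected edge features
#'
#' Features are z-scored and the response centred with training statistics
#' only; both are stored in the model so prediction applies the identical
#' transform to new subjects. Linear regression uses the SVD-based
#' minimum-norm least-squares solution (exact normal-equations solution
#' when the design has full column rank, defined behaviour when p >= n).
#' SVR solves the usual epsilon-insensitive quadratic program with a
#' linear kernel.
#'
#' @param X numeric `n x p` training matrix (`p >= 1`; a zero-feature fit
#'   is an error — callers decide how to handle empty selections).
#' @param y numeric response, length n.
#' @param spec a [model_spec()].
#' @param feature_indices optional original column indices carried along
#'   for bookkeeping (defaults to `1:p`).
#' @return an `"edge_model"` with `weights`/`intercept` in standardized
#'   feature space, the standardization parameters, and the spec echo.
#' @export
fit_edge_model <- function(X, y, spec, feature_indices = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  check_matrix(X, "X")
  n <- nrow(X)
  p <- ncol(X)
  if (p < 1) {
    stop("no features to fit; handle the empty selection in the caller ",
         "(e.g. predict the training mean)", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 training subjects", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (is.null(feature_indices)) feature_indices <- seq_len(p)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  Xs <- scale(X, center = x_center, scale = x_scale)
  y_center <- mean(y)
  yc <- y - y_center
  if (spec$kind == "lr") {
    sv <- svd(Xs)
    pos <- sv$d > max(sv$d[1], 0) * 1e-10
    w <- if (any(pos)) {
      sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
    } else {
      matrix(0, p, 1)
    }
    w <- drop(w)
    b <- 0
  } else {
    eps_eff <- spec$epsilon * stats::sd(y)
    if (!is.finite(eps_eff)) eps_eff <- spec$epsilon
    fit <- e1071::svm(x = Xs, y = yc, type = "eps-regression",
                      kernel = "linear", cost = spec$C,
                      epsilon = eps_eff, scale = FALSE)
    if (is.null(fit$coefs) || nrow(fit$coefs) == 0) {
      w <- rep(0, p)
      b <- 0
    } else {
      w <- drop(crossprod(fit$coefs, fit$SV))
      b <- -fit$rho
    }
  }
  structure(list(weights = as.numeric(w), intercept = b,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, spec = spec,
                 feature_indices = feature_indices),
            class = "edge_model")
}

#' @export
print.edge_model <- function(x, ...) {
  cat(sprintf("fitted %s on %d feature(s); |w| range [%.3g, %.3g]\n",
              if (x$spec$kind == "lr") "linear regression" else "linear SVR",
              length(x$weights), min(abs(x$weights)), max(abs(x$weights))))
  invisible(x)
}

#' Predict behavioural scores from a fitted edge model
#'
#' @param object an `"edge_model"`.
#' @param newdata numeric matrix with the same columns (in the same order)
#'   the model was trained on.
#' @param ... unused.
#' @return numeric vector of predicted scores.
#' @export
predict.edge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    stop(sprintf("newdata has %d columns but the model was trained on %d",
                 ncol(newdata), length(object$weights)), call. = FALSE)
  }
  Xs <- scale(newdata, center = object$x_center, scale = object$x_scale)
  drop(object$y_center + object$intercept + Xs %*% object$weights)
}

#' @export
coef.edge_model <- function(object, ...) {
  stats::setNames(object$weights,
                  paste0("f", object$feature_indices))
}
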