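#' Control parameters for randomized-LASSO stability selection
#'
#' @param B number of subsample resamples.
#' @param fraction fraction of subjects drawn (without replacement) per
#'   resample; the default half-sampling is what gives stability selection
#'   its false-selection control (a spuriously correlated feature rarely
#'   survives across half-subsamples).
#' @param weakness randomization strength alpha in (0, 1]: per-resample
#'   column weights are drawn uniformly from `[alpha, 1]`. `alpha = 1`
#'   disables the randomization, recovering plain subsampled LASSO.
#' @param threshold selection-frequency threshold pi: features whose
#'   frequency is `>= threshold` form the selected set.
#' @param lambda optional explicit descending lambda grid for the L1 path;
#'   when `NULL` a geometric grid of `n_lambda` points from
#'   `lambda_max = max|X'y| / n` (computed per resample after
#'   standardization and weighting) down to
#'   `lambda_min_ratio * lambda_max` is used.
#' @param n_lambda,lambda_min_ratio auto-grid shape.
#' @param rule when is a feature "selected in a resample": `"path"`
#'   (default) if its coefficient is nonzero anywhere on the lambda path —
#'   robust to grid miscalibration at small n — or `"fixed"` if nonzero at
#'   the single grid point closest to `fixed_lambda_ratio * lambda_max`.
#' @param q per-resample cap on the number of features the path may
#'   activate: the path is truncated once `q` features have entered, which
#'   is what keeps null-feature selection frequencies low and bounds the
#'   expected number of false selections. Default `NULL` chooses
#'   `ceiling(sqrt(0.4 * p))` at fit time (no cap at all for p <= 12, so
#'   small pre-screened feature sets are never starved), the usual order
#'   for stability-selection error control at threshold 0.6.
#' @param fixed_lambda_ratio grid position used by `rule = "fixed"`.
#' @param seed RNG seed for subsampling and column weights.
#' @return a `"stability_control"` list.
#' @export
stability_control <- function(B = 200, fraction = 0.5, weakness = 0.5,
                              threshold = 0.6, lambda = NULL,
                              n_lambda = 30, lambda_min_ratio = 1e-3,
                              rule = c("path", "fixed"), q = NULL,
                              fixed_lambda_ratio = 0.1, seed = 1) {
  rule <- match.arg(rule)
  check_scalar(B, "B", lower = 1)
  check_scalar(fraction, "fraction", lower = 1e-9, upper = 1)
  check_scalar(weakness, "weakness", lower = 1e-9, upper = 1)
  check_scalar(threshold, "threshold", lower = 1e-9, upper = 1)
  if (!is.null(lambda)) {
    if (any(diff(lambda) >= 0) || any(lambda <= 0)) {
      stop("'lambda' must be strictly descending and positive",
           call. = FALSE)
    }
  }
  structure(list(B = as.integer(B), fraction = fraction,
                 weakness = weakness, threshold = threshold,
                 lambda = lambda, n_lambda = as.integer(n_lambda), q = q,
                 lambda_min_ratio = lambda_min_ratio, rule = rule,
                 fixed_lambda_ratio = fixed_lambda_ratio,
                 seed = as.integer(seed)),
            class = "stability_control")
}

#' Randomized-LASSO stability selection
#'
#' Repeatedly subsamples subjects, randomly reweights feature columns
#' (the "randomized LASSO": each column is multiplied by an independent
#' weight drawn uniformly from `[weakness, 1]`, which spreads selection
#' across correlated predictors), fits the L1-penalized least-squares path,
#' and records which features enter the model. The per-feature selection
#' frequency across resamples is a robust sparsity pattern; features at or
#' above the frequency threshold form the selected set.
#'
#' Columns and the response are standardized within each resample (never
#' globally), so the procedure can be run inside cross-validation folds
#' without leaking held-out statistics. A column that is constant within a
#' resample is skipped for that resample with a warning.
#'
#' @param X numeric `n x p` feature matrix (subjects in rows).
#' @param y numeric response of length `n`; must be non-constant.
#' @param control a [stability_control()] object.
#' @return a `"stability_selection"` object: `frequencies` (per-feature, in
#'   [0, 1]), `selected` (ascending indices with frequency >= threshold),
#'   and the `control` echo.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 20), 60, 20)
#' y <- 2 * X[, 5] + rnorm(60, sd = 0.1)
#' sel <- stability_selection(X, y, stability_control(B = 50))
#' sel$selected
#' @export
stability_selection <- function(X, y, control = stability_control()) {
  stopifnot(inherits(control, "stability_control"))
  check_matrix(X, "X")
  n <- nrow(X)
  p <- ncol(X)
  if (n < 6) stop("need at least 6 subjects", call. = FALSE)
  if (p < 1) stop("need at least 1 feature", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (stats::sd(y) == 0) stop("'y' is constant", call. = FALSE)
  m <- max(2L, as.integer(floor(control$fraction * n)))
  q <- if (is.null(control$q)) {
    # sqrt-law cap for the sparse regime; a small, already-screened
    # feature set is never capped at all
    if (p <= 12L) p else ceiling(sqrt(0.4 * p))
  } else {
    as.integer(control$q)
  }
  counts <- numeric(p)
  skipped_any <- FALSE
  with_seed(control$seed, {
    for (b in seq_len(control$B)) {
      idx <- if (m >= n) seq_len(n) else sample.int(n, m)
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx] - mean(y[idx])
      mu <- colMeans(Xb)
      sdv <- sqrt(pmax(colMeans(Xb^2) - mu^2, 0) * m / (m - 1))
      keep <- which(sdv > 1e-12)
      if (!length(keep) || stats::sd(yb) == 0) next
      if (length(keep) < p) skipped_any <- TRUE
      Xb <- scale(Xb[, keep, drop = FALSE], center = mu[keep],
                  scale = sdv[keep])
      w <- if (control$weakness >= 1) rep(1, length(keep))
           else stats::runif(length(keep), control$weakness, 1)
      Xb <- Xb * rep(w, each = m)
      sel <- lasso_path_support(Xb, yb, control, q)
      counts[keep[sel]] <- counts[keep[sel]] + 1
    }
  })
  if (skipped_any) {
    warning("one or more zero-variance columns were skipped within ",
            "resamples", call. = FALSE)
  }
  freq <- counts / control$B
  structure(list(frequencies = freq,
                 selected = which(freq >= control$threshold),
                 control = control),
            class = "stability_selection")
}

# support of the L1 path for one standardized resample
lasso_path_support <- function(Xb, yb, control, q = ncol(Xb)) {
  m <- nrow(Xb)
  lam <- control$lambda
  if (is.null(lam)) {
    lam_max <- max(abs(crossprod(Xb, yb))) / m
    if (lam_max <= 0) return(integer())
    lam <- exp(seq(log(lam_max), log(control$lambda_min_ratio * lam_max),
                   length.out = control$n_lambda))
  }
  if (ncol(Xb) == 1L) {
    # closed form: a single standardized column enters at lambda < |x'y|/m
    entry <- abs(crossprod(Xb, yb)) / m
    hit <- if (control$rule == "fixed") {
      k <- which.min(abs(lam - control$fixed_lambda_ratio * lam[1]))
      lam[k] < entry
    } else {
      min(lam) < entry
    }
    return(if (hit) 1L else integer())
  }
  # glmnet warns whenever pmax truncates the path early; that truncation
  # is exactly the intended behaviour of the active-set cap, so those
  # warnings are muffled (anything else propagates)
  fit <- withCallingHandlers(
    glmnet::glmnet(Xb, yb, family = "gaussian", lambda = lam,
                   standardize = FALSE, intercept = FALSE,
                   pmax = max(q, 1L)),
    warning = function(w) {
      if (grepl("pmax|partial path|fewer than", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- fit$beta
  if (control$rule == "fixed") {
    target <- control$fixed_lambda_ratio * lam[1]
    k <- which.min(abs(fit$lambda - target))
    which(beta[, k] != 0)
  } else {
    which(apply(beta != 0, 1, any))
  }
}

#' Threshold a selection result at a given frequency
#'
#' @param result a `"stability_selection"` object.
#' @param threshold frequency threshold pi in (0, 1]; features with
#'   frequency `>= threshold` (inclusive) are kept.
#' @return ascending integer vector of selected feature indices.
#' @export
select_features <- function(result, threshold) {
  stopifnot(inherits(result, "stability_selection"))
  check_scalar(threshold, "threshold", lower = 1e-12, upper = 1)
  sort(which(result$frequencies >= threshold))
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf(paste0("stability selection: %d features, B = %d resamples",
                     " (fraction %.2f, weakness %.2f)\n"),
              length(x$frequencies), x$control$B, x$control$fraction,
              x$control$weakness))
  cat(sprintf("  selected %d feature(s) at threshold %.2f",
              length(x$selected), x$control$threshold))
  if (length(x$selected)) {
    show <- utils::head(x$selected, 10)
    cat(": ", paste(show, collapse = ", "),
        if (length(x$selected) > 10) ", ..." else "", sep = "")
  }
  cat("\n")
  invisible(x)
}
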