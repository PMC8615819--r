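#' Correlation-based evaluation of held-out predictions
#'
#' Prediction accuracy is summarised as the Pearson correlation r between
#' predicted and observed scores, with significance from the exact
#' t-transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Both one-sided (r > 0) and two-sided p values are reported; a
#' constant prediction vector is degenerate and scored r = 0.
#'
#' @param predicted,observed numeric vectors of equal length `n >= 3`;
#'   `observed` must be non-constant.
#' @return list with `r`, `n`, `df`, `t`, `p_one_sided`, `p_two_sided` and
#'   a `degenerate` flag.
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
evaluate_predictions <- function(predicted, observed) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(observed) == 0) stop("'observed' is constant", call. = FALSE)
  degenerate <- stats::sd(predicted) == 0
  r <- if (degenerate) 0 else stats::cor(predicted, observed)
  df <- n - 2L
  t_stat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p1 <- stats::pt(t_stat, df, lower.tail = FALSE)
  p2 <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(r = r, n = n, df = df, t = t_stat,
       p_one_sided = min(max(p1, .Machine$double.xmin), 1),
       p_two_sided = min(max(p2, .Machine$double.xmin), 1),
       degenerate = degenerate)
}

#' Inner-loop leave-one-out hyperparameter tuning
#'
#' For each candidate SVR hyperparameter pair, runs leave-one-out
#' cross-validation within the training subjects (fit on n - 1, predict
#' the one left out) and scores the candidate by the Pearson correlation
#' between inner predictions and inner truths. Constant inner predictions
#' score -1 so a fully regularized model can never win. Ties resolve
#' toward smaller C, then smaller epsilon. Linear regression has no
#' hyperparameters and is returned unchanged.
#'
#' @param X numeric training matrix restricted to the fold's selected
#'   features.
#' @param y training scores.
#' @param kind `"svr"` or `"lr"`.
#' @param grid data.frame of `C`, `epsilon` candidates (see [svr_grid()]).
#' @return the winning [model_spec()], with the per-candidate inner scores
#'   attached as attribute `"scores"`.
#' @export
inner_loocv_tune <- function(X, y, kind = c("svr", "lr"),
                             grid = svr_grid()) {
  kind <- match.arg(kind)
  if (kind == "lr") return(model_spec("lr"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 training subjects", call. = FALSE)
  grid <- grid[order(grid$C, grid$epsilon), , drop = FALSE]
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    spec <- model_spec("svr", C = grid$C[g], epsilon = grid$epsilon[g])
    preds <- vapply(seq_len(n), function(t) {
      fit <- fit_edge_model(X[-t, , drop = FALSE], y[-t], spec)
      predict(fit, X[t, , drop = FALSE])
    }, numeric(1))
    if (stats::sd(preds) == 0) -1 else stats::cor(preds, y)
  }, numeric(1))
  best <- which.max(scores)          # grid pre-sorted: first max wins ties
  out <- model_spec("svr", C = grid$C[best], epsilon = grid$epsilon[best])
  attr(out, "scores") <- data.frame(grid, r = scores)
  out
}

#' Majority vote over per-fold hyperparameter winners
#'
#' Returns the spec chosen by the most folds; ties resolve toward smaller
#' C, then smaller epsilon.
#'
#' @param winners nonempty list of [model_spec()] objects of one kind.
#' @return the winning [model_spec()].
#' @export
majority_vote <- function(winners) {
  if (!length(winners)) stop("empty winner list", call. = FALSE)
  kinds <- vapply(winners, function(s) s$kind, character(1))
  if (length(unique(kinds)) != 1L) {
    stop("cannot vote across model kinds", call. = FALSE)
  }
  if (kinds[1] == "lr") return(model_spec("lr"))
  tab <- data.frame(C = vapply(winners, `[[`, numeric(1), "C"),
                    epsilon = vapply(winners, `[[`, numeric(1), "epsilon"))
  agg <- stats::aggregate(list(votes = rep(1L, nrow(tab))),
                          by = tab, FUN = sum)
  agg <- agg[order(-agg$votes, agg$C, agg$epsilon), , drop = FALSE]
  model_spec("svr", C = agg$C[1], epsilon = agg$epsilon[1])
}

#' Nested leave-one-out cross-validated edge-based prediction
#'
#' The central fit of the package. For each subject i (outer loop):
#' stability selection is run on the remaining N - 1 subjects only — the
#' held-out subject never influences feature selection — and, for SVR, the
#' hyperparameters are tuned by an inner leave-one-out loop over those
#' same N - 1 subjects. Because the per-fold winners are rarely unanimous
#' at clinical sample sizes, a majority vote across folds fixes a single
#' hyperparameter pair, and a second pass refits every fold with its own
#' selected features under the voted spec and predicts its held-out
#' subject. Held-out predictions are then correlated with the observed
#' scores.
#'
#' The vote introduces a mild, documented cross-fold coupling (fold i's
#' spec depends on other folds' inner winners, though never on subject i's
#' own score through its own fold); `hyper = "per-fold"` gives the
#' strictly nested alternative in which each fold keeps its own winner.
#'
#' A fold whose selection comes back empty predicts its training-score
#' mean; this is reported via a message and in the fold records.
#'
#' @param X numeric `N x p` feature matrix (see [feature_pool()]).
#' @param y behavioural scores, length N (`N >= 6`).
#' @param model `"svr"` or `"lr"`.
#' @param control [stability_control()] for the fold-wise selection; each
#'   fold uses a child seed derived from `seed` so folds are independent
#'   but reproducible.
#' @param grid SVR hyperparameter grid.
#' @param seed master seed for the whole cross-validation.
#' @param hyper `"vote"` (majority-voted spec applied to all folds,
#'   default) or `"per-fold"` (strictly nested).
#' @param map optional edge index map carried to downstream reporting.
#' @param subject_ids optional subject identifiers.
#' @return a `"hoconn_cv"` object: per-fold records, held-out `predicted`
#'   vs `observed`, the [evaluate_predictions()] summary, and the voted
#'   spec. Methods: `print`, `summary`, `plot`, `fitted`, `residuals`.
#' @export
nested_loocv <- function(X, y, model = c("svr", "lr"),
                         control = stability_control(), grid = svr_grid(),
                         seed = 1, hyper = c("vote", "per-fold"),
                         map = NULL, subject_ids = NULL) {
  model <- match.arg(model)
  hyper <- match.arg(hyper)
  X <- as.matrix(X)
  check_matrix(X, "X")
  N <- nrow(X)
  if (N < 6) stop("need at least 6 subjects", call. = FALSE)
  if (length(y) != N) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(X)
    if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(N))
  }
  fold_seeds <- derive_seeds(seed, N)

  # pass 1: blind per-fold feature selection + inner hyperparameter tuning
  folds <- vector("list", N)
  for (i in seq_len(N)) {
    ctrl_i <- control
    ctrl_i$seed <- fold_seeds[i]
    sel <- stability_selection(X[-i, , drop = FALSE], y[-i], ctrl_i)
    feats <- sel$selected
    winner <- if (model == "lr") {
      model_spec("lr")
    } else if (length(feats)) {
      inner_loocv_tune(X[-i, feats, drop = FALSE], y[-i], "svr", grid)
    } else {
      NULL
    }
    folds[[i]] <- list(held_out = subject_ids[i], index = i,
                       selected = feats,
                       frequencies_max = max(sel$frequencies),
                       inner_spec = winner)
  }
  winners <- Filter(Negate(is.null), lapply(folds, `[[`, "inner_spec"))
  voted <- if (model == "lr") {
    model_spec("lr")
  } else if (length(winners)) {
    majority_vote(winners)
  } else {
    model_spec("svr", C = grid$C[1], epsilon = grid$epsilon[1])
  }

  # pass 2: refit with each fold's own features under the final spec
  predicted <- numeric(N)
  n_empty <- 0L
  for (i in seq_len(N)) {
    feats <- folds[[i]]$selected
    if (!length(feats)) {
      n_empty <- n_empty + 1L
      predicted[i] <- mean(y[-i])
      folds[[i]]$empty <- TRUE
      folds[[i]]$prediction <- predicted[i]
      next
    }
    spec_i <- if (hyper == "vote" || is.null(folds[[i]]$inner_spec)) voted
              else folds[[i]]$inner_spec
    fit <- fit_edge_model(X[-i, feats, drop = FALSE], y[-i], spec_i,
                          feature_indices = feats)
    predicted[i] <- predict(fit, X[i, feats, drop = FALSE])
    folds[[i]]$empty <- FALSE
    folds[[i]]$prediction <- predicted[i]
    folds[[i]]$model <- fit
  }
  if (n_empty) {
    message(sprintf(paste0("NOTE: %d of %d folds selected no features; ",
                           "those folds predict the training-score mean"),
                    n_empty, N))
  }
  ev <- evaluate_predictions(predicted, y)
  structure(list(folds = folds, predicted = predicted, observed = y,
                 subject_ids = subject_ids, evaluation = ev,
                 voted_spec = voted, model = model, hyper = hyper,
                 control = control, grid = grid, seed = as.integer(seed),
                 map = map, n_features = ncol(X)),
            class = "hoconn_cv")
}

#' @export
print.hoconn_cv <- function(x, ...) {
  ev <- x$evaluation
  cat(sprintf("nested LOOCV (%s, %s hyperparameters): %d subjects, %d features\n",
              toupper(x$model), x$hyper, ev$n, x$n_features))
  cat(sprintf("  held-out r = %.3f (one-sided p = %.2g, two-sided p = %.2g)\n",
              ev$r, ev$p_one_sided, ev$p_two_sided))
  if (x$model == "svr") {
    cat(sprintf("  voted hyperparameters: C = %g, epsilon = %g\n",
                x$voted_spec$C, x$voted_spec$epsilon))
  }
  invisible(x)
}

#' @export
summary.hoconn_cv <- function(object, ...) {
  sizes <- lengths(lapply(object$folds, `[[`, "selected"))
  cons <- consensus_features(object)
  out <- list(evaluation = object$evaluation,
              voted_spec = object$voted_spec,
              fold_feature_counts = sizes,
              n_empty_folds = sum(sizes == 0),
              consensus = cons)
  class(out) <- "summary.hoconn_cv"
  print(object)
  cat(sprintf("  features per fold: median %d [range %d-%d], %d empty fold(s)\n",
              as.integer(stats::median(sizes)), min(sizes), max(sizes),
              out$n_empty_folds))
  cat(sprintf("  consensus features (>= half of folds): %d\n", length(cons)))
  invisible(out)
}

#' @export
fitted.hoconn_cv <- function(object, ...) {
  stats::setNames(object$predicted, object$subject_ids)
}

#' @export
residuals.hoconn_cv <- function(object, ...) {
  stats::setNames(object$observed - object$predicted, object$subject_ids)
}

#' Scatter plot of held-out predictions against observed scores
#'
#' @param x a `"hoconn_cv"` object.
#' @param cutoff optional impairment annotation line on the observed axis
#'   (the tactile-discrimination abnormality criterion 60.25 by default;
#'   set `NULL` to suppress).
#' @param ... passed to [plot()].
#' @export
plot.hoconn_cv <- function(x, cutoff = 60.25, ...) {
  plot(x$observed, x$predicted,
       xlab = "observed score", ylab = "predicted score (held out)",
       main = sprintf("%s: r = %.2f", toupper(x$model), x$evaluation$r),
       pch = 19, ...)
  graphics::abline(stats::lm(x$predicted ~ x$observed), lty = 2)
  if (!is.null(cutoff)) graphics::abline(v = cutoff, col = "grey60",
                                         lty = 3)
  invisible(x)
}
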