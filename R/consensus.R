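#' Consensus features across cross-validation folds
#'
#' Fold-wise selections are rarely identical; the consensus set keeps the
#' features selected in at least half of the folds (inclusive: with 40
#' folds a feature present in exactly 20 is kept), or any other fraction
#' via `min_fraction`.
#'
#' @param x a `"hoconn_cv"` object, or a plain list of per-fold feature
#'   index vectors.
#' @param min_fraction minimum fraction of folds, default 0.5; a feature
#'   must appear in `>= ceiling(min_fraction * n_folds)` folds.
#' @return ascending integer vector of consensus feature indices.
#' @export
consensus_features <- function(x, min_fraction = 0.5) {
  sels <- if (inherits(x, "hoconn_cv")) {
    lapply(x$folds, `[[`, "selected")
  } else {
    x
  }
  if (!length(sels)) stop("need at least one fold", call. = FALSE)
  check_scalar(min_fraction, "min_fraction", lower = 1e-9, upper = 1)
  need <- ceiling(min_fraction * length(sels))
  counts <- table(unlist(sels))
  sort(as.integer(names(counts)[counts >= need]))
}

#' Build the final full-data model from a cross-validation run
#'
#' Implements the consensus protocol: (1) take the features selected in at
#' least half of the outer folds; (2) re-run randomized-LASSO stability
#' selection on *all* subjects restricted to those consensus columns;
#' (3) fit the majority-voted model spec on all subjects over the
#' surviving features. The result is the model intended for prospective
#' prediction, with its network edges named through the atlas table.
#'
#' @param X the full `N x p` feature matrix the cross-validation was run
#'   on.
#' @param y all N behavioural scores.
#' @param cv the `"hoconn_cv"` object from [nested_loocv()].
#' @param min_fraction consensus fraction (see [consensus_features()]).
#' @param control stability control for the re-selection; defaults to the
#'   cross-validation's own control with a fresh child seed (derived from
#'   the CV master seed one position past the fold seeds).
#' @param spec model spec for the final fit; defaults to the voted spec.
#' @param map edge index map (defaults to the one stored in `cv`).
#' @param labels atlas label table (see [read_atlas_labels()]); defaults
#'   to the 90-region AAL table when the map spans 90 regions, else plain
#'   region numbers.
#' @return a `"hoconn_model"`: `consensus` and `final_features` index
#'   vectors (`final_features` is a subset of `consensus`), the fitted
#'   `"edge_model"`, the named `edges` table, and the re-selection
#'   frequencies.
#' @export
finalize_model <- function(X, y, cv, min_fraction = 0.5, control = NULL,
                           spec = NULL, map = NULL, labels = NULL) {
  stopifnot(inherits(cv, "hoconn_cv"))
  X <- as.matrix(X)
  consensus <- consensus_features(cv, min_fraction)
  if (!length(consensus)) {
    stop("empty consensus feature set; relax the selection threshold or ",
         "the consensus fraction", call. = FALSE)
  }
  if (is.null(control)) {
    control <- cv$control
    n_folds <- length(cv$folds)
    control$seed <- derive_seeds(cv$seed, n_folds + 1L)[n_folds + 1L]
  }
  if (is.null(spec)) spec <- cv$voted_spec
  if (is.null(map)) map <- cv$map
  resel <- stability_selection(X[, consensus, drop = FALSE], y, control)
  final <- consensus[resel$selected]
  if (!length(final)) {
    warning("re-selection on all subjects kept no consensus feature; ",
            "fitting the full consensus set", call. = FALSE)
    final <- consensus
  }
  fit <- fit_edge_model(X[, final, drop = FALSE], y, spec,
                        feature_indices = final)
  edges <- if (is.null(map)) NULL else name_edges(final, map, labels)
  freqs <- stats::setNames(resel$frequencies, consensus)
  structure(list(consensus = consensus, final_features = final,
                 model = fit, edges = edges, spec = spec,
                 reselection_frequencies = freqs, map = map,
                 n_subjects = nrow(X), n_features = ncol(X)),
            class = "hoconn_model")
}

#' @export
print.hoconn_model <- function(x, ...) {
  cat(sprintf(paste0("final consensus model (%s): %d consensus -> %d final",
                     " feature(s), %d subjects\n"),
              if (x$spec$kind == "lr") "LR" else
                sprintf("SVR, C = %g, epsilon = %g", x$spec$C,
                        x$spec$epsilon),
              length(x$consensus), length(x$final_features), x$n_subjects))
  if (!is.null(x$edges)) {
    cat(sprintf("  edges: %d (%s)\n", nrow(x$edges),
                paste(sprintf("%s %d", names(table(x$edges$category)),
                              as.integer(table(x$edges$category))),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Predict scores for new subjects from the final model
#'
#' @param object a `"hoconn_model"`.
#' @param newdata feature matrix with the same `p` columns as the training
#'   pool (the model extracts its own final feature columns), or exactly
#'   the final feature columns.
#' @param ... unused.
#' @export
predict.hoconn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  k <- length(object$final_features)
  if (ncol(newdata) == object$n_features) {
    newdata <- newdata[, object$final_features, drop = FALSE]
  } else if (ncol(newdata) != k) {
    stop(sprintf("newdata must have %d (full pool) or %d (final features) columns",
                 object$n_features, k), call. = FALSE)
  }
  predict(object$model, newdata)
}

#' @export
coef.hoconn_model <- function(object, ...) {
  coef(object$model)
}

#' Name selected edge features through the atlas
#'
#' Maps feature indices through the edge index map to region pairs, merges
#' the low- and high-order occurrences of the same pair, and classifies
#' each edge as selected from the low-order pool only, the high-order pool
#' only, or both.
#'
#' @param feature_indices integer indices into the feature pool.
#' @param map edge index map (the `map` element of [feature_pool()]).
#' @param labels atlas label table with columns `name` and `abbreviation`
#'   (one row per region), a character vector of region names, or `NULL`
#'   for plain `R001`-style labels.
#' @return data.frame with one row per distinct region pair, ordered by
#'   (i, j): indices, region names, abbreviations, `category`
#'   (`"lofc-only"`, `"hofc-only"`, `"both"`).
#' @export
name_edges <- function(feature_indices, map, labels = NULL) {
  if (!length(feature_indices)) {
    return(data.frame(i = integer(), j = integer(),
                      region_a = character(), region_b = character(),
                      abbrev_a = character(), abbrev_b = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  if (any(feature_indices < 1) || any(feature_indices > nrow(map))) {
    stop("feature index out of range of the index map", call. = FALSE)
  }
  R <- max(map$j)
  if (is.null(labels)) {
    nm <- sprintf("R%03d", seq_len(R))
    ab <- nm
  } else if (is.data.frame(labels)) {
    if (nrow(labels) != R) {
      stop(sprintf("atlas table has %d rows but the map spans %d regions",
                   nrow(labels), R), call. = FALSE)
    }
    nm <- as.character(labels$name)
    ab <- as.character(if (!is.null(labels$abbreviation)) labels$abbreviation
                       else labels$name)
  } else {
    if (length(labels) != R) {
      stop(sprintf("%d labels supplied but the map spans %d regions",
                   length(labels), R), call. = FALSE)
    }
    nm <- as.character(labels)
    ab <- nm
  }
  hits <- map[feature_indices, , drop = FALSE]
  key <- paste(hits$i, hits$j, sep = "-")
  cat_of <- vapply(split(hits$pool, key), function(pools) {
    pools <- unique(pools)
    if (all(c("lofc", "hofc") %in% pools)) "both"
    else if (pools == "lofc") "lofc-only"
    else "hofc-only"
  }, character(1))
  uniq <- hits[!duplicated(key), c("i", "j")]
  uniq$category <- cat_of[paste(uniq$i, uniq$j, sep = "-")]
  uniq <- uniq[order(uniq$i, uniq$j), , drop = FALSE]
  data.frame(i = uniq$i, j = uniq$j,
             region_a = nm[uniq$i], region_b = nm[uniq$j],
             abbrev_a = ab[uniq$i], abbrev_b = ab[uniq$j],
             category = uniq$category, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' The 90-region AAL atlas label table
#'
#' Standard Automated Anatomical Labelling parcellation with the
#' cerebellum excluded: 45 left/right pairs of cerebral regions, in the
#' conventional AAL ordering, with the usual short abbreviations.
#'
#' @return data.frame with columns `index`, `name`, `abbreviation`
#'   (90 rows).
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "hoconn",
                      mustWork = TRUE)
  read_atlas_labels(path, n_regions = 90)
}
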