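#' Connectivity matrix objects
#'
#' A connectome is a symmetric R x R matrix of edge weights over a brain
#' parcellation, with unit diagonal and off-diagonal values in [-1, 1].
#' `as_connectome()` validates a plain matrix and tags it with its kind:
#' `"lofc"` for conventional (low-order) functional connectivity, i.e. the
#' Pearson correlation between regional time courses, or `"hofc"` for
#' high-order functional connectivity, the correlation between two regions'
#' whole-brain connectivity profiles.
#'
#' @param values numeric R x R matrix.
#' @param kind `"lofc"` or `"hofc"`.
#' @param labels optional character vector of region labels (length R).
#' @return a `"connectome"` object: the matrix with `kind` and region labels
#'   attached.
#' @export
as_connectome <- function(values, kind = c("lofc", "hofc"), labels = NULL) {
  kind <- match.arg(kind)
  check_matrix(values, "values")
  R <- nrow(values)
  if (ncol(values) != R) {
    stop("connectivity matrix must be square", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop("connectivity matrix must be symmetric (tolerance 1e-12)",
         call. = FALSE)
  }
  if (any(diag(values) != 1)) {
    stop("connectivity matrix must have unit diagonal", call. = FALSE)
  }
  off <- values[upper.tri(values)]
  if (length(off) && (min(off) < -1 || max(off) > 1)) {
    stop("off-diagonal connectivity values must lie in [-1, 1]",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(values))) rownames(values)
              else sprintf("R%03d", seq_len(R))
  }
  if (length(labels) != R) {
    stop("'labels' must have one entry per region", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("connectome", "matrix", "array"))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("%s connectome: %d regions\n", toupper(attr(x, "kind")),
              nrow(x)))
  off <- x[upper.tri(x)]
  cat(sprintf("  edges: %d | mean %.3f | range [%.3f, %.3f]\n",
              length(off), mean(off), min(off), max(off)))
  invisible(x)
}

#' Low-order functional connectivity from region time series
#'
#' Computes the conventional functional connectome: entry (i, j) is the
#' Pearson correlation between the time courses of regions i and j.
#'
#' @param ts numeric T x R matrix, one column per region (T time points).
#' @param labels optional region labels.
#' @param on_constant what to do with a zero-variance region: `"error"`
#'   (default; names the offending region) or `"zero"` (set that region's
#'   edges to 0 with a warning).
#' @return an `"lofc"` [as_connectome()] object.
#' @examples
#' ts <- matrix(rnorm(140 * 5), 140, 5)
#' lofc(ts)
#' @export
lofc <- function(ts, labels = NULL, on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  check_matrix(ts, "ts")
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  if (ncol(ts) < 2) stop("need at least 2 regions", call. = FALSE)
  if (is.null(labels) && !is.null(colnames(ts))) labels <- colnames(ts)
  sds <- apply(ts, 2, stats::sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    who <- if (is.null(labels)) paste(flat, collapse = ", ")
           else paste(labels[flat], collapse = ", ")
    if (on_constant == "error") {
      stop("constant time course for region(s): ", who, call. = FALSE)
    }
    warning("constant time course for region(s): ", who,
            "; their edges set to 0", call. = FALSE)
  }
  C <- suppressWarnings(stats::cor(ts))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  as_connectome(C, "lofc", labels)
}

#' High-order functional connectivity ("correlation of the correlation")
#'
#' Entry (i, j) of the high-order connectome is the Pearson correlation
#' between region i's and region j's low-order connectivity profiles, i.e.
#' rows i and j of the LOFC matrix. Under the default `"exclude-pair"`
#' convention the entries at positions i and j are removed from both
#' profiles before correlating (profile length R - 2), so an edge's own
#' value and the unit self-correlations never enter its high-order score.
#' `"full"` correlates complete rows, diagonal included.
#'
#' The computation is fully vectorized via row sums and the Gram matrix of
#' the LOFC, and agrees with a direct slice-and-correlate evaluation to
#' machine precision.
#'
#' @param x an `"lofc"` connectome (or a valid symmetric unit-diagonal
#'   matrix, validated on the way in).
#' @param profile `"exclude-pair"` (default) or `"full"`.
#' @param on_degenerate zero-variance residual profile handling: `"error"`
#'   (default, names the pair) or `"zero"` (entry set to 0 with a warning).
#' @return an `"hofc"` [as_connectome()] object.
#' @export
hofc <- function(x, profile = c("exclude-pair", "full"),
                 on_degenerate = c("error", "zero")) {
  profile <- match.arg(profile)
  on_degenerate <- match.arg(on_degenerate)
  if (inherits(x, "connectome")) {
    if (attr(x, "kind") != "lofc") {
      stop("high-order connectivity is computed from an LOFC connectome",
           call. = FALSE)
    }
    labels <- rownames(x)
    L <- unclass(x)
    attr(L, "kind") <- NULL
  } else {
    xc <- as_connectome(as.matrix(x), "lofc")
    labels <- rownames(xc)
    L <- unclass(xc)
    attr(L, "kind") <- NULL
  }
  R <- nrow(L)
  if (profile == "exclude-pair" && R < 4) {
    stop("exclude-pair high-order connectivity needs at least 4 regions ",
         "(residual profile length R - 2 must be >= 2)", call. = FALSE)
  }
  if (profile == "full") {
    H <- suppressWarnings(stats::cor(t(L)))
    bad <- which(!is.finite(H) & upper.tri(H), arr.ind = TRUE)
    H[!is.finite(H)] <- 0
  } else {
    m <- R - 2
    S <- rowSums(L)
    d <- diag(L)
    G <- L %*% L                       # Gram matrix (L symmetric)
    SA <- matrix(S - d, R, R) - L      # sum of row i's profile excl. {i,j}
    SB <- t(SA)
    CAB <- G - L * matrix(d, R, R) - t(L * matrix(d, R, R))
    SAA <- matrix(diag(G) - d^2, R, R) - L^2
    SBB <- t(SAA)
    num <- CAB - SA * SB / m
    va <- pmax(SAA - SA^2 / m, 0)
    vb <- pmax(SBB - SB^2 / m, 0)
    tol <- 1e-12 * m
    degen <- (va < tol | vb < tol)
    diag(degen) <- FALSE
    den <- sqrt(va * vb)
    den[degen] <- 1
    H <- num / den
    H[degen] <- NA_real_
    bad <- which(degen & upper.tri(degen), arr.ind = TRUE)
    H[degen] <- 0
  }
  if (length(bad)) {
    pairs <- paste(sprintf("(%s, %s)", labels[bad[, 1]], labels[bad[, 2]]),
                   collapse = ", ")
    if (on_degenerate == "error") {
      stop("zero-variance connectivity profile for region pair(s): ", pairs,
           call. = FALSE)
    }
    warning("zero-variance connectivity profile for region pair(s): ", pairs,
            "; entries set to 0", call. = FALSE)
  }
  H <- (H + t(H)) / 2
  H <- pmin(pmax(H, -1), 1)
  diag(H) <- 1
  as_connectome(H, "hofc", labels)
}

#' Edge index map for vectorized connectomes
#'
#' Row-major upper-triangle ordering: edges are listed as (1,2), (1,3),
#' ..., (1,R), (2,3), ..., (R-1,R). This ordering is fixed so feature
#' indices are stable across runs and pools.
#'
#' @param n_regions number of regions R.
#' @param pool pool tag recorded per edge (e.g. `"lofc"`).
#' @return data.frame with columns `pool`, `i`, `j` and `R * (R - 1) / 2`
#'   rows.
#' @export
edge_index_map <- function(n_regions, pool = "lofc") {
  R <- as.integer(n_regions)
  if (R < 2) stop("need at least 2 regions", call. = FALSE)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(k) (k + 1L):R))
  data.frame(pool = pool, i = i, j = j, stringsAsFactors = FALSE)
}

#' Vectorize a connectome into its upper-triangle edge values
#'
#' @param x a connectome (or square symmetric matrix).
#' @return numeric vector of length `R * (R - 1) / 2` in the row-major
#'   order of [edge_index_map()].
#' @seealso [edge_matrix()] for the exact inverse.
#' @export
edge_vector <- function(x) {
  x <- as.matrix(x)
  map <- edge_index_map(nrow(x))
  x[cbind(map$i, map$j)]
}

#' Rebuild a connectome matrix from an edge vector
#'
#' Exact inverse of [edge_vector()]: the round trip reproduces the matrix
#' bit-identically.
#'
#' @param values numeric edge vector, length `R * (R - 1) / 2`.
#' @param n_regions R.
#' @param kind,labels passed to [as_connectome()]; `kind = NULL` returns a
#'   bare matrix without validation against the connectome invariants.
#' @return a connectome (or plain matrix if `kind` is `NULL`).
#' @export
edge_matrix <- function(values, n_regions, kind = "lofc", labels = NULL) {
  R <- as.integer(n_regions)
  if (length(values) != R * (R - 1L) / 2L) {
    stop(sprintf("expected %d edge values for %d regions, got %d",
                 R * (R - 1L) / 2L, R, length(values)), call. = FALSE)
  }
  map <- edge_index_map(R)
  M <- diag(1, R)
  M[cbind(map$i, map$j)] <- values
  M[cbind(map$j, map$i)] <- values
  if (is.null(kind)) return(M)
  as_connectome(M, kind, labels)
}

#' Assemble a subjects-by-edges feature matrix from per-subject connectomes
#'
#' Builds the feature pool fed to feature selection and regression: each
#' subject's connectome(s) are vectorized and stacked into an
#' `n_subjects x n_features` matrix. The `"lofc"` pool has
#' `R * (R - 1) / 2` columns; the `"lofc+hofc"` pool concatenates the
#' low-order block first and the high-order block second, doubling the
#' width (8010 columns for the 90-region parcellation).
#'
#' @param lofc_list list of low-order connectomes, one per subject.
#' @param hofc_list list of high-order connectomes (required for the
#'   combined pool); computed with [hofc()] from `lofc_list` when `NULL`
#'   and the combined pool is requested.
#' @param pool `"lofc"` or `"lofc+hofc"`.
#' @return list with `X` (feature matrix, rows named by subject if the
#'   input list is named) and `map` (edge index map with a `pool` column).
#' @export
feature_pool <- function(lofc_list, hofc_list = NULL,
                         pool = c("lofc", "lofc+hofc")) {
  pool <- match.arg(pool)
  if (!length(lofc_list)) stop("empty subject list", call. = FALSE)
  Rs <- vapply(lofc_list, function(m) nrow(as.matrix(m)), integer(1))
  if (length(unique(Rs)) != 1L) {
    stop("all subjects must share the same region count", call. = FALSE)
  }
  R <- Rs[[1]]
  Xl <- do.call(rbind, lapply(lofc_list, edge_vector))
  rownames(Xl) <- names(lofc_list)
  map <- edge_index_map(R, "lofc")
  if (pool == "lofc") {
    return(list(X = Xl, map = map))
  }
  if (is.null(hofc_list)) {
    hofc_list <- lapply(lofc_list, hofc)
  }
  if (length(hofc_list) != length(lofc_list)) {
    stop("subject count mismatch between low- and high-order pools",
         call. = FALSE)
  }
  if (any(vapply(hofc_list, function(m) nrow(as.matrix(m)),
                 integer(1)) != R)) {
    stop("region count mismatch between low- and high-order pools",
         call. = FALSE)
  }
  Xh <- do.call(rbind, lapply(hofc_list, edge_vector))
  list(X = cbind(Xl, Xh),
       map = rbind(map, edge_index_map(R, "hofc")))
}
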