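#' Read a region-wise time-series matrix
#'
#' Time series are stored as header-free tab-delimited text, one row per
#' time point and one column per region.
#'
#' @param path file path.
#' @param n_regions optional expected region count; mismatch is an error
#'   naming the file.
#' @return numeric T x R matrix.
#' @export
read_timeseries <- function(path, n_regions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  widths <- unique(utils::count.fields(path, sep = "\t"))
  if (length(widths) != 1L) {
    stop("ragged rows in time-series file: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "numeric")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (anyNA(m)) stop("non-numeric or missing cells in: ", path,
                     call. = FALSE)
  if (!is.null(n_regions) && ncol(m) != n_regions) {
    stop(sprintf("%s has %d region columns, expected %d", path, ncol(m),
                 n_regions), call. = FALSE)
  }
  m
}

#' @rdname read_timeseries
#' @param ts numeric matrix to write.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as.matrix(ts)
  check_matrix(ts, "ts")
  # 17 significant digits so the text round trip is bit-identical
  fmt <- matrix(sprintf("%.17g", ts), nrow(ts))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `path` (time-series file,
#' relative paths resolved against the manifest's directory) and `score`
#' (behavioural score on the 0-100 scale; out-of-range values are retained
#' with a warning).
#'
#' @param path manifest CSV path.
#' @param check_paths verify every time-series file exists (default TRUE).
#' @return data.frame with resolved paths.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "score")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject ids in manifest", call. = FALSE)
  }
  df$score <- as.numeric(df$score)
  if (anyNA(df$score)) stop("non-numeric scores in manifest", call. = FALSE)
  if (any(df$score < 0 | df$score > 100)) {
    warning("manifest scores outside [0, 100]; values retained",
            call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  if (check_paths && !all(file.exists(abs))) {
    stop("missing time-series file(s): ",
         paste(df$subject_id[!file.exists(abs)], collapse = ", "),
         call. = FALSE)
  }
  df$path <- abs
  df
}

#' Read an atlas label table
#'
#' Tab-delimited with a header; must contain a `name` column, and
#' optionally `index` and `abbreviation`.
#'
#' @param path label-table path.
#' @param n_regions optional expected region count; mismatch is an error.
#' @return data.frame with columns `index`, `name`, `abbreviation`.
#' @export
read_atlas_labels <- function(path, n_regions = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) {
    stop("atlas table must have a 'name' column", call. = FALSE)
  }
  if (is.null(df$index)) df$index <- seq_len(nrow(df))
  if (is.null(df$abbreviation)) df$abbreviation <- df$name
  if (!is.null(n_regions) && nrow(df) != n_regions) {
    stop(sprintf("atlas table has %d rows, expected %d regions",
                 nrow(df), n_regions), call. = FALSE)
  }
  df[, c("index", "name", "abbreviation")]
}

#' Write a synthetic cohort to disk
#'
#' Writes one header-free TSV per subject, a manifest CSV
#' (`subject_id, path, score`), and a ground-truth JSON sidecar (planted
#' edges, weights, noise, score map, master seed) so a run can be
#' reproduced from its artifacts alone.
#'
#' @param cohort a time-series `"synthetic_cohort"` (from
#'   [simulate_cohort()]).
#' @param dir output directory, created if needed.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$subjects)) {
    stop("connectome-level cohorts have no time series to write; ",
         "use simulate_cohort()", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$subjects)
  files <- file.path(dir, paste0(ids, ".tsv"))
  for (s in seq_along(ids)) write_timeseries(cohort$subjects[[s]], files[s])
  manifest <- data.frame(subject_id = ids, path = paste0(ids, ".tsv"),
                         score = cohort$scores)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(n_regions = truth$n_regions, planted = truth$planted,
         weights = truth$weights, noise_sd = cohort$noise_sd,
         deviation_range = truth$deviation_range,
         score_offset = truth$score_offset,
         score_scale = truth$score_scale, truth_seed = truth$seed,
         master_seed = cohort$master_seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path path to a manifest CSV (see [read_manifest()]).
#' @param n_regions optional expected region count for every subject.
#' @return list with `subjects` (named list of T x R matrices), `scores`
#'   and `ids`.
#' @export
load_cohort <- function(manifest_path, n_regions = NULL) {
  mf <- read_manifest(manifest_path)
  subjects <- lapply(seq_len(nrow(mf)), function(s) {
    tryCatch(read_timeseries(mf$path[s], n_regions = n_regions),
             error = function(e) {
               stop(sprintf("subject %s: %s", mf$subject_id[s],
                            conditionMessage(e)), call. = FALSE)
             })
  })
  names(subjects) <- mf$subject_id
  list(subjects = subjects, scores = mf$score, ids = mf$subject_id)
}

#' Write / read a connectome as headered TSV
#'
#' First line is a comment carrying the kind (`# kind=lofc`), then a
#' header of region labels and the full matrix.
#'
#' @param x a connectome.
#' @param path file path.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", attr(x, "kind")), con)
  utils::write.table(as.data.frame(unclass(x)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^# kind=", "", first)
  if (!kind %in% c("lofc", "hofc")) {
    stop("missing or invalid kind header in: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE)
  M <- as.matrix(df)
  rownames(M) <- colnames(M)
  as_connectome(M, kind, colnames(M))
}

#' Write a cross-validation result
#'
#' Emits a JSON summary (r, both p values, voted spec, per-fold selected
#' features, config echo, seed) and a scatter-ready TSV of
#' `(subject_id, observed, predicted)`.
#'
#' @param cv a `"hoconn_cv"`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @export
write_cv_result <- function(cv, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(cv, "hoconn_cv"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(model = cv$model, hyper = cv$hyper,
           r = cv$evaluation$r, n = cv$evaluation$n,
           p_one_sided = cv$evaluation$p_one_sided,
           p_two_sided = cv$evaluation$p_two_sided,
           voted_spec = unclass(cv$voted_spec),
           seed = cv$seed,
           control = unclass(cv$control),
           folds = lapply(cv$folds, function(f) {
             list(held_out = f$held_out, selected = f$selected,
                  prediction = f$prediction, empty = f$empty)
           })),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(subject_id = cv$subject_ids, observed = cv$observed,
                 predicted = cv$predicted),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cv)
}

#' Model-by-pool accuracy summary table
#'
#' Assembles the standard four-row comparison (feature pool x regression
#' method) from named cross-validation results, with the correlation
#' between predicted and observed scores and its one- and two-sided p
#' values.
#'
#' @param results named list of `"hoconn_cv"` objects; names like
#'   `"lofc/svr"` are split on `/` into pool and model columns, otherwise
#'   the stored model kind is used.
#' @return data.frame with columns `pool`, `model`, `n`, `r`,
#'   `p_one_sided`, `p_two_sided`.
#' @export
cv_summary_table <- function(results) {
  stopifnot(length(results) > 0)
  rows <- lapply(names(results), function(nm) {
    cv <- results[[nm]]
    stopifnot(inherits(cv, "hoconn_cv"))
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    data.frame(pool = parts[1],
               model = if (length(parts) > 1) parts[2] else cv$model,
               n = cv$evaluation$n, r = cv$evaluation$r,
               p_one_sided = cv$evaluation$p_one_sided,
               p_two_sided = cv$evaluation$p_two_sided)
  })
  do.call(rbind, rows)
}

#' Flag impaired tactile discrimination
#'
#' Annotation only (never used in modelling): scores at or below the
#' normative abnormality criterion of 60.25 AUC indicate impaired tactile
#' discrimination.
#'
#' @param scores numeric scores on the 0-100 scale.
#' @param cutoff abnormality criterion, default 60.25.
#' @return logical vector, `TRUE` = impaired.
#' @export
impairment_flag <- function(scores, cutoff = 60.25) {
  scores <= cutoff
}
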