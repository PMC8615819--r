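#' Ground truth for a synthetic connectome cohort
#'
#' Defines the generative truth a synthetic cohort is built from: a
#' positive-definite base correlation structure shared by all subjects, a
#' sparse set of planted predictive edges, the linear weights tying those
#' edges to the behavioural score, and the affine map onto the 0-100 score
#' scale.
#'
#' The default base correlation is a 5-factor model `C = LL' + psi * I`
#' rescaled to unit diagonal, which gives the blocky community structure
#' typical of resting-state connectomes while guaranteeing positive
#' definiteness. Planted edges live in one of two pools: `"lofc"` edges
#' carry signal directly through a subject-specific deviation of the
#' correlation entry itself; `"hofc"` edges carry signal through the
#' high-order connectome. Because the exclude-pair profile convention
#' removes entries i and j from both profiles, perturbing entry (i, j)
#' alone cannot move the high-order value at (i, j); instead each planted
#' high-order edge is assigned a fixed random set of `hofc_shift_size`
#' off-pair entries in row i whose joint deviation shifts region i's
#' connectivity profile and hence its profile correlation with region j.
#'
#' The default score map (offset 22.6, scale 23.2, clipped to [0, 100])
#' mirrors the affected-hand tactile-discrimination distribution of a
#' chronic stroke cohort, including its floor effect.
#'
#' @param n_regions number of parcellation regions R.
#' @param planted data.frame with columns `i`, `j` (1-based region indices,
#'   `i < j`) and `pool` (`"lofc"` or `"hofc"`); may have zero rows.
#' @param weights numeric, one per planted edge (score units per unit of
#'   edge value).
#' @param noise_sd standard deviation of the additive Gaussian score noise,
#'   in latent-score units; may be overridden at generation time via
#'   `target_r2`.
#' @param base_correlation optional R x R correlation matrix (symmetric,
#'   unit diagonal, positive definite). Generated from the factor model
#'   when `NULL`.
#' @param n_factors number of latent factors for the default base model.
#' @param deviation_range half-width of the uniform subject deviation
#'   applied at planted edges.
#' @param subject_loading_sd standard deviation of the subject-specific
#'   perturbation of the factor loadings. This is what gives non-planted
#'   edges realistic between-subject variability (a generator without it
#'   emits constant null features, which no resting-state cohort does);
#'   because each subject's matrix is rebuilt from its own loadings it
#'   stays positive definite by construction, and the variability is
#'   low-rank, as empirical functional-connectivity variability is. Only
#'   used when the base correlation comes from the internal factor model.
#' @param edge_jitter_sd standard deviation of entry-wise background
#'   jitter, used instead of loading jitter when a custom
#'   `base_correlation` is supplied (followed by a positive-definite
#'   projection).
#' @param hofc_shift_size number of row entries perturbed per planted
#'   high-order edge.
#' @param hofc_entry_noise_sd independent noise added to each perturbed
#'   entry of a planted high-order edge. The common deviation plus
#'   entry-level noise means no single low-order edge is a clean proxy for
#'   the high-order signal — the profile correlation averages the noise
#'   out — which is what makes high-order features genuinely informative
#'   beyond the low-order pool.
#' @param score_offset,score_scale affine map from latent score to the
#'   behavioural scale.
#' @param seed seed for the base-correlation draw and the high-order shift
#'   sets (not for subjects; see [simulate_cohort()]).
#' @return a `"ground_truth"` object.
#' @export
ground_truth <- function(n_regions,
                         planted = data.frame(i = integer(), j = integer(),
                                              pool = character()),
                         weights = numeric(),
                         noise_sd = 0,
                         base_correlation = NULL,
                         n_factors = 5,
                         deviation_range = 0.3,
                         subject_loading_sd = 0.15,
                         edge_jitter_sd = 0.05,
                         hofc_shift_size = 8,
                         hofc_entry_noise_sd = 0.15,
                         score_offset = 22.6,
                         score_scale = 23.2,
                         seed = 1) {
  R <- as.integer(n_regions)
  if (R < 3) stop("need at least 3 regions", call. = FALSE)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    stopifnot(all(c("i", "j", "pool") %in% names(planted)))
    planted$i <- as.integer(planted$i)
    planted$j <- as.integer(planted$j)
    planted$pool <- as.character(planted$pool)
    if (any(planted$i >= planted$j)) {
      stop("planted edges must have i < j", call. = FALSE)
    }
    if (any(planted$j > R) || any(planted$i < 1)) {
      stop("planted edge indices exceed the region count", call. = FALSE)
    }
    if (!all(planted$pool %in% c("lofc", "hofc"))) {
      stop("planted edge pool must be 'lofc' or 'hofc'", call. = FALSE)
    }
    key <- paste(planted$pool, planted$i, planted$j)
    if (anyDuplicated(key)) {
      stop("planted edges must be distinct region pairs within a pool",
           call. = FALSE)
    }
  }
  if (length(weights) != nrow(planted)) {
    stop("'weights' must have one value per planted edge", call. = FALSE)
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  loadings <- NULL
  psi <- 2 * n_factors
  if (is.null(base_correlation)) {
    loadings <- with_seed(seed, matrix(stats::rnorm(R * n_factors), R,
                                       n_factors))
    base_correlation <- stats::cov2cor(tcrossprod(loadings) + diag(psi, R))
  }
  check_matrix(base_correlation, "base_correlation")
  if (nrow(base_correlation) != R || ncol(base_correlation) != R) {
    stop("base_correlation dimension does not match n_regions",
         call. = FALSE)
  }
  if (max(abs(base_correlation - t(base_correlation))) > 1e-10 ||
      any(abs(diag(base_correlation) - 1) > 1e-10)) {
    stop("base_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(base_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("base_correlation must be positive definite", call. = FALSE)
  }
  hofc_shift <- list()
  hofc_signs <- list()
  if (any(planted$pool == "hofc")) {
    hofc_shift <- with_seed(seed + 1L, {
      lapply(seq_len(nrow(planted)), function(k) {
        if (planted$pool[k] != "hofc") return(integer())
        pool_k <- setdiff(seq_len(R), c(planted$i[k], planted$j[k]))
        sort(sample(pool_k, min(hofc_shift_size, length(pool_k))))
      })
    })
    hofc_signs <- with_seed(seed + 2L, {
      lapply(hofc_shift, function(ks) sample(c(-1, 1), length(ks),
                                             replace = TRUE))
    })
  }
  check_scalar(edge_jitter_sd, "edge_jitter_sd", lower = 0)
  check_scalar(subject_loading_sd, "subject_loading_sd", lower = 0)
  structure(list(n_regions = R, planted = planted, weights = weights,
                 noise_sd = noise_sd, base_correlation = base_correlation,
                 loadings = loadings, psi = psi,
                 deviation_range = deviation_range,
                 subject_loading_sd = subject_loading_sd,
                 edge_jitter_sd = edge_jitter_sd,
                 hofc_shift = hofc_shift, hofc_signs = hofc_signs,
                 hofc_entry_noise_sd = hofc_entry_noise_sd,
                 score_offset = score_offset, score_scale = score_scale,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d regions, %d planted edge(s)\n",
              x$n_regions, nrow(x$planted)))
  if (nrow(x$planted)) {
    cat(sprintf("  pools: %s | noise_sd %.3g | score map %.1f + %.1f * latent\n",
                paste(sort(unique(x$planted$pool)), collapse = "+"),
                x$noise_sd, x$score_offset, x$score_scale))
  }
  invisible(x)
}

# nearest correlation matrix by eigenvalue clipping + unit-diagonal rescale
nearest_correlation <- function(M, floor = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  C <- e$vectors %*% (vals * t(e$vectors))
  C <- stats::cov2cor(C)
  (C + t(C)) / 2
}

# one subject's target correlation matrix + realized planted-edge values
subject_target <- function(truth, seed) {
  R <- truth$n_regions
  P <- truth$planted
  with_seed(seed, {
    # background between-subject variability
    perturbed <- FALSE
    if (!is.null(truth$loadings) && truth$subject_loading_sd > 0) {
      Ls <- truth$loadings +
        matrix(stats::rnorm(length(truth$loadings), 0,
                            truth$subject_loading_sd),
               nrow(truth$loadings))
      C <- stats::cov2cor(tcrossprod(Ls) + diag(truth$psi, R))
    } else {
      C <- truth$base_correlation
      if (truth$edge_jitter_sd > 0) {
        E <- matrix(0, R, R)
        ut <- upper.tri(E)
        E[ut] <- stats::rnorm(sum(ut), 0, truth$edge_jitter_sd)
        E <- E + t(E)
        C <- pmin(pmax(C + E, -0.99), 0.99)
        diag(C) <- 1
        perturbed <- TRUE
      }
    }
    if (nrow(P)) {
      delta <- stats::runif(nrow(P), -truth$deviation_range,
                            truth$deviation_range)
      # sparse symmetric deviation; if it breaks positive definiteness the
      # whole deviation is shrunk (not projected: eigenvalue clipping
      # would smear the planted sparse signal across every edge)
      D <- matrix(0, R, R)
      for (k in seq_len(nrow(P))) {
        if (P$pool[k] == "lofc") {
          D[P$i[k], P$j[k]] <- D[P$j[k], P$i[k]] <- delta[k]
        } else {
          ks <- truth$hofc_shift[[k]]
          d <- delta[k] * truth$hofc_signs[[k]] +
            stats::rnorm(length(ks), 0, truth$hofc_entry_noise_sd)
          D[P$i[k], ks] <- D[ks, P$i[k]] <- d
        }
      }
      is_pd <- function(M) !inherits(tryCatch(chol(M), error = identity),
                                     "error")
      gamma <- 1
      if (!is_pd(C + D)) {
        lo <- 0; hi <- 1
        for (it in 1:12) {
          mid <- (lo + hi) / 2
          if (is_pd(C + mid * D)) lo <- mid else hi <- mid
        }
        gamma <- 0.95 * lo
      }
      C <- C + gamma * D
      C <- pmin(pmax(C, -0.99), 0.99)
      diag(C) <- 1
      perturbed <- TRUE
    }
    if (perturbed && inherits(tryCatch(chol(C), error = identity),
                              "error")) {
      C <- nearest_correlation(C)
    }
    C
  })
}

# realized values of the planted edges for one subject target matrix
planted_values <- function(truth, target) {
  P <- truth$planted
  if (!nrow(P)) return(numeric())
  vals <- numeric(nrow(P))
  lo <- P$pool == "lofc"
  vals[lo] <- target[cbind(P$i[lo], P$j[lo])]
  if (any(!lo)) {
    H <- hofc(as_connectome(target, "lofc"))
    vals[!lo] <- H[cbind(P$i[!lo], P$j[!lo])]
  }
  vals
}

# shared core: subject targets, signals, scores
cohort_core <- function(n_subjects, truth, master_seed, target_r2) {
  n <- as.integer(n_subjects)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  seeds <- derive_seeds(master_seed, 2L * n + 1L)
  targets <- lapply(seq_len(n), function(s) subject_target(truth, seeds[s]))
  p <- nrow(truth$planted)
  if (p) {
    V <- vapply(targets, function(C) planted_values(truth, C), numeric(p))
    V <- t(matrix(V, nrow = p))            # n x p even when p == 1
  } else {
    V <- matrix(0, n, 0)
  }
  # centre edge values on their base-connectome baseline so the latent
  # score is deviation-driven and the score map lands on-scale
  baseline <- planted_values(truth, truth$base_correlation)
  signal <- as.numeric(sweep(V, 2, baseline) %*% truth$weights)
  noise_sd <- truth$noise_sd
  if (!is.null(target_r2)) {
    check_scalar(target_r2, "target_r2", lower = 1e-6, upper = 1)
    sd_sig <- stats::sd(signal)
    if (sd_sig == 0) stop("cannot calibrate noise: planted signal is constant",
                          call. = FALSE)
    noise_sd <- sd_sig * sqrt((1 - target_r2) / target_r2)
  }
  noise <- with_seed(seeds[2L * n + 1L], stats::rnorm(n, 0, noise_sd))
  latent <- signal + noise
  scores <- pmin(pmax(truth$score_offset + truth$score_scale * latent, 0), 100)
  list(targets = targets, edge_values = V, signal = signal,
       latent = latent, scores = scores, noise_sd_used = noise_sd,
       seeds = seeds)
}

#' Simulate a connectome-level cohort (no time-series sampling)
#'
#' Fast path for validating the selection and modelling stages: each
#' subject's low-order connectome is their target correlation matrix
#' itself, with no finite-sample estimation noise. Scores are the planted
#' linear signal plus Gaussian noise, affinely mapped to [0, 100].
#'
#' @param n_subjects cohort size.
#' @param truth a [ground_truth()] object.
#' @param master_seed integer; the whole cohort is a deterministic function
#'   of `(truth, master_seed)`. Per-subject seeds are derived from it via a
#'   fixed counter scheme.
#' @param target_r2 optional; when given, the score noise SD is calibrated
#'   so the oracle linear model on the true planted-edge values has this
#'   R-squared against the latent score.
#' @return a `"synthetic_cohort"` object with `connectomes` (list of
#'   `"lofc"` connectomes), `scores`, the realized planted `edge_values`
#'   and `signal`, the `noise_sd` actually used, and the `truth` echo.
#' @export
simulate_connectome_cohort <- function(n_subjects, truth, master_seed,
                                       target_r2 = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  core <- cohort_core(n_subjects, truth, master_seed, target_r2)
  structure(list(connectomes = lapply(core$targets, as_connectome,
                                      kind = "lofc"),
                 scores = core$scores, latent = core$latent,
                 signal = core$signal, edge_values = core$edge_values,
                 noise_sd = core$noise_sd_used, truth = truth,
                 master_seed = as.integer(master_seed), subjects = NULL),
            class = "synthetic_cohort")
}

#' Simulate a time-series cohort
#'
#' Full generative path: each subject's regional time series is drawn as a
#' zero-mean multivariate normal with the subject's target correlation
#' matrix, so the empirical Pearson connectome converges to the target as
#' the number of time points grows. Scores are generated exactly as in
#' [simulate_connectome_cohort()] from the targets (not from the sampled
#' series), so the planted signal is unaffected by sampling noise.
#'
#' @inheritParams simulate_connectome_cohort
#' @param n_timepoints time points per subject (140 in a typical
#'   resting-state protocol with TR = 3 s).
#' @return a `"synthetic_cohort"` object whose `subjects` field holds one
#'   `T x R` matrix per subject (named `sub001`, `sub002`, ...).
#' @export
simulate_cohort <- function(n_subjects, n_timepoints, truth, master_seed,
                            target_r2 = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  Tn <- as.integer(n_timepoints)
  if (Tn < 3) stop("need at least 3 time points", call. = FALSE)
  if (Tn < truth$n_regions) {
    message("note: fewer time points than regions; empirical connectomes ",
            "will be rank-deficient")
  }
  core <- cohort_core(n_subjects, truth, master_seed, target_r2)
  n <- length(core$scores)
  subjects <- lapply(seq_len(n), function(s) {
    U <- chol(core$targets[[s]])
    with_seed(core$seeds[n + s], {
      matrix(stats::rnorm(Tn * truth$n_regions), Tn) %*% U
    })
  })
  names(subjects) <- sprintf("sub%03d", seq_len(n))
  structure(list(connectomes = lapply(core$targets, as_connectome,
                                      kind = "lofc"),
                 scores = core$scores, latent = core$latent,
                 signal = core$signal, edge_values = core$edge_values,
                 noise_sd = core$noise_sd_used, truth = truth,
                 master_seed = as.integer(master_seed),
                 subjects = subjects),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(x$scores)
  cat(sprintf("synthetic cohort: %d subjects, %d regions%s\n", n,
              x$truth$n_regions,
              if (is.null(x$subjects)) " (connectome-level)"
              else sprintf(", %d time points", nrow(x$subjects[[1]]))))
  cat(sprintf("  scores: mean %.1f, sd %.1f, range [%.1f, %.1f]\n",
              mean(x$scores), stats::sd(x$scores), min(x$scores),
              max(x$scores)))
  cat(sprintf("  planted edges: %d | score noise sd %.3g\n",
              nrow(x$truth$planted), x$noise_sd))
  invisible(x)
}

#' Construct a ground truth with randomly planted edges
#'
#' Convenience constructor for validation experiments: draws a base
#' correlation from the factor model, then plants `n_lofc` low-order and
#' `n_hofc` high-order edges at random region pairs, avoiding pairs whose
#' base correlation is already strong (deviations there would be censored
#' by the [-1, 1] range) and, by default, reusing no region twice (so
#' planted features are not structurally collinear).
#'
#' The default score map here (offset 50, scale 10) keeps the planted
#' linear signal well inside the 0-100 scale, so recovery experiments are
#' not confounded by floor/ceiling censoring; the clinically shaped map
#' (22.6 / 23.2, strong floor effect) remains the [ground_truth()]
#' default.
#'
#' @param n_regions number of regions.
#' @param n_lofc,n_hofc number of planted low-/high-order edges.
#' @param weight common weight given to every planted edge; high-order
#'   edges receive `weight * hofc_weight_factor` instead.
#' @param hofc_weight_factor multiplier applied to high-order edge
#'   weights. Profile correlations move on a ~3x smaller scale than the
#'   raw correlations they are built from (under the default perturbation
#'   sizes), so the default of 3 gives both pools comparable per-edge
#'   effect shares in the latent score.
#' @param max_base_cor plant only on pairs with `|base correlation|` below
#'   this.
#' @param distinct_regions if TRUE (default) no region participates in two
#'   planted edges.
#' @param seed passed to [ground_truth()] and used for the edge draw.
#' @param ... further arguments to [ground_truth()].
#' @return a `"ground_truth"` object.
#' @export
random_truth <- function(n_regions, n_lofc = 8, n_hofc = 0, weight = 2,
                         hofc_weight_factor = 3,
                         max_base_cor = 0.4, distinct_regions = TRUE,
                         seed = 1, score_offset = 50, score_scale = 10,
                         ...) {
  n_edges <- n_lofc + n_hofc
  if (n_edges < 1) stop("plant at least one edge", call. = FALSE)
  base <- ground_truth(n_regions, seed = seed, ...)
  C <- base$base_correlation
  map <- edge_index_map(n_regions)
  ok <- which(abs(C[cbind(map$i, map$j)]) < max_base_cor)
  pick <- with_seed(seed, {
    sel <- integer()
    used <- integer()
    for (e in sample(ok)) {
      if (distinct_regions &&
          (map$i[e] %in% used || map$j[e] %in% used)) next
      sel <- c(sel, e)
      used <- c(used, map$i[e], map$j[e])
      if (length(sel) == n_edges) break
    }
    sel
  })
  if (length(pick) < n_edges) {
    stop("could not place the requested number of edges; relax ",
         "'max_base_cor' or 'distinct_regions'", call. = FALSE)
  }
  planted <- data.frame(i = map$i[pick], j = map$j[pick],
                        pool = rep(c("lofc", "hofc"), c(n_lofc, n_hofc)))
  ground_truth(n_regions, planted,
               weights = weight * ifelse(planted$pool == "hofc",
                                         hofc_weight_factor, 1),
               seed = seed, score_offset = score_offset,
               score_scale = score_scale, ...)
}
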