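# Independent brute-force oracles and shared fixtures for the test suite.

# Pearson correlation from the explicit sum formula (independent of
# stats::cor and of the package's vectorized paths)
naive_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# pairwise low-order connectome by looping the sum formula
naive_lofc <- function(ts) {
  R <- ncol(ts)
  M <- diag(1, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      M[i, j] <- M[j, i] <- naive_pearson(ts[, i], ts[, j])
    }
  }
  M
}

# high-order connectome by explicit slice-out-and-correlate
naive_hofc <- function(L) {
  R <- nrow(L)
  M <- diag(1, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      keep <- setdiff(seq_len(R), c(i, j))
      M[i, j] <- M[j, i] <- naive_pearson(L[i, keep], L[j, keep])
    }
  }
  M
}

# indices of a truth's planted edges inside a feature-pool map
planted_indices <- function(truth, map) {
  key <- paste(map$pool, map$i, map$j)
  match(paste(truth$planted$pool, truth$planted$i, truth$planted$j), key)
}

# memoised store for fixtures shared between expensive test blocks
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small connectome-level cohort + combined feature pool used across files
toy_cohort <- function(seed = 1, n = 30, R = 12, n_lofc = 2, n_hofc = 0,
                       weight = 4, target_r2 = 0.95) {
  truth <- random_truth(R, n_lofc = n_lofc, n_hofc = n_hofc,
                        weight = weight, seed = seed)
  cohort <- simulate_connectome_cohort(n, truth, master_seed = seed,
                                       target_r2 = target_r2)
  pool <- if (n_hofc > 0) "lofc+hofc" else "lofc"
  fp <- feature_pool(cohort$connectomes, pool = pool)
  list(truth = truth, cohort = cohort, X = fp$X, map = fp$map,
       y = cohort$scores, planted = planted_indices(truth, fp$map))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
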