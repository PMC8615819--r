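# Shared configurations for the end-to-end validation experiments.
# Problem sizes are the package's chosen balance between statistical
# resolution and runtime; see the methods vignette.

# selection operating point for p >> n cohorts (n ~ 40): the randomized-
# LASSO defaults of the field's reference implementation
paper_ctrl <- function(B = 50, seed = 1) {
  stability_control(B = B, fraction = 0.75, threshold = 0.25, seed = seed)
}

# coarser SVR tuning grid for multi-seed experiments
trend_grid <- function() {
  svr_grid(C = 2^seq(-3, 3, by = 2), epsilon = c(0.01, 0.1))
}

# criterion experiment: edge-recovery at 4005 features, n = 200
recovery_run <- function(s, B = 100) {
  truth <- random_truth(90, n_lofc = 10, weight = 2, seed = s)
  co <- simulate_connectome_cohort(200, truth, master_seed = s,
                                   target_r2 = 0.9)
  fp <- feature_pool(co$connectomes, pool = "lofc")
  idx <- planted_indices(truth, fp$map)
  sel <- suppressWarnings(
    stability_selection(fp$X, co$scores,
                        stability_control(B = B, seed = s)))
  yp <- with_seed_test(s + 1000, sample(co$scores))
  nul <- suppressWarnings(
    stability_selection(fp$X, yp,
                        stability_control(B = B, seed = s + 500)))
  list(freq_planted = sel$frequencies[idx],
       selected_planted = sum(idx %in% sel$selected),
       null_max = max(nul$frequencies))
}

# paper-scale strong-signal cohort: n = 40, combined pool, 8010 features
paper_scale_cv <- function(seed = 1, B = 100) {
  truth <- random_truth(90, n_lofc = 1, n_hofc = 1, weight = 2,
                        seed = seed)
  co <- simulate_connectome_cohort(40, truth, master_seed = seed,
                                   target_r2 = 0.9)
  fp <- feature_pool(co$connectomes, pool = "lofc+hofc")
  suppressMessages(suppressWarnings(
    nested_loocv(fp$X, co$scores, model = "svr",
                 control = paper_ctrl(B = B, seed = seed), seed = seed,
                 map = fp$map)))
}

# reduced-scale cohort for the trend / mid-signal / null experiments
small_cohort <- function(seed, n_lofc = 2, n_hofc = 2, target_r2 = 0.9) {
  truth <- random_truth(15, n_lofc = n_lofc, n_hofc = n_hofc, weight = 2,
                        seed = seed)
  co <- simulate_connectome_cohort(40, truth, master_seed = seed,
                                   target_r2 = target_r2)
  list(truth = truth, co = co)
}

small_cv <- function(co, model, pool, seed, B = 50, scores = NULL) {
  fp <- feature_pool(co$connectomes, pool = pool)
  if (is.null(scores)) scores <- co$scores
  suppressMessages(suppressWarnings(
    nested_loocv(fp$X, scores, model = model,
                 control = paper_ctrl(B = B, seed = seed),
                 grid = trend_grid(), seed = seed)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# 20 permutation-null LR runs at the reduced scale, shared between the
# signal-vs-null comparison and the null-calibration checks
null_runs <- function() {
  cached("null_runs_20", {
    base <- small_cohort(seed = 1, target_r2 = 0.5)
    lapply(1:20, function(s) {
      yp <- with_seed_test(3000 + s, sample(base$co$scores))
      cv <- small_cv(base$co, "lr", "lofc+hofc", seed = s, B = 30,
                     scores = yp)
      list(r = cv$evaluation$r, p = cv$evaluation$p_one_sided)
    })
  })
}
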