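test_that("cohort generation is bit-identical under a fixed master seed", {
  truth <- random_truth(10, n_lofc = 2, n_hofc = 1, weight = 3, seed = 7)
  a <- simulate_connectome_cohort(12, truth, master_seed = 99)
  b <- simulate_connectome_cohort(12, truth, master_seed = 99)
  expect_identical(a$scores, b$scores)
  expect_identical(a$connectomes, b$connectomes)
  c2 <- simulate_cohort(6, 40, truth, master_seed = 5)
  d2 <- simulate_cohort(6, 40, truth, master_seed = 5)
  expect_identical(c2$subjects, d2$subjects)
  expect_false(identical(a$scores,
                         simulate_connectome_cohort(12, truth, 100)$scores))
})

test_that("subject correlation targets are valid correlation matrices", {
  truth <- random_truth(15, n_lofc = 4, n_hofc = 2, weight = 3, seed = 3)
  co <- simulate_connectome_cohort(10, truth, master_seed = 2)
  for (C in co$connectomes) {
    M <- unclass(C)
    expect_equal(M, t(M))
    expect_equal(diag(M), rep(1, 15), ignore_attr = TRUE)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  expect_true(all(co$scores >= 0 & co$scores <= 100))
})

test_that("zero score noise gives an exact linear oracle (R^2 = 1)", {
  truth <- random_truth(12, n_lofc = 3, weight = 2, seed = 11,
                        score_offset = 50, score_scale = 5)
  co <- simulate_connectome_cohort(20, truth, master_seed = 4)
  expect_equal(co$noise_sd, 0)
  fit <- lm(co$scores ~ co$edge_values)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-12)
})

test_that("a positively weighted edge drives the score monotonically", {
  truth <- random_truth(10, n_lofc = 1, weight = 5, seed = 2,
                        score_offset = 50, score_scale = 8)
  co <- simulate_connectome_cohort(15, truth, master_seed = 6)
  v <- co$edge_values[, 1]
  expect_true(all(diff(co$scores[order(v)]) > 0))
})

test_that("least squares on the true planted edges recovers the weights", {
  truth <- random_truth(20, n_lofc = 10, weight = 2, seed = 13)
  co <- simulate_connectome_cohort(200, truth, master_seed = 13,
                                   target_r2 = 0.9)
  fit <- lm(co$scores ~ co$edge_values)
  est <- coef(fit)[-1]
  expected <- truth$weights * truth$score_scale
  relerr <- abs(est - expected) / expected
  expect_lt(mean(relerr), 0.1)
  expect_lt(max(relerr), 0.2)
  expect_gt(summary(fit)$r.squared, 0.85)
})

test_that("empirical connectomes converge to the subject target with T", {
  truth <- random_truth(15, n_lofc = 2, weight = 2, seed = 21)
  co <- simulate_cohort(3, 10000, truth, master_seed = 8)
  emp <- lofc(co$subjects[[1]])
  expect_lt(max(abs(unclass(emp) - unclass(co$connectomes[[1]]))), 0.05)
})

test_that("time-series and connectome-level cohorts share scores and targets", {
  truth <- random_truth(8, n_lofc = 2, weight = 3, seed = 5)
  a <- simulate_connectome_cohort(8, truth, master_seed = 31)
  b <- simulate_cohort(8, 25, truth, master_seed = 31)
  expect_identical(a$scores, b$scores)
  expect_identical(a$connectomes, b$connectomes)
})

test_that("invalid ground truths are rejected", {
  expect_error(ground_truth(10, data.frame(i = 5, j = 3, pool = "lofc"),
                            weights = 1), "i < j")
  expect_error(ground_truth(10, data.frame(i = 1, j = 11, pool = "lofc"),
                            weights = 1), "exceed")
  expect_error(ground_truth(10, data.frame(i = 1, j = 2, pool = "mid"),
                            weights = 1), "pool")
  expect_error(ground_truth(10, data.frame(i = 1, j = 2, pool = "lofc"),
                            weights = c(1, 2)), "one value per")
  bad <- matrix(0.99, 4, 4); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(ground_truth(4, base_correlation = bad), "positive definite")
})

test_that("high-order planted edges carry signal through the high-order pool", {
  truth <- random_truth(20, n_lofc = 0, n_hofc = 3, weight = 8, seed = 17)
  co <- simulate_connectome_cohort(60, truth, master_seed = 9)
  fp <- feature_pool(co$connectomes, pool = "lofc+hofc")
  idx <- planted_indices(truth, fp$map)
  expect_true(all(fp$map$pool[idx] == "hofc"))
  # the generator reads the planted value off the high-order connectome,
  # so the corresponding pool column must reproduce edge_values exactly
  expect_equal(fp$X[, idx], co$edge_values, ignore_attr = TRUE)
  # and it must vary across subjects (the shift mechanism works)
  expect_true(all(apply(co$edge_values, 2, sd) > 0.01))
})
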