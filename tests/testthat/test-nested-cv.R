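test_that("evaluation reproduces the exact t-transform of Pearson r", {
  ev <- evaluate_predictions(1:10, (1:10) * 2)
  expect_equal(ev$r, 1)
  expect_lte(ev$p_one_sided, 1e-10)

  # r = 0 at n = 40 is exactly p = 0.5 one-sided
  set.seed(1)
  o <- rnorm(40)
  p <- rnorm(40)
  p <- residuals(lm(p ~ o))           # force r exactly 0
  ev0 <- evaluate_predictions(p, o)
  expect_equal(ev0$r, 0, tolerance = 1e-12)
  expect_equal(ev0$p_one_sided, 0.5, tolerance = 1e-10)

  # degenerate constant predictions
  evd <- evaluate_predictions(rep(3, 10), rnorm(10))
  expect_true(evd$degenerate)
  expect_equal(evd$r, 0)
  expect_error(evaluate_predictions(1:3, rep(1, 3)), "constant")
})

test_that("printed r/p pairs of a 40-subject cohort are consistent with one-sided t", {
  # helper inverting the t-transform at given (r, n)
  p1 <- function(r, n) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    pt(t, n - 2, lower.tail = FALSE)
  }
  expect_equal(round(p1(0.54, 40), 4), 0.0002)
  expect_equal(round(p1(0.45, 40), 3), 0.002)
  # a correlation printed to two decimals pins p only to an interval:
  # the interval induced by r in [x - 0.005, x + 0.005) must contain the
  # printed p to its last digit
  expect_true(p1(0.315, 40) <= 0.0245 && 0.0235 <= p1(0.305, 40))
  expect_true(p1(0.285, 40) <= 0.0385 && 0.0375 <= p1(0.275, 40))
  # and the package's evaluator agrees with the closed form
  set.seed(2)
  o <- rnorm(40)
  p <- 0.54 * scale(o) + sqrt(1 - 0.54^2) * scale(residuals(lm(rnorm(40) ~ o)))
  ev <- evaluate_predictions(drop(p), o)
  expect_equal(ev$p_one_sided, p1(ev$r, 40), tolerance = 1e-12)
})

test_that("inner tuning scores candidates by inner LOOCV correlation", {
  tc <- cached("toy_strong", toy_cohort(seed = 1))
  sel <- stability_selection(tc$X, tc$y, stability_control(B = 50, seed = 1))
  feats <- sel$selected
  expect_gt(length(feats), 0)
  Xf <- tc$X[, feats, drop = FALSE]

  g1 <- data.frame(C = 2, epsilon = 0.1)
  expect_equal(inner_loocv_tune(Xf, tc$y, "svr", g1)$C, 2)

  spec <- inner_loocv_tune(Xf, tc$y, "svr", svr_grid())
  scores <- attr(spec, "scores")
  expect_equal(nrow(scores), 18)
  best <- max(scores$r)
  expect_equal(scores$r[scores$C == spec$C & scores$epsilon == spec$epsilon],
               best)
  # an over-regularized cost must not win on strong-signal data
  expect_gt(spec$C, min(svr_grid()$C))
  expect_equal(inner_loocv_tune(Xf, tc$y, "lr")$kind, "lr")

  # exact ties resolve toward smaller C: duplicate grid rows
  gdup <- data.frame(C = c(4, 2), epsilon = c(0.1, 0.1))
  s2 <- inner_loocv_tune(Xf, tc$y, "svr", rbind(gdup, gdup))
  s2b <- inner_loocv_tune(Xf, tc$y, "svr", gdup)
  expect_equal(s2$C, s2b$C)
})

test_that("majority vote picks the plurality spec with deterministic ties", {
  sp <- function(C) model_spec("svr", C = C, epsilon = 0.1)
  expect_equal(majority_vote(c(replicate(25, sp(1), simplify = FALSE),
                               replicate(15, sp(10), simplify = FALSE)))$C,
               1)
  expect_equal(majority_vote(c(replicate(20, sp(1), simplify = FALSE),
                               replicate(20, sp(10), simplify = FALSE)))$C,
               1)
  expect_equal(majority_vote(list(sp(4)))$C, 4)
  tie_eps <- list(model_spec("svr", C = 2, epsilon = 1),
                  model_spec("svr", C = 2, epsilon = 0.01))
  expect_equal(majority_vote(tie_eps)$epsilon, 0.01)
  expect_equal(majority_vote(list(model_spec("lr")))$kind, "lr")
  expect_error(majority_vote(list()), "empty")
})

test_that("held-out subjects never influence their own fold's selection or fit", {
  tc <- cached("toy_strong_lr", toy_cohort(seed = 3, n = 20))
  ctrl <- stability_control(B = 30, seed = 5)
  cv1 <- nested_loocv(tc$X, tc$y, model = "lr", control = ctrl, seed = 11)
  y2 <- tc$y
  i <- 4
  y2[i] <- y2[i] + 25
  cv2 <- nested_loocv(tc$X, y2, model = "lr", control = ctrl, seed = 11)
  expect_identical(cv1$folds[[i]]$selected, cv2$folds[[i]]$selected)
  expect_identical(cv1$folds[[i]]$model$weights, cv2$folds[[i]]$model$weights)
  expect_identical(cv1$predicted[i], cv2$predicted[i])
  # other folds *do* see the perturbed subject in training
  expect_false(identical(cv1$predicted[-i], cv2$predicted[-i]))
})

test_that("nested LOOCV is deterministic and records blind per-fold state", {
  tc <- cached("toy_strong_lr", toy_cohort(seed = 3, n = 20))
  ctrl <- stability_control(B = 30, seed = 5)
  a <- nested_loocv(tc$X, tc$y, model = "lr", control = ctrl, seed = 7)
  b <- nested_loocv(tc$X, tc$y, model = "lr", control = ctrl, seed = 7)
  expect_identical(a$predicted, b$predicted)
  expect_identical(a$evaluation$r, b$evaluation$r)
  expect_equal(length(a$folds), 20)
  expect_true(all(vapply(a$folds, function(f) is.numeric(f$prediction),
                         logical(1))))
})

test_that("folds with empty selections fall back to the training mean", {
  set.seed(9)
  X <- matrix(rnorm(12 * 30), 12, 30)
  y <- rnorm(12)
  ctrl <- stability_control(B = 20, threshold = 1, q = 2, seed = 3)
  expect_message(cv <- nested_loocv(X, y, model = "lr", control = ctrl,
                                    seed = 2), "folds selected no features")
  empty <- vapply(cv$folds, `[[`, logical(1), "empty")
  expect_gt(sum(empty), 0)
  for (i in which(empty)) {
    expect_equal(cv$predicted[i], mean(y[-i]))
  }
})

test_that("the voted spec is applied in pass two, or per-fold winners when asked", {
  tc <- cached("toy_strong", toy_cohort(seed = 1))
  ctrl <- stability_control(B = 30, seed = 2)
  grid <- svr_grid(C = c(0.5, 8), epsilon = c(0.1))
  cv <- nested_loocv(tc$X, tc$y, model = "svr", control = ctrl,
                     grid = grid, seed = 3)
  expect_true(cv$voted_spec$C %in% grid$C)
  winners <- vapply(Filter(Negate(is.null),
                           lapply(cv$folds, `[[`, "inner_spec")),
                    `[[`, numeric(1), "C")
  expect_equal(cv$voted_spec$C,
               majority_vote(Filter(Negate(is.null),
                                    lapply(cv$folds, `[[`, "inner_spec")))$C)
  used <- vapply(cv$folds, function(f) f$model$spec$C, numeric(1))
  expect_true(all(used == cv$voted_spec$C))
  cvp <- nested_loocv(tc$X, tc$y, model = "svr", control = ctrl,
                      grid = grid, seed = 3, hyper = "per-fold")
  used_p <- vapply(cvp$folds, function(f) f$model$spec$C, numeric(1))
  expect_equal(used_p, winners)
})

test_that("a strong planted signal yields high held-out correlation", {
  tc <- cached("toy_cv_strong", toy_cohort(seed = 2))
  cv <- cached("toy_cv_strong_fit",
               nested_loocv(tc$X, tc$y, model = "lr",
                            control = stability_control(B = 50, seed = 1),
                            seed = 5))
  expect_gt(cv$evaluation$r, 0.6)
  expect_lt(cv$evaluation$p_one_sided, 0.01)
})
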