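test_that("linear regression reproduces the closed-form solution", {
  # exact line
  fit <- fit_edge_model(matrix(1:3), c(2, 4, 6), model_spec("lr"))
  expect_equal(predict(fit, matrix(1:3)), c(2, 4, 6), tolerance = 1e-10)
  expect_equal(predict(fit, matrix(10)), 20, tolerance = 1e-8)

  # full-rank p < n: match lm()
  set.seed(1)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(30)
  fit <- fit_edge_model(X, drop(y), model_spec("lr"))
  expect_equal(predict(fit, X), unname(fitted(lm(y ~ X))),
               tolerance = 1e-8)
})

test_that("p >= n linear regression is the minimum-norm interpolator", {
  set.seed(2)
  X <- matrix(rnorm(5 * 12), 5, 12)
  y <- rnorm(5)
  fit <- fit_edge_model(X, y, model_spec("lr"))
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
  # independent oracle: pseudoinverse on the same standardized design
  Xs <- scale(X, center = fit$x_center, scale = fit$x_scale)
  w_ref <- drop(MASS::ginv(Xs) %*% (y - mean(y)))
  expect_equal(fit$weights, w_ref, tolerance = 1e-8)
})

test_that("linear SVR interpolates exact-linear data at large cost", {
  X <- matrix(1:3)
  fit <- fit_edge_model(X, c(2, 4, 6),
                        model_spec("svr", C = 1e4, epsilon = 0))
  expect_equal(predict(fit, X), c(2, 4, 6), tolerance = 1e-3)
})

test_that("linear SVR agrees with an independent convex solver", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% c(2, -1, 0, 0.5, 1)) + rnorm(30, sd = 0.4)
  C <- 2
  fit <- fit_edge_model(X, y, model_spec("svr", C = C, epsilon = 0.1))
  eps_eff <- 0.1 * sd(y)
  Xs <- scale(X, fit$x_center, fit$x_scale)
  yc <- y - fit$y_center
  primal <- function(w, b) {
    r <- yc - drop(Xs %*% w) - b
    0.5 * sum(w^2) + C * sum(pmax(abs(r) - eps_eff, 0))
  }
  obj_pkg <- primal(fit$weights, fit$intercept)
  ref <- kernlab::ksvm(Xs, yc, type = "eps-svr", kernel = "vanilladot",
                       C = C, epsilon = eps_eff, scaled = FALSE,
                       kpar = list(), tol = 1e-6)
  # read the reference hyperplane off kernlab's own predictions (the
  # model is linear, so probing the basis vectors recovers w and b)
  b_ref <- drop(kernlab::predict(ref, matrix(0, 1, 5)))
  w_ref <- drop(kernlab::predict(ref, diag(5))) - b_ref
  expect_equal(predict(fit, X),
               fit$y_center + drop(kernlab::predict(ref, Xs)),
               tolerance = 1e-2)
  obj_ref <- primal(w_ref, b_ref)
  # two independent convex solvers must land on the same optimum
  expect_lt(abs(obj_pkg - obj_ref) / max(1, abs(obj_ref)), 1e-3)
})

test_that("vanishing cost fully regularizes the SVR", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- drop(X %*% c(3, 1, -2)) + rnorm(40)
  fit <- fit_edge_model(X, y, model_spec("svr", C = 1e-6, epsilon = 0.1))
  expect_lt(max(abs(fit$weights)), 1e-3)
  preds <- predict(fit, X)
  expect_lt(diff(range(preds)), 0.05 * diff(range(y)))
})

test_that("SVR predictions are invariant to training-row order", {
  set.seed(5)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(25, sd = 0.3)
  Xnew <- matrix(rnorm(5 * 4), 5, 4)
  f1 <- fit_edge_model(X, y, model_spec("svr", C = 1, epsilon = 0.1))
  p <- sample(25)
  f2 <- fit_edge_model(X[p, ], y[p], model_spec("svr", C = 1,
                                                epsilon = 0.1))
  expect_equal(predict(f1, Xnew), predict(f2, Xnew), tolerance = 1e-4)
  expect_equal(predict(f1, Xnew[c(1, 1), ])[1],
               predict(f1, Xnew[c(1, 1), ])[2])
})

test_that("fitted models beat the zero-weight model under their own loss", {
  set.seed(6)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- drop(X %*% c(2, -1, 1)) + rnorm(30, sd = 0.5)
  for (spec in list(model_spec("lr"),
                    model_spec("svr", C = 1, epsilon = 0.1))) {
    fit <- fit_edge_model(X, y, spec)
    r_fit <- y - predict(fit, X)
    r_null <- y - mean(y)
    if (spec$kind == "lr") {
      expect_lte(sum(r_fit^2), sum(r_null^2))
    } else {
      eps_eff <- spec$epsilon * sd(y)
      loss <- function(r, w) 0.5 * sum(w^2) +
        spec$C * sum(pmax(abs(r) - eps_eff, 0))
      expect_lte(loss(r_fit, fit$weights), loss(r_null, rep(0, 3)) + 1e-8)
    }
  }
})

test_that("model interface guards its contracts", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(fit_edge_model(X[, 0], y, model_spec("lr")), "no features")
  fit <- fit_edge_model(X, y, model_spec("lr"))
  expect_error(predict(fit, matrix(rnorm(10), 10, 1)), "columns")
  expect_message(model_spec("svr", gamma = 0.1), "gamma")
  expect_silent(spec <- model_spec("lr"))
  expect_true(is.na(spec$C))
  g <- svr_grid()
  expect_equal(nrow(g), 18)
  expect_true(!is.unsorted(g$C))
})
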