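test_that("Gaussian imputation fills only missing entries from column moments", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  # no missing entries: every draw is the input
  imp0 <- impute_missing(x, n_draws = 3, seed = 1)
  expect_identical(imp0$draws[[1]], x)
  expect_identical(imp0$draws[[3]], x)

  # a constant observed column imputes its constant (sd = 0)
  xc <- cbind(a = c(0, 0, 0, 0, NA), b = rnorm(5))
  impc <- impute_missing(xc, n_draws = 4, seed = 2)
  filled <- vapply(impc$draws, function(d) d[5, "a"], numeric(1))
  expect_equal(filled, rep(0, 4))

  # 30% missing: mean of filled entries matches the observed column mean
  set.seed(3)
  big <- matrix(rnorm(4000, mean = 2), 2000, 2,
                dimnames = list(NULL, c("a", "b")))
  miss <- sample(2000, 600)
  bigm <- big
  bigm[miss, 1] <- NA
  imp <- impute_missing(bigm, n_draws = 10, seed = 4)
  obs_mean <- mean(bigm[-miss, 1])
  obs_sd <- sd(bigm[-miss, 1])
  fills <- unlist(lapply(imp$draws, function(d) d[miss, 1]))
  expect_lt(abs(mean(fills) - obs_mean), 3 * obs_sd / sqrt(length(fills)))
  # observed entries identical across draws; filled entries vary
  expect_identical(imp$draws[[1]][-miss, 1], bigm[-miss, 1])
  expect_false(identical(imp$draws[[1]][miss, 1], imp$draws[[2]][miss, 1]))

  all_na <- cbind(a = rep(NA_real_, 5), b = rnorm(5))
  expect_error(impute_missing(all_na), "unimputable-column")
})

test_that("univariate screen keeps positive significant predictors only", {
  set.seed(5)
  n <- 3000
  X <- cbind(pos = rnorm(n), neg = rnorm(n), noise = rnorm(n))
  y <- 0.7 * X[, "pos"] - 0.5 * X[, "neg"] + rnorm(n)
  kept <- univariate_screen(y, X, alpha = 0.01)
  expect_equal(as.character(kept), "pos")
  tab <- attr(kept, "screen")
  expect_true(tab$retained[tab$factor == "pos"])
  expect_false(tab$retained[tab$factor == "neg"])   # negative slope
  expect_false(tab$retained[tab$factor == "noise"]) # non-significant
  w <- testthat::capture_warnings(
    univariate_screen(y[1:5], X[1:5, , drop = FALSE]))
  expect_match(w, "complete pairs", all = TRUE)
})

test_that("noiseless data is identified exactly by the cross-validated fit", {
  cfg <- sim_config(n_regions = 400, weights = c(A = 0.8, B = 0.3),
                    intercept = 0.2, noise_sd = 0, missing_rate = 0)
  d <- generate_dataset(cfg, seed = 6)
  m <- fit_with_cv(d$occupancy[, "TUP1"], d$occupancy[, c("A", "B")],
                   seed = 7)
  expect_equal(unname(m$weights), c(0.8, 0.3), tolerance = 1e-6)
  expect_equal(m$intercept, 0.2, tolerance = 1e-6)
  expect_equal(m$r2_heldout, 1, tolerance = 1e-9)
})

test_that("collinear designs are refused with the offending pair named", {
  set.seed(8)
  X <- cbind(a = rnorm(100), b = rnorm(100))
  X <- cbind(X, c = X[, "a"])
  y <- rnorm(100)
  expect_error(fit_with_cv(y, X, seed = 1), "collinearity.*a.*c")
})

test_that("non-significant recruiters are dropped and the rest stay stable", {
  set.seed(9)
  n <- 2000
  X <- cbind(s1 = rnorm(n), s2 = rnorm(n), junk = rnorm(n))
  y <- 1 + 0.6 * X[, "s1"] + 0.4 * X[, "s2"] + rnorm(n, sd = 0.8)
  m <- fit_with_cv(y, X, seed = 10)
  expect_true("junk" %in% m$nonsignificant)
  red <- drop_nonsignificant(m, y, X)
  expect_setequal(red$included, c("s1", "s2"))
  expect_lt(max(abs(red$weights - m$weights[c("s1", "s2")])), 0.05)
  # a model whose recruiters are all significant is returned unchanged
  expect_identical(drop_nonsignificant(red, y, X), red)
})

test_that("nested model comparison has power and is calibrated", {
  set.seed(11)
  n <- 3000
  X <- cbind(a = rnorm(n), b = rnorm(n), extra = rnorm(n))
  y <- 0.5 * X[, "a"] + 0.3 * X[, "b"] + 0.7 * X[, "extra"] + rnorm(n)
  cm <- compare_models(y, X, base = c("a", "b"),
                       extended = c("a", "b", "extra"))
  expect_lt(cm$p_value, 1e-10)
  expect_gt(cm$delta_r2, 0)

  # adding pure noise: p uniform under the null
  pvals <- replicate(500, {
    Xs <- cbind(a = rnorm(200), junk = rnorm(200))
    ys <- 0.5 * Xs[, "a"] + rnorm(200)
    compare_models(ys, Xs, "a", c("a", "junk"))$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # identical models: no gain, p = 1
  cm0 <- compare_models(y, X, c("a", "b"), c("a", "b"))
  expect_equal(cm0$delta_r2, 0)
  expect_equal(cm0$p_value, 1)
  expect_error(compare_models(y, X, c("a", "zzz"), c("a", "b")),
               "non-nested")
})

test_that("prediction is the planted linear form and internally consistent", {
  m <- structure(list(intercept = 0.1, weights = c(r1 = 0.5, r2 = 0.2),
                      included = c("r1", "r2")),
                 class = "occupancy_model")
  X <- rbind(c(1, 2), c(0, 0), c(-1, 4))
  colnames(X) <- c("r1", "r2")
  expect_equal(unname(predict(m, X)),
               c(0.1 + 0.5 + 0.4, 0.1, 0.1 - 0.5 + 0.8))
  # all-zero recruiters predict the intercept everywhere
  expect_equal(unname(predict(m, X * 0)), rep(0.1, 3))
  # linearity: yhat(aX) + yhat(bX) - intercept = yhat((a+b)X)
  expect_equal(predict(m, 2 * X) + predict(m, 3 * X) - 0.1,
               predict(m, 5 * X))
  expect_error(predict(m, X[, 1, drop = FALSE]), "missing-recruiter")

  # on synthetic data, squared correlation of predictions tracks held-out R2
  d <- generate_dataset(sim_config(n_regions = 2000), seed = 12)
  fit <- fit_occupancy_model(d, seed = 13)
  imp <- impute_missing(d$occupancy[, fit$model$included, drop = FALSE],
                        n_draws = 1, seed = 14)
  yhat <- predict(fit$model, imp$draws[[1]])
  r2 <- cor(yhat, d$occupancy[, "TUP1"])^2
  expect_lt(abs(r2 - fit$model$r2_heldout), 0.05)
  # no optimistic leak across splits
  expect_lte(fit$model$r2_heldout, fit$model$r2_train + 0.05)
})

test_that("the full pipeline recovers the planted model on default data", {
  st <- regression_study(101, n_regions = 3000, n_decoys = 3)
  expect_true(st$active_set_exact)
  expect_lt(st$max_abs_error, 0.1)
  expect_gt(st$model$r2_heldout, 0.3)
})
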