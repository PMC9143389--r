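test_that("residuals are observed minus predicted", {
  expect_equal(prediction_residuals(prediction_set(c(1, 2), c(1, 2))),
               c(0, 0))
  expect_equal(prediction_residuals(prediction_set(c(1, 2), c(0, 4))),
               c(1, -2))
  p <- prediction_set(c(1, 2, 5), c(0, 4, 2))
  q <- prediction_set(c(0, 4, 2), c(1, 2, 5))
  expect_equal(prediction_residuals(p), -prediction_residuals(q))
})

test_that("error statistics match hand computation", {
  es <- error_stats(prediction_set(c(1, 0), c(0, 1)))  # residuals 1, -1
  expect_equal(es$rmse, 1); expect_equal(es$mae, 1)
  expect_equal(es$delta_max, 1); expect_equal(es$mean_error, 0)

  es2 <- error_stats(prediction_set(c(3, 4), c(0, 0)))  # residuals 3, 4
  expect_equal(es2$rmse, sqrt(25 / 2))
  expect_equal(es2$mae, 3.5)
  expect_equal(es2$s, sd(c(3, 4)))

  es0 <- error_stats(prediction_set(c(2, 5), c(2, 5)))
  expect_equal(unlist(es0), c(rmse = 0, mae = 0, s = 0,
                              delta_max = 0, mean_error = 0))
})

test_that("r2 honors its centering flag and guards its denominator", {
  perf <- prediction_set(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r_squared(perf, "observed_mean"), 1)
  expect_equal(r_squared(perf, "predicted_mean"), 1)

  p <- prediction_set(c(0, 1, 2), c(0, 1, 5))
  o <- oracle_stats(p$y_obs, p$y_pred)
  expect_equal(r_squared(p, "observed_mean"), o$r2_obs)
  expect_equal(r_squared(p, "predicted_mean"), o$r2_pred)
  expect_false(isTRUE(all.equal(o$r2_obs, o$r2_pred)))

  expect_error(r_squared(prediction_set(c(2, 2, 2), c(1, 2, 3))),
               "denominator")
  # asymmetry: r2 is not symmetric in (obs, pred), unlike CCC
  a <- prediction_set(c(0, 1, 2), c(0.2, 0.8, 2.5))
  b <- prediction_set(c(0.2, 0.8, 2.5), c(0, 1, 2))
  expect_false(isTRUE(all.equal(r_squared(a), r_squared(b))))
  expect_equal(ccc(a), ccc(b))
})

test_that("external q2 flavours use their defining reference means", {
  y <- c(0.5, 1.2, -0.3, 2.0, 0.8)
  perf <- prediction_set(y, y, train_mean = 0.1, train_n = 20)
  e <- external_q2(perf, train_ss = 5)
  expect_equal(e$qF1, 1); expect_equal(e$qF2, 1); expect_equal(e$qF3, 1)

  const <- prediction_set(y, rep(mean(y), 5), train_mean = 0.1,
                          train_n = 20)
  expect_equal(external_q2(const, train_ss = 5)$qF2, 0)

  set.seed(41)
  yh <- y + rnorm(5, sd = 0.3)
  tr_y <- rnorm(20, mean = -1)
  p <- prediction_set(y, yh, train_mean = mean(tr_y), train_n = 20)
  e2 <- external_q2(p, train_ss = sum((tr_y - mean(tr_y))^2))
  o <- oracle_stats(y, yh, train_mean = mean(tr_y), train_y = tr_y)
  expect_equal(e2$qF1, o$qF1, tolerance = 1e-12)
  expect_equal(e2$qF2, o$qF2, tolerance = 1e-12)
  expect_equal(e2$qF3, o$qF3, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(e2$qF1, e2$qF2)))

  # qF1 = qF2 exactly when the training mean equals the external mean
  p_eq <- prediction_set(y, yh, train_mean = mean(y), train_n = 20)
  e3 <- external_q2(p_eq, train_ss = 5)
  expect_equal(e3$qF1, e3$qF2)

  expect_error(external_q2(prediction_set(y, yh)), "train_mean")
})

test_that("concordance correlation penalizes location and scale shifts", {
  y <- c(0, 1, 2)
  expect_equal(ccc(prediction_set(y, y)), 1)
  ctr <- c(-1, 0, 1)
  expect_equal(ccc(prediction_set(ctr, -ctr)), -1)
  shifted <- prediction_set(y, y + 5)
  o <- oracle_stats(y, y + 5)
  expect_equal(ccc(shifted), o$ccc)
  expect_lt(ccc(shifted), 1)
})

test_that("through-origin regression yields slope and constrained R2", {
  y <- c(1, 2, 3, 4)
  id <- origin_regression(prediction_set(y, y))
  expect_equal(id$k, 1); expect_equal(id$r0_sq, 1)
  expect_equal(id$r0_prime_sq, 1)

  dbl <- origin_regression(prediction_set(y, 2 * y))
  expect_equal(dbl$k, sum(y * 2 * y) / sum(y^2))  # closed form

  orth <- origin_regression(prediction_set(c(1, -1, 1, -1),
                                           c(1, 1, -1, -1)))
  expect_equal(orth$k, 0)
  expect_equal(orth$r0_sq, 0)

  set.seed(42)
  yy <- rnorm(12); yh <- 0.8 * yy + rnorm(12, sd = 0.3)
  o <- oracle_stats(yy, yh)
  r <- origin_regression(prediction_set(yy, yh))
  expect_equal(r$k, o$k, tolerance = 1e-12)
  expect_equal(r$r0_sq, o$r0_sq, tolerance = 1e-12)
  expect_equal(r$r0_prime_sq, o$r0_prime_sq, tolerance = 1e-12)
})

test_that("the rm2 family computes both variants and their summary pair", {
  fx <- rm2_family(0.9, 0.9, 0.9)
  expect_equal(fx$rm2, 0.9); expect_equal(fx$rm2_prime, 0.9)
  expect_equal(fx$rm2_delta, 0)

  ap <- rm2_family(0.9, 0.8, 0.85, variant = "as_printed")
  expect_equal(ap$rm2, 0.9 * (1 - 0.1))        # 0.81
  sq <- rm2_family(0.9, 0.8, 0.85, variant = "sqrt")
  expect_equal(sq$rm2, 0.9 * (1 - sqrt(0.1)))  # ~0.6154
  expect_equal(sq$rm2, 0.61538, tolerance = 1e-4)

  set.seed(43)
  for (i in 1:20) {
    v <- runif(3)
    got <- rm2_family(v[1], v[2], v[3])
    want <- oracle_rm2(v[1], v[2], v[3])
    expect_equal(got[c("rm2", "rm2_prime", "rm2_avg", "rm2_delta")],
                 want, tolerance = 1e-12)
    expect_equal(got$rm2_avg, (got$rm2 + got$rm2_prime) / 2)
    expect_equal(got$rm2_delta, abs(got$rm2 - got$rm2_prime))
  }
  expect_warning(rm2_family(1.2, 0.5, 0.5), "outside")
})

test_that("validation reports obey their internal orderings", {
  set.seed(44)
  y <- rnorm(30); yh <- y + rnorm(30, sd = 0.4)
  rep <- validation_report(prediction_set(y, yh), set_role = "training")
  expect_gte(rep$rmse, rep$mae)
  expect_gte(rep$mae, 0)
  expect_gte(rep$delta_max, rep$rmse)
  expect_equal(rep$rm2_avg, (rep$rm2 + rep$rm2_prime) / 2)
  expect_equal(rep$rm2_delta, abs(rep$rm2 - rep$rm2_prime))
  expect_true(is.na(rep$qF1))
})

test_that("a perfect model fulfills every acceptance criterion", {
  y <- c(-3, -2.5, -1, 0, 1.2, 2)
  tr <- validation_report(prediction_set(y, y), set_role = "training",
                          q2_cv = 1)
  ex <- validation_report(
    prediction_set(y, y, train_mean = mean(y), train_n = 6),
    set_role = "external", train_ss = sum((y - mean(y))^2))
  v <- criteria_check(tr, ex)
  expect_true(v$overall)
  expect_true(all(v$train[!is.na(v$train)]))
  expect_true(all(v$external[!is.na(v$external)]))
  # q2_cv gap is training-only; external CCC is applicable
  expect_true(is.na(v$external["r2_q2cv_gap"]))
  expect_false(is.na(v$external["ccc_085"]))
})

test_that("cross-validated q2 separates signal from noise deterministically", {
  set.seed(45)
  x <- matrix(rnorm(200), ncol = 2)
  beta <- c(1.5, -0.7)
  ols <- function(xt, yt) {
    fit <- lm.fit(cbind(1, xt), yt)
    b <- fit$coefficients; b[is.na(b)] <- 0
    function(nd) drop(cbind(1, nd) %*% b)
  }
  y_exact <- drop(x %*% beta)
  expect_gte(kfold_cv(x, y_exact, ols, folds = 10, seed = 1), 0.999)

  y_noise <- rnorm(100)
  expect_lte(kfold_cv(x, y_noise, ols, folds = 10, seed = 1), 0.1)

  y_noisy <- y_exact + rnorm(100)
  a <- kfold_cv(x, y_noisy, ols, folds = 10, seed = 7)
  b <- kfold_cv(x, y_noisy, ols, folds = 10, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, kfold_cv(x, y_noisy, ols, folds = 10,
                                     seed = 8)))
})

test_that("Y-scrambling detects chance correlation levels", {
  set.seed(46)
  x <- matrix(rnorm(300), ncol = 3)
  y <- drop(x %*% c(2, -1, 0.5)) + rnorm(100, sd = 0.2)
  ols <- function(xt, yt) {
    fit <- lm.fit(cbind(1, xt), yt)
    b <- fit$coefficients; b[is.na(b)] <- 0
    function(nd) drop(cbind(1, nd) %*% b)
  }
  unscrambled <- r_squared(prediction_set(y, ols(x, y)(x)))
  expect_gt(unscrambled, 0.9)
  sc <- y_scramble(x, y, ols, reps = 25, seed = 2)
  expect_length(sc$rs2, 25L)
  expect_lt(sc$mean_rs2, 0.15)
  sc2 <- y_scramble(x, y, ols, reps = 25, seed = 2)
  expect_identical(sc$rs2, sc2$rs2)
  expect_error(y_scramble(x, y, ols, reps = 0), "reps")
})
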