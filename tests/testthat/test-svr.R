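test_that("SVR configurations validate their mode-specific parameter", {
  c1 <- svr_config("epsilon", C = 10, gamma = 1, epsilon = 0.01)
  expect_true(is.na(c1$nu))
  c2 <- svr_config("nu", C = 10, gamma = 1, nu = 0.5)
  expect_true(is.na(c2$epsilon))
  expect_error(svr_config("epsilon", C = -1, gamma = 1))
  expect_error(svr_config("nu", C = 1, gamma = 1, nu = 1.5))
})

test_that("a fitted SVR reproduces flat, smooth, and duplicated targets", {
  x <- matrix(seq(0, 2 * pi, length.out = 50), ncol = 1,
              dimnames = list(NULL, "t"))
  flat <- fit_svr(x, rep(2.5, 50),
                  svr_config("epsilon", C = 10, gamma = 1,
                             epsilon = 0.01))
  expect_true(all(abs(predict(flat, x) - 2.5) < 0.011))

  y <- sin(x[, 1])
  fit <- fit_svr(x, y, svr_config("epsilon", C = 10, gamma = 1,
                                  epsilon = 0.01))
  rmse <- sqrt(mean((predict(fit, x) - y)^2))
  expect_lt(rmse, 0.05)

  nufit <- fit_svr(x, y, svr_config("nu", C = 10, gamma = 1, nu = 0.5))
  expect_lt(sqrt(mean((predict(nufit, x) - y)^2)), 0.05)

  xdup <- rbind(x, x[1, , drop = FALSE])
  fitd <- fit_svr(xdup, c(y, y[1]),
                  svr_config("epsilon", C = 5, gamma = 1, epsilon = 0.05))
  pd <- predict(fitd, xdup)
  expect_equal(pd[1], pd[51])

  expect_error(fit_svr(matrix(c(1, NA), 2, 1), c(1, 2),
                       svr_config("epsilon", C = 1, gamma = 1)),
               "finite")
})

test_that("grid search is exhaustive with a deterministic tie-break", {
  set.seed(71)
  x <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(x %*% c(1, -1))
  single <- svr_grid(C = 4, gamma = 0.25, epsilon = 0.1)
  gs <- grid_search(x, y, single, cv_folds = 4)
  expect_equal(gs$best$C, 4)
  expect_equal(nrow(gs$scores), 1L)

  grid <- svr_grid(C = 4^(0:2), gamma = 4^(-2:0), epsilon = c(0.05, 0.1))
  gs2 <- grid_search(x, y, grid, cv_folds = 4, seed = 2)
  expect_equal(gs2$score, max(gs2$scores$score))
  # selected score dominates every other lattice point
  expect_true(all(gs2$scores$score <= gs2$score + 1e-12))

  # ties resolve to the earliest grid entry: scoring a constant-zero
  # response makes many configs equivalent
  gs3 <- grid_search(x, rnorm(40), grid, cv_folds = 4, seed = 3)
  first_max <- which.max(gs3$scores$score)
  expect_equal(gs3$best$C, gs3$scores$C[first_max])
  expect_error(grid_search(x, y, list()), "empty")
})

test_that("holdout selection recovers a generating configuration's quality", {
  set.seed(72)
  xtr <- matrix(runif(120, -2, 2), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  gen_cfg <- svr_config("epsilon", C = 16, gamma = 0.5, epsilon = 0.01)
  teacher <- fit_svr(xtr, sin(xtr[, 1]) + 0.5 * xtr[, 2], gen_cfg)
  y_clean <- predict(teacher, xtr)   # noiseless target the lattice contains
  xval <- matrix(runif(60, -2, 2), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  yval <- predict(teacher, xval)
  grid <- svr_grid(C = 4^(-1:3), gamma = 4^(-2:1), epsilon = c(0.01, 0.1))
  gs <- grid_search(xtr, y_clean, grid, selection = "holdout",
                    x_val = xval, y_val = yval)
  expect_gte(gs$score, 0.99)
  expect_true(all(gs$scores$score <= gs$score + 1e-12))
})

test_that("stacking identical members reproduces the member; mixed members improve", {
  set.seed(73)
  x <- matrix(runif(100, -2, 2), ncol = 1, dimnames = list(NULL, "a"))
  y <- sin(x[, 1]) + rnorm(100, sd = 0.05)
  cfg <- svr_config("epsilon", C = 10, gamma = 1, epsilon = 0.01)
  member <- fit_svr(x, y, cfg, subset = "a")
  ens_same <- structure(list(members = list(member, member, member),
                             candidate_index = 1:3),
                        class = "svr_ensemble")
  hs <- fit_meta(ens_same, x, y,
                 meta_grid = svr_grid(C = 1000, gamma = 0.5,
                                      epsilon = 0.001))
  # identity up to the dual solver's practical accuracy on clustered
  # meta inputs
  expect_lt(max(abs(predict(hs, x) - predict(member, x))), 0.05)

  # biased members: one under-, one over-estimating; the meta layer
  # must do at least as well as the best member (small slack)
  under <- member; over <- member
  under$fit$rho <- under$fit$rho + 0.5   # shifts predictions down
  over$fit$rho <- over$fit$rho - 0.5
  rmse <- function(p) sqrt(mean((p - y)^2))
  ens_bias <- structure(list(members = list(under, over),
                             candidate_index = 1:2),
                        class = "svr_ensemble")
  hs2 <- fit_meta(ens_bias, x, y,
                  meta_grid = svr_grid(C = 4^(0:3), gamma = 4^(-2:1),
                                       epsilon = 0.01))
  best_member <- min(rmse(predict(under, x)), rmse(predict(over, x)))
  expect_lte(rmse(predict(hs2, x)), best_member + 0.05)
})

test_that("hierarchical predictions compose members through the meta layer", {
  set.seed(74)
  dat <- generate_skin_data(synthetic_spec(n_compounds = 80, seed = 8))
  x <- normalize_table(dat$table)$values
  y <- dat$records$log_kp
  fit <- hsvr(x, y,
              subsets = list(c("log_P", "V_m"), c("log_P", "chi0")),
              grid = svr_grid(C = 4^(0:2), gamma = 4^(-2:0),
                              epsilon = 0.1),
              cv_folds = 3, seed = 1)
  # composition: meta applied to member predictions
  z <- member_predictions(fit$ensemble, x)
  expect_equal(predict(fit, x), unname(predict(fit$meta$fit, z)))
  # permutation equivariance
  perm <- sample(nrow(x))
  expect_equal(predict(fit, x[perm, ]), predict(fit, x)[perm])
  # single record
  one <- predict(fit, x[3, , drop = FALSE])
  expect_length(one, 1L)
  expect_true(is.finite(one))
  # missing descriptor is named in the error
  expect_error(predict(fit, x[, c("log_P", "V_m"), drop = FALSE]),
               "chi0")
  expect_equal(residuals(fit), y - fit$fitted)
})

test_that("model descriptions serialize to JSON", {
  set.seed(75)
  dat <- generate_skin_data(synthetic_spec(n_compounds = 40, seed = 9))
  x <- normalize_table(dat$table)$values
  fit <- hsvr(x, dat$records$log_kp,
              subsets = list(c("log_P", "V_m")),
              grid = svr_grid(C = 4, gamma = 0.25, epsilon = 0.1),
              cv_folds = 3)
  p <- tempfile(fileext = ".json")
  write_hsvr_model(fit, p)
  back <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_length(back$members, 1L)
  expect_equal(unlist(back$members[[1]]$subset), c("log_P", "V_m"))
})
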