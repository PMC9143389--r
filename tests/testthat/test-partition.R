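test_that("PCA projection recovers dimensionality and variance structure", {
  # rank-1: points on a line concentrate all variance in component 1
  set.seed(31)
  t1 <- seq(-3, 3, length.out = 40)
  line <- cbind(a = 2 * t1, b = -t1)
  tbl <- normalize_table(descriptor_table(line, paste0("c", 1:40),
                                          c("a", "b")))
  pr <- pca_project(tbl, n_components = 2)
  expect_equal(pr$explained_variance[1], 1.0, tolerance = 1e-9)

  # isotropic Gaussian spreads variance evenly
  set.seed(32)
  iso <- matrix(rnorm(1500), ncol = 3,
                dimnames = list(paste0("c", 1:500), c("x", "y", "z")))
  tbl3 <- descriptor_table(iso, rownames(iso), colnames(iso))
  pr3 <- pca_project(normalize_table(tbl3), n_components = 3)
  expect_true(all(abs(pr3$explained_variance - 1 / 3) < 0.05))
  expect_true(all(diff(pr3$explained_variance) <= 0))
  expect_true(all(pr3$explained_variance >= 0))
  expect_lte(sum(pr3$explained_variance), 1 + 1e-12)

  # k = p back-rotation reproduces the centered data
  recon <- pr3$scores %*% t(pr3$rotation)
  centered <- sweep(normalize_table(tbl3)$values, 2, pr3$center)
  expect_equal(recon, centered, tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(pca_project(tbl3, n_components = 9), "exceeds")
})

test_that("structural outliers trip on rotatable-bond or oxygen counts", {
  v <- cbind(N_rot = c(8, 7, 7, 12), N_O = c(2, 11, 10, 1),
             log_P = c(1, 2, 3, 4))
  tbl <- descriptor_table(v, paste0("c", 1:4), colnames(v))
  rec <- data.frame(id = paste0("c", 1:4))
  flagged <- flag_outliers(rec, tbl)
  expect_setequal(flagged, c("c1", "c2", "c4"))
  expect_false("c3" %in% flagged)
  tbl2 <- descriptor_table(v[, "log_P", drop = FALSE],
                           paste0("c", 1:4), "log_P")
  expect_error(flag_outliers(rec, tbl2), "N_rot")
})

test_that("the diverse split honors the 4:1 ratio and is deterministic", {
  set.seed(33)
  sc <- matrix(rnorm(91 * 3), ncol = 3)
  ids <- paste0("c", 1:91)
  sp <- diverse_split(sc, ids, train_fraction = 0.8, seed = 5)
  expect_length(sp$train_ids, 73L)
  expect_length(sp$test_ids, 18L)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)

  sp2 <- diverse_split(sc, ids, train_fraction = 0.8, seed = 5)
  expect_identical(sp$test_ids, sp2$test_ids)

  tiny <- diverse_split(matrix(rnorm(10), ncol = 2), paste0("c", 1:5),
                        train_fraction = 0.8, seed = 1)
  expect_length(tiny$train_ids, 4L)
  expect_length(tiny$test_ids, 1L)

  expect_error(diverse_split(matrix(rnorm(8), ncol = 2),
                             paste0("c", 1:4), seed = 1), "few")
})

test_that("farthest-point selection spreads the test set through score space", {
  # two well-separated clusters: a diverse test set must draw from both
  set.seed(34)
  sc <- rbind(matrix(rnorm(60, 0), ncol = 2),
              matrix(rnorm(60, 10), ncol = 2))
  ids <- paste0("c", 1:60)
  sp <- diverse_split(sc, ids, train_fraction = 0.8, seed = 2)
  test_idx <- match(sp$test_ids, ids)
  expect_gt(sum(test_idx <= 30), 0)
  expect_gt(sum(test_idx > 30), 0)
})

test_that("distribution reports quantify train/test similarity", {
  set.seed(35)
  a <- data.frame(log_kp = rnorm(100), mw = runif(100, 50, 500))
  same <- distribution_report(a, a, c("log_kp", "mw"))
  expect_length(same, 2L)
  expect_equal(same$log_kp$ks_statistic, 0)
  expect_equal(same$mw$ks_statistic, 0)

  b <- data.frame(log_kp = rnorm(100, 5))
  shift <- distribution_report(a, b, "log_kp")
  expect_length(shift, 1L)
  expect_gt(shift$log_kp$ks_statistic, 0.9)
  expect_equal(length(shift$log_kp$train_density), 10L)

  expect_error(distribution_report(a, data.frame(), "log_kp"), "absent")
})

test_that("split files round-trip subset membership", {
  sp <- diverse_split(matrix(rnorm(40), ncol = 2), paste0("c", 1:20),
                      seed = 3)
  dir <- tempfile("split_")
  write_split(sp, dir)
  tr <- read.csv(file.path(dir, "train.csv"))
  te <- read.csv(file.path(dir, "test.csv"))
  expect_setequal(tr$id, sp$train_ids)
  expect_setequal(te$id, sp$test_ids)
})
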