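# Independent brute-force oracles for the validation statistics:
# explicit element-by-element summation, written against the defining
# formulas and kept free of any package internals.

oracle_stats <- function(y, yh, train_mean = NULL, train_y = NULL) {
  n <- length(y)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- y[i] - yh[i]

  ssd <- 0; sad <- 0; dmax <- 0; dsum <- 0
  for (i in seq_len(n)) {
    ssd <- ssd + d[i]^2
    sad <- sad + abs(d[i])
    if (abs(d[i]) > dmax) dmax <- abs(d[i])
    dsum <- dsum + d[i]
  }
  dbar <- dsum / n
  s2 <- 0
  for (i in seq_len(n)) s2 <- s2 + (d[i] - dbar)^2

  my <- 0; myh <- 0
  for (i in seq_len(n)) { my <- my + y[i]; myh <- myh + yh[i] }
  my <- my / n; myh <- myh / n

  ss_obs <- 0; ss_pred_ctr <- 0
  for (i in seq_len(n)) {
    ss_obs <- ss_obs + (y[i] - my)^2
    ss_pred_ctr <- ss_pred_ctr + (y[i] - myh)^2
  }

  # concordance correlation coefficient
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y[i] - my) * (yh[i] - myh)
    sxx <- sxx + (y[i] - my)^2
    syy <- syy + (yh[i] - myh)^2
  }
  ccc <- 2 * sxy / (sxx + syy + n * (my - myh)^2)

  # through-origin regressions
  syyh <- 0; sy2 <- 0; syh2 <- 0
  for (i in seq_len(n)) {
    syyh <- syyh + y[i] * yh[i]
    sy2 <- sy2 + y[i]^2
    syh2 <- syh2 + yh[i]^2
  }
  k <- syyh / sy2
  kp <- syyh / syh2
  num0 <- 0; den0 <- 0; num0p <- 0; den0p <- 0
  for (i in seq_len(n)) {
    num0 <- num0 + (yh[i] - k * y[i])^2
    den0 <- den0 + (yh[i] - myh)^2
    num0p <- num0p + (y[i] - kp * yh[i])^2
    den0p <- den0p + (y[i] - my)^2
  }

  out <- list(
    rmse = sqrt(ssd / n),
    mae = sad / n,
    s = sqrt(s2 / (n - 1)),
    delta_max = dmax,
    mean_error = dbar,
    r2_obs = 1 - ssd / ss_obs,
    r2_pred = 1 - ssd / ss_pred_ctr,
    ccc = ccc,
    k = k,
    r0_sq = 1 - num0 / den0,
    r0_prime_sq = 1 - num0p / den0p)

  if (!is.null(train_mean) && !is.null(train_y)) {
    n_tr <- length(train_y)
    mtr <- 0
    for (i in seq_len(n_tr)) mtr <- mtr + train_y[i]
    mtr <- mtr / n_tr
    ss_tr <- 0
    for (i in seq_len(n_tr)) ss_tr <- ss_tr + (train_y[i] - mtr)^2
    ss_f1 <- 0
    for (i in seq_len(n)) ss_f1 <- ss_f1 + (y[i] - train_mean)^2
    out$qF1 <- 1 - ssd / ss_f1
    out$qF2 <- 1 - ssd / ss_obs
    out$qF3 <- 1 - (ssd / n) / (ss_tr / n_tr)
  }
  out
}

oracle_rm2 <- function(r2, r0, r0p, sqrt_variant = FALSE) {
  pen1 <- abs(r2 - r0); pen2 <- abs(r2 - r0p)
  if (sqrt_variant) { pen1 <- sqrt(pen1); pen2 <- sqrt(pen2) }
  rm2 <- r2 * (1 - pen1)
  rm2p <- r2 * (1 - pen2)
  list(rm2 = rm2, rm2_prime = rm2p,
       rm2_avg = (rm2 + rm2p) / 2, rm2_delta = abs(rm2 - rm2p))
}

# a validation_report built from externally supplied statistics (for
# checking the criteria logic against published report tables)
report_from_stats <- function(set_role, r2, q2_cv = NA, qF1 = NA,
                              qF2 = NA, qF3 = NA, ccc = NA, k, r0_sq,
                              r0_prime_sq, rm2, rm2_prime) {
  structure(list(set_role = set_role, n = NA_integer_, r2 = r2,
                 q2_cv = q2_cv, qF1 = qF1, qF2 = qF2, qF3 = qF3,
                 ccc = ccc, rmse = NA_real_, mae = NA_real_,
                 s = NA_real_, delta_max = NA_real_,
                 mean_error = NA_real_, k = k, r0_sq = r0_sq,
                 r0_prime_sq = r0_prime_sq, rm2 = rm2,
                 rm2_prime = rm2_prime,
                 rm2_avg = (rm2 + rm2_prime) / 2,
                 rm2_delta = abs(rm2 - rm2_prime)),
            class = "validation_report")
}

# the published validation table: training/test/outlier statistics of
# the stacked kernel model (hsvr) and the linear model (pls)
published_reports <- function() {
  list(
    hsvr_train = report_from_stats("training", r2 = 0.93, q2_cv = 0.90,
      k = 1.01, r0_sq = 0.93, r0_prime_sq = 0.92,
      rm2 = 0.91, rm2_prime = 0.85),
    pls_train = report_from_stats("training", r2 = 0.80, q2_cv = 0.90,
      k = 1.00, r0_sq = 0.80, r0_prime_sq = 0.76,
      rm2 = 0.80, rm2_prime = 0.64),
    hsvr_test = report_from_stats("external", r2 = 0.84, qF1 = 0.83,
      qF2 = 0.83, qF3 = 0.90, ccc = 0.92,
      k = 0.97, r0_sq = 0.84, r0_prime_sq = 0.83,
      rm2 = 0.80, rm2_prime = 0.75),
    pls_test = report_from_stats("external", r2 = 0.58, qF1 = 0.42,
      qF2 = 0.41, qF3 = 0.66, ccc = 0.75,
      k = 0.94, r0_sq = 0.45, r0_prime_sq = 0.57,
      rm2 = 0.37, rm2_prime = 0.52),
    hsvr_outlier = report_from_stats("external", r2 = 0.86, qF1 = 0.85,
      qF2 = 0.83, qF3 = 0.73, ccc = 0.91,
      k = 1.08, r0_sq = 0.86, r0_prime_sq = 0.85,
      rm2 = 0.81, rm2_prime = 0.80),
    pls_outlier = report_from_stats("external", r2 = 0.74, qF1 = -0.59,
      qF2 = -0.84, qF3 = -1.93, ccc = 0.64,
      k = 0.66, r0_sq = 0.51, r0_prime_sq = 0.72,
      rm2 = 0.38, rm2_prime = 0.63))
}

# write a small descriptor CSV; vals is a named list of columns
write_fixture_csv <- function(path, ...) {
  df <- data.frame(..., check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
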