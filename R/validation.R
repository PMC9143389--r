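#' Bundle observed and predicted responses for validation
#'
#' A prediction set pairs observed log Kp values with model predictions
#' for one dataset (training, test, or outlier). External-validation
#' statistics that reference the training distribution (qF1, qF3)
#' additionally need the training-set mean response and size.
#'
#' @param y_obs observed responses.
#' @param y_pred predicted responses (same length, >= 2).
#' @param ids optional compound ids.
#' @param train_mean optional mean observed response of the training
#'   set (required for \code{\link{external_q2}}).
#' @param train_n optional training-set size (required for qF3).
#' @return An object of class \code{"prediction_set"}.
#' @export
prediction_set <- function(y_obs, y_pred, ids = NULL,
                           train_mean = NULL, train_n = NULL) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  if (length(y_obs) != length(y_pred))
    stop("y_obs and y_pred must have equal length")
  if (length(y_obs) < 2) stop("need at least two observations")
  if (any(!is.finite(y_obs)) || any(!is.finite(y_pred)))
    stop("non-finite values in prediction set")
  structure(list(ids = ids, y_obs = y_obs, y_pred = y_pred,
                 train_mean = train_mean, train_n = train_n),
            class = "prediction_set")
}

#' Prediction residuals
#'
#' The residual for compound i is observed minus predicted,
#' Delta_i = y_i - yhat_i.
#'
#' @param p a \code{\link{prediction_set}}.
#' @return Numeric vector of residuals.
#' @export
prediction_residuals <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  p$y_obs - p$y_pred
}

#' Scalar error statistics of a prediction set
#'
#' @param p a \code{\link{prediction_set}}.
#' @return A list: \code{rmse} (root mean square error, n denominator),
#'   \code{mae} (mean absolute error), \code{s} (sample standard
#'   deviation of the residuals, n - 1 denominator), \code{delta_max}
#'   (largest absolute residual), \code{mean_error} (mean residual,
#'   signed; nonzero values indicate systematic bias).
#' @export
error_stats <- function(p) {
  d <- prediction_residuals(p)
  list(rmse = sqrt(mean(d^2)),
       mae = mean(abs(d)),
       s = stats::sd(d),
       delta_max = max(abs(d)),
       mean_error = mean(d))
}

#' Squared correlation coefficient (r2 / q2) of predictions
#'
#' Computes 1 - sum(Delta^2) / sum((y - c)^2). The conventional choice
#' centers on the observed mean (c = mean(y_obs)); a variant centering
#' on the predicted mean (c = mean(y_pred)) is selectable, as some
#' QSAR reports print the formula that way. Applied to a training set
#' this is r2; applied to an external set, q2.
#'
#' @param p a \code{\link{prediction_set}}.
#' @param centering \code{"observed_mean"} (default) or
#'   \code{"predicted_mean"}.
#' @return The squared correlation coefficient (can be negative for
#'   models worse than the mean).
#' @export
r_squared <- function(p, centering = c("observed_mean", "predicted_mean")) {
  centering <- match.arg(centering)
  d <- prediction_residuals(p)
  ctr <- if (centering == "observed_mean") mean(p$y_obs) else mean(p$y_pred)
  denom <- sum((p$y_obs - ctr)^2)
  if (denom <= 0) stop("zero denominator: observations do not vary about the centering value")
  1 - sum(d^2) / denom
}

#' External-validation determination coefficients qF1, qF2, qF3
#'
#' Three external q2 flavours differing in reference mean and
#' normalization: qF1 centers the denominator on the training-set mean
#' response; qF2 on the external-set mean; qF3 compares the external
#' mean squared error against the training-set response variance
#' (per-sample normalization with n_EXT and n_TR).
#'
#' @param p a \code{\link{prediction_set}} with \code{train_mean} set
#'   (and \code{train_n} plus \code{train_y} information via
#'   \code{train_ss}; see Details) .
#' @param train_ss total sum of squares of the training responses about
#'   their mean, sum((y_TR - mean(y_TR))^2). Required for qF3.
#' @return A list with \code{qF1}, \code{qF2}, \code{qF3}.
#' @details qF3 needs the training responses' spread, supplied as
#'   \code{train_ss} together with \code{p$train_n}; qF1 needs only the
#'   training mean.
#' @export
external_q2 <- function(p, train_ss = NULL) {
  stopifnot(inherits(p, "prediction_set"))
  if (is.null(p$train_mean))
    stop("train_mean is required for external q2 statistics")
  d <- prediction_residuals(p)
  n_ext <- length(p$y_obs)
  qF1 <- 1 - sum(d^2) / sum((p$y_obs - p$train_mean)^2)
  qF2 <- 1 - sum(d^2) / sum((p$y_obs - mean(p$y_obs))^2)
  qF3 <- NA_real_
  if (!is.null(train_ss) && !is.null(p$train_n))
    qF3 <- 1 - (sum(d^2) / n_ext) / (train_ss / p$train_n)
  list(qF1 = qF1, qF2 = qF2, qF3 = qF3)
}

#' Concordance correlation coefficient
#'
#' CCC penalizes both poor correlation and location/scale shifts
#' between observed and predicted values:
#' 2 * sum((y - my)(yhat - myhat)) /
#' (sum((y - my)^2) + sum((yhat - myhat)^2) + n (my - myhat)^2).
#' It is symmetric in its two arguments, unlike r2.
#'
#' @param p a \code{\link{prediction_set}}.
#' @return CCC in [-1, 1].
#' @export
ccc <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  y <- p$y_obs; yh <- p$y_pred
  my <- mean(y); myh <- mean(yh)
  n <- length(y)
  num <- 2 * sum((y - my) * (yh - myh))
  den <- sum((y - my)^2) + sum((yh - myh)^2) + n * (my - myh)^2
  num / den
}

#' Through-origin regression diagnostics (k, r0^2, r0'^2)
#'
#' Fits predicted-vs-observed regression lines forced through the
#' origin. \code{k} is the slope of the through-origin fit of predicted
#' on observed; \code{r0_sq} is the determination coefficient of that
#' fit (computed against deviations from the mean, after the
#' Golbraikh-Tropsha formulation); \code{r0_prime_sq} repeats with the
#' axes swapped (observed on predicted). A predictive model should
#' have k near 1 and r0^2 close to the unconstrained r2.
#'
#' @param p a \code{\link{prediction_set}}.
#' @return A list with \code{k}, \code{r0_sq}, \code{r0_prime_sq}.
#' @export
origin_regression <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  y <- p$y_obs; yh <- p$y_pred
  if (sum(y^2) <= 0 || sum(yh^2) <= 0)
    stop("through-origin regression undefined for all-zero values")
  # slope of yhat = k * y (no intercept)
  k <- sum(y * yh) / sum(y^2)
  # R2 of the constrained fit, measured about the mean of the
  # dependent variable (Golbraikh-Tropsha convention)
  r0 <- 1 - sum((yh - k * y)^2) / sum((yh - mean(yh))^2)
  kp <- sum(y * yh) / sum(yh^2)
  r0p <- 1 - sum((y - kp * yh)^2) / sum((y - mean(y))^2)
  list(k = k, r0_sq = r0, r0_prime_sq = r0p)
}

#' The rm2 family of validation metrics
#'
#' Contrasts the unconstrained determination coefficient r2 with its
#' through-origin counterparts r0^2 and r0'^2. Two variants are
#' provided: \code{"as_printed"} computes rm2 = r2 (1 - |r2 - r0^2|),
#' the form some reports print; \code{"sqrt"} computes
#' rm2 = r2 (1 - sqrt(|r2 - r0^2|)), the original Ojha-style
#' definition. The primed version uses r0'^2; the average and spread
#' are (rm2 + rm2')/2 and |rm2 - rm2'|.
#'
#' @param r2 unconstrained determination coefficient (r2 on a training
#'   set, q2 on an external set).
#' @param r0_sq,r0_prime_sq through-origin determination coefficients
#'   (see \code{\link{origin_regression}}).
#' @param variant \code{"as_printed"} (default) or \code{"sqrt"}.
#' @return A list with \code{rm2}, \code{rm2_prime}, \code{rm2_avg},
#'   \code{rm2_delta}.
#' @export
rm2_family <- function(r2, r0_sq, r0_prime_sq,
                       variant = c("as_printed", "sqrt")) {
  variant <- match.arg(variant)
  for (v in c(r2 = r2, r0_sq = r0_sq, r0_prime_sq = r0_prime_sq))
    if (is.finite(v) && (v < 0 || v > 1))
      warning("rm2 inputs outside [0, 1]; interpret with care")
  pen <- function(a, b)
    if (variant == "sqrt") sqrt(abs(a - b)) else abs(a - b)
  rm2 <- r2 * (1 - pen(r2, r0_sq))
  rm2p <- r2 * (1 - pen(r2, r0_prime_sq))
  list(rm2 = rm2, rm2_prime = rm2p,
       rm2_avg = (rm2 + rm2p) / 2,
       rm2_delta = abs(rm2 - rm2p))
}

#' Summarize an (rm2, rm2') pair
#'
#' The average and absolute spread of the two rm2 variants,
#' (rm2 + rm2')/2 and |rm2 - rm2'|; useful when the pair is given
#' directly (e.g. from a published table) rather than derived from
#' correlation coefficients.
#'
#' @param rm2,rm2_prime the rm2 metrics with and without axis swap.
#' @return A list with \code{rm2_avg} and \code{rm2_delta}.
#' @export
rm2_summary <- function(rm2, rm2_prime) {
  list(rm2_avg = (rm2 + rm2_prime) / 2,
       rm2_delta = abs(rm2 - rm2_prime))
}

#' Full validation report for one prediction set
#'
#' Computes the complete statistic battery for one (observed,
#' predicted) pairing: error statistics, r2/q2, external q2 flavours
#' and CCC (when training references are available), through-origin
#' diagnostics, and the rm2 family.
#'
#' @param p a \code{\link{prediction_set}}.
#' @param set_role \code{"training"} or \code{"external"}; controls
#'   which r2 enters the rm2 family and which criteria later apply.
#' @param q2_cv optional cross-validated q2 (training sets; see
#'   \code{\link{kfold_cv}}).
#' @param train_ss training response sum of squares for qF3 (external
#'   sets).
#' @param centering passed to \code{\link{r_squared}}.
#' @param rm2_variant passed to \code{\link{rm2_family}}.
#' @return An object of class \code{"validation_report"} (a list of
#'   named statistics; external-only fields are \code{NA} for training
#'   sets and vice versa).
#' @export
validation_report <- function(p, set_role = c("training", "external"),
                              q2_cv = NULL, train_ss = NULL,
                              centering = "observed_mean",
                              rm2_variant = "as_printed") {
  set_role <- match.arg(set_role)
  es <- error_stats(p)
  r2 <- r_squared(p, centering = centering)
  orr <- origin_regression(p)
  rm2 <- rm2_family(r2, orr$r0_sq, orr$r0_prime_sq, variant = rm2_variant)
  ext <- list(qF1 = NA_real_, qF2 = NA_real_, qF3 = NA_real_)
  ccc_v <- NA_real_
  if (set_role == "external") {
    if (!is.null(p$train_mean)) ext <- external_q2(p, train_ss = train_ss)
    ccc_v <- ccc(p)
  }
  structure(c(list(set_role = set_role, n = length(p$y_obs),
                   r2 = r2, q2_cv = if (is.null(q2_cv)) NA_real_ else q2_cv),
              ext, list(ccc = ccc_v), es, orr, rm2),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 2, ...) {
  cat(sprintf("Validation report (%s set, n = %d)\n", x$set_role, x$n))
  lab <- if (x$set_role == "training") "r2" else "q2"
  row <- function(name, v) if (is.finite(v))
    cat(sprintf("  %-10s %.*f\n", name, digits, v))
  row(lab, x$r2); row("q2_cv", x$q2_cv)
  row("qF1^2", x$qF1); row("qF2^2", x$qF2); row("qF3^2", x$qF3)
  row("CCC", x$ccc)
  row("Delta_max", x$delta_max); row("MAE", x$mae)
  row("s", x$s); row("RMSE", x$rmse)
  row("k", x$k); row("r0^2", x$r0_sq); row("r0'^2", x$r0_prime_sq)
  row("rm2", x$rm2); row("rm2'", x$rm2_prime)
  row("<rm2>", x$rm2_avg); row("delta rm2", x$rm2_delta)
  invisible(x)
}

# strict a < b that treats values numerically equal to the bound as not
# less: two-decimal report inputs like |0.80 - 0.90| sit exactly on a
# 0.10 bound, and double arithmetic must not sneak them under it
.lt_strict <- function(a, b) {
  (b - a) > sqrt(.Machine$double.eps) * max(1, abs(a), abs(b))
}

#' Stringent model-acceptance criteria check
#'
#' Evaluates the combined Golbraikh-Tropsha / Ojha / Roy /
#' Chirico-Gramatica acceptance rules against a training-set and an
#' external-set validation report:
#' \enumerate{
#'   \item every available determination coefficient (r2, q2_cv, q2,
#'     qF1, qF2, qF3) >= 0.70;
#'   \item |r2 - q2_cv| < 0.10 (training sets only);
#'   \item (r2 - r0^2)/r2 < 0.10 and 0.85 <= k <= 1.15;
#'   \item |r0^2 - r0'^2| < 0.30;
#'   \item rm2 >= 0.65;
#'   \item <rm2> >= 0.65 and delta rm2 < 0.20;
#'   \item CCC >= 0.85.
#' }
#' On external sets, r2 means q2 throughout. A criterion whose
#' statistics are absent from a report (e.g. q2_cv on an external set,
#' or CCC when never computed) is marked not-applicable and excluded
#' from the overall verdict.
#'
#' @param train_report \code{\link{validation_report}} of the training
#'   set (or \code{NULL} to check an external set alone).
#' @param external_report \code{\link{validation_report}} of an
#'   external set (or \code{NULL}).
#' @return An object of class \code{"criteria_verdict"}: per-set named
#'   logical vectors (\code{NA} = not applicable) plus \code{overall}.
#' @export
criteria_check <- function(train_report = NULL, external_report = NULL) {
  one_set <- function(rep) {
    if (is.null(rep)) return(NULL)
    r2 <- rep$r2
    coefs <- c(r2 = r2, q2_cv = rep$q2_cv, qF1 = rep$qF1,
               qF2 = rep$qF2, qF3 = rep$qF3)
    coefs <- coefs[is.finite(coefs)]
    v <- c(
      coefficients_070 = all(coefs >= 0.70),
      r2_q2cv_gap = if (rep$set_role == "training" && is.finite(rep$q2_cv))
        .lt_strict(abs(r2 - rep$q2_cv), 0.10) else NA,
      origin_r2_and_slope = .lt_strict((r2 - rep$r0_sq) / r2, 0.10) &&
        rep$k >= 0.85 && rep$k <= 1.15,
      r0_r0prime_gap = .lt_strict(abs(rep$r0_sq - rep$r0_prime_sq), 0.30),
      rm2_065 = rep$rm2 >= 0.65,
      rm2_avg_delta = rep$rm2_avg >= 0.65 &&
        .lt_strict(rep$rm2_delta, 0.20),
      ccc_085 = if (is.finite(rep$ccc)) rep$ccc >= 0.85 else NA)
    v
  }
  train <- one_set(train_report)
  external <- one_set(external_report)
  applicable <- c(train, external)
  overall <- all(applicable[!is.na(applicable)])
  structure(list(train = train, external = external, overall = overall),
            class = "criteria_verdict")
}

#' @export
print.criteria_verdict <- function(x, ...) {
  show <- function(v, label) {
    if (is.null(v)) return()
    cat(label, ":\n", sep = "")
    for (nm in names(v))
      cat(sprintf("  %-22s %s\n", nm,
                  if (is.na(v[[nm]])) "n/a" else
                    if (v[[nm]]) "fulfilled" else "FAILED"))
  }
  show(x$train, "Training set")
  show(x$external, "External set")
  cat("Overall:", if (x$overall) "fulfilled" else "FAILED", "\n")
  invisible(x)
}

#' k-fold cross-validated q2
#'
#' Assigns samples to folds at random under a fixed seed, fits the
#' supplied model on each training complement, pools the out-of-fold
#' predictions, and scores them with \code{\link{r_squared}}.
#'
#' @param x predictor matrix.
#' @param y response vector.
#' @param fitter function(x_train, y_train) returning an object with a
#'   \code{predict(object, newdata_matrix)} method, or a function
#'   returning a prediction function.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param centering passed to \code{\link{r_squared}}.
#' @return The cross-validated q2 (scalar).
#' @export
kfold_cv <- function(x, y, fitter, folds = 10, seed = 1,
                     centering = "observed_mean") {
  x <- as.matrix(x)
  n <- length(y)
  if (folds < 2 || folds > n) stop("folds must lie in [2, n]")
  set.seed(seed)
  assign <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- assign == f
    fit <- fitter(x[!hold, , drop = FALSE], y[!hold])
    pf <- if (is.function(fit)) fit else function(m) stats::predict(fit, m)
    pred[hold] <- pf(x[hold, , drop = FALSE])
  }
  r_squared(prediction_set(y, pred), centering = centering)
}

#' Y-scrambling (response randomization) test
#'
#' Estimates the level of chance correlation by repeatedly permuting
#' the response, refitting the model with the descriptors unchanged,
#' and recording the training r2 of each scrambled fit. A sound model
#' shows a near-zero mean scrambled r2 alongside a high unscrambled
#' r2.
#'
#' @param x predictor matrix.
#' @param y response vector.
#' @param fitter as in \code{\link{kfold_cv}}.
#' @param reps number of reshuffles (default 25).
#' @param seed integer seed for the permutations.
#' @param centering passed to \code{\link{r_squared}}.
#' @return A list: \code{mean_rs2}, \code{rs2} (per-repetition vector).
#' @export
y_scramble <- function(x, y, fitter, reps = 25, seed = 1,
                       centering = "observed_mean") {
  x <- as.matrix(x)
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  rs2 <- vapply(seq_len(reps), function(r) {
    ys <- sample(y)
    fit <- fitter(x, ys)
    pf <- if (is.function(fit)) fit else function(m) stats::predict(fit, m)
    pred <- pf(x)
    # training r2 of the scrambled fit; a negative value is chance-level
    r_squared(prediction_set(ys, pred), centering = centering)
  }, numeric(1))
  list(mean_rs2 = mean(rs2), rs2 = rs2)
}
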