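#' SVR runtime configuration
#'
#' One RBF-kernel support vector regression configuration: the
#' formulation (epsilon- or nu-SVR), the cost C, the kernel width
#' gamma, and the tube parameter (epsilon, or the support-vector
#' fraction bound nu).
#'
#' @param mode \code{"epsilon"} or \code{"nu"}.
#' @param C positive cost.
#' @param gamma positive RBF kernel width, k(u, v) =
#'   exp(-gamma ||u - v||^2).
#' @param epsilon non-negative insensitivity tube half-width
#'   (epsilon mode).
#' @param nu in (0, 1] (nu mode).
#' @return An object of class \code{"svr_config"}.
#' @export
svr_config <- function(mode = c("epsilon", "nu"), C, gamma,
                       epsilon = 0.1, nu = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.finite(C), C > 0, is.finite(gamma), gamma > 0)
  if (mode == "epsilon") {
    stopifnot(is.finite(epsilon), epsilon >= 0)
    nu <- NA_real_
  } else {
    stopifnot(is.finite(nu), nu > 0, nu <= 1)
    epsilon <- NA_real_
  }
  structure(list(mode = mode, C = C, gamma = gamma,
                 epsilon = epsilon, nu = nu),
            class = "svr_config")
}

#' @export
print.svr_config <- function(x, ...) {
  cat(sprintf("%s-SVR (C = %g, gamma = %g, %s = %g)\n",
              x$mode, x$C, x$gamma,
              if (x$mode == "epsilon") "epsilon" else "nu",
              if (x$mode == "epsilon") x$epsilon else x$nu))
  invisible(x)
}

#' Default SVR hyperparameter lattice
#'
#' The systematic grid explored when none is given: C over powers of 4
#' from 2^-5 to 2^15, gamma over powers of 4 from 2^-15 to 2^3,
#' epsilon in \{0.01, 0.05, 0.1, 0.2\} (epsilon mode) or nu in
#' \{0.25, 0.5, 0.75\} (nu mode).
#'
#' @param mode \code{"epsilon"} or \code{"nu"}.
#' @param C,gamma,epsilon,nu optional value vectors overriding the
#'   defaults.
#' @return A list of \code{\link{svr_config}} objects ordered by
#'   ascending C, then gamma, then epsilon (or descending nu) -- the
#'   deterministic tie-break order of \code{\link{grid_search}}.
#' @export
svr_grid <- function(mode = c("epsilon", "nu"),
                     C = 2^seq(-5, 15, by = 2),
                     gamma = 2^seq(-15, 3, by = 2),
                     epsilon = c(0.01, 0.05, 0.1, 0.2),
                     nu = c(0.25, 0.5, 0.75)) {
  mode <- match.arg(mode)
  if (mode == "epsilon") {
    g <- expand.grid(tube = sort(epsilon), gamma = sort(gamma),
                     C = sort(C))
  } else {
    g <- expand.grid(tube = sort(nu, decreasing = TRUE),
                     gamma = sort(gamma), C = sort(C))
  }
  # expand.grid varies the first factor fastest; reorder so C is the
  # slowest-varying, matching the documented tie-break precedence
  g <- g[order(g$C, g$gamma,
               if (mode == "epsilon") g$tube else -g$tube), ]
  lapply(seq_len(nrow(g)), function(i)
    if (mode == "epsilon")
      svr_config("epsilon", C = g$C[i], gamma = g$gamma[i],
                 epsilon = g$tube[i])
    else
      svr_config("nu", C = g$C[i], gamma = g$gamma[i], nu = g$tube[i]))
}

#' Fit one RBF-kernel SVR member
#'
#' Solves the epsilon- or nu-SVR problem with the radial basis kernel
#' on the given descriptor columns. The member remembers its
#' descriptor subset and predicts only from it. Inputs are used as
#' supplied (autoscale beforehand; no internal rescaling).
#'
#' @param x numeric matrix (rows = compounds) or
#'   \code{\link{descriptor_table}}.
#' @param y response vector.
#' @param config an \code{\link{svr_config}}.
#' @param subset optional character vector of descriptor names; default
#'   all columns of \code{x}.
#' @return An object of class \code{"svr_member"}.
#' @export
fit_svr <- function(x, y, config, subset = NULL) {
  if (inherits(x, "descriptor_table")) x <- x$values
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(subset)) subset <- colnames(x)
  absent <- setdiff(subset, colnames(x))
  if (length(absent) > 0)
    stop("missing descriptor(s): ", paste(absent, collapse = ", "))
  xs <- x[, subset, drop = FALSE]
  if (nrow(xs) < 2) stop("need at least two training rows")
  if (any(!is.finite(xs)) || any(!is.finite(y)))
    stop("non-finite values in training data")
  stopifnot(inherits(config, "svr_config"))
  fit <- if (config$mode == "epsilon")
    e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
               cost = config$C, gamma = config$gamma,
               epsilon = config$epsilon, scale = FALSE, fitted = FALSE)
  else
    e1071::svm(xs, y, type = "nu-regression", kernel = "radial",
               cost = config$C, gamma = config$gamma,
               nu = config$nu, scale = FALSE, fitted = FALSE)
  structure(list(subset = subset, config = config, fit = fit),
            class = "svr_member")
}

#' @export
predict.svr_member <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) &&
      ncol(newdata) == length(object$subset))
    colnames(newdata) <- object$subset
  absent <- setdiff(object$subset, colnames(newdata))
  if (length(absent) > 0)
    stop("missing descriptor(s): ", paste(absent, collapse = ", "))
  nd <- newdata[, object$subset, drop = FALSE]
  # a fit whose residuals all sit inside the tube has no support
  # vectors; its regression function is the constant -rho
  if (object$fit$tot.nSV == 0)
    return(rep(-object$fit$rho, nrow(nd)))
  unname(stats::predict(object$fit, nd))
}

#' @export
print.svr_member <- function(x, ...) {
  cat("SVR member on {", paste(x$subset, collapse = ", "), "}: ",
      sep = "")
  print(x$config)
  invisible(x)
}

#' Systematic grid search over SVR configurations
#'
#' Evaluates every lattice point and returns the configuration
#' maximizing the selection score: either the cross-validated q2 on
#' the training rows (\code{selection = "cv"}, the default -- no
#' held-out information enters model selection) or the q2 on an
#' explicit validation set (\code{selection = "holdout"}, mirroring
#' workflows that pick winners on the test samples). Ties resolve to
#' the earliest grid entry, i.e. smaller C, then smaller gamma, then
#' smaller epsilon (larger nu).
#'
#' @param x,y training descriptor matrix and response.
#' @param grid list of \code{\link{svr_config}}s (see
#'   \code{\link{svr_grid}}).
#' @param selection \code{"cv"} or \code{"holdout"}.
#' @param x_val,y_val validation data (holdout selection only).
#' @param cv_folds,seed cross-validation controls (cv selection).
#' @param subset optional descriptor subset (passed to
#'   \code{\link{fit_svr}}).
#' @return A list: \code{best} (an \code{svr_config}), \code{score}
#'   (its selection q2), \code{scores} (data frame over the lattice).
#' @export
grid_search <- function(x, y, grid, selection = c("cv", "holdout"),
                        x_val = NULL, y_val = NULL,
                        cv_folds = 5, seed = 1, subset = NULL) {
  selection <- match.arg(selection)
  if (length(grid) == 0) stop("empty grid")
  if (inherits(x, "descriptor_table")) x <- x$values
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  if (selection == "holdout") {
    if (is.null(x_val) || is.null(y_val))
      stop("holdout selection needs x_val and y_val")
    if (inherits(x_val, "descriptor_table")) x_val <- x_val$values
    x_val <- as.matrix(x_val)[, colnames(x), drop = FALSE]
  }
  score_one <- function(cfg) {
    if (selection == "cv") {
      kfold_cv(x, y, folds = cv_folds, seed = seed,
               fitter = function(xt, yt) {
                 m <- fit_svr(xt, yt, cfg)
                 function(nd) predict(m, nd)
               })
    } else {
      m <- fit_svr(x, y, cfg)
      r_squared(prediction_set(y_val, predict(m, x_val)))
    }
  }
  scores <- vapply(grid, score_one, numeric(1))
  best <- which.max(scores)   # first maximum = documented tie-break
  tab <- data.frame(C = vapply(grid, `[[`, 0, "C"),
                    gamma = vapply(grid, `[[`, 0, "gamma"),
                    epsilon = vapply(grid, `[[`, 0, "epsilon"),
                    nu = vapply(grid, `[[`, 0, "nu"),
                    score = scores)
  list(best = grid[[best]], score = scores[best], scores = tab)
}

#' Assemble an SVR ensemble under the parsimony rule
#'
#' Searches member combinations of increasing size m = 1, 2, ...,
#' \code{max_members} and returns the first combination that passes
#' the acceptance functional: simpler ensembles are preferred, and no
#' combination of size m + 1 is ever evaluated before every size-m
#' combination has a verdict. The full evaluation trace is attached to
#' the result (and to the error, when nothing passes).
#'
#' @param candidates list of candidate members, each a list with
#'   \code{subset} (descriptor names) and \code{config}
#'   (\code{\link{svr_config}}).
#' @param x_train,y_train,x_test,y_test training and test data.
#' @param acceptance function(ensemble, x_train, y_train, x_test,
#'   y_test) returning a list with at least \code{pass} (logical);
#'   default \code{\link{criteria_acceptance}}.
#' @param max_members largest ensemble size tried (default 3).
#' @return An object of class \code{"svr_ensemble"}: list with
#'   \code{members} (fitted \code{svr_member}s, order fixed),
#'   \code{candidate_index}, \code{trace} (data frame: order, size,
#'   combination, pass). Errors with class
#'   \code{"skinperm_no_ensemble"} carry the trace and best
#'   diagnostics when no combination passes.
#' @export
assemble_ensemble <- function(candidates, x_train, y_train,
                              x_test, y_test,
                              acceptance = criteria_acceptance,
                              max_members = 3) {
  if (length(candidates) == 0) stop("empty candidate list")
  if (inherits(x_train, "descriptor_table")) x_train <- x_train$values
  if (inherits(x_test, "descriptor_table")) x_test <- x_test$values
  fitted <- lapply(candidates, function(cand)
    fit_svr(x_train, y_train, cand$config, subset = cand$subset))
  trace <- data.frame(order = integer(0), size = integer(0),
                      combination = character(0), pass = logical(0))
  step <- 0L
  best <- NULL
  for (m in seq_len(min(max_members, length(fitted)))) {
    combos <- utils::combn(length(fitted), m, simplify = FALSE)
    for (idx in combos) {
      step <- step + 1L
      ens <- structure(list(members = fitted[idx],
                            candidate_index = idx),
                       class = "svr_ensemble")
      res <- acceptance(ens, x_train, y_train, x_test, y_test)
      trace <- rbind(trace, data.frame(
        order = step, size = m,
        combination = paste(idx, collapse = "+"),
        pass = isTRUE(res$pass)))
      if (isTRUE(res$pass)) {
        ens$trace <- trace
        ens$acceptance <- res
        return(ens)
      }
      if (is.null(best) || isTRUE(res$score > best$score))
        best <- list(index = idx, score = res$score, details = res)
    }
  }
  cond <- structure(
    class = c("skinperm_no_ensemble", "error", "condition"),
    list(message = sprintf(
      "no ensemble of size <= %d passed the acceptance criteria",
      max_members),
      call = sys.call(-1), trace = trace, best = best))
  stop(cond)
}

#' @export
print.svr_ensemble <- function(x, ...) {
  cat(sprintf("SVR ensemble with %d member(s)\n", length(x$members)))
  for (m in x$members)
    cat("  -", paste(m$subset, collapse = ", "), "\n")
  invisible(x)
}

#' Ensemble acceptance by the stringent validation criteria
#'
#' Default acceptance functional for \code{\link{assemble_ensemble}}:
#' stacks the candidate members under a meta-SVR, validates the
#' stacked model on the training and test sets, and passes the
#' combined verdict of \code{\link{criteria_check}}. The returned
#' \code{score} (training + test r2) ranks failed combinations for
#' diagnostics.
#'
#' @param ensemble an \code{"svr_ensemble"} of fitted members.
#' @param x_train,y_train,x_test,y_test data matrices/vectors.
#' @param meta_grid lattice for the meta-SVR (a compact default).
#' @param cv_folds,seed controls for q2_cv of the stacked model.
#' @return List: \code{pass}, \code{score}, \code{verdict}
#'   (\code{criteria_verdict}), \code{model} (the stacked
#'   \code{"hsvr"}).
#' @export
criteria_acceptance <- function(ensemble, x_train, y_train,
                                x_test, y_test,
                                meta_grid = svr_grid(
                                  C = 4^(0:4), gamma = 4^(-3:1),
                                  epsilon = 0.1),
                                cv_folds = 5, seed = 1) {
  model <- fit_meta(ensemble, x_train, y_train, meta_grid = meta_grid,
                    cv_folds = cv_folds, seed = seed)
  pr_tr <- predict(model, x_train)
  pr_te <- predict(model, x_test)
  q2cv <- kfold_cv(x_train, y_train, folds = cv_folds, seed = seed,
                   fitter = function(xt, yt) {
                     mm <- refit_hsvr(model, xt, yt)
                     function(nd) predict(mm, nd)
                   })
  train_rep <- validation_report(prediction_set(y_train, pr_tr),
                                 set_role = "training", q2_cv = q2cv)
  test_rep <- validation_report(
    prediction_set(y_test, pr_te, train_mean = mean(y_train),
                   train_n = length(y_train)),
    set_role = "external",
    train_ss = sum((y_train - mean(y_train))^2))
  verdict <- criteria_check(train_rep, test_rep)
  list(pass = verdict$overall,
       score = train_rep$r2 + test_rep$r2,
       verdict = verdict, model = model,
       train_report = train_rep, test_report = test_rep)
}

#' Stack an SVR ensemble under a meta-SVR (HSVR)
#'
#' Builds the n x m matrix of member predictions on the training rows
#' and fits a second-level SVR on it, grid-searched over
#' \code{meta_grid}. The hierarchical model blends the members' local
#' views into one global predictor.
#'
#' @param ensemble a fitted \code{"svr_ensemble"}.
#' @param x,y training descriptors and response.
#' @param meta_grid lattice of \code{\link{svr_config}}s for the
#'   meta-SVR.
#' @param selection,x_val,y_val,cv_folds,seed grid-search controls
#'   (see \code{\link{grid_search}}).
#' @return An object of class \code{"hsvr"}.
#' @export
fit_meta <- function(ensemble, x, y,
                     meta_grid = svr_grid(C = 4^(0:4), gamma = 4^(-3:1),
                                          epsilon = 0.1),
                     selection = "cv", x_val = NULL, y_val = NULL,
                     cv_folds = 5, seed = 1) {
  stopifnot(inherits(ensemble, "svr_ensemble"))
  if (inherits(x, "descriptor_table")) x <- x$values
  x <- as.matrix(x)
  z <- member_predictions(ensemble, x)
  z_val <- NULL
  if (selection == "holdout") {
    if (inherits(x_val, "descriptor_table")) x_val <- x_val$values
    z_val <- member_predictions(ensemble, as.matrix(x_val))
  }
  gs <- grid_search(z, y, meta_grid, selection = selection,
                    x_val = z_val, y_val = y_val,
                    cv_folds = cv_folds, seed = seed)
  meta <- fit_svr(z, y, gs$best)
  structure(list(ensemble = ensemble, meta = meta,
                 meta_score = gs$score,
                 fitted = predict(meta, z),
                 y = y),
            class = "hsvr")
}

#' Member prediction matrix
#'
#' @param ensemble an \code{"svr_ensemble"}.
#' @param x descriptor matrix.
#' @return n x m matrix; column j holds member j's predictions
#'   (columns named \code{member_1}, ..., preserving member order).
#' @export
member_predictions <- function(ensemble, x) {
  z <- vapply(ensemble$members, function(m) predict(m, x),
              numeric(nrow(as.matrix(x))))
  z <- matrix(z, nrow = nrow(as.matrix(x)))
  colnames(z) <- paste0("member_", seq_along(ensemble$members))
  z
}

# refit the same architecture (member subsets + configs + meta config)
# on new training data; used by cross-validation and Y-scrambling
#' @keywords internal
refit_hsvr <- function(model, x, y) {
  x <- as.matrix(x)
  members <- lapply(model$ensemble$members, function(m)
    fit_svr(x, y, m$config, subset = m$subset))
  ens <- structure(list(members = members,
                        candidate_index = model$ensemble$candidate_index),
                   class = "svr_ensemble")
  z <- member_predictions(ens, x)
  meta <- fit_svr(z, y, model$meta$config)
  structure(list(ensemble = ens, meta = meta,
                 fitted = predict(meta, z), y = y),
            class = "hsvr")
}

#' Hierarchical support vector regression
#'
#' The package's main fitting function. For each supplied descriptor
#' subset it grid-searches an RBF-kernel SVR member on the training
#' rows, then stacks the members' predictions under a grid-searched
#' meta-SVR. Model selection is cross-validated by default; a holdout
#' mode that selects on an explicit validation set is available (it
#' leaks test information into selection and is provided for
#' comparability with workflows that do so).
#'
#' @param x training descriptor matrix or normalized
#'   \code{\link{descriptor_table}}.
#' @param y training response (log10 Kp).
#' @param subsets list of character vectors, one descriptor subset per
#'   intended member.
#' @param grid member hyperparameter lattice (default
#'   \code{\link{svr_grid}()}).
#' @param meta_grid meta-SVR lattice (a compact default).
#' @param selection \code{"cv"} (default) or \code{"holdout"}.
#' @param x_val,y_val validation set (holdout selection).
#' @param cv_folds,seed selection controls.
#' @return An object of class \code{"hsvr"} with
#'   \code{print}, \code{summary}, \code{predict}, \code{residuals}
#'   and \code{plot} methods.
#' @examples
#' dat <- generate_skin_data(synthetic_spec(n_compounds = 60, seed = 1))
#' x <- dat$table$values
#' fit <- hsvr(x, dat$records$log_kp,
#'             subsets = list(c("log_P", "V_m"), c("log_P", "chi0")),
#'             grid = svr_grid(C = 4^(0:2), gamma = 4^(-2:0),
#'                             epsilon = 0.1),
#'             cv_folds = 3)
#' predict(fit, x[1:3, ])
#' @export
hsvr <- function(x, y, subsets, grid = svr_grid(),
                 meta_grid = svr_grid(C = 4^(0:4), gamma = 4^(-3:1),
                                      epsilon = 0.1),
                 selection = c("cv", "holdout"),
                 x_val = NULL, y_val = NULL, cv_folds = 5, seed = 1) {
  selection <- match.arg(selection)
  norm_params <- NULL
  if (inherits(x, "descriptor_table")) {
    norm_params <- x$norm_params
    x <- x$values
  }
  x <- as.matrix(x)
  members <- lapply(subsets, function(sub) {
    gs <- grid_search(x, y, grid, selection = selection,
                      x_val = x_val, y_val = y_val,
                      cv_folds = cv_folds, seed = seed, subset = sub)
    m <- fit_svr(x, y, gs$best, subset = sub)
    m$selection_score <- gs$score
    m
  })
  ens <- structure(list(members = members,
                        candidate_index = seq_along(members)),
                   class = "svr_ensemble")
  model <- fit_meta(ens, x, y, meta_grid = meta_grid,
                    selection = selection, x_val = x_val, y_val = y_val,
                    cv_folds = cv_folds, seed = seed)
  model$norm_params <- norm_params
  model$call <- match.call()
  model
}

#' Predict log Kp from a hierarchical SVR model
#'
#' Each member predicts from its own descriptor subset; the stacked
#' member predictions pass through the meta-SVR.
#'
#' @param object an \code{"hsvr"} model.
#' @param newdata matrix, data frame or \code{descriptor_table}
#'   carrying every descriptor any member uses.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.hsvr <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_table")) {
    if (!is.null(object$norm_params) && !newdata$normalized)
      newdata <- apply_normalization(newdata, object$norm_params)
    newdata <- newdata$values
  }
  newdata <- as.matrix(newdata)
  z <- member_predictions(object$ensemble, newdata)
  predict(object$meta, z)
}

#' @export
print.hsvr <- function(x, ...) {
  cat(sprintf("Hierarchical SVR: %d member(s) + meta-SVR\n",
              length(x$ensemble$members)))
  for (i in seq_along(x$ensemble$members)) {
    m <- x$ensemble$members[[i]]
    cat(sprintf("  member %d {%s}: ", i,
                paste(m$subset, collapse = ", ")))
    print(m$config)
  }
  cat("  meta: "); print(x$meta$config)
  invisible(x)
}

#' @export
summary.hsvr <- function(object, ...) {
  ps <- prediction_set(object$y, object$fitted)
  rep <- validation_report(ps, set_role = "training")
  cat("Hierarchical SVR model\n")
  cat(sprintf("  training n = %d, r2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              rep$n, rep$r2, rep$rmse, rep$mae))
  print(object)
  invisible(rep)
}

#' @export
residuals.hsvr <- function(object, ...) object$y - object$fitted

#' @export
coef.hsvr <- function(object, ...) {
  lapply(object$ensemble$members, function(m)
    list(subset = m$subset, config = m$config))
}

#' Observed-versus-predicted plot for an HSVR model
#' @param x an \code{"hsvr"} model.
#' @param ... passed to \code{plot}.
#' @export
plot.hsvr <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "predicted log Kp",
                 ylab = "observed log Kp",
                 main = "HSVR training fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize an HSVR model description to JSON
#'
#' Writes the architecture (member subsets and configurations, the
#' meta configuration, and normalization parameters); support vectors
#' are not serialized -- refit from data to reconstruct.
#'
#' @param model an \code{"hsvr"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hsvr_model <- function(model, path) {
  desc <- list(
    members = lapply(model$ensemble$members, function(m)
      list(subset = m$subset, config = unclass(m$config))),
    meta_config = unclass(model$meta$config),
    norm_params = model$norm_params)
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
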