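# NIPALS partial least squares for a single response. Returns scores,
# loadings, weights and the collapsed regression coefficients for each
# number of components up to ncomp. Written against centered/scaled or
# raw X; centering of X and y is always done internally and folded back
# into the intercept.
.nipals_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x); ym <- mean(y)
  E <- sweep(x, 2, xm)
  f <- y - ym
  W <- matrix(0, p, ncomp)   # X weights
  P <- matrix(0, p, ncomp)   # X loadings
  Q <- numeric(ncomp)        # y loadings
  Tm <- matrix(0, n, ncomp)  # scores
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) { ncomp <- a - 1L; break }
    w <- w / wn
    t <- E %*% w
    tt <- sum(t^2)
    p_a <- crossprod(E, t) / tt
    q_a <- sum(f * t) / tt
    E <- E - tcrossprod(t, p_a)
    f <- f - q_a * t
    W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a; Tm[, a] <- t
  }
  if (ncomp == 0) stop("response carries no covariance with the descriptors")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[seq_len(ncomp)]
  # collapsed regression coefficients: B = W (P'W)^-1 q
  coefs <- lapply(seq_len(ncomp), function(a) {
    Wa <- W[, 1:a, drop = FALSE]; Pa <- P[, 1:a, drop = FALSE]
    b <- Wa %*% solve(crossprod(Pa, Wa), Q[1:a])
    list(coef = drop(b), intercept = ym - sum(xm * b))
  })
  list(ncomp = ncomp, coefs = coefs)
}

#' Fit a PLS regression with cross-validated component selection
#'
#' Fits NIPALS partial least squares for 1..max_components latent
#' components, picks the component count maximizing the k-fold
#' cross-validated q2, and collapses the winner to plain regression
#' coefficients (intercept + per-descriptor weights). PLS tolerates
#' strongly collinear descriptors, which is why it partners the
#' kernel-based model in the two-QSAR scheme: its signed coefficients
#' stay interpretable.
#'
#' @param x descriptor matrix (or \code{\link{descriptor_table}}).
#' @param y response vector (log10 Kp).
#' @param max_components upper bound on latent components (default
#'   \code{min(p, 10)}).
#' @param cv_folds folds for the component-selection CV (default 10).
#' @param seed seed for the CV fold assignment.
#' @return An object of class \code{"kp_pls"}: list with
#'   \code{intercept}, \code{coefficients} (named), \code{n_components},
#'   \code{q2_cv} (of the selected size), \code{cv_trace} (q2 per
#'   candidate size), \code{norm_params} (carried from a normalized
#'   descriptor_table, else \code{NULL}).
#' @export
fit_pls <- function(x, y, max_components = NULL, cv_folds = 10, seed = 1) {
  norm_params <- NULL
  if (inherits(x, "descriptor_table")) {
    norm_params <- if (x$normalized) x$norm_params else NULL
    x <- x$values
  }
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(max_components)) max_components <- min(p, 10)
  if (max_components > min(n - 1, p))
    stop("max_components exceeds min(n - 1, p)")
  if (n <= cv_folds) stop("need more samples than folds")
  cv_trace <- vapply(seq_len(max_components), function(a) {
    kfold_cv(x, y, folds = cv_folds, seed = seed,
             fitter = function(xt, yt) {
               fit <- .nipals_pls(xt, yt, min(a, ncol(xt), nrow(xt) - 1))
               cf <- fit$coefs[[fit$ncomp]]
               function(m) drop(m %*% cf$coef) + cf$intercept
             })
  }, numeric(1))
  best <- which.max(cv_trace)
  fit <- .nipals_pls(x, y, best)
  cf <- fit$coefs[[fit$ncomp]]
  names(cf$coef) <- colnames(x)
  structure(list(intercept = cf$intercept,
                 coefficients = cf$coef,
                 n_components = fit$ncomp,
                 q2_cv = cv_trace[best],
                 cv_trace = cv_trace,
                 norm_params = norm_params),
            class = "kp_pls")
}

#' The published four-descriptor skin-permeability PLS model
#'
#' Returns, as a fixed \code{"kp_pls"} object, a published PLS equation
#' for log Kp of compounds permeating excised human skin:
#' log Kp = -2.62974 + 1.26972 log P - 0.55661 V_m - 0.554268 chi0
#' - 0.076344 Jurs_PPSA_1, where log P is the octanol-water partition
#' coefficient, V_m the molecular volume, chi0 the zeroth-order
#' molecular connectivity index, and Jurs_PPSA_1 the partial positive
#' surface area. The equation is evaluated as printed on whatever
#' descriptor values are supplied (the original report does not state
#' whether its inputs were autoscaled; no scaling is applied here).
#'
#' @return A \code{"kp_pls"} model with no \code{norm_params}.
#' @export
published_skin_model <- function() {
  structure(list(intercept = -2.62974,
                 coefficients = c(log_P = 1.26972, V_m = -0.55661,
                                  chi0 = -0.554268,
                                  Jurs_PPSA_1 = -0.076344),
                 n_components = NA_integer_,
                 q2_cv = NA_real_,
                 cv_trace = NULL,
                 norm_params = NULL),
            class = "kp_pls")
}

#' Predict from a PLS skin-permeability model
#'
#' Affine evaluation: intercept + sum(coefficient x descriptor). For a
#' model fitted on a normalized table, new descriptors pass through the
#' stored normalization parameters first.
#'
#' @param object a \code{"kp_pls"} model.
#' @param newdata matrix, data frame, or \code{descriptor_table} whose
#'   columns include every model descriptor.
#' @param ... unused.
#' @return Numeric vector of predicted log10 Kp, one per row.
#' @export
predict.kp_pls <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_table")) {
    if (!is.null(object$norm_params) && !newdata$normalized)
      newdata <- apply_normalization(newdata, object$norm_params)
    newdata <- newdata$values
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(object$norm_params)) {
      np <- object$norm_params
      newdata <- sweep(sweep(newdata, 2, np$center[colnames(newdata)]),
                       2, np$scale[colnames(newdata)], "/")
    }
  }
  need <- names(object$coefficients)
  absent <- setdiff(need, colnames(newdata))
  if (length(absent) > 0)
    stop("missing descriptor(s): ", paste(absent, collapse = ", "))
  drop(newdata[, need, drop = FALSE] %*% object$coefficients) +
    object$intercept
}

#' @export
print.kp_pls <- function(x, ...) {
  cat("PLS skin-permeability model")
  if (is.finite(x$n_components))
    cat(sprintf(" (%d latent component%s, q2_cv = %.3f)",
                x$n_components, if (x$n_components == 1) "" else "s",
                x$q2_cv))
  cat("\nlog Kp =", format(x$intercept, digits = 6))
  for (nm in names(x$coefficients)) {
    b <- x$coefficients[[nm]]
    cat(sprintf(" %s %s x %s", if (b >= 0) "+" else "-",
                format(abs(b), digits = 6), nm))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.kp_pls <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' Serialize a PLS model to JSON
#' @param model a \code{"kp_pls"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pls_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         n_components = model$n_components),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
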