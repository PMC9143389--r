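#' Specification for a synthetic skin-permeation dataset
#'
#' Collects the generating parameters of
#' \code{\link{generate_skin_data}}. The defaults emulate the
#' statistical structure of curated excised-human-skin permeability
#' collections: a bilinear (hinge) dependence of log Kp on log P that
#' rises up to a breakpoint near log P = 4 and falls beyond it; a pair
#' of size descriptors (molecular volume and the zeroth-order
#' connectivity index) correlated at about r = 0.98; a polarity
#' descriptor whose association with log Kp is positive inside a
#' transporter-substrate subgroup and negative outside it; and
#' additive Gaussian noise.
#'
#' @param n_compounds number of compounds (>= 20; default 300).
#' @param noise_sd response noise standard deviation (default 0.3 log
#'   units).
#' @param logp_breakpoint hinge location on the log P axis (default 4).
#' @param slope_up,slope_down hinge slopes below/above the breakpoint
#'   (defaults 0.5 and -0.4).
#' @param size_coef coefficient of the size descriptor (default -0.5).
#' @param polarity_coef magnitude of the subgroup-signed polarity
#'   effect (default 0.05).
#' @param size_collinearity_r target correlation between the two size
#'   descriptors (default 0.98; |r| must be < 1).
#' @param pgp_fraction fraction of compounds in the
#'   transporter-substrate subgroup (default 0.3).
#' @param seed integer seed.
#' @return A list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_compounds = 300, noise_sd = 0.3,
                           logp_breakpoint = 4, slope_up = 0.5,
                           slope_down = -0.4, size_coef = -0.5,
                           polarity_coef = 0.05,
                           size_collinearity_r = 0.98,
                           pgp_fraction = 0.3, seed = 1) {
  spec <- list(n_compounds = as.integer(n_compounds),
               noise_sd = noise_sd,
               logp_breakpoint = logp_breakpoint,
               slope_up = slope_up, slope_down = slope_down,
               size_coef = size_coef, polarity_coef = polarity_coef,
               size_collinearity_r = size_collinearity_r,
               pgp_fraction = pgp_fraction, seed = as.integer(seed))
  stopifnot(all(vapply(spec, is.finite, TRUE)))
  if (spec$n_compounds < 20) stop("n_compounds must be >= 20")
  if (abs(spec$size_collinearity_r) >= 1)
    stop("infeasible collinearity target: |r| must be < 1")
  if (spec$pgp_fraction < 0 || spec$pgp_fraction > 1)
    stop("pgp_fraction must lie in [0, 1]")
  structure(spec, class = "synthetic_spec")
}

# continuous hinge: slope_up below the breakpoint, slope_down above,
# meeting at the breakpoint
.hinge <- function(logp, bp, up, down)
  up * pmin(logp, bp) + down * pmax(logp - bp, 0)

#' Generate a synthetic skin-permeation dataset
#'
#' Draws a seeded dataset with the structure described in
#' \code{\link{synthetic_spec}}: log P ~ Uniform(-2, 7); V_m standard
#' normal; chi0 = r V_m + sqrt(1 - r^2) jitter so that their
#' population correlation is the collinearity target; Jurs_PPSA_1
#' standard normal; a Bernoulli subgroup label; and
#' log Kp = hinge(log P) + size_coef V_m +/- polarity_coef
#' Jurs_PPSA_1 + N(0, noise_sd), the polarity sign positive inside
#' the subgroup. Integer rotatable-bond (N_rot) and oxygen (N_O)
#' counts with a small heavy tail are emitted so a few rows trip the
#' structural-outlier thresholds.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list: \code{records} (data frame with \code{id},
#'   \code{log_kp}, \code{pgp_substrate}, \code{pka} list-column),
#'   \code{table} (raw \code{\link{descriptor_table}} with columns
#'   \code{log_P}, \code{V_m}, \code{chi0}, \code{Jurs_PPSA_1},
#'   \code{N_rot}, \code{N_O}), and \code{truth} (the generating
#'   parameters plus the noiseless response).
#' @export
generate_skin_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  set.seed(spec$seed)
  logp <- stats::runif(n, -2, 7)
  vm <- stats::rnorm(n)
  r <- spec$size_collinearity_r
  chi0 <- r * vm + sqrt(1 - r^2) * stats::rnorm(n)
  jurs <- stats::rnorm(n)
  pgp <- stats::runif(n) < spec$pgp_fraction
  # Poisson bulk + rare geometric excess gives a small heavy tail
  nrot <- stats::rpois(n, 3) +
    ifelse(stats::runif(n) < 0.08, stats::rgeom(n, 0.25) + 6L, 0L)
  nox <- stats::rpois(n, 3) +
    ifelse(stats::runif(n) < 0.05, stats::rgeom(n, 0.3) + 9L, 0L)
  signal <- .hinge(logp, spec$logp_breakpoint, spec$slope_up,
                   spec$slope_down) +
    spec$size_coef * vm +
    ifelse(pgp, 1, -1) * spec$polarity_coef * jurs
  y <- signal + stats::rnorm(n, 0, spec$noise_sd)
  ids <- sprintf("syn%03d", seq_len(n))
  vals <- cbind(log_P = logp, V_m = vm, chi0 = chi0,
                Jurs_PPSA_1 = jurs, N_rot = as.numeric(nrot),
                N_O = as.numeric(nox))
  records <- data.frame(id = ids, log_kp = y,
                        pgp_substrate = pgp, stringsAsFactors = FALSE)
  records$pka <- replicate(n, data.frame(value = numeric(0),
                                         type = character(0),
                                         stringsAsFactors = FALSE),
                           simplify = FALSE)
  list(records = records,
       table = descriptor_table(vals, ids, colnames(vals)),
       truth = c(unclass(spec), list(signal = signal)))
}

#' Generate an (observed, predicted) pair with known correlation
#'
#' Draws a prediction set whose population squared correlation between
#' observed and predicted values equals \code{true_r2}: y standard
#' normal, yhat = sqrt(true_r2) y + sqrt(1 - true_r2) independent
#' noise. Used as a seeded fixture for metric tests.
#'
#' @param n number of points (>= 2).
#' @param true_r2 population squared correlation in [0, 1).
#' @param seed integer seed.
#' @return A \code{\link{prediction_set}}.
#' @export
generate_prediction_pair <- function(n, true_r2, seed = 1) {
  if (true_r2 < 0 || true_r2 >= 1)
    stop("true_r2 must lie in [0, 1)")
  set.seed(seed)
  y <- stats::rnorm(n)
  yhat <- sqrt(true_r2) * y + sqrt(1 - true_r2) * stats::rnorm(n)
  prediction_set(y, yhat)
}
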