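#' Project compounds into PCA chemical space
#'
#' Projects the (already normalized) descriptor matrix onto its leading
#' principal components; the resulting score space is the "chemical
#' space" used for outlier inspection and the diversity-preserving
#' split.
#'
#' @param table a normalized \code{\link{descriptor_table}}.
#' @param n_components number of components to keep (default 3; must
#'   not exceed the number of descriptors).
#' @return A list: \code{scores} (n x k matrix),
#'   \code{explained_variance} (fractions of total variance, k values,
#'   non-increasing).
#' @export
pca_project <- function(table, n_components = 3) {
  stopifnot(inherits(table, "descriptor_table"))
  if (n_components > ncol(table$values))
    stop("n_components exceeds the number of descriptors")
  p <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  frac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained_variance = frac[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       center = p$center)
}

#' Flag structural outliers by rotatable-bond and oxygen counts
#'
#' Compounds with many rotatable bonds or many oxygens sit apart from
#' the bulk of curated skin-permeation datasets; they are designated
#' outliers (held out to challenge model robustness rather than
#' silently discarded). A compound is flagged when N_rot >=
#' \code{nrot_threshold} or N_O >= \code{n_oxygen_threshold}.
#' Optionally, compounds far from the centroid in PC-score space
#' (squared Mahalanobis distance above the chi-squared 0.975 quantile)
#' are flagged too.
#'
#' @param records compound record data frame (needs an \code{id}
#'   column).
#' @param table \code{\link{descriptor_table}} carrying the count
#'   descriptors.
#' @param nrot_threshold rotatable-bond cutoff (default 8).
#' @param n_oxygen_threshold oxygen-count cutoff (default 11).
#' @param nrot_name,n_oxygen_name descriptor column names (defaults
#'   \code{"N_rot"}, \code{"N_O"}).
#' @param scores optional PC score matrix; when supplied, the
#'   Mahalanobis rule is applied as well.
#' @return Character vector of flagged compound ids (possibly empty).
#' @export
flag_outliers <- function(records, table, nrot_threshold = 8,
                          n_oxygen_threshold = 11,
                          nrot_name = "N_rot", n_oxygen_name = "N_O",
                          scores = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  for (nm in c(nrot_name, n_oxygen_name))
    if (!nm %in% table$descriptor_names)
      stop("required descriptor absent: ", nm)
  nrot <- table$values[, nrot_name]
  nox <- table$values[, n_oxygen_name]
  flagged <- nrot >= nrot_threshold | nox >= n_oxygen_threshold
  ids <- table$compound_ids[flagged]
  if (!is.null(scores)) {
    d2 <- stats::mahalanobis(scores, colMeans(scores), stats::cov(scores))
    cut <- stats::qchisq(0.975, df = ncol(scores))
    ids <- union(ids, table$compound_ids[d2 > cut])
  }
  ids
}

# round half away from zero (so 0.8 * 91 = 72.8 -> 73)
.round_half_up <- function(x) floor(x + 0.5)

#' Diversity-preserving train/test split
#'
#' Splits compounds into a training and a test set of approximately
#' 4:1 ratio (by default) such that the test set is spread through the
#' occupied chemical space: test compounds are chosen by greedy
#' max-min (farthest-point) selection in PC-score space from a seeded
#' random start, and the remainder forms the training set. Outliers
#' must have been removed from \code{ids} beforehand.
#'
#' @param scores n x k PC score matrix (rows named by compound id, or
#'   in the order of \code{ids}).
#' @param ids compound ids, one per score row.
#' @param train_fraction fraction assigned to training (default 0.8);
#'   training size is round-half-away-from-zero of fraction x n.
#' @param seed integer seed controlling the farthest-point start.
#' @return An object of class \code{"data_split"}: list with
#'   \code{train_ids}, \code{test_ids}, \code{outlier_ids} (empty
#'   here), \code{ratio}, \code{seed}.
#' @export
diverse_split <- function(scores, ids, train_fraction = 0.8, seed = 1) {
  scores <- as.matrix(scores)
  n <- length(ids)
  if (nrow(scores) != n) stop("scores and ids must agree in length")
  if (n < 5) stop("too few compounds to honor the split ratio")
  n_train <- .round_half_up(train_fraction * n)
  n_test <- n - n_train
  if (n_test < 1) stop("test set would be empty at this fraction")
  # greedy farthest-point: pick a seeded start, then repeatedly add the
  # point maximizing its minimum distance to already-picked test points
  set.seed(seed)
  picked <- sample.int(n, 1)
  if (n_test > 1) {
    d <- as.matrix(stats::dist(scores))
    mind <- d[, picked]
    for (i in seq_len(n_test - 1)) {
      cand <- setdiff(seq_len(n), picked)
      nxt <- cand[which.max(mind[cand])]
      picked <- c(picked, nxt)
      mind <- pmin(mind, d[, nxt])
    }
  }
  structure(list(train_ids = ids[-picked],
                 test_ids = ids[picked],
                 outlier_ids = character(0),
                 ratio = n_train / n_test,
                 seed = seed),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("Data split: %d training / %d test (ratio %.2f:1)",
              length(x$train_ids), length(x$test_ids), x$ratio))
  if (length(x$outlier_ids) > 0)
    cat(sprintf(" + %d outliers", length(x$outlier_ids)))
  cat("\n")
  invisible(x)
}

#' Write split membership to CSV files
#' @param split a \code{"data_split"}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (subset in c("train", "test", "outlier")) {
    ids <- split[[paste0(subset, "_ids")]]
    if (subset == "outlier" && length(ids) == 0) next
    p <- file.path(dir, paste0(subset, ".csv"))
    utils::write.csv(data.frame(id = ids, subset = subset),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Compare property distributions between training and test sets
#'
#' A sound split preserves chemical and biological similarity between
#' the sets; this reports, for each named property, the two-sample
#' Kolmogorov-Smirnov statistic and histogram densities over shared
#' bins.
#'
#' @param train,test data frames (or named lists) holding the named
#'   numeric properties for each subset.
#' @param properties character vector of property names to compare.
#' @param bins number of shared histogram bins (default 10).
#' @return A named list (one entry per property) of lists with
#'   \code{ks_statistic}, \code{breaks}, \code{train_density},
#'   \code{test_density}.
#' @export
distribution_report <- function(train, test, properties, bins = 10) {
  out <- list()
  for (p in properties) {
    a <- train[[p]]; b <- test[[p]]
    if (is.null(a) || is.null(b) || length(a) == 0 || length(b) == 0)
      stop("property absent or empty in one set: ", p)
    ks <- suppressWarnings(stats::ks.test(a, b))
    breaks <- seq(min(a, b), max(a, b), length.out = bins + 1)
    # guard degenerate range
    if (breaks[1] == breaks[length(breaks)])
      breaks <- breaks[1] + c(-0.5, 0.5)
    ha <- graphics::hist(a, breaks = breaks, plot = FALSE)
    hb <- graphics::hist(b, breaks = breaks, plot = FALSE)
    out[[p]] <- list(ks_statistic = unname(ks$statistic),
                     breaks = breaks,
                     train_density = ha$density,
                     test_density = hb$density)
  }
  out
}
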