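#' Drop descriptors with too many missing values
#'
#' Descriptors missing more than \code{max_missing} values are removed
#' from the pool; a remaining missing entry in a retained descriptor is
#' imputed with the fitting-set column mean. Every drop and imputation
#' is recorded in the provenance log attached to the result (attribute
#' \code{"provenance"}, a list of records suitable for
#' \code{\link{write_provenance}}).
#'
#' @param table a \code{\link{descriptor_table}}.
#' @param max_missing maximum tolerated number of missing entries per
#'   descriptor (default 1).
#' @return The filtered \code{descriptor_table}, missing values imputed.
#' @export
drop_missing <- function(table, max_missing = 1) {
  stopifnot(inherits(table, "descriptor_table"))
  n_miss <- colSums(is.na(table$values))
  keep <- n_miss <= max_missing
  if (!any(keep)) stop("all descriptors exceed the missing-value limit")
  prov <- list()
  for (j in which(!keep))
    prov[[length(prov) + 1L]] <- list(
      action = "drop", reason = "missing_values",
      descriptor = table$descriptor_names[j],
      n_missing = unname(n_miss[j]))
  vals <- table$values[, keep, drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (any(miss)) {
      m <- mean(vals[!miss, j])
      vals[miss, j] <- m
      prov[[length(prov) + 1L]] <- list(
        action = "impute", reason = "single_missing_value",
        descriptor = colnames(vals)[j],
        rows = table$compound_ids[miss], imputed_value = m)
    }
  }
  out <- descriptor_table(vals, table$compound_ids, colnames(vals))
  attr(out, "provenance") <- prov
  out
}

#' Drop invariant (non-discriminating) descriptors
#'
#' Removes descriptors that show little or no discrimination across the
#' samples: fewer than \code{min_distinct} distinct values, or variance
#' at or below \code{min_variance}.
#'
#' @param table a \code{\link{descriptor_table}} without missing values.
#' @param min_distinct minimum number of distinct values (default 2).
#' @param min_variance variance must strictly exceed this (default 1e-12).
#' @return The filtered \code{descriptor_table} (possibly unchanged),
#'   with a provenance attribute listing drops.
#' @export
drop_invariant <- function(table, min_distinct = 2, min_variance = 1e-12) {
  stopifnot(inherits(table, "descriptor_table"))
  v <- apply(table$values, 2, stats::var)
  ndist <- apply(table$values, 2, function(x) length(unique(x)))
  keep <- ndist >= min_distinct & v > min_variance
  prov <- lapply(which(!keep), function(j) list(
    action = "drop", reason = "invariant",
    descriptor = table$descriptor_names[j],
    variance = unname(v[j]), n_distinct = unname(ndist[j])))
  out <- descriptor_table(table$values[, keep, drop = FALSE],
                          table$compound_ids,
                          table$descriptor_names[keep])
  attr(out, "provenance") <- unname(prov)
  out
}

#' Prune collinear descriptors by Spearman rank correlation
#'
#' Builds the Spearman correlation matrix among descriptors and removes
#' one member of every pair whose squared rank correlation strictly
#' exceeds \code{r2_threshold} (default 0.64, a deliberately stricter
#' cut than the conventional 0.80). Offending pairs are visited in order
#' of descending pair r-squared; within a pair, the descriptor with the
#' lower absolute Spearman correlation with the response is dropped
#' (ties: the lexicographically later name goes).
#'
#' @param table a \code{\link{descriptor_table}} without missing values.
#' @param response numeric response vector (one value per compound).
#' @param r2_threshold squared-correlation cutoff; pairs at exactly the
#'   threshold are both retained (strict inequality).
#' @param protect descriptor names never to drop (e.g. descriptors a
#'   modeller deliberately spreads across different ensemble members,
#'   such as near-duplicate size descriptors); a collinear pair whose
#'   members are both protected is left in place.
#' @return A list: \code{table} (pruned \code{descriptor_table}) and
#'   \code{dropped} (data frame reporting each removal: descriptor kept,
#'   descriptor dropped, pair r-squared, response correlations).
#' @export
spearman_prune <- function(table, response, r2_threshold = 0.64,
                           protect = character(0)) {
  stopifnot(inherits(table, "descriptor_table"))
  if (anyNA(table$values)) stop("table must not contain missing values")
  if (length(response) != nrow(table$values))
    stop("response length must match the number of compounds")
  vals <- table$values
  # average-rank Spearman; descriptors may contain repeated values
  rs_y <- suppressWarnings(
    abs(stats::cor(vals, response, method = "spearman")[, 1]))
  rs_y[is.na(rs_y)] <- 0
  dropped <- data.frame(kept = character(0), dropped = character(0),
                        pair_r2 = numeric(0), kept_abs_rho_y = numeric(0),
                        dropped_abs_rho_y = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    nm <- colnames(vals)
    if (ncol(vals) < 2) break
    cm <- suppressWarnings(stats::cor(vals, method = "spearman"))^2
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    # fully protected pairs stay together; blank them out of the search
    if (length(protect) > 0) {
      pi <- which(nm %in% protect)
      if (length(pi) > 1) cm[pi, pi] <- 0
    }
    if (max(cm) <= r2_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- nm[idx[1]]; b <- nm[idx[2]]
    # keep the member more correlated (in rank) with the response;
    # a protected member always survives
    loser <- if (a %in% protect) b
             else if (b %in% protect) a
             else if (rs_y[a] > rs_y[b]) b
             else if (rs_y[b] > rs_y[a]) a
             else max(a, b)                  # tie: later name goes
    winner <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped, data.frame(
      kept = winner, dropped = loser, pair_r2 = max(cm),
      kept_abs_rho_y = unname(rs_y[winner]),
      dropped_abs_rho_y = unname(rs_y[loser]),
      stringsAsFactors = FALSE))
    vals <- vals[, setdiff(nm, loser), drop = FALSE]
  }
  list(table = descriptor_table(vals, table$compound_ids, colnames(vals)),
       dropped = dropped)
}

#' Autoscale a descriptor table (centering and scaling)
#'
#' Transforms each descriptor to zero mean and unit sample standard
#' deviation (n - 1 denominator), so that wide-ranged descriptors
#' cannot override narrow-ranged ones. The centering/scaling parameters
#' are stored on the result so external compounds can be scaled with
#' the fitting-set parameters via \code{\link{apply_normalization}}.
#'
#' @param table a \code{\link{descriptor_table}} with no missing values
#'   and positive column variance.
#' @return A normalized \code{descriptor_table} carrying
#'   \code{norm_params}.
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  if (anyNA(table$values)) stop("table must not contain missing values")
  ctr <- colMeans(table$values)
  scl <- apply(table$values, 2, stats::sd)
  bad <- !is.finite(scl) | scl <= 0
  if (any(bad))
    stop("zero-variance descriptor(s): ",
         paste(table$descriptor_names[bad], collapse = ", "))
  vals <- sweep(sweep(table$values, 2, ctr), 2, scl, "/")
  descriptor_table(vals, table$compound_ids, table$descriptor_names,
                   normalized = TRUE,
                   norm_params = list(center = ctr, scale = scl))
}

#' Apply stored normalization parameters to a table
#'
#' Scales a (typically external or test) table with previously fitted
#' centering/scaling parameters rather than recomputing them; values
#' outside the fitting range transform without clipping.
#'
#' @param table a raw \code{\link{descriptor_table}}.
#' @param params a \code{norm_params} list (\code{center}, \code{scale})
#'   covering every descriptor of \code{table}.
#' @return A normalized \code{descriptor_table}.
#' @export
apply_normalization <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"))
  missing_par <- setdiff(table$descriptor_names, names(params$center))
  if (length(missing_par) > 0)
    stop("no normalization parameters for: ",
         paste(missing_par, collapse = ", "))
  ctr <- params$center[table$descriptor_names]
  scl <- params$scale[table$descriptor_names]
  vals <- sweep(sweep(table$values, 2, ctr), 2, scl, "/")
  descriptor_table(vals, table$compound_ids, table$descriptor_names,
                   normalized = TRUE,
                   norm_params = list(center = ctr, scale = scl))
}

#' Assign an ion class from pKa values
#'
#' Classifies a compound as zwitterion, acid, base, or neutral from its
#' pKa list relative to pH 7. The four textual clauses in common use
#' overlap; they are applied here with a fixed precedence that makes
#' them a partition: (i) zwitterion when the strongest acidic pKa
#' exceeds 7 and the strongest basic pKa is below 7; (ii) acid when no
#' pKa exceeds 7; (iii) base when no pKa is below 7; (iv) neutral
#' otherwise (including an empty pKa list).
#'
#' @param pka a data frame with columns \code{value} (numeric) and
#'   \code{type} (\code{"acid"} or \code{"base"}), possibly empty.
#' @return One of \code{"zwitterion"}, \code{"acid"}, \code{"base"},
#'   \code{"neutral"}.
#' @export
assign_ion_class <- function(pka) {
  if (is.null(pka) || nrow(pka) == 0) return("neutral")
  stopifnot(all(pka$type %in% c("acid", "base")))
  v <- pka$value
  acid_v <- v[pka$type == "acid"]
  base_v <- v[pka$type == "base"]
  # extreme acidic/basic pKa compared against pH 7 per the classing rule
  if (length(acid_v) > 0 && length(base_v) > 0 &&
      max(acid_v) > 7 && min(base_v) < 7) return("zwitterion")
  if (all(v <= 7)) return("acid")
  if (all(v >= 7)) return("base")
  "neutral"
}

#' Write a provenance log as JSON lines
#'
#' One JSON record per dropped or imputed descriptor, with the reason
#' and supporting statistics; appended in the order the events occurred.
#'
#' @param prov a list of provenance records (see
#'   \code{\link{drop_missing}}, \code{\link{drop_invariant}}).
#' @param path output file; overwritten.
#' @return \code{path}, invisibly.
#' @export
write_provenance <- function(prov, path) {
  lines <- vapply(prov, function(rec)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, path)
  invisible(path)
}
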