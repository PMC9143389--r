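#' Cross-validated q2 of a linear least-squares fit
#'
#' The default model-quality functional for descriptor selection:
#' ordinary least squares on the given descriptor columns, scored by
#' k-fold cross-validated q2. Returns -Inf for empty subsets.
#'
#' @param x descriptor matrix.
#' @param y response vector.
#' @param folds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return Scalar q2.
#' @export
linear_cv_q2 <- function(x, y, folds = 5, seed = 1) {
  x <- as.matrix(x)
  if (ncol(x) == 0) return(-Inf)
  kfold_cv(x, y, folds = folds, seed = seed,
           fitter = function(xt, yt) {
             fit <- stats::lm.fit(cbind(1, xt), yt)
             beta <- fit$coefficients
             beta[is.na(beta)] <- 0
             function(nd) drop(cbind(1, nd) %*% beta)
           })
}

.as_matrix_named <- function(x) {
  if (inherits(x, "descriptor_table")) x <- x$values
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

# keep a mask's popcount within [lo, hi] by random flips
.repair_mask <- function(mask, lo, hi) {
  k <- sum(mask)
  if (k < lo) {
    add <- sample(which(!mask), lo - k)
    mask[add] <- TRUE
  } else if (k > hi) {
    drop <- sample(which(mask), k - hi)
    mask[drop] <- FALSE
  }
  mask
}

#' Genetic-algorithm descriptor subset search
#'
#' First selection stage: a plain genetic algorithm over binary
#' descriptor masks -- tournament selection (size 2), uniform
#' crossover, per-bit mutation at rate 1/p, one elite carried over
#' unchanged per generation. Fitness defaults to the cross-validated
#' q2 of a linear least-squares fit on the masked descriptors
#' (\code{\link{linear_cv_q2}}) and is pluggable. Subset sizes are
#' kept within \code{subset_size_range} by random repair.
#'
#' @param x descriptor matrix or normalized
#'   \code{\link{descriptor_table}} (no missing values).
#' @param response response vector.
#' @param subset_size_range integer pair (min, max) of allowed subset
#'   sizes.
#' @param population chromosomes per generation (default 30).
#' @param generations number of generations (default 30; 0 returns the
#'   best of the seeded initial population).
#' @param fitness function(x_subset_matrix, y) -> scalar score;
#'   default \code{\link{linear_cv_q2}}.
#' @param seed integer seed; the whole run is deterministic given it.
#' @return An object of class \code{"selection_result"}: list with
#'   \code{chosen} (descriptor names), \code{fitness} (best score),
#'   \code{history} (per-generation best subset and score), and
#'   \code{seed}.
#' @export
ga_select <- function(x, response, subset_size_range = c(2, 5),
                      population = 30, generations = 30,
                      fitness = linear_cv_q2, seed = 1) {
  x <- .as_matrix_named(x)
  p <- ncol(x)
  lo <- subset_size_range[1]; hi <- subset_size_range[2]
  if (hi > p) stop("max subset size exceeds available descriptors")
  if (lo < 1 || lo > hi) stop("invalid subset_size_range")
  set.seed(seed)
  score_mask <- function(mask) fitness(x[, mask, drop = FALSE], response)
  pop <- lapply(seq_len(population), function(i)
    .repair_mask(sample(c(TRUE, FALSE), p, replace = TRUE), lo, hi))
  fit <- vapply(pop, score_mask, numeric(1))
  record <- function(mask, f) data.frame(
    generation = NA_integer_,
    subset = paste(colnames(x)[mask], collapse = "+"),
    fitness = f, stringsAsFactors = FALSE)
  best_i <- which.max(fit)
  history <- record(pop[[best_i]], fit[best_i])
  history$generation <- 0L
  if (generations > 0) {
    for (g in seq_len(generations)) {
      elite <- pop[[which.max(fit)]]
      nxt <- list(elite)
      while (length(nxt) < population) {
        pick <- function() {   # tournament of two
          c2 <- sample.int(population, 2)
          pop[[c2[which.max(fit[c2])]]]
        }
        pa <- pick(); pb <- pick()
        take <- sample(c(TRUE, FALSE), p, replace = TRUE)
        child <- ifelse(take, pa, pb)
        flip <- stats::runif(p) < 1 / p
        child[flip] <- !child[flip]
        nxt[[length(nxt) + 1L]] <- .repair_mask(child, lo, hi)
      }
      pop <- nxt
      fit <- vapply(pop, score_mask, numeric(1))
      best_i <- which.max(fit)
      h <- record(pop[[best_i]], fit[best_i]); h$generation <- g
      history <- rbind(history, h)
    }
  }
  best_i <- which.max(fit)
  structure(list(chosen = colnames(x)[pop[[best_i]]],
                 fitness = fit[best_i],
                 history = history, seed = seed),
            class = "selection_result")
}

#' Recursive feature elimination
#'
#' Second selection stage: starting from the current descriptor set,
#' repeatedly scores every leave-one-descriptor-out subset, identifies
#' the descriptor whose removal hurts least (the smallest contribution),
#' purges it, and stops at \code{target_size}. Ties break by dropping
#' the lexicographically later name.
#'
#' @param x descriptor matrix or \code{\link{descriptor_table}}.
#' @param response response vector.
#' @param target_size number of descriptors to keep (>= 1, < current).
#' @param scorer model-quality functional as in \code{\link{ga_select}};
#'   default \code{\link{linear_cv_q2}}.
#' @return A \code{"selection_result"}; \code{history} records each
#'   elimination with the score of the surviving subset.
#' @export
rfe_select <- function(x, response, target_size,
                       scorer = linear_cv_q2) {
  x <- .as_matrix_named(x)
  if (target_size < 1) stop("target_size must be >= 1")
  current <- colnames(x)
  history <- data.frame(dropped = character(0), subset = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  history <- rbind(history, data.frame(
    dropped = "", subset = paste(current, collapse = "+"),
    score = scorer(x[, current, drop = FALSE], response)))
  while (length(current) > target_size) {
    drops <- sort(current)  # deterministic candidate order
    scores <- vapply(drops, function(d)
      scorer(x[, setdiff(current, d), drop = FALSE], response),
      numeric(1))
    # the least-contributing descriptor: removal leaves the highest
    # score; on ties the lexicographically later name goes (drops is
    # sorted, so pick the last maximal entry)
    mx <- max(scores)
    victim <- drops[max(which(scores == mx))]
    current <- setdiff(current, victim)
    history <- rbind(history, data.frame(
      dropped = victim, subset = paste(current, collapse = "+"),
      score = mx))
  }
  structure(list(chosen = current,
                 fitness = history$score[nrow(history)],
                 history = history, seed = NA_integer_),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selected descriptors:", paste(x$chosen, collapse = ", "),
      sprintf("(score %.3f)\n", x$fitness))
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a \code{"selection_result"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_selection_result <- function(result, path) {
  jsonlite::write_json(list(chosen = result$chosen,
                            fitness = result$fitness,
                            history = result$history,
                            seed = result$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
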