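#' Configuration for a two-QSAR run
#'
#' Assembles every knob of \code{\link{run_two_qsar}} with defaults
#' reproducing the canonical workflow constants: Spearman prune at
#' r^2 > 0.64, a 4:1 (80/20) diversity-preserving split, 10-fold
#' cross-validation, 25 Y-scrambling repetitions, and ensembles of at
#' most 3 members.
#'
#' @param input path to a descriptor CSV, or a list with
#'   \code{records} and \code{table} (as from
#'   \code{\link{read_descriptor_table}} or
#'   \code{\link{generate_skin_data}}).
#' @param schema CSV schema (see \code{\link{read_descriptor_table}}).
#' @param max_missing,r2_prune preprocessing thresholds.
#' @param train_fraction,split_seed split controls.
#' @param member_subsets explicit list of descriptor subsets for the
#'   SVR members, or \code{NULL} to derive them by GA + RFE selection.
#' @param n_members number of members when subsets are derived
#'   (default 3).
#' @param grid,meta_grid SVR lattices (see \code{\link{svr_grid}}).
#' @param selection \code{"cv"} or \code{"holdout"} model selection.
#' @param max_members parsimony bound for ensemble assembly.
#' @param cv_folds folds for q2_cv (default 10).
#' @param scramble_reps Y-scrambling repetitions (default 25).
#' @param centering,rm2_variant statistic variants (see
#'   \code{\link{r_squared}}, \code{\link{rm2_family}}).
#' @param seed master seed for every random stage.
#' @param output_dir run directory to write artifacts into (created).
#' @return A list of class \code{"two_qsar_config"}.
#' @export
two_qsar_config <- function(input, schema = NULL, max_missing = 1,
                            r2_prune = 0.64, train_fraction = 0.8,
                            split_seed = NULL, member_subsets = NULL,
                            n_members = 3,
                            grid = svr_grid(C = 4^(0:4),
                                            gamma = 4^(-3:1),
                                            epsilon = c(0.05, 0.1)),
                            meta_grid = svr_grid(C = 4^(0:4),
                                                 gamma = 4^(-3:1),
                                                 epsilon = 0.1),
                            selection = "cv", max_members = 3,
                            cv_folds = 10, scramble_reps = 25,
                            centering = "observed_mean",
                            rm2_variant = "as_printed",
                            seed = 1, output_dir = tempfile("two_qsar_")) {
  if (missing(input) || is.null(input))
    stop("input is required (a CSV path or a records/table list)")
  structure(list(input = input, schema = schema,
                 max_missing = max_missing, r2_prune = r2_prune,
                 train_fraction = train_fraction,
                 split_seed = if (is.null(split_seed)) seed else split_seed,
                 member_subsets = member_subsets,
                 n_members = n_members, grid = grid,
                 meta_grid = meta_grid, selection = selection,
                 max_members = max_members, cv_folds = cv_folds,
                 scramble_reps = scramble_reps, centering = centering,
                 rm2_variant = rm2_variant, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "two_qsar_config")
}

# validation report for one subset of rows under one model predictor
.report_for <- function(y, pred, role, y_train, q2_cv = NULL,
                        centering, rm2_variant) {
  ps <- prediction_set(y, pred,
                       train_mean = if (role == "external")
                         mean(y_train) else NULL,
                       train_n = length(y_train))
  validation_report(ps, set_role = role, q2_cv = q2_cv,
                    train_ss = sum((y_train - mean(y_train))^2),
                    centering = centering, rm2_variant = rm2_variant)
}

#' Run the full two-QSAR workflow
#'
#' Executes the complete pipeline on one dataset: preprocessing
#' (missing-value and invariance filters, Spearman collinearity
#' pruning, autoscaling), chemical-space projection and structural
#' outlier designation, the diversity-preserving 4:1 split, descriptor
#' selection (unless member subsets are supplied), HSVR and PLS model
#' fitting, the full validation battery with criteria verdicts on the
#' training, test and outlier sets, 10-fold cross-validation, and
#' Y-scrambling. Every random stage is seeded from the config; all
#' artifacts (split CSVs, model JSON, report JSON, provenance log,
#' manifest) are written under \code{config$output_dir}.
#'
#' @param config a \code{\link{two_qsar_config}}.
#' @return Invisibly, a list with the fitted models, the split, every
#'   validation report and verdict, and \code{output_dir}.
#' @export
run_two_qsar <- function(config) {
  stopifnot(inherits(config, "two_qsar_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- if (is.character(config$input))
    read_descriptor_table(config$input, schema = config$schema)
  else config$input
  records <- dat$records
  table <- dat$table
  y_all <- records$log_kp
  if (anyNA(y_all)) stop("stage preprocess: missing response values")

  # --- preprocessing -----------------------------------------------
  prov <- list()
  table <- drop_missing(table, max_missing = config$max_missing)
  prov <- c(prov, attr(table, "provenance"))
  table <- drop_invariant(table)
  prov <- c(prov, attr(table, "provenance"))
  pr <- spearman_prune(table, y_all, r2_threshold = config$r2_prune,
                       protect = unique(unlist(config$member_subsets)))
  table <- pr$table
  write_provenance(prov, file.path(config$output_dir, "provenance.jsonl"))
  utils::write.csv(pr$dropped,
                   file.path(config$output_dir, "spearman_pruned.csv"),
                   row.names = FALSE)

  # --- chemical space, outliers, split -----------------------------
  norm_all <- normalize_table(table)
  pca <- pca_project(norm_all, n_components = min(3, ncol(table$values)))
  outlier_ids <- tryCatch(
    flag_outliers(records, table),
    error = function(e) character(0))   # count descriptors may be absent
  keep <- setdiff(table$compound_ids, outlier_ids)
  ki <- match(keep, table$compound_ids)
  split <- diverse_split(pca$scores[ki, , drop = FALSE], keep,
                         train_fraction = config$train_fraction,
                         seed = config$split_seed)
  split$outlier_ids <- outlier_ids
  write_split(split, config$output_dir)

  idx <- function(ids) match(ids, table$compound_ids)
  tr <- idx(split$train_ids); te <- idx(split$test_ids)
  ou <- idx(split$outlier_ids)
  y_tr <- y_all[tr]; y_te <- y_all[te]; y_ou <- y_all[ou]

  # training-set normalization parameters applied everywhere
  norm_train <- normalize_table(
    descriptor_table(table$values[tr, , drop = FALSE],
                     split$train_ids, table$descriptor_names))
  scale_rows <- function(ix) {
    apply_normalization(
      descriptor_table(table$values[ix, , drop = FALSE],
                       table$compound_ids[ix], table$descriptor_names),
      norm_train$norm_params)$values
  }
  x_tr <- norm_train$values
  x_te <- scale_rows(te)
  x_ou <- if (length(ou) > 0) scale_rows(ou) else NULL

  # --- descriptor selection ----------------------------------------
  subsets <- config$member_subsets
  selection_result <- NULL
  if (is.null(subsets)) {
    model_desc <- setdiff(colnames(x_tr), c("N_rot", "N_O"))
    pool_size <- min(config$n_members + 1L, length(model_desc))
    ga <- ga_select(x_tr[, model_desc, drop = FALSE], y_tr,
                    subset_size_range = c(min(2, pool_size), pool_size),
                    seed = config$seed)
    chosen <- ga$chosen
    if (length(chosen) > pool_size)
      chosen <- rfe_select(x_tr[, chosen, drop = FALSE], y_tr,
                           target_size = pool_size)$chosen
    selection_result <- ga
    # anchor: the descriptor most rank-correlated with the response;
    # each member pairs it with one further selected descriptor
    rho <- abs(stats::cor(x_tr[, chosen, drop = FALSE], y_tr,
                          method = "spearman")[, 1])
    anchor <- chosen[which.max(rho)]
    others <- setdiff(chosen, anchor)
    subsets <- lapply(others[seq_len(min(config$n_members,
                                         length(others)))],
                      function(d) c(anchor, d))
    write_selection_result(ga, file.path(config$output_dir,
                                         "selection.json"))
  }

  # --- HSVR ---------------------------------------------------------
  hsvr_model <- hsvr(x_tr, y_tr, subsets = subsets,
                     grid = config$grid, meta_grid = config$meta_grid,
                     selection = config$selection,
                     x_val = x_te, y_val = y_te,
                     cv_folds = min(config$cv_folds, 5),
                     seed = config$seed)
  write_hsvr_model(hsvr_model,
                   file.path(config$output_dir, "hsvr_model.json"))
  hsvr_q2cv <- kfold_cv(x_tr, y_tr, folds = config$cv_folds,
                        seed = config$seed,
                        fitter = function(xt, yt) {
                          m <- refit_hsvr(hsvr_model, xt, yt)
                          function(nd) predict(m, nd)
                        },
                        centering = config$centering)
  hsvr_scramble <- y_scramble(x_tr, y_tr,
                              fitter = function(xt, yt) {
                                m <- refit_hsvr(hsvr_model, xt, yt)
                                function(nd) predict(m, nd)
                              },
                              reps = config$scramble_reps,
                              seed = config$seed,
                              centering = config$centering)

  # --- PLS ----------------------------------------------------------
  pls_desc <- unique(unlist(subsets))
  pls_model <- fit_pls(x_tr[, pls_desc, drop = FALSE], y_tr,
                       cv_folds = min(config$cv_folds,
                                      length(y_tr) - 1),
                       seed = config$seed)
  pls_model$norm_params <- list(
    center = norm_train$norm_params$center[pls_desc],
    scale = norm_train$norm_params$scale[pls_desc])
  write_pls_model(pls_model,
                  file.path(config$output_dir, "pls_model.json"))
  pls_scramble <- y_scramble(
    x_tr[, pls_desc, drop = FALSE], y_tr,
    fitter = function(xt, yt) {
      fit <- stats::lm.fit(cbind(1, xt), yt)
      beta <- fit$coefficients; beta[is.na(beta)] <- 0
      function(nd) drop(cbind(1, nd) %*% beta)
    },
    reps = config$scramble_reps, seed = config$seed,
    centering = config$centering)

  # --- validation on the three sets ---------------------------------
  # pls_model was fitted on already-normalized rows: predict on the
  # scaled matrices directly
  predict_pls_raw <- function(m, x) {
    drop(x[, names(m$coefficients), drop = FALSE] %*% m$coefficients) +
      m$intercept
  }
  reports <- list()
  verdicts <- list()
  for (model_name in c("hsvr", "pls")) {
    pred_fun <- if (model_name == "hsvr")
      function(x) predict(hsvr_model, x)
    else function(x) predict_pls_raw(pls_model, x)
    q2cv <- if (model_name == "hsvr") hsvr_q2cv else pls_model$q2_cv
    reps <- list(
      train = .report_for(y_tr, pred_fun(x_tr), "training", y_tr,
                          q2_cv = q2cv, config$centering,
                          config$rm2_variant),
      test = .report_for(y_te, pred_fun(x_te), "external", y_tr,
                         centering = config$centering,
                         rm2_variant = config$rm2_variant))
    if (length(ou) >= 2)
      reps$outlier <- .report_for(y_ou, pred_fun(x_ou), "external",
                                  y_tr, centering = config$centering,
                                  rm2_variant = config$rm2_variant)
    reports[[model_name]] <- reps
    verdicts[[model_name]] <- list(
      test = criteria_check(reps$train, reps$test),
      outlier = if (!is.null(reps$outlier))
        criteria_check(reps$train, reps$outlier))
  }
  jsonlite::write_json(
    lapply(reports, function(mr) lapply(mr, unclass)),
    file.path(config$output_dir, "reports.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("skinperm")),
    seed = config$seed, split_seed = config$split_seed,
    r2_prune = config$r2_prune,
    train_fraction = config$train_fraction,
    cv_folds = config$cv_folds, scramble_reps = config$scramble_reps,
    max_members = config$max_members,
    member_subsets = subsets,
    n_train = length(tr), n_test = length(te),
    n_outlier = length(ou),
    hsvr_mean_rs2 = hsvr_scramble$mean_rs2,
    pls_mean_rs2 = pls_scramble$mean_rs2)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(hsvr = hsvr_model, pls = pls_model, split = split,
                 pca = pca, reports = reports, verdicts = verdicts,
                 hsvr_scramble = hsvr_scramble,
                 pls_scramble = pls_scramble,
                 selection = selection_result,
                 manifest = manifest,
                 output_dir = config$output_dir))
}
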