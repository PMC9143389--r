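#' Construct a descriptor table
#'
#' A descriptor table is the package's central container: an n x p numeric
#' matrix of molecular descriptors (rows are compounds, columns are
#' descriptors) together with its normalization state. Missing descriptor
#' values are stored as \code{NA} (explicitly present, never absent).
#'
#' @param values numeric matrix (n compounds x p descriptors); \code{NA}
#'   marks a missing value.
#' @param compound_ids character vector of unique compound identifiers,
#'   one per row.
#' @param descriptor_names character vector of descriptor names, one per
#'   column.
#' @param normalized logical; \code{TRUE} when columns have been centered
#'   and scaled (see \code{\link{normalize_table}}).
#' @param norm_params \code{NULL}, or a list with numeric vectors
#'   \code{center} and \code{scale} (one entry per descriptor) recording
#'   the fitting-set mean and sample standard deviation used.
#' @return An object of class \code{"descriptor_table"}.
#' @export
descriptor_table <- function(values, compound_ids, descriptor_names,
                             normalized = FALSE, norm_params = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (nrow(values) != length(compound_ids))
    stop("number of rows must equal number of compound ids")
  if (ncol(values) != length(descriptor_names))
    stop("number of columns must equal number of descriptor names")
  if (anyDuplicated(compound_ids))
    stop("duplicate compound id(s): ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (anyDuplicated(descriptor_names))
    stop("duplicate descriptor name(s)")
  dimnames(values) <- list(compound_ids, descriptor_names)
  if (normalized && is.null(norm_params))
    stop("a normalized table must carry norm_params")
  structure(list(values = values,
                 compound_ids = compound_ids,
                 descriptor_names = descriptor_names,
                 normalized = normalized,
                 norm_params = norm_params),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  nm <- x$descriptor_names
  if (length(nm) > 8) nm <- c(nm[1:8], "...")
  cat("  descriptors:", paste(nm, collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("  missing values:", n_na, "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' @export
as.matrix.descriptor_table <- function(x, ...) x$values

# column names treated as reserved (non-descriptor) roles when no schema given
.reserved_roles <- c(id = "id", name = "name", cas = "cas", smiles = "smiles",
                     response = "log_kp", pka_acid = "pka_acid",
                     pka_base = "pka_base")

.parse_numeric_cell <- function(x) {
  x <- trimws(x)
  x[x == "" | tolower(x) %in% c("na", "nan")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# pKa cells may carry several values separated by ';'
.parse_pka_cell <- function(cell, type) {
  v <- .parse_numeric_cell(strsplit(cell, ";", fixed = TRUE)[[1]])
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NULL)
  data.frame(value = v, type = rep(type, length(v)),
             stringsAsFactors = FALSE)
}

#' Read a compound descriptor table from CSV
#'
#' Reads an RFC-4180 CSV with a header row. Column roles are either
#' declared through \code{schema} or inferred from the reserved header
#' names \code{id}, \code{name}, \code{cas}, \code{smiles},
#' \code{log_kp}, \code{pka_acid}, \code{pka_base}; every remaining
#' column is treated as a numeric molecular descriptor. Empty cells,
#' \code{"NA"} and \code{"NaN"} (case-insensitive) in descriptor or
#' response columns parse to missing. pKa columns may carry several
#' values separated by \code{";"}.
#'
#' @param path path to a CSV file.
#' @param schema optional named list assigning columns to roles:
#'   \code{id}, \code{response}, \code{name}, \code{cas}, \code{smiles},
#'   \code{pka_acid}, \code{pka_base}, \code{passthrough} (character
#'   vector of columns to carry through unparsed), \code{descriptor}
#'   (character vector; default: all unassigned columns).
#' @param require_response logical; error when no response column is
#'   present (default \code{TRUE}).
#' @return A list with components \code{records} (a data frame with one
#'   row per compound: \code{id}, optional passthrough columns,
#'   \code{log_kp}, and a \code{pka} list-column of
#'   \code{data.frame(value, type)}) and \code{table} (a
#'   \code{\link{descriptor_table}}). Rows of both share order.
#' @seealso \code{\link{write_descriptor_table}} for the inverse.
#' @export
read_descriptor_table <- function(path, schema = NULL,
                                  require_response = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(raw)
  if (is.null(schema)) schema <- list()
  pick <- function(role, default) {
    if (!is.null(schema[[role]])) schema[[role]] else
      if (default %in% cols) default else NULL
  }
  id_col       <- pick("id", "id")
  resp_col     <- pick("response", "log_kp")
  name_col     <- pick("name", "name")
  cas_col      <- pick("cas", "cas")
  smiles_col   <- pick("smiles", "smiles")
  pka_acid_col <- pick("pka_acid", "pka_acid")
  pka_base_col <- pick("pka_base", "pka_base")
  passthrough  <- schema$passthrough

  if (is.null(id_col) || !id_col %in% cols)
    stop("no id column found (reserved name 'id' or schema$id)")
  if (require_response && (is.null(resp_col) || !resp_col %in% cols))
    stop("no response column found (reserved name 'log_kp' or schema$response)")

  ids <- trimws(raw[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  assigned <- c(id_col, resp_col, name_col, cas_col, smiles_col,
                pka_acid_col, pka_base_col, passthrough)
  desc_cols <- if (!is.null(schema$descriptor)) schema$descriptor
               else setdiff(cols, assigned)
  if (length(desc_cols) == 0) stop("no descriptor columns found")

  vals <- vapply(desc_cols, function(cn) .parse_numeric_cell(raw[[cn]]),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, desc_cols))

  pka <- lapply(seq_len(nrow(raw)), function(i) {
    out <- NULL
    if (!is.null(pka_acid_col))
      out <- rbind(out, .parse_pka_cell(raw[[pka_acid_col]][i], "acid"))
    if (!is.null(pka_base_col))
      out <- rbind(out, .parse_pka_cell(raw[[pka_base_col]][i], "base"))
    if (is.null(out))
      out <- data.frame(value = numeric(0), type = character(0),
                        stringsAsFactors = FALSE)
    out
  })

  records <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(name_col))   records$name   <- raw[[name_col]]
  if (!is.null(cas_col))    records$cas    <- raw[[cas_col]]
  if (!is.null(smiles_col)) records$smiles <- raw[[smiles_col]]
  for (pc in passthrough)   records[[pc]]  <- raw[[pc]]
  records$log_kp <- if (!is.null(resp_col) && resp_col %in% cols)
    .parse_numeric_cell(raw[[resp_col]]) else NA_real_
  records$pka <- pka

  list(records = records,
       table = descriptor_table(vals, ids, desc_cols))
}

#' Write a compound descriptor table to CSV
#'
#' Emits a CSV readable by \code{\link{read_descriptor_table}}; numeric
#' values are written with full double precision so that a
#' read-write-read round trip preserves them.
#'
#' @param records compound record data frame as returned by
#'   \code{\link{read_descriptor_table}}.
#' @param table the matching \code{\link{descriptor_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_descriptor_table <- function(records, table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!identical(records$id, table$compound_ids))
    stop("records and table must share compound order")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(id = records$id, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (cn in setdiff(names(records), c("id", "log_kp", "pka")))
    out[[cn]] <- records[[cn]]
  if (!is.null(records$pka)) {
    fmt_pka <- function(df, type) {
      v <- df$value[df$type == type]
      if (length(v) == 0) "" else paste(sprintf("%.17g", v), collapse = ";")
    }
    out$pka_acid <- vapply(records$pka, fmt_pka, "", type = "acid")
    out$pka_base <- vapply(records$pka, fmt_pka, "", type = "base")
  }
  out$log_kp <- fmt(records$log_kp)
  for (j in seq_along(table$descriptor_names))
    out[[table$descriptor_names[j]]] <- fmt(table$values[, j])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Skin permeability coefficient from steady-state flux
#'
#' Kp = Jss / dCv, the in vitro permeability coefficient: steady-state
#' flux across the membrane divided by the donor-side concentration
#' difference. Units are fixed at cm/h.
#'
#' @param jss steady-state flux.
#' @param delta_cv concentration difference; must be positive.
#' @return Kp (cm/h), vectorized over inputs.
#' @export
permeability_coefficient <- function(jss, delta_cv) {
  if (any(!is.finite(delta_cv)) || any(delta_cv <= 0))
    stop("delta_cv must be positive")
  jss / delta_cv
}

#' Base-10 log of a permeability coefficient
#'
#' The modelling scale throughout the package is log10 Kp; slow
#' permeants have negative values. The signed log is stored as-is
#' (never negated).
#'
#' @param kp permeability coefficient (cm/h); must be positive.
#' @return log10(kp).
#' @export
log_kp <- function(kp) {
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("kp must be positive")
  log10(kp)
}

#' Inverse of \code{\link{log_kp}}
#' @param log_kp_value log10 Kp.
#' @return Kp = 10^log_kp_value (cm/h).
#' @export
antilog_kp <- function(log_kp_value) 10^log_kp_value
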