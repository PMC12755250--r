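#' Construct a variable table
#'
#' The basic data container of the package: a numeric matrix of samples
#' (rows) by continuous variables (columns), with a role attached to every
#' variable.  Roles drive the default expert-knowledge constraints of
#' [hill_climb()]: the (single) `outcome` variable is a sink, and the
#' `genetic` variable may not point into aggregated parental factors.
#'
#' Missing values are rejected: complete-case filtering is expected to
#' happen at ingest, before a table is built (see [read_variable_table()]).
#'
#' @param values numeric matrix or data frame, n samples x p variables,
#'   with unique non-empty column names and n >= 3.
#' @param roles named character vector mapping variable names to one of
#'   `"predictor"`, `"outcome"`, `"genetic"`.  Unnamed variables default to
#'   `"predictor"`; at most one variable may be the outcome.
#' @return an object of class `variable_table`: the numeric matrix with a
#'   `roles` attribute.
#' @seealso [standardize()], [read_variable_table()]
#' @export
variable_table <- function(values, roles = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix or data frame")
  nm <- colnames(values)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
    stop("all variables must have non-empty names")
  if (anyDuplicated(nm))
    stop("duplicate variable names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (nrow(values) < 3L)
    stop("need at least 3 samples, got ", nrow(values))
  if (anyNA(values)) {
    bad <- nm[colSums(is.na(values)) > 0L]
    stop("missing values in: ", paste(bad, collapse = ", "),
         " (remove incomplete cases before building the table)")
  }
  full_roles <- rep("predictor", length(nm))
  names(full_roles) <- nm
  if (!is.null(roles)) {
    if (is.null(names(roles)) || !all(names(roles) %in% nm))
      stop("`roles` must be named by variables present in the table")
    if (!all(roles %in% c("predictor", "outcome", "genetic")))
      stop("roles must be 'predictor', 'outcome' or 'genetic'")
    full_roles[names(roles)] <- roles
  }
  if (sum(full_roles == "outcome") > 1L)
    stop("at most one variable may have role 'outcome'")
  structure(values, roles = full_roles, class = c("variable_table", "matrix"))
}

#' @export
print.variable_table <- function(x, ...) {
  roles <- variable_roles(x)
  cat("variable_table: ", nrow(x), " samples x ", ncol(x), " variables\n",
      sep = "")
  special <- roles[roles != "predictor"]
  if (length(special))
    cat("  roles: ", paste(names(special), special, sep = "=",
                           collapse = ", "), "\n", sep = "")
  if (isTRUE(attr(x, "standardized"))) cat("  standardized (z-scores)\n")
  invisible(x)
}

#' Variable roles of a table
#' @param table a [variable_table()].
#' @return named character vector of roles.
#' @export
variable_roles <- function(table) attr(table, "roles")

#' Read a variable table from CSV/TSV
#'
#' Expects a header row of variable names, one row per sample, `.` as the
#' decimal separator, UTF-8 encoding.  The dialect is chosen from the file
#' extension (`.tsv`/`.tab` = tab, otherwise comma) unless `sep` is given.
#' Rows containing any missing value are dropped (complete-case analysis),
#' with a message reporting how many.
#'
#' @param path file path.
#' @param outcome,genetic optional variable names assigned those roles.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return a [variable_table()].
#' @export
read_variable_table <- function(path, outcome = NULL, genetic = NULL,
                                sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          check.names = FALSE, fileEncoding = "UTF-8")
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    message("dropped ", sum(!keep), " incomplete rows of ", nrow(df))
    df <- df[keep, , drop = FALSE]
  }
  roles <- character(0)
  if (!is.null(outcome)) {
    if (!outcome %in% names(df)) stop("outcome variable not found: ", outcome)
    roles[outcome] <- "outcome"
  }
  if (!is.null(genetic)) {
    if (!genetic %in% names(df)) stop("genetic variable not found: ", genetic)
    roles[genetic] <- "genetic"
  }
  variable_table(df, roles = if (length(roles)) roles else NULL)
}

#' Write a variable table to CSV/TSV
#' @param table a [variable_table()].
#' @param path destination; extension selects the dialect as in
#'   [read_variable_table()].
#' @param sep field separator; `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_variable_table <- function(table, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(unclass_table(table)), path, sep = sep,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# strip class/attrs for plain-matrix math
unclass_table <- function(table) {
  x <- unclass(table)
  attr(x, "roles") <- NULL
  attr(x, "standardized") <- NULL
  attr(x, "true_dag") <- NULL
  attr(x, "true_coefficients") <- NULL
  x
}

#' Z-score standardization
#'
#' Centers every column to mean zero and scales to unit sample standard
#' deviation (denominator n - 1).  Standardizing twice is a no-op, and all
#' downstream scoring and effect estimates are expressed in standard units
#' because of this step.
#'
#' @param table a [variable_table()].
#' @return the standardized table, same class, with roles preserved and a
#'   `standardized` attribute set.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "variable_table"))
  x <- unclass_table(table)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero variance in: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  out <- variable_table(z, roles = variable_roles(table))
  attr(out, "standardized") <- TRUE
  out
}

#' Pearson correlation matrix of a table
#'
#' @param data a [variable_table()] with at least 3 samples.
#' @return symmetric p x p correlation matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
correlation_matrix <- function(data) {
  stopifnot(inherits(data, "variable_table"))
  r <- stats::cor(unclass_table(data))
  # cor() can drift off symmetry/unit diagonal at the last ulp
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", "matrix"))
}

#' @export
print.correlation_matrix <- function(x, digits = 3L, ...) {
  cat("correlation_matrix over", ncol(x), "variables\n")
  print(round(unclass(x), digits))
  invisible(x)
}
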