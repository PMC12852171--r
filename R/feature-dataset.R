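#' Construct a multisite feature dataset
#'
#' Bundles a subjects-by-features numeric matrix with per-subject site
#' labels and (optionally) biological covariates. This is the container
#' every fitting, transfer and evaluation function in the package operates
#' on. Rows are subjects, columns are features (voxels or ROIs); values are
#' e.g. unitless FA in roughly \[0, 1\] or MD in mm^2/s.
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#'   Must contain no missing or non-finite entries.
#' @param site vector of per-subject site labels (coerced to factor;
#'   unused levels are dropped).
#' @param covariates optional data.frame of per-subject covariates (e.g.
#'   `age` in years, `sex` coded 0/1 or a two-level factor). May be `NULL`.
#' @param feature_ids character vector of feature identifiers; defaults to
#'   the column names of `values` or `"f1" ... "fV"`.
#' @param subject_ids character vector of subject identifiers; defaults to
#'   the row names of `values` or `"s1" ... "sn"`.
#'
#' @return An object of class `feature_dataset`: a list with elements
#'   `values`, `site`, `covariates`, `feature_ids`, `subject_ids`.
#' @export
#' @examples
#' y <- matrix(rnorm(20), 10, 2)
#' d <- feature_dataset(y, site = rep(c("A", "B"), each = 5),
#'                      covariates = data.frame(age = runif(10, 12, 21)))
#' d
feature_dataset <- function(values, site, covariates = NULL,
                            feature_ids = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (length(site) != n)
    stop("length(site) [", length(site), "] != number of subjects [", n, "]")
  site <- droplevels(as.factor(site))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
  }
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must contain no missing or non-finite entries")
  if (is.null(feature_ids))
    feature_ids <- colnames(values)
  if (is.null(feature_ids))
    feature_ids <- paste0("f", seq_len(ncol(values)))
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length must equal the number of features")
  if (anyDuplicated(feature_ids))
    stop("feature_ids must be unique")
  if (is.null(subject_ids))
    subject_ids <- rownames(values)
  if (is.null(subject_ids))
    subject_ids <- paste0("s", seq_len(n))
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique")
  dimnames(values) <- list(subject_ids, feature_ids)
  structure(
    list(values = values, site = site, covariates = covariates,
         feature_ids = as.character(feature_ids),
         subject_ids = as.character(subject_ids)),
    class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("<feature_dataset> ", nrow(x$values), " subjects x ",
      ncol(x$values), " features\n", sep = "")
  cat("  sites: ",
      paste(sprintf("%s (n=%d)", levels(x$site), tabulate(x$site)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ", paste(names(x$covariates), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) dim(x$values)

# subset rows (subjects) of a dataset, keeping metadata aligned
#' Subset subjects of a feature dataset
#'
#' @param x a [feature_dataset()].
#' @param i subject index vector (integer, logical or subject ids).
#' @return A `feature_dataset` containing the selected subjects.
#' @export
subset_subjects <- function(x, i) {
  stopifnot(inherits(x, "feature_dataset"))
  if (is.character(i)) i <- match(i, x$subject_ids)
  feature_dataset(x$values[i, , drop = FALSE],
                  site = x$site[i],
                  covariates = if (is.null(x$covariates)) NULL else
                    x$covariates[i, , drop = FALSE],
                  feature_ids = x$feature_ids,
                  subject_ids = x$subject_ids[i])
}

# checks a dataset satisfies the *fitting* invariants (>=2 sites,
# >=2 subjects per site); plain datasets used only for transfer or
# evaluation are allowed to be smaller.
check_fittable <- function(dataset) {
  counts <- tabulate(dataset$site)
  if (nlevels(dataset$site) < 2)
    stop("fitting requires >= 2 sites; got ", nlevels(dataset$site))
  if (any(counts < 2))
    stop("fitting requires >= 2 subjects per site; site(s) ",
         paste(levels(dataset$site)[counts < 2], collapse = ", "),
         " have fewer")
  invisible(TRUE)
}

#' Read a feature dataset from a delimited table
#'
#' Expects one row per subject: a subject-id column, a site column, zero or
#' more covariate columns, then feature columns (all remaining columns).
#'
#' @param path file path of a CSV/TSV table (separator auto-detected from
#'   the extension: `.tsv` uses tab, anything else comma).
#' @param site_column name of the site column (default `"site"`).
#' @param id_column name of the subject-id column (default `"subject"`).
#' @param covariate_columns character vector of covariate column names
#'   (default none).
#' @return A [feature_dataset()].
#' @export
read_feature_dataset <- function(path, site_column = "site",
                                 id_column = "subject",
                                 covariate_columns = character()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(site_column, id_column, covariate_columns))
    if (!col %in% names(tab)) stop("column '", col, "' not found in ", path)
  meta <- c(id_column, site_column, covariate_columns)
  feat_cols <- setdiff(names(tab), meta)
  if (!length(feat_cols)) stop("no feature columns found in ", path)
  feature_dataset(as.matrix(tab[, feat_cols, drop = FALSE]),
                  site = tab[[site_column]],
                  covariates = if (length(covariate_columns))
                    tab[, covariate_columns, drop = FALSE] else NULL,
                  subject_ids = as.character(tab[[id_column]]))
}

#' Write a feature dataset to a delimited table
#'
#' Inverse of [read_feature_dataset()]: writes subject id, site, covariates
#' and then feature columns.
#'
#' @param dataset a [feature_dataset()].
#' @param path output file path (`.tsv` writes tab-separated, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_feature_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "feature_dataset"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- data.frame(subject = dataset$subject_ids,
                    site = as.character(dataset$site),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dataset$covariates)) tab <- cbind(tab, dataset$covariates)
  tab <- cbind(tab, as.data.frame(dataset$values, check.names = FALSE))
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
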