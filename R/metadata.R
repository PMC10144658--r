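#' Sample metadata
#'
#' Per-sample categorical group label plus named continuous clinical
#' parameters, each assigned to a parameter group (e.g. immune,
#' cardiovascular, endothelial, metabolites). Missing values are allowed
#' in parameters; each downstream test uses complete cases for its own
#' factor only.
#'
#' @param group named character/factor vector of group labels, names =
#'   sample ids.
#' @param parameters numeric matrix (samples x parameters) with dimnames;
#'   `NA` marks missing values. May have zero columns.
#' @param parameter_groups named character vector mapping parameter name
#'   to group name; parameters not mapped are assigned `"ungrouped"`.
#' @param reference_ranges optional named list of `c(low, high)` per
#'   parameter.
#' @return a `sample_metadata` object.
#' @export
sample_metadata <- function(group, parameters = NULL,
                            parameter_groups = character(),
                            reference_ranges = NULL) {
  ids <- names(group)
  if (is.null(ids)) stop("`group` must be a named vector (names = sample ids)")
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in metadata")
  if (is.null(parameters))
    parameters <- matrix(numeric(0), nrow = length(ids), ncol = 0,
                         dimnames = list(ids, NULL))
  if (!identical(rownames(parameters), ids))
    stop("parameter matrix rows must match group names")
  pg <- stats::setNames(rep("ungrouped", ncol(parameters)),
                        colnames(parameters))
  known <- intersect(names(parameter_groups), colnames(parameters))
  pg[known] <- parameter_groups[known]
  structure(list(group = stats::setNames(as.character(group), ids),
                 parameters = parameters,
                 parameter_groups = pg,
                 reference_ranges = reference_ranges),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("sample_metadata: %d samples, %d parameters in %d groups; groups: %s\n",
              length(x$group), ncol(x$parameters),
              length(unique(x$parameter_groups)),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Read sample metadata from TSV
#'
#' One row per sample; first column the sample id, a `group` column with
#' the categorical label, and one column per continuous parameter.
#' Missing values are empty cells or `NA`.
#'
#' @param path file to read.
#' @param group_spec named character vector mapping parameter name to
#'   parameter-group name. Parameters present in the file but not in
#'   `group_spec` are kept as `"ungrouped"` with a warning; names in
#'   `group_spec` absent from the file are skipped with a warning.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path, group_spec = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv_table(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in ", path)
  if (!"group" %in% names(df)) stop("metadata must contain a 'group' column")
  group <- stats::setNames(as.character(df$group), ids)
  par_cols <- setdiff(names(df), c(names(df)[1], "group"))
  params <- matrix(NA_real_, nrow = length(ids), ncol = length(par_cols),
                   dimnames = list(ids, par_cols))
  for (p in par_cols)
    params[, p] <- suppressWarnings(as.numeric(df[[p]]))
  absent <- setdiff(names(group_spec), par_cols)
  if (length(absent) > 0)
    warning("parameters in group_spec but absent from file, skipped: ",
            paste(absent, collapse = ", "))
  unmapped <- setdiff(par_cols, names(group_spec))
  if (length(unmapped) > 0 && length(group_spec) > 0)
    warning("parameters without a group assignment, kept as 'ungrouped': ",
            paste(unmapped, collapse = ", "))
  sample_metadata(group, params, group_spec)
}

#' Write sample metadata to TSV
#'
#' @param m a [sample_metadata()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(m, path) {
  df <- data.frame(sample = names(m$group), group = unname(m$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (p in colnames(m$parameters)) df[[p]] <- m$parameters[, p]
  write_tsv_table(df, path)
}

subset_samples_md <- function(m, keep) {
  sample_metadata(m$group[keep], m$parameters[keep, , drop = FALSE],
                  m$parameter_groups, m$reference_ranges)
}

#' Intersect a count table and metadata on shared samples
#'
#' Samples present in only one input are dropped (with a logged count);
#' the result is ordered by sorted sample id regardless of input order,
#' so downstream seeded analyses do not depend on file ordering.
#'
#' @param t a [count_table()].
#' @param m a [sample_metadata()].
#' @return list with elements `counts` and `metadata` on the common,
#'   sorted sample set.
#' @export
intersect_samples <- function(t, m) {
  common <- sort(intersect(sample_ids(t), names(m$group)))
  if (length(common) == 0)
    stop("no samples shared between count table and metadata")
  dropped <- (length(sample_ids(t)) - length(common)) +
    (length(m$group) - length(common))
  if (dropped > 0)
    msg("dropped %d unmatched sample entries; %d samples retained",
        dropped, length(common))
  list(counts = subset_samples_ct(t, common),
       metadata = subset_samples_md(m, common))
}
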