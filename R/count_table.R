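#' Taxon count tables
#'
#' A `count_table` holds a non-negative integer matrix of read counts
#' (samples in rows, taxa in columns) together with a rank-labelled
#' taxonomic lineage for every taxon. It is the raw observable every
#' downstream statistic is computed from.
#'
#' @name count_table
NULL

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Construct a count table
#'
#' @param counts numeric matrix, samples x taxa, with unique dimnames.
#'   Values must be non-negative integers (storage mode may be double).
#' @param lineages data.frame of lineage labels with one row per taxon
#'   (rownames = taxon ids) and columns from `kingdom` to `species`;
#'   `NA` marks ranks the taxon is unclassified at. If `NULL`, every
#'   taxon gets a lineage that is classified only at its own id (placed
#'   at `genus`).
#' @return a `count_table` object.
#' @export
count_table <- function(counts, lineages = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon identifiers in count table")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (is.null(lineages)) {
    lineages <- empty_lineages(colnames(counts))
    lineages$genus <- colnames(counts)
  } else {
    lineages <- as.data.frame(lineages, stringsAsFactors = FALSE)
    missing_taxa <- setdiff(colnames(counts), rownames(lineages))
    if (length(missing_taxa) > 0)
      stop("taxa without lineage entries: ",
           paste(utils::head(missing_taxa, 5), collapse = ", "))
    lineages <- lineages[colnames(counts), , drop = FALSE]
    for (r in setdiff(TAXONOMIC_RANKS, colnames(lineages)))
      lineages[[r]] <- NA_character_
    lineages <- lineages[, TAXONOMIC_RANKS, drop = FALSE]
  }
  structure(list(counts = counts, lineages = lineages),
            class = "count_table")
}

empty_lineages <- function(taxa) {
  df <- as.data.frame(matrix(NA_character_, nrow = length(taxa),
                             ncol = length(TAXONOMIC_RANKS)),
                      stringsAsFactors = FALSE)
  names(df) <- TAXONOMIC_RANKS
  rownames(df) <- taxa
  df
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, total %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(t) rownames(t$counts)
taxon_ids <- function(t) colnames(t$counts)

subset_taxa_ct <- function(t, keep) {
  count_table(t$counts[, keep, drop = FALSE],
              t$lineages[keep, , drop = FALSE])
}

subset_samples_ct <- function(t, keep) {
  count_table(t$counts[keep, , drop = FALSE], t$lineages)
}

# Parse one lineage string: either "k__X; p__Y; ..." style or plain
# semicolon-delimited rank values (kingdom first). Empty fields and
# bare prefixes ("g__") become NA.
parse_lineage_string <- function(s) {
  out <- stats::setNames(rep(NA_character_, length(TAXONOMIC_RANKS)),
                         TAXONOMIC_RANKS)
  if (is.na(s) || !nzchar(trimws(s))) return(out)
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  prefixed <- grepl("^[kpcofgs]__", parts)
  if (any(prefixed)) {
    for (p in parts[prefixed]) {
      code <- substr(p, 1, 3)
      rank <- names(RANK_PREFIXES)[RANK_PREFIXES == code]
      val <- substr(p, 4, nchar(p))
      if (length(rank) == 1 && nzchar(val)) out[rank] <- val
    }
  } else {
    n <- min(length(parts), length(TAXONOMIC_RANKS))
    vals <- parts[seq_len(n)]
    vals[!nzchar(vals)] <- NA_character_
    out[seq_len(n)] <- vals
  }
  out
}

format_lineage <- function(row) {
  vals <- unlist(row)
  keep <- !is.na(vals)
  if (!any(keep)) return("")
  paste0(RANK_PREFIXES[TAXONOMIC_RANKS[keep]], vals[keep], collapse = "; ")
}

#' Read a taxon count table
#'
#' TSV dialect: taxa as rows, samples as columns, first column the taxon
#' identifier, optional last column `lineage` holding either
#' `k__/p__/...`-prefixed or plain semicolon-delimited rank labels.
#' BIOM dialect: JSON (format 1.0) with taxonomy in the observation
#' metadata, read via the biomformat package.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom-json"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") return(read_count_table_biom(path))
  df <- read_tsv_table(path)
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers in ", path)
  has_lineage <- tolower(names(df)[ncol(df)]) == "lineage"
  value_cols <- seq(2, ncol(df) - as.integer(has_lineage))
  mat <- as.matrix(df[, value_cols, drop = FALSE])
  bad <- which(is.na(suppressWarnings(
    matrix(as.numeric(mat), nrow = nrow(mat)))) & !is.na(mat), arr.ind = TRUE)
  if (length(bad) > 0)
    stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                 taxa[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  storage.mode(mat) <- "double"
  rownames(mat) <- taxa
  lin <- empty_lineages(taxa)
  if (has_lineage) {
    parsed <- t(vapply(as.character(df[[ncol(df)]]), parse_lineage_string,
                       character(length(TAXONOMIC_RANKS))))
    lin[] <- parsed
  } else {
    lin$genus <- taxa
  }
  count_table(t(mat), lin)
}

read_count_table_biom <- function(path) {
  b <- biomformat::read_biom(path)
  mat <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
  lin <- empty_lineages(rownames(mat))
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(om) && NCOL(om) >= 1) {
    strings <- if (is.data.frame(om)) {
      apply(om, 1, function(r) paste(r[!is.na(r)], collapse = "; "))
    } else as.character(om)
    parsed <- t(vapply(strings, parse_lineage_string,
                       character(length(TAXONOMIC_RANKS))))
    lin[] <- parsed
  }
  count_table(t(mat), lin)
}

#' Write a count table
#'
#' @param t a [count_table()].
#' @param path output file.
#' @param format `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(t, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon = taxon_ids(t),
                     t(t$counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df$lineage <- apply(t$lineages, 1, function(r) format_lineage(r))
    write_tsv_table(df, path)
  } else {
    om <- data.frame(
      taxonomy = apply(t$lineages, 1, function(r) format_lineage(r)),
      row.names = taxon_ids(t), stringsAsFactors = FALSE)
    b <- biomformat::make_biom(t(t$counts), observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Aggregate a count table to a taxonomic rank
#'
#' Taxa sharing the same lineage down to `rank` are summed. Taxa
#' unclassified at `rank` are pooled by their deepest classified
#' ancestor under an `unclassified_<ancestor>` identifier, so the total
#' count of every sample is conserved.
#'
#' @param t a [count_table()].
#' @param rank one of `phylum`, `class`, `order`, `family`, `genus`,
#'   `species` (or `kingdom`).
#' @return a [count_table()] at the requested rank.
#' @export
aggregate_to_rank <- function(t, rank) {
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank: ", rank, " (expected one of ",
         paste(TAXONOMIC_RANKS, collapse = ", "), ")")
  ri <- match(rank, TAXONOMIC_RANKS)
  lin <- t$lineages
  keys <- character(nrow(lin))
  labels <- character(nrow(lin))
  for (i in seq_len(nrow(lin))) {
    prefix <- unlist(lin[i, seq_len(ri)])
    if (!is.na(prefix[ri])) {
      labels[i] <- prefix[ri]
    } else {
      anc <- prefix[!is.na(prefix)]
      labels[i] <- if (length(anc) > 0)
        paste0("unclassified_", anc[length(anc)]) else "unclassified"
      prefix[ri] <- labels[i]
    }
    keys[i] <- paste(ifelse(is.na(prefix), "", prefix), collapse = "|")
  }
  groups <- split(seq_len(nrow(lin)), keys)
  ord <- order(vapply(groups, min, 1L))  # stable: first-appearance order
  groups <- groups[ord]
  new_ids <- make.unique(vapply(groups, function(ix) labels[ix[1]], ""),
                         sep = "_")
  agg <- vapply(groups, function(ix)
    rowSums(t$counts[, ix, drop = FALSE]), numeric(nrow(t$counts)))
  if (nrow(t$counts) == 1) agg <- matrix(agg, nrow = 1,
                                         dimnames = list(sample_ids(t), NULL))
  colnames(agg) <- new_ids
  new_lin <- empty_lineages(new_ids)
  for (k in seq_along(groups)) {
    row <- unlist(lin[groups[[k]][1], seq_len(ri)])
    if (is.na(row[ri])) row[ri] <- labels[groups[[k]][1]]
    new_lin[k, seq_len(ri)] <- row
  }
  count_table(agg, new_lin)
}

#' Ranks a table's lineages are classified at
#'
#' @param t a [count_table()].
#' @return character vector of ranks with at least one classified taxon.
#' @export
available_ranks <- function(t) {
  TAXONOMIC_RANKS[vapply(t$lineages, function(col) any(!is.na(col)), TRUE)]
}
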