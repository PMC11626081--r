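#' Samples-by-features omics table
#'
#' Lightweight container for a numeric samples x features table together
#' with a flag marking compositional semantics (relative abundances or
#' counts whose per-sample total is a sequencing artifact, so that only
#' ratios between features are interpretable).
#'
#' @param values Numeric matrix, samples in rows and features in columns.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   rownames of `values` or `sample1..n`.
#' @param feature_ids Character vector of feature identifiers; defaults to
#'   colnames of `values` or `feature1..m`.
#' @param compositional Logical flag; `TRUE` for taxa count / relative
#'   abundance tables.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `compositional`.
#' @export
#' @examples
#' om <- omics_matrix(matrix(1:6, 2, 3), compositional = TRUE)
#' dim(om)
omics_matrix <- function(values, sample_ids = NULL, feature_ids = NULL,
                         compositional = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values)) stop("missing values are not allowed; remove or filter them first")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values)) stop("sample_ids length must match nrow(values)")
  if (length(feature_ids) != ncol(values)) stop("feature_ids length must match ncol(values)")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 compositional = isTRUE(compositional)),
            class = "omics_matrix")
}

#' @export
as.matrix.omics_matrix <- function(x, ...) x$values

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d samples x %d features (%scompositional)\n",
              nrow(x$values), ncol(x$values),
              if (x$compositional) "" else "non-"))
  invisible(x)
}

# Accept an omics_matrix or a plain matrix; return a numeric matrix.
om_values <- function(x) {
  if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
}

# Carry a new values matrix into a copy of `x`, updating feature ids.
om_update <- function(x, values, feature_ids = colnames(values)) {
  omics_matrix(values, sample_ids = x$sample_ids,
               feature_ids = feature_ids, compositional = x$compositional)
}

check_paired_samples <- function(A, B) {
  if (nrow(om_values(A)) != nrow(om_values(B)))
    stop("paired tables must have the same number of samples")
  if (inherits(A, "omics_matrix") && inherits(B, "omics_matrix") &&
      !identical(A$sample_ids, B$sample_ids))
    stop("sample_ids must be identical and identically ordered across paired tables")
  invisible(TRUE)
}

#' Read an omics table from TSV/CSV
#'
#' Reads a delimited table of abundances. By default samples are expected in
#' rows and features in columns; set `orientation = "features_in_rows"` for
#' the transposed dialect common in amplicon feature tables.
#'
#' @param path Path to a TSV or CSV file (delimiter inferred from the
#'   extension; `.csv` uses a comma, anything else a tab).
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param compositional Logical flag passed to [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_omics <- function(path, orientation = c("samples_in_rows", "features_in_rows"),
                       compositional = FALSE) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (orientation == "features_in_rows") m <- t(m)
  omics_matrix(m, compositional = compositional)
}

#' Write an omics table to TSV/CSV
#'
#' Inverse of [read_omics()]; preserves sample and feature order so tables
#' round-trip exactly.
#'
#' @param x An [omics_matrix()] or numeric matrix.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_omics <- function(x, path) {
  m <- om_values(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM v1 (JSON) table
#'
#' Maps a BIOM v1 observation table to an [omics_matrix()] with samples in
#' rows. Requires the `biomformat` package.
#'
#' @param path Path to a BIOM v1 JSON file.
#' @param compositional Logical flag; defaults to `TRUE` since BIOM tables
#'   typically hold taxon counts.
#' @return An [omics_matrix()].
#' @export
read_biom_table <- function(path, compositional = TRUE) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  omics_matrix(t(m), compositional = compositional)
}

#' Read a feature-to-group mapping
#'
#' Two-column TSV (feature_id, group_label), e.g. genus to phylum. Used to
#' build the group-structured weight constraint.
#'
#' @param path Path to the TSV file (no header required; a header line whose
#'   first field is `feature_id` is skipped).
#' @return Named character vector mapping feature id to group label.
#' @export
read_group_file <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", col.names = c("feature_id", "group"),
                   colClasses = "character")
  if (nrow(df) > 0 && df$feature_id[1] == "feature_id") df <- df[-1, , drop = FALSE]
  stats::setNames(df$group, df$feature_id)
}
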