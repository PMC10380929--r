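#' Read an expression (or probe) matrix from TSV/CSV
#'
#' Expects samples in rows and features in columns, a header row of feature
#' identifiers, and sample identifiers in the first column. An optional
#' `label` column (0/1) is carried through. Empty fields and the
#' `missing` sentinels are parsed as missing values.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` file.
#' @param missing Character vector of missing-value sentinels.
#' @return A dataset tibble (see [feature_names()]).
#' @export
read_expression <- function(path, missing = c("", "NA")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  x <- reader(path, na = missing, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) abort("duplicate sample ids in matrix file")
  if (anyDuplicated(names(x))) abort("duplicate feature ids in matrix file")
  if (nrow(x) < 2) abort("expression matrix needs at least 2 samples")
  tibble::as_tibble(x)
}

#' Write a dataset tibble as TSV
#'
#' @param data Dataset tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column sample label table
#'
#' @param path TSV with columns `sample_id`, `label` (0/1).
#' @return Tibble with character `sample_id` and integer `label`.
#' @export
read_labels <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("label file must have two columns: sample_id, label")
  names(x)[1:2] <- c("sample_id", "label")
  x$label <- check_binary_labels(x$label)
  x$sample_id <- as.character(x$sample_id)
  tibble::as_tibble(x[, c("sample_id", "label")])
}

#' Read a probe-to-gene mapping table
#'
#' @param path Two-column TSV (`probe_id`, `gene_id`); extra columns ignored.
#' @return Tibble with character columns `probe_id` and `gene_id`.
#' @export
read_mapping <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("mapping file must have two columns: probe_id, gene_id")
  names(x)[1:2] <- c("probe_id", "gene_id")
  tibble::tibble(probe_id = as.character(x$probe_id),
                 gene_id = as.character(x$gene_id))
}

#' Read a gene list (one identifier per line, `#` comments allowed)
#'
#' @param path Text file path.
#' @return Character vector of unique gene identifiers, file order.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}
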