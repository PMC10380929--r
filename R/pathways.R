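# Gene-set collections (MSigDB GMT dialect), minimum-size filtering, and the
# binary pathway-by-gene mask matrix with its size-normalization vector.

#' Read a gene-set collection in GMT format
#'
#' Each line holds `set name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate gene ids within a line are dropped (first occurrence kept);
#' duplicate set names are an error. Gene identifiers are opaque strings
#' matched exactly.
#'
#' @param path Path to a `.gmt` file.
#' @return A pathway collection: tibble with columns `pathway`,
#'   `description`, and list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(pathway = character(), description = character(),
                          genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", bad[1]))
  }
  out <- tibble::tibble(
    pathway = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(out$pathway)) {
    abort(sprintf("duplicate pathway name: %s",
                  out$pathway[duplicated(out$pathway)][1]))
  }
  if (any(lengths(out$genes) == 0)) abort("pathway with empty gene set")
  out
}

#' Write a pathway collection in GMT format
#'
#' @param collection Pathway collection tibble (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(p, d, g) paste(c(p, d, g), collapse = "\t"),
                  collection$pathway, collection$description, collection$genes)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Filter pathways against a gene universe and minimum size
#'
#' Each pathway's gene set is intersected with `universe` (preserving gene
#' order); pathways whose intersection holds fewer than `min_genes` genes
#' are dropped. Collection order is preserved.
#'
#' @param collection Pathway collection tibble.
#' @param universe Character vector of gene ids present in the expression
#'   data.
#' @param min_genes Minimum number of in-universe genes a pathway must
#'   retain. Default 10.
#' @return Filtered pathway collection with genes restricted to `universe`.
#' @export
filter_pathways <- function(collection, universe, min_genes = 10) {
  if (!is.numeric(min_genes) || min_genes < 1) abort("min_genes must be >= 1")
  genes <- lapply(collection$genes, function(g) g[g %in% universe])
  keep <- lengths(genes) >= min_genes
  out <- collection[keep, , drop = FALSE]
  out$genes <- genes[keep]
  if (nrow(out) == 0) {
    abort("no pathway retains enough genes; consider a smaller min_genes")
  }
  out
}

#' Build the binary pathway-by-gene mask matrix
#'
#' Constructs the m x n 0/1 matrix M with `M[i, j] = 1` iff gene j belongs
#' to pathway i, rows in collection order and columns in `gene_order`,
#' together with the per-pathway size-normalization vector u (see
#' [normalization_vector()]).
#'
#' @param collection Pathway collection already filtered against
#'   `gene_order` (see [filter_pathways()]).
#' @param gene_order Character vector fixing the gene/column order.
#' @param norm_mode `"inverse_sqrt"` (default; u = 1/sqrt(pathway size)),
#'   `"inverse"` (1/size) or `"none"` (all ones).
#' @return A `pinnet_mask` object: list with `M`, `pathway_names`,
#'   `gene_ids`, `u`, `norm_mode`.
#' @export
build_mask <- function(collection, gene_order,
                       norm_mode = c("inverse_sqrt", "inverse", "none")) {
  norm_mode <- match.arg(norm_mode)
  if (nrow(collection) == 0) abort("empty pathway collection: no mask rows")
  if (anyDuplicated(gene_order)) abort("gene_order contains duplicates")
  missing <- setdiff(unique(unlist(collection$genes)), gene_order)
  if (length(missing)) {
    abort(sprintf(
      "pathway gene(s) absent from gene_order (filter the collection first): %s",
      paste(head(missing, 5), collapse = ", ")))
  }
  m <- nrow(collection)
  n <- length(gene_order)
  M <- matrix(0, m, n, dimnames = list(collection$pathway, gene_order))
  for (i in seq_len(m)) {
    M[i, match(collection$genes[[i]], gene_order)] <- 1
  }
  mask <- structure(list(M = M,
                         pathway_names = collection$pathway,
                         gene_ids = gene_order,
                         u = NULL,
                         norm_mode = norm_mode),
                    class = "pinnet_mask")
  mask$u <- normalization_vector(mask, norm_mode)
  mask
}

#' Pathway-size normalization vector
#'
#' The pathway node's pre-activation is multiplied by a per-pathway scalar
#' u so that node magnitude does not grow with pathway size:
#' `u_i = 1` (`"none"`), `1 / size_i` (`"inverse"`) or `1 / sqrt(size_i)`
#' (`"inverse_sqrt"`, the default used throughout), where `size_i` is the
#' row sum of M.
#'
#' @param mask A `pinnet_mask` or a binary matrix.
#' @param mode Normalization mode.
#' @return Numeric vector of length m.
#' @export
normalization_vector <- function(mask, mode = c("inverse_sqrt", "inverse", "none")) {
  mode <- match.arg(mode)
  M <- if (inherits(mask, "pinnet_mask")) mask$M else mask
  sizes <- rowSums(M)
  if (any(sizes < 1)) abort("mask row with zero genes")
  switch(mode,
         none = rep(1, length(sizes)),
         inverse = 1 / sizes,
         inverse_sqrt = 1 / sqrt(sizes))
}

#' @export
print.pinnet_mask <- function(x, ...) {
  sizes <- rowSums(x$M)
  cat(sprintf("<pinnet_mask> %d pathways x %d genes (norm_mode = %s)\n",
              nrow(x$M), ncol(x$M), x$norm_mode))
  cat(sprintf("  pathway sizes: min %d / mean %.1f / max %d\n",
              min(sizes), mean(sizes), max(sizes)))
  invisible(x)
}

#' Export a mask matrix as TSV for inspection
#'
#' @param mask A `pinnet_mask`.
#' @param path Output path (pathway rows, gene columns, 0/1 entries).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  df <- tibble::as_tibble(as.data.frame(mask$M, optional = TRUE))
  df <- dplyr::bind_cols(tibble::tibble(pathway = mask$pathway_names), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
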