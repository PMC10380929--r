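#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif rbinom sd cor quantile IQR setNames
#' @importFrom utils head tail
NULL

# Columns of a dataset tibble that are metadata rather than features.
.META_COLS <- c("sample_id", "label")

#' Feature (gene or probe) columns of a dataset tibble
#'
#' Dataset tibbles carry one row per sample, a `sample_id` column, an
#' optional binary `label` column (case = 1, control = 0) and one numeric
#' column per feature.
#'
#' @param data A dataset tibble.
#' @return Character vector of feature column names, in column order.
#' @export
feature_names <- function(data) {
  setdiff(names(data), .META_COLS)
}

#' Extract the numeric feature matrix from a dataset tibble
#'
#' @param data A dataset tibble (see [feature_names()]).
#' @return A numeric matrix, samples in rows (rownames = `sample_id`),
#'   features in columns.
#' @export
feature_matrix <- function(data) {
  feats <- feature_names(data)
  m <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(data$sample_id)
  m
}

#' Assemble a dataset tibble from a matrix and labels
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param labels Optional integer vector of 0/1 labels, one per row.
#' @param sample_ids Optional sample identifiers; defaults to rownames or
#'   `s1..sn`.
#' @return A dataset tibble.
#' @export
as_dataset <- function(x, labels = NULL, sample_ids = NULL) {
  sample_ids <- sample_ids %||% rownames(x) %||% paste0("s", seq_len(nrow(x)))
  out <- tibble::as_tibble(as.data.frame(x, optional = TRUE))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    out <- dplyr::bind_cols(tibble::tibble(label = as.integer(labels)), out)
  }
  dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)), out)
}

#' Derive a stage-specific seed from a global seed
#'
#' All pipeline stages draw their randomness from seeds derived
#' deterministically from one global seed and the stage name, so a single
#' `--seed` reproduces a full run. The derivation is a small polynomial
#' string hash folded with the global seed, truncated to 31 bits.
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Defensive scalar checks ----------------------------------------------------

check_fraction <- function(x, name, upper_open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 &&
    (if (upper_open) x < 1 else x <= 1)
  if (!ok) abort(sprintf("`%s` must be a single number in [0, %s)", name,
                         if (upper_open) "1" else "1]"))
  invisible(x)
}

check_binary_labels <- function(y) {
  if (!all(y %in% c(0L, 1L))) abort("labels must be 0 (control) or 1 (case)")
  if (length(unique(y)) < 2) abort("both classes must be present")
  invisible(as.integer(y))
}
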