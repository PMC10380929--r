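# Expression-matrix preprocessing: imputation, IQR probe filtering,
# probe-to-gene collapse, min-max scaling, cross-dataset gene intersection.

#' Per-feature interquartile range
#'
#' IQR across samples for every feature column, using linear interpolation
#' between order statistics (quantile type 7). Missing values are ignored.
#'
#' @param data Dataset tibble.
#' @return Named numeric vector of IQRs, one per feature.
#' @export
feature_iqr <- function(data) {
  x <- feature_matrix(data)
  apply(x, 2, IQR, na.rm = TRUE, type = 7)
}

#' Replace missing values by the per-feature mean
#'
#' Each missing entry is replaced by the mean of the observed values of the
#' same feature; observed entries are untouched.
#'
#' @param data Dataset tibble, possibly with `NA` entries.
#' @return Dataset tibble with no missing feature values.
#' @export
mean_impute <- function(data) {
  feats <- feature_names(data)
  x <- feature_matrix(data)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    abort(sprintf("feature(s) with no observed values: %s",
                  paste(feats[n_obs == 0], collapse = ", ")))
  }
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
    data[, feats] <- tibble::as_tibble(as.data.frame(x, optional = TRUE))
  }
  data
}

#' Drop low-variability features by interquartile range
#'
#' Removes the `drop_fraction` of features with the lowest IQR across
#' samples, keeping the `ceiling((1 - drop_fraction) * P)` highest-IQR
#' features. Ties are broken by first occurrence; surviving columns keep
#' their original order.
#'
#' @param data Dataset tibble with no missing feature values.
#' @param drop_fraction Fraction of features to drop, in `[0, 1)`. Default
#'   0.30.
#' @return Filtered dataset tibble.
#' @export
iqr_filter <- function(data, drop_fraction = 0.30) {
  check_fraction(drop_fraction, "drop_fraction")
  feats <- feature_names(data)
  if (anyNA(data[, feats])) abort("run mean_impute() before iqr_filter()")
  iqr <- feature_iqr(data)
  n_keep <- as.integer(ceiling((1 - drop_fraction) * length(feats)))
  keep_set <- feats[order(-iqr, seq_along(iqr))[seq_len(n_keep)]]
  keep <- feats[feats %in% keep_set]
  data[, c(intersect(.META_COLS, names(data)), keep)]
}

#' Collapse probe columns to gene columns by maximum IQR
#'
#' Probes absent from the mapping are dropped. When several probes map to
#' the same gene, the values of the probe with the maximum IQR (first
#' occurrence on ties) are taken verbatim. Gene columns appear in the order
#' in which their first mapped probe appears.
#'
#' @param data Probe-level dataset tibble with no missing values.
#' @param mapping Tibble with columns `probe_id`, `gene_id`.
#' @return Gene-level dataset tibble.
#' @export
collapse_probes <- function(data, mapping) {
  feats <- feature_names(data)
  mapping <- mapping[mapping$probe_id %in% feats, , drop = FALSE]
  mapping <- mapping[!duplicated(mapping$probe_id), , drop = FALSE]
  if (nrow(mapping) == 0) abort("no probes in the matrix are covered by the mapping")
  iqr <- feature_iqr(data)
  gene_of <- setNames(mapping$gene_id, mapping$probe_id)
  mapped <- feats[feats %in% names(gene_of)]
  picked <- tibble::tibble(probe = mapped,
                           gene = unname(gene_of[mapped]),
                           iqr = unname(iqr[mapped])) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice(which.max(.data$iqr)) |>
    dplyr::ungroup()
  # gene order = order of each gene's first mapped probe
  first_seen <- match(unique(gene_of[mapped]), picked$gene)
  picked <- picked[first_seen, , drop = FALSE]
  out <- data[, c(intersect(.META_COLS, names(data)), picked$probe)]
  names(out)[match(picked$probe, names(out))] <- picked$gene
  out
}

#' Scale each feature to the unit interval
#'
#' Per-feature affine map onto `[0, 1]` using the minimum and maximum
#' computed on the fit partition (`fit_on = "all"`, the default, uses every
#' sample; `"train_only"` uses only `train_ids`, in which case held-out
#' samples may fall outside `[0, 1]` unless `clip = TRUE`). Constant
#' features map to 0. The fitted minima and ranges are attached as
#' attributes so [minmax_inverse()] can undo the map.
#'
#' @param data Dataset tibble with no missing feature values.
#' @param fit_on `"all"` or `"train_only"`.
#' @param train_ids Sample ids defining the fit partition when
#'   `fit_on = "train_only"`.
#' @param clip Clip scaled values into `[0, 1]`? Default `FALSE`.
#' @return Scaled dataset tibble with attributes `scale_min`, `scale_range`.
#' @export
minmax_scale <- function(data, fit_on = c("all", "train_only"),
                         train_ids = NULL, clip = FALSE) {
  fit_on <- match.arg(fit_on)
  feats <- feature_names(data)
  x <- feature_matrix(data)
  if (anyNA(x)) abort("run mean_impute() before minmax_scale()")
  fit_rows <- if (fit_on == "train_only") {
    if (is.null(train_ids)) abort("fit_on = 'train_only' requires train_ids")
    which(data$sample_id %in% train_ids)
  } else {
    seq_len(nrow(x))
  }
  lo <- apply(x[fit_rows, , drop = FALSE], 2, min)
  hi <- apply(x[fit_rows, , drop = FALSE], 2, max)
  rng <- hi - lo
  const <- rng <= 0
  rng[const] <- 1  # constant features map to 0 by convention
  scaled <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  scaled[, const] <- 0
  if (clip) scaled <- pmin(pmax(scaled, 0), 1)
  data[, feats] <- tibble::as_tibble(as.data.frame(scaled, optional = TRUE))
  attr(data, "scale_min") <- setNames(lo, feats)
  attr(data, "scale_range") <- setNames(rng, feats)
  attr(data, "scale_constant") <- setNames(const, feats)
  data
}

#' Invert a [minmax_scale()] transform
#'
#' @param data A tibble produced by [minmax_scale()] (carries the fit as
#'   attributes). Constant features are restored to their fitted minimum.
#' @return Dataset tibble on the original scale.
#' @export
minmax_inverse <- function(data) {
  lo <- attr(data, "scale_min")
  rng <- attr(data, "scale_range")
  if (is.null(lo) || is.null(rng)) abort("no min-max fit attached to this dataset")
  feats <- feature_names(data)
  x <- feature_matrix(data)
  orig <- sweep(sweep(x, 2, rng[feats], "*"), 2, lo[feats], "+")
  data[, feats] <- tibble::as_tibble(as.data.frame(orig, optional = TRUE))
  attr(data, "scale_min") <- NULL
  attr(data, "scale_range") <- NULL
  attr(data, "scale_constant") <- NULL
  data
}

#' Restrict two datasets to their common genes
#'
#' Both datasets are restricted to the sorted intersection of their gene
#' sets, giving identical column order.
#'
#' @param a,b Dataset tibbles.
#' @return Named list with elements `a` and `b`.
#' @export
intersect_genes <- function(a, b) {
  common <- sort(intersect(feature_names(a), feature_names(b)))
  if (length(common) == 0) abort("datasets share no genes")
  list(a = a[, c(intersect(.META_COLS, names(a)), common)],
       b = b[, c(intersect(.META_COLS, names(b)), common)])
}
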