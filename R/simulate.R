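# Synthetic transcriptome generator: overlapping pathway collections and
# min-max-scaled expression matrices with differential signal planted inside
# designated pathways, plus ground truth for recovery experiments.

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic cohort: sample count and
#' class imbalance, gene universe, an overlapping pathway collection, a set
#' of signal pathways whose member genes receive a mean shift in cases, and
#' the background noise model.
#'
#' @param n_samples Number of samples.
#' @param case_fraction Fraction of case (label 1) samples, in (0, 1).
#' @param n_genes Number of genes.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Length-2 integer vector, min/max genes per
#'   pathway (sizes drawn uniformly).
#' @param n_signal_pathways Number of pathways carrying planted signal.
#' @param n_signal_genes_per_pathway Member genes per signal pathway that
#'   receive the case mean shift (distinct across pathways).
#' @param effect_size Case mean shift, in pre-scaling noise-sd units.
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param background_corr Equicorrelation of the background noise across
#'   genes, in `[0, 1)` (0 = independent genes).
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 300, case_fraction = 1 / 3, n_genes = 1000,
                       n_pathways = 50, pathway_size_range = c(10, 60),
                       n_signal_pathways = 5, n_signal_genes_per_pathway = 4,
                       effect_size = 1.5, noise_sd = 1.0,
                       background_corr = 0, seed = 1L) {
  check_fraction(background_corr, "background_corr")
  if (case_fraction <= 0 || case_fraction >= 1) abort("case_fraction must be in (0,1)")
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (n_signal_pathways > n_pathways) abort("more signal pathways than pathways")
  if (pathway_size_range[1] > n_genes) abort("pathway min size exceeds gene count")
  if (n_signal_pathways * n_signal_genes_per_pathway > n_genes) {
    abort("more signal genes than genes")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate an overlapping pathway collection
#'
#' Pathway sizes are uniform in `pathway_size_range`; each pathway's genes
#' are drawn without replacement within the pathway but independently across
#' pathways, so pathways overlap, as curated collections do.
#'
#' @param cfg A [sim_config()].
#' @return A pathway collection tibble (see [read_gmt()]).
#' @export
generate_pathways <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- paste0("g", seq_len(cfg$n_genes))
  with_seed(derive_seed(cfg$seed, "pathways"), {
    size_hi <- min(cfg$pathway_size_range[2], cfg$n_genes)
    sizes <- sample(seq(cfg$pathway_size_range[1], size_hi),
                    cfg$n_pathways, replace = TRUE)
    tibble::tibble(
      pathway = sprintf("PW%03d", seq_len(cfg$n_pathways)),
      description = ifelse(seq_len(cfg$n_pathways) <= cfg$n_signal_pathways,
                           "signal", "background"),
      genes = lapply(sizes, function(s) sample(genes, s))
    )
  })
}

#' Generate a labelled expression dataset with planted pathway signal
#'
#' Baseline expression is Gaussian noise (optionally equicorrelated across
#' genes through a shared per-sample factor). For each signal pathway,
#' `n_signal_genes_per_pathway` member genes — distinct across pathways —
#' get a `+effect_size` mean shift in case samples. Every gene is then
#' min-max scaled to `[0, 1]`, mirroring the preprocessing the classifier
#' expects. Class labels are assigned to exactly
#' `round(n_samples * case_fraction)` samples.
#'
#' @param cfg A [sim_config()].
#' @param pathways Pathway collection from [generate_pathways()] (generated
#'   from `cfg` if omitted).
#' @return List with `data` (dataset tibble with `sample_id`, `label`, gene
#'   columns) and `truth` (list: `signal_genes`, `signal_pathways`,
#'   `effects` named per signal gene).
#' @export
generate_expression <- function(cfg, pathways = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  pathways <- pathways %||% generate_pathways(cfg)
  genes <- paste0("g", seq_len(cfg$n_genes))
  n <- cfg$n_samples
  n_case <- round(n * cfg$case_fraction)
  if (n_case < 1 || n_case > n - 1) abort("degenerate class split")

  with_seed(derive_seed(cfg$seed, "expression"), {
    labels <- sample(c(rep(1L, n_case), rep(0L, n - n_case)))
    x <- matrix(rnorm(n * cfg$n_genes, sd = cfg$noise_sd), n, cfg$n_genes,
                dimnames = list(paste0("s", seq_len(n)), genes))
    if (cfg$background_corr > 0) {
      shared <- rnorm(n, sd = cfg$noise_sd)
      x <- sqrt(1 - cfg$background_corr) * x +
        sqrt(cfg$background_corr) * matrix(shared, n, cfg$n_genes)
    }
    signal_pw <- pathways$pathway[seq_len(cfg$n_signal_pathways)]
    signal_genes <- character(0)
    for (pw in signal_pw) {
      members <- setdiff(pathways$genes[[match(pw, pathways$pathway)]], signal_genes)
      if (length(members) < cfg$n_signal_genes_per_pathway) {
        abort(sprintf("pathway %s has too few unused genes for the requested signal", pw))
      }
      signal_genes <- c(signal_genes, members[seq_len(cfg$n_signal_genes_per_pathway)])
    }
    shift <- cfg$effect_size * cfg$noise_sd
    if (shift > 0) {
      x[labels == 1L, signal_genes] <- x[labels == 1L, signal_genes] + shift
    } else if (cfg$effect_size == 0 && cfg$noise_sd == 0) {
      warn("effect and noise both zero: degenerate constant matrix")
    }
    data <- minmax_scale(as_dataset(x, labels = labels))
    attr(data, "scale_min") <- NULL
    attr(data, "scale_range") <- NULL
    attr(data, "scale_constant") <- NULL
    list(data = data,
         truth = list(signal_genes = signal_genes,
                      signal_pathways = signal_pw,
                      effects = setNames(rep(shift, length(signal_genes)),
                                         signal_genes)))
  })
}

#' The canonical synthetic benchmark bundle
#'
#' One call producing the fixed study conditions used throughout the
#' package's validation: 300 samples with 1:2 case/control imbalance, 1,000
#' genes, 50 pathways of 10-60 genes, 5 signal pathways x 4 signal genes
#' (20 truth genes), case mean shift 1.5 noise-sd units. Optionally writes
#' the bundle (`expr.tsv`, `labels.tsv`, `sets.gmt`, `truth.json`) to a
#' directory.
#'
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @param effect_size Override of the planted effect (0 gives the matched
#'   null benchmark).
#' @return List with `data`, `pathways`, `truth`, `config`.
#' @export
default_benchmark <- function(seed = 1L, dir = NULL, effect_size = 1.5) {
  cfg <- sim_config(n_samples = 300, case_fraction = 0.33, n_genes = 1000,
                    n_pathways = 50, pathway_size_range = c(10, 60),
                    n_signal_pathways = 5, n_signal_genes_per_pathway = 4,
                    effect_size = effect_size, noise_sd = 1.0, seed = seed)
  pw <- generate_pathways(cfg)
  sim <- generate_expression(cfg, pw)
  bundle <- list(data = sim$data, pathways = pw, truth = sim$truth, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(sim$data[, c("sample_id", feature_names(sim$data))],
                     file.path(dir, "expr.tsv"))
    readr::write_tsv(sim$data[, c("sample_id", "label")],
                     file.path(dir, "labels.tsv"), progress = FALSE)
    write_gmt(pw, file.path(dir, "sets.gmt"))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
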