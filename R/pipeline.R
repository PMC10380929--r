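# End-to-end pipeline: simulate -> preprocess -> mask -> train -> interpret
# -> select-features, driven by a JSON-serializable run configuration, with
# a content-hashed artifact manifest for reproducibility checks.

#' Assemble a run configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param expr,labels,gmt,known_genes Input paths (expression TSV, label
#'   TSV, GMT gene sets, known-gene list). `expr`/`labels`/`gmt` may be
#'   omitted when the `simulate` stage is requested.
#' @param stages Character vector of stages to run, in pipeline order, from
#'   `c("simulate", "preprocess", "mask", "train", "interpret",
#'   "select_features")`.
#' @param seed Global seed; each stage derives its own seed from it via
#'   [derive_seed()].
#' @param sim Simulation settings (arguments for [sim_config()]).
#' @param preprocess List with `drop_iqr` (IQR drop fraction) and optional
#'   `mapping` (probe-to-gene TSV path).
#' @param mask_opts List with `min_genes`, `norm_mode`.
#' @param train List with `grid` (data frame width/lr), `n_folds`, and
#'   [train_opts()] fields.
#' @param interpret List with `ref_size`, `fraction` (feature selection).
#' @return A `pinnet_run_config`.
#' @export
run_config <- function(out_dir, expr = NULL, labels = NULL, gmt = NULL,
                       known_genes = NULL,
                       stages = c("simulate", "mask", "train", "interpret"),
                       seed = 1L, sim = list(), preprocess = list(),
                       mask_opts = list(), train = list(), interpret = list()) {
  known <- c("simulate", "preprocess", "mask", "train", "interpret",
             "select_features")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  structure(list(out_dir = out_dir, expr = expr, labels = labels, gmt = gmt,
                 known_genes = known_genes, stages = stages,
                 seed = as.integer(seed),
                 sim = sim, preprocess = preprocess, mask_opts = mask_opts,
                 train = train, interpret = interpret),
            class = "pinnet_run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return A `pinnet_run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

validate_run_config <- function(config) {
  need_inputs <- !("simulate" %in% config$stages)
  if (need_inputs) {
    for (f in c("expr", "labels", "gmt")) {
      if (is.null(config[[f]])) abort(sprintf("config field `%s` is required", f))
      if (!file.exists(config[[f]])) abort(sprintf("%s file not found: %s", f, config[[f]]))
    }
  }
  if (!is.null(config$known_genes) && !file.exists(config$known_genes)) {
    abort(sprintf("known_genes file not found: %s", config$known_genes))
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order and writes every artifact under
#' `config$out_dir`, finishing with `manifest.json` listing each output
#' file and its MD5 content hash; re-running with an identical
#' configuration reproduces identical hashes.
#'
#' @param config A `pinnet_run_config` (or path to its JSON form).
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  artifacts <- character(0)
  seed <- config$seed

  if ("simulate" %in% config$stages) {
    cfg <- do.call(sim_config, c(config$sim,
                                 list(seed = derive_seed(seed, "simulate"))))
    pw <- generate_pathways(cfg)
    simd <- generate_expression(cfg, pw)
    data <- simd$data
    collection <- pw
    write_expression(data[, c("sample_id", feature_names(data))], out("expr.tsv"))
    readr::write_tsv(data[, c("sample_id", "label")], out("labels.tsv"),
                     progress = FALSE)
    write_gmt(pw, out("sets.gmt"))
    jsonlite::write_json(simd$truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    artifacts <- c(artifacts, "expr.tsv", "labels.tsv", "sets.gmt", "truth.json")
  } else {
    data <- read_expression(config$expr)
    lab <- read_labels(config$labels)
    data <- dplyr::inner_join(lab, data, by = "sample_id")
    collection <- read_gmt(config$gmt)
  }

  if ("preprocess" %in% config$stages) {
    drop_iqr <- config$preprocess$drop_iqr %||% 0.30
    data <- mean_impute(data)
    data <- iqr_filter(data, drop_fraction = drop_iqr)
    if (!is.null(config$preprocess$mapping)) {
      data <- collapse_probes(data, read_mapping(config$preprocess$mapping))
    }
    data <- minmax_scale(data)
    write_expression(data, out("preprocessed.tsv"))
    artifacts <- c(artifacts, "preprocessed.tsv")
  }

  mask <- NULL
  if (any(c("mask", "train", "interpret", "select_features") %in% config$stages)) {
    min_genes <- config$mask_opts$min_genes %||% 10
    norm_mode <- config$mask_opts$norm_mode %||% "inverse_sqrt"
    filtered <- filter_pathways(collection, feature_names(data), min_genes)
    mask <- build_mask(filtered, feature_names(data), norm_mode = norm_mode)
    if ("mask" %in% config$stages) {
      write_mask(mask, out("mask.tsv"))
      artifacts <- c(artifacts, "mask.tsv")
    }
  }

  cv <- NULL
  if (any(c("train", "interpret") %in% config$stages)) {
    tr <- config$train
    grid <- if (!is.null(tr$grid)) tibble::as_tibble(tr$grid) else NULL
    opts <- do.call(train_opts, tr[intersect(names(tr), names(formals(train_opts)))])
    cv <- cross_validate(data, mask = mask, grid = grid, opts = opts,
                         n_folds = tr$n_folds %||% 10,
                         seed = derive_seed(seed, "train"),
                         norm_mode = mask$norm_mode)
    readr::write_tsv(cv$reports, out("cv_reports.tsv"), progress = FALSE)
    jsonlite::write_json(as.list(glance(cv)), out("cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "cv_reports.tsv", "cv_summary.json")
  }

  if ("interpret" %in% config$stages) {
    ref_size <- config$interpret$ref_size %||% 100
    gi <- cv_importance(cv, data, layer = "genes", ref_size = ref_size,
                        seed = derive_seed(seed, "interpret"))
    pi_ <- cv_importance(cv, data, layer = "pathways", ref_size = ref_size,
                         seed = derive_seed(seed, "interpret"))
    readr::write_tsv(gi, out("gene_importance.tsv"), progress = FALSE)
    readr::write_tsv(pi_, out("pathway_importance.tsv"), progress = FALSE)
    artifacts <- c(artifacts, "gene_importance.tsv", "pathway_importance.tsv")
    if (!is.null(config$known_genes)) {
      kt <- known_gene_test(gi, read_gene_list(config$known_genes))
      jsonlite::write_json(as.list(kt), out("known_gene_test.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, "known_gene_test.json")
    }
    sc <- size_importance_correlation(mask, pi_)
    jsonlite::write_json(as.list(sc), out("size_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "size_correlation.json")
  }

  if ("select_features" %in% config$stages) {
    fraction <- config$interpret$fraction %||% 0.10
    opts <- do.call(train_opts, config$train[intersect(names(config$train),
                                                       names(formals(train_opts)))])
    fs <- feature_selection_experiment(data, mask, fraction = fraction,
                                       seed = derive_seed(seed, "select"),
                                       opts = opts,
                                       n_repeats = config$interpret$n_repeats %||% 10,
                                       ref_size = config$interpret$ref_size %||% 100)
    readr::write_tsv(fs, out("feature_selection.tsv"), progress = FALSE)
    artifacts <- c(artifacts, "feature_selection.tsv")
  }

  manifest <- tibble::tibble(
    file = artifacts,
    md5 = unname(tools::md5sum(file.path(config$out_dir, artifacts))))
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA)
  invisible(manifest)
}
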