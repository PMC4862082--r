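#' Run the full replicability workflow from one declarative config
#'
#' Orchestrates simulate (or read) -> per-batch network construction under
#' each requested data-treatment variant -> aggregation -> cross-validated
#' neighbor-voting scoring -> topology replicability report -> confound
#' diagnostics, writing all report tables plus a manifest into an output
#' directory. Every randomized stage takes a seed derived deterministically
#' from the config's root seed, so two runs with the same config are
#' byte-identical.
#'
#' @param config a named list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{simulation}{arguments for [simulationConfig()] (omit to read
#'       data instead).}
#'     \item{expression / format / sample_meta / unit}{input paths for
#'       [readExpression()] when not simulating.}
#'     \item{variants}{subset of \code{c("umi","cpm","binary","nozero",
#'       "pooled")} (default all five).}
#'     \item{annotations}{GMT path; when simulating, omit to derive sets
#'       from the planted modules.}
#'     \item{match_fraction, n_decoy_sets, size_range}{forwarded to
#'       [generateAnnotations()].}
#'     \item{min_size, max_size}{annotation size filter bounds.}
#'     \item{folds, fraction, n_null_draws, seed}{analysis parameters.}
#'     \item{out_dir}{output directory (created).}
#'   }
#' @return the manifest, invisibly (a named list, also written as
#'   \code{manifest.json})
#' @export
runWorkflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  root_seed <- as.integer(cfg("seed", 1L))
  variants <- cfg("variants", c("umi", "cpm", "binary", "nozero", "pooled"))
  folds <- cfg("folds", 3L)
  fraction <- cfg("fraction", 0.01)
  out_dir <- cfg("out_dir", "recoex_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # deterministic per-stage seeds derived from the root seed
  stage_seed <- function(k) (root_seed * 1000L + k) %% .Machine$integer.max

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- as.integer(cfg2(sim_args, "seed", stage_seed(1L)))
    sim <- generateSingleCellExperiment(do.call(simulationConfig, sim_args))
    se <- sim$expression
    truth <- sim$truth
  } else {
    se <- readExpression(config$expression,
                         format = cfg("format", "tsv"),
                         sample_meta = config$sample_meta,
                         unit = cfg("unit", "UMI"))
    truth <- NULL
  }

  annotations <- if (!is.null(config$annotations)) {
    readGmt(config$annotations)
  } else if (!is.null(truth)) {
    generateAnnotations(truth,
      match_fraction = cfg("match_fraction", 1),
      n_decoy_sets = cfg("n_decoy_sets", 0),
      size_range = unlist(cfg("size_range", c(20, 1000))),
      seed = stage_seed(2L))
  } else stop("no annotation source: give 'annotations' or simulate")

  batch_col <- cfg("batch_col", "batch")
  batches <- SummarizedExperiment::colData(se)[[batch_col]]
  results <- list()
  for (v in variants) {
    message("variant: ", v)
    sev <- switch(v,
      umi = , pooled = , nozero = se,
      cpm = cpmNormalize(se),
      binary = binarize(se),
      stop("unknown variant: ", v))
    zmiss <- identical(v, "nozero")
    nets <- if (identical(v, "pooled") || is.null(batches)) {
      list(spearmanNetwork(sev, zeros_as_missing = zmiss, variant = v))
    } else {
      lapply(split(seq_along(batches), batches), function(idx)
        spearmanNetwork(sev[, idx], zeros_as_missing = zmiss, variant = v))
    }
    agg <- if (length(nets) > 1L) aggregateNetworks(nets) else nets[[1L]]
    ann <- filterAnnotations(annotations, geneIds(agg),
                             min_size = cfg("min_size", 20),
                             max_size = cfg("max_size", 1000))
    perf <- crossValidatedPerformance(agg, ann, folds = folds,
                                      seed = stage_seed(3L))
    topo <- if (length(nets) > 1L) {
      topologyReport(nets, ann, fraction = fraction,
                     n_null_draws = cfg("n_null_draws", 20),
                     seed = stage_seed(4L))
    } else NULL
    confound <- list(
      degree_expression_rs = degreeExpressionCorrelation(agg, sev))

    vdir <- file.path(out_dir, v)
    dir.create(vdir, showWarnings = FALSE)
    write.table(perf@results, file.path(vdir, "functional_connectivity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mean_auroc = meanAuroc(perf),
           sd_auroc = sd(perf@results$auroc, na.rm = TRUE),
           n_networks = length(nets),
           replicability = if (is.null(topo)) NULL else
             topo$replicability[c("sd_observed", "sd_null", "fold")],
           confound = confound),
      file.path(vdir, "summary.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(topo)) {
      write.table(topo$semantic, file.path(vdir, "semantic.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(topo$ks, file.path(vdir, "ks.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results[[v]] <- list(mean_auroc = meanAuroc(perf),
                         n_networks = length(nets),
                         fold_over_null = if (is.null(topo)) NA_real_
                           else topo$replicability$fold)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("recoex")),
    r_version = R.version.string,
    seed = root_seed,
    variants = variants,
    n_genes = nrow(se), n_samples = ncol(se),
    results = results,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# config lookup with default for nested lists
cfg2 <- function(lst, name, default) {
  if (is.null(lst[[name]])) default else lst[[name]]
}
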