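#' Configuration for the synthetic expression generator
#'
#' Describes a batched single-cell (or bulk) experiment with planted
#' structure: co-expressed "state" modules driven by per-cell latent
#' factors, cell-type mean shifts that create compositional co-expression
#' when types are pooled, multiplicative batch effects, a wide baseline
#' expression gradient (so expression-level confounds can emerge
#' naturally), log-normal library sizes, and overdispersed count sampling.
#' Defaults emulate a small plate-based UMI experiment: 8 batches of 16
#' cells, two interneuron-like cell types in equal proportion.
#'
#' @param n_genes number of genes.
#' @param n_batches number of batches (plates).
#' @param cells_per_batch cells per batch.
#' @param cell_types named numeric vector of mixing proportions (must sum
#'   to 1).
#' @param module_sizes integer vector, one planted co-expression module per
#'   entry; module gene sets are disjoint and their total must not exceed
#'   \code{n_genes}.
#' @param module_placement \code{"random"} places module genes anywhere on
#'   the expression gradient; \code{"high_expression"} assigns them to the
#'   highest-baseline genes, emulating data whose co-expression programs
#'   live among well-detected genes (the regime in which expression level
#'   confounds functional connectivity).
#' @param loading_strength latent-factor loading magnitude, recycled to one
#'   value per module. 0 plants no signal; values near 1 give strong
#'   within-module correlation.
#' @param celltype_shift_sd SD of per-gene log-scale mean offsets between
#'   cell types; drives compositional co-expression when types are pooled.
#' @param batch_effect_sd SD of per-gene log-scale batch offsets.
#' @param baseline_log_mean_range range of per-gene baseline log means
#'   (uniform); spans low to high expressors.
#' @param library_size_lognormal \code{c(mu, sigma)} of per-cell relative
#'   library size on the log scale.
#' @param count_model \code{"negative_binomial"} (default; UMI data are
#'   overdispersed) or \code{"poisson"} (for closed-form sanity checks).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param dropout_prob optional independent per-entry drop-out probability,
#'   default 0: zeros normally arise from count sampling alone, with
#'   drop-out rate decreasing as the mean rises.
#' @param n_samples number of samples for the bulk generator.
#' @param proportion_sd SD of logit-scale cell-type proportion variation
#'   across bulk samples (0 = fixed composition).
#' @param noise_sd log-scale measurement noise SD for the bulk generator.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return a list of class \code{"SimulationConfig"}
#' @export
simulationConfig <- function(n_genes = 2000,
                             n_batches = 8,
                             cells_per_batch = 16,
                             cell_types = c(typeA = 0.5, typeB = 0.5),
                             module_sizes = rep(40L, 10),
                             module_placement = c("random", "high_expression"),
                             loading_strength = 1.0,
                             celltype_shift_sd = 0.5,
                             batch_effect_sd = 0.2,
                             baseline_log_mean_range = log(c(0.1, 60)),
                             library_size_lognormal = c(mu = 0, sigma = 0.3),
                             count_model = c("negative_binomial", "poisson"),
                             dispersion = 0.3,
                             dropout_prob = 0,
                             n_samples = 20,
                             proportion_sd = 0,
                             noise_sd = 0.2,
                             seed = 1L) {
  count_model <- match.arg(count_model)
  module_placement <- match.arg(module_placement)
  if (n_genes < 1 || n_batches < 1 || cells_per_batch < 1 || n_samples < 1)
    stop("dimensions must be positive")
  if (abs(sum(cell_types) - 1) > 1e-8)
    stop("cell type proportions must sum to 1")
  if (is.null(names(cell_types)))
    names(cell_types) <- paste0("type", seq_along(cell_types))
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) > n_genes)
    stop("module sizes exceed the number of genes")
  loading_strength <- rep_len(loading_strength, length(module_sizes))
  structure(list(
    n_genes = as.integer(n_genes), n_batches = as.integer(n_batches),
    cells_per_batch = as.integer(cells_per_batch), cell_types = cell_types,
    module_sizes = module_sizes, module_placement = module_placement,
    loading_strength = loading_strength,
    celltype_shift_sd = celltype_shift_sd, batch_effect_sd = batch_effect_sd,
    baseline_log_mean_range = baseline_log_mean_range,
    library_size_lognormal = library_size_lognormal,
    count_model = count_model, dispersion = dispersion,
    dropout_prob = dropout_prob, n_samples = as.integer(n_samples),
    proportion_sd = proportion_sd, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "SimulationConfig")
}

geneLabels <- function(n) sprintf("g%04d", seq_len(n))

# shared gene-level structure: baselines, module membership, loadings,
# per-cell-type shifts (drawn inside the caller's seeded RNG stream)
simGeneStructure <- function(config) {
  n <- config$n_genes
  baseline <- runif(n, config$baseline_log_mean_range[1L],
                    config$baseline_log_mean_range[2L])
  module <- rep(NA_integer_, n)
  if (length(config$module_sizes)) {
    n_mod_genes <- sum(config$module_sizes)
    picked <- if (identical(config$module_placement, "high_expression")) {
      sample(order(baseline, decreasing = TRUE)[seq_len(n_mod_genes)])
    } else {
      sample.int(n, n_mod_genes)
    }
    module[picked] <- rep(seq_along(config$module_sizes),
                          times = config$module_sizes)
  }
  loading <- ifelse(is.na(module), 0, config$loading_strength[module])
  shifts <- matrix(rnorm(n * length(config$cell_types),
                         sd = config$celltype_shift_sd),
                   n, length(config$cell_types),
                   dimnames = list(NULL, names(config$cell_types)))
  list(baseline = baseline, module = module, loading = loading,
       shifts = shifts)
}

#' Simulate a batched single-cell UMI experiment with known ground truth
#'
#' Counts for gene g in cell c are drawn from the configured count model
#' with mean \eqn{\exp(\beta_g + \lambda_g f_{m(g),c} + s_{g,t(c)} +
#' b_{g,B(c)}) \cdot \ell_c}, where \eqn{\beta_g} is the baseline log mean,
#' \eqn{f} the standard-normal latent factor of the gene's module,
#' \eqn{s} the cell-type shift, \eqn{b} the batch effect, and \eqn{\ell_c}
#' the cell's library-size factor divided by its mean across cells (so the
#' average scaling is 1 and CPM renormalization changes the data
#' measurably). Zeros arise from the count sampling itself, so drop-out
#' rates fall as the mean rises.
#'
#' @param config a [simulationConfig()]
#' @return list with elements \code{expression} (a
#'   \code{SummarizedExperiment}, unit UMI, colData columns \code{batch}
#'   and \code{cell_type}) and \code{truth} (module membership, latent
#'   factors, baselines, library sizes).
#' @export
generateSingleCellExperiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n_cells <- config$n_batches * config$cells_per_batch
  gs <- simGeneStructure(config)
  n_mod <- length(config$module_sizes)

  batch <- rep(paste0("batch", seq_len(config$n_batches)),
               each = config$cells_per_batch)
  cell_type <- sample(names(config$cell_types), n_cells, replace = TRUE,
                      prob = config$cell_types)
  factors <- matrix(rnorm(n_mod * n_cells), n_mod, n_cells)
  batch_eff <- matrix(rnorm(config$n_genes * config$n_batches,
                            sd = config$batch_effect_sd),
                      config$n_genes, config$n_batches)
  libsize <- rlnorm(n_cells, config$library_size_lognormal[1L],
                    config$library_size_lognormal[2L])
  scale_c <- libsize / mean(libsize)

  eta <- matrix(gs$baseline, config$n_genes, n_cells)
  if (n_mod) {
    fac_gene <- factors[ifelse(is.na(gs$module), 1L, gs$module), ,
                        drop = FALSE]
    fac_gene[is.na(gs$module), ] <- 0
    eta <- eta + gs$loading * fac_gene
  }
  eta <- eta + gs$shifts[, match(cell_type, colnames(gs$shifts))]
  eta <- eta + batch_eff[, rep(seq_len(config$n_batches),
                               each = config$cells_per_batch)]
  mu <- exp(eta) * rep(scale_c, each = config$n_genes)

  counts <- if (config$count_model == "poisson") {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  counts <- matrix(counts, config$n_genes, n_cells)
  if (config$dropout_prob > 0)
    counts[runif(length(counts)) < config$dropout_prob] <- 0L

  ids <- geneLabels(config$n_genes)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  dimnames(counts) <- list(ids, cells)
  se <- ExpressionExperiment(counts,
    sample_meta = data.frame(sample_id = cells, batch = batch,
                             cell_type = cell_type),
    unit = "UMI")
  truth <- list(module_membership = setNames(gs$module, ids),
                latent_factors = factors, baseline_log_mean = gs$baseline,
                celltype_shift = gs$shifts, library_size = libsize,
                batch = batch, cell_type = cell_type, config = config)
  list(expression = se, truth = truth)
}

#' Simulate a bulk expression experiment
#'
#' Each sample is the expectation over many cells: continuous non-negative
#' values with no per-cell count sampling. The value for gene g in sample s
#' is \eqn{\left(\sum_t p_{t,s} e^{\beta_g + s_{g,t}}\right)
#' e^{\lambda_g f_{m(g),s} + \epsilon_{g,s}}} with cell-type proportions
#' \eqn{p_{t,s}} optionally varying across samples on the logit scale
#' (\code{proportion_sd}), sample-level latent factors driving the planted
#' state modules, and log-normal measurement noise (\code{noise_sd}).
#' Varying proportions of cell types with anti-correlated marker modules
#' produce compositional co-expression.
#'
#' @param config a [simulationConfig()]; \code{n_samples}, \code{noise_sd}
#'   and \code{proportion_sd} control the bulk-specific parts.
#' @return list with \code{expression} (unit \code{"RPKM"}-like continuous
#'   values) and \code{truth}
#' @export
generateBulkExperiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n_s <- config$n_samples
  gs <- simGeneStructure(config)
  n_mod <- length(config$module_sizes)
  n_types <- length(config$cell_types)

  props <- matrix(rep(config$cell_types, n_s), n_types, n_s)
  if (config$proportion_sd > 0 && n_types > 1) {
    lg <- log(props) + matrix(rnorm(n_types * n_s, sd = config$proportion_sd),
                              n_types, n_s)
    props <- sweep(exp(lg), 2L, colSums(exp(lg)), "/")
  }
  factors <- matrix(rnorm(max(n_mod, 1L) * n_s), max(n_mod, 1L), n_s)

  base_type <- exp(outer(gs$baseline, rep(1, n_types)) + gs$shifts)
  mix <- base_type %*% props  # genes x samples expected composition
  state <- if (n_mod) {
    fac_gene <- factors[ifelse(is.na(gs$module), 1L, gs$module), ,
                        drop = FALSE]
    fac_gene[is.na(gs$module), ] <- 0
    gs$loading * fac_gene
  } else matrix(0, config$n_genes, n_s)
  noise <- matrix(rnorm(config$n_genes * n_s, sd = config$noise_sd),
                  config$n_genes, n_s)
  vals <- mix * exp(state + noise)

  ids <- geneLabels(config$n_genes)
  samples <- sprintf("sample%03d", seq_len(n_s))
  dimnames(vals) <- list(ids, samples)
  se <- ExpressionExperiment(vals,
    sample_meta = data.frame(sample_id = samples,
                             individual = samples),
    unit = "RPKM")
  truth <- list(module_membership = setNames(gs$module, ids),
                latent_factors = factors[seq_len(max(n_mod, 0L)), ,
                                         drop = FALSE],
                baseline_log_mean = gs$baseline,
                celltype_shift = gs$shifts, proportions = props,
                config = config)
  list(expression = se, truth = truth)
}

#' Derive annotation sets from simulation ground truth
#'
#' Each planted module yields one annotation set containing a chosen
#' fraction of its genes plus random filler genes (so the set size stays at
#' the module size, clamped into \code{size_range}); additional decoy sets
#' are pure random draws. With \code{match_fraction = 1} the sets equal the
#' modules exactly; with 0 they carry no information about the network and
#' neighbor-voting performance should sit at chance.
#'
#' @param truth the \code{truth} element of a generator result.
#' @param match_fraction fraction of each module's genes kept in its set.
#' @param n_decoy_sets number of unrelated random sets to add.
#' @param size_range inclusive bounds for emitted set sizes.
#' @param seed integer seed.
#' @return an [AnnotationMatrix-class] over all simulated genes
#' @export
generateAnnotations <- function(truth, match_fraction = 1, n_decoy_sets = 0,
                                size_range = c(20, 1000), seed = 1L) {
  stopifnot(match_fraction >= 0, match_fraction <= 1)
  set.seed(seed)
  mm <- truth$module_membership
  ids <- names(mm)
  n <- length(ids)
  if (size_range[1L] < 1 || size_range[1L] > n)
    stop("size_range must lie within [1, n_genes]")
  size_range[2L] <- min(size_range[2L], n)
  mods <- sort(unique(mm[!is.na(mm)]))
  sets <- list()
  for (k in mods) {
    genes_k <- ids[!is.na(mm) & mm == k]
    size <- min(max(length(genes_k), size_range[1L]), size_range[2L])
    n_match <- min(round(match_fraction * length(genes_k)), size)
    kept <- if (n_match > 0) sample(genes_k, n_match) else character()
    pool <- setdiff(ids, genes_k)
    fill <- if (size - n_match > 0) sample(pool, size - n_match) else character()
    sets[[paste0("module_set", k)]] <- c(kept, fill)
  }
  if (n_decoy_sets > 0) {
    sizes <- sample(seq(size_range[1L], min(size_range[2L], n)),
                    n_decoy_sets, replace = TRUE)
    for (d in seq_len(n_decoy_sets))
      sets[[paste0("decoy_set", d)]] <- sample(ids, sizes[d])
  }
  m <- matrix(0, n, length(sets), dimnames = list(ids, names(sets)))
  for (k in seq_along(sets)) m[sets[[k]], k] <- 1
  newAnnotation(m)
}

#' Generate a random rank-standardized network
#'
#' The upper-triangle weights are a random permutation of the standardized
#' rank grid \eqn{1/N, 2/N, \ldots, 1}, so the marginal distribution is
#' exactly the one every real rank-standardized network has, but edges
#' carry no signal. Aggregates of such networks are the null for the
#' replicability statistic.
#'
#' @param n_genes number of genes (at least 2).
#' @param seed integer seed.
#' @param gene_ids optional gene labels (defaults to g0001, ...).
#' @return a [CoexpressionNetwork-class]
#' @export
nullNetwork <- function(n_genes, seed = NULL, gene_ids = NULL) {
  if (n_genes < 2L) stop("n_genes must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- geneLabels(n_genes)
  n_pairs <- n_genes * (n_genes - 1L) / 2
  w <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
  w[upper.tri(w)] <- sample(seq_len(n_pairs)) / n_pairs
  w <- w + t(w)
  newNetwork(w, provenance = list(variant = "null", n_constituents = 1L))
}
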