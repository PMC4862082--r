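# shared fixtures and independent oracles, built in code

# wrap a symmetric weight matrix as a network (validity-checked)
makeNetwork <- function(w, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%04d", seq_len(nrow(w)))
  dimnames(w) <- list(ids, ids)
  diag(w) <- 0
  new("CoexpressionNetwork", weights = w,
      provenance = list(variant = "toy"))
}

# brute-force Mann-Whitney AUROC: count pos-neg pairs, ties one half
bruteForceAuroc <- function(scores, positives, negatives) {
  total <- 0
  for (p in positives) for (n in negatives) {
    total <- total + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
  }
  total / (length(positives) * length(negatives))
}

# independent rank-of-spearman-correlation network oracle: per-pair
# cor() calls, ranks over the explicit pair list
oracleSpearmanNetwork <- function(vals) {
  n <- nrow(vals)
  pairs <- t(combn(n, 2))
  r <- apply(pairs, 1L, function(ij) {
    cc <- suppressWarnings(
      cor(vals[ij[1L], ], vals[ij[2L], ], method = "spearman"))
    if (is.na(cc)) 0 else cc
  })
  wvec <- rank(r, ties.method = "average") / length(r)
  w <- matrix(0, n, n, dimnames = list(rownames(vals), rownames(vals)))
  w[pairs] <- wvec
  w + t(w)
}

# a small seeded single-cell simulation reused across test files
smallSim <- function(seed = 42, n_genes = 300, n_batches = 4,
                     module_sizes = rep(20, 5), loading = 1.0, ...) {
  cfg <- simulationConfig(n_genes = n_genes, n_batches = n_batches,
                          cells_per_batch = 16,
                          module_sizes = module_sizes,
                          loading_strength = loading, seed = seed, ...)
  generateSingleCellExperiment(cfg)
}

exprAssay <- function(se) SummarizedExperiment::assay(se, 1L)

perBatchNetworks <- function(se, ...) {
  batch <- SummarizedExperiment::colData(se)$batch
  lapply(split(seq_along(batch), batch), function(idx)
    spearmanNetwork(se[, idx], ...))
}
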