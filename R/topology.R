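#' Gene-pair semantic similarity counts
#'
#' For every gene pair, the number of annotation sets containing both
#' genes. Computed from (size-filtered, optionally non-IEA) annotations;
#' the diagonal is not meaningful and is zeroed.
#'
#' @param annotations an [AnnotationMatrix-class]
#' @return symmetric integer matrix, genes x genes
#' @export
pairSemanticMatrix <- function(annotations) {
  m <- membership(annotations)
  counts <- tcrossprod(m)
  diag(counts) <- 0
  counts
}

#' Semantic similarity of a network's top edges
#'
#' The mean number of shared annotated functions among the network's top
#' fraction of connections, next to the same mean over all gene pairs as
#' the chance baseline. A functional network concentrates functionally
#' similar pairs in its top edges, pushing the top mean above the
#' baseline; this needs no cross-validation, making it a cheap
#' annotation-based check on topology.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param semantic gene-pair count matrix from [pairSemanticMatrix()]; must
#'   cover the network's universe.
#' @param fraction top-edge fraction (default 1\%).
#' @return list with \code{mean_top}, \code{baseline_all}, and
#'   \code{n_edges}
#' @export
semanticSimilarityTop <- function(net, semantic, fraction = 0.01) {
  ids <- geneIds(net)
  if (!all(ids %in% rownames(semantic)))
    stop("semantic matrix does not cover the network's gene universe")
  sem <- semantic[ids, ids]
  edges <- topEdges(net, fraction)
  if (nrow(edges) == 0L) stop("empty edge set")
  mean_top <- mean(sem[cbind(edges$gene_a, edges$gene_b)])
  baseline <- mean(sem[upper.tri(sem)])
  list(mean_top = mean_top, baseline_all = baseline, n_edges = nrow(edges))
}

#' Jaccard overlap of two networks' top edges
#'
#' Intersection over union of the top-fraction edge sets, after reducing
#' both networks to their common gene universe. 1 means identical top
#' topology; two independent rank-standardized networks overlap only by
#' chance, at about f/(2-f) for fraction f.
#'
#' @param netA,netB [CoexpressionNetwork-class] objects.
#' @param fraction top-edge fraction (default 1\%).
#' @return a single number in [0, 1]
#' @export
jaccardTop <- function(netA, netB, fraction = 0.01) {
  shared <- intersect(geneIds(netA), geneIds(netB))
  if (length(shared) < 2L) stop("no shared gene universe")
  if (length(shared) < length(geneIds(netA))) netA <- subsetNetwork(netA, shared)
  if (length(shared) < length(geneIds(netB))) netB <- subsetNetwork(netB, shared)
  a <- edgeKeys(topEdges(netA, fraction))
  b <- edgeKeys(topEdges(netB, fraction))
  u <- union(a, b)
  if (length(u) == 0L) stop("empty edge-set union")
  length(intersect(a, b)) / length(u)
}

#' Replicability of topology from the spread of aggregate connectivity
#'
#' Every constituent network is rank-standardized to a uniform marginal,
#' so the aggregate's pre-re-ranking mean is, under independence, a mean
#' of B iid uniforms with SD \eqn{\sqrt{1/(12B)}}. If the same gene pairs
#' are highly ranked in every replicate, the mean spreads out: the ratio
#' of the observed SD to the SD of aggregates of randomly permuted
#' rank-standardized networks measures how replicable the topology is.
#' Perfectly replicated networks approach a fold of \eqn{\sqrt{B}}.
#'
#' @param nets list of at least two [CoexpressionNetwork-class] objects
#'   sharing a gene universe.
#' @param n_null_draws Monte-Carlo draws for the null SD.
#' @param seed integer seed for the null draws.
#' @return list: \code{sd_observed}, \code{sd_null}, \code{sd_null_se}
#'   (Monte-Carlo SE), \code{fold} = observed/null
#' @export
replicabilitySd <- function(nets, n_null_draws = 20, seed = 1L) {
  if (length(nets) < 2L) stop("need at least 2 networks")
  agg <- aggregateNetworks(nets)
  raw <- rawMean(agg)
  sd_obs <- sd(raw[upper.tri(raw)])
  B <- length(nets)
  n_pairs <- length(geneIds(agg)) * (length(geneIds(agg)) - 1L) / 2
  set.seed(seed)
  # each null constituent's upper triangle is a permutation of the
  # standardized rank grid — exactly nullNetwork(), kept in vector form
  grid <- seq_len(n_pairs) / n_pairs
  null_sds <- vapply(seq_len(n_null_draws), function(d) {
    acc <- numeric(n_pairs)
    for (b in seq_len(B)) acc <- acc + sample(grid)
    sd(acc / B)
  }, numeric(1L))
  sd_null <- mean(null_sds)
  list(sd_observed = sd_obs, sd_null = sd_null,
       sd_null_se = sd(null_sds) / sqrt(n_null_draws),
       fold = sd_obs / sd_null)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two connectivity-derived distributions — typically the
#' per-edge semantic-similarity values of two networks' top edges, or the
#' raw top-edge weights — with the two-sample KS statistic and its
#' asymptotic p value.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @return list with \code{D} and \code{p}
#' @export
ksCompare <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) stop("empty input")
  kt <- suppressWarnings(ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Full topology comparison report
#'
#' Convenience wrapper combining the top-edge semantic similarity of each
#' network, pairwise Jaccard overlaps, the SD replicability statistic, and
#' pairwise KS comparisons of per-edge semantic values among top edges.
#'
#' @param nets named list of [CoexpressionNetwork-class] objects on one
#'   gene universe.
#' @param annotations filtered [AnnotationMatrix-class] for the semantic
#'   matrix.
#' @param fraction top-edge fraction.
#' @param n_null_draws,seed forwarded to [replicabilitySd()].
#' @param ks_on compare distributions of per-edge \code{"semantic"} counts
#'   (default) or raw top-edge \code{"weights"}.
#' @return list: \code{semantic} (data.frame), \code{jaccard} (matrix),
#'   \code{replicability} (list), \code{ks} (data.frame)
#' @export
topologyReport <- function(nets, annotations, fraction = 0.01,
                           n_null_draws = 20, seed = 1L,
                           ks_on = c("semantic", "weights")) {
  ks_on <- match.arg(ks_on)
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  sem <- pairSemanticMatrix(annotations)
  ss <- lapply(nets, semanticSimilarityTop, semantic = sem,
               fraction = fraction)
  sem_tab <- data.frame(network = names(nets),
                        mean_top = vapply(ss, `[[`, 0, "mean_top"),
                        baseline_all = vapply(ss, `[[`, 0, "baseline_all"))
  K <- length(nets)
  jac <- matrix(1, K, K, dimnames = list(names(nets), names(nets)))
  for (i in seq_len(K)) for (j in seq_len(K)) if (i < j)
    jac[i, j] <- jac[j, i] <- jaccardTop(nets[[i]], nets[[j]], fraction)
  repl <- replicabilitySd(nets, n_null_draws = n_null_draws, seed = seed)
  edge_vals <- lapply(nets, function(net) {
    e <- topEdges(net, fraction)
    if (ks_on == "weights") e$weight else sem[cbind(e$gene_a, e$gene_b)]
  })
  ks_rows <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) if (i < j) {
    kt <- ksCompare(edge_vals[[i]], edge_vals[[j]])
    ks_rows[[length(ks_rows) + 1L]] <-
      data.frame(a = names(nets)[i], b = names(nets)[j], D = kt$D, p = kt$p)
  }
  list(semantic = sem_tab, jaccard = jac, replicability = repl,
       ks = if (length(ks_rows)) do.call(rbind, ks_rows) else NULL)
}
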