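#' Aggregate rank-standardized networks meta-analytically
#'
#' Averages the rank-standardized weights of the constituent networks
#' element-wise over their common gene universe, then re-ranks the mean to
#' [0, 1]. Averaging and summing give identical re-ranked networks; the
#' pre-re-ranking mean is retained in the \code{rawMean} slot because the
#' replicability statistic needs it (re-ranking restores a uniform marginal
#' and erases the agreement signal).
#'
#' @param nets non-empty list of [CoexpressionNetwork-class] objects;
#'   universes are intersected, and fewer than 2 shared genes is an error.
#' @return an [AggregateNetwork-class]
#' @export
aggregateNetworks <- function(nets) {
  if (length(nets) == 0L) stop("empty network list")
  shared <- Reduce(intersect, lapply(nets, geneIds))
  if (length(shared) < 2L) stop("gene universe intersection has < 2 genes")
  acc <- matrix(0, length(shared), length(shared),
                dimnames = list(shared, shared))
  for (net in nets) acc <- acc + networkWeights(net)[shared, shared]
  raw <- acc / length(nets)
  # distinct mean-rank values differ by at least 1/(B * n_pairs), far above
  # rounding noise: snapping keeps exact ties exact whatever the summation
  # order, so the re-ranking is permutation invariant
  raw <- round(raw, 9)
  diag(raw) <- 0
  new("AggregateNetwork", weights = rankMatrix01(raw), rawMean = raw,
      nConstituents = length(nets),
      provenance = list(variant = "aggregate",
                        constituents = lapply(nets, provenance)))
}

#' Performance as networks are aggregated in random order
#'
#' Repeats the aggregation schedule several times in random network order,
#' scoring the cumulative aggregate of the first k networks by
#' cross-validated neighbor voting at every k. A rising mean trajectory
#' indicates that functional signal replicates across the constituent
#' networks, so averaging accumulates it.
#'
#' @param nets list of at least two [CoexpressionNetwork-class] objects.
#' @param annotations an [AnnotationMatrix-class] (filtered sets).
#' @param n_runs number of random orderings.
#' @param folds cross-validation folds passed to scoring.
#' @param seed integer seed controlling orderings and fold assignment.
#' @return data.frame with columns \code{run}, \code{k},
#'   \code{mean_auroc}; runs coded 1..n_runs plus \code{run = 0} rows
#'   holding the mean trajectory over runs.
#' @export
aggregationCurve <- function(nets, annotations, n_runs = 10, folds = 3,
                             seed = 1L) {
  if (length(nets) < 2L) stop("need at least 2 networks")
  set.seed(seed)
  K <- length(nets)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ord <- sample.int(K)
    fold_seed <- sample.int(.Machine$integer.max, 1L)
    scores <- numeric(K)
    for (k in seq_len(K)) {
      agg <- if (k == 1L) nets[[ord[1L]]] else
        aggregateNetworks(nets[ord[seq_len(k)]])
      rep_k <- crossValidatedPerformance(agg, annotations, folds = folds,
                                         seed = fold_seed)
      scores[k] <- meanAuroc(rep_k)
    }
    rows[[r]] <- data.frame(run = r, k = seq_len(K), mean_auroc = scores)
  }
  out <- do.call(rbind, rows)
  avg <- aggregate(mean_auroc ~ k, out, mean)
  rbind(data.frame(run = 0L, k = avg$k, mean_auroc = avg$mean_auroc), out)
}
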