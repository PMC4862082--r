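#' Rank-standardize a collection of values to (0, 1]
#'
#' Replaces each value by its rank divided by the number of values, with
#' average ranks for ties: the maximum distinct value maps to exactly 1,
#' the minimum to 1/N, and the output is invariant under any strictly
#' monotone transform of the input. Standardizing edge correlations this
#' way damps experiment-specific distortions of the correlation
#' distribution (outlier samples shift values far more than ranks).
#'
#' @param values numeric vector, finite, non-empty.
#' @return numeric vector of the same length in (0, 1]
#' @export
rankStandardize <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite values")
  rank(values, ties.method = "average") / length(values)
}

#' Build a signed, weighted, rank-standardized co-expression network
#'
#' Computes the Spearman correlation between every pair of genes across
#' samples, sets undefined correlations (constant genes; too few complete
#' pairs) to zero, then rank-standardizes the upper-triangle correlations
#' to (0, 1] — signed, so the most negative correlation gets the smallest
#' weight and the most positive gets 1. The result is a fully connected
#' network; the diagonal is 0 and excluded from ranking.
#'
#' With \code{zeros_as_missing}, zeros are treated as missing data and each
#' pair's correlation uses only samples where both genes are non-zero
#' (requiring at least 3 complete pairs, else the correlation is undefined
#' and set to 0). This isolates the contribution of co-variation among
#' detected values from the shared zero pattern.
#'
#' @param se a \code{SummarizedExperiment} (any unit).
#' @param zeros_as_missing treat zeros as NA and use pairwise-complete
#'   samples per gene pair.
#' @param variant provenance tag recorded on the network (defaults to the
#'   expression unit).
#' @return a [CoexpressionNetwork-class]
#' @export
spearmanNetwork <- function(se, zeros_as_missing = FALSE, variant = NULL) {
  vals <- exprValues(se)
  if (ncol(vals) < 3L) stop("at least 3 samples are required")
  if (nrow(vals) < 2L) stop("at least 2 genes are required")
  x <- t(vals)
  if (zeros_as_missing) {
    x[x == 0] <- NA_real_
    r <- suppressWarnings(cor(x, method = "spearman",
                              use = "pairwise.complete.obs"))
    npair <- crossprod(!is.na(x))
    r[npair < 3L] <- NA_real_
  } else {
    r <- suppressWarnings(cor(x, method = "spearman"))
  }
  r[!is.finite(r)] <- 0  # undefined correlations enter the ranking as 0
  w <- rankMatrix01(r)
  newNetwork(w, provenance = list(
    variant = if (is.null(variant)) expressionUnit(se) else variant,
    n_samples = ncol(vals), n_constituents = 1L,
    zeros_as_missing = zeros_as_missing))
}

# rank-standardize the upper triangle of a symmetric matrix and mirror it;
# each unordered pair is ranked exactly once so ties are not double-counted
rankMatrix01 <- function(r) {
  ut <- upper.tri(r)
  w <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  w[ut] <- rankStandardize(r[ut])
  w + t(w)
}

#' The top fraction of network edges
#'
#' The \code{ceiling(fraction * n_pairs)} highest-weight unordered gene
#' pairs. Ties at the cutoff are broken by lexicographic gene-pair order so
#' the set is deterministic.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param fraction fraction of all off-diagonal pairs to keep (default the
#'   top 1\%).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}, one row per selected pair, plus attributes
#'   \code{fraction} and \code{n_pairs}.
#' @export
topEdges <- function(net, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  w <- networkWeights(net)
  ids <- geneIds(net)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  # lexicographic order of (gene_a, gene_b) as the deterministic tiebreak
  o <- order(-w[ut], ids[ut[, 1L]], ids[ut[, 2L]])
  n_top <- ceiling(fraction * nrow(ut))
  sel <- ut[o[seq_len(n_top)], , drop = FALSE]
  out <- data.frame(gene_a = ids[sel[, 1L]], gene_b = ids[sel[, 2L]],
                    weight = w[sel])
  attr(out, "fraction") <- fraction
  attr(out, "n_pairs") <- nrow(ut)
  out
}

# canonical unordered-pair keys for edge-set comparisons
edgeKeys <- function(edges) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  paste(a, b, sep = "\r")
}

#' Restrict a network to a gene subset
#'
#' Subsets the weight matrix to the given genes and re-ranks the surviving
#' upper-triangle weights so the result is again a valid rank-standardized
#' network over the smaller universe.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param genes character vector of gene ids to keep.
#' @return a [CoexpressionNetwork-class]
#' @export
subsetNetwork <- function(net, genes) {
  genes <- intersect(geneIds(net), genes)
  if (length(genes) < 2L) stop("fewer than 2 genes in the subset")
  w <- networkWeights(net)[genes, genes]
  prov <- provenance(net)
  prov$subset_of <- length(geneIds(net))
  newNetwork(rankMatrix01(w), provenance = prov)
}
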