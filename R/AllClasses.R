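#' @import methods
#' @importFrom stats cor median sd quantile rnorm rpois rnbinom rlnorm runif
#'   ks.test lm coef setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

#' Signed, weighted, rank-standardized co-expression network
#'
#' A fully connected gene-gene network in which each off-diagonal entry is
#' the rank of the underlying Spearman correlation, standardized to (0, 1].
#' Higher weight means the pair is more strongly (more positively)
#' co-expressed relative to all other pairs in the same network; the most
#' negative correlation gets the smallest weight. The diagonal is fixed at 0
#' by convention and excluded from ranking, node degree, and voting.
#'
#' @slot weights symmetric numeric matrix, genes x genes, values in [0, 1],
#'   diagonal 0, dimnames giving the gene universe.
#' @slot provenance named list describing how the network was built
#'   (\code{variant}, \code{n_samples}, \code{n_constituents}, ...).
#'
#' @seealso [spearmanNetwork()], [aggregateNetworks()], [nullNetwork()]
#' @export
setClass("CoexpressionNetwork",
  representation(weights = "matrix", provenance = "list"),
  prototype(provenance = list())
)

setValidity("CoexpressionNetwork", function(object) {
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != ncol(w))
    return("'weights' must be a square numeric matrix")
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("'weights' must carry gene ids as dimnames")
  if (!identical(rownames(w), colnames(w)))
    return("row and column gene ids differ")
  if (anyDuplicated(rownames(w)))
    return("duplicate gene ids")
  if (any(!is.finite(w)))
    return("non-finite weights")
  if (any(w < 0) || any(w > 1))
    return("weights outside [0, 1]")
  if (any(diag(w) != 0))
    return("diagonal must be 0")
  if (!isSymmetric(unname(w)))
    return("weights must be symmetric")
  TRUE
})

#' Meta-analytic aggregate of rank-standardized networks
#'
#' The element-wise mean of constituent rank-standardized networks,
#' re-ranked to [0, 1]. The pre-re-ranking mean is kept in \code{rawMean}:
#' the replicability statistic ([replicabilitySd()]) is the standard
#' deviation of these values, which re-ranking would destroy (re-ranking
#' restores a uniform marginal whatever the constituents agreed on).
#'
#' @slot rawMean symmetric numeric matrix of pre-re-ranking mean weights.
#' @slot nConstituents number of networks averaged.
#' @export
setClass("AggregateNetwork",
  contains = "CoexpressionNetwork",
  representation(rawMean = "matrix", nConstituents = "integer")
)

setValidity("AggregateNetwork", function(object) {
  if (!identical(dim(object@rawMean), dim(object@weights)))
    return("'rawMean' dimensions must match 'weights'")
  if (object@nConstituents < 1L)
    return("'nConstituents' must be >= 1")
  if (!isSymmetric(unname(object@rawMean)))
    return("'rawMean' must be symmetric")
  TRUE
})

#' Binary gene-by-function annotation matrix
#'
#' Membership of genes in functional gene sets (GO-slim-like categories or
#' candidate sets), the label source for neighbor voting. Column sums are
#' the set sizes used by the 20-1000 size filter.
#'
#' @slot membership numeric 0/1 matrix, genes x functions, with dimnames.
#' @export
setClass("AnnotationMatrix",
  representation(membership = "matrix")
)

setValidity("AnnotationMatrix", function(object) {
  m <- object@membership
  if (!is.numeric(m))
    return("'membership' must be numeric 0/1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("'membership' must carry gene and function ids as dimnames")
  if (anyDuplicated(colnames(m)))
    return("duplicate function ids")
  if (anyDuplicated(rownames(m)))
    return("duplicate gene ids")
  if (length(m) && !all(m %in% c(0, 1)))
    return("'membership' entries must be 0 or 1")
  TRUE
})

#' Neighbor-voting performance report
#'
#' Per-function AUROCs from cross-validated neighbor voting on one network,
#' with positive/negative counts and fold bookkeeping. The network-level
#' score is the arithmetic mean AUROC across functions; functions skipped
#' for having fewer positives than folds are excluded from the mean.
#'
#' @slot results data.frame with columns \code{function_id}, \code{auroc},
#'   \code{n_pos}, \code{n_neg}.
#' @slot folds number of cross-validation folds.
#' @slot seed seed used for fold assignment (NA if none given).
#' @export
setClass("FunctionalConnectivityReport",
  representation(results = "data.frame", folds = "integer", seed = "numeric")
)

setValidity("FunctionalConnectivityReport", function(object) {
  r <- object@results
  need <- c("function_id", "auroc", "n_pos", "n_neg")
  if (!all(need %in% names(r)))
    return(paste("results must have columns:", paste(need, collapse = ", ")))
  ok <- is.na(r$auroc) | (r$auroc >= 0 & r$auroc <= 1)
  if (!all(ok))
    return("AUROCs must lie in [0, 1] (or NA for skipped functions)")
  TRUE
})
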