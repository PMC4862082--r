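#' @rdname CoexpressionNetwork-class
#' @param object,x a \code{CoexpressionNetwork} or related object
#' @export
setGeneric("networkWeights", function(object) standardGeneric("networkWeights"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' Node degree: the sum of a gene's edge weights
#'
#' Degree of gene \eqn{i} is \eqn{\sum_{j \ne i} w_{ij}}. In a
#' rank-standardized network the expected degree of a gene with uniform
#' random weights is about \eqn{(n-1)/2}; hub genes sit far above this.
#'
#' @param object a [CoexpressionNetwork-class]
#' @return named numeric vector, one value per gene
#' @export
setGeneric("nodeDegree", function(object) standardGeneric("nodeDegree"))

#' @rdname AggregateNetwork-class
#' @param object an \code{AggregateNetwork}
#' @export
setGeneric("rawMean", function(object) standardGeneric("rawMean"))

#' @rdname AggregateNetwork-class
#' @export
setGeneric("nConstituents", function(object) standardGeneric("nConstituents"))

#' @rdname AnnotationMatrix-class
#' @param object an \code{AnnotationMatrix}
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("functionIds", function(object) standardGeneric("functionIds"))

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("functionSizes", function(object) standardGeneric("functionSizes"))

#' @rdname FunctionalConnectivityReport-class
#' @param object a \code{FunctionalConnectivityReport}
#' @export
setGeneric("functionAurocs", function(object) standardGeneric("functionAurocs"))

#' Mean neighbor-voting AUROC across functions
#'
#' The network-level performance score: the arithmetic mean of per-function
#' cross-validated AUROCs, skipped functions excluded.
#'
#' @param object a [FunctionalConnectivityReport-class]
#' @return a single number
#' @export
setGeneric("meanAuroc", function(object) standardGeneric("meanAuroc"))
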