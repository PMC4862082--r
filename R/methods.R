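#' @rdname CoexpressionNetwork-class
#' @aliases networkWeights,CoexpressionNetwork-method
#' @export
setMethod("networkWeights", "CoexpressionNetwork", function(object) object@weights)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("geneIds", "CoexpressionNetwork", function(object) rownames(object@weights))

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("geneIds", "AnnotationMatrix", function(object) rownames(object@membership))

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("provenance", "CoexpressionNetwork", function(object) object@provenance)

#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "CoexpressionNetwork", function(object) {
  rowSums(object@weights)  # diagonal is 0, so self-edges contribute nothing
})

#' @rdname AggregateNetwork-class
#' @export
setMethod("rawMean", "AggregateNetwork", function(object) object@rawMean)

#' @rdname AggregateNetwork-class
#' @export
setMethod("nConstituents", "AggregateNetwork", function(object) object@nConstituents)

#' @rdname AnnotationMatrix-class
#' @export
setMethod("membership", "AnnotationMatrix", function(object) object@membership)

#' @rdname AnnotationMatrix-class
#' @export
setMethod("functionIds", "AnnotationMatrix", function(object) colnames(object@membership))

#' @rdname AnnotationMatrix-class
#' @export
setMethod("functionSizes", "AnnotationMatrix", function(object) colSums(object@membership))

#' @rdname FunctionalConnectivityReport-class
#' @export
setMethod("functionAurocs", "FunctionalConnectivityReport", function(object) {
  setNames(object@results$auroc, object@results$function_id)
})

#' @rdname meanAuroc
#' @export
setMethod("meanAuroc", "FunctionalConnectivityReport", function(object) {
  mean(object@results$auroc, na.rm = TRUE)
})

setMethod("show", "CoexpressionNetwork", function(object) {
  p <- object@provenance
  cat("CoexpressionNetwork with", nrow(object@weights), "genes\n")
  if (!is.null(p$variant)) cat("  variant:", p$variant, "\n")
  if (!is.null(p$n_samples)) cat("  built from", p$n_samples, "samples\n")
  d <- nodeDegree(object)
  cat("  node degree: ", format(min(d), digits = 4), " .. ",
      format(max(d), digits = 4), "\n", sep = "")
})

setMethod("show", "AggregateNetwork", function(object) {
  cat("AggregateNetwork of", object@nConstituents, "networks,",
      nrow(object@weights), "genes\n")
  off <- object@rawMean[upper.tri(object@rawMean)]
  cat("  SD of pre-re-ranking mean weights:", format(sd(off), digits = 4), "\n")
})

setMethod("show", "AnnotationMatrix", function(object) {
  sizes <- functionSizes(object)
  cat("AnnotationMatrix:", nrow(object@membership), "genes x",
      ncol(object@membership), "functions\n")
  if (length(sizes))
    cat("  set sizes: ", min(sizes), " .. ", max(sizes),
        " (median ", median(sizes), ")\n", sep = "")
})

setMethod("show", "FunctionalConnectivityReport", function(object) {
  r <- object@results
  scored <- !is.na(r$auroc)
  cat("FunctionalConnectivityReport:", sum(scored), "functions scored",
      if (any(!scored)) paste0("(", sum(!scored), " skipped)") else "", "\n")
  cat("  folds:", object@folds, "\n")
  if (any(scored))
    cat("  mean AUROC: ", format(mean(r$auroc[scored]), digits = 4),
        "  (SD ", format(sd(r$auroc[scored]), digits = 4), ")\n", sep = "")
})

# internal constructors ------------------------------------------------------

newNetwork <- function(weights, provenance = list()) {
  new("CoexpressionNetwork", weights = weights, provenance = provenance)
}

newAnnotation <- function(membership) {
  storage.mode(membership) <- "double"
  new("AnnotationMatrix", membership = membership)
}
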