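#' Counts-per-million normalization
#'
#' Divides each sample's counts by the sample total and multiplies by 1e6,
#' so every column sums to one million. This renders the data compositional
#' — each value is a fraction of the sample total — which is exactly the
#' property whose network-level consequences the confound diagnostics
#' measure.
#'
#' @param se a \code{SummarizedExperiment} with unit \code{"UMI"}.
#' @param spike_prefix optional gene-id prefix (e.g. \code{"ERCC-"}) whose
#'   genes are excluded from the per-sample totals (spike-ins are not part
#'   of the endogenous pool); their values are still rescaled.
#' @return a \code{SummarizedExperiment} with unit \code{"CPM"}
#' @export
cpmNormalize <- function(se, spike_prefix = NULL) {
  if (expressionUnit(se) != "UMI")
    stop("cpmNormalize expects UMI counts, got unit '", expressionUnit(se), "'")
  vals <- exprValues(se)
  counted <- rep(TRUE, nrow(vals))
  if (!is.null(spike_prefix))
    counted <- !startsWith(rownames(vals), spike_prefix)
  totals <- colSums(vals[counted, , drop = FALSE])
  if (any(totals == 0)) stop("sample(s) with zero total count: ",
                             paste(colnames(vals)[totals == 0], collapse = ", "))
  out <- sweep(vals, 2L, totals, "/") * 1e6
  SummarizedExperiment::assay(se, 1L) <- out
  expressionUnit(se) <- "CPM"
  se
}

#' Binarize expression to presence/absence
#'
#' Sets all non-zero values to one. Networks built from binarized data
#' measure how informative mere gene detection is, stripped of all
#' variation in non-zero expression level.
#'
#' @param se a \code{SummarizedExperiment}
#' @return a \code{SummarizedExperiment} with unit \code{"binary"}
#' @export
binarize <- function(se) {
  vals <- exprValues(se)
  vals[vals != 0] <- 1
  SummarizedExperiment::assay(se, 1L) <- vals
  expressionUnit(se) <- "binary"
  se
}

#' Sample-level quality filters
#'
#' Removes samples detecting too few genes, then removes whole groups
#' (e.g. cell types) left with too few samples. Both thresholds are strict:
#' a sample with exactly \code{min_detected_genes} detected genes survives,
#' one with fewer does not, and likewise for group sizes.
#'
#' @param se a \code{SummarizedExperiment}
#' @param min_detected_genes minimum number of genes with value > 0 per
#'   sample (samples with fewer are removed).
#' @param min_samples_per_group minimum samples per group after the sample
#'   filter (groups with fewer are removed); 0 disables.
#' @param group_col colData column defining groups (e.g. \code{"cell_type"}).
#' @return the filtered \code{SummarizedExperiment}
#' @export
qcFilterSamples <- function(se, min_detected_genes = 1000,
                            min_samples_per_group = 10,
                            group_col = "cell_type") {
  vals <- exprValues(se)
  detected <- colSums(vals > 0)
  keep <- detected >= min_detected_genes
  if (min_samples_per_group > 0) {
    if (!group_col %in% names(SummarizedExperiment::colData(se)))
      stop("group column '", group_col, "' not in sample metadata")
    grp <- as.character(SummarizedExperiment::colData(se)[[group_col]])
    sizes <- table(grp[keep])
    keep <- keep & grp %in% names(sizes)[sizes >= min_samples_per_group]
  }
  if (!any(keep)) stop("all samples removed by QC filters")
  se[, keep]
}

#' Gene-level filters
#'
#' Two filtering modes used to probe expression-level effects:
#' \describe{
#'   \item{detection_fraction}{keep genes non-zero in strictly more than
#'     \code{threshold} of the samples of \emph{every} listed group (with
#'     no groups, of all samples). \code{threshold = 0.5} reproduces the
#'     "non-zero in more than 50\% of cells of both cell types" filter.}
#'   \item{median_threshold}{keep genes whose median expression exceeds
#'     \code{threshold}; with groups (e.g. batches) the median must exceed
#'     it in every group. \code{threshold = 16} on UMI counts gives the
#'     stringent high-expressor networks.}
#' }
#'
#' @param se a \code{SummarizedExperiment}
#' @param mode \code{"detection_fraction"} or \code{"median_threshold"}.
#' @param threshold filter threshold (fraction in [0,1] or expression value).
#' @param groups optional colData column name whose levels must each pass.
#' @param inclusive use \code{>=} instead of the default strict \code{>}
#'   for the median threshold.
#' @return the filtered \code{SummarizedExperiment}
#' @export
filterGenes <- function(se, mode = c("detection_fraction", "median_threshold"),
                        threshold = 0.5, groups = NULL, inclusive = FALSE) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  vals <- exprValues(se)
  idx <- if (is.null(groups)) {
    list(seq_len(ncol(vals)))
  } else {
    g <- as.character(SummarizedExperiment::colData(se)[[groups]])
    if (is.null(g)) stop("group column '", groups, "' not in sample metadata")
    split(seq_len(ncol(vals)), g)
  }
  keep <- rep(TRUE, nrow(vals))
  for (cols in idx) {
    sub <- vals[, cols, drop = FALSE]
    keep <- keep & if (mode == "detection_fraction") {
      rowMeans(sub > 0) > threshold
    } else if (inclusive) {
      apply(sub, 1L, median) >= threshold
    } else {
      apply(sub, 1L, median) > threshold
    }
  }
  if (!any(keep)) stop("no genes survive the ", mode, " filter")
  se[keep, ]
}
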