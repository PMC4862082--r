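#' Correlation between node degree and median expression
#'
#' The Spearman correlation of per-gene node degree against per-gene
#' median expression, excluding genes whose correlations were all
#' undefined (constant genes: their edges were injected as raw value 0
#' and carry no information). A strongly positive value is the signature
#' of the expression-level confound in raw-count networks; normalizations
#' that induce co-variation among lowly expressed genes push it the other
#' way.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param se the expression the network was built from.
#' @return a single correlation in [-1, 1]
#' @export
degreeExpressionCorrelation <- function(net, se) {
  ids <- intersect(geneIds(net), rownames(se))
  if (length(ids) < 3L) stop("fewer than 3 shared genes")
  vals <- exprValues(se)[ids, , drop = FALSE]
  med <- apply(vals, 1L, median)
  deg <- nodeDegree(net)[ids]
  defined <- apply(vals, 1L, function(v) length(unique(v)) > 1L)
  if (sum(defined) < 3L) stop("fewer than 3 genes with defined correlations")
  cor(deg[defined], med[defined], method = "spearman")
}

#' Fisher transformation z-score for a correlation
#'
#' \eqn{z = \mathrm{atanh}(r)\sqrt{n-3}}: the number of null standard
#' errors the observed correlation sits from zero, used to judge whether
#' degree-expression correlations across many networks are more extreme
#' than chance.
#'
#' @param r correlation, strictly inside (-1, 1).
#' @param n sample size (> 3).
#' @return z-score
#' @export
fisherZ <- function(r, n) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  if (any(n <= 3)) stop("n must exceed 3")
  atanh(r) * sqrt(n - 3)
}

#' Expression-matched control gene sets
#'
#' Bins the gene universe into expression quantiles (quartiles by
#' default), counts the target set's genes per bin, and draws control sets
#' with identical per-bin counts from the non-target genes of each bin,
#' without replacement within a set. Control sets therefore share the
#' target's expression profile but none of its biology: if they perform
#' as well as the target, expression level alone explains the target's
#' performance.
#'
#' @param target character vector of target gene ids.
#' @param expression named per-gene expression summary (e.g. median) over
#'   the universe.
#' @param n_sets number of control sets.
#' @param n_bins number of quantile bins (4 = quartiles).
#' @param seed integer seed.
#' @return list of character vectors, one control set each
#' @export
expressionMatchedSets <- function(target, expression, n_sets = 100,
                                  n_bins = 4, seed = 1L) {
  set.seed(seed)
  universe <- names(expression)
  target <- intersect(target, universe)
  if (length(target) == 0L) stop("target has no genes in the universe")
  # rank-based quantile bins are robust to heavy ties in count data
  bin <- ceiling(rank(expression, ties.method = "first") * n_bins /
                   length(expression))
  names(bin) <- universe
  per_bin_target <- tabulate(bin[target], nbins = n_bins)
  pool <- lapply(seq_len(n_bins), function(b)
    setdiff(universe[bin == b], target))
  short <- which(per_bin_target > lengths(pool))
  if (length(short))
    stop("not enough non-target genes in expression bin ", short[1L],
         " (need ", per_bin_target[short[1L]], ", have ",
         lengths(pool)[short[1L]], ")")
  lapply(seq_len(n_sets), function(s) {
    unlist(lapply(seq_len(n_bins), function(b) {
      if (per_bin_target[b] == 0L) character() else
        sample(pool[[b]], per_bin_target[b])
    }), use.names = FALSE)
  })
}

#' Per-gene performance versus expression level
#'
#' Runs leave-one-out neighbor voting on a gene set and correlates each
#' held-out gene's AUROC with its median expression. A strong positive
#' Spearman correlation means highly expressed members are the easy ones —
#' performance is riding on expression level rather than specific
#' connectivity.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param gene_set member gene ids.
#' @param se expression data covering the members.
#' @return list: \code{auroc} (named per-gene), \code{median_expression},
#'   \code{r_s}
#' @export
looExpressionRelationship <- function(net, gene_set, se) {
  auc <- looPerformance(net, gene_set)
  med <- apply(exprValues(se)[names(auc), , drop = FALSE], 1L, median)
  list(auroc = auc, median_expression = med,
       r_s = cor(auc, med, method = "spearman"))
}

#' Correlate network performance with data-quality covariates
#'
#' Spearman correlation of per-network mean AUROC against each supplied
#' covariate (total molecule counts, number of detected genes, or any
#' user column). Constant covariates yield NA.
#'
#' @param aurocs numeric vector, one mean AUROC per network.
#' @param covariates data.frame with one row per network.
#' @return data.frame with columns \code{covariate}, \code{r_s}, in the
#'   covariates' column order
#' @export
performanceVsCovariates <- function(aurocs, covariates) {
  if (length(aurocs) < 3L) stop("need at least 3 networks")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(aurocs))
    stop("one covariate row per network required")
  rs <- vapply(covariates, function(v) {
    if (length(unique(v)) < 2L) NA_real_
    else cor(aurocs, as.numeric(v), method = "spearman")
  }, numeric(1L))
  data.frame(covariate = names(covariates), r_s = unname(rs))
}

#' Per-group regression of performance on expression
#'
#' Ordinary least squares of per-network AUROC on per-network mean target
#' expression, fitted separately within each group (e.g. pre-natal vs
#' post-natal donors), reporting slope, intercept, R-squared, and adjusted
#' R-squared \eqn{1 - (1-R^2)(n-1)/(n-2)}. A positive, well-supported
#' slope says performance differences track expression level.
#'
#' @param aurocs numeric per-network AUROC.
#' @param mean_expr numeric per-network mean expression of the gene set.
#' @param group labels per network (a single group if NULL).
#' @return data.frame, one row per group: \code{group}, \code{n},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{adj_r_squared}
#' @export
connectivityExpressionRegression <- function(aurocs, mean_expr,
                                             group = NULL) {
  if (is.null(group)) group <- rep("all", length(aurocs))
  stopifnot(length(aurocs) == length(mean_expr),
            length(group) == length(aurocs))
  out <- lapply(split(seq_along(aurocs), group), function(idx) {
    if (length(idx) < 3L) stop("need at least 3 networks per group")
    x <- mean_expr[idx]; y <- aurocs[idx]
    if (length(unique(x)) < 2L) stop("degenerate (constant) predictor")
    fit <- lm(y ~ x)
    sm <- summary(fit)
    data.frame(group = group[idx[1L]], n = length(idx),
               slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = sm$r.squared,
               adj_r_squared = sm$adj.r.squared)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sunset ordering of a network's genes
#'
#' The gene permutation used to display a co-expression matrix as a
#' "sunset" plot: genes sorted by descending number of non-zero samples,
#' ties broken by descending median expression, then by gene id. With the
#' weight matrix reordered this way, expression-dependent topology shows
#' up as a bright corner of strong co-expression among the best-detected,
#' most highly expressed genes.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param se expression data covering the network's genes.
#' @return integer permutation of the network's gene indices, named by
#'   gene id
#' @export
sunsetOrder <- function(net, se) {
  ids <- geneIds(net)
  vals <- exprValues(se)[ids, , drop = FALSE]
  nz <- rowSums(vals > 0)
  med <- apply(vals, 1L, median)
  setNames(order(-nz, -med, ids), ids[order(-nz, -med, ids)])
}
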