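#' Build an annotation matrix from gene sets
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe gene universe for the rows; defaults to the union of
#'   all set members.
#' @return an [AnnotationMatrix-class]
#' @export
annotationFromSets <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  m <- matrix(0, length(universe), length(sets),
              dimnames = list(universe, names(sets)))
  for (k in seq_along(sets))
    m[intersect(sets[[k]], universe), k] <- 1
  newAnnotation(m)
}

#' Restrict annotation sets to a gene universe and filter by size
#'
#' Membership is first restricted to the network's gene universe (genes in
#' the universe but absent from the annotation source get empty rows), and
#' only then are sets filtered to those with between \code{min_size} and
#' \code{max_size} member genes, bounds inclusive. The order matters: a set
#' is judged by how many of its genes the network can actually see.
#'
#' @param annotations an [AnnotationMatrix-class]
#' @param universe character vector of gene ids (non-empty).
#' @param min_size,max_size inclusive set-size bounds (defaults 20-1000,
#'   the usual GO-slim filter).
#' @return an [AnnotationMatrix-class] over \code{universe}
#' @export
filterAnnotations <- function(annotations, universe, min_size = 20,
                              max_size = 1000) {
  if (length(universe) == 0L) stop("empty gene universe")
  m <- membership(annotations)
  out <- matrix(0, length(universe), ncol(m),
                dimnames = list(universe, colnames(m)))
  shared <- intersect(universe, rownames(m))
  out[shared, ] <- m[shared, , drop = FALSE]
  sizes <- colSums(out)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no annotation sets survive the size filter")
  newAnnotation(out[, keep, drop = FALSE])
}

#' Neighbor-voting scores for one function
#'
#' A gene's score for a function is the fraction of its connectivity going
#' to the function's known members: the sum of its edge weights to voter
#' genes divided by its node degree (the sum of all its edge weights).
#' Genes with zero degree score 0.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param voter_labels binary vector over the network's genes (named, or in
#'   network gene order): 1 marks a voter.
#' @return named numeric vector of scores in [0, 1]
#' @export
neighborVotingScores <- function(net, voter_labels) {
  w <- networkWeights(net)
  if (!is.null(names(voter_labels)))
    voter_labels <- voter_labels[geneIds(net)]
  voter_labels <- as.numeric(voter_labels)
  if (length(voter_labels) != nrow(w) || anyNA(voter_labels))
    stop("voter labels must cover the network's gene universe")
  if (sum(voter_labels) == 0) stop("no voter genes")
  deg <- rowSums(w)
  score <- as.vector(w %*% voter_labels) / ifelse(deg == 0, Inf, deg)
  setNames(score, geneIds(net))
}

#' AUROC from per-gene scores
#'
#' The Mann-Whitney area under the ROC curve with average ranks for ties:
#' \deqn{AUC = \frac{\sum_i Ranks_i - N_{Pos}(N_{Pos}+1)/2}{N_{Pos} N_{Neg}}}
#' where the ranks are those of the positives among the pooled
#' positive-and-negative scores, ascending in score. This equals the
#' probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half.
#'
#' @param scores named numeric vector of per-gene scores.
#' @param positives,negatives disjoint, non-empty gene id sets (must be
#'   named in \code{scores}).
#' @return a single number in [0, 1], or NA if either set is empty
#' @export
aurocFromScores <- function(scores, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) return(NA_real_)
  if (length(intersect(positives, negatives)))
    stop("positives and negatives must be disjoint")
  s <- scores[c(positives, negatives)]
  if (anyNA(s)) stop("scores missing for some genes")
  n_pos <- length(positives)
  n_neg <- length(negatives)
  ranks <- rank(s, ties.method = "average")
  (sum(ranks[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated neighbor-voting performance
#'
#' For every annotation set, the positives are split into random near-equal
#' folds; per fold, the held-out positives' labels are hidden, the
#' remaining positives vote, and the AUROC of the held-out positives
#' against all genes never annotated to the function is computed. The
#' per-function AUROC is the mean over folds; the network-level score is
#' the mean over functions. Functions with fewer positives in the universe
#' than folds are skipped with a warning and excluded from the mean.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param annotations an [AnnotationMatrix-class]; restricted to the
#'   network's universe internally.
#' @param folds number of cross-validation folds (default threefold).
#' @param seed integer seed for fold assignment (NULL leaves the RNG
#'   stream alone).
#' @return a [FunctionalConnectivityReport-class]
#' @export
crossValidatedPerformance <- function(net, annotations, folds = 3,
                                      seed = NULL) {
  stopifnot(folds >= 2)
  if (!is.null(seed)) set.seed(seed)
  w <- networkWeights(net)
  ids <- geneIds(net)
  m <- membership(annotations)
  keep <- intersect(ids, rownames(m))
  mm <- matrix(0, length(ids), ncol(m), dimnames = list(ids, colnames(m)))
  mm[keep, ] <- m[keep, , drop = FALSE]
  deg <- rowSums(w)
  inv_deg <- ifelse(deg == 0, 0, 1 / deg)

  n_fun <- ncol(mm)
  pos_list <- lapply(seq_len(n_fun), function(k) which(mm[, k] == 1))
  n_pos <- lengths(pos_list)
  scoreable <- n_pos >= folds
  if (any(!scoreable))
    warning(sum(!scoreable), " function(s) with fewer than ", folds,
            " positives skipped")

  fold_of <- lapply(seq_len(n_fun), function(k) {
    if (!scoreable[k]) return(integer())
    sample(rep_len(seq_len(folds), n_pos[k]))
  })

  auc <- matrix(NA_real_, n_fun, folds)
  for (f in seq_len(folds)) {
    voters <- mm
    for (k in which(scoreable))
      voters[pos_list[[k]][fold_of[[k]] == f], k] <- 0
    voters[, !scoreable] <- 0
    scores <- (w %*% voters) * inv_deg
    for (k in which(scoreable)) {
      held <- pos_list[[k]][fold_of[[k]] == f]
      negs <- which(mm[, k] == 0)
      auc[k, f] <- aurocFromScores(setNames(scores[, k], ids),
                                   ids[held], ids[negs])
    }
  }
  res <- data.frame(function_id = colnames(mm),
                    auroc = rowMeans(auc),
                    n_pos = as.integer(n_pos),
                    n_neg = as.integer(length(ids) - n_pos))
  new("FunctionalConnectivityReport", results = res,
      folds = as.integer(folds),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Leave-one-out neighbor-voting performance for a single gene set
#'
#' Hides each member gene in turn, lets the remaining members vote, and
#' reports the AUROC of the single hidden positive against all non-member
#' genes — i.e. the hidden gene's score quantile among the negatives. This
#' per-gene resolution is what links performance to per-gene covariates
#' such as expression level.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param gene_set character vector of member gene ids (at least 2 in the
#'   network's universe).
#' @return named numeric vector: per-member AUROC
#' @export
looPerformance <- function(net, gene_set) {
  ids <- geneIds(net)
  members <- intersect(gene_set, ids)
  if (length(members) < 2L) stop("need at least 2 set members in the universe")
  w <- networkWeights(net)
  deg <- rowSums(w)
  inv_deg <- ifelse(deg == 0, 0, 1 / deg)
  mvec <- as.numeric(ids %in% members)
  full <- as.vector(w %*% mvec)
  negs <- setdiff(ids, members)
  out <- setNames(numeric(length(members)), members)
  for (g in members) {
    # scores when g alone is hidden: drop g's own column contribution
    s <- setNames((full - w[, g]) * inv_deg, ids)
    out[g] <- aurocFromScores(s, g, negs)
  }
  out
}

#' AUROC of a fixed per-gene predictor for every function
#'
#' Scores each function by how well a single gene-level quantity (node
#' degree, median expression, ...) separates members from non-members. No
#' cross-validation is involved because the predictor ignores the labels.
#' Comparing these AUROCs to cross-validated voting AUROCs shows how much
#' of "functional" performance a label-blind covariate already achieves.
#'
#' @param score named numeric vector over the gene universe.
#' @param annotations an [AnnotationMatrix-class]
#' @return named numeric vector: per-function AUROC
#' @export
predictorPerformance <- function(score, annotations) {
  m <- membership(annotations)
  universe <- intersect(names(score), rownames(m))
  if (length(universe) == 0L) stop("score and annotations share no genes")
  m <- m[universe, , drop = FALSE]
  vapply(seq_len(ncol(m)), function(k) {
    pos <- universe[m[, k] == 1]
    neg <- universe[m[, k] == 0]
    aurocFromScores(score, pos, neg)
  }, numeric(1L)) |> setNames(colnames(m))
}
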