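# a batched UMI-like experiment whose co-expression program lives among
# high-expression genes: the regime where expression level confounds
# functional connectivity
confoundedSim <- function(seed) {
  cfg <- simulationConfig(n_genes = 900, n_batches = 8, cells_per_batch = 16,
                          module_sizes = 300L,
                          module_placement = "high_expression",
                          loading_strength = 0.8, celltype_shift_sd = 0,
                          batch_effect_sd = 0.1,
                          library_size_lognormal = c(0, 0.1),
                          baseline_log_mean_range = log(c(0.1, 60)),
                          seed = seed)
  generateSingleCellExperiment(cfg)
}

# an expression-tilted target set: drawn from the same per-quartile profile
# the matched controls will reproduce, heavier in high-expression genes
tiltedTarget <- function(med, n_per_bin = c(2, 8, 20, 30), seed = 1) {
  set.seed(seed)
  ids <- names(med)
  bin <- ceiling(rank(med, ties.method = "first") * 4 / length(med))
  unlist(lapply(1:4, function(b) sample(ids[bin == b], n_per_bin[b])))
}

test_that("degree tracks median expression when degree order matches, and
           not when expression is shuffled", {
  nn <- nullNetwork(50, seed = 2)
  deg <- nodeDegree(nn)
  # expression whose medians are ordered exactly like degree
  vals <- outer(rank(deg) * 10, c(0, 1, 2, 3, 4), "+")
  dimnames(vals) <- list(geneIds(nn), paste0("s", 1:5))
  se <- ExpressionExperiment(vals, unit = "RPKM")
  expect_equal(degreeExpressionCorrelation(nn, se), 1)
  rs <- vapply(1:8, function(s) {
    set.seed(s)
    perm <- vals[sample(nrow(vals)), ]
    rownames(perm) <- rownames(vals)
    degreeExpressionCorrelation(nn, ExpressionExperiment(perm, unit = "RPKM"))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(8) + 0.05)
})

test_that("raw-count networks show a positive degree-expression correlation
           that CPM reduces or flips", {
  sim <- confoundedSim(seed = 71)
  se <- sim$expression
  rs_raw <- degreeExpressionCorrelation(spearmanNetwork(se), se)
  rs_cpm <- degreeExpressionCorrelation(spearmanNetwork(cpmNormalize(se)), se)
  expect_gt(rs_raw, 0.3)
  expect_lt(rs_cpm, rs_raw)
})

test_that("fisher z matches the closed form", {
  expect_equal(fisherZ(0, 100), 0)
  expect_equal(fisherZ(0.5, 103), atanh(0.5) * 10, tolerance = 1e-12)
  expect_equal(fisherZ(-0.3, 50), -fisherZ(0.3, 50), tolerance = 1e-12)
  expect_error(fisherZ(1, 10), "< 1")
  expect_error(fisherZ(0.5, 3), "exceed 3")
})

test_that("expression-matched sets reproduce the target's per-bin counts
           exactly and fail loudly on exhausted bins", {
  set.seed(9)
  med <- setNames(rexp(200), sprintf("g%03d", 1:200))
  bin <- ceiling(rank(med, ties.method = "first") * 4 / 200)
  target <- c(names(med)[bin == 1][1:3], names(med)[bin == 2][1:2],
              names(med)[bin == 3][1])
  sets <- expressionMatchedSets(target, med, n_sets = 25, seed = 4)
  expect_length(sets, 25)
  for (s in sets) {
    expect_equal(unname(tabulate(bin[s], nbins = 4)), c(3, 2, 1, 0))
    expect_length(intersect(s, target), 0)
    expect_false(anyDuplicated(s) > 0)
  }
  expect_gt(length(unique(vapply(sets, paste, "", collapse = ","))), 1)
  # a target owning nearly a whole bin cannot be matched
  hog <- names(med)[bin == 4][1:49]
  expect_error(expressionMatchedSets(hog, med, n_sets = 2), "bin 4")
})

test_that("matched control sets perform like an expression-driven target", {
  sim <- confoundedSim(seed = 73)
  se <- sim$expression
  net <- spearmanNetwork(se)
  med <- apply(exprAssay(se), 1, median)
  target <- tiltedTarget(med, seed = 11)
  aucOf <- function(genes) {
    meanAuroc(crossValidatedPerformance(
      net, annotationFromSets(list(s = genes), universe = geneIds(net)),
      folds = 3, seed = 21))
  }
  auc_target <- aucOf(target)
  controls <- expressionMatchedSets(target, med, n_sets = 20, seed = 12)
  auc_ctrl <- vapply(controls, aucOf, numeric(1))
  expect_gt(auc_target, 0.55)            # expression profile alone performs
  ci <- quantile(auc_ctrl, c(0.025, 0.975))
  expect_gte(auc_target, ci[[1]])        # target indistinguishable from
  expect_lte(auc_target, ci[[2]])        # its expression-matched controls
})

test_that("restricting to high-expression genes erodes the target's
           performance", {
  sim <- confoundedSim(seed = 73)
  se <- sim$expression
  net <- spearmanNetwork(se)
  med <- apply(exprAssay(se), 1, median)
  target <- tiltedTarget(med, seed = 11)
  auc_full <- meanAuroc(crossValidatedPerformance(
    net, annotationFromSets(list(s = target), universe = geneIds(net)),
    folds = 3, seed = 21))
  se_hi <- filterGenes(se, "median_threshold", 16, groups = "batch")
  net_hi <- spearmanNetwork(se_hi)
  target_hi <- intersect(target, rownames(se_hi))
  expect_gte(length(target_hi), 3)
  auc_hi <- meanAuroc(crossValidatedPerformance(
    net_hi, annotationFromSets(list(s = target_hi),
                               universe = geneIds(net_hi)),
    folds = 3, seed = 21))
  expect_lt(auc_hi, auc_full)
})

test_that("held-out-gene performance tracks expression in confounded
           networks but not in noise-free bulk networks", {
  sim <- confoundedSim(seed = 77)
  se <- sim$expression
  net <- spearmanNetwork(se)
  med <- apply(exprAssay(se), 1, median)
  target <- tiltedTarget(med, seed = 13)
  rel <- looExpressionRelationship(net, target, se)
  expect_gt(rel$r_s, 0.3)
  expect_named(rel$auroc)
  expect_equal(length(rel$auroc), length(intersect(target, geneIds(net))))

  # bulk data with a randomly placed module: per-cell sampling noise absent,
  # so member recovery should not track expression
  rs_bulk <- vapply(1:4, function(s) {
    cfg <- simulationConfig(n_genes = 300, n_samples = 30,
                            module_sizes = 40L, loading_strength = 0.4,
                            celltype_shift_sd = 0, noise_sd = 0.6, seed = s)
    bulk <- generateBulkExperiment(cfg)
    mm <- bulk$truth$module_membership
    members <- names(mm)[!is.na(mm)]
    looExpressionRelationship(spearmanNetwork(bulk$expression), members,
                              bulk$expression)$r_s
  }, numeric(1))
  expect_lt(abs(mean(rs_bulk)), 2 * sd(rs_bulk) / sqrt(4) + 0.1)
})

test_that("covariate correlations behave at the identity, at random, and
           preserve row order", {
  aucs <- c(0.5, 0.55, 0.6, 0.62, 0.7, 0.52, 0.58, 0.65)
  tab <- performanceVsCovariates(aucs, data.frame(self = aucs,
                                                  flat = rep(1, 8)))
  expect_equal(tab$covariate, c("self", "flat"))
  expect_equal(tab$r_s[1], 1)
  expect_true(is.na(tab$r_s[2]))
  set.seed(5)
  rnd <- replicate(40, performanceVsCovariates(
    aucs, data.frame(x = rnorm(8)))$r_s)
  expect_lt(abs(mean(rnd)), 2 * sd(rnd) / sqrt(40))
  expect_error(performanceVsCovariates(c(0.5, 0.6), data.frame(x = 1:2)),
               "at least 3")
})

test_that("per-group regression matches closed forms", {
  # perfectly collinear: R^2 and adjusted R^2 both 1
  x <- c(1, 2, 3, 4); y <- 0.1 * x + 0.4
  fit <- suppressWarnings(connectivityExpressionRegression(y, x))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$adj_r_squared, 1)
  expect_equal(fit$slope, 0.1)

  # slope equals cov/var on a 5-point toy
  x5 <- c(0.2, 1.1, 2.3, 3.0, 4.8); y5 <- c(0.5, 0.62, 0.57, 0.66, 0.71)
  fit5 <- connectivityExpressionRegression(y5, x5)
  expect_equal(fit5$slope, cov(x5, y5) / var(x5), tolerance = 1e-12)
  expect_equal(fit5$intercept, mean(y5) - fit5$slope * mean(x5),
               tolerance = 1e-12)

  # independent inputs, n = 18: adjusted R^2 near zero, often negative
  set.seed(8)
  adj <- replicate(20, connectivityExpressionRegression(
    runif(18, 0.4, 0.8), rnorm(18))$adj_r_squared)
  expect_lt(mean(adj), 0.1)
  expect_true(any(adj < 0))

  # groups are fitted separately
  g <- rep(c("pre", "post"), each = 5)
  out <- connectivityExpressionRegression(c(y5, y5 + 0.1), c(x5, x5), g)
  expect_equal(nrow(out), 2)
  expect_equal(out$slope[1], out$slope[2], tolerance = 1e-12)
  expect_error(connectivityExpressionRegression(y5, rep(1, 5)), "degenerate")
})

test_that("sunset ordering sorts by detection then median then id", {
  vals <- rbind(allhi = c(5, 6, 7, 8),
                alllo = c(1, 1, 2, 2),
                patchy = c(0, 9, 9, 0),
                rare = c(0, 0, 3, 0))
  colnames(vals) <- paste0("s", 1:4)
  se <- ExpressionExperiment(vals, unit = "UMI")
  net <- nullNetwork(4, seed = 1, gene_ids = rownames(vals))
  ord <- sunsetOrder(net, se)
  expect_equal(names(ord), c("allhi", "alllo", "patchy", "rare"))
  # fully detected genes tie-break by median expression (allhi before alllo)
  expect_lt(unname(ord["allhi"]), unname(ord["alllo"]))
  # applying the permutation to the identity twice composes consistently
  w <- networkWeights(net)[ord, ord]
  expect_equal(sort(rownames(w)), sort(geneIds(net)))
})
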