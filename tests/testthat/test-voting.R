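test_that("annotation size filter is inclusive at 20 and 1000 and restricts
           to the universe first", {
  universe <- sprintf("g%04d", 1:1200)
  sets <- list(s19 = universe[1:19], s20 = universe[1:20],
               s1000 = universe[1:1000], s1001 = universe[1:1001],
               shrunk = c(universe[1:15], sprintf("x%02d", 1:10)))
  ann <- annotationFromSets(sets)
  filt <- filterAnnotations(ann, universe, min_size = 20, max_size = 1000)
  expect_setequal(functionIds(filt), c("s20", "s1000"))
  # 25-gene set with only 15 genes in the universe is judged at size 15
  expect_false("shrunk" %in% functionIds(filt))
  expect_error(filterAnnotations(ann, character()), "empty")
  expect_error(filterAnnotations(ann, universe, min_size = 5000), "survive")
})

test_that("neighbor voting scores are connectivity fractions", {
  w <- matrix(0, 5, 5)
  w[5, 1] <- w[1, 5] <- 0.9; w[5, 2] <- w[2, 5] <- 0.8
  w[5, 3] <- w[3, 5] <- 0.1; w[5, 4] <- w[4, 5] <- 0.2
  net <- makeNetwork(w, ids = paste0("g", 1:5))
  labels <- c(g1 = 1, g2 = 1, g3 = 0, g4 = 0, g5 = 0)
  s <- neighborVotingScores(net, labels)
  expect_equal(unname(s["g5"]), 1.7 / 2.0)
  # gene connected only to voters scores 1; only to non-voters scores 0
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 0.5        # g1 -- voter g2 only
  w2[3, 4] <- w2[4, 3] <- 0.7        # g3 -- non-voter g4 only
  net2 <- makeNetwork(w2, ids = paste0("g", 1:4))
  s2 <- neighborVotingScores(net2, c(g1 = 0, g2 = 1, g3 = 0, g4 = 0))
  expect_equal(unname(s2[c("g1", "g3")]), c(1, 0))
  expect_error(neighborVotingScores(net2, c(g1 = 0, g2 = 0, g3 = 0, g4 = 0)),
               "no voter")
})

test_that("auroc matches hand-computed cases and fails on bad sets", {
  s <- c(a = 0.9, b = 0.8, c = 0.8, d = 0.1)
  expect_equal(aurocFromScores(s, c("a", "c"), c("b", "d")), 0.875)
  expect_equal(aurocFromScores(s, c("a", "b"), c("c", "d")), 0.875)
  expect_equal(aurocFromScores(s, "a", c("b", "c", "d")), 1)
  tied <- setNames(rep(1, 6), letters[1:6])
  expect_equal(aurocFromScores(tied, letters[1:3], letters[4:6]), 0.5)
  expect_true(is.na(aurocFromScores(s, character(), "a")))
  expect_error(aurocFromScores(s, c("a", "b"), c("b", "d")), "disjoint")
})

test_that("auroc equals the pair-counting oracle, is monotone-invariant,
           and complement-symmetric", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    scores <- setNames(sample(seq(0, 1, by = 0.05), n, replace = TRUE),
                       paste0("g", seq_len(n)))
    n_pos <- sample(seq_len(n - 1), 1)
    pos <- names(scores)[seq_len(n_pos)]
    neg <- setdiff(names(scores), pos)
    expect_equal(aurocFromScores(scores, pos, neg),
                 unname(bruteForceAuroc(scores, pos, neg)), tolerance = 1e-12)
    expect_equal(aurocFromScores(scores, pos, neg),
                 aurocFromScores(exp(3 * scores) - 0.2, pos, neg))
  }
  # complement symmetry without ties
  s <- setNames(sample(seq_len(20)) / 20, paste0("g", 1:20))
  pos <- paste0("g", 1:8); neg <- paste0("g", 9:20)
  expect_equal(aurocFromScores(s, pos, neg) + aurocFromScores(-s, pos, neg), 1)
})

test_that("cross-validated voting recovers perfect block structure and is
           seed-reproducible", {
  # block network: within-set weights far above between-set weights
  n <- 60; ids <- sprintf("g%04d", 1:n)
  blocks <- rep(1:3, each = 20)
  w <- matrix(0, n, n)
  w[outer(blocks, blocks, "==")] <- 0.9
  w[outer(blocks, blocks, "!=")] <- 0.1
  w <- (w + t(w)) / 2
  net <- makeNetwork(w, ids = ids)
  ann <- annotationFromSets(split(ids, blocks) |>
                              setNames(paste0("block", 1:3)), universe = ids)
  rep1 <- crossValidatedPerformance(net, ann, folds = 3, seed = 5)
  expect_true(all(functionAurocs(rep1) >= 0.95))
  rep2 <- crossValidatedPerformance(net, ann, folds = 3, seed = 5)
  expect_identical(rep1@results, rep2@results)

  # voting with all labels visible ranks members above non-members
  s <- neighborVotingScores(net, setNames(as.numeric(blocks == 1), ids))
  expect_gt(aurocFromScores(s, ids[blocks == 1], ids[blocks != 1]), 0.5)
})

test_that("functions with fewer positives than folds are skipped with a
           warning and excluded from the mean", {
  nn <- nullNetwork(50, seed = 8)
  ids <- geneIds(nn)
  ann <- annotationFromSets(list(big = ids[1:20], tiny = ids[1:2]),
                            universe = ids)
  expect_warning(rep1 <- crossValidatedPerformance(nn, ann, folds = 3,
                                                   seed = 1), "skipped")
  r <- rep1@results
  expect_true(is.na(r$auroc[r$function_id == "tiny"]))
  expect_equal(meanAuroc(rep1), r$auroc[r$function_id == "big"])
})

test_that("leave-one-out performance reduces to score quantiles", {
  w <- matrix(0, 5, 5)
  w[5, 1] <- w[1, 5] <- 0.9; w[5, 2] <- w[2, 5] <- 0.8
  w[5, 3] <- w[3, 5] <- 0.1; w[5, 4] <- w[4, 5] <- 0.2
  w[1, 2] <- w[2, 1] <- 0.5
  net <- makeNetwork(w, ids = paste0("g", 1:5))
  loo <- looPerformance(net, c("g1", "g2"))
  # oracle: hide g1, voters {g2}; score_i = w_i,g2 / deg_i
  deg <- rowSums(w)
  s <- setNames(w[, 2] / deg, paste0("g", 1:5))
  expect_equal(unname(loo["g1"]),
               unname(bruteForceAuroc(s, "g1", c("g3", "g4", "g5"))))
  expect_error(looPerformance(net, "g1"), "at least 2")

  # member outscoring every negative gets 1; all-tied gets 0.5
  block <- matrix(0.5, 4, 4)
  block[1, 2] <- block[2, 1] <- 1
  netb <- makeNetwork(block, ids = paste0("g", 1:4))
  loob <- looPerformance(netb, c("g1", "g2"))
  expect_equal(unname(loob["g1"]), 1)
})

test_that("fixed per-gene predictors score as expected", {
  nn <- nullNetwork(40, seed = 10)
  ids <- geneIds(nn)
  ann <- annotationFromSets(list(f1 = ids[1:10], f2 = ids[11:30]),
                            universe = ids)
  const <- setNames(rep(1, 40), ids)
  expect_equal(unname(predictorPerformance(const, ann)), c(0.5, 0.5))
  indicator <- setNames(as.numeric(ids %in% ids[1:10]), ids)
  expect_equal(unname(predictorPerformance(indicator, ann)["f1"]), 1)
})

test_that("node degree as predictor tracks cross-validated performance on
           expression-confounded networks", {
  # co-expression programs live among high-expression genes, so functions
  # made of high expressors are learnable and hub-rich, while functions of
  # low expressors are neither: across such a mix, degree alone predicts
  # which functions cross-validation will score well
  cfg <- simulationConfig(n_genes = 600, n_batches = 8, cells_per_batch = 16,
                          module_sizes = rep(40, 5),
                          module_placement = "high_expression",
                          loading_strength = 0.8, celltype_shift_sd = 0,
                          batch_effect_sd = 0.1,
                          library_size_lognormal = c(0, 0.1), seed = 41)
  sim <- generateSingleCellExperiment(cfg)
  net <- spearmanNetwork(sim$expression)
  mm <- sim$truth$module_membership
  med <- apply(exprAssay(sim$expression), 1, median)
  low_pool <- names(mm)[is.na(mm)]
  low_pool <- low_pool[order(med[low_pool])][1:200]
  set.seed(42)
  sets <- c(split(names(mm)[!is.na(mm)], mm[!is.na(mm)]) |>
              setNames(paste0("module", 1:5)),
            setNames(lapply(1:5, function(k) sample(low_pool, 40)),
                     paste0("low", 1:5)))
  ann <- annotationFromSets(sets, universe = geneIds(net))
  cv <- functionAurocs(crossValidatedPerformance(net, ann, seed = 6))
  degp <- predictorPerformance(nodeDegree(net), ann)
  expect_gt(cor(cv, degp[names(cv)], method = "spearman"), 0)
})
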