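## training set whose similarities to a probe query are exactly
## {0.9, 0.5, 0.2, 0.1}: build fingerprints over 100 bits by controlled
## overlap with a 10-bit query
probeSet <- function() {
  q <- integer(100); q[1:10] <- 1L
  mk <- function(shared, extra) {
    v <- integer(100)
    if (shared > 0) v[seq_len(shared)] <- 1L
    if (extra > 0) v[10 + seq_len(extra)] <- 1L
    v
  }
  ## tanimoto = shared / (10 + extra)
  train <- rbind(t1 = mk(9, 0),   # 9/10  = 0.9
                 t2 = mk(5, 0),   # 5/10  = 0.5
                 t3 = mk(2, 0),   # 2/10  = 0.2
                 t4 = mk(1, 0))   # 1/10  = 0.1
  list(query = q, train = train)
}

test_that("fusion scores implement MAX, mean-of-top-k and mean-of-all", {
  ps <- probeSet()
  expect_equal(fusionScore(ps$query, ps$train, "MAX"), 0.9)
  expect_equal(fusionScore(ps$query, ps$train, "KNN3"), (0.9 + 0.5 + 0.2) / 3)
  expect_equal(fusionScore(ps$query, ps$train, "MPS"), (0.9 + 0.5 + 0.2 + 0.1) / 4)
  ## fewer training ligands than k: average over all
  expect_equal(fusionScore(ps$query, ps$train[1:2, ], "KNN3"), (0.9 + 0.5) / 2)
  expect_error(fusionScore(ps$query, ps$train[0, , drop = FALSE], "MAX"),
               class = "emptyTrainingSet")
})

test_that("exemplar score compares against exemplars only", {
  ps <- probeSet()
  ## cluster 1 = {t1, t2} with exemplar t2 (0.5); cluster 2 = {t3} (0.2)
  mem <- data.frame(member_id = c("t1", "t2", "t3"),
                    cluster_id = c("1", "1", "2"),
                    exemplar_id = c("t2", "t2", "t3"), stringsAsFactors = FALSE)
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  ## t1 (0.9) is a member but not exemplar: the score is capped at 0.5
  expect_equal(exemplarScore(ps$query, cl, ps$train), 0.5)
  ## all singleton clusters: exemplar score equals MAX
  memS <- data.frame(member_id = rownames(ps$train),
                     cluster_id = as.character(1:4),
                     exemplar_id = rownames(ps$train), stringsAsFactors = FALSE)
  clS <- new("LigandClusterSet", membership = memS, amw = numeric(0))
  expect_equal(exemplarScore(ps$query, clS, ps$train),
               fusionScore(ps$query, ps$train, "MAX"))
})

test_that("rank-based AUC equals brute-force pair counting", {
  ## separable and degenerate cases
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(aucScore(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)), 0.5)
  expect_error(aucScore(1:3, c(TRUE, TRUE, TRUE)), class = "degenerateLabels")
  ## listed 4-active / 6-decoy example vs the O(n^2) oracle
  sc <- c(0.9, 0.7, 0.7, 0.3, 0.8, 0.7, 0.5, 0.4, 0.2, 0.1)
  lab <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(aucScore(sc, lab), oracleAUC(sc, lab), tolerance = 1e-12)
  ## random score vectors
  set.seed(2)
  for (i in 1:20) {
    s <- sample(seq(0, 1, by = 0.05), 15, replace = TRUE)
    l <- sample(c(TRUE, FALSE), 15, replace = TRUE, prob = c(0.4, 0.6))
    if (any(l) && any(!l))
      expect_equal(aucScore(s, l), oracleAUC(s, l), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  s <- runif(30)
  l <- c(rep(TRUE, 10), rep(FALSE, 20))
  base <- aucScore(s, l)
  expect_equal(aucScore(s^3, l), base, tolerance = 1e-12)
  expect_equal(aucScore(log(s + 1), l), base, tolerance = 1e-12)
  expect_equal(aucScore(1000 * s - 5, l), base, tolerance = 1e-12)
})

test_that("Friedman post hoc flags a dominating method and ties as p = 1", {
  set.seed(9)
  ## one method strictly dominating in every one of 20 blocks
  base <- matrix(runif(20 * 3, 0.4, 0.6), 20, 3)
  tab <- cbind(base, best = apply(base, 1, max) + 0.1)
  colnames(tab) <- c("m1", "m2", "m3", "best")
  res <- friedmanPosthoc(tab)
  expect_lt(res$p_value, 0.01)
  expect_equal(unname(diag(res$pairwise)), rep(1, 4))
  expect_equal(res$pairwise, t(res$pairwise))
  ## the dominating method separates from every other
  expect_true(all(res$pairwise["best", c("m1", "m2", "m3")] < 0.05))
  ## permutation alternative agrees on the dominance call
  resp <- friedmanPosthoc(tab, posthoc = "permutation", nperm = 500, seed = 3)
  expect_true(all(resp$pairwise["best", c("m1", "m2", "m3")] < 0.05))
  ## two identical columns give pairwise p = 1
  tab2 <- cbind(tab, best2 = tab[, "best"])
  res2 <- friedmanPosthoc(tab2)
  expect_equal(res2$pairwise["best", "best2"], 1)
  ## all-constant table: warned, p = 1
  expect_warning(res3 <- friedmanPosthoc(matrix(0.5, 5, 3,
    dimnames = list(NULL, c("a", "b", "c")))), class = "constantRanks")
  expect_equal(res3$p_value, 1)
})

test_that("benchmark is deterministic given a seed and rejects tiny sets", {
  set.seed(1)
  m <- randomFps(40, nbits = 64, density = 0.3, seed = 30)
  sets <- list(list(target_id = "T1",
                    actives = m[1:12, ], decoys = m[13:40, ]))
  b1 <- quietly(runBenchmark(sets, repeats = 2, seed = 5))
  b2 <- quietly(runBenchmark(sets, repeats = 2, seed = 5))
  expect_identical(b1$auc, b2$auc)
  expect_true(all(b1$auc$auc >= 0 & b1$auc$auc <= 1))
  ## one active: training would consume it entirely
  tiny <- list(list(target_id = "T2", actives = m[1, , drop = FALSE],
                    decoys = m[2:10, ]))
  expect_error(quietly(runBenchmark(tiny, repeats = 1, seed = 1)),
               class = "insufficientActives")
})

test_that("exemplar scoring never exceeds MAX and saves evaluations", {
  fx <- synthFixture()
  sets <- quietly(makeScreenSets(synthConfig(n_targets = 2L, seed = 7L)))
  bm <- quietly(runBenchmark(sets, repeats = 5, seed = 7))
  wide <- stats::reshape(bm$auc, direction = "wide",
                         idvar = c("target", "rep"), timevar = "method")
  ## per-query dominance is checked at score level inside one repeat
  s <- sets[[1]]
  A <- bits(s$actives)
  set.seed(11)
  train <- A[sample(nrow(A), 7), ]
  cl <- quietly(clusterLigands(asFpSet(train)))
  for (q in sample(nrow(bits(s$decoys)), 10)) {
    qfp <- bits(s$decoys)[q, ]
    expect_lte(exemplarScore(qfp, cl, train),
               fusionScore(qfp, train, "MAX") + 1e-12)
  }
  ## evaluation counts: exemplars never outnumber the training set
  expect_true(all(bm$evaluations$n_exemplars <= bm$evaluations$n_train))
  expect_true(all(bm$evaluations$reduction_pct >= 0))
})
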