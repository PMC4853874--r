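## Ligand-set virtual screening: group-fusion scores against a training
## set of known actives (MAX, 3NN, MPS), the exemplar score that compares
## the query only against affinity-propagation cluster exemplars, and the
## repeated-split AUC benchmark with Friedman post hoc statistics.

.SCREEN_METHODS <- c("MAX", "KNN3", "MPS", "EXEMPLAR")

#' Group-fusion similarity score of a query against a training set
#'
#' MAX is the largest Tanimoto similarity to any training ligand, KNN3
#' the mean of the k largest similarities (all of them when fewer than k),
#' and MPS the mean of the similarities to every training ligand.
#'
#' @param query_fp binary fingerprint vector of the query.
#' @param train_fps FingerprintSet (or 0/1 matrix) of training ligands;
#'   an empty set raises \code{emptyTrainingSet}.
#' @param method one of "MAX", "KNN3", "MPS".
#' @param k neighbourhood size for KNN3 (default 3).
#' @return score in [0, 1].
#' @export
fusionScore <- function(query_fp, train_fps, method = c("MAX", "KNN3", "MPS"),
                        k = 3L) {
  method <- match.arg(method)
  Tm <- if (is(train_fps, "FingerprintSet")) bits(train_fps) else train_fps
  if (is.null(dim(Tm))) Tm <- matrix(Tm, nrow = 1)
  if (nrow(Tm) == 0)
    stopLcbn("emptyTrainingSet", "no training ligands to score against")
  sims <- as.numeric(tanimotoMatrix(matrix(as.integer(query_fp), nrow = 1), Tm))
  switch(method,
         MAX = max(sims),
         KNN3 = mean(sort(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))]),
         MPS = mean(sims))
}

#' Exemplar similarity score of a query
#'
#' The largest Tanimoto similarity between the query and any cluster
#' exemplar. Only exemplars are compared -- one evaluation per cluster
#' instead of one per training ligand -- which is the method's
#' speed/accuracy trade: a highly similar non-exemplar member does not
#' raise the score.
#'
#' @param query_fp binary fingerprint vector of the query.
#' @param clusters a LigandClusterSet of the training actives.
#' @param fps FingerprintSet covering at least the exemplar ligands.
#' @return score in [0, 1].
#' @export
exemplarScore <- function(query_fp, clusters, fps) {
  ex <- unique(exemplars(clusters))
  if (length(ex) == 0)
    stopLcbn("emptyTrainingSet", "cluster set has no exemplars")
  B <- if (is(fps, "FingerprintSet")) bits(fps) else fps
  fusionScore(query_fp, B[ex, , drop = FALSE], method = "MAX")
}

#' Rank-based AUC of a score vector
#'
#' The probability that a randomly chosen active outscores a randomly
#' chosen decoy, with ties counted one half (midrank convention); this is
#' the Mann-Whitney statistic scaled to [0, 1].
#'
#' @param scores numeric scores, higher = more active-like.
#' @param labels logical or "active"/"decoy" vector aligned with scores.
#' @return AUC in [0, 1]. Raises \code{degenerateLabels} when either
#'   class is empty.
#' @export
aucScore <- function(scores, labels) {
  act <- if (is.logical(labels)) labels else labels == "active"
  n1 <- sum(act); n0 <- sum(!act)
  if (n1 == 0 || n0 == 0)
    stopLcbn("degenerateLabels", "need at least one active and one decoy")
  r <- rank(scores)  # midranks for ties
  (sum(r[act]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## deterministic per-(target, repeat) seed below 2^31, derived from the
## master seed so repeats are independent but reproducible
.foldSeed <- function(seed, target_idx, rep_idx) {
  (as.numeric(seed) * 7919 + target_idx * 104729 + rep_idx * 1299709) %% 2147483647
}

#' Repeated-split virtual-screening benchmark
#'
#' For every target and repeat: a random fraction of the actives (ceiling,
#' so never empty) is the training set; the training actives are
#' AP-clustered (similarity edges above \code{clusterThreshold},
#' preference 0); the remaining actives plus all decoys are scored with
#' MAX, 3NN, MPS and EXEMPLAR; each method's AUC is recorded. Also
#' reports, per repeat, how many similarity evaluations EXEMPLAR needed
#' versus MAX (the exemplar count versus the training-set size).
#'
#' @param sets list of screen sets, each a list with elements
#'   \code{target_id}, \code{actives} and \code{decoys} (FingerprintSets
#'   or 0/1 matrices).
#' @param trainFraction fraction of actives used for training
#'   (default 0.2).
#' @param repeats number of random splits per target (default 50).
#' @param seed master seed; per-(target, repeat) seeds are derived from
#'   it deterministically.
#' @param k neighbourhood size for KNN3.
#' @param clusterThreshold similarity threshold for AP clustering of the
#'   training set (default 0.5).
#' @return list with \code{auc} (data.frame target, repeat, method, auc),
#'   \code{mean_auc} (named by method), \code{evaluations} (data.frame
#'   target, repeat, n_train, n_exemplars, reduction_pct) and
#'   \code{friedman} (see \code{\link{friedmanPosthoc}}).
#' @export
runBenchmark <- function(sets, trainFraction = 0.2, repeats = 50L, seed = 1L,
                         k = 3L, clusterThreshold = 0.5) {
  rows <- list(); evals <- list()
  for (ti in seq_along(sets)) {
    s <- sets[[ti]]
    A <- if (is(s$actives, "FingerprintSet")) bits(s$actives) else s$actives
    D <- if (is(s$decoys, "FingerprintSet")) bits(s$decoys) else s$decoys
    nA <- nrow(A)
    n_train <- ceiling(trainFraction * nA)
    if (n_train >= nA || n_train < 1)
      stopLcbn("insufficientActives",
               sprintf("target %s: %d actives leave no test actives at fraction %.2f",
                       s$target_id, nA, trainFraction))
    ## precompute similarities of every candidate item to every active
    test_all <- rbind(A, D)
    sim_all <- tanimotoMatrix(test_all, A)
    act_ids <- rownames(A)
    for (ri in seq_len(repeats)) {
      set.seed(.foldSeed(seed, ti, ri))
      train_ids <- sort(sample(act_ids, n_train))
      test_ids <- c(setdiff(act_ids, train_ids), rownames(D))
      labels <- c(rep(TRUE, nA - n_train), rep(FALSE, nrow(D)))
      S <- sim_all[test_ids, train_ids, drop = FALSE]
      train_fp <- new("FingerprintSet",
                      bits = A[train_ids, , drop = FALSE],
                      nbits = ncol(A), depth = NA_integer_,
                      family = "subset")
      cl <- suppressWarnings(
        clusterLigands(train_fp, threshold = clusterThreshold, preference = 0))
      ex <- unique(exemplars(cl))
      sc <- list(
        MAX = apply(S, 1, max),
        KNN3 = apply(S, 1, function(v)
          mean(sort(v, decreasing = TRUE)[seq_len(min(k, length(v)))])),
        MPS = rowMeans(S),
        EXEMPLAR = apply(S[, ex, drop = FALSE], 1, max))
      for (mth in .SCREEN_METHODS) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = s$target_id, rep = ri, method = mth,
          auc = aucScore(sc[[mth]], labels), stringsAsFactors = FALSE)
      }
      evals[[length(evals) + 1L]] <- data.frame(
        target = s$target_id, rep = ri, n_train = n_train,
        n_exemplars = length(ex),
        reduction_pct = 100 * (1 - length(ex) / n_train),
        stringsAsFactors = FALSE)
    }
  }
  auc <- do.call(rbind, rows)
  mean_auc <- tapply(auc$auc, auc$method, mean)[.SCREEN_METHODS]
  blocks <- stats::reshape(auc, direction = "wide",
                           idvar = c("target", "rep"), timevar = "method")
  mat <- as.matrix(blocks[, paste0("auc.", .SCREEN_METHODS)])
  colnames(mat) <- .SCREEN_METHODS
  list(auc = auc, mean_auc = mean_auc,
       evaluations = do.call(rbind, evals),
       friedman = friedmanPosthoc(mat))
}

#' Friedman test with post hoc pairwise comparisons
#'
#' Global Friedman rank test over blocks (rows) and methods (columns),
#' then Nemenyi-type pairwise comparisons: the difference in mean ranks
#' is referred to the studentized range distribution. A permutation-based
#' alternative for the pairwise step is available.
#'
#' @param aucTable numeric matrix, blocks x methods, with method names as
#'   column names.
#' @param posthoc "nemenyi" (studentized-range critical differences) or
#'   "permutation" (within-block label permutations of the rank
#'   difference).
#' @param nperm permutations when \code{posthoc = "permutation"}.
#' @param seed seed for the permutation draw.
#' @return list with \code{statistic}, \code{p_value} (global),
#'   \code{mean_ranks}, and \code{pairwise} (symmetric p-value matrix
#'   with unit diagonal). When every block ranks all methods identically
#'   the global p is 1 with a \code{constantRanks} warning.
#' @export
friedmanPosthoc <- function(aucTable, posthoc = c("nemenyi", "permutation"),
                            nperm = 2000L, seed = 1L) {
  posthoc <- match.arg(posthoc)
  stopifnot(is.matrix(aucTable), ncol(aucTable) >= 2, nrow(aucTable) >= 2)
  methods <- colnames(aucTable)
  n <- nrow(aucTable); kk <- ncol(aucTable)
  ranks <- t(apply(aucTable, 1, rank))
  mean_ranks <- colMeans(ranks)
  if (max(apply(aucTable, 1, function(x) length(unique(x)))) == 1) {
    lcbnWarning("constantRanks", "all methods tie in every block")
    pw <- matrix(1, kk, kk, dimnames = list(methods, methods))
    return(list(statistic = 0, p_value = 1, mean_ranks = mean_ranks,
                pairwise = pw, posthoc = posthoc))
  }
  ft <- stats::friedman.test(aucTable)
  pw <- matrix(1, kk, kk, dimnames = list(methods, methods))
  if (posthoc == "nemenyi") {
    se <- sqrt(kk * (kk + 1) / (12 * n))
    for (i in seq_len(kk - 1)) for (j in (i + 1):kk) {
      q <- abs(mean_ranks[i] - mean_ranks[j]) / se * sqrt(2)
      p <- stats::ptukey(q, nmeans = kk, df = Inf, lower.tail = FALSE)
      pw[i, j] <- pw[j, i] <- p
    }
  } else {
    set.seed(seed)
    obs <- abs(outer(mean_ranks, mean_ranks, "-"))
    cnt <- matrix(0, kk, kk)
    for (b in seq_len(nperm)) {
      permuted <- t(apply(ranks, 1, sample))
      d <- abs(outer(colMeans(permuted), colMeans(permuted), "-"))
      cnt <- cnt + (d >= obs - 1e-12)
    }
    pw <- (cnt + 1) / (nperm + 1)
    diag(pw) <- 1
    dimnames(pw) <- list(methods, methods)
  }
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       mean_ranks = mean_ranks, pairwise = pw, posthoc = posthoc)
}
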