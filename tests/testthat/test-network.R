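simMat <- function(v, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(nrow(v)))
  dimnames(v) <- list(ids, ids)
  diag(v) <- 1
  new("SimilarityMatrix", values = v, kind = "ligand_cluster")
}

randomSim <- function(n, seed = 1) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  simMat((M + t(M)) / 2)
}

test_that("network keeps edges strictly above the threshold", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.3
  v[1, 3] <- v[3, 1] <- 0.2
  net <- buildNetwork(simMat(v, c("P", "Q", "R")), threshold = 0.25)
  g <- networkGraph(net)
  expect_equal(igraph::ecount(g), 1L)
  expect_true(igraph::are_adjacent(g, "P", "Q"))
  expect_equal(igraph::degree(g)[["R"]], 0)  # isolated node retained
  ## threshold 0 keeps every positive similarity
  net0 <- buildNetwork(simMat(v, c("P", "Q", "R")), threshold = 0)
  expect_equal(igraph::ecount(networkGraph(net0)), 2L)
})

test_that("network edge set equals a brute-force filter on a random matrix", {
  sim <- randomSim(30, seed = 4)
  net <- buildNetwork(sim, threshold = 0.25)
  v <- simValues(sim)
  el <- igraph::as_data_frame(networkGraph(net), what = "edges")
  got <- sort(paste(pmin(el$from, el$to), pmax(el$from, el$to)))
  expected <- character(0)
  ids <- rownames(v)
  for (i in 1:29) for (j in (i + 1):30)
    if (v[i, j] > 0.25)
      expected <- c(expected, paste(min(ids[i], ids[j]), max(ids[i], ids[j])))
  expect_equal(got, sort(expected))
  ## edge weights carry the similarity
  for (r in seq_len(nrow(el)))
    expect_equal(el$weight[r], v[el$from[r], el$to[r]])
})

test_that("raising the threshold never adds edges", {
  sim <- randomSim(25, seed = 8)
  counts <- vapply(c(0, 0.25, 0.5, 0.75),
                   function(t) igraph::ecount(networkGraph(buildNetwork(sim, t))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected components match flood fill and are size-ordered", {
  v <- matrix(0, 5, 5)
  v[1, 2] <- v[2, 1] <- 0.9
  v[3, 4] <- v[4, 3] <- 0.8
  net <- buildNetwork(simMat(v), threshold = 0.25)
  comp <- networkComponents(net)
  expect_equal(lengths(comp), c(2L, 2L, 1L))
  expect_equal(lengths(networkComponents(net, dropIsolated = TRUE)), c(2L, 2L))
  ## empty edge set: all singletons
  net0 <- buildNetwork(simMat(matrix(0, 4, 4)), threshold = 0.25)
  expect_equal(lengths(networkComponents(net0)), rep(1L, 4))
  ## random graph vs oracle
  sim <- randomSim(30, seed = 12)
  netr <- buildNetwork(sim, threshold = 0.6)
  el <- igraph::as_data_frame(networkGraph(netr), what = "edges")
  oc <- oracleComponents(rownames(simValues(sim)), el)
  got <- networkComponents(netr)
  expect_equal(length(got), length(unique(oc)))
  for (grp in got)
    expect_equal(length(unique(oc[grp])), 1L)
})

test_that("AP communities recover a block-diagonal similarity structure", {
  v <- matrix(0.05, 8, 8)
  v[1:4, 1:4] <- 0.9
  v[5:8, 5:8] <- 0.9
  sim <- simMat(v)
  p <- suppressWarnings(communitiesAP(sim))
  l <- partitionLabels(p)
  expect_equal(length(unique(l)), 2L)
  expect_equal(length(unique(l[1:4])), 1L)
  expect_equal(length(unique(l[5:8])), 1L)
  ## all-zero off-diagonal: every protein its own community
  p0 <- suppressWarnings(communitiesAP(simMat(matrix(0, 5, 5))))
  expect_equal(length(unique(partitionLabels(p0))), 5L)
})

test_that("infomap adapter splits disconnected cliques; mcl reports missing backend", {
  v <- matrix(0, 6, 6)
  v[1:3, 1:3] <- 0.9
  v[4:6, 4:6] <- 0.9
  net <- buildNetwork(simMat(v), threshold = 0.25)
  p <- communitiesExternal(net, "infomap")
  l <- partitionLabels(p)
  expect_equal(length(unique(l)), 2L)
  expect_equal(length(unique(l[1:3])), 1L)
  if (!nzchar(Sys.which("mcl"))) {
    expect_error(communitiesExternal(net, "mcl"), class = "backendUnavailable")
  } else {
    pm <- communitiesExternal(net, "mcl")
    expect_equal(length(unique(partitionLabels(pm))), 2L)
  }
})

test_that("NMI matches its defining properties and a worked example", {
  a <- stats::setNames(c("x", "x", "x", "y", "y", "y"), as.character(1:6))
  b <- stats::setNames(c("u", "u", "v", "v", "v", "v"), as.character(1:6))
  ## identical partitions
  expect_equal(nmi(a, a), 1)
  ## constant partition carries no information
  const <- stats::setNames(rep("z", 6), as.character(1:6))
  expect_equal(nmi(a, const), 0)
  ## worked 6-node example against the double-loop oracle
  expect_equal(nmi(a, b), oracleNMI(a, b), tolerance = 1e-12)
  expect_equal(nmi(a, b), 0.47870397, tolerance = 1e-6)
  ## symmetry
  expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  ## max normalization is never larger than mean normalization
  expect_lte(nmi(a, b, normalizer = "max"), nmi(a, b))
  ## disjoint node sets
  c2 <- stats::setNames(c("x", "y"), c("n1", "n2"))
  expect_error(nmi(a, c2), class = "emptyOverlap")
})

test_that("NMI agrees with the oracle on random partition pairs", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    a <- stats::setNames(sample(letters[1:4], n, replace = TRUE), seq_len(n))
    b <- stats::setNames(sample(letters[1:5], n, replace = TRUE), seq_len(n))
    expect_equal(nmi(a, b), oracleNMI(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b, "max"), oracleNMI(a, b, "max"), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  }
})

test_that("network exports round-trip through GraphML and list isolated nodes in SIF", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.5
  net <- buildNetwork(simMat(v, c("A", "B", "C")), threshold = 0.25,
                      families = c(A = "f1", B = "f1", C = "f2"))
  gfile <- tempfile(fileext = ".graphml")
  writeGraphML(net, gfile)
  g2 <- igraph::read_graph(gfile, format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::ecount(g2), 1)
  expect_setequal(igraph::V(g2)$family, c("f1", "f1", "f2"))
  sfile <- tempfile(fileext = ".sif")
  writeSIF(net, sfile)
  lines <- readLines(sfile)
  expect_true(any(grepl("^A\tsim\tB$|^B\tsim\tA$", lines)))
  expect_true("C" %in% lines)
})
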