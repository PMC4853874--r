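test_that("interaction filter matches hand enumeration of the three rules", {
  tt <- toyFilterTable()
  out <- filterInteractions(tt$records, tt$ligands, tt$proteins)
  expect_equal(nrow(out$records), length(tt$kept))
  expect_equal(out$records$ligand_id, tt$records$ligand_id[tt$kept])
  expect_equal(out$records$protein_id, tt$records$protein_id[tt$kept])
  expect_equal(unname(out$report["bad_affinity_type"]), 1L)
  expect_equal(unname(out$report["unresolved_id"]), 2L)
  expect_equal(unname(out$report["affinity_rule"]), 1L)
  expect_equal(unname(out$report["mol_weight_rule"]), 2L)
  expect_equal(unname(out$report["seq_length_rule"]), 2L)
})

test_that("filtering is idempotent and empty survivors raise emptyResult", {
  tt <- toyFilterTable()
  once <- filterInteractions(tt$records, tt$ligands, tt$proteins)
  twice <- filterInteractions(once$records, tt$ligands, tt$proteins)
  expect_equal(twice$records, once$records)
  expect_true(all(twice$report[c("affinity_rule", "mol_weight_rule",
                                 "seq_length_rule")] == 0))
  heavy <- tt$records[6, , drop = FALSE]  # MW 800 always fails
  expect_error(filterInteractions(heavy, tt$ligands, tt$proteins),
               class = "emptyResult")
})

test_that("protein annotation sets one bit per bound cluster", {
  mem <- data.frame(member_id = c("a", "b", "c"),
                    cluster_id = c("1", "1", "2"),
                    exemplar_id = c("a", "a", "c"), stringsAsFactors = FALSE)
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  rec <- data.frame(ligand_id = c("a", "b", "c", "a"),
                    protein_id = c("P", "P", "Q", "R"), stringsAsFactors = FALSE)
  prof <- annotateProteins(rec, cl)
  B <- bits(prof)
  expect_equal(B["P", ], c(`1` = 1L, `2` = 0L))
  expect_equal(B["Q", ], c(`1` = 0L, `2` = 1L))
  ## bit is at cluster level: P (via a,b) and R (via a) share a profile bit
  expect_equal(B["R", "1"], 1L)
  ## unclustered ligand is an error
  rec2 <- rbind(rec, data.frame(ligand_id = "zz", protein_id = "P"))
  expect_error(annotateProteins(rec2, cl), class = "unclusteredLigand")
})

test_that("proteins binding disjoint ligands of one cluster get identical profiles", {
  mem <- data.frame(member_id = c("a", "b"), cluster_id = c("1", "1"),
                    exemplar_id = c("a", "a"), stringsAsFactors = FALSE)
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  rec <- data.frame(ligand_id = c("a", "b"), protein_id = c("P", "Q"),
                    stringsAsFactors = FALSE)
  B <- bits(annotateProteins(rec, cl))
  expect_equal(unname(B["P", ]), unname(B["Q", ]))
})

test_that("Jaccard similarity matrix matches the set-based oracle", {
  set.seed(13)
  B <- matrix(as.integer(runif(50 * 20) < 0.3), 50, 20,
              dimnames = list(sprintf("P%02d", 1:50), as.character(1:20)))
  B[rowSums(B) == 0, 1] <- 1L
  prof <- new("ClusterProfileSet", bits = B)
  J <- simValues(jaccardSimilarityMatrix(prof))
  for (k in 1:200) {
    i <- sample(50, 1); j <- sample(50, 1)
    expect_equal(J[i, j], oracleTanimoto(B[i, ], B[j, ]), tolerance = 1e-12)
  }
  ## worked examples
  P <- rbind(p = c(1L, 1L, 0L, 0L), q = c(0L, 1L, 1L, 0L), r = c(1L, 1L, 0L, 0L))
  colnames(P) <- as.character(1:4)
  Jp <- simValues(jaccardSimilarityMatrix(new("ClusterProfileSet", bits = P)))
  expect_equal(Jp["p", "q"], 1 / 3)
  expect_equal(Jp["p", "r"], 1)
})

test_that("sequence similarity is 1 - distance with strict validation", {
  d <- matrix(c(0, 0.78, 0.78, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  s <- sequenceSimilarityMatrix(d)
  expect_equal(simValues(s)["A", "B"], 0.22)
  expect_equal(kind(s), "sequence")
  d2 <- d; d2[1, 2] <- 0.5
  expect_error(sequenceSimilarityMatrix(d2), class = "matrixMalformed")
  d3 <- d; d3[1, 2] <- d3[2, 1] <- 1.5
  expect_error(sequenceSimilarityMatrix(d3), class = "matrixMalformed")
  d4 <- d; diag(d4) <- 0.2
  expect_error(sequenceSimilarityMatrix(d4), class = "matrixMalformed")
})

test_that("promiscuity statistics equal a brute-force recount", {
  set.seed(17)
  nl <- 50; np <- 10
  lig <- sprintf("L%02d", 1:nl)
  labels <- sample(1:8, nl, replace = TRUE)
  mem <- data.frame(member_id = lig, cluster_id = as.character(labels),
                    exemplar_id = stats::setNames(
                      lig[match(labels, labels)], NULL),
                    stringsAsFactors = FALSE)
  ## exemplar: first member of each cluster
  for (cid in unique(mem$cluster_id))
    mem$exemplar_id[mem$cluster_id == cid] <- mem$member_id[mem$cluster_id == cid][1]
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  rec <- data.frame(ligand_id = sample(lig, 120, replace = TRUE),
                    protein_id = sample(sprintf("P%02d", 1:np), 120, replace = TRUE),
                    stringsAsFactors = FALSE)
  prof <- annotateProteins(rec, cl)
  st <- promiscuityStats(rec, cl, prof)
  ## per-ligand recount
  for (r in seq_len(nrow(st$ligand))) {
    lg <- st$ligand$ligand_id[r]
    expect_equal(st$ligand$n_targets[r],
                 length(unique(rec$protein_id[rec$ligand_id == lg])))
  }
  ## per-cluster union recount + bounds
  for (r in seq_len(nrow(st$cluster))) {
    cid <- st$cluster$cluster_id[r]
    mids <- mem$member_id[mem$cluster_id == cid]
    truth <- length(unique(rec$protein_id[rec$ligand_id %in% mids]))
    expect_equal(st$cluster$n_targets[r], truth)
    ligCounts <- vapply(mids, function(lg)
      length(unique(rec$protein_id[rec$ligand_id == lg])), integer(1))
    if (any(ligCounts > 0)) {
      expect_gte(st$cluster$n_targets[r], max(ligCounts))
      expect_lte(st$cluster$n_targets[r], sum(ligCounts))
    }
  }
  ## per-protein: cluster count never exceeds ligand count
  expect_true(all(st$protein$n_clusters <= st$protein$n_ligands))
})

test_that("family-level cluster counts aggregate over member proteins", {
  mem <- data.frame(member_id = c("a", "b", "c"),
                    cluster_id = c("1", "2", "3"),
                    exemplar_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  rec <- data.frame(ligand_id = c("a", "b", "b", "c"),
                    protein_id = c("P", "P", "Q", "R"), stringsAsFactors = FALSE)
  prof <- annotateProteins(rec, cl)
  st <- promiscuityStats(rec, cl, prof,
                         families = c(P = "kinase", Q = "kinase", R = "gpcr"))
  expect_equal(st$family$n_clusters[st$family$family == "kinase"], 2L)
  expect_equal(st$family$n_clusters[st$family$family == "gpcr"], 1L)
})
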