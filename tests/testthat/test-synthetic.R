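test_that("generators are deterministic under a fixed seed", {
  cfg <- synthConfig(n_clusters = 3L, ligands_per_cluster = 4L,
                     n_proteins = 8L, n_communities = 2L, seed = 5L)
  a <- quietly(makeLigandLibrary(cfg))
  b <- quietly(makeLigandLibrary(cfg))
  expect_identical(a$molecules, b$molecules)
  expect_identical(a$labels, b$labels)
  expect_identical(bits(a$fps), bits(b$fps))
  ia <- makeInteractionTable(cfg, a)
  ib <- makeInteractionTable(cfg, b)
  expect_identical(ia$interactions, ib$interactions)
  expect_identical(ia$distances, ib$distances)
  expect_identical(ia$proteins, ib$proteins)
})

test_that("generators do not disturb the caller's RNG stream", {
  cfg <- synthConfig(n_clusters = 2L, ligands_per_cluster = 3L, seed = 5L)
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(quietly(makeLigandLibrary(cfg)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("ligand library separates planted clusters in fingerprint space", {
  fx <- recoveryFixture()
  lib <- fx$lib
  expect_equal(nrow(lib$molecules), 50L)
  expect_equal(length(unique(lib$labels)), 5L)
  expect_gt(lib$within_mean, lib$between_mean)
  ## the margin the generator validates
  expect_gte(lib$within_mean - lib$between_mean,
             0.5 * (fx$cfg$within_sim - fx$cfg$between_sim))
  ## single-molecule edge case
  tiny <- quietly(makeLigandLibrary(
    synthConfig(n_clusters = 1L, ligands_per_cluster = 1L, seed = 2L)))
  expect_equal(nrow(tiny$molecules), 1L)
  expect_equal(unname(tiny$labels), 1L)
})

test_that("interaction table carries planted communities in both spaces", {
  cfg <- synthConfig(n_clusters = 4L, ligands_per_cluster = 5L,
                     n_proteins = 12L, n_communities = 2L,
                     profile_noise = 0, seed = 11L)
  lib <- quietly(makeLigandLibrary(cfg))
  pl <- makeInteractionTable(cfg, lib)
  expect_true(all(pl$interactions$affinity_value_nM <= 10000))
  expect_true(all(pl$interactions$affinity_type %in% c("Ki", "Kd", "EC50", "IC50")))
  expect_true(all(nchar(pl$proteins$sequence) > 80))
  ## zero noise: proteins of one community have identical cluster profiles
  mem <- data.frame(member_id = names(lib$labels),
                    cluster_id = as.character(lib$labels),
                    exemplar_id = NA_character_, stringsAsFactors = FALSE)
  for (cid in unique(mem$cluster_id))
    mem$exemplar_id[mem$cluster_id == cid] <- mem$member_id[mem$cluster_id == cid][1]
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  prof <- annotateProteins(pl$interactions, cl)
  B <- bits(prof)
  comm <- pl$communities[rownames(B)]
  for (cc in unique(comm)) {
    rows <- B[comm == cc, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(x) length(unique(x)) == 1)))
  }
  ## disjoint blocks: cross-community Jaccard is 0, within is 1
  J <- simValues(jaccardSimilarityMatrix(prof))
  same <- outer(comm, comm, "==")
  expect_true(all(J[same] == 1))
  expect_true(all(J[!same] == 0))
  ## distance matrix is a valid input with planted block structure
  s <- sequenceSimilarityMatrix(pl$distances)
  v <- simValues(s)
  ut <- upper.tri(v)
  expect_gt(mean(v[same & ut]), mean(v[!same & ut]))
})

test_that("screen sets satisfy the benchmark geometry and chemotype margins", {
  sets <- quietly(makeScreenSets(synthConfig(n_targets = 2L, seed = 7L)))
  expect_equal(length(sets), 2L)
  for (s in sets) {
    expect_gte(nrow(bits(s$actives)), 30L)
    expect_gte(nrow(bits(s$decoys)), 50L)
    expect_equal(length(intersect(rownames(bits(s$actives)),
                                  rownames(bits(s$decoys)))), 0L)
    ## actives are closer to other actives than to decoys
    aa <- tanimotoMatrix(s$actives)
    ad <- tanimotoMatrix(s$actives, s$decoys)
    expect_gt(mean(aa[upper.tri(aa)]), mean(ad))
  }
  ## determinism
  sets2 <- quietly(makeScreenSets(synthConfig(n_targets = 2L, seed = 7L)))
  expect_identical(bits(sets2[[1]]$actives), bits(sets[[1]]$actives))
})

test_that("written synthetic data round-trips through the package readers", {
  cfg <- synthConfig(n_clusters = 3L, ligands_per_cluster = 4L,
                     n_proteins = 8L, n_communities = 2L,
                     n_targets = 1L, actives_per_scaffold = 11L,
                     n_decoys = 50L, seed = 3L)
  lib <- quietly(makeLigandLibrary(cfg))
  pl <- makeInteractionTable(cfg, lib)
  screens <- quietly(makeScreenSets(cfg))
  dir <- tempfile("synth")
  writeSyntheticData(dir, lib, pl, screens)
  smi <- readSmiFile(file.path(dir, "ligands.smi"))
  expect_equal(unname(smi), lib$molecules$smiles)
  ints <- readInteractions(file.path(dir, "interactions.tsv"))
  expect_equal(nrow(ints), nrow(pl$interactions))
  prot <- readFastaProteins(file.path(dir, "proteins.fasta"))
  expect_equal(prot$sequence, pl$proteins$sequence)
  d <- readDistanceMatrix(file.path(dir, "distances.tsv"))
  expect_equal(d, pl$distances, tolerance = 1e-12)
  fam <- utils::read.delim(file.path(dir, "families.tsv"))
  expect_equal(nrow(fam), cfg$n_proteins)
  act <- readSmiFile(file.path(dir, "screen", "T01", "actives.smi"))
  expect_gte(length(act), 30L)
  ## the whole directory parses back through the pipeline entry point
  res <- quietly(runPipeline(file.path(dir, "ligands.smi"),
                             file.path(dir, "interactions.tsv"),
                             file.path(dir, "proteins.fasta"),
                             file.path(dir, "distances.tsv"),
                             outDir = tempfile()))
  expect_gte(nClusters(res$clusters), 3L)
})
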