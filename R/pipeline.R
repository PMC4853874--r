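## End-to-end orchestration: ligands -> fingerprints -> clusters ->
## protein profiles -> LCBN/SBN networks -> communities -> NMI report ->
## knowledge base, with a run manifest for reproducibility.

#' Pipeline default parameters
#'
#' All method constants in one place: fingerprint length and depth, the
#' ligand-pair similarity threshold and AP preference, the network
#' display threshold, the three interaction filter cutoffs, the
#' screening-benchmark geometry and the query depth.
#'
#' @return named list of defaults.
#' @export
lcbnDefaults <- function() {
  list(
    fingerprint_bits = 2048L,      # fingerprint length
    fingerprint_depth = 7L,        # maximum path length (bonds)
    ligand_edge_threshold = 0.5,   # ligand pairs kept for clustering
    ap_preference = 0,             # shared AP preference
    ap_damping = 0.5,
    ap_maxit = 1000L,
    ap_convits = 50L,
    network_threshold = 0.25,      # protein network display threshold
    max_affinity_nM = 10000,       # 10 uM, inclusive
    max_mw_Da = 800,               # exclusive
    min_seq_len = 80L,             # exclusive
    knn_k = 3L,
    train_fraction = 0.2,
    benchmark_repeats = 50L,
    query_top_k = 10L
  )
}

#' Run the full analysis pipeline
#'
#' Stages: parse and fingerprint ligands, cluster them by thresholded
#' Tanimoto similarity with affinity propagation, filter the interaction
#' table, annotate proteins as cluster profiles, build the
#' ligand-cluster-based and (when a distance matrix is given)
#' sequence-based similarity matrices and threshold networks, detect AP
#' communities in both, compare all partitions (and family labels) by
#' NMI, and assemble the exemplar knowledge base. Artifacts and a run
#' manifest are written to \code{outDir}.
#'
#' @param ligands named character vector of SMILES, or path to a .smi
#'   file.
#' @param interactions data.frame or path to an interaction TSV.
#' @param proteins data.frame (protein_id, sequence, optional family) or
#'   path to a FASTA file.
#' @param distances optional square distance matrix (or path) for the
#'   sequence-based side.
#' @param families optional named character vector protein_id -> family
#'   label (overrides a family column in \code{proteins}).
#' @param outDir output directory; created if needed.
#' @param params list of parameters, see \code{\link{lcbnDefaults}};
#'   entries given here override the defaults.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return (invisibly) list with clusters, profiles, similarity matrices,
#'   networks, partitions, the NMI report, the knowledge base and the
#'   manifest.
#' @export
runPipeline <- function(ligands, interactions, proteins, distances = NULL,
                        families = NULL, outDir = tempfile("lcbn_run"),
                        params = list(), seed = 1L) {
  p <- utils::modifyList(lcbnDefaults(), params)
  .checkParams(p)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()
  if (is.character(ligands) && length(ligands) == 1 && file.exists(ligands)) {
    inputs$ligands <- unname(tools::md5sum(ligands))
    ligands <- readSmiFile(ligands)
  }
  if (is.character(interactions)) {
    inputs$interactions <- unname(tools::md5sum(interactions))
    interactions <- readInteractions(interactions)
  }
  if (is.character(proteins)) {
    inputs$proteins <- unname(tools::md5sum(proteins))
    proteins <- readFastaProteins(proteins)
  }
  if (is.character(distances)) {
    inputs$distances <- unname(tools::md5sum(distances))
    distances <- readDistanceMatrix(distances)
  }
  if (is.null(families) && "family" %in% names(proteins))
    families <- stats::setNames(proteins$family, proteins$protein_id)

  mols <- parseMolecules(unname(ligands), names(ligands), onError = "drop")
  fps <- fingerprintMolecules(mols, nbits = p$fingerprint_bits,
                              depth = p$fingerprint_depth)
  clusters <- clusterLigands(
    fps, molWeights = stats::setNames(mols$mol_weight, mols$ligand_id),
    threshold = p$ligand_edge_threshold, preference = p$ap_preference,
    damping = p$ap_damping, maxit = p$ap_maxit, convits = p$ap_convits)
  writeClustersTSV(clusters, file.path(outDir, "clusters.tsv"))
  writeClustersJSON(clusters, file.path(outDir, "clusters.json"))

  filt <- filterInteractions(interactions, mols, proteins,
                             max_affinity_nM = p$max_affinity_nM,
                             max_mw_Da = p$max_mw_Da,
                             min_seq_len = p$min_seq_len)
  profiles <- annotateProteins(filt$records, clusters)
  writeProfilesTSV(profiles, file.path(outDir, "profiles.tsv"))

  lcSim <- jaccardSimilarityMatrix(profiles)
  lcbnNet <- buildNetwork(lcSim, threshold = p$network_threshold,
                          families = families)
  writeGraphML(lcbnNet, file.path(outDir, "lcbn.graphml"))
  writeSIF(lcbnNet, file.path(outDir, "lcbn.sif"))
  partitions <- list(lcbn_ap = communitiesAP(lcSim, preference = p$ap_preference))
  writePartitionTSV(partitions$lcbn_ap, file.path(outDir, "lcbn_ap.tsv"))

  sqSim <- NULL; sbnNet <- NULL
  if (!is.null(distances)) {
    common <- intersect(rownames(simValues(lcSim)), rownames(distances))
    sqSim <- sequenceSimilarityMatrix(distances[common, common, drop = FALSE])
    sbnNet <- buildNetwork(sqSim, threshold = p$network_threshold,
                           families = families)
    writeGraphML(sbnNet, file.path(outDir, "sbn.graphml"))
    writeSIF(sbnNet, file.path(outDir, "sbn.sif"))
    partitions$sbn_ap <- communitiesAP(sqSim, preference = p$ap_preference)
    writePartitionTSV(partitions$sbn_ap, file.path(outDir, "sbn_ap.tsv"))
  }
  if (!is.null(families))
    partitions$family <- new("Partition",
                             labels = families[!is.na(families)],
                             method = "family")
  nmiReport <- nmiReportTable(partitions)
  utils::write.table(nmiReport, file.path(outDir, "nmi_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  kb <- buildKnowledgeBase(clusters, fps, filt$records)
  writeKnowledgeBase(kb, file.path(outDir, "kb"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("lcbn")),
    fingerprint = list(family = "hashed-linear-path",
                       nbits = p$fingerprint_bits, depth = p$fingerprint_depth),
    thresholds = p[c("ligand_edge_threshold", "network_threshold",
                     "max_affinity_nM", "max_mw_Da", "min_seq_len")],
    ap = p[c("ap_preference", "ap_damping", "ap_maxit", "ap_convits")],
    nmi_normalizer = "mean",
    seed = seed,
    inputs = inputs,
    filter_report = as.list(filt$report),
    n_ligands = nrow(mols), n_clusters = nClusters(clusters),
    n_proteins = nrow(bits(profiles)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(molecules = mols, fps = fps, clusters = clusters,
                 filtered = filt, profiles = profiles,
                 lcbn_sim = lcSim, sbn_sim = sqSim,
                 lcbn_net = lcbnNet, sbn_net = sbnNet,
                 partitions = partitions, nmi_report = nmiReport,
                 kb = kb, manifest = manifest, out_dir = outDir))
}

.checkParams <- function(p) {
  chk <- function(cond, msg) if (!cond) stopLcbn("configError", msg)
  chk(p$ligand_edge_threshold >= 0 && p$ligand_edge_threshold <= 1,
      "ligand_edge_threshold must be in [0, 1]")
  chk(p$network_threshold >= 0 && p$network_threshold <= 1,
      "network_threshold must be in [0, 1]")
  chk(p$fingerprint_bits >= 8, "fingerprint_bits must be at least 8")
  chk(p$fingerprint_depth >= 0, "fingerprint_depth must be non-negative")
  chk(p$train_fraction > 0 && p$train_fraction < 1,
      "train_fraction must be in (0, 1)")
  chk(p$max_affinity_nM > 0, "max_affinity_nM must be positive")
  invisible(TRUE)
}

#' Pairwise NMI table over a set of partitions
#'
#' @param partitions named list of Partition objects.
#' @param normalizer passed to \code{\link{nmi}}.
#' @return data.frame with columns a, b, nmi for every unordered pair.
#' @export
nmiReportTable <- function(partitions, normalizer = "mean") {
  nm <- names(partitions)
  rows <- list()
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      v <- suppressWarnings(nmi(partitions[[i]], partitions[[j]],
                                normalizer = normalizer))
      rows[[length(rows) + 1L]] <- data.frame(a = nm[i], b = nm[j], nmi = v)
    }
  }
  if (length(rows) == 0)
    return(data.frame(a = character(0), b = character(0), nmi = numeric(0)))
  do.call(rbind, rows)
}
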