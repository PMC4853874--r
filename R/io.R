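## Readers and writers for the pipeline's file dialects: .smi ligand
## files, interaction TSVs, protein FASTA, square or PHYLIP-style
## distance matrices, cluster/profile/partition tables and the
## knowledge-base directory.

#' Read a .smi file ("SMILES<whitespace>ID" per line)
#' @param path file path.
#' @return named character vector of SMILES (names are ligand ids).
#' @export
readSmiFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))
  if (anyNA(ids)) stop("every .smi line needs 'SMILES<whitespace>ID'")
  stats::setNames(smi, ids)
}

#' Write a .smi file
#' @param smiles named character vector (names = ligand ids).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSmiFile <- function(smiles, path) {
  stopifnot(!is.null(names(smiles)))
  writeLines(paste(smiles, names(smiles), sep = "\t"), path)
  invisible(path)
}

#' Read a protein-ligand interaction TSV
#'
#' Expects at least ligand_id, protein_id, affinity_type and
#' affinity_value_nM columns; optional smiles and mol_weight columns are
#' carried through.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readInteractions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "protein_id", "affinity_type", "affinity_value_nM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("interaction table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return data.frame with protein_id and sequence.
#' @export
readFastaProteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  data.frame(protein_id = sub("\\s.*$", "", names(aa)),
             sequence = as.character(aa), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write protein sequences as FASTA
#' @param proteins data.frame with protein_id and sequence.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaProteins <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a pairwise distance matrix
#'
#' Accepts either a square TSV with ids in the header row and first
#' column, or PHYLIP-style (first line the count, then one id plus
#' values per line).
#'
#' @param path file path.
#' @return square numeric matrix with id dimnames.
#' @export
readDistanceMatrix <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {
    n <- as.integer(trimws(first))
    lines <- readLines(path)[-1]
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[`, character(1), 1)
    d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(d) <- list(ids, ids)
  } else {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    d <- as.matrix(df)
    if (nrow(d) != ncol(d)) stop("distance matrix must be square")
    colnames(d) <- rownames(d)
  }
  d
}

#' Write a distance matrix as square TSV
#' @param d square matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  utils::write.table(cbind(id = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ligand clusters as TSV (one member per row)
#' @param clusters a LigandClusterSet.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClustersTSV <- function(clusters, path) {
  m <- membership(clusters)
  utils::write.table(m[, c("cluster_id", "exemplar_id", "member_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ligand clusters from TSV
#' @param path file written by \code{\link{writeClustersTSV}}.
#' @return a LigandClusterSet (without molecular weights).
#' @export
readClustersTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$cluster_id <- as.character(df$cluster_id)
  new("LigandClusterSet",
      membership = df[, c("member_id", "cluster_id", "exemplar_id")],
      amw = numeric(0))
}

#' Write ligand clusters as JSON (with average molecular weight)
#' @param clusters a LigandClusterSet.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClustersJSON <- function(clusters, path) {
  m <- membership(clusters)
  amw <- clusterAMW(clusters)
  obj <- lapply(split(m, m$cluster_id), function(g) {
    cid <- as.character(g$cluster_id[1])
    list(cluster_id = cid, exemplar_id = g$exemplar_id[1],
         members = g$member_id,
         amw = if (cid %in% names(amw)) amw[[cid]] else NULL)
  })
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cluster profiles as sparse TSV (protein_id, cluster_id)
#' @param profiles a ClusterProfileSet.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfilesTSV <- function(profiles, path) {
  B <- bits(profiles)
  idx <- which(B == 1L, arr.ind = TRUE)
  df <- data.frame(protein_id = rownames(B)[idx[, 1]],
                   cluster_id = colnames(B)[idx[, 2]])
  df <- df[order(df$protein_id, df$cluster_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a partition as TSV (node_id, method, label)
#' @param partition a Partition.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePartitionTSV <- function(partition, path) {
  l <- partitionLabels(partition)
  utils::write.table(
    data.frame(node_id = names(l), method = partition@method, label = unname(l)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column annotation TSV
#' @param path file with a header and two columns (entity id, annotation
#'   id).
#' @param idCol,annCol column names to standardise to.
#' @return data.frame with the two requested columns.
#' @export
readAnnotationTSV <- function(path, idCol = "protein_id",
                              annCol = "annotation_id") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2)
  out <- df[, 1:2]
  names(out) <- c(idCol, annCol)
  out
}

#' Serialise a knowledge base to a directory of TSVs
#'
#' Writes clusters.tsv, exemplar fingerprints as hex, cluster targets,
#' any annotation tables, and a manifest JSON recording the fingerprint
#' parameters.
#'
#' @param kb a KnowledgeBase.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeClustersTSV(kb@clusters, file.path(dir, "clusters.tsv"))
  hex <- fingerprintToHex(kb@exemplarFps)
  utils::write.table(data.frame(cluster_id = names(hex), fingerprint = unname(hex)),
                     file.path(dir, "exemplar_fps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg <- data.frame(
    cluster_id = rep(names(kb@clusterTargets), lengths(kb@clusterTargets)),
    protein_id = unlist(kb@clusterTargets, use.names = FALSE))
  utils::write.table(tg, file.path(dir, "cluster_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(kb@annotations))
    utils::write.table(kb@annotations[[nm]],
                       file.path(dir, paste0("annotation_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(nbits = kb@exemplarFps@nbits, depth = kb@exemplarFps@depth,
         family = kb@exemplarFps@family,
         n_clusters = nClusters(kb@clusters),
         annotations = names(kb@annotations)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a knowledge base from a directory
#' @param dir directory written by \code{\link{writeKnowledgeBase}}.
#' @return a KnowledgeBase.
#' @export
readKnowledgeBase <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  clusters <- readClustersTSV(file.path(dir, "clusters.tsv"))
  fpdf <- utils::read.delim(file.path(dir, "exemplar_fps.tsv"),
                            stringsAsFactors = FALSE)
  fps <- hexToFingerprint(stats::setNames(fpdf$fingerprint,
                                          as.character(fpdf$cluster_id)),
                          depth = man$depth, family = man$family)
  tg <- utils::read.delim(file.path(dir, "cluster_targets.tsv"),
                          stringsAsFactors = FALSE)
  targets <- lapply(split(tg$protein_id, as.character(tg$cluster_id)),
                    function(x) sort(unique(x)))
  ann <- list()
  for (nm in c("pathway", "disease", "adr")) {
    f <- file.path(dir, paste0("annotation_", nm, ".tsv"))
    if (file.exists(f)) ann[[nm]] <- utils::read.delim(f, stringsAsFactors = FALSE)
  }
  new("KnowledgeBase", clusters = clusters, exemplarFps = fps,
      clusterTargets = targets, annotations = ann)
}
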