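## Interaction filtering and the ligand-cluster view of protein space.
##
## Proteins are annotated by the ligand clusters they bind (a binary
## profile over all clusters); protein similarity is then the Jaccard
## index of two profiles. A parallel sequence-based similarity is read
## from an externally computed global-distance matrix as 1 - distance.

.AFFINITY_TYPES <- c("Ki", "Kd", "EC50", "IC50")

#' Filter a protein-ligand interaction table
#'
#' Applies the three retention rules: affinity at most
#' \code{max_affinity_nM} (inclusive), ligand molecular weight strictly
#' below \code{max_mw_Da}, and protein sequence length strictly above
#' \code{min_seq_len}. Records with an affinity type other than Ki, Kd,
#' EC50 or IC50, or referencing an unknown ligand or protein, are dropped
#' and counted.
#'
#' @param records data.frame with columns ligand_id, protein_id,
#'   affinity_type, affinity_value_nM.
#' @param ligands data.frame from \code{\link{parseMolecules}} (ligand_id,
#'   mol_weight) or named numeric vector of molecular weights.
#' @param proteins data.frame with columns protein_id, sequence (and
#'   optionally family), or named character vector of sequences.
#' @param max_affinity_nM affinity cutoff in nM, inclusive (default 10000,
#'   i.e. 10 uM).
#' @param max_mw_Da molecular weight cutoff in daltons, exclusive
#'   (default 800).
#' @param min_seq_len sequence length cutoff, exclusive (default 80).
#' @return list with \code{records} (surviving rows) and \code{report}
#'   (named integer vector of counts removed per rule). Raises
#'   \code{emptyResult} if nothing survives.
#' @export
filterInteractions <- function(records, ligands, proteins,
                               max_affinity_nM = 10000, max_mw_Da = 800,
                               min_seq_len = 80) {
  stopifnot(all(c("ligand_id", "protein_id", "affinity_type",
                  "affinity_value_nM") %in% names(records)))
  mw <- if (is.data.frame(ligands))
    stats::setNames(ligands$mol_weight, ligands$ligand_id) else ligands
  seqlen <- if (is.data.frame(proteins))
    stats::setNames(nchar(proteins$sequence), proteins$protein_id)
  else nchar(proteins)
  n0 <- nrow(records)
  report <- c(bad_affinity_type = 0L, unresolved_id = 0L,
              affinity_rule = 0L, mol_weight_rule = 0L, seq_length_rule = 0L)

  ok_type <- records$affinity_type %in% .AFFINITY_TYPES
  report["bad_affinity_type"] <- sum(!ok_type)
  records <- records[ok_type, , drop = FALSE]

  resolved <- records$ligand_id %in% names(mw) &
    records$protein_id %in% names(seqlen)
  report["unresolved_id"] <- sum(!resolved)
  records <- records[resolved, , drop = FALSE]

  keep_aff <- records$affinity_value_nM <= max_affinity_nM
  report["affinity_rule"] <- sum(!keep_aff)
  records <- records[keep_aff, , drop = FALSE]

  keep_mw <- mw[records$ligand_id] < max_mw_Da
  report["mol_weight_rule"] <- sum(!keep_mw)
  records <- records[keep_mw, , drop = FALSE]

  keep_len <- seqlen[records$protein_id] > min_seq_len
  report["seq_length_rule"] <- sum(!keep_len)
  records <- records[keep_len, , drop = FALSE]

  if (nrow(records) == 0)
    stopLcbn("emptyResult",
             sprintf("no interaction of %d survived the filters", n0))
  rownames(records) <- NULL
  list(records = records, report = report)
}

#' Annotate proteins as bit vectors over ligand clusters
#'
#' Bit i of a protein's profile is set iff the protein has at least one
#' retained interaction with a ligand belonging to cluster i.
#'
#' @param records filtered interaction data.frame (ligand_id, protein_id).
#' @param clusters a LigandClusterSet covering every ligand in
#'   \code{records}; a record whose ligand is unclustered raises
#'   \code{unclusteredLigand}.
#' @return a \code{\link{ClusterProfileSet}} with one row per protein.
#' @export
annotateProteins <- function(records, clusters) {
  m <- membership(clusters)
  cl <- stats::setNames(m$cluster_id, m$member_id)
  miss <- setdiff(unique(records$ligand_id), names(cl))
  if (length(miss))
    stopLcbn("unclusteredLigand",
             sprintf("%d ligand(s) in the interaction table belong to no cluster: %s",
                     length(miss), paste(utils::head(miss, 5), collapse = ", ")))
  prot <- sort(unique(records$protein_id))
  cids <- sort(unique(m$cluster_id))
  b <- matrix(0L, length(prot), length(cids),
              dimnames = list(prot, as.character(cids)))
  b[cbind(records$protein_id, as.character(cl[records$ligand_id]))] <- 1L
  new("ClusterProfileSet", bits = b)
}

#' Jaccard similarity matrix over protein cluster profiles
#'
#' Entry (p, q) is |profile_p AND profile_q| / |profile_p OR profile_q|.
#' Profiles are never all-zero (class invariant), so the ratio is always
#' defined.
#'
#' @param profiles a ClusterProfileSet with at least 2 proteins.
#' @return a \code{\link{SimilarityMatrix}} of kind "ligand_cluster".
#' @export
jaccardSimilarityMatrix <- function(profiles) {
  B <- bits(profiles)
  stopifnot(nrow(B) >= 2)
  storage.mode(B) <- "double"
  inter <- B %*% t(B)
  uni <- outer(rowSums(B), rowSums(B), "+") - inter
  stopifnot(all(uni > 0))
  v <- inter / uni
  new("SimilarityMatrix", values = v, kind = "ligand_cluster")
}

#' Sequence similarity from a global-distance matrix
#'
#' Converts an externally computed global sequence distance (e.g. from a
#' progressive multiple aligner) to similarity as 1 - distance.
#'
#' @param distances square numeric matrix of pairwise distances in [0, 1],
#'   symmetric with zero diagonal.
#' @param ids optional protein ids; defaults to the matrix dimnames.
#' @return a \code{\link{SimilarityMatrix}} of kind "sequence". Raises
#'   \code{matrixMalformed} on asymmetry beyond 1e-9 or out-of-range
#'   values.
#' @export
sequenceSimilarityMatrix <- function(distances, ids = rownames(distances)) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d))
    stopLcbn("matrixMalformed", "distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-9)
    stopLcbn("matrixMalformed", "distance matrix is not symmetric")
  if (any(d < 0 | d > 1))
    stopLcbn("matrixMalformed", "distances must lie in [0, 1]")
  if (any(abs(diag(d)) > 1e-9))
    stopLcbn("matrixMalformed", "distance diagonal must be zero")
  if (is.null(ids)) stop("protein ids required (dimnames or ids=)")
  v <- 1 - d
  diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  new("SimilarityMatrix", values = v, kind = "sequence")
}

#' Promiscuity statistics of ligands, clusters and proteins
#'
#' Counts, from the retained interactions: the number of distinct targets
#' per ligand and per ligand cluster (the union over member ligands), the
#' number of distinct ligands and clusters per protein, the per-cluster
#' average molecular weight, and -- when family labels are supplied -- the
#' number of non-redundant clusters bound by each protein family.
#'
#' @param records filtered interaction data.frame.
#' @param clusters a LigandClusterSet.
#' @param profiles a ClusterProfileSet (from \code{\link{annotateProteins}}).
#' @param families optional named character vector protein_id -> family.
#' @return list of data.frames: \code{ligand} (ligand_id, n_targets),
#'   \code{cluster} (cluster_id, size, n_targets, amw), \code{protein}
#'   (protein_id, n_ligands, n_clusters), and \code{family} (family,
#'   n_clusters) when labels were given.
#' @export
promiscuityStats <- function(records, clusters, profiles, families = NULL) {
  m <- membership(clusters)
  cl <- stats::setNames(m$cluster_id, m$member_id)
  lig <- tapply(records$protein_id, records$ligand_id,
                function(p) length(unique(p)))
  ligand_df <- data.frame(ligand_id = names(lig), n_targets = as.integer(lig),
                          stringsAsFactors = FALSE)
  rec_cl <- as.character(cl[records$ligand_id])
  clt <- tapply(records$protein_id, rec_cl, function(p) length(unique(p)))
  sizes <- clusterSizes(clusters)
  amw <- clusterAMW(clusters)
  cid <- names(sizes)
  cluster_df <- data.frame(
    cluster_id = cid, size = as.integer(sizes[cid]),
    n_targets = as.integer(ifelse(cid %in% names(clt), clt[cid], 0L)),
    amw = if (length(amw)) as.numeric(amw[cid]) else NA_real_,
    stringsAsFactors = FALSE)
  B <- bits(profiles)
  nl <- tapply(records$ligand_id, records$protein_id,
               function(x) length(unique(x)))
  protein_df <- data.frame(
    protein_id = rownames(B),
    n_ligands = as.integer(nl[rownames(B)]),
    n_clusters = as.integer(rowSums(B)), stringsAsFactors = FALSE)
  out <- list(ligand = ligand_df, cluster = cluster_df, protein = protein_df)
  if (!is.null(families)) {
    fam <- families[rownames(B)]
    known <- !is.na(fam)
    nfc <- tapply(seq_len(nrow(B))[known], fam[known], function(i) {
      sum(colSums(B[i, , drop = FALSE]) > 0)
    })
    out$family <- data.frame(family = names(nfc), n_clusters = as.integer(nfc),
                             stringsAsFactors = FALSE)
  }
  out
}
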