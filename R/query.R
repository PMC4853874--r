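## The query layer: match a molecule against cluster exemplars only and
## read its likely target range off the top-ranked clusters; conditional
## include/exclude search over protein and pathway annotations; and the
## retrospective evaluation protocol for new interactions.

#' Build an exemplar knowledge base
#'
#' Couples a ligand clustering with the proteins each cluster binds
#' (union over member ligands with retained interactions) and optional
#' annotation tables. Clusters without any target are dropped from the
#' target map but keep their exemplar fingerprint for similarity search.
#'
#' @param clusters a LigandClusterSet.
#' @param fps FingerprintSet covering the exemplar ligands.
#' @param records filtered interaction data.frame (ligand_id, protein_id).
#' @param pathway,disease optional data.frames (protein_id, annotation_id).
#' @param adr optional data.frame (cluster_id, annotation_id) of adverse
#'   reactions.
#' @return a \code{\link{KnowledgeBase}}.
#' @export
buildKnowledgeBase <- function(clusters, fps, records,
                               pathway = NULL, disease = NULL, adr = NULL) {
  m <- membership(clusters)
  cl <- stats::setNames(as.character(m$cluster_id), m$member_id)
  rec <- records[records$ligand_id %in% names(cl), , drop = FALSE]
  targets <- split(rec$protein_id, cl[rec$ligand_id])
  targets <- lapply(targets, function(x) sort(unique(x)))
  ex <- exemplars(clusters)
  B <- bits(fps)
  miss <- setdiff(unname(ex), rownames(B))
  if (length(miss))
    stop("fingerprints missing for exemplar(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  exB <- B[unname(ex), , drop = FALSE]
  rownames(exB) <- names(ex)
  ann <- list()
  if (!is.null(pathway)) ann$pathway <- pathway
  if (!is.null(disease)) ann$disease <- disease
  if (!is.null(adr)) ann$adr <- adr
  new("KnowledgeBase", clusters = clusters,
      exemplarFps = new("FingerprintSet", bits = exB, nbits = ncol(exB),
                        depth = fps@depth, family = fps@family),
      clusterTargets = targets, annotations = ann)
}

#' Rank knowledge-base clusters by similarity to a query molecule
#'
#' Compares the query fingerprint against cluster exemplars only, ranks
#' clusters by Tanimoto similarity (ties broken by cluster id) and
#' accumulates the protein target union over the top ranks.
#'
#' @param query a SMILES string, a one-row data.frame from
#'   \code{\link{parseMolecule}}, or a fingerprint vector.
#' @param kb a KnowledgeBase.
#' @param k number of clusters to return (default 10; capped at the
#'   number of clusters).
#' @return list with \code{ranking} (data.frame cluster_id, similarity,
#'   non-increasing) and \code{accumulated_targets} (list; element i is
#'   the union of targets of the top-i clusters, non-decreasing under
#'   inclusion).
#' @export
querySimilarClusters <- function(query, kb, k = 10L) {
  stopifnot(is(kb, "KnowledgeBase"))
  qfp <- .queryFingerprint(query, kb)
  exB <- bits(kb@exemplarFps)
  sims <- as.numeric(tanimotoMatrix(matrix(qfp, nrow = 1), exB))
  ord <- order(-sims, rownames(exB))
  k <- min(k, nrow(exB))
  top <- ord[seq_len(k)]
  ranking <- data.frame(cluster_id = rownames(exB)[top],
                        similarity = sims[top], stringsAsFactors = FALSE)
  acc <- vector("list", k)
  cur <- character(0)
  for (i in seq_len(k)) {
    cur <- sort(union(cur, kb@clusterTargets[[ranking$cluster_id[i]]]))
    acc[[i]] <- cur
  }
  list(ranking = ranking, accumulated_targets = acc)
}

.queryFingerprint <- function(query, kb) {
  if (is.character(query) && length(query) == 1) {
    mol <- parseMolecule(query, "query")
    return(as.integer(bits(fingerprintMolecules(mol, nbits = kb@exemplarFps@nbits,
                                                depth = kb@exemplarFps@depth))[1, ]))
  }
  if (is.data.frame(query)) {
    return(as.integer(bits(fingerprintMolecules(query, nbits = kb@exemplarFps@nbits,
                                                depth = kb@exemplarFps@depth))[1, ]))
  }
  as.integer(query)
}

#' Conditional include/exclude search over the knowledge base
#'
#' Returns the clusters whose target set intersects every include term
#' and no exclude term. A protein term is the protein itself; a pathway
#' term is the set of proteins annotated to that pathway (OR within the
#' term). Include terms combine with AND by default ("combination"
#' semantics); set \code{any = TRUE} for OR-of-terms. With no terms at
#' all, every cluster with targets is returned.
#'
#' @param kb a KnowledgeBase.
#' @param includeProteins,excludeProteins character vectors of protein ids.
#' @param includePathways,excludePathways character vectors of pathway ids
#'   (requires a pathway annotation table in the kb).
#' @param any combine include terms with OR instead of AND.
#' @return sorted character vector of cluster ids. Unresolvable ids raise
#'   \code{unknownIdentifier}.
#' @export
conditionalSearch <- function(kb, includeProteins = character(0),
                              excludeProteins = character(0),
                              includePathways = character(0),
                              excludePathways = character(0),
                              any = FALSE) {
  stopifnot(is(kb, "KnowledgeBase"))
  allProt <- sort(unique(unlist(kb@clusterTargets, use.names = FALSE)))
  pw <- kb@annotations$pathway
  pwIds <- if (is.null(pw)) character(0) else unique(pw$annotation_id)
  unknown <- c(setdiff(c(includeProteins, excludeProteins), allProt),
               setdiff(c(includePathways, excludePathways), pwIds))
  if (length(unknown))
    stopLcbn("unknownIdentifier",
             paste("unresolvable identifier(s):", paste(unknown, collapse = ", ")))
  pwSet <- function(id) unique(pw$protein_id[pw$annotation_id == id])
  terms_inc <- c(as.list(includeProteins), lapply(includePathways, pwSet))
  terms_exc <- c(as.list(excludeProteins), lapply(excludePathways, pwSet))
  hits <- vapply(names(kb@clusterTargets), function(cid) {
    tg <- kb@clusterTargets[[cid]]
    inc_ok <- if (length(terms_inc) == 0) TRUE else {
      m <- vapply(terms_inc, function(tt) length(intersect(tg, tt)) > 0, logical(1))
      if (any) base::any(m) else all(m)
    }
    exc_ok <- all(!vapply(terms_exc, function(tt) length(intersect(tg, tt)) > 0,
                          logical(1)))
    inc_ok && exc_ok
  }, logical(1))
  sort(names(kb@clusterTargets)[hits])
}

#' Evaluate target predictions for held-out interactions
#'
#' For each query molecule with a known true target set (disjoint from
#' the knowledge base's source data), ranks clusters by exemplar
#' similarity and checks at every rank whether any true protein appears
#' in the accumulated target range. Hits accumulate monotonically from
#' rank 1 to k.
#'
#' @param newInteractions list of entries, each a list with \code{query}
#'   (SMILES, molecule data.frame, or fingerprint) and \code{proteins}
#'   (character vector of true targets).
#' @param kb a KnowledgeBase.
#' @param k search depth (default 10).
#' @return list with \code{hits_at_rank} (integer vector length k,
#'   non-decreasing: interactions predicted within the top r),
#'   \code{n_interactions}, and \code{similarity_by_rank} (list of the
#'   query-exemplar similarities observed at each rank).
#' @export
evaluatePredictions <- function(newInteractions, kb, k = 10L) {
  k <- min(k, nrow(bits(kb@exemplarFps)))
  hit_rank <- integer(0)
  simsByRank <- vector("list", k)
  for (entry in newInteractions) {
    res <- querySimilarClusters(entry$query, kb, k = k)
    first <- NA_integer_
    for (r in seq_len(k)) {
      simsByRank[[r]] <- c(simsByRank[[r]], res$ranking$similarity[r])
      if (is.na(first) && length(intersect(entry$proteins,
                                           res$accumulated_targets[[r]])) > 0)
        first <- r
    }
    hit_rank <- c(hit_rank, first)
  }
  hits_at_rank <- vapply(seq_len(k), function(r) sum(!is.na(hit_rank) & hit_rank <= r),
                         integer(1))
  list(hits_at_rank = hits_at_rank, n_interactions = length(newInteractions),
       similarity_by_rank = simsByRank)
}
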