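#' Fingerprint bit matrix
#'
#' @param x a FingerprintSet, ClusterProfileSet or SimilarityMatrix.
#' @return for FingerprintSet and ClusterProfileSet the 0/1 integer matrix;
#'   for SimilarityMatrix the numeric similarity matrix.
#' @export
setGeneric("bits", function(x) standardGeneric("bits"))

#' @rdname bits
#' @export
setMethod("bits", "FingerprintSet", function(x) x@bits)

#' @rdname bits
#' @export
setMethod("bits", "ClusterProfileSet", function(x) x@bits)

#' Similarity values of a SimilarityMatrix
#' @param x a SimilarityMatrix.
#' @return the symmetric numeric matrix.
#' @export
simValues <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  x@values
}

#' Kind of a similarity matrix or network
#' @param x a SimilarityMatrix or ProteinNetwork.
#' @return "ligand_cluster"/"sequence" or "LCBN"/"SBN".
#' @export
setGeneric("kind", function(x) standardGeneric("kind"))

#' @rdname kind
#' @export
setMethod("kind", "SimilarityMatrix", function(x) x@kind)

#' @rdname kind
#' @export
setMethod("kind", "ProteinNetwork", function(x) x@kind)

#' Cluster membership table
#' @param x a LigandClusterSet.
#' @return data.frame with columns member_id, cluster_id, exemplar_id.
#' @export
membership <- function(x) {
  stopifnot(is(x, "LigandClusterSet"))
  x@membership
}

#' Cluster exemplars
#' @param x a LigandClusterSet.
#' @return named character vector: cluster id -> exemplar ligand id.
#' @export
exemplars <- function(x) {
  stopifnot(is(x, "LigandClusterSet"))
  m <- unique(x@membership[, c("cluster_id", "exemplar_id")])
  stats::setNames(m$exemplar_id, as.character(m$cluster_id))
}

#' Cluster sizes
#' @param x a LigandClusterSet.
#' @return named integer vector of member counts per cluster.
#' @export
clusterSizes <- function(x) {
  stopifnot(is(x, "LigandClusterSet"))
  tab <- table(x@membership$cluster_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Average molecular weight per cluster
#' @param x a LigandClusterSet.
#' @return named numeric vector (daltons), empty if weights were not given.
#' @export
clusterAMW <- function(x) {
  stopifnot(is(x, "LigandClusterSet"))
  x@amw
}

#' Number of clusters
#' @param x a LigandClusterSet.
#' @return integer count of clusters.
#' @export
nClusters <- function(x) length(unique(membership(x)$cluster_id))

#' Community labels of a Partition
#' @param x a Partition.
#' @return named character vector node id -> label.
#' @export
partitionLabels <- function(x) {
  stopifnot(is(x, "Partition"))
  x@labels
}

#' Underlying igraph of a ProteinNetwork
#' @param x a ProteinNetwork.
#' @return the igraph object with weighted edges.
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "ProteinNetwork"))
  x@graph
}

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d molecules, %d bits (%s, depth %d)\n",
              nrow(object@bits), object@nbits, object@family, object@depth))
})

setMethod("show", "LigandClusterSet", function(object) {
  sz <- clusterSizes(object)
  cat(sprintf("LigandClusterSet: %d ligands in %d clusters (sizes %d..%d)\n",
              nrow(object@membership), length(sz),
              if (length(sz)) min(sz) else 0L, if (length(sz)) max(sz) else 0L))
})

setMethod("show", "ClusterProfileSet", function(object) {
  cat(sprintf("ClusterProfileSet: %d proteins x %d ligand clusters, density %.3f\n",
              nrow(object@bits), ncol(object@bits),
              if (length(object@bits)) mean(object@bits) else 0))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d proteins\n",
              object@kind, nrow(object@values)))
})

setMethod("show", "ProteinNetwork", function(object) {
  g <- object@graph
  cat(sprintf("ProteinNetwork (%s): %d nodes, %d edges, similarity > %.2f\n",
              object@kind, igraph::vcount(g), igraph::ecount(g),
              object@threshold))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition (%s): %d nodes in %d communities\n", object@method,
              length(object@labels), length(unique(object@labels))))
})

setMethod("show", "KnowledgeBase", function(object) {
  cat(sprintf("KnowledgeBase: %d clusters, %d with targets, annotations: %s\n",
              nClusters(object@clusters), length(object@clusterTargets),
              if (length(object@annotations))
                paste(names(object@annotations), collapse = ", ")
              else "none"))
})
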