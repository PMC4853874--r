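#' @import methods
NULL

#' Set of binary molecular fingerprints
#'
#' Holds one hashed linear-path fingerprint per molecule as the rows of a
#' 0/1 integer matrix. Row names are ligand identifiers. The fingerprint
#' family and its parameters (bit length, maximum path depth) are carried
#' along so that downstream outputs can record how similarity was computed.
#'
#' @slot bits integer matrix (molecules x bits) with entries in {0, 1}.
#' @slot nbits fingerprint length in bits.
#' @slot depth maximum path length (number of bonds) encoded.
#' @slot family short string naming the fingerprint family.
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  representation(bits = "matrix", nbits = "integer", depth = "integer",
                 family = "character"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@bits) != object@nbits)
      msg <- c(msg, sprintf("bit matrix has %d columns, expected %d",
                            ncol(object@bits), object@nbits))
    if (is.null(rownames(object@bits)) && nrow(object@bits) > 0)
      msg <- c(msg, "bit matrix must have ligand ids as row names")
    if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
      msg <- c(msg, "fingerprint entries must be 0 or 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' Ligand clustering result
#'
#' A partition of a ligand universe into clusters, each represented by an
#' exemplar chosen by affinity propagation. Singleton ligands that had no
#' similarity edge form their own cluster with themselves as exemplar.
#'
#' @slot membership data.frame with columns member_id, cluster_id,
#'   exemplar_id; one row per ligand.
#' @slot amw named numeric vector of per-cluster average molecular weight
#'   (daltons); may be empty when weights were not supplied.
#' @exportClass LigandClusterSet
setClass("LigandClusterSet",
  representation(membership = "data.frame", amw = "numeric"),
  validity = function(object) {
    m <- object@membership
    msg <- NULL
    need <- c("member_id", "cluster_id", "exemplar_id")
    if (!all(need %in% names(m)))
      return(paste("membership must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(m$member_id))
      msg <- c(msg, "each ligand must belong to exactly one cluster")
    ex <- unique(m[, c("cluster_id", "exemplar_id")])
    if (anyDuplicated(ex$cluster_id))
      msg <- c(msg, "a cluster must have exactly one exemplar")
    bad <- !ex$exemplar_id %in% m$member_id[match(ex$cluster_id, m$cluster_id)]
    ok <- vapply(seq_len(nrow(ex)), function(i) {
      ex$exemplar_id[i] %in% m$member_id[m$cluster_id == ex$cluster_id[i]]
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "every exemplar must be a member of its own cluster")
    if (is.null(msg)) TRUE else msg
  }
)

#' Per-protein ligand-cluster binding profiles
#'
#' A binary matrix with one row per protein and one column per ligand
#' cluster; bit (p, c) is 1 iff protein p has at least one retained
#' interaction with a ligand belonging to cluster c.
#'
#' @slot bits integer matrix (proteins x clusters) with entries in {0, 1}.
#' @exportClass ClusterProfileSet
setClass("ClusterProfileSet",
  representation(bits = "matrix"),
  validity = function(object) {
    b <- object@bits
    msg <- NULL
    if (length(b) && !all(b %in% c(0L, 1L)))
      msg <- c(msg, "profile entries must be 0 or 1")
    if (nrow(b) && (is.null(rownames(b)) || is.null(colnames(b))))
      msg <- c(msg, "profiles need protein row names and cluster column names")
    if (nrow(b) && any(rowSums(b) < 1))
      msg <- c(msg, "every protein profile must have at least one set bit")
    if (is.null(msg)) TRUE else msg
  }
)

#' Symmetric protein-protein similarity matrix
#'
#' @slot values symmetric numeric matrix in [0, 1] with unit diagonal and
#'   protein ids as dimnames.
#' @slot kind either "ligand_cluster" (Jaccard over cluster profiles) or
#'   "sequence" (1 - global sequence distance).
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(values = "matrix", kind = "character"),
  validity = function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    else {
      if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
      if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "values must lie in [0, 1]")
      if (nrow(v) && max(abs(diag(v) - 1)) > 1e-12)
        msg <- c(msg, "diagonal must be 1")
      if (is.null(rownames(v))) msg <- c(msg, "protein ids required as dimnames")
    }
    if (!object@kind %in% c("ligand_cluster", "sequence"))
      msg <- c(msg, "kind must be 'ligand_cluster' or 'sequence'")
    if (is.null(msg)) TRUE else msg
  }
)

#' Weighted undirected protein similarity network
#'
#' @slot graph an igraph object; edge attribute \code{weight} holds the
#'   similarity, node attribute \code{family} an optional family label.
#' @slot threshold the similarity threshold edges had to exceed (0 for an
#'   integrate network that keeps all positive similarities).
#' @slot kind "LCBN" (ligand-cluster-based) or "SBN" (sequence-based).
#' @exportClass ProteinNetwork
setClass("ProteinNetwork",
  representation(graph = "ANY", threshold = "numeric", kind = "character"),
  validity = function(object) {
    if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
    msg <- NULL
    g <- object@graph
    if (igraph::is_directed(g)) msg <- c(msg, "network must be undirected")
    if (igraph::ecount(g) > 0) {
      w <- igraph::E(g)$weight
      if (is.null(w)) msg <- c(msg, "edges must carry a weight attribute")
      else if (any(w <= object@threshold))
        msg <- c(msg, "all edge weights must exceed the threshold")
    }
    if (igraph::any_loop(g)) msg <- c(msg, "self-loops are not allowed")
    if (igraph::any_multiple(g)) msg <- c(msg, "parallel edges are not allowed")
    if (is.null(msg)) TRUE else msg
  }
)

#' A partition of network nodes into communities
#'
#' @slot labels named vector mapping node id to community label.
#' @slot method the community-detection method that produced it.
#' @exportClass Partition
setClass("Partition",
  representation(labels = "character", method = "character"),
  validity = function(object) {
    if (length(object@labels) && is.null(names(object@labels)))
      return("labels must be named by node id")
    if (anyDuplicated(names(object@labels)))
      return("each node must carry exactly one label")
    TRUE
  }
)

#' Exemplar knowledge base for multi-target ligand queries
#'
#' Couples the ligand clustering with the proteins each cluster binds and
#' optional annotation maps, so that a query molecule can be matched
#' against cluster exemplars only and its likely target range read off the
#' top-ranked clusters.
#'
#' @slot clusters a LigandClusterSet.
#' @slot exemplarFps FingerprintSet of the cluster exemplars; row names are
#'   cluster ids.
#' @slot clusterTargets named list mapping cluster id to the character
#'   vector of protein ids bound by any member of the cluster.
#' @slot annotations list with optional elements \code{pathway} and
#'   \code{disease} (data.frames protein_id, annotation_id) and \code{adr}
#'   (data.frame cluster_id, annotation_id).
#' @exportClass KnowledgeBase
setClass("KnowledgeBase",
  representation(clusters = "LigandClusterSet", exemplarFps = "FingerprintSet",
                 clusterTargets = "list", annotations = "list"),
  validity = function(object) {
    cid <- as.character(unique(object@clusters@membership$cluster_id))
    msg <- NULL
    if (!all(names(object@clusterTargets) %in% cid))
      msg <- c(msg, "clusterTargets refers to unknown cluster ids")
    if (!all(rownames(object@exemplarFps@bits) %in% cid))
      msg <- c(msg, "exemplar fingerprints refer to unknown cluster ids")
    if (is.null(msg)) TRUE else msg
  }
)
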