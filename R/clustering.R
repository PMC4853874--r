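## Affinity propagation over a thresholded Tanimoto similarity graph.
##
## Ligand pairs below the similarity threshold are not stored; clustering
## runs independently per connected component of the retained edges, with
## missing within-component similarities imputed as a large negative
## value (ligands that are not similar must not co-elect an exemplar).

#' Thresholded all-pairs similarity edge list
#'
#' Computes Tanimoto similarity for every pair of fingerprints and keeps
#' the pairs strictly above \code{threshold}. Items with no retained edge
#' stay in the universe and later become singleton clusters.
#'
#' @param fps a FingerprintSet.
#' @param threshold minimum (exclusive) similarity for an edge; default 0.5.
#' @return list with \code{entries} (data.frame id_a, id_b, similarity,
#'   each unordered pair once, no self-edges) and \code{universe}
#'   (character vector of all ids).
#' @export
buildSimilarityEdges <- function(fps, threshold = 0.5) {
  ids <- rownames(bits(fps))
  stopifnot(length(ids) >= 1)
  S <- tanimotoMatrix(fps)
  keep <- which(upper.tri(S) & S > threshold, arr.ind = TRUE)
  entries <- data.frame(
    id_a = ids[keep[, 1]], id_b = ids[keep[, 2]],
    similarity = S[keep], stringsAsFactors = FALSE)
  list(entries = entries, universe = ids, threshold = threshold)
}

#' Affinity propagation on a dense similarity matrix
#'
#' Frey-Dueck message passing: responsibilities and availabilities are
#' updated with damping until the exemplar set is stable. The shared
#' preference (self-similarity) controls how many exemplars emerge; the
#' input order breaks ties, so callers sort items by id for determinism.
#'
#' @param S square similarity matrix with dimnames; the diagonal is
#'   overwritten with \code{preference}.
#' @param preference shared preference value (default 0).
#' @param damping message damping factor in [0.5, 1) (default 0.5).
#' @param maxit maximum number of iterations (default 1000).
#' @param convits stop once the exemplar set is unchanged for this many
#'   iterations (default 50).
#' @return list with \code{exemplars} (character), \code{labels} (named
#'   character: item id -> exemplar id), \code{iterations}, and
#'   \code{converged}. A \code{convergenceWarning} is signalled when
#'   \code{maxit} is hit; the last state is still returned.
#' @export
affinityPropagation <- function(S, preference = 0, damping = 0.5,
                                maxit = 1000L, convits = 50L) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  n <- nrow(S)
  ids <- rownames(S)
  if (n == 1)
    return(list(exemplars = ids, labels = stats::setNames(ids, ids),
                iterations = 0L, converged = TRUE))
  diag(S) <- preference
  ## tiny deterministic jitter to break exact message symmetry (the
  ## standard AP implementations add random noise for the same reason);
  ## scaled by the off-diagonal magnitude so an all-zero matrix is exact
  off <- S[row(S) != col(S)]
  off <- off[is.finite(off)]
  eps <- 1e-9 * max(abs(off), 0)
  if (eps > 0) {
    i <- row(S); j <- col(S)
    S <- S + eps * (((i * 73 + j * 151) %% 997) / 997) * (i != j)
  }
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  eOld <- rep(NA, n); stable <- 0L; it <- 0L
  while (it < maxit) {
    it <- it + 1L
    ## responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    AS <- A + S
    m1idx <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), m1idx)]
    AS2 <- AS; AS2[cbind(seq_len(n), m1idx)] <- -Inf
    m2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rmax <- matrix(m1, n, n)
    Rmax[cbind(seq_len(n), m1idx)] <- m2
    R <- damping * R + (1 - damping) * (S - Rmax)
    ## availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(matrix(cs, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- cs - diag(Rp)
    A <- damping * A + (1 - damping) * Anew
    e <- (diag(A) + diag(R)) > 0
    if (identical(e, eOld)) stable <- stable + 1L else stable <- 0L
    eOld <- e
    if (stable >= convits && any(e)) break
  }
  converged <- stable >= convits
  if (!converged)
    lcbnWarning("convergenceWarning",
                sprintf("affinity propagation did not converge in %d iterations", maxit))
  ex <- which(eOld)
  if (length(ex) == 0) ex <- seq_len(n)  # no positive evidence: all singletons
  assign_idx <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_idx[ex] <- ex
  list(exemplars = ids[ex],
       labels = stats::setNames(ids[assign_idx], ids),
       iterations = it, converged = converged)
}

#' Cluster ligands by fingerprint similarity with affinity propagation
#'
#' Runs AP independently on every connected component of the thresholded
#' similarity graph; ligands without any edge become singleton clusters
#' whose exemplar is themselves. Ligands are sorted by id beforehand so
#' the result is deterministic.
#'
#' @param fps a FingerprintSet, or an edge list from
#'   \code{\link{buildSimilarityEdges}}.
#' @param molWeights optional named numeric vector of molecular weights
#'   used to compute per-cluster average molecular weight.
#' @param threshold similarity threshold for edges (default 0.5; ignored
#'   when an edge list is passed).
#' @param preference shared AP preference (default 0).
#' @param ... further arguments to \code{\link{affinityPropagation}}.
#' @return a \code{\link{LigandClusterSet}}.
#' @export
clusterLigands <- function(fps, molWeights = NULL, threshold = 0.5,
                           preference = 0, ...) {
  edges <- if (is(fps, "FingerprintSet")) buildSimilarityEdges(fps, threshold) else fps
  universe <- sort(edges$universe)
  ent <- edges$entries
  g <- igraph::graph_from_data_frame(
    ent[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = universe))
  igraph::E(g)$similarity <- ent$similarity
  comp <- igraph::components(g)
  labels <- character(0)
  for (ci in seq_len(comp$no)) {
    mem <- sort(names(comp$membership)[comp$membership == ci])
    if (length(mem) == 1) {
      labels[mem] <- mem
      next
    }
    S <- matrix(-1e6, length(mem), length(mem), dimnames = list(mem, mem))
    sub <- ent[ent$id_a %in% mem & ent$id_b %in% mem, , drop = FALSE]
    S[cbind(sub$id_a, sub$id_b)] <- sub$similarity
    S[cbind(sub$id_b, sub$id_a)] <- sub$similarity
    fit <- affinityPropagation(S, preference = preference, ...)
    labels[mem] <- fit$labels[mem]
  }
  ex_sorted <- sort(unique(labels))
  cluster_id <- match(labels, ex_sorted)
  membership <- data.frame(
    member_id = names(labels), cluster_id = cluster_id,
    exemplar_id = labels, stringsAsFactors = FALSE)
  membership <- membership[order(membership$cluster_id, membership$member_id), ]
  rownames(membership) <- NULL
  amw <- numeric(0)
  if (!is.null(molWeights)) {
    mw <- molWeights[membership$member_id]
    amw <- tapply(mw, membership$cluster_id, mean)
    amw <- stats::setNames(as.numeric(amw), names(amw))
  }
  new("LigandClusterSet", membership = membership, amw = amw)
}

#' Histogram of ligand cluster sizes
#'
#' @param clusters a LigandClusterSet.
#' @return named integer vector: cluster size -> number of clusters of
#'   that size; sums to the number of clusters.
#' @export
clusterSizeHistogram <- function(clusters) {
  sz <- clusterSizes(clusters)
  if (length(sz) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(sz)
  stats::setNames(as.integer(tab), names(tab))
}
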