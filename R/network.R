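## Protein similarity networks, community detection and partition
## comparison by normalized mutual information.

#' Build a protein similarity network
#'
#' Keeps the edges whose similarity is strictly above \code{threshold}
#' (the display threshold of the threshold network; use 0 to keep every
#' positive similarity, i.e. the integrate network). All proteins stay as
#' nodes; proteins without a surviving edge are isolated.
#'
#' @param sim a SimilarityMatrix.
#' @param threshold edge threshold (default 0.25).
#' @param kind network label; defaults to "LCBN" for ligand-cluster
#'   similarity and "SBN" for sequence similarity.
#' @param families optional named character vector protein_id -> family
#'   stored as a node attribute.
#' @return a \code{\link{ProteinNetwork}}.
#' @export
buildNetwork <- function(sim, threshold = 0.25, kind = NULL, families = NULL) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (is.null(kind))
    kind <- if (kind(sim) == "ligand_cluster") "LCBN" else "SBN"
  v <- simValues(sim)
  ids <- rownames(v)
  keep <- which(upper.tri(v) & v > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      weight = v[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(families))
    igraph::V(g)$family <- unname(families[ids])
  new("ProteinNetwork", graph = g, threshold = threshold, kind = kind)
}

#' Connected components of a protein network
#'
#' @param net a ProteinNetwork.
#' @param dropIsolated drop singleton components (isolated proteins) from
#'   the listing; they are retained in the network object itself.
#' @return list of character vectors of node ids, ordered by decreasing
#'   size.
#' @export
networkComponents <- function(net, dropIsolated = FALSE) {
  comp <- igraph::components(networkGraph(net))
  groups <- split(names(comp$membership), comp$membership)
  if (dropIsolated) groups <- groups[lengths(groups) > 1]
  unname(groups[order(-lengths(groups))])
}

#' Community detection by affinity propagation
#'
#' Runs the package's affinity propagation engine on the full protein
#' similarity matrix (nodes sorted by id for determinism) and labels each
#' community by its exemplar protein.
#'
#' @param sim a SimilarityMatrix.
#' @param preference shared AP preference (default 0).
#' @param ... further arguments to \code{\link{affinityPropagation}}.
#' @return a \code{\link{Partition}} with method "AP".
#' @export
communitiesAP <- function(sim, preference = 0, ...) {
  v <- simValues(sim)
  ord <- order(rownames(v))
  v <- v[ord, ord]
  fit <- affinityPropagation(v, preference = preference, ...)
  new("Partition", labels = fit$labels, method = "AP")
}

#' Community detection through an external backend
#'
#' Adapter around third-party community methods run on the thresholded
#' network: "infomap" uses the igraph implementation of the map equation;
#' "mcl" requires an \code{mcl} executable on the PATH (Markov clustering
#' with the given inflation). A missing backend raises a clean
#' \code{backendUnavailable} condition rather than crashing.
#'
#' @param net a ProteinNetwork.
#' @param method "infomap" or "mcl".
#' @param inflation MCL inflation parameter (default 4.0).
#' @return a \code{\link{Partition}}.
#' @export
communitiesExternal <- function(net, method = c("infomap", "mcl"),
                                inflation = 4.0) {
  method <- match.arg(method)
  g <- networkGraph(net)
  if (method == "infomap") {
    if (!"cluster_infomap" %in% getNamespaceExports("igraph"))
      stopLcbn("backendUnavailable", "igraph infomap backend not available")
    cm <- igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight)
    labels <- stats::setNames(as.character(igraph::membership(cm)),
                              igraph::V(g)$name)
    return(new("Partition", labels = labels, method = "infomap"))
  }
  mcl_bin <- Sys.which("mcl")
  if (!nzchar(mcl_bin))
    stopLcbn("backendUnavailable", "mcl executable not found on PATH")
  dir <- tempfile("mcl"); dir.create(dir)
  abc <- file.path(dir, "in.abc"); outf <- file.path(dir, "out.mcl")
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el[, c("from", "to", "weight")], abc, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  status <- system2(mcl_bin, c(abc, "--abc", "-I", format(inflation),
                               "-o", outf), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outf))
    stopLcbn("backendUnavailable", "mcl run failed")
  lines <- readLines(outf)
  labels <- character(0)
  for (i in seq_along(lines)) {
    for (nd in strsplit(lines[i], "\t")[[1]]) labels[nd] <- as.character(i)
  }
  iso <- setdiff(igraph::V(g)$name, names(labels))
  if (length(iso))
    labels[iso] <- paste0("singleton_", iso)
  new("Partition", labels = labels[igraph::V(g)$name], method = "mcl")
}

## entropy (nats) of a count vector
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' I(A;B) over the label contingency table, normalized by the arithmetic
#' mean of the two entropies (default) or by their maximum. Partitions
#' over unequal node sets are compared on the intersection with a
#' warning; disjoint node sets raise \code{emptyOverlap}. Two constant
#' (single-community) partitions have zero entropy; their NMI is defined
#' as 1 if identical in the trivial sense and the comparison of any
#' partition against a constant one yields 0.
#'
#' @param a,b Partition objects (or named label vectors).
#' @param normalizer "mean" or "max".
#' @return NMI in [0, 1].
#' @export
nmi <- function(a, b, normalizer = c("mean", "max")) {
  normalizer <- match.arg(normalizer)
  la <- if (is(a, "Partition")) partitionLabels(a) else a
  lb <- if (is(b, "Partition")) partitionLabels(b) else b
  common <- intersect(names(la), names(lb))
  if (length(common) == 0)
    stopLcbn("emptyOverlap", "partitions share no nodes")
  if (length(common) < length(la) || length(common) < length(lb))
    lcbnWarning("partialOverlap",
                sprintf("comparing partitions on %d shared nodes", length(common)))
  la <- la[common]; lb <- lb[common]
  tab <- table(la, lb)
  n <- sum(tab)
  ha <- .entropy(rowSums(tab)); hb <- .entropy(colSums(tab))
  if (ha == 0 && hb == 0) return(1)  # both constant: identical labellings
  if (ha == 0 || hb == 0) return(0)  # constant vs anything: no information
  pij <- tab / n
  pi_ <- rowSums(tab) / n; pj_ <- colSums(tab) / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  norm <- if (normalizer == "mean") (ha + hb) / 2 else max(ha, hb)
  min(1, max(0, mi / norm))
}

#' Export a protein network as GraphML
#'
#' Writes node attributes (family when present) and edge weights.
#'
#' @param net a ProteinNetwork.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGraphML <- function(net, path) {
  g <- networkGraph(net)
  igraph::V(g)$kind <- net@kind
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a protein network in SIF format
#'
#' One line per edge: \code{source sim target}; isolated nodes are listed
#' alone on their line.
#'
#' @param net a ProteinNetwork.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSIF <- function(net, path) {
  g <- networkGraph(net)
  el <- igraph::as_data_frame(g, what = "edges")
  lines <- sprintf("%s\tsim\t%s", el$from, el$to)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}
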