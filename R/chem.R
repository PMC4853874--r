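## Molecule parsing and hashed linear-path fingerprints.
##
## SMILES handling is delegated to Open Babel (via ChemmineOB/ChemmineR):
## every molecule is canonicalised at parse time, so two SMILES spellings
## of the same structure map to the same atom ordering and therefore the
## same fingerprint. The fingerprint itself is a hashed enumeration of all
## simple linear atom paths up to a configurable depth, folded onto a
## fixed-length bit vector.

.canonicalSmiles <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- sub("\t.*$", "", sub("\n$", "", out))
  trimws(out)
}

#' Parse a single SMILES string into a molecule record
#'
#' Canonicalises the SMILES with Open Babel and computes the molecular
#' weight from the parsed structure when not supplied. An unparseable
#' SMILES raises a \code{parseError} condition carrying the ligand id --
#' invalid structures are rejected, never silently fingerprinted as empty.
#'
#' @param smiles a SMILES string.
#' @param ligand_id identifier used in error messages and downstream tables.
#' @param mol_weight optional molecular weight in daltons; computed from
#'   the structure when \code{NA}.
#' @return one-row data.frame with columns ligand_id, smiles (canonical)
#'   and mol_weight.
#' @examples
#' parseMolecule("CCO", "ethanol")
#' @export
parseMolecule <- function(smiles, ligand_id, mol_weight = NA_real_) {
  parseMolecules(smiles, ligand_id, mol_weight, onError = "stop")
}

#' Parse a vector of SMILES strings
#'
#' Vectorised \code{\link{parseMolecule}}. Duplicate ligand ids with the
#' same canonical structure are merged; duplicates with conflicting
#' structures keep the first occurrence with a warning.
#'
#' @param smiles character vector of SMILES.
#' @param ids character vector of ligand ids (same length).
#' @param mol_weight optional numeric vector of weights (daltons); missing
#'   entries are computed from the structure.
#' @param onError "stop" to raise a \code{parseError} on the first invalid
#'   SMILES, "drop" to discard invalid records with a warning.
#' @return data.frame with columns ligand_id, smiles (canonical),
#'   mol_weight; attribute \code{n_rejected} counts dropped records.
#' @export
parseMolecules <- function(smiles, ids, mol_weight = NULL, onError = c("stop", "drop")) {
  onError <- match.arg(onError)
  stopifnot(length(smiles) == length(ids), all(nzchar(smiles)))
  if (is.null(mol_weight)) mol_weight <- rep(NA_real_, length(smiles))
  canon <- vapply(smiles, .canonicalSmiles, character(1), USE.NAMES = FALSE)
  bad <- !nzchar(canon)
  if (any(bad)) {
    if (onError == "stop")
      stopLcbn("parseError",
               sprintf("invalid SMILES for ligand '%s': %s",
                       ids[which(bad)[1]], smiles[which(bad)[1]]),
               ligand_id = ids[which(bad)[1]])
    lcbnWarning("parseWarning",
                sprintf("dropped %d unparseable SMILES record(s): %s",
                        sum(bad), paste(utils::head(ids[bad], 5), collapse = ", ")))
  }
  df <- data.frame(ligand_id = as.character(ids[!bad]), smiles = canon[!bad],
                   mol_weight = as.numeric(mol_weight[!bad]),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$ligand_id)) {
    split_str <- split(df$smiles, df$ligand_id)
    conflict <- names(split_str)[vapply(split_str, function(s) length(unique(s)) > 1, logical(1))]
    if (length(conflict))
      lcbnWarning("duplicateStructure",
                  sprintf("conflicting structures for duplicated ligand id(s): %s; keeping first",
                          paste(utils::head(conflict, 5), collapse = ", ")))
    df <- df[!duplicated(df$ligand_id), , drop = FALSE]
  }
  need_mw <- is.na(df$mol_weight)
  if (any(need_mw)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(df$smiles[need_mw], df$ligand_id[need_mw])))
    props <- ChemmineR::propOB(sdf)
    df$mol_weight[need_mw] <- props$MW
  }
  rownames(df) <- NULL
  attr(df, "n_rejected") <- sum(bad)
  df
}

## ---- path enumeration ------------------------------------------------

## Enumerate every simple linear path of 1..(depth+1) atoms in the
## molecular graph, as strings "el(b)el(b)el..." over element symbols and
## bond orders, keeping the lexicographically smaller reading direction so
## the feature is independent of traversal order.
.linearPaths <- function(elems, bondFrom, bondTo, bondOrder, depth) {
  n <- length(elems)
  adj <- vector("list", n)
  ord <- vector("list", n)
  for (k in seq_along(bondFrom)) {
    i <- bondFrom[k]; j <- bondTo[k]; o <- bondOrder[k]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  paths <- character(0)
  walk <- function(path, labels) {
    last <- path[length(path)]
    if (length(path) > 1 && path[1] < last) {
      fwd <- paste(labels, collapse = "")
      rev_ <- paste(rev(labels), collapse = "")
      paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    }
    if (length(path) > depth) return()
    nb <- adj[[last]]
    for (m in seq_along(nb)) {
      nxt <- nb[m]
      if (!nxt %in% path)
        walk(c(path, nxt), c(labels, ord[[last]][m], elems[nxt]))
    }
  }
  for (s in seq_len(n)) walk(s, elems[s])
  unique(c(elems, paths))
}

## 32-bit FNV-1a over the path string, in double arithmetic (R has no
## native unsigned 32-bit integers). Cached per unique string because
## molecules from a common scaffold share most of their paths.
.hashCache <- new.env(parent = emptyenv())

.fnv1a32 <- function(s) {
  hit <- .hashCache[[s]]
  if (!is.null(hit)) return(hit)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 65536; hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  .hashCache[[s]] <- h
  h
}

.fingerprintOne <- function(sdf, nbits, depth) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  if (is.null(bb) || nrow(bb) == 0) {
    feats <- unique(elems)
  } else {
    feats <- .linearPaths(elems, as.integer(bb[, 1]), as.integer(bb[, 2]),
                          as.integer(bb[, 3]), depth)
  }
  idx <- vapply(feats, .fnv1a32, numeric(1)) %% nbits + 1
  v <- integer(nbits)
  v[idx] <- 1L
  v
}

#' Hashed linear-path fingerprints for a set of molecules
#'
#' Converts canonical SMILES to connection tables and encodes, for each
#' molecule, the set of all simple linear atom paths up to \code{depth}
#' bonds (element symbols interleaved with bond orders), hashed onto a
#' \code{nbits}-long binary vector. The fingerprint is deterministic and
#' invariant to how the input SMILES was written.
#'
#' @param mols data.frame from \code{\link{parseMolecules}} (columns
#'   ligand_id, smiles), or a named character vector of SMILES.
#' @param nbits fingerprint length in bits (default 2048).
#' @param depth maximum path length in bonds (default 7).
#' @return a \code{\link{FingerprintSet}}.
#' @examples
#' fps <- fingerprintMolecules(c(eth = "CCO", benz = "c1ccccc1"))
#' bits(fps)[, 1:4]
#' @export
fingerprintMolecules <- function(mols, nbits = 2048L, depth = 7L) {
  if (is.character(mols)) {
    stopifnot(!is.null(names(mols)))
    mols <- parseMolecules(mols, names(mols))
  }
  nbits <- as.integer(nbits); depth <- as.integer(depth)
  stopifnot(nbits > 0, depth >= 0)
  if (nrow(mols) == 0) {
    return(new("FingerprintSet",
               bits = matrix(integer(0), 0, nbits,
                             dimnames = list(character(0), NULL)),
               nbits = nbits, depth = depth, family = "hashed-linear-path"))
  }
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(mols$smiles, mols$ligand_id)))
  m <- t(vapply(seq_along(sdfs), function(i) .fingerprintOne(sdfs[[i]], nbits, depth),
                integer(nbits)))
  rownames(m) <- mols$ligand_id
  new("FingerprintSet", bits = m, nbits = nbits, depth = depth,
      family = "hashed-linear-path")
}

## ---- similarity kernels ----------------------------------------------

#' Tanimoto coefficient of two binary fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}. Two all-zero vectors compare as 1
#' (identical objects); zero against non-zero is 0.
#'
#' @param a,b binary vectors of equal length (0/1 numeric or logical).
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)) # 2/4
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  if (length(a) != length(b))
    stopLcbn("lengthMismatch",
             sprintf("fingerprint lengths differ: %d vs %d", length(a), length(b)))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 1 else inter / uni
}

#' All-pairs Tanimoto similarity between fingerprint sets
#'
#' @param x a FingerprintSet (or 0/1 matrix with row names).
#' @param y optional second set; defaults to \code{x}.
#' @return numeric matrix of similarities, rows from \code{x}, columns
#'   from \code{y}.
#' @export
tanimotoMatrix <- function(x, y = NULL) {
  X <- if (is(x, "FingerprintSet")) bits(x) else x
  Y <- if (is.null(y)) X else if (is(y, "FingerprintSet")) bits(y) else y
  if (ncol(X) != ncol(Y))
    stopLcbn("lengthMismatch", "fingerprint sets have different bit lengths")
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  inter <- X %*% t(Y)
  uni <- outer(rowSums(X), rowSums(Y), "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  dimnames(sim) <- list(rownames(X), rownames(Y))
  sim
}

## ---- fingerprint serialisation ---------------------------------------

#' Serialise fingerprints as hex strings
#' @param fps a FingerprintSet.
#' @return named character vector of hex strings (4 bits per character).
#' @export
fingerprintToHex <- function(fps) {
  b <- bits(fps)
  apply(b, 1, function(v) {
    nyb <- matrix(v, nrow = 4)
    paste(sprintf("%x", colSums(nyb * c(8L, 4L, 2L, 1L))), collapse = "")
  })
}

#' Rebuild a FingerprintSet from hex strings
#' @param hex named character vector produced by \code{fingerprintToHex}.
#' @param depth,family metadata to record on the rebuilt set.
#' @return a FingerprintSet.
#' @export
hexToFingerprint <- function(hex, depth = 7L, family = "hashed-linear-path") {
  stopifnot(!is.null(names(hex)))
  depth <- suppressWarnings(as.integer(depth))
  if (length(depth) == 0 || is.na(depth)) depth <- NA_integer_
  nbits <- 4L * nchar(hex[1])
  m <- t(vapply(hex, function(h) {
    nyb <- strtoi(strsplit(h, "")[[1]], 16L)
    as.integer(rbind(nyb %/% 8 %% 2, nyb %/% 4 %% 2, nyb %/% 2 %% 2, nyb %% 2))
  }, integer(nbits)))
  rownames(m) <- names(hex)
  new("FingerprintSet", bits = m, nbits = nbits, depth = depth,
      family = family)
}
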