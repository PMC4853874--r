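## Synthetic fixtures with planted structure: ligand libraries built by
## decorating distinct scaffolds (so the real SMILES/fingerprint stack is
## exercised), interaction tables whose proteins carry planted community
## structure in both their cluster-binding profiles and a companion
## sequence-distance matrix, and DUD-style active/decoy screening sets.

## every scaffold ends at an atom that can take one more substituent
## (appending the decoration chain must stay chemically valid)
.SCAFFOLDS <- c(
  "c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1", "c1ccc2ccccc2c1",
  "C1CCOCC1", "c1ccsc1", "C1CCNC1", "c1ccoc1", "C1CCCCCC1",
  "C1CCCC1", "C1COCCN1", "C1CCSCC1", "C1CNCCN1", "C1CCC1", "C1CCOC1")

.DECORATIONS <- c(
  "CC(=O)NCC", "CCOC(=O)CC", "CNC(=O)CCC", "CCCN(C)CC", "COCCOCC",
  "CCSC(C)CC", "CC(C)OCCC", "CCN(CC)CC", "CSCCNCC", "CCC(=O)NCC",
  "COC(=O)CCC", "CN(C)CCOC", "CCOCCNC", "CC(C)NC(=O)C", "CCCSCCN",
  "COCC(=O)NC")

.TAILS <- c("", "C", "N", "O", "CC", "CO", "CN", "OC", "NC", "CCC",
            "CCO", "CCN", "OCC", "NCC", "CC(C)", "COC")

.HOLDOUT_TAILS <- c("CCCO", "CNCC", "OCCC", "CCCN", "COCC", "NCCO")

.AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## run expr with a private RNG stream; the caller's .Random.seed is
## untouched
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions every planted-structure test
#' runs under: 10 ligand clusters of 10 decorated-scaffold ligands, 30
#' proteins in 5 communities (each community binding a disjoint block of
#' 2 clusters, so one profile bit-flip cannot erase its signal), high
#' within-cluster and low between-cluster fingerprint similarity, a 2%
#' profile bit-flip noise, and 5 screening targets of 36 actives and 60
#' decoys each.
#'
#' @param n_clusters planted ligand clusters.
#' @param ligands_per_cluster members per cluster.
#' @param n_proteins proteins in the interaction table.
#' @param n_communities planted protein communities.
#' @param within_sim target mean within-cluster Tanimoto similarity.
#' @param between_sim target mean between-cluster Tanimoto similarity.
#' @param profile_noise probability of flipping a protein's
#'   cluster-binding bit.
#' @param n_targets,n_active_scaffolds,actives_per_scaffold,n_decoys
#'   screening-set geometry.
#' @param seed master seed; identical configs generate identical data.
#' @return a list of class \code{SynthConfig}.
#' @export
synthConfig <- function(n_clusters = 10L, ligands_per_cluster = 10L,
                        n_proteins = 30L, n_communities = 5L,
                        within_sim = 0.8, between_sim = 0.1,
                        profile_noise = 0.02,
                        n_targets = 5L, n_active_scaffolds = 3L,
                        actives_per_scaffold = 12L, n_decoys = 60L,
                        seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              ligands_per_cluster = as.integer(ligands_per_cluster),
              n_proteins = as.integer(n_proteins),
              n_communities = as.integer(n_communities),
              within_sim = within_sim, between_sim = between_sim,
              profile_noise = profile_noise,
              n_targets = as.integer(n_targets),
              n_active_scaffolds = as.integer(n_active_scaffolds),
              actives_per_scaffold = as.integer(actives_per_scaffold),
              n_decoys = as.integer(n_decoys),
              seed = as.integer(seed))
  stopifnot(cfg$n_clusters >= 1, cfg$ligands_per_cluster >= 1,
            cfg$n_proteins >= 1, cfg$n_communities >= 1,
            cfg$profile_noise >= 0, cfg$profile_noise <= 1,
            cfg$within_sim > cfg$between_sim)
  class(cfg) <- "SynthConfig"
  cfg
}

.makeClusterSmiles <- function(scaffold, decoration, tails) {
  paste0(scaffold, decoration, tails)
}

#' Generate a ligand library with planted cluster structure
#'
#' Each planted cluster is one scaffold carrying a cluster-specific
#' decoration chain; members differ only in a short terminal tail, so
#' within-cluster fingerprint similarity is high while different
#' scaffolds stay dissimilar. The generator measures both means and
#' resamples the decoration assignment (up to \code{retries} times) if
#' the separation margin is not met; raises \code{generationFailed}
#' otherwise.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param retries resampling attempts (default 3).
#' @return list with \code{molecules} (data.frame ligand_id, smiles,
#'   mol_weight), \code{labels} (named integer vector: planted cluster
#'   per ligand), \code{fps} (FingerprintSet), and the measured
#'   \code{within_mean} / \code{between_mean} similarities.
#' @export
makeLigandLibrary <- function(cfg, retries = 3L) {
  stopifnot(inherits(cfg, "SynthConfig"))
  stopifnot(cfg$n_clusters <= length(.SCAFFOLDS))
  .withSeed(cfg$seed, {
    for (attempt in seq_len(retries)) {
      sc <- sample(.SCAFFOLDS, cfg$n_clusters)
      dec <- sample(.DECORATIONS, cfg$n_clusters)
      tailPool <- .TAILS
      while (length(tailPool) < cfg$ligands_per_cluster)
        tailPool <- unique(c(tailPool, as.vector(outer(.TAILS[-1], .TAILS[-1], paste0))))
      smi <- character(0); ids <- character(0); labels <- integer(0)
      for (ci in seq_len(cfg$n_clusters)) {
        tails <- sample(tailPool, cfg$ligands_per_cluster)
        s <- .makeClusterSmiles(sc[ci], dec[ci], tails)
        id <- sprintf("L%02d_%02d", ci, seq_along(s))
        smi <- c(smi, s); ids <- c(ids, id)
        labels <- c(labels, rep(ci, length(s)))
      }
      mols <- parseMolecules(smi, ids)
      names(labels) <- ids
      fps <- fingerprintMolecules(mols)
      S <- tanimotoMatrix(fps)
      same <- outer(labels[rownames(S)], labels[colnames(S)], "==")
      ut <- upper.tri(S)
      within_mean <- mean(S[ut & same])
      between_mean <- if (cfg$n_clusters > 1) mean(S[ut & !same]) else 0
      margin <- 0.5 * (cfg$within_sim - cfg$between_sim)
      if (is.nan(within_mean)) within_mean <- 1  # single-member clusters
      if (within_mean - between_mean >= margin) {
        return(list(molecules = mols, labels = labels, fps = fps,
                    stems = stats::setNames(paste0(sc, dec),
                                            seq_len(cfg$n_clusters)),
                    within_mean = within_mean, between_mean = between_mean))
      }
    }
    stopLcbn("generationFailed",
             sprintf("could not reach similarity margins after %d attempts", retries))
  })
}

#' Generate an interaction table with planted protein communities
#'
#' Proteins are split evenly into communities; community c binds the
#' ligands of a characteristic block of planted clusters -- the clusters
#' are divided into nearly equal contiguous, disjoint blocks, one per
#' community (communities wrap over the clusters when there are fewer
#' clusters than communities). Binding bits are flipped with
#' probability \code{profile_noise} (never leaving a protein without
#' interactions). Affinities are drawn log-uniformly in (3, 10000] nM so
#' every planted record survives the affinity filter. A companion
#' sequence-distance matrix is generated with small within-community and
#' large between-community distances, plus random protein sequences
#' (length 150-400) and a family label equal to the planted community.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param library output of \code{\link{makeLigandLibrary}} for this cfg.
#' @return list with \code{interactions} (data.frame ligand_id,
#'   protein_id, affinity_type, affinity_value_nM), \code{proteins}
#'   (data.frame protein_id, sequence, family), \code{communities}
#'   (named character vector protein -> planted community),
#'   \code{distances} (square matrix), and \code{community_clusters}
#'   (list: community -> planted cluster ids it binds).
#' @export
makeInteractionTable <- function(cfg, library) {
  stopifnot(inherits(cfg, "SynthConfig"))
  labels <- library$labels
  .withSeed(cfg$seed + 1L, {
    prot <- sprintf("P%03d", seq_len(cfg$n_proteins))
    comm <- sprintf("C%02d", rep_len(seq_len(cfg$n_communities), cfg$n_proteins))
    names(comm) <- prot
    ## characteristic clusters per community: disjoint contiguous blocks
    ## when possible, wrapping when there are fewer clusters than
    ## communities
    commClusters <- if (cfg$n_clusters >= cfg$n_communities) {
      unname(split(seq_len(cfg$n_clusters),
                   sort(rep_len(seq_len(cfg$n_communities), cfg$n_clusters))))
    } else {
      lapply(seq_len(cfg$n_communities), function(c)
        ((c - 1L) %% cfg$n_clusters) + 1L)
    }
    names(commClusters) <- sprintf("C%02d", seq_len(cfg$n_communities))
    rows <- list()
    for (p in prot) {
      bound <- commClusters[[comm[p]]]
      ## profile noise: flip each cluster bit independently
      for (ci in seq_len(cfg$n_clusters)) {
        has <- ci %in% bound
        if (stats::runif(1) < cfg$profile_noise) has <- !has
        if (has) bound <- union(bound, ci) else bound <- setdiff(bound, ci)
      }
      if (length(bound) == 0) bound <- commClusters[[comm[p]]]
      for (ci in bound) {
        members <- names(labels)[labels == ci]
        pick <- sample(members, min(length(members), sample(2:4, 1)))
        for (lg in pick) {
          rows[[length(rows) + 1L]] <- data.frame(
            ligand_id = lg, protein_id = p,
            affinity_type = sample(.AFFINITY_TYPES, 1),
            affinity_value_nM = 10^stats::runif(1, 0.5, 4),
            stringsAsFactors = FALSE)
        }
      }
    }
    interactions <- do.call(rbind, rows)
    sequences <- vapply(prot, function(p)
      paste(sample(.AMINO_ACIDS, sample(150:400, 1), replace = TRUE),
            collapse = ""), character(1))
    proteins <- data.frame(protein_id = prot, sequence = unname(sequences),
                           family = paste0("FAM_", comm), stringsAsFactors = FALSE)
    d <- matrix(0, cfg$n_proteins, cfg$n_proteins, dimnames = list(prot, prot))
    for (i in seq_len(cfg$n_proteins - 1)) for (j in (i + 1):cfg$n_proteins) {
      d[i, j] <- d[j, i] <- if (comm[i] == comm[j])
        stats::runif(1, 0.05, 0.25) else stats::runif(1, 0.65, 0.95)
    }
    list(interactions = interactions, proteins = proteins, communities = comm,
         distances = d, community_clusters = commClusters)
  })
}

#' Generate DUD-style screening sets
#'
#' Per target, actives are decorated variants of a few scaffolds (shared
#' chemotypes) and decoys are single molecules from unrelated
#' scaffold/decoration combinations of comparable size. The generator
#' checks that actives are on average more similar to their own
#' chemotype than to decoys.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list of screen sets, each a list with \code{target_id},
#'   \code{actives} and \code{decoys} (FingerprintSets) and
#'   \code{molecules} (data.frame with a role column).
#' @export
makeScreenSets <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  .withSeed(cfg$seed + 2L, {
    sets <- vector("list", cfg$n_targets)
    for (ti in seq_len(cfg$n_targets)) {
      asc <- sample(.SCAFFOLDS, cfg$n_active_scaffolds)
      adec <- sample(.DECORATIONS, cfg$n_active_scaffolds)
      act_smi <- character(0)
      for (si in seq_len(cfg$n_active_scaffolds)) {
        tails <- sample(.TAILS, cfg$actives_per_scaffold)
        act_smi <- c(act_smi, .makeClusterSmiles(asc[si], adec[si], tails))
      }
      names(act_smi) <- sprintf("T%02d_A%03d", ti, seq_along(act_smi))
      dsc <- setdiff(.SCAFFOLDS, asc)
      ddec <- setdiff(.DECORATIONS, adec)
      dec_smi <- paste0(sample(dsc, cfg$n_decoys, replace = TRUE),
                        sample(ddec, cfg$n_decoys, replace = TRUE),
                        sample(.TAILS, cfg$n_decoys, replace = TRUE))
      names(dec_smi) <- sprintf("T%02d_D%03d", ti, seq_along(dec_smi))
      amols <- parseMolecules(unname(act_smi), names(act_smi))
      dmols <- parseMolecules(unname(dec_smi), names(dec_smi))
      afps <- fingerprintMolecules(amols)
      dfps <- fingerprintMolecules(dmols)
      sets[[ti]] <- list(
        target_id = sprintf("T%02d", ti), actives = afps, decoys = dfps,
        molecules = rbind(cbind(amols, role = "active"),
                          cbind(dmols, role = "decoy")))
    }
    sets
  })
}

#' Generate held-out query interactions for prediction evaluation
#'
#' New molecules are fresh decorations of the planted cluster scaffolds
#' (tails never used in the library); each query's true targets are the
#' proteins that bind its parent cluster in the planted interaction
#' table.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param library output of \code{\link{makeLigandLibrary}}.
#' @param planted output of \code{\link{makeInteractionTable}}.
#' @param perCluster queries per planted cluster (default 5).
#' @return list of entries with \code{query} (molecule data.frame),
#'   \code{proteins} (true target ids) and \code{cluster} (planted
#'   cluster).
#' @export
makeNewInteractions <- function(cfg, library, planted, perCluster = 5L) {
  labels <- library$labels
  ## recover the scaffold+decoration stem of each cluster from a member id
  .withSeed(cfg$seed + 3L, {
    cl_map <- planted$community_clusters
    comm <- planted$communities
    out <- list()
    for (ci in seq_len(cfg$n_clusters)) {
      members <- names(labels)[labels == ci]
      ## true proteins: any protein planted on this cluster
      prots <- names(comm)[vapply(comm, function(cc)
        ci %in% cl_map[[cc]], logical(1))]
      if (length(prots) == 0) next
      stem_smi <- library$stems[[as.character(ci)]]
      tails <- sample(.HOLDOUT_TAILS, min(perCluster, length(.HOLDOUT_TAILS)))
      for (qi in seq_along(tails)) {
        qsmi <- paste0(stem_smi, tails[qi])
        mol <- tryCatch(parseMolecule(qsmi, sprintf("Q%02d_%02d", ci, qi)),
                        error = function(e) NULL)
        if (is.null(mol)) next
        out[[length(out) + 1L]] <- list(query = mol, proteins = prots,
                                        cluster = ci)
      }
    }
    out
  })
}

#' Write synthetic data in the pipeline's file dialects
#'
#' Emits a .smi ligand file, interactions TSV, protein FASTA, a square
#' distance-matrix TSV, a family annotation TSV and DUD-style
#' actives/decoys directories -- the exact formats the package's readers
#' consume.
#'
#' @param dir output directory (created if needed).
#' @param library,planted,screens outputs of the generators (screens
#'   optional).
#' @return the directory path, invisibly.
#' @export
writeSyntheticData <- function(dir, library, planted, screens = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSmiFile(stats::setNames(library$molecules$smiles,
                               library$molecules$ligand_id),
               file.path(dir, "ligands.smi"))
  utils::write.table(planted$interactions, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeFastaProteins(planted$proteins, file.path(dir, "proteins.fasta"))
  writeDistanceMatrix(planted$distances, file.path(dir, "distances.tsv"))
  utils::write.table(
    data.frame(protein_id = planted$proteins$protein_id,
               family = planted$proteins$family),
    file.path(dir, "families.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(screens)) {
    for (s in screens) {
      td <- file.path(dir, "screen", s$target_id)
      dir.create(td, showWarnings = FALSE, recursive = TRUE)
      act <- s$molecules[s$molecules$role == "active", ]
      dec <- s$molecules[s$molecules$role == "decoy", ]
      writeSmiFile(stats::setNames(act$smiles, act$ligand_id),
                   file.path(td, "actives.smi"))
      writeSmiFile(stats::setNames(dec$smiles, dec$ligand_id),
                   file.path(td, "decoys.smi"))
    }
  }
  invisible(dir)
}
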