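## Independent brute-force oracles and shared fixtures. Oracles
## deliberately use a different formulation (explicit sets and loops)
## than the vectorised implementations they check.

## Tanimoto/Jaccard via explicit index sets
oracleTanimoto <- function(a, b) {
  sa <- which(a != 0); sb <- which(b != 0)
  if (length(sa) == 0 && length(sb) == 0) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

## random 0/1 fingerprint matrix
randomFps <- function(n, nbits = 128, density = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(as.integer(runif(n * nbits) < density), n, nbits)
  rownames(m) <- sprintf("F%03d", seq_len(n))
  ## no all-zero rows: set one deterministic bit
  zero <- rowSums(m) == 0
  m[cbind(which(zero), (which(zero) %% nbits) + 1L)] <- 1L
  m
}

asFpSet <- function(m) {
  new("FingerprintSet", bits = m, nbits = ncol(m), depth = NA_integer_,
      family = "random")
}

## flood-fill connected components over an edge data.frame
oracleComponents <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

## AUC by counting every active/decoy pair
oracleAUC <- function(scores, active) {
  wins <- 0; total <- 0
  for (i in which(active)) for (j in which(!active)) {
    total <- total + 1
    if (scores[i] > scores[j]) wins <- wins + 1
    else if (scores[i] == scores[j]) wins <- wins + 0.5
  }
  wins / total
}

## NMI by explicit double loops over label values
oracleNMI <- function(a, b, normalizer = "mean") {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    nxy <- sum(a == x & b == y)
    if (nxy > 0)
      mi <- mi + (nxy / n) * log((nxy * n) / (sum(a == x) * sum(b == y)))
  }
  ent <- function(l) {
    h <- 0
    for (x in unique(l)) {
      p <- sum(l == x) / length(l)
      h <- h - p * log(p)
    }
    h
  }
  ha <- ent(a); hb <- ent(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / (if (normalizer == "mean") (ha + hb) / 2 else max(ha, hb))
}

## reference affinity propagation (scikit-learn) on a similarity matrix;
## returns integer labels in input order
sklearnAP <- function(S, preference = 0, damping = 0.5) {
  f <- tempfile(fileext = ".csv")
  utils::write.table(S, f, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.cluster import AffinityPropagation\n",
    "S = np.loadtxt(%s, delimiter=',')\n",
    "ap = AffinityPropagation(affinity='precomputed', preference=%f, ",
    "damping=%f, max_iter=1000, convergence_iter=50, random_state=0).fit(S)\n",
    "print(' '.join(map(str, ap.labels_)))"), deparse(f), preference, damping)
  out <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = FALSE))
  as.integer(strsplit(utils::tail(out, 1), " ")[[1]])
}

samePartition <- function(labelsA, labelsB) {
  tab <- table(labelsA, labelsB)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

## shared synthetic fixtures, built once per test session
.fixtureEnv <- new.env(parent = emptyenv())

synthFixture <- function() {
  if (is.null(.fixtureEnv$fx)) {
    cfg <- synthConfig(seed = 7L)
    lib <- quietly(makeLigandLibrary(cfg))
    planted <- makeInteractionTable(cfg, lib)
    .fixtureEnv$fx <- list(cfg = cfg, lib = lib, planted = planted)
  }
  .fixtureEnv$fx
}

recoveryFixture <- function() {
  ## the 5-cluster x 10-ligand recovery library
  if (is.null(.fixtureEnv$rec)) {
    cfg <- synthConfig(n_clusters = 5L, ligands_per_cluster = 10L, seed = 7L)
    lib <- quietly(makeLigandLibrary(cfg))
    .fixtureEnv$rec <- list(cfg = cfg, lib = lib)
  }
  .fixtureEnv$rec
}

## suppress Open Babel chatter written straight to the console
quietly <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

## a tiny hand-built knowledge base: 3 clusters with controlled exemplar
## fingerprints and targets {P}, {P, Q}, {R}
toyKB <- function() {
  mem <- data.frame(member_id = c("a", "b", "c", "d"),
                    cluster_id = c("1", "1", "2", "3"),
                    exemplar_id = c("a", "a", "c", "d"),
                    stringsAsFactors = FALSE)
  cl <- new("LigandClusterSet", membership = mem, amw = numeric(0))
  bits <- rbind(
    a = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0),  # sim to query 9/10
    b = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0),  # non-exemplar
    c = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 1),  # sim 8/12
    d = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1))  # sim 1/12
  storage.mode(bits) <- "integer"
  fps <- new("FingerprintSet", bits = bits, nbits = 12L, depth = NA_integer_,
             family = "toy")
  records <- data.frame(
    ligand_id = c("a", "b", "c", "c", "d"),
    protein_id = c("P", "P", "P", "Q", "R"), stringsAsFactors = FALSE)
  list(kb = buildKnowledgeBase(cl, fps, records),
       query = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L),
       clusters = cl, fps = fps, records = records)
}

## 12-row toy interaction table spanning all three filter rules; the
## expected survivors are enumerated by hand from the rule definitions
## (affinity <= 10 uM inclusive, MW < 800 exclusive, length > 80
## exclusive).
toyFilterTable <- function() {
  ligands <- stats::setNames(c(400, 799, 800, 850, 400, 400),
                             c("mw400", "mw799", "mw800", "mw850", "small", "small2"))
  proteins <- stats::setNames(
    c(strrep("A", 300), strrep("A", 81), strrep("A", 80), strrep("A", 79)),
    c("len300", "len81", "len80", "len79"))
  records <- data.frame(
    ligand_id = c("mw400", "mw400", "mw400", "mw400", "mw799", "mw800",
                  "mw850", "small", "small", "small2", "ghost", "mw400"),
    protein_id = c("len300", "len300", "len300", "len81", "len300", "len300",
                   "len300", "len80", "len79", "len300", "len300", "missing"),
    affinity_type = c("Ki", "IC50", "Kd", "EC50", "Ki", "Ki",
                      "Kd", "Ki", "Ki", "Kc", "Ki", "Ki"),
    affinity_value_nM = c(5000, 20000, 10000, 100, 100, 100,
                          100, 100, 100, 100, 100, 100),
    stringsAsFactors = FALSE)
  ## hand enumeration:
  ##  1 kept (Ki 5 uM, MW 400, len 300)
  ##  2 dropped: IC50 20 uM > 10 uM
  ##  3 kept (Kd exactly 10 uM: cutoff inclusive)
  ##  4 kept (len 81 > 80)
  ##  5 kept (MW 799 < 800)
  ##  6 dropped: MW 800 not < 800
  ##  7 dropped: MW 850
  ##  8 dropped: len 80 not > 80
  ##  9 dropped: len 79
  ## 10 dropped: affinity type Kc not accepted
  ## 11 dropped: unknown ligand id
  ## 12 dropped: unknown protein id
  list(records = records, ligands = ligands, proteins = proteins,
       kept = c(1L, 3L, 4L, 5L))
}
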