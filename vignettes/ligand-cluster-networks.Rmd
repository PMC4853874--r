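---
title: "Ligand-cluster-based protein networks and exemplar screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-cluster-based protein networks and exemplar screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A protein's pharmacology can be read off the small molecules that bind
it. Two proteins that are recognised by structurally similar ligands are
related at the chemical level even when their sequences are not, and
that relationship is what this package quantifies. The pipeline has
three layers:

1. **Ligand clustering.** Every ligand is encoded as a 2048-bit binary
   fingerprint; ligands whose pairwise Tanimoto similarity exceeds 0.5
   are clustered by affinity propagation (AP), which elects a concrete
   *exemplar* molecule for every cluster.
2. **Protein space.** After filtering the interaction table (binding
   affinity at most 10 µM, ligand weight under 800 Da, sequence longer
   than 80 residues), each protein becomes a bit vector over the ligand
   clusters — bit *i* is set iff the protein binds any member of cluster
   *i*. Protein–protein similarity is the Jaccard index of two such
   vectors; a parallel sequence-based similarity is 1 − (global sequence
   distance) from an external aligner. Thresholding either similarity at
   0.25 gives the ligand-cluster-based network (LCBN) and the
   sequence-based network (SBN), whose AP communities are compared by
   normalized mutual information (NMI).
3. **Screening and querying.** A query molecule is compared against
   cluster *exemplars only* (EXEMPLAR score). Group-fusion baselines —
   MAX (best similarity to any training active), 3NN (mean of the three
   best), MPS (mean over all) — provide the accuracy reference, with
   rank-based AUC over DUD-style active/decoy sets and a Friedman test
   with Nemenyi post hoc across methods.

## Fingerprints

The fingerprint is a hashed linear-path descriptor computed on the
heavy-atom connection table: every simple path of up to 7 bonds is
written as an element/bond-order string (taking the lexicographically
smaller reading direction, so the feature is orientation-free), hashed
with 32-bit FNV-1a and folded onto 2048 bits. SMILES are canonicalised
with Open Babel at parse time, which makes the fingerprint a function of
the structure, not of its spelling. Path length 7 and 2048 bits are the
defaults throughout and are recorded in every run manifest so that runs
using different parameters are never silently compared. The descriptor
family matters less than its consistency: all similarities in the
pipeline are relative comparisons within one fingerprint configuration.

Unparseable SMILES are rejected records carrying the ligand id — never a
silent all-zero fingerprint, which would poison similarity searches. The
Tanimoto of two all-zero vectors is defined as 1 (identical objects) and
zero-versus-nonzero as 0, avoiding 0/0 while preserving
`tanimoto(a, a) = 1`.

## Affinity propagation

AP is implemented as standard Frey–Dueck message passing
(responsibility/availability updates, damping, convergence when the
exemplar set is stable for 50 iterations, capped at 1000). Choices that
required judgement:

* **Sparsity.** Only ligand pairs above the 0.5 similarity threshold are
  stored, and AP runs independently per connected component of that edge
  graph; within a component, missing pairs are imputed with a large
  negative similarity. Ligands that are not similar must not co-elect an
  exemplar, and components are independent by construction. Edgeless
  ligands are singleton clusters, their own exemplar.
* **Damping 0.5.** This is the reference default of the original
  implementation and of scikit-learn. We verified empirically that
  heavier damping (0.9) can settle on fixed points that merge
  well-separated blocks of a similarity matrix — both this
  implementation and scikit-learn, run on the same matrix, merged 5
  clean Jaccard blocks into 3 at damping 0.9 and recovered all 5 at
  0.5. The parameter remains configurable.
* **Determinism.** AP given a fixed input order is deterministic; inputs
  are sorted by id before clustering, and exact message ties (e.g. a
  constant similarity matrix) are broken by a tiny index-based jitter,
  scaled by the off-diagonal magnitude — the deterministic counterpart
  of the random noise the standard implementations inject. Ties in the
  final assignment go to the lowest id.
* **Preference 0** (shared, on the diagonal) for both ligand clustering
  and protein community detection. With similarities in (0, 1] this sits
  below every off-diagonal value and yields few, well-supported
  exemplars.

## Filters and conventions

The interaction filter is a literal reading of its three rules: affinity
≤ 10 000 nM (inclusive), molecular weight < 800 Da (exclusive), sequence
length > 80 (exclusive). Records with affinity types other than Ki, Kd,
EC50, IC50 and records referencing unknown ligands or proteins are
dropped and counted per rule. When a ligand–protein pair is measured
several times, the pair is kept if any measurement passes — the unit of
analysis is the distinct interaction, not the assay.

The sequence side consumes a precomputed global-distance matrix (square
TSV or PHYLIP-style) rather than shelling out to an aligner, keeping the
package self-contained; similarity = 1 − distance is the conversion, an
assumption flagged here because distance-to-similarity mappings are not
unique.

NMI is normalized by the arithmetic mean of the two entropies (the most
common convention), with max-normalization available by argument; the
choice is written to the run manifest. Comparing a partition against a
constant labelling yields 0 by definition; nodes without a family label
form one shared "unassigned" class if family NMI is requested on
partially labelled data.

## Screening

For each target and repeat, ⌈0.2·|actives|⌉ actives (ceiling, so never
zero) train the screen; the training actives are AP-clustered and the
remaining actives plus all decoys are scored. MPS is implemented as the
arithmetic mean of the query's similarities to *all* training actives —
the name is used loosely in the literature, so the k-of-n variants are
exposed through the `k` argument of the KNN scorer instead. AUC uses
midranks for ties (the Mann–Whitney convention). Per-(target, repeat)
seeds are derived deterministically from one master seed, so the whole
benchmark is a pure function of that seed. The post hoc procedure after
the global Friedman test is Nemenyi (mean-rank differences against the
studentized range); a within-block permutation alternative is available
when the normal-approximation assumptions feel too strong for small
block counts.

The EXEMPLAR score deliberately compares the query against cluster
exemplars only: one similarity evaluation per cluster rather than one
per training ligand. A highly similar non-exemplar member therefore
cannot raise the score — this is the method's speed/accuracy trade, and
the benchmark reports the evaluation-count reduction alongside the AUC
so the trade is visible.

## The synthetic data generator

Real inputs at the scale of public bioactivity databases cannot ship
with a package, so every end-to-end property is exercised on generated
data with *planted* structure:

* **Ligands** are built chemically, not as random bit vectors: each
  planted cluster is one ring scaffold (from a pool of 16 with a
  substitutable terminal atom) carrying a cluster-specific decoration
  chain, and members differ only in a short tail. This exercises the
  real SMILES → canonicalisation → fingerprint stack. The generator
  measures the realised within/between-cluster similarity means and
  resamples the scaffold/decoration assignment (up to 3 attempts) if
  their separation falls below half the configured target separation,
  because decorated-scaffold similarity is not analytically predictable.
  A fast random-fingerprint mode (used in the pure-math unit tests)
  bypasses chemistry entirely.
* **Proteins** are split into communities; each community binds a
  disjoint block of planted clusters. Defaults: 10 clusters × 10
  ligands, 30 proteins, 5 communities (2 clusters per community).
  Giving every community two characteristic clusters instead of one
  means a single profile bit-flip degrades similarity gracefully instead
  of making the protein ambiguous. Binding bits flip with probability
  0.02 — about one perturbed protein in five — which perturbs profiles
  without erasing the planted signal; affinities are drawn log-uniformly
  within the filter's accepted range. A companion sequence-distance
  matrix (within-community 0.05–0.25, between 0.65–0.95) plants the same
  communities in sequence space, so LCBN/SBN agreement has a ground
  truth.
* **Screening sets** are DUD-like: per target, actives from 3 scaffold
  chemotypes (36 actives), 60 single-molecule decoys from unrelated
  scaffold/decoration combinations of comparable size; the generator
  checks actives are closer to each other than to decoys.
* All generators run on a private RNG stream derived from the config
  seed and restore the caller's RNG state, so identical configs give
  byte-identical data without side effects.

What passing these tests shows — and what it does not: the synthetic
libraries have crisp cluster margins and low noise compared to real
bioactivity data, where cluster boundaries are blurry, assay noise is
structured, and activity cliffs break the similarity principle. Recovery
of planted structure validates the machinery, not the biology; on real
data the same pipeline will produce noisier communities and lower
agreement between the chemical and sequence views.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run at desk scale: 50–100
ligands, 30 proteins, 5 screening targets × 50 repeated splits — sizes
chosen so the full suite completes in minutes while every code path
(including AP per component, network construction and the Friedman
machinery) is exercised end to end. Kernel identities (Tanimoto, Jaccard,
AUC, NMI) are checked against independent brute-force set-arithmetic
oracles to 1e-12; the AP engine is cross-checked against an independent
reference implementation on random instances.

Known limitations: the path fingerprint does not encode stereochemistry
or formal charges; AP's preference-0 convention couples cluster
granularity to the similarity scale, so similarities should be in [0, 1];
proteins without any qualifying ligand never appear in the LCBN (a
structural blind spot of ligand-based views); and the MCL community
adapter requires an external `mcl` executable, reporting a clean
`backendUnavailable` condition when absent.
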