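---
title: "Conformational splitting of protein structure corpora: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational splitting of protein structure corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsplit)
```

## The problem

Structure-prediction networks are trained on the PDB, so when a sequence has
been solved in several conformations — an open and a closed state of an
enzyme, say — an evaluation of "can the model predict the alternative
conformation?" is meaningless unless the alternative state was genuinely
withheld from training. A *conformational split* partitions a structure
corpus at the level of structural clusters so that, for every sequence with
several distinct conformations, exactly one conformation is available for
training and all others are reserved for evaluation.

`confsplit` implements that procedure end to end — corpus filtering,
two-tier sequence clustering, TM-score structural clustering, detection and
curation of alternative conformations, and the seeded train/validation/test
assignment — together with the evaluation machinery for conformational
prediction ensembles (best-of-N TM-scores, outcome fractions,
change-type classification, confidence and embedding statistics) and a
synthetic C-alpha structure generator that provides fully ground-truthed
benchmarks.

## Scoring model

All structural similarity is measured by the TM-score after optimal rigid
superposition,

$$\mathrm{TM} = \frac{1}{L_\mathrm{norm}} \sum_{i=1}^{n_\mathrm{aligned}}
  \frac{1}{1 + (d_i/d_0)^2}, \qquad
  d_0 = 1.24\,(L_\mathrm{norm}-15)^{1/3} - 1.8\ \text{Å},$$

with $L_\mathrm{norm} - 15$ clamped at 1 before the cube root and $d_0$
clamped below at 0.5 Å so that very short chains remain scoreable. The score
is computed under both chain-length normalizations; `tm_min` (the
conservative value, normalized by the longer chain) drives clustering and
alternative-conformation calls, while ensemble evaluation uses `tm_max` to
absorb length differences between resolved native regions and full predicted
sequences.

The superposition maximizing the TM-score is found by iterative
fragment-seeded optimization: contiguous aligned fragments seed Kabsch
superpositions, and each seed is refined by repeatedly superposing on the
residues within $d_0$ of their partners (growing the cutoff by 0.5 Å
whenever fewer than three qualify) until the score changes by less than
1e-6 or 20 iterations. For chains of at most 60 aligned residues every
fourth fragment length is seeded (score landscapes are rugged and refits are
cheap there); longer chains use the halving schedule n, n/2, n/4, ... ≥ 4.
A final restart from the inlier set of the best superposition polishes the
result. The test suite checks this engine against an exhaustive
fragment-seed plus rotation-grid brute-force oracle on chains up to 60
residues, requiring agreement within 0.01 TM.

Residue correspondence comes from global sequence alignment
(Needleman–Wunsch, BLOSUM62, affine gaps −11/−1 in the convention where a
gap of length $k$ costs $\mathrm{open} + k\cdot\mathrm{extend}$), not from
structure-based alignment: every comparison in the pipeline is between
sequences at 90% or more identity, where the sequence alignment determines
the correspondence reliably. This is a deliberate simplification relative to
full structural aligners, and it means the package should not be used to
score remote homologs.

One classical property deserves a caveat: "TM normalized by the longer chain
never exceeds TM normalized by the shorter" holds for structurally related
pairs (a shared core with modest deviations) but is not a theorem — for
unrelated point sets near the short-chain $d_0$ clamp the per-residue terms
are not monotone in $L_\mathrm{norm}$ and violations of order 0.003 occur.
The property test therefore asserts it on related pairs, the regime in which
the pipeline operates.

## Pipeline stages and thresholds

| Parameter | Default | Role |
|---|---|---|
| `min_len` | 50 residues | shortest chain kept in the corpus |
| `max_nonregular_frac` | 0.8 | maximum fraction of non-regular (`X`) residues (strict `<`) |
| `max_resolution` | 5.0 Å | X-ray/EM resolution cutoff; chains without a reported resolution are excluded |
| `seq_identity_broad` | 0.30 | broad clustering tier (identity over the shorter sequence, coverage 0.8 of the member) |
| `seq_identity_fine` | 0.90 | near-identical tier whose clusters are scanned for alternative conformations |
| `tm_cluster` | 0.8 | `tm_min` to the representative required to join a structural cluster |
| `alt_tm` | 0.8 | aligned-region TM below which two structures are alternative conformations (a difference > 0.2 from self-identity) |
| `success_tm` | 0.8 | strict `>` threshold for a successful prediction |
| `fold_baseline_tm` | 0.6 | minimum single-prediction `tm_min` for a target to be evaluable at all (0.5 is merely same-fold) |
| `val_fraction` | 0.05 | fraction of non-alternative training clusters held out for validation |

Clustering is greedy centroid clustering: sequences (or structures) are
visited longest-first with lexicographic tie-breaks, joining the first
representative they match at threshold, founding a new cluster otherwise.
This reproduces the threshold semantics of MMseqs2-style clustering
(`--min-seq-id X -c 0.8 --cov-mode 1`: coverage measured on the member side)
deterministically and without external binaries; exact reproduction of any
particular tool's clusters is a non-goal. Centroid linkage was chosen over
single linkage (available semantics differ only for borderline chains) for
determinism and O(N·K) cost. Structures that cannot be aligned against any
representative are reported as *unclusterable* rather than forced into a
cluster, mirroring real corpora in which a few percent of chains defeat
pairwise alignment.

Alternative conformations are detected inside 90%-identity clusters that
span at least two structural clusters. Each cross-cluster pair is scored on
its *aligned region only* — sequences are aligned, the corresponding
sub-chains extracted, and the TM recomputed — so that differences caused by
disordered termini or construct-length mismatches never masquerade as
conformational changes. One representative pair is kept per structural
cluster pair, maximizing `(overlap_fraction, 1 − TM)` lexicographically:
longest overlap first, then biggest structural difference.

The published procedure relied on manual inspection to discard pairs whose
difference reflects experimental artifacts. `automated_curation()` replaces
that step with three explicit, tunable rules: a pair is rejected when (i)
trimming 10 residues from each end of the aligned region lifts the TM back
to or above the alternative threshold (terminal/loop mobility), (ii) either
aligned region contains a backbone break (consecutive C-alpha > 10 Å), or
(iii) the overlap covers less than 80% of the shorter chain. An automated
surrogate cannot reproduce expert judgement exactly; counts on real corpora
will differ from manually curated ones, and the rejection table is returned
so borderline calls can be audited.

`make_split()` forms alternative sets as connected components of the curated
pair graph over structural clusters — a 90% cluster may span three or more
conformations. Per set, one cluster is drawn uniformly at random (seeded)
into the training pool; all others go to test. The validation partition is
drawn only from non-alternative training clusters so that conformational
evaluation is never contaminated. `verify_split()` asserts that no curated
pair has both clusters on the training side; note that two clusters of one
pair may legitimately both sit in test when a set has three or more
conformations (one trains, the rest are evaluated), so "both in test" is not
a violation.

## Ensemble evaluation

Sampling schedules follow the two standard conformational-sampling
strategies: MSA clustering (cluster counts 16, 32, 64, 128, 256, 512, 1024,
5120 with 13 samples each, 104 jobs per target) and dropout sampling
(100 jobs). `msa_cluster_sample()` subsamples an A3M into k centers — the
query always among them — assigning remaining sequences to centers by
Hamming distance over match columns. The predictor itself is external to the
package: schedules are emitted, ensembles (directories of model PDBs with
per-residue confidence in the B-factor column) are consumed.

Each ensemble is scored best-of-N against both native conformations;
per-sample outcomes are labeled *test* / *train* / *neither* at the strict
0.8 threshold with ties above threshold going to the higher score.
`classify_conformational_change()` types each alternative pair
automatically:

1. **fold switch** — more than 15% of aligned residues change three-state
   secondary structure in blocks of at least 6 residues;
2. **hinge** — otherwise, at least two rigid bodies of 25+ residues (maximal
   contiguous blocks whose distance-difference matrix stays below 2 Å at the
   95th percentile) each superpose at TM ≥ 0.8 while the global aligned TM
   is below 0.8;
3. **rearrangement** — everything else. Pairs with fewer than 50 aligned
   residues are left unassigned.

Secondary structure is assigned from C-alpha geometry alone (the corpus is
C-alpha-level): each 4-residue window is labeled by its nearest ideal
prototype in (d(i,i+2), d(i,i+3)) space — helix (5.43, 5.05 Å) or extended
strand (6.60, 10.08 Å) — within a 1.6 Å acceptance radius, residues take the
majority label of their covering windows, and structured runs shorter than 3
are relabeled coil. The prototype/vote design (in the spirit of
C-alpha-only assigners such as P-SEA) was chosen over hard distance windows
because junction windows then fall between prototypes and vote coil
deterministically, keeping the assignment stable under sub-Ångström
coordinate noise; the 95th-percentile criterion in rigid-body segmentation
exists for the same reason (a max criterion fragments genuinely rigid
domains once enough noisy pairs are scanned). On the synthetic benchmark the
classifier recovers at least 90% of planted labels per type.

The composite training loss is aggregated as
`0.5·FAPE + 0.5·AUX + 0.3·Distance + 0.2·MSA + 0.01·Confidence`; the loss
terms themselves come from a training system outside this package's scope.

## Embedding comparison

Two conventions are provided for the length-normalized cosine similarity of
single-sequence embeddings (L×d), because the printed formula
$A\cdot B/(|A||B|)\cdot 1/L$ is dimensionally ambiguous for a matrix: the
default `per_residue_mean` averages row-wise cosines and is calibrated to
[−1, 1]; `frobenius_over_L` is the literal flattened reading, bounded by
±1/L. Neither is asserted to be the published convention; both are exact to
1e-12 against direct re-evaluation. The pair-embedding difference is the
mean absolute elementwise difference $\frac{1}{n}\sum\sqrt{(C-D)^2}$ (the
printed form; a true RMS variant sits behind the `rms` flag for sensitivity
checks). Embedding–structure association uses Spearman rank correlation with
a seeded permutation p-value (10,000 permutations by default).

## The synthetic benchmark: what it does and does not emulate

`make_benchmark()` builds a corpus with known ground truth: sequence
families (default 50) of ideal-geometry two-domain C-alpha chains
(helix rise 1.5 Å at 100°/residue and radius 2.3 Å, strand rise 3.3 Å
zigzag, coil as a self-avoiding 3.8 Å walk; lengths 70–120), members at 95%
within-family identity with 0.3 Å coordinate noise, and 10% of families
given a second conformation produced by a hinge, a multi-pivot
rearrangement, or a fold switch. Deformations are calibrated by bisection so
the aligned-region TM between conformations hits a planted target drawn from
[0.55, 0.75] — a 0.25–0.45 TM gap, comfortably beyond the >0.2
alternative-conformation threshold — and every planted value is confirmed
within ±0.05. Fold switches rebuild a C-terminal region (sized from the
target TM) in the complementary secondary structure, because rebuilding a
mid-chain region necessarily displaces everything downstream of it; a hinge
on the retained part fine-tunes the score. All generators are deterministic
per seed.

What passing tests on this benchmark demonstrate: the thresholds, the
clustering and split logic, the TM engine, and the classifiers behave as
specified when the ground truth is known. What they do not demonstrate:
performance on real crystallographic data — real conformational changes are
not ideal rigid rotations, real sequences have family-specific substitution
patterns rather than uniform random mutations, real termini are disordered
in messier ways, and the synthetic per-residue confidence
(`100·exp(−dev/4)` plus reporting noise) is a tunable stand-in, not a claim
about any predictor's plDDT. Counts from real corpora additionally depend on
the PDB snapshot date and on manual curation choices.

## Numerical choices and degenerate inputs

- Kabsch superposition refuses fewer than 3 point pairs and collinear
  configurations; the proper-rotation branch of the SVD is always taken.
- TM-score requires at least 5 aligned pairs; `d0` is floored at 0.5 Å.
- Greedy clustering breaks length ties lexicographically by id, making every
  run reproducible from input order alone.
- `make_split()` draws from a single RNG stream seeded by the manifest seed;
  identical seeds give byte-identical manifests.
- Zero-variance inputs to correlation estimators return a degenerate flag
  with `NA` rather than an error or a fabricated value.
- Identity denominators default to the shorter sequence (the common
  clustering-tool convention); `aligned_columns` is available.

## Problem sizes used in the shipped tests

The acceptance suite runs the full pipeline on 50-family corpora (about 160
chains of 70–120 residues) across 5 seeds, checks the TM engine against the
brute-force oracle on 50 pairs of up to 60 residues, and classifies 30
planted cases per change type. These sizes give exact planted-recovery
checks and stable statistics while keeping a full run of the suite in the
minutes range on one CPU; the same machinery scales to larger corpora
linearly in the number of pairwise comparisons.

## Known limitations

- Sequence-guided superposition only; no remote-homolog structural search.
- C-alpha-level models throughout; no side chains, no full-backbone
  geometry, no assemblies.
- The curation rules are a documented surrogate for expert inspection.
- Greedy centroid clustering approximates, not reproduces, external
  clustering tools.
- The release-date based corpus comparisons (pre/post a training-date
  cutoff) are not implemented; `release_date` is parsed and preserved so the
  filter is a one-liner for users who need it.
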