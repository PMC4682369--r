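---
title: "Motif-subgrouped prediction of O-GlcNAcylation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-subgrouped prediction of O-GlcNAcylation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oglcnac)
```

## The problem

O-GlcNAc transferase (OGT) attaches a single GlcNAc moiety to serine and
threonine hydroxyls. Unlike many kinases, OGT has no single consensus
motif: verified substrates fall into several distinct flanking-sequence
classes. A pooled model of all positive sites therefore blurs the
class-specific signals. The approach implemented here first *partitions*
the positive peptide windows into motif subgroups, then models each
subgroup separately, and finally lets a discriminative layer arbitrate
among the subgroup scores.

Throughout, a site is represented by an 11-mer window (half-width w = 5)
centred on the candidate Ser/Thr. Windows overlapping a protein terminus
are padded with `-`, which downstream models treat as a 21st symbol with
its own background frequency; unknown residues are mapped to `X`, which
belongs to no physicochemical group and is skipped by the dependence
statistics. Coordinates are 1-based and fully closed, the convention of
UniProt site annotations.

## Maximal dependence decomposition

The 20 amino acids are partitioned into five physicochemical groups:

| group | letters |
|---|---|
| polar | S T C N Q Y |
| acidic | D E |
| basic | H K R |
| hydrophobic | A G I L M P V |
| aromatic | F W |

This table is a configuration value (`default_group_scheme()`,
`read_group_scheme()`), so an alternative partition can be dropped in
without touching the algorithms. The partition above follows the common
physicochemical classification in which proline, valine, alanine and
glycine count as hydrophobic, lysine/arginine/histidine as basic, and
serine/threonine as polar.

For a position pair (A_i, A_j), both non-centre, the 5×5 contingency
table X counts group co-occurrence over the positive windows; windows
with a null symbol (`X` or `-`) at either position are skipped. The
dependence statistic is Pearson's

$$\chi^2(A_i, A_j) = \sum_{m=1}^{5}\sum_{n=1}^{5}
  \frac{(X_{mn} - E_{mn})^2}{E_{mn}}, \qquad
  E_{mn} = \frac{X_{mR}\,X_{Cn}}{X}.$$

Cells with `E = 0` contribute 0 (the standard convention for structurally
empty cells; it keeps the statistic finite and equal to the value obtained
by dropping empty rows/columns). The centre position is excluded: it is
constant Ser/Thr by construction and carries no usable dependence.

MDD splits a node on the position with maximal aggregate dependence
`D_i = sum_j chi^2(A_i, A_j)` (ties: smallest offset), using the modal
group at that position (ties: fixed group order polar < acidic < basic <
hydrophobic < aromatic) — members carrying the group go to one child, the
rest to the other. The aggregate-D rule is our resolution of an
under-determined point: a pairwise maximum identifies a *pair*, not a
single split position, and the Burge–Karlin-style aggregate reproduces the
described binary has-group/lacks-group tree shape. Splitting stops when no
pair exceeds `chi2_cutoff` (default 34.3 = `qchisq(0.995, 16)`, the upper
0.005 point at (5−1)² degrees of freedom) or the node has fewer than
`min_size` members (default 30, exposed as a parameter). No explicit
depth guard is needed: once a branch is conditioned on a group at a
position, every table involving that position is concentrated in one row,
its chi-squared contribution is identically zero, and the position cannot
be chosen again along that path.

Leaves are labelled `OGT1..OGTk` depth-first, with-branch first, and this
order fixes the feature order of the second layer.

## Profile HMMs and bit scores

Each leaf's fragments form a gapless fixed-length alignment, so the
profile HMM has one match state per column. Match emissions use a
background-weighted additive estimator,

$$e_p(a) = \frac{c_p(a) + \alpha\,q(a)}{n + \alpha},$$

with pseudocount mass α = 1 by default and null model q uniform (1/20 per
letter, with `-` given the empirical padding frequency of the training
alignment; an empirical null is available). The bit score of a window is
`log2 P(window | model) / P(window | null)`, which for an equal-length
gapless window decomposes into a per-position log-odds sum plus a constant
transition term. Insert/delete states exist and the full forward algorithm
(`phmm_forward()`) is implemented both for variable-length queries and as
an independent oracle for the fast path, but the default transition leak
is 0: the fixed-length window design makes indels vestigial, and a zero
leak keeps the score exactly position-decomposable (and the closed forms
exact, e.g. a pseudocount-free consensus model scores its consensus at
`11 * log2(20)` ≈ 47.55 bits). A ratio floor of 1e-9 guards positions
where both emission and null are zero (e.g. padding never seen in
training), scoring them neutrally instead of producing 0/0.

Per-leaf bit-score thresholds are calibrated by scanning the midpoints of
the observed scores and maximizing accuracy (Youden's J is available) on
the leaf's positives against the balanced negatives; ties resolve to the
smaller threshold, favouring sensitivity. These thresholds do not gate the
final call — that is the second layer's job — but drive the reported
matched motif: the best-scoring HMM above its threshold, or the overall
best flagged `*` when none clears it.

## Negative balancing and the second layer

Training negatives (every non-annotated Ser/Thr window) outnumber
positives by two orders of magnitude, so the negative class is
undersampled to exactly the positive count: windows are one-hot encoded
(21 symbols per position by default; a 5-group encoding is available),
clustered with k-means into as many clusters as positives wanted, and the
member nearest each centroid is kept. Lloyd iterations can leave clusters
empty; missing slots are backfilled with the unchosen fragments nearest
their own centroids, so the contract |selected| = |positives| holds
exactly and the selection is always a duplicate-free subset.

The second layer is an RBF-kernel SVM over the k-dimensional bit-score
vector. Bit scores share a unit, so they are passed unscaled. The
(C, gamma) pair is chosen from a coarse log grid (C ∈ 2^{−5..15} by 4,
gamma ∈ 2^{−15..3} by 4) by seeded stratified cross-validated accuracy
(ties: smaller C, then smaller gamma); the probability map is a logistic
fit on out-of-fold decision values (Platt scaling), oriented so larger
decision values mean "positive". A site is called positive when the
probability strictly exceeds 0.5 — a probability of exactly 0.5 is
negative.

The SVM itself is `e1071::svm` (libsvm); its support vectors,
coefficients and rho are extracted into the model object and the decision
function is evaluated from those stored arrays, so a model bundle saved
to JSON reloads to bit-identical predictions and two trainings with the
same seed produce byte-identical bundles (model metadata records seeds
and parameters, never timestamps).

## Evaluation machinery

`classification_metrics()` computes Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Acc = (TP+TN)/total and
MCC = (TP·TN − FN·FP)/√((TP+FN)(TN+FP)(TP+FP)(TN+FN)), with MCC defined
as 0 when any factor under the root vanishes (the common convention).
`cross_validate()` runs repeated stratified k-fold CV — "thirty rounds"
of 5-fold CV is read as 30 independent repartitions; the repeat count is
a parameter and the tests use 1–3 repeats. The full training pipeline,
including MDD, is re-run inside each training fold so no clustering
information leaks into the held-out fold; per-fold and per-round
reductions are both reported since averaging order is ambiguous.
`homology_filter()` removes test windows whose ungapped identity to any
training window reaches a cutoff (default 1.0, i.e. exact duplicates;
identity counts matching positions over the window length, two padding
symbols matching). `independent_test()` applies the trained model and the
0.5 rule to a disjoint labelled set.

## The synthetic generator

`generate_windows()` emulates the structure of a site-prediction training
set: positives are a mixture over motif specifications, each enforcing a
physicochemical group at chosen offsets with a chosen probability (the
letter is drawn uniformly within the group); negatives are pure
background; the centre is S or T with a configurable ratio.
`generate_proteins()` embeds positive windows into background proteins
and emits matching FASTA/annotation files. The default background is
uniform over the 20 letters — deliberately, so that motif signal strength
is controlled entirely by the spec — with a natural-composition preset
available. The generator plants group-level positional signals only; real
flanking sequences additionally carry letter-level biases, compositional
skew, and correlated disorder/accessibility structure that it does not
imitate. Passing tests therefore demonstrate that the machinery recovers
planted structure of the kind the method assumes, not that any particular
accuracy will be met on biological data.

Problem sizes used by the test-suite benchmarks were chosen to keep the
planted signals comfortably detectable at desk scale: 200 positives /
2,000 negatives for end-to-end comparisons (5-fold CV, 3 repeats, 10
generator seeds for the two-layer vs pooled-HMM ordering), 400 fragments
× 20 seeds for MDD recovery, and 410-from-5,000 for the balancing
contract, mirroring the positive/negative scale of a curated O-GlcNAc
training set.

## Known limitations and open choices

- The group scheme is a literature-style default, not a fitted object;
  motif trees are sensitive to it, which is why it is configurable.
- The aggregate-D split rule and the modal-group choice are documented
  resolutions of under-determined points; other MDD variants split on the
  maximal pair directly.
- E-values are not computed: the pipeline thresholds on bit scores, and
  probability arbitration happens in the SVM layer anyway.
- The per-pair chi-squared cutoff controls each test at P = 0.005, but 45
  pairs are scanned per node; under a pure null, roughly one node in five
  will still show some pair above 34.3. The `min_size` floor, not the
  cutoff alone, is what keeps spurious leaves small in practice.
- `X` residues contribute no group counts and score 0 bits at their
  position (an unknown residue is uninformative, and its unknown emission
  probability cancels in the model/null ratio); windows dominated by `X`
  carry little signal.
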