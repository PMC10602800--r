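---
title: "coralign: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coralign: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralign)
```

## 1. The alignment model

`coralign` computes global pairwise protein alignments in which the score
of matching position `i` of sequence A with position `k` of sequence B is

$$S(i,k) \;=\; w_1\, S_{20}(A_i, B_k) \;+\; w_2\, \beta(i,k),$$

with $S_{20}$ a conventional symmetric 20×20 substitution matrix and
$\beta$ a *pair bonus* derived from a 400×400 pair-substitution matrix
$S_{400}$ over correlated position pairs of sequence A. Gaps are affine: a
run of $L$ gapped residues costs $p + Lq$ (the first gapped residue pays
$p+q$, each further one $q$). Optionally, leading and trailing gap runs
are free (`free_end_gaps`, semi-global behaviour).

### The pair bonus

A correlation map for sequence A — a symmetric $n\times n$ matrix of
contextual dependence strengths, supplied externally (a protein language
model's position-correlation output, a structural contact map, or a
synthetic map) — is thresholded into a set of selected pairs $(i,j)$.
When the aligner considers matching $i$ with $k$, each selected partner
$j$ of $i$ votes: the partner's aligned position is unknown at that point
in the dynamic program, so the bonus *probes a sliding window* of
candidate positions $l \in [k + (j-i) - W,\; k + (j-i) + W]$ around the
diagonal projection of $j$, and takes the best pair score
$\max_l S_{400}(A_i, A_j, B_k, B_l)$. Votes from multiple partners are
combined by their mean (default) or sum.

Two properties motivated this definition over alternatives:

* **Markov property.** The bonus depends only on the cell $(i,k)$, not on
  the rest of the alignment, so the Gotoh optimality argument carries over
  unchanged and the returned score is a true optimum of a well-defined
  objective. The test suite certifies this against exhaustive enumeration
  of all global alignments on small instances, with the pair term both off
  and on.
* **Scale stability.** The mean combination keeps $\beta$ on the scale of
  a single $S_{400}$ entry regardless of how many partners a position has,
  so one `w2` value behaves comparably across positions and proteins. The
  `sum` mode is available for sensitivity analysis.

An alternative *iterative frozen-alignment* mode (`align_iterative`)
aligns with $w_2=0$, maps partners through the alignment obtained, rescores
with partners frozen at their aligned positions, and repeats (at most 10
rounds). It is exposed for sensitivity analysis, not as the default: its
fixed point need not be an optimum of any single objective.

Each endpoint of a correlated pair contributes its own bonus (position
$i$ probes for $j$, and when the program later scores $j$'s column, $j$
probes for $i$), mirroring the per-endpoint form of the scoring equations.
`endpoint_scale = 0.5` halves the bonus so that a pair effectively
contributes once; the default is 1.

### Parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `w1` | 1.0 | Weight of the single-residue score. |
| `w2` | 0.1 | Relative weight of the pair term; valid 0–0.9. 0 disables it. |
| `gap_open` (p) | 10 | Affine opening penalty, on the scale of half-bit matrices like BLOSUM62. |
| `gap_extend` (q) | 0.5 | Per-residue extension penalty. |
| `window` (W) | 10 | Half-window of the partner probe, in residues. Large enough to absorb indel drift between remote homologs, small enough to keep cost `O(n·m·partners·W)`. |
| `free_end_gaps` | FALSE | The method is global; end-gap freedom is explicit, never silent. |
| `min_separation` | 3 | Minimum `j-i` of selected pairs; suppresses trivial near-diagonal correlations, which dominate e.g. disordered-protein contact maps. |
| `max_partners` | 16 | Per-position cap, bounding DP cost; strongest pairs kept, ties to the smaller index. |
| correlation cutoff | 0.5 | Applied to a min–max rescaled map (`corrmap_rescale`), making the default provider-agnostic. An explicit cutoff skips rescaling. |

Traceback ties are broken deterministically: match > gap-in-B > gap-in-A.
Symmetrically scored inputs therefore produce mirror-consistent scores
under argument swap (the op lists mirror up to this tie order).

## 2. Homolog-closeness gating

Before aligning, the relationship between the two inputs can be estimated
from per-residue embedding matrices (N×D, one row per residue) produced by
a protein language model. Each matrix is compressed to a fixed-size
signature by 2D discrete cosine transform truncation: orthonormal DCT-II,
keep the top-left (low-frequency) block, inverse DCT at the target size,
then rescale by $\sqrt{(t_r t_c)/(N D)}$ so a constant input is preserved
exactly. The conventional signature keeps a deep layer at 5×44 and a
mid-depth layer at 3×85 — the layer/shape combination found most accurate
for remote-homolog detection in the embedding-distance literature — and
the distance between signatures is the L1 norm over all 475 cells,
computed on min–max uint8-quantized blocks by default (a `quantized =
FALSE` float mode exists). Quantization maps a block's range onto 0–255
with half-up rounding; a constant block maps to 128 by convention.

The distance gates two alignment parameters through a monotone schedule:
closer pairs get a *lower* map cutoff (more correlated pairs enter) and a
*higher* `w2`; distant pairs fall back to the single-residue matrix alone.
The default schedule (`default_gate_schedule`) uses fractions of the
maximum possible distance $D_{max} = 255 \times 475$:

| distance | cutoff | w2 |
|---|---|---|
| ≤ 0.20 · D_max | 0.3 | 0.10 |
| ≤ 0.50 · D_max | 0.5 | 0.05 |
| beyond | 1.1 (no pairs) | 0.00 |

These bounds are this package's own convention — the qualitative rule
(closer ⇒ smaller cutoff, larger weight) is established, the numbers are
not externally validated — and are fully configurable. Sequences shorter
than the signature's row count are an error rather than being padded:
padding semantics are undefined and silent extrapolation would be worse.

## 3. Building the matrices from MSAs

### Column-pair statistics

* **Mutual information** (`column_mi`): $\sum_{ab} f_{ab}\log_2
  \frac{f_{ab}}{f_a f_b}$ over the 20-letter alphabet with optional row
  weights and joint pseudocounts. Fast, but blind to transitivity.
* **Mean-field DCA** (`mfdca_di`): the standard global model — rows
  reweighted by 80%-identity clustering, single/pair frequencies smoothed
  with a uniform pseudocount fraction of 0.5, covariance over the 20
  non-gap states per column, couplings as the negative inverse covariance,
  pairs scored by direct information from the two-site model with
  self-consistent fields. This removes transitive correlations: in the
  test suite a planted chain A→B→C yields DI(A,C) below both direct links.

Columns with more than 50% gaps are excluded from ranking and counting,
and any substitution tuple touching a gap is skipped; the source
statistics never define gap handling, so these are package conventions.

### Log-odds construction

`build_ps400` selects, per family, the top 15% of column pairs by the
ranking statistic (selection is per-family; a pooled mode across families
was considered and rejected because families differ in width and signal
strength, which would let one large family dominate). For every ordered
pair of rows and each selected column pair it counts the 4-tuple
"pair $(a_i,a_j)$ substitutes to $(b_i,b_j)$"; the background is the same
count over *all* eligible column pairs. Both read orders of each column
pair are accumulated, which enforces the swap identity
$S_{400}(i,j,k,l) = S_{400}(j,i,l,k)$ by construction while leaving
directional asymmetry $S_{400}(i,j,k,l) \ne S_{400}(k,l,i,j)$
representable. `build_protsub` is the single-residue analogue (counts at
both columns of each selected pair, optional structural proximity filter
in MSA-column coordinates).

Entries are natural-log odds of *smoothed relative frequencies*:

$$\text{score} = \ln\frac{f_{fg} + \lambda/K}{f_{bg} + \lambda/K},
\qquad f = c / N,\; K = \text{cells},\; \lambda = 0.5 .$$

A flat additive pseudocount (add 0.5 to every cell of both count tables)
was deliberately rejected: foreground and background totals differ by
orders of magnitude, so every tuple unseen in *both* tables would receive
the constant $\ln(N_{bg}/N_{fg}) > 0$ — the largest entries in the whole
matrix would be the ones with no evidence at all. Under frequency
smoothing, unseen-everywhere tuples score exactly 0, foreground equal to
background yields the all-zero matrix exactly, and observed tuples behave
like ordinary log-odds. `to_half_bits` exports any 20×20 matrix in the
classic rounded `2/ln 2`-scaled integer convention.

## 4. Structural congruence

`normalized_aligned_rmsd` evaluates a sequence alignment against two
structures: collect representative-atom coordinates (Cα; contact maps use
Cβ with Cα fallback for glycine) at MATCH columns where both sides are
resolved, superpose them optimally (Kabsch, SVD with the determinant
correction guaranteeing a proper rotation), and divide the RMSD by the
number of such columns. "Number of aligned residues" is read as *matched
residue pairs*, not total alignment length — the statistic should reward
alignments that match the right residues, and unmatched columns carry no
coordinates to deviate. Columns lacking a coordinate are skipped, never
imputed; fewer than 3 usable columns is an error. For degenerate
(collinear) point sets the RMSD is still well-defined though the rotation
is not unique.

## 5. Synthetic data: what it emulates, what it does not

All test inputs are generated in code, seeded, and pure functions of
their arguments:

* `make_covarying_msa` draws i.i.d. rows from a background composition
  (uniform by default; `mutation_rate < 1` switches to mutated copies of a
  consensus) and plants covarying column pairs: with probability
  `coupling`, the partner column's letter is a fixed permutation image of
  the source column's letter. This reproduces the *statistical* signature
  of coevolving pairs that the builders and rankings are designed to
  detect. It does **not** emulate phylogenetic correlation between rows
  (star topology only), realistic amino-acid composition, indel history,
  or secondary-structure constraints. A green builder test therefore
  establishes that the statistics recover planted dependence at realistic
  depth (500 rows) — not that the resulting matrices match any published
  matrix built from real families.
* `make_toy_structure` produces ideal-geometry Cα traces (helix: radius
  2.3 Å, rise 1.5 Å, 100°/residue, giving consecutive Cα–Cα ≈ 3.8 Å;
  hairpin: two antiparallel strands 4.8 Å apart), sufficient to exercise
  contact derivation and superposition, and nothing more.
* `make_random_corrmap` / `make_random_embeddings` provide structureless
  random inputs for property tests.

Defaults used in the acceptance suite (depth 500, 20 seeded replicates,
perfect coupling, 15-column families) were fixed before the criteria were
evaluated and are not tuned to outcomes.

## 6. Numerical and degenerate-input choices

* Scores are doubles throughout; integer matrix files are parsed to
  reals because `w2`-weighted mixtures are non-integer.
* Score self-consistency (`score_alignment` equals the emitted score) is
  asserted to 1e-9 absolute.
* Non-standard residues: B→D, Z→E, J→L, U→C, O→K; X and any other letter
  becomes an internal unknown that scores the minimum off-diagonal entry
  of the matrix in use. Non-letter characters are hard errors naming the
  record and position.
* Asymmetric dense correlation maps are symmetrized by averaging (the use
  is undirected; attention-derived maps are often asymmetric); the
  diagonal is zeroed. Sparse triplet files are 1-based and mirrored.
* Empty pair selections are valid (the aligner degrades to plain Gotoh);
  empty sequences are errors.
* `select_pairs` requires strictly positive weights, so zero cells never
  enter the partner set even at cutoff 0.
* MI of columns with no gap-free row pair is 0 by convention; mfDCA
  errors on a singular covariance with advice to raise the pseudocount.

## 7. Known limitations

* The aligner is `O(n·m·partners·W)` time in pure R; fine at desk scale
  (hundreds of residues), not tuned for proteome-wide use.
* Local alignment is out of scope by design: the correlation maps the
  method consumes describe complete sequences, and their meaning for
  subdomains is not established.
* The package never runs a language model; correlation maps and embedding
  matrices are inputs. The map-production recipe (which attention layers,
  what normalization) is deliberately outside the package boundary.
* The gate schedule's numeric thresholds are conventions, not validated
  calibration; treat them as starting points.
* Stockholm reading keeps sequence lines only (annotation is dropped);
  the `pair` alignment format mirrors the EMBOSS needle block layout but
  is not bit-compatible with EMBOSS output.
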