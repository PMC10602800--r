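# coralign

Correlation-map-guided global protein sequence alignment.

## The problem

Pairwise alignments of remote homologs — sequence identity in the 20–35%
"twilight zone" — are unreliable when scored with a single-residue
substitution matrix alone. Yet homologous families carry a second,
largely untapped signal: strongly **correlated position pairs**, where a
substitution at one position is compensated by a specific substitution at
the partner position. These pairs track structural contacts and
longer-range contextual dependencies, and they survive even when the two
proteins have drifted apart in sequence, changed conformation, or (as with
intrinsically disordered proteins) have no single stable fold at all.

`coralign` implements a global aligner that uses those pairs directly.
For sequences A and B, the score of matching residue `i` of A with residue
`k` of B is

    S(i,k) = w1 * S20(A[i], B[k]) + w2 * S400(A[i], A[j], B[k], B[l])

where `S20` is a conventional 20×20 substitution matrix (e.g. BLOSUM62),
`S400` is a 400×400 **pair-substitution matrix** scoring the replacement of
the residue pair `(A[i], A[j])` by `(B[k], B[l])`, `j` ranges over the
partners of `i` selected from a per-sequence **correlation map** (produced
externally, e.g. by a protein language model, or synthetically), and `l`
is probed over a sliding window around the diagonal projection
`k + (j - i)`. Defaults: `w1 = 1.0`, `w2 = 0.1` (valid range 0–0.9), with
affine gap penalties (`gap_open` p, `gap_extend` q; a gap of length L
costs `p + L*q`). With `w2 = 0` the aligner reduces exactly to
Needleman–Wunsch/Gotoh.

The package also contains the full supporting toolchain:

| Area | Functions |
|---|---|
| Sequence/MSA/alignment I/O | `read_fasta`, `read_msa` (FASTA/Stockholm), `write_alignment` |
| Score matrices | `read_matrix20` (NCBI/EMBOSS layout, bundled BLOSUM62/EPAM250), `parse_matrix400` (documented 4-tuple TSV) |
| Correlation/contact maps | `load_corrmap`, `select_pairs`, `contacts_from_coords` |
| The aligner | `align_global`, `pair_bonus`, `score_alignment`, `sequence_identity`, `align_iterative` |
| Matrix builders from MSAs | `column_mi` (mutual information), `mfdca_di` (mean-field direct coupling analysis), `build_ps400` (400×400 log-odds), `build_protsub` (20×20 log-odds) |
| Embedding signatures | `compress_embedding` (2D-DCT truncation to 5×44 / 3×85), `quantize`, `embedding_distance` (L1), `gate_parameters` (homolog-closeness gating of `w2` and the map cutoff) |
| Structure evaluation | `kabsch_superpose`, `normalized_aligned_rmsd` (RMSD over matched columns divided by their count) |
| Synthetic data | `make_covarying_msa`, `make_toy_structure`, `make_random_corrmap`, `make_random_embeddings` |
| CLI | `coralign_main()`; installed script `exec/coralign` with subcommands `align`, `build-ps400`, `build-protsub`, `embed-distance`, `gate`, `contact-map`, `eval-rmsd`, `synth` |

Everything is testable offline: the synthetic generators produce every
input class the toolkit consumes.

## Worked example

Build a pair-substitution matrix from a synthetic covarying family, then
align two of its rows with and without the pair term:

```r
library(coralign)

fam <- make_covarying_msa(80, 40,
  planted_pairs = list(list(i = 4L, j = 12L), list(i = 20L, j = 30L)),
  coupling = 0.9, seed = 42)
ps400 <- build_ps400(fam, ranking_method = "mfdca", top_fraction = 0.15)

seqA <- protein_seq("famA", fam$rows[1])
seqB <- protein_seq("famB", fam$rows[2])
map  <- make_random_corrmap(40, density = 0.15, seed = 7)
ctx  <- pair_bonus_ctx(select_pairs(corrmap_rescale(map), cutoff = 0.5), ps400)
b62  <- read_matrix20("BLOSUM62")
res  <- align_global(seqA, seqB, b62,
                     dp_params(w2 = 0.1, gap_open = 10, gap_extend = 0.5), ctx)
cat(write_alignment(res, seqA, seqB, format = "pair", m20 = b62), sep = "\n")
```

Output (abridged):

```
# A: famA (40 aa)
# B: famB (40 aa)
# Score: -5.0126
# Identity: 17.6% (9/51 columns)

famA    1 VMVNIRQTGC VVLVSITKFS TTCV--WADP NSWTKI---- -----NWWSG   39
          |        | : :  :  |  |  |  |  |   |  :          :| : 
famB    1 V--------C M-MHKMQDFY TIGVIHWQIP --WQPVIQAN WSWGHDWDTS   39
```

The header reports the combined DP score and percent identity over all
alignment columns (9 identical matches / 51 columns = 17.6%, i.e. a
twilight-zone pair); `|` marks identities, `:` positive BLOSUM62 scores.
`score_alignment(res, ...)` re-derives the score from the op list and is
guaranteed to equal `res$score`.

To judge a candidate alignment against structures, use the normalized
congruence statistic — the Kabsch RMSD over matched columns divided by the
number of matched columns (smaller is better):

```r
normalized_aligned_rmsd(res, coordsA, coordsB)   # e.g. 0.15 A per residue
```

## Command line

```sh
CORALIGN=$(Rscript -e 'cat(system.file("exec", "coralign", package = "coralign"))')
Rscript "$CORALIGN" align A.fa B.fa --matrix20 BLOSUM62 \
    --matrix400 ps400.tsv --corr map.txt --w2 0.1 --out aln.txt
Rscript "$CORALIGN" build-ps400 --msa-dir msas/ --method mfdca --out ps400.tsv
```

Exit codes: 0 success, 2 usage/input error.

## Further reading

`vignettes/coralign-methods.Rmd` documents the model, the pair-bonus
semantics, every tunable parameter with its default and rationale, the
synthetic-data generators' scope, and known limitations.
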