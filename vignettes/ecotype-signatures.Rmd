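---
title: "Methods: replication-strand-aware genome and proteome signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication-strand-aware genome and proteome signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosig)
```

# Scope and model

`ecosig` analyses panels of complete bacterial replicons for the joint
footprint of replication, mutational pressure and selection. Its
motivating system is a panel of closely related marine picocyanobacterial
ecotypes in which some lineages show pronounced replication-strand
asymmetry in synonymous codon usage while others — typically the more
reduced, A+T-rich genomes — do not. Every stage is an ordinary, exported R
function; `run_all()` only sequences them.

## Replichores from GC skew

On most bacterial chromosomes the leading strand is enriched in G (and T),
so the per-window skew $(G-C)/(G+C)$ changes sign at the replication
origin and terminus. We integrate the per-window skew into a cumulative
curve and place **oriC at its global minimum** and **ter at its global
maximum**: moving from oriC toward ter along increasing coordinates, the
plus strand is the G-rich leading strand and the cumulative curve rises.
The default window is 10 kb, non-overlapping, wrapping across the junction
of a circular genome (`step < window` gives overlapping windows). Windows
without G or C score 0; a perfectly flat cumulative curve is reported as
"no replichore structure" rather than returning an arbitrary extremum.

Predictions are window-quantized, so the expected error is on the order of
one window. Classification then only needs the two positions: a gene whose
midpoint lies on the oriC→ter arc (replichore 1) is leading-strand encoded
when its coding strand is `+`, lagging when `-`, and vice versa on
replichore 2. Genes straddling a boundary are classified by midpoint; a
midpoint exactly on ter counts as replichore 1 (the tie is otherwise
arbitrary and is documented so results are reproducible). The curated
validation the original analyses performed by eye — flanking gene context
at the origin — is not automated; a DnaA-box scan
(`find_dnaa_boxes()`, 9-mer consensus TTATCCACA, ≤ 1 mismatch, ±5 kb) plus
explicit `oriC`/`ter` arguments on `replichore_map()` replace it, because
gene-context validation would require a homology search pipeline.

## Codon usage and ordination

RSCU for codon $c$ in a synonymous family of size $n$ is
$n\,x_c/\sum_{c'} x_{c'}$; Met, Trp and stops carry no synonymous choice
and are excluded, leaving 59 columns. A family absent from a gene scores 0
for all its codons (the convention of the classic codon-usage tools,
rather than row-mean imputation). GC3s/GT3s are computed over the same 59
codons — i.e. only where the third position is free to vary synonymously.

Correspondence analysis is run **on the RSCU matrix itself**, matching the
long-standing behaviour of codon-usage ordination software: the matrix is
scaled to a grand total of 1, standardized residuals
$(P - rc^\top)/\sqrt{rc^\top}$ are decomposed by SVD, and row/column
principal coordinates plus inertia fractions are returned. Axis signs are
arbitrary; downstream comparisons use $|r|$. The implementation is checked
in the test suite against an independent CA implementation
(`MASS::corresp`) to $10^{-10}$.

Strand asymmetry is tested per codon with a 2×2 chi-square of
(codon vs its synonymous alternatives) × (leading vs lagging), which keeps
amino-acid composition differences between the strand classes from
confounding the synonymous signal. No continuity correction is applied;
when any expected count is below 5 the p-value comes from Fisher's exact
test. P-values are reported raw with the conventional $p < 0.001$ screen —
the screen the motivating analyses used — and a Bonferroni flag is
available for sensitivity analysis.

## Dinucleotide signatures

$\rho^*_{XY} = f^*_{XY}/(f^*_X f^*_Y)$ is computed on the
strand-symmetrized sequence: the sequence and its reverse complement are
counted separately (never across the junction between the two copies) and
pooled, which makes complementary pairs exactly equal (16 dinucleotides,
10 distinct values). Circular genomes contribute the wrap dinucleotide
within each strand copy — an $O(1/L)$ effect, included for exactness.
Over/under-representation uses the conventional inclusive cutoffs 1.23 and
0.78. Group-level contrasts are reported descriptively (per-group mean ±
SD per dinucleotide); no inferential test is attached because none is
standard for this statistic. Whether to profile whole genomes or
concatenated coding regions was an open choice; whole genomes are used, as
the signature is a property of the full genomic context.

## Proteome traits

Amino-acid usage is standardized as a **ratio** to a reference proteome
(reference maps to 1 for every residue), because the downstream heatmap
semantics are over/under-representation around a neutral value; a z-score
variant is available behind `method = "zscore"`. Clustering is
single-linkage on Euclidean distances, reported with the heatmap matrix
and per-cell over/normal/under classes (band ±0.1 around neutral by
default; the bin boundary is configurable since no canonical value
exists).

Per-protein indices use the published constants: Kyte–Doolittle hydropathy
for GRAVY, the Guruprasad 400-entry dipeptide weight table for the
instability index (packaged with a checksum test; dipeptides containing a
nonstandard residue contribute the neutral weight 1), and the
Bjellqvist/ExPASy pKa set for the isoelectric point (side chains D 4.05,
E 4.45, H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0; C-terminus 3.55; N-terminus
residue-specific where defined, otherwise 7.5). pI is found by bisection on
[0, 14]; the net-charge function is monotone decreasing in pH, so the
bisection always converges (tolerance $10^{-4}$ charge units by default).

The secondary-structure summary is a deliberately simple propensity
heuristic — smoothed (window 5) Chou–Fasman helix/sheet propensities,
argmax against a coil baseline of 1 — suitable for *ordering* proteome
means, not for per-protein structure prediction. Dedicated predictors are
out of scope, and no numerical secondary-structure percentages should be
compared against predictions from such tools.

## Orthologs, dN/dS, synteny, remnants

Homology searches are external: the package consumes the standard
12-column tabular hit format plus `qlen`/`slen`. The ortholog screen is
identity ≥ 60%, length difference ≤ 20% **relative to the longer
sequence** (the natural symmetric choice), E ≤ 1e-20, followed by
reciprocal-best-hit reduction (best = lowest E, then highest identity,
then highest bit score, then lexicographic id — a total order that makes
reruns deterministic). Core groups are **full RBH cliques** with exactly
one member per genome: stricter than single-linkage closure and immune to
paralog chaining; `linkage = "single"` gives the permissive alternative.

dN/dS uses the modified Nei–Gojobori site counting: at each codon
position the transition route has probability $R/(R+1)$ and each
transversion $1/(2(R+1))$, where $R$ is the transition/transversion
*ratio* (transitions over total transversions), so $R = 0.5$ recovers the
classic unweighted 1/3-per-route counting. Site counts are averaged over
the two sequences; changes producing stop codons count as nonsynonymous.
Observed differences at codons differing in 2–3 positions are averaged
with equal weight over substitution pathways avoiding stop codons (all
pathways, counted with stops allowed, only when every route is blocked — a
rare degenerate case). The Jukes–Cantor correction
$d = -\tfrac34\ln(1-\tfrac43 p)$ is applied to both proportions;
$p \ge 3/4$ leaves the estimate undefined and flagged `saturated`,
distinct from `missing` inputs, since both occur in real core-genome scans
and downstream Venn counts must exclude them explicitly. $R$ defaults to
an estimate from fourfold-degenerate third positions of the input pair
(falling back to 0.5 when uninformative), because the upstream tool
setting the motivating analyses used is not recoverable.

Synteny comparison linearizes both chromosomes at their origins, emits one
line per ortholog pair (origin-relative positions, same-strand flag) and
counts **signed-adjacency breakpoints**: consecutive orthologs along A
whose counterparts are not adjacent in B with preserved relative
orientation. The count is an addition for testability — the figure-style
output is the pair-line table — and the definition is stated exactly so
the trivial cases (identity → 0; a single inverted block of $k$ genes →
2) are forced.

Remnant screening applies identity ≥ 30%, aligned length ≥ 15 aa,
E < 1e-3 to translated-search hits of intergenic segments, merges
overlapping passing hits per segment, and reports each merged region with
its G+C. `naive_translated_search()` is a test-scale six-frame
Smith–Waterman stand-in for an external translated search, usable whenever
BLAST-class output is unavailable.

# The synthetic generator

`simulate_genome()` builds a replicon in which every measured signal is
planted and recorded in a truth object: genes alternate strands with
A+T-enriched spacers between them; per-gene codon usage is a Dirichlet
draw (concentration 40) around a composition prior matching the target
G+C; synonymous third positions of leading-strand genes are switched
toward G/T with probability δ and those of lagging-strand genes toward
A/C with the same probability — the two coding strands experience
complementary mutational pressure, which is what a single asymmetric
mutation process acting on the chromosome produces; spacers carry the same
keto excess on the leading strand. Decayed gene copies (per-base
substitution rate 0.10 with a 75% A/T-biased spectrum) are inserted into
spacers as remnants.

Defaults describe a reduced, A+T-rich marine-cyanobacterium-like replicon
at desk scale: 200 kb, 150 genes of mean 300 codons, G+C 0.35, spacers 5
points more A+T-rich, δ = 0.10, ten remnants, two structural RNAs. These
sizes are chosen so that a full property-recovery suite runs in about a
minute while every statistic retains comfortable power; the strand-bias
panels used for the ordination checks raise δ to 0.15 (planted) against 0
(null), and divergence panels are produced by `simulate_panel()` —
ancestral genes evolved along per-genome branches by a Gillespie codon
walk with ts/tv ratio R and nonsynonymous acceptance ω, stop-creating
mutations rejected.

What the generator does **not** emulate: operons and transcription-
coupled repair, gene-density asymmetry between replichores, indel
evolution, recombination and horizontal transfer, rRNA operon structure,
and realistic E-values — `make_hit_table()`'s surrogate
$E = qlen \cdot slen \cdot 2^{-S/2}$ is deterministic and monotone in the
alignment score, which is exactly what threshold logic needs and nothing
more. Passing recovery tests therefore demonstrates the correctness of
the estimators under a known model, not robustness to every property of
real sequence data.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive convention is converted at the parsing boundary. Genes
  spanning the circular junction are stored unwrapped (`end > L`) and
  reduced modulo `L` only when slicing.
* Ambiguity codes: N is excluded from all composition counts, codons and
  dinucleotides containing non-ACGT characters are skipped, and CDS with
  frame or internal-stop pathologies are skipped with a warning — repair
  is never attempted.
* CA drops all-zero rows/columns before decomposition and re-embeds the
  dropped genes as NA coordinates; a rank-zero (all-identical) matrix
  returns zero coordinates and zero inertia rather than erroring.
* The chi-square uses the closed 2×2 form; ties in the RBH ordering are
  broken deterministically; single-linkage merge heights are guaranteed
  non-decreasing by `hclust`.
* All randomness is seeded: generator configs require a seed, and the
  pipeline seeds once at entry. Identical config + seed gives
  byte-identical outputs.

# Known limitations

Single-replicon genomes only (no draft assemblies or plasmids); no gene
prediction; archaeal multi-origin replication is out of scope. The
ordination separates strand classes only when the planted (or real)
asymmetry is strong relative to gene-to-gene codon-usage noise — with the
generator's gene lengths the two-cluster structure emerges cleanly at
δ ≈ 0.15 and the axis–GT3s correlation from δ ≈ 0.1. Real-genome values
of published analyses additionally depend on the exact annotation release
and the behaviour of the external search tools those analyses used, which
is why this package's tests are recovery- and oracle-based rather than
tied to published per-genome numbers.
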