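---
title: "Annotating fucoxanthin chlorophyll a/c-binding proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating fucoxanthin chlorophyll a/c-binding proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diatoms, haptophytes and related Chromista harvest light with fucoxanthin
chlorophyll a/c-binding proteins (FCPs), a branch of the light-harvesting
complex (LHC) superfamily. An FCP repertoire splits into families with
distinct roles: Lhcf (the main PSII-associated antenna), Lhcr
(PSI-associated), Lhcx (photoprotection), and Lhcz, a sister clade of Lhcr
of unknown function. Annotating a newly sequenced proteome therefore means
answering four questions in sequence:

1. **Which proteins are FCPs at all?** Found by local-alignment similarity
   to characterized FCPs of reference species.
2. **Which family does each candidate belong to?** Decided by the best
   similarity match against labeled reference panels, with a cladogram as
   arbiter when the best-hit evidence is weak.
3. **How does the Lhcf family structure across lineages?** A
   neighbor-joining cladogram of Lhcf proteins from several species
   partitions them into lineage-restricted groups (A: mainly haptophyte,
   B: haptophyte-only, C: diatom-only, D: brown-seaweed-only).
4. **Which pigment-binding residues are conserved?** Chlorophyll and
   fucoxanthin ligands known from a crystallographic reference structure
   are transferred onto each target Lhcf through alignment columns, and
   per-site presence percentages are reported.

`fcptools` implements this workflow end to end with its own alignment,
distance and tree primitives, plus a simulator that generates every input
with known truth.

## Sequence comparison and E-values

Local alignments are computed by Smith–Waterman dynamic programming under
affine gap penalties: a gap of length $L$ costs
$\text{open} + L\cdot\text{extend}$. The defaults are BLOSUM62 with open
11 / extend 1 — the classic protein-search parameterization — so scores
are directly comparable to conventional BLASTP output. Ties among
equal-scoring optima break to the lowest-coordinate end cell, and the
score floors at zero (two sequences with no positively scoring residue
pair return an empty alignment).

Raw scores $S$ are normalized to bit scores
$S' = (\lambda S - \ln K)/\ln 2$ with the standard gapped-BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$ (held in `fcp_config()`, not in
code), and expectations follow Karlin–Altschul:
$E = m\,n\,2^{-S'}$ for query length $m$ and database size $n$ residues.
Discovery keeps hits with $E < 10^{-40}$, the stringency used in FCP
survey work. That cutoff is deliberately conservative: with ~200-residue
queries it corresponds to roughly 50% identity over the full protein,
which separates genuine family members from the background while leaving
cross-family relationships (~25% identity) below threshold — which is why
family assignment relies on the *best* hit rather than on mere presence
of a hit.

A candidate's family is the family of its single best bit-score hit. The
call is flagged *ambiguous* when fewer than two qualifying hits exist,
when the best score ties across families, or when the bit-score margin
between the best and second-best family is under `margin_bits` (default
10 bits ≈ 26 raw score points; the threshold is a design choice — the
situation it guards against is a classification hanging on one weak
match). Ambiguous candidates are re-decided by the cladogram: the
smallest enclosing clade with at least `k_clade = 3` labeled reference
leaves votes by majority family, and a tied vote leaves the sequence
`unclassified` rather than forcing a label. The pipeline can therefore
always emit "ambiguous" — important because real repertoires contain
sequences (an Lhcx-like protein, say) that resist confident placement.

## Alignments, distances, trees

The progressive aligner builds all-against-all global pairwise alignments,
converts them to p-distances, derives a neighbor-joining guide tree, and
merges profiles leaf-to-root with global profile–profile alignment (mean
sum-of-pairs column scores, affine gaps). There is no iterative
refinement: the downstream statistics — distance matrices, presence
percentages — are robust to modest column-level differences, and exact
reproduction of any particular aligner's columns is not a goal. The one
hard invariant, checked after every alignment, is that each row ungaps to
its input sequence. Columns are reported 1-based, matching residue
convention; 0-based indices exist only internally.

Distances use pairwise deletion (columns where either row is gapped are
skipped) and the 20-state Jukes–Cantor correction
$d = -\tfrac{19}{20}\ln\!\left(1 - \tfrac{20}{19}p\right)$, the protein
analogue of the model conventionally paired with neighbor-joining
cladograms; the state count is 20 because these are amino-acid sequences.
$p \ge 19/20$ is saturated and errors rather than returning a number.

Neighbor-joining is the standard Q-criterion algorithm with two
determinism guarantees: equal-minimum Q pairs join in lexicographic id
order, and negative branch lengths are clamped to zero with the total
deficit recorded on the tree (`clamped_deficit` attribute). NJ is exact on
additive matrices, which the test suite exploits as an oracle.

Bootstrap supports resample alignment columns with replacement,
recompute distances and the NJ tree per replicate, and score each
internal edge of the full-data tree by the percentage of replicates
containing the same bipartition. The default is 100 replicates, the
customary setting for published cladograms at this scale. One root seed
drives the run; per-replicate seeds are drawn once from it, so results
are reproducible and independent of evaluation order. Supports are stored
both as node labels and keyed by bipartition, which keeps them stable
under the midpoint rooting used for clade extraction.

Lhcf groups are read off the (midpoint-rooted) cladogram as maximal
clades with bootstrap support at least `min_support = 50` and at least
`min_size = 3` leaves: all-haptophyte clades form group B, all-diatom
group C, all-seaweed group D, and mixed clades with a haptophyte
majority, at least one diatom and no seaweed form group A. Larger clades
are considered first, so a qualifying clade absorbs its sub-clades;
leaves outside any qualifying clade stay `unassigned`. The support and
size thresholds are design choices — published cladograms display
supports only for main nodes, so no published threshold exists to adopt.
The Lhcz family is detected without a hard-coded member list: it is
reported as the smallest clade containing the supplied Lhcz-like
reference sequences, whatever Lhcr candidates co-cluster there.

## Binding-site transfer

Each annotation row names a reference sequence, a 1-based position, a
primary residue and optional alternates (e.g. "T or V" cells of the
published tables), a ligand class (central ligand vs H-bond), and a
conserved/not-conserved flag. On loading, every row is cross-checked
against the reference sequence; a residue disagreement is an error naming
the site, not a warning.

Transfer locates the reference residue's alignment column and inspects
each target at that column, then at residue offsets $\pm 1 \ldots \pm w$
(nearest first, negative side first on ties). Offsets count *residues* of
the target, skipping gaps, because a "3 amino-acid shift" is a statement
about the peptide, not about alignment columns. The default window
$w = 3$ equals the largest shift documented in this family — the Fx302
tyrosine, which sits three residues downstream in the target species —
so that site is recognized at `offset = +3` exactly when $w \ge 3$. A
match through an alternate residue is flagged `via_alternate`, keeping
conserved and non-conserved table columns separable. `X` never matches
anything.

Percentages are `round(100 * n_present / n_total)` with half-up rounding
(the published tables print integers; half-up reproduces their
convention). The denominator is always the full set of target-family
members: whether fragmentary proteins should be excluded is unstated in
the source material, and including all members is the reproducible
choice. Two documented quirks are handled explicitly: fucoxanthin sites
Fx306/Fx307 are representable in the annotation table but excluded from
default reports (the published comparison is restricted to Fx301–305),
and one published "25%" cell is arithmetically inconsistent with any
numerator over the stated denominator — the package always reports the
full-family percentage and does not attempt to reproduce that cell.

## The synthetic-data generator

Every pipeline stage is validated against simulated families with known
truth, because the original sequence sets are not redistributable inside
the package. The generator's design goals are analytic checkability and
clean truth, not biological realism:

* **Trees**: Yule (pure-birth) topologies rescaled to unit root-to-tip
  depth, so the `rate` parameter *is* the expected root-to-tip
  divergence in substitutions per site.
* **Substitution**: uniform-exchange 20-state model — along a branch of
  length $d$ a site keeps its residue with probability
  $\tfrac{1}{20} + \tfrac{19}{20}e^{-\frac{20}{19}d}$. This matches the
  Jukes–Cantor assumption used downstream, so distance recovery
  ($\hat p \to \hat d$) is exactly checkable.
* **Defaults**: `rate = 0.26` gives ~60% pairwise within-family identity
  (typical of a protein family), `between_divergence = 0.7` leaves ~25%
  between-family identity; sequences are 210–240 residues, the size of a
  mature LHC-family protein.
* **Binding sites** are implanted *after* evolution: each target retains
  the ligand residue with its retention probability (or an exact quota,
  below), and a window around each site is scrubbed of chance
  occurrences of the allowed residues first. Retention is therefore the
  only signal a transfer within the window can find, giving exact
  binomial truth for presence percentages. Shifted sites place the
  residue at a fixed or random displacement.
* **No indels**: alignment machinery is exercised with substitution-only
  families plus hand-made gapped fixtures in the tests.

The study-scale emulation (`simulate_study()`) instantiates the full
annotation problem at the dimensions of the reported repertoire, which
are treated as fixed study conditions: 52 FCPs (28 Lhcf across two haptophyte lineage
groups, 12 Lhcr of which 3 in the Lhcz sub-clade, 12 Lhcx) hidden among
100 random background proteins; diatom reference panels of 12 sequences
per family; a 134-sequence, eight-species Lhcf panel structured
`((A,C),(B,D))` with group sizes 44/30/40/20; and per-site retentions
equal to the published presence percentages. Retention uses an exact
quota (`round(retention * 28)` members) rather than binomial draws, so a
correct pipeline recovers each printed percentage to within one count in
the numerator and the comparison is meaningful at the printed precision.
Divergence settings (family roots at 0.55 substitutions/site from a
common ancestor, lineage-group edges at 0.06, within-group depth 0.12)
put within-family identity near 60–75% and between-family identity near
25% — the regime in which best-hit classification is expected to work,
and the E-value arithmetic places family members ~20 orders of magnitude
below the discovery cutoff while background and cross-family pairs stay
well above it.

What passing these tests shows — and does not show. Recovery of the
study's counts from the emulation demonstrates that the pipeline's logic
(thresholding, best-hit bookkeeping, clade rules, column mapping,
rounding) is correct under the stated statistical conditions. It does not
demonstrate column-level agreement with any external aligner on real
sequences, nor that real FCP families satisfy the uniform-substitution
assumptions; percentages on real data would inherit alignment
uncertainty that the gap-free emulation deliberately removes.

## Numerical and engineering choices

* Alignment kernels are compiled (Rcpp); the database search uses a
  score-only rolling-row Smith–Waterman pass and computes full tracebacks
  only for hits below the E-value threshold.
* Profile merges score column pairs by matrix products of residue-count
  profiles, so each merge is one BLAS call plus a quadratic DP.
* All tie-breaks (SW end cell, NJ pair choice, transfer offset order,
  profile DP moves) are deterministic, making every output a pure
  function of inputs, config and seed.
* The bootstrap guards against resampled saturation by capping p just
  under 19/20 inside replicates (the full-data matrix still errors on
  saturation, which is the user-facing contract).
* Problem sizes in the shipped tests — 200 additive matrices of 5–8
  taxa, 50-seed alignment-oracle sweeps, 30-seed retention recovery at
  28 sequences, 20-seed classification recovery at 60 sequences, one
  study-scale run of ~290 sequences with 100 bootstrap replicates — were
  chosen to exercise each claim at the scale the study reports while
  keeping a full suite run in the minutes range on one CPU.

## Limitations

* No profile/HMM search and no heuristic seeding: discovery is full
  dynamic programming, appropriate at repertoire scale (hundreds of
  sequences), not at database scale.
* No maximum-likelihood or Bayesian tree inference; rooting is midpoint
  and only for clade extraction and display.
* Transfer asserts residue conservation, not function: a transferred
  site is a candidate, and only structural work can confirm binding.
* The simulator's uniform substitution model and indel-free families are
  idealizations; conclusions about real proteomes require the real
  sequence sets.
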