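---
title: "Methods: light-chain sequon analysis with lcsequon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light-chain sequon analysis with lcsequon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsequon)
```

## The scientific problem

Antibody light chains (LCs) come in two isotypes, κ and λ, each derived
from germline V and J gene segments and diversified by somatic
hypermutation. N-linked glycosylation of the variable (V) domain requires
the sequon motif NxS/T — asparagine, any residue except proline, then
serine or threonine — and most V-domain sequons are created by somatic
mutation rather than encoded in the germline. Sequons, and hence
glycosylation, are over-represented among κ LCs from patients with AL
amyloidosis relative to multiple myeloma (MM) clones and the polyclonal
repertoire. `lcsequon` implements the sequence and structure analyses
needed to quantify that association: where sequons sit on the IMGT
scaffold, how mutation load differs between sequon-bearing and sequon-free
LCs, how strongly groups differ in sequon prevalence, and whether sequon
positions are solvent-exposed in native V-domains and in amyloid fibril
structures.

## Numbering model

Every analysis is anchored on the IMGT unique numbering of the V-domain,
taken here as a 127-position scaffold. Region boundaries default to the
IMGT convention (FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104,
CDR3 105–117, FR4 118–127) and IMGT "strand" spans (A, B, C, C′, C″, D,
E, F, G) ship as editable TSV tables, because strands are bookkeeping
intervals rather than strict secondary-structure elements. A motif of
span 3 cannot start in the last two scaffold positions, so 125 positions
are *detectable* (`count_detectable_positions(127, 3)`), and positional
histograms and correlations run over those 125 slots, including empty
ones.

Numbering is transferred by global pairwise alignment of the query to its
assigned germline V gene concatenated with the locus J gene
(Needleman–Wunsch with affine gaps via Biostrings; BLOSUM62, gap open 10,
gap extend 1 — library defaults chosen once and configurable). Query
residues inherit the IMGT position of the germline residue they align to;
residues in insertion columns get markers anchored to the preceding
canonical position (`"50.1"`); germline residues deleted from the query
leave their position unoccupied. The CDR3 stretch between FR3 (≤ 104) and
FR4 (≥ 118) is renumbered inward from both ends (105, 106, … from the
left; …, 116, 117 from the right; overflow beyond 13 residues becomes
insertions anchored at 111), matching the IMGT junction convention and
acknowledging that CDR3 is structurally heterogeneous, so positional
claims there are weaker than elsewhere. Alignments below 50% identity are
flagged as having a dubious germline assignment; sequences with
non-standard residue letters are excluded upstream and accounted for in
the pipeline's exclusion report.

## Sequon detection

Detection uses the regular expression `N(?=[^P][ST])` (lookahead, so
overlapping motifs such as both hits in `NNSS` are reported); the
cysteine variant NxC is scanned separately with `N(?=[^P]C)` and never
merged into NxS/T statistics. Reporting all matches is a superset of
non-overlapping regex semantics; presence/absence and first-sequon
analyses — which is what the group statistics consume — are invariant to
that choice. Each hit carries a context window at offsets −5..+5 around
the asparagine (padded with `-` at termini, never silently truncated),
the +2 residue identity (threonine at +2 favours glycosylation more than
serine), and two germline flags: whether the position is a *progenitor*
site (a single nucleotide change away from a sequon) and whether the
germline itself encodes a sequon there; a third flag records whether the
three motif residues are unchanged from germline, since a germline
sequon destroyed and re-created by mutation is otherwise ambiguous.
When a sequence carries several sequons, positional analyses use only the
most N-terminal one. Hits at insertion markers have no canonical position
and are excluded from histograms (with a message) while still counting
toward presence/absence.

## Mutation load

A V-domain with S substitutions, I insertions and D deletions relative to
a germline of length L has mutation fraction

$$\frac{S}{L} + \frac{I}{L+I} + \frac{D}{L+D},$$

zero exactly when the sequence is germline-identical, strictly increasing
in each count, and equal to the Hamming fraction when only substitutions
occur. It is reported both as a fraction and as a percentage of germline
length. Because the analysis is protein-only, non-templated junction
residues in CDR3 are counted as substitutions against the V+J reference;
this is a documented overestimate of true somatic mutation load that
affects all groups equally.

## Statistics

Prevalence comparisons use 2×2 tables (with/without sequon × group). The
cross-product odds ratio carries a Wald 95% CI,
$\exp(\log\mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. An adjustment
factor of 0.1 can be added to the cells to avoid division by zero; the
default policy applies it *only when some cell is zero*, which leaves
all-non-zero tables exact, with an always-apply option available. The
logistic-regression estimator (binomial GLM, optionally stratified by
locus or precursor gene) equals the cross-product OR on unstratified
all-non-zero tables and falls back to the adjusted manual estimator, with
a warning, when a zero cell makes the likelihood separable. Printed
confidence intervals in the source literature for these cohorts are not
reproducible by standard Wald arithmetic, so only point estimates are
treated as reference values.

Mutation-load contrasts use the two-sided Wilcoxon rank-sum test, exact
when the combined sample is ≤ 20 without ties and normal-approximated
with tie/continuity correction otherwise. Families of tests (one family
per analysis: prevalence, per-gene, mutation contrasts) are adjusted by
Benjamini–Hochberg, with FDR ≤ 0.05 the conventional significance
threshold. Per-gene comparisons report only genes with at least 10
sequences in the index group (configurable). Positional histograms are
compared by Pearson correlation across all 125 detectable positions,
zero counts included; zero-variance histograms return an explicit
undefined flag. Logo matrices are per-offset residue frequencies (not
information content), excluding terminal padding from denominators.

## Structural exposure

Solvent-accessible surface area is computed by the Shrake–Rupley method:
each atom inflated by a probe radius (default 1.4 Å) and sampled with a
deterministic Fibonacci lattice of 960 points per atom; accessible area
is the fraction of points outside all neighbouring inflated atoms. The
engine is validated against closed-form one- and two-sphere areas.
Structures (PDB or mmCIF, via bio3d) keep author numbering and insertion
codes; alternate locations resolve to the highest-occupancy conformer
(ties to the first listed); chains without protein residues are skipped
with a warning.

Relative exposure divides a residue's SASA in context by a reference
maximum. The default reference is the *same residue's atoms in
isolation*, which bounds relative exposure in [0, 1], is exact for
residues with missing atoms, and needs no sidechain idealisation; the
widely used theoretical Gly-X-Gly maxima (Tien et al. 2013) ship as
`max_sasa_reference()` for users who prefer a fixed table. This
self-referencing normalisation was chosen because a fixed table makes the
isolated-residue sanity check (relative exposure ≈ 1) unattainable for
free termini, while a table recomputed by the package's own engine would
require idealised sidechain builders for all twenty residue types.

Classification: positions in the conserved heavy-chain interface set
(IMGT 42, 44, 49, 52, 55, 103, 118) are `interface` regardless of
exposure; otherwise relative exposure ≥ 10% is `surface`, below is
`core`. The threshold rule replaces manual review of borderline residues
with a deterministic rule plus a low-confidence flag for exposures within
2 percentage points of the threshold. Raising the threshold can only move
residues from surface to core (monotonicity), and adding occluding
context chains can only reduce SASA — both are tested invariants. For
fibrils, exposures should be computed with stacked neighbour layers as
context, since burial is meaningless for an isolated chain. Sequon
positions absent from a structure's coordinates are reported
`unresolved`; the package reports exposure only and does not attempt the
qualitative concave-surface judgments sometimes made for fibril
surfaces.

## Synthetic data

The generator emulates what the analysis assumes about real repertoires:
sequences are germline V+J concatenations carrying independent
per-residue substitutions (uniform over the 19 alternative residues —
never ambiguity codes), and, with a group-dependent conversion
probability, one progenitor site rewritten into a sequon (N at the site;
S or T at +2, threonine with configurable probability, default favouring
T for AL-like groups; a proline placed at +1 by a background substitution
is restored to germline so the introduced motif is always valid).
Sequon-bearing sequences can receive an extra substitution increment to
emulate the observed association between sequons and higher mutation
load. Background substitutions may create *spontaneous* sequons at other
positions, as in reality; the truth table distinguishes introduced from
spontaneous. Indels default to off, keeping numbering tests crisp; they
can be enabled for alignment stress tests. Identical seed and
configuration give byte-identical output.

What the generator does *not* emulate: somatic-hypermutation hotspot
motifs, clonal lineage structure, allele-level germline variation, or
realistic CDR3 junction diversity. Tests passing on synthetic data
therefore demonstrate the correctness and calibration of the machinery,
not biological conclusions about real repertoires. The bundled germline
bundle itself is synthetic (canonical V-domain architecture with
conserved Cys23/Trp41/Cys104 and named after commonly analysed genes);
the progenitor table is likewise a reconstructed fixture, and both are
user-replaceable inputs.

Toy structures serve the exposure classifier: an idealised fully extended
peptide (every residue solvent-exposed), a cubic poly-alanine lattice
(centre residue buried), and a cross-β stack of serpentine three-strand
layers at a 4.8 Å rise (middle-strand residues face the packed interior,
outer strands the solvent). Geometry uses standard bond lengths and
angles placed by internal-coordinate construction.

## Calibration checks and problem sizes

The test suite verifies, among others: detector equivalence with a
brute-force window oracle over all $5^6$ sequences on the alphabet
{N, P, S, T, A}; alignment-score equality with an independent affine-gap
dynamic-programming oracle on 1000 random pairs of length ≤ 30;
germline self-numbering as the identity for every bundled gene; Wald
interval coverage in the 93–97% band across 200 simulated repertoires of
500 sequences per group at true odds ratios 1, 2 and 6, with the median
estimate within 10% of truth; recovery (direction and significance) of a
1.9-percentage-point mutation-load shift injected into sequon-bearing
sequences at 150 sequences per group; and positional-histogram
correlations near 1 for groups sharing position preferences and near 0
for disjoint ones. These sizes were chosen to give stable Monte-Carlo
estimates while keeping the default suite fast.

## Known limitations

- The bundled references are synthetic; analyses of real data must supply
  real IMGT germline sequences and a curated progenitor list.
- Junction residues inflate mutation counts (documented above).
- Wald intervals are first-order; at very small cell counts the 0.1
  adjustment stabilises the point estimate but the interval remains
  approximate.
- IMGT-position-based structural mapping assumes the numbering tracks the
  fold, which may fail for unusual CDR conformations.
- NxC motifs are detected and tabulated but no claim is made about their
  glycosylation in vivo; glycosylation-propensity prediction is out of
  scope.
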