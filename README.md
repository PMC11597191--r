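# lcsequon

Analysis of N-glycosylation sequons in antibody light-chain variable
domains.

In AL (light-chain) amyloidosis, a patient's monoclonal antibody light
chain misfolds and aggregates as amyloid fibrils. N-glycosylation — marked
in the sequence by the sequon motif **NxS/T** (asparagine, any residue
except proline, then serine or threonine; **NxC** is the rarer cysteine
variant) — is more frequent among amyloid-associated κ light chains than
among light chains from multiple myeloma (MM) or the healthy polyclonal
repertoire, for reasons that are not understood. `lcsequon` packages the
sequence- and structure-level analyses needed to study this association:

- **IMGT numbering** of V-domain sequences by global alignment to their
  assigned germline V/J genes (127-position scaffold, FR/CDR regions,
  IMGT strands), so residues are comparable across light chains;
- **sequon detection** with the regular expression `N[^P][ST]` (all
  matches, including overlapping), annotated with IMGT position, region,
  ±5-residue context, +2 residue identity, and whether the position is a
  germline *progenitor* site (one nucleotide change away from a sequon);
- **mutation load** against the germline: for S substitutions, I
  insertions and D deletions on a germline of length L,

  ```
  fraction mutated = S/L + I/(L + I) + D/(L + D)
  ```

- **enrichment statistics**: 2×2 odds ratios by the cross-product
  estimator (optional 0.1 adjustment to zero cells) and by logistic
  regression, Wald 95% CIs, Benjamini–Hochberg FDR, Wilcoxon rank-sum
  comparisons of mutation load, Pearson correlation of positional
  histograms across the 125 detectable positions, and residue-frequency
  logo matrices;
- **structural exposure**: Shrake–Rupley solvent-accessible surface area
  on PDB/mmCIF structures, relative-exposure classification into surface
  (≥ 10%), core (< 10%) and the conserved heavy-chain interface positions
  {42, 44, 49, 52, 55, 103, 118}, with sequon positions mapped onto
  native and amyloid-fibril structures (unresolved positions reported as
  such);
- a **seeded synthetic repertoire generator** (germline-derived sequences
  with configurable substitution/indel rates and group-dependent
  progenitor-to-sequon conversion probabilities) and **toy structure
  builders** (extended peptides, packed lattices, cross-β stacks at
  4.8 Å rise), so every stage is testable without external data.

The bundled germline reference (`inst/extdata/germline_vj_synthetic.fasta`)
and progenitor-site table are **synthetic** stand-ins with the canonical
V-domain architecture; replace them with real IMGT-derived references for
production analyses.

## Worked example

Simulate an AL-like and an MM-like cohort over four κ germline genes
(30% vs 8% chance of converting a progenitor site into a sequon), run the
pipeline, and inspect the κ prevalence contrast:

```r
library(lcsequon)
set <- annotate_progenitor_sites(read_germline_set())
usage <- setNames(rep(0.25, 4), c("IGKV1-33", "IGKV1-39", "IGKV1-16", "IGKV3-20"))
cfg <- repertoire_config(seed = 7, n_per_group = 200, groups = list(
  AL = list(usage = usage, sub_rate = 0.04, conversion_prob = 0.30, plus2_T_prob = 0.6),
  MM = list(usage = usage, sub_rate = 0.04, conversion_prob = 0.08)))
rep <- generate_repertoire(cfg, set)
res <- run_pipeline(rep, set, compute_mutations = FALSE)
res$prevalence[res$prevalence$scope == "IGK", c("comparison", "method", "odds_ratio", "ci_low", "ci_high", "p_value")]
#> # A tibble: 2 × 6
#>   comparison method          odds_ratio ci_low ci_high      p_value
#> 1 AL vs MM   manual_adjusted        4.2   2.53    6.98 0.0000000299
#> 2 AL vs MM   glm                    4.2   2.53    6.98 0.0000000299
```

The detected odds ratio (4.2, CI 2.5–7.0) recovers the simulated
enrichment (true OR ≈ 4.9). The positional histogram of first sequons
concentrates on the κ progenitor sites, with a few spontaneous sequons
created by background substitutions:

```r
hist <- res$histograms[["AL.IGK"]]
hist[hist > 0]
#> 12 18 20 24 40 66 67 75 86 88
#>  1 16  1  1  2  1  2 14 18 19
res$plus2[["AL.IGK"]]$fraction
#> [1] 0.6266667
```

Positions 18, 75, 86 and 88 dominate (86/88 sit in FR3 strand E), and the
+2 threonine fraction reproduces the configured 60%.

Published cohort counts can be analysed directly, without sequences, in
counts-only mode:

```r
sequon_prevalence_stats()   # bundled AL/MM/OAS count table
```

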