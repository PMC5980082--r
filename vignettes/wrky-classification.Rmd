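---
title: "Classifying WRKY transcription factors: methods and design notes"
author: "wrkyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying WRKY transcription factors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyscan)
```

# The problem

WRKY proteins form one of the largest plant transcription-factor
families. Each member carries one or two ~60-residue WRKY domains: an
almost invariant heptapeptide (canonically `WRKYGQK`) followed by a
zinc-finger structure whose metal-coordinating residues come in two
arrangements. The family's standard classification keys on exactly these
two observables:

* **Group I** — two WRKY domains, C2H2 fingers
  (`C-X(4-5)-C-X(22-23)-H-X(1)-H`);
* **Group II** — one domain, C2H2 finger; five subgroups IIa–IIe that are
  *not* distinguishable by the grammar and require phylogenetic context;
* **Group III** — one domain, C2HC finger (`C-X(7)-C-X(23)-H-X(1)-C`).

On trees of WRKY domains the five Group II subgroups collapse into three
superclades — IIa+IIb, IIc, IId+IIe — a structure this package checks
explicitly (`superclade_check()`).

In transcriptome surveys of species without a reference genome the
available evidence is a set of assembled protein sequences, often
truncated. `wrkyscan` turns the informal published procedure — domain
spotting, manual motif annotation, a neighbor-joining tree against
Arabidopsis references, qPCR follow-up — into a deterministic, tested
pipeline.

# Domain scanning

`scan_protein()` anchors on exact heptapeptide matches. The default
variant set is `{WRKYGQK, WRKYGKK}`: these are the only variants observed
in gymnosperms, while angiosperm variants (`WRKYGEK`, `WRKYGKR`,
`WRKYEDK`, `WKKYGQK`, `WHQYGLK`) are opt-in via
`wrky_variants("extended")`. Matching is exact-string, not fuzzy: the
field treats variants as an enumerated list, and a distance-based matcher
would blur the WRKYGKK/WK-box biology that motivates reporting variants
at all.

Downstream of each heptapeptide the scanner searches a **window of 80
residues** for a zinc-finger arrangement. No published bound exists; 80
covers the ~60-residue canonical domain with margin while keeping the
search from wandering into a following domain. Within the window the
*earliest* arrangement wins — lowest first-cysteine position, then the
lexicographically smallest position vector — which makes results
independent of scan order and reproducible. Every reported arrangement
re-validates against its grammar (`validate_zinc_finger()`), and a
property test asserts this on generated data.

Three deliberate conventions:

* **Tie-break C2H2 over C2HC** when a domain satisfies both grammars
  (possible, since the spacer ranges overlap once extra cysteines are
  around). C2H2 is the majority class by far; the `ambiguous` flag is
  kept so placement evidence can override the provisional type.
* **Overlap resolution keeps the leftmost anchor**: a heptapeptide
  starting inside an accepted domain is dropped. Deterministic and
  order-independent.
* **All coordinates are 0-based, half-open** throughout the package;
  1-based prose belongs to the reporting layer only.

# Two-tier classification

`rule_classify()` applies the structural rules above; they are complete
for Groups I and III and leave Group II "pending". `placement_classify()`
resolves the rest against a labelled reference panel (user-supplied, e.g.
Arabidopsis AtWRKY domains, or the bundled synthetic panel):

1. all query domains and panel domains enter **one joint anchored
   alignment** (one tree per batch, not per query — cheaper and it
   matches how such trees are published);
2. pairwise p-distances (pairwise deletion) are Poisson-corrected,
   `d = -ln(1 - p)`;
3. an in-package neighbor-joining tree is built;
4. each query takes the label of the **smallest clade containing it whose
   reference leaves are uniformly labelled** (other queries in the clade
   are ignored); if no such clade exists below the root, the nearest
   reference by corrected distance decides.

The smallest-uniform-clade rule is this package's own tie-break — no
published rule exists for queries falling between subgroups. Clade
bootstrap support is reported as evidence but never gates a label, since
no support threshold is part of the published procedure. A single-domain
C2H2 query that clades with I-N or I-C references is labelled Group I:
this "truncated Group I rescue" is what reconciles transcriptome
assemblies (where many Group I members lose one domain to truncation)
with the rule tier. Panels carrying labels outside
{I-N, I-C, IIa–IIe, III} are rejected at load time: IIf/IIg-style labels
are rare, species-restricted and would silently distort placement.

# Phylogenetic machinery

**Anchored alignment instead of progressive alignment.** WRKY domains are
short and share an invariant heptapeptide, so rows are shifted to pin the
anchor into one column and flanks are padded with terminal gaps. No
internal gaps are ever introduced; for indel-rich domains this is a
documented approximation, and column-level identity with any particular
progressive aligner is not claimed — topology-level structure is the
target.

**Pairwise deletion** (not complete deletion) for gapped columns:
truncated domains would otherwise erase most columns for everyone.
Saturated pairs (p = 1 on very short overlaps) are capped just below 1
before correction, with a warning.

**Neighbor joining** is the standard Q-criterion algorithm with
Saitou–Nei branch lengths. Ties in Q are broken by the lexicographically
lowest label pair (each internal node inherits the smallest leaf label of
its subtree), making output deterministic on degenerate inputs. Negative
branch lengths are clamped to zero and the clamped magnitude recorded as
the `clamped_deficit` attribute. On additive matrices the algorithm is
exact; the test suite verifies this against exhaustive topology
enumeration (all unrooted topologies, least-squares fit) for 4–5 taxa and
against an independent NJ implementation for larger n.

**Bootstrap** resamples alignment columns with replacement (equal
weights, one seeded generator per run; the seed is mandatory and recorded
on the tree). Supports are mapped only onto the point-estimate tree's
bipartitions, as percentages.

# Motif annotation

EAR repression motifs are matched by their structural classes —
`L-x-L-x-L` and `D-L-N-x-x-P` — rather than by any hard-coded list of
named 6-mers; the literal matched core (plus one residue of trailing
context for the LxLxL class) is reported as the subtype, so conventional
names like `LKLDLY` or `LSLGLN` fall out of the general rule. The
`LXLXLX` notation sometimes used for the same element is treated as the
LxLxL class, not a distinct pattern. Overlapping hits are all reported —
proteins genuinely carry tandem EAR cores — and no greedy collapsing is
done. `LxxLL` and HARF (`RTGHARFRR(A/G)P`) are exact-class regexes.

The leucine-zipper detector is a *heuristic of this package's own
construction* (maximal runs of ≥ 4 leucines on an exact 7-residue
raster, optionally tolerating I/V internally): published zipper calls in
this family come from profile databases, which this package deliberately
does not re-implement. Profile-based domains (Plant_zf_clust, CaMBD,
HSF) can be merged from an external annotation TSV
(`merge_external_annotations()`) but are never computed.

# Expression analytics

`contrast_matrix()` computes signed log2 fold changes between two
log2-scale columns per contrast, with a missing-value mask propagated
from either column. The significance criterion is a plain |log2FC|
threshold (default 1.0) — a config knob, not a statistical test, because
read-level quantification is out of scope and published "changed
significantly" counts in this literature typically come without a named
test. `cluster_genes()` is average-linkage Euclidean `hclust`; rows with
masked cells are dropped by default (zero-imputation behind an explicit
flag), and equal-distance merges follow `hclust`'s deterministic
lowest-index rule.

`ddct()` implements plain 2^−ΔΔCt: replicate Ct wells averaged
arithmetically, ΔCt against a reference gene per sample, ΔΔCt against a
calibrator sample, no amplification-efficiency correction. The
calibrator maps to 1 exactly, and the estimate is invariant to any
constant Ct offset applied to a whole sample — both property-tested.

# The synthetic-data generator

The generator exists so that every analyser can be tested against known
truth without any downloads. Design points:

* **Templates.** Each subgroup has a hand-built consensus domain template
  conforming to its grammar, derived from one ancestral segment set
  through fixed mutation fractions that mirror the family's superclade
  structure (I-N/I-C from one parent, IIa/IIb from another, IId/IIe from
  a third, IIc and III on their own branches). Templates are pure
  functions of hard-coded seeds via a minimal LCG, independent of R's
  RNG; the generator never calls the scanner, so generator and analyser
  remain independent code paths.
* **Fixed per-label spacer lengths.** Each template fixes its zinc-finger
  spacer lengths (within the grammar ranges), with superclade partners
  sharing a profile. Under the anchored (internal-gap-free) alignment,
  same-label domains with *different* spacer draws would misalign
  everywhere downstream of the first spacer and within-label divergence
  would swamp between-label signal; fixing the spacing keeps columns
  homologous. Uniform drawing from the full ranges remains available
  (`spacer_jitter = TRUE`) for stress testing.
* **Truth uniqueness.** Template filler avoids C and H outside the
  anchors, W outside the heptapeptide, and L entirely; substitutions draw
  from the same restricted pool; background sequence excludes C and is
  rejection-scrubbed of any heptapeptide variant, motif-class pattern or
  heptad leucine raster outside the planted features. Planted motifs are
  padded by four glycines. Consequently the planted parse is the unique
  parse at rate 0, which is what makes "100% recovery" a meaningful
  assertion rather than a tolerance.
* **Study-scale defaults.** The default protein set mirrors the group
  sizes of a real conifer transcriptome survey (16/8/10/14/5/7/1 across
  I, IIa–IIe, III; 61 proteins). The default expression plan plants
  7 up / 43 down (of 61), 10/45 and 15/42 across three treatment
  contrasts with |log2FC| ∈ [1.5, 4.1], cell noise sd 0.1 and 5%
  masked genes per dataset. The default qPCR plan covers one gene per
  subgroup over a 0/1/3/6 h elicitor time course with peak inductions up
  to 16.5-fold at 3 h, triplicate wells, per-well Ct noise sd 0.05
  cycles.

What passing tests on this generator shows — and what it does not: the
analysers are exact on data that obey the grammar and diverge by
substitution only. Real assemblies contain indels, sequencing errors,
fragmentary domains and compositional bias that the generator does not
emulate (substitution-only evolution, uniform background). Tests at
substitution rates up to 0.2 demonstrate graceful degradation, not
field accuracy.

# Problem sizes and numerical choices

The shipped test-and-verification workloads use 700 zero-noise proteins
(100 per group) for grammar/classifier recovery, 200 random additive
matrices of 4–8 taxa (exhaustive topology verification for n ≤ 5) for
neighbor joining, a 10⁻³ grid on [0, 0.99] for Poisson monotonicity, and
100 seeded replicates for noisy ΔΔCt recovery — sizes chosen to exercise
each code path thoroughly while keeping a full run in tens of seconds on
one core. Distance symmetry is enforced to 10⁻¹²; newick round-trips are
checked to 10⁻⁹ on branch lengths; Q-criterion ties use a relative 10⁻¹²
tolerance before the lexicographic tie-break.

At per-well Ct noise sd 0.05 the ΔΔCt estimator's sampling error is
about 0.058 cycles (≈ 4% on the fold change), so recovery is asserted on
the mean and median relative error across replicates; individual
replicates can legitimately exceed a tight bound and are not treated as
failures.

# Known limitations

* Heptapeptide matching is exact; heavily diverged anchors are invisible
  (by design, matching the enumerated-variant convention).
* The anchored alignment cannot represent internal indels; placement of
  indel-rich domains may deviate from progressive-alignment trees.
* Subgroup labels are only as good as the reference panel; with a panel
  lacking some subgroup, queries of that subgroup will take the nearest
  available label.
* Profile-HMM domain detection (and E-values) are intentionally out of
  scope; the package annotates only regex-class motifs and imports
  external profile annotations.
* The expression module starts from expression matrices; read assembly
  and quantification are out of scope.
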