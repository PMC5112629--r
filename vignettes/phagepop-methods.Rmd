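---
title: "Methods: delineating and characterizing phage genotypic populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating and characterizing phage genotypic populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phagepop)
```

`phagepop` analyses collections of finished, annotated genomes of closely
related dsDNA phages — the regime of T4-like cyanophage isolates sampled
densely from a few sites on one host. This vignette is the package's own
account of the methods, the parameters that matter, the synthetic
communities used for validation, and the choices made where the design was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Gene families and ANI

All-vs-all gene comparison uses local alignment (match 2, mismatch −3, gap
open 5, extend 2 — the classic nucleotide-BLAST weighting). Two genes are
homologs when the best alignment reaches **40% identity** over **at least
60% of the shorter gene**; both boundaries are treated as inclusive ("at
least" is explicit for coverage and the identity boundary is harmonized
with it). The homology graph, weighted by percent identity, is clustered
by Markov clustering (MCL) with **inflation 2**: self-loops at the maximum
incident weight, alternating expansion and inflation until the largest
entry change falls below 1e−6 (error at 200 iterations), clusters read off
the converged attractor support. Nodes are sorted lexicographically before
matrix construction, so the result is invariant to input order; genes with
no surviving edges become singleton clusters. A *core* cluster has at
least one member in every genome.

By default the all-vs-all step prescreens candidate pairs with exact
12-mer seeds (indexed every 6 bp): any pair sharing a 17 bp exact run is
guaranteed to be examined, which retains homologs down to roughly 70%
identity. For collections where homologs near the 40% boundary matter,
set `prescreen = FALSE` (exhaustive, quadratic).

**ANI** between two genomes is the unweighted mean of the percent
identities of all shared homologous gene pairs (same cluster, different
genomes). Unweighted (rather than length-weighted) averaging follows the
plain reading of averaging per gene pair. The **shared-gene fraction**
divides the number of shared clusters by each genome's own cluster count
(singletons included), reporting both directed fractions and their mean.

## Barcode-gap delimitation

Populations are delimited from Jukes–Cantor distances,
d = −¾·ln(1 − 4p/3), where p is the mismatch proportion over ungapped,
unambiguous aligned columns of the concatenated single-copy core genes.
For each prior maximum intra-population divergence P in a grid (default
ten log-spaced values, 0.001–0.1 substitutions/site):

1. sort the distinct pairwise distances;
2. candidate intraspecific distances are those ≤ P, anchored at zero (the
   self-distance); when no observed distance falls below P the smallest
   observed distance serves as the reference spacing;
3. the barcode gap is the first interval between consecutive distances
   wider than **1.5×** the largest candidate spacing;
4. split by single linkage at the gap's lower edge and recurse within
   each group.

The specific gap rule and the single-linkage thresholding are this
package's choices — the published barcode-gap method fixes only the
distance model, the 1.5× factor and the prior grid. The zero anchor
matters: without it, a prior below all observed distances has no
calibration and the first within-group spacing would trigger a spurious
split.

Small priors canonically oversplit (each recent recombinant or outlier
becomes its own group), and the group count stabilizes as P grows. The
**converged** count is therefore read from the terminal plateau of the
count-versus-prior curve (a warning is raised if the top of the grid has
not stabilized); the modal count over the grid is also reported, and the
two coincide on clean data. The returned partition is the one at the
largest prior.

Ordination arcsine-square-root transforms the ANI fractions and runs
principal components on the transformed genome × genome matrix (classical
multidimensional scaling is available as an alternative). Degenerate
all-equal matrices return zero coordinates and zero explained variance.
Lineage divergence is tested by a two-tailed Mann–Whitney U comparing the
focal lineage's between-lineage distances against the rest — exact
enumeration when both samples have ≤ 8 observations and no ties, otherwise
the normal approximation with tie correction.

## Nucleotide diversity and F_ST

π is the mean over unordered sequence pairs of the per-site mismatch
proportion; columns with a gap or ambiguous base in either member are
excluded pairwise. F_ST between two subpopulations follows
F_ST = 1 − π_within/π_between with π_within the mean of the two
within-subpopulation diversities and **π_between computed over
cross-subpopulation pairs only** — that reading makes the printed identity
exact: internally monomorphic, mutually distinct subpopulations give
F_ST = 1, and exchangeable labels give F_ST ≈ 0. A single-member
subpopulation has π = 0 with a warning (the pipeline's per-site table
additionally requires two members per site); π_between = 0 leaves F_ST
undefined (`NA`). Core alignment blocks from an external whole-genome
aligner are consumed as input and filtered to length **> 500 bp** (strict)
with all genomes present.

## McDonald–Kreitman machinery

Within each lineage, alleles carried by **strictly less than 15%** of the
members are replaced by the lineage major allele (exactly 15% is kept);
the filter acts per allele so fixed-difference counting downstream is
unaffected. Whether the original rule acted per site or per haplotype is
not documented; per-allele replacement is the reading that preserves the
rest of the counting.

Per codon column of a codon-aligned gene: a column monomorphic in both
lineages for different codons is a fixed difference (a synonymous, c
nonsynonymous); a column segregating in either lineage contributes each
distinct segregating codon once, classified against that lineage's major
codon (b/d), and never also counts as fixed. Codons differing at several
positions are averaged over minimal mutational pathways (fractional
counts; pathways through intermediate stop codons are excluded unless all
are). Columns containing gaps or ambiguous bases are skipped; a gene whose
major codon at an internal position is a stop is skipped with a warning.

The two-tailed Fisher's exact p sums hypergeometric probabilities no
larger than the observed table's (fractional counts rounded for the test,
kept raw for the effect size). The phi coefficient is
φ = (ad − bc)/√(efgh), undefined when a marginal is zero. With a = fixed
synonymous and c = fixed nonsynonymous, nonsynonymous-fixation excess
means ad < bc, i.e. **negative φ under this orientation** — which is why
significant positively selected genes carry negative effect sizes while
the magnitude cutoff is stated as φ ≥ 0.1. The default call is
p < 0.05 AND |φ| ≥ 0.1 AND ad < bc; `phi_gate = "signed"` instead gates on
−φ ≥ 0.1, which is equivalent given the direction requirement and offered
because the sign convention is a point where descriptions in the
literature diverge. The scan runs on **all clusters shared by a lineage
pair** (not only core clusters — restricting to the strict core silently
drops fast-evolving selected genes whose lineage copy has been split off
its family by MCL), skipping pairs where a lineage lacks the gene or
carries duplicates, and reports the expected false positives
(0.05 × number of tests) alongside, since genuine selection signals can be
indistinguishable from that rate.

## Recombination

Event tables from dedicated coalescent or substitution detectors are
first-class inputs; rates are normalized as count/n_L within a lineage and
count/(n_L1 + n_L2) between. Breakpoints are mapped to full-genome
coordinates by taking the **50 bp of ungapped sequence preceding the
breakpoint column**, locating it exactly in the participant's genome
(falling back to local alignment at ≥ 90% identity), and placing the
coordinate immediately after the flank (0-based). A coordinate inside an
annotated gene is *genic*, otherwise *intergenic*; multiple equally good
flank hits, or no hit at the identity floor, give *ambiguous*. Flanks that
would span an alignment-block junction are a known blind spot (the source
method's handling is undocumented); they surface as ambiguous rather than
mislocated.

The built-in `detect_events_simple()` is a deliberately simple windowed
mosaic scanner — per-window mismatch counts pick the closer of two
candidate parents, a sustained switch (≥ 3 windows of 200 columns on each
side) proposes a breakpoint, and significance comes from permuting column
order (95th percentile of null run lengths). It is a documented stand-in
used when no external table is supplied, never a re-implementation of the
cited detectors: within-lineage events at ~1% divergence sit near its
detection floor, and a detected chimera can also appear mirrored in a
parent's scan.

## The synthetic communities

`simulate_community()` builds an ancestral genome of codon-structured
genes (start codon, sense codons, terminal stop) separated by 40–80 bp
spacers, with the core genes first so that core coordinates are shared by
all genomes regardless of later gain/loss. Lineage founders and
within-lineage tips diverge by per-site Jukes–Cantor substitution,
codon-aware inside genes: proposals creating internal stops are redrawn
and, with probability `syn_bias` (default 0.5), a hit is redirected to a
synonymous alternative when one exists. Defaults emulate the target
regime: 6 lineages × 5 genomes, within-lineage pairwise divergence 0.01
(ANI ≈ 99%), between-lineage 0.11–0.20 (ANI 80–89%), shared-gene fraction
within lineages > 96% via flexible-gene gain/loss, 5 selected genes, and
2 within-lineage plus 3 between-lineage recombination tracts of 800 bp
(tract length scaled to the ~10 kb desk-scale core as real ~1 kb tracts
are to a > 100 kb core).

Selection plants extra forced nonsynonymous substitutions in the selected
gene on its lineage's founder branch so that the *pairwise* nonsynonymous
fixed-difference count is multiplied (both branches contribute to a pair's
fixed differences, so the extras equal (multiplier − 1) × twice the
branch's nonsynonymous count). A visible desk-scale consequence: at
multiplier 5 the selected copy can become divergent enough that MCL splits
it out of its family — a real pathology of strict core-gene scans, and the
reason the MK scan covers all shared clusters.

Within-lineage genealogy is a `"star"` by default — a single unstructured
population, which is both the assumption behind barcode-gap delimitation
and the panmictic null under which between-site F_ST ≈ 0 in the emulated
regime. The `"clades"` option (two subclades per lineage) instead makes
polymorphisms segregate at shared intermediate frequencies, which is what
real genealogies do and what the < 15% filter needs to leave any
polymorphism standing in larger samples; it is the right choice for
frequency-filter studies but deliberately violates panmixia. Low-frequency
polymorphisms are additionally injected into floor(0.1 × n) members
(nothing is injected below n = 10, where a single carrier already exceeds
15%). Recombination is planted by copying donor core segments into
recipients, resampling tract positions so tracts never overlap on a
participant (otherwise later events overwrite earlier ones and the truth
table would no longer describe the emitted genomes); start breakpoints
fall in intergenic spacers with probability 0.1.

What the generator does **not** emulate: indels and genome rearrangement
(so "alignment" of core regions is exact concatenation), rate
heterogeneity across sites, codon-usage bias beyond the synonymous
redirect, realistic T4 genome architecture, and coalescent-exact
genealogies. Passing tests therefore demonstrate the statistical machinery
on cleanly structured communities; on real data, alignment error, intron
artifacts and deeper genealogical structure will add noise the tests do
not exercise.

## Validation design and problem sizes

The test suite validates each stage at sizes chosen to run in minutes on
one CPU: formula oracles (φ, Fisher, Jukes–Cantor, π, F_ST) against
independent brute-force implementations; exact family recovery for
planted families (within ≥ 90%, between ≤ 30% identity) over 30 genes;
delimitation recovery for 2–8 lineages × 10 seeds at within 0.005 /
between 0.11–0.20 on star genealogies (exact at every prior); F_ST over
50 random site splits of one panmictic 10-member lineage (|F_ST| < 0.02 in
≥ 95%); MK recall ≥ 0.8 on 5 planted selected genes at multiplier 5 in a
recombination-free community (recombination has its own criterion — a
tract landing in a selected gene turns its fixed differences into
polymorphism and genuinely erases the signal, which is why the end-to-end
recall reported by the acceptance script is lower than the isolated MK
recall), with false positives under the binomial 95% envelope of the
nominal rate (the direction and effect-size gates make the realized rate
conservative, so the envelope is checked from above); exact recombination
normalization, exact breakpoint round trips, and planted intergenic
fractions within binomial bounds; and byte-identical pipeline reruns under
a fixed seed.

## Numerical conventions and degenerate inputs

0-based half-open coordinates internally, converted at the GFF3 boundary
(1-based closed). GC content excludes ambiguous bases from the
denominator; an all-N sequence has undefined GC. Grubbs' outlier test is
two-sided, G = max|x−mean|/sd against the t-based critical value; zero
spread defines G = 0 and no outlier; summaries use the sample (n−1)
standard deviation, with sd flagged rather than undefined for
single-member lineages. Jukes–Cantor distances error at p ≥ 0.75. MCL ties
are broken by lexicographic node order. Fisher's test on the all-zero
table returns p = 1, flagged. All randomized steps (simulation,
permutation tests) run under a caller-supplied seed with R's default
Mersenne-Twister generator, and identical seeds reproduce outputs byte for
byte.
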