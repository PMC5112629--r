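# phagepop

Population genomics of closely related double-stranded DNA phage isolate
genomes.

Whether wild dsDNA phages form a genomic continuum or discrete,
species-like populations is a question that can only be answered with
dense, per-site isolate sampling. `phagepop` implements the analysis
toolkit for such collections — tens to hundreds of finished phage genomes
isolated on a single host from a few water samples — and answers three
questions about them:

1. **Are there discrete genotypic populations?** Genes are grouped into
   protein clusters (all-vs-all similarity, a 40% identity / 60%
   coverage-of-shorter homology filter, Markov clustering at inflation
   2). Populations are then delineated three independent ways: shared-gene
   fractions, average nucleotide identity (ANI) of shared genes, and
   recursive barcode-gap partitioning of Jukes–Cantor distances
   (d = −¾ ln(1 − 4p/3)) on the concatenated core genes over a grid of
   prior intra-population divergences (0.001–0.1 substitutions/site, gap
   factor 1.5), reading the converged group count from the plateau of the
   prior curve.
2. **Is there gene flow between sites?** The fixation index between the
   coastal and offshore members of each population,
   F<sub>ST</sub> = 1 − π<sub>within</sub>/π<sub>between</sub>,
   with nucleotide diversity π the mean pairwise per-site difference over
   the core genomic regions (blocks > 500 bp).
3. **Is selection or recombination shaping the populations?**
   Non-polarized McDonald–Kreitman tests on all shared genes between all
   lineage pairs: synonymous/nonsynonymous fixed differences (a, c) vs
   polymorphisms (b, d), after removing polymorphisms segregating in
   < 15% of a lineage's members; a two-tailed Fisher's exact test
   (p < 0.05) with the phi effect size φ = (ad − bc)/√(efgh), |φ| ≥ 0.1,
   oriented toward nonsynonymous fixation excess. Recombination events
   (from external coalescent/substitution detectors, or a simple built-in
   windowed scanner) are normalized by lineage sizes (count/n within,
   count/(n₁+n₂) between) and their breakpoints mapped to full-genome
   coordinates via the 50 bp flank preceding the breakpoint, then
   classified as genic or intergenic.

Every stage is validated end to end on synthetic phage communities with
known truth: `simulate_community()` plants lineages at chosen divergences,
gene gain/loss, selected genes with multiplied nonsynonymous fixation,
recombination tracts with recorded breakpoints, and low-frequency
polymorphisms, and emits the matching FASTA/GFF3 plus truth tables.

## Worked example

```r
library(phagepop)

sim <- simulate_community(sim_config(
  seed = 42, n_lineages = 3, genomes_per_lineage = 4,
  n_core_genes = 8, n_flexible_genes = 4, mean_gene_codons = 120,
  n_selected_genes = 2, recomb_within_per_lineage = 1,
  recomb_between_events = 1, recomb_segment = 300))
sim
#> simulated phage community (seed 42):
#> phage_community: 12 genomes, 157 genes
#>   sites: coastal=6, offshore=6
#>   genome length range: 5641 - 6187 bp
#>   lineages: 3 | selected genes: 2 | planted events: 4

res <- run_pipeline(sim$community,
                    pipeline_config(detect_permutations = 100))
res
#> phagepop pipeline result
#>   genomes: 12 | gene families: 21 ( 7 core )
#>   populations (converged over prior grid): 3
#>   ANI within 98.88% / between 85.12%; shared genes 0.994 / 0.663
#>   max F_ST across site splits: -0.0052
#>   MK tests: 26 | selected: 2 (expected false positives 1.3)
#>   recombination rates within 0.417 / between 0.000

res$delimitation
#> barcode-gap delimitation over 10 priors
#>   groups per prior: 3 3 3 3 3 3 3 3 3 3
#>   converged group count: 3 (terminal plateau of 10 priors; modal 3 )

truth_compare(sim$truth, partition = res$partition)
#> $partition_ari
#> [1] 1
```

Reading the output: the three planted lineages are recovered at every
prior in the barcode-gap grid (adjusted Rand index 1 against truth); ANI
within populations is ~99% versus ~85% between, with shared-gene fractions
0.99 versus 0.66, i.e. discretely bounded populations. F<sub>ST</sub>
between the coastal and offshore members of each population is ≈ 0 (high
gene flow between sites), the MK scan flags 2 gene × lineage-pair
combinations (the two planted selected genes), and the within-lineage
recombination rate exceeds the between rate.

Real data enter through `read_community()` (FASTA + GFF3 + site labels),
`read_blast_pairs()` (precomputed 12-column tabular alignments),
`read_alignment()`/`filter_core_blocks()` (externally aligned core
blocks), and the `external_events` argument of `run_pipeline()` (event
tables from dedicated recombination detectors). A thin command-line
front end lives in `inst/cli/phagepop.R`
(`Rscript phagepop.R simulate|run ...`).

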