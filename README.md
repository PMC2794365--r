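# relmod

Detection of **regulatory-linkage modules** from a segregating population.

## What problem this solves

In a cross between two strains, a DNA polymorphism in a regulatory protein
can shift the expression of a whole group of target genes. Per-gene eQTL
mapping often misses these trans effects: each individual gene moves only
modestly, and thousands of traits are tested. `relmod` integrates a second,
independent data source — a compendium of expression signatures from
strains each mutated in a single regulatory protein — and searches
*simultaneously* for a group of co-expressed genes, the contiguous linkage
interval they are jointly linked to, and the regulatory proteins whose
perturbation signatures they respond in. It is aimed at quantitative
geneticists and systems biologists working with genotype + expression data
for recombinant haploid populations (the motivating setting is a yeast
laboratory × wild cross) together with a mutant-expression compendium.

## The statistic at its core

For every marker *m* and gene *g*, linkage is scored by a two-class
regression LOD over the n segregants observed for both,

    LOD(m, g) = (n/2) · log10(RSS0 / RSS1),

with RSS0 the residual sum of squares about the grand expression mean and
RSS1 about the per-allele-class means. For every (marker, signature) pair
the **ReL score** is then computed by (1) splitting the signature about its
mean into over-/under-expressed genes, (2) scanning all observed LOD values
as thresholds and picking the one whose high-linkage set
(LOD ≥ t) is most hypergeometrically enriched in one expression group,
(3) comparing signature values of the high-linkage genes against all
remaining genes with a Welch t-test. The ReL score is −log10 of the
Bonferroni-corrected P (corrected over all marker × signature pairs;
836,548 for a 2956-marker, 283-signature design). **ReL modules** —
contiguous marker intervals paired with signature sets whose submatrix of
ReL scores is coherently high — are extracted by an iterative signature
algorithm whose marker step is constrained to one contiguous interval,
optimized each iteration by maximum-subarray dynamic programming. Modules
are annotated with trans target genes (hit in ≥ 60% of module entries,
cis genes within 30 gene positions of the interval excluded),
regulatory-protein scores, process enrichments, telomere flags, causal
candidate genes inside the interval, and a column-permutation P-value.

See `vignettes/regulatory-linkage.Rmd` for the full model, parameter
meanings and design decisions.

## Worked example

Simulate a 112-segregant cross with three planted modules, run the full
chain, and inspect the top module:

```r
library(relmod)

cfg <- sim_config(rng_seed = 7)      # 3 x 100 markers, 1000 genes, 40 signatures
d   <- simulate_dataset(cfg)

lk   <- compute_linkage_matrix(d$genotypes, d$expression)
rel  <- compute_rel_matrix(lk, d$compendium, d$map)
mods <- find_modules(rel)

length(mods)
#> [1] 12
print(mods[[1]])
#> ReL module II:435.644–534.653 (11 markers x 3 signatures), score 19.58
#>   signatures: s04, s05, s06
module_size_pvalue(mods[[1]], rel, n_perm = 100, rng_seed = 7)
#> [1] 0.00990099
tg <- target_genes(mods[[1]], rel, d$gene_positions)
length(tg)
#> [1] 40
protein_scores(mods[[1]], rel)
#>     REG2
#> 19.57802
```

The top module's interval (11 markers around 435–535 kb on chromosome II)
contains the planted causal marker at position 50 of that chromosome; its
three signatures are exactly the planted regulator's, the 40 target genes
are the planted members, the best-scoring regulatory protein is the planted
`REG2`, and the module survives 100 within-signature permutations
(P ≈ 0.01, the smallest value 100 permutations can produce). The remaining
modules are the other two planted modules followed by small
borderline-score fragments.

A command-line front end mirrors the same stages
(`inst/scripts/relmod <simulate|linkage|relscore|modules|run> [--flags]`).

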