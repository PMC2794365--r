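---
title: "Regulatory-linkage analysis: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory-linkage analysis: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Expression quantitative trait locus (eQTL) mapping in a segregating
population links DNA polymorphism to expression variation one gene at a
time, and loses power exactly where the biology is most interesting: a
polymorphism in a regulatory protein shifts a whole group of target genes,
each by a modest amount. `relmod` pools evidence across such groups by
bringing in a second, independent data source — a compendium of expression
signatures from strains each mutated in a single regulatory protein. If a
group of genes is both co-linked to one genomic interval in the cross and
coherently over- or under-expressed in a mutant signature, the two
observations reinforce each other: the interval plausibly harbours a
polymorphism acting through that regulator (or through the pathway the
regulator reports on).

The unit of output is a *regulatory-linkage module*: a contiguous marker
interval, a set of regulatory signatures, and a derived set of trans-acting
target genes, annotated with regulatory-protein scores, enriched biological
processes, and putative causal regulators located inside the interval.

## The statistic

**Linkage.** For marker $m$ and gene $g$, with haploid allele classes
coded 0/1, the eQTL likelihood is the two-class regression LOD
$$\mathrm{LOD}(m,g) = \frac{n}{2}\,
  \log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},$$
where $\mathrm{RSS}_0$ is the residual sum of squares about the grand mean
of $g$'s expression, $\mathrm{RSS}_1$ about the per-allele-class means, and
$n$ the number of segregants with both values observed (pairwise deletion
per marker–gene pair). The statistic is non-negative, invariant to
expression shifts and allele relabelling, and monotone in the two-sample
$t$ statistic. Degenerate perfect fits ($\mathrm{RSS}_1 = 0$) are capped at
50 so the downstream threshold scan remains finite and totally ordered; a
constant trait scores 0, as does a pair where either allele class has fewer
than three observations (counted and reported). Downstream analysis
consumes only the ordering and the observed values of these scores, so any
monotone-equivalent linkage statistic would yield the same modules with
shifted thresholds.

**The ReL score.** For each (marker, signature) pair:

1. The signature is split about its mean into over-expressed
   ($>$ mean) and under-expressed ($<$ mean) genes. The defining cutoff is
   the signature mean because the hit-gene rule below is anchored at the
   average signature value; using the mean for both keeps the two rules
   consistent.
2. Every observed linkage score is a candidate threshold. For each
   candidate $t$ and each direction, the upper-tail hypergeometric
   probability of the overlap between the high-linkage set
   ($\mathrm{LOD} \ge t$, boundary inclusive) and the expression group is
   computed over the universe of all scored genes; the pair $(t, d)$
   minimizing this probability is selected. Ties go to the smaller
   threshold (the larger, more conservative high-linkage set), then to the
   "up" direction. The hypergeometric scan, unlike a $t$-test, accounts
   for the *number* of high-linkage genes and keeps the threshold from
   drifting too high.
3. The signature values of the high-linkage genes are compared with those
   of all remaining scored genes by a Welch (unequal-variance) two-sample
   $t$-test — the subset sizes and variances are unbalanced by
   construction, so the pooled-variance form would be anti-conservative.
   The ReL score is $-\log_{10}$ of the Bonferroni-corrected two-sided
   $P$, corrected over all marker × signature pairs of the run (for a
   2956-marker, 283-signature design this factor is 836,548), floored at 0.
4. The entry's *hit genes* are the high-linkage genes on the selected
   direction's side of the signature mean; they feed the module
   target-gene rule.

A consequence worth stating plainly: because the threshold is chosen to
minimize an enrichment probability *before* the $t$-test is run, the
uncorrected $t$-test $P$-values are anti-conservative under a global null.
The package's own null calibration (the structureless simulation in the
acceptance script and test suite) measures the fraction of uncorrected
$P < 10^{-3}$ at roughly 30 times the nominal rate. This is a property of
the selection-then-test construction, not a defect of the implementation;
module-level inference therefore never rests on these raw $P$-values but on
the Bonferroni-corrected score floor and on column permutation (below),
both of which the null simulation shows to be well behaved.

## Biclustering with a contiguity constraint

Modules are high-mean submatrices of the ReL matrix whose marker rows form
one contiguous genomic interval. The iterative signature algorithm (ISA) is
adapted accordingly; each iteration alternates:

- **Signature step.** Keep the signatures whose mean ReL score over the
  current interval is at least `tau_col` (boundary inclusive).
- **Interval step.** For each marker $m$ of the chromosome let $g(m)$ be
  the mean ReL score over the current signatures; choose the contiguous
  interval maximizing $\sum_m (g(m) - \texttt{tau\_row})$ by
  maximum-subarray dynamic programming (Kadane's algorithm, linear time;
  ties resolved toward the earliest interval).

Iteration starts from a single seed entry and stops when the
(interval, signature-set) state repeats exactly; a longer cycle within
`max_iter` (default 50) iterations counts as non-convergence and discards
the seed. The iteration involves no randomness, so a module is a
deterministic function of its seed and parameters.

Choices made where the design was genuinely open:

- **Single chromosome per interval.** The interval is confined to the seed
  marker's chromosome. Linkage intervals are physical ranges on one
  chromosome; allowing growth across chromosome boundaries has no genetic
  interpretation. This is recorded as an assumption, not a theorem.
- **Seeding.** The literal rule seeds from every matrix entry; identical
  attractors make this wasteful. The default seeds only from entries with
  ReL score ≥ 3 (`min_seed_score = 0` restores the literal rule). An
  entry below the reporting floor cannot anchor a reportable module in
  practice, and every planted-recovery test passes under the restricted
  rule.
- **Thresholds.** `tau_row = tau_col = 3` by default, aligned with the
  module reporting floor (`score_floor = 3`, i.e. corrected
  $P < 10^{-3}$): a module is the region over which membership and
  reporting use one consistent significance currency. Thresholds are on
  the $-\log_{10}$ corrected-P scale directly, not in standard-deviation
  units of a normalized matrix — the ReL matrix is already a matrix of
  calibrated significances, so an absolute threshold is interpretable and
  portable across runs.
- **Deduplication.** Seeds converging to overlapping attractors are merged
  when their entry-cell sets overlap at Jaccard ≥ 0.5 (transitive
  closure), keeping each component's highest-scoring representative.
- **Permutation significance.** The null shuffles scores independently
  within each signature column: each signature's score distribution is
  preserved exactly while the marker-range structure — the thing a module
  claims — is destroyed. Each permutation reruns the ISA from the permuted
  matrix's best entry; the statistic is module area × mean score, and
  $P = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$,
  never exactly zero.

## Module annotation

- **Target genes**: genes hit in at least 60% of the module's interval ×
  signature entries. Genes inside the interval or fewer than 30 genes away
  from its boundary are removed; "genes away" is gene-order index distance
  on the chromosome, not kilobases, so the rule adapts to local gene
  density (a gene 29 genes away is excluded, 30 away is kept). Hit genes
  without a position cannot be cis-excluded and are retained with a
  warning.
- **Protein scores**: a signature's score is its interval-mean ReL score; a
  protein's score averages over its signatures (several signatures may
  probe one protein). The argmax is the module's best-scoring regulatory
  protein.
- **Process enrichment**: upper-tail hypergeometric per annotation term,
  Bonferroni-corrected over the tested terms (Benjamini–Hochberg
  available); the best significant term is the primary biological process.
- **Causal candidates**: every gene located in the interval is tested
  against three criteria — sharing the primary process, a direct network
  edge to any module protein, and enrichment of its binding targets among
  the module targets (hypergeometric, Bonferroni over interval genes,
  corrected $P < 0.05$). Candidates are ranked by criteria met, then by
  the binding-enrichment $P$. The binding table is kept separate from the
  protein–DNA edges of the network: the two criteria ask different
  questions (physical contact with the module's *regulators* vs.
  regulatory coverage of the module's *targets*).
- **Telomere flag**: a module is flagged when ≥ 50% of its positioned
  targets lie within 30 kb of a chromosome end and those genes span ≥ 3
  chromosomes. The thresholds are package defaults for a screen that was
  originally applied by eye; all three are exposed as arguments.

## The synthetic cross

The simulator generates the conditions under which the method is tested:
112 haploid segregants; 3 chromosomes × 100 evenly spaced markers over
1000 kb; first-marker alleles Bernoulli(0.5) and a parent switch with
probability $r = 0.1$ between adjacent markers (a uniform Markov
recombination model — adequate for testing contiguity, not a genetic map
function); 1000 genes; 40 signatures. Three planted modules each tie 40
member genes to one causal marker (expression shift $\beta = 1$ per allele
against noise $\sigma_e = 0.5$, so a member's expected single-locus
$R^2$ is $0.25/0.5 = 0.5$) and to 3 regulator signatures (member shift
$\delta = 2$ against signature noise 0.3, all three signatures mapping to
one protein, which also exercises the many-signatures-per-protein path).
Member genes are always placed on a different chromosome than their causal
marker so that cis exclusion never removes a true target and recovery can
be scored cleanly. Signature count per module, $\sigma_e$ and the
signature noise are package choices (the compendium's modules in real data
involve one to a few dozen signatures; three is a conservative low end,
and the noise levels put per-gene signals in the clearly-detectable but
not-trivial regime).

What the simulator does *not* emulate: linkage disequilibrium structure of
a real cross beyond first-order recombination, recombination interference
and hotspots, batch effects and array normalization artifacts, correlated
background co-expression, missing data, and signatures whose perturbation
effects overlap partially. Passing the recovery tests therefore
demonstrates correctness of the inference machinery under the declared
generative model — not performance on real arrays, where background
correlation in particular will inflate the effective number of chance
co-linked groups.

Problem sizes used by the test suite and the acceptance script — 20
simulation seeds for recovery, 20 structureless seeds for null calibration
(100 markers × 20 signatures × 500 genes each), 100 permutations per
module, 200 random instances for the interval-optimization oracle and 50
for the threshold-scan oracle — were chosen as the smallest designs at
which the binomial/Monte-Carlo error bars are well inside the asserted
tolerances.

## Numerical choices and degenerate inputs

- $t$-test $P$-values are floored at $10^{-300}$ before $-\log_{10}$ so
  scores stay finite; a zero-variance split with equal means scores
  $P = 1$.
- A signature with all values identical cannot be split and its entries
  score 0 (counted, reported) rather than `NA`, so the biclustering always
  sees a complete matrix.
- A high-linkage or rest set with fewer than two members scores 0 and is
  flagged.
- Hypergeometric ties in the threshold scan share candidate thresholds
  (score ≥ t is inclusive); equal minima resolve to the smaller threshold,
  then direction "up", making the scan deterministic.
- Empty genotype classes in the two-locus summary report `NA` class means;
  the joint $R^2$ is fitted over the populated classes.
- Chromosome display order is the order of first appearance in the marker
  map (Roman numerals do not sort lexically).

## Known limitations

- The raw (uncorrected) ReL $P$-values are not calibrated, by
  construction; see above. Compare runs only through corrected scores and
  permutation $P$-values.
- Modules carry a single linkage interval; targets governed by interacting
  loci surface as separate modules at best. The two-locus summary
  (`two_locus_summary`) supports checking a suspected pair for additivity
  manually, but no automatic epistasis search is attempted.
- The module inventory is conditioned on the compendium: a regulator with
  no signature, or an effect specific to a very short interval or a
  handful of genes, is invisible.
- Bonferroni correction across all pairs is conservative for dense
  designs; no FDR alternative is offered for the entry-level test in this
  version.
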