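---
title: "Evolutionary transcriptome indices across development: methods and design"
author: "devoTAI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary transcriptome indices across development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The question the package addresses

Developmental series often show ontogeny–phylogeny correlations at the
transcriptome level: mid-development (the phylotypic period) tends to express
evolutionarily older, slower-evolving, more codon-biased genes than early and
late development, producing an hourglass-shaped profile. devoTAI implements
the quantitative machinery for detecting such patterns in any ordered,
replicated RNA-seq series — for example a 12-stage somatic-embryogenesis
series from early induction (EI) through the globular, heart, torpedo and
cotyledonary stages to the juvenile plant (JP).

# The model

## Expression

Raw counts are converted per sample to the fraction of transcripts,
$\tau_i = (c_i/l_i)/\sum_j (c_j/l_j)$ when gene lengths are supplied
(TPM semantics on a 0–1 scale), or plain count fractions otherwise. Whether
the length correction is applied is a flag (`useLengths`) because the
relative-abundance measure is meaningful in both forms and length data are
not always available; the default is length-free, and both routes are
tested. Replicates are collapsed to the stage level by the median (the even
count convention is the mean of the two central order statistics), and
stage columns are then rescaled to sum to one. This rescaling restores the
"columns sum to 1" property that the median collapse breaks; it is harmless
because every downstream index is invariant to per-stage positive rescaling,
and it makes stage-level values directly interpretable as expression
fractions.

## Evolutionary indices

All four indices share the expression-weighted mean form
$$x_s = \frac{\sum_i w_i\, e_{is}}{\sum_i e_{is}},$$
where $e_{is}$ is the stage-level normalized expression and $w_i$ a
gene-level evolutionary attribute: the phylostratum $ps_i$ (transcriptome
age index, TAI; 1 = oldest), the nonsynonymous divergence $dN_i$ (TdNI),
the synonymous divergence $dS_i$ (TdSI), or Wright's effective number of
codons $ENC_i$ (transcriptome codon-bias index, TCBI; low = strong bias).
Each index uses the intersection of expressed genes and genes carrying that
attribute, and the count is reported on the profile, because real datasets
have different denominators per attribute (a divergence estimate requires
an ortholog, ENC requires a CDS, an age requires a homology hit).

Profiles are bounded by the range of the weights, invariant to per-stage
rescaling, and strictly increasing in the expression of any gene whose
weight exceeds the current stage value — properties the suite checks
directly. The cumulative variant restricts TAI to genes with $ps \le k$,
showing at which evolutionary depth the profile shape settles; min–max
normalization $(x_s - \min x)/(\max x - \min x)$ maps a profile to [0, 1]
for cross-dataset overlays, and per-phylostratum relative expression
applies the same min–max scaling to the stratum-mean expression across
stages.

## Phylostratigraphy

Gene ages come from homology hit tables (BLAST tabular) plus a
taxon-to-phylostratum lineage map, which can be built from a rooted Newick
consensus phylogeny: internodes on the root-to-focal path are indexed from
1 (root, oldest) upward, every taxon maps to the internode where its lineage
leaves that path, and the focal species occupies the youngest stratum. A
gene is assigned to the oldest stratum among its hits at `e <= cutoff`
(inclusive threshold, fixed for reproducibility); genes without a
qualifying hit are reported as unassigned and excluded downstream rather
than defaulted to the focal stratum. The e-value sweep recomputes the map
over a ladder of cutoffs (default 10 down to 1e-40, eleven values) and
reports monotonicity violations: a stricter cutoff can only shrink a gene's
hit set, so its stratum index may only increase (look younger) or the gene
drops out — any age decrease indicates an inconsistency in the inputs.

## Effective number of codons

Wright's $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$ with
codon homozygosity $F = (n\sum \hat p^2 - 1)/(n-1)$ per amino-acid family;
Leu, Ser and Arg are treated as their own sixfold class. Families observed
at most once are excluded from their class average; a missing threefold
class (Ile) is imputed from the mean of the two- and fourfold averages, any
other missing class from the mean of the computable class averages, and the
estimate is capped at 61 because the finite-sample estimator can exceed the
theoretical maximum. Internal stops and non-ACGT codons are an error by
default (`skipInvalid` skips them); a trailing stop codon is tolerated and
not counted.

One estimator property worth knowing: because of the $(n-1)$ correction,
$N_c$ of a sequence and of its concatenated duplicate differ by a term of
order $(1-F)/2n$ amplified by $1/F^2$, which is negligible under strong
bias but can reach a few tenths of a unit near uniform usage at a thousand
codons. The duplication-invariance test therefore asserts the property in
the strongly biased regime where it genuinely holds.

## Significance: the flat-line test

The statistic is the variance across stages of the index profile. The null
is built by permuting the gene-level weights across genes while keeping the
expression matrix fixed, so stage-wise expression structure is preserved
and only the weight–expression association is tested. The default p value
is the empirical permutation p with the +1 correction,
$p = (1 + \#\{V_{null} \ge V_{obs}\})/(1 + n_{perm})$, chosen for
transparency; a gamma distribution fitted to the null variances is offered
(`gammaFit = TRUE`) because fitted nulls are common in this test's
lineage. The per-stage mean ± sd of the permuted profiles forms the null
band for plotting. Profiles whose standard deviation is below $10^{-8}$ of
their level (e.g. under constant weights) are treated as numerically flat
so that the degenerate case returns p = 1 rather than an artifact of
round-off. The seed is a required argument.

Hedges' g implements the pooled-SD standardized mean difference with the
small-sample correction $J = 1 - 3/(4(n_1+n_2-2) - 1)$, alongside the
two-sided pooled-variance t test and the 95% CI of the mean difference —
the form used for small two-arm induction-rate experiments.

## Standardized expression and enrichment

For enrichment and profile work, genes with more than two zero-expression
stages are discarded; a single interior zero is interpolated with the mean
of the two adjacent stages and a boundary zero takes its only neighbor's
value. Genes with exactly two zeros are retained (the discard rule is
"more than two") and filled by the same rules iteratively left to right —
the minimal consistent extension of the single-zero rules, and the audit
reports how many genes each rule touched. Profiles are then standardized
as $\log_2 e_{is} - \mathrm{median}_s(\log_2 e_{is})$, so 0 means "at this
gene's median level". Taking the median on the log scale is identical to
dividing by the median for an odd number of stages and uses the geometric
mean of the two central stages when even; this convention makes the median
of every standardized profile exactly zero, which in turn makes the
upregulation criterion ("at least 0.5, log2 scale, above the gene's own
median", inclusive) exact.

Enrichment per stage is the two-sided hypergeometric test by the
minimum-likelihood convention (sum of all outcome probabilities at most
that of the observed table, with the standard 1e-7 relative tolerance on
the comparison; tail doubling is available as an option), with effect size
reported as $\log_2[(k/n)/(K/N)]$ — the frequency of the annotation among
the stage's upregulated genes over its background frequency — using a
Haldane–Anscombe 0.5 correction only when $k = 0$, where the ratio is
otherwise undefined. The background defaults to genes carrying at least
one annotation after restriction to the declared term subset (a GO slim,
for instance), configurable to a full gene list. Benjamini–Hochberg
adjustment is applied within each stage by default because results are
reported per stage; a global family across the whole scan is available.
Annotations are tested exactly as supplied — no GO-graph ancestor
propagation.

# The synthetic-data generator

The generator exists so that every downstream stage is testable against
known ground truth without any external download. Its defaults are the
study conditions of the motivating design: 12 ordered stages with 3
replicates each (5 for the C2 and EP stages), 18 phylostrata, a few
thousand genes, and an hourglass centred on the heart stage (H).

Design: per-gene log2 baselines are Normal(5, 1.5) on a relative scale;
the hourglass is an age-weighted Gaussian bump over the stage index
(sd = one sixth of the series length) centred on the phylotypic stage for
old genes, and its complement — peaks at the series ends — for young
genes, each scaled by `effectSize` (log2 units; 0 switches the mechanism
off and makes stage means exchangeable, the null used for calibration).
Counts are negative-binomial around the designed stage means with
log-normal library sizes (meanlog log(3e6), sdlog 0.2); `dispersion` is
the NB size parameter $\theta$ (variance $\mu + \mu^2/\theta$, default 5,
Poisson in the large-$\theta$ limit). Phylostrata are drawn with geometric
tilt toward old strata, as in real phylostratigraphic maps; dN and dS are
gamma with ps-dependent scale (expected dN 0.1→0.4 and dS 1→3 from oldest
to youngest), giving the age–divergence coupling that makes TAI and
TdNI/TdSI co-move; target ENC rises with ps (35→55 ± 2, clamped to
[20, 61]) so old genes are more codon-biased; GO-like labels are sparse
(Poisson(1.5) terms per gene from a 50-term pool) and independent of
expression, so enrichment scans on simulated data are null by
construction.

Hit tables list, for each gene, `taxaPerPs` taxa in every stratum from its
true origin through the focal stratum, with e-values log-uniform in
[1e-30, 1e-5], so the oldest-hit rule at the generating cutoff (1e-3)
recovers the true ages exactly at `noise = 0`; noise adds, per gene with
the given probability, one spurious oldest-stratum hit, making the
expected mis-ageing rate exactly `noise` times the fraction of genes with
`true_ps > 1`. CDS are emitted at each gene's length with per-family codon
compositions constructed (not sampled) to realize the target homozygosity,
plus a greedy single-move refinement toward the target Nc; randomness
enters only through which codon is preferred and the codon order, keeping
realized ENC within a fraction of a unit of target for long sequences and
within ±2 above 300 codons.

What the generator does **not** emulate: read-level noise and mapping
artifacts (no FASTQ), gene–gene correlation structure, GC/length biases in
counts, real codon-usage covariation with expression level, lineage-specific
rate variation, or annotation bias toward old genes. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of the
machinery, not the biological claims themselves on any particular dataset.

# Numerical choices and degenerate inputs

- Ties in reciprocal best hits break by bitscore, then e-value, then
  lexicographic subject id, so orthology calls are deterministic.
- A stage with zero total expression over the weighted gene set, a constant
  index profile under min–max normalization, a constant stratum-mean row in
  relative expression, and a retained gene that still has a zero after
  filling are all hard errors naming the offending stage/stratum/gene —
  silent NaN propagation is avoided throughout.
- All generators and the permutation test are deterministic given their
  seed; the pipeline runner flows everything from one configured seed and
  writes md5 digests of every artifact so identical runs are byte-identical.

# Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make its statistical
checks sharp yet quick: oracle equivalence on 100 random 50×12 instances;
flat-line calibration on 500 null simulations of 200 genes with 1,000
permutations (rejection at 5% expected in [0.03, 0.08], plus a KS
uniformity check); hourglass recovery on 100 simulations of 2,000 genes at
effect size 2 (argmin at the designed stage and p < 0.05 in ≥95%);
exhaustive two-sided hypergeometric agreement for all backgrounds N ≤ 60;
and 200 null enrichment scans for the false-positive rate. The
`scripts/acceptance.R` study runs 5,000 genes end to end.

# Known limitations

- The package consumes divergence tables and homology hit tables; it does
  not run alignments or similarity searches itself.
- The flat-line test addresses departure from flatness only; it does not
  discriminate hourglass from early-conservation shapes.
- ENC follows Wright's estimator and conventions; codon-usage measures that
  model background nucleotide composition are out of scope.
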