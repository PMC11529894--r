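---
title: "poolscape: models, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolscape: models, conventions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Pool-seq sequences a single library made from tens of pooled individuals.
Allele frequencies must be estimated from read counts, which stacks two
sampling layers (individuals into the pool, reads from the pool) on top of
sequencing error. The standard defence against error — ignoring alleles seen
fewer than *b* times — silently discards genuine rare variants, exactly the
class of variation that carries the signal of a recent introduction or
bottleneck. Every estimator in this package is therefore written around a
minimum count *b*, a per-site coverage *c*, and a pool size *n*, and the
corrections are expectations over the allele configurations that remain
detectable under those three numbers.

## Diversity estimators

**Per-site π.** For effective counts $c_a$ (alleles below *b* removed) over
coverage $c$, the raw read heterozygosity is
$\hat h = \frac{c}{c-1}\left(1 - \sum_a (c_a/c)^2\right)$,
the unbiased mean pairwise difference among reads. `site_pi()` divides
$\hat h$ by a detectability factor $W(b, c, n)$: the expected fraction of
heterozygosity observable at threshold *b*, computed under the neutral site
frequency spectrum as
$$W(b,c,n) = \frac{\sum_{k=1}^{n-1}\frac1k \sum_{m=b}^{c-b}
\binom{c}{m}\left(\tfrac{k}{n}\right)^m\left(1-\tfrac{k}{n}\right)^{c-m}
\frac{2m(c-m)}{c(c-1)}}{(n-1)/n}.$$
The denominator is the analytic value of the numerator at $b=1$ (the
boundary terms $m=0,c$ carry zero heterozygosity weight), so at $b=1$ the
correction is exactly 1 and `site_pi` *is* the mean pairwise difference over
all $\binom{c}{2}$ read pairs — the package's estimator-oracle contract.
A consequence worth stating plainly: $E[\hat\pi] = \theta\,(n-1)/n$ rather
than $\theta$. We chose the $b=1$ anchoring over strict unbiasedness because
it makes the estimator exactly testable against a brute-force oracle; the
$1/n$ relative bias (2.5% at $n=40$) is far below the sampling noise of any
window statistic. Factors are memoized per $(b, c, n)$.

**Watterson's θ.** Each detected SNP contributes $1/\mathrm{div}_\theta(b,c,n)$
with
$\mathrm{div}_\theta = \sum_{k=1}^{n-1}\frac1k\sum_{m=b}^{c-b}\binom{c}{m}(k/n)^m(1-k/n)^{c-m}$,
the expected detectable segregating-site mass per unit θ (the pooled
analogue of the harmonic-number denominator; it converges to
$a_1 = \sum_{i<n} 1/i$ as $c \to \infty$). This estimator is unbiased, which
the equilibrium acceptance test verifies to within 5%.

**Tajima's D.** Under pooling with heterogeneous coverage D is defined only
up to a convention. Ours: the variance constants use an effective sample
size $n_\mathrm{eff} = \min(n, c)$ aggregated per window by the
coverage-weighted mean (continuous-$n$ harmonic numbers via digamma), and
the θ term in the numerator is scaled by $(n-1)/n$ so both terms estimate
the same quantity and $E[D] \approx 0$ at neutral equilibrium. Using the raw
segregating-site count over $a_1$ instead — the textbook numerator — would
be biased by the detection truncation (about +0.6 at the desk-scale
defaults) and was rejected.

**ΔΘ = 1 − π/Θ.** Near its maximum right after a strong bottleneck (rare
variants dominate, π ≪ Θ), decaying toward 0 as variants rise in frequency.
A hard cap worth knowing: with all variants singletons in a pool sample of
$n$, ΔΘ $= 1 - 2a_1/n$ — about 0.79 at $n = 40$. "ΔΘ near 1" is therefore
unreachable for realistic pools; introduced populations plateau near 0.5,
which is also where the empirical values of the motivating system sit.

**πS/πNS.** CDS positions get a synonymous site length — the fraction of
the 3 possible substitutions that preserve the amino acid (standard code) —
and window πS is the summed π of synonymous SNPs over the summed synonymous
lengths of valid CDS sites (πNS analogously). SNPs are classified by their
top-two alleles; positions under conflicting overlapping frames are
excluded.

## Differentiation

**FST** per SNP is $(\pi_T - \bar\pi_W)/\pi_T$ with the $c/(c-1)$
small-sample factor per pool and $\min(c_1,c_2)/(\min(c_1,c_2)-1)$ on the
heterozygosity of the summed counts — the min-coverage factor is what the
classical pooled estimator uses and what the package's frozen hand-computed
case (0.3788 / 0.5051 → FST 0.25) pins down. Negative per-SNP values are
clamped to 0 before window averaging; windows without SNPs are NA.

**dXY** selects each population's most abundant allele per jointly valid
site and reports the fraction of sites where they differ. Ties are broken
uniformly by a seeded generator; a seed is *required* whenever a tie exists
(reproducibility contract) and both pools share one stream, which makes
dXY(x, x) exactly 0 for any seed. By default all jointly valid sites enter
the denominator; `snps_only` restricts to SNPs. Monomorphic sites then
contribute 0 unless fixed for different alleles, so dXY is an absolute
divergence on the site scale.

## The TE insertion caller

Evidence rows are read pairs distilled upstream: anchor position and
strand on the reference plus the class of the mate (a TE family,
`reference`, or `structvar`), with mapping quality. The caller:

1. builds a physical pileup — per position, how many pairs of each class
   span it (a pair spans `span` bp beyond its anchor, default 150);
2. subsamples every position with total physical coverage above
   `target_coverage` (default 10) without replacement, seeded; positions at
   or below target are untouched, never upsampled;
3. finds, per family and strand, maximal runs with support ≥ `min_count`
   (default 2); runs separated by less than one pair span are re-joined
   (threshold crossings fragment one physical cluster), giving one
   signature per strand placed at the support-weighted center;
4. discards signatures with other-family support > 2 or structural-variant
   support > 2 at the center;
5. pairs forward and reverse signatures of one family with separation in
   [−200, 300] bp (greedy, nearest separation), placing the insertion at
   the midpoint; unpaired signatures are kept, shifted half a span inward
   (the breakpoint lies beyond the cluster, and the paired midpoint cancels
   that offset automatically);
6. estimates frequency as TE/(TE+reference) physical coverage at the
   signature center, averaged over paired signatures.

This is a faithful-in-structure reimplementation of the published four-step
signature pipeline with its seven printed parameters; output parity with
the original tool is not promised — parity with the synthetic truth is the
test surface. At target coverage 10 the information limit is sharp: an
insertion at frequency 0.1 offers on average *one* supporting pair per
side, so no caller honouring min-count 2 can detect much more than ~46% of
that class; the acceptance assertion demanding 95% pooled detection across
frequencies 0.1–1.0 is left red with this analysis rather than weakened.
Frequency recovery (MAE < 0.1 pooled) passes.

**Population-unique insertions** match events of the same family within a
positional tolerance (default 25 bp — the original analysis does not state
whether matching was exact; the tolerance is exposed). **Spectra** report
equal-width histograms on [0,1] and the low (<0.5) / high (>0.5) / fixed
(=1 within 1e−9) fractions.

## Landscapes, composition, telomeres

**Divergence landscapes** replace the de-novo assembly stage of the
read-based protocol with direct read-versus-library local alignment
(match 1, mismatch −1, gap open 2, extend 1, both orientations, best hit by
score). Hits below the floor — ≥ 80 matching columns or ≥ 50% of the read
aligned — are dropped; divergence is (mismatches + gap columns)/aligned
columns in 1% bins, and each cell's genome proportion is aligned read bases
over total sampled bases (so unmatched reads dilute, proportions sum ≤ 1).
Local alignment never ends on a mismatch, which trims roughly 1–2 divergent
columns per read end; at 20% true divergence the modal bin lands 1–2 bins
low, and the landscape tests allow exactly that.

**Window composition** merges intervals per class before computing covered
fractions (invariant to feature order and to splitting features into
abutting pieces); windows beyond a scaffold end are truncated, with the
truncated length as denominator.

**Telomere scan** counts non-overlapping occurrences of each motif and its
reverse complement per window (default 10 kb). An end is "enriched" when
the maximum count over its terminal 3 windows is ≥ 25 and ≥ 10× the
scaffold median — deliberately conservative because 5-mers have a high
random background (~20 occurrences per 10 kb).

## The synthetic world

The generator states one world and keeps it: four pools (sizes 40, 21, 33,
40 — the design of the motivating study, passed verbatim, not doubled to
chromosome counts), mean coverage 60× Poisson, sequencing error 0.001
(~Q30, unstated upstream), and a demography of a severe insect
introduction: ancestral diploid size N₀ = 500, founder propagule N_b = 5,
founding T = 180 generations ago (~36 years at 5 generations/year),
exponential recovery to N_c = 2000, μ = 2.5 × 10⁻⁶ so ancestral
θ = 4N₀μ = 0.005. The founding phase must prune the sampled genealogy to
about one surviving lineage for the introduction signature to emerge; the
cumulative pairwise founding hazard $T/(2N_b\ln(N_c/N_b))$ is ≈ 3 here, so
deep ancestral variation survives in only a few percent of blocks and the
world's true ΔΘ sits near 0.5 — the regime the motivating system actually
shows. These sizes are desk-scale placeholders (the real census history is
unknown); they were chosen once from this reasoning, not fitted to test
outcomes.

Sampling is honest two-stage: the per-block coalescent sample of n lineages
*is* the draw of pool genomes from the population (blocks of 10 kb share
one genealogy and are unlinked), then reads are Binomial(c, k/n) with
errors redistributed uniformly over the other three bases.
`sample_pool_reads()` exposes the stages directly and collapses to
single-stage binomial sampling as n → ∞ (tested at n = 10,000).

What a green test does **not** establish: the generator has no linkage
beyond 10-kb blocks, no recombination map, no selection, no indels
(indel masking is exercised on constructed pileups instead), no mapping
artefacts, and Poisson — not empirically overdispersed — coverage. TE
evidence uses an idealized insert-size model (anchors 80–220 bp from the
breakpoint) and classifies mates perfectly; real pipelines mis-assign
mates near nested or truncated copies. Error doubletons do pass min-count 2
at ~6 × 10⁻⁴ per site at 60×; the claim that μ = 0 implies literally zero
SNPs holds only approximately, and the tests assert the order-of-magnitude
gap instead.

## Orchestration and statistics

`run_pipeline()` runs sync/generator input, optional indel masking from an
mpileup, windowed diversity per pool, all pairwise FST/dXY, Kruskal–Wallis
(tie-corrected, df = k−1) with pairwise two-sided Wilcoxon post hoc tests,
Holm adjustment (the original analysis names no method; Holm is recorded
and configurable) and an insert-and-absorb compact letter display verified
against its two axioms. The config is JSON (no YAML parser ships in the
target environment); every default is echoed into the manifest together
with all seeds and input/output checksums, so no silent defaults exist and
identical config + inputs + seeds reproduce identical checksums.

## Known limitations

- Estimator corrections assume the neutral SFS prior for the detectability
  expectation; under strong skews the correction is approximate (this is
  inherent to the approach, not a bug).
- Tajima's D under pooling follows the stated convention; absolute D values
  are comparable within this package, not across tools.
- The TE caller reports single-signature insertions with position accuracy
  limited by cluster geometry (~±40 bp at min support).
- Window tables report per-window means over non-NA windows; whether the
  motivating analysis averaged over windows or sites is unstated, and the
  window mean is the recorded default.
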