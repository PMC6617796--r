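---
title: "Heterozygosity analysis: model, scan conventions, and simulator design"
author: "HetScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity analysis: model, scan conventions, and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HetScan)
```

## The population-genetic model

An inherited autosomal-dominant variant reaches a patient on a chromosome
segment, R, bounded by the two recombination events closest to the
variant in its transmission history. Within R the disease chromosome is a
frozen copy of the founder haplotype; the homologous chromosome is an
ordinary population draw. For a biallelic marker in R with founder-side
allele *A* at population frequency $f$, disease-allele frequency $e$, and
complete disequilibrium ($D = D_{\max} = e(1-f)$, so the $u\!-\!B$
haplotype is absent and $D' = 1$), a carrier is heterozygous whenever the
non-disease chromosome carries $B$:

$$H \;=\; P(B \mid +) \;=\; \frac{1-f}{1-e} \;>\; 1-f,$$

compared with the Hardy–Weinberg $2f(1-f)$ anywhere else. The enrichment
$r = 1/[2f(1-e)]$ grows without bound as $f \to 0$: rare markers on the
founder haplotype are almost always heterozygous in carriers while being
almost always homozygous in everyone else. `haplotypeFreqs()`,
`hetNearDisease()`, `hetRandom()` and `hetRatio()` implement this model
exactly and serve as the analytic oracle for the simulator.

Assumptions worth keeping in mind: the model is two-locus, ignores decay
of $D$ over generations (R is *imposed*, not evolved), and the elevated
heterozygosity requires the founder to carry the *minor* allele — where
the founder carries the major allele, carrier heterozygosity is actually
*below* background (see "Simulator design" for the consequences).

## Stage 1: the moving-average scan

At every variant at least $m$ variants from each chromosome end,
`computeHTrack()` counts homozygous ($g$) and heterozygous ($h$)
genotypes over the $(2m+1)$-variant window, pooled over all samples, and
emits $H = h/(g+h)$.

- **`m` (default 50).** The window is counted in *variants*, not bp, so
  a 101-point average spans ~100 kb at WGS density and much more in
  exomes. Averaging cancels the allele-frequency dependence of
  single-site heterozygosity; the default matches the classic 101-point
  choice. Results vary somewhat with the window size, as they do for any
  windowed scan.
- **Pooling.** With $n$ individuals analyzed jointly, raw counts are
  pooled, so $g + h = (2m+1)\,n$ without missingness. Pooling counts is
  not the same as averaging per-individual $H$ under missingness; the
  counts formulation is the one that keeps $H = h/(g+h)$ exact, and the
  package's tests verify the per-sample decomposition.
- **Missing genotypes** contribute to neither count. A window in which
  *every* genotype is missing yields no $H$ at all — the variant is
  skipped (and counted in the track's `nSkipped`), *not* scored 0, which
  would fabricate homozygosity and distort segment boundaries.
- **Edges.** The first and last $m$ variants of a chromosome carry no
  value; windows never span a chromosome boundary. Chromosomes with
  $\le 2m$ variants are skipped with a warning.
- Sex chromosomes are scanned like autosomes but flagged, since
  hemizygous genotypes make "heterozygosity" a different quantity there.

## Stage 2: regions of increased heterozygosity

`segmentRIH()` scans the successive differences of consecutive $H$
values. Runs of equal $H$ are collapsed first (zero differences are
skipped), then a segment is a maximal rise-to-a-local-maximum-then-fall.
Conventions the package fixes where prose alone is ambiguous:

- Stated in terms of signed differences the rule is easy to garble
  (whether a negative $C_i = H_i - H_{i-1}$ marks a rise or a fall
  depends on which end of the run one scans from); the operational
  intent — segments rise to $H_{\max}$ and then fall — is unambiguous
  and is what is implemented.
- A segment *includes* the local minimum it rises from; when two
  segments are adjacent, the shared minimum stays with the earlier
  segment's fall, keeping segments disjoint.
- Strictly monotone stretches between a fall and the next rise, a
  falling prefix at the chromosome start, and a terminal rise that never
  falls belong to **no** segment. A target variant there is reported as
  the explicit "n" state rather than given an artificial rank.
- $H_{\max}$ ties inside a segment cannot occur after collapsing; across
  segments, ties share the smallest (competition) rank. The position
  attaining $H_{\max}$ is the leftmost variant of its run.
- Segment length defaults to bp (`end − start` of member variants),
  since localization distances are physical; a variant-count alternative
  is available via `lengthUnit = "variants"`.
- The length filters rank2–4 discard segments with length $< w/4$,
  $w/2$, $w$ ("at least" comparisons), with $w$ the genome-wide mean
  length; per-chromosome averaging was rejected as it would make ranks
  incomparable across chromosomes. The target's own segment is subject
  to the same filter — rank4 is deliberately risky and may discard the
  true segment, which the report shows as `n`.

Ranks use competition ranking throughout (rank = 1 + number of strictly
larger values), the conservative choice for a reported candidate rank.
Top-percent is $100\cdot\mathrm{rank}/N_\mathrm{var}$ at full precision
internally, displayed with one decimal, half-up (`formatTopPct()`).

## Empirical significance

`empiricalP()` places a null disease variant uniformly among the
variants with an emitted $H$, $N$ times (default 999), with replacement.
Since the scan is identical whatever the target, each replicate's
analysis reproduces the observed track exactly; the replicate values are
therefore read off the precomputed track — an *exact* shortcut, verified
in the tests against a literal per-replicate re-scan. The count $k$ of
values at least as large as the observed one *includes the observed
value itself*, forced by the floor $p = 1/(N+1)$ (0.001 at $N = 999$):
with $k \ge 1$, $p = k/(N+1)$ can never be 0. Null positions landing in
no RIH contribute no $H_{\max}$ exceedance. Edge variants without $H$
are excluded from the null draw because the observed statistic requires
one. $p$ is super-uniform under the null (verified by simulation) and
bit-reproducible given a seed.

## Carrier discrimination

A *low* top-percent marks a carrier; `classifyThreshold()` predicts
carrier when `topPct < threshold`. (Described verbally one sometimes
says scores "above" a threshold line; the worked arithmetic — six
individuals below an 18.2 cut predicted carriers — fixes the direction,
and the package follows the arithmetic.) `rocCurve()` sweeps a cut just
above each distinct observed score plus the degenerate endpoints;
placing the cut "just above" never changes a confusion matrix, so the
curve is exact. The trapezoidal AUC equals Mann–Whitney concordance with
half-credit ties, which the tests check pairwise and against an
independent ROC library. The packaged rule `carrierCallRule` (top-% <
21, sensitivity 0.889, specificity 0.750, total correct 0.824) is
estimated from the bundled 17-individual set; with $n = 17$ it is a
screening heuristic, not a calibrated classifier.

## Simulator design

`simulateCohort()` generates what the model needs and nothing more:
uniform marker positions, minor-allele frequencies from
$f = \max(f_{\min},\, 0.5\,\mathrm{Beta}(1, 4))$ (mean ≈ 0.10, skewed
toward rare, floored at 0.005), Hardy–Weinberg genotypes everywhere
except carriers inside R, where one haplotype is the shared founder.
Defaults — 3 chromosomes × 2,000 markers over 2 Mb (1 marker/kb), 3
carriers, 3 noncarriers, 2% missingness, R half-width 50 kb — are the
package's reference conditions, chosen so a desk-scale genome still has
\>5,000 scan windows and \>1,000 RIH segments.

Two defaults deserve justification:

- **`founderMinor = TRUE`.** If the founder allele were drawn at the
  population frequency, carrier heterozygosity inside R would average
  $f(1-f) + (1-f)f = 2f(1-f)$ — exactly the background, with zero mean
  excess: sites where the founder carries the major allele *suppress*
  heterozygosity by just as much as minor-allele sites boost it. Real
  data escape this cancellation through ascertainment: a cohort VCF only
  contains sites polymorphic in the sequenced samples, and inside R the
  founder haplotype's own rare alleles are guaranteed into the site list
  by the carriers themselves, precisely the sites where every carrier is
  heterozygous. Rather than model ascertainment (which would break the
  generator's clean Hardy–Weinberg contract for carrier-free cohorts),
  the generator plants the minor allele on the founder haplotype —
  the post-ascertainment regime the closed-form model describes.
  `founderMinor = FALSE` provides the population-frequency founder, and
  a test demonstrates its no-signal property.
- **R half-width 50 kb ≈ 50 markers.** An R much wider than the
  $(2m+1)$-variant window produces a broad fluctuating plateau of high
  $H$ that fragments into several RIH, any of which may carry the
  regional maximum; the variant's own segment then ranks well but not
  top. With R at the window scale, $H$ peaks *at* the disease variant —
  the geometry the 101-point window is designed for — and the
  truth-containing segment carries the peak. Biologically this is the
  old-variant regime: many transmissions, short unrecombined segment.

The disease variant itself is emitted as a site (heterozygous in
carriers, homozygous reference in noncarriers). The generator is
deterministic given its seed, to the byte in the written VCF.

**What the simulator does not model:** background linkage
disequilibrium outside the founder segment, site ascertainment,
genotyping error, population structure, pedigree-based shrinkage of R
(a direct-R imposition replaces the recombination process), and
hemizygosity. Passing tests on these cohorts therefore demonstrate the
scan's statistical behaviour under its own model — clean HWE background
with a planted founder segment — not performance on real sequencing
artifacts.

## Problem sizes and numerical choices in the test suite

The suite runs desk-scale versions of every check: oracle equivalence of
the windowed counts against a brute-force double loop up to
$10^4 \times 5$ matrices; segmentation against an independently coded
local-extremum bracketing on random tracks; the significance shortcut
against a literal re-scan at $10^3$ variants, $N = 99$; simulator
concordance with the closed-form model at $10^4$ markers × 20 carriers
(3 Monte-Carlo standard errors); super-uniformity of null p-values over
200 seeded trials (tolerance $2/(N+1)$ plus 3 SE of estimation); and
end-to-end recovery over 50 seeded cohorts at the default conditions
(truth segment in the top 1% of $H_{\max}$ ranks, simulated ROC
AUC > 0.8). Fixed seeds make every stochastic check reproducible.

## Known limitations

Beyond the simulator's scope above: the scan has no variant-quality or
allele-frequency weighting (windowed averaging is the only defence);
results depend on the window size $m$; physical bp lengths make RIH
comparisons across recombination-rate regimes imperfect (an LD-map
metric would be better); and a *de novo* dominant variant has no founder
segment and produces no signal at all. Empirical p-values are
genome-wide for a *single* tested candidate; testing many candidates
needs additional multiplicity control.
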