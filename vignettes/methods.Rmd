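---
title: "Classifying somatic variants from tumor RNA-seq without a matched normal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying somatic variants from tumor RNA-seq without a matched normal: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasomatic)
```

## The problem

Calling somatic mutations normally requires a matched-normal sample: the
normal genome tells the caller which variants are inherited.  When only
tumor RNA-seq is available, the caller's output is a mixture of somatic
mutations, germline variants, and RNA-specific artifacts, with germline
variants outnumbering somatic mutations by orders of magnitude.  No single
annotation separates the two classes — population databases miss rare
germline variants, allele fractions overlap once tumor purity and
allele-specific expression blur them, and panels of normals are incomplete —
so `rnasomatic` combines 31 weak signals in a random-forest ensemble, then
scrubs the predicted-somatic calls with an RNA-specific filter chain.

The package implements the full computational path: variant-table ingestion
and labeling, panel-of-normals (PoN) scoring, a beta-binomial
detection-power model, feature assembly, fold-wise ensemble training with
majority-vote prediction, the filter chain, per-sample evaluation, and
tumor-mutational-burden (TMB) survival analysis.  A synthetic-cohort
simulator generates every input, so the whole pipeline is exercisable
without access-controlled sequencing data.

## Panel-of-normals score

Each genomic position in a panel of normals is summarized by an 8-bin
histogram $\vec h$ of the normals' evidence: bin 1 holds normals with total
coverage below 8 (insufficient), bins 3–8 hold normals meeting nested
(alt count, alt fraction) thresholds — $(1, 0.1\%), (2, 0.3\%), (3, 1\%),
(3, 3\%), (3, >20\%), (10, 20\%)$ — and bin 2 holds covered normals below
every threshold.  Because the thresholds are nested we assign each normal
to the *highest* satisfied bin, so the bins partition the panel and
$\sum_b h_b$ equals the panel size.

A candidate variant's allele fraction is modeled as
$f \sim \mathrm{Beta}(n_{alt}+1,\; n_{ref}+1)$, the posterior under a
uniform prior, which propagates count uncertainty instead of using the
point fraction.  The density is integrated over the six fraction slices
$[0, 0.1\%), [0.1\%, 0.3\%), \dots, [20\%, 100\%]$ via the regularized
incomplete beta function (`pbeta`), giving a mass vector $\vec f$ with
$\sum_i f_i = 1$ exactly; slices are closed on the left, open on the right,
the last closed at 1.  The score is $S = \vec f \cdot \vec h_{3:8}$ and a
variant is PoN-filtered when $\log_{10} S \ge -2.5$.  Numerical choices:
$\log_{10} 0$ is clamped to $-10$ (any value below the threshold works;
$-10$ keeps the classifier feature finite), and a position absent from the
panel map is interpreted as "all normals covered, no alt evidence"
($h = (0, m, 0, \dots, 0)$), which yields $S = 0$ and keeps the variant —
the permissive reading of an uninformative panel.  Slice integrals use
`pbeta` rather than quadrature for speed; quadrature and Monte-Carlo
binning are retained in the test suite as independent oracles.

## Detection power

For a mutation seen in RNA with $x$ alternate and $y$ reference reads, the
power to re-detect it in DNA at coverage $N$ integrates the binomial
detection probability over the allele-fraction posterior, giving the
beta-binomial tail

$$P(k \mid x, y, N) = \binom{N}{k}
  \frac{B(k+x+1,\; N-k+y+1)}{B(x+1,\; y+1)},
  \qquad \text{power} = \sum_{k \ge k_{\min}} P(k),$$

evaluated in log space (`lchoose` + `lbeta`) so coverage in the hundreds
does not overflow.  The minimal read count $k_{\min}$ is the smallest $k$
whose binomial upper tail under the site's error rate falls strictly below
1%.  The error rate uses the matched normal's maximal alternate count $m$
with an add-one (Laplace) correction; we implement the binomial
success/failure form $(m+1)/(N+2)$ by default and expose the four-category
form $(m+1)/(N+4)$ behind the `correction` switch, since the two readings
of "Laplace correction over the maximal alternate allele" differ only in
the denominator convention.  The tail comparison uses $P(X \ge k)$; with
the strict `<1%` cutoff both it and $P(X > k)$ conventions coincide except
at knife-edge parameter values.  A mutation is "powered" when power
$> 0.95$ (strict) and it has at least 4 alternate reads.

## The 31 features and the ensemble

Per variant, in frozen order: tumor ref/alt read counts, caller LOD, allele
fraction (1–4); presence and allele frequency in each of four germline
databases (5–12), where a missing frequency — absent variant or absent
annotation — is imputed with the resource-wide mean AF; a non-coding
indicator for IGR/Intron/RNA/lincRNA classifications (13), informative
because germline variants are common enough to appear in
fuzzy-transcription regions where somatic calls essentially never survive;
and the DNA and RNA PoN blocks, eight bins plus the $\log_{10} S$ score
each (14–31).  The ordered name list is hashed into every trained model and
checked at prediction time, so a model can never be applied to reordered
features.

Training follows a sample-wise protocol: 100 samples are drawn for
training, divided into 5 folds of 80/20; one 50-tree random forest
(`ranger`, $\lfloor\sqrt{31}\rfloor = 5$ candidate features per split,
impurity importance, single-threaded for reproducibility) is fitted per
fold, and per-sample precision/recall is recorded on each fold's validation
samples.  Folds are sample-wise rather than variant-wise because the
evaluation unit is the sample; variant-wise folds would leak a sample's
variants across the boundary.  Unseen variants get the label that wins at
least 3 of the 5 forests' votes; with five binary voters no tie exists.
Class imbalance is left untouched by default — the germline class dominates
roughly 50:1 and the forests handle it — with an optional
`downsample_germline` switch for cohorts where germline contamination of
the predicted set becomes substantial.  Tree depth and class weights are
the fitting library's defaults and are recorded in the model archive's
metadata.  Feature importances are each forest's impurity importances
normalized to sum to one, averaged across folds.

Variants are labeled for training from the matched-normal caller run:
rejection tags `normal_lod`, `germline_risk`, or `alt_allele_in_normal`
mean germline; a clean pass of the full pipeline means somatic; anything
else (artifact rejections) is excluded rather than labeled germline, which
would inject label noise.

## The RNA filter chain

Predicted-somatic calls pass a fixed-order chain: minimum 3 alt reads; DNA
PoN score; realignment hook; RNA PoN score; population MAF $> 5\%$ (strict,
and only on recorded frequencies — an entry without an AF is no evidence of
being common); non-coding regions; RNA-editing sites; duplicate
supporting-read collapse (reads stacked at identical coordinates count
once, after which the 3-read floor is re-checked); sequencing leakage; and
pseudogene/IgG genes.  A removed variant is attributed to the first filter
that removes it, and per-filter counts are reported.

The leakage rule fires when at least 3 of the 6 flanking bases in the
7-mer reference context equal the alternate base; the center base is
excluded since the reference context carries the reference base there,
making an alt comparison at the center ill-defined.  The realignment step
requires external aligners and is out of scope; it is a user-suppliable
hook, and every report notes when it was not applied since precision may be
overestimated without it.

## TMB and survival

TMB is the raw count of non-silent somatic SNVs per sample (missense,
nonsense, nonstop, splice-site, translation-start); no per-megabase
normalization is attempted because that requires a coverage footprint the
variant table does not carry.  Stratifications: a median split (a sample
exactly at the median is "high"; configurable tie convention) and a
three-group split whose very-high tier is the top decile, boundary
inclusive, with the remaining samples median-split; a `top_fraction` of 0
degenerates to the plain median split by construction.  Group differences
use the logrank test (`survival::survdiff`) and the multivariate analysis
is a Cox proportional-hazards fit on $\log_{10}(\mathrm{TMB}+1)$, age, and
ordinal-coded stage.  The $+1$ guards samples with zero TMB, which real
melanoma cohorts rarely contain but simulated and low-burden cohorts do;
samples with unmappable stage are excluded with a logged count.

## What the simulator emulates — and what it does not

The simulator is the package's study condition, not a demo.  Per sample it
draws a somatic burden from a negative binomial (mean 20, dispersion 2 —
one knob spans melanoma-like and colon-like burdens), 1000 germline
variants (the 50:1 excess is load-bearing: it is what makes single-feature
classification hopeless at realistic database miss rates), and a 1%
admixture of artifact records that each violate exactly one filter rule.
Somatic allele fractions are $\text{purity} \times \text{clonality}/2$ with
purity $\sim U(0.2, 1)$; germline heterozygous fractions are dispersed
around $0.5$ by a $\mathrm{Beta}(5,5)$ allele-specific-expression model
(about $\pm 0.15$), without which a simple allele-fraction threshold would
separate the classes far better than it can on real RNA-seq.  Database
presence is 95% for germline (a 10% rare tail present at 65% per database,
the common-variant presence solved to keep the marginal at 95%) and 1% for
somatic.  Panels of normals cover 80% (DNA) / 70% (RNA) of germline
positions with Hardy–Weinberg genotypes at the population AF; panel size
defaults to 100 normals — a desk-scale stand-in for the thousands of
normals real panels aggregate, which mainly coarsens the histogram
resolution.  Survival times are exponential with hazard multiplied by
$\exp(-0.5 \cdot \log_{10}(\mathrm{TMB}+1))$, matching the protective
hazard ratios around 0.6 reported for log-TMB in melanoma.

Truth-somatic records are generated to pass the filter chain (contexts
below the leakage threshold, distinct supporting reads, coding
classifications, at least 3 alt reads, no panel representation): the
ground-truth somatic set in a matched-normal study is itself the output of
that chain, so records violating it could never carry a somatic label.
Sub-seeds derive from the master seed as $\text{master} + 7919 i$, so
growing the cohort never perturbs earlier samples, and single-threaded
forests make the end-to-end run byte-reproducible.

Features of real data deliberately not emulated: shared germline variants
across individuals (each simulated sample's variants are private, so PoN
and database entries are per-cohort constructions), trinucleotide mutation
spectra, strand artifacts, alignment-induced errors that the realignment
step would catch, and per-gene expression structure.  Passing tests
therefore demonstrate that the machinery — scoring, training protocol,
vote, chain, survival link — behaves as specified under controlled
conditions, not that any particular precision/recall level transfers to a
given real cohort.

## Problem sizes and verification

The bundled study uses 200 samples (100 train, 100 held out), roughly
206,000 variant records, and 100-normal panels; the end-to-end run takes
about two minutes on one core.  At these conditions the held-out per-sample
median precision and recall are at or near 1.0 and 0.99 while the best
single feature stays below F1 0.5 — the qualitative contrast between
ensemble and single features that motivates the design, deliberately not a
reproduction of any published cohort's numbers, which require
access-controlled data.  Every distributional component is tested against
an independent oracle: beta slices against quadrature and Monte-Carlo
binning, the beta-binomial against exact beta-function arithmetic, the
minimal read count against brute-force tail scans, the logrank statistic
against an explicit risk-table computation and a type-I-error simulation,
and the Cox fit against a hand-coded partial likelihood maximized
independently.

## Known limitations

Indels, multi-allelic records (each ref/alt pair is treated as an
independent record), and VCF input are out of scope; the realignment and
oxidation-artifact filters are hooks or absent; vote counts are not
calibrated into probabilities; and the classifier inherits whatever
population bias the germline databases carry — cohorts from ancestries
underrepresented in those databases will see more germline leakage into
the predicted somatic set.
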