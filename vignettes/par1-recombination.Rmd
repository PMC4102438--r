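---
title: "Crossover maps and GC-biased evolution in the pseudoautosomal region"
author: "par1map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover maps and GC-biased evolution in the pseudoautosomal region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(par1map)
```

## The scientific setting

PAR1, the ~2.7 Mb pseudoautosomal region at the tips of the human X and Y
short arms, must host one crossover in every male meiosis for the sex
chromosomes to disjoin properly. That obligation concentrates roughly
50 cM of male genetic map into under 3 Mb — a recombination rate an order
of magnitude above the genome average — while the female map of the same
region is unremarkable. `par1map` implements, end to end, the
computational machinery needed to study recombination in such a region
from three independent kinds of evidence:

1. **Direct observation**: crossovers detected in nuclear families from
   SNP genotypes, via a Lander-Green hidden Markov model adapted to
   genotyping error and missing parents, and sex-specific genetic maps
   accumulated from the crossover posteriors.
2. **Historical recombination**: comparison of the pedigree maps with
   LD-based maps — rank correlation at a physical scale, rate profiles
   centred on crossovers or on PRDM9 motif/binding-peak anchors, mixture
   fits expressing one map as a weighted blend of two others, and a
   model-free mean-squared-difference bootstrap.
3. **Sequence evolution**: GC-biased gene conversion (gcBGC) read out of
   derived-allele-frequency spectra, and human–chimpanzee substitution
   patterns regressed on recombination rate.

A seeded synthetic-data module generates every input the pipeline
consumes, so each stage is testable at desk scale with no external data.

## The crossover HMM

For a nuclear family with $n$ children the hidden state at each marker is
the *inheritance vector*: $2n$ bits recording which of each parent's two
haplotype slots each child received (paternal bits first). Founder
ordered genotypes are summed out marker by marker under Hardy–Weinberg
with the panel's allele frequencies; because founder haplotypes are
assumed in linkage equilibrium this per-marker sum is exactly the sum
over founder phases, which is why phase does not need to be part of the
state.

* **Transitions.** Between adjacent markers each meiosis bit flips
  independently with the Haldane probability
  $\theta = (1 - e^{-2d})/2$, where $d$ is the inter-marker distance in
  Morgans under the sex-appropriate prior map. No crossover interference
  is modelled; intervals are short. The default priors are uniform maps
  of 50 cM (male) and 5 cM (female) across the panel span, reflecting
  the obligatory-crossover expectation; the posterior map can be re-fed
  as prior for a refinement pass, though see *Limitations*.
* **Emission.** Each observed genotype is correct with probability
  $1-\varepsilon$ and misread uniformly over the two wrong genotypes
  otherwise; missing observations contribute likelihood 1. An
  ungenotyped founder is marginalised under Hardy–Weinberg. The default
  $\varepsilon = 0.002$ is a typical array-genotyping error rate.
* **Output.** Forward–backward recursions yield, for every meiosis and
  inter-marker interval, the posterior probability of recombination in
  that interval, plus the family log-likelihood. A Mendelian-impossible
  family at $\varepsilon = 0$ reports a log-likelihood of $-\infty$
  rather than failing.

Beyond the pseudoautosomal boundary, fathers and sons are hemizygous:
`augmentParBoundary()` appends X-linked markers at which the father is
modelled with one real X haplotype and one *dummy* chromosome carrying a
fixed allele and no recombination. A son's paternal bit is pinned to the
dummy (Y) side and a daughter's to the real X, so the paternal bits are
effectively observed in the X region, which is what makes crossovers
between the last pseudoautosomal marker and the boundary detectable.
Hemizygous genotypes are coded with the dummy counting as allele "A".

**Identifiability note.** Without a genotyped grandparent, founder phase
is only defined up to a global flip, so a family with two children cannot
attribute a single crossover to a specific child — the posterior splits
it 0.5/0.5 between them (their bit patterns are exchangeable under the
flip). Three or more children break the tie because the flipped
explanation then requires multiple crossovers. Summed over meioses (the
quantity map building uses) the mass is unaffected.

## From posteriors to maps and events

`buildSexMaps()` follows the direct estimator: add the posterior
crossover probability in each interval over all parents of one sex and
divide by the number of meioses of that sex; the per-interval quotients,
taken as Morgans, accumulate into the cumulative map. `callEvents()`
post-processes each meiosis: maximal contiguous runs of positive
posterior whose mass reaches the event threshold (default 0.5) yield
`round(mass)` events (at least one), split at event-count quantiles of
the run's cumulative mass, and each event is reported on the smallest
contiguous marker span holding 95% of its mass (ties leftmost). With one
obligatory, well-localised crossover this reduces to exactly one event
in the true interval; the threshold of 0.5 makes the
one-event-per-obligatory-crossover case exact in expectation.

## Map comparison statistics

All pedigree-derived significance resamples **parents**, not events,
because events of one father are not independent.

* `spearmanAtScale()` tiles the shared span with non-overlapping windows
  (50 kb is the scale used for pedigree-vs-LD comparisons) and rank-
  correlates the windowed rates; exact p for ≤ 9 windows.
* `profileAroundPoints()` averages, over anchors, the windowed rate at
  each offset of a symmetric grid (e.g. 5 kb windows at 500 bp offsets
  around crossover midpoints; 2 kb at 100 bp around motif anchors).
  Anchor-offset cells whose window leaves the mapped span are missing,
  not zero. `bootstrapPeakTest()` tests the central elevation against
  the region-wide mean by resampling anchors (5000 draws in the study's
  usage).
* `fitMixtureWeight()` expresses an admixed population's map as
  $\alpha A + (1-\alpha) B$: the shared span is cut into 10 kb bins,
  each bin's crossover probability is its blended genetic mass, each
  event spreads uniformly (by physical length) over the bins its
  interval covers, and $\alpha$ maximises the event log-likelihood by
  1-D search. A likelihood (rather than least-squares) objective was
  chosen because it handles the very uneven per-bin masses gracefully
  and makes the identical-maps case analytically degenerate — which is
  surfaced via a flag, not hidden. Events overlapping bin edges are
  split by physical overlap.
* `msdBootstrap()` is the model-free counterpart: resample fathers,
  rebuild a windowed rate track from their events, and record which
  candidate map is closer in mean squared difference. Ties count one
  half, so swapping the candidates maps the fraction $f$ to $1-f$
  exactly.
* `regionRateDifference()` contrasts event-mass rates between two
  disjoint regions (telomere-proximal vs boundary-proximal contrasts),
  with bootstrap-over-parents significance.

## Anchors: motifs and binding peaks

The canonical PRDM9 target in humans is the degenerate 13-bp motif
`CCnCCnTnnCCnC`. `scanDegenerateMotif()` reports match midpoints in
forward-strand 0-based coordinates, scanning both strands by default
(the motif is not palindromic). An `N` in the sequence never matches,
even at degenerate positions — an unknown base is not evidence of a
motif. Anchor hygiene follows the published filtering rules exactly:
motifs require more than one SNP per 2 kb in the surrounding 50 kb
(strict inequality), motif clusters within 150 bp thin to the most
central member (minimum summed distance, ties leftmost — "most central"
is not defined operationally in the source, so this is a documented
choice), and binding peaks within 10 kb thin to the smallest p-value.
Annotation overlap is half-open containment.

## GC-biased gene conversion statistics

Variants polarized by the chimpanzee allele fall into six classes:
AT→GC transitions/transversions (GC-gaining), GC→AT (GC-losing), and
the GC-conservative A↔T and C↔G. Sites in a CpG context on either
strand (ancestral *or* derived base forming CpG with its flank) are
excluded by default because methyl-C deamination dominates their
mutation process. The minor-allele-frequency inclusion cutoff is a
parameter (default 0.01; the study's printed cutoff is not legible in
the source text), and spectra use 0.10-wide frequency bins so the
extreme bins are the >90% and <10% tails.

* `fixationBias()` counts GC-gaining vs GC-losing sites with derived
  frequency in [0.95, 1) and returns their ratio — 1 under equal
  fixation pressure — with a binomial test on the split.
* `fitUMixture()` models a target spectrum as
  $\lambda U + (1-\lambda)\,\text{background}$ where $U$ puts mass
  0.5/0.5 on the two extreme bins (a binned idealisation of "derived
  alleles either newly arisen or nearly fixed"; point masses at 0 and 1
  are impossible for segregating sites). $\lambda$ maximises the binned
  multinomial likelihood on a 0.01 grid polished by golden-section
  search (the boundary optima at 0 and 1 matter), with a bootstrap CI
  over target sites.
* `qqCompare()` and `compareExtremeBins()` compare two spectra by
  matched quantiles with a Wilcoxon shift test, and by a Fisher exact
  test on the extreme-bin 2×2 table. The rank-based choice is a
  documented decision; the source reports p-values without naming
  tests.
* `estimateMapFromAFS()` turns the 70th percentile of GC-gaining
  derived-allele frequencies per window into a linear predictor of the
  reference map's window rates, smoothed to 250 kb at 10 kb steps.

The synthetic generator draws population frequencies from a stationary
density $\propto (1 - e^{-B(1-x)})/(x(1-x))$ with class-specific scaled
conversion bias $B$, truncated at $\delta = 5\times10^{-5}$, reducing to
the neutral $1/x$ as $B \to 0$ (enforced by test); observed frequencies
are binomial draws of `nChromosomes = 200` chromosomes, with the
(frequency, count) pair rejection-sampled jointly until the site
segregates. This emulates the *shape* features the statistics rely on —
class-labelled spectra with tunable bias — not linkage between sites.

## Human–chimpanzee divergence

With no usable second outgroup, substitution direction cannot be
polarized; classes are keyed (chimp state → human state). 2 kb windows
are kept when at least 1 kb is aligned, unmasked and gap-free and total
divergence is at most 5% (clustered high-divergence windows are
alignment artefacts); windows outside the supplied map's span are
dropped. Validity is assessed before the divergence filter. Per-base
rates divide by the window's usable bases, not 2000. The per-class OLS
regression controls for locus effects by including the five other class
rates, GC content and CpG content, reporting the recombination
coefficient per 10 cM/Mb. `hotspotExcess()` contrasts the hottest and
coldest 15% of windows against intermediate ones, bootstrapping windows
within strata. `stepwiseRatePredict()` does bidirectional stepwise
selection from the intercept-only model over the eight candidates with
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$.

## Synthetic-data defaults and what they emulate

The generator defaults mirror the study design: a ~2.7 Mb region; a male
map dominated by one obligatory chiasma (50 cM; positioned by map
density, transmitted with probability 1/2, rare Poisson extras at rate
0.002) and a 5 cM Poisson female map; families of 2–3 children with one
parent ungenotyped with probability 0.86 (19 of 135 study families had
both parents); per-genotype error 0.002; marker allele frequencies
uniform on (0.2, 0.8). Hotspots are 1–2 kb segments with exponential
masses at uniform positions. What is *not* emulated: linkage
disequilibrium between variants, ancestry structure within families,
marker ascertainment, and real hotspot motif placement — so passing
tests demonstrate correctness of the estimators under their stated
models, not robustness to every artefact of real data.

## Numerical choices

* Coordinates are 0-based half-open internally; map files are read as
  printed. Distances are stored in cM; the cumulative-distance file
  dialect accepts Morgans (column legend style) and converts on input.
  The cM dialect round-trips bit-stably; Morgans round-trips to within
  one ulp of the ×100 conversion.
* Outside-span queries extrapolate at zero rate: no rate is reported
  where there are no markers.
* Rate-track windows may overlap (250 kb windows at 10 kb steps);
  windows leaving the mapped span are `NA`, never 0.
* Forward–backward uses per-step normalisation; a zero normaliser
  (impossible data at $\varepsilon = 0$) short-circuits to
  $-\infty$/`NA` output.
* Bootstrap p-values use an add-one correction, so they are never
  exactly zero.
* Event-interval selection minimises physical span with leftmost
  tie-breaking; mixture and U-mixture optimisation are 1-D searches on
  [0, 1] (grid-polished for the U-mixture, whose optimum can sit on the
  boundary).

## Problem sizes used in the tests

The suite runs everything at desk scale, chosen to keep each property
detectable with comfortable margins: HMM-vs-enumeration on families of
up to 5 markers × 3 children; map recovery on 200 families × 50 markers;
mixture recovery at 500 events across the α grid; peak-test calibration
over 500 null replicates of 30 anchors; fixation bias at 20,000 sites;
U-mixture at 1,000 sites; regression recovery on 500 two-kb windows;
motif-scan equivalence on 1 Mb; and the obligatory-crossover law over
10,000 meioses.

## Known limitations

* **Posterior-sum map length under the obligatory model.** The HMM's
  no-interference prior assigns $\theta^2$ mass to double crossovers at
  isolated genotype discordances. Under a generator in which doubles
  never occur (one chiasma per bivalent) this inflates the posterior-sum
  map length by a few percent at $\varepsilon = 0.002$ with ~50 markers.
  Under a Poisson-consistent generator the estimator is calibrated, as
  the test suite verifies. Event-threshold counts are much less
  sensitive. Re-feeding the posterior map as prior does not remove this
  bias (it reinforces mass already placed at error sites).
* **Percentile-bootstrap conservatism at spike scale.** When windowed
  rates are dominated by rare 1–2 kb spikes, the anchor-resampling peak
  test is conservative (type-I ≈ 0.01–0.02 at nominal 0.05 with 30
  anchors); on maps with broad-scale rate variation it is calibrated.
  It never becomes anticonservative in our checks.
* **Stepwise-AIC selection is not consistent.** With the standard 2k
  penalty, each pure-noise candidate enters with probability ≈ 0.157,
  so with eight candidates the intercept-only model survives a null
  search only ~25% of the time. The planted-predictor property is that
  true predictors are found, not that noise is always excluded.
* Families are strictly nuclear; no half-sibs, no multi-generation
  pedigrees, and no LD-based map estimation from haplotypes (published
  LD maps are inputs).

## A worked synthetic run

```{r demo, eval = FALSE}
report <- runParDemo(list(seed = 7, nFamilies = 60))
report$maleMapCM          # recovered male map length (cM)
report$maleEventsPerMeiosis
report$mixtureAlpha       # vs report$mixtureTruth
report$fixationBias       # > 1 under planted AT->GC conversion bias
```

The README shows a complete worked example with the numbers it prints.
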