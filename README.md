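# par1map

Tools for studying recombination in the human pseudoautosomal region
PAR1 — the ~2.7 Mb region of X/Y homology whose obligatory male
crossover packs ~50 cM into under 3 Mb — and, more generally, for any
region where crossovers must be mapped from incomplete nuclear families
and their evolutionary footprint read out of sequence data.

The package is aimed at statistical geneticists who have: SNP genotypes
for families with two or more children and at least one genotyped
parent; one or more LD-based recombination maps; PRDM9 motif or
ChIP-seq binding-peak coordinates; polarized population variants; or a
human–chimpanzee alignment. Every analysis also runs on built-in seeded
generators, so the whole pipeline is exercisable with no external data.

## What it computes

**Crossover detection and sex-specific maps.** A Lander–Green hidden
Markov model over inheritance vectors, with per-genotype error
probability ε and Hardy–Weinberg marginalisation of ungenotyped
founders. For family genotypes $G$ and inheritance vectors $v_m$ at
markers $m$,

$$P(G) = \sum_{v_1..v_L} \frac{1}{|V|} \prod_m P(G_m \mid v_m)
         \prod_m \prod_j \theta_{mj}^{[v \text{ flips}]}
         (1-\theta_{mj})^{[v \text{ holds}]},$$

with Haldane transitions $\theta = (1 - e^{-2d})/2$ from sex-specific
prior map distances $d$ (Morgans). Forward–backward posteriors give the
per-interval recombination probability of every meiosis; summing over
parents of one sex and dividing by that sex's meiosis count yields the
genetic map. X-linked markers beyond the pseudoautosomal boundary are
modelled with a recombination-free dummy chromosome in fathers and
sons, which pins the paternal inheritance bits and makes
boundary-proximal crossovers detectable. Event post-processing turns
posterior mass runs into discrete crossovers with resolution intervals.

**Map comparison.** Spearman correlation of windowed rates at a chosen
physical scale; rate profiles centred on crossovers or motif/peak
anchors with bootstrap significance (resampling anchors); the
mixture-weight likelihood fit $\alpha A + (1-\alpha)B$ over 10 kb bins
(bootstrap over fathers); a model-free mean-squared-difference
bootstrap; and regional rate contrasts.

**Anchors.** Degenerate-motif scanning (default `CCnCCnTnnCCnC`, both
strands), SNP-density filtering (> 1 SNP / 2 kb in the surrounding
50 kb), 150 bp motif thinning to the most central copy, 10 kb peak
thinning to the most significant call, and annotation containment.

**GC-biased gene conversion.** Six-class variant classification with
CpG exclusion; binned derived-allele-frequency spectra; extreme-bin and
quantile–quantile comparisons; the near-fixation bias ratio
(AT→GC : GC→AT counts at derived frequency 0.95–1); a U-shaped mixture
estimate of the fraction of extremely active motifs; near-anchor
spectra at 25/500 bp; and an AFS-percentile map estimate.

**Divergence.** 2 kb human–chimp windows (≥ 1 kb clean, ≤ 5%
divergence), six substitution classes keyed chimp→human with CpG
exclusion in either species, per-class OLS on recombination rate
controlling for the other classes and base composition,
hotspot/coldspot excess estimation, and stepwise-AIC rate prediction.

## Worked example

Simulate a study-like cohort, detect crossovers, and rebuild the maps:

```r
library(par1map)

maleSim   <- simMap(2.7e6, backgroundCM = 20, nHotspots = 25,
                    hotspotMassDist = function(n) rexp(n, n / 30),
                    sexLabel = "male", seed = 11)
femaleMap <- GeneticMap(c(0, 2.7e6), c(0, 5), sexLabel = "female")
ped <- simPedigrees(120, maleSim$map, femaleMap, panelSize = 60,
                    epsilon = 0.002, parentMissingProb = 0.86, seed = 12)

priorM <- GeneticMap(c(0, 2.7e6), c(0, 50), sexLabel = "male")
priorF <- GeneticMap(c(0, 2.7e6), c(0, 5),  sexLabel = "female")
posts <- lapply(ped$families, familyPosteriors, panel = ped$panel,
                priorMapMale = priorM, priorMapFemale = priorF,
                epsilon = 0.002)
maps <- buildSexMaps(posts)
maps$male
#> GeneticMap (male, pedigree posterior): 60 markers, 22477-2639617 bp, 50.91 cM

events <- do.call(rbind, lapply(posts, callEvents))
eventsPerMeiosis(events[events$sex == "male", ],
                 maps$nMeioses[["male"]])$rate
#> [1] 0.5328720     # ~0.5 events per male meiosis, as the obligatory
                    # crossover predicts
```

The recovered 50.9 cM male map matches the generating 50 cM map; the
0.53 events/meiosis rate is the obligatory-crossover transmission law
(one chiasma per bivalent, in the transmitted gamete half the time).
Rates are sharply elevated at the generating hotspots:

```r
anchors <- (maleSim$hotspots$start + maleSim$hotspots$end) / 2
bootstrapPeakTest(maleSim$map, anchors, avgWindowBp = 5000,
                  nBoot = 2000, seed = 13)[c("statistic", "p")]
#> $statistic [1] 215.5587   # cM/Mb above the regional mean
#> $p         [1] 0.0004997
```

Mixture-weight recovery and gcBGC statistics on synthetic inputs:

```r
A  <- simMap(2.7e6, 10, 25, seed = 21)$map
B  <- simMap(2.7e6, 10, 25, seed = 22)$map
ev <- simEventsFromMap(blendMaps(A, B, 0.7), 500, seed = 23)
fitMixtureWeight(ev, A, B, binBp = 10000, nBoot = 200, seed = 24)
#> MixtureWeightFit: alpha = 0.710 (s.e. 0.029), p vs 0.5 = 0.00995

v <- simAfsVariants(20000, biasB = setNames(c(2, 2, 0, 0, 0, 0),
                    afsClasses), nChromosomes = 100, seed = 25)
fixationBias(v$variants)
#> BiasEstimate: 2.46 (140 GC-gaining vs 57 GC-losing in [0.95, 1.00)), p = 3.03e-09

al <- simAlignment(500, rates = runif(500, 0, 30), seed = 26)
classRateRegression(al$windows, "ATGCts")
#> RegressionResult (ATGCts): 0.09772% per 10 cM/Mb (s.e. 0.0091%), p = 2.38e-24
```

The mixture fit recovers the planted 0.7 weight; the fixation-bias
ratio of 2.46 reflects the planted conversion bias B = 2 on GC-gaining
classes (1.0 under neutrality); and the regression recovers a per-base
GC-transition effect close to the planted 0.11% per 10 cM/Mb (this
realisation drew 0.098%, within one standard error).

`runParDemo(list(seed = 7))` chains all stages end to end and writes
maps, events and a report table.

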