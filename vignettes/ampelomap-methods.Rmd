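---
title: "Leaf morphometrics to QTL: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf morphometrics to QTL: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampelomap)
```

ampelomap turns 21-landmark grapevine leaf coordinates into 16 phenotypes,
assembles them into genotype-by-attribute matrices across leaf position,
photoperiod and year, scans ABH-coded F1 genotypes for QTL, and tests
pathway enrichment around QTL hotspots. This vignette explains the models,
the tunable parameters and the choices made where the design was genuinely
open. Everything stated here is computed by the package's tests or the
acceptance script; nothing is an external empirical claim.

## The landmark scheme and the trait engine

Each leaf is 21 homologous points: four vein-base landmarks across the
petiole junction (1–4), branch-base and width landmarks for the proximal,
distal and middle vein systems (5–13), and eight margin landmarks — vein and
lobe tips, sinuses and the leaf tip (14–21). Coordinates are treated as
already calibrated to cm (an optional uniform scale factor is applied at
read time) with y increasing toward the tip; that orientation is checked by
QC flags, never by errors.

Vein lengths are Euclidean distances: L1 from the midpoint of landmarks 3
and 4 to the tip (21); L2 from the midpoint of 2 and 3 to the distal lobe
tip (18); L3 from 2 to the distal branch tip (17); L4 from the midpoint of 1
and 2 to the proximal lobe tip (15); L5, the petiolar sinus width, defaults
to the distance between landmarks 6 and 14 — the anatomy never pins down a
unique endpoint pair, so the pair is configurable.

Areas use the absolute shoelace sum over closed landmark cycles, making
vertex direction irrelevant. The boundary cycle uses the eight margin
landmarks in margin order: these are the only landmarked points on the
blade edge, so the "total area" is the landmarked approximation of the
blade region, not a pixel area. For the vein polygons the natural traversal
of a vein-plus-branch sliver is: base landmark on the branch side, up that
side to the *proximal* branch base, out to the branch tip, back to the
*distal* branch base, on to the vein tip, across to the width landmark on
the opposite side, and down to the far base landmark — defaults
`mid = 3,12,20,11,21,13,4`, `dist = 2,9,17,8,18,10,3`,
`prox = 1,6,14,5,15,7,2`. Visiting the distal branch base *before* the
branch tip instead forces the two base-to-branch edges to cross the sliver
in opposite directions, which self-intersects on any well-formed leaf; the
ordering above is therefore the package default, and every cycle remains
configurable through `polygon_config()`. `vein_area` is the sum of the
three vein polygons and `blade_area = total_area - vein_area`, both held
exactly by construction.

The six shape ratios are `log(vein_area / blade_area)` (natural log — a
plain "log of ratio" is base-ambiguous, and the natural log makes the trait
symmetric around 0), L4/L2, L4/L1, L2/L1, L3/L1, and L5 over total area.
Dimensional analysis gives free invariants: under uniform rescaling by k,
lengths scale by k, areas by k², five ratios are unchanged and the
sinus-to-area ratio scales by 1/k; all 16 traits are invariant under rigid
motions and reflection. The tests assert these to 1e-9.

## Trait matrix and descriptive statistics

One leaf per genotype × position × daylength × year cell gives, over 16
phenotypes, 3 positions, 2 daylengths and 2 years, 192 attribute columns;
135 own-rooted and 105 grafted genotypes give 25,920 and 20,160 cells.
Replicate leaves in a cell are averaged (a strict mode rejects them) and
missing cells stay missing — pairwise-complete handling for correlations,
flagged mean-imputation for PCA, and complete-case dropping before variance
partitioning.

The z-transform standardizes within phenotype × position × presentation,
pooling daylengths, years and genotypes: leaf positions differ in scale,
and this grouping is the coarsest one that removes that scale difference
without removing the daylength and year signals under study. PCA uses the
correlation matrix by default (traits mix cm, cm² and unitless ratios, so
covariance PCA would just rank traits by unit size).

Factor effects on component scores are decomposed by a factorial linear
model with sequential sums of squares in the fixed order year, daylength,
position, genotype, genotype:year, genotype:position. A smooth-term model
over purely categorical covariates reduces to exactly this factorial model
— there is nothing to penalize — so the decomposition is exact and cheap.
Sequential decomposition makes the reported fractions order-dependent;
fixing and documenting the order (design factors before genotype, main
effects before interactions) is the price of an exact unit-sum partition.
Under pure noise each term's expected fraction is its df/(n−1), which the
tests verify by simulation.

## Genetic map and QTL scan

Genotypes are ABH-coded (A/B the two homozygotes, H the heterozygote) in
the R/qtl CSV dialect; marker names follow `rh<chromosome>_<bp>`, and a
sidecar map CSV overrides name-parsing when names differ. Map summaries
report per-group length, gaps, mean spacing `total cM / (markers − groups)`
and an *approximate* genome-wide recombination rate, total cM over total
spanned Mbp — the spanned physical length is the only denominator available
from marker positions alone, and the summary labels it as approximate.
Pairwise recombination fractions use an EM estimator over the 3 × 3 joint
genotype table (the double heterozygote is the only latent class); both
phase orientations are fit and the better likelihood kept, so repulsion
coding cannot push estimates above one half.

Each trait-matrix attribute passes a normality gate before scanning: keep
the raw scale if Shapiro–Wilk p ≥ 0.05, else log (positive traits), else
Box–Cox with the profile-likelihood λ on the fixed grid −2 to 2 in steps of
0.1; the first rung that passes wins, and traits that defeat the ladder are
scanned by ranks. The parametric scan is single-locus marker regression
with additive (−1, 0, +1) plus dominance (H = 1) coding — with three
genotype classes this is the saturated one-way model, so
`LOD = (n/2) log10(RSS0 / RSS1)` with RSS1 the within-class residual sum of
squares; individuals missing a call are dropped per marker, and markers
with fewer than two observed classes score 0 with a flag. At the map
densities this package targets (~2 cM spacing) an interval-mapping grid
between markers buys little localization, so scanning at markers only is
the default design. The rank scan reports the Kruskal–Wallis statistic as
the LOD analog `H / (2 ln 10)`, the standard rank-scan convention, with a
null mean of `2 / (2 ln 10) ≈ 0.434` for three classes.

Genome-wide thresholds are empirical 95th percentiles (type-7 quantile) of
the maximum LOD over phenotype permutations — 1000 by default, the
analysis-scale setting; the calibration suites use 200 to keep runtimes
down. The phenotype is sorted before permuting, which leaves the
permutation distribution untouched but makes thresholds exactly invariant
to relabeling individuals. Percent variance explained uses the standard
identity `PVE = 100 (1 − 10^(−2·LOD/n))`, and stored peak PVEs always
back-compute exactly from LOD and n. Credible intervals treat normalized
`10^LOD` over one linkage group as a posterior and take the smallest
contiguous cM window that contains the peak and 95% of the mass, found by
exact search; a flat curve returns the whole group with a flag. One peak
per linkage group per trait is reported (the maximal LOD at or above the
threshold); secondary peaks on a group are out of scope.

## Hotspots and enrichment

Hotspots are groups of at least `min_qtl` QTL sharing an identical peak
marker whose credible intervals pairwise overlap; for 1-D intervals
pairwise overlap is equivalent to a common stab point, so the largest
overlapping subset is found exactly by a sweep. The default `min_qtl = 3`
takes the inclusive side of the two published phrasings of the rule ("more
than 3" vs "three or greater"); it is configurable. Gene windows take genes
whose annotated position (point representation, 1-based start) lies within
700 kb of the peak — a closed 1.4 Mb interval; span-overlap inclusion is a
documented configuration away. Enrichment per pathway is the one-sided
Fisher exact p, i.e. the hypergeometric upper tail of the 2 × 2 table; the
significance flag follows the raw p < 0.05 rule, with BH-adjusted values
always reported alongside, and the universe defaults to all genes in the
supplied table. Discreteness makes the test conservative at small counts —
the null calibration test sizes its universe so tails are near-continuous
and documents the conservatism.

## The synthetic-data generators

The generators exist so every stage is testable without external data; they
emulate the *statistical* structure the analysis assumes, not leaf biology.

Genotypes: two independent gametes per individual per linkage group, each a
Markov chain over markers with Haldane recombination probability
`(1 − e^(−2d/100))/2` for spacing d cM, summed to A/H/B with expected 1:2:1
frequencies. This intercross coding matches the ABH analysis coding rather
than modeling outbred F1 four-allele meiosis — the analysis layer, not
meiosis fidelity, is under test. The default map is 19 groups × 50 markers
× 92 cM (~1750 cM at ~1.9 cM spacing, the scale the analysis targets), with
`bp = cM × 1e5` marker names keeping physical parsing exercisable.

Phenotypes: `y = μ + a·s + d·h + ε` with the residual SD solved from
`σ² = V_g (1 − p)/p`, `V_g = a²/2 + d²/4`, so the marker explains the
target fraction p in expectation; large-n tests verify realized R² within
±0.02.

Leaves: three idealized position templates (apical smaller with relatively
wider veins, basal larger — the familiar heteroblastic allometry; template
coordinates are synthetic fixtures, not measurements). Each leaf is its
template scaled by `exp(genotype effect + daylength effect + year effect +
noise)` with independent landmark jitter; planted shape QTL stretch x
anisotropically so ratios, not just sizes, respond. Defaults: 135
genotypes, daylength effect −0.08 (13 h leaves ~8% smaller), year effect
+0.05, individual log-scale SD 0.08, jitter SD 0.02 cm — chosen once as
plausible magnitudes for a vineyard common-garden design. Size-QTL effects
are solved from the target PVE against the log-scale SD alone; landmark
jitter adds a small extra variance, so realized trait-level PVE runs a
shade under nominal for small leaves. What passing tests show is that the
*pipeline* recovers what it assumes; none of this certifies behavior on
real scans with segmentation errors, missing leaves or shared environments.

## Numerical choices and degenerate inputs

Self-intersecting cycles warn and still return the absolute shoelace value
(QC, not the trait engine, is the gate); blade area ≤ 0 is an error, as are
degenerate all-coincident landmarks and zero denominators in ratios, each
named for the offending trait. Perfect-fit markers have RSS1 floored at
`1e-12 × RSS0` so LODs stay finite. Ties in the rank scan use the standard
correction `1 − Σ(t³−t)/(N³−N)`; completely tied Kruskal–Wallis input
reports H = 0, p = 1. Credible-interval ties break toward fewer markers.
All stochastic stages require explicit seeds, derive per-attribute child
seeds deterministically, and write provenance headers without timestamps,
so a fixed seed reproduces every output byte-for-byte.

## Known limitations

Power and localization at modest effect sizes bound what the scan can
promise: with a 15%-PVE locus in 135 individuals on this map, the genome
scan detects a significant peak in about 80% of replicates but places the
peak marker within 10 cM of the truth in only about 65–70% — consistent
with classical QTL interval-width results; at n = 200 the within-10 cM rate
reaches ~90% (rates measured by this package's own simulations). The scan
is single-locus only: no multiple-QTL models, covariates or epistasis. The
EM recombination estimator assumes intercross coding; outbred four-way
phase inference is out of scope, as are de novo linkage grouping and map
curation. The credible interval is slightly conservative at marker
resolution (measured coverage ~0.98 at nominal 0.95). Problem sizes in the
test and acceptance suites (reduced genomes, 200-permutation thresholds,
20-replicate recovery) are the package's own choices for routine runs;
analysis-scale defaults remain 1000 permutations and the full map.
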