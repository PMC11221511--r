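---
title: "Scoring nucleosome accessibility and stability from MNase titrations"
author: "nucMACCr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nucleosome accessibility and stability from MNase titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The measurement

Micrococcal nuclease (MNase) preferentially cleaves linker DNA between
nucleosomes. Digesting the same chromatin with a *titration* of MNase
concentrations and paired-end sequencing the protected fragments turns a
single static nucleosome map into a kinetic readout: nucleosomes in open
chromatin are released already under mild digestion, while nucleosomes that
are intrinsically fragile are destroyed under harsh digestion. `nucMACCr`
quantifies both effects per nucleosome position:

* the **nucMACC score** (nucleosome accessibility) is the negated slope of an
  ordinary least-squares regression of
  $\log_2(\text{normalized mono-nucleosomal count} + p)$ on
  $\log_2(\text{MNase concentration } c)$. A positive score means the
  position loses mono-nucleosomal fragments as digestion increases -- it was
  preferentially released at mild MNase, i.e. it is accessible.
* the **sub-nucMACC score** (nucleosome stability) is the analogous slope --
  not negated -- computed on sub-nucleosomal fragments (< 140 bp), which
  arise from cleavage inside the nucleosome core. Strongly negative scores
  mark unstable ("fragile") particles whose sub-nucleosomal signal is present
  under mild digestion and vanishes under harsh digestion.

Fragments are size-classified before anything else: mono-nucleosomal
fragments are those with template length in the half-open window
$[140, 200)$ bp, sub-nucleosomal fragments are shorter than 140 bp, and
longer fragments (di-nucleosomes and up) are discarded. The window is
half-open so the partition is exact; the upper boundary of the mono class is
stated both inclusively and exclusively in the field, and we use the
exclusive form.

## Position calling

Nucleosome positions are called internally rather than through an external
caller, because nothing in the scoring depends on a particular caller's
internals -- only on the conventions used to build the pileup:

1. each fragment is reduced to its midpoint and extended to 70 bp;
2. the pileup is normalized so that mean coverage over the *effective*
   (mappable) genome equals 1;
3. the track is smoothed with a 21-bp moving average, local maxima at least
   0.5 (half the genome-average coverage) high become candidate summits,
   and summits are accepted greedily by decreasing height subject to a
   minimum center distance of 120 bp, with ties broken toward the smaller
   coordinate so the output is deterministic;
4. each accepted summit is extended to a fixed 147-bp interval (the
   core-particle footprint), clipped at chromosome ends.

Mono-nucleosome positions are called from the pooled mono fragments of *all*
samples (pooling maximizes coverage; replicate concordance should be checked
first, see `replicateCorrelation()`). Sub-nucleosome positions are called
from the sub fragments of the *lowest*-concentration sample(s) only: under
mild digestion a sub-nucleosomal footprint cannot be a digestion
intermediate, so this is where fragile particles are visible. An externally
produced position BED can be substituted by constructing a `PositionSet`
directly, for users who want parity with a specific caller.

`minHeight = 0.5` is a default we chose (no published threshold exists for
this step); it is deliberately permissive because the count filter below is
the actual robustness gate. With `minCenterDist` (120) smaller than the
position width (147), adjacent called intervals may overlap by up to 27 bp;
fragment-to-position assignment is therefore by *midpoint*, with ties going
to the leftmost position, so every fragment counts at most once.

## Counting, normalization, and the regression

Counts are midpoint-in-interval tallies per position and sample. Positions
with a total raw count below 30 (mono) or 5 (sub) across samples are
removed. The thresholds are applied to the *total* rather than per sample:
a position absent only under extreme digestion is signal, not noise.

Counts are normalized to CPM using, as library size, the total number of
size-selected fragments of that sample's fraction. With spike-in chromatin
the per-sample factor is the spike-derived fragment count divided by one
million. Since the score is a slope across samples, any per-sample factor
common to all positions cancels; this is why spike-ins are not required for
the scores (and why, when spike counts are proportional to library sizes,
spike and CPM scores agree exactly -- a property the test suite asserts to
$10^{-9}$).

The pseudocount $p$ is the median over samples of the per-sample median
normalized count. It stabilizes the log transform at weak positions, at the
cost of attenuating slopes: a position whose normalized count is comparable
to $p$ has roughly half its release exponent recovered. The simulation
studies below make this attenuation visible and quantifiable; it compresses
scores toward zero monotonically and therefore moves rankings very little.
Replicates at the same concentration enter the regression as separate
points by default, preserving degrees of freedom; pooling replicates before
normalization is possible by summing counts upstream but is not the
default, since pooling is only required for position calling.

The package warns when the titration spans less than a 10-fold
concentration range, the minimum gap at which two-condition designs remain
reliable.

## GC correction

MNase has a sequence preference, and the apparent release kinetics of a
position can correlate with its GC content. The correction follows the
scores, not the counts: positions with rare extreme GC (outside the
[1st, 99th] percentile window of the GC distribution) are removed, a LOESS
fit $L(g)$ of raw score on GC fraction $g$ is computed with span
$\alpha = 0.1$ (degree-2 local polynomial, tricube weights, no robustness
iterations, evaluated at the observed $g$), and each score is shifted by the
deviation of the fit from the median raw score:

$$\text{corrected}_i = \text{raw}_i - (L(g_i) - \operatorname{median}(\text{raw})).$$

When scores are independent of GC, $L$ is flat at the median and the
correction is numerically the identity. Below 200 positions the fit is
unstable and the correction is skipped with a warning rather than applied.

## Selecting the extreme classes

Extreme positions are selected by the rank-slope rule also used to call
super-enhancers from ranked enhancer signal. Scores are sorted ascending and
drawn on a unit square (rank normalized by $n$, score normalized by its
range); a LOESS fit (span 0.1) of the curve is differentiated by central
finite differences on the fitted values. Positions before the slope first
drops below 1 form the low tail (hypo-accessible for nucMACC, unstable for
sub-nucMACC); positions from the last upward crossing of slope 1 onward form
the high tail (hyper-accessible, noncanonical). Choices the geometric rule
itself does not fix:

* the derivative estimator (central differences on the fitted grid);
* scanning directions -- first crossing from the left for the low tail, last
  upward crossing for the high tail;
* if the curve starts flatter than the diagonal, the low tail is empty;
* slope comparisons use a $10^{-8}$ tolerance so an exactly diagonal curve
  (all scores equally spaced) yields empty tails instead of rounding noise;
* a zero score range is an error, not an empty result.

Because both axes are normalized, the labels are invariant under positive
affine transforms of the scores.

Before stability classification, sub-nucleosome positions are filtered for
informativeness: a sub position is kept if it overlaps no mono position, or
if its normalized count in the lowest-MNase condition is at least fourfold
("at least" is inclusive: exactly 4.0 passes) that of the overlapping mono
position. When several mono positions overlap, the largest-overlap partner
is used, ties toward the leftmost. The ratio always compares
fraction-specific CPM -- each fraction normalized by its own library --
independent of the score normalization mode; a per-sample spike factor is
common to both fractions and would collapse the rule to a raw-count ratio.

Promoters are classified by whether an unstable-particle summit lies in a
strand-oriented window around the TSS: the default window is 200 bp upstream
to 0 downstream (suitable for compact genomes); a 150-upstream /
50-downstream preset matches common mammalian usage.

## Depth bookkeeping: FPN

Sequencing depth is reported genome-independently as fragments per
nucleosome, $\mathrm{FPN} = n \,/\, (G / L)$ with $G$ the effective genome
size and $L = 170$ bp the approximate nucleosome repeat length.
`fpnReport()` computes FPN(total) over all fragments, FPN(mono) over
size-selected mono fragments of all samples, and FPN(sub) over sub fragments
of the lowest concentration only, and warns below 240 FPN(total) -- the
depth under which stability analysis returns too few sub-nucleosome
positions to be meaningful.

## What the simulator emulates -- and what it does not

`simulateExperiment()` generates titration experiments in which the planted
parameters are exactly the estimands of the scoring regression:

* mono-nucleosomal counts at nucleosome $i$ under concentration $c$ are
  Poisson with mean $\text{depth} \cdot c^{-a_i}$, so nucMACC estimates the
  planted accessibility $a_i$;
* sub-nucleosomal counts are Poisson with mean
  $\text{depth} \cdot w_i \cdot c^{+s_i}$, so sub-nucMACC estimates the
  planted stability $s_i$; the emission weight $w_i$ is high
  (`subFractionWeight = 2`) for a planted fragile subpopulation
  (`fragileFraction = 0.2`) and low (`baselineSubWeight = 0.05`) elsewhere,
  which is what makes fragile positions survive the unique-or-fourfold
  filter while canonical positions are (correctly) discarded as
  uninformative;
* fragment lengths are Gaussian (mono $N(160, 12)$ clipped to $[140, 200)$,
  sub $N(110, 15)$ clipped below 140), midpoints jitter around the dyad with
  $\sigma = 10$ bp, dyad spacing is uniform on 170--200 bp, and the genome
  sequence is drawn with per-nucleosome target GC ($N(0.45, 0.08)$,
  truncated);
* with `gcBiasBeta` $\neq 0$, counts acquire a concentration-coupled GC bias
  $2^{\beta\,(g_i - \bar g)\,\log_2 c}$, i.e. the apparent release exponent
  is shifted by $-\beta (g_i - \bar g)$. A GC bias that multiplies counts
  equally at every concentration would cancel exactly in the slope, so only
  the concentration-coupled form produces the score--GC correlation the
  LOESS step is designed to remove.

Default conditions mirror a standard titration design: concentrations
1.5 / 6.25 / 25 / 100 U in duplicate, depth 100 expected mono fragments per
nucleosome per sample at 1 U. The planted accessibility and stability
distributions default to $N(0, 0.2)$: most nucleosomes have similar
accessibility, with genuine extremes being small minorities, and the narrow
dispersion keeps the regression in the regime where the pseudocount's
attenuation is modest.

The simulator does **not** emulate: sequencing errors, PCR duplicates,
mappability gaps, di-nucleosome carry-over, positioned nucleosome arrays
with phasing decay, copy-number variation, or digestion-time (as opposed to
concentration) titrations. Recovery results on simulated data therefore
demonstrate the correctness of the estimator and the classification
geometry, not robustness to every artifact of real libraries. Spike-in
material is represented only by per-sample spike fragment counts on the
sample sheet, which is all the normalization consumes.

Simulated experiments at a fixed seed are byte-identical across runs, and
the pipeline itself is deterministic, so score tables reproduce exactly.

## Worked example

```{r example, eval = FALSE}
library(nucMACCr)
cfg <- SimConfig(nNucleosomes = 1000, seed = 7)
sim <- simulateExperiment(cfg)
res <- runNucMACC(sim$sheetPath, sim$genome)
res$mono

m <- matchPositionsToTruth(res$mono, sim$truth)
ok <- !is.na(m)
cor(sim$truth$accessibility[m[ok]], scores(res$mono)[ok])
```

The test suite runs this design (1000 nucleosomes, 8 samples, roughly 1.2
million fragments) for recovery and determinism checks, a 5000-nucleosome
variant for GC-bias removal, and small analytic fixtures for every operation
boundary; the full suite completes in about a minute on one CPU.

## Known limitations

* The internal position caller is deliberately simple (greedy local maxima);
  exact coordinates will differ from dedicated callers, although the scoring
  downstream depends only on pileup conventions.
* The pseudocount attenuates score magnitudes at positions whose counts are
  comparable to the median; scores are best interpreted as a ranking with
  approximately linear low-magnitude behavior.
* Two-titration designs need roughly a 10-fold concentration gap; the
  package warns, but cannot rescue, narrower designs.
* Absolute occupancy comparisons between biological conditions are out of
  scope; they require spike-ins used quantitatively, not just as a
  normalization mode.
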