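---
title: "Modelling transfer-competence dynamics of ICEclc-type elements"
author: "icepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transfer-competence dynamics of ICEclc-type elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icepop)
```

## Background

ICE*clc*-type integrative and conjugative elements transfer horizontally
from a specialised *transfer-competent* (tc) subpopulation that arises
bistably: in wild-type cultures only a few percent of cells activate the
transfer program on entry into stationary phase, whereas derepression of the
element's regulatory operon pushes the switching probability towards one.
Becoming transfer competent carries a fitness cost: tc cells divide more
slowly and die or arrest after reinoculation into fresh medium. `icepop`
provides the quantitative toolkit around this biology: a population model of
tc dynamics in batch and serial-transfer culture, the measurement statistics
of transfer and survival assays, single-cell reporter fraction calling, a
windowed genomic screen for related elements, and seeded generators for
every data type the analyses consume.

## The two-subpopulation Monod model

A batch culture holds one limiting substrate $S$ (mg/ml) and two biomass
compartments (mg dry weight/ml): ordinary cells $B_{ntc}$ and transfer
competent cells $B_{tc}$. Both grow with Monod kinetics,
$\mu_i(S) = \frac{\ln 2}{g_i}\,\frac{S}{K_s + S}$, with generation times
$g_{ntc} = 1$ h and $g_{tc} = 2$ h at saturation, and tc cells die at a
first-order rate $\delta_{tc} = 0.4$ h$^{-1}$:

$$
\frac{dB_{ntc}}{dt} = \mu_{ntc}(S) B_{ntc}, \qquad
\frac{dB_{tc}}{dt} = \mu_{tc}(S) B_{tc} - \delta_{tc} B_{tc}, \qquad
\frac{dS}{dt} = -\frac{1}{Y}\left(\mu_{ntc} B_{ntc} + \mu_{tc} B_{tc}\right).
$$

Default parameters are the published set: fresh-medium substrate
$C_{total} = 4.25$ mg/ml, $K_s = 0.02$ mg/ml, yield $Y = 0.3$ g/g,
single-cell dry weight $2\times10^{-12}$ g, switching probability
$P_{tc} = 0.025$ (wild type) or $0.5$ (derepressed mutant), and a 1:1000
serial transfer. $C_{total}$ is treated directly as consumable substrate
mass and $Y$ applied to it without a carbon-to-substrate conversion, since
the parameter set pairs the two numbers with no conversion factor.

Stationary entry is declared when $S$ falls below
`stationary_s_frac * c_total` (default $10^{-3}$, i.e. 99.9% of the
substrate consumed); at that instant — once per batch — a fraction $P_{tc}$
of the non-tc biomass moves to the tc compartment. The threshold choice is a
design decision: only "appearance in stationary phase" is specified
biologically, and any threshold well below $K_s$ gives an indistinguishable
switch time on the scale of the batch.

Further modelling choices that the biology leaves open, decided once here:

* **Death window.** $\delta_{tc}$ acts on tc cells whenever they exist
  (default). Before substrate exhaustion this is almost equivalent to
  death-only-after-transfer, because tc cells appear just as growth stops;
  after reinoculation death competes with division and the tc subpopulation
  collapses, reproducing its reported rapid demise. The alternative reading
  (death only in post-transfer batches) is exposed as
  `death_window = "post_transfer"`.
* **tc substrate use.** tc cells consume substrate while dividing: they
  appear in the mass balance like any other biomass.
* **Heritability.** Daughters of tc cells are tc; the growth-arrest
  phenotype is lineage-bound.
* **Division cap.** The observation that tc cells divide only a few times
  after reinoculation is *emergent*, not imposed: with division at
  $\ln 2 / 2 \approx 0.35$ h$^{-1}$ competing against death at 0.4 h$^{-1}$,
  each tc cell completes a geometric number of divisions with mean below
  one, and lineages die out. The agent-based twin reports the realised
  per-cell division counts so this can be audited.
* **Inoculum.** The published figure does not state the starting density;
  the default is $10^6$ cells/ml, a typical 1:1000 dilution of a stationary
  culture, and it is configurable everywhere.

### Numerical treatment

`simulateBatch()` integrates with `deSolve`'s stiff-capable `lsodar`
(relative tolerance $10^{-8}$, absolute $10^{-12}$, output grid 0.05 h).
Stationary entry is located by a root function on the substrate threshold,
so the switch is applied at the exact crossing instant rather than at a grid
point. Substrate below $10^{-10}$ mg/ml — ten orders below working
concentrations — is treated as exhausted, which keeps the integrator from
grinding on the asymptotic decay to zero. With death disabled the integrator
conserves mass to $\sim10^{-6}$ relative: $Y\,(S_0 - S(t)) = B(t) - B_0$ at
every output point, and the suite asserts this.

The ODE applies switching deterministically (a fraction $P_{tc}$ moves);
the agent-based twin (`agentSimulate()`) draws a per-cell
Bernoulli($P_{tc}$) at stationary entry, exponential division waiting times
at the Monod rate, and exponential tc death. Substrate changes only at
division events, so propensities are piecewise constant and the Gillespie
simulation is exact. Because the published parameters imply a carrying
capacity of $\sim6\times10^{8}$ cells/ml, agent runs use small culture
volumes: the equivalence checks in the suite use $10^4$ starting cells in
$3\times10^{-5}$ ml (capacity a few $10^4$ cells, $\sim2\times10^4$ events
per replicate), a size chosen so 50 seeded replicates complete in seconds
while demographic noise stays small enough for a 3-standard-error
comparison against the ODE mean at every grid point. Agent runs require an
explicit seed and restore the caller's RNG state.

### Fitted quantities

`fitGenerationTime()` implements the study's reporting convention:
generation time $= \ln 2 / \mu$ with $\mu$ the OLS slope of natural-log
turbidity versus time over at least five exponential-phase points, flagging
fits with $R^2 \le 0.96$. On model output the exponential window is taken
as the grid points with $S > 10 K_s$; there the Monod factor exceeds 0.9
and the recovered doubling time of a wild-type batch is within ~1% of the
1 h generation time used to generate it (the residual bias comes from the
tail of the window where substrate begins to drop).

`lagTime()` defines lag as (time to reach a biomass threshold) minus (the
time a pure exponential at a reference rate would need from the same
inoculum), with log-linear interpolation between grid points. In
post-transfer batches the population inherits a dying tc fraction: a
culture seeded with 50% tc shows a visibly longer lag than one seeded with
2.5% tc, while the *late* exponential rate — fitted after total biomass
passes the geometric midpoint of the exponential window
(`lateExponentialWindow()`), by which point the tc contribution has decayed
to well under 1% — is identical within 2% between the two scenarios. This
is exactly the paradox the model explains: a large tc burden prolongs
apparent lag without changing the exponential growth rate of the
population that survives.

## Transfer and survival statistics

The assay statistics mirror the study's definitions: transfer frequency is
transconjugant CFU per donor CFU (`transferFrequency()`), survival is the
percentage ratio of CFU on selective versus non-selective plates
(`survivalRate()`), and group contrasts use the two-tailed pooled-variance
Student's t test (`tTestEqualVar()`, checked against the closed form to
$10^{-10}$). Multi-group comparisons (`anovaTukey()`) run a one-way ANOVA
followed by all pairwise Tukey-Kramer comparisons on the studentized range
distribution, with the harmonic correction for unequal group sizes, and
render the result as a compact letter display: groups share a letter if
and only if their pairwise comparison is not significant. Letters are
assigned by an insert-and-absorb construction over the non-significance
graph (open a set for every uncovered non-significant pair, absorb it to a
maximal clique, cover isolated groups with singletons, drop subset sets),
which satisfies the iff property by construction; the suite verifies the
partition against a brute-force `TukeyHSD` oracle and checks type-I
calibration under the null (the fraction of all-null triplicate datasets
receiving more than one letter matches $\alpha$ within the binomial band).

Because frequencies span four or more orders of magnitude, ANOVA is run on
$\log_{10}$ frequencies by default design (a raw-scale flag exists). Zero
transconjugant counts are recorded as frequency 0; under the log transform
they must be replaced by an explicit, logged pseudo-frequency floor (half a
detection limit is the sensible choice), never silently dropped.

## Single-cell reporter fractions

`callPositiveFraction()` turns a per-cell intensity table into an
on-fraction with a 95% Wilson score interval. Intensities are normalised to
a reference exposure (20 ms) by per-ms scaling before thresholding. Three
threshold strategies exist because no single rule covers the 0.001-1
on-fraction range:

* *background* (default): kernel-density mode of the off component on the
  log scale plus $k = 3$ estimated off-spreads — robust when positives are
  a minority, meaningless when they dominate;
* *mixture*: two-component Gaussian EM on log intensity (\pkg{mclust}),
  thresholded at the equal-posterior boundary — works at any on-fraction
  provided the components separate;
* *fixed*: a user threshold, for instrument-calibrated cutoffs.

`detectionLimit()` encodes the microscopy floor of roughly one fluorescent
cell among $10^3$-$10^4$: the smallest observable fraction is $1/n$, and
the one-sided 95% upper bound compatible with zero observed positives is
the rule-of-three $3/n$. `dualQuadrantFractions()` gives the four quadrant
fractions of a dual-reporter experiment (summing to 1 exactly), matching
cells across channels by id.

## The windowed genomic screen

`iceScan()` reimplements the comparative screen for related elements. It
consumes *precomputed* homology/annotation feature tables (BLAST tabular
and GFF3 readers are provided; the screen itself never runs BLAST): anchor
hits to the key regulator, core-region homology blocks, integrase genes and
tRNA-Gly genes, in 1-based inclusive coordinates. Anchors survive at
E-value strictly below $10^{-15}$; a candidate element is called when core
blocks with more than 75% nucleotide identity lie within 1-100 kb of the
anchor and an integrase lies within 5-20 kb. Distances are nearest-edge,
window bounds inclusive — the source material never defines measurement
points, so the least surprising convention was fixed and documented. Two
further decisions: "complete" core homology is operationalised as a
configurable minimum of 10 kb summed qualifying block length (fragmented
alignments allowed); and where the reported window for the integrase
differs between descriptions (1-100 kb versus 5-20 kb), the figure-level
5-20 kb values are the defaults, both configurable. A tRNA-Gly within 5 kb
of a qualifying integrase is scored but never gates a call, and strand
never gates anything. Overlapping calls from nearby anchors merge
(`mergeOverlappingCalls()`); output is row-order invariant and exports to
TSV and 0-based half-open BED.

## Synthetic data: what it does and does not show

Every generator is seeded, bit-reproducible, and returns its ground truth
so recovery tests compare against the truth rather than magic numbers:

* `genGrowthCurve()` — model trajectories with multiplicative lognormal
  turbidity noise (default sd 0.02 on the log scale, typical of plate-
  reader OD scatter);
* `genCfuDataset()` / `genTransferAssay()` — lognormal replicate scatter
  around geometric means (plating error is multiplicative; counts stay
  positive), default three biological replicates, default sd 0.2
  $\log_{10}$ units;
* `genCellIntensities()` — two-component lognormal off/on mixture (off:
  meanlog $\log 100$, sdlog 0.3; on: meanlog $\log 5000$, sdlog 0.4 —
  roughly a 50-fold separation, as seen between off and on reporter
  populations);
* `genFeatureTable()` — planted screen constellations plus decoys that
  each violate exactly one criterion (E-value $10^{-12}$, identity 70%,
  integrase at 30 kb, core at 150 kb), one constellation per contig.

These generators emulate the *statistical structure* the analyses assume —
Monod-shaped curves with noise, multiplicative replicate scatter, bimodal
intensity mixtures, coordinate-level feature constellations. They do not
emulate plate-reader saturation, autofluorescence tails, segmentation
artefacts, fragmented real genome assemblies or compositional biases, so
passing recovery tests demonstrates correctness of the computations, not
robustness to every failure mode of real data. Sequence-level simulation
is deliberately out of scope.

## Limitations

* The model contains no mechanism for element loss or curing; stationary
  survival percentages are measured quantities, not model outputs.
* No intracellular model of the regulatory cascade is attempted; $P_{tc}$
  is a phenomenological switch probability.
* The discrepancy between ~80-100% of cells activating reporters in the
  derepressed mutant and the modelling value $P_{tc} = 0.5$ is inherited
  from the source material; the package reports fractions and leaves the
  interpretation to the user.
* Microarray-based expression analysis, RT-PCR design, image segmentation
  and running alignment tools are all out of scope.
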