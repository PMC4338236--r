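---
title: "Detecting and classifying selective sweeps with haplotype homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying selective sweeps with haplotype homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classic genome scans for positive selection look for the signature of a
*hard* selective sweep: a single adaptive haplotype rises to high
frequency and erases local variation. In large populations, however,
adaptation often proceeds through *soft* sweeps, in which several
haplotypes carrying independently arisen adaptive mutations (or a standing
variant present on several backgrounds) rise together. Soft sweeps
perturb diversity and the site frequency spectrum far less than hard
sweeps, so methods keyed to hard-sweep signatures miss them.

`haplosweep` implements a scan built on *haplotype homozygosity* in
windows of a fixed number of SNPs, which retains power for both sweep
types, together with a second statistic that separates them, a simulator
used both to calibrate significance and to study power, and an
approximate Bayesian computation (ABC) layer that quantifies sweep
softness.

## Statistics

If $p_i$ is the frequency of the $i$-th most common haplotype among $n$
sampled haplotypes in a window, the package computes

* $H1 = \sum_i p_i^2$ — plain haplotype homozygosity, maximal for hard
  sweeps;
* $H12 = (p_1 + p_2)^2 + \sum_{i>2} p_i^2 = H1 + 2 p_1 p_2$ — pools the
  two most frequent haplotypes, gaining power for soft sweeps in which
  two (or more) haplotypes share the sweep;
* $H123$ — the analogous statistic pooling the top three haplotypes;
* $H2 = H1 - p_1^2$ and the ratio $H2/H1$, which rises monotonically with
  the softness of a sweep and is informative precisely where $H12$ is
  high (near sweep centres). A hard sweep can produce high $H12$ but not
  simultaneously a high $H2/H1$.

Windows hold a fixed number of SNPs (default 400, stepping by 50) rather
than a fixed physical length, which removes the variance in haplotype
spectra caused by fluctuating SNP density; 400 SNPs corresponds to
roughly 10 kb at the SNP density of the reference data set the defaults
emulate.

Within a window, haplotypes are grouped by exact sequence identity.
Missing data ("N") are handled as in the reference analysis: a haplotype
with missing calls joins an existing cluster when it is consistent with
the cluster representative at every genotyped site; when several clusters
are consistent one is chosen uniformly at random; otherwise the haplotype
founds a new cluster. Because this rule is order- and randomness-
dependent, the clustering consumes R's global RNG and is reproducible
under `set.seed()`. The representative of a cluster is the first
haplotype assigned to it; this is one consistent reading of the published
procedure, which does not specify whether later comparisons are made
against complete or partially missing sequences.

## Scan, calibration and peaks

`scan_chromosome()` slides the window across a chromosome and records the
statistics per window. Windows whose centre falls in a region of local
recombination rate below $5 \times 10^{-7}$ cM/bp — or outside the
supplied map — are *masked*: they keep their statistics but are excluded
from peak calling, because low-recombination regions generate long
haplotypes under neutrality.

Significance uses a *1-per-genome false discovery rate*: simulate ten
times as many neutral replicates as there are analysis windows in the
scanned genome, and set the critical value $H12_o$ to the 10th-highest
simulated $H12$; about one neutral window per genome is then expected to
exceed it. Neutral replicates use the central 400 SNPs of each simulated
locus, discarding replicates with fewer than 400 segregating sites, which
mirrors the sweep-analysis convention of centring windows on the adaptive
site.

`call_peaks()` groups consecutive unmasked windows above $H12_o$ into
peaks, represents each peak by its highest-$H12$ window, and reports
peaks in decreasing order of that representative value. A masked window
terminates a run even if its own $H12$ is high.

## The simulator

Neutral samples are drawn from a sequentially Markovian coalescent
(SMC') with recombination and piecewise-constant population size,
implemented in C++. The SMC' approximation replaces the full ancestral
recombination graph by a Markov process along the sequence in which the
marginal genealogy is locally updated at each recombination breakpoint
(allowing "invisible" re-coalescences onto the same branch); it is the
approximation used by the standard fast coalescent simulators and is
essentially exact for linkage and haplotype statistics at these
parameter values. During development the implementation was checked
against analytic expectations (Watterson's segregating-site count,
Tajima's pairwise diversity) and against an independent coalescent
simulator, which matched the full distribution of window $H12$ to within
Monte Carlo error.

Sweep samples are generated forward in time under a rescaled
Wright–Fisher model. With rescaling factor $Q$, a population of
$N' = N_e/Q$ diploids evolves with $\mu' = Q\mu$, $r' = Qr$ and
$s' = Qs$, which preserves the population-scaled parameters
$\theta = 4 N_e \mu L$, $\rho = 4 N_e r L$, $\theta_A = 4 N_e \mu_A$ and
$2 N_e s$, while times contract as $t' = t/Q$. Selection is co-dominant
(fitnesses $1 : 1+s' : 1+2s'$, so the homozygote has twice the
heterozygote advantage). The adaptive site sits at the locus centre.
Two sweep modes are provided:

* **de novo** — recurrent adaptive mutation at rate
  $\mu_A' = \theta_A / 4N'$ per gamete; each new mutation receives a
  distinct origin label, and the labels carried by sampled haplotypes
  measure how many independent origins contributed to the sweep;
* **standing variation (sgv)** — a single neutral copy is introduced and
  required, by rejection, to drift to frequency $f_0$ before selection
  begins; the copies present at onset are then relabelled as distinct
  standing origins, preserving the identity-by-descent structure that
  governs softness from standing variation.

Selection switches off when the combined adaptive frequency first
reaches the partial frequency $PF$; the population then ages neutrally
for $T_E \cdot 4N'$ generations ($T_E$ in units of $4 N_e$ generations)
before $n$ haplotypes are sampled without replacement. Samples with
fewer than 400 segregating sites are discarded and redrawn.

Three numerical choices deserve mention:

* **Stationary initialisation.** Instead of a long neutral burn-in, the
  forward phase starts from a coalescent draw of all $2N'$ population
  haplotypes, which is a draw from the stationary distribution; this
  removes the dominant cost of forward simulation without changing the
  sampling distribution.
* **Waiting-time elision (de novo).** While no adaptive copy segregates,
  the population is neutral and stationary, so the generations spent
  waiting for the next adaptive mutation are statistically exchangeable
  and are skipped: the arrival is forced into the next generation. After
  a failed sweep attempt the background is, strictly, only approximately
  stationary, but failed attempts at the default parameters die within a
  few generations at minute frequencies, so the approximation is
  negligible.
* **Rescaling limits.** With $N' = 500$ and $N_e = 10^6$, $Q = 2000$ and
  $s' = 2000 s$, so for strong selection the scaled fitness differences
  are large and the sweep completes in a handful of scaled generations.
  Recombination and mutation *per sweep* are preserved by the rescaling
  (their per-generation rates scale up exactly as the duration scales
  down), which is what the haplotype statistics respond to; the
  granularity of drift during the sweep is not, which is the usual cost
  of aggressive rescaling. The rescaling-invariance test (Q = 500
  versus Q = 1000) checks that the distribution of window statistics is
  insensitive to this choice at test scale.

The admixture demography is a *template*: the present population is
founded by drawing haplotypes from two coalescent source populations in
a given proportion and then evolved forward to the present; for sweep
modes the selection onset is uniform on [0, founding time] with
selection running to sampling, and standing copies are seeded at
frequency $f_0$ at onset (here without drift conditioning, since the
founding bottleneck resets the background). Because forward time is
rescaled by $Q$, very recent founding times round to few scaled
generations; users who need fine temporal resolution should raise $N'$.
The published admixture parameter values are not reproduced in the
available text, so all template parameters are user-supplied.

## ABC inference of sweep softness

The softness parameter $\theta_A$ is inferred from an observed pair
$(H12, H2/H1)$ by rejection ABC. Priors follow the reference analysis:
$\theta_A \sim U[0, 100]$, $s \sim U[0, 1]$, $PF \sim U[0, 1]$,
$T_E \sim U[0, 0.001]$ (in $4N_e$ units; the alternative prior
$U[0, 10^4]$ that appears once in the source material is taken to be a
typo and is configurable), and the recombination rate is drawn uniformly
within one of five rate bins. A draw is accepted when the
variance-normalised distance

$$d_i = \sqrt{ \frac{(H12_{obs} - H12_i)^2}{\mathrm{Var}(H12)}
             + \frac{(H2/H1_{obs} - H2/H1_i)^2}{\mathrm{Var}(H2/H1)} }$$

is below the acceptance radius, with variances estimated from all
simulations of the run (hard and soft sets pooled, for Bayes factors).
The published analysis phrases acceptance both as "within 10% of the
observed values" and as the distance rule with radius 0.1; the package
uses the distance rule (the phrasing written as a formula) and offers the
per-component relative-10% rule behind `rule = "relative"`. The
$\theta_A^{MAP}$ estimate is the mode of a Gaussian kernel density
(Silverman bandwidth, 512-point grid on the prior support) over accepted
draws; the credible interval is the empirical 2.5/97.5 percentile pair.

Bayes factors compare point hypotheses: hard sweeps are simulated with
$\theta_A = 0.01$, soft sweeps with $\theta_A \in \{5, 10, 50\}$ or
$\theta_A^{MAP}$, nuisance parameters integrated over their priors, and
$BF = \#\{\text{soft within radius}\} / \#\{\text{hard within radius}\}$.
A zero hard count is reported as a flagged lower bound ($BF \ge n_{soft}$)
rather than infinity, and a doubly empty radius as an undefined result.

**Desk-scale acceptance rules.** The publication-scale analysis uses
radius 0.1 with $10^5$–$10^6$ simulations per observation. At the
reference-table sizes used in this package's validation suite (a few
thousand draws), almost no draw falls within 0.1 normalised units of a
sweep-like observation, because most of the prior volume produces
sweep-free statistics. The validation experiments therefore use (a) for
posterior recovery, the `"nearest"` acceptance rule — accept the `target`
draws with the smallest normalised distance, the standard
fixed-acceptance-fraction form of rejection ABC — and (b) for Bayes
factors, a radius of 0.5 with observations averaged over replicate
sweeps, both chosen once from pilot runs; the factor-of-three recovery
tolerance absorbs the extra smoothing. The radius defaults to the
publication value 0.1 in the user-facing functions. A further caveat
applies to prior draws with $s$ near 1: at $Q = 2000$ the scaled
coefficient $s' = Qs$ is far above 1, the sweep completes within a few
scaled generations, and recombination fragments the sweeping haplotype
more evenly than it would in real time, inflating H2/H1 for some
strong-$s$, low-$PF$ hard draws. This is the standard fidelity limit of
aggressive rescaling (faithful for $Qs \ll 1$) and is why the
classification experiments quote directional, not calibrated, evidence.

## LD decay and iHS

`ld_decay()` reproduces the pairwise-LD methodology used to choose the
window size: $R^2$ between the first allele-frequency-passing SNP of each
10-kb window (stepped by 50 bp) and every other passing SNP in the
window, requiring at least 4 haplotypes complete at both sites, averaged
in 20-bp distance bins up to 300 bp and 150-bp bins beyond.

`ihs_scan()` implements an unpolarized iHS: per SNP with minor allele
frequency at least 0.05, the EHH curves of the major and minor alleles
are integrated (trapezoidally, over physical distance) out to the point
where EHH decays below 0.05, and the score $\ln(iHH_{major}/iHH_{minor})$
is standardised to zero mean and unit variance within MAF bins of width
0.05. Haplotypes with missing data in the traversed region are discarded
as the region extends (keeping the core carrier pair count as the
denominator, which preserves monotonicity of EHH); SNPs whose EHH never
reaches the cutoff before a chromosome end are dropped with reason
"edge", and single-SNP MAF bins keep a centred score of 0.
`enrichment_windows()` counts SNPs with $|iHS| > 2$ in non-overlapping
100-kb windows and flags the top decile by count, breaking ties toward
the leftmost window — the comparison scan used to corroborate H12 peaks.
The expected chance overlap between the two candidate sets is the
product of their genome-coverage fractions (`expected_overlap()`).

## What the synthetic data do and do not show

The generator's defaults are the reference study conditions: constant
$N_e = 10^6$, $\mu = 10^{-9}$/bp/generation, $\rho = 5 \times 10^{-7}$
cM/bp, loci of $10^5$ bp, samples of 145 haplotypes, 400-SNP windows.
Under these conditions the package's null calibration reproduces the
published critical value (the 20 000-replicate surrogate in the test
suite estimates the 99.992-percentile of neutral $H12$ and brackets
0.0171), and the directional facts the method rests on hold: $H12$
decreases and $H2/H1$ increases with $\theta_A$; origin counts grow with
$\theta_A$; sweep signatures decay with $T_E$.

Synthetic data are phased, error-free, uniformly sampled and simulated
under a single panmictic (or template) demography. Real data add
genotyping error, inversion polymorphism, population structure and
cryptic relatedness, all of which can inflate haplotype homozygosity;
passing tests on synthetic data therefore validate the statistics and
their calibration, not the robustness checks (inversion association,
subsampling, relatedness filtering) that a real-data analysis needs.

## Problem sizes used for validation

The test suite runs at desk scale by design: 20 000 neutral replicates
for the calibration surrogate (at the full $10^5$ bp locus), 100
replicates per point for the $\theta_A$ trend checks, reference tables of
a few thousand draws for ABC recovery and a few hundred per hypothesis
for Bayes-factor direction, with seeds fixed in the tests. Module tests
use small loci ($10^4$–$5\times10^4$ bp) and small samples so that each
file runs in seconds. The ABC recovery experiment uses a
$4 \times 10^4$ bp locus — the windowed statistics are computed on the
central 400 SNPs, whose joint law does not depend on the flanking locus
length, so this choice only reduces cost — while the Bayes-factor
reference sets keep the full $10^5$ bp locus, because with a shorter
locus the $\ge 400$-SNP sample filter preferentially discards clean hard
sweeps and would bias the hard reference. Prior draws whose sample
cannot reach 400 segregating sites after a bounded number of redraws are
recorded as failed and excluded, matching the published practice of
discarding sub-400-SNP samples.

## Known limitations

* The SMC' neutral arm and the coalescent-initialised forward arm are
  approximations, excellent for window statistics but not a full ARG.
* Aggressive rescaling ($Q \sim 10^3$) coarsens drift during the sweep;
  properties that depend on fine-grained establishment dynamics (e.g.
  fixation-time distributions) should be studied at larger $N'$.
* The admixture template is a founding-bottleneck caricature with
  user-supplied parameters, not a fitted demographic model.
* The iHS implementation integrates over physical distance without a
  genetic map and does not polarise alleles; only the published MAF
  filter, standardisation and enrichment rules are contractual.
* H2/H1 is only interpretable where H12 is already high; at low H12 both
  hard and soft sweeps are compatible with a wide range of H2/H1.
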