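---
title: "Measuring homologous recombination in bacterial core genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring homologous recombination in bacterial core genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corerecomb)
```

## The problem

Within a bacterial species, homologous recombination overwrites stretches of
a genome with the corresponding fragment from another strain. Between a
*typical* pair of strains — whose common ancestor lies far in the past — the
genome is a mosaic of overlapping transfers and nothing can be resolved
event by event. But in a large sample some pairs of strains share a recent
common ancestor. For such **close pairs** the genome is mostly a clonal
backbone carrying only the handful of point mutations accumulated since the
ancestor, and each recombination event stands out as a block of locally
elevated divergence. `corerecomb` implements the analysis chain built on
this observation:

1. **core_data** — aligned core-genome haplotypes, pairwise synonymous
   difference profiles, fixed-size identity blocks, sliding-window
   divergence.
2. **cphmm** — a pairwise hidden Markov model (CP-HMM) that segments a close
   pair's genome into clonal and recombined regions and emits individual
   transfer events.
3. **mosaic_model** — the accumulated-transfers model linking a pair's
   clonal fraction to its genome-wide divergence, and the timescale ratio
   T_mrca/T_mosaic.
4. **transfer_stats** — cohort statistics: transfer accumulation trends,
   apparent recombination rates, transfer lengths, donor-divergence
   distributions against a random-segment null.
5. **sharing** — runs of shared ancestry, the genome-wide haplotype-sharing
   landscape, its coefficient of variation, and permutation tests for
   hotspot concordance.
6. **within_host** — dual-colonization detection, quasi-phasing of the
   dominant strain, gene-specific sweep detection.
7. **neutral_sim** — the generators that supply validation oracles and null
   distributions for everything above.

## The pair HMM

For one close pair we observe a binary vector over the compared synonymous
sites: 1 where the alleles differ, 0 where they agree (sites missing in
either strain are excluded from numerator and denominator alike). The hidden
chain has one **clonal** state, emitting differences as Bernoulli(d_clonal),
and a **recombined** macro-state expanded into one sub-state per bin of the
*empirical distribution of local divergence* (default 12 log-spaced bins).
Each sub-state emits Bernoulli(bin divergence); the chain enters bin *k*
from the clonal state with probability `t_enter * w_k` (w_k the bin mass)
and returns with probability `t_exit`, with no direct bin-to-bin moves. The
empirical emission architecture matters: transfer divergences vary over an
order of magnitude within one species (within-clade versus between-clade
donors), and a single-divergence emission model either misses faint
transfers or shreds strongly diverged ones.

`d_clonal`, `t_enter` and `t_exit` are re-estimated by Baum–Welch
(log-likelihood asserted non-decreasing at every step); the bin divergences
and weights stay fixed at their empirical values. Decoding is by Viterbi —
posterior mean recombined occupancy is reported as QC — with ties broken
toward the clonal state, which is conservative toward fewer events.

Numerical and filtering choices, each configurable:

* **Initialization**: `d_clonal` from the SNV density of low-count identity
  blocks; `t_exit = 1/2000` sites (a prior mean tract of 2,000 synonymous
  sites); `t_enter = (1 - c0) * t_exit` with `c0` the identity-block-implied
  clonal fraction. A crude moment match that keeps EM away from label swaps.
* **Separability guard**: emission bins below 3x the initial clonal
  divergence are dropped (and `d_clonal` is capped at half the lowest bin),
  so the clonal state cannot migrate into the recombined regime.
* **Minimum event support**: decoded segments carrying fewer than 2 SNVs are
  discarded — a 1-SNV segment is indistinguishable from a point mutation.
  This is the method's sensitivity floor.
* **Micro-gap merging**: events separated by under 100 bp of clonal path are
  merged; such gaps are emission noise, not evidence of two transfers.
* **Close-pair regime guard**: pairs whose genome-wide divergence exceeds
  0.02 (near the typical divergence of prevalent gut species) are rejected
  with a diagnostic rather than decoded; final cohort selection applies the
  clonal-divergence and clonal-fraction thresholds `d* = 1e-4` and
  `fc* = 0.2` (both per-species configurable).
* **Event lengths in bp** extend each decoded segment half-way to the
  flanking compared sites, so `length_bp` reflects the local density of
  synonymous sites rather than the positions of the outermost SNVs.

Whether one decodes with Viterbi or a posterior threshold is a genuinely
open choice; we use Viterbi because event counts and boundaries are the
quantities of interest, and report mean posterior occupancy so users can
flag pairs where the two disagree.

## The accumulated-transfers (mosaic) model

As a pair's clonal divergence `d_cl` grows, transfers accumulate and the
surviving clonal fraction decays as `c = exp(-kappa * d_cl)`. The parameter
`kappa` is deliberately expressed per unit *clonal divergence* — not per
generation — because divergence is the only observable clock; for a transfer
rate of R events per unit clonal divergence with mean tract `l_r` on a
genome of L sites, `kappa = R * l_r / L`. Genome-wide divergence is then

d(c) = c * d_cl(c) + (1 - c) * d_bar_r,

with `d_bar_r` the mean divergence of recombined sequence. A block of B
synonymous sites is identical only if clonal and mutation-free:
`f_id = c * exp(-B * d_cl)`.

`fit_mosaic()` inverts the *joint* relation
`f_id = exp(-(kappa + B) d_cl)` per trial `kappa` (a two-step plug-in that
first converts `f_id` to `c` biases `d_cl` when it is non-negligible),
profiles out `d_bar_r` in closed form, and optimizes `kappa` on a log grid.
Weights default to the inverse local density of points along the `f_id`
axis so that the many near-clonal pairs of a well-sampled species do not
dominate the fit; this weighting is a declared choice and can be replaced.
Two identifiability guards: a fit whose `kappa` lands on the search boundary,
or that improves on the no-recombination (`kappa -> 0`) limit by less than 1%
of the weighted variance, is flagged unidentifiable — pure-mutation cohorts
land here.

The timescale ratio is `T_mrca / T_mosaic = kappa * d_bar_r`: `1/kappa` is
the clonal divergence at which the genome is 1/e clonal (the mosaic time in
divergence units) and `d_bar_r` proxies the typical pair coalescence time
(the divergence recombined regions actually carry). The proxy is an
approximation: it assumes donors are typical strains. Simulation recovery
(see below) bounds its bias under the study conditions at a few percent.

On cohorts simulated at realistic study conditions (kappa = 500,
d_bar_r = 0.02, 150–200 pairs, 1e6 synonymous sites) the fit recovers
`kappa` and `d_bar_r` within a few percent; at 5-fold smaller genomes the
per-pair Poisson noise in the realized recombined fraction is correlated
between `f_id` and `d` and attenuates `kappa` by ~25% — an
errors-in-variables effect users should keep in mind for short core genomes.

## Sharing landscapes and selection scans

A **run of shared ancestry** is a maximal stretch of zero differences. The
longest run is compared between co-colonizing strains (one pair per
dual-colonized host) and between-host pairs with a one-sided
Kolmogorov–Smirnov test. The K-S *statistic* is classical; its p-value is
computed by **label permutation** (default 999 permutations) rather than the
asymptotic formula, which is mildly anti-conservative at the sample sizes of
dual-colonization cohorts (tens of hosts). Calibration on null replicates
puts the empirical type-I error at ~0.06 for nominal 0.05. A fundamental
power limit applies: if a fraction eps of within-host pairs carry a recent
transfer, the one-sided K-S distance is bounded by eps, so at n = 30 hosts a
10% contamination (D <= 0.1, critical value ~0.25) is essentially
undetectable by any ECDF-supremum test — enrichment must exceed roughly a
quarter of hosts before this test can see it.

The **sharing landscape** evaluates, at every synonymous site where a full
window fits, the fraction of eligible strain pairs identical across the
window. The automatic window is `ceil(15 / d_bar)` synonymous sites, long
enough (`l * d_bar >> 1`) that typically diverged pairs essentially never
match, so sharing isolates recent transfers and recent ancestry. "Identical"
requires zero mismatches on observed sites with at least 90% of window sites
observed in both strains. Windows are centered; half-windows at the ends are
excluded. The coefficient of variation of the landscape separates
selection-driven hotspot structure from the tight neutral band obtained by
rerunning the landscape on neutral Moran simulations.

The hotspot concordance/discordance test statistic is Spearman correlation
(top-k overlap available); the null rotates one landscape by a uniform
random offset, preserving its spatial autocorrelation — site-wise shuffles
would be badly anti-conservative. Both orientations are exposed and recorded
in the output because "same hotspots" and "actively different hotspots" are
different claims: concordance asks whether the observed statistic beats the
rotations, discordance whether it falls below them. Discordance is only
detectable when each landscape carries several hotspots at aperiodic
positions; a single shifted hotspot is statistically indistinguishable from
a typical rotation.

The closed-form neutral expectation for the number of shared fragments
longer than `l`, `C * L / (d_bar * l^2 * (1 + r/mu)^2)`, is provided with
its constant calibrated once against the Moran simulator (N = 200,
d_bar = 0.02, r/mu = 1, l = 10/d_bar). A known limitation: in the Moran
simulator the zero-SNV-run census follows renewal theory,
`L * m / (1 + l * m)^2` with marker density `m = d_bar * (1 + r/mu)` — a
*single* factor of `(1 + r/mu)` at large `l` (about a 2-fold reduction from
r/mu = 0 to 1, not 4-fold), partly because gene conversion also *creates*
long shared tracts between recipient and donor lineages. The formula's
exponents in `l` (log–log slope -2, verified by ensemble regression) and its
4-fold closed-form ratio are exposed separately so users can test either
claim against their own simulations.

## Within-host analyses

Dual colonization is called when at least 100 usable SNVs (depth >= 10,
configurable) have alt-allele frequency strictly inside (0.2, 0.8); the
dominant strain frequency is the mode of the folded major-allele
frequencies. Quasi-phasing assigns the dominant strain's allele wherever the
major allele exceeds 80% frequency and masks the rest; on simulated 85/15
mixtures at depth 80 the recovered haplotype's error rate equals the
binomial mis-call rate of the threshold, which is below 0.5%.

Gene-specific sweep calls require (i) a zero-intermediate-SNV region of at
least 10 kb, (ii) flanks that remain polymorphic (>= 1 intermediate SNV per
2 kb over each 10 kb flank) so that a region where the two strains happen to
be identical is not called, and (iii) region median coverage within
(0.6, 1.5) of the genome-wide median — the "copy number close to one"
criterion that rules out deletions. Longitudinal mode additionally requires
the region to have been polymorphic at the earlier timepoint, making its
call set a strict subset of the single-timepoint calls.

## The simulators, and what passing tests do (and do not) show

`simulate_pair()` generates exactly the object the CP-HMM sees — a clonal
Bernoulli backbone overwritten by Poisson-many geometric-length transfers
whose interiors are Bernoulli(donor divergence) — plus the ground truth of
*visible* (post-overlap, last-writer-wins) segments. Its defaults are the
close-pair study conditions used throughout the validation suite: 1e6
synonymous sites, clonal divergence 5e-5, ten transfers of mean 2e4 sites,
and a two-mode donor mixture (70% mass near 1%, 30% near 10%, lognormal
spreads 0.3 and 0.2) emulating a species with two subspecies whose
between-clade divergence is ~10-fold the within-clade value.

`simulate_population()` is a forward-time Moran model with gene conversion:
per event one individual is replaced by another's offspring, which acquires
Poisson(mu L) mutations and Poisson(rho L) conversions copying
geometric-length tracts from random donors, with an optional initiation-rate
hotspot. With uniform birth and death a pair coalesces at rate 2/N^2 per
event, so expected pairwise divergence is N mu; the default burn-in of 10 N
generations is ~20x the mean pair coalescence time (stationarity was checked
by divergence plateau during development). A forward model at desk scale
(N <= 500, L <= 1e6) was chosen over a coalescent with gene conversion
because it is much easier to implement correctly; to emulate larger
populations, rescale: hold N mu (divergence), rho/mu, and the tract length
fixed and results at the pairwise level are unchanged.

Star and two-clade generators provide fixed-divergence controls (the
"mutations randomly scattered" limit), `inject_sweep()` plants hard or soft
sweeps by copying donor haplotypes into a carrier fraction, and
`plant_close_pairs()` grafts close partners whose transfers are copied from
*real* donor strains of the population (so their local divergences follow
the population's true structure — the construction used for clade-barrier
tests).

What the generators deliberately do **not** emulate: real missingness and
quasi-phasing error patterns, gene boundaries and codon structure (the
synonymous annotation is taken as given), varying site density along real
core genomes, linkage between core and accessory elements, selection other
than the injected sweeps, and demographic structure beyond two clades.
Passing the validation suite therefore shows the algorithms are correct and
calibrated *under their own model assumptions*; it does not certify
performance on data whose error modes violate them (e.g., systematic
quasi-phasing artifacts shared between samples).

## Validation problem sizes

The test suite regenerates everything from seeded simulators: 200 close
pairs of 1e6 synonymous sites for CP-HMM operating characteristics
(sensitivity for >= 5-SNV transfers, false events per pair, clonal-divergence
bias); 150–200 pairs for mosaic recovery; 50 Moran replicates (N = 200) for
the shared-fragment slope; 100 neutral replicates (N = 100, L = 3e4) for the
landscape CV band; 200 null and 60 contaminated replicates for K-S
calibration and power; 40 replicates for the hotspot-direction check; and a
24-strain two-clade population with 10 planted close pairs for the
donor-divergence suppression test. `scripts/acceptance.R` recomputes the
same quantities at moderately smaller ensemble sizes and records each with
the problem size used.
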