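---
title: "Linking courtship display structure to population-genetic divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking courtship display structure to population-genetic divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(courtpop)
```

## The problem

Courtship displays are under strong selection for choreographic precision,
yet they differ enormously between species — so something must let them
diverge. One way to catch divergence in the act is to compare populations
that are genetically isolated but recently separated: if display structure
tracks genetic distance, drift or local selection is reshaping the
choreography; if the display stays put while the genome drifts, stabilizing
forces dominate. courtpop implements both sides of that comparison — a
behavioral-sequence pipeline and a population-genetics pipeline — and the
join between them, for the kind of data a field study of a displaying
insect actually produces: scored video bouts and a reduced-representation
SNP panel.

This vignette explains the models and estimators, the parameters that
matter, what the built-in simulators do and do not emulate, and the choices
made where the design was genuinely open.

## Behavioral states and sequences

The scoring unit is the *bout*: a maximal interval during which one
behavior is continuously expressed by one actor. Behaviors of a single fly
are not mutually exclusive (a male can orient and wing-vibrate at once), so
the instantaneous *state* is the set of concurrently active behaviors.
`derive_state_sequence()` partitions an actor's timeline at every bout
boundary, labels each segment with its active set, merges identical
neighbors, and drops empty segments (those are inter-bout gaps, not
states). Labels are canonical — behaviors sorted in C-locale order, joined
with `-`, plus an actor tag — so `Wing-vibrate` after `Orient` and
`Orient` after `Wing-vibrate` produce the same composite
`Orient-Wing-vibrate-(M)`. Sentinel states `Bout-start`/`Bout-end` delimit
every sequence and are ordinary states in the transition analysis, so the
network records how displays open and close.

Three choices here were open and are worth stating:

- **Bout merging tolerance is 0 s.** Two bouts of the same behavior merge
  only if they touch or overlap. Field scoring at 60 fps gives 1/60 s
  resolution; no rounding is applied. A tolerance could be added if a
  scorer splits bouts at dropped frames, but none is assumed.
- **Minimum bout duration is not enforced.** Whether scored bouts had an
  enforced minimum in any particular study is a property of the scoring
  protocol, not of the analysis; the pipeline takes the log at face value.
- **Wrong-sex behaviors are rejected at load** (a female `Straddle` is
  almost certainly a scoring error); this can be disabled.

Per-pair metrics are proportions by construction — mean bout duration,
bout count, and mean inter-bout interval, each divided by total interaction
duration (or total bout count for frequency) — so pairs with different
interaction lengths are comparable. Frequencies sum to one within a pair;
behaviors with a single bout have an undefined inter-bout interval and are
flagged `NA` rather than zero.

## Transition networks and the permutation null

Within-individual transitions (state *i* immediately followed by state *j*
in the same fly's sequence) are tallied into an S × S count matrix.
Because identical neighbors were merged, the diagonal is structurally zero.

Which transitions are *nonrandom*? The null model keeps each sequence's
state multiset but destroys its order: states are shuffled independently
within every sequence (sentinels pinned at the ends), the aggregate matrix
recounted, and this repeated B times (default 1,000). The one-sided
p-value for a cell is `(1 + #[permuted ≥ observed]) / (B + 1)`; the +1
correction keeps p-values off zero, so the smallest attainable value is
`1/(B+1)`. Cells with p ≤ α (default 0.05) form the significant-transition
network, exported as an edge list or GraphML with node centralities
(percentage of all state occurrences).

Two open points, resolved as follows:

- **No multiple-testing correction on edges.** The network is a
  descriptive filter, not a family of confirmatory tests; correcting at
  S² cells would gut it. Users wanting strict control can filter the
  returned p-values themselves.
- **Actor scope.** The default counts transitions within each individual's
  own sequence, which matches the definition of the statistic; an
  *interleaved* mode (`interleave_pair()`, or
  `pair_transition_matrices(mode = "interleaved")`) merges a pair's male
  and female states by onset time so cross-sex transitions appear, which
  matches how display networks are usually drawn. Both are first-class;
  analyses in this package default to the former.

Calibration: on i.i.d. sequences the test flags about 5% of testable cells
at α = 0.05. Count statistics are discrete, and ties make the test
conservative for short sequences; the calibration check in the test suite
uses sequences of 300 states so the null distributions are smooth enough
for the nominal rate to be meaningful.

## Courtship distances

Individual displays are compared through their transition matrices:
flattened row-major to S² count vectors and fed to a Dirichlet-smoothed KL
divergence,

p̂ᵢ = (y₁ᵢ + a)/(n₁ + aS²),  q̂ᵢ = (y₂ᵢ + a)/(n₂ + aS²),  D = Σ p̂ᵢ ln(p̂ᵢ/q̂ᵢ)

in nats, with pseudocount a = 1 by default. Smoothing keeps both estimates
on full support, so divergences are always finite; `KL((1,0), (0,1), a=1)`
is `ln(2)/3 ≈ 0.231`, a useful hand check. KL is asymmetric; summaries over
population pairs average the two directions first, because a population-
pair mean has no natural direction.

A practical point that shapes every KL-based comparison: with finite
sequences the divergence between two *identical* processes is not zero but
a noise floor that scales roughly with S²/n. Between- and within-population
means share this floor, so their *difference* is informative at realistic
sequence lengths, but detecting monotone trends in the between mean itself
needs long chains. The package's own checks use 500-state chains for that
reason, and `population_divergence_summary()` always reports the within-
population means alongside.

## Population-genetic estimators

All estimators work on biallelic dosage matrices (0/1/2, `NA` missing).

- **Filtering** is sequential — reproducibility, then call rate, then
  minor-allele frequency, keeping loci at or above each threshold
  (defaults 0.98 / 0.95 / 0.02) — with a per-step attrition report. A
  quality threshold of "minor allele count 0.02" in DArT-style pipelines
  is a frequency in all but name; the report says so explicitly.
- **Heterozygosities** use the Nei–Chesser sample-size-corrected gene
  diversity `Hs = n/(n−1)·(1 − Σp² − Ho/2n)` per locus, averaged over
  loci; `F_IS = 1 − H_O/H_E` on the averages, undefined (flagged) for
  monomorphic populations.
- **Pairwise F_ST** is Weir–Cockerham θ with per-locus variance
  components combined as a ratio of sums; multilocus estimates can be
  negative and are never clipped. Bootstrap p-values resample loci; p is
  the add-one-corrected fraction of bootstrap estimates ≤ 0 (a one-sided
  test of any differentiation — which side the original toolchains used
  is not documented, so the simplest defensible convention was chosen).
- **Population-specific F_ST** is the Weir–Goudet allele-matching
  estimator: within-population matching Mᵢ against the mean
  between-population matching, `βᵢ = (Mᵢ − M_B)/(1 − M_B)`, matching
  proportions averaged over loci before the ratio.
- **AMOVA** is distance-based with three strata. The needed squared
  allele distances are computed phase-free: for biallelic loci the sum of
  squared differences over the four cross-haplotype pairs of two
  individuals is `2g_u + 2g_v − 2g_u g_v`, a function of dosages only,
  and the within-individual distance is the heterozygous-locus count.
  Missing loci are pairwise-deleted. Significance permutes individuals
  among populations (add-one-corrected p on the among-population
  component). Negative components are reported as computed.
- **Nei (1972) distance** sums gene identities over loci before the
  ratio; populations sharing no alleles give `Inf`, flagged as such.
- **Kosman distance** between individuals is one minus half the shared
  alleles per locus (`|g_u − g_v|/2` for dosages), averaged over jointly
  genotyped loci; it is a metric on complete data.
- **Isolation by distance** correlates linearized `F_ST/(1−F_ST)` with
  great-circle kilometers (haversine). Coordinates in degrees are not
  planar, so haversine is the default even where a legacy toolchain used
  planar "Euclidean" distance; a planar option exists for strict
  replication. Distances are not log-transformed by default for the same
  reason. The Mantel test is the package's own (needed for exhaustive
  enumeration at small n, used as a test oracle) and agrees with vegan's
  statistic.
- **PCA** mean-imputes missing dosages per locus, centers, and uses SVD.

## The courtship–genetics join

`courtship_vs_genetic()` reduces both matrices to one number per unordered
population pair — mean symmetrized KL and mean Kosman distance over
cross-population individual pairs — and fits courtship on genetic by OLS.
The two matrices may come from different individuals; only the populations
must correspond, since field studies rarely film the same animals they
genotype. With three populations the fit has three points; the result
carries a `small_n` flag below ten pairs, and a Spearman rho is reported
alongside because three-point R² values are fragile.

## What the simulators emulate

`simulate_behavior()` is semi-Markov: composite states are the atoms
(drawn from `P_pop = (1−ε)·P_base + ε·P_perturb(pop)`), with gamma bout
durations and positive gamma inter-state gaps, terminated by a per-step
stopping probability. Composite states are simulated directly rather than
by overlaying independent behavior processes — the observed state
inventory of a real display is far smaller than the power set of its
behaviors, so the atoms are the realistic unit — and a decomposition table
expands each state into its constituent behavior bouts for the event log,
which round-trips exactly through `derive_state_sequence()`. The baseline
matrix is a fixed, deterministic, strongly heterogeneous stochastic matrix;
perturbation matrices are drawn once per population from the seed.
Defaults mirror the motivating field design: seven beach populations with
the study's sample sizes and coordinates, courtship filmed in three of
them at 15 pairs each, bout parameters chosen so simulated interactions
center near the observed ~90 s median, and a mild divergence knob
(ε = 0.1) consistent with courtship that is largely stable across
populations. A reduced 12-state vocabulary keeps tests fast; a 41-state
preset mirrors the full published state list (two of whose printed labels
fall outside the core 18-behavior ethogram and are carried as extended
female behaviors so the preset round-trips).

`simulate_snps()` is Balding–Nichols: ancestral frequencies uniform on
[0.1, 0.9], deme frequencies Beta-distributed with differentiation F
(default 0.2, matching the study-wide differentiation), binomial
genotypes. Per-locus missingness rates are Beta(0.8, 40) (≈2% mean, a
right tail that the call-rate filter truncates, leaving ≈1.2% residual
missingness); reproducibility scores are Beta(60, 0.9) so the 0.98
threshold removes a realistic minority of loci. `spatial = TRUE` drifts
frequencies sequentially along the latitude-ordered demes, producing
isolation by distance. The simulators do **not** emulate linkage
disequilibrium between loci, allele-frequency-dependent missingness,
within-pair behavioral feedback (male and female chains are independent),
kinematics, or multimodal signals — so passing tests demonstrate that the
estimators recover the generative parameters under clean assumptions, not
that real data meet those assumptions.

`simulate_coupled_study()` drives both sides from a shared divergence axis
z: courtship ε and genetic F increase with z, mixed with an independent
shuffle in proportion to a `coupling` knob. It exists to verify the
join: at full coupling the courtship-vs-genetic R² should be high, at
zero coupling low.

## Numerical choices and degenerate inputs

- All permutation/bootstrap p-values use the add-one correction; minimum
  attainable p is `1/(B+1)`. B defaults: 1,000 (edge test, AMOVA),
  1,000 (F_ST bootstrap), 10,000 (Mantel); every routine takes a seed.
- Degenerate inputs fail loudly: zero-duration interactions, empty
  populations, all-loci-removed filters, single-population F_ST, B below
  its floor. Quietly degenerate quantities (single-bout intervals,
  monomorphic F_IS, single-individual within-population means, pairs with
  no shared loci) are `NA`, never silently zero.
- Proportions, variance components and F estimates are reported as
  computed — negative where the estimator goes negative.

## Problem sizes in the test suite

The suite exercises everything at desk scale: oracle-equivalence checks on
instances of ≤10 individuals × ≤20 loci and sequences of ≤50 states
against brute-force reimplementations (fine-grid labeling, explicit
haplotypes, scalar allele accounting); calibration of the permutation
procedures over 200 replicates; and parameter recovery at 7 demes × 15
diploids × 5,000 loci (F̂ within ±0.03 of the generative 0.2), with KL
monotonicity probed on 500-state chains. These sizes were chosen as the
smallest at which each property is statistically crisp.

## Known limitations

- The KL noise floor means absolute courtship distances are comparable
  only between chains of similar length; the package reports means with
  standard errors but does not bias-correct the divergence itself.
- AMOVA's within-individual stratum assumes diploidy and codominant
  biallelic markers.
- The OLS R² over a handful of population pairs is descriptive; with
  three pairs it can take any value and the `small_n` flag should be
  taken seriously.
- Beta-regression modeling of the proportional metrics (the usual next
  step for per-behavior population contrasts) is deliberately out of
  scope; the metric tables are emitted analysis-ready instead.
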