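---
title: "Methods: coupled population genetics and larval dispersal for a range-expanding coral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled population genetics and larval dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefconnect)
```

# The problem

A broadcast-spawning coral expanding poleward along a western-boundary
current poses two linked questions: how much genetic diversity do the young
range-edge populations carry, and can ocean currents actually deliver larvae
between the subtropical core and the temperate edge? `reefconnect` answers
both halves with one tested code base: microsatellite population-genetic
statistics on the one hand, and a biophysical larval-transport simulation on
the other, joined by an isolation-by-distance (IBD) analysis that regresses
genetic differentiation on geographic and oceanographic distance.

Every stage also runs on synthetic data with known truth, so the whole
pipeline is verifiable end to end without any external download.

# Genotype model and filters

Input genotypes are diploid microsatellite calls (GenePop format, 2- or
3-digit alleles; missing = `000`). Allele pairs are stored unordered because
microsatellites are unphased. The filter cascade mirrors the field's usual
practice for a dataset containing cryptic lineages and clones:

1. **Lineage filter.** Individuals are kept when their membership in the
   designated cluster of an externally supplied admixture Q-matrix is at
   least the threshold (default 0.70, inclusive) in *every* supplied
   clustering solution (e.g. both K = 2 and K = 3). The clustering itself
   (STRUCTURE-style MCMC) is out of scope; only the supplied coefficients
   are filtered on.
2. **Locus exclusion.** Loci flagged upstream (e.g. suspected null alleles)
   are dropped by name.
3. **Clone correction.** Colonies sharing a multilocus genotype (MLG) at
   every co-scored locus form one genet; missing calls act as wildcards and
   groups merge transitively. A duplicate group counts as a true clone only
   when its probability of identity — per locus
   `sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`, multiplied over scored loci —
   falls below 0.001; then one ramet represents the genet downstream.
   The clonal fraction is `1 - MLG/N` whatever the flag, matching the usual
   reporting convention.
4. **Population filter.** Populations with fewer than 9 distinct MLGs are
   dropped entirely (inclusive boundary: 9 stays).

# Statistics

* **Diversity** per population and locus: allele count, observed and
  expected heterozygosity (`He = 1 - sum(p^2)`, with the `2N/(2N-1)`
  small-sample variant), `FIS = (He - Ho)/He`, fixed-locus counts, private
  alleles with their carriers, and allelic richness rarefied by
  hypergeometric sampling of `2g` gene copies
  (`A = sum_i [1 - C(2N - n_i, 2g)/C(2N, 2g)]`). The default rarefaction
  depth is the smallest retained population, consistent with the 9-MLG
  inclusion rule.
* **FST.** Weir–Cockerham's variance-components estimator θ, components
  summed over alleles and loci, globally and pairwise; permutation p-values
  reallocate individuals among populations. θ is the package's primary
  differentiation estimator: it has an analytic truth under the generator
  (below) and is the de-facto standard.
* **Jost's DEST.** Per locus
  `D = (k/(k-1)) (Ht' - Hs')/(1 - Hs')` with Nei–Chesser small-sample
  corrections on harmonic-mean sample size; loci combined by the harmonic
  mean of per-locus D when all are positive, otherwise the arithmetic mean
  (a harmonic mean is undefined for non-positive values). Note a subtlety:
  with the corrections, two *identical* finite samples give
  `Ht' - Hs' = Hs'(1-k)/(2 n k) < 0`, so D is a hair below zero rather than
  exactly zero; tests bound it by that algebraic remainder.
* **AMOVA.** Three-level variance decomposition (among groups / among
  populations within groups / within populations) of allelic distances:
  the number of non-shared alleles between two diploid genotypes (0/1/2 per
  locus via maximum multiset matching), summed over loci. Permutation
  schemes follow convention: whole populations among groups for FCT,
  individuals among populations within groups for FSC, individuals among
  all populations for FST. *Scale caveat:* this individual-level distance
  is nonlinear in gene identity, so the resulting fixation index is exact
  at 0 and at 1 but runs above gene-level θ at intermediate divergence
  (about 1.5× on the generator's island model). Comparisons across methods
  should use θ.
* **Exact differentiation tests.** Per locus, a Monte-Carlo exact test on
  the 2 × k allele-count table: fixed-margin tables via `r2dtable`, p =
  fraction with conditional probability ≤ the observed table's. Loci are
  combined by Fisher's method; families of pairwise tests are corrected by
  the sequential Bonferroni (Holm) step-down rule via `p.adjust`.
* **Ordination and trees.** PCoA by classical metric scaling (`cmdscale`)
  on any symmetric distance (population-level or the individual allelic
  distance); Nei's standard genetic distance `D = -ln I` with
  neighbour-joining (`ape::nj`) and bootstrap-over-loci support on internal
  splits.
* **Assignment.** Rannala–Mountain Bayesian assignment: the likelihood of a
  multilocus genotype under each population's Dirichlet-posterior allele
  frequencies (prior 1/k per allele, k = alleles seen at the locus
  dataset-wide, so unseen alleles never zero out a likelihood), own alleles
  left out of the home population's counts, probabilities normalized across
  candidates. Assignment requires best probability > 0.70; an assignment to
  a population of a different region class flags a putative immigrant.
* **Genotypic linkage disequilibrium.** G statistic on the two-locus
  genotype table summed over populations; p by permuting one locus's
  genotypes among individuals within populations.

# Spawning phenology and particle tracking

Spawning at a site begins relative to the first full moon once the water
has been warm enough for long enough: daily degree-days `max(T - 13, 0)`
accumulate from February 1, and the exceedance date is the day the running
integral reaches 1000 °C·day (each day's excess accrues by the end of that
day, so a constant 10 °C excess completes the integral exactly 100 days
after the start). The spawning full moon is the latest full moon on or
before the exceedance date; particles are released daily for 10 days
starting 3 days before that moon, 50 particles per site-day — 500 per site
and season. The lunar calendar is a fixed synodic progression
(29.530588 d), deterministic and sufficient for scheduling; no ephemeris.

Larvae are passive surface particles. Positions advance by 4th-order
Runge–Kutta (default step 2 h) on velocities interpolated bilinearly in
space and linearly in time, with degree/metre conversion by the local
cos(latitude). A particle may settle in the first habitat cell (one grid
cell, default 1/12°) it occupies at age ≥ 3 days — its natal cell included,
so self-recruitment is possible; at 42 days unsettled particles expire;
leaving the grid is recorded as exited. Particles attempting to enter a
land cell are held at their previous position (no-flux) rather than killed,
which keeps the conservation law `settled + expired + exited = released`
exactly testable. Two numerical constraints matter: the step must not
exceed one day, and settlement is only detected at integration steps, so
the step should be short enough that a particle cannot cross a habitat cell
between checks (at 1.2 m/s a 2 h step moves ~8.6 km against an ~9 km cell;
faster flows or coarser sampling need a smaller step).

Annual connectivity divides settlers by the 500 released per site-year;
years average element-wise (a site-year with no spawning contributes a zero
row and stays in the denominator; the year list is always explicit).
Multi-generation accumulation iterates the row-normalized chain:
`A[1] = C`, `A[g+1] = A[g] ⊕ (A[g] %*% Chat)` with the element-wise
saturating combine `a ⊕ b = a + b - ab`, which is monotone non-decreasing,
capped at 1, and stabilizes (default horizon 1000 generations, early stop
on max change < 1e-9). The rule reproduces the intended behaviours —
stepping-stone filling of forward-reachable pairs, stabilization, and
strict preservation of one-way barriers — without inventing population
dynamics the data cannot constrain.

# Isolation by distance

Three predictors of pairwise FST: great-circle (haversine, R = 6371 km)
distance; shortest sea-path distance by Dijkstra on the 8-connected
sea-cell lattice with great-circle edge weights (a reproducible replacement
for hand-measured around-land distances; it can never undercut the great
circle); and the connectivity-derived dissimilarity
`-log((C_ij + C_ji)/2 + eps)` with eps half the smallest positive
symmetrized flow, which keeps zero-flow pairs strictly farthest without
infinities. The Mantel statistic is the Pearson correlation of lower
triangles; the test permutes one matrix's row/column order jointly and is
one-tailed for positive association (the IBD convention). Raw FST is the
default response; the `FST/(1-FST)` linearization is available but off.

# The synthetic study system

`generate_genotypes()` plants known truth. In the island layout each
population's allele frequencies are Balding–Nichols draws,
`Dirichlet(p_anc (1-F)/F)`, making the planted F the analytic expectation
of θ — the basis of the estimator-recovery tests (mean θ within ±0.02 of
F ∈ {0.02…0.15} over 100 replicates at 13 × 20 × 8). The linear layout
chains populations by serial multinomial drift (effective gene number
≈ 1/F per step), so diversity erodes toward the range edge and FST grows
with chain distance — the stepping-stone situation that produces IBD.
Clonal replication copies whole rows (exact ramets), the cryptic lineage
mixes in a second, independently drawn frequency pool with per-individual
membership exposed as a true Q-matrix, and missing data is masked at a
configurable rate.

`generate_ocean()` builds a Gaussian-profile jet along a prescribed
poleward path (peak speed on the core, default 1.2 m/s and 0.8° width,
realistic for a western-boundary current), optional smooth random-phase
eddy noise, polygon land masks with zero velocity on land, and per-site
daily SST, `a0 + a1·lat + A sin(2π(day - phase)/365.25)` — defaults chosen
so subtropical sites sit near 23–29 °C and temperate sites near 16–26 °C,
which makes the degree-day rule fire in May–July, later at higher latitude,
as observed for broadcast spawners in this region.

What the generator does *not* emulate: mesoscale realism (only sinusoidal
eddies), vertical structure or larval behaviour, mutation (frequencies are
drawn, not evolved), and linkage. Passing tests therefore demonstrate that
the estimators and the transport code are correct and internally coherent
— not that any particular field dataset will match.

# Numerical and design choices

* Degree-day exceedance uses the end-of-day convention (above); ties in
  Monte-Carlo exact tests count as "as extreme" (`≤ observed + 1e-9`).
* All permutation p-values use the `(1 + hits)/(B + 1)` estimator, so no
  test ever reports zero.
* Every stochastic operation takes an explicit seed; the pipeline derives
  stage seeds from one master seed, and identical configurations reproduce
  every output file byte for byte.
* Missing genotypes are deleted locus-wise (pairwise deletion) in every
  frequency-based statistic; an all-missing individual is excluded with a
  warning at clone detection.
* The Dijkstra sea-path and the particle tracker share one land mask, so
  "oceanographic distance" and simulated transport see the same geography.
* Grids for gridded fields exchange as long-format CSV (`time, lon, lat,
  u, v, land`) — an array-tool-friendly text convention; the synthetic
  generator is the normal source of fields.
* Desk-scale problem sizes in the tests and drivers (13 × 20 × 8 genotypes,
  ~1° × 10° ocean at 1/12°, 1–2 years × ≤ 13 sites, permutation counts in
  the hundreds) were chosen so each property is measured with useful power
  while the whole suite stays quick; all sizes are configuration values and
  scale up without code changes.

# Known limitations

* The AMOVA fixation index inherits the scale property of the
  allele-mismatch distance described above; use θ for cross-study
  comparison.
* The iterated connectivity saturates forward-reachable pairs toward 1, so
  its `-log` transform can *invert* distance ranking for well-connected
  distant pairs — one reason the connectivity predictor can correlate
  worse with FST than plain geography, as the IBD stage's own output
  shows.
* The sea-path lattice permits diagonal moves between diagonally adjacent
  sea cells (no corner-cutting rule beyond cell adjacency); with 1-cell
  land walls this can thread a diagonal gap. Masks should be drawn at the
  resolution at which land matters.
* Clone detection compares all pairs within a population (O(n²) per
  population), which is ample at these sample sizes.
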