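---
title: "Forward Wright-Fisher simulation under the Poisson Random Field model"
author: "prfsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward Wright-Fisher simulation under the Poisson Random Field model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfsim)
```

## The model and its assumptions

`prfsim` simulates the frequencies of derived alleles at unlinked sites
forward in time. Under the Poisson Random Field (PRF) assumptions —
free recombination between sites, no recurrent mutation at a segregating
site — every mutation's trajectory is independent of every other's, so a
"population" is fully described by an array with one row per segregating
mutation and one column per population. This is what makes the simulation
vectorizable: each generation is a block update of the whole array rather
than a loop over individuals, and the number of simulated sites `L` enters
only through the mutation influx. The same assumptions are the model's main
limitation: linked selection, haplotype structure, and multiple hits at a
site are outside its scope, and scenarios in which segregating mutations
become a substantial fraction of `L` (very long runs, very high `mu*L`)
strain the no-multiple-hits premise.

A scenario (`wf_scenario()`) supplies the parameter surfaces of the model,
each allowed to vary by population `j` and generation `t`:

| parameter | meaning | default |
|---|---|---|
| `mu(j,t)` | mutation rate per site per chromosome per generation | 0 |
| `N(j,t)` | census size, individuals; 0 = not (yet) extant | — |
| `F(j,t)` | inbreeding coefficient in [0,1] | 0 |
| `h(j,t)` | dominance; outside [0,1] = over/underdominance | 0.5 |
| `s(j,t,x)` | selection coefficient, > −1; may depend on frequency | 0 |
| `m(k,j,t)` | fraction of population j drawn from population k | identity |
| `L` | number of simulated sites | — |

Drift operates on `Ne(j,t) = 2N/(1+F)` *effective chromosomes*, rounded to
the nearest integer because it is a binomial trial count (an extant
population never drops below `Ne = 1`). `F` interpolates the diploid model
(`F = 0`, `Ne = 2N`) to the haploid one (`F = 1`, `Ne = N`), and likewise
modulates how dominance is felt by selection.

The generation cycle is migration, then selection, then drift:

* migration is *conservative*: each offspring pool is a convex combination
  of the parental pools, `x_mig[,j] = sum_k m(k,j) x[,k]` with columns of
  `m` summing to 1, so frequencies cannot leave [0,1];
* selection replaces `x` by the deterministic expectation
  `x_sel = (x^2 s + x(1-x) s (F+h-hF) + x) / (x^2 s + x(1-x) s (F+2h-2hF) + 1)`,
  which reduces to the textbook diploid viability recursion at `F = 0` and
  to `x(1+s)/(1+sx)` at `F = 1` (`select_freq()`);
* drift resamples `x' = k/Ne` with `k ~ Binomial(Ne, x_sel)`, putting
  frequencies on the lattice `i/Ne` with absorbing boundaries 0 and 1.

New mutations then enter as `Poisson(Ne mu L)` fresh rows per population at
frequency `1/Ne`; they first feel selection and drift in the following
generation. Mutations at frequency 0 in every extant population (lost) or 1
in every extant population (fixed) are inert and are physically removed
every `compact_interval` generations and once more at the end of the run;
fixed removals are logged per generation as divergence. A mutation fixed in
one population but segregating in another is retained, and can leave
frequency 1 only through migration.

## Time conventions and founding events

Generation 0 is the initialized state. The update that produces generation
`t` evaluates every parameter function at `t` — the offspring generation's
index. The binomial trial count likewise uses the offspring generation's
`Ne`, the standard Wright–Fisher convention in which the offspring pool
size is what limits sampling; the same choice applies to the influx mean
when the population size changes in that generation. Frequency-dependent
selection coefficients are evaluated at the post-migration frequency, as
the selection step's position in the cycle implies.

A founding event `(generation, source, target)` models a population split:
at the start of the update producing `generation`, the source column is
copied into the (hitherto empty, `N = 0`) target column; the target's own
census size at that generation then governs selection and drift, so a
bottleneck at the split is expressed by a small initial target size. Before
founding, a population carries frequency 0 everywhere and neither sends nor
receives migrants.

## Equilibrium initialization

Besides a blank array or a stored array from a previous run
(`read_mutation_array()`), a run can start at mutation–selection
equilibrium. The expected count of mutations at frequency `x` is the
diffusion sojourn density

`lambda(x) = 2 mu L / (x (1-x) G(x)) * int_x^1 G / int_0^1 G`,

`G(y) = exp(-Ne s(y) y {(2h + (1-2h)y)(1-F) + 2F})`.

The exponent of `G` is `int_0^x 2M/V` for the simulator's own first-order
drift `M(x) = s x (1-x) [(F+h-hF) + x (1-2h)(1-F)]` and variance
`V(x) = x(1-x)/Ne`, so the density is the equilibrium of the very process
being simulated, in its diffusion limit. Two conventions are fixed here and
verified by tests:

* the frequency classes are the drift lattice `i/Ne`, `i = 1..Ne-1`, and
  `lambda(i/Ne)` is read directly as the *expected count per class*; in the
  neutral limit `lambda = 2 mu L / x`, i.e. `2 Ne mu L / i` per class and
  `2 Ne mu L * H_{Ne-1}` segregating sites in total — the classical
  `theta/i` spectrum with `theta = 2 Ne mu` per site;
* the class counts are realized as independent Poisson draws with mean
  `lambda(i/Ne)` (inverse-CDF sampling through R's Poisson generator),
  consistent with the PRF property that class counts are Poisson.

The integrals are computed by a composite trapezoid rule on a uniform grid
of `Ne * ceiling(4096/Ne)` intervals, so every class point is a grid node
and one cached cumulative sum serves all upper limits; the rule is exact
for the constant neutral integrand, which is why the neutral closed form is
met to 1e-6 and better. Exponentials are shift-stabilized and assembled in
log space, so strong selection (`|Ne s|` in the hundreds) does not
overflow; a genuinely non-finite integrand (e.g. a selection function
returning `NaN`) is reported with the offending frequency.

Because the density is a first-order-in-`s` diffusion result while the
engine is exact and discrete, the realized equilibrium carries an `O(1/Ne)`
bias: at `Ne = 200` and `Ne s = -4` the standing segregating count sits
about 3% above `sum(lambda)`, shrinking with `Ne`. The stationarity tests
assert agreement at 5%. Equilibrium initialization covers single
populations and multiple *isolated* populations; with migration active
there is no product-form equilibrium, and a burn-in from a blank or stored
array is the supported route.

## Randomness and reproducibility

A run consumes one seeded R Mersenne-Twister stream: `simulate()` calls
`set.seed(seed)` once and draws everything — equilibrium Poisson counts,
binomial drift, mutation influx, sample spectra — from that stream in a
fixed order. Identical seeds give bit-identical results on any platform
with R's default generator. Changing `compact_interval` changes how many
draws each mutation sees (dead rows stop consuming draws once removed), so
individual trajectories differ between schedules; only the *law* of the
process is schedule-invariant, and that is what the test suite asserts
(segregating-site distributions across intervals 1/10/100 are compared by a
Kruskal–Wallis test). The fused selection-plus-drift kernel is compiled,
but calls R's own `rbinom` at C level: it is draw-for-draw identical to the
decomposed R code path, which a test pins down.

Boundary frequencies skip the binomial draw (`Binomial(Ne, 0)` and
`Binomial(Ne, 1)` are degenerate), so absorbed-but-not-yet-compacted rows
cost no randomness; R's generator consumes no variates in those edge cases
either, keeping the two code paths aligned.

## Site frequency spectra

`population_sfs()` bins mutations by their lattice class `i/Ne`, excluding
the monomorphic classes. `sample_sfs()` draws a derived-allele count
`k ~ Binomial(n, x)` per mutation — sampling chromosomes with replacement,
the appropriate model when `n` is much smaller than the population, and the
convention that matches PRF-based inference tools; a hypergeometric
(without-replacement) option is available for samples comparable to `Ne`.
Classes 0 and `n` are not segregating and are excluded from counts and from
the `num_segregating` denominator used by `normalize_sfs()`. Spectra export
as two-column TSV or as a dadi-style frequency-spectrum text file (header
`"<n+1> unfolded"`, the `n+1` values including zeroed monomorphic corners,
and a mask line flagging those corners).

## Scaling property

As with diffusion-based methods, population size and time can be rescaled
together: `(N/c, T/c, c*s, c*mu, c*m)` has the same diffusion limit as
`(N, T, s, mu, m)`, so normalized spectra agree up to `O(1/Ne)`
discretization. This is both a practical lever — a 5-fold scaled-down run
is 5 times cheaper per generation and 5 times shorter — and a correctness
check: the suite compares pooled normalized sample spectra of a two-epoch,
two-population scenario at scale 1 and scale 5 by a Kolmogorov–Smirnov
test.

## What the test scenarios emulate, and what they do not

All test inputs are generated in code: equilibrium starts, replicate-chain
arrays (50,000 single-mutation chains run as rows of one array), and the
two-population split-and-growth scenario with a 0.05-fold bottleneck,
exponential recovery, weak purifying selection (`2 N_ref s = -4`) and
symmetric migration that serves as the end-to-end validation (~3 million
mutations at the final generation, ~556,000 segregating in a
1001-chromosome sample of the derived population). These exercise
demography, selection, migration, drift, and influx jointly, but they are
still synthetic: real data add linkage, variable mutation rate along the
genome, ascertainment, and sampling noise that no PRF simulation
reproduces, so passing tests certify the simulator against its own model
class, not against genomes.

Problem sizes in the routine suite are chosen for desk-scale runtimes: unit
checks run populations of `Ne` in the hundreds for a few hundred
generations, the exact-chain comparison uses `Ne = 50` with 50,000
replicates against the 10th matrix power, the invariance checks use 50
seeds per condition, and the shape of the validation spectrum is assessed
on one full run (the count criteria) rather than the 50-run average a
publication figure would use. The exact finite-`Ne` Markov chain
(`wf_transition_matrix()`, `absorption_probability()`) is kept to
`Ne <= 500`, where its quadratic memory is trivial and its absorption
probabilities bracket both the neutral martingale result `i/Ne` and
Kimura's diffusion approximation.

## Known limitations

* No linkage, recombination, haplotypes, or multiple alleles per site; no
  recurrent mutation at segregating sites.
* Equilibrium initialization excludes migration-coupled populations
  (burn-in instead) and is a diffusion approximation with `O(1/Ne)` bias.
* The frequency lattice is per-population; comparing lattice classes across
  populations of different `Ne` requires sampling to a common `n` first.
* Selection coefficients must exceed −1; `s` far from 0 stretches the
  first-order equilibrium density (the engine itself remains exact).
* Census sizes above ~10^9 individuals exceed the integer binomial-count
  range of the drift sampler.
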