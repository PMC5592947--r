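# prfsim

Forward-in-time Wright–Fisher simulation of single-locus mutation frequency
trajectories under the Poisson Random Field (PRF) model, for population
geneticists who need expected site frequency spectra (SFS) — or full
frequency trajectories — under demographic and selection scenarios too
complex for analytical or diffusion-based solutions. Because sites are
unlinked and mutations evolve independently, the whole mutation array can be
updated as a block each generation; the inner update loop is compiled, so
scenarios with millions of segregating mutations across multiple populations
run in minutes on one CPU core.

## The model

A population of `N(j,t)` diploid individuals with inbreeding coefficient
`F(j,t)` carries `Ne = 2N/(1+F)` *effective chromosomes* — the binomial
trial count that governs drift, interpolating from outbred diploid (`F = 0`)
to haploid (`F = 1`). Each segregating mutation is a row of a frequency
array `x[mutation, population]`. One generation applies, in order:

1. **Migration** (conservative): `x_mig[j] = Σ_k m(k,j) x[k]`, a convex
   combination over source populations, columns of `m` summing to 1.
2. **Selection** with coefficient `s(j,t,x)` (which may depend on frequency,
   time, and population) and dominance `h(j,t)`:

   ```
   x_sel = [x² s + x(1−x) s (F + h − hF) + x] / [x² s + x(1−x) s (F + 2h − 2hF) + 1]
   ```

   At `F = 0` this is the textbook diploid viability recursion; at `F = 1`
   the haploid `x(1+s)/(1+sx)`.
3. **Drift**: `x' = k/Ne`, `k ~ Binomial(Ne, x_sel)`; 0 and 1 are absorbing.

New mutations enter each population as `Poisson(Ne · μ · L)` rows per
generation at frequency `1/Ne` (the PRF influx over `L` unlinked sites, no
multiple hits). Mutations lost or fixed in *all* extant populations are
removed by periodic compaction, with fixations logged as divergence.
Populations can be founded mid-run by copying a source population's
frequencies through a bottleneck (a population split).

A run can start from a blank array, a stored array from a previous run, or
directly at mutation–selection equilibrium, where the expected number of
mutations at frequency `x` is

```
λ(x) = 2μL / (x(1−x)G(x)) · ∫ₓ¹G(y)dy / ∫₀¹G(y)dy,
G(y) = exp(−Ne s(y) y {(2h + (1−2h)y)(1−F) + 2F})
```

(the standard diffusion sojourn density; `λ = 2μL/x`, i.e. the classical
`θ/i` spectrum, in the neutral limit), and per-class counts are drawn as
`Poisson(λ(i/Ne))`.

## A worked example

Five hundred generations of a single population of 500 diploids under weak
purifying selection (`Ne·s = −4`), started at equilibrium:

```r
library(prfsim)
sc <- wf_scenario(num_populations = 1, num_sites = 1e7, num_generations = 500,
                  mutation_rate = 1e-8, census_size = 500, selection = -0.004,
                  dominance = 0.5, seed = 1)
sim <- simulate(sc)
summary(sim)
#> Generations simulated: 500
#> Mutations in final array: 1,146
#> Segregating per population: 1,146
#> Removed as fixed (divergence): 8
#> Final Ne (chromosomes): 1000
```

The 1,146 segregating mutations sit near the equilibrium expectation
`Σ λ(i/Ne) ≈ 1162` for these parameters; 8 mutations fixed and now count
toward divergence. A 20-chromosome sample SFS, normalized by its
segregating sites:

```r
sfs <- normalize_sfs(sample_sfs(sim, population = 1, n = 20, seed = 2))
head(as.data.frame(sfs), 5)
#>   class count normalized
#> 1     1   179 0.41724942
#> 2     2    75 0.17482517
#> 3     3    49 0.11421911
#> 4     4    27 0.06293706
#> 5     5    22 0.05128205
```

42% of sampled segregating sites are singletons — the excess over the
neutral `1/(k·H)` expectation (~28%) reflects the purifying selection.
Spectra can be written as TSV or in dadi's frequency-spectrum text format
(`write_sfs_dadi()`) for diffusion-based tools.

Shell users can drive everything from YAML configurations:

```sh
exec/prfsim simulate --config inst/extdata/split_growth_small.yaml --out out/
exec/prfsim sfs --array out/mutation_array.tsv --pop 2 --n 10 --seed 1 --out out/ --dadi
```

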