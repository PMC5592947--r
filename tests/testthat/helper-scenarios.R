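## Shared fixtures: standard scenarios and independent oracles, all built in
## code at test time.

## Single neutral population, constant size, equilibrium start.
neutral_scenario <- function(N = 200, T = 100, muL = 0.1, seed = 1,
                             compact_interval = 10, L = 1e6,
                             initial_state = "equilibrium") {
  wf_scenario(num_populations = 1, num_sites = L, num_generations = T,
              mutation_rate = muL / L, census_size = N,
              compact_interval = compact_interval, seed = seed,
              initial_state = initial_state)
}

## The two-population validation scenario: ancestral population of Nref
## diploids in mutation-selection equilibrium, instantaneous expansion to
## 2*Nref, split after 100 generations with a 0.05*Nref bottleneck in the
## derived population followed by exponential growth to 5*Nref over 900
## generations, symmetric migration 5e-5, weakly deleterious codominant
## mutations (2*Nref*s = -4), mu = 1e-9, L = 2e9.
split_growth_scenario <- function(seed = 1, Nref = 10000, L = 2e9,
                                  compact_interval = 10) {
  Tsplit <- 101L; Tend <- 1000L
  g <- log(5 / 0.05) / (Tend - Tsplit)
  N_fun <- function(j, t) {
    if (j == 1) { if (t == 0) Nref else 2 * Nref }
    else if (t < Tsplit) 0 else 0.05 * Nref * exp(g * (t - Tsplit))
  }
  mig <- function(t) {
    M <- diag(2)
    if (t >= Tsplit) { M[1, 2] <- M[2, 1] <- 5e-5; diag(M) <- 1 - 5e-5 }
    M
  }
  wf_scenario(num_populations = 2, num_sites = L, num_generations = Tend,
              mutation_rate = 1e-9, census_size = N_fun,
              dominance = 0.5, selection = -2e-4, migration = mig,
              founding_events = founding_event(Tsplit, 1, 2),
              compact_interval = compact_interval, seed = seed,
              initial_state = "equilibrium")
}

## Independent hand-coded outbred-diploid viability recursion
## x' = (x^2 (1+s) + x(1-x)(1+hs)) / wbar -- the textbook form the engine's
## update must reproduce at F = 0.
viability_select <- function(x, s, h) {
  wbar <- 1 + s * x^2 + 2 * h * s * x * (1 - x)
  (x^2 * (1 + s) + x * (1 - x) * (1 + h * s)) / wbar
}

## Chi-square goodness-of-fit with pooling of low-expectation cells.
## observed: integer counts per category; expected: expected counts
## (same length, summing to sum(observed)). Returns the p-value.
chisq_pooled <- function(observed, expected, min_expected = 5) {
  stopifnot(length(observed) == length(expected))
  o <- numeric(0); e <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in order(expected)) {
    acc_o <- acc_o + observed[i]; acc_e <- acc_e + expected[i]
    if (acc_e >= min_expected) {
      o <- c(o, acc_o); e <- c(e, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 && length(e)) { o[length(o)] <- o[length(o)] + acc_o
                                e[length(e)] <- e[length(e)] + acc_e }
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(e) - 1, lower.tail = FALSE)
}

## Run n_chain independent single-mutation chains (as rows of one array,
## which the engine treats independently) to absorption; returns the
## fraction fixed.
fixation_fraction <- function(n_chains, Ne, start, s = 0, h = 0.5,
                              N = Ne / 2, T = 100 * Ne, seed = 1) {
  arr <- mutation_array(matrix(start, n_chains, 1))
  sc <- wf_scenario(num_populations = 1, num_sites = 1, num_generations = T,
                    mutation_rate = 0, census_size = N, selection = s,
                    dominance = h, compact_interval = 1, seed = seed,
                    initial_state = arr)
  sim <- simulate(sc, stop_if_absorbed = TRUE)
  stopifnot(nrow(sim$array$freq) == 0)     # all chains absorbed
  n_fixed(sim) / n_chains
}
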