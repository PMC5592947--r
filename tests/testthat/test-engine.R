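test_that("conservative migration averages frequencies by immigrant weights", {
  x <- matrix(runif(20), 10, 2)
  expect_equal(migrate_freqs(x, diag(2)), x)
  m <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  got <- migrate_freqs(matrix(c(0.2, 0.8), 1, 2), m)
  expect_equal(got[1, 1], 0.9 * 0.2 + 0.1 * 0.8)   # 0.26 by hand
  expect_equal(got[1, 2], 0.1 * 0.2 + 0.9 * 0.8)
  ## convexity: equal frequencies are a fixed point of any valid matrix
  set.seed(1)
  for (i in 1:20) {
    P <- sample(2:4, 1)
    m <- matrix(rexp(P * P), P, P)
    m <- sweep(m, 2, colSums(m), "/")
    p <- runif(1)
    expect_equal(migrate_freqs(matrix(p, 3, P), m),
                 matrix(p, 3, P))
  }
  bad <- matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2)
  expect_error(migrate_freqs(x, bad), "sum to")
})

test_that("selection update matches the printed form and the textbook recursion", {
  expect_equal(select_freq(0.5, s = 0.1, h = 0.5, F = 0), 0.5375 / 1.05)
  ## neutral identity, absorbing boundaries
  x <- c(0, runif(50), 1)
  expect_equal(select_freq(x, 0, h = 0.7, F = 0.3), x)
  expect_equal(select_freq(c(0, 1), s = 0.5, h = 1.2, F = 0.2), c(0, 1))
  ## outbred diploid: agrees with independent viability recursion
  set.seed(4)
  for (i in 1:25) {
    x <- runif(20); s <- runif(1, -0.5, 0.5); h <- runif(1, -0.5, 1.5)
    expect_equal(select_freq(x, s, h, F = 0), viability_select(x, s, h),
                 tolerance = 1e-12)
  }
  ## haploid limit: x' = x(1+s)/(1+sx) regardless of h
  x <- runif(20); s <- 0.3
  expect_equal(select_freq(x, s, h = 0.1, F = 1), x * (1 + s) / (1 + s * x))
  expect_error(select_freq(0.5, s = -1.5), "> -1")
})

test_that("binomial drift has the right moments, lattice, and exact law", {
  expect_equal(drift_freq(rep(0, 100), 50), rep(0, 100))
  expect_equal(drift_freq(rep(1, 100), 50), rep(1, 100))
  set.seed(10)
  R <- 10000
  x <- drift_freq(rep(0.3, R), 1000)
  expect_true(all(round(x * 1000) == x * 1000))       # lattice i/Ne
  expect_lt(abs(mean(x) - 0.3), 4 * sqrt(0.3 * 0.7 / (1000 * R)))
  ## Ne = 2 from 0.5: exact distribution {0: 1/4, 1/2: 1/2, 1: 1/4}
  set.seed(11)
  y <- drift_freq(rep(0.5, R), 2)
  obs <- c(sum(y == 0), sum(y == 0.5), sum(y == 1))
  expect_gt(chisq_pooled(obs, R * c(0.25, 0.5, 0.25)), 0.001)
})

test_that("the fused compiled update is draw-for-draw the R composition", {
  x <- c(0, runif(500), 1)
  s <- -0.02; h <- 0.6; F <- 0.25; Ne <- 73L
  set.seed(5)
  a <- prfsim:::.select_drift_cpp(x, s, h, F, Ne)
  set.seed(5)
  b <- drift_freq(select_freq(x, s, h, F), Ne)
  expect_identical(a, b)
})

test_that("new mutations arrive as Poisson(Ne*mu*L) at frequency 1/Ne", {
  sc <- neutral_scenario(N = 200, muL = 0)
  empty <- mutation_array(matrix(numeric(0), 0, 1))
  expect_identical(n_mutations(add_new_mutations(sc, 1, empty)), 0L)
  ## Ne = 20000 chromosomes, mu = 1e-9, L = 2e9 -> Poisson mean 40000
  sc40 <- wf_scenario(num_populations = 1, num_sites = 2e9,
                      num_generations = 1, mutation_rate = 1e-9,
                      census_size = 10000, seed = 1)
  set.seed(21)
  R <- 300
  counts <- vapply(seq_len(R),
                   function(i) n_mutations(add_new_mutations(sc40, 1, empty)),
                   integer(1))
  expect_lt(abs(mean(counts) - 40000), 3 * sqrt(40000 / R))
  ## contract: one nonzero entry per row, equal to 1/Ne, tagged with t and j
  sc2 <- wf_scenario(num_populations = 2, num_sites = 1e9,
                     num_generations = 5, mutation_rate = 1e-9,
                     census_size = function(j, t) if (j == 1) 500 else 250,
                     seed = 1)
  a <- add_new_mutations(sc2, 3, mutation_array(matrix(numeric(0), 0, 2)))
  expect_gt(n_mutations(a), 0)
  nz <- rowSums(a$freq > 0)
  expect_true(all(nz == 1))
  for (j in 1:2) {
    rows <- a$origin_population == j
    ne <- effective_chromosomes(sc2$census_size(j, 3), 0)
    expect_true(all(a$freq[rows, j] == 1 / ne))
  }
  expect_true(all(a$origin_generation == 3))
})

test_that("compaction removes only globally lost and globally fixed rows", {
  f <- matrix(c(0, 1, 0.5,
                0, 1, 0.2), ncol = 2)
  arr <- mutation_array(f, 1:3, rep(1L, 3), 1:3)
  out <- compact_mutations(arr)
  expect_identical(n_mutations(out$array), 1L)
  expect_equal(out$array$freq, matrix(c(0.5, 0.2), 1, 2))
  expect_identical(out$n_fixed, 1L)
  expect_identical(out$n_lost, 1L)
  ## fixed in one population but segregating in another is retained
  part <- compact_mutations(mutation_array(matrix(c(1, 0.4), 1, 2)))
  expect_identical(n_mutations(part$array), 1L)
  ## empty input passes through
  e <- compact_mutations(mutation_array(matrix(numeric(0), 0, 2)))
  expect_identical(n_mutations(e$array), 0L)
  ## survivor order is preserved
  f2 <- matrix(c(0.1, 0, 0.2, 1, 0.3), ncol = 1)
  out2 <- compact_mutations(mutation_array(f2, 1:5, rep(1L, 5), 1:5))
  expect_equal(as.vector(out2$array$freq), c(0.1, 0.2, 0.3))
  expect_equal(out2$array$origin_index, c(1L, 3L, 5L))
  ## non-extant populations are ignored when judging loss/fixation
  g <- compact_mutations(mutation_array(matrix(c(1, 0.4), 1, 2)),
                         extant = c(TRUE, FALSE))
  expect_identical(n_mutations(g$array), 0L)
  expect_identical(g$n_fixed, 1L)
})

test_that("a huge population drifts negligibly in one generation", {
  x <- runif(200)
  arr <- mutation_array(matrix(x, ncol = 1))
  sc <- wf_scenario(num_populations = 1, num_sites = 1, num_generations = 1,
                    mutation_rate = 0, census_size = 5e8, seed = 1,
                    initial_state = arr)
  out <- step_generation(sc, 1, arr, seed = 2)
  ## sd of the change is sqrt(x(1-x)/1e9) <= 1.6e-5
  expect_lt(max(abs(out$freq - x)), 8 * sqrt(0.25 / 1e9))
})

test_that("neutral fixation probability equals the starting frequency", {
  frac <- fixation_fraction(n_chains = 5000, Ne = 100, start = 0.5, seed = 31)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 5000))
})

test_that("simulation is reproducible and respects the generation-0 contract", {
  sc <- neutral_scenario(N = 150, T = 80, muL = 0.3, seed = 17)
  s1 <- simulate(sc)
  s2 <- simulate(sc)
  expect_identical(s1$array, s2$array)
  expect_identical(s1$fixation_log, s2$fixation_log)
  s3 <- simulate(sc, seed = 18)
  expect_false(identical(s1$array, s3$array))
  ## T = 0 returns the compacted initial state
  sc0 <- neutral_scenario(N = 150, T = 0, muL = 0.3, seed = 17)
  s0 <- simulate(sc0)
  expect_identical(s0$array, init_equilibrium(sc0, seed = 17))
  expect_identical(s0$generations_run, 0L)
})

test_that("frequencies stay in [0,1] on the drift lattice through a split scenario", {
  sc <- wf_scenario(
    num_populations = 2, num_sites = 1e7, num_generations = 60,
    mutation_rate = 1e-7,
    census_size = function(j, t) if (j == 1) 150 else if (t >= 30) 80 else 0,
    migration = function(t) {
      M <- diag(2)
      if (t >= 30) { M[1, 2] <- M[2, 1] <- 0.02; diag(M) <- 0.98 }
      M
    },
    founding_events = founding_event(30, 1, 2),
    selection = -0.01, seed = 23, compact_interval = 7)
  sim <- simulate(sc)
  f <- sim$array$freq
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(abs(f * rep(sim$final_Ne, each = nrow(f)) -
                      round(f * rep(sim$final_Ne, each = nrow(f)))) < 1e-6))
  expect_false(any(rowSums(f) == 0) || any(rowSums(f) == 2))
  ids <- paste(sim$array$origin_generation, sim$array$origin_population,
               sim$array$origin_index)
  expect_false(anyDuplicated(ids) > 0)
  ## fixation log is non-negative with monotone cumulative totals
  expect_true(all(sim$fixation_log$fixed >= 0))
})

test_that("founding copies the source column and the bottleneck drifts it", {
  arr <- mutation_array(matrix(c(0.5, 0.25), 2, 1))
  sc <- wf_scenario(
    num_populations = 2, num_sites = 1, num_generations = 1,
    mutation_rate = 0,
    census_size = function(j, t) if (j == 1) 5e8 else if (t >= 1) 10 else 0,
    founding_events = founding_event(1, 1, 2), seed = 2,
    initial_state = mutation_array(matrix(c(0.5, 0.25, 0, 0), 2, 2)))
  sim <- simulate(sc)
  f <- sim$array$freq
  ## source barely moves (huge Ne); target is on the 1/20 lattice
  expect_lt(max(abs(f[, 1] - c(0.5, 0.25))), 1e-3)
  expect_true(all(round(f[, 2] * 20) == f[, 2] * 20))
})

test_that("mutation trajectories can be recorded and extracted", {
  sc <- neutral_scenario(N = 100, T = 30, muL = 0.5, seed = 9)
  sim <- simulate(sc, record_generations = c(0, 10, 20, 30))
  expect_length(sim$trajectories, 4)
  a0 <- sim$trajectories[["0"]]
  tr <- get_trajectory(sim, a0$origin_generation[1], a0$origin_population[1],
                       a0$origin_index[1])
  expect_true(all(diff(tr$generation) > 0))
  expect_true(all(tr$freq_pop1 >= 0 & tr$freq_pop1 <= 1))
  ## a mutation born mid-run first appears at frequency 1/Ne
  born <- sim$trajectories[["10"]]
  newborn <- born[born$origin_generation == 10, , drop = FALSE]
  if (nrow(newborn)) expect_true(all(newborn$freq_pop1 == 1 / 200))
})

test_that("a neutral equilibrium run stays at equilibrium", {
  ## stationarity: segregating count after 10*Ne generations keeps the
  ## equilibrium mean, averaged over replicate runs
  N <- 50; muL <- 0.2; Ne <- 100
  sc <- neutral_scenario(N = N, T = 10 * Ne, muL = muL, seed = 1)
  d <- equilibrium_density(Ne, muL / 1e6, 1e6, s = 0)
  expected <- sum(d$expected_counts)
  sims <- simulate(sc, nsim = 50, seed = 1200)
  S <- vapply(sims, function(s) nrow(s$array$freq), integer(1))
  se <- sqrt(expected / 50)     # segregating counts are Poisson under the PRF
  expect_lt(abs(mean(S) - expected), 4 * se)
})
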