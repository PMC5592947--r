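test_that("neutral equilibrium density equals 2*mu*L/x on every grid point", {
  for (prm in list(list(Ne = 100, F = 0), list(Ne = 997, F = 0.5),
                   list(Ne = 2000, F = 1))) {
    mu <- 1e-7; L <- 1e7
    d <- equilibrium_density(prm$Ne, mu, L, s = 0, h = 0.3, F = prm$F)
    closed <- 2 * mu * L / d$frequencies
    expect_lt(max(abs(d$expected_counts - closed) / closed), 1e-6)
  }
})

test_that("zero mutation rate gives an empty equilibrium", {
  d <- equilibrium_density(100, 0, 1e6, s = -0.01)
  expect_true(all(d$expected_counts == 0))
  sc <- wf_scenario(num_populations = 1, num_sites = 1e6,
                    num_generations = 5, mutation_rate = 0,
                    census_size = 100, seed = 1)
  expect_identical(n_mutations(init_equilibrium(sc, seed = 1)), 0L)
})

test_that("selection tilts the density in the expected direction", {
  mu <- 1e-6; L <- 1e6
  neu <- equilibrium_density(500, mu, L, s = 0)
  del <- equilibrium_density(500, mu, L, s = -0.01)
  pos <- equilibrium_density(500, mu, L, s = 0.01)
  ## purifying selection depletes, positive selection enriches, high classes
  hi <- 400:499
  expect_true(all(del$expected_counts[hi] < neu$expected_counts[hi]))
  expect_true(all(pos$expected_counts[hi] > neu$expected_counts[hi]))
  expect_true(all(is.finite(del$expected_counts)))
})

test_that("density is invariant under joint rescaling Ne/c, c*s, c*mu", {
  mu <- 1e-6; L <- 1e6; c <- 5
  a <- equilibrium_density(400, mu, L, s = -0.01)
  b <- equilibrium_density(400 / c, mu * c, L, s = -0.01 * c)
  ## per-unit-frequency density Ne*lambda agrees at the coarse grid points
  shared <- seq_len(400 / c - 1)
  da <- 400 * a$expected_counts[shared * c]
  db <- (400 / c) * b$expected_counts[shared]
  expect_lt(max(abs(da - db) / db), 1e-6)
})

test_that("a non-finite integrand is reported with the offending frequency", {
  expect_error(
    equilibrium_density(100, 1e-6, 1e6,
                        s = function(x) ifelse(x > 0.9, NaN, 0)),
    "non-finite at frequency")
  ## strong selection is handled without overflow
  d <- equilibrium_density(2000, 1e-6, 1e6, s = -0.5)
  expect_true(all(is.finite(d$expected_counts)))
  expect_true(all(d$expected_counts >= 0))
})

test_that("equilibrium initialization draws Poisson counts with mean lambda", {
  sc <- wf_scenario(num_populations = 1, num_sites = 1e6,
                    mutation_rate = 5e-7, num_generations = 1,
                    census_size = 100, selection = -0.005, seed = 1)
  d <- equilibrium_density(200, 5e-7, 1e6, s = -0.005)
  lambda_tot <- sum(d$expected_counts)
  R <- 200
  set.seed(99)
  totals <- vapply(seq_len(R), function(i) n_mutations(init_equilibrium(sc)),
                   integer(1))
  se <- sqrt(lambda_tot / R)            # Poisson variance = mean
  expect_lt(abs(mean(totals) - lambda_tot), 3 * se)
  ## counts lie on the lattice and carry generation-0 origin IDs
  a <- init_equilibrium(sc, seed = 7)
  expect_true(all(abs(a$freq * 200 - round(a$freq * 200)) < 1e-9))
  expect_true(all(a$origin_generation == 0))
  expect_false(anyDuplicated(a$origin_index) > 0)
})

test_that("a purifying-selection equilibrium start is stationary under the engine", {
  ## the engine itself is the cross-check of the density's sign and scale:
  ## starting from the computed equilibrium, the segregating count holds its
  ## expectation over many generations of simulation
  ## the density is a diffusion-limit result (first order in s), so the
  ## discrete engine carries an O(1/Ne) excess; at Ne = 200 it is ~3%
  N <- 100; Ne <- 200; s <- -0.02; muL <- 0.3   # Ne*s = -4
  sc <- wf_scenario(num_populations = 1, num_sites = 1e6,
                    num_generations = 2 * Ne, mutation_rate = muL / 1e6,
                    census_size = N, selection = s, seed = 1)
  d <- equilibrium_density(Ne, muL / 1e6, 1e6, s = s)
  expected <- sum(d$expected_counts)
  sims <- simulate(sc, nsim = 50, seed = 500)
  S <- vapply(sims, function(x) nrow(x$array$freq), integer(1))
  expect_lt(abs(mean(S) - expected) / expected, 0.05)
})

test_that("equilibrium initialization is deterministic under a fixed seed", {
  sc <- neutral_scenario(N = 150, muL = 0.2)
  expect_identical(init_equilibrium(sc, seed = 42), init_equilibrium(sc, seed = 42))
})

test_that("equilibrium start is refused when migration is active from the outset", {
  m <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  sc <- wf_scenario(num_populations = 2, num_sites = 1e6,
                    num_generations = 10, mutation_rate = 1e-7,
                    census_size = 100, migration = m, seed = 1)
  expect_error(init_equilibrium(sc), "migration")
  expect_error(simulate(sc), "migration")
})

test_that("density export writes a two-column table", {
  d <- equilibrium_density(50, 1e-6, 1e6)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_density_tsv(d, tf)
  tab <- read.delim(tf)
  expect_identical(names(tab), c("x", "lambda"))
  expect_equal(nrow(tab), 49)
})
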