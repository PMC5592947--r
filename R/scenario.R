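#' Effective number of chromosomes
#'
#' Converts a census size of `N` diploid individuals with inbreeding
#' coefficient `F` into the effective number of chromosomes
#' `Ne = 2N / (1 + F)`, the binomial trial count that governs genetic drift.
#' `F = 0` gives the outbred diploid value `2N`; `F = 1` gives the haploid
#' value `N`; intermediate `F` interpolates between them.
#'
#' `Ne` is rounded to the nearest integer because it is used as a binomial
#' trial count; a population with `N > 0` always has `Ne >= 1`, and an
#' extinct or not-yet-founded population (`N = 0`) has `Ne = 0`.
#'
#' @param N census size in individuals (vectorized, each `>= 0`).
#' @param F inbreeding coefficient in `[0, 1]` (scalar or same length as `N`).
#' @return Integer vector of effective chromosome counts.
#' @examples
#' effective_chromosomes(10000, 0)   # 20000
#' effective_chromosomes(10000, 1)   # 10000
#' effective_chromosomes(100, 0.5)   # 133
#' @export
effective_chromosomes <- function(N, F = 0) {
  if (any(!is.finite(N)) || any(N < 0))
    stop("census size N must be finite and >= 0")
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("inbreeding coefficient F must lie in [0, 1]")
  ne <- as.integer(round(2 * N / (1 + F)))
  ne[N > 0] <- pmax(1L, ne[N > 0])
  ne[N == 0] <- 0L
  ne
}

## Coerce a scalar to a constant parameter function of (j, t), pass functions
## through unchanged.
as_jt_fun <- function(x, name) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    force(x)
    return(function(j, t) x)
  }
  stop(sprintf("'%s' must be a scalar or a function(j, t)", name))
}

as_sel_fun <- function(x) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1) {
    force(x)
    return(function(j, t, freq) x)
  }
  stop("'selection' must be a scalar or a function(j, t, x)")
}

## Migration specification -> function(t) returning a P x P matrix whose
## entry [k, j] is the proportion of population j's offspring pool drawn
## from population k (columns sum to 1; conservative model).
as_mig_fun <- function(m, P) {
  if (is.null(m)) {
    id <- diag(P)
    return(function(t) id)
  }
  if (is.matrix(m)) {
    if (!all(dim(m) == c(P, P)))
      stop("constant migration matrix must be num_populations x num_populations")
    force(m)
    return(function(t) m)
  }
  if (is.function(m)) return(m)
  stop("'migration' must be NULL, a P x P matrix, or a function(t) -> matrix")
}

#' Founding event: a population split
#'
#' At the start of the update producing generation `generation`, the source
#' population's frequency column is copied into the (previously empty) target
#' population; the target's own census size at that generation then governs
#' selection and drift, so a bottleneck at the split is expressed simply by
#' giving the target a small initial size.
#'
#' @param generation offspring generation at which the target is founded.
#' @param source index of the extant source population.
#' @param target index of the newly founded population.
#' @return A `founding_event` object.
#' @export
founding_event <- function(generation, source, target) {
  stopifnot(generation >= 1, source >= 1, target >= 1, source != target)
  structure(list(generation = as.integer(generation),
                 source = as.integer(source),
                 target = as.integer(target)),
            class = "founding_event")
}

#' Define a Wright-Fisher simulation scenario
#'
#' A scenario bundles the full evolutionary model -- demography, mutation,
#' selection, dominance, inbreeding and migration, each allowed to vary over
#' populations and generations -- together with the run controls. Mutations
#' are simulated as independent frequency trajectories (Poisson Random Field
#' assumption: free recombination between sites, no multiple hits), so the
#' number of sites `num_sites` enters only through the Poisson mutation
#' influx `Ne * mu * L` per population per generation.
#'
#' Parameter functions are evaluated at the *offspring* generation's index:
#' the update that produces generation `t` (for `t = 1..num_generations`)
#' uses `N(j, t)`, `mu(j, t)`, and so on. Generation 0 is the initialized
#' state. All parameter functions must be pure (no state, no randomness).
#'
#' @param num_populations number of populations (columns of the mutation
#'   frequency array). Populations may be founded later via `founding_events`;
#'   until founded they must have census size 0 and carry frequency 0.
#' @param num_sites `L`, the number of simulated sites.
#' @param num_generations `T`, generations to simulate beyond generation 0.
#' @param mutation_rate per-site per-chromosome mutation rate; scalar or
#'   `function(j, t)`.
#' @param census_size individuals `N(j, t)`; scalar or `function(j, t)`.
#'   `N = 0` marks a population as not (yet) extant.
#' @param inbreeding coefficient `F(j, t)` in `[0, 1]`; scalar or function.
#' @param dominance coefficient `h(j, t)`; scalar or function. Unrestricted:
#'   values outside `[0, 1]` model over/underdominance.
#' @param selection coefficient `s(j, t, x) > -1`; scalar or
#'   `function(j, t, x)` vectorized over the frequency vector `x`, enabling
#'   frequency-dependent selection.
#' @param migration `NULL` (none), a constant `P x P` matrix, or a
#'   `function(t)` returning the matrix whose `[k, j]` entry is the
#'   proportion of population `j` drawn from population `k`; each column must
#'   sum to 1 (conservative migration).
#' @param founding_events list of [founding_event()] objects.
#' @param compact_interval generations between removals of lost/fixed
#'   mutations. A performance knob: the law of the process does not depend
#'   on it.
#' @param seed default RNG seed used by [simulate.wf_scenario()].
#' @param initial_state `"equilibrium"` (numerical mutation-selection
#'   equilibrium, see [equilibrium_density()]), `"blank"` (empty array), or a
#'   [mutation_array()] from a previous run.
#' @param sampling list of `list(population =, n =)` entries used by
#'   [cli_simulate()] to emit sample spectra.
#' @return An object of class `wf_scenario`.
#' @seealso [simulate.wf_scenario()], [validate_scenario()]
#' @examples
#' sc <- wf_scenario(num_populations = 1, num_sites = 1e7,
#'                   num_generations = 100, mutation_rate = 1e-8,
#'                   census_size = 500, seed = 1)
#' sim <- simulate(sc)
#' summary(sim)
#' @export
wf_scenario <- function(num_populations = 1,
                        num_sites,
                        num_generations,
                        mutation_rate = 0,
                        census_size,
                        inbreeding = 0,
                        dominance = 0.5,
                        selection = 0,
                        migration = NULL,
                        founding_events = list(),
                        compact_interval = 10,
                        seed = NULL,
                        initial_state = "equilibrium",
                        sampling = list()) {
  P <- as.integer(num_populations)
  stopifnot(P >= 1, num_sites >= 1, num_generations >= 0, compact_interval >= 1)
  if (inherits(founding_events, "founding_event"))
    founding_events <- list(founding_events)
  sc <- structure(list(
    num_populations = P,
    num_sites = as.numeric(num_sites),
    num_generations = as.integer(num_generations),
    mutation_rate = as_jt_fun(mutation_rate, "mutation_rate"),
    census_size = as_jt_fun(census_size, "census_size"),
    inbreeding = as_jt_fun(inbreeding, "inbreeding"),
    dominance = as_jt_fun(dominance, "dominance"),
    selection = as_sel_fun(selection),
    migration = as_mig_fun(migration, P),
    founding_events = founding_events,
    compact_interval = as.integer(compact_interval),
    seed = seed,
    initial_state = initial_state,
    sampling = sampling), class = "wf_scenario")
  sc
}

#' @export
print.wf_scenario <- function(x, ...) {
  cat("Wright-Fisher scenario:", x$num_populations, "population(s),",
      format(x$num_sites, big.mark = ","), "sites,",
      x$num_generations, "generations\n")
  cat("  initial state:",
      if (is.character(x$initial_state)) x$initial_state else "stored mutation array",
      "| compact every", x$compact_interval, "generations\n")
  if (length(x$founding_events))
    for (ev in x$founding_events)
      cat(sprintf("  founding event: population %d from %d at generation %d\n",
                  ev$target, ev$source, ev$generation))
  invisible(x)
}

## Evaluate the migration matrix at generation t, restricted to extant
## populations: non-extant populations neither send nor receive migrants.
migration_matrix_at <- function(sc, t, extant) {
  M <- sc$migration(t)
  P <- sc$num_populations
  if (!is.matrix(M) || !all(dim(M) == c(P, P)))
    stop("migration function must return a num_populations x num_populations matrix")
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative migration proportion from population %d into population %d at generation %d (do the rates into population %d sum to more than 1?)",
      bad[1], bad[2], t, bad[2]))
  }
  if (any(!extant)) {
    M[!extant, ] <- 0
    M[, !extant] <- 0
    diag(M)[!extant] <- 1
  }
  cs <- colSums(M)
  bad <- which(abs(cs - 1) > 1e-9)
  if (length(bad))
    stop(sprintf(
      "migration proportions into population %d sum to %.10g (must be 1) at generation %d",
      bad[1], cs[bad[1]], t))
  M
}

#' Validate a scenario against its model invariants
#'
#' Checks, over a sampled grid of generations and frequencies, that census
#' sizes are non-negative with `Ne >= 1` wherever `N > 0`, inbreeding lies in
#' `[0, 1]`, selection satisfies `s > -1` (fitness must stay positive),
#' migration columns are non-negative and sum to 1 over extant populations,
#' and founding events reference an extant source and a target that is empty
#' beforehand. The first violated invariant is reported by name.
#'
#' @param scenario a [wf_scenario()].
#' @param t_grid generations at which to evaluate the parameter functions;
#'   defaults to ~64 points spanning `1..num_generations`.
#' @param x_grid frequencies at which frequency-dependent selection is probed.
#' @return The scenario, invisibly, if valid; otherwise an error.
#' @export
validate_scenario <- function(scenario,
                              t_grid = NULL,
                              x_grid = c(0, 1e-4, 0.1, 0.25, 0.5, 0.75, 0.9, 1)) {
  sc <- scenario
  stopifnot(inherits(sc, "wf_scenario"))
  P <- sc$num_populations
  if (is.null(t_grid)) {
    Tn <- max(1L, sc$num_generations)
    t_grid <- unique(c(1L, as.integer(round(seq(1, Tn, length.out = min(64, Tn))))))
  }
  for (t in t_grid) {
    N <- vapply(seq_len(P), function(j) sc$census_size(j, t), numeric(1))
    if (any(!is.finite(N)) || any(N < 0))
      stop(sprintf("invalid census size at generation %d: N must be finite and >= 0", t))
    F <- vapply(seq_len(P), function(j) sc$inbreeding(j, t), numeric(1))
    if (any(F < 0) || any(F > 1))
      stop(sprintf("inbreeding coefficient outside [0, 1] at generation %d", t))
    mu <- vapply(seq_len(P), function(j) sc$mutation_rate(j, t), numeric(1))
    if (any(mu < 0))
      stop(sprintf("negative mutation rate at generation %d", t))
    ne <- effective_chromosomes(N, F)
    if (any(N > 0 & ne < 1))
      stop(sprintf("Ne < 1 for an extant population at generation %d", t))
    for (j in seq_len(P)) {
      sv <- sc$selection(j, t, x_grid)
      if (any(!is.finite(sv)) || any(sv <= -1))
        stop(sprintf(
          "selection coefficient s <= -1 (negative fitness) for population %d at generation %d",
          j, t))
    }
    migration_matrix_at(sc, t, extant = N > 0)
  }
  for (ev in sc$founding_events) {
    if (ev$source > P || ev$target > P)
      stop("founding event references a population index beyond num_populations")
    if (sc$census_size(ev$source, ev$generation) <= 0)
      stop(sprintf("founding event at generation %d: source population %d is not extant",
                   ev$generation, ev$source))
    if (ev$generation > 1 && sc$census_size(ev$target, ev$generation - 1) != 0)
      stop(sprintf("founding event at generation %d: target population %d already extant",
                   ev$generation, ev$target))
    if (sc$census_size(ev$target, ev$generation) <= 0)
      stop(sprintf("founding event at generation %d: target population %d has N = 0 at founding",
                   ev$generation, ev$target))
  }
  invisible(sc)
}

#' Piecewise demographic (or other per-generation) parameter functions
#'
#' Build a `function(t)` from epoch segments, for use inside `function(j, t)`
#' parameter functions or via [per_population()]. Outside all segments the
#' function returns `default` (0 for a not-yet-founded population).
#'
#' `epoch_constant(value, from, to)` holds `value` on `from <= t <= to`;
#' `epoch_exponential(from_value, to_value, from, to)` interpolates
#' geometrically, reaching `to_value` at `t = to`.
#'
#' @param ... epoch segments.
#' @param default value outside every segment.
#' @return `piecewise()` returns a `function(t)`; the `epoch_*` helpers
#'   return segment descriptors.
#' @examples
#' N <- piecewise(epoch_constant(1000, 0, 99),
#'                epoch_exponential(1000, 5000, 100, 200))
#' N(50); N(200)
#' @export
piecewise <- function(..., default = 0) {
  segs <- list(...)
  force(default)
  function(t) {
    for (sg in segs) {
      if (t >= sg$from && t <= sg$to) return(sg$eval(t))
    }
    default
  }
}

#' @rdname piecewise
#' @param value constant value of the segment.
#' @param from,to first and last generation of the segment (inclusive).
#' @export
epoch_constant <- function(value, from, to) {
  force(value)
  list(from = from, to = to, eval = function(t) value)
}

#' @rdname piecewise
#' @param from_value,to_value values at the start and end of the segment.
#' @export
epoch_exponential <- function(from_value, to_value, from, to) {
  stopifnot(from_value > 0, to_value > 0, to > from)
  r <- log(to_value / from_value) / (to - from)
  list(from = from, to = to,
       eval = function(t) from_value * exp(r * (t - from)))
}

#' @rdname piecewise
#' @param funs list of `function(t)`, one per population.
#' @export
per_population <- function(funs) {
  force(funs)
  function(j, t) funs[[j]](t)
}
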