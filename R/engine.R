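## Generation cycle: x_t -> migration -> selection -> drift -> x_{t+1},
## then Poisson mutation influx, with periodic compaction of lost/fixed rows.

#' Conservative migration step
#'
#' New frequency in population `j` is the average of the current frequencies
#' in all populations weighted by the immigrant proportions into `j`:
#' `x_mig[, j] = sum_k m[k, j] * x[, k]`. Columns of `m` must sum to 1
#' (each offspring pool is fully accounted for), so frequencies stay in
#' `[0, 1]` by convexity.
#'
#' @param freq numeric matrix (mutations x populations) or a vector for a
#'   single population.
#' @param m migration matrix; entry `[k, j]` is the proportion of population
#'   `j` drawn from population `k`.
#' @return Matrix of post-migration frequencies.
#' @export
migrate_freqs <- function(freq, m) {
  if (!is.matrix(freq)) freq <- matrix(freq, ncol = 1)
  if (any(m < 0)) stop("migration proportions must be >= 0")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9))
    stop(sprintf("migration proportions into population %d sum to %.10g, not 1",
                 which.max(abs(cs - 1)), cs[which.max(abs(cs - 1))]))
  freq %*% m
}

#' Expected post-selection frequency
#'
#' Deterministic viability-selection update for a mutation at frequency `x`
#' with selection coefficient `s`, dominance `h` and inbreeding `F`:
#' \deqn{x' = \frac{x^2 s + x(1-x)s(F + h - hF) + x}
#'                 {x^2 s + 2x(1-x)s(F + 2h - 2hF)/2 + 1}.}
#' At `F = 0` this is the standard diploid recursion
#' `x' = (x^2(1+s) + x(1-x)(1+hs)) / wbar`; at `F = 1` the haploid
#' `x' = x(1+s)/(1+sx)`. Neutral (`s = 0`) is the identity, and 0 and 1 are
#' fixed points (absorbing boundaries).
#'
#' @param x frequencies in `[0, 1]` (vectorized).
#' @param s selection coefficient(s) `> -1`; length 1 or `length(x)`.
#' @param h dominance coefficient.
#' @param F inbreeding coefficient in `[0, 1]`.
#' @return Expected offspring frequencies, same length as `x`.
#' @examples
#' select_freq(0.5, s = 0.1, h = 0.5, F = 0)  # 0.5375/1.05
#' @export
select_freq <- function(x, s, h = 0.5, F = 0) {
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]")
  if (any(s <= -1)) stop("selection coefficient must be > -1")
  .select_expected_cpp(as.numeric(x), as.numeric(s), h, F)
}

#' Binomial drift step
#'
#' Resamples each frequency as `k/Ne` with `k ~ Binomial(Ne, x)`: mean `x`,
#' variance `x(1-x)/Ne` on the frequency scale. Output lies on the lattice
#' `{0, 1/Ne, ..., 1}`; 0 and 1 are absorbing.
#'
#' @param x expected offspring frequencies in `[0, 1]`.
#' @param Ne effective chromosome count (binomial trial count, `>= 1`).
#' @return Realized frequencies.
#' @export
drift_freq <- function(x, Ne) {
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]")
  stopifnot(Ne >= 1)
  stats::rbinom(length(x), Ne, x) / Ne
}

#' Append new mutations for one generation
#'
#' For each extant population `j`, draws the number of new mutations from
#' `Poisson(Ne(j,t) * mu(j,t) * L)` (the Poisson Random Field influx) and
#' appends one row per mutation at starting frequency `1/Ne(j,t)` in
#' population `j` and 0 elsewhere, with origin ID `(t, j, running index)`.
#'
#' @param scenario a [wf_scenario()].
#' @param t offspring generation index (`>= 1`).
#' @param array a [mutation_array()].
#' @return The array with appended rows.
#' @export
add_new_mutations <- function(scenario, t, array) {
  sc <- scenario
  stopifnot(t >= 1)
  P <- sc$num_populations
  blocks <- list(array$freq)
  og <- list(array$origin_generation)
  op <- list(array$origin_population)
  oi <- list(array$origin_index)
  for (j in seq_len(P)) {
    N <- sc$census_size(j, t)
    if (N <= 0) next
    ne <- effective_chromosomes(N, sc$inbreeding(j, t))
    lam <- ne * sc$mutation_rate(j, t) * sc$num_sites
    nj <- stats::rpois(1, lam)
    if (nj == 0) next
    fr <- matrix(0, nj, P)
    fr[, j] <- 1 / ne
    blocks[[length(blocks) + 1]] <- fr
    og[[length(og) + 1]] <- rep.int(as.integer(t), nj)
    op[[length(op) + 1]] <- rep.int(j, nj)
    oi[[length(oi) + 1]] <- seq_len(nj)
  }
  mutation_array(do.call(rbind, blocks), unlist(og), unlist(op), unlist(oi))
}

#' Remove lost and fixed mutations
#'
#' Drops rows at frequency 0 in every extant population (lost) and rows at
#' frequency 1 in every extant population (fixed -- these contribute to
#' divergence and are counted in the fixation log). A mutation fixed in one
#' population but still segregating in another is retained. Relative order
#' of surviving rows is preserved.
#'
#' @param array a [mutation_array()].
#' @param extant logical vector marking extant populations (default: all).
#' @return List with elements `array` (compacted), `n_lost`, `n_fixed`.
#' @export
compact_mutations <- function(array, extant = rep(TRUE, ncol(array$freq))) {
  f <- array$freq[, extant, drop = FALSE]
  ne <- ncol(f)
  if (ne == 0 || nrow(f) == 0)
    return(list(array = array, n_lost = 0L, n_fixed = 0L))
  rs <- rowSums(f)
  lost <- rs == 0
  fixed <- rs == ne            # all frequencies <= 1, so sum = ne iff all = 1
  keep <- !(lost | fixed)
  out <- mutation_array(array$freq[keep, , drop = FALSE],
                        array$origin_generation[keep],
                        array$origin_population[keep],
                        array$origin_index[keep])
  list(array = out, n_lost = sum(lost), n_fixed = sum(fixed))
}

## ---- internal engine state: preallocated frequency block -----------------

## The state buffer (capacity x P frequency matrix + origin-ID vectors,
## first n rows active) is mutated in place by compiled primitives, so a
## generation update copies no R objects proportional to the array size.

new_state <- function(array, P) {
  st <- new.env(parent = emptyenv())
  n <- nrow(array$freq)
  cap <- max(1024L, as.integer(ceiling(n * 1.3)))
  st$freq <- matrix(0, cap, P)
  if (n > 0) st$freq[seq_len(n), ] <- array$freq
  st$og <- integer(cap); st$op <- integer(cap); st$oi <- integer(cap)
  if (n > 0) {
    st$og[seq_len(n)] <- array$origin_generation
    st$op[seq_len(n)] <- array$origin_population
    st$oi[seq_len(n)] <- array$origin_index
  }
  st$n <- n
  st$P <- P
  st
}

state_reserve <- function(st, extra) {
  need <- st$n + extra
  cap <- nrow(st$freq)
  if (need <= cap) return(invisible(st))
  newcap <- max(need, 2L * cap)
  fr <- matrix(0, newcap, st$P)
  idx <- seq_len(st$n)
  fr[idx, ] <- st$freq[idx, , drop = FALSE]
  st$freq <- fr
  for (nm in c("og", "op", "oi")) {
    v <- vector("integer", newcap)
    v[idx] <- st[[nm]][idx]
    st[[nm]] <- v
  }
  invisible(st)
}

state_to_array <- function(st) {
  idx <- seq_len(st$n)
  mutation_array(st$freq[idx, , drop = FALSE],
                 st$og[idx], st$op[idx], st$oi[idx])
}

state_compact <- function(st, extant) {
  if (st$n == 0) return(0L)
  res <- .compact_cpp(st$freq, st$og, st$op, st$oi, st$n, as.logical(extant))
  st$n <- res[1]
  res[2]
}

## One generation update on the internal state (offspring generation t).
state_step <- function(sc, t, st) {
  P <- st$P
  for (ev in sc$founding_events)
    if (ev$generation == t && st$n > 0)
      .copy_column_cpp(st$freq, st$n, ev$source, ev$target)
  N <- vapply(seq_len(P), function(j) sc$census_size(j, t), numeric(1))
  extant <- N > 0
  Fv <- vapply(seq_len(P), function(j) sc$inbreeding(j, t), numeric(1))
  Ne <- effective_chromosomes(N, Fv)
  if (st$n > 0) {
    M <- migration_matrix_at(sc, t, extant)
    offdiag <- any(M[row(M) != col(M)] > 0)
    ## synchronous update: all post-migration frequencies are computed from
    ## the generation-t block before any column is overwritten
    Xm <- if (offdiag) .migrate_block_cpp(st$freq, st$n, M) else NULL
    for (j in which(extant)) {
      xj <- if (offdiag) Xm[, j] else .active_column_cpp(st$freq, st$n, j)
      sj <- sc$selection(j, t, xj)
      .select_drift_inplace_cpp(st$freq, st$n, j, xj, as.numeric(sj),
                                sc$dominance(j, t), Fv[j], Ne[j])
    }
  }
  ## Poisson mutation influx, after drift: new mutations first experience
  ## selection and drift in the following generation.
  for (j in which(extant)) {
    lam <- Ne[j] * sc$mutation_rate(j, t) * sc$num_sites
    if (lam <= 0) next
    nj <- stats::rpois(1, lam)
    if (nj == 0) next
    state_reserve(st, nj)
    .append_rows_cpp(st$freq, st$og, st$op, st$oi, st$n, nj, j,
                     1 / Ne[j], as.integer(t))
    st$n <- st$n + nj
  }
  extant
}

#' Advance a mutation array by one generation
#'
#' Applies any founding event scheduled at `t`, then the synchronous
#' migration -> selection -> drift update column-by-column over the whole
#' mutation block, then the Poisson influx of new mutations. Exposed mainly
#' for testing and for stepping stored states; [simulate.wf_scenario()] runs
#' the full loop with compaction.
#'
#' @param scenario a [wf_scenario()].
#' @param t offspring generation index (`>= 1`).
#' @param array a [mutation_array()].
#' @param seed optional seed (otherwise the current RNG state is used).
#' @return The updated [mutation_array()].
#' @export
step_generation <- function(scenario, t, array, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- new_state(array, scenario$num_populations)
  state_step(scenario, t, st)
  state_to_array(st)
}

#' Run a Wright-Fisher forward simulation
#'
#' Initializes the mutation array per `scenario$initial_state`, advances it
#' `num_generations` generations, removing lost and globally fixed mutations
#' every `compact_interval` generations and once more before returning.
#' Fixed-mutation removals are logged per generation and population.
#'
#' @param object a [wf_scenario()].
#' @param nsim number of independent replicate runs; replicate `i` uses seed
#'   `seed + i - 1`. For `nsim > 1` a list of `wf_sim` objects is returned.
#' @param seed RNG seed (defaults to `scenario$seed`).
#' @param ... unused.
#' @param compact_interval override of the scenario's compaction interval.
#' @param record_generations integer vector of generations (0 = initial
#'   state) at which to snapshot all mutation frequencies with their origin
#'   IDs, enabling per-mutation frequency trajectories (see
#'   [get_trajectory()]).
#' @param stop_if_absorbed stop early once the array is empty; intended for
#'   replicate-chain studies with `mutation_rate = 0` where nothing can
#'   re-enter the array.
#' @param verbose print progress every 100 generations.
#' @return An object of class `wf_sim`: list with the final
#'   [mutation_array()], `fixation_log` (data.frame `generation`,
#'   `population`, `fixed`), `final_Ne`, `extant`, `trajectories`, the
#'   scenario and the seed used.
#' @examples
#' sc <- wf_scenario(num_populations = 1, num_sites = 1e6,
#'                   num_generations = 200, mutation_rate = 1e-7,
#'                   census_size = 200, seed = 7)
#' sim <- simulate(sc)
#' sim
#' @export
simulate.wf_scenario <- function(object, nsim = 1, seed = NULL, ...,
                                 compact_interval = NULL,
                                 record_generations = NULL,
                                 stop_if_absorbed = FALSE,
                                 verbose = FALSE) {
  sc <- object
  if (nsim > 1) {
    base_seed <- if (!is.null(seed)) seed else sc$seed
    if (is.null(base_seed)) stop("a seed is required for replicate runs")
    return(lapply(seq_len(nsim) - 1L, function(k)
      simulate.wf_scenario(sc, nsim = 1, seed = base_seed + k, ...,
                           compact_interval = compact_interval,
                           record_generations = record_generations,
                           stop_if_absorbed = stop_if_absorbed)))
  }
  validate_scenario(sc)
  if (is.null(seed)) seed <- sc$seed
  if (!is.null(seed)) set.seed(seed)
  ci <- if (!is.null(compact_interval)) as.integer(compact_interval)
        else sc$compact_interval
  P <- sc$num_populations

  init <- sc$initial_state
  array0 <- if (inherits(init, "mutation_array")) {
    if (ncol(init$freq) != P)
      stop("stored initial array has a different number of populations")
    init
  } else if (identical(init, "blank")) {
    mutation_array(matrix(numeric(0), 0, P))
  } else if (identical(init, "equilibrium")) {
    init_equilibrium(sc)
  } else stop("initial_state must be 'blank', 'equilibrium', or a mutation_array")

  st <- new_state(array0, P)
  traj <- list()
  snap <- function(t) {
    a <- state_to_array(st)
    df <- as.data.frame(a)
    df <- cbind(data.frame(generation = t), df)
    traj[[as.character(t)]] <<- df
  }
  if (0 %in% record_generations) snap(0)

  Tn <- sc$num_generations
  fix_gen <- integer(0); fix_cnt <- integer(0); fix_pop <- integer(0)
  extant <- vapply(seq_len(P), function(j) sc$census_size(j, 0), numeric(1)) > 0
  t <- 0L
  while (t < Tn) {
    t <- t + 1L
    extant <- state_step(sc, t, st)
    if (t %% ci == 0L) {
      nfix <- state_compact(st, extant)
      if (nfix > 0) {
        ex <- which(extant)
        fix_gen <- c(fix_gen, rep.int(t, length(ex)))
        fix_pop <- c(fix_pop, ex)
        fix_cnt <- c(fix_cnt, rep.int(nfix, length(ex)))
      }
    }
    if (t %in% record_generations) snap(t)
    if (verbose && t %% 100 == 0)
      message(sprintf("generation %d / %d: %d mutations in array", t, Tn, st$n))
    if (stop_if_absorbed && st$n == 0L) break
  }
  nfix <- state_compact(st, extant)   # final compaction, also covers T = 0
  if (nfix > 0) {
    ex <- which(extant)
    fix_gen <- c(fix_gen, rep.int(t, length(ex)))
    fix_pop <- c(fix_pop, ex)
    fix_cnt <- c(fix_cnt, rep.int(nfix, length(ex)))
  }
  N_end <- vapply(seq_len(P), function(j) sc$census_size(j, max(t, 0)), numeric(1))
  F_end <- vapply(seq_len(P), function(j) sc$inbreeding(j, max(t, 0)), numeric(1))
  structure(list(
    array = state_to_array(st),
    fixation_log = data.frame(generation = fix_gen, population = fix_pop,
                              fixed = fix_cnt),
    final_Ne = effective_chromosomes(N_end, F_end),
    extant = N_end > 0,
    trajectories = traj,
    generations_run = t,
    scenario = sc,
    seed = seed), class = "wf_sim")
}

#' Total fixations recorded in a run
#' @param sim a `wf_sim` object.
#' @param population population index (fixation removal is global across
#'   extant populations, so counts agree across them; default 1).
#' @return Number of mutations removed as fixed.
#' @export
n_fixed <- function(sim, population = 1) {
  fl <- sim$fixation_log
  if (nrow(fl) == 0) return(0L)
  keep <- fl$population == population
  if (!any(keep)) keep <- !duplicated(fl$generation)
  sum(fl$fixed[keep])
}

#' Frequency trajectory of one mutation
#'
#' Extracts the recorded frequencies of the mutation identified by its
#' origin triple from the snapshots taken at `record_generations`.
#'
#' @param sim a `wf_sim` run with `record_generations` set.
#' @param origin_generation,origin_population,origin_index the mutation ID.
#' @return data.frame with columns `generation` and one frequency column per
#'   population, rows in increasing generation order (absent rows mean the
#'   mutation was not yet born or already removed).
#' @export
get_trajectory <- function(sim, origin_generation, origin_population,
                           origin_index) {
  if (!length(sim$trajectories))
    stop("run was simulated without record_generations")
  out <- lapply(sim$trajectories, function(df) {
    df[df$origin_generation == origin_generation &
       df$origin_population == origin_population &
       df$origin_index == origin_index, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$generation),
      c("generation", grep("^freq_pop", names(out), value = TRUE)),
      drop = FALSE]
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("Wright-Fisher forward simulation:", x$generations_run, "generations,",
      ncol(x$array$freq), "population(s)\n")
  cat("  segregating mutations in final array:",
      format(nrow(x$array$freq), big.mark = ","), "\n")
  cat("  mutations removed as fixed:",
      format(n_fixed(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
summary.wf_sim <- function(object, ...) {
  a <- object$array
  seg <- if (nrow(a$freq)) colSums(a$freq > 0 & a$freq < 1) else
    numeric(ncol(a$freq))
  out <- list(generations = object$generations_run,
              total_mutations = nrow(a$freq),
              segregating_per_population = seg,
              fixed = n_fixed(object),
              final_Ne = object$final_Ne,
              extant = object$extant)
  class(out) <- "summary.wf_sim"
  out
}

#' @export
print.summary.wf_sim <- function(x, ...) {
  cat("Generations simulated:", x$generations, "\n")
  cat("Mutations in final array:", format(x$total_mutations, big.mark = ","), "\n")
  cat("Segregating per population:",
      paste(format(x$segregating_per_population, big.mark = ","), collapse = ", "), "\n")
  cat("Removed as fixed (divergence):", format(x$fixed, big.mark = ","), "\n")
  cat("Final Ne (chromosomes):", paste(x$final_Ne, collapse = ", "), "\n")
  invisible(x)
}

#' Plot the population site frequency spectrum of a run
#' @param x a `wf_sim` object.
#' @param population population index.
#' @param ... passed to [plot.wf_sfs()].
#' @return The [population_sfs()] object, invisibly.
#' @export
plot.wf_sim <- function(x, population = 1, ...) {
  sfs <- population_sfs(x, population)
  plot(sfs, ...)
  invisible(sfs)
}
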