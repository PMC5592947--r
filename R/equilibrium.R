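#' Expected mutation-frequency density at mutation-selection equilibrium
#'
#' Computes, for every frequency class `x = i/Ne` (`i = 1..Ne-1`), the
#' expected number of segregating mutations at that frequency when mutation
#' influx, selection, dominance, inbreeding and drift balance:
#'
#' \deqn{\lambda(x) = \frac{2\mu L}{x(1-x)\,G(x)}
#'   \frac{\int_x^1 G(y)\,dy}{\int_0^1 G(y)\,dy},
#'   \quad G(y) = e^{-N_e s(y)\, y \{(2h+(1-2h)y)(1-F)+2F\}}.}
#'
#' The exponent of `G` is the integrated drift-to-variance ratio of the
#' simulator's own update: to first order in `s` the per-generation expected
#' change is `M(x) = s x(1-x) [(F+h-hF) + x(1-2h)(1-F)]` and the drift
#' variance is `V(x) = x(1-x)/Ne`, and `int_0^x 2M/V dy` equals
#' `Ne s x {(2h+(1-2h)x)(1-F)+2F}`, so this is the standard diffusion
#' sojourn density for the model. In the neutral limit (`s = 0`) it reduces
#' exactly to `2*mu*L/x`, the classical `theta/i` site-frequency expectation
#' per class (`lambda(i/Ne) = 2*Ne*mu*L/i`); purifying selection (`s < 0`)
#' depletes the middle and high frequency classes, positive selection
#' enriches them.
#'
#' The two integrals are evaluated by a composite trapezoid rule on a uniform
#' lattice aligned with the frequency classes (grid size
#' `Ne * ceiling(4096/Ne)` intervals), with one cached cumulative pass shared
#' by all upper limits, so the computation is deterministic and O(grid);
#' the exponentials are shift-stabilized and combined in log space, so
#' strong selection does not overflow.
#'
#' @param Ne effective number of chromosomes (`>= 2`).
#' @param mu per-site per-chromosome mutation rate (`>= 0`).
#' @param L number of sites (`>= 1`).
#' @param s selection coefficient: scalar, or a function of frequency
#'   (vectorized) for frequency-dependent selection.
#' @param h dominance coefficient.
#' @param F inbreeding coefficient in `[0, 1]`.
#' @return An object of class `wf_eq_density`: list with `frequencies`
#'   (`i/Ne`), `expected_counts` (`lambda` at each class), and the inputs.
#' @examples
#' d <- equilibrium_density(Ne = 100, mu = 1e-4, L = 1e4, s = 0)
#' all.equal(d$expected_counts[50], 2 * 1e-4 * 1e4 / 0.5)
#' @export
equilibrium_density <- function(Ne, mu, L, s = 0, h = 0.5, F = 0) {
  stopifnot(Ne >= 2, mu >= 0, L >= 1)
  Ne <- as.integer(round(Ne))
  sfun <- if (is.function(s)) s else function(x) rep_len(s, length(x))
  step <- max(1L, as.integer(ceiling(4096 / Ne)))
  M <- Ne * step                      # grid intervals; class i sits at node i*step
  y <- seq(0, 1, length.out = M + 1)
  wt <- (2 * h + (1 - 2 * h) * y) * (1 - F) + 2 * F
  expo <- -Ne * sfun(y) * y * wt          # log G(y)
  if (any(!is.finite(expo))) {
    bad <- y[which(!is.finite(expo))[1]]
    stop(sprintf("equilibrium integrand is non-finite at frequency x = %g", bad))
  }
  ## shifted G keeps the integrals in range; the shift cancels in the ratio
  g <- exp(expo - max(expo))
  ## cumulative trapezoid: cum[k+1] = integral_0^{y_k} of the shifted G
  cum <- c(0, cumsum((g[-1] + g[-(M + 1)]) / (2 * M)))
  total <- cum[M + 1]
  i <- seq_len(Ne - 1)
  x <- i / Ne
  node <- i * step + 1L
  ## log lambda = log(2 mu L / (x(1-x))) - log G(x) + log tail - log total
  lam <- if (mu == 0) numeric(Ne - 1) else
    2 * mu * L / (x * (1 - x)) *
      exp(-expo[node] + log(pmax(total - cum[node], 0)) - log(total))
  structure(list(frequencies = x, expected_counts = lam,
                 Ne = Ne, mu = mu, L = L, h = h, F = F),
            class = "wf_eq_density")
}

#' @export
print.wf_eq_density <- function(x, ...) {
  cat("Equilibrium mutation-frequency density: Ne =", x$Ne,
      "chromosomes,", length(x$frequencies), "classes\n")
  cat("  expected segregating mutations:",
      format(sum(x$expected_counts), big.mark = ","), "\n")
  invisible(x)
}

#' Write an equilibrium density as two-column TSV
#' @param density a [equilibrium_density()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(density, path) {
  stopifnot(inherits(density, "wf_eq_density"))
  utils::write.table(
    data.frame(x = density$frequencies, lambda = density$expected_counts),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Initialize a mutation array at mutation-selection equilibrium
#'
#' For each extant population the per-class expected counts from
#' [equilibrium_density()] (evaluated with that population's parameters at
#' generation 0) are realized as independent Poisson draws -- the count of
#' mutations placed at frequency `i/Ne` is `Poisson(lambda(i/Ne))`, sampled
#' by R's inverse-CDF Poisson generator. Mutations receive origin generation
#' 0 and a running index within their population.
#'
#' The routine covers single populations and multiple isolated populations;
#' scenarios with migration active at the first update have no product-form
#' equilibrium and must instead be started from a burn-in (`"blank"` start or
#' a stored array).
#'
#' @param scenario a [wf_scenario()].
#' @param seed optional seed; when `NULL` the current RNG state is used
#'   (as inside [simulate.wf_scenario()]).
#' @return A [mutation_array()].
#' @export
init_equilibrium <- function(scenario, seed = NULL) {
  sc <- scenario
  stopifnot(inherits(sc, "wf_scenario"))
  if (!is.null(seed)) set.seed(seed)
  P <- sc$num_populations
  N0 <- vapply(seq_len(P), function(j) sc$census_size(j, 0), numeric(1))
  extant <- N0 > 0
  if (sum(extant) > 1) {
    M <- migration_matrix_at(sc, 1, extant)
    offdiag <- M; diag(offdiag) <- 0
    if (any(offdiag > 0))
      stop(paste("equilibrium initialization does not support migration between",
                 "multiple populations; start from a burn-in instead"))
  }
  freqs <- list(); og <- list(); op <- list(); oi <- list()
  for (j in which(extant)) {
    Fj <- sc$inbreeding(j, 0)
    ne <- effective_chromosomes(N0[j], Fj)
    if (ne < 2) stop("equilibrium initialization needs Ne >= 2")
    d <- equilibrium_density(ne, sc$mutation_rate(j, 0), sc$num_sites,
                             s = function(x) sc$selection(j, 0, x),
                             h = sc$dominance(j, 0), F = Fj)
    counts <- stats::rpois(ne - 1, d$expected_counts)
    ntot <- sum(counts)
    if (ntot == 0) next
    fr <- matrix(0, ntot, P)
    fr[, j] <- rep.int(d$frequencies, counts)
    freqs[[length(freqs) + 1]] <- fr
    og[[length(og) + 1]] <- integer(ntot)
    op[[length(op) + 1]] <- rep.int(j, ntot)
    oi[[length(oi) + 1]] <- seq_len(ntot)
  }
  if (!length(freqs))
    return(mutation_array(matrix(numeric(0), 0, P)))
  mutation_array(do.call(rbind, freqs),
                 unlist(og), unlist(op), unlist(oi))
}
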