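## Site frequency spectra: population (lattice) and sample (binomially
## subsampled) histograms, with segregating-site normalization.

new_sfs <- function(counts, n, type, population, num_segregating = sum(counts)) {
  structure(list(counts = as.numeric(counts),
                 sample_size = as.integer(n),
                 type = type,
                 population = as.integer(population),
                 num_segregating = num_segregating,
                 normalized = NULL),
            class = "wf_sfs")
}

#' Population site frequency spectrum
#'
#' Bins the mutations of one population by their frequency class `i/Ne`
#' (`i = 1..Ne-1`); classes 0 and `Ne` (lost/fixed) are excluded. The
#' frequencies must lie on the `1/Ne` lattice, which holds for any array
#' that has gone through at least one drift update with that `Ne`.
#'
#' @param x a `wf_sim` object, or a [mutation_array()] (then `Ne` is
#'   required).
#' @param population population index.
#' @param Ne effective chromosome count defining the lattice; defaults to
#'   the final `Ne` of the run when `x` is a `wf_sim`.
#' @return An object of class `wf_sfs` with per-class `counts`,
#'   `sample_size = Ne` and `num_segregating`.
#' @export
population_sfs <- function(x, population = 1, Ne = NULL) {
  if (inherits(x, "wf_sim")) {
    if (!x$extant[population]) stop("population is not extant at the end of the run")
    if (is.null(Ne)) Ne <- x$final_Ne[population]
    array <- x$array
  } else array <- x
  stopifnot(inherits(array, "mutation_array"))
  if (is.null(Ne)) stop("Ne is required when binning a bare mutation array")
  if (population > ncol(array$freq)) stop("no such population")
  f <- array$freq[, population]
  k <- round(f * Ne)
  if (length(k) && max(abs(f * Ne - k)) > 1e-6)
    stop("frequencies do not lie on the i/Ne lattice for the given Ne")
  counts <- tabulate(k[k >= 1 & k <= Ne - 1], nbins = Ne - 1)
  new_sfs(counts, Ne, "population", population)
}

#' Sample site frequency spectrum
#'
#' Draws, for every mutation at population frequency `x`, a derived-allele
#' count `k ~ Binomial(n, x)` (sampling `n` chromosomes with replacement,
#' appropriate for `n` much smaller than the population) and accumulates the
#' counts with `0 < k < n`; monomorphic outcomes are not segregating in the
#' sample and are excluded, as is standard for spectra normalized by
#' segregating sites. Set `replace = FALSE` for hypergeometric
#' (without-replacement) sampling from the `Ne` chromosomes.
#'
#' @param x a `wf_sim` or [mutation_array()].
#' @param population population index.
#' @param n number of sampled chromosomes (`>= 2`).
#' @param seed optional RNG seed.
#' @param replace binomial (`TRUE`, default) or hypergeometric sampling;
#'   the latter requires `Ne`.
#' @param Ne population chromosome count (only for `replace = FALSE`;
#'   defaults to the run's final `Ne`).
#' @return A `wf_sfs` with classes `1..n-1`.
#' @export
sample_sfs <- function(x, population = 1, n, seed = NULL,
                       replace = TRUE, Ne = NULL) {
  stopifnot(n >= 2)
  if (inherits(x, "wf_sim")) {
    if (is.null(Ne)) Ne <- x$final_Ne[population]
    array <- x$array
  } else array <- x
  stopifnot(inherits(array, "mutation_array"))
  if (!is.null(seed)) set.seed(seed)
  f <- array$freq[, population]
  k <- if (replace) {
    stats::rbinom(length(f), n, f)
  } else {
    if (is.null(Ne)) stop("Ne is required for without-replacement sampling")
    stats::rhyper(length(f), round(f * Ne), Ne - round(f * Ne), n)
  }
  counts <- tabulate(k[k >= 1 & k <= n - 1], nbins = n - 1)
  new_sfs(counts, n, "sample", population)
}

#' Normalize a spectrum by its number of segregating sites
#'
#' Sets the `normalized` field to `counts / num_segregating`, which sums to
#' one; idempotent, and invariant to scaling all counts by a positive
#' constant.
#'
#' @param sfs a `wf_sfs`.
#' @return The spectrum with `normalized` filled in.
#' @export
normalize_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "wf_sfs"))
  if (sfs$num_segregating <= 0)
    stop("cannot normalize a spectrum with zero segregating sites")
  sfs$normalized <- sfs$counts / sfs$num_segregating
  sfs
}

#' @export
print.wf_sfs <- function(x, ...) {
  cat(sprintf("%s site frequency spectrum, population %d\n",
              if (x$type == "sample") "Sample" else "Population", x$population))
  cat("  classes: 1 ..", length(x$counts),
      if (x$type == "sample") sprintf(" (n = %d chromosomes)", x$sample_size)
      else sprintf(" (Ne = %d chromosomes)", x$sample_size), "\n")
  cat("  segregating sites:", format(x$num_segregating, big.mark = ","), "\n")
  if (!is.null(x$normalized)) cat("  normalized: yes\n")
  invisible(x)
}

#' @export
as.data.frame.wf_sfs <- function(x, ...) {
  df <- data.frame(class = seq_along(x$counts), count = x$counts)
  if (!is.null(x$normalized)) df$normalized <- x$normalized
  df
}

#' Plot a site frequency spectrum
#' @param x a `wf_sfs`.
#' @param log plot counts on a log y-axis.
#' @param max_class truncate the x-axis (useful for large spectra).
#' @param ... passed to [graphics::plot()].
#' @export
plot.wf_sfs <- function(x, log = TRUE, max_class = length(x$counts), ...) {
  i <- seq_len(min(max_class, length(x$counts)))
  y <- if (!is.null(x$normalized)) x$normalized[i] else x$counts[i]
  graphics::plot(i, y, type = "h", xlab = "derived-allele count class",
                 ylab = if (!is.null(x$normalized)) "proportion of segregating sites"
                        else "mutations",
                 log = if (log && all(y[y > 0] > 0)) "y" else "", ...)
  invisible(x)
}

#' Binomial projection of a population spectrum to sample size n
#'
#' Expected sample spectrum under binomial subsampling:
#' `E[counts_n[k]] = sum_i pop_counts[i] * C(n,k) (i/Ne)^k (1-i/Ne)^(n-k)`.
#' Used as the analytic counterpart of [sample_sfs()].
#'
#' @param sfs a population `wf_sfs`.
#' @param n target sample size.
#' @return Numeric vector of expected counts for classes `1..n-1`.
#' @export
project_sfs <- function(sfs, n) {
  stopifnot(inherits(sfs, "wf_sfs"), sfs$type == "population", n >= 2)
  Ne <- sfs$sample_size
  xs <- seq_len(Ne - 1) / Ne
  keep <- sfs$counts > 0
  vapply(seq_len(n - 1), function(k)
    sum(sfs$counts[keep] * stats::dbinom(k, n, xs[keep])), numeric(1))
}

#' Write a spectrum as two-column TSV
#' @param sfs a `wf_sfs`.
#' @param path output file.
#' @param digest optional provenance digest written as a header comment.
#' @return `path`, invisibly.
#' @export
write_sfs_tsv <- function(sfs, path, digest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# manifest_digest: ", digest), con)
  df <- as.data.frame(sfs)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spectrum in dadi's frequency-spectrum text format
#'
#' Single-population unfolded format readable by diffusion-based SFS tools:
#' a header line `"{n+1} unfolded"`, one line of `n+1` space-separated
#' values for derived-allele counts `0..n` (the untracked monomorphic
#' classes are written as 0), and a mask line flagging the two monomorphic
#' corner classes.
#'
#' @param sfs a `wf_sfs`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sfs_dadi <- function(sfs, path) {
  n <- sfs$sample_size
  full <- c(0, sfs$counts, 0)
  mask <- c(1, rep(0, n - 1), 1)
  writeLines(c(sprintf("%d unfolded", n + 1),
               paste(format(full, trim = TRUE, scientific = FALSE),
                     collapse = " "),
               paste(mask, collapse = " ")),
             path)
  invisible(path)
}
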