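#' Mutation frequency array
#'
#' The state container of the simulation: one row per segregating mutation,
#' one column per population, holding derived-allele frequencies in `[0, 1]`.
#' Each mutation carries an origin ID -- the triple (origin generation,
#' origin population, running index within that generation and population) --
#' which is unique for the whole run and supports allele-age and trajectory
#' analyses.
#'
#' @param freq numeric matrix (mutations x populations) of frequencies.
#' @param origin_generation,origin_population,origin_index integer vectors,
#'   one entry per row of `freq`.
#' @return An object of class `mutation_array`.
#' @export
mutation_array <- function(freq,
                           origin_generation = integer(nrow(freq)),
                           origin_population = rep(1L, nrow(freq)),
                           origin_index = seq_len(nrow(freq))) {
  if (!is.matrix(freq)) freq <- matrix(as.numeric(freq), ncol = 1)
  n <- nrow(freq)
  if (length(origin_generation) != n || length(origin_population) != n ||
      length(origin_index) != n)
    stop("origin ID vectors must have one entry per mutation")
  if (n > 0 && (min(freq) < 0 || max(freq) > 1))
    stop("frequencies must lie in [0, 1]")
  structure(list(freq = freq,
                 origin_generation = as.integer(origin_generation),
                 origin_population = as.integer(origin_population),
                 origin_index = as.integer(origin_index)),
            class = "mutation_array")
}

#' @export
print.mutation_array <- function(x, ...) {
  cat("mutation_array:", nrow(x$freq), "mutations x",
      ncol(x$freq), "population(s)\n")
  if (nrow(x$freq) > 0) {
    seg <- colSums(x$freq > 0 & x$freq < 1)
    cat("  segregating per population:", paste(seg, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.mutation_array <- function(x) dim(x$freq)

#' Number of mutations in an array
#' @param array a [mutation_array()].
#' @return Integer count of rows.
#' @export
n_mutations <- function(array) nrow(array$freq)

#' @export
as.data.frame.mutation_array <- function(x, ...) {
  fr <- as.data.frame(x$freq)
  names(fr) <- paste0("freq_pop", seq_len(ncol(x$freq)))
  cbind(data.frame(origin_generation = x$origin_generation,
                   origin_population = x$origin_population,
                   origin_index = x$origin_index),
        fr)
}
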