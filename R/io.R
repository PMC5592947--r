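## Serialization (TSV with provenance headers), YAML scenario configs,
## run manifests, and the two command-line entry points.

#' Write / read a mutation array as TSV
#'
#' Columns: `origin_generation`, `origin_population`, `origin_index`, then
#' one `freq_pop<j>` column per population. Header comment lines (prefixed
#' `#`) carry provenance: an optional manifest digest and the final `Ne` per
#' population, which lets [cli_sfs()] rebuild the population spectrum
#' without re-specifying the lattice. Frequencies are written with
#' round-trip precision: reading the file back reproduces them exactly.
#'
#' @param array a [mutation_array()].
#' @param path output file.
#' @param digest optional manifest digest for the header.
#' @param final_Ne optional integer vector of per-population `Ne` to record.
#' @return `path` (write) or a [mutation_array()] with attribute `final_Ne`
#'   when the header carries it (read).
#' @export
write_mutation_array <- function(array, path, digest = NULL, final_Ne = NULL) {
  stopifnot(inherits(array, "mutation_array"))
  hdr <- "# prfsim mutation array v1"
  if (!is.null(digest)) hdr <- c(hdr, paste0("# manifest_digest: ", digest))
  if (!is.null(final_Ne))
    hdr <- c(hdr, paste0("# final_ne: ", paste(final_Ne, collapse = " ")))
  writeLines(hdr, path)
  df <- as.data.frame(array)
  ## frequencies with 17 significant digits: decimal -> binary round trip
  ## is exact, so reading the file reproduces the doubles bit for bit
  for (nm in grep("^freq_pop", names(df), value = TRUE))
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_mutation_array
#' @export
read_mutation_array <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  df <- data.table::fread(path, sep = "\t", skip = length(hdr),
                          header = TRUE, data.table = FALSE)
  fcols <- grep("^freq_pop", names(df), value = TRUE)
  fm <- unname(as.matrix(df[fcols]))
  storage.mode(fm) <- "double"
  arr <- mutation_array(fm,
                        df$origin_generation, df$origin_population,
                        df$origin_index)
  ne_line <- grep("^# final_ne: ", hdr, value = TRUE)
  if (length(ne_line))
    attr(arr, "final_Ne") <-
      as.integer(strsplit(sub("^# final_ne: ", "", ne_line[1]), " ")[[1]])
  arr
}

#' Write a fixation log as TSV
#' @param fixation_log data.frame from a `wf_sim`.
#' @param path output file.
#' @param digest optional manifest digest for the header.
#' @return `path`, invisibly.
#' @export
write_fixation_log <- function(fixation_log, path, digest = NULL) {
  hdr <- "# prfsim fixation log v1"
  if (!is.null(digest)) hdr <- c(hdr, paste0("# manifest_digest: ", digest))
  writeLines(hdr, path)
  data.table::fwrite(fixation_log, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

## ---- YAML scenario configuration -----------------------------------------

## A parameter entry is either a scalar (constant over the run) or a list of
## epoch maps: {model: constant, value:, from:, to:} or
## {model: exponential, from_value:, to_value:, from:, to:}.
config_param_fun <- function(entry, default = 0) {
  if (is.null(entry)) return(function(t) default)
  if (is.numeric(entry) && length(entry) == 1) {
    force(entry)
    return(function(t) entry)
  }
  segs <- lapply(entry, function(e) {
    model <- if (is.null(e$model)) "constant" else e$model
    from <- if (is.null(e$from)) 0 else e$from
    to <- if (is.null(e$to)) Inf else e$to
    switch(model,
      constant = epoch_constant(e$value, from, to),
      exponential = epoch_exponential(e$from_value, e$to_value, from, to),
      stop(sprintf("unknown epoch model '%s'", model)))
  })
  do.call(piecewise, c(segs, list(default = default)))
}

#' Build a scenario from a YAML configuration file
#'
#' The configuration has sections `run` (`num_sites`, `num_generations`,
#' `compact_interval`, `seed`, `initial_state`), `populations` (a list; each
#' entry gives `size` plus optional `mutation_rate`, `selection`,
#' `dominance`, `inbreeding` -- scalars or epoch lists -- and an optional
#' `founded: {generation:, source:}` clause), `migration` (a list of
#' `{from:, to:, rate:, start:, end:}` windows), and `sampling` (a list of
#' `{population:, n:}`). See
#' `system.file("extdata", "neutral_small.yaml", package = "prfsim")` for a
#' worked file.
#'
#' @param path YAML file.
#' @return A validated [wf_scenario()] with attribute `config_digest` (MD5
#'   of the file, for the run manifest).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$run)) stop("config is missing the 'run' section")
  if (is.null(cfg$populations) || !length(cfg$populations))
    stop("config is missing the 'populations' section")
  P <- length(cfg$populations)
  run <- cfg$run
  size_funs <- lapply(cfg$populations, function(p) {
    if (is.null(p$size)) stop("every population needs a 'size' entry")
    config_param_fun(p$size, default = 0)
  })
  pull <- function(field, default) {
    funs <- lapply(cfg$populations, function(p)
      config_param_fun(p[[field]], default = default))
    function(j, t) funs[[j]](t)
  }
  sel_funs <- lapply(cfg$populations, function(p)
    config_param_fun(p$selection, default = 0))
  founding <- list()
  for (j in seq_len(P)) {
    fd <- cfg$populations[[j]]$founded
    if (!is.null(fd))
      founding[[length(founding) + 1]] <-
        founding_event(fd$generation, fd$source, j)
  }
  mig <- NULL
  if (!is.null(cfg$migration) && length(cfg$migration)) {
    entries <- cfg$migration
    mig <- function(t) {
      M <- diag(P)
      for (e in entries) {
        start <- if (is.null(e$start)) 0 else e$start
        end <- if (is.null(e$end)) Inf else e$end
        if (t >= start && t <= end) M[e$from, e$to] <- e$rate
      }
      diag(M) <- 0
      diag(M) <- 1 - colSums(M)
      M
    }
  }
  sampling <- list()
  if (!is.null(cfg$sampling))
    sampling <- lapply(cfg$sampling, function(s) {
      ## accept `sample_size` or `n` (YAML 1.1 parses a bare `n` key as the
      ## boolean FALSE, so that spelling arrives under the name "FALSE")
      nn <- s$sample_size
      if (is.null(nn)) nn <- s$n
      if (is.null(nn)) nn <- s[["FALSE"]]
      if (is.null(nn)) stop("each sampling entry needs a sample_size")
      list(population = s$population, n = nn)
    })
  sc <- wf_scenario(
    num_populations = P,
    num_sites = run$num_sites,
    num_generations = run$num_generations,
    mutation_rate = pull("mutation_rate", 0),
    census_size = function(j, t) size_funs[[j]](t),
    inbreeding = pull("inbreeding", 0),
    dominance = pull("dominance", 0.5),
    selection = function(j, t, x) {
      v <- sel_funs[[j]](t)
      rep_len(v, length(x))
    },
    migration = mig,
    founding_events = founding,
    compact_interval = if (is.null(run$compact_interval)) 10 else run$compact_interval,
    seed = run$seed,
    initial_state = if (is.null(run$initial_state)) "equilibrium" else run$initial_state,
    sampling = sampling)
  validate_scenario(sc)
  attr(sc, "config_digest") <- unname(tools::md5sum(path))
  sc
}

run_manifest <- function(digest, seed, scenario, compact_interval, outputs) {
  list(tool = "prfsim",
       version = as.character(utils::packageVersion("prfsim")),
       config_digest = digest,
       seed = seed,
       num_generations = scenario$num_generations,
       compact_interval = compact_interval,
       outputs = outputs)
}

## ---- command-line operations ---------------------------------------------

#' Run a simulation from a configuration file (CLI backend)
#'
#' Reads and validates the config, runs the simulation, and writes into
#' `out_dir`: `mutation_array.tsv`, `fixation_log.tsv`, `manifest.json`,
#' and, for every `sampling` entry, `sfs_pop<j>_n<n>.tsv` (sample spectrum
#' with its normalized column) plus a dadi-format `sfs_pop<j>_n<n>.fs`.
#' All text outputs carry the config's MD5 digest in a header comment.
#'
#' @param config path to the YAML scenario file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @param compact_interval optional override.
#' @param init_array optional path to a mutation-array TSV used as the
#'   initial state (checkpoint restart), overriding the config's
#'   `initial_state`.
#' @param verbose print progress.
#' @return Named list of output paths, invisibly.
#' @export
cli_simulate <- function(config, out_dir, seed = NULL,
                         compact_interval = NULL, init_array = NULL,
                         verbose = FALSE) {
  sc <- read_scenario_config(config)
  digest <- attr(sc, "config_digest")
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  if (is.null(sc$seed)) stop("no seed: provide one in the config or via --seed")
  if (!is.null(compact_interval)) sc$compact_interval <- as.integer(compact_interval)
  if (!is.null(init_array)) sc$initial_state <- read_mutation_array(init_array)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate(sc, verbose = verbose)
  paths <- list(array = file.path(out_dir, "mutation_array.tsv"),
                fixations = file.path(out_dir, "fixation_log.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_mutation_array(sim$array, paths$array, digest = digest,
                       final_Ne = sim$final_Ne)
  write_fixation_log(sim$fixation_log, paths$fixations, digest = digest)
  for (sm in sc$sampling) {
    sfs <- sample_sfs(sim, population = sm$population, n = sm$n)
    tag <- sprintf("sfs_pop%d_n%d", sm$population, sm$n)
    if (sfs$num_segregating > 0) sfs <- normalize_sfs(sfs)
    else warning(sprintf("population %d: no segregating sites in sample; %s",
                         sm$population, "normalized spectrum omitted"))
    paths[[tag]] <- file.path(out_dir, paste0(tag, ".tsv"))
    write_sfs_tsv(sfs, paths[[tag]], digest = digest)
    paths[[paste0(tag, "_dadi")]] <- file.path(out_dir, paste0(tag, ".fs"))
    write_sfs_dadi(sfs, paths[[paste0(tag, "_dadi")]])
  }
  manifest <- run_manifest(digest, sc$seed, sc, sc$compact_interval,
                           vapply(paths, identity, character(1)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Build spectra from a stored mutation array (CLI backend)
#'
#' Reads a mutation-array TSV, writes the population spectrum (when the
#' array header records `final_ne` or `Ne` is given), the `n`-chromosome
#' sample spectrum, and its normalized version; optionally also the
#' dadi-format file. With zero segregating sampled sites the normalized
#' spectrum is omitted with a warning.
#'
#' @param array_path mutation-array TSV written by [write_mutation_array()].
#' @param population population index.
#' @param n sample size in chromosomes.
#' @param seed RNG seed for the binomial sampling.
#' @param out_dir output directory.
#' @param dadi also write the dadi-format sample spectrum.
#' @param Ne lattice size for the population spectrum (overrides the header).
#' @return Named list of output paths, invisibly.
#' @export
cli_sfs <- function(array_path, population, n, seed, out_dir,
                    dadi = FALSE, Ne = NULL) {
  arr <- read_mutation_array(array_path)
  if (population > ncol(arr$freq))
    stop(sprintf("array has no population column %d", population))
  if (is.null(Ne)) Ne <- attr(arr, "final_Ne")[population]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(Ne) && !is.na(Ne)) {
    pop <- population_sfs(arr, population, Ne = Ne)
    paths$population <- file.path(out_dir,
                                  sprintf("sfs_population_pop%d.tsv", population))
    write_sfs_tsv(pop, paths$population)
  }
  sfs <- sample_sfs(arr, population, n = n, seed = seed)
  paths$sample <- file.path(out_dir, sprintf("sfs_sample_pop%d_n%d.tsv",
                                             population, n))
  write_sfs_tsv(sfs, paths$sample)
  if (sfs$num_segregating > 0) {
    norm <- normalize_sfs(sfs)
    paths$normalized <- file.path(out_dir,
                                  sprintf("sfs_normalized_pop%d_n%d.tsv",
                                          population, n))
    write_sfs_tsv(norm, paths$normalized)
  } else {
    warning("no segregating sites in sample; normalized spectrum omitted")
  }
  if (dadi) {
    paths$dadi <- file.path(out_dir, sprintf("sfs_sample_pop%d_n%d.fs",
                                             population, n))
    write_sfs_dadi(sfs, paths$dadi)
  }
  invisible(paths)
}
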