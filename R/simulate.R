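## Synthetic-data generator: pure-birth tree samples, packaged study
## fixtures, and Multivariate-Normal isotope records with exactly the
## covariance structure the model assumes.

#' Configuration for the synthetic isotope generator
#'
#' Holds the true parameter values (beta, sigma_j, lambda) used to generate
#' individual records, for parameter-recovery and model-selection
#' experiments.
#'
#' @param species character vector of species codes (length S >= 2).
#' @param n_per_species integer: records per species (scalar or length S).
#' @param beta true coefficients, in the column order of the design built by
#'   [build_design()] for `fixed_effect_id` (names optional).
#' @param sigma true per-species SD (per mil): scalar or length S in
#'   `sort(species)` order, or named.
#' @param lambda true Pagel's lambda in \[0, 1\].
#' @param fixed_effect_id fixed-effect structure generating the mean
#'   (default 1 = species means, the structure best supported by the study
#'   this generator emulates).
#' @param tree_count number of trees in the simulated sample.
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` object.
#' @export
sim_config <- function(species, n_per_species, beta, sigma, lambda,
                       fixed_effect_id = 1, tree_count = 100, seed = 1) {
  species <- as.character(species)
  if (length(species) < 2L || anyDuplicated(species))
    stop_input("`species` must be >= 2 unique codes")
  S <- length(species)
  if (length(n_per_species) == 1L) n_per_species <- rep(n_per_species, S)
  if (length(n_per_species) != S || any(n_per_species < 1))
    stop_input("`n_per_species` must be positive, length 1 or S")
  assert_scalar_number(lambda, "lambda", 0, 1)
  if (any(sigma <= 0)) stop_input("all `sigma` must be > 0")
  assert_scalar_number(seed, "seed")
  assert_scalar_number(tree_count, "tree_count", 1)
  structure(list(species = species, species_count = S,
                 n_per_species = as.integer(n_per_species),
                 beta = beta, sigma = sigma, lambda = lambda,
                 fixed_effect_id = as.integer(fixed_effect_id),
                 tree_count = as.integer(tree_count),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a sample of ultrametric pure-birth trees
#'
#' Draws `tree_count` independent Yule (pure-birth) trees and rescales each
#' to unit depth, standing in for a pseudo-posterior tree sample: only the
#' shared-path structure matters for the downstream correlation matrix.
#'
#' @param species_count number of tips (>= 2), or supply `tip_labels`.
#' @param tree_count number of trees.
#' @param seed integer seed (byte-identical output for equal seeds).
#' @param tip_labels optional tip labels (default `sp01`, `sp02`, ...);
#'   assigned to tips in each tree's own order, so topological placement
#'   varies across trees.
#' @return a `multiPhylo` object.
#' @export
simulate_tree_set <- function(species_count, tree_count = 1, seed = 1,
                              tip_labels = NULL) {
  if (is.null(tip_labels))
    tip_labels <- sprintf("sp%02d", seq_len(species_count))
  else species_count <- length(tip_labels)
  if (species_count < 2L) stop_input("`species_count` must be >= 2")
  if (tree_count < 1L) stop_input("`tree_count` must be >= 1")
  trees <- with_seed(seed, lapply(seq_len(tree_count), function(i) {
    tr <- ape::rphylo(species_count, birth = 1, death = 0)
    depth <- max(tip_depths(tr))
    tr$edge.length <- tr$edge.length / depth
    ## random assignment of codes to tips so placement varies across trees
    tr$tip.label <- sample(tip_labels)
    tr
  }))
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate individual isotope records under the mixed model
#'
#' Draws y ~ MVN(X beta, Sigma) with Sigma from [expand_to_individuals()]
#' (the generating covariance is exactly the model covariance), and attaches
#' station, year, sex and mass labels drawn independently of y — matching
#' the null structure of covariates that do not enter the generating mean.
#'
#' @param config a [sim_config()].
#' @param traits species trait table covering `config$species` (needed when
#'   the generating structure uses trait covariates).
#' @param stations station covariate table (stations are assigned by
#'   sampling its `station` column; omit for a single dummy station).
#' @param correlation `phylo_corr` covering `config$species`.
#' @param year year label attached to every record (default 2013).
#' @param prob_male probability a record is male (default 0.75).
#' @param conspecific within-species covariance convention, see
#'   [expand_to_individuals()].
#' @return record data.frame: `individual_id`, `species`, `station`, `year`,
#'   `age` ("ASY"), `sex`, `mass` (g), `d2hf` (per mil).
#' @export
simulate_dataset <- function(config, traits = NULL, stations = NULL,
                             correlation, year = 2013, prob_male = 0.75,
                             conspecific = c("lambda", "independent")) {
  conspecific <- match.arg(conspecific)
  stopifnot(inherits(config, "sim_config"))
  missing_sp <- setdiff(config$species, correlation$species)
  if (length(missing_sp))
    stop_input(sprintf(
      "dimension mismatch: config species absent from correlation: %s",
      paste(missing_sp, collapse = ", ")))
  with_seed(config$seed, {
    sp <- rep(config$species, config$n_per_species)
    n <- length(sp)
    station_ids <- if (!is.null(stations)) stations$station else "st1"
    base_mass <- setNames(runif(config$species_count, 9, 32), config$species)
    records <- data.frame(
      individual_id = sprintf("%s_%03d", sp, stats::ave(seq_len(n), sp,
                                                        FUN = seq_along)),
      species = sp,
      station = sample(as.character(station_ids), n, replace = TRUE),
      year = year,
      age = "ASY",
      sex = sample(c("M", "F"), n, replace = TRUE,
                   prob = c(prob_male, 1 - prob_male)),
      mass = round(rnorm(n, base_mass[sp], 0.8), 1),
      stringsAsFactors = FALSE)
    des <- build_design(records, traits, stations, config$fixed_effect_id)
    X <- des$X
    if (length(config$beta) != ncol(X))
      stop_input(sprintf(
        "`beta` has length %d but the structure-%d design has %d columns (%s)",
        length(config$beta), config$fixed_effect_id, ncol(X),
        paste(colnames(X), collapse = ", ")))
    Sigma <- expand_to_individuals(correlation, config$lambda, config$sigma,
                                   records$species, conspecific)
    mu <- drop(X %*% as.numeric(config$beta))
    L <- chol(Sigma + diag(1e-12 * max(diag(Sigma)), n))
    records$d2hf <- mu + drop(crossprod(L, rnorm(n)))
    records
  })
}

#' Simulate the two-year interspecific comparison
#'
#' Year is a label: species means are shifted between the two year labels by
#' configured per-species offsets, with independent Normal noise. Used for
#' the year x species interaction experiment.
#'
#' @param species species codes (length S).
#' @param n_per_cell records per species-year cell (scalar or S x 2 matrix).
#' @param means per-species baseline mean in the first year (per mil).
#' @param offsets per-species mean shift in the second year (per mil).
#' @param sd residual SD (scalar or per species), per mil.
#' @param years the two year labels.
#' @param seed integer seed.
#' @return record data.frame with `individual_id`, `species`, `year`, `age`,
#'   `d2hf`.
#' @export
simulate_year_dataset <- function(species, n_per_cell, means, offsets, sd = 8,
                                  years = c(2011, 2013), seed = 1) {
  S <- length(species)
  if (length(years) != 2L) stop_input("`years` must have length 2")
  if (is.matrix(n_per_cell)) {
    if (!all(dim(n_per_cell) == c(S, 2L)))
      stop_input("`n_per_cell` matrix must be S x 2")
    ncell <- n_per_cell
  } else ncell <- matrix(n_per_cell, S, 2L)
  if (length(sd) == 1L) sd <- rep(sd, S)
  stopifnot(length(means) == S, length(offsets) == S, length(sd) == S)
  with_seed(seed, {
    rows <- list()
    for (j in seq_len(S)) for (yy in 1:2) {
      njy <- ncell[j, yy]
      if (njy < 1) next
      mu <- means[j] + if (yy == 2L) offsets[j] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        species = species[j], year = years[yy], age = "ASY",
        d2hf = rnorm(njy, mu, sd[j]), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$individual_id <- sprintf("%s_%s_%03d", out$species, out$year,
                                 stats::ave(seq_len(nrow(out)),
                                            paste(out$species, out$year),
                                            FUN = seq_along))
    out[, c("individual_id", "species", "year", "age", "d2hf")]
  })
}

## ---- packaged fixtures ----------------------------------------------------

fixture_path <- function(file)
  system.file("extdata", file, package = "isofeather", mustWork = TRUE)

#' Packaged study fixtures: species traits and station covariates
#'
#' Returns the transcribed species table (21 boreal songbird species: sample
#' size, forage substrate, diet, nesting substrate) and station table (36
#' capture locations collapsed to 33 rows: coordinates, EOSD land cover at
#' the station and within 100 m, wetland area, per-station feather isotope
#' mean/SD/n).
#'
#' @return list with `species` and `stations` data.frames.
#' @export
make_study_fixture <- function() {
  list(species = read_traits(fixture_path("table2_species.csv"),
                             extra_cols = TRUE),
       stations = read_stations(fixture_path("table1_stations.csv")))
}

#' Synthetic per-species isotope means and SDs
#'
#' The study data are not deposited, so per-species means are not available;
#' this synthetic table (see its filename) anchors every printed constraint
#' — the local species span -162 (SAVS) to -127 (SWTH) per mil, SDs span 4
#' (MOWA) to 22 (SOSP) per mil, and the six presumed non-local molters span
#' -97 to -51 per mil with large SDs — and interpolates the rest.
#'
#' @return data.frame with `species`, `mean_d2hf`, `sd_d2hf`,
#'   `presumed_molt_origin`.
#' @export
fixture_species_means <- function() {
  read.csv(fixture_path("species_means_synthetic.csv"),
           stringsAsFactors = FALSE)
}

#' Expand the species fixture into per-bird records
#'
#' Produces one row per sampled bird (species code repeated `n` times, age
#' ASY) and, when a means table is supplied, draws synthetic isotope values
#' from the per-species Normal.
#'
#' @param species_table species fixture with `species` and `n` columns
#'   (default the packaged table).
#' @param means optional per-species means table (see
#'   [fixture_species_means()]); when supplied, `d2hf` is simulated.
#' @param stations optional station table; stations are sampled with
#'   probability proportional to their per-station `n`.
#' @param seed integer seed for the simulated values.
#' @param year year label (default 2013).
#' @return record data.frame.
#' @export
expand_fixture_records <- function(species_table = NULL, means = NULL,
                                   stations = NULL, seed = 1, year = 2013) {
  if (is.null(species_table)) species_table <- make_study_fixture()$species
  sp <- rep(as.character(species_table$species), species_table$n)
  n <- length(sp)
  with_seed(seed, {
    out <- data.frame(
      individual_id = sprintf("%s_%03d", sp,
                              stats::ave(seq_len(n), sp, FUN = seq_along)),
      species = sp, year = year, age = "ASY",
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25)),
      stringsAsFactors = FALSE)
    if (!is.null(stations)) {
      w <- stations$n %||% rep(1, nrow(stations))
      out$station <- sample(as.character(stations$station), n, replace = TRUE,
                            prob = w / sum(w))
    }
    if (!is.null(means)) {
      mu <- setNames(means$mean_d2hf, means$species)[sp]
      s <- setNames(means$sd_d2hf, means$species)[sp]
      if (anyNA(mu) || anyNA(s))
        stop_input("means table does not cover every species in the fixture")
      out$d2hf <- rnorm(n, mu, s)
    }
    out
  })
}
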