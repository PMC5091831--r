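## Validated file I/O and end-to-end orchestration.

read_table_checked <- function(path, required, file_label = path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop_input(sprintf("file %s is missing column(s): %s", file_label,
                       paste(missing, collapse = ", ")))
  d
}

#' Read and validate an individual record table
#'
#' Required columns: `individual_id`, `species`, `year`, `d2hf`; recognised
#' optional columns: `station`, `age`, `sex`, `mass`. Duplicate individual
#' ids are rejected; `sex` must be F/M; `d2hf` must be numeric (per mil).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_records <- function(path) {
  d <- read_table_checked(path, c("individual_id", "species", "year", "d2hf"))
  dup <- d$individual_id[duplicated(d$individual_id)]
  if (length(dup))
    stop_input(sprintf("file %s: duplicate individual id(s): %s", path,
                       paste(unique(dup), collapse = ", ")))
  if (!is.numeric(d$d2hf))
    stop_input(sprintf("file %s: column d2hf must be numeric", path))
  if (!is.null(d$sex)) check_levels(d$sex, SEX_LEVELS, "sex", path)
  if (!is.null(d$mass) && any(d$mass <= 0, na.rm = TRUE))
    stop_input(sprintf("file %s: column mass must be positive", path))
  d
}

#' Read and validate a species trait table
#'
#' Required columns: `species`, `forage_substrate` (A/G/LCS/UC), `diet`
#' (I/O), `nest_substrate` (closed category set). Species codes must be
#' unique.
#'
#' @param path CSV path.
#' @param extra_cols keep unrecognised columns (e.g. the fixture's `n`)?
#' @return validated data.frame.
#' @export
read_traits <- function(path, extra_cols = TRUE) {
  d <- read_table_checked(path, c("species", "forage_substrate", "diet",
                                  "nest_substrate"))
  if (anyDuplicated(d$species))
    stop_input(sprintf("file %s: species codes must be unique", path))
  check_levels(d$forage_substrate, FORAGE_LEVELS, "forage_substrate", path)
  check_levels(d$diet, DIET_LEVELS, "diet", path)
  check_levels(d$nest_substrate, NEST_LEVELS, "nest_substrate", path)
  if (!extra_cols)
    d <- d[, c("species", "forage_substrate", "diet", "nest_substrate")]
  d
}

#' Read and validate a station covariate table
#'
#' Required columns: `station`, `latitude`, `longitude`, `habitat_station`,
#' `habitat_100m`, `wetland_area` (m^2, >= 0). Land cover levels are checked
#' against the EOSD category set.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_stations <- function(path) {
  d <- read_table_checked(path, c("station", "latitude", "longitude",
                                  "habitat_station", "habitat_100m",
                                  "wetland_area"))
  if (anyDuplicated(d$station))
    stop_input(sprintf("file %s: station ids must be unique", path))
  check_levels(d$habitat_station, HABITAT_LEVELS, "habitat_station", path)
  check_levels(d$habitat_100m, HABITAT_LEVELS, "habitat_100m", path)
  if (any(d$wetland_area < 0, na.rm = TRUE))
    stop_input(sprintf("file %s: wetland_area must be >= 0", path))
  d
}

#' Read a Newick tree sample (one tree per line)
#'
#' @param path Newick file.
#' @return a `multiPhylo` object (single trees are wrapped).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    class(trees) <- "multiPhylo"
  }
  if (!length(trees)) stop_input(sprintf("no trees in %s", path))
  trees
}

#' Write a tree sample as Newick, one tree per line
#'
#' @param trees `multiPhylo` or `phylo`.
#' @param path output file.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

## ---- pipeline -------------------------------------------------------------

log_line <- function(con, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = con, append = TRUE)
  invisible(msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: read/validate inputs, screen records,
#' pool the tree sample into a species correlation matrix, fit the candidate
#' set, rank by AICc, and (when the records carry exactly two year labels
#' for >= 2 species) run the year x species ANOVA. Every stage logs its row
#' counts; artifacts are written to `config$out_dir` and the run is
#' deterministic given the config and seed.
#'
#' @param config list (or path to a JSON file) with fields: `records`,
#'   `traits`, `stations`, `trees` (paths or in-memory objects), `out_dir`,
#'   `seed`; optional `min_n` (default 9), `exclusion` (species codes),
#'   `ids` (default 0:15), `variances` (default hom+het), `n_starts`,
#'   `anova_species` (restrict the ANOVA to these species).
#' @return invisibly, a list with the screening report, fits, ranking and
#'   ANOVA table (NULL when not applicable), plus artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (fld in c("records", "traits", "stations", "trees", "out_dir"))
    if (is.null(config[[fld]]))
      stop_input(sprintf("pipeline config is missing `%s`", fld))
  seed <- config$seed %||% stop_input("pipeline config needs a `seed`")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "log.txt")
  cat("", file = log_file)

  records <- if (is.character(config$records)) read_records(config$records)
             else config$records
  traits <- if (is.character(config$traits)) read_traits(config$traits)
            else config$traits
  stations <- if (is.character(config$stations)) read_stations(config$stations)
              else config$stations
  trees <- if (is.character(config$trees)) read_trees(config$trees)
           else config$trees
  log_line(log_file, "inputs: %d records, %d species (traits), %d stations, %d trees",
           nrow(records), nrow(traits), nrow(stations), length(trees))

  scr <- screen_records(records, min_n = config$min_n %||% 9,
                        exclusion = config$exclusion %||% character())
  log_line(log_file, "screening: %d -> %d records (%d species retained, %d excluded)",
           scr$n_input, scr$retained_records, length(scr$retained_species),
           length(scr$excluded_species))
  stopifnot(scr$retained_records +
              (scr$n_input - scr$retained_records) == nrow(records))
  jsonlite::write_json(screening_to_list(scr),
                       file.path(out_dir, "screening_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(scr$records, file.path(out_dir, "screened_records.csv"),
            row.names = FALSE)

  keep <- scr$retained_species
  trees_sub <- lapply(trees, function(tr)
    ape::keep.tip(tr, intersect(tr$tip.label, keep)))
  class(trees_sub) <- "multiPhylo"
  corr <- correlation_from_trees(trees_sub,
                                 method = config$pooling %||% "mean_correlation")
  write_correlation(corr, file.path(out_dir, "correlation.csv"))
  log_line(log_file, "correlation: %d species pooled over %d trees",
           length(corr$species), length(trees_sub))

  fits <- fit_candidates(scr$records, traits, stations, corr,
                         ids = config$ids %||% 0:15,
                         variances = config$variances %||% c("hom", "het"),
                         n_starts = config$n_starts %||% 5, seed = seed)
  log_line(log_file, "fits: %d candidates on n = %d complete-case records",
           length(fits), fits[[1]]$n)
  jsonlite::write_json(lapply(fits, fitted_to_list),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ranking <- rank_models(fits)
  write_ranking(ranking, file.path(out_dir, "ranking.csv"))
  log_line(log_file, "ranking: top model %s (wAICc = %.3f)",
           ranking$model[1], ranking$waicc[1])

  anova_tab <- NULL
  arec <- scr$records
  if (!is.null(config$anova_species))
    arec <- arec[arec$species %in% config$anova_species, , drop = FALSE]
  if (length(unique(arec$year)) == 2L &&
      length(unique(arec$species)) >= 2L &&
      all(table(arec$species, arec$year) >= 2L)) {
    anova_tab <- year_species_anova(arec)
    write.csv(as.data.frame(anova_tab), file.path(out_dir, "anova.csv"),
              row.names = FALSE)
    log_line(log_file, "anova: full-model F = %.2f on %d df",
             anova_tab$F[anova_tab$effect == "Full model (cell means)"],
             anova_tab$df[anova_tab$effect == "Full model (cell means)"])
  } else {
    log_line(log_file, "anova: skipped (needs exactly 2 years and filled cells)")
  }

  manifest <- list(
    seed = seed,
    package_version = as.character(packageVersion("isofeather")),
    r_version = R.version.string,
    settings = list(min_n = config$min_n %||% 9,
                    exclusion = config$exclusion %||% character(),
                    ids = config$ids %||% 0:15,
                    variances = config$variances %||% c("hom", "het"),
                    pooling = config$pooling %||% "mean_correlation",
                    n_starts = config$n_starts %||% 5),
    inputs = list(
      records = if (is.character(config$records)) config$records else
        sprintf("<in-memory: %d rows>", nrow(records)),
      traits = if (is.character(config$traits)) config$traits else
        sprintf("<in-memory: %d rows>", nrow(traits)),
      stations = if (is.character(config$stations)) config$stations else
        sprintf("<in-memory: %d rows>", nrow(stations)),
      trees = if (is.character(config$trees)) config$trees else
        sprintf("<in-memory: %d trees>", length(trees))))
  tf <- tempfile(); jsonlite::write_json(manifest, tf, auto_unbox = TRUE)
  manifest$config_hash <- unname(tools::md5sum(tf)); unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(screening = scr, correlation = corr, fits = fits,
                 ranking = ranking, anova = anova_tab, out_dir = out_dir))
}
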