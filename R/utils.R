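## Internal helpers: seeded evaluation, validation, closed vocabularies.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package code does not disturb
#' the caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_input(sprintf("`%s` must be a single number in [%s, %s]",
                       name, format(lower), format(upper)))
  invisible(x)
}

## Closed category sets (trait and station vocabularies)
FORAGE_LEVELS <- c("A", "G", "LCS", "UC")
DIET_LEVELS <- c("I", "O")
NEST_LEVELS <- c("Agricultural", "Bogs", "Treed/shrubby swamp",
                 "Coniferous Woodland", "Deciduous Woodland",
                 "Early Successional", "Marsh", "Mixed Woodland",
                 "Open Woodland")
HABITAT_LEVELS <- c("Broadleaf", "Coniferous", "Mixedwood", "Wetland",
                    "Exposed Land", "Wetland-Shrub", "Wetland-Treed",
                    "Shrub-Tall", "Water")
SEX_LEVELS <- c("F", "M")

check_levels <- function(x, allowed, column, file = NULL) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad)) {
    where <- if (is.null(file)) column else sprintf("%s (file %s)", column, file)
    stop_input(sprintf("unknown level(s) %s in %s; allowed levels: %s",
                       paste(sQuote(bad), collapse = ", "), where,
                       paste(allowed, collapse = ", ")))
  }
  invisible(x)
}
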