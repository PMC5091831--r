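## Pre-model screening, the year x species ANOVA, and transfer-function
## comparisons.

#' Screen individual records before model fitting
#'
#' Applies, in order: (1) the age filter (only after-second-year, ASY,
#' birds are retained when an `age` column is present); (2) the explicit
#' species exclusion list (e.g. species whose feathers were judged to have
#' been grown off the breeding grounds); (3) the minimum-sample rule
#' (species with fewer than `min_n` remaining records are dropped). The
#' operation is idempotent.
#'
#' @param records record table with `species` (and optionally `age`).
#' @param min_n minimum records per retained species (default 9).
#' @param exclusion character vector of species codes to drop.
#' @param age_class retained age class when `age` is present.
#' @return a `screening_report`: counts, retained and excluded species with
#'   reasons, per-species mean and SD of `d2hf` (when present), and the
#'   filtered records in `$records`.
#' @export
screen_records <- function(records, min_n = 9, exclusion = character(),
                           age_class = "ASY") {
  if (is.null(records$species)) stop_input("records must have a `species` column")
  input_species <- sort(unique(as.character(records$species)))
  n_input <- nrow(records)
  d <- as.data.frame(records)

  dropped_age <- 0L
  if (!is.null(d$age)) {
    keep <- d$age == age_class
    dropped_age <- sum(!keep)
    d <- d[keep, , drop = FALSE]
  }
  excluded <- list()
  if (length(exclusion)) {
    for (s in intersect(exclusion, unique(as.character(d$species))))
      excluded[[s]] <- "on exclusion list"
    d <- d[!(d$species %in% exclusion), , drop = FALSE]
  }
  counts <- table(as.character(d$species))
  small <- names(counts)[counts < min_n]
  for (s in small) excluded[[s]] <- sprintf("n = %d < min_n = %d",
                                            counts[[s]], min_n)
  d <- d[!(d$species %in% small), , drop = FALSE]
  if (!nrow(d))
    stop_input("no records remain after screening (empty result set)")
  d$species <- droplevels(factor(as.character(d$species)))

  per_species <- if (!is.null(d$d2hf)) {
    agg <- aggregate(d2hf ~ species, data = d, FUN = function(v)
      c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else NA))
    data.frame(species = agg$species,
               n = agg$d2hf[, "n"],
               mean_d2hf = agg$d2hf[, "mean"],
               sd_d2hf = agg$d2hf[, "sd"])
  } else {
    data.frame(species = names(table(d$species)),
               n = as.integer(table(d$species)),
               mean_d2hf = NA_real_, sd_d2hf = NA_real_)
  }

  structure(list(
    n_input = n_input,
    retained_records = nrow(d),
    dropped_age = dropped_age,
    retained_species = sort(levels(d$species)),
    excluded_species = excluded,
    per_species = per_species,
    min_n = min_n,
    records = d), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening: %d input records -> %d retained across %d species\n",
              x$n_input, x$retained_records, length(x$retained_species)))
  if (x$dropped_age) cat(sprintf("  dropped %d non-ASY records\n", x$dropped_age))
  if (length(x$excluded_species)) {
    cat("  excluded species:\n")
    for (s in names(x$excluded_species))
      cat(sprintf("    %s: %s\n", s, x$excluded_species[[s]]))
  }
  invisible(x)
}

#' Serialize a screening report to a JSON-ready list
#' @param report a `screening_report`.
#' @return plain list (without the record table).
#' @export
screening_to_list <- function(report) {
  list(n_input = report$n_input,
       retained_records = report$retained_records,
       dropped_age = report$dropped_age,
       retained_species = report$retained_species,
       excluded_species = report$excluded_species,
       per_species = report$per_species,
       min_n = report$min_n)
}

#' Flag candidate non-local molters from per-species means
#'
#' Species whose mean feather value exceeds (is strictly greater, i.e. less
#' negative, than) the upper bound of the expected local band are flagged as
#' having likely grown the sampled feathers on the wintering grounds or
#' during migration. A mean exactly at the bound is not flagged (strict
#' inequality).
#'
#' @param species_means data.frame with `species` and a mean column
#'   (`mean_d2hf` or `mean`), per mil.
#' @param band numeric length-2 `(low, high)` expected local range in per
#'   mil; default upper bound -110 sits between typical local boreal means
#'   and wintering-ground values.
#' @return character vector of flagged species codes.
#' @export
flag_nonlocal_molt <- function(species_means, band = c(-Inf, -110)) {
  if (length(band) != 2L || band[1] > band[2])
    stop_input("`band` must be (low, high) with low <= high")
  m <- species_means[["mean_d2hf"]] %||% species_means[["mean"]]
  if (is.null(m)) stop_input("`species_means` needs a `mean_d2hf`/`mean` column")
  sort(as.character(species_means$species[m > band[2]]))
}

#' Two-way year x species ANOVA
#'
#' Fixed-effects ANOVA of the isotope values on year, species and their
#' interaction, with Type-II sums of squares (suited to the unbalanced
#' species samples). Emits the Year, Species and Year:Species rows plus a
#' full-model row (the F test of all cell-mean differences, numerator df =
#' cells - 1) because reported interaction F statistics sometimes refer to
#' the full cell-means model.
#'
#' @param records record table with `d2hf`, `species`, `year`; exactly two
#'   year labels and at least two species, with >= 2 records per
#'   year-species cell.
#' @return data.frame with columns `effect`, `df`, `sum_sq`, `F`, `p`
#'   (Residuals row has NA F/p), of class `anova_table`.
#' @export
year_species_anova <- function(records) {
  d <- as.data.frame(records)
  for (v in c("d2hf", "species", "year"))
    if (is.null(d[[v]])) stop_input(sprintf("records must have `%s`", v))
  d$species <- droplevels(factor(as.character(d$species)))
  d$year <- droplevels(factor(as.character(d$year)))
  if (nlevels(d$year) != 2L)
    stop_input(sprintf("exactly 2 year labels required, got %d", nlevels(d$year)))
  if (nlevels(d$species) < 2L) stop_input("at least 2 species required")
  cell <- table(d$species, d$year)
  if (any(cell < 2L)) {
    bad <- which(cell < 2L, arr.ind = TRUE)[1, ]
    stop_input(sprintf(
      "unbalanced design: cell species = %s, year = %s has %d (< 2) records",
      rownames(cell)[bad[1]], colnames(cell)[bad[2]],
      cell[bad[1], bad[2]]))
  }
  fit <- lm(d2hf ~ year * species, data = d)
  a2 <- car::Anova(fit, type = 2)
  rows <- data.frame(effect = rownames(a2),
                     df = a2$Df,
                     sum_sq = a2$`Sum Sq`,
                     F = a2$`F value`,
                     p = a2$`Pr(>F)`,
                     stringsAsFactors = FALSE)
  sm <- summary(fit)$fstatistic
  full <- data.frame(effect = "Full model (cell means)",
                     df = unname(sm["numdf"]),
                     sum_sq = NA_real_,
                     F = unname(sm["value"]),
                     p = pf(sm["value"], sm["numdf"], sm["dendf"],
                            lower.tail = FALSE),
                     stringsAsFactors = FALSE)
  out <- rbind(rows, full)
  rownames(out) <- NULL
  attr(out, "residual_df") <- unname(sm["dendf"])
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Predict the feather-isotope band from a precipitation value
#'
#' Evaluates configured transfer functions (regressions of feather on
#' growing-season precipitation values): point prediction
#' `intercept + slope * d2hp` with a +/- residual-SD band per function. The
#' coefficients are study inputs supplied by configuration, not estimated
#' here.
#'
#' @param d2hp precipitation isotope value (per mil).
#' @param transfer_functions list of lists/data.frame rows, each with
#'   `label`, `intercept` (per mil), `slope` (unitless), `resid_sd` (> 0,
#'   per mil).
#' @return data.frame with `label`, `fit`, `lower`, `upper`.
#' @export
predict_feather_band <- function(d2hp, transfer_functions) {
  if (!length(transfer_functions))
    stop_input("no transfer functions configured")
  if (is.data.frame(transfer_functions))
    transfer_functions <- split(transfer_functions,
                                seq_len(nrow(transfer_functions)))
  rows <- lapply(transfer_functions, function(tf) {
    tf <- as.list(tf)
    for (fld in c("label", "intercept", "slope", "resid_sd"))
      if (is.null(tf[[fld]]))
        stop_input(sprintf("transfer function missing `%s`", fld))
    if (tf$resid_sd <= 0) stop_input("`resid_sd` must be > 0")
    fit <- tf$intercept + tf$slope * d2hp
    data.frame(label = tf$label, fit = fit,
               lower = fit - tf$resid_sd, upper = fit + tf$resid_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a species mean against a predicted feather band
#'
#' @param mean_d2hf observed species (or group) mean, per mil.
#' @param band numeric `(lower, upper)` predicted interval, per mil.
#' @return `"consistent with local molt"` if the mean lies inside the closed
#'   interval, otherwise `"outside predicted band"`.
#' @export
classify_local_molt <- function(mean_d2hf, band) {
  if (length(band) != 2L || band[1] > band[2])
    stop_input("`band` must be (lower, upper)")
  if (mean_d2hf >= band[1] && mean_d2hf <= band[2])
    "consistent with local molt" else "outside predicted band"
}
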