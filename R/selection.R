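## AICc multimodel inference over the candidate set.

#' Small-sample corrected Akaike Information Criterion
#'
#' AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1). The correction is
#' undefined for n <= k + 1.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc (scalar).
#' @examples
#' aicc(-100, 3, 20)  # 207.5
#' @export
aicc <- function(loglik, k, n) {
  if (!is.finite(loglik)) stop_input("`loglik` must be finite")
  if (n <= k + 1) stop_input(sprintf(
    "AICc undefined: n (%d) must exceed k + 1 (%d)", n, k + 1))
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank fitted candidates by AICc
#'
#' Computes delta AICc against the best candidate and Akaike weights
#' wAICc = exp(-delta/2) / sum(exp(-delta/2)), jointly over all supplied
#' fits. Ties are broken by smaller k, then by model label. All fits must
#' come from the same record set (equal n); mixed n would make the
#' likelihoods non-comparable.
#'
#' @param fits list of `fitted_mvn` (or `fitted_dc`-like) objects with
#'   `label`, `spec`, `k`, `n`, `loglik`, `aicc`.
#' @param warn_unconverged warn if any fit carries `converged = FALSE`.
#' @return a `ranking_table`: data.frame with columns `model`, `variance`,
#'   `fixed_effect`, `k`, `loglik`, `aicc`, `delta_aicc`, `waicc`, sorted
#'   by ascending AICc.
#' @export
rank_models <- function(fits, warn_unconverged = TRUE) {
  if (inherits(fits, "fitted_mvn")) fits <- list(fits)
  if (!length(fits)) stop_input("no fits supplied")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop_input("fits use different record sets (n differs): AICc values are not comparable")
  if (warn_unconverged) {
    bad <- vapply(fits, function(f) !isTRUE(f$converged), logical(1))
    if (any(bad))
      warning("unconverged fits in ranking: ",
              paste(vapply(fits[bad], function(f) f$label, character(1)),
                    collapse = ", "))
  }
  df <- data.frame(
    model = vapply(fits, function(f) f$label, character(1)),
    variance = vapply(fits, function(f) f$spec$variance, character(1)),
    fixed_effect = vapply(fits, function(f)
      FIXED_EFFECT_LABELS[f$spec$fixed_effect_id + 1L], character(1)),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    lambda = vapply(fits, function(f) f$lambda, numeric(1)),
    stringsAsFactors = FALSE)
  df$delta_aicc <- df$aicc - min(df$aicc)
  w <- exp(-df$delta_aicc / 2)
  df$waicc <- w / sum(w)
  df <- df[order(df$aicc, df$k, df$model), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ranking_table", "data.frame"),
            n = unique(ns))
}

#' @export
print.ranking_table <- function(x, digits = 2, max_rows = 32L, ...) {
  cat(sprintf("Candidate models ranked by AICc (n = %d)\n", attr(x, "n")))
  show <- utils::head(as.data.frame(x), max_rows)
  show$loglik <- round(show$loglik, digits)
  show$aicc <- round(show$aicc, digits)
  show$delta_aicc <- round(show$delta_aicc, digits)
  show$waicc <- round(show$waicc, 3)
  show$lambda <- round(show$lambda, 3)
  print(show, row.names = TRUE)
  invisible(x)
}

#' Write a ranking table as CSV
#'
#' AICc columns are written at 2 decimals (full precision is retained in the
#' in-memory object); weights at 4 decimals.
#'
#' @param ranking a `ranking_table`.
#' @param path output CSV path.
#' @export
write_ranking <- function(ranking, path) {
  out <- as.data.frame(ranking)
  for (col in c("loglik", "aicc", "delta_aicc"))
    out[[col]] <- sprintf("%.2f", out[[col]])
  out$waicc <- sprintf("%.4f", out$waicc)
  out$lambda <- sprintf("%.4f", out$lambda)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Fit every candidate in the 32-model set
#'
#' Applies a complete-case rule first: records missing any covariate used by
#' any requested candidate are dropped up front, so all candidates are fit
#' on an identical record set and their AICc values are comparable.
#'
#' @inheritParams fit_ml
#' @param ids fixed-effect structures to include (default 0:15).
#' @param variances variance structures to include.
#' @param n_starts,seed,reltol passed to [fit_ml()].
#' @param verbose print one line per fitted candidate.
#' @return list of `fitted_mvn` objects (names = candidate labels), with the
#'   record set used attached as attribute `records`.
#' @export
fit_candidates <- function(records, traits = NULL, stations = NULL,
                           correlation, ids = 0:15,
                           variances = c("hom", "het"), n_starts = 5,
                           seed = 1, reltol = 1e-8, verbose = FALSE) {
  need <- unique(unlist(lapply(ids, covariates_for)))
  d <- merge_covariates(records, traits, stations)
  have <- intersect(need, names(d))
  if (length(have)) {
    cc <- complete.cases(d[, have, drop = FALSE])
    if (!all(cc)) records <- records[cc, , drop = FALSE]
  }
  if (!nrow(records)) stop_input("no complete-case records remain")
  fits <- list()
  for (v in variances) for (id in ids) {
    sp <- model_spec(id, v)
    fits[[sp$label]] <- fit_ml(sp, records, traits, stations, correlation,
                               n_starts = n_starts, seed = seed,
                               reltol = reltol)
    if (verbose)
      cat(sprintf("  %-6s logLik %10.3f  AICc %10.2f\n", sp$label,
                  fits[[sp$label]]$loglik, fits[[sp$label]]$aicc))
  }
  attr(fits, "records") <- records
  fits
}
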