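## The Multivariate-Normal phylogenetic mixed model:
##   y ~ MVN(X beta, Sigma),  Sigma[il] = sigma_j sigma_k t_jk lambda  (i != l)
##                            Sigma[ii] = sigma_j^2
## for individual i of species j and individual l of species k. Equivalently
##   Sigma = D_sigma (lambda * Z T Z' + (1 - lambda) I) D_sigma
## with Z the n x S species indicator and T the unit-diagonal species
## correlation matrix, which is what the fast likelihood path exploits.

FIXED_EFFECT_FORMULAS <- c(
  "~ 1",                       # 0  null
  "~ species",                 # 1  species means
  "~ forsub",                  # 2  ground vs non-ground forager
  "~ diet",                    # 3  insectivore vs omnivore
  "~ nest_substrate",          # 4  nesting substrate
  "~ habitat_station",         # 5  land cover at the station point
  "~ habitat_100m",            # 6  dominant land cover within 100 m
  "~ wetland_area",            # 7  wetland area within 100 m (continuous)
  "~ latitude",                # 8  station latitude (continuous)
  "~ mass",                    # 9  individual mass, linear
  "~ mass + I(mass^2)",        # 10 individual mass, quadratic
  "~ sex",                     # 11 sex
  "~ forsub * diet",           # 12
  "~ forsub * habitat_station",# 13 forage substrate x land cover
  "~ nest_substrate * diet",   # 14
  "~ forsub * diet * nest_substrate" # 15
)

FIXED_EFFECT_LABELS <- c("Null", "Species", "ForSub", "Diet", "NestSub",
                         "LandStation", "Land100m", "WetArea", "Latitude",
                         "IndMass", "IndMass2", "Sex", "ForSub x Diet",
                         "ForSub x Habitat", "NestSub x Diet",
                         "ForSub x Diet x NestSub")

#' Specify one candidate model
#'
#' A candidate is one of the 16 fixed-effect structures (0 = null,
#' 1 = species, ..., 15 = forage substrate x diet x nest substrate) crossed
#' with a variance structure: `"hom"` (one residual SD sigma for all
#' species) or `"het"` (a species-specific sigma_j). Pagel's lambda is
#' estimated in every candidate unless `estimate_lambda = FALSE`.
#'
#' @param fixed_effect_id integer 0-15.
#' @param variance `"hom"` or `"het"`.
#' @param estimate_lambda estimate lambda (default TRUE)? When FALSE,
#'   supply `lambda_fixed` to [fit_ml()].
#' @return a `model_spec` object.
#' @export
model_spec <- function(fixed_effect_id, variance = c("hom", "het"),
                       estimate_lambda = TRUE) {
  variance <- match.arg(variance)
  if (!is.numeric(fixed_effect_id) || length(fixed_effect_id) != 1L ||
      is.na(fixed_effect_id) || fixed_effect_id %% 1 != 0 ||
      fixed_effect_id < 0 || fixed_effect_id > 15)
    stop_input("`fixed_effect_id` must be an integer in 0..15")
  structure(list(fixed_effect_id = as.integer(fixed_effect_id),
                 variance = variance,
                 estimate_lambda = isTRUE(estimate_lambda),
                 label = paste0(ifelse(variance == "het", "Het", "Hom"),
                                fixed_effect_id)),
            class = "model_spec")
}

#' The full 32-candidate set
#'
#' @return list of `model_spec` objects: Hom0-Hom15 then Het0-Het15.
#' @export
candidate_set <- function() {
  out <- list()
  for (v in c("hom", "het"))
    for (id in 0:15) out[[length(out) + 1L]] <- model_spec(id, v)
  out
}

covariates_for <- function(fixed_effect_id) {
  switch(as.character(fixed_effect_id),
    "0" = character(), "1" = "species", "2" = "forsub", "3" = "diet",
    "4" = "nest_substrate", "5" = "habitat_station", "6" = "habitat_100m",
    "7" = "wetland_area", "8" = "latitude", "9" = "mass", "10" = "mass",
    "11" = "sex", "12" = c("forsub", "diet"),
    "13" = c("forsub", "habitat_station"),
    "14" = c("nest_substrate", "diet"),
    "15" = c("forsub", "diet", "nest_substrate"))
}

## Merge records with species traits and station covariates and derive the
## modelling variables (including the 2-level ground / non-ground forager).
merge_covariates <- function(records, traits = NULL, stations = NULL) {
  d <- as.data.frame(records)
  d$.row <- seq_len(nrow(d))
  if (!is.null(traits)) {
    tr <- as.data.frame(traits)[, intersect(
      c("species", "forage_substrate", "diet", "nest_substrate"),
      names(traits)), drop = FALSE]
    d <- merge(d, tr, by = "species", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(stations)) {
    st <- as.data.frame(stations)[, intersect(
      c("station", "latitude", "longitude", "habitat_station",
        "habitat_100m", "wetland_area"), names(stations)), drop = FALSE]
    d <- merge(d, st, by = "station", all.x = TRUE, sort = FALSE)
  }
  d <- d[order(d$.row), , drop = FALSE]
  d$.row <- NULL
  if (!is.null(d$forage_substrate))
    d$forsub <- factor(ifelse(d$forage_substrate == "G", "ground", "nonground"),
                       levels = c("ground", "nonground"))
  for (v in c("species", "diet", "nest_substrate", "habitat_station",
              "habitat_100m", "sex"))
    if (!is.null(d[[v]])) d[[v]] <- factor(as.character(d[[v]]))
  d
}

#' Build the fixed-effect design matrix for one candidate structure
#'
#' Treatment-coded factor expansion with intercept for the requested
#' structure (see [model_spec()] for the id - structure map). Interactions
#' include their main effects. Records missing any required covariate raise
#' an error naming the offending individuals.
#'
#' @param records individual record table (`species`, `station`, `sex`,
#'   `mass`, ... as required by the structure).
#' @param traits species trait table (merged by `species`).
#' @param stations station covariate table (merged by `station`).
#' @param fixed_effect_id integer 0-15.
#' @return list with `X` (design matrix), `labels` (column labels) and
#'   `formula`.
#' @export
build_design <- function(records, traits = NULL, stations = NULL,
                         fixed_effect_id = 0) {
  d <- merge_covariates(records, traits, stations)
  need <- covariates_for(fixed_effect_id)
  for (v in need) {
    if (is.null(d[[v]]))
      stop_input(sprintf("covariate `%s` required by structure %d is absent",
                         v, fixed_effect_id))
    if (anyNA(d[[v]])) {
      who <- d$individual_id[is.na(d[[v]])] %||% which(is.na(d[[v]]))
      stop_input(sprintf(
        "covariate `%s` (structure %d) is missing for record(s): %s",
        v, fixed_effect_id, paste(utils::head(who, 10), collapse = ", ")))
    }
    if (is.factor(d[[v]])) d[[v]] <- droplevels(d[[v]])
  }
  f <- as.formula(FIXED_EFFECT_FORMULAS[fixed_effect_id + 1L])
  X <- model.matrix(f, data = d)
  list(X = X, labels = colnames(X), formula = f)
}

## ---- covariance expansion -------------------------------------------------

resolve_sigma <- function(sigma, sp_levels) {
  S <- length(sp_levels)
  if (length(sigma) == 1L && is.null(names(sigma))) sigma <- rep(sigma, S)
  if (!is.null(names(sigma))) {
    if (!all(sp_levels %in% names(sigma)))
      stop_input("named `sigma` must cover every species present")
    sigma <- sigma[sp_levels]
  }
  if (length(sigma) != S)
    stop_input(sprintf("`sigma` has length %d but there are %d species",
                       length(sigma), S))
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop_input("all `sigma` must be finite and > 0")
  unname(sigma)
}

species_factor <- function(species_index, corr) {
  sp <- as.character(species_index)
  missing <- setdiff(unique(sp), corr$species)
  if (length(missing))
    stop_input(sprintf("species not in the correlation matrix: %s",
                       paste(missing, collapse = ", ")))
  factor(sp, levels = sort(unique(sp)))
}

#' Individual-level covariance matrix of the isotope model
#'
#' Expands a species correlation matrix to the covariance matrix over
#' individuals: the diagonal entry for an individual of species j is
#' sigma_j^2 and the off-diagonal entry for individuals of species j and k
#' is sigma_j sigma_k t_jk lambda. The formula is applied literally at
#' j = k, so two distinct conspecific individuals have covariance
#' lambda * sigma_j^2 (`conspecific = "lambda"`, the default); with
#' `conspecific = "independent"` conspecific individuals are uncorrelated
#' given their species mean.
#'
#' @param correlation a `phylo_corr` object (or unit-diagonal matrix).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param sigma per-species SD (scalar, or vector over the species present
#'   in alphabetical order, or named vector).
#' @param species_index species code of each individual (character/factor,
#'   length n).
#' @param conspecific within-species correlation convention, see above.
#' @return n x n covariance matrix with attributes `species_index` and
#'   `sigma`.
#' @export
expand_to_individuals <- function(correlation, lambda, sigma, species_index,
                                  conspecific = c("lambda", "independent")) {
  conspecific <- match.arg(conspecific)
  assert_scalar_number(lambda, "lambda", 0, 1)
  if (!inherits(correlation, "phylo_corr"))
    correlation <- new_phylo_corr(as.matrix(correlation),
                                  rownames(as.matrix(correlation)))
  spf <- species_factor(species_index, correlation)
  sp_levels <- levels(spf)
  sig <- resolve_sigma(sigma, sp_levels)
  Tm <- correlation$matrix[sp_levels, sp_levels, drop = FALSE]
  idx <- as.integer(spf)
  M <- lambda * Tm[idx, idx, drop = FALSE]
  if (conspecific == "independent") {
    same <- outer(idx, idx, "==")
    M[same] <- 0
  }
  diag(M) <- 1
  s_ind <- sig[idx]
  Sigma <- M * tcrossprod(s_ind)
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(sig)^2)
    stop("internal: expanded covariance is not positive semidefinite")
  dimnames(Sigma) <- list(as.character(spf), as.character(spf))
  attr(Sigma, "species_index") <- as.character(spf)
  attr(Sigma, "sigma") <- setNames(sig, sp_levels)
  Sigma
}

## ---- likelihood -----------------------------------------------------------

## Structured evaluation of M^{-1}-quadratic forms and log|M| for
## M = lambda Z T Z' + (1 - lambda) I via the Woodbury identity and the
## matrix determinant lemma: O(n S + S^3) per evaluation.
## R: n x m matrix already scaled by 1/sigma_i. Returns list(Q, logdet_M)
## with Q = R' M^{-1} R.
struct_parts <- function(R, idx, Tm, lambda) {
  n <- nrow(R); S <- ncol(Tm)
  a <- 1 - lambda
  nj <- tabulate(idx, nbins = S)
  W <- lambda * Tm
  A <- a * diag(S) + nj * W            # aI + N W (rows of W scaled by n_j)
  U <- rowsum(R, idx)                   # S x m species sums (idx covers 1..S)
  G <- W %*% solve(A)                   # = (a W^{-1} + N)^{-1}, symmetric
  Q <- (crossprod(R) - crossprod(U, G %*% U)) / a
  Q <- (Q + t(Q)) / 2
  ld <- determinant(A, logarithm = TRUE)
  logdet_M <- (n - S) * log(a) + as.numeric(ld$modulus)
  list(Q = Q, logdet_M = logdet_M)
}

## Dense Cholesky fallback (used at lambda ~ 1 and for the "independent"
## conspecific convention).
dense_parts <- function(R, idx, Tm, lambda, conspecific = "lambda") {
  M <- lambda * Tm[idx, idx, drop = FALSE]
  if (conspecific == "independent") M[outer(idx, idx, "==")] <- 0
  diag(M) <- 1
  L <- tryCatch(chol(M), error = function(e)
    stop_input(paste0("singular model covariance (lambda = ", lambda,
                      "); with conspecific individuals lambda must be < 1")))
  Z <- backsolve(L, R, transpose = TRUE)
  list(Q = crossprod(Z), logdet_M = 2 * sum(log(diag(L))))
}

mvn_parts <- function(R, idx, Tm, lambda, conspecific = "lambda") {
  if (conspecific == "lambda" && (1 - lambda) > 1e-10)
    struct_parts(R, idx, Tm, lambda)
  else
    dense_parts(R, idx, Tm, lambda, conspecific)
}

#' Exact log-likelihood of the isotope mixed model
#'
#' Multivariate-Normal log-density of `y` at mean `design %*% beta` with the
#' covariance of [expand_to_individuals()], evaluated through a
#' factorization-based path (Woodbury/determinant-lemma reduction of the
#' species-block structure, or a dense Cholesky at the lambda = 1 boundary).
#'
#' @param y response vector (per mil).
#' @param design design matrix (n x p), e.g. `build_design(...)$X`.
#' @param beta coefficient vector (length p).
#' @param sigma residual SD: scalar (hom) or per-species vector (het), per
#'   [expand_to_individuals()].
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param correlation `phylo_corr` object.
#' @param species_index species code of each observation.
#' @param conspecific within-species covariance convention.
#' @return the log-likelihood (scalar).
#' @export
loglik <- function(y, design, beta, sigma, lambda, correlation, species_index,
                   conspecific = c("lambda", "independent")) {
  conspecific <- match.arg(conspecific)
  assert_scalar_number(lambda, "lambda", 0, 1)
  X <- if (is.list(design)) design$X else as.matrix(design)
  n <- length(y)
  if (nrow(X) != n || ncol(X) != length(beta))
    stop_input("dimension mismatch between y, design and beta")
  spf <- species_factor(species_index, correlation)
  sig <- resolve_sigma(sigma, levels(spf))
  Tm <- correlation$matrix[levels(spf), levels(spf), drop = FALSE]
  idx <- as.integer(spf)
  s_ind <- sig[idx]
  r <- (y - drop(X %*% beta)) / s_ind
  parts <- mvn_parts(cbind(r), idx, Tm, lambda, conspecific)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(s_ind)) + parts$logdet_M +
            parts$Q[1, 1])
}

## Profile negative log-likelihood over (sigma, lambda): beta is replaced by
## its GLS solution. Returns the nll plus the profiled beta and, for hom,
## the profiled sigma.
profile_nll <- function(y, X, sig_sp, lambda, idx, Tm, hom_profile = FALSE,
                        conspecific = "lambda") {
  n <- length(y)
  s_ind <- sig_sp[idx]
  R <- cbind(y, X) / s_ind
  parts <- mvn_parts(R, idx, Tm, lambda, conspecific)
  Q <- parts$Q
  Qxx <- Q[-1, -1, drop = FALSE]
  Qxy <- Q[-1, 1]
  beta <- tryCatch(solve(Qxx, Qxy), error = function(e)
    stop_input("singular GLS system: design columns are aliased"))
  qres <- max(Q[1, 1] - sum(beta * Qxy), 1e-300)
  if (hom_profile) {
    sigma2 <- qres / n
    nll <- 0.5 * (n * log(2 * pi) + n * log(sigma2) + 2 * sum(log(s_ind)) +
                    parts$logdet_M + n)
    list(nll = nll, beta = beta, sigma_scale = sqrt(sigma2))
  } else {
    nll <- 0.5 * (n * log(2 * pi) + 2 * sum(log(s_ind)) + parts$logdet_M +
                    qres)
    list(nll = nll, beta = beta, sigma_scale = 1)
  }
}

drop_aliased <- function(X) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(list(X = X, dropped = character()))
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  list(X = X[, keep, drop = FALSE], dropped = colnames(X)[-keep])
}

#' Maximum-likelihood fit of one candidate model
#'
#' Fits the Multivariate-Normal mixed model by direct numerical maximum
#' likelihood: the fixed effects beta are profiled out by generalized least
#' squares at every (sigma, lambda), and the remaining parameters are
#' maximized on the transformed scale (log sigma, logit lambda). For the
#' homoscedastic structure sigma^2 is additionally profiled in closed form,
#' reducing the search to one dimension in lambda (a coarse logit-lambda
#' grid brackets the optimum for [stats::optimize()]); heteroscedastic fits
#' use multi-start BFGS. Aliased design columns are dropped before fitting
#' and reported in the result.
#'
#' @param spec a [model_spec()].
#' @param records individual record table with `d2hf` (per mil) and the
#'   covariates the structure needs.
#' @param traits,stations lookup tables merged into the design.
#' @param correlation `phylo_corr` covering all species present.
#' @param lambda_fixed optional fixed lambda (used when
#'   `spec$estimate_lambda` is FALSE, e.g. 0 or 1).
#' @param n_starts number of BFGS starts for heteroscedastic fits.
#' @param seed seed for the start-point jitter (fit is deterministic given
#'   data and this seed).
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param conspecific within-species covariance convention, see
#'   [expand_to_individuals()].
#' @return a `fitted_mvn` object: estimates (`beta`, `sigma`, `lambda`),
#'   `loglik`, parameter count `k`, `n`, `aicc`, and an honest `converged`
#'   flag.
#' @export
fit_ml <- function(spec, records, traits = NULL, stations = NULL,
                   correlation, lambda_fixed = NULL, n_starts = 5,
                   seed = 1, reltol = 1e-8,
                   conspecific = c("lambda", "independent")) {
  conspecific <- match.arg(conspecific)
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(records$d2hf) || anyNA(records$d2hf))
    stop_input("records must carry a complete `d2hf` column")
  y <- as.numeric(records$d2hf)
  n <- length(y)

  des <- build_design(records, traits, stations, spec$fixed_effect_id)
  da <- drop_aliased(des$X)
  X <- da$X
  p <- ncol(X)

  spf <- species_factor(records$species, correlation)
  S <- nlevels(spf)
  idx <- as.integer(spf)
  nj <- tabulate(idx, nbins = S)
  if (spec$variance == "het" && any(nj < 2))
    stop_input(paste0("heteroscedastic variance needs >= 2 individuals per ",
                      "species; offending: ",
                      paste(levels(spf)[nj < 2], collapse = ", ")))
  Tm <- correlation$matrix[levels(spf), levels(spf), drop = FALSE]

  est_lambda <- spec$estimate_lambda && is.null(lambda_fixed)
  if (!est_lambda) {
    lam_fix <- lambda_fixed %||% stop_input(
      "`lambda_fixed` required when spec does not estimate lambda")
    assert_scalar_number(lam_fix, "lambda_fixed", 0, 1)
  }

  ## start values from an OLS fit
  ols <- lm.fit(X, y)
  res <- ols$residuals
  pooled_sd <- max(sqrt(sum(res^2) / n), 1e-3)
  sd_j <- vapply(seq_len(S), function(j) {
    rj <- res[idx == j]
    if (length(rj) >= 2) stats::sd(rj) else pooled_sd
  }, numeric(1))
  sd_j <- pmax(sd_j, 0.25 * pooled_sd, 1e-3)

  converged <- FALSE
  details <- list(dropped_columns = da$dropped)

  if (spec$variance == "hom") {
    nll_lam <- function(lam)
      profile_nll(y, X, rep(1, S), lam, idx, Tm, hom_profile = TRUE,
                  conspecific = conspecific)$nll
    if (est_lambda) {
      ## bracket the optimum on a logit-lambda grid, then refine
      grid_u <- seq(-9, 9, length.out = 37)
      grid_lam <- plogis(grid_u)
      vals <- vapply(grid_lam, nll_lam, numeric(1))
      i0 <- which.min(vals)
      lo <- grid_u[max(1, i0 - 1)]; hi <- grid_u[min(length(grid_u), i0 + 1)]
      opt <- optimize(function(u) nll_lam(plogis(u)), c(lo, hi),
                      tol = 1e-9)
      lam_hat <- plogis(opt$minimum)
      if (nll_lam(0) <= opt$objective) lam_hat <- 0   # boundary check
      converged <- TRUE
    } else {
      lam_hat <- lam_fix
      converged <- TRUE
    }
    pf <- profile_nll(y, X, rep(1, S), lam_hat, idx, Tm, hom_profile = TRUE,
                      conspecific = conspecific)
    sigma_hat <- pf$sigma_scale
    beta_hat <- pf$beta
    ll <- -pf$nll
    sigma_out <- sigma_hat
    n_sigma <- 1L
  } else {
    ## heteroscedastic: theta = (log sigma_1..S [, logit lambda])
    nll_theta <- function(theta) {
      sig <- exp(theta[seq_len(S)])
      lam <- if (est_lambda) plogis(theta[S + 1L]) else lam_fix
      if (any(!is.finite(sig)) || any(sig > 1e6) || any(sig < 1e-8))
        return(1e10)
      out <- tryCatch(
        profile_nll(y, X, sig, lam, idx, Tm, conspecific = conspecific)$nll,
        error = function(e) 1e10)
      if (!is.finite(out)) 1e10 else out
    }
    lam_starts <- c(0.25, 0.5, 0.75, 0.1, 0.9)
    starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
      jit <- if (s == 1L) rep(0, S) else rnorm(S, 0, 0.2)
      th <- log(sd_j) + jit
      if (est_lambda) th <- c(th, qlogis(lam_starts[((s - 1L) %% 5L) + 1L]))
      th
    }))
    best <- NULL
    for (th0 in starts) {
      o <- tryCatch(optim(th0, nll_theta, method = "BFGS",
                          control = list(maxit = 500, reltol = reltol)),
                    error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-12 ||
          (o$value < best$value + 1e-12 && o$convergence == 0 &&
             best$convergence != 0))
        best <- o
    }
    if (is.null(best))
      stop_input("all optimizer starts failed for ", spec$label)
    converged <- best$convergence == 0
    sig_hat <- exp(best$par[seq_len(S)])
    lam_hat <- if (est_lambda) plogis(best$par[S + 1L]) else lam_fix
    pf <- profile_nll(y, X, sig_hat, lam_hat, idx, Tm,
                      conspecific = conspecific)
    beta_hat <- pf$beta
    ll <- -pf$nll
    sigma_out <- setNames(sig_hat, levels(spf))
    n_sigma <- S
    details$optim_value <- best$value
    details$n_starts <- n_starts
  }

  k <- p + n_sigma + as.integer(est_lambda)
  structure(list(
    spec = spec, label = spec$label,
    beta = setNames(as.numeric(beta_hat), colnames(X)),
    sigma = sigma_out, lambda = lam_hat,
    loglik = ll, k = k, n = n,
    aicc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
    converged = converged, species = levels(spf),
    details = details), class = "fitted_mvn")
}

#' @export
print.fitted_mvn <- function(x, ...) {
  cat(sprintf("Model %s (%s): logLik = %.3f, k = %d, n = %d, AICc = %.2f%s\n",
              x$label, FIXED_EFFECT_LABELS[x$spec$fixed_effect_id + 1L],
              x$loglik, x$k, x$n, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  lambda = %.4f\n", x$lambda))
  if (length(x$sigma) == 1L) cat(sprintf("  sigma = %.3f\n", x$sigma))
  else cat("  sigma_j:", paste(sprintf("%s=%.2f", names(x$sigma), x$sigma),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model to a JSON-ready list
#'
#' @param fit a `fitted_mvn` object.
#' @return a plain list suitable for `jsonlite::write_json()`.
#' @export
fitted_to_list <- function(fit) {
  list(label = fit$label,
       fixed_effect_id = fit$spec$fixed_effect_id,
       variance = fit$spec$variance,
       beta = as.list(fit$beta),
       sigma = if (length(fit$sigma) == 1L) unname(fit$sigma)
               else as.list(fit$sigma),
       lambda = fit$lambda, loglik = fit$loglik, k = fit$k, n = fit$n,
       aicc = fit$aicc, converged = fit$converged)
}

## ---- data cloning ---------------------------------------------------------

#' Data-cloning MCMC cross-check of the ML fit
#'
#' Runs a componentwise random-walk Metropolis sampler on the posterior of
#' K cloned copies of the data (likelihood raised to the power K times a
#' proper, diffuse prior). As K grows the posterior mean converges to the
#' maximum-likelihood estimate and K times the posterior variance to the
#' asymptotic ML variance, so the sampler is an independent check on the
#' numerical optimizer. Proposal scales adapt toward ~35% acceptance during
#' burn-in and are then frozen; chains are deterministic given `seed`.
#'
#' @inheritParams fit_ml
#' @param clones_K number of data clones (>= 1).
#' @param n_iter post-burn-in iterations.
#' @param burnin adaptation iterations (discarded).
#' @param seed RNG seed for the chain.
#' @return a `fitted_dc` object: point estimates (posterior means), per
#'   parameter `k_times_var` (K x posterior variance), acceptance rates and
#'   a `mixing_ok` flag (all acceptance rates within \[0.05, 0.8\]).
#' @export
fit_dataclone <- function(spec, records, traits = NULL, stations = NULL,
                          correlation, clones_K = 16, n_iter = 4000,
                          burnin = 1500, seed = 1,
                          conspecific = c("lambda", "independent")) {
  conspecific <- match.arg(conspecific)
  stopifnot(inherits(spec, "model_spec"))
  if (clones_K < 1) stop_input("`clones_K` must be >= 1")
  y <- as.numeric(records$d2hf)
  n <- length(y)
  des <- build_design(records, traits, stations, spec$fixed_effect_id)
  X <- drop_aliased(des$X)$X
  p <- ncol(X)
  spf <- species_factor(records$species, correlation)
  S <- nlevels(spf)
  idx <- as.integer(spf)
  Tm <- correlation$matrix[levels(spf), levels(spf), drop = FALSE]
  n_sigma <- if (spec$variance == "het") S else 1L

  ## theta = (beta_1..p, log sigma_1..n_sigma, logit lambda)
  npar <- p + n_sigma + 1L
  par_names <- c(colnames(X),
                 if (n_sigma == 1L) "log_sigma"
                 else paste0("log_sigma_", levels(spf)),
                 "logit_lambda")

  logpost <- function(theta) {
    beta <- theta[seq_len(p)]
    sig <- exp(theta[p + seq_len(n_sigma)])
    lam <- plogis(theta[npar])
    if (any(!is.finite(sig)) || any(sig > 1e5)) return(-Inf)
    sig_sp <- if (n_sigma == 1L) rep(sig, S) else sig
    s_ind <- sig_sp[idx]
    r <- (y - drop(X %*% beta)) / s_ind
    ll <- tryCatch({
      parts <- mvn_parts(cbind(r), idx, Tm, lam, conspecific)
      -0.5 * (n * log(2 * pi) + 2 * sum(log(s_ind)) + parts$logdet_M +
                parts$Q[1, 1])
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(-Inf)
    ## proper diffuse priors on the working scale
    lp <- sum(dnorm(beta, 0, 500, log = TRUE)) +
      sum(dnorm(theta[p + seq_len(n_sigma)], log(10), 3, log = TRUE)) +
      dnorm(theta[npar], 0, 2.5, log = TRUE)
    clones_K * ll + lp
  }

  ## crude start: OLS + residual SDs, lambda = 0.5
  ols <- lm.fit(X, y)
  sd0 <- max(sqrt(sum(ols$residuals^2) / n), 1e-2)
  theta <- c(ols$coefficients, rep(log(sd0), n_sigma), 0)
  theta[!is.finite(theta)] <- 0

  with_seed(seed, {
    scales <- rep(0.5, npar) / sqrt(clones_K)
    lp_cur <- logpost(theta)
    acc <- integer(npar); prop <- integer(npar)
    draws <- matrix(NA_real_, n_iter, npar)
    total <- burnin + n_iter
    for (it in seq_len(total)) {
      for (j in seq_len(npar)) {
        cand <- theta
        cand[j] <- cand[j] + rnorm(1, 0, scales[j])
        lp_new <- logpost(cand)
        prop[j] <- prop[j] + 1L
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp_cur) {
          theta <- cand; lp_cur <- lp_new; acc[j] <- acc[j] + 1L
        }
      }
      if (it <= burnin && it %% 50L == 0L) {
        rate <- acc / pmax(prop, 1L)
        scales <- scales * exp(0.6 * (rate - 0.35))
        acc[] <- 0L; prop[] <- 0L
      }
      if (it == burnin) { acc[] <- 0L; prop[] <- 0L }
      if (it > burnin) draws[it - burnin, ] <- theta
    }
    rates <- acc / pmax(prop, 1L)
    colnames(draws) <- par_names
    post_mean <- colMeans(draws)
    post_var <- apply(draws, 2, var)
    beta_hat <- post_mean[seq_len(p)]
    sig_hat <- exp(post_mean[p + seq_len(n_sigma)])
    lam_hat <- plogis(post_mean[npar])
    structure(list(
      spec = spec, label = spec$label,
      beta = setNames(beta_hat, colnames(X)),
      sigma = if (n_sigma == 1L) unname(sig_hat)
              else setNames(sig_hat, levels(spf)),
      lambda = lam_hat,
      clones_K = clones_K,
      k_times_var = clones_K * post_var,
      acceptance = setNames(rates, par_names),
      mixing_ok = all(rates >= 0.05 & rates <= 0.8),
      n_iter = n_iter, burnin = burnin, seed = seed,
      draws_summary = list(mean = post_mean, var = post_var)),
      class = "fitted_dc")
  })
}

#' @export
print.fitted_dc <- function(x, ...) {
  cat(sprintf("Data-cloning fit %s: K = %d, lambda = %.4f%s\n",
              x$label, x$clones_K, x$lambda,
              if (x$mixing_ok) "" else "  [POOR MIXING]"))
  if (length(x$sigma) == 1L) cat(sprintf("  sigma = %.3f\n", x$sigma))
  else cat("  sigma_j:", paste(sprintf("%.2f", x$sigma), collapse = ", "), "\n")
  invisible(x)
}
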