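test_that("design matrices follow the candidate structures", {
  fx <- make_study_fixture()
  keep <- fx$species$species[!fx$species$species %in%
                               c("CHSP", "TRES", "REVI", "LEFL", "CEDW", "ALFL")]
  rec <- expand_fixture_records(fx$species[fx$species$species %in% keep, ],
                                means = fixture_species_means(),
                                stations = fx$stations, seed = 2)

  d0 <- build_design(rec, fx$species, fx$stations, 0)
  expect_equal(ncol(d0$X), 1)
  expect_true(all(d0$X == 1))

  d1 <- build_design(rec, fx$species, fx$stations, 1)
  expect_equal(ncol(d1$X), 15)     # intercept + 14 species contrasts

  d3 <- build_design(rec, fx$species, fx$stations, 3)
  expect_equal(ncol(d3$X), 2)      # treatment coding of a 2-level factor

  d2 <- build_design(rec, fx$species, fx$stations, 2)
  expect_equal(ncol(d2$X), 2)      # ground vs non-ground collapse

  # quadratic mass has 3 columns; interactions include main effects
  rec$mass <- 15 + seq_len(nrow(rec)) %% 7
  d10 <- build_design(rec, fx$species, fx$stations, 10)
  expect_equal(ncol(d10$X), 3)
  d12 <- build_design(rec, fx$species, fx$stations, 12)
  expect_setequal(colnames(d12$X),
                  c("(Intercept)", "forsubnonground", "dietO",
                    "forsubnonground:dietO"))

  # missing covariates are reported with the offending records
  rec_bad <- rec
  rec_bad$sex <- NULL
  expect_error(build_design(rec_bad, fx$species, fx$stations, 11), "sex")
  rec_bad <- rec
  rec_bad$mass[3] <- NA
  expect_error(build_design(rec_bad, fx$species, fx$stations, 9),
               rec_bad$individual_id[3])
})

test_that("covariance expansion matches the elementwise formula", {
  corr <- worked_corr()
  sp <- c("A", "A", "B", "B", "C", "C")
  sig <- c(A = 1, B = 2, C = 3)
  lam <- 0.5
  S <- expand_to_individuals(corr, lam, sig, sp)
  # brute-force elementwise oracle: cov = sigma_j sigma_k t_jk lambda off the
  # diagonal (t_jj = 1 for distinct conspecifics), sigma_j^2 on it
  Tjk <- worked_corr()$matrix
  for (i in 1:6) for (l in 1:6) {
    expected <- if (i == l) sig[sp[i]]^2
                else sig[sp[i]] * sig[sp[l]] * Tjk[sp[i], sp[l]] * lam
    expect_equal(unname(S[i, l]), unname(expected))
  }

  # lambda = 0: diagonal matrix of species variances
  S0 <- expand_to_individuals(corr, 0, sig, sp)
  expect_equal(unname(S0), diag(sig[sp]^2), ignore_attr = TRUE)

  # 2 species x 1 individual, hom sigma, lambda = 1: sigma^2 C exactly
  S1 <- expand_to_individuals(corr, 1, 3, c("A", "B", "C"))
  expect_equal(unname(S1), 9 * unname(Tjk), ignore_attr = TRUE)

  # independent conspecific convention zeroes the within-species off-diagonal
  Si <- expand_to_individuals(corr, lam, sig, sp, conspecific = "independent")
  expect_equal(Si[1, 2], 0)
  expect_equal(Si[1, 3], S[1, 3])
})

test_that("log-likelihood agrees with the naive dense oracle", {
  # n = 1 at its mean under unit SD: standard normal density at 0
  c1 <- apply_lambda(matrix(1, 1, 1, dimnames = list("A", "A")), 1)
  expect_equal(loglik(5, cbind(1), 5, 1, 0.3, c1, "A"),
               -0.5 * log(2 * pi))

  # lambda = 0 with het sigma: sum of independent univariate log-densities
  inst <- random_instance(1)
  ll0 <- loglik(inst$y, inst$X, inst$beta, inst$sigma, 0, inst$corr, inst$sp)
  mu <- drop(inst$X %*% inst$beta)
  expect_equal(ll0, sum(dnorm(inst$y, mu, inst$sigma[inst$sp], log = TRUE)))

  # 20 random small instances against the dense determinant-and-solve oracle
  for (s in 1:20) {
    inst <- random_instance(s)
    Sigma <- expand_to_individuals(inst$corr, inst$lambda, inst$sigma, inst$sp)
    got <- loglik(inst$y, inst$X, inst$beta, inst$sigma, inst$lambda,
                  inst$corr, inst$sp)
    want <- dense_mvn_loglik(inst$y, drop(inst$X %*% inst$beta), Sigma)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to record permutation", {
  inst <- random_instance(33)
  ll <- loglik(inst$y, inst$X, inst$beta, inst$sigma, inst$lambda,
               inst$corr, inst$sp)
  set.seed(1); perm <- sample(inst$n)
  ll_p <- loglik(inst$y[perm], inst$X[perm, , drop = FALSE], inst$beta,
                 inst$sigma, inst$lambda, inst$corr, inst$sp[perm])
  expect_equal(ll, ll_p, tolerance = 1e-10)
})

test_that("iid closed form: intercept-only hom fit with lambda 0", {
  set.seed(4)
  y <- rnorm(40, -140, 8)
  rec <- toy_records(c("A", "B", "C", "D"), 10, d2hf = y)
  corr <- correlation_from_tree(simulate_tree_set(4, 1, seed = 2,
                                                  tip_labels = LETTERS[1:4])[[1]])
  f <- fit_ml(model_spec(0, "hom", estimate_lambda = FALSE), rec,
              correlation = corr, lambda_fixed = 0)
  expect_equal(unname(f$beta[1]), mean(y), tolerance = 1e-8)
  expect_equal(unname(f$sigma^2), mean((y - mean(y))^2), tolerance = 1e-8)
  expect_equal(f$k, 2)  # intercept + sigma, lambda fixed
  expect_true(f$converged)
})

test_that("tiny-instance ML matches a dense grid search over (sigma, lambda)", {
  set.seed(9)
  corr <- worked_corr()
  sp <- c("A", "A", "B", "B", "C", "C")
  rec <- toy_records(c("A", "B", "C"), 2,
                     d2hf = rnorm(6, -140, 6))
  f <- fit_ml(model_spec(0, "hom"), rec, correlation = corr)
  X <- cbind(rep(1, 6))
  # independent oracle: dense GLS + dense MVN density on a two-stage grid
  grid_ll <- function(sig, lam) {
    Sigma <- expand_to_individuals(corr, lam, sig, sp)
    Si <- solve(Sigma)
    beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% rec$d2hf)
    dense_mvn_loglik(rec$d2hf, drop(X %*% beta), Sigma)
  }
  coarse <- expand.grid(sig = seq(1, 15, by = 0.25),
                        lam = seq(0, 0.98, by = 0.02))
  vals <- mapply(grid_ll, coarse$sig, coarse$lam)
  b <- coarse[which.max(vals), ]
  fine <- expand.grid(sig = seq(max(0.2, b$sig - 0.3), b$sig + 0.3, by = 0.005),
                      lam = pmin(0.999, pmax(0, seq(b$lam - 0.03, b$lam + 0.03,
                                                    by = 0.001))))
  best <- max(mapply(grid_ll, fine$sig, fine$lam))
  expect_equal(f$loglik, best, tolerance = 1e-3)
  expect_gte(f$loglik, best - 1e-3)   # optimizer at least as good as the grid
})

test_that("one individual per species with lambda 1 reduces to textbook PGLS", {
  set.seed(12)
  labs <- sprintf("sp%02d", 1:8)
  corr <- correlation_from_trees(simulate_tree_set(8, 10, seed = 6))
  rec <- toy_records(labs, 1, d2hf = rnorm(8, -140, 10))
  rec$mass <- runif(8, 10, 30)
  f <- fit_ml(model_spec(9, "hom", estimate_lambda = FALSE), rec,
              correlation = corr, lambda_fixed = 1)
  # direct matrix-inverse GLS oracle under the Brownian covariance C
  C <- corr$matrix
  X <- cbind(1, rec$mass)
  Ci <- solve(C)
  beta_gls <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% rec$d2hf)
  expect_equal(unname(f$beta), drop(beta_gls), tolerance = 1e-6)
})

test_that("likelihood nesting holds across candidate structures", {
  fx <- make_study_fixture()
  keep <- c("AMRE", "CAWA", "CCSP", "COYE", "LISP", "MAWA", "MOWA", "OVEN")
  sp_tab <- fx$species[fx$species$species %in% keep, ]
  corr <- correlation_from_trees(simulate_tree_set(8, 20, seed = 10,
                                                   tip_labels = keep))
  rec <- expand_fixture_records(sp_tab, means = fixture_species_means(),
                                stations = fx$stations, seed = 6)
  f2 <- fit_ml(model_spec(2, "hom"), rec, sp_tab, fx$stations, corr)
  f3 <- fit_ml(model_spec(3, "hom"), rec, sp_tab, fx$stations, corr)
  f12 <- fit_ml(model_spec(12, "hom"), rec, sp_tab, fx$stations, corr)
  expect_gte(f12$loglik, f2$loglik - 1e-6)   # model 12 nests 2 and 3
  expect_gte(f12$loglik, f3$loglik - 1e-6)
  f12h <- fit_ml(model_spec(12, "het"), rec, sp_tab, fx$stations, corr)
  expect_gte(f12h$loglik, f12$loglik - 1e-6) # het nests hom
})

test_that("free species means drive the lambda estimate to zero", {
  # with species indicators in the mean, within-species contrasts identify
  # only sigma_j^2 (1 - lambda) and the determinant penalty is increasing in
  # lambda, so the profile likelihood peaks at the lambda = 0 boundary
  labs <- LETTERS[1:6]
  corr <- correlation_from_trees(simulate_tree_set(6, 30, seed = 5,
                                                   tip_labels = labs))
  cfg <- sim_config(labs, 20, beta = c(-140, 5, -8, 3, 10, -4),
                    sigma = c(4, 6, 8, 10, 14, 20), lambda = 0.6,
                    fixed_effect_id = 1, seed = 9)
  dat <- simulate_dataset(cfg, correlation = corr)
  lls <- sapply(c(0, 0.3, 0.6, 0.9), function(l)
    fit_ml(model_spec(1, "het", estimate_lambda = FALSE), dat,
           correlation = corr, lambda_fixed = l, n_starts = 2)$loglik)
  expect_true(all(diff(lls) < 0))
  f <- fit_ml(model_spec(1, "het"), dat, correlation = corr, n_starts = 2)
  expect_lt(f$lambda, 0.05)
})

test_that("het fits demand two individuals per species", {
  corr <- worked_corr()
  rec <- toy_records(c("A", "B", "C"), c(3, 1, 3),
                     d2hf = rnorm(7, -140, 5))
  expect_error(fit_ml(model_spec(0, "het"), rec, correlation = corr), "B")
})
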