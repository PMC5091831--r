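# Shared builders and independent oracles used across the suite.

# the worked three-taxon tree: corr(A,B) = 0.5, corr with C = 0
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

worked_corr <- function() correlation_from_tree(worked_tree())

# naive dense MVN log-density: explicit determinant and solve, no
# factorization shortcuts — the independent likelihood oracle
dense_mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  q <- drop(t(y - mu) %*% solve(Sigma) %*% (y - mu))
  -0.5 * (n * log(2 * pi) + ld + q)
}

# minimal record table: species codes repeated, optional isotope values
toy_records <- function(species, n_per, d2hf = NULL, year = 2013) {
  sp <- rep(species, n_per)
  out <- data.frame(
    individual_id = paste0(sp, "_", stats::ave(seq_along(sp), sp, FUN = seq_along)),
    species = sp, year = year, age = "ASY", stringsAsFactors = FALSE)
  if (!is.null(d2hf)) out$d2hf <- d2hf
  out
}

# hand-assembled fitted-model stub for ranking arithmetic tests
make_fit <- function(label, loglik, k, n = 100,
                     variance = if (grepl("^Het", label)) "het" else "hom") {
  id <- as.integer(sub("^(Het|Hom)", "", label))
  structure(list(spec = model_spec(id, variance), label = label,
                 loglik = loglik, k = k, n = n,
                 aicc = aicc(loglik, k, n), lambda = 0.1, converged = TRUE),
            class = "fitted_mvn")
}

# random small instance for likelihood cross-checks: a Yule tree over S
# species, heteroscedastic sigmas, random design
random_instance <- function(seed, S_max = 5, n_max = 12) {
  set.seed(seed)
  S <- sample(2:S_max, 1)
  labs <- LETTERS[seq_len(S)]
  tree <- simulate_tree_set(S, 1, seed = seed, tip_labels = labs)[[1]]
  corr <- correlation_from_tree(tree)
  n_per <- pmax(1L, sample.int(max(1L, n_max %/% S), S, replace = TRUE))
  sp <- rep(labs, n_per)
  n <- length(sp)
  X <- cbind(1, rnorm(n))
  beta <- c(-140, 3) + rnorm(2)
  sigma <- setNames(runif(S, 2, 20), labs)
  lambda <- runif(1, 0, 0.95)
  y <- rnorm(n, -140, 15)
  list(tree = tree, corr = corr, sp = sp, X = X, beta = beta,
       sigma = sigma, lambda = lambda, y = y, n = n, S = S)
}
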