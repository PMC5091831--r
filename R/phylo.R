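## Species-level phylogenetic correlation matrices and the lambda transform.

new_phylo_corr <- function(matrix, species) {
  dimnames(matrix) <- list(species, species)
  structure(list(species = species, matrix = matrix), class = "phylo_corr")
}

#' @export
as.matrix.phylo_corr <- function(x, ...) x$matrix

#' @export
print.phylo_corr <- function(x, ...) {
  cat(sprintf("Phylogenetic correlation matrix: %d species\n", length(x$species)))
  print(round(x$matrix, 3))
  invisible(x)
}

validate_phylo_corr <- function(x, tol = 1e-8) {
  m <- x$matrix
  if (!isSymmetric(m, tol = tol)) stop_input("correlation matrix is not symmetric")
  if (any(abs(diag(m) - 1) > tol)) stop_input("correlation diagonal must be 1")
  off <- m[upper.tri(m)]
  if (any(off < -tol | off > 1 + tol))
    stop_input("off-diagonal correlations must lie in [0, 1]")
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop_input("correlation matrix is not positive semidefinite")
  invisible(x)
}

tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

#' Phylogenetic correlation matrix from one ultrametric tree
#'
#' Element (j, k) is the shared root-to-MRCA path length between species j
#' and k, divided by total tree depth, so the diagonal is exactly 1 and the
#' matrix is a correlation matrix (the normalized \eqn{t_{jk}} of the
#' isotope model). Species are returned in alphabetical order.
#'
#' @param tree an ultrametric `phylo` object with unique tip labels.
#' @param tol relative tolerance on the tip-depth spread used to test
#'   ultrametricity (default `1e-6`).
#' @return a `phylo_corr` object (list with `species` and `matrix`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' correlation_from_tree(tr)$matrix
#' @export
correlation_from_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop_input("`tree` must be a `phylo` object")
  if (anyDuplicated(tree$tip.label)) stop_input("tree tip labels must be unique")
  depths <- tip_depths(tree)
  depth <- max(depths)
  if (depth <= 0) stop_input("tree has zero depth")
  if ((depth - min(depths)) / depth > tol)
    stop_input(sprintf(
      "tree is not ultrametric: relative tip-depth spread %.3g exceeds %g",
      (depth - min(depths)) / depth, tol))
  v <- ape::vcv(tree)          # shared path lengths (root-to-MRCA heights)
  m <- v / depth
  diag(m) <- 1
  ord <- order(rownames(m))
  new_phylo_corr(m[ord, ord, drop = FALSE], rownames(m)[ord])
}

#' Pooled phylogenetic correlation over a tree sample
#'
#' Pools a sample of trees (e.g. pseudo-posterior trees) into a single
#' species correlation matrix. With `method = "mean_correlation"` each tree
#' is normalized to unit depth and the per-tree correlation matrices are
#' averaged elementwise; with `method = "mean_height"` the shared node
#' heights are averaged first and the mean-height matrix is then normalized.
#' The diagonal is re-fixed to 1 in both cases.
#'
#' @param trees a `multiPhylo` object or list of `phylo` trees sharing one
#'   leaf set.
#' @param method pooling order, see Details.
#' @param tol ultrametricity tolerance passed to [correlation_from_tree()].
#' @return a `phylo_corr` object.
#' @export
correlation_from_trees <- function(trees,
                                   method = c("mean_correlation", "mean_height"),
                                   tol = 1e-6) {
  method <- match.arg(method)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop_input("empty tree sample")
  labs <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!setequal(trees[[i]]$tip.label, labs) ||
        length(trees[[i]]$tip.label) != length(labs))
      stop_input(sprintf("tree %d has a different leaf set", i))
  }
  if (method == "mean_correlation") {
    acc <- 0
    for (tr in trees) acc <- acc + correlation_from_tree(tr, tol = tol)$matrix
    m <- acc / length(trees)
  } else {
    acc <- 0
    for (tr in trees) {
      depths <- tip_depths(tr)
      if ((max(depths) - min(depths)) / max(depths) > tol)
        stop_input("non-ultrametric tree in sample")
      v <- ape::vcv(tr)
      ord <- order(rownames(v))
      acc <- acc + v[ord, ord, drop = FALSE]
    }
    v <- acc / length(trees)
    m <- v / mean(diag(v))
  }
  diag(m) <- 1
  new_phylo_corr(m, rownames(m))
}

#' Apply Pagel's lambda to a correlation matrix
#'
#' Multiplies every off-diagonal element by `lambda`, leaving the unit
#' diagonal unchanged. For a unit-diagonal matrix C this equals
#' \eqn{\lambda C + (1 - \lambda) I}: `lambda = 0` removes all phylogenetic
#' signal (identity matrix, traits independent of phylogeny) and
#' `lambda = 1` returns C unchanged (Brownian-motion expectation).
#'
#' @param corr a `phylo_corr` object or square unit-diagonal matrix.
#' @param lambda value in \[0, 1\].
#' @return a `phylo_corr` object.
#' @export
apply_lambda <- function(corr, lambda) {
  assert_scalar_number(lambda, "lambda", 0, 1)
  if (inherits(corr, "phylo_corr")) {
    m <- corr$matrix
    species <- corr$species
  } else {
    m <- as.matrix(corr)
    species <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  }
  out <- lambda * m
  diag(out) <- 1
  new_phylo_corr(out, species)
}

#' Write a correlation matrix as CSV
#'
#' @param corr a `phylo_corr` object.
#' @param path output file; first column `species`, remaining columns one per
#'   species in `corr$species` order.
#' @export
write_correlation <- function(corr, path) {
  df <- data.frame(species = corr$species, corr$matrix, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a correlation matrix written by [write_correlation()]
#'
#' @param path CSV file path.
#' @return a `phylo_corr` object.
#' @export
read_correlation <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  species <- as.character(df$species)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- species
  x <- new_phylo_corr(m, species)
  validate_phylo_corr(x)
  x
}
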