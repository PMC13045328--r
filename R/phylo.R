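#' Read and validate an ultrametric phylogeny from Newick
#'
#' Parses Newick text or a file, normalizes tip labels (spaces to
#' underscores), optionally prunes to a species list, and validates that the
#' tree is rooted, has branch lengths, unique tips, and is ultrametric within
#' tolerance. Non-ultrametric trees are rejected rather than silently
#' normalized.
#'
#' @param x Newick string (contains `(`) or a path to a Newick file.
#' @param species Optional character vector; tree is pruned to these tips.
#'   Any requested species missing from the tree is an error.
#' @param tol Relative ultrametricity tolerance on tip depths.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(x, species = NULL, tol = 1e-6) {
  tree <- if (length(x) == 1L && grepl("(", x, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    tryCatch(ape::read.tree(x),
             error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tree)) {
    stop_canopyshift("malformed Newick input", "canopyshift_parse_error")
  }
  tree$tip.label <- normalize_species(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop_canopyshift("duplicate tip labels in tree", "canopyshift_validation_error")
  }
  if (is.null(tree$edge.length)) {
    stop_canopyshift("tree has no branch lengths", "canopyshift_parse_error")
  }
  if (any(tree$edge.length < 0)) {
    stop_canopyshift("negative branch lengths", "canopyshift_validation_error")
  }
  if (!is.null(species)) {
    species <- normalize_species(species)
    missing <- setdiff(species, tree$tip.label)
    if (length(missing)) {
      stop_canopyshift(
        paste0("species missing from tree: ", paste(missing, collapse = ", ")),
        "canopyshift_key_error"
      )
    }
    tree <- ape::keep.tip(tree, species)
  }
  check_ultrametric(tree, tol = tol)
  tree
}

#' Check a tree is ultrametric within relative tolerance
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on the spread of root-to-tip depths.
#' @return Invisibly, the common tip depth.
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  T0 <- max(d)
  if (T0 <= 0 || (max(d) - min(d)) / T0 > tol) {
    stop_canopyshift(
      sprintf("tree is not ultrametric within relative tolerance %g", tol),
      "canopyshift_validation_error"
    )
  }
  invisible(T0)
}

# root-to-tip path lengths, named by tip
tip_depths <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  d <- nd[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Shared root-to-MRCA path lengths between tips under the Brownian
#' convention: `Sigma[i, j]` is the shared path length, the diagonal equals
#' the tip depth T. With `normalize = "depth"` the matrix is divided by T so
#' the diagonal is 1 (used before entering mixed-model random effects); the
#' scaling convention is recorded in the `"scaling"` attribute.
#'
#' @param tree Ultrametric `phylo`.
#' @param normalize `"none"` (raw path lengths) or `"depth"` (unit diagonal).
#' @param tol Ultrametricity tolerance.
#' @return Symmetric positive semi-definite matrix with species dimnames and
#'   attribute `scaling`.
#' @export
brownian_covariance <- function(tree, normalize = c("none", "depth"),
                                tol = 1e-6) {
  normalize <- match.arg(normalize)
  T0 <- check_ultrametric(tree, tol = tol)
  V <- ape::vcv.phylo(tree)
  if (normalize == "depth") V <- V / T0
  attr(V, "scaling") <- normalize
  attr(V, "depth") <- T0
  V
}

# lambda-scaled covariance: off-diagonals multiplied by lambda
lambda_scale <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# profiled multivariate-normal log-likelihood for a given lambda:
# GLS mean and Brownian rate profiled out analytically
lambda_profile_loglik <- function(lambda, V, y) {
  n <- length(y)
  Vl <- lambda_scale(V, lambda)
  R <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_1 <- backsolve(R, forwardsolve(t(R), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  s2 <- sum(r * Vi_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Estimates the phylogenetic-signal parameter lambda in \[0, 1\] by
#' maximizing the multivariate-normal log-likelihood whose covariance is the
#' Brownian matrix with off-diagonals scaled by lambda; the ancestral mean
#' and the Brownian rate are profiled out analytically. Bounded scalar
#' optimization over \[0, 1\]; boundary optima are reported as exactly 0 or
#' 1. A likelihood-ratio test against lambda = 0 (no signal) uses the
#' chi-square(1) reference.
#'
#' @param tree Ultrametric `phylo`.
#' @param x Named numeric vector of one trait value per tip.
#' @return List with `lambda`, `loglik`, `loglik0`, `lrt_stat`, `p_value`.
#' @export
pagel_lambda <- function(tree, x) {
  x <- x[tree$tip.label]
  if (length(x) < 4L || any(!is.finite(x))) {
    stop_canopyshift("need >= 4 tips with finite trait values",
                     "canopyshift_invalid_argument")
  }
  if (stats::sd(x) == 0) {
    stop_canopyshift("trait has zero variance", "canopyshift_degenerate_data")
  }
  V <- ape::vcv.phylo(tree)
  f <- function(l) lambda_profile_loglik(l, V, x)
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  # compare interior optimum against the exact boundaries
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, f, numeric(1))
  i <- which.max(ll)
  lambda_hat <- cand[i]
  if (lambda_hat < 1e-7) lambda_hat <- 0
  if (lambda_hat > 1 - 1e-7) lambda_hat <- 1
  loglik <- ll[i]
  loglik0 <- ll[1]
  stat <- max(0, 2 * (loglik - loglik0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(lambda = lambda_hat, loglik = loglik, loglik0 = loglik0,
       lrt_stat = stat, p_value = p)
}

#' Permute species identities
#'
#' Uniform random permutation of species labels, the null-model move used
#' for standardized effect sizes: trait values (or tree tips) are shuffled
#' among species while community frequencies stay untouched.
#'
#' @param x A `phylo` tree (tip labels permuted), a named vector, or a
#'   matrix/data.frame with species rownames (rows permuted).
#' @param seed Optional integer seed.
#' @return Object of the same shape with species identities permuted.
#' @export
shuffle_tips <- function(x, seed = NULL) {
  with_seed(seed, {
    if (inherits(x, "phylo")) {
      x$tip.label <- sample(x$tip.label)
      x
    } else if (is.matrix(x) || is.data.frame(x)) {
      if (is.null(rownames(x))) {
        stop_canopyshift("matrix must have species rownames",
                         "canopyshift_invalid_argument")
      }
      out <- x[sample(nrow(x)), , drop = FALSE]
      rownames(out) <- rownames(x)
      out
    } else if (!is.null(names(x))) {
      out <- x[sample(length(x))]
      names(out) <- names(x)
      out
    } else {
      stop_canopyshift("input must be a tree, named vector, or named matrix",
                       "canopyshift_invalid_argument")
    }
  })
}
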