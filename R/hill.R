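#' Taxonomic Hill number
#'
#' Effective number of species of order `q`. At `q = 1` this is the
#' exponential of Shannon entropy, `exp(-sum p_i log p_i)` with
#' `0 * log 0 := 0`.
#'
#' @param p Nonnegative abundance vector; normalized to relative abundances.
#' @param q Diversity order (default 1).
#' @return Effective species number.
#' @export
hill_taxonomic <- function(p, q = 1) {
  if (any(p < 0)) {
    stop_canopyshift("abundances must be nonnegative", "canopyshift_invalid_argument")
  }
  if (sum(p) == 0) {
    stop_canopyshift("all-zero abundance vector", "canopyshift_invalid_argument")
  }
  p <- p / sum(p)
  p <- p[p > 0]
  if (abs(q - 1) < 1e-10) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

# entropy helper: sum a*log(a) over positive entries
xlogx_sum <- function(a) {
  a <- a[a > 0]
  sum(a * log(a))
}

#' Phylogenetic Hill-number partitioning of two assemblages
#'
#' Branch-length-weighted mean phylogenetic diversity of order `q` for each
#' era, the equal-weight pooled assemblage (gamma), the normalized mean
#' across the N = 2 assemblages (alpha), multiplicative beta
#' `gamma / alpha` in \[1, N\], and the local overlap similarity which at
#' q = 1 is `1 - log(beta) / log(N)`, in \[0, 1\].
#'
#' At q = 1 the per-assemblage quantity is
#' `exp(-sum_b (L_b / T) a_b log a_b)` over branches `b` with length `L_b`,
#' descendant abundance share `a_b`, and tree depth `T`. On a star tree the
#' partition reduces exactly to the taxonomic partition.
#'
#' @param tree Ultrametric `phylo` covering every species with nonzero
#'   frequency.
#' @param f1,f2 Named (or tree-ordered) nonnegative frequency vectors.
#' @param q Diversity order (default 1; only q = 1 is exercised by the
#'   reported analyses).
#' @return List: `gamma`, `alpha`, `beta`, `similarity`.
#' @export
hill_phylo_partition <- function(tree, f1, f2, q = 1) {
  sp <- union(names(f1)[f1 > 0], names(f2)[f2 > 0])
  if (is.null(names(f1))) {
    stopifnot(length(f1) == ape::Ntip(tree), length(f2) == ape::Ntip(tree))
    names(f1) <- names(f2) <- tree$tip.label
    sp <- tree$tip.label
  }
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing)) {
    stop_canopyshift(
      paste0("species absent from tree: ", paste(missing, collapse = ", ")),
      "canopyshift_key_error"
    )
  }
  br <- branch_structure(tree)
  P <- cbind(f1[tree$tip.label], f2[tree$tip.label])
  P[is.na(P)] <- 0
  P <- sweep(P, 2, colSums(P), "/")
  phylo_partition_core(br, P, q)
}

# incidence of tips under each branch, with branch lengths and depth
branch_structure <- function(tree) {
  check_ultrametric(tree)
  ntip <- ape::Ntip(tree)
  tips_under <- lapply(seq_len(nrow(tree$edge)), function(i) {
    node <- tree$edge[i, 2]
    if (node <= ntip) node else {
      unlist(phangorn_descendants(tree, node, ntip))
    }
  })
  B <- matrix(0, nrow(tree$edge), ntip,
              dimnames = list(NULL, tree$tip.label))
  for (i in seq_along(tips_under)) B[i, tips_under[[i]]] <- 1
  list(B = B, L = tree$edge.length, T = max(tip_depths(tree)))
}

# tip descendants of an internal node (iterative, no extra deps)
phangorn_descendants <- function(tree, node, ntip) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

# q-order partition given branch incidence and per-assemblage rel. abundances
phylo_partition_core <- function(br, P, q = 1) {
  N <- ncol(P)
  Abk <- br$B %*% P                  # branch abundance share per assemblage
  abar <- rowMeans(Abk)              # equal-weight pooled assemblage
  w <- br$L / br$T
  if (abs(q - 1) < 1e-10) {
    gamma <- exp(-sum(w * ifelse(abar > 0, abar * log(abar), 0)))
    Ak <- Abk / N
    alpha <- exp(-sum(w * ifelse(Ak > 0, Ak * log(Ak), 0))) / N
  } else {
    gamma <- sum(w * abar^q)^(1 / (1 - q))
    alpha <- (1 / N) * sum(w * (Abk / N)^q)^(1 / (1 - q))
  }
  beta <- min(max(gamma / alpha, 1), N)
  sim <- if (abs(q - 1) < 1e-10) {
    1 - log(beta) / log(N)
  } else {
    1 - (beta^(1 - q) - 1) / (N^(1 - q) - 1)
  }
  list(gamma = gamma, alpha = alpha, beta = beta,
       similarity = min(max(sim, 0), 1))
}

#' Functional (distance-based) Hill-number partitioning of two assemblages
#'
#' Rao quadratic entropy `Q = sum_ij d_ij p_i p_j` of the pooled assemblage
#' normalizes the pairwise distances; at q = 1 the gamma quantity is the
#' exponential pair-entropy `exp(-sum_ij (d_ij/Q) g_i g_j log(g_i g_j))` of
#' the pooled relative abundances `g`, and alpha sums the distance-weighted
#' pair entropy over all ordered pairs of the N assemblages, divided by N^2.
#' Beta `gamma / alpha` lies in \[1, N^2\]; the q = 1 local overlap
#' similarity is `1 - log(beta) / log(N^2)`.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal,
#'   species in rows/columns.
#' @param f1,f2 Nonnegative frequency vectors matching `d`'s species order
#'   (or named).
#' @param q Diversity order (default 1).
#' @param tol Asymmetry tolerance for `d`.
#' @return List: `gamma`, `alpha`, `beta`, `similarity`, `Q` (pooled Rao Q).
#' @export
hill_functional_partition <- function(d, f1, f2, q = 1, tol = 1e-8) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > tol) {
    stop_canopyshift("distance matrix is asymmetric beyond tolerance",
                     "canopyshift_validation_error")
  }
  if (any(d < 0)) {
    stop_canopyshift("negative distances", "canopyshift_validation_error")
  }
  if (!is.null(names(f1)) && !is.null(rownames(d))) {
    f1 <- f1[rownames(d)]
    f2 <- f2[rownames(d)]
  }
  P <- cbind(f1, f2)
  P[is.na(P)] <- 0
  P <- sweep(P, 2, colSums(P), "/")
  functional_partition_core(d, P, q)
}

functional_partition_core <- function(d, P, q = 1) {
  N <- ncol(P)
  g <- rowMeans(P)
  Q <- c(g %*% d %*% g)
  if (Q <= 0) {
    # all mass on one species or all distances zero: define as identical
    return(list(gamma = 1, alpha = 1, beta = 1, similarity = 1, Q = Q))
  }
  W <- d / Q
  M <- outer(g, g)
  if (abs(q - 1) < 1e-10) {
    gamma <- exp(-sum(W * M * ifelse(M > 0, log(M), 0)))
    s <- 0
    for (k in seq_len(N)) {
      for (m in seq_len(N)) {
        A <- outer(P[, k], P[, m]) / N^2
        s <- s + sum(W * A * ifelse(A > 0, log(A), 0))
      }
    }
    alpha <- exp(-s) / N^2
  } else {
    gamma <- sum(W * M^q)^(1 / (1 - q))
    s <- 0
    for (k in seq_len(N)) {
      for (m in seq_len(N)) {
        A <- outer(P[, k], P[, m]) / N^2
        s <- s + sum(W * A^q)
      }
    }
    alpha <- (1 / N^2) * s^(1 / (1 - q))
  }
  beta <- min(max(gamma / alpha, 1), N^2)
  sim <- if (abs(q - 1) < 1e-10) {
    1 - log(beta) / log(N^2)
  } else {
    1 - (beta^(1 - q) - 1) / (N^(2 * (1 - q)) - 1)
  }
  list(gamma = gamma, alpha = alpha, beta = beta,
       similarity = min(max(sim, 0), 1), Q = Q)
}
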