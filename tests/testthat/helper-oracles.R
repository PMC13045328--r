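# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Brownian covariance by explicit path enumeration: Sigma[i, j] is the
# depth of the MRCA of tips i and j (root-to-node path length).
oracle_brownian_cov <- function(tree) {
  ntip <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree)
  V <- matrix(NA_real_, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      V[i, j] <- if (i == j) depths[i] else depths[mr[i, j]]
    }
  }
  V
}

# q = 1 phylogenetic partition by literal branch enumeration using
# ape::prop.part for clade membership (distinct from the package's
# edge-walk construction).
oracle_phylo_partition_q1 <- function(tree, f1, f2) {
  ntip <- ape::Ntip(tree)
  T0 <- max(ape::node.depth.edgelength(tree)[seq_len(ntip)])
  # clade membership per edge: tips descending from the child node
  pp <- ape::prop.part(tree)
  clade <- function(node) {
    if (node <= ntip) node else pp[[node - ntip]]
  }
  p1 <- f1 / sum(f1); p2 <- f2 / sum(f2)
  H <- function(weights) {
    s <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- clade(tree$edge[e, 2])
      a <- sum(weights[tips])
      if (a > 0) s <- s + (tree$edge.length[e] / T0) * a * log(a)
    }
    -s
  }
  gamma <- exp(H((p1 + p2) / 2))
  # alpha: joint entropy over assemblage copies at weight 1/2 each
  s <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- clade(tree$edge[e, 2])
    for (p in list(p1, p2)) {
      a <- sum(p[tips]) / 2
      if (a > 0) s <- s + (tree$edge.length[e] / T0) * a * log(a)
    }
  }
  alpha <- exp(-s) / 2
  beta <- gamma / alpha
  list(gamma = gamma, alpha = alpha, beta = beta,
       similarity = 1 - log(beta) / log(2))
}

# q = 1 functional partition by literal evaluation of the double sums
oracle_functional_partition_q1 <- function(d, f1, f2) {
  p1 <- f1 / sum(f1); p2 <- f2 / sum(f2)
  g <- (p1 + p2) / 2
  S <- length(g)
  Q <- 0
  for (i in 1:S) for (j in 1:S) Q <- Q + d[i, j] * g[i] * g[j]
  hg <- 0
  for (i in 1:S) for (j in 1:S) {
    m <- g[i] * g[j]
    if (m > 0) hg <- hg + (d[i, j] / Q) * m * log(m)
  }
  gamma <- exp(-hg)
  ha <- 0
  for (pk in list(p1, p2)) for (pm in list(p1, p2)) {
    for (i in 1:S) for (j in 1:S) {
      a <- pk[i] * pm[j] / 4
      if (a > 0) ha <- ha + (d[i, j] / Q) * a * log(a)
    }
  }
  alpha <- exp(-ha) / 4
  beta <- gamma / alpha
  list(gamma = gamma, alpha = alpha, beta = beta,
       similarity = 1 - log(beta) / log(4))
}

# small balanced ultrametric test trees
tree_star4 <- function() ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
tree_bal4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
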