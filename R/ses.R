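#' Functional distance matrix from species-mean traits
#'
#' Euclidean distance on z-scored species-mean traits by default (the
#' conventional choice when no metric is mandated), or Gower distance
#' (range-normalized mean absolute difference) for mixed/robust use.
#'
#' @param traits Numeric matrix/data.frame, species in rows.
#' @param metric `"euclidean"` or `"gower"`.
#' @param scale Z-score columns first (euclidean only).
#' @return Symmetric distance matrix with species dimnames.
#' @export
functional_distance <- function(traits, metric = c("euclidean", "gower"),
                                scale = TRUE) {
  metric <- match.arg(metric)
  X <- as.matrix(traits)
  if (metric == "euclidean") {
    if (scale) {
      sds <- apply(X, 2, stats::sd)
      sds[sds == 0] <- 1
      X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
    }
    d <- as.matrix(stats::dist(X))
  } else {
    rng <- apply(X, 2, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    Xs <- sweep(X, 2, rng, "/")
    d <- matrix(0, nrow(X), nrow(X))
    for (j in seq_len(ncol(Xs))) {
      d <- d + abs(outer(Xs[, j], Xs[, j], "-"))
    }
    d <- d / ncol(Xs)
    dimnames(d) <- list(rownames(X), rownames(X))
  }
  d
}

# q = 1 functional similarity of one site pair, streamlined for permutation
# loops: abundance-dependent pieces are precomputed once per site.
func_site_precompute <- function(p1, p2) {
  s1 <- sum(p1); s2 <- sum(p2)
  p1 <- if (s1 > 0) p1 / s1 else p1
  p2 <- if (s2 > 0) p2 / s2 else p2
  g <- (p1 + p2) / 2
  G <- outer(g, g)
  U <- ifelse(G > 0, G * log(G), 0)
  C <- matrix(0, length(g), length(g))
  for (a in list(p1, p2)) {
    for (b in list(p1, p2)) {
      A <- outer(a, b) / 4
      C <- C + ifelse(A > 0, A * log(A), 0)
    }
  }
  list(G = G, U = U, C = C)
}

func_site_similarity <- function(d, pre) {
  Q <- sum(d * pre$G)
  if (Q <= 0) return(NA_real_)
  lnbeta <- (sum(d * pre$C) - sum(d * pre$U)) / Q + log(4)
  lnbeta <- min(max(lnbeta, 0), log(4))
  1 - lnbeta / log(4)
}

# q = 1 phylogenetic similarity of one site pair given branch incidence
phylo_site_similarity <- function(br, p1, p2, perm = NULL) {
  B <- if (is.null(perm)) br$B else br$B[, perm, drop = FALSE]
  s1 <- sum(p1); s2 <- sum(p2)
  a1 <- as.vector(B %*% (if (s1 > 0) p1 / s1 else p1))
  a2 <- as.vector(B %*% (if (s2 > 0) p2 / s2 else p2))
  w <- br$L / br$T
  abar <- (a1 + a2) / 2
  hg <- sum(w * ifelse(abar > 0, abar * log(abar), 0))
  A <- cbind(a1, a2) / 2
  ha <- sum(w * ifelse(A > 0, A * log(A), 0))
  lnbeta <- ha - hg + log(2)
  lnbeta <- min(max(lnbeta, 0), log(2))
  1 - lnbeta / log(2)
}

#' Permutation-null standardized effect sizes of site similarity
#'
#' Observed functional or phylogenetic q = 1 similarity per paired site,
#' against a null distribution built by shuffling species identities on the
#' trait matrix (functional) or across the tree's tips (phylogenetic) while
#' holding species' frequencies constant within sites.
#' `SES = (observed - null mean) / null sd`; a null sd of (numerically)
#' zero flags the SES as undefined rather than silently zero.
#'
#' @param comm1,comm2 Site-by-species frequency matrices, one per era, same
#'   dimnames.
#' @param facet `"functional"` or `"phylogenetic"`.
#' @param traits Species-mean trait matrix (functional facet); species rows
#'   must match community columns.
#' @param tree Ultrametric `phylo` (phylogenetic facet).
#' @param n_perm Number of permutations (>= 100; default 999).
#' @param seed Integer seed recorded in the output.
#' @param metric Distance metric passed to [functional_distance()].
#' @return data.frame per site: `site`, `facet`, `q`, `observed`,
#'   `null_mean`, `null_sd`, `ses`, `n_perm`, `seed`, `degenerate`.
#' @export
similarity_ses <- function(comm1, comm2,
                           facet = c("functional", "phylogenetic"),
                           traits = NULL, tree = NULL,
                           n_perm = 999, seed = NULL,
                           metric = "euclidean") {
  facet <- match.arg(facet)
  if (n_perm < 100) {
    stop_canopyshift("n_perm must be >= 100", "canopyshift_invalid_argument")
  }
  stopifnot(identical(dim(comm1), dim(comm2)))
  sp <- colnames(comm1)
  m <- nrow(comm1)
  sites <- rownames(comm1)
  if (is.null(sites)) sites <- as.character(seq_len(m))

  if (facet == "functional") {
    if (is.null(traits)) {
      stop_canopyshift("functional facet needs a trait matrix",
                       "canopyshift_invalid_argument")
    }
    X <- as.matrix(traits)
    if (!is.null(rownames(X)) && !is.null(sp)) X <- X[sp, , drop = FALSE]
    d <- functional_distance(X, metric = metric)
    S <- ncol(comm1)
    pre <- lapply(seq_len(m), function(i) func_site_precompute(comm1[i, ], comm2[i, ]))
    obs <- vapply(seq_len(m), function(i) func_site_similarity(d, pre[[i]]),
                  numeric(1))
    null_mat <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        perm <- sample.int(S)
        dp <- d[perm, perm]
        vapply(seq_len(m), function(i) func_site_similarity(dp, pre[[i]]),
               numeric(1))
      }, numeric(m))
    })
  } else {
    if (is.null(tree)) {
      stop_canopyshift("phylogenetic facet needs a tree",
                       "canopyshift_invalid_argument")
    }
    if (!is.null(sp)) {
      missing <- setdiff(sp, tree$tip.label)
      if (length(missing)) {
        stop_canopyshift(
          paste0("species absent from tree: ", paste(missing, collapse = ", ")),
          "canopyshift_key_error"
        )
      }
      tree <- ape::keep.tip(tree, sp)
      ord <- match(tree$tip.label, sp)
    } else {
      ord <- seq_len(ape::Ntip(tree))
    }
    br <- branch_structure(tree)
    c1 <- comm1[, ord, drop = FALSE]
    c2 <- comm2[, ord, drop = FALSE]
    S <- ncol(c1)
    obs <- vapply(seq_len(m), function(i) {
      phylo_site_similarity(br, c1[i, ], c2[i, ])
    }, numeric(1))
    null_mat <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        perm <- sample.int(S)
        vapply(seq_len(m), function(i) {
          phylo_site_similarity(br, c1[i, ], c2[i, ], perm = perm)
        }, numeric(1))
      }, numeric(m))
    })
  }
  null_mat <- matrix(null_mat, nrow = m)
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1, stats::sd)
  degenerate <- !is.finite(sdv) | sdv < 1e-12 | !is.finite(obs)
  ses <- ifelse(degenerate, NA_real_, (obs - mu) / sdv)
  data.frame(site = sites, facet = facet, q = 1, observed = obs,
             null_mean = mu, null_sd = sdv, ses = ses,
             n_perm = n_perm,
             seed = if (is.null(seed)) NA_integer_ else seed,
             degenerate = degenerate)
}

#' t-test of standardized effect sizes against zero
#'
#' One-sample two-sided t of the site SES values against 0 (default, the
#' design implied by a df of sites-minus-one), or a paired t of the observed
#' similarities against their per-site null means.
#'
#' @param records data.frame from [similarity_ses()], or a numeric SES
#'   vector for `type = "one_sample"`.
#' @param type `"one_sample"` or `"paired"`.
#' @return List with `t`, `df`, `p_value`, `method`.
#' @export
ses_ttest <- function(records, type = c("one_sample", "paired")) {
  type <- match.arg(type)
  if (is.data.frame(records)) {
    x <- records$ses[!records$degenerate & is.finite(records$ses)]
  } else {
    x <- records[is.finite(records)]
  }
  if (type == "one_sample") {
    if (length(x) < 2L) {
      stop_canopyshift("need >= 2 finite SES values", "canopyshift_insufficient_data")
    }
    if (stats::sd(x) == 0) {
      if (all(x == 0)) {
        return(list(t = 0, df = length(x) - 1, p_value = 1,
                    method = "degenerate: all SES zero"))
      }
      stop_canopyshift("zero variance in SES", "canopyshift_degenerate_test")
    }
    tt <- stats::t.test(x, mu = 0)
  } else {
    stopifnot(is.data.frame(records))
    ok <- is.finite(records$observed) & is.finite(records$null_mean)
    if (sum(ok) < 2L) {
      stop_canopyshift("need >= 2 finite pairs", "canopyshift_insufficient_data")
    }
    tt <- stats::t.test(records$observed[ok], records$null_mean[ok],
                        paired = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = tt$method)
}
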