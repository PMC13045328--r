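#' Define a simulation scenario
#'
#' Collects the generative parameters for synthetic paired-era community
#' data: the zero-inflated Poisson frequency model with site, species,
#' phylogenetic, nested-phylogenetic, and trait-slope random effects, plus
#' lambda-scaled Brownian trait evolution on a pure-birth tree. Defaults
#' emulate the Wisconsin resurvey design: 19 species, 138 paired sites,
#' 80 stems per site.
#'
#' @param n_species,n_sites,stems_per_site Design sizes.
#' @param birth_rate Pure-birth rate for tree simulation.
#' @param lambda_trait Named vector of Pagel's lambda per simulated trait
#'   (in \[0, 1\]); the first trait is the designated "mesophyte score"
#'   that drives era-2 turnover.
#' @param sigma_bm Named vector of Brownian rates per trait.
#' @param beta0 Global log-mean frequency; default
#'   `log(stems_per_site / n_species)`.
#' @param beta1 Named vector of per-trait fixed-effect slopes.
#' @param sigma2_site,sigma2_spp,sigma2_spp_phy,sigma2_nested,sigma2_slope
#'   Random-effect variances (all >= 0).
#' @param pi_zero Structural-zero probability in \[0, 1\].
#' @param turnover Era-2 mean-shift magnitude on species log-frequencies,
#'   applied proportionally to the standardized mesophyte score.
#' @param seed Master seed for all draws.
#' @return A `canopyshift_scenario` list.
#' @export
simulation_scenario <- function(n_species = 19, n_sites = 138,
                                stems_per_site = 80, birth_rate = 1,
                                lambda_trait = c(meso_score = 0.8),
                                sigma_bm = stats::setNames(
                                  rep(1, length(lambda_trait)),
                                  names(lambda_trait)),
                                beta0 = log(stems_per_site / n_species),
                                beta1 = stats::setNames(
                                  rep(0.4, length(lambda_trait)),
                                  names(lambda_trait)),
                                sigma2_site = 0.05, sigma2_spp = 0.5,
                                sigma2_spp_phy = 0.3, sigma2_nested = 0.5,
                                sigma2_slope = 0.25, pi_zero = 0.1,
                                turnover = 0.5, seed = 1L) {
  if (n_species < 2) {
    stop_canopyshift("n_species must be >= 2", "canopyshift_invalid_argument")
  }
  if (stems_per_site <= 0) {
    stop_canopyshift("stems_per_site must be positive", "canopyshift_invalid_argument")
  }
  if (pi_zero < 0 || pi_zero > 1) {
    stop_canopyshift("pi_zero must lie in [0, 1]", "canopyshift_invalid_argument")
  }
  vars <- c(sigma2_site, sigma2_spp, sigma2_spp_phy, sigma2_nested,
            sigma2_slope)
  if (any(vars < 0)) {
    stop_canopyshift("variances must be nonnegative", "canopyshift_invalid_argument")
  }
  if (any(lambda_trait < 0 | lambda_trait > 1)) {
    stop_canopyshift("lambda_trait must lie in [0, 1]", "canopyshift_invalid_argument")
  }
  structure(list(
    n_species = n_species, n_sites = n_sites,
    stems_per_site = stems_per_site, birth_rate = birth_rate,
    lambda_trait = lambda_trait, sigma_bm = sigma_bm, beta0 = beta0,
    beta1 = beta1, sigma2_site = sigma2_site, sigma2_spp = sigma2_spp,
    sigma2_spp_phy = sigma2_spp_phy, sigma2_nested = sigma2_nested,
    sigma2_slope = sigma2_slope, pi_zero = pi_zero, turnover = turnover,
    seed = as.integer(seed)
  ), class = "canopyshift_scenario")
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule (pure-birth) tree with branch lengths rescaled to unit root-to-tip
#' depth; the simplest process producing rooted, bifurcating, ultrametric
#' trees with exchangeable tips.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Per-lineage speciation rate.
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @return Ultrametric `phylo` with tips `sp01 ... spNN`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) {
    stop_canopyshift("n_species must be >= 2", "canopyshift_invalid_argument")
  }
  with_seed(seed, {
    tree <- if (n_species == 2) {
      ape::read.tree(text = "(sp01:1,sp02:1);")
    } else {
      ape::rphylo(n_species, birth = birth_rate, death = 0)
    }
    depth <- max(tip_depths(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
    tree
  })
}

#' Simulate lambda-scaled Brownian traits on a tree
#'
#' Draws one value per tip from a multivariate normal with covariance
#' `sigma2 * Sigma(lambda)`, where `Sigma(lambda)` keeps the Brownian
#' diagonal and scales off-diagonals by lambda. Independent draws per
#' trait.
#'
#' @param tree Ultrametric `phylo`.
#' @param lambda Named vector of lambda values in \[0, 1\], one per trait.
#' @param sigma2 Brownian rate(s); recycled to `length(lambda)`.
#' @param seed Integer seed.
#' @return data.frame, species in rows (rownames), one column per trait.
#' @export
simulate_traits <- function(tree, lambda = c(trait1 = 1), sigma2 = 1,
                            seed = NULL) {
  if (any(lambda < 0 | lambda > 1)) {
    stop_canopyshift("lambda must lie in [0, 1]", "canopyshift_invalid_argument")
  }
  check_ultrametric(tree)
  V <- ape::vcv.phylo(tree)
  n <- nrow(V)
  sigma2 <- rep_len(sigma2, length(lambda))
  nm <- names(lambda)
  if (is.null(nm)) nm <- paste0("trait", seq_along(lambda))
  with_seed(seed, {
    cols <- lapply(seq_along(lambda), function(j) {
      S <- sigma2[j] * lambda_scale(V, lambda[j])
      if (all(S == 0)) rep(0, n) else
        as.vector(MASS::mvrnorm(1, mu = rep(0, n), Sigma = S))
    })
    out <- as.data.frame(stats::setNames(cols, nm))
    rownames(out) <- tree$tip.label
    out
  })
}

# draw one era's linear predictor given realized effects
zip_linear_predictor <- function(beta0, a_site, c_spp, d_phy, slopes,
                                 beta1, traitM, z_nested, shift = 0) {
  m <- length(a_site)
  n <- length(c_spp)
  eta <- matrix(beta0, m, n)
  eta <- eta + a_site + matrix(c_spp + d_phy + shift, m, n, byrow = TRUE)
  if (length(beta1)) {
    for (t in seq_along(beta1)) {
      eta <- eta + outer(beta1[t] + slopes[, t], traitM[, t])
    }
  }
  eta + z_nested
}

#' Simulate a paired-era community table
#'
#' Counts are drawn from the zero-inflated Poisson generative model: with
#' probability `pi_zero` a structural zero, otherwise Poisson with log-mean
#' `beta0 + a_site + c_spp + d_spp_phy + (beta1 + f_site) * trait +
#' z_nested`, where `d` has covariance `sigma2_spp_phy * Sigma_phy`
#' (depth-normalized) and the nested clustering term `z` has covariance
#' `kron(I_m, sigma2_nested * Sigma_phy)`. Era 2 re-draws the site and
#' nested effects and adds a mean shift `turnover * standardized mesophyte
#' score` to the species log-frequencies, so temporal turnover has a known
#' direction. All realized effects are returned for recovery testing.
#'
#' @param scenario A [simulation_scenario()].
#' @param tree Optional tree (simulated from the scenario if `NULL`).
#' @param traits Optional trait data.frame indexed by tree tips (simulated
#'   if `NULL`).
#' @return List: `era1`, `era2` (site x species count matrices), `long`
#'   (canonical long table), `tree`, `traits`, `effects`, `scenario`.
#' @export
simulate_community_pair <- function(scenario, tree = NULL, traits = NULL) {
  stopifnot(inherits(scenario, "canopyshift_scenario"))
  sc <- scenario
  if (is.null(tree)) {
    tree <- simulate_tree(sc$n_species, sc$birth_rate,
                          seed = sub_seed(sc$seed, 1L))
  }
  if (is.null(traits)) {
    traits <- simulate_traits(tree, sc$lambda_trait, sc$sigma_bm,
                              seed = sub_seed(sc$seed, 2L))
  }
  if (!setequal(rownames(traits), tree$tip.label)) {
    stop_canopyshift("traits must be indexed by tree tips",
                     "canopyshift_invalid_argument")
  }
  traitM <- as.matrix(traits[tree$tip.label, , drop = FALSE])
  m <- sc$n_sites
  n <- sc$n_species
  Sigma <- brownian_covariance(tree, normalize = "depth")
  Lchol <- t(chol(Sigma + diag(1e-10, n)))
  beta1 <- sc$beta1[colnames(traitM)]
  beta1[is.na(beta1)] <- 0
  with_seed(sub_seed(sc$seed, 3L), {
    a1 <- stats::rnorm(m, 0, sqrt(sc$sigma2_site))
    a2 <- stats::rnorm(m, 0, sqrt(sc$sigma2_site))
    c_spp <- stats::rnorm(n, 0, sqrt(sc$sigma2_spp))
    d_phy <- as.vector(Lchol %*% stats::rnorm(n, 0, sqrt(sc$sigma2_spp_phy)))
    slopes <- matrix(stats::rnorm(m * ncol(traitM), 0,
                                  sqrt(sc$sigma2_slope)), m, ncol(traitM))
    z1 <- t(Lchol %*% matrix(stats::rnorm(m * n, 0, sqrt(sc$sigma2_nested)),
                             n, m))
    z2 <- t(Lchol %*% matrix(stats::rnorm(m * n, 0, sqrt(sc$sigma2_nested)),
                             n, m))
    meso <- traitM[, 1]
    meso_z <- if (stats::sd(meso) > 0) (meso - mean(meso)) / stats::sd(meso)
              else meso * 0
    eta1 <- zip_linear_predictor(sc$beta0, a1, c_spp, d_phy, slopes, beta1,
                                 traitM, z1)
    eta2 <- zip_linear_predictor(sc$beta0, a2, c_spp, d_phy, slopes, beta1,
                                 traitM, z2, shift = sc$turnover * meso_z)
    draw <- function(eta) {
      y <- matrix(stats::rpois(m * n, exp(pmin(eta, 20))), m, n)
      zero <- matrix(stats::runif(m * n) < sc$pi_zero, m, n)
      y[zero] <- 0L
      dimnames(y) <- list(sprintf("site%03d", seq_len(m)), tree$tip.label)
      y
    }
    era1 <- draw(eta1)
    era2 <- draw(eta2)
    long <- rbind(community_to_long(era1, era = 1L),
                  community_to_long(era2, era = 2L))
    list(era1 = era1, era2 = era2, long = long, tree = tree,
         traits = as.data.frame(traitM),
         effects = list(a1 = a1, a2 = a2, c_spp = c_spp, d_phy = d_phy,
                        slopes = slopes, z1 = z1, z2 = z2,
                        eta1 = eta1, eta2 = eta2, meso_shift = sc$turnover * meso_z),
         scenario = sc)
  })
}

#' Convert a site-by-species matrix to the canonical long table
#'
#' @param mat Count matrix with site rownames and species colnames.
#' @param era Era label.
#' @return data.frame with `site`, `species`, `era`, `count`.
#' @export
community_to_long <- function(mat, era) {
  data.frame(
    site = rep(rownames(mat), times = ncol(mat)),
    species = rep(colnames(mat), each = nrow(mat)),
    era = era,
    count = as.vector(mat),
    stringsAsFactors = FALSE
  )
}

#' Convert the canonical long table to a site-by-species matrix
#'
#' @param long data.frame with `site`, `species`, `era`, `count`.
#' @param era Which era to extract.
#' @return Count matrix, sites in rows.
#' @export
long_to_matrix <- function(long, era) {
  d <- long[long$era == era, , drop = FALSE]
  sites <- sort(unique(d$site))
  sp <- sort(unique(d$species))
  mat <- matrix(0, length(sites), length(sp), dimnames = list(sites, sp))
  mat[cbind(match(d$site, sites), match(d$species, sp))] <- d$count
  mat
}

#' Write simulated data as plain-text files
#'
#' Community pairs as long-format CSV (`site,species,era,count`), traits as
#' CSV with a `species` column, tree as Newick.
#'
#' @param sim Result of [simulate_community_pair()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    community = file.path(dir, "community.csv"),
    traits = file.path(dir, "traits.csv"),
    tree = file.path(dir, "tree.nwk")
  )
  utils::write.csv(sim$long, paths[["community"]], row.names = FALSE)
  tr <- data.frame(species = rownames(sim$traits), sim$traits,
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(tr, paths[["traits"]], row.names = FALSE)
  ape::write.tree(sim$tree, paths[["tree"]])
  invisible(paths)
}
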