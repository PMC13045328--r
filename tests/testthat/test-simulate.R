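test_that("tree simulation is ultrametric, reproducible, and exchangeable", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)
  expect_equal(unname(canopyshift:::tip_depths(t2)),
               rep(max(canopyshift:::tip_depths(t2)), 2))

  a <- ape::write.tree(simulate_tree(19, seed = 99))
  b <- ape::write.tree(simulate_tree(19, seed = 99))
  expect_identical(a, b)

  mpd <- sapply(1:100, function(s) {
    tr <- simulate_tree(50, seed = s)
    mean(ape::cophenetic.phylo(tr))
  })
  expect_true(all(mpd > 0))
  depths <- sapply(1:20, function(s) {
    max(canopyshift:::tip_depths(simulate_tree(50, seed = s)))
  })
  expect_equal(depths, rep(1, 20), tolerance = 1e-9)
  expect_error(simulate_tree(1), class = "canopyshift_invalid_argument")
})

test_that("trait simulation honors lambda and the Brownian closed form", {
  # lambda = 0: sister tips uncorrelated
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  vals <- t(sapply(1:500, function(s) {
    simulate_traits(tr, lambda = c(x = 0), seed = 7000 + s)[c("A", "B"), 1]
  }))
  expect_lt(abs(cor(vals[, 1], vals[, 2])), 0.12)

  # lambda = 1 on a 2-tip tree of depth T: Var(x1 - x2) = 2 sigma^2 T
  t2 <- read_newick("(A:2,B:2);")
  difs <- sapply(1:1000, function(s) {
    x <- simulate_traits(t2, lambda = c(x = 1), sigma2 = 1.5,
                         seed = 8000 + s)[, 1]
    x[1] - x[2]
  })
  expect_equal(var(difs), 2 * 1.5 * 2, tolerance = 0.15)

  # zero rate: all tips at the root state
  z <- simulate_traits(simulate_tree(6, seed = 2), lambda = c(x = 1),
                       sigma2 = 0, seed = 3)
  expect_true(all(z[, 1] == 0))
  expect_error(simulate_traits(t2, lambda = c(x = 1.5)),
               class = "canopyshift_invalid_argument")
})

test_that("community generation matches its zero-inflated Poisson moments", {
  # degenerate mixture: pi = 1 gives all zeros
  sc1 <- simulation_scenario(n_species = 5, n_sites = 10, pi_zero = 1,
                             seed = 5)
  sim1 <- simulate_community_pair(sc1)
  expect_true(all(sim1$era1 == 0))
  expect_true(all(sim1$era2 == 0))

  # all variances zero, beta1 = 0, pi = 0: iid Poisson(4)
  sc2 <- simulation_scenario(
    n_species = 10, n_sites = 60, beta0 = log(4),
    beta1 = c(meso_score = 0), sigma2_site = 0, sigma2_spp = 0,
    sigma2_spp_phy = 0, sigma2_nested = 0, sigma2_slope = 0,
    pi_zero = 0, turnover = 0, seed = 6
  )
  sim2 <- simulate_community_pair(sc2)
  nn <- length(sim2$era1)
  expect_lt(abs(mean(sim2$era1) - 4), 3 * sqrt(4 / nn))
  expect_lt(abs(var(as.vector(sim2$era1)) - 4), 1)

  # zero-inflation moment: P(0) = pi + (1 - pi) exp(-mu)
  sc3 <- simulation_scenario(
    n_species = 10, n_sites = 100, beta0 = log(3),
    beta1 = c(meso_score = 0), sigma2_site = 0, sigma2_spp = 0,
    sigma2_spp_phy = 0, sigma2_nested = 0, sigma2_slope = 0,
    pi_zero = 0.25, turnover = 0, seed = 7
  )
  sim3 <- simulate_community_pair(sc3)
  p0 <- 0.25 + 0.75 * exp(-3)
  obs0 <- mean(sim3$era1 == 0)
  expect_lt(abs(obs0 - p0), 4 * sqrt(p0 * (1 - p0) / length(sim3$era1)))

  # reproducibility: identical scenario, identical draw
  simA <- simulate_community_pair(sc3)
  expect_identical(simA$era1, sim3$era1)
  expect_identical(simA$era2, sim3$era2)
})

test_that("nested phylogenetic variance induces within-site phylogenetic clustering", {
  stat_one <- function(nested, seed) {
    sc <- simulation_scenario(
      n_species = 10, n_sites = 40, beta0 = log(4),
      beta1 = c(meso_score = 0), sigma2_site = 0, sigma2_spp = 0,
      sigma2_spp_phy = 0, sigma2_nested = nested, sigma2_slope = 0,
      pi_zero = 0, turnover = 0, seed = seed
    )
    sim <- simulate_community_pair(sc)
    occ <- sim$era1 > 0
    V <- brownian_covariance(sim$tree, normalize = "depth")
    pairs <- which(upper.tri(V), arr.ind = TRUE)
    co <- apply(pairs, 1, function(ij) {
      a <- occ[, ij[1]]; b <- occ[, ij[2]]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    })
    suppressWarnings(cor(V[upper.tri(V)], co, use = "complete.obs"))
  }
  with_nested <- sapply(1:30, function(s) stat_one(1.5, 9000 + s))
  without <- sapply(1:30, function(s) stat_one(0, 9500 + s))
  expect_gt(mean(with_nested, na.rm = TRUE), mean(without, na.rm = TRUE))
  expect_lt(t.test(with_nested, without)$p.value, 0.01)
})

test_that("era-2 turnover shifts composition toward high mesophyte scores", {
  sc <- simulation_scenario(n_species = 12, n_sites = 60, turnover = 0.8,
                            seed = 12)
  sim <- simulate_community_pair(sc)
  meso <- sim$traits[colnames(sim$era1), 1]
  cw1 <- colSums(sim$era1) / sum(sim$era1)
  cw2 <- colSums(sim$era2) / sum(sim$era2)
  expect_gt(sum(cw2 * meso), sum(cw1 * meso))
  tb <- tbi_table(sim$era1, sim$era2)
  expect_true(all(tb$tbi > 0))
})

test_that("simulation writers produce readable plain-text artifacts", {
  sc <- simulation_scenario(n_species = 6, n_sites = 8, seed = 3)
  sim <- simulate_community_pair(sc)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  comm <- utils::read.csv(paths[["community"]])
  expect_identical(sort(unique(comm$era)), c(1L, 2L))
  expect_equal(long_to_matrix(comm, 1), sim$era1, ignore_attr = FALSE)
  tr <- read_newick(paths[["tree"]])
  expect_setequal(tr$tip.label, rownames(sim$traits))
})
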