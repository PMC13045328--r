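small_sim <- function(seed, n_species = 8, n_sites = 20, nested = 0.5,
                      pi_zero = 0.1, beta1 = 0.4, slope = 0,
                      spp = 0.3) {
  sc <- simulation_scenario(
    n_species = n_species, n_sites = n_sites, beta0 = log(4),
    beta1 = c(meso_score = beta1), sigma2_site = 0.05, sigma2_spp = spp,
    sigma2_spp_phy = 0, sigma2_nested = nested, sigma2_slope = slope,
    pi_zero = pi_zero, lambda_trait = c(meso_score = 0.8), seed = seed
  )
  simulate_community_pair(sc)
}

test_that("design assembly produces the full site-by-species response grid", {
  sim <- small_sim(101, n_species = 3, n_sites = 2)
  d <- build_design(sim$era1, traits = sim$traits, tree = sim$tree)
  expect_equal(nrow(d$data), 6)
  expect_identical(as.character(d$data$site),
                   rep(rownames(sim$era1), each = 3))
  expect_equal(d$data$y, as.vector(t(sim$era1)))

  # the survey design scale: 19 species x 138 sites = 2622 model rows
  big <- matrix(0L, 138, 19,
                dimnames = list(sprintf("s%03d", 1:138),
                                sprintf("sp%02d", 1:19)))
  big[, 1] <- 1L
  db <- build_design(big, terms = c("site", "species"))
  expect_equal(nrow(db$data), 2622)

  expect_warning(
    build_design(sim$era1,
                 traits = data.frame(flat = rep(1, 3),
                                     row.names = colnames(sim$era1)),
                 terms = c("site", "species")),
    "constant"
  )
  expect_error(
    build_design(sim$era1, tree = ape::read.tree(text = "(x:1,y:1);")),
    class = "canopyshift_key_error"
  )
})

test_that("nested-term construction matches the brute-force Kronecker oracle", {
  sim <- small_sim(102, n_species = 5, n_sites = 8)
  d <- build_design(sim$era1, tree = sim$tree,
                    terms = c("site", "species", "nested"))
  phy_cols <- grep("^\\.phy", names(d$data), value = TRUE)
  Z <- as.matrix(d$data[, phy_cols])
  # within each site block the covariance contributed by the nested term
  # is L L' = Sigma; across blocks it is zero => kron(I_m, Sigma)
  m <- d$m; n <- d$n
  implied <- matrix(0, m * n, m * n)
  for (i in seq_len(m)) {
    rows <- ((i - 1) * n + 1):(i * n)
    implied[rows, rows] <- Z[rows, ] %*% t(Z[rows, ])
  }
  oracle <- nested_covariance(d$Sigma, m)
  expect_equal(implied, unname(oracle), tolerance = 1e-8)

  # star tree: blocks are identity-proportional
  st <- ape::read.tree(text = "(sp1:1,sp2:1,sp3:1);")
  mat <- matrix(1L, 2, 3, dimnames = list(c("a", "b"), st$tip.label))
  ds <- build_design(mat, tree = st, terms = c("nested"))
  Zs <- as.matrix(ds$data[, grep("^\\.phy", names(ds$data))])
  expect_equal(Zs[1:3, ] %*% t(Zs[1:3, ]), diag(3),
               ignore_attr = TRUE, tolerance = 1e-6)

  expect_error(nested_covariance(diag(50), 200),
               class = "canopyshift_invalid_argument")
})

test_that("the ZIP likelihood reduces to Poisson and the intercept MLE is exact", {
  y <- c(0, 1, 3, 2, 5, 0, 4)
  lam <- c(0.5, 1, 2, 3, 1, 0.2, 4)
  expect_equal(canopyshift:::zip_loglik_pointwise(y, lam, 0),
               dpois(y, lam, log = TRUE), tolerance = 1e-12)

  mat <- matrix(c(0L, 2L, 3L, 1L, 4L, 2L), 2, 3,
                dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  d <- build_design(mat, terms = character(0), zi = FALSE)
  f <- fit_pglmm(d)
  expect_equal(f$beta$estimate[1], log(mean(mat)), tolerance = 1e-6)
  expect_equal(f$pi, 0)
})

test_that("zero-inflation probability is recovered at high counts", {
  set.seed(3)
  pis <- sapply(1:25, function(r) {
    sc <- simulation_scenario(
      n_species = 8, n_sites = 25, beta0 = log(20),
      beta1 = c(meso_score = 0), sigma2_site = 0.05, sigma2_spp = 0.2,
      sigma2_spp_phy = 0, sigma2_nested = 0, sigma2_slope = 0,
      pi_zero = 0.5, seed = 4000 + r
    )
    sim <- simulate_community_pair(sc)
    d <- build_design(sim$era1, terms = c("site", "species"))
    suppressWarnings(fit_pglmm(d))$pi
  })
  expect_lt(abs(mean(pis) - 0.5), 0.05)
})

test_that("laplace and mcmc backends agree on the global intercept", {
  sim <- small_sim(201, n_species = 10, n_sites = 20)
  d <- build_design(sim$era1, tree = sim$tree,
                    terms = c("site", "species", "nested"))
  fl <- suppressWarnings(fit_pglmm(d, backend = "laplace", seed = 1))
  fm <- suppressWarnings(fit_pglmm(d, backend = "mcmc", seed = 1,
                                   mcmc_iter = 3000, mcmc_warmup = 500))
  expect_lt(abs(fl$beta$estimate[1] - fm$beta$estimate[1]), 0.1)
  expect_gt(fm$accept_rate, 0.1)
  expect_true(all(fm$sigma2 >= 0))
})

test_that("the boundary LRT is null-safe and detects real nested variance", {
  sim <- small_sim(301)
  d_full <- build_design(sim$era1, tree = sim$tree,
                         terms = c("site", "species", "nested"))
  f_full <- suppressWarnings(fit_pglmm(d_full))
  r0 <- lrt_random_effect(f_full, f_full)
  expect_equal(r0$stat, 0)
  expect_equal(r0$p_value, 1)

  set.seed(5)
  rej <- mean(sapply(1:20, function(r) {
    sim <- small_sim(5000 + r, nested = 1, n_species = 8, n_sites = 20)
    df <- build_design(sim$era1, tree = sim$tree,
                       terms = c("site", "species", "nested"))
    dr <- build_design(sim$era1, terms = c("site", "species"))
    ff <- suppressWarnings(fit_pglmm(df))
    fr <- suppressWarnings(fit_pglmm(dr))
    lrt_random_effect(ff, fr)$p_value < 0.05
  }))
  expect_gte(rej, 0.85)

  f_red <- suppressWarnings(
    fit_pglmm(build_design(sim$era1, terms = c("site", "species")))
  )
  expect_error(lrt_random_effect(f_red, f_full),
               class = "canopyshift_invalid_comparison")
})

test_that("variance reduction reproduces simple ratios and guards zero", {
  expect_equal(variance_reduction(0.3, 0.6), 50)
  expect_equal(variance_reduction(0.5, 0.5), 0)
  expect_error(variance_reduction(0.1, 0),
               class = "canopyshift_undefined_reduction")
})

test_that("species intercepts preserve frequency ranks and flag absences", {
  sim <- small_sim(401, n_species = 10, n_sites = 30, nested = 0,
                   beta1 = 1, pi_zero = 0.05)
  mat <- sim$era1
  mat[, 1] <- 0L   # force one species absent
  r <- species_frequency_intercepts(mat)
  expect_true(r$absent[1])
  expect_true(is.na(r$intercept[1]))
  present <- !r$absent
  freq <- colMeans(mat)[present]
  expect_gt(cor(r$intercept[present], log(freq + 0.1),
                method = "spearman"), 0.85)

  # two eras generated identically yield near-identical intercepts
  r1 <- species_frequency_intercepts(sim$era1)
  sc2 <- simulation_scenario(
    n_species = 10, n_sites = 30, beta0 = log(4),
    beta1 = c(meso_score = 1), sigma2_site = 0.05, sigma2_spp = 0.3,
    sigma2_spp_phy = 0, sigma2_nested = 0, sigma2_slope = 0,
    pi_zero = 0.05, lambda_trait = c(meso_score = 0.8), seed = 401
  )
  # identical scenario seed regenerates the same era-1 table
  sim2 <- simulate_community_pair(sc2)
  r2 <- species_frequency_intercepts(sim2$era1)
  expect_equal(r1$intercept, r2$intercept, tolerance = 1e-8)
})

test_that("forward selection keeps the generating trait and screens noise", {
  set.seed(6)
  hits <- replicate(4, {
    seed <- sample.int(1e6, 1)
    sc <- simulation_scenario(
      n_species = 19, n_sites = 30, beta0 = log(4),
      beta1 = c(meso_score = 0.8, noise = 0),
      lambda_trait = c(meso_score = 1, noise = 0),
      sigma2_site = 0.05, sigma2_spp = 0.1, sigma2_spp_phy = 0,
      sigma2_nested = 0.2, sigma2_slope = 0.05, pi_zero = 0.1,
      seed = seed
    )
    sim <- simulate_community_pair(sc)
    sel <- forward_trait_selection(sim$era1, sim$traits, sim$tree,
                                   candidates = c("meso_score", "noise"),
                                   seed = seed)
    lam0 <- sel$table$lambda[sel$table$trait == "noise"]
    c(kept = "meso_score" %in% sel$selected,
      noise_lambda = lam0)
  })
  expect_gte(mean(hits["kept", ]), 0.75)
  # a lambda = 0 trait rarely shows strong spurious conservatism
  expect_lt(mean(hits["noise_lambda", ] > 0.5), 0.75)
  expect_error(
    forward_trait_selection(matrix(1, 2, 2), NULL, NULL, character(0)),
    class = "canopyshift_invalid_argument"
  )
})
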