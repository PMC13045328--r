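test_that("hydraulic derivations follow the unit arithmetic", {
  r <- derive_hydraulics(K = 10, stem_area_mm2 = 3, pith_area_mm2 = 1,
                         leaf_area_m2 = 0.5, sapwood_area_mm2 = 2)
  expect_equal(r$K_S, 5)
  expect_equal(r$K_L, 20)
  # 200 cm^2 of leaf area = 0.02 m^2 = 2e4 mm^2; over 2 mm^2 of sapwood
  r2 <- derive_hydraulics(10, 3, 1, leaf_area_m2 = 0.02,
                          sapwood_area_mm2 = 2)
  expect_equal(r2$AL_AS, 1e4)
  expect_error(derive_hydraulics(10, 2, 2, 0.5, 2),
               class = "canopyshift_invalid_geometry")
})

test_that("osmometry conversion matches van 't Hoff and is linear", {
  r <- osmolality_to_tlp(1000, temperature_c = 25)
  expect_equal(r$pi_osm, -8.314 * 298.15 * 1e-3, tolerance = 1e-9)
  expect_lt(abs(r$pi_osm - (-2.478)), 0.002)
  small <- osmolality_to_tlp(1e-6)
  expect_equal(small$tlp, -0.631, tolerance = 1e-4)
  expect_equal(osmolality_to_tlp(2000)$pi_osm,
               2 * osmolality_to_tlp(1000)$pi_osm, tolerance = 1e-12)
  expect_error(osmolality_to_tlp(0), class = "canopyshift_invalid_argument")
})

test_that("trait transforms apply log/sqrt/z with provenance guarding", {
  tab <- data.frame(LA = c(exp(1), exp(2), exp(3)),
                    AL_AS = c(1, 4, 9), K_L = c(4, 9, 16),
                    LMA = c(30, 60, 90))
  raw <- transform_traits(tab, z_cols = character(0))
  expect_equal(raw$LA, c(1, 2, 3))
  expect_equal(raw$AL_AS, c(1, 2, 3))
  expect_equal(raw$K_L, c(2, 3, 4))

  z <- transform_traits(tab)
  for (cl in names(z)) {
    expect_equal(mean(z[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[cl]]), 1, tolerance = 1e-12)
  }
  expect_error(transform_traits(z), class = "canopyshift_transform_error")

  skewed <- withr::with_seed(2, data.frame(LA = exp(rnorm(100, 0, 1.2))))
  before <- canopyshift:::sample_skewness(skewed$LA)
  after <- canopyshift:::sample_skewness(
    transform_traits(skewed, z_cols = character(0))$LA
  )
  expect_lt(abs(after), abs(before))

  bad <- data.frame(LA = c(1, -2), row.names = c("good_sp", "bad_sp"))
  err <- tryCatch(transform_traits(bad), error = function(e) conditionMessage(e))
  expect_match(err, "bad_sp")
})

test_that("flammability PCA conserves variance, fixes sign, and reconstructs", {
  set.seed(4)
  n <- 60
  z <- rnorm(n)
  burn <- data.frame(
    species = rep(letters[1:12], each = 5),
    flame_height = 50 + 10 * z + rnorm(n, 0, 3),
    flame_duration = 30 + 5 * z + rnorm(n, 0, 2),
    smolder_duration = 100 + rnorm(n, 0, 10),
    percent_consumed = pmin(100, pmax(0, 60 + 15 * z + rnorm(n, 0, 5)))
  )
  r <- flammability_pca(burn)
  expect_equal(sum(r$variance_fractions), 1, tolerance = 1e-12)
  expect_gt(r$loadings["flame_height", 1], 0)
  expect_equal(length(r$pc1_fire), 12)
  # flipping one input column leaves the spectrum unchanged
  burn2 <- burn
  burn2$smolder_duration <- -burn2$smolder_duration
  r2 <- flammability_pca(burn2)
  expect_equal(r$variance_fractions, r2$variance_fractions, tolerance = 1e-9)
  # two-variable closed form: PC1 fraction = (1 + |r|) / 2
  b2 <- burn[, c("species", "flame_height", "flame_duration")]
  rho <- abs(cor(b2$flame_height, b2$flame_duration))
  r3 <- flammability_pca(b2)
  expect_equal(r3$variance_fractions[1], (1 + rho) / 2, tolerance = 1e-9)
  # reconstruction: scores %*% t(loadings) recovers the scaled input
  Xs <- scale(as.matrix(burn[, -1]))
  back <- r$scores %*% t(r$loadings)
  expect_equal(unname(back), unname(Xs), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(
    flammability_pca(data.frame(species = c("a", "a", "b"),
                                flame_height = c(1, 2, 3),
                                const = c(5, 5, 5))),
    class = "canopyshift_degenerate_pca"
  )
})

test_that("variance decomposition recovers the injected level and sums to one", {
  make <- function(genus_sd, resid_sd, seed) {
    withr::with_seed(seed, {
      g <- rep(sprintf("g%02d", 1:12), each = 20)
      s <- paste0(g, "_s", rep(rep(1:4, each = 5), 12))
      mu <- rnorm(12, 0, genus_sd)[as.integer(factor(g))]
      data.frame(genus = g, species = s,
                 value = exp(2 + mu + rnorm(length(g), 0, resid_sd)))
    })
  }
  d <- make(genus_sd = 1.2, resid_sd = 0.15, seed = 10)
  vd <- variance_decomposition(d, "value", levels = c("genus", "species"))
  expect_equal(sum(vd$share), 1, tolerance = 1e-9)
  expect_gte(vd$share[vd$level == "genus"], 0.8)

  d2 <- make(genus_sd = 0.001, resid_sd = 0.5, seed = 11)
  vd2 <- variance_decomposition(d2, "value", levels = c("genus", "species"))
  expect_gte(vd2$share[vd2$level == "residual"], 0.9)
  expect_error(
    variance_decomposition(data.frame(genus = "a", species = "s",
                                      value = -1),
                           "value"),
    class = "canopyshift_invalid_response"
  )
})

test_that("variance decomposition agrees with a nested-ANOVA oracle on balanced designs", {
  d <- withr::with_seed(21, {
    g <- rep(sprintf("g%02d", 1:10), each = 24)
    s <- paste0(g, "_s", rep(rep(1:4, each = 6), 10))
    mu_g <- rnorm(10, 0, 0.6)[as.integer(factor(g))]
    mu_s <- rnorm(40, 0, 0.3)[as.integer(factor(s))]
    data.frame(genus = g, species = s,
               value = exp(3 + mu_g + mu_s + rnorm(length(g), 0, 0.2)))
  })
  vd <- variance_decomposition(d, "value", levels = c("genus", "species"))
  # oracle: Gaussian nested mixed model on the log response
  lf <- lme4::lmer(log(value) ~ 1 + (1 | genus) + (1 | genus:species),
                   data = d)
  vc <- as.data.frame(lme4::VarCorr(lf))
  tot <- sum(vc$vcov)
  oracle_genus <- vc$vcov[vc$grp == "genus"] / tot
  got_genus <- vd$share[vd$level == "genus"]
  expect_lt(abs(got_genus - oracle_genus) / oracle_genus, 0.10)
})

test_that("bark-at-reference prediction is exact on lines and calibrated under noise", {
  d <- data.frame(species = "a", dbh = c(4, 8, 12, 16),
                  bark = 0.5 * c(4, 8, 12, 16))
  r <- bark_at_reference_dbh(d)
  expect_equal(r$bark_at_ref, 5.0, tolerance = 1e-10)

  flat <- data.frame(species = "b", dbh = c(5, 10, 15, 20),
                     bark = c(3, 3, 3, 3))
  expect_equal(bark_at_reference_dbh(flat)$bark_at_ref, 3, tolerance = 1e-10)

  expect_error(
    bark_at_reference_dbh(data.frame(species = "c", dbh = c(7, 7, 7),
                                     bark = c(1, 2, 3))),
    class = "canopyshift_singular_fit"
  )

  set.seed(31)
  cover <- mean(replicate(500, {
    dbh <- runif(25, 4, 20)
    d <- data.frame(species = "x", dbh = dbh,
                    bark = 0.5 * dbh + rnorm(25, 0, 0.6))
    r <- bark_at_reference_dbh(d)
    tcrit <- qt(0.975, 23)
    r$bark_at_ref - tcrit * r$se <= 5 && 5 <= r$bark_at_ref + tcrit * r$se
  }))
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)
})
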