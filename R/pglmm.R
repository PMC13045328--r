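#' Assemble the design for a zero-inflated Poisson phylogenetic GLMM
#'
#' Builds the site-by-species response (length m*n, including zeros for
#' absent species), the fixed-effect matrix (intercept plus z-scored
#' species-mean traits), and the random-effect structures of the frequency
#' model: `(1|site)`, `(1|species)`, the phylogenetic species intercept
#' `(1|species__)` with covariance `sigma2 * Sigma_phy`, per-trait site
#' slopes `(trait|site)`, and the nested phylogenetic clustering term
#' `(1|species__@site)` with covariance `kron(I_m, sigma2 * Sigma_phy)`.
#'
#' Phylogenetic terms are realized through Cholesky-transformed covariates:
#' with `L L' = Sigma_phy`, a homogeneous-variance random effect on the
#' columns of `L` has marginal covariance `sigma2 * Sigma_phy`; grouping
#' those columns by site yields the Kronecker nested structure blockwise,
#' so the dense mn-by-mn matrix is never materialized. `Sigma_phy` is
#' depth-normalized (unit diagonal) before entering the model; the scaling
#' is recorded in the design.
#'
#' @param community Site-by-species count matrix for one era, or the
#'   canonical long table restricted to one era.
#' @param traits Optional data.frame of species-mean traits (rownames or
#'   `species` column); used for fixed effects and site slopes.
#' @param tree Ultrametric `phylo`; required for phylogenetic terms.
#' @param trait_names Traits entering as fixed effects (default: all
#'   numeric columns of `traits`).
#' @param terms Random-effect terms to include, a subset of
#'   `c("site", "species", "species_phy", "trait_slopes", "nested")`.
#' @param zi Include a single global zero-inflation probability.
#' @return A `pglmm_design` list: `data`, `formula`, `ziformula`, `X`,
#'   `term_order`, `Sigma`, `L`, `m`, `n`, `trait_names`.
#' @export
build_design <- function(community, traits = NULL, tree = NULL,
                         trait_names = NULL,
                         terms = c("site", "species", "species_phy",
                                   "trait_slopes", "nested"),
                         zi = TRUE) {
  allowed <- c("site", "species", "species_phy", "trait_slopes", "nested")
  stopifnot(all(terms %in% allowed))
  mat <- if (is.matrix(community)) community else {
    if (length(unique(community$era)) > 1) {
      stop_canopyshift("long community table covers several eras; filter to one",
                       "canopyshift_invalid_argument")
    }
    long_to_matrix(community, era = unique(community$era))
  }
  sp <- normalize_species(colnames(mat))
  colnames(mat) <- sp
  m <- nrow(mat)
  n <- ncol(mat)

  needs_phy <- any(c("species_phy", "nested") %in% terms)
  Sigma <- NULL
  L <- NULL
  if (needs_phy) {
    if (is.null(tree)) {
      stop_canopyshift("phylogenetic terms need a tree", "canopyshift_invalid_argument")
    }
    missing <- setdiff(sp, normalize_species(tree$tip.label))
    if (length(missing)) {
      stop_canopyshift(
        paste0("species missing from tree: ", paste(missing, collapse = ", ")),
        "canopyshift_key_error"
      )
    }
    tree <- ape::keep.tip(tree, sp)
    Sigma <- brownian_covariance(tree, normalize = "depth")[sp, sp]
    L <- t(chol(Sigma + diag(1e-10, n)))
  }

  trait_mat <- NULL
  if (!is.null(traits)) {
    tt <- as.data.frame(traits)
    if ("species" %in% names(tt)) {
      rownames(tt) <- normalize_species(tt$species)
      tt$species <- NULL
    }
    missing <- setdiff(sp, rownames(tt))
    if (length(missing)) {
      stop_canopyshift(
        paste0("species missing from trait table: ",
               paste(missing, collapse = ", ")),
        "canopyshift_key_error"
      )
    }
    if (is.null(trait_names)) {
      trait_names <- names(tt)[vapply(tt, is.numeric, logical(1))]
    }
    trait_mat <- as.matrix(tt[sp, trait_names, drop = FALSE])
    const <- apply(trait_mat, 2, function(v) stats::sd(v) == 0)
    if (any(const)) {
      warning("constant trait column(s) dropped: ",
              paste(trait_names[const], collapse = ", "))
      trait_names <- trait_names[!const]
      trait_mat <- trait_mat[, !const, drop = FALSE]
    }
  } else {
    trait_names <- character(0)
  }

  sites <- rownames(mat)
  if (is.null(sites)) sites <- sprintf("site%03d", seq_len(m))
  dat <- data.frame(
    y = as.vector(t(mat)),
    site = factor(rep(sites, each = n), levels = sites),
    species = factor(rep(sp, times = m), levels = sp)
  )
  dat$.one <- factor("all")
  if (length(trait_names)) {
    for (tn in trait_names) {
      dat[[tn]] <- trait_mat[as.integer(dat$species), tn]
    }
  }
  phy_cols <- character(0)
  if (needs_phy) {
    phy_cols <- sprintf(".phy%02d", seq_len(n))
    for (j in seq_len(n)) {
      dat[[phy_cols[j]]] <- L[as.integer(dat$species), j]
    }
  }

  rhs <- if (length(trait_names)) paste(trait_names, collapse = " + ") else "1"
  re <- character(0)
  term_order <- character(0)
  if ("site" %in% terms) {
    re <- c(re, "(1 | site)"); term_order <- c(term_order, "site")
  }
  if ("species" %in% terms) {
    re <- c(re, "(1 | species)"); term_order <- c(term_order, "species")
  }
  if ("species_phy" %in% terms) {
    re <- c(re, paste0("homdiag(0 + ", paste(phy_cols, collapse = " + "),
                       " | .one)"))
    term_order <- c(term_order, "species_phy")
  }
  if ("trait_slopes" %in% terms && length(trait_names)) {
    for (tn in trait_names) {
      re <- c(re, paste0("(0 + ", tn, " | site)"))
      term_order <- c(term_order, paste0("slope_", tn))
    }
  }
  if ("nested" %in% terms) {
    re <- c(re, paste0("homdiag(0 + ", paste(phy_cols, collapse = " + "),
                       " | site)"))
    term_order <- c(term_order, "nested")
  }
  fml <- stats::as.formula(
    paste("y ~", paste(c(rhs, re), collapse = " + "))
  )
  # finite-sample df per variance component: grouping levels minus one
  # (species-level terms are informed by the n species; site-grouped terms,
  # including the nested clustering term, by the m site blocks)
  term_df <- vapply(term_order, function(tm) {
    switch(sub("_.*", "", tm),
           species = n - 1L,
           m - 1L)
  }, integer(1))
  X <- cbind(`(Intercept)` = 1, trait_mat[as.integer(dat$species), ,
                                          drop = FALSE])
  structure(list(
    data = dat, formula = fml, ziformula = if (zi) ~1 else ~0, X = X,
    term_order = term_order, term_df = term_df, Sigma = Sigma, L = L,
    m = m, n = n, trait_names = trait_names, sigma_scaling = "depth"
  ), class = "pglmm_design")
}

#' Dense nested phylogenetic covariance (oracle-scale only)
#'
#' Materializes `kron(I_m, Sigma)` for cross-checking the blockwise
#' construction; guarded to small problems.
#'
#' @param Sigma Species covariance matrix.
#' @param m Number of sites.
#' @param max_size Refuse beyond `m * nrow(Sigma) > max_size`.
#' @return Dense `mn x mn` matrix, rows ordered site-major.
#' @export
nested_covariance <- function(Sigma, m, max_size = 5000) {
  n <- nrow(Sigma)
  if (m * n > max_size) {
    stop_canopyshift("dense nested covariance refused above max_size",
                     "canopyshift_invalid_argument")
  }
  kronecker(diag(m), Sigma)
}

# pointwise zero-inflated Poisson log-likelihood
zip_loglik_pointwise <- function(y, lambda, pi) {
  ifelse(y == 0,
         log(pi + (1 - pi) * exp(-lambda)),
         log(1 - pi) + stats::dpois(y, lambda, log = TRUE))
}

#' Fit the zero-inflated Poisson phylogenetic GLMM
#'
#' The `"laplace"` backend maximizes the marginal likelihood of the ZIP
#' mixture `P(0) = pi + (1 - pi) exp(-mu)`,
#' `P(k) = (1 - pi) exp(-mu) mu^k / k!` with log-link linear predictor,
#' integrating random effects by Laplace approximation (deterministic,
#' the default). The `"mcmc"` backend runs adaptive random-walk Metropolis
#' over the Laplace-approximated marginal posterior with weakly-informative
#' priors: normal(0, 5) on fixed effects, half-normal(0, 2.5) on
#' random-effect standard deviations, uniform on the zero-inflation
#' probability. Both report an approximate WAIC from pointwise conditional
#' ZIP log-likelihoods with random effects at their conditional modes
#' (parameter uncertainty via normal-approximation draws for the laplace
#' backend, posterior draws for mcmc).
#'
#' @param design A [build_design()] object.
#' @param backend `"laplace"` or `"mcmc"`.
#' @param seed Seed for WAIC draws / MCMC.
#' @param n_draws Parameter draws for the WAIC computation.
#' @param mcmc_iter,mcmc_warmup MCMC length and warmup.
#' @return A `pglmm_fit` list: `beta` (estimate, se), `sigma2` (named by
#'   term), `pi`, `loglik`, `AIC`, `waic`, `convergence`, `backend`,
#'   `seed`, and for mcmc `draws` and credible intervals.
#' @export
fit_pglmm <- function(design, backend = c("laplace", "mcmc"), seed = NULL,
                      n_draws = 400, mcmc_iter = 2000, mcmc_warmup = 500) {
  backend <- match.arg(backend)
  stopifnot(inherits(design, "pglmm_design"))
  ctrl <- glmmTMB::glmmTMBControl(
    optCtrl = list(iter.max = 2000, eval.max = 2000)
  )
  fit <- suppressWarnings(glmmTMB::glmmTMB(
    design$formula, ziformula = design$ziformula,
    family = stats::poisson(), data = design$data, control = ctrl
  ))
  bad <- function(f) {
    !is.null(f$fit$convergence) && f$fit$convergence != 0
  }
  if (bad(fit)) {
    # retry from scratch with the derivative-free outer optimizer
    fit2 <- tryCatch(suppressWarnings(glmmTMB::glmmTMB(
      design$formula, ziformula = design$ziformula,
      family = stats::poisson(), data = design$data,
      control = glmmTMB::glmmTMBControl(
        optimizer = stats::optim, optArgs = list(method = "BFGS")
      )
    )), error = function(e) NULL)
    if (!is.null(fit2) && !bad(fit2)) fit <- fit2
  }
  if (bad(fit)) {
    grad <- tryCatch(max(abs(fit$obj$gr(fit$fit$par))), error = function(e) NA)
    stop_canopyshift(
      sprintf("optimizer did not converge (max |gradient| = %g)", grad),
      "canopyshift_nonconvergence"
    )
  }
  pdh <- isTRUE(fit$sdr$pdHess)
  beta_hat <- glmmTMB::fixef(fit)$cond
  se_beta <- tryCatch(summary(fit)$coefficients$cond[, "Std. Error"],
                      error = function(e) rep(NA_real_, length(beta_hat)))
  vc <- glmmTMB::VarCorr(fit)$cond
  sigma2 <- stats::setNames(
    vapply(seq_along(design$term_order),
           function(i) unname(vc[[i]][1, 1]), numeric(1)),
    design$term_order
  )
  has_zi <- !identical(deparse(design$ziformula), "~0")
  zi_logit <- if (has_zi) unname(glmmTMB::fixef(fit)$zi[1]) else -Inf
  pi_hat <- stats::plogis(zi_logit)
  ll <- as.numeric(stats::logLik(fit))
  # logLik() withholds the value when the Hessian is suspect; the achieved
  # objective is still the maximized Laplace marginal log-likelihood
  if (!is.finite(ll)) ll <- -as.numeric(fit$fit$objective)
  y <- design$data$y

  out <- list(
    beta = data.frame(term = names(beta_hat), estimate = unname(beta_hat),
                      se = unname(se_beta)),
    sigma2 = sigma2, pi = pi_hat, zi_logit = zi_logit,
    loglik = ll, AIC = stats::AIC(fit),
    convergence = list(ok = TRUE, pdHess = pdh),
    backend = backend, seed = seed, n_obs = length(y),
    term_order = design$term_order, trait_names = design$trait_names,
    fit = fit
  )

  out$waic <- with_seed(sub_seed(seed, 11L), {
    waic_eta_normal(fit, y, zi_logit, has_zi, n_draws)
  })
  if (backend == "laplace") {
    out$sigma2_ci <- sigma2_wald_ci(fit, design)
  } else {
    mc <- with_seed(sub_seed(seed, 13L), {
      mcmc_marginal(fit, design, mcmc_iter, mcmc_warmup)
    })
    out$draws <- mc$draws
    out$beta <- mc$beta
    out$sigma2 <- mc$sigma2
    out$sigma2_ci <- mc$sigma2_ci
    out$pi <- mc$pi
    out$accept_rate <- mc$accept_rate
  }
  class(out) <- "pglmm_fit"
  out
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("Zero-inflated Poisson phylogenetic GLMM (", x$backend, " backend)\n",
      sep = "")
  cat("Fixed effects:\n")
  print(x$beta, row.names = FALSE)
  cat("Random-effect variances:\n")
  print(round(x$sigma2, 4))
  cat(sprintf("Zero-inflation pi = %.3f; logLik = %.2f; WAIC = %.2f\n",
              x$pi, x$loglik, x$waic$waic))
  invisible(x)
}

# Approximate WAIC from the normal approximation to the posterior of the
# per-observation linear predictor. predict(se.fit) propagates the joint
# uncertainty of fixed effects and random-effect modes, so the pointwise
# log-likelihood variance (p_waic) reflects the compensated posterior, not
# fixed effects jittered against frozen random effects. Draws are
# independent per observation, which is all the WAIC functional uses.
waic_eta_normal <- function(fit, y, zi_logit, has_zi, n_draws) {
  pr <- stats::predict(fit, type = "link", se.fit = TRUE)
  eta_hat <- pr$fit
  se_eta <- pr$se.fit
  se_zi <- 0
  if (has_zi) {
    V <- tryCatch(stats::vcov(fit)$zi, error = function(e) NULL)
    if (!is.null(V)) se_zi <- sqrt(V[1, 1])
  }
  N <- length(y)
  ll <- matrix(NA_real_, n_draws, N)
  for (s in seq_len(n_draws)) {
    eta <- eta_hat + se_eta * stats::rnorm(N)
    pi_s <- if (has_zi) stats::plogis(zi_logit + se_zi * stats::rnorm(1)) else 0
    ll[s, ] <- zip_loglik_pointwise(y, exp(pmin(eta, 30)), pi_s)
  }
  lppd <- sum(apply(ll, 2, function(v) {
    mx <- max(v)
    mx + log(mean(exp(v - mx)))
  }))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

# Wald-type intervals for variance components on the log-sd scale, with a
# t reference at (grouping levels - 1) df as the finite-sample correction
# for the effective replication behind each component
sigma2_wald_ci <- function(fit, design, level = 0.90) {
  sdr <- tryCatch(fit$sdr, error = function(e) NULL)
  if (is.null(sdr)) return(NULL)
  est <- sdr$par.fixed
  ii <- which(names(est) == "theta")
  if (!length(ii)) return(NULL)
  se <- tryCatch(sqrt(diag(sdr$cov.fixed))[ii], error = function(e) NULL)
  if (is.null(se)) return(NULL)
  dfv <- design$term_df
  if (is.null(dfv)) dfv <- rep(Inf, length(ii))
  q <- stats::qt(1 - (1 - level) / 2, df = pmax(dfv, 1))
  th <- est[ii]
  lo <- exp(2 * (th - q * se))
  hi <- exp(2 * (th + q * se))
  out <- data.frame(term = design$term_order, sigma2 = exp(2 * th),
                    lower = lo, upper = hi, level = level, df = dfv)
  rownames(out) <- NULL
  out
}

# adaptive random-walk Metropolis over the Laplace marginal posterior
mcmc_marginal <- function(fit, design, iter, warmup) {
  obj <- fit$obj
  par0 <- fit$fit$par
  pn <- names(par0)
  nb <- sum(pn == "beta")
  nz <- sum(pn == "betazi")
  nt <- sum(pn == "theta")
  log_post <- function(p) {
    nll <- tryCatch(as.numeric(obj$fn(p)), error = function(e) Inf)
    if (!is.finite(nll)) return(-Inf)
    lp <- 0
    if (nb) lp <- lp + sum(stats::dnorm(p[pn == "beta"], 0, 5, log = TRUE))
    if (nz) lp <- lp + sum(stats::dlogis(p[pn == "betazi"], log = TRUE))
    if (nt) {
      sdv <- exp(p[pn == "theta"])
      lp <- lp + sum(stats::dnorm(sdv, 0, 2.5, log = TRUE) + log(sdv))
    }
    -nll + lp
  }
  V <- tryCatch({
    H <- stats::optimHess(par0, obj$fn, obj$gr)
    solve((H + t(H)) / 2)
  }, error = function(e) diag(1e-2, length(par0)))
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8)
  Lp <- ev$vectors %*% diag(sqrt(ev$values), length(par0))
  scale <- 2.4 / sqrt(length(par0))
  cur <- par0
  cur_lp <- log_post(cur)
  draws <- matrix(NA_real_, iter, length(par0))
  acc <- 0L
  for (s in seq_len(iter)) {
    prop <- cur + scale * as.vector(Lp %*% stats::rnorm(length(par0)))
    plp <- log_post(prop)
    if (is.finite(plp) && log(stats::runif(1)) < plp - cur_lp) {
      cur <- prop; cur_lp <- plp; acc <- acc + 1L
    }
    draws[s, ] <- cur
    if (s <= warmup && s %% 100 == 0) {
      rate <- acc / s
      scale <- scale * exp(rate - 0.3)
    }
  }
  keep <- draws[(warmup + 1):iter, , drop = FALSE]
  bd <- keep[, pn == "beta", drop = FALSE]
  colnames(bd) <- names(glmmTMB::fixef(fit)$cond)
  zd <- if (nz) keep[, pn == "betazi", drop = FALSE][, 1] else
    rep(-Inf, nrow(keep))
  td <- keep[, pn == "theta", drop = FALSE]
  s2d <- exp(2 * td)
  colnames(s2d) <- design$term_order
  qs <- function(v) stats::quantile(v, c(0.05, 0.95))
  list(
    draws = keep, beta_draws = bd, zi_draws = zd,
    beta = data.frame(term = colnames(bd), estimate = colMeans(bd),
                      se = apply(bd, 2, stats::sd)),
    sigma2 = colMeans(s2d),
    sigma2_ci = data.frame(term = design$term_order,
                           sigma2 = colMeans(s2d),
                           lower = apply(s2d, 2, function(v) qs(v)[1]),
                           upper = apply(s2d, 2, function(v) qs(v)[2]),
                           level = 0.90),
    pi = mean(stats::plogis(zd)),
    accept_rate = acc / iter
  )
}

#' Likelihood-ratio test for a variance component on the boundary
#'
#' Twice the marginal log-likelihood difference between the full and the
#' reduced (nested) model, referred to the 50:50 mixture of chi-square(0)
#' and chi-square(1) appropriate for a single variance tested at zero.
#'
#' @param fit_full,fit_reduced `pglmm_fit` objects on the same data; the
#'   reduced model's random terms must be a subset of the full model's.
#' @return List with `stat`, `p_value`, `df_note`.
#' @export
lrt_random_effect <- function(fit_full, fit_reduced) {
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop_canopyshift("models were fit to different data", "canopyshift_invalid_comparison")
  }
  if (!all(fit_reduced$term_order %in% fit_full$term_order)) {
    stop_canopyshift("reduced model is not nested in the full model",
                     "canopyshift_invalid_comparison")
  }
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (stat <= 1e-10) 1 else 0.5 * stats::pchisq(stat, df = 1,
                                                     lower.tail = FALSE)
  list(stat = stat, p_value = p,
       df_note = "50:50 mixture of chi-square(0) and chi-square(1)")
}

#' Percent reduction in nested phylogenetic variance explained by traits
#'
#' `100 * (sigma2_without - sigma2_with) / sigma2_without` for the nested
#' clustering term, the headline statistic for how much of the phylogenetic
#' clustering the measured traits account for. Accepts fitted models (the
#' `nested` component is extracted) or bare variances.
#'
#' @param fit_with Fit including trait effects, or its nested variance.
#' @param fit_without Fit without trait terms, or its nested variance.
#' @return Percent reduction (negative if variance increased).
#' @export
variance_reduction <- function(fit_with, fit_without) {
  getv <- function(f) {
    if (inherits(f, "pglmm_fit")) {
      if (!"nested" %in% names(f$sigma2)) {
        stop_canopyshift("fit lacks the nested (1|species__@site) term",
                         "canopyshift_invalid_comparison")
      }
      unname(f$sigma2[["nested"]])
    } else {
      as.numeric(f)
    }
  }
  w <- getv(fit_with)
  wo <- getv(fit_without)
  if (wo == 0) {
    stop_canopyshift("reference nested variance is zero: reduction undefined",
                     "canopyshift_undefined_reduction")
  }
  100 * (wo - w) / wo
}

#' Per-species frequency intercepts from an intercept-only ZIP GLMM
#'
#' Intercept-only zero-inflated Poisson mixed model with species and site
#' random intercepts for a single era; the per-species conditional
#' intercept (global intercept plus species effect) reflects the species'
#' average frequency across sites and is comparable across eras. Species
#' entirely absent in the era are reported as absent, not as a zero
#' coefficient.
#'
#' @param community Site-by-species count matrix (one era) or long table
#'   with an `era` column plus `era` argument.
#' @param era Era to extract when `community` is long.
#' @return data.frame: `species`, `intercept`, `absent`.
#' @export
species_frequency_intercepts <- function(community, era = NULL) {
  mat <- if (is.matrix(community)) community else {
    if (is.null(era)) {
      stop_canopyshift("specify era for a long community table",
                       "canopyshift_invalid_argument")
    }
    long_to_matrix(community, era = era)
  }
  absent <- colSums(mat) == 0
  present <- colnames(mat)[!absent]
  sub <- mat[, !absent, drop = FALSE]
  design <- build_design(sub, terms = c("site", "species"), zi = TRUE)
  f <- fit_pglmm(design, backend = "laplace")
  re <- glmmTMB::ranef(f$fit)$cond$species
  b0 <- f$beta$estimate[f$beta$term == "(Intercept)"]
  ic <- b0 + re[present, 1]
  out <- data.frame(
    species = colnames(mat),
    intercept = NA_real_,
    absent = unname(absent)
  )
  out$intercept[match(present, out$species)] <- ic
  out
}

#' Forward selection of trait fixed effects
#'
#' Stage 1 keeps candidate traits demonstrating phylogenetic conservatism
#' (Pagel's lambda above `lambda_threshold`). Stage 2 adds each surviving
#' trait (fixed effect plus trait-by-site slope) to the non-phylogenetic
#' null model (site and species intercepts, zero inflation) and keeps
#' traits that lower WAIC relative to that null.
#'
#' @param community Site-by-species count matrix (one era).
#' @param traits Species-mean trait table (z-scored candidates).
#' @param tree Ultrametric `phylo`.
#' @param candidates Trait column names to screen.
#' @param lambda_threshold Stage-1 lambda cutoff (default 0.5).
#' @param seed Seed forwarded to WAIC draws.
#' @return List: `table` (per-candidate screen log), `selected`.
#' @export
forward_trait_selection <- function(community, traits, tree, candidates,
                                    lambda_threshold = 0.5, seed = NULL) {
  if (!length(candidates)) {
    stop_canopyshift("empty candidate set", "canopyshift_invalid_argument")
  }
  tt <- as.data.frame(traits)
  if ("species" %in% names(tt)) {
    rownames(tt) <- normalize_species(tt$species)
    tt$species <- NULL
  }
  lam <- vapply(candidates, function(tr) {
    x <- stats::setNames(tt[tree$tip.label, tr], tree$tip.label)
    pagel_lambda(tree, x)$lambda
  }, numeric(1))
  pass1 <- lam > lambda_threshold
  null_design <- build_design(community, terms = c("site", "species"),
                              zi = TRUE)
  null_fit <- fit_pglmm(null_design, seed = sub_seed(seed, 1L))
  waic_null <- null_fit$waic$waic
  waic_tr <- rep(NA_real_, length(candidates))
  names(waic_tr) <- candidates
  for (tr in candidates[pass1]) {
    d <- build_design(community, traits = tt, tree = tree,
                      trait_names = tr,
                      terms = c("site", "species", "trait_slopes"),
                      zi = TRUE)
    ft <- fit_pglmm(d, seed = sub_seed(seed, 2L))
    waic_tr[tr] <- ft$waic$waic
  }
  accepted <- pass1 & !is.na(waic_tr) & waic_tr < waic_null
  tab <- data.frame(
    trait = candidates, lambda = unname(lam), lambda_pass = unname(pass1),
    waic_null = waic_null, waic_trait = unname(waic_tr),
    accepted = unname(accepted)
  )
  list(table = tab, selected = candidates[accepted])
}
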