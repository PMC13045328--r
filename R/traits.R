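#' Derive hydraulic quantities from raw conductivity and geometry
#'
#' Converts maximum stem hydraulic conductivity `K` (g mm s^-1 MPa^-1) into
#' xylem-area-specific conductivity `K_S = K / (stem area - pith area)`
#' (g s^-1 MPa^-1 mm^-1), leaf-area-specific conductivity
#' `K_L = K / bulk leaf area` (per m^2 of supported leaf area), and the leaf
#' area to sapwood area ratio `A_L:A_S` (dimensionless, after reconciling
#' leaf area in m^2 against sapwood area in mm^2).
#'
#' @param K Maximum hydraulic conductivity, g mm s^-1 MPa^-1.
#' @param stem_area_mm2,pith_area_mm2 Stem and pith cross-sections, mm^2.
#' @param leaf_area_m2 Bulk leaf area supported by the segment, m^2.
#' @param sapwood_area_mm2 Sapwood cross-section, mm^2.
#' @return data.frame with `K_S`, `K_L`, `AL_AS`.
#' @export
derive_hydraulics <- function(K, stem_area_mm2, pith_area_mm2,
                              leaf_area_m2, sapwood_area_mm2) {
  if (any(K < 0)) {
    stop_canopyshift("K must be nonnegative", "canopyshift_invalid_argument")
  }
  if (any(stem_area_mm2 <= 0) || any(leaf_area_m2 <= 0) ||
      any(sapwood_area_mm2 <= 0) || any(pith_area_mm2 < 0)) {
    stop_canopyshift("areas must be positive", "canopyshift_invalid_argument")
  }
  if (any(pith_area_mm2 >= stem_area_mm2)) {
    stop_canopyshift("pith area must be smaller than stem area",
                     "canopyshift_invalid_geometry")
  }
  xylem <- stem_area_mm2 - pith_area_mm2
  data.frame(
    K_S = K / xylem,
    K_L = K / leaf_area_m2,
    AL_AS = (leaf_area_m2 * 1e6) / sapwood_area_mm2
  )
}

#' Convert osmometer readings to turgor loss point
#'
#' Van 't Hoff osmotic potential `pi_osm = -R T c` from osmolality
#' (mmol/kg, treated as mol m^-3 at unit solution density), then the linear
#' calibration `Psi_TLP = slope * pi_osm + intercept`. The default
#' coefficients follow the published rapid-osmometry calibration for
#' turgor loss point and are configuration values, not hard-coded truth.
#'
#' @param osmolality_mmol_kg Positive osmolality readings, mmol/kg.
#' @param temperature_c Chamber temperature, degrees C (default 25).
#' @param coefficients Named vector `c(slope, intercept)` of the linear map
#'   from osmotic potential (MPa) to turgor loss point (MPa).
#' @return data.frame with `pi_osm` (MPa) and `tlp` (MPa).
#' @export
osmolality_to_tlp <- function(osmolality_mmol_kg, temperature_c = 25,
                              coefficients = c(slope = 0.832,
                                               intercept = -0.631)) {
  if (any(osmolality_mmol_kg <= 0)) {
    stop_canopyshift("osmolality must be positive", "canopyshift_invalid_argument")
  }
  R <- 8.314  # J mol^-1 K^-1
  pi_osm <- -R * (temperature_c + 273.15) * osmolality_mmol_kg * 1e-6  # MPa
  tlp <- coefficients[["slope"]] * pi_osm + coefficients[["intercept"]]
  data.frame(pi_osm = pi_osm, tlp = tlp)
}

#' Apply the prescribed trait transforms and z-scoring
#'
#' Log-transforms highly skewed leaf area, square-root-transforms the leaf
#' area:sapwood area ratio and leaf-area-specific conductivity, then
#' z-scores every analysis column to mean 0, sd 1 so model coefficients are
#' comparable across traits. Transform provenance is recorded in the
#' `"transforms"` attribute and a second application is refused.
#'
#' @param table data.frame of species trait values (species in rows or a
#'   `species` column).
#' @param log_cols,sqrt_cols Columns to log / square-root transform.
#' @param z_cols Columns to z-score afterwards; default all numeric columns.
#' @return Transformed data.frame with a `"transforms"` attribute.
#' @export
transform_traits <- function(table, log_cols = intersect("LA", names(table)),
                             sqrt_cols = intersect(c("AL_AS", "K_L"),
                                                   names(table)),
                             z_cols = NULL) {
  if (!is.null(attr(table, "transforms"))) {
    stop_canopyshift("table already carries transform provenance; refusing to transform twice",
                     "canopyshift_transform_error")
  }
  out <- table
  for (cl in log_cols) {
    v <- out[[cl]]
    if (any(v <= 0)) {
      bad <- rownames(out)[v <= 0]
      if (is.null(bad)) bad <- which(v <= 0)
      stop_canopyshift(
        paste0("nonpositive value in log column ", cl, " for: ",
               paste(bad, collapse = ", ")),
        "canopyshift_transform_error"
      )
    }
    out[[cl]] <- log(v)
  }
  for (cl in sqrt_cols) {
    v <- out[[cl]]
    if (any(v < 0)) {
      stop_canopyshift(paste0("negative value in sqrt column ", cl),
                       "canopyshift_transform_error")
    }
    out[[cl]] <- sqrt(v)
  }
  if (is.null(z_cols)) {
    z_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  }
  for (cl in z_cols) {
    v <- out[[cl]]
    s <- stats::sd(v)
    out[[cl]] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  attr(out, "transforms") <- list(log = log_cols, sqrt = sqrt_cols,
                                  z = z_cols)
  out
}

#' Litter flammability PCA
#'
#' PCA of burn-trial variables (flame height, flame duration, smolder
#' duration, percent consumed, consumption rate, fireline intensity).
#' Variables whose absolute skewness exceeds `skew_threshold` are
#' log-transformed first, then all are standardized. The first principal
#' component is sign-oriented so that a larger PC1 score corresponds to more
#' intense, rapid, consumptive fire behavior (positive loading on flame
#' height); the per-species PC1 score is the mean of its sample scores.
#'
#' @param burn_table data.frame with a `species` column and numeric burn
#'   variables (one row per burn sample).
#' @param species_col Name of the species column.
#' @param flame_col Variable used to fix the PC1 sign.
#' @param skew_threshold Absolute skewness above which a variable is
#'   log-transformed (log1p for zero-containing variables).
#' @return List: `loadings`, `scores`, `variance_fractions`, `pc1_fire`
#'   (named per-species means), `logged` (variables log-transformed).
#' @export
flammability_pca <- function(burn_table, species_col = "species",
                             flame_col = "flame_height",
                             skew_threshold = 1) {
  sp <- burn_table[[species_col]]
  X <- burn_table[, setdiff(names(burn_table), species_col), drop = FALSE]
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  if (anyNA(X)) {
    stop_canopyshift("missing burn values; impute or drop before PCA",
                     "canopyshift_invalid_argument")
  }
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    stop_canopyshift(
      paste0("constant burn variable(s): ",
             paste(names(X)[const], collapse = ", ")),
      "canopyshift_degenerate_pca"
    )
  }
  n_per <- table(sp)
  if (any(n_per < 3)) {
    warning("fewer than 3 burn samples for: ",
            paste(names(n_per)[n_per < 3], collapse = ", "))
  }
  logged <- character(0)
  for (cl in names(X)) {
    if (abs(sample_skewness(X[[cl]])) > skew_threshold) {
      X[[cl]] <- if (any(X[[cl]] <= 0)) log1p(X[[cl]]) else log(X[[cl]])
      logged <- c(logged, cl)
    }
  }
  pca <- stats::prcomp(as.matrix(X), center = TRUE, scale. = TRUE)
  vf <- pca$sdev^2 / sum(pca$sdev^2)
  if (flame_col %in% rownames(pca$rotation) &&
      pca$rotation[flame_col, 1] < 0) {
    pca$rotation[, 1] <- -pca$rotation[, 1]
    pca$x[, 1] <- -pca$x[, 1]
  }
  pc1 <- tapply(pca$x[, 1], sp, mean)
  list(loadings = pca$rotation, scores = pca$x,
       variance_fractions = vf, pc1_fire = pc1[unique(as.character(sp))],
       logged = logged, center = pca$center, scale = pca$scale)
}

#' Variance decomposition of a trait across taxonomic levels
#'
#' Gamma generalized linear mixed model with log link and nested random
#' intercepts (genus, species within genus, and individual within species
#' where sampled). Reported shares are each variance component divided by
#' the total (components plus the link-scale residual variance,
#' `trigamma(shape)` for the Gamma family), so they sum to 1.
#'
#' @param data data.frame with the response and grouping columns.
#' @param response Name of the (positive) trait column.
#' @param levels Character vector of nested grouping columns, outermost
#'   first, e.g. `c("genus", "species", "individual")`.
#' @return data.frame with `level` and `share` (includes `residual`).
#' @export
variance_decomposition <- function(data, response,
                                   levels = c("genus", "species")) {
  y <- data[[response]]
  if (any(y <= 0)) {
    stop_canopyshift("Gamma response must be positive",
                     "canopyshift_invalid_response")
  }
  for (lv in levels) {
    if (length(unique(data[[lv]])) < 2) {
      stop_canopyshift(paste0("need >= 2 groups at level ", lv),
                       "canopyshift_invalid_argument")
    }
  }
  terms <- paste0("(1 | ", vapply(seq_along(levels), function(i) {
    paste(levels[seq_len(i)], collapse = ":")
  }, character(1)), ")")
  fml <- stats::as.formula(paste(response, "~ 1 +",
                                 paste(terms, collapse = " + ")))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(fml, data = data, family = stats::Gamma(link = "log"))
  )
  vc <- glmmTMB::VarCorr(fit)$cond
  comp <- vapply(vc, function(m) m[1, 1], numeric(1))
  # map "genus:species" style names back to the level labels
  nice <- vapply(names(comp), function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    levels[length(parts)]
  }, character(1))
  # link-scale residual variance of a Gamma log-link response
  shape <- 1 / stats::sigma(fit)^2
  resid_var <- trigamma(shape)
  total <- sum(comp) + resid_var
  data.frame(level = c(nice, "residual"),
             share = c(comp, resid_var) / total,
             variance = c(comp, resid_var),
             row.names = NULL)
}

#' Bark thickness predicted at a reference diameter
#'
#' Per-species linear regression of bark thickness on diameter at breast
#' height, with the fitted value and its standard error at the reference
#' diameter (10 cm by default).
#'
#' @param data data.frame with `species`, `dbh`, `bark` columns.
#' @param ref_dbh Reference DBH in the same units as `dbh`.
#' @return data.frame per species: `species`, `bark_at_ref`, `se`, `n`.
#' @export
bark_at_reference_dbh <- function(data, ref_dbh = 10) {
  out <- lapply(split(data, data$species), function(d) {
    if (nrow(d) < 3) {
      stop_canopyshift(paste0("need >= 3 (dbh, bark) pairs for ",
                              d$species[1]),
                       "canopyshift_invalid_argument")
    }
    if (stats::sd(d$dbh) == 0) {
      stop_canopyshift(paste0("degenerate design (all equal DBH) for ",
                              d$species[1]),
                       "canopyshift_singular_fit")
    }
    fit <- stats::lm(bark ~ dbh, data = d)
    pr <- stats::predict(fit, newdata = data.frame(dbh = ref_dbh),
                         se.fit = TRUE)
    data.frame(species = d$species[1], bark_at_ref = unname(pr$fit),
               se = unname(pr$se.fit), n = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
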