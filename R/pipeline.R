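#' Validate community, trait, and tree inputs
#'
#' Cross-checks species sets (community vs traits vs tree), era pairing of
#' sites, and count nonnegativity; distinguishes warnings (extra trait
#' species, ignored) from fatal problems (species missing from tree,
#' unpaired sites, negative counts).
#'
#' @param community Long community table (`site`, `species`, `era`,
#'   `count`).
#' @param traits Species trait table.
#' @param tree Ultrametric `phylo`.
#' @return List with `fatal` and `warnings` character vectors and
#'   `ok = !length(fatal)`.
#' @export
validate_inputs <- function(community, traits = NULL, tree = NULL) {
  fatal <- character(0)
  warn <- character(0)
  req <- c("site", "species", "era", "count")
  if (!all(req %in% names(community))) {
    fatal <- c(fatal, paste0("community table lacks columns: ",
                             paste(setdiff(req, names(community)),
                                   collapse = ", ")))
    return(list(ok = FALSE, fatal = fatal, warnings = warn))
  }
  neg <- which(community$count < 0)
  if (length(neg)) {
    fatal <- c(fatal, paste0("negative counts at rows: ",
                             paste(utils::head(neg, 10), collapse = ", ")))
  }
  eras <- sort(unique(community$era))
  if (length(eras) == 2) {
    s1 <- unique(community$site[community$era == eras[1]])
    s2 <- unique(community$site[community$era == eras[2]])
    unpaired <- c(setdiff(s1, s2), setdiff(s2, s1))
    if (length(unpaired)) {
      fatal <- c(fatal, paste0("sites unpaired across eras: ",
                               paste(unpaired, collapse = ", ")))
    }
  }
  sp <- unique(normalize_species(community$species))
  n_combo <- length(sp) * length(unique(community$site))
  if (!is.null(traits)) {
    tt <- as.data.frame(traits)
    tn <- if ("species" %in% names(tt)) normalize_species(tt$species)
          else normalize_species(rownames(tt))
    miss <- setdiff(sp, tn)
    extra <- setdiff(tn, sp)
    if (length(miss)) {
      fatal <- c(fatal, paste0("species missing from trait table: ",
                               paste(miss, collapse = ", ")))
    }
    if (length(extra)) {
      warn <- c(warn, paste0("trait table species not in community (ignored): ",
                             paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(tree)) {
    miss <- setdiff(sp, normalize_species(tree$tip.label))
    if (length(miss)) {
      fatal <- c(fatal, paste0("species missing from tree: ",
                               paste(miss, collapse = ", ")))
    }
  }
  list(ok = !length(fatal), fatal = fatal, warnings = warn,
       n_species = length(sp), n_sites = length(unique(community$site)),
       n_site_species = n_combo)
}

#' Standardize site totals to a fixed stem count
#'
#' Sites whose era total exceeds `stems` are resampled without replacement
#' down to exactly `stems` individuals, mirroring survey standardization to
#' a fixed number of stems per site; smaller sites are left untouched.
#'
#' @param mat Site-by-species count matrix.
#' @param stems Target stems per site (default 80).
#' @param seed Integer seed.
#' @return Matrix of the same shape with row sums at most `stems`.
#' @export
standardize_stems <- function(mat, stems = 80, seed = NULL) {
  with_seed(seed, {
    out <- mat
    for (i in seq_len(nrow(mat))) {
      tot <- sum(mat[i, ])
      if (tot > stems) {
        pool <- rep(seq_len(ncol(mat)), times = mat[i, ])
        keep <- sample(pool, stems, replace = FALSE)
        out[i, ] <- tabulate(keep, nbins = ncol(mat))
      }
    }
    out
  })
}

#' Run the full paired-era analysis pipeline
#'
#' Executes the stages in dependency order -- input validation, optional
#' stem standardization, TBI with gain/loss comparison, functional and
#' phylogenetic Hill similarity with permutation SES, CWM shift tests, and
#' the ZIP phylogenetic GLMMs with and without trait terms per era
#' (yielding the nested-variance percent reduction) -- and writes per-stage
#' CSV outputs plus a machine-readable JSON summary. Every stochastic stage
#' records its seed; rerunning with the same inputs and seeds reproduces
#' the summary.
#'
#' @param community Long community table covering two eras.
#' @param traits Species-mean trait table (z-scored analysis columns).
#' @param tree Ultrametric `phylo`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param trait_names Traits used for CWM, functional distances, and PGLMM
#'   fixed effects (default: all numeric trait columns).
#' @param n_perm_ses,n_perm_cwm Permutation counts (999 / 1000).
#' @param seed Master seed.
#' @param stems Stem standardization target; `NULL` to skip.
#' @param run_pglmm Fit the mixed models (the slow stage).
#' @return List of stage results and the `summary` list (invisibly written
#'   to `summary.json` when `out_dir` is given).
#' @export
run_pipeline <- function(community, traits, tree, out_dir = NULL,
                         trait_names = NULL, n_perm_ses = 999,
                         n_perm_cwm = 1000, seed = 1L, stems = NULL,
                         run_pglmm = TRUE) {
  val <- validate_inputs(community, traits, tree)
  if (!val$ok) {
    stop_canopyshift(paste0("input validation failed: ",
                            paste(val$fatal, collapse = "; ")),
                     "canopyshift_validation_error")
  }
  for (w in val$warnings) warning(w)
  eras <- sort(unique(community$era))
  c1 <- long_to_matrix(community, eras[1])
  c2 <- long_to_matrix(community, eras[2])
  c2 <- c2[rownames(c1), colnames(c1), drop = FALSE]
  if (!is.null(stems)) {
    c1 <- standardize_stems(c1, stems, seed = sub_seed(seed, 21L))
    c2 <- standardize_stems(c2, stems, seed = sub_seed(seed, 22L))
  }
  tt <- as.data.frame(traits)
  if ("species" %in% names(tt)) {
    rownames(tt) <- normalize_species(tt$species)
    tt$species <- NULL
  }
  if (is.null(trait_names)) {
    trait_names <- names(tt)[vapply(tt, is.numeric, logical(1))]
  }
  tt <- tt[, trait_names, drop = FALSE]

  # -- temporal beta diversity
  tbi <- tbi_table(c1, c2)
  gl <- compare_gain_loss(tbi)

  # -- similarity + SES
  ses_fun <- similarity_ses(c1, c2, facet = "functional",
                            traits = tt[colnames(c1), , drop = FALSE],
                            n_perm = n_perm_ses,
                            seed = sub_seed(seed, 31L))
  ses_phy <- similarity_ses(c1, c2, facet = "phylogenetic", tree = tree,
                            n_perm = n_perm_ses,
                            seed = sub_seed(seed, 32L))
  t_fun <- ses_ttest(ses_fun)
  t_phy <- ses_ttest(ses_phy)

  # -- community-weighted means
  long12 <- rbind(community_to_long(c1, eras[1]),
                  community_to_long(c2, eras[2]))
  cwm <- compute_cwm(long12, data.frame(species = rownames(tt), tt))
  cwm_tests <- cwm_shift_test(cwm, n_perm = n_perm_cwm,
                              seed = sub_seed(seed, 41L))

  # -- mixed models per era: with traits vs without trait terms
  pg <- NULL
  if (run_pglmm) {
    pg <- lapply(stats::setNames(list(c1, c2), paste0("era", eras)),
                 function(mat) {
      d_with <- build_design(mat, traits = tt, tree = tree,
                             trait_names = trait_names,
                             terms = c("site", "species", "species_phy",
                                       "trait_slopes", "nested"))
      d_wo <- build_design(mat, tree = tree,
                           terms = c("site", "species", "species_phy",
                                     "nested"))
      f_with <- fit_pglmm(d_with, seed = sub_seed(seed, 51L))
      f_wo <- fit_pglmm(d_wo, seed = sub_seed(seed, 52L))
      list(with = f_with, without = f_wo,
           reduction_pct = variance_reduction(f_with, f_wo))
    })
  }

  summary <- list(
    seed = seed,
    n_sites = nrow(c1), n_species = ncol(c1),
    tbi = list(mean = mean(tbi$tbi),
               mean_gain = mean(tbi$gain), mean_loss = mean(tbi$loss),
               gain_loss_t = gl$t, gain_loss_df = gl$df,
               gain_loss_p = gl$p_value),
    similarity = list(
      functional_mean = mean(ses_fun$observed, na.rm = TRUE),
      phylogenetic_mean = mean(ses_phy$observed, na.rm = TRUE),
      functional_ses_t = t_fun$t, functional_ses_p = t_fun$p_value,
      phylogenetic_ses_t = t_phy$t, phylogenetic_ses_p = t_phy$p_value,
      n_perm = n_perm_ses,
      seeds = c(sub_seed(seed, 31L), sub_seed(seed, 32L))
    ),
    cwm = cwm_tests,
    pglmm = if (!is.null(pg)) {
      lapply(pg, function(e) list(
        reduction_pct = e$reduction_pct,
        sigma2_with = as.list(e$with$sigma2),
        sigma2_without = as.list(e$without$sigma2),
        pi_with = e$with$pi, pi_without = e$without$pi,
        waic_with = e$with$waic$waic, waic_without = e$without$waic$waic
      ))
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tbi, file.path(out_dir, "tbi_records.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(ses_fun, ses_phy),
                     file.path(out_dir, "similarity_ses.csv"),
                     row.names = FALSE)
    utils::write.csv(cwm, file.path(out_dir, "cwm_values.csv"),
                     row.names = FALSE)
    utils::write.csv(cwm_tests, file.path(out_dir, "cwm_shift_tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(list(validation = val, tbi = tbi, gain_loss = gl,
                 ses_functional = ses_fun, ses_phylogenetic = ses_phy,
                 cwm = cwm, cwm_tests = cwm_tests, pglmm = pg,
                 summary = summary))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON key/value configuration naming the input paths
#' (`community`, `traits`, `tree`), permutation counts, seed, and output
#' directory; referenced paths must exist.
#'
#' @param path Configuration file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("community", "traits", "tree")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_canopyshift(paste0("configured path does not exist: ",
                              cfg[[key]]),
                       "canopyshift_validation_error")
    }
  }
  cfg
}
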