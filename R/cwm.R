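#' Community-weighted means per site and era
#'
#' Abundance-weighted average of each species-mean trait within each
#' site-era community: `cwm = sum_i f_i t_i / sum_i f_i` over the species
#' present. Species without trait values are excluded from both numerator
#' and denominator (with a warning); a site-era with zero total frequency
#' after exclusion yields an `NA` CWM flagged `undefined`.
#'
#' @param community Long-format data.frame with columns `site`, `species`,
#'   `era`, `count`.
#' @param traits data.frame with a `species` column (or species rownames)
#'   and numeric trait columns.
#' @return Long data.frame: `site`, `era`, `trait`, `cwm`, `undefined`.
#' @export
compute_cwm <- function(community, traits) {
  stopifnot(all(c("site", "species", "era", "count") %in% names(community)))
  tt <- as.data.frame(traits)
  if ("species" %in% names(tt)) {
    rownames(tt) <- normalize_species(tt$species)
    tt$species <- NULL
  }
  num_cols <- names(tt)[vapply(tt, is.numeric, logical(1))]
  community$species <- normalize_species(community$species)
  missing <- setdiff(unique(community$species), rownames(tt))
  if (length(missing)) {
    warning("species without trait values dropped from CWM: ",
            paste(missing, collapse = ", "))
    community <- community[!community$species %in% missing, , drop = FALSE]
  }
  key <- interaction(community$site, community$era, drop = TRUE)
  res <- lapply(split(community, key), function(d) {
    f <- d$count
    tot <- sum(f)
    vals <- vapply(num_cols, function(tr) {
      tv <- tt[d$species, tr]
      if (tot > 0) sum(f * tv) / tot else NA_real_
    }, numeric(1))
    data.frame(site = d$site[1], era = d$era[1], trait = num_cols,
               cwm = unname(vals), undefined = tot == 0,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Permutation test of temporal CWM shifts
#'
#' For each trait, the observed statistic is the paired t statistic of the
#' site-level CWM differences between eras (or its median-based analogue).
#' The null swaps era labels independently within each site pair `n_perm`
#' times; the two-sided add-one permutation p-value is
#' `(1 + #(|null| >= |obs|)) / (n_perm + 1)`, so it is never exactly zero.
#' A Wilcoxon signed-rank p-value is reported alongside as the
#' assumption-light companion test.
#'
#' @param cwm Long data.frame from [compute_cwm()] covering two eras with
#'   the same paired sites.
#' @param n_perm Number of era-label permutations (default 1000).
#' @param seed Integer seed.
#' @param statistic `"mean"` (paired t) or `"median"` (median difference /
#'   MAD-scaled).
#' @param null `"pair_swap"` (era labels swapped within site, default) or
#'   `"global"` (site-level differences sign-flipped all together -- the
#'   coarser global-permutation alternative).
#' @return data.frame per trait: `trait`, `obs_stat`, `perm_p`,
#'   `wilcoxon_p`, `direction`, `n_sites`, `n_perm`, `seed`.
#' @export
cwm_shift_test <- function(cwm, n_perm = 1000, seed = NULL,
                           statistic = c("mean", "median"),
                           null = c("pair_swap", "global")) {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  eras <- sort(unique(cwm$era))
  if (length(eras) != 2) {
    stop_canopyshift("CWM table must cover exactly two eras",
                     "canopyshift_invalid_argument")
  }
  out <- lapply(split(cwm, cwm$trait), function(d) {
    w <- stats::reshape(
      d[, c("site", "era", "cwm")], direction = "wide",
      idvar = "site", timevar = "era"
    )
    x1 <- w[[paste0("cwm.", eras[1])]]
    x2 <- w[[paste0("cwm.", eras[2])]]
    ok <- is.finite(x1) & is.finite(x2)
    x1 <- x1[ok]; x2 <- x2[ok]
    m <- length(x1)
    if (m < 6) {
      warning("fewer than 6 site pairs for trait ", d$trait[1],
              ": permutation resolution is poor")
    }
    diffs <- x2 - x1
    # a zero-spread difference vector with a nonzero center is an
    # unambiguous shift: report it as an infinite statistic rather than 0
    scaled_center <- function(center, s, mlen) {
      if (s == 0) {
        if (center == 0) 0 else sign(center) * Inf
      } else {
        center / (s / sqrt(mlen))
      }
    }
    stat_fun <- if (statistic == "mean") {
      function(z) scaled_center(mean(z), stats::sd(z), length(z))
    } else {
      function(z) scaled_center(stats::median(z), stats::mad(z), length(z))
    }
    obs <- stat_fun(diffs)
    null_stats <- with_seed(seed, {
      if (null == "pair_swap") {
        vapply(seq_len(n_perm), function(b) {
          stat_fun(diffs * sample(c(-1, 1), m, replace = TRUE))
        }, numeric(1))
      } else {
        vapply(seq_len(n_perm), function(b) {
          stat_fun(diffs * sample(c(-1, 1), 1))
        }, numeric(1))
      }
    })
    perm_p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_perm + 1)
    wp <- if (all(diffs == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(x2, x1, paired = TRUE)$p.value)
    }
    data.frame(trait = d$trait[1], obs_stat = obs, perm_p = perm_p,
               wilcoxon_p = wp,
               direction = ifelse(obs > 0, "increase",
                                  ifelse(obs < 0, "decrease", "none")),
               n_sites = m, n_perm = n_perm,
               seed = if (is.null(seed)) NA_integer_ else seed,
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
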