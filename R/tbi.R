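#' Temporal beta diversity index for one site
#'
#' Bray-Curtis percentage difference between the two survey eras of a single
#' site, decomposed into the component driven by species losses and the
#' component driven by species gains. With per-species minima
#' `A = sum_j min(y1j, y2j)`, losses `B = sum_j max(y1j - y2j, 0)` and gains
#' `C = sum_j max(y2j - y1j, 0)`, the index is `(B + C) / (2A + B + C)`,
#' ranging from 0 (no change) to 1 (completely novel community), with
#' `tbi = loss + gain` exactly.
#'
#' @param y1,y2 Nonnegative frequency vectors in the same species order.
#' @param site Optional site identifier carried into the record.
#' @return A one-row data.frame: `site`, `A`, `B`, `C`, `tbi`, `loss`, `gain`.
#' @export
compute_tbi <- function(y1, y2, site = NA) {
  if (length(y1) != length(y2)) {
    stop_canopyshift("era vectors differ in length", "canopyshift_invalid_argument")
  }
  if (any(y1 < 0) || any(y2 < 0)) {
    stop_canopyshift("frequencies must be nonnegative", "canopyshift_invalid_argument")
  }
  if (sum(y1) == 0 && sum(y2) == 0) {
    stop_canopyshift("both eras all-zero: dissimilarity undefined",
                     "canopyshift_undefined_dissimilarity")
  }
  A <- sum(pmin(y1, y2))
  B <- sum(pmax(y1 - y2, 0))
  C <- sum(pmax(y2 - y1, 0))
  den <- 2 * A + B + C
  data.frame(site = site, A = A, B = B, C = C,
             tbi = (B + C) / den, loss = B / den, gain = C / den)
}

#' TBI records for all paired sites
#'
#' @param comm1,comm2 Site-by-species frequency matrices (same dimnames) for
#'   the two eras.
#' @return data.frame of per-site TBI records.
#' @export
tbi_table <- function(comm1, comm2) {
  stopifnot(all(dim(comm1) == dim(comm2)))
  if (!is.null(rownames(comm1)) && !is.null(rownames(comm2))) {
    stopifnot(identical(rownames(comm1), rownames(comm2)))
  }
  sites <- rownames(comm1)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(comm1)))
  out <- lapply(seq_len(nrow(comm1)), function(i) {
    compute_tbi(comm1[i, ], comm2[i, ], site = sites[i])
  })
  do.call(rbind, out)
}

#' Compare gain and loss components of temporal dissimilarity
#'
#' Tests whether the share of dissimilarity driven by species gains differs
#' from that driven by losses across sites: Welch two-sample t by default,
#' or a paired t on the per-site gain-loss differences.
#'
#' @param records data.frame from [tbi_table()] with `gain` and `loss`.
#' @param paired Paired t-test instead of Welch.
#' @return List with `t`, `df`, `p_value`, `method`.
#' @export
compare_gain_loss <- function(records, paired = FALSE) {
  if (nrow(records) < 2L) {
    stop_canopyshift("need >= 2 sites", "canopyshift_invalid_argument")
  }
  g <- records$gain
  l <- records$loss
  if (stats::sd(g) == 0 && stats::sd(l) == 0 && !paired) {
    if (all(g == l)) {
      return(list(t = 0, df = 2 * (length(g) - 1), p_value = 1,
                  method = "degenerate: identical constant components"))
    }
    stop_canopyshift("zero variance in both components",
                     "canopyshift_degenerate_test")
  }
  if (paired && stats::sd(g - l) == 0) {
    if (all(g == l)) {
      return(list(t = 0, df = length(g) - 1, p_value = 1,
                  method = "degenerate: gains equal losses at every site"))
    }
    stop_canopyshift("zero variance in paired differences",
                     "canopyshift_degenerate_test")
  }
  tt <- if (paired) stats::t.test(g, l, paired = TRUE)
        else stats::t.test(g, l, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = tt$method)
}
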