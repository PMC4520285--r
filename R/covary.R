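# Co-variation and regionality of SNEPs.
#
# Mark-by-mark Spearman correlations of per-nucleosome ChIP/MNase
# signal; co-variation of SNEP sets across marks (significant divergence
# in the second mark, same direction); regionality as the frequency of
# SNEPs among the ten ordinal neighbours on each side, against a
# label-reassignment null; positional-class and persistence contingency
# tests.

#' Mark-by-mark Spearman correlation matrix
#'
#' @param signal matrix nucleosome x mark of per-nucleosome ChIP/MNase
#'   signal in one strain
#' @param min_n minimum number of complete nucleosomes
#' @return symmetric correlation matrix with unit diagonal; rows of
#'   constant marks are masked (NA)
#' @export
mark_correlation <- function(signal, min_n = 100L) {
  signal <- as.matrix(signal)
  ok <- complete.cases(signal)
  fail_if(sum(ok) < min_n, "need >= %d nucleosomes with full signal",
          min_n)
  s <- signal[ok, , drop = FALSE]
  const <- apply(s, 2, function(x) var(x) == 0)
  rho <- suppressWarnings(cor(s, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho)[!const] <- 1
  rho
}

#' Co-variation of one mark's SNEPs with another mark
#'
#' A SNEP of mark 1 co-varies with mark 2 when mark 2's interaction
#' p-value at the same nucleosome is below `p_threshold` AND its
#' direction has the same sign (a zero estimate counts as
#' non-co-varying).  Enrichment over the non-SNEP background is tested
#' by Fisher's exact test.
#'
#' @param snep1 logical vector: SNEP calls of mark 1 on the shared unit
#'   universe
#' @param dir1 integer vector: directions of mark 1 (sign of estimate)
#' @param p2,dir2 mark-2 interaction p-values and directions on the same
#'   universe
#' @param p_threshold nominal p threshold for mark-2 divergence
#' @return list(fraction, n, table, fisher_p); fraction is NA (typed
#'   "undefined") for an empty SNEP set
#' @export
snep_covariation <- function(snep1, dir1, p2, dir2, p_threshold = 0.01) {
  covary <- !is.na(p2) & p2 < p_threshold & dir2 != 0 & dir2 == dir1
  if (!any(snep1, na.rm = TRUE))
    return(list(fraction = NA_real_, n = 0L, table = NULL,
                fisher_p = NA_real_))
  in_set <- which(snep1)
  out_set <- which(!snep1)
  tab <- matrix(c(sum(covary[in_set]), length(in_set) - sum(covary[in_set]),
                  sum(covary[out_set]),
                  length(out_set) - sum(covary[out_set])),
                2, 2, dimnames = list(c("covary", "no"),
                                      c("snep", "background")))
  ft <- fisher.test(tab, alternative = "greater")
  list(fraction = sum(covary[in_set]) / length(in_set),
       n = length(in_set), table = tab, fisher_p = ft$p.value)
}

#' Regionality of SNEPs along the nucleosome order
#'
#' For each SNEP, records whether its k-th ordinal neighbour (k in
#' -window..window, 0 excluded) is also a SNEP; neighbours beyond the
#' ends are dropped from the denominator.  The expectation is estimated
#' by re-assigning the same number of SNEP labels to random nucleosomes
#' of the eligible universe.
#'
#' @param snep logical vector of SNEP calls on genome-ordered nucleosomes
#' @param window ordinal neighbourhood radius
#' @param n_randomizations randomization count
#' @param seed integer seed
#' @param universe optional logical vector restricting the randomization
#'   universe (e.g. above-background ChIP signal); SNEP positions are
#'   always part of the universe
#' @return list(offsets, observed, expected, envelope_lo, envelope_hi)
#' @export
regionality <- function(snep, window = 10L, n_randomizations = 100L,
                        seed = 1L, universe = NULL) {
  n <- length(snep)
  fail_if(sum(snep) < 2, "need >= 2 SNEPs")
  if (is.null(universe)) universe <- rep(TRUE, n)
  universe <- universe | snep
  offsets <- setdiff(seq(-window, window), 0L)
  profile_of <- function(lab) {
    idx <- which(lab)
    vapply(offsets, function(k) {
      nb <- idx + k
      ok <- nb >= 1L & nb <= n
      if (!any(ok)) return(NA_real_)
      mean(lab[nb[ok]])
    }, numeric(1))
  }
  obs <- profile_of(snep)
  n_snep <- sum(snep)
  uni_idx <- which(universe)
  rand <- with_seed(derive_seed(seed, 30L), {
    vapply(seq_len(n_randomizations), function(r) {
      lab <- logical(n)
      lab[sample(uni_idx, n_snep)] <- TRUE
      profile_of(lab)
    }, numeric(length(offsets)))
  })
  rand <- matrix(rand, nrow = length(offsets))
  list(offsets = offsets, observed = obs,
       expected = rowMeans(rand, na.rm = TRUE),
       envelope_lo = apply(rand, 1, min, na.rm = TRUE),
       envelope_hi = apply(rand, 1, max, na.rm = TRUE))
}

#' Positional-class enrichment of calls
#'
#' Contingency of call frequency across positional classes (+1, -1,
#' other), chi-square test with an exact-test fallback when any expected
#' cell is below 5.
#'
#' @param calls logical vector (SNEP or shifted flags)
#' @param classes character vector of class labels, same length
#' @return list(table, freq, p, method); classes with zero members are
#'   dropped with a warning
#' @export
class_enrichment <- function(calls, classes) {
  keep <- !is.na(classes) & !is.na(calls)
  calls <- calls[keep]; classes <- classes[keep]
  tabn <- table(classes)
  if (any(tabn == 0)) {
    warning("dropping empty classes")
    classes <- factor(classes)
  }
  fail_if(length(unique(classes)) < 2, "need >= 2 classes")
  tab <- table(factor(calls, levels = c(FALSE, TRUE)), classes)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 5)) {
    p <- fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                     B = 1e4)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(chisq.test(tab)$p.value)
    method <- "chisq"
  }
  freq <- tab[2, ] / colSums(tab)
  list(table = tab, freq = freq, p = p, method = method)
}

#' Persistence vs co-variation contingency
#'
#' Chi-square independence test of SNEP persistence (persistent/labile)
#' against co-variation with another mark, optionally within strata
#' (e.g. genetic-control status); strata with a degenerate margin fall
#' back to Fisher's exact test, and empty strata are "unevaluable".
#'
#' @param persistence character vector ("persistent"/"labile")
#' @param covaries logical vector, same length
#' @param strata optional stratum labels
#' @return data.frame(stratum, n, p, method)
#' @export
persistence_covariation <- function(persistence, covaries,
                                    strata = NULL) {
  if (is.null(strata)) strata <- rep("all", length(persistence))
  if (length(persistence) == 0)
    return(data.frame(stratum = "all", n = 0L, p = NA_real_,
                      method = "unevaluable"))
  out <- lapply(unique(strata), function(s) {
    sel <- strata == s & !is.na(persistence) & !is.na(covaries)
    if (sum(sel) == 0)
      return(data.frame(stratum = s, n = 0L, p = NA_real_,
                        method = "unevaluable"))
    tab <- table(factor(persistence[sel],
                        levels = c("labile", "persistent")),
                 factor(covaries[sel], levels = c(FALSE, TRUE)))
    if (any(rowSums(tab) < 2) || any(colSums(tab) < 2)) {
      p <- fisher.test(tab)$p.value
      method <- "fisher"
    } else {
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_counts < 5)) {
        p <- fisher.test(tab)$p.value
        method <- "fisher"
      } else {
        p <- suppressWarnings(chisq.test(tab)$p.value)
        method <- "chisq"
      }
    }
    data.frame(stratum = s, n = sum(sel), p = p, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
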