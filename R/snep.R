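# Single-nucleosome epi-polymorphism (SNEP) detection.
#
# Each testable unit (matched well-positioned pair or UNR) gets an
# integer count of forward read starts per sample, taken in the sample's
# own strain coordinates.  Counts are modelled as negative binomial with
# a log link and an offset for the sample size factor:
#
#   log mu = log(sf) + strain + assay + strain:assay
#
# The SNEP statistic is the likelihood-ratio test (1 df) of the
# strain:assay interaction: a ChIP difference not explained by the MNase
# (occupancy) difference.  The occupancy-only test is the strain-effect
# LRT on MNase counts alone.  Dispersion is a per-unit method-of-moments
# estimate shrunk halfway toward a mean-dispersion trend fitted across
# units (floored at 1e-8), giving small-replicate stability without
# importing a specific package's shrinkage scheme.

#' Extract per-unit read counts
#'
#' Matched pairs are counted over [dyad - 73, dyad + 74) in each strain's
#' own coordinates; UNRs over their interval (strain-1 coordinates,
#' translated for strain-2 samples).  Units that fail to translate are
#' excluded and logged via a message.
#'
#' @param rs a `read_set`
#' @param matched output of [match_maps()]
#' @return a `count_table`: list(counts (units x samples), units, meta)
#' @export
extract_counts <- function(rs, matched) {
  pairs <- matched$pairs
  unrs <- matched$unrs
  cur_set <- matched$cur_set
  units <- rbind(
    if (nrow(pairs) > 0)
      data.frame(unit_id = pairs$id1, type = "pair",
                 start1 = pairs$dyad1 - 73L, end1 = pairs$dyad1 + 74L,
                 start2 = pairs$dyad2 - 73L, end2 = pairs$dyad2 + 74L,
                 stringsAsFactors = FALSE),
    if (nrow(unrs) > 0)
      data.frame(unit_id = unrs$unr_id, type = "unr",
                 start1 = unrs$start, end1 = unrs$end,
                 start2 = translate(cur_set, unrs$start, "ref2alt"),
                 end2 = translate(cur_set, unrs$end - 1L, "ref2alt") + 1L,
                 stringsAsFactors = FALSE))
  bad <- is.na(units$start2) | is.na(units$end2)
  if (any(bad)) {
    message(sprintf("excluding %d units outside CURs", sum(bad)))
    units <- units[!bad, , drop = FALSE]
  }
  meta <- rs$meta
  counts <- matrix(0L, nrow(units), nrow(meta),
                   dimnames = list(units$unit_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    ss <- sort(rs$reads[[meta$sample_id[j]]])
    if (meta$strain[j] == rs$strains[1]) {
      lo <- units$start1; hi <- units$end1
    } else {
      lo <- units$start2; hi <- units$end2
    }
    counts[, j] <- findInterval(hi - 1L, ss) - findInterval(lo - 1L, ss)
  }
  structure(list(counts = counts, units = units, meta = meta),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d units x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The classic median-of-ratios estimator: for each sample, the median
#' over all-positive rows of count / row geometric mean.  If no row is
#' all-positive, falls back to total-count ratios with a warning.
#'
#' @param counts integer matrix (units x samples) or a `count_table`
#' @return named numeric vector of positive size factors
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no row with all-positive counts; using total-count ratios")
    tot <- colSums(counts)
    return(setNames(tot / exp(mean(log(tot))), colnames(counts)))
  }
  lc <- log(counts[pos, , drop = FALSE])
  lgm <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - lgm)))
  setNames(sf, colnames(counts))
}

# ---- NB GLM machinery ----------------------------------------------------

# LRT of the last column of X_full against X_red, NB family with fixed
# theta, log link, offset.  Returns c(p, estimate) or NA on failure.
.nb_lrt <- function(y, X_full, X_red, offset, theta) {
  fam <- MASS::negative.binomial(theta = theta)
  fit_full <- tryCatch(
    suppressWarnings(stats::glm.fit(X_full, y, family = fam,
                                    offset = offset)),
    error = function(e) NULL)
  fit_red <- tryCatch(
    suppressWarnings(stats::glm.fit(X_red, y, family = fam,
                                    offset = offset)),
    error = function(e) NULL)
  if (is.null(fit_full) || is.null(fit_red) ||
        !fit_full$converged || !fit_red$converged)
    return(c(NA_real_, NA_real_))
  stat <- max(fit_red$deviance - fit_full$deviance, 0)
  df <- ncol(X_full) - ncol(X_red)
  p <- pchisq(stat, df, lower.tail = FALSE)
  c(p, fit_full$coefficients[ncol(X_full)])
}

#' Estimate per-unit NB dispersions
#'
#' Method-of-moments within strain x assay cells on size-factor
#' normalized counts, pooled per unit, then shrunk 50 percent toward a
#' parametric mean-dispersion trend alpha(mu) = a0 + a1 / mu fitted
#' across units; floored at 1e-8.
#'
#' @param counts matrix (units x samples)
#' @param sf size factors (one per sample)
#' @param cell factor defining replicate groups (strain x assay)
#' @return numeric vector of dispersions, one per unit
#' @export
estimate_dispersions <- function(counts, sf, cell) {
  q <- sweep(counts, 2, sf, "/")
  cells <- split(seq_len(ncol(q)), cell)
  n_units <- nrow(q)
  mu_mat <- sapply(cells, function(idx) rowMeans(q[, idx, drop = FALSE]))
  v_mat <- sapply(cells, function(idx)
    apply(q[, idx, drop = FALSE], 1, var))
  mu_mat <- matrix(mu_mat, nrow = n_units)
  v_mat <- matrix(v_mat, nrow = n_units)
  num <- rowSums(v_mat - mu_mat, na.rm = TRUE)
  den <- rowSums(mu_mat^2, na.rm = TRUE)
  raw <- pmax(num / pmax(den, 1e-12), 0)
  mu_bar <- rowMeans(mu_mat, na.rm = TRUE)
  use <- raw > 0 & mu_bar > 0
  if (sum(use) >= 10) {
    fit <- lm(raw[use] ~ I(1 / mu_bar[use]))
    a <- pmax(stats::coef(fit), 0)
    trend <- a[1] + a[2] / pmax(mu_bar, 1e-8)
  } else {
    trend <- rep(median(raw[use], na.rm = TRUE), n_units)
    trend[!is.finite(trend)] <- 0.01
  }
  pmax(0.5 * raw + 0.5 * trend, 1e-8)
}

#' Interaction (SNEP) test for one unit
#'
#' NB log-link model with size-factor offsets; likelihood-ratio test
#' (1 df) of the strain:assay interaction.  The direction is the sign of
#' the interaction coefficient: positive means higher ChIP per occupancy
#' in strain 2 (the non-reference strain).
#'
#' @param y integer counts for one unit
#' @param strain factor/character of strain per sample (2 levels)
#' @param assay factor/character of assay per sample ("MNase"/"ChIP")
#' @param sf size factors per sample
#' @param dispersion NB dispersion (alpha; variance mu + alpha mu^2)
#' @return list(p, estimate, direction); p is NA with a reason attribute
#'   when the unit is untestable
#' @export
test_interaction <- function(y, strain, assay, sf, dispersion = 0.01) {
  strain <- factor(strain)
  assay <- factor(assay, levels = c("MNase", "ChIP"))
  fail_if(nlevels(strain) != 2, "need exactly two strains")
  tab <- table(strain, assay)
  if (any(tab < 2))
    return(structure(list(p = NA_real_, estimate = NA_real_,
                          direction = 0L), reason = "insufficient replicates"))
  chip <- assay == "ChIP"
  if (all(y[chip] == 0))
    return(structure(list(p = NA_real_, estimate = NA_real_,
                          direction = 0L), reason = "insufficient signal"))
  X_full <- stats::model.matrix(~ strain * assay)
  X_red <- stats::model.matrix(~ strain + assay)
  theta <- 1 / max(dispersion, 1e-8)
  res <- .nb_lrt(y, X_full, X_red, log(sf), theta)
  list(p = res[1], estimate = res[2],
       direction = if (is.na(res[2])) 0L else as.integer(sign(res[2])))
}

#' Occupancy test for one unit (MNase-only strain effect)
#'
#' @inheritParams test_interaction
#' @return list(p, estimate)
#' @export
test_occupancy <- function(y, strain, sf, dispersion = 0.01) {
  strain <- factor(strain)
  fail_if(nlevels(strain) != 2, "need exactly two strains")
  if (any(table(strain) < 2))
    return(structure(list(p = NA_real_, estimate = NA_real_),
                     reason = "insufficient replicates"))
  X_full <- stats::model.matrix(~ strain)
  X_red <- X_full[, 1, drop = FALSE]
  theta <- 1 / max(dispersion, 1e-8)
  res <- .nb_lrt(y, X_full, X_red, log(sf), theta)
  list(p = res[1], estimate = res[2])
}

#' Benjamini-Hochberg SNEP calls
#'
#' Step-up FDR control across all tested units of one mark x strain
#' pair.  NA p-values (untestable units) are excluded from the
#' adjustment and called FALSE.
#'
#' @param p numeric vector of interaction p-values
#' @param fdr false discovery rate (default 1e-4)
#' @return logical vector of calls, same length as `p`
#' @export
call_sneps <- function(p, fdr = 1e-4) {
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (!any(ok)) return(out)
  out[ok] <- p.adjust(p[ok], method = "BH") <= fdr
  out
}

#' Full SNEP scan of a count table for one mark
#'
#' Runs the occupancy and interaction tests on every unit using the
#' MNase samples plus the ChIP samples of `mark`, with size factors
#' computed across those samples and dispersions from
#' [estimate_dispersions()].
#'
#' @param ct a `count_table`
#' @param mark ChIP mark to test
#' @param fdr FDR for [call_sneps()]
#' @param sf optional pre-computed size factors (all samples)
#' @param dispersions optional pre-computed per-unit dispersions
#' @return data.frame(unit_id, type, mark, p_interaction, estimate,
#'   direction, p_occupancy, called)
#' @export
snep_scan <- function(ct, mark, fdr = 1e-4, sf = NULL,
                      dispersions = NULL) {
  meta <- ct$meta
  sel <- meta$assay == "MNase" | (meta$assay == "ChIP" &
                                    !is.na(meta$mark) & meta$mark == mark)
  fail_if(sum(sel & meta$assay == "ChIP") == 0,
          "no ChIP samples for mark %s", mark)
  sub <- ct$counts[, sel, drop = FALSE]
  m <- meta[sel, ]
  if (is.null(sf)) sf <- size_factors(sub)
  cell <- paste(m$strain, m$assay)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(sub, sf, cell)
  strain <- factor(m$strain)
  assay <- factor(m$assay, levels = c("MNase", "ChIP"))
  X_full <- stats::model.matrix(~ strain * assay)
  X_red <- stats::model.matrix(~ strain + assay)
  mn <- assay == "MNase"
  X_occ <- stats::model.matrix(~ strain)[mn, , drop = FALSE]
  X_occ0 <- X_occ[, 1, drop = FALSE]
  off <- log(sf)
  n <- nrow(sub)
  p_int <- est <- p_occ <- rep(NA_real_, n)
  chip <- !mn
  for (i in seq_len(n)) {
    y <- sub[i, ]
    theta <- 1 / max(dispersions[i], 1e-8)
    if (any(y[chip] > 0)) {
      r <- .nb_lrt(y, X_full, X_red, off, theta)
      p_int[i] <- r[1]; est[i] <- r[2]
    }
    r2 <- .nb_lrt(y[mn], X_occ, X_occ0, off[mn], theta)
    p_occ[i] <- r2[1]
  }
  data.frame(unit_id = ct$units$unit_id, type = ct$units$type,
             mark = mark, p_interaction = p_int, estimate = est,
             direction = ifelse(is.na(est), 0L, as.integer(sign(est))),
             p_occupancy = p_occ,
             called = call_sneps(p_int, fdr),
             stringsAsFactors = FALSE)
}
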