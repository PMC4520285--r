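# Gene-level analysis.
#
# Each gene longer than 100 bp and fully inside a CUR is segmented into
# 600 bins: 250 fixed 10-bp bins upstream of the TSS (bins 1-250, bin
# 250 abutting the TSS), 100 percentile bins spanning TSS to TES (bins
# 251-350) and 250 fixed 10-bp bins downstream of the TES (bins
# 351-600), all oriented 5' to 3'.  Bin values are per-million forward
# read starts, size-factor normalized, replicate averaged.  Derived
# log2(ChIP/MNase) profiles feed the differential-pattern clustering and
# the per-gene divergence statistic epidiv.

# integer partition of `len` into `n` bins, remainder spread from the 5'
# side; widths differ by at most 1 bp and sum exactly to len
percentile_widths <- function(len, n = 100L) {
  base <- len %/% n
  extra <- len %% n
  base + as.integer(seq_len(n) <= extra)
}

# per-bin genomic boundaries (strain-1, 0-based) for one gene, in 5'->3'
# bin order; returns (n_bins+1)-vector of boundaries, increasing for "+"
# genes and decreasing for "-" genes
.gene_bin_boundaries <- function(gene, n_flank = 250L, flank_bin = 10L,
                                 n_body = 100L) {
  len <- gene$end - gene$start
  w <- percentile_widths(len, n_body)
  if (gene$strand == "+") {
    up <- gene$start - flank_bin * (n_flank:0)
    body <- gene$start + cumsum(c(0L, w))
    down <- gene$end + flank_bin * (0:n_flank)
    c(up, body[-1], down[-1])
  } else {
    up <- gene$end + flank_bin * (n_flank:0)
    body <- gene$end - cumsum(c(0L, w))
    down <- gene$start - flank_bin * (0:n_flank)
    c(up, body[-1], down[-1])
  }
}

#' Bin gene profiles over 600 segments
#'
#' @param rs a `read_set`
#' @param genes gene table (gene_id, start, end, strand, tss, tes)
#' @param cur_set a `cur_set`; genes not fully inside a single CUR are
#'   excluded (logged)
#' @param sf optional size factors per sample (default: all equal);
#'   chunk- or count-derived factors may be supplied
#' @param min_length minimal gene length (bp)
#' @return a `gene_profiles` object: list(arr [gene x bin x sample],
#'   collapsed [gene x bin x strain x assay] replicate averages, genes,
#'   meta, strains, marks)
#' @export
bin_genes <- function(rs, genes, cur_set, sf = NULL, min_length = 100L) {
  meta <- rs$meta
  if (is.null(sf)) sf <- setNames(rep(1, nrow(meta)), meta$sample_id)
  curs <- cur_set$curs
  inside <- vapply(seq_len(nrow(genes)), function(i) {
    any(curs$ref_start <= genes$start[i] & curs$ref_end >= genes$end[i])
  }, logical(1))
  keep <- inside & (genes$end - genes$start) > min_length
  if (any(!keep))
    message(sprintf("excluding %d genes (short or outside CURs)",
                    sum(!keep)))
  genes <- genes[keep, , drop = FALSE]
  fail_if(nrow(genes) == 0, "no usable genes")
  n_bins <- 600L
  arr <- array(NA_real_, dim = c(nrow(genes), n_bins, nrow(meta)),
               dimnames = list(genes$gene_id, NULL, meta$sample_id))
  strains <- rs$strains
  totals <- lengths(rs$reads)[meta$sample_id]
  sorted <- lapply(rs$reads, sort)
  for (i in seq_len(nrow(genes))) {
    bb1 <- .gene_bin_boundaries(genes[i, ])
    for (j in seq_len(nrow(meta))) {
      bb <- bb1
      if (meta$strain[j] != strains[1]) {
        bb <- translate(cur_set, bb1, "ref2alt")
        # flank boundaries outside CURs stay NA and yield NA bins
      }
      ss <- sorted[[meta$sample_id[j]]]
      fi <- findInterval(bb - 1L, ss)
      asc <- bb1[1] < bb1[length(bb1)]
      cnt <- if (asc) diff(fi) else -diff(fi)
      arr[i, , j] <- (cnt / totals[j] * 1e6) / sf[meta$sample_id[j]]
    }
  }
  marks <- sort(unique(na.omit(meta$mark)))
  assays <- c("MNase", marks)
  collapsed <- array(NA_real_,
                     dim = c(nrow(genes), n_bins, length(strains),
                             length(assays)),
                     dimnames = list(genes$gene_id, NULL, strains, assays))
  for (st in strains) {
    for (a in assays) {
      idx <- which(meta$strain == st &
                     (if (a == "MNase") meta$assay == "MNase"
                      else !is.na(meta$mark) & meta$mark == a))
      if (length(idx) > 0)
        collapsed[, , st, a] <-
          apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
    }
  }
  structure(list(arr = arr, collapsed = collapsed, genes = genes,
                 meta = meta, strains = strains, marks = marks),
            class = "gene_profiles")
}

#' @export
print.gene_profiles <- function(x, ...) {
  cat(sprintf("gene_profiles: %d genes x 600 bins, %d strains, %d marks\n",
              nrow(x$genes), length(x$strains), length(x$marks)))
  invisible(x)
}

#' log2(ChIP/MNase) profiles
#'
#' @param gp a `gene_profiles`
#' @param pseudo pseudo-count (per-million units) stabilizing the ratio
#' @return array [gene x bin x strain x mark]
#' @export
chip_mnase_logratio <- function(gp, pseudo = 0.1) {
  out <- array(NA_real_,
               dim = c(dim(gp$collapsed)[1:3], length(gp$marks)),
               dimnames = c(dimnames(gp$collapsed)[1:3],
                            list(gp$marks)))
  for (st in gp$strains)
    for (m in gp$marks)
      out[, , st, m] <- log2((gp$collapsed[, , st, m] + pseudo) /
                               (gp$collapsed[, , st, "MNase"] + pseudo))
  out
}

#' Meta-gene average profiles
#' @param gp a `gene_profiles`
#' @return array [bin x strain x assay]: profiles averaged across genes
#' @export
metagene_profiles <- function(gp) {
  apply(gp$collapsed, c(2, 3, 4), mean, na.rm = TRUE)
}

#' Differential patterns and complete-linkage clustering
#'
#' Per gene, the five-mark log-ratio profiles are truncated to 500 bp
#' upstream of the TSS and downstream of the TES (bins 201-450),
#' concatenated, and differenced between two strains; genes with
#' near-zero ChIP signal for all marks in all strains are dropped.
#' Complete-linkage clustering on Euclidean distances.
#'
#' @param gp a `gene_profiles`
#' @param pair character(2) strains (difference = first - second)
#' @param pseudo pseudo-count for the log ratio
#' @param near_zero mean per-million ChIP threshold under which a gene
#'   counts as signal-free for a mark
#' @return list(vectors (gene x feature), tree (hclust), dropped)
#' @export
differential_patterns <- function(gp, pair = gp$strains[1:2],
                                  pseudo = 0.1, near_zero = 1e-3) {
  lr <- chip_mnase_logratio(gp, pseudo)
  keep_bins <- 201:450
  # near-zero-signal exclusion: mean ChIP coverage below threshold for
  # every mark in every strain
  zero <- rep(TRUE, dim(gp$collapsed)[1])
  for (st in pair)
    for (m in gp$marks)
      zero <- zero & (rowMeans(gp$collapsed[, , st, m, drop = FALSE],
                               na.rm = TRUE) < near_zero)
  vecs <- do.call(cbind, lapply(gp$marks, function(m) {
    lr[, keep_bins, pair[1], m] - lr[, keep_bins, pair[2], m]
  }))
  rownames(vecs) <- dimnames(lr)[[1]]
  vecs <- vecs[!zero, , drop = FALSE]
  fail_if(nrow(vecs) < 2, "need >= 2 genes after exclusion")
  vecs0 <- vecs
  vecs0[is.na(vecs0)] <- 0
  tree <- hclust(dist(vecs0), method = "complete")
  list(vectors = vecs, tree = tree,
       dropped = dimnames(lr)[[1]][zero])
}

#' Cut a differential-pattern tree
#' @param dp output of [differential_patterns()]
#' @param k number of clusters
#' @return named integer vector of cluster assignments
#' @export
cut_patterns <- function(dp, k) stats::cutree(dp$tree, k = k)

#' Per-gene epigenomic divergence (epidiv)
#'
#' Balanced ANOVA of the log-ratio over strain, mark and bin with the
#' model terms strain + mark + bin + strain:mark + strain:bin +
#' strain:mark:bin; the mark:bin subspace is deliberately absent and is
#' absorbed by the residual (df = (marks-1)(bins-1)).  Effects are
#' orthogonal in this balanced one-observation-per-cell layout, so each
#' term's SS equals its classical balanced-ANOVA SS regardless of order.
#' epidiv is the F statistic of the strain:mark term.
#'
#' @param y 3-d array [strain x mark x bin] of replicate-averaged
#'   log-ratios for one gene (no missing cells)
#' @return list(epidiv, table) with the full ANOVA table
#' @export
epidiv <- function(y) {
  d <- dim(y)
  fail_if(length(d) != 3, "y must be a 3-d array [strain x mark x bin]")
  S <- d[1]; M <- d[2]; B <- d[3]
  fail_if(S < 2 || M < 2 || B < 2, "need >= 2 strains, marks and bins")
  fail_if(anyNA(y), "missing cells: gene skipped")
  g <- mean(y)
  ms <- apply(y, 1, mean) - g
  mm <- apply(y, 2, mean) - g
  mb <- apply(y, 3, mean) - g
  sm <- apply(y, c(1, 2), mean) - outer(ms, mm, "+") - g
  sb <- apply(y, c(1, 3), mean) - outer(ms, mb, "+") - g
  mkb <- apply(y, c(2, 3), mean) - outer(mm, mb, "+") - g
  ss <- c(strain = M * B * sum(ms^2),
          mark = S * B * sum(mm^2),
          bin = S * M * sum(mb^2),
          `strain:mark` = B * sum(sm^2),
          `strain:bin` = M * sum(sb^2))
  ss_mb <- S * sum(mkb^2)
  total <- sum((y - g)^2)
  ss <- c(ss, `strain:mark:bin` = max(total - sum(ss) - ss_mb, 0))
  df <- c(S - 1, M - 1, B - 1, (S - 1) * (M - 1), (S - 1) * (B - 1),
          (S - 1) * (M - 1) * (B - 1))
  tab <- data.frame(term = names(ss), ss = as.numeric(ss), df = df)
  tab <- rbind(tab, data.frame(term = "residual", ss = ss_mb,
                               df = (M - 1) * (B - 1)))
  tab$ms <- tab$ss / tab$df
  f <- tab$ms[tab$term == "strain:mark"] / tab$ms[tab$term == "residual"]
  list(epidiv = as.numeric(f), table = tab)
}

#' epidiv for every gene of a profile set
#'
#' @param gp a `gene_profiles`
#' @param pseudo pseudo-count for the log ratio
#' @param bins bin subset used (default all 600)
#' @return data.frame(gene_id, epidiv); genes with missing cells are
#'   skipped with reason "missing cells"
#' @export
epidiv_all <- function(gp, pseudo = 0.1, bins = seq_len(600L)) {
  lr <- chip_mnase_logratio(gp, pseudo)
  n <- dim(lr)[1]
  out <- data.frame(gene_id = dimnames(lr)[[1]],
                    epidiv = NA_real_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    y <- aperm(lr[i, bins, , , drop = FALSE][1, , , ], c(2, 3, 1))
    if (anyNA(y)) {
      out$reason[i] <- "missing cells"
      next
    }
    out$epidiv[i] <- epidiv(y)$epidiv
  }
  out
}

#' Select genes by 3'-vs-5' differential imbalance (delta)
#'
#' delta = median of the differential profile over R2 (segments
#' 284-333, mid gene body) minus the median over R1 (segments 251-266,
#' immediately downstream of the TSS); genes with delta above `cutoff`
#' are selected.
#'
#' @param d matrix gene x 600 of differential profile values
#' @param r1,r2 segment index vectors
#' @param cutoff selection threshold
#' @return data.frame(gene_id, delta, selected)
#' @export
delta_select <- function(d, r1 = 251:266, r2 = 284:333, cutoff = 10) {
  delta <- apply(d[, r2, drop = FALSE], 1, median) -
    apply(d[, r1, drop = FALSE], 1, median)
  data.frame(gene_id = rownames(d), delta = as.numeric(delta),
             selected = as.numeric(delta) > cutoff,
             stringsAsFactors = FALSE)
}

#' Two-sample KS test of a subset against all values
#'
#' @param values numeric vector (e.g. per-nucleosome log ratios)
#' @param mask logical subset indicator (non-empty proper subset)
#' @return list(statistic, p)
#' @export
subset_shift_test <- function(values, mask) {
  fail_if(!any(mask) || all(mask), "mask must be a non-empty proper subset")
  kt <- suppressWarnings(ks.test(values[mask], values))
  list(statistic = as.numeric(kt$statistic), p = kt$p.value)
}

#' QTL scan of a profile-redistribution metaphenotype
#'
#' Per gene and segregant, nucleosome values are rank-transformed across
#' segregants; the gene-level phenotype is the mean rank over second-half
#' nucleosomes minus the mean rank over first-half nucleosomes.  A PCA
#' across genes summarizes the segregant-level trend; components passing
#' the permutation significance rule (at most `max_components` of them)
#' become metaphenotypes.  Every marker is tested by a Wilcoxon rank-sum
#' of metaphenotype by genotype; the genome-wide significance threshold
#' is the maximum score over `n_permutations` genotype-permuted scans.
#'
#' @param values list of gene matrices (nucleosome x segregant)
#' @param halves integer vector (1 = 5' half, 2 = 3' half) per nucleosome
#' @param genotypes matrix segregants x markers, values in 0/1
#' @param n_permutations permutations for the threshold (default 10)
#' @param seed integer seed (threshold is deterministic given the seed)
#' @param max_components metaphenotypes retained
#' @param n_pca_perm permutations for component significance
#' @return list(scores, threshold, metaphenotypes, significant_markers,
#'   phen)
#' @export
qtl_scan <- function(values, halves, genotypes, n_permutations = 10L,
                     seed = 1L, max_components = 2L, n_pca_perm = 3L) {
  n_seg <- nrow(genotypes)
  fail_if(n_seg < 10, "scan refuses: fewer than 10 segregants")
  fail_if(!all(genotypes %in% c(0L, 1L)), "genotypes must be 0/1")
  phen <- sapply(values, function(v) {
    rk <- t(apply(v, 1, rank))
    colMeans(rk[halves == 2L, , drop = FALSE]) -
      colMeans(rk[halves == 1L, , drop = FALSE])
  })  # segregants x genes
  pca <- pca_components(t(phen), n_permutations = n_pca_perm,
                        seed = seed, normalize = "none")
  sig <- which(pca$significant)
  used <- if (length(sig) > 0) head(sig, max_components) else 1L
  meta <- pca$scores[, used, drop = FALSE]
  poly <- apply(genotypes, 2, function(g) length(unique(g)) == 2)
  score_fun <- function(gt) {
    pmat <- sapply(seq_len(ncol(meta)), function(k)
      wilcox_scan(meta[, k], gt))
    pmat <- matrix(pmat, nrow = ncol(gt))
    apply(pmat, 1, function(p)
      if (all(is.na(p))) NA_real_ else max(-log10(p), na.rm = TRUE))
  }
  scores <- score_fun(genotypes)
  perm_max <- with_seed(derive_seed(seed, 20L), {
    vapply(seq_len(n_permutations), function(k) {
      gp <- genotypes[sample.int(n_seg), , drop = FALSE]
      max(score_fun(gp), na.rm = TRUE)
    }, numeric(1))
  })
  threshold <- max(perm_max)
  list(scores = scores, threshold = threshold,
       metaphenotypes = meta, pca = pca,
       significant_markers =
         which(!is.na(scores) & poly & scores > threshold),
       phen = phen)
}

#' Vectorized Wilcoxon rank-sum p-values across markers
#'
#' Normal approximation with tie correction and continuity correction,
#' numerically matching `wilcox.test(..., exact = FALSE, correct =
#' TRUE)`; one two-sided p-value per marker column.  Monomorphic
#' markers yield NA.
#'
#' @param ph numeric phenotype vector (one value per segregant)
#' @param gt 0/1 genotype matrix, segregants x markers
#' @return numeric vector of p-values, one per marker
#' @export
wilcox_scan <- function(ph, gt) {
  n <- length(ph)
  r <- rank(ph)
  tie <- table(r)
  tiecorr <- sum(tie^3 - tie)
  n1 <- colSums(gt)
  W <- as.vector(crossprod(gt, r)) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  sigma2 <- (n1 * (n - n1) / 12) *
    ((n + 1) - tiecorr / (n * (n - 1)))
  z <- W - mu
  z <- z - sign(z) * 0.5
  p <- 2 * stats::pnorm(abs(z) / sqrt(sigma2), lower.tail = FALSE)
  p <- pmin(p, 1)
  p[n1 == 0 | n1 == n] <- NA_real_
  p
}

#' Associate a gene-level statistic with a covariate
#'
#' Spearman rank correlation for quantitative covariates, Wilcoxon
#' rank-sum for binary ones; also returns a smoothed average curve for
#' plotting.
#'
#' @param x numeric vector (e.g. epidiv per gene)
#' @param covariate numeric or two-level vector, same length
#' @param test "auto", "rank" (Spearman) or "two-group" (Wilcoxon)
#' @return list(test, statistic, p, smooth)
#' @export
covariate_assoc <- function(x, covariate, test = c("auto", "rank",
                                                   "two-group")) {
  test <- match.arg(test)
  ok <- is.finite(x) & !is.na(covariate)
  fail_if(sum(ok) < 10, "need >= 10 genes with both values")
  x <- x[ok]; covariate <- covariate[ok]
  fail_if(length(unique(covariate)) < 2, "constant covariate")
  binary <- length(unique(covariate)) == 2
  if (test == "auto") test <- if (binary) "two-group" else "rank"
  if (test == "two-group") {
    fail_if(!binary, "two-group test needs a binary covariate")
    lv <- sort(unique(covariate))
    wt <- wilcox.test(x[covariate == lv[1]], x[covariate == lv[2]],
                      exact = FALSE)
    sm <- NULL
    list(test = "wilcoxon", statistic = as.numeric(wt$statistic),
         p = wt$p.value, smooth = sm)
  } else {
    ct <- suppressWarnings(cor.test(x, as.numeric(covariate),
                                    method = "spearman", exact = FALSE))
    sm <- stats::lowess(as.numeric(covariate), x)
    list(test = "spearman", statistic = as.numeric(ct$estimate),
         p = ct$p.value, smooth = sm)
  }
}
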