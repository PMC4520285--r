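# Chunked genome coverage.
#
# Every CUR is segmented into fixed-size chunks (default 90 bp).  For
# each sample the chunk value is the number of forward read starts inside
# the chunk (in the sample's own strain coordinates), converted to reads
# per million and divided by the chunk's strain-specific length -- border
# chunks are shorter, and translated chunks can differ from 90 bp where
# indels fall inside them.

#' Chunked coverage matrix over CURs
#'
#' @param rs a `read_set` (forward starts only; reverse records are
#'   already dropped at BED import)
#' @param cur_set a pairwise `cur_set`; the read set's first strain must
#'   be the ref strain
#' @param chunk_size chunk size in bp
#' @return a `coverage_matrix`: list(values (chunks x samples), chunks
#'   (per-chunk intervals in both strains), meta (sample sheet))
#' @export
chunk_coverage <- function(rs, cur_set, chunk_size = 90L) {
  stopifnot(inherits(rs, "read_set"), inherits(cur_set, "cur_set"))
  curs <- cur_set$curs
  fail_if(nrow(curs) == 0, "cur_set is empty")
  chunks <- do.call(rbind, lapply(seq_len(nrow(curs)), function(i) {
    cc <- curs[i, ]
    starts <- seq(cc$ref_start, cc$ref_end - 1L, by = chunk_size)
    ends <- pmin(starts + chunk_size, cc$ref_end)
    data.frame(cur_id = cc$cur_id, chunk = seq_along(starts),
               ref_start = starts, ref_end = ends)
  }))
  # translated interval on the alt strain (end-exclusive boundary maps
  # through the last included base)
  chunks$alt_start <- translate(cur_set, chunks$ref_start, "ref2alt")
  chunks$alt_end <- translate(cur_set, chunks$ref_end - 1L, "ref2alt") + 1L
  chunks$ref_len <- chunks$ref_end - chunks$ref_start
  chunks$alt_len <- chunks$alt_end - chunks$alt_start
  meta <- rs$meta
  values <- matrix(0, nrow(chunks), nrow(meta),
                   dimnames = list(NULL, meta$sample_id))
  strains <- rs$strains
  for (j in seq_len(nrow(meta))) {
    st <- meta$strain[j]
    starts <- rs$reads[[meta$sample_id[j]]]
    total <- length(starts)
    fail_if(total == 0, "sample %s has zero forward reads",
            meta$sample_id[j])
    if (st == strains[1]) {
      lo <- chunks$ref_start; hi <- chunks$ref_end; len <- chunks$ref_len
    } else {
      lo <- chunks$alt_start; hi <- chunks$alt_end; len <- chunks$alt_len
    }
    ss <- sort(starts)
    cnt <- findInterval(hi - 1L, ss) - findInterval(lo - 1L, ss)
    values[, j] <- (cnt / total * 1e6) / pmax(len, 1L)
  }
  structure(list(values = values, chunks = chunks, meta = meta),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d chunks x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Replicate quality control
#'
#' A replicate is flagged when 1 - Spearman correlation of its log1p
#' coverage with the element-wise median profile of its strain x assay
#' group exceeds `threshold`.  Groups of size 1 are "unevaluable".  If
#' every replicate of a group is flagged the group is unusable and an
#' error is raised.
#'
#' @param cm a `coverage_matrix`
#' @param threshold QC distance threshold
#' @return data.frame(sample_id, group, distance, verdict)
#' @export
qc_replicates <- function(cm, threshold = 0.25) {
  meta <- cm$meta
  grp <- paste(meta$strain, ifelse(is.na(meta$mark), "MNase", meta$mark),
               sep = ".")
  out <- data.frame(sample_id = meta$sample_id, group = grp,
                    distance = NA_real_, verdict = "ok",
                    stringsAsFactors = FALSE)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) {
      out$verdict[idx] <- "unevaluable"
      next
    }
    lv <- log1p(cm$values[, idx, drop = FALSE])
    med <- apply(lv, 1, median)
    d <- vapply(seq_along(idx), function(k) {
      1 - suppressWarnings(cor(lv[, k], med, method = "spearman"))
    }, numeric(1))
    d[!is.finite(d)] <- 1
    out$distance[idx] <- d
    out$verdict[idx] <- ifelse(d > threshold, "flagged", "ok")
    fail_if(all(d > threshold),
            "all replicates of group %s deviate from each other", g)
  }
  out
}

#' PCA of coverage profiles with permutation-based significance
#'
#' Columns are first normalized by their sum.  Component k is flagged
#' significant iff its variance fraction exceeds the maximum variance
#' fraction of component k across `n_permutations` runs on permuted
#' data (each chunk's values independently permuted across samples,
#' destroying inter-sample structure while preserving per-chunk
#' marginals).
#'
#' @param cm a `coverage_matrix` or a plain numeric matrix (chunks x
#'   samples)
#' @param n_permutations number of permuted PCA runs
#' @param seed integer seed for the permutations
#' @param log_transform apply log1p before PCA (default FALSE: PCA on
#'   sum-normalized raw coverages)
#' @param normalize "colsum" (divide each value by its column sum; the
#'   convention for non-negative coverage matrices) or "none" (for
#'   signed inputs such as rank phenotypes)
#' @return list(scores, varfrac, perm_max, significant, rotation)
#' @export
pca_components <- function(cm, n_permutations = 3L, seed = 1L,
                           log_transform = FALSE,
                           normalize = c("colsum", "none")) {
  normalize <- match.arg(normalize)
  m <- if (inherits(cm, "coverage_matrix")) cm$values else cm
  fail_if(ncol(m) < 3, "need >= 3 samples for PCA")
  if (normalize == "colsum") {
    cs <- colSums(m)
    fail_if(any(cs == 0), "constant zero column")
    m <- sweep(m, 2, cs, "/")
  }
  if (log_transform) m <- log1p(m)
  fail_if(all(apply(m, 1, var) == 0),
          "constant matrix: no components (degenerate input)")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- length(vf)
  perm_max <- rep(-Inf, k)
  with_seed(derive_seed(seed, 10L), {
    for (p in seq_len(n_permutations)) {
      mp <- t(apply(m, 1, sample))
      pp <- prcomp(t(mp), center = TRUE, scale. = FALSE)
      vfp <- pp$sdev^2 / sum(pp$sdev^2)
      kk <- min(k, length(vfp))
      perm_max[1:kk] <- pmax(perm_max[1:kk], vfp[1:kk])
    }
  })
  list(scores = pc$x, varfrac = vf, perm_max = perm_max,
       significant = vf > perm_max, rotation = pc$rotation)
}

#' Normalize ChIP coverage by the per-strain mean MNase profile
#'
#' Each ChIP column is divided, chunk-wise, by the mean of the MNase
#' columns of the same strain.  Chunks where the MNase profile falls
#' below `floor` are masked (NA), not divided.
#'
#' @param cm a `coverage_matrix`
#' @param floor minimal MNase value for division
#' @return a `coverage_matrix` whose ChIP columns are ratios; MNase
#'   columns are kept unchanged
#' @export
mnase_normalize <- function(cm, floor = 1e-6) {
  meta <- cm$meta
  values <- cm$values
  for (st in unique(meta$strain)) {
    mn <- which(meta$strain == st & meta$assay == "MNase")
    fail_if(length(mn) == 0, "strain %s lacks MNase samples", st)
    prof <- rowMeans(values[, mn, drop = FALSE])
    mask <- prof < floor
    ch <- which(meta$strain == st & meta$assay == "ChIP")
    for (j in ch) {
      v <- values[, j] / prof
      v[mask] <- NA_real_
      values[, j] <- v
    }
  }
  structure(list(values = values, chunks = cm$chunks, meta = meta),
            class = "coverage_matrix")
}
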