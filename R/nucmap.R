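# Nucleosome maps.
#
# Dyads are called per replicate from MNase-seq forward read starts
# (dyad = start + 73), smoothed with a Gaussian kernel and picked
# greedily highest-score-first with a 120-bp exclusion zone.  A consensus
# nucleosome is "well-positioned" when every replicate contributes
# exactly one dyad inside the consensus window and the replicate dyads'
# SD stays below a threshold; other occupied territory is "fuzzy".
# Cross-strain matching is mutual-nearest-neighbour after coordinate
# translation within a +/-75 bp window; everything unpaired is merged
# into unaligned nucleosomal regions (UNRs).

#' Call nucleosome dyads from one MNase-seq replicate
#'
#' @param starts 0-based forward read start positions
#' @param genome_length length of the contig (bp)
#' @param sigma Gaussian smoothing bandwidth (bp)
#' @param exclusion minimum distance between called dyads (bp)
#' @param score_floor_quantile score floor as a quantile of nonzero
#'   smoothed coverage; peaks below it are suppressed
#' @param noise_sd minimum peak prominence (height above the larger of
#'   the two flanking minima within the exclusion window) in SD units of
#'   the uniform-reads Poisson null, sqrt(density * ||k||^2) for
#'   smoothing kernel k; suppresses peak calling on unstructured
#'   coverage of matched depth while keeping weak but isolated peaks
#' @return data.frame(dyad, score), sorted by position
#' @export
call_dyads <- function(starts, genome_length, sigma = 15,
                       exclusion = 120L, score_floor_quantile = 0.25,
                       noise_sd = 3.5) {
  if (length(starts) == 0) {
    warning("no reads: returning an empty dyad map")
    return(data.frame(dyad = integer(), score = numeric()))
  }
  dyad_pos <- starts + 73L
  dyad_pos <- dyad_pos[dyad_pos >= 0 & dyad_pos < genome_length]
  cov <- tabulate(dyad_pos + 1L, nbins = genome_length)
  sm <- gaussian_smooth(cov, sigma)
  floor_val <- quantile(sm[sm > 0], score_floor_quantile, names = FALSE)
  hw <- ceiling(4 * sigma)
  k <- stats::dnorm(-hw:hw, sd = sigma)
  k <- k / sum(k)
  dens <- length(dyad_pos) / genome_length
  min_prom <- noise_sd * sqrt(dens * sum(k^2))
  # local maxima (plateau-safe: strictly greater than left, >= right)
  n <- length(sm)
  left <- c(-Inf, sm[-n])
  right <- c(sm[-1], -Inf)
  cand <- which(sm > left & sm >= right & sm > floor_val)
  if (length(cand) > 0) {
    prom <- vapply(cand, function(p) {
      lo <- max(1L, p - exclusion)
      hi <- min(n, p + exclusion)
      sm[p] - max(min(sm[lo:p]), min(sm[p:hi]))
    }, numeric(1))
    cand <- cand[prom >= min_prom]
  }
  if (length(cand) == 0)
    return(data.frame(dyad = integer(), score = numeric()))
  o <- cand[order(sm[cand], decreasing = TRUE)]
  taken <- logical(n)
  picked <- integer()
  for (p in o) {
    if (!taken[p]) {
      picked <- c(picked, p)
      lo <- max(1L, p - exclusion + 1L)
      hi <- min(n, p + exclusion - 1L)
      taken[lo:hi] <- TRUE
    }
  }
  picked <- sort(picked)
  data.frame(dyad = picked - 1L, score = sm[picked])
}

#' Classify positioning reproducibility across replicates
#'
#' Pooled replicate dyads are grouped by splitting at gaps larger than
#' `window`.  A group is a well-positioned nucleosome iff each replicate
#' contributes exactly one dyad and the dyads' SD is at most `sigma_max`;
#' otherwise its occupied footprint is emitted as a fuzzy region.
#'
#' @param replicate_maps list of data.frames from [call_dyads()], one per
#'   replicate (>= 2)
#' @param window consensus window (bp)
#' @param sigma_max maximum replicate-dyad SD for a well-positioned call
#' @param strain strain label attached to the map
#' @return a `nuc_map`: data.frame(id, class, dyad, start, end, score,
#'   n_rep) with class "well" or "fuzzy"; fuzzy rows have NA dyad
#' @export
classify_reproducibility <- function(replicate_maps, window = 75L,
                                     sigma_max = 20, strain = "strain") {
  fail_if(length(replicate_maps) < 2, "need >= 2 replicates")
  pooled <- do.call(rbind, lapply(seq_along(replicate_maps), function(r) {
    m <- replicate_maps[[r]]
    if (nrow(m) == 0) return(NULL)
    data.frame(rep = r, dyad = m$dyad, score = m$score)
  }))
  if (is.null(pooled) || nrow(pooled) == 0)
    return(.empty_nuc_map(strain))
  pooled <- pooled[order(pooled$dyad), ]
  grp <- cumsum(c(1L, as.integer(diff(pooled$dyad) > window)))
  n_rep <- length(replicate_maps)
  rows <- lapply(split(pooled, grp), function(g) {
    reps_ok <- length(g$rep) == n_rep && all(sort(g$rep) == seq_len(n_rep))
    sd_ok <- if (nrow(g) > 1) sd(g$dyad) <= sigma_max else TRUE
    if (reps_ok && sd_ok) {
      d <- as.integer(round(mean(g$dyad)))
      data.frame(class = "well", dyad = d, start = d - 73L, end = d + 74L,
                 score = mean(g$score), n_rep = n_rep,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class = "fuzzy", dyad = NA_integer_,
                 start = min(g$dyad) - 73L, end = max(g$dyad) + 74L,
                 score = mean(g$score), n_rep = length(unique(g$rep)),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), ]
  out$id <- sprintf("%s_nuc%05d", strain, seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out[, c("id", "class", "dyad", "start", "end", "score",
                    "n_rep")],
            class = c("nuc_map", "data.frame"), strain = strain)
}

.empty_nuc_map <- function(strain) {
  structure(data.frame(id = character(), class = character(),
                       dyad = integer(), start = integer(),
                       end = integer(), score = numeric(),
                       n_rep = integer()),
            class = c("nuc_map", "data.frame"), strain = strain)
}

#' Build a per-strain nucleosome map from MNase replicates
#'
#' Convenience wrapper: calls dyads in each MNase replicate of a strain
#' and classifies reproducibility.
#' @param rs a `read_set`
#' @param strain strain name
#' @param genome_length contig length for that strain
#' @param ... passed to [call_dyads()] and [classify_reproducibility()]
#' @inheritParams classify_reproducibility
#' @return a `nuc_map`
#' @export
nucleosome_map <- function(rs, strain, genome_length, window = 75L,
                           sigma_max = 20, ...) {
  sel <- rs$meta$strain == strain & rs$meta$assay == "MNase"
  fail_if(sum(sel) < 2, "strain %s has fewer than 2 MNase replicates",
          strain)
  maps <- lapply(rs$meta$sample_id[sel], function(id)
    call_dyads(rs$reads[[id]], genome_length, ...))
  classify_reproducibility(maps, window = window, sigma_max = sigma_max,
                           strain = strain)
}

#' Match nucleosome maps of two strains
#'
#' Strain-1 dyads are translated into strain-2 coordinates; well-positioned
#' nucleosomes are paired by mutual nearest neighbour within
#' `match_window`.  All unpaired calls (wells without a partner, and all
#' fuzzy regions) are merged into UNRs, so that every call belongs to
#' exactly one pair or one UNR.
#'
#' @param map1,map2 `nuc_map` objects from two different strains; map1
#'   must be on the ref strain of `cur_set`
#' @param cur_set the pairwise `cur_set`
#' @param match_window maximum |shift| accepted for a pair (bp)
#' @return list(pairs, unrs, map1, map2); `pairs` has columns id1, id2,
#'   dyad1, dyad2, dyad1_tr (translated), shift; `unrs` has per-strain
#'   intervals (strain-1 coordinates plus member ids)
#' @export
match_maps <- function(map1, map2, cur_set, match_window = 75L) {
  fail_if(identical(attr(map1, "strain"), attr(map2, "strain")),
          "maps come from the same strain")
  w1 <- map1[map1$class == "well", , drop = FALSE]
  w2 <- map2[map2$class == "well", , drop = FALSE]
  d1t <- translate(cur_set, w1$dyad, "ref2alt")
  ok1 <- !is.na(d1t)
  # nearest strain-2 well for each translated strain-1 well and vice versa
  pairs <- data.frame(id1 = character(), id2 = character(),
                      dyad1 = integer(), dyad2 = integer(),
                      dyad1_tr = integer(), shift = integer())
  if (nrow(w2) > 0 && any(ok1)) {
    idx1 <- which(ok1)
    nn12 <- .nearest_index(d1t[idx1], w2$dyad)
    nn21 <- .nearest_index(w2$dyad, d1t[idx1])
    mutual <- which(nn21[nn12] == seq_along(idx1))
    if (length(mutual) > 0) {
      i1 <- idx1[mutual]
      i2 <- nn12[mutual]
      shift <- w2$dyad[i2] - d1t[i1]
      keep <- abs(shift) <= match_window
      pairs <- data.frame(id1 = w1$id[i1[keep]], id2 = w2$id[i2[keep]],
                          dyad1 = w1$dyad[i1[keep]],
                          dyad2 = w2$dyad[i2[keep]],
                          dyad1_tr = d1t[i1[keep]],
                          shift = as.integer(shift[keep]),
                          stringsAsFactors = FALSE)
    }
  }
  # unpaired territory -> UNRs, merged in strain-1 coordinates
  un1 <- map1[!(map1$id %in% pairs$id1), , drop = FALSE]
  un2 <- map2[!(map2$id %in% pairs$id2), , drop = FALSE]
  iv <- list()
  if (nrow(un1) > 0)
    iv[[1]] <- data.frame(start = un1$start, end = un1$end, id = un1$id,
                          strain = attr(map1, "strain"))
  if (nrow(un2) > 0) {
    s2 <- translate(cur_set, un2$start, "alt2ref")
    e2 <- translate(cur_set, un2$end - 1L, "alt2ref") + 1L
    keep <- !is.na(s2) & !is.na(e2)
    if (any(keep))
      iv[[2]] <- data.frame(start = s2[keep], end = e2[keep],
                            id = un2$id[keep],
                            strain = attr(map2, "strain"))
  }
  unrs <- .merge_unrs(do.call(rbind, iv))
  list(pairs = pairs, unrs = unrs, map1 = map1, map2 = map2,
       cur_set = cur_set)
}

# index of nearest element of `ref` for each element of `x`
.nearest_index <- function(x, ref) {
  o <- order(ref)
  rs <- ref[o]
  k <- findInterval(x, rs)
  lo <- pmax(k, 1L)
  hi <- pmin(k + 1L, length(rs))
  pick <- ifelse(abs(x - rs[lo]) <= abs(rs[hi] - x), lo, hi)
  o[pick]
}

.merge_unrs <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0)
    return(data.frame(unr_id = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      members = character()))
  iv <- iv[order(iv$start), ]
  grp <- cumsum(c(1L, as.integer(iv$start[-1] > cummax(iv$end[-nrow(iv)]))))
  rows <- lapply(split(iv, grp), function(g) {
    data.frame(start = min(g$start), end = max(g$end),
               n_members = nrow(g),
               members = paste(g$id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$unr_id <- sprintf("UNR%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("unr_id", "start", "end", "n_members", "members")]
}

#' Positional-divergence analysis of matched maps
#'
#' A matched pair is flagged "shifted" when |shift| exceeds
#' `shift_threshold`.  A strain-1 well-positioned nucleosome with no
#' partner joins the diverged subpopulation unless it lies almost
#' entirely (>= `overlap_threshold`) inside a UNR arising from strain-2
#' occupancy -- such cases are conserved occupancy, not positional
#' divergence -- and only if its nearest strain-2 well dyad is further
#' than `dist_threshold`.
#'
#' @param matched output of [match_maps()]
#' @param shift_threshold |shift| above which a pair is "shifted" (bp)
#' @param dist_threshold distance to the nearest strain-2 well above
#'   which an unmatched well diverges (bp)
#' @param overlap_threshold fractional UNR overlap at or above which
#'   occupancy is considered conserved
#' @return list(shifted, subpopulation, divergent_set); `shifted` is the
#'   pairs table with a `shifted` flag, `subpopulation` the diverged
#'   unmatched wells of strain 1
#' @export
divergence_analysis <- function(matched, shift_threshold = 10L,
                                dist_threshold = 40L,
                                overlap_threshold = 0.99) {
  pairs <- matched$pairs
  pairs$shifted <- abs(pairs$shift) > shift_threshold
  map1 <- matched$map1; map2 <- matched$map2
  un1 <- map1[map1$class == "well" & !(map1$id %in% pairs$id1), ,
              drop = FALSE]
  sub <- data.frame(id = character(), dist = numeric(),
                    unr_overlap = numeric(), diverged = logical())
  if (nrow(un1) > 0) {
    d1t <- translate(matched$cur_set, un1$dyad, "ref2alt")
    w2 <- map2[map2$class == "well", , drop = FALSE]
    dist <- rep(Inf, nrow(un1))
    if (nrow(w2) > 0 && any(!is.na(d1t))) {
      ok <- !is.na(d1t)
      nn <- .nearest_index(d1t[ok], w2$dyad)
      dist[ok] <- abs(d1t[ok] - w2$dyad[nn])
    }
    # fractional overlap with UNRs that contain strain-2 occupancy
    unrs <- matched$unrs
    s2 <- attr(map2, "strain")
    u2 <- unrs[grepl(s2, unrs$members), , drop = FALSE]
    ov <- numeric(nrow(un1))
    if (nrow(u2) > 0) {
      for (i in seq_len(nrow(un1))) {
        inter <- pmin(u2$end, un1$end[i]) - pmax(u2$start, un1$start[i])
        ov[i] <- max(c(0, inter)) / (un1$end[i] - un1$start[i])
      }
    }
    conserved <- ov >= overlap_threshold
    sub <- data.frame(id = un1$id, dist = dist, unr_overlap = ov,
                      diverged = !conserved & dist > dist_threshold,
                      stringsAsFactors = FALSE)
  }
  list(shifted = pairs,
       subpopulation = sub,
       divergent_set = c(pairs$id1[pairs$shifted],
                         sub$id[sub$diverged]))
}

#' Annotate nucleosome calls relative to genes and TF binding sites
#'
#' The +1 nucleosome of a gene is the first well-positioned dyad within
#' `promoter_window` downstream of its TSS (strand-aware); the -1
#' nucleosome the first upstream.  A nucleosome serving as -1 of one gene
#' and +1 of another (divergent promoters) keeps both annotations.
#'
#' @param map a `nuc_map`
#' @param genes gene table (see [generate_genes()])
#' @param tf_sites optional data.frame(start, end) of TF binding sites
#' @param cur_set optional `cur_set` for local polymorphism (+/-30 bp)
#' @param promoter_window search window around the TSS (bp)
#' @param tf_window maximum dyad-to-site distance called proximal (bp;
#'   strictly greater is not proximal)
#' @return data.frame(id, dyad, position_class, is_plus1, is_minus1,
#'   genic_percentile, tf_proximal, local_poly); the full gene-by-role
#'   table (so divergent-promoter nucleosomes keep both roles) is in
#'   attribute "roles".  `position_class` resolves ties as +1 > -1.
#' @export
annotate_calls <- function(map, genes, tf_sites = NULL, cur_set = NULL,
                           promoter_window = 300L, tf_window = 30L) {
  w <- map[map$class == "well", , drop = FALSE]
  is_p1 <- logical(nrow(w))
  is_m1 <- logical(nrow(w))
  perc <- rep(NA_real_, nrow(w))
  roles <- list()
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      down <- which(w$dyad >= tss & w$dyad <= tss + promoter_window)
      up <- which(w$dyad < tss & w$dyad >= tss - promoter_window)
      p1 <- if (length(down)) down[which.min(w$dyad[down])] else NA
      m1 <- if (length(up)) up[which.max(w$dyad[up])] else NA
    } else {
      down <- which(w$dyad <= tss & w$dyad >= tss - promoter_window)
      up <- which(w$dyad > tss & w$dyad <= tss + promoter_window)
      p1 <- if (length(down)) down[which.max(w$dyad[down])] else NA
      m1 <- if (length(up)) up[which.min(w$dyad[up])] else NA
    }
    if (!is.na(p1)) {
      is_p1[p1] <- TRUE
      roles[[length(roles) + 1L]] <-
        data.frame(gene_id = genes$gene_id[i], role = "+1", id = w$id[p1])
    }
    if (!is.na(m1)) {
      is_m1[m1] <- TRUE
      roles[[length(roles) + 1L]] <-
        data.frame(gene_id = genes$gene_id[i], role = "-1", id = w$id[m1])
    }
    genic <- w$dyad >= genes$start[i] & w$dyad < genes$end[i]
    x <- (w$dyad[genic] - genes$start[i]) /
      (genes$end[i] - genes$start[i])
    if (genes$strand[i] == "-") x <- 1 - x
    perc[genic] <- x
  }
  cls <- ifelse(is_p1, "+1", ifelse(is_m1, "-1", "other"))
  tf_prox <- rep(NA, nrow(w))
  if (!is.null(tf_sites) && nrow(tf_sites) > 0) {
    tf_prox <- vapply(w$dyad, function(d) {
      dd <- pmax(tf_sites$start - d, d - (tf_sites$end - 1L), 0L)
      any(dd <= tf_window)
    }, logical(1))
  }
  lp <- if (!is.null(cur_set))
    local_polymorphism(cur_set, w$dyad, halfwidth = 30L) else
      rep(NA_real_, nrow(w))
  out <- data.frame(id = w$id, dyad = w$dyad, position_class = cls,
                    is_plus1 = is_p1, is_minus1 = is_m1,
                    genic_percentile = perc, tf_proximal = tf_prox,
                    local_poly = lp, stringsAsFactors = FALSE)
  attr(out, "roles") <- if (length(roles)) do.call(rbind, roles) else
    data.frame(gene_id = character(), role = character(), id = character())
  out
}

#' Write a nucleosome map as BED (name = id:class)
#' @param map a `nuc_map`
#' @param path output path
#' @param contig contig name
#' @export
write_nuc_map_bed <- function(map, path, contig = "chrI") {
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = map$start + 1L, end = map$end))
  gr$name <- paste(map$id, map$class, sep = ":")
  gr$score <- round(ifelse(is.finite(map$score), map$score, 0), 3)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
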