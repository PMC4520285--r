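# Synthetic-data generator.
#
# Produces strain genomes diverged from a common ancestor, nucleosome
# landscapes with planted positional divergence, NB-distributed MNase /
# ChIP read counts with planted per-nucleosome mark differences (SNEPs),
# gene annotations and a segregant cross with a planted QTL.  Every
# departure from the null is recorded in a ground-truth object so that
# downstream detections can be scored exactly.

#' Generate strain genomes from a common ancestor
#'
#' Strain 1 is the ancestral sequence; each further strain receives an
#' independent set of SNPs and short indels relative to it.  The exact
#' variant list (per strain, ancestor coordinates) and an
#' alignment-block table are recorded in the returned truth, so the
#' alignment module can be exercised without running an aligner.
#'
#' @param seed integer seed; identical seeds give identical output
#' @param length genome length in bp (>= 10000)
#' @param n_strains number of strains (>= 2)
#' @param snp_rate per-bp substitution probability (default 0.005,
#'   the typical divergence between unrelated wild yeast isolates)
#' @param indel_rate per-bp indel initiation probability
#' @param indel_size_max largest indel size in bp
#' @param indel_exclude optional data.frame(start, end) of 0-based
#'   half-open intervals where indels are suppressed (e.g. gene bodies,
#'   so that gene binning stays well-defined)
#' @param contig contig name
#' @return list with `sequences` (named character vector of genome
#'   sequences), `alignments` (list of `alignment_blocks`, one per
#'   non-ancestral strain vs strain 1) and `truth` (variant tables)
#' @export
generate_genomes <- function(seed, length, n_strains = 2L,
                             snp_rate = 0.005, indel_rate = 0,
                             indel_size_max = 10L, indel_exclude = NULL,
                             contig = "chrI") {
  fail_if(length < 10000, "genome length must be >= 10000 bp")
  fail_if(snp_rate < 0 || snp_rate >= 1 || indel_rate < 0 || indel_rate >= 1,
          "rates must be in [0, 1)")
  fail_if(n_strains < 2, "need at least two strains")
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, 0L), {
    anc <- sample(bases, length, replace = TRUE)
    strains <- paste0("strain", seq_len(n_strains))
    seqs <- setNames(vector("list", n_strains), strains)
    seqs[[1]] <- anc
    truth <- list()
    alns <- list()
    for (s in 2:n_strains) {
      n_snp <- rbinom(1L, length, snp_rate)
      snp_pos <- sort(sample.int(length, n_snp) - 1L)
      n_ind <- rbinom(1L, length, indel_rate)
      ind_pos <- sort(sample.int(length, min(n_ind, length)) - 1L)
      ind_size <- if (n_ind > 0)
        sample.int(indel_size_max, n_ind, replace = TRUE) else integer()
      ind_type <- if (n_ind > 0)
        sample(c("ins", "del"), n_ind, replace = TRUE) else character()
      # keep indels clear of excluded intervals, genome edges and of each
      # other (a 2*size guard band keeps the alignment unambiguous)
      if (n_ind > 0) {
        keep <- ind_pos > 100 & ind_pos + ind_size < length - 100
        if (!is.null(indel_exclude) && nrow(indel_exclude) > 0) {
          for (i in seq_len(nrow(indel_exclude))) {
            keep <- keep & !(ind_pos + ind_size > indel_exclude$start[i] &
                               ind_pos < indel_exclude$end[i])
          }
        }
        ind_pos <- ind_pos[keep]; ind_size <- ind_size[keep]
        ind_type <- ind_type[keep]
        if (length(ind_pos) > 1) {
          gap_ok <- c(TRUE, diff(ind_pos) >
                        (ind_size[-length(ind_size)] + 20L))
          ind_pos <- ind_pos[gap_ok]; ind_size <- ind_size[gap_ok]
          ind_type <- ind_type[gap_ok]
        }
      } else {
        ind_pos <- integer(); ind_size <- integer(); ind_type <- character()
      }
      # SNPs falling inside deleted segments are invisible: drop them
      if (length(ind_pos) > 0 && length(snp_pos) > 0) {
        del <- ind_type == "del"
        if (any(del)) {
          bad <- rep(FALSE, length(snp_pos))
          ds <- ind_pos[del]; de <- ind_pos[del] + ind_size[del]
          j <- findInterval(snp_pos, ds)
          bad <- j > 0 & snp_pos < de[pmax(j, 1)]
          snp_pos <- snp_pos[!bad]
        }
        snp_pos <- setdiff(snp_pos, ind_pos)
      }
      variants <- rbind(
        if (length(snp_pos))
          data.frame(ref_contig = contig, ref_pos = snp_pos, type = "snp",
                     size = 1L, stringsAsFactors = FALSE),
        if (length(ind_pos))
          data.frame(ref_contig = contig, ref_pos = ind_pos,
                     type = ind_type, size = ind_size,
                     stringsAsFactors = FALSE))
      if (is.null(variants))
        variants <- data.frame(ref_contig = character(),
                               ref_pos = integer(), type = character(),
                               size = integer())
      variants <- variants[order(variants$ref_pos), , drop = FALSE]
      rownames(variants) <- NULL
      # apply variants to the ancestor
      derived <- anc
      is_snp <- variants$type == "snp"
      if (any(is_snp)) {
        p <- variants$ref_pos[is_snp] + 1L
        old <- derived[p]
        new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "")
        derived[p] <- new
      }
      if (any(!is_snp)) {
        pieces <- list()
        cursor <- 1L
        idx <- which(!is_snp)
        for (i in idx) {
          p <- variants$ref_pos[i] + 1L
          sz <- variants$size[i]
          pieces[[base::length(pieces) + 1L]] <-
            derived[seq.int(cursor, p - 1L)]
          if (variants$type[i] == "ins") {
            pieces[[base::length(pieces) + 1L]] <-
              sample(bases, sz, replace = TRUE)
            cursor <- p
          } else {
            cursor <- p + sz
          }
        }
        pieces[[base::length(pieces) + 1L]] <-
          derived[seq.int(cursor, base::length(derived))]
        derived <- unlist(pieces)
      }
      seqs[[s]] <- derived
      alt_len <- base::length(derived)
      blocks <- data.frame(ref_contig = contig, ref_start = 0L,
                           ref_end = length, alt_contig = contig,
                           alt_start = 0L, alt_end = alt_len,
                           stringsAsFactors = FALSE)
      alns[[strains[s]]] <- alignment_blocks(
        blocks, variants, strains = c(strains[1], strains[s]))
      truth[[strains[s]]] <- variants
    }
    list(sequences = lapply(seqs, paste0, collapse = ""),
         alignments = alns,
         truth = list(variants = truth, seed = seed, contig = contig,
                      length = length),
         contig = contig)
  })
}

#' Write genomes to FASTA
#' @param genomes output of [generate_genomes()]
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (s in names(genomes$sequences)) {
    dss <- Biostrings::DNAStringSet(genomes$sequences[[s]])
    names(dss) <- genomes$contig
    p <- file.path(dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(dss, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Generate a nucleosome landscape with planted positional divergence
#'
#' Strain-1 dyads are laid down at roughly regular spacing; strain-2 dyads
#' are the strain-1 dyads lifted through the pairwise coordinate map,
#' except at planted shifts, evictions and fuzzy sites, all of which are
#' recorded in the truth table.
#'
#' @param seed integer seed
#' @param genomes output of [generate_genomes()] (two strains are used)
#' @param spacing_mean mean dyad-to-dyad distance in bp (> 147; default
#'   165, the canonical yeast nucleosome repeat length)
#' @param fuzzy_fraction fraction of nucleosomes with irreproducible
#'   positioning between replicates
#' @param n_shifted number of planted positional shifts in strain 2
#' @param shift_bp planted shift magnitude(s) in bp (recycled; random
#'   signs), each at most `shift_max`
#' @param shift_max upper bound on planted shifts (bp)
#' @param n_evicted number of nucleosomes evicted in strain 2
#' @return list with `nucs` (truth table: nuc_id, dyad1, dyad2, class,
#'   planted_shift, evicted), `contig`, `lengths`, and the lift map
#' @export
generate_landscape <- function(seed, genomes, spacing_mean = 165,
                               fuzzy_fraction = 0, n_shifted = 0L,
                               shift_bp = 30L, shift_max = 75L,
                               n_evicted = 0L) {
  fail_if(spacing_mean <= 147, "spacing_mean must exceed 147 bp")
  fail_if(any(abs(shift_bp) > shift_max),
          "planted shifts must be <= shift_max (%d bp)", shift_max)
  strains <- names(genomes$sequences)
  fail_if(length(strains) < 2, "need two strains")
  len1 <- nchar(genomes$sequences[[1]])
  # lift map with no thresholds so every position translates
  lift <- build_curs(genomes$alignments[[strains[2]]],
                     min_length = 1L, max_indel = .Machine$integer.max)
  with_seed(derive_seed(seed, 1L), {
    spacings <- pmax(150, round(rnorm(ceiling(len1 / (spacing_mean - 10)),
                                      spacing_mean, 8)))
    dyads1 <- 100L + cumsum(as.integer(spacings))
    dyads1 <- dyads1[dyads1 < len1 - 200L]
    n <- length(dyads1)
    fail_if(n_shifted + n_evicted > n,
            "n_shifted + n_evicted exceeds available nucleosomes (%d)", n)
    dyads2 <- translate(lift, dyads1, "ref2alt")
    cls <- rep("well", n)
    n_fuzzy <- rbinom(1L, n, fuzzy_fraction)
    special <- sample.int(n, n_shifted + n_evicted + n_fuzzy)
    sh_idx <- head(special, n_shifted)
    ev_idx <- special[seq_len(n_evicted) + n_shifted]
    fz_idx <- tail(special, n_fuzzy)
    cls[fz_idx] <- "fuzzy"
    planted_shift <- integer(n)
    if (n_shifted > 0) {
      mag <- rep_len(as.integer(shift_bp), n_shifted)
      sgn <- sample(c(-1L, 1L), n_shifted, replace = TRUE)
      planted_shift[sh_idx] <- sgn * mag
      dyads2[sh_idx] <- dyads2[sh_idx] + planted_shift[sh_idx]
    }
    evicted <- logical(n)
    evicted[ev_idx] <- TRUE
    dyads2[ev_idx] <- NA_integer_
    nucs <- data.frame(nuc_id = seq_len(n), dyad1 = dyads1, dyad2 = dyads2,
                       class = cls, planted_shift = planted_shift,
                       evicted = evicted, stringsAsFactors = FALSE)
    list(nucs = nucs, contig = genomes$contig,
         strains = strains[1:2],
         lengths = setNames(c(len1, nchar(genomes$sequences[[2]])),
                            strains[1:2]),
         lift = lift, seed = seed)
  })
}

#' Generate gene annotations tiling the genome
#'
#' Genes alternate strands along strain-1 coordinates with fixed
#' intergenic gaps, so that a known fraction of nucleosomes is genic.
#' @param seed integer seed
#' @param genome_length strain-1 genome length (bp)
#' @param n_genes number of genes
#' @param length_range gene length range (bp), sampled uniformly
#' @param margin bp kept gene-free at each genome end
#' @return data.frame(gene_id, start, end, strand, tss, tes) in 0-based
#'   half-open strain-1 coordinates
#' @export
generate_genes <- function(seed, genome_length, n_genes = 20L,
                           length_range = c(800L, 2000L), margin = 2000L) {
  with_seed(derive_seed(seed, 2L), {
    avail <- genome_length - 2L * margin
    slot <- floor(avail / n_genes)
    fail_if(slot < max(length_range) + 200,
            "genome too short for %d genes of up to %d bp",
            n_genes, max(length_range))
    lens <- sample(seq(length_range[1], length_range[2]), n_genes,
                   replace = TRUE)
    starts <- margin + (seq_len(n_genes) - 1L) * slot +
      sample.int(100L, n_genes, replace = TRUE)
    strand <- rep(c("+", "-"), length.out = n_genes)
    ends <- starts + lens
    data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
               start = as.integer(starts), end = as.integer(ends),
               strand = strand,
               tss = as.integer(ifelse(strand == "+", starts, ends - 1L)),
               tes = as.integer(ifelse(strand == "+", ends - 1L, starts)),
               stringsAsFactors = FALSE)
  })
}

#' Write gene annotations as GFF3
#' @param genes output of [generate_genes()]
#' @param path output path
#' @param contig contig name
#' @export
write_genes_gff <- function(genes, path, contig = "chrI") {
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read gene annotations from GFF3
#' @param path GFF3 path
#' @return data.frame as produced by [generate_genes()]
#' @export
read_genes_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  start <- as.integer(GenomicRanges::start(gr) - 1L)
  end <- as.integer(GenomicRanges::end(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%03d", seq_along(gr))
  data.frame(gene_id = id, start = start, end = end, strand = strand,
             tss = as.integer(ifelse(strand == "+", start, end - 1L)),
             tes = as.integer(ifelse(strand == "+", end - 1L, start)),
             stringsAsFactors = FALSE)
}

# default gene-body enrichment profiles: piecewise-linear over TSS->TES
# percentiles (0..1).  Acetylation marks and H3K4me3 are 5'-skewed,
# H3K4me1 is 3'-skewed, mirroring typical yeast genic distributions.
default_enrichment_profiles <- function(marks) {
  shapes <- list(
    H3K4me3 = function(x) 2.5 - 2 * x,
    H3K9ac  = function(x) 2.2 - 1.6 * x,
    H3K14ac = function(x) 2.2 - 1.6 * x,
    H4K12ac = function(x) 2.0 - 1.2 * x,
    H3K4me1 = function(x) 0.5 + 2 * x)
  out <- lapply(marks, function(m) {
    if (m %in% names(shapes)) shapes[[m]] else function(x) rep(1, length(x))
  })
  setNames(out, marks)
}

#' Simulate MNase and ChIP read starts over a landscape
#'
#' Counts per nucleosome are negative-binomial via a Gamma-Poisson
#' mixture; read starts are placed at the nucleosome 5' edge
#' (dyad - 73) plus Normal(0, sigma = 10) jitter, forward strand only.
#' Fuzzy nucleosomes receive an extra per-replicate dyad displacement.
#' A planted SNEP of log2 fold change f multiplies the strain-2 ChIP
#' weight by 2^f; MNase counts are unaffected.
#'
#' @param seed integer seed
#' @param landscape output of [generate_landscape()]
#' @param marks character vector of ChIP marks (may be empty for
#'   MNase-only simulations)
#' @param n_reads expected number of reads per sample before the
#'   per-sample depth multiplier (drawn log-uniform in [0.5, 2])
#' @param planted_sneps data.frame(nuc_id, mark, log2fc) or NULL
#' @param dispersion NB overdispersion (0 = Poisson)
#' @param n_replicates replicates per strain x assay (>= 2)
#' @param genes optional gene table shaping per-mark enrichment along
#'   gene bodies (default profiles); intergenic nucleosomes get weight 1
#' @param enrichment_profiles named list of functions mark ->
#'   (percentile in [0,1]) -> weight; default [default_enrichment_profiles()]
#' @param jitter_sd read-start jitter sd (bp)
#' @param fuzzy_sd extra per-replicate dyad sd for fuzzy nucleosomes (bp)
#' @param occupancy_cv coefficient of variation of per-nucleosome
#'   occupancy (Gamma distributed, mean 1)
#' @return a `read_set`: list(meta, reads) where `meta` is a sample sheet
#'   (sample_id, strain, assay, mark, replicate) and `reads` a named list
#'   of 0-based forward start vectors in each sample's own coordinates
#' @export
simulate_reads <- function(seed, landscape, marks = character(),
                           n_reads = 2e5, planted_sneps = NULL,
                           dispersion = 0.05, n_replicates = 3L,
                           genes = NULL, enrichment_profiles = NULL,
                           jitter_sd = 10, fuzzy_sd = 25,
                           occupancy_cv = 0.4) {
  nucs <- landscape$nucs
  fail_if(nrow(nucs) == 0, "empty landscape")
  fail_if(n_replicates < 2, "need >= 2 replicates per strain x assay")
  fail_if(dispersion < 0, "dispersion must be >= 0")
  if (!is.null(planted_sneps) && nrow(planted_sneps) > 0) {
    fail_if(!all(planted_sneps$nuc_id %in% nucs$nuc_id),
            "planted SNEPs reference unknown nucleosomes")
    fail_if(!all(planted_sneps$mark %in% marks),
            "planted SNEPs reference unknown marks")
  }
  if (is.null(enrichment_profiles))
    enrichment_profiles <- default_enrichment_profiles(marks)
  n <- nrow(nucs)
  strains <- landscape$strains
  # genic percentile per nucleosome (strain-1 coordinates), NA intergenic
  perc <- rep(NA_real_, n)
  if (!is.null(genes) && nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      sel <- nucs$dyad1 >= genes$start[i] & nucs$dyad1 < genes$end[i]
      x <- (nucs$dyad1[sel] - genes$start[i]) /
        (genes$end[i] - genes$start[i])
      if (genes$strand[i] == "-") x <- 1 - x
      perc[sel] <- x
    }
  }
  with_seed(derive_seed(seed, 3L), {
    occ <- rgamma(n, shape = 1 / occupancy_cv^2, scale = occupancy_cv^2)
    assays <- c("MNase", marks)
    meta <- expand.grid(replicate = seq_len(n_replicates),
                        strain = strains, assay = assays,
                        stringsAsFactors = FALSE)
    meta$mark <- ifelse(meta$assay == "MNase", NA_character_, meta$assay)
    meta$assay <- ifelse(meta$assay == "MNase", "MNase", "ChIP")
    meta$sample_id <- sprintf("%s_%s_rep%d", meta$strain,
                              ifelse(is.na(meta$mark), "MNase", meta$mark),
                              meta$replicate)
    meta$depth_multiplier <- exp(runif(nrow(meta), log(0.5), log(2)))
    meta <- meta[, c("sample_id", "strain", "assay", "mark", "replicate",
                     "depth_multiplier")]
    reads <- setNames(vector("list", nrow(meta)), meta$sample_id)
    for (j in seq_len(nrow(meta))) {
      st <- meta$strain[j]
      dyads <- if (st == strains[1]) nucs$dyad1 else nucs$dyad2
      present <- !is.na(dyads)
      w <- occ
      if (meta$assay[j] == "ChIP") {
        mk <- meta$mark[j]
        prof <- enrichment_profiles[[mk]]
        e <- rep(1, n)
        gi <- !is.na(perc)
        if (any(gi)) e[gi] <- pmax(prof(perc[gi]), 0.05)
        w <- w * e
        if (st == strains[2] && !is.null(planted_sneps) &&
              nrow(planted_sneps) > 0) {
          ps <- planted_sneps[planted_sneps$mark == mk, , drop = FALSE]
          if (nrow(ps) > 0) {
            idx <- match(ps$nuc_id, nucs$nuc_id)
            w[idx] <- w[idx] * 2^ps$log2fc
          }
        }
      }
      w[!present] <- 0
      mu <- n_reads * meta$depth_multiplier[j] * w / sum(w)
      if (dispersion > 0) {
        lam <- rgamma(n, shape = 1 / dispersion, scale = mu * dispersion)
      } else lam <- mu
      cnt <- rpois(n, lam)
      dy <- dyads
      fz <- nucs$class == "fuzzy"
      if (any(fz))
        dy[fz] <- dy[fz] + as.integer(round(rnorm(sum(fz), 0, fuzzy_sd)))
      starts <- rep(dy, cnt) - 73L +
        as.integer(round(rnorm(sum(cnt), 0, jitter_sd)))
      L <- landscape$lengths[[st]]
      starts <- pmin(pmax(starts, 0L), L - 51L)
      reads[[j]] <- sort(starts)
    }
    structure(list(meta = meta, reads = reads, contig = landscape$contig,
                   strains = strains, seed = seed),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d samples (%s), %.2fM reads total\n",
              nrow(x$meta), paste(x$strains, collapse = " vs "),
              sum(lengths(x$reads)) / 1e6))
  invisible(x)
}

#' Write a read set as one BED6 file per sample
#' @param rs a `read_set`
#' @param dir output directory
#' @return invisibly, a sample sheet data.frame with a `path` column
#' @export
write_reads_bed <- function(rs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- rs$meta
  meta$path <- file.path(dir, paste0(meta$sample_id, ".bed"))
  for (j in seq_len(nrow(meta)))
    write_starts_bed(rs$reads[[meta$sample_id[j]]], meta$path[j],
                     contig = rs$contig, name = meta$sample_id[j])
  invisible(meta)
}

#' Read a read set from a sample sheet of BED files
#' @param sheet data.frame with columns sample_id, strain, assay, mark,
#'   replicate, path
#' @param contig contig name
#' @return a `read_set`
#' @export
read_reads_bed <- function(sheet, contig = "chrI") {
  reads <- setNames(lapply(sheet$path, read_starts_bed), sheet$sample_id)
  structure(list(meta = sheet[, setdiff(names(sheet), "path")],
                 reads = reads, contig = contig,
                 strains = unique(sheet$strain)),
            class = "read_set")
}

#' Simulate a nucleosome-level count table directly
#'
#' Bypasses read placement and draws per-unit NB counts for a two-strain
#' design (MNase + one ChIP mark, `n_rep` replicates each), the count
#' model that the SNEP test assumes: count ~ NB(mean = depth x occupancy
#' [x 2^log2fc for strain-2 ChIP at planted units], dispersion).  Planted
#' occupancy differences multiply both assays of strain 2 (the pure
#' occupancy scenario).  Per-unit occupancy is Gamma(mean 1).
#'
#' @param seed integer seed
#' @param n_units number of units
#' @param depth expected count per unit at occupancy 1
#' @param dispersion NB overdispersion
#' @param n_rep replicates per strain x assay
#' @param snep_units indices of units with planted SNEPs
#' @param log2fc planted log2 fold changes (recycled over `snep_units`;
#'   signs kept as given)
#' @param occupancy_ratio optional per-unit strain-2/strain-1 occupancy
#'   ratio (length 1 or n_units)
#' @param occupancy_cv coefficient of variation of per-unit occupancy
#' @return list(counts, meta, snep_units, log2fc)
#' @export
simulate_unit_counts <- function(seed, n_units, depth = 200,
                                 dispersion = 0.05, n_rep = 3L,
                                 snep_units = integer(), log2fc = 2,
                                 occupancy_ratio = 1,
                                 occupancy_cv = 0.4) {
  fail_if(dispersion < 0, "dispersion must be >= 0")
  with_seed(derive_seed(seed, 5L), {
    meta <- expand.grid(replicate = seq_len(n_rep),
                        strain = c("strain1", "strain2"),
                        assay = c("MNase", "ChIP"),
                        stringsAsFactors = FALSE)
    meta$mark <- ifelse(meta$assay == "ChIP", "mark", NA_character_)
    meta$sample_id <- sprintf("%s_%s_rep%d", meta$strain, meta$assay,
                              meta$replicate)
    occ <- rgamma(n_units, shape = 1 / occupancy_cv^2,
                  scale = occupancy_cv^2)
    fc <- rep(1, n_units)
    if (length(snep_units) > 0)
      fc[snep_units] <- 2^rep_len(log2fc, length(snep_units))
    oratio <- rep_len(occupancy_ratio, n_units)
    counts <- matrix(0L, n_units, nrow(meta),
                     dimnames = list(NULL, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- depth * occ
      if (meta$strain[j] == "strain2") {
        mu <- mu * oratio
        if (meta$assay[j] == "ChIP") mu <- mu * fc
      }
      if (dispersion > 0) {
        lam <- rgamma(n_units, shape = 1 / dispersion,
                      scale = mu * dispersion)
      } else lam <- mu
      counts[, j] <- rpois(n_units, lam)
    }
    list(counts = counts, meta = meta, snep_units = snep_units,
         log2fc = rep_len(log2fc, max(length(snep_units), 1)))
  })
}

#' Generate a segregant cross with a planted QTL
#'
#' Genotypes follow a Markov chain along markers (recombination fraction
#' `recomb` between adjacent markers).  Per-gene, per-nucleosome values
#' are standard normal; segregants carrying the planted allele get
#' `effect` (in SD units) added to nucleosomes of the second half of the
#' gene body, creating a 3'-vs-5' imbalance.
#'
#' @param seed integer seed
#' @param n_segregants number of segregants (>= 10)
#' @param n_markers number of genotyped markers
#' @param qtl_marker index of the causal marker (NA or 0 for no QTL)
#' @param effect standardized shift added at the planted allele
#' @param n_genes number of genes carrying the effect
#' @param n_nucs nucleosomes per gene (split into two halves)
#' @param recomb recombination fraction between adjacent markers
#' @return list(genotypes, values, halves, truth); `values` is a list of
#'   gene matrices (nucleosome x segregant), `halves` the per-gene
#'   half-assignment (1 = 5' half, 2 = 3' half)
#' @export
generate_cross <- function(seed, n_segregants = 60L, n_markers = 200L,
                           qtl_marker = NA, effect = 0, n_genes = 100L,
                           n_nucs = 6L, recomb = 0.1) {
  fail_if(n_segregants < 10, "need >= 10 segregants")
  has_qtl <- !is.na(qtl_marker) && qtl_marker >= 1
  fail_if(has_qtl && qtl_marker > n_markers,
          "qtl_marker out of range (1..%d)", n_markers)
  with_seed(derive_seed(seed, 4L), {
    g <- matrix(0L, n_segregants, n_markers)
    g[, 1] <- rbinom(n_segregants, 1L, 0.5)
    if (n_markers > 1) {
      for (m in 2:n_markers) {
        flip <- rbinom(n_segregants, 1L, recomb)
        g[, m] <- ifelse(flip == 1L, 1L - g[, m - 1L], g[, m - 1L])
      }
    }
    colnames(g) <- sprintf("m%03d", seq_len(n_markers))
    rownames(g) <- sprintf("seg%03d", seq_len(n_segregants))
    halves <- rep(c(1L, 2L), each = ceiling(n_nucs / 2))[seq_len(n_nucs)]
    carrier <- if (has_qtl) g[, qtl_marker] == 1L else rep(FALSE, n_segregants)
    values <- lapply(seq_len(n_genes), function(i) {
      v <- matrix(rnorm(n_nucs * n_segregants), n_nucs, n_segregants)
      if (has_qtl && effect != 0)
        v[halves == 2L, carrier] <- v[halves == 2L, carrier] + effect
      colnames(v) <- rownames(g)
      v
    })
    names(values) <- sprintf("gene%03d", seq_len(n_genes))
    list(genotypes = g, values = values, halves = halves,
         truth = list(qtl_marker = if (has_qtl) qtl_marker else NA,
                      effect = effect, seed = seed))
  })
}
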