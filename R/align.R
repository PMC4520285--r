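# Cross-strain coordinate maps.
#
# A pairwise whole-genome alignment is ingested as a table of colinear
# blocks plus a per-block variant list (SNPs and short indels), the product
# of an external aligner such as MUMmer.  From these, common uninterrupted
# regions (CURs) are derived: colinear segments longer than a minimum
# length in BOTH strains and containing no indel above a maximum size.
# All quantitative comparisons downstream are restricted to CURs.
#
# Variant conventions (all coordinates 0-based, half-open, on the "ref"
# strain unless stated):
#   snp: size 1 mismatch at ref_pos.
#   del: ref bases [ref_pos, ref_pos + size) absent from the alt strain.
#   ins: `size` alt bases present immediately before ref position ref_pos.

#' Construct an alignment-block set
#'
#' @param blocks data.frame with columns `ref_contig`, `ref_start`,
#'   `ref_end`, `alt_contig`, `alt_start`, `alt_end` (0-based half-open).
#' @param variants data.frame with columns `ref_contig`, `ref_pos`,
#'   `type` (one of "snp", "ins", "del") and `size`.
#' @param strains character(2), names of the ref and alt strain.
#' @return an object of class `alignment_blocks`
#' @export
alignment_blocks <- function(blocks, variants = NULL,
                             strains = c("ref", "alt")) {
  need <- c("ref_contig", "ref_start", "ref_end",
            "alt_contig", "alt_start", "alt_end")
  fail_if(!all(need %in% names(blocks)),
          "blocks must have columns: %s", paste(need, collapse = ", "))
  fail_if(any(blocks$ref_end <= blocks$ref_start) ||
            any(blocks$alt_end <= blocks$alt_start),
          "alignment blocks must have end > start")
  fail_if(any(blocks$ref_start < 0) || any(blocks$alt_start < 0),
          "alignment blocks must have non-negative coordinates")
  if (is.null(variants))
    variants <- data.frame(ref_contig = character(), ref_pos = integer(),
                           type = character(), size = integer())
  fail_if(!all(variants$type %in% c("snp", "ins", "del")),
          "variant types must be snp, ins or del")
  fail_if(any(variants$size < 1), "variant sizes must be >= 1")
  # reject overlapping blocks, reporting the offending pair
  for (side in c("ref", "alt")) {
    sc <- blocks[[paste0(side, "_contig")]]
    ss <- blocks[[paste0(side, "_start")]]
    se <- blocks[[paste0(side, "_end")]]
    o <- order(sc, ss)
    sc <- sc[o]; ss <- ss[o]; se <- se[o]
    if (length(ss) > 1) {
      bad <- which(sc[-1] == sc[-length(sc)] & ss[-1] < se[-length(se)])
      fail_if(length(bad) > 0,
              "overlapping %s blocks: rows %d and %d", side,
              o[bad[1]], o[bad[1] + 1L])
    }
  }
  variants <- variants[order(variants$ref_contig, variants$ref_pos,
                             variants$type), , drop = FALSE]
  structure(list(blocks = blocks, variants = variants, strains = strains),
            class = "alignment_blocks")
}

#' Read alignment blocks and variants from TSV files
#'
#' The block table must have columns ref_contig, ref_start, ref_end,
#' alt_contig, alt_start, alt_end; the variant table ref_contig, ref_pos,
#' type, size.  This is the package's documented MUMmer-style dialect;
#' the aligner itself is never invoked.
#' @param blocks_path,variants_path TSV paths (variants optional)
#' @param strains character(2) strain names
#' @return an `alignment_blocks` object
#' @export
read_alignment_blocks <- function(blocks_path, variants_path = NULL,
                                  strains = c("ref", "alt")) {
  blocks <- read_tsv(blocks_path)
  variants <- if (!is.null(variants_path)) read_tsv(variants_path) else NULL
  alignment_blocks(blocks, variants, strains)
}

# alt-side length of a ref segment [s, e) given its variants
.alt_span <- function(len, vars) {
  len + sum(vars$size[vars$type == "ins"]) -
    sum(vars$size[vars$type == "del"])
}

#' Build common uninterrupted regions (CURs)
#'
#' Blocks are split at every indel larger than `max_indel`, then segments
#' shorter than `min_length` in either strain are discarded (greedy split,
#' unique solution).  The defaults retain regions larger than 4 kb with no
#' indel above 30 bp.
#'
#' @param aln an `alignment_blocks` object
#' @param min_length minimum CUR length, required in both strains (bp)
#' @param max_indel largest indel tolerated inside a CUR (bp)
#' @return an object of class `cur_set`
#' @export
build_curs <- function(aln, min_length = 4000L, max_indel = 30L) {
  stopifnot(inherits(aln, "alignment_blocks"))
  fail_if(min_length < 1, "min_length must be positive")
  out_curs <- list()
  out_vars <- list()
  cur_id <- 0L
  for (b in seq_len(nrow(aln$blocks))) {
    blk <- aln$blocks[b, ]
    v <- aln$variants[aln$variants$ref_contig == blk$ref_contig &
                        aln$variants$ref_pos >= blk$ref_start &
                        aln$variants$ref_pos < blk$ref_end, , drop = FALSE]
    v <- v[order(v$ref_pos), , drop = FALSE]
    big <- v[v$type %in% c("ins", "del") & v$size > max_indel, , drop = FALSE]
    # split points on the ref strain: a big deletion removes
    # [pos, pos+size); a big insertion cuts between pos-1 and pos
    seg_start <- blk$ref_start
    cuts <- data.frame(from = integer(), to = integer())
    if (nrow(big) > 0) {
      for (i in seq_len(nrow(big))) {
        gap_end <- if (big$type[i] == "del") big$ref_pos[i] + big$size[i]
                   else big$ref_pos[i]
        cuts <- rbind(cuts, data.frame(from = big$ref_pos[i], to = gap_end))
      }
    }
    segs <- data.frame(start = integer(), end = integer())
    pos <- blk$ref_start
    if (nrow(cuts) > 0) {
      for (i in seq_len(nrow(cuts))) {
        segs <- rbind(segs, data.frame(start = pos, end = cuts$from[i]))
        pos <- cuts$to[i]
      }
    }
    segs <- rbind(segs, data.frame(start = pos, end = blk$ref_end))
    segs <- segs[segs$end > segs$start, , drop = FALSE]
    # alt coordinate of each segment start: walk variants cumulatively
    for (i in seq_len(nrow(segs))) {
      s <- segs$start[i]; e <- segs$end[i]
      sv <- v[v$ref_pos >= s & v$ref_pos < e, , drop = FALSE]
      sv <- sv[!(sv$type %in% c("ins", "del") & sv$size > max_indel), ,
               drop = FALSE]
      # an insertion exactly at the segment start precedes the segment's
      # first base; its bases are accounted for in the start shift
      sv <- sv[!(sv$type == "ins" & sv$ref_pos == s), , drop = FALSE]
      # shift of the segment start relative to the block start: an
      # insertion at ref_pos == s sits before base s in the alt strain
      ins_b <- v$type == "ins" & v$ref_pos <= s
      del_b <- v$type == "del" & (v$ref_pos + v$size) <= s
      shift <- sum(v$size[ins_b]) - sum(v$size[del_b])
      ref_len <- e - s
      alt_len <- .alt_span(ref_len, sv)
      if (ref_len >= min_length && alt_len >= min_length) {
        cur_id <- cur_id + 1L
        alt_s <- blk$alt_start + (s - blk$ref_start) + shift
        out_curs[[cur_id]] <- data.frame(
          cur_id = cur_id,
          ref_contig = blk$ref_contig, ref_start = s, ref_end = e,
          alt_contig = blk$alt_contig, alt_start = alt_s,
          alt_end = alt_s + alt_len,
          stringsAsFactors = FALSE)
        if (nrow(sv) > 0) {
          sv$cur_id <- cur_id
          out_vars[[cur_id]] <- sv
        }
      }
    }
  }
  curs <- if (length(out_curs)) do.call(rbind, out_curs) else
    data.frame(cur_id = integer(), ref_contig = character(),
               ref_start = integer(), ref_end = integer(),
               alt_contig = character(), alt_start = integer(),
               alt_end = integer())
  vars <- if (length(out_vars)) do.call(rbind, out_vars) else
    data.frame(ref_contig = character(), ref_pos = integer(),
               type = character(), size = integer(), cur_id = integer())
  # precompute alt coordinates of each variant (anchor on its CUR)
  if (nrow(vars) > 0) {
    vars$alt_pos <- NA_integer_
    for (cid in unique(vars$cur_id)) {
      sel <- which(vars$cur_id == cid)
      cc <- curs[curs$cur_id == cid, ]
      shift <- 0L
      for (j in sel) {
        vars$alt_pos[j] <- cc$alt_start + (vars$ref_pos[j] - cc$ref_start) +
          shift
        if (vars$type[j] == "ins") shift <- shift + vars$size[j]
        if (vars$type[j] == "del") shift <- shift - vars$size[j]
      }
    }
  } else {
    vars$alt_pos <- integer()
  }
  structure(list(curs = curs, variants = vars, strains = aln$strains),
            class = "cur_set")
}

#' @export
print.cur_set <- function(x, ...) {
  cat(sprintf("cur_set: %d CURs (%s vs %s), %d variants, %.1f kb total\n",
              nrow(x$curs), x$strains[1], x$strains[2],
              nrow(x$variants),
              sum(x$curs$ref_end - x$curs$ref_start) / 1000))
  invisible(x)
}

# translation machinery for one CUR: given positions p (ref side),
# return alt coordinates.  Positions inside a deleted segment map to the
# left flank of the deletion (deterministic, monotone).
.translate_in_cur <- function(p, cur, vars, direction) {
  if (direction == "ref2alt") {
    from_start <- cur$ref_start; to_start <- cur$alt_start
    vpos <- vars$ref_pos
    ins <- vars$type == "ins"; del <- vars$type == "del"
  } else {
    # mirrored view: an insertion in alt coordinates is a deletion when
    # mapping alt -> ref, and vice versa
    from_start <- cur$alt_start; to_start <- cur$ref_start
    vpos <- vars$alt_pos
    ins <- vars$type == "del"; del <- vars$type == "ins"
  }
  keep <- ins | del
  vpos <- vpos[keep]; sz <- vars$size[keep]
  ins <- ins[keep]; del <- del[keep]
  out <- to_start + (p - from_start)
  if (length(vpos) == 0) return(out)
  o <- order(vpos)
  vpos <- vpos[o]; sz <- sz[o]; ins <- ins[o]; del <- del[o]
  # threshold after which the variant's shift applies
  thr <- ifelse(del, vpos + sz, vpos)
  shift <- ifelse(ins, sz, -sz)
  cum <- cumsum(shift)
  k <- findInterval(p, thr)
  out <- out + ifelse(k > 0, cum[pmax(k, 1)], 0)
  # positions inside deleted segments -> left flank
  if (any(del)) {
    dstart <- vpos[del]; dend <- vpos[del] + sz[del]
    cum_before <- c(0, cum)[which(del)]  # cumulative shift before each del
    j <- findInterval(p, dstart)
    inside <- j > 0 & p < dend[pmax(j, 1)]
    if (any(inside)) {
      jj <- j[inside]
      out[inside] <- to_start + (dstart[jj] - from_start) + cum_before[jj]
    }
  }
  out
}

#' Translate positions between strains through a CUR set
#'
#' Positions outside every CUR are untranslatable and yield `NA` (a typed
#' missing result, not an error).  Translation is monotone within a CUR
#' and round-trips exactly for positions not inside indels; positions
#' inside a deleted segment map to the left flank of the deletion.
#'
#' @param cur_set a `cur_set`
#' @param pos integer vector of 0-based positions
#' @param direction "ref2alt" or "alt2ref"
#' @param contig contig name (default: first contig in the set)
#' @return integer vector, `NA` where untranslatable
#' @export
translate <- function(cur_set, pos, direction = c("ref2alt", "alt2ref"),
                      contig = NULL) {
  stopifnot(inherits(cur_set, "cur_set"))
  direction <- match.arg(direction)
  curs <- cur_set$curs
  side <- if (direction == "ref2alt") "ref" else "alt"
  if (!is.null(contig))
    curs <- curs[curs[[paste0(side, "_contig")]] == contig, , drop = FALSE]
  out <- rep(NA_integer_, length(pos))
  if (nrow(curs) == 0) return(out)
  starts <- curs[[paste0(side, "_start")]]
  ends <- curs[[paste0(side, "_end")]]
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; ids <- curs$cur_id[o]
  k <- findInterval(pos, starts)
  hit <- k > 0 & pos < ends[pmax(k, 1)]
  for (cid in unique(ids[k[hit]])) {
    sel <- which(hit & ids[pmax(k, 1)] == cid)
    cc <- cur_set$curs[cur_set$curs$cur_id == cid, ]
    vv <- cur_set$variants[cur_set$variants$cur_id == cid, , drop = FALSE]
    out[sel] <- as.integer(.translate_in_cur(pos[sel], cc, vv, direction))
  }
  out
}

#' Local polymorphism density around positions
#'
#' Counts SNPs and indels (each indel as one event) within +/- `halfwidth`
#' of each center position, divided by the window length.  Windows fully
#' outside CURs are untranslatable (`NA`).
#'
#' @param cur_set a `cur_set`
#' @param center integer vector of 0-based ref-strain positions
#' @param halfwidth window half width in bp (window length 2*halfwidth+1)
#' @param percent return the rate in percent (default) or per bp
#' @return numeric vector of rates
#' @export
local_polymorphism <- function(cur_set, center, halfwidth = 30L,
                               percent = TRUE) {
  stopifnot(inherits(cur_set, "cur_set"))
  curs <- cur_set$curs
  starts <- sort(curs$ref_start)
  ends <- curs$ref_end[order(curs$ref_start)]
  vpos <- sort(cur_set$variants$ref_pos)
  w <- 2L * halfwidth + 1L
  lo <- center - halfwidth
  hi <- center + halfwidth
  k <- findInterval(center, starts)
  in_cur <- k > 0 & center < ends[pmax(k, 1)]
  n <- findInterval(hi, vpos) - findInterval(lo - 1L, vpos)
  rate <- n / w
  rate[!in_cur] <- NA_real_
  if (percent) rate * 100 else rate
}

#' Export a CUR set to BED and TSV
#'
#' Writes one BED file of CUR intervals per strain plus an offset-table
#' TSV of the retained variants.
#' @param cur_set a `cur_set`
#' @param prefix output path prefix
#' @return invisibly, the written paths
#' @export
write_curs <- function(cur_set, prefix) {
  paths <- c(ref = paste0(prefix, ".", cur_set$strains[1], ".bed"),
             alt = paste0(prefix, ".", cur_set$strains[2], ".bed"),
             var = paste0(prefix, ".variants.tsv"))
  for (side in c("ref", "alt")) {
    cc <- cur_set$curs
    gr <- GenomicRanges::GRanges(
      seqnames = cc[[paste0(side, "_contig")]],
      ranges = IRanges::IRanges(start = cc[[paste0(side, "_start")]] + 1L,
                                end = cc[[paste0(side, "_end")]]))
    gr$name <- sprintf("CUR%d", cc$cur_id)
    rtracklayer::export(gr, paths[[side]], format = "BED")
  }
  write_tsv(cur_set$variants, paths[["var"]])
  invisible(paths)
}
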