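# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code from fixed seeds; no data files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small two-strain world: 120 kb, SNPs + indels, ~700 nucleosomes,
# one ChIP mark, planted shifts/evictions/SNEPs
fix_world <- function() fixture("world", function() {
  g <- generate_genomes(11, 120000, 2, snp_rate = 0.005,
                        indel_rate = 1e-4, indel_size_max = 10)
  land <- generate_landscape(11, g, n_shifted = 20, shift_bp = 30,
                             n_evicted = 10, fuzzy_fraction = 0.03)
  sneps <- data.frame(nuc_id = c(25, 125, 225),
                      mark = "H3K4me3", log2fc = c(2, -2, 2))
  rs <- simulate_reads(11, land, marks = "H3K4me3", n_reads = 1.5e5,
                       planted_sneps = sneps, dispersion = 0.05)
  cs <- build_curs(g$alignments$strain2, min_length = 4000,
                   max_indel = 30)
  list(g = g, land = land, sneps = sneps, rs = rs, cs = cs)
})

fix_maps <- function() fixture("maps", function() {
  w <- fix_world()
  m1 <- nucleosome_map(w$rs, "strain1", w$land$lengths[1])
  m2 <- nucleosome_map(w$rs, "strain2", w$land$lengths[2])
  mm <- match_maps(m1, m2, w$cs)
  list(m1 = m1, m2 = m2, mm = mm)
})

fix_counts <- function() fixture("counts", function() {
  w <- fix_world()
  extract_counts(w$rs, fix_maps()$mm)
})

# identity CUR set over [0, len): ref == alt, no variants
identity_curs <- function(len = 1e6L) {
  aln <- alignment_blocks(
    data.frame(ref_contig = "chrI", ref_start = 0L, ref_end = len,
               alt_contig = "chrI", alt_start = 0L, alt_end = len))
  build_curs(aln, min_length = 1L, max_indel = 30L)
}

# hand-built read_set from a named list of start vectors + sample sheet
make_read_set <- function(reads, meta, strains = c("strain1", "strain2"),
                          contig = "chrI") {
  structure(list(meta = meta, reads = reads, contig = contig,
                 strains = strains), class = "read_set")
}

# standard 2-strain x 2-assay sample sheet
make_meta <- function(n_rep = 2L, strains = c("strain1", "strain2"),
                      mark = "H3K4me3") {
  meta <- expand.grid(replicate = seq_len(n_rep), strain = strains,
                      assay = c("MNase", "ChIP"),
                      stringsAsFactors = FALSE)
  meta$mark <- ifelse(meta$assay == "ChIP", mark, NA_character_)
  meta$sample_id <- sprintf("%s_%s_rep%d", meta$strain, meta$assay,
                            meta$replicate)
  meta
}
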