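# Configuration-driven orchestration.
#
# A pipeline config (JSON on disk; a plain named list in R) either
# points at existing inputs (sample sheet of BED read files, an
# alignment-block table, a GFF3 of genes) or asks for a synthetic
# dataset, then runs the stages in dependency order:
# curs -> coverage -> nucmap -> snep -> genediv -> covary.
# Every stage writes TSV/BED artifacts under the output directory and a
# manifest records parameters, derived seeds and input checksums.  All
# randomness flows from the single config seed.

#' Build and validate a pipeline configuration
#'
#' @param config named list or path to a JSON config file.  Recognized
#'   fields: `seed`, `outdir`, `simulate` (list of arguments for the
#'   synthetic generator) or `inputs` (list with `sample_sheet`,
#'   `blocks`, `variants`, `genes`), and `thresholds` (any of
#'   chunk_size, min_cur_length, max_indel, fdr, p, delta_cutoff,
#'   window, permutations).
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(chunk_size = 90L, min_cur_length = 4000L,
                   max_indel = 30L, fdr = 1e-4, p = 0.01,
                   delta_cutoff = 10, window = 10L, permutations = 10L)
  th <- utils::modifyList(defaults, config$thresholds %||% list())
  fail_if(any(unlist(th) <= 0), "all thresholds must be positive")
  fail_if(is.null(config$seed), "config needs a seed")
  fail_if(is.null(config$outdir), "config needs an outdir")
  fail_if(is.null(config$simulate) && is.null(config$inputs),
          "config needs either a simulate block or inputs")
  if (!is.null(config$inputs)) {
    for (f in c("sample_sheet", "blocks", "genes")) {
      p <- config$inputs[[f]]
      fail_if(is.null(p) || !file.exists(p),
              "input file for '%s' missing or does not exist", f)
    }
  }
  config$thresholds <- th
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a pipeline configuration to JSON
#' @param config a `pipeline_config`
#' @param path output path
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# validate the sample sheet: >= 2 MNase replicates per strain
.check_samples <- function(meta) {
  for (st in unique(meta$strain)) {
    n_mn <- sum(meta$strain == st & meta$assay == "MNase")
    fail_if(n_mn < 2,
            "strain %s lacks MNase samples (need >= 2 replicates)", st)
  }
  invisible(NULL)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages execute in dependency order; a failing stage halts the run
#' with its name while earlier artifacts are retained.  Re-running with
#' the same config and seed reproduces identical outputs.
#'
#' @param config a `pipeline_config` (or list/path coercible to one)
#' @return invisibly, the manifest list (also written to
#'   `outdir/manifest.json`)
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  th <- config$thresholds
  seed <- as.integer(config$seed)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, thresholds = th, stages = list())
  t0 <- Sys.time()

  # ---- inputs ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    gen <- .stage("simulate", {
      g <- generate_genomes(seed,
                            length = sim$genome_length %||% 200000L,
                            n_strains = 2L,
                            snp_rate = sim$snp_rate %||% 0.005,
                            indel_rate = sim$indel_rate %||% 2e-4,
                            indel_size_max = sim$indel_size_max %||% 10L)
      genes <- generate_genes(seed, sim$genome_length %||% 200000L,
                              n_genes = sim$n_genes %||% 20L)
      land <- generate_landscape(seed, g,
                                 fuzzy_fraction = sim$fuzzy_fraction %||% 0.05,
                                 n_shifted = sim$n_shifted %||% 10L,
                                 n_evicted = sim$n_evicted %||% 5L)
      sneps <- NULL
      marks <- sim$marks %||% c("H3K4me3", "H3K14ac")
      if (!is.null(sim$n_sneps) && sim$n_sneps > 0) {
        with_seed(derive_seed(seed, 40L), {
          ids <- sample(land$nucs$nuc_id[!land$nucs$evicted &
                                           land$nucs$class == "well"],
                        sim$n_sneps)
          sneps <- data.frame(nuc_id = ids,
                              mark = sample(marks, sim$n_sneps,
                                            replace = TRUE),
                              log2fc = sample(c(-2, -1.5, 1.5, 2),
                                              sim$n_sneps, replace = TRUE))
        })
      }
      rs <- simulate_reads(seed, land, marks = marks,
                           n_reads = sim$n_reads %||% 2e5,
                           planted_sneps = sneps,
                           dispersion = sim$dispersion %||% 0.05,
                           genes = genes)
      sheet <- write_reads_bed(rs, file.path(outdir, "reads"))
      write_tsv(sheet, file.path(outdir, "sample_sheet.tsv"))
      write_genes_gff(genes, file.path(outdir, "genes.gff3"))
      write_genomes(g, file.path(outdir, "genomes"))
      list(aln = g$alignments[["strain2"]], genes = genes, rs = rs,
           land = land,
           truth_sneps = sneps)
    })
    aln <- gen$aln; genes <- gen$genes; rs <- gen$rs
    manifest$stages$simulate <- list(done = TRUE,
                                     n_samples = nrow(rs$meta))
  } else {
    sheet <- read_tsv(config$inputs$sample_sheet)
    aln <- read_alignment_blocks(config$inputs$blocks,
                                 config$inputs$variants,
                                 strains = unique(sheet$strain)[1:2])
    genes <- read_genes_gff(config$inputs$genes)
    rs <- read_reads_bed(sheet)
    manifest$inputs <- lapply(config$inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  }
  .check_samples(rs$meta)

  # ---- curs --------------------------------------------------------------
  cur_set <- .stage("curs", {
    cs <- build_curs(aln, min_length = th$min_cur_length,
                     max_indel = th$max_indel)
    fail_if(nrow(cs$curs) == 0, "no CURs pass the thresholds")
    write_curs(cs, file.path(outdir, "curs"))
    cs
  })
  manifest$stages$curs <- list(done = TRUE, n_curs = nrow(cur_set$curs))

  # ---- coverage ----------------------------------------------------------
  cov <- .stage("coverage", {
    cm <- chunk_coverage(rs, cur_set, chunk_size = th$chunk_size)
    qc <- qc_replicates(cm)
    write_tsv(qc, file.path(outdir, "qc_replicates.tsv"))
    keep <- qc$verdict != "flagged"
    cm$values <- cm$values[, keep, drop = FALSE]
    cm$meta <- cm$meta[keep, , drop = FALSE]
    pca <- pca_components(cm, n_permutations = 3L, seed = seed)
    write_tsv(data.frame(component = seq_along(pca$varfrac),
                         varfrac = pca$varfrac,
                         significant = pca$significant),
              file.path(outdir, "pca_components.tsv"))
    write_tsv(cbind(cm$chunks, as.data.frame(cm$values)),
              file.path(outdir, "coverage_matrix.tsv"))
    list(cm = cm, qc = qc, pca = pca)
  })
  rs$meta <- rs$meta[rs$meta$sample_id %in% cov$cm$meta$sample_id, ]
  manifest$stages$coverage <- list(done = TRUE,
                                   n_chunks = nrow(cov$cm$values),
                                   n_flagged = sum(cov$qc$verdict ==
                                                     "flagged"))

  # ---- nucmap ------------------------------------------------------------
  nuc <- .stage("nucmap", {
    strains <- rs$strains
    lens <- vapply(strains, function(st) {
      max(unlist(lapply(rs$reads[rs$meta$sample_id[rs$meta$strain == st]],
                        max))) + 200L
    }, numeric(1))
    map1 <- nucleosome_map(rs, strains[1], lens[1])
    map2 <- nucleosome_map(rs, strains[2], lens[2])
    matched <- match_maps(map1, map2, cur_set)
    div <- divergence_analysis(matched, shift_threshold = 10L)
    write_nuc_map_bed(map1, file.path(outdir,
                                      paste0("nucmap_", strains[1], ".bed")))
    write_nuc_map_bed(map2, file.path(outdir,
                                      paste0("nucmap_", strains[2], ".bed")))
    write_tsv(matched$pairs, file.path(outdir, "matched_pairs.tsv"))
    write_tsv(matched$unrs, file.path(outdir, "unrs.tsv"))
    list(matched = matched, div = div, map1 = map1, map2 = map2)
  })
  manifest$stages$nucmap <- list(done = TRUE,
                                 n_pairs = nrow(nuc$matched$pairs),
                                 n_unrs = nrow(nuc$matched$unrs))

  # ---- snep --------------------------------------------------------------
  snep <- .stage("snep", {
    ct <- extract_counts(rs, nuc$matched)
    marks <- sort(unique(na.omit(rs$meta$mark)))
    res <- do.call(rbind, lapply(marks, function(m)
      snep_scan(ct, m, fdr = th$fdr)))
    write_tsv(res, file.path(outdir, "sneps.tsv"))
    list(ct = ct, res = res, marks = marks)
  })
  manifest$stages$snep <- list(done = TRUE,
                               n_units = nrow(snep$ct$counts),
                               n_called = sum(snep$res$called))

  # ---- genediv -----------------------------------------------------------
  gdiv <- .stage("genediv", {
    sf <- size_factors(snep$ct)
    gp <- bin_genes(rs, genes, cur_set, sf = sf)
    ep <- epidiv_all(gp)
    write_tsv(ep, file.path(outdir, "epidiv.tsv"))
    mark1 <- snep$marks[1]
    d <- gp$collapsed[, , gp$strains[2], mark1] -
      gp$collapsed[, , gp$strains[1], mark1]
    ds <- delta_select(d, cutoff = th$delta_cutoff)
    write_tsv(ds, file.path(outdir, "delta_selection.tsv"))
    list(gp = gp, ep = ep, ds = ds)
  })
  manifest$stages$genediv <- list(done = TRUE,
                                  n_genes = nrow(gdiv$gp$genes),
                                  n_selected = sum(gdiv$ds$selected))

  # ---- covary ------------------------------------------------------------
  cvy <- .stage("covary", {
    ct <- snep$ct; res <- snep$res
    meta <- ct$meta
    # per-nucleosome ChIP/MNase signal per mark, strain 1
    st1 <- rs$strains[1]
    mn <- rowMeans(ct$counts[, meta$strain == st1 &
                               meta$assay == "MNase", drop = FALSE])
    signal <- sapply(snep$marks, function(m) {
      ch <- rowMeans(ct$counts[, meta$strain == st1 &
                                 !is.na(meta$mark) & meta$mark == m,
                               drop = FALSE])
      log2((ch + 0.5) / (mn + 0.5))
    })
    rho <- if (length(snep$marks) >= 2)
      mark_correlation(signal, min_n = min(100L, nrow(signal))) else NULL
    if (!is.null(rho))
      write_tsv(as.data.frame(rho), file.path(outdir,
                                              "mark_correlation.tsv"))
    reg <- NULL
    m1 <- snep$marks[1]
    ord <- order(ct$units$start1)  # genome order for ordinal neighbours
    calls1 <- res$called[res$mark == m1][ord]
    if (sum(calls1) >= 2) {
      reg <- regionality(calls1, window = th$window, seed = seed)
      write_tsv(data.frame(offset = reg$offsets, observed = reg$observed,
                           expected = reg$expected),
                file.path(outdir, "regionality.tsv"))
    }
    ann <- annotate_calls(nuc$map1, genes, cur_set = cur_set)
    write_tsv(ann, file.path(outdir, "annotations.tsv"))
    list(rho = rho, reg = reg, ann = ann)
  })
  manifest$stages$covary <- list(done = TRUE)

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
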