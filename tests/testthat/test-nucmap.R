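# Dyad calling, reproducibility classification, cross-strain matching.

test_that("call_dyads recovers planted nucleosomes", {
  set.seed(31)
  # one planted nucleosome: 200 reads, start = dyad - 73 + N(0, 10)
  starts <- 5000L - 73L + as.integer(round(rnorm(200, 0, 10)))
  d <- call_dyads(starts, 10000L)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$dyad - 5000L), 5L)

  # two nucleosomes 165 bp apart: both found, order preserved
  starts2 <- c(starts, 5165L - 73L + as.integer(round(rnorm(200, 0, 10))))
  d2 <- call_dyads(starts2, 10000L)
  expect_equal(nrow(d2), 2L)
  expect_true(all(diff(d2$dyad) > 0))
  expect_lt(max(abs(d2$dyad - c(5000L, 5165L))), 5L)

  # empty input: warning, empty map
  expect_warning(d0 <- call_dyads(integer(), 1000L), "no reads")
  expect_equal(nrow(d0), 0L)
})

test_that("uniform reads produce far fewer calls than structured reads", {
  set.seed(32)
  n_nuc <- 60L
  dyads <- 200L + 165L * (0:(n_nuc - 1L))
  L <- max(dyads) + 400L
  structured <- rep(dyads, each = 30) - 73L +
    as.integer(round(rnorm(30 * n_nuc, 0, 10)))
  uniform <- sample.int(L, length(structured), replace = TRUE) - 1L
  n_s <- nrow(call_dyads(structured, L))
  n_u <- nrow(call_dyads(uniform, L))
  expect_gte(n_s, 0.9 * n_nuc)
  expect_lte(n_u, 0.1 * n_s + 2)
})

test_that("reproducibility rule: sigma and multiplicity", {
  mk <- function(dyads) data.frame(dyad = dyads,
                                   score = rep(1, length(dyads)))
  # three replicates at 1000/1002/998 -> well-positioned at 1000
  m <- classify_reproducibility(list(mk(1000L), mk(1002L), mk(998L)),
                                strain = "s1")
  expect_equal(m$class, "well")
  expect_equal(m$dyad, 1000L)

  # 1000/1000/1060: sd ~ 34.6 > 20 -> fuzzy
  m2 <- classify_reproducibility(list(mk(1000L), mk(1000L), mk(1060L)),
                                 strain = "s1")
  expect_equal(m2$class, "fuzzy")

  # two dyads from one replicate inside the window -> fuzzy
  m3 <- classify_reproducibility(list(mk(c(1000L, 1040L)), mk(1010L),
                                      mk(1005L)), strain = "s1")
  expect_true(all(m3$class == "fuzzy"))

  # a replicate with no call in a region -> region fuzzy, not an error
  m4 <- classify_reproducibility(list(mk(1000L), mk(1001L), mk(integer())),
                                 strain = "s1")
  expect_equal(m4$class, "fuzzy")

  expect_error(classify_reproducibility(list(mk(1L))), "replicates")
})

test_that("match_maps: identity, partition identity, symmetry", {
  w <- fix_world()
  maps <- fix_maps()
  mm <- maps$mm
  # exhaustive partition: every call is in exactly one pair or one UNR
  expect_equal(nrow(mm$pairs) * 2 + sum(mm$unrs$n_members),
               nrow(maps$m1) + nrow(maps$m2))
  # same strain twice -> rejected
  expect_error(match_maps(maps$m1, maps$m1, w$cs), "same strain")

  # identical maps with identity translation: all pairs, shift 0, no UNRs
  cs_id <- identity_curs(200000L)
  m <- maps$m1[maps$m1$class == "well", ]
  m2 <- m
  attr(m, "strain") <- "a"; attr(m2, "strain") <- "b"
  class(m) <- class(m2) <- c("nuc_map", "data.frame")
  mm_id <- match_maps(m, m2, cs_id)
  expect_equal(nrow(mm_id$pairs), nrow(m))
  expect_true(all(mm_id$pairs$shift == 0))
  expect_equal(nrow(mm_id$unrs), 0L)

  # symmetry under map exchange (identity translation): negated shifts
  m3 <- m2
  m3$dyad <- m3$dyad + sample(c(-8L, 8L), nrow(m3), replace = TRUE)
  m3$start <- m3$dyad - 73L; m3$end <- m3$dyad + 74L
  mm_ab <- match_maps(m, m3, cs_id)
  mm_ba <- match_maps(m3, m, cs_id)
  expect_equal(nrow(mm_ab$pairs), nrow(mm_ba$pairs))
  expect_equal(sort(mm_ab$pairs$shift), sort(-mm_ba$pairs$shift))
})

test_that("planted shifts and evictions are recovered", {
  w <- fix_world()
  mm <- fix_maps()$mm
  dv <- divergence_analysis(mm)
  truth <- w$land$nucs
  sh_truth <- truth[truth$planted_shift != 0 & !truth$evicted, ]
  called <- dv$shifted[dv$shifted$shifted, ]
  # each planted 30-bp shift recovered with shift ~ 30 +/- 5
  rec <- vapply(seq_len(nrow(sh_truth)), function(i) {
    j <- which(abs(called$dyad1 - sh_truth$dyad1[i]) < 40)
    length(j) == 1 &&
      abs(abs(called$shift[j]) - abs(sh_truth$planted_shift[i])) <= 5
  }, logical(1))
  expect_gte(mean(rec), 0.85)

  # evicted nucleosomes leave their strain-1 footprint in a UNR
  ev <- truth[truth$evicted, ]
  in_unr <- vapply(ev$dyad1, function(d)
    any(mm$unrs$start <= d & mm$unrs$end > d), logical(1))
  expect_gte(mean(in_unr), 0.8)
})

test_that("divergence rules: thresholds and conserved-occupancy", {
  # all shifts in [-5, 5] -> zero flagged
  pairs <- data.frame(id1 = paste0("a", 1:10), id2 = paste0("b", 1:10),
                      dyad1 = 1000L * (1:10), dyad2 = 1000L * (1:10),
                      dyad1_tr = 1000L * (1:10),
                      shift = as.integer(c(-5, 5, 0, 3, -3, 1, 2, 4, -4, 0)))
  fake <- list(pairs = pairs,
               unrs = data.frame(unr_id = character(), start = integer(),
                                 end = integer(), n_members = integer(),
                                 members = character()),
               map1 = structure(data.frame(id = pairs$id1, class = "well",
                                           dyad = pairs$dyad1,
                                           start = pairs$dyad1 - 73L,
                                           end = pairs$dyad1 + 74L,
                                           score = 1, n_rep = 3L),
                                class = c("nuc_map", "data.frame"),
                                strain = "s1"),
               map2 = structure(data.frame(id = pairs$id2, class = "well",
                                           dyad = pairs$dyad2,
                                           start = pairs$dyad2 - 73L,
                                           end = pairs$dyad2 + 74L,
                                           score = 1, n_rep = 3L),
                                class = c("nuc_map", "data.frame"),
                                strain = "s2"),
               cur_set = identity_curs(20000L))
  dv <- divergence_analysis(fake)
  expect_equal(sum(dv$shifted$shifted), 0L)

  # an unmatched well fully inside a strain-2 UNR is conserved occupancy
  fake$map1 <- rbind(fake$map1,
                     data.frame(id = "a11", class = "well", dyad = 15000L,
                                start = 15000L - 73L, end = 15000L + 74L,
                                score = 1, n_rep = 3L))
  attr(fake$map1, "strain") <- "s1"
  class(fake$map1) <- c("nuc_map", "data.frame")
  fake$unrs <- data.frame(unr_id = "UNR00001", start = 14900L,
                          end = 15100L, n_members = 1L,
                          members = "s2_nuc00099")
  dv2 <- divergence_analysis(fake)
  expect_false(dv2$subpopulation$diverged[dv2$subpopulation$id == "a11"])
  # without the covering UNR it diverges (distance to nearest well large)
  fake$unrs <- fake$unrs[0, ]
  dv3 <- divergence_analysis(fake)
  expect_true(dv3$subpopulation$diverged[dv3$subpopulation$id == "a11"])
})

test_that("annotate_calls assigns +1/-1, TFBS proximity, polymorphism", {
  map <- structure(
    data.frame(id = paste0("n", 1:5), class = "well",
               dyad = c(920L, 1080L, 1250L, 1420L, 3000L),
               start = c(920L, 1080L, 1250L, 1420L, 3000L) - 73L,
               end = c(920L, 1080L, 1250L, 1420L, 3000L) + 74L,
               score = 1, n_rep = 3L),
    class = c("nuc_map", "data.frame"), strain = "s1")
  genes <- data.frame(gene_id = "geneA", start = 1000L, end = 2000L,
                      strand = "+", tss = 1000L, tes = 1999L)
  tf <- data.frame(start = 1449L, end = 1455L)  # 29 bp from dyad 1420
  ann <- annotate_calls(map, genes, tf_sites = tf)
  # dyad 80 bp downstream of the TSS, nearest such -> +1
  expect_equal(ann$position_class[ann$dyad == 1080], "+1")
  expect_equal(ann$position_class[ann$dyad == 920], "-1")
  expect_equal(ann$position_class[ann$dyad == 1250], "other")
  # strict 30-bp TFBS boundary
  expect_true(ann$tf_proximal[ann$dyad == 1420])
  tf31 <- data.frame(start = 1451L, end = 1455L)  # 31 bp away
  ann31 <- annotate_calls(map, genes, tf_sites = tf31)
  expect_false(ann31$tf_proximal[ann31$dyad == 1420])

  # divergent promoter: same nucleosome is -1 of A and +1 of B
  # geneB transcribes leftward from TSS 990: dyad 920 is its +1 and
  # simultaneously the -1 of geneA (TSS 1000, rightward)
  genes2 <- rbind(genes,
                  data.frame(gene_id = "geneB", start = 400L, end = 991L,
                             strand = "-", tss = 990L, tes = 400L))
  ann2 <- annotate_calls(map, genes2)
  roles <- attr(ann2, "roles")
  r920 <- roles[roles$id == "n1", ]
  expect_setequal(r920$role, c("-1", "+1"))
  expect_true(ann2$is_plus1[1] && ann2$is_minus1[1])
})

test_that(">=95% of planted wells are called within 10 bp", {
  w <- fix_world()
  m1 <- fix_maps()$m1
  truth <- w$land$nucs
  wells <- truth[truth$class == "well", ]
  hit <- vapply(wells$dyad1, function(d)
    any(abs(m1$dyad - d) <= 10, na.rm = TRUE), logical(1))
  expect_gte(mean(hit), 0.95)
})
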