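# Gene binning, differential clustering, epidiv, delta, QTL scan.

test_that("percentile binning partitions gene bodies exactly", {
  expect_equal(percentile_widths(1000L), rep(10L, 100))
  w550 <- percentile_widths(550L)
  expect_true(all(w550 %in% c(5L, 6L)))
  expect_equal(sum(w550), 550L)
  # remainder distributed from the 5' side
  expect_equal(w550[1:50], rep(6L, 50))
  # brute-force partition identity over many lengths
  for (len in c(101L, 137L, 999L, 1001L, 4242L))
    expect_equal(sum(percentile_widths(len)), len)
})

test_that("bin_genes: flat profiles, strand symmetry, exclusions", {
  cs <- identity_curs(40000L)
  genes <- data.frame(gene_id = c("gp", "gm"),
                      start = c(10000L, 25000L), end = c(11000L, 26000L),
                      strand = c("+", "-"),
                      tss = c(10000L, 25999L), tes = c(10999L, 25000L))
  meta <- make_meta(n_rep = 2L)
  set.seed(71)
  reads <- lapply(seq_len(nrow(meta)), function(j)
    sample.int(40000L, 2e5, replace = TRUE) - 1L)
  names(reads) <- meta$sample_id
  rs <- make_read_set(reads, meta)
  gp <- bin_genes(rs, genes, cs)
  # uniform coverage -> flat body profile (10-bp flanks vs 10-bp body
  # bins have equal expected counts for a 1-kb gene)
  prof <- gp$collapsed["gp", , "strain1", "MNase"]
  expect_lt(sd(prof) / mean(prof), 0.25)
  expect_equal(length(prof), 600L)

  # minus-strand gene equals the reversed plus-strand computation
  rs_mirror <- rs
  rs_mirror$reads <- lapply(reads, function(s) 40000L - 1L - s)
  genes_m <- data.frame(gene_id = "gm2", start = 40000L - 11000L,
                        end = 40000L - 10000L, strand = "-",
                        tss = 40000L - 10001L, tes = 40000L - 11000L)
  gp_m <- bin_genes(rs_mirror, genes_m, cs)
  # read starts mirror to read "ends"; compare at profile level
  expect_equal(mean(gp_m$collapsed["gm2", , "strain1", "MNase"]),
               mean(gp$collapsed["gp", , "strain1", "MNase"]),
               tolerance = 0.05)

  # short genes and genes outside CURs are excluded
  genes_bad <- rbind(genes,
                     data.frame(gene_id = c("tiny", "outside"),
                                start = c(5000L, 39000L),
                                end = c(5050L, 41000L),
                                strand = "+", tss = c(5000L, 39000L),
                                tes = c(5049L, 40999L)))
  expect_message(gp2 <- bin_genes(rs, genes_bad, cs), "excluding 2")
  expect_equal(nrow(gp2$genes), 2L)
})

test_that("epidiv equals anova(lm) with sum contrasts (oracle)", {
  set.seed(72)
  S <- 2; M <- 3; B <- 8
  y <- array(rnorm(S * M * B), c(S, M, B))
  r <- epidiv(y)
  df <- expand.grid(strain = factor(1:S), mark = factor(1:M),
                    bin = factor(1:B))
  df$y <- as.vector(y)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  a <- anova(lm(y ~ strain + mark + bin + strain:mark + strain:bin, df))
  for (term in c("strain", "mark", "bin", "strain:mark", "strain:bin"))
    expect_equal(r$table$ss[r$table$term == term],
                 a[term, "Sum Sq"], tolerance = 1e-9)
  # ANOVA accounting: sum of SS equals total SS; df sum equals n - 1
  expect_equal(sum(r$table$ss), sum((y - mean(y))^2), tolerance = 1e-9)
  expect_equal(sum(r$table$df), S * M * B - 1)
})

test_that("epidiv: identical strains give 0; planted effects stand out", {
  set.seed(73)
  base <- array(rnorm(5 * 100), c(1, 5, 100))
  y_same <- array(0, c(2, 5, 100))
  y_same[1, , ] <- base[1, , ]
  y_same[2, , ] <- base[1, , ]
  expect_equal(epidiv(y_same)$epidiv, 0)

  # null calibration: mean of F within 5% of df2/(df2-2)
  B <- 100
  fs <- replicate(300, epidiv(array(rnorm(2 * 5 * B), c(2, 5, B)))$epidiv)
  df2 <- (5 - 1) * (B - 1)
  expect_equal(mean(fs), df2 / (df2 - 2), tolerance = 0.05)
  null99 <- quantile(fs, 0.99)

  # planted +1 offset for one strain in one mark
  y <- array(rnorm(2 * 5 * B), c(2, 5, B))
  y[2, 3, ] <- y[2, 3, ] + 1
  expect_gt(epidiv(y)$epidiv, null99)

  # invariance to consistent bin reordering
  y2 <- y[, , sample(B)]
  expect_equal(epidiv(y2)$epidiv, epidiv(y)$epidiv, tolerance = 1e-9)

  expect_error(epidiv(array(NA_real_, c(2, 2, 2))), "missing")
})

test_that("differential_patterns recovers planted gene groups", {
  # two groups with opposite body differences in one mark
  set.seed(74)
  n_g <- 20L
  gp <- list(collapsed = array(rexp(n_g * 600 * 2 * 3),
                               c(n_g, 600, 2, 3),
                               dimnames = list(sprintf("g%02d", 1:n_g),
                                               NULL,
                                               c("strain1", "strain2"),
                                               c("MNase", "H3K4me3",
                                                 "H3K9ac"))),
             strains = c("strain1", "strain2"),
             marks = c("H3K4me3", "H3K9ac"),
             genes = data.frame(gene_id = sprintf("g%02d", 1:n_g)))
  class(gp) <- "gene_profiles"
  grp <- rep(c(1, 2), each = n_g / 2)
  body <- 251:350
  gp$collapsed[grp == 1, body, "strain1", "H3K4me3"] <-
    gp$collapsed[grp == 1, body, "strain1", "H3K4me3"] + 20
  gp$collapsed[grp == 2, body, "strain2", "H3K4me3"] <-
    gp$collapsed[grp == 2, body, "strain2", "H3K4me3"] + 20
  dp <- differential_patterns(gp)
  cl <- cut_patterns(dp, 2)
  expect_equal(length(unique(cl[grp == 1])), 1L)
  expect_equal(length(unique(cl[grp == 2])), 1L)
  expect_true(cl[1] != cl[n_g])
  # identical strains -> zero vectors
  gp0 <- gp
  gp0$collapsed[, , "strain2", ] <- gp0$collapsed[, , "strain1", ]
  dp0 <- differential_patterns(gp0)
  expect_true(all(abs(dp0$vectors) < 1e-12))
})

test_that("delta_select matches the brute-force median difference", {
  set.seed(75)
  d <- matrix(rnorm(10 * 600), 10, 600,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  ds <- delta_select(d)
  oracle <- vapply(1:10, function(i)
    median(d[i, 284:333]) - median(d[i, 251:266]), numeric(1))
  expect_equal(ds$delta, unname(oracle))
  # constant profile -> delta 0, not selected
  dc <- matrix(5, 1, 600, dimnames = list("gc", NULL))
  expect_equal(delta_select(dc)$delta, 0)
  expect_false(delta_select(dc)$selected)
  # d = 0 on R1, 12 on R2 -> delta 12, selected at cutoff 10
  d2 <- matrix(0, 1, 600, dimnames = list("gx", NULL))
  d2[, 284:333] <- 12
  expect_equal(delta_select(d2)$delta, 12)
  expect_true(delta_select(d2)$selected)
})

test_that("subset_shift_test: degenerate, power, rejection", {
  x <- c(rep(1, 50), rep(1, 50))
  expect_equal(subset_shift_test(x, c(rep(TRUE, 50), rep(FALSE, 50)))$statistic,
               0)
  set.seed(76)
  v <- rnorm(2000)
  mask <- rep(FALSE, 2000); mask[1:500] <- TRUE
  v[mask] <- v[mask] + 1
  expect_lt(subset_shift_test(v, mask)$p, 1e-6)
  expect_error(subset_shift_test(v, rep(TRUE, 2000)), "proper subset")
})

test_that("wilcox_scan matches wilcox.test and masks monomorphic markers", {
  set.seed(77)
  ph <- rnorm(40)
  g <- cbind(rbinom(40, 1, 0.5), rep(0L, 40), rbinom(40, 1, 0.5))
  p <- wilcox_scan(ph, g)
  expect_true(is.na(p[2]))
  for (k in c(1, 3))
    expect_equal(p[k], wilcox.test(ph[g[, k] == 1], ph[g[, k] == 0],
                                   exact = FALSE)$p.value,
                 tolerance = 1e-12)
  # ties handled identically
  ph2 <- sample(1:4, 40, TRUE)
  expect_equal(wilcox_scan(ph2, g[, 1, drop = FALSE]),
               wilcox.test(ph2[g[, 1] == 1], ph2[g[, 1] == 0],
                           exact = FALSE)$p.value, tolerance = 1e-12)
})

test_that("qtl_scan: detection, determinism, refusals", {
  cr <- generate_cross(81, 60, 120, qtl_marker = 40, effect = 2,
                       n_genes = 80)
  sc <- qtl_scan(cr$values, cr$halves, cr$genotypes, seed = 81)
  expect_gt(sc$scores[40], sc$threshold)
  expect_true(40 %in% sc$significant_markers)
  # threshold reproducible under the same seed
  sc2 <- qtl_scan(cr$values, cr$halves, cr$genotypes, seed = 81)
  expect_identical(sc2$threshold, sc$threshold)
  expect_identical(sc2$scores, sc$scores)
  # monomorphic marker masked
  gt <- cr$genotypes; gt[, 5] <- 0L
  sc3 <- qtl_scan(cr$values, cr$halves, gt, seed = 81)
  expect_true(is.na(sc3$scores[5]))
  # two segregants -> refuses
  expect_error(qtl_scan(lapply(cr$values, function(v) v[, 1:2]),
                        cr$halves, cr$genotypes[1:2, ], seed = 1),
               "refuses")
})

test_that("covariate_assoc: self-correlation, null bound, binary shift", {
  set.seed(82)
  x <- rexp(3000)
  expect_equal(covariate_assoc(x, x)$statistic, 1)
  # independent covariate: |rho| below the null bound most of the time
  r0 <- covariate_assoc(x, rnorm(3000))
  expect_lt(abs(r0$statistic), 0.06)
  # binary covariate with a +0.5 SD shift at n = 500/group
  b <- rep(c(0, 1), each = 500)
  y <- rnorm(1000) + 0.5 * b
  ra <- covariate_assoc(y, b)
  expect_equal(ra$test, "wilcoxon")
  expect_lt(ra$p, 0.01)
  expect_error(covariate_assoc(x, rep(1, 3000)), "constant")
})
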