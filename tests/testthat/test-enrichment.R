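# SNEP distribution statistics: density maps, feature-proximity enrichment,
# local correlation, conserved-site categories, expression association,
# ranked-gene windows, remodeled-nucleosome enrichment.

# a chromosome of tiled tested nucleosomes with programmable SNEP labels
make_tests <- function(n = 200, snep = rep(FALSE, n), direction = rep("BYac", n),
                       chrom = "chrI", pitch = 165) {
  starts <- seq(0, by = pitch, length.out = n)
  data.frame(pair_id = sprintf("%s_p%05d", chrom, seq_len(n)), chrom = chrom,
             start = starts, end = starts + 147,
             significant = snep, direction = direction,
             fold_change = 1.3, p = ifelse(snep, 1e-8, 0.5),
             stringsAsFactors = FALSE)
}

test_that("density map fractions equal brute-force counting, with unalignable bins distinct", {
  n <- 200
  snep <- rep(FALSE, n); snep[1:10] <- TRUE   # 10 SNEPs in the first bins
  tests <- make_tests(n, snep)
  dm <- snep_density_map(tests, bin_bp = 1000)
  # brute force per bin
  mid <- (tests$start + tests$end) / 2
  for (b in seq_len(nrow(dm))) {
    sel <- mid >= dm$start[b] & mid < dm$end[b]
    if (any(sel)) expect_equal(dm$fraction[b], mean(snep[sel]))
  }
  # all or nothing
  expect_true(all(snep_density_map(make_tests(50, rep(TRUE, 50)))$fraction %in% c(1, NA)))
  expect_true(all(snep_density_map(make_tests(50))$fraction %in% c(0, NA), na.rm = TRUE))
  # a bin with no nucleosomes is NA, not zero
  tests_gap <- make_tests(20)
  tests_gap$start <- tests_gap$start + ifelse(tests_gap$start >= 1000, 4000, 0)
  tests_gap$end <- tests_gap$start + 147
  dmg <- snep_density_map(tests_gap, bin_bp = 1000)
  expect_true(any(is.na(dmg$fraction)))
})

test_that("chi-square matches the textbook formula on the printed example", {
  tab <- matrix(c(30, 10, 70, 190), 2, 2)
  cs <- snepr:::chisq_2x2(tab)
  # direct Sum (O-E)^2 / E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(cs$chi2, sum((tab - E)^2 / E))
  expect_equal(cs$chi2, 36.06, tolerance = 0.001)  # hand-computed from the table
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(cs$chi2, unname(ref$statistic))
  expect_equal(cs$p, ref$p.value)
  # margins conserved
  expect_equal(rowSums(E), rowSums(tab))
  expect_equal(colSums(E), colSums(tab))
})

test_that("upstream enrichment is null under uniform SNEP placement and detects a hotspot", {
  set.seed(17)
  n <- 2000
  snep <- runif(n) < 0.1
  tests <- make_tests(n, snep)
  anchors <- data.frame(chrom = "chrI", pos = 150000, side = "left")
  ue <- upstream_enrichment(tests, anchors, interval_bp = 10000, n_intervals = 5)
  expect_lt(abs(ue$fold - 1), 0.6)
  expect_gt(ue$p, 0.01)

  # hotspot: all nucleosomes in the first upstream interval are SNEPs
  mid <- (tests$start + tests$end) / 2
  snep2 <- snep
  snep2[mid >= 140000 & mid < 150000] <- TRUE
  ue2 <- upstream_enrichment(make_tests(n, snep2), anchors)
  expect_gt(ue2$fold, 5)
  expect_lt(ue2$p, 1e-6)

  # zero SNEPs near the anchor: fold 0
  snep3 <- snep
  snep3[mid >= 140000 & mid < 150000] <- FALSE
  ue3 <- upstream_enrichment(make_tests(n, snep3), anchors)
  expect_equal(ue3$fold, 0)
})

test_that("local correlation is zero for isolated SNEPs and one for saturated maps", {
  n <- 300
  snep <- rep(FALSE, n); snep[150] <- TRUE
  lc <- local_correlation(make_tests(n, snep), radius = 5, n_perm = 5, seed = 2)
  expect_true(all(lc$observed == 0))

  lc1 <- local_correlation(make_tests(50, rep(TRUE, 50)), radius = 3, n_perm = 5, seed = 2)
  expect_true(all(lc1$observed == 1))

  # permuted control approximates the global same-direction SNEP frequency
  set.seed(3)
  snep_r <- runif(n) < 0.2
  lcr <- local_correlation(make_tests(n, snep_r), radius = 5, n_perm = 200, seed = 4)
  expect_lt(max(abs(lcr$control - mean(snep_r))), 0.03)
})

test_that("category assignment honors the full-coverage and midpoint rules", {
  tests <- make_tests(3, pitch = 500)   # calls [0,147) [500,647) [1000,1147)
  crs <- list(intervals = data.frame(chrom = "chrI", start = 50, end = 60))
  # call 1 fully covers the 10 bp site -> category 1
  cat1 <- snepr:::nucleosome_category(tests, crs$intervals,
                                      data.frame(chrom = character(), start = numeric(),
                                                 end = numeric()))
  expect_equal(cat1, c(1L, 3L, 3L))
  # covering 9 of 10 bp is not category 1
  crs9 <- data.frame(chrom = "chrI", start = 140, end = 150)
  cat9 <- snepr:::nucleosome_category(tests, crs9,
                                      data.frame(chrom = character(), start = numeric(),
                                                 end = numeric()))
  expect_equal(cat9[1], 3L)
  # midpoint-in-conserved-noncoding -> category 2 unless already 1
  cnc <- data.frame(chrom = "chrI", start = 550, end = 600)
  cat2 <- snepr:::nucleosome_category(tests, crs$intervals, cnc)
  expect_equal(cat2, c(1L, 2L, 3L))
})

test_that("category enrichment folds behave under uniform and concentrated SNEPs", {
  set.seed(21)
  n <- 3000
  tests <- make_tests(n, runif(n) < 0.1)
  # every 10th nucleosome covers a CRS
  crs_iv <- data.frame(chrom = "chrI", start = tests$start[seq(1, n, 10)] + 50,
                       end = tests$start[seq(1, n, 10)] + 60)
  cnc_iv <- data.frame(chrom = "chrI", start = tests$start[seq(5, n, 10)] + 40,
                       end = tests$start[seq(5, n, 10)] + 80)
  ce <- category_enrichment(tests, list(intervals = crs_iv), list(intervals = cnc_iv))
  byac <- ce[ce$direction == "BYac", ]
  expect_equal(nrow(ce), 6L)
  expect_lt(abs(byac$fold[byac$category == 1] - 1), 0.5)
  expect_true(all(ce$ci_lower <= ce$fraction & ce$fraction <= ce$ci_upper, na.rm = TRUE))

  # all category-1 nucleosomes SNEP, none elsewhere
  cat_ <- snepr:::nucleosome_category(tests, crs_iv, cnc_iv)
  tests2 <- tests; tests2$significant <- cat_ == 1L
  ce2 <- category_enrichment(tests2, list(intervals = crs_iv), list(intervals = cnc_iv))
  b2 <- ce2[ce2$direction == "BYac", ]
  expect_equal(b2$fraction[b2$category == 1], 1)
  expect_equal(b2$fraction[b2$category == 3], 0)
  expect_lt(b2$p[b2$category == 1], 1e-10)
})

test_that("ranked-gene windows reduce to the global mean and track monotone trends", {
  set.seed(23)
  n_genes <- 40
  genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)), chrom = "chrI",
                      strand = "+",
                      cds_start = seq(0, by = 2000, length.out = n_genes),
                      cds_end = seq(1500, by = 2000, length.out = n_genes))
  genes$tss <- genes$cds_start - 60; genes$tes <- genes$cds_end + 60
  # nucleosomes within each gene; SNEP frequency increases with gene index
  rows <- list()
  for (g in seq_len(n_genes)) {
    starts <- seq(genes$cds_start[g], genes$cds_end[g] - 147, by = 165)
    rows[[g]] <- data.frame(chrom = "chrI", start = starts, end = starts + 147,
                            significant = runif(length(starts)) < g / n_genes,
                            direction = "BYac")
  }
  tests <- do.call(rbind, rows)
  scores <- data.frame(gene_id = genes$gene_id, value = seq_len(n_genes))
  # window of the full gene set: the windowed value is the global mean
  rk_all <- ranked_gene_enrichment(tests, genes, scores, window_genes = n_genes)
  per_gene <- rk_all$freq
  expect_equal(rk_all$windowed, rep(mean(per_gene, na.rm = TRUE), n_genes))
  # small windows: monotone increasing trend along the ranking
  rk <- ranked_gene_enrichment(tests, genes, scores, window_genes = 10)
  expect_gt(rk$windowed[n_genes] , rk$windowed[1])
  expect_gt(cor(rk$rank, rk$windowed, method = "spearman"), 0.8)
})

test_that("remodeled-nucleosome enrichment reproduces folds and the printed fraction", {
  set.seed(27)
  n <- 4000
  base_rate <- 0.1
  tests <- make_tests(n, runif(n) < base_rate)
  # remodeled regions containing the first 200 nucleosomes
  rem_iv <- data.frame(chrom = "chrI", start = tests$start[1:200] - 5,
                       end = tests$end[1:200] + 5)
  # equal SNEP rates: fold about 1
  re <- remodeled_enrichment(tests, list(intervals = rem_iv))
  expect_equal(re$n_remodeled, 200L)
  expect_lt(abs(re$fold - 1), 0.6)
  # doubled SNEP rate among remodeled: fold about 2 and significant
  tests2 <- tests
  tests2$significant[1:200] <- runif(200) < 2 * base_rate
  re2 <- remodeled_enrichment(tests2, list(intervals = rem_iv))
  expect_gt(re2$fold, 1.3)
  expect_lt(re2$p, 0.05)
  # printed-scale check: 147 remodeled among 147 + 61,623 is about 0.2%
  expect_equal(round(147 / (147 + 61623) * 100, 1), 0.2)
})

test_that("expression association is near-null by construction and exact in the limit", {
  set.seed(31)
  n_genes <- 60
  genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)), chrom = "chrI",
                      strand = "+",
                      tss = seq(0, by = 3000, length.out = n_genes))
  genes$tes <- genes$tss + 2400
  genes$cds_start <- genes$tss + 60; genes$cds_end <- genes$tes - 60
  pos <- seq(0, max(genes$tes), by = 20)
  ratio_by <- data.frame(chrom = "chrI", position = pos, value = rnorm(length(pos), 0.5, 0.2))
  ratio_rm <- data.frame(chrom = "chrI", position = pos, value = rnorm(length(pos), 0.5, 0.2))
  calls <- make_calls(0, max(genes$tes) + 100)
  starts <- seq(0, max(genes$tes) - 147, by = 165)
  tests <- data.frame(chrom = "chrI", start = starts, end = starts + 147,
                      significant = runif(length(starts)) < 0.1,
                      direction = sample(c("BYac", "RMac"), length(starts), TRUE))
  expr <- data.frame(gene_id = genes$gene_id, value = rnorm(n_genes))
  ea <- expression_association(genes, ratio_by, ratio_rm, calls, calls, tests,
                               expr, n_perm = 30, seed = 5)
  expect_equal(ea$correlations$region, c("beginning", "middle", "end"))
  # independent by construction: weak correlations
  expect_true(all(abs(ea$correlations$pearson) < 0.35))
  # SNEP directions assigned independently of expression: permuted and
  # observed fractions share their mean (exchangeability)
  expect_equal(mean(ea$snep_fraction, na.rm = TRUE),
               mean(ea$snep_fraction_permuted, na.rm = TRUE), tolerance = 0.02)
})
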