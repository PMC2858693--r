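# Metagene profiles, TSS occupancy matrices, promoter clustering, and
# cross-strain occupancy dissimilarity.

one_gene <- function(strand = "+", chrom = "chrI") {
  if (strand == "+")
    data.frame(gene_id = "g1", chrom = chrom, strand = strand,
               tss = 940, tes = 2560, cds_start = 1000, cds_end = 2500)
  else
    data.frame(gene_id = "g1", chrom = chrom, strand = strand,
               tss = 2560, tes = 940, cds_start = 1000, cds_end = 2500)
}

flat_ratio <- function(value = 0.5, lo = 0, hi = 3000, by = 10, chrom = "chrI") {
  data.frame(chrom = chrom, position = seq(lo, hi, by = by), value = value,
             stringsAsFactors = FALSE)
}

full_calls <- function(lo = 0, hi = 3000) make_calls(lo, hi)

test_that("uniform signal gives a flat metagene profile at that value", {
  genes <- one_gene()
  ratio <- flat_ratio(0.7)
  tests <- data.frame(chrom = "chrI", start = seq(0, 2900, by = 150),
                      end = seq(147, 3047, by = 150),
                      significant = FALSE, direction = "BYac")
  prof <- metagene_profiles(genes, ratio, ratio, full_calls(), full_calls(), tests)
  expect_equal(prof$signal_by, rep(0.7, nrow(prof)))
  expect_equal(prof$signal_rm, rep(0.7, nrow(prof)))
  expect_equal(prof$snep_frac_by, rep(0, nrow(prof)))
})

test_that("per-bin means are recovered exactly for a hand-built gene", {
  genes <- one_gene()
  # value = floor(position / 150): piecewise-constant on the 150 bp CDS bins
  pos <- seq(0, 3000, by = 10)
  ratio <- data.frame(chrom = "chrI", position = pos, value = floor(pos / 150))
  prof <- metagene_profiles(genes, ratio, ratio, full_calls(), full_calls(),
                            snep_tests = data.frame(chrom = character(), start = numeric(),
                                                    end = numeric(), significant = logical(),
                                                    direction = character()),
                            flank_bp = 300, bin_bp = 100)
  # CDS bins are [1000,1150), [1150,1300), ...: constant values 1000/150 etc.
  cds_rows <- which(prof$label == "cds1"):which(prof$label == "cds10")
  manual <- vapply(seq_len(10), function(b) {
    lo <- 1000 + (b - 1) * 150; hi <- lo + 150
    mean(floor(pos[pos >= lo & pos < hi] / 150))
  }, numeric(1))
  expect_equal(prof$signal_by[cds_rows], manual)
})

test_that("SNEP fractions appear only in the bins where SNEPs were injected", {
  genes <- one_gene()
  ratio <- flat_ratio()
  # nucleosomes tile the region; only those upstream of the CDS are SNEPs
  starts <- seq(300, 2800, by = 160)
  tests <- data.frame(chrom = "chrI", start = starts, end = starts + 147,
                      significant = starts + 147 < 1000, direction = "BYac")
  prof <- metagene_profiles(genes, ratio, ratio, full_calls(), full_calls(), tests,
                            flank_bp = 300, bin_bp = 100)
  up_rows <- grepl("^up", prof$label)
  dn_rows <- grepl("^dn", prof$label)
  expect_true(all(prof$snep_frac_by[up_rows] > 0))
  expect_true(all(prof$snep_frac_by[dn_rows] == 0, na.rm = TRUE))
  expect_true(all(prof$snep_frac_rm == 0, na.rm = TRUE))
  expect_true(all(prof$snep_frac_by >= 0 & prof$snep_frac_by <= 1, na.rm = TRUE))
  # brute-force check of one upstream bin: bin [700, 800) overlaps nucleosomes
  ov <- starts < 800 & starts + 147 > 700
  expect_equal(prof$snep_frac_by[prof$label == "up3"],
               mean((starts + 147 < 1000)[ov]))
})

test_that("metagene binning is strand-equivariant", {
  pos <- seq(0, 3500, by = 10)
  ratio <- data.frame(chrom = "chrI", position = pos, value = pos / 1000)
  empty_tests <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                            significant = logical(), direction = character())
  pf <- metagene_profiles(one_gene("+"), ratio, ratio, full_calls(hi = 3500),
                          full_calls(hi = 3500), empty_tests,
                          flank_bp = 300, bin_bp = 100)
  pr <- metagene_profiles(one_gene("-"), ratio, ratio, full_calls(hi = 3500),
                          full_calls(hi = 3500), empty_tests,
                          flank_bp = 300, bin_bp = 100)
  # a monotone increasing track reads increasing on + and decreasing on -
  expect_true(all(diff(pf$signal_by) > 0))
  expect_true(all(diff(pr$signal_by) < 0))
})

test_that("TSS occupancy matrix has 60 strand-oriented bins", {
  genes <- rbind(one_gene("+"), one_gene("-"))
  genes$gene_id <- c("gp", "gm")
  post <- data.frame(chrom = "chrI", position = seq(0, 3000, by = 5), post_nuc = 1)
  mat <- tss_occupancy_matrix(genes, post)
  expect_equal(dim(mat), c(2L, 60L))
  expect_true(all(mat == 1))

  # an asymmetric dip upstream of the TSS lands in the same bins for both strands
  post2 <- post
  post2$post_nuc[post2$position >= 940 - 150 & post2$position < 940] <- 0  # + gene NDR
  post2$post_nuc[post2$position >= 2560 & post2$position < 2560 + 150] <- 0 # - gene NDR
  mat2 <- tss_occupancy_matrix(genes, post2)
  expect_equal(unname(mat2["gp", ]), unname(mat2["gm", ]))
  expect_true(all(mat2["gp", 16:30] == 0))
  expect_true(all(mat2["gp", 31:60] == 1))

  # genes whose window leaves the chromosome are excluded
  g_edge <- one_gene(); g_edge$tss <- 100
  expect_equal(nrow(tss_occupancy_matrix(g_edge, post)), 0L)
})

test_that("promoter clustering separates well-separated profile groups", {
  set.seed(13)
  a <- matrix(rnorm(20 * 60, 0, 0.1), 20, 60)
  b <- matrix(rnorm(20 * 60, 1, 0.1), 20, 60)
  mat <- rbind(a, b)
  rownames(mat) <- paste0("g", 1:40)
  cl <- cluster_promoters(mat, k = 2, seed = 3)
  truth <- rep(1:2, each = 20)
  # adjusted Rand index 1 <=> the two labelings are identical up to renaming
  tab <- table(cl$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), 40L)
  # determinism under the same seed
  cl2 <- cluster_promoters(mat, k = 2, seed = 3)
  expect_identical(cl$labels, cl2$labels)
  # diagnostic sweep covers K = 1..k_max
  expect_equal(cl$diagnostic$k, 1:10)
  expect_error(cluster_promoters(mat, k = 100), "more clusters")
})

test_that("promoter dissimilarity is 1 - Spearman with degenerate profiles flagged", {
  m1 <- matrix(rep(1:60, 3), 3, 60, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  m2 <- m1
  m2["b", ] <- rev(m2["b", ])        # perfectly anti-correlated
  m2["c", ] <- 5                     # constant: undefined
  d <- promoter_dissimilarity(m1, m2)$dissimilarity
  expect_equal(unname(d["a"]), 0)
  expect_equal(unname(d["b"]), 2)
  expect_true(is.na(d["c"]))

  # hand-built 5-bin example with one swapped pair: 1 - 0.9 = 0.1
  p1 <- matrix(1:5, 1, dimnames = list("g", NULL))
  p2 <- matrix(c(2, 1, 3, 4, 5), 1, dimnames = list("g", NULL))
  expect_equal(unname(promoter_dissimilarity(p1, p2)$dissimilarity), 0.1)
})

test_that("dissimilarity-expression association is reported when a table is given", {
  set.seed(4)
  m1 <- matrix(rnorm(600), 10, 60, dimnames = list(paste0("g", 1:10), NULL))
  m2 <- matrix(rnorm(600), 10, 60, dimnames = list(paste0("g", 1:10), NULL))
  expr <- data.frame(gene_id = paste0("g", 1:10), value = rnorm(10))
  out <- promoter_dissimilarity(m1, m2, expr)
  expect_true(is.numeric(out$rho_expression))
  expect_equal(out$n_genes_expression, 10L)
})
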