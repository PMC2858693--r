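# Gene-anchored profiles: metagene acetylation/SNEP profiles, TSS occupancy
# matrices, promoter clustering and cross-strain occupancy dissimilarity.
# All bin arithmetic is strand-oriented: minus-strand genes are flipped so
# bin 1 is always the most upstream.

#' Per-probe acetylation log-ratio track for one strain
#'
#' `log2(ac/nuc)` per probe: mean of the strain's ChIP replicates minus the
#' mean of its nucleosome-mapping replicates (both already log2).
#'
#' @param x normalized [intensity_matrix()].
#' @param probe_map probe map giving the BY coordinates of each probe.
#' @param strain `"BY"` or `"RM"`.
#' @return data.frame `chrom position value probe_id`.
#' @export
probe_log_ratio <- function(x, probe_map, strain) {
  chip <- build_probe_track(x, probe_map, strain, assay = "chip")
  nuc <- build_probe_track(x, probe_map, strain, assay = "nuc")
  stopifnot(identical(chip$probe_id, nuc$probe_id))
  data.frame(chrom = chip$chrom, position = chip$position,
             value = chip$signal - nuc$signal, probe_id = chip$probe_id,
             stringsAsFactors = FALSE)
}

# strand-oriented bin intervals for one gene: n_flank upstream 100-bp bins,
# n_cds equal coding-sequence bins, n_flank downstream bins
gene_bins <- function(gene, flank_bp, bin_bp, n_cds = 10) {
  n_flank <- floor(flank_bp / bin_bp)
  if (gene$strand == "+") {
    up <- seq(gene$cds_start - n_flank * bin_bp, gene$cds_start - bin_bp, by = bin_bp)
    up_iv <- cbind(up, up + bin_bp)
    cds_edges <- seq(gene$cds_start, gene$cds_end, length.out = n_cds + 1)
    cds_iv <- cbind(cds_edges[-(n_cds + 1)], cds_edges[-1])
    dn <- seq(gene$cds_end, gene$cds_end + (n_flank - 1) * bin_bp, by = bin_bp)
    dn_iv <- cbind(dn, dn + bin_bp)
    rbind(up_iv, cds_iv, dn_iv)
  } else {
    up <- seq(gene$cds_end + (n_flank - 1) * bin_bp, gene$cds_end, by = -bin_bp)
    up_iv <- cbind(up, up + bin_bp)
    cds_edges <- seq(gene$cds_end, gene$cds_start, length.out = n_cds + 1)
    cds_iv <- cbind(cds_edges[-1], cds_edges[-(n_cds + 1)])
    dn <- seq(gene$cds_start - bin_bp, gene$cds_start - n_flank * bin_bp, by = -bin_bp)
    dn_iv <- cbind(dn, dn + bin_bp)
    rbind(up_iv, cds_iv, dn_iv)
  }
}

#' Metagene acetylation and SNEP profiles
#'
#' Each gene contributes one value per bin: the mean `log2(ac/nuc)` of the
#' intra-nucleosomal probes whose midpoint falls in the bin (probes in
#' linkers do not contribute), and the fraction of SNEPs among the tested
#' nucleosomes overlapping the bin at least partially. Bins are `n_flank`
#' upstream 100-bp bins, 10 equal coding-sequence bins, and `n_flank`
#' downstream bins; per-bin values are averaged across genes. Genes with
#' fewer than `min_frac_bins` of their signal bins populated are excluded.
#'
#' @param genes gene models ([read_genes()]).
#' @param ratio_by,ratio_rm per-probe log-ratio tracks
#'   ([probe_log_ratio()]), BY coordinates.
#' @param calls_by,calls_rm nucleosome calls per strain (RM projected to BY
#'   coordinates); probes outside any call are treated as linker.
#' @param snep_tests `tests` data.frame from [snep_scan()] (needs `chrom`,
#'   `start`, `end`, `significant`, `direction`).
#' @param flank_bp flank length (default 500).
#' @param bin_bp flank bin width (default 100).
#' @param min_frac_bins minimum fraction of populated signal bins per gene.
#' @return data.frame with one row per bin: `bin label signal_by signal_rm
#'   snep_frac_by snep_frac_rm n_genes`.
#' @export
metagene_profiles <- function(genes, ratio_by, ratio_rm, calls_by, calls_rm,
                              snep_tests, flank_bp = 500, bin_bp = 100,
                              min_frac_bins = 0.5) {
  n_flank <- floor(flank_bp / bin_bp)
  n_bins <- 2 * n_flank + 10
  labels <- c(paste0("up", rev(seq_len(n_flank))), paste0("cds", 1:10),
              paste0("dn", seq_len(n_flank)))
  ratio_by <- mark_intranucleosomal(ratio_by, calls_by)
  ratio_rm <- mark_intranucleosomal(ratio_rm, calls_rm)

  sig_by <- matrix(NA_real_, nrow(genes), n_bins)
  sig_rm <- matrix(NA_real_, nrow(genes), n_bins)
  fr_by <- matrix(NA_real_, nrow(genes), n_bins)
  fr_rm <- matrix(NA_real_, nrow(genes), n_bins)

  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    iv <- gene_bins(gene, flank_bp, bin_bp)
    rb <- ratio_by[ratio_by$chrom == gene$chrom & ratio_by$in_nuc, , drop = FALSE]
    rr <- ratio_rm[ratio_rm$chrom == gene$chrom & ratio_rm$in_nuc, , drop = FALSE]
    st <- snep_tests[snep_tests$chrom == gene$chrom, , drop = FALSE]
    for (b in seq_len(n_bins)) {
      in_b <- rb$position >= iv[b, 1] & rb$position < iv[b, 2]
      if (any(in_b)) sig_by[g, b] <- mean(rb$value[in_b], na.rm = TRUE)
      in_r <- rr$position >= iv[b, 1] & rr$position < iv[b, 2]
      if (any(in_r)) sig_rm[g, b] <- mean(rr$value[in_r], na.rm = TRUE)
      ov <- st$end > iv[b, 1] & st$start < iv[b, 2]  # overlap at least partially
      if (any(ov)) {
        fr_by[g, b] <- mean(st$significant[ov] & st$direction[ov] == "BYac")
        fr_rm[g, b] <- mean(st$significant[ov] & st$direction[ov] == "RMac")
      }
    }
  }
  keep <- rowMeans(!is.na(sig_by)) >= min_frac_bins
  data.frame(
    bin = seq_len(n_bins), label = labels,
    signal_by = colMeans(sig_by[keep, , drop = FALSE], na.rm = TRUE),
    signal_rm = colMeans(sig_rm[keep, , drop = FALSE], na.rm = TRUE),
    snep_frac_by = colMeans(fr_by[keep, , drop = FALSE], na.rm = TRUE),
    snep_frac_rm = colMeans(fr_rm[keep, , drop = FALSE], na.rm = TRUE),
    n_genes = colSums(!is.na(sig_by[keep, , drop = FALSE])),
    stringsAsFactors = FALSE)
}

# flag probes whose midpoint lies inside a nucleosome call
mark_intranucleosomal <- function(ratio, calls) {
  ratio$in_nuc <- FALSE
  for (chr in unique(ratio$chrom)) {
    i <- which(ratio$chrom == chr)
    cc <- calls[calls$chrom == chr, , drop = FALSE]
    if (nrow(cc) == 0L) next
    ratio$in_nuc[i] <- overlaps_any(floor(ratio$position[i]), floor(ratio$position[i]) + 1L,
                                    cc$start, cc$end)
  }
  ratio
}

#' TSS-centered occupancy matrix
#'
#' For every gene, the +/- `half_window_bp` region around the TSS is divided
#' into `2 * half_window_bp / bin_bp` bins (strand-oriented, bin 1 most
#' upstream) and each bin receives the mean merged nucleosome posterior of
#' the probes whose midpoint falls in it. Genes whose window leaves the
#' chromosome are excluded.
#'
#' @param genes gene models.
#' @param post posterior track (`chrom position post_nuc`).
#' @param half_window_bp half-window around the TSS (default 300).
#' @param bin_bp bin width (default 10).
#' @return numeric matrix genes x bins with gene ids as rownames; bins with
#'   no probe are `NA`.
#' @export
tss_occupancy_matrix <- function(genes, post, half_window_bp = 300, bin_bp = 10) {
  n_bins <- as.integer(2 * half_window_bp / bin_bp)
  keep <- genes$tss - half_window_bp >= 0
  genes <- genes[keep, , drop = FALSE]
  mat <- matrix(NA_real_, nrow(genes), n_bins,
                dimnames = list(genes$gene_id, NULL))
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    pp <- post[post$chrom == gene$chrom, , drop = FALSE]
    if (gene$strand == "+") {
      edges <- seq(gene$tss - half_window_bp, gene$tss + half_window_bp, by = bin_bp)
      b <- findInterval(pp$position, edges, left.open = FALSE, rightmost.closed = FALSE)
      in_w <- b >= 1L & b <= n_bins & pp$position < edges[n_bins + 1L]
    } else {
      edges <- seq(gene$tss + half_window_bp, gene$tss - half_window_bp, by = -bin_bp)
      b <- findInterval(-pp$position, -edges, left.open = TRUE)
      in_w <- b >= 1L & b <= n_bins & pp$position > edges[n_bins + 1L]
    }
    if (!any(in_w)) next
    means <- tapply(pp$post_nuc[in_w], factor(b[in_w], levels = seq_len(n_bins)),
                    mean, na.rm = TRUE)
    mat[g, ] <- as.numeric(means)
  }
  mat
}

#' Cluster promoter occupancy profiles
#'
#' Best-of-`restarts` K-means (Euclidean distance) on the TSS occupancy
#' matrix; genes with any missing bin are excluded. A variance-ratio
#' diagnostic (between-cluster over within-cluster sum of squares) is
#' reported for K = 1..`k_max` to support the choice of K.
#'
#' @param mat matrix from [tss_occupancy_matrix()].
#' @param k number of clusters (default 6).
#' @param restarts K-means restarts (default 25).
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param k_max largest K for the diagnostic sweep (default 10).
#' @return list `labels` (named by gene), `centers` (k x bins),
#'   `diagnostic` (data.frame `k variance_ratio tot_withinss`), `excluded`.
#' @export
cluster_promoters <- function(mat, k = 6, restarts = 25, seed = 1, k_max = 10) {
  complete <- stats::complete.cases(mat)
  m <- mat[complete, , drop = FALSE]
  if (k > nrow(m)) stop("more clusters than genes with complete profiles", call. = FALSE)
  set.seed(seed)
  fit <- stats::kmeans(m, centers = k, nstart = restarts, iter.max = 100)
  diag_rows <- lapply(seq_len(min(k_max, nrow(m) - 1L)), function(kk) {
    f <- stats::kmeans(m, centers = kk, nstart = restarts, iter.max = 100)
    data.frame(k = kk,
               variance_ratio = if (f$tot.withinss > 0) f$betweenss / f$tot.withinss else Inf,
               tot_withinss = f$tot.withinss)
  })
  list(labels = stats::setNames(fit$cluster, rownames(m)),
       centers = fit$centers,
       diagnostic = do.call(rbind, diag_rows),
       excluded = rownames(mat)[!complete])
}

#' Cross-strain promoter occupancy dissimilarity
#'
#' Per gene, `1 - R` where R is the Spearman correlation between the BY and
#' RM occupancy profiles (range 0..2). Genes with a constant profile in
#' either strain are flagged `NA`. If an expression difference table is
#' supplied, the cross-gene Spearman correlation between dissimilarity and
#' `|expression difference|` is reported.
#'
#' @param mat_by,mat_rm occupancy matrices on the same genes and bin grid.
#' @param expression optional per-gene score table (`gene_id value`,
#'   e.g. log2 expression ratios).
#' @return list `dissimilarity` (named numeric) and, when expression is
#'   given, `rho_expression` (Spearman) and `n_genes_expression`.
#' @export
promoter_dissimilarity <- function(mat_by, mat_rm, expression = NULL) {
  shared <- intersect(rownames(mat_by), rownames(mat_rm))
  d <- vapply(shared, function(g) {
    a <- mat_by[g, ]; b <- mat_rm[g, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    1 - stats::cor(a[ok], b[ok], method = "spearman")
  }, numeric(1))
  out <- list(dissimilarity = d)
  if (!is.null(expression)) {
    e <- expression$value[match(names(d), expression$gene_id)]
    ok <- !is.na(d) & !is.na(e)
    out$rho_expression <- stats::cor(d[ok], abs(e[ok]), method = "spearman")
    out$n_genes_expression <- sum(ok)
  }
  out
}
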