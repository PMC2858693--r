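# Genome-wide SNEP distribution statistics. Throughout, "nucleosomes" means
# the tested aligned pairs (rows of the snep_scan() tests table); nucleosome
# to bin/region assignment is by midpoint except where a rule explicitly
# requires full coverage ("entirely") or partial overlap.

snep_flags <- function(tests, direction = NULL) {
  if (is.null(direction)) tests$significant
  else tests$significant & tests$direction == direction
}

#' Per-bin SNEP density along chromosomes
#'
#' Fraction of tested nucleosomes (assigned to bins by midpoint) that are
#' significant SNEPs, in fixed-width bins; bins containing no aligned
#' nucleosome are `NA` rather than 0, to keep unalignable regions distinct.
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param bin_bp bin width (default 1000).
#' @param direction optionally restrict to `"BYac"` or `"RMac"` SNEPs.
#' @return data.frame `chrom start end n_nucleosomes n_sneps fraction`.
#' @export
snep_density_map <- function(tests, bin_bp = 1000, direction = NULL) {
  is_snep <- snep_flags(tests, direction)
  mid <- interval_mid(tests$start, tests$end)
  res <- list()
  for (chr in unique(tests$chrom)) {
    i <- tests$chrom == chr
    lo <- 0
    hi <- ceiling(max(tests$end[i]) / bin_bp) * bin_bp
    starts <- seq(lo, hi - bin_bp, by = bin_bp)
    b <- findInterval(mid[i], c(starts, hi))
    n <- tabulate(b, nbins = length(starts))
    k <- tabulate(b[is_snep[i]], nbins = length(starts))
    res[[length(res) + 1L]] <- data.frame(
      chrom = chr, start = starts, end = starts + bin_bp,
      n_nucleosomes = n, n_sneps = k,
      fraction = ifelse(n > 0, k / n, NA_real_),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' SNEP enrichment in intervals upstream of anchor features
#'
#' For each anchor (e.g. the rDNA locus, or each Ty insertion), consecutive
#' `interval_bp` intervals are laid out on the anchor's upstream side and
#' the fraction of direction-matched SNEPs among tested nucleosomes
#' (midpoint assignment) is computed per interval; for multi-anchor sets the
#' per-interval fractions are averaged across anchors. The fold is the
#' first-interval fraction over the genome-wide fraction, with a chi-square
#' test (no continuity correction) on the pooled 2x2 table SNEP x
#' (first interval vs elsewhere).
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param anchors data.frame `chrom pos side` with `side` `"left"`
#'   (upstream = lower coordinates) or `"right"`.
#' @param interval_bp interval width (default 10000).
#' @param n_intervals number of upstream intervals (default 5).
#' @param direction SNEP direction to count (default `"BYac"`).
#' @return list `per_interval` (data.frame `interval fraction n_nucleosomes
#'   n_sneps`), `fold`, `chi2`, `p`, `genome_fraction`, `counts`.
#' @export
upstream_enrichment <- function(tests, anchors, interval_bp = 10000,
                                n_intervals = 5, direction = "BYac") {
  is_snep <- snep_flags(tests, direction)
  mid <- interval_mid(tests$start, tests$end)
  frac <- matrix(NA_real_, nrow(anchors), n_intervals)
  nn <- matrix(0L, nrow(anchors), n_intervals)
  kk <- matrix(0L, nrow(anchors), n_intervals)
  for (a in seq_len(nrow(anchors))) {
    on_chr <- tests$chrom == anchors$chrom[a]
    for (i in seq_len(n_intervals)) {
      if (anchors$side[a] == "left") {
        lo <- anchors$pos[a] - i * interval_bp; hi <- lo + interval_bp
      } else {
        lo <- anchors$pos[a] + (i - 1) * interval_bp; hi <- lo + interval_bp
      }
      sel <- on_chr & mid >= lo & mid < hi
      nn[a, i] <- sum(sel); kk[a, i] <- sum(sel & is_snep)
      if (nn[a, i] > 0) frac[a, i] <- kk[a, i] / nn[a, i]
    }
  }
  per_interval <- data.frame(
    interval = seq_len(n_intervals),
    fraction = colMeans(frac, na.rm = TRUE),
    n_nucleosomes = colSums(nn), n_sneps = colSums(kk))
  genome_fraction <- mean(is_snep)
  fold <- per_interval$fraction[1] / genome_fraction
  in_first <- colSums(nn)[1]; snep_first <- colSums(kk)[1]
  tab <- matrix(c(snep_first, in_first - snep_first,
                  sum(is_snep) - snep_first,
                  nrow(tests) - in_first - (sum(is_snep) - snep_first)), 2, 2)
  cs <- chisq_2x2(tab)
  list(per_interval = per_interval, fold = fold, chi2 = cs$chi2, p = cs$p,
       genome_fraction = genome_fraction, counts = tab)
}

#' Local correlation of SNEPs along the nucleosome sequence
#'
#' Nucleosomes are ordered by midpoint along each chromosome. For each SNEP
#' and each offset in `-radius..radius`, the neighbor at that offset is
#' checked for being a SNEP of the same direction; the fraction over all
#' interrogated positions is reported. The control repeats the computation
#' after randomly permuting the (significant, direction) labels over
#' nucleosomes, preserving counts, averaged over `n_perm` permutations.
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param radius number of neighbors on each side (default 10).
#' @param n_perm number of label permutations (default 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return data.frame `offset observed control n_interrogated`.
#' @export
local_correlation <- function(tests, radius = 10, n_perm = 100, seed) {
  set.seed(seed)
  ord <- order(tests$chrom, interval_mid(tests$start, tests$end))
  chrom <- tests$chrom[ord]
  lab <- ifelse(tests$significant, tests$direction, "none")[ord]
  n <- length(lab)
  offsets <- setdiff(seq(-radius, radius), 0L)

  same_dir_frac <- function(lab) {
    is_s <- lab != "none"
    centers <- which(is_s)
    obs <- numeric(length(offsets)); cnt <- integer(length(offsets))
    for (oi in seq_along(offsets)) {
      o <- offsets[oi]
      j <- centers + o
      ok <- j >= 1L & j <= n
      ok[ok] <- chrom[j[ok]] == chrom[centers[ok]]
      cnt[oi] <- sum(ok)
      obs[oi] <- if (cnt[oi] > 0) mean(lab[j[ok]] == lab[centers[ok]]) else NA_real_
    }
    list(frac = obs, n = cnt)
  }
  observed <- same_dir_frac(lab)
  perm <- matrix(NA_real_, n_perm, length(offsets))
  for (p in seq_len(n_perm)) perm[p, ] <- same_dir_frac(sample(lab))$frac
  data.frame(offset = offsets, observed = observed$frac,
             control = colMeans(perm, na.rm = TRUE),
             n_interrogated = observed$n)
}

#' SNEP enrichment at conserved regulatory and conserved non-coding DNA
#'
#' Tested nucleosomes are divided into three categories: (1) the call fully
#' covers at least one conserved regulatory site; (2) not (1) but the call
#' midpoint lies in conserved non-coding sequence; (3) neither. Per category
#' and direction, the SNEP fraction with a 95% Wilson interval, the fold
#' versus category 3, and a chi-square p-value (category vs 3) are
#' reported.
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param crs feature set of conserved regulatory sites
#'   ([read_feature_bed()] or a list with `$intervals`).
#' @param conserved_nc feature set of conserved non-coding intervals.
#' @return data.frame with one row per (category, direction).
#' @export
category_enrichment <- function(tests, crs, conserved_nc) {
  cat_ <- nucleosome_category(tests, crs$intervals, conserved_nc$intervals)
  rows <- list()
  for (dir in c("BYac", "RMac")) {
    is_snep <- snep_flags(tests, dir)
    f3 <- mean(is_snep[cat_ == 3L])
    for (k in 1:3) {
      n <- sum(cat_ == k); x <- sum(is_snep & cat_ == k)
      ci <- wilson_ci(x, n)
      p <- NA_real_; chi2 <- NA_real_
      if (k < 3L && n > 0) {
        tab <- matrix(c(x, n - x, sum(is_snep & cat_ == 3L),
                        sum(cat_ == 3L) - sum(is_snep & cat_ == 3L)), 2, 2)
        cs <- chisq_2x2(tab)
        p <- cs$p; chi2 <- cs$chi2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        category = k, direction = dir, n_nucleosomes = n, n_sneps = x,
        fraction = if (n > 0) x / n else NA_real_,
        ci_lower = ci[1], ci_upper = ci[2],
        fold = if (k < 3L && f3 > 0 && n > 0) (x / n) / f3 else if (k == 3L) 1 else NA_real_,
        chi2 = chi2, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 1 = fully covers a CRS; 2 = midpoint in conserved non-coding; 3 = neither
nucleosome_category <- function(tests, crs_iv, cnc_iv) {
  n <- nrow(tests)
  cat_ <- rep(3L, n)
  mid <- interval_mid(tests$start, tests$end)
  for (chr in unique(tests$chrom)) {
    i <- which(tests$chrom == chr)
    cv <- crs_iv[crs_iv$chrom == chr, , drop = FALSE]
    if (nrow(cv)) {
      covers <- vapply(i, function(t_)
        any(tests$start[t_] <= cv$start & tests$end[t_] >= cv$end), logical(1))
      cat_[i][covers] <- 1L
    }
    nc <- cnc_iv[cnc_iv$chrom == chr, , drop = FALSE]
    if (nrow(nc)) {
      in_nc <- overlaps_any(floor(mid[i]), floor(mid[i]) + 1L, nc$start, nc$end)
      cat_[i][cat_[i] != 1L & in_nc] <- 2L
    }
  }
  cat_
}

# per-gene thirds of the transcript, strand-oriented
gene_regions <- function(gene, boundaries = c(1 / 3, 2 / 3)) {
  lo <- min(gene$tss, gene$tes); hi <- max(gene$tss, gene$tes)
  cuts <- lo + c(0, boundaries, 1) * (hi - lo)
  iv <- cbind(cuts[-length(cuts)], cuts[-1])
  if (gene$strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  rownames(iv) <- c("beginning", "middle", "end")
  iv
}

#' Association between acetylation differences, SNEPs, and expression
#'
#' Two views per gene region (beginning / middle / end of the transcript):
#' (a) the Pearson correlation between the per-gene inter-strain acetylation
#' difference `log2(acBY/nucBY) - log2(acRM/nucRM)` (averaged over
#' intra-nucleosomal probes of the region) and the expression statistic;
#' (b) the per-gene fraction of SNEPs acetylated in the higher-expressed
#' strain among the region's tested nucleosomes, compared with a
#' permutation null obtained by shuffling the expression values across
#' genes.
#'
#' @param genes gene models.
#' @param ratio_by,ratio_rm intra-nucleosome-marked log-ratio tracks (from
#'   [probe_log_ratio()] after [snep_scan()]; probes in linkers are
#'   ignored -- pass tracks through `calls` via `mark_intranucleosomal`
#'   semantics by providing `calls_by`/`calls_rm`).
#' @param calls_by,calls_rm nucleosome calls (BY coordinates) defining
#'   intra-nucleosomal probes.
#' @param tests `tests` data.frame from [snep_scan()].
#' @param expression per-gene expression difference table (`gene_id value`,
#'   positive = higher in BY).
#' @param n_perm permutations for the null densities (default 100).
#' @param seed RNG seed.
#' @param boundaries region boundaries as fractions of the transcript
#'   (default thirds).
#' @return list with `correlations` (data.frame `region pearson n`),
#'   `snep_fraction` (per-gene observed fractions by region) and
#'   `snep_fraction_permuted` (pooled permutation values by region).
#' @export
expression_association <- function(genes, ratio_by, ratio_rm, calls_by, calls_rm,
                                   tests, expression, n_perm = 100, seed = 1,
                                   boundaries = c(1 / 3, 2 / 3)) {
  set.seed(seed)
  ratio_by <- mark_intranucleosomal(ratio_by, calls_by)
  ratio_rm <- mark_intranucleosomal(ratio_rm, calls_rm)
  expr <- expression$value[match(genes$gene_id, expression$gene_id)]
  keep <- !is.na(expr)
  genes <- genes[keep, , drop = FALSE]; expr <- expr[keep]
  n_g <- nrow(genes)
  region_names <- c("beginning", "middle", "end")

  delta <- matrix(NA_real_, n_g, 3, dimnames = list(genes$gene_id, region_names))
  frac_high <- function(expr_vec) {
    out <- matrix(NA_real_, n_g, 3, dimnames = list(genes$gene_id, region_names))
    for (g in seq_len(n_g)) {
      gene <- genes[g, ]
      iv <- gene_regions(gene, boundaries)
      st <- tests[tests$chrom == gene$chrom, , drop = FALSE]
      mid <- interval_mid(st$start, st$end)
      high_dir <- if (expr_vec[g] > 0) "BYac" else "RMac"
      for (r in 1:3) {
        sel <- mid >= min(iv[r, ]) & mid < max(iv[r, ])
        if (any(sel))
          out[g, r] <- mean(st$significant[sel] & st$direction[sel] == high_dir)
      }
    }
    out
  }
  for (g in seq_len(n_g)) {
    gene <- genes[g, ]
    iv <- gene_regions(gene, boundaries)
    rb <- ratio_by[ratio_by$chrom == gene$chrom & ratio_by$in_nuc, , drop = FALSE]
    rr <- ratio_rm[ratio_rm$chrom == gene$chrom & ratio_rm$in_nuc, , drop = FALSE]
    for (r in 1:3) {
      sb <- rb$position >= min(iv[r, ]) & rb$position < max(iv[r, ])
      sr <- rr$position >= min(iv[r, ]) & rr$position < max(iv[r, ])
      if (any(sb) && any(sr))
        delta[g, r] <- mean(rb$value[sb], na.rm = TRUE) - mean(rr$value[sr], na.rm = TRUE)
    }
  }
  correlations <- do.call(rbind, lapply(1:3, function(r) {
    ok <- !is.na(delta[, r])
    data.frame(region = region_names[r],
               pearson = if (sum(ok) > 2) stats::cor(delta[ok, r], expr[ok]) else NA_real_,
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  observed <- frac_high(expr)
  permuted <- vector("list", n_perm)
  for (p in seq_len(n_perm)) permuted[[p]] <- frac_high(sample(expr))
  perm_pooled <- do.call(rbind, permuted)
  list(correlations = correlations, delta = delta,
       snep_fraction = observed, snep_fraction_permuted = perm_pooled)
}

#' SNEP frequency along a gene ranking
#'
#' Per gene, the direction-specific SNEP frequency among tested nucleosomes
#' whose midpoint lies in the coding region extended by `flank_bp` on both
#' sides; genes are ranked by `scores` and the frequency is averaged in
#' sliding windows of `window_genes` genes.
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param genes gene models.
#' @param scores per-gene ranking table (`gene_id value`), e.g.
#'   transcriptional plasticity or expression divergence.
#' @param window_genes sliding-window size in genes (default 500; a single
#'   window if fewer genes).
#' @param flank_bp coding-region extension (default 250).
#' @param direction `"BYac"` or `"RMac"`.
#' @return data.frame `rank gene_id score freq windowed` ordered by rank.
#' @export
ranked_gene_enrichment <- function(tests, genes, scores, window_genes = 500,
                                   flank_bp = 250, direction = "BYac") {
  sc <- scores$value[match(genes$gene_id, scores$gene_id)]
  keep <- !is.na(sc)
  genes <- genes[keep, , drop = FALSE]; sc <- sc[keep]
  is_snep <- snep_flags(tests, direction)
  mid <- interval_mid(tests$start, tests$end)
  freq <- vapply(seq_len(nrow(genes)), function(g) {
    gene <- genes[g, ]
    sel <- tests$chrom == gene$chrom &
      mid >= gene$cds_start - flank_bp & mid < gene$cds_end + flank_bp
    if (!any(sel)) return(NA_real_)
    mean(is_snep[sel])
  }, numeric(1))
  ord <- order(sc)
  out <- data.frame(rank = seq_along(ord), gene_id = genes$gene_id[ord],
                    score = sc[ord], freq = freq[ord], stringsAsFactors = FALSE)
  w <- min(window_genes, nrow(out))
  half <- floor(w / 2)
  out$windowed <- vapply(seq_len(nrow(out)), function(i) {
    lo <- max(1L, i - half); hi <- min(nrow(out), lo + w - 1L); lo <- max(1L, hi - w + 1L)
    mean(out$freq[lo:hi], na.rm = TRUE)
  }, numeric(1))
  out
}

#' SNEP enrichment among remodeled nucleosomes
#'
#' A tested nucleosome is remodeled iff its BY call lies entirely within a
#' remodeled region; the 2x2 chi-square (SNEP x remodeled) and the fold
#' (SNEP rate among remodeled over the rate among unperturbed) are
#' reported.
#'
#' @param tests `tests` data.frame from [snep_scan()].
#' @param remodeled feature set of remodeled regions.
#' @param direction optionally restrict the SNEP definition to a direction.
#' @return list `fold`, `chi2`, `p`, `counts`, `n_remodeled`,
#'   `remodeled_fraction`.
#' @export
remodeled_enrichment <- function(tests, remodeled, direction = NULL) {
  is_snep <- snep_flags(tests, direction)
  iv <- remodeled$intervals
  rem <- rep(FALSE, nrow(tests))
  for (chr in unique(tests$chrom)) {
    i <- which(tests$chrom == chr)
    rv <- iv[iv$chrom == chr, , drop = FALSE]
    if (nrow(rv) == 0L) next
    rem[i] <- vapply(i, function(t_)
      any(tests$start[t_] >= rv$start & tests$end[t_] <= rv$end), logical(1))
  }
  n_rem <- sum(rem)
  tab <- matrix(c(sum(is_snep & rem), sum(!is_snep & rem),
                  sum(is_snep & !rem), sum(!is_snep & !rem)), 2, 2)
  rate_rem <- if (n_rem > 0) sum(is_snep & rem) / n_rem else NA_real_
  rate_un <- sum(is_snep & !rem) / sum(!rem)
  cs <- if (n_rem > 0) chisq_2x2(tab) else list(chi2 = NA_real_, p = NA_real_)
  list(fold = if (n_rem > 0) rate_rem / rate_un else NA_real_,
       chi2 = cs$chi2, p = cs$p, counts = tab, n_remodeled = n_rem,
       remodeled_fraction = n_rem / nrow(tests))
}
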