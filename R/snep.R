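# SNEP detection: per aligned nucleosome pair, a two-way ANOVA with probe
# effects tests the strain x experiment-type interaction; Benjamini-Hochberg
# step-up controls the FDR over all tested pairs.

#' Assemble the observation table for one nucleosome pair
#'
#' Collects, in long format, the normalized log2 intensities of every
#' dual-match probe whose footprint is entirely covered by both the BY and
#' the RM call of the pair, across all arrays. Pairs sharing fewer than
#' `min_shared` probes are skipped (returns `NULL`).
#'
#' @param pair one row of the [align_maps()] output (status `"aligned"`).
#' @param x normalized [intensity_matrix()].
#' @param probe_map BY probe map restricted to the dual-match probe set.
#' @param min_shared minimum number of shared probes (default 15).
#' @return data.frame `probe array strain type replicate y`, or `NULL`.
#' @export
assemble_pair_data <- function(pair, x, probe_map, min_shared = 15) {
  pm <- probe_map[probe_map$chrom == pair$chrom, , drop = FALSE]
  inside <- pm$start >= pair$by_start & (pm$start + pm$length) <= pair$by_end &
    pm$start >= pair$rm_start & (pm$start + pm$length) <= pair$rm_end
  ids <- pm$probe_id[inside]
  ids <- intersect(ids, rownames(x$values))
  if (length(ids) < min_shared) return(NULL)
  v <- x$values[ids, , drop = FALSE]
  man <- x$manifest
  obs <- data.frame(
    probe = rep(ids, times = ncol(v)),
    array = rep(colnames(v), each = nrow(v)),
    strain = rep(man$strain, each = nrow(v)),
    type = rep(man$assay, each = nrow(v)),
    replicate = rep(man$replicate, each = nrow(v)),
    y = as.vector(v),
    stringsAsFactors = FALSE)
  obs <- obs[!is.na(obs$y), , drop = FALSE]
  attr(obs, "shared_probes") <- length(ids)
  obs
}

#' Fit the strain x experiment-type interaction ANOVA
#'
#' Ordinary least squares of
#' `y = u + strain + type + probe + strain:type + e`; the interaction is
#' tested by model comparison against the additive model with an F statistic
#' on 1 numerator degree of freedom (2 strains x 2 types). Probes observed
#' in only one (strain, type) cell are dropped before fitting. The reported
#' interaction contrast is computed from cell means over the shared probes:
#' `delta = [mean(chip,BY) - mean(nuc,BY)] - [mean(chip,RM) - mean(nuc,RM)]`,
#' positive when BY is the more acetylated strain.
#'
#' @param obs observation table from [assemble_pair_data()].
#' @param p_floor lower cap on the p-value (default 1e-300).
#' @return list `F, p, df_num, df_den, delta, n_obs, n_probes`, or `NULL`
#'   if the design collapses (fewer than two strains or types after drops).
#' @export
fit_interaction <- function(obs, p_floor = 1e-300) {
  # drop probes observed in a single (strain, type) cell
  cell <- paste(obs$strain, obs$type)
  tab <- table(obs$probe, cell)
  bad <- rownames(tab)[rowSums(tab > 0) < 2L]
  if (length(bad)) obs <- obs[!(obs$probe %in% bad), , drop = FALSE]
  if (nrow(obs) == 0L) return(NULL)
  strain <- factor(obs$strain); type <- factor(obs$type); probe <- factor(obs$probe)
  if (nlevels(strain) < 2L || nlevels(type) < 2L) return(NULL)

  X1 <- stats::model.matrix(~ probe + strain * type)
  X0 <- stats::model.matrix(~ probe + strain + type)
  f1 <- stats::lm.fit(X1, obs$y)
  f0 <- stats::lm.fit(X0, obs$y)
  rss1 <- sum(f1$residuals^2)
  rss0 <- sum(f0$residuals^2)
  df_num <- f1$rank - f0$rank
  df_den <- length(obs$y) - f1$rank
  if (df_num < 1L || df_den < 1L) return(NULL)

  eps <- 1e-12 * max(1, sum(obs$y^2))
  if (rss1 <= eps) {
    if (rss0 - rss1 <= eps) { Fstat <- 0; p <- 1 } else { Fstat <- Inf; p <- p_floor }
  } else {
    Fstat <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
    p <- max(stats::pf(Fstat, df_num, df_den, lower.tail = FALSE), p_floor)
  }

  cm <- tapply(obs$y, list(strain, type), mean)
  delta <- (cm["BY", "chip"] - cm["BY", "nuc"]) - (cm["RM", "chip"] - cm["RM", "nuc"])
  list(F = Fstat, p = p, df_num = df_num, df_den = df_den, delta = unname(delta),
       n_obs = nrow(obs), n_probes = nlevels(probe))
}

#' Call SNEPs under Benjamini-Hochberg FDR control
#'
#' Step-up over the full p-value vector; the implied genome-wide nominal
#' cutoff `k * alpha / m` (k = number of rejections, m = number of tests) is
#' reported alongside. Direction comes from the sign of the cell-mean
#' interaction contrast (`delta > 0` = BYac) and the fold-change is
#' `2^|delta|`.
#'
#' @param fits data.frame with one row per tested pair: columns `pair_id`,
#'   `p`, `delta` plus any annotation columns to carry through.
#' @param alpha_fdr FDR level (default 0.0001).
#' @return list with `tests` (the input plus `q`, `direction`,
#'   `fold_change`, `significant`), `m`, `k`, `cutoff`, `alpha_fdr`.
#' @export
call_sneps <- function(fits, alpha_fdr = 1e-4) {
  if (nrow(fits) == 0L) stop("empty p-value vector: no tested pairs", call. = FALSE)
  fits$q <- stats::p.adjust(fits$p, method = "BH")
  fits$significant <- fits$q <= alpha_fdr
  fits$direction <- ifelse(fits$delta > 0, "BYac", "RMac")
  fits$fold_change <- 2^abs(fits$delta)
  m <- nrow(fits); k <- sum(fits$significant)
  list(tests = fits, m = m, k = k,
       cutoff = k * alpha_fdr / m, alpha_fdr = alpha_fdr)
}

#' Scan all aligned pairs for SNEPs
#'
#' Assembles the observation table of every aligned pair, fits the
#' interaction ANOVA, and applies BH control over the resulting p-values.
#'
#' @param pairs output of [align_maps()].
#' @param x normalized [intensity_matrix()].
#' @param probe_map BY probe map restricted to dual-match probes.
#' @param min_shared minimum shared probes per pair (default 15).
#' @param alpha_fdr FDR level (default 0.0001).
#' @return result of [call_sneps()]; `tests` carries `chrom`, `start`,
#'   `end` (BY call coordinates) and `shared_probes`; skipped pairs are
#'   listed in `$skipped` with a reason.
#' @export
snep_scan <- function(pairs, x, probe_map, min_shared = 15, alpha_fdr = 1e-4) {
  al <- pairs[pairs$status == "aligned", , drop = FALSE]
  rows <- vector("list", nrow(al))
  skipped <- list()
  for (i in seq_len(nrow(al))) {
    pr <- al[i, ]
    obs <- assemble_pair_data(pr, x, probe_map, min_shared = min_shared)
    if (is.null(obs)) {
      skipped[[length(skipped) + 1L]] <- data.frame(pair_id = pr$pair_id,
                                                    reason = "fewer shared probes than minimum")
      next
    }
    fit <- fit_interaction(obs)
    if (is.null(fit)) {
      skipped[[length(skipped) + 1L]] <- data.frame(pair_id = pr$pair_id,
                                                    reason = "degenerate design")
      next
    }
    rows[[i]] <- data.frame(pair_id = pr$pair_id, chrom = pr$chrom,
                            start = pr$by_start, end = pr$by_end,
                            F = fit$F, p = fit$p, delta = fit$delta,
                            shared_probes = attr(obs, "shared_probes"),
                            n_obs = fit$n_obs, stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- call_sneps(fits, alpha_fdr = alpha_fdr)
  out$skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Monte-Carlo calibration of the SNEP interaction test
#'
#' Simulates nucleosome pairs under the model's own assumptions (per-probe
#' effects, replicate Gaussian noise) with and without an injected
#' interaction of size `log2(fold)`, and reports rejection rates at the
#' given nominal level.
#'
#' @param fold acetylation fold-difference under the alternative (1 = null).
#' @param noise_sd replicate noise sd in log2 units.
#' @param n_probes probes per pair.
#' @param n_nuc_rep,n_chip_rep replicates per strain and assay.
#' @param n_sim simulated pairs per hypothesis.
#' @param level nominal p-value threshold.
#' @param seed RNG seed.
#' @return list `type_I`, `power`, `p_null`, `p_alt` (the p-value vectors).
#' @export
snep_power_sim <- function(fold = 1.5, noise_sd = 0.25, n_probes = 20,
                           n_nuc_rep = 3, n_chip_rep = 6, n_sim = 1000,
                           level = 0.05, seed = 1) {
  set.seed(seed)
  man <- rbind(
    expand.grid(strain = c("BY", "RM"), type = "nuc", rep = seq_len(n_nuc_rep),
                stringsAsFactors = FALSE),
    expand.grid(strain = c("BY", "RM"), type = "chip", rep = seq_len(n_chip_rep),
                stringsAsFactors = FALSE))
  n_arr <- nrow(man)
  probe <- factor(rep(seq_len(n_probes), times = n_arr))
  strain <- factor(rep(man$strain, each = n_probes))
  type <- factor(rep(man$type, each = n_probes))
  X1 <- stats::model.matrix(~ probe + strain * type)
  X0 <- stats::model.matrix(~ probe + strain + type)
  df_num <- ncol(X1) - ncol(X0)
  df_den <- length(probe) - ncol(X1)
  delta <- log2(fold)
  # interaction applied to the BY chip cell only; probe effects resampled
  shift_alt <- ifelse(strain == "BY" & type == "chip", delta, 0)
  ac_base <- ifelse(type == "chip", 0.5, 0)

  sim_p <- function(shift) {
    vapply(seq_len(n_sim), function(s) {
      pe <- stats::rnorm(n_probes, 0, 0.5)[as.integer(probe)]
      y <- pe + ac_base + shift + stats::rnorm(length(probe), 0, noise_sd)
      r1 <- stats::lm.fit(X1, y)$residuals
      r0 <- stats::lm.fit(X0, y)$residuals
      rss1 <- sum(r1^2); rss0 <- sum(r0^2)
      Fs <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
      stats::pf(Fs, df_num, df_den, lower.tail = FALSE)
    }, numeric(1))
  }
  p_null <- sim_p(rep(0, length(probe)))
  p_alt <- if (fold == 1) p_null else sim_p(shift_alt)
  list(type_I = mean(p_null < level), power = mean(p_alt < level),
       p_null = p_null, p_alt = p_alt)
}
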