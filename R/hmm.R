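# Nucleosome calling: sliding-window EM fits of a duration-structured
# 3-state HMM (linker / well-positioned / delocalized), probe-wise averaging
# of window parameters and posteriors, then one global decode per
# chromosome segment.

#' Build a probe-level signal track for one strain and assay
#'
#' Averages normalized log2 intensities across the replicates of the given
#' strain/assay and attaches genomic probe midpoints. Probes absent from the
#' probe map (or restricted away upstream) are dropped; probes missing on
#' every replicate are kept as missing so the HMM can marginalize them.
#'
#' @param x an [intensity_matrix()], already normalized.
#' @param probe_map probe map of the strain ([read_probe_map()]).
#' @param strain `"BY"` or `"RM"`.
#' @param assay assay whose replicates are averaged (default `"nuc"`).
#' @return data.frame `chrom, position, signal, probe_id` sorted by
#'   chromosome and midpoint position.
#' @export
build_probe_track <- function(x, probe_map, strain, assay = "nuc") {
  stopifnot(inherits(x, "intensity_matrix"))
  cols <- x$manifest$strain == strain & x$manifest$assay == assay
  if (!any(cols)) stop(sprintf("no %s/%s arrays in manifest", strain, assay), call. = FALSE)
  sig <- rowMeans(x$values[, cols, drop = FALSE], na.rm = TRUE)
  sig[is.nan(sig)] <- NA_real_
  pm <- probe_map[match(rownames(x$values), probe_map$probe_id), , drop = FALSE]
  keep <- !is.na(pm$chrom)
  out <- data.frame(chrom = pm$chrom[keep],
                    position = pm$start[keep] + pm$length[keep] / 2,
                    signal = sig[keep],
                    probe_id = pm$probe_id[keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$position), , drop = FALSE]
}

#' Default HMM configuration for a probe spacing
#'
#' Duration encodings follow the nucleosome geometry: the well-positioned
#' state lasts `round(147 / spacing)` probes, the delocalized state at least
#' `round(100 / spacing)` probes with a geometric continuation tuned so its
#' mean length is about 160 bp.
#'
#' @param spacing median probe spacing in bp.
#' @param window_bp sliding-window length (default 1000).
#' @param step_bp window step (default `window_bp / 2`).
#' @param min_probes minimum informative probes to fit a window (default 30).
#' @param max_gap_bp probe gaps longer than this split chromosomes into
#'   independent decoding segments (default 500).
#' @param min_len_bp minimum call length (default 100).
#' @param probe_len probe footprint length in bp (default 25).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list of configuration values.
#' @export
hmm_config <- function(spacing, window_bp = 1000, step_bp = window_bp / 2,
                       min_probes = 30, max_gap_bp = 500, min_len_bp = 100,
                       probe_len = 25, max_iter = 50, tol = 1e-4) {
  d_w <- max(2L, as.integer(round(147 / spacing)))
  d_d <- max(1L, as.integer(round(100 / spacing)))
  extra <- max((160 - 100) / spacing, 1e-3)  # geometric tail, mean D length ~160 bp
  p_cont <- extra / (1 + extra)
  list(spacing = spacing, window_bp = window_bp, step_bp = step_bp,
       min_probes = min_probes, max_gap_bp = max_gap_bp, min_len_bp = min_len_bp,
       probe_len = probe_len, d_w = d_w, d_d = d_d, p_cont = p_cont,
       max_iter = max_iter, tol = tol, sd_floor = 0.01)
}

# deterministic, scale-adaptive initialization for one window
init_window_model <- function(signal, global_sd, p_cont, jitter_sd = 0) {
  q <- stats::quantile(signal, c(0.25, 0.60, 0.90), na.rm = TRUE, names = FALSE)
  mu <- c(q[1], q[3], q[2])            # L, W, D
  if (jitter_sd > 0) mu <- mu + stats::rnorm(3, 0, jitter_sd)
  list(mu = mu, sd = rep(max(global_sd, 0.05), 3),
       trans = c(0.80, 0.15, 0.05, p_cont))
}

#' Fit the HMM on one window by EM
#'
#' Baum-Welch on the duration-expanded state chain; missing probes
#' contribute emission likelihood 1. Convergence when the log-likelihood
#' changes by less than `cfg$tol` (or after `cfg$max_iter` iterations).
#'
#' @param signal numeric vector of probe signals (NA = missing).
#' @param cfg an [hmm_config()].
#' @param init initialization as returned by the internal percentile rule;
#'   computed from the window when `NULL`.
#' @param global_sd robust global noise scale used for initialization.
#' @param jitter_sd optional sd of Gaussian jitter on the initial means.
#' @return list with elements `mu` (L,W,D), `sd`, `trans`
#'   (`pLL,pLW,pLD,p_cont`), `gamma` (probes x 3 macro-state posteriors),
#'   `loglik`, `niter`, `converged`; or `NULL` if the window has fewer than
#'   `cfg$min_probes` informative probes.
#' @export
fit_window <- function(signal, cfg, init = NULL, global_sd = NULL, jitter_sd = 0) {
  obs <- !is.na(signal)
  if (sum(obs) < cfg$min_probes) return(NULL)
  if (is.null(global_sd)) global_sd <- stats::mad(signal, na.rm = TRUE)
  if (is.null(init)) init <- init_window_model(signal, global_sd, cfg$p_cont, jitter_sd)
  x <- signal
  x[!obs] <- 0  # value ignored when flagged missing
  hmm_em_window_cpp(x, !obs, cfg$d_w, cfg$d_d, init$mu, init$sd, init$trans,
                    cfg$max_iter, cfg$tol, cfg$sd_floor)
}

#' Average window models probe-wise
#'
#' Each probe receives the arithmetic mean of every emission and transition
#' parameter and of every macro-state posterior over all successfully fitted
#' windows covering it; posteriors are renormalized to sum to one. Probes
#' covered by no window are marked undecodable.
#'
#' @param window_fits list of [fit_window()] results (NULL allowed for
#'   skipped windows).
#' @param window_idx list of integer probe-index vectors, parallel to
#'   `window_fits`.
#' @param n_probes number of probes in the segment.
#' @return list with matrices `mu`, `sd` (n x 3), `trans` (n x 4), `gamma`
#'   (n x 3) and logical `decodable`.
#' @export
average_models <- function(window_fits, window_idx, n_probes) {
  mu <- matrix(0, n_probes, 3); sd_ <- matrix(0, n_probes, 3)
  trans <- matrix(0, n_probes, 4); gamma <- matrix(0, n_probes, 3)
  cover <- integer(n_probes)
  for (k in seq_along(window_fits)) {
    fit <- window_fits[[k]]
    if (is.null(fit)) next
    i <- window_idx[[k]]
    mu[i, ] <- mu[i, ] + rep(fit$mu, each = length(i))
    sd_[i, ] <- sd_[i, ] + rep(fit$sd, each = length(i))
    trans[i, ] <- trans[i, ] + rep(fit$trans, each = length(i))
    gamma[i, ] <- gamma[i, ] + fit$gamma
    cover[i] <- cover[i] + 1L
  }
  dec <- cover > 0L
  for (j in 1:3) { mu[dec, j] <- mu[dec, j] / cover[dec]; sd_[dec, j] <- sd_[dec, j] / cover[dec] }
  for (j in 1:4) trans[dec, j] <- trans[dec, j] / cover[dec]
  gsum <- rowSums(gamma)
  ok <- dec & !is.na(gsum) & gsum > 0
  gamma[ok, ] <- gamma[ok, ] / gsum[ok]
  list(mu = mu, sd = sd_, trans = trans, gamma = gamma, decodable = dec)
}

#' Globally decode a segment with position-specific parameters
#'
#' One Viterbi pass (ties broken toward the linker state) and one
#' forward-backward pass using the probe-wise averaged emission and
#' transition parameters.
#'
#' @param signal numeric probe signal of the segment (NA = missing).
#' @param averaged output of [average_models()].
#' @param cfg an [hmm_config()].
#' @return list `path` (0 = linker, 1 = well-positioned, 2 = delocalized,
#'   NA = undecodable) and `gamma` (probes x 3 posterior matrix, rows sum
#'   to 1 on decodable probes).
#' @export
decode_global <- function(signal, averaged, cfg) {
  n <- length(signal)
  path <- rep(NA_integer_, n)
  gamma <- matrix(NA_real_, n, 3)
  dec <- averaged$decodable
  if (!any(dec)) return(list(path = path, gamma = gamma))
  runs <- split(which(dec), cumsum(c(1L, diff(which(dec)) != 1L)))
  for (idx in runs) {
    x <- signal[idx]
    miss <- is.na(x)
    x[miss] <- 0
    mu <- averaged$mu[idx, , drop = FALSE]
    sd_ <- averaged$sd[idx, , drop = FALSE]
    tr <- averaged$trans[idx, , drop = FALSE]
    path[idx] <- hmm_viterbi_cpp(x, miss, cfg$d_w, cfg$d_d, mu, sd_, tr)
    post <- hmm_posterior_cpp(x, miss, cfg$d_w, cfg$d_d, mu, sd_, tr)
    gamma[idx, ] <- post$gamma
  }
  list(path = path, gamma = gamma)
}

#' Convert a decoded state path into nucleosome calls
#'
#' Maximal runs of the well-positioned state become well-positioned calls,
#' maximal runs of the delocalized state delocalized calls. Call boundaries
#' run from the first probe's footprint start to the last probe's footprint
#' end; calls shorter than `min_len_bp` are dropped. The call posterior is
#' the mean merged nucleosome posterior (W + D) over the run.
#'
#' @param path integer macro-state path from [decode_global()].
#' @param gamma posterior matrix from [decode_global()].
#' @param positions probe midpoints (bp).
#' @param cfg an [hmm_config()].
#' @param strain,chrom labels attached to the calls.
#' @return data.frame of calls
#'   (`strain chrom start end category posterior n_probes`).
#' @export
calls_from_path <- function(path, gamma, positions, cfg, strain = NA, chrom = NA) {
  empty <- data.frame(strain = character(), chrom = character(),
                      start = numeric(), end = numeric(), category = character(),
                      posterior = numeric(), n_probes = integer(),
                      stringsAsFactors = FALSE)
  nucp <- !is.na(path) & path > 0L
  if (!any(nucp)) return(empty)
  r <- rle(ifelse(is.na(path), -1L, path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  if (!any(keep)) return(empty)
  half <- cfg$probe_len / 2
  call_start <- floor(positions[starts[keep]] - half)
  out <- data.frame(
    strain = strain, chrom = chrom,
    start = call_start,
    end = call_start + (positions[ends[keep]] - positions[starts[keep]]) + cfg$probe_len,
    category = ifelse(r$values[keep] == 1L, "well-positioned", "delocalized"),
    n_probes = r$lengths[keep],
    stringsAsFactors = FALSE
  )
  out$posterior <- vapply(which(keep), function(k) {
    i <- starts[k]:ends[k]
    mean(rowSums(gamma[i, 2:3, drop = FALSE]), na.rm = TRUE)
  }, numeric(1))
  out <- out[out$end - out$start >= cfg$min_len_bp, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("strain", "chrom", "start", "end", "category", "posterior", "n_probes")]
}

#' Call nucleosomes on a probe track
#'
#' Runs the full sliding-window procedure per chromosome: split at probe
#' gaps longer than `cfg$max_gap_bp`, fit the HMM by EM in overlapping
#' windows, average parameters and posteriors probe-wise, decode globally,
#' and extract calls.
#'
#' @param track probe track from [build_probe_track()].
#' @param cfg an [hmm_config()]; defaults to the track's median probe
#'   spacing.
#' @param strain strain label for the calls.
#' @param seed optional seed controlling EM initialization jitter.
#' @param jitter_sd sd of the initialization jitter (0 = fully
#'   deterministic initialization).
#' @return list with `calls` (data.frame of nucleosome calls) and
#'   `posteriors` (data.frame `chrom position signal path post_l post_w
#'   post_d post_nuc` per probe; `post_nuc` is the merged W+D posterior).
#' @export
call_nucleosomes <- function(track, cfg = NULL, strain = NA_character_,
                             seed = NULL, jitter_sd = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cfg)) {
    spacing <- stats::median(diff(sort(track$position[track$chrom == track$chrom[1]])))
    cfg <- hmm_config(spacing)
  }
  all_calls <- list(); all_post <- list()
  for (chr in unique(track$chrom)) {
    tr <- track[track$chrom == chr, , drop = FALSE]
    tr <- tr[order(tr$position), , drop = FALSE]
    seg_id <- cumsum(c(1, diff(tr$position) > cfg$max_gap_bp))
    for (sid in unique(seg_id)) {
      seg <- tr[seg_id == sid, , drop = FALSE]
      if (nrow(seg) < cfg$min_probes) next
      res <- decode_segment(seg$signal, seg$position, cfg, jitter_sd)
      calls <- calls_from_path(res$path, res$gamma, seg$position, cfg,
                               strain = strain, chrom = chr)
      all_calls[[length(all_calls) + 1L]] <- calls
      all_post[[length(all_post) + 1L]] <- data.frame(
        chrom = chr, position = seg$position, signal = seg$signal,
        path = res$path,
        post_l = res$gamma[, 1], post_w = res$gamma[, 2], post_d = res$gamma[, 3],
        post_nuc = res$gamma[, 2] + res$gamma[, 3],
        stringsAsFactors = FALSE)
    }
  }
  list(calls = if (length(all_calls)) do.call(rbind, all_calls) else
         calls_from_path(integer(), matrix(numeric(), 0, 3), numeric(), cfg),
       posteriors = if (length(all_post)) do.call(rbind, all_post) else NULL)
}

# sliding-window fit + averaging + global decode for one gap-free segment
decode_segment <- function(signal, positions, cfg, jitter_sd = 0) {
  n <- length(signal)
  global_sd <- stats::mad(signal, na.rm = TRUE)
  w_starts <- seq(positions[1], max(positions[1], positions[n] - cfg$step_bp),
                  by = cfg$step_bp)
  fits <- list(); idxs <- list()
  for (w in w_starts) {
    i <- which(positions >= w & positions < w + cfg$window_bp)
    if (length(i) == 0L) next
    fit <- fit_window(signal[i], cfg, global_sd = global_sd, jitter_sd = jitter_sd)
    fits[[length(fits) + 1L]] <- fit
    idxs[[length(idxs) + 1L]] <- i
  }
  avg <- average_models(fits, idxs, n)
  decode_global(signal, avg, cfg)
}
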