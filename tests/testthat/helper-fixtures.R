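# Shared fixture builders. Everything is generated in code; coordinates are
# 0-based half-open as in the package internals.

# identity alignment: one block covering [0, len) on a single chromosome
identity_blocks <- function(len = 10000, chrom = "chrI", contig = chrom) {
  data.frame(ref_chrom = chrom, ref_start = 0L, ref_end = len,
             qry_contig = contig, qry_start = 0L, qry_end = len,
             orientation = "+", stringsAsFactors = FALSE)
}

make_probes <- function(starts, chrom = "chrI", n_matches = 1L, len = 25L,
                        ids = sprintf("p%04d", seq_along(starts))) {
  data.frame(probe_id = ids, chrom = chrom, start = starts, strand = "+",
             length = len, n_matches = n_matches, stringsAsFactors = FALSE)
}

make_calls <- function(starts, ends, chrom = "chrI", strain = "BY",
                       category = "well-positioned", posterior = 1) {
  data.frame(strain = strain, chrom = chrom, start = starts, end = ends,
             category = category, posterior = posterior,
             n_probes = pmax(1L, floor((ends - starts) / 5)),
             stringsAsFactors = FALSE)
}

# minimal manifest: n_nuc + n_chip replicates per strain
make_manifest <- function(n_nuc = 3, n_chip = 6) {
  man <- rbind(
    expand.grid(strain = c("BY", "RM"), assay = "nuc", replicate = seq_len(n_nuc),
                stringsAsFactors = FALSE),
    expand.grid(strain = c("BY", "RM"), assay = "chip", replicate = seq_len(n_chip),
                stringsAsFactors = FALSE))
  man$array_id <- sprintf("%s_%s_%d", man$strain, man$assay, man$replicate)
  man[, c("array_id", "strain", "assay", "replicate")]
}

# brute-force maximum-cardinality minimum-cost one-to-one matching cost,
# enumerating every assignment (crossings allowed): the oracle for align_maps
brute_force_match_cost <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) return(0)
  if (m < n) { tmp <- a; a <- b; b <- tmp; m <- length(a); n <- length(b) }
  best <- Inf
  subsets <- utils::combn(m, n, simplify = FALSE)
  perms <- all_perms(n)
  for (s in subsets) {
    for (p in perms) {
      cost <- sum(abs(a[s[p]] - b))
      if (cost < best) best <- cost
    }
  }
  best
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# step-up FDR oracle, straight from the definition
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) k <- i
  rejected <- rep(FALSE, m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}
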