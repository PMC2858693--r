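# Liftover through alignment blocks, anchor-and-recurse nucleosome map
# alignment, conservation summaries, occupancy difference windows.

test_that("liftover maps calls by block offset, both orientations", {
  # identity block
  blocks <- identity_blocks(1000)
  calls <- make_calls(100, 250, strain = "RM")
  out <- liftover_calls(calls, blocks)
  expect_equal(out$start, 100)
  expect_equal(out$end, 250)

  # offset block: qry [37, 1037) maps to ref [0, 1000)
  blocks2 <- data.frame(ref_chrom = "chrI", ref_start = 0L, ref_end = 1000L,
                        qry_contig = "chrI", qry_start = 37L, qry_end = 1037L,
                        orientation = "+")
  out2 <- liftover_calls(make_calls(100, 250, strain = "RM"), blocks2)
  expect_equal(out2$start, 63)
  expect_equal(out2$end, 213)

  # reverse-orientation block: qry interval maps to the mirrored ref interval
  blocks3 <- data.frame(ref_chrom = "chrI", ref_start = 0L, ref_end = 1000L,
                        qry_contig = "ctg", qry_start = 0L, qry_end = 1000L,
                        orientation = "-")
  out3 <- liftover_calls(make_calls(100, 250, chrom = "ctg", strain = "RM"), blocks3)
  expect_equal(out3$start, 750)
  expect_equal(out3$end, 900)

  # malformed block
  bad <- blocks2; bad$ref_end <- -5L
  expect_error(liftover_calls(calls, bad), "length")
})

test_that("calls spanning block boundaries are dropped with a count", {
  # two blocks separated by a 50 bp indel on the query side
  blocks <- data.frame(
    ref_chrom = "chrI", ref_start = c(0L, 1000L), ref_end = c(1000L, 2000L),
    qry_contig = "chrI", qry_start = c(0L, 1050L), qry_end = c(1000L, 2050L),
    orientation = "+")
  calls <- make_calls(c(100, 950, 1200), c(250, 1100, 1350), strain = "RM")
  out <- liftover_calls(calls, blocks)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(out$start, c(100, 1150))  # third call shifted by -50
})

test_that("identical call sets align perfectly with no indels", {
  calls <- make_calls(seq(0, 1980, by = 180), seq(147, 2127, by = 180))
  pairs <- align_maps(calls, calls)
  expect_true(all(pairs$status == "aligned"))
  expect_true(all(pairs$midpoint_distance == 0))
  expect_true(all(pairs$overlap_fraction_by == 1))
})

test_that("the anchor rule boundary is half the average nucleosome size", {
  # two 147 bp calls: threshold is (147+147)/4 = 73.5
  by <- make_calls(1000, 1147)
  rm73 <- make_calls(1073, 1220, strain = "RM")
  p73 <- align_maps(by, rm73)
  expect_equal(p73$status, "aligned")
  expect_equal(p73$midpoint_distance, 73)
  rm74 <- make_calls(1074, 1221, strain = "RM")
  p74 <- align_maps(by, rm74)
  # distance 74 exceeds the anchor bound; with no other anchors the interval
  # recursion still assigns the single closest pair
  expect_equal(sort(p74$midpoint_distance), 74)
})

test_that("interleaved calls match the exhaustive minimum-cost assignment", {
  # 3 BY and 2 RM calls between anchors; leftover BY becomes an insertion
  by <- make_calls(c(0, 400, 600, 800, 1400), c(147, 547, 747, 947, 1547))
  rm_ <- make_calls(c(5, 610, 850, 1395), c(152, 757, 997, 1542), strain = "RM")
  pairs <- align_maps(by, rm_)
  al <- pairs[pairs$status == "aligned", ]
  cost <- sum(al$midpoint_distance)
  oracle <- brute_force_match_cost(
    (by$start + by$end) / 2, (rm_$start + rm_$end) / 2)
  expect_equal(cost, oracle)
  expect_equal(sum(pairs$status == "insertion"), 1L)
  # conservation: every input call appears exactly once
  expect_equal(sum(pairs$status != "deletion"), nrow(by))
  expect_equal(sum(pairs$status != "insertion"), nrow(rm_))
})

test_that("the recursion assignment equals the exhaustive matching oracle", {
  set.seed(100)
  for (rep_ in 1:100) {
    m <- sample(1:5, 1); n <- sample(1:4, 1)
    a <- sort(runif(m, 0, 1000)); b <- sort(runif(n, 0, 1000))
    mp <- match_min_cost(a, b)
    cost <- sum(abs(a[!is.na(mp)] - b[mp[!is.na(mp)]]))
    expect_equal(sum(!is.na(mp)), min(m, n))       # maximum cardinality
    expect_equal(cost, brute_force_match_cost(a, b))
  }
})

test_that("alignment equals the exhaustive oracle on random realistic intervals", {
  set.seed(101)
  for (rep_ in 1:60) {
    n_by <- sample(2:5, 1)
    spacing <- 165
    by_start <- cumsum(c(200, rep(spacing, n_by - 1))) + round(rnorm(n_by, 0, 8))
    by <- make_calls(by_start, by_start + 147)
    # query calls: jittered copies with either occasional drops or an extra
    # trailing nucleosome (one-sided differences, so the anchor semantics
    # and the maximum-cardinality oracle agree on cardinality)
    rm_start <- by_start + round(rnorm(n_by, 0, 10))
    if (runif(1) < 0.5) {
      drop <- runif(n_by) < 0.2
      rm_start <- rm_start[!drop]
    } else if (runif(1) < 0.6) {
      rm_start <- c(rm_start, max(by_start) + spacing)
    }
    rm_start <- sort(rm_start)
    if (length(rm_start) == 0L) next
    rm_ <- make_calls(rm_start, rm_start + 147, strain = "RM")
    pairs <- align_maps(by, rm_)
    cost <- sum(pairs$midpoint_distance[pairs$status == "aligned"])
    oracle <- brute_force_match_cost((by$start + by$end) / 2,
                                     (rm_$start + rm_$end) / 2)
    expect_equal(cost, oracle)
    # nucleosome conservation
    expect_equal(nrow(pairs), sum(pairs$status == "aligned") +
                   sum(pairs$status == "insertion") + sum(pairs$status == "deletion"))
    expect_equal(sum(pairs$status != "deletion"), nrow(by))
  }
})

test_that("alignment is symmetric under strain exchange up to label swap", {
  set.seed(55)
  by_start <- cumsum(rep(170, 8)) + round(rnorm(8, 0, 5))
  rm_start <- by_start + round(rnorm(8, 0, 10))
  rm_start <- rm_start[-3]
  by <- make_calls(by_start, by_start + 147)
  rm_ <- make_calls(sort(rm_start), sort(rm_start) + 147, strain = "RM")
  fwd <- align_maps(by, rm_)
  rev_ <- align_maps(rm_, by)
  expect_equal(sum(fwd$status == "aligned"), sum(rev_$status == "aligned"))
  expect_equal(sum(fwd$status == "insertion"), sum(rev_$status == "deletion"))
  expect_equal(sum(fwd$status == "deletion"), sum(rev_$status == "insertion"))
  expect_equal(sort(fwd$midpoint_distance[fwd$status == "aligned"]),
               sort(rev_$midpoint_distance[rev_$status == "aligned"]))
})

test_that("pair likelihood annotations multiply the posterior state probabilities", {
  by <- make_calls(100, 250)
  rm_ <- make_calls(110, 260, strain = "RM")
  post <- data.frame(chrom = "chrI", position = seq(100, 260, by = 5),
                     post_nuc = 0.9)
  pairs <- align_maps(by, rm_, by_post = post, rm_post = post)
  expect_equal(pairs$B_n, 0.9, tolerance = 1e-9)
  expect_equal(pairs$L_aligned, 0.9 * 0.9, tolerance = 1e-9)
  expect_equal(pairs$L_insertion, 0.9 * 0.1, tolerance = 1e-9)
  expect_equal(pairs$L_deletion, 0.1 * 0.9, tolerance = 1e-9)
})

test_that("conservation statistics use interpolated quantiles", {
  pairs <- data.frame(status = "aligned",
                      midpoint_distance = c(0, 10, 20, 40),
                      overlap_fraction_by = c(1, 1, 0.9, 0.8))
  st <- conservation_stats(pairs, probs = 0.75)
  expect_equal(unname(st$distance_quantiles), 25)  # type-7 interpolation
  expect_equal(st$fraction_aligned, 1)
  expect_error(conservation_stats(pairs[0, ]), "no aligned")

  # all-zero distances
  p0 <- data.frame(status = "aligned", midpoint_distance = rep(0, 10),
                   overlap_fraction_by = 1)
  expect_equal(unname(conservation_stats(p0, probs = 0.75)$distance_quantiles), 0)
})

test_that("midpoint jitter maps to the half-normal quantile in conservation stats", {
  set.seed(77)
  n <- 4000
  starts <- seq(0, by = 180, length.out = n)
  by <- make_calls(starts, starts + 147)
  rm_ <- make_calls(starts + round(rnorm(n, 0, 8)), starts + 147 + 0, strain = "RM")
  rm_$end <- rm_$start + 147
  pairs <- align_maps(by, rm_)
  st <- conservation_stats(pairs, probs = 0.75)
  # |N(0, 8^2)| has 75th percentile 8 * qnorm(0.875) = 9.2; rounding adds noise
  expect_equal(unname(st$distance_quantiles), 8 * qnorm(0.875), tolerance = 0.08)
})

test_that("occupancy difference windows flag extremes and exclude indels", {
  set.seed(5)
  pos <- seq(0, 500000, by = 100)
  by_post <- data.frame(chrom = "chrI", position = pos,
                        post_nuc = rep(0.8, length(pos)))
  rm_post <- by_post
  # identical posteriors: all differences zero, nothing flagged
  pol0 <- data.frame(kind = character(), chrom = character(), pos = integer(),
                     ref_len = integer(), qry_len = integer())
  w0 <- occupancy_difference_windows(by_post, rm_post, pol0)
  expect_true(all(w0$diff == 0))
  expect_false(any(w0$flagged))

  # one depleted window in RM among neutral ones -> flagged
  rm2 <- rm_post
  rm2$post_nuc[rm2$position >= 100000 & rm2$position < 102500] <- 0
  w1 <- occupancy_difference_windows(by_post, rm2, pol0)
  expect_true(w1$flagged[w1$start == 100000])

  # a window containing a 6 bp deletion is absent from the output
  pol6 <- data.frame(kind = "deletion", chrom = "chrI", pos = 200100L,
                     ref_len = 0L, qry_len = 6L)
  w2 <- occupancy_difference_windows(by_post, rm_post, pol6)
  expect_false(any(w2$start <= 200100 & w2$end > 200100))
})
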