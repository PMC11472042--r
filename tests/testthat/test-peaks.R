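# The binning/chain/candidate/valley/fit/threshold peak-calling stack.

test_that("midpoint binning tallies each fragment once", {
  genome <- toy_genome(1000L)
  # midpoints 10, 30, 40
  frags <- tibble::tibble(
    chrom = "chr1", start = c(5L, 25L, 35L), end = c(15L, 35L, 45L)
  )
  tr <- bin_fragments(frags, genome, 25L)
  expect_equal(tr$count[tr$bin == 0], 1)
  expect_equal(tr$count[tr$bin == 1], 2)
  expect_equal(sum(tr$count), 3)

  expect_equal(sum(bin_fragments(frags[0, ], genome)$count), 0)

  withr::local_seed(11)
  rnd <- random_fragments(3000)
  tr <- bin_fragments(rnd, toy_genome(), 25L)
  mids <- (rnd$start + rnd$end) %/% 2L
  want <- tabulate(mids %/% 25L + 1L, nbins = ceiling(100000 / 25))
  expect_equal(tr$count[order(tr$bin)], as.numeric(want))
})

test_that("background subtraction scales by library size and clamps at zero", {
  t1 <- track_from_vector(c(10, 2, 10))
  c1 <- track_from_vector(c(4, 5, 4))
  sub_eq <- subtract_background(t1, c1, lib_treatment = 100, lib_control = 100)
  expect_equal(sub_eq$count, c(6, 0, 6))
  sub_2x <- subtract_background(t1, c1, lib_treatment = 200, lib_control = 100)
  expect_equal(sub_2x$count, c(2, 0, 2))
  expect_equal(attr(sub_2x, "scale_factor"), 2)
  expect_error(subtract_background(t1, c1, 100, 0), "zero")
})

test_that("chain filtering removes bins outside 8-bin chains", {
  run7 <- track_from_vector(c(0, rep(1, 7), 0, 0))
  expect_equal(sum(chain_filter(run7)$count), 0)

  run8 <- track_from_vector(c(0, rep(1, 8), 0))
  expect_equal(sum(chain_filter(run8)$count > 0), 8)

  run9_iso <- track_from_vector(c(rep(2, 9), 0, 0, 5, 0))
  filtered <- chain_filter(run9_iso)
  v <- filtered$count[order(filtered$bin)]
  expect_equal(v, c(rep(2, 9), 0, 0, 0, 0))
})

test_that("candidate bins beat the left neighbour and tie-break plateaus left", {
  expect_equal(find_candidate_bins(track_from_vector(c(1, 3, 2)))$bin, 1L)
  # rising to the chromosome edge: the edge behaves as zero
  expect_equal(find_candidate_bins(track_from_vector(c(1, 2, 3, 4)))$bin, 3L)
  expect_equal(find_candidate_bins(track_from_vector(c(0, 5, 5, 4)))$bin, 1L)
  expect_equal(nrow(find_candidate_bins(track_from_vector(rep(0, 6)))), 0L)
})

test_that("valley and separation rules resolve candidate pairs", {
  params <- peak_params()
  mk <- function(valley) {
    v <- rep(0, 20)
    v[11] <- 100; v[17] <- 80
    v[12:16] <- valley
    track_from_vector(v)
  }
  # valley 40 < 0.6 * 80 = 48: both kept
  tr <- mk(40)
  res <- resolve_candidates(find_candidate_bins(tr), tr, params)
  expect_equal(res$bin, c(10L, 16L))
  # valley 60 >= 48: second discarded
  tr <- mk(60)
  res <- resolve_candidates(find_candidate_bins(tr), tr, params)
  expect_equal(res$bin, 10L)
  # separation > 200 bp overrides a shallow valley
  v <- rep(0, 30)
  v[11] <- 100; v[24] <- 80 # 13 bins = 325 bp apart
  v[12:23] <- 79
  tr <- track_from_vector(v)
  res <- resolve_candidates(find_candidate_bins(tr), tr, params)
  expect_equal(res$bin, c(10L, 23L))
})

test_that("summit fitting recovers planted Gaussian parameters", {
  bw <- 25L
  centers <- seq(12.5, by = 25, length.out = 100)
  mu0 <- 1012; a0 <- 200; s0 <- 100
  v <- a0 * exp(-(centers - mu0)^2 / (2 * s0^2))
  tr <- track_from_vector(v)
  cand <- find_candidate_bins(tr)
  pk <- fit_summits(tr, cand, peak_params())
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$mu - mu0), 5)
  expect_lt(abs(pk$amplitude - a0) / a0, 0.05)
  expect_true(pk$converged)
  # reads in peak: bins with centers within +/- 200 bp of mu
  expect_equal(pk$reads_in_peak,
               sum(v[centers >= pk$mu - 200 & centers < pk$mu + 200]))

  # single spike: mu falls back to the bin center
  spike <- track_from_vector(c(rep(0, 10), 100, rep(0, 10)))
  pk2 <- fit_summits(spike, find_candidate_bins(spike), peak_params())
  expect_equal(pk2$mu, 10 * 25 + 12.5, tolerance = 1e-6)

  # exact symmetry pins the fitted center
  sym <- track_from_vector(c(1, 5, 20, 40, 20, 5, 1))
  pk3 <- fit_summits(sym, find_candidate_bins(sym), peak_params())
  expect_equal(pk3$mu, 3 * 25 + 12.5, tolerance = 1e-6)
})

test_that("read threshold is strict and blocklisted summits are dropped", {
  peaks <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    candidate_bin = 1L, mu = c(130000000, 130000000, 5000),
    amplitude = 10, sigma = 100,
    reads_in_peak = c(75, 200, 76),
    summit_start = c(129999995L, 129999995L, 4995L),
    summit_end = c(130000005L, 130000005L, 5005L),
    converged = TRUE
  )
  # exactly 75 reads is excluded under the strict > rule
  kept <- filter_peaks(peaks, min_reads = 75)
  expect_equal(kept$reads_in_peak, c(200, 76))
  # the chr1 centromeric region swallows the surviving chr1 peak
  kept_bl <- filter_peaks(peaks, 75, blocklist_centromeric_hg38())
  expect_equal(kept_bl$chrom, "chr2")
})

test_that("candidate+valley resolution matches the brute-force reference", {
  withr::local_seed(77)
  params <- peak_params()
  for (i in 1:60) {
    n <- sample(10:100, 1)
    v <- sample(0:50, n, replace = TRUE)
    if (runif(1) < 0.3) v[sample(n, n %/% 2)] <- 0 # sparse tracks too
    tr <- track_from_vector(v)
    got <- resolve_candidates(find_candidate_bins(tr), tr, params)$bin
    want <- brute_peak_bins(v)
    expect_equal(got, as.integer(want), info = paste("track", i))
  }
})

test_that("raising the read threshold never adds peaks", {
  withr::local_seed(88)
  genome <- toy_genome(20000L)
  mids <- c(round(rnorm(900, 5000, 120)), round(rnorm(500, 11000, 90)))
  frags <- tibble::tibble(chrom = "chr1", start = as.integer(mids - 30),
                          end = as.integer(mids + 30))
  track <- chain_filter(bin_fragments(frags, genome))
  acc <- resolve_candidates(find_candidate_bins(track), track, peak_params())
  pk <- fit_summits(track, acc, peak_params())
  counts <- vapply(c(0, 50, 100, 400, 1000),
                   function(th) nrow(filter_peaks(pk, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("shifting fragments by whole bins shifts summit lines equally", {
  withr::local_seed(99)
  genome <- toy_genome(40000L)
  mids <- round(rnorm(1200, 9000, 110))
  frags <- tibble::tibble(chrom = "chr1", start = as.integer(mids - 35),
                          end = as.integer(mids + 35))
  k <- 7L
  shifted <- dplyr::mutate(frags, start = start + k * 25L, end = end + k * 25L)
  run <- function(f) {
    tr <- chain_filter(bin_fragments(f, genome))
    acc <- resolve_candidates(find_candidate_bins(tr), tr, peak_params())
    fit_summits(tr, acc, peak_params())
  }
  p1 <- run(frags)
  p2 <- run(shifted)
  expect_equal(p2$summit_start, p1$summit_start + k * 25L)
  expect_equal(p2$summit_end, p1$summit_end + k * 25L)
})

test_that("call_peaks composes the stages and tidies", {
  withr::local_seed(110)
  genome <- toy_genome(30000L)
  mids <- round(rnorm(2000, 15000, 100))
  frags <- tibble::tibble(chrom = "chr1", start = as.integer(mids - 30),
                          end = as.integer(mids + 30), strand = "+",
                          umi = NA_character_)
  res <- call_peaks(frags, genome)
  expect_s3_class(res, "dff_peaks")
  pk <- tidy(res)
  expect_gte(nrow(pk), 1L)
  main <- pk[which.max(pk$reads_in_peak), ]
  expect_lt(abs(main$mu - 15000), 25)
  expect_gt(main$reads_in_peak, 75)
  g <- glance(res)
  expect_equal(g$n_peaks, nrow(pk))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
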