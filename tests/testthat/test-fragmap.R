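# fragMap matrices, sorted heatmaps and center profiles.

test_that("fragMap accumulates per-bp occupancy in oriented coordinates", {
  frags <- tibble::tibble(chrom = "chr1", start = 990L, end = 1010L)
  plus <- tibble::tibble(chrom = "chr1", pos = 1000L, strand = "+")
  fm <- fragmap(frags, plus, x_half = 100L, min_len = 10L, max_len = 50L)
  expect_equal(sum(fm$matrix), 20)
  row20 <- fm$matrix["20", ]
  expect_equal(sum(row20), 20)
  expect_equal(as.integer(names(row20[row20 > 0])), -10:9)

  minus <- tibble::tibble(chrom = "chr1", pos = 1000L, strand = "-")
  fm_m <- fragmap(frags, minus, x_half = 100L, min_len = 10L, max_len = 50L)
  hit <- fm_m$matrix["20", ]
  expect_equal(as.integer(names(hit[hit > 0])), -9:10)

  # out-of-range lengths contribute nothing
  fm0 <- fragmap(frags, plus, x_half = 100L, min_len = 30L, max_len = 50L)
  expect_equal(sum(fm0$matrix), 0)
})

test_that("fragMap mass equals the per-pair overlap sum", {
  withr::local_seed(61)
  frags <- random_fragments(800, 20000L, min_len = 20L, max_len = 250L)
  anchors <- tibble::tibble(
    chrom = "chr1", pos = as.integer(sample(2000:18000, 15)),
    strand = sample(c("+", "-"), 15, TRUE)
  )
  xh <- 300L
  fm <- fragmap(frags, anchors, x_half = xh, min_len = 20L, max_len = 250L)
  mass <- 0
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(frags))) {
      if (frags$chrom[j] != anchors$chrom[i]) next
      if (anchors$strand[i] == "+") {
        rs <- frags$start[j] - anchors$pos[i]
        re <- frags$end[j] - anchors$pos[i]
      } else {
        rs <- anchors$pos[i] - frags$end[j] + 1L
        re <- anchors$pos[i] - frags$start[j] + 1L
      }
      mass <- mass + max(0, min(re, xh + 1L) - max(rs, -xh))
    }
  }
  expect_equal(sum(fm$matrix), mass)
  expect_equal(glance(fm)$mass, mass)
  expect_error(fragmap(frags, anchors[0, ]), "empty")
})

test_that("simulated factor+nucleosome libraries show both length modes", {
  spec_tf <- footprint_spec("TF", c(70, 70), fragments_per_site = 60,
                            end_jitter_sd = 3)
  spec_nuc <- footprint_spec("nucleosome", c(147, 147),
                             fragments_per_site = 40, end_jitter_sd = 3)
  sim <- simulate_genome(400000L, 0.41, list(spec_tf), n_sites = 30,
                         seed = 71)
  truth_nuc <- dplyr::mutate(
    sim$truth, class = "nucleosome",
    center = center + 110L, start = center - 73L, end = center + 74L
  )
  frags <- simulate_fragments(
    dplyr::bind_rows(sim$truth, truth_nuc),
    list(spec_tf, spec_nuc), sim$genome,
    background_rate = 0.2, seed = 72
  )
  anchors <- tibble::tibble(chrom = sim$truth$chrom, pos = sim$truth$center,
                            strand = "+")
  fm <- fragmap(frags, anchors, x_half = 300L, min_len = 18L, max_len = 250L)
  # row mass / row length ~ fragments per length row (a 147 bp fragment
  # deposits twice the per-bp mass of a 70 bp one)
  lens <- as.integer(rownames(fm$matrix))
  rs <- rowSums(fm$matrix) / lens
  primary <- lens[which.max(rs)]
  expect_lte(abs(primary - 70), 5)
  nuc_zone <- lens >= 120 & lens <= 180
  secondary <- lens[nuc_zone][which.max(rs[nuc_zone])]
  expect_lte(abs(secondary - 147), 10)
})

test_that("heatmap rows sort by the window signal with stable ties", {
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(1000L, 10), rep(5000L, 25)),
    end = c(rep(1001L, 10), rep(5001L, 25))
  )
  anchors <- tibble::tibble(chrom = "chr1", pos = c(1000L, 5000L),
                            strand = "+")
  hm <- coverage_heatmap(frags, anchors, span = c(-50L, 50L),
                         sort_window = c(-10L, 10L), bin_width = 10L)
  expect_equal(hm$row_order, c(2L, 1L)) # richer region first
  expect_equal(sum(hm$matrix[1, ]), 25)

  tie <- tibble::tibble(chrom = "chr1", pos = c(1000L, 1000L), strand = "+")
  hm_tie <- coverage_heatmap(frags, tie, span = c(-50L, 50L),
                             sort_window = c(-10L, 10L))
  expect_equal(hm_tie$row_order, c(1L, 2L)) # ties keep input order
})

test_that("a saved permutation reproduces a sort by another dataset", {
  withr::local_seed(81)
  a <- random_fragments(2000, 50000L)
  b <- random_fragments(2000, 50000L)
  anchors <- tibble::tibble(chrom = "chr1",
                            pos = as.integer(sample(5000:45000, 12)),
                            strand = sample(c("+", "-"), 12, TRUE))
  sorted_by_a <- coverage_heatmap(b, anchors, span = c(-200L, 400L),
                                  sort_window = c(-50L, 250L), sort_frags = a)
  ref <- coverage_heatmap(a, anchors, span = c(-200L, 400L),
                          sort_window = c(-50L, 250L))
  replayed <- coverage_heatmap(b, anchors, span = c(-200L, 400L),
                               order = ref$row_order)
  expect_equal(replayed$matrix, sorted_by_a$matrix)
  expect_equal(replayed$row_order, sorted_by_a$row_order)
})

test_that("center profiles normalize to one and mirror with strand", {
  frags <- tibble::tibble(chrom = "chr1", start = 1020L, end = 1064L)
  anchors <- tibble::tibble(chrom = "chr1", pos = 1000L, strand = "+")
  pr <- center_profile(frags, anchors, size_class = c(40L, 60L),
                       span = c(1L, 200L))
  expect_equal(sum(pr$density), 1)
  expect_equal(pr$density[pr$position == 42], 1)

  # out-of-class length gives an empty (all-zero) profile with a warning
  expect_warning(
    empty <- center_profile(frags, anchors, size_class = c(100L, 120L)),
    "no fragment centers"
  )
  expect_equal(sum(empty$density), 0)

  withr::local_seed(91)
  rnd <- random_fragments(3000, 10000L, min_len = 40L, max_len = 60L)
  plus <- tibble::tibble(chrom = "chr1", pos = 5000L, strand = "+")
  minus <- tibble::tibble(chrom = "chr1", pos = 5000L, strand = "-")
  p_plus <- center_profile(rnd, plus, c(40L, 60L), span = c(-150L, 150L))
  p_minus <- center_profile(rnd, minus, c(40L, 60L), span = c(-150L, 150L))
  expect_equal(p_plus$count, rev(p_minus$count))
})

test_that("matrix results tidy and plot", {
  withr::local_seed(95)
  frags <- random_fragments(500, 20000L)
  anchors <- tibble::tibble(chrom = "chr1", pos = c(5000L, 12000L),
                            strand = "+")
  fm <- fragmap(frags, anchors, x_half = 200L, min_len = 20L, max_len = 200L)
  td <- tidy(fm)
  expect_equal(sum(td$count), sum(fm$matrix))
  expect_s3_class(autoplot(fm), "ggplot")
  hm <- coverage_heatmap(frags, anchors, span = c(-100L, 100L),
                         sort_window = c(-50L, 50L))
  expect_equal(sum(tidy(hm)$count), sum(hm$matrix))
  expect_s3_class(autoplot(hm), "ggplot")
})
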