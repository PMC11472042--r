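# Brute-force reference implementations and small generators used across the
# suite. Each oracle is written directly from the rule it checks, with naive
# loops, independent of the package internals.

random_fragments <- function(n, chrom_size = 100000L, chroms = "chr1",
                             min_len = 20L, max_len = 300L, with_umi = FALSE) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- sapply(len, function(l) sample.int(chrom_size - l, 1L) - 1L)
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(start + len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    umi = if (with_umi) {
      replicate(n, paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""))
    } else NA_character_
  )
}

toy_genome <- function(size = 100000L, chroms = "chr1") {
  tibble::tibble(chrom = chroms, size = as.integer(size))
}

# Dense track tibble from a plain count vector (bins 0..n-1 on one chrom).
track_from_vector <- function(v, chrom = "chr1", bin_width = 25L) {
  tr <- tibble::tibble(chrom = chrom, bin = seq_along(v) - 1L,
                       count = as.numeric(v))
  attr(tr, "bin_width") <- as.integer(bin_width)
  tr
}

# Local maxima (edges as zero, leftmost plateau bin) followed by an
# exhaustive left-to-right application of the valley/separation rules.
# Returns accepted bin indices, 0-based.
brute_peak_bins <- function(v, bin_width = 25L, valley_frac = 0.6,
                            max_sep = 200L) {
  n <- length(v)
  cand <- integer()
  for (i in seq_len(n)) {
    left <- if (i == 1) 0 else v[i - 1]
    right <- if (i == n) 0 else v[i + 1]
    if (v[i] > left && v[i] >= right) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(integer())
  acc <- cand[1]
  for (j in cand[-1]) {
    i <- acc[length(acc)]
    take <- (j - i) * bin_width > max_sep
    if (!take && j - i >= 2) {
      valley <- min(v[(i + 1):(j - 1)])
      take <- valley < valley_frac * min(v[i], v[j])
    }
    if (take) acc <- c(acc, j)
  }
  acc - 1L
}

# Exhaustive greedy center-cluster caller over every window start.
brute_ccs <- function(centers, window, depth) {
  if (length(centers) == 0) return(NULL)
  starts <- 0:max(centers)
  cnt <- vapply(starts, function(s) {
    sum(centers >= s & centers < s + window)
  }, numeric(1))
  active <- rep(TRUE, length(starts))
  rows <- list()
  repeat {
    idx <- which(active)
    if (length(idx) == 0) break
    best <- idx[which.max(cnt[idx])]
    if (cnt[best] < depth) break
    s <- starts[best]
    inside <- centers[centers >= s & centers < s + window]
    freq <- table(inside)
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = s + window, center_count = length(inside),
      modal_center = as.integer(names(freq)[which.max(freq)])
    )
    active[starts > s - window & starts < s + window] <- FALSE
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# Naive per-row containment / overlap tally.
brute_site_counts <- function(sites, frags, rule = "contain") {
  vapply(seq_len(nrow(sites)), function(i) {
    same <- frags$chrom == sites$chrom[i]
    if (rule == "contain") {
      sum(same & frags$start <= sites$start[i] & frags$end >= sites$end[i])
    } else {
      sum(same & frags$start < sites$end[i] & frags$end > sites$start[i])
    }
  }, numeric(1))
}

# Naive key-based duplicate filter retaining the first record in canonical
# order.
brute_dedup <- function(frags) {
  frags <- frags[order(frags$chrom, frags$start, frags$end), ]
  key <- paste(frags$chrom, frags$start, frags$end, frags$strand, frags$umi,
               sep = "\r")
  frags[!duplicated(key), ]
}

# Textbook Pearson correlation.
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

expect_same_fragments <- function(a, b) {
  cols <- c("chrom", "start", "end", "strand", "umi")
  strip <- function(x) {
    x <- data.frame(lapply(as.data.frame(x)[, cols], unname))
    rownames(x) <- NULL
    x
  }
  expect_equal(strip(a), strip(b))
}
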