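# Fragment-level operations: UMI deduplication, length gating, coverage
# tracks and replicate correlations.

#' Collapse PCR duplicates
#'
#' Retains at most one fragment per key. The key is
#' `(chrom, start, end, strand, umi)`; fragments lacking a UMI fall back to
#' the coordinate key `(chrom, start, end, strand)`. The retained fragment is
#' the first in canonical (chrom, start, end) order, so the result is
#' deterministic and `dedup_fragments()` is idempotent.
#'
#' @param frags Fragment tibble.
#' @param use_strand Include strand in the key (default `TRUE`). The libraries
#'   this toolkit targets carry strand on mate 1; set `FALSE` to collapse
#'   across strands.
#' @param use_umi Include the UMI in the key (default `TRUE`). With
#'   `use_umi = FALSE` deduplication is purely coordinate-based.
#' @return Deduplicated fragment tibble with attribute `n_duplicates`, the
#'   number of fragments removed.
#' @export
dedup_fragments <- function(frags, use_strand = TRUE, use_umi = TRUE) {
  frags <- canonical_sort(as_fragment_tbl(frags))
  validate_fragments(frags)
  key_cols <- c("chrom", "start", "end")
  if (use_strand) key_cols <- c(key_cols, "strand")
  if (use_umi) key_cols <- c(key_cols, "umi")
  out <- dplyr::distinct(frags, dplyr::across(dplyr::all_of(key_cols)),
                         .keep_all = TRUE)
  attr(out, "n_duplicates") <- nrow(frags) - nrow(out)
  out
}

#' Gate fragments by length
#'
#' Keeps fragments with `min_len <= end - start <= max_len` (both bounds
#' inclusive). The sequencing pipeline this models trims templates to
#' 18–1000 bp, the default gate.
#'
#' @param frags Fragment tibble.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return Filtered fragment tibble.
#' @export
filter_fragment_length <- function(frags, min_len = 18L, max_len = 1000L) {
  if (min_len < 1 || min_len > max_len) {
    stop("need 1 <= min_len <= max_len")
  }
  frags <- as_fragment_tbl(frags)
  len <- frags$end - frags$start
  frags[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Per-base fragment coverage as a bedGraph-style track
#'
#' Computes, at 1-bp resolution, the number of fragments overlapping each
#' position and emits maximal runs of constant non-zero value. Total mass
#' (interval length times value, summed) equals the summed fragment lengths.
#'
#' @param frags Fragment tibble.
#' @param genome Optional chromosome sizes tibble used to validate bounds.
#' @return A coverage tibble with columns `chrom`, `start`, `end`, `count`.
#' @export
fragment_coverage <- function(frags, genome = NULL) {
  frags <- as_fragment_tbl(frags)
  validate_fragments(frags, genome = genome)
  if (nrow(frags) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  count = integer()))
  }
  per_chrom <- function(d) {
    ev <- tibble(
      pos = c(d$start, d$end),
      delta = rep(c(1L, -1L), each = nrow(d))
    )
    ev <- ev |>
      group_by(.data$pos) |>
      summarise(delta = sum(.data$delta), .groups = "drop") |>
      arrange(.data$pos)
    val <- cumsum(ev$delta)
    k <- nrow(ev)
    tibble(
      start = ev$pos[-k], end = ev$pos[-1], count = val[-k]
    ) |>
      filter(.data$count > 0)
  }
  frags |>
    group_by(.data$chrom) |>
    dplyr::group_modify(~ per_chrom(.x)) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Write a coverage track as 4-column bedGraph
#'
#' @param coverage Tibble from [fragment_coverage()].
#' @param path Output path.
#' @param track_line Optional track definition line to prepend (none by
#'   default).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path, track_line = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  readr::write_tsv(
    coverage[, c("chrom", "start", "end", "count")],
    con, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

bin_read_sums <- function(x, genome, bin_width) {
  nbins <- ceiling(genome$size / bin_width)
  offset <- c(0, cumsum(nbins))[seq_len(nrow(genome))]
  names(offset) <- genome$chrom
  total <- sum(nbins)
  if ("count" %in% names(x)) {
    # coverage track: allocate value * bp overlap into each bin
    acc <- numeric(total)
    for (i in seq_len(nrow(x))) {
      b0 <- x$start[i] %/% bin_width
      b1 <- (x$end[i] - 1L) %/% bin_width
      for (b in b0:b1) {
        lo <- max(x$start[i], b * bin_width)
        hi <- min(x$end[i], (b + 1) * bin_width)
        acc[offset[[x$chrom[i]]] + b + 1] <-
          acc[offset[[x$chrom[i]]] + b + 1] + x$count[i] * (hi - lo)
      }
    }
    acc
  } else {
    # fragments: each counted once, in the bin containing its start
    idx <- offset[x$chrom] + x$start %/% bin_width + 1
    tabulate(idx, nbins = total)
  }
}

#' Replicate correlation over genomic bins
#'
#' Divides the genome into fixed-width bins (10 kb by default), sums the
#' reads per bin for each replicate, and returns the Pearson correlation of
#' the two bin vectors. A fragment is counted once, in the bin containing
#' its start; a coverage track contributes value times bp of overlap.
#'
#' @param a,b Fragment tibbles, or coverage tibbles from
#'   [fragment_coverage()].
#' @param genome Chromosome sizes tibble shared by both inputs.
#' @param bin_width Bin width in bp (default 10000).
#' @return Pearson r as a single number.
#' @export
replicate_correlation <- function(a, b, genome, bin_width = 10000L) {
  va <- bin_read_sums(a, genome, bin_width)
  vb <- bin_read_sums(b, genome, bin_width)
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("undefined correlation: a bin vector has zero variance")
  }
  if (identical(as.numeric(va), as.numeric(vb))) return(1)
  cor(va, vb)
}
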