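# fragMap matrices (fragment length x position relative to oriented
# anchors), sorted coverage heatmaps, and fragment-center profiles.
#
# Relative coordinate 0 is the anchor base itself. For a '-' strand anchor
# both the position axis and the fragment span are mirrored: base g maps to
# rel = pos - g, so a fragment [start, end) occupies relative positions
# [pos - end + 1, pos - start + 1).

validate_anchors <- function(anchors) {
  stopifnot(is.data.frame(anchors))
  if (nrow(anchors) == 0) stop("anchor list is empty")
  missing_cols <- setdiff(c("chrom", "pos"), names(anchors))
  if (length(missing_cols) > 0) {
    stop("anchor table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  anchors <- as_tibble(anchors)
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  anchors$strand[!(anchors$strand %in% c("+", "-"))] <- "+"
  anchors
}

# One row per (anchor, same-chromosome fragment) pair with the fragment span
# in oriented relative coordinates.
pair_relative <- function(frags, anchors, max_reach) {
  frags <- as_fragment_tbl(frags)
  anchors <- validate_anchors(anchors)
  anchors$.region <- seq_len(nrow(anchors))
  pairs <- inner_join(
    frags, anchors,
    by = "chrom", suffix = c("", "_anchor"), relationship = "many-to-many"
  )
  if (nrow(pairs) == 0) {
    return(tibble(.region = integer(), rel_start = integer(),
                  rel_end = integer(), len = integer()))
  }
  minus <- pairs$strand_anchor == "-"
  rel_start <- ifelse(minus, pairs$pos - pairs$end + 1L, pairs$start - pairs$pos)
  rel_end <- ifelse(minus, pairs$pos - pairs$start + 1L, pairs$end - pairs$pos)
  out <- tibble(
    .region = pairs$.region,
    rel_start = as.integer(rel_start),
    rel_end = as.integer(rel_end),
    len = pairs$end - pairs$start
  )
  out[out$rel_end > -max_reach & out$rel_start <= max_reach, , drop = FALSE]
}

#' Build a fragMap matrix
#'
#' A fragMap is a 2D count matrix with fragment length on the rows and
#' position relative to oriented anchors on the columns. Every admitted
#' (anchor, fragment) pair adds 1 to the fragment's length row at every
#' column its span covers inside `[-x_half, +x_half]`, reproducing the
#' horizontal-bar appearance of published fragMaps. Counts are raw sums over
#' all anchors; the anchor count is kept so per-anchor averages are
#' derivable.
#'
#' @param frags Fragment tibble.
#' @param anchors Anchor tibble (`chrom`, `pos`, `strand`), e.g. from
#'   [read_anchors()].
#' @param x_half Half-width of the position axis in bp.
#' @param min_len,max_len Inclusive fragment-length range (matrix rows).
#' @return An object of class `dff_fragmap` holding the matrix (rows named
#'   by length, columns by relative position) plus `n_anchors`. Use
#'   [tidy()] for a long tibble and [autoplot()] to render.
#' @export
fragmap <- function(frags, anchors, x_half = 500L, min_len = 18L,
                    max_len = 400L) {
  stopifnot(min_len <= max_len, x_half >= 1)
  pairs <- pair_relative(frags, anchors, x_half)
  pairs <- pairs[pairs$len >= min_len & pairs$len <= max_len, , drop = FALSE]
  nrows <- max_len - min_len + 1L
  ncols <- 2L * x_half + 1L
  cs <- pmax(pairs$rel_start, -x_half)
  ce <- pmin(pairs$rel_end, x_half + 1L)
  keep <- cs < ce
  cs <- cs[keep]; ce <- ce[keep]
  row_i <- pairs$len[keep] - min_len + 1L
  nrun <- ce - cs
  cols <- sequence(nrun, from = cs + x_half + 1L)
  rows <- rep(row_i, nrun)
  counts <- tabulate((cols - 1L) * nrows + rows, nbins = nrows * ncols)
  m <- matrix(counts, nrow = nrows, ncol = ncols,
              dimnames = list(min_len:max_len, -x_half:x_half))
  structure(
    list(matrix = m, n_anchors = nrow(validate_anchors(anchors)),
         x_half = as.integer(x_half),
         len_range = c(as.integer(min_len), as.integer(max_len))),
    class = "dff_fragmap"
  )
}

#' @export
print.dff_fragmap <- function(x, ...) {
  cat(sprintf(
    "<dff_fragmap> lengths %d-%d x positions %+d..%+d over %d anchors (mass %g)\n",
    x$len_range[1], x$len_range[2], -x$x_half, x$x_half, x$n_anchors,
    sum(x$matrix)
  ))
  invisible(x)
}

# Per-bp oriented coverage contributions for heatmap/profile builders.
heatmap_cells <- function(frags, anchors, span, bin_width) {
  a <- span[1]; b <- span[2]
  pairs <- pair_relative(frags, anchors, max(abs(span)) + 1L)
  cs <- pmax(pairs$rel_start, a)
  ce <- pmin(pairs$rel_end, b + 1L)
  keep <- cs < ce
  cs <- cs[keep]; ce <- ce[keep]
  region <- pairs$.region[keep]
  nrun <- ce - cs
  relpos <- sequence(nrun, from = cs)
  tibble(
    region = rep(region, nrun),
    col = (relpos - a) %/% bin_width + 1L
  )
}

#' Sorted coverage heatmap around anchors
#'
#' Builds one row of oriented fragment coverage per anchor over the relative
#' span, binned into `bin_width`-bp columns, and orders rows by descending
#' total coverage of `sort_frags` (default: the same fragments) inside
#' `sort_window`; ties preserve input order. The permutation is kept so that
#' a second dataset can be plotted in the same order by passing it as
#' `order`.
#'
#' @param frags Fragment tibble supplying the displayed coverage.
#' @param anchors Anchor tibble (`chrom`, `pos`, `strand`).
#' @param span Relative span `c(a, b)` (inclusive, bp) of each row.
#' @param sort_window Relative window `c(a, b)` (inclusive) whose summed
#'   coverage ranks the rows.
#' @param sort_frags Fragments used for the ranking; defaults to `frags`.
#' @param bin_width Column bin width in bp (default 10).
#' @param order Optional explicit row permutation (indices into the anchor
#'   list) reused from a previous heatmap; overrides the sort.
#' @return An object of class `dff_heatmap`: the row-sorted matrix, the
#'   `row_order` permutation, `bin_width` and `span`.
#' @export
coverage_heatmap <- function(frags, anchors, span = c(-500L, 1000L),
                             sort_window = c(-50L, 250L), sort_frags = NULL,
                             bin_width = 10L, order = NULL) {
  stopifnot(span[1] < span[2], bin_width >= 1)
  anchors <- validate_anchors(anchors)
  n_regions <- nrow(anchors)
  ncols <- (span[2] - span[1] + 1L) %/% bin_width +
    as.integer((span[2] - span[1] + 1L) %% bin_width > 0)
  cells <- heatmap_cells(frags, anchors, span, bin_width)
  counts <- tabulate((cells$col - 1L) * n_regions + cells$region,
                     nbins = n_regions * ncols)
  m <- matrix(counts, nrow = n_regions, ncol = ncols)
  colnames(m) <- span[1] + (seq_len(ncols) - 1L) * bin_width
  if (is.null(order)) {
    stopifnot(sort_window[1] <= sort_window[2])
    sf <- if (is.null(sort_frags)) frags else sort_frags
    sc <- heatmap_cells(sf, anchors, sort_window, 1L)
    sums <- tabulate(sc$region, nbins = n_regions)
    order <- base::order(-sums) # stable: ties keep input order
  }
  structure(
    list(matrix = m[order, , drop = FALSE], row_order = order,
         bin_width = as.integer(bin_width), span = as.integer(span),
         n_regions = n_regions),
    class = "dff_heatmap"
  )
}

#' @export
print.dff_heatmap <- function(x, ...) {
  cat(sprintf(
    "<dff_heatmap> %d regions x %d columns (%d bp bins, span %+d..%+d)\n",
    nrow(x$matrix), ncol(x$matrix), x$bin_width, x$span[1], x$span[2]
  ))
  invisible(x)
}

#' Normalized fragment-center profile
#'
#' Histograms the oriented relative positions of fragment centers for
#' fragments in a length class (e.g. engaged polymerase, 40–60 bp, or
#' polymerase abutted to the +1 nucleosome, 170–210 bp) across all anchors,
#' and normalizes the histogram to sum to 1 so profiles of different depth
#' are comparable. An empty selection yields an all-zero profile with a
#' warning.
#'
#' @param frags Fragment tibble.
#' @param anchors Anchor tibble (`chrom`, `pos`, `strand`).
#' @param size_class Inclusive length range `c(min, max)` in bp.
#' @param span Inclusive relative span `c(a, b)` of admitted centers.
#' @return A tibble of class `dff_profile` with columns `position`, `count`,
#'   `density` (summing to 1, or 0 when empty).
#' @export
center_profile <- function(frags, anchors, size_class = c(40L, 60L),
                           span = c(1L, 200L)) {
  stopifnot(size_class[1] <= size_class[2], span[1] <= span[2])
  frags <- as_fragment_tbl(frags)
  len <- frags$end - frags$start
  frags <- frags[len >= size_class[1] & len <= size_class[2], , drop = FALSE]
  anchors <- validate_anchors(anchors)
  anchors$.region <- seq_len(nrow(anchors))
  pairs <- inner_join(frags, anchors, by = "chrom",
                      suffix = c("", "_anchor"),
                      relationship = "many-to-many")
  center <- (pairs$start + pairs$end) %/% 2L
  rel <- ifelse(pairs$strand_anchor == "-", pairs$pos - center,
                center - pairs$pos)
  rel <- rel[rel >= span[1] & rel <= span[2]]
  counts <- tabulate(rel - span[1] + 1L, nbins = span[2] - span[1] + 1L)
  total <- sum(counts)
  if (total == 0) {
    warning("no fragment centers in the requested size class and span")
  }
  out <- tibble(
    position = span[1]:span[2],
    count = counts,
    density = if (total > 0) counts / total else rep(0, length(counts))
  )
  class(out) <- c("dff_profile", class(out))
  attr(out, "size_class") <- as.integer(size_class)
  attr(out, "span") <- as.integer(span)
  out
}
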