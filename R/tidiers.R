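# broom-style tidiers for the package's result objects.

#' Tidy a peak-calling result
#'
#' @param x A `dff_peaks` object from [call_peaks()].
#' @param ... Unused.
#' @return The per-peak tibble: one row per retained peak with the fitted
#'   Gaussian parameters and read counts.
#' @export
tidy.dff_peaks <- function(x, ...) {
  x$peaks
}

#' One-row summary of a peak-calling result
#'
#' @param x A `dff_peaks` object.
#' @param ... Unused.
#' @return A tibble with peak, candidate and fragment counts, the
#'   subtraction scale factor (NA when no control was used) and the number
#'   of non-converged fits.
#' @export
glance.dff_peaks <- function(x, ...) {
  tibble(
    n_peaks = nrow(x$peaks),
    n_candidates = x$n_candidates,
    n_accepted = x$n_accepted,
    n_fragments = x$n_fragments,
    scale_factor = x$scale_factor,
    n_unconverged = sum(!x$peaks$converged),
    min_reads = x$params$min_reads
  )
}

#' Tidy a fragMap
#'
#' @param x A `dff_fragmap` object from [fragmap()].
#' @param ... Unused.
#' @return A long tibble with `length`, `position`, `count`.
#' @export
tidy.dff_fragmap <- function(x, ...) {
  m <- x$matrix
  tibble(
    length = rep(as.integer(rownames(m)), times = ncol(m)),
    position = rep(as.integer(colnames(m)), each = nrow(m)),
    count = as.vector(m)
  )
}

#' One-row summary of a fragMap
#'
#' @param x A `dff_fragmap` object.
#' @param ... Unused.
#' @return A tibble with the anchor count, total mass and the modal
#'   fragment length (the row with the largest total count).
#' @export
glance.dff_fragmap <- function(x, ...) {
  rs <- rowSums(x$matrix)
  tibble(
    n_anchors = x$n_anchors,
    mass = sum(x$matrix),
    modal_length = as.integer(rownames(x$matrix)[which.max(rs)])
  )
}

#' Tidy a coverage heatmap
#'
#' @param x A `dff_heatmap` object from [coverage_heatmap()].
#' @param ... Unused.
#' @return A long tibble with `row` (display order), `region` (input anchor
#'   index), `position` (bin start, bp relative to the anchor) and `count`.
#' @export
tidy.dff_heatmap <- function(x, ...) {
  m <- x$matrix
  tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    region = rep(x$row_order, times = ncol(m)),
    position = rep(as.integer(colnames(m)), each = nrow(m)),
    count = as.vector(m)
  )
}
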