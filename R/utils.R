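# Internal helpers shared across modules.

# Columns every fragment tibble carries. `strand` is "+", "-" or "*" and
# `umi` is an 8-nt string or NA.
FRAGMENT_COLS <- c("chrom", "start", "end", "strand", "umi")

empty_fragments <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), umi = character()
  )
}

#' Validate a fragment tibble
#'
#' Checks the invariants every fragment table must satisfy: required columns,
#' `0 <= start < end`, and (when present) UMIs matching `[ACGTN]{8}`. Called
#' at the entry of user-facing functions; returns its input invisibly.
#'
#' @param frags A data frame with columns `chrom`, `start`, `end` and
#'   optionally `strand` and `umi`.
#' @param genome Optional genome tibble (`chrom`, `size`); if supplied, every
#'   fragment must lie within its chromosome.
#' @return `frags`, invisibly.
#' @export
validate_fragments <- function(frags, genome = NULL) {
  stopifnot(is.data.frame(frags))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(frags))
  if (length(missing_cols) > 0) {
    stop("fragment table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(frags) == 0) return(invisible(frags))
  if (any(frags$start < 0) || any(frags$start >= frags$end)) {
    bad <- which(frags$start < 0 | frags$start >= frags$end)[1]
    stop(sprintf(
      "invalid fragment at row %d: %s:%s-%s (need 0 <= start < end)",
      bad, frags$chrom[bad], frags$start[bad], frags$end[bad]
    ))
  }
  if ("umi" %in% names(frags)) {
    umi <- frags$umi[!is.na(frags$umi)]
    if (length(umi) > 0 && !all(grepl("^[ACGTN]{8}$", umi))) {
      stop("UMIs must match [ACGTN]{8}")
    }
  }
  if (!is.null(genome)) {
    chk <- dplyr::left_join(frags, genome, by = "chrom")
    if (anyNA(chk$size)) {
      bad <- which(is.na(chk$size))[1]
      stop("unknown chromosome in fragment record: ", frags$chrom[bad])
    }
    if (any(chk$end > chk$size)) {
      bad <- which(chk$end > chk$size)[1]
      stop(sprintf(
        "fragment %s:%d-%d extends past chromosome end (%d bp)",
        chk$chrom[bad], chk$start[bad], chk$end[bad], chk$size[bad]
      ))
    }
  }
  invisible(frags)
}

# Canonical (chrom, start, end) order used before any write and by dedup.
canonical_sort <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

as_fragment_tbl <- function(x) {
  x <- as_tibble(x)
  if (!"strand" %in% names(x)) x$strand <- "*"
  if (!"umi" %in% names(x)) x$umi <- NA_character_
  x$strand[is.na(x$strand) | !(x$strand %in% c("+", "-"))] <- "*"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  dplyr::select(x, dplyr::all_of(FRAGMENT_COLS), dplyr::everything())
}

# TRUE for rows of `x` overlapping (>= 1 bp, half-open) any interval of `ivl`.
overlaps_any <- function(x, ivl) {
  if (nrow(x) == 0 || is.null(ivl) || nrow(ivl) == 0) {
    return(rep(FALSE, nrow(x)))
  }
  hit <- rep(FALSE, nrow(x))
  for (ch in unique(ivl$chrom)) {
    b <- ivl[ivl$chrom == ch, ]
    sel <- which(x$chrom == ch)
    if (length(sel) == 0) next
    for (k in seq_len(nrow(b))) {
      hit[sel] <- hit[sel] | (x$start[sel] < b$end[k] & x$end[sel] > b$start[k])
    }
  }
  hit
}

#' Remove intervals overlapping a blocklist
#'
#' Drops every row of `x` whose `[start, end)` interval overlaps a blocklist
#' interval by at least one base pair.
#'
#' @param x A tibble with `chrom`, `start`, `end` columns (clusters, peaks,
#'   motif sites, arbitrary intervals).
#' @param blocklist A tibble of blocklisted intervals (`chrom`, `start`,
#'   `end`), e.g. [blocklist_centromeric_hg38()]; `NULL` is a no-op.
#' @return `x` without blocklisted rows.
#' @export
filter_blocklist <- function(x, blocklist = NULL) {
  if (is.null(blocklist) || nrow(x) == 0) return(x)
  x[!overlaps_any(x, blocklist), , drop = FALSE]
}
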