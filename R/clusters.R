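# Fragment-center cluster calling: the footprint-detection unit for
# sequence-specific transcription factors. A center cluster (CC) is a
# fixed-width window holding at least `depth` fragment midpoints; clusters
# are selected greedily (highest count first, leftmost on ties) so that the
# returned set is pairwise non-overlapping.

#' Center-cluster parameters
#'
#' @param min_len,max_len Inclusive fragment-length gate (bp) applied before
#'   centers are computed.
#' @param window Scanning window width in bp.
#' @param depth Minimum number of fragment centers a window must hold.
#' @return A list of class `cc_params`.
#' @seealso [cc_preset()] for the published parameterizations.
#' @export
cc_params <- function(min_len, max_len, window, depth) {
  stopifnot(min_len <= max_len, window >= 1, depth >= 1)
  structure(
    list(min_len = as.integer(min_len), max_len = as.integer(max_len),
         window = as.integer(window), depth = as.integer(depth)),
    class = "cc_params"
  )
}

#' Published center-cluster parameterizations
#'
#' Three presets: `"ctcf-native"` (50–75 bp fragments, 25 bp window, depth
#' 50) for tightly positioned native CTCF footprints; `"ctcf-xlink"`
#' (50–100 bp, 100 bp window, depth 50) for crosslinked CTCF; `"irf"`
#' (40–200 bp, 200 bp window, depth 100) for IRF-site discovery in GR
#' libraries.
#'
#' @param preset Preset name.
#' @return A [cc_params()] object.
#' @export
cc_preset <- function(preset = c("ctcf-native", "ctcf-xlink", "irf")) {
  switch(match.arg(preset),
    "ctcf-native" = cc_params(50, 75, 25, 50),
    "ctcf-xlink" = cc_params(50, 100, 100, 50),
    "irf" = cc_params(40, 200, 200, 100)
  )
}

#' Fragment centers after a length gate
#'
#' Emits `floor((start + end) / 2)` for every fragment whose length passes
#' the inclusive gate.
#'
#' @param frags Fragment tibble.
#' @param min_len,max_len Inclusive length gate; `NULL` disables a bound.
#' @return A tibble (`chrom`, `center`) sorted by chromosome and position.
#' @export
fragment_centers <- function(frags, min_len = NULL, max_len = NULL) {
  frags <- as_fragment_tbl(frags)
  len <- frags$end - frags$start
  keep <- rep(TRUE, nrow(frags))
  if (!is.null(min_len)) keep <- keep & len >= min_len
  if (!is.null(max_len)) keep <- keep & len <= max_len
  out <- tibble(
    chrom = frags$chrom[keep],
    center = (frags$start[keep] + frags$end[keep]) %/% 2L
  )
  arrange(out, .data$chrom, .data$center)
}

cluster_centers_chrom <- function(centers, window, depth) {
  centers <- sort(centers)
  lo <- max(0L, min(centers) - window + 1L)
  hi <- max(centers)
  # window-start score f[s] = number of centers in [s, s + window)
  span <- hi + window - lo
  pos_counts <- tabulate(centers - lo + 1L, nbins = span)
  cum <- c(0, cumsum(pos_counts))
  starts <- lo:hi
  f <- cum[starts - lo + window + 1L] - cum[starts - lo + 1L]
  out <- list()
  repeat {
    i <- which.max(f) # leftmost maximum
    if (f[i] < depth) break
    s <- starts[i]
    inside <- centers[centers >= s & centers < s + window]
    tab <- tabulate(inside - s + 1L, nbins = window)
    out[[length(out) + 1L]] <- tibble(
      start = s, end = s + window, center_count = length(inside),
      modal_center = s + which.max(tab) - 1L,
      mean_center = mean(inside)
    )
    # suppress every window overlapping the accepted one
    kill <- max(1L, i - window + 1L):min(length(f), i + window - 1L)
    f[kill] <- -1L
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), center_count = integer(),
                  modal_center = integer(), mean_center = numeric()))
  }
  arrange(bind_rows(out), .data$start)
}

#' Call center clusters from sorted centers
#'
#' Scores every window of width `window` at 1-bp offsets by the number of
#' centers it holds, then greedily accepts the highest-scoring window
#' (leftmost on ties), suppresses all windows overlapping an accepted one,
#' and repeats until no remaining window reaches `depth`.
#'
#' @param centers Tibble from [fragment_centers()].
#' @param window Window width in bp.
#' @param depth Minimum centers per cluster.
#' @return Cluster tibble: `chrom`, `start`, `end`, `center_count`,
#'   `modal_center` (most frequent center, leftmost on ties), `mean_center`.
#' @export
cluster_centers <- function(centers, window, depth) {
  if (nrow(centers) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  center_count = integer(), modal_center = integer(),
                  mean_center = numeric()))
  }
  pieces <- lapply(split(centers, centers$chrom), function(d) {
    ccs <- cluster_centers_chrom(d$center, window, depth)
    if (nrow(ccs) > 0) ccs$chrom <- d$chrom[1]
    ccs
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  center_count = integer(), modal_center = integer(),
                  mean_center = numeric()))
  }
  arrange(
    dplyr::select(out, "chrom", "start", "end", "center_count",
                  "modal_center", "mean_center"),
    .data$chrom, .data$start
  )
}

#' Call center clusters from fragments
#'
#' Applies the length gate of `params`, computes fragment centers, and calls
#' non-overlapping center clusters (see [cluster_centers()] for the scanning
#' scheme).
#'
#' @param frags Fragment tibble.
#' @param params A [cc_params()] object or preset name for [cc_preset()].
#' @param blocklist Optional blocklist tibble; overlapping clusters are
#'   removed.
#' @return Cluster tibble as in [cluster_centers()], with the parameters in
#'   attribute `params`.
#' @export
call_center_clusters <- function(frags, params = cc_preset("ctcf-native"),
                                 blocklist = NULL) {
  if (is.character(params)) params <- cc_preset(params)
  stopifnot(inherits(params, "cc_params"))
  centers <- fragment_centers(frags, params$min_len, params$max_len)
  ccs <- cluster_centers(centers, params$window, params$depth)
  ccs <- filter_blocklist(ccs, blocklist)
  attr(ccs, "params") <- params
  ccs
}

#' Expand clusters to a fixed width
#'
#' Replaces each cluster interval by a `width`-bp interval centered on the
#' floored cluster midpoint: `[c - floor(width/2), c - floor(width/2) + width)`
#' with `c = floor((start + end) / 2)`. Used e.g. to expand 25-bp clusters to
#' 125 bp before motif discovery. Intervals are clipped at chromosome ends
#' (with a warning and a `clipped` flag) when `genome` is supplied.
#'
#' @param ccs Cluster tibble.
#' @param width Target width in bp; must be at least the current width.
#' @param genome Optional chromosome sizes tibble for clipping.
#' @return A tibble `chrom`, `start`, `end`, `clipped`.
#' @export
expand_clusters <- function(ccs, width, genome = NULL) {
  if (nrow(ccs) > 0 && any(width < ccs$end - ccs$start)) {
    stop("target width is smaller than a cluster width")
  }
  mid <- (ccs$start + ccs$end) %/% 2L
  start <- mid - width %/% 2L
  end <- start + as.integer(width)
  out <- tibble(chrom = ccs$chrom, start = start, end = end, clipped = FALSE)
  low <- out$start < 0L
  out$start[low] <- 0L
  out$clipped <- low
  if (!is.null(genome)) {
    sz <- genome$size[match(out$chrom, genome$chrom)]
    high <- !is.na(sz) & out$end > sz
    out$end[high] <- sz[high]
    out$clipped <- out$clipped | high
  }
  if (any(out$clipped)) {
    warning(sum(out$clipped), " expanded interval(s) clipped at chromosome ends")
  }
  out
}

#' Write the cluster table
#'
#' Tab-delimited with one header line: `chrom start end center_count
#' modal_center mean_center`.
#'
#' @param ccs Cluster tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(ccs, path) {
  readr::write_tsv(
    ccs[, c("chrom", "start", "end", "center_count", "modal_center",
            "mean_center")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write clusters as BED6 with the center count as score
#'
#' @param ccs Cluster tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(ccs, path) {
  out <- tibble(
    chrom = ccs$chrom, start = ccs$start, end = ccs$end,
    name = sprintf("CC_%d", seq_len(nrow(ccs))),
    score = ccs$center_count, strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
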