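# ChIP-Seq peak calling: 25-bp binning, chain filtering, candidate
# detection, valley-rule resolution, Gaussian summit refinement and
# thresholding/blocklisting.

#' Peak-calling parameters
#'
#' Defaults reproduce the reference parameterization: 25 bp bins, an 8-bin
#' (200 bp) chain requirement, the 60% valley rule, a 200 bp separation
#' override, a 400 bp Gaussian fit window, a 10 bp summit line, and a strict
#' >75-read threshold.
#'
#' @param bin_width Bin width in bp.
#' @param chain_len Minimum run of consecutive above-floor bins for a bin to
#'   survive chain filtering.
#' @param valley_frac Two candidates are well separated when the minimum bin
#'   strictly between them is below this fraction of the smaller candidate.
#' @param max_separation Candidates farther apart than this (bp) are kept
#'   regardless of the valley rule.
#' @param fit_width Width (bp) of the Gaussian used for summit refinement;
#'   bins within `fit_width` of the candidate center enter the fit and reads
#'   are summed over `fit_width/2` either side of the fitted center.
#' @param summit_line Width (bp) of the line drawn over the fitted summit.
#' @param min_reads Peaks must have strictly more reads than this.
#' @param chain_floor Bins must exceed this value to count as occupied in
#'   chain filtering.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(bin_width = 25L, chain_len = 8L, valley_frac = 0.60,
                        max_separation = 200L, fit_width = 400L,
                        summit_line = 10L, min_reads = 75, chain_floor = 0) {
  stopifnot(
    bin_width > 0, chain_len >= 1, valley_frac > 0, valley_frac < 1,
    fit_width > 0, fit_width %% bin_width == 0, summit_line > 0
  )
  structure(
    list(
      bin_width = as.integer(bin_width), chain_len = as.integer(chain_len),
      valley_frac = valley_frac, max_separation = max_separation,
      fit_width = as.integer(fit_width), summit_line = as.integer(summit_line),
      min_reads = min_reads, chain_floor = chain_floor
    ),
    class = "peak_params"
  )
}

#' Bin fragment midpoints into a fixed-width track
#'
#' Each fragment counts once, in the bin containing its midpoint
#' `floor((start + end) / 2)`; bin `i` spans `[i * bin_width, (i+1) * bin_width)`.
#' The track is dense: every bin of every chromosome in `genome` is present.
#'
#' @param frags Fragment tibble.
#' @param genome Chromosome sizes tibble.
#' @param bin_width Bin width in bp (default 25).
#' @return A bin-track tibble (`chrom`, `bin`, `count`) with attribute
#'   `bin_width`.
#' @export
bin_fragments <- function(frags, genome, bin_width = 25L) {
  frags <- as_fragment_tbl(frags)
  validate_fragments(frags, genome = genome)
  tracks <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    nb <- as.integer(ceiling(genome$size[i] / bin_width))
    d <- frags[frags$chrom == ch, ]
    mid <- (d$start + d$end) %/% 2L
    cnt <- tabulate(mid %/% bin_width + 1L, nbins = nb)
    tibble(chrom = ch, bin = seq_len(nb) - 1L, count = as.numeric(cnt))
  })
  out <- bind_rows(tracks)
  attr(out, "bin_width") <- as.integer(bin_width)
  out
}

track_bin_width <- function(track, default = 25L) {
  bw <- attr(track, "bin_width")
  if (is.null(bw)) as.integer(default) else bw
}

# Apply a per-chromosome vector transform to a dense bin track.
track_transform <- function(track, f) {
  bw <- track_bin_width(track)
  pieces <- lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$bin), ]
    d$count <- f(d$count)
    d
  })
  out <- bind_rows(pieces)
  attr(out, "bin_width") <- bw
  out
}

#' Library-size-normalized background subtraction
#'
#' Scales the control track by `lib_treatment / lib_control` and subtracts it
#' from the treatment track, clamping negative bins to zero. Used to remove
#' background (e.g. an untreated control) before peak calling.
#'
#' @param treatment,control Dense bin tracks from [bin_fragments()] over the
#'   same genome and bin width.
#' @param lib_treatment,lib_control Library sizes (reads); default to the
#'   total counts of each track.
#' @return A bin track of the clamped difference, with attribute
#'   `scale_factor`.
#' @export
subtract_background <- function(treatment, control,
                                lib_treatment = NULL, lib_control = NULL) {
  if (is.null(lib_treatment)) lib_treatment <- sum(treatment$count)
  if (is.null(lib_control)) lib_control <- sum(control$count)
  if (lib_control == 0) stop("control library size is zero")
  scale <- lib_treatment / lib_control
  merged <- inner_join(
    treatment, control,
    by = c("chrom", "bin"), suffix = c("_t", "_c")
  )
  if (nrow(merged) != nrow(treatment)) {
    stop("treatment and control tracks do not share the same bins")
  }
  out <- tibble(
    chrom = merged$chrom, bin = merged$bin,
    count = pmax(0, merged$count_t - merged$count_c * scale)
  )
  attr(out, "bin_width") <- track_bin_width(treatment)
  attr(out, "scale_factor") <- scale
  out
}

#' Zero bins outside long occupied chains
#'
#' A bin survives only if it sits inside a run of at least `chain_len`
#' consecutive bins whose value exceeds `floor`; all other bins are set to
#' zero. With the defaults this removes any bin not part of an 8-bin
#' (200 bp) chain of occupied bins.
#'
#' @param track Dense bin track.
#' @param chain_len Minimum run length in bins.
#' @param floor Occupancy floor; bins must be strictly greater to count.
#' @return The chain-filtered track.
#' @export
chain_filter <- function(track, chain_len = 8L, floor = 0) {
  stopifnot(chain_len >= 1)
  track_transform(track, function(v) {
    r <- rle(v > floor)
    keep <- rep(r$values & r$lengths >= chain_len, r$lengths)
    v[!keep] <- 0
    v
  })
}

candidate_bins_vec <- function(v) {
  # Chromosome edges behave as zero-count neighbours; plateau tie-break is
  # strict > on the left, >= on the right (leftmost plateau bin wins).
  prev <- c(0, head(v, -1))
  nxt <- c(tail(v, -1), 0)
  which(v > prev & v >= nxt)
}

#' Candidate peak bins
#'
#' Bins with higher signal than the immediately adjacent upstream bin and at
#' least the downstream bin (so the leftmost bin of a plateau is the
#' candidate); chromosome edges are treated as zero.
#'
#' @param track Dense bin track, normally after [chain_filter()].
#' @return Tibble of candidates: `chrom`, `bin`, `count`.
#' @export
find_candidate_bins <- function(track) {
  pieces <- lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$bin), ]
    idx <- candidate_bins_vec(d$count)
    tibble(chrom = d$chrom[idx], bin = d$bin[idx], count = d$count[idx])
  })
  arrange(bind_rows(pieces), .data$chrom, .data$bin)
}

resolve_chrom <- function(bins, heights, counts, bin_width, valley_frac,
                          max_separation) {
  n <- length(bins)
  if (n == 0) return(integer())
  accepted <- 1L
  last <- 1L
  for (j in seq_len(n)[-1]) {
    sep_bp <- (bins[j] - bins[last]) * bin_width
    ok <- sep_bp > max_separation
    if (!ok) {
      between <- counts[(bins[last] + 1L):(bins[j] - 1L) + 1L]
      # adjacent candidates have no bin strictly between them: not separated
      if (bins[j] - bins[last] >= 2L) {
        valley <- min(between)
        ok <- valley < valley_frac * min(heights[last], heights[j])
      }
    }
    if (ok) {
      accepted <- c(accepted, j)
      last <- j
    }
  }
  accepted
}

#' Resolve candidate peaks by the valley and separation rules
#'
#' Scans candidates left to right per chromosome. The first candidate is
#' accepted; each subsequent candidate is accepted if the minimum bin
#' strictly between it and the last accepted candidate is below
#' `valley_frac` of the smaller of the two candidate heights, or if the two
#' candidates are more than `max_separation` bp apart. Rejected candidates
#' are discarded and the scan continues against the same accepted peak.
#'
#' @param candidates Tibble from [find_candidate_bins()].
#' @param track The dense bin track the candidates were called on.
#' @param params [peak_params()].
#' @return The accepted subset of `candidates`.
#' @export
resolve_candidates <- function(candidates, track, params = peak_params()) {
  bw <- track_bin_width(track, params$bin_width)
  pieces <- lapply(split(candidates, candidates$chrom), function(d) {
    d <- d[order(d$bin), ]
    tr <- track[track$chrom == d$chrom[1], ]
    v <- tr$count[order(tr$bin)]
    keep <- resolve_chrom(d$bin, d$count, v, bw, params$valley_frac,
                          params$max_separation)
    d[keep, ]
  })
  arrange(bind_rows(pieces), .data$chrom, .data$bin)
}

fit_gaussian_bins <- function(x, y, a0, mu0, sigma0, sigma_lo, sigma_hi) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      start = list(A = a0, mu = mu0, sigma = sigma0),
      lower = c(A = 0, mu = min(x), sigma = sigma_lo),
      upper = c(A = Inf, mu = max(x), sigma = sigma_hi),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(A = a0, mu = mu0, sigma = sigma0, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), mu = unname(cf["mu"]),
       sigma = unname(cf["sigma"]), converged = TRUE)
}

#' Refine summits by Gaussian fitting
#'
#' For each accepted candidate, least-squares fits
#' `A * exp(-(x - mu)^2 / (2 * sigma^2))` to the bin counts whose centers lie
#' within `fit_width` bp of the candidate bin center, initialized at the bin
#' height, the bin center and `sigma = fit_width / 4` (so a 400 bp fit
#' window starts at sigma = 100 bp). `reads_in_peak` sums the counts of bins
#' whose centers fall in `[mu - fit_width/2, mu + fit_width/2)`. Fits that
#' fail fall back to the initialization and are flagged `converged = FALSE`.
#'
#' @param track Dense bin track (the track whose reads are being counted).
#' @param accepted Tibble of accepted candidates from [resolve_candidates()].
#' @param params [peak_params()].
#' @return A peak tibble: `chrom`, `candidate_bin`, `mu`, `amplitude`,
#'   `sigma`, `reads_in_peak`, `summit_start`, `summit_end`, `converged`.
#' @export
fit_summits <- function(track, accepted, params = peak_params()) {
  bw <- track_bin_width(track, params$bin_width)
  fw <- params$fit_width
  half_line <- params$summit_line / 2
  rows <- purrr::pmap(
    list(accepted$chrom, accepted$bin, accepted$count),
    function(ch, b, h) {
      d <- track[track$chrom == ch, ]
      d <- d[order(d$bin), ]
      centers <- d$bin * bw + bw / 2
      c0 <- b * bw + bw / 2
      sel <- abs(centers - c0) <= fw
      fit <- fit_gaussian_bins(
        centers[sel], d$count[sel],
        a0 = h, mu0 = c0, sigma0 = fw / 4, sigma_lo = bw, sigma_hi = fw
      )
      in_peak <- centers >= fit$mu - fw / 2 & centers < fit$mu + fw / 2
      reads <- sum(d$count[in_peak])
      tibble(
        chrom = ch, candidate_bin = b, mu = fit$mu, amplitude = fit$A,
        sigma = fit$sigma, reads_in_peak = reads,
        summit_start = as.integer(round(fit$mu - half_line)),
        summit_end = as.integer(round(fit$mu - half_line) + params$summit_line),
        converged = fit$converged
      )
    }
  )
  if (length(rows) == 0) {
    return(tibble(
      chrom = character(), candidate_bin = integer(), mu = numeric(),
      amplitude = numeric(), sigma = numeric(), reads_in_peak = numeric(),
      summit_start = integer(), summit_end = integer(), converged = logical()
    ))
  }
  bind_rows(rows)
}

#' Threshold and blocklist peaks
#'
#' Retains peaks with strictly more than `min_reads` reads whose 10-bp
#' summit line does not overlap any blocklist interval.
#'
#' @param peaks Peak tibble from [fit_summits()].
#' @param min_reads Strict lower bound on `reads_in_peak` (default 75).
#' @param blocklist Optional blocklist tibble (`chrom`, `start`, `end`),
#'   e.g. [blocklist_centromeric_hg38()].
#' @return The retained peaks.
#' @export
filter_peaks <- function(peaks, min_reads = 75, blocklist = NULL) {
  peaks <- peaks[peaks$reads_in_peak > min_reads, , drop = FALSE]
  if (!is.null(blocklist) && nrow(peaks) > 0) {
    lines <- tibble(chrom = peaks$chrom, start = peaks$summit_start,
                    end = peaks$summit_end)
    peaks <- peaks[!overlaps_any(lines, blocklist), , drop = FALSE]
  }
  peaks
}

#' Call peaks from fragments
#'
#' Runs the full pipeline: midpoint binning, optional library-size-normalized
#' background subtraction, chain filtering, candidate detection, valley-rule
#' resolution, Gaussian summit refinement, and threshold/blocklist filtering.
#'
#' @param frags Treatment fragment tibble.
#' @param genome Chromosome sizes tibble.
#' @param control Optional control fragment tibble to subtract.
#' @param params [peak_params()].
#' @param blocklist Optional blocklist tibble.
#' @param lib_treatment,lib_control Library sizes for the subtraction scale
#'   factor; default to fragment counts.
#' @return An object of class `dff_peaks`: use [tidy()] for the per-peak
#'   table, [glance()] for a one-row summary, [autoplot()] to plot.
#' @export
call_peaks <- function(frags, genome, control = NULL, params = peak_params(),
                       blocklist = NULL, lib_treatment = NULL,
                       lib_control = NULL) {
  track <- bin_fragments(frags, genome, params$bin_width)
  scale_factor <- NA_real_
  if (!is.null(control)) {
    ctrack <- bin_fragments(control, genome, params$bin_width)
    if (is.null(lib_treatment)) lib_treatment <- nrow(frags)
    if (is.null(lib_control)) lib_control <- nrow(control)
    track <- subtract_background(track, ctrack, lib_treatment, lib_control)
    scale_factor <- attr(track, "scale_factor")
  }
  filtered <- chain_filter(track, params$chain_len, params$chain_floor)
  cands <- find_candidate_bins(filtered)
  accepted <- resolve_candidates(cands, filtered, params)
  peaks <- fit_summits(filtered, accepted, params)
  kept <- filter_peaks(peaks, params$min_reads, blocklist)
  structure(
    list(
      peaks = kept, params = params, n_candidates = nrow(cands),
      n_accepted = nrow(accepted), n_fragments = nrow(frags),
      scale_factor = scale_factor
    ),
    class = "dff_peaks"
  )
}

#' Write summit lines as bedGraph
#'
#' Emits one 10-bp line per peak (`chrom`, `mu - 5`, `mu + 5`,
#' `reads_in_peak`).
#'
#' @param peaks Peak tibble (or `dff_peaks` object).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summit_bedgraph <- function(peaks, path) {
  if (inherits(peaks, "dff_peaks")) peaks <- peaks$peaks
  out <- tibble(chrom = peaks$chrom, start = peaks$summit_start,
                end = peaks$summit_end, count = peaks$reads_in_peak)
  write_bedgraph(out, path)
}

#' @export
print.dff_peaks <- function(x, ...) {
  cat(sprintf(
    "<dff_peaks> %d peaks (%d candidates, %d accepted) from %d fragments\n",
    nrow(x$peaks), x$n_candidates, x$n_accepted, x$n_fragments
  ))
  print(x$peaks, ...)
  invisible(x)
}
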