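# PWM handling, genome-wide motif scanning with exact lattice p-values, and
# coverage-based selection of occupied motif sites.

BASES <- c("A", "C", "G", "T")

new_pwm <- function(mat, background = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) == 4)
  colnames(mat) <- BASES
  sums <- rowSums(mat)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("PWM rows must each sum to 1 (tolerance 1e-6)")
  }
  mat <- mat / sums
  if (nrow(mat) < 4) stop("PWM width must be >= 4")
  structure(mat, class = c("dff_pwm", "matrix"), background = background)
}

#' Read a position weight matrix
#'
#' Accepts MEME minimal motif format (the first motif in the file; the
#' background line is honoured when present) or a plain whitespace-separated
#' table with four columns of per-position probabilities in A, C, G, T
#' order (an optional `A C G T` header line is allowed).
#'
#' @param path Input file.
#' @param format `"auto"` (detect a `MEME version` header), `"meme"` or
#'   `"table"`.
#' @return A `dff_pwm` matrix (positions x A,C,G,T) with an optional
#'   `background` attribute.
#' @export
read_pwm <- function(path, format = c("auto", "meme", "table")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "table"
  }
  if (format == "meme") {
    bg <- NULL
    bg_at <- grep("^Background letter frequencies", lines)
    if (length(bg_at) > 0) {
      toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      bg <- vals[!is.na(vals)]
      if (length(bg) != 4) bg <- NULL
    }
    hdr <- grep("letter-probability matrix", lines)
    if (length(hdr) == 0) stop("no letter-probability matrix in ", path)
    w <- as.integer(stringr::str_match(lines[hdr[1]], "w=\\s*(\\d+)")[, 2])
    rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    new_pwm(mat, background = bg)
  } else {
    rows <- lines[trimws(lines) != ""]
    first <- strsplit(trimws(rows[1]), "\\s+")[[1]]
    if (all(toupper(first) %in% BASES)) rows <- rows[-1]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    new_pwm(mat)
  }
}

#' Build a PWM from a consensus sequence
#'
#' Each position assigns `strength` to the consensus base and splits the
#' remainder over the other three; `N` positions are uniform.
#'
#' @param consensus A string over `ACGTN`, length >= 4.
#' @param strength Probability of the consensus base (default 0.997).
#' @return A `dff_pwm` matrix.
#' @export
pwm_from_consensus <- function(consensus, strength = 0.997) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(chars %in% c(BASES, "N")), length(chars) >= 4)
  mat <- t(vapply(chars, function(ch) {
    if (ch == "N") rep(0.25, 4)
    else ifelse(BASES == ch, strength, (1 - strength) / 3)
  }, numeric(4)))
  rownames(mat) <- NULL
  new_pwm(mat)
}

revcomp_pwm <- function(pwm) {
  m <- unclass(pwm)[nrow(pwm):1, c("T", "G", "C", "A")]
  colnames(m) <- BASES
  m
}

# Discretized log-odds lattice and the exact null score distribution
# (dynamic programming over positions, background-weighted).
pwm_lattice <- function(lo, background) {
  rng <- max(lo) - min(lo)
  eps <- if (rng == 0) 1 else rng / 1000
  s_int <- round(lo / eps)
  mins <- apply(s_int, 1, min)
  shifted <- s_int - mins
  total <- sum(apply(shifted, 1, max))
  dist <- 1
  for (k in seq_len(nrow(shifted))) {
    nd <- numeric(length(dist) + max(shifted[k, ]))
    for (l in 1:4) {
      sh <- shifted[k, l]
      nd[(sh + 1):(sh + length(dist))] <-
        nd[(sh + 1):(sh + length(dist))] + background[l] * dist
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist)))
  tail_p <- pmin(tail_p, 1)
  list(eps = eps, s_int = s_int, shift0 = sum(mins), tail_p = tail_p,
       dist = dist, total = total)
}

scan_strand <- function(codes, lat, w) {
  n <- length(codes) - w + 1L
  if (n < 1) return(list(score = numeric(), p = numeric(), offset = integer()))
  acc <- numeric(n)
  for (k in seq_len(w)) {
    contrib <- lat$s_int[k, ][codes[k:(k + n - 1L)]]
    contrib[is.na(contrib)] <- 0 # N scores as background
    acc <- acc + contrib
  }
  shifted <- pmin(pmax(acc - lat$shift0, 0), lat$total)
  list(score = acc * lat$eps, p = lat$tail_p[shifted + 1L],
       offset = seq_len(n))
}

seq_as_codes <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  match(chars, BASES) # N and friends become NA
}

genome_sequences <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
    return(seqs)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("genome must be a FASTA path, DNAStringSet, or named character vector")
}

#' Scan a genome with a PWM
#'
#' Scores every window on both strands with log-odds against the background
#' and keeps sites whose exact p-value is at most `p_thresh`. P-values come
#' from the full null score distribution computed by dynamic programming
#' over a discretized score lattice (the same lattice scores the windows, so
#' p-values are exact for the reported scores and monotone in them). The
#' minus strand is scanned with the reverse-complemented PWM; overlapping
#' opposite-strand hits are both reported. Non-ACGT characters score as
#' background.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @param pwm A `dff_pwm` from [read_pwm()] or [pwm_from_consensus()].
#' @param p_thresh P-value threshold in (0, 1]; default `1e-4`.
#' @param background Length-4 A,C,G,T background probabilities. Defaults to
#'   the PWM's embedded background if present, otherwise the genome-wide
#'   mononucleotide frequencies.
#' @param pseudocount Added to every PWM cell before log-odds (default
#'   `1e-4`).
#' @return A site tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `score` (discretized log2 odds), `p_value`.
#' @export
scan_pwm <- function(genome, pwm, p_thresh = 1e-4, background = NULL,
                     pseudocount = 1e-4) {
  stopifnot(p_thresh > 0, p_thresh <= 1)
  seqs <- genome_sequences(genome)
  if (is.null(background)) background <- attr(pwm, "background")
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                        "")), levels = BASES))
    # add-one smoothing keeps the background positive on skewed sequences
    background <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  }
  if (any(background <= 0)) {
    stop("background probabilities must be positive for all of A, C, G, T")
  }
  background <- background / sum(background)
  p <- unclass(pwm) + pseudocount
  p <- p / rowSums(p)
  w <- nrow(p)
  lo_fwd <- log2(sweep(p, 2, background, "/"))
  rc <- revcomp_pwm(new_pwm(p))
  lo_rev <- log2(sweep(rc, 2, background, "/"))
  lat_fwd <- pwm_lattice(lo_fwd, background)
  lat_rev <- pwm_lattice(lo_rev, background)
  out <- list()
  for (ch in names(seqs)) {
    codes <- seq_as_codes(seqs[[ch]])
    for (str in c("+", "-")) {
      lat <- if (str == "+") lat_fwd else lat_rev
      hit <- scan_strand(codes, lat, w)
      keep <- hit$p <= p_thresh
      if (!any(keep)) next
      out[[length(out) + 1L]] <- tibble(
        chrom = ch,
        start = hit$offset[keep] - 1L,
        end = hit$offset[keep] - 1L + w,
        strand = str,
        score = hit$score[keep],
        p_value = hit$p[keep]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(),
                  p_value = numeric()))
  }
  arrange(bind_rows(out), .data$chrom, .data$start, .data$strand)
}

#' Select occupied motif sites by fragment coverage
#'
#' Counts, for every site, the fragments whose span fully contains the motif
#' interval (`rule = "contain"`, matching reads that cover the whole motif)
#' or that overlap it by at least 1 bp (`rule = "overlap"`), and keeps sites
#' whose count reaches `min_reads` (`>=` by default; `strict = TRUE` demands
#' `>`).
#'
#' @param sites Site tibble from [scan_pwm()] (any `chrom`/`start`/`end`
#'   tibble works).
#' @param frags Fragment tibble.
#' @param min_reads Read threshold (default 200).
#' @param rule `"contain"` (default) or `"overlap"`.
#' @param strict Use a strict `>` comparison instead of `>=`.
#' @return The retained sites with an `n_fragments` column.
#' @export
filter_sites_by_coverage <- function(sites, frags, min_reads = 200L,
                                     rule = c("contain", "overlap"),
                                     strict = FALSE) {
  rule <- match.arg(rule)
  frags <- as_fragment_tbl(frags)
  sites <- as_tibble(sites)
  sites$.site <- seq_len(nrow(sites))
  pairs <- inner_join(
    sites, dplyr::select(frags, "chrom", f_start = "start", f_end = "end"),
    by = "chrom", relationship = "many-to-many"
  )
  covered <- if (rule == "contain") {
    pairs$f_start <= pairs$start & pairs$f_end >= pairs$end
  } else {
    pairs$f_start < pairs$end & pairs$f_end > pairs$start
  }
  counts <- tabulate(pairs$.site[covered], nbins = nrow(sites))
  sites$n_fragments <- counts
  keep <- if (strict) counts > min_reads else counts >= min_reads
  dplyr::select(sites[keep, , drop = FALSE], -".site")
}
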