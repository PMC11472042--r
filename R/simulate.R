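# Synthetic genomes and footprint-fragment libraries with known truth.
# Emulates the protection classes a blunt-cutting, footprint-respecting
# nuclease leaves behind: ~70 bp transcription-factor footprints, 65-85 bp
# preinitiation complexes, 40-60 bp engaged polymerase, ~147 bp nucleosomes
# and 160-210 bp factor+nucleosome composites, over a background nucleosome
# ladder.

#' Describe a protection class
#'
#' @param class_name Class label, e.g. `"TF"`, `"PIC"`, `"pausedPol"`,
#'   `"nucleosome"`, `"composite"`.
#' @param length_range Inclusive protection length range in bp (within
#'   10–1000); a site's protection length is drawn uniformly from it.
#' @param fragments_per_site Fragments emitted per planted site.
#' @param end_jitter_sd SD (bp) of the Normal noise applied to fragment
#'   boundaries.
#' @param motif Optional motif sequence embedded at the center of each
#'   planted site (string over ACGT).
#' @return A list of class `footprint_spec`.
#' @export
footprint_spec <- function(class_name, length_range,
                           fragments_per_site = 60L, end_jitter_sd = 3,
                           motif = NULL) {
  stopifnot(
    length(length_range) == 2, length_range[1] <= length_range[2],
    length_range[1] >= 10, length_range[2] <= 1000,
    end_jitter_sd >= 0, fragments_per_site >= 0
  )
  structure(
    list(class_name = class_name,
         length_range = as.integer(length_range),
         fragments_per_site = as.integer(fragments_per_site),
         end_jitter_sd = end_jitter_sd, motif = motif),
    class = "footprint_spec"
  )
}

#' Default protection classes
#'
#' The feature sizes the method resolves: TF footprints (~70 bp), PICs
#' (65–85 bp), engaged polymerase (40–60 bp), nucleosomes (~147 bp) and
#' factor+nucleosome composites (160–210 bp).
#'
#' @return A named list of [footprint_spec()] objects.
#' @export
protection_classes <- function() {
  list(
    TF = footprint_spec("TF", c(65, 75)),
    PIC = footprint_spec("PIC", c(65, 85)),
    pausedPol = footprint_spec("pausedPol", c(40, 60)),
    nucleosome = footprint_spec("nucleosome", c(140, 154)),
    composite = footprint_spec("composite", c(160, 210))
  )
}

#' Simulate a genome with planted footprint sites
#'
#' Draws a random sequence at the stated GC content, places `n_sites`
#' non-overlapping sites per spec (uniformly, rejecting overlaps), embeds
#' each spec's motif (if any) at the site center, and records the truth.
#' Deterministic under `seed`.
#'
#' @param length Genome length in bp (single chromosome).
#' @param gc GC fraction of the background sequence.
#' @param specs List of [footprint_spec()] objects.
#' @param n_sites Sites per spec (recycled across specs).
#' @param seed Integer seed; all randomness flows from it.
#' @param chrom Chromosome name.
#' @return A list with `sequence` (named character), `genome` (chrom sizes
#'   tibble), `truth` (tibble: `chrom`, `center`, `class`, `start`, `end`,
#'   `motif_start`, `motif_end`) and `specs`.
#' @export
simulate_genome <- function(length, gc = 0.41, specs, n_sites, seed = 1L,
                            chrom = "chrS") {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  if (inherits(specs, "footprint_spec")) specs <- list(specs)
  n_sites <- rep_len(as.integer(n_sites), length(specs))
  withr::local_seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(probs), length, replace = TRUE, prob = probs)
  # place sites without overlap; margin keeps protections inside the genome
  margin <- max(vapply(specs, function(s) s$length_range[2], numeric(1)))
  if (sum(n_sites) * 2 * margin > 0.5 * length) {
    stop("overcrowded genome: requested sites cannot be placed without overlap")
  }
  occupied_lo <- integer() # placed protection intervals
  occupied_hi <- integer()
  truth <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    placed <- 0L
    tries <- 0L
    while (placed < n_sites[si]) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_sites[si])) {
        stop("overcrowded genome: could not place all sites for class ",
             spec$class_name)
      }
      len <- sample_range(spec$length_range[1], spec$length_range[2], 1L)
      center <- sample(seq.int(margin + 1L, length - margin - 1L), 1L)
      lo <- center - len %/% 2L
      hi <- lo + len
      if (any(lo < occupied_hi + 50L & hi > occupied_lo - 50L)) next
      occupied_lo <- c(occupied_lo, lo)
      occupied_hi <- c(occupied_hi, hi)
      motif_start <- NA_integer_
      motif_end <- NA_integer_
      if (!is.null(spec$motif)) {
        mlen <- nchar(spec$motif)
        motif_start <- center - mlen %/% 2L
        motif_end <- motif_start + mlen
        chars[(motif_start + 1L):motif_end] <-
          strsplit(toupper(spec$motif), "")[[1]]
      }
      truth[[length(truth) + 1L]] <- tibble(
        chrom = chrom, center = center, class = spec$class_name,
        start = lo, end = hi,
        motif_start = motif_start, motif_end = motif_end
      )
      placed <- placed + 1L
    }
  }
  truth <- if (length(truth) > 0) bind_rows(truth) else {
    tibble(chrom = character(), center = integer(), class = character(),
           start = integer(), end = integer(), motif_start = integer(),
           motif_end = integer())
  }
  seq <- paste(chars, collapse = "")
  names(seq) <- chrom
  list(
    sequence = seq,
    genome = tibble(chrom = chrom, size = as.integer(length)),
    truth = arrange(truth, .data$chrom, .data$start),
    specs = specs
  )
}

# sample() treats a length-1 vector as 1:n; guard degenerate ranges
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

random_umis <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a footprint-fragment library from planted truth
#'
#' Per planted site, emits `fragments_per_site` fragments whose boundaries
#' are the protection boundaries plus rounded `Normal(0, end_jitter_sd)`
#' noise (`jitter_mode = "ends"`), or whose whole span is shifted by one
#' such draw so the protection length is preserved
#' (`jitter_mode = "center"`). Fragment length is floored at 10 bp.
#' Background fragments are added at `background_rate` per kb with
#' nucleosome-ladder lengths (147, 294, 441 bp plus jitter) unless
#' `background_lengths` supplies an inclusive uniform length range. Optional
#' UMIs and flat-rate PCR duplicates (exact copies of existing fragments)
#' complete the library. Deterministic under `seed`.
#'
#' @param truth Truth tibble from [simulate_genome()] (columns `chrom`,
#'   `class`, `start`, `end`).
#' @param specs The spec list used to generate `truth` (matched by
#'   `class_name`).
#' @param genome Chromosome sizes tibble.
#' @param background_rate Background fragments per kb of genome.
#' @param background_lengths `NULL` for the nucleosome ladder, or `c(min,
#'   max)` for uniform lengths.
#' @param duplicate_rate Fraction of the library re-emitted as exact
#'   duplicates (same coordinates and UMI).
#' @param umi Attach random 8-nt UMIs.
#' @param seed Integer seed.
#' @param jitter_mode `"ends"` (independent boundary noise) or `"center"`
#'   (rigid shift preserving length).
#' @return A fragment tibble with attributes `n_duplicates_injected` and
#'   `n_background`.
#' @export
simulate_fragments <- function(truth, specs, genome, background_rate = 1,
                               background_lengths = NULL, duplicate_rate = 0,
                               umi = TRUE, seed = 1L,
                               jitter_mode = c("ends", "center")) {
  jitter_mode <- match.arg(jitter_mode)
  if (inherits(specs, "footprint_spec")) specs <- list(specs)
  spec_by_class <- stats::setNames(
    specs, vapply(specs, function(s) s$class_name, character(1))
  )
  withr::local_seed(seed)
  frag_list <- list()
  for (i in seq_len(nrow(truth))) {
    spec <- spec_by_class[[truth$class[i]]]
    if (is.null(spec)) stop("no spec for class ", truth$class[i])
    n <- spec$fragments_per_site
    if (n == 0) next
    if (jitter_mode == "ends") {
      s <- truth$start[i] + round(rnorm(n, 0, spec$end_jitter_sd))
      e <- truth$end[i] + round(rnorm(n, 0, spec$end_jitter_sd))
    } else {
      shift <- round(rnorm(n, 0, spec$end_jitter_sd))
      s <- truth$start[i] + shift
      e <- truth$end[i] + shift
    }
    e <- pmax(e, s + 10L) # minimum fragment length
    frag_list[[length(frag_list) + 1L]] <- tibble(
      chrom = truth$chrom[i], start = as.integer(s), end = as.integer(e),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  }
  # background
  n_background <- 0L
  for (gi in seq_len(nrow(genome))) {
    nb <- rpois(1, background_rate * genome$size[gi] / 1000)
    if (nb == 0) next
    n_background <- n_background + nb
    if (is.null(background_lengths)) {
      k <- sample(1:3, nb, replace = TRUE, prob = c(0.7, 0.2, 0.1))
      lens <- pmax(10L, as.integer(147L * k + round(rnorm(nb, 0, 10))))
    } else {
      lens <- sample_range(background_lengths[1], background_lengths[2], nb)
    }
    starts <- floor(runif(nb, 0, pmax(1, genome$size[gi] - lens)))
    frag_list[[length(frag_list) + 1L]] <- tibble(
      chrom = genome$chrom[gi], start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), nb, replace = TRUE)
    )
  }
  frags <- if (length(frag_list) > 0) bind_rows(frag_list) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character())
  }
  frags$umi <- if (umi && nrow(frags) > 0) random_umis(nrow(frags)) else {
    rep(NA_character_, nrow(frags))
  }
  n_dup <- round(duplicate_rate * nrow(frags))
  if (n_dup > 0) {
    frags <- bind_rows(frags, frags[sample(nrow(frags), n_dup, replace = TRUE), ])
  }
  out <- canonical_sort(as_fragment_tbl(frags))
  attr(out, "n_duplicates_injected") <- as.integer(n_dup)
  attr(out, "n_background") <- as.integer(n_background)
  out
}

#' Write a simulated genome to FASTA
#'
#' @param sim Result of [simulate_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequence), path)
  invisible(path)
}
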