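# Reading and writing the plain-text formats the toolkit consumes:
# chromosome sizes, BEDPE/BED fragments, SAM alignments, BED anchors.

#' Read a chromosome sizes table
#'
#' @param path Two-column tab-separated text: chromosome name, length in bp.
#' @return A tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "size"),
    col_types = readr::cols(chrom = "c", size = "d"),
    progress = FALSE
  )
  x$size <- as.integer(x$size)
  x
}

umi_from_name <- function(name) {
  m <- stringr::str_match(name, "[_:]([ACGTN]{8})$")[, 2]
  m
}

#' Read paired-end fragments
#'
#' Ingests one sequenced fragment per template from BEDPE (both mates on one
#' line), BED (one interval per fragment, optional UMI in column 7), or a
#' SAM/BAM alignment with proper pairs. For BEDPE/SAM the fragment span is
#' `[min(mate starts), max(mate ends))` and the strand recorded is mate 1's.
#' UMIs are recovered from a trailing `_XXXXXXXX` / `:XXXXXXXX` tag on the
#' read name (8 characters of `ACGTN`), or from BED column 7.
#'
#' Discordant/unmapped pairs and malformed lines are dropped; their counts
#' are attached as attributes `n_discordant` and `n_malformed` and reported
#' with a message.
#'
#' @param path Input file. Format is guessed from the extension unless given.
#' @param format One of `"auto"`, `"bedpe"`, `"bed"`, `"sam"`.
#' @param genome Optional chromosome sizes tibble; if supplied, records on
#'   unknown chromosomes raise an error naming the record.
#' @return A fragment tibble (`chrom`, `start`, `end`, `strand`, `umi`) in
#'   canonical (chrom, start, end) order.
#' @export
read_fragments <- function(path, format = c("auto", "bedpe", "bed", "sam"),
                           genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      bedpe = "bedpe",
      bed = "bed",
      sam = "sam",
      bam = "sam",
      stop("cannot guess format from extension of ", path)
    )
  }
  out <- switch(format,
    bedpe = read_fragments_bedpe(path),
    bed = read_fragments_bed(path),
    sam = read_fragments_sam(path)
  )
  frags <- canonical_sort(as_fragment_tbl(out$frags))
  validate_fragments(frags, genome = genome)
  attr(frags, "n_malformed") <- out$n_malformed
  attr(frags, "n_discordant") <- out$n_discordant
  if (out$n_malformed + out$n_discordant > 0) {
    message(sprintf(
      "read_fragments: dropped %d malformed and %d discordant/unmapped records",
      out$n_malformed, out$n_discordant
    ))
  }
  frags
}

read_raw_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(NULL)
  readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    comment = "#", progress = FALSE
  )
}

read_fragments_bedpe <- function(path) {
  x <- read_raw_tsv(path)
  if (is.null(x) || nrow(x) == 0) {
    return(list(frags = empty_fragments(), n_malformed = 0L, n_discordant = 0L))
  }
  if (ncol(x) < 10) stop("BEDPE requires at least 10 columns, got ", ncol(x))
  s1 <- suppressWarnings(as.integer(x[[2]]))
  e1 <- suppressWarnings(as.integer(x[[3]]))
  s2 <- suppressWarnings(as.integer(x[[5]]))
  e2 <- suppressWarnings(as.integer(x[[6]]))
  malformed <- is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2) |
    is.na(x[[1]]) | is.na(x[[4]])
  # bedtools marks unmapped mates with chrom "." and -1 coordinates
  discordant <- !malformed &
    (x[[1]] == "." | x[[4]] == "." | x[[1]] != x[[4]] | s1 < 0 | s2 < 0)
  keep <- !malformed & !discordant
  frags <- tibble(
    chrom = x[[1]][keep],
    start = pmin(s1[keep], s2[keep]),
    end = pmax(e1[keep], e2[keep]),
    strand = ifelse(x[[9]][keep] %in% c("+", "-"), x[[9]][keep], "*"),
    umi = umi_from_name(x[[7]][keep])
  )
  list(frags = frags, n_malformed = sum(malformed), n_discordant = sum(discordant))
}

read_fragments_bed <- function(path) {
  x <- read_raw_tsv(path)
  if (is.null(x) || nrow(x) == 0) {
    return(list(frags = empty_fragments(), n_malformed = 0L, n_discordant = 0L))
  }
  s <- suppressWarnings(as.integer(x[[2]]))
  e <- suppressWarnings(as.integer(x[[3]]))
  malformed <- is.na(s) | is.na(e) | is.na(x[[1]])
  keep <- !malformed
  strand <- if (ncol(x) >= 6) x[[6]][keep] else rep("*", sum(keep))
  umi <- rep(NA_character_, sum(keep))
  if (ncol(x) >= 7) {
    cand <- x[[7]][keep]
    ok <- !is.na(cand) & grepl("^[ACGTN]{8}$", cand)
    umi[ok] <- cand[ok]
  }
  if (ncol(x) >= 4) {
    from_name <- umi_from_name(x[[4]][keep])
    umi[is.na(umi)] <- from_name[is.na(umi)]
  }
  frags <- tibble(
    chrom = x[[1]][keep], start = s[keep], end = e[keep],
    strand = ifelse(strand %in% c("+", "-"), strand, "*"), umi = umi
  )
  list(frags = frags, n_malformed = sum(malformed), n_discordant = 0L)
}

read_fragments_sam <- function(path) {
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mpos", "isize", "strand", "flag"),
    flag = Rsamtools::scanBamFlag(isFirstMateRead = TRUE)
  )
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- length(r$pos)
  proper <- bitwAnd(r$flag, 2L) == 2L
  ok <- proper & !is.na(r$pos) & !is.na(r$isize) & r$isize != 0L
  left <- ifelse(r$isize[ok] > 0, r$pos[ok], r$mpos[ok]) - 1L
  frags <- tibble(
    chrom = as.character(r$rname[ok]),
    start = as.integer(left),
    end = as.integer(left + abs(r$isize[ok])),
    strand = as.character(r$strand[ok]),
    umi = umi_from_name(r$qname[ok])
  )
  list(frags = frags, n_malformed = 0L, n_discordant = n_total - sum(ok))
}

#' Write fragments as BED6(+UMI)
#'
#' Writes `chrom start end name score strand` with the UMI in column 7 when
#' any fragment carries one; the file round-trips through
#' `read_fragments(format = "bed")`. Output is in canonical order.
#'
#' @param frags Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  frags <- canonical_sort(as_fragment_tbl(frags))
  out <- tibble(
    chrom = frags$chrom, start = frags$start, end = frags$end,
    name = ".", score = 0L,
    strand = ifelse(frags$strand %in% c("+", "-"), frags$strand, ".")
  )
  if (any(!is.na(frags$umi))) {
    out$umi <- ifelse(is.na(frags$umi), ".", frags$umi)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read single-base anchors from BED6
#'
#' The anchor coordinate is the interval start for `+` strand entries and
#' `end - 1` for `-` strand entries (so a 1-bp BED interval anchors on that
#' base regardless of strand). Missing/`.` strands are treated as `+`.
#'
#' @param path BED file (>= 3 columns; strand read from column 6).
#' @return A tibble with columns `chrom`, `pos`, `strand`.
#' @export
read_anchors <- function(path) {
  x <- read_raw_tsv(path)
  if (is.null(x) || nrow(x) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character()))
  }
  s <- as.integer(x[[2]])
  e <- as.integer(x[[3]])
  strand <- if (ncol(x) >= 6) x[[6]] else rep("+", nrow(x))
  strand[!(strand %in% c("+", "-"))] <- "+"
  tibble(
    chrom = x[[1]],
    pos = as.integer(ifelse(strand == "-", e - 1L, s)),
    strand = strand
  )
}
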