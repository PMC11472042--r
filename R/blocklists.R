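# Bundled hg38 blocklists. The printed source coordinates are UCSC-style
# 1-based inclusive; they are stored 0-based half-open here.

#' Centromeric blocklist for hg38 ChIP-Seq peak calling
#'
#' Six centromeric/repetitive regions that yield spurious peaks above the
#' read threshold even after background subtraction.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
blocklist_centromeric_hg38 <- function() {
  tibble(
    chrom = c("chr1", "chr4", "chr10", "chr16", "chr21", "chrY"),
    start = c(125037718L, 49056148L, 39350927L, 38069295L, 8144873L,
              26450075L) - 1L,
    end = c(143553145L, 49737993L, 42213196L, 46485764L, 8557778L,
            57055992L)
  )
}

#' Blocklist for hg38 IRF center-cluster analysis
#'
#' Regions excluded when calling center clusters on GR libraries to find IRF
#' sites.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
blocklist_irf_hg38 <- function() {
  tibble(
    chrom = c("chr5", "chr10", "chr15", "chr20", "chrY"),
    start = c(49600783L, 41838938L, 19773761L, 26560426L, 56672149L) - 1L,
    end = c(49670029L, 42110985L, 19792684L, 28500888L, 57217277L)
  )
}
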