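#' Build a genomic-interval tibble
#'
#' All coordinates in this package are 0-based half-open (BED convention);
#' conversion to and from 1-based closed coordinates happens only at the
#' boundary with GenomicRanges or file formats. An interval tibble has
#' columns `chrom`, `start`, `end` and `strand` (one of `"+"`, `"-"`,
#' `"*"`).
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `start < end`.
#' @param strand Strand; `"*"` (default) means unstranded.
#' @param ... Further columns carried along unchanged.
#'
#' @return A tibble with one row per interval.
#' @export
#' @examples
#' interval_tbl("chr1", 0L, 100L)
interval_tbl <- function(chrom, start, end, strand = "*", ...) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    ...
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  assert_that(all(c("chrom", "start", "end") %in% names(x)),
    sprintf("%s table needs chrom/start/end columns", what))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s at row %d: need 0 <= start < end (got [%s, %s))",
      what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])
    ))
  }
  if ("strand" %in% names(x)) {
    assert_that(all(x$strand %in% c("+", "-", "*")),
      "strand must be '+', '-' or '*'")
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed). Clipping to
# chromosome bounds is handled upstream in R, so no seqinfo is attached.
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# GRanges -> 0-based half-open tibble.
granges_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# Merge overlapping/adjacent intervals within a set; strand is ignored.
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(dplyr::mutate(x, strand = "*")))
  granges_tbl(gr)[, c("chrom", "start", "end")]
}

# Total bases in the intersection of two merged interval sets.
intersect_bases <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- as_granges(dplyr::mutate(a, strand = "*"))
  gb <- as_granges(dplyr::mutate(b, strand = "*"))
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(GenomicRanges::reduce(ga), GenomicRanges::reduce(gb))
  )))
}

total_bases <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Count, for each query interval, how many subject intervals overlap it by
# >= 1 bp. Strand-blind.
count_overlaps_tbl <- function(query, subject) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(integer(nrow(query)))
  gq <- as_granges(dplyr::mutate(query, strand = "*"))
  gs <- as_granges(dplyr::mutate(subject, strand = "*"))
  GenomicRanges::countOverlaps(gq, gs, ignore.strand = TRUE)
}
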