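#' Extend sequencing tags to library fragment length
#'
#' Each tag becomes an interval of `fragment_length` bp anchored at its 5'
#' end: on the + strand the fragment starts at the tag start; on the -
#' strand it ends at the tag end; unstranded tags extend from their start.
#' Fragments are clipped silently at chromosome bounds (position 0, and
#' the chromosome end when `chrom_sizes` is supplied).
#'
#' @param tags A `tag_set` from [read_bed_tags()] / [tag_set()], or an
#'   interval tibble (then `fragment_length` must be given).
#' @param chrom_sizes Named numeric vector of chromosome lengths, used for
#'   right-edge clipping; `NULL` skips it.
#' @param fragment_length Fragment size in bp; defaults to the tag set's
#'   own value.
#' @return Fragment tibble with the same attributes (`fragment_length`,
#'   `total_count`) carried over.
#' @export
extend_tags <- function(tags, chrom_sizes = NULL, fragment_length = NULL) {
  if (is.null(fragment_length)) fragment_length <- attr(tags, "fragment_length")
  assert_that(is.numeric(fragment_length) && fragment_length > 0,
    "fragment_length must be > 0")
  start <- ifelse(tags$strand == "-", tags$end - fragment_length, tags$start)
  end <- start + fragment_length
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, unname(chrom_sizes[tags$chrom]))
  }
  frags <- tibble(chrom = tags$chrom, start = start, end = end,
    strand = tags$strand)
  n_clipped <- sum(end - start < fragment_length)
  log_attrition("fragments clipped at chromosome bounds", n_clipped)
  attr(frags, "fragment_length") <- fragment_length
  attr(frags, "total_count") <- nrow(frags)
  frags
}

#' Normalized read count (NRC)
#'
#' The log2 ratio of local fragment density to the genome-average
#' density: `log2(((count + pseudocount) / width) / (total_count /
#' genome_size))`. This is the unit in which every track in the package
#' is expressed.
#'
#' @param count Reads/fragments attributed to the target interval.
#' @param width Interval width in bp used for the local density.
#' @param total_count Library size.
#' @param genome_size Total genome length in bp.
#' @param pseudocount Added to `count` only (default 0); the log2 is
#'   undefined at zero counts, so binned tracks use a pseudocount of 1.
#' @return NRC value(s), log2 scale.
#' @export
#' @examples
#' nrc(10, 200, 1e6, 2e7) # 0: density equals the genome average
#' nrc(20, 200, 1e6, 2e7) # 1: doubling adds one log2 unit
nrc <- function(count, width, total_count, genome_size, pseudocount = 0) {
  assert_that(all(width > 0), "width must be > 0")
  assert_that(all(total_count > 0), "total_count must be > 0")
  assert_that(all(genome_size > 0), "genome_size must be > 0")
  log2_safe(((count + pseudocount) / width) / (total_count / genome_size))
}

#' Bin extended fragments into a fixed-width count track
#'
#' Each bin's raw count is the number of fragments overlapping it by at
#' least 1 bp, so a fragment spanning k bins contributes to all k. The
#' NRC column converts counts to normalized read counts; because an
#' extended fragment can overlap a bin from `width + fragment_length - 1`
#' distinct start positions, that effective width is used as the density
#' denominator so that uniform libraries calibrate to NRC 0.
#'
#' @param fragments Fragment tibble from [extend_tags()] (or any interval
#'   tibble).
#' @param chrom_sizes Named numeric vector of chromosome lengths; every
#'   fragment chromosome must appear here.
#' @param bin_width Bin size in bp (default 200).
#' @param pseudocount Pseudocount for the NRC (default 1).
#' @param total_count Library size; defaults to the fragment tibble's
#'   `total_count` attribute, else `nrow(fragments)`.
#' @param fragment_length Fragment size used for the effective width;
#'   defaults to the tibble's attribute, else 1.
#' @return A `binned_track` tibble with columns chrom/start/end/count/nrc
#'   and attributes `bin_width`, `total_count`, `genome_size`,
#'   `fragment_length`, `pseudocount`.
#' @export
bin_counts <- function(fragments, chrom_sizes, bin_width = 200,
                       pseudocount = 1, total_count = NULL,
                       fragment_length = NULL) {
  assert_that(bin_width >= 1, "bin_width must be >= 1")
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    abort(sprintf("fragments on unknown chromosome: %s", unknown[1]))
  }
  if (is.null(total_count)) {
    total_count <- attr(fragments, "total_count") %||% nrow(fragments)
  }
  if (is.null(fragment_length)) {
    fragment_length <- attr(fragments, "fragment_length") %||% 1
  }
  genome_size <- sum(chrom_sizes)

  bins <- purrr::map(names(chrom_sizes), function(ch) {
    n_bins <- ceiling(chrom_sizes[[ch]] / bin_width)
    start <- (seq_len(n_bins) - 1) * bin_width
    tibble(chrom = ch, start = start,
      end = pmin(start + bin_width, chrom_sizes[[ch]]))
  })
  bins <- bind_rows(bins)
  bins$count <- count_overlaps_tbl(bins, fragments)
  eff_width <- (bins$end - bins$start) + fragment_length - 1
  bins$nrc <- nrc(bins$count, eff_width, total_count, genome_size, pseudocount)

  class(bins) <- c("binned_track", class(bins))
  attr(bins, "bin_width") <- bin_width
  attr(bins, "total_count") <- total_count
  attr(bins, "genome_size") <- genome_size
  attr(bins, "fragment_length") <- fragment_length
  attr(bins, "pseudocount") <- pseudocount
  bins
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf(
    "<binned_track> %d bins of %g bp, library %g tags, genome %g bp\n",
    nrow(x), attr(x, "bin_width"), attr(x, "total_count"),
    attr(x, "genome_size")
  ))
  NextMethod()
}

#' Tags to NRC track in one step
#'
#' Convenience wrapper: extend, bin, normalize.
#'
#' @inheritParams extend_tags
#' @inheritParams bin_counts
#' @return A `binned_track`.
#' @export
coverage_track <- function(tags, chrom_sizes, bin_width = 200,
                           pseudocount = 1, fragment_length = NULL) {
  frags <- extend_tags(tags, chrom_sizes, fragment_length)
  bin_counts(frags, chrom_sizes, bin_width, pseudocount)
}

#' Per-feature normalized read count
#'
#' Computes the NRC of each feature interval directly from extended
#' fragments (overlap counting, not resampled from a 200-bp genome
#' track), with the feature length (plus the fragment effective-width
#' correction) as the density denominator.
#'
#' @param fragments Fragment tibble from [extend_tags()].
#' @param features Interval tibble of target features.
#' @param total_count Library size (defaults to fragment attribute).
#' @param genome_size Genome length in bp.
#' @param pseudocount Pseudocount added to each feature's count (default 1).
#' @param fragment_length Fragment size for the effective width (defaults
#'   to the fragment attribute, else 1).
#' @return Numeric vector of NRC values, one per feature row.
#' @export
feature_nrc <- function(fragments, features, genome_size,
                        total_count = NULL, pseudocount = 1,
                        fragment_length = NULL) {
  assert_that(all(features$end - features$start > 0),
    "zero-length feature interval")
  if (is.null(total_count)) {
    total_count <- attr(fragments, "total_count") %||% nrow(fragments)
  }
  if (is.null(fragment_length)) {
    fragment_length <- attr(fragments, "fragment_length") %||% 1
  }
  count <- count_overlaps_tbl(features, fragments)
  eff_width <- (features$end - features$start) + fragment_length - 1
  nrc(count, eff_width, total_count, genome_size, pseudocount)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
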