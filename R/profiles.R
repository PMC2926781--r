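#' Partition an interval into equal-count scaled bins
#'
#' `n_bins` contiguous sub-intervals tiling the interval with lengths
#' differing by at most 1 bp; the remainder is distributed left-to-right
#' in transcription orientation, and for - strand features the returned
#' rows are ordered so bin 1 is always the 5' bin.
#'
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"`, `"-"` or `"*"` (treated as `"+"`).
#' @param n_bins Number of bins (>= 1).
#' @return Tibble with `bin` (1..n_bins, 5' to 3'), `start`, `end`.
#' @export
#' @examples
#' scaled_bins(0, 13, "+", 10)
scaled_bins <- function(start, end, strand = "+", n_bins = 10) {
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  len <- end - start
  assert_that(len >= 1, "interval length must be >= 1")
  base <- len %/% n_bins
  rem <- len %% n_bins
  widths <- base + as.numeric(seq_len(n_bins) <= rem) # transcription order
  genomic_widths <- if (strand == "-") rev(widths) else widths
  bounds <- start + c(0, cumsum(genomic_widths))
  out <- tibble(bin = seq_len(n_bins),
    start = head(bounds, -1), end = tail(bounds, -1))
  if (strand == "-") {
    out$start <- rev(out$start)
    out$end <- rev(out$end)
  }
  out
}

# Vectorized scaled binning over a feature table; returns a long tibble
# with .feature (row index), bin, start, end. Features shorter than
# n_bins bp are dropped (they cannot tile) and their count is attached.
scaled_bins_many <- function(features, n_bins) {
  n_bins <- as.integer(n_bins)
  len <- features$end - features$start
  keep <- which(len >= n_bins)
  n_skipped <- nrow(features) - length(keep)
  if (length(keep) == 0) {
    out <- tibble(.feature = integer(), bin = integer(),
      start = numeric(), end = numeric())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  f <- features[keep, ]
  len <- len[keep]
  base <- len %/% n_bins
  rem <- len %% n_bins
  # widths[i, j]: width of transcription-order bin j of feature i
  widths <- outer(base, rep(1, n_bins)) +
    outer(rem, seq_len(n_bins), FUN = function(r, j) as.numeric(j <= r))
  minus <- f$strand == "-"
  gw <- widths
  gw[minus, ] <- widths[minus, n_bins:1, drop = FALSE]
  cs <- apply(gw, 1, cumsum)
  cs <- if (n_bins == 1) matrix(cs, ncol = 1) else t(cs)
  ends_g <- cs + f$start
  starts_g <- ends_g - gw
  bin_of_col <- function(i) {
    if (minus[i]) (n_bins + 1L) - seq_len(n_bins) else seq_len(n_bins)
  }
  out <- tibble(
    .feature = rep(keep, each = n_bins),
    # vapply yields an n_bins x n_features matrix whose column-major
    # flattening is feature-major, matching the row order above
    bin = as.integer(vapply(seq_along(keep), bin_of_col, integer(n_bins))),
    start = as.numeric(t(starts_g)),
    end = as.numeric(t(ends_g))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

# Fixed-width flank bins on one side of oriented features.
# side = "up" (5') or "down" (3'); bins are labeled 1..flank_bins moving
# away from the feature is FALSE: bin 1 is the most distal 5' bin for
# "up" and the nearest bin for "down", so that concatenating
# up / inside / down yields a left-to-right 5'->3' axis.
flank_bins_many <- function(features, flank_bp, flank_bins, side) {
  if (flank_bins == 0 || flank_bp == 0) {
    return(tibble(.feature = integer(), bin = integer(),
      start = numeric(), end = numeric()))
  }
  w <- flank_bp / flank_bins
  minus <- features$strand == "-"
  # anchor: 5' feature edge for "up", 3' edge for "down"
  anchor <- if (side == "up") {
    ifelse(minus, features$end, features$start)
  } else {
    ifelse(minus, features$start, features$end)
  }
  offs <- seq_len(flank_bins)
  out <- purrr::map(seq_len(nrow(features)), function(i) {
    if (side == "up") {
      # genomic: [anchor - flank, anchor) on +, [anchor, anchor + flank) on -
      if (!minus[i]) {
        start <- anchor[i] - flank_bp + (offs - 1) * w
      } else {
        start <- anchor[i] + flank_bp - offs * w
      }
    } else {
      if (!minus[i]) {
        start <- anchor[i] + (offs - 1) * w
      } else {
        start <- anchor[i] - offs * w
      }
    }
    tibble(.feature = i, bin = offs, start = start, end = start + w)
  })
  bind_rows(out)
}

new_profile_matrix <- function(values, bin_labels, feature_ids,
                               n_skipped = 0L) {
  structure(
    list(values = values, bins = bin_labels, feature_ids = feature_ids,
      n_skipped = n_skipped),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d features x %d bins (%d skipped)\n",
    nrow(x$values), ncol(x$values), x$n_skipped))
  print(profile_summary(x), ...)
  invisible(x)
}

#' Column summary of a profile matrix
#'
#' @param x A `profile_matrix`.
#' @return Tibble with bin label, segment, mean NRC and the number of
#'   contributing features per bin.
#' @export
profile_summary <- function(x) {
  m <- x$values
  tibble(
    bin = x$bins$bin,
    segment = x$bins$segment,
    mean_nrc = unname(colMeans(m, na.rm = TRUE)),
    n = unname(colSums(!is.na(m)))
  )
}

#' Aligned average profile over a feature set
#'
#' For each feature: fixed-width bins over `flank_bp` on the 5' side,
#' `n_bins` scaled bins inside the feature, and fixed-width bins over
#' `flank_bp` on the 3' side, each scored as a normalized read count from
#' extended fragments. The profile is the column-wise mean over features.
#' Features shorter than `n_bins` bp are skipped and counted.
#'
#' @param fragments Fragment tibble from [extend_tags()].
#' @param features Interval tibble (strand used for orientation).
#' @param genome_size Genome length in bp.
#' @param n_bins Scaled bins inside each feature.
#' @param flank_bp Flank extent on each side in bp (0 disables flanks).
#' @param flank_bins Number of fixed-width bins per flank.
#' @param pseudocount NRC pseudocount.
#' @return A `profile_matrix`; bins are labeled `up*`, `in*`, `down*`
#'   left-to-right along the 5'->3' axis.
#' @export
feature_profile <- function(fragments, features, genome_size, n_bins = 10,
                            flank_bp = 1000, flank_bins = 5,
                            pseudocount = 1) {
  assert_that(nrow(features) > 0, "empty feature list")
  if (!"strand" %in% names(features)) features$strand <- "*"

  inside <- scaled_bins_many(features, n_bins)
  n_skipped <- attr(inside, "n_skipped")
  kept <- sort(unique(inside$.feature))
  if (length(kept) == 0) abort("all features shorter than n_bins")
  fkept <- features[kept, ]
  remap <- match(inside$.feature, kept)

  up <- flank_bins_many(fkept, flank_bp, flank_bins, "up")
  down <- flank_bins_many(fkept, flank_bp, flank_bins, "down")

  parts <- list(
    up = tibble(.feature = up$.feature, bin = up$bin, start = up$start,
      end = up$end, segment = "up"),
    inside = tibble(.feature = remap, bin = inside$bin, start = inside$start,
      end = inside$end, segment = "in"),
    down = tibble(.feature = down$.feature, bin = down$bin,
      start = down$start, end = down$end, segment = "down")
  )
  all_bins <- bind_rows(parts)
  all_bins$chrom <- fkept$chrom[all_bins$.feature]

  profile_from_bins(all_bins, fragments, genome_size, length(kept),
    flank_bins, n_bins, pseudocount,
    feature_ids = feature_ids_of(fkept), n_skipped = n_skipped)
}

feature_ids_of <- function(features) {
  if ("transcript_id" %in% names(features)) return(features$transcript_id)
  if ("name" %in% names(features)) return(features$name)
  paste0(features$chrom, ":", format_coord(features$start), "-",
    format_coord(features$end))
}

# Shared scorer: NRC per sub-interval -> feature x bin matrix.
profile_from_bins <- function(all_bins, fragments, genome_size, n_features,
                              flank_bins, n_bins, pseudocount,
                              feature_ids, n_skipped) {
  # clip at position 0; drop zero/negative-width bins as NA
  all_bins$start <- pmax(all_bins$start, 0)
  valid <- all_bins$end > all_bins$start
  vals <- rep(NA_real_, nrow(all_bins))
  if (any(valid)) {
    vals[valid] <- feature_nrc(fragments, all_bins[valid, ], genome_size,
      pseudocount = pseudocount)
  }

  seg_order <- c(up = 0, `in` = 1, down = 2)
  col_index <- seg_order[all_bins$segment] * 1000 + all_bins$bin
  cols <- sort(unique(col_index))
  m <- matrix(NA_real_, nrow = n_features, ncol = length(cols))
  m[cbind(all_bins$.feature, match(col_index, cols))] <- vals

  seg_of <- names(seg_order)[cols %/% 1000 + 1]
  bin_of <- cols %% 1000
  labels <- tibble(
    bin = paste0(ifelse(seg_of == "in", "in", seg_of), bin_of),
    segment = seg_of
  )
  colnames(m) <- labels$bin
  rownames(m) <- feature_ids
  new_profile_matrix(m, labels, feature_ids, n_skipped)
}

#' TSS-anchored profiles, optionally split by promoter CGI status
#'
#' Fixed-width bins across `[TSS - flank_bp, TSS + flank_bp)`, oriented
#' 5' to 3' (bin offsets are transcription-relative positions of each
#' bin's 5' edge).
#'
#' @param fragments Fragment tibble from [extend_tags()].
#' @param promoters Promoter tibble from [annotate_promoters()] (needs
#'   `tss`, `strand` and, when splitting, `cgi_status`).
#' @param genome_size Genome length in bp.
#' @param flank_bp Half-width of the profiled window.
#' @param bin_width Bin size in bp.
#' @param split_by_cgi Return one profile per CGI status?
#' @param pseudocount NRC pseudocount.
#' @return A `profile_matrix`, or a list with elements `cgi` and
#'   `non_cgi` when `split_by_cgi` is TRUE (an empty class yields NULL
#'   and a message).
#' @export
tss_profile <- function(fragments, promoters, genome_size, flank_bp = 1000,
                        bin_width = 200, split_by_cgi = TRUE,
                        pseudocount = 1) {
  build <- function(p) {
    if (nrow(p) == 0) return(NULL)
    n_bins <- as.integer(2 * flank_bp / bin_width)
    offsets <- -flank_bp + (seq_len(n_bins) - 1) * bin_width
    minus <- p$strand == "-"
    rows <- purrr::map(seq_len(nrow(p)), function(i) {
      if (!minus[i]) {
        start <- p$tss[i] + offsets
      } else {
        start <- p$tss[i] - offsets - bin_width + 1
      }
      tibble(.feature = i, bin = seq_len(n_bins), start = start,
        end = start + bin_width, segment = "in", chrom = p$chrom[i])
    })
    all_bins <- bind_rows(rows)
    pm <- profile_from_bins(all_bins, fragments, genome_size, nrow(p),
      0, n_bins, pseudocount, feature_ids = feature_ids_of(p), n_skipped = 0L)
    pm$bins$offset <- offsets
    pm$bins$bin <- sprintf("tss%+d", offsets)
    colnames(pm$values) <- pm$bins$bin
    pm
  }
  if (!split_by_cgi) return(build(promoters))
  assert_that("cgi_status" %in% names(promoters),
    "promoters need a cgi_status column to split by CGI")
  out <- list(
    cgi = build(promoters[promoters$cgi_status, ]),
    non_cgi = build(promoters[!promoters$cgi_status, ])
  )
  if (is.null(out$cgi)) inform("no CGI promoters; cgi profile is NULL")
  if (is.null(out$non_cgi)) inform("no non-CGI promoters; non_cgi profile is NULL")
  out
}

#' Ten-bin exon/intron profiles per exon class
#'
#' Builds scaled-bin profiles for each exon class (`NCE`, `ICE_5prime`,
#' `ICE_internal`, `internal`, `LCE`), with the UTR and CDS sub-segments
#' of ICE/LCE exons profiled separately, plus intron profiles keyed by
#' the class of the 5'-flanking exon. Transcripts whose CDS sits in a
#' single exon are excluded from the LCE profiles. Classes with no
#' members are omitted with a message.
#'
#' @param fragments Fragment tibble from [extend_tags()].
#' @param exon_records Exon records from [classify_exons()].
#' @param introns Intron tibble from [introns_of()].
#' @param genome_size Genome length in bp.
#' @param n_bins Scaled bins per feature.
#' @param pseudocount NRC pseudocount.
#' @return Named list of `profile_matrix` objects; segment profiles are
#'   named like `"ICE_internal.CDS"`, intron profiles like
#'   `"intron.internal"`.
#' @export
exon_intron_profile <- function(fragments, exon_records, introns,
                                genome_size, n_bins = 10, pseudocount = 1) {
  profiles <- list()
  add <- function(name, feats) {
    if (is.null(feats) || nrow(feats) == 0) {
      inform(sprintf("exon class %s has no members; omitted", name))
      return(invisible(NULL))
    }
    profiles[[name]] <<- feature_profile(fragments, feats, genome_size,
      n_bins = n_bins, flank_bp = 0, flank_bins = 0,
      pseudocount = pseudocount)
  }

  ex <- exon_records[!exon_records$single_cds_exon, ]
  for (cls in c("NCE", "internal")) {
    add(cls, ex[ex$exon_class == cls, ])
  }
  for (cls in c("ICE_5prime", "ICE_internal", "LCE")) {
    sub <- ex[ex$exon_class == cls, ]
    if (nrow(sub) == 0) {
      inform(sprintf("exon class %s has no members; omitted", cls))
      next
    }
    segs <- bind_rows(purrr::map(seq_len(nrow(sub)), function(i) {
      s <- sub$segments[[i]]
      s$chrom <- sub$chrom[i]
      s$strand <- sub$strand[i]
      s$transcript_id <- sub$transcript_id[i]
      s
    }))
    for (lab in unique(segs$label)) {
      add(paste0(cls, ".", lab), segs[segs$label == lab, ])
    }
  }

  if (nrow(introns) > 0) {
    # key each intron by the class of its 5'-flanking exon
    key <- paste(introns$transcript_id, introns$upstream_exon_ordinal)
    exkey <- paste(exon_records$transcript_id, exon_records$ordinal)
    up_class <- exon_records$exon_class[match(key, exkey)]
    for (cls in unique(up_class[!is.na(up_class)])) {
      add(paste0("intron.", cls), introns[!is.na(up_class) & up_class == cls, ])
    }
  }
  profiles
}

#' Split features by mean methylation level
#'
#' Scores each feature by its mean methylation NRC (from methylation
#' fragments or a binned methylation track) and splits at the stated
#' quantile: the top `1 - threshold_quantile` fraction (nearest rank,
#' ties broken by feature order) is the "high" (methylated) set. Used to
#' overlay profiles of methylated versus unmethylated CpG islands.
#'
#' @param features Interval tibble.
#' @param methylation Fragment tibble (from [extend_tags()]) or a
#'   `binned_track` of methylation NRC.
#' @param genome_size Genome length in bp (needed for fragment input).
#' @param threshold_quantile Quantile cut (default 0.75: top quartile is
#'   "high").
#' @return List with `high` and `low` feature tibbles, each with a
#'   `meth_nrc` column.
#' @export
split_by_methylation <- function(features, methylation, genome_size = NULL,
                                 threshold_quantile = 0.75) {
  assert_that(nrow(features) > 0, "empty feature set")
  if (inherits(methylation, "binned_track")) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(dplyr::mutate(features, strand = "*")),
      as_granges(dplyr::mutate(methylation, strand = "*"))
    )
    v <- tapply(methylation$nrc[S4Vectors::subjectHits(hits)],
      factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(features))),
      mean)
    score <- as.numeric(v)
    score[is.na(score)] <- -Inf
  } else {
    assert_that(!is.null(genome_size), "genome_size needed for fragment input")
    score <- feature_nrc(methylation, features, genome_size)
  }
  features$meth_nrc <- score
  if (length(unique(score)) == 1) {
    warn("all features have identical methylation; nothing in the high set")
    return(list(high = features[0, ], low = features))
  }
  n_high <- nearest_rank_count(nrow(features), 1 - threshold_quantile)
  high_idx <- stable_rank(-score) <= n_high
  list(high = features[high_idx, ], low = features[!high_idx, ])
}
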