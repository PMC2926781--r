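#' Classify exons into positional/coding classes with UTR/CDS segments
#'
#' Implements the exon taxonomy used throughout the package: exons
#' entirely outside the CDS are non-coding exons (NCE); the first
#' CDS-containing exon in transcription order is the initial coding exon
#' (ICE; `ICE_5prime` when it is also the transcript's first exon,
#' `ICE_internal` otherwise); the last CDS-containing exon is the last
#' coding exon (LCE); CDS-containing exons between them are `internal`.
#' ICE and LCE are segmented into UTR and CDS parts at the start/stop
#' codon boundaries. A transcript whose CDS is confined to a single exon
#' is labeled LCE with a full UTR5+CDS+UTR3 segmentation and flagged via
#' `single_cds_exon`, so profile averages can exclude it from ICE/LCE
#' classes.
#'
#' @param genes Gene-model tibble from [read_bed12_genes()].
#' @return Exon-record tibble: one row per exon with `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `ordinal` (1-based transcription
#'   order), `n_exons`, `exon_class`, `is_internal` (neither first nor
#'   last exon of the transcript, regardless of coding status),
#'   `single_cds_exon`, and a `segments` list-column of
#'   start/end/label tibbles that tile the exon exactly.
#' @export
classify_exons <- function(genes) {
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    classify_exons_one(genes[i, ])
  })
  bind_rows(out)
}

classify_exons_one <- function(gene) {
  ex <- gene$exons[[1]]
  n <- nrow(ex)
  minus <- gene$strand == "-"
  # transcription order: coordinate order on +, reversed on -
  ord <- if (minus) rev(seq_len(n)) else seq_len(n)
  ordinal <- integer(n); ordinal[ord] <- seq_len(n)

  cds_start <- gene$cds_start; cds_end <- gene$cds_end
  coding <- !is.na(cds_start)
  if (coding) {
    in_union <- any(cds_start >= ex$start & cds_start < ex$end)
    end_in_union <- any(cds_end > ex$start & cds_end <= ex$end)
    if (!in_union || !end_in_union) {
      abort(sprintf("transcript %s: CDS bounds fall outside the exon union",
        gene$transcript_id))
    }
  }

  has_cds <- if (coding) ex$end > cds_start & ex$start < cds_end else rep(FALSE, n)
  cls <- rep("NCE", n)
  single_cds <- FALSE
  if (coding) {
    cds_ordinals <- ordinal[has_cds]
    ice_ord <- min(cds_ordinals)
    lce_ord <- max(cds_ordinals)
    if (ice_ord == lce_ord) {
      single_cds <- TRUE
      cls[ordinal == lce_ord] <- "LCE"
    } else {
      cls[ordinal == ice_ord] <- if (ice_ord == 1) "ICE_5prime" else "ICE_internal"
      cls[ordinal == lce_ord] <- "LCE"
      cls[has_cds & ordinal > ice_ord & ordinal < lce_ord] <- "internal"
    }
  }

  segments <- purrr::map(seq_len(n), function(j) {
    exon_segments(ex$start[j], ex$end[j], cds_start, cds_end, minus, coding)
  })

  tibble(
    transcript_id = gene$transcript_id,
    chrom = gene$chrom,
    strand = gene$strand,
    start = ex$start,
    end = ex$end,
    ordinal = ordinal,
    n_exons = n,
    exon_class = cls,
    is_internal = ordinal > 1 & ordinal < n,
    single_cds_exon = single_cds & cls == "LCE",
    segments = segments
  )
}

# Tile one exon with UTR5/CDS/UTR3 segments (genomic coordinates).
exon_segments <- function(start, end, cds_start, cds_end, minus, coding) {
  if (!coding) {
    return(tibble(start = start, end = end, label = "UTR5"))
  }
  if (end <= cds_start || start >= cds_end) {
    # entirely untranslated exon: 5' or 3' of the CDS in transcription order
    genomically_left <- end <= cds_start
    lab <- if (xor(genomically_left, minus)) "UTR5" else "UTR3"
    return(tibble(start = start, end = end, label = lab))
  }
  cuts <- sort(unique(c(start, end, max(start, cds_start), min(end, cds_end))))
  seg <- tibble(start = head(cuts, -1), end = tail(cuts, -1))
  seg$label <- ifelse(seg$end <= cds_start, if (minus) "UTR3" else "UTR5",
    ifelse(seg$start >= cds_end, if (minus) "UTR5" else "UTR3", "CDS"))
  seg
}

#' Promoter windows around transcription start sites
#'
#' The window spans `upstream` bp 5' of the TSS through `downstream` bp
#' 3' of it (default -1000 bp to +500 bp), in transcription orientation;
#' on the - strand the window is reflected so "upstream" is 5' of the
#' gene. Windows are clipped at chromosome edges and the clipped count is
#' reported via the `n_clipped` attribute.
#'
#' @param genes Gene-model tibble.
#' @param upstream,downstream Window extent in bp relative to the TSS.
#' @param chrom_sizes Optional named vector for right-edge clipping.
#' @return Tibble: transcript_id/chrom/start/end/strand plus `tss` (the
#'   0-based position of the first transcribed base).
#' @export
promoter_window <- function(genes, upstream = 1000, downstream = 500,
                            chrom_sizes = NULL) {
  minus <- genes$strand == "-"
  tss <- ifelse(minus, genes$end - 1, genes$start)
  start <- ifelse(minus, tss - downstream + 1, tss - upstream)
  end <- ifelse(minus, tss + upstream + 1, tss + downstream)
  raw_start <- start
  raw_end <- end
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) end <- pmin(end, unname(chrom_sizes[genes$chrom]))
  out <- tibble(
    transcript_id = genes$transcript_id,
    chrom = genes$chrom,
    start = start,
    end = end,
    strand = genes$strand,
    tss = tss
  )
  n_clipped <- sum(start != raw_start | end != raw_end)
  log_attrition("promoter windows clipped at chromosome edges", n_clipped)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Does each promoter window overlap a CpG island?
#'
#' True for >= 1 bp overlap under half-open coordinates (an island
#' abutting the window does not count).
#'
#' @param windows Promoter-window tibble from [promoter_window()].
#' @param cgis Interval tibble of CpG islands.
#' @return Logical vector, one element per window.
#' @export
promoter_has_cgi <- function(windows, cgis) {
  count_overlaps_tbl(windows, cgis) > 0
}

#' Annotate promoters with CGI status
#'
#' @inheritParams promoter_window
#' @param cgis CpG-island interval tibble.
#' @return [promoter_window()] output plus a logical `cgi_status` column.
#' @export
annotate_promoters <- function(genes, cgis, upstream = 1000,
                               downstream = 500, chrom_sizes = NULL) {
  w <- promoter_window(genes, upstream, downstream, chrom_sizes)
  w$cgi_status <- promoter_has_cgi(w, cgis)
  w
}

#' Introns of gene models
#'
#' Gaps between consecutive exons, one row per intron, ordered in
#' transcription order (`ordinal` 1 = the intron following the first
#' transcribed exon). Single-exon transcripts contribute no rows.
#'
#' @param genes Gene-model tibble.
#' @return Tibble: transcript_id/chrom/strand/start/end/ordinal plus
#'   `upstream_exon_ordinal`, the transcription-order ordinal of the
#'   exon on the intron's 5' side.
#' @export
introns_of <- function(genes) {
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    n <- nrow(ex)
    if (n < 2) {
      return(tibble(transcript_id = character(), chrom = character(),
        strand = character(), start = numeric(), end = numeric(),
        ordinal = integer(), upstream_exon_ordinal = integer()))
    }
    minus <- genes$strand[i] == "-"
    start <- ex$end[-n]
    end <- ex$start[-1]
    k <- n - 1
    ordinal <- if (minus) rev(seq_len(k)) else seq_len(k)
    tibble(
      transcript_id = genes$transcript_id[i],
      chrom = genes$chrom[i],
      strand = genes$strand[i],
      start = start,
      end = end,
      ordinal = ordinal,
      upstream_exon_ordinal = ordinal
    )
  })
  bind_rows(out)
}
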