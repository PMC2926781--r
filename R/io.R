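#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; record order is preserved. Duplicate headers
#' are an error. Only the first whitespace-delimited token of each header
#' is used as the name.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0) abort(sprintf("empty FASTA file: %s", path))
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA header '%s' in %s", nm[duplicated(nm)][1], path))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read sequencing tags from a BED file
#'
#' Accepts BED3 or BED6; the strand column, when present, is kept so tags
#' can later be extended from their 5' ends. Missing strand means the tag
#' is unstranded and will be extended from its start.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#' @param fragment_length Library fragment size in bp (e.g. 150); stored on
#'   the returned object and used by [extend_tags()].
#' @return A `tag_set`: a tibble of intervals with attributes
#'   `fragment_length` and `total_count`.
#' @export
read_bed_tags <- function(path, fragment_length) {
  assert_that(is.numeric(fragment_length) && fragment_length > 0,
    "fragment_length must be > 0")
  raw <- read_bed_raw(path)
  strand <- if (ncol(raw) >= 6) as.character(raw[[6]]) else rep("*", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "*"
  tags <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    strand = strand
  )
  check_bed_coords(tags, path)
  tag_set(tags, fragment_length)
}

#' Construct a tag set from an interval tibble
#'
#' @param tags Interval tibble (chrom/start/end/strand).
#' @param fragment_length Library fragment size in bp.
#' @return A `tag_set` tibble.
#' @export
tag_set <- function(tags, fragment_length) {
  validate_intervals(tags, "tag")
  if (!"strand" %in% names(tags)) tags$strand <- "*"
  out <- as_tibble(tags)
  class(out) <- c("tag_set", class(out))
  attr(out, "fragment_length") <- as.numeric(fragment_length)
  attr(out, "total_count") <- nrow(out)
  out
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf(
    "<tag_set> %d tags, fragment_length = %g bp\n",
    attr(x, "total_count"), attr(x, "fragment_length")
  ))
  NextMethod()
}

# Shared low-level BED reader with line-numbered errors.
read_bed_raw <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) {
    abort(sprintf("%s line %d: fewer than 3 BED columns", path, which(ncols < 3)[1]))
  }
  k <- min(ncols)
  raw <- as.data.frame(
    do.call(rbind, lapply(parts, `[`, seq_len(k))),
    stringsAsFactors = FALSE
  )
  for (j in 2:3) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      abort(sprintf("%s line %d: non-numeric coordinate '%s'",
        path, which(is.na(v))[1], raw[[j]][which(is.na(v))[1]]))
    }
    raw[[j]] <- v
  }
  raw
}

check_bed_coords <- function(x, path) {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid interval [%s, %s)", path, bad[1],
      format(x$start[bad[1]]), format(x$end[bad[1]])))
  }
  invisible(x)
}

#' Read gene models from a BED12 file
#'
#' Exons are reconstructed from blockStarts/blockSizes; CDS bounds come
#' from thickStart/thickEnd, with `thickStart == thickEnd` encoding a
#' non-coding transcript.
#'
#' @param path Path to a BED12 file.
#' @return A gene-model tibble: one row per transcript with columns
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, `cds_start`,
#'   `cds_end` (NA when non-coding) and a list-column `exons` of
#'   start/end tibbles sorted by genomic coordinate.
#' @export
read_bed12_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12) abort(sprintf("%s line %d: BED12 needs 12 columns", path, i))
    chrom_start <- as.numeric(p[2]); chrom_end <- as.numeric(p[3])
    if (is.na(chrom_start) || is.na(chrom_end) || chrom_start < 0 || chrom_start >= chrom_end) {
      abort(sprintf("%s line %d: invalid chromStart/chromEnd", path, i))
    }
    thick_start <- as.numeric(p[7]); thick_end <- as.numeric(p[8])
    n_blocks <- as.integer(p[10])
    sizes <- as.numeric(strsplit(sub(",$", "", p[11]), ",")[[1]])
    starts <- as.numeric(strsplit(sub(",$", "", p[12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      abort(sprintf("%s line %d: blockCount %d does not match block lists (%d, %d)",
        path, i, n_blocks, length(sizes), length(starts)))
    }
    ex_start <- chrom_start + starts
    ex_end <- ex_start + sizes
    if (any(ex_start < chrom_start) || any(ex_end > chrom_end)) {
      abort(sprintf("%s line %d: block outside [chromStart, chromEnd)", path, i))
    }
    coding <- thick_start < thick_end
    genes[[i]] <- tibble(
      transcript_id = p[4],
      chrom = p[1],
      strand = p[6],
      start = chrom_start,
      end = chrom_end,
      cds_start = if (coding) thick_start else NA_real_,
      cds_end = if (coding) thick_end else NA_real_,
      exons = list(tibble(start = ex_start, end = ex_end))
    )
  }
  out <- bind_rows(genes)
  validate_gene_models(out)
  out
}

# Gene-model invariants: sorted non-overlapping exons; CDS inside exon span.
validate_gene_models <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    assert_that(all(diff(ex$start) > 0) && all(ex$end[-nrow(ex)] <= ex$start[-1]),
      sprintf("transcript %s: exons must be sorted and non-overlapping",
        genes$transcript_id[i]))
    if (!is.na(genes$cds_start[i])) {
      assert_that(genes$cds_start[i] < genes$cds_end[i],
        sprintf("transcript %s: cds_start must be < cds_end", genes$transcript_id[i]))
      assert_that(genes$cds_start[i] >= ex$start[1] && genes$cds_end[i] <= ex$end[nrow(ex)],
        sprintf("transcript %s: CDS outside exon span", genes$transcript_id[i]))
    }
  }
  invisible(genes)
}

#' Write gene models to a BED12 file
#'
#' @param genes Gene-model tibble as returned by [read_bed12_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12_genes <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    thick <- if (is.na(genes$cds_start[i])) {
      c(genes$start[i], genes$start[i])
    } else {
      c(genes$cds_start[i], genes$cds_end[i])
    }
    paste(
      genes$chrom[i],
      format_coord(genes$start[i]), format_coord(genes$end[i]),
      genes$transcript_id[i], 0, genes$strand[i],
      format_coord(thick[1]), format_coord(thick[2]), "0,0,0",
      nrow(ex),
      paste0(paste(format_coord(ex$end - ex$start), collapse = ","), ","),
      paste0(paste(format_coord(ex$start - genes$start[i]), collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write intervals to a BED file
#'
#' Writes BED6 when a strand column is present (name/score filled with
#' `.`/`0`), BED3 otherwise. Extra columns named in `extra` are appended.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @param extra Character vector of extra column names to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = character()) {
  validate_intervals(x)
  df <- data.frame(
    chrom = x$chrom,
    start = format_coord(x$start),
    end = format_coord(x$end),
    stringsAsFactors = FALSE
  )
  if ("strand" %in% names(x) || length(extra) > 0) {
    df$name <- if ("name" %in% names(x)) x$name else "."
    df$score <- 0
    df$strand <- if ("strand" %in% names(x)) x$strand else "*"
  }
  for (col in extra) df[[col]] <- x[[col]]
  write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an interval BED file (BED3/BED6+)
#'
#' @param path Path to a BED file.
#' @return Interval tibble with a `strand` column (`"*"` when absent).
#' @export
read_bed <- function(path) {
  raw <- read_bed_raw(path)
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = numeric(),
      end = numeric(), strand = character()))
  }
  strand <- if (ncol(raw) >= 6) as.character(raw[[6]]) else rep("*", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "*"
  out <- tibble(chrom = as.character(raw[[1]]), start = raw[[2]],
    end = raw[[3]], strand = strand)
  check_bed_coords(out, path)
  out
}

#' Write a binned track as bedGraph
#'
#' One line per bin with the NRC value (or raw count when `value =
#' "count"`). A `track type=bedGraph` header line is always written, so an
#' empty track yields a header-only file.
#'
#' @param track A `binned_track` from [bin_counts()].
#' @param path Output path.
#' @param value Which column to write: `"nrc"` or `"count"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = c("nrc", "count")) {
  value <- match.arg(value)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", value), con)
  if (nrow(track) > 0) {
    writeLines(paste(track$chrom, format_coord(track$start),
      format_coord(track$end),
      formatC(track[[value]], digits = 8, format = "g"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file into an interval/value tibble
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with chrom/start/end/value columns.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(),
      end = numeric(), value = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[`, character(1), 3)),
    value = as.numeric(vapply(parts, `[`, character(1), 4))
  )
}

#' Write a tibble as a TSV with header
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
}
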