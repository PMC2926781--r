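#' GC fraction of a sequence
#'
#' (#G + #C) / #non-N bases. `N` bases are excluded from the denominator.
#'
#' @param seq Character vector of DNA sequences over A/C/G/T/N.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    assert_that(nzchar(s), "empty sequence")
    b <- base_counts(s)
    denom <- sum(b[c("A", "C", "G", "T")])
    assert_that(denom > 0, "sequence is all N")
    (b[["G"]] + b[["C"]]) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Observed/expected CpG ratio
#'
#' The Gardiner-Garden density statistic: `(#CpG * N) / (#C * #G)` with
#' `N` the number of non-N bases; 0 when the sequence has no C or no G.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of ratios (>= 0).
#' @export
#' @examples
#' cpg_obs_exp("CGCG") # 2
#' cpg_obs_exp("ACGT") # 4
cpg_obs_exp <- function(seq) {
  vapply(seq, function(s) {
    assert_that(nzchar(s), "empty sequence")
    b <- base_counts(s)
    n <- sum(b[c("A", "C", "G", "T")])
    cg <- count_cpg(s)
    if (b[["C"]] == 0 || b[["G"]] == 0) return(0)
    (cg * n) / (b[["C"]] * b[["G"]])
  }, numeric(1), USE.NAMES = FALSE)
}

base_counts <- function(s) {
  r <- charToRaw(s)
  c(
    A = sum(r == charToRaw("A")),
    C = sum(r == charToRaw("C")),
    G = sum(r == charToRaw("G")),
    T = sum(r == charToRaw("T"))
  )
}

count_cpg <- function(s) {
  r <- charToRaw(s)
  if (length(r) < 2) return(0L)
  sum(r[-length(r)] == charToRaw("C") & r[-1] == charToRaw("G"))
}

#' Detect CpG islands by sliding-window scan
#'
#' Every window of width `window` (advanced by `step`) whose GC fraction
#' is at least `min_gc` and whose observed/expected CpG ratio exceeds
#' `min_obs_exp` seeds an island; overlapping or adjacent seeds are
#' merged, and a merged region is emitted only if the merged region
#' itself satisfies all three criteria, including `length >= min_len`.
#' Windows with more than 50% `N` bases never qualify. The defaults
#' implement the classical criteria: GC >= 50%, length > 200 bp,
#' obs/exp > 0.6.
#'
#' @param genome Named character vector of chromosome sequences (a single
#'   unnamed sequence is treated as one chromosome called `"seq"`).
#' @param min_gc Minimum GC fraction (inclusive).
#' @param min_len Minimum island length in bp (inclusive; 201 encodes
#'   "greater than 200 bp").
#' @param min_obs_exp Observed/expected CpG ratio threshold (exclusive).
#' @param window Sliding-window width in bp.
#' @param step Window step in bp.
#' @return Tibble of islands: chrom/start/end plus `gc_fraction` and
#'   `obs_exp` of each emitted island; non-overlapping, sorted.
#' @export
detect_cgis <- function(genome, min_gc = 0.5, min_len = 201,
                        min_obs_exp = 0.6, window = 200, step = 1) {
  if (is.null(names(genome))) {
    assert_that(length(genome) == 1, "multiple sequences must be named")
    names(genome) <- "seq"
  }
  out <- purrr::map(names(genome), function(ch) {
    isl <- detect_cgis_one(genome[[ch]], min_gc, min_len, min_obs_exp,
      window, step)
    if (nrow(isl) > 0) isl$chrom <- ch
    isl
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
      gc_fraction = numeric(), obs_exp = numeric()))
  }
  out[, c("chrom", "start", "end", "gc_fraction", "obs_exp")]
}

detect_cgis_one <- function(seq, min_gc, min_len, min_obs_exp, window, step) {
  n <- nchar(seq)
  assert_that(window <= n, "window larger than sequence")
  r <- charToRaw(toupper(seq))
  is_c <- r == charToRaw("C")
  is_g <- r == charToRaw("G")
  is_base <- is_c | is_g | r == charToRaw("A") | r == charToRaw("T")
  is_cpg <- c(is_c[-n] & is_g[-1], FALSE)

  cum <- function(x) c(0, cumsum(x))
  cc <- cum(is_c); cg <- cum(is_g); cb <- cum(is_base); ccpg <- cum(is_cpg)

  starts <- seq.int(1L, n - window + 1L, by = step)
  ends <- starts + window - 1L
  w_c <- cc[ends + 1] - cc[starts]
  w_g <- cg[ends + 1] - cg[starts]
  w_base <- cb[ends + 1] - cb[starts]
  # dinucleotides fully inside the window start at positions starts..ends-1
  w_cpg <- ccpg[ends] - ccpg[starts]

  gc <- ifelse(w_base > 0, (w_c + w_g) / w_base, 0)
  oe <- ifelse(w_c > 0 & w_g > 0, (w_cpg * w_base) / (w_c * w_g), 0)
  ok <- w_base >= window / 2 & gc >= min_gc & oe > min_obs_exp

  empty <- tibble(start = numeric(), end = numeric(),
    gc_fraction = numeric(), obs_exp = numeric())
  if (!any(ok)) return(empty)

  seeds <- IRanges::reduce(IRanges::IRanges(start = starts[ok], width = window))
  regions <- purrr::map(seq_along(seeds), function(i) {
    s1 <- IRanges::start(seeds)[i]; e1 <- IRanges::end(seeds)[i]
    sub <- substr(seq, s1, e1)
    len <- e1 - s1 + 1
    gcf <- gc_fraction(sub)
    oer <- cpg_obs_exp(sub)
    if (len >= min_len && gcf >= min_gc && oer > min_obs_exp) {
      tibble(start = s1 - 1, end = as.numeric(e1),
        gc_fraction = gcf, obs_exp = oer)
    } else {
      empty
    }
  })
  bind_rows(regions)
}

#' Canonical trinucleotide key
#'
#' The lexicographic minimum of a 3-mer and its reverse complement;
#' collapses the 64 trinucleotides to 32 strand-symmetric keys.
#'
#' @param tri Character vector of 3-mers over A/C/G/T.
#' @return Character vector of canonical keys.
#' @export
#' @examples
#' canonical_trinucleotide(c("TTT", "ACG")) # "AAA", "ACG"
canonical_trinucleotide <- function(tri) {
  assert_that(all(nchar(tri) == 3), "trinucleotides must have length 3")
  assert_that(all(grepl("^[ACGT]+$", tri)), "non-ACGT character in trinucleotide")
  rc <- reverse_complement(tri)
  pmin(tri, rc)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Construct a bendability parameter table
#'
#' @param values Named numeric vector keyed by trinucleotide; keys may be
#'   any of the 64 3-mers, but a key and its reverse complement must not
#'   carry conflicting values. Exactly the 32 canonical keys must be
#'   covered.
#' @return Named numeric vector with the 32 canonical keys.
#' @export
bendability_table <- function(values) {
  keys <- canonical_trinucleotide(names(values))
  tab <- tapply(values, keys, function(v) {
    assert_that(length(unique(v)) == 1,
      "conflicting values for a trinucleotide and its reverse complement")
    v[1]
  })
  out <- setNames(as.numeric(tab), names(tab))
  assert_that(length(out) == 32,
    sprintf("bendability table must cover all 32 canonical trinucleotides (got %d)",
      length(out)))
  out
}

#' Read a bendability parameter table from TSV
#'
#' Two columns, no header requirement beyond `trinucleotide` and `value`
#' names when a header is present.
#'
#' @param path Path to a TSV file (trinucleotide, value).
#' @return Named numeric vector with 32 canonical keys.
#' @export
read_bendability_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  bendability_table(setNames(df[[2]], df[[1]]))
}

#' DNA bendability of a sequence
#'
#' Sums a bending-propensity parameter over all overlapping
#' trinucleotides of the sequence; parameters are keyed on the 32
#' canonical (strand-symmetrized) trinucleotides, so the score is
#' invariant under reverse complement. 3-mers containing `N` are skipped.
#'
#' @param seq Character vector of sequences (each of length >= 3).
#' @param table Bendability table from [bendability_table()].
#' @return Numeric vector of summed scores.
#' @export
bendability <- function(seq, table) {
  table <- bendability_table(setNames(table, names(table)))
  vapply(seq, function(s) {
    assert_that(nchar(s) >= 3, "sequence shorter than 3 bp")
    counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(s))
    canon <- canonical_trinucleotide(names(counts))
    sum(counts * table[canon])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Binned bendability track over a genome
#'
#' Scores every trinucleotide position (assigned to the bin containing
#' its first base) and sums within fixed-width bins.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param table Bendability table.
#' @param bin_width Bin size in bp.
#' @return Tibble chrom/start/end/score.
#' @export
bendability_track <- function(genome, table, bin_width = 200) {
  table <- bendability_table(setNames(table, names(table)))
  tris <- names(Biostrings::trinucleotideFrequency(Biostrings::DNAString("AAA")))
  lookup <- setNames(table[canonical_trinucleotide(tris)], tris)
  out <- purrr::map(names(genome), function(ch) {
    s <- genome[[ch]]
    n <- nchar(s)
    pos_tri <- substring(s, seq_len(n - 2), seq_len(n - 2) + 2)
    v <- unname(lookup[pos_tri])
    v[is.na(v)] <- 0 # 3-mers containing N
    csum <- c(0, cumsum(v))
    bin_start <- seq(0, n - 1, by = bin_width)
    bin_end <- pmin(bin_start + bin_width, n)
    # trinucleotide starts (0-based) that fall inside each bin;
    # csum has length n - 1, indexed by v position + 1
    lo <- bin_start + 1
    hi <- pmin(bin_end - 1, n - 3) + 1
    empty_bin <- hi < lo
    lo_c <- pmin(lo, length(csum))
    hi_c <- pmin(hi + 1, length(csum))
    score <- csum[hi_c] - csum[lo_c]
    score[empty_bin] <- 0
    tibble(chrom = ch, start = bin_start, end = bin_end, score = score)
  })
  bind_rows(out)
}
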