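#' Exon inclusiveness scores from RNA-seq fragments
#'
#' For every transcript with at least three exons, computes each exon's
#' RNA-seq NRC and mean-centers it within the transcript: `score = NRC -
#' mean(NRC over all exons of the transcript)`. The score measures how
#' inclusive splicing is of the exon (strongly negative = candidate
#' skipped exon). Scores are returned for all exons with an
#' `is_internal` flag; within a transcript they sum to zero by
#' construction. Transcripts with fewer than three exons are skipped and
#' counted in the `n_skipped_genes` attribute.
#'
#' @param fragments Extended RNA-seq fragment tibble.
#' @param genes Gene-model tibble.
#' @param genome_size Genome length in bp.
#' @param pseudocount NRC pseudocount.
#' @return Tibble: transcript_id/chrom/strand/start/end/ordinal/
#'   is_internal/exon_nrc/score.
#' @export
exon_inclusiveness <- function(fragments, genes, genome_size,
                               pseudocount = 1) {
  eligible <- vapply(genes$exons, nrow, integer(1)) >= 3
  log_attrition("transcripts with < 3 exons skipped", sum(!eligible))
  g <- genes[eligible, ]
  if (nrow(g) == 0) {
    out <- tibble(transcript_id = character(), chrom = character(),
      strand = character(), start = numeric(), end = numeric(),
      ordinal = integer(), is_internal = logical(),
      exon_nrc = numeric(), score = numeric())
    attr(out, "n_skipped_genes") <- sum(!eligible)
    return(out)
  }
  recs <- classify_exons(g)
  recs <- recs[, c("transcript_id", "chrom", "strand", "start", "end",
    "ordinal", "is_internal")]
  recs$exon_nrc <- feature_nrc(fragments, recs, genome_size,
    pseudocount = pseudocount)
  recs <- recs |>
    group_by(.data$transcript_id) |>
    mutate(score = .data$exon_nrc - mean(.data$exon_nrc)) |>
    ungroup()
  attr(recs, "n_skipped_genes") <- sum(!eligible)
  recs
}

#' Classify internal exons as skipped / included / highly expressed
#'
#' Empirical-quantile classification of pooled internal-exon
#' inclusiveness scores: the lowest `low_q` fraction is `skipped`, the
#' top `1 - high_q` fraction is `high` (used as a sequencing-bias
#' control), and the rest is `included`. Quantiles are nearest-rank with
#' ties broken by record order. When all scores are identical everything
#' is `included`, with a warning.
#'
#' @param records Output of [exon_inclusiveness()]; only internal exons
#'   are classified (and returned).
#' @param low_q Lower quantile (default 0.10).
#' @param high_q Upper quantile (default 0.90).
#' @return The internal-exon records with an `inclusion_class` column.
#' @export
classify_inclusiveness <- function(records, low_q = 0.10, high_q = 0.90) {
  recs <- if ("is_internal" %in% names(records)) {
    records[records$is_internal, ]
  } else {
    records
  }
  n <- nrow(recs)
  assert_that(n >= 10, "need at least 10 internal exons to form deciles")
  if (length(unique(recs$score)) == 1) {
    warn("all inclusiveness scores identical; classifying everything as included")
    recs$inclusion_class <- "included"
    return(recs)
  }
  r <- stable_rank(recs$score)
  k_low <- nearest_rank_count(n, low_q)
  k_high <- nearest_rank_count(n, 1 - high_q)
  cls <- rep("included", n)
  cls[r <= k_low] <- "skipped"
  cls[r > n - k_high] <- "high"
  recs$inclusion_class <- cls
  recs
}

#' Odds-ratio enrichment of a mark within a feature set
#'
#' Base-level contingency: `p_f` is the fraction of feature bases
#' carrying the mark and `p_g` the fraction of the mappable genome
#' carrying it; the odds ratio `[p_f/(1-p_f)] / [p_g/(1-p_g)]` measures
#' how much more likely the mark is inside the features than elsewhere.
#' `level = "element"` instead takes `p_f` as the fraction of feature
#' elements overlapping at least one mark interval.
#'
#' @param marks Interval tibble of the mark (e.g. DNase hypersensitive
#'   sites); merged internally.
#' @param features Interval tibble of the feature set (e.g. CGIs).
#' @param mappable_size Genome size in bp before the mappability
#'   correction.
#' @param mappable_fraction Mappable fraction of the genome (default
#'   0.8).
#' @param level `"base"` (default) or `"element"`.
#' @return One-row tibble with the contingency cells `a`..`d` (target
#'   bases with/without the mark, background bases with/without),
#'   `p_feature`, `p_background` and `odds_ratio`. Degenerate fractions
#'   (0 or 1) yield an infinite or zero ratio with a warning.
#' @export
odds_ratio_enrichment <- function(marks, features, mappable_size,
                                  mappable_fraction = 0.8,
                                  level = c("base", "element")) {
  level <- match.arg(level)
  marks_m <- merge_intervals(marks)
  feats_m <- merge_intervals(features)
  feature_bases <- sum(feats_m$end - feats_m$start)
  background <- mappable_size * mappable_fraction
  mark_bases <- sum(marks_m$end - marks_m$start)

  if (level == "base") {
    a <- intersect_bases(marks_m, feats_m)
    p_f <- a / feature_bases
    b <- feature_bases - a
  } else {
    hit <- count_overlaps_tbl(feats_m, marks_m) > 0
    p_f <- mean(hit)
    a <- sum(hit); b <- sum(!hit)
  }
  p_g <- mark_bases / background
  c_ <- mark_bases
  d <- background - mark_bases

  if (p_f %in% c(0, 1) || p_g %in% c(0, 1)) {
    warn("degenerate mark fraction; odds ratio is 0 or infinite")
  }
  or <- (p_f / (1 - p_f)) / (p_g / (1 - p_g))
  tibble(a = a, b = b, c = c_, d = d,
    p_feature = p_f, p_background = p_g, odds_ratio = or)
}

#' Bisulfite methylation level
#'
#' Fraction of intact (methylated) cytosines among intact plus
#' bisulfite-converted reads at a site; `NA` when no reads cover the
#' site.
#'
#' @param intact Count of unconverted (methylated) cytosine reads.
#' @param converted Count of converted (unmethylated) reads.
#' @return Numeric vector of fractions in \[0, 1\], `NA` where both
#'   counts are zero.
#' @export
bisulfite_level <- function(intact, converted) {
  assert_that(all(intact >= 0) && all(converted >= 0),
    "counts must be non-negative")
  total <- intact + converted
  ifelse(total > 0, intact / total, NA_real_)
}

#' Splice-site dinucleotides of exons
#'
#' Returns the acceptor (last two intronic bases before the exon, AG for
#' canonical sites) and donor (first two intronic bases after the exon,
#' GT) dinucleotides in transcription orientation.
#'
#' @param exon_records Exon records (chrom/start/end/strand).
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with `acceptor` and `donor` columns (`NA` at
#'   chromosome edges).
#' @export
splice_site_dinucs <- function(exon_records, genome) {
  get2 <- function(chrom, start) {
    # 0-based [start, start + 2)
    n <- nchar(genome[[chrom]])
    if (is.na(start) || start < 0 || start + 2 > n) return(NA_character_)
    substr(genome[[chrom]], start + 1, start + 2)
  }
  minus <- exon_records$strand == "-"
  acceptor <- donor <- character(nrow(exon_records))
  for (i in seq_len(nrow(exon_records))) {
    if (!minus[i]) {
      acceptor[i] <- get2(exon_records$chrom[i], exon_records$start[i] - 2)
      donor[i] <- get2(exon_records$chrom[i], exon_records$end[i])
    } else {
      a <- get2(exon_records$chrom[i], exon_records$end[i])
      d <- get2(exon_records$chrom[i], exon_records$start[i] - 2)
      acceptor[i] <- if (is.na(a)) NA_character_ else reverse_complement(a)
      donor[i] <- if (is.na(d)) NA_character_ else reverse_complement(d)
    }
  }
  tibble(acceptor = acceptor, donor = donor)
}

# Simple donor/acceptor position-weight matrices (probability of each
# base at each position), loosely shaped like canonical splice-site
# consensus. Rows A/C/G/T; donor columns cover the first 6 intronic
# bases (GTRAGT-like), acceptor columns the last 6 intronic bases
# (YYNYAG-like).
default_donor_pwm <- function() {
  m <- matrix(c(
    # G     T     A/R   A     G     T
    0.02, 0.02, 0.60, 0.70, 0.08, 0.15,
    0.02, 0.02, 0.05, 0.08, 0.06, 0.15,
    0.94, 0.02, 0.30, 0.12, 0.80, 0.20,
    0.02, 0.94, 0.05, 0.10, 0.06, 0.50
  ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

default_acceptor_pwm <- function() {
  m <- matrix(c(
    # Y     Y     N     Y     A     G
    0.08, 0.08, 0.25, 0.05, 0.94, 0.02,
    0.40, 0.42, 0.25, 0.45, 0.02, 0.02,
    0.08, 0.08, 0.25, 0.05, 0.02, 0.94,
    0.44, 0.42, 0.25, 0.45, 0.02, 0.02
  ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

#' Log-odds position-weight splice-site scores (stand-in scorer)
#'
#' A deliberately simple scorer for exon splice-site strength: the sum
#' over donor and acceptor windows of `log2(p_base / 0.25)` under small
#' built-in position-weight matrices shaped like the canonical GT/AG
#' consensus. Scores from any external model can be substituted wherever
#' a splice-site score is consumed.
#'
#' @param exon_records Exon records (chrom/start/end/strand).
#' @param genome Named character vector of chromosome sequences.
#' @param donor_pwm,acceptor_pwm Optional 4 x L probability matrices
#'   (rows A/C/G/T).
#' @return Numeric vector: donor + acceptor log-odds score per exon
#'   (`NA` when a window runs off the chromosome).
#' @export
score_splice_sites <- function(exon_records, genome, donor_pwm = NULL,
                               acceptor_pwm = NULL) {
  donor_pwm <- donor_pwm %||% default_donor_pwm()
  acceptor_pwm <- acceptor_pwm %||% default_acceptor_pwm()
  ld <- ncol(donor_pwm); la <- ncol(acceptor_pwm)

  fetch <- function(chrom, start, len, rc) {
    n <- nchar(genome[[chrom]])
    if (start < 0 || start + len > n) return(NA_character_)
    s <- substr(genome[[chrom]], start + 1, start + len)
    if (rc) reverse_complement(s) else s
  }
  pwm_score <- function(s, pwm) {
    if (is.na(s) || grepl("[^ACGT]", s)) return(NA_real_)
    b <- match(strsplit(s, "")[[1]], rownames(pwm))
    sum(log2(pwm[cbind(b, seq_along(b))] / 0.25))
  }

  minus <- exon_records$strand == "-"
  vapply(seq_len(nrow(exon_records)), function(i) {
    if (!minus[i]) {
      dseq <- fetch(exon_records$chrom[i], exon_records$end[i], ld, FALSE)
      aseq <- fetch(exon_records$chrom[i], exon_records$start[i] - la, la, FALSE)
    } else {
      dseq <- fetch(exon_records$chrom[i], exon_records$start[i] - ld, ld, TRUE)
      aseq <- fetch(exon_records$chrom[i], exon_records$end[i], la, TRUE)
    }
    pwm_score(dseq, donor_pwm) + pwm_score(aseq, acceptor_pwm)
  }, numeric(1))
}

#' Weak-exon eligibility filter and strength classes
#'
#' Reproduces the weak-splice-site exon stratification: eligible exons
#' are internal, 50-250 bp long (inclusive), flanked on both sides by
#' introns of at least 70 bp, carry canonical AG acceptor / GT donor
#' dinucleotides, and are not U12-type (an optional `u12` logical column
#' on `exon_records`; absent means none). Among eligible exons the
#' lowest-scoring 5% are `very_weak`, the lowest 10% `weak` (the
#' `is_weak` flag contains `is_very_weak`), and the rest `not_weak`.
#'
#' @param exon_records Exon records from [classify_exons()].
#' @param introns Intron tibble from [introns_of()].
#' @param scores Numeric vector of summed donor+acceptor splice-site
#'   scores, one per `exon_records` row (e.g. from
#'   [score_splice_sites()]); a missing score for an eligible exon is an
#'   error.
#' @param genome Optional genome (named character vector) used to read
#'   splice-site dinucleotides; alternatively supply `acceptor`/`donor`
#'   columns on `exon_records`.
#' @param min_len,max_len Exon length bounds in bp (inclusive).
#' @param min_intron Minimum flanking intron length in bp (inclusive).
#' @param very_weak_q,weak_q Lower quantiles defining the classes.
#' @return Tibble of eligible exons with `score`, `strength_class`
#'   (`very_weak`/`weak`/`not_weak`), and logical `is_weak`,
#'   `is_very_weak` columns.
#' @export
weak_exon_filter <- function(exon_records, introns, scores, genome = NULL,
                             min_len = 50, max_len = 250, min_intron = 70,
                             very_weak_q = 0.05, weak_q = 0.10) {
  assert_that(length(scores) == nrow(exon_records),
    "need one splice-site score per exon record")
  ex <- exon_records
  ex$score <- scores

  if (!all(c("acceptor", "donor") %in% names(ex))) {
    assert_that(!is.null(genome),
      "supply acceptor/donor columns or a genome to read them from")
    dn <- splice_site_dinucs(ex, genome)
    ex$acceptor <- dn$acceptor
    ex$donor <- dn$donor
  }
  if (!"u12" %in% names(ex)) ex$u12 <- FALSE

  # flanking intron lengths via transcription-order ordinals
  ikey <- paste(introns$transcript_id, introns$ordinal)
  ilen <- introns$end - introns$start
  up_len <- ilen[match(paste(ex$transcript_id, ex$ordinal - 1), ikey)]
  down_len <- ilen[match(paste(ex$transcript_id, ex$ordinal), ikey)]
  ex$upstream_intron_len <- up_len
  ex$downstream_intron_len <- down_len

  len <- ex$end - ex$start
  eligible <- ex$is_internal &
    len >= min_len & len <= max_len &
    !is.na(up_len) & up_len >= min_intron &
    !is.na(down_len) & down_len >= min_intron &
    !is.na(ex$acceptor) & ex$acceptor == "AG" &
    !is.na(ex$donor) & ex$donor == "GT" &
    !ex$u12
  out <- ex[eligible, ]
  if (anyNA(out$score)) {
    abort(sprintf("missing splice-site score for eligible exon %s (ordinal %d)",
      out$transcript_id[which(is.na(out$score))[1]],
      out$ordinal[which(is.na(out$score))[1]]))
  }
  n <- nrow(out)
  if (n == 0) {
    out$strength_class <- character(0)
    out$is_weak <- logical(0)
    out$is_very_weak <- logical(0)
    return(out)
  }
  r <- stable_rank(out$score)
  k5 <- nearest_rank_count(n, very_weak_q)
  k10 <- nearest_rank_count(n, weak_q)
  out$is_very_weak <- r <= k5
  out$is_weak <- r <= k10
  out$strength_class <- ifelse(out$is_very_weak, "very_weak",
    ifelse(out$is_weak, "weak", "not_weak"))
  out
}

#' Absolute and relative exonic enrichment of a mark
#'
#' For each internal exon: `absolute` is the exon's mark NRC; `relative`
#' subtracts the mean NRC of the two flanking intronic windows (up to
#' `flank_bp` into each intron, truncated at the neighboring exon).
#'
#' @param fragments Extended mark fragments (e.g. MBD methylation).
#' @param exon_records Exon records from [classify_exons()].
#' @param introns Intron tibble from [introns_of()].
#' @param genome_size Genome length in bp.
#' @param flank_bp Maximum flank width in bp (default 200).
#' @param pseudocount NRC pseudocount.
#' @return Exon records (internal exons with at least one flanking
#'   intron) plus `absolute`, `relative`, `upstream_flank_bp`,
#'   `downstream_flank_bp`.
#' @export
relative_exonic_enrichment <- function(fragments, exon_records, introns,
                                       genome_size, flank_bp = 200,
                                       pseudocount = 1) {
  ex <- exon_records[exon_records$is_internal, ]
  assert_that(nrow(ex) > 0, "no internal exons")
  ikey <- paste(introns$transcript_id, introns$ordinal)
  up_i <- match(paste(ex$transcript_id, ex$ordinal - 1), ikey)
  down_i <- match(paste(ex$transcript_id, ex$ordinal), ikey)

  flank_interval <- function(idx, at_exon_5prime) {
    # returns start/end of the <= flank_bp intronic window adjacent to
    # the exon, NA-width when the intron is missing
    ok <- !is.na(idx)
    start <- end <- rep(NA_real_, length(idx))
    w <- pmin(flank_bp, introns$end[idx] - introns$start[idx])
    minus <- ex$strand == "-"
    # the intron 5' of the exon is genomically left on + and right on -
    left <- xor(at_exon_5prime, minus)
    start[ok & left] <- introns$end[idx[ok & left]] - w[ok & left]
    end[ok & left] <- introns$end[idx[ok & left]]
    start[ok & !left] <- introns$start[idx[ok & !left]]
    end[ok & !left] <- introns$start[idx[ok & !left]] + w[ok & !left]
    tibble(chrom = ex$chrom, start = start, end = end, width = w)
  }
  up_f <- flank_interval(up_i, at_exon_5prime = TRUE)
  down_f <- flank_interval(down_i, at_exon_5prime = FALSE)

  ex$absolute <- feature_nrc(fragments, ex, genome_size,
    pseudocount = pseudocount)
  flank_nrc <- function(f) {
    out <- rep(NA_real_, nrow(f))
    ok <- !is.na(f$start) & f$end > f$start
    if (any(ok)) {
      out[ok] <- feature_nrc(fragments, f[ok, ], genome_size,
        pseudocount = pseudocount)
    }
    out
  }
  up_nrc <- flank_nrc(up_f)
  down_nrc <- flank_nrc(down_f)
  flank_mean <- rowMeans(cbind(up_nrc, down_nrc), na.rm = TRUE)
  keep <- !is.nan(flank_mean)
  log_attrition("internal exons with no flanking intron window", sum(!keep))
  ex$relative <- ex$absolute - flank_mean
  ex$upstream_flank_bp <- up_f$width
  ex$downstream_flank_bp <- down_f$width
  ex[keep, ]
}

#' Pol II elongation efficiency per transcript
#'
#' The ratio of gene expression level to the density of Ser5-
#' phosphorylated pol II over the transcript body, reported in log2. The
#' pol II density is the library-normalized linear-scale fragment
#' density over the transcript span (so a transcript at the genome-
#' average pol II density has density 1).
#'
#' @param expression Positive expression level, one value per gene row.
#' @param fragments Extended Ser5-pol II fragments.
#' @param genes Gene-model tibble.
#' @param genome_size Genome length in bp.
#' @param pseudocount Pseudocount on the pol II fragment count.
#' @return Tibble: transcript_id, expression, polII_density, and
#'   `efficiency` = log2(expression / density); `NA` (with attrition
#'   logged) where the density is zero.
#' @export
elongation_efficiency <- function(expression, fragments, genes, genome_size,
                                  pseudocount = 0) {
  assert_that(all(expression > 0), "expression levels must be > 0")
  assert_that(length(expression) == nrow(genes),
    "need one expression value per gene")
  density <- 2^feature_nrc(fragments, genes, genome_size,
    pseudocount = pseudocount)
  zero <- density == 0
  log_attrition("transcripts with zero pol II density", sum(zero))
  eff <- ifelse(zero, NA_real_, log2(expression / density))
  tibble(
    transcript_id = genes$transcript_id,
    expression = expression,
    polII_density = density,
    efficiency = eff
  )
}

#' Mark levels and CGI-promoter share across gene-value quantiles
#'
#' Bins genes into `n_quantiles` equal-count bins of a per-gene value
#' (expression level or elongation efficiency; nearest-rank, ties broken
#' by gene order) and summarises, per bin, the mean level of each
#' per-exon mark over the internal exons of the bin's genes, plus the
#' percentage of genes whose promoter contains a CGI. Mark columns are
#' NRC (log2) values; averaging is done on the linear scale and
#' re-logged.
#'
#' @param exon_marks Tibble with `transcript_id` and one or more numeric
#'   mark columns (one row per internal exon).
#' @param gene_values Tibble with `transcript_id`, `value` (the grouping
#'   variable) and logical `cgi_promoter`.
#' @param n_quantiles Number of equal-count bins (default 10).
#' @return Tibble: one row per quantile with `n_genes`, a `<mark>_mean`
#'   column per mark and `pct_cgi_promoter`.
#' @export
quantile_profile <- function(exon_marks, gene_values, n_quantiles = 10) {
  n <- nrow(gene_values)
  assert_that(n_quantiles <= n, "more quantiles than genes")
  if (length(unique(gene_values$value)) == 1) {
    warn("all gene values identical; single degenerate bin")
    gene_values$quantile <- 1L
  } else {
    r <- stable_rank(gene_values$value)
    gene_values$quantile <- as.integer(ceiling(r * n_quantiles / n))
  }
  mark_cols <- setdiff(names(exon_marks)[vapply(exon_marks, is.numeric,
    logical(1))], "transcript_id")
  joined <- left_join(exon_marks,
    gene_values[, c("transcript_id", "quantile")], by = "transcript_id")
  joined <- joined[!is.na(joined$quantile), ]

  per_bin_marks <- joined |>
    group_by(.data$quantile) |>
    summarise(across(all_of(mark_cols), ~ log2(mean(2^.x, na.rm = TRUE)),
      .names = "{.col}_mean"), .groups = "drop")
  per_bin_genes <- gene_values |>
    group_by(.data$quantile) |>
    summarise(n_genes = n(),
      pct_cgi_promoter = 100 * mean(.data$cgi_promoter), .groups = "drop")
  left_join(per_bin_genes, per_bin_marks, by = "quantile")
}

#' Normalize a methylation NRC by CpG density
#'
#' Divides the linear-scale methylation level by the local
#' observed/expected CpG ratio and re-logs, removing the density
#' confound of affinity-based methylation measurements. `NA` where the
#' ratio is not positive.
#'
#' @param methylation_nrc Methylation NRC (log2 scale).
#' @param obs_exp Observed/expected CpG ratio of the same region.
#' @return Normalized level, log2 scale.
#' @export
normalize_by_cpg_density <- function(methylation_nrc, obs_exp) {
  ifelse(obs_exp > 0, log2(2^methylation_nrc / obs_exp), NA_real_)
}

#' H3K36me3 density relative to nucleosome occupancy
#'
#' Per-nucleosome modification density: the difference of the two log2
#' NRCs, separating the nucleosome-level component of an H3K36me3 signal
#' from the modification-density component.
#'
#' @param h3k36me3_nrc H3K36me3 NRC (log2).
#' @param nucleosome_nrc Nucleosome NRC (log2).
#' @return Relative density, log2 scale.
#' @export
normalize_by_nucleosome <- function(h3k36me3_nrc, nucleosome_nrc) {
  h3k36me3_nrc - nucleosome_nrc
}
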