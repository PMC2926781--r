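three_exon_gene <- function(strand = "+") {
  tibble::tibble(
    transcript_id = "tx", chrom = "chr1", strand = strand,
    start = 1000, end = 5000, cds_start = NA_real_, cds_end = NA_real_,
    exons = list(tibble::tibble(start = c(1000, 2500, 4500),
      end = c(1500, 3000, 5000)))
  )
}

test_that("inclusiveness scores are mean-centered per transcript", {
  # plant exon counts so NRCs are controlled: equal-width exons
  gene <- three_exon_gene()
  withr::with_seed(51, {
    frag_rows <- lapply(seq_len(3), function(i) {
      ex <- gene$exons[[1]]
      tibble::tibble(chrom = "chr1",
        start = floor(runif(c(100, 200, 400)[i], ex$start[i], ex$end[i] - 150)))
    })
  })
  frags <- dplyr::bind_rows(frag_rows)
  frags$end <- frags$start + 150
  frags$strand <- "+"
  attr(frags, "fragment_length") <- 150
  attr(frags, "total_count") <- nrow(frags)

  recs <- exon_inclusiveness(frags, gene, 1e6)
  expect_equal(sum(recs$score), 0, tolerance = 1e-9)
  expect_equal(recs$is_internal, c(FALSE, TRUE, FALSE))
  # doubling counts adds about one log2 unit per step
  expect_gt(recs$exon_nrc[2], recs$exon_nrc[1])
  expect_gt(recs$exon_nrc[3], recs$exon_nrc[2])

  # transcripts with < 3 exons are skipped
  g2 <- three_exon_gene()
  g2$exons <- list(g2$exons[[1]][1:2, ])
  out <- exon_inclusiveness(frags, g2, 1e6)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_skipped_genes"), 1)
})

test_that("decile classification matches exact rank arithmetic", {
  recs <- tibble::tibble(score = as.numeric(1:100),
    is_internal = TRUE)
  cls <- classify_inclusiveness(recs)
  expect_equal(which(cls$inclusion_class == "skipped"), 1:10)
  expect_equal(which(cls$inclusion_class == "high"), 91:100)
  expect_equal(sum(cls$inclusion_class == "included"), 80)

  expect_warning(
    all_eq <- classify_inclusiveness(tibble::tibble(score = rep(1, 20),
      is_internal = TRUE)),
    "identical"
  )
  expect_true(all(all_eq$inclusion_class == "included"))
  expect_error(classify_inclusiveness(recs[1:5, ]), "at least 10")
})

test_that("per-transcript scores always sum to zero on synthetic data", {
  sim <- sim_tiny()
  frags <- extend_tags(sim$tags$rnaseq, sim$chrom_sizes)
  recs <- exon_inclusiveness(frags, sim$genes, sim$genome_size)
  sums <- tapply(recs$score, recs$transcript_id, sum)
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("odds ratio reproduces the hand-evaluated contingency case", {
  # features: 50 bases with 30 marked; background: 1000 mappable bases
  # with 100 marked in total
  feats <- tibble::tibble(chrom = "chr1", start = 0, end = 50)
  marks <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(30, 570))
  or <- odds_ratio_enrichment(marks, feats, mappable_size = 1000,
    mappable_fraction = 1)
  expect_equal(or$p_feature, 0.6)
  expect_equal(or$p_background, 0.1)
  expect_equal(or$odds_ratio, (0.6 / 0.4) / (0.1 / 0.9))

  # uniform mark (p_f == p_g) gives OR 1
  feats2 <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  marks2 <- tibble::tibble(chrom = "chr1", start = seq(0, 990, 10))
  marks2$end <- marks2$start + 5
  or2 <- odds_ratio_enrichment(marks2, feats2, 1000, 1)
  expect_equal(or2$odds_ratio, 1)

  # degenerate fractions warn
  expect_warning(odds_ratio_enrichment(
    tibble::tibble(chrom = "chr1", start = 0, end = 50), feats, 1000, 1),
    "degenerate")
})

test_that("odds ratio equals the per-base membership oracle", {
  withr::with_seed(52, {
    for (i in 1:5) {
      glen <- 1e4
      marks <- tibble::tibble(chrom = "chr1",
        start = sort(sample.int(glen - 100, 30)))
      marks$end <- marks$start + sample.int(80, 30)
      feats <- tibble::tibble(chrom = "chr1",
        start = sort(sample.int(glen - 200, 10)))
      feats$end <- feats$start + sample.int(150, 10) + 20
      got <- odds_ratio_enrichment(marks, feats, glen, 0.8)$odds_ratio
      expect_equal(got, oracle_odds_ratio(marks, feats, glen, 0.8))
    }
  })
})

test_that("element-level odds ratio counts features, not bases", {
  feats <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(50, 150))
  marks <- tibble::tibble(chrom = "chr1", start = 10, end = 12)
  or <- odds_ratio_enrichment(marks, feats, 1000, 1, level = "element")
  expect_equal(or$p_feature, 0.5)
  expect_equal(or$a, 1)
  expect_equal(or$b, 1)
})

test_that("bisulfite methylation level handles zero coverage", {
  expect_equal(bisulfite_level(3, 1), 0.75)
  expect_equal(bisulfite_level(0, 5), 0)
  expect_true(is.na(bisulfite_level(0, 0)))
  expect_equal(bisulfite_level(c(3, 0, 0), c(1, 5, 0)), c(0.75, 0, NA))
  expect_error(bisulfite_level(-1, 2), "non-negative")
})

test_that("weak-exon eligibility applies every filter and boundary", {
  # construct 6 internal exons with controlled properties
  ex <- tibble::tibble(
    transcript_id = "tx", chrom = "chr1", strand = "+",
    start = c(1000, 3000, 5000, 7000, 9000, 11000),
    end = c(1100, 3040, 5100, 7100, 9100, 11100),
    ordinal = 2:7, n_exons = 9, exon_class = "internal",
    is_internal = TRUE, single_cds_exon = FALSE,
    acceptor = c("AG", "AG", "AG", "CG", "AG", "AG"),
    donor = c("GT", "GT", "GT", "GT", "GC", "GT"),
    u12 = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  introns <- tibble::tibble(
    transcript_id = "tx", chrom = "chr1", strand = "+",
    start = c(0, ex$end[1:6]),
    end = c(ex$start[1:6], 13000),
    ordinal = 1:7
  )
  # exon 3 gets a 69-bp upstream intron (one below the inclusive bound)
  introns$start[3] <- ex$start[3] - 69
  scores <- c(5, 4, 3, 2, 1, 0)
  ws <- weak_exon_filter(ex, introns, scores)
  # exon 2 fails length (40 bp), exon 3 the 70-bp intron bound, exon 4
  # the acceptor, exon 5 the donor, exon 6 the U12 flag
  expect_equal(ws$ordinal, 2)

  # inclusive boundaries: 50/250 bp length, 70-bp introns qualify
  ex$end[2] <- ex$start[2] + 50
  introns$start[3] <- ex$start[3] - 70
  ws2 <- weak_exon_filter(ex, introns, scores)
  expect_equal(ws2$ordinal, c(2, 3, 4))

  # missing score for an eligible exon errors
  expect_error(weak_exon_filter(ex, introns, c(5, NA, 3, 2, 1, 0)),
    "missing splice-site score")
})

test_that("weak-exon classes follow exact rank arithmetic", {
  n <- 1000
  ex <- tibble::tibble(
    transcript_id = sprintf("t%04d", 1:n), chrom = "chr1", strand = "+",
    start = seq(1000, by = 1000, length.out = n), ordinal = 2,
    n_exons = 3, exon_class = "internal", is_internal = TRUE,
    single_cds_exon = FALSE, acceptor = "AG", donor = "GT"
  )
  ex$end <- ex$start + 100
  introns <- dplyr::bind_rows(
    tibble::tibble(transcript_id = ex$transcript_id, chrom = "chr1",
      strand = "+", start = ex$start - 200, end = ex$start, ordinal = 1),
    tibble::tibble(transcript_id = ex$transcript_id, chrom = "chr1",
      strand = "+", start = ex$end, end = ex$end + 200, ordinal = 2)
  )
  withr::with_seed(53, {
    scores <- sample(seq_len(n)) # distinct ranks 1..n in random order
  })
  ws <- weak_exon_filter(ex, introns, scores)
  expect_equal(nrow(ws), n)
  expect_setequal(ws$transcript_id[ws$is_very_weak],
    ex$transcript_id[scores <= 50])
  expect_setequal(ws$transcript_id[ws$is_weak],
    ex$transcript_id[scores <= 100])
  expect_true(all(ws$is_weak[ws$is_very_weak]))
  expect_equal(sum(ws$strength_class == "not_weak"), 900)
})

test_that("splice-site dinucleotides and PWM scores read both strands", {
  # exon [10, 16) on chr1; acceptor bases at [8,10), donor at [16,18)
  genome <- c(chr1 = paste0("AAAAAAAA", "AG", "CCCCCC", "GT", "AAAGTAAGTAAA"))
  ex <- tibble::tibble(transcript_id = "t", chrom = "chr1", strand = "+",
    start = 10, end = 16)
  dn <- splice_site_dinucs(ex, genome)
  expect_equal(dn$acceptor, "AG")
  expect_equal(dn$donor, "GT")
  # minus strand: reverse-complemented, roles swap genomic sides
  exm <- ex; exm$strand <- "-"
  dnm <- splice_site_dinucs(exm, genome)
  expect_equal(dnm$acceptor, "AC") # rc of donor-side GT
  expect_equal(dnm$donor, "CT")    # rc of acceptor-side AG

  sc <- score_splice_sites(ex, genome)
  expect_true(is.finite(sc))
  # a canonical-consensus context scores higher than its reverse
  g2 <- c(chr1 = paste0(strrep("A", 4), "TTTCAG", "CCCCCC", "GTAAGT",
    strrep("A", 4)))
  ex2 <- tibble::tibble(transcript_id = "t", chrom = "chr1", strand = "+",
    start = 10, end = 16)
  g3 <- c(chr1 = paste0(strrep("A", 4), "GGGGGG", "CCCCCC", "CCCCCC",
    strrep("A", 4)))
  expect_gt(score_splice_sites(ex2, g2), score_splice_sites(ex2, g3))
})

test_that("relative exonic enrichment subtracts truncated intron flanks", {
  # uniform fragments: relative enrichment near zero
  tags <- uniform_point_tags(n = 2e5, genome_size = 1e6)
  frags <- extend_tags(tags, c(chr1 = 1e6))
  sim_gene <- tibble::tibble(
    transcript_id = "tx", chrom = "chr1", strand = "+",
    start = 10000, end = 20000, cds_start = NA_real_, cds_end = NA_real_,
    exons = list(tibble::tibble(
      start = c(10000, 12000, 12600, 15000),
      end = c(11000, 12500, 13000, 20000)))
  )
  recs <- classify_exons(sim_gene)
  intr <- introns_of(sim_gene)
  ree <- relative_exonic_enrichment(frags, recs, intr, 1e6)
  expect_equal(nrow(ree), 2)
  expect_lt(max(abs(ree$relative)), 0.5)
  # exon 3's upstream intron is only 100 bp: flank truncated
  expect_equal(ree$upstream_flank_bp[ree$ordinal == 3], 100)
  expect_equal(ree$downstream_flank_bp[ree$ordinal == 2], 100)
  expect_equal(ree$upstream_flank_bp[ree$ordinal == 2], 200)
})

test_that("elongation efficiency is expression over pol II density in log2", {
  gene <- three_exon_gene()
  # fragments covering the transcript span at a controlled count
  withr::with_seed(54, {
    st <- floor(runif(400, 1000, 4850))
  })
  frags <- tibble::tibble(chrom = "chr1", start = st, end = st + 150,
    strand = "+")
  attr(frags, "fragment_length") <- 150
  attr(frags, "total_count") <- 400
  eff <- elongation_efficiency(8, frags, gene, 1e6)
  dens <- 2^feature_nrc(frags, gene, 1e6, pseudocount = 0)
  expect_equal(eff$efficiency, log2(8 / dens))
  # doubling expression adds exactly one log2 unit
  eff2 <- elongation_efficiency(16, frags, gene, 1e6)
  expect_equal(eff2$efficiency - eff$efficiency, 1)
  expect_error(elongation_efficiency(0, frags, gene, 1e6), "expression")
})

test_that("quantile profiles bin genes and summarise marks monotonically", {
  withr::with_seed(55, {
    n_genes <- 60
    gene_vals <- tibble::tibble(
      transcript_id = sprintf("g%02d", 1:n_genes),
      value = runif(n_genes),
      cgi_promoter = rep(c(TRUE, FALSE), n_genes / 2)
    )
    # two internal exons per gene; nucleosome decreasing in expression
    # rank, h3k36me3 increasing
    r <- rank(gene_vals$value)
    marks <- tibble::tibble(
      transcript_id = rep(gene_vals$transcript_id, each = 2),
      nucleosome = rep(-r / n_genes, each = 2) + rnorm(2 * n_genes, 0, 0.01),
      h3k36me3 = rep(r / n_genes, each = 2) + rnorm(2 * n_genes, 0, 0.01)
    )
  })
  qp <- quantile_profile(marks, gene_vals, n_quantiles = 6)
  expect_equal(nrow(qp), 6)
  expect_equal(qp$n_genes, rep(10, 6))
  expect_true(all(diff(qp$nucleosome_mean) < 0))
  expect_true(all(diff(qp$h3k36me3_mean) > 0))

  # all-CGI flags give 100% in every bin
  qp2 <- quantile_profile(marks,
    dplyr::mutate(gene_vals, cgi_promoter = TRUE), 6)
  expect_true(all(qp2$pct_cgi_promoter == 100))

  expect_warning(quantile_profile(marks,
    dplyr::mutate(gene_vals, value = 1), 6), "identical")
  expect_error(quantile_profile(marks, gene_vals, 61), "quantiles")
  expect_s3_class(plot_quantile_profile(qp), "ggplot")
})

test_that("normalizations follow their closed forms", {
  expect_equal(normalize_by_cpg_density(1.5, 1), 1.5)
  expect_true(is.na(normalize_by_cpg_density(1.5, 0)))
  withr::with_seed(56, {
    m <- rnorm(20); oe <- runif(20, 0.1, 2)
  })
  expect_equal(normalize_by_cpg_density(m, oe), log2(2^m / oe))

  expect_equal(normalize_by_nucleosome(2, 1), 1)
  expect_equal(normalize_by_nucleosome(1.3, 1.3), 0)
})

test_that("nucleosome-normalized H3K36me3 removes the planted exon factor", {
  # planted decomposition: exon-specific nucleosome enrichment with a
  # uniform per-nucleosome modification density
  sim <- sim_long_features()
  frags_nuc <- extend_tags(sim$tags$nucleosome, sim$chrom_sizes)
  frags_h3k <- extend_tags(sim$tags$h3k36me3, sim$chrom_sizes)
  recs <- classify_exons(sim$genes)
  internal <- recs[recs$exon_class == "internal", ]
  intr <- introns_of(sim$genes)
  nuc_ex <- feature_nrc(frags_nuc, internal, sim$genome_size)
  h3k_ex <- feature_nrc(frags_h3k, internal, sim$genome_size)
  nuc_in <- feature_nrc(frags_nuc, intr, sim$genome_size)
  h3k_in <- feature_nrc(frags_h3k, intr, sim$genome_size)
  abs_diff <- mean(h3k_ex) - mean(h3k_in)
  rel_diff <- mean(normalize_by_nucleosome(h3k_ex, nuc_ex)) -
    mean(normalize_by_nucleosome(h3k_in, nuc_in))
  expect_equal(abs_diff, 1, tolerance = 0.15)
  expect_lt(abs(rel_diff), 0.15)
})
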