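test_that("scaled bins tile intervals with remainder left-to-right 5'->3'", {
  b <- scaled_bins(0, 100, "+", 10)
  expect_equal(b$end - b$start, rep(10, 10))

  b13 <- scaled_bins(0, 13, "+", 10)
  expect_equal(b13$end - b13$start, c(2, 2, 2, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(sum(b13$end - b13$start), 13)
  expect_equal(b13$start[1], 0)

  # minus strand: same sub-intervals, bin 1 is the 5' (rightmost) one
  bm <- scaled_bins(0, 100, "-", 10)
  expect_equal(bm$start[bm$bin == 1], 90)
  expect_equal(sort(bm$start), seq(0, 90, 10))
  # the 13-bp minus case puts the longer bins at the genomic right
  bm13 <- scaled_bins(0, 13, "-", 10)
  expect_equal((bm13$end - bm13$start)[bm13$bin <= 3], c(2, 2, 2))
  expect_error(scaled_bins(0, 10, "+", 0), "n_bins")
})

test_that("single-feature profile equals that feature's own bin NRCs", {
  withr::with_seed(41, {
    st <- sample.int(9500, 800, replace = TRUE)
  })
  frags <- tibble::tibble(chrom = "chr1", start = st, end = st + 150,
    strand = "+")
  attr(frags, "fragment_length") <- 150
  attr(frags, "total_count") <- 800
  feat <- tibble::tibble(chrom = "chr1", start = 4000, end = 5000,
    strand = "+")
  pm <- feature_profile(frags, feat, 10000, n_bins = 10, flank_bp = 0,
    flank_bins = 0)
  bins <- scaled_bins(4000, 5000, "+", 10)
  bins$chrom <- "chr1"
  expect_equal(unname(pm$values[1, ]), feature_nrc(frags, bins, 10000))
  expect_equal(profile_summary(pm)$mean_nrc, unname(pm$values[1, ]))
})

test_that("uniform tags give a flat null profile over any feature set", {
  tags <- uniform_point_tags(n = 3e5, genome_size = 2e6)
  frags <- extend_tags(tags, c(chr1 = 2e6))
  withr::with_seed(42, {
    feats <- tibble::tibble(chrom = "chr1",
      start = sample.int(1.8e6, 100), strand = sample(c("+", "-"), 100, TRUE))
    feats$end <- feats$start + sample(500:2000, 100, TRUE)
  })
  pm <- feature_profile(frags, feats, 2e6, n_bins = 10, flank_bp = 1000,
    flank_bins = 5)
  expect_true(all(abs(profile_summary(pm)$mean_nrc) < 0.1))
})

test_that("mean-of-means consistency for equal-length features", {
  tags <- uniform_point_tags(n = 1e5, genome_size = 1e6)
  frags <- extend_tags(tags, c(chr1 = 1e6))
  withr::with_seed(43, {
    feats <- tibble::tibble(chrom = "chr1", start = sample.int(9e5, 50),
      strand = "+")
    feats$end <- feats$start + 1000
  })
  pm <- feature_profile(frags, feats, 1e6, n_bins = 10, flank_bp = 0,
    flank_bins = 0)
  expect_equal(mean(pm$values), mean(rowMeans(pm$values)), tolerance = 1e-9)
  expect_equal(glance(pm)$grand_mean_nrc, mean(pm$values))
})

test_that("features shorter than n_bins are skipped and counted", {
  tags <- uniform_point_tags(n = 1e4, genome_size = 1e5)
  frags <- extend_tags(tags, c(chr1 = 1e5))
  feats <- tibble::tibble(chrom = "chr1", start = c(1000, 2000, 3000),
    end = c(1005, 3000, 4000), strand = "+")
  pm <- feature_profile(frags, feats, 1e5, n_bins = 10, flank_bp = 0,
    flank_bins = 0)
  expect_equal(pm$n_skipped, 1)
  expect_equal(nrow(pm$values), 2)
  expect_error(feature_profile(frags, feats[1, ], 1e5, n_bins = 10),
    "shorter than n_bins")
  expect_error(feature_profile(frags, feats[0, ], 1e5), "empty")
})

test_that("orientation: mirrored genomes give mirrored profiles", {
  withr::with_seed(44, {
    st <- sample.int(9500, 3000, replace = TRUE)
  })
  gsz <- 10000
  frags <- tibble::tibble(chrom = "chr1", start = st, end = st + 100,
    strand = "+")
  attr(frags, "fragment_length") <- 100
  attr(frags, "total_count") <- 3000
  feat <- tibble::tibble(chrom = "chr1", start = 4000, end = 5000,
    strand = "+")
  pm_fwd <- feature_profile(frags, feat, gsz, n_bins = 10, flank_bp = 500,
    flank_bins = 2)
  # reflect all fragments and the feature through the genome midpoint
  refl <- tibble::tibble(chrom = "chr1", start = gsz - frags$end,
    end = gsz - frags$start, strand = "+")
  attr(refl, "fragment_length") <- 100
  attr(refl, "total_count") <- 3000
  feat_m <- tibble::tibble(chrom = "chr1", start = gsz - feat$end,
    end = gsz - feat$start, strand = "-")
  pm_rev <- feature_profile(refl, feat_m, gsz, n_bins = 10, flank_bp = 500,
    flank_bins = 2)
  expect_equal(unname(pm_rev$values), unname(pm_fwd$values))
})

test_that("TSS profiles split by CGI status and orient 5'->3'", {
  withr::with_seed(45, {
    st <- sample.int(2e6 - 150, 2e5, replace = TRUE)
  })
  frags <- tibble::tibble(chrom = "chr1", start = st, end = st + 150,
    strand = "+")
  attr(frags, "fragment_length") <- 150
  attr(frags, "total_count") <- 2e5
  prom <- tibble::tibble(
    transcript_id = sprintf("t%d", 1:40),
    chrom = "chr1",
    tss = round(seq(50000, 1950000, length.out = 40)),
    strand = rep(c("+", "-"), 20),
    cgi_status = rep(c(TRUE, FALSE), each = 20)
  )
  prom$start <- prom$tss - 1000
  prom$end <- prom$tss + 500
  tp <- tss_profile(frags, prom, 2e6, flank_bp = 1000, bin_width = 200)
  expect_named(tp, c("cgi", "non_cgi"))
  expect_equal(nrow(tp$cgi$values), 20)
  expect_equal(ncol(tp$cgi$values), 10)
  expect_equal(tp$cgi$bins$offset, seq(-1000, 800, by = 200))

  # all promoters in one class: the other is NULL and flagged
  expect_message(
    tp1 <- tss_profile(frags, dplyr::mutate(prom, cgi_status = FALSE), 2e6),
    "no CGI promoters"
  )
  expect_null(tp1$cgi)

  # unsplit profile over everything
  tpu <- tss_profile(frags, prom, 2e6, split_by_cgi = FALSE)
  expect_equal(nrow(tpu$values), 40)
})

test_that("exon/intron profiles recover a planted class-specific factor", {
  sim <- sim_long_features()
  frags <- extend_tags(sim$tags$nucleosome, sim$chrom_sizes)
  recs <- classify_exons(sim$genes)
  intr <- introns_of(sim$genes)
  profs <- suppressMessages(
    exon_intron_profile(frags, recs, intr, sim$genome_size))
  expect_true(all(c("internal", "NCE") %in% names(profs)))
  exon_mean <- mean(profile_summary(profs$internal)$mean_nrc)
  intron_means <- unlist(lapply(grep("^intron\\.", names(profs),
    value = TRUE), function(nm) profile_summary(profs[[nm]])$mean_nrc))
  # planted exon factor 2 -> about one log2 unit over introns
  expect_equal(exon_mean - mean(intron_means), 1, tolerance = 0.1)
  # NCEs are genuinely exonic here too (enrichment applies to all exons)
  expect_gt(mean(profile_summary(profs$NCE)$mean_nrc), mean(intron_means))
})

test_that("methylation split recovers a planted methylated subset", {
  withr::with_seed(46, {
    feats <- tibble::tibble(chrom = "chr1",
      start = seq(10000, 990000, length.out = 50))
    feats$end <- feats$start + 1000
    # plant +2 NRC (4x fragments) on a random 20%
    hot <- sample.int(50, 10)
    n_per <- ifelse(seq_len(50) %in% hot, 400, 100)
    frag_rows <- lapply(seq_len(50), function(i) {
      tibble::tibble(chrom = "chr1",
        start = floor(runif(n_per[i], feats$start[i], feats$end[i] - 150)))
    })
  })
  frags <- dplyr::bind_rows(frag_rows)
  frags$end <- frags$start + 150
  frags$strand <- "+"
  attr(frags, "fragment_length") <- 150
  attr(frags, "total_count") <- nrow(frags)
  sp <- split_by_methylation(feats, frags, 1e6, threshold_quantile = 0.8)
  expect_equal(nrow(sp$high), 10)
  expect_setequal(sp$high$start, feats$start[hot])

  # even split with ties broken by order
  feats10 <- feats[1:10, ]
  feats10$score_override <- NULL
  sp2 <- split_by_methylation(feats10, frags, 1e6, threshold_quantile = 0.5)
  expect_equal(nrow(sp2$high), 5)
  expect_equal(nrow(sp2$low), 5)

  # degenerate: identical methylation everywhere
  empty_frags <- frags[0, ]
  attr(empty_frags, "fragment_length") <- 150
  attr(empty_frags, "total_count") <- 1
  expect_warning(sp3 <- split_by_methylation(feats, empty_frags, 1e6),
    "identical")
  expect_equal(nrow(sp3$high), 0)
})

test_that("profile tidiers and plots expose the matrix faithfully", {
  tags <- uniform_point_tags(n = 2e4, genome_size = 2e5)
  frags <- extend_tags(tags, c(chr1 = 2e5))
  feats <- tibble::tibble(chrom = "chr1", start = c(10000, 50000),
    end = c(12000, 52000), strand = "+")
  pm <- feature_profile(frags, feats, 2e5, flank_bp = 400, flank_bins = 2)
  td <- tidy(pm)
  expect_equal(nrow(td), 2 * (10 + 4))
  expect_equal(unique(td$segment), c("up", "in", "down"))
  expect_s3_class(autoplot(pm), "ggplot")
  expect_s3_class(plot_profiles(list(a = pm, b = pm)), "ggplot")
})
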