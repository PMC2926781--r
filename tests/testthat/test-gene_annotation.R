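make_gene <- function(exons, strand = "+", cds = c(NA, NA),
                      id = "tx", chrom = "chr1") {
  tibble::tibble(
    transcript_id = id, chrom = chrom, strand = strand,
    start = exons$start[1], end = exons$end[nrow(exons)],
    cds_start = cds[1], cds_end = cds[2], exons = list(exons)
  )
}

test_that("a single-exon non-coding transcript is one NCE", {
  g <- make_gene(tibble::tibble(start = 100, end = 400))
  rec <- classify_exons(g)
  expect_equal(rec$exon_class, "NCE")
  expect_false(rec$is_internal)
  expect_equal(rec$segments[[1]]$label, "UTR5")
})

test_that("plus-strand 4-exon gene with CDS mid-exon-2 to mid-exon-4", {
  ex <- tibble::tibble(start = c(0, 200, 400, 600),
    end = c(100, 300, 500, 700))
  g <- make_gene(ex, "+", cds = c(250, 650))
  rec <- classify_exons(g)
  expect_equal(rec$exon_class, c("NCE", "ICE_internal", "internal", "LCE"))
  expect_equal(rec$ordinal, 1:4)
  # ICE split at the start codon
  seg2 <- rec$segments[[2]]
  expect_equal(seg2$label, c("UTR5", "CDS"))
  expect_equal(seg2$start, c(200, 250))
  expect_equal(seg2$end, c(250, 300))
  # internal coding exon is 100% CDS
  expect_equal(rec$segments[[3]]$label, "CDS")
  # LCE split at the stop codon
  seg4 <- rec$segments[[4]]
  expect_equal(seg4$label, c("CDS", "UTR3"))
  expect_equal(seg4$start, c(600, 650))
  # segments tile each exon exactly
  for (i in 1:4) {
    s <- rec$segments[[i]]
    expect_equal(s$start[1], rec$start[i])
    expect_equal(s$end[nrow(s)], rec$end[i])
    expect_equal(sum(s$end - s$start), rec$end[i] - rec$start[i])
  }
})

test_that("minus-strand classification reflects transcription order", {
  # genomic exons left to right; transcription runs right to left
  ex <- tibble::tibble(start = c(0, 200, 400), end = c(100, 300, 500))
  # CDS starts mid the first TRANSCRIBED exon (genomic exon 3) and ends
  # mid the last transcribed exon (genomic exon 1)
  g <- make_gene(ex, "-", cds = c(50, 450))
  rec <- classify_exons(g)
  expect_equal(rec$ordinal, c(3, 2, 1))
  expect_equal(rec$exon_class[rec$ordinal == 1], "ICE_5prime")
  expect_equal(rec$exon_class[rec$ordinal == 2], "internal")
  expect_equal(rec$exon_class[rec$ordinal == 3], "LCE")
  # UTR labels follow transcription orientation: genomic-left of the CDS
  # on a minus gene is the 3' UTR
  seg_lce <- rec$segments[[1]]
  expect_equal(seg_lce$label, c("UTR3", "CDS"))
  seg_ice <- rec$segments[[3]]
  expect_equal(seg_ice$label, c("CDS", "UTR5"))
})

test_that("exactly one ICE and one LCE per coding transcript, CDS tiled once", {
  sim <- sim_tiny()
  recs <- classify_exons(sim$genes)
  coding <- sim$genes$transcript_id[!is.na(sim$genes$cds_start)]
  for (tid in coding) {
    r <- recs[recs$transcript_id == tid, ]
    if (any(r$single_cds_exon)) {
      expect_equal(sum(r$exon_class == "LCE"), 1)
      next
    }
    expect_equal(sum(r$exon_class %in% c("ICE_5prime", "ICE_internal")), 1)
    expect_equal(sum(r$exon_class == "LCE"), 1)
    ice_ord <- r$ordinal[r$exon_class %in% c("ICE_5prime", "ICE_internal")]
    expect_lte(ice_ord, r$ordinal[r$exon_class == "LCE"])
    # every CDS base in exactly one CDS segment
    segs <- dplyr::bind_rows(r$segments)
    cds_segs <- segs[segs$label == "CDS", ]
    g <- sim$genes[sim$genes$transcript_id == tid, ]
    cds_exonic <- sum(pmax(0,
      pmin(g$cds_end, r$end) - pmax(g$cds_start, r$start)))
    expect_equal(sum(cds_segs$end - cds_segs$start), cds_exonic)
  }
})

test_that("CDS bounds outside the exon union are rejected", {
  ex <- tibble::tibble(start = c(0, 200), end = c(100, 300))
  g <- make_gene(ex, "+", cds = c(120, 280)) # 120 falls in the intron
  expect_error(classify_exons(g), "outside the exon union")
})

test_that("promoter windows span TSS-1000..TSS+500 in orientation", {
  g <- make_gene(tibble::tibble(start = 10000, end = 12000))
  w <- promoter_window(g)
  expect_equal(c(w$start, w$end), c(9000, 10500))
  expect_equal(w$end - w$start, 1500)

  gm <- make_gene(tibble::tibble(start = 18000, end = 20000), "-")
  wm <- promoter_window(gm)
  # TSS is the rightmost transcribed base (19999); 1000 bp upstream lies
  # genomically right of it, 500 bp downstream left of it
  expect_equal(wm$tss, 19999)
  expect_equal(c(wm$start, wm$end), c(19500, 21000))
  expect_equal(wm$end - wm$start, 1500)

  # edge clipping
  ge <- make_gene(tibble::tibble(start = 300, end = 900))
  we <- promoter_window(ge)
  expect_equal(c(we$start, we$end), c(0, 800))
  expect_equal(attr(we, "n_clipped"), 1)
})

test_that("promoter-CGI overlap uses half-open semantics", {
  g <- make_gene(tibble::tibble(start = 10000, end = 12000))
  w <- promoter_window(g)
  expect_true(promoter_has_cgi(w, tibble::tibble(chrom = "chr1",
    start = 9100, end = 9300)))
  # abutting island does not overlap
  expect_false(promoter_has_cgi(w, tibble::tibble(chrom = "chr1",
    start = 10500, end = 10700)))

  # brute-force all-pairs check on random windows/islands
  withr::with_seed(31, {
    ws <- tibble::tibble(chrom = "chr1", start = sample.int(1e5, 200))
    ws$end <- ws$start + 1500
    cg <- tibble::tibble(chrom = "chr1", start = sample.int(1e5, 100))
    cg$end <- cg$start + sample.int(2000, 100)
  })
  got <- promoter_has_cgi(ws, cg)
  want <- vapply(seq_len(nrow(ws)), function(i) {
    any(cg$start < ws$end[i] & cg$end > ws$start[i])
  }, logical(1))
  expect_equal(got, want)
})

test_that("introns tile the gaps between exons", {
  ex <- tibble::tibble(start = c(0, 200), end = c(100, 300))
  g <- make_gene(ex)
  intr <- introns_of(g)
  expect_equal(c(intr$start, intr$end), c(100, 200))

  expect_equal(nrow(introns_of(make_gene(tibble::tibble(start = 0,
    end = 100)))), 0)

  # exon union + intron union tiles the transcript span exactly
  sim <- sim_tiny()
  intr <- introns_of(sim$genes)
  for (i in seq_len(nrow(sim$genes))) {
    ex <- sim$genes$exons[[i]]
    ii <- intr[intr$transcript_id == sim$genes$transcript_id[i], ]
    covered <- sum(ex$end - ex$start) + sum(ii$end - ii$start)
    expect_equal(covered, sim$genes$end[i] - sim$genes$start[i])
  }
  # minus-strand intron ordinals run 5'->3'
  m <- sim$genes[sim$genes$strand == "-" &
    vapply(sim$genes$exons, nrow, integer(1)) > 2, ][1, ]
  im <- intr[intr$transcript_id == m$transcript_id, ]
  expect_equal(im$ordinal[order(im$start, decreasing = TRUE)],
    seq_len(nrow(im)))
})
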