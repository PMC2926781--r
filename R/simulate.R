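#' Simulation configuration for the synthetic genome/epigenome generator
#'
#' Defines the study conditions for the toy genome: chromosome layout,
#' gene architecture, planted CpG islands, and the multiplicative
#' factors planted into each sequencing track. All randomness is driven
#' by `seed`; the same config always reproduces the same dataset.
#'
#' Planted factors are multiplicative fragment-density factors relative
#' to a baseline of 1: `promoter_nfr_depletion` applies over
#' `[TSS - nfr_width, TSS)` of CGI promoters only (the nucleosome-free
#' region), `exon_nucleosome_enrichment` and
#' `exon_methylation_enrichment` over exons,
#' `cgi_methylation_depletion` over islands,
#' `skipped_fold_reduction` over skipped exons in the RNA-seq track, and
#' `h3k36me3_expression_coupling` exponentiates each gene's relative
#' expression in the H3K36me3 gene-body intensity.
#'
#' @param seed Integer seed.
#' @param genome_size Total genome length in bp.
#' @param n_chromosomes Number of (equal-sized) chromosomes.
#' @param background_gc Background GC fraction.
#' @param n_cgis Number of intergenic planted islands (promoter islands
#'   are planted in addition, one per CGI-promoter gene).
#' @param cgi_length Island length range in bp.
#' @param cgi_gc Island GC fraction (iid bases give an observed/expected
#'   CpG ratio near 1).
#' @param n_genes Number of genes.
#' @param exons_per_gene Range of exon counts.
#' @param exon_length,intron_length Exon/intron length ranges in bp.
#' @param coding_fraction Fraction of transcripts with a CDS.
#' @param promoter_cgi_fraction Fraction of genes whose promoter gets a
#'   planted island spanning the TSS.
#' @param promoter_nfr_depletion,nfr_width Nucleosome depletion factor
#'   and width of the promoter NFR window.
#' @param exon_nucleosome_enrichment,exon_methylation_enrichment,
#'   cgi_methylation_depletion,h3k36me3_expression_coupling Planted
#'   factors (see above).
#' @param skipped_exon_fraction Fraction of internal exons skipped.
#' @param skipped_fold_reduction RNA-seq density factor on skipped exons.
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   distribution parameters.
#' @param efficiency_sdlog Log-normal spread of pol II elongation
#'   efficiency (mean log 0).
#' @param library_size Tags per track.
#' @param fragment_length Library fragment size in bp.
#' @param tag_length Written tag length in bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_size = 1e7,
                       n_chromosomes = 2L,
                       background_gc = 0.30,
                       n_cgis = 100L,
                       cgi_length = c(1000, 2500),
                       cgi_gc = 0.70,
                       n_genes = 500L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(300, 900),
                       intron_length = c(800, 2400),
                       coding_fraction = 0.9,
                       promoter_cgi_fraction = 0.5,
                       promoter_nfr_depletion = 0.25,
                       nfr_width = 200,
                       exon_nucleosome_enrichment = 2,
                       exon_methylation_enrichment = 2,
                       cgi_methylation_depletion = 0.25,
                       h3k36me3_expression_coupling = 1,
                       skipped_exon_fraction = 0.10,
                       skipped_fold_reduction = 0.25,
                       expression_meanlog = log(10),
                       expression_sdlog = 1,
                       efficiency_sdlog = 0.7,
                       library_size = 1e6,
                       fragment_length = 150,
                       tag_length = 25) {
  cfg <- as.list(environment())
  assert_that(cfg$skipped_exon_fraction >= 0 && cfg$skipped_exon_fraction < 1,
    "skipped_exon_fraction must be in [0, 1)")
  factors <- c(cfg$promoter_nfr_depletion, cfg$exon_nucleosome_enrichment,
    cfg$exon_methylation_enrichment, cfg$cgi_methylation_depletion,
    cfg$skipped_fold_reduction)
  assert_that(all(factors > 0), "planted factors must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif_int <- function(n, range) {
  floor(runif(n, range[1], range[2] + 1))
}

# Deterministic coordinate layout: chromosome sizes, gene structures and
# all planted island intervals. Genes and intergenic islands are placed
# as shuffled units separated by >= min_gap, which guarantees that no
# island contaminates the promoter window of a non-CGI gene and no
# promoter island reaches a neighboring unit.
layout_simulation <- function(config) {
  with_seed(config$seed, layout_simulation_impl(config))
}

layout_simulation_impl <- function(config) {
  n_chrom <- config$n_chromosomes
  base_size <- floor(config$genome_size / n_chrom)
  chrom_sizes <- setNames(rep(base_size, n_chrom), paste0("chr", seq_len(n_chrom)))
  chrom_sizes[n_chrom] <- config$genome_size - base_size * (n_chrom - 1)

  n_genes <- config$n_genes
  # gene structures
  structures <- purrr::map(seq_len(n_genes), function(i) {
    k <- runif_int(1, config$exons_per_gene)
    ex_len <- runif_int(k, config$exon_length)
    in_len <- if (k > 1) runif_int(k - 1, config$intron_length) else numeric(0)
    list(exon_len = ex_len, intron_len = in_len,
      span = sum(ex_len) + sum(in_len))
  })
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  coding <- runif(n_genes) < config$coding_fraction
  n_cgi_prom <- round(n_genes * config$promoter_cgi_fraction)
  cgi_promoter <- rep(FALSE, n_genes)
  if (n_cgi_prom > 0) cgi_promoter[sample.int(n_genes, n_cgi_prom)] <- TRUE

  n_isl <- config$n_cgis
  isl_len <- runif_int(n_isl, config$cgi_length)
  prom_isl_len <- runif_int(n_genes, config$cgi_length)

  # units: genes (span) + intergenic islands (length), shuffled
  unit_span <- c(vapply(structures, `[[`, numeric(1), "span"), isl_len)
  unit_type <- c(rep("gene", n_genes), rep("island", n_isl))
  ord <- sample.int(length(unit_span))
  unit_span <- unit_span[ord]
  unit_type <- unit_type[ord]
  unit_id <- c(seq_len(n_genes), seq_len(n_isl))[ord]

  min_gap <- 4000
  edge <- 2500
  # proportional allocation of units to chromosomes
  alloc <- diff(round(seq(0, length(unit_span), length.out = n_chrom + 1)))
  placed <- vector("list", length(unit_span))
  u0 <- 0
  for (ci in seq_len(n_chrom)) {
    idx <- u0 + seq_len(alloc[ci])
    u0 <- u0 + alloc[ci]
    if (length(idx) == 0) next
    spans <- unit_span[idx]
    free <- chrom_sizes[ci] - 2 * edge - sum(spans) -
      (length(idx) + 1) * min_gap
    if (free < 0) {
      abort(sprintf(
        "genome cannot accommodate all genes/islands on %s (deficit %g bp)",
        names(chrom_sizes)[ci], -free))
    }
    w <- runif(length(idx) + 1)
    extra <- floor(free * w / sum(w))
    gaps <- min_gap + extra
    starts <- edge + cumsum(gaps)[seq_along(idx)] +
      c(0, cumsum(spans))[seq_along(idx)]
    for (j in seq_along(idx)) {
      placed[[idx[j]]] <- list(chrom = names(chrom_sizes)[ci],
        start = starts[j])
    }
  }

  genes <- vector("list", n_genes)
  islands <- list()
  for (u in seq_along(unit_span)) {
    p <- placed[[u]]
    if (unit_type[u] == "island") {
      islands[[length(islands) + 1]] <- tibble(
        chrom = p$chrom, start = p$start, end = p$start + unit_span[u],
        promoter = FALSE, transcript_id = NA_character_)
      next
    }
    gi <- unit_id[u]
    st <- structures[[gi]]
    k <- length(st$exon_len)
    ex_start <- p$start + c(0, cumsum(st$exon_len[-k] + st$intron_len))
    ex_end <- ex_start + st$exon_len
    gene_strand <- strand[gi]
    # CDS bounds: midpoints of the 2nd and (k-1)th transcription-order
    # exons (clamped for short transcripts)
    cds <- c(NA_real_, NA_real_)
    if (coding[gi]) {
      a_t <- min(2, k); b_t <- max(k - 1, a_t)
      to_genomic <- function(t_ord) if (gene_strand == "-") k + 1 - t_ord else t_ord
      mids <- vapply(c(a_t, b_t), function(t_ord) {
        j <- to_genomic(t_ord)
        floor((ex_start[j] + ex_end[j]) / 2)
      }, numeric(1))
      cds <- sort(mids)
      if (cds[1] == cds[2]) cds[2] <- cds[2] + 1
    }
    tid <- sprintf("gene%04d", gi)
    tss <- if (gene_strand == "-") ex_end[k] - 1 else ex_start[1]
    genes[[gi]] <- tibble(
      transcript_id = tid, chrom = p$chrom, strand = gene_strand,
      start = ex_start[1], end = ex_end[k],
      cds_start = cds[1], cds_end = cds[2],
      exons = list(tibble(start = ex_start, end = ex_end))
    )
    if (cgi_promoter[gi]) {
      # island spans the TSS: 3' edge 300 bp downstream of it
      L <- prom_isl_len[gi]
      if (gene_strand == "-") {
        isl <- c(tss - 300 + 1, tss - 300 + 1 + L)
      } else {
        isl <- c(tss + 300 - L, tss + 300)
      }
      islands[[length(islands) + 1]] <- tibble(
        chrom = p$chrom, start = isl[1], end = isl[2],
        promoter = TRUE, transcript_id = tid)
    }
  }

  genes <- bind_rows(genes)
  islands <- bind_rows(islands)
  if (nrow(islands) == 0) {
    islands <- tibble(chrom = character(), start = numeric(),
      end = numeric(), promoter = logical(), transcript_id = character())
  }
  islands <- arrange(islands, .data$chrom, .data$start)

  # skipped exons among internal exons of transcripts with >= 3 exons
  skipped <- purrr::map(seq_len(nrow(genes)), function(i) {
    k <- nrow(genes$exons[[i]])
    if (k < 3) return(NULL)
    internal <- 2:(k - 1)
    hit <- internal[runif(length(internal)) < config$skipped_exon_fraction]
    if (length(hit) == 0) return(NULL)
    tibble(transcript_id = genes$transcript_id[i], ordinal = hit)
  })
  skipped <- bind_rows(skipped)
  if (nrow(skipped) == 0) {
    skipped <- tibble(transcript_id = character(), ordinal = integer())
  }

  expression <- rlnorm(n_genes, config$expression_meanlog,
    config$expression_sdlog)
  efficiency <- rlnorm(n_genes, 0, config$efficiency_sdlog)

  list(
    chrom_sizes = chrom_sizes,
    genes = genes,
    islands = islands,
    cgi_promoter = setNames(cgi_promoter, genes$transcript_id),
    skipped = skipped,
    expression = setNames(expression, genes$transcript_id),
    efficiency = setNames(efficiency, genes$transcript_id)
  )
}

#' Generate the synthetic genome sequence with planted CpG islands
#'
#' Background bases are iid at `background_gc`; planted island intervals
#' are overwritten with iid bases at `cgi_gc`, which satisfies all three
#' island criteria (GC >= 0.5, obs/exp CpG around 1, length > 200 bp)
#' with margin. Byte-identical output under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `chrom_sizes`,
#'   and `cgis` (planted island tibble with `promoter` flag and owning
#'   `transcript_id`).
#' @export
generate_genome <- function(config) {
  layout <- layout_simulation(config)
  bases <- c("A", "C", "G", "T")
  genome <- with_seed(config$seed + 1L, {
    out <- setNames(vector("character", length(layout$chrom_sizes)),
      names(layout$chrom_sizes))
    for (ch in names(layout$chrom_sizes)) {
      n <- layout$chrom_sizes[[ch]]
      gc <- config$background_gc
      p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      letters_vec <- bases[sample.int(4, n, replace = TRUE, prob = p)]
      isl <- layout$islands[layout$islands$chrom == ch, ]
      if (nrow(isl) > 0) {
        gci <- config$cgi_gc
        pi_ <- c((1 - gci) / 2, gci / 2, gci / 2, (1 - gci) / 2)
        for (j in seq_len(nrow(isl))) {
          len <- isl$end[j] - isl$start[j]
          letters_vec[(isl$start[j] + 1):isl$end[j]] <-
            bases[sample.int(4, len, replace = TRUE, prob = pi_)]
        }
      }
      out[[ch]] <- paste(letters_vec, collapse = "")
    }
    out
  })
  list(genome = genome, chrom_sizes = layout$chrom_sizes,
    cgis = layout$islands)
}

#' Generate synthetic gene models and ground truth
#'
#' @param config A [sim_config()].
#' @param genome Output of [generate_genome()] (used for its layout
#'   consistency; the layout is deterministic in the config seed).
#' @return List with `genes` (gene-model tibble) and `truth`, a list
#'   holding planted island intervals, per-promoter CGI/NFR flags,
#'   skipped-exon identifiers, and per-gene expression, elongation
#'   efficiency and pol II density.
#' @export
generate_genes <- function(config, genome) {
  layout <- layout_simulation(config)
  genes <- layout$genes
  promoters <- promoter_window(genes, chrom_sizes = layout$chrom_sizes)
  promoters$cgi_status <- promoter_has_cgi(promoters, layout$islands)
  promoters$nfr <- layout$cgi_promoter[promoters$transcript_id]
  truth <- list(
    cgis = layout$islands,
    promoters = promoters,
    skipped_exons = layout$skipped,
    genes = tibble(
      transcript_id = genes$transcript_id,
      expression = unname(layout$expression),
      efficiency = unname(layout$efficiency),
      polII_density = unname(layout$expression / layout$efficiency)
    )
  )
  list(genes = genes, truth = truth)
}

# Piecewise-constant intensity: baseline 1 over each chromosome,
# multiplied by each overlay factor where its intervals lie. Returns a
# tibble of disjoint segments chrom/start/end/weight (weight = intensity
# x length is computed by the sampler).
intensity_segments <- function(chrom_sizes, overlays) {
  out <- purrr::map(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    logf <- S4Vectors::Rle(0, size)
    for (ov in overlays) {
      iv <- ov$intervals
      iv$.factor <- ov$factor # scalar or one value per row
      iv <- iv[iv$chrom == ch & iv$end > iv$start, , drop = FALSE]
      if (nrow(iv) == 0) next
      s <- pmax(iv$start, 0); e <- pmin(iv$end, size)
      keep <- e > s
      if (!any(keep)) next
      cov <- IRanges::coverage(
        IRanges::IRanges(start = s[keep] + 1, end = e[keep]),
        weight = log(iv$.factor[keep]), width = size
      )
      logf <- logf + cov
    }
    ends <- cumsum(S4Vectors::runLength(logf))
    starts <- c(0, head(ends, -1))
    tibble(chrom = ch, start = starts, end = ends,
      intensity = exp(S4Vectors::runValue(logf)))
  })
  bind_rows(out)
}

# Sample `n` fragment centers from piecewise-constant segments and emit
# 5'-anchored tags of tag_length with random strand.
sample_tags <- function(segments, n, fragment_length, tag_length,
                        chrom_sizes) {
  w <- segments$intensity * (segments$end - segments$start)
  keep <- w > 0
  segments <- segments[keep, ]
  w <- w[keep]
  idx <- sample.int(nrow(segments), n, replace = TRUE, prob = w)
  center <- floor(segments$start[idx] +
    runif(n) * (segments$end[idx] - segments$start[idx]))
  half <- floor(fragment_length / 2)
  chrom <- segments$chrom[idx]
  # keep the whole fragment on the chromosome
  center <- pmax(center, half)
  center <- pmin(center, unname(chrom_sizes[chrom]) - (fragment_length - half))
  fs <- center - half
  fe <- fs + fragment_length
  minus <- runif(n) < 0.5
  start <- ifelse(minus, fe - tag_length, fs)
  end <- start + tag_length
  ord <- order(chrom, start)
  tag_set(tibble(chrom = chrom[ord], start = start[ord], end = end[ord],
    strand = ifelse(minus, "-", "+")[ord]), fragment_length)
}

#' Generate the five synthetic tag tracks
#'
#' Samples fragment centers from piecewise-constant intensities built
#' from the planted factors, then writes 5'-anchored tags of
#' `tag_length` bp (to be re-extended to `fragment_length` by the
#' pipeline):
#' * `nucleosome`: baseline, exon enrichment, NFR depletion in CGI
#'   promoters;
#' * `methylation`: baseline, exon enrichment, island depletion;
#' * `h3k36me3`: nucleosome-style exon enrichment multiplied by each
#'   gene's relative expression raised to the coupling exponent;
#' * `polII`: gene bodies at each gene's planted pol II density over a
#'   low intergenic baseline;
#' * `rnaseq`: exons only, proportional to gene expression, skipped
#'   exons at the planted fold-reduction.
#'
#' @param config A [sim_config()].
#' @param genome Output of [generate_genome()].
#' @param genes Gene-model tibble from [generate_genes()].
#' @param truth Ground-truth list from [generate_genes()].
#' @return Named list of `tag_set` tibbles.
#' @export
generate_tags <- function(config, genome, genes, truth) {
  chrom_sizes <- genome$chrom_sizes
  exon_tbl <- bind_rows(purrr::map(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    tibble(chrom = genes$chrom[i], start = ex$start, end = ex$end,
      transcript_id = genes$transcript_id[i],
      ordinal = if (genes$strand[i] == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex)))
  }))
  gene_tbl <- genes[, c("chrom", "start", "end", "transcript_id")]
  prom <- truth$promoters
  nfr <- prom[prom$nfr, ]
  minus <- nfr$strand == "-"
  nfr_win <- tibble(
    chrom = nfr$chrom,
    start = ifelse(minus, nfr$tss + 1, nfr$tss - config$nfr_width),
    end = ifelse(minus, nfr$tss + 1 + config$nfr_width, nfr$tss)
  )
  islands <- truth$cgis

  expr <- setNames(truth$genes$expression, truth$genes$transcript_id)
  rel_expr <- expr / mean(expr)
  dens <- setNames(truth$genes$polII_density, truth$genes$transcript_id)
  rel_dens <- dens / mean(dens)

  skipped_key <- paste(truth$skipped_exons$transcript_id,
    truth$skipped_exons$ordinal)
  exon_skipped <- paste(exon_tbl$transcript_id, exon_tbl$ordinal) %in% skipped_key

  tracks <- list(
    nucleosome = list(
      list(intervals = exon_tbl, factor = config$exon_nucleosome_enrichment),
      list(intervals = nfr_win, factor = config$promoter_nfr_depletion)
    ),
    methylation = list(
      list(intervals = exon_tbl, factor = config$exon_methylation_enrichment),
      list(intervals = islands, factor = config$cgi_methylation_depletion)
    ),
    h3k36me3 = list(
      list(intervals = exon_tbl, factor = config$exon_nucleosome_enrichment),
      list(intervals = gene_tbl,
        factor = rel_expr[gene_tbl$transcript_id]^config$h3k36me3_expression_coupling)
    ),
    polII = list(
      # low intergenic baseline, gene bodies at the planted density
      list(intervals = tibble(chrom = names(chrom_sizes), start = 0,
        end = unname(chrom_sizes)), factor = 0.05),
      list(intervals = gene_tbl,
        factor = rel_dens[gene_tbl$transcript_id] / 0.05)
    )
  )

  with_seed(config$seed + 2L, {
    out <- purrr::map(tracks, function(ovl) {
      seg <- intensity_segments(chrom_sizes, ovl)
      sample_tags(seg, config$library_size, config$fragment_length,
        config$tag_length, chrom_sizes)
    })
    # RNA-seq: exonic only
    rna_w <- unname(expr[exon_tbl$transcript_id]) *
      ifelse(exon_skipped, config$skipped_fold_reduction, 1)
    rna_seg <- tibble(chrom = exon_tbl$chrom, start = exon_tbl$start,
      end = exon_tbl$end, intensity = rna_w)
    out$rnaseq <- sample_tags(rna_seg, config$library_size,
      config$fragment_length, config$tag_length, chrom_sizes)
    out
  })
}

#' Run the full synthetic-data generator
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genome`, `chrom_sizes`, `cgis`, `genes`,
#'   `truth` and `tags` (named list of tag sets).
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- generate_genome(config)
  gg <- generate_genes(config, g)
  tags <- generate_tags(config, g, gg$genes, gg$truth)
  list(config = config, genome = g$genome, chrom_sizes = g$chrom_sizes,
    cgis = g$cgis, genes = gg$genes, truth = gg$truth, tags = tags)
}
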