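#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis. Inputs
#' come either from a simulation config (`sim`) or from file paths
#' (`inputs`, a named list with `genome_fa`, `genes_bed12`, and a
#' `tags` list of per-track BED paths; optional `cgis_bed` to use an
#' external island set instead of the de novo scan).
#'
#' @param sim A [sim_config()], or NULL when reading files.
#' @param inputs Named list of input paths (see above), or NULL.
#' @param fragment_length Fragment extension length in bp.
#' @param bin_width Genome-track bin width in bp.
#' @param pseudocount NRC pseudocount.
#' @param promoter_upstream,promoter_downstream Promoter window in bp.
#' @param n_bins Scaled bins per exon/intron.
#' @param tss_flank TSS profile half-width in bp.
#' @param low_q,high_q Inclusiveness class quantiles.
#' @param very_weak_q,weak_q Weak-exon class quantiles.
#' @param mappable_fraction Mappable genome fraction for the odds ratio.
#' @param n_quantiles Gene-value quantile bins.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            fragment_length = 150, bin_width = 200,
                            pseudocount = 1, promoter_upstream = 1000,
                            promoter_downstream = 500, n_bins = 10,
                            tss_flank = 1000, low_q = 0.10, high_q = 0.90,
                            very_weak_q = 0.05, weak_q = 0.10,
                            mappable_fraction = 0.8, n_quantiles = 10) {
  cfg <- as.list(environment())
  assert_that(!is.null(cfg$sim) || !is.null(cfg$inputs),
    "either sim or inputs must be provided")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim` map
#' is passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

read_pipeline_inputs <- function(config) {
  inp <- config$inputs
  required <- c("genome_fa", "genes_bed12", "tags")
  for (f in required) {
    if (is.null(inp[[f]])) abort(sprintf("missing input field: %s", f))
  }
  for (f in c("genome_fa", "genes_bed12")) {
    if (!file.exists(inp[[f]])) {
      abort(sprintf("input field %s: file not found: %s", f, inp[[f]]))
    }
  }
  genome <- read_fasta(inp$genome_fa)
  chrom_sizes <- setNames(nchar(genome), names(genome))
  genes <- read_bed12_genes(inp$genes_bed12)
  tags <- purrr::imap(inp$tags, function(p, nm) {
    if (!file.exists(p)) abort(sprintf("input field tags$%s: file not found: %s", nm, p))
    read_bed_tags(p, config$fragment_length)
  })
  cgis <- if (!is.null(inp$cgis_bed)) read_bed(inp$cgis_bed) else NULL
  expression <- if (!is.null(inp$expression_tsv)) {
    read_table_tsv(inp$expression_tsv)
  } else {
    NULL
  }
  list(genome = genome, chrom_sizes = chrom_sizes, genes = genes,
    tags = tags, cgis = cgis, expression = expression, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> coverage tracks -> CGI detection ->
#' exon/promoter annotation -> metagene profiles -> inclusiveness,
#' weak-exon and enrichment statistics, writing every result as a plain
#' text file plus a manifest with content hashes. Outputs are
#' deterministic given the config (and its seed), so re-running
#' reproduces the manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with `outdir`, the `manifest` tibble and
#'   the in-memory result objects.
#' @export
run_pipeline <- function(config, outdir, quiet = TRUE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(file, writer) {
    p <- file.path(outdir, file)
    writer(p)
    paths <<- c(paths, p)
    p
  }

  # ---- inputs ------------------------------------------------------
  if (!is.null(config$sim)) {
    say("simulating dataset (seed %d)", config$sim$seed)
    sim <- simulate_dataset(config$sim)
    genome <- sim$genome; chrom_sizes <- sim$chrom_sizes
    genes <- sim$genes; tags <- sim$tags; truth <- sim$truth
    expression <- tibble(transcript_id = truth$genes$transcript_id,
      expression = truth$genes$expression)
    emit("genome.fa", function(p) write_fasta(genome, p))
    emit("genes.bed12", function(p) write_bed12_genes(genes, p))
    emit("cgis_planted.bed", function(p) write_bed(sim$cgis, p))
    for (nm in names(tags)) {
      emit(paste0("tags_", nm, ".bed"),
        local({ t <- tags[[nm]]; function(p) write_bed(t, p) }))
    }
    emit("expression.tsv", function(p) write_table_tsv(expression, p))
    emit("truth.json", function(p) jsonlite::write_json(
      list(
        skipped_exons = truth$skipped_exons,
        promoters = truth$promoters,
        genes = truth$genes
      ), p, digits = NA))
    external_cgis <- NULL
  } else {
    loaded <- read_pipeline_inputs(config)
    genome <- loaded$genome; chrom_sizes <- loaded$chrom_sizes
    genes <- loaded$genes; tags <- loaded$tags; truth <- NULL
    expression <- loaded$expression
    external_cgis <- loaded$cgis
  }
  genome_size <- sum(chrom_sizes)

  # ---- coverage tracks ---------------------------------------------
  say("building %d coverage tracks", length(tags))
  frags <- purrr::map(tags, extend_tags, chrom_sizes = chrom_sizes,
    fragment_length = config$fragment_length)
  for (nm in names(frags)) {
    track <- bin_counts(frags[[nm]], chrom_sizes, config$bin_width,
      config$pseudocount)
    emit(paste0("track_", nm, ".bedgraph"),
      local({ tr <- track; function(p) write_bedgraph(tr, p) }))
  }

  # ---- CGI detection -----------------------------------------------
  say("detecting CpG islands")
  cgis <- external_cgis %||% detect_cgis(genome)
  emit("cgis_detected.bed", function(p) write_bed(cgis, p,
    extra = intersect(c("gc_fraction", "obs_exp"), names(cgis))))

  # ---- annotation --------------------------------------------------
  say("annotating exons and promoters")
  exon_records <- classify_exons(genes)
  introns <- introns_of(genes)
  promoters <- annotate_promoters(genes, cgis, config$promoter_upstream,
    config$promoter_downstream, chrom_sizes)
  emit("exons.tsv", function(p) write_table_tsv(
    exon_records[, setdiff(names(exon_records), "segments")], p))
  emit("promoters.tsv", function(p) write_table_tsv(promoters, p))

  # ---- profiles ----------------------------------------------------
  nuc <- frags$nucleosome
  results <- list()
  if (!is.null(nuc)) {
    say("computing metagene profiles")
    results$cgi_profile <- feature_profile(nuc, cgis, genome_size,
      pseudocount = config$pseudocount)
    emit("profile_cgi.tsv", function(p)
      write_table_tsv(profile_summary(results$cgi_profile), p))
    tssp <- tss_profile(nuc, promoters, genome_size,
      flank_bp = config$tss_flank, pseudocount = config$pseudocount)
    results$tss_profiles <- tssp
    for (nm in names(tssp)) {
      if (is.null(tssp[[nm]])) next
      emit(paste0("profile_tss_", nm, ".tsv"),
        local({ s <- profile_summary(tssp[[nm]]); function(p) write_table_tsv(s, p) }))
    }
    eip <- exon_intron_profile(nuc, exon_records, introns, genome_size,
      n_bins = config$n_bins, pseudocount = config$pseudocount)
    results$exon_intron_profiles <- eip
    eip_tbl <- bind_rows(purrr::imap(eip, function(p, nm) {
      s <- profile_summary(p); s$profile <- nm; s
    }))
    emit("profile_exon_intron.tsv", function(p) write_table_tsv(eip_tbl, p))
  }

  # ---- splicing statistics -----------------------------------------
  if (!is.null(frags$rnaseq)) {
    say("scoring exon inclusiveness")
    incl <- exon_inclusiveness(frags$rnaseq, genes, genome_size,
      config$pseudocount)
    incl_cls <- classify_inclusiveness(incl, config$low_q, config$high_q)
    results$inclusiveness <- incl_cls
    emit("inclusiveness.tsv", function(p) write_table_tsv(incl_cls, p))
  }

  say("filtering weak exons")
  scores <- score_splice_sites(exon_records, genome)
  weak <- weak_exon_filter(exon_records, introns, scores, genome,
    very_weak_q = config$very_weak_q, weak_q = config$weak_q)
  results$weak_exons <- weak
  emit("weak_exons.tsv", function(p) write_table_tsv(
    weak[, setdiff(names(weak), "segments")], p))

  # ---- open-chromatin enrichment -----------------------------------
  # promoter NFR windows serve as the open-chromatin interval set
  open_chromatin <- {
    minus <- promoters$strand == "-"
    tibble(
      chrom = promoters$chrom,
      start = ifelse(minus, promoters$tss + 1, promoters$tss - 200),
      end = ifelse(minus, promoters$tss + 201, promoters$tss)
    )
  }
  or_tbl <- odds_ratio_enrichment(open_chromatin, cgis, genome_size,
    config$mappable_fraction)
  results$odds_ratio <- or_tbl
  emit("odds_ratio.tsv", function(p) write_table_tsv(or_tbl, p))

  # ---- expression / elongation quantile profiles -------------------
  if (!is.null(expression) && !is.null(frags$polII) &&
      !is.null(results$inclusiveness)) {
    say("computing quantile profiles")
    expr <- expression$expression[match(genes$transcript_id,
      expression$transcript_id)]
    ok <- !is.na(expr) & expr > 0
    eff <- elongation_efficiency(expr[ok], frags$polII, genes[ok, ],
      genome_size, pseudocount = 1)
    results$elongation <- eff
    emit("elongation_efficiency.tsv", function(p) write_table_tsv(eff, p))

    internal <- exon_records[exon_records$is_internal, ]
    marks <- tibble(
      transcript_id = internal$transcript_id,
      nucleosome = if (!is.null(frags$nucleosome))
        feature_nrc(frags$nucleosome, internal, genome_size) else NULL,
      methylation = if (!is.null(frags$methylation))
        feature_nrc(frags$methylation, internal, genome_size) else NULL,
      h3k36me3 = if (!is.null(frags$h3k36me3))
        feature_nrc(frags$h3k36me3, internal, genome_size) else NULL
    )
    gene_vals <- tibble(
      transcript_id = genes$transcript_id[ok],
      value = expr[ok],
      cgi_promoter = promoters$cgi_status[match(genes$transcript_id[ok],
        promoters$transcript_id)]
    )
    nq <- min(config$n_quantiles, nrow(gene_vals))
    results$quantile_expression <- quantile_profile(marks, gene_vals, nq)
    emit("quantile_expression.tsv", function(p)
      write_table_tsv(results$quantile_expression, p))

    gene_eff <- gene_vals
    gene_eff$value <- eff$efficiency[match(gene_eff$transcript_id,
      eff$transcript_id)]
    gene_eff <- gene_eff[!is.na(gene_eff$value), ]
    results$quantile_efficiency <- quantile_profile(marks, gene_eff,
      min(config$n_quantiles, nrow(gene_eff)))
    emit("quantile_efficiency.tsv", function(p)
      write_table_tsv(results$quantile_efficiency, p))
  }

  # ---- manifest ----------------------------------------------------
  manifest <- tibble(
    file = basename(paths),
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths))
  ) |> arrange(.data$file)
  write_table_tsv(manifest, file.path(outdir, "manifest.tsv"))
  say("pipeline complete: %d files", nrow(manifest))
  invisible(list(outdir = outdir, manifest = manifest, results = results,
    truth = truth))
}
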