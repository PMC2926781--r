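# Lazily built, memoised simulation fixtures shared across test files.
# Heavy datasets are built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, builder(), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# Default study conditions: 10-Mb genome, 500 genes, 1e6 tags per track.
sim_default <- function() {
  cached("default", function() {
    sim <- simulate_dataset(sim_config(seed = 42))
    sim$genome_size <- sum(sim$chrom_sizes)
    sim
  })
}

# Long-feature config: exons/introns large relative to the 150-bp
# fragment so planted density factors are resolvable in ten-bin
# profiles.
sim_long_features <- function(seed = 11, ...) {
  key <- paste0("long", seed)
  cached(key, function() {
    sim <- simulate_dataset(sim_config(seed = seed, n_genes = 100,
      exons_per_gene = c(6, 10), exon_length = c(1500, 2500),
      intron_length = c(4000, 8000), n_cgis = 0,
      promoter_cgi_fraction = 0, skipped_exon_fraction = 0, ...))
    sim$genome_size <- sum(sim$chrom_sizes)
    sim
  })
}

# Tiny fast simulation for structural checks.
sim_tiny <- function() {
  cached("tiny", function() {
    sim <- simulate_dataset(sim_config(seed = 3, genome_size = 2e6,
      n_chromosomes = 1, n_genes = 30, n_cgis = 15, library_size = 2e5))
    sim$genome_size <- sum(sim$chrom_sizes)
    sim
  })
}

# Uniform point-tag library on a bare genome.
uniform_point_tags <- function(n = 1e5, genome_size = 1e6, seed = 99) {
  withr::with_seed(seed, {
    st <- floor(runif(n, 0, genome_size - 1))
    tag_set(tibble::tibble(chrom = "chr1", start = st, end = st + 1,
      strand = "+"), fragment_length = 1)
  })
}

expect_tbl_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
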