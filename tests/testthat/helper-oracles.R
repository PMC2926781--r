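# Independent brute-force oracles. These deliberately use different
# primitives (character splitting, per-base logical vectors, naive
# loops) from the implementation they check.

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch != "N"]
  sum(ch %in% c("G", "C")) / length(ch)
}

oracle_obs_exp <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  keep <- ch != "N"
  n <- sum(keep)
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  if (nc == 0 || ng == 0) return(0)
  cpg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  cpg * n / (nc * ng)
}

# Window enumeration + merge + re-validation, written as a plain loop.
oracle_detect_cgis <- function(seq, min_gc = 0.5, min_len = 201,
                               min_obs_exp = 0.6, window = 200) {
  n <- nchar(seq)
  seeds <- list()
  for (s in seq_len(n - window + 1)) {
    w <- substr(seq, s, s + window - 1)
    ch <- strsplit(w, "")[[1]]
    if (sum(ch == "N") > window / 2) next
    if (oracle_gc(w) >= min_gc && oracle_obs_exp(w) > min_obs_exp) {
      seeds[[length(seeds) + 1]] <- c(s, s + window - 1)
    }
  }
  if (length(seeds) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  merged <- list()
  cur <- seeds[[1]]
  for (sd in seeds[-1]) {
    if (sd[1] <= cur[2] + 1) {
      cur[2] <- max(cur[2], sd[2])
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- sd
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- list()
  for (m in merged) {
    sub <- substr(seq, m[1], m[2])
    len <- m[2] - m[1] + 1
    if (len >= min_len && oracle_gc(sub) >= min_gc &&
        oracle_obs_exp(sub) > min_obs_exp) {
      out[[length(out) + 1]] <- data.frame(start = m[1] - 1, end = m[2])
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  do.call(rbind, out)
}

oracle_bendability <- function(seq, table) {
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  total <- 0
  for (i in seq_len(length(ch) - 2)) {
    tri <- ch[i:(i + 2)]
    if (any(!tri %in% names(comp))) next
    fwd <- paste(tri, collapse = "")
    rc <- paste(rev(unname(comp[tri])), collapse = "")
    key <- if (fwd <= rc) fwd else rc
    total <- total + table[[key]]
  }
  total
}

# Naive per-bin overlap scan for fragments on one chromosome.
oracle_bin_counts <- function(starts, ends, chrom_len, bin_width) {
  n_bins <- ceiling(chrom_len / bin_width)
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    b0 <- (b - 1) * bin_width
    b1 <- min(b0 + bin_width, chrom_len)
    counts[b] <- sum(starts < b1 & ends > b0)
  }
  counts
}

# Per-base membership odds ratio on a small genome.
oracle_odds_ratio <- function(marks, features, genome_len,
                              mappable_fraction) {
  mark_vec <- logical(genome_len)
  for (i in seq_len(nrow(marks))) {
    mark_vec[(marks$start[i] + 1):marks$end[i]] <- TRUE
  }
  feat_vec <- logical(genome_len)
  for (i in seq_len(nrow(features))) {
    feat_vec[(features$start[i] + 1):features$end[i]] <- TRUE
  }
  p_f <- sum(mark_vec & feat_vec) / sum(feat_vec)
  p_g <- sum(mark_vec) / (genome_len * mappable_fraction)
  (p_f / (1 - p_f)) / (p_g / (1 - p_g))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

random_bend_table <- function() {
  tris <- names(Biostrings::trinucleotideFrequency(Biostrings::DNAString("AAA")))
  canon <- unique(canonical_trinucleotide(tris))
  setNames(round(runif(32, -1, 1), 4), canon)
}
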