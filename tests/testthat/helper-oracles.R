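# Independent oracles and small fixture builders shared across tests.

# Poisson upper tail by direct pmf summation from k upward, entirely
# independent of the regularized-gamma path used by the implementation.
oracle_poisson_upper <- function(k, lambda) {
  if (k == 0) return(1)
  i <- k
  total <- 0
  repeat {
    term <- exp(-lambda + i * log(lambda) - lgamma(i + 1))
    total <- total + term
    i <- i + 1
    if (term < total * 1e-18 || i > k + lambda + 2000) break
  }
  total
}

# Per-base rasterization oracle for bin counting: extend each read by the
# strand rule, walk its bases, and mark every bin touched (once per read).
oracle_bin_counts <- function(reads, chrom_lengths, bin_size, extension) {
  counts <- lapply(chrom_lengths, function(len)
    numeric(ceiling(len / bin_size)))
  for (i in seq_len(nrow(reads))) {
    ch <- reads$chrom[i]
    if (reads$strand[i] == "+") {
      s <- reads$start[i]; e <- reads$start[i] + extension
    } else {
      s <- reads$end[i] - extension; e <- reads$end[i]
    }
    s <- max(s, 0); e <- min(e, chrom_lengths[[ch]])
    if (s >= e) next
    touched <- unique((seq(s, e - 1)) %/% bin_size)
    counts[[ch]][touched + 1] <- counts[[ch]][touched + 1] + 1
  }
  counts
}

# Exhaustive per-read classification oracle: test every category
# independently against the raw window intervals of every gene, then apply
# the fixed priority order.
oracle_classify_read <- function(read_start, read_end, read_chrom, windows) {
  order_ <- c("tss_region", "utr5", "tts_region", "utr3", "exonic", "intronic")
  hits <- character(0)
  for (cls in order_) {
    for (w in windows) {
      if (w$chrom != read_chrom) next
      iv <- w[[cls]]
      if (NROW(iv) && any(iv$start < read_end & read_start < iv$end)) {
        hits <- c(hits, cls)
        break
      }
    }
  }
  for (cls in order_) if (cls %in% hits) return(cls)
  "intergenic"
}

# Direct windowed-mean oracle for the local background estimator.
oracle_windowed_mean <- function(x, window_bins) {
  half <- (window_bins - 1) %/% 2
  vapply(seq_along(x), function(i) {
    lo <- max(i - half, 1); hi <- min(i + half, length(x))
    mean(x[lo:hi])
  }, 0)
}

# ---- fixtures ----------------------------------------------------------

toy_gene_plus <- function() {
  gene_model("TOYP", "chrT", "+", 1000, 5000,
             exons = data.frame(start = c(1000, 2500, 4200),
                                end = c(1800, 3000, 5000)),
             cds_start = 1400, cds_end = 4600)
}

toy_gene_minus <- function() {
  gene_model("TOYM", "chrT", "-", 1000, 5000,
             exons = data.frame(start = c(1000, 2500, 4200),
                                end = c(1800, 3000, 5000)),
             cds_start = 1400, cds_end = 4600)
}

# a small random gene on one chromosome (used by property tests)
random_gene <- function(id, chrom, chrom_length) {
  len <- sample(1500:4000, 1)
  start <- sample(500:(chrom_length - len - 500), 1)
  n_ex <- sample(2:4, 1)
  n_seg <- 2 * n_ex - 1
  min_seg <- 120
  extra <- as.vector(stats::rmultinom(1, len - n_seg * min_seg,
                                      rep(1, n_seg)))
  seg <- min_seg + extra
  bounds <- start + c(0, cumsum(seg))
  ex_idx <- seq(1, n_seg, by = 2)
  exons <- data.frame(start = bounds[ex_idx], end = bounds[ex_idx + 1])
  gene_model(id, chrom, sample(c("+", "-"), 1), start, start + len, exons,
             cds_start = exons$start[1] + 60,
             cds_end = exons$end[n_ex] - 60)
}

random_reads <- function(n, chrom_lengths, read_length = 36) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  start <- floor(runif(n, 0, unname(chrom_lengths[chrom]) - read_length))
  data.frame(chrom = chrom, start = start, end = start + read_length,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

# tiny two-transcript GTF for the multi-transcript collapse test
write_toy_gtf <- function(path) {
  attr1 <- 'gene_id "GX"; transcript_id "GX.1";'
  attr2 <- 'gene_id "GX"; transcript_id "GX.2";'
  lines <- c(
    paste("chr1", "toy", "exon", 101, 300, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "toy", "exon", 501, 700, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "toy", "CDS", 151, 300, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "toy", "CDS", 501, 650, ".", "+", ".", attr2, sep = "\t"),
    paste("chr1", "toy", "exon", 201, 420, ".", "+", ".", attr2, sep = "\t"),
    paste("chr1", "toy", "exon", 501, 800, ".", "+", ".", attr2, sep = "\t"))
  writeLines(lines, path)
  path
}

# small quick simulation config for end-to-end tests (defaults overridable)
small_config <- function(seed, ...) {
  args <- list(seed = seed, n_chroms = 2, chrom_length = 4e5, n_genes = 40,
               set_sizes = c(BRD4 = 12, BRD4_JMJD6 = 10, BRD4_CHD4 = 8),
               n_responsive = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
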