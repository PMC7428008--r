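# Synthetic two-condition ChIP-Seq experiment generator.
#
# Libraries are {BRD4, gH2AX, RNAPII ser2, whole-cell-extract input} x
# {DMSO, JQ1}. Background read starts are uniform over the genome; target
# libraries implant extra reads over the bodies of set-member genes at rate
# background_rate x (fold - 1) per bin, with BRD4 additionally concentrated
# at TSS windows. A configurable subset of BRD4-regulated genes is
# "JQ1-responsive": gH2AX gains (fold 4 vs 1 by default) while BRD4 and
# RNAPII ser2 enrichment drops under JQ1.

.SIM_TARGETS <- c("brd4", "gh2ax", "rnapii_ser2", "input")
.SIM_CONDITIONS <- c("DMSO", "JQ1")

.default_fold_table <- function() {
  # fold = per-bin enrichment multiple over background at affected genes;
  # applies to gene-set members only (class: responsive / nonresponsive)
  rbind(
    data.frame(target = "gh2ax", condition = c("DMSO", "JQ1", "DMSO", "JQ1"),
               gene_class = c("responsive", "responsive",
                              "nonresponsive", "nonresponsive"),
               fold = c(1, 4, 1, 1)),
    data.frame(target = "brd4", condition = c("DMSO", "JQ1", "DMSO", "JQ1"),
               gene_class = c("responsive", "responsive",
                              "nonresponsive", "nonresponsive"),
               fold = c(4, 1.5, 4, 4)),
    data.frame(target = "rnapii_ser2",
               condition = c("DMSO", "JQ1", "DMSO", "JQ1"),
               gene_class = c("responsive", "responsive",
                              "nonresponsive", "nonresponsive"),
               fold = c(3, 1.2, 3, 3)),
    data.frame(target = "input", condition = c("DMSO", "JQ1"),
               gene_class = "any", fold = c(1, 1)))
}

#' Configuration for the synthetic ChIP-Seq experiment
#'
#' Defaults describe the emulated study design: a 500-gene genome with 39
#' JQ1-responsive damage genes inside the BRD4-regulated set, background of
#' 0.5 reads per 25-bp bin per library, and gH2AX enrichment fold 4 (JQ1)
#' vs 1 (DMSO) at responsive genes while BRD4 and RNAPII ser2 drop.
#'
#' @param seed Integer seed; the same seed reproduces the experiment
#'   byte-identically.
#' @param n_chroms,chrom_length Genome shape (default 4 x 2 Mb).
#' @param n_genes Number of genes (default 500).
#' @param set_sizes Named sizes of the gene sets (default `BRD4 = 120`,
#'   `BRD4_JMJD6 = 150`, `BRD4_CHD4 = 120`; memberships may overlap).
#' @param n_responsive JQ1-responsive genes, drawn from the BRD4 set
#'   (default 39).
#' @param background_rate Expected background reads per bin per library
#'   (default 0.5).
#' @param enrichment_fold data.frame(`target`, `condition`, `gene_class`,
#'   `fold`) of per-bin enrichment multiples at gene-set members;
#'   `gene_class` is `"responsive"` or `"nonresponsive"` (or `"any"`).
#'   Folds must be >= 1; fold 1 means background only.
#' @param library_depths Reads per library: scalar, or named per-library
#'   (names like `"gh2ax_JQ1"`). Default: `background_rate` times the
#'   number of genome bins.
#' @param read_length Read length in bases (default 36).
#' @param bin_size Bin width defining `background_rate` (default 25).
#' @param brd4_tss_fraction Fraction of BRD4 enrichment reads concentrated
#'   in the TSS window rather than the gene body (default 0.5).
#' @param gh2ax_spread Bases by which gH2AX enrichment spreads beyond the
#'   gene body on each side (default 2000), emulating the propagation of
#'   damage signaling around the damaged locus; the implanted fold is then
#'   expressed over the whole region downstream calling scores.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_chroms = 4L, chrom_length = 2e6,
                              n_genes = 500L,
                              set_sizes = c(BRD4 = 120L, BRD4_JMJD6 = 150L,
                                            BRD4_CHD4 = 120L),
                              n_responsive = 39L,
                              background_rate = 0.5,
                              enrichment_fold = .default_fold_table(),
                              library_depths = NULL,
                              read_length = 36L,
                              bin_size = 25L,
                              brd4_tss_fraction = 0.5,
                              gh2ax_spread = 2000L) {
  if (missing(seed)) .stopf("simulation_config: seed is required")
  if (n_chroms < 1 || chrom_length < 1) .stopf("zero-length genome")
  if (n_genes < 1) .stopf("need at least one gene")
  if (!"BRD4" %in% names(set_sizes)) .stopf("set_sizes must include BRD4")
  if (any(set_sizes > n_genes)) .stopf("gene set larger than gene count")
  if (n_responsive > set_sizes[["BRD4"]])
    .stopf("n_responsive exceeds the BRD4 set size")
  if (background_rate <= 0) .stopf("background_rate must be positive")
  if (any(enrichment_fold$fold < 1))
    .stopf("enrichment folds must be >= 1 (1 = background only)")
  n_bins <- n_chroms * ceiling(chrom_length / bin_size)
  if (is.null(library_depths)) library_depths <- round(background_rate * n_bins)
  libs <- .library_names()
  if (length(library_depths) == 1L && is.null(names(library_depths)))
    library_depths <- setNames(rep(as.numeric(library_depths), length(libs)),
                               libs)
  if (!all(libs %in% names(library_depths)))
    .stopf("library_depths must cover all 8 libraries or be a single number")
  if (any(library_depths <= 0)) .stopf("library depths must be positive")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.numeric(chrom_length),
                 n_genes = as.integer(n_genes), set_sizes = set_sizes,
                 n_responsive = as.integer(n_responsive),
                 background_rate = background_rate,
                 enrichment_fold = enrichment_fold,
                 library_depths = library_depths[libs],
                 read_length = as.integer(read_length),
                 bin_size = as.integer(bin_size),
                 brd4_tss_fraction = brd4_tss_fraction,
                 gh2ax_spread = as.numeric(gh2ax_spread)),
            class = "simulation_config")
}

.library_names <- function() {
  as.vector(outer(.SIM_TARGETS, .SIM_CONDITIONS, paste, sep = "_"))
}

# independent per-library RNG stream: a fixed offset per library name, so
# adding a library never perturbs the reads of an existing one
.library_seed <- function(base_seed, lib) {
  offset <- match(lib, .library_names())
  if (is.na(offset)) .stopf("unknown library %s", lib)
  (as.integer(base_seed) + offset * 10007L) %% 2147480000L
}

# ---- annotation generation --------------------------------------------

.simulate_genes <- function(config, chrom_lengths) {
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes <- list()
  gi <- 0L
  for (ci in seq_along(chrom_lengths)) {
    k <- n_per[ci]
    if (k == 0L) next
    len <- chrom_lengths[[ci]]
    glen <- sample(seq(2000L, 6000L, by = 100L), k, replace = TRUE)
    margin <- 5000
    free <- len - 2 * margin - sum(glen)
    if (free < k + 1) .stopf("chromosome too short for requested genes")
    gaps <- as.vector(stats::rmultinom(1, size = free, prob = rep(1, k + 1)))
    starts <- margin + cumsum(gaps[seq_len(k)]) +
      c(0, cumsum(glen[-k]))
    for (j in seq_len(k)) {
      gi <- gi + 1L
      genes[[gi]] <- .simulate_gene_structure(
        sprintf("G%04d", gi), names(chrom_lengths)[ci],
        starts[j], starts[j] + glen[j])
    }
  }
  genes
}

.simulate_gene_structure <- function(gene_id, chrom, tx_start, tx_end) {
  strand <- sample(c("+", "-"), 1)
  L <- tx_end - tx_start
  n_ex <- sample(2:5, 1)
  n_seg <- 2L * n_ex - 1L            # exon, intron, exon, ...
  # terminal exons long enough to hold a UTR that outreaches the fixed
  # TSS/TTS windows, so apportionment exercises every class
  min_seg <- c(500L, rep(100L, n_seg - 2L), 500L)
  extra <- as.vector(stats::rmultinom(1, size = L - sum(min_seg),
                                      prob = rep(1, n_seg)))
  seg <- min_seg + extra
  bounds <- tx_start + c(0, cumsum(seg))
  ex_idx <- seq(1, n_seg, by = 2)
  exons <- data.frame(start = bounds[ex_idx], end = bounds[ex_idx + 1])
  # UTRs: 400 bases at the 5' end, 300 at the 3' end (strand-aware), with
  # CDS boundaries inside the terminal exons
  utr_lo <- if (strand == "+") 400L else 300L
  utr_hi <- if (strand == "+") 300L else 400L
  cds_start <- exons$start[1] + utr_lo
  cds_end <- exons$end[n_ex] - utr_hi
  gene_model(gene_id, chrom, strand, tx_start, tx_end, exons,
             cds_start, cds_end)
}

# ---- read generation ---------------------------------------------------

.uniform_reads <- function(n, chrom_lengths, read_length) {
  if (n <= 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  start <- floor(runif(n, 0, chrom_lengths[chrom] - read_length))
  data.frame(chrom = chrom, start = start, end = start + read_length,
             strand = sample(c("+", "-"), n, replace = TRUE),
             row.names = NULL)
}

.reads_in_interval <- function(n, chrom, lo, hi, read_length, chrom_length) {
  lo <- max(lo, 0); hi <- min(hi, chrom_length)
  start <- floor(runif(n, lo, max(hi - read_length, lo + 1)))
  data.frame(chrom = chrom, start = start, end = start + read_length,
             strand = sample(c("+", "-"), n, replace = TRUE),
             row.names = NULL)
}

.fold_for <- function(fold_table, target, condition, gene_class) {
  hit <- fold_table$target == target & fold_table$condition == condition &
    fold_table$gene_class %in% c(gene_class, "any")
  if (!any(hit)) 1 else fold_table$fold[which(hit)[1]]
}

.simulate_library <- function(config, chrom_lengths, genes, truth,
                              target, condition) {
  lib <- paste(target, condition, sep = "_")
  set.seed(.library_seed(config$seed, lib))
  depth <- config$library_depths[[lib]]
  rl <- config$read_length
  parts <- list()
  if (target != "input") {
    for (g in genes) {
      if (!length(g$sets)) next  # enrichment only at gene-set members
      cls <- truth$class[truth$gene_id == g$gene_id]
      fold <- .fold_for(config$enrichment_fold, target, condition,
                        if (cls == "responsive") "responsive" else "nonresponsive")
      if (fold <= 1) next
      clen <- chrom_lengths[[g$chrom]]
      # gH2AX damage domains spread beyond the gene body; BRD4 and RNAPII
      # enrichment stays within the transcript
      spread <- if (target == "gh2ax") config$gh2ax_spread else 0
      lo <- max(g$tx_start - spread, 0)
      hi <- min(g$tx_end + spread, clen)
      rate <- (fold - 1) * config$background_rate * (hi - lo) / config$bin_size
      n <- rpois(1, rate)
      if (n == 0) next
      if (target == "brd4") {
        n_tss <- rbinom(1, n, config$brd4_tss_fraction)
        tss <- if (g$strand == "+")
          c(g$tx_start - .TSS_UP, g$tx_start + .TSS_DOWN)
        else c(g$tx_end - .TSS_DOWN, g$tx_end + .TSS_UP)
        parts[[length(parts) + 1L]] <-
          .reads_in_interval(n_tss, g$chrom, tss[1], tss[2], rl, clen)
        n <- n - n_tss
      }
      if (n > 0)
        parts[[length(parts) + 1L]] <-
          .reads_in_interval(n, g$chrom, lo, hi, rl, clen)
    }
  }
  n_enrich <- sum(vapply(parts, nrow, 0L))
  if (n_enrich > depth)
    .stopf("library %s: enrichment reads (%d) exceed depth (%g); increase depth",
           lib, n_enrich, depth)
  parts[[length(parts) + 1L]] <-
    .uniform_reads(depth - n_enrich, chrom_lengths, rl)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate a paired DMSO/JQ1 ChIP-Seq experiment
#'
#' Generates a genome, gene models with exon/CDS structure, overlapping
#' gene-set memberships, a ground-truth table, and the eight read libraries
#' ({BRD4, gH2AX, RNAPII ser2, input} x {DMSO, JQ1}). Input libraries are
#' background-only. Each library draws from its own seeded random stream,
#' so the same `config` reproduces identical output and adding a library
#' never changes another. Total reads per library equal the configured
#' depth exactly.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes `genes.bed12`
#'   (annotation), `<set>.txt` gene-set lists, `truth.tsv`, and
#'   `<library>.bed` read files there.
#' @return List with `chrom_lengths`, `genes` (list of [gene_model]),
#'   `gene_sets` (named list of gene-ID vectors), `truth` (data.frame:
#'   `gene_id`, `class`, `expected_gh2ax_fold`, `brd4_direction`,
#'   `rnapii_ser2_direction`), `libraries` (named list of read
#'   data.frames), and the `config`.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  set.seed(config$seed)
  genes <- .simulate_genes(config, chrom_lengths)
  ids <- vapply(genes, `[[`, "", "gene_id")

  # responsive genes are BRD4-set members; other memberships random
  brd4_members <- sample(ids, config$set_sizes[["BRD4"]])
  responsive <- sample(brd4_members, config$n_responsive)
  gene_sets <- list(BRD4 = sort(brd4_members))
  for (sn in setdiff(names(config$set_sizes), "BRD4"))
    gene_sets[[sn]] <- sort(sample(ids, config$set_sizes[[sn]]))
  for (i in seq_along(genes)) {
    member <- names(gene_sets)[vapply(gene_sets, function(s) ids[i] %in% s, TRUE)]
    genes[[i]]$sets <- member
  }

  resp <- ids %in% responsive
  g_fold_t <- vapply(ids, function(id) .fold_for(
    config$enrichment_fold, "gh2ax", "JQ1",
    if (id %in% responsive) "responsive" else "nonresponsive"), 0)
  g_fold_c <- vapply(ids, function(id) .fold_for(
    config$enrichment_fold, "gh2ax", "DMSO",
    if (id %in% responsive) "responsive" else "nonresponsive"), 0)
  in_any_set <- vapply(genes, function(g) length(g$sets) > 0, TRUE)
  truth <- data.frame(
    gene_id = ids,
    class = ifelse(resp, "responsive", "non_responsive"),
    expected_gh2ax_fold = ifelse(in_any_set, g_fold_t / g_fold_c, 1),
    brd4_direction = ifelse(resp, "down", "unchanged"),
    rnapii_ser2_direction = ifelse(resp, "down", "unchanged"))

  libraries <- lapply(setNames(nm = .library_names()), function(lib) {
    parts <- strsplit(lib, "_(?=[^_]+$)", perl = TRUE)[[1]]
    .simulate_library(config, chrom_lengths, genes, truth,
                      parts[1], parts[2])
  })

  result <- list(chrom_lengths = chrom_lengths, genes = genes,
                 gene_sets = gene_sets, truth = truth,
                 libraries = libraries, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_bed12(genes, file.path(out_dir, "genes.bed12"))
    for (sn in names(gene_sets))
      writeLines(gene_sets[[sn]], file.path(out_dir, paste0(sn, ".txt")))
    data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(chrom = names(chrom_lengths),
                             length = as.integer(chrom_lengths)),
      file.path(out_dir, "chrom.sizes"), sep = "\t", col.names = FALSE)
    for (lib in names(libraries))
      write_reads(libraries[[lib]], file.path(out_dir, paste0(lib, ".bed")))
  }
  result
}

#' Write a read library as BED6
#'
#' One record per read: chrom, start, end, name (`read<N>`), score 0,
#' strand. Round-trips exactly through [read_reads_bed()].
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  dt <- data.table::data.table(
    chrom = reads$chrom, start = as.integer(reads$start),
    end = as.integer(reads$end),
    name = if (nrow(reads)) paste0("read", seq_len(nrow(reads)))
           else character(0),
    score = integer(nrow(reads)), strand = reads$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed12 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    sizes <- g$exons$end - g$exons$start
    rel <- g$exons$start - g$tx_start
    data.table::data.table(
      chrom = g$chrom, start = as.integer(g$tx_start),
      end = as.integer(g$tx_end), name = g$gene_id, score = 0L,
      strand = g$strand,
      thickStart = as.integer(if (is.na(g$cds_start)) g$tx_start else g$cds_start),
      thickEnd = as.integer(if (is.na(g$cds_end)) g$tx_start else g$cds_end),
      itemRgb = "0", blockCount = nrow(g$exons),
      blockSizes = paste0(paste(sizes, collapse = ","), ","),
      blockStarts = paste0(paste(rel, collapse = ","), ","))
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Scalar fields map directly to [simulation_config()] arguments;
#' `enrichment_fold` may be given as a list of records with `target`,
#' `condition`, `gene_class`, `fold`.
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$enrichment_fold) && !is.data.frame(raw$enrichment_fold))
    raw$enrichment_fold <- do.call(rbind,
                                   lapply(raw$enrichment_fold, as.data.frame))
  if (!is.null(raw$set_sizes)) raw$set_sizes <- unlist(raw$set_sizes)
  do.call(simulation_config, raw)
}
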