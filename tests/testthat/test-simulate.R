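test_that("the same seed reproduces the experiment byte-identically", {
  cfg <- small_config(seed = 99)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$libraries, b$libraries)
  expect_identical(a$truth, b$truth)
  # and through files
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulate_experiment(cfg, out_dir = d1)
  simulate_experiment(cfg, out_dir = d2)
  f <- "gh2ax_JQ1.bed"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("library depths are conserved exactly", {
  cfg <- small_config(seed = 4)
  exp <- simulate_experiment(cfg)
  for (lib in names(exp$libraries))
    expect_equal(nrow(exp$libraries[[lib]]),
                 unname(cfg$library_depths[[lib]]))
})

test_that("ground truth labels the implanted responsive genes", {
  cfg <- small_config(seed = 12)
  exp <- simulate_experiment(cfg)
  expect_equal(nrow(exp$truth), cfg$n_genes)
  expect_equal(sum(exp$truth$class == "responsive"), cfg$n_responsive)
  expect_true(all(exp$truth$expected_gh2ax_fold >= 0))
  expect_equal(exp$truth$expected_gh2ax_fold[exp$truth$class == "responsive"],
               rep(4, cfg$n_responsive))
  # responsive genes are drawn from the BRD4 set
  resp <- exp$truth$gene_id[exp$truth$class == "responsive"]
  expect_true(all(resp %in% exp$gene_sets$BRD4))
  expect_true(all(exp$truth$brd4_direction[exp$truth$class == "responsive"]
                  == "down"))
})

test_that("input libraries have Poisson per-bin background counts", {
  # chi-square goodness of fit of 5'-start counts per bin against
  # Poisson(background_rate) over 1e5 bins, alpha = 0.001
  cfg <- simulation_config(seed = 2024, n_chroms = 1, chrom_length = 2.5e6,
                           n_genes = 5,
                           set_sizes = c(BRD4 = 2, BRD4_JMJD6 = 2,
                                         BRD4_CHD4 = 2),
                           n_responsive = 1)
  exp <- simulate_experiment(cfg)
  reads <- exp$libraries$input_DMSO
  bins <- reads$start %/% cfg$bin_size
  n_bins <- ceiling(cfg$chrom_length / cfg$bin_size)
  obs <- tabulate(bins + 1L, nbins = n_bins)
  kmax <- max(obs)
  observed <- tabulate(obs + 1L, nbins = kmax + 1L)  # counts of bins with k reads
  expected <- dpois(0:kmax, cfg$background_rate) * n_bins
  # pool the sparse right tail so expected cell counts stay >= 5
  cut <- max(which(expected >= 5))
  obs_p <- c(observed[1:cut], sum(observed[-(1:cut)]))
  exp_p <- c(expected[1:cut], n_bins - sum(expected[1:cut]))
  chi2 <- sum((obs_p - exp_p)^2 / exp_p)
  pval <- pchisq(chi2, df = length(obs_p) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("a null configuration implants no enrichment anywhere", {
  folds <- expand.grid(target = c("brd4", "gh2ax", "rnapii_ser2", "input"),
                       condition = c("DMSO", "JQ1"),
                       gene_class = c("responsive", "nonresponsive", "any"),
                       stringsAsFactors = FALSE)
  folds$fold <- 1
  cfg <- small_config(seed = 31, enrichment_fold = folds)
  exp <- simulate_experiment(cfg)
  # treatment density over responsive gene bodies matches the genome-wide
  # background within Poisson noise
  resp <- exp$truth$gene_id[exp$truth$class == "responsive"]
  gsub <- exp$genes[vapply(exp$genes, function(g) g$gene_id %in% resp, TRUE)]
  reads <- exp$libraries$gh2ax_JQ1
  body_bases <- sum(vapply(gsub, function(g) g$tx_end - g$tx_start, 0))
  genome <- sum(exp$chrom_lengths)
  in_body <- sum(vapply(gsub, function(g)
    sum(reads$chrom == g$chrom & reads$start >= g$tx_start &
          reads$start < g$tx_end), 0))
  expected <- nrow(reads) * body_bases / genome
  expect_lt(abs(in_body - expected), 4 * sqrt(expected))
})

test_that("configs validate their invariants", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, n_genes = 0), "gene")
  expect_error(small_config(seed = 1, n_responsive = 50), "BRD4 set")
  expect_error(small_config(seed = 1, background_rate = 0), "positive")
  folds <- data.frame(target = "gh2ax", condition = "JQ1",
                      gene_class = "responsive", fold = 0.5)
  expect_error(small_config(seed = 1, enrichment_fold = folds), ">= 1")
})

test_that("simulation outputs round-trip through the annotation loader", {
  cfg <- small_config(seed = 8)
  dir <- file.path(tempdir(), "simrt")
  exp <- simulate_experiment(cfg, out_dir = dir)
  genes <- load_genes(file.path(dir, "genes.bed12"),
                      set_lists = list(BRD4 = file.path(dir, "BRD4.txt")))
  expect_length(genes, cfg$n_genes)
  ids <- vapply(genes, `[[`, "", "gene_id")
  orig <- exp$genes[[5]]
  back <- genes[[which(ids == orig$gene_id)]]
  expect_equal(back$tx_start, orig$tx_start)
  expect_equal(back$tx_end, orig$tx_end)
  expect_equal(back$exons, orig$exons)
  expect_equal(back$cds_start, orig$cds_start)
  expect_equal(back$strand, orig$strand)
  # read libraries round-trip
  lib <- read_reads_bed(file.path(dir, "input_DMSO.bed"))
  expect_equal(nrow(lib), unname(cfg$library_depths[["input_DMSO"]]))
  expect_equal(lib$start, exp$libraries$input_DMSO$start)
})

test_that("configs load from JSON", {
  cfgfile <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(seed = 5, n_chroms = 2, chrom_length = 4e5,
                            n_genes = 40,
                            set_sizes = list(BRD4 = 12, BRD4_JMJD6 = 10,
                                             BRD4_CHD4 = 8),
                            n_responsive = 5),
                       cfgfile, auto_unbox = TRUE)
  cfg <- read_simulation_config(cfgfile)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$seed, 5L)
  expect_equal(cfg$n_genes, 40L)
})
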