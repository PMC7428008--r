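test_that("BED12 loading yields one model per gene with set membership", {
  bed <- file.path(tempdir(), "one.bed")
  writeLines(paste("chrT", 1000, 5000, "TOYP", 0, "+", 1400, 4600, "0",
                   3, "800,500,800,", "0,1500,3200,", sep = "\t"), bed)
  genes <- load_genes(bed)
  expect_length(genes, 1)
  g <- genes[[1]]
  expect_equal(g$gene_id, "TOYP")
  expect_equal(g$tx_start, 1000)
  expect_equal(g$tx_end, 5000)
  expect_equal(g$exons,
               data.frame(start = c(1000, 2500, 4200),
                          end = c(1800, 3000, 5000)))
  expect_equal(g$cds_start, 1400)
  expect_equal(g$cds_end, 4600)
  expect_identical(g$sets, character(0))

  # same gene in two set lists -> union of memberships
  s1 <- file.path(tempdir(), "s1.txt"); writeLines(c("# jmjd6", "TOYP"), s1)
  s2 <- file.path(tempdir(), "s2.txt"); writeLines("TOYP", s2)
  genes <- load_genes(bed, list(BRD4_JMJD6 = s1, BRD4_CHD4 = s2))
  expect_setequal(genes[[1]]$sets, c("BRD4_JMJD6", "BRD4_CHD4"))

  # unknown IDs reported, not fatal
  s3 <- file.path(tempdir(), "s3.txt"); writeLines(c("TOYP", "NOPE"), s3)
  expect_warning(genes <- load_genes(bed, list(BRD4 = s3)), "NOPE")
  expect_setequal(genes[[1]]$sets, "BRD4")
})

test_that("two transcripts of one gene collapse to the union model", {
  gtf <- write_toy_gtf(file.path(tempdir(), "toy.gtf"))
  genes <- load_genes(gtf)
  expect_length(genes, 1)
  g <- genes[[1]]
  # frozen hand-computed union of the two-transcript fixture
  expect_equal(g$tx_start, 100)
  expect_equal(g$tx_end, 800)
  expect_equal(g$exons, data.frame(start = c(100, 500), end = c(420, 800)))
  expect_equal(g$cds_start, 150)
  expect_equal(g$cds_end, 650)
})

test_that("malformed and empty annotation files raise descriptive errors", {
  bad <- file.path(tempdir(), "bad.bed")
  writeLines(c(paste("chrT", 0, 100, "A", 0, "+", 0, 100, "0", 1, "100,", "0,",
                     sep = "\t"),
               "chrT\t5\t50"), bad)
  expect_error(load_genes(bad), "line 2")
  empty <- file.path(tempdir(), "empty.bed")
  writeLines(character(0), empty)
  expect_error(load_genes(empty), "empty")
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("B", "c", "+", 500, 100), "tx_start")
  expect_error(gene_model("B", "c", "+", 0, 1000,
                          exons = data.frame(start = c(0, 300),
                                             end = c(400, 900))),
               "overlapping")
  expect_error(gene_model("B", "c", "+", 0, 1000,
                          exons = data.frame(start = 0, end = 500),
                          cds_start = 100, cds_end = 700),
               "exons")
})

test_that("feature windows follow the strand-aware 50/300 and 50/200 rules", {
  wp <- derive_feature_windows(toy_gene_plus(), 1e6)
  expect_equal(wp$tss_region, data.frame(start = 950, end = 1300))
  expect_equal(wp$tts_region, data.frame(start = 4950, end = 5200))
  wm <- derive_feature_windows(toy_gene_minus(), 1e6)
  expect_equal(wm$tss_region, data.frame(start = 4700, end = 5050))
  # minus-strand 3' end at tx_start: 200 downstream (smaller coordinates),
  # 50 upstream -> [800, 1050), keeping the 250-base TTS span
  expect_equal(wm$tts_region, data.frame(start = 800, end = 1050))
  # spans: 350 and 250 bases
  expect_equal(sum(wp$tss_region$end - wp$tss_region$start), 350)
  expect_equal(sum(wp$tts_region$end - wp$tts_region$start), 250)

  # clipping at the chromosome start
  near0 <- gene_model("N", "chrT", "+", 20, 2000)
  wn <- derive_feature_windows(near0, 1e6)
  expect_equal(wn$tss_region, data.frame(start = 0, end = 320))
})

test_that("UTRs are the exonic sequence outside the CDS, strand-aware", {
  wp <- derive_feature_windows(toy_gene_plus(), 1e6)
  expect_equal(wp$utr5, data.frame(start = 1000, end = 1400))
  expect_equal(wp$utr3, data.frame(start = 4600, end = 5000))
  wm <- derive_feature_windows(toy_gene_minus(), 1e6)
  expect_equal(wm$utr5, data.frame(start = 4600, end = 5000))
  expect_equal(wm$utr3, data.frame(start = 1000, end = 1400))
  # non-coding gene: empty UTRs, not an error
  nc <- gene_model("NC", "chrT", "+", 100, 900)
  wn <- derive_feature_windows(nc, 1e6)
  expect_equal(nrow(wn$utr5), 0)
  expect_equal(nrow(wn$utr3), 0)
})

test_that("exonic + UTRs + intronic partition the transcript span exactly", {
  set.seed(11)
  for (i in 1:25) {
    g <- random_gene(sprintf("R%02d", i), "chrT", 1e5)
    w <- derive_feature_windows(g, 1e5)
    pieces <- rbind(w$utr5, w$utr3, w$exonic, w$intronic)
    pieces <- pieces[order(pieces$start), ]
    # non-overlapping and exactly covering [tx_start, tx_end)
    expect_equal(sum(pieces$end - pieces$start), g$tx_end - g$tx_start)
    expect_equal(min(pieces$start), g$tx_start)
    expect_equal(max(pieces$end), g$tx_end)
    expect_true(all(pieces$start[-1] >= pieces$end[-nrow(pieces)]))
  }
})

test_that("strand reversal with coordinate reflection mirrors TSS windows", {
  L <- 1e5
  set.seed(3)
  for (i in 1:10) {
    g <- random_gene(sprintf("M%02d", i), "chrT", L)
    reflected <- gene_model(
      g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
      L - g$tx_end, L - g$tx_start,
      exons = data.frame(start = rev(L - g$exons$end),
                         end = rev(L - g$exons$start)),
      cds_start = L - g$cds_end, cds_end = L - g$cds_start)
    w <- derive_feature_windows(g, L)
    wr <- derive_feature_windows(reflected, L)
    expect_equal(wr$tss_region,
                 data.frame(start = L - w$tss_region$end,
                            end = L - w$tss_region$start))
    expect_equal(wr$tts_region,
                 data.frame(start = L - w$tts_region$end,
                            end = L - w$tts_region$start))
  }
})

test_that("feature windows export as BED6 with the class in the name", {
  g <- toy_gene_plus()
  w <- derive_feature_windows(g, 1e6)
  path <- file.path(tempdir(), "win.bed")
  write_feature_windows(w, g, path)
  dt <- read.delim(path, header = FALSE)
  expect_equal(ncol(dt), 6)
  expect_true(any(grepl("^tss_region", dt$V4)))
  expect_true(all(dt$V6 == "+"))
})
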