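test_that("Poisson upper tail matches closed forms and the summation oracle", {
  expect_equal(poisson_upper_tail(0, 0.5), 1.0)
  expect_equal(poisson_upper_tail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_upper_tail(30, 5), oracle_poisson_upper(30, 5),
               tolerance = 1e-12)
  expect_error(poisson_upper_tail(3, 0), "lambda")
  expect_error(poisson_upper_tail(-1, 2), "non-negative")
  expect_error(poisson_upper_tail(2.5, 2), "integers")
})

test_that("global background is the depth-scaled mean input rate", {
  # uniform 4 events per bin, equal depths -> lambda 4
  trk <- binned_track(list(c1 = rep(4, 100)), c(c1 = 2500), depth = 400)
  bg <- estimate_background(trk, target_depth = 400)
  expect_equal(bg$lambda, 4.0)
  # doubling the target depth doubles lambda
  bg2 <- estimate_background(trk, target_depth = 800)
  expect_equal(bg2$lambda, 8.0)
  # floor
  lo <- binned_track(list(c1 = c(1, rep(0, 99))), c(c1 = 2500), depth = 1)
  expect_equal(estimate_background(lo, 1)$lambda, 0.1)
  empty <- binned_track(list(c1 = rep(0, 100)), c(c1 = 2500), depth = 0)
  expect_error(estimate_background(empty, 10), "empty")
  norm <- normalize_depth(trk)
  expect_error(estimate_background(norm, 400), "un-normalized")
})

test_that("local background equals the windowed-mean oracle", {
  set.seed(41)
  x <- rpois(500, 3) + rep(c(0, 8), each = 250)   # structured input
  trk <- binned_track(list(c1 = x), c(c1 = 12500), depth = sum(x))
  bg <- estimate_background(trk, target_depth = 2 * sum(x), mode = "local",
                            window_bins = 51, lambda_min = 0.01)
  expect_equal(bg$lambda$c1, pmax(oracle_windowed_mean(x, 51) * 2, 0.01))
  expect_error(estimate_background(trk, 1, mode = "local", window_bins = 50),
               "odd")
})

test_that("significance boundary sits at the minimal count with p <= alpha", {
  # locate k* for lambda = 1 with the summation oracle
  kstar <- 1
  while (oracle_poisson_upper(kstar, 1) > 1e-9) kstar <- kstar + 1
  x <- numeric(100); x[1] <- kstar - 1; x[2] <- kstar
  trk <- binned_track(list(c1 = x), c(c1 = 2500), depth = sum(x))
  input <- binned_track(list(c1 = rep(1, 100)), c(c1 = 2500), depth = sum(x))
  bg <- estimate_background(input, target_depth = sum(x))
  expect_equal(bg$lambda, 1.0)
  sig <- significant_bins(trk, bg, alpha = 1e-9)
  expect_equal(nrow(sig), 2)  # zero-count bins omitted
  expect_equal(sig$significant, c(FALSE, TRUE))
  expect_equal(sig$bin_index, c(0L, 1L))

  # all-zero track: nothing to report
  zero <- binned_track(list(c1 = numeric(100)), c(c1 = 2500), depth = 0)
  expect_equal(nrow(significant_bins(zero, bg)), 0)
  # the Poisson model needs raw counts
  expect_error(significant_bins(normalize_depth(trk), bg), "raw")
})

test_that("significance is monotone in count and anti-monotone in lambda", {
  set.seed(17)
  counts <- sample(0:40, 200, replace = TRUE)
  for (lam in c(0.5, 2, 8)) {
    p <- poisson_upper_tail(counts, lam)
    p_up <- poisson_upper_tail(counts + 1, lam)
    expect_true(all(p_up <= p))
    p_lam_up <- poisson_upper_tail(counts, lam * 1.5)
    expect_true(all(p_lam_up >= p))
  }
})

test_that("gene signal sums normalized bins over regions additively", {
  x <- numeric(400); x[11] <- 4; x[12] <- 6; x[100] <- 10
  trk <- binned_track(list(chrT = x), c(chrT = 10000), depth = 20,
                      normalized = TRUE)
  # region covering no nonzero bins
  expect_equal(gene_signal(trk, "chrT", 5000, 6000), 0)
  # hand-summed: bins 10 and 11 cover [250, 300)
  expect_equal(gene_signal(trk, "chrT", 250, 300), 10)
  # a single base overlapping bin 10
  expect_equal(gene_signal(trk, "chrT", 274, 275), 4)
  # additivity over disjoint regions
  expect_equal(gene_signal(trk, "chrT", c(250, 2475), c(300, 2500)), 20)
  expect_error(gene_signal(trk, "nope", 0, 10), "chromosome")
  raw <- binned_track(list(chrT = x), c(chrT = 10000), depth = 20)
  expect_error(gene_signal(raw, "chrT", 0, 10), "normalized")
})

test_that("fold enrichment is a pseudocount-stabilized ratio", {
  expect_equal(fold_enrichment(5, 5, 1), 1.0)
  expect_equal(fold_enrichment(10, 0, 1), 11.0)
  expect_error(fold_enrichment(1, 1, 0), "pseudocount")
  # monotone in the treatment signal
  f <- fold_enrichment(seq(0, 20, by = 0.5), 3, 0.25)
  expect_true(all(diff(f) > 0))
})

test_that("gene calling is null on identical tracks and strict at 2-fold", {
  genes <- list(gene_model("G1", "chrT", "+", 2000, 4000))
  x <- numeric(400); x[81:160] <- 5
  trk <- binned_track(list(chrT = x), c(chrT = 10000), depth = 400,
                      normalized = TRUE)
  res <- call_enriched_genes(genes, trk, trk, require_significant = FALSE,
                             pseudocount = 1e-9)
  expect_false(any(res$genes$called))
  expect_equal(unname(res$set_counts["all"]), 0L)

  # treatment exactly 2x control: not called under the strict > threshold
  x2 <- x * 2
  trk2 <- binned_track(list(chrT = x2), c(chrT = 10000), depth = 400,
                       normalized = TRUE)
  res2 <- call_enriched_genes(genes, trk2, trk, require_significant = FALSE,
                              pseudocount = 1e-12)
  expect_equal(res2$genes$fold_change, 2.0, tolerance = 1e-9)
  expect_false(res2$genes$called)

  # mismatched grids error
  trk3 <- binned_track(list(chrT = numeric(200)), c(chrT = 10000),
                       bin_size = 50, depth = 1, normalized = TRUE)
  expect_error(call_enriched_genes(genes, trk3, trk,
                                   require_significant = FALSE,
                                   pseudocount = 1), "grid")
})

test_that("set summaries count called genes per membership", {
  genes <- list(
    gene_model("A", "chrT", "+", 1000, 2000, sets = "BRD4"),
    gene_model("B", "chrT", "+", 4000, 5000, sets = c("BRD4", "BRD4_CHD4")),
    gene_model("C", "chrT", "+", 7000, 8000))
  x <- numeric(400)
  x[screen_bins <- 41:80] <- 1      # gene A region modest
  x2 <- x; x2[screen_bins] <- 10    # treatment strongly up at A only
  ctrl <- binned_track(list(chrT = x), c(chrT = 10000), depth = 100,
                       normalized = TRUE)
  trt <- binned_track(list(chrT = x2), c(chrT = 10000), depth = 100,
                      normalized = TRUE)
  res <- call_enriched_genes(genes, trt, ctrl, require_significant = FALSE,
                             pseudocount = 0.5, flank = 0)
  expect_true(res$genes$called[res$genes$gene_id == "A"])
  expect_equal(unname(res$set_counts["BRD4"]), 1L)
  expect_equal(unname(res$set_counts["BRD4_CHD4"]), 0L)
  expect_equal(unname(res$set_counts["all"]), 1L)
})
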