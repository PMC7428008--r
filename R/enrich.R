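#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, the significance measure for
#' binned ChIP-Seq counts against the background model. Computed through
#' the regularized incomplete gamma function (via [stats::ppois()]), which
#' keeps relative accuracy well below `1e-12` for tail probabilities down
#' to `1e-15` and beyond.
#'
#' @param k Observed count(s); non-negative integers.
#' @param lambda Expected background count(s); positive.
#' @return Upper-tail probabilities in `[0, 1]`; `k = 0` gives exactly 1.
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) .stopf("lambda must be positive")
  if (any(k < 0) || any(k != floor(k))) .stopf("k must be non-negative integers")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Estimate the per-bin Poisson background rate from an input library
#'
#' The whole-cell-extract (input) library defines the background. In
#' `"global"` mode (default) a single rate is used everywhere:
#' `lambda = mean bin-overlap events in the input  x  target_depth / input
#' depth`, floored at `lambda_min`. In `"local"` mode the same depth
#' scaling is applied to a sliding mean of the input track over
#' `window_bins` bins (edge bins average over the part of the window that
#' exists).
#'
#' @param input_track Un-normalized [binned_track] of the input library.
#' @param target_depth Depth of the library the model will be applied to.
#' @param mode `"global"` or `"local"`.
#' @param window_bins Odd window width in bins for local mode (default 201,
#'   i.e. ~5 kb at 25-bp bins).
#' @param lambda_min Floor applied to the rate (default 0.1), preventing
#'   degenerate zero-background bins.
#' @return Object of class `background_model` with the per-bin rate(s).
#' @export
estimate_background <- function(input_track, target_depth,
                                mode = c("global", "local"),
                                window_bins = 201L, lambda_min = 0.1) {
  stopifnot(inherits(input_track, "binned_track"))
  mode <- match.arg(mode)
  if (input_track$normalized)
    .stopf("background estimation needs the raw (un-normalized) input track")
  if (target_depth <= 0) .stopf("target_depth must be positive")
  total <- sum(vapply(input_track$counts, sum, 0))
  nb <- sum(lengths(input_track$counts))
  if (nb == 0L || total == 0) .stopf("input track is empty")
  scale <- target_depth / input_track$depth
  if (mode == "global") {
    lam <- max(total / nb * scale, lambda_min)
  } else {
    if (window_bins < 1L || window_bins %% 2L == 0L)
      .stopf("window_bins must be a positive odd integer")
    lam <- lapply(input_track$counts, function(x) {
      # sliding mean; partial windows at chromosome edges average over the
      # bins that exist
      half <- (window_bins - 1L) %/% 2L
      idx <- seq_along(x)
      lo <- pmax(idx - half, 1L); hi <- pmin(idx + half, length(x))
      cs <- cumsum(c(0, x))
      m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      pmax(m * scale, lambda_min)
    })
  }
  structure(list(mode = mode, lambda = lam, lambda_min = lambda_min,
                 window_bins = if (mode == "local") window_bins else NA_integer_,
                 input_depth = input_track$depth,
                 target_depth = target_depth,
                 bin_size = input_track$bin_size),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  if (x$mode == "global")
    cat(sprintf("<background_model> global lambda = %.4g per bin\n", x$lambda))
  else
    cat(sprintf("<background_model> local, window %d bins, floor %.3g\n",
                x$window_bins, x$lambda_min))
  invisible(x)
}

# rate vector for one chromosome
.lambda_for <- function(background, chrom, n_bins) {
  if (background$mode == "global") rep(background$lambda, n_bins)
  else {
    lam <- background$lambda[[chrom]]
    if (is.null(lam) || length(lam) != n_bins)
      .stopf("background model has no local rates for chromosome %s", chrom)
    lam
  }
}

#' Identify significantly enriched bins under the Poisson background
#'
#' Every bin with a positive raw count is tested with
#' [poisson_upper_tail()] against the background rate; a bin is significant
#' when `p <= alpha` (default `1e-9`). Zero-count bins are never
#' significant (`P(X >= 0) = 1`) and are omitted from the result.
#'
#' @param track Un-normalized [binned_track] (the Poisson model applies to
#'   raw counts; a normalized track is an error).
#' @param background A [estimate_background()] model.
#' @param alpha Significance threshold on the upper-tail p-value.
#' @return data.frame with `chrom`, `bin_index` (0-based), `start`, `end`,
#'   `count`, `lambda`, `p_value`, `significant`.
#' @export
significant_bins <- function(track, background, alpha = 1e-9) {
  stopifnot(inherits(track, "binned_track"),
            inherits(background, "background_model"))
  if (track$normalized)
    .stopf("significance needs raw counts; supply the un-normalized track")
  res <- lapply(names(track$counts), function(ch) {
    x <- track$counts[[ch]]
    idx <- which(x > 0)
    if (!length(idx)) return(NULL)
    lam <- .lambda_for(background, ch, length(x))[idx]
    p <- poisson_upper_tail(x[idx], lam)
    data.frame(chrom = ch, bin_index = idx - 1L,
               start = (idx - 1L) * track$bin_size,
               end = pmin(idx * track$bin_size, track$chrom_lengths[[ch]]),
               count = x[idx], lambda = lam, p_value = p,
               significant = p <= alpha)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), bin_index = integer(0),
                      start = numeric(0), end = numeric(0),
                      count = numeric(0), lambda = numeric(0),
                      p_value = numeric(0), significant = logical(0))
  rownames(out) <- NULL
  out
}

#' Summed normalized signal over a genomic region
#'
#' Sums the depth-normalized counts of every bin overlapping each supplied
#' interval (by at least one base); with several intervals the per-interval
#' sums are added, so signal is additive over disjoint regions.
#'
#' @param track Normalized [binned_track].
#' @param chrom Chromosome of the region.
#' @param start,end Interval(s), 0-based half-open; vectors for multiple
#'   regions.
#' @return Total signal (a single number).
#' @export
gene_signal <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "binned_track"))
  if (!track$normalized) .stopf("gene_signal expects a depth-normalized track")
  if (!chrom %in% names(track$counts)) .stopf("unknown chromosome %s", chrom)
  x <- track$counts[[chrom]]
  len <- track$chrom_lengths[[chrom]]
  s <- pmax(start, 0); e <- pmin(end, len)
  tot <- 0
  for (i in seq_along(s)) {
    if (s[i] >= e[i]) next
    b <- .bin_span(s[i], e[i], track$bin_size)
    tot <- tot + sum(x[(b[, "first"]:b[, "last"]) + 1L])
  }
  tot
}

#' Fold enrichment between two signals
#'
#' `(signal_treatment + pseudocount) / (signal_control + pseudocount)`.
#' The pseudocount stabilizes ratios at low coverage.
#'
#' @param signal_treatment,signal_control Non-negative signals.
#' @param pseudocount Positive stabilizer added to both.
#' @return Fold change (vectorized).
#' @export
fold_enrichment <- function(signal_treatment, signal_control, pseudocount) {
  if (any(pseudocount <= 0)) .stopf("pseudocount must be positive")
  if (any(signal_treatment < 0) || any(signal_control < 0))
    .stopf("signals must be non-negative")
  (signal_treatment + pseudocount) / (signal_control + pseudocount)
}

#' Call per-gene fold enrichment between conditions
#'
#' For every gene, signal is the summed normalized track over the gene span
#' expanded by `flank` bases each side; the fold change is
#' [fold_enrichment()] of treatment over control. A gene is *called* when
#' its fold exceeds `fold_threshold` (strictly) and — when
#' `require_significant = TRUE` — at least one Poisson-significant bin
#' (computed from the raw-count treatment track against `background`) lies
#' inside its scored region. Called genes are then summarized per gene set.
#'
#' @param genes List of [gene_model] objects.
#' @param treatment_track,control_track Depth-normalized [binned_track]s on
#'   the same bin grid.
#' @param fold_threshold Call genes with fold strictly greater than this
#'   (default 2).
#' @param flank Bases added to each side of the gene span when scoring
#'   (default 2000).
#' @param pseudocount Stabilizer for the ratio; default is the normalized
#'   equivalent of one raw read in the smaller of the two libraries
#'   (`scale_per / min(depth_treatment, depth_control)`).
#' @param require_significant Additionally require a significant treatment
#'   bin in the region (default `TRUE`).
#' @param treatment_raw Un-normalized treatment track (needed when
#'   `require_significant = TRUE`).
#' @param background [estimate_background()] model for the significance
#'   test.
#' @param alpha Bin-level significance threshold (default `1e-9`).
#' @return Object of class `gene_enrichment`: list with `genes` (a
#'   data.frame of per-gene results: signals, fold, significant-bin count,
#'   call, set membership) and `set_counts` (named vector of called-gene
#'   counts per gene set, plus `all`).
#' @export
call_enriched_genes <- function(genes, treatment_track, control_track,
                                fold_threshold = 2.0, flank = 2000L,
                                pseudocount = NULL,
                                require_significant = TRUE,
                                treatment_raw = NULL, background = NULL,
                                alpha = 1e-9) {
  stopifnot(inherits(treatment_track, "binned_track"),
            inherits(control_track, "binned_track"))
  if (!treatment_track$normalized || !control_track$normalized)
    .stopf("both tracks must be depth-normalized")
  if (treatment_track$bin_size != control_track$bin_size ||
      !identical(lengths(treatment_track$counts),
                 lengths(control_track$counts)))
    .stopf("treatment and control tracks are on different bin grids")
  if (is.null(pseudocount)) {
    d <- c(treatment_track$depth, control_track$depth)
    if (anyNA(d)) .stopf("supply pseudocount explicitly for tracks without depth")
    pseudocount <- treatment_track$scale_per / min(d)
  }
  sig <- NULL
  if (require_significant) {
    if (is.null(treatment_raw) || is.null(background))
      .stopf("require_significant needs treatment_raw and background")
    sb <- significant_bins(treatment_raw, background, alpha)
    sb <- sb[sb$significant, c("chrom", "bin_index")]
    sig <- lapply(split(sb$bin_index, sb$chrom), sort)
  }
  bs <- treatment_track$bin_size
  res <- lapply(genes, function(g) {
    s <- max(g$tx_start - flank, 0)
    e <- min(g$tx_end + flank, treatment_track$chrom_lengths[[g$chrom]])
    st <- gene_signal(treatment_track, g$chrom, s, e)
    sc <- gene_signal(control_track, g$chrom, s, e)
    fold <- fold_enrichment(st, sc, pseudocount)
    nsig <- 0L
    if (require_significant) {
      bins <- sig[[g$chrom]]
      if (!is.null(bins)) {
        b <- .bin_span(s, e, bs)
        nsig <- sum(bins >= b[, "first"] & bins <= b[, "last"])
      }
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               signal_control = sc, signal_treatment = st,
               fold_change = fold, n_significant_bins = nsig,
               called = fold > fold_threshold &&
                 (!require_significant || nsig > 0L),
               sets = paste(g$sets, collapse = ","))
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  set_names <- sort(unique(unlist(lapply(genes, `[[`, "sets"))))
  set_counts <- vapply(set_names, function(sn) {
    in_set <- vapply(genes, function(g) sn %in% g$sets, TRUE)
    sum(tab$called & in_set)
  }, 0L)
  set_counts <- c(set_counts, all = sum(tab$called))
  structure(list(genes = tab, set_counts = set_counts,
                 fold_threshold = fold_threshold, flank = flank,
                 pseudocount = pseudocount, alpha = alpha,
                 require_significant = require_significant),
            class = "gene_enrichment")
}

#' @export
print.gene_enrichment <- function(x, ...) {
  cat(sprintf("<gene_enrichment> %d gene(s), %d called at fold > %g\n",
              nrow(x$genes), sum(x$genes$called), x$fold_threshold))
  if (length(x$set_counts)) {
    cat("  called per set: ",
        paste(sprintf("%s=%d", names(x$set_counts), x$set_counts),
              collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Write per-gene enrichment results as TSV
#'
#' @param enrichment A [call_enriched_genes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  stopifnot(inherits(enrichment, "gene_enrichment"))
  data.table::fwrite(enrichment$genes, path, sep = "\t")
  invisible(path)
}
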