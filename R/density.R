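#' Read an aligned-read library from BED6
#'
#' Each record is one mapped read as a stranded interval (BED is natively
#' 0-based half-open, matching the internal convention).
#'
#' @param path BED file with at least 6 columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_reads_bed <- function(path) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0))
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 6L)
    .stopf("%s: expected BED6 (got %d columns)", path, ncol(dt))
  out <- data.frame(chrom = as.character(dt[[1]]), start = as.numeric(dt[[2]]),
                    end = as.numeric(dt[[3]]), strand = as.character(dt[[6]]))
  if (any(out$start >= out$end)) .stopf("%s: read with start >= end", path)
  if (any(!out$strand %in% c("+", "-")))
    .stopf("%s: read strand must be '+' or '-'", path)
  out
}

#' Extend reads to a fixed fragment length
#'
#' Each read is extended to `extension` bases in its 3' direction from its
#' 5' start: plus-strand reads become `[start, start + extension)`,
#' minus-strand reads `[end - extension, end)`. Intervals are clipped to
#' `[0, chrom_length)`.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param extension Target fragment length in bases (default 200).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return data.frame of extended intervals (`chrom`, `start`, `end`).
#' @export
extend_reads <- function(reads, extension = 200L, chrom_lengths) {
  if (extension <= 0) .stopf("extension must be positive")
  .check_chrom_lengths(chrom_lengths)
  unknown <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(unknown))
    .stopf("reads on unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  plus <- reads$strand == "+"
  s <- ifelse(plus, reads$start, reads$end - extension)
  e <- ifelse(plus, reads$start + extension, reads$end)
  len <- chrom_lengths[reads$chrom]
  data.frame(chrom = reads$chrom, start = pmax(s, 0), end = pmin(e, len),
             row.names = NULL)
}

#' Construct a binned track from per-chromosome count vectors
#'
#' Low-level constructor; most users will call [bin_counts()]. Bin `b` of a
#' chromosome covers bases `[b*bin_size, (b+1)*bin_size)`; vectors have
#' `ceiling(chrom_length / bin_size)` entries.
#'
#' @param counts Named list of numeric vectors, one per chromosome.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width in bases.
#' @param extension Read extension the counts were computed with.
#' @param depth Total reads counted.
#' @param normalized Whether counts are depth-normalized.
#' @param scale_per Reads-per-`scale_per` scale used when normalized.
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(counts, chrom_lengths, bin_size = 25L,
                         extension = 200L, depth, normalized = FALSE,
                         scale_per = 1e6) {
  .check_chrom_lengths(chrom_lengths)
  if (!setequal(names(counts), names(chrom_lengths)))
    .stopf("counts and chrom_lengths name the same chromosomes")
  counts <- counts[names(chrom_lengths)]
  for (ch in names(counts)) {
    nb <- as.integer(ceiling(chrom_lengths[[ch]] / bin_size))
    if (length(counts[[ch]]) != nb)
      .stopf("chromosome %s: expected %d bins, got %d", ch, nb,
             length(counts[[ch]]))
    if (any(counts[[ch]] < 0)) .stopf("negative bin count on %s", ch)
  }
  if (!normalized) {
    ok <- vapply(counts, function(x) all(x == floor(x)), TRUE)
    if (!all(ok)) .stopf("un-normalized track must have integer counts")
  }
  structure(list(counts = counts, chrom_lengths = chrom_lengths,
                 bin_size = as.integer(bin_size),
                 extension = as.integer(extension),
                 depth = as.numeric(depth), normalized = isTRUE(normalized),
                 scale_per = as.numeric(scale_per)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf(
    "<binned_track> %d chromosome(s), %d bins of %d bp, extension %d bp\n",
    length(x$counts), sum(lengths(x$counts)), x$bin_size, x$extension))
  cat(sprintf("  depth %g read(s); %s\n", x$depth,
              if (x$normalized)
                sprintf("normalized to %g reads", x$scale_per)
              else "raw counts"))
  invisible(x)
}

#' Tally extended reads over fixed-width genome bins
#'
#' Every read is extended with [extend_reads()]; each bin overlapped by at
#' least one base of the extended interval receives one count for that read
#' (presence/absence, not base-fraction weighting). Bins tile each
#' chromosome from coordinate 0; the final partial bin is kept. The track's
#' `depth` is the number of reads supplied.
#'
#' @inheritParams extend_reads
#' @param bin_size Bin width in bases (default 25).
#' @return A raw-count [binned_track].
#' @export
bin_counts <- function(reads, chrom_lengths, bin_size = 25L,
                       extension = 200L) {
  .check_chrom_lengths(chrom_lengths)
  ext <- extend_reads(reads, extension, chrom_lengths)
  counts <- lapply(names(chrom_lengths), function(ch) {
    nb <- as.integer(ceiling(chrom_lengths[[ch]] / bin_size))
    x <- numeric(nb)
    sel <- ext$chrom == ch & ext$start < ext$end
    if (any(sel)) {
      b <- .bin_span(ext$start[sel], ext$end[sel], bin_size)
      # difference-array accumulation: +1 at first bin, -1 after last
      d <- numeric(nb + 1L)
      t1 <- tabulate(b[, "first"] + 1L, nbins = nb + 1L)
      t2 <- tabulate(pmin(b[, "last"] + 2L, nb + 1L), nbins = nb + 1L)
      x <- cumsum(t1 - t2)[seq_len(nb)]
    }
    x
  })
  names(counts) <- names(chrom_lengths)
  binned_track(counts, chrom_lengths, bin_size = bin_size,
               extension = extension, depth = nrow(reads),
               normalized = FALSE)
}

#' Normalize a binned track by sequencing depth
#'
#' Multiplies every bin by `scale_per / depth` (reads-per-million by
#' default), so tracks from libraries of different depth are comparable.
#' Normalizing twice is an error.
#'
#' @param track A raw-count [binned_track].
#' @param scale_per Scale reads to this library size (default `1e6`).
#' @return The normalized track.
#' @export
normalize_depth <- function(track, scale_per = 1e6) {
  stopifnot(inherits(track, "binned_track"))
  if (track$normalized) .stopf("track is already depth-normalized")
  if (track$depth <= 0) .stopf("cannot normalize a track of depth 0")
  f <- scale_per / track$depth
  track$counts <- lapply(track$counts, function(x) x * f)
  track$normalized <- TRUE
  track$scale_per <- scale_per
  track
}

#' Write a binned track as bedGraph or fixed-step wiggle
#'
#' bedGraph output merges runs of equal-valued adjacent bins and can omit
#' zero bins; wiggle output is fixedStep with `step = span = bin_size` and
#' writes every bin.
#'
#' @param track A [binned_track].
#' @param path Output path.
#' @param format `"bedgraph"` (default) or `"wig"`.
#' @param omit_zero Drop zero-valued records in bedGraph output (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig"),
                        omit_zero = TRUE) {
  stopifnot(inherits(track, "binned_track"))
  format <- match.arg(format)
  lines <- character(0)
  if (format == "bedgraph") {
    lines <- "track type=bedGraph"
    for (ch in names(track$counts)) {
      x <- track$counts[[ch]]
      if (!length(x)) next
      r <- rle(x)
      ends0 <- cumsum(r$lengths) * track$bin_size
      starts0 <- ends0 - r$lengths * track$bin_size
      ends0 <- pmin(ends0, track$chrom_lengths[[ch]])
      keep <- if (omit_zero) r$values != 0 else rep(TRUE, length(r$values))
      if (!any(keep)) next
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch,
                                as.integer(starts0[keep]),
                                as.integer(ends0[keep]),
                                format(r$values[keep], trim = TRUE,
                                       scientific = FALSE, digits = 15)))
    }
  } else {
    lines <- "track type=wiggle_0"
    for (ch in names(track$counts)) {
      x <- track$counts[[ch]]
      if (!length(x)) next
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         ch, track$bin_size, track$bin_size),
                 format(x, trim = TRUE, scientific = FALSE, digits = 15))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into a binned track
#'
#' Inverse of [write_track()] for bedGraph output on a known bin grid:
#' every record must start and end on grid boundaries (the final partial
#' bin may end at the chromosome end). Bins absent from the file are zero.
#'
#' @param path bedGraph file.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width the file was written at.
#' @param extension,depth,normalized,scale_per Track metadata to attach
#'   (bedGraph itself does not carry them).
#' @return A [binned_track].
#' @export
read_track_bedgraph <- function(path, chrom_lengths, bin_size = 25L,
                                extension = 200L, depth = NA_real_,
                                normalized = TRUE, scale_per = 1e6) {
  .check_chrom_lengths(chrom_lengths)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  counts <- lapply(chrom_lengths, function(len)
    numeric(as.integer(ceiling(len / bin_size))))
  if (length(lines)) {
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"))
    unknown <- setdiff(unique(dt$chrom), names(chrom_lengths))
    if (length(unknown))
      .stopf("bedGraph records on unknown chromosome(s): %s",
             paste(unknown, collapse = ", "))
    for (ch in unique(dt$chrom)) {
      sub <- dt[dt$chrom == ch, ]
      if (any(sub$start %% bin_size != 0))
        .stopf("bedGraph record off the %d-bp grid on %s", bin_size, ch)
      b <- .bin_span(sub$start, sub$end, bin_size)
      for (i in seq_len(nrow(sub)))
        counts[[ch]][(b[i, "first"]:b[i, "last"]) + 1L] <- sub$value[i]
    }
  }
  binned_track(counts, chrom_lengths, bin_size = bin_size,
               extension = extension, depth = depth,
               normalized = normalized, scale_per = scale_per)
}
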