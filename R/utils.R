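# Internal interval helpers. All public coordinates are 0-based half-open;
# IRanges is 1-based closed, so [s, e) maps to IRanges(s + 1, e).

# 0-based half-open intervals (two-column matrix or data.frame) -> IRanges
.as_iranges <- function(iv) {
  if (is.null(iv) || NROW(iv) == 0L) return(IRanges::IRanges())
  IRanges::IRanges(start = iv[[1]] + 1L, end = iv[[2]])
}

# IRanges -> 0-based half-open data.frame(start, end)
.as_intervals <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

.empty_intervals <- function() data.frame(start = integer(0), end = integer(0))

# clip 0-based half-open intervals to [0, chrom_length); drops empty results
.clip_intervals <- function(iv, chrom_length) {
  s <- pmax(iv$start, 0L)
  e <- pmin(iv$end, chrom_length)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

# bin index range covered by [start, end) on a fixed grid from 0
.bin_span <- function(start, end, bin_size) {
  cbind(first = start %/% bin_size, last = (end - 1L) %/% bin_size)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_chrom_lengths <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    .stopf("chrom_lengths must be a named vector of chromosome lengths")
  if (any(chrom_lengths <= 0))
    .stopf("chromosome lengths must be positive")
  chrom_lengths
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length in bases (the
#' standard `chrom.sizes` layout).
#'
#' @param path Path to the file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  if (nrow(dt) == 0L) .stopf("empty chrom.sizes file: %s", path)
  setNames(as.numeric(dt$length), dt$chrom)
}
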