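#' Feature classes, in apportionment priority order
#'
#' Reads are assigned to the first class whose genome-wide interval set
#' they overlap by at least one base: TSS region, 5'UTR, TTS region, 3'UTR,
#' exonic, intronic; reads overlapping none are intergenic.
#'
#' @export
FEATURE_CLASSES <- c("tss_region", "utr5", "tts_region", "utr3",
                     "exonic", "intronic", "intergenic")

#' Build a genome-wide feature index from gene models
#'
#' Derives [derive_feature_windows()] for every gene and merges each
#' feature class into one reduced interval set per chromosome. The index is
#' genome-wide: a read overlapping windows of different genes in different
#' classes takes the higher-priority class overall.
#'
#' @param genes List of [gene_model] objects.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Object of class `feature_index`: per class, a named list of
#'   [IRanges::IRanges] per chromosome.
#' @export
build_feature_index <- function(genes, chrom_lengths) {
  .check_chrom_lengths(chrom_lengths)
  classes <- setdiff(FEATURE_CLASSES, "intergenic")
  acc <- lapply(classes, function(cls)
    lapply(setNames(nm = names(chrom_lengths)), function(ch) list()))
  names(acc) <- classes
  for (g in genes) {
    if (!g$chrom %in% names(chrom_lengths))
      .stopf("gene %s on unknown chromosome %s", g$gene_id, g$chrom)
    w <- derive_feature_windows(g, chrom_lengths[[g$chrom]])
    for (cls in classes) {
      iv <- w[[cls]]
      if (NROW(iv))
        acc[[cls]][[g$chrom]] <- c(acc[[cls]][[g$chrom]], list(iv))
    }
  }
  index <- lapply(acc, function(per_chrom)
    lapply(per_chrom, function(parts) {
      if (!length(parts)) return(IRanges::IRanges())
      IRanges::reduce(.as_iranges(do.call(rbind, parts)))
    }))
  structure(list(index = index, chrom_lengths = chrom_lengths),
            class = "feature_index")
}

#' Classify reads into genomic feature classes
#'
#' Sequential apportionment: each (unextended) read goes to the first class
#' in [FEATURE_CLASSES] whose interval set it overlaps by at least one
#' base, anywhere in the genome; otherwise `intergenic`. Read strand is
#' ignored (feature strand is already encoded in the window construction).
#'
#' @param reads data.frame with `chrom`, `start`, `end`.
#' @param feature_index A [build_feature_index()] result.
#' @return Factor of class labels, levels [FEATURE_CLASSES], one per read.
#' @export
classify_reads <- function(reads, feature_index) {
  stopifnot(inherits(feature_index, "feature_index"))
  unknown <- setdiff(unique(reads$chrom), names(feature_index$chrom_lengths))
  if (length(unknown))
    .stopf("reads on unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  out <- factor(rep("intergenic", nrow(reads)), levels = FEATURE_CLASSES)
  if (!nrow(reads)) return(out)
  priority <- setdiff(FEATURE_CLASSES, "intergenic")
  for (ch in unique(reads$chrom)) {
    sel <- which(reads$chrom == ch)
    ir <- .as_iranges(data.frame(start = reads$start[sel],
                                 end = reads$end[sel]))
    unassigned <- rep(TRUE, length(sel))
    for (cls in priority) {
      if (!any(unassigned)) break
      win <- feature_index$index[[cls]][[ch]]
      if (!length(win)) next
      hit <- unassigned & IRanges::overlapsAny(ir, win)
      out[sel[hit]] <- cls
      unassigned <- unassigned & !hit
    }
  }
  out
}

#' Apportion a read library over feature classes
#'
#' Applies [classify_reads()] to every read and tabulates the class
#' distribution. The counts always partition the library exactly:
#' their sum equals the number of reads.
#'
#' @inheritParams classify_reads
#' @return Object of class `feature_counts`: named integer vector over
#'   [FEATURE_CLASSES] with attributes `total` and `fractions`.
#' @export
apportion_library <- function(reads, feature_index) {
  cls <- classify_reads(reads, feature_index)
  counts <- table(cls)
  counts <- setNames(as.integer(counts), names(counts))[FEATURE_CLASSES]
  structure(counts, total = nrow(reads),
            fractions = if (nrow(reads)) counts / nrow(reads)
                        else setNames(rep(NA_real_, length(counts)),
                                      names(counts)),
            class = "feature_counts")
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("<feature_counts> %d read(s)\n", attr(x, "total")))
  for (nm in names(unclass(x)))
    cat(sprintf("  %-11s %8d  (%.3f)\n", nm, x[[nm]],
                attr(x, "fractions")[[nm]]))
  invisible(x)
}

#' Write a feature-class distribution as TSV
#'
#' Columns: class, count, fraction.
#'
#' @param counts A [apportion_library()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_counts <- function(counts, path) {
  stopifnot(inherits(counts, "feature_counts"))
  data.table::fwrite(
    data.table::data.table(class = names(unclass(counts)),
                           count = as.integer(counts),
                           fraction = as.numeric(attr(counts, "fractions"))),
    path, sep = "\t")
  invisible(path)
}
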