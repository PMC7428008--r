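#' Construct a gene model
#'
#' One collapsed gene: transcript span, strand, exon structure, optional CDS
#' and gene-set memberships. Coordinates are 0-based half-open.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end Transcript span (0-based half-open).
#' @param exons data.frame with columns `start`, `end`; sorted,
#'   non-overlapping, all within the transcript span. Defaults to a single
#'   exon covering the whole span.
#' @param cds_start,cds_end Coding region, or `NA` for non-coding genes.
#'   When present, the CDS must lie within the span and be fully covered by
#'   exons.
#' @param sets Character vector of gene-set names this gene belongs to.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end,
                       exons = NULL, cds_start = NA, cds_end = NA,
                       sets = character(0)) {
  if (!strand %in% c("+", "-")) .stopf("gene %s: strand must be '+' or '-'", gene_id)
  tx_start <- as.numeric(tx_start); tx_end <- as.numeric(tx_end)
  if (!(tx_start < tx_end)) .stopf("gene %s: tx_start must be < tx_end", gene_id)
  if (is.null(exons)) exons <- data.frame(start = tx_start, end = tx_end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end))
    .stopf("gene %s: empty or inverted exon", gene_id)
  if (exons$start[1] < tx_start || exons$end[nrow(exons)] > tx_end)
    .stopf("gene %s: exon outside transcript span", gene_id)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    .stopf("gene %s: overlapping exons", gene_id)
  if (!is.na(cds_start) || !is.na(cds_end)) {
    if (is.na(cds_start) || is.na(cds_end))
      .stopf("gene %s: cds_start and cds_end must both be given", gene_id)
    if (!(tx_start <= cds_start && cds_start < cds_end && cds_end <= tx_end))
      .stopf("gene %s: CDS outside transcript span", gene_id)
    # thickStart/thickEnd semantics: both CDS boundaries fall in exons
    # (the spliced CDS is then covered by the exon chain)
    in_exon <- function(pos) any(exons$start <= pos & pos < exons$end)
    if (!in_exon(cds_start) || !in_exon(cds_end - 1))
      .stopf("gene %s: CDS boundaries must lie within exons", gene_id)
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, tx_start = tx_start, tx_end = tx_end,
                 exons = exons,
                 cds_start = if (is.na(cds_start)) NA_real_ else as.numeric(cds_start),
                 cds_end = if (is.na(cds_end)) NA_real_ else as.numeric(cds_end),
                 sets = unique(as.character(sets))),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) exons=%d cds=%s sets=[%s]\n",
              x$gene_id, x$chrom, x$tx_start, x$tx_end, x$strand,
              nrow(x$exons),
              if (is.na(x$cds_start)) "none" else
                sprintf("%d-%d", x$cds_start, x$cds_end),
              paste(x$sets, collapse = ",")))
  invisible(x)
}

# ---- loading -----------------------------------------------------------

.read_set_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

.precheck_columns <- function(path, min_cols, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (!any(keep)) .stopf("empty annotation file: %s", path)
  bad <- which(keep)[nf < min_cols]
  if (length(bad))
    .stopf("malformed %s record at line %d of %s (expected >= %d fields)",
           what, bad[1], path, min_cols)
}

# BED12 rows (possibly several transcripts sharing a name) -> gene models
.genes_from_bed12 <- function(path) {
  .precheck_columns(path, 12L, "BED12")
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) .stopf("empty annotation file: %s", path)
  ids <- as.character(gr$name)
  out <- lapply(split(seq_along(gr), ids), function(ix) {
    sub <- gr[ix]
    chrom <- as.character(GenomicRanges::seqnames(sub)[1])
    strand <- as.character(BiocGenerics::strand(sub)[1])
    if (strand == "*") strand <- "+"
    tx_start <- min(BiocGenerics::start(sub)) - 1L
    tx_end <- max(BiocGenerics::end(sub))
    # blocks are 1-based relative to each transcript's start
    ex <- IRanges::IRanges()
    for (j in seq_along(sub)) {
      bl <- sub$blocks[[j]]
      off <- BiocGenerics::start(sub)[j] - 1L   # 0-based tx start
      ex <- c(ex, IRanges::shift(bl, off))
    }
    ex <- IRanges::reduce(ex)
    cds_start <- NA; cds_end <- NA
    th <- sub$thick
    tw <- BiocGenerics::width(th)
    if (any(tw > 0)) {
      cds_start <- min(BiocGenerics::start(th)[tw > 0]) - 1L
      cds_end <- max(BiocGenerics::end(th)[tw > 0])
    }
    .collapse_gene(ids[ix[1]], chrom, strand, tx_start, tx_end,
                   .as_intervals(ex), cds_start, cds_end)
  })
  unname(out)
}

.genes_from_gtf <- function(path) {
  .precheck_columns(path, 9L, "GTF")
  gr <- rtracklayer::import(path, format = "GTF")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) .stopf("no exon records in GTF: %s", path)
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    .stopf("GTF exon records lack gene_id attributes: %s", path)
  cds <- gr[gr$type == "CDS"]
  cds_by <- if (length(cds)) split(seq_along(cds), as.character(cds$gene_id))
            else list()
  out <- lapply(split(seq_along(ex), as.character(ex$gene_id)), function(ix) {
    sub <- ex[ix]
    gid <- as.character(sub$gene_id[1])
    chrom <- as.character(GenomicRanges::seqnames(sub)[1])
    strand <- as.character(BiocGenerics::strand(sub)[1])
    if (strand == "*") strand <- "+"
    exi <- IRanges::reduce(IRanges::IRanges(BiocGenerics::start(sub),
                                            BiocGenerics::end(sub)))
    cds_start <- NA; cds_end <- NA
    if (gid %in% names(cds_by)) {
      cs <- cds[cds_by[[gid]]]
      cds_start <- min(BiocGenerics::start(cs)) - 1L
      cds_end <- max(BiocGenerics::end(cs))
    }
    .collapse_gene(gid, chrom, strand,
                   min(BiocGenerics::start(exi)) - 1L,
                   max(BiocGenerics::end(exi)),
                   .as_intervals(exi), cds_start, cds_end)
  })
  unname(out)
}

# Build the collapsed per-gene model; if the CDS hull's boundaries fall
# outside the unioned exons (can happen across transcripts), drop it with a
# warning.
.collapse_gene <- function(gene_id, chrom, strand, tx_start, tx_end,
                           exons, cds_start, cds_end) {
  if (!is.na(cds_start)) {
    in_exon <- function(pos) any(exons$start <= pos & pos < exons$end)
    covered <- in_exon(cds_start) && in_exon(cds_end - 1)
    if (!covered) {
      warning(sprintf("gene %s: collapsed CDS hull not covered by exons; treating as non-coding",
                      gene_id), call. = FALSE)
      cds_start <- NA; cds_end <- NA
    }
  }
  gene_model(gene_id, chrom, strand, tx_start, tx_end, exons,
             cds_start, cds_end)
}

#' Load gene models and gene-set memberships
#'
#' Reads a BED12 or GTF annotation (format chosen by file extension, or
#' forced with `format`) and collapses multiple transcripts of a gene into a
#' single model: the transcript span is the union span, the exons are the
#' union of all transcripts' exons, and the CDS is the min-max hull of the
#' transcripts' coding regions. Gene-set files contain one gene ID per line
#' (`#` comments allowed); IDs absent from the annotation are reported with
#' a warning but are not fatal.
#'
#' @param annotation_path BED12 or GTF file. In GTF, genes are identified by
#'   the ENSEMBL-style `gene_id` attribute; in BED12 by the `name` column.
#' @param set_lists Named list of file paths, one per gene set (e.g.
#'   `list(BRD4 = "brd4.txt")`).
#' @param format `"auto"` (default, by extension), `"bed12"` or `"gtf"`.
#' @return List of [gene_model] objects, one per gene ID.
#' @export
load_genes <- function(annotation_path, set_lists = list(), format = "auto") {
  format <- match.arg(format, c("auto", "bed12", "gtf"))
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", annotation_path,
                        ignore.case = TRUE)) "gtf" else "bed12"
  }
  genes <- if (format == "gtf") .genes_from_gtf(annotation_path)
           else .genes_from_bed12(annotation_path)
  if (length(set_lists)) {
    if (is.null(names(set_lists)) || any(!nzchar(names(set_lists))))
      .stopf("set_lists must be a named list of file paths")
    known <- vapply(genes, `[[`, "", "gene_id")
    for (set_name in names(set_lists)) {
      ids <- .read_set_list(set_lists[[set_name]])
      unknown <- setdiff(ids, known)
      if (length(unknown))
        warning(sprintf("gene set %s: %d ID(s) not in annotation (e.g. %s)",
                        set_name, length(unknown),
                        paste(head(unknown, 3), collapse = ", ")),
                call. = FALSE)
      hit <- which(known %in% ids)
      for (i in hit) genes[[i]]$sets <- union(genes[[i]]$sets, set_name)
    }
  }
  genes
}

# ---- feature windows ---------------------------------------------------

# TSS window: 50 bp upstream to 300 bp downstream of the start site.
# TTS window: 50 bp upstream to 200 bp downstream of the transcript 3' end.
.TSS_UP <- 50L; .TSS_DOWN <- 300L
.TTS_UP <- 50L; .TTS_DOWN <- 200L

#' Derive fixed genomic feature windows for one gene
#'
#' Strand-aware windows used for read apportionment:
#' * `tss_region` — 50 bp upstream to 300 bp downstream of the TSS
#'   (350 bases, clipped at chromosome ends);
#' * `tts_region` — 50 bp upstream to 200 bp downstream of the transcript
#'   3' end (250 bases);
#' * `utr5` / `utr3` — exonic sequence between the transcript end and the
#'   CDS boundary (empty for non-coding genes);
#' * `exonic` — exons minus the UTRs;
#' * `intronic` — transcript span minus exons.
#'
#' On the minus strand the TSS sits at `tx_end` and "upstream" means larger
#' coordinates. For any gene, `intronic` and `exonic + utr5 + utr3`
#' partition the transcript span exactly.
#'
#' @param gene A [gene_model].
#' @param chrom_length Chromosome length in bases (windows are clipped to
#'   `[0, chrom_length)`).
#' @return Object of class `feature_windows`: list of interval
#'   data.frames (`start`, `end`, 0-based half-open) named `tss_region`,
#'   `tts_region`, `utr5`, `utr3`, `exonic`, `intronic`.
#' @export
derive_feature_windows <- function(gene, chrom_length) {
  stopifnot(inherits(gene, "gene_model"))
  if (chrom_length < gene$tx_end)
    .stopf("gene %s: chrom_length %g < tx_end %g", gene$gene_id,
           chrom_length, gene$tx_end)
  s <- gene$tx_start; e <- gene$tx_end
  if (gene$strand == "+") {
    tss <- data.frame(start = s - .TSS_UP, end = s + .TSS_DOWN)
    tts <- data.frame(start = e - .TTS_UP, end = e + .TTS_DOWN)
  } else {
    tss <- data.frame(start = e - .TSS_DOWN, end = e + .TSS_UP)
    tts <- data.frame(start = s - .TTS_DOWN, end = s + .TTS_UP)
  }
  ex_ir <- .as_iranges(gene$exons)
  span_ir <- .as_iranges(data.frame(start = s, end = e))
  utr5 <- utr3 <- IRanges::IRanges()
  if (!is.na(gene$cds_start)) {
    before <- .as_iranges(data.frame(start = s, end = gene$cds_start))
    after <- .as_iranges(data.frame(start = gene$cds_end, end = e))
    if (gene$strand == "+") {
      utr5 <- IRanges::intersect(ex_ir, before)
      utr3 <- IRanges::intersect(ex_ir, after)
    } else {
      utr5 <- IRanges::intersect(ex_ir, after)
      utr3 <- IRanges::intersect(ex_ir, before)
    }
  }
  exonic <- IRanges::setdiff(IRanges::setdiff(ex_ir, utr5), utr3)
  intronic <- IRanges::setdiff(span_ir, ex_ir)
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 tss_region = .clip_intervals(tss, chrom_length),
                 tts_region = .clip_intervals(tts, chrom_length),
                 utr5 = .as_intervals(utr5),
                 utr3 = .as_intervals(utr3),
                 exonic = .as_intervals(exonic),
                 intronic = .as_intervals(intronic)),
            class = "feature_windows")
}

#' Write derived feature windows as BED6
#'
#' One record per interval; the feature class goes in the BED name column,
#' the gene strand in the strand column.
#'
#' @param windows List of [derive_feature_windows()] results (or a single
#'   one).
#' @param genes Matching list of [gene_model] objects (for strands).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_windows <- function(windows, genes, path) {
  if (inherits(windows, "feature_windows")) windows <- list(windows)
  if (inherits(genes, "gene_model")) genes <- list(genes)
  strands <- setNames(vapply(genes, `[[`, "", "strand"),
                      vapply(genes, `[[`, "", "gene_id"))
  rows <- list()
  for (w in windows) {
    for (cls in c("tss_region", "utr5", "tts_region", "utr3",
                  "exonic", "intronic")) {
      iv <- w[[cls]]
      if (NROW(iv) == 0L) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = w$chrom, start = iv$start, end = iv$end,
        name = paste0(cls, "|", w$gene_id), score = 0L,
        strand = strands[[w$gene_id]])
    }
  }
  out <- if (length(rows)) data.table::rbindlist(rows)
         else data.table::data.table(chrom = character(0), start = integer(0),
                                     end = integer(0), name = character(0),
                                     score = integer(0), strand = character(0))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
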