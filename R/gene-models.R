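#' Construct a gene model
#'
#' Exon intervals of one gene.  Input intervals are 0-based half-open (BED
#' convention); overlapping or book-ended exons are merged.  Internally the
#' exons are stored as a [GenomicRanges::GRanges] (1-based closed, the
#' Bioconductor convention).
#'
#' @param gene_id gene symbol.
#' @param chrom chromosome name.
#' @param starts,ends integer vectors, 0-based half-open exon bounds.
#' @param strand `"+"` or `"-"`.
#' @return object of class `GeneModel`: list with `gene_id`, `chrom`,
#'   `strand`, `exons` (GRanges, reduced and sorted), `coding_length`.
#' @export
gene_model <- function(gene_id, chrom, starts, ends, strand = "+") {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) == 0L) pf_data_error(
    sprintf("gene '%s' has no exons", gene_id))
  if (any(ends <= starts)) pf_data_error(
    sprintf("gene '%s' has exon interval(s) with end <= start", gene_id))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    strand = strand)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 strand = as.character(strand),
                 exons = gr,
                 coding_length = sum(GenomicRanges::width(gr))),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s): %d exon(s), coding length %d bp\n",
              x$gene_id, x$chrom, x$strand, length(x$exons),
              x$coding_length))
  invisible(x)
}

#' Read gene exon models from a BED file
#'
#' Each BED row is one exon; the name column (4th) carries the gene
#' symbol and rows sharing a symbol are collected into one gene model with
#' overlapping exons merged.  Intervals with `end <= start` are fatal.
#'
#' @param path BED file (>= 4 columns, 0-based half-open).
#' @return named list of [gene_model()] objects, keyed by gene id.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) pf_data_error(sprintf("file not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) pf_data_error(
                   sprintf("cannot parse BED '%s': %s",
                           path, conditionMessage(e))))
  if (length(gr) == 0L) pf_data_error(sprintf("BED file '%s' is empty", path))
  if (any(GenomicRanges::width(gr) < 1L)) {
    pf_data_error(sprintf("BED '%s' contains interval(s) with end <= start",
                          path))
  }
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) {
    pf_data_error(sprintf("BED '%s' lacks the name column with gene ids",
                          path))
  }
  by_gene <- split(gr, nm)
  models <- lapply(names(by_gene), function(g) {
    sub <- by_gene[[g]]
    strand <- as.character(GenomicRanges::strand(sub)[1])
    if (strand == "*") strand <- "+"
    gene_model(g, as.character(GenomicRanges::seqnames(sub))[1],
               starts = GenomicRanges::start(sub) - 1,
               ends = GenomicRanges::end(sub),
               strand = strand)
  })
  names(models) <- names(by_gene)
  models
}

#' Write gene models to a BED file
#'
#' One row per exon, 0-based half-open, name column = gene id.  Rows are
#' sorted by chromosome then start, so output is deterministic.
#'
#' @param models named list of `GeneModel` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  grl <- lapply(models, function(m) {
    gr <- m$exons
    gr$name <- m$gene_id
    gr
  })
  all <- sort_granges(concat_granges(grl))
  write_atomic(path, function(tmp) {
    rtracklayer::export(all, tmp, format = "bed")
  })
  invisible(path)
}
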