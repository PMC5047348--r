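# Internal error and I/O helpers shared across modules.

# Structured conditions: usage errors (bad arguments / CLI flags) and data
# errors (malformed input files) map to distinct CLI exit codes.
pf_usage_error <- function(msg) {
  stop(structure(class = c("pf_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

pf_data_error <- function(msg) {
  stop(structure(class = c("pf_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Write a file atomically: the writer produces a temp file in the target
# directory which is then renamed over the destination.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    pf_data_error(sprintf("cannot write output file '%s'", path))
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Concatenate GRanges built independently (possibly disjoint seqlevels);
# the Seqinfo merge warning is noise here.
concat_granges <- function(lst) {
  suppressWarnings(unname(do.call(c, unname(lst))))
}

# Deterministic GRanges ordering: alphabetical chromosome order regardless
# of the order chromosomes were first seen, then start coordinate.
sort_granges <- function(gr) {
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
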