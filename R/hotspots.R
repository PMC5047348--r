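# Mutational hotspot detection: iterative extraction of the bounded-width
# genomic window with the highest mutation count.

#' Best mutation window of bounded width
#'
#' Over all genomic windows of width at most `L` bp, finds the one
#' containing the largest total mutation count, and shrinks it to the
#' minimal span whose bounds are mutated positions.  Ties are broken by
#' smaller span, then smaller start coordinate, which makes the result
#' deterministic and prefers compact windows.
#'
#' An optimal window can always be slid until its left edge sits on a
#' mutated site, so only site-anchored windows need scanning.
#'
#' @param site_counts named integer vector (names = 1-based positions,
#'   values = mutation counts) or a two-column data.frame `pos`, `count`.
#' @param L maximum window width in bp (span `end - start + 1 <= L`).
#' @return list with `start`, `end` (1-based inclusive, both mutated
#'   positions) and `n_mutations`.
#' @examples
#' best_window(c(`100` = 3, `150` = 2, `500` = 1), L = 100)
#' @export
best_window <- function(site_counts, L = 100) {
  if (is.data.frame(site_counts)) {
    pos <- as.numeric(site_counts$pos)
    cnt <- as.numeric(site_counts$count)
  } else {
    pos <- as.numeric(names(site_counts))
    cnt <- as.numeric(site_counts)
  }
  if (!length(pos)) pf_usage_error("site_counts must be non-empty")
  if (L < 1) pf_usage_error("L must be >= 1")
  o <- order(pos)
  pos <- pos[o]; cnt <- cnt[o]
  n <- length(pos)
  # j[i]: index of the rightmost site within L bp of site i.
  j <- findInterval(pos + L - 1, pos)
  cs <- cumsum(cnt)
  total <- cs[j] - c(0, cs)[seq_len(n)]
  span <- pos[j] - pos + 1
  best <- order(-total, span, pos)[1]
  list(start = pos[best], end = pos[j[best]],
       n_mutations = as.integer(total[best]))
}

# Tally PAM positions of one gene into a site-count table.
site_count_table <- function(positions) {
  tab <- table(positions)
  data.frame(pos = as.numeric(names(tab)), count = as.integer(tab))
}

#' Iterative hotspot detection in one gene
#'
#' Repeatedly extracts the [best_window()] of width at most `L` over the
#' remaining mutations, removing the mutations it contains, until every
#' remaining site carries fewer than two mutations.  Every emitted hotspot
#' therefore contains at least two mutations, and hotspots consume
#' disjoint mutation sets.
#'
#' @param positions 1-based genomic positions of the gene's
#'   protein-affecting mutations (one entry per mutation; indels at their
#'   start coordinate), or a data.frame with a `pos` column (e.g. the
#'   `mutations` slot of a `Cohort` subset to one gene).
#' @param L maximum hotspot width in bp (default 100).
#' @param gene_id,chrom carried into the output for labeling.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_mutations`, `iteration`; zero rows when no
#'   recurrent site exists.
#' @export
find_hotspots <- function(positions, L = 100, gene_id = NA_character_,
                          chrom = NA_character_) {
  if (is.data.frame(positions)) {
    if (is.na(gene_id) && "gene_id" %in% names(positions) &&
        nrow(positions)) gene_id <- positions$gene_id[1]
    if (is.na(chrom) && "chrom" %in% names(positions) &&
        nrow(positions)) chrom <- positions$chrom[1]
    positions <- positions$pos
  }
  out <- list()
  it <- 0L
  tab <- site_count_table(positions)
  while (nrow(tab) && max(tab$count) >= 2L) {
    bw <- best_window(tab, L = L)
    it <- it + 1L
    out[[it]] <- data.frame(gene_id = gene_id, chrom = chrom,
                            start = bw$start, end = bw$end,
                            n_mutations = bw$n_mutations, iteration = it,
                            stringsAsFactors = FALSE)
    tab <- tab[tab$pos < bw$start | tab$pos > bw$end, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_mutations = integer(), iteration = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Choose hotspot or whole-exome representation for a gene
#'
#' Runs [find_hotspots()] on the gene's PAMs and checks whether the
#' hotspots jointly capture at least `min_fraction` of them (80% by
#' default).  If so the gene is represented by its hotspots individually;
#' otherwise its complete coding exome enters the panel.
#'
#' @param gene_mutations data.frame of one gene's PAM records (needs
#'   columns `pos`, and ideally `gene_id`, `chrom`).
#' @param model the gene's [gene_model()]; required when the whole-exome
#'   fallback fires (fatal if missing then).
#' @param L maximum hotspot width in bp.
#' @param min_fraction minimum captured fraction in (0, 1] to stay in
#'   hotspot mode.
#' @return object of class `GeneRepresentation`: list with `gene_id`,
#'   `mode` (`"hotspots"` or `"whole_exome"`), `hotspots` (data.frame,
#'   empty in whole-exome mode), `captured_fraction`, `n_pams`.
#' @export
represent_gene <- function(gene_mutations, model = NULL, L = 100,
                           min_fraction = 0.8) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    pf_usage_error("min_fraction must be in (0, 1]")
  }
  gene_id <- if (nrow(gene_mutations)) gene_mutations$gene_id[1] else
    (model$gene_id %||% NA_character_)
  hs <- find_hotspots(gene_mutations, L = L)
  n_pams <- nrow(gene_mutations)
  captured <- if (n_pams > 0) sum(hs$n_mutations) / n_pams else 0
  mode <- if (n_pams > 0 && captured >= min_fraction) "hotspots" else
    "whole_exome"
  if (mode == "whole_exome") {
    if (is.null(model)) {
      pf_data_error(sprintf(
        "gene '%s' requires its whole exome but has no gene model", gene_id))
    }
    hs <- hs[0, , drop = FALSE]
  }
  structure(list(gene_id = gene_id, mode = mode, hotspots = hs,
                 captured_fraction = captured, n_pams = n_pams),
            class = "GeneRepresentation")
}

#' @export
print.GeneRepresentation <- function(x, ...) {
  cat(sprintf("GeneRepresentation %s: %s (%d hotspot(s), %.1f%% of %d PAMs captured)\n",
              x$gene_id, x$mode, nrow(x$hotspots),
              100 * x$captured_fraction, x$n_pams))
  invisible(x)
}
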