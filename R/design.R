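# Panel design: greedy maximum-marginal-coverage ranking of panel items
# (whole genes or hotspots), tier classification against the expected
# per-rank CMF gain, and the end-to-end design pipeline.

#' Construct a panel item
#'
#' A unit of panel content: either one mutational hotspot or a gene's
#' whole coding exome.  Intervals are held as a GRanges (1-based closed);
#' `covered_samples` are the cohort samples with at least one PAM falling
#' inside the intervals.
#'
#' @param item_id unique item identifier (used for deterministic
#'   tie-breaking).
#' @param gene_id gene symbol.
#' @param kind `"whole_gene"` or `"hotspot"`.
#' @param intervals GRanges of the targeted regions.
#' @param covered_samples character vector of covered sample ids.
#' @return object of class `PanelItem`.
#' @export
panel_item <- function(item_id, gene_id, kind = c("whole_gene", "hotspot"),
                       intervals, covered_samples) {
  kind <- match.arg(kind)
  length_bp <- sum(GenomicRanges::width(intervals))
  if (length_bp <= 0) pf_usage_error(
    sprintf("panel item '%s' has zero target length", item_id))
  structure(list(item_id = as.character(item_id),
                 gene_id = as.character(gene_id), kind = kind,
                 intervals = intervals, length_bp = as.integer(length_bp),
                 covered_samples = sort(unique(as.character(covered_samples)))),
            class = "PanelItem")
}

# Samples whose PAM positions overlap a set of intervals.
samples_hitting <- function(cohort, intervals) {
  mut <- cohort$mutations[cohort$mutations$pam, , drop = FALSE]
  if (!nrow(mut)) return(character())
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(mut$chrom, IRanges::IRanges(mut$pos, mut$pos)),
    intervals)
  sort(unique(mut$sample_id[S4Vectors::queryHits(hits)]))
}

#' Greedy CMF ranking of panel items
#'
#' Orders items by greedy maximum marginal coverage: at each rank the item
#' covering the most samples not yet covered by earlier items is selected,
#' and the cumulative mutational frequency advances by
#' `|new samples| / n_samples`.  Ties are broken by larger total covered
#' set, then lexicographic `item_id`.  Items with zero marginal gain are
#' appended in the same tie-break order with the CMF unchanged.
#'
#' @param items list of [panel_item()] objects with `covered_samples`
#'   precomputed against `cohort`.
#' @param cohort a `Cohort`; its full sample set is the CMF denominator.
#' @return data.frame with one row per item in rank order: `rank`,
#'   `item_id`, `gene_id`, `kind`, `marginal_new_samples`, `cmf`,
#'   `length_bp`.  The input items, reordered, are attached as
#'   `attr(, "items")`.
#' @export
greedy_rank <- function(items, cohort) {
  if (!length(items)) pf_usage_error("no panel items to rank")
  n_s <- length(cohort$samples)
  if (n_s == 0L) pf_data_error("cohort has zero samples")
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) pf_usage_error("duplicate panel item ids")
  sets <- lapply(items, `[[`, "covered_samples")
  tot <- lengths(sets)
  # Pre-sort by the tie-break key so which.max resolves ties correctly.
  ord0 <- order(-tot, ids)
  items <- items[ord0]; sets <- sets[ord0]; tot <- tot[ord0]; ids <- ids[ord0]
  n <- length(items)
  covered <- character()
  sel <- integer(n); marg <- integer(n)
  remaining <- seq_len(n)
  for (r in seq_len(n)) {
    gains <- vapply(remaining,
                    function(i) sum(!(sets[[i]] %in% covered)), integer(1))
    pick <- remaining[which.max(gains)]   # first max = tie-break order
    sel[r] <- pick
    marg[r] <- max(gains)
    covered <- union(covered, sets[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  items <- items[sel]
  out <- data.frame(
    rank = seq_len(n),
    item_id = vapply(items, `[[`, character(1), "item_id"),
    gene_id = vapply(items, `[[`, character(1), "gene_id"),
    kind = vapply(items, `[[`, character(1), "kind"),
    marginal_new_samples = marg,
    cmf = cumsum(marg) / n_s,
    length_bp = vapply(items, `[[`, integer(1), "length_bp"),
    stringsAsFactors = FALSE)
  attr(out, "items") <- items
  attr(out, "n_samples") <- n_s
  out
}

#' Assign CMF tiers to ranked items
#'
#' The expected per-rank CMF gain `s` is the slope of the CMF trend over
#' the items that contribute new samples, i.e. the mean marginal gain
#' fraction across positive-gain items.  Tier 1 items gain at least `s`
#' (or `2 * s` under the stringent option), Tier 2 items gain less but
#' more than zero, and Tier 3 items contribute nothing.  Greedy ordering
#' makes marginal gains non-increasing, so tiers are contiguous; this is
#' asserted.
#'
#' @param ranked output of [greedy_rank()].
#' @param stringent use the stricter Tier-1 threshold `2 * s`.
#' @param threshold optional explicit Tier-1 threshold (a gain fraction),
#'   overriding the slope-derived one.
#' @return `ranked` with an integer `tier` column added.
#' @export
assign_tiers <- function(ranked, stringent = FALSE, threshold = NULL) {
  n_s <- attr(ranked, "n_samples")
  gains <- ranked$marginal_new_samples / n_s
  pos <- gains > 0
  if (is.null(threshold)) {
    if (sum(pos) < 2L) {
      # Degenerate fit: every contributing item is Tier 1.
      threshold <- 0
    } else {
      s <- mean(gains[pos])
      threshold <- if (stringent) 2 * s else s
    }
  }
  tier <- ifelse(!pos, 3L, ifelse(gains >= threshold, 1L, 2L))
  # Contiguity follows from greedy monotonicity of the gains.
  stopifnot(!is.unsorted(tier))
  ranked$tier <- tier
  ranked
}

#' k-mutation coverage of a set of panel items
#'
#' Fraction of cohort samples with PAMs in at least `k` distinct panel
#' items.
#'
#' @param items list of [panel_item()] objects.
#' @param cohort a `Cohort`.
#' @param k minimum number of distinct mutated items (>= 1).
#' @return a fraction in \[0, 1\].
#' @export
coverage_k <- function(items, cohort, k = 1) {
  if (k < 1) pf_usage_error("k must be >= 1")
  n_s <- length(cohort$samples)
  if (n_s == 0L) pf_data_error("cohort has zero samples")
  hits <- table(unlist(lapply(items, `[[`, "covered_samples")))
  sum(hits >= k) / n_s
}

# Build PanelItem objects for one gene given its representation decision.
build_gene_items <- function(rep, cohort, model) {
  if (rep$mode == "hotspots") {
    lapply(seq_len(nrow(rep$hotspots)), function(i) {
      h <- rep$hotspots[i, ]
      gr <- GenomicRanges::GRanges(h$chrom, IRanges::IRanges(h$start, h$end))
      panel_item(item_id = sprintf("%s:hotspot_%d", rep$gene_id, h$iteration),
                 gene_id = rep$gene_id, kind = "hotspot", intervals = gr,
                 covered_samples = samples_hitting(cohort, gr))
    })
  } else {
    gr <- model$exons
    list(panel_item(item_id = rep$gene_id, gene_id = rep$gene_id,
                    kind = "whole_gene", intervals = gr,
                    covered_samples = samples_hitting(cohort, gr)))
  }
}

#' Design a cancer gene panel
#'
#' End-to-end pipeline: restrict the cohort to protein-affecting mutations
#' in the listed genes; decide hotspot versus whole-exome representation
#' per gene ([represent_gene()]); build panel items; rank them greedily by
#' marginal CMF gain ([greedy_rank()]); assign tiers ([assign_tiers()]);
#' and compute 1-, 2- and 3-mutation coverage and the total panel size in
#' Kbps.
#'
#' @param cohort a `Cohort`.
#' @param gene_lists a `GeneList` or list of them; the candidate gene set
#'   is their union.
#' @param models named list of `GeneModel` objects (from
#'   [read_gene_models()] or [simulate_gene_models()]).
#' @param hotspots if `FALSE`, hotspot detection is skipped and every gene
#'   enters as its whole exome.
#' @param L maximum hotspot width in bp (default 100).
#' @param min_fraction minimum fraction of a gene's PAMs that its hotspots
#'   must capture (default 0.8).
#' @param stringent stricter Tier-1 threshold (see [assign_tiers()]).
#' @param tier_threshold optional explicit Tier-1 gain threshold.
#' @param keep_tiers tiers to retain in the final panel (default all
#'   three).  Tiers are contiguous in rank, so restriction keeps a prefix
#'   of the greedy order and earlier items' statistics are unchanged.
#' @return object of class `PanelDesign`: list with `cohort_name`,
#'   `n_samples`, `items` (the ranked & tiered data.frame),
#'   `panel_items` (list of `PanelItem` in rank order), `total_kbps`,
#'   `coverage_k1`, `coverage_k2`, `coverage_k3`, and `representations`
#'   (per-gene `GeneRepresentation`).
#' @export
design_panel <- function(cohort, gene_lists, models, hotspots = TRUE,
                         L = 100, min_fraction = 0.8, stringent = FALSE,
                         tier_threshold = NULL, keep_tiers = c(1L, 2L, 3L)) {
  if (inherits(gene_lists, "GeneList")) gene_lists <- list(gene_lists)
  if (!length(gene_lists)) pf_usage_error("at least one gene list required")
  genes <- sort(unique(unlist(lapply(gene_lists, `[[`, "gene_ids"))))
  mut <- cohort$mutations
  pam <- mut[mut$pam & mut$gene_id %in% genes, , drop = FALSE]
  if (!nrow(pam)) {
    pf_data_error(sprintf(
      paste0("no listed gene carries protein-affecting mutations in the ",
             "cohort (%d candidate genes, %d cohort mutations of which %d ",
             "PAMs)"),
      length(genes), nrow(mut), sum(mut$pam)))
  }
  mutated_genes <- sort(unique(pam$gene_id))
  reps <- lapply(mutated_genes, function(g) {
    gm <- pam[pam$gene_id == g, , drop = FALSE]
    if (hotspots) {
      represent_gene(gm, model = models[[g]], L = L,
                     min_fraction = min_fraction)
    } else {
      if (is.null(models[[g]])) pf_data_error(sprintf(
        "gene '%s' requires its whole exome but has no gene model", g))
      structure(list(gene_id = g, mode = "whole_exome",
                     hotspots = find_hotspots(gm, L = L)[0, ],
                     captured_fraction = 0, n_pams = nrow(gm)),
                class = "GeneRepresentation")
    }
  })
  names(reps) <- mutated_genes
  items <- unlist(lapply(mutated_genes, function(g) {
    build_gene_items(reps[[g]], cohort, models[[g]])
  }), recursive = FALSE)
  ranked <- greedy_rank(items, cohort)
  ranked <- assign_tiers(ranked, stringent = stringent,
                         threshold = tier_threshold)
  keep <- ranked$tier %in% keep_tiers
  ranked_kept <- ranked[keep, , drop = FALSE]
  kept_items <- attr(ranked, "items")[keep]
  attr(ranked_kept, "items") <- kept_items
  attr(ranked_kept, "n_samples") <- attr(ranked, "n_samples")
  structure(list(
    cohort_name = cohort$name,
    n_samples = length(cohort$samples),
    items = ranked_kept,
    panel_items = kept_items,
    total_kbps = sum(ranked_kept$length_bp) / 1000,
    coverage_k1 = coverage_k(kept_items, cohort, 1),
    coverage_k2 = coverage_k(kept_items, cohort, 2),
    coverage_k3 = coverage_k(kept_items, cohort, 3),
    representations = reps,
    params = list(hotspots = hotspots, L = L, min_fraction = min_fraction,
                  stringent = stringent, tier_threshold = tier_threshold,
                  keep_tiers = keep_tiers)),
    class = "PanelDesign")
}

#' @export
print.PanelDesign <- function(x, ...) {
  cat(sprintf("PanelDesign on '%s' (%d samples)\n", x$cohort_name,
              x$n_samples))
  cat(sprintf("  %d items (%d hotspot, %d whole-gene); tiers: %s\n",
              nrow(x$items), sum(x$items$kind == "hotspot"),
              sum(x$items$kind == "whole_gene"),
              paste(sprintf("T%d=%d", 1:3, tabulate(x$items$tier, 3)),
                    collapse = " ")))
  cat(sprintf("  coverage (k=1/2/3): %.3f / %.3f / %.3f; total %.2f Kbps\n",
              x$coverage_k1, x$coverage_k2, x$coverage_k3, x$total_kbps))
  invisible(x)
}

#' Export a panel design as a BED file
#'
#' One row per exon of each whole-gene item and one row per hotspot,
#' 0-based half-open, sorted by chromosome then start.  The name column is
#' `gene|tierN|hotspot_k` or `gene|tierN|whole_gene`.
#'
#' @param design a `PanelDesign`.
#' @param path output BED path.
#' @param flank_bp optional symmetric padding (bp) added to every written
#'   interval; affects the BED only, never the design's size accounting.
#' @return `path`, invisibly.
#' @export
write_bed <- function(design, path, flank_bp = 0) {
  stopifnot(inherits(design, "PanelDesign"))
  rows <- lapply(seq_len(nrow(design$items)), function(i) {
    it <- design$panel_items[[i]]
    gr <- it$intervals
    label <- if (it$kind == "hotspot") {
      sub("^.*:", "", it$item_id)   # hotspot_k
    } else "whole_gene"
    gr$name <- sprintf("%s|tier%d|%s", it$gene_id, design$items$tier[i],
                       label)
    gr
  })
  all <- concat_granges(rows)
  if (flank_bp > 0) {
    all <- GenomicRanges::resize(all, GenomicRanges::width(all) + 2 * flank_bp,
                                 fix = "center")
    all <- GenomicRanges::trim(all)
  }
  all <- sort_granges(all)
  write_atomic(path, function(tmp) rtracklayer::export(all, tmp,
                                                       format = "bed"))
  invisible(path)
}

#' Serialize the ranked panel table to TSV
#'
#' Columns: rank, item_id, gene, kind, tier, marginal_samples, cmf,
#' length_bp.
#'
#' @param design a `PanelDesign`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(design, path) {
  df <- data.frame(rank = design$items$rank,
                   item_id = design$items$item_id,
                   gene = design$items$gene_id,
                   kind = design$items$kind,
                   tier = design$items$tier,
                   marginal_samples = design$items$marginal_new_samples,
                   cmf = design$items$cmf,
                   length_bp = design$items$length_bp,
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
  invisible(path)
}

#' Panel design summary as a list (JSON-ready)
#'
#' @param design a `PanelDesign`.
#' @return list with cohort name, sample count, item/tier counts,
#'   coverage at k = 1, 2, 3 and total Kbps.
#' @export
design_summary <- function(design) {
  list(cohort = design$cohort_name,
       n_samples = design$n_samples,
       n_items = nrow(design$items),
       n_tier1 = sum(design$items$tier == 1L),
       n_tier2 = sum(design$items$tier == 2L),
       n_tier3 = sum(design$items$tier == 3L),
       coverage_k1 = design$coverage_k1,
       coverage_k2 = design$coverage_k2,
       coverage_k3 = design$coverage_k3,
       total_kbps = design$total_kbps)
}
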