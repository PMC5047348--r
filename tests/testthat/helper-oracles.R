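# Independent oracles (brute force / direct set computation) and fixture
# builders shared across the suite.  The oracles deliberately share no
# code with the implementation paths they check.

# Exhaustive best-window scan: every pair of mutated sites (i, j) with
# span <= L is a candidate; ties by (smaller span, smaller start).
bf_best_window <- function(pos, cnt, L) {
  o <- order(pos)
  pos <- pos[o]; cnt <- cnt[o]
  cs <- c(0, cumsum(cnt))
  best <- NULL
  for (i in seq_along(pos)) {
    for (j in i:length(pos)) {
      span <- pos[j] - pos[i] + 1
      if (span > L) break
      tot <- cs[j + 1] - cs[i]
      if (is.null(best) ||
          tot > best[1] ||
          (tot == best[1] && span < best[2]) ||
          (tot == best[1] && span == best[2] && pos[i] < best[3])) {
        best <- c(tot, span, pos[i], pos[j])
      }
    }
  }
  list(start = best[3], end = best[4], n_mutations = as.integer(best[1]))
}

# Independent greedy oracle over explicit covered-sample sets: recomputes
# every remaining item's marginal from scratch at each rank and applies
# the documented tie-break (larger total set, then lexicographic id).
bf_greedy_order <- function(sets) {
  ids <- names(sets)
  covered <- character()
  order_out <- character(); marg_out <- integer()
  remaining <- ids
  while (length(remaining)) {
    gains <- vapply(remaining, function(i) {
      length(setdiff(sets[[i]], covered))
    }, integer(1))
    tots <- vapply(remaining, function(i) length(sets[[i]]), integer(1))
    pick <- remaining[order(-gains, -tots, remaining)][1]
    order_out <- c(order_out, pick)
    marg_out <- c(marg_out, gains[[pick]])
    covered <- union(covered, sets[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  list(order = order_out, marginals = unname(marg_out))
}

# Direct union-based coverage of a family of sample sets.
bf_union_coverage <- function(sets, n_samples) {
  length(unique(unlist(sets))) / n_samples
}

# Brute-force marginal gain of each candidate set given already-covered
# samples; used to verify greedy dominance rank by rank.
bf_marginals <- function(sets, covered) {
  vapply(sets, function(s) length(setdiff(s, covered)), integer(1))
}

# Minimal cohort from a compact spec: list(sample = c(gene, ...)).
make_gene_cohort <- function(sample_genes, extra_samples = character(),
                             name = "toy") {
  rows <- do.call(rbind, lapply(names(sample_genes), function(s) {
    genes <- sample_genes[[s]]
    if (!length(genes)) return(NULL)
    data.frame(sample_id = s, gene_id = genes, stringsAsFactors = FALSE)
  }))
  gene_ids <- sort(unique(rows$gene_id))
  gpos <- setNames((seq_along(gene_ids)) * 10000L, gene_ids)
  mut <- data.frame(sample_id = rows$sample_id, gene_id = rows$gene_id,
                    chrom = "chrT", pos = gpos[rows$gene_id] +
                      match(rows$sample_id, unique(rows$sample_id)),
                    ref = "A", alt = "T", consequence = "missense",
                    stringsAsFactors = FALSE)
  new_cohort(mut, samples = extra_samples, name = name)
}

# Whole-gene models matching make_gene_cohort's synthetic layout.
make_gene_models <- function(gene_ids) {
  gene_ids <- sort(gene_ids)
  models <- lapply(seq_along(gene_ids), function(i) {
    start0 <- i * 10000L - 1L
    gene_model(gene_ids[i], "chrT", start0, start0 + 2000L)
  })
  setNames(models, gene_ids)
}

# PanelItem with an explicit covered-sample set and a dummy interval.
make_item <- function(id, covered, slot = 1L, len = 10L) {
  panel_item(item_id = id, gene_id = id, kind = "whole_gene",
             intervals = GenomicRanges::GRanges(
               "chrX", IRanges::IRanges(slot * 10000L, slot * 10000L + len - 1L)),
             covered_samples = covered)
}

# Cohort whose sample universe is given explicitly (for item-level tests).
make_sample_cohort <- function(samples, name = "samples-only") {
  mut <- data.frame(sample_id = samples[1], gene_id = "GX", chrom = "chrX",
                    pos = 1L, ref = "A", alt = "T",
                    consequence = "synonymous", stringsAsFactors = FALSE)
  new_cohort(mut, samples = samples, name = name)
}

# Random site-count instance for property tests.
random_sites <- function(n_sites, max_pos = 3000L, max_count = 5L) {
  pos <- sort(sample.int(max_pos, n_sites))
  data.frame(pos = pos, count = sample.int(max_count, n_sites,
                                           replace = TRUE))
}
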