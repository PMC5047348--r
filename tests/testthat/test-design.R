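# Greedy CMF ranking, tier assignment, k-mutation coverage and the
# end-to-end design pipeline.

test_that("greedy_rank reproduces the worked example and tie-breaks", {
  co <- make_sample_cohort(c("S1", "S2", "S3", "S4"))
  items <- list(make_item("A", c("S1", "S2", "S3"), 1),
                make_item("B", c("S3", "S4"), 2),
                make_item("C", "S1", 3))
  r <- greedy_rank(items, co)
  expect_equal(r$item_id, c("A", "B", "C"))
  expect_equal(r$marginal_new_samples, c(3L, 1L, 0L))
  expect_equal(r$cmf, c(0.75, 1.0, 1.0))

  # Single saturating item.
  r2 <- greedy_rank(list(make_item("Z", c("S1", "S2", "S3", "S4"))), co)
  expect_equal(r2$cmf, 1.0)

  # Identical coverage sets: first by id, second has zero marginal.
  r3 <- greedy_rank(list(make_item("B", c("S1", "S2"), 1),
                         make_item("A", c("S1", "S2"), 2)), co)
  expect_equal(r3$item_id, c("A", "B"))
  expect_equal(r3$marginal_new_samples, c(2L, 0L))

  expect_error(greedy_rank(list(), co), "no panel items")
})

test_that("greedy CMF is monotone and sums exactly to coverage", {
  set.seed(11)
  for (rep in 1:30) {
    samples <- sprintf("S%02d", 1:20)
    co <- make_sample_cohort(samples)
    n_items <- sample(2:10, 1)
    items <- lapply(seq_len(n_items), function(i) {
      make_item(sprintf("I%02d", i),
                sample(samples, sample.int(12, 1)), i)
    })
    r <- greedy_rank(items, co)
    expect_true(all(diff(r$cmf) >= 0))
    expect_true(all(r$cmf >= 0 & r$cmf <= 1))
    expect_true(all(diff(r$marginal_new_samples) <= 0))
    sets <- lapply(items, `[[`, "covered_samples")
    expect_identical(sum(r$marginal_new_samples) / 20,
                     bf_union_coverage(sets, 20))
    # Greedy dominance at every rank against brute-force marginals.
    covered <- character()
    ord <- attr(r, "items")
    for (k in seq_len(n_items)) {
      rem <- ord[k:n_items]
      gains <- bf_marginals(lapply(rem, `[[`, "covered_samples"), covered)
      expect_equal(r$marginal_new_samples[k], max(gains))
      covered <- union(covered, ord[[k]]$covered_samples)
    }
  }
})

test_that("assign_tiers splits by the expected per-rank gain", {
  # Gains [.40 .30 .05 .05 0]: s = mean positive gain = .20.
  co <- make_sample_cohort(sprintf("S%02d", 1:20))
  sets <- list(A = sprintf("S%02d", 1:8),      # 0.40
               B = sprintf("S%02d", 9:14),     # 0.30
               C = sprintf("S%02d", 15),       # 0.05
               D = sprintf("S%02d", 16),       # 0.05
               E = sprintf("S%02d", 1:3))      # 0 marginal
  items <- lapply(names(sets), function(i) {
    make_item(i, sets[[i]], match(i, names(sets)))
  })
  r <- greedy_rank(items, co)
  expect_equal(r$marginal_new_samples, c(8L, 6L, 1L, 1L, 0L))
  expect_equal(assign_tiers(r)$tier, c(1L, 1L, 2L, 2L, 3L))
  # Stringent doubles the threshold to 0.40.
  expect_equal(assign_tiers(r, stringent = TRUE)$tier,
               c(1L, 2L, 2L, 2L, 3L))
  # Explicit override wins.
  expect_equal(assign_tiers(r, threshold = 0.5)$tier,
               c(2L, 2L, 2L, 2L, 3L))

  # Uniform positive gains: everything is Tier 1.
  items_eq <- list(make_item("A", c("S01", "S02"), 1),
                   make_item("B", c("S03", "S04"), 2))
  expect_equal(assign_tiers(greedy_rank(items_eq, co))$tier, c(1L, 1L))

  # Fewer than two positive-gain items: degenerate fit, all Tier 1.
  items_one <- list(make_item("A", c("S01", "S02"), 1),
                    make_item("B", c("S01"), 2))
  expect_equal(assign_tiers(greedy_rank(items_one, co))$tier, c(1L, 3L))
})

test_that("stringent Tier 1 is a subset of default Tier 1", {
  set.seed(23)
  for (rep in 1:25) {
    samples <- sprintf("S%02d", 1:30)
    co <- make_sample_cohort(samples)
    items <- lapply(1:8, function(i) {
      make_item(sprintf("I%d", i), sample(samples, sample.int(15, 1)), i)
    })
    r <- greedy_rank(items, co)
    t_def <- assign_tiers(r)
    t_str <- assign_tiers(r, stringent = TRUE)
    expect_true(all(t_str$item_id[t_str$tier == 1L] %in%
                    t_def$item_id[t_def$tier == 1L]))
  }
})

test_that("coverage_k counts distinct items and is monotone in k", {
  co <- make_sample_cohort(c("S1", "S2", "S3", "S4"))
  items <- list(make_item("A", c("S1", "S2"), 1),
                make_item("B", c("S1", "S3"), 2),
                make_item("C", c("S1"), 3))
  expect_equal(coverage_k(items, co, 1), 3 / 4)
  expect_equal(coverage_k(items, co, 2), 1 / 4)   # only S1 hits >= 2 items
  expect_equal(coverage_k(items, co, 3), 1 / 4)
  expect_error(coverage_k(items, co, 0), "k must")

  # k = 1 equals the final greedy CMF.
  r <- greedy_rank(items, co)
  expect_identical(coverage_k(items, co, 1), r$cmf[nrow(r)])

  # No sample in >= 3 items once C is dropped.
  expect_equal(coverage_k(items[1:2], co, 3), 0)
})

test_that("design_panel composes the pipeline (whole-gene mode)", {
  co <- make_gene_cohort(list(S1 = c("A", "C"), S2 = "A", S3 = c("A", "B"),
                              S4 = "B"))
  models <- make_gene_models(c("A", "B", "C"))
  d <- design_panel(co, gene_list(c("A", "B", "C"), "driver"), models,
                    hotspots = FALSE)
  expect_equal(nrow(d$items), 3L)
  expect_true(all(d$items$kind == "whole_gene"))
  expect_equal(d$items$gene_id, c("A", "B", "C"))
  expect_equal(d$coverage_k1, 1.0)
  expect_equal(d$total_kbps, sum(d$items$length_bp) / 1000)
  expect_true(d$coverage_k3 <= d$coverage_k2,
              d$coverage_k2 <= d$coverage_k1)
})

test_that("design_panel uses hotspot items when hotspots capture enough", {
  pos <- c(rep(10100, 5), rep(10150, 3), rep(10900, 2))
  mut <- data.frame(sample_id = sprintf("S%02d", seq_along(pos)),
                    gene_id = "HG", chrom = "chrT", pos = pos,
                    ref = "A", alt = "T", consequence = "missense",
                    stringsAsFactors = FALSE)
  co <- new_cohort(mut)
  models <- list(HG = gene_model("HG", "chrT", 10000, 12000))
  d <- design_panel(co, gene_list("HG", "driver"), models)
  expect_equal(nrow(d$items), 2L)
  expect_true(all(d$items$kind == "hotspot"))
  expect_equal(sort(d$items$item_id), c("HG:hotspot_1", "HG:hotspot_2"))
  # Hotspot panel is far smaller than the whole gene at equal coverage.
  d_wg <- design_panel(co, gene_list("HG", "driver"), models,
                       hotspots = FALSE)
  expect_identical(d$coverage_k1, d_wg$coverage_k1)
  expect_lt(d$total_kbps, d_wg$total_kbps)
})

test_that("tier restriction keeps a prefix and Tier-3 removal is free", {
  co <- make_gene_cohort(list(S1 = c("A", "B"), S2 = "A", S3 = "A",
                              S4 = "B", S5 = "C"))
  models <- make_gene_models(c("A", "B", "C", "D"))
  full <- design_panel(co, gene_list(c("A", "B", "C"), "driver"), models,
                       hotspots = FALSE)
  no_t3 <- design_panel(co, gene_list(c("A", "B", "C"), "driver"), models,
                        hotspots = FALSE, keep_tiers = c(1L, 2L))
  expect_identical(no_t3$coverage_k1, full$coverage_k1)
  t1 <- design_panel(co, gene_list(c("A", "B", "C"), "driver"), models,
                     hotspots = FALSE, keep_tiers = 1L)
  expect_lte(t1$total_kbps, full$total_kbps)
  expect_true(all(t1$items$tier == 1L))
  lost <- sum(full$items$marginal_new_samples[full$items$tier != 1L])
  expect_equal(t1$coverage_k1, full$coverage_k1 - lost / full$n_samples)
})

test_that("design_panel fails informatively with no mutated listed gene", {
  co <- make_gene_cohort(list(S1 = "A"))
  models <- make_gene_models(c("A", "Z"))
  expect_error(design_panel(co, gene_list("Z", "driver"), models),
               "no listed gene")
  # All non-PAM mutations are equivalent to an unmutated cohort.
  mut <- co$mutations
  mut$consequence <- "synonymous"
  co2 <- new_cohort(mut)
  expect_error(design_panel(co2, gene_list("A", "driver"), models),
               "no listed gene")
})
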