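# Cohort, gene model and BED input/output.

write_simple_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_mutations <- function() {
  data.frame(
    sample = c("S1", "S2", "S3"),
    gene = c("TP53", "TP53", "KRAS"),
    chrom = c("chr17", "chr17", "chr12"),
    pos = c(7578406L, 7578406L, 25398284L),
    ref = c("C", "C", "C"),
    alt = c("T", "T", "A"),
    consequence = c("missense", "missense", "missense"),
    stringsAsFactors = FALSE)
}

test_that("read_mutation_table parses both dialects and skips bad rows", {
  p <- write_simple_tsv(toy_mutations())
  co <- read_mutation_table(p)
  expect_s3_class(co, "Cohort")
  expect_equal(nrow(co$mutations), 3L)
  expect_setequal(co$samples, c("S1", "S2", "S3"))
  expect_true(all(co$mutations$pam))

  maf <- toy_mutations()
  names(maf) <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                  "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification")
  maf$Variant_Classification <- c("Missense_Mutation", "Silent",
                                  "Frame_Shift_Del")
  co2 <- read_mutation_table(write_simple_tsv(maf), dialect = "maf")
  expect_equal(co2$mutations$pam[order(co2$mutations$sample_id)],
               c(TRUE, FALSE, TRUE))

  # A row with unparseable position is skipped with a warning.
  bad <- toy_mutations()
  bad$pos <- as.character(bad$pos)
  bad$pos[2] <- "NA"
  expect_warning(co3 <- read_mutation_table(write_simple_tsv(bad)),
                 "malformed")
  expect_equal(nrow(co3$mutations), 2L)

  # Missing required column is fatal and names the column.
  broken <- toy_mutations()[-4]
  expect_error(read_mutation_table(write_simple_tsv(broken),
                                   dialect = "simple_tsv"), "pos")
  # Empty file is fatal.
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(read_mutation_table(empty), "empty|parse")
})

test_that("cohort parsing is order-independent and deduplicates", {
  df <- toy_mutations()
  co1 <- read_mutation_table(write_simple_tsv(df))
  co2 <- read_mutation_table(write_simple_tsv(df[c(3, 1, 2), ]))
  expect_identical(co1$mutations, co2$mutations)
  expect_identical(co1$samples, co2$samples)

  # Identical (sample, gene, pos, alt) rows collapse to one.
  dup <- rbind(df, df[1, ])
  co3 <- new_cohort(setNames(dup, c("sample_id", "gene_id", "chrom", "pos",
                                    "ref", "alt", "consequence")))
  expect_equal(nrow(co3$mutations), 3L)
})

test_that("sample manifest keeps mutation-free samples in the denominator", {
  p <- write_simple_tsv(toy_mutations())
  manifest <- tempfile()
  writeLines(c("S1", "S2", "S3", "S4", "S5"), manifest)
  co <- read_mutation_table(p, samples = manifest)
  expect_equal(length(co$samples), 5L)
  # Coverage denominators include the silent samples.
  models <- list(
    TP53 = gene_model("TP53", "chr17", 7578000, 7579000),
    KRAS = gene_model("KRAS", "chr12", 25398000, 25399000))
  d <- design_panel(co, gene_list(c("TP53", "KRAS"), "driver"), models,
                    hotspots = FALSE)
  expect_equal(d$coverage_k1, 3 / 5)
})

test_that("classify_pam partitions the vocabulary and warns on unknowns", {
  expect_true(classify_pam("missense"))
  expect_false(classify_pam("synonymous"))
  expect_warning(v <- classify_pam("upstream_gene_variant"),
                 "unrecognized")
  expect_false(v)
  vocab <- c(PAM_CLASSES, panelforge:::NONPAM_CLASSES)
  flags <- classify_pam(vocab)
  expect_identical(vocab[flags], PAM_CLASSES)
  expect_identical(vocab[!flags], panelforge:::NONPAM_CLASSES)
  # Overriding the whitelist is honored.
  expect_false(classify_pam("missense", pam_classes = "nonsense"))
})

test_that("gene models merge exons and compute coding length", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tGENE1\t0\t+",
               "chr1\t200\t250\tGENE1\t0\t+",
               "chr2\t0\t100\tGENE2\t0\t-",
               "chr2\t50\t150\tGENE2\t0\t-"), bed)
  models <- read_gene_models(bed)
  expect_equal(models$GENE1$coding_length, 150)
  expect_equal(models$GENE2$coding_length, 150)   # overlapping rows merge
  expect_equal(length(models$GENE2$exons), 1L)
  expect_equal(models$GENE1$strand, "+")

  degenerate <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tGENE1", degenerate)
  expect_error(read_gene_models(degenerate), "end <= start|parse")
})

test_that("simulated gene models round-trip through BED", {
  models <- simulate_gene_models(20, seed = 7)
  bed <- tempfile(fileext = ".bed")
  write_gene_models(models, bed)
  back <- read_gene_models(bed)
  expect_setequal(names(back), names(models))
  for (g in names(models)) {
    expect_equal(back[[g]]$coding_length, models[[g]]$coding_length)
    expect_equal(GenomicRanges::start(back[[g]]$exons),
                 GenomicRanges::start(models[[g]]$exons))
    expect_equal(GenomicRanges::end(back[[g]]$exons),
                 GenomicRanges::end(models[[g]]$exons))
  }
})

test_that("simulated cohorts round-trip through the simple TSV dialect", {
  models <- simulate_gene_models(10, seed = 3)
  sim <- simulate_cohort(simulation_config(n_samples = 40, n_genes = 10,
                                           seed = 3), models)
  p <- tempfile(fileext = ".tsv")
  write_cohort(sim$cohort, p, force_manifest = TRUE)
  back <- read_mutation_table(p, samples = paste0(p, ".samples"),
                              name = sim$cohort$name)
  expect_identical(back$mutations, sim$cohort$mutations)
  expect_identical(back$samples, sim$cohort$samples)
})

test_that("write_bed uses 0-based half-open coordinates and round-trips", {
  co <- make_gene_cohort(list(S1 = "GA", S2 = "GA", S3 = "GA"))
  models <- make_gene_models("GA")
  d <- design_panel(co, gene_list("GA", "driver"), models)
  bed <- tempfile(fileext = ".bed")
  write_bed(d, bed)
  raw <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  gr <- d$panel_items[[1]]$intervals
  expect_equal(raw$V2[1], GenomicRanges::start(gr)[1] - 1L)  # 1-based -> 0-based
  expect_equal(raw$V3[1], GenomicRanges::end(gr)[1])
  expect_match(raw$V4, "^GA\\|tier[123]\\|")
  # Re-import reproduces the interval set bit-exactly.
  back <- read_panel_bed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  # Total written length matches the design's Kbps accounting.
  expect_equal(sum(raw$V3 - raw$V2) / 1000, d$total_kbps)
})

test_that("whole-gene designs expand to one BED row per exon", {
  co <- make_gene_cohort(list(S1 = "GB", S2 = "GB"))
  # Two PAMs at different positions -> no recurrent site -> whole exome.
  models <- list(GB = gene_model("GB", "chrT", c(9999, 12000),
                                 c(10500, 12400)))
  d <- design_panel(co, gene_list("GB", "driver"), models)
  expect_equal(d$items$kind, "whole_gene")
  bed <- tempfile(fileext = ".bed")
  write_bed(d, bed)
  raw <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(raw), 2L)
  expect_true(all(raw$V4 == raw$V4[1]))
})
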