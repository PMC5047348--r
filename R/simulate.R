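# Synthetic cohort generator with known ground truth: per-gene background
# mutation rates, implanted recurrent hotspots and a configurable fraction
# of non-protein-affecting mutations.  Everything is deterministic given
# the seed; draws are ordered by (gene, sample) so realizations do not
# depend on iteration order.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) pf_usage_error("a seed is mandatory for simulation")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Simulate gene exon models
#'
#' Lays `n_genes` non-overlapping genes (named `G001`, `G002`, ...) on
#' synthetic chromosomes (`chrS1`, `chrS2`, ...), each with a random
#' number of exons of random lengths separated by introns.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_len_range exon length range in bp.
#' @param intron_len_range intron length range in bp.
#' @param genes_per_chrom genes laid per synthetic chromosome.
#' @param gap_bp intergenic gap.
#' @param seed RNG seed (mandatory).
#' @return named list of [gene_model()] objects.
#' @export
simulate_gene_models <- function(n_genes, exons_per_gene = c(2, 8),
                                 exon_len_range = c(80, 300),
                                 intron_len_range = c(200, 2000),
                                 genes_per_chrom = 10, gap_bp = 10000,
                                 seed = 1) {
  stopifnot(n_genes >= 0, all(exons_per_gene >= 1),
            all(exon_len_range >= 1), all(intron_len_range >= 1))
  if (n_genes == 0L) return(setNames(list(), character(0)))
  with_seed(seed, {
    models <- vector("list", n_genes)
    cursor <- 1; chrom_i <- 1L
    for (g in seq_len(n_genes)) {
      if (g > 1 && (g - 1) %% genes_per_chrom == 0L) {
        chrom_i <- chrom_i + 1L
        cursor <- 1
      }
      n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
      ex_len <- sample(seq(exon_len_range[1], exon_len_range[2]), n_ex,
                       replace = TRUE)
      introns <- if (n_ex > 1) {
        sample(seq(intron_len_range[1], intron_len_range[2]), n_ex - 1,
               replace = TRUE)
      } else integer(0)
      starts0 <- cursor + cumsum(c(0, ex_len[-n_ex] + introns))
      ends0 <- starts0 + ex_len
      gene_id <- sprintf("G%03d", g)
      models[[g]] <- gene_model(gene_id, sprintf("chrS%d", chrom_i),
                                starts0, ends0,
                                strand = c("+", "-")[1 + (g %% 2)])
      cursor <- max(ends0) + gap_bp
    }
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
    models
  })
}

#' Simulation configuration
#'
#' Describes the synthetic tumor cohort: sample count, gene count, which
#' genes are drivers, per-driver carrier probability, implanted hotspot
#' geometry (width and the share of a carrier's driver mutations placed
#' inside it), per-gene-per-sample background mutation rate, and the
#' fraction of non-protein-affecting mutations.
#'
#' @param n_samples number of tumor samples.
#' @param n_genes number of genes (must not exceed the gene models
#'   supplied to [simulate_cohort()]).
#' @param n_drivers number of driver genes (the first `n_drivers` in gene
#'   order).
#' @param n_hotspot_drivers how many drivers carry an implanted hotspot
#'   (the first ones).
#' @param driver_mut_prob per-sample probability of carrying a mutation in
#'   each driver gene.
#' @param hotspot_width implanted hotspot window width in bp (<= L used
#'   downstream).
#' @param hotspot_share probability that a carrier's driver mutation falls
#'   inside the implanted window (rest uniform over exons).
#' @param background_rate per-gene per-sample probability of a background
#'   (passenger) mutation.
#' @param nonpam_fraction fraction of mutations marked with a
#'   non-protein-affecting consequence.
#' @param seed RNG seed (mandatory).
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_samples = 200, n_genes = 30, n_drivers = 8,
                              n_hotspot_drivers = 5, driver_mut_prob = 0.15,
                              hotspot_width = 50, hotspot_share = 0.9,
                              background_rate = 0.01, nonpam_fraction = 0.1,
                              seed = 1) {
  probs <- c(driver_mut_prob, hotspot_share, background_rate,
             nonpam_fraction)
  if (any(probs < 0 | probs > 1)) {
    pf_usage_error("probabilities must lie in [0, 1]")
  }
  stopifnot(n_samples >= 1, n_genes >= 1, n_drivers >= 0,
            n_hotspot_drivers <= n_drivers, hotspot_width >= 1)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_drivers = n_drivers,
                 n_hotspot_drivers = n_hotspot_drivers,
                 driver_mut_prob = driver_mut_prob,
                 hotspot_width = hotspot_width,
                 hotspot_share = hotspot_share,
                 background_rate = background_rate,
                 nonpam_fraction = nonpam_fraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Map positions in concatenated exon space (1..coding_length) to genomic
# coordinates.
exon_space_to_genomic <- function(model, u) {
  w <- GenomicRanges::width(model$exons)
  cw <- cumsum(w)
  ex <- findInterval(u, c(0, cw), left.open = TRUE)  # exon index per u
  offset <- u - c(0, cw)[ex]
  GenomicRanges::start(model$exons)[ex] + offset - 1
}

# Deterministic ref/alt pair from a position (no RNG draw needed).
ref_alt_at <- function(pos) {
  bases <- c("A", "C", "G", "T")
  r <- bases[(pos %% 4) + 1]
  a <- bases[((pos + 1) %% 4) + 1]
  list(ref = r, alt = a)
}

.PAM_SIM_CLASSES <- c("missense", "missense", "missense", "nonsense",
                      "frameshift_indel", "splice_site")
.NONPAM_SIM_CLASSES <- c("synonymous", "synonymous", "intron", "utr")

#' Simulate a tumor mutation cohort with implanted hotspots
#'
#' For each driver gene, carriers are drawn per sample with
#' `driver_mut_prob`; each carrier receives one driver mutation, placed
#' uniformly inside the implanted hotspot window with probability
#' `hotspot_share` and uniformly over the gene's exons otherwise.  Every
#' gene additionally receives background mutations per sample with
#' probability `background_rate`.  Each mutation is marked
#' non-protein-affecting with probability `nonpam_fraction`.  All draws
#' are ordered by (gene, sample) under a single seeded stream, so the
#' realization is reproducible byte-for-byte.
#'
#' @param config a [simulation_config()].
#' @param models named list of gene models covering at least
#'   `config$n_genes` genes (e.g. from [simulate_gene_models()]).
#' @return list with `cohort` (a `Cohort`; all samples retained in the
#'   denominator, mutated or not) and `truth` (class `GroundTruth`):
#'   `hotspot_windows` (data.frame gene/chrom/start/end), `driver_genes`,
#'   `genes`, `mutations` (realized per-mutation provenance: origin is
#'   `"hotspot"`, `"exome"` or `"background"`).
#' @export
simulate_cohort <- function(config, models) {
  stopifnot(inherits(config, "SimulationConfig"))
  gene_ids <- sort(names(models))
  if (length(gene_ids) < config$n_genes) {
    pf_usage_error("models do not cover n_genes genes")
  }
  gene_ids <- gene_ids[seq_len(config$n_genes)]
  drivers <- gene_ids[seq_len(config$n_drivers)]
  hs_drivers <- drivers[seq_len(config$n_hotspot_drivers)]
  samples <- sprintf("S%04d", seq_len(config$n_samples))

  with_seed(config$seed, {
    # Implant one hotspot window per hotspot driver, fully inside one exon
    # (so exon-space positions are always protein-plausible).
    windows <- lapply(hs_drivers, function(g) {
      m <- models[[g]]
      w <- GenomicRanges::width(m$exons)
      ok <- which(w >= config$hotspot_width)
      if (!length(ok)) pf_usage_error(sprintf(
        "hotspot window (%d bp) does not fit inside any exon of gene '%s'",
        config$hotspot_width, g))
      ex <- ok[sample.int(length(ok), 1)]
      lo <- GenomicRanges::start(m$exons)[ex]
      hi <- GenomicRanges::end(m$exons)[ex] - config$hotspot_width + 1
      st <- lo + sample.int(hi - lo + 1, 1) - 1
      data.frame(gene = g, chrom = m$chrom, start = st,
                 end = st + config$hotspot_width - 1,
                 stringsAsFactors = FALSE)
    })
    windows <- if (length(windows)) do.call(rbind, windows) else
      data.frame(gene = character(), chrom = character(),
                 start = numeric(), end = numeric())

    rows <- list()
    for (g in gene_ids) {
      m <- models[[g]]
      is_driver <- g %in% drivers
      win <- windows[windows$gene == g, , drop = FALSE]
      for (s in samples) {
        # Driver mutation.
        if (is_driver && runif(1) < config$driver_mut_prob) {
          in_hs <- nrow(win) == 1L && runif(1) < config$hotspot_share
          pos <- if (in_hs) {
            win$start + sample.int(config$hotspot_width, 1) - 1
          } else {
            exon_space_to_genomic(m, sample.int(m$coding_length, 1))
          }
          nonpam <- runif(1) < config$nonpam_fraction
          cons <- if (nonpam) {
            .NONPAM_SIM_CLASSES[(pos %% length(.NONPAM_SIM_CLASSES)) + 1]
          } else {
            .PAM_SIM_CLASSES[(pos %% length(.PAM_SIM_CLASSES)) + 1]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, gene = g, chrom = m$chrom, pos = pos,
            consequence = cons,
            origin = if (in_hs) "hotspot" else "exome",
            stringsAsFactors = FALSE)
        }
        # Background mutation.
        if (runif(1) < config$background_rate) {
          pos <- exon_space_to_genomic(m, sample.int(m$coding_length, 1))
          nonpam <- runif(1) < config$nonpam_fraction
          cons <- if (nonpam) {
            .NONPAM_SIM_CLASSES[(pos %% length(.NONPAM_SIM_CLASSES)) + 1]
          } else {
            .PAM_SIM_CLASSES[(pos %% length(.PAM_SIM_CLASSES)) + 1]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, gene = g, chrom = m$chrom, pos = pos,
            consequence = cons, origin = "background",
            stringsAsFactors = FALSE)
        }
      }
    }
    raw <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample = character(), gene = character(),
                 chrom = character(), pos = integer(),
                 consequence = character(), origin = character(),
                 stringsAsFactors = FALSE)
    ra <- ref_alt_at(raw$pos)
    mut <- data.frame(sample_id = raw$sample, gene_id = raw$gene,
                      chrom = raw$chrom, pos = raw$pos, ref = ra$ref,
                      alt = ra$alt, consequence = raw$consequence,
                      stringsAsFactors = FALSE)
    cohort <- new_cohort(mut, samples = samples, name = "simulated_cohort")
    truth <- structure(list(
      hotspot_windows = windows,
      driver_genes = drivers,
      genes = gene_ids,
      samples = samples,
      mutations = cbind(raw, pam = classify_pam(raw$consequence)),
      config = config),
      class = "GroundTruth")
    list(cohort = cohort, truth = truth)
  })
}

#' Ground-truth coverage by direct set computation
#'
#' Independently of the design pipeline, computes the fraction of samples
#' with protein-affecting mutations in at least `k` distinct genes of
#' `genes`, straight from the realized truth table.
#'
#' @param truth a `GroundTruth`.
#' @param genes gene subset (defaults to all simulated genes).
#' @param k minimum number of distinct mutated genes.
#' @return a fraction in \[0, 1\].
#' @export
truth_coverage <- function(truth, genes = truth$genes, k = 1) {
  m <- truth$mutations
  m <- m[m$pam & m$gene %in% genes, , drop = FALSE]
  per_sample <- tapply(m$gene, m$sample, function(g) length(unique(g)))
  sum(per_sample >= k) / length(truth$samples)
}

#' Write a simulation to disk in the formats the pipeline consumes
#'
#' Writes the MAF-like simple TSV cohort (plus sample manifest), the exon
#' BED, the driver gene list, and the ground truth as JSON.
#'
#' @param sim result of [simulate_cohort()].
#' @param models the gene models used.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             manifest = file.path(dir, "cohort.tsv.samples"),
             models = file.path(dir, "exons.bed"),
             genes = file.path(dir, "genes_driver.txt"),
             truth = file.path(dir, "truth.json"))
  write_cohort(sim$cohort, paths[["cohort"]], force_manifest = TRUE)
  write_gene_models(models, paths[["models"]])
  write_atomic(paths[["genes"]], function(tmp) {
    writeLines(sim$truth$driver_genes, tmp)
  })
  write_atomic(paths[["truth"]], function(tmp) {
    jsonlite::write_json(
      list(hotspot_windows = sim$truth$hotspot_windows,
           driver_genes = sim$truth$driver_genes,
           genes = sim$truth$genes,
           n_samples = length(sim$truth$samples),
           coverage_k1 = truth_coverage(sim$truth, sim$truth$genes, 1)),
      tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(paths)
}
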