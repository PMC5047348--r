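# Cost-effectiveness evaluation of panels (designed or external BED)
# against a cohort: coverage, k-mutation coverage, targeted Kbps.

#' Read an external panel from a BED file
#'
#' @param path BED file (0-based half-open).  The name column, when
#'   present, labels intervals; intervals sharing a label form one panel
#'   item for k-mutation coverage, and the gene id is taken as the part of
#'   the label before the first `|`.  Unnamed intervals each form their
#'   own item.
#' @return GRanges with a `label` metadata column.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) pf_data_error(sprintf("file not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) pf_data_error(
                   sprintf("cannot parse BED '%s': %s",
                           path, conditionMessage(e))))
  if (length(gr) == 0L) pf_data_error(sprintf("BED file '%s' is empty", path))
  lab <- gr$name
  if (is.null(lab) || anyNA(lab) || !all(nzchar(lab))) {
    lab <- sprintf("region_%d", seq_along(gr))
  }
  gr$label <- lab
  gr
}

# Gene id encoded in a panel label ("GENE|tier1|hotspot_2" -> "GENE").
label_gene <- function(label) sub("\\|.*$", "", label)

#' Evaluate a panel against a cohort
#'
#' A sample counts as covered when at least one of its protein-affecting
#' mutations falls inside any panel interval.  Panel size in Kbps is the
#' total length after merging overlapping intervals (DNA is sequenced
#' once).  k-mutation coverage counts distinct panel items (intervals
#' grouped by label) hit per sample.
#'
#' @param panel GRanges of panel intervals (e.g. from [read_panel_bed()]),
#'   optionally with a `label` or `name` metadata column, or a
#'   `PanelDesign`.
#' @param cohort a `Cohort`.
#' @param driver_catalog optional character vector of driver gene symbols;
#'   enables `driver_fraction` (fraction of panel genes in the catalog).
#' @param name panel name for reporting.
#' @return object of class `PanelEvaluation`: list with `panel_name`,
#'   `coverage`, `coverage_k2`, `coverage_k3`, `kbps`, `n_items`,
#'   `driver_fraction` (NA without a catalog).
#' @export
evaluate_panel <- function(panel, cohort, driver_catalog = NULL,
                           name = "panel") {
  if (inherits(panel, "PanelDesign")) {
    rows <- lapply(seq_len(nrow(panel$items)), function(i) {
      it <- panel$panel_items[[i]]
      gr <- it$intervals
      gr$label <- it$item_id
      gr
    })
    panel <- concat_granges(rows)
  }
  if (!inherits(panel, "GRanges") || length(panel) == 0L) {
    pf_usage_error("panel must be a non-empty GRanges or PanelDesign")
  }
  lab <- panel$label %||% panel$name %||% sprintf("region_%d",
                                                  seq_along(panel))
  n_s <- length(cohort$samples)
  if (n_s == 0L) pf_data_error("cohort has zero samples")
  mut <- cohort$mutations[cohort$mutations$pam, , drop = FALSE]
  kbps <- sum(GenomicRanges::width(GenomicRanges::reduce(
    panel, ignore.strand = TRUE))) / 1000
  if (nrow(mut)) {
    mgr <- GenomicRanges::GRanges(mut$chrom,
                                  IRanges::IRanges(mut$pos, mut$pos))
    ov <- GenomicRanges::findOverlaps(mgr, panel, ignore.strand = TRUE)
    pairs <- unique(data.frame(
      sample = mut$sample_id[S4Vectors::queryHits(ov)],
      item = lab[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE))
    hits <- table(pairs$sample)
  } else {
    hits <- table(character())
  }
  drv <- NA_real_
  if (!is.null(driver_catalog)) {
    genes <- unique(label_gene(lab))
    drv <- mean(genes %in% driver_catalog)
  }
  structure(list(panel_name = name,
                 coverage = sum(hits >= 1) / n_s,
                 coverage_k2 = sum(hits >= 2) / n_s,
                 coverage_k3 = sum(hits >= 3) / n_s,
                 kbps = kbps,
                 n_items = length(unique(lab)),
                 driver_fraction = drv),
            class = "PanelEvaluation")
}

#' @export
print.PanelEvaluation <- function(x, ...) {
  cat(sprintf("PanelEvaluation '%s': coverage %.3f (k2 %.3f, k3 %.3f), %.2f Kbps%s\n",
              x$panel_name, x$coverage, x$coverage_k2, x$coverage_k3,
              x$kbps,
              if (is.na(x$driver_fraction)) "" else
                sprintf(", driver fraction %.2f", x$driver_fraction)))
  invisible(x)
}

#' Compare multiple panels on one cohort
#'
#' Evaluates each panel and tabulates the results sorted by
#' cost-effectiveness (coverage per Kbps, descending).  The returned table
#' doubles as bubble-plot data (x = coverage, y = kbps,
#' size = driver_fraction).
#'
#' @param panels named list of panels (each a GRanges or `PanelDesign`).
#'   Names must be unique.
#' @param cohort a `Cohort`.
#' @param driver_catalog optional driver gene symbols.
#' @return data.frame with columns `panel`, `coverage`, `coverage_k2`,
#'   `coverage_k3`, `kbps`, `n_items`, `driver_fraction`,
#'   `coverage_per_kbp`.
#' @export
compare_panels <- function(panels, cohort, driver_catalog = NULL) {
  if (!length(panels)) pf_usage_error("at least one panel required")
  nm <- names(panels)
  if (is.null(nm) || any(!nzchar(nm))) {
    pf_usage_error("panels must be a named list")
  }
  if (anyDuplicated(nm)) pf_data_error("duplicate panel names")
  evs <- lapply(nm, function(p) {
    evaluate_panel(panels[[p]], cohort, driver_catalog = driver_catalog,
                   name = p)
  })
  out <- data.frame(
    panel = nm,
    coverage = vapply(evs, `[[`, numeric(1), "coverage"),
    coverage_k2 = vapply(evs, `[[`, numeric(1), "coverage_k2"),
    coverage_k3 = vapply(evs, `[[`, numeric(1), "coverage_k3"),
    kbps = vapply(evs, `[[`, numeric(1), "kbps"),
    n_items = vapply(evs, `[[`, numeric(1), "n_items"),
    driver_fraction = vapply(evs, `[[`, numeric(1), "driver_fraction"),
    stringsAsFactors = FALSE)
  out$coverage_per_kbp <- out$coverage / out$kbps
  out <- out[order(-out$coverage_per_kbp, out$panel), , drop = FALSE]
  rownames(out) <- NULL
  out
}
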