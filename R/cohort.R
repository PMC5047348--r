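#' Consequence classes counted as protein-affecting
#'
#' The default whitelist of normalized consequence classes treated as
#' protein-affecting mutations (PAMs): missense, nonsense (stop gain),
#' stop loss, start loss, splice site (donor/acceptor), frameshift and
#' inframe indels.  Synonymous, intronic, UTR, intergenic and unrecognized
#' classes are non-PAM.  Overridable in [classify_pam()] and
#' [design_panel()].
#'
#' @format Character vector of normalized consequence classes.
#' @export
PAM_CLASSES <- c("missense", "nonsense", "stop_loss", "start_lost",
                 "splice_site", "frameshift_indel", "inframe_indel")

NONPAM_CLASSES <- c("synonymous", "intron", "utr", "intergenic", "other")

# Normalization table: MAF Variant_Classification and common VEP/SO terms
# to the internal vocabulary.  Matching is case-insensitive.
.CONSEQUENCE_ALIASES <- c(
  missense              = "missense",
  missense_mutation     = "missense",
  missense_variant      = "missense",
  nonsense              = "nonsense",
  nonsense_mutation     = "nonsense",
  stop_gained           = "nonsense",
  stop_gain             = "nonsense",
  stop_loss             = "stop_loss",
  stop_lost             = "stop_loss",
  nonstop_mutation      = "stop_loss",
  start_lost            = "start_lost",
  start_loss            = "start_lost",
  translation_start_site = "start_lost",
  splice_site           = "splice_site",
  splice_donor_variant  = "splice_site",
  splice_acceptor_variant = "splice_site",
  frameshift_indel      = "frameshift_indel",
  frame_shift_del       = "frameshift_indel",
  frame_shift_ins       = "frameshift_indel",
  frameshift_variant    = "frameshift_indel",
  inframe_indel         = "inframe_indel",
  in_frame_del          = "inframe_indel",
  in_frame_ins          = "inframe_indel",
  inframe_deletion      = "inframe_indel",
  inframe_insertion     = "inframe_indel",
  synonymous            = "synonymous",
  silent                = "synonymous",
  synonymous_variant    = "synonymous",
  intron                = "intron",
  intron_variant        = "intron",
  utr                   = "utr",
  `3'utr`               = "utr",
  `5'utr`               = "utr",
  `3_prime_utr_variant` = "utr",
  `5_prime_utr_variant` = "utr",
  intergenic            = "intergenic",
  igr                   = "intergenic",
  intergenic_variant    = "intergenic",
  other                 = "other"
)

#' Normalize consequence strings to the internal vocabulary
#'
#' Maps MAF `Variant_Classification` values and common VEP/Sequence
#' Ontology terms onto the internal consequence classes.  Unrecognized
#' strings become `"other"` with a warning.
#'
#' @param x character vector of consequence strings.
#' @param warn warn once per unrecognized value (default `TRUE`).
#' @return character vector of normalized classes.
#' @export
normalize_consequence <- function(x, warn = TRUE) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.CONSEQUENCE_ALIASES[key])
  bad <- is.na(out) & !is.na(key) & nzchar(key)
  if (any(bad) && warn) {
    warning(sprintf("unrecognized consequence class(es) treated as 'other': %s",
                    paste(unique(key[bad]), collapse = ", ")),
            call. = FALSE)
  }
  out[is.na(out)] <- "other"
  out
}

#' Is a consequence class protein-affecting?
#'
#' Pure total predicate over the consequence vocabulary.  Input strings are
#' normalized first (see [normalize_consequence()]); unknown strings are
#' non-PAM and trigger a warning, never an error.
#'
#' @param consequence character vector of consequence classes (raw or
#'   normalized).
#' @param pam_classes whitelist of PAM classes; defaults to [PAM_CLASSES].
#' @return logical vector.
#' @examples
#' classify_pam(c("missense", "synonymous"))
#' @export
classify_pam <- function(consequence, pam_classes = PAM_CLASSES) {
  normalize_consequence(consequence) %in% pam_classes
}

#' Construct a mutation cohort
#'
#' A `Cohort` holds deduplicated somatic mutation records plus the sample
#' universe.  Samples with zero mutations (supplied via `samples`) are
#' retained: the CMF denominator is all samples in the cohort, not only
#' mutated ones.
#'
#' @param mutations data.frame with columns `sample_id`, `gene_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `consequence`; optional
#'   `protein_change`.
#' @param samples optional character vector of additional sample ids
#'   (a sample manifest); the cohort sample set is the union of these and
#'   the ids observed in `mutations`.
#' @param name cohort label.
#' @param pam_classes PAM whitelist passed to [classify_pam()].
#' @return an object of class `Cohort`: list with `name`, `samples`,
#'   `mutations` (with added logical column `pam` and normalized
#'   `consequence`).
#' @export
new_cohort <- function(mutations, samples = NULL, name = "cohort",
                       pam_classes = PAM_CLASSES) {
  required <- c("sample_id", "gene_id", "chrom", "pos", "ref", "alt",
                "consequence")
  missing_cols <- setdiff(required, names(mutations))
  if (length(missing_cols)) {
    pf_data_error(sprintf("mutation table lacks required column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  mut <- mutations[required]
  mut$protein_change <- if ("protein_change" %in% names(mutations)) {
    as.character(mutations$protein_change)
  } else rep(NA_character_, nrow(mut))
  mut$sample_id <- as.character(mut$sample_id)
  mut$gene_id <- as.character(mut$gene_id)
  mut$chrom <- as.character(mut$chrom)
  mut$pos <- as.integer(mut$pos)
  stopifnot(all(mut$pos >= 1L))
  mut$consequence <- normalize_consequence(mut$consequence)
  mut$pam <- mut$consequence %in% pam_classes
  # Deduplicate identical observations (same sample/gene/position/alt):
  # resequenced variants must not be double-counted.
  key <- paste(mut$sample_id, mut$gene_id, mut$chrom, mut$pos, mut$alt,
               sep = "\r")
  mut <- mut[!duplicated(key), , drop = FALSE]
  # Canonical row order makes the cohort independent of input row order.
  mut <- mut[order(mut$gene_id, mut$sample_id, mut$chrom, mut$pos, mut$alt), ,
             drop = FALSE]
  rownames(mut) <- NULL
  structure(
    list(name = as.character(name),
         samples = sort(unique(c(as.character(samples), mut$sample_id))),
         mutations = mut),
    class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d samples, %d mutations (%d PAMs) in %d genes\n",
              x$name, length(x$samples), nrow(x$mutations),
              sum(x$mutations$pam), length(unique(x$mutations$gene_id))))
  invisible(x)
}

# Column maps per dialect.
.MAF_COLS <- c(sample_id = "Tumor_Sample_Barcode", gene_id = "Hugo_Symbol",
               chrom = "Chromosome", pos = "Start_Position",
               ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
               consequence = "Variant_Classification")
.SIMPLE_COLS <- c(sample_id = "sample", gene_id = "gene", chrom = "chrom",
                  pos = "pos", ref = "ref", alt = "alt",
                  consequence = "consequence")

#' Read a somatic mutation cohort from a TSV file
#'
#' Supports two dialects: `"maf"` (MAF column names:
#' `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`) and
#' `"simple_tsv"` (`sample`, `gene`, `chrom`, `pos`, `ref`, `alt`,
#' `consequence`).  `"auto"` picks whichever header matches.  Coordinates
#' are 1-based inclusive (MAF convention).  Rows with unparseable or
#' non-positive positions, or empty sample/gene ids, are skipped with one
#' summary warning.
#'
#' @param path TSV file path.
#' @param dialect `"auto"`, `"maf"`, or `"simple_tsv"`.
#' @param samples optional sample manifest: character vector or path to a
#'   one-id-per-line file; manifest-only samples are kept with zero
#'   mutations.
#' @param name cohort label; defaults to the file base name.
#' @inheritParams new_cohort
#' @return a [new_cohort()] object.
#' @export
read_mutation_table <- function(path, dialect = c("auto", "maf", "simple_tsv"),
                                samples = NULL, name = NULL,
                                pam_classes = PAM_CLASSES) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pf_data_error(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      comment.char = "#", quote = ""),
    error = function(e) pf_data_error(sprintf("cannot parse '%s': %s",
                                              path, conditionMessage(e))))
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    pf_data_error(sprintf("empty mutation file: %s", path))
  }
  colmap <- switch(dialect,
    maf = .MAF_COLS,
    simple_tsv = .SIMPLE_COLS,
    auto = if (all(.MAF_COLS %in% names(raw))) .MAF_COLS
           else if (all(.SIMPLE_COLS %in% names(raw))) .SIMPLE_COLS
           else pf_data_error(sprintf(
             "header of '%s' matches neither the MAF nor the simple dialect",
             path)))
  absent <- setdiff(unname(colmap), names(raw))
  if (length(absent)) {
    pf_data_error(sprintf("missing required column(s) in '%s': %s",
                          path, paste(absent, collapse = ", ")))
  }
  df <- setNames(raw[unname(colmap)], names(colmap))
  if ("protein_change" %in% names(raw)) df$protein_change <- raw$protein_change
  pos <- suppressWarnings(as.integer(df$pos))
  ok <- !is.na(pos) & pos >= 1L & nzchar(trimws(df$sample_id)) &
    nzchar(trimws(df$gene_id))
  if (any(!ok)) {
    warning(sprintf("%d malformed row(s) skipped while reading '%s'",
                    sum(!ok), path), call. = FALSE)
  }
  df <- df[ok, , drop = FALSE]
  df$pos <- pos[ok]
  if (is.character(samples) && length(samples) == 1L && file.exists(samples)) {
    samples <- read_id_list(samples)
  }
  new_cohort(df, samples = samples,
             name = name %||% sub("\\.[^.]*$", "", basename(path)),
             pam_classes = pam_classes)
}

#' Read a one-identifier-per-line list file
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) pf_data_error(sprintf("file not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a categorized gene list
#'
#' @param path one-symbol-per-line text file.
#' @param category one of `"driver"`, `"biomarker"`, `"user"`.
#' @return object of class `GeneList`: list with `gene_ids` (character)
#'   and `category`.
#' @export
read_gene_list <- function(path, category = c("driver", "biomarker", "user")) {
  category <- match.arg(category)
  ids <- unique(read_id_list(path))
  if (!length(ids)) pf_data_error(sprintf("gene list '%s' is empty", path))
  gene_list(ids, category)
}

#' @rdname read_gene_list
#' @param gene_ids character vector of gene symbols.
#' @export
gene_list <- function(gene_ids, category = c("driver", "biomarker", "user")) {
  category <- match.arg(category)
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) pf_usage_error("gene list must be non-empty")
  structure(list(gene_ids = gene_ids, category = category),
            class = "GeneList")
}

#' Write a cohort back to the simple TSV dialect
#'
#' Row order is canonical (gene, sample, position), so identical cohorts
#' serialize byte-identically.  A sample manifest is written alongside when
#' the cohort contains mutation-free samples.
#'
#' @param cohort a `Cohort`.
#' @param path output TSV path.
#' @param manifest_path optional path for the sample manifest; defaults to
#'   `<path>.samples`.  Written only if needed, or if `force_manifest`.
#' @param force_manifest always write the manifest.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, manifest_path = NULL,
                         force_manifest = FALSE) {
  stopifnot(inherits(cohort, "Cohort"))
  df <- cohort$mutations
  out <- data.frame(sample = df$sample_id, gene = df$gene_id,
                    chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, consequence = df$consequence,
                    protein_change = df$protein_change,
                    stringsAsFactors = FALSE)
  write_tsv_atomic(out, path)
  extra <- setdiff(cohort$samples, df$sample_id)
  if (length(extra) || force_manifest) {
    mp <- manifest_path %||% paste0(path, ".samples")
    write_atomic(mp, function(tmp) writeLines(cohort$samples, tmp))
  }
  invisible(path)
}
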