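# Annotation of panel mutations and genes against user-supplied catalogs:
# validated oncogenic mutations, drug-response biomarkers, gene mode of
# action and clonality tendency.  Annotation is pure decoration: it never
# alters panel membership, ranks, tiers, coverage or Kbps.

read_catalog_tsv <- function(path, required, what) {
  if (!file.exists(path)) pf_data_error(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.delim(path, header = TRUE, sep = "\t",
                                   colClasses = "character",
                                   check.names = FALSE, quote = ""),
                 error = function(e) pf_data_error(
                   sprintf("cannot parse %s catalog '%s': %s", what, path,
                           conditionMessage(e))))
  absent <- setdiff(required, names(df))
  if (length(absent)) pf_data_error(
    sprintf("%s catalog '%s' lacks column(s): %s", what, path,
            paste(absent, collapse = ", ")))
  df
}

# Normalize an HGVS-p short form: strip a leading "p." and surrounding
# whitespace; matching is exact-string after that (no fuzzy matching).
normalize_protein_change <- function(x) {
  sub("^p\\.", "", trimws(as.character(x)))
}

validate_match_key <- function(df, path, what) {
  ok <- df$match_key %in% c("genomic_change", "protein_change")
  if (any(!ok)) {
    warning(sprintf("%d row(s) with unknown match_key skipped in %s '%s'",
                    sum(!ok), what, path), call. = FALSE)
  }
  df[ok, , drop = FALSE]
}

#' Read a validated-oncogenic-mutations catalog
#'
#' TSV schema: `gene`, `match_key` (`genomic_change` or `protein_change`),
#' `key` (e.g. `chr7:140453136:A>T` or `V600E`), `cancer_types`
#' (comma-separated, may be empty), `validated` (`TRUE`/`FALSE`).
#'
#' @param path TSV path.
#' @return data.frame of catalog entries.
#' @export
read_oncogenic_catalog <- function(path) {
  df <- read_catalog_tsv(path, c("gene", "match_key", "key"), "oncogenic")
  df <- validate_match_key(df, path, "oncogenic catalog")
  df$validated <- if ("validated" %in% names(df)) {
    toupper(df$validated) %in% c("TRUE", "T", "1", "YES")
  } else TRUE
  if (!"cancer_types" %in% names(df)) df$cancer_types <- ""
  df
}

#' Read a drug-biomarker catalog
#'
#' TSV schema: `gene`, `match_key`, `key`, `drug`, `effect` (`response`
#' or `resistance`), `cancer_types`.  Rows with an unknown effect are
#' skipped with a warning.
#'
#' @param path TSV path.
#' @return data.frame of catalog entries.
#' @export
read_biomarker_catalog <- function(path) {
  df <- read_catalog_tsv(path, c("gene", "match_key", "key", "drug",
                                 "effect"), "biomarker")
  df <- validate_match_key(df, path, "biomarker catalog")
  ok <- df$effect %in% c("response", "resistance")
  if (any(!ok)) {
    warning(sprintf("%d biomarker row(s) with unknown effect skipped in '%s'",
                    sum(!ok), path), call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  if (!"cancer_types" %in% names(df)) df$cancer_types <- ""
  df
}

#' Read a gene-level annotation catalog
#'
#' TSV schema: `gene`, `mode_of_action` (`loss_of_function`, `activation`
#' or `unknown`), optional `major_clone_cancer_types` (comma-separated
#' cancer types where the gene's mutations tend to occur in the major
#' clone).  On conflicting duplicate rows the first wins, with a warning.
#'
#' @param path TSV path.
#' @return data.frame of catalog entries (deduplicated by gene).
#' @export
read_gene_catalog <- function(path) {
  df <- read_catalog_tsv(path, c("gene", "mode_of_action"), "gene")
  bad <- !df$mode_of_action %in% c("loss_of_function", "activation",
                                   "unknown")
  if (any(bad)) {
    warning(sprintf("%d gene catalog row(s) with unknown mode_of_action set to 'unknown' in '%s'",
                    sum(bad), path), call. = FALSE)
    df$mode_of_action[bad] <- "unknown"
  }
  if (!"major_clone_cancer_types" %in% names(df)) {
    df$major_clone_cancer_types <- ""
  }
  if (anyDuplicated(df$gene)) {
    warning(sprintf("duplicate gene rows in '%s'; first occurrence wins",
                    path), call. = FALSE)
    df <- df[!duplicated(df$gene), , drop = FALSE]
  }
  df
}

# Match keys of a mutation table against one catalog; returns, per
# mutation row, the integer indices of matching catalog rows.
catalog_matches <- function(mut, catalog) {
  gkey <- sprintf("%s:%d:%s>%s", mut$chrom, mut$pos, mut$ref, mut$alt)
  pkey <- ifelse(is.na(mut$protein_change), NA_character_,
                 paste0(mut$gene_id, "/",
                        normalize_protein_change(mut$protein_change)))
  ckey <- ifelse(catalog$match_key == "genomic_change",
                 catalog$key,
                 paste0(catalog$gene, "/",
                        normalize_protein_change(catalog$key)))
  is_gen <- catalog$match_key == "genomic_change"
  lapply(seq_len(nrow(mut)), function(i) {
    which((is_gen & ckey == gkey[i]) |
          (!is_gen & !is.na(pkey[i]) & ckey == pkey[i]))
  })
}

#' Annotate cohort mutations with oncogenic and biomarker catalogs
#'
#' Every mutation is retained; unmatched mutations simply get empty
#' annotation.  Biomarker hits are reported as a semicolon-separated,
#' deterministically sorted `drug(effect)` list, so the result is
#' invariant to catalog row order.
#'
#' @param cohort a `Cohort`.
#' @param oncogenic optional oncogenic catalog data.frame
#'   ([read_oncogenic_catalog()]).
#' @param biomarkers optional biomarker catalog data.frame
#'   ([read_biomarker_catalog()]).
#' @return data.frame: the cohort mutation table plus `oncogenic`
#'   (logical), `n_biomarker_hits` (integer) and `biomarker_hits`
#'   (character).
#' @export
annotate_mutations <- function(cohort, oncogenic = NULL, biomarkers = NULL) {
  mut <- cohort$mutations
  out <- mut
  out$oncogenic <- FALSE
  out$n_biomarker_hits <- 0L
  out$biomarker_hits <- ""
  if (!nrow(mut)) return(out)
  if (!is.null(oncogenic) && nrow(oncogenic)) {
    m <- catalog_matches(mut, oncogenic)
    out$oncogenic <- vapply(m, function(ix) {
      any(oncogenic$validated[ix])
    }, logical(1))
  }
  if (!is.null(biomarkers) && nrow(biomarkers)) {
    m <- catalog_matches(mut, biomarkers)
    hits <- lapply(m, function(ix) {
      if (!length(ix)) return(character())
      sort(unique(sprintf("%s(%s)", biomarkers$drug[ix],
                          biomarkers$effect[ix])))
    })
    out$n_biomarker_hits <- lengths(hits)
    out$biomarker_hits <- vapply(hits, paste, character(1), collapse = ";")
  }
  out
}

#' Annotate a gene set with mode of action and clonality
#'
#' Total map: genes absent from the catalog get
#' `mode_of_action = "unknown"` and no major-clone cancer types.
#'
#' @param genes character vector of gene symbols.
#' @param gene_catalog optional catalog data.frame
#'   ([read_gene_catalog()]).
#' @return data.frame with columns `gene`, `mode_of_action`,
#'   `major_clone_cancer_types`, one row per input gene.
#' @export
annotate_genes <- function(genes, gene_catalog = NULL) {
  genes <- as.character(genes)
  out <- data.frame(gene = genes,
                    mode_of_action = "unknown",
                    major_clone_cancer_types = "",
                    stringsAsFactors = FALSE)
  if (!is.null(gene_catalog) && nrow(gene_catalog)) {
    ix <- match(genes, gene_catalog$gene)
    hit <- !is.na(ix)
    out$mode_of_action[hit] <- gene_catalog$mode_of_action[ix[hit]]
    out$major_clone_cancer_types[hit] <-
      gene_catalog$major_clone_cancer_types[ix[hit]]
  }
  out
}
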