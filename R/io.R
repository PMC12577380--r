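# Readers and writers for the tab-separated tables and FASTA files the
# pipeline consumes. All tables are UTF-8 TSV with a header row; abundance
# tables carry sample ids in the first column and one column per ASV.
# Validation is strict: malformed input raises a typed condition rather than
# being silently coerced.

#' Read an ASV count table
#'
#' Reads a samples-by-ASVs table of non-negative integer read counts. The
#' first column must be named `sample_id`; every remaining column is one ASV.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `sample_id` followed by one integer column per ASV.
#'   Row and column order are preserved.
#' @export
read_count_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) >= 1) names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  check_wide_table(tbl, "count table", integer_counts = TRUE)
  tbl
}

#' Write an ASV count table
#' @param counts Count table tibble as returned by [read_count_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  check_wide_table(counts, "count table", integer_counts = TRUE)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Write a relative or absolute abundance table
#' @param tbl Wide abundance tibble (`sample_id` first).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tbl, path) {
  check_wide_table(tbl, "abundance table")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a relative or absolute abundance table
#' @param path Path to a TSV file written by [write_abundance_table()].
#' @return Wide abundance tibble.
#' @export
read_abundance_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) >= 1) names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  check_wide_table(tbl, "abundance table")
  tbl
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `experiment_id`, `treatment_group`,
#' `supplements` (semicolon-separated labels, may be empty),
#' `oxygen_status` (`oxic`/`anoxic`), `time_days`, `replicate_id`, `well_id`.
#' `treatment_group` must come from the closed vocabulary of
#' [treatment_groups()]. `InSitu` samples may leave `time_days` empty; the
#' groundwater was pumped several days before the incubations were set up,
#' so in-situ samples are placed at a configurable negative offset relative
#' to the incubation start at time zero.
#'
#' @param path Path to a TSV file.
#' @param insitu_time_days Time (days) imputed for `InSitu` rows with a
#'   missing `time_days`; default -4.
#' @param supplement_vocab Known supplement labels; unknown labels warn but
#'   are retained.
#' @return A tibble with one row per sample; `supplements` is a list-column
#'   of character vectors.
#' @export
read_metadata <- function(path, insitu_time_days = -4,
                          supplement_vocab = supplement_vocabulary()) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("sample_id", "experiment_id", "treatment_group", "supplements",
                "oxygen_status", "time_days", "replicate_id", "well_id")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop_format(paste0("metadata: missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  tbl$time_days <- suppressWarnings(as.numeric(tbl$time_days))
  validate_metadata(tbl, insitu_time_days = insitu_time_days,
                    supplement_vocab = supplement_vocab)
}

# Shared validation for metadata whether read from disk or simulated.
validate_metadata <- function(tbl, insitu_time_days = -4,
                              supplement_vocab = supplement_vocabulary()) {
  if (anyDuplicated(tbl$sample_id)) {
    dup <- unique(tbl$sample_id[duplicated(tbl$sample_id)])
    stop_format(paste0("metadata: duplicate sample id(s): ",
                       paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$treatment_group), treatment_groups())
  if (length(bad)) {
    stop_vocab(paste0("metadata: unknown treatment group(s): ",
                      paste(bad, collapse = ", "),
                      "; allowed: ", paste(treatment_groups(), collapse = ", ")))
  }
  insitu <- tbl$treatment_group == "InSitu"
  tbl$time_days[insitu & is.na(tbl$time_days)] <- insitu_time_days
  if (any(is.na(tbl$time_days))) {
    bad_ids <- tbl$sample_id[is.na(tbl$time_days)]
    stop_format(paste0("metadata: missing time_days for non-InSitu sample(s): ",
                       paste(bad_ids, collapse = ", ")))
  }
  if (any(tbl$time_days[!insitu] < 0)) {
    stop_format("metadata: negative time_days for non-InSitu sample")
  }
  bad_oxy <- setdiff(unique(tbl$oxygen_status), c("oxic", "anoxic"))
  if (length(bad_oxy)) {
    stop_vocab(paste0("metadata: oxygen_status must be oxic/anoxic, got: ",
                      paste(bad_oxy, collapse = ", ")))
  }
  if (!is.list(tbl$supplements)) {
    supp <- stringr::str_split(dplyr::coalesce(tbl$supplements, ""), ";")
    supp <- lapply(supp, function(x) tolower(trimws(x[nzchar(trimws(x))])))
    tbl$supplements <- supp
  }
  unknown <- setdiff(unique(unlist(tbl$supplements)), supplement_vocab)
  if (length(unknown)) {
    warn(paste0("metadata: unknown supplement label(s) kept: ",
                paste(unknown, collapse = ", ")),
         class = "cprenrich_vocabulary_warning")
  }
  as_tibble(tbl)
}

#' Write sample metadata
#' @param meta Metadata tibble (list-column `supplements` is flattened to a
#'   semicolon-separated string).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  if (is.list(out$supplements)) {
    out$supplements <- vapply(out$supplements, paste, "", collapse = ";")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' One row per ASV with SILVA-style rank columns. Missing ranks may be empty
#' strings; a missing `class` is normalised to `"unclassified"` so the CPR
#' flag is always defined.
#'
#' @param path Path to a TSV with columns `asv_id`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus` (ranks after `class` optional).
#' @param cpr_classes Class labels treated as CPR when deriving `is_cpr`.
#' @return Tibble with the rank columns plus logical `is_cpr`.
#' @export
read_taxonomy <- function(path, cpr_classes = cpr_default_classes()) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!"asv_id" %in% names(tbl)) names(tbl)[1] <- "asv_id"
  required <- c("asv_id", "domain", "phylum", "class", "order")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop_format(paste0("taxonomy: missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$asv_id)) {
    dup <- unique(tbl$asv_id[duplicated(tbl$asv_id)])
    stop_format(paste0("taxonomy: duplicate ASV id(s): ",
                       paste(dup, collapse = ", ")))
  }
  for (col in c("family", "genus")) if (!col %in% names(tbl)) tbl[[col]] <- ""
  add_cpr_flag(as_tibble(tbl), cpr_classes)
}

#' Derive the CPR flag from taxonomic class membership
#'
#' `is_cpr` is a pure function of the `class` column and the configured CPR
#' class list; empty or missing classes become `"unclassified"` and are never
#' CPR.
#'
#' @param taxonomy Taxonomy tibble with a `class` column.
#' @param cpr_classes Character vector of CPR class labels.
#' @return The taxonomy tibble with a (re)computed logical `is_cpr` column.
#' @export
add_cpr_flag <- function(taxonomy, cpr_classes = cpr_default_classes()) {
  cls <- taxonomy$class
  cls[is.na(cls) | !nzchar(cls)] <- "unclassified"
  taxonomy$class <- cls
  taxonomy$is_cpr <- cls %in% cpr_classes
  taxonomy
}

#' Write a taxonomy table
#' @param taxonomy Taxonomy tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, progress = FALSE)
  invisible(path)
}

#' Read total 16S qPCR copy numbers
#'
#' @param path TSV with columns `sample_id` and `copies_per_liter`.
#' @return Tibble with positive `copies_per_liter` per sample.
#' @export
read_qpcr <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "copies_per_liter") %in% names(tbl))) {
    stop_format("qPCR table: need columns sample_id, copies_per_liter")
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) {
    stop_format("qPCR table: duplicate sample id(s)")
  }
  if (anyNA(tbl$copies_per_liter) || any(tbl$copies_per_liter <= 0)) {
    stop_format("qPCR table: copies_per_liter must be positive")
  }
  as_tibble(tbl[, c("sample_id", "copies_per_liter")])
}

#' Write a qPCR totals table
#' @param qpcr qPCR tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr <- function(qpcr, path) {
  readr::write_tsv(qpcr, path, progress = FALSE)
  invisible(path)
}

#' Read an EC reaction classification table
#'
#' Maps Enzyme Commission numbers onto the oxygen-dependence partition of a
#' metabolic reaction network: `oxic` (requires molecular oxygen or an
#' oxygen-derived metabolite), `anoxic` (strictly oxygen-free), `augmented`
#' (anaerobic reactions replaced by aerobic alternatives). Partial EC numbers
#' (such as `1.4.3.-`) are retained verbatim and later matched only against
#' identical partial keys.
#'
#' @param path TSV with columns `ec` and `category`.
#' @return Tibble `ec`, `category`.
#' @export
read_reaction_classes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("ec", "category") %in% names(tbl))) {
    stop_format("reaction class table: need columns ec, category")
  }
  tbl$ec <- normalize_ec(tbl$ec)
  bad <- !is_valid_ec(tbl$ec)
  if (any(bad)) {
    stop_format(paste0("reaction class table: malformed EC string(s): ",
                       paste(unique(tbl$ec[bad]), collapse = ", ")))
  }
  if (anyDuplicated(tbl$ec)) {
    stop_format("reaction class table: duplicate EC key(s)")
  }
  bad_cat <- setdiff(unique(tbl$category), c("oxic", "anoxic", "augmented"))
  if (length(bad_cat)) {
    stop_vocab(paste0("reaction class table: unknown category: ",
                      paste(bad_cat, collapse = ", ")))
  }
  as_tibble(tbl[, c("ec", "category")])
}

# Strip "EC:"/"ec:" prefixes and surrounding whitespace.
normalize_ec <- function(x) {
  x <- trimws(x)
  sub("^[Ee][Cc]:\\s*", "", x)
}

# Four dot-separated fields; trailing fields may be "-" (partial EC) or an
# "n"-prefixed preliminary serial number.
is_valid_ec <- function(x) {
  grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|n[0-9]+|-)$", x)
}

#' Read gene-to-EC annotations for a set of genomes
#'
#' One row per gene, DRAM-style: `mag_id`, `gene_id`, `ec` (zero, one or
#' several EC numbers separated by `ec_delim`), optional `ko` and
#' `function_label`. EC strings are normalised (whitespace stripped, `EC:`
#' prefix removed); a malformed EC raises a warning and is dropped from that
#' gene while the gene itself is kept.
#'
#' @param path TSV path.
#' @param ec_delim Delimiter between multiple EC numbers in one cell.
#' @return Tibble with one row per gene; `ec` is a list-column of character
#'   vectors (possibly empty).
#' @export
read_annotations <- function(path, ec_delim = ";") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("mag_id", "gene_id", "ec") %in% names(tbl))) {
    stop_format("annotations: need columns mag_id, gene_id, ec")
  }
  dup <- tbl |>
    dplyr::count(.data$mag_id, .data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop_format(paste0("annotations: duplicate gene id(s) within MAG: ",
                       paste(dup$gene_id, collapse = ", ")))
  }
  ecs <- stringr::str_split(dplyr::coalesce(tbl$ec, ""), stringr::fixed(ec_delim))
  ecs <- lapply(ecs, function(x) {
    x <- normalize_ec(x[nzchar(trimws(x))])
    bad <- !is_valid_ec(x)
    if (any(bad)) {
      warn(paste0("annotations: dropping malformed EC string(s): ",
                  paste(x[bad], collapse = ", ")),
           class = "cprenrich_format_warning")
    }
    x[!bad]
  })
  tbl$ec <- ecs
  if (!"ko" %in% names(tbl)) tbl$ko <- NA_character_
  if (!"function_label" %in% names(tbl)) tbl$function_label <- NA_character_
  as_tibble(tbl[, c("mag_id", "gene_id", "ec", "ko", "function_label")])
}

#' Write a gene annotation table
#' @param annotations Annotation tibble with list-column `ec`.
#' @param path Output TSV path.
#' @param ec_delim Delimiter joining multiple ECs.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, ec_delim = ";") {
  out <- annotations
  if (is.list(out$ec)) {
    out$ec <- vapply(out$ec, paste, "", collapse = ec_delim)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-genome quality and taxonomy
#'
#' @param path TSV with columns `mag_id`, `taxon_class`, `completeness`
#'   (percent), `contamination` (percent).
#' @return Validated tibble.
#' @export
read_mag_info <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("mag_id", "taxon_class", "completeness", "contamination")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop_format(paste0("MAG info: missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$mag_id)) stop_format("MAG info: duplicate mag_id")
  if (any(tbl$completeness < 0 | tbl$completeness > 100)) {
    stop_format("MAG info: completeness must be within [0, 100]")
  }
  if (any(tbl$contamination < 0)) {
    stop_format("MAG info: contamination must be >= 0")
  }
  as_tibble(tbl[, required])
}

#' Read reference sequences with a class label per sequence
#'
#' Loads a FASTA file of 16S reference sequences and joins the taxonomy
#' table on sequence id. Every sequence must have a class assignment.
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param taxonomy_path TSV taxonomy keyed by the FASTA ids (first token of
#'   each header), read with [read_taxonomy()].
#' @param cpr_classes Passed to [read_taxonomy()].
#' @return Tibble `seq_id`, `sequence`, plus taxonomy columns.
#' @export
read_fasta_with_taxonomy <- function(fasta_path, taxonomy_path,
                                     cpr_classes = cpr_default_classes()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1)
  db <- tibble(seq_id = ids, sequence = unname(as.character(seqs)))
  tax <- read_taxonomy(taxonomy_path, cpr_classes = cpr_classes)
  tax <- rename(tax, seq_id = "asv_id")
  missing <- setdiff(db$seq_id, tax$seq_id)
  if (length(missing)) {
    stop_format(paste0("reference DB: sequences without taxonomy: ",
                       paste(head(missing, 5), collapse = ", ")))
  }
  left_join(db, tax, by = "seq_id")
}

#' Write sequences to FASTA
#' @param db Tibble with `seq_id` and `sequence` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(setNames(db$sequence, db$seq_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
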