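# Normalization of ASV counts: total sum scaling to relative abundances,
# qPCR anchoring to absolute 16S gene copies per liter, and per-ASV fold
# enrichment versus the incubation start.

#' Total sum scaling
#'
#' Converts raw read counts to relative abundances by dividing each sample's
#' counts by that sample's total. Samples with zero total reads stay all-zero
#' and are reported via a warning rather than producing `NaN`.
#'
#' @param counts Wide count tibble (`sample_id` first, one column per ASV).
#' @return Wide tibble of the same shape with entries in `[0, 1]`; every row
#'   with nonzero source counts sums to 1.
#' @export
#' @examples
#' counts <- tibble::tibble(sample_id = "S1", asv1 = 3L, asv2 = 1L)
#' total_sum_scale(counts)
total_sum_scale <- function(counts) {
  check_wide_table(counts, "count table", integer_counts = TRUE)
  m <- wide_to_matrix(counts)
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warn(paste0("total_sum_scale: sample(s) with zero total counts kept ",
                "all-zero: ", paste(rownames(m)[zero], collapse = ", ")),
         class = "cprenrich_zero_row_warning")
  }
  scale <- ifelse(zero, 0, 1 / totals)
  matrix_to_wide(m * scale)
}

#' Anchor relative abundances to qPCR totals
#'
#' Estimates the absolute abundance of each ASV as its relative abundance
#' multiplied by the sample's total bacterial 16S rRNA gene copy number per
#' liter from quantitative PCR.
#'
#' @param rel Wide relative-abundance tibble from [total_sum_scale()].
#' @param qpcr Tibble `sample_id`, `copies_per_liter` ([read_qpcr()]).
#' @return Wide tibble of estimated 16S gene copies per liter; each row sums
#'   to the sample's qPCR total (up to floating-point rounding).
#' @export
absolute_abundance <- function(rel, qpcr) {
  check_wide_table(rel, "relative abundance table")
  missing <- setdiff(rel$sample_id, qpcr$sample_id)
  if (length(missing)) {
    stop_input(paste0("absolute_abundance: no qPCR total for sample(s): ",
                      paste(missing, collapse = ", ")))
  }
  totals <- qpcr$copies_per_liter[match(rel$sample_id, qpcr$sample_id)]
  m <- wide_to_matrix(rel)
  matrix_to_wide(m * totals)
}

#' Maximum fold enrichment versus the incubation start
#'
#' For each ASV within each experiment, the baseline is the mean absolute
#' abundance across the experiment's Start replicates (time zero). Each later
#' time point is averaged across replicates, and the maximum ratio to the
#' baseline is reported. Only ASVs that increased (fold > 1) are retained;
#' ASVs with a zero baseline have no defined fold and are dropped with a
#' warning. In-situ samples (negative time) never enter the computation.
#'
#' @param abs_tbl Wide absolute-abundance tibble.
#' @param meta Metadata tibble ([read_metadata()]).
#' @return Tibble `asv_id`, `experiment_id`, `baseline`, `max_abundance`,
#'   `time_of_max`, `fold_enrichment`, sorted by decreasing fold.
#' @export
fold_enrichment <- function(abs_tbl, meta) {
  check_wide_table(abs_tbl, "absolute abundance table")
  long <- tidyr::pivot_longer(abs_tbl, -"sample_id",
                              names_to = "asv_id", values_to = "abundance")
  long <- inner_join(long,
                     select(meta, "sample_id", "experiment_id",
                            "treatment_group", "time_days"),
                     by = "sample_id")
  long <- filter(long, .data$time_days >= 0)

  no_start <- long |>
    group_by(.data$experiment_id) |>
    summarise(has_start = any(.data$time_days == 0), .groups = "drop") |>
    filter(!.data$has_start)
  if (nrow(no_start)) {
    stop_input(paste0("fold_enrichment: experiment(s) without a Start ",
                      "(time 0) sample: ",
                      paste(no_start$experiment_id, collapse = ", ")))
  }

  by_time <- long |>
    group_by(.data$experiment_id, .data$asv_id, .data$time_days) |>
    summarise(abundance = mean(.data$abundance), .groups = "drop")

  baseline <- by_time |>
    filter(.data$time_days == 0) |>
    select("experiment_id", "asv_id", baseline = "abundance")

  later <- by_time |>
    filter(.data$time_days > 0) |>
    left_join(baseline, by = c("experiment_id", "asv_id"))

  zero_base <- later |>
    filter(.data$baseline == 0, .data$abundance > 0) |>
    distinct(.data$experiment_id, .data$asv_id)
  if (nrow(zero_base)) {
    warn(paste0("fold_enrichment: ", nrow(zero_base),
                " (ASV, experiment) pair(s) excluded: zero Start baseline"),
         class = "cprenrich_zero_baseline_warning")
  }

  later |>
    filter(.data$baseline > 0) |>
    group_by(.data$experiment_id, .data$asv_id, .data$baseline) |>
    summarise(max_abundance = max(.data$abundance),
              time_of_max = .data$time_days[which.max(.data$abundance)],
              .groups = "drop") |>
    mutate(fold_enrichment = .data$max_abundance / .data$baseline) |>
    filter(.data$fold_enrichment > 1) |>
    select("asv_id", "experiment_id", "baseline", "max_abundance",
           "time_of_max", "fold_enrichment") |>
    arrange(dplyr::desc(.data$fold_enrichment))
}

#' Plot the fold-enrichment distribution per taxonomic group
#'
#' Box plots of maximum fold enrichment (log scale), grouped at the given
#' taxonomic rank, CPR facetted from non-CPR.
#'
#' @param enrichment Tibble from [fold_enrichment()].
#' @param taxonomy Taxonomy tibble with `is_cpr`.
#' @param rank Rank column used for grouping (default `"class"`).
#' @return A ggplot object.
#' @export
plot_fold_enrichment <- function(enrichment, taxonomy, rank = "class") {
  df <- inner_join(enrichment, taxonomy, by = "asv_id") |>
    mutate(group = ifelse(.data$is_cpr, "CPR", "non-CPR"))
  ggplot(df, aes(x = .data[[rank]], y = .data$fold_enrichment)) +
    geom_boxplot(outlier.size = 0.6) +
    scale_y_log10() +
    facet_wrap(~group, scales = "free_x") +
    coord_flip() +
    labs(x = NULL, y = "maximum fold enrichment vs. start") +
    theme_bw()
}
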