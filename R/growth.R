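# Exponential growth-rate estimation per ASV. The model is
# N_i(t) = N_i(0) * exp(k t); ordinary least squares of ln(absolute
# abundance) on incubation time yields the rate k as the slope, and the
# doubling time follows as T_d = ln(2) / k for positive rates. Because a
# single slope is fitted over the whole incubation, the estimates are
# conservative: an organism that grew fast early and stalled later gets a
# rate below its true peak.

#' Fit per-ASV exponential growth rates
#'
#' For every (ASV, experiment) pair, regresses the natural logarithm of the
#' absolute abundance on incubation time using only observations where the
#' ASV occurred (abundance > 0). A fit is produced only when the ASV occurs
#' at at least `min_time_points` distinct time values; replicates at the same
#' time all enter the regression but count once toward that threshold.
#' In-situ samples (negative time) are excluded.
#'
#' @param abs_tbl Wide absolute-abundance tibble (copies per liter).
#' @param meta Metadata tibble; `experiment_id`, `time_days`,
#'   `treatment_group` and `replicate_id` are used.
#' @param min_time_points Minimum number of distinct occupied time points
#'   (default 3).
#' @param per_replicate If `TRUE`, fit each replicate separately instead of
#'   pooling replicates of an experiment.
#' @return A `growth_fit` tibble with one row per fitted pair: `asv_id`,
#'   `experiment_id` (suffixed with the replicate in per-replicate mode),
#'   `k` (per day), `ln_n0`, `n_points`, `n_time_points`, `r_squared`, and
#'   `doubling_time_days` (`NA` for non-positive rates).
#' @export
#' @examples
#' abs_tbl <- tibble::tibble(
#'   sample_id = c("a", "b", "c"),
#'   asv1 = 1e6 * exp(0.5 * c(0, 1, 2))
#' )
#' meta <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), experiment_id = "E1",
#'   treatment_group = c("Start", "Auto", "Auto"),
#'   time_days = c(0, 1, 2), replicate_id = "r1"
#' )
#' fit_growth_rates(abs_tbl, meta)
fit_growth_rates <- function(abs_tbl, meta, min_time_points = 3,
                             per_replicate = FALSE) {
  check_wide_table(abs_tbl, "absolute abundance table")
  long <- tidyr::pivot_longer(abs_tbl, -"sample_id",
                              names_to = "asv_id", values_to = "abundance")
  long <- inner_join(long,
                     select(meta, "sample_id", "experiment_id",
                            "time_days", "replicate_id"),
                     by = "sample_id")
  long <- filter(long, .data$time_days >= 0, .data$abundance > 0)
  if (per_replicate) {
    long$experiment_id <- paste(long$experiment_id, long$replicate_id,
                                sep = "/")
  }
  eligible <- long |>
    group_by(.data$asv_id, .data$experiment_id) |>
    summarise(n_tp = dplyr::n_distinct(.data$time_days), .groups = "drop") |>
    filter(.data$n_tp >= min_time_points)
  fits <- long |>
    semi_join(eligible, by = c("asv_id", "experiment_id")) |>
    group_by(.data$asv_id, .data$experiment_id) |>
    summarise(fit = list(ols_loglinear(.data$time_days, .data$abundance)),
              .groups = "drop") |>
    tidyr::unnest_wider("fit")
  if (nrow(fits)) {
    fits$doubling_time_days <- doubling_time(fits$k)
  } else {
    fits <- tibble(asv_id = character(), experiment_id = character(),
                   k = double(), ln_n0 = double(), n_points = integer(),
                   n_time_points = integer(), r_squared = double(),
                   doubling_time_days = double())
  }
  structure(fits, class = c("growth_fit", class(tibble())))
}

# OLS of ln(y) on t; slope k, intercept ln_n0, r^2 (1 for a perfectly
# collinear fit, NA when time has no spread after filtering).
ols_loglinear <- function(t, y) {
  if (length(t) == 0) {
    # type probe on an empty group: no fit
    return(list(k = NA_real_, ln_n0 = NA_real_, n_points = 0L,
                n_time_points = 0L, r_squared = NA_real_))
  }
  ly <- log(y)
  fit <- lm(ly ~ t)
  cf <- coef(fit)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  list(k = unname(cf[2]), ln_n0 = unname(cf[1]),
       n_points = length(t),
       n_time_points = length(unique(t)),
       r_squared = r2)
}

#' Doubling time from an exponential growth rate
#'
#' `T_d = ln(2) / k` for positive rates; negative or zero rates describe
#' decline or stasis and have no doubling time (`NA`). Vectorised.
#'
#' @param k Growth rate(s), per day.
#' @return Doubling time(s) in days, `NA` where `k <= 0`.
#' @export
#' @examples
#' doubling_time(log(2))   # 1 day
#' doubling_time(-0.1)     # NA: declining
doubling_time <- function(k) {
  stopifnot(is.numeric(k))
  ifelse(is.finite(k) & k > 0, log(2) / k, NA_real_)
}

#' Summarise growth estimates per taxonomic group
#'
#' Keeps only positive growth rates (declining fits carry no doubling time)
#' and summarises doubling times and rates per group at the requested rank,
#' split into CPR and non-CPR. Groups without any positive-rate estimate are
#' omitted with a message.
#'
#' @param estimates `growth_fit` tibble from [fit_growth_rates()].
#' @param taxonomy Taxonomy tibble with `is_cpr` and the rank column.
#' @param rank Taxonomic rank to group by (default `"class"`).
#' @return Tibble with one row per (CPR status, group): `n`, median, Q1, Q3,
#'   min and max of `doubling_time_days`, and the median rate `k_median`.
#' @export
summarize_growth <- function(estimates, taxonomy, rank = "class") {
  if (!rank %in% names(taxonomy)) {
    stop_input(paste0("summarize_growth: rank column '", rank,
                      "' not in taxonomy"))
  }
  df <- inner_join(as_tibble(estimates), taxonomy, by = "asv_id")
  dropped <- df |>
    group_by(.data$is_cpr, group = .data[[rank]]) |>
    summarise(any_pos = any(.data$k > 0), .groups = "drop") |>
    filter(!.data$any_pos)
  if (nrow(dropped)) {
    inform(paste0("summarize_growth: group(s) without positive growth ",
                  "omitted: ", paste(dropped$group, collapse = ", ")))
  }
  df |>
    filter(.data$k > 0) |>
    group_by(cpr = ifelse(.data$is_cpr, "CPR", "non-CPR"),
             group = .data[[rank]]) |>
    summarise(
      n = n(),
      td_median = median(.data$doubling_time_days),
      td_q1 = unname(quantile(.data$doubling_time_days, 0.25)),
      td_q3 = unname(quantile(.data$doubling_time_days, 0.75)),
      td_min = min(.data$doubling_time_days),
      td_max = max(.data$doubling_time_days),
      k_median = median(.data$k),
      .groups = "drop"
    )
}

#' @export
tidy.growth_fit <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.growth_fit <- function(x, ...) {
  pos <- x$k > 0
  tibble(
    n_fits = nrow(x),
    n_positive = sum(pos),
    k_median = if (any(pos)) median(x$k[pos]) else NA_real_,
    td_median = if (any(pos)) median(x$doubling_time_days[pos]) else NA_real_,
    r_squared_median = if (nrow(x)) median(x$r_squared) else NA_real_
  )
}

#' Box plots of doubling times per taxonomic group
#'
#' Mirrors the standard presentation for enrichment growth screens: doubling
#' times of positively growing ASVs, grouped by rank, CPR facetted from
#' non-CPR.
#'
#' @param object `growth_fit` tibble.
#' @param taxonomy Taxonomy tibble with `is_cpr`.
#' @param rank Rank column for grouping.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_fit <- function(object, taxonomy, rank = "class", ...) {
  df <- inner_join(as_tibble(object), taxonomy, by = "asv_id") |>
    filter(.data$k > 0) |>
    mutate(group = ifelse(.data$is_cpr, "CPR", "non-CPR"))
  ggplot(df, aes(x = .data[[rank]], y = .data$doubling_time_days)) +
    geom_boxplot(outlier.size = 0.6) +
    scale_y_log10() +
    facet_wrap(~group, scales = "free_x") +
    coord_flip() +
    labs(x = NULL, y = "doubling time [days]") +
    theme_bw()
}
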