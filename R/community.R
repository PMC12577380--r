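# Community-level statistics: Shannon diversity of the CPR sub-community,
# rank-correlation screening of ASV abundances against supplements and
# oxygen status, and generic rank-based group comparisons with Dunn's
# post-hoc test.

#' Shannon diversity of the CPR sub-community
#'
#' Restricts each sample to its CPR ASVs, renormalizes that sub-composition
#' to sum to one and computes the Shannon index H = -sum(p * ln p) with the
#' natural logarithm (via [vegan::diversity()]). Samples without any CPR
#' abundance have no defined CPR diversity and are omitted with a message.
#'
#' @param rel Wide relative-abundance tibble.
#' @param taxonomy Taxonomy tibble with `is_cpr`.
#' @return Tibble `sample_id`, `n_cpr_asvs` (ASVs with nonzero abundance),
#'   `shannon`.
#' @export
#' @examples
#' rel <- tibble::tibble(sample_id = "S1", a = 0.3, b = 0.3, c = 0.4)
#' tax <- tibble::tibble(asv_id = c("a", "b", "c"),
#'                       class = c("Parcubacteria", "ABY1", "Bacteroidia"))
#' tax <- add_cpr_flag(tax)
#' shannon_cpr(rel, tax)  # ln(2): two equally abundant CPR ASVs
shannon_cpr <- function(rel, taxonomy) {
  check_wide_table(rel, "relative abundance table")
  cpr_ids <- taxonomy$asv_id[taxonomy$is_cpr]
  missing <- setdiff(names(rel)[-1], taxonomy$asv_id)
  if (length(missing)) {
    stop_input(paste0("shannon_cpr: ASV(s) missing from taxonomy: ",
                      paste(head(missing, 5), collapse = ", ")))
  }
  keep <- intersect(names(rel)[-1], cpr_ids)
  m <- wide_to_matrix(rel)[, keep, drop = FALSE]
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    inform(paste0("shannon_cpr: sample(s) without CPR abundance omitted: ",
                  paste(rownames(m)[zero], collapse = ", ")))
  }
  m <- m[!zero, , drop = FALSE]
  if (!nrow(m)) {
    return(tibble(sample_id = character(), n_cpr_asvs = integer(),
                  shannon = double()))
  }
  # diversity() normalises rows internally, so H is computed on the
  # renormalized CPR sub-composition
  h <- vegan::diversity(m, index = "shannon")
  tibble(sample_id = rownames(m),
         n_cpr_asvs = as.integer(rowSums(m > 0)),
         shannon = unname(h))
}

#' Spearman screen of ASV abundances against incubation parameters
#'
#' For every (ASV, parameter) pair, computes the Spearman rank correlation
#' between the parameter's presence/absence indicator and the ASV's relative
#' abundance across samples. Parameters are all supplement labels occurring
#' in the metadata plus `oxic` (the oxygen status coded as a separate binary
#' indicator). Because these correlations run on compositional data, a
#' stringent raw-p cutoff is used instead of multiple-testing correction.
#' Parameters constant across the tested samples are skipped with a message.
#'
#' @param rel Wide relative-abundance tibble.
#' @param meta Metadata tibble with list-column `supplements` and
#'   `oxygen_status`.
#' @param alpha Significance cutoff on the raw two-sided p (default 0.001).
#' @param asv_ids Optional subset of ASVs to test (e.g. CPR ASVs only);
#'   default all columns of `rel`.
#' @return Tibble `asv_id`, `parameter`, `rho`, `p_value`, `significant`,
#'   `direction`.
#' @export
supplement_association <- function(rel, meta, alpha = 0.001,
                                   asv_ids = NULL) {
  check_wide_table(rel, "relative abundance table")
  meta <- meta[match(rel$sample_id, meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop_input("supplement_association: metadata missing for some samples")
  }
  labels <- sort(unique(unlist(meta$supplements)))
  indicators <- lapply(labels, function(s) {
    as.numeric(vapply(meta$supplements, function(x) s %in% x, logical(1)))
  })
  names(indicators) <- labels
  indicators$oxic <- as.numeric(meta$oxygen_status == "oxic")

  keep <- vapply(indicators, function(v) var(v) > 0, logical(1))
  if (any(!keep)) {
    inform(paste0("supplement_association: constant parameter(s) skipped: ",
                  paste(names(indicators)[!keep], collapse = ", ")))
  }
  indicators <- indicators[keep]
  if (!length(indicators)) {
    return(tibble(asv_id = character(), parameter = character(),
                  rho = double(), p_value = double(),
                  significant = logical(), direction = character()))
  }
  if (is.null(asv_ids)) asv_ids <- names(rel)[-1]
  m <- wide_to_matrix(rel)[, asv_ids, drop = FALSE]

  out <- purrr::map_dfr(names(indicators), function(par) {
    ind <- indicators[[par]]
    purrr::map_dfr(asv_ids, function(asv) {
      ct <- suppressWarnings(
        cor.test(ind, m[, asv], method = "spearman", exact = FALSE)
      )
      tibble(asv_id = asv, parameter = par,
             rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
  out |>
    mutate(rho = ifelse(is.na(.data$rho), 0, .data$rho),
           p_value = ifelse(is.na(.data$p_value), 1, .data$p_value),
           significant = .data$p_value < alpha,
           direction = ifelse(.data$rho >= 0, "positive", "negative"))
}

#' Merge externally computed differential-abundance results
#'
#' Accepts a table from an external differential-abundance method (such as a
#' bias-corrected compositional model) with columns `asv_id`, `parameter`,
#' `log2_fold_change`, `p_adjusted`, applies the adjusted-p significance
#' rule, and binds it to a Spearman association report under a `method`
#' column.
#'
#' @param associations Tibble from [supplement_association()].
#' @param diffabund_path TSV with columns `asv_id`, `parameter`,
#'   `log2_fold_change`, `p_adjusted`.
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @return Tibble with columns `asv_id`, `parameter`, `method`, `effect`
#'   (rho or log2 fold change), `p_value`, `significant`, `direction`.
#' @export
ingest_differential_abundance <- function(associations, diffabund_path,
                                          alpha = 0.05) {
  ext <- readr::read_tsv(diffabund_path, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("asv_id", "parameter", "log2_fold_change", "p_adjusted")
  missing <- setdiff(required, names(ext))
  if (length(missing)) {
    stop_format(paste0("differential abundance table: missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  spearman <- associations |>
    mutate(method = "spearman", effect = .data$rho) |>
    select("asv_id", "parameter", "method", "effect", "p_value",
           "significant", "direction")
  external <- ext |>
    mutate(method = "external_da",
           effect = .data$log2_fold_change,
           p_value = .data$p_adjusted,
           significant = .data$p_adjusted < alpha,
           direction = ifelse(.data$log2_fold_change >= 0, "positive",
                              "negative")) |>
    select("asv_id", "parameter", "method", "effect", "p_value",
           "significant", "direction")
  bind_rows(spearman, external)
}

#' Rank-based comparison of groups
#'
#' Kruskal-Wallis omnibus test across groups, optionally followed by Dunn's
#' pairwise post-hoc z tests with the chosen multiple-testing correction.
#' Groups with fewer than 2 observations are excluded with a message.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param post_hoc Run Dunn's pairwise tests (default `TRUE`).
#' @param correction `"bonferroni"` or `"none"`.
#' @return A `group_difference` object: list with `omnibus` (tibble:
#'   `statistic`, `df`, `p_value`, `n`, `n_groups`) and `pairwise` (tibble
#'   from Dunn's test, or `NULL`).
#' @export
#' @examples
#' group_difference(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
group_difference <- function(values, groups, post_hoc = TRUE,
                             correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(values) == length(groups))
  g <- as.character(groups)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    inform(paste0("group_difference: group(s) with n < 2 excluded: ",
                  paste(small, collapse = ", ")))
    keep <- !g %in% small
    values <- values[keep]
    g <- g[keep]
  }
  if (length(unique(g)) < 2) {
    stop_input("group_difference: need at least 2 groups with n >= 2")
  }
  gf <- factor(g)
  kw <- kruskal.test(values, gf)
  omnibus <- tibble(statistic = unname(kw$statistic),
                    df = unname(kw$parameter),
                    p_value = kw$p.value,
                    n = length(values),
                    n_groups = nlevels(gf))
  pairwise <- if (post_hoc) {
    dunn_posthoc(values, gf, correction = correction)
  } else {
    NULL
  }
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "group_difference")
}

# Dunn (1964) post-hoc z tests on the joint ranks, with the usual tie
# correction; p values are two-sided normal tail probabilities, optionally
# Bonferroni-multiplied by the number of pairwise comparisons.
dunn_posthoc <- function(values, groups, correction = "bonferroni") {
  gf <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, gf, mean)
  sizes <- tapply(r, gf, length)
  levs <- levels(gf)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  res <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- if (se == 0) 0 else (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble(group1 = a, group2 = b, z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- if (correction == "bonferroni") {
    pmin(res$p_value * m, 1)
  } else {
    res$p_value
  }
  res
}

#' @export
print.group_difference <- function(x, ...) {
  cat("Kruskal-Wallis rank sum test\n")
  print(x$omnibus)
  if (!is.null(x$pairwise)) {
    cat("Dunn post-hoc:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @export
tidy.group_difference <- function(x, ...) {
  if (is.null(x$pairwise)) x$omnibus else x$pairwise
}

#' @export
glance.group_difference <- function(x, ...) {
  x$omnibus
}

#' Heat-map style view of significant supplement associations
#'
#' Tiles of Spearman rho for (ASV, parameter) pairs passing the significance
#' cutoff, green-to-red by sign as is conventional for association screens.
#'
#' @param associations Tibble from [supplement_association()].
#' @return A ggplot object.
#' @export
plot_associations <- function(associations) {
  sig <- filter(associations, .data$significant)
  ggplot(sig, aes(x = .data$asv_id, y = .data$parameter,
                  fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "firebrick", mid = "white",
                         high = "darkgreen", limits = c(-1, 1)) +
    labs(x = "ASV", y = NULL, fill = "Spearman rho") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
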