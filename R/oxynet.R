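# Oxygen-related metabolic profiling of genome annotations. Each MAG's gene
# annotations are reduced to a deduplicated set of single-EC assignments,
# mapped onto a reaction classification that partitions enzymatic reactions
# by oxygen dependence (oxic / anoxic / augmented), and screened for enzymes
# that use molecular oxygen directly. Functional enrichment between CPR
# groups uses rank tests on per-MAG presence/absence.

#' Filter genomes by assembly quality
#'
#' Keeps MAGs with completeness at or above `min_completeness` percent and
#' contamination at or below `max_contamination` percent (inclusive
#' thresholds on both sides).
#'
#' @param mags MAG info tibble ([read_mag_info()]).
#' @param min_completeness Minimum completeness, percent (default 50).
#' @param max_contamination Maximum contamination, percent (default 10).
#' @return Filtered tibble.
#' @export
#' @examples
#' mags <- tibble::tibble(mag_id = c("m1", "m2"), taxon_class = "x",
#'                        completeness = c(50, 49.9), contamination = c(10, 2))
#' filter_mags(mags)  # keeps only m1
filter_mags <- function(mags, min_completeness = 50, max_contamination = 10) {
  filter(mags, .data$completeness >= min_completeness,
         .data$contamination <= max_contamination)
}

#' Deduplicated single-EC sets per genome
#'
#' Genes annotated with exactly one EC number contribute that EC; genes
#' carrying more than one EC describe ambiguous or multifunctional products
#' and are excluded entirely; genes without an EC are ignored. Each EC is
#' counted once per MAG regardless of how many genes carry it.
#'
#' @param annotations Gene annotation tibble with list-column `ec`
#'   ([read_annotations()]).
#' @return Tibble `mag_id`, `ec`, one row per distinct (MAG, EC).
#' @export
extract_ec_sets <- function(annotations) {
  n_ec <- lengths(annotations$ec)
  single <- annotations[n_ec == 1, c("mag_id", "ec")]
  if (!nrow(single)) return(tibble(mag_id = character(), ec = character()))
  single$ec <- unlist(single$ec)
  distinct(as_tibble(single))
}

#' Classify per-MAG EC sets by oxygen dependence
#'
#' Counts, per MAG, how many of its distinct ECs fall into each category of
#' the reaction classification; ECs absent from the table are tallied as
#' unclassified. Partial EC keys (e.g. `1.4.3.-`) match only identical
#' partial strings.
#'
#' @param ec_sets Tibble `mag_id`, `ec` from [extract_ec_sets()].
#' @param reaction_classes Tibble `ec`, `category`
#'   ([read_reaction_classes()]).
#' @param mag_ids Optional character vector of MAGs that must appear in the
#'   output even with zero counts (e.g. genomes without single-EC genes).
#' @return Tibble `mag_id`, `n_oxic`, `n_anoxic`, `n_augmented`,
#'   `n_unclassified`.
#' @export
classify_reactions <- function(ec_sets, reaction_classes, mag_ids = NULL) {
  cat <- reaction_classes$category[match(ec_sets$ec, reaction_classes$ec)]
  cat[is.na(cat)] <- "unclassified"
  counts <- ec_sets |>
    mutate(category = cat) |>
    dplyr::count(.data$mag_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (col in c("oxic", "anoxic", "augmented", "unclassified")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  all_ids <- union(if (is.null(mag_ids)) character() else mag_ids,
                   counts$mag_id)
  out <- tibble(mag_id = all_ids) |>
    left_join(counts, by = "mag_id") |>
    mutate(across(all_of(c("oxic", "anoxic", "augmented", "unclassified")),
                  ~ dplyr::coalesce(.x, 0L)))
  select(out, "mag_id", n_oxic = "oxic", n_anoxic = "anoxic",
         n_augmented = "augmented", n_unclassified = "unclassified")
}

#' Catalog of enzymes that use oxygen directly
#'
#' Oxygenases and oxidases whose reactions consume molecular oxygen, with
#' their standard-nomenclature EC assignments. Override or extend by passing
#' your own tibble of the same shape wherever a catalog is accepted.
#'
#' @return Tibble `enzyme_label`, `ec`.
#' @export
oxygen_enzyme_catalog <- function() {
  tibble(
    enzyme_label = c(
      "l-aspartate oxidase",
      "kynurenine 3-monooxygenase",
      "pyridoxamine 5'-phosphate oxidase",
      "catechol 2,3-dioxygenase",
      "4-hydroxyphenylpyruvate dioxygenase",
      "d-amino-acid oxidase"
    ),
    ec = c("1.4.3.16", "1.14.13.9", "1.4.3.5",
           "1.13.11.2", "1.13.11.27", "1.4.3.3")
  )
}

#' Flag oxygen-utilizing enzymes in per-MAG EC sets
#'
#' @param ec_sets Tibble `mag_id`, `ec` from [extract_ec_sets()].
#' @param catalog Tibble `enzyme_label`, `ec`
#'   (default [oxygen_enzyme_catalog()]).
#' @return Tibble `mag_id`, `enzyme_label`, `ec`, one row per hit.
#' @export
flag_oxygen_enzymes <- function(ec_sets, catalog = oxygen_enzyme_catalog()) {
  if (anyDuplicated(catalog$enzyme_label)) {
    stop_input("flag_oxygen_enzymes: duplicate enzyme labels in catalog")
  }
  inner_join(ec_sets, catalog, by = "ec") |>
    select("mag_id", "enzyme_label", "ec") |>
    arrange(.data$mag_id, .data$enzyme_label)
}

#' Full oxygen-metabolism profile per genome
#'
#' Convenience wrapper: quality-filters the MAGs, extracts deduplicated
#' single-EC sets, classifies them by oxygen dependence and screens for
#' oxygen-utilizing enzymes.
#'
#' @param mags MAG info tibble.
#' @param annotations Gene annotation tibble.
#' @param reaction_classes Reaction classification tibble.
#' @param catalog Oxygen-enzyme catalog.
#' @param min_completeness,max_contamination Passed to [filter_mags()].
#' @return List with `profiles` (one row per retained MAG, with
#'   `taxon_class`, category counts and `n_oxygen_enzymes`) and `enzyme_hits`
#'   (per-hit rows from [flag_oxygen_enzymes()]).
#' @export
mag_oxy_profiles <- function(mags, annotations, reaction_classes,
                             catalog = oxygen_enzyme_catalog(),
                             min_completeness = 50, max_contamination = 10) {
  kept <- filter_mags(mags, min_completeness, max_contamination)
  ann <- filter(annotations, .data$mag_id %in% kept$mag_id)
  ec_sets <- extract_ec_sets(ann)
  profiles <- classify_reactions(ec_sets, reaction_classes,
                                 mag_ids = kept$mag_id)
  hits <- flag_oxygen_enzymes(ec_sets, catalog)
  hit_counts <- dplyr::count(hits, .data$mag_id, name = "n_oxygen_enzymes")
  profiles <- kept |>
    select("mag_id", "taxon_class") |>
    left_join(profiles, by = "mag_id") |>
    left_join(hit_counts, by = "mag_id") |>
    mutate(n_oxygen_enzymes = dplyr::coalesce(.data$n_oxygen_enzymes, 0L))
  list(profiles = profiles, enzyme_hits = hits)
}

#' Compare function prevalence between CPR groups
#'
#' Tests, per function, whether its presence frequency differs between each
#' focal class and all other genomes combined: a Kruskal-Wallis omnibus test
#' on the 0/1 presence values across the groups (each focal class plus
#' `"other"`), followed by Dunn's pairwise post-hoc test with Bonferroni
#' correction. A function is selected for a focal class when its adjusted
#' focal-vs-other p value falls below `alpha`.
#'
#' @param presence Tibble `mag_id`, `function_label`: one row per (MAG,
#'   function) where the function is present. Functions may be KEGG
#'   Orthology ids or free labels.
#' @param mags MAG info tibble (`mag_id`, `taxon_class`) covering every MAG
#'   to include — MAGs without any function row count as absences.
#' @param focal_classes Character vector of focal taxon classes.
#' @param alpha Selection threshold on the Bonferroni-adjusted p (default
#'   0.05).
#' @return Tibble with one row per (function, focal class):
#'   `function_label`, `focal_class`, `prevalence_focal`, `prevalence_other`,
#'   `p_kruskal`, `p_adjusted`, `direction`, `selected`.
#' @export
compare_function_prevalence <- function(presence, mags, focal_classes,
                                        alpha = 0.05) {
  grp <- ifelse(mags$taxon_class %in% focal_classes,
                mags$taxon_class, "other")
  names(grp) <- mags$mag_id
  sizes <- table(grp)
  if (length(sizes) < 2) {
    stop_input("compare_function_prevalence: need at least 2 groups")
  }
  if (any(sizes < 2)) {
    stop_input(paste0("compare_function_prevalence: group(s) with fewer ",
                      "than 2 MAGs: ",
                      paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  unknown <- setdiff(unique(presence$mag_id), mags$mag_id)
  if (length(unknown)) {
    stop_input(paste0("compare_function_prevalence: presence rows for ",
                      "unknown MAG(s): ", paste(head(unknown, 5),
                                                collapse = ", ")))
  }
  focal_present <- intersect(focal_classes, unique(grp))

  purrr::map_dfr(unique(presence$function_label), function(fn) {
    has <- mags$mag_id %in% presence$mag_id[presence$function_label == fn]
    x <- as.numeric(has)
    g <- factor(unname(grp), levels = c(focal_present, "other"))
    kw <- suppressWarnings(kruskal.test(x, g))
    dunn <- dunn_posthoc(x, g, correction = "bonferroni")
    purrr::map_dfr(focal_present, function(fc) {
      row <- dunn[(dunn$group1 == fc & dunn$group2 == "other") |
                    (dunn$group1 == "other" & dunn$group2 == fc), ]
      prev_f <- mean(x[g == fc])
      prev_o <- mean(x[g == "other"])
      tibble(
        function_label = fn,
        focal_class = fc,
        prevalence_focal = prev_f,
        prevalence_other = prev_o,
        p_kruskal = kw$p.value,
        p_adjusted = row$p_adjusted[1],
        direction = ifelse(prev_f >= prev_o, "focal_enriched",
                           "focal_depleted"),
        selected = is.finite(row$p_adjusted[1]) & row$p_adjusted[1] < alpha
      )
    })
  })
}

#' Stacked view of oxygen-dependence category counts per genome
#' @param profiles `profiles` tibble from [mag_oxy_profiles()].
#' @return A ggplot object.
#' @export
plot_oxy_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(
    profiles,
    all_of(c("n_oxic", "n_anoxic", "n_augmented", "n_unclassified")),
    names_to = "category", values_to = "n_reactions"
  )
  ggplot(long, aes(x = .data$taxon_class, y = .data$n_reactions)) +
    geom_boxplot(outlier.size = 0.6) +
    facet_wrap(~category, scales = "free_y") +
    coord_flip() +
    labs(x = NULL, y = "distinct EC numbers per MAG") +
    theme_bw()
}
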