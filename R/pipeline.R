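# End-to-end orchestration: one configuration (R list or YAML file) drives
# simulation or ingestion of inputs, normalization, qPCR anchoring, growth
# and enrichment estimation, primer-coverage assessment, oxygen-metabolism
# profiling, co-occurrence networks, and community statistics, writing every
# stage's table plus a manifest into one output directory. Identical
# configurations produce byte-identical bundles.

#' Default pipeline configuration
#'
#' @param seed Master seed; split per stage via [derive_seed()].
#' @param output_dir Where the report bundle is written.
#' @param simulate A [synth_config()]-style list, or `NULL` when `inputs`
#'   point at files on disk.
#' @param inputs Named list of input paths (`counts`, `metadata`, `qpcr`,
#'   `taxonomy`, `reference_fasta`, `reference_taxonomy`, `mag_info`,
#'   `annotations`, `reaction_classes`); ignored when `simulate` is set.
#' @param cpr_classes CPR class list used to derive `is_cpr`.
#' @param thresholds Named list: `mismatch_budget`, `edge_min_weight`,
#'   `alpha_association`, `alpha_enrichment`, `min_completeness`,
#'   `max_contamination`, `min_time_points`.
#' @param network Named list: `method` (`"rank"`/`"sparcc"`),
#'   `min_prevalence`, `top_n`, `min_links`.
#' @param focal_classes Focal classes for the function-prevalence
#'   comparison.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, output_dir = tempfile("cprenrich_run_"),
                            simulate = list(), inputs = NULL,
                            cpr_classes = cpr_default_classes(),
                            thresholds = list(), network = list(),
                            focal_classes = c("Saccharimonadia",
                                              "Berkelbacteria")) {
  thr <- modifyList(list(mismatch_budget = 2, edge_min_weight = 0.1,
                         alpha_association = 0.001, alpha_enrichment = 0.05,
                         min_completeness = 50, max_contamination = 10,
                         min_time_points = 3),
                    thresholds)
  net <- modifyList(list(method = "rank", min_prevalence = 0.2,
                         top_n = 200, min_links = 3),
                    network)
  structure(list(seed = seed, output_dir = output_dir, simulate = simulate,
                 inputs = inputs, cpr_classes = cpr_classes,
                 thresholds = thr, network = net,
                 focal_classes = focal_classes),
            class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)),
          class = "cprenrich_stage_error", parent = e)
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes each stage's TSV output plus a
#' `manifest.yaml` (configuration hash, seed, package version, per-file MD5
#' checksums) to the configured output directory.
#'
#' @param config A [pipeline_config()], a plain list of its fields, or the
#'   path to a YAML file holding them.
#' @param output_dir Overrides the configured output directory.
#' @return Invisibly, a list with every stage's in-memory result and
#'   `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  if (!is.null(output_dir)) config$output_dir <- output_dir
  use_sim <- is.null(config$inputs)
  if (!use_sim && is.null(config$inputs$qpcr)) {
    stop_config(paste0("pipeline stage 'growth' needs qPCR totals: provide ",
                       "inputs$qpcr or a simulate block"))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  thr <- config$thresholds
  res <- list()

  if (use_sim) {
    sim_cfg <- do.call(synth_config,
                       modifyList(list(seed = config$seed),
                                  as.list(config$simulate)))
    run_stage("simulate", {
      res$experiment <- simulate_experiment(sim_cfg)
      res$reference <- simulate_reference_db(sim_cfg)
      res$mags_sim <- simulate_mag_annotations(sim_cfg)
    })
    counts <- res$experiment$counts
    meta <- res$experiment$metadata
    qpcr <- res$experiment$qpcr
    taxonomy <- add_cpr_flag(res$experiment$taxonomy, config$cpr_classes)
    ref_db <- left_join(res$reference$db,
                        select(res$reference$taxonomy, asv_id = "asv_id"),
                        by = c("seq_id" = "asv_id"))
    mags <- res$mags_sim$mags
    annotations <- res$mags_sim$annotations
    reaction_classes <- res$mags_sim$reaction_classes
  } else {
    run_stage("read_inputs", {
      counts <- read_count_table(config$inputs$counts)
      meta <- read_metadata(config$inputs$metadata)
      qpcr <- read_qpcr(config$inputs$qpcr)
      taxonomy <- read_taxonomy(config$inputs$taxonomy,
                                cpr_classes = config$cpr_classes)
      ref_db <- read_fasta_with_taxonomy(config$inputs$reference_fasta,
                                         config$inputs$reference_taxonomy,
                                         cpr_classes = config$cpr_classes)
      mags <- read_mag_info(config$inputs$mag_info)
      annotations <- read_annotations(config$inputs$annotations)
      reaction_classes <- read_reaction_classes(config$inputs$reaction_classes)
    })
  }

  run_stage("normalize", {
    res$rel <- suppressWarnings(total_sum_scale(counts))
    write_abundance_table(res$rel, out("rel_abundance.tsv"))
  })
  run_stage("absolute", {
    res$abs <- absolute_abundance(res$rel, qpcr)
    write_abundance_table(res$abs, out("abs_abundance.tsv"))
  })
  run_stage("growth", {
    res$growth <- fit_growth_rates(res$abs, meta,
                                   min_time_points = thr$min_time_points)
    res$growth_summary <- summarize_growth(res$growth, taxonomy)
    readr::write_tsv(as_tibble(res$growth), out("growth_estimates.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$growth_summary, out("growth_summary.tsv"),
                     progress = FALSE)
  })
  run_stage("enrichment", {
    res$enrichment <- suppressWarnings(fold_enrichment(res$abs, meta))
    readr::write_tsv(res$enrichment, out("fold_enrichment.tsv"),
                     progress = FALSE)
  })
  run_stage("primer_coverage", {
    pairs <- list(amplicon = amplicon_primers(), qpcr = qpcr_primers())
    res$primer_coverage <- purrr::imap_dfr(pairs, function(pr, label) {
      coverage_by_class(ref_db, pr$fwd, pr$rev,
                        budget = thr$mismatch_budget) |>
        mutate(primer_pair = paste0(pr$fwd$name, "/", pr$rev$name),
               assay = label, .before = 1)
    })
    readr::write_tsv(res$primer_coverage, out("primer_coverage.tsv"),
                     progress = FALSE)
  })
  run_stage("oxynet", {
    oxy <- mag_oxy_profiles(mags, annotations, reaction_classes,
                            min_completeness = thr$min_completeness,
                            max_contamination = thr$max_contamination)
    res$oxy_profiles <- oxy$profiles
    res$oxy_hits <- oxy$enzyme_hits
    readr::write_tsv(oxy$profiles, out("oxy_profiles.tsv"), progress = FALSE)
    readr::write_tsv(oxy$enzyme_hits, out("oxygen_enzyme_hits.tsv"),
                     progress = FALSE)
    kept <- filter_mags(mags, thr$min_completeness, thr$max_contamination)
    presence <- extract_ec_sets(
      filter(annotations, .data$mag_id %in% kept$mag_id)
    ) |>
      rename(function_label = "ec")
    # each focal class and the pooled remainder need >= 2 MAGs to test
    sizes <- table(kept$taxon_class)
    focal <- intersect(config$focal_classes,
                       names(sizes)[sizes >= 2])
    n_other <- sum(!kept$taxon_class %in% focal)
    if (length(focal) && n_other < 2) {
      inform("oxynet: too few non-focal MAGs for prevalence comparison")
      focal <- character()
    }
    res$function_enrichment <- if (length(focal)) {
      compare_function_prevalence(presence, kept, focal,
                                  alpha = thr$alpha_enrichment)
    } else {
      tibble()
    }
    readr::write_tsv(res$function_enrichment, out("function_enrichment.tsv"),
                     progress = FALSE)
  })
  run_stage("cooccurrence", {
    treat_of_exp <- meta |>
      filter(!.data$treatment_group %in% c("Start", "InSitu")) |>
      distinct(.data$experiment_id, treatment = .data$treatment_group)
    samples_by_treatment <- meta |>
      filter(.data$treatment_group != "InSitu") |>
      left_join(treat_of_exp, by = "experiment_id") |>
      filter(!is.na(.data$treatment))
    nets <- list()
    links <- list()
    for (tr in sort(unique(samples_by_treatment$treatment))) {
      ids <- samples_by_treatment$sample_id[samples_by_treatment$treatment == tr]
      sub <- counts[counts$sample_id %in% ids, , drop = FALSE]
      if (nrow(sub) < 4) {
        inform(paste0("cooccurrence: treatment ", tr,
                      " skipped (fewer than 4 samples)"))
        next
      }
      net <- estimate_network(sub, method = config$network$method,
                              treatment_group = tr,
                              min_prevalence = config$network$min_prevalence)
      filt <- filter_cpr_edges(net, taxonomy,
                               min_weight = thr$edge_min_weight)
      nets[[tr]] <- filt
      links[[tr]] <- count_order_links(filt, taxonomy,
                                       top_n = config$network$top_n,
                                       min_links = config$network$min_links)
      readr::write_tsv(as_tibble(filt),
                       out(paste0("network_", tr, ".tsv")), progress = FALSE)
    }
    res$networks <- nets
    res$link_counts <- bind_rows(links)
    readr::write_tsv(res$link_counts, out("link_counts.tsv"),
                     progress = FALSE)
  })
  run_stage("diversity", {
    res$shannon <- shannon_cpr(res$rel, taxonomy)
    readr::write_tsv(res$shannon, out("shannon_cpr.tsv"), progress = FALSE)
  })
  run_stage("associate", {
    cpr_ids <- intersect(names(res$rel)[-1],
                         taxonomy$asv_id[taxonomy$is_cpr])
    res$associations <- supplement_association(
      res$rel, meta, alpha = thr$alpha_association, asv_ids = cpr_ids
    )
    readr::write_tsv(res$associations, out("associations.tsv"),
                     progress = FALSE)
  })

  run_stage("manifest", {
    files <- sort(setdiff(list.files(config$output_dir), "manifest.yaml"))
    manifest <- list(
      package = "cprenrich",
      version = as.character(utils::packageVersion("cprenrich")),
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
      stage_seeds = lapply(
        setNames(nm = c("growth_rates", "initial_abundances", "latent_noise",
                        "sequencing", "qpcr", "reference_db",
                        "mag_annotations")),
        function(s) derive_seed(config$seed, s)
      ),
      files = as.list(tools::md5sum(file.path(config$output_dir, files)))
    )
    names(manifest$files) <- files
    yaml::write_yaml(manifest, out("manifest.yaml"))
  })

  res$output_dir <- config$output_dir
  invisible(res)
}
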