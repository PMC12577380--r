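# Synthetic-data generator with planted ground truth. Emulates the
# statistical structure of the study's inputs: multi-treatment incubation
# time series whose latent absolute abundances follow N_i(t) = N_i(0) *
# exp(k_i * t) with multiplicative lognormal noise and multinomial
# sequencing sampling; qPCR totals with lognormal error; 16S reference
# sequences with planted primer-site mismatch patterns; and MAG annotation
# tables with planted EC category memberships. One master seed is split
# deterministically per sub-generator, so adding one simulation never
# perturbs another.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a scaled-down groundwater enrichment study: four
#' incubation experiments (one per treatment), six sampling time points over
#' six weeks, three replicate bottles, and a community of CPR and non-CPR
#' ASVs growing (or declining) exponentially from in-situ-like starting
#' abundances. Growth rates default to a normal distribution centred near
#' 0.046 per day, i.e. a doubling time around 15 days for the typical
#' grower, with a spread that also produces fast growers and decliners.
#'
#' @param seed Master integer seed.
#' @param n_asv_cpr,n_asv_noncpr Number of CPR / non-CPR ASVs.
#' @param n_experiments Number of experiments; treatments cycle through
#'   Auto, Methylo, Defined, Complex.
#' @param time_points Strictly increasing sampling times in days; must
#'   start at 0 (the incubation start).
#' @param n_replicates Replicate bottles per experiment.
#' @param growth_rates Per-ASV rates (numeric vector recycled to the number
#'   of ASVs) or a list `list(mean =, sd =)` to sample from.
#' @param initial_abundances Per-ASV copies per liter at time zero (numeric
#'   vector) or a list `list(meanlog =, sdlog =)` to sample lognormally.
#' @param noise_sd_log Sigma of the multiplicative lognormal noise on latent
#'   abundances.
#' @param qpcr_noise_sd_log Sigma of the lognormal qPCR measurement error.
#' @param depth Sequencing reads per sample; `Inf` requests the noise-free
#'   surrogate in which counts are the rounded latent abundances.
#' @param primer_design Named list (per taxon class) of integer vectors with
#'   elements `n_perfect`, `n_two_mismatch_internal`, `n_3prime_broken`,
#'   `n_three_mismatch`; `NULL` gives every CPR class a 10-sequence design
#'   with 9 amplifiable.
#' @param amplicon_insert Length-2 range of the insert between the primer
#'   sites in simulated reference sequences.
#' @param ec_design List describing the planted MAG annotations: `n_mags`,
#'   per-MAG single-EC counts `n_oxic`, `n_anoxic`, `n_augmented`,
#'   `n_unclassified`, plus `n_duplicate_genes` (extra genes repeating an
#'   already-counted EC) and `n_multi_ec_genes` (genes with two ECs, which
#'   the profiler must exclude).
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(seed = 1,
                         n_asv_cpr = 30, n_asv_noncpr = 70,
                         n_experiments = 4,
                         time_points = c(0, 7, 14, 21, 28, 42),
                         n_replicates = 3,
                         growth_rates = list(mean = 0.046, sd = 0.05),
                         initial_abundances = list(meanlog = log(1e5),
                                                   sdlog = 1),
                         noise_sd_log = 0.1,
                         qpcr_noise_sd_log = 0.2,
                         depth = 20000,
                         primer_design = NULL,
                         amplicon_insert = c(300, 450),
                         ec_design = list(n_mags = 20, n_oxic = 3,
                                          n_anoxic = 25, n_augmented = 30,
                                          n_unclassified = 2,
                                          n_duplicate_genes = 2,
                                          n_multi_ec_genes = 2)) {
  if (is.null(primer_design)) {
    primer_design <- stats::setNames(
      rep(list(c(n_perfect = 8, n_two_mismatch_internal = 1,
                 n_3prime_broken = 1, n_three_mismatch = 0)),
          length(cpr_default_classes())),
      cpr_default_classes()
    )
  }
  cfg <- list(seed = seed, n_asv_cpr = n_asv_cpr,
              n_asv_noncpr = n_asv_noncpr, n_experiments = n_experiments,
              time_points = time_points, n_replicates = n_replicates,
              growth_rates = growth_rates,
              initial_abundances = initial_abundances,
              noise_sd_log = noise_sd_log,
              qpcr_noise_sd_log = qpcr_noise_sd_log, depth = depth,
              primer_design = primer_design,
              amplicon_insert = amplicon_insert, ec_design = ec_design)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_asv_cpr < 0 || cfg$n_asv_noncpr < 0 || cfg$n_experiments < 1 ||
      cfg$n_replicates < 1) {
    stop_config("synth_config: counts must be non-negative")
  }
  if (is.unsorted(cfg$time_points, strictly = TRUE)) {
    stop_config("synth_config: time_points must be strictly increasing")
  }
  if (any(cfg$time_points < 0) || cfg$time_points[1] != 0) {
    stop_config("synth_config: time_points must start at 0")
  }
  if (cfg$noise_sd_log < 0 || cfg$qpcr_noise_sd_log < 0) {
    stop_config("synth_config: noise sigmas must be >= 0")
  }
  n_asv <- cfg$n_asv_cpr + cfg$n_asv_noncpr
  if (!is.infinite(cfg$depth) && cfg$depth <= 0 && n_asv > 0) {
    stop_config("synth_config: depth must be positive (or Inf)")
  }
  invisible(cfg)
}

# Taxonomy scaffold for the simulated community: CPR classes from the
# default list, non-CPR classes typical for groundwater.
synth_taxonomy <- function(n_cpr, n_noncpr) {
  cpr_orders <- list(
    Parcubacteria = c("Kaiserbacteria", "UBA9983", "Nomurabacteria"),
    ABY1 = c("Magasanikbacteria", "Uhrbacteria"),
    Gracilibacteria = c("Peregrinibacteria"),
    Saccharimonadia = c("Saccharimonadales"),
    Berkelbacteria = c("Berkelbacteria_ord"),
    Microgenomatia = c("Microgenomatia_ord")
  )
  noncpr_orders <- list(
    Gammaproteobacteria = c("Burkholderiales", "Pseudomonadales"),
    Bacteroidia = c("Chitinophagales", "Flavobacteriales"),
    Alphaproteobacteria = c("Rhizobiales"),
    Nitrospiria = c("Nitrospirales"),
    Planctomycetes = c("Pirellulales"),
    Verrucomicrobiae = c("Verrucomicrobiales")
  )
  pick <- function(pool, n, prefix, phylum) {
    classes <- rep(names(pool), length.out = n)
    orders <- vapply(seq_len(n), function(i) {
      ords <- pool[[classes[i]]]
      ords[((i - 1) %% length(ords)) + 1]
    }, "")
    tibble(asv_id = sprintf("%s%03d", prefix, seq_len(n)),
           domain = "Bacteria", phylum = phylum,
           class = classes, order = orders,
           family = paste0(orders, "_fam"), genus = paste0(orders, "_gen"))
  }
  tax <- bind_rows(pick(cpr_orders, n_cpr, "cpr", "Patescibacteria"),
                   pick(noncpr_orders, n_noncpr, "ncpr", "various"))
  add_cpr_flag(tax)
}

#' Simulate an enrichment experiment bundle
#'
#' Generates the latent exponential trajectories, applies multiplicative
#' lognormal noise per observation, draws sequencing counts from a
#' multinomial at the configured depth, reports qPCR totals with lognormal
#' error, and assembles matching metadata and taxonomy. With `depth = Inf`
#' the noise-free surrogate is used: counts are the rounded latent
#' abundances and the qPCR total is their exact sum (times the qPCR error,
#' if any), so absolute abundances are recovered exactly downstream.
#'
#' @param config A [synth_config()].
#' @return List with `counts`, `metadata`, `qpcr`, `taxonomy`, and `truth`
#'   (list: `asv` with planted `k` and `n0`, `samples` with true totals,
#'   `latent` long tibble of latent abundances).
#' @export
simulate_experiment <- function(config) {
  validate_synth_config(config)
  n_asv <- config$n_asv_cpr + config$n_asv_noncpr
  if (n_asv == 0) stop_config("simulate_experiment: no ASVs configured")
  taxonomy <- synth_taxonomy(config$n_asv_cpr, config$n_asv_noncpr)

  k <- with_local_seed(derive_seed(config$seed, "growth_rates"), {
    if (is.list(config$growth_rates)) {
      rnorm(n_asv, config$growth_rates$mean, config$growth_rates$sd)
    } else {
      rep_len(config$growth_rates, n_asv)
    }
  })
  n0 <- with_local_seed(derive_seed(config$seed, "initial_abundances"), {
    if (is.list(config$initial_abundances)) {
      rlnorm(n_asv, config$initial_abundances$meanlog,
             config$initial_abundances$sdlog)
    } else {
      rep_len(config$initial_abundances, n_asv)
    }
  })

  treatments <- rep(c("Auto", "Methylo", "Defined", "Complex"),
                    length.out = config$n_experiments)
  supplements_for <- list(
    Auto = "thiosulfate;ammonium", Methylo = "methylamine;methanol",
    Defined = "cellulose;starch", Complex = "soil_seepage;necromass"
  )
  grid <- tidyr::expand_grid(
    experiment = seq_len(config$n_experiments),
    time_days = config$time_points,
    replicate = seq_len(config$n_replicates)
  )
  meta <- grid |>
    mutate(
      experiment_id = sprintf("E%02d", .data$experiment),
      sample_id = sprintf("E%02d_t%03d_r%d", .data$experiment,
                          round(.data$time_days), .data$replicate),
      treatment = treatments[.data$experiment],
      treatment_group = ifelse(.data$time_days == 0, "Start", .data$treatment),
      supplements = unlist(supplements_for[.data$treatment]),
      oxygen_status = ifelse(.data$experiment %% 2 == 1, "oxic", "anoxic"),
      replicate_id = sprintf("r%d", .data$replicate),
      well_id = ifelse(.data$oxygen_status == "oxic", "H41", "H52")
    )

  n_samples <- nrow(meta)
  latent <- with_local_seed(derive_seed(config$seed, "latent_noise"), {
    eps <- if (config$noise_sd_log > 0) {
      matrix(rnorm(n_samples * n_asv, 0, config$noise_sd_log),
             n_samples, n_asv)
    } else {
      matrix(0, n_samples, n_asv)
    }
    outer(rep(1, n_samples), n0) * exp(outer(meta$time_days, k)) * exp(eps)
  })
  dimnames(latent) <- list(meta$sample_id, taxonomy$asv_id)
  true_totals <- rowSums(latent)

  counts <- with_local_seed(derive_seed(config$seed, "sequencing"), {
    if (is.infinite(config$depth)) {
      round(latent)
    } else {
      t(vapply(seq_len(n_samples), function(s) {
        as.integer(rmultinom(1, config$depth, latent[s, ] / true_totals[s]))
      }, integer(n_asv)))
    }
  })
  storage.mode(counts) <- "integer"
  reported_total <- if (is.infinite(config$depth)) {
    rowSums(counts)
  } else {
    true_totals
  }
  qpcr_vals <- with_local_seed(derive_seed(config$seed, "qpcr"), {
    reported_total * exp(rnorm(n_samples, 0, config$qpcr_noise_sd_log))
  })

  dimnames(counts) <- list(meta$sample_id, taxonomy$asv_id)
  count_tbl <- matrix_to_wide(counts)

  metadata <- validate_metadata(tibble(
    sample_id = meta$sample_id, experiment_id = meta$experiment_id,
    treatment_group = meta$treatment_group, supplements = meta$supplements,
    oxygen_status = meta$oxygen_status, time_days = meta$time_days,
    replicate_id = meta$replicate_id, well_id = meta$well_id
  ))
  qpcr <- tibble(sample_id = meta$sample_id,
                 copies_per_liter = unname(qpcr_vals))

  latent_long <- matrix_to_wide(latent) |>
    tidyr::pivot_longer(-"sample_id", names_to = "asv_id",
                        values_to = "latent_abundance")

  truth <- list(
    asv = bind_rows(tibble(asv_id = taxonomy$asv_id, k = k, n0 = n0)) |>
      left_join(select(taxonomy, "asv_id", "class", "is_cpr"), by = "asv_id"),
    samples = tibble(sample_id = meta$sample_id,
                     true_total = unname(true_totals)),
    latent = latent_long
  )
  list(counts = count_tbl, metadata = metadata, qpcr = qpcr,
       taxonomy = taxonomy, truth = truth)
}

# Pick, per degenerate primer position, a concrete base inside (realize) or
# outside (mismatch) the primer's nucleotide set.
realize_base <- function(mask, inside = TRUE) {
  bases <- c("A", "C", "G", "T")
  in_set <- bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L
  pool <- if (inside) bases[in_set] else bases[!in_set]
  if (!length(pool)) stop_config("cannot plant a mismatch against 'N'")
  pool[sample.int(length(pool), 1)]
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a 16S reference database with planted primer-site patterns
#'
#' For each taxon class in the configured design, generates sequences
#' containing a realization of the forward-primer site and the
#' reverse-complemented reverse-primer site separated by a random insert.
#' Four patterns are planted on the forward site: a perfect match; exactly
#' two internal mismatches with the 3' dinucleotide intact (still
#' amplifiable under the default budget); one mismatch inside the 3'
#' terminal dinucleotide (never amplifiable); and three internal mismatches
#' (over budget). True per-class coverage is therefore
#' `(n_perfect + n_two_mismatch_internal) / total` by construction.
#'
#' @param config A [synth_config()]; `primer_design` and `amplicon_insert`
#'   are used.
#' @param fwd,rev Primer pair the sites are built from (default
#'   [amplicon_primers()]).
#' @return List with `db` (tibble `seq_id`, `sequence`, `class`,
#'   `planted_pattern`), `taxonomy` (minimal rank table for the sequences)
#'   and `truth` (per-class `n_total`, `n_amplifiable`, `coverage`).
#' @export
simulate_reference_db <- function(config, fwd = amplicon_primers()$fwd,
                                  rev = amplicon_primers()$rev) {
  validate_synth_config(config)
  fmask <- seq_to_masks(fwd$sequence)
  rsite <- reverse_complement(rev$sequence)
  rmask <- seq_to_masks(rsite)
  lf <- length(fmask)
  if (lf < 5) stop_config("simulate_reference_db: forward primer too short")

  with_local_seed(derive_seed(config$seed, "reference_db"), {
    rows <- purrr::imap(config$primer_design, function(design, cls) {
      patterns <- rep(
        c("perfect", "two_mismatch_internal", "three_prime_broken",
          "three_mismatch"),
        times = c(design[["n_perfect"]],
                  design[["n_two_mismatch_internal"]],
                  design[["n_3prime_broken"]],
                  design[["n_three_mismatch"]])
      )
      purrr::map2_dfr(patterns, seq_along(patterns), function(pat, i) {
        fsite <- vapply(fmask, realize_base, "", inside = TRUE)
        # a mismatch can only be planted where the primer set is incomplete
        internal <- which(fmask[seq_len(lf - 2)] != 15L)
        if (length(internal) < 3) {
          stop_config("simulate_reference_db: primer too degenerate to plant mismatches")
        }
        flip <- switch(pat,
          perfect = integer(),
          two_mismatch_internal = sample(internal, 2),
          three_prime_broken = sample((lf - 1):lf, 1),
          three_mismatch = sample(internal, 3)
        )
        for (p in flip) fsite[p] <- realize_base(fmask[p], inside = FALSE)
        rsite_real <- vapply(rmask, realize_base, "", inside = TRUE)
        insert_len <- sample(config$amplicon_insert[1]:config$amplicon_insert[2], 1)
        seqn <- paste0(random_bases(sample(20:60, 1)),
                       paste(fsite, collapse = ""),
                       random_bases(insert_len),
                       paste(rsite_real, collapse = ""),
                       random_bases(sample(20:60, 1)))
        tibble(seq_id = sprintf("%s_seq%03d", cls, i), sequence = seqn,
               class = cls, planted_pattern = pat)
      })
    })
    db <- bind_rows(rows)
    truth <- db |>
      group_by(class = .data$class) |>
      summarise(
        n_total = n(),
        n_amplifiable = sum(.data$planted_pattern %in%
                              c("perfect", "two_mismatch_internal")),
        coverage = .data$n_amplifiable / .data$n_total,
        .groups = "drop"
      )
    taxonomy <- add_cpr_flag(tibble(
      asv_id = db$seq_id, domain = "Bacteria", phylum = "synthetic",
      class = db$class, order = paste0(db$class, "_ord"),
      family = "", genus = ""
    ))
    list(db = db, taxonomy = taxonomy, truth = truth)
  })
}

# Synthetic EC universes per category; oxic pool includes the
# oxygen-utilizing enzyme catalog so enzyme screening is exercised.
synth_ec_pools <- function(ec_design) {
  list(
    oxic = unique(c(oxygen_enzyme_catalog()$ec,
                    sprintf("1.14.13.%d", 100 + seq_len(ec_design$n_oxic * 3)))),
    anoxic = sprintf("2.7.1.%d", 200 + seq_len(ec_design$n_anoxic * 3)),
    augmented = sprintf("6.3.4.%d", 300 + seq_len(ec_design$n_augmented * 3)),
    unclassified = sprintf("3.5.1.%d", 400 +
                             seq_len(max(1, ec_design$n_unclassified) * 3))
  )
}

#' Simulate MAG annotations with planted EC category memberships
#'
#' Each simulated MAG receives the configured number of distinct single-EC
#' genes per oxygen-dependence category (plus ECs absent from the reaction
#' table, which must end up unclassified), `n_duplicate_genes` extra genes
#' repeating an EC already present (testing per-MAG deduplication), and
#' `n_multi_ec_genes` genes carrying two ECs (which the profiler must
#' exclude). Completeness and contamination straddle the 50% / 10% quality
#' thresholds: the first MAG sits exactly on the boundary (kept), the last
#' two are planted just outside it (excluded).
#'
#' @param config A [synth_config()]; `ec_design` is used.
#' @return List with `mags` (quality table), `annotations` (gene table),
#'   `reaction_classes` (EC to category), and `truth` (per MAG: planted
#'   category counts, `n_oxygen_enzymes`, `passes_quality`).
#' @export
simulate_mag_annotations <- function(config) {
  validate_synth_config(config)
  des <- config$ec_design
  pools <- synth_ec_pools(des)
  reaction_classes <- bind_rows(
    tibble(ec = pools$oxic, category = "oxic"),
    tibble(ec = pools$anoxic, category = "anoxic"),
    tibble(ec = pools$augmented, category = "augmented")
  )
  catalog <- oxygen_enzyme_catalog()
  cpr_classes <- cpr_default_classes()

  with_local_seed(derive_seed(config$seed, "mag_annotations"), {
    n <- des$n_mags
    completeness <- round(runif(n, 55, 99), 1)
    contamination <- round(runif(n, 0, 9), 1)
    completeness[1] <- 50.0
    contamination[1] <- 10.0
    if (n >= 3) completeness[n - 1] <- 49.9
    if (n >= 2) contamination[n] <- 10.1
    mags <- tibble(
      mag_id = sprintf("mag%03d", seq_len(n)),
      taxon_class = rep(cpr_classes, length.out = n),
      completeness = completeness,
      contamination = contamination
    )
    sim_one <- function(mag_id) {
      drawn <- list(
        oxic = sample(pools$oxic, des$n_oxic),
        anoxic = sample(pools$anoxic, des$n_anoxic),
        augmented = sample(pools$augmented, des$n_augmented),
        unclassified = sample(pools$unclassified, des$n_unclassified)
      )
      single <- unlist(drawn, use.names = FALSE)
      genes <- tibble(mag_id = mag_id,
                      gene_id = sprintf("%s_g%03d", mag_id,
                                        seq_along(single)),
                      ec = as.list(single))
      ng <- nrow(genes)
      if (des$n_duplicate_genes > 0) {
        dup_ecs <- sample(single, des$n_duplicate_genes, replace = TRUE)
        genes <- bind_rows(genes, tibble(
          mag_id = mag_id,
          gene_id = sprintf("%s_g%03d", mag_id, ng + seq_along(dup_ecs)),
          ec = as.list(dup_ecs)
        ))
        ng <- nrow(genes)
      }
      if (des$n_multi_ec_genes > 0) {
        multi <- replicate(des$n_multi_ec_genes,
                           c(sample(pools$oxic, 1), sample(pools$anoxic, 1)),
                           simplify = FALSE)
        genes <- bind_rows(genes, tibble(
          mag_id = mag_id,
          gene_id = sprintf("%s_g%03d", mag_id, ng + seq_along(multi)),
          ec = multi
        ))
      }
      genes$ko <- NA_character_
      genes$function_label <- NA_character_
      list(genes = genes,
           n_oxygen_enzymes = length(intersect(drawn$oxic, catalog$ec)))
    }
    sims <- lapply(mags$mag_id, sim_one)
    annotations <- bind_rows(lapply(sims, `[[`, "genes"))
    truth <- mags |>
      mutate(
        n_oxic = des$n_oxic, n_anoxic = des$n_anoxic,
        n_augmented = des$n_augmented, n_unclassified = des$n_unclassified,
        n_oxygen_enzymes = vapply(sims, `[[`, 0L, "n_oxygen_enzymes"),
        passes_quality = .data$completeness >= 50 & .data$contamination <= 10
      )
    list(mags = mags, annotations = annotations,
         reaction_classes = reaction_classes, truth = truth)
  })
}

#' Write a full synthetic fixture bundle to a directory
#'
#' Runs all three simulators and writes every input the pipeline reads
#' (counts, metadata, qPCR, taxonomy, reference FASTA + taxonomy, MAG
#' quality/annotations, reaction classes) plus the planted-truth tables.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
simulate_fixture_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  exp_data <- simulate_experiment(config)
  ref <- simulate_reference_db(config)
  mag <- simulate_mag_annotations(config)

  write_count_table(exp_data$counts, p("counts.tsv"))
  write_metadata(exp_data$metadata, p("metadata.tsv"))
  write_qpcr(exp_data$qpcr, p("qpcr.tsv"))
  write_taxonomy(exp_data$taxonomy, p("taxonomy.tsv"))
  readr::write_tsv(exp_data$truth$asv, p("truth_asv.tsv"), progress = FALSE)
  readr::write_tsv(exp_data$truth$samples, p("truth_samples.tsv"),
                   progress = FALSE)
  write_fasta(ref$db, p("reference.fasta"))
  write_taxonomy(ref$taxonomy, p("reference_taxonomy.tsv"))
  readr::write_tsv(ref$truth, p("truth_primer_coverage.tsv"),
                   progress = FALSE)
  readr::write_tsv(mag$mags, p("mag_info.tsv"), progress = FALSE)
  write_annotations(mag$annotations, p("annotations.tsv"))
  readr::write_tsv(mag$reaction_classes, p("reaction_classes.tsv"),
                   progress = FALSE)
  readr::write_tsv(mag$truth, p("truth_mags.tsv"), progress = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}
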