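# Synthetic-data generator: determinism, conservation, planted truths.

test_that("configuration validation catches impossible settings", {
  expect_error(synth_config(time_points = c(0, 2, 2)),
               class = "cprenrich_config_error")
  expect_error(synth_config(time_points = c(1, 2)),
               class = "cprenrich_config_error")
  expect_error(synth_config(noise_sd_log = -1),
               class = "cprenrich_config_error")
  expect_error(synth_config(depth = 0),
               class = "cprenrich_config_error")
})

test_that("identical configurations produce bit-identical outputs", {
  cfg <- synth_config(seed = 33, n_asv_cpr = 5, n_asv_noncpr = 5,
                      n_experiments = 2, time_points = c(0, 3, 6),
                      n_replicates = 2, depth = 5000)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a, b)
  expect_identical(simulate_reference_db(cfg), simulate_reference_db(cfg))
  expect_identical(simulate_mag_annotations(cfg),
                   simulate_mag_annotations(cfg))
  # a different seed changes the data
  c2 <- simulate_experiment(synth_config(seed = 34, n_asv_cpr = 5,
                                         n_asv_noncpr = 5,
                                         n_experiments = 2,
                                         time_points = c(0, 3, 6),
                                         n_replicates = 2, depth = 5000))
  expect_false(identical(a$counts, c2$counts))
})

test_that("seed streams are independent per sub-generator", {
  expect_false(derive_seed(42, "qpcr") == derive_seed(42, "sequencing"))
  expect_equal(derive_seed(42, "qpcr"), derive_seed(42, "qpcr"))
})

test_that("counts conserve the sequencing depth and truths are consistent", {
  cfg <- synth_config(seed = 8, n_asv_cpr = 10, n_asv_noncpr = 20,
                      n_experiments = 1, time_points = c(0, 5, 10),
                      n_replicates = 2, depth = 7000)
  sim <- simulate_experiment(cfg)
  m <- as.matrix(sim$counts[, -1])
  expect_true(all(rowSums(m) == 7000))
  # stored true totals equal the sum of stored latent abundances
  totals <- sim$truth$latent |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(latent_abundance))
  merged <- dplyr::inner_join(totals, sim$truth$samples, by = "sample_id")
  expect_equal(merged$s, merged$true_total, tolerance = 1e-12)
})

test_that("the noise-free surrogate recovers latent abundances exactly", {
  k <- c(0.3466, -0.05, 0.1, 0)
  n0 <- c(2e6, 5e6, 1e6, 3e6)
  cfg <- synth_config(seed = 2, n_asv_cpr = 2, n_asv_noncpr = 2,
                      n_experiments = 1, time_points = c(0, 2, 4, 6),
                      n_replicates = 1, growth_rates = k,
                      initial_abundances = n0,
                      noise_sd_log = 0, qpcr_noise_sd_log = 0, depth = Inf)
  sim <- simulate_experiment(cfg)
  ab <- absolute_abundance(total_sum_scale(sim$counts), sim$qpcr)
  want <- outer(sim$metadata$time_days, k, function(t, kk) exp(kk * t)) %*%
    diag(n0)
  got <- as.matrix(ab[, -1])
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
  # k = 0 ASV has constant latent abundance
  lat <- sim$truth$latent
  a4 <- lat$latent_abundance[lat$asv_id == "ncpr002"]
  expect_true(all(a4 == a4[1]))
})

test_that("reference-database truths force the planted coverage", {
  cfg <- synth_config(seed = 3, primer_design = list(
    A = c(n_perfect = 9, n_two_mismatch_internal = 0, n_3prime_broken = 1,
          n_three_mismatch = 0),
    B = c(n_perfect = 0, n_two_mismatch_internal = 0, n_3prime_broken = 0,
          n_three_mismatch = 5),
    C = c(n_perfect = 4, n_two_mismatch_internal = 3, n_3prime_broken = 2,
          n_three_mismatch = 1)
  ))
  ref <- simulate_reference_db(cfg)
  truth <- ref$truth[match(c("A", "B", "C"), ref$truth$class), ]
  expect_equal(truth$coverage, c(0.9, 0, 0.7))
  expect_equal(truth$n_total, c(10L, 5L, 10L))
})

test_that("MAG simulation plants dedup genes, multi-EC genes and boundary qualities", {
  cfg <- synth_config(seed = 6)
  sim <- simulate_mag_annotations(cfg)
  des <- cfg$ec_design
  one <- sim$annotations[sim$annotations$mag_id == "mag001", ]
  n_single <- des$n_oxic + des$n_anoxic + des$n_augmented + des$n_unclassified
  expect_equal(nrow(one),
               n_single + des$n_duplicate_genes + des$n_multi_ec_genes)
  expect_equal(sum(lengths(one$ec) > 1), des$n_multi_ec_genes)
  # boundary MAG exactly at 50 / 10 is planted as passing
  expect_true(sim$truth$passes_quality[sim$truth$completeness == 50 &
                                         sim$truth$contamination == 10])
  expect_true(any(!sim$truth$passes_quality))
})

test_that("the fixture bundle round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 4, n_asv_cpr = 4, n_asv_noncpr = 6,
                      n_experiments = 1, time_points = c(0, 3, 6),
                      n_replicates = 2, depth = 2000,
                      ec_design = list(n_mags = 4, n_oxic = 2, n_anoxic = 3,
                                       n_augmented = 3, n_unclassified = 1,
                                       n_duplicate_genes = 1,
                                       n_multi_ec_genes = 1))
  simulate_fixture_bundle(cfg, dir)
  sim <- simulate_experiment(cfg)
  expect_equal(read_count_table(file.path(dir, "counts.tsv")), sim$counts)
  expect_equal(read_qpcr(file.path(dir, "qpcr.tsv"))$copies_per_liter,
               sim$qpcr$copies_per_liter)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$sample_id, sim$metadata$sample_id)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$is_cpr, sim$taxonomy$is_cpr)
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  magsim <- simulate_mag_annotations(cfg)
  expect_equal(ann$ec, magsim$annotations$ec)
  ref <- read_fasta_with_taxonomy(file.path(dir, "reference.fasta"),
                                  file.path(dir, "reference_taxonomy.tsv"))
  refsim <- simulate_reference_db(cfg)
  expect_equal(ref$sequence, refsim$db$sequence)
})
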