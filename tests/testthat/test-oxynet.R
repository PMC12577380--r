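# EC extraction, oxygen-dependence classification, enzyme screening, and
# prevalence comparisons.

test_that("quality filter uses inclusive thresholds", {
  mags <- tibble::tibble(
    mag_id = c("keep_boundary", "drop_completeness", "drop_contamination",
               "keep_good"),
    taxon_class = "Parcubacteria",
    completeness = c(50.0, 49.9, 90, 80),
    contamination = c(10.0, 2, 10.1, 1)
  )
  kept <- filter_mags(mags)
  expect_equal(kept$mag_id, c("keep_boundary", "keep_good"))
})

test_that("EC sets deduplicate and exclude multi-EC genes", {
  ann <- tibble::tibble(
    mag_id = "m1",
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    ec = list("1.1.1.1", "1.1.1.1", "2.7.1.1",
              c("1.1.1.1", "3.2.1.21"), character())
  )
  s <- extract_ec_sets(ann)
  expect_setequal(s$ec, c("1.1.1.1", "2.7.1.1"))
  # a MAG with no EC-bearing genes gives an empty set
  empty <- extract_ec_sets(tibble::tibble(mag_id = "m2", gene_id = "g",
                                          ec = list(character())))
  expect_equal(nrow(empty), 0)
})

test_that("reaction classification counts categories and unclassified ECs", {
  rc <- tibble::tibble(ec = c("1.1.1.1", "2.7.1.1"),
                       category = c("oxic", "anoxic"))
  sets <- tibble::tibble(mag_id = c("m1", "m1", "m1"),
                         ec = c("1.1.1.1", "2.7.1.1", "9.9.9.9"))
  prof <- classify_reactions(sets, rc, mag_ids = c("m1", "m_empty"))
  m1 <- prof[prof$mag_id == "m1", ]
  expect_equal(c(m1$n_oxic, m1$n_anoxic, m1$n_augmented, m1$n_unclassified),
               c(1L, 1L, 0L, 1L))
  empty <- prof[prof$mag_id == "m_empty", ]
  expect_equal(empty$n_oxic + empty$n_anoxic + empty$n_augmented +
                 empty$n_unclassified, 0L)
})

test_that("partial EC keys match only identical partial strings", {
  rc <- tibble::tibble(ec = "1.4.3.-", category = "oxic")
  sets <- tibble::tibble(mag_id = "m1", ec = c("1.4.3.-", "1.4.3.16"))
  prof <- classify_reactions(sets, rc)
  expect_equal(prof$n_oxic, 1L)
  expect_equal(prof$n_unclassified, 1L)
})

test_that("classification is idempotent under duplicated input ECs", {
  rc <- tibble::tibble(ec = c("1.1.1.1", "2.7.1.1"),
                       category = c("oxic", "anoxic"))
  sets <- tibble::tibble(mag_id = "m1", ec = c("1.1.1.1", "2.7.1.1"))
  dup <- dplyr::bind_rows(sets, sets) |> dplyr::distinct()
  expect_equal(classify_reactions(sets, rc), classify_reactions(dup, rc))
})

test_that("oxygen-utilizing enzymes are flagged from the catalog", {
  sets <- tibble::tibble(mag_id = "m1", ec = c("1.4.3.16", "2.7.1.1"))
  hits <- flag_oxygen_enzymes(sets)
  expect_equal(hits$enzyme_label, "l-aspartate oxidase")
  expect_equal(nrow(flag_oxygen_enzymes(
    tibble::tibble(mag_id = character(), ec = character()))), 0)
  all6 <- tibble::tibble(mag_id = "m2", ec = oxygen_enzyme_catalog()$ec)
  expect_equal(nrow(flag_oxygen_enzymes(all6)), 6)
})

test_that("planted MAG designs are recovered exactly, including exclusions", {
  cfg <- synth_config(seed = 21)
  sim <- simulate_mag_annotations(cfg)
  oxy <- mag_oxy_profiles(sim$mags, sim$annotations, sim$reaction_classes)
  truth <- sim$truth

  # quality filter agrees with the planted pass/fail flags
  expect_setequal(oxy$profiles$mag_id,
                  truth$mag_id[truth$passes_quality])

  merged <- dplyr::inner_join(oxy$profiles, truth, by = "mag_id")
  expect_equal(merged$n_oxic.x, merged$n_oxic.y)
  expect_equal(merged$n_anoxic.x, merged$n_anoxic.y)
  expect_equal(merged$n_augmented.x, merged$n_augmented.y)
  expect_equal(merged$n_unclassified.x, merged$n_unclassified.y)
  expect_equal(merged$n_oxygen_enzymes.x, merged$n_oxygen_enzymes.y)
})

test_that("category counts partition every MAG's EC set", {
  cfg <- synth_config(seed = 22)
  sim <- simulate_mag_annotations(cfg)
  sets <- extract_ec_sets(sim$annotations)
  prof <- classify_reactions(sets, sim$reaction_classes)
  sizes <- dplyr::count(sets, mag_id)
  merged <- dplyr::inner_join(prof, sizes, by = "mag_id")
  expect_equal(merged$n_oxic + merged$n_anoxic + merged$n_augmented +
                 merged$n_unclassified, merged$n)
})

test_that("prevalence comparison separates extreme designs and ignores equal ones", {
  mags <- tibble::tibble(
    mag_id = sprintf("m%02d", 1:60),
    taxon_class = rep(c("Saccharimonadia", "other1", "other2"),
                      times = c(10, 25, 25)),
    completeness = 90, contamination = 1
  )
  # function fA: 10/10 focal vs 0/50 other; fB: 5/10 vs 25/50 (equal prevalence)
  presence <- dplyr::bind_rows(
    tibble::tibble(mag_id = mags$mag_id[1:10], function_label = "fA"),
    tibble::tibble(mag_id = mags$mag_id[c(1:5, 11:35)],
                   function_label = "fB")
  )
  res <- compare_function_prevalence(presence, mags, "Saccharimonadia")
  a <- res[res$function_label == "fA", ]
  expect_true(a$selected)
  expect_equal(a$direction, "focal_enriched")
  b <- res[res$function_label == "fB", ]
  expect_false(b$selected)
})

test_that("prevalence comparison rejects undersized groups", {
  mags <- tibble::tibble(mag_id = c("m1", "m2", "m3"),
                         taxon_class = c("A", "other", "other"),
                         completeness = 90, contamination = 1)
  presence <- tibble::tibble(mag_id = "m1", function_label = "f")
  expect_error(compare_function_prevalence(presence, mags, "A"),
               class = "cprenrich_input_error")
})

test_that("planted prevalence differences are detected with high power", {
  # 60% vs 5% presence, 30 MAGs per group; reduced resampling here (the
  # acceptance suite's power criteria run elsewhere)
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    mags <- tibble::tibble(mag_id = sprintf("m%02d", 1:60),
                           taxon_class = rep(c("Focal", "other"), each = 30),
                           completeness = 90, contamination = 1)
    present <- c(runif(30) < 0.6, runif(30) < 0.05)
    presence <- tibble::tibble(mag_id = mags$mag_id[present],
                               function_label = "f")
    res <- compare_function_prevalence(presence, mags, "Focal")
    isTRUE(res$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
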