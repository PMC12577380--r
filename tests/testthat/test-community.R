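# CPR diversity, supplement associations, and rank-based group comparisons.

test_that("CPR Shannon diversity matches closed forms", {
  tax <- tiny_taxonomy(c("a", "b", "c", "x"),
                       c("Parcubacteria", "ABY1", "Gracilibacteria",
                         "Bacteroidia"))
  rel <- tibble::tibble(
    sample_id = c("even2", "single", "uniform3"),
    a = c(0.2, 0.5, 0.2), b = c(0.2, 0, 0.2), c = c(0, 0, 0.2),
    x = c(0.6, 0.5, 0.4)
  )
  h <- shannon_cpr(rel, tax)
  expect_equal(h$shannon[h$sample_id == "even2"], log(2), tolerance = 1e-12)
  expect_equal(h$shannon[h$sample_id == "single"], 0)
  expect_equal(h$shannon[h$sample_id == "uniform3"], log(3),
               tolerance = 1e-12)
  # renormalization: the non-CPR fraction does not change H
  rel2 <- rel
  rel2$x <- 0
  expect_equal(shannon_cpr(rel2, tax)$shannon, h$shannon)
})

test_that("samples without CPR abundance are omitted and bounds hold", {
  tax <- tiny_taxonomy(c("a", "b", "x"),
                       c("Parcubacteria", "ABY1", "Bacteroidia"))
  rel <- tibble::tibble(sample_id = c("S1", "S2"),
                        a = c(0.3, 0), b = c(0.3, 0), x = c(0.4, 1))
  expect_message(h <- shannon_cpr(rel, tax), "S2")
  expect_equal(h$sample_id, "S1")
  expect_true(all(h$shannon >= 0 & h$shannon <= log(h$n_cpr_asvs)))
})

test_that("clean supplement separation is significantly positive", {
  meta <- make_meta(c(0, 7), n_rep = 20)
  meta$supplements <- rep(list(character(), "thiosulfate"),
                          each = 20)
  rel <- tibble::tibble(
    sample_id = meta$sample_id,
    asv1 = ifelse(vapply(meta$supplements, length, 0L) > 0,
                  runif(40, 0.4, 0.6), runif(40, 0.0, 0.05))
  )
  res <- supplement_association(rel, meta)
  hit <- res[res$parameter == "thiosulfate", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "positive")
})

test_that("constant parameters are skipped", {
  meta <- make_meta(c(0, 7), n_rep = 3)
  meta$supplements <- rep(list("cellulose"), 6)   # present everywhere
  rel <- tibble::tibble(sample_id = meta$sample_id, asv1 = runif(6))
  expect_message(res <- supplement_association(rel, meta), "cellulose")
  expect_false("cellulose" %in% res$parameter)
  expect_false("oxic" %in% res$parameter)         # oxygen constant too
})

test_that("negating the indicator flips direction and preserves p", {
  meta <- make_meta(c(0, 7), n_rep = 10)
  set.seed(5)
  meta$supplements <- rep(list(character(), "nitrate"), 10)
  meta$oxygen_status <- rep(c("oxic", "anoxic"), 10)
  rel <- tibble::tibble(sample_id = meta$sample_id, asv1 = runif(20))
  res <- supplement_association(rel, meta, alpha = 0.5)
  # oxic indicator is the complement of the nitrate indicator here
  a <- res[res$parameter == "nitrate", ]
  b <- res[res$parameter == "oxic", ]
  expect_equal(a$rho, -b$rho, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("external differential-abundance results merge with the stated rule", {
  assoc <- tibble::tibble(asv_id = "a", parameter = "thiosulfate",
                          rho = 0.8, p_value = 1e-5,
                          significant = TRUE, direction = "positive")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\tparameter\tlog2_fold_change\tp_adjusted",
               "a\tthiosulfate\t2.5\t0.01",
               "b\tthiosulfate\t-1.0\t0.2"), path)
  merged <- ingest_differential_abundance(assoc, path)
  ext <- merged[merged$method == "external_da", ]
  expect_equal(ext$significant, c(TRUE, FALSE))
  expect_equal(ext$direction, c("positive", "negative"))
  expect_equal(nrow(merged), 3)
})

test_that("identical groups give a null statistic; separated groups a maximal one", {
  same <- group_difference(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$omnibus$statistic, 0, tolerance = 1e-12)
  expect_gte(same$omnibus$p_value, 0.9)

  sep <- group_difference(c(1, 2, 3, 101, 102, 103),
                          rep(c("a", "b"), each = 3))
  # maximal Kruskal-Wallis statistic for 3 vs 3 without ties
  expect_equal(sep$omnibus$statistic,
               kruskal.test(c(1, 2, 3, 10, 20, 30),
                            factor(rep(c("a", "b"), each = 3)))$statistic,
               ignore_attr = TRUE)
  expect_equal(sep$pairwise$p_adjusted, sep$pairwise$p_value)  # one pair
})

test_that("small groups are excluded with a message", {
  expect_message(
    gd <- group_difference(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "tiny")),
    "tiny")
  expect_equal(gd$omnibus$n_groups, 2L)
  expect_error(group_difference(c(1, 2), c("a", "b")),
               class = "cprenrich_input_error")
})

test_that("rank shift of one pooled SD is detected with high power", {
  set.seed(77)
  rej <- vapply(1:200, function(i) {
    x <- c(rnorm(50), rnorm(50, 1))
    g <- rep(c("a", "b"), each = 50)
    group_difference(x, g, post_hoc = FALSE)$omnibus$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("Dunn post-hoc agrees with the normal-tail closed form for two groups", {
  # with two groups and no ties, Dunn's z^2 equals the KW statistic
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  g <- rep(c("a", "b"), each = 4)
  gd <- group_difference(x, g)
  expect_equal(gd$pairwise$z^2, gd$omnibus$statistic, tolerance = 1e-9)
})

test_that("tidy and glance methods expose omnibus and pairwise results", {
  gd <- group_difference(c(1, 2, 3, 6, 7, 8), rep(c("a", "b"), each = 3))
  expect_equal(glance(gd), gd$omnibus)
  expect_equal(tidy(gd), gd$pairwise)
  gd2 <- group_difference(c(1, 2, 3, 6, 7, 8), rep(c("a", "b"), each = 3),
                          post_hoc = FALSE)
  expect_equal(tidy(gd2), gd2$omnibus)
})
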