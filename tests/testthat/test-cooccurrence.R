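# Network estimation, CPR edge filtering, and order-level link counting.

make_counts <- function(m, prefix = "S") {
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0(prefix, seq_len(nrow(m)))),
    tibble::as_tibble(as.data.frame(m))
  )
}

test_that("rank networks give +/-1 for perfectly (anti-)ranked pairs", {
  # constant background keeps per-sample totals monotone in x, so relative
  # abundances preserve (anti-)ranks of the constructed pair
  n <- 20
  x <- as.integer(seq(10, 200, length.out = n))
  bg <- matrix(30L, n, 5)
  m <- cbind(a = x, b = x, c = max(x) + 10L - x, bg)
  colnames(m) <- c("a", "b", "c", paste0("bg", 1:5))
  net <- estimate_network(make_counts(m), method = "rank",
                          min_prevalence = 0)
  edges <- tibble::as_tibble(net)
  ab <- edges$weight[edges$asv_a == "a" & edges$asv_b == "b"]
  expect_equal(ab, 1)
  ac <- edges$weight[edges$asv_a == "a" & edges$asv_b == "c"]
  expect_equal(ac, -1)
})

test_that("network estimation enforces sample floor and prevalence floor", {
  m <- matrix(rpois(6, 10), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(estimate_network(make_counts(m)),
               class = "cprenrich_input_error")
  # ASV present in 1/10 samples is dropped at the default 20% floor
  m2 <- matrix(rpois(30, 10), 10, 3,
               dimnames = list(NULL, c("a", "b", "rare")))
  m2[, "rare"] <- c(5L, rep(0L, 9))
  net <- estimate_network(make_counts(m2))
  expect_false("rare" %in% c(net$asv_a, net$asv_b))
})

test_that("sparcc estimates are deterministic and bounded", {
  set.seed(12)
  m <- matrix(rpois(200 * 20, 40), 200, 20,
              dimnames = list(NULL, paste0("t", 1:20)))
  n1 <- estimate_network(make_counts(m), method = "sparcc")
  n2 <- estimate_network(make_counts(m), method = "sparcc")
  expect_equal(tibble::as_tibble(n1), tibble::as_tibble(n2))
  expect_true(all(abs(n1$weight) <= 1))
})

test_that("sparcc reports near-zero association for independent taxa", {
  # two independent lognormal taxa among 50 background taxa; reduced seed
  # count here, the acceptance suite runs the full Monte-Carlo
  ok <- vapply(1:30, function(s) {
    set.seed(s)
    n <- 100
    lat <- cbind(x = rlnorm(n, 5, 0.6), y = rlnorm(n, 5, 0.6),
                 matrix(rlnorm(n * 50, 4, 0.5), n))
    colnames(lat) <- c("x", "y", paste0("bg", 1:50))
    counts <- t(vapply(seq_len(n), function(i) {
      as.integer(rmultinom(1, 10000, lat[i, ] / sum(lat[i, ])))
    }, integer(ncol(lat))))
    colnames(counts) <- colnames(lat)
    net <- estimate_network(make_counts(counts), method = "sparcc")
    w <- net$weight[net$asv_a == "x" & net$asv_b == "y"]
    abs(w) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("CPR edge filter keeps only CPR-containing edges strictly above threshold", {
  edges <- tibble::tibble(
    asv_a = c("cpr1", "cpr1", "ncpr1", "cpr2"),
    asv_b = c("ncpr1", "ncpr2", "ncpr2", "ncpr1"),
    weight = c(0.25, 0.1, 0.9, -0.5)
  )
  net <- cprenrich:::new_cooc_network(edges, "Auto", "rank", 10)
  tax <- tiny_taxonomy(c("cpr1", "cpr2", "ncpr1", "ncpr2"),
                       c("Parcubacteria", "ABY1", "Bacteroidia",
                         "Gammaproteobacteria"))
  kept <- filter_cpr_edges(net, tax)
  expect_equal(nrow(kept), 1)       # 0.1 dropped (strict >), negatives dropped
  expect_equal(kept$weight, 0.25)
  expect_error(filter_cpr_edges(net, tax[-1, ]),
               class = "cprenrich_input_error")
})

test_that("filter soundness holds over random networks", {
  set.seed(99)
  tax <- tiny_taxonomy(sprintf("t%02d", 1:20),
                       rep(c("Parcubacteria", "Bacteroidia"), each = 10))
  for (i in 1:25) {
    pairs <- t(combn(sprintf("t%02d", sample(20, 12)), 2))
    edges <- tibble::tibble(asv_a = pairs[, 1], asv_b = pairs[, 2],
                            weight = runif(nrow(pairs), -1, 1))
    net <- cprenrich:::new_cooc_network(edges, "X", "rank", 8)
    kept <- filter_cpr_edges(net, tax)
    is_cpr <- stats::setNames(tax$is_cpr, tax$asv_id)
    expect_true(all(kept$weight > 0.1))
    expect_true(all(is_cpr[kept$asv_a] | is_cpr[kept$asv_b]))
  }
})

test_that("order links: CPR-CPR excluded, top-200 cap, more-than-two rule", {
  tax <- tiny_taxonomy(
    c("c1", "c2", sprintf("n%03d", 1:300)),
    c("Parcubacteria", "Saccharimonadia", rep("Bacteroidia", 300)),
    orders = c("Kaiserbacteria", "Saccharimonadales",
               rep(c("Chitinophagales", "Flavobacteriales"), 150))
  )
  # 3 links c1-Chitinophagales (kept), 2 links c2-Flavobacteriales (dropped),
  # plus a CPR-CPR edge that must not be counted
  edges <- tibble::tibble(
    asv_a = c("c1", "c1", "c1", "c2", "c2", "c1"),
    asv_b = c("n001", "n003", "n005", "n002", "n004", "c2"),
    weight = c(0.9, 0.8, 0.7, 0.95, 0.85, 0.99)
  )
  net <- cprenrich:::new_cooc_network(edges, "Auto", "rank", 10)
  lc <- count_order_links(net, tax)
  expect_equal(nrow(lc), 1)
  expect_equal(lc$cpr_order, "Kaiserbacteria")
  expect_equal(lc$non_cpr_order, "Chitinophagales")
  expect_equal(lc$n_links, 3L)

  # 250 edges in -> exactly 200 counted
  big <- tibble::tibble(asv_a = "c1",
                        asv_b = sprintf("n%03d", 1:250),
                        weight = seq(0.99, 0.2, length.out = 250))
  bignet <- cprenrich:::new_cooc_network(big, "Auto", "rank", 10)
  lc2 <- count_order_links(bignet, tax, min_links = 1)
  expect_equal(sum(lc2$n_links), 200L)
})

test_that("planted proportional CPR/non-CPR pairs survive the filtered network", {
  tax <- tiny_taxonomy(c("cpr_x", "host_y", paste0("bg", 1:20)),
                       c("Parcubacteria", "Bacteroidia",
                         rep("Gammaproteobacteria", 20)))
  hits <- vapply(1:30, function(s) {
    set.seed(400 + s)
    n <- 100
    host <- rlnorm(n, 5, 0.8)
    lat <- cbind(cpr_x = 0.5 * host, host_y = host,
                 matrix(rlnorm(n * 20, 4.5, 0.5), n))
    colnames(lat) <- tax$asv_id
    counts <- t(vapply(seq_len(n), function(i) {
      as.integer(rmultinom(1, 10000, lat[i, ] / sum(lat[i, ])))
    }, integer(ncol(lat))))
    colnames(counts) <- tax$asv_id
    net <- estimate_network(make_counts(counts), method = "rank")
    kept <- filter_cpr_edges(net, tax)
    any(kept$asv_a == "cpr_x" & kept$asv_b == "host_y")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidy/glance/print expose the network surface", {
  edges <- tibble::tibble(asv_a = "a", asv_b = "b", weight = 0.5)
  net <- cprenrich:::new_cooc_network(edges, "Auto", "rank", 12)
  expect_equal(tidy(net), edges)
  g <- glance(net)
  expect_equal(g$n_edges, 1L)
  expect_equal(g$treatment_group, "Auto")
  expect_output(print(net), "cooc_network")
})
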