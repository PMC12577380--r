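# Co-occurrence networks on compositional abundance data, estimated per
# treatment, with CPR-specific edge filtering and order-level link counting.
# Two estimators are provided: a deterministic pairwise Spearman correlation
# on relative abundances ("rank", the default reference estimator), and a
# SparCC basis-correlation estimator ("sparcc") that works on log-ratio
# variances: with fractions x_i, the variation matrix t_ij = var(log(x_i /
# x_j)) relates to basis variances w_i and correlations r_ij via
# t_ij = w_i + w_j - 2 r_ij sqrt(w_i w_j); assuming sparse correlations the
# basis variances solve a linear system, and the strongest correlated pair
# is iteratively excluded from that system to reduce its bias.

#' Estimate a co-occurrence network for one treatment
#'
#' ASVs present in fewer than `min_prevalence` of the treatment's samples
#' are removed before estimation, as is standard practice for compositional
#' network inference. Weights are correlation-like scores in `[-1, 1]`;
#' pairs whose weight is undefined (constant ASV under the rank method) are
#' omitted.
#'
#' @param counts Wide count tibble holding only the samples of one
#'   treatment.
#' @param method `"rank"` (Spearman on relative abundances; deterministic)
#'   or `"sparcc"` (log-ratio basis correlations as described above).
#' @param treatment_group Label stored on the result (default `NA`).
#' @param min_prevalence Minimum fraction of samples an ASV must occur in
#'   (default 0.2).
#' @param pseudocount Added to every count before forming fractions for the
#'   SparCC estimator (default 1; no Dirichlet resampling, so the estimate
#'   is deterministic).
#' @param exclusion_threshold SparCC: stop excluding once the strongest
#'   remaining absolute correlation is below this value (default 0.1).
#' @param max_excluded SparCC: maximum number of excluded pairs (default
#'   10).
#' @return A `cooc_network` tibble: `asv_a`, `asv_b` (canonical order, each
#'   unordered pair once), `weight`; attributes `treatment_group`, `method`,
#'   `n_samples`.
#' @export
estimate_network <- function(counts, method = c("rank", "sparcc"),
                             treatment_group = NA_character_,
                             min_prevalence = 0.2, pseudocount = 1,
                             exclusion_threshold = 0.1, max_excluded = 10) {
  method <- match.arg(method)
  check_wide_table(counts, "count table", integer_counts = TRUE)
  m <- wide_to_matrix(counts)
  if (nrow(m) < 4) {
    stop_input("estimate_network: need at least 4 samples")
  }
  prev <- colMeans(m > 0)
  m <- m[, prev >= min_prevalence, drop = FALSE]
  if (ncol(m) < 2) {
    stop_input("estimate_network: fewer than 2 ASVs pass the prevalence floor")
  }
  w <- switch(method,
    rank = {
      rel <- m / rowSums(m)
      suppressWarnings(cor(rel, method = "spearman"))
    },
    sparcc = sparcc_correlations(m, pseudocount = pseudocount,
                                 exclusion_threshold = exclusion_threshold,
                                 max_excluded = max_excluded)
  )
  ids <- colnames(m)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  edges <- tibble(asv_a = ids[idx[, 1]], asv_b = ids[idx[, 2]],
                  weight = w[idx])
  edges <- filter(edges, !is.na(.data$weight))
  # canonical ordering of each pair for deterministic downstream handling
  cp <- canonical_pair(edges$asv_a, edges$asv_b)
  edges$asv_a <- cp$asv_a
  edges$asv_b <- cp$asv_b
  edges <- arrange(edges, .data$asv_a, .data$asv_b)
  new_cooc_network(edges, treatment_group = treatment_group, method = method,
                   n_samples = nrow(m))
}

new_cooc_network <- function(edges, treatment_group, method, n_samples) {
  structure(edges,
            class = c("cooc_network", class(tibble())),
            treatment_group = treatment_group,
            method = method,
            n_samples = n_samples)
}

# SparCC basis correlations with iterative pair exclusion; deterministic
# (pseudocount instead of Dirichlet resampling).
sparcc_correlations <- function(m, pseudocount = 1,
                                exclusion_threshold = 0.1,
                                max_excluded = 10) {
  frac <- (m + pseudocount) / rowSums(m + pseudocount)
  lf <- log(frac)
  v <- cov(lf)
  d <- ncol(m)
  tmat <- outer(diag(v), diag(v), "+") - 2 * v  # t_ij = var(log(x_i/x_j))

  mmat <- matrix(1, d, d)
  diag(mmat) <- d - 1
  tvec <- rowSums(tmat)
  basis_rho <- function(mm, tv) {
    w <- solve(mm, tv)
    w <- pmax(w, 1e-12)
    rho <- (outer(w, w, "+") - tmat) / (2 * sqrt(outer(w, w)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }
  rho <- basis_rho(mmat, tvec)
  excluded <- matrix(FALSE, d, d)
  for (iter in seq_len(max_excluded)) {
    cand <- abs(rho)
    cand[excluded | !upper.tri(cand)] <- -Inf
    top <- which.max(cand)
    if (!is.finite(cand[top]) || cand[top] < exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    i <- ij[1]
    j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    mmat[i, j] <- mmat[i, j] - 1
    mmat[j, i] <- mmat[j, i] - 1
    mmat[i, i] <- mmat[i, i] - 1
    mmat[j, j] <- mmat[j, j] - 1
    tvec[i] <- tvec[i] - tmat[i, j]
    tvec[j] <- tvec[j] - tmat[i, j]
    if (any(diag(mmat) < 1)) break
    rho <- basis_rho(mmat, tvec)
  }
  dimnames(rho) <- dimnames(v)
  rho
}

#' Keep CPR-containing, positive, above-threshold edges
#'
#' Retains an edge only when at least one endpoint is a CPR ASV and the
#' weight strictly exceeds `min_weight` (so a weight of exactly 0.1 is
#' dropped under the default).
#'
#' @param net A `cooc_network`.
#' @param taxonomy Taxonomy tibble with `is_cpr`, covering every ASV in the
#'   network.
#' @param min_weight Weight threshold (default 0.1).
#' @return Filtered `cooc_network`.
#' @export
filter_cpr_edges <- function(net, taxonomy, min_weight = 0.1) {
  ids <- union(net$asv_a, net$asv_b)
  missing <- setdiff(ids, taxonomy$asv_id)
  if (length(missing)) {
    stop_input(paste0("filter_cpr_edges: ASV(s) missing from taxonomy: ",
                      paste(head(missing, 5), collapse = ", ")))
  }
  is_cpr <- setNames(taxonomy$is_cpr, taxonomy$asv_id)
  kept <- filter(as_tibble(net),
                 (is_cpr[.data$asv_a] | is_cpr[.data$asv_b]),
                 .data$weight > min_weight)
  new_cooc_network(kept,
                   treatment_group = attr(net, "treatment_group"),
                   method = attr(net, "method"),
                   n_samples = attr(net, "n_samples"))
}

#' Count CPR-order to non-CPR-order links
#'
#' From a filtered network, keeps only CPR to non-CPR edges, selects the
#' `top_n` edges with the highest weight when there are more (ties broken by
#' the canonical edge id for determinism), counts links per (CPR order,
#' non-CPR order), and drops non-CPR orders with fewer than `min_links`
#' total links.
#'
#' @param net Filtered `cooc_network` ([filter_cpr_edges()]).
#' @param taxonomy Taxonomy tibble with `is_cpr` and `order`.
#' @param top_n Maximum number of edges considered (default 200).
#' @param min_links Minimum total links a non-CPR order needs to be
#'   reported; the default 3 keeps orders with more than two links.
#' @return Tibble `treatment_group`, `cpr_order`, `non_cpr_order`,
#'   `n_links`.
#' @export
count_order_links <- function(net, taxonomy, top_n = 200, min_links = 3) {
  is_cpr <- setNames(taxonomy$is_cpr, taxonomy$asv_id)
  ord <- setNames(taxonomy$order, taxonomy$asv_id)
  edges <- as_tibble(net) |>
    mutate(cpr_a = is_cpr[.data$asv_a], cpr_b = is_cpr[.data$asv_b]) |>
    filter(xor(.data$cpr_a, .data$cpr_b))
  if (nrow(edges) > top_n) {
    edges <- edges |>
      arrange(dplyr::desc(.data$weight), .data$asv_a, .data$asv_b) |>
      head(top_n)
  }
  counts <- edges |>
    mutate(
      cpr_order = unname(ifelse(.data$cpr_a, ord[.data$asv_a],
                                ord[.data$asv_b])),
      non_cpr_order = unname(ifelse(.data$cpr_a, ord[.data$asv_b],
                                    ord[.data$asv_a]))
    ) |>
    dplyr::count(.data$cpr_order, .data$non_cpr_order, name = "n_links")
  keep_orders <- counts |>
    group_by(.data$non_cpr_order) |>
    summarise(total = sum(.data$n_links), .groups = "drop") |>
    filter(.data$total >= min_links) |>
    pull(.data$non_cpr_order)
  counts |>
    filter(.data$non_cpr_order %in% keep_orders) |>
    mutate(treatment_group = attr(net, "treatment_group") %||% NA_character_,
           .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> treatment: %s, method: %s, %d samples, %d edges\n",
              attr(x, "treatment_group"), attr(x, "method"),
              attr(x, "n_samples"), nrow(x)))
  NextMethod()
}

#' @export
tidy.cooc_network <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "treatment_group") <- NULL
  attr(out, "method") <- NULL
  attr(out, "n_samples") <- NULL
  out
}

#' @export
glance.cooc_network <- function(x, ...) {
  tibble(treatment_group = attr(x, "treatment_group") %||% NA_character_,
         method = attr(x, "method") %||% NA_character_,
         n_samples = attr(x, "n_samples") %||% NA_integer_,
         n_edges = nrow(x),
         n_positive = sum(x$weight > 0),
         weight_max = if (nrow(x)) max(x$weight) else NA_real_)
}

#' Tile view of order-level link counts
#'
#' Plain tabular stand-in for a chord diagram: CPR orders against non-CPR
#' orders, tile fill giving the number of links.
#'
#' @param object A `cooc_network` (filtered), or a link-count tibble from
#'   [count_order_links()] passed via `link_counts`.
#' @param taxonomy Taxonomy tibble (needed when `object` is a network).
#' @param ... Passed to [count_order_links()].
#' @return A ggplot object.
#' @export
autoplot.cooc_network <- function(object, taxonomy, ...) {
  counts <- count_order_links(object, taxonomy, ...)
  plot_link_counts(counts)
}

#' @rdname autoplot.cooc_network
#' @param link_counts Link-count tibble from [count_order_links()].
#' @export
plot_link_counts <- function(link_counts) {
  ggplot(link_counts, aes(x = .data$non_cpr_order, y = .data$cpr_order,
                          fill = .data$n_links)) +
    geom_tile() +
    labs(x = "non-CPR order", y = "CPR order", fill = "links") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
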