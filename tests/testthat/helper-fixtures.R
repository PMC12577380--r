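# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

tiny_counts <- function() {
  tibble::tibble(sample_id = c("S1", "S2"),
                 asv1 = c(3L, 1L), asv2 = c(0L, 2L))
}

tiny_taxonomy <- function(asv_ids, classes,
                          orders = paste0(classes, "_ord")) {
  add_cpr_flag(tibble::tibble(
    asv_id = asv_ids, domain = "Bacteria", phylum = "p",
    class = classes, order = orders, family = "", genus = ""
  ))
}

# Metadata for one experiment with the given time points and replicates;
# time 0 is labelled Start.
make_meta <- function(times, n_rep = 1, experiment_id = "E1",
                      treatment = "Auto") {
  grid <- expand.grid(time_days = times, rep = seq_len(n_rep))
  tibble::tibble(
    sample_id = sprintf("%s_t%g_r%d", experiment_id, grid$time_days,
                        grid$rep),
    experiment_id = experiment_id,
    treatment_group = ifelse(grid$time_days == 0, "Start", treatment),
    supplements = list(character()),
    oxygen_status = "oxic",
    time_days = grid$time_days,
    replicate_id = sprintf("r%d", grid$rep),
    well_id = "H41"
  )
}

# Wide absolute-abundance table for exact exponential trajectories:
# one column per ASV, N0[i] * exp(k[i] * t) evaluated at the metadata times.
make_exp_abs <- function(meta, k, n0) {
  cols <- lapply(seq_along(k), function(i) n0[i] * exp(k[i] * meta$time_days))
  names(cols) <- names(k) %||% sprintf("asv%d", seq_along(k))
  dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                   tibble::as_tibble(cols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent brute-force primer-matching oracle -----------------------
# Set-based re-implementation of the matching rules, used only to verify the
# bitmask scanner: enumerate every offset, count set-intersection mismatches,
# apply the 3'-anchor rule, pick fewest mismatches (leftmost tie).

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_alignment <- function(primer, target, budget = 2, anchor = "right") {
  p <- strsplit(toupper(primer), "")[[1]]
  tg <- strsplit(toupper(target), "")[[1]]
  lp <- length(p)
  n_off <- length(tg) - lp + 1
  anchor_idx <- if (anchor == "right") c(lp - 1, lp) else c(1, 2)
  best <- NULL
  global <- NULL
  for (off in seq_len(n_off) - 1L) {
    mm <- 0L
    anchor_ok <- TRUE
    for (j in seq_len(lp)) {
      ps <- oracle_iupac_sets[[p[j]]]
      tc <- tg[off + j]
      ts <- oracle_iupac_sets[[tc]]
      hit <- length(intersect(ps, ts)) > 0
      if (!hit) mm <- mm + 1L
      if (j %in% anchor_idx) {
        concrete <- tc %in% c("A", "C", "G", "T", "U")
        if (!(hit && concrete)) anchor_ok <- FALSE
      }
    }
    if (is.null(global) || mm < global$mismatches) {
      global <- list(position = off, mismatches = mm)
    }
    if (mm <= budget && anchor_ok &&
        (is.null(best) || mm < best$mismatches)) {
      best <- list(position = off, mismatches = mm)
    }
  }
  if (!is.null(best)) {
    list(matched = TRUE, mismatches = best$mismatches,
         position = best$position)
  } else {
    list(matched = FALSE, mismatches = global$mismatches,
         position = global$position)
  }
}

random_iupac_primer <- function(len, degeneracy = 0.15) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  amb <- runif(len) < degeneracy
  # keep the two 3'-terminal positions concrete, as real primers do
  amb[c(len - 1, len)] <- FALSE
  base[amb] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), sum(amb),
                      replace = TRUE)
  paste(base, collapse = "")
}

random_target <- function(len, ambiguous_rate = 0.02) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  amb <- runif(len) < ambiguous_rate
  x[amb] <- sample(c("N", "W", "Y"), sum(amb), replace = TRUE)
  paste(x, collapse = "")
}
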