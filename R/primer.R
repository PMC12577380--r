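# In-silico PCR with IUPAC-degenerate primers. Matching is ungapped: the
# primer slides over every offset of the target strand, a mismatch being any
# position where the primer's nucleotide set does not intersect the
# target's. A site is accepted when total mismatches stay within the budget
# (default 2) and the two 3'-terminal primer bases pair perfectly — the
# target base there must be a concrete A/C/G/T inside the primer base's set,
# since polymerase extension requires true base pairing.

# IUPAC nucleotide codes as 4-bit sets over (A, C, G, T); U behaves as T.
iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

seq_to_masks <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  m <- iupac_masks[chars]
  if (anyNA(m)) {
    stop_input(paste0("non-IUPAC character(s) in sequence: ",
                      paste(unique(chars[is.na(m)]), collapse = ", ")))
  }
  unname(m)
}

#' Are two IUPAC codes compatible?
#'
#' Two codes are compatible when their nucleotide sets intersect, e.g. `N`
#' pairs with anything while `W` (A/T) does not pair with `C`. Vectorised
#' over both arguments.
#'
#' @param primer_base,target_base Single-letter IUPAC codes.
#' @return Logical vector.
#' @export
#' @examples
#' iupac_compatible("N", "G")  # TRUE
#' iupac_compatible("W", "C")  # FALSE
iupac_compatible <- function(primer_base, target_base) {
  p <- iupac_masks[toupper(primer_base)]
  t <- iupac_masks[toupper(target_base)]
  if (anyNA(p) || anyNA(t)) {
    stop_input("iupac_compatible: non-IUPAC character")
  }
  unname(bitwAnd(p, t) > 0L)
}

#' Define a PCR primer
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string, written 5' to 3' as synthesized.
#' @param orientation `"forward"` or `"reverse"`.
#' @return A `primer_spec` object.
#' @export
#' @examples
#' primer_spec("Bakt341F", "CCTACGGGNGGCWGCAG", "forward")
primer_spec <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 4) {
    stop_input("primer_spec: primer must be at least 4 nt long")
  }
  seq_to_masks(sequence)  # validates the alphabet
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec> %s (%s): 5'-%s-3'\n",
              x$name, x$orientation, x$sequence))
  invisible(x)
}

#' The amplicon-sequencing primer pair (V3-V5 region)
#' @return List with `fwd` and `rev` [primer_spec()] objects.
#' @export
amplicon_primers <- function() {
  list(fwd = primer_spec("Bakt341F", "CCTACGGGNGGCWGCAG", "forward"),
       rev = primer_spec("Bakt785R", "GACTACHVGGGTATCTAATCC", "reverse"))
}

#' The total-16S quantification primer pair
#' @return List with `fwd` and `rev` [primer_spec()] objects.
#' @export
qpcr_primers <- function() {
  list(fwd = primer_spec("Bac8Fmod", "AGAGTTTGATYMTGGCTCAG", "forward"),
       rev = primer_spec("Bac338Rabc", "GCWGCCWCCCGTAGGWGT", "reverse"))
}

#' Reverse-complement a (possibly degenerate) nucleotide sequence
#' @param x Character vector of IUPAC strings.
#' @return Reverse-complemented strings.
#' @export
#' @examples
#' reverse_complement("ACGTW")  # "WACGT"
reverse_complement <- function(x) {
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Mismatch count of the primer mask vector at every offset of the target
# mask vector, plus whether the 3'-anchor rule holds there. `anchor_left`
# marks primers matched as a reverse complement, whose 3' end lies at the
# left of the aligned window.
scan_offsets <- function(pmask, tmask, anchor_left = FALSE,
                         strict_three_prime = TRUE) {
  lp <- length(pmask)
  n_off <- length(tmask) - lp + 1L
  if (n_off < 1L) {
    return(tibble(position = integer(), mismatches = integer(),
                  three_prime_intact = logical()))
  }
  mism <- integer(n_off)
  anchor_ok <- rep(TRUE, n_off)
  anchor_pos <- if (anchor_left) 1:2 else (lp - 1L):lp
  for (j in seq_len(lp)) {
    tj <- tmask[j:(j + n_off - 1L)]
    hit <- bitwAnd(pmask[j], tj) > 0L
    mism <- mism + !hit
    if (j %in% anchor_pos) {
      ok <- hit
      if (strict_three_prime) {
        # concrete target base required at the anchor: the polymerase needs
        # a true base pair, not an ambiguity-code overlap
        ok <- ok & tj %in% c(1L, 2L, 4L, 8L)
      }
      anchor_ok <- anchor_ok & ok
    }
  }
  tibble(position = 0:(n_off - 1L), mismatches = mism,
         three_prime_intact = anchor_ok)
}

#' Best ungapped alignment of a primer on a target strand
#'
#' Slides the primer (as written, 5' to 3') over every offset of the target
#' strand. A candidate site is valid when its mismatch count is within
#' `budget` and the two 3'-terminal primer positions are perfectly paired to
#' concrete target bases. Among valid sites the one with fewest mismatches
#' wins, leftmost on ties; when no site is valid the minimum-mismatch
#' diagnostics are returned with `matched = FALSE`.
#'
#' @param primer A [primer_spec()] or plain IUPAC string.
#' @param target Target sequence (IUPAC string), the strand to be examined.
#' @param budget Maximum allowed mismatches (default 2).
#' @param strict_three_prime Require concrete (unambiguous) target bases at
#'   the two anchor positions (default `TRUE`).
#' @param anchor `"right"` for a primer matched as written; `"left"` when
#'   the caller passes a reverse-complemented primer, whose 3' end sits at
#'   the left edge of the window.
#' @return One-row tibble: `primer_name`, `matched`, `mismatches`,
#'   `position` (0-based offset of the window start), `three_prime_intact`.
#' @export
#' @examples
#' best_primer_alignment("ACGT", "TTACGTTT")
best_primer_alignment <- function(primer, target, budget = 2,
                                  strict_three_prime = TRUE,
                                  anchor = c("right", "left")) {
  anchor <- match.arg(anchor)
  pname <- if (inherits(primer, "primer_spec")) primer$name else NA_character_
  pseq <- if (inherits(primer, "primer_spec")) primer$sequence else primer
  pmask <- seq_to_masks(pseq)
  tmask <- seq_to_masks(target)
  if (length(tmask) < length(pmask)) {
    stop_input("best_primer_alignment: target shorter than primer")
  }
  cand <- scan_offsets(pmask, tmask, anchor_left = anchor == "left",
                       strict_three_prime = strict_three_prime)
  valid <- cand[cand$mismatches <= budget & cand$three_prime_intact, ]
  if (nrow(valid)) {
    best <- valid[which.min(valid$mismatches), ]  # which.min is leftmost
    matched <- TRUE
  } else {
    best <- cand[which.min(cand$mismatches), ]
    matched <- FALSE
  }
  tibble(primer_name = pname, matched = matched,
         mismatches = best$mismatches, position = best$position,
         three_prime_intact = best$three_prime_intact)
}

#' Can a primer pair amplify a target sequence?
#'
#' The forward primer is matched on the given strand as written; the reverse
#' primer (given 5' to 3' as synthesized) is reverse-complemented and matched
#' downstream of — and not overlapping — the forward site. The implied
#' amplicon (forward 5' end to reverse-site 3' end) must fall within
#' `amplicon_bounds`.
#'
#' @param fwd,rev [primer_spec()] objects or IUPAC strings.
#' @param target Target sequence.
#' @param budget Mismatch budget applied to each primer.
#' @param amplicon_bounds Length 2: allowed amplicon length range in nt.
#' @param strict_three_prime See [best_primer_alignment()].
#' @return One-row tibble: `amplifiable`, `fwd_position`, `rev_position`,
#'   `amplicon_length` (`NA` when not amplifiable), `fwd_mismatches`,
#'   `rev_mismatches` (best-site diagnostics).
#' @export
sequence_amplifiable <- function(fwd, rev, target, budget = 2,
                                 amplicon_bounds = c(50, 2000),
                                 strict_three_prime = TRUE) {
  fseq <- if (inherits(fwd, "primer_spec")) fwd$sequence else fwd
  rseq <- if (inherits(rev, "primer_spec")) rev$sequence else rev
  fmask <- seq_to_masks(fseq)
  rmask <- seq_to_masks(reverse_complement(rseq))
  tmask <- seq_to_masks(target)
  lf <- length(fmask)
  lr <- length(rmask)
  empty <- tibble(amplifiable = FALSE, fwd_position = NA_integer_,
                  rev_position = NA_integer_, amplicon_length = NA_integer_,
                  fwd_mismatches = NA_integer_, rev_mismatches = NA_integer_)
  if (length(tmask) < max(lf, lr)) return(empty)

  fc <- scan_offsets(fmask, tmask, anchor_left = FALSE,
                     strict_three_prime = strict_three_prime)
  rc <- scan_offsets(rmask, tmask, anchor_left = TRUE,
                     strict_three_prime = strict_three_prime)
  fv <- fc[fc$mismatches <= budget & fc$three_prime_intact, ]
  rv <- rc[rc$mismatches <= budget & rc$three_prime_intact, ]
  empty$fwd_mismatches <- min(fc$mismatches)
  empty$rev_mismatches <- min(rc$mismatches)
  if (!nrow(fv) || !nrow(rv)) return(empty)

  # every valid (fwd, rev) placement; amplicon = fwd 5' .. rev-site 3'
  grid <- tidyr::expand_grid(f = fv$position, r = rv$position) |>
    mutate(len = .data$r + lr - .data$f) |>
    filter(.data$r >= .data$f + lf,
           .data$len >= amplicon_bounds[1], .data$len <= amplicon_bounds[2])
  if (!nrow(grid)) return(empty)
  grid <- arrange(grid, .data$f, .data$r)
  f0 <- grid$f[1]
  r0 <- grid$r[1]
  tibble(amplifiable = TRUE, fwd_position = as.integer(f0),
         rev_position = as.integer(r0),
         amplicon_length = as.integer(grid$len[1]),
         fwd_mismatches = fv$mismatches[fv$position == f0][1],
         rev_mismatches = rv$mismatches[rv$position == r0][1])
}

#' Per-class in-silico primer coverage
#'
#' Runs [sequence_amplifiable()] over a reference database and reports, per
#' taxonomic class, the number of sequences, the number amplifiable by the
#' primer pair and the coverage fraction. Classes without sequences are
#' simply absent.
#'
#' @param db Tibble with columns `seq_id`, `sequence`, `class`
#'   ([read_fasta_with_taxonomy()] or [simulate_reference_db()]).
#' @param fwd,rev Primer pair ([primer_spec()] or strings).
#' @param budget Mismatch budget (default 2).
#' @param amplicon_bounds Allowed amplicon length range.
#' @param strict_three_prime See [best_primer_alignment()].
#' @return Tibble `class`, `n_sequences`, `n_amplifiable`, `coverage`.
#' @export
coverage_by_class <- function(db, fwd, rev, budget = 2,
                              amplicon_bounds = c(50, 2000),
                              strict_three_prime = TRUE) {
  if (!all(c("seq_id", "sequence", "class") %in% names(db))) {
    stop_input("coverage_by_class: db needs seq_id, sequence, class columns")
  }
  amp <- vapply(db$sequence, function(s) {
    sequence_amplifiable(fwd, rev, s, budget = budget,
                         amplicon_bounds = amplicon_bounds,
                         strict_three_prime = strict_three_prime)$amplifiable
  }, logical(1), USE.NAMES = FALSE)
  db |>
    mutate(amplifiable = amp) |>
    group_by(class = .data$class) |>
    summarise(n_sequences = n(),
              n_amplifiable = sum(.data$amplifiable),
              coverage = mean(.data$amplifiable),
              .groups = "drop")
}

#' Bar chart of per-class primer coverage
#' @param report Tibble from [coverage_by_class()].
#' @return A ggplot object.
#' @export
plot_primer_coverage <- function(report) {
  ggplot(report, aes(x = .data$class, y = .data$coverage)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "fraction of sequences amplifiable") +
    theme_bw()
}
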