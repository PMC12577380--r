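---
title: "Models and methods behind cprenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cprenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprenrich)
```

This vignette explains the models the package implements, the assumptions
they rest on, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## Absolute abundance by qPCR anchoring

Amplicon sequencing yields compositions: per-sample counts are total-sum
scaled (`total_sum_scale()`) to relative abundances \(p_i\) summing to 1.
Quantitative PCR of total bacterial 16S rRNA genes supplies an external
scale \(T\) (copies per liter), and the absolute abundance estimate per
ASV is simply \(N_i = p_i \cdot T\) (`absolute_abundance()`). The estimate
inherits the biases of both assays: primer coverage differences, 16S
operon copy-number variation (deliberately not corrected here — see
Non-goals below), and qPCR calibration error. Samples with zero total
counts stay all-zero and are flagged rather than producing undefined
values.

Fold enrichment (`fold_enrichment()`) compares each later time point's
replicate-mean absolute abundance to the mean across the experiment's
Start (time-zero) replicates, and reports the maximum ratio. Replicates
are aggregated by the arithmetic mean because it is linear in the
multinomial expectation; ASVs absent at Start have no defined baseline and
are excluded with a log entry rather than being assigned infinity, and
only ASVs that increased (fold > 1) are reported. In-situ samples —
groundwater sampled before the incubations were set up, carried at a
configurable negative time (default −4 days) — never enter baselines or
regressions.

## Growth rates and doubling times

The growth model is exponential, \(N_i(t) = N_i(0)\,e^{k t}\), fitted as
ordinary least squares of \(\ln N_i(t)\) on time (`fit_growth_rates()`).
Three choices deserve comment:

* **Zeros are non-occurrence.** \(\ln 0\) is undefined, and a zero count
  under multinomial sampling is indistinguishable from "below detection".
  Observations with zero absolute abundance are dropped, not imputed with
  pseudocounts; the fit conditions on occurrence.
* **"Three time points" means three distinct time values.** Replicates at
  one time all enter the regression but count once toward the threshold.
  This is the stricter of the two possible readings and prevents a single
  sampling day with three bottles from qualifying as a time series.
* **One slope per incubation.** No windowing or changepoint fitting. If an
  organism grew fast early and stalled later, the single slope
  underestimates its peak rate — the estimates are conservative lower
  bounds, which the test suite asserts on constructed stall series.

Doubling time is \(T_d = \ln 2 / k\) for \(k > 0\); negative rates
describe decline and carry no doubling time. Summaries
(`summarize_growth()`) report median, quartiles and range per taxon group,
CPR split from non-CPR, using positive-rate fits only. Replicates are
pooled per experiment by default; a per-replicate mode
(`per_replicate = TRUE`) fits each bottle separately. No r² or
slope-significance filter is applied beyond rate positivity, as none is
part of the stated procedure.

## In-silico PCR

Matching is ungapped: PCR mismatch tolerance is about base pairing at
fixed register, and indels would shift the register of everything
downstream. A primer matches a window when at most `budget` (default 2)
positions have disjoint IUPAC nucleotide sets, and the two 3′-terminal
primer positions pair perfectly. The 3′ rule is interpreted strictly: the
target base under the anchor must be a concrete A/C/G/T inside the primer
base's set, because polymerase extension requires a true base pair — an
ambiguity code in the reference would otherwise count as a "match" that no
real duplex guarantees. This strictness is switchable
(`strict_three_prime = FALSE`). Elsewhere, degenerate-vs-degenerate
positions score as matches when the sets intersect, with no fractional
penalties — deterministic, and the convention of common in-silico PCR
tools. `U` is treated as `T` throughout; coordinates are 0-based
internally.

A sequence is amplifiable (`sequence_amplifiable()`) when the forward
primer matches the given strand, the reverse primer (reverse-complemented)
matches downstream without overlap, and the implied amplicon is 50–2000 nt
(both bounds configurable; the upper bound mainly guards against absurd
pairings in long references). Only the given strand is scanned: 16S
reference databases are stored in a fixed orientation, and the test suite
verifies coverage is invariant under reverse-complementing the database
with the primer roles swapped.

## Oxygen-related metabolic profiling

Gene annotations are reduced per MAG to a *set* of EC numbers: genes with
exactly one EC contribute it, genes with several ECs (ambiguous or fused
products) are excluded entirely, and duplicates within a MAG count once —
an incomplete genome with two copies of one enzyme gene is not "twice as
aerobic". The set is mapped onto a reaction classification table with
categories oxic (requires molecular oxygen or an oxygen-derived
metabolite), anoxic (strictly oxygen-free), and augmented (anaerobic
reactions replaced by aerobic alternatives). The table ships as data, not
code: the package never hard-codes category membership, and the bundled
synthetic tables are labelled as such. Partial ECs (`1.4.3.-`) match only
identical partial keys — matching them against all completions would
over-claim specificity. Genome quality filtering uses inclusive thresholds
(completeness ≥ 50%, contamination ≤ 10%).

The oxygen-enzyme screen checks the EC set against a small catalog of
oxygenases/oxidases whose reactions consume molecular oxygen directly
(l-aspartate oxidase 1.4.3.16, kynurenine 3-monooxygenase 1.14.13.9,
pyridoxamine 5′-phosphate oxidase 1.4.3.5, catechol 2,3-dioxygenase
1.13.11.2, 4-hydroxyphenylpyruvate dioxygenase 1.13.11.27, d-amino-acid
oxidase 1.4.3.3). The EC assignments are standard-nomenclature mappings
made here and are overridable via the catalog argument.

Function-prevalence comparisons (`compare_function_prevalence()`) treat
each focal class and the pooled remainder as groups, run Kruskal–Wallis on
the 0/1 presence values, then Dunn's pairwise post-hoc z tests with
Bonferroni correction; a function is selected when its adjusted
focal-vs-other p falls below 0.05. On binary data the rank tests reduce to
proportion comparisons, which is exactly the intended question. Groups
need at least two genomes each.

## Co-occurrence networks

The default estimator is pairwise Spearman correlation on relative
abundances: deterministic, fast, and adequate as a reference estimator for
the filtering rules downstream. The alternative `"sparcc"` implements the
log-ratio basis-correlation procedure: with fractions \(x_i\) (pseudocount
1), the variation matrix \(t_{ij} = \mathrm{var}\,\log(x_i/x_j)\) relates
to basis variances \(\omega_i\) and correlations \(\rho_{ij}\) through
\(t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}\);
assuming sparse correlations, the \(\omega_i\) solve the linear system
\((D-2)\,\omega + \mathbf{1}\mathbf{1}^\top \omega = t\cdot\mathbf{1}\),
and the strongest-correlated pair is iteratively removed from the system
(exclusion threshold 0.1, at most 10 pairs) to reduce its leverage. No
Dirichlet resampling is performed by default, so the estimate is
deterministic; correlations are clipped to \([-1, 1]\). ASVs present in
fewer than 20% of a treatment's samples are removed before estimation —
rare-taxon correlations on compositional data are dominated by zeros — and
at least 4 samples are required.

Edge filtering keeps edges with at least one CPR endpoint and weight
strictly above 0.1 ("exceeding", so exactly 0.1 is dropped); the edge
weight and the correlation value are the same quantity. Link counting
excludes CPR–CPR edges, caps the network at the 200 highest-weight edges
(ties broken by the canonical edge id so reruns are identical), and drops
non-CPR orders with fewer than three total links. No bootstrap pseudo-p
filtering is applied, as none is part of the stated procedure.

## Community statistics

CPR Shannon diversity restricts each sample to CPR ASVs, renormalizes the
sub-composition, and computes \(H = -\sum p \ln p\) (natural log, via
`vegan::diversity()`). Renormalization was an open choice — the
alternative is computing H on raw CPR proportions — and was chosen so that
H measures CPR *evenness* independently of how large the CPR fraction is;
since Shannon entropy is invariant to rescaling a composition, the two
differ only when the non-CPR remainder is included, which would conflate
CPR structure with total CPR load.

The supplement screen computes Spearman correlations between each
supplement's presence/absence indicator (plus `oxic`, coded as its own
binary parameter — the oxygen regime is a property of the bottle, not an
amendment) and relative ASV abundances, two-sided, with midrank tie
handling and the asymptotic t approximation (a binary indicator always
produces ties, so the exact permutation p is unavailable anyway). The
cutoff is a stringent raw p < 0.001 rather than a multiplicity correction,
reflecting that these correlations on compositional data are a screening
aid, not confirmatory inference. The acceptance suite verifies the
empirical type-I error at this cutoff lies in [0.0005, 0.002] over 10,000
null pairs at n = 40. Externally computed differential-abundance results
(e.g. from a bias-corrected compositional model) can be merged via
`ingest_differential_abundance()`, which applies an adjusted-p < 0.05 rule
to that branch.

## The synthetic-data generator

`simulate_experiment()` draws latent trajectories
\(N_i(t) = N_i(0)\,e^{k_i t}\,\varepsilon_{it}\) with
\(\varepsilon_{it} \sim \mathrm{Lognormal}(0, \sigma^2)\), reports qPCR
totals as the true total times \(\mathrm{Lognormal}(0, \sigma_q^2)\), and
draws counts per sample from a multinomial at the configured depth — the
standard generative model behind TSS plus qPCR anchoring. Defaults: 30 CPR
and 70 non-CPR ASVs, four experiments (one per treatment), time points
0–42 days, three replicates, depth 20,000, \(\sigma = 0.1\),
\(\sigma_q = 0.2\) (the qPCR error magnitude is not empirically
constrained; 0.2 on the log scale is an arbitrary, overridable choice),
rates \(k \sim \mathcal{N}(0.046, 0.05^2)\) per day — centred on a
doubling time of 15 days, the regime typical of oligotrophic groundwater,
with a spread that produces both fast growers and decliners — and
\(N_i(0) \sim \mathrm{Lognormal}(\ln 10^5, 1)\). `depth = Inf` requests a
noise-free surrogate (counts are rounded latent abundances, the qPCR total
their exact sum) used for exactness tests. One master seed is split
deterministically per sub-generator (`derive_seed()`), so adding one
simulation never perturbs another; identical configurations give
bit-identical outputs.

`simulate_reference_db()` plants four mismatch patterns on the forward
primer site (perfect; two internal mismatches with the 3′ dinucleotide
intact; one mismatch inside the 3′ dinucleotide; three internal
mismatches), so true per-class coverage is forced by construction.
`simulate_mag_annotations()` plants per-category single-EC genes plus
duplicate-EC and multi-EC genes, and quality values straddling the 50%/10%
thresholds, including a genome exactly on the boundary.

What the generator does **not** emulate: chimeras and sequencing error
(ASV inference is upstream of this package), structural zeros, primer-bias
in the counts themselves, 16S copy-number variation, temporal
autocorrelation of the noise, and ecological interactions beyond planted
proportionality. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
failure mode of real amplicon data.

## Problem sizes and determinism

The test and acceptance runs use scaled-down cohorts — typically 100 ASVs,
72 samples, 20 MAGs, 10-sequence-per-class reference databases, 200-seed
Monte-Carlo loops for growth recovery, 100 seeds for network detection,
and 10,000 null pairs for calibration — sizes chosen so that
planted-truth recovery is sharp while a full run stays comfortably
interactive. The pipeline writes a manifest with a configuration hash and
per-file checksums; rerunning the same configuration reproduces every
output byte for byte.

## Known limitations

* qPCR anchoring propagates total-assay error into every ASV's absolute
  abundance; rates are unbiased by i.i.d. multiplicative error but their
  uncertainties are understated by plain OLS.
* The per-ASV growth model ignores replicate random effects; the pooled
  fit is the default by design, not a claim that bottles are exchangeable.
* The SparCC-style estimator is run without resampling; its weights are
  point estimates without uncertainty.
* Order-level link counts depend on the taxonomy's order assignments;
  unclassified orders propagate as their placeholder strings.
* 16S operon copy-number correction and rarefaction are out of scope.
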