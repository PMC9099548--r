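---
title: "Methods: the nodal-signature discovery workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nodal-signature discovery workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalsig)
```

# Scope

`nodalsig` implements the computational stages of a lymph-node-metastasis
(N+/N−) expression-signature study in endometrioid endometrial carcinoma:
sample QC, voom-weighted moderated-t differential expression, SD-cutoff
hierarchical clustering with subsampled consensus, nearest-shrunken-centroid
(NSC) signature discovery, an MSE-based centroid validator, GMT
over-representation analysis, and exact clinico-pathological comparison
statistics. A synthetic cohort generator stands in for the patient data,
which are not publicly available. This vignette documents the models, their
assumptions, the defaults and the design decisions that were genuinely open.

# The synthetic cohort

`sim_config()` / `simulate_counts()` emulate the study conditions the
analysis assumes:

* 28 samples in three latent clusters — A: 7 samples, all N+; B: 10
  samples (6 N+ / 4 N−); C: 11 samples (3 N+ / 8 N−) — hence 16 N+ and
  12 N− overall.
* ~18,000 genes with negative-binomial counts, variance `mu + phi * mu^2`.
  Gene baselines are log-normal (`baseline_sd_log = 1.8`, a typical bulk
  RNA-seq dynamic range); gene dispersions are log-normal with median 0.15
  (`dispersion_shape = 0.5` on the log scale), at the noisy end of human
  bulk data because the emulated material is FFPE.
* Library sizes log-uniform over 5·10⁶–2·10⁷ fragments. The lower edge
  deliberately straddles the QC inclusion threshold so that filtering is
  exercised on realistic input.
* Independent Bernoulli dropout (`zero_inflation = 0.03`) zeroes entries
  post-hoc, mimicking the FFPE degradation that motivates the zero-count
  QC rule.
* Three 500-gene DE modules, one per cluster, at |log₂FC| = 2 (the C
  module is down-regulated). Module size was fixed at 500 because the
  emulated study reports roughly 950–1500 DE genes per inter-cluster
  contrast; two 500-gene modules per pairwise contrast reproduce that
  order of magnitude under the default power.

A single seed governs everything; per-stage sub-streams are derived
deterministically (`derive_seed`), so any stage can be reproduced in
isolation. What the generator does **not** emulate: correlated gene-gene
noise within modules beyond the mean shift, isoform structure, batch
effects, GC/length biases, or sequencing error profiles. Tests passing on
this generator therefore demonstrate the correctness and calibration of the
algorithms, not their field performance on real FFPE cohorts.

Clinical covariates (`simulate_clinical_table()`) are drawn per arm with the
cohort's published cell frequencies (e.g. substantial angioinvasion 2/12 in
N− vs 9/16 in N+) and tumor size from per-arm normals (46.8 ± 22.5 mm vs
50.1 ± 25.9 mm). The same counts are exposed directly by
`eec_node_tables()` for deterministic testing.

# Merged-read splitting

Short FFPE fragments produce overlapping R1/R2 pairs that adapter-removal
tools merge into single-end reads. To keep those fragments in a paired-end
alignment workflow, `split_merged_read()` cuts a merged read of length L at
the midpoint: R1 keeps the first ⌈L/2⌉ bases unchanged; R2 is the reverse
complement of the remainder with reversed qualities. Two choices here were
open:

* **Split point.** The midpoint maximizes the shorter mate and is
  symmetric; any other cut would bias mate lengths with no benefit.
* **R2 orientation.** R2 is re-complemented so the emitted pair has the
  standard FR orientation a downstream aligner expects of a paired-end
  library. The identity `merge(R1, revcomp(R2)) == merged` holds for every
  record and is enforced by a 10,000-read round-trip test.

# Sample QC

`sample_qc()` keeps a sample iff aligned total > 5,000,000 **and**
zero-count genes < 3500. Both inequalities are strict, so a sample sitting
exactly at a threshold is excluded; the boundary tests pin this down. The
aligned total is operationalized as the column sum of the count matrix
(what the pipeline can see post-counting); a separate vector of
alignment-level totals can be supplied when available, and "5 M" is
interpreted as counted fragments.

# Differential expression

The DE stage re-implements the voom/moderated-t chain from its published
formulas rather than wrapping a library, so that every quantity (weights,
prior df, posterior variances) is exposed; the installed reference
implementation is used in the test suite as an independent oracle and the
two agree to machine precision on shared inputs.

* `logcpm`: `log2((count + 0.5)/(libsize + 1) * 1e6)`.
* `voom_weights`: per-gene group-means fit on logCPM; lowess (span 0.5, the
  reference default) of `sqrt(residual SD)` on average log₂ count;
  observation weight = trend(fitted log-count)⁻⁴, with constant
  extrapolation outside the fitted range and the predicted square-root SD
  floored at 10⁻⁴ so degenerate genes (zero residual variance) cannot
  produce infinite weights. All-zero genes are removed; no other gene
  pre-filtering is applied.
* `fit_moderated_t`: weighted LS contrast per gene; prior `(d0, s0²)` by
  moment matching on `log s²` (digamma/trigamma; the trigamma inverse is a
  Newton iteration converged to 10⁻¹⁰). If the excess spread of the log
  variances is non-positive the inversion has no solution and the prior df
  is taken as infinite — all genes then share `s0²`, the stable fallback.
  `prior = "none"` disables moderation (d0 = 0), reducing the statistic to
  the ordinary weighted two-sample t — used in tests as a limiting-case
  check.
* Calling: BH-adjusted p < 0.05 **and** fold change ≥ 2, applied as a
  conjunction (equivalent to sequential filtering).
* Contrasts between clusters are run pairwise as two-group fits (A–B, A–C,
  B–C, A–BC, A–C′) rather than through one joint design matrix; with a
  single factor the two parameterizations give identical contrasts, and
  pairwise fits keep each contrast's variance pooling local to the samples
  involved.

Calibration is verified on null simulations: across 20 negative-binomial
null data sets (5000 genes, 12 vs 16 samples, dispersion 0.15) the observed
false-discovery proportion of the full chain at FDR 0.05 / FC ≥ 2 stays
below 0.10 (it is typically exactly 0).

# Clustering

Distance is 1 − Pearson correlation between samples with average linkage
(UPGMA, via `stats::hclust`).

**Gene centering.** Sample correlations are computed after subtracting each
gene's mean (default `center = TRUE`). On uncentered logCPM the shared
abundance profile dominates: all sample pairs correlate near +1, no split
can ever be anti-correlated, and the SD-sweep's selection criterion is
vacuous. Centering is the standard practice for correlation-based sample
clustering and makes the anti-correlation score meaningful. It can be
disabled for sensitivity analyses.

**SD-cutoff selection** (`select_sd_cutoff`). Cutoffs sweep 40 evenly
spaced quantiles of the gene-SD distribution. For each cutoff the retained
genes are clustered, the tree is cut into its two top branches, and the
score A = mean pairwise cross-branch sample correlation is recorded. The
chosen cutoff minimizes A subject to A < 0 and ≥ 3000 genes retained
(`min_genes`). Splits with A ≈ 0 are treated as chance groupings. A is
computed on the retained genes (not all genes), and as the mean over all
cross-branch sample pairs — the least parametric estimator of
between-branch similarity; the full sweep is returned so alternatives
(e.g. centroid correlation) can be compared. If no cutoff achieves
negative anti-correlation the result carries status `"no_structure"`
rather than an arbitrary clustering.

**Consensus clustering** (`consensus_cluster`). Default 10,000 iterations,
each drawing ⌈0.6·n⌉ samples without replacement (leave-out 40%),
re-clustering, cutting at k; consensus(i,j) = co-clustered / co-sampled.
Final assignments cluster 1 − consensus with average linkage. k defaults
to 3 (the number of expression groups the workflow targets) and a `k_range`
sweep reports per-k consensus-CDF areas for judging the cluster count.
Entries never sampled together get consensus 0. The package's own
stability checks and examples run 300–1000 iterations, which already
saturate the consensus matrix on separable data; the default stays at
10,000 for production use.

# Signature discovery and validation

`fit_shrunken_centroids` implements NSC with the usual pooled within-class
SD `s_i`, fudge `s0 = median(s_i)`, size factors `m_k = sqrt(1/n_k − 1/n)`,
soft-thresholded offsets `d'_ik = sign(d_ik)·max(|d_ik| − Δ, 0)` and the
diagonal discriminant with prior term `−2 log π_k`. Priors default to the
observed class frequencies (`"uniform"` available). At Δ = 0 the classifier
is exactly diagonal-covariance nearest-centroid classification — enforced
against a brute-force oracle; at full shrinkage every sample goes to the
largest-prior class.

`cross_validate_nsc` stratifies folds by class; with fewer members in the
smallest class than the requested 10 folds it falls back to leave-one-out —
the operative branch at cohort scale (7 vs 8 samples). The CV-error
minimizer is chosen with ties broken toward the **larger** Δ, preferring the
smaller signature. Accuracy, sensitivity and specificity are reported with
N+ as the positive class.

`centroid_validator` re-checks a signature independently of the NSC
machinery: training-group centroids are plain means over signature genes;
a validation sample is assigned by minimal MSE. Its randomization test
permutes the sample's expression values across the signature genes and
recomputes the best MSE: with B = 1000 draws the p-value is the add-one
estimate (r+1)/(B+1); when the signature is small enough that all
permutations fit in B, the null is enumerated exhaustively and the p-value
is exact (the identity permutation guarantees p > 0). What exactly should
be "randomized" in an MSE score is ambiguous; within-sample permutation was
chosen because it preserves the sample's value distribution while breaking
the gene-to-centroid correspondence, which is the quantity the score
measures. Equal-MSE ties go to the first group in sorted label order and
are flagged in the report.

# Enrichment

`ora` computes the hypergeometric upper tail P(X ≥ k) for each set with BH
across sets — the standard over-representation computation for GMT
collections; ranked (walk-statistic) GSEA is out of scope. The universe
defaults to the genes surviving QC; set members outside the universe are
ignored.

# Clinical statistics

`fisher_exact_rxc` enumerates every table with the observed margins
(Freeman–Halton) via log-factorials and sums the probabilities of tables no
more probable than the observed one. Two-sided Fisher definitions differ;
the probability-mass criterion with relative tolerance 1 + 10⁻⁷ matches the
de-facto reference implementation and reproduces the cohort's printed
p-values (0.013, 0.07, 0.12, 0.06, 0.1, 0.4). All-zero rows/columns are
dropped first (provably p-invariant — the molecular-classification table is
tested with and without its empty POLE row). Enumeration is refused above a
grand total of 200; the cohort tables are all n = 28. The t-test is the
Welch (unequal-variance) form with Satterthwaite df, which reproduces the
printed tumor-size p = 0.7 from the summary statistics alone; when both SDs
are zero with equal means, t = 0 by convention. Two cohort rows print
p = 0.9 where the exact two-sided p computes to 1.0; this is a display
convention of the source table and those rows are not used as checks.

# Pipeline

`run_pipeline` chains the stages and renames clusters by decreasing N+
fraction (A = most enriched), making the "N+ cluster" and "N− cluster"
identification programmatic instead of by inspection. The refinement step
(`refine_cluster`) drops samples whose node label disagrees with their
cluster's majority before the signature contrast — turning cluster C into
the all-N− group C′. The validator gets a stratified hold-out (default one
third) of the signature-contrast samples. Every stage writes TSV; the
manifest records seed, thresholds and md5 per output, and reruns with the
same config are hash-identical.

# Problem sizes in the test suite

The suite exercises full-scale objects where it matters (18,000-gene
simulations for clustering recovery; 10,000-read round trips; 20-replicate
null calibration at 5,000 genes) and reduced sizes elsewhere (consensus
runs of 150–1000 iterations, 1,500–4,000-gene DE fixtures), chosen so the
whole suite completes in about a minute while still covering every
algorithmic branch.

# Known limitations

* The generator's modules shift means only; real cluster-defining programs
  carry correlated within-module noise, so real-data ARI will be lower than
  the synthetic benchmark suggests.
* NSC assumes a diagonal covariance; strongly co-expressed signature genes
  violate this and can make the CV error optimistic.
* The SD-sweep's anti-correlation criterion assumes two genuinely opposed
  expression programs exist; weak or one-sided structure yields
  `"no_structure"` by design rather than a forced clustering.
* `fisher_exact_rxc` is exact but exponential in table size; it is meant
  for clinico-pathological tables, not genomic-scale contingency tables.
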