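---
title: "Methods: from phosphosite tables to kinase activities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phosphosite tables to kinase activities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phosphoswing analyses multiplexed (TMT) phosphoproteome and proteome
experiments of the kind used to profile acute signalling responses in brain
tissue: two 11-channel plexes, one per dissection timepoint, each holding
pooled untreated controls, mock-injected controls and treated animals. This
vignette explains the statistical machinery, the tunable parameters, the
synthetic-data generator used to validate the pipeline, and the numerical
choices that were genuinely open.

## Ingest and feature definition

Phosphosite-level search-engine exports quantify *peptide forms*: the same
phosphosite can appear on several charge states and modification variants.
The pipeline re-annotates every site against the search FASTA (recomputing
the site-centered ±7 sequence window, `_`-padded at protein termini, and
verifying the stated acceptor residue), then collapses rows sharing
(gene, sorted site positions, multiplicity) to one *phosphopeptide feature*
whose per-sample value is the median of the log2 intensities over
non-missing duplicates. Zero reporter intensities are treated as missing,
the usual TMT convention for failed quantification.

Localization filtering keeps a multi-phosphorylated form when its primary
site has class-1 probability above 0.5 in at least one experimental group
and another site exceeds 0.75 in at least one group. The thresholds for
singly phosphorylated forms are not forced by that rule; we require the
site probability to exceed 0.75 in at least one group, mirroring the
secondary-evidence threshold, and record this convention here because other
choices (e.g. 0.5) are defensible.

## Preprocessing

Each plex is processed separately, in this order: group-missingness filter
→ quantile normalization → kNN imputation → surrogate-variable correction
→ outlier screening. Filtering before normalizing means the reference
distribution is computed from features with reasonable support; the order
is recorded in the run manifest.

* **Missingness** (`missing.max_group_frac = 0.25`): a feature is kept only
  if every sample group misses at most 25% of its values. Note that for a
  three-replicate group this allows zero missing values.
* **Quantile normalization** forces all samples onto the per-rank mean
  distribution. With missing data, observed values are mapped through
  interpolated ranks, which reduces to the classical definition for
  complete data.
* **kNN imputation** (`impute.k = 10`, the classical default): a missing
  entry becomes the mean, in that sample, of the k nearest features by
  Euclidean distance on co-observed samples. Distances are averaged per
  co-observed column so features with different missingness patterns are
  comparable; observed values are never altered.
* **Surrogate variables** are estimated by the iterative residual-SVD
  procedure with the Buja–Eyuboglu permutation criterion choosing the
  count (20 permutations; the criterion's own significance rule is used).
  Two application modes exist: `sva.mode = "regress"` (default) removes
  the surrogate components from the matrix before testing, which keeps the
  downstream interface simple but cannot credit the degrees of freedom
  consumed; `"covariate"` includes the surrogates in the per-feature
  linear model, which is the statistically cleaner option and the one used
  when false-positive control under batch structure matters most.
* **Outlier screening** projects samples onto the first two principal
  components and flags samples whose squared Mahalanobis distance exceeds
  the chi-square(2) quantile at 1 − 1e-4. The reference mean and
  covariance are estimated leaving the candidate sample out: with the
  sample included, the squared distance is algebraically bounded by
  (n−1)²/n ≈ 9.1 for an 11-channel plex, below the 18.4 threshold, so a
  gross outlier could never be flagged. A flagged sample triggers exactly
  one re-run of the plex without it. (Re-annotation and median collapsing
  are per-sample operations, so the re-run can start at the missingness
  filter without changing any number.)

## Moderated differential testing

Per feature and plex, ordinary least squares estimates the group means
(plus surrogate covariates in covariate mode). The residual variance
\(s_g^2\) on \(d_g\) degrees of freedom is shrunk toward a prior
\((d_0, s_0^2)\) estimated by moment matching on \(\log s_g^2\):

\[
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\widehat{\mathrm{lfc}}_g}{\tilde s_g \sqrt{c^\top (X^\top X)^{-1} c}},
\]

with \(t_g\) referred to a t distribution on \(d_0 + d_g\) degrees of
freedom. \(d_0 = 0\) recovers the ordinary t-test and \(d_0 = \infty\) the
fully pooled test; both limits are exposed for verification. P-values are
Benjamini–Hochberg adjusted per contrast within each plex and adjusted
p < 0.05 is called significant. Fold changes are treatment minus control:
pilocarpine − mock (`P/M`) and mock − untreated (`D/U`, the diazepam
response) at each timepoint.

Significant phosphopeptides whose gene's *protein* is significant in the
matching comparison at either timepoint are flagged `protein_excluded`, so
retained phospho-signals reflect stoichiometry rather than expression;
phosphopeptides without any protein record are always kept.

## Kinase activity inference

Each kinase's substrate specificity is modeled as a position weight matrix
over its known substrate ±7 windows:
freq = (count + pseudocount) / (n + 20·pseudocount), with pseudocount 0.01
and a uniform amino-acid background. The denominator uses the per-position
count of non-padding residues, so every column is a probability
distribution even when windows are truncated at protein termini (for
padding-free columns this equals the number of substrate sequences). A
window's match score is the summed log2 likelihood ratio over the 15
positions; kinases with both Ser/Thr and Tyr specificity are modeled once
per residue class (the Tyr model is suffixed `_TYR`).

Scores are calibrated empirically: 1000 windows drawn from the detected
phosphopeptide windows of the matching residue class give an add-one
p-value, and matches at p ≤ 0.05 become network edges. Multi-phosphorylated
features contribute the window of their first site.

Per kinase, with \(p^+\) and \(p^-\) the proportions of its substrates
whose fold change is significantly positive or negative (raw p ≤ 0.05, per
the network's local-connectivity definition),

\[
\mathrm{swing} = (p^+ - p^-)\,\ln(n_{\mathrm{edges}}+1)\,\ln(n_{\mathrm{seqs}}+1),
\]

z-transformed across kinases. The logarithmic weighting realises "weighted
by the number of edges and the number of substrate sequences" while keeping
high-degree kinases from dominating; it is a documented choice, not a claim
of bit-compatibility with other implementations. Significance comes from a
degree-preserving permutation null: substrate nodes are reassigned to
kinases at random (each kinase keeps its edge count; draws are without
replacement from the network's substrate pool), and each tail is assigned
(1 + #{permuted ≥ observed}) / (N + 1) over N = 1000 permutations.

As an orthogonal validation, the mean significant log2 fold change of each
kinase's *known* substrates is reported, matching database entries to
detected features by identical gene name and identical ±4 window core, with
duplicate (gene, window) pairs counted once and at least four significant
substrates required.

## Regulatory sites, ranked lists, enrichment

Curated regulatory phosphosites (function plus induced/inhibited direction)
are matched by gene name and ±4 window core, via the first site for
multi-phosphorylated features; redundant matches keep the largest-magnitude
fold change. Per (function, direction) the pipeline reports the median
significant log2 fold change and the perturbed percentage (significant
matched sites over detected matched sites).

Ranked gene lists sum a significance rank (ascending adjusted p) and a
magnitude rank (descending |log2FC|); ties on the combined rank are broken
by the significance rank and then alphabetically, making the order
deterministic and input-order independent. Gene duplicates keep their best
entry; the background is the genes detected in both the proteome and the
phosphoproteome. The ordered enrichment evaluates, per term, the
hypergeometric upper-tail probability at every list prefix and reports the
minimum with BH adjustment across terms — a transparent stand-in for
external ordered-query services, which truncate the list by their own
iterative rule; the prefix-minimum is anti-conservative in absolute terms
and is meant for ranking terms, not for calibrated inference. Heatmap
ordering uses complete-linkage clustering on Euclidean distance.

## The synthetic-data generator

`generate_experiment()` emits every pipeline input — phosphosite and
protein-group tables, FASTA, design, kinase-substrate and regulatory-site
files — with a serialized ground-truth record. It emulates:

* the two-plex, 11-channel layout (3 untreated + 4 mock + 4 pilocarpine);
* log2 intensities = baseline (N(20, 2²)) + planted effects + batch
  component + noise with within-group SD 0.5;
* ~25% missing values imposed by a logistic function of intensity
  (left-censoring, the dominant TMT missingness mechanism); an MCAR mode
  exists for imputation unit tests;
* one balanced batch vector loading on 40% of features (SD 0.5);
* motif-coherent kinase substrates: each synthetic kinase has a random
  consensus whose substrate windows are noisy copies (per-position
  substitution probability 0.2), so its own substrates score highest under
  its PWM;
* planted treatment effects of |log2FC| = 1 with random sign on 25% of
  features, applied to the pilocarpine group in both plexes — the planted
  fraction mirrors the ~28% of quantified phosphopeptides a strong
  convulsant stimulus perturbs, and persistent effects are the natural
  reading of a timepoint-free planting record;
* protein-level confounds that shift a gene's protein feature *and* all its
  phosphopeptides, exercising the exclusion filter;
* localization probabilities drawn so a configurable fraction of
  effect-free features fails the 0.5/0.75 rule, plus charge-variant
  duplicate rows to exercise median collapsing.

It does **not** emulate TMT ratio compression, isotope impurity,
identification (PSM-level) uncertainty, peptide-sharing between protein
groups, or correlated biological co-regulation beyond the planted
structure. Passing tests therefore demonstrate the statistical machinery
under a clean generative model, not performance on raw instrument output.

Validation runs use 3,000–5,000 features, 12–50 kinases and 1,000
permutations; these sizes give stable statistics while keeping a full
validation suite in the order of a minute.

## Statistical power under the validation conditions

With log2FC 1.0, within-group SD 0.5 and 4 vs 4 replicates, the standard
error of a contrast is 0.354 and the noncentrality ≈ 2.8. Per contrast, the
BH fixed point at adjusted p < 0.05 then caps sensitivity near 0.78 even if
every feature carried an effect, and near 0.55 at a 25% planted fraction;
counting detection at either timepoint raises this to ≈ 0.8 on complete
data, slightly less once left-censored missingness and imputation
attenuate effects (the recovery checks report the measured values). This
is a property of the design, not of the estimator: effect recovery at
these settings is limited by replication, which is worth remembering when
interpreting per-timepoint significant counts from comparable experiments.

## Known limitations

* Each plex is analysed separately; no plex-bridging normalization is
  attempted, so cross-timepoint comparisons are set-based, not ratio-based.
* The swing weighting and background-sampling count are documented
  conventions; other published weightings exist.
* The ordered-enrichment stand-in evaluates all prefixes rather than an
  iterative truncation, and its minimum-p is not calibrated.
* kNN imputation treats features as exchangeable neighbours; it does not
  model the censoring mechanism that generated the missingness.
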