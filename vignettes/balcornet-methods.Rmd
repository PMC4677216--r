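---
title: "Methods: correlation-network analysis of BAL miRNA/mRNA profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-network analysis of BAL miRNA/mRNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balcornet)
```

## The problem

Pulmonary sarcoidosis is a granulomatous lung disease driven by a
cytokine/chemokine network in bronchoalveolar lavage (BAL) cells. How that
network is regulated — post-transcriptionally by microRNAs, and
transcriptionally by the Th1 lineage factor T-bet — can be probed without
functional experiments by correlating paired miRNA and mRNA qPCR profiles
across patients. `balcornet` implements that analysis end to end for a
three-group design (healthy controls, patients whose disease regresses, and
patients whose disease progresses over a two-year follow-up): qPCR
quantification, nonparametric differential expression, significance-filtered
Spearman correlation networks, self-organizing-map (SOM) clustering of
patients, and a nearest-neighbour reduction of the full coexpression graph.

Because per-patient expression data of this kind are generally not public,
the package ships a synthetic-cohort generator with *known ground truth*.
Every downstream stage is tested against cohorts whose group shifts and rank
correlations were planted, so correctness claims never depend on access to
the original measurements.

## Synthetic cohorts: a Gaussian copula with log-normal marginals

`generate_cohort()` draws a latent Gaussian vector per sample and maps it
through `exp`, giving strictly positive, right-skewed marginals — the shape
calibrator-relative qPCR expression values actually have. Three choices
matter:

* **Marginal scale.** `base_log_mean = log(0.1)` and `base_log_sd = 0.5`.
  Typical relative-expression magnitudes in BAL panels span roughly 0.005 to
  2 with group means mostly near 0.01–0.5, so a log-normal centred at 0.1
  with log-sd 0.5 (≈ 65 % coefficient of variation) is a realistic default.
  Published summaries report only group means and 95 % CIs, so the
  dispersion is a modelling choice, not a measured value; it is held fixed
  across all analyses here.
* **Planted rank correlations.** A target Spearman correlation
  $\rho_s$ is imposed on the latent scale as
  $\rho_P = 2\sin(\pi\rho_s/6)$, which is exact for Gaussian copulas;
  because `exp` is strictly monotone, the generated pair has population
  Spearman correlation exactly $\rho_s$. Correlations restricted to a
  subset of groups use a different latent correlation matrix per group
  (group-specific correlation patterns are exactly what the analysis is
  meant to detect). Non-planted pairs have latent correlation 0.
* **Validity.** The per-group latent matrix must be positive semi-definite.
  A "hub" feature strongly correlated with several mutually uncorrelated
  partners quickly violates this; the generator rejects such structures and
  names the offending pairs rather than silently distorting them
  (`analysis/01_simulate.R` shows a valid hub-plus-clique construction).

Planted group effects shift the log-mean of one feature in one group, so a
shift of $\ln 2$ doubles that group's geometric mean.

What the generator does **not** emulate: cell-type composition (BAL
lymphocyte/macrophage fractions), assay-specific technical noise,
heteroskedasticity across the dynamic range, or heavy-tailed outliers.
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under a clean copula model — not that the pipeline is
robust to every artefact of real qPCR data. Rank-based statistics downstream
make the latter gap smaller than it would be for parametric pipelines.

## Cq calling: locating the second-derivative maximum

The quantification cycle is defined as the fractional cycle at which the
amplification curve's second derivative peaks on the rising phase — a
threshold-free quantity (instrument software popularised it as the
"second-derivative-maximum method" without publishing a formula).

Estimating where the second derivative of a *sampled* sigmoid peaks is more
delicate than it looks. For a logistic curve
$F(c) = (1+e^{-k(c-c_0)})^{-1}$ the second derivative peaks at
$c_0 + \log\!\big((3-\sqrt3)/(3+\sqrt3)\big)/k$ (≈ $c_0 - 1.317$ for
$k = 1$), which provides a closed-form oracle. Against that oracle, the
obvious recipe — central second differences at unit cycle spacing followed by
a 3-point quadratic peak fit — is biased by **−0.14 cycles**: the
second-difference operator itself smears the skewed peak leftwards
(−0.09), and the quadratic vertex through three unit-spaced samples of a
skewed peak adds the rest. No symmetric smoothing fixes this; Savitzky–Golay
pre-smoothing makes it *worse* (window 7 shifts the call by a further
−0.4), because any symmetric low-pass moves the peak of a skewed function.

`call_cq()` therefore reconstructs the derivative spectrally:

1. first differences $d_1[j] = F(c_{j+1}) - F(c_j)$ decay to ~0 at both
   ends of a complete run (flat baseline, flat plateau) and — because the
   logistic derivative's Fourier transform $\pi\omega/\sinh(\pi\omega)$ is
   negligible beyond the cycle-sampling Nyquist frequency — form an
   essentially band-limited sequence;
2. the difference operator is deconvolved exactly in the frequency domain
   ($-\omega^2/(e^{i\omega}-1)$ turns the first-difference spectrum into the
   second-derivative spectrum), with a raised-cosine taper above
   $0.75\pi$ rad/cycle suppressing out-of-band noise;
3. the second derivative is evaluated on a 32× upsampled grid, the argmax is
   restricted to the growth phase (at most four cycles before the maximum
   slope, which keeps baseline noise from winning), and a final quadratic
   refinement interpolates between fine-grid points.

On the noiseless logistic oracle the call is off by **−0.019 cycles**; it is
exactly invariant to affine fluorescence rescaling and shifts with the curve
to ~0.02 cycles. Residual error grows for very steep curves ($k \gtrsim 2$,
under-sampled at one reading per cycle) — a documented limitation. The
`smoothing_window` argument retains optional Savitzky–Golay smoothing for
very noisy runs, with the explicit caveat that it trades a leftward bias for
variance; the default is off.

Flat or falling curves return a `no_amplification` flag rather than an
error; in a run context (`call_cq_run()`) any curve rising less than 10 % of
the run's dynamic range is likewise flagged.

Relative expression follows the standard efficiency-power form
$E_t^{\,Cq_{t,cal}-Cq_{t,s}} / E_r^{\,Cq_{r,cal}-Cq_{r,s}}$ with
efficiencies in $(1,2]$ and default 2 (perfect doubling); per-assay
efficiencies are accepted but not estimated (no dilution-series module).

## Nonparametric differential expression

`de_table()` mirrors the three comparisons of the study design:
Kruskal–Wallis across the three groups, Mann–Whitney for pooled patients vs
controls, and Mann–Whitney for regressing vs progressing disease.

* **Exact small-sample nulls.** The Mann–Whitney exact mode uses the full
  labeling distribution of U (the count distribution for tie-free data;
  direct enumeration over `combn` labelings with midranks when ties are
  present). Mode `"auto"` switches to the tie-corrected,
  continuity-corrected normal approximation above $n_a + n_b = 20$. At the
  study's group sizes the approximation's empirical size is ≈ 0.04–0.05,
  i.e. slightly conservative, which the calibration tests quantify.
* **No multiplicity adjustment drives the flags.** Significance is the
  unadjusted `p < 0.05` criterion, matching the analysis this package
  models; Benjamini–Hochberg columns are emitted alongside for readers who
  want them, but they never feed the `sig_*` flags.
* **Confidence intervals** are t-based, $\bar x \pm t_{n-1,0.975}\,s/\sqrt n$
  (correct small-n coverage; whether the original tables used normal or t
  quantiles is not decidable from published group summaries, and the
  difference is small at $n \ge 14$).
* **Ties** take midranks everywhere.

## Spearman correlation networks and the chord-weight transform

`correlation_result()` computes all (miRNA ∪ T-bet) × mRNA Spearman
coefficients on one group's samples with two-sided P values: exact by full
rank-permutation enumeration for $n \le 9$ (the null is cached per $n$),
otherwise via $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df. Constant
features make the coefficient undefined; they are flagged and reported,
never silently NaN.

Chord-diagram band weights use

$$w = 1 + 10\,(|r_s| - t)^2,$$

where $t$ is the significance threshold on $|r_s|$: the smallest attainable
coefficient with two-sided $P < \alpha$ at the group's sample size
(`critical_rho()`; closed-form inversion of the t relation for large $n$,
enumeration for small $n$). Written with the square and the parenthesis this
is the only smooth reading that is minimal (and equal to 1) exactly at the
significance boundary, increases strictly with $|r_s|$ beyond it, and
ignores the correlation's sign — the properties a band-width transform
needs. Each group's diagram gets its own $t$ (a group's threshold depends on
its own $n$); a fixed global `critical_t` can be configured instead.
An empty edge set is a legitimate result: at control-group sizes
($n = 14$, $t \approx 0.53$) a null cohort yields only the ~$\alpha$
fraction of chance edges.

The clustered heatmap orders rows by their correlation *profiles*: the
dissimilarity between two row features is $1 - \mathrm{cor}$ of their rows
of the coefficient matrix (sign-preserving, so positively and negatively
acting regulators land in different blocks), with average linkage by
default and lexicographic pre-sorting of features so that the leaf order is
deterministic and invariant to input permutations. Covariates such as BAL
lymphocyte fractions can be appended as extra correlation rows; by default
they enter the heatmap analysis only, not the chord diagrams.

## SOM clustering of patients

`train_som()` is a classic online Kohonen map: rectangular 2-D grid,
best-matching unit by Euclidean distance, Gaussian neighbourhood on the
grid, learning rate and radius decaying linearly over presentations,
codebook initialised from random data rows — all seeded and exactly
reproducible. Features are z-scored first; miRNA and mRNA panels differ by
orders of magnitude, and without scaling a handful of abundant transcripts
would own the distance. Defaults: 4 × 3 grid (about a dozen neurons suits a
~50-patient cohort; a map much larger than the sample count trivially
memorises, much smaller cannot separate), 100 epochs, learning rate
0.5 → 0.02, radius max(grid)/2 → 0.5. With radius 0 the update degenerates
to online k-means on the grid cells, which the tests exercise directly.

`assign_and_report()` reports, per occupied neuron, the class fractions
(summing to 1), the percent of the cohort captured (summing to 100), the top
class, and a purity summary — the form in which SOM results for
patient-subgroup separation are usually communicated. The original study's
SOM hyperparameters are unpublished, so its specific neuron percentages are
not reproduction targets; the reporting format and the separability
behaviour are.

## Nearest-neighbour reduction of the coexpression graph

`full_weighted_graph()` builds the complete graph over all measured
molecules with weights $|r_s|$ (relationship strength regardless of sign;
the signed coefficient is kept in the edge table). `prune_nearest_neighbors()`
keeps edge $(a,b)$ iff $b$ is among $a$'s top-$k$ neighbours *or* vice
versa, with $k = 1$ by default — "only edges connecting nearest neighbours".
The OR rule is what makes vertex sizes informative: a molecule that is the
top correlate of many others keeps all those edges and acquires a high
degree, while the AND rule would cap every degree at $k$. Weight ties break
lexicographically on the neighbour's name, so the pruned graph is a
deterministic function of the weight matrix. The pruned edge set provably
contains every vertex's own top neighbour (degree ≥ 1) and grows
monotonically with $k$; tests verify exact agreement with a brute-force
oracle on random graphs.

## Orchestration

`run_all()` sequences the stages on one cohort — simulated from a design or
read from TSV — writing TSV/GraphML/newick text artifacts, a run log
(α, per-group $n$ and $t$, seed) and an MD5 manifest; reruns with the same
seed are byte-identical. The numbered scripts under `analysis/` run the same
stages as a narrated workflow. YAML configs (`read_run_config()`) cover the
same surface.

## Problem sizes used by the test suite

The suite favours exact small instances plus calibrated simulations sized to
run comfortably on one CPU: full-enumeration cross-checks up to
$n_a+n_b = 12$ (Mann–Whitney) and $n = 7$ (Spearman); copula recovery at
$n = 5000$ per planted coefficient (tolerance ± 0.03); type-I calibration
over 1000 simulated cohorts at the 14/28/20 design sizes, judged against the
95 % binomial band around α; power for a $\ln 2$ progression shift over 500
cohorts; SOM purity over 20 seeds; nearest-neighbour pruning against brute
force on 100 random 10-vertex graphs. The whole suite runs in well under a
minute.

## Known limitations

* The Cq caller assumes one reading per cycle on a complete curve (flat
  baseline and plateau inside the window); truncated or very steep curves
  lose accuracy, and take-off-point corrections applied by some instrument
  software are not reproduced.
* Exact Spearman nulls are enumerated only to $n = 9$ (the $t$
  approximation takes over well before any study-relevant $n$); the exact
  null assumes tie-free ranks.
* The generator's single log-sd for all features ignores feature-specific
  dispersion; planted-effect power statements are therefore relative to that
  common noise level.
* miRNA-target nomination, binding-site prediction and all graphical
  rendering (Circos, heatmap images, network layouts) are out of scope —
  the package emits the standard text inputs for those tools instead.
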