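---
title: "Estimating tumor fraction from ultra-low-pass WGS of cfDNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor fraction from ultra-low-pass WGS of cfDNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture of fragments
shed by normal cells and by tumor cells. At ultra-low-pass whole-genome
sequencing depth (ULP-WGS, ~0.1x, roughly 1.5 million reads), individual
loci are essentially uncovered, but megabase-scale somatic copy-number
alterations (SCNAs) leave a measurable imprint on read depth: a region
present at three copies in tumor cells attracts proportionally more
fragments. `ulpcna` exploits this to estimate, without a matched normal
sample and without prior knowledge of the tumor's mutations, (i) the
fraction of cfDNA derived from tumor cells (tumor fraction, TF), (ii) the
average tumor ploidy, and (iii) a genome-wide segmentation into discrete
copy-number states. The main practical use is triage: samples with TF at
or above 0.10 carry enough tumor signal for standard-depth exome
sequencing of the same plasma sample.

# Observation model

The genome is tiled into 1 Mb bins (`build_bin_grid()`), reads are counted
per bin, and centromere-adjacent bins are masked with a 1 Mb flank.
Coverage is corrected for GC-content and mappability bias by two
sequential LOESS fits (GC first, then mappability on the GC-corrected
values), fitted on autosomes only and applied everywhere. Corrected
coverage is divided by a reference panel `h` -- the per-bin median of
corrected coverage across healthy donors (27 by default) -- and the
observation for bin $t$ is the log2 copy ratio
$l_t = \log_2(r_t / h_t)$.

Two modeling identities anchor everything else. First, the observed
coverage of a bin with tumor copy number $c$ in a sample with normal
fraction $n$ is proportional to the DNA mixture $2n + (1-n)c$; for events
carried by only part of the tumor (subclone-absent fraction $s$), a third
component $2s(1-n)$ represents tumor cells without the event. Second,
because coverage is normalized by total reads, the denominator of every
ratio is the sample-average copy number $2n + (1-n)\phi$, with $\phi$ the
average tumor ploidy. The expected log2 ratio of state $g$ is therefore

$$\mu_g = \log_2\!\frac{2n + 2s(1-n) + (1-s)(1-n)c_g}{2n + (1-n)\phi},$$

with $s = 0$ for clonal states. We use base 2 so the means live on the
same scale as the data; the neutral state at $\phi = 2$ then sits at 0.

# Hidden Markov model

States are HETD (1 copy), NEUT (2), GAIN (3), AMP (4), HLAMP (modeled at
exactly 5 copies), plus subclonal HETD and GAIN. Homozygous deletions are
not modeled: at 1 Mb they are smaller than a bin. Emissions are Student's
t with state mean $\mu_g$, precision $\lambda_g$, and a fixed 2.1 degrees
of freedom -- heavy tails that absorb residual artifact bins. Transitions
are stationary with self-transition $e = 0.99999$, strongly favoring
megabase-scale segments; the matrix is constructed from $e$ and held
fixed by default (`estimate_transitions = TRUE` switches on a fully
data-driven Dirichlet update, which we found prone to degenerate
relabeling solutions on tumor-free samples).

**Chain structure.** Each chromosome is an independent chain sharing all
parameters. This matters quantitatively: in a single genome-wide chain a
whole-chromosome event pays two transition penalties of
$\log\frac{(1-e)/(K-1)}{e} \approx -13.3$, which at ULP noise levels
(per-bin log-ratio SD ~0.065 at 0.1x, essentially the Poisson floor of
~520 reads/bin) prices arm-scale events out of the decoding until TF
~0.06. With per-chromosome chains such events enter through the initial
distribution at a cost of a few log units, and the detection limit of the
arm-level spike-in experiment drops to ~0.03, where the per-bin shift is
only $\log_2(1.015) \approx 0.02$. The initial distribution is updated by
the posterior-mean (add-one) Dirichlet estimate over the chain starts; a
MAP update with unit concentration can zero out a state and permanently
bar whole-chromosome events.

**Priors.** All priors are flat (Beta(1,1) for $n$ and $s$, flat over the
bounded support for $\phi$, unit-concentration Dirichlet for $\pi$)
except the Gamma prior on each precision, which is set from the sample:
shape 3 and scale $(\mathrm{sd}(l)/\sqrt{|K|})^{-1}$, read as the scale
parameter so the prior mean $3\sqrt{|K|}/\mathrm{sd}(l)$ tracks the
sample's own noise scale.

**Shared subclonal precision.** The two subclonal states share the
neutral state's precision (one free parameter for the tied group,
estimated from pooled sufficient statistics). This is a deliberate
restriction of the per-state precision model: as $s \to 1$ the subclonal
means collapse onto the neutral mean, and with free precisions the
subclonal states turn into extra mixture components that fit the *shape*
of the noise distribution rather than copy number. That degeneracy both
inflates the marginal likelihood of no-call solutions and traps EM in
local optima at tumor fractions below ~0.1. Physically the restriction is
mild: a subclonal event's coverage is intermediate between neutral and
the clonal event, so its counting noise is the same process.

# Estimation

Parameters $\{n, s, \phi, \lambda, \pi\}$ are estimated by MAP EM. The
E-step is the scaled forward-backward recursion (implemented in C++, as
is Viterbi). In the M-step, each precision has a closed-form update via
the Student-t latent-scale weights $u = (\nu+1)/(\nu + \lambda d^2)$; the
global parameters $n$, $s$, $\phi$ have no closed form ($\mu_g$ is
nonlinear in them) and are updated by bounded Brent maximization of the
penalized expected log posterior, one coordinate pass per iteration, with
each move guarded to never decrease the objective. Bounds are
$n, s \in [0.01, 0.99]$ and $\phi \in [1.5, 5]$. Chromosome 19 stays in
its chain and is decoded, but is weighted out of the M-step sums
(residual coverage bias on chr19 is a known artifact of GC correction);
chrX is excluded by default because its copy state is confounded with sex
without allelic data. Sex is inferred first (chrY read proportion >
0.001 and median chrX log ratio < -0.5 calls a male) and male chrX is
rescaled by its median.

Convergence is declared when the objective (marginal log-likelihood plus
log prior) changes by less than `max(tol, rtol * |F|)`; the printed
headline rule of 0.1% is exposed but the default `rtol = 1e-4` is
tighter, because at $|F| \sim 3000$ a 0.1% step still allows $n$ to
drift by ~0.01 per iteration and leaves restart candidates
half-converged and mis-ranked. EM is deterministic given data and an
initialization; there is no RNG anywhere in inference.

To escape local optima, EM is restarted from the grid
$n_0 \in \{0.35, 0.45, 0.50, 0.65, 0.75, 0.85, 0.95\}$ times
$\phi_0 \in \{2, 3, 4\}$ (21 runs; benchmarks on near-diploid material
restrict $\phi_0 = 2$).

# Solution selection

Each restart is decoded (Viterbi per chromosome) and summarized. The
selection statistic $F$ is the complete-data log posterior at the decoded
path, $\log p(l, \hat G \mid \theta) + \log p(\theta)$. Evaluating at the
hard path rather than the marginal makes restart comparison immune to the
noise-shape artifact described above: components not on the path
contribute nothing.

Candidates are filtered before the maximum-$F$ choice:

* more than 50% of the genome in subclonal states, or more than 70% of
  altered calls subclonal -- clonal/subclonal identifiability has broken
  down;
* 95% or more of the genome in a *single* non-neutral state -- such a
  solution is observationally a relabeled diploid genome at a different
  ploidy (the classic ploidy confound of coverage-only data), and the
  diploid reading is the identifiable one. A selected solution of this
  form is reported as tumor fraction 0 (flag `RELABELED_DIPLOID`).

The winner is subject to the zero-TF rule: under 5% of bins altered *and*
no event of 50+ bins means the apparent signal is indistinguishable from
noise, and tumor fraction is reported as 0 (`ZERO_TF`).

**The clonal/subclonal ridge.** Clonal events at DNA fraction $t$ are
exactly mimicked by subclonal events at tumor fraction $t/(1-s)$ for any
$s$: a flat likelihood ridge on which EM lands arbitrarily, so the raw
$1-\hat n$ of an all-subclonal solution can be badly inflated. When every
candidate fails the subclonality filters (the typical outcome for a
low-burden sample whose few events are all labeled subclonal), the
fallback winner's tumor fraction is re-estimated from the decoded
segments themselves: each altered segment contributes
$t = D(2^{\Delta}-1)/(c-2)$, where $\Delta$ is its median log ratio
relative to the empirical neutral level (median of bins decoded NEUT)
and $D = 2n+(1-n)\phi$; segments are combined by bin-weighted median
(flag `TF_FROM_SEGMENTS`), so scattered spurious segments with near-zero
implied fraction cannot dilute the dominant events. Hard segment medians
are immune to the soft-assignment contamination that biases the EM point
estimates when states overlap. Anchoring to the decoded neutral level
also absorbs the small negative offset ($\approx -\sigma^2/2\ln 2$) that
log ratios of mean-normalized counts carry.

Reported tumor fraction is otherwise $1-\hat n$, uncorrected for $s$; on
genuinely subclonal disease it is an underestimate relative to allelic
purity estimates, by construction.

# Synthetic data and what the benchmarks show

`sim_genome()` builds the hg19 autosome grid (~2,897 bins) with a GC
track centered at 0.40 whose variation is mostly bin-to-bin (SD 0.04)
plus a mild smooth regional component, and near-1 mappability with ~2% of
bins degraded. Bin-level GC variation matters: a long-range-smooth GC
field makes whole-chromosome events partially collinear with the GC
curve, and the LOESS correction then absorbs 30-50% of the event signal --
real 1 Mb GC tracks are not collinear with chromosomes. `simulate_counts()`
draws Poisson counts around the admixture intensity
$2(1-tf) + tf\,(2s_t + (1-s_t)c_t)$, scaled to the target read total and
multiplied by a quadratic GC bias curve (peak 0.45, +/-20%) and by
mappability. An optional negative-binomial size parameter adds the extra
dispersion of real libraries; the default is pure Poisson, the
counting-noise floor.

The benchmark constructions mirror the published designs at desk scale:

* **Serial mixtures** (`benchmark_serial_mixtures()`): a high-burden
  tumor source (design purity 0.78, ploidy ~2.06, ~36% of the genome
  altered in whole-chromosome and arm-scale events) and a tumor-free
  source are simulated at ~1x, mixed at read proportions
  {0.01, 0.05, 0.11, 0.21, 0.35, 0.45}, thinned to {0.1x, 0.5x, 1x},
  three replicates each, and analyzed with the 7x1 restart grid.
  Expected TF is proportion x 0.78.
* **Tumor-free donors** (`benchmark_tumor_free()`): 22 copy-neutral
  samples at 0.1x through the full 21-restart pipeline; specificity is
  read at the 0.10 and 0.03 cut-offs.
* **Spike-ins** (`benchmark_spike_in()`): one whole-chromosome gain
  (chr8, 146 bins) plus one whole-chromosome loss (chr13, 115 bins) --
  the canonical arm-scale alterations of metastatic breast/prostate
  disease, both >100 bins and, like real arm-level events, bounded by
  chromosome ends -- spiked into copy-neutral 0.1x tracks at TF
  0.01-0.10, five replicates each, every replicate an independent
  background (its own genome, donor panel and neutral track) so
  between-sample variance is represented. Losses are applied by binomial read
  thinning and gains by Poisson read augmentation of the observed counts,
  so each bin keeps its own realized noise and bias; an earlier
  residual-resampling design destroyed the per-bin alignment with the
  reference panel and attenuated the spiked signal. Detection means an
  estimated TF at or above 0.03 in a majority of replicates.
* **Sensitivity panel** (`benchmark_sensitivity_panel()`): 0.1x mixtures
  with expected TF > 0.10 (ladder 0.15-0.45, four replicates), classified
  against the 0.10 exome-eligibility threshold.

Problem sizes (54 + 22 + 50 + 36 pipeline runs, each 7 or 21 EM fits)
were chosen so the full suite completes in a few minutes on one core.

What passing these benchmarks does *not* show: the generator draws
independent Poisson counts around a smooth bias -- real cfDNA coverage has
correlated artifacts (fragment-size structure, batch effects, imperfect
panel match) that make real noise heavier and structured; clonal truth is
used throughout, so the subclonal machinery is exercised only as a
nuisance dimension; and hg19 coordinates stand in for a real alignment.
Accuracy on real plasma therefore depends on the quality of the reference
panel in a way these simulations cannot probe.

# Numerical choices and edge cases

* Ties in Viterbi break toward the lowest state index (HETD < NEUT < ...),
  so exact ties cannot invent gains.
* The LOESS curves are evaluated on a 256-point covariate grid and
  interpolated; outside the fitted range the curve is clamped to its
  nearest end. Near-constant covariates skip the fit with a warning
  rather than fitting a degenerate curve. Bins with mappability < 0.9 are
  excluded from fitting and flagged invalid.
* Corrected coverage is scaled to mean 1 over valid autosomal bins --
  mean, not median, because total-read normalization is what the
  $2n+(1-n)\phi$ denominator models.
* `build_reference()` marks bins invalid where the panel median is
  non-positive or undefined; log ratios propagate validity from both
  sample and panel.
* Zero-variance data, fewer than 100 analysis bins, or an all-`-Inf`
  emission row raise errors rather than warnings.
* Restart failures are logged and skipped; only an all-fail raises.

# Limitations

Ploidy is weakly identified from coverage alone; the relabeled-diploid
filter resolves the uniform-genome case, but a genuinely triploid tumor
with no internal copy-number contrast will be reported near TF 0.
Subclonal prevalence is modeled with a single shared $s$ ("one detectable
subclone"), and reported TF does not include the $s$ correction. The
detection limit of ~0.03 TF holds for arm-scale events at 0.1x; focal
events or lower coverage push it up, as the power analysis in
`power_grid()` quantifies for the downstream exome decision. A caveat on
reading the spike-in benchmark: detection there means an estimated TF at
or above the 0.03 cut-off, and because the estimator is calibrated
(neither inflating nor shrinking the event fraction), a sample spiked at
exactly the cut-off exceeds it in only about half of replicates --
the measured limit therefore fluctuates between the 0.03 and 0.04 rungs
of the ladder across simulation seeds.
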