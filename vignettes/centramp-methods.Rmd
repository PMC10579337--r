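---
title: "Quantifying and modelling centrosome amplification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and modelling centrosome amplification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`centramp` implements a complete analysis chain for centrosome
amplification (CA) in high-content immunofluorescence data: per-field
image quantification, cohort-level CA statistics, a hierarchical
mean–variance copula mixed model for the distribution of CA scores, and
two companion genomic analyses (CA20/CIN25 expression-signature scoring
and a compositional test on copy-number-signature exposures). Because
the clinical imaging data such assays produce is access-restricted, the
package ships a first-class synthetic-data generator for every input,
with serialized ground truth, and all statistical claims are validated
against that ground truth.

# The synthetic imaging fields

`simulate_image_field()` renders a four-channel z-stack — DNA, PCM
(pericentriolar material), pHH3 (mitosis marker) and CEP164
(distal-appendage marker) — of planted objects:

* **Nuclei** are soft-edged discs (radial profile $e^{-(d/r)^8}$ in-plane,
  Gaussian along z). The super-Gaussian plateau means a global threshold
  recovers the nominal radius, which a plain Gaussian blob would not.
  Mitotic nuclei are drawn condensed (radius × 0.75, amplitude × 1.8)
  and appear in the pHH3 channel; their centrosomes are still planted,
  because mitotic exclusion is an analysis step, not a staining step.
* **Centrosome spots** are isotropic 3-D Gaussians (default σ = 1.6 px)
  placed within 1.5 nuclear radii of the owner centroid (centrosomes are
  perinuclear), with a minimum pairwise separation of 4σ so the planted
  configuration is optically resolvable. Per-cell spot counts are drawn
  from a configurable distribution; the true per-cell distribution in
  tissue is unknown, so it is a free parameter rather than a baked-in
  assumption.
* **Micronuclei** are small DNA discs with radius 10–35% of the owner's,
  placed fully outside every nucleus within two owner radii. A
  resolvability floor of 1.8 px is applied to the radius: below that a
  DNA body is smaller than the optical grain and no detector could
  recover it, so planting it would only measure the floor of the
  renderer, not the detector.
* **Noise** is Poisson shot noise on signal-plus-background with
  additive Gaussian read noise; `snr` is defined as the peak spot
  amplitude over the background standard deviation. `snr = Inf`
  disables noise entirely, which is what the exact-recovery tests use.

All randomness flows from one root seed through named substreams
(`substream_seed(root, "field", i)` etc.), so each field, channel and
stage is independently reproducible.

What the generator does **not** emulate: realistic PSF side-lobes and
spectral bleed-through, FFPE section artefacts, stromal/tumour texture,
and the partial-volume effects of thick (25 µm) sections. Exact
recovery on these synthetic fields therefore demonstrates that the
quantification logic is correct — ownership, exclusion rules,
arithmetic — not that the segmenter would match a proprietary
commercial pipeline on real tissue.

# Image quantification

The pipeline mirrors a standard high-content workflow: maximum
projection of the z-stack; nuclei segmentation (Gaussian smoothing σ = 2
px → Otsu threshold → hole filling → distance-transform watershed) with
an area band (150–6000 px²) and border-object removal; spot detection by
multiscale Laplacian-of-Gaussian filtering (scales σ·{0.8, 1, 1.25},
scale-normalized, per-pixel max) with a data-relative threshold
(background median + 8 MADs of the response, floored at 15% of the peak
response) and a greedy merge rule — maxima closer than 2σ count as one
spot. Every spot receives a subpixel centre (intensity-weighted centroid)
and an ellipse fitted to its above-half-maximum region; its size is
width × length of that ellipse on the projection, the convention used
for PCM size in tissue. Spots farther than two equivalent radii from
every nucleus are discarded as stromal/background; micronuclei are
detected on a finer mask (σ = 1) and assigned within 2.2 equivalent
radii — slightly wider than the biological two-radius annulus because
thresholded masks underestimate the geometric radius by a few percent.

Every threshold is relative to the data (Otsu, quantiles, MADs), which
gives exact invariance of all counts to global intensity rescaling.

Per-field outputs follow the assay's definitions: CA score =
total centrosomes / total whole nuclei; CA frequency = share of
non-mitotic cells with ≥ 2 centrosomes; MN frequency = share of
non-mitotic cells with ≥ 1 micronucleus; mitotic index = mitotic /
whole cells. Fields with CA score below 0.1 are removed (`qc_min`), the
published guard against staining background.

# Cohort statistics

Per-sample summaries are medians over post-QC fields; tissue
heterogeneity is the standard deviation of log CA scores across fields.
The log base is configurable and natural by default — the choice only
rescales every heterogeneity score by one constant, so comparisons are
unaffected. Normalization divides each sample's median CA by the median
of control samples within its cohort; division (not subtraction) is used
because a control-relative fold is the only reading under which normal
tissue sits at 1 and a threshold of ~1.8 reads as "fold over normal".

The CA threshold is derived from the normal fallopian-tube (FT) sample
with the highest normalized median CA, as the upper bound of the
boxplot-notch 95% CI for its median: median + 1.58·IQR/√n. The notch
formula is used because it is the stated interval convention for
comparing medians in this assay's figures; a bootstrap percentile CI is
available behind `method = "bootstrap"`. Whether the published cutoff
was computed on raw or normalized scores is not documented; the package
defaults to normalized (`threshold_on_normalized = TRUE`) since that is
the scale on which the cutoff is applied, and exposes the choice.
CA calls are strict (`normalized_ca > threshold`); a sample exactly at
the cutoff is negative. Patients with several tissues are summarised by
the median of sample scores, with per-sample calls preserved so
intra-patient discordance stays visible.

# The copula mixed model

Per-field log CA scores are modelled as
$$y_{ij} = x_i^\top\beta + b_i + \sigma_i\,\varepsilon_{ij}$$
with tissue-type fixed effects $\beta$; Gaussian random intercepts
$b_i = \tau u_i$; gamma-distributed random within-tissue SDs
$\sigma_i = e^{x_i^\top\gamma}\,Q_\Gamma(\Phi(v_i);\alpha)$ where
$Q_\Gamma$ is the quantile function of a mean-1 gamma with shape
$\alpha$ (so $\gamma$ is interpretable as log-mean-SD effects and
$E[\sigma_i] = e^{x_i^\top\gamma}$); a Gaussian copula
$\mathrm{corr}(u_i, v_i) = \rho$ linking location and scale; and
standardized Student-t residuals with $\nu$ degrees of freedom (unit
variance, Gaussian as $\nu \to \infty$). The symmetric one-shape t
family realises the heavy-tailed error class; it is isolated behind the
simulation interface so a two-shape generalisation can be substituted.
Modelling is done on the log scale: CA scores are positive and
right-skewed, and the log is the only scale on which an additive model
with these components is coherent. At $\rho = 0, \alpha = \infty,
\nu = \infty$ the model reduces exactly to a homoscedastic Gaussian LMM,
which is both a correctness check and a bridge to standard software.

## Estimation

The likelihood is intractable but simulation is cheap, so estimation is
by indirect inference with an iterative bootstrap. The auxiliary
statistic maps a dataset to a crude plug-in estimate of the full
parameter vector on a transformed scale
$(\beta, \gamma, \log\tau, \log\alpha, \operatorname{atanh}\rho,
\log(\nu-2))$:
regression of tissue means on the design (→ β), regression of log
tissue SDs on the design (→ γ), between-tissue variance of mean
residuals minus the mean within-tissue sampling variance (→ τ²),
trigamma-inverse of the log-SD residual variance (→ α, since
$\operatorname{Var}\log\sigma_i = \psi_1(\alpha)$ for a mean-1 gamma),
the correlation of the two residual series (→ ρ), and the pooled excess
kurtosis of within-tissue standardized residuals (→ ν, via
$6/(\nu-4)$). Each coordinate is biased in finite samples — that is
fine, because the iterative bootstrap
$$\theta^{(k+1)} = \theta^{(k)} + \lambda\,[\hat\pi_{\mathrm{obs}} -
\bar\pi_H(\theta^{(k)})]$$
matches observed and simulated statistics *under the same map*, which
removes the bias at the fixed point. Common random numbers across
iterations make $\bar\pi_H$ smooth in $\theta$; defaults are damping
λ = 0.5, H = 100 simulations per iteration, sup-norm tolerance 0.01,
at most 100 iterations. Divergence (five consecutive growing updates)
raises an error suggesting stronger damping.

Two consequences of the kurtosis route to ν are worth knowing: the tail
parameter is only identified for ν > 4 (finite kurtosis), and on
Gaussian-like data the ν and α coordinates drift to their upper clamps
(≈ 10⁵ on the transformed scale) rather than diverging — estimates
there should be read as "at the Gaussian boundary", not as finite
values.

## Uncertainty and validation

Confidence intervals come from the indirect-inference sandwich:
numerically differentiate the binding function (central differences,
common random numbers) to get $J$, estimate the auxiliary covariance
$\Sigma$ from independent simulations at the estimate, and use
$\operatorname{Var}(\hat\theta) = (1 + 1/H)\,J^{-1}\Sigma J^{-\top}$;
the $1/H$ term accounts for simulation noise in the matched average.
Intervals are built on the transformed scale and back-transformed, so
positivity and range constraints are respected automatically. Wald
p-values are reported only where a zero null is meaningful (β, γ
coordinates, and ρ via atanh ρ); τ, α and ν are positivity/boundary
parameters and get intervals only. A parametric bootstrap is available
as a slower cross-check.

`coverage_experiment()` validates the whole chain: simulate at known
parameters, fit, build 95% intervals, and report per-parameter
empirical coverage with Monte-Carlo standard errors. At the package's
study conditions (60 tissues split 20/40, 25 fields each, τ = 0.3,
α = 4, ρ = 0.5, ν = 8, contrasts of 0.5; 200 replicates) all eight
parameters cover within a few Monte-Carlo standard errors of 0.95, and
`bias_experiment()` shows per-parameter bias shrinking as the tissue
count grows through 25 → 200. Boundary truths (τ = 0) are expected to
undercover — intervals on log τ cannot reach 0 — and such runs should
be read via the bias table, not the coverage line. Replicates whose fit
does not converge (a few percent at these sizes) are excluded from the
coverage denominator and reported as a rate.

Problem sizes throughout (60 tissues × 25 fields, 200 replicates,
H = 100) were chosen as the smallest sizes at which the Monte-Carlo
error of a coverage estimate (≈ 0.015) is well below the width of the
claim being checked.

# Signature scoring and compositional testing

CA20/CIN25 scores are per-sample sums of log2 median-centred expression
over the signature genes, after quantile normalization for count-scale
input (`limma::normalizeQuantiles`; ties share the averaged reference
value). The log transform is `log2(x + 0.5)` on the normalized scale.
Because median-centring subtracts a per-gene constant, a planted
between-group shift of Δ log2 units on the 20 CA20 genes moves the
group score gap by exactly 20Δ — the generator/test pair exploits this
closed form. High/low labels are a median split with ties assigned low
(deterministic). Missing signature genes are refused by default and
listed; `allow_partial` scores the present subset.

Copy-number-signature exposures (7 parts summing to 1) are tested via
the additive log-ratio transform with signature 7 as denominator
(coordinates $\ln s_k/s_7$), zeros replaced by half the smallest
positive exposure. The group test regresses all six coordinates jointly
on the group indicator and tests the six contrasts simultaneously —
Hotelling's T² form of the Wald statistic with the exact
$F(q, n-q-1)$ reference, which holds its size exactly under Gaussian
coordinates (the generator's regime) and is asymptotically the
chi-square Wald otherwise. A multivariate regression was chosen over
stacked univariate fits because the global null concerns the joint
shift, and the coordinate errors are correlated by closure.

# Repository layout

The computation lives in the package (`R/`); the numbered scripts under
`analysis/` are thin drivers that generate the simulated study inputs
(`01`), quantify the imaging fields against truth (`02`), run the
cohort statistics (`03`), fit and validate the mixed model (`04`) and
run the genomic analyses (`05`), writing their tables under `results/`.
`scripts/acceptance.R` re-runs the full 200-replicate coverage
experiment from scratch.

# Known limitations

* The segmentation/detection stack is validated on the package's own
  synthetic fields; real FFPE tissue adds artefact classes the
  generator deliberately omits, and parameters (area bands, MAD
  multipliers) would need re-tuning per assay.
* ν is estimated through kurtosis and is effectively capped below by 4;
  extremely heavy tails are reported at the cap.
* The compositional test assumes exchangeable samples within group; it
  does not model patient-level clustering of exposures.
* `wilcox`/Kruskal comparisons treat fields or samples as independent;
  for spatially adjacent imaging fields this overstates the effective n,
  which is precisely the motivation for the mixed model.
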