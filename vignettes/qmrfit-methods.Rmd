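---
title: "Models and numerical methods in qmrfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in qmrfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrfit)
```

`qmrfit` fits voxelwise signal models to 4D MR series through one shared
least-squares engine. This vignette documents the models, the numerical
choices behind them, the tunable parameters with their defaults and units,
and what the synthetic phantoms do and do not demonstrate.

## The shared fitting engine

Every modality reduces to one of three solvers.

**Linear and weighted least squares.** `solve_ls()` solves the normal
equations b = (AᵀA)⁻¹Aᵀy; `solve_wls()` uses b = (AᵀWA)⁻¹AᵀWy with a
diagonal precision matrix W. Rank-deficient designs are an error: a
voxelwise fit should fail loudly rather than return one of infinitely many
solutions.

**Non-negative least squares.** `solve_nnls()` implements the
Lawson–Hanson active-set algorithm. It is used wherever the unknowns are
physically non-negative component amplitudes (multi-exponential T1/T2
spectra, EPG spectra). The entering variable is the one with the largest
positive gradient; ties break to the lowest index so the algorithm is fully
deterministic. The test suite checks it against exhaustive enumeration of
all active sets on random 3-parameter systems.

**Damped Gauss–Newton (Levenberg–Marquardt).** `fit_nonlinear()` iterates

b ← b + (AᵀA + λ diag(AᵀA))⁻¹ Aᵀ(y − f(b))

with A the Jacobian of the model at b. Defaults (all overridable via
`solver_config()`): initial damping λ₀ = 1 (λ₀ = 0 gives pure
Gauss–Newton), damping divisor r = 10 applied after every accepted step
(λ ← λ/r), maximum 100 iterations, and a stopping rule on the relative
change of the total squared residual R (tolerance 1e-8). These defaults
were chosen as conventional LM settings; the damping schedule itself (divide
by r per accepted iteration) is the defining behaviour. Three further
choices close gaps the update rule alone leaves open:

* **Step rejection.** A step that increases R is rejected and λ multiplied
  by r — the standard LM trust-region heuristic.
* **Stalled convergence.** If λ exceeds 1e14 the proposed steps have become
  numerically zero; provided at least one step was accepted, the fit is
  reported converged ("stalled at a minimum within Jacobian precision").
  Only exhausting the iteration cap reports non-convergence. A relative
  residual floor (R ≤ 1e-20 Σy²) likewise counts as converged, so noiseless
  data with a near-exact initialisation does not spin.
* **Bounds.** Box bounds are enforced by clipping after each step, and an
  optional projection callback handles joint constraints (the NODDI fraction
  simplex). Clipping is simple and deterministic; for the interior optima of
  all phantoms used here it is never active at the solution.

Jacobians default to central finite differences with relative step 1e-6
(absolute floor 1e-4 per parameter); linear models pass analytic Jacobians.
The NODDI family uses finite differences for **all** six parameters: the
orientation and dispersion derivatives have no convenient closed form under
the discrete Watson quadrature, and benchmarking showed the fraction/S0
derivatives are too cheap for an analytic special case to matter.

**Error maps.** Parameter uncertainty is reported as σ²(AᵀA)⁻¹ with
σ² = R/(m − n) (A = design or final Jacobian), serialised as the n
variances followed by the n(n−1)/2 upper-triangle covariances in row-major
order — n(n+1)/2 volumes in total, e.g. 3 for a two-parameter fit. The σ²
estimator is the usual unbiased residual-variance estimate for
independent, identically distributed Gaussian errors.

## Units and I/O conventions

All times are milliseconds internally; b-values are s·mm⁻²; diffusivities
mm²/s; CBF is reported in ml/100g/min (the unit conversions of the ASL
equations happen inside those equations only). b-vectors are read in
FSL dialect (3 whitespace-delimited rows of T entries) and interpreted in
the image voxel frame; b > 0 directions must be unit-norm within 1e-3.
Voxel and slice selections are 0-based. Negative signal values (possible
after cubic resampling of acquired data) are kept for linear fits but
excluded per-observation from any log-transform (ADC, tensor, T2 start
values). Voxels outside the mask are exactly zero in all outputs, and every
output NIfTI copies the source affine and header geometry.

## ASL perfusion

`cbf_pcasl()`/`cbf_pasl()` implement the consensus single-compartment CBF
equations; constants default to λ = 0.9 ml/g, T1_blood = 1650 ms, labelling
efficiency α = 0.85 (PCASL) or 0.98 (PASL) — all flags. For 2D read-outs
the post-labelling delay grows slice-wise, PLD_k = PLD + k·dPLD. The M0
normalisation volume may be a measured proton-density image or the S0 map
of a saturation-recovery T1 fit (`fit_t1_single`), which uses the same
millisecond conventions, so the two-step pipeline has no unit mismatch.

Outlier rejection (`reject_outlier_pairs()`) summarises each control/label
repeat by its mean within-mask intensity — of the pairwise difference
("difference" mode) or of each raw volume ("raw" mode, rejecting the repeat
if either volume is an outlier) — and drops repeats with |z| above a
threshold (default 2.5). A zero-variance summary set rejects nothing, so
identical repeats pass through untouched. Rejection happens **before**
pair averaging; the equations then use the means of the kept repeats.
Negative CBF values are retained (they are legitimate noise outcomes in
low-perfusion regions), and motion correction is out of scope — series are
assumed pre-corrected.

Partial-volume correction follows the local-regression idea: within an
n×n (2D) or n×n×n (3D) kernel the GM and WM CBF are assumed constant, and
[gm_frac, wm_frac] · [CBF_gm, CBF_wm]ᵀ = CBF is solved by least squares.
Rank-deficient kernels (e.g. pure-GM neighbourhoods) are flagged rather
than fatal; the single-tissue estimate is still returned where it is
well-defined. Kernel size is arbitrary by construction, so the corrected
maps are interpretive, not quantitative — the same caution as the original
method.

## T1 relaxometry

Single-component fits solve [S0, T1] in the saturation- or
inversion-recovery models by LM, initialised at S0 = max signal and
T1 = median TI unless a 4D init map is supplied (initialisation applies to
the nonlinear routines only). Multi-component fits are linear: NNLS over a
basis of recovery curves at fixed grid T1s — each basis column uses its own
component T1ᵢ — then normalisation so fractions sum to 1 with S0 factored
out. Inversion-recovery magnitude data whose sign was lost near the null
point is *not* polarity-restored; fits assume real-valued (signed) data.
This is a documented limitation.

## T2 relaxometry and the EPG model

Single-component T2 fits are nonlinear in [S0, T2], started from the
log-linear solution over the positive samples. Multi-component fits are
NNLS over exp(−TE/T2ᵢ) at fixed grid T2s; the myelin water fraction is the
fraction sum for components with T2 below a threshold (default 50 ms,
`-mwfthreshold`). Optional voxelwise priors enter as a Tikhonov pull:
rows √s·I are appended to the design with targets √s·S0·prior, where s is
the prior strength (default 0 = off) and S0 comes from a first NNLS pass.
A penalty (rather than a hard constraint) was chosen because the prior is
itself an imperfect segmentation-derived estimate; s = 0 recovers the
unconstrained fit exactly.

**EPG.** Refocused (CPMG) echo trains with refocusing angle α < π generate
stimulated echoes; `epg_forward()` simulates the echo amplitudes with the
extended-phase-graph recursion: per half echo-spacing, T2 decay of
transverse configuration states, T1 decay plus regrowth of longitudinal
states, and a unit shift of the dephasing order; each pulse mixes
(F⁺ₖ, F⁻ₖ, Zₖ) with the standard rotation matrix. Because the excitation is
90° out of phase with the refocusing pulses, the complex state space splits
into two closed *real* subspaces — the in-phase transverse pathway and a
quadrature pathway fed by regrown longitudinal magnetisation — so the
recursion runs entirely in real arithmetic and the echo combines the two in
quadrature. The test suite verifies this implementation to 1e-10 against a
naive full-complex reference and to 1e-9 against the analytic
mono-exponential limit at α = π. Longitudinal relaxation uses a fixed
T1 = 1000 ms by default (configurable); within a 384 ms echo train its
influence is small but not negligible at late echoes. The excitation pulse
is assumed exactly 90°: only the refocusing angle varies with B1.

`fit_t2_epg()` estimates the refocusing angle per voxel by a 1D search:
residuals of NNLS spectral fits over EPG basis curves on a 64-point α grid
over [0, π] (bases precomputed once per call), then golden-section
refinement of the bracket to 1e-3 rad. Flat signals leave α undefined and
are flagged. The α map is the B1 output, in radians.

## Diffusion models

`fit_adc()` offers both log-linear and nonlinear mono-exponential fits —
they agree on noiseless data and differ under noise exactly where the
log-transform distorts the error distribution. `fit_dti()` is the standard
log-linear tensor fit with design rows
(1, −b gx², −2b gx gy, −2b gx gz, −b gy², −2b gy gz, −b gz²); the mcmap
stores the six tensor elements then S0. Eigenvalues are sorted descending
and the principal direction's sign is fixed to non-negative z (then y,
then x) so outputs are deterministic.

**NODDI.** Three compartments: Watson-dispersed sticks (intra-cellular),
an anisotropic Gaussian (extra-cellular), and free water:
S = S0(v_in A_in + v_ex A_ex + v_iso e^(−b d_iso)), v_ex = 1 − v_in − v_iso.
Fixed diffusivities: d_iso = 3×10⁻³ mm²/s and d_∥ = 1.7×10⁻³ mm²/s (the
standard intrinsic diffusivity; flag-overridable). The stick response is
e^(−b d_∥ (r·n)²) — quadratic in the direction cosine, the only
dimensionally consistent form. The extra-cellular radial diffusivity is
tortuosity-coupled, d_⊥ = d_∥(1 − v_in), reflecting the coupled
intra/extra-cellular space. The Watson average uses a deterministic
Fibonacci-sphere point set (default 724 directions) with weights
proportional to the Watson density exp(κ(μ·n)²), normalised over the set —
no RNG enters the forward model, and doubling the sampling changes signals
by < 1e-4. The dispersion parameter γ ∈ [0, 1] maps to concentration by
κ = 1/tan(γπ/2), so γ behaves as an orientation-dispersion index (γ → 0
parallel, γ = 1 isotropic); below γ = 1e-5 the forward model switches to
the analytic zero-dispersion stick to avoid a degenerate discrete density.
The extra-cellular tensor uses the same weights through the Watson-averaged
orientation tensor, keeping both compartments consistent.

`fit_noddi()` initialises from a tensor fit of the same data — orientation
from the PDD, v_iso from where MD sits between tissue and free-water
diffusivity, v_in from FA (both clamped to the open simplex), γ = 0.4 —
and runs LM over [v_in, v_iso, γ, S0, θ, φ] with fractions projected onto
the simplex after each step. Orientation is parameterised by unbounded
spherical polars during optimisation (the model is smooth and antipodally
symmetric there) and canonicalised to θ ∈ [0, π], φ ∈ [0, 2π), z ≥ 0 on
output, which avoids boundary artefacts for fibres along +z.

## Multi-modal extensions

**TE-augmented NODDI** (`fit_noddi_te()`) multiplies the tissue compartments
by e^(−TE/T2_wm) and the free-water compartment by e^(−TE/T2_iso), with
fixed T2_wm = 80 ms and T2_iso = 400 ms defaults (flags). Only the b = 0
volumes vary in TE in the intended acquisition; at b = 0 the model is a
two-component T2 decay, which is what ties v_iso across the two contrasts.
With a single distinct TE the model is TE-blind and the fit falls back to
standard NODDI with a warning.

**g-ratio.** The aggregate g-ratio is Γ = (v_mwf/v_in′ + 1)^(−1/2) with
v_in′ = v_in(1 − v_mwf), since the diffusion model sees no myelin signal
and its fractions must be rescaled by (1 − v_mwf). `gratio_two_step()`
combines independently fitted v_in (NODDI) and v_mwf (multi-component T2)
maps. `fit_joint_gratio()` instead optimises both data blocks at once: the
DWI block keeps its own S0, v_in, γ and orientation; the T2 block is a
three-compartment decay (myelin / tissue / free water) with its own S0 and
fixed compartment T2s — the myelin-water T2 defaults to 20 ms, a standard
short-pool value the two-step spectrum grid uses as well; Γ and v_iso are
single shared unknowns. Γ is parameterised directly and v_mwf derived by
inverting the g-ratio relation (v_mwf = c/(1+c), c = v_in(1−Γ²)/Γ²), which
makes the coupling self-consistent by construction — the alternative,
penalising disagreement between separately parameterised fractions, adds a
weight with no principled value. The four-compartment fractions
(v_mwf, v_in′, v_ex′, v_iso′) sum to one identically under this
bookkeeping. The DWI residual block is down-weighted (default
weight 0.2, i.e. residuals scaled by √0.2) so the T2 data dominate the
shared v_iso — the diffusion estimate of v_iso is the noisier of the two.
If the joint fit fails to converge, the voxel falls back to the two-step
result and is flagged.

## Synthetic phantoms: what they show and what they don't

`generate_phantom()` builds three-slab block phantoms (tissue-A / tissue-B /
fluid along x) with literature-plausible values — T2 {45, 80, 400} ms,
T1 {1400, 800, 4000} ms, CBF {60, 20, 0} ml/100g/min with a 3:1 GM:WM
ratio, NODDI v_in {0.6, 0.4, 0} with v_iso = 1 in fluid — and
forward-simulates the series under each modality's own signal model, adding
Gaussian noise with σ = mean(S0)/SNR. Identical (spec, seed) inputs are
bit-identical. Block truths (not smooth fields) keep recovery tolerances
sharp. The diffusion schedule reproduces a realistic 3-shell design:
12 b = 0 volumes plus 8/32/72 directions at b = 300/700/2000 s·mm⁻²; the
refocused T2 train is 32 echoes at 12 ms spacing; PCASL uses 30
control/label pairs with 1650 ms label duration and 1800 ms PLD; PASL uses
TI₁ = 800 ms, TI₂ = 2000 ms.

Validation problem sizes, chosen as the package's standard checks: a
20×20×3 EPG phantom at α = 2.6 rad and SNR 200 (recovered α within
0.05 rad, myelin fraction bias within 0.02, and at least twice that bias
when EPG is disabled); a 500-voxel three-region NODDI phantom fitted
noiselessly to within 0.01 in all fractions and 2° in orientation — the
acceptance phantom uses three *tissue-like* regions because γ and the
orientation are undefined where v_iso = 1; a TE-augmented phantom with
v_iso = 0.25 where the TE-aware fit recovers v_iso within 0.02 while the
TE-blind fit is biased by far more; and 200 seeded noise draws at SNR 50
for the joint-vs-two-step g-ratio comparison, where the coupled estimator's
sampling spread is no larger than the two-step one. SNR 50 is typical of
the b = 0 / early-echo signal in such acquisitions.

Because generation and fitting share the same forward models, these
phantoms demonstrate *estimator correctness and identifiability*, not
robustness to model misspecification. Real data additionally contain
Rician (magnitude) noise — available in the generator behind
`noise_model = "rician"` for robustness experiments, but not the validation
condition, since the fitting assumes Gaussian errors — plus motion, partial
volume at region boundaries, slice-profile and excitation-B1 effects,
exchange between water pools, and multi-fibre voxels. None of those are
emulated.

## Known limitations

* Gaussian noise model throughout; no Rician-likelihood fitting (high-b
  diffusion data at low SNR will bias d upward in the log-linear route —
  both ADC routes are exposed so the difference is measurable).
* IR polarity is not restored for magnitude data.
* Single-fibre NODDI only; no multi-delay ASL kinetics; no IVIM; no
  Bayesian posteriors (the -error maps are local Gaussian approximations).
* Bound handling by clipping is exact only for interior solutions;
  estimates pinned at a bound have optimistic error maps.
* Registration, resampling and brain extraction are out of scope — inputs
  are assumed co-registered.
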