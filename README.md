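# qmrfit

Multi-parametric quantitative MRI model fitting in R.

`qmrfit` is for researchers who quantify tissue properties from 4D MR image
series: perfusion from arterial spin labelling (ASL), relaxation times from
multi-TI/multi-echo acquisitions, and microstructure from diffusion-weighted
imaging. Every modality is fitted voxelwise through one shared least-squares
engine, so the same machinery also supports *joint* models that couple two
modalities — TE-augmented NODDI and MRI g-ratio mapping.

## What it computes

All fits minimise the residual of a forward signal model per voxel using
ordinary, weighted or non-negative least squares, or damped Gauss–Newton
iteration

b_{t+1} = b_t + (AᵀA + λ diag(AᵀA))⁻¹ Aᵀ Δy,  λ_{t+1} = λ_t / r,

where A is the model Jacobian (Levenberg–Marquardt; λ = 0 gives pure
Gauss–Newton).

| Modality | Model | Key outputs |
|---|---|---|
| ASL (PCASL/PASL) | CBF = 6000λ/(2α) · e^(PLD/T1b) / (T1b(1−e^(−τ/T1b))) · ΔS/S_PD (consensus single-compartment forms) | CBF [ml/100g/min], outlier-filtered pairs, Asllani partial-volume-corrected GM/WM CBF |
| T1 relaxometry | S₀(1−e^(−TI/T1)) (SR) or S₀(1−2e^(−TI/T1)+e^(−TR/T1)) (IR); NNLS over a fixed T1 grid for spectra | T1 and S₀ maps, component fractions (Σvᵢ = 1) |
| T2 relaxometry | S₀e^(−TE/T2); NNLS multi-exponential spectra; extended-phase-graph (EPG) basis for refocused trains | T2 maps, spectra, myelin water fraction (Σ of T2 < 50 ms fractions), per-voxel refocusing angle (B1) map |
| Diffusion | ADC, log-linear diffusion tensor, NODDI (Watson-dispersed sticks + tortuosity zeppelin + free water) | S₀/d, tensor + MD/FA/PDD, v_in, v_iso, orientation dispersion γ |
| Multi-modal | TE-aware NODDI (variable-TE b0s); g-ratio Γ = (v_mwf/v_in′ + 1)^(−1/2), v_in′ = v_in(1−v_mwf), two-step or coupled | v_iso untangled from T2, Γ maps |

A seeded phantom generator (`generate_phantom()`) forward-simulates every
modality from known region-wise parameter maps with Gaussian noise, so each
fitting route can be validated by simulate-and-recover.

## Worked example

Simulate a 32-echo refocused T2 acquisition with an imperfect refocusing
angle (2.6 rad instead of the nominal π), then fit it with and without the
EPG stimulated-echo model:

```r
library(qmrfit)

ph <- generate_phantom("t2epg", shape = c(6, 6, 2), snr = 200, seed = 1)
fit <- fit_t2_epg(ph$voxels, ph$schedule, ph$truth$t2_grid_ms)
mean(fit$b1map)
#> mean refocusing angle (rad): 2.606

mwf <- compute_mwf(fit$mcmap[, , , 1:3, drop = FALSE], ph$truth$t2_grid_ms)
tapply(mwf, ph$truth$region, mean)
#> mean MWF by region: 0.151 0.099 0.002

blind <- fit_t2_multicomponent(ph$voxels, ph$schedule, ph$truth$t2_grid_ms)
mwf_b <- compute_mwf(blind$mcmap[, , , 1:3, drop = FALSE], ph$truth$t2_grid_ms)
tapply(mwf_b, ph$truth$region, mean)
#> mean MWF by region (no EPG): 0.073 0.018 0

gratio_two_step(0.514, 0.141)$gratio
#> 0.8706
```

The phantom's true myelin water fractions are 0.15 / 0.10 / 0 in its three
regions. The EPG fit recovers them (0.151 / 0.099 / 0.002) together with the
refocusing angle (2.606 vs 2.6 rad truth); the TE-blind multi-exponential
fit on the same data misattributes the stimulated-echo signal and halves the
short-T2 component (0.073 / 0.018) — the reason EPG correction matters for
myelin water imaging. The last line evaluates the g-ratio for typical
white-matter volume fractions.

## Command-line interface

Thin wrappers over the package functions live in `inst/cli/` (after
installation: `system.file("cli", package = "qmrfit")`): `fit_asl.R`,
`fit_qt1.R`, `fit_qt2.R`, `fit_dwi.R`, `fit_gratio.R`, `make_phantom.R`.
They read/write NIfTI volumes and plain-text schedule files (FSL-style
bval/bvec, tab-delimited TE/TI row vectors):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", package = "qmrfit"))')
Rscript $CLI/make_phantom.R --modality dwi_dti --shape 16,16,4 --snr 50 --outdir ph
Rscript $CLI/fit_dwi.R --source ph/series.nii.gz --bval ph/bvals --bvec ph/bvecs \
        --dti --mcmap dti.nii.gz --fa fa.nii.gz --md md.nii.gz
```

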