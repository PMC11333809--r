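# dynpet

Quantitative dynamic FDG-PET brain imaging without arterial blood sampling.

Measuring the cerebral glucose uptake rate Ki from a 60-minute dynamic
FDG-PET scan requires the arterial plasma input function C<sub>p</sub>(t).
`dynpet` derives it non-invasively from the internal carotid arteries: the
image-derived input function (IDIF) is extracted from a carotid
segmentation, then corrected for the partial-volume and spillover
degradation that the scanner's ~4 mm point-spread function inflicts on
vessels of comparable size. The corrected input (MCIF, model-corrected
input function) feeds Patlak graphical analysis,

&nbsp;&nbsp;&nbsp;&nbsp;C<sub>t</sub>(t)/C<sub>p</sub>(t) = Ki ·
&int;<sub>0</sub><sup>t</sup> C<sub>p</sub>(&tau;)d&tau; / C<sub>p</sub>(t) + V,

whose slope yields a voxelwise Ki map; regional means are standardized
across 36 brain super-regions and regions with z < −2 are flagged as
hypometabolic (a seizure-focus marker in epilepsy work-ups).

The correction model is a 15-parameter compartment system — a 7-parameter
Feng-type plasma input, two-tissue rates (K1, k2, k3, k4) and four mixing
coefficients (blood/tissue recovery and mutual spillover):

&nbsp;&nbsp;&nbsp;&nbsp;IDIF = r<sub>b</sub>·C<sub>p</sub> + s<sub>t</sub>·C<sub>t</sub>,
&nbsp;&nbsp;tissue = s<sub>b</sub>·C<sub>p</sub> + r<sub>t</sub>·C<sub>t</sub>.

It is inverted two ways: multi-start bounded nonlinear least squares with a
peak-weighted cost (`fit_mcif()`), and a recurrent network (LSTM stack with
a bidirectional GRU block, `train_mcif_net()`) that learns the IDIF→MCIF
mapping directly. Carotid segmentation is likewise available classically
(threshold + 26-connected island analysis) and as a 3D U-Net with
squeeze-and-excitation blocks trained on a combined Dice + binary
cross-entropy loss — both networks are implemented natively (C++ GEMM
convolutions, hand-derived backpropagation) with no external deep-learning
runtime.

Everything is exercised on synthetic 4D phantoms (`generate_phantom()`)
whose ground truth — carotid geometry, plasma curve, per-region kinetics,
analytic Ki — is known exactly, so every stage can be scored against truth.

## Worked example

Simulate a default study (38 frames / 60 min, 64³ @ 2 mm, 4.1 mm PSF,
count-dependent noise) with a 30% focal Ki reduction injected into region 7,
then run the full pipeline:

```r
library(dynpet)

spec   <- phantom_spec(seed = 21)
rates  <- inject_hypometabolic_region(
            default_region_tissue_params(36, seed = 21), 7, 0.30)
study  <- generate_phantom(spec, region_params = rates, seed = 21)

cfg <- pipeline_config(phantom = NULL, volume = study$volume,
                       region_labels = study$truth$region_labels,
                       brain_mask    = study$truth$brain_mask,
                       seg_mode = "classic", n_starts = 2, seed = 21)
res <- run_pipeline(cfg)

res$frame_index
#> [1] 4
res$mcif_fit
#> mcif_fit_result: cost 5037 (peak 137, curve 4.9e+03, anchor 0.195), converged: TRUE
#>   mixing: rb=0.846 st=0.154 sb=0.002 rt=0.998; MCIF peak 1.206e+04 Bq/cc
subset(res$report, hypometabolic)
#>   region_id n_voxels    mean_Ki   z_score hypometabolic
#> 7         7     1855 0.03390461 -4.026432          TRUE
```

Frame 4 (30–40 s post injection) is the bolus-transit frame; the classical
segmenter recovers the carotid tubes from it (Dice 1.0 against truth here),
and the corrected input's peak (~12 kBq/cc) exceeds the partial-volume
diluted IDIF peak (~9.7 kBq/cc). Region 7 sits 4 SD below the across-region
mean Ki and is the only flagged region. The absolute scale of a fitted
input is only weakly identified on noisy data (see the methods vignette);
the z-score endpoint is exactly invariant to it.

The same stages are scriptable individually (`select_reference_frame()`,
`threshold_islands_segment()` / `predict_mask()`, `extract_tac()`,
`fit_mcif()` / `predict_mcif()`, `ki_map()`, `regional_zscores()`), and a
thin command-line front end ships in `inst/exec/dpet` with subcommands
`simulate`, `select-frame`, `motion-correct`, `segment`, `idif`,
`mcif-fit`, `patlak`, `report` and `run-all`.

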