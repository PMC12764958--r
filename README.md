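# porhmeso

Layer-resolved analysis of cutaneous microvascular endothelial function from
raster-scan optoacoustic mesoscopy (RSOM) during post-occlusive reactive
hyperemia (PORH) tests — together with a fully synthetic imaging chain
(vascular skin phantoms → broadband acoustic forward model → dual-band
delay-and-sum reconstruction → surface flattening and skin-layer
segmentation) so that every stage can be exercised and validated with known
ground truth.

The package is aimed at researchers working on optoacoustic/photoacoustic
skin imaging and on microvascular function testing: it provides the
biomarker definitions and statistics used to compare subject groups (e.g.
smokers vs. non-smokers, cardiovascular disease vs. matched controls), and a
simulation framework for testing how reliably those biomarkers are recovered
from noisy measurements.

## The model

During a PORH test (baseline — arterial cuff occlusion — release), the mean
RSOM image intensity of a skin layer follows a characteristic course:
constant at baseline, decaying toward a floor while the cuff blocks inflow,
then overshooting after release (reactive hyperemia) before relaxing back.
On the baseline-normalized scale the package models this as a piecewise
curve whose three parameters are the endothelial-function biomarkers:

* **MVC** (maximum volume change): the occlusion curve decays toward
  `1 − MVC`;
* **HR** (hyperemia ratio): the post-release peak equals `1 / (1 − HR)`, so
  `HR = (PIV − MVB) / PIV` in percent;
* **TP** (time-to-peak): the peak occurs `TP` minutes after cuff release.

Estimation follows the window-statistic definitions: `MVB` is the mean over
the baseline window, `MVIC` the mean over the occlusion window, `PIV` the
post-release peak, and

```
MVC = MVB − MVIC        HR = 100 · (PIV − MVB) / PIV        TP = t(PIV) − t_release
```

Layers are the epidermis (EP), subpapillary dermis (SD), reticular dermis
(RD) and the whole dermal vasculature (DV = SD ∪ RD), obtained by flattening
the skin surface and splitting depth at the epidermal boundary.

Two cuff protocols are built in: `long` (2 min baseline / 5 min occlusion /
3 min recovery) and `short` (1/3/2 min), at a 1 s frame interval (0.5 s
supported).

## Worked example

Fit the PORH response of a single subject and read off the biomarkers:

```r
library(porhmeso)

prot  <- porh_protocol("long")                                # 2/5/3-min PORH
truth <- hemodynamic_params(mvc = 0.48, hr = 0.2038, tp = 1.42)
tt    <- protocol_times(prot)
set.seed(7)
y   <- pmax(hemodynamic_modulation(truth, prot, tt) + rnorm(length(tt), 0, 0.02), 0)
fit <- porh_fit(tt, y, protocol = prot)
fit
#> PORH response fit (layer DV, long protocol)
#> biomarkers [DV]: MVB 1.0000 | MVIC 0.5432 | PIV 1.2377 @ 8.35 min
#>   MVC 0.4568  HR 19.21%  TP 1.350 min
```

The fitted MVC 0.457, HR 19.2% and TP 1.35 min recover the configured
truths (0.48, 20.38%, 1.42 min) to within the estimator's resolution: the
occlusion window retains a small inflow transient (which lowers MVC
slightly) and the peak is located to about one frame. `coef()`, `plot()`,
`predict()`, `residuals()` and `simulate()` behave as for any fitted model.

Group comparison on synthetic cohorts drawn from the built-in presets:

```r
pre <- cohort_presets()
bm_s <- cohort_biomarkers(generate_cohort(pre$smoker,    "DV", prot, 0.02, seed = 42))
bm_n <- cohort_biomarkers(generate_cohort(pre$nonsmoker, "DV", prot, 0.02, seed = 43))
compare_groups(bm_s$MVC, bm_n$MVC, labels = c("smoker", "nonsmoker"))
#> smoker: 0.3549 +/- 0.06454 (n=10)  vs  nonsmoker: 0.458 +/- 0.05203 (n=10)
#>   unpaired t test: statistic -3.934, p = 0.001047 (significant at alpha = 0.05)
```

The comparison applies a per-group Shapiro–Wilk normality gate and falls
back to the unpaired Wilcoxon rank-sum test for non-normal samples.

For the imaging chain, see `simulate_raw_scan()` / `beamform()` /
`dual_band_reconstruct()` (10–40 MHz and 40–120 MHz bands), `mip()`,
`detect_surface()` / `flatten()` / `segment_layers()`, and
`vessel_fwhm()` / `total_blood_volume()` / `depth_resolved_tp()` for the
image-derived metrics. `run_porh_pipeline()` (or
`inst/scripts/run_porh.R` from a shell) orchestrates an end-to-end run from
a YAML configuration.

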