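# angiocal

Multilevel calibration of a hybrid agent-based/continuum model of
tumor-induced angiogenesis.

## The problem

In a 3D microfluidic platform, breast cancer cells seeded in collagen
around an endothelialized parent vessel secrete VEGF and induce
angiogenic sprouting that can be followed for weeks by confocal
microscopy. Linking a mechanism-based model to such data requires
calibrating parameters that live at different scales: per-cell VEGF
production and consumption rates (from plate experiments), the stalk
cell divide time that sets how fast sprouts elongate (from sprout
length measurements), and the spacing at which new tip cells activate
(from vascular density images).

`angiocal` implements that whole chain for modelers who want to
calibrate sprouting models against multimodal data:

* ODE models of cell growth and VEGF kinetics with daily media resets
  to a 1100 pg/mL baseline (`endothelial_growth`, `tumor_growth`,
  `vegf_trajectory`, `elisa_daily_series`);
* generic Bayesian machinery — uniform priors, iid Gaussian likelihood
  `-N/2·log(2πσ²) − φ(m)/(2σ²)`, naive grid quadrature,
  Metropolis–Hastings, Gaussian posterior fits (`quadrature_posterior`,
  `metropolis_hastings`, `fit_gaussian`);
* an agent-based sprouting model — tip activation above a VEGF
  threshold with minimum tip spacing `d_tip`, division-limited
  elongation at rate `2R/(d_sc + g_sc)`, chemotaxis under a
  compact-support potential, anastomosis, secretion shutoff — coupled
  to an explicit reaction–diffusion VEGF field
  (`simulate_angiogenesis`);
* the vessel-image pipeline: z-projection, intensity + area
  thresholding, density profiles, Dice-based region selection,
  Zhang–Suen skeletonization and bidirectional mean centerline
  distances (`project_and_binarize`, `skeletonize`,
  `centerline_distance`);
* the five calibration scenarios (`scenario1_growth` …
  `scenario5_local`), uncertainty propagation with 1- or 4-parameter
  sampling (`predict_with_uncertainty`) and centerline prediction
  envelopes (`prediction_envelope`);
* synthetic-data generators for every input — cell counts, ELISA
  series, platform scenes, confocal-like stacks — each emitting ground
  truth beside the noisy observation (`gen_*`).

See `vignettes/angiogenesis-calibration.Rmd` for the models,
assumptions and numerical choices.

## Worked example

Calibrate growth and VEGF kinetics from synthetic plate data, then the
sprout elongation rate from the observed mean sprout lengths:

```r
library(angiocal)

cfg    <- synth_config(elisa_rel_sd = 0.05)          # study conditions
counts <- gen_cell_counts(synth_config(count_cv = 0.05), seed = 42)
elisa  <- gen_elisa_series(cfg, seed = 42)

s1 <- scenario1_growth(counts$tumor, counts$endothelial)
unlist(lapply(s1$mle$growth, signif, 3))
#> lambda_e_g    theta_e lambda_T_g
#>   3.98e-02   2.71e+05   8.53e-03

s2 <- scenario2_vegf(elisa$tumor, elisa$endothelial, s1, n_grid = 100)
fit_gaussian(s2$posterior)
#>                    mean           sd
#> lambda_T_p 1.587074e-03 1.307468e-04
#> lambda_e_c 8.998185e-07 1.566378e-07
#> theta_V    4.196607e+03 8.493322e+01
```

With 5% measurement noise the sweep recovers the generating kinetics
(production rate 1.7e-3 pg/(mL·h·cell), consumption rate 8.9e-7
1/(h·cell), capacity 4035 pg/mL) to within about 10%.

```r
tab <- sprout_length_table()       # observed mean lengths, days 3-19
s3  <- scenario3_sprout_length(ang_series(tab$day * 24,
                                          tab$observed_mean_um),
                               seed = 42)
round(s3$implied_rate, 2)
#> [1] 1.89
format_gaussian(s3$gaussian_fit["d_sc", "mean"],
                s3$gaussian_fit["d_sc", "sd"], 2)
#> [1] "N(4.27, 0.44)"
```

The posterior-mean elongation rate is ~1.9 µm/h: dividing a 10 µm cell
once per ~5.3 h cycle reproduces the observed lengths. Summaries
follow the study convention (mean ± sample sd):

```r
error_summary(density_error_table()$calibration_pct)
#>      mean        sd
#> 17.733333  6.285168
```

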