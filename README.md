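# nemaiq

Quantitative harmonisation of Gallium-68 PET-CT, at desk scale: `nemaiq`
simulates acquisitions of the NEMA IEC body phantom (six hot spheres of
37–10 mm, warm background, cold lung insert) with controllable resolution
loss, Gibbs-type edge enhancement and spatially correlated noise, and
implements the analysis chain used to standardise scanners across a
multi-centre trial:

* **Segmentation** — 50%-of-maximum 3D isocontour sphere VOIs, the
  360-region circular background battery (six diameters × 12 positions ×
  5 slices), and the floating 1-cm³ peak sphere.
* **Image-quality metrics** — recovery coefficient `RC = C_m / C_dc` and
  contrast recovery `CRC = (C_m − C_bkg.m) / (C_dc − C_bkg.dc)` in
  max/mean/peak flavours; background variability
  `BV_r = sd_k(C_{r,k}) / mean(C_{r,k})` and image roughness
  `IR_{r,k} = sd_i(C_{i,r}) / C_{r,k}` with sample denominators.
* **Edge artifacts** — six 1D profiles per sphere on the largest-area
  slice, peak-to-valley ratios, and concave/conical/flat surface
  classification.
* **Harmonisation** — aggregation of results across scanners, mean ± 2 SD
  specification limits, compliance checks against the shipped Ga-68 limits
  table (conventional and advanced reconstruction families), Welch t tests
  and percentage differences between reconstruction variants.
* **Clinical agreement** — Bland–Altman analysis of log-transformed
  per-lesion SUVs with 1.96-SD limits of agreement and paired t tests,
  plus a synthetic lesion-cohort generator so the stage is testable
  without patient data.

It is aimed at PET physicists and trial methodologists who want to probe
how reconstruction choices (PSF post-filter width `w`, penalised-likelihood
factor `β`), positron range and scanner calibration interact with the
standard image-quality battery — and at anyone who needs a reproducible,
tested implementation of that battery.

## Worked example

```r
library(nemaiq)

phantom <- nema_phantom()                  # the six-sphere NEMA IQ geometry
fill    <- fill_spec(19.9, 2.4)            # kBq/ml: spheres / background (8.3:1)
scanner <- scanner_profile()               # 2.7-mm grid, 4.5-mm PSF, Ga-68-ready

img <- simulate_acquisition(phantom, fill, scanner,
                            recon_config("bpl", beta = 800), seed = 1)
iq  <- analyse_iq(img, phantom, fill)
print(iq)
```

```
<iq_result [BPL_800]>
 diameter RC_max RC_mean RC_peak CRC_max CRC_mean CRC_peak
       37  1.107   0.835   1.028   1.122    0.811    1.031
       28  1.051   0.774   0.990   1.057    0.743    0.988
       22  1.079   0.738   0.935   1.090    0.701    0.926
       17  0.822   0.573   0.677   0.797    0.514    0.633
       13  0.706   0.469   0.488   0.666    0.396    0.418
       10  0.399   0.262   0.285   0.316    0.160    0.186
noise:
 diameter    BV    IR IR_sd
       37 0.037 0.117 0.019
       ...
       10 0.087 0.086 0.035
```

Recovery falls with sphere size (partial volume, amplified by the 2.9-mm
Ga-68 positron range); the background battery puts this acquisition's noise
at BV ≈ 4–9% and IR ≈ 9–12%. Checking the spheres against the shipped
Ga-68 limits for advanced reconstructions:

```r
check_compliance(iq, ga68_limits(), family = "advanced")
```

```
<compliance: 16/18 pass>
 diameter metric value lower upper deviation_pct
       17 RC_max 0.822  0.84  1.16         -2.12
       10 RC_max 0.399  0.41  0.59         -2.64
```

— this simulated scanner sits 2–3% below the lower RC_max bound for two
spheres, exactly the kind of marginal finding the limits exist to flag.
Edge artifacts are quantified on noiseless optimisation runs:

```r
sc0 <- scanner_profile(noise_level = 0)
for (b in c(200, 800)) {
  img_b <- simulate_acquisition(phantom, fill, sc0,
                                recon_config("bpl", beta = b), seed = 1)
  print(mean_ptv(extract_profiles(img_b, segment_sphere(img_b, phantom, 1))))
}
```

```
<ptv_result: 1.044 +/- 0.002 (concave)>   # beta = 200: edge overshoot
<ptv_result: 1.001 +/- 0.000 (flat)>      # beta = 800: suppressed
```

A weakly penalised reconstruction shows the concave surface (peak at the
sphere edge, valley at its centre) characteristic of Gibbs overshoot;
β = 800 flattens it. Full experiment presets (`optimise`, `multicentre`,
`clinical`, `contrast_sweep`) are driven by `run_experiment()` from a YAML
or list configuration and write CSV/JSON report bundles with a manifest;
reruns with the same configuration and seed are byte-identical.

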