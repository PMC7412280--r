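# leafvision

Receptor-noise-limited visual discrimination of foliage colours, for the
sensory-ecology question: can a trichromatic insect eye tell leaves of
different ages apart, and if so, by hue or by intensity?

The package models the complete analysis chain for a leafhopper-style eye
with ultraviolet, blue and green photoreceptors:

* **Reflectance processing** — white-standard normalization
  *R*(λ) = *S*(λ)/*L*(λ)·100 and integrated reflectance intensity
  *I* = ∫ *R*(λ) dλ over 300–700 nm.
* **Receptor physiology** — ERG amplitudes linearized through the
  Naka–Rushton function *V*/*V*<sub>max</sub> = *I*ⁿ/(*I*ⁿ + *K*ⁿ),
  converted to spectral sensitivity, and decomposed into Stavenga/Govardovskii
  visual-pigment nomogram templates by bounded nonlinear least squares.
* **Discrimination** — quantum catches *Q<sub>j</sub>* = ∫ *q<sub>j</sub>R I* dλ,
  receptor-noise-limited chromatic contrast

  ΔS = √[ (ω<sub>S</sub>²(Δf<sub>L</sub>−Δf<sub>M</sub>)² + ω<sub>M</sub>²(Δf<sub>L</sub>−Δf<sub>S</sub>)² + ω<sub>L</sub>²(Δf<sub>M</sub>−Δf<sub>S</sub>)²) / ((ω<sub>S</sub>ω<sub>M</sub>)² + (ω<sub>S</sub>ω<sub>L</sub>)² + (ω<sub>M</sub>ω<sub>L</sub>)²) ]

  with Δf<sub>j</sub> = ln(*Q<sub>j</sub><sup>a</sup>*/*Q<sub>j</sub><sup>b</sup>*),
  Michelson achromatic contrast *C* = (*Q*<sub>max</sub>−*Q*<sub>min</sub>)/(*Q*<sub>max</sub>+*Q*<sub>min</sub>),
  threshold calls (ΔS ≥ 2.3 JND, *C* ≥ 0.08) and top/middle/bottom shoot-zone
  classification.
* **Supporting statistics** — inter-leaf spectral regressions (hue drift),
  intensity-versus-leaf-age regression, trap-count correlations, RPKM.
* **Synthetic data** — seeded generators for leaf reflectance series (affine
  inter-leaf structure), ERG spectral scans and behavioural choice counts, so
  the whole pipeline is testable end to end.

## Worked example

Fit the receptor set from a synthetic ERG recording, then ask which leaves
of an 11-leaf shoot the fitted eye can discriminate from the top leaf:

```r
library(leafvision)

gen  <- generate_erg_dataset(seed = 1)
sens <- sensitivity_from_erg(gen$dataset, list(v_max = 10, k = 5e10, n = 1))
fit  <- fit_receptor_set(sens)
fit
#> Trichromatic receptor-set fit
#>   lambda_max (S,M,L): 356.4, 431.0, 541.7 nm
#>   amplitude ratio   : 1 : 0.59 : 6.38
#>   RSS = 0.001504 on 41 wavelengths

leaves <- generate_leaf_series(seed = 1)
dm <- discrimination_matrix(leaves$series, fit$receptor_set)
vs_reference(dm, 1)
#>    leaf   delta_s michelson_c chromatic_call achromatic_call
#> 1     2 0.9316877  0.03293000          FALSE           FALSE
#> 2     3 1.0988560  0.04435745          FALSE           FALSE
#> 3     4 1.2832647  0.05645055          FALSE           FALSE
#> 4     5 1.4832263  0.06838008          FALSE           FALSE
#> 5     6 1.7016930  0.08098725          FALSE            TRUE
#> ...
#> 10   11 3.0948743  0.14732204           TRUE            TRUE

classify_zones(dm)
#>        1        2        3        4        5        6  ...       11
#>    "top" "middle" "middle" "middle" "middle" "bottom"  ... "bottom"
```

Reading the output: the generator plants a true eye with pigment peaks at
356/435/542 nm and amplitude ratio 1:0.6:6.4, which the fit recovers from
noisy ERG scans. Against the top leaf, the near leaves (2–4) stay below both
thresholds — their ΔS of ~0.9–1.3 JND means their *hue* difference is
invisible — while from leaf 6 down the Michelson contrast crosses 0.08 and
the leaves become discriminable *by intensity*. That is the model's core
claim: reflected intensity, not spectral composition, is the usable cue for
locating tender top leaves.

`run_pipeline(seed = 1, out_dir = "out")` chains every stage (simulation,
Naka–Rushton calibration, receptor fit, regressions, discrimination matrix,
zoning, choice-count analysis) and writes CSV/JSON artifacts plus a
provenance block listing every default that stands in for an unmeasured
quantity (Weber fractions, illuminant, achromatic channel).

## Package layout

* `R/spectrum.R` — spectral data model, normalization, integration
* `R/templates.R` — pigment nomograms and composite sensitivity
* `R/naka_rushton.R`, `R/erg.R` — response linearization and receptor fitting
* `R/discrimination.R` — catches, ΔS, Michelson *C*, zoning
* `R/stats.R` — regression/correlation records, RPKM
* `R/synthetic.R` — seeded generators (leaves, ERG, choice counts)
* `R/pipeline.R`, `R/io.R` — end-to-end runner, CSV/YAML/JSON interfaces
* `vignettes/receptor-noise-foliage.Rmd` — model assumptions, conventions,
  calibration rationale and limitations
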