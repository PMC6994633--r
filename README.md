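# mobflim

Label-free metabolic profiling of single hematopoietic cells from NAD(P)H /
FAD autofluorescence lifetime imaging (FLIM).

Hematopoietic stem cells (HSCs) favor anaerobic glycolysis; their progeny
shift toward oxidative metabolism. Because free NAD(P)H decays fast
(~0.45 ns) and enzyme-bound NAD(P)H slowly (2–4 ns), per-pixel decay
kinetics report the coenzyme binding state — and with it the cell's
metabolic program — without any label. `mobflim` implements the full
analysis chain for such data, for imaging groups and method developers who
want a tested, reproducible reference implementation:

1. **Phasor transform** of TCSPC decay stacks:
   `g = Σ I(t)·cos(nωt) / Σ I(t)`, `s = Σ I(t)·sin(nωt) / Σ I(t)`,
   `ω = 2π/T`, with reference-fluorophore calibration (phase + modulation).
   Single exponentials lie on the universal semicircle
   `(g − ½)² + s² = ¼` at `g = 1/(1+(ωτ)²)`, `s = ωτ·g`.
2. **Two-component unmixing** with fixed `τ_free`: the chord from the
   free-NAD(P)H semicircle point through the pooled cell phasor is
   intersected with the semicircle, yielding `τ_bound = s_b/(ω·g_b)` and
   `α_bound = |P_cell − P_f| / |P_b − P_f|`; a total-least-squares
   trajectory fit estimates both lifetimes when neither is fixed.
3. **Five metabolic optical biomarkers (MOBs) per cell**: optical redox
   ratio ORR = FAD/(FAD + NAD(P)H), `α_bound`, `τ_bound`, edge/center
   NAD(P)H intensity ratio, and intensity polarity (mass-center vs
   geometric-center displacement over the equivalent radius).
4. **Population gating**: z-scored MOBs → 3-component PCA → binary LDA
   plane (`w ∝ Σ⁻¹(μ_target − μ_rest)`, equal priors) with per-population
   gate fractions.
5. **HSC identification**: RBF-SVM over the five MOBs with stratified-CV
   grid search, balanced class weights, Platt-scaled probabilities fit on
   held-out folds, and reporter-based sensitivity/specificity evaluation.
6. **A ground-truthed synthetic FLIM generator** — wrapped two-component
   exponential decays, Poisson photon statistics, Gaussian IRF, multi-cell
   fields with population presets, peripheral enrichment, polarized
   intensity, and a paired-perturbation model — so every stage is testable
   without a microscope.

## Worked example

```r
library(mobflim)

acq     <- acquisition_config(frame_shape = c(96, 96))   # 80 MHz, 256 bins
presets <- load_population_presets(n_cells = 10)
truths  <- sample_population(presets$HSC, acq$frame_shape, seed = 42)
field   <- render_field(truths, acq, seed = 43)

cells <- extract_mob_field(field)
round(colMeans(cells[, c("orr", "alpha_bound", "tau_bound_ns",
                         "edge_center_ratio", "polarity")]), 3)
#>               orr       alpha_bound      tau_bound_ns edge_center_ratio
#>             0.150             0.768             3.568             1.751
#>          polarity
#>             0.383
```

Ten synthetic HSCs rendered at 10⁴ photons each and pushed through the full
extraction chain recover the preset HSC profile: low redox ratio (0.15,
glycolytic), high bound fraction (0.77) and long bound lifetime (3.57 ns,
high LDH engagement), peripheral NAD(P)H (edge/center 1.75) and strong
polarization (0.38). Single cells work the same way:

```r
gs  <- cell_phasor(phasor_transform(field$nadph), field$mask == truths$cell_id[1])
fit <- decompose_fixed_free(gs, tau_free = 0.45, omega = omega(acq))
#> cell 1: alpha_bound 0.757, tau_bound 3.715 ns   (truth: 0.771, 3.717 ns)
```

An end-to-end demo (simulate → phasor → extract → gate → classify →
report):

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "mobflim"),
             out_dir = "demo_out")
```

or from a shell:

```sh
Rscript inst/cli/mobflim.R run --config inst/extdata/demo_config.json --out demo_out
```

The report bundle contains per-population MOB summaries, LDA gate fractions,
classifier metrics, the serialized gate/classifier models, and the frozen
resolved configuration; reruns with the same seed are byte-identical.

See `vignettes/mobflim-methods.Rmd` for the model, parameter conventions,
numerical choices, and known limitations.

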