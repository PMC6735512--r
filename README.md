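# dmfpi — respiratory-gated dual-phase perfusion imaging for DCEUS

Dynamic contrast-enhanced ultrasound (DCEUS) measures tissue perfusion by
filming a microbubble bolus washing through a 2-D imaging plane and
reducing each region to a time-intensity curve (TIC). Under free breathing
the liver slides through that plane, so consecutive frames image different
anatomy: TICs get contaminated with the kinetics of whatever moved into
view and the parametric perfusion maps built from them are distorted.
`dmfpi` implements a fully automatic dual-phase gating scheme for this
problem, aimed at DCEUS researchers who need motion-robust perfusion
quantification without registration:

1. **Respiratory kinetics by PCA.** The loop is flattened to a
   frames-by-pixels matrix `Y` (each column one pixel's raw TIC),
   mean-centered and decomposed, `Y ≈ Σᵢ cᵢ wᵢᵀ`, into orthonormal temporal
   components `cᵢ` with spatial weights `wᵢ`. The bolus dominates `c₁`;
   periodic breathing concentrates in `c₂`, which is taken as the
   respiratory kinetic curve `r(t)` (p = 4 components retained).
2. **Derivative zero-crossing dual-phase detection.** `r(t)` is smoothed
   with a zero-phase moving average and band-passed around its dominant
   frequency; sign changes of its first difference mark the
   end-of-inspiration (EOI) and end-of-expiration (EOE) extremes, with
   minimum-separation pruning and enforced alternation.
3. **Gating and TICs.** One frame per detected extremum forms each
   dual-phase subsequence; TICs are extracted on a 3×3-pixel grid and
   denoised with a dual-weighted (twice-cascaded triangular) moving
   average.
4. **Six-parameter maps.** Per grid cell: wash-in time `WIT`, wash-out
   time `WOT`, peak value `PV`, area under curve `AUC`, wash-in rate
   `WIR = PV/WIT`, wash-out rate `WOR = PV/WOT`, by 10%-of-peak threshold
   conventions; maps are normalized to shared dynamic ranges, quantized to
   256 levels and colour-coded.
5. **Evaluation metrics.** Signal-to-clutter ratio (SCR) of TICs, TIC mean
   square error against motion-free references, density MSE and
   correlation R between maps, and the mean noise coefficient (MNC) of a
   colour map.

Because no public DCEUS acquisitions exist for this protocol, the package
ships a synthetic flow phantom (`simulate_dceus()`): a vessel cross-section
with laminar-profile log-normal bolus kinetics, sinusoidal out-of-plane
deformation at 0.27 Hz, alternate-phase intruding anatomy, speckle, and
motion-frozen static ground-truth loops at both extreme phases.

## Worked example

```r
library(dmfpi)

run <- run_pipeline(phantom = phantom_config(seed = 3), phases = "eoi")
print(run)
#> <pipeline_run> f0 = 0.2688 Hz, 31 EOI + 32 EOE cycles, 111.7 s
#>   eoi: SCR gated 41.06 dB vs ungated 8.37 dB
#>       TIC MSE vs static: gated 48.1, ungated 2.19e+03
```

The simulated loop breathes at 0.27 Hz; the second principal component
recovers `f0 = 0.2688` Hz and yields 31 EOI / 32 EOE gated cycles over
120 s (one per breath; extrema at the series boundary are discarded). The
gated lumen TIC has a ~33 dB higher signal-to-clutter ratio than the
ungated one, and lies ~45 times closer (MSE 48 vs 2190) to the TIC of the
motion-frozen control loop. Per-parameter map metrics live in the report:

```r
run$report$phases$eoi$fpi$WOT[c("fpi_mse_rg", "fpi_mse_norg", "r_rg", "r_norg")]
#> $fpi_mse_rg    [1] 594.1...
#> $fpi_mse_norg  [1] 7585.0...
#> $r_rg          [1] 0.801...
#> $r_norg        [1] -0.068...
```

The gated wash-out-time map's value distribution is ~13× closer to the
static ground truth than the ungated one, with density correlation 0.80
versus -0.07. `run$maps$eoi$rg$WOT$rgb` holds the colour-coded map;
`run_pipeline(..., out = "dir/")` writes maps (PNG), the respiratory curve
(CSV), phase indices and the metric report (JSON).

Individual stages are exposed as plain functions — `read_sequence()`,
`flatten_sequence()`, `pca_decompose()`, `extract_respiratory_curve()`,
`smooth_curve()`, `detect_phases()`, `gate_sequence()`,
`extract_tic_grid()`, `dwma_filter()`, `estimate_perfusion_params()`,
`build_parameter_maps()`, `encode_rgb()`, `scr()`, `tic_mse()`,
`fpi_mse()`, `fpi_correlation()`, `mnc()` — see the methods vignette
(`vignettes/dmfpi-methods.Rmd`) for the models behind them. A thin
command-line wrapper over the same functions is at `inst/cli/dmfpi.R`.

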