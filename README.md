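# mosswave

Automated, unbiased analysis of calcium-imaging timelapses of moss
protonemal colonies.

Protonemata — the juvenile, filamentous stage of mosses such as
*Physcomitrium patens* — respond to fungal chitin with colony-wide cytosolic
calcium oscillations reported by the GCaMP indicator. Quantifying those
dynamics cell by cell is a bottleneck: manual ROI tracing is slow, biased,
and blind to subcellular domains such as the fast-oscillating caulonemal
apical tip. `mosswave` segments colonies *by their dynamics*: every colony
pixel's fluorescence time course is Z-scored, `Z = (x − µ)/σ`, and pixels
are grouped by k-means under the cosine distance, so regions with the same
temporal signature — whole cells or subcellular domains — emerge without any
geometric prior. Clusters are split into 8-connected components, pruned
below 12 px², and reduced to per-ROI ΔF/F₀ traces.

Calcium waves are then detected as peaks with topographic prominence
≥ 0.35 × MAD of the trace and measured at fractions of their prominence:
FW10 (full width at 10%), rise and fall times (10%→90%), peak-to-peak
intervals and their CV, instantaneous wave probability, maximum lagged
cross-correlation between ROIs, and per-stimulus-pulse response latency and
normalized AUC. For a Gaussian wave of scale σ the detector's closed forms
are FW10 = 2σ√(2 ln 10) and rise = fall = σ(√(2 ln 10) − √(2 ln(10/9))),
which the test suite verifies to within one frame.

A synthetic colony generator (`build_geometry`, `schedule_waves`,
`render_stack`, `simulate_colony`) renders branching CA/CH filament
colonies with programmed Gaussian calcium waves, stimulus-locked latencies
that drift over repeated pulses, shot/read noise and PSF blur — with full
ground truth — so every pipeline stage is testable without microscopy data.

## Worked example

Simulate a small colony driven by ten 1-minute stimulus pulses every
4 minutes, run the full pipeline, and look at the entrainment:

```r
library(mosswave)

protocol <- pulse_train(10, 60, 240, first_on_s = 120, duration_s = 2640)
sim <- simulate_colony(seed = 1000, n_filaments = 3, cells_per_filament = 3,
                       protocol = protocol)
sim$stack
#> <timelapse_stack> 200 x 156 px, 2640 frames (2.9 um/px, 1 s/frame)

res <- run_all(sim$stack, protocol, run_config(seed = 7))
res
#> <pipeline_result> 16 ROIs, 161 waves from a 200 x 156 x 2640 stack

iv <- wave_intervals(res$waves)
median(iv$intervals$interval_s)
#> [1] 244
res$pulse$per_pulse[1:4, c("pulse", "waves_per_roi", "auc_norm", "latency_mean_s")]
#>  pulse waves_per_roi  auc_norm latency_mean_s
#>      1             1 1.0000000       32.47302
#>      2             1 0.9411839       32.12427
#>      3             1 0.9618814       33.28214
#>      4             1 0.8928797       41.26918
```

Each of the 16 automatically segmented ROIs fires one wave per pulse; the
pooled median inter-wave interval is 244 s, i.e. the colony is entrained to
the 240 s stimulation period (within ~2%), and per-pulse mean response
latencies drift upward across pulses — the signature of response adaptation.
`write_results(res$traces, res$waves, "out/", res$manifest)` writes the
trace matrix, the wave table and a reproducibility manifest as
deterministic CSV/JSON.

A thin command-line wrapper is installed at `inst/cli/mosswave`
(`mosswave {simulate, mask, run} …`).

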