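# hydromem

Antecedent-flow "hydrological memory" analysis for stream
macroinvertebrate communities in ungauged catchments.

Small headwater streams — the motivating case is a 0.26 km² high-Andean
páramo micro-catchment — are rarely gauged, yet short-term flow history
is a first-order control on their benthic communities. hydromem
implements the full analysis chain for such settings:

1. **Discharge reconstruction** from daily rainfall with a conceptual
   daily model: curve-number runoff depth
   (S = 25400/CN − 254, Ia = λS, Q = (P − Ia)²/(P − Ia + S)),
   Clark unit-hydrograph routing (time–area curve + linear reservoir,
   sub-daily internal step), and exponential recession baseflow
   (Q₀ = 0.005 m³ s⁻¹, k = 0.95 day⁻¹ by default).
2. **Antecedent descriptors** over the w ∈ {3, 6, 9} days preceding
   each sampling event: mean discharge Q_mean, Richards–Baker
   flashiness RB = Σ|ΔQ|/ΣQ, the number of day-to-day rises nΔQ>0, and
   the cumulative rise, fall and absolute-change magnitudes ΣΔQ>0,
   ΣΔQ<0, Σ|ΔQ|.
3. **Diversity indices** per event: Shannon H, Pielou E, Simpson
   dominance D = Σp², and — from a families × 41-category fuzzy trait
   matrix over eight biological traits — Rao's quadratic entropy
   Σ dᵢⱼ pᵢ pⱼ, functional attribute diversity FAD1 = Σᵢ<ⱼ dᵢⱼ, and
   community-weighted functional divergence wFDc.
4. **Window selection and descriptor importance**: per window and
   index, penalised additive models y = α + Σⱼ sⱼ(xⱼ) with basis
   dimension k = 3 (AR(1) residual structure attempted first, an
   event-index smooth as fallback; beta family for E and D); windows
   compared by mean adjusted R², triaged by RMSE and Shapiro–Wilk
   residual normality; descriptor importance by drop-one ΔR²adj.

A synthetic-data generator plants a tunable monotone dependence of
community evenness on a chosen descriptor at a known window, so the
whole chain is validated by simulation: it must recover a signal it was
given.

## Worked example

```r
library(hydromem)

# one synthetic study: 10 years of rainfall, 60 sampling events,
# evenness planted on the cumulative negative flow change at 9 days
st <- synth_memory_study(memory_scenario(n_events = 60), seed = 1)
fm <- flow_memory(st$diversity, st$descriptors)
fm
#> Antecedent-flow memory analysis
#>   windows compared: 3, 6, 9 days
#>   responses: H, E, D, Rao, FAD1, wFDc
#>   best window: 9 days
#>   excluded from importance (non-normal residuals): E, D, FAD1
#>   top descriptor per response at the best window:
#>     H     sum_fall (delta R2_adj = 0.02)
#>     Rao   n_rise (delta R2_adj = 0.05)
#>     wFDc  sum_fall (delta R2_adj = 0.03)

round(fm$window_summary, 3)
#>   window mean_r2_adj sd_r2_adj mean_rmse sd_rmse
#> 1      3       0.039     0.017     1.106   2.596
#> 2      6       0.154     0.099     1.115   2.630
#> 3      9       0.214     0.135     1.102   2.602
```

The fit selects the planted 9-day window (mean R²adj rises
monotonically from the 3- to the 9-day window) and ranks the planted
driver `sum_fall` — cumulative flow recession, the stabilising limb of
the hydrograph — top for Shannon diversity. Indices whose residuals
fail the Shapiro–Wilk screen at the selected window are excluded from
the importance stage and reported as such.

`run_pipeline()` wraps the same chain with CSV/JSON input and output
for scripted use, and `summary()`/`plot()` methods give the full
per-model metric tables.

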