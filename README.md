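# sfcwbreath

Breath detection for stepped-frequency continuous-wave (SFCW) ultra-wideband
radar, built on **operational bandwidth segmentation**.

A stationary person hidden from view — behind a wall, under rubble — betrays
their presence to a radar only through the millimetre-scale motion of the
chest wall. Classical processing chains work purely along the slow-time axis
of the echo data and ignore the defining asset of an ultra-wideband radar:
its enormous operational bandwidth. This package implements, end to end, a
detection scheme that exploits that bandwidth, together with a seeded
simulator that generates every input the method needs, so the whole chain is
testable without measured radar data.

## The method

An SFCW radar sweeps discrete frequencies `f_m = f0 + m·Δf` (m = 0…M−1) and
records, sweep after sweep (slow time `t_n = n·Ts`, n = 0…N−1), the complex
gain of the scene, giving an M×N echo matrix. A breathing target at nominal
range `d0` with chest displacement `Δd·sin(2π f_b t)` contributes

    R[m,n] = S[m] · α · exp(−j2π f_m τ0) · exp(−j2π f_m Δτ · sin(2π f_b t_n)),

with `τ0 = 2 d0 / c`, `Δτ = 2 Δd / c`, reflectivity `α`, and transmit
spectrum `S`. By the Jacobi–Anger expansion the sinusoidal phase term is a
line spectrum at harmonics of `f_b` whose structure is *consistent across
operational frequencies*, whereas static clutter — distorted unpredictably
by propagation through obstacles — is *random across them*. Averaging along
the operational frequency therefore enhances breath and suppresses clutter.

The processing chain:

1. **Segmentation** — a rectangular window of `L` frequency bins slides in
   steps of `Δl`, cutting the band into `⌊(M−L)/Δl⌋+1` overlapping
   sub-bands (78 for the radar's 874-bin band with L = 100, Δl = 10).
2. **Range synthesis** — IFFT along the (zero-padded) frequency axis of each
   sub-band puts all sub-bands on one common range grid.
3. **Breath detection** per sub-band and range bin along slow time: block
   averaging/resampling on range, a 160-order moving-average motion filter,
   power normalization to [−1, 1], and a 321-tap FIR low-pass at 0.5 Hz.
4. **Slow-time FFT** — breathing appears as a spectral line at `f_b`.
5. **Averaging over sub-bands** at a configurable stage (`AoF`, `AoR`,
   `AaT`, `AaF`, `AaA`; `AaT` — averaging after the time-domain breath
   detection — performs best; `NON` is the conventional unsegmented flow).

The enhanced range×frequency matrix peaks at the target's range and
breathing frequency; the power-range plot
`P[m] = 20·log10(max_k R̃[m,k] / max R̃)` exposes the
signal-to-noise-and-clutter ratio (SNCR) as the height of its floor. For
target identification, the per-sub-band power peaks are clustered by
k-means (k = 2, target vs clutter outliers); presence is declared only when
a compact majority cluster agrees with the enhanced peak, which suppresses
false alarms on target-free scenes.

## Worked example

```r
library(sfcwbreath)

# A breathing target 3 m away (5 mm chest displacement at 0.2 Hz) in a
# cluttered, noisy scene; 5 GHz bandwidth, 10 s record.
echo <- generate_fixture("breathing_cluttered", seed = 3)

em  <- run_enhancement(echo, segmentation_params(L = 100, delta_l = 10),
                       pipeline_params("AaT"))
print(em)
#> <enhanced_matrix> 51 range bins x 1001 frequency bins
#>   peak 54 at 3.127 m, 0.200 Hz

print(power_range_plot(em))
#> <power_range_plot> 51 bins, peak at 3.127 m, SNCR 31.5 dB

# the unsegmented conventional flow on the same data
print(power_range_plot(run_enhancement(echo, pipe = pipeline_params("NON"))))
#> <power_range_plot> 51 bins, peak at 3.127 m, SNCR 21.1 dB

identify_target(echo, segmentation_params(100, 10), seed = 3)$decision
#> [1] "present"
```

The enhanced matrix localizes the target at 3.13 m (one 0.3 m range bin
from truth) and 0.200 Hz, and sub-band averaging lifts the SNCR by ~10 dB
over the unsegmented flow. On a clutter-only scene
(`generate_fixture("clutter_only", ...)`) the identification step returns
`"absent"`.

A command-line interface wraps the same functions
(`simulate | segment | enhance | identify | spectrum`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "sfcwbreath.R", package = "sfcwbreath"))')" \
  simulate --out echo.txt
```

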