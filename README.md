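# resppair

Quantifying discrepancies between two simultaneously recorded respiratory
surrogate signals — an infrared marker-displacement trace (RPM-style) and an
abdominal pressure-belt trace (ANZAI-style) — and propagating them through
4D CT local-amplitude phase sorting into per-phase anatomy differences and
gating-window mismatch.

## Who this is for

Medical physicists and methods developers in respiratory motion management
who need a tested, scriptable implementation of the paired-surrogate
comparison workflow: when one monitoring system sorts the 4D CT and a
different one gates treatment delivery, how large are the resulting
per-phase anatomy and beam-on-window mismatches?

No patient data ships with the package; a first-class synthetic module
generates internal motion plus two distorted surrogates with *known* lag,
limb-shape warps and noise, so every downstream stage is verifiable against
ground truth.

## What it computes

For two traces `a(t)`, `b(t)` sharing a start trigger:

* **Phase shift** — per-cycle EOI latency `lag_i = t_EOI,b(i) − t_EOI,a(i)`
  (positive = first argument leads), as mean ± SD in seconds and in % of
  the respiratory period; and an alternative estimate from the direct
  least-squares ellipse fit of the correlation scatter, where a lag φ gives
  diagonal/antidiagonal semi-axes ∝ cos(φ/2), sin(φ/2), hence
  φ = 2·atan(minor/major).
* **Cycle statistics** — per-cycle period `T` (EOI-to-EOI) and depth `d`
  (EOE→EOI increment on the 0–100 renormalized trace), paired differences,
  and whole-trace Pearson correlation.
* **Average cycle shape** — per-cycle 0–100 renormalization, EOI alignment,
  pointwise averaging; inhale/exhale limb steepness verdicts
  (`A_steeper` / `B_steeper` / `matched`).
* **Local amplitude sorting** — ten phases (1 = 100%Ex … 6 = 0%In …
  10 = 80%In) assigned by nearest nominal amplitude fraction on each limb.
* **Digital motion phantom** — a cine acquisition over a linear
  diaphragm/lung model, reconstructed once per surrogate, yielding
  per-phase apex positions (quantized to the 2 mm slice) and lung volumes,
  and their single-phase differences.
* **Gating mismatch** — duty cycles, Jaccard overlap of the planned vs
  applied beam-on time sets (closed form `(w−Δ)/(w+Δ)` for a pure lag Δ and
  window width `w`), and residual diaphragm motion during beam-on.

## Worked example

```r
library(resppair)

params <- breathing_params(mean_period = 4, duration = 120, seed = 42)
pair <- generate_pair(params,
  distortion_a = surrogate_distortion(extra_noise_sd = 2),
  distortion_b = surrogate_distortion(lag = 0.2, exhale_steepness = 1.8,
                                      extra_noise_sd = 2))

eoi_latency_shift(pair$surrogate_b, pair$surrogate_a)
#> <phase_shift_result> 29 cycle pairs: 0.229 +/- 0.109 s (5.5% +/- 2.7% of period)
#>   positive = first argument reaches EOI earlier

trace_correlation(normalize_global(pair$surrogate_a),
                  normalize_global(pair$surrogate_b))
#> [1] 0.793

compare_limbs(trace_average_shape(pair$surrogate_a),
              trace_average_shape(pair$surrogate_b))
#> <limb_comparison> exhale: B_steeper (score -16.09), inhale: matched (score -0.00), threshold 3.0

geom   <- phantom_geometry()                       # 20 mm excursion, 2 mm slices
sched  <- acquisition_schedule(10, 6, frame_rate = 4, start = 1)
frames <- simulate_acquisition(pair$internal, geom, sched)
compare_sortings(reconstruct_phases(frames, pair$surrogate_b, NULL, geom),
                 reconstruct_phases(frames, pair$surrogate_a, NULL, geom))
#> <mismatch_report> volume diff % range (-8.11, 15.62); position diff range (-6.0, 10.0) mm

gating_mismatch(gating_window("amplitude", 0, 30),
                normalize_global(pair$surrogate_a),
                normalize_global(pair$surrogate_b), pair$internal)
#> <gating_mismatch> duty design 0.485 / applied 0.578; overlap 0.682
#>   residual motion: design 6.1 mm, applied 16.1 mm
```

Reading it: the injected 0.2 s belt lead is recovered as 0.23 ± 0.11 s
(5.5% of the period); the injected exhale warp is classified `B_steeper`
with the inhale limbs matched; sorting the *same* acquisition with the two
surrogates moves per-phase diaphragm positions by up to 5 slices and lung
volumes by up to ~16%; and an EOE-centered amplitude gate planned on the
marker trace overlaps only 68% in time with the same gate applied to the
belt trace, while residual motion during beam-on grows from 6 mm to 16 mm.

A full synthetic cohort (period/lag/warp parameters drawn per patient) runs
with `run_full_study(list(n_patients = 15, seed = 1))`, emitting per-patient
period/depth/correlation tables, phase shifts, limb verdicts and mismatch
ranges plus cohort summaries, deterministically per seed.

## Command line

```sh
exec/resppair simulate --config cfg.json --out-dir data/
exec/resppair convert  --anzai data/surrogate_b.csv --rpm-ref data/surrogate_a.vxp --out data/b_as_rpm.vxp
exec/resppair shift    --a data/surrogate_b.csv --b data/surrogate_a.vxp --method both --report shift.json
exec/resppair study    --config cfg.json --report study.json
```

File dialects (plain-text, documented in `?file_dialect`): a VXP-like
displacement format with millisecond timestamps, TTL beam-edge indicators
and EOI/EOE marks, and a pressure CSV (`time_s,pressure,ttl`).

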