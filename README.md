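# limbquant

Quantification pipeline for **longitudinal intravital two-photon
microendoscopy of the femoral bone marrow**, with accompanying micro-CT
bone morphometry and post-surgical welfare analytics.

Implanted GRIN-lens microendoscopes image the *same* deep marrow volume
of a living mouse over weeks. `limbquant` turns such time-lapse stacks
into numbers: how fast blood vessels of different calibers remodel, how
B-lineage cells move, how sharp and stable the optical system is, and
how thick the cortical bone is around the implant. Every analysis stage
is paired with a seeded synthetic-scene generator with known ground
truth, so the whole pipeline is testable end to end without any
external data.

## What it computes

**Vessel remodeling.** Sessions are segmented (Gaussian smoothing +
Otsu), vessels are the 26-connected components of the union of the two
sessions' masks, and each vessel *v* gets the normalized volume change

```
delta(v) = ( V_appear + V_disappear ) / V_t1
```

where `V_appear` is the volume present only at the later session,
`V_disappear` the volume present only at the earlier one, and `V_t1`
the vessel's volume at the later session (all in µm³). Vessels are
stratified by the median of a local-thickness diameter map (maximal
inscribed spheres on the exact anisotropic Euclidean distance
transform) into small (5–15 µm), mid (15–35 µm), and large (>35 µm)
classes, compared by one-way ANOVA with Bonferroni follow-ups.

**Cell motility.** Detection (robust background threshold + 3D
watershed), classification by the 500 µm³ volume boundary (a 10 µm
diameter sphere; larger cells are plasma cells), greedy nearest-first
track linking with deterministic tie-breaks, the strict
more-than-10-timepoints inclusion filter (≥ 5 min at 30 s frames), and
per-track mean velocity and displacement rate in µm/min.

**Optics QC.** Per-bead 3D Gaussian PSF fits (FWHM = 2√(2 ln 2) σ;
lateral = mean of x and y), aggregated as mean ± s.d., and
`SNR = mean(foreground) / sd(background)`.

**Photoactivation.** ROI mean intensity, fluorescent volume and signal
centroid per session; single-exponential decay fit
`I(t) = A e^(−kt) + C`; centroid drift and persistence horizon as a
positional-stability report.

**Micro-CT.** Cortical thickness as the FWHM of each component of a
two-Gaussian fit to a cross-wall intensity profile; bone volume (BV),
bone surface (BS, exposed-face counting) and BV/BS; paired t-tests.

**Cohort.** Total clinical score (sum of eight 0–3 subscores) and
activity normalized to the mean of the three days before surgery.

## Worked example

```r
library(limbquant)

# two imaging sessions of a synthetic vascular bed, 24 h apart
scene <- generate_vessel_scene(seed = 1)
vx <- scene$volume$voxel_size

m0 <- segment_vessels(tlv_frame(scene$volume, 1), voxel_size = vx)
m1 <- segment_vessels(tlv_frame(scene$volume, 2), voxel_size = vx)
pair <- pair_sessions(m0, m1)
rem  <- remodeling_statistic(pair, local_diameter(m1))
print(rem)
#> Vessel remodeling: 5 component(s), 0 fully disappeared, 0 below minimum diameter
#>  class n       mean          sd
#>  small 2 0.43719003 0.015475380
#>    mid 2 0.16854891 0.003057311
#>  large 1 0.05042755          NA

compute_snr(tlv_frame(scene$volume, 1))
#> SNR 29.46 (foreground mean 69.52 / background sd 2.36)
```

The scene was generated with per-class remodeling rates 0.4 / 0.15 /
0.05 per 24 h; the class means recover that ordering and magnitude:
small vessels exchanged ~44% of their volume within the interval, large
ones ~5%. The SNR report says the vessel signal stands 29 background
standard deviations above the noise floor, comfortably past the ≥ 5
quality bound.

PSF characterization on a synthetic bead stack:

```r
bs <- generate_bead_stack(seed = 3)            # 23 beads, FWHM (0.8, 5.2) µm
cand <- detect_beads(bs$volume)
fits <- lapply(seq_len(nrow(cand)),
               function(i) fit_bead(bs$volume, as.numeric(cand[i, 1:3])))
summarize_psf(fits)
#> PSF estimate from 23 bead(s):
#>   lateral FWHM 0.80 +- 0.00 um
#>   axial   FWHM 5.20 +- 0.00 um
```

A ready-made demo pipeline (simulate → segment → remodel → ANOVA) with
a run manifest:

```r
run_pipeline(run_config(seed = 1, out_dir = "demo_run"))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/limbquant.R` (`Rscript .../limbquant.R simulate --type vessels
--seed 1 --out out/`).

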