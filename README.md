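# ClusTrack

Single-molecule tracking and cluster kinetics of membrane transporters.

GLUT4, the insulin-responsive glucose transporter, is not spread uniformly
over the adipocyte plasma membrane: a large share of it sits in elongated
nanoscale clusters (~170 × 90 nm) that exchange molecules with a freely
diffusing monomer pool and feed endocytosis, while exocytic fusion of
~50 nm storage vesicles either disperses its cargo or nucleates a new
cluster. Photoactivated single-molecule TIRF recordings resolve these
processes, but turning movies into rate constants takes a chain of
estimators, each easy to get quietly wrong. ClusTrack implements that
chain for R, end to end, with a ground-truthed synthetic-data generator
so every stage is verifiable by parameter recovery:

- **Localization and tracking** — sub-pixel 2D Gaussian spot fitting,
  step-wise bleaching validation of single-molecule identity, and greedy
  nearest-neighbour linking that bridges blink gaps of up to 3 frames
  (`localizeFrame`, `detectBleachSteps`, `linkTrajectories`).
- **Motion classification** — time-averaged MSD curves, the linear
  diffusion law MSD(t) = 4Dt + C, and per-trajectory classification as
  free, directed, or confined against simulation-based 95% confidence
  envelopes for individual random walks, using a 5-consecutive-lag run
  rule (`computeMSD`, `fitLinearMSD`, `buildEnvelope`,
  `classifyTrajectory`).
- **Cluster morphology** — cluster regions from ≥30-frame single-molecule
  residency, second-moment ellipse fits corrected in quadrature for the
  30 nm localization uncertainty, circularity 4πA/P², confinement-zone
  diameters from MSD plateaus (`identifyClusters`, `fitEllipse`,
  `circularity`, `estimateConfinementSize`).
- **Dwell-time kinetics** — cluster dwell times under the
  "lost for more than three consecutive frames" rule, exponential fits of
  dwell histograms, and the relative-exposure decomposition
  **K(p) = p·K_b + K_d + K_e**: recording at constant exposure but longer
  frame intervals scales only the bleaching term, so extrapolating K(p)
  to p = 0 removes bleaching, the ATP-depletion (endocytosis-off) branch
  pins K_d, and the intercept difference isolates K_e
  (`extractDwellTimes`, `fitDisappearanceRate`, `decomposeRates`).
- **Fusion events** — reporter-channel flash detection and classification
  of each event as fusion-with-dispersal or fusion-with-retention from
  the molecule-channel response (`detectFlashes`, `classifyFusion`).
- **Simulator** — Brownian motion among reflecting elliptical cluster
  domains with capture, dissociation, endocytosis, bleaching, blinking and
  localization noise; competing-clock dwell sampling; PSF movie rendering;
  fusion movies; all with complete ground truth (`makeScenario`,
  `simulateTrajectories`, `simulateDwellTimes`, `renderMovie`,
  `simulateFusionMovie`).

## Worked example

Recover the dissociation and endocytosis rates of the basal condition
from synthetic dwell-time data:

```r
library(ClusTrack)

protocols <- c(0.2, 0.5, 1, 2)   # frame intervals, s (t_exp = 200 ms)
branch <- function(preset, seed0) {
  cfg <- makeScenario(preset)
  do.call(rbind, lapply(seq_along(protocols), function(i) {
    sch <- acquisitionSchedule(0.2, protocols[i], 600)
    dw  <- simulateDwellTimes(cfg, sch, 2000, seed = seed0 + i)
    est <- fitDisappearanceRate(dw, "histogram", bootstrap = 200,
                                seed = seed0 + 50 + i)
    data.frame(p = relativeExposure(sch), K = est@K, se = est@se)
  }))
}
decomposeRates(branch("basal", 200), branch("basal_kcn", 300))
```

```
RateDecomposition (K(p) = p Kb + Kd + Ke)
  Kd = 0.1382 +/- 0.015 min^-1
  Ke = 0.5616 +/- 0.028 min^-1
  Kb = 1.95 / 1.89 min^-1
```

The endocytosis-off intercept returns the dissociation rate (ground truth
0.12 min⁻¹), the intercept difference the endocytosis rate (0.57 min⁻¹),
and the slopes the bleaching rate (2 min⁻¹) — all within their sampling
error. `runPipeline()` chains the full analysis (simulate → track →
classify → clusters → kinetics) and emits one reproducible JSON report.

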