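#' @import methods
NULL

#' Acquisition schedule for a time-lapse recording
#'
#' Captures the camera timing of a photoactivated single-molecule recording:
#' exposure per frame, interval between frame starts, and number of frames.
#' The relative exposure \eqn{p = t_{exp}/t_{int}} is the fraction of
#' acquisition time under illumination; it scales the effective bleaching
#' rate in the dwell-time decomposition.
#'
#' @slot tExp exposure per frame, seconds.
#' @slot tInt interval between frame starts, seconds.
#' @slot nFrames number of frames.
#' @seealso [acquisitionSchedule()], [relativeExposure()]
#' @export
setClass("AcquisitionSchedule",
    representation(tExp = "numeric", tInt = "numeric", nFrames = "integer"))

setValidity("AcquisitionSchedule", function(object) {
    msg <- character()
    if (length(object@tExp) != 1L || !is.finite(object@tExp) || object@tExp <= 0)
        msg <- c(msg, "tExp must be a single positive number")
    if (length(object@tInt) != 1L || !is.finite(object@tInt) ||
        object@tInt < object@tExp)
        msg <- c(msg, "tInt must satisfy 0 < tExp <= tInt")
    if (length(object@nFrames) != 1L || is.na(object@nFrames) ||
        object@nFrames < 1L)
        msg <- c(msg, "nFrames must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Simulation scenario configuration
#'
#' Full parameterisation of the synthetic-data generator: free and
#' intra-cluster diffusion, first-order rates for cluster dissociation,
#' endocytic removal, bleaching and association, cluster geometry and
#' density, blinking and localization noise. Rates are stored in
#' min\eqn{^{-1}}; lengths in nm except `fieldSize` (µm); diffusion in
#' µm\eqn{^2}/s.
#'
#' @slot preset name of the originating preset.
#' @slot DFree free-diffusion coefficient, µm^2/s.
#' @slot DIn intra-cluster diffusion coefficient, µm^2/s.
#' @slot Kd cluster dissociation rate, min^-1.
#' @slot Ke endocytosis rate from clusters, min^-1.
#' @slot Kb bleaching rate per unit illuminated time, min^-1.
#' @slot Ka association (capture) rate for rate-based association, min^-1.
#' @slot pCapture capture probability on geometric cluster entry, in [0,1].
#' @slot clusterDensity clusters per µm^2.
#' @slot clusterMajor,clusterMinor mean cluster diameters (major/minor), nm.
#' @slot clusterAxisSD spread of cluster diameters, nm.
#' @slot fieldSize width and height of the field, µm.
#' @slot nMolecules number of activated molecules.
#' @slot blinkOffProb per-frame probability of switching dark.
#' @slot blinkMaxGap maximum dark gap, frames.
#' @slot sigmaLoc localization noise per coordinate, nm.
#' @slot fClustered0 initial clustered fraction.
#' @slot association `"rate"` (first-order capture hazard) or `"spatial"`
#'   (capture on geometric cluster entry with probability `pCapture`).
#' @slot seed integer seed.
#' @seealso [makeScenario()]
#' @export
setClass("ScenarioConfig",
    representation(
        preset = "character",
        DFree = "numeric", DIn = "numeric",
        Kd = "numeric", Ke = "numeric", Kb = "numeric", Ka = "numeric",
        pCapture = "numeric", clusterDensity = "numeric",
        clusterMajor = "numeric", clusterMinor = "numeric",
        clusterAxisSD = "numeric",
        fieldSize = "numeric", nMolecules = "integer",
        blinkOffProb = "numeric", blinkMaxGap = "integer",
        sigmaLoc = "numeric", fClustered0 = "numeric",
        association = "character", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    rates <- c(Kd = object@Kd, Ke = object@Ke, Kb = object@Kb, Ka = object@Ka)
    if (any(!is.finite(rates)) || any(rates < 0))
        msg <- c(msg, "all rates must be finite and >= 0")
    if (object@pCapture < 0 || object@pCapture > 1)
        msg <- c(msg, "pCapture must lie in [0, 1]")
    if (object@clusterMajor <= 0 || object@clusterMinor <= 0 ||
        object@clusterMajor < object@clusterMinor)
        msg <- c(msg, "cluster axes must be positive with major >= minor")
    if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
        msg <- c(msg, "fieldSize must be two positive numbers (µm)")
    if (object@DFree < 0 || object@DIn < 0)
        msg <- c(msg, "diffusion coefficients must be >= 0")
    if (object@fClustered0 < 0 || object@fClustered0 > 1)
        msg <- c(msg, "fClustered0 must lie in [0, 1]")
    if (!object@association %in% c("rate", "spatial"))
        msg <- c(msg, "association must be 'rate' or 'spatial'")
    if (length(msg)) msg else TRUE
})

#' Table of single-molecule localizations
#'
#' The interchange format between imaging and analysis: one row per accepted
#' localization with frame index (0-based), continuous coordinates in nm
#' (origin at the top-left corner of pixel (0,0)), per-coordinate
#' uncertainty in nm, and channel label. Synthetic tables additionally carry
#' the generating molecule id.
#'
#' @slot locs data.frame with columns `frame`, `molecule`, `x`, `y`,
#'   `sigma`, `channel`.
#' @slot pixelSize pixel size, nm.
#' @slot schedule the [AcquisitionSchedule-class] of the recording.
#' @export
setClass("LocalizationTable",
    representation(locs = "data.frame", pixelSize = "numeric",
                   schedule = "AcquisitionSchedule"))

setValidity("LocalizationTable", function(object) {
    need <- c("frame", "molecule", "x", "y", "sigma", "channel")
    if (!all(need %in% names(object@locs)))
        return(paste("locs must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@locs) && any(object@locs$frame < 0))
        return("frame indices must be >= 0")
    TRUE
})

#' Ground truth of a synthetic recording
#'
#' Complete event log of the generator: per-molecule birth/end frames and
#' departure cause, true per-frame positions with cluster membership, and
#' the planted cluster geometries. Enables parameter-recovery testing of
#' every downstream stage.
#'
#' @slot molecules data.frame: `molecule`, `birthFrame`, `endFrame`,
#'   `cause` (one of bleach, endocytosis, censored).
#' @slot positions data.frame: `frame`, `molecule`, `x`, `y` (nm),
#'   `clusterId` (0 = free).
#' @slot clusters data.frame: `clusterId`, `cx`, `cy`, `a`, `b` (semi-axes,
#'   nm), `theta` (rad).
#' @export
setClass("GroundTruth",
    representation(molecules = "data.frame", positions = "data.frame",
                   clusters = "data.frame"))

#' Multi-frame image stack
#'
#' A photon-count movie for one channel: frames stored as a 3D array
#' (y, x, frame), with the pixel size and acquisition schedule attached.
#'
#' @slot data numeric array height x width x frames, photons.
#' @slot pixelSize pixel size, nm.
#' @slot channel channel name.
#' @slot schedule the [AcquisitionSchedule-class].
#' @export
setClass("ImageStack",
    representation(data = "array", pixelSize = "numeric",
                   channel = "character", schedule = "AcquisitionSchedule"))

setValidity("ImageStack", function(object) {
    if (length(dim(object@data)) != 3L)
        return("data must be a 3D array (y, x, frame)")
    if (any(object@data < 0)) return("pixel values must be non-negative")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
})

#' Set of linked trajectories
#'
#' Result of frame-to-frame linking: one row per detection, grouped by
#' track id, frames strictly increasing within a track, internal gaps no
#' longer than the linker's `maxGap`.
#'
#' @slot spots data.frame with columns `track`, `frame`, `x`, `y` (nm) and
#'   optionally `molecule` (truth id for synthetic data).
#' @slot tInt frame interval, seconds.
#' @export
setClass("TrackSet",
    representation(spots = "data.frame", tInt = "numeric"))

setValidity("TrackSet", function(object) {
    need <- c("track", "frame", "x", "y")
    if (!all(need %in% names(object@spots)))
        return(paste("spots must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@spots)) {
        ok <- tapply(object@spots$frame, object@spots$track,
                     function(f) all(diff(sort(f)) >= 1))
        if (!all(unlist(ok))) return("frames must be strictly increasing per track")
    }
    TRUE
})

#' Time-averaged mean-squared-displacement curve
#'
#' MSD of one trajectory (or a pooled average) at integer multiples of the
#' frame interval, with the number of displacement pairs contributing to
#' each lag.
#'
#' @slot lags lag times, seconds (strictly increasing).
#' @slot msd MSD values, µm^2.
#' @slot counts number of ordered pairs per lag.
#' @slot trackId source track id (`NA` for pooled curves).
#' @export
setClass("MSDCurve",
    representation(lags = "numeric", msd = "numeric", counts = "numeric",
                   trackId = "integer"))

setValidity("MSDCurve", function(object) {
    if (length(object@lags) != length(object@msd) ||
        length(object@lags) != length(object@counts))
        return("lags, msd and counts must have equal length")
    if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
    if (any(object@msd < -1e-12)) return("MSD must be >= 0")
    TRUE
})

#' Diffusion-coefficient fit of an MSD curve
#'
#' Weighted linear fit MSD(t) = 4 D t + C over the first lags, with the
#' offset C absorbing localization noise (C = 4 sigma^2 for pure noise).
#' A negative D is reported with a warning flag rather than clamped, so
#' estimator bias stays measurable.
#'
#' @slot D diffusion coefficient, µm^2/s.
#' @slot C offset, µm^2.
#' @slot se standard errors, named c(D, C).
#' @slot nLags number of initial lags fitted.
#' @slot warn TRUE when D < 0 (noise-dominated).
#' @export
setClass("DiffusionFit",
    representation(D = "numeric", C = "numeric", se = "numeric",
                   nLags = "integer", warn = "logical"))

#' Random-walk confidence envelope for MSD classification
#'
#' Per-lag 2.5% and 97.5% quantiles of individual time-averaged MSD curves
#' of pure random walks matched in length and localization noise, generated
#' by seeded simulation. Trajectories leaving the envelope for a run of
#' consecutive lags are classified as directed (above) or confined (below).
#'
#' @slot lags lag times, seconds.
#' @slot lower,upper per-lag 2.5% / 97.5% quantiles, µm^2.
#' @slot params generating parameters (D, trackLength, sigmaLoc,
#'   replicates, seed).
#' @export
setClass("Envelope",
    representation(lags = "numeric", lower = "numeric", upper = "numeric",
                   params = "list"))

setValidity("Envelope", function(object) {
    if (length(object@lags) != length(object@lower) ||
        length(object@lags) != length(object@upper))
        return("lags, lower and upper must have equal length")
    if (any(object@lower > object@upper))
        return("lower must be <= upper at every lag")
    TRUE
})

#' Set of reconstructed cluster regions
#'
#' Clusters identified by single-molecule residency: regions where a
#' molecule's consecutive localizations stay within a diffraction-limited
#' radius for at least the residency threshold. Each region carries its
#' member positions, the second-moment ellipse (with localization-noise
#' correction), and optionally a circularity value.
#'
#' @slot summary data.frame: `clusterId`, `cx`, `cy`, `n` (positions),
#'   `residency` (frames), `a`, `b` (uncorrected semi-axes, nm), `aCorr`,
#'   `bCorr`, `Dmax`, `Dmin` (corrected diameters, nm), `theta` (rad),
#'   `circularity`, `degenerate` flag.
#' @slot members list of per-region position matrices (columns x, y, nm).
#' @export
setClass("ClusterRegionSet",
    representation(summary = "data.frame", members = "list"))

setValidity("ClusterRegionSet", function(object) {
    if (nrow(object@summary) != length(object@members))
        return("summary rows and members list must align")
    TRUE
})

#' Cluster dwell-time records
#'
#' One row per residency episode of a molecule at a cluster: the time
#' between appearance at the cluster site and loss (for more than the loss
#' gap), frame-quantized, with censoring at the end of acquisition and the
#' departure cause when known.
#'
#' @slot records data.frame: `duration` (s), `frames`, `censored`,
#'   `cause`, `p` (relative exposure), `molecule`, `cluster`, `condition`.
#' @slot schedule the generating [AcquisitionSchedule-class].
#' @slot condition condition label.
#' @export
setClass("DwellRecords",
    representation(records = "data.frame", schedule = "AcquisitionSchedule",
                   condition = "character"))

setValidity("DwellRecords", function(object) {
    need <- c("duration", "frames", "censored", "cause", "p")
    if (!all(need %in% names(object@records)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    r <- object@records
    if (nrow(r)) {
        if (any(r$duration <= 0)) return("durations must be > 0")
        if (any(r$p <= 0 | r$p > 1)) return("p must lie in (0, 1]")
        lim <- object@schedule@nFrames * object@schedule@tInt
        if (any(r$duration > lim + 1e-9))
            return("no dwell may exceed nFrames * tInt")
    }
    TRUE
})

#' Single disappearance-rate estimate
#'
#' Rate of molecular disappearance from clusters under one illumination
#' protocol, from an exponential fit of the dwell-time histogram (default)
#' or censored-exponential maximum likelihood.
#'
#' @slot K rate, min^-1.
#' @slot se standard error, min^-1.
#' @slot n number of records used.
#' @slot method "histogram" or "mle".
#' @export
setClass("RateEstimate",
    representation(K = "numeric", se = "numeric", n = "integer",
                   method = "character"))

#' Decomposition of disappearance rates into bleaching, dissociation and
#' endocytosis
#'
#' Linear fits of the per-protocol disappearance rate K(p) = p Kb + Kd + Ke
#' against relative exposure p for a control branch and an endocytosis-off
#' (ATP-depleted) branch. The endocytosis-off intercept gives Kd; the
#' difference of intercepts gives Ke; the slope gives Kb.
#'
#' @slot perProtocol data.frame: `branch`, `p`, `K`, `se`, `n`.
#' @slot Kd dissociation rate, min^-1.
#' @slot Ke endocytosis rate, min^-1.
#' @slot Kb bleaching rate(s), min^-1 (named per branch, or single pooled).
#' @slot se standard errors, named c(Kd, Ke, Kb.control, Kb.kcn).
#' @slot diagnostics list of per-branch lm fits and residuals.
#' @export
setClass("RateDecomposition",
    representation(perProtocol = "data.frame", Kd = "numeric", Ke = "numeric",
                   Kb = "numeric", se = "numeric", diagnostics = "list"))

setValidity("RateDecomposition", function(object) {
    if (any(c(object@Kd, object@Ke, object@Kb) < 0))
        return("reported rates must be >= 0 (negative estimates are clamped with a warning)")
    TRUE
})

#' Detected exocytic fusion event
#'
#' A transient reporter-channel flash with its molecule-channel response:
#' classified as fusion-with-dispersal (delivered molecules leave the site
#' by diffusion), fusion-with-retention (a persistent punctum forms), or
#' ambiguous.
#'
#' @slot events data.frame: `frame`, `x`, `y` (nm), `amplitude`,
#'   `mode`, `delay` (s, dispersal only).
#' @slot roiRadius ROI radius used for the molecule-channel trace, nm.
#' @export
setClass("FusionEventSet",
    representation(events = "data.frame", roiRadius = "numeric"))
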