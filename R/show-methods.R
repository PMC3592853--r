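#' @describeIn AcquisitionSchedule-class compact display
#' @param object the object.
#' @export
setMethod("show", "AcquisitionSchedule", function(object) {
    cat(sprintf(
        "AcquisitionSchedule: tExp %g s, tInt %g s (p = %.3g), %d frames\n",
        object@tExp, object@tInt, relativeExposure(object), object@nFrames))
})

#' @describeIn ScenarioConfig-class compact display
#' @param object the object.
#' @export
setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf("ScenarioConfig '%s'\n", object@preset))
    cat(sprintf("  D (free/in-cluster): %g / %g um^2/s\n",
                object@DFree, object@DIn))
    cat(sprintf("  rates (min^-1): Kd %g, Ke %g, Kb %g, Ka %.3g\n",
                object@Kd, object@Ke, object@Kb, object@Ka))
    cat(sprintf("  clusters: %g/um^2, %g x %g nm (sd %g); field %g x %g um\n",
                object@clusterDensity, object@clusterMajor,
                object@clusterMinor, object@clusterAxisSD,
                object@fieldSize[1], object@fieldSize[2]))
    cat(sprintf("  %d molecules; sigmaLoc %g nm; association '%s'; seed %d\n",
                object@nMolecules, object@sigmaLoc, object@association,
                object@seed))
})

#' @describeIn LocalizationTable-class compact display
#' @param object the object.
#' @export
setMethod("show", "LocalizationTable", function(object) {
    cat(sprintf(
        "LocalizationTable: %d localizations, %d frames, pixel %g nm\n",
        nrow(object@locs), object@schedule@nFrames, object@pixelSize))
})

#' @describeIn TrackSet-class compact display
#' @param object the object.
#' @export
setMethod("show", "TrackSet", function(object) {
    n <- length(unique(object@spots$track))
    cat(sprintf("TrackSet: %d tracks, %d detections, tInt %g s\n",
                n, nrow(object@spots), object@tInt))
})

#' @describeIn MSDCurve-class compact display
#' @param object the object.
#' @export
setMethod("show", "MSDCurve", function(object) {
    cat(sprintf("MSDCurve: %d lags (%.3g..%.3g s), MSD %.3g..%.3g um^2\n",
                length(object@lags), min(object@lags), max(object@lags),
                min(object@msd), max(object@msd)))
})

#' @describeIn DiffusionFit-class compact display
#' @param object the object.
#' @export
setMethod("show", "DiffusionFit", function(object) {
    cat(sprintf("DiffusionFit: D = %.4g +/- %.2g um^2/s, C = %.4g um^2 (%d lags)%s\n",
                object@D, object@se["D"], object@C, object@nLags,
                if (object@warn) " [noise-dominated]" else ""))
})

#' @describeIn ClusterRegionSet-class compact display
#' @param object the object.
#' @export
setMethod("show", "ClusterRegionSet", function(object) {
    s <- object@summary
    cat(sprintf("ClusterRegionSet: %d regions\n", nrow(s)))
    if (nrow(s) && any(!is.na(s$Dmax)))
        cat(sprintf("  corrected diameters: Dmax %.0f nm, Dmin %.0f nm (means)\n",
                    mean(s$Dmax, na.rm = TRUE), mean(s$Dmin, na.rm = TRUE)))
})

#' @describeIn DwellRecords-class compact display
#' @param object the object.
#' @export
setMethod("show", "DwellRecords", function(object) {
    r <- object@records
    cat(sprintf("DwellRecords '%s': %d records (%d censored), p = %.3g\n",
                object@condition, nrow(r), sum(r$censored),
                relativeExposure(object@schedule)))
})

#' @describeIn RateEstimate-class compact display
#' @param object the object.
#' @export
setMethod("show", "RateEstimate", function(object) {
    cat(sprintf("RateEstimate (%s): K = %.4g +/- %.2g min^-1 (n = %d)\n",
                object@method, object@K, object@se, object@n))
})

#' @describeIn RateDecomposition-class compact display
#' @param object the object.
#' @export
setMethod("show", "RateDecomposition", function(object) {
    cat("RateDecomposition (K(p) = p Kb + Kd + Ke)\n")
    cat(sprintf("  Kd = %.4g +/- %.2g min^-1\n", object@Kd, object@se["Kd"]))
    cat(sprintf("  Ke = %.4g +/- %.2g min^-1\n", object@Ke, object@se["Ke"]))
    cat(sprintf("  Kb = %s min^-1\n",
                paste(sprintf("%.3g", object@Kb), collapse = " / ")))
})

#' @describeIn FusionEventSet-class compact display
#' @param object the object.
#' @export
setMethod("show", "FusionEventSet", function(object) {
    cat(sprintf("FusionEventSet: %d events (%s)\n", nrow(object@events),
                paste(names(table(object@events$mode)),
                      table(object@events$mode), sep = ":",
                      collapse = ", ")))
})
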