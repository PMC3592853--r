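#' Extract per-track data.frames from a TrackSet
#'
#' @param x a [TrackSet-class].
#' @return named list of data.frames (frame, x, y), one per track.
#' @export
tracks <- function(x) {
    stopifnot(is(x, "TrackSet"))
    split(x@spots[c("frame", "x", "y")], x@spots$track)
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' For each integer lag n, averages the squared displacement over all
#' ordered pairs of detections exactly n frames apart. Gaps are allowed:
#' pairs spanning a blink gap contribute at their true time lag, and the
#' pair count per lag is recorded (for weighting the linear fit).
#'
#' @param track a data.frame with columns `frame`, `x`, `y` (nm), or a
#'   [TrackSet-class] holding a single track.
#' @param tInt frame interval, s (taken from the TrackSet if given one).
#' @param maxLag largest lag in frames (default: span - 1).
#' @return An [MSDCurve-class] with lags in s and MSD in µm^2.
#' @examples
#' tr <- data.frame(frame = 0:4, x = c(0, 100, 200, 300, 400), y = 0)
#' computeMSD(tr, tInt = 0.2)@msd  # (n * 100 nm)^2 in µm^2
#' @export
computeMSD <- function(track, tInt = NULL, maxLag = NULL) {
    if (is(track, "TrackSet")) {
        tInt <- track@tInt
        track <- track@spots
        if (length(unique(track$track)) != 1L)
            stop("computeMSD expects a single track; see pooledMSD")
    }
    if (is.null(tInt)) stop("tInt is required")
    if (nrow(track) < 2L) stop("track must have at least 2 detections")
    o <- order(track$frame)
    fr <- track$frame[o]; x <- track$x[o]; y <- track$y[o]
    span <- max(fr) - min(fr)
    if (is.null(maxLag)) maxLag <- span
    msd <- numeric(maxLag); cnt <- numeric(maxLag)
    # dense position-by-frame lookup turns each lag into one vector op
    xs <- rep(NA_real_, span + 1L); ys <- xs
    xs[fr - min(fr) + 1L] <- x; ys[fr - min(fr) + 1L] <- y
    for (lag in seq_len(maxLag)) {
        dx <- xs[-seq_len(lag)] - xs[seq_len(length(xs) - lag)]
        dy <- ys[-seq_len(lag)] - ys[seq_len(length(ys) - lag)]
        ok <- !is.na(dx)
        cnt[lag] <- sum(ok)
        msd[lag] <- if (cnt[lag]) mean(dx[ok]^2 + dy[ok]^2) else NA_real_
    }
    keep <- cnt > 0
    new("MSDCurve", lags = (seq_len(maxLag) * tInt)[keep],
        msd = msd[keep] / NM2_PER_UM2, counts = cnt[keep],
        trackId = NA_integer_)
}

#' Pool MSD curves across trajectories
#'
#' Averages time-averaged MSD curves over trajectories at each common lag,
#' weighting each trajectory's value by its pair count, so the pooled
#' curve estimates the population MSD.
#'
#' @param curves list of [MSDCurve-class] objects sharing a lag grid, or a
#'   [TrackSet-class] (curves computed per track).
#' @param maxLag largest lag in frames when computing from a TrackSet.
#' @return A pooled [MSDCurve-class].
#' @export
pooledMSD <- function(curves, maxLag = 10L) {
    if (is(curves, "TrackSet")) {
        tInt <- curves@tInt
        curves <- lapply(tracks(curves), computeMSD, tInt = tInt,
                         maxLag = maxLag)
    }
    stopifnot(length(curves) >= 1L)
    lags <- sort(unique(unlist(lapply(curves, function(cv) cv@lags))))
    num <- den <- numeric(length(lags))
    for (cv in curves) {
        i <- match(cv@lags, lags)
        num[i] <- num[i] + cv@msd * cv@counts
        den[i] <- den[i] + cv@counts
    }
    keep <- den > 0
    new("MSDCurve", lags = lags[keep], msd = (num / den)[keep],
        counts = den[keep], trackId = NA_integer_)
}

#' Fit the linear diffusion law MSD(t) = 4 D t + C
#'
#' Weighted least squares over the first `nLags` lags, with weights equal
#' to the displacement-pair counts. D = slope / 4; the offset C absorbs
#' localization noise (pure noise gives C = 4 sigma^2). Negative D is
#' reported with a warning flag, not clamped.
#'
#' @param curve an [MSDCurve-class] (single-track or pooled).
#' @param nLags number of initial lags to fit (>= 2; default 4).
#' @return A [DiffusionFit-class].
#' @examples
#' cv <- new("MSDCurve", lags = (1:4) * 0.2, msd = 4 * 0.1 * (1:4) * 0.2,
#'           counts = rep(10, 4), trackId = NA_integer_)
#' fitLinearMSD(cv)@D  # 0.1
#' @export
fitLinearMSD <- function(curve, nLags = 4L) {
    stopifnot(is(curve, "MSDCurve"))
    if (nLags < 2L) stop("nLags must be >= 2")
    k <- min(nLags, length(curve@lags))
    if (k < 2L) stop("curve has fewer than 2 lags")
    t <- curve@lags[seq_len(k)]; m <- curve@msd[seq_len(k)]
    w <- curve@counts[seq_len(k)]
    if (length(unique(t)) < 2L) stop("degenerate lag grid")
    fit <- stats::lm(m ~ t, weights = w)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    D <- unname(cf[2]) / 4
    # Class= spelled out: a slot named C would otherwise partial-match it
    new(Class = "DiffusionFit", D = D, C = unname(cf[1]),
        se = c(D = unname(se[2]) / 4, C = unname(se[1])),
        nLags = as.integer(k), warn = D < 0)
}

#' Simulation-based 95\% confidence envelope for random-walk MSD curves
#'
#' Simulates pure random walks matched in length and localization noise to
#' the trajectories under classification, computes each realization's
#' time-averaged MSD, and records the per-lag empirical 2.5\% and 97.5\%
#' quantiles. A trajectory whose MSD leaves this envelope for a sustained
#' run of lags is not compatible with free diffusion.
#'
#' @param D diffusion coefficient conditioning the envelope, µm^2/s.
#' @param trackLength frames per simulated walk.
#' @param sigmaLoc localization noise per coordinate, nm.
#' @param tInt frame interval, s.
#' @param replicates number of simulated walks (>= 100; default 1000).
#' @param seed integer seed.
#' @param maxLag largest lag in frames. The default, the first quarter of
#'   the track length (minimum 6), keeps classification on the
#'   well-averaged lags: time-averaged MSD values at lags comparable to
#'   the track length rest on very few displacement pairs and are almost
#'   perfectly correlated between neighbouring lags, so including them
#'   produces spurious sustained excursions.
#' @return An [Envelope-class].
#' @export
buildEnvelope <- function(D, trackLength, sigmaLoc = 30, tInt = 0.2,
                          replicates = 1000L, seed = 1L, maxLag = NULL) {
    if (replicates < 100L) stop("replicates must be >= 100")
    if (is.null(maxLag))
        maxLag <- min(trackLength - 1L, max(6L, floor(trackLength / 4)))
    ts <- simulateFreeTracks(replicates, trackLength, D = D,
                             sigmaLoc = sigmaLoc, tInt = tInt, seed = seed)
    curves <- lapply(tracks(ts), computeMSD, tInt = tInt, maxLag = maxLag)
    msds <- vapply(curves, function(cv) cv@msd[seq_len(maxLag)],
                   numeric(maxLag))
    lo <- apply(msds, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(msds, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
    new("Envelope", lags = seq_len(maxLag) * tInt, lower = unname(lo),
        upper = unname(hi),
        params = list(D = D, trackLength = trackLength, sigmaLoc = sigmaLoc,
                      tInt = tInt, replicates = replicates, seed = seed))
}

#' Classify a trajectory as free, directed or confined
#'
#' Compares a trajectory's MSD curve against the random-walk envelope: a
#' run of at least `runRule` consecutive lags above the upper bound is
#' scored directed; below the lower bound, confined; otherwise free.
#'
#' @param curve an [MSDCurve-class].
#' @param envelope an [Envelope-class] on the same lag grid.
#' @param runRule consecutive-lag run length required (default 5).
#' @return A one-row data.frame: `label`, `maxRunAbove`, `maxRunBelow`.
#' @export
classifyTrajectory <- function(curve, envelope, runRule = 5L) {
    stopifnot(is(curve, "MSDCurve"), is(envelope, "Envelope"))
    i <- match(round(curve@lags, 9), round(envelope@lags, 9))
    ok <- !is.na(i)
    if (!any(ok)) stop("curve and envelope lag grids do not overlap")
    above <- curve@msd[ok] > envelope@upper[i[ok]]
    below <- curve@msd[ok] < envelope@lower[i[ok]]
    runAbove <- .maxRun(above); runBelow <- .maxRun(below)
    label <- if (runAbove >= runRule && runAbove >= runBelow) "directed"
             else if (runBelow >= runRule) "confined" else "free"
    data.frame(label = label, maxRunAbove = runAbove, maxRunBelow = runBelow)
}

.maxRun <- function(flag) {
    if (!length(flag) || !any(flag)) return(0L)
    r <- rle(flag)
    max(r$lengths[r$values])
}

#' Classify every trajectory of a TrackSet
#'
#' Convenience wrapper: computes each track's MSD (over the envelope's lag
#' grid) and applies [classifyTrajectory()]. Tracks shorter than
#' `minPoints` detections are dropped first.
#'
#' @param trackset a [TrackSet-class].
#' @param envelope an [Envelope-class].
#' @param runRule consecutive-lag rule (default 5).
#' @param minPoints minimum detections per track (default 30).
#' @return data.frame: `track`, `label`, `maxRunAbove`, `maxRunBelow`.
#' @export
classifyTracks <- function(trackset, envelope, runRule = 5L,
                           minPoints = 30L) {
    trackset <- filterTrajectories(trackset, minPoints)
    trl <- tracks(trackset)
    maxLag <- length(envelope@lags)
    out <- lapply(names(trl), function(id) {
        cv <- computeMSD(trl[[id]], tInt = trackset@tInt, maxLag = maxLag)
        cbind(track = as.integer(id),
              classifyTrajectory(cv, envelope, runRule))
    })
    do.call(rbind, out)
}

#' Population fractions of motion classes with SEM across cells
#'
#' The cell is the replication unit: each cell contributes one fraction
#' per class, and the population estimate is the mean with its standard
#' error across cells. Directed tracks can be excluded from the
#' free/confined denominator (intracellular vesicle transport seen under
#' wide-field activation is not plasma-membrane diffusion).
#'
#' @param classesPerCell list (one element per cell) of character vectors
#'   of labels in {free, directed, confined}.
#' @param excludeDirected drop directed tracks from the denominator
#'   (default TRUE).
#' @return data.frame: `label`, `fraction`, `sem`, `nCells` (`sem` is NA,
#'   with a warning, for a single cell).
#' @export
populationFractions <- function(classesPerCell, excludeDirected = TRUE) {
    if (!length(classesPerCell)) stop("at least one cell is required")
    labs <- c("free", "confined", "directed")
    per <- lapply(classesPerCell, function(cl) {
        den <- if (excludeDirected) cl[cl != "directed"] else cl
        c(free = mean(den == "free"), confined = mean(den == "confined"),
          directed = mean(cl == "directed"))
    })
    mat <- do.call(rbind, per)
    frac <- colMeans(mat)
    sem <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
    if (nrow(mat) == 1L) {
        warning("single cell: SEM undefined")
        sem[] <- NA_real_
    }
    data.frame(label = labs, fraction = unname(frac[labs]),
               sem = unname(sem[labs]), nCells = length(classesPerCell))
}

#' Estimate confinement-zone diameter from the MSD plateau
#'
#' For a molecule confined to a domain, the time-averaged MSD saturates:
#' for positions independently and uniformly distributed over a disc of
#' radius R, the expected squared displacement between two positions is
#' exactly R^2, so plateau MSD = R^2 + 4 sigma^2 once localization noise
#' is included. The estimator locates the plateau (lags beyond the knee,
#' the first lag where MSD < 0.5 x 4 D t), subtracts the noise floor in
#' quadrature, and inverts: diameter = 2 sqrt(plateau - 4 sigma^2),
#' clamped at 0 with a warning when noise exceeds the plateau.
#'
#' @param curve an [MSDCurve-class] of a confined trajectory.
#' @param sigmaLoc localization noise per coordinate, nm.
#' @param DFree free-diffusion coefficient locating the knee, µm^2/s.
#' @return list: `diameter` (nm), `plateau` (µm^2), `flagged` (TRUE when
#'   the plateau is not reached or the noise term dominates).
#' @export
estimateConfinementSize <- function(curve, sigmaLoc = 30, DFree = 0.092) {
    stopifnot(is(curve, "MSDCurve"))
    knee <- which(curve@msd < 0.5 * 4 * DFree * curve@lags)
    if (!length(knee))
        return(list(diameter = NA_real_, plateau = NA_real_, flagged = TRUE))
    i0 <- knee[1]
    iN <- max(i0, floor(length(curve@lags) * 0.75))
    idx <- i0:iN
    plateau <- stats::weighted.mean(curve@msd[idx], curve@counts[idx])
    noise <- 4 * (sigmaLoc / 1000)^2
    flagged <- FALSE
    inner <- plateau - noise
    if (inner < 0) {
        warning("noise floor exceeds MSD plateau; diameter clamped to 0")
        inner <- 0; flagged <- TRUE
    }
    list(diameter = 2 * sqrt(inner) * 1000, plateau = plateau,
         flagged = flagged)
}
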