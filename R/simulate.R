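#' Simulate photoactivated single-molecule trajectories with ground truth
#'
#' The generative model behind every parameter-recovery test in the
#' package. Free molecules perform 2D Brownian motion (per-coordinate step
#' variance 2 D tInt) in a field with reflecting edges. Elongated
#' cluster ellipses are planted at the configured density; captured
#' molecules diffuse with a reflecting boundary at the ellipse (the
#' boundary is enforced on Brownian substeps small relative to the minor
#' axis, so the stationary intra-cluster distribution is uniform). Per
#' frame, hazards are applied in the order bleach (rate Kb over the
#' illuminated time tExp) -> endocytosis (clustered molecules, rate Ke) ->
#' dissociation (rate Kd). Association is either rate-based (free
#' molecules are captured at hazard Ka and bind the nearest cluster) or
#' spatial (capture with probability `pCapture` on geometric entry into an
#' ellipse). Localizations are true positions plus independent Gaussian
#' noise per coordinate (sd `sigmaLoc`); blinking removes localizations
#' for truncated-geometric gaps of at most `blinkMaxGap` frames.
#'
#' @param config a [ScenarioConfig-class] from [makeScenario()].
#' @param schedule an [AcquisitionSchedule-class].
#' @return A list with elements `locs` (a [LocalizationTable-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' cfg <- makeScenario("basal", nMolecules = 20, seed = 7)
#' sim <- simulateTrajectories(cfg, acquisitionSchedule(0.2, 0.2, 50))
#' head(sim$locs@locs)
#' @export
simulateTrajectories <- function(config, schedule) {
    stopifnot(is(config, "ScenarioConfig"), is(schedule, "AcquisitionSchedule"))
    n <- config@nMolecules
    if (n < 1L) stop("at least one molecule is required")
    set.seed(config@seed)
    tInt <- schedule@tInt
    nF <- schedule@nFrames
    W <- config@fieldSize[1] * 1000  # nm
    H <- config@fieldSize[2] * 1000
    Dfree <- config@DFree * NM2_PER_UM2   # nm^2/s
    Din <- config@DIn * NM2_PER_UM2

    clusters <- .plantClusters(config, W, H)
    nC <- nrow(clusters)

    # per-frame hazards (rates are min^-1; bleach acts over tExp only)
    pBleach <- 1 - exp(-perMinToPerSec(config@Kb) * schedule@tExp)
    pEndo <- 1 - exp(-perMinToPerSec(config@Ke) * tInt)
    pDiss <- 1 - exp(-perMinToPerSec(config@Kd) * tInt)
    pAssoc <- 1 - exp(-perMinToPerSec(config@Ka) * tInt)

    x <- runif(n, 0, W); y <- runif(n, 0, H)
    memb <- integer(n)
    if (nC > 0 && config@fClustered0 > 0) {
        init <- which(runif(n) < config@fClustered0)
        if (length(init)) {
            cid <- sample.int(nC, length(init), replace = TRUE)
            pos <- .uniformInEllipse(clusters[cid, , drop = FALSE])
            x[init] <- pos[, 1]; y[init] <- pos[, 2]
            memb[init] <- cid
        }
    }
    alive <- rep(TRUE, n)
    cause <- rep(NA_character_, n)
    endFrame <- rep(nF - 1L, n)
    offLeft <- integer(n)

    sd1 <- sqrt(2 * Dfree * tInt)
    # substeps keep intra-cluster rms steps below ~ a quarter of the
    # typical minor semi-axis (capped: cluster membership and residency,
    # not fine intra-cluster geometry, are what this simulation feeds)
    bTyp <- if (nC) stats::median(clusters$b) else Inf
    nSub <- if (nC && Din > 0)
        min(64L, max(1L, ceiling(2 * Din * tInt / (bTyp / 4)^2))) else 1L

    tx <- matrix(NA_real_, n, nF); ty <- matrix(NA_real_, n, nF)
    tc <- matrix(NA_integer_, n, nF)
    vis <- matrix(FALSE, n, nF)

    for (f in seq_len(nF)) {
        idx <- which(alive)
        if (!length(idx)) break
        tx[idx, f] <- x[idx]; ty[idx, f] <- y[idx]; tc[idx, f] <- memb[idx]

        # blinking bookkeeping: dark molecules are not localized this frame
        dark <- offLeft[idx] > 0L
        offLeft[idx[dark]] <- offLeft[idx[dark]] - 1L
        lit <- idx[!dark]
        if (length(lit) && config@blinkOffProb > 0) {
            go <- runif(length(lit)) < config@blinkOffProb
            if (any(go)) {
                gl <- .truncGeomGap(sum(go), config@blinkOffProb,
                                    config@blinkMaxGap)
                # the switch frame itself is the first dark frame
                offLeft[lit[go]] <- gl - 1L
                lit <- lit[!go]
            }
        }
        vis[lit, f] <- TRUE

        # hazards, in order bleach -> endocytosis -> dissociation
        u <- runif(length(idx))
        bl <- u < pBleach
        if (any(bl)) {
            alive[idx[bl]] <- FALSE
            cause[idx[bl]] <- "bleach"; endFrame[idx[bl]] <- f - 1L
        }
        left <- idx[!bl]
        cl <- left[memb[left] > 0L]
        if (length(cl) && pEndo > 0) {
            en <- runif(length(cl)) < pEndo
            if (any(en)) {
                alive[cl[en]] <- FALSE
                cause[cl[en]] <- "endocytosis"; endFrame[cl[en]] <- f - 1L
                cl <- cl[!en]
            }
        }
        if (length(cl) && pDiss > 0) {
            di <- runif(length(cl)) < pDiss
            memb[cl[di]] <- 0L
        }

        # association of free molecules (rate-based mode)
        fr <- which(alive & memb == 0L)
        if (length(fr) && nC > 0 && config@association == "rate" && pAssoc > 0) {
            as_ <- fr[runif(length(fr)) < pAssoc]
            if (length(as_)) {
                cid <- .nearestCluster(x[as_], y[as_], clusters)
                pos <- .uniformInEllipse(clusters[cid, , drop = FALSE])
                x[as_] <- pos[, 1]; y[as_] <- pos[, 2]
                memb[as_] <- cid
            }
        }

        # movement
        fr <- which(alive & memb == 0L)
        if (length(fr)) {
            x[fr] <- foldUnit((x[fr] + rnorm(length(fr), 0, sd1)) / W) * W
            y[fr] <- foldUnit((y[fr] + rnorm(length(fr), 0, sd1)) / H) * H
            if (nC > 0 && config@association == "spatial" &&
                config@pCapture > 0) {
                hit <- .ellipseHit(x[fr], y[fr], clusters)
                cap <- hit > 0L & runif(length(fr)) < config@pCapture
                memb[fr[cap]] <- hit[cap]
            }
        }
        cl <- which(alive & memb > 0L)
        if (length(cl)) {
            pos <- .confinedStep(x[cl], y[cl], clusters[memb[cl], , drop = FALSE],
                                 Din, tInt, nSub)
            x[cl] <- pos[, 1]; y[cl] <- pos[, 2]
        }
    }
    cause[is.na(cause)] <- "censored"

    frameIdx <- matrix(rep(seq_len(nF) - 1L, each = n), n, nF)
    molIdx <- matrix(rep(seq_len(n), nF), n, nF)
    keep <- !is.na(tx)
    positions <- data.frame(frame = frameIdx[keep], molecule = molIdx[keep],
                            x = tx[keep], y = ty[keep],
                            clusterId = tc[keep])
    positions <- positions[order(positions$molecule, positions$frame), ]
    rownames(positions) <- NULL

    obs <- keep & vis
    locs <- data.frame(frame = frameIdx[obs], molecule = molIdx[obs],
                       x = tx[obs] + rnorm(sum(obs), 0, config@sigmaLoc),
                       y = ty[obs] + rnorm(sum(obs), 0, config@sigmaLoc),
                       sigma = config@sigmaLoc, channel = "activated")
    locs <- locs[order(locs$molecule, locs$frame), ]
    rownames(locs) <- NULL

    molecules <- data.frame(molecule = seq_len(n), birthFrame = 0L,
                            endFrame = endFrame, cause = cause)
    list(locs = new("LocalizationTable", locs = locs, pixelSize = 160,
                    schedule = schedule),
         truth = new("GroundTruth", molecules = molecules,
                     positions = positions, clusters = clusters))
}

.plantClusters <- function(config, W, H) {
    nC <- round(config@clusterDensity * (W / 1000) * (H / 1000))
    if (nC < 1)
        return(data.frame(clusterId = integer(), cx = numeric(),
                          cy = numeric(), a = numeric(), b = numeric(),
                          theta = numeric()))
    a <- pmax(60, rnorm(nC, config@clusterMajor, config@clusterAxisSD)) / 2
    b <- pmax(40, rnorm(nC, config@clusterMinor, config@clusterAxisSD)) / 2
    swap <- b > a
    if (any(swap)) { tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp }
    data.frame(clusterId = seq_len(nC),
               cx = runif(nC, 0, W), cy = runif(nC, 0, H),
               a = a, b = b, theta = runif(nC, 0, pi))
}

# uniform draws inside each row's ellipse
.uniformInEllipse <- function(cl) {
    n <- nrow(cl)
    r <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
    u <- r * cos(phi) * cl$a; v <- r * sin(phi) * cl$b
    ct <- cos(cl$theta); st <- sin(cl$theta)
    cbind(cl$cx + ct * u - st * v, cl$cy + st * u + ct * v)
}

.nearestCluster <- function(x, y, clusters) {
    vapply(seq_along(x), function(i)
        which.min((clusters$cx - x[i])^2 + (clusters$cy - y[i])^2),
        integer(1))
}

# id of containing ellipse (0 if none); densities are sparse so O(n * nC)
.ellipseHit <- function(x, y, clusters) {
    hit <- integer(length(x))
    for (j in seq_len(nrow(clusters))) {
        inj <- hit == 0L & insideEllipse(x, y, clusters$cx[j], clusters$cy[j],
                                         clusters$a[j], clusters$b[j],
                                         clusters$theta[j])
        hit[inj] <- j
    }
    hit
}

# truncated-geometric blink gap lengths in 1..maxGap
.truncGeomGap <- function(n, pOff, maxGap) {
    g <- 1L + rgeom(n, prob = max(0.25, 1 - pOff))
    pmin(g, as.integer(maxGap))
}

# Brownian substeps with radial reflection inside each molecule's ellipse,
# done in ellipse-aligned coordinates; substeps keep rms << minor axis so
# the stationary distribution is uniform over the ellipse.
.confinedStep <- function(x, y, cl, Dnm, tInt, nSub) {
    ct <- cos(cl$theta); st <- sin(cl$theta)
    dx <- x - cl$cx; dy <- y - cl$cy
    u <- ct * dx + st * dy
    v <- -st * dx + ct * dy
    sd <- sqrt(2 * Dnm * (tInt / nSub))
    n <- length(x)
    for (s in seq_len(nSub)) {
        u <- u + rnorm(n, 0, sd)
        v <- v + rnorm(n, 0, sd)
        rho <- sqrt((u / cl$a)^2 + (v / cl$b)^2)
        out <- rho > 1
        if (any(out)) {
            fac <- foldUnit(rho[out]) / rho[out]
            u[out] <- u[out] * fac
            v[out] <- v[out] * fac
        }
    }
    cbind(cl$cx + ct * u - st * v, cl$cy + st * u + ct * v)
}

#' Simulate pure free-diffusion trajectories
#'
#' Random walks with localization noise and no clusters; the workhorse for
#' diffusion-coefficient recovery and for the MSD confidence envelope.
#'
#' @param nTracks number of trajectories.
#' @param nFrames frames per trajectory.
#' @param D diffusion coefficient, µm^2/s.
#' @param sigmaLoc localization noise per coordinate, nm.
#' @param tInt frame interval, s.
#' @param seed integer seed.
#' @return A [TrackSet-class].
#' @export
simulateFreeTracks <- function(nTracks, nFrames, D = 0.092, sigmaLoc = 30,
                               tInt = 0.2, seed = 1L) {
    stopifnot(nTracks >= 1, nFrames >= 2)
    set.seed(seed)
    sd1 <- sqrt(2 * D * NM2_PER_UM2 * tInt)
    sx <- matrix(rnorm(nTracks * (nFrames - 1), 0, sd1), nTracks)
    sy <- matrix(rnorm(nTracks * (nFrames - 1), 0, sd1), nTracks)
    x <- cbind(0, t(apply(sx, 1, cumsum)))
    y <- cbind(0, t(apply(sy, 1, cumsum)))
    if (nFrames == 2) { x <- cbind(0, sx); y <- cbind(0, sy) }
    x <- x + rnorm(length(x), 0, sigmaLoc)
    y <- y + rnorm(length(y), 0, sigmaLoc)
    spots <- data.frame(track = rep(seq_len(nTracks), each = nFrames),
                        frame = rep(seq_len(nFrames) - 1L, nTracks),
                        x = as.vector(t(x)), y = as.vector(t(y)))
    new("TrackSet", spots = spots, tInt = tInt)
}

#' Simulate trajectories confined in reflecting circular domains
#'
#' Each trajectory diffuses inside its own reflecting disc of the given
#' diameter (Brownian substeps with specular radial reflection, small
#' relative to the radius, so positions are uniform over the disc at
#' stationarity). Used for confinement-size parameter recovery.
#'
#' @param nTracks number of trajectories (one disc each).
#' @param nFrames frames per trajectory.
#' @param diameter disc diameter, nm.
#' @param D intra-domain diffusion coefficient, µm^2/s.
#' @param sigmaLoc localization noise per coordinate, nm.
#' @param tInt frame interval, s.
#' @param seed integer seed.
#' @return A [TrackSet-class].
#' @export
simulateConfinedTracks <- function(nTracks, nFrames, diameter = 120,
                                   D = 0.092, sigmaLoc = 30, tInt = 0.2,
                                   seed = 1L) {
    stopifnot(nTracks >= 1, nFrames >= 2, diameter > 0)
    set.seed(seed)
    R <- diameter / 2
    Dnm <- D * NM2_PER_UM2
    nSub <- max(1L, ceiling(2 * Dnm * tInt / (R / 5)^2))
    sd <- sqrt(2 * Dnm * (tInt / nSub))
    r0 <- R * sqrt(runif(nTracks)); phi0 <- runif(nTracks, 0, 2 * pi)
    x <- r0 * cos(phi0); y <- r0 * sin(phi0)
    X <- matrix(NA_real_, nTracks, nFrames); Y <- X
    X[, 1] <- x; Y[, 1] <- y
    for (f in 2:nFrames) {
        for (s in seq_len(nSub)) {
            x <- x + rnorm(nTracks, 0, sd)
            y <- y + rnorm(nTracks, 0, sd)
            rho <- sqrt(x^2 + y^2) / R
            out <- rho > 1
            if (any(out)) {
                fac <- foldUnit(rho[out]) / rho[out]
                x[out] <- x[out] * fac; y[out] <- y[out] * fac
            }
        }
        X[, f] <- x; Y[, f] <- y
    }
    X <- X + rnorm(length(X), 0, sigmaLoc)
    Y <- Y + rnorm(length(Y), 0, sigmaLoc)
    spots <- data.frame(track = rep(seq_len(nTracks), each = nFrames),
                        frame = rep(seq_len(nFrames) - 1L, nTracks),
                        x = as.vector(t(X)), y = as.vector(t(Y)))
    new("TrackSet", spots = spots, tInt = tInt)
}

#' Simulate cluster dwell times from competing exponential clocks
#'
#' Bypasses the spatial simulation for fast kinetics testing: each dwell is
#' the minimum of independent exponential clocks for bleaching (rate
#' p Kb, with p the relative exposure of the schedule), dissociation (Kd)
#' and endocytosis (Ke), discretized to frame intervals and right-censored
#' at the end of acquisition; the winning cause is recorded.
#'
#' @param config a [ScenarioConfig-class] (supplies Kb, Kd, Ke).
#' @param schedule an [AcquisitionSchedule-class] (supplies p, tInt,
#'   nFrames).
#' @param n number of dwells to draw (>= 1).
#' @param seed optional integer seed.
#' @return A [DwellRecords-class].
#' @examples
#' cfg <- makeScenario("basal")
#' dw <- simulateDwellTimes(cfg, acquisitionSchedule(0.2, 0.5, 600), 100,
#'                          seed = 1)
#' table(dw@records$cause)
#' @export
simulateDwellTimes <- function(config, schedule, n, seed = NULL) {
    stopifnot(is(config, "ScenarioConfig"), is(schedule, "AcquisitionSchedule"))
    if (n < 1) stop("n must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    p <- relativeExposure(schedule)
    rates <- c(bleach = p * perMinToPerSec(config@Kb),
               dissociation = perMinToPerSec(config@Kd),
               endocytosis = perMinToPerSec(config@Ke))
    draw <- vapply(rates, function(r)
        if (r > 0) rexp(n, r) else rep(Inf, n), numeric(n))
    if (n == 1L) draw <- matrix(draw, nrow = 1,
                                dimnames = list(NULL, names(rates)))
    tmin <- apply(draw, 1, min)
    cause <- colnames(draw)[apply(draw, 1, which.min)]
    frames <- pmax(1, ceiling(tmin / schedule@tInt))
    cens <- frames > schedule@nFrames | !is.finite(tmin)
    frames[cens] <- schedule@nFrames
    cause[cens] <- "censored"
    if (all(cens))
        warning("all dwell records are censored (rates too small or zero)")
    records <- data.frame(duration = frames * schedule@tInt,
                          frames = as.integer(frames), censored = cens,
                          cause = cause, p = p,
                          molecule = seq_len(n), cluster = NA_integer_,
                          condition = config@preset)
    new("DwellRecords", records = records, schedule = schedule,
        condition = config@preset)
}
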