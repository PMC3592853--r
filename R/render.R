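# pixel-integrated isotropic Gaussian PSF: adds `photons` split over the
# pixel grid for emitters at (x, y) nm; img is modified and returned
.addEmitters <- function(img, x, y, photons, psfSigma, pixelSize) {
    sPx <- psfSigma / pixelSize
    nx <- ncol(img); ny <- nrow(img)
    for (i in seq_along(x)) {
        cx <- x[i] / pixelSize; cy <- y[i] / pixelSize
        c0 <- max(1, floor(cx - 4 * sPx)); c1 <- min(nx, ceiling(cx + 4 * sPx))
        r0 <- max(1, floor(cy - 4 * sPx)); r1 <- min(ny, ceiling(cy + 4 * sPx))
        if (c0 > c1 || r0 > r1) next
        px <- stats::pnorm(c0:c1, cx, sPx) - stats::pnorm((c0:c1) - 1, cx, sPx)
        py <- stats::pnorm(r0:r1, cy, sPx) - stats::pnorm((r0:r1) - 1, cy, sPx)
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + photons[i] * outer(py, px)
    }
    img
}

#' Render a ground-truth event log into a photon-count movie
#'
#' Each active emitter contributes an isotropic pixel-integrated 2D
#' Gaussian PSF with the given photon budget per frame on a uniform
#' background; Poisson shot noise is applied when requested. The `bulk`
#' channel instead renders the non-activated cluster fluorescence as
#' static puncta at the planted cluster sites over the diffusely
#' distributed free pool.
#'
#' @param truth a [GroundTruth-class] (an empty one renders background
#'   only).
#' @param schedule an [AcquisitionSchedule-class].
#' @param channel `"activated"` (single molecules) or `"bulk"`.
#' @param psfSigma PSF Gaussian sigma, nm (> 0).
#' @param photonBudget photons per emitter per frame.
#' @param background photons per pixel per frame.
#' @param pixelSize pixel size, nm (> 0).
#' @param fieldSize field width and height, µm.
#' @param shotNoise apply Poisson noise (default TRUE).
#' @param clusterPhotons photons per cluster per frame (bulk channel).
#' @param seed optional seed for the shot noise.
#' @return An [ImageStack-class].
#' @export
renderMovie <- function(truth, schedule, channel = c("activated", "bulk"),
                        psfSigma = 130, photonBudget = 500, background = 5,
                        pixelSize = 160, fieldSize = c(10, 10),
                        shotNoise = TRUE, clusterPhotons = 2000,
                        seed = NULL) {
    stopifnot(is(truth, "GroundTruth"), is(schedule, "AcquisitionSchedule"))
    channel <- match.arg(channel)
    if (pixelSize <= 0) stop("pixelSize must be positive")
    if (psfSigma <= 0) stop("psfSigma must be positive")
    if (!is.null(seed)) set.seed(seed)
    nx <- ceiling(fieldSize[1] * 1000 / pixelSize)
    ny <- ceiling(fieldSize[2] * 1000 / pixelSize)
    nF <- schedule@nFrames
    stack <- array(background, c(ny, nx, nF))
    if (channel == "activated" && nrow(truth@positions)) {
        byFrame <- split(truth@positions, truth@positions$frame)
        for (nm in names(byFrame)) {
            f <- as.integer(nm) + 1L
            if (f > nF) next
            pp <- byFrame[[nm]]
            stack[, , f] <- .addEmitters(stack[, , f], pp$x, pp$y,
                                         rep(photonBudget, nrow(pp)),
                                         psfSigma, pixelSize)
        }
    }
    if (channel == "bulk" && nrow(truth@clusters)) {
        frame0 <- .addEmitters(matrix(background, ny, nx),
                               truth@clusters$cx, truth@clusters$cy,
                               rep(clusterPhotons, nrow(truth@clusters)),
                               psfSigma, pixelSize)
        stack <- array(rep(frame0, nF), c(ny, nx, nF))
    }
    if (shotNoise)
        stack[] <- stats::rpois(length(stack), stack)
    new("ImageStack", data = stack, pixelSize = pixelSize,
        channel = channel, schedule = schedule)
}

#' Simulate a two-channel exocytic fusion movie with ground truth
#'
#' Each fusion event produces a transient flash in the reporter channel
#' (the luminal pH reporter de-quenches on fusion-pore opening: a step
#' increase decaying back to baseline within a couple of frames). In the
#' molecule channel the delivered cargo either disperses -- point emitters
#' leave the site by free diffusion after a short delay -- or is retained
#' as a persistent punctum.
#'
#' @param nEvents number of fusion events.
#' @param modeMix fraction of events with retention, in [0, 1].
#' @param schedule an [AcquisitionSchedule-class].
#' @param psfSigma PSF sigma, nm.
#' @param pixelSize pixel size, nm.
#' @param fieldSize field width and height, µm.
#' @param background photons per pixel per frame.
#' @param flashPhotons reporter-flash photons at peak.
#' @param cargoEmitters emitters delivered per event (dispersal).
#' @param emitterPhotons photons per cargo emitter per frame.
#' @param puncumPhotons photons per retained punctum per frame.
#' @param D post-dispersal diffusion coefficient, µm^2/s.
#' @param seed integer seed.
#' @return list: `reporter` and `molecule` ([ImageStack-class]), `truth`
#'   (data.frame: `event`, `frame`, `x`, `y`, `mode`, `delay` in s).
#' @export
simulateFusionMovie <- function(nEvents, modeMix, schedule,
                                psfSigma = 130, pixelSize = 160,
                                fieldSize = c(10, 10), background = 5,
                                flashPhotons = 8000, cargoEmitters = 12L,
                                emitterPhotons = 400, puncumPhotons = 4000,
                                D = 0.092, seed = 1L) {
    stopifnot(modeMix >= 0, modeMix <= 1, nEvents >= 1)
    set.seed(seed)
    nx <- ceiling(fieldSize[1] * 1000 / pixelSize)
    ny <- ceiling(fieldSize[2] * 1000 / pixelSize)
    nF <- schedule@nFrames
    tInt <- schedule@tInt
    margin <- 1500  # keep ROIs inside the frame
    W <- fieldSize[1] * 1000; H <- fieldSize[2] * 1000
    # fusion sites are sparse; enforce separation so analysis ROIs of
    # neighbouring events do not overlap
    minSep <- 2500
    ex <- ey <- numeric(nEvents)
    for (i in seq_len(nEvents)) {
        for (try in 1:200) {
            px0 <- runif(1, margin, W - margin)
            py0 <- runif(1, margin, H - margin)
            if (i == 1L || all(sqrt((ex[seq_len(i - 1L)] - px0)^2 +
                                    (ey[seq_len(i - 1L)] - py0)^2) >= minSep))
                break
        }
        ex[i] <- px0; ey[i] <- py0
    }
    minF <- 12L
    maxF <- max(minF + 1L, nF - ceiling(12 / tInt))
    ef <- sample(minF:maxF, nEvents, replace = TRUE)
    retention <- runif(nEvents) < modeMix
    delay <- runif(nEvents, 0.5, 1.5)
    rep_ <- array(background, c(ny, nx, nF))
    mol <- array(background, c(ny, nx, nF))
    sd1 <- sqrt(2 * D * NM2_PER_UM2 * tInt)
    for (i in seq_len(nEvents)) {
        # reporter flash: peak then fast decay to baseline (1-2 frames)
        for (k in 0:3) {
            f <- ef[i] + k
            if (f > nF) break
            amp <- flashPhotons * exp(-k / 0.7)
            rep_[, , f] <- .addEmitters(rep_[, , f], ex[i], ey[i], amp,
                                        psfSigma, pixelSize)
        }
        if (retention[i]) {
            for (f in (ef[i]):nF)
                mol[, , f] <- .addEmitters(mol[, , f], ex[i], ey[i],
                                           puncumPhotons, psfSigma,
                                           pixelSize)
        } else {
            dFrames <- round(delay[i] / tInt)
            px <- rep(ex[i], cargoEmitters); py <- rep(ey[i], cargoEmitters)
            for (f in (ef[i]):nF) {
                if (f - ef[i] > dFrames) {
                    px <- px + rnorm(cargoEmitters, 0, sd1)
                    py <- py + rnorm(cargoEmitters, 0, sd1)
                }
                mol[, , f] <- .addEmitters(mol[, , f], px, py,
                                           rep(emitterPhotons, cargoEmitters),
                                           psfSigma, pixelSize)
            }
        }
    }
    rep_[] <- stats::rpois(length(rep_), rep_)
    mol[] <- stats::rpois(length(mol), mol)
    truth <- data.frame(event = seq_len(nEvents), frame = ef - 1L,
                        x = ex, y = ey,
                        mode = ifelse(retention, "retention", "dispersal"),
                        delay = ifelse(retention, NA_real_, delay))
    list(reporter = new("ImageStack", data = rep_, pixelSize = pixelSize,
                        channel = "reporter", schedule = schedule),
         molecule = new("ImageStack", data = mol, pixelSize = pixelSize,
                        channel = "molecule", schedule = schedule),
         truth = truth)
}
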