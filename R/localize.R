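#' Detect and sub-pixel-localize single emitters in one frame
#'
#' Assumes the sparse-activation regime of photoactivated single-molecule
#' imaging (0.01-0.1 activated emitters per µm^2): local maxima above
#' threshold are refined to sub-pixel positions by least-squares fit of an
#' isotropic 2D Gaussian (pixel-integrated) on a window around the peak;
#' candidate pairs closer than one PSF FWHM are merged. The localization
#' uncertainty is the photon-limited estimate sigma_psf / sqrt(N).
#'
#' Coordinates are continuous nm with origin at the top-left corner of
#' pixel (0,0); pixel centres lie at (i + 0.5) x pixelSize.
#'
#' @param frame 2D numeric matrix, photons (y rows, x columns).
#' @param threshold detection threshold in photons above local background
#'   (> 0).
#' @param psfSigma PSF Gaussian sigma, nm.
#' @param pixelSize pixel size, nm.
#' @return data.frame: `x`, `y` (nm), `intensity` (photons), `background`
#'   (photons/pixel), `uncertainty` (nm). Zero rows for empty frames.
#' @export
localizeFrame <- function(frame, threshold, psfSigma = 130,
                          pixelSize = 160) {
    stopifnot(is.matrix(frame), threshold > 0, psfSigma > 0, pixelSize > 0)
    bg <- stats::median(frame)
    peaks <- .localMaxima(frame, bg + threshold)
    if (!nrow(peaks))
        return(data.frame(x = numeric(), y = numeric(),
                          intensity = numeric(), background = numeric(),
                          uncertainty = numeric()))
    win <- max(2L, ceiling(3 * psfSigma / pixelSize))
    fits <- lapply(seq_len(nrow(peaks)), function(i)
        .fitGaussian(frame, peaks$row[i], peaks$col[i], win,
                     psfSigma / pixelSize, bg))
    out <- do.call(rbind, fits)
    out$x <- out$x * pixelSize
    out$y <- out$y * pixelSize
    # Thompson-style photon-limited uncertainty with pixelation and
    # background terms
    Nph <- pmax(out$intensity, 1)
    s2 <- psfSigma^2 + pixelSize^2 / 12
    bgVar <- pmax(out$background, 0)
    out$uncertainty <- sqrt(s2 / Nph +
        8 * pi * s2^2 * bgVar / (pixelSize^2 * Nph^2))
    # reject/merge pairs closer than one PSF FWHM
    fwhm <- 2.355 * psfSigma
    keep <- rep(TRUE, nrow(out))
    if (nrow(out) > 1L) {
        d <- as.matrix(stats::dist(out[, c("x", "y")]))
        for (i in seq_len(nrow(out) - 1L)) for (j in (i + 1L):nrow(out)) {
            if (keep[i] && keep[j] && d[i, j] < fwhm)
                keep[if (out$intensity[i] >= out$intensity[j]) j else i] <- FALSE
        }
    }
    out <- out[keep & out$intensity > 0, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.localMaxima <- function(img, level) {
    nr <- nrow(img); nc <- ncol(img)
    cand <- which(img >= level, arr.ind = TRUE)
    cand <- cand[cand[, 1] > 1 & cand[, 1] < nr &
                 cand[, 2] > 1 & cand[, 2] < nc, , drop = FALSE]
    ok <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1]; c2 <- cand[i, 2]
        nb <- img[(r - 1):(r + 1), (c2 - 1):(c2 + 1)]
        ok[i] <- img[r, c2] == max(nb)
    }
    data.frame(row = cand[ok, 1], col = cand[ok, 2])
}

# LS fit of pixel-integrated Gaussian; coordinates in pixel units
.fitGaussian <- function(img, r0, c0, win, sigmaPx, bg) {
    rows <- max(1, r0 - win):min(nrow(img), r0 + win)
    cols <- max(1, c0 - win):min(ncol(img), c0 + win)
    z <- img[rows, cols]
    # pixel centres at index - 0.5 (origin at corner of pixel (0,0))
    yc <- rows - 0.5; xc <- cols - 0.5
    model <- function(par) {
        dxf <- stats::pnorm(xc + 0.5, par[1], sigmaPx) -
               stats::pnorm(xc - 0.5, par[1], sigmaPx)
        dyf <- stats::pnorm(yc + 0.5, par[2], sigmaPx) -
               stats::pnorm(yc - 0.5, par[2], sigmaPx)
        par[3] * outer(dyf, dxf) + par[4]
    }
    obj <- function(par) sum((z - model(par))^2)
    a0 <- max(sum(z - bg), 1)
    fit <- stats::optim(c(c0 - 0.5, r0 - 0.5, a0, bg), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    data.frame(x = fit$par[1], y = fit$par[2], intensity = fit$par[3],
               background = fit$par[4])
}

#' Count step-wise drops in a single-molecule intensity trace
#'
#' Piecewise-constant fit by binary-segmentation change-point search with a
#' BIC-style penalty. A trace validating single-molecule identity shows
#' exactly one downward step to background (single-step bleaching); two
#' overlapping emitters show a two-level staircase.
#'
#' @param trace numeric intensity trace (length >= 10).
#' @param penalty change-point acceptance penalty as a multiple of
#'   log(n) x residual variance (default 4).
#' @return list: `nSteps` (downward steps), `stepFrames` (1-based change
#'   positions: last frame before each drop), `levels` (segment means).
#' @export
detectBleachSteps <- function(trace, penalty = 4) {
    if (length(trace) < 10L) stop("trace must have length >= 10")
    n <- length(trace)
    noise <- stats::mad(diff(trace)) / sqrt(2)
    if (noise == 0) noise <- stats::sd(trace)
    if (is.na(noise) || noise == 0) noise <- 1
    pen <- penalty * log(n) * noise^2
    cps <- sort(.binseg(trace, 1L, n, pen))
    bounds <- c(0L, cps, n)
    levels <- vapply(seq_len(length(bounds) - 1L), function(i)
        mean(trace[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
    down <- which(diff(levels) < 0)
    list(nSteps = length(down), stepFrames = cps[down], levels = levels)
}

.binseg <- function(x, from, to, pen) {
    n <- to - from + 1L
    if (n < 4L) return(integer())
    seg <- x[from:to]
    csum <- cumsum(seg); csq <- cumsum(seg^2)
    total <- csq[n] - csum[n]^2 / n
    k <- seq_len(n - 1L)
    rssL <- csq[k] - csum[k]^2 / k
    rssR <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
    gain <- total - (rssL + rssR)
    best <- which.max(gain)
    if (gain[best] <= pen) return(integer())
    cp <- from + best - 1L
    c(cp, .binseg(x, from, cp, pen), .binseg(x, cp + 1L, to, pen))
}

#' Link localizations into gap-tolerant trajectories
#'
#' Frame-to-frame nearest-neighbour assignment (greedy in order of
#' increasing distance, which resolves assignment conflicts in favour of
#' the closer pair) within `maxDisp` per frame of elapsed time. A molecule
#' that disappears and reappears within `maxGap` frames continues its
#' track with a recorded gap; longer absences start a new track. Every
#' localization is used by at most one track.
#'
#' @param locs a [LocalizationTable-class] or a data.frame with columns
#'   `frame`, `x`, `y` (nm; `molecule` is carried through if present).
#' @param maxDisp maximum displacement, nm per frame interval.
#' @param maxGap maximum bridged absence, frames (default 3).
#' @param tInt frame interval, s (taken from the LocalizationTable's
#'   schedule when given one).
#' @return A [TrackSet-class].
#' @export
linkTrajectories <- function(locs, maxDisp = 500, maxGap = 3L,
                             tInt = NULL) {
    if (is(locs, "LocalizationTable")) {
        tInt <- locs@schedule@tInt
        locs <- locs@locs
    }
    if (is.null(tInt)) stop("tInt is required")
    if (!nrow(locs))
        return(new("TrackSet",
                   spots = data.frame(track = integer(), frame = integer(),
                                      x = numeric(), y = numeric()),
                   tInt = tInt))
    hasMol <- "molecule" %in% names(locs)
    o <- order(locs$frame)
    locs <- locs[o, , drop = FALSE]
    trackId <- integer(nrow(locs))
    # active track state: id, last index into locs, last frame
    act <- list(id = integer(), idx = integer(), frame = integer())
    nextId <- 1L
    rowsByFrame <- split(seq_len(nrow(locs)), locs$frame)
    for (fr in as.integer(names(rowsByFrame))) {
        rows <- rowsByFrame[[as.character(fr)]]
        # drop tracks whose absence already exceeds maxGap
        keep <- fr - act$frame <= maxGap + 1L
        act <- lapply(act, `[`, keep)
        if (length(act$id) && length(rows)) {
            dx <- outer(locs$x[rows], locs$x[act$idx], `-`)
            dy <- outer(locs$y[rows], locs$y[act$idx], `-`)
            dist <- sqrt(dx^2 + dy^2)
            lim <- matrix(rep(maxDisp * (fr - act$frame), each = length(rows)),
                          nrow = length(rows))
            dist[dist > lim] <- NA
            repeat {
                if (all(is.na(dist))) break
                m <- arrayInd(which.min(dist), dim(dist))
                i <- m[1]; j <- m[2]
                trackId[rows[i]] <- act$id[j]
                act$idx[j] <- rows[i]; act$frame[j] <- fr
                dist[i, ] <- NA; dist[, j] <- NA
            }
        }
        newRows <- rows[trackId[rows] == 0L]
        if (length(newRows)) {
            ids <- seq.int(nextId, length.out = length(newRows))
            trackId[newRows] <- ids
            nextId <- nextId + length(newRows)
            act$id <- c(act$id, ids)
            act$idx <- c(act$idx, newRows)
            act$frame <- c(act$frame, rep(fr, length(newRows)))
        }
    }
    spots <- data.frame(track = trackId, frame = locs$frame,
                        x = locs$x, y = locs$y)
    if (hasMol) spots$molecule <- locs$molecule
    spots <- spots[order(spots$track, spots$frame), ]
    rownames(spots) <- NULL
    new("TrackSet", spots = spots, tInt = tInt)
}

#' Keep only trajectories with enough detections
#'
#' Length counts detections, not frame span: a track bridging blink gaps
#' must still contain at least `minPoints` localizations to enter motion
#' analysis.
#'
#' @param trackset a [TrackSet-class].
#' @param minPoints minimum detections (default 30, >= 2).
#' @return A filtered [TrackSet-class].
#' @export
filterTrajectories <- function(trackset, minPoints = 30L) {
    stopifnot(is(trackset, "TrackSet"), minPoints >= 2L)
    if (!nrow(trackset@spots)) return(trackset)
    len <- table(trackset@spots$track)
    keep <- names(len)[len >= minPoints]
    spots <- trackset@spots[trackset@spots$track %in% as.integer(keep), ,
                            drop = FALSE]
    rownames(spots) <- NULL
    new("TrackSet", spots = spots, tInt = trackset@tInt)
}
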