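# Independent oracles and small fixture builders, kept deliberately naive.

# brute-force time-averaged MSD: double loop over all ordered pairs
bruteForceMSD <- function(frame, x, y, tInt) {
    span <- max(frame) - min(frame)
    lags <- seq_len(span)
    msd <- cnt <- numeric(span)
    for (lag in lags) {
        acc <- 0; n <- 0
        for (i in seq_along(frame)) for (j in seq_along(frame)) {
            if (frame[j] - frame[i] == lag) {
                acc <- acc + (x[j] - x[i])^2 + (y[j] - y[i])^2
                n <- n + 1
            }
        }
        msd[lag] <- if (n) acc / n else NA
        cnt[lag] <- n
    }
    list(lags = lags * tInt, msd = msd / 1e6, counts = cnt)
}

# dense polygonal approximation of an ellipse (for perimeter/area oracles)
ellipsePolygon <- function(a, b, n = 2000L) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(a * cos(th), b * sin(th))
}

# uniform draws from a rotated ellipse (cluster-geometry fixture)
uniformEllipsePoints <- function(n, a, b, theta = 0, cx = 0, cy = 0) {
    r <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
    u <- a * r * cos(phi); v <- b * r * sin(phi)
    cbind(cx + cos(theta) * u - sin(theta) * v,
          cy + sin(theta) * u + cos(theta) * v)
}

# single-track TrackSet from vectors
makeTrack <- function(frame, x, y, tInt = 0.2, track = 1L) {
    new("TrackSet",
        spots = data.frame(track = track, frame = frame, x = x, y = y),
        tInt = tInt)
}

emptyGroundTruth <- function() {
    new("GroundTruth",
        molecules = data.frame(molecule = integer(), birthFrame = integer(),
                               endFrame = integer(), cause = character()),
        positions = data.frame(frame = integer(), molecule = integer(),
                               x = numeric(), y = numeric(),
                               clusterId = integer()),
        clusters = data.frame(clusterId = integer(), cx = numeric(),
                              cy = numeric(), a = numeric(), b = numeric(),
                              theta = numeric()))
}

staticEmitterTruth <- function(x, y, nFrames = 1L) {
    new("GroundTruth",
        molecules = data.frame(molecule = 1L, birthFrame = 0L,
                               endFrame = nFrames - 1L, cause = "censored"),
        positions = data.frame(frame = seq_len(nFrames) - 1L, molecule = 1L,
                               x = x, y = y, clusterId = 0L),
        clusters = data.frame(clusterId = integer(), cx = numeric(),
                              cy = numeric(), a = numeric(), b = numeric(),
                              theta = numeric()))
}
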