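# Unit conventions, shared everywhere:
#   time      internal seconds; rates exposed in min^-1
#   length    nm (fieldSize in µm at the config surface only)
#   diffusion µm^2/s; MSD µm^2
NM2_PER_UM2 <- 1e6

perMinToPerSec <- function(k) k / 60
perSecToPerMin <- function(k) k * 60

#' Create an acquisition schedule
#'
#' @param tExp exposure per frame, seconds.
#' @param tInt interval between frame starts, seconds.
#' @param nFrames number of frames.
#' @return An [AcquisitionSchedule-class].
#' @examples
#' sch <- acquisitionSchedule(0.2, 0.5, 600)
#' relativeExposure(sch)  # 0.4
#' @export
acquisitionSchedule <- function(tExp = 0.2, tInt = tExp, nFrames = 600L) {
    new("AcquisitionSchedule", tExp = tExp, tInt = tInt,
        nFrames = as.integer(nFrames))
}

#' Relative exposure p = tExp / tInt
#'
#' The fraction of acquisition time under illumination; the effective
#' bleaching rate under a protocol is p times the continuous-illumination
#' bleaching rate.
#'
#' @param schedule an [AcquisitionSchedule-class].
#' @return p, dimensionless in (0, 1].
#' @export
relativeExposure <- function(schedule) {
    stopifnot(is(schedule, "AcquisitionSchedule"))
    schedule@tExp / schedule@tInt
}

# Deterministic per-stage substream seed from one root seed, kept inside
# the 32-bit integer range.
substreamSeed <- function(root, name) {
    u <- utf8ToInt(name)
    h <- sum(u * seq_along(u))
    as.integer((as.numeric(root) * 7919 + h) %% 2147483647)
}

# is point inside ellipse (centre cx,cy; semi-axes a,b; rotation theta)?
insideEllipse <- function(x, y, cx, cy, a, b, theta) {
    ct <- cos(theta); st <- sin(theta)
    dx <- x - cx; dy <- y - cy
    u <- (ct * dx + st * dy) / a
    v <- (-st * dx + ct * dy) / b
    u * u + v * v <= 1
}

# Fold a radial coordinate into [0, 1] by repeated reflection at 0 and 1
# (period-2 triangle wave); used for reflecting boundaries.
foldUnit <- function(r) 1 - abs(1 - r %% 2)
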