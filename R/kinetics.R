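#' Extract cluster dwell times from tracks and cluster regions
#'
#' A dwell starts when a molecule's localization first falls inside a
#' cluster region (or first appears there upon activation) and ends at the
#' last in-cluster frame before either an absence of more than `lossGap`
#' consecutive frames or a sustained departure beyond the cluster radius.
#' Molecules still resident at the end of acquisition are censored at the
#' observation limit.
#'
#' @param trackset a [TrackSet-class].
#' @param clusters a [ClusterRegionSet-class], or a data.frame with
#'   columns `clusterId`, `cx`, `cy` (nm).
#' @param schedule the [AcquisitionSchedule-class] of the recording.
#' @param lossGap maximum tolerated absence, frames (default 3: a dwell
#'   survives a loss of up to 3 consecutive frames).
#' @param radius membership radius around cluster centres, nm
#'   (default 125).
#' @param condition condition label attached to the records.
#' @return A [DwellRecords-class].
#' @export
extractDwellTimes <- function(trackset, clusters, schedule, lossGap = 3L,
                              radius = 125, condition = "unknown") {
    stopifnot(is(trackset, "TrackSet"), is(schedule, "AcquisitionSchedule"))
    if (is(clusters, "ClusterRegionSet")) clusters <- clusters@summary
    if (!nrow(clusters)) stop("no clusters supplied")
    sp <- trackset@spots
    lastFrame <- schedule@nFrames - 1L
    rec <- list()
    for (id in unique(sp$track)) {
        tr <- sp[sp$track == id, , drop = FALSE]
        tr <- tr[order(tr$frame), , drop = FALSE]
        # nearest-cluster membership per localization
        d2 <- outer(tr$x, clusters$cx, `-`)^2 + outer(tr$y, clusters$cy, `-`)^2
        nearest <- max.col(-d2)
        inC <- sqrt(d2[cbind(seq_len(nrow(tr)), nearest)]) <= radius
        if (!any(inC)) next
        inFrames <- tr$frame[inC]
        clustIds <- clusters$clusterId[nearest[inC]]
        # split membership frames into dwells at absences > lossGap
        brk <- which(diff(inFrames) > lossGap + 1L)
        starts <- c(1L, brk + 1L); ends <- c(brk, length(inFrames))
        for (s in seq_along(starts)) {
            f0 <- inFrames[starts[s]]; f1 <- inFrames[ends[s]]
            censored <- f1 + lossGap >= lastFrame
            frames <- f1 - f0 + 1L
            rec[[length(rec) + 1L]] <- data.frame(
                duration = frames * schedule@tInt,
                frames = as.integer(frames), censored = censored,
                cause = if (censored) "censored" else "lost",
                p = relativeExposure(schedule),
                molecule = id, cluster = clustIds[starts[s]],
                condition = condition)
        }
    }
    records <- if (length(rec)) do.call(rbind, rec) else
        data.frame(duration = numeric(), frames = integer(),
                   censored = logical(), cause = character(), p = numeric(),
                   molecule = integer(), cluster = integer(),
                   condition = character())
    new("DwellRecords", records = records, schedule = schedule,
        condition = condition)
}

#' Fit the single disappearance rate of a dwell-time sample
#'
#' Default method follows the histogram procedure: dwell durations are
#' binned at the frame interval and a single exponential is fitted to the
#' histogram by a Poisson log-linear fit over the full bin range (zero
#' bins included -- dropping empty tail bins would flatten the decay);
#' censored records are excluded.
#' The `mle` alternative is the censored-exponential maximum-likelihood
#' estimator (with a half-frame midpoint correction for the frame
#' quantization), strictly more efficient and robust to censoring. The
#' histogram SE is a bootstrap over records.
#'
#' @param dwells a [DwellRecords-class].
#' @param method `"histogram"` (default) or `"mle"`.
#' @param bootstrap bootstrap resamples for the histogram SE (default 500;
#'   0 falls back to the GLM slope standard error).
#' @param seed optional integer seed for the bootstrap.
#' @param minRecords minimum uncensored records (default 30).
#' @return A [RateEstimate-class]; K in min^-1.
#' @export
fitDisappearanceRate <- function(dwells, method = c("histogram", "mle"),
                                 bootstrap = 500L, seed = NULL,
                                 minRecords = 30L) {
    stopifnot(is(dwells, "DwellRecords"))
    method <- match.arg(method)
    r <- dwells@records
    tInt <- dwells@schedule@tInt
    if (method == "mle") {
        d <- sum(!r$censored)
        if (d < 1L) stop("all records censored; cannot estimate a rate")
        tot <- sum(ifelse(r$censored, r$duration, r$duration - tInt / 2))
        Ks <- d / tot
        return(new("RateEstimate", K = perSecToPerMin(Ks),
                   se = perSecToPerMin(Ks / sqrt(d)), n = nrow(r),
                   method = "mle"))
    }
    unc <- r$frames[!r$censored]
    if (length(unc) < minRecords)
        stop("histogram fit requires >= ", minRecords, " uncensored records")
    fit <- .histRate(unc, tInt, withSE = TRUE)
    if (bootstrap > 0L) {
        if (!is.null(seed)) set.seed(seed)
        bootKs <- vapply(seq_len(bootstrap), function(b) {
            .histRate(sample(unc, replace = TRUE), tInt)
        }, numeric(1))
        se <- stats::sd(bootKs, na.rm = TRUE)
    } else se <- fit["se"]
    new("RateEstimate", K = perSecToPerMin(unname(fit["K"])),
        se = perSecToPerMin(unname(se)),
        n = length(unc), method = "histogram")
}

# exponential decay rate (s^-1) of the dwell-frame histogram: Poisson
# log-linear fit over the full bin range, zero bins included (dropping
# empty tail bins flattens the decay and underestimates the rate); this is
# the ML exponential fit of the histogram and is exact in expectation for
# geometric (frame-quantized) data
.histRate <- function(frames, tInt, withSE = FALSE) {
    kmax <- max(frames)
    bins <- seq_len(kmax)
    cnt <- as.numeric(table(factor(frames, levels = bins)))
    t <- bins * tInt
    if (sum(cnt > 0) < 3L)
        return(if (withSE) c(K = NA_real_, se = NA_real_) else NA_real_)
    fit <- suppressWarnings(stats::glm(cnt ~ t, family = stats::poisson()))
    K <- -unname(stats::coef(fit)[2])
    if (!withSE) return(K)
    c(K = K, se = unname(sqrt(stats::vcov(fit)[2, 2])))
}

#' Decompose disappearance rates into bleaching, dissociation and
#' endocytosis
#'
#' Molecules vanish from clusters by photobleaching (rate scaling with the
#' relative exposure p), lateral dissociation, and endocytic removal:
#' K(p) = p Kb + Kd + Ke. Recording the same cells at constant exposure
#' but increasing frame intervals varies p; extrapolating the weighted
#' linear fit of K against p to p = 0 removes bleaching. The ATP-depleted
#' branch, in which endocytosis is abolished, has intercept Kd; the
#' control branch has intercept Kd + Ke, so the intercept difference
#' isolates Ke, and the slope estimates Kb.
#'
#' @param control data.frame of control-branch measurements: `p`, `K`
#'   (min^-1), `se` (optionally `n`).
#' @param kcn data.frame of the endocytosis-off branch, same columns.
#' @param pooledSlope share one bleaching slope between branches
#'   (default FALSE: independent slopes).
#' @return A [RateDecomposition-class].
#' @examples
#' p <- c(1, 0.4, 0.2, 0.1)
#' ctl <- data.frame(p = p, K = 2 * p + 0.69, se = 0.01)
#' kcn <- data.frame(p = p, K = 2 * p + 0.12, se = 0.01)
#' dec <- decomposeRates(ctl, kcn)
#' c(dec@Kd, dec@Ke)  # 0.12, 0.57
#' @export
decomposeRates <- function(control, kcn, pooledSlope = FALSE) {
    for (b in list(control, kcn)) {
        if (!all(c("p", "K", "se") %in% names(b)))
            stop("branches need columns p, K, se")
        if (length(unique(b$p)) < 3L)
            stop("at least 3 distinct p values per branch are required")
    }
    if (!length(intersect(round(control$p, 6), round(kcn$p, 6))))
        stop("control and endocytosis-off p grids do not overlap")
    wc <- 1 / pmax(control$se, 1e-12)^2
    wk <- 1 / pmax(kcn$se, 1e-12)^2
    if (pooledSlope) {
        dat <- rbind(cbind(control, branch = "control"),
                     cbind(kcn, branch = "kcn"))
        w <- c(wc, wk)
        fit <- stats::lm(K ~ p + branch, data = dat, weights = w)
        cf <- stats::coef(fit); vc <- stats::vcov(fit)
        interceptC <- unname(cf["(Intercept)"])
        interceptK <- unname(cf["(Intercept)"] + cf["branchkcn"])
        slopes <- c(pooled = unname(cf["p"]))
        seC <- sqrt(vc["(Intercept)", "(Intercept)"])
        seK <- sqrt(vc["(Intercept)", "(Intercept)"] +
                    vc["branchkcn", "branchkcn"] +
                    2 * vc["(Intercept)", "branchkcn"])
        seE <- sqrt(vc["branchkcn", "branchkcn"])
        seB <- c(sqrt(vc["p", "p"]), sqrt(vc["p", "p"]))
        diag <- list(fit = fit)
    } else {
        fc <- stats::lm(K ~ p, data = control, weights = wc)
        fk <- stats::lm(K ~ p, data = kcn, weights = wk)
        interceptC <- unname(stats::coef(fc)[1])
        interceptK <- unname(stats::coef(fk)[1])
        slopes <- c(control = unname(stats::coef(fc)[2]),
                    kcn = unname(stats::coef(fk)[2]))
        seC <- sqrt(stats::vcov(fc)[1, 1])
        seK <- sqrt(stats::vcov(fk)[1, 1])
        seE <- sqrt(seC^2 + seK^2)
        seB <- c(sqrt(stats::vcov(fc)[2, 2]), sqrt(stats::vcov(fk)[2, 2]))
        diag <- list(control = fc, kcn = fk)
    }
    Kd <- interceptK
    Ke <- interceptC - interceptK
    if (Kd < 0 || Ke < 0 || any(slopes < 0)) {
        warning("negative rate estimate(s) clamped to 0")
        Kd <- max(Kd, 0); Ke <- max(Ke, 0); slopes <- pmax(slopes, 0)
    }
    per <- rbind(cbind(control, branch = "control"),
                 cbind(kcn, branch = "kcn"))
    if (!"n" %in% names(per)) per$n <- NA_integer_
    new("RateDecomposition",
        perProtocol = per[c("branch", "p", "K", "se", "n")],
        Kd = Kd, Ke = Ke, Kb = slopes,
        se = c(Kd = seK, Ke = seE, Kb.control = seB[1], Kb.kcn = seB[2]),
        diagnostics = diag)
}

#' Association rate from the dissociation rate and population fractions
#'
#' At equilibrium the clustered and free pools exchange so that capture
#' balances dissociation. Two conventions circulate: the `printed` form
#' Ka = Kd x fFree / fClustered, and the `detailed_balance` form
#' Ka = Kd x fClustered / fFree (the one under which Ka [free] =
#' Kd [clustered] holds). Both are always returned side by side and
#' labelled, because the two differ whenever the pools are unequal and the
#' field uses both; `convention` selects which is reported as `value`.
#'
#' @param Kd dissociation rate, min^-1.
#' @param fFree free fraction in (0, 1).
#' @param fClustered clustered fraction in (0, 1).
#' @param convention `"printed"` (default) or `"detailed_balance"`.
#' @return list: `value`, `convention`, `printed`, `detailed_balance`
#'   (all rates in min^-1).
#' @examples
#' estimateAssociationRate(0.12, 0.52, 0.48)$printed  # 0.13
#' @export
estimateAssociationRate <- function(Kd, fFree, fClustered,
                                    convention = c("printed",
                                                   "detailed_balance")) {
    convention <- match.arg(convention)
    if (fFree <= 0 || fFree >= 1 || fClustered <= 0 || fClustered >= 1 ||
        fFree + fClustered > 1 + 1e-9)
        stop("fractions must lie in (0,1) with sum <= 1")
    printed <- Kd * fFree / fClustered
    db <- Kd * fClustered / fFree
    list(value = if (convention == "printed") printed else db,
         convention = convention, printed = printed,
         detailed_balance = db)
}
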