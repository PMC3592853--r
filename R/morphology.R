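#' Accumulate accepted localizations into a super-resolved point map
#'
#' Every accepted localization becomes one point; no averaging across
#' frames, so repeated observations of one molecule build up the density
#' of its residence region (the basis of the reconstruction image).
#' Optionally also bins the points into a 2D histogram image for display.
#'
#' @param locs a [LocalizationTable-class] or data.frame with `x`, `y`
#'   (nm; `frame` and `molecule` carried through if present).
#' @param binSize histogram bin, nm (NULL = points only; 10-20 nm typical).
#' @return list: `points` (data.frame x, y and carried columns), `image`
#'   (matrix of counts, or NULL), `binSize`.
#' @export
reconstructPositions <- function(locs, binSize = NULL) {
    if (is(locs, "LocalizationTable")) locs <- locs@locs
    if (!nrow(locs))
        return(list(points = locs, image = NULL, binSize = binSize))
    pts <- locs[intersect(c("frame", "molecule", "x", "y"), names(locs))]
    img <- NULL
    if (!is.null(binSize)) {
        bx <- floor(pts$x / binSize); by <- floor(pts$y / binSize)
        nx <- max(bx) + 1L; ny <- max(by) + 1L
        img <- matrix(0L, ny, nx)
        for (i in seq_len(nrow(pts)))
            img[by[i] + 1L, bx[i] + 1L] <- img[by[i] + 1L, bx[i] + 1L] + 1L
    }
    list(points = pts, image = img, binSize = binSize)
}

#' Identify cluster regions by single-molecule residency
#'
#' A cluster is declared where a molecule's consecutive localizations stay
#' within a diffraction-limited radius for at least `residencyMin` frames
#' (far longer than free diffusion would allow at ~0.1 µm^2/s), following
#' the residency definition of confinement. Runs from different molecules
#' whose centroids overlap are merged into one region; free-diffusion
#' positions never enter a region.
#'
#' @param locs a [LocalizationTable-class] or data.frame with `frame`,
#'   `molecule`, `x`, `y` (nm).
#' @param residencyMin minimum residency, frames (default 30).
#' @param radius grouping radius, nm (default 125, half the diffraction
#'   limit).
#' @param lossGap tolerated excursion, in consecutive localizations
#'   outside `radius`, before the residency run ends (default 3, matching
#'   the tracker's loss rule; localization noise regularly throws single
#'   positions of a genuinely resident molecule beyond the radius).
#' @return A [ClusterRegionSet-class]; geometry columns are filled by
#'   [fitEllipse()] and [circularity()].
#' @export
identifyClusters <- function(locs, residencyMin = 30L, radius = 125,
                             lossGap = 3L) {
    if (is(locs, "LocalizationTable")) locs <- locs@locs
    runs <- list()
    if (nrow(locs)) for (mol in unique(locs$molecule)) {
        m <- locs[locs$molecule == mol, , drop = FALSE]
        m <- m[order(m$frame), , drop = FALSE]
        inRun <- 1L      # indices of inside-radius members of current run
        cx <- m$x[1]; cy <- m$y[1]
        nOut <- 0L
        flush <- function(members) {
            span <- m$frame[members[length(members)]] -
                    m$frame[members[1]] + 1L
            if (span >= residencyMin && length(members) >= 3L)
                runs[[length(runs) + 1L]] <<- m[members, , drop = FALSE]
        }
        if (nrow(m) >= 2L) for (i in 2L:nrow(m)) {
            if (sqrt((m$x[i] - cx)^2 + (m$y[i] - cy)^2) > radius) {
                nOut <- nOut + 1L
                if (nOut > lossGap) {
                    flush(inRun)
                    inRun <- i; cx <- m$x[i]; cy <- m$y[i]; nOut <- 0L
                }
            } else {
                n <- length(inRun)
                cx <- (cx * n + m$x[i]) / (n + 1)
                cy <- (cy * n + m$y[i]) / (n + 1)
                inRun <- c(inRun, i)
                nOut <- 0L
            }
        }
        flush(inRun)
    }
    if (!length(runs)) {
        emptySummary <- data.frame(clusterId = integer(), cx = numeric(),
            cy = numeric(), n = integer(), residency = integer(),
            a = numeric(), b = numeric(), aCorr = numeric(),
            bCorr = numeric(), Dmax = numeric(), Dmin = numeric(),
            theta = numeric(), circularity = numeric(),
            degenerate = logical())
        return(new("ClusterRegionSet", summary = emptySummary,
                   members = list()))
    }
    cen <- t(vapply(runs, function(r) c(mean(r$x), mean(r$y)), numeric(2)))
    # merge runs whose centroids overlap (single-link)
    grp <- seq_len(nrow(cen))
    for (i in seq_len(nrow(cen) - 1L)) for (j in (i + 1L):nrow(cen)) {
        if (sqrt(sum((cen[i, ] - cen[j, ])^2)) <= radius)
            grp[grp == grp[j]] <- grp[i]
    }
    ids <- unique(grp)
    members <- lapply(ids, function(g) {
        r <- do.call(rbind, runs[grp == g])
        as.matrix(r[, c("x", "y")])
    })
    residency <- vapply(ids, function(g)
        max(vapply(runs[grp == g], function(r)
            max(r$frame) - min(r$frame) + 1L, integer(1))), integer(1))
    summary <- data.frame(
        clusterId = seq_along(ids),
        cx = vapply(members, function(m) mean(m[, 1]), numeric(1)),
        cy = vapply(members, function(m) mean(m[, 2]), numeric(1)),
        n = vapply(members, nrow, integer(1)),
        residency = residency,
        a = NA_real_, b = NA_real_, aCorr = NA_real_, bCorr = NA_real_,
        Dmax = NA_real_, Dmin = NA_real_, theta = NA_real_,
        circularity = NA_real_, degenerate = FALSE)
    new("ClusterRegionSet", summary = summary, members = members)
}

#' Second-moment ellipse fit with localization-uncertainty correction
#'
#' Fits each region's covariance ellipse under the uniform-filled-ellipse
#' convention: for a uniform ellipse with semi-axis a the positional
#' variance along that axis is a^2/4, so semi-axes are 2 sqrt(eigenvalue).
#' Localization scatter inflates both eigenvalues by sigma^2; the
#' correction subtracts sigma^2 in quadrature before conversion (corrected
#' diameters Dmax = 2 aCorr, Dmin = 2 bCorr). Eigenvalues driven negative
#' by the correction clamp to zero with a warning; near-collinear point
#' sets are flagged degenerate.
#'
#' @param x a [ClusterRegionSet-class] (all regions fitted) or a
#'   two-column matrix of positions (nm).
#' @param sigmaLoc per-coordinate localization uncertainty, nm.
#' @param minPoints minimum positions per region (default 10).
#' @return For a matrix: list `a`, `b`, `aCorr`, `bCorr`, `Dmax`, `Dmin`,
#'   `theta`, `degenerate`. For a ClusterRegionSet: the set with geometry
#'   columns filled (regions below `minPoints` stay NA).
#' @examples
#' set.seed(1)
#' r <- sqrt(runif(500)); phi <- runif(500, 0, 2 * pi)
#' xy <- cbind(85 * r * cos(phi), 45 * r * sin(phi))
#' fitEllipse(xy, sigmaLoc = 0)$Dmax  # ~170
#' @export
fitEllipse <- function(x, sigmaLoc = 30, minPoints = 10L) {
    if (is(x, "ClusterRegionSet")) {
        for (i in seq_along(x@members)) {
            if (nrow(x@members[[i]]) < minPoints) next
            f <- fitEllipse(x@members[[i]], sigmaLoc, minPoints)
            x@summary[i, c("a", "b", "aCorr", "bCorr", "Dmax", "Dmin",
                           "theta")] <-
                list(f$a, f$b, f$aCorr, f$bCorr, f$Dmax, f$Dmin, f$theta)
            x@summary$degenerate[i] <- f$degenerate
        }
        return(x)
    }
    x <- as.matrix(x)
    if (nrow(x) < minPoints) stop("at least ", minPoints, " positions required")
    cv <- stats::cov(x)
    e <- eigen(cv, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    degenerate <- ev[2] < 1e-9 * max(ev[1], 1)
    aAx <- 2 * sqrt(ev[1]); bAx <- 2 * sqrt(ev[2])
    evc <- ev - sigmaLoc^2
    if (any(evc < 0) && sigmaLoc > 0) {
        warning("uncertainty correction exceeds an eigenvalue; clamped to 0")
        evc <- pmax(evc, 0)
    }
    theta <- atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi
    list(a = aAx, b = bAx, aCorr = 2 * sqrt(evc[1]), bCorr = 2 * sqrt(evc[2]),
         Dmax = 4 * sqrt(evc[1]), Dmin = 4 * sqrt(evc[2]),
         theta = theta, degenerate = degenerate)
}

#' Circularity 4 pi A / P^2 of a region outline
#'
#' Normalised isoperimetric quotient: exactly 1 for a circle, ~0.86 for a
#' smooth 170 x 90 ellipse, and much lower for the ragged outlines traced
#' by localization scatter. For a polygon the shoelace area and polygonal
#' perimeter are used directly. For a point set the boundary is an
#' occupancy outline: points are rasterised, closed with a disc probe of
#' `probeRadius`, hole-filled, and the region's area and perimeter are
#' measured on the resulting mask.
#'
#' @param x a closed polygon (two-column matrix, vertices in order), a
#'   point-set matrix with `asPolygon = FALSE`, or a
#'   [ClusterRegionSet-class].
#' @param asPolygon treat a matrix as polygon vertices (default TRUE).
#' @param probeRadius closing probe radius for point sets, nm (default 50).
#' @param binSize raster bin for point sets, nm (default 10).
#' @return circularity in (0, 1] (values can marginally exceed 1 on a
#'   rasterised disc; capped at 1), or the ClusterRegionSet with its
#'   `circularity` column filled.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)[-1]
#' circularity(cbind(cos(th), sin(th)))  # 1.00
#' @export
circularity <- function(x, asPolygon = TRUE, probeRadius = 50,
                        binSize = 10) {
    if (is(x, "ClusterRegionSet")) {
        x@summary$circularity <- vapply(seq_along(x@members), function(i) {
            if (nrow(x@members[[i]]) < 3L) return(NA_real_)
            circularity(x@members[[i]], asPolygon = FALSE,
                        probeRadius = probeRadius, binSize = binSize)
        }, numeric(1))
        return(x)
    }
    x <- as.matrix(x)
    if (nrow(x) < 3L) stop("at least 3 points required")
    if (asPolygon) return(.polygonCircularity(x))
    .pointSetCircularity(x, probeRadius, binSize)
}

.polygonCircularity <- function(poly) {
    n <- nrow(poly)
    if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
    xs <- poly[, 1]; ys <- poly[, 2]
    xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
    A <- abs(sum(xs * yn - xn * ys)) / 2
    P <- sum(sqrt((xn - xs)^2 + (yn - ys)^2))
    min(4 * pi * A / P^2, 1)
}

.pointSetCircularity <- function(pts, probeRadius, binSize) {
    pr <- max(1L, round(probeRadius / binSize))
    pad <- 2L * pr + 2L
    bx <- round((pts[, 1] - min(pts[, 1])) / binSize) + pad
    by <- round((pts[, 2] - min(pts[, 2])) / binSize) + pad
    nx <- max(bx) + pad; ny <- max(by) + pad
    mask <- matrix(0, ny, nx)
    mask[cbind(by, bx)] <- 1
    brush <- EBImage::makeBrush(2L * pr + 1L, shape = "disc")
    closed <- EBImage::closing(mask, brush)
    closed <- EBImage::fillHull(closed)
    lab <- EBImage::bwlabel(closed)
    feats <- EBImage::computeFeatures.shape(lab)
    i <- which.max(feats[, "s.area"])
    A <- feats[i, "s.area"] * binSize^2
    P <- feats[i, "s.perimeter"] * binSize
    min(4 * pi * A / P^2, 1)
}

#' Clustered fraction from the bulk-channel intensity
#'
#' Estimates what fraction of the fluorophore population sits in clusters
#' by comparing the integrated intensity of segmented puncta with the
#' uniform background of freely diffusing molecules on a time-averaged
#' image: puncta are thresholded above the diffuse level (median + k x
#' robust sd), and the fraction is (puncta intensity above the diffuse
#' level) / (total intensity above the camera offset).
#'
#' @param image time-averaged 2D matrix of the bulk channel, photons.
#' @param k threshold in robust sds above the diffuse level (default 3).
#' @param darkOffset camera offset per pixel, photons (default 0).
#' @param dilate radius (pixels) by which the puncta mask is grown so the
#'   PSF tails below threshold are still counted (default 3).
#' @return fraction in [0, 1].
#' @export
clusteredFraction <- function(image, k = 3, darkOffset = 0, dilate = 3L) {
    stopifnot(is.matrix(image))
    if (all(image == 0)) stop("all-zero image")
    diffuse <- stats::median(image)
    s <- stats::mad(image)
    if (s == 0) s <- stats::sd(image)
    mask <- image > diffuse + k * s
    if (!any(mask)) return(0)
    if (dilate > 0)
        mask <- EBImage::dilate(mask * 1,
                                EBImage::makeBrush(2L * dilate + 1L,
                                                   "disc")) > 0
    punct <- sum(image[mask] - diffuse)
    total <- sum(image - darkOffset)
    max(0, min(1, punct / total))
}
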