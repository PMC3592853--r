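test_that("reconstruction accumulates raw localizations without averaging", {
    set.seed(30)
    locs <- data.frame(frame = 0:99, molecule = 1L,
                       x = 500 + rnorm(100, 0, 30),
                       y = 700 + rnorm(100, 0, 30),
                       sigma = 30, channel = "activated")
    rec <- reconstructPositions(locs, binSize = 20)
    expect_equal(nrow(rec$points), 100L)
    expect_equal(sd(rec$points$x), 30, tolerance = 0.2)
    expect_equal(sum(rec$image), 100L)
    empty <- reconstructPositions(locs[0, ])
    expect_equal(nrow(empty$points), 0L)
    # two well-separated emitters appear as two modes at true separation
    loc2 <- rbind(locs, transform(locs, x = x + 2000, molecule = 2L))
    rec2 <- reconstructPositions(loc2)
    km <- stats::kmeans(rec2$points[c("x", "y")], centers = 2, nstart = 5)
    sep <- dist(km$centers)
    expect_equal(as.numeric(sep), 2000, tolerance = 0.05)
})

test_that("residency rule creates regions only where molecules linger", {
    # pure free diffusion at 0.092 µm^2/s: staying within 125 nm for 30
    # frames is vanishingly rare
    cfg <- makeScenario("custom", clusterDensity = 0, fClustered0 = 0,
                        Ka = 0, Kb = 0, Ke = 0, nMolecules = 80L,
                        seed = 31L, fieldSize = c(30, 30))
    sim <- simulateTrajectories(cfg, acquisitionSchedule(0.2, 0.2, 200))
    expect_equal(nrow(identifyClusters(sim$locs)@summary), 0L)
    # 29-frame residency misses the >= 30-frame rule
    stay <- data.frame(frame = 0:28, molecule = 1L,
                       x = 100 + rnorm(29, 0, 20), y = 100 + rnorm(29, 0, 20),
                       sigma = 20, channel = "activated")
    expect_equal(nrow(identifyClusters(stay, residencyMin = 30)@summary), 0L)
    stay30 <- transform(rbind(stay, stay[29, ]), frame = 0:29)
    expect_equal(nrow(identifyClusters(stay30, residencyMin = 30)@summary), 1L)
})

test_that("detected region count tracks the planted clusters", {
    cfg <- makeScenario("basal", nMolecules = 150L, seed = 32L)
    sim <- simulateTrajectories(cfg, acquisitionSchedule(0.2, 0.2, 400))
    regs <- identifyClusters(sim$locs)
    # truth: clusters hosting a >= 30-consecutive-frame resident molecule
    pos <- sim$truth@positions
    resident <- unique(unlist(lapply(split(pos, pos$molecule), function(p) {
        p <- p[order(p$frame), ]
        r <- rle(p$clusterId)
        r$values[r$values > 0 & r$lengths >= 30]
    })))
    expect_gt(length(resident), 5L)
    expect_lt(abs(nrow(regs@summary) - length(resident)) / length(resident),
              0.2)
})

test_that("ellipse fit follows the uniform-ellipse second-moment convention", {
    set.seed(33)
    # isotropy: uniform disc of radius r gives a = b = r
    xy <- uniformEllipsePoints(4000, 100, 100)
    f <- fitEllipse(xy, sigmaLoc = 0)
    expect_equal(f$a, 100, tolerance = 0.05)
    expect_equal(f$b, 100, tolerance = 0.05)
    # analytic inversion: covariance eigenvalues of a uniform ellipse are
    # a^2/4 and b^2/4 (checked against brute-force Monte-Carlo moments)
    xy2 <- uniformEllipsePoints(200000, 85, 45)
    ev <- sort(eigen(cov(xy2))$values, decreasing = TRUE)
    expect_equal(ev, c(85^2 / 4, 45^2 / 4), tolerance = 0.02)
    f2 <- fitEllipse(xy2, sigmaLoc = 0)
    expect_equal(f2$Dmax, 170, tolerance = 0.02)
    expect_equal(f2$Dmin, 90, tolerance = 0.02)
    # with sigma = 0 corrected and uncorrected axes agree exactly
    expect_identical(c(f2$a, f2$b), c(f2$aCorr, f2$bCorr))
    expect_error(fitEllipse(xy[1:5, ]), "positions")
})

test_that("quadrature correction recovers true axes under 30 nm scatter", {
    set.seed(34)
    dmax <- dmin <- numeric(300)
    for (i in 1:300) {
        th <- runif(1, 0, pi)
        xy <- uniformEllipsePoints(60, 85, 45, theta = th) +
            rnorm(120, 0, 30)
        f <- suppressWarnings(fitEllipse(xy, sigmaLoc = 30))
        dmax[i] <- f$Dmax; dmin[i] <- f$Dmin
    }
    expect_equal(mean(dmax), 170, tolerance = 0.10)
    expect_equal(mean(dmin), 90, tolerance = 0.15)
})

test_that("ellipse fit is rotation-equivariant and noise-monotone", {
    set.seed(35)
    xy <- uniformEllipsePoints(3000, 85, 45)
    f0 <- fitEllipse(xy, sigmaLoc = 0)
    th <- 0.7
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    fR <- fitEllipse(xy %*% t(R), sigmaLoc = 0)
    expect_equal(fR$a, f0$a, tolerance = 1e-9)
    expect_equal(fR$b, f0$b, tolerance = 1e-9)
    expect_equal((fR$theta - f0$theta) %% pi, th, tolerance = 1e-6)
    # adding scatter never shrinks the mean uncorrected axes
    fN <- fitEllipse(xy + rnorm(6000, 0, 40), sigmaLoc = 0)
    expect_gte(fN$a, f0$a)
    expect_gte(fN$b, f0$b)
})

test_that("circularity is exact on circles, matches the ellipse oracle, and is invariant", {
    circ <- ellipsePolygon(1, 1)
    expect_equal(circularity(circ), 1, tolerance = 0.01)
    ell <- ellipsePolygon(85, 45)
    # oracle: area pi a b, perimeter from dense polygonal approximation
    P <- sum(sqrt(rowSums((ell - rbind(ell[-1, ], ell[1, ]))^2)))
    oracle <- 4 * pi * (pi * 85 * 45) / P^2
    expect_equal(oracle, 0.86, tolerance = 0.01)
    expect_equal(circularity(ell), oracle, tolerance = 0.005)
    # scale and rotation invariance
    th <- 1.1
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(circularity(ell * 7.3), circularity(ell), tolerance = 1e-6)
    expect_equal(circularity(ell %*% t(R)), circularity(ell),
                 tolerance = 1e-6)
    expect_error(circularity(ell[1:2, ]), "points")
})

test_that("point-set boundary circularity separates smooth from ragged", {
    set.seed(36)
    # dense disc: closing traces a near-circular outline
    disc <- uniformEllipsePoints(800, 300, 300)
    cDisc <- circularity(disc, asPolygon = FALSE)
    expect_gt(cDisc, 0.8)
    # sparse elongated scatter: ragged outline depresses circularity
    rag <- uniformEllipsePoints(40, 300, 80) + rnorm(80, 0, 60)
    cRag <- circularity(rag, asPolygon = FALSE)
    expect_lt(cRag, cDisc)
})

test_that("clustered-fraction bookkeeping matches planted photon shares", {
    img <- matrix(10, 60, 60)
    expect_equal(clusteredFraction(matrix(10 + 0.0, 50, 50)), 0)
    expect_error(clusteredFraction(matrix(0, 10, 10)), "zero")
    # single punctum carrying 30% of all photons
    P <- sum(img) * 0.3 / 0.7
    imgp <- ClusTrack:::.addEmitters(img, 4800, 4800, P, 130, 160)
    expect_equal(clusteredFraction(imgp), 0.30, tolerance = 0.02 / 0.30)
})

test_that("time-averaged basal movie yields the 40-50% clustered fraction", {
    # bulk channel: clusters carry 48% of the photon budget, the free pool
    # spreads the rest diffusely
    set.seed(37)
    nC <- 30
    img <- matrix(0, 64, 64)
    cxy <- cbind(runif(nC, 800, 9400), runif(nC, 800, 9400))
    totalPhotons <- 64 * 64 * 20
    img[] <- (totalPhotons * 0.52) / (64 * 64)
    img <- ClusTrack:::.addEmitters(img, cxy[, 1], cxy[, 2],
                                    rep(totalPhotons * 0.48 / nC, nC),
                                    130, 160)
    img[] <- rpois(length(img), img)
    fr <- clusteredFraction(img)
    expect_gt(fr, 0.40)
    expect_lt(fr, 0.50)
})
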