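test_that("MSD matches the brute-force all-pairs oracle, gaps included", {
    set.seed(8)
    # 5-point toy track and a gappy 50-point track
    cases <- list(
        list(frame = 0:4, x = c(0, 50, 30, 90, 120), y = c(0, 10, 40, 20, 0)),
        list(frame = sort(sample(0:69, 50)), x = cumsum(rnorm(50, 0, 80)),
             y = cumsum(rnorm(50, 0, 80))))
    for (cs in cases) {
        cv <- computeMSD(data.frame(cs), tInt = 0.2)
        oracle <- bruteForceMSD(cs$frame, cs$x, cs$y, 0.2)
        keep <- oracle$counts > 0
        expect_equal(cv@lags, oracle$lags[keep])
        expect_equal(cv@msd, oracle$msd[keep], tolerance = 1e-12)
        expect_equal(cv@counts, oracle$counts[keep])
    }
})

test_that("deterministic kinematics give exact MSD curves", {
    # stationary track
    st <- computeMSD(data.frame(frame = 0:9, x = 5, y = -3), tInt = 0.2)
    expect_true(all(st@msd == 0))
    # straight line, step d per frame: MSD(n tInt) = (n d)^2
    d <- 70
    ln <- computeMSD(data.frame(frame = 0:9, x = (0:9) * d, y = 0),
                     tInt = 0.2)
    expect_equal(ln@msd, ((seq_len(9) * d)^2) / 1e6, tolerance = 1e-12)
    expect_error(computeMSD(data.frame(frame = 0, x = 1, y = 1), tInt = 0.2))
})

test_that("linear MSD fit is exact on noiseless lines and scale-equivariant", {
    lag <- (1:6) * 0.2
    cv <- new("MSDCurve", lags = lag, msd = 4 * 0.1 * lag,
              counts = rep(50, 6), trackId = NA_integer_)
    f <- fitLinearMSD(cv, nLags = 4)
    expect_equal(f@D, 0.1, tolerance = 1e-12)
    expect_equal(f@C, 0, tolerance = 1e-12)
    expect_false(f@warn)
    # scaling coordinates by s multiplies D and C by s^2
    s <- 3
    tr <- data.frame(frame = 0:29, x = cumsum(rnorm(30, 0, 100)),
                     y = cumsum(rnorm(30, 0, 100)))
    f1 <- fitLinearMSD(computeMSD(tr, tInt = 0.2))
    tr2 <- transform(tr, x = s * x, y = s * y)
    f2 <- fitLinearMSD(computeMSD(tr2, tInt = 0.2))
    expect_equal(f2@D, s^2 * f1@D, tolerance = 1e-9)
    expect_equal(f2@C, s^2 * f1@C, tolerance = 1e-9)
    expect_error(fitLinearMSD(cv, nLags = 1), "nLags")
})

test_that("pure localization noise appears as the offset C = 4 sigma^2", {
    ts <- simulateFreeTracks(200, 40, D = 0, sigmaLoc = 30, tInt = 0.2,
                             seed = 13)
    f <- fitLinearMSD(pooledMSD(ts, maxLag = 8))
    expect_equal(f@C, 4 * (30 / 1000)^2, tolerance = 0.05)
    expect_lt(abs(f@D), 0.002)  # noise-dominated, near zero
})

test_that("envelope median follows 4 D t + 4 sigma^2 and is calibrated", {
    D <- 0.092; s <- 30; tInt <- 0.2
    env <- buildEnvelope(D, 30, sigmaLoc = s, tInt = tInt,
                         replicates = 1000, seed = 17)
    expect_error(buildEnvelope(D, 30, replicates = 50), "replicates")
    mid <- (env@lower + env@upper) / 2
    expected <- 4 * D * env@lags + 4 * (s / 1000)^2
    # envelope centre tracks the analytic expectation on early lags
    expect_equal(mid[1:4], expected[1:4], tolerance = 0.15)
    expect_true(all(env@lower <= env@upper))
    # hold-out calibration: ~5% of fresh walks fall outside per lag
    ts <- simulateFreeTracks(800, 30, D = D, sigmaLoc = s, tInt = tInt,
                             seed = 18)
    outRate <- vapply(seq_along(env@lags), function(i) {
        v <- vapply(tracks(ts), function(tr)
            computeMSD(tr, tInt = tInt, maxLag = length(env@lags))@msd[i],
            numeric(1))
        mean(v < env@lower[i] | v > env@upper[i])
    }, numeric(1))
    expect_true(all(outRate > 0.005 & outRate < 0.12))
    expect_lt(abs(mean(outRate) - 0.05), 0.03)
})

test_that("motion classes are assigned by sustained envelope excursions", {
    # 2000 replicates: the empirical 2.5/97.5% quantiles are noisy enough
    # at 1000 to cost ~0.5-1% specificity
    env <- buildEnvelope(0.092, 30, sigmaLoc = 30, tInt = 0.2,
                         replicates = 2000, seed = 19)
    # the envelope midline itself is free
    mid <- new("MSDCurve", lags = env@lags,
               msd = (env@lower + env@upper) / 2,
               counts = rep(30, length(env@lags)), trackId = NA_integer_)
    expect_equal(classifyTrajectory(mid, env)$label, "free")
    # specificity: >= 97% of pure random walks stay labelled free
    ts <- simulateFreeTracks(1000, 30, D = 0.092, sigmaLoc = 30, tInt = 0.2,
                             seed = 20)
    cls <- classifyTracks(ts, env)
    expect_gte(mean(cls$label == "free"), 0.97)
    # confined tracks in 120 nm reflecting discs are detected
    cs <- simulateConfinedTracks(100, 40, diameter = 120, sigmaLoc = 30,
                                 seed = 21)
    clsC <- classifyTracks(cs, env)
    expect_gte(mean(clsC$label == "confined"), 0.90)
    # constant-velocity motion (quadratic MSD) reads as directed; at
    # ~1.5 µm/s (vesicle transport speed) the parabola clears the
    # envelope from the second lag on
    dr <- lapply(1:10, function(i)
        data.frame(track = i, frame = 0:29,
                   x = (0:29) * 300 + rnorm(30, 0, 30),
                   y = rnorm(30, 0, 30)))
    td <- new("TrackSet", spots = do.call(rbind, dr), tInt = 0.2)
    clsD <- classifyTracks(td, env)
    expect_true(all(clsD$label == "directed"))
})

test_that("population fractions use the cell as the replication unit", {
    expect_warning(
        one <- populationFractions(list(c(rep("free", 10),
                                          rep("confined", 10)))), "SEM")
    expect_equal(one$fraction[one$label == "free"], 0.5)
    expect_warning(populationFractions(list(rep("free", 3))), "SEM")
    cells <- list(c(rep("free", 6), rep("confined", 4)),
                  c(rep("free", 5), rep("confined", 5), "directed"),
                  c(rep("free", 4), rep("confined", 6)))
    pf <- populationFractions(cells)
    expect_equal(pf$fraction[pf$label == "free"], mean(c(0.6, 0.5, 0.4)))
    expect_true(all(is.finite(pf$sem)))
    expect_error(populationFractions(list()), "cell")
})

test_that("confinement diameter inverts the disc plateau identity", {
    # closed form: plateau 3600 nm^2, no noise -> 120 nm
    lag <- (1:20) * 0.2
    cv <- new("MSDCurve", lags = lag,
              msd = pmin(4 * 0.092 * lag, 3600 / 1e6),
              counts = rep(100, 20), trackId = NA_integer_)
    est <- estimateConfinementSize(cv, sigmaLoc = 0)
    expect_equal(est$diameter, 120, tolerance = 1e-6)
    expect_false(est$flagged)
    # noise exceeding the plateau clamps to zero with a warning
    tiny <- new("MSDCurve", lags = lag, msd = rep(0.001, 20),
                counts = rep(100, 20), trackId = NA_integer_)
    expect_warning(est0 <- estimateConfinementSize(tiny, sigmaLoc = 40),
                   "clamp")
    expect_equal(est0$diameter, 0)
    expect_true(est0$flagged)
})

test_that("confinement estimator recovers diameters across 60-240 nm", {
    errs <- vapply(c(60, 120, 240), function(dTrue) {
        ts <- simulateConfinedTracks(60, 100, diameter = dTrue,
                                     sigmaLoc = 30, seed = round(dTrue))
        # at 60 nm the noise floor occasionally tops the plateau (clamped
        # with a warning); those tracks still enter the mean as 0
        d <- suppressWarnings(vapply(tracks(ts), function(tr) {
            cv <- computeMSD(tr, tInt = 0.2)
            estimateConfinementSize(cv, sigmaLoc = 30)$diameter
        }, numeric(1)))
        abs(mean(d, na.rm = TRUE) - dTrue) / dTrue
    }, numeric(1))
    expect_true(all(errs <= 0.15))
})
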