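test_that("noise-free rendered emitter is recovered to sub-nm accuracy", {
    truth <- staticEmitterTruth(803, 1207)
    st <- renderMovie(truth, acquisitionSchedule(0.2, 0.2, 1),
                      photonBudget = 2000, background = 2,
                      fieldSize = c(3, 3), shotNoise = FALSE)
    sp <- localizeFrame(st@data[, , 1], threshold = 10)
    expect_equal(nrow(sp), 1L)
    expect_lt(sqrt((sp$x - 803)^2 + (sp$y - 1207)^2), 1)
})

test_that("pure background yields no spots and empty frames do not fail", {
    set.seed(1)
    expect_equal(nrow(localizeFrame(matrix(rpois(900, 5), 30),
                                    threshold = 25)), 0L)
    expect_equal(nrow(localizeFrame(matrix(0, 20, 20), threshold = 5)), 0L)
})

test_that("localization is equivariant under whole-pixel translation", {
    truth <- staticEmitterTruth(800, 960)
    st <- renderMovie(truth, acquisitionSchedule(0.2, 0.2, 1),
                      photonBudget = 3000, background = 3,
                      fieldSize = c(3, 3), shotNoise = FALSE)
    img <- st@data[, , 1]
    shifted <- matrix(3, nrow(img), ncol(img))
    shifted[4:nrow(img), 3:ncol(img)] <- img[1:(nrow(img) - 3),
                                             1:(ncol(img) - 2)]
    a <- localizeFrame(img, threshold = 10)
    b <- localizeFrame(shifted, threshold = 10)
    expect_equal(b$x - a$x, 2 * 160, tolerance = 1e-6)
    expect_equal(b$y - a$y, 3 * 160, tolerance = 1e-6)
})

test_that("sparse-regime detection has high recall and low false positives", {
    # 0.05 emitters/µm^2 on 8x8 µm ~ 3-4 spots/frame at SNR ~ 10
    set.seed(5)
    n <- 4
    xy <- cbind(runif(n, 500, 7500), runif(n, 500, 7500))
    truth <- new("GroundTruth",
        molecules = data.frame(molecule = seq_len(n), birthFrame = 0L,
                               endFrame = 0L, cause = "censored"),
        positions = data.frame(frame = 0L, molecule = seq_len(n),
                               x = xy[, 1], y = xy[, 2], clusterId = 0L),
        clusters = emptyGroundTruth()@clusters)
    recall <- fp <- 0
    for (rep in 1:10) {
        st <- renderMovie(truth, acquisitionSchedule(0.2, 0.2, 1),
                          photonBudget = 800, background = 5,
                          fieldSize = c(8, 8), shotNoise = TRUE, seed = rep)
        sp <- localizeFrame(st@data[, , 1], threshold = 18)
        d <- outer(sp$x, xy[, 1], `-`)^2 + outer(sp$y, xy[, 2], `-`)^2
        matched <- apply(sqrt(d), 2, min) < 200
        recall <- recall + sum(matched)
        fp <- fp + max(0, nrow(sp) - sum(apply(sqrt(d), 1, min) < 200))
    }
    expect_gte(recall / (10 * n), 0.95)
    expect_lte(fp / (10 * 64), 0.05)  # per µm^2 per frame
})

test_that("bleach-step counting finds the change points it should", {
    set.seed(2)
    one <- c(rnorm(40, 1000, 50), rnorm(40, 0, 50))
    s1 <- detectBleachSteps(one)
    expect_equal(s1$nSteps, 1L)
    expect_lte(abs(s1$stepFrames - 40), 1)
    two <- c(rnorm(30, 2000, 50), rnorm(30, 1000, 50), rnorm(30, 0, 50))
    expect_equal(detectBleachSteps(two)$nSteps, 2L)
    expect_equal(detectBleachSteps(rnorm(60, 500, 30))$nSteps, 0L)
    expect_error(detectBleachSteps(rnorm(5)), "length")
})

test_that("linking bridges gaps up to three frames and splits at four", {
    loc3 <- data.frame(frame = c(0:4, 8:12), x = c(0:4, 8:12) * 50, y = 0)
    t3 <- linkTrajectories(loc3, maxDisp = 300, maxGap = 3, tInt = 0.2)
    expect_equal(length(unique(t3@spots$track)), 1L)
    loc4 <- data.frame(frame = c(0:4, 9:12), x = c(0:4, 9:12) * 50, y = 0)
    t4 <- linkTrajectories(loc4, maxDisp = 300, maxGap = 3, tInt = 0.2)
    expect_equal(length(unique(t4@spots$track)), 2L)
})

test_that("linking preserves identity of well-separated crossing molecules", {
    # two molecules pass within > maxDisp of each other per frame
    f <- 0:20
    a <- data.frame(frame = f, x = f * 100, y = 0, molecule = 1L)
    b <- data.frame(frame = f, x = 2000 - f * 100, y = 700, molecule = 2L)
    ts <- linkTrajectories(rbind(a, b), maxDisp = 400, maxGap = 3,
                           tInt = 0.2)
    expect_equal(length(unique(ts@spots$track)), 2L)
    purity <- vapply(split(ts@spots, ts@spots$track), function(tr)
        max(table(tr$molecule)) / nrow(tr), numeric(1))
    expect_true(all(purity == 1))
    # conservation: every detection appears in exactly one track
    expect_equal(nrow(ts@spots), 42L)
})

test_that("track filtering applies the 30-detection rule exactly", {
    mk <- function(id, n) data.frame(track = id, frame = seq_len(n) - 1L,
                                     x = 0, y = 0)
    ts <- new("TrackSet", spots = rbind(mk(1L, 29), mk(2L, 30), mk(3L, 45)),
              tInt = 0.2)
    kept <- filterTrajectories(ts, 30)
    expect_setequal(unique(kept@spots$track), c(2L, 3L))
    empt <- new("TrackSet",
                spots = data.frame(track = integer(), frame = integer(),
                                   x = numeric(), y = numeric()),
                tInt = 0.2)
    expect_equal(nrow(filterTrajectories(empt, 30)@spots), 0L)
})

test_that("linker fragmentation stays low on blinking simulator output", {
    cfg <- makeScenario("custom", clusterDensity = 0, fClustered0 = 0,
                        Ka = 0, Kb = 0.5, Ke = 0, blinkOffProb = 0.05,
                        blinkMaxGap = 3L, nMolecules = 40L, seed = 6L,
                        fieldSize = c(30, 30))
    sim <- simulateTrajectories(cfg, acquisitionSchedule(0.2, 0.2, 150))
    # maxDisp at ~5x the rms frame step: the Rayleigh tail above 3x rms
    # (~1.3% of steps) would otherwise fragment tracks
    ts <- linkTrajectories(sim$locs, maxDisp = 1500, maxGap = 3L)
    sp <- ts@spots
    # fragmentation: linked tracks per true molecule
    nTracks <- length(unique(sp$track))
    nMol <- length(unique(sim$locs@locs$molecule))
    expect_lte(nTracks / nMol, 1.1)
    # identity swaps during close encounters are inherent to
    # nearest-neighbour linking; purity only degrades gracefully
    purity <- vapply(split(sp, sp$track), function(tr)
        max(table(tr$molecule)) / nrow(tr), numeric(1))
    expect_gt(mean(purity), 0.9)
})
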