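test_that("phantom generation is deterministic and seed-sensitive", {
    sc <- get_scene7()
    sc2 <- makePhantom(seed = 7)
    expect_identical(intensities(sceneVolume(sc)), intensities(sceneVolume(sc2)))
    expect_identical(sceneFiducials(sc), sceneFiducials(sc2))
    sc3 <- makePhantom(seed = 8)
    expect_false(isTRUE(all.equal(sceneFiducials(sc), sceneFiducials(sc3),
                                  check.attributes = FALSE)))
})

test_that("the default scene carries 20 surface fiducials with a
           non-repetitive distance pattern", {
    sc <- get_scene7()
    fid <- sceneFiducials(sc)
    expect_equal(nrow(fid), 20L)
    # every fiducial sits on a body-surface voxel center
    surf <- arguide:::.maskSurfaceBits(maskBits(sceneMasks(sc)$body))
    idx <- round(voxelFromWorld(sceneVolume(sc), fid)) + 1
    expect_true(all(surf[idx]))
    # minimum separation and distance-multiset distinctness
    d <- as.matrix(dist(fid)); diag(d) <- Inf
    expect_gte(min(d), sc@config$fiducialMinSepMm)
    expect_gt(distanceMultisetGap(fid), sc@config$fiducialDistinctTolMm)
})

test_that("tumors are spheres of the requested size inside the liver", {
    sc <- get_scene7()
    tm <- sceneTumors(sc)[[1]]
    expect_equal(maskVolumeMm3(tm), 4 / 3 * pi * 7.5^3, tolerance = 0.05)
    expect_true(all(maskBits(tm) <= maskBits(sceneMasks(sc)$liver)))
    expect_error(makePhantom(phantomConfig(tumorDiametersMm = 45), seed = 1),
                 class = "arguide_value_error")
    expect_error(
        makePhantom(phantomConfig(tumorDiametersMm = 20,
                                  tumorCenters = rbind(c(60, 60, 0))),
                    seed = 1),
        class = "arguide_value_error")
})

test_that("the five-marker clip has a non-repetitive pattern and unit axis", {
    clip <- makeClipModel()
    expect_equal(nrow(clipMarkers(clip)), 5L)
    expect_gt(distanceMultisetGap(clipMarkers(clip)), 2)
    expect_equal(sqrt(sum(clip@axis^2)), 1, tolerance = 1e-9)
    expect_error(makeClipModel(markers = matrix(0, 5, 3)))
})

test_that("marker observation reproduces its stated noise model", {
    sc <- get_scene7()
    fid <- sceneFiducials(sc)

    # noiseless, no occlusion, identity frame: a pure permutation
    o <- observeMarkers(fid, observationModel(sigma = 0, occlusion = 0),
                        seed = 1)
    expect_equal(unname(o$points), unname(fid[o$truth, ]), tolerance = 1e-12)

    # occlusion 0.1: mean surviving count ~ Binomial(20, 0.9)
    m <- observationModel(sigma = 0, occlusion = 0.1)
    surv <- vapply(1:2000, function(i)
        nrow(observeMarkers(fid, m, seed = i)$points), numeric(1))
    expect_equal(mean(surv), 18.0, tolerance = 0.1 / 18)

    # sigma 0.5: per-axis residual SD ~ 0.5 mm
    m2 <- observationModel(sigma = 0.5, occlusion = 0)
    res <- do.call(rbind, lapply(1:300, function(i) {
        o <- observeMarkers(fid, m2, seed = i)
        o$points - fid[o$truth, ]
    }))
    expect_equal(sd(as.vector(res)), 0.5, tolerance = 0.05)
})

test_that("breathing displaces internal structures rigidly with
           attenuated skin motion", {
    sc <- get_scene7()
    expect_identical(simulateBreathing(sc, amplitude = 0), sc)
    expect_error(simulateBreathing(sc, 5, direction = c(0, 0, 2)),
                 class = "arguide_value_error")

    b <- simulateBreathing(sc, amplitude = 8, direction = c(0, 0, 1),
                           phase = 0.25)
    # truth tumor center moves exactly amplitude * sin(pi/2) = 8 mm
    expect_equal(as.numeric(sceneTumorCenters(b) - sceneTumorCenters(sc)),
                 c(0, 0, 8))
    # skin fiducials move by the attenuated fraction
    expect_equal(unname(sceneFiducials(b) - sceneFiducials(sc)),
                 matrix(c(0, 0, 2.4), 20, 3, byrow = TRUE),
                 tolerance = 1e-12)
    expect_equal(b@displacement, c(0, 0, 8))
    # rasterized structures conserve voxel counts within 1 percent
    for (what in c("liver", "vessels")) {
        n0 <- sum(maskBits(sceneMasks(sc)[[what]]))
        n1 <- sum(maskBits(sceneMasks(b)[[what]]))
        expect_lt(abs(n1 - n0) / n0, 0.01)
    }
    n0 <- sum(maskBits(sceneTumors(sc)[[1]]))
    n1 <- sum(maskBits(sceneTumors(b)[[1]]))
    expect_lt(abs(n1 - n0) / n0, 0.01)
})

test_that("phase-matched targeting beats random-phase targeting", {
    # breathing moves the target 8 mm; guidance planned at phase 0 hits
    # when insertion happens at the same phase, and misses by the
    # displacement when the phase is random
    sc <- get_scene7()
    set.seed(99)
    amp <- 8; dir <- c(0, 0, 1)
    planned_center <- sceneTumorCenters(sc)[1, ]
    err_matched <- numeric(200); err_random <- numeric(200)
    for (i in 1:200) {
        noise <- rnorm(3, 0, 0.5)
        err_matched[i] <- sqrt(sum(noise^2))
        ph <- runif(1)
        true_center <- planned_center + amp * sin(2 * pi * ph) * dir
        err_random[i] <- sqrt(sum((planned_center + noise - true_center)^2))
    }
    expect_gt(mean(err_random), mean(err_matched))
})

test_that("simulated ablation builds the stated necrosis geometries", {
    sc <- get_scene7()
    tumor <- sceneTumors(sc)[[1]]
    r <- sc@tumorDiameters[1] / 2
    expect_error(simulateAblation(tumor, radius = 0),
                 class = "arguide_value_error")

    # full-margin ablation: zero residuals downstream
    nec <- simulateAblation(tumor, radius = r + 5 + 1.5)
    a <- assessAblation(tumor, nec, margin = 5)
    expect_equal(a@tumorResidualPct, 0)
    expect_equal(a@marginResidualPct, 0)

    # ablation of the tumor only: complete ablation, full residual
    # margin. Centered on the true tumor center the ball reproduces the
    # tumor rasterization exactly; centered on the mask centroid the
    # sub-voxel offset may leave a few boundary voxels uncovered.
    true_ctr <- sceneTumorCenters(sc)[1, ]
    centroid <- colMeans(arguide:::.maskWorldPoints(tumor))
    nec_exact <- simulateAblation(tumor, centerOffset = true_ctr - centroid,
                                  radius = r)
    a_exact <- assessAblation(tumor, nec_exact, margin = 5)
    expect_equal(a_exact@tumorResidualPct, 0)
    expect_gt(a_exact@marginResidualPct, 95)
    nec2 <- simulateAblation(tumor, radius = r)
    a2 <- assessAblation(tumor, nec2, margin = 5)
    expect_lt(a2@tumorResidualPct, 1.5)

    # 4-mm off-center ablation leaves a far-side margin defect
    nec3 <- simulateAblation(tumor, centerOffset = c(4, 0, 0),
                             radius = r + 5)
    a3 <- assessAblation(tumor, nec3, margin = 5)
    expect_gt(a3@marginResidualPct, 1)
    expect_false(a3@technicalSuccess)
    # brute-force check: the uncovered shell voxels all sit opposite the
    # offset direction
    shell <- marginShell(tumor, 5)
    uncovered <- maskBits(shell) & !maskBits(nec3)
    pts <- worldFromVoxel(shell, which(uncovered, arr.ind = TRUE) - 1)
    ctr <- colMeans(arguide:::.maskWorldPoints(tumor))
    # with a +x offset the uncovered frontier sits at x = (offset/2)
    # relative to the tumor center; everything beyond is covered
    expect_lt(max(pts[, 1] - ctr[1]), 3)
    expect_lt(mean(pts[, 1] - ctr[1]), -3)
})

test_that("constellation generation rejects impossible requests", {
    expect_error(randomConstellation(30, minSepMm = 80,
                                     box = c(100, 100, 50), seed = 1,
                                     poolSize = 500, maxRetries = 2),
                 class = "arguide_generation_error")
})
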