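# Small spherical-body scene used by the planning tests: every surface
# voxel is a candidate, so the brute-force optimum is exact.
plan_fixture <- function(with_slab = FALSE) {
    dims <- c(41L, 41L, 21L)
    sp <- c(1, 1, 2)
    v <- Volume(array(0, dims), spacing = sp, origin = -(dims - 1) * sp / 2)
    g <- gridGeometry(v)
    body <- BinaryMask(arguide:::.rasterEllipsoid(g, c(0, 0, 0),
                                                  c(18, 18, 18)), g)
    target <- c(6, 0, 0)
    forb <- list()
    if (with_slab) {
        bits <- array(FALSE, dims)
        cc <- arguide:::.axisCoords(g)
        ix <- which(cc$x >= 9 & cc$x <= 13)
        iy <- which(abs(cc$y) <= 10)
        iz <- which(abs(cc$z) <= 10)
        bits[ix, iy, iz] <- TRUE
        forb <- list(BinaryMask(bits & maskBits(body), g))
    }
    list(body = body, target = target, forbidden = forb, geom = g)
}

test_that("unconstrained planning picks the nearest skin point", {
    fx <- plan_fixture()
    plan <- planTrajectory(fx$body, fx$target, maxCandidates = 1e6)
    surf <- arguide:::.maskSurfaceBits(maskBits(fx$body))
    pts <- worldFromVoxel(fx$geom, which(surf, arr.ind = TRUE) - 1)
    d <- sqrt(rowSums(sweep(pts, 2, fx$target)^2))
    expect_equal(plan@depth, min(d), tolerance = 1e-9)
    expect_equal(plan@direction,
                 (fx$target - plan@entry) / plan@depth, tolerance = 1e-12)
    expect_true(is.infinite(plan@clearance))
    # deterministic
    plan2 <- planTrajectory(fx$body, fx$target, maxCandidates = 1e6)
    expect_identical(plan@entry, plan2@entry)
})

test_that("an obstructing slab forces a cleared path", {
    fx <- plan_fixture(with_slab = TRUE)
    plan <- planTrajectory(fx$body, fx$target, forbidden = fx$forbidden,
                           minClearance = 2, maxCandidates = 1e6)
    # dense-sampling oracle on the chosen segment
    cl <- brute_force_clearance(plan@entry, fx$target, fx$forbidden[[1]])
    expect_gte(cl, 2 - 1e-6)
    expect_equal(plan@clearance, cl, tolerance = 0.3)
    # the blocked straight-in path (through +x) was rejected: the chosen
    # path is longer than the unconstrained optimum
    free_plan <- planTrajectory(fx$body, fx$target, maxCandidates = 1e6)
    expect_gt(plan@depth, free_plan@depth)
})

test_that("planning failures name the binding constraint", {
    fx <- plan_fixture()
    expect_error(planTrajectory(fx$body, fx$target, maxPathLength = 2,
                                maxCandidates = 1e6),
                 "path length", class = "arguide_planning_error")
    # target outside the liver violates the precondition
    liver <- BinaryMask(arguide:::.rasterBall(fx$geom, c(0, 0, 0), 5),
                        fx$geom)
    expect_error(planTrajectory(fx$body, c(15, 0, 0), liver = liver),
                 class = "arguide_value_error")
})

test_that("needle pose is exact for noiseless clip observations", {
    clip <- makeClipModel()
    # observations at the model positions: tip at the calibrated offset
    pose <- needlePose(clipMarkers(clip), clip)
    expect_equal(pose@tip, clip@tipOffset, tolerance = 1e-9)
    expect_equal(pose@axis, clip@axis, tolerance = 1e-9)
    expect_lt(pose@fre, 1e-9)

    # known rigid motion of the clip, seen through a tracker frame
    set.seed(31)
    for (i in 1:5) {
        motion <- random_rigid()
        frame <- random_rigid()
        obs <- applyTransform(frame,
                              applyTransform(motion, clipMarkers(clip)))
        pose2 <- needlePose(obs, clip, worldToTracker = frame)
        expect_equal(pose2@tip,
                     as.numeric(applyTransform(motion, clip@tipOffset)),
                     tolerance = 1e-9)
        expect_equal(pose2@axis,
                     as.numeric(rotateVector(motion, clip@axis)),
                     tolerance = 1e-9)
    }
    expect_error(needlePose(clipMarkers(clip)[1:2, ], clip),
                 class = "arguide_tracking_error")
    expect_error(needlePose(clipMarkers(clip) +
                            matrix(rnorm(15, 0, 20), 5), clip),
                 class = "arguide_tracking_error")
})

test_that("tip error grows with the clip-to-tip lever arm", {
    clip0 <- makeClipModel()
    set.seed(32)
    errs <- vapply(c(50, 100, 150), function(arm) {
        clip <- makeClipModel(markers = clipMarkers(clip0),
                              tipOffset = colMeans(clipMarkers(clip0)) +
                                  c(0, 0, -arm))
        mean(vapply(1:150, function(i) {
            obs <- clipMarkers(clip) + matrix(rnorm(15, 0, 0.5), 5)
            rownames(obs) <- rownames(clipMarkers(clip))
            pose <- needlePose(obs, clip)
            sqrt(sum((pose@tip - clip@tipOffset)^2))
        }, numeric(1)))
    }, numeric(1))
    expect_true(errs[1] < errs[2] && errs[2] < errs[3])
    # lever-arm amplification: tip error exceeds marker-level noise
    expect_gt(errs[2], 0.5)
})

test_that("alignment status implements the inclusive blue/green rule", {
    plan <- new("TrajectoryPlan", entry = c(0, 0, 0), target = c(0, 0, 100),
                direction = c(0, 0, 1), depth = 100, clearance = Inf)
    on_plan <- new("NeedlePose", tip = c(0, 0, 0), axis = c(0, 0, 1),
                   fre = 0)
    st <- alignmentStatus(on_plan, plan)
    expect_true(st@aligned)
    expect_equal(st@angleDeg, 0)
    expect_equal(st@lateralMm, 0)

    # 90-degree rotation: grossly misaligned
    crooked <- new("NeedlePose", tip = c(0, 0, 0), axis = c(1, 0, 0),
                   fre = 0)
    expect_false(alignmentStatus(crooked, plan)@aligned)

    # deviation exactly tau_ang with zero offset stays green (inclusive)
    tau <- 1.0
    tilted_axis <- c(sin(tau * pi / 180), 0, cos(tau * pi / 180))
    tilted <- new("NeedlePose", tip = c(0, 0, 0), axis = tilted_axis,
                  fre = 0)
    st2 <- alignmentStatus(tilted, plan, tauAng = tau, tauLat = 100)
    expect_equal(st2@angleDeg, tau, tolerance = 1e-9)
    expect_true(st2@aligned)

    # invariant under a common rigid motion of pose and plan
    set.seed(33)
    tr <- random_rigid()
    plan_m <- new("TrajectoryPlan",
                  entry = as.numeric(applyTransform(tr, plan@entry)),
                  target = as.numeric(applyTransform(tr, plan@target)),
                  direction = as.numeric(rotateVector(tr, plan@direction)),
                  depth = plan@depth, clearance = plan@clearance)
    pose_m <- new("NeedlePose",
                  tip = as.numeric(applyTransform(tr, tilted@tip)),
                  axis = as.numeric(rotateVector(tr, tilted@axis)), fre = 0)
    st3 <- alignmentStatus(pose_m, plan_m, tauAng = tau, tauLat = 100)
    expect_equal(st3@angleDeg, st2@angleDeg, tolerance = 1e-9)
    expect_equal(st3@lateralMm, st2@lateralMm, tolerance = 1e-6)
})

test_that("depth readout tracks the insertion, including overshoot", {
    plan <- new("TrajectoryPlan", entry = c(0, 0, 0), target = c(0, 0, 80),
                direction = c(0, 0, 1), depth = 80, clearance = Inf)
    at_entry <- new("NeedlePose", tip = c(0, 0, 0), axis = c(0, 0, 1),
                    fre = 0)
    expect_equal(insertionDepth(plan, at_entry)$remaining, 80)
    at_target <- new("NeedlePose", tip = c(0, 0, 80), axis = c(0, 0, 1),
                     fre = 0)
    expect_equal(insertionDepth(plan, at_target)$remaining, 0)
    # 6 mm past the target center: remaining is -6, inside the
    # recommended 5-7 mm overshoot window
    past <- new("NeedlePose", tip = c(0, 0, 86), axis = c(0, 0, 1), fre = 0)
    rem <- insertionDepth(plan, past)$remaining
    expect_equal(rem, -6)
    expect_true(-rem >= 5 && -rem <= 7)
})

test_that("tip-to-target is the Euclidean endpoint metric", {
    expect_equal(tipToTarget(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(tipToTarget(c(0, 0, 0), c(3, 0, 4)), 5)
    expect_error(tipToTarget(c(0, 0), c(1, 1, 1)),
                 class = "arguide_value_error")
})

test_that("an injected 3-mm registration bias propagates to the tip error", {
    # a constant 3-mm bias of the tracker's marker observations biases
    # the estimated world frame; the operator, converging the estimated
    # tip onto the displayed target, plants the true tip 3 mm off
    sc <- get_scene7()
    fid <- sceneFiducials(sc)
    t_true <- sceneTumorCenters(sc)[1, ]
    Ttrue <- tracker_frame()
    d <- c(3, 0, 0)
    obs <- sweep(applyTransform(Ttrue, fid), 2, d, "+")
    reg <- fitRigid(obs, fid)                     # tracker -> est. world
    w2t <- invertTransform(registrationTransform(reg))
    target_tracker <- applyTransform(w2t, t_true)
    nominal <- as.numeric(applyTransform(invertTransform(Ttrue),
                                         target_tracker))
    clip <- makeClipModel()
    R <- arguide:::.rotation_between(clip@axis, c(0, 0, 1))
    clip_world <- rigidTransform(R, nominal - as.vector(R %*% clip@tipOffset))
    obs_clip <- applyTransform(Ttrue,
                               applyTransform(clip_world, clipMarkers(clip)))
    rownames(obs_clip) <- rownames(clipMarkers(clip))
    pose <- needlePose(obs_clip, clip, w2t)
    tip_final <- nominal - (pose@tip - t_true)
    expect_equal(tipToTarget(tip_final, t_true), 3, tolerance = 0.1)
})
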