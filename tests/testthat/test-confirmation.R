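# Isotropic sphere fixtures for the margin arithmetic.
sphere_fixture <- function(spacing = 0.5, half_extent = 20) {
    n <- as.integer(2 * floor(half_extent / spacing) + 1)
    dims <- rep(n, 3)
    v <- Volume(array(0, dims), spacing = rep(spacing, 3),
                origin = -(dims - 1) * spacing / 2)
    gridGeometry(v)
}

raster_ball <- function(g, center, r) {
    BinaryMask(arguide:::.rasterBall(g, center, r), g)
}

test_that("pre/post mask registration recovers known motions", {
    dims <- rep(80L, 3); sp <- rep(0.75, 3)
    g <- gridGeometry(Volume(array(0, dims), spacing = sp,
                             origin = -(dims - 1) * sp / 2))
    semi <- c(22, 13, 26)
    pre <- BinaryMask(arguide:::.rasterEllipsoid(g, c(0, 0, 0), semi), g)

    # identical masks: identity, Dice ~ 1
    tr0 <- registerPrePost(pre, pre, refine = FALSE)
    expect_lt(max(abs(tr0@rotation - diag(3))), 1e-6)
    expect_lt(max(abs(tr0@translation)), 1e-6)
    expect_gt(attr(tr0, "dice"), 0.999)

    # pure translation recovered within one voxel
    post_t <- BinaryMask(arguide:::.rasterEllipsoid(g, c(4, -3, 2), semi), g)
    tr1 <- registerPrePost(pre, post_t)
    expect_lt(max(abs(tr1@translation - c(4, -3, 2))), max(sp))
    expect_lt(max(abs(tr1@rotation - diag(3))), 0.05)

    # 5-degree axial rotation recovered within 1 degree
    cc <- arguide:::.axisCoords(g)
    G <- as.matrix(expand.grid(cc$x, cc$y, cc$z))
    R5 <- axisRotation("z", 5)@rotation
    bits <- array(rowSums(((G %*% R5) /
                           matrix(semi, nrow(G), 3, byrow = TRUE))^2) <= 1,
                  dims)
    post_r <- BinaryMask(bits, g)
    tr2 <- registerPrePost(pre, post_r)
    ang <- acos((sum(diag(tr2@rotation)) - 1) / 2) * 180 / pi
    expect_lt(abs(ang - 5), 1)

    # hopeless overlap fails loudly
    far <- BinaryMask(arguide:::.rasterEllipsoid(g, c(0, 0, 0),
                                                 c(4, 25, 4)), g)
    expect_error(registerPrePost(pre, far, refine = FALSE, minDice = 0.9),
                 class = "arguide_registration_error")
    empty <- BinaryMask(array(FALSE, dims), g)
    expect_error(registerPrePost(pre, empty), class = "arguide_value_error")
})

test_that("margin shell volume approaches the analytic spherical shell", {
    # center-to-center dilation undershoots the continuous shell by up
    # to half a voxel at the outer boundary, so the digital volume sits
    # slightly below the analytic one and converges as voxels shrink
    analytic <- 4 / 3 * pi * (15^3 - 10^3)
    rel_err <- vapply(c(1, 0.5, 0.25), function(h) {
        g <- sphere_fixture(h)
        abs(maskVolumeMm3(marginShell(raster_ball(g, c(0, 0, 0), 10), 5)) -
            analytic) / analytic
    }, numeric(1))
    expect_lt(rel_err[2], 0.03)
    expect_lt(rel_err[3], 0.015)
    expect_true(all(diff(rel_err) < 0))

    g <- sphere_fixture(0.5)
    tumor <- raster_ball(g, c(0, 0, 0), 10)
    shell <- marginShell(tumor, 5)
    # monotone in the margin
    thin <- marginShell(tumor, 0.5)
    expect_true(all(maskBits(thin) <= maskBits(shell)))
    expect_error(marginShell(tumor, 0), class = "arguide_value_error")
    expect_error(marginShell(BinaryMask(array(FALSE, dim(tumor)), g), 5),
                 class = "arguide_value_error")
})

test_that("shell clipping keeps the margin inside the liver", {
    g <- sphere_fixture(1, 25)
    liver <- raster_ball(g, c(0, 0, 0), 20)
    tumor <- raster_ball(g, c(14, 0, 0), 6)   # abuts the liver surface
    clipped <- marginShell(tumor, 5, liver = liver, clipToLiver = TRUE)
    expect_equal(sum(maskBits(clipped) & !maskBits(liver)), 0L)
    unclipped <- marginShell(tumor, 5, liver = liver, clipToLiver = FALSE)
    expect_gt(sum(maskBits(unclipped) & !maskBits(liver)), 0L)
})

test_that("assessment reproduces the concentric-sphere oracle", {
    g <- sphere_fixture(0.5)
    tumor <- raster_ball(g, c(0, 0, 0), 10)
    nec13 <- raster_ball(g, c(0, 0, 0), 13)
    a <- assessAblation(tumor, nec13, margin = 5)
    analytic <- 100 * (15^3 - 13^3) / (15^3 - 10^3)
    expect_lt(abs(a@marginResidualPct - analytic), 1.5)
    expect_equal(a@tumorResidualPct, 0)
    expect_true(a@completeAblation)
    expect_false(a@marginSuccess)

    # necrosis covering the whole margin: zero residuals, success
    nec15 <- raster_ball(g, c(0, 0, 0), 15)
    a15 <- assessAblation(tumor, nec15, margin = 5)
    expect_equal(a15@marginResidualPct, 0)
    expect_true(a15@technicalSuccess)

    # necrosis = tumor exactly: complete ablation, no margin
    a_eq <- assessAblation(tumor, tumor, margin = 5)
    expect_equal(a_eq@tumorResidualPct, 0)
    expect_equal(a_eq@marginResidualPct, 100)
    expect_true(a_eq@completeAblation)
    expect_false(a_eq@technicalSuccess)
})

test_that("margin residual is monotone in the necrosis radius", {
    g <- sphere_fixture(0.5, 18)
    tumor <- raster_ball(g, c(0, 0, 0), 8)
    res <- vapply(c(8, 9, 10, 11, 12, 13), function(r)
        assessAblation(tumor, raster_ball(g, c(0, 0, 0), r),
                       margin = 5)@marginResidualPct, numeric(1))
    expect_true(all(diff(res) <= 0))
})

test_that("assessment is invariant under a common rigid motion of frames", {
    g <- sphere_fixture(1, 16)
    tumor <- raster_ball(g, c(0, 0, 0), 8)
    nec <- raster_ball(g, c(2, 0, 0), 11)
    a0 <- assessAblation(tumor, nec, margin = 5)

    # post frame translated: same voxel pattern, shifted grid, with the
    # transform updated accordingly
    shift <- c(7, -4, 3)
    g2 <- gridGeometry(Volume(array(0, dim(nec)), spacing = voxelSpacing(nec),
                              origin = voxelOrigin(nec) + shift))
    nec_moved <- BinaryMask(maskBits(nec), g2)
    a1 <- assessAblation(tumor, nec_moved,
                         transform = rigidTransform(diag(3), shift),
                         margin = 5)
    expect_equal(a1@marginResidualPct, a0@marginResidualPct, tolerance = 0.02)
    expect_equal(a1@tumorResidualPct, a0@tumorResidualPct, tolerance = 0.5)
})

test_that("empty necrosis is assessed with full residuals and a warning", {
    g <- sphere_fixture(1, 12)
    tumor <- raster_ball(g, c(0, 0, 0), 6)
    empty <- BinaryMask(array(FALSE, dim(tumor)), g)
    expect_warning(a <- assessAblation(tumor, empty, margin = 5),
                   "empty")
    expect_equal(a@tumorResidualPct, 100)
    expect_equal(a@marginResidualPct, 100)
    expect_true(a@emptyNecrosis)
    expect_false(a@technicalSuccess)
    expect_error(assessAblation(empty, tumor), class = "arguide_value_error")
})

test_that("success flags follow the strict >90 percent margin rule", {
    # the reported 5.4 percent residual case: all flags true
    f <- ablationFlags(0, 5.4)
    expect_true(f$completeAblation && f$marginSuccess && f$technicalSuccess)
    # 12.1 percent residual: complete ablation but margin failure
    f2 <- ablationFlags(0, 12.1)
    expect_true(f2$completeAblation)
    expect_false(f2$marginSuccess)
    expect_false(f2$technicalSuccess)
    # any unablated tumor voids technical success
    f3 <- ablationFlags(1, 0)
    expect_false(f3$completeAblation)
    expect_false(f3$technicalSuccess)
    # boundary: residual exactly 10.0 means exactly 90 percent ablated,
    # which does not satisfy "> 90 percent"
    expect_false(ablationFlags(0, 10.0)$marginSuccess)
    expect_true(ablationFlags(0, 9.999)$marginSuccess)

    # technicalSuccess() re-derives flags from a stored assessment
    g <- sphere_fixture(1, 12)
    tumor <- raster_ball(g, c(0, 0, 0), 6)
    nec <- raster_ball(g, c(0, 0, 0), 11.5)
    a <- assessAblation(tumor, nec, margin = 5)
    expect_identical(technicalSuccess(a),
                     ablationFlags(a@tumorResidualPct, a@marginResidualPct))
})
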