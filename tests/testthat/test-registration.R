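test_that("rigid transforms compose, invert and validate", {
    set.seed(21)
    a <- random_rigid(); b <- random_rigid()
    p <- matrix(runif(15, -40, 40), 5)
    expect_equal(applyTransform(composeTransforms(a, b), p),
                 applyTransform(a, applyTransform(b, p)), tolerance = 1e-12)
    expect_equal(applyTransform(invertTransform(a), applyTransform(a, p)),
                 p, tolerance = 1e-9)
    expect_error(rigidTransform(rotation = diag(c(1, 1, -1))))
    # JSON round trip
    pth <- file.path(withr::local_tempdir(), "t.json")
    writeTransform(a, pth)
    a2 <- readTransform(pth)
    expect_equal(a@rotation, a2@rotation, tolerance = 1e-12)
    expect_equal(a@translation, a2@translation, tolerance = 1e-12)
})

test_that("fitRigid recovers a generating transform to numerical precision", {
    set.seed(22)
    P <- matrix(runif(60, -80, 80), 20)
    # self-registration
    self <- fitRigid(P, P)
    expect_lt(registrationFRE(self), 1e-9)
    expect_equal(registrationTransform(self)@rotation, diag(3),
                 tolerance = 1e-9)
    # known rigid motion
    for (i in 1:5) {
        tr <- random_rigid()
        fit <- fitRigid(P, applyTransform(tr, P))
        expect_lt(max(abs(registrationTransform(fit)@rotation - tr@rotation)),
                  1e-9)
        expect_lt(max(abs(registrationTransform(fit)@translation -
                          tr@translation)), 1e-9)
        expect_lt(registrationFRE(fit), 1e-9)
    }
})

test_that("fitRigid is invariant to pair order and common rigid motion", {
    set.seed(23)
    P <- matrix(runif(36, -50, 50), 12)
    Q <- applyTransform(random_rigid(), P) + matrix(rnorm(36, 0, 0.5), 12)
    f1 <- fitRigid(P, Q)
    perm <- sample(12)
    f2 <- fitRigid(P[perm, ], Q[perm, ])
    expect_equal(registrationFRE(f1), registrationFRE(f2), tolerance = 1e-12)
    common <- random_rigid()
    f3 <- fitRigid(applyTransform(common, P), applyTransform(common, Q))
    expect_equal(registrationFRE(f1), registrationFRE(f3), tolerance = 1e-9)
})

test_that("degenerate configurations are rejected", {
    line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
    expect_error(fitRigid(line, line), class = "arguide_degeneracy_error")
    expect_error(fitRigid(line[1:2, ], line[1:2, ]),
                 class = "arguide_degeneracy_error")
})

test_that("mean squared FRE follows the (1 - 2/N) * 3 sigma^2 expectation", {
    set.seed(24)
    P <- matrix(runif(60, -80, 80), 20)
    tr <- random_rigid()
    Q0 <- applyTransform(tr, P)
    fre2 <- vapply(1:500, function(i)
        registrationFRE(fitRigid(P, Q0 + matrix(rnorm(60, 0, 0.5), 20)))^2,
        numeric(1))
    expect_equal(mean(fre2), (1 - 2 / 20) * 3 * 0.5^2, tolerance = 0.05)
})

test_that("removing the worst pair never increases the refit FRE", {
    set.seed(25)
    for (i in 1:10) {
        P <- matrix(runif(30, -50, 50), 10)
        Q <- applyTransform(random_rigid(), P) + matrix(rnorm(30, 0, 0.4), 10)
        Q[1, ] <- Q[1, ] + c(5, -3, 2)   # outlier
        full <- fitRigid(P, Q)
        worst <- which.max(full@residuals)
        reduced <- fitRigid(P[-worst, ], Q[-worst, ])
        expect_lte(registrationFRE(reduced), registrationFRE(full))
    }
})

test_that("constellation matching recovers identity and noiseless transforms", {
    con <- get_constellation3()
    ref <- constellationPoints(con)
    # exact self-match, permuted
    set.seed(26)
    perm <- sample(20)
    res <- matchConstellation(ref[perm, ], con)
    expect_lt(registrationFRE(res), 1e-9)
    co <- registrationCorrespondence(res)
    expect_equal(unname(co[, 2]), perm[co[, 1]])
})

test_that("noiseless transformed constellations are matched exactly", {
    con <- get_constellation3()
    ref <- constellationPoints(con)
    set.seed(27)
    for (i in 1:5) {
        tr <- random_rigid()
        perm <- sample(20)
        obs <- applyTransform(tr, ref)[perm, ]
        res <- matchConstellation(obs, con)
        co <- registrationCorrespondence(res)
        expect_equal(unname(co[, 2]), perm[co[, 1]])
        expect_lt(registrationFRE(res), 1e-6)
        # the estimated transform reproduces the inverse generating map
        inv <- invertTransform(tr)
        expect_lt(max(abs(registrationTransform(res)@rotation -
                          inv@rotation)), 1e-6)
    }
})

test_that("matching survives noise and occlusion", {
    con <- get_constellation3()
    ref <- constellationPoints(con)
    n_ok <- 0L
    for (i in 1:40) {
        set.seed(400 + i)
        tr <- random_rigid()
        n_occ <- if (i %% 2 == 0) 2L else 0L
        keep <- sort(sample(20, 20 - n_occ))
        obs <- applyTransform(tr, ref[keep, ]) +
            matrix(rnorm(3 * length(keep), 0, 0.5), length(keep))
        perm <- sample(length(keep))
        obs <- obs[perm, ]
        truth <- keep[perm]
        res <- matchConstellation(obs, con)
        co <- registrationCorrespondence(res)
        if (nrow(co) == length(keep) && all(truth[co[, 1]] == co[, 2]))
            n_ok <- n_ok + 1L
    }
    expect_equal(n_ok, 40L)
    expect_error(matchConstellation(ref[1:3, ], con),
                 class = "arguide_matching_error")
})

test_that("signature matching agrees with the exhaustive oracle on small sets", {
    set.seed(28)
    for (i in 1:8) {
        con <- randomConstellation(7, minSepMm = 20, distinctTolMm = 2,
                                   box = c(120, 120, 80), seed = 500 + i)
        ref <- constellationPoints(con)
        tr <- random_rigid()
        perm <- sample(7)[1:6]   # one marker occluded
        obs <- applyTransform(tr, ref[perm, ]) + matrix(rnorm(18, 0, 0.3), 6)
        fast <- matchConstellation(obs, con)
        slow <- matchExhaustive(obs, con)
        co_f <- registrationCorrespondence(fast)
        co_s <- registrationCorrespondence(slow)
        expect_equal(unname(co_f[order(co_f[, 1]), 2]),
                     unname(co_s[order(co_s[, 1]), 2]))
    }
})

test_that("target registration error reflects translation and lever arm", {
    set.seed(29)
    P <- matrix(runif(60, -60, 60), 20)
    tr <- random_rigid()
    fit <- fitRigid(P, applyTransform(tr, P))
    targets <- matrix(runif(15, -60, 60), 5)
    expect_equal(targetRegistrationError(fit, tr, targets), rep(0, 5),
                 tolerance = 1e-9)

    # a pure 2-mm translation error gives TRE 2 everywhere
    shifted <- composeTransforms(rigidTransform(diag(3), c(2, 0, 0)), tr)
    expect_equal(targetRegistrationError(shifted, tr, targets), rep(2, 5),
                 tolerance = 1e-9)

    # under noisy fits, TRE grows with distance from the fiducial centroid
    ctr <- colMeans(P)
    far <- rbind(ctr + c(50, 0, 0), ctr + c(100, 0, 0), ctr + c(150, 0, 0))
    tre <- matrix(0, 200, 3)
    for (i in 1:200) {
        Qn <- applyTransform(tr, P) + matrix(rnorm(60, 0, 0.5), 20)
        tre[i, ] <- targetRegistrationError(fitRigid(P, Qn), tr, far)
    }
    m <- colMeans(tre)
    expect_true(m[1] < m[2] && m[2] < m[3])
})
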