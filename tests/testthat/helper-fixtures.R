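# Shared fixtures, built in code. The reference phantom scene and its
# session preparation are expensive, so they are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

get_scene7 <- function() {
    if (is.null(.fixture_cache$scene7))
        .fixture_cache$scene7 <- makePhantom(seed = 7)
    .fixture_cache$scene7
}

get_prep7 <- function() {
    if (is.null(.fixture_cache$prep7))
        .fixture_cache$prep7 <- prepareSession(get_scene7())
    .fixture_cache$prep7
}

get_constellation3 <- function() {
    if (is.null(.fixture_cache$con3))
        .fixture_cache$con3 <- randomConstellation(20, minSepMm = 15,
                                                   distinctTolMm = 0.1,
                                                   seed = 3)
    .fixture_cache$con3
}

# A representative tracker frame (rotation + translation).
tracker_frame <- function() {
    composeTransforms(axisRotation("y", 20, c(100, 50, -30)),
                      axisRotation("z", -35))
}

# Random proper rotation (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
}

random_rigid <- function(tmax = 50) {
    rigidTransform(random_rotation(), runif(3, -tmax, tmax))
}

# Brute-force Euclidean distance of every voxel center to the mask
# foreground (the independent oracle for the distance transform).
brute_force_distances <- function(mask) {
    dims <- dim(mask)
    fg <- which(maskBits(mask), arr.ind = TRUE) - 1
    pfg <- worldFromVoxel(mask, fg)
    idx <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                                 0:(dims[3] - 1)))
    pall <- worldFromVoxel(mask, idx)
    d <- apply(pall, 1, function(p) sqrt(min(colSums((t(pfg) - p)^2))))
    array(d, dims)
}

# Minimum distance from points sampled densely on a segment to the
# foreground voxel centers of a mask (oracle for trajectory clearance).
brute_force_clearance <- function(entry, target, mask, step = 0.25) {
    fg <- worldFromVoxel(mask, which(maskBits(mask), arr.ind = TRUE) - 1)
    n <- max(2, ceiling(sqrt(sum((target - entry)^2)) / step))
    tt <- seq(0, 1, length.out = n)
    pts <- outer(tt, target - entry) + matrix(entry, n, 3, byrow = TRUE)
    min(apply(pts, 1, function(p) sqrt(min(colSums((t(fg) - p)^2)))))
}

# Small uniform-geometry volume for I/O and morphology tests.
small_volume <- function(dims = c(16L, 16L, 8L), spacing = c(0.5, 0.5, 2),
                         origin = c(0, 0, 0), values = NULL) {
    if (is.null(values)) values <- array(0, dims)
    Volume(values, spacing = spacing, origin = origin)
}
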