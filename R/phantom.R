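# Seeded synthetic-data generator: CT-like abdominal scenes with truth
# masks, a 20-marker skin fiducial constellation with a non-repetitive
# pairwise-distance pattern, tracker observations, breathing displacement
# and simulated ablation volumes.

# --- rasterization helpers (identity direction grids) ----------------------

.axisCoords <- function(geom) {
    list(x = geom@origin[1L] + geom@spacing[1L] * (seq_len(geom@dim[1L]) - 1),
         y = geom@origin[2L] + geom@spacing[2L] * (seq_len(geom@dim[2L]) - 1),
         z = geom@origin[3L] + geom@spacing[3L] * (seq_len(geom@dim[3L]) - 1))
}

.rasterEllipsoid <- function(geom, center, semi) {
    cc <- .axisCoords(geom)
    dx2 <- ((cc$x - center[1L]) / semi[1L])^2
    dy2 <- ((cc$y - center[2L]) / semi[2L])^2
    dz2 <- ((cc$z - center[3L]) / semi[3L])^2
    plane <- outer(dx2, dy2, "+")
    arr <- array(FALSE, geom@dim)
    for (k in seq_along(dz2)) arr[, , k] <- plane + dz2[k] <= 1
    arr
}

.rasterBall <- function(geom, center, radius) {
    .rasterEllipsoid(geom, center, rep(radius, 3L))
}

.rasterCylinderZ <- function(geom, cx, cy, radius, zmin = -Inf, zmax = Inf) {
    cc <- .axisCoords(geom)
    plane <- outer((cc$x - cx)^2, (cc$y - cy)^2, "+") <= radius^2
    arr <- array(FALSE, geom@dim)
    inz <- cc$z >= zmin & cc$z <= zmax
    for (k in which(inz)) arr[, , k] <- plane
    arr
}

# Tube of given radius around a polyline of world segments, rasterized on
# the bounding box only.
.rasterSegments <- function(geom, segments, radius) {
    cc <- .axisCoords(geom)
    arr <- array(FALSE, geom@dim)
    for (seg in segments) {
        a <- seg[[1L]]; b <- seg[[2L]]
        lo <- pmin(a, b) - radius; hi <- pmax(a, b) + radius
        ix <- which(cc$x >= lo[1L] & cc$x <= hi[1L])
        iy <- which(cc$y >= lo[2L] & cc$y <= hi[2L])
        iz <- which(cc$z >= lo[3L] & cc$z <= hi[3L])
        if (!length(ix) || !length(iy) || !length(iz)) next
        G <- as.matrix(expand.grid(x = cc$x[ix], y = cc$y[iy], z = cc$z[iz]))
        ab <- b - a
        len2 <- sum(ab^2)
        t_ <- .clamp((sweep(G, 2L, a) %*% ab) / len2, 0, 1)
        proj <- sweep(t_ %*% t(ab), 2L, a, "+")
        hit <- .row_norms(G - proj) <= radius
        sub <- array(hit, dim = c(length(ix), length(iy), length(iz)))
        arr[ix, iy, iz] <- arr[ix, iy, iz] | sub
    }
    arr
}

# Foreground voxels with at least one 6-neighbour outside the mask.
.maskSurfaceBits <- function(bits) {
    d <- dim(bits)
    nb_out <- array(FALSE, d)
    mark <- function(outside) nb_out <<- nb_out | outside
    o <- array(TRUE, d); o[2:d[1L], , ] <- !bits[1:(d[1L] - 1L), , ]; mark(o)
    o <- array(TRUE, d); o[1:(d[1L] - 1L), , ] <- !bits[2:d[1L], , ]; mark(o)
    o <- array(TRUE, d); o[, 2:d[2L], ] <- !bits[, 1:(d[2L] - 1L), ]; mark(o)
    o <- array(TRUE, d); o[, 1:(d[2L] - 1L), ] <- !bits[, 2:d[2L], ]; mark(o)
    o <- array(TRUE, d); o[, , 2:d[3L]] <- !bits[, , 1:(d[3L] - 1L)]; mark(o)
    o <- array(TRUE, d); o[, , 1:(d[3L] - 1L)] <- !bits[, , 2:d[3L]]; mark(o)
    bits & nb_out
}

# Nearest-neighbour rigid translation of a mask (constant world shift).
.shiftMaskBits <- function(bits, shift_vox) {
    k <- as.integer(round(shift_vox))
    d <- dim(bits)
    out <- array(FALSE, d)
    src <- list(seq_len(d[1L]) - k[1L], seq_len(d[2L]) - k[2L],
                seq_len(d[3L]) - k[3L])
    ok <- lapply(seq_len(3L), function(a) src[[a]] >= 1L & src[[a]] <= d[a])
    out[ok[[1L]], ok[[2L]], ok[[3L]]] <-
        bits[src[[1L]][ok[[1L]]], src[[2L]][ok[[2L]]], src[[3L]][ok[[3L]]]]
    out
}

# --- configuration ---------------------------------------------------------

#' Default phantom configuration
#'
#' Emulates the acquisition geometry of an abdominal CECT for AR-guided
#' ablation: 2-mm slices, sub-millimetre in-plane pixels, twenty skin
#' fiducials around the right hypochondrium, hypodense liver tumors.
#' The grid defaults to 128 x 128 x 60 at 0.7 x 0.7 x 2.0 mm (the
#' clinical in-plane matrix is configurable via \code{dim}).
#'
#' @param dim grid extent (voxels).
#' @param spacing voxel size, mm.
#' @param tumorDiametersMm requested tumor diameters, mm (5-40 each).
#' @param tumorCenters optional K x 3 matrix of tumor centers, mm; when
#'   NULL centers are sampled inside the liver envelope.
#' @param nFiducials number of skin fiducials (default 20).
#' @param fiducialMinSepMm minimum marker separation, mm.
#' @param fiducialDistinctTolMm required gap between any two pairwise
#'   distances of the constellation, mm.
#' @param markerDiameterMm rendered fiducial diameter, mm.
#' @param noiseSd optional Gaussian image noise, HU.
#' @param palette named HU constants (air < soft < liver < vessel < bone
#'   < marker; tumors are hypodense relative to liver).
#' @param maxRetries bounded retries for marker/tumor placement.
#' @return configuration list for \code{\link{makePhantom}}.
#' @export
phantomConfig <- function(dim = c(128L, 128L, 60L),
                          spacing = c(0.7, 0.7, 2.0),
                          tumorDiametersMm = 15,
                          tumorCenters = NULL,
                          nFiducials = 20L,
                          fiducialMinSepMm = 15,
                          fiducialDistinctTolMm = 0.1,
                          markerDiameterMm = 4,
                          noiseSd = 0,
                          palette = list(air = -1000, soft = 45, spleen = 50,
                                         liver = 60, tumor = 30, vessel = 150,
                                         bone = 700, marker = 2000),
                          maxRetries = 50L) {
    list(dim = as.integer(dim), spacing = as.numeric(spacing),
         bodyHalfAxes = c(40, 30),
         liverCenter = c(-15, -4, 8), liverSemiAxes = c(21, 16, 24),
         spleenCenter = c(26, 6, 2), spleenSemiAxes = c(8, 6, 10),
         spineCenter = c(0, 23), spineRadius = 7,
         nVessels = 3L, vesselRadius = 2.2,
         tumorDiametersMm = tumorDiametersMm, tumorCenters = tumorCenters,
         nFiducials = as.integer(nFiducials),
         fiducialMinSepMm = fiducialMinSepMm,
         fiducialDistinctTolMm = fiducialDistinctTolMm,
         markerDiameterMm = markerDiameterMm,
         noiseSd = noiseSd, palette = palette,
         maxRetries = as.integer(maxRetries))
}

# --- constellation sampling ------------------------------------------------

# Incrementally accept candidate points keeping (a) minimum separation and
# (b) all pairwise distances distinct by more than `tol`.
.sample_constellation <- function(pool, n, minSep, tol, maxRetries) {
    npool <- nrow(pool)
    if (npool < n) return(NULL)
    for (try_ in seq_len(maxRetries)) {
        ord <- sample.int(npool)
        acc <- matrix(0, 0L, 3L)
        dists <- numeric(0)
        for (idx in ord) {
            cand <- pool[idx, ]
            if (nrow(acc) == 0L) {
                acc <- rbind(acc, cand)
                next
            }
            dnew <- .row_norms(sweep(acc, 2L, cand, "-"))
            if (any(dnew < minSep)) next
            ds <- sort(dnew)
            if (length(ds) > 1L && min(diff(ds)) <= tol) next
            if (length(dists) > 0L) {
                all_d <- sort(c(dists, ds))
                if (min(diff(all_d)) <= tol) next
            }
            acc <- rbind(acc, cand)
            dists <- sort(c(dists, ds))
            if (nrow(acc) == n) return(acc)
        }
    }
    NULL
}

#' Random non-repetitive constellation in a box
#'
#' Rejection-samples \code{n} points with a minimum separation and a
#' distinct pairwise-distance multiset, the same procedure used for the
#' phantom's skin fiducials.
#'
#' @param n number of markers.
#' @param minSepMm minimum marker separation, mm.
#' @param distinctTolMm required gap between any two pairwise distances,
#'   mm.
#' @param box box extent (mm, length-3); points are sampled uniformly in
#'   \code{[0, box]}.
#' @param seed integer seed.
#' @param poolSize candidate pool per attempt.
#' @param maxRetries bounded retries before a generation error.
#' @return A \linkS4class{Constellation}.
#' @export
randomConstellation <- function(n = 20L, minSepMm = 15, distinctTolMm = 0.1,
                                box = c(200, 200, 100), seed = 1L,
                                poolSize = 4000L, maxRetries = 20L) {
    .with_seed(seed, {
        pool <- cbind(runif(poolSize, 0, box[1L]), runif(poolSize, 0, box[2L]),
                      runif(poolSize, 0, box[3L]))
        pts <- .sample_constellation(pool, n, minSepMm, distinctTolMm,
                                     maxRetries)
        if (is.null(pts))
            .abort("could not place a non-repetitive constellation after bounded retries",
                   "arguide_generation_error")
        Constellation(pts[order(pts[, 1L], pts[, 2L], pts[, 3L]), , drop = FALSE])
    })
}

# --- clip model ------------------------------------------------------------

#' Five-marker needle clip model
#'
#' Marker coordinates in the clip frame with a non-repetitive pairwise
#' distance pattern, the needle tip offset, and the shaft axis. The
#' default geometry places the tip 100 mm from the clip centroid along
#' -z (a rigid coaxial introducer).
#'
#' @param markers 5 x 3 marker coordinates, mm.
#' @param tipOffset clip-frame vector to the needle tip, mm.
#' @param axis unit shaft direction in the clip frame.
#' @return A \linkS4class{ClipModel}.
#' @export
makeClipModel <- function(markers = NULL, tipOffset = NULL,
                          axis = c(0, 0, -1)) {
    if (is.null(markers)) {
        # pairwise distances 21.1-65.7 mm, multiset gaps all > 3.6 mm
        markers <- rbind(c(11.8, 5.5, 52.5), c(26.0, 3.6, 2.4),
                         c(3.0, 24.4, 49.2), c(0.9, 1.9, 29.5),
                         c(42.3, 41.3, 53.7))
        rownames(markers) <- sprintf("C%d", 1:5)
    }
    if (is.null(tipOffset)) {
        tipOffset <- colMeans(markers) + c(0, 0, -100)
    }
    new("ClipModel", markers = .as_points(markers, "clip markers"),
        tipOffset = as.numeric(tipOffset), axis = .unit(axis))
}

#' Clip marker coordinates
#' @param clip a \linkS4class{ClipModel}.
#' @return 5 x 3 matrix, mm.
#' @export
clipMarkers <- function(clip) clip@markers

setMethod("show", "ClipModel", function(object) {
    cat(sprintf("ClipModel | 5 markers | tip offset %.1f mm from centroid\n",
                sqrt(sum((object@tipOffset - colMeans(object@markers))^2))))
})

# --- scene construction ----------------------------------------------------

.renderScene <- function(geom, masks, tumors, palette, noiseSd, seed) {
    arr <- array(palette$air, geom@dim)
    arr[masks$body@bits] <- palette$soft
    arr[masks$spleen@bits] <- palette$spleen
    arr[masks$liver@bits] <- palette$liver
    arr[masks$vessels@bits] <- palette$vessel
    for (tm in tumors) arr[tm@bits] <- palette$tumor
    arr[masks$bone@bits] <- palette$bone
    arr[masks$markers@bits] <- palette$marker
    if (noiseSd > 0) {
        arr <- arr + .with_seed(seed,
            array(rnorm(prod(geom@dim), 0, noiseSd), geom@dim))
    }
    new("Volume", geometry = geom, intensities = arr)
}

#' Generate a synthetic CT phantom scene
#'
#' Deterministic for a fixed seed. The scene comprises an elliptic body,
#' a liver ellipsoid with vessels and hypodense spherical tumors, spleen,
#' a bony spine, and \code{nFiducials} skin fiducials placed on the
#' anterior body surface by rejection sampling so that the constellation
#' has no repetitive pairwise-distance pattern.
#'
#' @param config a list from \code{\link{phantomConfig}}.
#' @param seed integer seed.
#' @return A \linkS4class{PhantomScene}.
#' @export
makePhantom <- function(config = phantomConfig(), seed = 1L) {
    cfg <- utils::modifyList(phantomConfig(), config)
    diam <- cfg$tumorDiametersMm
    if (any(diam < 5 | diam > 40))
        .value_error("tumor diameters must be 0.5-4 cm (5-40 mm)")
    geom <- new("GridGeometry", dim = cfg$dim, spacing = cfg$spacing,
                origin = -(cfg$dim - 1) * cfg$spacing / 2, direction = diag(3))
    cc <- .axisCoords(geom)
    zHalf <- max(cc$z) - 2 * cfg$spacing[3L]

    body_bits <- array(FALSE, geom@dim)
    ell <- outer((cc$x / cfg$bodyHalfAxes[1L])^2,
                 (cc$y / cfg$bodyHalfAxes[2L])^2, "+") <= 1
    for (k in which(cc$z >= -zHalf & cc$z <= zHalf))
        body_bits[, , k] <- ell

    liver_bits <- .rasterEllipsoid(geom, cfg$liverCenter, cfg$liverSemiAxes)
    spleen_bits <- .rasterEllipsoid(geom, cfg$spleenCenter, cfg$spleenSemiAxes)
    bone_bits <- .rasterCylinderZ(geom, cfg$spineCenter[1L], cfg$spineCenter[2L],
                                  cfg$spineRadius, -zHalf, zHalf)
    liver_bits <- liver_bits & body_bits & !bone_bits
    spleen_bits <- spleen_bits & body_bits & !bone_bits

    state <- .with_seed(seed, {
        # tumors first: spheres inside the (shrunken) liver envelope
        centers <- cfg$tumorCenters
        if (is.null(centers)) {
            centers <- matrix(0, 0L, 3L)
            for (d in diam) {
                r <- d / 2
                placed <- FALSE
                for (it in seq_len(200L)) {
                    u <- rnorm(3L); u <- u / sqrt(sum(u^2))
                    rad <- runif(1L)^(1 / 3)
                    cand <- cfg$liverCenter +
                        u * rad * (cfg$liverSemiAxes - r - 2)
                    if (nrow(centers) > 0L &&
                        any(.row_norms(sweep(centers, 2L, cand, "-")) <
                            r + max(diam) / 2 + 4)) next
                    centers <- rbind(centers, cand)
                    placed <- TRUE
                    break
                }
                if (!placed)
                    .abort("could not fit the requested tumors inside the liver",
                           "arguide_generation_error")
            }
        } else {
            centers <- .as_points(centers, "tumorCenters")
            for (i in seq_len(nrow(centers))) {
                r <- diam[min(i, length(diam))] / 2
                if (sum(((centers[i, ] - cfg$liverCenter) /
                         (cfg$liverSemiAxes - r))^2) > 1)
                    .value_error("requested tumor does not fit inside the liver envelope")
            }
        }

        # vessels: tubes from the liver hilum toward random interior
        # points, preferring routes clear of the tumors (a route through
        # a tumor is tolerated as a last resort; the tumor sphere is
        # rendered on top and the vessel truth mask is clipped to it)
        radii <- rep(diam / 2, length.out = nrow(centers))
        segs <- vector("list", cfg$nVessels)
        for (i in seq_len(cfg$nVessels)) {
            best_seg <- NULL; best_margin <- -Inf
            for (it in seq_len(60L)) {
                u <- rnorm(3L); u <- u / sqrt(sum(u^2))
                seg <- list(cfg$liverCenter,
                            cfg$liverCenter + u * 0.75 * cfg$liverSemiAxes)
                ab <- seg[[2L]] - seg[[1L]]
                margin <- min(vapply(seq_len(nrow(centers)), function(k) {
                    t_ <- .clamp(sum((centers[k, ] - seg[[1L]]) * ab) /
                                 sum(ab^2), 0, 1)
                    sqrt(sum((seg[[1L]] + t_ * ab - centers[k, ])^2)) -
                        radii[k]
                }, numeric(1L)))
                if (margin > best_margin) {
                    best_margin <- margin; best_seg <- seg
                }
                if (margin >= cfg$vesselRadius + 1) break
            }
            segs[[i]] <- best_seg
        }
        vessel_bits <- .rasterSegments(geom, segs, cfg$vesselRadius) & liver_bits

        # fiducials on the anterior body surface
        surf <- .maskSurfaceBits(body_bits)
        sidx <- which(surf, arr.ind = TRUE) - 1
        spts <- worldFromVoxel(geom, sidx)
        pool <- spts[spts[, 2L] <= 5, , drop = FALSE]
        fid <- .sample_constellation(pool, cfg$nFiducials,
                                     cfg$fiducialMinSepMm,
                                     cfg$fiducialDistinctTolMm,
                                     cfg$maxRetries)
        if (is.null(fid))
            .abort("could not place the skin fiducial constellation after bounded retries",
                   "arguide_generation_error")
        fid <- fid[order(fid[, 1L], fid[, 2L], fid[, 3L]), , drop = FALSE]
        rownames(fid) <- sprintf("F%02d", seq_len(nrow(fid)))
        list(vessel_bits = vessel_bits, centers = centers, fid = fid)
    })

    tumors <- lapply(seq_len(nrow(state$centers)), function(i) {
        r <- diam[min(i, length(diam))] / 2
        BinaryMask(.rasterBall(geom, state$centers[i, ], r) & liver_bits, geom)
    })
    for (tm in tumors)
        state$vessel_bits <- state$vessel_bits & !tm@bits

    marker_bits <- array(FALSE, geom@dim)
    for (i in seq_len(nrow(state$fid)))
        marker_bits <- marker_bits |
            .rasterBall(geom, state$fid[i, ], cfg$markerDiameterMm / 2)

    masks <- list(
        body = BinaryMask(body_bits, geom),
        liver = BinaryMask(liver_bits, geom),
        spleen = BinaryMask(spleen_bits, geom),
        bone = BinaryMask(bone_bits, geom),
        vessels = BinaryMask(state$vessel_bits, geom),
        markers = BinaryMask(marker_bits, geom))
    vol <- .renderScene(geom, masks, tumors, cfg$palette, cfg$noiseSd, seed)
    centers <- state$centers
    rownames(centers) <- sprintf("T%d", seq_len(nrow(centers)))
    new("PhantomScene", volume = vol, masks = masks, tumors = tumors,
        tumorCenters = centers,
        tumorDiameters = rep(diam, length.out = nrow(centers)),
        fiducials = state$fid, palette = cfg$palette,
        displacement = c(0, 0, 0), config = cfg, seed = as.numeric(seed))
}

#' Scene accessors
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @return \code{sceneVolume}: the rendered \linkS4class{Volume};
#'   \code{sceneMasks}: named list of truth masks; \code{sceneTumors}:
#'   list of tumor masks; \code{sceneFiducials}: labelled fiducial matrix,
#'   mm; \code{sceneTumorCenters}: true tumor centers, mm.
#' @export
sceneVolume <- function(scene) scene@volume

#' @rdname sceneVolume
#' @export
sceneMasks <- function(scene) scene@masks

#' @rdname sceneVolume
#' @export
sceneTumors <- function(scene) scene@tumors

#' @rdname sceneVolume
#' @export
sceneFiducials <- function(scene) scene@fiducials

#' @rdname sceneVolume
#' @export
sceneTumorCenters <- function(scene) scene@tumorCenters

setMethod("show", "PhantomScene", function(object) {
    cat(sprintf(
        "PhantomScene %s | %d fiducials | %d tumor(s) (%s mm) | displacement (%s) mm\n",
        paste(dim(object@volume), collapse = "x"), nrow(object@fiducials),
        length(object@tumors),
        paste(signif(object@tumorDiameters, 3), collapse = ", "),
        paste(signif(object@displacement, 3), collapse = ", ")))
})

# --- observation model -----------------------------------------------------

#' Construct an ObservationModel
#'
#' @param sigma per-axis Gaussian noise, mm.
#' @param occlusion per-marker dropout probability in [0, 1).
#' @param frame \linkS4class{RigidTransform} from scene world to tracker
#'   frame.
#' @param seed integer seed or NA (draw from the current stream).
#' @return An \linkS4class{ObservationModel}.
#' @export
observationModel <- function(sigma = 0.5, occlusion = 0,
                             frame = identityTransform(), seed = NA_real_) {
    new("ObservationModel", sigma = sigma, occlusion = occlusion,
        frame = frame, seed = as.numeric(seed))
}

#' Observe markers through the tracker
#'
#' Each surviving point is mapped by the frame transform and perturbed by
#' i.i.d. Gaussian noise per axis; occluded markers are dropped and the
#' output order is randomly permuted (labels withheld). The ground-truth
#' correspondence is returned separately for auditing.
#'
#' @param points labelled N x 3 matrix of world points, mm.
#' @param model an \linkS4class{ObservationModel}.
#' @param seed optional seed overriding the model's.
#' @return list with \code{points} (M x 3 observed, unlabelled),
#'   \code{truth} (original row index of each observed row) and
#'   \code{kept} (logical, which inputs survived).
#' @export
observeMarkers <- function(points, model, seed = NULL) {
    p <- .as_points(points)
    use_seed <- if (!is.null(seed)) seed else model@seed
    .with_seed(use_seed, {
        n <- nrow(p)
        kept <- runif(n) >= model@occlusion
        q <- applyTransform(model@frame, p[kept, , drop = FALSE])
        if (model@sigma > 0)
            q <- q + matrix(rnorm(length(q), 0, model@sigma), ncol = 3L)
        perm <- sample.int(nrow(q))
        out <- q[perm, , drop = FALSE]
        rownames(out) <- NULL
        list(points = out, truth = which(kept)[perm], kept = kept)
    })
}

# --- breathing -------------------------------------------------------------

#' Apply a breathing displacement to a scene
#'
#' Internal structures (liver, spleen, vessels, tumors) are rigidly
#' translated by \code{amplitude * sin(2*pi*phase) * direction}; skin
#' fiducials move by an attenuated fraction of that vector (the stated
#' failure mode of skin-registered guidance under free breathing). The
#' applied displacement is recorded in the scene truth state and the
#' volume is re-rendered.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param amplitude peak displacement, mm (>= 0).
#' @param direction unit world vector.
#' @param phase breathing phase in [0, 1].
#' @param attenuation skin-motion attenuation factor (default 0.3).
#' @return The displaced \linkS4class{PhantomScene}.
#' @export
simulateBreathing <- function(scene, amplitude, direction = c(0, 0, 1),
                              phase = 0.25, attenuation = 0.3) {
    if (amplitude < 0) .value_error("amplitude must be >= 0")
    .check_unit(direction)
    disp <- amplitude * sin(2 * pi * phase) * direction
    if (all(disp == 0) ) return(scene)
    geom <- scene@volume@geometry
    shift_vox <- disp / geom@spacing
    body <- scene@masks$body@bits
    shift1 <- function(m) BinaryMask(.shiftMaskBits(m@bits, shift_vox) & body,
                                     geom)
    masks <- scene@masks
    masks$liver <- shift1(masks$liver)
    masks$spleen <- shift1(masks$spleen)
    masks$vessels <- shift1(masks$vessels)
    tumors <- lapply(scene@tumors, shift1)
    fid <- sweep(scene@fiducials, 2L, attenuation * disp, "+")
    centers <- sweep(scene@tumorCenters, 2L, disp, "+")
    # skin markers move with the skin: re-rasterize at displaced points
    marker_bits <- array(FALSE, geom@dim)
    for (i in seq_len(nrow(fid)))
        marker_bits <- marker_bits |
            .rasterBall(geom, fid[i, ], scene@config$markerDiameterMm / 2)
    masks$markers <- BinaryMask(marker_bits, geom)
    vol <- .renderScene(geom, masks, tumors, scene@palette,
                        scene@config$noiseSd, scene@seed)
    initialize(scene, volume = vol, masks = masks, tumors = tumors,
               tumorCenters = centers, fiducials = fid,
               displacement = scene@displacement + disp)
}

# --- ablation --------------------------------------------------------------

#' Simulate an ablation (necrosis) volume
#'
#' The necrosis is a metric ball of the given radius centered at the
#' tumor centroid plus an offset, rasterized on the tumor grid; it is the
#' post-ablation truth consumed by the confirmation stage.
#'
#' @param tumor a \linkS4class{BinaryMask}.
#' @param centerOffset mm vector added to the tumor centroid.
#' @param radius ball radius, mm (> 0).
#' @return The necrosis \linkS4class{BinaryMask}.
#' @export
simulateAblation <- function(tumor, centerOffset = c(0, 0, 0), radius) {
    if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
        radius <= 0)
        .value_error("ablation radius must be > 0")
    if (!any(tumor@bits)) .value_error("tumor mask is empty")
    ctr <- colMeans(.maskWorldPoints(tumor)) + centerOffset
    BinaryMask(.rasterBall(tumor@geometry, ctr, radius), tumor)
}
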