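# Threshold/morphology segmentation of the phantom palette: body, bone,
# liver, vessels, spleen and radiopaque markers, plus seeded
# semi-automatic tumor segmentation. This is a declared stand-in for a
# clinical segmenter: it supplies the masks the pipeline contract needs
# and is validated on phantoms only.

#' Default HU thresholds for automatic segmentation
#'
#' Assumes the phantom palette ordering air < soft < liver < vessels <
#' bone < markers.
#'
#' @param body HU above which a voxel is tissue.
#' @param liverBand HU window of liver parenchyma.
#' @param spleenBand HU window of the spleen.
#' @param vesselBand HU window of enhanced vessels.
#' @param boneBand HU window of bone.
#' @param marker HU above which a voxel is a radiopaque marker.
#' @param closingMm closing radius applied to the liver candidate, mm.
#' @return named list of thresholds.
#' @export
segThresholds <- function(body = -200, liverBand = c(55, 75),
                          spleenBand = c(47, 53), vesselBand = c(120, 600),
                          boneBand = c(600, 1200), marker = 1200,
                          closingMm = 3) {
    list(body = body, liverBand = liverBand, spleenBand = spleenBand,
         vesselBand = vesselBand, boneBand = boneBand, marker = marker,
         closingMm = closingMm)
}

.largest_component <- function(bits) {
    lab <- .labelComponents(bits)
    if (max(lab) == 0L) return(bits & FALSE)
    counts <- tabulate(lab[lab > 0L])
    lab == which.max(counts)
}

#' Automatic segmentation of a phantom CT volume
#'
#' Threshold + connected-component + morphological cleanup: the body is
#' the largest tissue component (holes filled), the liver is the largest
#' liver-band component closed and hole-filled (so hypodense tumors and
#' enhanced vessels inside it are retained), vessels are the enhanced
#' voxels adjacent to the liver, and markers are the components above the
#' marker threshold.
#'
#' @param volume a \linkS4class{Volume} with the phantom HU palette.
#' @param thresholds list from \code{\link{segThresholds}}.
#' @return A \linkS4class{SegmentationResult}.
#' @export
segmentAuto <- function(volume, thresholds = segThresholds()) {
    th <- utils::modifyList(segThresholds(), thresholds)
    arr <- volume@intensities
    geom <- volume@geometry

    tissue <- arr > th$body
    if (!any(tissue))
        .abort("empty body mask: the volume contains no tissue",
               "arguide_segmentation_error")
    body <- .fillHoles(.largest_component(tissue))

    marker_bits <- arr >= th$marker
    bone_bits <- arr >= th$boneBand[1L] & arr < th$boneBand[2L] & body

    liver_cand <- arr >= th$liverBand[1L] & arr <= th$liverBand[2L] &
        body & !marker_bits
    liver_cand <- .largest_component(liver_cand)
    liver_mask <- BinaryMask(liver_cand, geom)
    if (th$closingMm > 0) liver_mask <- closeMetric(liver_mask, th$closingMm)
    liver_bits <- .fillHoles(liver_mask@bits) & body & !marker_bits

    vessel_bits <- arr >= th$vesselBand[1L] & arr <= th$vesselBand[2L] &
        dilateMetric(BinaryMask(liver_bits, geom), 2)@bits
    spleen_bits <- arr >= th$spleenBand[1L] & arr <= th$spleenBand[2L] & body
    spleen_bits <- .largest_component(spleen_bits)

    masks <- list(body = BinaryMask(body, geom),
                  bone = BinaryMask(bone_bits, geom),
                  liver = BinaryMask(liver_bits, geom),
                  vessels = BinaryMask(vessel_bits, geom),
                  spleen = BinaryMask(spleen_bits, geom),
                  markers = BinaryMask(marker_bits, geom))
    centroids <- markerCentroids(masks$markers, volume)
    new("SegmentationResult", masks = masks, markerCentroids = centroids)
}

#' Structure masks of a segmentation result
#' @param x a \linkS4class{SegmentationResult}.
#' @return named list of \linkS4class{BinaryMask} objects.
#' @export
segmentationMasks <- function(x) x@masks

#' Marker centroids of a segmentation result
#' @param x a \linkS4class{SegmentationResult}.
#' @return labelled N x 3 matrix of world points, mm.
#' @export
segmentationMarkers <- function(x) x@markerCentroids

setMethod("show", "SegmentationResult", function(object) {
    vols <- vapply(object@masks, maskVolumeMm3, numeric(1L))
    cat(sprintf("SegmentationResult | %d marker centroids\n",
                nrow(object@markerCentroids)))
    for (nm in names(vols))
        cat(sprintf("  %-8s %10.0f mm^3\n", nm, vols[nm]))
})

#' Intensity-weighted marker centroids
#'
#' One centroid per connected marker component, in world mm, with labels
#' assigned by a deterministic lexicographic spatial sort (correspondence
#' is established downstream by geometry, so labels need only be stable).
#'
#' @param markerMask marker \linkS4class{BinaryMask}.
#' @param volume the source \linkS4class{Volume} (intensity weights).
#' @return labelled N x 3 matrix, mm.
#' @export
markerCentroids <- function(markerMask, volume) {
    lab <- .labelComponents(markerMask@bits)
    ncomp <- max(lab)
    if (ncomp < 3L)
        .abort(sprintf("insufficient fiducials: %d marker component(s), need >= 3",
                       ncomp),
               "arguide_insufficient_fiducials_error")
    idx <- which(lab > 0L, arr.ind = TRUE)
    labs <- lab[lab > 0L]
    w <- pmax(volume@intensities[lab > 0L], 0)
    pts <- worldFromVoxel(volume, idx - 1)
    cents <- t(vapply(seq_len(ncomp), function(k) {
        sel <- labs == k
        wk <- w[sel]
        if (sum(wk) == 0) wk <- rep(1, sum(sel))
        colSums(pts[sel, , drop = FALSE] * wk) / sum(wk)
    }, numeric(3L)))
    ord <- order(round(cents[, 1L], 6), round(cents[, 2L], 6),
                 round(cents[, 3L], 6))
    cents <- cents[ord, , drop = FALSE]
    rownames(cents) <- sprintf("M%02d", seq_len(nrow(cents)))
    cents
}

#' Seeded semi-automatic tumor segmentation
#'
#' Region growing from a seed point, constrained to voxels whose HU lies
#' within \code{band} of the seed HU and within \code{maxRadius} of the
#' seed; the single connected component containing the seed is kept and
#' morphologically closed. A \code{degenerate} attribute flags growths
#' that stayed at (essentially) the seed voxel or flooded the whole
#' search ball, both signs of missing contrast.
#'
#' @param volume a \linkS4class{Volume}.
#' @param seedWorld seed point, world mm (must lie inside the body).
#' @param band HU tolerance around the seed intensity.
#' @param maxRadius growth limit, mm.
#' @param closingMm closing radius, mm.
#' @param bodyMask optional body \linkS4class{BinaryMask} used for the
#'   seed-location check (computed by thresholding when absent).
#' @return A \linkS4class{BinaryMask} with a logical \code{degenerate}
#'   attribute.
#' @export
segmentTumorSeeded <- function(volume, seedWorld, band = 15, maxRadius = 25,
                               closingMm = 1.5, bodyMask = NULL) {
    geom <- volume@geometry
    seed_idx <- round(voxelFromWorld(geom, seedWorld))
    if (!insideGrid(geom, seed_idx))
        .value_error("seed point lies outside the volume")
    si <- as.integer(seed_idx) + 1L
    if (is.null(bodyMask)) {
        inside_body <- volume@intensities[si[1L], si[2L], si[3L]] > -200
    } else {
        inside_body <- bodyMask@bits[si[1L], si[2L], si[3L]]
    }
    if (!inside_body) .value_error("seed point lies outside the body")

    seed_hu <- volume@intensities[si[1L], si[2L], si[3L]]
    cc <- .axisCoords(geom)
    d2 <- outer(outer((cc$x - seedWorld[1L])^2, (cc$y - seedWorld[2L])^2, "+"),
                (cc$z - seedWorld[3L])^2, "+")
    eligible <- abs(volume@intensities - seed_hu) <= band & d2 <= maxRadius^2
    lab <- .labelComponents(eligible)
    comp <- lab == lab[si[1L], si[2L], si[3L]]
    mask <- BinaryMask(comp, geom)
    if (closingMm > 0) {
        mask <- closeMetric(mask, closingMm)
        mask <- BinaryMask(mask@bits & d2 <= maxRadius^2, geom)
    }
    ball_n <- sum(d2 <= maxRadius^2)
    degenerate <- sum(comp) <= 7L || sum(mask@bits) >= 0.95 * ball_n
    attr(mask, "degenerate") <- degenerate
    mask
}
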