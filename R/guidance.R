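# Trajectory planning, needle pose from the five-marker clip, blue/green
# alignment logic, depth readout and the tip-to-target accuracy metric.

#' Guidance configuration defaults
#'
#' @param tauAngDeg angular alignment threshold, degrees.
#' @param tauLatMm lateral alignment threshold, mm.
#' @param overshootMm recommended tip overshoot beyond the deep tumor
#'   margin, mm (midpoint of the 5-7 mm window).
#' @param freCeilingMm matching / clip-fit FRE acceptance ceiling, mm.
#' @param matchTolMm distance-signature tolerance for marker matching, mm.
#' @param minClearanceMm minimum path clearance from forbidden masks, mm.
#' @param maxCandidates cap on skin entry candidates (deterministic
#'   striding).
#' @param nFrames tracker frames averaged per pose readout.
#' @return named list of settings.
#' @export
guidanceConfig <- function(tauAngDeg = 1.0, tauLatMm = 2.0, overshootMm = 6,
                           freCeilingMm = 5, matchTolMm = 2,
                           minClearanceMm = 2, maxCandidates = 5000L,
                           nFrames = 3L) {
    list(tauAngDeg = tauAngDeg, tauLatMm = tauLatMm, overshootMm = overshootMm,
         freCeilingMm = freCeilingMm, matchTolMm = matchTolMm,
         minClearanceMm = minClearanceMm,
         maxCandidates = as.integer(maxCandidates),
         nFrames = as.integer(nFrames))
}

#' Plan a skin-to-target needle trajectory
#'
#' Entry candidates are the body-surface voxel centers (subsampled
#' deterministically to at most \code{maxCandidates}); a candidate is
#' feasible when the segment from entry to target keeps at least
#' \code{minClearance} mm distance from every forbidden mask and is no
#' longer than \code{maxPathLength}. Among feasible entries the shortest
#' path wins; ties break by lexicographic spatial sort.
#'
#' @param body body \linkS4class{BinaryMask} (skin = its surface).
#' @param target target center, world mm.
#' @param forbidden list of \linkS4class{BinaryMask} obstacles.
#' @param minClearance minimum obstacle clearance, mm.
#' @param maxPathLength maximum skin-to-target length, mm.
#' @param maxCandidates entry-candidate cap.
#' @param liver optional liver \linkS4class{BinaryMask}; when supplied the
#'   target is required to lie inside it.
#' @return A \linkS4class{TrajectoryPlan}.
#' @export
planTrajectory <- function(body, target, forbidden = list(),
                           minClearance = 2, maxPathLength = Inf,
                           maxCandidates = 5000L, liver = NULL) {
    geom <- gridGeometry(body)
    if (!is.null(liver)) {
        ti <- round(voxelFromWorld(liver, target))
        inside <- insideGrid(liver, ti) &&
            liver@bits[ti[1L] + 1L, ti[2L] + 1L, ti[3L] + 1L]
        if (!inside)
            .value_error("target center must lie inside the liver mask")
    }
    surf <- .maskSurfaceBits(body@bits)
    if (!any(surf))
        .abort("planning failure: empty skin surface",
               "arguide_planning_error")
    sidx <- which(surf, arr.ind = TRUE) - 1
    entries <- worldFromVoxel(geom, sidx)
    if (nrow(entries) > maxCandidates) {
        stride <- ceiling(nrow(entries) / maxCandidates)
        entries <- entries[seq(1L, nrow(entries), by = stride), , drop = FALSE]
    }
    depths <- .row_norms(sweep(entries, 2L, target, "-"))

    dist_maps <- lapply(forbidden, distanceTransform)
    clearance_of <- function(entry, depth) {
        if (!length(dist_maps)) return(Inf)
        ds <- min(geom@spacing) / 2
        nstep <- max(2L, ceiling(depth / ds) + 1L)
        t_ <- seq(0, 1, length.out = nstep)
        pts <- outer(t_, target - entry) + matrix(entry, nstep, 3L,
                                                  byrow = TRUE)
        idx <- round(voxelFromWorld(geom, pts))
        ok <- insideGrid(geom, idx)
        cmin <- Inf
        if (any(ok)) {
            lin <- 1L + idx[ok, 1L] + geom@dim[1L] *
                (idx[ok, 2L] + geom@dim[2L] * idx[ok, 3L])
            for (dm in dist_maps) cmin <- min(cmin, dm[lin])
        }
        cmin
    }

    ord <- order(depths, round(entries[, 1L], 6), round(entries[, 2L], 6),
                 round(entries[, 3L], 6))
    n_blocked <- 0L; n_long <- 0L
    for (i in ord) {
        if (depths[i] > maxPathLength) { n_long <- n_long + 1L; next }
        cl <- clearance_of(entries[i, ], depths[i])
        if (cl < minClearance) { n_blocked <- n_blocked + 1L; next }
        d <- target - entries[i, ]
        return(new("TrajectoryPlan", entry = entries[i, ], target = as.numeric(target),
                   direction = as.numeric(d / depths[i]), depth = depths[i],
                   clearance = cl))
    }
    binding <- if (n_blocked >= n_long) {
        sprintf("clearance >= %.1f mm (blocked %d candidates)", minClearance,
                n_blocked)
    } else {
        sprintf("path length <= %.1f mm (rejected %d candidates)",
                maxPathLength, n_long)
    }
    .abort(paste0("planning failure: no feasible entry; binding constraint: ",
                  binding),
           "arguide_planning_error")
}

setMethod("show", "TrajectoryPlan", function(object) {
    cat(sprintf(
        "TrajectoryPlan | depth %.1f mm | entry (%s) -> target (%s) | clearance %s mm\n",
        object@depth, paste(signif(object@entry, 4), collapse = ", "),
        paste(signif(object@target, 4), collapse = ", "),
        if (is.finite(object@clearance)) sprintf("%.1f", object@clearance)
        else "unconstrained"))
})

#' Needle pose from observed clip markers
#'
#' Rigidly fits the clip model to the observed marker positions (tracker
#' frame), establishing correspondence by distance signatures when the
#' observations are unlabelled, then maps tip and shaft axis into the
#' world frame.
#'
#' @param observed K x 3 observed clip marker positions in the tracker
#'   frame, mm (K >= 3). Rows named with clip labels skip the matching
#'   step.
#' @param clip a \linkS4class{ClipModel}.
#' @param worldToTracker \linkS4class{RigidTransform} from world to
#'   tracker frame (from fiducial registration).
#' @param freCeiling tracking-lost ceiling on the clip-fit FRE, mm.
#' @return A \linkS4class{NeedlePose} in the world frame.
#' @export
needlePose <- function(observed, clip, worldToTracker = identityTransform(),
                       freCeiling = 5) {
    obs <- .as_points(observed, "observed clip markers")
    if (nrow(obs) < 3L)
        .abort("needle pose needs at least 3 observed clip markers",
               "arguide_tracking_error")
    model <- clip@markers
    if (!is.null(rownames(obs)) && all(rownames(obs) %in% rownames(model))) {
        pairs <- cbind(match(rownames(obs), rownames(model)), seq_len(nrow(obs)))
        fit <- fitRigid(model[pairs[, 1L], , drop = FALSE], obs, pairs)
    } else if (nrow(obs) >= 4L) {
        m <- matchConstellation(obs, model, tol = 2, freCeiling = freCeiling)
        # m maps observed -> clip frame; invert to clip -> tracker
        fit <- fitRigid(model[m@correspondence[, 2L], , drop = FALSE],
                        obs[m@correspondence[, 1L], , drop = FALSE])
    } else {
        .abort("unlabelled clip observations need at least 4 markers",
               "arguide_tracking_error")
    }
    if (fit@fre > freCeiling)
        .abort(sprintf("tracking lost: clip fit FRE %.2f mm exceeds %.2f mm",
                       fit@fre, freCeiling),
               "arguide_tracking_error")
    trackerToWorld <- invertTransform(worldToTracker)
    clipToWorld <- composeTransforms(trackerToWorld, fit@transform)
    tip <- as.numeric(applyTransform(clipToWorld, clip@tipOffset))
    axis <- as.numeric(rotateVector(clipToWorld, clip@axis))
    new("NeedlePose", tip = tip, axis = .unit(axis), fre = fit@fre)
}

setMethod("show", "NeedlePose", function(object) {
    cat(sprintf("NeedlePose | tip (%s) mm | clip FRE %.3f mm\n",
                paste(signif(object@tip, 4), collapse = ", "), object@fre))
})

#' Blue/green alignment status of a tracked needle against a plan
#'
#' Green (aligned) iff the angular deviation between needle axis and the
#' planned direction is at most \code{tauAng} degrees AND the target
#' center lies within \code{tauLat} mm of the infinite needle line; both
#' boundaries inclusive.
#'
#' @param pose a \linkS4class{NeedlePose}.
#' @param plan a \linkS4class{TrajectoryPlan}.
#' @param tauAng angular threshold, degrees.
#' @param tauLat lateral threshold, mm.
#' @return An \linkS4class{AlignmentStatus}.
#' @export
alignmentStatus <- function(pose, plan, tauAng = 1.0, tauLat = 2.0) {
    ang <- acos(.clamp(sum(pose@axis * plan@direction), -1, 1)) * 180 / pi
    v <- plan@target - pose@tip
    along <- sum(v * pose@axis)
    lateral <- sqrt(max(sum(v^2) - along^2, 0))
    new("AlignmentStatus", aligned = (ang <= tauAng) && (lateral <= tauLat),
        angleDeg = ang, lateralMm = lateral, remainingMm = along,
        tauAng = tauAng, tauLat = tauLat)
}

setMethod("show", "AlignmentStatus", function(object) {
    cat(sprintf(
        "AlignmentStatus | %s | deviation %.2f deg (tau %.2f) | lateral %.2f mm (tau %.2f) | remaining %.1f mm\n",
        if (object@aligned) "GREEN (aligned)" else "BLUE (not aligned)",
        object@angleDeg, object@tauAng, object@lateralMm, object@tauLat,
        object@remainingMm))
})

#' Real-time depth readout
#'
#' @param plan a \linkS4class{TrajectoryPlan}.
#' @param pose a \linkS4class{NeedlePose}.
#' @return list with \code{depth} (skin to target center, mm) and
#'   \code{remaining} (projection of tip-to-target on the needle axis,
#'   mm; negative means the tip is past the target center).
#' @export
insertionDepth <- function(plan, pose) {
    list(depth = plan@depth,
         remaining = sum((plan@target - pose@tip) * pose@axis))
}

#' Tip-to-target distance
#'
#' Euclidean distance in mm between the device tip and the geometric
#' target center, the deployment-accuracy endpoint (presented to 0.1 mm
#' by the reporting layer).
#'
#' @param tip device tip, world mm.
#' @param target target center, world mm.
#' @return distance, mm.
#' @export
tipToTarget <- function(tip, target) {
    if (!.is_num3(as.numeric(tip)) || !.is_num3(as.numeric(target)))
        .value_error("tip and target must be finite length-3 points")
    sqrt(sum((as.numeric(tip) - as.numeric(target))^2))
}
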