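# End-to-end simulated AR-guided session: segmentation -> fiducial
# co-registration -> trajectory planning -> tracked insertion -> tip
# placement -> simulated ablation and confirmation, with per-target
# tip-to-target distances and a full truth log for auditing.

.run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
        .abort(sprintf("stage '%s': %s", stage, conditionMessage(e)),
               "arguide_stage_error")
    })
}

#' Precompute the scene-dependent session stages
#'
#' Segmentation and trajectory planning depend only on the scene, so a
#' Monte-Carlo study over tracker noise can share them across sessions.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param config list from \code{\link{guidanceConfig}}.
#' @param useTruthMasks plan on the truth masks instead of running the
#'   segmenter (faster; used by property studies that are not about
#'   segmentation).
#' @return list with the segmentation, CT marker centroids, per-tumor
#'   plans and per-tumor target estimates.
#' @export
prepareSession <- function(scene, config = guidanceConfig(),
                           useTruthMasks = FALSE) {
    if (length(scene@tumors) < 1L)
        .value_error("the scene must contain at least one tumor")
    if (useTruthMasks) {
        masks <- scene@masks
        ct_markers <- scene@fiducials
        targets <- scene@tumorCenters
    } else {
        seg <- .run_stage("segmentation", segmentAuto(scene@volume))
        masks <- seg@masks
        ct_markers <- seg@markerCentroids
        targets <- t(vapply(scene@tumors, function(tm) {
            m <- .run_stage("segmentation", segmentTumorSeeded(
                scene@volume,
                colMeans(.maskWorldPoints(tm)),
                bodyMask = masks$body))
            colMeans(.maskWorldPoints(m))
        }, numeric(3L)))
    }
    plans <- lapply(seq_len(nrow(targets)), function(i) {
        .run_stage("planning", planTrajectory(
            masks$body, targets[i, ],
            forbidden = list(masks$bone),
            minClearance = config$minClearanceMm,
            maxCandidates = config$maxCandidates))
    })
    list(masks = masks, ctMarkers = ct_markers, targets = targets,
         plans = plans)
}

#' Simulate one AR-guided targeting session
#'
#' Runs the full pipeline on a phantom scene with a noisy marker tracker:
#' the skin constellation is observed and matched against the
#' CT-segmented markers to estimate the world-to-tracker transform; for
#' each tumor the operator is modelled as converging the tracked
#' (estimated) needle tip onto the displayed target, so the true tip
#' inherits the stacked registration and clip-tracking errors; the
#' resulting tip-to-target distance, a simulated ablation and its margin
#' assessment are recorded.
#'
#' @param scene a \linkS4class{PhantomScene} with at least one tumor.
#' @param model an \linkS4class{ObservationModel} for the tracker.
#' @param config list from \code{\link{guidanceConfig}}.
#' @param seed integer seed for this session's observations.
#' @param prepared optional result of \code{\link{prepareSession}}.
#' @param patientId id recorded in the session rows.
#' @param withAblation also simulate the ablation and margin assessment.
#' @return list with \code{records} (one data.frame row per target:
#'   patient, target, size_cm, distance_mm, time_min, modality, and when
#'   ablation is simulated margin residual and flags) and \code{truth}
#'   (registration result, per-target poses, alignment, truth errors).
#' @export
simulateSession <- function(scene, model = observationModel(),
                            config = guidanceConfig(), seed = 1L,
                            prepared = NULL, patientId = 1L,
                            withAblation = TRUE) {
    if (is.null(prepared)) prepared <- prepareSession(scene, config)
    clip <- makeClipModel()

    .with_seed(seed, {
        obs <- .run_stage("observation",
                          observeMarkers(scene@fiducials, model, seed = NULL))
        reg <- .run_stage("registration", matchConstellation(
            obs$points, Constellation(prepared$ctMarkers),
            tol = config$matchTolMm, freCeiling = config$freCeilingMm))
        # matchConstellation maps observed (tracker) -> CT world; the
        # guidance display needs world -> tracker
        worldToTracker <- invertTransform(reg@transform)
        truthWorldToTracker <- model@frame

        records <- NULL
        truths <- list()
        for (i in seq_along(prepared$plans)) {
            plan <- prepared$plans[[i]]
            target_est <- prepared$targets[i, ]
            true_center <- scene@tumorCenters[i, ]

            # displayed target in the tracker frame, and where a needle
            # whose ESTIMATED tip sits there truly ends up
            target_tracker <- as.numeric(applyTransform(worldToTracker,
                                                        target_est))
            nominal_tip <- as.numeric(applyTransform(
                invertTransform(truthWorldToTracker), target_tracker))

            # clip-tracking error at the nominal pose, averaged over
            # nFrames tracker frames
            Rclip <- .rotation_between(clip@axis, plan@direction)
            clip_world <- rigidTransform(
                Rclip, nominal_tip - as.vector(Rclip %*% clip@tipOffset))
            markers_world <- applyTransform(clip_world, clip@markers)
            tips_est <- matrix(0, config$nFrames, 3L)
            pose <- NULL
            for (f in seq_len(config$nFrames)) {
                obs_clip <- observeMarkers(markers_world, model, seed = NULL)
                # the tracker maintains clip marker identity across frames
                pts <- obs_clip$points
                rownames(pts) <- rownames(clip@markers)[obs_clip$truth]
                pose <- .run_stage("tracking", needlePose(
                    pts, clip, worldToTracker,
                    freCeiling = config$freCeilingMm))
                tips_est[f, ] <- pose@tip
            }
            tip_est <- colMeans(tips_est)
            # operator converges the estimated tip onto the displayed
            # target: shift the true needle by the residual
            tip_true <- nominal_tip - (tip_est - target_est)

            dist_mm <- tipToTarget(tip_true, true_center)
            align <- alignmentStatus(pose, plan, config$tauAngDeg,
                                     config$tauLatMm)
            time_min <- max(3.2, min(5.7, rnorm(1L, 4.3, 0.9)))
            modality <- if (runif(1L) < 7 / 15) "US" else "CT"

            row <- data.frame(patient = patientId, target = i,
                              size_cm = scene@tumorDiameters[i] / 10,
                              distance_mm = dist_mm, time_min = time_min,
                              modality = modality,
                              stringsAsFactors = FALSE)
            if (withAblation) {
                tumor <- scene@tumors[[i]]
                r_abl <- scene@tumorDiameters[i] / 2 + 5 + 1
                necrosis <- simulateAblation(
                    tumor, centerOffset = tip_true - true_center,
                    radius = r_abl)
                assess <- .run_stage("confirmation", assessAblation(
                    tumor, necrosis, identityTransform(), margin = 5,
                    liver = scene@masks$liver))
                row$margin_residual_pct <- assess@marginResidualPct
                row$complete_ablation <- assess@completeAblation
                row$margin_success <- assess@marginSuccess
                row$technical_success <- assess@technicalSuccess
            }
            records <- rbind(records, row)
            truths[[i]] <- list(plan = plan, pose = pose, alignment = align,
                                tip_true = tip_true, tip_est = tip_est,
                                target_est = target_est,
                                true_center = true_center)
        }
        list(records = records,
             truth = list(registration = reg,
                          observedMarkers = obs,
                          worldToTracker = worldToTracker,
                          targets = truths))
    })
}

# Proper rotation taking unit vector a to unit vector b (roll fixed by a
# deterministic auxiliary axis).
.rotation_between <- function(a, b, aux = NULL) {
    a <- .unit(a); b <- .unit(b)
    v <- c(a[2L] * b[3L] - a[3L] * b[2L],
           a[3L] * b[1L] - a[1L] * b[3L],
           a[1L] * b[2L] - a[2L] * b[1L])
    s <- sqrt(sum(v^2)); c_ <- sum(a * b)
    if (s < 1e-12) {
        if (c_ > 0) return(diag(3))
        # 180 degrees: rotate about any axis orthogonal to a
        if (is.null(aux) || abs(sum(aux * a)) > 0.99)
            aux <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        w <- .unit(aux - sum(aux * a) * a)
        return(2 * outer(w, w) - diag(3))
    }
    K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - c_) / s^2)
}
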