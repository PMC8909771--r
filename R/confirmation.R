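# Post-procedure confirmation: rigid pre/post co-registration by mask
# overlap, periablational margin-shell construction, tumor-coverage and
# residual-margin quantification, and the technical-success rule
# (complete ablation AND > 90 percent of the 5-mm margin ablated).

# Dice of a pre-frame mask mapped into the post frame by T (pre -> post),
# evaluated by nearest-neighbour lookup of post foreground points in the
# pre frame.
.mask_dice_under <- function(transform, pre, post, post_pts, n_post) {
    inv <- invertTransform(transform)
    src <- applyTransform(inv, post_pts)
    idx <- round(voxelFromWorld(pre, src))
    ok <- insideGrid(pre, idx)
    overlap <- 0L
    if (any(ok)) {
        g <- gridGeometry(pre)
        lin <- 1L + idx[ok, 1L] + g@dim[1L] * (idx[ok, 2L] + g@dim[2L] * idx[ok, 3L])
        overlap <- sum(pre@bits[lin])
    }
    2 * overlap / (sum(pre@bits) + n_post)
}

.euler_zyx <- function(a) {
    # small-angle parameterization used by the local refinement
    composeTransforms(axisRotation("z", a[3L]),
        composeTransforms(axisRotation("y", a[2L]), axisRotation("x", a[1L])))@rotation
}

#' Rigidly co-register a pre-ablation mask onto a post-ablation mask
#'
#' Initializes with centroid + principal-axes alignment (trying the four
#' proper sign combinations) and refines translation and rotation by a
#' deterministic coordinate-descent search that maximizes the Dice
#' overlap under nearest-neighbour resampling. Returns the transform
#' mapping pre-frame points into the post frame; the achieved Dice is
#' attached as the \code{"dice"} attribute.
#'
#' @param pre,post nonempty \linkS4class{BinaryMask} objects (typically
#'   liver masks of the pre- and post-ablation scans).
#' @param refine run the local Dice refinement (default TRUE).
#' @param minDice registration-failure threshold on the final Dice.
#' @return A \linkS4class{RigidTransform} (pre to post) with attribute
#'   \code{dice}.
#' @export
registerPrePost <- function(pre, post, refine = TRUE, minDice = 0.5) {
    if (!any(pre@bits) || !any(post@bits))
        .value_error("pre and post masks must be nonempty")
    P <- .maskWorldPoints(pre)
    Q <- .maskWorldPoints(post)
    pc <- colMeans(P); qc <- colMeans(Q)
    covP <- stats::cov(P); covQ <- stats::cov(Q)
    EP <- eigen(covP, symmetric = TRUE)$vectors
    EQ <- eigen(covQ, symmetric = TRUE)$vectors
    if (det(EP) < 0) EP[, 3L] <- -EP[, 3L]
    if (det(EQ) < 0) EQ[, 3L] <- -EQ[, 3L]

    n_post <- nrow(Q)
    # subsample post points for the overlap objective (deterministic)
    if (nrow(Q) > 40000L) {
        stride <- ceiling(nrow(Q) / 40000L)
        Qs <- Q[seq(1L, nrow(Q), by = stride), , drop = FALSE]
    } else Qs <- Q
    score <- function(tr) .mask_dice_under(tr, pre, post, Qs,
                                           as.numeric(n_post) * nrow(Qs) / nrow(Q))

    signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    best <- NULL; best_dice <- -Inf
    for (s in signs) {
        R <- EQ %*% diag(s) %*% t(EP)
        tr <- rigidTransform(R, qc - as.vector(R %*% pc))
        d <- score(tr)
        if (d > best_dice) { best <- tr; best_dice <- d }
    }

    if (refine) {
        # parameters: rotation offsets (deg, about the post centroid) and
        # translation offsets (mm) applied on top of the initialization
        par <- rep(0, 6L)
        apply_par <- function(par) {
            dR <- .euler_zyx(par[1:3])
            R <- dR %*% best@rotation
            t0 <- qc - as.vector(dR %*% (qc - best@translation))
            rigidTransform(R, t0 + par[4:6])
        }
        cur <- score(apply_par(par))
        for (step in c(2, 1, 0.5, 0.25)) {
            improved <- TRUE
            while (improved) {
                improved <- FALSE
                for (k in seq_len(6L)) {
                    for (dir in c(-1, 1)) {
                        cand <- par
                        cand[k] <- cand[k] + dir * step
                        val <- score(apply_par(cand))
                        if (val > cur + 1e-9) {
                            par <- cand; cur <- val; improved <- TRUE
                        }
                    }
                }
            }
        }
        best <- apply_par(par)
        best_dice <- cur
    }
    final_dice <- .mask_dice_under(best, pre, post, Q, n_post)
    if (final_dice < minDice)
        .abort(sprintf(
            "pre/post registration failure: Dice %.2f below %.2f",
            final_dice, minDice),
            "arguide_registration_error")
    attr(best, "dice") <- final_dice
    best
}

#' Periablational margin shell
#'
#' The shell of tissue within \code{margin} mm of the tumor boundary:
#' metric dilation of the tumor minus the tumor itself, optionally
#' clipped to the liver (tissue outside the organ cannot be ablated).
#'
#' @param tumor tumor \linkS4class{BinaryMask} (nonempty).
#' @param margin shell thickness, mm (> 0; default 5).
#' @param liver optional liver \linkS4class{BinaryMask}.
#' @param clipToLiver clip the shell to the liver when a liver mask is
#'   given.
#' @return The shell \linkS4class{BinaryMask}.
#' @export
marginShell <- function(tumor, margin = 5, liver = NULL, clipToLiver = TRUE) {
    if (!is.numeric(margin) || length(margin) != 1L || is.na(margin) ||
        margin <= 0)
        .value_error("margin must be > 0 mm")
    if (!any(tumor@bits)) .value_error("tumor mask is empty")
    shell <- dilateMetric(tumor, margin)@bits & !tumor@bits
    if (!is.null(liver) && clipToLiver) shell <- shell & liver@bits
    BinaryMask(shell, tumor)
}

# Map a pre-frame mask onto the post grid by nearest neighbour under the
# pre -> post transform.
.resample_to_post <- function(mask, transform, post_geom) {
    inv <- invertTransform(transform)
    d <- post_geom@dim
    out <- array(FALSE, d)
    # post voxel centers, chunked by slice to bound memory
    cc <- .axisCoords(post_geom)
    for (k in seq_len(d[3L])) {
        G <- cbind(rep(cc$x, times = d[2L]), rep(cc$y, each = d[1L]), cc$z[k])
        src <- applyTransform(inv, G)
        idx <- round(voxelFromWorld(mask, src))
        ok <- insideGrid(mask, idx)
        vals <- rep(FALSE, nrow(G))
        if (any(ok)) {
            g <- gridGeometry(mask)
            lin <- 1L + idx[ok, 1L] + g@dim[1L] *
                (idx[ok, 2L] + g@dim[2L] * idx[ok, 3L])
            vals[ok] <- mask@bits[lin]
        }
        out[, , k] <- vals
    }
    BinaryMask(out, post_geom)
}

#' Quantify tumor coverage and residual margin after ablation
#'
#' Maps the pre-frame tumor and its margin shell into the post frame
#' (nearest neighbour), then reports the percentage of each outside the
#' necrosis: residual = 100 * |X \ necrosis| / |X|. Flags follow the
#' technical-success rule: complete ablation iff the tumor residual is
#' exactly 0; margin success iff the margin residual is strictly below
#' 10 percent (margin ablated > 90 percent).
#'
#' @param tumor pre-frame tumor \linkS4class{BinaryMask}.
#' @param necrosis post-frame necrosis \linkS4class{BinaryMask}.
#' @param transform \linkS4class{RigidTransform} mapping the pre frame
#'   into the post frame.
#' @param margin margin thickness, mm.
#' @param liver optional pre-frame liver mask for shell clipping.
#' @param clipToLiver clip the shell to the liver (logged in the result).
#' @return An \linkS4class{AblationAssessment}. An empty necrosis yields
#'   100 percent residuals and a warning flag.
#' @export
assessAblation <- function(tumor, necrosis, transform = identityTransform(),
                           margin = 5, liver = NULL, clipToLiver = TRUE) {
    if (!any(tumor@bits)) .value_error("tumor mask is empty")
    shell <- marginShell(tumor, margin, liver = liver,
                         clipToLiver = clipToLiver)
    post_geom <- gridGeometry(necrosis)
    same_frame <- .sameGeometry(tumor, necrosis) &&
        max(abs(transform@rotation - diag(3))) < 1e-12 &&
        max(abs(transform@translation)) < 1e-12
    if (same_frame) {
        tumor_post <- tumor
        shell_post <- shell
    } else {
        tumor_post <- .resample_to_post(tumor, transform, post_geom)
        shell_post <- .resample_to_post(shell, transform, post_geom)
    }
    n_t <- sum(tumor_post@bits)
    n_s <- sum(shell_post@bits)
    empty_necrosis <- !any(necrosis@bits)
    if (empty_necrosis) {
        warning("necrosis mask is empty; residuals reported as 100%")
        t_res <- 100
        s_res <- 100
    } else {
        t_res <- 100 * sum(tumor_post@bits & !necrosis@bits) / max(n_t, 1L)
        s_res <- if (n_s > 0)
            100 * sum(shell_post@bits & !necrosis@bits) / n_s else 0
    }
    vv <- prod(post_geom@spacing)
    flags <- ablationFlags(t_res, s_res)
    new("AblationAssessment",
        tumorResidualPct = t_res, marginResidualPct = s_res,
        completeAblation = flags$completeAblation,
        marginSuccess = flags$marginSuccess,
        technicalSuccess = flags$technicalSuccess,
        marginMm = margin,
        volumesMm3 = c(tumor = n_t * vv, necrosis = sum(necrosis@bits) * vv,
                       shell = n_s * vv),
        clippedToLiver = !is.null(liver) && clipToLiver,
        emptyNecrosis = empty_necrosis)
}

#' Success flags from residual percentages
#'
#' Pure re-derivation of the endpoint flags: complete ablation iff the
#' tumor residual is 0; margin success iff the 5-mm margin residual is
#' strictly below 10 percent (a residual of exactly 10.0 fails, since the
#' rule requires > 90 percent ablated); technical success is their
#' conjunction.
#'
#' @param tumorResidualPct percent of tumor outside the necrosis.
#' @param marginResidualPct percent of the margin shell outside the
#'   necrosis.
#' @return list with \code{completeAblation}, \code{marginSuccess},
#'   \code{technicalSuccess}.
#' @export
ablationFlags <- function(tumorResidualPct, marginResidualPct) {
    complete <- tumorResidualPct == 0
    margin_ok <- marginResidualPct < 10
    list(completeAblation = complete, marginSuccess = margin_ok,
         technicalSuccess = complete && margin_ok)
}

#' Re-derive the success flags of an assessment
#'
#' @param assessment an \linkS4class{AblationAssessment}.
#' @return list with \code{completeAblation}, \code{marginSuccess},
#'   \code{technicalSuccess}.
#' @export
technicalSuccess <- function(assessment) {
    ablationFlags(assessment@tumorResidualPct, assessment@marginResidualPct)
}

setMethod("show", "AblationAssessment", function(object) {
    cat(sprintf(
        paste0("AblationAssessment | tumor residual %.1f%% | %.0f-mm margin ",
               "residual %.1f%%\n  complete ablation: %s | margin success: %s",
               " | technical success: %s%s\n"),
        object@tumorResidualPct, object@marginMm, object@marginResidualPct,
        object@completeAblation, object@marginSuccess, object@technicalSuccess,
        if (object@emptyNecrosis) " | WARNING: empty necrosis" else ""))
})
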