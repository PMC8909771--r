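# Fiducial co-registration: distance-signature correspondence between the
# CT-segmented and tracker-observed marker constellations, closed-form
# rigid fitting (Kabsch with reflection guard), and FRE/TRE metrics.

#' Construct a Constellation
#'
#' @param points N x 3 numeric matrix of marker positions, mm; rownames
#'   are used as labels (generated when absent).
#' @return A \linkS4class{Constellation}.
#' @export
Constellation <- function(points) {
    p <- .as_points(points)
    if (is.null(rownames(p)))
        rownames(p) <- sprintf("M%02d", seq_len(nrow(p)))
    new("Constellation", points = p)
}

#' Marker coordinates of a constellation
#' @param x a \linkS4class{Constellation}.
#' @return labelled N x 3 matrix, mm.
#' @export
constellationPoints <- function(x) x@points

setMethod("show", "Constellation", function(object) {
    d <- sort(as.vector(dist(object@points)))
    cat(sprintf(
        "Constellation of %d markers | distances %.1f-%.1f mm | min multiset gap %.3f mm\n",
        nrow(object@points), min(d), max(d),
        if (length(d) > 1) min(diff(d)) else NA_real_))
})

#' Pairwise-distance signatures of a point set
#'
#' For every point, the sorted vector of distances to all other points.
#' On a non-repetitive constellation these signatures identify markers
#' even under partial occlusion.
#'
#' @param x a \linkS4class{Constellation} or N x 3 matrix.
#' @return list of sorted numeric vectors, one per point.
#' @export
distanceSignatures <- function(x) {
    p <- if (is(x, "Constellation")) x@points else .as_points(x)
    D <- as.matrix(dist(p))
    lapply(seq_len(nrow(p)), function(i) sort(D[i, -i]))
}

#' Smallest gap of the pairwise-distance multiset
#'
#' The non-repetitive-pattern figure of merit: the minimum absolute
#' difference between any two distinct pairwise distances.
#'
#' @inheritParams distanceSignatures
#' @return scalar mm.
#' @export
distanceMultisetGap <- function(x) {
    p <- if (is(x, "Constellation")) x@points else .as_points(x)
    d <- sort(as.vector(dist(p)))
    if (length(d) < 2L) return(Inf)
    min(diff(d))
}

# ---------------------------------------------------------------------------
# Rigid fitting
# ---------------------------------------------------------------------------

#' Closed-form least-squares rigid fit of corresponding point pairs
#'
#' Demeans both sets, factorizes the cross-covariance (SVD) and applies
#' the standard reflection guard: if the orthogonal factor has
#' determinant -1, the smallest singular direction is flipped so the
#' result is a proper rotation. The fitted transform maps
#' \code{source} points onto \code{target} points.
#'
#' @param source,target N x 3 matrices of corresponding points (N >= 3,
#'   non-collinear), mm.
#' @param correspondence optional two-column index matrix recorded in the
#'   result (defaults to the row pairing).
#' @return A \linkS4class{RegistrationResult} with the transform, the FRE
#'   (RMS residual, mm) and per-marker residuals.
#' @export
fitRigid <- function(source, target, correspondence = NULL) {
    p <- .as_points(source, "source")
    q <- .as_points(target, "target")
    if (nrow(p) != nrow(q)) .value_error("source and target sizes differ")
    n <- nrow(p)
    if (n < 3L) .abort("rigid fit needs at least 3 point pairs",
                       "arguide_degeneracy_error")
    pc <- colMeans(p); qc <- colMeans(q)
    X <- sweep(p, 2L, pc); Y <- sweep(q, 2L, qc)
    # collinearity check on the source spread
    sx <- svd(X)$d
    if (sx[2L] <= 1e-9 * max(sx[1L], 1))
        .abort("degenerate (collinear) fiducial configuration",
               "arguide_degeneracy_error")
    H <- crossprod(X, Y)
    sv <- svd(H)
    S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% S %*% t(sv$u)
    t_ <- qc - as.vector(R %*% pc)
    tr <- rigidTransform(R, t_)
    res <- .row_norms(applyTransform(tr, p) - q)
    if (is.null(correspondence))
        correspondence <- cbind(seq_len(n), seq_len(n))
    new("RegistrationResult", transform = tr,
        correspondence = matrix(as.integer(correspondence), ncol = 2L),
        fre = sqrt(mean(res^2)), residuals = res)
}

#' Fiducial registration error of a fit
#' @param result a \linkS4class{RegistrationResult}.
#' @return FRE in mm.
#' @export
registrationFRE <- function(result) result@fre

#' Fitted transform of a registration result
#' @inheritParams registrationFRE
#' @return A \linkS4class{RigidTransform}.
#' @export
registrationTransform <- function(result) result@transform

#' Correspondence index pairs of a registration result
#' @inheritParams registrationFRE
#' @return two-column integer matrix (source index, target index).
#' @export
registrationCorrespondence <- function(result) result@correspondence

setMethod("show", "RegistrationResult", function(object) {
    cat(sprintf("RegistrationResult | %d pairs | FRE %.3f mm (max residual %.3f mm)\n",
                nrow(object@correspondence), object@fre,
                if (length(object@residuals)) max(object@residuals) else NA_real_))
})

#' Target registration error against a known truth transform
#'
#' TRE(target) = || estimated(target) - truth(target) ||; only available
#' in simulation where the generating transform is known.
#'
#' @param result a \linkS4class{RegistrationResult} (or a
#'   \linkS4class{RigidTransform}).
#' @param truth the generating \linkS4class{RigidTransform}.
#' @param targets N x 3 matrix of target points in the source frame, mm.
#' @return numeric vector of per-target TRE, mm.
#' @export
targetRegistrationError <- function(result, truth, targets) {
    est <- if (is(result, "RegistrationResult")) result@transform else result
    .row_norms(applyTransform(est, targets) - applyTransform(truth, targets))
}

# ---------------------------------------------------------------------------
# Correspondence by pairwise-distance signatures
# ---------------------------------------------------------------------------

# Count how many of the sorted distances `a` find a partner in the sorted
# distances `b` within tol.
.signature_hits <- function(a, b, tol) {
    if (length(b) == 0L) return(0L)
    idx <- findInterval(a, b)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(b))
    sum(pmin(abs(a - b[lo]), abs(a - b[hi])) <= tol)
}

#' Match an observed point set against a reference constellation
#'
#' Candidate identities are ranked by pairwise-distance-signature
#' compatibility within \code{tol}; a mutually distance-consistent seed
#' assignment is grown greedily, verified by a rigid fit, and refined by
#' one nearest-neighbour reassignment pass. Works with occluded markers
#' (observed may be any subset of the reference of size >= 4).
#'
#' @param observed M x 3 matrix of observed (unlabelled) points, mm.
#' @param reference a \linkS4class{Constellation} (or N x 3 matrix).
#' @param tol distance-compatibility tolerance, mm.
#' @param freCeiling accept a hypothesis only if its FRE is below this
#'   ceiling, mm.
#' @param maxHypotheses number of alternative seeds tried before the
#'   matcher gives up.
#' @return A \linkS4class{RegistrationResult}; correspondence rows are
#'   (observed index, reference index) and the transform maps observed
#'   points into the reference frame.
#' @export
matchConstellation <- function(observed, reference, tol = 2,
                               freCeiling = 5, maxHypotheses = 12L) {
    obs <- .as_points(observed, "observed")
    ref <- if (is(reference, "Constellation")) reference@points
           else .as_points(reference, "reference")
    m <- nrow(obs); n <- nrow(ref)
    if (m < 4L) .abort("constellation matching needs at least 4 observed points",
                       "arguide_matching_error")
    Dobs <- as.matrix(dist(obs))
    Dref <- as.matrix(dist(ref))
    sig_obs <- lapply(seq_len(m), function(i) sort(Dobs[i, -i]))
    sig_ref <- lapply(seq_len(n), function(j) sort(Dref[j, -j]))
    S <- matrix(0L, m, n)
    for (i in seq_len(m))
        for (j in seq_len(n))
            S[i, j] <- .signature_hits(sig_obs[[i]], sig_ref[[j]], tol)

    ord <- order(-as.vector(S))
    seeds <- head(ord, max(maxHypotheses, 1L))
    best <- NULL
    for (seed in seeds) {
        si <- (seed - 1L) %% m + 1L
        sj <- (seed - 1L) %/% m + 1L
        assign <- .grow_assignment(si, sj, S, Dobs, Dref, tol)
        if (nrow(assign) < 3L) next
        fit0 <- tryCatch(
            fitRigid(obs[assign[, 1L], , drop = FALSE],
                     ref[assign[, 2L], , drop = FALSE], assign),
            error = function(e) NULL)
        if (is.null(fit0)) next
        fit <- .refine_assignment(obs, ref, fit0, freCeiling)
        if (is.null(fit) || fit@fre > freCeiling) next
        # prefer the hypothesis explaining the most markers; FRE breaks ties
        if (is.null(best) ||
            nrow(fit@correspondence) > nrow(best@correspondence) ||
            (nrow(fit@correspondence) == nrow(best@correspondence) &&
             fit@fre < best@fre)) best <- fit
        if (!is.null(best) && best@fre < 0.25 * freCeiling &&
            nrow(best@correspondence) == m) break
    }
    if (is.null(best) || best@fre > freCeiling)
        .abort(sprintf(
            "no marker correspondence with FRE below the %.1f mm ceiling", freCeiling),
            "arguide_matching_error")
    best
}

# Greedy growth of a mutually distance-consistent assignment from a seed
# pair, adding at each step the highest-scoring consistent candidate.
.grow_assignment <- function(si, sj, S, Dobs, Dref, tol) {
    m <- nrow(S); n <- ncol(S)
    used_i <- rep(FALSE, m); used_j <- rep(FALSE, n)
    ai <- si; aj <- sj
    used_i[si] <- TRUE; used_j[sj] <- TRUE
    repeat {
        cand_best <- NULL; cand_score <- -1L
        for (i in which(!used_i)) {
            for (j in which(!used_j)) {
                if (S[i, j] <= cand_score) next
                if (all(abs(Dobs[i, ai] - Dref[j, aj]) <= tol)) {
                    cand_best <- c(i, j); cand_score <- S[i, j]
                }
            }
        }
        if (is.null(cand_best)) break
        ai <- c(ai, cand_best[1L]); aj <- c(aj, cand_best[2L])
        used_i[cand_best[1L]] <- TRUE; used_j[cand_best[2L]] <- TRUE
    }
    cbind(ai, aj, deparse.level = 0)
}

# One nearest-neighbour reassignment pass under the current fit, then a
# refit; returns NULL when the refined fit degenerates.
.refine_assignment <- function(obs, ref, fit, freCeiling) {
    mapped <- applyTransform(fit@transform, obs)
    m <- nrow(obs); n <- nrow(ref)
    D <- matrix(0, m, n)
    for (j in seq_len(n))
        D[, j] <- .row_norms(sweep(mapped, 2L, ref[j, ], "-"))
    # greedy injective nearest-neighbour assignment
    assign <- matrix(0L, 0L, 2L)
    Dwork <- D
    gate <- max(3 * freCeiling, 10)
    repeat {
        k <- which.min(Dwork)
        if (!length(k) || !is.finite(Dwork[k]) || Dwork[k] > gate) break
        i <- (k - 1L) %% m + 1L
        j <- (k - 1L) %/% m + 1L
        assign <- rbind(assign, c(i, j))
        Dwork[i, ] <- Inf; Dwork[, j] <- Inf
        if (nrow(assign) == min(m, n)) break
    }
    if (nrow(assign) < 3L) return(NULL)
    tryCatch(
        fitRigid(obs[assign[, 1L], , drop = FALSE],
                 ref[assign[, 2L], , drop = FALSE], assign),
        error = function(e) NULL)
}

#' Exhaustive correspondence search (audit oracle for small sets)
#'
#' Minimizes the FRE over every injective mapping of the observed points
#' into the reference; factorially expensive, so it is restricted to
#' small constellations and serves as an independent check of
#' \code{\link{matchConstellation}}.
#'
#' @inheritParams matchConstellation
#' @param maxPoints guard on the reference size (default 8).
#' @return A \linkS4class{RegistrationResult}.
#' @export
matchExhaustive <- function(observed, reference, maxPoints = 8L) {
    obs <- .as_points(observed, "observed")
    ref <- if (is(reference, "Constellation")) reference@points
           else .as_points(reference, "reference")
    m <- nrow(obs); n <- nrow(ref)
    if (n > maxPoints)
        .value_error("matchExhaustive is an oracle for small sets only")
    if (m < 3L) .abort("need at least 3 observed points",
                       "arguide_matching_error")
    best <- NULL
    perm_rec <- function(chosen, remaining) {
        if (length(chosen) == m) {
            fit <- tryCatch(
                fitRigid(obs, ref[chosen, , drop = FALSE],
                         cbind(seq_len(m), chosen)),
                error = function(e) NULL)
            if (!is.null(fit) && (is.null(best) || fit@fre < best@fre))
                best <<- fit
            return(invisible(NULL))
        }
        for (j in remaining)
            perm_rec(c(chosen, j), setdiff(remaining, j))
        invisible(NULL)
    }
    perm_rec(integer(0), seq_len(n))
    if (is.null(best)) .abort("no valid correspondence found",
                              "arguide_matching_error")
    best
}
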