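# Rigid transforms: construction, application, composition, inversion,
# and JSON serialization.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 vector, mm.
#' @return A \linkS4class{RigidTransform} mapping x to rotation %*% x +
#'   translation.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
    new("RigidTransform", rotation = rotation,
        translation = as.numeric(translation))
}

#' Identity rigid transform
#' @return A \linkS4class{RigidTransform}.
#' @export
identityTransform <- function() rigidTransform()

#' Rotation about a coordinate axis
#'
#' @param axis "x", "y" or "z".
#' @param angleDeg rotation angle in degrees (right-handed).
#' @param translation optional translation, mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
axisRotation <- function(axis = c("x", "y", "z"), angleDeg,
                         translation = c(0, 0, 0)) {
    axis <- match.arg(axis)
    a <- angleDeg * pi / 180
    c_ <- cos(a); s_ <- sin(a)
    R <- switch(axis,
        x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
        y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
        z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
    rigidTransform(R, translation)
}

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param points N x 3 matrix (or length-3 vector) of world points, mm.
#' @return transformed points, same shape as input rows.
#' @export
applyTransform <- function(transform, points) {
    p <- .as_points(points)
    out <- sweep(p %*% t(transform@rotation), 2L, transform@translation, "+")
    rownames(out) <- rownames(p)
    out
}

#' Apply only the rotational part of a transform to direction vectors
#'
#' @inheritParams applyTransform
#' @param vectors N x 3 matrix (or length-3 vector) of directions.
#' @return rotated vectors.
#' @export
rotateVector <- function(transform, vectors) {
    .as_points(vectors, "vectors") %*% t(transform@rotation)
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(a, b)} applies \code{b} first, then \code{a}.
#'
#' @param a,b \linkS4class{RigidTransform} objects.
#' @return The composed \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(a, b) {
    rigidTransform(a@rotation %*% b@rotation,
                   as.vector(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return The inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
    Rt <- t(transform@rotation)
    rigidTransform(Rt, -as.vector(Rt %*% transform@translation))
}

setMethod("show", "RigidTransform", function(object) {
    ang <- acos(.clamp((sum(diag(object@rotation)) - 1) / 2, -1, 1)) * 180 / pi
    cat(sprintf("RigidTransform | rotation %.3f deg | translation (%s) mm\n",
                ang, paste(signif(object@translation, 4), collapse = ", ")))
})

#' Write a rigid transform to JSON
#'
#' Row-major rotation plus translation, the interchange format used by
#' the other pipeline stages.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTransform <- function(transform, path) {
    jsonlite::write_json(
        list(rotation = as.vector(t(transform@rotation)),
             translation = transform@translation),
        path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path file written by \code{\link{writeTransform}}.
#' @return A \linkS4class{RigidTransform}.
#' @export
readTransform <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    rigidTransform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
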