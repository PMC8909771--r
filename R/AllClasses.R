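#' @useDynLib arguide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif sd quantile optim rbinom
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Grid geometry and volumetric containers
# ---------------------------------------------------------------------------

#' GridGeometry: sampling grid of a volumetric image
#'
#' World coordinates are millimetres in a right-handed (LPS-style)
#' convention; voxel indices are 0-based and refer to voxel centers, so
#' index (0,0,0) maps exactly to \code{origin}.
#'
#' @slot dim integer length-3 array extent.
#' @slot spacing numeric length-3 voxel size, mm, all > 0.
#' @slot origin numeric length-3 world position of the center of voxel
#'   (0,0,0), mm.
#' @slot direction 3x3 right-handed orthonormal direction matrix (columns
#'   are the world directions of the voxel axes).
#' @exportClass GridGeometry
setClass("GridGeometry",
    representation(dim = "integer", spacing = "numeric",
                   origin = "numeric", direction = "matrix"))

setValidity("GridGeometry", function(object) {
    if (length(object@dim) != 3L || any(object@dim < 1L))
        return("dim must be three positive integers")
    if (!.is_num3(object@spacing) || any(object@spacing <= 0))
        return("all spacing components must be > 0")
    if (!.is_num3(object@origin))
        return("origin must be a finite length-3 vector")
    D <- object@direction
    if (!all(dim(D) == c(3L, 3L)))
        return("direction must be 3x3")
    if (max(abs(crossprod(D) - diag(3))) > 1e-6)
        return("direction must be orthonormal")
    if (det(D) < 0)
        return("direction must be right-handed (det +1)")
    TRUE
})

#' Volume: 3-D scalar image with world geometry
#'
#' @slot geometry a \linkS4class{GridGeometry}.
#' @slot intensities 3-D numeric array (HU-like, dimensionless).
#' @exportClass Volume
setClass("Volume",
    representation(geometry = "GridGeometry", intensities = "array"))

setValidity("Volume", function(object) {
    if (length(dim(object@intensities)) != 3L)
        return("intensities must have rank exactly 3")
    if (!identical(dim(object@intensities), as.integer(object@geometry@dim)))
        return("intensity array shape must match grid dim")
    TRUE
})

#' BinaryMask: boolean voxel set on a reference grid
#'
#' @slot geometry the parent grid's \linkS4class{GridGeometry}.
#' @slot bits 3-D logical array, same shape as the parent grid.
#' @exportClass BinaryMask
setClass("BinaryMask",
    representation(geometry = "GridGeometry", bits = "array"))

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@bits) || length(dim(object@bits)) != 3L)
        return("bits must be a 3-D logical array")
    if (!identical(dim(object@bits), as.integer(object@geometry@dim)))
        return("mask shape must match grid dim")
    TRUE
})

# ---------------------------------------------------------------------------
# Rigid geometry
# ---------------------------------------------------------------------------

#' RigidTransform: proper rotation plus translation
#'
#' Maps points of one world frame into another as \eqn{x' = R x + t}.
#'
#' @slot rotation 3x3 proper orthonormal matrix.
#' @slot translation numeric length-3, mm.
#' @exportClass RigidTransform
setClass("RigidTransform",
    representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        return("rotation must be orthonormal (R'R = I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
        return("rotation determinant must be +1 within 1e-9")
    if (!.is_num3(object@translation))
        return("translation must be a finite length-3 vector")
    TRUE
})

#' Constellation: labelled fiducial point set
#'
#' A marker arrangement whose pairwise distances are (by construction)
#' non-repetitive, so geometric correspondence is unambiguous.
#'
#' @slot points N x 3 numeric matrix of world points, mm; rownames are the
#'   marker labels.
#' @exportClass Constellation
setClass("Constellation", representation(points = "matrix"))

setValidity("Constellation", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L) return("points must be N x 3 numeric")
    if (nrow(p) < 3L) return("a constellation needs at least 3 points")
    if (!all(is.finite(p))) return("points must be finite")
    TRUE
})

#' RegistrationResult: rigid fit with residual diagnostics
#'
#' @slot transform the fitted \linkS4class{RigidTransform} (source to
#'   target frame).
#' @slot correspondence two-column integer matrix of (source, target)
#'   index pairs; injective.
#' @slot fre fiducial registration error: RMS of the per-marker residuals,
#'   mm.
#' @slot residuals per-marker residual distances after the fit, mm.
#' @exportClass RegistrationResult
setClass("RegistrationResult",
    representation(transform = "RigidTransform", correspondence = "matrix",
                   fre = "numeric", residuals = "numeric"))

setValidity("RegistrationResult", function(object) {
    co <- object@correspondence
    if (ncol(co) != 2L) return("correspondence must have two columns")
    if (anyDuplicated(co[, 1L]) || anyDuplicated(co[, 2L]))
        return("correspondence must be injective")
    if (length(object@residuals) > 0 &&
        abs(object@fre^2 - mean(object@residuals^2)) > 1e-6 * max(1, object@fre^2))
        return("FRE^2 must equal the mean squared residual")
    TRUE
})

# ---------------------------------------------------------------------------
# Phantom scene and tracked-device models
# ---------------------------------------------------------------------------

#' ClipModel: five-marker tracking clip of the coaxial needle
#'
#' @slot markers 5 x 3 marker coordinates in the clip frame, mm; pairwise
#'   distances are all distinct (non-repetitive pattern).
#' @slot tipOffset vector from the clip frame origin to the needle tip, mm.
#' @slot axis unit vector of the needle shaft in the clip frame.
#' @exportClass ClipModel
setClass("ClipModel",
    representation(markers = "matrix", tipOffset = "numeric", axis = "numeric"))

setValidity("ClipModel", function(object) {
    if (nrow(object@markers) != 5L || ncol(object@markers) != 3L)
        return("a clip has exactly 5 markers")
    d <- sort(as.vector(dist(object@markers)))
    if (min(diff(d)) <= 2 - 1e-9)
        return("clip pairwise distances must be distinct by > 2 mm")
    if (!.is_num3(object@tipOffset)) return("tipOffset must be length-3")
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
        return("axis must have unit norm")
    TRUE
})

#' ObservationModel: abstracted marker tracker
#'
#' Stands in for the stereo camera: it delivers noisy 3-D marker positions
#' in the tracker frame, with per-marker dropout.
#'
#' @slot sigma i.i.d. Gaussian noise per axis, mm.
#' @slot occlusion per-marker dropout probability in [0, 1).
#' @slot frame \linkS4class{RigidTransform} from scene world to tracker
#'   frame.
#' @slot seed integer seed, or NA to draw from the current RNG stream.
#' @exportClass ObservationModel
setClass("ObservationModel",
    representation(sigma = "numeric", occlusion = "numeric",
                   frame = "RigidTransform", seed = "numeric"))

setValidity("ObservationModel", function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@occlusion < 0 || object@occlusion >= 1)
        return("occlusion probability must be in [0, 1)")
    TRUE
})

#' PhantomScene: synthetic CT scene with ground truth
#'
#' @slot volume rendered \linkS4class{Volume} (HU-like palette).
#' @slot masks named list of truth \linkS4class{BinaryMask} objects
#'   (body, liver, spleen, bone, vessels, markers).
#' @slot tumors list of truth tumor masks.
#' @slot tumorCenters K x 3 matrix of true tumor centers, mm.
#' @slot tumorDiameters tumor diameters, mm.
#' @slot fiducials 20 x 3 labelled matrix of skin fiducial points, mm.
#' @slot palette named list of tissue HU constants.
#' @slot displacement any applied breathing displacement, mm vector.
#' @slot config the generating configuration list.
#' @slot seed the generating seed.
#' @exportClass PhantomScene
setClass("PhantomScene",
    representation(volume = "Volume", masks = "list", tumors = "list",
                   tumorCenters = "matrix", tumorDiameters = "numeric",
                   fiducials = "matrix", palette = "list",
                   displacement = "numeric", config = "list", seed = "numeric"))

# ---------------------------------------------------------------------------
# Guidance
# ---------------------------------------------------------------------------

#' TrajectoryPlan: planned needle path from skin to target
#'
#' @slot entry world entry point on the skin, mm.
#' @slot target world target center, mm.
#' @slot direction unit vector from entry to target.
#' @slot depth planned depth, mm (= entry-to-target distance).
#' @slot clearance minimum distance from the path to any forbidden mask,
#'   mm (Inf when unconstrained).
#' @exportClass TrajectoryPlan
setClass("TrajectoryPlan",
    representation(entry = "numeric", target = "numeric",
                   direction = "numeric", depth = "numeric",
                   clearance = "numeric"))

setValidity("TrajectoryPlan", function(object) {
    d <- object@target - object@entry
    len <- sqrt(sum(d^2))
    if (abs(object@depth - len) > 1e-6 * max(1, len))
        return("depth must equal the entry-to-target distance")
    if (max(abs(object@direction - d / len)) > 1e-6)
        return("direction must be the unit entry-to-target vector")
    TRUE
})

#' NeedlePose: tracked device line
#'
#' @slot tip world tip position, mm.
#' @slot axis unit insertion direction.
#' @slot fre clip-fit fiducial registration error, mm.
#' @exportClass NeedlePose
setClass("NeedlePose",
    representation(tip = "numeric", axis = "numeric", fre = "numeric"))

setValidity("NeedlePose", function(object) {
    if (!.is_num3(object@tip)) return("tip must be finite length-3")
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
        return("axis must have unit norm")
    TRUE
})

#' AlignmentStatus: blue/green needle-to-plan alignment feedback
#'
#' @slot aligned TRUE (green) iff angular deviation <= tauAng and lateral
#'   offset <= tauLat, boundaries inclusive.
#' @slot angleDeg angular deviation between needle axis and planned
#'   direction, degrees.
#' @slot lateralMm distance of the target center from the infinite needle
#'   line, mm.
#' @slot remainingMm remaining depth along the needle axis, mm (negative
#'   means overshoot).
#' @slot tauAng,tauLat the thresholds used, degrees / mm.
#' @exportClass AlignmentStatus
setClass("AlignmentStatus",
    representation(aligned = "logical", angleDeg = "numeric",
                   lateralMm = "numeric", remainingMm = "numeric",
                   tauAng = "numeric", tauLat = "numeric"))

# ---------------------------------------------------------------------------
# Confirmation and reporting
# ---------------------------------------------------------------------------

#' AblationAssessment: tumor coverage and residual margin quantification
#'
#' @slot tumorResidualPct percent of tumor voxels outside the necrosis.
#' @slot marginResidualPct percent of margin-shell voxels outside the
#'   necrosis.
#' @slot completeAblation TRUE iff tumor residual is exactly 0.
#' @slot marginSuccess TRUE iff the margin is ablated > 90 percent, i.e.
#'   residual strictly < 10.
#' @slot technicalSuccess completeAblation AND marginSuccess.
#' @slot marginMm margin thickness, mm (default 5).
#' @slot volumesMm3 named vector: tumor, necrosis, margin shell, mm^3.
#' @slot clippedToLiver whether the shell was clipped to the liver.
#' @slot emptyNecrosis TRUE when assessment ran against an empty necrosis
#'   mask (residuals forced to 100).
#' @exportClass AblationAssessment
setClass("AblationAssessment",
    representation(tumorResidualPct = "numeric", marginResidualPct = "numeric",
                   completeAblation = "logical", marginSuccess = "logical",
                   technicalSuccess = "logical", marginMm = "numeric",
                   volumesMm3 = "numeric", clippedToLiver = "logical",
                   emptyNecrosis = "logical"))

setValidity("AblationAssessment", function(object) {
    r <- c(object@tumorResidualPct, object@marginResidualPct)
    if (any(r < 0 | r > 100)) return("residual percentages must be in [0, 100]")
    if (object@completeAblation != (object@tumorResidualPct == 0))
        return("completeAblation must mirror tumor residual == 0")
    if (object@marginSuccess != (object@marginResidualPct < 10))
        return("marginSuccess must mirror margin residual < 10")
    if (object@technicalSuccess !=
        (object@completeAblation && object@marginSuccess))
        return("technicalSuccess must be the conjunction of the two flags")
    TRUE
})

#' SummaryStats: descriptive summary of one numeric record field
#'
#' @slot field the summarized field name.
#' @slot n number of values.
#' @slot mean arithmetic mean.
#' @slot sd sample standard deviation (n - 1 denominator; 0 when n = 1,
#'   with \code{singleton} flagged).
#' @slot min,max range.
#' @slot singleton TRUE when n = 1.
#' @exportClass SummaryStats
setClass("SummaryStats",
    representation(field = "character", n = "integer", mean = "numeric",
                   sd = "numeric", min = "numeric", max = "numeric",
                   singleton = "logical"))

setValidity("SummaryStats", function(object) {
    if (object@n >= 1L &&
        (object@min > object@mean + 1e-9 || object@mean > object@max + 1e-9))
        return("min <= mean <= max must hold")
    if (object@sd < 0) return("sd must be >= 0")
    TRUE
})

#' SegmentationResult: structure masks plus marker centroids
#'
#' @slot masks named list of \linkS4class{BinaryMask} objects (body, bone,
#'   liver, vessels, markers, optionally spleen).
#' @slot markerCentroids labelled N x 3 matrix of marker centroids in
#'   world mm.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
    representation(masks = "list", markerCentroids = "matrix"))
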