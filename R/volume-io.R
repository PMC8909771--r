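# Volumetric data model, coordinate conversions, metric morphology and
# standard-format I/O (NIfTI via RNifti; MetaImage natively).

#' Construct a Volume
#'
#' @param intensities 3-D numeric array.
#' @param spacing per-axis voxel size, mm (all > 0).
#' @param origin world position of the center of voxel (0,0,0), mm.
#' @param direction 3x3 right-handed orthonormal direction matrix
#'   (identity = axis-aligned LPS-style world).
#' @return A \linkS4class{Volume}.
#' @examples
#' v <- Volume(array(0, c(16, 16, 8)), spacing = c(0.5, 0.5, 2))
#' dim(v)
#' @export
Volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
    intensities <- as.array(intensities)
    if (length(dim(intensities)) != 3L)
        .format_error(sprintf("expected a rank-3 array, got rank %d",
                              length(dim(intensities))))
    geom <- new("GridGeometry", dim = as.integer(dim(intensities)),
                spacing = as.numeric(spacing), origin = as.numeric(origin),
                direction = direction)
    new("Volume", geometry = geom, intensities = intensities)
}

#' Construct a BinaryMask on the grid of a Volume (or another mask)
#'
#' @param bits 3-D logical array (numeric input is coerced: nonzero = TRUE).
#' @param grid a \linkS4class{Volume}, \linkS4class{BinaryMask} or
#'   \linkS4class{GridGeometry} supplying the geometry.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(bits, grid) {
    geom <- gridGeometry(grid)
    bits <- array(as.logical(bits), dim = dim(as.array(bits)))
    new("BinaryMask", geometry = geom, bits = bits)
}

#' Grid geometry accessor
#'
#' @param x a Volume, BinaryMask or GridGeometry.
#' @return The \linkS4class{GridGeometry}.
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @rdname gridGeometry
#' @export
setMethod("gridGeometry", "Volume", function(x) x@geometry)
#' @rdname gridGeometry
#' @export
setMethod("gridGeometry", "BinaryMask", function(x) x@geometry)
#' @rdname gridGeometry
#' @export
setMethod("gridGeometry", "GridGeometry", function(x) x)

#' @export
setMethod("dim", "Volume", function(x) x@geometry@dim)
#' @export
setMethod("dim", "BinaryMask", function(x) x@geometry@dim)
#' @export
setMethod("dim", "GridGeometry", function(x) x@dim)

#' Voxel spacing in mm
#' @param x a Volume, BinaryMask or GridGeometry.
#' @return numeric length-3.
#' @export
voxelSpacing <- function(x) gridGeometry(x)@spacing

#' World origin (center of voxel (0,0,0)) in mm
#' @inheritParams voxelSpacing
#' @return numeric length-3.
#' @export
voxelOrigin <- function(x) gridGeometry(x)@origin

#' Axis direction matrix
#' @inheritParams voxelSpacing
#' @return 3x3 orthonormal matrix.
#' @export
voxelDirection <- function(x) gridGeometry(x)@direction

#' Intensity array of a Volume
#' @param x a \linkS4class{Volume}.
#' @return the 3-D numeric array.
#' @export
intensities <- function(x) x@intensities

#' Logical array of a BinaryMask
#' @param x a \linkS4class{BinaryMask}.
#' @return the 3-D logical array.
#' @export
maskBits <- function(x) x@bits

#' Foreground volume of a mask in cubic millimetres
#'
#' count(TRUE) times the voxel volume.
#' @param x a \linkS4class{BinaryMask}.
#' @return scalar mm^3.
#' @export
maskVolumeMm3 <- function(x) sum(x@bits) * prod(voxelSpacing(x))

setMethod("show", "Volume", function(object) {
    g <- object@geometry
    cat(sprintf("Volume %s | spacing %s mm | origin %s mm\n",
                paste(g@dim, collapse = "x"),
                paste(signif(g@spacing, 4), collapse = "x"),
                paste(signif(g@origin, 4), collapse = ", ")))
    cat(sprintf("  intensity range [%g, %g]\n",
                min(object@intensities), max(object@intensities)))
})

setMethod("show", "BinaryMask", function(object) {
    g <- object@geometry
    cat(sprintf("BinaryMask %s | %d foreground voxels | %.1f mm^3\n",
                paste(g@dim, collapse = "x"), sum(object@bits),
                maskVolumeMm3(object)))
})

.sameGeometry <- function(a, b, tol = 1e-6) {
    ga <- gridGeometry(a); gb <- gridGeometry(b)
    identical(ga@dim, gb@dim) &&
        max(abs(ga@spacing - gb@spacing)) < tol &&
        max(abs(ga@origin - gb@origin)) < tol &&
        max(abs(ga@direction - gb@direction)) < tol
}

# ---------------------------------------------------------------------------
# World <-> voxel conversions (0-based indices, voxel centers)
# ---------------------------------------------------------------------------

#' Map voxel indices to world coordinates
#'
#' world = origin + direction %*% (spacing * index); indices are 0-based,
#' continuous (fractional) indices are allowed, and voxel centers map to
#' world points.
#'
#' @param grid a Volume, BinaryMask or GridGeometry.
#' @param index N x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return N x 3 matrix of world points, mm.
#' @export
worldFromVoxel <- function(grid, index) {
    g <- gridGeometry(grid)
    idx <- .as_points(index, "index")
    sweep(idx %*% diag(g@spacing) %*% t(g@direction), 2L, g@origin, "+")
}

#' Map world coordinates to (continuous) voxel indices
#'
#' Inverse of \code{\link{worldFromVoxel}}; out-of-bounds coordinates are
#' permitted and can be detected with \code{\link{insideGrid}}.
#'
#' @inheritParams worldFromVoxel
#' @param world N x 3 matrix (or length-3 vector) of world points, mm.
#' @return N x 3 matrix of 0-based continuous voxel indices.
#' @export
voxelFromWorld <- function(grid, world) {
    g <- gridGeometry(grid)
    w <- .as_points(world, "world")
    sweep(w, 2L, g@origin, "-") %*% g@direction %*% diag(1 / g@spacing)
}

#' Are voxel indices inside the grid?
#'
#' @inheritParams worldFromVoxel
#' @return logical vector, one entry per row of \code{index}.
#' @export
insideGrid <- function(grid, index) {
    g <- gridGeometry(grid)
    idx <- .as_points(index, "index")
    idx[, 1L] >= -0.5 & idx[, 1L] <= g@dim[1L] - 0.5 &
        idx[, 2L] >= -0.5 & idx[, 2L] <= g@dim[2L] - 0.5 &
        idx[, 3L] >= -0.5 & idx[, 3L] <= g@dim[3L] - 0.5
}

# World coordinates of every foreground voxel of a mask.
.maskWorldPoints <- function(mask) {
    idx <- which(mask@bits, arr.ind = TRUE) - 1
    worldFromVoxel(mask, idx)
}

# ---------------------------------------------------------------------------
# Metric morphology (exact anisotropic Euclidean distance transform)
# ---------------------------------------------------------------------------

#' Euclidean distance transform of a mask
#'
#' Per-voxel distance (mm) from each voxel center to the nearest
#' foreground voxel center, exact under anisotropic spacing. Background
#' of an empty mask is Inf.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param squared return squared distances.
#' @return 3-D numeric array of distances on the mask grid.
#' @export
distanceTransform <- function(mask, squared = FALSE) {
    g <- gridGeometry(mask)
    d2 <- .edt_squared(as.vector(mask@bits), g@dim, g@spacing)
    d2 <- array(d2, dim = g@dim)
    if (squared) d2 else sqrt(d2)
}

#' Metric dilation of a mask
#'
#' Returns the set of voxels whose Euclidean distance (spacing-aware) to
#' the input foreground is at most \code{radius} mm; always a superset of
#' the input and monotone in the radius.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param radius dilation radius, mm (>= 0).
#' @return A \linkS4class{BinaryMask}.
#' @export
dilateMetric <- function(mask, radius) {
    if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
        radius < 0)
        .value_error("dilation radius must be a single number >= 0")
    if (radius == 0) return(mask)
    d2 <- distanceTransform(mask, squared = TRUE)
    BinaryMask(d2 <= radius^2 + 1e-9, mask)
}

#' Metric erosion of a mask
#'
#' Keeps the voxels whose distance to the background exceeds
#' \code{radius} mm (the dual of \code{\link{dilateMetric}}).
#'
#' @inheritParams dilateMetric
#' @return A \linkS4class{BinaryMask}.
#' @export
erodeMetric <- function(mask, radius) {
    if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
        radius < 0)
        .value_error("erosion radius must be a single number >= 0")
    if (radius == 0) return(mask)
    inv <- BinaryMask(!mask@bits, mask)
    d2 <- distanceTransform(inv, squared = TRUE)
    BinaryMask(mask@bits & d2 > radius^2 + 1e-9, mask)
}

#' Morphological closing with a metric ball
#'
#' @inheritParams dilateMetric
#' @return A \linkS4class{BinaryMask}.
#' @export
closeMetric <- function(mask, radius) {
    erodeMetric(dilateMetric(mask, radius), radius)
}

# Label 6-connected components; returns an integer array (0 = background).
.labelComponents <- function(bits) {
    dims <- dim(bits)
    array(.label_components6(as.vector(bits), as.integer(dims)), dim = dims)
}

# Fill background components not connected to the array border.
.fillHoles <- function(bits) {
    lab <- .labelComponents(!bits)
    d <- dim(bits)
    border <- unique(c(lab[c(1L, d[1L]), , ], lab[, c(1L, d[2L]), ],
                       lab[, , c(1L, d[3L])]))
    border <- border[border != 0L]
    bits | !(lab %in% c(0L, border))
}

# ---------------------------------------------------------------------------
# File I/O
# ---------------------------------------------------------------------------

.affine_of <- function(geom) {
    rbind(cbind(geom@direction %*% diag(geom@spacing), geom@origin),
          c(0, 0, 0, 1))
}

.geom_from_affine <- function(aff, dims) {
    M <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(M^2))
    direction <- M %*% diag(1 / spacing)
    # guard against numerical drift in stored single-precision headers
    sv <- svd(direction)
    direction <- sv$u %*% t(sv$v)
    if (det(direction) < 0) {
        # flip the axis with the smallest singular value to stay proper
        j <- which.min(sv$d)
        u <- sv$u; u[, j] <- -u[, j]
        direction <- u %*% t(sv$v)
    }
    new("GridGeometry", dim = as.integer(dims), spacing = as.numeric(spacing),
        origin = as.numeric(aff[1:3, 4]), direction = direction)
}

#' Read a volumetric image
#'
#' Supports NIfTI (.nii, .nii.gz) and MetaImage (.mha, .mhd) with a 3-D
#' scalar payload. Header spacing and origin are reflected faithfully;
#' intensities are unchanged.
#'
#' @param path file path.
#' @return A \linkS4class{Volume}.
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) .format_error(sprintf("no such file: %s", path))
    lower <- tolower(path)
    if (grepl("\\.nii(\\.gz)?$", lower)) {
        img <- RNifti::readNifti(path)
        arr <- as.array(img)
        arr <- array(as.numeric(arr), dim = dim(arr))
        if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
            arr <- array(arr, dim = dim(arr)[1:3])
        if (length(dim(arr)) != 3L)
            .format_error(sprintf(
                "%s: expected a 3-D scalar payload, got rank %d",
                path, length(dim(arr))))
        aff <- RNifti::xform(img)
        geom <- .geom_from_affine(aff, dim(arr))
        new("Volume", geometry = geom, intensities = arr)
    } else if (grepl("\\.mhd?a?$", lower)) {
        .readMetaImage(path)
    } else {
        .format_error(sprintf("unsupported volume format: %s", path))
    }
}

#' Write a volumetric image
#'
#' Format follows the file extension: NIfTI (.nii, .nii.gz) or MetaImage
#' (.mha single-file, .mhd header + .raw).
#'
#' @param volume a \linkS4class{Volume}.
#' @param path output path.
#' @param datatype storage type: "auto" picks int16 for integer-valued
#'   payloads in range, float64 otherwise; or one of "uint8", "int16",
#'   "int32", "float32", "float64".
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, datatype = "auto") {
    stopifnot(is(volume, "Volume"))
    lower <- tolower(path)
    arr <- volume@intensities
    if (datatype == "auto") {
        intish <- all(arr == round(arr)) && min(arr) >= -32768 &&
            max(arr) <= 32767
        datatype <- if (intish) "int16" else "float64"
    }
    if (grepl("\\.nii(\\.gz)?$", lower)) {
        img <- RNifti::asNifti(arr)
        aff <- structure(.affine_of(volume@geometry), code = 2L)
        img <- RNifti::`sform<-`(img, aff)
        nt <- switch(datatype, uint8 = "uint8", int16 = "int16",
                     int32 = "int32", float32 = "float", float64 = "double",
                     .value_error(sprintf("unknown datatype %s", datatype)))
        RNifti::writeNifti(img, path, datatype = nt)
    } else if (grepl("\\.mhd?a?$", lower)) {
        .writeMetaImage(volume, path, datatype)
    } else {
        .format_error(sprintf("unsupported volume format: %s", path))
    }
    invisible(path)
}

#' Read a binary mask
#'
#' Reads a 0/1 volume and returns it as a \linkS4class{BinaryMask}
#' (any nonzero voxel is foreground).
#'
#' @inheritParams readVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path) {
    v <- readVolume(path)
    new("BinaryMask", geometry = v@geometry,
        bits = array(v@intensities != 0, dim = dim(v@intensities)))
}

#' Write a binary mask as an 8-bit 0/1 volume
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @inheritParams writeVolume
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
    v <- new("Volume", geometry = mask@geometry,
             intensities = array(as.numeric(mask@bits), dim = dim(mask@bits)))
    writeVolume(v, path, datatype = "uint8")
}

# --- MetaImage (.mha / .mhd + .raw), uncompressed little-endian ------------

.met_types <- list(
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
    MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

.readMetaImage <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    hdr <- list()
    repeat {
        line <- readLines(con, n = 1L, warn = FALSE)
        if (length(line) == 0L)
            .format_error(sprintf("%s: missing ElementDataFile key", path))
        kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
        if (length(kv) != 3L)
            .format_error(sprintf("%s: malformed header line '%s'", path, line))
        hdr[[kv[2L]]] <- trimws(kv[3L])
        if (kv[2L] == "ElementDataFile") break
    }
    ndims <- as.integer(hdr[["NDims"]])
    if (is.null(hdr[["NDims"]]) || is.na(ndims) || ndims != 3L)
        .format_error(sprintf("%s: expected NDims = 3, got %s", path,
                              hdr[["NDims"]]))
    dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1L]])
    spacing <- if (!is.null(hdr[["ElementSpacing"]]))
        as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1L]]) else c(1, 1, 1)
    origin <- if (!is.null(hdr[["Offset"]]))
        as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1L]]) else c(0, 0, 0)
    direction <- if (!is.null(hdr[["TransformMatrix"]]))
        matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1L]]),
               3L, 3L, byrow = TRUE) else diag(3)
    if (identical(tolower(hdr[["CompressedData"]]), "true"))
        .format_error(sprintf("%s: compressed MetaImage is not supported", path))
    tinfo <- .met_types[[hdr[["ElementType"]]]]
    if (is.null(tinfo))
        .format_error(sprintf("%s: unsupported ElementType %s", path,
                              hdr[["ElementType"]]))
    n <- prod(dims)
    if (identical(hdr[["ElementDataFile"]], "LOCAL")) {
        raw_con <- con
    } else {
        raw_path <- file.path(dirname(path), hdr[["ElementDataFile"]])
        if (!file.exists(raw_path))
            .format_error(sprintf("%s: data file %s not found", path, raw_path))
        raw_con <- file(raw_path, "rb")
        on.exit(close(raw_con), add = TRUE)
    }
    vals <- readBin(raw_con, what = tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
    if (length(vals) != n)
        .format_error(sprintf("%s: truncated payload", path))
    new("Volume",
        geometry = new("GridGeometry", dim = dims, spacing = spacing,
                       origin = origin, direction = t(direction)),
        intensities = array(as.numeric(vals), dim = dims))
}

.writeMetaImage <- function(volume, path, datatype) {
    g <- volume@geometry
    mt <- switch(datatype, uint8 = "MET_UCHAR", int16 = "MET_SHORT",
                 int32 = "MET_INT", float32 = "MET_FLOAT",
                 float64 = "MET_DOUBLE",
                 .value_error(sprintf("unknown datatype %s", datatype)))
    tinfo <- .met_types[[mt]]
    local_data <- grepl("\\.mha$", tolower(path))
    data_file <- if (local_data) "LOCAL" else
        sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(
        "ObjectType = Image",
        "NDims = 3",
        "BinaryData = True",
        "BinaryDataByteOrderMSB = False",
        "CompressedData = False",
        paste("TransformMatrix =",
              paste(format(as.vector(t(g@direction)), digits = 15),
                    collapse = " ")),
        paste("Offset =", paste(format(g@origin, digits = 15), collapse = " ")),
        paste("ElementSpacing =",
              paste(format(g@spacing, digits = 15), collapse = " ")),
        paste("DimSize =", paste(g@dim, collapse = " ")),
        paste("ElementType =", mt),
        paste("ElementDataFile =", data_file))
    vals <- as.vector(volume@intensities)
    if (tinfo$what == "integer") vals <- as.integer(round(vals))
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    if (local_data) {
        writeBin(vals, con, size = tinfo$size, endian = "little")
    } else {
        rcon <- file(file.path(dirname(path), data_file), "wb")
        on.exit(close(rcon), add = TRUE)
        writeBin(vals, rcon, size = tinfo$size, endian = "little")
    }
    invisible(path)
}
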