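# Internal helpers shared across modules.

# Classed errors so callers can distinguish contract violations from stage
# failures (mirrored by the CLI exit codes).
.abort <- function(msg, class) {
    stop(errorCondition(msg, class = c(class, "arguide_error")))
}

.value_error   <- function(msg) .abort(msg, "arguide_value_error")
.format_error  <- function(msg) .abort(msg, "arguide_format_error")
.stage_error   <- function(msg) .abort(msg, "arguide_stage_error")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  seed = NULL draws from the current
# stream.
.with_seed <- function(seed, code) {
    if (is.null(seed) || (length(seed) == 1L && is.na(seed))) {
        return(force(code))
    }
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

.is_num3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

.unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) .value_error("cannot normalize a zero-length vector")
    v / nv
}

.check_unit <- function(v, what = "direction", tol = 1e-6) {
    if (!.is_num3(v)) .value_error(sprintf("%s must be a finite length-3 vector", what))
    if (abs(sqrt(sum(v^2)) - 1) > tol) {
        .value_error(sprintf("%s must have unit norm", what))
    }
    invisible(v)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Points are handled as N x 3 matrices throughout.
.as_points <- function(x, what = "points") {
    if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) {
        x <- matrix(x, nrow = 1L)
    }
    x <- as.matrix(x)
    if (ncol(x) != 3L || !is.numeric(x)) {
        .value_error(sprintf("%s must be an N x 3 numeric matrix", what))
    }
    storage.mode(x) <- "double"
    x
}

.row_norms <- function(m) sqrt(rowSums(m^2))

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b Logical arrays (or \linkS4class{BinaryMask} objects) of
#'   identical shape.
#' @return The Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)}; \code{NaN}
#'   if both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
    if (is(a, "BinaryMask")) a <- maskBits(a)
    if (is(b, "BinaryMask")) b <- maskBits(b)
    if (!identical(dim(a), dim(b))) .value_error("masks must share a grid")
    sa <- sum(a); sb <- sum(b)
    if (sa + sb == 0) return(NaN)
    2 * sum(a & b) / (sa + sb)
}
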