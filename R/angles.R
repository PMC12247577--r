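#' Wrap an angle into the axial orientation space [0, 180)
#'
#' Orientation gratings are axial stimuli: a grating at \code{theta} degrees is
#' physically identical to one at \code{theta + 180}. All orientation
#' bookkeeping in this package therefore lives on the half-circle
#' \eqn{[0, 180)}.
#'
#' @param angle Numeric vector of angles in degrees. Must be finite.
#' @return Numeric vector of the same length, congruent to \code{angle}
#'   modulo 180 and lying in \eqn{[0, 180)}.
#' @examples
#' wrap180(165 + 30)  # 15
#' wrap180(15 - 30)   # 165
#' @export
wrap180 <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("'angle' must be finite numeric", call. = FALSE)
  }
  angle %% 180
}

#' Axial (180 degree periodic) distance between two orientations
#'
#' The absolute circular distance between orientations on the axial
#' half-circle: \code{min(|a - b|, 180 - |a - b|)}, in degrees, in
#' \eqn{[0, 90]}.
#'
#' @param a,b Numeric vectors of orientations in degrees, each in
#'   \eqn{[0, 180)}. Recycled to a common length.
#' @return Numeric vector of axial distances in degrees.
#' @examples
#' axial_distance(15, 165)  # 30
#' axial_distance(15, 105)  # 90
#' @export
axial_distance <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) ||
      any(!is.finite(a)) || any(!is.finite(b))) {
    stop("orientations must be finite numeric", call. = FALSE)
  }
  if (any(a < 0 | a >= 180) || any(b < 0 | b >= 180)) {
    stop("orientations must lie in [0, 180)", call. = FALSE)
  }
  d <- abs(a - b)
  pmin(d, 180 - d)
}

#' The six grating orientations used in the task
#'
#' @return Integer vector \code{c(15, 45, 75, 105, 135, 165)} (degrees).
#' @export
task_orientations <- function() {
  c(15L, 45L, 75L, 105L, 135L, 165L)
}

#' The five rotation instructions used in the task
#'
#' @return Integer vector \code{c(-60, -30, 0, 30, 60)} (signed degrees).
#' @export
task_rotations <- function() {
  c(-60L, -30L, 0L, 30L, 60L)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so seeded helpers compose deterministically.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("'seed' must be a single finite number", call. = FALSE)
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
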