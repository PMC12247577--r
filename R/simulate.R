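#' Random population coding scheme for orientation
#'
#' A coding scheme maps an axial orientation onto a feature-space pattern:
#' two random patterns (each \code{n_features} i.i.d. standard-normal values)
#' are weighted by the sine and cosine of the doubled orientation angle.
#' Doubling maps the 180 degree axial orientation space onto the full circle,
#' so that orthogonal gratings (90 degrees apart) receive opposite patterns.
#'
#' @param n_features Number of features (default 20).
#' @return Object of class \code{"coding_scheme"}: list with \code{w_sin},
#'   \code{w_cos}.
#' @export
coding_scheme <- function(n_features = 20) {
  structure(list(w_sin = stats::rnorm(n_features),
                 w_cos = stats::rnorm(n_features)),
            class = "coding_scheme")
}

#' Pattern evoked by an orientation under a coding scheme
#'
#' @param scheme A \code{\link{coding_scheme}}.
#' @param theta Orientation(s) in degrees, in \eqn{[0, 180)}.
#' @return If \code{theta} is scalar, a pattern vector; otherwise a matrix
#'   with one row per orientation.
#' @examples
#' s <- local({set.seed(1); coding_scheme(20)})
#' all.equal(pattern_for_orientation(s, 0), s$w_cos)  # sin(0) = 0
#' @export
pattern_for_orientation <- function(scheme, theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta >= 180)) {
    stop("'theta' must lie in [0, 180)", call. = FALSE)
  }
  rad <- 2 * theta * pi / 180
  out <- outer(sin(rad), scheme$w_sin) + outer(cos(rad), scheme$w_cos)
  if (length(theta) == 1L) drop(out) else out
}

#' Scenario specification for the generative simulations
#'
#' Defines one maintenance scenario for the simulated feature patterns after
#' the rotation instruction:
#' \describe{
#'   \item{rotated_only}{Only the rotation product is coded; the original
#'     (cued) item vanishes.}
#'   \item{partial_rotation}{A single item halfway between original and
#'     rotation product is coded.}
#'   \item{same_scheme_both}{Original and rotated item are both coded, in one
#'     shared coding scheme.}
#'   \item{same_scheme_one}{Shared scheme, but only one of the two items
#'     (fair coin per trial) is coded.}
#'   \item{unique_scheme_both}{Both items coded in two independent schemes.}
#'   \item{unique_scheme_one}{Independent schemes, one item per trial.}
#' }
#' Trial-wise noise is a fresh standard-normal feature vector scaled by a
#' scalar drawn from Normal(\code{noise_mu}, \code{noise_sd}) on every trial,
#' emulating trial-wise fluctuations in neural noise level. The scalar is
#' used as drawn (no truncation). Optionally an explicit rotation-condition
#' signal is added: one unique random pattern per rotation level.
#'
#' @param name Scenario name, see Details.
#' @param include_rotation_signal Add the per-rotation-level pattern?
#' @param n_features Feature-space dimension (default 20).
#' @param noise_mu,noise_sd Noise-scalar distribution (defaults 10 and 3).
#' @param amplitude Item-signal amplitude relative to the unit-normal scheme
#'   patterns (default 1).
#' @return Object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(name = c("rotated_only", "partial_rotation",
                                   "same_scheme_both", "same_scheme_one",
                                   "unique_scheme_both",
                                   "unique_scheme_one"),
                          include_rotation_signal = FALSE,
                          n_features = 20, noise_mu = 10, noise_sd = 3,
                          amplitude = 1) {
  name <- match.arg(name)
  stopifnot(noise_sd >= 0, n_features >= 2)  # sd 0: noiseless degenerate
  structure(list(name = name,
                 include_rotation_signal = isTRUE(include_rotation_signal),
                 n_features = as.integer(n_features),
                 noise_mu = noise_mu, noise_sd = noise_sd,
                 amplitude = amplitude),
            class = "scenario_spec")
}

#' Simulate one subject's impulse-evoked feature patterns
#'
#' Generates trial x feature patterns for a given trial design under a
#' maintenance scenario: the scenario's signal term plus trial-wise scaled
#' noise (see \code{\link{scenario_spec}}). All randomness flows from
#' \code{seed}; reruns are bit-identical.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param design A \code{\link{generate_design}} trial table.
#' @param seed Integer seed for this subject.
#' @return Object of class \code{"simulated_dataset"}: list with
#'   \code{features} (trials x n_features), \code{design}, \code{schemes},
#'   \code{noise_scale} (the per-trial noise scalars, for diagnostics),
#'   \code{spec}, \code{seed}.
#' @export
simulate_subject <- function(spec, design, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_design(design)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  n <- nrow(design)
  p <- spec$n_features
  with_seed(seed, {
    s1 <- coding_scheme(p)  # original / shared item scheme
    s2 <- coding_scheme(p)  # rotated item scheme (unique-scheme scenarios)
    theta_c <- design$cued_ori
    theta_r <- design$rotated_ori
    sig <- switch(
      spec$name,
      rotated_only = pattern_for_orientation(s2, theta_r),
      partial_rotation = pattern_for_orientation(
        s1, wrap180(theta_c + design$rotation / 2)),
      same_scheme_both = pattern_for_orientation(s1, theta_c) +
        pattern_for_orientation(s1, theta_r),
      same_scheme_one = {
        pick <- stats::runif(n) < 0.5
        ifelse(pick, 1, 0) * pattern_for_orientation(s1, theta_c) +
          ifelse(pick, 0, 1) * pattern_for_orientation(s1, theta_r)
      },
      unique_scheme_both = pattern_for_orientation(s1, theta_c) +
        pattern_for_orientation(s2, theta_r),
      unique_scheme_one = {
        pick <- stats::runif(n) < 0.5
        ifelse(pick, 1, 0) * pattern_for_orientation(s1, theta_c) +
          ifelse(pick, 0, 1) * pattern_for_orientation(s2, theta_r)
      },
      stop("unknown scenario: ", spec$name, call. = FALSE)
    )
    sig <- spec$amplitude * sig
    if (spec$include_rotation_signal) {
      levels_rot <- sort(unique(design$rotation))
      rot_pat <- matrix(stats::rnorm(length(levels_rot) * p),
                        length(levels_rot), p)
      sig <- sig + rot_pat[match(design$rotation, levels_rot), , drop = FALSE]
    }
    scal <- stats::rnorm(n, spec$noise_mu, spec$noise_sd)
    noise <- matrix(stats::rnorm(n * p), n, p) * scal
    structure(list(features = sig + noise, design = design,
                   schemes = list(item1 = s1, item2 = s2),
                   noise_scale = scal, spec = spec, seed = seed),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: scenario '%s', %d trials x %d features\n",
              x$spec$name, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Embed simulated feature patterns into an epochs carrier
#'
#' Builds a trials x channels x samples epochs array whose impulse window
#' carries the simulated pattern, so the feature-extraction chain can be
#' exercised end to end. The feature vector is laid out on the
#' (channel x time) grid of the extraction window (time varying fastest
#' within channel); the grid size must equal the number of features. A
#' per-trial, per-channel random offset plus a slow ramp that plateaus over
#' the window emulate drift; both are removed exactly by the within-window
#' mean-removal of the extraction step.
#'
#' @param dataset A \code{\link{simulate_subject}} result (or plain matrix).
#' @param channels Character vector of carrier channel names.
#' @param srate Sampling rate in Hz (default 100, i.e. the extraction grid).
#' @param window Extraction window (start, end) in seconds, half-open.
#' @param span Epoch span (start, end) in seconds (default c(-0.15, 0.6)).
#' @param drift_sd SD of the per-trial/channel offset and ramp magnitude
#'   (default 0: clean carrier).
#' @param noise_sd SD of additive white sensor noise (default 0).
#' @param seed Optional seed for drift/noise.
#' @return An \code{\link{epochs}} object.
#' @export
embed_in_epochs <- function(dataset, channels, srate = 100,
                            window = c(0.1, 0.4), span = c(-0.15, 0.6),
                            drift_sd = 0, noise_sd = 0, seed = NULL) {
  x <- if (inherits(dataset, "simulated_dataset")) dataset$features else
    as.matrix(dataset)
  n_trials <- nrow(x)
  n_ch <- length(channels)
  times <- seq(span[1L], span[2L], by = 1 / srate)
  win_idx <- which(times >= window[1L] - 1e-9 & times < window[2L] - 1e-9)
  n_t <- length(win_idx)
  if (n_ch * n_t != ncol(x)) {
    stop(sprintf(
      "carrier grid (%d channels x %d samples = %d) does not match %d features",
      n_ch, n_t, n_ch * n_t, ncol(x)), call. = FALSE)
  }
  arr <- array(0, dim = c(n_trials, n_ch, length(times)))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      pat <- matrix(x[tr, ], nrow = n_t, ncol = n_ch)  # time within channel
      for (ch in seq_len(n_ch)) {
        base <- rep(0, length(times))
        if (drift_sd > 0) {
          offset <- stats::rnorm(1, 0, drift_sd)
          slope <- stats::rnorm(1, 0, drift_sd)
          # ramp that freezes at the window onset: constant over the window
          base <- offset + slope * pmin(times, times[win_idx[1L]])
        }
        if (noise_sd > 0) base <- base + stats::rnorm(length(times), 0,
                                                      noise_sd)
        arr[tr, ch, ] <- base
        arr[tr, ch, win_idx] <- arr[tr, ch, win_idx] + pat[, ch]
      }
    }
  })
  epochs(arr, channel_names = channels, times = times, srate = srate)
}
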