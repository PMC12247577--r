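#' Epoched multichannel data container
#'
#' @param data Numeric array, trials x channels x samples (volts).
#' @param channel_names Character vector, one per channel.
#' @param times Sample times in seconds relative to impulse onset; strictly
#'   increasing with uniform spacing \code{1/srate}.
#' @param srate Sampling rate in Hz.
#' @param impulse_tag Optional tag, e.g. \code{"impulse1"} or
#'   \code{"impulse2"}.
#' @return Object of class \code{"epochs"}.
#' @export
epochs <- function(data, channel_names, times, srate,
                   impulse_tag = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[2L] != length(channel_names)) {
    stop("channel_names length must match dim(data)[2]", call. = FALSE)
  }
  if (dim(data)[3L] != length(times)) {
    stop("times length must match dim(data)[3]", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1 / srate)) > 1e-6) {
    stop("times must be strictly increasing with spacing 1/srate",
         call. = FALSE)
  }
  structure(list(data = data, channel_names = as.character(channel_names),
                 times = as.numeric(times), srate = srate,
                 impulse_tag = impulse_tag),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Epochs%s: %d trials x %d channels x %d samples (%g Hz, %g..%g s)\n",
    if (is.null(x$impulse_tag)) "" else paste0(" [", x$impulse_tag, "]"),
    d[1L], d[2L], d[3L], x$srate, min(x$times), max(x$times)))
  invisible(x)
}

#' The 17 posterior channels of interest
#'
#' @return Character vector of posterior channel labels.
#' @export
posterior_channels <- function() {
  c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
}

#' Idealised 2-D layout for the posterior channels
#'
#' A schematic flat projection (arbitrary units) of the 17 posterior
#' channels, for use with \code{\link{searchlight_groups}} when no measured
#' montage is at hand. Real analyses should supply digitised electrode
#' coordinates.
#'
#' @return \code{data.frame} with columns \code{channel}, \code{x}, \code{y}.
#' @export
posterior_layout <- function() {
  data.frame(
    channel = posterior_channels(),
    x = c(-4, -3, -2, -1, 0, 1, 2, 3, 4,
          -3, -1.5, 0, 1.5, 3,
          -1.5, 0, 1.5),
    y = c(rep(2, 9), rep(1, 5), rep(0, 3)),
    stringsAsFactors = FALSE)
}

# FIR anti-alias low-pass + subsample, row-wise on a (signals x samples)
# matrix. q = 1 is the identity.
.decimate_rows <- function(mat, q) {
  if (q == 1L) return(mat)
  n_s <- ncol(mat)
  ord <- min(64L, 2L * ((n_s - 2L) %/% 2L))  # even order <= n_s - 2
  if (ord < 4L) stop("window too short to decimate", call. = FALSE)
  b <- signal::fir1(ord, 0.9 / q)
  pad <- min(ord, n_s - 1L)
  out <- t(apply(mat, 1L, function(r) {
    # odd-reflection padding keeps filter transients out of the window
    left <- 2 * r[1L] - r[(pad + 1L):2L]
    right <- 2 * r[n_s] - r[(n_s - 1L):(n_s - pad)]
    f <- signal::filtfilt(b, c(left, r, right))
    f[pad + seq_len(n_s)]
  }))
  out[, seq(1L, n_s, by = q), drop = FALSE]
}

# shared crop/baseline/decimate core; returns trials x (channels*time)
# with time varying fastest within channel, plus the kept output times
.extract_window <- function(ep, channels, window, fs_out) {
  miss <- setdiff(channels, ep$channel_names)
  if (length(miss)) {
    stop("channel(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (window[1L] < min(ep$times) - 1e-9 ||
      window[2L] > max(ep$times) + 1 / ep$srate + 1e-9) {
    stop(sprintf("window [%g, %g) lies outside the epoch span [%g, %g]",
                 window[1L], window[2L], min(ep$times), max(ep$times)),
         call. = FALSE)
  }
  q <- ep$srate / fs_out
  if (abs(q - round(q)) > 1e-9) {
    stop("srate must be an integer multiple of fs_out", call. = FALSE)
  }
  q <- as.integer(round(q))
  idx <- which(ep$times >= window[1L] - 1e-9 & ep$times < window[2L] - 1e-9)
  ch_idx <- match(channels, ep$channel_names)
  n_trials <- dim(ep$data)[1L]
  n_t_out <- length(seq(1L, length(idx), by = q))
  vals <- matrix(0, n_trials, length(channels) * n_t_out)
  for (ci in seq_along(ch_idx)) {
    seg <- ep$data[, ch_idx[ci], idx, drop = FALSE]
    seg <- matrix(seg, n_trials, length(idx))
    seg <- seg - rowMeans(seg)            # relative within-window baseline
    seg <- .decimate_rows(seg, q)
    seg <- seg - rowMeans(seg)            # re-zero after filter transients
    cols <- (ci - 1L) * n_t_out + seq_len(n_t_out)
    vals[, cols] <- seg
  }
  times_out <- ep$times[idx][seq(1L, length(idx), by = q)]
  list(values = vals, times = times_out)
}

#' Spatiotemporal feature extraction
#'
#' Extracts the impulse-evoked multivariate pattern: for each trial the
#' selected channels are cropped to the window, the mean voltage over the
#' window is removed per trial and channel (a relative, within-window
#' baseline that removes drift and isolates the evoked dynamics), the trace
#' is down-sampled to \code{fs_out} with an anti-alias FIR filter, and the
#' remaining time points are concatenated across channels. The default
#' 17 posterior channels x 300 ms window at 100 Hz give 510 features.
#'
#' @param ep An \code{\link{epochs}} object.
#' @param channels Channels to use (default the posterior set).
#' @param window Half-open window (start, end) in seconds relative to
#'   impulse onset; default \code{c(0.1, 0.4)}.
#' @param fs_out Output sampling rate in Hz (default 100).
#' @return Object of class \code{"feature_matrix"}: list with \code{values}
#'   (trials x features), \code{feature_index} (channel/time per column),
#'   \code{window}, \code{times}.
#' @export
extract_spatiotemporal <- function(ep, channels = posterior_channels(),
                                   window = c(0.1, 0.4), fs_out = 100) {
  stopifnot(inherits(ep, "epochs"))
  ex <- .extract_window(ep, channels, window, fs_out)
  structure(list(values = ex$values,
                 feature_index = data.frame(
                   channel = rep(channels, each = length(ex$times)),
                   time = rep(ex$times, times = length(channels))),
                 window = window, times = ex$times),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d trials x %d features (window %g..%g s)\n",
              nrow(x$values), ncol(x$values), x$window[1L], x$window[2L]))
  invisible(x)
}

#' Sliding-window time-course feature extraction
#'
#' Applies the spatiotemporal extraction in a sliding window: one
#' \code{feature_matrix} per window centre, each using the centre +/- half
#' the window width (100 ms by default, i.e. 10 time points at 100 Hz, 170
#' features over the 17 posterior channels).
#'
#' @param ep An \code{\link{epochs}} object.
#' @param channels Channels to use.
#' @param centers Window centres in seconds (default -0.05 to 0.55 in 10 ms
#'   steps).
#' @param width Window width in seconds (default 0.1).
#' @param fs_out Output rate in Hz (default 100).
#' @return Named list of \code{feature_matrix} objects, one per centre, with
#'   attribute \code{"centers"}.
#' @export
extract_timecourse <- function(ep, channels = posterior_channels(),
                               centers = seq(-0.05, 0.55, by = 0.01),
                               width = 0.1, fs_out = 100) {
  stopifnot(inherits(ep, "epochs"))
  out <- lapply(centers, function(ct)
    extract_spatiotemporal(ep, channels,
                           window = c(ct - width / 2, ct + width / 2),
                           fs_out = fs_out))
  names(out) <- sprintf("%+.3f", centers)
  attr(out, "centers") <- centers
  out
}

#' Searchlight channel neighbourhoods
#'
#' For every channel, the group of the channel itself plus its two nearest
#' neighbours by Euclidean distance in the supplied coordinates. Distance
#' ties are broken by channel order in the table.
#'
#' @param layout \code{data.frame} with a \code{channel} column and numeric
#'   coordinate columns (2-D or 3-D), e.g. \code{\link{posterior_layout}}.
#' @return Named list: per channel, a character vector of 3 channel names
#'   (the channel first).
#' @export
searchlight_groups <- function(layout) {
  stopifnot(is.data.frame(layout), "channel" %in% names(layout))
  coords <- as.matrix(layout[vapply(layout, is.numeric, logical(1))])
  if (nrow(layout) < 3L) stop("need at least 3 channels", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  out <- lapply(seq_len(nrow(layout)), function(i) {
    ord <- order(d[i, ], layout$channel)  # label order breaks distance ties
    ord <- ord[ord != i]
    c(layout$channel[i], layout$channel[ord[1:2]])
  })
  names(out) <- layout$channel
  out
}

#' Gaussian smoothing of a time-course
#'
#' Convolution with a Gaussian kernel of the given standard deviation; at
#' the series edges the kernel is truncated and renormalised to sum to one,
#' so constants pass through unchanged.
#'
#' @param values Numeric vector, one value per window centre.
#' @param sd Kernel SD in seconds (default 0.016).
#' @param spacing Centre spacing in seconds (default 0.01).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_timecourse <- function(values, sd = 0.016, spacing = 0.01) {
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  n <- length(values)
  half <- ceiling(4 * sd / spacing)
  kern <- stats::dnorm(seq(-half, half) * spacing, sd = sd)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    w <- kern[ok]
    out[i] <- sum(w * values[j[ok]]) / sum(w)
  }
  out
}
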