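#' Half-cosine basis function value
#'
#' Tuning weight between two orientations separated by an axial distance
#' \code{delta}: \code{cos(delta in radians)^power} on the axial scale
#' (equivalently the half cosine of the doubled angle). Non-negative, 1 at
#' zero offset, 0 at the maximal axial distance of 90 degrees. Raising to
#' the 5th power (the default) narrows the tuning so that information pools
#' only across similar orientations.
#'
#' @param delta Axial distance(s) in degrees, in \eqn{[0, 90]}.
#' @param power Exponent (default 5).
#' @return Numeric weight(s).
#' @examples
#' basis_value(0)    # 1
#' basis_value(90)   # 0
#' basis_value(60)   # 0.5^5 = 0.03125
#' @export
basis_value <- function(delta, power = 5) {
  if (any(!is.finite(delta)) || any(delta < 0 | delta > 90)) {
    stop("'delta' must lie in [0, 90]", call. = FALSE)
  }
  cos(delta * pi / 180)^power
}

# 6 x 6 basis matrix mapping raw class means to basis-smoothed class means
.basis_matrix <- function(centers = task_orientations(), power = 5) {
  n <- length(centers)
  outer(seq_len(n), seq_len(n), function(i, j)
    basis_value(axial_distance(centers[i], centers[j]), power))
}

#' Decoding strength from class-mean distances
#'
#' Summarises the Mahalanobis distances from one test trial to the six
#' orientation class means into a single scalar: the (sign-flipped) cosine
#' vector mean of the mean-centred distances against the doubled angular
#' offsets,
#' \deqn{s = -\mathrm{mean}_k[\cos(2(\theta - c_k)) (d_k - \bar d)].}
#' Positive values mean that class means near the trial's true orientation
#' are closer (in Mahalanobis distance) than far ones, i.e. evidence for the
#' labelled orientation.
#'
#' @param distances Numeric vector, one distance per orientation centre.
#' @param true_theta The trial's orientation in degrees.
#' @param centers Orientation centres in degrees (default the task's six).
#' @return Scalar decoding strength.
#' @export
strength_from_distances <- function(distances, true_theta,
                                    centers = task_orientations()) {
  if (length(distances) != length(centers)) {
    stop("'distances' length must match 'centers'", call. = FALSE)
  }
  dc <- distances - mean(distances)
  -mean(cos(2 * (true_theta - centers) * pi / 180) * dc)
}

# Mahalanobis distances from rows of x to rows of means, given sigma_inv.
# Returns trials x classes matrix of (non-squared) distances.
.maha_dist <- function(x, means, sigma_inv) {
  cross <- x %*% sigma_inv %*% t(means)        # trials x classes
  qx <- rowSums((x %*% sigma_inv) * x)         # trial quadratic forms
  qm <- rowSums((means %*% sigma_inv) * means) # class quadratic forms
  d2 <- outer(qx, qm, `+`) - 2 * cross
  sqrt(pmax(d2, 0))
}

# shared CV decoding engine; train/test may index different feature sets
# (cross-impulse generalisation) but share trial folds.
.decode_cv <- function(x_train, x_test, labels_train, labels_test,
                       test_mask, k, n_reps, centers, power,
                       folds = NULL) {
  lab_tr <- match(labels_train, centers)
  lab_te <- match(labels_test, centers)
  if (any(is.na(lab_tr)) || any(is.na(lab_te[test_mask]))) {
    stop("labels must be one of the orientation centres", call. = FALSE)
  }
  n <- nrow(x_train)
  n_class <- length(centers)
  if (any(tabulate(lab_tr, n_class) < k)) {
    stop("every orientation needs at least k trials", call. = FALSE)
  }
  bmat <- .basis_matrix(centers, power)
  cosmat <- cos(2 * outer(centers[lab_te], centers, `-`) * pi / 180)
  if (!is.null(folds)) folds <- as.matrix(folds)
  acc <- numeric(n)
  for (rep_i in seq_len(n_reps)) {
    ff <- if (is.null(folds)) .folds_impl(lab_tr, k) else
      folds[, (rep_i - 1L) %% ncol(folds) + 1L]
    for (f in seq_len(k)) {
      te <- which(ff == f & test_mask)
      if (!length(te)) next
      tr <- which(ff != f)
      tr <- .equalise(tr, lab_tr, n_class)
      m <- rowsum(x_train[tr, , drop = FALSE], lab_tr[tr]) /
        tabulate(lab_tr[tr], n_class)
      xc <- x_train[tr, , drop = FALSE] - m[lab_tr[tr], , drop = FALSE]
      sigma_inv <- psd_pinv(shrinkage_covariance(xc)$sigma)
      sm <- bmat %*% m                        # basis-smoothed class means
      d <- .maha_dist(x_test[te, , drop = FALSE], sm, sigma_inv)
      dc <- d - rowMeans(d)
      acc[te] <- acc[te] - rowMeans(cosmat[te, , drop = FALSE] * dc)
    }
  }
  acc / n_reps
}

#' Trial-wise Mahalanobis orientation decoding
#'
#' Decodes a 6-level orientation label from trial patterns with 8-fold
#' cross-validation: per fold, training trials are equalised across classes
#' by random subsampling, class-mean patterns are convolved with the
#' half-cosine basis set to pool information across similar orientations,
#' the noise covariance (Ledoit-Wolf shrinkage) is estimated from the
#' class-mean-centred training trials, and the Mahalanobis distances from
#' each test trial to the six smoothed class means are summarised into a
#' per-trial decoding strength (\code{\link{strength_from_distances}}).
#' Strengths are averaged over repetitions.
#'
#' @param features Trials x features matrix (or \code{feature_matrix}).
#' @param labels Orientation label per trial, in degrees (6 levels).
#' @param k Folds (default 8).
#' @param n_reps Repetitions with fresh folds/subsamples (default 100).
#' @param seed Optional seed.
#' @param centers Orientation centres (default the task's six).
#' @param power Basis exponent (default 5).
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference).
#' @param folds Optional precomputed fold vector/matrix (see
#'   \code{\link{compute_rdm}}).
#' @return Object of class \code{"strength_series"}: data.frame with
#'   \code{trial} and \code{strength}.
#' @export
decode_item <- function(features, labels, k = 8, n_reps = 100, seed = NULL,
                        centers = task_orientations(), power = 5,
                        engine = c("cpp", "r"), folds = NULL) {
  engine <- match.arg(engine)
  x <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  stopifnot(nrow(x) == length(labels))
  s <- with_seed(seed,
    .decode_dispatch(x, x, labels, labels, rep(TRUE, nrow(x)), k, n_reps,
                     centers, power, engine, folds))
  structure(data.frame(trial = seq_len(nrow(x)), strength = s),
            class = c("strength_series", "data.frame"))
}

# engine dispatch shared by decode_item and cross_generalise; runs inside
# the caller's RNG scope
.decode_dispatch <- function(x_train, x_test, labels_train, labels_test,
                             test_mask, k, n_reps, centers, power, engine,
                             folds = NULL) {
  if (engine == "r") {
    return(.decode_cv(x_train, x_test, labels_train, labels_test,
                      test_mask, k, n_reps, centers, power, folds))
  }
  lab_tr <- match(labels_train, centers)
  lab_te <- match(labels_test, centers)
  if (any(is.na(lab_tr)) || any(is.na(lab_te[test_mask]))) {
    stop("labels must be one of the orientation centres", call. = FALSE)
  }
  if (any(tabulate(lab_tr, length(centers)) < k)) {
    stop("every orientation needs at least k trials", call. = FALSE)
  }
  if (!is.null(folds)) {
    folds <- as.matrix(folds)
    storage.mode(folds) <- "integer"
  }
  delta <- outer(centers[lab_te], centers, `-`)
  delta[is.na(delta)] <- 0  # masked-out trials; never read
  cosmat <- cos(2 * delta * pi / 180)
  .decode_cv_cpp(x_train, x_test, lab_tr,
                 ifelse(is.na(lab_te), 1L, lab_te),
                 as.integer(test_mask), length(centers),
                 as.integer(k), as.integer(n_reps),
                 .basis_matrix(centers, power), cosmat, folds)
}

#' Cross-temporal generalisation of the orientation code
#'
#' Trains the Mahalanobis decoder on one set of patterns (e.g. the cued item
#' at the first impulse) and tests it on another set from the same trials
#' (e.g. the second impulse), labelling the test trials either with the cued
#' or with the rotated orientation. Folds are defined on shared trial ids,
#' so no trial contributes to both training and test within a fold pass.
#' Training uses all trials; testing is restricted to rotation trials
#' (\code{test_mask}). When a cue side is supplied, the analysis runs within
#' each side separately and the resulting strengths are pooled.
#'
#' @param train_features,test_features Trials x features matrices, row-
#'   aligned to the same trials.
#' @param train_labels Orientation labels for training (degrees).
#' @param test_labels Orientation labels for the test read-out (degrees).
#' @param test_mask Logical per trial; which trials enter the test set
#'   (default: all).
#' @param side Optional per-trial cue side for per-location analysis.
#' @param k,n_reps,seed,centers,power,engine As in
#'   \code{\link{decode_item}}.
#' @return List with \code{strengths} (a \code{strength_series} over the
#'   tested trials) and \code{mean_strength}.
#' @export
cross_generalise <- function(train_features, test_features, train_labels,
                             test_labels, test_mask = NULL, side = NULL,
                             k = 8, n_reps = 100, seed = NULL,
                             centers = task_orientations(), power = 5,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  xtr <- if (inherits(train_features, "feature_matrix"))
    train_features$values else as.matrix(train_features)
  xte <- if (inherits(test_features, "feature_matrix"))
    test_features$values else as.matrix(test_features)
  stopifnot(nrow(xtr) == nrow(xte))
  n <- nrow(xtr)
  if (is.null(test_mask)) test_mask <- rep(TRUE, n)
  s <- rep(NA_real_, n)
  with_seed(seed, {
    groups <- if (is.null(side)) list(seq_len(n)) else
      split(seq_len(n), side)
    for (g in groups) {
      if (!any(test_mask[g])) {
        stop("a cue-side group has no test trials", call. = FALSE)
      }
      s[g] <- .decode_dispatch(xtr[g, , drop = FALSE],
                               xte[g, , drop = FALSE],
                               train_labels[g], test_labels[g],
                               test_mask[g], k, n_reps, centers, power,
                               engine)
    }
  })
  keep <- which(test_mask)
  out <- structure(data.frame(trial = keep, strength = s[keep]),
                   class = c("strength_series", "data.frame"))
  list(strengths = out, mean_strength = mean(s[keep]))
}

#' Correlation of trial-wise decoding strengths
#'
#' Pearson correlation between two aligned strength series (e.g. cued and
#' rotated item at the second impulse, rotation trials only), Fisher
#' z-transformed. A positive group-level z indicates that trials carrying a
#' strong code for one item also carry a strong code for the other
#' (simultaneous maintenance); a negative z indicates a trade-off (only one
#' item coded per trial).
#'
#' @param s1,s2 Numeric vectors or \code{strength_series} of equal length.
#' @return Fisher z (atanh of the Pearson r).
#' @export
correlate_strengths <- function(s1, s2) {
  v1 <- if (is.data.frame(s1)) s1$strength else as.numeric(s1)
  v2 <- if (is.data.frame(s2)) s2$strength else as.numeric(s2)
  if (length(v1) != length(v2)) stop("series lengths differ", call. = FALSE)
  if (length(v1) < 3L) stop("need at least 3 trials", call. = FALSE)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("zero-variance strength series", call. = FALSE)
  }
  r <- stats::cor(v1, v2)
  fisher_z(r)
}
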