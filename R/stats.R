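#' Fisher z transform
#'
#' @param r Correlation coefficient(s), strictly inside (-1, 1).
#' @return \code{atanh(r)}.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("|r| must be < 1 for the Fisher z transform", call. = FALSE)
  }
  atanh(r)
}

# one-sample t statistic(s) against 0, column-wise for matrices
.tstat <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    m <- colMeans(x)
    s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
    m / (s / sqrt(n))
  } else {
    mean(x) / (stats::sd(x) / sqrt(length(x)))
  }
}

#' Permutation-based one-sample t-test
#'
#' Tests a per-subject statistic against zero using a permutation null: the
#' caller supplies, for every permutation, the per-subject statistic
#' recomputed under shuffled condition labels (or, by default, the null is
#' formed by random per-subject sign flips). Each null draw is converted to
#' a t value across subjects; the p value is the proportion of null |t| at
#' or above the observed |t| (two-sided by default), with the observed
#' statistic included in the null count, so p >= 1/(n_perm + 1).
#'
#' @param values Numeric vector, one statistic per subject (>= 2 subjects).
#' @param null Either a subjects x n_perm matrix of null statistics, a
#'   function(i) returning the per-subject null vector for permutation i, or
#'   NULL for a sign-flip null.
#' @param n_perm Number of permutations (default 1000; ignored when
#'   \code{null} is a matrix).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param seed Optional seed (used for the sign-flip null or when calling a
#'   generator).
#' @return Object of class \code{"perm_test"}: list with \code{statistic}
#'   (observed t), \code{null_t}, \code{p}, \code{n}, \code{alternative}.
#' @export
perm_ttest <- function(values, null = NULL, n_perm = 1000,
                       alternative = c("two.sided", "greater", "less"),
                       seed = NULL) {
  alternative <- match.arg(alternative)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (stats::sd(values) == 0) {
    # no effect and no variance: t is 0 by convention; a constant nonzero
    # statistic is genuinely degenerate
    if (all(values == 0)) {
      return(structure(list(statistic = 0, null_t = numeric(0), p = 1,
                            n = n, alternative = alternative),
                       class = "perm_test"))
    }
    stop("zero-variance subject statistics", call. = FALSE)
  }
  t_obs <- .tstat(values)
  null_mat <- with_seed(seed, {
    if (is.matrix(null)) {
      stopifnot(nrow(null) == n)
      null
    } else if (is.function(null)) {
      vapply(seq_len(n_perm), null, numeric(n))
    } else {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n)
      values * signs
    }
  })
  keep <- apply(null_mat, 2L, stats::sd) > 0
  null_t <- .tstat(null_mat[, keep, drop = FALSE])
  n_perm <- length(null_t)
  p <- switch(alternative,
    two.sided = (sum(abs(null_t) >= abs(t_obs)) + 1) / (n_perm + 1),
    greater = (sum(null_t >= t_obs) + 1) / (n_perm + 1),
    less = (sum(null_t <= t_obs) + 1) / (n_perm + 1))
  structure(list(statistic = t_obs, null_t = null_t, p = p, n = n,
                 alternative = alternative),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation t-test (%d subjects, %d permutations, %s): t = %.3f, p = %.4g\n",
    x$n, length(x$null_t), x$alternative, x$statistic, x$p))
  invisible(x)
}

# contiguous runs above threshold; returns list of index vectors
.runs <- function(mask) {
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mapply(function(s, e) s:e, starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

.cluster_stats <- function(tvals, tcrit) {
  pos <- .runs(tvals > tcrit)
  neg <- .runs(tvals < -tcrit)
  clusters <- c(pos, neg)
  stats <- vapply(clusters, function(ix) sum(tvals[ix]), numeric(1))
  list(clusters = clusters, stats = stats)
}

#' Cluster-based permutation test over a time-course
#'
#' Corrects the mass-univariate one-sample t-test over window centres for
#' multiple comparisons: contiguous runs of centres whose |t| exceeds the
#' cluster-forming threshold (two-sided p < \code{alpha_form} under the t
#' distribution) form clusters, scored by their summed t. The null is the
#' distribution of the maximum absolute cluster score under random
#' per-subject sign flips.
#'
#' @param timecourses Subjects x centres matrix of per-subject statistics.
#' @param n_perm Permutations (default 1000).
#' @param alpha_form Cluster-forming threshold (default 0.05).
#' @param seed Optional seed.
#' @return Object of class \code{"cluster_perm"}: list with \code{t}
#'   (per-centre t values), \code{clusters} (list of centre index runs),
#'   \code{cluster_stat}, \code{p} (per cluster), \code{null_max}.
#' @export
cluster_perm <- function(timecourses, n_perm = 1000, alpha_form = 0.05,
                         seed = NULL) {
  x <- as.matrix(timecourses)
  n <- nrow(x)
  if (n < 2L || ncol(x) < 2L) {
    stop("need >= 2 subjects and >= 2 centres", call. = FALSE)
  }
  tcrit <- stats::qt(1 - alpha_form / 2, df = n - 1L)
  t_obs <- .tstat(x)
  obs <- .cluster_stats(t_obs, tcrit)
  null_max <- with_seed(seed, {
    ssq <- colSums(x^2)
    vapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      m <- colMeans(x * signs)
      s <- sqrt((ssq - n * m^2) / (n - 1))
      tv <- m / (s / sqrt(n))
      cs <- .cluster_stats(tv, tcrit)
      if (length(cs$stats)) max(abs(cs$stats)) else 0
    }, numeric(1))
  })
  p <- vapply(obs$stats, function(s)
    (sum(null_max >= abs(s)) + 1) / (n_perm + 1), numeric(1))
  structure(list(t = t_obs, clusters = obs$clusters,
                 cluster_stat = obs$stats, p = p, null_max = null_max,
                 tcrit = tcrit),
            class = "cluster_perm")
}

#' @export
print.cluster_perm <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d cluster(s), forming |t| > %.2f\n",
              length(x$clusters), x$tcrit))
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  centres %d..%d: sum t = %.2f, p = %.4g\n",
                  min(x$clusters[[i]]), max(x$clusters[[i]]),
                  x$cluster_stat[i], x$p[i]))
    }
  }
  invisible(x)
}

#' Trial-wise neural-to-behaviour regression
#'
#' Tests whether the per-trial decoding strengths of the cued/original and
#' the rotated item predict behaviour. Per subject, each strength series is
#' residualised on the other (simple linear regression) so that the two
#' regressors explain unique variance; accuracy is modelled by logistic
#' regression and log response time by linear regression on both residual
#' series simultaneously. Group-level inference is a permutation t-test on
#' the per-subject betas, with the null built by shuffling trials (breaking
#' the neural-behaviour link) and refitting; tests are one-sided in the
#' direction of facilitation (positive for accuracy, negative for log-RT).
#'
#' Subjects whose logistic fit is degenerate (complete separation or
#' constant accuracy) are excluded from the accuracy aggregate and listed in
#' the result.
#'
#' @param data data.frame with columns \code{subject}, \code{s_cued},
#'   \code{s_rot}, \code{accuracy} (0/1), \code{rt} (seconds, > 0). Supply
#'   rotation trials only.
#' @param n_perm Permutations for the group test (default 1000; the full
#'   analysis uses 10000).
#' @param seed Optional seed.
#' @return Object of class \code{"behaviour_fit"}: list with \code{betas}
#'   (per subject x 4: acc_cued, acc_rot, rt_cued, rt_rot), \code{tests}
#'   (data.frame of group t and one-sided p), \code{excluded} (subjects
#'   dropped from the logistic aggregate).
#' @export
behaviour_regression <- function(data, n_perm = 1000, seed = NULL) {
  need <- c("subject", "s_cued", "s_rot", "accuracy", "rt")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(data$rt <= 0, na.rm = TRUE)) stop("rt must be positive",
                                            call. = FALSE)
  subjects <- unique(data$subject)

  fit_one <- function(d, perm = NULL) {
    r_c <- stats::lm.fit(cbind(1, d$s_rot), d$s_cued)$residuals
    r_r <- stats::lm.fit(cbind(1, d$s_cued), d$s_rot)$residuals
    acc <- d$accuracy
    lrt <- log(d$rt)
    if (!is.null(perm)) {
      acc <- acc[perm]
      lrt <- lrt[perm]
    }
    xm <- cbind(1, r_c, r_r)
    rtb <- stats::lm.fit(xm, lrt)$coefficients[2:3]
    accb <- c(NA_real_, NA_real_)
    sep <- length(unique(acc)) < 2L
    if (!sep) {
      gl <- suppressWarnings(
        stats::glm.fit(xm, acc, family = stats::binomial()))
      fitted <- gl$fitted.values
      if (gl$converged && all(fitted > 1e-8) && all(fitted < 1 - 1e-8)) {
        accb <- unname(gl$coefficients[2:3])
      } else {
        sep <- TRUE
      }
    }
    list(beta = c(acc_cued = accb[1L], acc_rot = accb[2L],
                  rt_cued = unname(rtb[1L]), rt_rot = unname(rtb[2L])),
         separated = sep)
  }

  per <- lapply(subjects, function(s)
    fit_one(data[data$subject == s, , drop = FALSE]))
  betas <- t(vapply(per, `[[`, numeric(4), "beta"))
  rownames(betas) <- subjects
  colnames(betas) <- c("acc_cued", "acc_rot", "rt_cued", "rt_rot")
  excluded <- subjects[vapply(per, `[[`, logical(1), "separated")]

  null_arr <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      t(vapply(subjects, function(s) {
        d <- data[data$subject == s, , drop = FALSE]
        fit_one(d, perm = sample.int(nrow(d)))$beta
      }, numeric(4)))
    }, matrix(0, length(subjects), 4L))
  })

  tests <- do.call(rbind, lapply(seq_len(4L), function(j) {
    obs <- betas[, j]
    keep <- !is.na(obs)
    if (sum(keep) < 2L) {
      return(data.frame(term = colnames(betas)[j], t = NA_real_,
                        p = NA_real_, n = sum(keep)))
    }
    nm <- null_arr[keep, j, , drop = FALSE]
    dim(nm) <- c(sum(keep), n_perm)
    ok <- !apply(nm, 2L, anyNA)
    t_obs <- .tstat(obs[keep])
    null_t <- .tstat(nm[, ok, drop = FALSE])
    side <- if (j <= 2L) `>=` else `<=`   # accuracy up, log-RT down
    p <- (sum(side(null_t, t_obs)) + 1) / (length(null_t) + 1)
    data.frame(term = colnames(betas)[j], t = t_obs, p = p, n = sum(keep))
  }))
  structure(list(betas = betas, tests = tests, excluded = excluded),
            class = "behaviour_fit")
}

#' @export
print.behaviour_fit <- function(x, ...) {
  cat("Neural-to-behaviour regression (group permutation test)\n")
  print(x$tests, row.names = FALSE)
  if (length(x$excluded)) {
    cat("excluded from logistic aggregate:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
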