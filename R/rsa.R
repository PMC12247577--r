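#' Stratified cross-validation folds
#'
#' Assigns trials to \code{k} folds so that, within every condition, fold
#' counts differ by at most one. Which folds receive the extra trials is
#' randomised per condition.
#'
#' @param condition Integer or factor vector, one condition label per trial.
#' @param k Number of folds (default 8).
#' @param seed Optional integer seed; folds are deterministic given it.
#' @return Integer vector of fold indices in \code{1:k}, aligned to trials.
#' @export
stratified_folds <- function(condition, k = 8, seed = NULL) {
  cond <- as.integer(as.factor(condition))
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  counts <- tabulate(cond)
  bad <- which(counts < k)
  if (length(bad)) {
    stop("condition(s) with fewer than k trials: ",
         paste(levels(as.factor(condition))[bad], collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, .folds_impl(cond, k))
}

# fold assignment using the current RNG stream (internal hot path)
.folds_impl <- function(cond, k) {
  folds <- integer(length(cond))
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    f <- rep_len(sample.int(k), length(idx))
    folds[idx] <- sample(f)
  }
  folds
}

# Equalise per-condition counts by random subsampling (uses current RNG).
# Returns the selected trial indices; every condition keeps min-count trials.
.equalise <- function(idx, cond, n_cond) {
  counts <- tabulate(cond[idx], nbins = n_cond)
  m <- min(counts[counts > 0L])
  o <- idx[order(cond[idx], stats::runif(length(idx)))]
  o[sequence(counts[counts > 0L]) <= m]
}

#' Cross-validated squared Mahalanobis distance (linear discriminant contrast)
#'
#' The bilinear form
#' \deqn{MD^2 = (P_A - P_B)_{train} \Sigma^{+} (P_A - P_B)_{test}^T}
#' between the train- and test-set estimates of a condition-pair pattern
#' difference. Because train and test are independent, the estimate is
#' unbiased and may be negative.
#'
#' @param d_train,d_test Numeric feature vectors: the condition-mean
#'   difference in the train and test data.
#' @param sigma_inv (Pseudo)inverse of the noise covariance, estimated from
#'   the train data.
#' @return Scalar cross-validated squared Mahalanobis distance.
#' @export
ldc_distance <- function(d_train, d_test, sigma_inv) {
  d_train <- as.numeric(d_train)
  d_test <- as.numeric(d_test)
  sigma_inv <- as.matrix(sigma_inv)
  if (length(d_train) != length(d_test) ||
      any(dim(sigma_inv) != length(d_train))) {
    stop("dimension mismatch between patterns and covariance",
         call. = FALSE)
  }
  drop(d_train %*% sigma_inv %*% d_test)
}

#' Cross-validated Mahalanobis RDM
#'
#' Computes the condition-by-condition representational dissimilarity matrix
#' of cross-validated squared Mahalanobis distances. Per repetition, trials
#' are split into \code{k} stratified folds; for each held-out test fold the
#' per-condition trial counts are equalised by random subsampling within the
#' test fold and within the training folds separately, condition-mean
#' patterns are formed in both sets, the noise covariance is estimated from
#' the condition-mean-centred training trials with a Ledoit-Wolf shrinkage
#' estimator, and all pairwise distances are filled. Distances are averaged
#' over folds and repetitions; the diagonal is exactly zero and off-diagonal
#' entries may be negative (the estimator is unbiased).
#'
#' @param features Numeric matrix, trials x features, or a
#'   \code{feature_matrix} from \code{\link{extract_spatiotemporal}}.
#' @param condition Per-trial condition index or factor; trials with
#'   \code{NA} are excluded.
#' @param labels Optional character labels for the conditions (in level
#'   order).
#' @param k Folds (default 8).
#' @param n_reps Number of random fold/subsample repetitions (default 100;
#'   reduce for quick runs).
#' @param seed Optional integer seed.
#' @param cov Covariance treatment: \code{"shrinkage"} (default) or
#'   \code{"identity"} (forces \eqn{\Sigma^{+} = I}, turning the LDC into a
#'   cross-validated squared Euclidean distance; used for validation).
#' @param engine \code{"cpp"} (compiled kernel, default) or \code{"r"}
#'   (pure-R reference implementation of the same algorithm; used for
#'   cross-checking).
#' @param folds Optional precomputed fold assignment: integer vector (one
#'   fold per trial, reused across repetitions) or matrix with one column
#'   per repetition. When supplied, the random fold stage is bypassed.
#' @return An object of class \code{"rdm"}: list with \code{values} (square
#'   symmetric matrix), \code{labels}, \code{n_conditions}, \code{k},
#'   \code{n_reps}.
#' @export
compute_rdm <- function(features, condition, labels = NULL, k = 8,
                        n_reps = 100, seed = NULL,
                        cov = c("shrinkage", "identity"),
                        engine = c("cpp", "r"), folds = NULL) {
  cov <- match.arg(cov)
  engine <- match.arg(engine)
  x <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  keep <- !is.na(condition)
  x <- x[keep, , drop = FALSE]
  cond <- as.integer(as.factor(condition[keep]))
  n_cond <- max(cond)
  if (is.null(labels)) labels <- levels(as.factor(condition[keep]))
  counts <- tabulate(cond, nbins = n_cond)
  if (any(counts == 0L)) stop("empty condition in 'condition'", call. = FALSE)
  if (any(counts < k)) {
    stop("condition(s) with fewer than k trials: ",
         paste(labels[counts < k], collapse = ", "), call. = FALSE)
  }
  if (!is.null(folds)) {
    folds <- as.matrix(folds)
    storage.mode(folds) <- "integer"
    stopifnot(nrow(folds) == nrow(x), all(folds %in% seq_len(k)))
  }
  values <- with_seed(seed, {
    if (engine == "cpp") {
      .rdm_cv_cpp(x, cond, n_cond, as.integer(k), as.integer(n_reps),
                  cov == "identity", folds)
    } else {
      acc <- matrix(0, n_cond, n_cond)
      for (rep_i in seq_len(n_reps)) {
        ff <- if (is.null(folds)) .folds_impl(cond, k) else
          folds[, (rep_i - 1L) %% ncol(folds) + 1L]
        for (f in seq_len(k)) {
          acc <- acc + .rdm_fold(x, cond, n_cond, which(ff != f),
                                 which(ff == f), cov)
        }
      }
      acc / (n_reps * k)
    }
  })
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(list(values = values, labels = labels, n_conditions = n_cond,
                 k = k, n_reps = n_reps),
            class = "rdm")
}

# One fold's contribution to the RDM (uses current RNG for subsampling).
.rdm_fold <- function(x, cond, n_cond, train_idx, test_idx, cov) {
  tr <- .equalise(train_idx, cond, n_cond)
  te <- .equalise(test_idx, cond, n_cond)
  m_tr <- rowsum(x[tr, , drop = FALSE], cond[tr]) /
    tabulate(cond[tr], n_cond)
  m_te <- rowsum(x[te, , drop = FALSE], cond[te]) /
    tabulate(cond[te], n_cond)
  if (cov == "identity") {
    m <- tcrossprod(m_tr, m_te)
  } else {
    xc <- x[tr, , drop = FALSE] - m_tr[cond[tr], , drop = FALSE]
    sigma <- shrinkage_covariance(xc)$sigma
    m <- m_tr %*% psd_pinv(sigma) %*% t(m_te)
  }
  d <- diag(m)
  outer(d, d, `+`) - m - t(m)
}

#' @export
print.rdm <- function(x, ...) {
  v <- x$values[lower.tri(x$values)]
  cat(sprintf(
    "Cross-validated Mahalanobis RDM: %d conditions (%d-fold CV, %d reps)\n",
    x$n_conditions, x$k, x$n_reps))
  cat(sprintf("  off-diagonal MD^2: mean %.4g, range [%.4g, %.4g]\n",
              mean(v), min(v), max(v)))
  invisible(x)
}

#' @export
plot.rdm <- function(x, ...) {
  n <- x$n_conditions
  graphics::image(seq_len(n), seq_len(n), t(x$values[n:1, , drop = FALSE]),
                  xlab = "condition", ylab = "condition",
                  main = "cross-validated MD^2", ...)
  invisible(x)
}

#' Hypothesis (model) RDMs for the task
#'
#' Builds the square model matrices that are regressed against the data RDM:
#' \describe{
#'   \item{location}{0 for same cue side, 1 for different.}
#'   \item{cued / uncued / rotated}{Parametric circular coding of the named
#'     item: the axial distance between the item's orientations in the two
#'     conditions.}
#'   \item{generalisation}{Axial distance between one item in condition i and
#'     a different item in condition j, symmetrised; tests whether two items
#'     share a coding scheme.}
#'   \item{rotation}{Same-vs-different coding of a single rotation
#'     instruction \code{level}: cells whose two conditions both carry that
#'     instruction get -1 (higher similarity, lower distance), all other
#'     cells +1. One model per level; no relationship between levels is
#'     assumed.}
#' }
#' With \code{location_mode} \code{"within"} (\code{"across"}) the cells of
#' different-side (same-side) condition pairs are down-weighted by replacing
#' them with the mean of the full matrix computed before replacement, so that
#' after z-scoring they are 0.
#'
#' @param keys Condition key table as returned by
#'   \code{\link{condition_keys}} (the \code{keys} element).
#' @param kind Model kind, see Details.
#' @param items For \code{kind = "generalisation"}: the two item columns to
#'   cross, e.g. \code{c("cued_ori", "rotated_ori")}.
#' @param item For item models: which orientation column codes the item
#'   (defaults by kind).
#' @param level For \code{kind = "rotation"}: the rotation level in degrees.
#' @param location_mode \code{"all"}, \code{"within"} or \code{"across"}.
#' @return Object of class \code{"model_rdm"}: list with \code{values},
#'   \code{name}, \code{location_mode}.
#' @export
model_rdm <- function(keys,
                      kind = c("location", "cued", "uncued", "rotated",
                               "generalisation", "rotation"),
                      items = c("cued_ori", "rotated_ori"),
                      item = NULL, level = NULL,
                      location_mode = c("all", "within", "across")) {
  kind <- match.arg(kind)
  location_mode <- match.arg(location_mode)
  n <- nrow(keys)
  name <- kind
  if (kind == "location") {
    if (is.null(keys$cue_side)) stop("keys carry no cue side", call. = FALSE)
    v <- outer(keys$cue_side, keys$cue_side, `!=`) * 1
  } else if (kind %in% c("cued", "uncued", "rotated")) {
    col <- if (!is.null(item)) item else
      switch(kind, cued = "cued_ori", uncued = "uncued_ori",
             rotated = "rotated_ori")
    if (is.null(keys[[col]])) stop("keys lack column ", col, call. = FALSE)
    v <- outer(seq_len(n), seq_len(n), function(i, j)
      axial_distance(keys[[col]][i], keys[[col]][j]))
  } else if (kind == "generalisation") {
    a <- keys[[items[1L]]]
    b <- keys[[items[2L]]]
    if (is.null(a) || is.null(b)) {
      stop("keys lack generalisation columns ",
           paste(items, collapse = ", "), call. = FALSE)
    }
    ab <- outer(seq_len(n), seq_len(n), function(i, j)
      axial_distance(a[i], b[j]))
    v <- (ab + t(ab)) / 2
    name <- paste0("generalisation_", sub("_ori$", "", items[1L]), "_",
                   sub("_ori$", "", items[2L]))
  } else {  # rotation one-vs-rest
    if (is.null(level)) stop("'level' required for rotation model",
                             call. = FALSE)
    if (is.null(keys$rotation)) stop("keys carry no rotation", call. = FALSE)
    touch <- keys$rotation == level
    v <- ifelse(outer(touch, touch, `&`), -1, 1)
    name <- paste0("rotation_", level)
  }
  if (location_mode != "all") {
    if (is.null(keys$cue_side)) stop("keys carry no cue side", call. = FALSE)
    same <- outer(keys$cue_side, keys$cue_side, `==`)
    unwanted <- if (location_mode == "within") !same else same
    avg <- mean(v)
    v[unwanted] <- avg
    name <- paste0(name, "_", location_mode)
  }
  structure(list(values = v, name = name, location_mode = location_mode),
            class = "model_rdm")
}

# z-score a vector over its entries; a constant vector maps to zeros.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# lower-triangle vectorisation of the unique off-diagonal cells
rdm_vec <- function(x) {
  v <- if (inherits(x, c("rdm", "model_rdm"))) x$values else as.matrix(x)
  v[lower.tri(v)]
}

#' Regress model RDMs against a data RDM
#'
#' Vectorises the unique off-diagonal cells of the data RDM and of every
#' model RDM, z-scores each vector, and fits an ordinary least-squares
#' multiple regression (with intercept) of the data on all models
#' simultaneously. Returns the fitted object; \code{coef} gives one beta per
#' model.
#'
#' @param data_rdm An \code{rdm} (or square matrix).
#' @param models A \code{model_rdm}, or a (possibly named) list of them.
#' @return Object of class \code{"rsa_fit"} with elements \code{beta} (named
#'   numeric), \code{residuals} (of the z-scored data vector) and
#'   \code{models}.
#' @export
regress_models <- function(data_rdm, models) {
  if (inherits(models, "model_rdm")) models <- list(models)
  y <- zscore(rdm_vec(data_rdm))
  xm <- vapply(models, function(m) zscore(rdm_vec(m)), numeric(length(y)))
  nm <- names(models)
  auto <- vapply(models, function(m)
    if (inherits(m, "model_rdm")) m$name else "model", character(1))
  if (is.null(nm)) nm <- auto else nm[nm == ""] <- auto[nm == ""]
  colnames(xm) <- nm
  .check_rank(xm)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xm), y)
  structure(list(beta = fit$coefficients[-1L], residuals = fit$residuals,
                 models = nm),
            class = "rsa_fit")
}

.check_rank <- function(xm) {
  keep <- colSums(xm != 0) > 0  # all-constant models z-score to zero
  if (any(keep)) {
    q <- qr(xm[, keep, drop = FALSE])
    if (q$rank < sum(keep)) {
      cm <- stats::cor(xm[, keep, drop = FALSE])
      diag(cm) <- 0
      w <- which(abs(cm) > 1 - 1e-10, arr.ind = TRUE)
      if (nrow(w)) {
        stop("collinear model RDMs: ",
             colnames(cm)[w[1L, 1L]], " and ", colnames(cm)[w[1L, 2L]],
             call. = FALSE)
      }
      stop("model RDM set is rank deficient", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat("RSA model regression (z-scored OLS)\n")
  print(round(x$beta, 4), ...)
  invisible(x)
}

#' @export
coef.rsa_fit <- function(object, ...) object$beta

#' Fit a model RDM on the residual of other models
#'
#' Implements the residualised fitting used when hypothesis models are
#' statistically related: the data vector is first regressed on the removal
#' models; the residual is z-scored; the test model is then fit to it by
#' (z-scored) OLS. The returned beta is the test model's coefficient.
#'
#' @param data_rdm The data \code{rdm}.
#' @param remove A \code{model_rdm} or list of them to regress out first.
#' @param test The \code{model_rdm} whose residual fit is wanted.
#' @return Scalar beta.
#' @export
residual_fit <- function(data_rdm, remove, test) {
  if (inherits(remove, "model_rdm")) remove <- list(remove)
  y <- zscore(rdm_vec(data_rdm))
  xm <- vapply(remove, function(m) zscore(rdm_vec(m)), numeric(length(y)))
  res <- stats::lm.fit(cbind(1, xm), y)$residuals
  res <- zscore(res)
  tv <- zscore(rdm_vec(test))
  unname(stats::lm.fit(cbind(1, tv), res)$coefficients[2L])
}

#' Residualised Impulse-2 model fits
#'
#' The full model workflow applied after the rotation instruction: the
#' rotation one-vs-rest models (and the cue-side model, when present) are fit
#' simultaneously by multiple regression; the cued-item model is fit on the
#' residual left by the rotated-item model; the rotated-item model is fit on
#' the residual left by the cued-item model and the rotation models (the
#' rotated item is marginally related to the rotation instruction); the
#' cued-rotated generalisation model is fit on the residual left by both item
#' models.
#'
#' @param data_rdm The data \code{rdm} over Impulse-2 conditions.
#' @param keys Condition key table (the \code{keys} element of
#'   \code{\link{condition_keys}}).
#' @param location_mode Passed to the item/generalisation models.
#' @param residualise If FALSE (appropriate when 0-rotation trials were
#'   excluded, so cued and rotated orientations are unrelated), the item and
#'   generalisation models are fit directly rather than on residuals.
#' @return Named numeric vector of betas: \code{cued}, \code{rotated},
#'   \code{generalisation}, \code{rotation} (mean of the per-level rotation
#'   model betas) and, when the keys carry a cue side, \code{location}.
#' @export
fit_impulse2_models <- function(data_rdm, keys, location_mode = "all",
                                residualise = TRUE) {
  rot_levels <- sort(unique(keys$rotation))
  rot_models <- lapply(rot_levels, function(l)
    model_rdm(keys, "rotation", level = l))
  names(rot_models) <- paste0("rotation_", rot_levels)
  first <- rot_models
  if (!is.null(keys$cue_side)) {
    first <- c(list(location = model_rdm(keys, "location")), first)
  }
  base <- regress_models(data_rdm, first)$beta
  rot_beta <- mean(base[paste0("rotation_", rot_levels)])

  m_cued <- model_rdm(keys, "cued", location_mode = location_mode)
  m_rot <- model_rdm(keys, "rotated", location_mode = location_mode)
  m_gen <- model_rdm(keys, "generalisation",
                     items = c("cued_ori", "rotated_ori"),
                     location_mode = location_mode)
  if (residualise) {
    b_cued <- residual_fit(data_rdm, m_rot, m_cued)
    b_rot <- residual_fit(data_rdm, c(list(m_cued), rot_models), m_rot)
    b_gen <- residual_fit(data_rdm, list(m_cued, m_rot), m_gen)
  } else {
    y <- zscore(rdm_vec(data_rdm))
    bf <- function(m) unname(
      stats::lm.fit(cbind(1, zscore(rdm_vec(m))), y)$coefficients[2L])
    b_cued <- bf(m_cued)
    b_rot <- bf(m_rot)
    b_gen <- bf(m_gen)
  }
  out <- c(cued = b_cued, rotated = b_rot, generalisation = b_gen,
           rotation = unname(rot_beta))
  if (!is.null(keys$cue_side)) out <- c(out, location = unname(base["location"]))
  out
}

#' Split-half regress-out control
#'
#' Control analysis for related item models: trials are split into two random
#' halves; an RDM is computed in each half independently (4-fold CV, one
#' repetition per iteration); the fit of one item model estimated in half 1
#' is scaled out of half 2's (z-scored) data vector; both item models are
#' then fit to the z-scored residual. Averaging over iterations, the removed
#' model's residual fit should be centred on zero while the other item's fit
#' survives, if and only if the two items carry genuinely separate pattern
#' information.
#'
#' @param features Trials x features matrix.
#' @param condition Per-trial condition index (NA trials excluded).
#' @param keys Condition key table matching \code{condition}.
#' @param n_iter Number of random split iterations (default 1000; reduce for
#'   quick runs).
#' @param k Folds within each half (default 4).
#' @param location_mode Passed to the item models.
#' @param seed Optional seed.
#' @return Matrix of averaged betas with rows \code{removed_cued},
#'   \code{removed_rotated} and columns \code{cued}, \code{rotated}.
#' @export
split_half_regress_out <- function(features, condition, keys, n_iter = 1000,
                                   k = 4, location_mode = "all",
                                   seed = NULL) {
  x <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  keep <- !is.na(condition)
  x <- x[keep, , drop = FALSE]
  cond <- as.integer(as.factor(condition[keep]))
  n_cond <- max(cond)
  if (min(tabulate(cond, n_cond)) < 2L * k) {
    stop("need at least 2*k trials per condition for the split-half control",
         call. = FALSE)
  }
  m_cued <- model_rdm(keys, "cued", location_mode = location_mode)
  m_rot <- model_rdm(keys, "rotated", location_mode = location_mode)
  zc <- zscore(rdm_vec(m_cued))
  zr <- zscore(rdm_vec(m_rot))
  acc <- matrix(0, 2L, 2L,
                dimnames = list(c("removed_cued", "removed_rotated"),
                                c("cued", "rotated")))
  simple_beta <- function(y, z) unname(
    stats::lm.fit(cbind(1, z), y)$coefficients[2L])
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      half <- .folds_impl(cond, 2L)
      r1 <- compute_rdm(x[half == 1L, , drop = FALSE], cond[half == 1L],
                        k = k, n_reps = 1)
      r2 <- compute_rdm(x[half == 2L, , drop = FALSE], cond[half == 2L],
                        k = k, n_reps = 1)
      y1 <- zscore(rdm_vec(r1))
      y2 <- zscore(rdm_vec(r2))
      for (rm_i in 1:2) {
        zrm <- if (rm_i == 1L) zc else zr
        b1 <- simple_beta(y1, zrm)
        res <- zscore(y2 - b1 * zrm)
        acc[rm_i, 1L] <- acc[rm_i, 1L] + simple_beta(res, zc)
        acc[rm_i, 2L] <- acc[rm_i, 2L] + simple_beta(res, zr)
      }
    }
  })
  acc / n_iter
}
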