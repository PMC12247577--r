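# Precompute the z-scored model vectors for an Impulse-2 style key set so
# the residual workflow can be re-run cheaply on many (null) RDMs.
.prep_impulse2_models <- function(keys, location_mode = "all") {
  rot_levels <- sort(unique(keys$rotation))
  zrot <- vapply(rot_levels, function(l)
    zscore(rdm_vec(model_rdm(keys, "rotation", level = l))),
    numeric(nrow(keys) * (nrow(keys) - 1L) / 2L))
  colnames(zrot) <- paste0("rotation_", rot_levels)
  prep <- list(
    zc = zscore(rdm_vec(model_rdm(keys, "cued",
                                  location_mode = location_mode))),
    zr = zscore(rdm_vec(model_rdm(keys, "rotated",
                                  location_mode = location_mode))),
    zg = zscore(rdm_vec(model_rdm(keys, "generalisation",
                                  items = c("cued_ori", "rotated_ori"),
                                  location_mode = location_mode))),
    zrot = zrot,
    zloc = if (!is.null(keys$cue_side))
      zscore(rdm_vec(model_rdm(keys, "location"))) else NULL)
  prep
}

.sbeta <- function(y, z) unname(stats::lm.fit(cbind(1, z), y)$coefficients[2L])

# residual workflow on a raw RDM value matrix given precomputed models
.fit_impulse2_fast <- function(values, prep) {
  y <- zscore(values[lower.tri(values)])
  xm <- prep$zrot
  if (!is.null(prep$zloc)) xm <- cbind(loc = prep$zloc, xm)
  base <- stats::lm.fit(cbind(1, xm), y)$coefficients[-1L]
  rot_beta <- mean(base[grep("^rotation_", names(base))])
  res_c <- zscore(stats::lm.fit(cbind(1, prep$zr), y)$residuals)
  res_r <- zscore(stats::lm.fit(cbind(1, prep$zc, prep$zrot), y)$residuals)
  res_g <- zscore(stats::lm.fit(cbind(1, prep$zc, prep$zr), y)$residuals)
  out <- c(cued = .sbeta(res_c, prep$zc),
           rotated = .sbeta(res_r, prep$zr),
           generalisation = .sbeta(res_g, prep$zg),
           rotation = unname(rot_beta))
  if (!is.null(prep$zloc)) out <- c(out, location = unname(base["loc"]))
  out
}

#' Run the generative scenario battery
#'
#' Simulates a cohort of subjects under each maintenance scenario and
#' analyses every simulated dataset exactly like real post-rotation impulse
#' data: a cross-validated Mahalanobis RDM over the cued-orientation x
#' rotation conditions, the residualised model fits (cued item, rotated
#' item, cued-rotated generalisation, rotation instruction), and the
#' correlation of trial-wise decoding strengths of the cued and rotated item
#' (rotation trials only). Group-level significance uses permutation nulls:
#' model betas are recomputed from RDMs built after shuffling the trial
#' condition labels (at a reduced repetition count, \code{null_reps}), the
#' strength correlation by shuffling one strength series; each null draw is
#' converted to a t value across subjects.
#'
#' Simulated patterns carry no cue-side code, so conditions ignore the cue
#' side (30 conditions for the full design).
#'
#' @param scenarios Character vector of scenario names (default: all six).
#' @param n_subjects Simulated subjects per scenario (default 30).
#' @param n_trials Trials per subject (default 1440).
#' @param n_reps RDM fold/subsample repetitions for the observed analysis
#'   (default 10).
#' @param null_reps Repetitions for each null RDM (default 1).
#' @param n_perm Label permutations per subject (default 200).
#' @param decode_reps Repetitions for the trial-wise decoder (default 10).
#' @param k Cross-validation folds (default 8).
#' @param include_rotation_signal Add an explicit rotation-condition pattern
#'   to every scenario (default FALSE).
#' @param amplitude Item signal amplitude (default 1).
#' @param seed Integer seed; the whole battery is deterministic given it.
#' @param verbose Print progress (default FALSE).
#' @return Object of class \code{"scenario_battery"}: list with
#'   \code{results} (data.frame: scenario, measure, estimate, t, p,
#'   significant), \code{subject} (per-scenario per-subject betas and
#'   Fisher z values) and the settings.
#' @export
run_scenario_battery <- function(scenarios = c("rotated_only",
                                               "partial_rotation",
                                               "same_scheme_both",
                                               "same_scheme_one",
                                               "unique_scheme_both",
                                               "unique_scheme_one"),
                                 n_subjects = 30, n_trials = 1440,
                                 n_reps = 10, null_reps = 1, n_perm = 200,
                                 decode_reps = 10, k = 8,
                                 include_rotation_signal = FALSE,
                                 amplitude = 1, seed, verbose = FALSE) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  measures <- c("cued", "rotated", "generalisation", "rotation")
  res <- list()
  subj_out <- list()
  with_seed(seed, {
    for (sc in scenarios) {
      spec <- scenario_spec(sc,
                            include_rotation_signal = include_rotation_signal,
                            amplitude = amplitude)
      betas <- matrix(NA_real_, n_subjects, length(measures),
                      dimnames = list(NULL, measures))
      null_t_acc <- matrix(0, n_perm, length(measures))
      null_betas <- array(NA_real_,
                          c(n_subjects, n_perm, length(measures)))
      zs <- numeric(n_subjects)
      z_null <- matrix(NA_real_, n_subjects, n_perm)
      for (s in seq_len(n_subjects)) {
        design <- generate_design(n_trials,
                                  seed = sample.int(2147483646L, 1L))
        sim <- simulate_subject(spec, design,
                                seed = sample.int(2147483646L, 1L))
        ck <- condition_keys(design, "impulse2", location = FALSE)
        prep <- .prep_impulse2_models(ck$keys)
        rdm <- compute_rdm(sim$features, ck$id, k = k, n_reps = n_reps)
        betas[s, ] <- .fit_impulse2_fast(rdm$values, prep)
        for (j in seq_len(n_perm)) {
          perm_id <- sample(ck$id)
          rdm_n <- compute_rdm(sim$features, perm_id, k = k,
                               n_reps = null_reps)
          null_betas[s, j, ] <- .fit_impulse2_fast(rdm_n$values, prep)
        }
        # trial-wise decoding strengths, rotation trials only
        mask <- design$rotation != 0
        xr <- sim$features[mask, , drop = FALSE]
        s_c <- decode_item(xr, design$cued_ori[mask], k = k,
                           n_reps = decode_reps)
        s_r <- decode_item(xr, design$rotated_ori[mask], k = k,
                           n_reps = decode_reps)
        zs[s] <- correlate_strengths(s_c, s_r)
        for (j in seq_len(n_perm)) {
          z_null[s, j] <- correlate_strengths(
            s_c$strength[sample.int(nrow(s_c))], s_r$strength)
        }
        if (verbose) {
          message(sprintf("[%s] subject %d/%d done", sc, s, n_subjects))
        }
      }
      rows <- do.call(rbind, lapply(seq_along(measures), function(m) {
        pt <- perm_ttest(betas[, m], null = null_betas[, , m])
        data.frame(scenario = sc, measure = measures[m],
                   estimate = mean(betas[, m]), t = pt$statistic, p = pt$p)
      }))
      ptz <- perm_ttest(zs, null = z_null)
      rows <- rbind(rows,
                    data.frame(scenario = sc,
                               measure = "strength_correlation",
                               estimate = mean(zs), t = ptz$statistic,
                               p = ptz$p))
      res[[sc]] <- rows
      subj_out[[sc]] <- list(betas = betas, fisher_z = zs)
    }
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  results$significant <- results$p < 0.05
  structure(list(results = results, subject = subj_out,
                 settings = list(n_subjects = n_subjects,
                                 n_trials = n_trials, n_reps = n_reps,
                                 null_reps = null_reps, n_perm = n_perm,
                                 decode_reps = decode_reps, k = k,
                                 include_rotation_signal =
                                   include_rotation_signal,
                                 amplitude = amplitude, seed = seed)),
            class = "scenario_battery")
}

#' @export
print.scenario_battery <- function(x, ...) {
  cat(sprintf("Scenario battery: %d subjects/scenario, %d trials\n",
              x$settings$n_subjects, x$settings$n_trials))
  df <- x$results
  df$estimate <- round(df$estimate, 4)
  df$t <- round(df$t, 2)
  df$flag <- ifelse(df$significant, "*", "")
  print(df[, c("scenario", "measure", "estimate", "t", "p", "flag")],
        row.names = FALSE)
  invisible(x)
}
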