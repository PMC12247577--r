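#' Generate the balanced factorial trial design
#'
#' Builds the retro-cue mental-rotation trial table: two orientation gratings
#' (left/right), a cue side, a signed rotation instruction, the resulting
#' rotated (task-relevant) orientation, and a probe. The design is a full
#' factorial of 6 cued orientations x 6 uncued orientations x 2 cue sides x
#' 5 rotations (360 cells), replicated \code{n_trials / 360} times and
#' shuffled. The probe matches the task-relevant item (the rotation product)
#' in 50\% of the trials of every design cell; non-matching probes are drawn
#' uniformly from the other five orientations.
#'
#' Note that the cued and uncued orientation may coincide within a trial:
#' balancing is experiment-wide, which is what yields the 72 unique
#' (cued, uncued, side) combinations used by the representational analyses.
#'
#' @param n_trials Number of trials; must be a positive multiple of 360.
#'   Default 1440 (the full experiment: 4 sessions x 24 blocks x 15 trials).
#' @param seed Integer seed; the returned table is a pure function of it.
#' @return A \code{data.frame} of class \code{"trial_table"} with columns
#'   \code{trial_id}, \code{session}, \code{block}, \code{cue_side},
#'   \code{cued_ori}, \code{uncued_ori}, \code{rotation}, \code{rotated_ori},
#'   \code{probe_ori}, \code{probe_match}, \code{accuracy}, \code{rt}
#'   (the last two are \code{NA} until filled by a simulation or real data).
#' @examples
#' d <- generate_design(360, seed = 1)
#' nrow(d)                 # 360: every factorial cell once
#' table(d$rotation)       # balanced rotations
#' @export
generate_design <- function(n_trials = 1440, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1 ||
      n_trials %% 360 != 0) {
    stop("'n_trials' must be a positive multiple of 360 ",
         "(the 6 x 6 x 2 x 5 factorial)", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  oris <- task_orientations()
  rots <- task_rotations()
  n_rep <- n_trials %/% 360L

  cells <- expand.grid(cued_ori = oris, uncued_ori = oris,
                       cue_side = c("left", "right"), rotation = rots,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- cells[rep(seq_len(nrow(cells)), each = n_rep), , drop = FALSE]
  tab$rotated_ori <- wrap180(tab$cued_ori + tab$rotation)

  with_seed(seed, {
    # probe_match: exactly half TRUE within every design cell when the
    # replication count is even; odd remainders are balanced across cells.
    # With an odd replication count a cell cannot split exactly 50/50; the
    # leading value then alternates across cells so the global rate stays 1/2.
    cell_id <- rep(seq_len(nrow(cells)), each = n_rep)
    pm <- logical(nrow(tab))
    for (i in seq_len(nrow(cells))) {
      idx <- which(cell_id == i)
      lead <- i %% 2L == 0L
      pm[idx] <- sample(rep(c(lead, !lead), length.out = n_rep))
    }
    tab$probe_match <- pm

    tab$probe_ori <- ifelse(tab$probe_match, tab$rotated_ori, NA_real_)
    nm <- which(!tab$probe_match)
    # non-matching probes: uniform over the five other orientations
    other <- vapply(nm, function(i) {
      sample(setdiff(oris, tab$rotated_ori[i]), 1L)
    }, numeric(1))
    tab$probe_ori[nm] <- other

    ord <- sample.int(nrow(tab))
    tab <- tab[ord, , drop = FALSE]
  })

  tab$trial_id <- seq_len(nrow(tab))
  tab$session <- ((tab$trial_id - 1L) %/% 360L) %% 4L + 1L
  within_session <- (tab$trial_id - 1L) %% 360L
  tab$block <- within_session %/% 15L + 1L
  tab$accuracy <- NA
  tab$rt <- NA_real_

  tab <- tab[, c("trial_id", "session", "block", "cue_side", "cued_ori",
                 "uncued_ori", "rotation", "rotated_ori", "probe_ori",
                 "probe_match", "accuracy", "rt")]
  rownames(tab) <- NULL
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial design: %d trials, %d sessions\n",
              nrow(x), length(unique(x$session))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

#' Condition keys for the representational analyses
#'
#' Maps each trial to the experimental condition used when building an RDM.
#' Three keyings are supported: \code{"impulse1"} crosses the cued and uncued
#' orientation with the cue side (72 conditions); \code{"impulse2"} crosses
#' the cued orientation with the rotation instruction and cue side (60);
#' \code{"impulse2_norot"} is the same after dropping 0-rotation trials (48).
#' With \code{location = FALSE} (used for simulated data, which carries no
#' spatial code) the cue side is ignored, halving the counts.
#'
#' @param design A \code{trial_table}.
#' @param impulse One of \code{"impulse1"}, \code{"impulse2"},
#'   \code{"impulse2_norot"}.
#' @param location Logical; include the cue side in the key (default TRUE).
#' @return A list with \code{keys} (one row per condition, in label order),
#'   \code{id} (per-trial condition index, \code{NA} for excluded trials) and
#'   \code{labels} (character condition labels).
#' @export
condition_keys <- function(design,
                           impulse = c("impulse1", "impulse2",
                                       "impulse2_norot"),
                           location = TRUE) {
  impulse <- match.arg(impulse)
  stopifnot(is.data.frame(design))
  keep <- rep(TRUE, nrow(design))
  if (impulse == "impulse1") {
    vars <- c("cued_ori", "uncued_ori")
  } else {
    vars <- c("cued_ori", "rotation")
    if (impulse == "impulse2_norot") keep <- design$rotation != 0
  }
  if (location) vars <- c(vars, "cue_side")
  df <- design[vars]
  keys <- unique(df[keep, , drop = FALSE])
  keys <- keys[do.call(order, keys), , drop = FALSE]
  rownames(keys) <- NULL
  if (impulse != "impulse1") {
    keys$rotated_ori <- wrap180(keys$cued_ori + keys$rotation)
  }
  labels <- apply(keys[vars], 1L, paste, collapse = "/")
  id <- rep(NA_integer_, nrow(design))
  id[keep] <- match(apply(df[keep, , drop = FALSE], 1L, paste,
                          collapse = "/"),
                    labels)
  list(keys = keys, id = id, labels = labels)
}

# Internal design validation used by tests and simulate_subject().
validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("trial_id", "cue_side", "cued_ori", "uncued_ori", "rotation",
            "rotated_ori")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(wrap180(design$cued_ori + design$rotation) != design$rotated_ori)) {
    stop("rotated_ori must equal wrap180(cued_ori + rotation)",
         call. = FALSE)
  }
  invisible(design)
}
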