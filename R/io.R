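#' Write / read a trial design as CSV
#'
#' Fixed, documented column order (\code{trial_id}, \code{session},
#' \code{block}, \code{cue_side}, \code{cued_ori}, \code{uncued_ori},
#' \code{rotation}, \code{rotated_ori}, \code{probe_ori},
#' \code{probe_match}, \code{accuracy}, \code{rt}); angles in integer
#' degrees, booleans as 0/1.
#'
#' @param design A \code{trial_table}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly (write) or the \code{trial_table} (read).
#' @export
write_trial_table <- function(design, path) {
  validate_design(design)
  out <- as.data.frame(design)
  for (b in c("probe_match", "accuracy")) {
    out[[b]] <- ifelse(is.na(out[[b]]), NA_integer_,
                       as.integer(as.logical(out[[b]])))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (b in c("probe_match", "accuracy")) {
    if (!is.null(tab[[b]])) tab[[b]] <- as.logical(tab[[b]])
  }
  validate_design(tab)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Write / read an RDM as a labelled square CSV
#'
#' @param rdm An \code{rdm} object (or square matrix with labels).
#' @param path CSV path; the header row carries the condition labels.
#' @return \code{path} invisibly (write); an \code{rdm} (read).
#' @export
write_rdm <- function(rdm, path) {
  v <- if (inherits(rdm, "rdm")) rdm$values else as.matrix(rdm)
  labels <- if (inherits(rdm, "rdm")) rdm$labels else colnames(rdm)
  colnames(v) <- labels
  utils::write.csv(as.data.frame(v), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  v <- as.matrix(df)
  structure(list(values = unname(v), labels = colnames(df),
                 n_conditions = ncol(v), k = NA_integer_,
                 n_reps = NA_integer_),
            class = "rdm")
}

#' Write / read epochs as a raw binary array with a JSON sidecar
#'
#' The array is stored as little-endian doubles in trial-major order; the
#' sidecar (same path plus \code{.json}) records dimensions, channel names,
#' times and sampling rate.
#'
#' @param ep An \code{\link{epochs}} object.
#' @param path Output path for the binary payload (e.g. \code{"x.dat"}).
#' @return \code{path} invisibly (write); an \code{epochs} (read).
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "epochs"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(ep$data), con, size = 8L, endian = "little")
  meta <- list(dim = dim(ep$data), channel_names = ep$channel_names,
               times = ep$times, srate = ep$srate,
               impulse_tag = ep$impulse_tag)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  epochs(array(x, dim = meta$dim), channel_names = meta$channel_names,
         times = meta$times, srate = meta$srate,
         impulse_tag = meta$impulse_tag)
}

#' Load and validate a battery run configuration
#'
#' Plain-text YAML configuration for \code{\link{run_scenario_battery}}.
#' Recognised fields (with defaults): \code{seed}, \code{scenarios},
#' \code{n_subjects}, \code{n_trials}, \code{k_folds}, \code{n_reps},
#' \code{null_reps}, \code{n_perm}, \code{decode_reps},
#' \code{include_rotation_signal}, \code{amplitude}, \code{output_dir}.
#'
#' @param path YAML file path.
#' @return Validated named list of settings.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(scenarios = c("rotated_only", "partial_rotation",
                                 "same_scheme_both", "same_scheme_one",
                                 "unique_scheme_both", "unique_scheme_one"),
                   n_subjects = 30L, n_trials = 1440L, k_folds = 8L,
                   n_reps = 10L, null_reps = 1L, n_perm = 200L,
                   decode_reps = 10L, include_rotation_signal = FALSE,
                   amplitude = 1, output_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$seed)) stop("config must set 'seed'", call. = FALSE)
  counts <- c("n_subjects", "n_trials", "k_folds", "n_reps", "null_reps",
              "n_perm", "decode_reps")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop("config field '", nm, "' must be a count >= 1", call. = FALSE)
    }
  }
  if (cfg$n_trials %% 360 != 0) {
    stop("n_trials must be a multiple of 360", call. = FALSE)
  }
  bad <- setdiff(cfg$scenarios,
                 c("rotated_only", "partial_rotation", "same_scheme_both",
                   "same_scheme_one", "unique_scheme_both",
                   "unique_scheme_one"))
  if (length(bad)) stop("unknown scenario(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg
}

#' Run a configured scenario battery and write its outputs
#'
#' Convenience orchestration: runs \code{\link{run_scenario_battery}} from a
#' configuration (path or list), writes the results table and the
#' per-subject statistics as CSV into \code{output_dir}, plus a JSON
#' manifest recording every setting and the md5 of each written file.
#'
#' @param config Path to a YAML config or a list from
#'   \code{\link{load_run_config}}.
#' @param output_dir Overrides the config's output directory if given.
#' @return The \code{scenario_battery} object, invisibly.
#' @export
run_battery_config <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) load_run_config(config) else config
  dir <- if (!is.null(output_dir)) output_dir else cfg$output_dir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  bat <- run_scenario_battery(
    scenarios = cfg$scenarios, n_subjects = cfg$n_subjects,
    n_trials = cfg$n_trials, n_reps = cfg$n_reps,
    null_reps = cfg$null_reps, n_perm = cfg$n_perm,
    decode_reps = cfg$decode_reps, k = cfg$k_folds,
    include_rotation_signal = cfg$include_rotation_signal,
    amplitude = cfg$amplitude, seed = cfg$seed)
  res_path <- file.path(dir, "battery_results.csv")
  utils::write.csv(bat$results, res_path, row.names = FALSE)
  subj <- do.call(rbind, lapply(names(bat$subject), function(sc) {
    b <- bat$subject[[sc]]$betas
    data.frame(scenario = sc, subject = seq_len(nrow(b)), b,
               fisher_z = bat$subject[[sc]]$fisher_z)
  }))
  subj_path <- file.path(dir, "battery_subjects.csv")
  utils::write.csv(subj, subj_path, row.names = FALSE)
  manifest <- list(settings = bat$settings,
                   files = as.list(tools::md5sum(c(res_path, subj_path))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bat)
}
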