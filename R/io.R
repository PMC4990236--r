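# File I/O and reproducible-run plumbing. Plain-text CSV is the canonical
# interchange; JSON manifests record the resolved configuration and seed.

#' Read a waveform from CSV
#'
#' Accepts a two-column CSV `(time_s, mv)` — the sampling rate is inferred
#' from the uniform time spacing — or a single-column sample stream with `fs`
#' supplied. Rows with non-finite voltage are dropped with a warning giving
#' the count.
#'
#' @param path CSV file path.
#' @param fs Sampling rate (Hz); required for single-column input, checked
#'   against the time column otherwise.
#' @param subject_id Label for the record (default: file name without
#'   extension).
#' @return A [waveform_record()].
#' @export
read_waveform <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (ncol(df) >= 2L) {
    t <- as.numeric(df[[1L]]); v <- as.numeric(df[[2L]])
    dt <- diff(t)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      stop("time column must be strictly increasing")
    }
    if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
      stop("time column is not uniformly spaced")
    }
    fs_inferred <- 1 / stats::median(dt)
    if (!is.null(fs) && abs(fs - fs_inferred) > 1e-6 * fs) {
      stop(sprintf("supplied fs = %g Hz disagrees with time column (%g Hz)",
                   fs, fs_inferred))
    }
    fs <- fs_inferred
    t0 <- t[1L]
  } else {
    if (is.null(fs)) stop("single-column waveform input requires 'fs'")
    v <- as.numeric(df[[1L]])
    t0 <- 0
  }
  bad <- !is.finite(v)
  if (any(bad)) {
    warning(sprintf("dropped %d non-finite sample row(s)", sum(bad)))
    v <- v[!bad]
  }
  waveform_record(v, fs, subject_id, t0 = t0)
}

#' Write a waveform to two-column CSV
#'
#' @param record A [waveform_record()].
#' @param path Output CSV path (`time_s`, `mv`).
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  n <- length(record$samples)
  utils::write.csv(
    data.frame(time_s = record$t0 + (seq_len(n) - 1) / record$fs,
               mv = record$samples),
    path, row.names = FALSE)
  invisible(path)
}

# canonical physiological panel fields a column map may address
physio_fields <- c("subject_id", "timepoint", "map_mmHg", "rap_mmHg",
                   "lad_flow", "cao2_mldl", "cvo2_mldl", "lac_a_mM",
                   "lac_v_mM", "paco2_mmHg", "pvco2_mmHg")

#' Read a per-timepoint physiological panel from CSV
#'
#' @param path CSV path, one row per (subject, timepoint).
#' @param column_map Named character vector mapping canonical field names
#'   (see details) to the file's column names; canonical names already
#'   present in the file need no mapping. Unmapped extra columns are
#'   dropped with a message.
#' @details Canonical fields: `subject_id`, `timepoint`, `map_mmHg`,
#'   `rap_mmHg`, `lad_flow`, `cao2_mldl`, `cvo2_mldl`, `lac_a_mM`,
#'   `lac_v_mM`, `paco2_mmHg`, `pvco2_mmHg`. Any subset may be present;
#'   downstream operations error cleanly on fields they need but lack.
#' @return Data frame with canonical column names.
#' @export
read_physio_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("physiological table is empty")
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("mapped column(s) not in file: %s",
                   paste(missing_cols, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      df[[canon]] <- df[[column_map[[canon]]]]
    }
  }
  keep <- intersect(physio_fields, names(df))
  dropped <- setdiff(names(df), c(keep, unname(column_map)))
  if (length(dropped) > 0) {
    message(sprintf("ignoring unmapped column(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  df[, keep, drop = FALSE]
}

#' Assemble a run configuration
#'
#' Bundles every tunable of a pipeline run — spectral analysis settings,
#' generator profile and spec, statistics options, seed — into one
#' serializable object so a run can be reproduced from its manifest.
#'
#' @param spectral A [spectral_config()].
#' @param profile A [vf_profile()].
#' @param generator A [generator_spec()].
#' @param n_subjects Cohort size.
#' @param alpha,alpha_strict Significance tiers for pairwise annotation.
#' @param seed Master seed (overrides `generator$seed` when given).
#' @return An object of class `run_config`.
#' @export
run_config <- function(spectral = spectral_config(),
                       profile = default_paper_profile(),
                       generator = generator_spec(),
                       n_subjects = 16, alpha = 0.05, alpha_strict = 0.001,
                       seed = NULL) {
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(
    list(spectral = spectral, profile = profile, generator = generator,
         n_subjects = as.integer(n_subjects), alpha = alpha,
         alpha_strict = alpha_strict, seed = generator$seed),
    class = "run_config"
  )
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  plain <- list(
    spectral = unclass(config$spectral),
    profile = list(minute = config$profile$minute,
                   target_amsa = config$profile$target_amsa,
                   center_freq = config$profile$center_freq,
                   bandwidth = config$profile$bandwidth),
    generator = unclass(config$generator),
    n_subjects = config$n_subjects, alpha = config$alpha,
    alpha_strict = config$alpha_strict, seed = config$seed)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    spectral = do.call(spectral_config, y$spectral),
    profile = vf_profile(data.frame(minute = y$profile$minute,
                                    target_amsa = y$profile$target_amsa),
                         center_freq = y$profile$center_freq,
                         bandwidth = y$profile$bandwidth),
    generator = do.call(generator_spec, y$generator),
    n_subjects = y$n_subjects, alpha = y$alpha,
    alpha_strict = y$alpha_strict, seed = y$seed)
}

#' Minute-mean AMSA table for a cohort of records
#'
#' Runs [amsa_timeseries()] on each record and assembles the subjects x
#' minutes matrix of minute-mean AMSA.
#'
#' @param records List of [waveform_record()].
#' @param config A [spectral_config()].
#' @return A [cohort_table()] with minute labels `"1"`, `"2"`, ...
#' @export
cohort_minute_table <- function(records, config = spectral_config()) {
  series <- lapply(records, amsa_timeseries, config = config)
  minutes <- sort(unique(unlist(lapply(series, `[[`, "minute"))))
  m <- matrix(NA_real_, length(series), length(minutes),
              dimnames = list(vapply(series, `[[`, "", "subject_id"),
                              as.character(minutes)))
  for (i in seq_along(series)) {
    s <- series[[i]]
    m[i, as.character(s$minute)] <- s$minute_amsa
  }
  cohort_table(m)
}

#' Run the simulate-analyze-summarize pipeline end to end
#'
#' Generates a synthetic cohort from the configured profile, computes every
#' subject's minute-mean AMSA trajectory with the spectral pipeline, and
#' compares the cohort-mean trajectory with the profile knots.
#'
#' @param config A [run_config()]; defaults to the published three-phase
#'   profile with 16 subjects.
#' @return List with `minute_table` (a [cohort_table()]), `scales`
#'   (per-subject offsets), `summary` (per-minute descriptives), and
#'   `knots` (data frame `minute`, `target_amsa`, `cohort_mean`,
#'   `relative_error`).
#' @export
reproduce_profile <- function(config = run_config()) {
  gen <- config$generator
  need_s <- max(config$profile$minute) * 60
  if (gen$duration_s < need_s) gen$duration_s <- need_s
  cohort <- generate_cohort(config$n_subjects, config$profile, gen,
                            config$spectral)
  tab <- cohort_minute_table(cohort$records, config$spectral)
  des <- descriptives(tab)
  knot_lab <- as.character(config$profile$minute)
  cohort_mean <- des$mean[match(knot_lab, des$timepoint)]
  knots <- data.frame(
    minute = config$profile$minute,
    target_amsa = config$profile$target_amsa,
    cohort_mean = cohort_mean,
    relative_error = abs(cohort_mean - config$profile$target_amsa) /
      config$profile$target_amsa)
  list(minute_table = tab, scales = cohort$scales, summary = des,
       knots = knots)
}

#' Write a JSON run manifest
#'
#' Records the resolved configuration, package version, seed and input file
#' digests so deterministic stages can be reproduced bit for bit.
#'
#' @param config A [run_config()].
#' @param path Output JSON path.
#' @param inputs Optional character vector of input file paths to digest
#'   (md5).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, inputs = character(0)) {
  manifest <- list(
    package = "vfwave",
    version = as.character(utils::packageVersion("vfwave")),
    seed = config$seed,
    spectral = unclass(config$spectral),
    profile = list(minute = config$profile$minute,
                   target_amsa = config$profile$target_amsa,
                   center_freq = config$profile$center_freq,
                   bandwidth = config$profile$bandwidth),
    generator = unclass(config$generator),
    n_subjects = config$n_subjects,
    inputs = if (length(inputs) > 0) {
      data.frame(path = inputs, md5 = tools::md5sum(inputs),
                 row.names = NULL)
    } else NULL
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
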