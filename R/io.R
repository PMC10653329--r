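#' Read a tap-table CSV into tapping trials
#'
#' Reads the package's tap-table schema — one row per tap with columns
#' `trial_id`, `tempo_bpm`, `first_beat_time_s`, `cue_time_s`, `tap_time_s`
#' (times in seconds) — and groups rows into [tap_trial()] objects. Row
#' order within the file is irrelevant: taps are sorted by time within each
#' trial. Duplicate timestamps within a trial, missing columns, or
#' non-numeric fields raise structured errors naming the offending trial or
#' column.
#'
#' @param path Path to the CSV file.
#' @return Named list of [tap_trial()] objects (names = trial ids, in order
#'   of first appearance).
#' @export
read_taps_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_id", "tempo_bpm", "first_beat_time_s", "cue_time_s",
              "tap_time_s")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in needed[-1]) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("column ", col, " is not numeric (first bad row: ",
           if (length(bad)) bad[1] else "?", ")")
    }
  }
  ids <- unique(df$trial_id)
  trials <- lapply(ids, function(id) {
    d <- df[df$trial_id == id, ]
    if (length(unique(d$tempo_bpm)) != 1 ||
        length(unique(d$cue_time_s)) != 1 ||
        length(unique(d$first_beat_time_s)) != 1) {
      stop("trial ", id, ": tempo, cue and first-beat time must be constant",
           " within a trial")
    }
    tt <- sort(d$tap_time_s)
    if (anyDuplicated(tt)) {
      stop("trial ", id, ": duplicate tap timestamp at ",
           tt[which(duplicated(tt))[1]], " s")
    }
    tap_trial(trial_id = id, tempo_bpm = d$tempo_bpm[1],
              cue_time = d$cue_time_s[1], tap_times = tt,
              first_beat_time = d$first_beat_time_s[1])
  })
  stats::setNames(trials, ids)
}

#' Write tapping trials to the tap-table CSV schema
#'
#' @param trials A list of [tap_trial()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_taps_csv <- function(trials, path) {
  df <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, tempo_bpm = tr$tempo_bpm,
               first_beat_time_s = tr$first_beat_time,
               cue_time_s = tr$cue_time, tap_time_s = tr$tap_times,
               stringsAsFactors = FALSE)
  }))
  write_csv6(df, path)
  invisible(path)
}

#' Write classification results, summaries, and a run manifest
#'
#' Writes three files into `dir`: `trials.csv` (per-trial classification),
#' `summary.csv` (per-tempo outcome counts and proportions), and
#' `manifest.json` (package version, seed, and the full effective
#' configuration, so any run can be reconstructed from its manifest).
#' Empty outcome lists yield valid header-only tables.
#'
#' @param outcomes List of `trial_outcome` objects (possibly empty).
#' @param dir Output directory (created if needed).
#' @param config Named list echoed into the manifest.
#' @param seed Seed recorded in the manifest (`NA` for deterministic runs).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_results <- function(outcomes, dir, config = list(), seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             summary = file.path(dir, "summary.csv"),
             manifest = file.path(dir, "manifest.json"))
  if (length(outcomes)) {
    df <- outcomes_to_df(outcomes)
    summ <- summarize_dataset(df)$by_tempo
  } else {
    df <- data.frame(trial_id = character(0), tempo_bpm = numeric(0),
                     laps = integer(0), outcome = character(0),
                     subtype = character(0), taps_in_window = integer(0),
                     taps_per_lap = numeric(0))
    summ <- data.frame(tempo_bpm = numeric(0), n_successful = integer(0),
                       n_unsuccessful = integer(0), n_incomplete = integer(0),
                       n_noncompliant = integer(0), p_successful = numeric(0),
                       p_unsuccessful = numeric(0), p_incomplete = numeric(0))
  }
  write_csv6(df, paths[["trials"]])
  write_csv6(summ, paths[["summary"]])
  manifest <- list(package = "phasing",
                   version = as.character(utils::packageVersion("phasing")),
                   seed = seed, n_trials = length(outcomes), config = config)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

# CSV writer with a fixed numeric format: seconds and radians to 6 decimal
# places, so outputs are diff-able and bit-identical across runs.
write_csv6 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          sprintf("%.6f", out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
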