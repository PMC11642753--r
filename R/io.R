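## Delimited-text interchange for cohorts: spikes.csv, units.csv, trials.csv
## (header row, UTF-8, '.' decimal) plus manifest.json.

#' Write a cohort to delimited-text files
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing files? Defaults to `FALSE`; existing
#'   outputs are never clobbered silently.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("spikes.csv", "units.csv", "trials.csv",
                            "manifest.json"))
  if (!overwrite && any(file.exists(paths)))
    stop("output files exist in ", dir, "; use overwrite = TRUE")
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    df
  }
  write.csv(fmt(cohort$spikes), paths[1], row.names = FALSE, quote = FALSE)
  write.csv(cohort$units, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(fmt_trials(cohort$trials), paths[3], row.names = FALSE, quote = FALSE)
  man <- cohort$manifest
  jsonlite::write_json(man, paths[4], dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

fmt_trials <- function(tr) {
  tr$event_time_s <- sprintf("%.6f", tr$event_time_s)
  tr
}

read_numeric_column <- function(x, col, file) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "" & x != "NA")
  if (length(bad))
    stop(sprintf("%s: malformed numeric value '%s' in column '%s', row %d",
                 file, x[bad[1]], col, bad[1]))
  v
}

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(file, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read a cohort (or any compatible spike/unit/trial tables) from disk
#'
#' Validates required columns and numeric fields, reporting the offending row
#' on parse failure. The manifest, if present, is attached.
#'
#' @param dir Directory containing `spikes.csv`, `units.csv`, `trials.csv`
#'   and optionally `manifest.json`.
#' @return A list of class `cohort` with `spikes`, `units`, `trials` and
#'   (possibly `NULL`) `manifest`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  sp <- require_columns(rd("spikes.csv"),
                        c("recording_id", "unit_id", "spike_time_s"), "spikes.csv")
  sp$spike_time_s <- read_numeric_column(sp$spike_time_s, "spike_time_s", "spikes.csv")
  if (any(sp$spike_time_s < 0)) stop("spikes.csv: negative spike time")
  un <- require_columns(rd("units.csv"),
                        c("recording_id", "unit_id", "area", "depth_frac",
                          "is_single"), "units.csv")
  un$depth_frac <- read_numeric_column(un$depth_frac, "depth_frac", "units.csv")
  un$is_single <- as.logical(un$is_single)
  if ("is_pv_true" %in% names(un)) un$is_pv_true <- as.logical(un$is_pv_true)
  tr <- require_columns(rd("trials.csv"),
                        c("recording_id", "event_time_s", "protocol"), "trials.csv")
  tr$event_time_s <- read_numeric_column(tr$event_time_s, "event_time_s", "trials.csv")
  if ("lag_ms" %in% names(tr))
    tr$lag_ms <- read_numeric_column(tr$lag_ms, "lag_ms", "trials.csv")
  if ("intensity_frac" %in% names(tr))
    tr$intensity_frac <- read_numeric_column(tr$intensity_frac, "intensity_frac",
                                             "trials.csv")
  if ("hand_on" %in% names(tr)) tr$hand_on <- as.logical(tr$hand_on)
  bad <- !sp$unit_id %in% un$unit_id
  if (any(bad))
    stop("spikes.csv: unit id not present in units.csv: ", sp$unit_id[which(bad)[1]])
  man_path <- file.path(dir, "manifest.json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path, simplifyVector = TRUE)
         else NULL
  for (el in c("ground_truth", "probe_geometry"))
    if (!is.null(man) && !is.null(man[[el]]))
      man[[el]] <- as.data.frame(man[[el]])
  structure(list(spikes = sp, units = un, trials = tr, manifest = man),
            class = "cohort")
}
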