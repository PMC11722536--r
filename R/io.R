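# Schema-validated table IO. All tables are UTF-8 CSV with a header row and
# units encoded in column names (time_h, time_min, length_um). Validation
# never partially succeeds silently: either a fully typed tibble is returned
# or an error listing the offending line numbers is raised.

table_schemas <- list(
  killcurve = list(
    columns = c(condition = "character", antibiotic = "character",
                replicate = "character", time_h = "numeric",
                cfu_per_ml = "numeric", lod = "numeric"),
    group = c("condition", "antibiotic", "replicate"),
    time_col = "time_h"
  ),
  tracks = list(
    columns = c(track_id = "character", frame = "numeric",
                time_min = "numeric", length_um = "numeric",
                fluor_au = "numeric", division = "numeric"),
    group = "track_id",
    time_col = "time_min"
  ),
  events = list(
    columns = c(sample = "character", value = "numeric"),
    group = NULL, time_col = NULL
  )
)

#' Read and validate a pipeline table
#'
#' Parses a CSV file against one of the package schemas (`"killcurve"`,
#' `"tracks"`, `"events"`) and either returns the fully typed tibble or
#' raises an error listing every offending file line (missing columns,
#' non-numeric fields, negative counts/lengths, non-monotone times within a
#' series).
#'
#' @param path CSV file path.
#' @param schema_name one of `"killcurve"`, `"tracks"`, `"events"`.
#' @return A typed tibble. On failure, an error of class
#'   `persistkit_validation_error` whose condition carries the issue table
#'   (`line`, `problem`).
#' @export
validate_table <- function(path, schema_name) {
  if (!schema_name %in% names(table_schemas)) {
    stop("unknown schema '", schema_name, "'; expected one of ",
         paste(names(table_schemas), collapse = ", "))
  }
  sch <- table_schemas[[schema_name]]
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  issues <- list()
  add <- function(line, problem) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(line = line,
                                                     problem = problem)
  }
  miss <- setdiff(names(sch$columns), names(raw))
  if (length(miss)) {
    add(1L, paste("missing column(s):", paste(miss, collapse = ", ")))
    validation_stop(path, do.call(rbind, issues))
  }
  out <- raw[names(sch$columns)]
  for (col in names(sch$columns)) {
    if (sch$columns[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(is.na(v) & !is.na(out[[col]]) | is.na(out[[col]]))
      for (i in bad) add(i + 1L, paste0("non-numeric or missing ", col,
                                        ": '", out[[col]][i], "'"))
      out[[col]] <- v
    }
  }
  if (!length(issues)) {
    if (schema_name == "killcurve") {
      for (i in which(out$cfu_per_ml < 0)) add(i + 1L, "negative CFU count")
      for (i in which(out$lod <= 0)) add(i + 1L, "non-positive lod")
      for (i in which(out$time_h < 0)) add(i + 1L, "negative time")
    }
    if (schema_name == "tracks") {
      for (i in which(out$length_um <= 0)) add(i + 1L, "non-positive length")
      for (i in which(out$fluor_au < 0)) add(i + 1L, "negative fluorescence")
      for (i in which(!out$division %in% c(0, 1))) {
        add(i + 1L, "division flag must be 0 or 1")
      }
    }
    if (schema_name == "events") {
      for (i in which(!is.finite(out$value))) add(i + 1L, "non-finite value")
    }
    if (!is.null(sch$group) && !length(issues)) {
      key <- do.call(paste, c(out[sch$group], sep = "\r"))
      tv <- out[[sch$time_col]]
      for (g in unique(key)) {
        idx <- which(key == g)
        bad <- idx[which(diff(tv[idx]) <= 0) + 1L]
        for (i in bad) {
          add(i + 1L, paste0("non-increasing ", sch$time_col, " within ",
                             paste(sch$group, collapse = "/"), " series"))
        }
      }
    }
  }
  if (length(issues)) validation_stop(path, do.call(rbind, issues))
  out
}

validation_stop <- function(path, issues) {
  shown <- utils::head(issues, 20)
  msg <- paste0(
    "validation of '", path, "' failed with ", nrow(issues), " issue(s):\n",
    paste(sprintf("  line %d: %s", shown$line, shown$problem),
          collapse = "\n"),
    if (nrow(issues) > 20) "\n  ..." else "")
  cond <- structure(
    class = c("persistkit_validation_error", "error", "condition"),
    list(message = msg, call = NULL, issues = issues))
  stop(cond)
}

#' Read kill curves from CSV
#'
#' Validates against the kill-curve schema and splits into one
#' [kill_curve()] object per condition/antibiotic pair.
#'
#' @param path CSV file path.
#' @return Named list of `kill_curve` objects.
#' @export
read_kill_curves <- function(path) {
  tab <- validate_table(path, "killcurve")
  key <- paste(tab$condition, tab$antibiotic, sep = "/")
  lapply(split(tab, key), kill_curve)
}

#' Read single-cell tracks from CSV
#'
#' @param path CSV file path (track schema).
#' @return A validated tibble (use [analyze_tracks()] or [cell_track()]).
#' @export
read_tracks <- function(path) validate_table(path, "tracks")

#' Read cytometry events from CSV
#'
#' @param path CSV file path (event schema).
#' @return Named list of [event_table()] objects, one per sample.
#' @export
read_events <- function(path) {
  tab <- validate_table(path, "events")
  lapply(split(tab, tab$sample), event_table)
}

#' Write a run manifest
#'
#' Every pipeline output directory contains exactly one `manifest.json`
#' recording the configuration hash, master seed, software version, file
#' inventory and timestamp.
#'
#' @param out_dir output directory.
#' @param config the pipeline configuration list.
#' @param seed master seed.
#' @param files character vector of files written.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, seed, files) {
  manifest <- list(
    tool = "persistkit",
    version = as.character(utils::packageVersion("persistkit")),
    seed = seed,
    config_hash = config_hash(config),
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
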