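#' Read a generic track CSV
#'
#' Reads a comma-separated table of tracked positions into a track table.
#' Column names are mapped through `column_map`, so exports from arbitrary
#' tracking tools can be ingested by naming which of their columns hold the
#' track identifier, frame number and coordinates.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping the roles `track_id`,
#'   `frame`, `x`, `y` (and optionally `group`) to column names in the file.
#' @param frame_interval Minutes between consecutive frames (default 20).
#'
#' @return A track table (tibble) as described in [as_tracks()], with the
#'   frame interval attached as the `frame_interval` attribute.
#'
#' @details Frames are shifted so the smallest frame in the file becomes 0.
#'   Rows may appear in any order; the result is sorted. Duplicate
#'   `(track_id, frame)` rows are an integrity error.
#' @export
read_tracks <- function(path,
                        column_map = c(track_id = "track_id", frame = "frame",
                                       x = "x_um", y = "y_um"),
                        frame_interval = 20) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "saltatr_io_error")
  }
  stopifnot(frame_interval > 0)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  roles <- c("track_id", "frame", "x", "y")
  missing_roles <- setdiff(roles, names(column_map))
  if (length(missing_roles) > 0) {
    abort(paste0("column_map must name columns for: ",
                 paste(missing_roles, collapse = ", ")),
          class = "saltatr_format_error")
  }
  missing_cols <- setdiff(unname(column_map[roles]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "saltatr_format_error")
  }
  out <- tibble(
    track_id = as.character(raw[[column_map[["track_id"]]]]),
    frame    = parse_numeric_col(raw[[column_map[["frame"]]]], column_map[["frame"]]),
    x        = parse_numeric_col(raw[[column_map[["x"]]]], column_map[["x"]]),
    y        = parse_numeric_col(raw[[column_map[["y"]]]], column_map[["y"]])
  )
  if ("group" %in% names(column_map) && column_map[["group"]] %in% names(raw)) {
    out$group <- as.character(raw[[column_map[["group"]]]])
  }
  out$frame <- out$frame - min(out$frame)
  out <- as_tracks(out)
  attr(out, "frame_interval") <- frame_interval
  out
}

parse_numeric_col <- function(v, name) {
  num <- suppressWarnings(as.numeric(as.character(v)))
  bad <- which(is.na(num) & !is.na(v))
  if (length(bad) > 0) {
    abort(paste0("non-numeric value '", v[bad[1]], "' in column '", name,
                 "' at data row ", bad[1]),
          class = "saltatr_parse_error")
  }
  num
}

#' Read an Imaris spots statistics CSV export
#'
#' Parses the "Position" sheet of an Imaris statistics CSV export: a short
#' preamble (title and/or blank lines) precedes the real column-header row,
#' which contains `Position X`, `Position Y`, `Time` and `TrackID` columns
#' (possibly with suffixes such as units in brackets). The preamble length
#' is auto-detected by scanning for the header row.
#'
#' @inheritParams read_tracks
#' @return A track table, identical in contract to [read_tracks()]; the
#'   `Time` column is converted to a 0-based frame index.
#' @details A unit annotation other than micrometres on the position columns
#'   triggers a warning (coordinates are passed through unconverted). Any Z
#'   column is ignored: the package analyses 2D (projected) tracks.
#' @export
read_imaris_tracks <- function(path, frame_interval = 20) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "saltatr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  header_i <- which(grepl("Position X", lines) & grepl("TrackID", lines))[1]
  if (is.na(header_i)) {
    abort(paste0("could not locate the Imaris column-header row (needs ",
                 "'Position X' and 'TrackID') in ", path),
          class = "saltatr_dialect_error")
  }
  unit_lines <- lines[seq_len(min(header_i + 1, length(lines)))]
  if (any(grepl("\\b(mm|nm)\\b", unit_lines)) &&
      !any(grepl("um|µm|μm|micron", unit_lines, ignore.case = TRUE))) {
    warn("Imaris export does not appear to use micrometre units; coordinates passed through unconverted")
  }
  raw <- readr::read_csv(I(paste(lines[header_i:length(lines)], collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  find_col <- function(prefix) {
    hit <- which(startsWith(trimws(names(raw)), prefix))
    if (length(hit) == 0) {
      abort(paste0("Imaris export lacks a '", prefix, "' column"),
            class = "saltatr_dialect_error")
    }
    hit[1]
  }
  out <- tibble(
    track_id = as.character(raw[[find_col("TrackID")]]),
    frame    = parse_numeric_col(raw[[find_col("Time")]], "Time"),
    x        = parse_numeric_col(raw[[find_col("Position X")]], "Position X"),
    y        = parse_numeric_col(raw[[find_col("Position Y")]], "Position Y")
  )
  out$frame <- out$frame - min(out$frame)
  out <- as_tracks(out)
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Write / read a per-track feature table
#'
#' `write_feature_table()` serialises a feature table (one row per track:
#' `track_id`, `group`, then the descriptor columns) to CSV with a sidecar
#' comment line recording descriptor units. `read_feature_table()` reads it
#' back; numeric values round-trip to within 1e-9 relative tolerance.
#'
#' @param features A feature table, e.g. from [compute_features()].
#' @param path Output (input) CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature table as a tibble.
#' @details Columns in the file that are not in the active descriptor
#'   registry are preserved on read with a warning.
#' @export
write_feature_table <- function(features, path) {
  reg <- feature_registry()
  units <- setNames(reg$unit, reg$name)
  known <- intersect(names(features), reg$name)
  header <- paste0("# units: ",
                   paste(paste0(known, "=", units[known]), collapse = ";"))
  writeLines(c(header, readr::format_csv(features)), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "saltatr_io_error")
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  extra <- setdiff(names(out), c("track_id", "group", feature_registry()$name))
  if (length(extra) > 0) {
    warn(paste0("feature table contains column(s) outside the descriptor ",
                "registry, preserved as metadata: ",
                paste(extra, collapse = ", ")))
  }
  out$track_id <- as.character(out$track_id)
  out
}
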