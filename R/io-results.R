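RESULT_COLUMNS <- c(
  "frame", "time_s", "muscle", "length_mm", "moment_arm_mm",
  "ma_elevation_mm", "ma_plane_mm", "ma_axial_mm",
  "departure_x", "departure_y", "departure_z",
  "uvec_x", "uvec_y", "uvec_z", "flags"
)

#' Assemble one moment-arm record
#'
#' @param frame 0-based frame number.
#' @param time_s time in seconds (NA when the motion carries no timestamps).
#' @param muscle muscle line identifier.
#' @param length_mm muscle length.
#' @param moment_arm_mm resultant moment arm.
#' @param ma_elevation_mm,ma_plane_mm,ma_axial_mm decomposed components.
#' @param departure_point,departure_uvec departure point and line-of-action
#'   unit vector (length-3).
#' @param flags character vector of flag tokens
#'   (`no_contact`, `unconverged`, `buckling`, `departure_jump`).
#' @return A one-row data frame with the package's result schema.
#' @export
moment_arm_record <- function(frame, time_s, muscle, length_mm, moment_arm_mm,
                              ma_elevation_mm = NA_real_, ma_plane_mm = NA_real_,
                              ma_axial_mm = NA_real_,
                              departure_point = c(NA_real_, NA_real_, NA_real_),
                              departure_uvec = c(NA_real_, NA_real_, NA_real_),
                              flags = character(0)) {
  data.frame(
    frame = as.integer(frame), time_s = as.numeric(time_s), muscle = as.character(muscle),
    length_mm = length_mm, moment_arm_mm = moment_arm_mm,
    ma_elevation_mm = ma_elevation_mm, ma_plane_mm = ma_plane_mm,
    ma_axial_mm = ma_axial_mm,
    departure_x = departure_point[1], departure_y = departure_point[2],
    departure_z = departure_point[3],
    uvec_x = departure_uvec[1], uvec_y = departure_uvec[2], uvec_z = departure_uvec[3],
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Write moment-arm records to CSV
#'
#' One row per frame x muscle (x mode when a `mode` column is present), with
#' the fixed column schema `frame, time_s, muscle, length_mm, moment_arm_mm,
#' ma_elevation_mm, ma_plane_mm, ma_axial_mm, departure_x/y/z, uvec_x/y/z,
#' flags`.
#'
#' @param records data frame of records ([moment_arm_record] rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    warning("writing header-only results file (no records)")
    writeLines(paste(RESULT_COLUMNS, collapse = ","), path)
    return(invisible(path))
  }
  cols <- RESULT_COLUMNS
  if ("mode" %in% names(records)) cols <- c(cols, "mode")
  missing <- setdiff(cols, names(records))
  if (length(missing)) stop("records are missing columns: ", paste(missing, collapse = ", "))
  write.csv(records[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}
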