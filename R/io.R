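schema_check <- function(df, required, what) {
  if (!is.data.frame(df)) stop(what, " table must be a data.frame", call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- setdiff(required, c("trial_id", "bone", "joint", "marker_id",
                             "camera_id"))
  for (col in num)
    if (!is.numeric(df[[col]]))
      stop("schema error in ", what, " table: column '", col,
           "' is not numeric", call. = FALSE)
  invisible(df)
}

marker_cols <- c("trial_id", "frame", "marker_id", "x_mm", "y_mm", "z_mm")
marker2d_cols <- c("trial_id", "frame", "camera_id", "marker_id",
                   "u_px", "v_px")
pose_cols <- c("trial_id", "frame", "bone", "r11", "r12", "r13",
               "r21", "r22", "r23", "r31", "r32", "r33",
               "tx_mm", "ty_mm", "tz_mm")
angle_cols <- c("trial_id", "frame", "joint", "tx_mm", "ty_mm", "tz_mm",
                "rz_deg", "ry_deg", "rx_deg")

check_marker_df <- function(df) schema_check(df, marker_cols, "marker")
check_pose_df <- function(df) schema_check(df, pose_cols, "pose")
check_angle_df <- function(df) schema_check(df, angle_cols, "angle")

# Unit discipline: units live in the column names (mm, px, deg).  A file
# whose headers carry other unit suffixes is rejected as a unit mismatch
# rather than silently reinterpreted.
check_units <- function(header, what) {
  bad <- grep("_(rad|m|cm|in)$", header, value = TRUE)
  if (length(bad))
    stop("unit error in ", what, " file: column(s) ",
         paste(bad, collapse = ", "),
         " are not in the required units (mm / px / deg)", call. = FALSE)
}

write_table_csv <- function(df, path, meta = list()) {
  con <- file(path, open = "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con, sep = "\n")
  # 17 significant digits guarantee a lossless double round trip
  out <- df
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

read_table_csv <- function(path, required, what) {
  lines <- readLines(path, n = 200L)
  hdr_i <- which(!startsWith(lines, "#"))[1]
  if (is.na(hdr_i)) stop("schema error: ", what, " file has no header",
                         call. = FALSE)
  meta_lines <- lines[seq_len(hdr_i - 1L)][startsWith(lines[seq_len(hdr_i - 1L)], "#")]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*:\\s*", "", kv)
    meta[[k]] <- v
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_units(names(df), what)
  schema_check(df, required, what)
  if ("frame" %in% names(df)) {
    fr <- sort(unique(df$frame))
    if (length(fr) > 1L && any(diff(fr) != 1L))
      stop("schema error in ", what,
           " table: column 'frame' is not uniformly numbered", call. = FALSE)
  }
  attr(df, "meta") <- meta
  df
}

#' Read and write kinematic tables as CSV
#'
#' All kinematic tables travel as plain CSV with units fixed by the column
#' names (`_mm`, `_px`, `_deg`) and provenance (seed, configuration hash,
#' stage history) embedded as `# key: value` comment lines.  Round trips
#' are lossless at full double precision, and identical inputs produce
#' byte-identical files.
#'
#' Schemas: markers `trial_id, frame, marker_id, x_mm, y_mm, z_mm`
#' (2D variant `trial_id, frame, camera_id, marker_id, u_px, v_px`);
#' poses `trial_id, frame, bone, r11..r33, tx_mm, ty_mm, tz_mm`; angles
#' `trial_id, frame, joint, tx_mm, ty_mm, tz_mm, rz_deg, ry_deg, rx_deg`.
#'
#' @param df table in the matching schema.
#' @param path file path.
#' @param meta named list of provenance strings written as header
#'   comments.
#' @return Readers return the table with the parsed provenance in
#'   `attr(, "meta")`; writers return `path` invisibly.
#' @name kinematic_csv
NULL

#' @rdname kinematic_csv
#' @export
write_marker_csv <- function(df, path, meta = list()) {
  check_marker_df(df)
  write_table_csv(df, path, meta)
}

#' @rdname kinematic_csv
#' @export
read_marker_csv <- function(path) read_table_csv(path, marker_cols, "marker")

#' @rdname kinematic_csv
#' @export
write_marker2d_csv <- function(df, path, meta = list()) {
  schema_check(df, marker2d_cols, "2D marker")
  write_table_csv(df, path, meta)
}

#' @rdname kinematic_csv
#' @export
read_marker2d_csv <- function(path)
  read_table_csv(path, marker2d_cols, "2D marker")

#' @rdname kinematic_csv
#' @export
write_pose_csv <- function(df, path, meta = list()) {
  check_pose_df(df)
  write_table_csv(df, path, meta)
}

#' @rdname kinematic_csv
#' @export
read_pose_csv <- function(path) read_table_csv(path, pose_cols, "pose")

#' @rdname kinematic_csv
#' @export
write_angle_csv <- function(df, path, meta = list()) {
  check_angle_df(df)
  m <- meta
  if (is.null(m$sign_converted))
    m$sign_converted <- isTRUE(attr(df, "sign_converted"))
  write_table_csv(df, path, m)
}

#' @rdname kinematic_csv
#' @export
read_angle_csv <- function(path) {
  df <- read_table_csv(path, angle_cols, "angle")
  meta <- attr(df, "meta")
  attr(df, "sign_converted") <- identical(meta$sign_converted, "TRUE")
  df
}

#' Read and write DLT cameras as JSON
#'
#' @param camera an [dlt_camera()] or list of cameras.
#' @param path file path.
#' @return `read_camera_json()` returns a [dlt_camera()] or list of them.
#' @export
write_camera_json <- function(camera, path) {
  payload <- if (inherits(camera, "fk_camera"))
    list(coefficients = camera$coefficients)
  else lapply(camera, function(cm) list(coefficients = cm$coefficients))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!is.null(x$coefficients)) return(dlt_camera(x$coefficients))
  lapply(x, function(cm) dlt_camera(cm$coefficients))
}

#' Read and write gait profiles as JSON
#'
#' @param profile an `fk_profile`.
#' @param path file path.
#' @return `read_profile_json()` returns the `fk_profile`.
#' @export
write_profile_json <- function(profile, path) {
  wf <- lapply(profile$waveforms, function(jw)
    lapply(jw, function(k) list(percent = k[, 1], value = k[, 2])))
  payload <- list(waveforms = wf,
                  stance_fraction = profile$stance_fraction,
                  cycle_duration = profile$cycle_duration,
                  frame_rate = profile$frame_rate,
                  forward_speed = profile$forward_speed,
                  trial_scaling = profile$trial_scaling)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wf <- lapply(x$waveforms, function(jw)
    lapply(jw, function(k) cbind(k$percent, k$value)))
  ts <- x$trial_scaling
  if (!is.null(ts)) ts <- list(joint = ts$joint, axis = ts$axis,
                               anchor = ts$anchor, range = ts$range)
  gait_profile(wf, stance_fraction = x$stance_fraction,
               cycle_duration = x$cycle_duration,
               frame_rate = x$frame_rate,
               forward_speed = x$forward_speed,
               trial_scaling = ts)
}

#' Deterministic configuration hash
#'
#' 32-bit FNV-1a hash of the canonical (minified, unboxed) JSON encoding
#' of a configuration object; used to stamp every output file so that a
#' pipeline re-run with identical inputs is verifiably identical.
#'
#' @param config any JSON-serialisable R object.
#' @return 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte (b < 256)
    lowbyte <- h %% 256
    h <- h - lowbyte + bitwXor(as.integer(lowbyte), as.integer(b))
    # multiply modulo 2^32 in split halves to stay within double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
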