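#' Gold-standard accuracy residuals
#'
#' Compares two joint series frame by frame — typically a marker-driven
#' gold standard against a candidate reconstruction — and reports, per
#' joint and DOF, the mean absolute residual, its standard deviation and
#' its maximum.  Rotational channels are unwrapped before differencing so
#' a 360-degree wrap never inflates a residual, and the metric is
#' symmetric in its two arguments.
#'
#' Residuals are conventionally computed on sign-converted series so the
#' numbers are directly comparable to reported accuracy tables.
#'
#' @param gold,candidate angle tables covering the same trials, joints and
#'   frames.
#' @return data.frame of class `fk_residuals`: `joint, dof, unit,
#'   mean_abs, sd, max` with `dof` one of tx, ty, tz, rz, ry, rx.
#' @export
accuracy_residuals <- function(gold, candidate) {
  check_angle_df(gold)
  check_angle_df(candidate)
  key <- function(d) paste(d$trial_id, d$joint, d$frame)
  g <- gold[base::order(key(gold)), , drop = FALSE]
  cnd <- candidate[base::order(key(candidate)), , drop = FALSE]
  if (nrow(g) != nrow(cnd) || !all(key(g) == key(cnd)))
    stop("gold and candidate series do not cover the same joints/frames",
         call. = FALSE)
  dofs <- c(tx = "tx_mm", ty = "ty_mm", tz = "tz_mm",
            rz = "rz_deg", ry = "ry_deg", rx = "rx_deg")
  rows <- list()
  for (j in unique(g$joint)) {
    sel <- g$joint == j
    for (d in names(dofs)) {
      col <- dofs[[d]]
      a <- g[[col]][sel]
      b <- cnd[[col]][sel]
      if (grepl("deg$", col)) {
        a <- unwrap_angle_series(a)
        b <- unwrap_angle_series(b)
        # align branch: remove any whole-turn offset between the streams
        b <- b - 360 * round(mean(b - a) / 360)
      }
      r <- abs(a - b)
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, dof = d, unit = if (grepl("mm$", col)) "mm" else "deg",
        mean_abs = mean(r), sd = stats::sd(r), max = max(r),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fk_residuals", "data.frame")
  out
}

#' Repeated-registration precision
#'
#' Spread of repeated registrations of a single frame: per DOF the
#' standard deviation and range across the K repeats, the standard
#' repeated-measures precision test for manual registration.
#'
#' @param registrations K x 6 matrix or data.frame of repeated joint
#'   values with columns `tx_mm, ty_mm, tz_mm, rz_deg, ry_deg, rx_deg`
#'   (K >= 2), or a K-row angle table for a single joint and frame.
#' @return data.frame `dof, unit, sd, range`.
#' @export
precision_repeated <- function(registrations) {
  cols <- c("tx_mm", "ty_mm", "tz_mm", "rz_deg", "ry_deg", "rx_deg")
  m <- as.data.frame(registrations)
  if (!all(cols %in% names(m)))
    stop("registrations must carry columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  if (nrow(m) < 2L)
    stop("at least 2 repeated registrations are required", call. = FALSE)
  out <- do.call(rbind, lapply(cols, function(col) {
    v <- as.numeric(m[[col]])
    data.frame(dof = sub("_.*", "", col),
               unit = if (grepl("mm$", col)) "mm" else "deg",
               sd = stats::sd(v), range = max(v) - min(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
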