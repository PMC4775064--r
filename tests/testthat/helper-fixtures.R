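# In-code fixtures (no data files): gait segment tables and small angle
# tables used by the step-cycle tests.

segments_fixture <- function(phases, len = 80L) {
  n <- length(phases)
  starts <- (seq_len(n) - 1L) * len
  structure(data.frame(trial_id = "fix", segment = seq_len(n),
                       phase = phases, start_frame = starts,
                       end_frame = starts + len - 1L,
                       stringsAsFactors = FALSE),
            class = c("fk_segments", "data.frame"))
}

angle_fixture <- function(joint = "elbow", rz = 0, ry = 0, rx = 0,
                          trial_id = "t") {
  n <- max(length(rz), length(ry), length(rx))
  data.frame(trial_id = trial_id, frame = seq_len(n) - 1L, joint = joint,
             tx_mm = 0, ty_mm = 0, tz_mm = 0,
             rz_deg = rep_len(rz, n), ry_deg = rep_len(ry, n),
             rx_deg = rep_len(rx, n), stringsAsFactors = FALSE)
}
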