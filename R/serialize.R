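# Plain-text session serialization: a directory with CSV signal tables and
# a JSON header, so sessions survive any toolchain.

#' Write a synthetic session to a directory of text files
#'
#' Layout: `signals.csv` (one column per channel), `channels.csv`
#' (label/kind), `truth_phase.csv` (phase, valid), `truth_cycles.csv`, and
#' `meta.json` (sampling rate plus the generator configuration).
#'
#' @param session a [generate_session()] result.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- as.data.frame(t(session$recording$signals))
  names(sig) <- session$recording$labels
  utils::write.csv(sig, file.path(dir, "signals.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(label = session$recording$labels,
               kind = session$recording$kinds),
    file.path(dir, "channels.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(phase = session$truth_phase$phase,
               valid = session$truth_phase$valid),
    file.path(dir, "truth_phase.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$truth_cycles),
                   file.path(dir, "truth_cycles.csv"), row.names = FALSE)
  cfg <- unclass(session$config)
  jsonlite::write_json(list(fs = session$recording$fs, config = cfg),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing the session files.
#' @return a `synthetic_session` list (recording, truth_phase,
#'   truth_cycles, config).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ch <- utils::read.csv(file.path(dir, "channels.csv"),
                        colClasses = "character")
  sig <- utils::read.csv(file.path(dir, "signals.csv"), check.names = FALSE)
  rec <- recording(t(as.matrix(sig)), meta$fs, ch$label, ch$kind)
  tp <- utils::read.csv(file.path(dir, "truth_phase.csv"))
  cyc <- utils::read.csv(file.path(dir, "truth_cycles.csv"))
  cycles <- gait_cycle_table(cyc$lift_sample, cyc$strike_sample,
                             cyc$next_lift_sample, meta$fs)
  cfg <- meta$config
  cfg$modulation_bands <- lapply(
    if (is.data.frame(cfg$modulation_bands)) {
      split(as.matrix(cfg$modulation_bands),
            seq_len(nrow(cfg$modulation_bands)))
    } else cfg$modulation_bands,
    as.numeric)
  cfg <- structure(cfg, class = "session_config")
  structure(
    list(recording = rec,
         truth_phase = phase_series(tp$phase, as.logical(tp$valid),
                                    meta$fs),
         truth_cycles = cycles,
         config = cfg),
    class = "synthetic_session"
  )
}
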