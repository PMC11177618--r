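## Deterministic models of the stimulation schedules as pulse-time
## sequences. Theta-burst protocols deliver 50-Hz triplet bursts every
## 200 ms (5 Hz): continuously for 40 s (cTBS) or in 2-s-on/8-s-off
## trains (iTBS), 600 pulses either way at 80% resting motor threshold.
## The sham condition is a 20-Hz protocol (2-s trains, 28-s off, 20 min)
## at 10% RMT.

#' Build a stimulation pulse schedule
#'
#' @param protocol one of `"cTBS"`, `"iTBS"`, `"rTMS20"`, `"sham"`.
#' @return An object of class `pulse_schedule` with the pulse onset times
#'   (seconds from train start), burst/train structure and intensity in
#'   percent of resting motor threshold. `"sham"` shares the 20-Hz
#'   timing of `"rTMS20"` at 10% RMT; the active 20-Hz intensity is not
#'   modeled (`NA`).
#' @export
build_schedule <- function(protocol = c("cTBS", "iTBS", "rTMS20",
                                        "sham")) {
  protocol <- match.arg(protocol)
  triplet <- (0:2) / 50                      # 3 pulses at 50 Hz
  if (protocol == "cTBS") {
    bursts <- (0:199) * 0.2                  # one continuous 5-Hz train
    times <- as.vector(outer(triplet, bursts, `+`))
    sched <- list(burst_size = 3L, intra_burst_hz = 50,
                  burst_rate_hz = 5, train_on_s = 40, train_off_s = 0,
                  n_bursts = 200L, n_trains = 1L, intensity_pct_rmt = 80)
  } else if (protocol == "iTBS") {
    trains <- (0:19) * 10                    # 2 s on + 8 s off
    bursts <- as.vector(outer((0:9) * 0.2, trains, `+`))
    times <- as.vector(outer(triplet, bursts, `+`))
    sched <- list(burst_size = 3L, intra_burst_hz = 50,
                  burst_rate_hz = 5, train_on_s = 2, train_off_s = 8,
                  n_bursts = 200L, n_trains = 20L, intensity_pct_rmt = 80)
  } else {                                   # 20-Hz: 2 s on, 28 s off, 20 min
    trains <- (0:39) * 30
    times <- as.vector(outer((0:39) / 20, trains, `+`))
    sched <- list(burst_size = 1L, intra_burst_hz = 20,
                  burst_rate_hz = 20, train_on_s = 2, train_off_s = 28,
                  n_bursts = 1600L, n_trains = 40L,
                  intensity_pct_rmt = if (protocol == "sham") 10
                                      else NA_real_)
  }
  structure(c(list(protocol = protocol, pulse_times_s = sort(times)),
              sched),
            class = "pulse_schedule")
}

#' Summarize a pulse schedule
#'
#' `nominal_duration_s` is the last train onset plus the train-on time
#' (for a continuous train, the full train length); note the
#' convention that a 2-s-on/8-s-off 20-train schedule is quoted by its
#' final-train onset (190 s), not its 192-s first-to-last span.
#'
#' @param s a [build_schedule()] result.
#' @return List: `pulse_count`, `n_bursts`, `n_trains`,
#'   `nominal_duration_s`, `last_train_onset_s`.
#' @export
schedule_summary <- function(s) {
  stopifnot(inherits(s, "pulse_schedule"))
  if (!length(s$pulse_times_s))
    return(list(pulse_count = 0L, n_bursts = 0L, n_trains = 0L,
                nominal_duration_s = 0, last_train_onset_s = 0))
  last_onset <- (s$n_trains - 1) * (s$train_on_s + s$train_off_s)
  list(pulse_count = length(s$pulse_times_s),
       n_bursts = s$n_bursts,
       n_trains = s$n_trains,
       nominal_duration_s = last_onset + s$train_on_s,
       last_train_onset_s = last_onset)
}

#' @export
print.pulse_schedule <- function(x, ...) {
  ss <- schedule_summary(x)
  cat("pulse_schedule ", x$protocol, ": ", ss$pulse_count, " pulses, ",
      ss$n_trains, " train(s), nominal duration ", ss$nominal_duration_s,
      " s, intensity ", x$intensity_pct_rmt, "% RMT\n", sep = "")
  invisible(x)
}

#' Export a schedule as two-column TSV
#'
#' @param s a [build_schedule()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(s, path) {
  df <- data.frame(pulse = seq_along(s$pulse_times_s),
                   time_s = s$pulse_times_s)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
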