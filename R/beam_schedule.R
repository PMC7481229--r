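#' Pulsed-XFEL timing: trains, recorded pulses, duty cycle
#'
#' A `pulse_schedule` describes a facility's pulse pattern: trains of
#' `pulses_per_train` pulses separated by `intra_spacing` seconds, trains
#' repeating every `train_period` seconds. The first `calibration_pulses`
#' pulses of each train are excluded from recording and every
#' `record_stride`-th of the remainder is kept (detector calibration and
#' frame-rate constraints).
#'
#' @param train_period_s Time between train starts, s.
#' @param pulses_per_train Integer >= 1.
#' @param intra_spacing_s Time between pulses within a train, s
#'   (>= 0; irrelevant for single-pulse trains).
#' @param calibration_pulses Leading pulses excluded from recording
#'   (integer >= 0).
#' @param record_stride Stride over the remaining pulses (integer >= 1).
#' @return An object of class `pulse_schedule`.
#' @examples
#' eu <- facility_preset("euxfel")
#' recorded_pulse_ids(eu)        # 3, 5, ..., 31
#' continuous_waste_fraction(eu) # ~0.9997
#' @export
pulse_schedule <- function(train_period_s, pulses_per_train,
                           intra_spacing_s, calibration_pulses = 0,
                           record_stride = 1) {
  stopifnot_positive(train_period_s = train_period_s)
  stopifnot_positive(intra_spacing_s = intra_spacing_s, .allow_zero = TRUE)
  stopifnot(pulses_per_train >= 1, pulses_per_train == round(pulses_per_train),
            calibration_pulses >= 0,
            calibration_pulses == round(calibration_pulses),
            record_stride >= 1, record_stride == round(record_stride))
  if (train_period_s <= (pulses_per_train - 1) * intra_spacing_s) {
    stop("train period must exceed the span of the pulses within a train",
         call. = FALSE)
  }
  structure(list(
    train_period = train_period_s,
    pulses_per_train = as.integer(pulses_per_train),
    intra_spacing = intra_spacing_s,
    calibration_pulses = as.integer(calibration_pulses),
    record_stride = as.integer(record_stride)
  ), class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat("<pulse_schedule>\n")
  cat(sprintf("  %g trains/s x %d pulses, %.4g us apart (span %.4g us)\n",
              1 / x$train_period, x$pulses_per_train, x$intra_spacing * 1e6,
              train_span(x) * 1e6))
  cat(sprintf("  recorded in-train pulse ids: %s\n",
              paste(recorded_pulse_ids(x), collapse = ", ")))
  invisible(x)
}

#' Facility timing presets
#'
#' `"euxfel"` is the burst-mode setting used during early user operation:
#' 10 Hz trains of 32 pulses spaced 889 ns, with the first 2 pulses used
#' for detector calibration and every second remaining pulse recorded
#' (15 patterns per train). The single-pulse machines (`"lcls"` 120 Hz,
#' `"sacla30"`, `"sacla60"`, `"pal"` 60 Hz, `"swissfel"` 100 Hz) are
#' modelled as 1-pulse trains at their repetition rate.
#'
#' @param name One of `"euxfel"`, `"lcls"`, `"sacla30"`, `"sacla60"`,
#'   `"pal"`, `"swissfel"`.
#' @return A [pulse_schedule()].
#' @export
facility_preset <- function(name = c("euxfel", "lcls", "sacla30", "sacla60",
                                     "pal", "swissfel")) {
  name <- match.arg(name)
  single <- function(rate) pulse_schedule(1 / rate, 1L, 0)
  switch(name,
    euxfel = pulse_schedule(0.1, 32L, 889e-9,
                            calibration_pulses = 2L, record_stride = 2L),
    lcls = single(120),
    sacla30 = single(30),
    sacla60 = single(60),
    pal = single(60),
    swissfel = single(100)
  )
}

#' Absolute pulse times over several trains
#'
#' Pulse `j` (0-based) of train `i` (0-based) fires at
#' `i * train_period + j * intra_spacing`.
#'
#' @param schedule A [pulse_schedule()].
#' @param n_trains Number of trains (integer >= 1).
#' @return Strictly increasing numeric vector of length
#'   `n_trains * pulses_per_train`, seconds.
#' @export
pulse_times <- function(schedule, n_trains) {
  stopifnot(inherits(schedule, "pulse_schedule"),
            n_trains >= 1, n_trains == round(n_trains))
  trains <- rep(seq_len(n_trains) - 1, each = schedule$pulses_per_train)
  pulses <- rep(seq_len(schedule$pulses_per_train) - 1, times = n_trains)
  trains * schedule$train_period + pulses * schedule$intra_spacing
}

#' In-train indices of the recorded pulses
#'
#' Recording starts after the calibration pulses and keeps every
#' `record_stride`-th pulse. With the EuXFEL preset this yields pulses
#' 3, 5, ..., 31 — 15 patterns per train (pulse 32 is never recorded
#' under this scheme).
#'
#' @param schedule A [pulse_schedule()].
#' @return Integer vector of 1-based in-train pulse indices.
#' @export
recorded_pulse_ids <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  first <- schedule$calibration_pulses + 1L
  if (first > schedule$pulses_per_train) return(integer(0))
  seq.int(first, schedule$pulses_per_train, by = schedule$record_stride)
}

#' First-pulse-to-last-pulse span of one train
#'
#' @param schedule A [pulse_schedule()].
#' @return `(pulses_per_train - 1) * intra_spacing`, seconds.
#' @export
train_span <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  (schedule$pulses_per_train - 1) * schedule$intra_spacing
}

#' Fraction of sample wasted under continuous injection
#'
#' Under continuous jetting only the sample passing the interaction point
#' during a pulse train can be probed; the complement of the train duty
#' cycle is wasted. Returns `1 - train_span / train_period`, clipped to
#' [0, 1]. Single-pulse facilities (span 0) return 1 under the
#' instantaneous-pulse convention; pass `probe_window_s` for a refined
#' estimate with a finite effective probe window per train.
#'
#' @param schedule A [pulse_schedule()].
#' @param probe_window_s Optional effective probed duration per train, s;
#'   overrides the first-to-last-pulse span.
#' @return Wasted fraction in [0, 1].
#' @export
continuous_waste_fraction <- function(schedule, probe_window_s = NULL) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  span <- if (is.null(probe_window_s)) train_span(schedule) else probe_window_s
  min(max(1 - span / schedule$train_period, 0), 1)
}
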