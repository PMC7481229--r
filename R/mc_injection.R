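#' Describe the droplet plug train arriving at the interaction point
#'
#' The segmented stream is modelled as an alternating timeline: an aqueous
#' plug of duration `p_aq / f_d` followed by an oil slug of duration
#' `(1 - p_aq) / f_d`, repeating. `phase` is the start of an aqueous plug
#' relative to t = 0 of the simulation; `NULL` (the default) means
#' unsynchronised operation, where the phase is drawn uniformly on one
#' plug period independently for every pulse train (droplet generation
#' and the X-ray clock are uncorrelated, and plug periods are comparable
#' to the train period, so train-to-train phase decorrelates).
#'
#' @param frequency_hz Plug (droplet) frequency `f_d`, Hz (> 0).
#' @param p_aq Aqueous fraction of the period, in [0, 1].
#' @param phase_s Fixed phase offset, s, or `NULL` for unsynchronised.
#' @param period_jitter_cv Coefficient of variation of the plug period
#'   (lognormal multiplier, mean 1). Default 0 (stable generation).
#' @param interface_window_s Half-width of the boundary zone around each
#'   aqueous/oil transition classified as mixed phase, s. Default 0.
#' @return A `droplet_train` object.
#' @export
droplet_train <- function(frequency_hz, p_aq, phase_s = NULL,
                          period_jitter_cv = 0, interface_window_s = 0) {
  stopifnot_positive(frequency_hz = frequency_hz)
  stopifnot(p_aq >= 0, p_aq <= 1,
            period_jitter_cv >= 0, interface_window_s >= 0)
  structure(list(
    frequency = frequency_hz,
    p_aq = p_aq,
    phase = phase_s,
    period_jitter_cv = period_jitter_cv,
    interface_window = interface_window_s
  ), class = "droplet_train")
}

#' Monte Carlo simulation of droplet-pulse overlap
#'
#' Plays the plug timeline of a [droplet_train()] against the pulse times
#' of a [pulse_schedule()]. Each pulse is classified as `aqueous`, `oil`
#' or (within `interface_window_s` of a transition) `boundary`; aqueous
#' pulses illuminate a Poisson-distributed number of crystals with the
#' given mean ([mean_hit_fraction()] supplies it from the plug-flow
#' model); non-aqueous pulses yield no hits. The recorded-pulse mask of
#' the schedule is carried through. Deterministic given `seed`.
#'
#' Period jitter, when enabled, rescales each train's local plug period by
#' an independent lognormal multiplier; within a train the timeline is
#' locally periodic (trains last ~30 us against plug periods of tens of
#' ms, so drift within a train is negligible).
#'
#' @param train A [droplet_train()].
#' @param schedule A [pulse_schedule()].
#' @param mean_hit Expected crystals per aqueous pulse (>= 0).
#' @param n_trains Number of trains to simulate (integer >= 1).
#' @param seed Integer seed (mandatory).
#' @return Data frame with one row per pulse: `train_index` (1-based),
#'   `pulse_id` (1-based in-train), `time_s`, `phase_label`, `hit`,
#'   `recorded`.
#' @examples
#' tr <- droplet_train(20, p_aq = 0.3)
#' out <- simulate_injection(tr, facility_preset("euxfel"),
#'                           mean_hit = 0.05, n_trains = 50, seed = 1)
#' mean(out$phase_label == "aqueous")
#' @export
simulate_injection <- function(train, schedule, mean_hit, n_trains, seed) {
  stopifnot(inherits(train, "droplet_train"),
            inherits(schedule, "pulse_schedule"),
            mean_hit >= 0, n_trains >= 1, n_trains == round(n_trains))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  n_trains <- as.integer(n_trains)
  p <- schedule$pulses_per_train
  base_period <- 1 / train$frequency

  train_index <- rep(seq_len(n_trains), each = p)
  pulse_id <- rep(seq_len(p), times = n_trains)
  tau <- (pulse_id - 1) * schedule$intra_spacing           # in-train offset
  time_s <- (train_index - 1) * schedule$train_period + tau

  cv <- train$period_jitter_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    mult <- stats::rlnorm(n_trains, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    mult <- rep(1, n_trains)
  }
  period <- (base_period * mult)[train_index]
  aq_dur <- train$p_aq * period

  if (is.null(train$phase)) {
    phase <- (stats::runif(n_trains) * base_period * mult)[train_index]
    u <- (tau - phase) %% period
  } else {
    u <- (time_s - train$phase) %% period
  }

  label <- ifelse(u < aq_dur, "aqueous", "oil")
  w <- train$interface_window
  if (w > 0) {
    d_edge <- pmin(u, period - u, abs(u - aq_dur))
    label[d_edge <= w] <- "boundary"
  }

  hit <- integer(length(u))
  aq <- label == "aqueous"
  if (mean_hit > 0 && any(aq)) hit[aq] <- stats::rpois(sum(aq), mean_hit)

  data.frame(
    train_index = train_index,
    pulse_id = pulse_id,
    time_s = time_s,
    phase_label = label,
    hit = hit,
    recorded = pulse_id %in% recorded_pulse_ids(schedule),
    stringsAsFactors = FALSE
  )
}

#' Phase-lock the droplet train to the pulse trains
#'
#' Returns a copy of the droplet train with its frequency snapped to the
#' train repetition rate and its phase chosen so that one aqueous plug is
#' centred on the pulse span of every train. When the plug duration
#' covers the train span, every recorded pulse lands in aqueous sample.
#'
#' @param train A [droplet_train()] whose frequency should match the train
#'   repetition rate (it is set to `1 / train_period`).
#' @param schedule A [pulse_schedule()].
#' @return The phase-locked `droplet_train`, with attribute
#'   `covers_train` (logical). A warning is raised when the plug is
#'   shorter than the train span.
#' @export
synchronized_mode <- function(train, schedule) {
  stopifnot(inherits(train, "droplet_train"),
            inherits(schedule, "pulse_schedule"))
  f <- 1 / schedule$train_period
  plug <- train$p_aq / f
  span <- train_span(schedule)
  covers <- plug >= span
  if (!covers) {
    warning("aqueous plug (", signif(plug * 1e6, 3),
            " us) is shorter than the pulse-train span (",
            signif(span * 1e6, 3), " us); full aqueous coverage impossible")
  }
  out <- droplet_train(
    frequency_hz = f, p_aq = train$p_aq,
    phase_s = span / 2 - plug / 2,
    period_jitter_cv = train$period_jitter_cv,
    interface_window_s = train$interface_window
  )
  attr(out, "covers_train") <- covers
  out
}

#' Aggregate a simulated run
#'
#' Totals over a pulse-outcome table: pulses, recorded pulses, observed
#' aqueous fraction, total hits on recorded pulses (unrecorded pulses
#' produce no patterns), crystal-suspension volume consumed and hits per
#' uL, and the per-pulse-id hit histogram over the recorded ids.
#'
#' @param outcomes Data frame from [simulate_injection()].
#' @param q_aq_ul_min Aqueous flow rate during the run, uL/min.
#' @param duration_s Wall-clock run duration, s.
#' @return A `run_summary` object.
#' @export
summarize_run <- function(outcomes, q_aq_ul_min, duration_s) {
  if (!is.data.frame(outcomes) || nrow(outcomes) == 0) {
    stop("outcomes must be a non-empty data frame", call. = FALSE)
  }
  stopifnot_positive(q_aq_ul_min = q_aq_ul_min, duration_s = duration_s)
  rec <- outcomes[outcomes$recorded, , drop = FALSE]
  volume_ul <- q_aq_ul_min * duration_s / 60
  total_hits <- sum(rec$hit)
  ids <- sort(unique(rec$pulse_id))
  per_id <- vapply(ids, function(i) sum(rec$hit[rec$pulse_id == i]),
                   numeric(1))
  names(per_id) <- ids
  structure(list(
    n_pulses = nrow(outcomes),
    n_recorded = nrow(rec),
    aqueous_fraction_observed = mean(outcomes$phase_label == "aqueous"),
    total_hits = total_hits,
    volume_ul = volume_ul,
    hits_per_ul = total_hits / volume_ul,
    per_pulse_id_hits = per_id
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  cat(sprintf("  %d pulses (%d recorded), aqueous fraction %.3f\n",
              x$n_pulses, x$n_recorded, x$aqueous_fraction_observed))
  cat(sprintf("  %d hits in %.3g uL -> %.2f hits/uL\n",
              x$total_hits, x$volume_ul, x$hits_per_ul))
  invisible(x)
}

#' Continuous-versus-segmented consumption comparison
#'
#' Builds a run-accounting comparison: hits per uL for every condition,
#' fold-change of hits/uL against a reference condition, and the percent
#' reduction in sample consumption rate against that reference. Rates are
#' compared per minute so that conditions of unequal duration are on the
#' same footing; for matched durations the reduction equals
#' `100 * (1 - volume / volume_ref)` exactly.
#'
#' @param rows Data frame with columns `label`, `minutes`, `volume_ul`,
#'   `hits` (one row per injection condition).
#' @param reference_label Value of `label` to compare against
#'   (typically the continuous-injection condition).
#' @return A `consumption_report` data frame: the input columns plus
#'   `hits_per_ul`, `q_aq_ul_min` (mean consumption rate), `fold_change`
#'   and `percent_reduction`.
#' @examples
#' tab <- data.frame(
#'   label = c("continuous", "segmented"),
#'   minutes = c(26, 26), volume_ul = c(260, 110), hits = c(577, 735))
#' consumption_report(tab, "continuous")
#' @export
consumption_report <- function(rows, reference_label) {
  req <- c("label", "minutes", "volume_ul", "hits")
  if (!is.data.frame(rows) || !all(req %in% names(rows))) {
    stop("rows must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(rows$volume_ul <= 0) || any(rows$minutes <= 0)) {
    stop("volumes and durations must be positive", call. = FALSE)
  }
  if (!reference_label %in% rows$label) {
    stop("reference label '", reference_label, "' not found", call. = FALSE)
  }
  out <- rows
  out$hits_per_ul <- out$hits / out$volume_ul
  out$q_aq_ul_min <- out$volume_ul / out$minutes
  ref <- out[match(reference_label, out$label), ]
  out$fold_change <- out$hits_per_ul / ref$hits_per_ul
  out$percent_reduction <- 100 * (1 - out$q_aq_ul_min / ref$q_aq_ul_min)
  class(out) <- c("consumption_report", class(out))
  attr(out, "reference") <- reference_label
  out
}
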