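#' Wrap a photodetector voltage trace
#'
#' The in-line droplet detector shines a 1550 nm laser through the
#' capillary; oil and aqueous plugs transmit differently, so the
#' photodetector voltage alternates between two levels as plugs pass.
#'
#' @param voltages Numeric vector of readings, V (length >= 2).
#' @param sample_rate_hz Sampling rate, Hz (> 0).
#' @param meta Optional named list of labels.
#' @return A `detector_trace` object.
#' @export
detector_trace <- function(voltages, sample_rate_hz, meta = list()) {
  stopifnot(is.numeric(voltages), length(voltages) >= 2,
            all(is.finite(voltages)))
  stopifnot_positive(sample_rate_hz = sample_rate_hz)
  structure(list(voltages = as.numeric(voltages),
                 sample_rate = sample_rate_hz, meta = meta),
            class = "detector_trace")
}

#' Segment a two-level detector trace into droplet events
#'
#' Thresholds the trace at the midpoint of its robust low/high levels
#' (10th/90th percentiles) with a hysteresis band, merges dwells shorter
#' than a minimum number of samples into their neighbours, and reports
#' the event list, the droplet frequency (aqueous-event starts per unit
#' time) and the mean per-phase dwell times. The estimate is invariant to
#' affine transforms (offset/gain) of the voltage.
#'
#' Which transmission level is aqueous is configurable; the default
#' (`"low"`) assumes water absorbs more at 1550 nm than the fluorinated
#' oil — an assumption, not a measured fact.
#'
#' @param trace A [detector_trace()].
#' @param aqueous_level `"low"` or `"high"`: which voltage level is the
#'   aqueous phase.
#' @param hysteresis_frac Hysteresis band as a fraction of the level
#'   separation. Default 0.2.
#' @param min_dwell_samples Minimum event length, samples. Default 3.
#' @param min_separation_frac Minimum level separation, as a fraction of
#'   the overall voltage range, below which the trace is declared
#'   single-level. Default 1e-6 of full scale (absolute floor 1e-12 V).
#' @return A `droplet_events` object: `events` (data frame `start_s`,
#'   `end_s`, `phase_label`), `estimated_frequency` (Hz, `NA` if fewer
#'   than 2 aqueous events), `mean_aqueous_dwell`, `mean_oil_dwell` (s,
#'   interior events only), and logical `no_droplets` diagnostic flag.
#' @examples
#' syn <- make_trace(f_hz = 10, p_aq = 0.3, duration_s = 2,
#'                   noise_sd_v = 0, seed = 1)
#' detect_droplets(syn$trace)$estimated_frequency  # 10 Hz
#' @export
detect_droplets <- function(trace, aqueous_level = c("low", "high"),
                            hysteresis_frac = 0.2, min_dwell_samples = 3,
                            min_separation_frac = 1e-6) {
  stopifnot(inherits(trace, "detector_trace"))
  aqueous_level <- match.arg(aqueous_level)
  v <- trace$voltages
  lo <- stats::quantile(v, 0.1, names = FALSE)
  hi <- stats::quantile(v, 0.9, names = FALSE)
  sep <- hi - lo
  floor_sep <- max(min_separation_frac * (max(v) - min(v)), 1e-12)

  empty <- structure(list(
    events = data.frame(start_s = numeric(0), end_s = numeric(0),
                        phase_label = character(0),
                        stringsAsFactors = FALSE),
    estimated_frequency = NA_real_,
    mean_aqueous_dwell = NA_real_, mean_oil_dwell = NA_real_,
    no_droplets = TRUE
  ), class = "droplet_events")
  if (sep <= floor_sep) return(empty)

  mid <- (lo + hi) / 2
  band <- hysteresis_frac * sep / 2
  # hysteresis: state flips only on crossing the outer thresholds
  state <- integer(length(v))              # +1 high, -1 low, 0 undecided
  state[v > mid + band] <- 1L
  state[v < mid - band] <- -1L
  decided <- which(state != 0L)
  if (length(decided) == 0L) return(empty)
  # carry the last decided state forward (and the first one backward)
  filled <- state
  idx <- cummax(ifelse(state != 0L, seq_along(state), 0L))
  filled[idx > 0L] <- state[idx[idx > 0L]]
  filled[idx == 0L] <- state[decided[1]]

  r <- rle(filled)
  # merge dwells shorter than the minimum into the preceding run
  while (length(r$lengths) > 1 && any(r$lengths < min_dwell_samples)) {
    i <- which(r$lengths < min_dwell_samples)[1]
    j <- if (i == 1) 2L else i - 1L
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    r <- rle(inverse.rle(r))
  }
  if (length(r$lengths) < 2) return(empty)

  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  dt <- 1 / trace$sample_rate
  aq_is_low <- aqueous_level == "low"
  labels <- ifelse((r$values == -1L) == aq_is_low, "aqueous", "oil")
  events <- data.frame(
    start_s = (starts - 1) * dt,
    end_s = ends * dt,
    phase_label = labels,
    stringsAsFactors = FALSE
  )

  aq_starts <- events$start_s[events$phase_label == "aqueous"]
  est_f <- if (length(aq_starts) >= 2) {
    (length(aq_starts) - 1) / (aq_starts[length(aq_starts)] - aq_starts[1])
  } else NA_real_
  interior <- events[-c(1, nrow(events)), , drop = FALSE]
  mean_dwell <- function(lab) {
    d <- interior$end_s[interior$phase_label == lab] -
      interior$start_s[interior$phase_label == lab]
    if (length(d)) mean(d) else NA_real_
  }
  structure(list(
    events = events,
    estimated_frequency = est_f,
    mean_aqueous_dwell = mean_dwell("aqueous"),
    mean_oil_dwell = mean_dwell("oil"),
    no_droplets = FALSE
  ), class = "droplet_events")
}

#' @export
print.droplet_events <- function(x, ...) {
  cat("<droplet_events>\n")
  if (x$no_droplets) {
    cat("  no droplets detected (single-level trace)\n")
  } else {
    cat(sprintf("  %d events, f = %.3g Hz, dwell aq %.3g ms / oil %.3g ms\n",
                nrow(x$events), x$estimated_frequency,
                x$mean_aqueous_dwell * 1e3, x$mean_oil_dwell * 1e3))
  }
  invisible(x)
}

#' Relative deviation of the detected frequency from a model prediction
#'
#' Real-time feedback during injection: compare the frequency recovered
#' from the detector trace with the frequency predicted from the flow
#' rates ([droplet_frequency()]).
#'
#' @param events A `droplet_events` object from [detect_droplets()].
#' @param predicted_f Model-predicted frequency, Hz (> 0).
#' @return `(estimated - predicted) / predicted`.
#' @export
compare_to_model <- function(events, predicted_f) {
  stopifnot(inherits(events, "droplet_events"))
  stopifnot_positive(predicted_f = predicted_f)
  if (is.na(events$estimated_frequency)) {
    stop("no estimated frequency available (too few events)", call. = FALSE)
  }
  (events$estimated_frequency - predicted_f) / predicted_f
}

#' Horizontal diffuse-scattering profile of detector panel images
#'
#' Sums each panel image along rows (horizontal projection), averages the
#' per-image profiles over the stack, and scores the prominence of the
#' profile maximum inside a row band where an oil scattering ring would
#' fall, relative to the median profile level outside the band. Oil
#' presence in the probed sample shows up as a diffuse ring, hence a
#' ridge in the projected profile; droplet injection should score low,
#' co-flowing oil high.
#'
#' @param images A list of numeric matrices of identical dimensions, or a
#'   3-D array (row, column, image).
#' @param band Integer vector `c(first_row, last_row)` of the ring search
#'   band; default the middle third of the rows.
#' @return A `panel_profile` object: `profile` (mean projected intensity
#'   per row), `n_hits` (images aggregated), `ring_score` (peak
#'   prominence, >= 0), `band`.
#' @export
panel_horizontal_profile <- function(images, band = NULL) {
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  }
  if (!is.list(images) || length(images) == 0) {
    stop("images must be a non-empty list of matrices or a 3-D array",
         call. = FALSE)
  }
  dims <- dim(images[[1]])
  if (is.null(dims) || length(dims) != 2) {
    stop("each image must be a 2-D matrix", call. = FALSE)
  }
  same <- vapply(images, function(m) identical(dim(m), dims), logical(1))
  if (!all(same)) stop("all images must share dimensions", call. = FALSE)

  profiles <- vapply(images, rowSums, numeric(dims[1]))
  profile <- rowMeans(profiles)

  n_rows <- dims[1]
  if (is.null(band)) {
    band <- c(floor(n_rows / 3) + 1, min(n_rows, floor(2 * n_rows / 3)))
  }
  stopifnot(length(band) == 2, band[1] >= 1, band[2] <= n_rows,
            band[1] <= band[2])
  inside <- seq.int(band[1], band[2])
  outside <- setdiff(seq_len(n_rows), inside)
  baseline <- if (length(outside)) stats::median(profile[outside]) else 0
  ring_score <- max(max(profile[inside]) - baseline, 0)

  structure(list(profile = profile, n_hits = length(images),
                 ring_score = ring_score, band = band),
            class = "panel_profile")
}
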