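#' Synthetic droplet-frequency characterisation dataset
#'
#' Emulates a bench characterisation of the T-junction: a grid of flow
#' conditions spanning a total-velocity range and a range of aqueous
#' fractions, with the true frequency given by the model at `k_true` and
#' observational noise from counting 60-80 droplets per condition.
#'
#' Two noise modes are offered (the measurement-error model of such
#' characterisations is under-specified): `"multiplicative"` (default)
#' applies Gaussian relative noise of sd `noise_cv` to the frequency;
#' `"counting"` jitters each counted droplet period by `noise_cv` and
#' derives the frequency as count/elapsed-time, giving a frequency error
#' of roughly `noise_cv / sqrt(n_droplets)`.
#'
#' @param fluid A [fluid_system()].
#' @param k_true Generating prefactor, m/s. Default 3.7.
#' @param n_points Number of measurements. Default 70.
#' @param v_tot_range_mm_s Total-velocity range, mm/s. Default c(10, 20).
#' @param p_aq_range Aqueous-fraction range. Default c(0.15, 0.5),
#'   bracketing typical aqueous:oil flow-ratio combinations.
#' @param noise_cv Relative noise level. Default 0.05.
#' @param droplets_range Range of droplets counted per point.
#'   Default c(60, 80).
#' @param noise_mode `"multiplicative"` or `"counting"`.
#' @param seed Integer seed (mandatory; the dataset is reproducible).
#' @return Data frame with columns `q_aq_ul_min`, `q_oil_ul_min`, `f_hz`,
#'   `n_droplets`, `f_true_hz`.
#' @export
make_frequency_dataset <- function(fluid, k_true = 3.7, n_points = 70,
                                   v_tot_range_mm_s = c(10, 20),
                                   p_aq_range = c(0.15, 0.5),
                                   noise_cv = 0.05,
                                   droplets_range = c(60, 80),
                                   noise_mode = c("multiplicative",
                                                  "counting"),
                                   seed) {
  stopifnot(inherits(fluid, "fluid_system"), n_points >= 2, noise_cv >= 0)
  noise_mode <- match.arg(noise_mode)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))

  n_p <- 7L
  n_v <- ceiling(n_points / n_p)
  grid <- expand.grid(
    v_tot = seq(v_tot_range_mm_s[1], v_tot_range_mm_s[2],
                length.out = n_v) * 1e-3,
    p_aq = seq(p_aq_range[1], p_aq_range[2], length.out = n_p)
  )[seq_len(n_points), ]

  q_tot_ul_min <- m3s_to_ul_min(grid$v_tot * fluid$area)
  q_aq <- q_tot_ul_min * grid$p_aq
  q_oil <- q_tot_ul_min - q_aq

  f_true <- vapply(seq_len(n_points), function(i) {
    droplet_frequency(fluid, flow_condition(fluid, q_aq[i], q_oil[i]),
                      k_true)
  }, numeric(1))

  n_droplets <- sample(seq.int(droplets_range[1], droplets_range[2]),
                       n_points, replace = TRUE)
  f_obs <- if (noise_cv == 0) {
    f_true
  } else if (noise_mode == "multiplicative") {
    pmax(f_true * (1 + stats::rnorm(n_points, sd = noise_cv)),
         .Machine$double.eps)
  } else {
    vapply(seq_len(n_points), function(i) {
      periods <- (1 / f_true[i]) *
        pmax(1 + stats::rnorm(n_droplets[i], sd = noise_cv), 0.01)
      n_droplets[i] / sum(periods)
    }, numeric(1))
  }

  data.frame(
    q_aq_ul_min = q_aq,
    q_oil_ul_min = q_oil,
    f_hz = f_obs,
    n_droplets = n_droplets,
    f_true_hz = f_true
  )
}

#' Synthetic two-level detector trace
#'
#' Alternating two-level voltage signal with duty `p_aq`, linear
#' transition ramps of `rise_frac` of a period, and additive Gaussian
#' noise; mirrors the in-line droplet-detector oscilloscope signal. The
#' aqueous phase sits at the low level by default.
#'
#' @param f_hz Droplet frequency, Hz.
#' @param p_aq Aqueous duty fraction in [0, 1].
#' @param duration_s Trace duration, s (`duration_s * f_hz >= 1`).
#' @param sample_rate_hz Sampling rate, Hz. Default 10 kHz.
#' @param amplitude_v Level separation, V. Default 1.
#' @param noise_sd_v Additive Gaussian noise sd, V. Default 0.
#' @param rise_frac Transition ramp duration as a fraction of the period.
#'   Default 0.01.
#' @param seed Integer seed (used only when `noise_sd_v > 0`).
#' @return List with `trace` (a [detector_trace()]) and `truth`
#'   (list of the generating `f_hz`, `p_aq`, `n_periods`).
#' @export
make_trace <- function(f_hz, p_aq, duration_s, sample_rate_hz = 1e4,
                       amplitude_v = 1, noise_sd_v = 0, rise_frac = 0.01,
                       seed = NULL) {
  stopifnot_positive(f_hz = f_hz, duration_s = duration_s,
                     sample_rate_hz = sample_rate_hz,
                     amplitude_v = amplitude_v)
  stopifnot(p_aq >= 0, p_aq <= 1, duration_s * f_hz >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))

  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  period <- 1 / f_hz
  aq <- p_aq * period
  rise <- rise_frac * period
  u <- t %% period
  # aqueous (low) on [0, aq), oil (high) on [aq, period); linear ramps
  v <- ifelse(u < aq, 0, 1)
  if (rise > 0 && p_aq > 0 && p_aq < 1) {
    down <- u < rise                      # oil -> aqueous at u = 0
    v[down] <- 1 - u[down] / rise
    up <- u >= aq & u < aq + rise         # aqueous -> oil at u = aq
    v[up] <- (u[up] - aq) / rise
  }
  v <- v * amplitude_v
  if (noise_sd_v > 0) v <- v + stats::rnorm(length(v), sd = noise_sd_v)

  list(
    trace = detector_trace(v, sample_rate_hz,
                           meta = list(source = "synthetic")),
    truth = list(f_hz = f_hz, p_aq = p_aq,
                 n_periods = duration_s * f_hz)
  )
}

#' Synthetic per-pulse hit stream
#'
#' Convenience wrapper around [simulate_injection()] for building
#' pipeline fixtures from scalar parameters.
#'
#' @param f_hz Droplet frequency, Hz.
#' @param p_aq Aqueous fraction.
#' @param schedule A [pulse_schedule()].
#' @param mean_hit Expected crystals per aqueous pulse.
#' @param n_trains Number of trains.
#' @param seed Integer seed.
#' @param ... Further arguments to [droplet_train()].
#' @return Pulse-outcome data frame (see [simulate_injection()]).
#' @export
make_hit_stream <- function(f_hz, p_aq, schedule, mean_hit, n_trains,
                            seed, ...) {
  simulate_injection(droplet_train(f_hz, p_aq, ...), schedule,
                     mean_hit = mean_hit, n_trains = n_trains, seed = seed)
}

#' Synthetic detector-panel image stack
#'
#' Small panel images with optional horizontal Gaussian ridge emulating
#' an oil diffuse-scattering ring at a known row position, over a flat
#' background with Gaussian noise. Used to exercise
#' [panel_horizontal_profile()].
#'
#' @param n_images Number of images.
#' @param n_rows,n_cols Panel dimensions. Defaults 64 x 128.
#' @param background Mean background level. Default 1.
#' @param noise_sd Pixel noise sd. Default 0.05.
#' @param ring_row Centre row of the ridge, or `NULL` for no ring.
#' @param ring_amplitude Ridge height above background. Default 1.
#' @param ring_sd Ridge width (rows). Default 2.
#' @param seed Integer seed.
#' @return List of `n_images` matrices.
#' @export
make_panel_stack <- function(n_images = 10, n_rows = 64, n_cols = 128,
                             background = 1, noise_sd = 0.05,
                             ring_row = NULL, ring_amplitude = 1,
                             ring_sd = 2, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  ridge <- if (is.null(ring_row)) {
    rep(0, n_rows)
  } else {
    ring_amplitude * exp(-((seq_len(n_rows) - ring_row)^2) / (2 * ring_sd^2))
  }
  lapply(seq_len(n_images), function(i) {
    matrix(background + ridge +
             stats::rnorm(n_rows * n_cols, sd = noise_sd),
           nrow = n_rows, ncol = n_cols)
  })
}
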