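#' Read a droplet-frequency measurement table
#'
#' Delimited text with header columns `q_aq_ul_min`, `q_oil_ul_min`,
#' `f_hz`, `n_droplets`; one row per flow condition. Malformed rows are
#' reported by number.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop("parse error in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  req <- c("q_aq_ul_min", "q_oil_ul_min", "f_hz", "n_droplets")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) {
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, req]
    bad <- !is.numeric(unlist(row)) || anyNA(row) ||
      row$q_aq_ul_min < 0 || row$q_oil_ul_min < 0 ||
      row$f_hz <= 0 || row$n_droplets < 1
    if (bad) {
      stop("parse error in ", path, ": invalid values in row ", i,
           call. = FALSE)
    }
  }
  tab
}

#' Read a structured key-value configuration file
#'
#' Configuration files carry unit-suffixed keys (e.g. `q_aq_ul_min`,
#' `intra_spacing_ns`) so values are unambiguous and greppable. Unknown
#' keys are rejected by the typed loaders.
#'
#' @param path Path to a YAML key-value file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Build a fluid system from a configuration list
#'
#' Expected keys: `viscosity_mpas`, `tension_mn_m`, `width_um`,
#' `depth_um`, `dispersed_diameter_um`; optional `prefactor_m_s` is
#' attached as attribute `k`.
#'
#' @param cfg Named list (e.g. from [read_config()]).
#' @return A [fluid_system()], with attribute `k` when the config
#'   includes a fitted prefactor.
#' @export
fluid_from_config <- function(cfg) {
  known <- c("name", "viscosity_mpas", "tension_mn_m", "width_um",
             "depth_um", "dispersed_diameter_um", "prefactor_m_s")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown fluid config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fs <- fluid_system(
    viscosity_mpas = cfg$viscosity_mpas,
    tension_mn_m = cfg$tension_mn_m,
    width_um = cfg$width_um,
    depth_um = cfg$depth_um,
    dispersed_diameter_um = cfg$dispersed_diameter_um
  )
  if (!is.null(cfg$prefactor_m_s)) attr(fs, "k") <- cfg$prefactor_m_s
  fs
}

#' Build a pulse schedule from a configuration list
#'
#' Expected keys: `train_period_s`, `pulses_per_train`,
#' `intra_spacing_ns`, `calibration_pulses`, `record_stride`.
#'
#' @param cfg Named list (e.g. from [read_config()]).
#' @return A [pulse_schedule()].
#' @export
schedule_from_config <- function(cfg) {
  known <- c("name", "train_period_s", "pulses_per_train",
             "intra_spacing_ns", "calibration_pulses", "record_stride")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown schedule config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pulse_schedule(
    train_period_s = cfg$train_period_s,
    pulses_per_train = cfg$pulses_per_train,
    intra_spacing_s = cfg$intra_spacing_ns * 1e-9,
    calibration_pulses = cfg$calibration_pulses %||% 0,
    record_stride = cfg$record_stride %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled configuration preset for the fluorinated-oil system
#'
#' The 10:1 perfluorodecalin:perfluorooctanol continuous phase against
#' aqueous mother liquor in the 100 x 75 um T-junction, with the fitted
#' prefactor 3.7 m/s.
#'
#' @return A [fluid_system()] with attribute `k`.
#' @export
pfd_pfo_preset <- function() {
  fluid_from_config(read_config(
    system.file("extdata", "pfd_pfo_system.yml", package = "segflow",
                mustWork = TRUE)
  ))
}

#' Fit the frequency model to a measurement table
#'
#' Reads (or accepts) a measurement table, fits the prefactor, and
#' returns the fit together with a smooth fitted curve of frequency
#' against the composite model term for plotting.
#'
#' @param measurements Data frame or path to a CSV table
#'   (see [read_frequency_table()]).
#' @param fluid A [fluid_system()].
#' @param weighted Passed to [fit_prefactor()].
#' @return List with `fit` (a `prefactor_fit`), `points` (the measurement
#'   table with the composite term `x` added) and `curve` (data frame
#'   `x`, `f_hz` of the fitted line).
#' @export
fit_frequency_model <- function(measurements, fluid, weighted = TRUE) {
  if (is.character(measurements)) {
    measurements <- read_frequency_table(measurements)
  }
  fit <- fit_prefactor(measurements, fluid, weighted = weighted)
  x <- vapply(seq_len(nrow(measurements)), function(i) {
    composite_term(flow_condition(fluid, measurements$q_aq_ul_min[i],
                                  measurements$q_oil_ul_min[i]))
  }, numeric(1))
  measurements$x <- x
  xx <- seq(0, max(x) * 1.05, length.out = 100)
  list(
    fit = fit,
    points = measurements,
    curve = data.frame(x = xx, f_hz = fit$k_hat * xx / fluid$width)
  )
}

#' Plan a segmented-flow injection for a target facility or frequency
#'
#' Solves the frequency model for the flow rates that deliver one droplet
#' per pulse train (or any target frequency), then derives the droplet
#' volume, plug dwell time in the jet, whether the plug spans the pulse
#' train, the predicted hits per pulse (when beam/crystal parameters are
#' supplied), and the sample saving relative to continuous injection at
#' the same total flow.
#'
#' @param fluid A [fluid_system()].
#' @param k Fitted prefactor, m/s.
#' @param target_f_hz Target droplet frequency, Hz; defaults to the train
#'   repetition rate of `facility`.
#' @param facility Facility preset name (see [facility_preset()]) or a
#'   [pulse_schedule()].
#' @param flow_ratio Aqueous-to-oil flow-rate ratio. Default 0.3.
#' @param jet_speed_m_s Jet speed, m/s. Default 50.
#' @param beam Optional [beam_crystal()] for hit-fraction prediction.
#' @return An `injection_plan` list: the solved flow condition, droplet
#'   volume (pL), plug duration (us), `spans_train`, predicted hit
#'   fraction (or `NA`), and `sample_saving_fraction = 1 - p_aq`.
#' @export
plan_injection <- function(fluid, k, target_f_hz = NULL, facility = NULL,
                           flow_ratio = 0.3, jet_speed_m_s = 50,
                           beam = NULL) {
  schedule <- if (inherits(facility, "pulse_schedule")) {
    facility
  } else if (!is.null(facility)) {
    facility_preset(facility)
  } else {
    NULL
  }
  if (is.null(target_f_hz)) {
    if (is.null(schedule)) {
      stop("supply target_f_hz or a facility", call. = FALSE)
    }
    target_f_hz <- 1 / schedule$train_period
  }
  cond <- solve_flow_for_frequency(fluid, k, target_f_hz, flow_ratio)
  vol <- droplet_volume(m3s_to_ul_min(cond$q_aq), target_f_hz)
  jet <- jet_params(m3s_to_ul_min(cond$q_tot), jet_speed_m_s)
  plug <- plug_geometry(m3_to_pl(vol), m3s_to_ul_min(cond$q_aq),
                        m3s_to_ul_min(cond$q_oil), jet)
  structure(list(
    target_f_hz = target_f_hz,
    condition = cond,
    q_aq_ul_min = m3s_to_ul_min(cond$q_aq),
    q_oil_ul_min = m3s_to_ul_min(cond$q_oil),
    composite_term = composite_term(cond),
    droplet_volume_pl = m3_to_pl(vol),
    plug_duration_us = plug$aqueous_duration * 1e6,
    jet_radius_um = jet$r_j * 1e6,
    spans_train = if (is.null(schedule)) NA else spans_train(plug, schedule),
    hit_fraction = if (is.null(beam)) NA_real_ else
      mean_hit_fraction(jet, beam, cond$p_aq),
    sample_saving_fraction = 1 - cond$p_aq
  ), class = "injection_plan")
}

#' @export
print.injection_plan <- function(x, ...) {
  cat("<injection_plan>\n")
  cat(sprintf("  target %.3g Hz: Q_aq = %.3g, Q_oil = %.3g uL/min\n",
              x$target_f_hz, x$q_aq_ul_min, x$q_oil_ul_min))
  cat(sprintf("  droplet %.3g pL, plug %.3g us, spans train: %s\n",
              x$droplet_volume_pl, x$plug_duration_us, x$spans_train))
  cat(sprintf("  sample saving vs continuous: %.0f%%\n",
              100 * x$sample_saving_fraction))
  invisible(x)
}

#' Write a report as JSON with a provenance block
#'
#' Every written report carries the package version, creation time and
#' (when given) the seed, so outputs are traceable to the code and
#' randomness that produced them.
#'
#' @param x List (or coercible) report content.
#' @param path Output file path.
#' @param seed Optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, seed = NULL) {
  payload <- list(
    provenance = list(
      package = "segflow",
      version = as.character(utils::packageVersion("segflow")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed
    ),
    report = x
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
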