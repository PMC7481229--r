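#' T-junction droplet-generation frequency model
#'
#' The generation frequency of aqueous droplets sheared off at a T-junction
#' follows the power-law scaling
#'
#' \deqn{f_d = \frac{K \, Ca^{4/3}}{W} \cdot \frac{v_d}{v_{tot}}}
#'
#' where `Ca` is the capillary number of the continuous phase, `W` the
#' continuous-phase channel width, `v_d`/`v_tot` the dispersed-to-total
#' velocity ratio (equal to the flow-rate ratio under the shared
#' cross-section convention), and `K` a system prefactor obtained by
#' fitting measured frequencies ([fit_prefactor()]).
#'
#' @param fluid A [fluid_system()].
#' @param condition A [flow_condition()].
#' @param k Prefactor `K`, m/s (> 0).
#' @return Predicted droplet frequency, Hz. Zero when `v_d = 0`.
#' @seealso [composite_term()], [fit_prefactor()],
#'   [solve_flow_for_frequency()]
#' @examples
#' fs <- fluid_system()
#' fc <- flow_condition(fs, 4.5, 12)
#' droplet_frequency(fs, fc, k = 3.7)
#' @export
droplet_frequency <- function(fluid, condition, k) {
  stopifnot(inherits(fluid, "fluid_system"),
            inherits(condition, "flow_condition"))
  stopifnot_positive(k = k)
  if (condition$continuous_mode) {
    stop("droplet frequency is undefined in continuous mode (no oil flow)",
         call. = FALSE)
  }
  if (condition$v_tot <= 0) stop("total velocity must be positive",
                                 call. = FALSE)
  k * composite_term(condition) / fluid$width
}

#' Composite scaling term of the frequency model
#'
#' `x = Ca^(4/3) * v_d / v_tot`, the dimensionless driver of the frequency
#' model: `f_d = K x / W`. Useful for planning (a target frequency maps to
#' `x = f W / K`).
#'
#' @param condition A [flow_condition()].
#' @return Dimensionless composite term.
#' @export
composite_term <- function(condition) {
  stopifnot(inherits(condition, "flow_condition"))
  condition$ca^(4 / 3) * condition$v_d / condition$v_tot
}

#' Fit the frequency-model prefactor to measured droplet frequencies
#'
#' Zero-intercept least squares of measured frequency against the model
#' regressor `x/W` (the model has no intercept). By default each point is
#' weighted by `n_droplets / f^2`, i.e. inversely to the per-point variance
#' implied by counting 60-80 droplets with multiplicative error; set
#' `weighted = FALSE` for an ordinary fit.
#'
#' @param measurements Data frame with columns `q_aq_ul_min`,
#'   `q_oil_ul_min`, `f_hz` and (if `weighted`) `n_droplets`; one row per
#'   flow condition. See [read_frequency_table()].
#' @param fluid A [fluid_system()].
#' @param weighted Use counting-derived weights (default `TRUE`).
#' @return An object of class `prefactor_fit`: `k_hat` and `k_se` (m/s),
#'   `n_points`, `residual_summary` (residual standard error of the
#'   weighted fit), and the underlying `lm` fit as `model`.
#' @examples
#' fs <- fluid_system()
#' dat <- make_frequency_dataset(fs, k_true = 3.7, noise_cv = 0, seed = 1)
#' fit_prefactor(dat, fs)$k_hat  # 3.7 to machine precision
#' @export
fit_prefactor <- function(measurements, fluid, weighted = TRUE) {
  stopifnot(inherits(fluid, "fluid_system"), is.data.frame(measurements))
  req <- c("q_aq_ul_min", "q_oil_ul_min", "f_hz")
  if (weighted) req <- c(req, "n_droplets")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(measurements) < 2) {
    stop("degenerate fit: need at least 2 measurements", call. = FALSE)
  }
  if (any(measurements$f_hz <= 0)) {
    stop("measured frequencies must be positive", call. = FALSE)
  }
  x <- vapply(seq_len(nrow(measurements)), function(i) {
    composite_term(flow_condition(fluid,
                                  measurements$q_aq_ul_min[i],
                                  measurements$q_oil_ul_min[i]))
  }, numeric(1))
  if (diff(range(x)) <= 0) {
    stop("degenerate fit: all composite terms identical", call. = FALSE)
  }
  reg <- x / fluid$width
  w <- if (weighted) measurements$n_droplets / measurements$f_hz^2 else NULL
  fit <- stats::lm(measurements$f_hz ~ 0 + reg, weights = w)
  sm <- suppressWarnings(summary(fit))  # zero-residual (noiseless) fits are fine
  structure(list(
    k_hat = unname(stats::coef(fit)[1]),
    k_se = unname(sm$coefficients[1, "Std. Error"]),
    n_points = nrow(measurements),
    residual_summary = sm$sigma,
    weighted = weighted,
    model = fit
  ), class = "prefactor_fit")
}

#' @export
print.prefactor_fit <- function(x, ...) {
  cat("<prefactor_fit>\n")
  cat(sprintf("  K = %.3f +/- %.3f m/s (%d points, %sweighted)\n",
              x$k_hat, x$k_se, x$n_points, if (x$weighted) "" else "un"))
  invisible(x)
}

#' Solve for the flow rates that give a target droplet frequency
#'
#' Inverts the frequency model at a fixed aqueous:oil flow-rate ratio by a
#' bracketed scalar search on the total flow rate. The frequency is
#' strictly increasing in total flow at fixed ratio, so the root is unique
#' when it exists in the bracket (0.01 to 1000 uL/min total).
#'
#' @param fluid A [fluid_system()].
#' @param k Prefactor, m/s.
#' @param target_f Target droplet frequency, Hz (> 0).
#' @param flow_ratio Aqueous-to-oil flow-rate ratio `q_aq / q_oil` (> 0).
#' @param rel_tol Relative tolerance on the recovered frequency.
#' @return The [flow_condition()] whose forward frequency equals
#'   `target_f` (to `rel_tol`).
#' @examples
#' fs <- fluid_system()
#' cond <- solve_flow_for_frequency(fs, k = 3.7, target_f = 10,
#'                                  flow_ratio = 0.3)
#' droplet_frequency(fs, cond, 3.7)  # 10 Hz
#' @export
solve_flow_for_frequency <- function(fluid, k, target_f, flow_ratio,
                                     rel_tol = 1e-6) {
  stopifnot(inherits(fluid, "fluid_system"))
  stopifnot_positive(k = k, target_f = target_f, flow_ratio = flow_ratio)
  f_of_qtot <- function(q_tot_ul_min) {
    q_aq <- q_tot_ul_min * flow_ratio / (1 + flow_ratio)
    q_oil <- q_tot_ul_min / (1 + flow_ratio)
    droplet_frequency(fluid, flow_condition(fluid, q_aq, q_oil), k)
  }
  lo <- 1e-2
  hi <- 1e3
  f_lo <- f_of_qtot(lo) - target_f
  f_hi <- f_of_qtot(hi) - target_f
  if (f_lo * f_hi > 0) {
    stop(sprintf(
      "no solution: target %.3g Hz outside achievable range [%.3g, %.3g] Hz",
      target_f, f_of_qtot(lo), f_of_qtot(hi)), call. = FALSE)
  }
  root <- stats::uniroot(function(q) f_of_qtot(q) - target_f,
                         lower = lo, upper = hi,
                         tol = .Machine$double.eps^0.5)$root
  q_aq <- root * flow_ratio / (1 + flow_ratio)
  cond <- flow_condition(fluid, q_aq, root - q_aq)
  achieved <- droplet_frequency(fluid, cond, k)
  if (abs(achieved - target_f) / target_f > rel_tol) {
    stop("root finding did not converge to the requested tolerance",
         call. = FALSE)
  }
  cond
}

#' Droplet volume from aqueous flow rate and generation frequency
#'
#' Volume conservation: every period one droplet carries the aqueous
#' throughput, so `V_d = Q_aq / f_d` and `f_d * V_d = Q_aq` exactly.
#'
#' @param q_aq_ul_min Aqueous flow rate, uL/min (> 0).
#' @param f_hz Droplet generation frequency, Hz (> 0).
#' @return Droplet volume in m^3 (use [m3_to_pl()] for pL).
#' @examples
#' m3_to_pl(droplet_volume(4.5, 100))  # 750 pL
#' @export
droplet_volume <- function(q_aq_ul_min, f_hz) {
  stopifnot_positive(q_aq_ul_min = q_aq_ul_min, f_hz = f_hz)
  ul_min_to_m3s(q_aq_ul_min) / f_hz
}
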