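#' Breathing scenario specification
#'
#' Captures the characteristics of the six simulated respiratory
#' scenarios: S1 amplitude variations only; S2 adds a downward baseline
#' shift mid-scan; S3 amplitude variations plus baseline shifts; S4 a
#' period/amplitude change partway through; S5 slow breathing with a
#' gradually decaying amplitude; S6 the combination of period/amplitude
#' changes and baseline shifts.
#'
#' @param scenario_id one of `"S1"`..`"S6"` or `"custom"`.
#' @param period_s breathing period in seconds (> 0).
#' @param peak_to_peak_mm diaphragm peak-to-peak motion in mm (>= 0).
#' @param amplitude_jitter per-cycle multiplicative Gaussian jitter SD
#'   (fraction; 0 disables).
#' @param baseline_shift_mm vector of baseline step amplitudes in mm.
#' @param baseline_shift_time_s matching vector of step times in seconds.
#' @param period_change_time_s time of the period/amplitude change (or
#'   `NA`), with `period2_s` and `amp_factor2` the post-change values.
#' @param period2_s,amp_factor2 post-change period and amplitude factor.
#' @param amp_decay_frac total fractional amplitude decay over the scan
#'   (S5-style slow-breathing decay; 0 disables).
#' @param seed RNG seed for the jitter draws.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id = "S1", period_s = 5,
                          peak_to_peak_mm = 20, amplitude_jitter = 0.1,
                          baseline_shift_mm = numeric(0),
                          baseline_shift_time_s = numeric(0),
                          period_change_time_s = NA_real_,
                          period2_s = NA_real_, amp_factor2 = 1,
                          amp_decay_frac = 0, seed = 1) {
  known <- c(paste0("S", 1:6), "custom")
  if (!scenario_id %in% known)
    stop("unknown scenario_id: ", scenario_id)
  stopifnot(period_s > 0, peak_to_peak_mm >= 0,
            length(baseline_shift_mm) == length(baseline_shift_time_s))
  preset <- switch(scenario_id,
    S1 = list(),
    S2 = list(baseline_shift_mm = -7, baseline_shift_time_s = 90),
    S3 = list(baseline_shift_mm = c(-5, 4),
              baseline_shift_time_s = c(60, 120)),
    S4 = list(period_change_time_s = 60, period2_s = 3.5, amp_factor2 = 1.4),
    S5 = list(period_s = 8, peak_to_peak_mm = 12, amplitude_jitter = 0.05,
              amp_decay_frac = 0.4),
    S6 = list(period_change_time_s = 60, period2_s = 3.5, amp_factor2 = 1.3,
              baseline_shift_mm = c(-6, 3),
              baseline_shift_time_s = c(45, 120)),
    custom = list())
  spec <- list(scenario_id = scenario_id, period_s = period_s,
               peak_to_peak_mm = peak_to_peak_mm,
               amplitude_jitter = amplitude_jitter,
               baseline_shift_mm = baseline_shift_mm,
               baseline_shift_time_s = baseline_shift_time_s,
               period_change_time_s = period_change_time_s,
               period2_s = period2_s, amp_factor2 = amp_factor2,
               amp_decay_frac = amp_decay_frac, seed = seed)
  # scenario presets override only fields the caller left at defaults
  supplied <- names(as.list(match.call())[-1])
  for (nm in setdiff(names(preset), supplied)) spec[[nm]] <- preset[[nm]]
  structure(spec, class = "scenario_spec")
}

#' Read a scenario specification from a YAML config
#' @param path YAML file whose keys match [scenario_spec()] arguments.
#' @return A `scenario_spec`.
#' @export
read_scenario_yaml <- function(path) {
  do.call(scenario_spec, yaml::read_yaml(path))
}

#' Simulate a diaphragm motion trace
#'
#' Generates the per-frame superior-inferior diaphragm displacement for a
#' breathing scenario.  The waveform is the classical `sin^4` breathing
#' model: zero (end-of-exhale) at the cycle boundaries with a natural
#' exhale dwell, reaching `-peak_to_peak_mm` at peak inhale (inferior
#' displacement is negative).  A per-cycle multiplicative Gaussian jitter
#' perturbs the amplitude; baseline steps, period/amplitude changes and a
#' linear amplitude decay implement the scenario families.  The
#' instantaneous phase is integrated through period changes so the
#' waveform stays continuous.  Deterministic given `spec$seed`.
#'
#' @param spec a [scenario_spec()].
#' @param duration_s scan duration in seconds (> 0).
#' @param dt_ms frame interval in ms (the frame temporal resolution).
#' @return An object of class `motion_trace` with fields `amplitude`
#'   (total per-frame displacement in mm, baseline included), `baseline`,
#'   `time_s`, `dt_ms`, `scenario_id`.  `N_t = ceiling(duration / dt)`.
#' @export
make_motion_trace <- function(spec, duration_s = 180, dt_ms = 98.6) {
  stopifnot(inherits(spec, "scenario_spec"), duration_s > 0, dt_ms > 0)
  n_t <- as.integer(ceiling(duration_s * 1000 / dt_ms))
  t_s <- (seq_len(n_t) - 0.5) * dt_ms / 1000

  period <- rep(spec$period_s, n_t)
  ampf <- rep(1, n_t)
  if (!is.na(spec$period_change_time_s)) {
    after <- t_s >= spec$period_change_time_s
    period[after] <- ifelse(is.na(spec$period2_s), spec$period_s, spec$period2_s)
    ampf[after] <- spec$amp_factor2
  }
  if (spec$amp_decay_frac > 0)
    ampf <- ampf * (1 - spec$amp_decay_frac * t_s / duration_s)

  # integrate instantaneous frequency so phase is continuous across changes
  phase <- cumsum((dt_ms / 1000) / period)
  cycle <- floor(phase)

  jit <- rep(1, n_t)
  if (spec$amplitude_jitter > 0) {
    ncyc <- max(cycle) + 1L
    jdraw <- with_seed(spec$seed,
                       pmax(0.2, rnorm(ncyc, 1, spec$amplitude_jitter)))
    jit <- jdraw[cycle + 1L]
  }

  baseline <- rep(0, n_t)
  for (i in seq_along(spec$baseline_shift_mm))
    baseline <- baseline +
      spec$baseline_shift_mm[i] * (t_s >= spec$baseline_shift_time_s[i])

  cyc <- -spec$peak_to_peak_mm * ampf * jit * sin(pi * phase)^4
  structure(list(amplitude = baseline + cyc, baseline = baseline,
                 time_s = t_s, dt_ms = dt_ms, n_t = n_t,
                 scenario_id = spec$scenario_id, spec = spec),
            class = "motion_trace")
}
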