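#' Configuration for the synthetic CGM generator
#'
#' The generator is phenomenological: a baseline plus additive circadian,
#' meal, and exercise components with AR(1) sensor noise, clipped to the
#' sensor range. It reproduces the statistical structure a glucose forecaster
#' sees — smooth autocorrelated traces in 40–400 mg/dL, meal excursions,
#' glucose falls during aerobic and rises during anaerobic exercise, and
#' dropouts that break days — without claiming metabolic fidelity.
#'
#' @param n_days Number of simulated days (default 10).
#' @param baseline Baseline glucose, mg/dL (default 120).
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dL (default 15).
#' @param circadian_phase Phase shift in minutes (default 180).
#' @param meal_times Scheduled daily meal times, minutes after midnight
#'   (default 07:30, 12:30, 19:00).
#' @param meal_time_jitter_sd SD of the per-meal timing jitter, minutes
#'   (default 20).
#' @param meal_amplitude Mean peak meal excursion, mg/dL (default 60).
#' @param meal_amplitude_sd SD of the per-meal peak, mg/dL (default 10).
#' @param meal_rise_tau,meal_decay_tau Time constants of the bi-exponential
#'   meal bump, minutes (defaults 20 and 60; rise must be < decay).
#' @param pa_schedule Data frame with columns `day`, `start_minute`
#'   (after midnight), `duration_minutes`, `type`; `NULL` gives a default
#'   schedule of 60-minute evening sessions of `pa_type` every other day
#'   starting on day 2.
#' @param pa_type Activity type used by the default schedule
#'   (`"aerobic"` or `"anaerobic"`).
#' @param aerobic_drop_rate Glucose fall during aerobic exercise, mg/dL per
#'   10 minutes (default 8).
#' @param anaerobic_rise Peak glucose rise during anaerobic exercise, mg/dL
#'   (default 30).
#' @param pre_exercise_snack Add a snack excursion shortly before each aerobic
#'   session (default FALSE; off by default so the exercise effect is
#'   identifiable in paired simulations).
#' @param snack_amplitude Peak of the pre-exercise snack, mg/dL (default 25).
#' @param ar_coefficient Lag-1 coefficient of the AR(1) sensor noise, in
#'   `[0, 1)` (default 0.8).
#' @param noise_sd Stationary SD of the sensor noise, mg/dL (default 3).
#' @param dropout_events Data frame with columns `day`, `start_minute`,
#'   `duration_minutes` marking sensor disconnections, or `NULL`.
#' @param clip_range Sensor reporting range, mg/dL (default `c(40, 400)`).
#' @param seed Integer seed; identical seeds give identical traces.
#' @param patient_id Identifier attached to the series.
#' @param start_date First simulated day (`"YYYY-MM-DD"`, UTC midnight).
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_days = 10L, baseline = 120,
                              circadian_amplitude = 15, circadian_phase = 180,
                              meal_times = c(450, 750, 1140),
                              meal_time_jitter_sd = 20,
                              meal_amplitude = 60, meal_amplitude_sd = 10,
                              meal_rise_tau = 20, meal_decay_tau = 60,
                              pa_schedule = NULL, pa_type = "aerobic",
                              aerobic_drop_rate = 8, anaerobic_rise = 30,
                              pre_exercise_snack = FALSE, snack_amplitude = 25,
                              ar_coefficient = 0.8, noise_sd = 3,
                              dropout_events = NULL,
                              clip_range = c(40, 400), seed = 1L,
                              patient_id = "sim", start_date = "2021-03-01") {
  stopifnot(n_days >= 1L, circadian_amplitude >= 0, meal_amplitude >= 0,
            aerobic_drop_rate >= 0, anaerobic_rise >= 0, noise_sd >= 0,
            ar_coefficient >= 0, ar_coefficient < 1,
            meal_rise_tau > 0, meal_decay_tau > meal_rise_tau,
            clip_range[1] < clip_range[2])
  if (is.null(pa_schedule)) {
    days <- seq.int(2L, n_days, by = 2L)
    pa_schedule <- data.frame(day = days, start_minute = 1050,
                              duration_minutes = 60, type = pa_type)
  }
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Bi-exponential meal excursion
#'
#' `amplitude * (exp(-t/decay_tau) - exp(-t/rise_tau)) / normalizer`, zero for
#' `t < 0`, where the normalizer makes the analytic peak (at
#' `t* = log(decay/rise) * rise * decay / (decay - rise)`) equal exactly
#' `amplitude`.
#'
#' @param minutes_since_meal Numeric vector of times since meal start.
#' @param amplitude Peak excursion, mg/dL.
#' @param rise_tau,decay_tau Time constants in minutes, `rise_tau < decay_tau`.
#' @return Numeric vector of glucose offsets (mg/dL).
#' @export
meal_excursion <- function(minutes_since_meal, amplitude,
                           rise_tau = 20, decay_tau = 60) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau)
  t_star <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  norm <- exp(-t_star / decay_tau) - exp(-t_star / rise_tau)
  t <- as.numeric(minutes_since_meal)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- amplitude * (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / norm
  out
}

#' Glucose offset caused by an exercise bout
#'
#' Aerobic exercise pulls glucose down linearly at `aerobic_drop_rate` mg/dL
#' per 10 minutes for the whole bout, then recovers linearly to zero over a
#' span equal to the bout's duration. Anaerobic exercise raises glucose
#' linearly to `+anaerobic_rise` by mid-bout, holds it to the end, then decays
#' linearly to zero within 120 minutes.
#'
#' @param minutes_since_start Numeric vector of times since the bout started.
#' @param duration_minutes Bout duration (> 0).
#' @param type `"aerobic"` or `"anaerobic"`.
#' @param aerobic_drop_rate mg/dL fall per 10 minutes of aerobic exercise.
#' @param anaerobic_rise Peak mg/dL rise of anaerobic exercise.
#' @return Numeric vector of glucose offsets (mg/dL).
#' @export
exercise_effect <- function(minutes_since_start, duration_minutes,
                            type = c("aerobic", "anaerobic"),
                            aerobic_drop_rate = 8, anaerobic_rise = 30) {
  type <- match.arg(type)
  stopifnot(duration_minutes > 0)
  t <- as.numeric(minutes_since_start)
  d <- duration_minutes
  out <- numeric(length(t))
  if (type == "aerobic") {
    depth <- aerobic_drop_rate * d / 10
    during <- t >= 0 & t < d
    out[during] <- -aerobic_drop_rate * t[during] / 10
    recov <- t >= d & t < 2 * d
    out[recov] <- -depth * (1 - (t[recov] - d) / d)
  } else {
    ramp <- t >= 0 & t < d / 2
    out[ramp] <- anaerobic_rise * t[ramp] / (d / 2)
    hold <- t >= d / 2 & t <= d
    out[hold] <- anaerobic_rise
    decay <- t > d & t < d + 120
    out[decay] <- anaerobic_rise * (1 - (t[decay] - d) / 120)
  }
  out
}

#' Mark sensor-disconnection intervals as missing
#'
#' @param series A [cgm_series()].
#' @param dropout_events Data frame with columns `day` (1-based), `start_minute`
#'   (after that day's midnight) and `duration_minutes`.
#' @return The series with the listed minutes marked missing; all other
#'   minutes untouched.
#' @export
inject_dropouts <- function(series, dropout_events) {
  if (is.null(dropout_events) || nrow(dropout_events) == 0L) return(series)
  n <- length(series$values)
  for (i in seq_len(nrow(dropout_events))) {
    from <- (dropout_events$day[i] - 1L) * 1440L + dropout_events$start_minute[i] + 1L
    to <- from + dropout_events$duration_minutes[i] - 1L
    if (to < 1L || from > n) {
      stop(sprintf("inject_dropouts(): event %d outside the series span", i),
           call. = FALSE)
    }
    idx <- max(1L, from):min(n, to)
    series$missing[idx] <- TRUE
    series$values[idx] <- NA_real_
  }
  series
}

#' Simulate one synthetic CGM patient
#'
#' Builds a minute-grid trace as baseline + circadian sinusoid + meal
#' excursions + exercise effects + AR(1) noise, clipped to the sensor range,
#' then applies the configured dropouts. One random stream per patient is
#' consumed in a fixed component order (meal timing, meal amplitude, noise),
#' so turning one component off does not perturb the others' draws.
#'
#' @param cfg A [simulation_config()].
#' @return List with `series` (a [cgm_series()]), `events` (an
#'   [activity_events()] data frame), and `truth` — the noise-free ground
#'   truth with per-component traces (`circadian`, `meals`, `exercise`,
#'   `noise`) and `noise_free = clip(baseline + sum of components)`.
#' @export
simulate_patient <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_days * 1440L
  minute <- seq_len(n) - 1L           # 0-based minute since first midnight
  set.seed(cfg$seed)
  n_meals <- cfg$n_days * length(cfg$meal_times)
  jitter <- stats::rnorm(n_meals, 0, cfg$meal_time_jitter_sd)
  amps <- pmax(0, stats::rnorm(n_meals, cfg$meal_amplitude, cfg$meal_amplitude_sd))
  noise0 <- stats::rnorm(1, 0, cfg$noise_sd)
  innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_coefficient^2)
  innov <- stats::rnorm(n, 0, innov_sd)

  circadian <- cfg$circadian_amplitude *
    sin(2 * pi * (minute - cfg$circadian_phase) / 1440)

  meals <- numeric(n)
  k <- 0L
  for (d in seq_len(cfg$n_days)) {
    for (m in cfg$meal_times) {
      k <- k + 1L
      t0 <- (d - 1L) * 1440 + m + jitter[k]
      meals <- meals + meal_excursion(minute - t0, amps[k],
                                      cfg$meal_rise_tau, cfg$meal_decay_tau)
    }
  }

  exercise <- numeric(n)
  sched <- cfg$pa_schedule
  for (i in seq_len(NROW(sched))) {
    t0 <- (sched$day[i] - 1L) * 1440 + sched$start_minute[i]
    exercise <- exercise + exercise_effect(minute - t0, sched$duration_minutes[i],
                                           sched$type[i],
                                           cfg$aerobic_drop_rate,
                                           cfg$anaerobic_rise)
    if (cfg$pre_exercise_snack && sched$type[i] == "aerobic") {
      meals <- meals + meal_excursion(minute - (t0 - 30), cfg$snack_amplitude,
                                      cfg$meal_rise_tau, cfg$meal_decay_tau)
    }
  }

  noise <- as.numeric(stats::filter(innov, cfg$ar_coefficient,
                                    method = "recursive", init = noise0))

  clip <- function(x) pmin(pmax(x, cfg$clip_range[1]), cfg$clip_range[2])
  trace <- clip(cfg$baseline + circadian + meals + exercise + noise)

  start_time <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  series <- cgm_series(trace, start_time = start_time,
                       missing = rep(FALSE, n), patient_id = cfg$patient_id)
  series <- inject_dropouts(series, cfg$dropout_events)

  events <- if (NROW(sched) > 0L) {
    t0 <- start_time + 60 * ((sched$day - 1L) * 1440 + sched$start_minute)
    activity_events(start = t0, end = t0 + 60 * sched$duration_minutes,
                    pa_type = sched$type)
  } else {
    data.frame(start = start_time[0], end = start_time[0], pa_type = character(0))
  }

  list(series = series, events = events,
       truth = list(circadian = circadian, meals = meals, exercise = exercise,
                    noise = noise,
                    noise_free = clip(cfg$baseline + circadian + meals + exercise)))
}

#' Write a simulated patient to the package's CSV dialects
#'
#' @param sim Result of [simulate_patient()].
#' @param cgm_path,events_path Output CSV paths (CGM readings and activity
#'   annotations in the dialects read by [read_cgm_table()] and
#'   [read_activity_table()]).
#' @return Invisibly, the two paths.
#' @export
write_simulated_patient <- function(sim, cgm_path, events_path) {
  times <- series_times(sim$series)
  keep <- !sim$series$missing
  utils::write.csv(
    data.frame(timestamp = format(times[keep], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               glucose_mg_dl = sim$series$values[keep]),
    cgm_path, row.names = FALSE)
  utils::write.csv(
    data.frame(start = format(sim$events$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               end = format(sim$events$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               type = sim$events$pa_type),
    events_path, row.names = FALSE)
  invisible(c(cgm_path, events_path))
}
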