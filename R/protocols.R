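#' Protocol configuration
#'
#' All tunables of the three training protocols in one validated object.
#' Defaults are the study settings: 30-minute horizon, 10-minute input
#' window, 4 hidden neurons, offline training on the initial 80% of the first
#' 24 h with validation on the remaining 20% (learning rate 0.1, at most 500
#' epochs, early stopping after 10 failed validation checks every 4 epochs,
#' gradient clipping at 0.3), and online updates every 5 timestamps on the
#' trailing 24 h of CGM at learning rate 0.01.
#'
#' @param PH Prediction horizon in minutes (default 30).
#' @param M Input window length in minutes (default 10).
#' @param L Hidden-layer width (default 4).
#' @param first_day_minutes Length of the initial offline-training day
#'   (default 1440).
#' @param train_fraction Offline train fraction of the first day (default 0.8).
#' @param online_window_minutes Trailing CGM span used by each online update
#'   (default 1440).
#' @param update_cadence Online update every this many test timestamps
#'   (default 5; `Inf` disables updates).
#' @param lr_offline,lr_online Learning rates (defaults 0.1 and 0.01).
#' @param clip_value Elementwise gradient clip, `NULL` to disable
#'   (default 0.3, applied in both phases).
#' @param max_epochs,validation_check_every,patience_checks Offline
#'   early-stopping settings (defaults 500, 4, 10).
#' @param online_epochs_per_update Full-batch passes over the trailing window
#'   per update (default 1).
#' @param penalty_enabled Use the penalty-weighted loss during online updates
#'   (default FALSE).
#' @param penalty_use_magnitude Apply penalty thresholds to `|e|` (default TRUE).
#' @param train_bias Train bias terms (default FALSE: the bias-free model).
#' @param standardize Map the glucose windows and targets onto `[-1, 1]` by
#'   the offline training split's range (midrange center, half-range scale)
#'   before they reach the network, and map predictions back to mg/dL
#'   (default TRUE). The learning rates, Glorot initialization, and clip
#'   value are all unit-scale quantities; on raw 100-plus mg/dL inputs
#'   full-batch descent at these settings is unstable. The scaler is frozen
#'   after the offline phase and shared by the online updates. Penalty
#'   weights are always computed on mg/dL-scale errors.
#' @param seed Integer seed for weight initialization.
#' @return Validated list of class `protocol_config`.
#' @export
protocol_config <- function(PH = 30L, M = 10L, L = 4L,
                            first_day_minutes = 1440L, train_fraction = 0.8,
                            online_window_minutes = 1440L, update_cadence = 5,
                            lr_offline = 0.1, lr_online = 0.01,
                            clip_value = 0.3, max_epochs = 500L,
                            validation_check_every = 4L, patience_checks = 10L,
                            online_epochs_per_update = 1L,
                            penalty_enabled = FALSE,
                            penalty_use_magnitude = TRUE,
                            train_bias = FALSE, standardize = TRUE, seed = 1L) {
  stopifnot(PH >= 1L, M >= 1L, L >= 1L, update_cadence >= 1,
            train_fraction > 0, train_fraction < 1,
            online_window_minutes >= 1L, online_epochs_per_update >= 0L,
            lr_offline > 0, lr_online >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "protocol_config"
  cfg
}

offline_hyper <- function(cfg) {
  training_hyperparams(learning_rate = cfg$lr_offline,
                       max_epochs = cfg$max_epochs,
                       clip_value = cfg$clip_value,
                       validation_check_every = cfg$validation_check_every,
                       patience_checks = cfg$patience_checks)
}

# Affine glucose scaler mapping the offline training split's glucose range
# onto [-1, 1] (midrange center, half-range scale), the classic feed-forward
# preprocessing. The network trains in scaled units, the records stay in
# mg/dL. Frozen after the offline phase.
make_scaler <- function(train, standardize) {
  if (!standardize) return(list(center = 0, scale = 1))
  g <- c(train$inputs, train$targets)
  half <- (max(g) - min(g)) / 2
  list(center = (max(g) + min(g)) / 2, scale = if (half > 0) half else 1)
}

scale_ds <- function(ds, scaler) {
  ds$inputs <- (ds$inputs - scaler$center) / scaler$scale
  ds$targets <- (ds$targets - scaler$center) / scaler$scale
  ds
}

# Offline phase shared by all protocols: init weights from cfg$seed and fit
# the 80/20 chronological split of the first 24 h of the first group (MSE).
fit_offline_phase <- function(groups, cfg) {
  if (length(groups) == 0L || length(groups[[1L]]) < cfg$first_day_minutes) {
    stop("protocol: the first continuous-day group must span at least 24 h",
         call. = FALSE)
  }
  ds1 <- build_supervised_windows(groups[[1L]], M = cfg$M, PH = cfg$PH)
  split <- chronological_split(ds1, first_day_minutes = cfg$first_day_minutes,
                               train_fraction = cfg$train_fraction)
  scaler <- make_scaler(split$train, cfg$standardize)
  init <- jumpnet_params(M = cfg$M, L = cfg$L, seed = cfg$seed,
                         train_bias = cfg$train_bias)
  fit <- train_offline(init, scale_ds(split$train, scaler),
                       scale_ds(split$validation, scaler),
                       hyper = offline_hyper(cfg), loss = "mse")
  list(params = fit$params, scaler = scaler, init = init, fit = fit, ds1 = ds1)
}

# Forecast a batch of raw-mg/dL windows with a scaled network.
predict_scaled <- function(params, scaler, inputs) {
  scaler$center +
    scaler$scale * jumpnet_forward(params, (inputs - scaler$center) / scaler$scale)
}

# Test pairs of one group: all pairs, except that in the first group pairs
# anchored inside the offline training day are excluded from testing.
test_pair_indices <- function(ds, cfg, is_first_group) {
  if (is_first_group) which(ds$anchor_times > cfg$first_day_minutes)
  else seq_len(n_windows(ds))
}

run_result <- function(records, config, params_init, params_final,
                       update_count, updates_applied, patient_id) {
  structure(list(records = records, config = config,
                 params_init = params_init, params_final = params_final,
                 update_count = update_count, updates_applied = updates_applied,
                 patient_id = patient_id),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Run '%s' for '%s': %d predictions, %d update event(s)\n",
              x$config, x$patient_id, nrow(x$records), x$update_count))
  invisible(x)
}

make_records <- function(ds, idx, preds, pa) {
  if (length(idx) == 0L) return(NULL)
  data.frame(
    time = ds$origin + 60 * (ds$target_times[idx] - 1L),
    anchor_time = ds$origin + 60 * (ds$anchor_times[idx] - 1L),
    truth = ds$targets[idx],
    prediction = preds,
    y_anchor = ds$inputs[idx, ds$M],
    pa_flag = pa[ds$target_times[idx]],
    group = ds$group_id)
}

#' Offline protocol: train once, freeze, test on everything that follows
#'
#' The network is trained on the 80/20 chronological split of the first 24 h
#' of the first continuous-day group (MSE loss, early stopping) and its
#' weights are then frozen; every eligible timestamp of the remaining data —
#' the rest of the first group and every later group — is forecast with the
#' fixed model. A prediction is eligible when the anchor has a full
#' `M`-minute history and its target lies inside the same group.
#'
#' @param groups List of [cgm_day_group()]s from [find_continuous_day_groups()].
#' @param events Activity annotations ([activity_events()]) or `NULL`.
#' @param cfg A [protocol_config()].
#' @return A `run_result`: `records` data frame (`time`, `anchor_time`,
#'   `truth`, `prediction`, `y_anchor`, `pa_flag`, `group`), the trained
#'   parameter snapshots, and the update count (0 for offline).
#' @export
run_offline <- function(groups, events = NULL, cfg = protocol_config()) {
  off <- fit_offline_phase(groups, cfg)
  params <- off$params
  recs <- list()
  for (gi in seq_along(groups)) {
    if (length(groups[[gi]]) < cfg$M + cfg$PH) next
    ds <- if (gi == 1L) off$ds1 else
      build_supervised_windows(groups[[gi]], M = cfg$M, PH = cfg$PH)
    idx <- test_pair_indices(ds, cfg, gi == 1L)
    if (length(idx) == 0L) next
    preds <- predict_scaled(params, off$scaler, ds$inputs[idx, , drop = FALSE])
    recs[[length(recs) + 1L]] <-
      make_records(ds, idx, preds, pa_mask(groups[[gi]], events))
  }
  res <- run_result(do.call(rbind, recs), config = "offline",
                    params_init = params, params_final = params,
                    update_count = 0L, updates_applied = 0L,
                    patient_id = groups[[1L]]$patient_id)
  res$scaler <- off$scaler
  res
}

#' Online protocols: sliding 24-hour retraining, with or without penalty
#'
#' Starts from the offline-trained weights (the offline phase is run first,
#' or supplied via `warm_start`). Each eligible test timestamp is forecast
#' with the current weights; after every `update_cadence`-th prediction the
#' network takes `online_epochs_per_update` full-batch clipped
#' gradient-descent steps (learning rate `lr_online`) on the pairs of the
#' trailing `online_window_minutes` of CGM. Only pairs whose window lies
#' fully inside the trailing span, whose target has already realized
#' (target time at most the current test instant), and which belong to the
#' current group are used, so updates are causal and never span a gap; after
#' a gap the trailing window must refill before update steps resume, while
#' predictions resume as soon as a window and target fit in the new group.
#'
#' With `penalty_enabled = TRUE` each update weights the squared errors by
#' [penalty()] evaluated at the current-model errors (the third protocol);
#' otherwise the update loss is the plain MSE (the second protocol).
#'
#' @inheritParams run_offline
#' @param warm_start Optional warm start shared across configurations: an
#'   offline `run_result`, or a list with elements `params` (a
#'   `jumpnet_params`) and `scaler`, or a bare `jumpnet_params` (the glucose
#'   scaler is then recomputed from the offline training split). When `NULL`
#'   the offline phase is run internally.
#' @return A `run_result`; `update_count` is the number of triggered update
#'   events (`floor(n_predictions / update_cadence)`), `updates_applied` the
#'   subset that had a nonempty, refilled trailing window.
#' @export
run_online <- function(groups, events = NULL, cfg = protocol_config(),
                       warm_start = NULL) {
  if (is.null(warm_start)) {
    off <- fit_offline_phase(groups, cfg)
    params <- off$params
    scaler <- off$scaler
  } else {
    off <- NULL
    if (inherits(warm_start, "run_result")) {
      params <- warm_start$params_init
      scaler <- warm_start$scaler
    } else if (inherits(warm_start, "jumpnet_params")) {
      params <- warm_start
      ds1 <- build_supervised_windows(groups[[1L]], M = cfg$M, PH = cfg$PH)
      split <- chronological_split(ds1, cfg$first_day_minutes, cfg$train_fraction)
      scaler <- make_scaler(split$train, cfg$standardize)
    } else {
      params <- warm_start$params
      scaler <- warm_start$scaler
    }
  }
  params_init <- params
  recs <- list()
  counter <- 0L
  update_count <- 0L
  updates_applied <- 0L
  for (gi in seq_along(groups)) {
    if (length(groups[[gi]]) < cfg$M + cfg$PH) next
    ds <- if (gi == 1L && !is.null(off)) off$ds1 else
      build_supervised_windows(groups[[gi]], M = cfg$M, PH = cfg$PH)
    idx <- test_pair_indices(ds, cfg, gi == 1L)
    if (length(idx) == 0L) next
    pa <- pa_mask(groups[[gi]], events)
    preds <- numeric(length(idx))
    pos <- 1L
    while (pos <= length(idx)) {
      take <- length(idx) - pos + 1L
      if (is.finite(cfg$update_cadence)) {
        until_update <- cfg$update_cadence - (counter %% cfg$update_cadence)
        take <- min(take, until_update)
      }
      block <- idx[pos:(pos + take - 1L)]
      preds[pos:(pos + take - 1L)] <-
        predict_scaled(params, scaler, ds$inputs[block, , drop = FALSE])
      counter <- counter + take
      pos <- pos + take
      if (is.finite(cfg$update_cadence) && counter %% cfg$update_cadence == 0L) {
        update_count <- update_count + 1L
        t_now <- ds$anchor_times[block[length(block)]]
        if (t_now >= cfg$online_window_minutes &&
            cfg$lr_online > 0 && cfg$online_epochs_per_update > 0L) {
          w_start <- t_now - cfg$online_window_minutes + 1L
          elig <- which(ds$anchor_times - cfg$M + 1L >= w_start &
                          ds$target_times <= t_now)
          if (length(elig) > 0L) {
            updates_applied <- updates_applied + 1L
            X <- (ds$inputs[elig, , drop = FALSE] - scaler$center) / scaler$scale
            y <- (ds$targets[elig] - scaler$center) / scaler$scale
            for (ep in seq_len(cfg$online_epochs_per_update)) {
              w <- 1
              if (cfg$penalty_enabled) {
                # penalty thresholds are mg/dL quantities
                w <- penalty(scaler$scale * (y - jumpnet_forward(params, X)),
                             use_magnitude = cfg$penalty_use_magnitude)
              }
              g <- jumpnet_gradients(params, X, y, sample_weights = w)
              if (!is.finite(g$loss)) {
                stop(sprintf("run_online(): update diverged at minute %d of group %d",
                             t_now, ds$group_id), call. = FALSE)
              }
              if (!is.null(cfg$clip_value)) g <- clip_gradients(g, cfg$clip_value)
              params <- sgd_step(params, g, cfg$lr_online)
            }
          }
        }
      }
    }
    recs[[length(recs) + 1L]] <- make_records(ds, idx, preds, pa)
  }
  res <- run_result(do.call(rbind, recs),
                    config = if (cfg$penalty_enabled) "online_penalty" else "online",
                    params_init = params_init, params_final = params,
                    update_count = update_count, updates_applied = updates_applied,
                    patient_id = groups[[1L]]$patient_id)
  res$scaler <- scaler
  res
}

#' Run all three protocols from one shared offline initialization
#'
#' Trains the offline model once, then runs the offline, online, and
#' online-with-penalty protocols for one patient, all warm-started from the
#' identical offline weights, and tabulates the total-days and
#' physical-activity RMSEs side by side.
#'
#' @inheritParams run_offline
#' @param pa_type The patient's activity type label for the summary table.
#' @return List with `runs` (named list of three `run_result`s), `summaries`
#'   (per-configuration [summarize_run()] rows), and `table` — the
#'   one-patient comparison from [render_comparison()].
#' @export
compare_configurations <- function(groups, events = NULL,
                                   cfg = protocol_config(),
                                   pa_type = NA_character_) {
  off_run <- run_offline(groups, events, cfg)
  cfg_on <- cfg; cfg_on$penalty_enabled <- FALSE
  cfg_pen <- cfg; cfg_pen$penalty_enabled <- TRUE
  on_run <- run_online(groups, events, cfg_on, warm_start = off_run)
  pen_run <- run_online(groups, events, cfg_pen, warm_start = off_run)
  runs <- list(offline = off_run, online = on_run, online_penalty = pen_run)
  summaries <- lapply(runs, summarize_run, pa_type = pa_type)
  tab <- render_comparison(summaries$offline, summaries$online,
                           summaries$online_penalty)
  list(runs = runs, summaries = summaries, table = tab)
}

#' Persistence baseline RMSE on a run's test set
#'
#' The naive forecast `yhat(t + PH) = y(t)` — the last observed value carried
#' forward — evaluated on exactly the same prediction records as the run.
#' This is the standard skill floor for CGM forecasting.
#'
#' @param run A `run_result`.
#' @return Scalar RMSE (mg/dL) of the persistence forecast.
#' @export
persistence_rmse <- function(run) {
  rmse(run$records$truth - run$records$y_anchor)
}

#' Write a run's predictions and summary to disk
#'
#' @param run A `run_result`.
#' @param csv_path Per-timestamp CSV (time, truth, prediction, pa_flag, group).
#' @param json_path Optional JSON summary path.
#' @return Invisibly, the CSV path.
#' @export
write_run_result <- function(run, csv_path, json_path = NULL) {
  out <- run$records
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$anchor_time <- format(out$anchor_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- summarize_run(run)
    jsonlite::write_json(list(config = run$config, patient_id = run$patient_id,
                              n_predictions = nrow(run$records),
                              update_count = run$update_count,
                              rmse_total_days = s$rmse_total_days,
                              rmse_pa = s$rmse_pa),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
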