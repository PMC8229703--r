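#' Supervised forecasting pairs from one continuous-day group
#'
#' For every anchor minute `t` with a full `M`-minute history and a realized
#' target inside the group, one pair is formed: the input window is the
#' glucose over `[t - M + 1, t]` (oldest first, current value last) and the
#' label is the glucose at `t + PH`. With a group of `N` minutes the valid
#' anchors are `t = M, ..., N - PH`, giving `N - PH - M + 1` pairs; windows
#' never span a gap because groups are gap-free by construction.
#'
#' @param group A [cgm_day_group()].
#' @param M Input window length in minutes (default 10).
#' @param PH Prediction horizon in minutes (default 30).
#' @return Object of class `windowed_dataset`: list with `inputs`
#'   (`n x M` matrix), `targets` (length `n`), `anchor_times` and
#'   `target_times` (1-based minute offsets within the group), `M`, `PH`,
#'   `origin` (the group's start `POSIXct`), `patient_id`, `group_id`.
#' @export
build_supervised_windows <- function(group, M = 10L, PH = 30L) {
  stopifnot(M >= 1L, PH >= 1L)
  N <- length(group$values)
  if (N < M + PH) {
    stop(sprintf("group %d of '%s' too short: N = %d < M + PH = %d",
                 group$group_id, group$patient_id, N, M + PH), call. = FALSE)
  }
  t <- seq.int(M, N - PH)
  ds <- list(inputs = matrix(group$values[outer(t - M, seq_len(M), "+")],
                             ncol = M),
             targets = group$values[t + PH],
             anchor_times = t,
             target_times = t + PH,
             M = as.integer(M), PH = as.integer(PH),
             origin = group$start_time,
             patient_id = group$patient_id, group_id = group$group_id)
  class(ds) <- "windowed_dataset"
  ds
}

n_windows <- function(ds) length(ds$targets)

#' Subset a windowed dataset by pair index
#'
#' @param ds A `windowed_dataset`.
#' @param idx Integer indices of pairs to keep (time order preserved).
#' @return A `windowed_dataset` with the selected pairs.
#' @export
subset_windows <- function(ds, idx) {
  ds$inputs <- ds$inputs[idx, , drop = FALSE]
  ds$targets <- ds$targets[idx]
  ds$anchor_times <- ds$anchor_times[idx]
  ds$target_times <- ds$target_times[idx]
  ds
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("Windowed dataset: %d pairs (M = %d, PH = %d) from group %d of '%s'\n",
              n_windows(x), x$M, x$PH, x$group_id, x$patient_id))
  invisible(x)
}

#' Chronological train/validation split of the first day
#'
#' Restricts the dataset to pairs whose target time falls within the first
#' `first_day_minutes` of the group, then sends the earliest
#' `floor(train_fraction * count)` pairs to the training set and the remainder
#' to validation — a strictly chronological split (no shuffling), so every
#' training anchor precedes every validation anchor.
#'
#' @param ds A `windowed_dataset` from [build_supervised_windows()].
#' @param first_day_minutes Length of the initial training day (default 1440).
#' @param train_fraction Fraction of first-day pairs used for training,
#'   strictly between 0 and 1 (default 0.8).
#' @return List with elements `train` and `validation`, both
#'   `windowed_dataset`s.
#' @export
chronological_split <- function(ds, first_day_minutes = 1440L,
                                train_fraction = 0.8) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("chronological_split(): train_fraction must be in (0, 1)", call. = FALSE)
  }
  keep <- which(ds$target_times <= first_day_minutes)
  if (length(keep) < 2L) {
    stop(sprintf("chronological_split(): only %d pair(s) inside the first %d minutes",
                 length(keep), first_day_minutes), call. = FALSE)
  }
  n_train <- floor(train_fraction * length(keep))
  if (n_train < 1L || n_train >= length(keep)) {
    stop("chronological_split(): split leaves an empty train or validation set",
         call. = FALSE)
  }
  list(train = subset_windows(ds, keep[seq_len(n_train)]),
       validation = subset_windows(ds, keep[(n_train + 1L):length(keep)]))
}
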