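#' Prediction error series
#'
#' Computes the signed forecast error `e(t) = y(t) - yhat(t)` (truth minus
#' prediction), the sign convention used throughout the package: a positive
#' error means the model under-predicted the realized glucose.
#'
#' @param truths Numeric vector of realized glucose values (mg/dL).
#' @param predictions Numeric vector of forecasts (mg/dL), same length.
#' @param times Optional timestamps matching the errors; kept as an attribute.
#' @return Numeric vector of errors in mg/dL (attribute `times` if supplied).
#' @export
error_series <- function(truths, predictions, times = NULL) {
  if (length(truths) == 0L) {
    stop("error_series(): empty input", call. = FALSE)
  }
  if (length(truths) != length(predictions)) {
    stop(sprintf("error_series(): length mismatch (%d truths vs %d predictions)",
                 length(truths), length(predictions)), call. = FALSE)
  }
  e <- as.numeric(truths) - as.numeric(predictions)
  if (!is.null(times)) {
    if (length(times) != length(e)) {
      stop("error_series(): times length must match errors", call. = FALSE)
    }
    attr(e, "times") <- times
  }
  e
}

#' Mean squared error
#'
#' @param errors Numeric vector of forecast errors (mg/dL).
#' @return Scalar MSE in (mg/dL)^2.
#' @export
mse <- function(errors) {
  if (length(errors) == 0L) stop("mse(): empty error vector", call. = FALSE)
  mean(as.numeric(errors)^2)
}

#' Root mean squared error
#'
#' @inheritParams mse
#' @return Scalar RMSE in mg/dL.
#' @export
rmse <- function(errors) {
  sqrt(mse(errors))
}

#' Piecewise penalty weight for the penalized squared-error loss
#'
#' Maps a forecast error to a nonnegative sample weight that grows with the
#' error: 0 for errors up to 5 mg/dL, 1 up to 10, 2 up to 20, and `0.5 * e`
#' beyond 20 mg/dL. Boundary values take the lower branch (the conditions are
#' inclusive on the left). Small errors are thereby ignored entirely while
#' large misses dominate the training signal ("negative reinforcement").
#'
#' By default the thresholds are applied to the error magnitude `|e|`, so a
#' large under- or over-prediction is penalized symmetrically. Setting
#' `use_magnitude = FALSE` applies the thresholds to the signed error, under
#' which any negative error falls in the first branch and gets weight 0.
#'
#' @param e Numeric vector of forecast errors (mg/dL).
#' @param use_magnitude Apply thresholds to `|e|` (default) or to signed `e`.
#' @return Numeric vector of nonnegative penalty weights (dimensionless).
#' @export
penalty <- function(e, use_magnitude = TRUE) {
  if (any(!is.finite(e))) stop("penalty(): non-finite error", call. = FALSE)
  a <- if (use_magnitude) abs(e) else as.numeric(e)
  w <- numeric(length(a))
  w[a > 5 & a <= 10] <- 1
  w[a > 10 & a <= 20] <- 2
  big <- a > 20
  w[big] <- 0.5 * a[big]
  w
}

#' Penalty-weighted squared-error loss
#'
#' The mean over samples of `e(t)^2 * penalty(e(t))`. Equals zero when every
#' error is within 5 mg/dL, and reduces to the plain MSE when every penalty
#' weight is 1.
#'
#' @inheritParams error_series
#' @param use_magnitude Passed to [penalty()].
#' @return Scalar penalized loss.
#' @export
penalized_loss <- function(truths, predictions, use_magnitude = TRUE) {
  e <- error_series(truths, predictions)
  mean(e^2 * penalty(e, use_magnitude = use_magnitude))
}
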