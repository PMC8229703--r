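#' Jump neural network parameters
#'
#' A jump network is a one-hidden-layer feed-forward regressor whose `M`
#' inputs are wired both to `L` tanh hidden neurons and directly ("jumping"
#' over the hidden layer) to the single linear output neuron:
#'
#'     yhat = IOW . I + HOW . tanh(IHW . I)  (+ biases if enabled)
#'
#' The direct input-output weights `IOW` carry the linear part of the
#' input-target relationship; the hidden path captures the nonlinear residual.
#'
#' Weights are drawn uniformly on +/- sqrt(6 / (fan_in + fan_out)) per weight
#' set (Glorot bounds); biases start at zero and are updated during training
#' only when `train_bias = TRUE`, so the default model is exactly the bias-free
#' form above.
#'
#' @param M Input width: number of past minute-grid glucose samples (default 10).
#' @param L Hidden-layer width (default 4).
#' @param seed Integer seed; the same seed yields identical parameters.
#' @param train_bias Should bias terms receive gradient updates? Default FALSE.
#' @return An object of class `jumpnet_params`: list with `IHW` (L x M),
#'   `HOW` (length L), `IOW` (length M), `hidden_bias` (length L),
#'   `output_bias` (scalar), `M`, `L`, `train_bias`, `activation = "tanh"`.
#' @export
jumpnet_params <- function(M = 10L, L = 4L, seed = 1L, train_bias = FALSE) {
  stopifnot(M >= 1L, L >= 1L)
  set.seed(seed)
  r_ihw <- sqrt(6 / (M + L))
  r_how <- sqrt(6 / (L + 1))
  r_iow <- sqrt(6 / (M + 1))
  p <- list(
    IHW = matrix(stats::runif(L * M, -r_ihw, r_ihw), nrow = L, ncol = M),
    HOW = stats::runif(L, -r_how, r_how),
    IOW = stats::runif(M, -r_iow, r_iow),
    hidden_bias = numeric(L),
    output_bias = 0,
    M = as.integer(M), L = as.integer(L),
    train_bias = isTRUE(train_bias),
    activation = "tanh"
  )
  class(p) <- "jumpnet_params"
  p
}

#' @export
print.jumpnet_params <- function(x, ...) {
  cat(sprintf("Jump network: M = %d inputs, L = %d tanh hidden neurons%s\n",
              x$M, x$L, if (x$train_bias) ", trainable biases" else ""))
  invisible(x)
}

as_input_matrix <- function(params, inputs) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  if (ncol(inputs) != params$M) {
    stop(sprintf("jumpnet: input width %d does not match M = %d",
                 ncol(inputs), params$M), call. = FALSE)
  }
  inputs
}

#' Jump network forward pass
#'
#' @param params A [jumpnet_params()] object.
#' @param inputs One input window (length-`M` vector, oldest value first,
#'   current value last) or a batch as an `n x M` matrix.
#' @return Numeric vector of `n` predicted glucose values (mg/dL).
#' @export
jumpnet_forward <- function(params, inputs) {
  X <- as_input_matrix(params, inputs)
  H <- tanh(sweep(X %*% t(params$IHW), 2L, params$hidden_bias, "+"))
  drop(X %*% params$IOW + H %*% params$HOW) + params$output_bias
}

#' Gradients of the (sample-weighted) mean squared error
#'
#' Exact analytic gradients of `(1/n) * sum_i w_i * (y_i - yhat_i)^2` with
#' respect to every parameter, by backpropagation. The sample weights are
#' treated as constants: when they come from [penalty()] evaluated at the
#' current errors, no gradient flows through the weight itself (stop-gradient
#' semantics), which keeps the objective a plain weighted least squares at
#' each step.
#'
#' @param params A [jumpnet_params()] object.
#' @param inputs `n x M` matrix (or length-`M` vector) of input windows.
#' @param targets Length-`n` vector of target glucose values (mg/dL).
#' @param sample_weights Length-`n` nonnegative weights, or a scalar recycled
#'   to the batch (default 1 = plain MSE).
#' @return List with components `IHW`, `HOW`, `IOW`, `hidden_bias`,
#'   `output_bias`, shaped like the parameters, plus the scalar `loss`.
#' @export
jumpnet_gradients <- function(params, inputs, targets, sample_weights = 1) {
  X <- as_input_matrix(params, inputs)
  n <- nrow(X)
  if (length(targets) != n) {
    stop("jumpnet_gradients(): targets length must match batch size", call. = FALSE)
  }
  w <- rep_len(as.numeric(sample_weights), n)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("jumpnet_gradients(): sample weights must be finite and >= 0", call. = FALSE)
  }
  H <- tanh(sweep(X %*% t(params$IHW), 2L, params$hidden_bias, "+"))
  yhat <- drop(X %*% params$IOW + H %*% params$HOW) + params$output_bias
  e <- as.numeric(targets) - yhat
  g <- -2 * w * e / n                      # dL/dyhat_i
  D <- (g %o% params$HOW) * (1 - H^2)      # n x L, dL/d(pre-activation)
  list(
    IHW = t(D) %*% X,
    HOW = drop(crossprod(H, g)),
    IOW = drop(crossprod(X, g)),
    hidden_bias = colSums(D),
    output_bias = sum(g),
    loss = mean(w * e^2)
  )
}

#' Elementwise gradient clipping
#'
#' Clamps every gradient component into `[-clip_value, clip_value]`
#' (`mode = "value"`, the default, matching the usual clip-by-value flag of
#' deep-learning frameworks), or rescales the whole gradient set so its global
#' L2 norm does not exceed `clip_value` (`mode = "norm"`). Clipping never
#' increases the magnitude of any component.
#'
#' @param grads Gradient list as returned by [jumpnet_gradients()].
#' @param clip_value Positive clipping threshold.
#' @param mode `"value"` (elementwise clamp) or `"norm"` (global rescale).
#' @return The clipped gradient list.
#' @export
clip_gradients <- function(grads, clip_value, mode = c("value", "norm")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(clip_value), clip_value > 0)
  sets <- c("IHW", "HOW", "IOW", "hidden_bias", "output_bias")
  if (mode == "value") {
    for (s in sets) grads[[s]] <- pmin(pmax(grads[[s]], -clip_value), clip_value)
  } else {
    nrm <- sqrt(sum(vapply(sets, function(s) sum(grads[[s]]^2), numeric(1))))
    if (nrm > clip_value) {
      for (s in sets) grads[[s]] <- grads[[s]] * (clip_value / nrm)
    }
  }
  grads
}

#' One gradient-descent update
#'
#' Decrements every trainable parameter by `learning_rate` times its gradient.
#' Bias terms are updated only when the parameter object has
#' `train_bias = TRUE`.
#'
#' @param params A [jumpnet_params()] object.
#' @param grads Gradient list from [jumpnet_gradients()] (possibly clipped).
#' @param learning_rate Nonnegative step size.
#' @return Updated `jumpnet_params`.
#' @export
sgd_step <- function(params, grads, learning_rate) {
  stopifnot(is.numeric(learning_rate), learning_rate >= 0)
  params$IHW <- params$IHW - learning_rate * grads$IHW
  params$HOW <- params$HOW - learning_rate * grads$HOW
  params$IOW <- params$IOW - learning_rate * grads$IOW
  if (params$train_bias) {
    params$hidden_bias <- params$hidden_bias - learning_rate * grads$hidden_bias
    params$output_bias <- params$output_bias - learning_rate * grads$output_bias
  }
  params
}

#' Training hyperparameters
#'
#' @param learning_rate Positive step size (default 0.1, the offline setting).
#' @param max_epochs Maximum full-batch epochs (default 500).
#' @param clip_value Elementwise gradient clip, or `NULL` to disable
#'   (default 0.3).
#' @param validation_check_every Validation MSE is evaluated every this many
#'   epochs (default 4).
#' @param patience_checks Training stops after this many consecutive
#'   validation checks without strict improvement (default 10).
#' @return A validated list of class `training_hyperparams`.
#' @export
training_hyperparams <- function(learning_rate = 0.1, max_epochs = 500L,
                                 clip_value = 0.3,
                                 validation_check_every = 4L,
                                 patience_checks = 10L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("training_hyperparams(): learning_rate must be > 0", call. = FALSE)
  }
  if (max_epochs < 1L || validation_check_every < 1L || patience_checks < 1L) {
    stop("training_hyperparams(): all counts must be >= 1", call. = FALSE)
  }
  if (!is.null(clip_value) && clip_value <= 0) {
    stop("training_hyperparams(): clip_value must be > 0 or NULL", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 clip_value = clip_value,
                 validation_check_every = as.integer(validation_check_every),
                 patience_checks = as.integer(patience_checks)),
            class = "training_hyperparams")
}

#' Offline training with early stopping
#'
#' Full-batch clipped gradient descent on the training pairs, monitoring the
#' validation MSE every `validation_check_every` epochs. Training stops when
#' the validation MSE has not strictly improved for `patience_checks`
#' consecutive checks (ties count as no improvement), or at `max_epochs`. The
#' returned parameters are the snapshot from the best validation check, not
#' the last epoch.
#'
#' With `loss = "penalized"` each sample's squared error is weighted by
#' [penalty()] evaluated at the current-epoch error (recomputed every epoch,
#' treated as a constant within the gradient). Validation is always monitored
#' in plain MSE.
#'
#' @param params Initial [jumpnet_params()].
#' @param train,val [windowed_dataset] objects (both nonempty).
#' @param hyper A [training_hyperparams()] object.
#' @param loss `"mse"` or `"penalized"`.
#' @param penalty_use_magnitude Passed to [penalty()] when `loss = "penalized"`.
#' @return List: `params` (best-validation snapshot), `history` (data frame
#'   with epoch, train loss, validation MSE — `NA` between checks),
#'   `best_epoch`, `stopped_early`.
#' @export
train_offline <- function(params, train, val, hyper = training_hyperparams(),
                          loss = c("mse", "penalized"),
                          penalty_use_magnitude = TRUE) {
  loss <- match.arg(loss)
  stopifnot(inherits(hyper, "training_hyperparams"))
  if (n_windows(train) == 0L || n_windows(val) == 0L) {
    stop("train_offline(): train and validation sets must be nonempty", call. = FALSE)
  }
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  bad_checks <- 0L
  stopped_early <- FALSE
  history <- data.frame(epoch = seq_len(hyper$max_epochs),
                        train_loss = NA_real_, val_mse = NA_real_)
  for (epoch in seq_len(hyper$max_epochs)) {
    w <- 1
    if (loss == "penalized") {
      e <- train$targets - jumpnet_forward(params, train$inputs)
      w <- penalty(e, use_magnitude = penalty_use_magnitude)
    }
    g <- jumpnet_gradients(params, train$inputs, train$targets, sample_weights = w)
    if (!is.finite(g$loss)) {
      stop(sprintf("train_offline(): training diverged (non-finite loss) at epoch %d",
                   epoch), call. = FALSE)
    }
    history$train_loss[epoch] <- g$loss
    if (!is.null(hyper$clip_value)) g <- clip_gradients(g, hyper$clip_value)
    params <- sgd_step(params, g, hyper$learning_rate)
    if (epoch %% hyper$validation_check_every == 0L) {
      vm <- mse(val$targets - jumpnet_forward(params, val$inputs))
      history$val_mse[epoch] <- vm
      if (vm < best_val) {
        best_val <- vm
        best_params <- params
        best_epoch <- epoch
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
        if (bad_checks >= hyper$patience_checks) {
          stopped_early <- TRUE
          history <- history[seq_len(epoch), , drop = FALSE]
          break
        }
      }
    }
  }
  if (best_epoch == 0L) best_params <- params  # no validation check ever ran
  list(params = best_params, history = history,
       best_epoch = best_epoch, best_val_mse = best_val,
       stopped_early = stopped_early)
}

#' Save / load network parameters as flat JSON
#'
#' The checkpoint lists the weight matrix row-major together with the layer
#' sizes and activation name, so it round-trips exactly.
#'
#' @param params A [jumpnet_params()] object.
#' @param path File path for the JSON checkpoint.
#' @return `save_jumpnet()` returns `path` invisibly; `load_jumpnet()` the
#'   restored `jumpnet_params`.
#' @export
save_jumpnet <- function(params, path) {
  x <- list(IHW = as.vector(t(params$IHW)), HOW = params$HOW, IOW = params$IOW,
            hidden_bias = params$hidden_bias, output_bias = params$output_bias,
            L = params$L, M = params$M, train_bias = params$train_bias,
            activation = params$activation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_jumpnet
#' @export
load_jumpnet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- list(IHW = matrix(x$IHW, nrow = x$L, ncol = x$M, byrow = TRUE),
            HOW = as.numeric(x$HOW), IOW = as.numeric(x$IOW),
            hidden_bias = as.numeric(x$hidden_bias),
            output_bias = as.numeric(x$output_bias),
            M = as.integer(x$M), L = as.integer(x$L),
            train_bias = isTRUE(x$train_bias), activation = x$activation)
  class(p) <- "jumpnet_params"
  p
}
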