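# Independent oracles and small fixture builders shared across the suite.

# Per-neuron forward-pass oracle: scalar products and tanh computed element
# by element, no matrix algebra.
loop_forward <- function(params, x) {
  out <- params$output_bias
  for (j in seq_len(params$M)) out <- out + params$IOW[j] * x[j]
  for (l in seq_len(params$L)) {
    pre <- params$hidden_bias[l]
    for (j in seq_len(params$M)) pre <- pre + params$IHW[l, j] * x[j]
    out <- out + params$HOW[l] * tanh(pre)
  }
  out
}

# Weighted-SSE objective with the sample weights held fixed (the stop-gradient
# semantics of the penalized loss).
wsse_objective <- function(params, X, y, w) {
  mean(w * (y - jumpnet_forward(params, X))^2)
}

# Central finite differences of wsse_objective for every scalar parameter.
fd_gradients <- function(params, X, y, w, eps = 1e-6) {
  g <- list(IHW = params$IHW * 0, HOW = params$HOW * 0, IOW = params$IOW * 0,
            hidden_bias = params$hidden_bias * 0, output_bias = 0)
  for (set in names(g)) {
    for (i in seq_along(g[[set]])) {
      up <- params; up[[set]][i] <- up[[set]][i] + eps
      dn <- params; dn[[set]][i] <- dn[[set]][i] - eps
      g[[set]][i] <- (wsse_objective(up, X, y, w) -
                        wsse_objective(dn, X, y, w)) / (2 * eps)
    }
  }
  g
}

# A day group built from an explicit value vector starting at midnight.
make_group <- function(values, patient_id = "toy", group_id = 1L,
                       day = "2021-03-01") {
  cgm_day_group(values, as.POSIXct(paste(day, "00:00:00"), tz = "UTC"),
                patient_id = patient_id, group_id = group_id)
}

# A smooth strictly positive synthetic day-group signal (no package RNG).
smooth_signal <- function(n, base = 130, amp = 40) {
  base + amp * sin(2 * pi * seq_len(n) / 480) + 10 * sin(2 * pi * seq_len(n) / 97)
}

at_minute <- function(day_start, minute) day_start + 60 * minute
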